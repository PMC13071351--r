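#' Integrate the meta-ecosystem forward in time
#'
#' Solves the coupled dynamics with an adaptive solver
#' ([deSolve::lsoda()]), which switches automatically between non-stiff
#' and stiff methods as the step-size behaviour demands; if it stalls
#' anyway, the run is retried once with the implicit BDF solver
#' ([deSolve::vode()]) before an error is raised. The trajectory is
#' recorded coarsely over the burn-in (transient) phase and densely over
#' the evaluation window `[t_transient, t_end]`, where attractor
#' classification and time averages are computed. With the default
#' `dt_eval = 1` and the baseline cycle periods of 120--160 time units the
#' window resolves oscillation extrema with >100 points per period.
#'
#' Tiny negative solver excursions (above `-1e-9`) are clipped to zero in
#' the stored states; anything more negative, or a solver failure after
#' the stiff fallback, raises an error carrying the offending parameter
#' set.
#'
#' @param params a [meta_params()] object.
#' @param topo a `meta_topology`.
#' @param x0 initial state: a [meta_state()] or flat vector of length `3n`,
#'   non-negative.
#' @param t_transient length of the discarded burn-in (time units).
#' @param t_end total integration time; must exceed `t_transient`.
#' @param dt_eval output spacing over the evaluation window.
#' @param dt_transient output spacing over the burn-in (sparse by default;
#'   only affects what is stored, not solver accuracy).
#' @param rtol,atol relative/absolute solver tolerances. Tight defaults
#'   (1e-8 / 1e-10), because spatial-heterogeneity detection compares
#'   patch averages at the 1e-3 level and the oscillation-amplitude
#'   tolerance sits at 1e-5.
#' @param engine `"compiled"` (default, C right-hand side) or `"R"`
#'   (reference implementation [meta_derivative()]); both give identical
#'   dynamics.
#' @param maxsteps solver step budget per output interval.
#' @return A `meta_trajectory`: list with `times`, `states` (rows =
#'   times, columns `N_A1, ..., C_B2`), `transient_end` (index of the
#'   first row of the evaluation window), `params`, `topo`, `solver`.
#' @examples
#' p <- meta_params(d_N = 5, d_C = 0.4)
#' topo <- nested_topology()
#' eq <- closed_equilibrium(meta_params())
#' x0 <- rep(c(eq$N, eq$P, eq$C), each = 4) * runif(12, 0.5, 1.5)
#' traj <- simulate_meta(p, topo, x0, t_transient = 200, t_end = 400)
#' @export
simulate_meta <- function(params, topo, x0,
                          t_transient = 10000, t_end = 15000,
                          dt_eval = 1, dt_transient = NULL,
                          rtol = 1e-8, atol = 1e-10,
                          engine = c("compiled", "R"),
                          maxsteps = 1e8) {
  engine <- match.arg(engine)
  bad <- validate_topology(topo, params)
  if (length(bad)) stop("invalid topology: ", paste(bad, collapse = "; "))
  y0 <- state_vector(x0)
  if (length(y0) != 3L * topo$n)
    stop("initial state has length ", length(y0),
         " but the topology needs ", 3L * topo$n)
  if (any(y0 < 0)) stop("initial state must be non-negative")
  if (t_transient >= t_end) stop("`t_transient` must be below `t_end`")

  if (is.null(dt_transient))
    dt_transient <- max(dt_eval, t_transient / 50)
  t_pre <- if (t_transient > 0)
    seq(0, t_transient, by = dt_transient) else 0
  t_eval <- seq(t_transient, t_end, by = dt_eval)
  times <- unique(c(t_pre, t_eval))

  # solver warnings are collected, not escalated: the output itself is
  # validated (completeness, finiteness, nonnegativity). When the
  # primary adaptive solver stalls, the same problem is retried with a
  # fully implicit stiff method before giving up.
  warns <- character()
  attempt <- function(solver) {
    withCallingHandlers(
      tryCatch(
        if (engine == "compiled") {
          solver(y0, times, func = "metanest_derivs",
                 dllname = "metanest", initfunc = "metanest_initmod",
                 parms = pack_parms(params, topo),
                 rtol = rtol, atol = atol, maxsteps = maxsteps)
        } else {
          rhs <- function(t, y, parms) list(meta_derivative(y, params, topo))
          solver(y0, times, rhs, parms = NULL,
                 rtol = rtol, atol = atol, maxsteps = maxsteps)
        },
        error = function(e) {
          warns <<- c(warns, conditionMessage(e))
          matrix(numeric(0), 0, 1 + length(y0))
        }),
      warning = function(w) {
        warns <<- c(warns, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
  }
  complete <- function(o) nrow(o) == length(times) && all(is.finite(o))
  out <- attempt(deSolve::lsoda)
  if (!complete(out)) out <- attempt(deSolve::vode)   # stiff fallback
  if (!complete(out))
    integration_failure(
      simpleError(paste(c("integration incomplete", unique(warns)),
                        collapse = "; ")), params)

  states <- out[, -1L, drop = FALSE]
  if (any(states < -1e-9)) integration_failure(
    simpleError(paste0("solver produced negative stocks (min ",
                       format(min(states), digits = 3), ")")), params)
  states[states < 0] <- 0
  nm <- patch_names(topo)
  colnames(states) <- c(paste0("N_", nm), paste0("P_", nm), paste0("C_", nm))

  structure(
    list(times = out[, 1L],
         states = states,
         transient_end = match(t_transient, out[, 1L]),
         params = params, topo = topo,
         solver = list(rtol = rtol, atol = atol, engine = engine)),
    class = "meta_trajectory")
}

integration_failure <- function(cond, params) {
  stop("integration failed: ", conditionMessage(cond),
       "\n  parameter set: ",
       paste(names(unlist(unclass(params))), unlist(unclass(params)),
             sep = "=", collapse = ", "),
       call. = FALSE)
}

#' Evaluation-window view of a trajectory
#'
#' @param traj a `meta_trajectory`.
#' @return List with `times` and `states` restricted to the post-transient
#'   evaluation window.
#' @export
eval_window <- function(traj) {
  idx <- seq(traj$transient_end, length(traj$times))
  list(times = traj$times[idx],
       states = traj$states[idx, , drop = FALSE])
}

#' @export
print.meta_trajectory <- function(x, ...) {
  cat("<meta_trajectory> ", x$topo$n, " patches, t in [",
      min(x$times), ", ", max(x$times), "], evaluation window from t = ",
      x$times[x$transient_end], " (", length(x$times), " samples)\n",
      sep = "")
  invisible(x)
}

#' Tidy data-frame view of a trajectory
#'
#' One row per (time, patch): columns `t`, `patch`, `type`, `location`,
#' `N`, `P`, `C`. This is also the CSV export layout.
#'
#' @param x a `meta_trajectory`.
#' @param window keep only the evaluation window?
#' @param ... unused.
#' @return A `data.frame`.
#' @export
as.data.frame.meta_trajectory <- function(x, window = FALSE, ...) {
  src <- if (window) eval_window(x) else x[c("times", "states")]
  n <- x$topo$n
  nm <- patch_names(x$topo)
  do.call(rbind, lapply(seq_len(n), function(i) {
    data.frame(t = src$times,
               patch = nm[i],
               type = x$topo$type_label[i],
               location = x$topo$location_label[i],
               N = src$states[, i],
               P = src$states[, n + i],
               C = src$states[, 2L * n + i],
               row.names = NULL)
  }))
}

#' @rdname as.data.frame.meta_trajectory
#' @param traj a `meta_trajectory`.
#' @param path output CSV path.
#' @export
write_trajectory_csv <- function(traj, path) {
  utils::write.csv(as.data.frame(traj), path, row.names = FALSE)
  invisible(path)
}

#' Seeded ensemble of random initial conditions
#'
#' Draws `n_draws` independent initial states, each patch-compartment
#' sampled uniformly between the range bounds for its compartment. The
#' default ranges span (0, 2 x closed-ecosystem equilibrium] per
#' compartment, which brackets the attractors at baseline rates and
#' reliably discovers both branches of the bistable heterogeneous
#' equilibrium. Identical seeds give identical ensembles.
#'
#' @param seed integer RNG seed (mandatory; no silent nondeterminism).
#' @param n_draws number of initial states (>= 1).
#' @param params parameter set used to derive the default ranges.
#' @param n_patches patch count of the target topology.
#' @param ranges optional named list `list(N = c(lo, hi), P = ..., C = ...)`
#'   overriding the defaults; bounds must satisfy `0 <= lo < hi`.
#' @return An `ic_ensemble`: list with `seed`, `ranges`, and `draws` (a
#'   list of flat state vectors, all strictly positive).
#' @examples
#' ens <- sample_initial_conditions(seed = 1, n_draws = 50)
#' length(ens$draws)
#' @export
sample_initial_conditions <- function(seed, n_draws = 50,
                                      params = meta_params(),
                                      n_patches = 4, ranges = NULL) {
  if (missing(seed) || !is.finite(seed))
    stop("`seed` is mandatory for initial-condition ensembles")
  if (n_draws < 1) stop("`n_draws` must be at least 1")
  if (is.null(ranges)) {
    eq <- closed_equilibrium(params)
    ranges <- list(N = c(0, 2 * eq$N), P = c(0, 2 * eq$P), C = c(0, 2 * eq$C))
  }
  for (nm in c("N", "P", "C")) {
    r <- ranges[[nm]]
    if (is.null(r) || length(r) != 2L || r[2] <= 0 || r[1] < 0 || r[1] >= r[2])
      stop("range for ", nm, " must be c(lo, hi) with 0 <= lo < hi")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  draws <- lapply(seq_len(n_draws), function(k) {
    y <- c(stats::runif(n_patches, ranges$N[1], ranges$N[2]),
           stats::runif(n_patches, ranges$P[1], ranges$P[2]),
           stats::runif(n_patches, ranges$C[1], ranges$C[2]))
    # strictly positive draws: a zero draw has probability zero but would
    # start a compartment on an invariant boundary
    y[y == 0] <- .Machine$double.eps
    y
  })
  structure(list(seed = as.integer(seed), ranges = ranges, draws = draws),
            class = "ic_ensemble")
}
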