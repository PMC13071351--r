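#' Classify the long-term dynamics of a trajectory
#'
#' Assigns the qualitative state of the attractor reached over the
#' evaluation window, along two axes:
#'
#' * **kind** -- `"equilibrium"` if every state variable's peak-to-peak
#'   amplitude over the window is below `tol_eq`, else `"oscillation"`.
#' * **spatial** -- `"heterogeneous"` if, for any compartment, the spread
#'   of time-averaged stocks across patches of the same ecosystem type
#'   exceeds `tol_het`, else `"homogeneous"`. Averages are used so that
#'   heterogeneous oscillations are detected even when patches cycle with
#'   equal amplitude around different means. A secondary criterion catches
#'   the converse case (equal means, unequal cycles): a spread of
#'   per-patch peak-to-peak amplitudes across same-type patches exceeding
#'   both `tol_het` and 5 percent of the largest amplitude also counts as
#'   heterogeneous; the relative floor keeps extremum-sampling noise on
#'   synchronized cycles from triggering it.
#'
#' The two axes combine into the state codes `HOM_EQ`, `HOM_OSC`,
#' `HET_OSC`, `HET_EQ`. For oscillatory windows a dominant period is
#' estimated from upward mean-crossings of the meta-level consumer stock;
#' if the window is shorter than two periods the report is flagged
#' inconclusive rather than silently labelled. A phase diagnostic (the
#' cross-correlation lag between same-type consumer series) is recorded
#' but does not affect the label.
#'
#' Tolerance defaults: `tol_eq = 1e-5` sits above the solver's amplitude
#' noise floor (about 3e-6 at the default tolerances) and far below the
#' order-one amplitude of the model's limit cycles; `tol_het = 1e-3` sits
#' far below the order-one stock differences of the heterogeneous states
#' and above the residual spread left by slowly decaying symmetric
#' transients at the default sweep horizon. Both are configurable; the
#' methods vignette discusses the choice.
#'
#' @param traj a `meta_trajectory` from [simulate_meta()].
#' @param tol_eq absolute peak-to-peak amplitude below which a variable
#'   counts as constant.
#' @param tol_het absolute spread of time-averaged stocks across same-type
#'   patches above which the state counts as spatially heterogeneous.
#' @param n_windows number of equal sub-windows used for the convergence
#'   diagnostics stored in the report.
#' @return An `attractor_report`: list with `kind`, `spatial`,
#'   `state_code`, `inconclusive`, per-column `mean`/`min`/`max`,
#'   `het_spread`, `amplitude`, `meta_C_range`, `period`, `phase_lag`,
#'   and per-sub-window diagnostic series.
#' @seealso [classify_ensemble()]
#' @export
classify_trajectory <- function(traj, tol_eq = 1e-5, tol_het = 1e-3,
                                n_windows = 8) {
  w <- eval_window(traj)
  if (length(w$times) < 3L)
    stop("evaluation window is empty or too short to classify")
  topo <- traj$topo
  n <- topo$n

  mins <- apply(w$states, 2, min)
  maxs <- apply(w$states, 2, max)
  means <- apply(w$states, 2, function(z) trapezoid_mean(w$times, z))
  amp <- max(maxs - mins)
  kind <- if (amp < tol_eq) "equilibrium" else "oscillation"

  het <- same_type_spread(means, topo)
  amp_spread <- same_type_spread(maxs - mins, topo)
  spatial <- if (het > tol_het ||
                 (amp_spread > tol_het && amp_spread > 0.05 * amp))
    "heterogeneous" else "homogeneous"

  metaC <- rowSums(w$states[, 2L * n + seq_len(n), drop = FALSE])
  period <- NA_real_
  inconclusive <- FALSE
  if (kind == "oscillation") {
    period <- dominant_period(w$times, metaC)
    span <- max(w$times) - min(w$times)
    if (is.na(period) || span < 2 * period) inconclusive <- TRUE
  }

  # sub-window convergence diagnostics
  idx <- floor(seq(1L, length(w$times), length.out = n_windows + 1L))
  sub_het <- sub_amp <- numeric(n_windows)
  for (k in seq_len(n_windows)) {
    rows <- idx[k]:idx[k + 1L]
    m_k <- apply(w$states[rows, , drop = FALSE], 2,
                 function(z) trapezoid_mean(w$times[rows], z))
    sub_het[k] <- same_type_spread(m_k, topo)
    sub_amp[k] <- max(apply(w$states[rows, , drop = FALSE], 2,
                            function(z) diff(range(z))))
  }

  structure(
    list(kind = kind, spatial = spatial,
         state_code = state_code(kind, spatial),
         inconclusive = inconclusive,
         mean = means, min = mins, max = maxs,
         amplitude = amp, het_spread = het, amp_spread = amp_spread,
         meta_C_range = range(metaC),
         period = period,
         phase_lag = same_type_phase_lag(w, topo, period),
         sub_het = sub_het, sub_amp = sub_amp,
         tol = c(eq = tol_eq, het = tol_het),
         attractor_id = NA_integer_),
    class = "attractor_report")
}

state_code <- function(kind, spatial) {
  paste0(if (spatial == "homogeneous") "HOM" else "HET", "_",
         if (kind == "equilibrium") "EQ" else "OSC")
}

trapezoid_mean <- function(t, z) {
  dt <- diff(t)
  sum(dt * (z[-length(z)] + z[-1]) / 2) / (t[length(t)] - t[1])
}

# max over compartments and types of the spread of per-patch averages
same_type_spread <- function(means, topo) {
  n <- topo$n
  spread <- 0
  for (comp in 0:2) for (ty in unique(topo$type_label)) {
    v <- means[comp * n + which(topo$type_label == ty)]
    spread <- max(spread, diff(range(v)))
  }
  spread
}

# period from upward crossings of the centred series; NA if < 3 crossings
dominant_period <- function(t, z) {
  zc <- z - mean(z)
  if (max(abs(zc)) == 0) return(NA_real_)
  up <- which(zc[-length(zc)] < 0 & zc[-1] >= 0)
  if (length(up) < 3L) return(NA_real_)
  mean(diff(t[up]))
}

# cross-correlation lag (time units) between the consumer series of the
# first same-type patch pair; diagnostic only
same_type_phase_lag <- function(w, topo, period) {
  if (is.na(period)) return(NA_real_)
  ty <- topo$type_label[1]
  pair <- which(topo$type_label == ty)[1:2]
  n <- topo$n
  a <- w$states[, 2L * n + pair[1]]; b <- w$states[, 2L * n + pair[2]]
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(NA_real_)
  dt <- stats::median(diff(w$times))
  lag_max <- min(ceiling(period / dt), floor(length(a) / 3))
  cc <- stats::ccf(a, b, lag.max = lag_max, plot = FALSE)
  cc$lag[which.max(cc$acf)] * dt
}

#' @export
print.attractor_report <- function(x, ...) {
  cat("<attractor_report> ", x$state_code,
      if (x$inconclusive) " (inconclusive)", "\n",
      "  max amplitude ", format(x$amplitude, digits = 3),
      ", same-type spread ", format(x$het_spread, digits = 3), "\n", sep = "")
  invisible(x)
}

#' Ensemble verdict across initial conditions
#'
#' Groups the attractor reports of an initial-condition ensemble into
#' distinct attractors (time-averaged stocks matching within `match_tol`),
#' determines the consensus state, and flags bistability when two
#' attractors are mirror images under the location-swap symmetry.
#'
#' The consensus is the common state code when every conclusive report
#' agrees; disagreement yields `"MIXED"` (typically a cell on a state
#' boundary). Inconclusive reports are counted and excluded from the
#' consensus, never silently dropped. Attractors are counted *before*
#' symmetry reduction, so a bistable mirror pair counts as two attractors
#' with `bistable = TRUE`.
#'
#' @param reports list of `attractor_report`s from the same parameter set.
#' @param match_tol relative tolerance for grouping reports into one
#'   attractor, applied to time-averaged stocks after canonicalizing by
#'   the location swap that puts the larger type-A producer average at
#'   location 1.
#' @param topo the `meta_topology` the reports refer to; needed for the
#'   mirror detection (taken from the first report's dimensions when the
#'   ensemble was built by [run_ensemble()]).
#' @return An `ensemble_verdict`: list with `state_code`, `n_attractors`,
#'   `bistable`, `n_inconclusive`, `attractors` (data frame of group
#'   sizes and mean stocks) and `members` (group index per report).
#' @export
classify_ensemble <- function(reports, match_tol = 1e-3, topo) {
  if (length(reports) < 2L)
    stop("an ensemble verdict needs at least 2 reports")
  concl <- !vapply(reports, `[[`, logical(1), "inconclusive")
  codes <- vapply(reports, `[[`, character(1), "state_code")
  state <- if (!any(concl)) "INCONCLUSIVE"
           else if (length(unique(codes[concl])) == 1L) unique(codes[concl])
           else "MIXED"

  means <- do.call(rbind, lapply(reports, `[[`, "mean"))
  scale <- max(abs(means), 1e-8)
  group <- integer(nrow(means))
  for (i in seq_len(nrow(means))) {
    hit <- 0L
    for (g in seq_len(max(group))) {
      rep_g <- means[which(group == g)[1L], ]
      if (max(abs(means[i, ] - rep_g)) <= match_tol * scale) { hit <- g; break }
    }
    group[i] <- if (hit) hit else max(group) + 1L
  }
  n_att <- max(group)

  # mirror detection: two groups whose stocks match after a location swap
  bistable <- FALSE
  if (n_att >= 2L && length(sort(unique(topo$location_label))) == 2L) {
    perm <- location_swap(topo)
    swap_cols <- c(perm, topo$n + perm, 2L * topo$n + perm)
    reps <- means[match(seq_len(n_att), group), , drop = FALSE]
    for (g1 in seq_len(n_att - 1L)) for (g2 in (g1 + 1L):n_att) {
      if (max(abs(reps[g1, swap_cols] - reps[g2, ])) <= match_tol * scale)
        bistable <- TRUE
    }
  }

  att <- data.frame(attractor = seq_len(n_att),
                    n_members = tabulate(group, n_att),
                    state_code = vapply(seq_len(n_att), function(g)
                      codes[which(group == g)[1L]], character(1)))
  att <- cbind(att, as.data.frame(
    means[match(seq_len(n_att), group), , drop = FALSE]))

  structure(list(state_code = state,
                 n_attractors = n_att,
                 bistable = bistable,
                 n_inconclusive = sum(!concl),
                 attractors = att,
                 members = group),
            class = "ensemble_verdict")
}

#' @export
print.ensemble_verdict <- function(x, ...) {
  cat("<ensemble_verdict> ", x$state_code, ", ", x$n_attractors,
      " attractor(s)", if (x$bistable) ", bistable",
      if (x$n_inconclusive) paste0(", ", x$n_inconclusive, " inconclusive"),
      "\n", sep = "")
  invisible(x)
}

#' Serialize an ensemble verdict to JSON
#'
#' @param verdict an `ensemble_verdict`.
#' @param path optional output path; when `NULL` the JSON string is
#'   returned.
#' @return The JSON string (invisibly when written to a file).
#' @export
verdict_to_json <- function(verdict, path = NULL) {
  x <- list(state_code = verdict$state_code,
            n_attractors = verdict$n_attractors,
            bistable = verdict$bistable,
            n_inconclusive = verdict$n_inconclusive)
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

#' Run and classify a whole initial-condition ensemble
#'
#' Convenience wrapper implementing the stable-state protocol for one
#' parameter set: draw a seeded ensemble, integrate each draw, classify
#' each trajectory, and return the ensemble verdict together with the
#' per-draw reports and one representative trajectory per attractor.
#'
#' @param params a [meta_params()] object.
#' @param topo a `meta_topology`.
#' @param seed RNG seed for the ensemble.
#' @param n_ic ensemble size.
#' @param t_transient,t_end,dt_eval,rtol,atol passed to [simulate_meta()].
#' @param tol_eq,tol_het,n_windows passed to [classify_trajectory()].
#' @param match_tol passed to [classify_ensemble()].
#' @param keep_trajectories keep a representative `meta_trajectory` per
#'   attractor (needed by the metrics pipeline)?
#' @return List with `verdict`, `reports`, and (optionally)
#'   `representatives` (named by attractor index).
#' @export
run_ensemble <- function(params, topo, seed, n_ic = 50,
                         t_transient = 10000, t_end = 15000, dt_eval = 1,
                         rtol = 1e-8, atol = 1e-10,
                         tol_eq = 1e-5, tol_het = 1e-3, n_windows = 8,
                         match_tol = 1e-3, keep_trajectories = FALSE) {
  ens <- sample_initial_conditions(seed, n_ic, params = strip_flows(params),
                                   n_patches = topo$n)
  trajs <- vector("list", n_ic)
  reports <- vector("list", n_ic)
  for (k in seq_len(n_ic)) {
    tr <- simulate_meta(params, topo, ens$draws[[k]],
                        t_transient = t_transient, t_end = t_end,
                        dt_eval = dt_eval, rtol = rtol, atol = atol)
    reports[[k]] <- classify_trajectory(tr, tol_eq = tol_eq,
                                        tol_het = tol_het,
                                        n_windows = n_windows)
    if (keep_trajectories) trajs[[k]] <- tr
  }
  verdict <- classify_ensemble(reports, match_tol = match_tol, topo = topo)
  out <- list(verdict = verdict, reports = reports)
  if (keep_trajectories) {
    first_of <- match(seq_len(verdict$n_attractors), verdict$members)
    out$representatives <- stats::setNames(trajs[first_of],
                                           seq_len(verdict$n_attractors))
  }
  out
}

# default IC ranges must not depend on the swept spatial rates
strip_flows <- function(params) {
  q <- unclass(params)
  q$d_N <- 0; q$d_C <- 0; q$d_P <- 0
  do.call(meta_params, q)
}
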