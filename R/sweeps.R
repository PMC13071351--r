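#' Specification of a sweep experiment
#'
#' Collects everything a sweep needs: the topology, the grid axes, the
#' ensemble protocol and the numerical tolerances. The long default
#' horizon (`t_transient = 1e6`, evaluation window of 2e4 time units) is
#' what the state classification requires: near the symmetry-breaking
#' threshold, symmetric transients decay with time constants of 1e5--1e6
#' time units, so short burn-ins would report transient asymmetry as
#' spatial heterogeneity (see the methods vignette).
#'
#' @param topology `"nested"` or `"fully_connected"`.
#' @param d_N numeric vector: resource-flow axis (or a single value).
#' @param d_C numeric vector: dispersal axis, equal rates for both types.
#'   For ecosystem-specific rates use `d_CA` and `d_CB` instead.
#' @param d_CA,d_CB numeric vectors for type-specific dispersal axes
#'   (used by [dispersal_plane()]).
#' @param n_ic ensemble size per grid cell (the replication protocol uses
#'   50; transect-scale work uses 10).
#' @param seed base RNG seed; each cell derives its own sub-seed from it,
#'   so grids are reproducible cell by cell and independent of execution
#'   order.
#' @param n_locations passed to the topology builder.
#' @param normalization connectivity normalization, see [meta_topology()].
#' @param params local parameter set (spatial rates are taken from the
#'   grid axes, not from this object).
#' @param t_transient,t_window,dt_eval integration protocol: burn-in,
#'   evaluation-window length, output spacing.
#' @param rtol,atol solver tolerances.
#' @param tol_eq,tol_het,match_tol classification tolerances, see
#'   [classify_trajectory()] and [classify_ensemble()].
#' @param out_dir optional directory for incremental CSV output and the
#'   JSON run manifest; cells already present in an existing output file
#'   are skipped, making interrupted sweeps resumable.
#' @return A `sweep_spec` list.
#' @seealso [state_diagram()], [bifurcation_transect()],
#'   [dispersal_plane()], [functions_transect()], [replication_preset()]
#' @export
sweep_spec <- function(topology = c("nested", "fully_connected"),
                       d_N = seq(0, 5, by = 0.05),
                       d_C = 0.4, d_CA = NULL, d_CB = NULL,
                       n_ic = 10, seed = 1,
                       n_locations = 2,
                       normalization = "donor_split",
                       params = meta_params(),
                       t_transient = 1e6, t_window = 2e4, dt_eval = 1,
                       rtol = 1e-8, atol = 1e-10,
                       tol_eq = 1e-5, tol_het = 1e-3, match_tol = 1e-3,
                       out_dir = NULL) {
  topology <- match.arg(topology)
  if (!is.null(d_CA) || !is.null(d_CB)) {
    if (is.null(d_CA) || is.null(d_CB))
      stop("supply both `d_CA` and `d_CB` axes (or neither)")
  }
  stopifnot(length(d_N) >= 1, all(d_N >= 0), n_ic >= 1,
            t_transient > 0, t_window > 0, dt_eval > 0)
  if (missing(seed)) stop("`seed` is mandatory in sweep specs")
  structure(list(topology = topology, d_N = d_N, d_C = d_C,
                 d_CA = d_CA, d_CB = d_CB,
                 n_ic = n_ic, seed = as.integer(seed),
                 n_locations = n_locations, normalization = normalization,
                 params = params,
                 t_transient = t_transient, t_window = t_window,
                 dt_eval = dt_eval, rtol = rtol, atol = atol,
                 tol_eq = tol_eq, tol_het = tol_het, match_tol = match_tol,
                 out_dir = out_dir),
            class = "sweep_spec")
}

build_topology <- function(spec) {
  builder <- switch(spec$topology,
                    nested = nested_topology,
                    fully_connected = fully_connected_topology)
  builder(spec$n_locations, spec$normalization)
}

cell_seed <- function(base, index) {
  as.integer((as.double(base) + 104729 * as.double(index)) %% 2147483647)
}

cell_params <- function(spec, d_N, d_CA, d_CB) {
  q <- unclass(spec$params)
  q$d_N <- d_N
  q$d_C <- c(A = d_CA, B = d_CB)
  do.call(meta_params, q)
}

run_cell <- function(spec, topo, d_N, d_CA, d_CB, index,
                     keep_trajectories = FALSE) {
  params <- cell_params(spec, d_N, d_CA, d_CB)
  run_ensemble(params, topo, seed = cell_seed(spec$seed, index),
               n_ic = spec$n_ic,
               t_transient = spec$t_transient,
               t_end = spec$t_transient + spec$t_window,
               dt_eval = spec$dt_eval,
               rtol = spec$rtol, atol = spec$atol,
               tol_eq = spec$tol_eq, tol_het = spec$tol_het,
               match_tol = spec$match_tol,
               keep_trajectories = keep_trajectories)
}

# shared driver: iterate cells row-major, classify, bind rows; failures are
# logged and coded FAILED, never aborting the grid
sweep_cells <- function(spec, cells, collect, out_file = NULL) {
  topo <- build_topology(spec)
  done <- NULL
  if (!is.null(out_file) && file.exists(out_file)) {
    done <- utils::read.csv(out_file)
    message("resuming: ", nrow(done), " cells already in ", out_file)
  }
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    key <- cells[k, , drop = FALSE]
    if (!is.null(done) &&
        nrow(merge(done, key)) > 0) next
    row <- tryCatch(
      collect(spec, topo, key, k),
      error = function(e) {
        message("cell ", k, " (",
                paste(names(key), unlist(key), sep = "=", collapse = ", "),
                ") FAILED: ", conditionMessage(e))
        cbind(key, state_code = "FAILED", n_attractors = NA_integer_,
              bistable = NA, n_inconclusive = NA_integer_)
      })
    rows[[k]] <- row
    if (!is.null(out_file))
      utils::write.table(row, out_file, sep = ",", append = file.exists(out_file),
                         col.names = !file.exists(out_file),
                         row.names = FALSE, qmethod = "double")
  }
  out <- do.call(rbind_fill, rows[!vapply(rows, is.null, logical(1))])
  if (!is.null(done)) out <- rbind_fill(done, out)
  out[do.call(order, out[intersect(c("d_N", "d_CA", "d_CB"), names(out))]), ,
      drop = FALSE]
}

rbind_fill <- function(...) {
  dfs <- list(...)
  cols <- unique(unlist(lapply(dfs, names)))
  do.call(rbind, lapply(dfs, function(d) {
    for (nm in setdiff(cols, names(d))) d[[nm]] <- NA
    d[cols]
  }))
}

#' State diagram over resource-flow and dispersal rates
#'
#' Runs the stable-state protocol (seeded initial-condition ensemble,
#' long integration, per-trajectory classification, ensemble consensus)
#' on every `(d_N, d_C)` grid cell and returns the qualitative state of
#' each cell. Deterministic given the spec's seed; failed cells are coded
#' `FAILED` and the grid continues.
#'
#' @param spec a [sweep_spec()] with `d_N` and `d_C` axes.
#' @return Data frame: `d_N`, `d_CA`, `d_CB`, `state_code`,
#'   `n_attractors`, `bistable`, `n_inconclusive`.
#' @export
state_diagram <- function(spec) {
  cells <- expand.grid(d_CA = spec$d_C, d_N = spec$d_N,
                       KEEP.OUT.ATTRS = FALSE)[, c("d_N", "d_CA")]
  cells$d_CB <- cells$d_CA
  out_file <- sweep_out_file(spec, "state_diagram")
  collect <- function(spec, topo, key, k) {
    res <- run_cell(spec, topo, key$d_N, key$d_CA, key$d_CB, k)
    cbind(key, verdict_row(res$verdict))
  }
  res <- sweep_cells(spec, cells, collect, out_file)
  write_manifest(spec, "state_diagram")
  res
}

verdict_row <- function(v) {
  data.frame(state_code = v$state_code, n_attractors = v$n_attractors,
             bistable = v$bistable, n_inconclusive = v$n_inconclusive)
}

#' Bifurcation transect along the resource-flow rate
#'
#' Fixes the dispersal rate and sweeps `d_N`, recording for each cell the
#' consensus state and the meta-level consumer minimum and maximum over
#' the evaluation window (taken from the representative trajectory of the
#' largest attractor group) -- the data behind a bifurcation diagram. At
#' equilibrium cells minimum and maximum coincide.
#'
#' @param spec a [sweep_spec()]; `d_C` must be a single value.
#' @return Data frame: `d_N`, `d_CA`, `d_CB`, `C_meta_min`, `C_meta_max`,
#'   `state_code`, `n_attractors`, `bistable`, `n_inconclusive`.
#' @export
bifurcation_transect <- function(spec) {
  if (length(spec$d_C) != 1L)
    stop("a bifurcation transect fixes `d_C` at a single value")
  cells <- data.frame(d_N = spec$d_N, d_CA = spec$d_C, d_CB = spec$d_C)
  out_file <- sweep_out_file(spec, "bifurcation")
  collect <- function(spec, topo, key, k) {
    res <- run_cell(spec, topo, key$d_N, key$d_CA, key$d_CB, k)
    big <- which.max(res$verdict$attractors$n_members)
    rep_report <- res$reports[[match(big, res$verdict$members)]]
    cbind(key,
          C_meta_min = rep_report$meta_C_range[1],
          C_meta_max = rep_report$meta_C_range[2],
          verdict_row(res$verdict))
  }
  res <- sweep_cells(spec, cells, collect, out_file)
  write_manifest(spec, "bifurcation")
  res
}

#' State plane over ecosystem-specific dispersal rates
#'
#' Fixes `d_N` and sweeps the two type-specific dispersal rates
#' `(d_CA, d_CB)` independently -- the experiment showing that the
#' dispersal rate of either ecosystem type can gate the emergence of the
#' cross-scale source-sink state.
#'
#' @param spec a [sweep_spec()] with a single `d_N` value and `d_CA`,
#'   `d_CB` axes.
#' @return Data frame as for [state_diagram()].
#' @export
dispersal_plane <- function(spec) {
  if (length(spec$d_N) != 1L)
    stop("a dispersal plane fixes `d_N` at a single value")
  if (is.null(spec$d_CA) || is.null(spec$d_CB))
    stop("supply `d_CA` and `d_CB` axes in the spec")
  cells <- expand.grid(d_CB = spec$d_CB, d_CA = spec$d_CA,
                       KEEP.OUT.ATTRS = FALSE)[, c("d_CA", "d_CB")]
  cells <- cbind(d_N = spec$d_N, cells)
  out_file <- sweep_out_file(spec, "dispersal_plane")
  collect <- function(spec, topo, key, k) {
    res <- run_cell(spec, topo, key$d_N, key$d_CA, key$d_CB, k)
    cbind(key, verdict_row(res$verdict))
  }
  res <- sweep_cells(spec, cells, collect, out_file)
  write_manifest(spec, "dispersal_plane")
  res
}

#' Local and meta-ecosystem functions along a resource-flow transect
#'
#' For each `d_N` on the transect, runs the ensemble protocol, keeps one
#' representative trajectory per attractor, and tabulates per-patch net
#' flows, production, retention and the net trophic effect `E_i` (against
#' an uncoupled reference run computed once, since the local parameters do
#' not change along the transect), together with the meta-level totals.
#'
#' @param spec a [sweep_spec()]; `d_C` must be a single value.
#' @return List of two data frames, `local` (one row per `d_N` x attractor
#'   x patch) and `meta` (one row per `d_N` x attractor).
#' @export
functions_transect <- function(spec) {
  if (length(spec$d_C) != 1L)
    stop("a functions transect fixes `d_C` at a single value")
  topo <- build_topology(spec)
  ref <- reference_run(spec, topo)
  loc <- list(); met <- list()
  for (k in seq_along(spec$d_N)) {
    dn <- spec$d_N[k]
    res <- tryCatch(
      run_cell(spec, topo, dn, spec$d_C, spec$d_C, k,
               keep_trajectories = TRUE),
      error = function(e) {
        message("d_N = ", dn, " FAILED: ", conditionMessage(e)); NULL
      })
    if (is.null(res)) next
    for (a in seq_along(res$representatives)) {
      s <- flux_function_summary(res$representatives[[a]], ref)
      key <- data.frame(d_N = dn, d_CA = spec$d_C, d_CB = spec$d_C,
                        attractor = a,
                        state_code = res$verdict$attractors$state_code[a])
      loc[[length(loc) + 1L]] <- cbind(key, s$local)
      met[[length(met) + 1L]] <- cbind(key, s$meta)
    }
  }
  out <- list(local = do.call(rbind, loc), meta = do.call(rbind, met))
  if (!is.null(spec$out_dir)) {
    dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.csv(out$local,
                     file.path(spec$out_dir, "functions_local.csv"),
                     row.names = FALSE)
    utils::write.csv(out$meta,
                     file.path(spec$out_dir, "functions_meta.csv"),
                     row.names = FALSE)
    write_manifest(spec, "functions")
  }
  out
}

# uncoupled reference trajectory for E_i; the uncoupled system converges
# fast, so a shorter burn-in suffices
reference_run <- function(spec, topo) {
  params0 <- cell_params(spec, 0, 0, 0)
  ens <- sample_initial_conditions(cell_seed(spec$seed, 0L), 1,
                                   params = strip_flows(params0),
                                   n_patches = topo$n)
  simulate_meta(params0, topo, ens$draws[[1]],
                t_transient = min(spec$t_transient, 5e4),
                t_end = min(spec$t_transient, 5e4) + spec$t_window,
                dt_eval = spec$dt_eval,
                rtol = spec$rtol, atol = spec$atol)
}

#' Threshold extraction from sweep tables
#'
#' `state_threshold()` returns the smallest `d_N` whose consensus state
#' matches one of `codes`; `heterogeneity_threshold()` is the common case
#' of the smallest `d_N` classified spatially heterogeneous (oscillatory
#' or not). `NA` if no cell matches.
#'
#' @param df a data frame from [state_diagram()] or
#'   [bifurcation_transect()].
#' @param codes character vector of state codes to match.
#' @param axis column to minimize over (default `"d_N"`).
#' @return A single numeric value or `NA`.
#' @export
state_threshold <- function(df, codes, axis = "d_N") {
  hit <- df[[axis]][df$state_code %in% codes]
  if (!length(hit)) NA_real_ else min(hit)
}

#' @rdname state_threshold
#' @export
heterogeneity_threshold <- function(df, axis = "d_N") {
  state_threshold(df, c("HET_OSC", "HET_EQ"), axis)
}

sweep_out_file <- function(spec, what) {
  if (is.null(spec$out_dir)) return(NULL)
  dir.create(spec$out_dir, showWarnings = FALSE, recursive = TRUE)
  file.path(spec$out_dir, paste0(what, ".csv"))
}

write_manifest <- function(spec, what) {
  if (is.null(spec$out_dir)) return(invisible(NULL))
  manifest <- list(
    sweep = what,
    package_version = as.character(utils::packageVersion("metanest")),
    timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
    topology = spec$topology,
    normalization = spec$normalization,
    axes = list(d_N = spec$d_N, d_C = spec$d_C,
                d_CA = spec$d_CA, d_CB = spec$d_CB),
    ensemble = list(n_ic = spec$n_ic, seed = spec$seed),
    protocol = list(t_transient = spec$t_transient,
                    t_window = spec$t_window, dt_eval = spec$dt_eval,
                    rtol = spec$rtol, atol = spec$atol,
                    tol_eq = spec$tol_eq, tol_het = spec$tol_het,
                    match_tol = spec$match_tol),
    params = params_to_list(spec$params))
  path <- file.path(spec$out_dir, paste0(what, "_manifest.json"))
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Replication presets
#'
#' Ready-made [sweep_spec()]s for the package's replication experiments:
#'
#' * `"states_nested"` / `"states_control"`: state diagrams over
#'   `(d_N, d_C)` for the nested and fully connected topologies.
#' * `"transect_nested"` / `"transect_control"`: bifurcation transects at
#'   a fixed dispersal rate (`d_C` argument; 0.4 by default, 0.1 being
#'   the other canonical choice).
#' * `"functions"`: local/meta function transect at `d_C = 0.4`.
#' * `"dispersal_plane"`: ecosystem-specific dispersal plane at `d_N = 5`.
#' * `"ci"`: a small, fast smoke-test grid (8 initial conditions, coarse
#'   axes). With so few initial conditions bistability discovery is not
#'   guaranteed; use the full presets for science.
#'
#' Resource-flow axes extend to an order of magnitude above the dispersal
#' rates, reflecting the scale contrast between the two flow types. The
#' exact axis extents are editable: presets return ordinary specs.
#'
#' @param name preset name.
#' @param seed base seed.
#' @param d_C dispersal rate for the transect presets.
#' @param n_ic override the ensemble size.
#' @param out_dir optional output directory.
#' @return A [sweep_spec()].
#' @export
replication_preset <- function(name = c("states_nested", "states_control",
                                  "transect_nested", "transect_control",
                                  "functions", "dispersal_plane", "ci"),
                         seed = 1, d_C = 0.4, n_ic = NULL,
                         out_dir = NULL) {
  name <- match.arg(name)
  spec <- switch(name,
    states_nested = sweep_spec("nested", d_N = seq(0, 5, by = 0.05),
                       d_C = seq(0.02, 0.5, by = 0.02), n_ic = 50,
                       seed = seed),
    states_control = sweep_spec("fully_connected", d_N = seq(0, 5, by = 0.05),
                       d_C = seq(0.02, 0.5, by = 0.02), n_ic = 50,
                       seed = seed),
    transect_nested = sweep_spec("nested", d_N = seq(0, 5, by = 0.05), d_C = d_C,
                       n_ic = 50, seed = seed),
    transect_control = sweep_spec("fully_connected", d_N = seq(0, 5, by = 0.05),
                       d_C = d_C, n_ic = 50, seed = seed),
    functions = sweep_spec("nested", d_N = seq(0, 5, by = 0.05), d_C = 0.4,
                        n_ic = 50, seed = seed),
    dispersal_plane = sweep_spec("nested", d_N = 5,
                      d_CA = seq(0.02, 0.5, by = 0.02),
                      d_CB = seq(0.02, 0.5, by = 0.02),
                      n_ic = 50, seed = seed),
    ci = sweep_spec("nested", d_N = c(0.5, 3, 5), d_C = 0.4, n_ic = 8,
                    seed = seed, t_transient = 2e5, t_window = 1e4))
  if (!is.null(n_ic)) spec$n_ic <- n_ic
  spec$out_dir <- out_dir
  spec
}
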