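#' Read a run configuration file
#'
#' Run configs are YAML (or JSON) documents with up to three sections:
#' `params` (flat key-value parameter block, unknown keys are an error),
#' `topology` (either a builder shorthand
#' `list(builder = "nested", n_locations = 2, normalization = ...)` or an
#' explicit matrix block as written by [topology_to_list()]), and `sweep`
#' (arguments for [sweep_spec()]). Seeds are mandatory wherever an
#' ensemble is requested; a config without one fails rather than running
#' irreproducibly.
#'
#' @param path path to the YAML/JSON config.
#' @return List with `params` ([meta_params()]), `topology`
#'   (`meta_topology` or `NULL`), and `sweep` (a [sweep_spec()] or
#'   `NULL`).
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  out <- list(params = NULL, topology = NULL, sweep = NULL)
  if (!is.null(cfg$params)) out$params <- params_from_list(cfg$params)
  if (!is.null(cfg$topology)) {
    tp <- cfg$topology
    out$topology <- if (!is.null(tp$builder)) {
      builder <- switch(tp$builder,
                        nested = nested_topology,
                        fully_connected = fully_connected_topology,
                        stop("unknown topology builder: ", tp$builder))
      args <- tp[setdiff(names(tp), "builder")]
      do.call(builder, args)
    } else {
      topology_from_list(tp)
    }
  }
  if (!is.null(cfg$sweep)) {
    args <- cfg$sweep
    if (is.null(args$seed)) stop("sweep config must set a seed")
    if (!is.null(out$params)) args$params <- out$params
    out$sweep <- do.call(sweep_spec, args)
  }
  out
}
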