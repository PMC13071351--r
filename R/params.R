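#' Model parameters for the meta-ecosystem food chain
#'
#' Bundles all rate constants of the local nutrient--producer--consumer
#' dynamics together with the spatial-flow rates. Each local ecosystem
#' receives a constant inorganic nutrient input `I_N` and exports nutrients
#' at rate `e_N`; producers and consumers take up resources through
#' saturating (Monod) functional responses with maximum rates `a_P`, `a_C`
#' and half-saturation constants `b_P`, `b_C`; biomass is lost at rates
#' `m_P`, `m_C`, of which fractions `r_P`, `r_C` are recycled into the local
#' nutrient pool (the remainder leaves the meta-ecosystem). `d_N` is the
#' rate of inorganic resource flow between connected patches and `d_C` the
#' consumer dispersal rate.
#'
#' `d_C` may be a single rate (all patches), a length-2 vector giving the
#' rates of ecosystem types A and B (equivalently the `d_CA` / `d_CB`
#' arguments), or a full per-patch vector matching a topology's patch count.
#' Patches joined by a dispersal link must share one rate or the exchanged
#' biomass would not be conserved in transit; this is enforced when a
#' parameter set is paired with a topology (see [validate_topology()]).
#'
#' The defaults are the baseline parameterization used throughout the
#' package's replication presets.
#'
#' @param I_N nutrient input rate (mass / time).
#' @param e_N nutrient export rate (1 / time).
#' @param m_P,m_C producer and consumer loss rates (1 / time).
#' @param a_P,a_C maximum uptake rates (1 / time).
#' @param b_P,b_C half-saturation constants (mass).
#' @param r_P,r_C recycled fractions of producer/consumer losses, in `[0, 1]`.
#' @param d_N resource-flow rate between connected patches (1 / time).
#' @param d_C consumer dispersal rate(s); scalar, per-type pair, or per-patch
#'   vector (1 / time).
#' @param d_P producer spatial-flow rate (1 / time). Zero in the default
#'   model: producer movement is assumed to stay within an ecosystem. A
#'   nonzero value only acts together with a topology whose `S_P` is
#'   non-zero.
#' @param d_CA,d_CB convenience alternative to `d_C`: type-specific
#'   dispersal rates for ecosystem types A and B. Supply either `d_C` or
#'   the pair, not both.
#'
#' @return An object of class `meta_params` (a validated named list).
#' @examples
#' p <- meta_params()                    # baseline rates
#' p <- meta_params(d_N = 5, d_CA = 0.4, d_CB = 0.4)
#' d_CA(p)
#' @seealso [closed_equilibrium()], [meta_derivative()], [nested_topology()]
#' @export
meta_params <- function(I_N = 0.05, e_N = 0.01, m_P = 0.05, m_C = 0.24,
                        a_P = 1, b_P = 10, a_C = 0.6, b_C = 6,
                        r_P = 0.8, r_C = 0.8,
                        d_N = 0, d_C = 0, d_P = 0,
                        d_CA = NULL, d_CB = NULL) {
  if (!is.null(d_CA) || !is.null(d_CB)) {
    if (is.null(d_CA) || is.null(d_CB))
      stop("supply both `d_CA` and `d_CB` (or neither)")
    if (!missing(d_C))
      stop("supply either `d_C` or the `d_CA`/`d_CB` pair, not both")
    d_C <- c(A = as.numeric(d_CA), B = as.numeric(d_CB))
  }
  p <- list(I_N = I_N, e_N = e_N, m_P = m_P, m_C = m_C,
            a_P = a_P, b_P = b_P, a_C = a_C, b_C = b_C,
            r_P = r_P, r_C = r_C,
            d_N = d_N, d_C = as.numeric(d_C), d_P = d_P)
  validate_params(p)
  structure(p, class = "meta_params")
}

validate_params <- function(p) {
  scalars <- c("I_N", "e_N", "m_P", "m_C", "a_P", "b_P", "a_C", "b_C",
               "r_P", "r_C", "d_N", "d_P")
  for (nm in scalars) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v))
      stop("parameter `", nm, "` must be a single finite number")
    if (v < 0) stop("parameter `", nm, "` must be non-negative")
  }
  if (p$r_P > 1 || p$r_C > 1)
    stop("recycled fractions `r_P`, `r_C` must lie in [0, 1]")
  if (!is.numeric(p$d_C) || any(is.na(p$d_C)) || any(p$d_C < 0))
    stop("`d_C` must be non-negative")
  if (p$a_C <= p$m_C)
    warning("a_C <= m_C: consumers cannot persist ",
            "(no positive consumer equilibrium)")
  invisible(p)
}

#' @export
print.meta_params <- function(x, ...) {
  cat("<meta_params>\n")
  flat <- unlist(x)
  cat(paste0("  ", format(names(flat), width = 5), " = ",
             format(flat, digits = 6), collapse = "\n"), "\n")
  invisible(x)
}

#' Type-level dispersal-rate accessors
#'
#' Read the consumer dispersal rate of ecosystem type A or B from a
#' parameter set. When `d_C` was given per patch, a topology must be
#' supplied so patches can be mapped to types, and all patches of the type
#' must share one rate.
#'
#' @param params a [meta_params()] object.
#' @param topo optionally, a topology whose `type_label` maps patches to
#'   types; required when `d_C` is a per-patch vector. Without a topology
#'   the two-type patch ordering (A, B, A, B, ...) is assumed.
#' @return A single dispersal rate.
#' @export
d_CA <- function(params, topo = NULL) type_rate(params, "A", topo)

#' @rdname d_CA
#' @export
d_CB <- function(params, topo = NULL) type_rate(params, "B", topo)

type_rate <- function(params, type, topo = NULL) {
  dc <- params$d_C
  if (length(dc) == 1L) return(unname(dc))
  if (length(dc) == 2L) {
    if (!is.null(names(dc)) && all(c("A", "B") %in% names(dc)))
      return(unname(dc[[type]]))
    return(unname(dc[[match(type, c("A", "B"))]]))
  }
  types <- if (!is.null(topo)) topo$type_label
           else rep(c("A", "B"), length.out = length(dc))
  vals <- unique(dc[types == type])
  if (length(vals) != 1L)
    stop("patches of type ", type, " do not share one dispersal rate")
  vals
}

#' Expand `d_C` to one dispersal rate per patch
#'
#' @param params a [meta_params()] object.
#' @param topo a topology; supplies the patch count and type labels.
#' @return Numeric vector of length `topo$n`.
#' @keywords internal
#' @export
expand_dispersal <- function(params, topo) {
  dc <- params$d_C
  n <- topo$n
  if (length(dc) == 1L) return(rep(dc, n))
  if (length(dc) == 2L) {
    rates <- c(A = type_rate(params, "A"), B = type_rate(params, "B"))
    return(unname(rates[topo$type_label]))
  }
  if (length(dc) != n)
    stop("`d_C` has length ", length(dc), " but the topology has ", n,
         " patches")
  unname(dc)
}

#' Round-trip a parameter set through a flat key-value list
#'
#' Configuration files store parameters as a flat section; these helpers
#' convert to and from that representation. Unknown keys are an error so a
#' misspelled rate cannot silently fall back to its default.
#'
#' @param params a [meta_params()] object.
#' @param x a named list (e.g. parsed from YAML/JSON).
#' @return `params_to_list()` a plain named list; `params_from_list()` a
#'   [meta_params()] object.
#' @examples
#' p <- meta_params(d_N = 2)
#' identical(params_from_list(params_to_list(p)), p)
#' @export
params_to_list <- function(params) {
  stopifnot(inherits(params, "meta_params"))
  out <- unclass(params)
  out$d_C <- as.numeric(out$d_C)  # drop names for serialization
  if (length(params$d_C) == 2L) out$d_C <- stats::setNames(out$d_C, c("A", "B"))
  out
}

#' @rdname params_to_list
#' @export
params_from_list <- function(x) {
  known <- names(formals(meta_params))
  known <- setdiff(known, c("d_CA", "d_CB"))
  extra <- setdiff(names(x), known)
  if (length(extra))
    stop("unknown parameter name(s) in config: ", paste(extra, collapse = ", "))
  if (is.null(names(x)) || any(names(x) == ""))
    stop("parameter config entries must all be named")
  do.call(meta_params, x)
}
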