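#' Meta-ecosystem topology: per-compartment connectivity matrices
#'
#' A topology holds, for each ecosystem compartment `x` in `{N, C, P}`, an
#' `n x n` connectivity matrix `S_x` whose entry `S_x[i, j]` (row =
#' receiving patch) is the fraction of patch `j`'s export arriving in patch
#' `i`; diagonal entries are negative and record what leaves a patch. Every
#' column sums to zero, so material is conserved in transit, and the spatial
#' term of the dynamics for patch `i` is `d_x * sum_j S_x[i, j] * x_j`.
#'
#' Two normalizations of the off-diagonal weights are supported:
#' `"donor_split"` (default) puts -1 on the diagonal and splits each patch's
#' export equally among its receivers, so the total per-patch emigration
#' rate is `d_x` regardless of how many links a patch has -- which keeps
#' topologies with different link densities comparable at equal rates;
#' `"per_link"` puts weight 1 on every link and `-degree` on the diagonal.
#' For degree-1 graphs (every patch one link per compartment, as in the
#' 4-patch nested topology) the two coincide.
#'
#' @param type_label character vector of per-patch ecosystem types
#'   (`"A"`/`"B"`).
#' @param location_label integer vector of per-patch location ids.
#' @param S_N,S_C,S_P connectivity matrices for nutrients, consumers and
#'   producers. `S_P` defaults to the zero matrix (producers do not move
#'   between patches in the default model).
#' @return An object of class `meta_topology`: a list with fields `n`,
#'   `type_label`, `location_label`, `S_N`, `S_C`, `S_P`, `normalization`.
#' @seealso [nested_topology()], [fully_connected_topology()],
#'   [validate_topology()]
#' @export
meta_topology <- function(type_label, location_label, S_N, S_C,
                          S_P = NULL) {
  n <- length(type_label)
  if (is.null(S_P)) S_P <- matrix(0, n, n)
  topo <- structure(
    list(n = n,
         type_label = as.character(type_label),
         location_label = as.integer(location_label),
         S_N = unname(as.matrix(S_N)),
         S_C = unname(as.matrix(S_C)),
         S_P = unname(as.matrix(S_P)),
         normalization = "custom"),
    class = "meta_topology")
  bad <- validate_topology(topo)
  bad <- bad[!grepl("dispersal rate", bad)]  # rate rules need params
  if (length(bad)) stop("invalid topology: ", paste(bad, collapse = "; "))
  topo
}

#' Patch labels in "A1", "B1", ... form
#' @param topo a `meta_topology`.
#' @return Character vector of length `topo$n`.
#' @export
patch_names <- function(topo) paste0(topo$type_label, topo$location_label)

# Build one conservative connectivity matrix from a 2-column edge list
# (undirected links), with the requested normalization.
connectivity_from_edges <- function(n, edges, normalization) {
  S <- matrix(0, n, n)
  if (length(edges)) {
    edges <- as.matrix(edges)
    for (k in seq_len(nrow(edges))) {
      i <- edges[k, 1]; j <- edges[k, 2]
      S[i, j] <- S[j, i] <- 1
    }
  }
  deg <- colSums(S)
  if (normalization == "donor_split") {
    for (j in seq_len(n)) if (deg[j] > 0) S[, j] <- S[, j] / deg[j]
    diag(S) <- ifelse(deg > 0, -1, 0)
  } else {                                # per_link
    diag(S) <- -deg
  }
  S
}

#' Spatially nested topology
#'
#' Builds the meta-ecosystem in which resource flows act at the small
#' (within-location) scale and consumer dispersal at the large
#' (between-location) scale. Each location holds one ecosystem of type A
#' and one of type B, coupled by flows of inorganic nutrients; ecosystems
#' of the same type at different locations are coupled by consumer
#' dispersal. Patch ordering is (A-loc1, B-loc1, A-loc2, B-loc2, ...).
#'
#' @param n_locations number of locations (>= 2; default 2 gives the
#'   4-patch meta-ecosystem).
#' @param normalization `"donor_split"` or `"per_link"`; see
#'   [meta_topology()].
#' @param dispersal_graph how same-type patches are linked across locations
#'   when `n_locations > 2`: `"complete"` (all pairs) or `"ring"`. Ignored
#'   for 2 locations, where there is a single partner.
#' @return A `meta_topology`.
#' @examples
#' topo <- nested_topology(2)
#' topo$S_N   # A1<->B1 and A2<->B2 resource links
#' topo$S_C   # A1<->A2 and B1<->B2 dispersal links
#' @export
nested_topology <- function(n_locations = 2,
                            normalization = c("donor_split", "per_link"),
                            dispersal_graph = c("complete", "ring")) {
  normalization <- match.arg(normalization)
  dispersal_graph <- match.arg(dispersal_graph)
  if (n_locations < 2)
    stop("`n_locations` must be >= 2: with a single location there are no ",
         "distant same-type patches to couple by dispersal")
  n <- 2L * n_locations
  type <- rep(c("A", "B"), n_locations)
  loc <- rep(seq_len(n_locations), each = 2L)
  # resource flows: within-location, across types
  eN <- cbind(seq(1, n, by = 2), seq(2, n, by = 2))
  # dispersal: across locations, within type
  eC <- same_type_edges(type, loc, dispersal_graph)
  topo <- structure(
    list(n = n, type_label = type, location_label = loc,
         S_N = connectivity_from_edges(n, eN, normalization),
         S_C = connectivity_from_edges(n, eC, normalization),
         S_P = matrix(0, n, n),
         normalization = normalization),
    class = "meta_topology")
  topo
}

same_type_edges <- function(type, loc, dispersal_graph) {
  out <- NULL
  for (ty in unique(type)) {
    idx <- which(type == ty)
    idx <- idx[order(loc[idx])]
    pairs <- if (dispersal_graph == "complete" || length(idx) <= 3)
      t(utils::combn(idx, 2))
    else
      cbind(idx, c(idx[-1], idx[1]))     # ring over locations
    out <- rbind(out, pairs)
  }
  out
}

#' Fully connected resource-flow control topology
#'
#' Identical to [nested_topology()] except that resource flows link every
#' pair of patches, regardless of type or location -- the control used to
#' isolate the effect of restricting resource flows to the within-location
#' scale. Consumer dispersal links are unchanged.
#'
#' @inheritParams nested_topology
#' @return A `meta_topology`.
#' @examples
#' topo <- fully_connected_topology(2)
#' colSums(topo$S_N)          # all zero: conservative transit
#' topo$S_N[1, 2]             # 1/3 under donor-split normalization
#' @export
fully_connected_topology <- function(n_locations = 2,
                                     normalization = c("donor_split",
                                                       "per_link"),
                                     dispersal_graph = c("complete",
                                                         "ring")) {
  normalization <- match.arg(normalization)
  topo <- nested_topology(n_locations, normalization, dispersal_graph)
  n <- topo$n
  eN <- t(utils::combn(seq_len(n), 2))
  topo$S_N <- connectivity_from_edges(n, eN, normalization)
  topo
}

#' Validate a topology (and optionally its pairing with parameters)
#'
#' Checks the structural invariants: matrix shapes; non-negative
#' off-diagonals and non-positive diagonals; column sums zero (mass
#' conserved in transit); consumer dispersal restricted to same-type
#' patches carrying equal per-patch dispersal rates when `params` is given.
#' Violations are reported, never thrown, so the function can be used to
#' inspect hand-built topologies.
#'
#' @param topo a `meta_topology`.
#' @param params optionally a [meta_params()] object, enabling the
#'   shared-dispersal-rate check across `S_C` links.
#' @param tol numeric tolerance for the zero column-sum check.
#' @return Character vector of violation messages; empty if all hold.
#' @export
validate_topology <- function(topo, params = NULL, tol = 1e-12) {
  out <- character()
  n <- topo$n
  if (length(topo$type_label) != n || length(topo$location_label) != n)
    out <- c(out, "label lengths do not match patch count")
  for (nm in c("S_N", "S_C", "S_P")) {
    S <- topo[[nm]]
    if (!is.matrix(S) || any(dim(S) != n)) {
      out <- c(out, paste0(nm, " is not ", n, "x", n))
      next
    }
    off <- S; diag(off) <- 0
    if (any(off < 0))
      out <- c(out, paste0(nm, " has negative off-diagonal entries"))
    if (any(diag(S) > 0))
      out <- c(out, paste0(nm, " has positive diagonal entries"))
    cs <- colSums(S)
    if (any(abs(cs) > tol))
      out <- c(out, paste0(nm, " column sums are not zero (max |sum| = ",
                           format(max(abs(cs)), digits = 3),
                           "): transit does not conserve mass"))
  }
  if (is.matrix(topo$S_C) && all(dim(topo$S_C) == n)) {
    off <- topo$S_C; diag(off) <- 0
    links <- which(off > 0, arr.ind = TRUE)
    cross <- topo$type_label[links[, 1]] != topo$type_label[links[, 2]]
    if (any(cross))
      out <- c(out, "S_C links patches of different types")
    if (!is.null(params) && nrow(links)) {
      dc <- tryCatch(expand_dispersal(params, topo), error = function(e) NULL)
      if (is.null(dc)) {
        out <- c(out, "d_C cannot be mapped onto the topology's patches")
      } else {
        uneq <- dc[links[, 1]] != dc[links[, 2]]
        if (any(uneq))
          out <- c(out, paste0("patches joined by a dispersal link do not ",
                               "share one dispersal rate (conservation)"))
      }
    }
  }
  out
}

#' @export
print.meta_topology <- function(x, ...) {
  cat("<meta_topology> ", x$n, " patches (",
      paste(patch_names(x), collapse = ", "), "), ",
      x$normalization, " normalization\n", sep = "")
  nm <- patch_names(x)
  show <- function(S, lab) {
    dimnames(S) <- list(nm, nm)
    cat(lab, ":\n", sep = "")
    print(round(S, 4))
  }
  show(x$S_N, "S_N (resource flows)")
  show(x$S_C, "S_C (consumer dispersal)")
  if (any(x$S_P != 0)) show(x$S_P, "S_P (producer flows)")
  invisible(x)
}

#' Location-swap permutation of a two-location topology
#'
#' Returns the patch permutation that exchanges the two locations while
#' preserving ecosystem types -- the spatial symmetry of the model. Applying
#' it to a state relabels patch `A1 <-> A2` and `B1 <-> B2`.
#'
#' @param topo a `meta_topology` with exactly two locations.
#' @return Integer vector `perm` with `perm[i]` the patch whose role patch
#'   `i` takes after the swap.
#' @export
location_swap <- function(topo) {
  locs <- sort(unique(topo$location_label))
  if (length(locs) != 2L)
    stop("location swap is defined for two-location topologies")
  perm <- integer(topo$n)
  for (i in seq_len(topo$n)) {
    other <- setdiff(locs, topo$location_label[i])
    perm[i] <- which(topo$type_label == topo$type_label[i] &
                     topo$location_label == other)
  }
  perm
}

#' Serialize a topology to/from a plain-list representation
#'
#' Used by the run-config file format; matrices are stored row-wise (row =
#' receiving patch) as lists of numeric vectors.
#'
#' @param topo a `meta_topology`.
#' @param x a list produced by `topology_to_list()` (e.g. parsed YAML).
#' @return A plain list, or a `meta_topology`.
#' @export
topology_to_list <- function(topo) {
  list(type_label = topo$type_label,
       location_label = topo$location_label,
       S_N = apply(topo$S_N, 1, identity, simplify = FALSE),
       S_C = apply(topo$S_C, 1, identity, simplify = FALSE),
       S_P = apply(topo$S_P, 1, identity, simplify = FALSE))
}

#' @rdname topology_to_list
#' @export
topology_from_list <- function(x) {
  rows <- function(l) do.call(rbind, lapply(l, as.numeric))
  meta_topology(x$type_label, x$location_label,
                rows(x$S_N), rows(x$S_C), rows(x$S_P))
}

#' Write a topology's connectivity matrices to CSV files
#'
#' One file per compartment, named `<prefix>_S_N.csv` etc., with patch
#' names as row (receiver) and column (donor) headers.
#'
#' @param topo a `meta_topology`.
#' @param prefix path prefix for the output files.
#' @return Invisibly, the paths written.
#' @export
write_topology_csv <- function(topo, prefix) {
  nm <- patch_names(topo)
  paths <- character()
  for (s in c("S_N", "S_C", "S_P")) {
    S <- topo[[s]]
    dimnames(S) <- list(nm, nm)
    path <- paste0(prefix, "_", s, ".csv")
    utils::write.csv(S, path)
    paths <- c(paths, path)
  }
  invisible(paths)
}
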