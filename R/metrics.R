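#' Net spatial flows and source/sink status per patch
#'
#' For each patch and each mobile compartment, the time average over the
#' evaluation window of the spatial term of the dynamics,
#' `d_x * sum_j S_x[i, j] * x_j`. A negative value means the patch exports
#' more than it receives -- a *source* of that compartment; a positive
#' value marks a net importer, a *sink*. Status is defined purely by the
#' net flow direction, not by whether the patch is self-sustaining. Net
#' flows sum to zero over the meta-ecosystem (conservative transit).
#'
#' @param traj a classified or raw `meta_trajectory`.
#' @param role_tol net flows with absolute value at or below this are
#'   labelled `"neutral"` (e.g. exactly zero flows in a spatially uniform
#'   state).
#' @return A data frame with one row per patch: `patch`, `type`,
#'   `location`, `net_resource_flow`, `net_dispersal`, `role_N`, `role_C`.
#' @examples
#' ## spatially uniform state: every net flow is exactly zero
#' @export
net_flows <- function(traj, role_tol = 1e-12) {
  w <- eval_window(traj)
  topo <- traj$topo; params <- traj$params
  n <- topo$n
  avg <- apply(w$states, 2, function(z) trapezoid_mean(w$times, z))
  N <- avg[seq_len(n)]; C <- avg[2L * n + seq_len(n)]
  nf_N <- params$d_N * as.numeric(topo$S_N %*% N)
  nf_C <- expand_dispersal(params, topo) * as.numeric(topo$S_C %*% C)
  role <- function(v) ifelse(abs(v) <= role_tol, "neutral",
                             ifelse(v < 0, "source", "sink"))
  data.frame(patch = patch_names(topo),
             type = topo$type_label,
             location = topo$location_label,
             net_resource_flow = nf_N,
             net_dispersal = nf_C,
             role_N = role(nf_N),
             role_C = role(nf_C),
             row.names = NULL)
}

#' Net trophic-regulation effect of spatial flows
#'
#' Quantifies, per patch, whether the spatial flows act net top-down or
#' net bottom-up on producer stocks, by comparing how secondary and
#' primary production respond to coupling:
#' \deqn{E_i = [\langle C_i f_C(P_i)\rangle_{d>0}
#'            - \langle C_i f_C(P_i)\rangle_{d=0}]
#'          - [\langle P_i f_P(N_i)\rangle_{d>0}
#'            - \langle P_i f_P(N_i)\rangle_{d=0}]}
#' where the second trajectory is a reference run of the identical system
#' with all spatial rates zero. `E_i > 0`: flows strengthen grazing
#' relative to uptake (net top-down impact on producers); `E_i < 0`: net
#' bottom-up. Averages are taken over each run's evaluation window, so on
#' fixed points the expression reduces to its equilibrium value.
#'
#' @param traj a `meta_trajectory` of the coupled system.
#' @param traj_ref the uncoupled reference (`d_N = d_C = d_P = 0`), same
#'   local parameters and topology.
#' @return Named numeric vector of `E_i` per patch.
#' @export
trophic_effect <- function(traj, traj_ref) {
  pr <- traj_ref$params
  if (pr$d_N != 0 || any(pr$d_C != 0) || pr$d_P != 0)
    stop("the reference run must have all spatial rates zero")
  local_of <- function(p) unlist(unclass(p)[c("I_N", "e_N", "m_P", "m_C",
                                              "a_P", "b_P", "a_C", "b_C",
                                              "r_P", "r_C")])
  if (!isTRUE(all.equal(local_of(traj$params), local_of(pr))))
    stop("coupled and reference runs use different local parameters")
  if (traj$topo$n != traj_ref$topo$n)
    stop("coupled and reference runs use different patch counts")
  lf <- local_functions(traj)
  lf0 <- local_functions(traj_ref)
  E <- (lf$secondary_production - lf0$secondary_production) -
       (lf$primary_production - lf0$primary_production)
  stats::setNames(E, lf$patch)
}

#' Local ecosystem functions
#'
#' Long-term (evaluation-window) averages per patch of primary production
#' `P_i f_P(N_i)`, secondary production `C_i f_C(P_i)`, and nutrient
#' retention measured as a turnover time: total local stocks
#' `(N_i + P_i + C_i)` divided by the instantaneous rate at which
#' nutrients leave the meta-ecosystem through patch `i`,
#' `L_i = e_N N_i + (1 - r_P) m_P P_i + (1 - r_C) m_C C_i`
#' (export plus the unrecycled fractions of mortality; transfers between
#' patches stay in the system and are not losses). Retention is averaged
#' ratio-first, `<stocks / L>`.
#'
#' @param traj a `meta_trajectory`.
#' @return Data frame per patch: `patch`, `type`, `location`,
#'   `primary_production`, `secondary_production`, `nutrient_retention`,
#'   and mean stocks `N`, `P`, `C`.
#' @export
local_functions <- function(traj) {
  w <- eval_window(traj)
  topo <- traj$topo; p <- traj$params
  n <- topo$n
  iN <- seq_len(n); iP <- n + iN; iC <- 2L * n + iN
  N <- w$states[, iN, drop = FALSE]
  P <- w$states[, iP, drop = FALSE]
  C <- w$states[, iC, drop = FALSE]
  prim <- P * p$a_P * N / (p$b_P + N)
  sec <- C * p$a_C * P / (p$b_C + P)
  L <- p$e_N * N + (1 - p$r_P) * p$m_P * P + (1 - p$r_C) * p$m_C * C
  ratio <- (N + P + C) / ifelse(L > 0, L, NA_real_)
  tm <- function(M) apply(M, 2, function(z) trapezoid_mean(w$times, z))
  data.frame(patch = patch_names(topo),
             type = topo$type_label,
             location = topo$location_label,
             primary_production = unname(tm(prim)),
             secondary_production = unname(tm(sec)),
             nutrient_retention = unname(tm(ratio)),
             N = unname(tm(N)), P = unname(tm(P)), C = unname(tm(C)),
             row.names = NULL)
}

#' Meta-ecosystem functions and stocks
#'
#' Totals over patches of the local production functions, the pooled
#' nutrient-retention turnover time `<sum_i(N_i+P_i+C_i) / sum_i L_i>`,
#' total mean stocks per compartment, and the meta-level consumer
#' minimum/maximum over the window (the quantity plotted in bifurcation
#' diagrams; at an equilibrium minimum and maximum coincide).
#'
#' @param traj a `meta_trajectory`.
#' @return One-row data frame: `primary_production`,
#'   `secondary_production`, `nutrient_retention`, `N`, `P`, `C`,
#'   `C_min`, `C_max`.
#' @export
meta_functions <- function(traj) {
  w <- eval_window(traj)
  topo <- traj$topo; p <- traj$params
  n <- topo$n
  lf <- local_functions(traj)
  iN <- seq_len(n); iP <- n + iN; iC <- 2L * n + iN
  totals <- w$states[, iN] + w$states[, iP] + w$states[, iC]
  L <- p$e_N * w$states[, iN] + (1 - p$r_P) * p$m_P * w$states[, iP] +
    (1 - p$r_C) * p$m_C * w$states[, iC]
  pooled <- rowSums(totals) / rowSums(L)
  metaC <- rowSums(w$states[, iC, drop = FALSE])
  data.frame(primary_production = sum(lf$primary_production),
             secondary_production = sum(lf$secondary_production),
             nutrient_retention = trapezoid_mean(w$times, pooled),
             N = sum(lf$N), P = sum(lf$P), C = sum(lf$C),
             C_min = min(metaC), C_max = max(metaC))
}

#' Full flux-and-function summary for one trajectory
#'
#' Joins [net_flows()], [local_functions()] and, when a reference run is
#' supplied, [trophic_effect()] into the per-patch summary, plus the
#' [meta_functions()] totals.
#'
#' @param traj a `meta_trajectory`.
#' @param traj_ref optional uncoupled reference run for `E_i`.
#' @return List with `local` (per-patch data frame) and `meta` (one-row
#'   data frame).
#' @export
flux_function_summary <- function(traj, traj_ref = NULL) {
  local <- merge(net_flows(traj), local_functions(traj),
                 by = c("patch", "type", "location"), sort = FALSE)
  if (!is.null(traj_ref))
    local$E <- unname(trophic_effect(traj, traj_ref)[local$patch])
  list(local = local, meta = meta_functions(traj))
}
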