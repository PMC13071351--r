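# Shared fixtures: baseline parameter set, small topologies, and a
# constructor for constant synthetic trajectories used by the metric
# oracles.

baseline_params <- function(...) meta_params(...)

# a meta_trajectory whose states are constant in time (analytic fixture)
const_trajectory <- function(y, params, topo, t = seq(0, 100, by = 1),
                             transient_frac = 0.2) {
  states <- matrix(rep(state_vector(y), each = length(t)),
                   nrow = length(t))
  nm <- patch_names(topo)
  colnames(states) <- c(paste0("N_", nm), paste0("P_", nm), paste0("C_", nm))
  structure(list(times = t, states = states,
                 transient_end = max(1L, floor(transient_frac * length(t))),
                 params = params, topo = topo,
                 solver = list(rtol = NA, atol = NA, engine = "synthetic")),
            class = "meta_trajectory")
}

# random non-negative state for property loops
random_state <- function(n = 4, max = 10) {
  stats::runif(3 * n, 0, max)
}

# independent brute-force oracle for the closed-ecosystem fixed point:
# root-finding on the balance equations, no quadratic algebra shared with
# closed_equilibrium()
brute_force_equilibrium <- function(p) {
  Pstar <- stats::uniroot(function(P) uptake_consumer(P, p) - p$m_C,
                          c(1e-8, 1e6), tol = 1e-14)$root
  nut_balance <- function(C) {
    fP <- (p$m_P * Pstar + p$m_C * C) / Pstar   # producer balance
    N <- p$b_P * fP / (p$a_P - fP)
    p$I_N - p$e_N * N + p$m_P * p$r_P * Pstar + p$m_C * p$r_C * C -
      Pstar * fP
  }
  Cstar <- stats::uniroot(nut_balance, c(1e-10, 1), tol = 1e-14)$root
  fP <- (p$m_P * Pstar + p$m_C * Cstar) / Pstar
  list(N = p$b_P * fP / (p$a_P - fP), P = Pstar, C = Cstar)
}
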