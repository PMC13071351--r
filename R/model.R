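#' Meta-ecosystem state
#'
#' Per-patch stocks of inorganic nutrients `N`, primary producers `P` and
#' consumers `C`. Internally states travel as a flat numeric vector ordered
#' `(N_1..N_n, P_1..P_n, C_1..C_n)`; this constructor and
#' [state_vector()] convert between the two forms.
#'
#' @param N,P,C numeric vectors of equal length (one entry per patch), all
#'   non-negative.
#' @return An object of class `meta_state`.
#' @export
meta_state <- function(N, P, C) {
  n <- length(N)
  if (length(P) != n || length(C) != n)
    stop("N, P and C must have one entry per patch")
  if (any(c(N, P, C) < 0)) stop("stocks must be non-negative")
  structure(list(N = as.numeric(N), P = as.numeric(P), C = as.numeric(C)),
            class = "meta_state")
}

#' @rdname meta_state
#' @param state a `meta_state` or a flat numeric vector of length `3n`.
#' @export
state_vector <- function(state) {
  if (inherits(state, "meta_state")) return(c(state$N, state$P, state$C))
  as.numeric(state)
}

state_from_vector <- function(y) {
  n <- length(y) %/% 3L
  meta_state(y[seq_len(n)], y[n + seq_len(n)], y[2L * n + seq_len(n)])
}

#' Producer and consumer uptake (Monod functional responses)
#'
#' Per-capita uptake rates: producers take up nutrients at
#' `a_P * N / (b_P + N)` and consumers graze producers at
#' `a_C * P / (b_C + P)`. Both saturate at the maximum rate and are zero at
#' zero resource.
#'
#' @param N,P resource stock (non-negative; vectorized).
#' @param params a [meta_params()] object.
#' @return Uptake rate per unit biomass, in `[0, a_x)`.
#' @examples
#' p <- meta_params()
#' uptake_producer(10, p)   # half-saturation: a_P / 2
#' uptake_consumer(6, p)    # half-saturation: a_C / 2
#' @export
uptake_producer <- function(N, params) {
  if (any(N < 0)) stop("nutrient stock must be non-negative")
  params$a_P * N / (params$b_P + N)
}

#' @rdname uptake_producer
#' @export
uptake_consumer <- function(P, params) {
  if (any(P < 0)) stop("producer stock must be non-negative")
  params$a_C * P / (params$b_C + P)
}

#' Time-derivative of the full meta-ecosystem
#'
#' Evaluates the right-hand side of the coupled dynamics. For each patch
#' `i`:
#' \deqn{dN_i/dt = I_N - e_N N_i + m_P r_P P_i + m_C r_C C_i
#'       - P_i f_P(N_i) + d_N \sum_j S_N[i,j] N_j}
#' \deqn{dP_i/dt = P_i f_P(N_i) - m_P P_i - C_i f_C(P_i)
#'       + d_P \sum_j S_P[i,j] P_j}
#' \deqn{dC_i/dt = C_i f_C(P_i) - m_C C_i + d_{C,i} \sum_j S_C[i,j] C_j}
#' with the saturating uptake functions of [uptake_producer()] /
#' [uptake_consumer()]. The producer spatial term vanishes in the default
#' model (`d_P = 0`, `S_P = 0`).
#'
#' This reference implementation in R defines the model; the integrator
#' uses an equivalent compiled version (tested against this one).
#'
#' @param state a [meta_state()] or flat numeric vector of length `3n`.
#' @param params a [meta_params()] object.
#' @param topo a `meta_topology` with `n` patches.
#' @return The rate of change, in the same shape as `state` was given.
#' @export
meta_derivative <- function(state, params, topo) {
  as_state <- inherits(state, "meta_state")
  y <- state_vector(state)
  n <- topo$n
  if (length(y) != 3L * n)
    stop("state has length ", length(y), " but the topology needs ", 3L * n)
  N <- y[seq_len(n)]; P <- y[n + seq_len(n)]; C <- y[2L * n + seq_len(n)]
  fP <- uptake_producer(N, params)
  fC <- uptake_consumer(P, params)
  dC_patch <- expand_dispersal(params, topo)
  dN <- params$I_N - params$e_N * N + params$m_P * params$r_P * P +
    params$m_C * params$r_C * C - P * fP +
    params$d_N * as.numeric(topo$S_N %*% N)
  dP <- P * fP - params$m_P * P - C * fC +
    params$d_P * as.numeric(topo$S_P %*% P)
  dC <- C * fC - params$m_C * C + dC_patch * as.numeric(topo$S_C %*% C)
  out <- c(dN, dP, dC)
  if (as_state) {
    structure(list(N = dN, P = dP, C = dC), class = "meta_state")
  } else out
}

#' Interior equilibrium of a closed (uncoupled) ecosystem
#'
#' With all spatial rates zero every patch follows the same
#' three-compartment food chain, whose interior fixed point has a closed
#' form used throughout the package as an analytic oracle. The consumer
#' balance pins the producer stock at `P* = b_C m_C / (a_C - m_C)`;
#' substituting the producer balance `f_P(N*) = m_P + m_C C* / P*` into the
#' nutrient balance and clearing the Monod denominator leaves a quadratic
#' in `C*`:
#' \deqn{(A - l_C C)(a_P - m_P - g C) - e_N b_P (m_P + g C) = 0}
#' with `A = I_N - (1 - r_P) m_P P*`, `l_C = (1 - r_C) m_C` and
#' `g = m_C / P*`. When both roots are positive the one yielding
#' `f_P < a_P` (hence a positive, finite `N*`) is the ecologically feasible
#' fixed point; the other root sits beyond the uptake saturation and is
#' unphysical.
#'
#' @param params a [meta_params()] object with `a_C > m_C`.
#' @return A list with elements `N`, `P`, `C` (scalars).
#' @examples
#' eq <- closed_equilibrium(meta_params())
#' eq$P      # exactly 4 at baseline rates
#' @export
closed_equilibrium <- function(params) {
  p <- params
  if (p$a_C <= p$m_C)
    stop("no positive consumer equilibrium: a_C <= m_C ",
         "(consumers cannot persist)")
  Pstar <- p$b_C * p$m_C / (p$a_C - p$m_C)
  g <- p$m_C / Pstar                      # d f_P / d C along the balance
  A <- p$I_N - (1 - p$r_P) * p$m_P * Pstar
  lC <- (1 - p$r_C) * p$m_C
  # quadratic a2 C^2 + a1 C + a0 = 0
  a2 <- lC * g
  a1 <- -(A * g + lC * (p$a_P - p$m_P) + p$e_N * p$b_P * g)
  a0 <- A * (p$a_P - p$m_P) - p$e_N * p$b_P * p$m_P
  disc <- a1^2 - 4 * a2 * a0
  if (disc < 0)
    stop("no positive interior equilibrium for these parameters ",
         "(complex roots)")
  roots <- if (a2 == 0) -a0 / a1 else (-a1 + c(-1, 1) * sqrt(disc)) / (2 * a2)
  feas <- roots[roots > 0 & p$m_P + g * roots < p$a_P]
  if (!length(feas))
    stop("no positive interior equilibrium for these parameters")
  Cstar <- min(feas)                      # feasible branch (f_P < a_P)
  fP <- p$m_P + g * Cstar
  Nstar <- p$b_P * fP / (p$a_P - fP)
  if (Nstar <= 0)
    stop("no positive interior equilibrium for these parameters")
  list(N = Nstar, P = Pstar, C = Cstar)
}

# ---- packing for the compiled right-hand side --------------------------

MAXN <- 16L
N_PARMS <- 13L + MAXN + 3L * MAXN * MAXN

pack_parms <- function(params, topo) {
  n <- topo$n
  if (n > MAXN)
    stop("compiled derivative supports at most ", MAXN, " patches")
  v <- c(n,
         params$I_N, params$e_N, params$m_P, params$m_C,
         params$a_P, params$b_P, params$a_C, params$b_C,
         params$r_P, params$r_C, params$d_N, params$d_P,
         expand_dispersal(params, topo),
         as.numeric(topo$S_N), as.numeric(topo$S_C), as.numeric(topo$S_P))
  c(v, numeric(N_PARMS - length(v)))
}
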