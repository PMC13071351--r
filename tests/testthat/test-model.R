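test_that("uptake functions follow the saturating form", {
  p <- baseline_params()
  # half-saturation points
  expect_equal(uptake_producer(10, p), 0.5)
  expect_equal(uptake_consumer(6, p), 0.3)
  # zero resource, zero uptake
  expect_identical(uptake_producer(0, p), 0)
  expect_identical(uptake_consumer(0, p), 0)
  # hand evaluations
  expect_equal(uptake_producer(0.5842, p), 0.5842 / 10.5842, tolerance = 1e-12)
  # consumer uptake at P = 4 equals the loss rate: the single-patch
  # equilibrium condition
  expect_equal(uptake_consumer(4, p), p$m_C, tolerance = 1e-12)
  # bounded by the maximum rate and monotone
  N <- seq(0, 1e4, length.out = 200)
  u <- uptake_producer(N, p)
  expect_true(all(u >= 0 & u < p$a_P))
  expect_true(all(diff(u) > 0))
  expect_error(uptake_producer(-1, p), "non-negative")
  expect_error(uptake_consumer(-0.1, p), "non-negative")
})

test_that("parameter validation enforces the model's constraints", {
  expect_error(meta_params(r_P = 1.2), "\\[0, 1\\]")
  expect_error(meta_params(m_C = -0.1), "non-negative")
  expect_warning(meta_params(a_C = 0.2, m_C = 0.24), "persist")
  expect_error(meta_params(d_C = 0.1, d_CA = 0.2, d_CB = 0.2), "not both")
  p <- meta_params(d_CA = 0.1, d_CB = 0.3)
  expect_equal(d_CA(p), 0.1)
  expect_equal(d_CB(p), 0.3)
  topo <- nested_topology()
  expect_equal(expand_dispersal(p, topo), c(0.1, 0.3, 0.1, 0.3))
})

test_that("parameter config round-trip is exact and typo-safe", {
  p <- meta_params(d_N = 2.5, d_CA = 0.1, d_CB = 0.4)
  expect_identical(params_from_list(params_to_list(p)), p)
  bad <- params_to_list(p)
  names(bad)[1] <- "I_n"
  expect_error(params_from_list(bad), "unknown parameter")
})

test_that("derivative reproduces the hand-evaluated right-hand side", {
  p <- baseline_params()  # d_N = d_C = 0
  topo <- nested_topology()
  d <- meta_derivative(rep(1, 12), p, topo)
  # per patch at N = P = C = 1: nutrient balance 0.272 - f_P(1),
  # producer f_P(1) - 0.05 - f_C(1), consumer f_C(1) - 0.24
  expect_equal(d[1:4], rep(0.272 - 1 / 11, 4), tolerance = 1e-12)
  expect_equal(d[5:8], rep(1 / 11 - 0.05 - 0.6 / 7, 4), tolerance = 1e-12)
  expect_equal(d[9:12], rep(0.6 / 7 - 0.24, 4), tolerance = 1e-12)
  # spatially uniform states feel no spatial term under any conservative
  # topology
  p2 <- meta_params(d_N = 5, d_C = 0.4)
  for (topo2 in list(nested_topology(), fully_connected_topology(),
                     fully_connected_topology(normalization = "per_link"))) {
    expect_equal(meta_derivative(rep(1, 12), p2, topo2), d, tolerance = 1e-12)
  }
  expect_error(meta_derivative(rep(1, 9), p, topo), "length")
})

test_that("closed-ecosystem equilibrium matches the brute-force oracle", {
  p <- baseline_params()
  eq <- closed_equilibrium(p)
  expect_identical(eq$P, 4)                 # b_C m_C / (a_C - m_C) exactly
  oracle <- brute_force_equilibrium(p)
  expect_equal(eq$N, oracle$N, tolerance = 1e-10)
  expect_equal(eq$C, oracle$C, tolerance = 1e-10)
  # the equilibrium really is a fixed point of the uncoupled dynamics
  st <- rep(c(eq$N, eq$P, eq$C), each = 4)
  expect_lt(max(abs(meta_derivative(st, p, nested_topology()))), 1e-10)
  # and for a second, perturbed parameter set
  p2 <- meta_params(I_N = 0.08, m_C = 0.2, r_C = 0.6)
  eq2 <- closed_equilibrium(p2)
  o2 <- brute_force_equilibrium(p2)
  expect_equal(unlist(eq2), unlist(o2), tolerance = 1e-8)
  expect_error(closed_equilibrium(suppressWarnings(meta_params(a_C = 0.2))),
               "persist")
})

test_that("mass bookkeeping: internal transfers conserve, only external
           terms change the total", {
  set.seed(101)
  p <- meta_params(d_N = 3.7, d_CA = 0.25, d_CB = 0.4)
  topos <- list(nested_topology(), fully_connected_topology(),
                nested_topology(normalization = "per_link"))
  for (topo in topos) for (rep in 1:50) {
    y <- random_state()
    d <- meta_derivative(y, p, topo)
    N <- y[1:4]; P <- y[5:8]; C <- y[9:12]
    external <- 4 * p$I_N - sum(p$e_N * N + (1 - p$r_P) * p$m_P * P +
                                  (1 - p$r_C) * p$m_C * C)
    expect_equal(sum(d), external, tolerance = 1e-12)
  }
})

test_that("derivative commutes with the location-swap symmetry", {
  set.seed(7)
  p <- meta_params(d_N = 5, d_C = 0.4)
  for (topo in list(nested_topology(), fully_connected_topology())) {
    perm <- location_swap(topo)
    sv <- c(perm, 4 + perm, 8 + perm)
    for (rep in 1:20) {
      y <- random_state()
      expect_equal(meta_derivative(y[sv], p, topo),
                   meta_derivative(y, p, topo)[sv], tolerance = 1e-12)
    }
  }
})

test_that("empty compartments cannot be driven negative", {
  set.seed(11)
  p <- meta_params(d_N = 5, d_CA = 0.4, d_CB = 0.1)
  topo <- nested_topology()
  for (rep in 1:50) {
    y <- random_state()
    comp <- sample(0:2, 1); patch <- sample(1:4, 1)
    y[comp * 4 + patch] <- 0
    d <- meta_derivative(y, p, topo)
    expect_gte(d[comp * 4 + patch], 0)
  }
})
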