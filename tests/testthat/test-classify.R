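p0 <- meta_params(d_N = 5, d_C = 0.4)
topo4 <- nested_topology()

# constant trajectory with an optional sinusoid injected into one column
synthetic_traj <- function(base, wiggle_col = NULL, amp = 0.5,
                           period = 50, offset = 0, t = seq(0, 400)) {
  tr <- const_trajectory(base, p0, topo4, t = t)
  if (!is.null(wiggle_col))
    tr$states[, wiggle_col] <- tr$states[, wiggle_col] + offset +
      amp * sin(2 * pi * t / period)
  tr
}

test_that("constant identical patches classify as homogeneous equilibrium", {
  rep1 <- classify_trajectory(synthetic_traj(rep(1, 12)))
  expect_equal(rep1$state_code, "HOM_EQ")
  expect_false(rep1$inconclusive)
  expect_equal(rep1$amplitude, 0)
  expect_true(all(rep1$min <= rep1$mean & rep1$mean <= rep1$max))
})

test_that("a cycle in one patch makes the state an oscillation and breaks
           spatial homogeneity", {
  rep1 <- classify_trajectory(synthetic_traj(rep(1, 12), wiggle_col = 9))
  expect_equal(rep1$kind, "oscillation")
  expect_equal(rep1$spatial, "heterogeneous")
  # same cycle with a mean shift is caught through the averages too
  rep2 <- classify_trajectory(synthetic_traj(rep(1, 12), wiggle_col = 9,
                                             offset = 0.3))
  expect_equal(rep2$spatial, "heterogeneous")
  # but patch-identical cycles stay homogeneous
  tr <- synthetic_traj(rep(1, 12))
  tr$states[, 9:12] <- tr$states[, 9:12] +
    0.5 * sin(2 * pi * tr$times / 50)
  rep3 <- classify_trajectory(tr)
  expect_equal(rep3$state_code, "HOM_OSC")
  expect_false(rep3$inconclusive)
  expect_gt(rep3$period, 45); expect_lt(rep3$period, 55)
})

test_that("windows shorter than two periods are flagged inconclusive", {
  tr <- synthetic_traj(rep(1, 12), wiggle_col = 9, period = 300,
                       t = seq(0, 500))
  rep1 <- classify_trajectory(tr)
  expect_true(rep1$inconclusive)
})

test_that("labels are invariant under the location swap", {
  set.seed(21)
  perm <- location_swap(topo4)
  sv <- c(perm, 4 + perm, 8 + perm)
  x0 <- random_state(max = 2)
  for (dn in c(0.5, 5)) {
    p <- meta_params(d_N = dn, d_C = 0.4)
    a <- classify_trajectory(simulate_meta(p, topo4, x0,
                                           t_transient = 2e5, t_end = 2.1e5))
    b <- classify_trajectory(simulate_meta(p, topo4, x0[sv],
                                           t_transient = 2e5, t_end = 2.1e5))
    expect_equal(a$state_code, b$state_code)
    expect_equal(a$mean[sv], unname(b$mean), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
})

test_that("loosening the amplitude tolerance only moves labels toward
           equilibrium", {
  tr <- synthetic_traj(rep(1, 12), wiggle_col = 9, amp = 1e-4)
  tols <- c(1e-6, 1e-5, 1e-3, 1e-1)
  kinds <- vapply(tols, function(tl)
    classify_trajectory(tr, tol_eq = tl)$kind, character(1))
  # once equilibrium, always equilibrium for looser tolerances
  eq_seen <- FALSE
  for (k in kinds) {
    if (eq_seen) expect_equal(k, "equilibrium")
    if (k == "equilibrium") eq_seen <- TRUE
  }
  expect_equal(kinds[1], "oscillation")
  expect_equal(kinds[4], "equilibrium")
})

test_that("ensemble grouping counts attractors and spots mirror pairs", {
  mk_report <- function(mean, code = "HET_EQ", inconclusive = FALSE) {
    structure(list(kind = "equilibrium", spatial = "heterogeneous",
                   state_code = code, inconclusive = inconclusive,
                   mean = mean), class = "attractor_report")
  }
  perm <- location_swap(topo4)
  sv <- c(perm, 4 + perm, 8 + perm)
  # same-type patches differ between locations, so the swap is not the
  # identity
  a <- c(0.5, 0.6, 0.55, 0.62, 2, 6.7, 6.7, 1.9, 0.028, 0.034, 0.034, 0.027)
  b <- a[sv]
  stopifnot(!isTRUE(all.equal(a, b)))
  # identical reports: one attractor, no bistability
  v1 <- classify_ensemble(list(mk_report(a), mk_report(a)), topo = topo4)
  expect_equal(v1$n_attractors, 1)
  expect_false(v1$bistable)
  expect_equal(v1$state_code, "HET_EQ")
  # location-swapped twins: two attractors, bistable, same state class
  v2 <- classify_ensemble(list(mk_report(a), mk_report(b), mk_report(a)),
                          topo = topo4)
  expect_equal(v2$n_attractors, 2)
  expect_true(v2$bistable)
  expect_equal(v2$attractors$n_members, c(2, 1))
  # disagreement on the state code signals a boundary cell
  v3 <- classify_ensemble(list(mk_report(a), mk_report(a, "HET_OSC")),
                          topo = topo4)
  expect_equal(v3$state_code, "MIXED")
  # inconclusive members are counted, not dropped
  v4 <- classify_ensemble(list(mk_report(a), mk_report(a, inconclusive = TRUE)),
                          topo = topo4)
  expect_equal(v4$n_inconclusive, 1)
  expect_equal(v4$state_code, "HET_EQ")
  js <- jsonlite::fromJSON(verdict_to_json(v2))
  expect_true(js$bistable)
  expect_equal(js$n_attractors, 2)
})

test_that("classification agrees with a direct root-find on the
           homogeneous-equilibrium region", {
  # low resource flow: the coupled system settles on the symmetric fixed
  # point, which solves the closed-ecosystem balance (spatial terms vanish
  # on symmetric states)
  p <- meta_params(d_N = 0.2, d_C = 0.4)
  res <- run_ensemble(p, topo4, seed = 4, n_ic = 3,
                      t_transient = 3e5, t_end = 3.1e5)
  expect_equal(res$verdict$state_code, "HOM_EQ")
  eq <- closed_equilibrium(p)
  expect_equal(unname(res$reports[[1]]$mean),
               rep(c(eq$N, eq$P, eq$C), each = 4), tolerance = 1e-5)
})
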