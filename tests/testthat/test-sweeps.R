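# Small grids with a shortened protocol: these exercise the sweep
# machinery (determinism, cell independence, thresholds, failure coding),
# using parameter values far from state boundaries so the shortened
# horizon still classifies correctly.
fast_spec <- function(...) {
  sweep_spec(n_ic = 6, seed = 11, t_transient = 2e5, t_window = 1e4,
             dt_eval = 2, ...)
}

test_that("state diagrams are deterministic and label distant regimes
           correctly", {
  spec <- fast_spec(topology = "nested", d_N = c(0.5, 5), d_C = 0.4)
  a <- state_diagram(spec)
  b <- state_diagram(spec)
  expect_identical(a, b)
  expect_equal(a$state_code[a$d_N == 0.5], "HOM_EQ")
  expect_equal(a$state_code[a$d_N == 5], "HET_EQ")
  expect_true(a$bistable[a$d_N == 5])
})

test_that("bifurcation transects record the meta consumer envelope", {
  spec <- fast_spec(topology = "nested", d_N = c(0.5, 2.8, 5), d_C = 0.4)
  tr <- bifurcation_transect(spec)
  expect_named(tr, c("d_N", "d_CA", "d_CB", "C_meta_min", "C_meta_max",
                     "state_code", "n_attractors", "bistable",
                     "n_inconclusive"))
  # equilibrium cells: a collapsed envelope
  eqs <- tr$state_code %in% c("HOM_EQ", "HET_EQ")
  expect_true(all(tr$C_meta_max[eqs] - tr$C_meta_min[eqs] < 1e-4))
  # the oscillatory cell has an open envelope (narrowed by partial
  # cancellation of antiphase patches in the meta-level sum)
  expect_gt(tr$C_meta_max[tr$d_N == 2.8] - tr$C_meta_min[tr$d_N == 2.8], 0.05)
  expect_equal(heterogeneity_threshold(tr), 2.8)
  expect_equal(state_threshold(tr, "HET_EQ"), 5)
  expect_true(is.na(state_threshold(tr, "FAILED")))
})

test_that("the dispersal plane is symmetric in the two type rates", {
  spec <- fast_spec(topology = "nested", d_N = 5,
                    d_CA = c(0.1, 0.4), d_CB = c(0.1, 0.4))
  pl <- dispersal_plane(spec)
  get <- function(a, b) pl$state_code[pl$d_CA == a & pl$d_CB == b]
  expect_equal(get(0.1, 0.4), get(0.4, 0.1))
  expect_equal(get(0.4, 0.4), "HET_EQ")
  # dropping either type's dispersal loses the heterogeneous equilibrium
  expect_false(get(0.1, 0.4) == "HET_EQ")
})

test_that("functions transect reports both heterogeneous patch roles", {
  spec <- fast_spec(topology = "nested", d_N = c(0.5, 5), d_C = 0.4)
  ft <- functions_transect(spec)
  hom <- ft$local[ft$local$d_N == 0.5, ]
  # homogeneous region: both patches of a type report identical functions
  for (ty in c("A", "B")) {
    v <- hom$primary_production[hom$type == ty]
    expect_lt(diff(range(v)), 1e-6)
  }
  het <- ft$local[ft$local$d_N == 5 & ft$local$attractor == 1, ]
  # the top-down patch (E > 0) of each type has the lower primary
  # production of its pair
  for (ty in c("A", "B")) {
    sub <- het[het$type == ty, ]
    expect_equal(nrow(sub), 2)
    expect_true(xor(sub$E[1] > 0, sub$E[2] > 0))
    expect_lt(sub$primary_production[which.max(sub$E)],
              sub$primary_production[which.min(sub$E)])
  }
  # meta producer stock is higher on the heterogeneous branch
  met <- ft$meta
  expect_gt(met$P[met$d_N == 5][1], met$P[met$d_N == 0.5][1])
})

test_that("failed cells are coded FAILED without aborting the grid", {
  spec <- fast_spec(topology = "nested", d_N = c(0.5, 5), d_C = 0.4)
  spec$params$b_P <- -10    # corrupt: invalid uptake parameters
  expect_message(res <- state_diagram(spec), "FAILED")
  expect_true(all(res$state_code == "FAILED"))
  expect_equal(nrow(res), 2)
})

test_that("sweeps write incremental CSV output and a run manifest", {
  out <- file.path(tempdir(), paste0("sweep", sample.int(1e6, 1)))
  spec <- fast_spec(topology = "nested", d_N = c(0.5, 5), d_C = 0.4,
                    out_dir = out)
  res <- state_diagram(spec)
  csv <- utils::read.csv(file.path(out, "state_diagram.csv"))
  expect_equal(nrow(csv), 2)
  expect_equal(sort(csv$state_code), sort(res$state_code))
  man <- jsonlite::read_json(file.path(out, "state_diagram_manifest.json"))
  expect_equal(man$ensemble$seed, 11)
  expect_equal(man$protocol$tol_het, 1e-3)
  # resuming skips the cells already on disk
  expect_message(state_diagram(spec), "resuming")
  unlink(out, recursive = TRUE)
})

test_that("presets encode the replication protocols", {
  s <- replication_preset("transect_nested", seed = 3, d_C = 0.1)
  expect_equal(s$d_C, 0.1)
  expect_equal(s$n_ic, 50)
  expect_equal(s$seed, 3)
  expect_equal(s$topology, "nested")
  s6 <- replication_preset("dispersal_plane")
  expect_equal(s6$d_N, 5)
  expect_false(is.null(s6$d_CA))
  ci <- replication_preset("ci")
  expect_lt(ci$n_ic, 50)
})

test_that("run configs round-trip through YAML", {
  cfg <- list(params = list(I_N = 0.05, d_N = 2.5, d_C = 0.4),
              topology = list(builder = "fully_connected",
                              n_locations = 2),
              sweep = list(topology = "nested", d_N = c(1, 2),
                           d_C = 0.4, n_ic = 2, seed = 7))
  path <- tempfile(fileext = ".yaml")
  yaml::write_yaml(cfg, path)
  got <- read_run_config(path)
  expect_s3_class(got$params, "meta_params")
  expect_equal(got$params$d_N, 2.5)
  expect_equal(got$topology$S_N[1, 3], 1 / 3)
  expect_equal(got$sweep$seed, 7)
  # a config with a typo in a parameter name is refused
  cfg$params$I_n <- 0.05; cfg$params$I_N <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(read_run_config(path), "unknown parameter")
  # a sweep without a seed is refused
  cfg$params <- list(I_N = 0.05); cfg$sweep$seed <- NULL
  yaml::write_yaml(cfg, path)
  expect_error(read_run_config(path), "seed")
})
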