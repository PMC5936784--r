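# Synthetic-data generator: library content, determinism, ground truth.

test_that("builtin library has the documented coverage", {
  lib <- fixture_library()
  expect_gte(nrow(lib), 150L)
  # worked-example compounds all present with their counter-ions
  tc <- table_compounds()
  idx <- match(tc$name, lib$name)
  expect_false(anyNA(idx))
  expect_identical(lib$formula[idx], tc$formula)
  expect_identical(lib$adduct[idx], tc$adduct)
  # at least 3 representatives of every lipid heat-map class
  for (cl in c("PA", "PE", "PG", "PS", "PI", "PC", "MG", "DG", "TG")) {
    expect_gte(sum(lib$compound_class == cl), 3L, label = cl)
  }
  # preferred-adduct ions inside the analysis range
  mzv <- library_ion_mz(lib)
  expect_true(all(mzv >= 100 & mzv <= 1500))
  # both N-free and N-containing metabolites, so stoichiometry scenarios
  # are expressible
  n_counts <- vapply(lib$formula, function(f) {
    element_count(f, "N")
  }, integer(1))
  expect_gt(sum(n_counts == 0), 20L)
  expect_gt(sum(n_counts > 0), 20L)
  expect_false(anyDuplicated(lib$name) > 0)
})

test_that("simulation is deterministic under a fixed seed", {
  lib <- fixture_library()
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 3L,
    library_size = 40L, rng_seed = 7L
  )
  a <- simulate_experiment(cfg, lib)
  b <- simulate_experiment(cfg, lib)
  expect_identical(a$spectra, b$spectra)
  expect_identical(a$truth$metabolites, b$truth$metabolites)
  cfg2 <- simulation_config("light_dark",
    n_cells_per_group = 3L,
    library_size = 40L, rng_seed = 8L
  )
  c <- simulate_experiment(cfg2, lib)
  expect_false(identical(a$spectra, c$spectra))
})

test_that("noise-free null config gives identical peak sets and no flags", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 3L, library_size = 30L,
    fraction_differential = 0, mz_jitter_sd = 0,
    n_noise_peaks_mean = 0, rng_seed = 1L
  )
  sim <- simulate_experiment(cfg, fixture_library())
  mz1 <- sim$spectra[[1]]$mz
  for (s in sim$spectra[-1]) expect_equal(s$mz, mz1)
  expect_identical(sum(sim$truth$metabolites$differential), 0L)
})

test_that("differential flag count follows the rounding rule", {
  cfg <- simulation_config("light_dark",
    library_size = 100L,
    fraction_differential = 0.3, rng_seed = 2L
  )
  sim <- simulate_experiment(cfg, fixture_library())
  expect_identical(sum(sim$truth$metabolites$differential), 30L)
})

test_that("every non-noise peak traces to a (metabolite, adduct, k)", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 2L, library_size = 50L,
    mz_jitter_sd = 0, n_noise_peaks_mean = 0, rng_seed = 4L
  )
  sim <- simulate_experiment(cfg, fixture_library())
  theo <- sort(as.vector(outer(
    sim$truth$metabolites$ion_mz, (0:4) * 1.00336, `+`
  )))
  for (s in sim$spectra) {
    d <- vapply(s$mz, function(m) min(abs(theo - m)), numeric(1))
    expect_lt(max(d), 1e-9)
  }
})

test_that("noise peaks avoid true envelopes by the exclusion margin", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 2L, library_size = 30L,
    mz_jitter_sd = 0, n_noise_peaks_mean = 100, rng_seed = 5L
  )
  sim <- simulate_experiment(cfg, fixture_library())
  theo <- sort(as.vector(outer(
    sim$truth$metabolites$ion_mz, (0:4) * 1.00336, `+`
  )))
  for (s in sim$spectra) {
    d <- vapply(s$mz, function(m) min(abs(theo - m)), numeric(1))
    # every peak is either on-envelope (generated) or beyond the margin
    expect_true(all(d < 1e-9 | d > cfg$noise_exclusion))
  }
})

test_that("n_limitation draws differential metabolites from N-free pool", {
  cfg <- simulation_config("n_limitation", rng_seed = 6L)
  sim <- simulate_experiment(cfg, fixture_library())
  met <- sim$truth$metabolites
  d <- met[met$differential, ]
  expect_true(all(d$n_N == 0))
  expect_true(all(d$log2fc > 0)) # all up in the deplete group
})

test_that("light_dark regulates lipids in both directions", {
  cfg <- simulation_config("light_dark", rng_seed = 10L)
  sim <- simulate_experiment(cfg, fixture_library())
  fc <- sim$truth$metabolites$log2fc
  expect_gt(sum(fc > 0), 0L)
  expect_gt(sum(fc < 0), 0L)
})

test_that("empirical effect size converges to log2_effect_mean", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 200L, library_size = 40L,
    fraction_differential = 0.5, log2_effect_sd = 0,
    n_noise_peaks_mean = 0, rng_seed = 12L
  )
  sim <- simulate_experiment(cfg, fixture_library())
  met <- sim$truth$metabolites
  ab <- sim$truth$abundance
  g2 <- sim$truth$cells$condition == "dark"
  emp <- apply(log2(ab), 2, function(v) mean(v[g2]) - mean(v[!g2]))
  d <- which(met$differential)
  # each |empirical fc| estimates 1 with se = cell_log2_sd * sqrt(2/200);
  # the mean over n_diff metabolites shrinks that by sqrt(n_diff)
  se <- cfg$cell_log2_sd * sqrt(2 / 200) / sqrt(length(d))
  expect_lt(abs(mean(abs(emp[d])) - cfg$log2_effect_mean), 3 * se)
  # non-differential metabolites have no systematic shift
  expect_lt(abs(mean(emp[-d])), 3 * cfg$cell_log2_sd * sqrt(2 / 200) /
    sqrt(length(emp) - length(d)))
})

test_that("config invariants are validated before generation", {
  expect_error(
    simulation_config("light_dark", n_cells_per_group = 1L),
    "n_cells_per_group"
  )
  expect_error(
    simulation_config("light_dark", fraction_differential = 1.2),
    "fraction_differential"
  )
  expect_error(
    simulation_config("light_dark", mz_jitter_sd = -1),
    "standard deviations"
  )
})

test_that("thin_library output satisfies its separation guarantees", {
  libt <- fixture_thinned()
  masses <- vapply(libt$formula, monoisotopic_mass, numeric(1))
  pref <- masses + adduct_shift(libt$adduct)
  grid <- sort(as.vector(outer(masses, adduct_shift(adduct_table()$name),
    `+`
  )))
  for (i in seq_along(pref)) {
    others <- setdiff(seq_along(grid), which(abs(grid - pref[i]) < 1e-9))
    expect_gt(min(abs(grid[others] - pref[i])), 0.025)
  }
  # preferred ions clear of each other's replica positions
  repl <- outer(pref, (1:4) * 1.00336, `+`) # row i = replicas of ion i
  for (i in seq_along(pref)) {
    other_repl <- repl[-i, , drop = FALSE]
    expect_gt(min(abs(other_repl - pref[i])), 0.01)
  }
})
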