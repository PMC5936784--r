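# Filtering, TIC normalization, deisotoping, alignment.

test_that("intensity filter keeps strictly-above-threshold peaks", {
  s <- toy_spectrum(c(100, 200, 300, 400), c(800, 1000, 1200, 5000))
  out <- filter_low_intensity(s, 1000)
  expect_equal(out$spectrum$intensity, c(1200, 5000))
  expect_equal(out$report$fraction_peaks_removed, 0.5)
  expect_equal(out$report$fraction_intensity_retained, 6200 / 8000)

  # threshold 0 is the identity on all-positive spectra
  ident <- filter_low_intensity(s, 0)
  expect_equal(ident$spectrum$intensity, s$intensity)

  # empty spectrum: 0 removed, all (vacuously) retained
  e <- filter_low_intensity(toy_spectrum(numeric(0), numeric(0)), 1000)
  expect_equal(e$report$fraction_peaks_removed, 0)
  expect_equal(e$report$fraction_intensity_retained, 1.0)
})

test_that("TIC normalization yields unit total and errors on zero TIC", {
  s <- toy_spectrum(c(100, 200, 300), c(2000, 3000, 5000))
  n <- tic_normalize(s)
  expect_equal(n$intensity, c(0.2, 0.3, 0.5))
  expect_equal(sum(n$intensity), 1, tolerance = 1e-9)
  expect_equal(n$mz, s$mz)
  expect_equal(tic_normalize(toy_spectrum(150, 42))$intensity, 1.0)
  expect_error(
    tic_normalize(toy_spectrum(c(100, 200), c(0, 0))),
    "total ion current is zero"
  )
})

test_that("isotope envelopes collapse to the monoisotopic peak", {
  p <- alignment_params()
  s <- toy_spectrum(
    c(500.0000, 501.0034, 502.0067), c(1.0e6, 1.0e5, 1.0e4)
  )
  out <- collapse_isotopes(s, p)
  expect_equal(out$mz, 500.0000)
  expect_equal(out$intensity, 1.11e6)

  # outside the tolerance: 501.2 - 500 - 1.00336 = 0.197 > 0.05
  s2 <- toy_spectrum(c(500.0, 501.2), c(10, 5))
  expect_equal(length(collapse_isotopes(s2, p)$mz), 2L)
})

test_that("the replica cap splits long equally spaced runs", {
  p <- alignment_params() # max 5 replicas
  mz <- 500 + (0:6) * 1.00336
  s <- toy_spectrum(mz, rep(10, 7))
  out <- collapse_isotopes(s, p)
  expect_equal(out$mz, c(500, 500 + 5 * 1.00336))
  expect_equal(out$intensity, c(50, 20))
})

test_that("deisotoping conserves intensity and is idempotent", {
  set.seed(31)
  mz <- sort(runif(120, 100, 1000))
  s <- toy_spectrum(mz, runif(120, 1e3, 1e6))
  p <- alignment_params()
  out <- collapse_isotopes(s, p)
  expect_equal(sum(out$intensity), sum(s$intensity), tolerance = 1e-9)
  again <- collapse_isotopes(out, p)
  expect_equal(again$mz, out$mz)
  expect_equal(again$intensity, out$intensity)
})

test_that("competing peaks resolve to the nearest expected position", {
  p <- alignment_params()
  # foreign ion 0.02 below the replica slot; true replica is closer
  s <- toy_spectrum(
    c(500.0000, 500.9834, 501.0034), c(1e6, 5e5, 1e5)
  )
  out <- collapse_isotopes(s, p)
  # foreign ion survives as its own envelope; replica joins its parent
  expect_equal(out$mz, c(500.0000, 500.9834))
  expect_equal(out$intensity, c(1.1e6, 5e5))
})

test_that("alignment clusters by gap and weights the consensus", {
  sp <- list(
    toy_spectrum(400.2000, 1.0, "c1", "a"),
    toy_spectrum(400.2008, 3.0, "c2", "a"),
    toy_spectrum(400.1995, 1.0, "c3", "b"),
    toy_spectrum(500.0000, 1.0, "c4", "b")
  )
  fm <- align_features(sp, alignment_params())
  expect_equal(length(fm$consensus_mz), 2L)
  expect_equal(
    fm$consensus_mz[1],
    sum(c(400.2000, 400.2008, 400.1995) * c(1, 3, 1)) / 5
  )

  # gap 0.015 > 0.01 splits
  sp2 <- list(
    toy_spectrum(400.2000, 1.0, "c1", "a"),
    toy_spectrum(400.2150, 1.0, "c2", "b")
  )
  expect_equal(length(align_features(sp2)$consensus_mz), 2L)
})

test_that("alignment drops out-of-range peaks and zero-fills", {
  sp <- list(
    toy_spectrum(c(50, 400.2, 1600), c(1, 2, 3), "c1", "a"),
    toy_spectrum(400.2005, 5, "c2", "b")
  )
  fm <- align_features(sp)
  expect_equal(length(fm$consensus_mz), 1L)
  expect_equal(unname(fm$values[, 1]), c(2, 5))
})

test_that("adjacent consensus m/z always differ by > align_delta", {
  fm <- fixture_fm()
  expect_true(all(diff(fm$consensus_mz) > alignment_params()$align_delta))
  # per-cell normalized totals never exceed 1 (range drops only)
  expect_true(all(rowSums(fm$values) <= 1 + 1e-9))
})

test_that("jitter-free simulation recovers the exact ion count", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 3L, library_size = 60L,
    mz_jitter_sd = 0, n_noise_peaks_mean = 0, rng_seed = 8L
  )
  sim <- simulate_experiment(cfg, fixture_thinned())
  pre <- preprocess_spectra(sim$spectra)
  # thinned library: no two ions coincide, all in range
  expect_equal(
    length(pre$fm$consensus_mz), nrow(sim$truth$metabolites)
  )
})

test_that("alignment recovery meets the ground-truth oracle bound", {
  sim <- fixture_sim() # jitter sd 0.002, defaults, 200 metabolites
  fm <- fixture_fm()
  rec <- recovery_stats(fm, sim$truth)
  expect_gte(rec$recovery_rate, 0.95)
})
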