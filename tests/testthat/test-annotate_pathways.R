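# Adduct-aware mass matching, matrix annotation, pathway roll-up.

test_that("match_feature returns complete isomer sets at zero error", {
  lib <- fixture_library()
  mz <- adduct_mz("C33H36N4O6", "+Na+")
  cand <- match_feature(mz, lib, tolerance = 0.01)
  iso <- cand[abs(cand$mass_error) < 1e-9, ]
  expect_setequal(
    iso$name[iso$adduct == "+Na+"],
    c("(3Z)-Phytochromobilin", "15,16-Dihydrobiliverdin", "Bilirubin")
  )
  # outside tolerance: empty
  expect_equal(nrow(match_feature(mz + 0.02, lib, tolerance = 0.01)), 0L)
})

test_that("match_feature agrees with a brute-force scan", {
  lib <- fixture_library()
  adducts <- adduct_table()$name
  masses <- vapply(lib$formula, monoisotopic_mass, numeric(1))
  brute <- function(mz, tol) {
    hits <- character(0)
    for (i in seq_len(nrow(lib))) {
      for (a in adducts) {
        if (abs(mz - (masses[i] + adduct_shift(a))) <= tol) {
          hits <- c(hits, paste(lib$name[i], a))
        }
      }
    }
    sort(hits)
  }
  set.seed(17)
  queries <- c(
    runif(150, 100, 1000),
    sample(masses, 50) + sample(adduct_shift(adducts), 50, TRUE) +
      runif(50, -0.02, 0.02)
  )
  for (mz in queries) {
    got <- match_feature(mz, lib, tolerance = 0.01)
    expect_identical(
      sort(paste(got$name, got$adduct)), brute(mz, 0.01),
      info = sprintf("mz %.4f", mz)
    )
  }
})

test_that("candidate lists are monotone in tolerance", {
  lib <- fixture_library()
  mz <- adduct_mz("C19H12O5", "+K+") + 0.004
  small <- match_feature(mz, lib, tolerance = 0.005)
  large <- match_feature(mz, lib, tolerance = 0.05)
  expect_true(all(
    paste(small$name, small$adduct) %in% paste(large$name, large$adduct)
  ))
  expect_gte(nrow(large), nrow(small))
})

test_that("annotation is deterministic under library row order", {
  lib <- fixture_library()
  fm <- feature_matrix(
    matrix(0.5, 1, 2), "c1", "a",
    c(adduct_mz("C6H12O6", "+Na+"), adduct_mz("C33H36N4O6", "+Na+"))
  )
  a1 <- annotate_matrix(fm, lib)
  set.seed(5)
  a2 <- annotate_matrix(fm, lib[sample(nrow(lib)), ])
  expect_equal(as.data.frame(a1), as.data.frame(a2))
  # best flag goes to the lexicographically smallest isomer name
  best2 <- a1[a1$feature_id == fm$feature_ids[2] & a1$is_best, ]
  expect_identical(best2$name, "(3Z)-Phytochromobilin")
})

test_that("annotate_matrix handles empty/degenerate cases", {
  fm <- feature_matrix(matrix(0.5, 1, 1), "c1", "a", 500.123)
  empty <- annotate_matrix(fm, fixture_library()[0, ])
  expect_equal(nrow(empty), 0L)
  expect_equal(attr(empty, "summary")$n_unannotated, 1L)
})

test_that("jitter-free synthetic features best-annotate to their truth", {
  cfg <- simulation_config("light_dark",
    n_cells_per_group = 2L, library_size = 80L,
    mz_jitter_sd = 0, n_noise_peaks_mean = 0, rng_seed = 13L
  )
  libt <- fixture_thinned()
  sim <- simulate_experiment(cfg, libt)
  pre <- preprocess_spectra(sim$spectra)
  ann <- annotate_matrix(pre$fm, libt)
  rec <- recovery_stats(pre$fm, sim$truth)
  acc <- annotation_accuracy(ann, rec)
  expect_identical(acc$n_correct, acc$n_checked)
})

test_that("pathway roll-up counts distinct names and filters by min_hits", {
  lib <- fixture_library()
  mzs <- c(
    adduct_mz("C19H12O5", "+K+"), # two polyketide isomers, one pathway
    adduct_mz("C21H38O6", "+Na+") # one macrolide
  )
  fm <- feature_matrix(matrix(0.5, 1, 2), "c1", "a", sort(mzs))
  ann <- annotate_matrix(fm, lib)
  pt <- builtin_pathways()
  roll <- pathway_rollup(ann, fm$feature_ids, pt, min_hits = 2)
  expect_true("map01057" %in% roll$pathway_id)
  expect_equal(roll$n_hits[roll$pathway_id == "map01057"], 2L)
  # the single-hit macrolide pathway is dropped at min_hits = 2
  expect_false("map00522" %in% roll$pathway_id)
  # ... and retained at min_hits = 1
  roll1 <- pathway_rollup(ann, fm$feature_ids, pt, min_hits = 1)
  expect_true("map00522" %in% roll1$pathway_id)
  # restricting the significant set shrinks or drops pathways
  roll_sub <- pathway_rollup(ann, fm$feature_ids[1], pt, min_hits = 2)
  expect_true(nrow(roll_sub) <= nrow(roll))
})

test_that("increasing min_hits never grows the pathway table", {
  fm <- fixture_fm()
  ann <- annotate_matrix(fm, fixture_thinned())
  pt <- builtin_pathways()
  sizes <- vapply(1:4, function(k) {
    nrow(pathway_rollup(ann, fm$feature_ids, pt, min_hits = k))
  }, integer(1))
  expect_true(all(diff(sizes) <= 0))
})
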