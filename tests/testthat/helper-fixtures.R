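# Shared fixtures, built once per test run and memoised.

.fixtures <- new.env(parent = emptyenv())

memo <- function(key, expr) {
  if (is.null(.fixtures[[key]])) .fixtures[[key]] <- force(expr)
  .fixtures[[key]]
}

fixture_library <- function() memo("lib", builtin_library())

fixture_thinned <- function() memo("thinned", thin_library(fixture_library()))

# one standard light/dark simulation on the unambiguous library
fixture_sim <- function() {
  memo("sim", {
    cfg <- simulation_config("light_dark", library_size = 200L, rng_seed = 3L)
    simulate_experiment(cfg, fixture_thinned())
  })
}

fixture_fm <- function() {
  memo("fm", preprocess_spectra(fixture_sim()$spectra)$fm)
}

# tiny hand-made spectra for unit tests
toy_spectrum <- function(mz, intensity, cell = "c1", cond = "a") {
  spectrum(cell, cond, mz, intensity)
}

# Table 1-style worked-example compounds: (name, formula, counter-ion)
table_compounds <- function() {
  tibble::tribble(
    ~name, ~formula, ~adduct,
    "6-Deoxyerythronolide B", "C21H38O6", "+Na+",
    "Avermectin A2a", "C49H76O15", "+H+",
    "Avermectin A2a aglycone", "C35H52O9", "+Na+",
    "Avermectin B2b", "C47H72O15", "+Na+",
    "Demethyllactenocin", "C37H61NO14", "+NH4+",
    "Erythronolide B", "C21H38O7", "+K+",
    "L-Oleandrosyl-oleandolide", "C27H46O10", "+Na+",
    "(3Z)-Phytochromobilin", "C33H36N4O6", "+Na+",
    "15,16-Dihydrobiliverdin", "C33H36N4O6", "+Na+",
    "Bilirubin", "C33H36N4O6", "+Na+",
    "I-Urobilinogen", "C33H44N4O6", "+K+",
    "19-Hydroxytetrangulol", "C19H12O5", "+K+",
    "Dehydrorabelomycin", "C19H12O5", "+K+",
    "(3R)-3-Isopropenyl-6-oxoheptanoate", "C10H16O3", "+NH4+",
    "(3S)-3-Isopropenyl-6-oxoheptanoate", "C10H16O3", "+NH4+",
    "1,6,6-Trimethyl-2,7-dioxabicyclo[3.2.2]nonan-3-one", "C10H16O3",
    "+NH4+",
    "4,5-Dihydro-5,5-dimethyl-4-(3-oxobutyl)furan-2(3H)-one", "C10H16O3",
    "+NH4+"
  )
}
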