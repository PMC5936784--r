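# Synthetic-data generator: a built-in metabolite library and a per-cell
# spectrum simulator with full ground truth, emulating two-condition
# single-cell direct-infusion experiments (light/dark illumination and
# N-replete/N-deplete nutrient status of a phytoplankton culture).

LIPID_CLASSES <- c("PA", "PE", "PG", "PS", "PI", "PC", "MG", "DG", "TG")

# formula of a glycerolipid/phospholipid species given its class and total
# acyl carbon:double-bond count, using standard head-group compositions
.lipid_formula <- function(class, n, d) {
  switch(class,
    PA = sprintf("C%dH%dO8P", n + 3L, 2L * n + 5L - 2L * d),
    PE = sprintf("C%dH%dNO8P", n + 5L, 2L * n + 10L - 2L * d),
    PC = sprintf("C%dH%dNO8P", n + 8L, 2L * n + 16L - 2L * d),
    PG = sprintf("C%dH%dO10P", n + 6L, 2L * n + 11L - 2L * d),
    PS = sprintf("C%dH%dNO10P", n + 6L, 2L * n + 10L - 2L * d),
    PI = sprintf("C%dH%dO13P", n + 9L, 2L * n + 15L - 2L * d),
    MG = sprintf("C%dH%dO4", n + 3L, 2L * n + 6L - 2L * d),
    DG = sprintf("C%dH%dO5", n + 3L, 2L * n + 4L - 2L * d),
    TG = sprintf("C%dH%dO6", n + 3L, 2L * n + 2L - 2L * d),
    stop("unknown lipid class: ", class)
  )
}

.lipid_block <- function(class, specs, adduct) {
  tibble::tibble(
    name = sprintf("%s(%d:%d)", class, specs[, 1L], specs[, 2L]),
    formula = vapply(
      seq_len(nrow(specs)),
      function(i) .lipid_formula(class, specs[i, 1L], specs[i, 2L]),
      character(1L)
    ),
    compound_class = class,
    adduct = adduct,
    pathways = if (class %in% c("MG", "DG", "TG")) "map00561" else "map00564"
  )
}

#' Built-in metabolite library
#'
#' A reference library of small metabolites and membrane/storage lipids
#' covering m/z 100-1500 as singly charged adduct ions: phycobilin-pathway
#' tetrapyrroles, macrolide and polyketide intermediates, terpenoids, the
#' proteinogenic amino acids, common sugars, organic acids, nucleotides and
#' cofactors, free fatty acids, and glycerolipid species of the classes
#' PA, PE, PG, PS, PI, PC, MG, DG and TG. Each record carries a Hill
#' formula, a compound class, a preferred counter-ion, and zero or more
#' pathway memberships (most records are deliberately unmapped, as is
#' typical for KEGG coverage of algal metabolomes).
#'
#' @return Tibble with columns `name`, `formula`, `compound_class`,
#'   `adduct`, `pathways` (semicolon-separated pathway ids, possibly "").
#' @export
builtin_library <- function() {
  aa <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "Glycine", "C2H5NO2", "+K+", "map00260",
    "L-Alanine", "C3H7NO2", "+Na+", "",
    "L-Serine", "C3H7NO3", "+Na+", "map00260",
    "L-Proline", "C5H9NO2", "+H+", "map00330",
    "L-Valine", "C5H11NO2", "+H+", "map00290",
    "L-Threonine", "C4H9NO3", "+H+", "map00260",
    "L-Cysteine", "C3H7NO2S", "+H+", "",
    "L-Leucine", "C6H13NO2", "+H+", "map00290",
    "L-Isoleucine", "C6H13NO2", "+Na+", "map00290",
    "L-Asparagine", "C4H8N2O3", "+H+", "",
    "L-Aspartate", "C4H7NO4", "+H+", "",
    "L-Glutamine", "C5H10N2O3", "+H+", "",
    "L-Lysine", "C6H14N2O2", "+H+", "",
    "L-Glutamate", "C5H9NO4", "+H+", "",
    "L-Methionine", "C5H11NO2S", "+H+", "",
    "L-Histidine", "C6H9N3O2", "+H+", "",
    "L-Phenylalanine", "C9H11NO2", "+H+", "",
    "L-Arginine", "C6H14N4O2", "+H+", "map00330",
    "L-Tyrosine", "C9H11NO3", "+H+", "",
    "L-Tryptophan", "C11H12N2O2", "+H+", ""
  )
  aa$compound_class <- "amino acid"

  sugars <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "D-Glucose", "C6H12O6", "+Na+", "map00010;map00500",
    "D-Fructose", "C6H12O6", "+K+", "map00010",
    "D-Galactose", "C6H12O6", "+H+", "",
    "myo-Inositol", "C6H12O6", "+NH4+", "",
    "Sucrose", "C12H22O11", "+Na+", "map00500",
    "Trehalose", "C12H22O11", "+K+", "map00500",
    "D-Ribose", "C5H10O5", "+Na+", "",
    "D-Xylose", "C5H10O5", "+K+", "",
    "D-Mannitol", "C6H14O6", "+Na+", "",
    "Glycerol", "C3H8O3", "+K+", "map00561"
  )
  sugars$compound_class <- "sugar"

  acids <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "Pyruvate", "C3H4O3", "+K+", "map00010",
    "L-Lactate", "C3H6O3", "+K+", "map00010",
    "Succinate", "C4H6O4", "+H+", "map00020",
    "Fumarate", "C4H4O4", "+H+", "map00020",
    "L-Malate", "C4H6O5", "+H+", "map00020",
    "Citrate", "C6H8O7", "+H+", "map00020",
    "2-Oxoglutarate", "C5H6O5", "+H+", "map00020",
    "Oxaloacetate", "C4H4O5", "+Na+", "map00020"
  )
  acids$compound_class <- "organic acid"

  nucl <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "Adenine", "C5H5N5", "+H+", "map00230",
    "Guanine", "C5H5N5O", "+H+", "map00230",
    "Uracil", "C4H4N2O2", "+H+", "map00240",
    "Cytosine", "C4H5N3O", "+H+", "map00240",
    "Thymine", "C5H6N2O2", "+H+", "map00240",
    "Adenosine", "C10H13N5O4", "+H+", "map00230",
    "Guanosine", "C10H13N5O5", "+H+", "map00230",
    "Uridine", "C9H12N2O6", "+H+", "map00240",
    "Cytidine", "C9H13N3O5", "+H+", "map00240",
    "Inosine", "C10H12N4O5", "+H+", "map00230",
    "Hypoxanthine", "C5H4N4O", "+H+", "map00230",
    "Xanthine", "C5H4N4O2", "+H+", "map00230",
    "Urate", "C5H4N4O3", "+H+", "map00230",
    "AMP", "C10H14N5O7P", "+H+", "map00230",
    "GMP", "C10H14N5O8P", "+H+", "map00230",
    "UMP", "C9H13N2O9P", "+H+", "map00240",
    "CMP", "C9H14N3O8P", "+H+", "map00240",
    "ADP", "C10H15N5O10P2", "+H+", "map00230",
    "ATP", "C10H16N5O13P3", "+H+", "map00230",
    "NAD+", "C21H27N7O14P2", "+H+", "",
    "NADP+", "C21H28N7O17P3", "+H+", "",
    "FAD", "C27H33N9O15P2", "+H+", ""
  )
  nucl$compound_class <- "nucleotide"

  misc <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "Chlorophyll a", "C55H72MgN4O5", "+H+", "map00860",
    "Pheophytin a", "C55H74N4O5", "+H+", "map00860",
    "beta-Carotene", "C40H56", "+H+", "",
    "Phytol", "C20H40O", "+H+", "",
    "alpha-Tocopherol", "C29H50O2", "+H+", "",
    "Glycine betaine", "C5H11NO2", "+Na+", "",
    "Proline betaine", "C7H13NO2", "+H+", "",
    "DMSP", "C5H10O2S", "+H+", "",
    "Glutathione", "C10H17N3O6S", "+H+", "",
    "L-Ascorbate", "C6H8O6", "+H+", "",
    "Riboflavin", "C17H20N4O6", "+H+", "",
    "Pantothenate", "C9H17NO5", "+H+", "",
    "Biotin", "C10H16N2O3S", "+H+", "",
    "Folate", "C19H19N7O6", "+H+", "",
    "Pyridoxine", "C8H11NO3", "+H+", "",
    "Nicotinamide", "C6H6N2O", "+H+", "",
    "L-Carnitine", "C7H15NO3", "+H+", "",
    "O-Acetylcarnitine", "C9H17NO4", "+H+", "",
    "Spermidine", "C7H19N3", "+H+", "",
    "Spermine", "C10H26N4", "+H+", "",
    "Putrescine", "C4H12N2", "+K+", "",
    "Taurine", "C2H7NO3S", "+H+", "",
    "Creatine", "C4H9N3O2", "+H+", "",
    "L-Citrulline", "C6H13N3O3", "+H+", "",
    "L-Ornithine", "C5H12N2O2", "+H+", "map00330",
    "4-Aminobutanoate", "C4H9NO2", "+K+", "",
    "Ectoine", "C6H10N2O2", "+H+", "",
    "Sarcosine", "C3H7NO2", "+K+", "map00260",
    "Choline phosphate", "C5H14NO4P", "+H+", "map00564",
    "Ethanolamine phosphate", "C2H8NO4P", "+H+", "map00564",
    "Fucoxanthin", "C42H58O6", "+Na+", "",
    "Peridinin", "C39H50O7", "+Na+", "",
    "Diadinoxanthin", "C40H54O3", "+H+", "",
    "Diatoxanthin", "C40H54O2", "+H+", "",
    "Zeaxanthin", "C40H56O2", "+H+", "",
    "Violaxanthin", "C40H56O4", "+H+", "",
    "Astaxanthin", "C40H52O4", "+H+", "",
    "Echinenone", "C40H54O", "+H+", "",
    "Cholesterol", "C27H46O", "+H+", "",
    "beta-Sitosterol", "C29H50O", "+H+", "",
    "Brassicasterol", "C28H46O", "+H+", "",
    "Ergosterol", "C28H44O", "+H+", "",
    "Squalene", "C30H50", "+H+", "",
    "Pheophorbide a", "C35H36N4O5", "+H+", "map00860",
    "Chlorophyllide a", "C35H34MgN4O5", "+H+", "map00860",
    "Protoporphyrin IX", "C34H34N4O4", "+H+", "map00860",
    "Heme b", "C34H32FeN4O4", "+H+", "map00860",
    "Retinol", "C20H30O", "+H+", "",
    "Retinal", "C20H28O", "+H+", ""
  )
  misc$compound_class <- "other"

  # phycobilin-pathway tetrapyrroles, macrolides, polyketides, terpenoids
  special <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways, ~compound_class,
    "6-Deoxyerythronolide B", "C21H38O6", "+Na+", "map00522", "macrolide",
    "Avermectin A2a", "C49H76O15", "+H+", "map00522", "macrolide",
    "Avermectin A2a aglycone", "C35H52O9", "+Na+", "map00522", "macrolide",
    "Avermectin B2b", "C47H72O15", "+Na+", "map00522", "macrolide",
    "Demethyllactenocin", "C37H61NO14", "+NH4+", "map00522", "macrolide",
    "Erythronolide B", "C21H38O7", "+K+", "map00522", "macrolide",
    "L-Oleandrosyl-oleandolide", "C27H46O10", "+Na+", "map00522", "macrolide",
    "(3Z)-Phytochromobilin", "C33H36N4O6", "+Na+", "map00860", "tetrapyrrole",
    "15,16-Dihydrobiliverdin", "C33H36N4O6", "+Na+", "map00860",
    "tetrapyrrole",
    "Bilirubin", "C33H36N4O6", "+Na+", "map00860", "tetrapyrrole",
    "I-Urobilinogen", "C33H44N4O6", "+K+", "map00860", "tetrapyrrole",
    "19-Hydroxytetrangulol", "C19H12O5", "+K+", "map01057", "polyketide",
    "Dehydrorabelomycin", "C19H12O5", "+K+", "map01057", "polyketide",
    "(3R)-3-Isopropenyl-6-oxoheptanoate", "C10H16O3", "+NH4+", "map00903",
    "terpenoid",
    "(3S)-3-Isopropenyl-6-oxoheptanoate", "C10H16O3", "+NH4+", "map00903",
    "terpenoid",
    "1,6,6-Trimethyl-2,7-dioxabicyclo[3.2.2]nonan-3-one", "C10H16O3",
    "+NH4+", "map00902", "terpenoid",
    "4,5-Dihydro-5,5-dimethyl-4-(3-oxobutyl)furan-2(3H)-one", "C10H16O3",
    "+NH4+", "map00902", "terpenoid"
  )

  fa_specs <- rbind(
    c(10, 0), c(12, 0), c(13, 0), c(14, 0), c(14, 1), c(15, 0), c(16, 0),
    c(16, 1), c(17, 0), c(18, 0), c(18, 1), c(18, 2), c(18, 3), c(19, 0),
    c(20, 0), c(20, 1), c(20, 4), c(20, 5), c(21, 0), c(22, 1), c(22, 2),
    c(22, 6), c(24, 0), c(24, 1), c(26, 0)
  )
  fa <- tibble::tibble(
    name = sprintf("FA(%d:%d)", fa_specs[, 1L], fa_specs[, 2L]),
    formula = sprintf(
      "C%dH%dO2", fa_specs[, 1L], 2L * fa_specs[, 1L] - 2L * fa_specs[, 2L]
    ),
    compound_class = "FA",
    adduct = "+Na+",
    pathways = "map00071"
  )

  cer_n <- c(14L, 16L, 18L, 20L, 22L, 24L)
  sphingo <- rbind(
    tibble::tibble(
      name = sprintf("Cer(d18:1/%d:0)", cer_n),
      formula = sprintf("C%dH%dNO3", 18L + cer_n, 35L + 2L * cer_n),
      compound_class = "Cer", adduct = "+H+", pathways = ""
    ),
    tibble::tibble(
      name = sprintf("SM(d18:1/%d:0)", cer_n),
      formula = sprintf("C%dH%dN2O6P", 23L + cer_n, 47L + 2L * cer_n),
      compound_class = "SM", adduct = "+H+", pathways = ""
    ),
    tibble::tibble(
      name = sprintf("HexCer(d18:1/%d:0)", c(16L, 18L, 22L, 24L)),
      formula = sprintf(
        "C%dH%dNO8", 24L + c(16L, 18L, 22L, 24L),
        45L + 2L * c(16L, 18L, 22L, 24L)
      ),
      compound_class = "HexCer", adduct = "+H+", pathways = ""
    )
  )

  acyl_n <- c(3L, 4L, 6L, 8L, 10L, 12L, 14L, 16L, 18L)
  carn <- tibble::tibble(
    name = sprintf("Acylcarnitine(%d:0)", acyl_n),
    formula = sprintf("C%dH%dNO4", 7L + acyl_n, 13L + 2L * acyl_n),
    compound_class = "acylcarnitine", adduct = "+H+", pathways = "map00071"
  )

  lyso_specs <- rbind(
    c(14, 0), c(16, 0), c(16, 1), c(18, 0), c(18, 1), c(18, 2),
    c(20, 4), c(22, 6)
  )
  lyso <- rbind(
    tibble::tibble(
      name = sprintf("LPC(%d:%d)", lyso_specs[, 1L], lyso_specs[, 2L]),
      formula = sprintf(
        "C%dH%dNO7P", lyso_specs[, 1L] + 8L,
        2L * lyso_specs[, 1L] + 18L - 2L * lyso_specs[, 2L]
      ),
      compound_class = "LPC", adduct = "+H+", pathways = "map00564"
    ),
    tibble::tibble(
      name = sprintf("LPE(%d:%d)", lyso_specs[, 1L], lyso_specs[, 2L]),
      formula = sprintf(
        "C%dH%dNO7P", lyso_specs[, 1L] + 5L,
        2L * lyso_specs[, 1L] + 12L - 2L * lyso_specs[, 2L]
      ),
      compound_class = "LPE", adduct = "+H+", pathways = "map00564"
    ),
    tibble::tibble(
      name = sprintf(
        "LPA(%d:%d)", lyso_specs[1:5, 1L], lyso_specs[1:5, 2L]
      ),
      formula = sprintf(
        "C%dH%dO7P", lyso_specs[1:5, 1L] + 3L,
        2L * lyso_specs[1:5, 1L] + 7L - 2L * lyso_specs[1:5, 2L]
      ),
      compound_class = "LPA", adduct = "+NH4+", pathways = "map00564"
    )
  )

  natural <- tibble::tribble(
    ~name, ~formula, ~adduct, ~pathways,
    "Okadaic acid", "C44H68O13", "+Na+", "",
    "Domoic acid", "C15H21NO6", "+H+", "",
    "Saxitoxin", "C10H17N7O4", "+H+", "",
    "Abscisic acid", "C15H20O4", "+H+", "",
    "Jasmonic acid", "C12H18O3", "+H+", "",
    "Loliolide", "C11H16O3", "+H+", "",
    "Indole-3-acetate", "C10H9NO2", "+H+", "",
    "Gibberellin A3", "C19H22O6", "+H+", "",
    "Pyropheophorbide a", "C33H34N4O3", "+H+", "map00860",
    "gamma-Tocopherol", "C28H48O2", "+H+", ""
  )
  natural$compound_class <- "other"

  # even-chain acyl grids only: keeps PE(n,d) and PC(n-3,d), which share a
  # formula, from both appearing
  lipids <- rbind(
    .lipid_block("PA", rbind(
      c(30, 0), c(32, 0), c(32, 1), c(34, 1), c(34, 2), c(36, 1),
      c(36, 2), c(36, 3), c(36, 4), c(38, 4), c(38, 5), c(38, 6), c(40, 6)
    ), "+NH4+"),
    .lipid_block("PE", rbind(
      c(30, 0), c(32, 0), c(34, 1), c(34, 2), c(36, 1), c(36, 2),
      c(36, 3), c(36, 4), c(38, 4), c(38, 5), c(38, 6), c(40, 6), c(40, 7)
    ), "+H+"),
    .lipid_block("PC", rbind(
      c(30, 0), c(30, 1), c(32, 0), c(32, 1), c(34, 1), c(34, 2),
      c(34, 3), c(36, 1), c(36, 2), c(36, 3), c(36, 4), c(36, 5),
      c(38, 4), c(38, 5), c(38, 6), c(40, 6), c(40, 7), c(42, 6)
    ), "+H+"),
    .lipid_block("PG", rbind(
      c(30, 0), c(32, 0), c(34, 1), c(34, 2), c(34, 3), c(36, 1),
      c(36, 2), c(36, 3), c(36, 4), c(38, 5), c(38, 6)
    ), "+NH4+"),
    .lipid_block("PS", rbind(
      c(32, 0), c(34, 1), c(34, 2), c(36, 1), c(36, 2), c(36, 3),
      c(38, 3), c(38, 4), c(38, 5), c(40, 5), c(40, 6)
    ), "+H+"),
    .lipid_block("PI", rbind(
      c(30, 0), c(32, 0), c(34, 1), c(34, 2), c(36, 1), c(36, 2),
      c(36, 3), c(38, 3), c(38, 4), c(38, 5), c(40, 6)
    ), "+NH4+"),
    .lipid_block("MG", rbind(
      c(12, 0), c(14, 0), c(16, 0), c(16, 1), c(17, 0), c(18, 0),
      c(18, 1), c(18, 2), c(20, 3), c(20, 4), c(20, 5), c(22, 5),
      c(22, 6)
    ), "+Na+"),
    .lipid_block("DG", rbind(
      c(28, 0), c(30, 0), c(30, 1), c(32, 0), c(32, 1), c(32, 2),
      c(34, 0), c(34, 1), c(34, 2), c(36, 1), c(36, 2), c(36, 3),
      c(36, 4), c(38, 4), c(38, 5), c(38, 6), c(40, 6), c(40, 7)
    ), "+NH4+"),
    .lipid_block("TG", rbind(
      c(42, 0), c(44, 0), c(44, 1), c(46, 0), c(46, 1), c(46, 2),
      c(48, 0), c(48, 1), c(48, 2), c(50, 0), c(50, 1), c(50, 2),
      c(50, 3), c(52, 1), c(52, 2), c(52, 3), c(52, 4), c(54, 2),
      c(54, 3), c(54, 4), c(54, 5), c(54, 6), c(56, 2), c(56, 3),
      c(56, 5), c(56, 7), c(58, 3), c(58, 8), c(60, 3)
    ), "+NH4+")
  )

  cols <- c("name", "formula", "compound_class", "adduct", "pathways")
  lib <- rbind(
    special[, cols], aa[, cols], sugars[, cols], acids[, cols],
    nucl[, cols], misc[, cols], natural[, cols], fa[, cols],
    carn[, cols], sphingo[, cols], lyso[, cols], lipids[, cols]
  )
  tibble::as_tibble(lib)
}

#' Theoretical ion m/z for library records
#'
#' @param lib A metabolite library tibble (see [builtin_library()]).
#' @return Numeric vector: monoisotopic adduct m/z of each record's
#'   preferred counter-ion.
#' @export
library_ion_mz <- function(lib) {
  vapply(
    seq_len(nrow(lib)),
    function(i) adduct_mz(lib$formula[i], lib$adduct[i]),
    numeric(1L)
  )
}

#' Enforce unambiguous m/z structure within a library
#'
#' Greedily drops records so that (a) no two remaining records have
#' theoretical adduct m/z (over the full record-by-adduct grid) closer
#' than `min_sep`, and (b) no remaining record's preferred ion falls
#' within `envelope_sep` of another's isotope-replica positions
#' (preferred ion plus k times the 13C spacing). Used by recovery tests,
#' which require an unambiguous ion-to-metabolite mapping: (a) means a
#' jittered ion can only match its true generator, and (b) means no ion
#' can be swallowed into a neighbour's isotope envelope during
#' deisotoping.
#'
#' @param lib Metabolite library tibble.
#' @param min_sep Minimum separation (Da) between a preferred ion and any
#'   other candidate m/z. The default 0.025 exceeds the 0.02 ambiguity
#'   bound and the alignment merge bound (align delta 0.01 plus 6 jitter
#'   standard deviations at the 0.002 Da default).
#' @param adducts Adduct names spanned by the separation check.
#' @param envelope_sep Minimum distance (Da) between a preferred ion and
#'   any other record's replica positions; default 0.01 (about 5 jitter
#'   standard deviations: closer collisions cannot be resolved by
#'   nearest-position envelope assignment).
#' @param max_isotope_replicas,isotope_spacing Envelope geometry guarded
#'   against.
#' @return The thinned library tibble (earlier rows win conflicts).
#' @export
thin_library <- function(lib, min_sep = 0.025,
                         adducts = adduct_table()$name,
                         envelope_sep = 0.01,
                         max_isotope_replicas = 5L,
                         isotope_spacing = 1.00336) {
  masses <- vapply(lib$formula, monoisotopic_mass, numeric(1L))
  pref <- masses + adduct_shift(lib$adduct)
  ks <- seq_len(max_isotope_replicas - 1L) * isotope_spacing
  shifts <- adduct_shift(adducts)
  keep <- logical(nrow(lib))
  kept_mz <- numeric(0) # full adduct grid of kept records
  kept_pref <- numeric(0) # preferred (generated) ions of kept records
  mindist <- function(a, b) {
    if (length(a) == 0L || length(b) == 0L) {
      return(Inf)
    }
    min(vapply(a, function(m) min(abs(b - m)), numeric(1L)))
  }
  for (i in seq_len(nrow(lib))) {
    mzs <- masses[i] + shifts
    # only pairs involving a generated (preferred) ion can create
    # ambiguity: a candidate near my ion, or my candidates near an
    # already-kept ion
    ok <- mindist(pref[i], kept_mz) > min_sep &&
      mindist(mzs, kept_pref) > min_sep
    if (ok && length(kept_pref) > 0L && length(ks) > 0L) {
      kept_replicas <- as.vector(outer(kept_pref, ks, `+`))
      my_replicas <- pref[i] + ks
      ok <- min(abs(kept_replicas - pref[i])) > envelope_sep &&
        mindist(my_replicas, kept_pref) > envelope_sep
    }
    if (ok) {
      keep[i] <- TRUE
      kept_mz <- c(kept_mz, mzs)
      kept_pref <- c(kept_pref, pref[i])
    }
  }
  lib[keep, , drop = FALSE]
}

#' Read / write a metabolite library TSV
#'
#' Columns: `name`, `formula`, `compound_class`, `adduct`, `pathways`
#' (semicolon-separated ids, possibly empty).
#'
#' @param path File path.
#' @return `read_metabolite_library()`: library tibble.
#' @export
read_metabolite_library <- function(path) {
  df <- utils::read.delim(path,
    comment.char = "#", stringsAsFactors = FALSE,
    na.strings = NULL
  )
  need <- c("name", "formula", "compound_class", "adduct", "pathways")
  if (!all(need %in% colnames(df))) {
    stop("library must have columns: ", paste(need, collapse = ", "))
  }
  invisible(lapply(df$formula, parse_formula)) # validate
  adduct_shift(df$adduct) # validate
  tibble::as_tibble(df[, need])
}

#' @rdname read_metabolite_library
#' @param lib Library tibble.
#' @export
write_metabolite_library <- function(lib, path) {
  utils::write.table(lib, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read the packaged (or a user) pathway table
#'
#' @param path Path to a two-column TSV (`pathway_id`, `name`); defaults to
#'   the packaged offline fixture.
#' @return Tibble with columns `pathway_id`, `name`.
#' @export
builtin_pathways <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "pathways.tsv",
      package = "scmetab", mustWork = TRUE
    )
  }
  df <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("pathway_id", "name") %in% colnames(df))) {
    stop("pathway table must have columns pathway_id, name")
  }
  tibble::as_tibble(df)
}

#' Simulation configuration
#'
#' Defines the study conditions emulated by [simulate_experiment()]. The
#' two scenarios mirror the two experiment designs: `light_dark` (15 cells
#' per group, differential metabolites regulated in both directions) and
#' `n_limitation` (10 cells per group, differential metabolites drawn
#' preferentially from N-free compound classes and up-regulated in the
#' deplete group, so the true abundance-weighted C:N rises under
#' limitation).
#'
#' @param scenario `"light_dark"` or `"n_limitation"`.
#' @param n_cells_per_group Cells per condition; default 15 for
#'   `light_dark`, 10 for `n_limitation`.
#' @param library_size Number of library metabolites expressed per cell.
#' @param fraction_differential Proportion of expressed metabolites with a
#'   true between-condition effect; the differential count is
#'   `round(fraction_differential * library_size)`.
#' @param log2_effect_mean,log2_effect_sd Magnitude distribution of true
#'   log2 fold changes.
#' @param cell_log2_sd Within-group biological variation of each
#'   metabolite's per-cell abundance (log2 units).
#' @param baseline_log_intensity_mean,baseline_log_intensity_sd Natural-log
#'   baseline ion-intensity distribution across metabolites (arbitrary ion
#'   counts; the default centres peak intensities well above the usual
#'   1000-count export floor).
#' @param tic_scale_sd Log-normal sd of the per-cell total-ion-current
#'   scale factor.
#' @param mz_jitter_sd Gaussian m/z measurement error, Da.
#' @param n_noise_peaks_mean Poisson mean of low-intensity noise peaks per
#'   cell.
#' @param noise_intensity_range Uniform intensity range for noise peaks
#'   (straddling the export floor so filtering removes most of them).
#' @param noise_exclusion Noise peaks are never placed within this distance
#'   (Da) of a theoretical envelope position.
#' @param isotope_max_replicas Isotope replicas simulated per ion.
#' @param intensity_floor Intensity threshold context carried into the run
#'   configuration (the pipeline filter default).
#' @param rng_seed Integer seed; identical seeds give identical output.
#' @return List of class `simulation_config`.
#' @export
simulation_config <- function(scenario = c("light_dark", "n_limitation"),
                              n_cells_per_group = NULL,
                              library_size = 200L,
                              fraction_differential = 0.3,
                              log2_effect_mean = 1,
                              log2_effect_sd = 0.25,
                              cell_log2_sd = 0.6,
                              baseline_log_intensity_mean = log(5e4),
                              baseline_log_intensity_sd = 1,
                              tic_scale_sd = 0.3,
                              mz_jitter_sd = 0.002,
                              n_noise_peaks_mean = 50,
                              noise_intensity_range = c(100, 3000),
                              noise_exclusion = 0.05,
                              isotope_max_replicas = 5L,
                              intensity_floor = 1000,
                              rng_seed = 1L) {
  scenario <- match.arg(scenario)
  if (is.null(n_cells_per_group)) {
    n_cells_per_group <- if (scenario == "light_dark") 15L else 10L
  }
  cfg <- list(
    scenario = scenario,
    n_cells_per_group = as.integer(n_cells_per_group),
    library_size = as.integer(library_size),
    fraction_differential = fraction_differential,
    log2_effect_mean = log2_effect_mean,
    log2_effect_sd = log2_effect_sd,
    cell_log2_sd = cell_log2_sd,
    baseline_log_intensity_mean = baseline_log_intensity_mean,
    baseline_log_intensity_sd = baseline_log_intensity_sd,
    tic_scale_sd = tic_scale_sd,
    mz_jitter_sd = mz_jitter_sd,
    n_noise_peaks_mean = n_noise_peaks_mean,
    noise_intensity_range = noise_intensity_range,
    noise_exclusion = noise_exclusion,
    isotope_max_replicas = as.integer(isotope_max_replicas),
    intensity_floor = intensity_floor,
    rng_seed = as.integer(rng_seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (n_cells_per_group < 2L) stop("n_cells_per_group must be >= 2")
    if (library_size < 1L) stop("library_size must be >= 1")
    if (fraction_differential < 0 || fraction_differential > 1) {
      stop("fraction_differential must lie in [0, 1]")
    }
    sds <- c(
      log2_effect_sd, cell_log2_sd, baseline_log_intensity_sd,
      tic_scale_sd, mz_jitter_sd
    )
    if (any(sds < 0)) stop("all standard deviations must be >= 0")
    if (isotope_max_replicas < 1L) stop("isotope_max_replicas must be >= 1")
    if (n_noise_peaks_mean < 0) stop("n_noise_peaks_mean must be >= 0")
    if (length(noise_intensity_range) != 2L ||
      noise_intensity_range[1L] > noise_intensity_range[2L]) {
      stop("noise_intensity_range must be (min, max)")
    }
  })
  invisible(cfg)
}

.scenario_conditions <- function(scenario) {
  if (scenario == "light_dark") c("light", "dark") else c("replete", "deplete")
}

#' Simulate a two-condition single-cell experiment
#'
#' For each cell, every expressed metabolite contributes its preferred
#' adduct ion at the theoretical m/z plus Gaussian jitter, with isotope
#' replicas at multiples of the 13C spacing whose relative heights follow a
#' binomial 13C model on the carbon count (I(M+1)/I(M) ~ 0.0107 * nC).
#' Per-cell abundances are log-normal with a condition shift on the
#' differential metabolites; every spectrum is scaled by a log-normal
#' per-cell total-ion-current factor; noise peaks are uniform in m/z
#' (never within `noise_exclusion` of a true envelope position) with
#' intensities from `noise_intensity_range`.
#'
#' @param cfg A [simulation_config()].
#' @param lib Metabolite library tibble; defaults to [builtin_library()].
#'   When larger than `cfg$library_size` a random subset is expressed.
#' @return List of class `sc_experiment` with `spectra` (list of
#'   [spectrum()]), `truth` (ground-truth record, see Details) and
#'   `config`. The truth holds per-metabolite identity, theoretical ion
#'   m/z, differential flag and true log2 fold change; per-cell condition
#'   and TIC scale; and the full true per-cell abundance matrix.
#' @export
simulate_experiment <- function(cfg, lib = builtin_library()) {
  stopifnot(inherits(cfg, "simulation_config"))
  validate_simulation_config(cfg)
  if (nrow(lib) == 0L) stop("library is empty")
  withr::with_seed(cfg$rng_seed, .simulate_experiment_impl(cfg, lib))
}

.simulate_experiment_impl <- function(cfg, lib) {
  lsize <- min(cfg$library_size, nrow(lib))
  idx <- if (nrow(lib) > lsize) {
    sort(sample.int(nrow(lib), lsize))
  } else {
    seq_len(nrow(lib))
  }
  lib <- lib[idx, , drop = FALSE]
  formulas <- lapply(lib$formula, parse_formula)
  ion_mz <- vapply(formulas, monoisotopic_mass, numeric(1L)) +
    adduct_shift(lib$adduct)
  n_c <- vapply(formulas, element_count, integer(1L), element = "C")
  n_n <- vapply(formulas, element_count, integer(1L), element = "N")
  n_p <- vapply(formulas, element_count, integer(1L), element = "P")

  n_diff <- round(cfg$fraction_differential * lsize)
  conds <- .scenario_conditions(cfg$scenario)
  if (cfg$scenario == "n_limitation") {
    n_free <- which(n_n == 0L)
    take <- min(n_diff, length(n_free))
    diff_idx <- if (take > 0L) sample(n_free, take) else integer(0)
    if (take < n_diff) {
      diff_idx <- c(diff_idx, sample(setdiff(seq_len(lsize), n_free),
        n_diff - take))
    }
    signs <- rep(1, n_diff) # up in the deplete group
  } else {
    diff_idx <- if (n_diff > 0L) sample.int(lsize, n_diff) else integer(0)
    signs <- sample(c(-1, 1), n_diff, replace = TRUE)
  }
  log2fc <- numeric(lsize)
  if (n_diff > 0L) {
    log2fc[diff_idx] <- signs *
      abs(stats::rnorm(n_diff, cfg$log2_effect_mean, cfg$log2_effect_sd))
  }
  baseline <- stats::rnorm(
    lsize, cfg$baseline_log_intensity_mean, cfg$baseline_log_intensity_sd
  )

  n_cells <- 2L * cfg$n_cells_per_group
  condition <- rep(conds, each = cfg$n_cells_per_group)
  cell_id <- sprintf("%s_%02d", condition,
    rep(seq_len(cfg$n_cells_per_group), times = 2L))
  tic_scale <- exp(stats::rnorm(n_cells, 0, cfg$tic_scale_sd))

  # true (pre-TIC) abundances, log-normal around the condition mean
  shift <- outer(as.numeric(condition == conds[2L]), log2fc * log(2))
  log_ab <- matrix(baseline, n_cells, lsize, byrow = TRUE) + shift +
    matrix(
      stats::rnorm(n_cells * lsize, 0, cfg$cell_log2_sd * log(2)),
      n_cells, lsize
    )
  abundance <- exp(log_ab)
  dimnames(abundance) <- list(cell_id, lib$name)

  # isotope-envelope relative heights: binomial 13C model on carbon count
  p13 <- 0.0107
  k_max <- cfg$isotope_max_replicas - 1L
  ks <- 0L:k_max
  ratio <- t(vapply(
    n_c,
    function(nc) ifelse(ks <= nc, choose(nc, ks) * (p13 / (1 - p13))^ks, 0),
    numeric(k_max + 1L)
  ))

  theo_pos <- sort(as.vector(outer(ion_mz, ks * 1.00336, `+`)))
  base_mz <- as.vector(t(outer(ion_mz, ks * 1.00336, `+`))) # ion-major
  ion_of_peak <- rep(seq_len(lsize), each = k_max + 1L)
  ratio_vec <- as.vector(t(ratio))

  spectra <- vector("list", n_cells)
  for (j in seq_len(n_cells)) {
    ints <- rep(abundance[j, ] * tic_scale[j], each = k_max + 1L) * ratio_vec
    keep <- ints > 0
    mzs <- base_mz[keep] +
      stats::rnorm(sum(keep), 0, cfg$mz_jitter_sd)
    ints <- ints[keep]
    n_noise <- stats::rpois(1L, cfg$n_noise_peaks_mean)
    if (n_noise > 0L) {
      noise_mz <- numeric(0)
      while (length(noise_mz) < n_noise) {
        cand <- stats::runif(n_noise - length(noise_mz), 100, 1500)
        d <- vapply(cand, function(m) min(abs(theo_pos - m)), numeric(1L))
        noise_mz <- c(noise_mz, cand[d > cfg$noise_exclusion])
      }
      noise_int <- stats::runif(
        n_noise, cfg$noise_intensity_range[1L], cfg$noise_intensity_range[2L]
      )
      mzs <- c(mzs, noise_mz)
      ints <- c(ints, noise_int)
    }
    # coincident ions (isomers sharing formula and adduct) merge into one
    # observed peak, as in a real spectrum
    if (anyDuplicated(mzs)) {
      agg <- rowsum(ints, group = mzs)
      mzs <- as.numeric(rownames(agg))
      ints <- as.numeric(agg)
    }
    spectra[[j]] <- spectrum(cell_id[j], condition[j], mzs, ints)
  }

  truth <- list(
    metabolites = tibble::tibble(
      name = lib$name,
      formula = lib$formula,
      compound_class = lib$compound_class,
      adduct = lib$adduct,
      ion_mz = ion_mz,
      n_C = n_c, n_N = n_n, n_P = n_p,
      differential = seq_len(lsize) %in% diff_idx,
      log2fc = log2fc,
      baseline_log_intensity = baseline,
      pathways = lib$pathways
    ),
    cells = tibble::tibble(
      cell_id = cell_id, condition = condition, tic_scale = tic_scale
    ),
    abundance = abundance,
    conditions = conds
  )
  structure(
    list(spectra = spectra, truth = truth, config = cfg),
    class = "sc_experiment"
  )
}

#' @export
print.sc_experiment <- function(x, ...) {
  cat(sprintf(
    "<sc_experiment> %s: %d cells (%s), %d metabolites, %d differential\n",
    x$config$scenario, length(x$spectra),
    paste(.scenario_conditions(x$config$scenario), collapse = " vs "),
    nrow(x$truth$metabolites), sum(x$truth$metabolites$differential)
  ))
  invisible(x)
}

#' Write a simulated experiment to disk
#'
#' Writes one peak list per cell, a manifest, and the ground truth as TSV
#' sidecars (`ground_truth_metabolites.tsv`, `ground_truth_cells.tsv`).
#'
#' @param sim An `sc_experiment` from [simulate_experiment()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the manifest path.
#' @export
write_experiment <- function(sim, dir) {
  stopifnot(inherits(sim, "sc_experiment"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- vapply(sim$spectra, function(s) {
    p <- paste0(s$cell_id, ".tsv")
    write_peaklist(s, file.path(dir, p))
    p
  }, character(1L))
  manifest <- data.frame(
    path = paths,
    cell_id = vapply(sim$spectra, `[[`, character(1L), "cell_id"),
    condition = vapply(sim$spectra, `[[`, character(1L), "condition"),
    stringsAsFactors = FALSE
  )
  mpath <- file.path(dir, "manifest.tsv")
  write_manifest(manifest, mpath)
  utils::write.table(sim$truth$metabolites,
    file.path(dir, "ground_truth_metabolites.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  utils::write.table(sim$truth$cells,
    file.path(dir, "ground_truth_cells.tsv"),
    sep = "\t", quote = FALSE, row.names = FALSE
  )
  invisible(mpath)
}

#' Simulate a null feature matrix at the statistical layer
#'
#' Builds a cells-by-features matrix directly from the generator's
#' abundance model with no differential effects: log-normal per-feature
#' baselines, log-normal per-cell biological noise, a per-cell
#' total-ion-current scale, and row (TIC) normalization. Used for
#' large-scale type-I-error calibration of the differential tests, where
#' the spectrum-level generator would be needlessly slow.
#'
#' @param n_cells_per_group Cells per condition.
#' @param n_features Number of features.
#' @param cell_log2_sd Within-group per-cell variation (log2 units).
#' @param baseline_log_intensity_mean,baseline_log_intensity_sd Natural-log
#'   baseline distribution across features.
#' @param tic_scale_sd Log-normal sd of the per-cell scale.
#' @param conditions Two group labels.
#' @param rng_seed Integer seed.
#' @return A [feature_matrix()] with evenly spaced placeholder m/z.
#' @export
simulate_null_matrix <- function(n_cells_per_group = 15L,
                                 n_features = 10000L,
                                 cell_log2_sd = 0.6,
                                 baseline_log_intensity_mean = log(5e4),
                                 baseline_log_intensity_sd = 1,
                                 tic_scale_sd = 0.3,
                                 conditions = c("light", "dark"),
                                 rng_seed = 1L) {
  stopifnot(n_cells_per_group >= 2L, n_features >= 1L,
    length(conditions) == 2L)
  n <- 2L * n_cells_per_group
  withr::with_seed(rng_seed, {
    base <- stats::rnorm(
      n_features, baseline_log_intensity_mean, baseline_log_intensity_sd
    )
    x <- exp(
      matrix(base, n, n_features, byrow = TRUE) +
        matrix(stats::rnorm(n * n_features, 0, cell_log2_sd * log(2)),
          n, n_features)
    )
    x <- x * exp(stats::rnorm(n, 0, tic_scale_sd))
    x <- x / rowSums(x)
    cond <- rep(conditions, each = n_cells_per_group)
    feature_matrix(
      x,
      sprintf("%s_%02d", cond, rep(seq_len(n_cells_per_group), 2L)),
      cond,
      seq(100, 1500, length.out = n_features)
    )
  })
}

#' Ground-truth recovery statistics for an aligned matrix
#'
#' Matches each true ion (theoretical adduct m/z) to aligned features by
#' nearest m/z within `mz_tol` and counts ions in a mutual one-to-one
#' correspondence with a feature. Ions sharing an identical theoretical
#' m/z with another ion (exact isomer/adduct coincidences) merge into a
#' single observed peak by construction and are excluded from the
#' denominator.
#'
#' @param fm A [feature_matrix()].
#' @param truth Ground truth from [simulate_experiment()].
#' @param mz_tol Matching tolerance in Da.
#' @return List: `n_ions`, `n_recovered` (mutual 1:1 matches),
#'   `recovery_rate`, and `pairs` (tibble of matched ion/feature indices).
#' @export
recovery_stats <- function(fm, truth, mz_tol = 0.01) {
  met <- truth$metabolites
  amb <- duplicated(met$ion_mz) | duplicated(met$ion_mz, fromLast = TRUE)
  ions <- which(!amb)
  ion_mz <- met$ion_mz[ions]
  f_mz <- fm$consensus_mz
  nearest_feature <- vapply(ion_mz, function(m) {
    d <- abs(f_mz - m)
    j <- which.min(d)
    if (d[j] <= mz_tol) j else NA_integer_
  }, integer(1L))
  nearest_ion <- vapply(f_mz, function(m) {
    d <- abs(ion_mz - m)
    j <- which.min(d)
    if (d[j] <= mz_tol) j else NA_integer_
  }, integer(1L))
  mutual <- which(!is.na(nearest_feature) &
    nearest_ion[nearest_feature] == seq_along(ion_mz))
  pairs <- tibble::tibble(
    metabolite = met$name[ions[mutual]],
    adduct = met$adduct[ions[mutual]],
    ion_mz = ion_mz[mutual],
    feature = fm$feature_ids[nearest_feature[mutual]],
    consensus_mz = f_mz[nearest_feature[mutual]]
  )
  list(
    n_ions = length(ions),
    n_recovered = length(mutual),
    recovery_rate = length(mutual) / length(ions),
    pairs = pairs
  )
}

#' Best-candidate annotation accuracy against ground truth
#'
#' Over the 1:1 recovered features from [recovery_stats()], the fraction
#' whose best annotation candidate names the true generating metabolite
#' (and its counter-ion).
#'
#' @param ann Annotation tibble from [annotate_matrix()].
#' @param rec Result of [recovery_stats()].
#' @return List: `n_checked`, `n_correct`, `accuracy`.
#' @export
annotation_accuracy <- function(ann, rec) {
  best <- ann[ann$is_best %in% TRUE, , drop = FALSE]
  m <- match(rec$pairs$feature, best$feature_id)
  ok <- !is.na(m) &
    best$name[m] == rec$pairs$metabolite &
    best$adduct[m] == rec$pairs$adduct
  list(
    n_checked = nrow(rec$pairs),
    n_correct = sum(ok),
    accuracy = if (nrow(rec$pairs) > 0L) sum(ok) / nrow(rec$pairs) else NA_real_
  )
}
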