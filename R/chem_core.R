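# Chemistry kernel: molecular formulas, monoisotopic masses, adduct m/z.
# Atomic masses and adduct shifts are pinned in plain-text tables under
# inst/extdata so every downstream number is reproducible.

.chem <- new.env(parent = emptyenv())

ELECTRON_MASS <- 0.00054858

.load_chem_tables <- function() {
  if (!is.null(.chem$masses)) {
    return(invisible(NULL))
  }
  mfile <- system.file("extdata", "atomic_masses.tsv",
    package = "scmetab", mustWork = TRUE
  )
  mt <- utils::read.delim(mfile, comment.char = "#", stringsAsFactors = FALSE)
  .chem$masses <- stats::setNames(mt$monoisotopic_mass, mt$element)
  afile <- system.file("extdata", "adducts.tsv",
    package = "scmetab", mustWork = TRUE
  )
  .chem$adducts <- utils::read.delim(afile,
    comment.char = "#",
    stringsAsFactors = FALSE
  )
  invisible(NULL)
}

#' Packaged monoisotopic atomic masses
#'
#' @return Named numeric vector of monoisotopic atomic masses (Da), one entry
#'   per supported element symbol.
#' @export
atomic_masses <- function() {
  .load_chem_tables()
  .chem$masses
}

#' Supported positive-mode adducts
#'
#' The four singly charged counter-ions observed in positive-mode
#' electrospray of small metabolites: `+H+`, `+NH4+`, `+Na+`, `+K+`.
#' Mass shifts are electron-corrected (the ion is a +1 cation, so one
#' electron mass is subtracted from the neutral adduct group).
#'
#' @return Data frame with columns `name`, `group_formula`, `mass_shift`
#'   (Da) and `charge`.
#' @export
adduct_table <- function() {
  .load_chem_tables()
  .chem$adducts
}

#' @rdname adduct_table
#' @param name Character vector of adduct names (e.g. `"+Na+"`).
#' @return `adduct_shift()`: numeric vector of m/z shifts in Da.
#' @export
adduct_shift <- function(name) {
  at <- adduct_table()
  idx <- match(name, at$name)
  if (anyNA(idx)) {
    stop(
      "unsupported adduct name(s): ",
      paste(unique(name[is.na(idx)]), collapse = ", "),
      " (supported: ", paste(at$name, collapse = ", "), ")"
    )
  }
  at$mass_shift[idx]
}

#' Parse a Hill-style molecular formula
#'
#' Accepts plain concatenations of element symbols with optional integer
#' multiplicities (e.g. `"C33H36N4O6"`). No parentheses, hydrates, charges
#' or isotope labels. An absent multiplicity means 1; a repeated symbol is
#' accumulated. The empty map (from `format_formula` of a null formula) is
#' not parseable; an empty string is rejected.
#'
#' @param text A single formula string.
#' @return A `chem_formula`: named integer vector of element counts.
#' @examples
#' parse_formula("C33H36N4O6")
#' @export
parse_formula <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text)) {
    stop("formula must be a single character string")
  }
  s <- trimws(text)
  if (!nzchar(s)) {
    stop("empty formula string")
  }
  known <- names(atomic_masses())
  counts <- integer(0)
  rest <- s
  while (nzchar(rest)) {
    sym <- regmatches(rest, regexpr("^[A-Z][a-z]?", rest))
    if (length(sym) == 0L) {
      stop(sprintf(
        "cannot parse formula '%s': invalid token at '%s'", text, rest
      ))
    }
    # two-letter match may shadow a one-letter element followed by junk;
    # prefer the longest known symbol
    if (!(sym %in% known) && nchar(sym) == 2L &&
      substr(sym, 1L, 1L) %in% known) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    }
    if (!(sym %in% known)) {
      stop(sprintf("unknown element symbol '%s' in formula '%s'", sym, text))
    }
    rest <- substr(rest, nchar(sym) + 1L, nchar(rest))
    num <- regmatches(rest, regexpr("^[0-9]+", rest))
    n <- 1L
    if (length(num) == 1L && nzchar(num)) {
      n <- suppressWarnings(as.integer(num))
      if (is.na(n)) {
        stop(sprintf("multiplicity overflow for '%s' in '%s'", sym, text))
      }
      if (n == 0L) {
        stop(sprintf(
          "zero multiplicity for element '%s' in formula '%s'", sym, text
        ))
      }
      rest <- substr(rest, nchar(num) + 1L, nchar(rest))
    }
    counts[sym] <- if (sym %in% names(counts)) counts[[sym]] + n else n
  }
  structure(counts, class = "chem_formula")
}

#' Format a formula in Hill order
#'
#' Carbon first, then hydrogen, then remaining elements alphabetically
#' (all alphabetical when no carbon). `format_formula(parse_formula(x))`
#' re-parses to an identical count map.
#'
#' @param f A `chem_formula` (or a string, parsed first).
#' @return A single formula string; `""` for the null formula.
#' @export
format_formula <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0L) {
    return("")
  }
  els <- names(f)
  if ("C" %in% els) {
    rest <- sort(setdiff(els, c("C", "H")))
    ord <- c("C", intersect("H", els), rest)
  } else {
    ord <- sort(els)
  }
  paste0(ord, ifelse(unclass(f)[ord] == 1L, "", unclass(f)[ord]),
    collapse = ""
  )
}

#' @export
print.chem_formula <- function(x, ...) {
  cat("<chem_formula> ", format_formula(x), "\n", sep = "")
  invisible(x)
}

as_chem_formula <- function(f) {
  if (inherits(f, "chem_formula")) {
    return(f)
  }
  if (is.character(f) && length(f) == 1L) {
    return(parse_formula(f))
  }
  if (is.numeric(f) && !is.null(names(f))) {
    n <- as.integer(f)
    if (any(n < 1L)) stop("all element counts must be >= 1")
    return(structure(stats::setNames(n, names(f)), class = "chem_formula"))
  }
  stop("cannot interpret object as a molecular formula")
}

#' Monoisotopic mass of a neutral formula
#'
#' Elementwise sum of packaged monoisotopic atomic masses. The null
#' formula has mass 0.
#'
#' @param f A `chem_formula` or formula string.
#' @return Mass in Da.
#' @examples
#' monoisotopic_mass("H2O") # 18.010565
#' @export
monoisotopic_mass <- function(f) {
  f <- as_chem_formula(f)
  if (length(f) == 0L) {
    return(0)
  }
  am <- atomic_masses()
  miss <- setdiff(names(f), names(am))
  if (length(miss) > 0L) {
    stop(
      "no packaged monoisotopic mass for element(s): ",
      paste(miss, collapse = ", ")
    )
  }
  sum(am[names(f)] * as.numeric(unclass(f)))
}

#' m/z of a singly charged adduct ion
#'
#' `m/z = monoisotopic_mass(f) + mass_shift(adduct)` where the shift is
#' electron-corrected (e.g. `+H+` adds 1.007276 Da, not 1.007825).
#'
#' @param f A `chem_formula` or formula string.
#' @param adduct Adduct name, one of `adduct_table()$name`; vectorised.
#' @return m/z value(s) in Th (Da per unit charge; charge is +1).
#' @examples
#' adduct_mz("C33H36N4O6", "+Na+")
#' @export
adduct_mz <- function(f, adduct) {
  monoisotopic_mass(f) + adduct_shift(adduct)
}

#' Count atoms of one element in a formula
#'
#' @param f A `chem_formula` or formula string.
#' @param element Element symbol; must be a known symbol.
#' @return Integer count (0 when the element is absent).
#' @examples
#' element_count("C33H36N4O6", "N") # 4
#' @export
element_count <- function(f, element) {
  if (!is.character(element) || length(element) != 1L) {
    stop("element must be a single symbol")
  }
  if (!(element %in% names(atomic_masses()))) {
    stop(sprintf("unknown element symbol '%s'", element))
  }
  f <- as_chem_formula(f)
  if (element %in% names(f)) as.integer(unclass(f)[[element]]) else 0L
}
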