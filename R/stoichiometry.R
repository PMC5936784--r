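# Abundance-weighted elemental stoichiometry of the annotated metabolome:
# per-cell C:N and C:P ratios and their between-condition comparison.

#' Abundance-weighted atom count over a metabolite set
#'
#' `sum_i element_count(formula_i) * abundance_i` — the weighted elemental
#' sum underlying the metabolome C:N and C:P statistics. An empty scope
#' gives 0.
#'
#' @param formulas List (or character vector) of molecular formulas.
#' @param abundances Numeric vector of the same length (relative
#'   abundances).
#' @param element Element symbol (e.g. `"C"`, `"N"`, `"P"`).
#' @return The weighted sum (dimensionless).
#' @export
weighted_element_sum <- function(formulas, abundances, element) {
  if (length(formulas) != length(abundances)) {
    stop("formulas and abundances must have the same length")
  }
  if (length(formulas) == 0L) {
    return(0)
  }
  if (anyNA(formulas)) {
    stop("metabolite without a formula in scope; ",
      "restrict the scope to annotated features")
  }
  counts <- vapply(formulas, element_count, integer(1L), element = element)
  sum(counts * abundances)
}

#' Per-cell elemental C:N and C:P ratios of annotated features
#'
#' For each cell, sums the product of each scope metabolite's C, N and P
#' atom counts with its relative abundance (the feature-matrix value), and
#' forms C:N = weighted C / weighted N and C:P = weighted C / weighted P.
#' A zero denominator gives a flagged undefined ratio (NA), never an
#' infinity. Ratios are invariant to rescaling a cell's abundance vector
#' by any positive constant.
#'
#' @param fm A [feature_matrix()].
#' @param ann Annotation tibble from [annotate_matrix()]; the best
#'   candidate supplies each feature's formula (isomer ties share a
#'   formula, so the choice cannot affect elemental counts).
#' @param scope Character vector of feature ids to include; every scope
#'   feature must be annotated.
#' @return Tibble: `cell_id`, `condition`, `weighted_C`, `weighted_N`,
#'   `weighted_P`, `c_n`, `c_p`, `c_n_defined`, `c_p_defined`.
#' @export
elemental_ratios <- function(fm, ann, scope) {
  stopifnot(inherits(fm, "feature_matrix"))
  if (length(scope) == 0L) {
    stop("empty feature scope; nothing to sum")
  }
  idx <- match(scope, fm$feature_ids)
  if (anyNA(idx)) {
    stop("scope features absent from matrix: ",
      paste(scope[is.na(idx)], collapse = ", "))
  }
  best <- ann[ann$is_best %in% TRUE, , drop = FALSE]
  frm <- best$formula[match(scope, best$feature_id)]
  if (anyNA(frm)) {
    stop(
      "scope features without an annotation: ",
      paste(scope[is.na(frm)], collapse = ", ")
    )
  }
  counts <- vapply(
    frm,
    function(f) {
      fp <- parse_formula(f)
      c(
        element_count(fp, "C"), element_count(fp, "N"),
        element_count(fp, "P")
      )
    },
    numeric(3L)
  ) # 3 x n_scope
  vals <- fm$values[, idx, drop = FALSE]
  w <- unname(vals %*% t(counts)) # cells x 3
  c_n <- ifelse(w[, 2L] > 0, w[, 1L] / w[, 2L], NA_real_)
  c_p <- ifelse(w[, 3L] > 0, w[, 1L] / w[, 3L], NA_real_)
  tibble::tibble(
    cell_id = fm$cell_ids,
    condition = fm$conditions,
    weighted_C = w[, 1L],
    weighted_N = w[, 2L],
    weighted_P = w[, 3L],
    c_n = c_n,
    c_p = c_p,
    c_n_defined = !is.na(c_n),
    c_p_defined = !is.na(c_p)
  )
}

#' Compare per-cell elemental ratios between two conditions
#'
#' Welch t-test on the defined per-cell ratios; undefined-ratio cells are
#' excluded with an explicit count. Errors when fewer than two defined
#' ratios remain in either group.
#'
#' @param ratios Tibble from [elemental_ratios()].
#' @param ratio Which ratio to compare, `"c_n"` or `"c_p"`.
#' @return Tibble with one row: group means (named after the conditions),
#'   `t`, `df`, `p`, `n_excluded`.
#' @export
compare_ratios <- function(ratios, ratio = c("c_n", "c_p")) {
  ratio <- match.arg(ratio)
  lv <- unique(ratios$condition)
  if (length(lv) != 2L) {
    stop("expected exactly two conditions")
  }
  v <- ratios[[ratio]]
  defined <- !is.na(v)
  n_excluded <- sum(!defined)
  a <- v[defined & ratios$condition == lv[1L]]
  b <- v[defined & ratios$condition == lv[2L]]
  if (length(a) < 2L || length(b) < 2L) {
    stop(
      "fewer than 2 defined ", ratio, " ratios in group '",
      lv[which.min(c(length(a), length(b)))], "'"
    )
  }
  tt <- t_test_feature(a, b)
  out <- tibble::tibble(
    ratio = ratio,
    mean_1 = mean(a), mean_2 = mean(b),
    t = tt$t, df = tt$df, p = tt$p,
    n_excluded = n_excluded
  )
  names(out)[names(out) == "mean_1"] <- paste0("mean_", lv[1L])
  names(out)[names(out) == "mean_2"] <- paste0("mean_", lv[2L])
  out
}
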