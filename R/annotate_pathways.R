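# Tentative metabolite labeling of aligned features by adduct-aware
# monoisotopic-mass matching against a library, plus the two-hit pathway
# roll-up over significantly regulated features.

.candidate_grid <- function(lib, adducts) {
  masses <- vapply(lib$formula, monoisotopic_mass, numeric(1L))
  grid <- expand.grid(
    record = seq_len(nrow(lib)), adduct = adducts,
    stringsAsFactors = FALSE
  )
  grid$theoretical_mz <- masses[grid$record] + adduct_shift(grid$adduct)
  grid
}

# range query + ranking against a precomputed candidate grid
.match_grid <- function(mz, lib, grid, tol_da) {
  err <- mz - grid$theoretical_mz
  hit <- abs(err) <= tol_da
  res <- tibble::tibble(
    name = lib$name[grid$record[hit]],
    formula = lib$formula[grid$record[hit]],
    compound_class = lib$compound_class[grid$record[hit]],
    adduct = grid$adduct[hit],
    theoretical_mz = grid$theoretical_mz[hit],
    mass_error = err[hit],
    pathways = lib$pathways[grid$record[hit]]
  )
  res[order(abs(res$mass_error), res$name, res$adduct, method = "radix"), ]
}

#' Match one m/z against a metabolite library
#'
#' Returns every (metabolite, adduct) pair whose theoretical singly charged
#' adduct m/z lies within `tolerance` of the query, ranked by absolute mass
#' error with a deterministic tie-break (name, then adduct, byte order).
#' True isomers therefore all appear, sharing identical errors. An empty
#' result is valid — most features of a real cell go unannotated.
#'
#' @param mz Query m/z (Da).
#' @param lib Metabolite library tibble (see [builtin_library()]).
#' @param adducts Adduct names to consider; default all four.
#' @param tolerance Tolerance; interpreted in Da (`mode = "da"`, default)
#'   or parts-per-million (`mode = "ppm"`).
#' @param mode Tolerance mode.
#' @return Tibble with columns `name`, `formula`, `compound_class`,
#'   `adduct`, `theoretical_mz`, `mass_error` (observed minus theoretical,
#'   Da), ordered by `abs(mass_error)`.
#' @export
match_feature <- function(mz, lib, adducts = adduct_table()$name,
                          tolerance = 0.01, mode = c("da", "ppm")) {
  mode <- match.arg(mode)
  stopifnot(tolerance > 0, length(mz) == 1L)
  grid <- .candidate_grid(lib, adducts)
  tol_da <- if (mode == "da") tolerance else tolerance * 1e-6 * mz
  .match_grid(mz, lib, grid, tol_da)
}

#' Annotate every feature of a matrix
#'
#' Runs [match_feature()] per feature and stacks the candidate lists. The
#' best-candidate flag marks, per feature, the smallest absolute mass
#' error; among exact ties (isomers) the lexicographically smallest name
#' wins, and since isomers share a formula, downstream elemental counting
#' is unaffected by the choice.
#'
#' @param fm A [feature_matrix()].
#' @param lib Metabolite library tibble.
#' @param adducts Adduct names to consider.
#' @param tolerance,mode See [match_feature()].
#' @return Tibble with columns `feature_id`, `feature_mz`, `rank`, the
#'   [match_feature()] columns, and `is_best`. Attribute `summary` holds
#'   `n_features`, `n_annotated`, `n_unannotated` and `n_names` (distinct
#'   best-candidate metabolite names).
#' @export
annotate_matrix <- function(fm, lib, adducts = adduct_table()$name,
                            tolerance = 0.01, mode = c("da", "ppm")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fm, "feature_matrix"))
  grid <- if (nrow(lib) > 0L) .candidate_grid(lib, adducts) else NULL
  per_feature <- lapply(seq_along(fm$consensus_mz), function(j) {
    if (nrow(lib) == 0L) {
      return(NULL)
    }
    mzj <- fm$consensus_mz[j]
    tol_da <- if (mode == "da") tolerance else tolerance * 1e-6 * mzj
    cand <- .match_grid(mzj, lib, grid, tol_da)
    if (nrow(cand) == 0L) {
      return(NULL)
    }
    cand$feature_id <- fm$feature_ids[j]
    cand$feature_mz <- fm$consensus_mz[j]
    cand$rank <- seq_len(nrow(cand))
    cand$is_best <- seq_len(nrow(cand)) == 1L
    cand
  })
  out <- do.call(rbind, per_feature)
  if (is.null(out)) {
    out <- tibble::tibble(
      name = character(0), formula = character(0),
      compound_class = character(0), adduct = character(0),
      theoretical_mz = numeric(0), mass_error = numeric(0),
      pathways = character(0), feature_id = character(0),
      feature_mz = numeric(0), rank = integer(0), is_best = logical(0)
    )
  }
  cols <- c(
    "feature_id", "feature_mz", "rank", "name", "formula",
    "compound_class", "adduct", "theoretical_mz", "mass_error", "is_best",
    "pathways"
  )
  out <- out[, cols]
  n_annotated <- length(unique(out$feature_id))
  attr(out, "summary") <- list(
    n_features = length(fm$feature_ids),
    n_annotated = n_annotated,
    n_unannotated = length(fm$feature_ids) - n_annotated,
    n_names = length(unique(out$name[out$is_best]))
  )
  out
}

#' Pathway roll-up with a minimum-hit criterion
#'
#' Counts, per pathway, the distinct annotated metabolite names attached to
#' a given set of (typically significantly regulated) features, and retains
#' pathways reaching at least `min_hits` distinct metabolites. Counting
#' distinct names guards against one metabolite observed as several
#' features inflating a pathway; requiring two hits guards against the
#' limited reliability of m/z-only identifications.
#'
#' @param ann Annotation tibble from [annotate_matrix()].
#' @param significant_features Character vector of feature ids (must be a
#'   subset of the annotated matrix's features).
#' @param pathway_table Tibble with `pathway_id`, `name` columns.
#' @param min_hits Minimum distinct metabolites per retained pathway.
#' @return Tibble: `pathway_id`, `pathway_name`, `n_hits`, `metabolites`
#'   (semicolon-joined names), sorted by decreasing `n_hits` then id.
#' @export
pathway_rollup <- function(ann, significant_features, pathway_table,
                           min_hits = 2L) {
  stopifnot(min_hits >= 1L)
  sub <- ann[ann$feature_id %in% significant_features, , drop = FALSE]
  if (nrow(sub) == 0L) {
    return(tibble::tibble(
      pathway_id = character(0), pathway_name = character(0),
      n_hits = integer(0), metabolites = character(0)
    ))
  }
  # explode the semicolon-separated pathway memberships of every candidate
  pw_list <- strsplit(sub$pathways, ";", fixed = TRUE)
  rows <- rep(seq_len(nrow(sub)), lengths(pw_list))
  pw <- unlist(pw_list, use.names = FALSE)
  keep <- nzchar(pw)
  rows <- rows[keep]
  pw <- pw[keep]
  if (length(pw) == 0L) {
    return(tibble::tibble(
      pathway_id = character(0), pathway_name = character(0),
      n_hits = integer(0), metabolites = character(0)
    ))
  }
  hits <- split(sub$name[rows], pw)
  hits <- lapply(hits, function(x) sort(unique(x), method = "radix"))
  counts <- lengths(hits)
  res <- tibble::tibble(
    pathway_id = names(hits),
    pathway_name = pathway_table$name[
      match(names(hits), pathway_table$pathway_id)
    ],
    n_hits = as.integer(counts),
    metabolites = vapply(hits, paste, character(1L), collapse = ";")
  )
  res <- res[res$n_hits >= min_hits, , drop = FALSE]
  res[order(-res$n_hits, res$pathway_id, method = "radix"), ]
}

`%||%` <- function(a, b) if (is.null(a)) b else a
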