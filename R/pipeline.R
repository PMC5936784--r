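# Orchestration: config-driven end-to-end runs and the run summary.
# Stage order: filter -> normalize -> deisotope -> align -> annotate ->
# differential tests -> PLS-DA (fit, permutation, Q2) -> heat-map data ->
# stoichiometry -> pathway roll-up.

#' Pipeline configuration
#'
#' Every default follows the conventional acquisition/processing settings
#' for this kind of direct-infusion experiment: intensity floor 1000
#' counts, analysis range 100-1500 m/z, 5 isotope replicas at 0.05 Da, a
#' 0.01 Da alignment delta, raw alpha 0.05, annotation tolerance 0.01 Da,
#' and a two-hit pathway criterion. All randomness (permutations, CV
#' folds) fans out from the single `seed`.
#'
#' @param intensity_threshold Filter threshold (ion counts).
#' @param params An [alignment_params()].
#' @param tolerance Annotation mass tolerance.
#' @param tolerance_mode `"da"` or `"ppm"`.
#' @param alpha Raw per-feature significance level.
#' @param var_equal Pooled-variance t-tests instead of Welch.
#' @param n_components PLS-DA components.
#' @param n_permutations Label permutations for the PLS-DA test (1999 puts
#'   the attainable p floor at 5e-4; 999 at 1e-3).
#' @param folds Cross-validation folds for Q2.
#' @param ratio_scope `"significant-annotated"` (features both
#'   significantly regulated and annotated; the scope used for the
#'   elemental-ratio comparison) or `"all-annotated"`.
#' @param min_hits Pathway roll-up hit criterion.
#' @param seed Root integer seed.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(intensity_threshold = 1000,
                            params = alignment_params(),
                            tolerance = 0.01,
                            tolerance_mode = "da",
                            alpha = 0.05,
                            var_equal = FALSE,
                            n_components = 2L,
                            n_permutations = 1999L,
                            folds = 10L,
                            ratio_scope = c(
                              "significant-annotated", "all-annotated"
                            ),
                            min_hits = 2L,
                            seed = 1L) {
  ratio_scope <- match.arg(ratio_scope)
  stopifnot(
    intensity_threshold >= 0, inherits(params, "alignment_params"),
    tolerance > 0, alpha >= 0, alpha <= 1, n_permutations >= 19L,
    folds >= 2L, min_hits >= 1L
  )
  structure(
    list(
      intensity_threshold = intensity_threshold,
      params = params,
      tolerance = tolerance,
      tolerance_mode = tolerance_mode,
      alpha = alpha,
      var_equal = var_equal,
      n_components = as.integer(n_components),
      n_permutations = as.integer(n_permutations),
      folds = as.integer(folds),
      ratio_scope = ratio_scope,
      min_hits = as.integer(min_hits),
      seed = as.integer(seed)
    ),
    class = "pipeline_config"
  )
}

#' Run the full analysis pipeline
#'
#' Executes the complete chain on a list of raw per-cell spectra and
#' returns a run summary whose every number is recomputable from the
#' returned stage objects. With an `output_dir`, all stage tables and a
#' machine-readable summary are also written; identical inputs, config and
#' seed give byte-identical outputs.
#'
#' @param spectra List of [spectrum()] objects (or a manifest path /
#'   manifest data frame, from which spectra are read).
#' @param lib Metabolite library tibble.
#' @param pathway_table Pathway id/name tibble.
#' @param config A [pipeline_config()].
#' @param output_dir Optional directory for stage outputs.
#' @return List of class `pipeline_result` with `summary` (the run
#'   summary), `fm`, `annotations`, `differential`, `plsda`,
#'   `permutation`, `q2`, `heatmap`, `ratios`, `ratio_comparisons`,
#'   `pathways`, `config`.
#' @export
run_pipeline <- function(spectra,
                         lib = builtin_library(),
                         pathway_table = builtin_pathways(),
                         config = pipeline_config(),
                         output_dir = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(spectra) || is.data.frame(spectra)) {
    spectra <- read_experiment(spectra)
  }

  pre <- preprocess_spectra(spectra,
    threshold = config$intensity_threshold, params = config$params
  )
  fm <- pre$fm

  ann <- annotate_matrix(fm, lib,
    tolerance = config$tolerance, mode = config$tolerance_mode
  )
  ann_summary <- attr(ann, "summary")

  diff <- differential_features(fm,
    alpha = config$alpha,
    var_equal = config$var_equal
  )
  diff_counts <- attr(diff, "counts")
  sig_features <- diff$feature_id[diff$significant]

  fit <- plsda_fit(fm, config$n_components)
  perm <- plsda_permutation_test(fm,
    n_components = config$n_components,
    n_permutations = config$n_permutations,
    seed = config$seed + 1L
  )
  q2 <- plsda_q2(fm,
    n_components = config$n_components,
    folds = config$folds, seed = config$seed + 2L
  )

  # heat-map matrix over significantly regulated lipid-class features
  best <- ann[ann$is_best %in% TRUE, , drop = FALSE]
  lipid_features <- best$feature_id[best$compound_class %in% LIPID_CLASSES]
  heat_features <- intersect(sig_features, lipid_features)
  heat <- if (length(heat_features) >= 2L) {
    heatmap_data(fm, heat_features)
  } else {
    NULL
  }

  annotated_features <- unique(ann$feature_id)
  scope <- if (config$ratio_scope == "significant-annotated") {
    intersect(sig_features, annotated_features)
  } else {
    annotated_features
  }
  ratios <- NULL
  comparisons <- NULL
  ratio_note <- NULL
  if (length(scope) > 0L) {
    ratios <- elemental_ratios(fm, ann, scope)
    comparisons <- do.call(rbind, lapply(c("c_n", "c_p"), function(r) {
      tryCatch(compare_ratios(ratios, r), error = function(e) NULL)
    }))
  } else {
    ratio_note <- "no features in ratio scope"
  }

  pathways <- pathway_rollup(ann, sig_features, pathway_table,
    min_hits = config$min_hits
  )

  lv <- .two_conditions(fm)
  summary <- list(
    n_cells = length(fm$cell_ids),
    conditions = stats::setNames(
      as.integer(table(fm$conditions)[lv]), lv
    ),
    filter = pre$filter_report,
    n_features_pre_deisotope = pre$n_features_pre_deisotope,
    n_features = length(fm$feature_ids),
    annotation = ann_summary,
    differential = diff_counts,
    plsda = list(
      explained_y = fit$explained_y,
      separation = fit$separation,
      permutation_p = perm$p,
      q2 = q2
    ),
    ratio_scope = config$ratio_scope,
    n_ratio_scope_features = length(scope),
    ratio_comparisons = if (!is.null(comparisons)) {
      lapply(seq_len(nrow(comparisons)), function(i) as.list(comparisons[i, ]))
    } else {
      ratio_note
    },
    n_pathways_retained = nrow(pathways),
    seed = config$seed
  )

  result <- structure(
    list(
      summary = summary,
      fm = fm,
      annotations = ann,
      differential = diff,
      plsda = fit,
      permutation = perm,
      q2 = q2,
      heatmap = heat,
      ratios = ratios,
      ratio_comparisons = comparisons,
      pathways = pathways,
      config = config
    ),
    class = "pipeline_result"
  )
  if (!is.null(output_dir)) {
    write_pipeline_outputs(result, output_dir)
  }
  result
}

#' @export
print.pipeline_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(
    paste0(
      "<pipeline_result> %d cells (%s)\n",
      "  features: %d (pre-deisotoping %d); annotated %d\n",
      "  differential: %d significant (%s)\n",
      "  PLS-DA: permutation p = %.3g, Q2 = %.3f\n",
      "  pathways retained: %d\n"
    ),
    s$n_cells,
    paste(sprintf("%s n=%d", names(s$conditions), s$conditions),
      collapse = ", "
    ),
    s$n_features, s$n_features_pre_deisotope, s$annotation$n_annotated,
    s$differential$n_significant,
    paste(sprintf(
      "%s-high %d", names(s$differential$n_up), s$differential$n_up
    ), collapse = ", "),
    s$plsda$permutation_p, s$plsda$q2,
    s$n_pathways_retained
  ))
  invisible(x)
}

#' Write all pipeline outputs to a directory
#'
#' Emits the feature matrix (CSV), annotation/differential/score/ratio/
#' pathway tables (TSV), the heat-map matrix with its row and column
#' orders, and the run summary as JSON (`run_summary.json`) plus a
#' human-readable text rendering.
#'
#' @param result A `pipeline_result`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, `dir`.
#' @export
write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    utils::write.table(x, file.path(dir, f),
      sep = "\t", quote = FALSE,
      row.names = FALSE
    )
  }
  write_feature_matrix(result$fm, file.path(dir, "feature_matrix.csv"))
  write_annotations(result$annotations, file.path(dir, "annotations.tsv"))
  wt(result$differential, "differential.tsv")
  scores <- data.frame(
    cell_id = result$fm$cell_ids,
    condition = result$fm$conditions,
    result$plsda$scores
  )
  colnames(scores)[-(1:2)] <- paste0("comp", seq_len(ncol(result$plsda$scores)))
  wt(scores, "plsda_scores.tsv")
  if (!is.null(result$ratios)) wt(result$ratios, "elemental_ratios.tsv")
  if (!is.null(result$ratio_comparisons)) {
    wt(result$ratio_comparisons, "ratio_comparisons.tsv")
  }
  wt(result$pathways, "pathways.tsv")
  if (!is.null(result$heatmap)) {
    zm <- data.frame(
      feature_id = rownames(result$heatmap$z), result$heatmap$z,
      check.names = FALSE
    )
    wt(zm, "heatmap_matrix.tsv")
  }
  jsonlite::write_json(
    result$summary,
    file.path(dir, "run_summary.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  txt <- utils::capture.output(print(result))
  writeLines(txt, file.path(dir, "run_summary.txt"))
  invisible(dir)
}
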