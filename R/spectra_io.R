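# Readers and writers for on-disk artifacts: per-cell peak lists (TSV),
# the cells x features matrix (CSV with a consensus-m/z comment header),
# experiment manifests, and the annotation table.

#' Construct a single-cell spectrum
#'
#' A centroided peak list for one cell: strictly increasing m/z, non-negative
#' intensities, plus cell and condition identifiers.
#'
#' @param cell_id Single string identifying the cell.
#' @param condition Single string, the experimental group label.
#' @param mz Numeric vector of m/z values (Da); sorted on construction.
#' @param intensity Numeric vector of intensities (arbitrary ion-count
#'   units), same length as `mz`.
#' @return An object of class `spectrum`.
#' @export
spectrum <- function(cell_id, condition, mz, intensity) {
  stopifnot(
    is.character(cell_id), length(cell_id) == 1L,
    is.character(condition), length(condition) == 1L,
    is.numeric(mz), is.numeric(intensity), length(mz) == length(intensity)
  )
  if (anyNA(mz) || anyNA(intensity)) {
    stop("NA values in peak list for cell '", cell_id, "'")
  }
  if (any(intensity < 0)) {
    stop("negative intensities in peak list for cell '", cell_id, "'")
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  if (length(mz) > 1L && any(diff(mz) == 0)) {
    stop("duplicate m/z values in peak list for cell '", cell_id, "'")
  }
  structure(
    list(
      cell_id = cell_id, condition = condition,
      mz = as.numeric(mz), intensity = as.numeric(intensity)
    ),
    class = "spectrum"
  )
}

#' @export
print.spectrum <- function(x, ...) {
  cat(sprintf(
    "<spectrum> cell %s (%s): %d peaks, m/z %s\n",
    x$cell_id, x$condition, length(x$mz),
    if (length(x$mz)) {
      sprintf("%.4f-%.4f", min(x$mz), max(x$mz))
    } else {
      "(empty)"
    }
  ))
  invisible(x)
}

#' Read a tab-delimited peak list
#'
#' Two tab-separated numeric columns (m/z, intensity). Lines starting with
#' `#` are comments; a first non-comment line whose fields are not all
#' numeric is treated as a header and skipped. Malformed data rows raise an
#' error naming the offending line.
#'
#' @param path File path.
#' @param cell_id,condition Identifiers attached to the returned spectrum.
#' @return A [spectrum()].
#' @export
read_peaklist <- function(path, cell_id, condition) {
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L) {
    stop("empty peak list file: ", path)
  }
  parse_row <- function(x) {
    suppressWarnings(as.numeric(strsplit(x, "\t", fixed = TRUE)[[1L]]))
  }
  first <- parse_row(lines[1L])
  if (anyNA(first)) { # header line
    lines <- lines[-1L]
    lineno <- lineno[-1L]
    if (length(lines) == 0L) {
      stop("peak list file has a header but no data rows: ", path)
    }
  }
  mz <- numeric(length(lines))
  intensity <- numeric(length(lines))
  for (i in seq_along(lines)) {
    v <- parse_row(lines[i])
    if (length(v) < 2L || anyNA(v[1:2])) {
      stop(sprintf(
        "malformed peak-list row at line %d of %s: '%s'",
        lineno[i], path, lines[i]
      ))
    }
    mz[i] <- v[1L]
    intensity[i] <- v[2L]
  }
  spectrum(cell_id, condition, mz, intensity)
}

#' Write a spectrum as a tab-delimited peak list
#'
#' m/z is written with 6 decimals, intensity with 12 significant digits.
#'
#' @param s A [spectrum()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_peaklist <- function(s, path) {
  stopifnot(inherits(s, "spectrum"))
  lines <- c(
    "mz\tintensity",
    sprintf("%.6f\t%s", s$mz, formatC(s$intensity, digits = 12, format = "g"))
  )
  writeLines(lines, path)
  invisible(path)
}

.make_feature_ids <- function(consensus_mz) {
  ids <- sprintf("%.4f", consensus_mz)
  while (anyDuplicated(ids)) {
    d <- duplicated(ids)
    ids[d] <- paste0(ids[d], "a")
  }
  ids
}

#' Construct a cells x features matrix
#'
#' @param values Numeric matrix, cells in rows, features in columns.
#' @param cell_ids Character vector of unique cell identifiers (rows).
#' @param conditions Character vector of group labels, one per cell.
#' @param consensus_mz Strictly increasing numeric vector of feature m/z.
#' @param feature_ids Optional feature identifiers; by default the consensus
#'   m/z rendered to 4 decimals with a disambiguating suffix on collision.
#' @return An object of class `feature_matrix` with fields `values`,
#'   `cell_ids`, `conditions`, `consensus_mz`, `feature_ids`.
#' @export
feature_matrix <- function(values, cell_ids, conditions, consensus_mz,
                           feature_ids = NULL) {
  values <- as.matrix(values)
  stopifnot(
    nrow(values) == length(cell_ids),
    length(cell_ids) == length(conditions),
    ncol(values) == length(consensus_mz)
  )
  if (anyDuplicated(cell_ids)) stop("duplicate cell_ids")
  if (length(consensus_mz) > 1L && any(diff(consensus_mz) <= 0)) {
    stop("consensus_mz must be strictly increasing")
  }
  if (any(values < 0)) stop("feature-matrix values must be non-negative")
  if (is.null(feature_ids)) {
    feature_ids <- .make_feature_ids(consensus_mz)
  }
  if (anyDuplicated(feature_ids)) stop("duplicate feature ids")
  dimnames(values) <- list(cell_ids, feature_ids)
  structure(
    list(
      values = values,
      cell_ids = as.character(cell_ids),
      conditions = as.character(conditions),
      consensus_mz = as.numeric(consensus_mz),
      feature_ids = as.character(feature_ids)
    ),
    class = "feature_matrix"
  )
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "<feature_matrix> %d cells x %d features; conditions: %s\n",
    nrow(x$values), ncol(x$values),
    paste(sprintf(
      "%s (n=%d)", names(table(x$conditions)), as.integer(table(x$conditions))
    ), collapse = ", ")
  ))
  invisible(x)
}

#' Write / read a feature matrix as CSV
#'
#' Layout: a `#consensus_mz` comment line carrying full-precision feature
#' m/z, then a CSV with columns `cell_id`, `condition`, and one column per
#' feature. Round trips preserve values to better than 1e-12 relative and
#' consensus m/z to better than 1e-6 Da.
#'
#' @param fm A [feature_matrix()].
#' @param path File path.
#' @return `write_feature_matrix()`: invisibly `path`;
#'   `read_feature_matrix()`: a [feature_matrix()].
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  header <- paste0(
    "#consensus_mz,,", paste(fmt(fm$consensus_mz), collapse = ",")
  )
  cols <- paste(c("cell_id", "condition", fm$feature_ids), collapse = ",")
  rows <- vapply(seq_along(fm$cell_ids), function(i) {
    paste(c(
      fm$cell_ids[i], fm$conditions[i],
      fmt(fm$values[i, ])
    ), collapse = ",")
  }, character(1L))
  writeLines(c(header, cols, rows), path)
  invisible(path)
}

#' @rdname write_feature_matrix
#' @export
read_feature_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  mzline <- grep("^#consensus_mz", lines, value = TRUE)
  if (length(mzline) != 1L) {
    stop("feature-matrix file lacks a #consensus_mz header: ", path)
  }
  consensus_mz <- as.numeric(strsplit(mzline, ",", fixed = TRUE)[[1L]][-(1:2)])
  df <- utils::read.csv(
    text = paste(lines[!grepl("^#", lines)], collapse = "\n"),
    check.names = FALSE, stringsAsFactors = FALSE
  )
  ids <- colnames(df)[-(1:2)]
  if (anyDuplicated(ids)) {
    stop("duplicated feature id in feature-matrix file: ", path)
  }
  if (length(ids) != length(consensus_mz)) {
    stop("feature-matrix shape mismatch between header and columns: ", path)
  }
  values <- as.matrix(df[, -(1:2), drop = FALSE])
  storage.mode(values) <- "double"
  feature_matrix(values, df$cell_id, df$condition, consensus_mz,
    feature_ids = ids
  )
}

#' Read / write an experiment manifest
#'
#' Tab-separated table with columns `path`, `cell_id`, `condition`; exactly
#' two condition labels, each with at least two cells, unique cell ids.
#'
#' @param path Manifest file path.
#' @return A data frame with the three manifest columns.
#' @export
read_manifest <- function(path) {
  df <- utils::read.delim(path,
    comment.char = "#",
    stringsAsFactors = FALSE
  )
  validate_manifest(df)
  df
}

#' @rdname read_manifest
#' @param manifest A manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  validate_manifest(manifest)
  utils::write.table(manifest, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE
  )
  invisible(path)
}

validate_manifest <- function(df) {
  need <- c("path", "cell_id", "condition")
  if (!all(need %in% colnames(df))) {
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  }
  if (anyDuplicated(df$cell_id)) stop("manifest cell_ids must be unique")
  tab <- table(df$condition)
  if (length(tab) != 2L) {
    stop("manifest must contain exactly two condition labels, found ",
      length(tab))
  }
  if (any(tab < 2L)) {
    stop("each condition needs at least 2 cells")
  }
  invisible(df)
}

#' Read all spectra listed in a manifest
#'
#' @param manifest Manifest data frame or path to a manifest file.
#' @param base_dir Directory against which relative `path` entries are
#'   resolved (defaults to the manifest's own directory when a path is
#'   given, else the working directory).
#' @return List of [spectrum()] objects.
#' @export
read_experiment <- function(manifest, base_dir = NULL) {
  if (is.character(manifest) && length(manifest) == 1L) {
    if (is.null(base_dir)) base_dir <- dirname(manifest)
    manifest <- read_manifest(manifest)
  } else {
    validate_manifest(manifest)
    if (is.null(base_dir)) base_dir <- "."
  }
  lapply(seq_len(nrow(manifest)), function(i) {
    p <- manifest$path[i]
    if (!file.exists(p)) p <- file.path(base_dir, manifest$path[i])
    read_peaklist(p, manifest$cell_id[i], manifest$condition[i])
  })
}

#' Write an annotation table as TSV
#'
#' @param ann Annotation tibble from [annotate_matrix()].
#' @param path Output path.
#' @export
write_annotations <- function(ann, path) {
  utils::write.table(ann, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
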