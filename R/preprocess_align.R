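# Spectral preprocessing chain: intensity-threshold filtering with
# excluded-fraction accounting, TIC normalization, isotope-envelope
# collapsing, and cross-cell m/z alignment into a feature matrix.
# Stage order is fixed: filter -> normalize -> deisotope -> align.

#' Alignment and deisotoping parameters
#'
#' Defaults follow standard direct-infusion MS practice for Orbitrap data:
#' analysis range 100-1500 m/z, at most 5 isotopic replicas per envelope,
#' 0.05 Da maximum deviation between observed and expected isotope
#' positions, and 0.01 Da maximum gap when aligning peaks across cells.
#' Isotope spacing is the 13C-12C mass difference at charge 1.
#'
#' @param mz_min,mz_max Analysis range in Da.
#' @param max_isotope_replicas Maximum peaks per isotope envelope (>= 1).
#' @param isotope_delta Tolerance (Da) for joining a peak to an envelope.
#' @param align_delta Maximum gap (Da) within one aligned feature.
#' @param isotope_spacing Da between successive isotope replicas.
#' @return A list of class `alignment_params`.
#' @export
alignment_params <- function(mz_min = 100, mz_max = 1500,
                             max_isotope_replicas = 5L,
                             isotope_delta = 0.05, align_delta = 0.01,
                             isotope_spacing = 1.00336) {
  stopifnot(
    mz_min < mz_max,
    max_isotope_replicas >= 1L,
    isotope_delta > 0, align_delta > 0, isotope_spacing > 0
  )
  structure(
    list(
      mz_min = mz_min, mz_max = mz_max,
      max_isotope_replicas = as.integer(max_isotope_replicas),
      isotope_delta = isotope_delta, align_delta = align_delta,
      isotope_spacing = isotope_spacing
    ),
    class = "alignment_params"
  )
}

#' Remove low-intensity background peaks
#'
#' Keeps peaks with intensity strictly greater than `threshold` and reports
#' what was excluded, both as a fraction of peaks and as a fraction of total
#' signal intensity retained. An empty input (or one emptied entirely) is a
#' valid result; downstream stages decide how to treat it.
#'
#' @param s A [spectrum()].
#' @param threshold Intensity threshold; default 1000 ion counts, the usual
#'   export cutoff for background suppression.
#' @return List with elements `spectrum` (filtered) and `report` (fields
#'   `n_peaks_in`, `n_peaks_kept`, `fraction_peaks_removed`,
#'   `fraction_intensity_retained`).
#' @export
filter_low_intensity <- function(s, threshold = 1000) {
  stopifnot(inherits(s, "spectrum"), threshold >= 0)
  keep <- s$intensity > threshold
  n_in <- length(s$intensity)
  n_kept <- sum(keep)
  total <- sum(s$intensity)
  report <- list(
    n_peaks_in = n_in,
    n_peaks_kept = n_kept,
    fraction_peaks_removed = if (n_in > 0L) 1 - n_kept / n_in else 0,
    fraction_intensity_retained = if (total > 0) {
      sum(s$intensity[keep]) / total
    } else {
      1.0
    }
  )
  out <- spectrum(s$cell_id, s$condition, s$mz[keep], s$intensity[keep])
  list(spectrum = out, report = report)
}

#' Normalize a spectrum to its total ion current
#'
#' Divides every intensity by the spectrum's total so intensities sum to 1,
#' making abundances comparable across cells despite shot-to-shot variation
#' in absolute ion signal.
#'
#' @param s A [spectrum()] with positive total intensity.
#' @return A [spectrum()] with relative intensities.
#' @export
tic_normalize <- function(s) {
  stopifnot(inherits(s, "spectrum"))
  total <- sum(s$intensity)
  if (total <= 0) {
    stop(
      "cannot TIC-normalize cell '", s$cell_id,
      "': total ion current is zero"
    )
  }
  spectrum(s$cell_id, s$condition, s$mz, s$intensity / total)
}

#' Collapse isotope envelopes to monoisotopic features
#'
#' Scans peaks in ascending m/z. A peak is joined to an open envelope when
#' it lies within `isotope_delta` of that envelope's next expected replica
#' position (monoisotopic m/z plus k times `isotope_spacing`, with the
#' envelope holding fewer than `max_isotope_replicas` peaks). When several
#' envelopes qualify, the smallest |observed - expected| wins; exact ties go
#' to the lower monoisotopic m/z. Each envelope becomes a single peak at its
#' monoisotopic m/z carrying the summed intensity, so total signal is
#' conserved. Re-running on its own output changes nothing.
#'
#' @param s A [spectrum()] (peaks are sorted by construction).
#' @param p An [alignment_params()].
#' @return A deisotoped [spectrum()].
#' @export
collapse_isotopes <- function(s, p = alignment_params()) {
  stopifnot(inherits(s, "spectrum"), inherits(p, "alignment_params"))
  n <- length(s$mz)
  if (n == 0L) {
    return(s)
  }
  # open envelopes tracked as parallel vectors: monoisotopic m/z,
  # number of peaks so far, accumulated intensity
  env_m0 <- numeric(0)
  env_k <- integer(0)
  env_int <- numeric(0)
  open <- logical(0)
  for (i in seq_len(n)) {
    m <- s$mz[i]
    # close envelopes that can never accept this or any later peak
    if (length(env_m0) > 0L) {
      expected <- env_m0 + env_k * p$isotope_spacing
      open <- open & (env_k < p$max_isotope_replicas) &
        (expected >= m - p$isotope_delta)
    }
    joined <- FALSE
    if (any(open)) {
      cand <- which(open)
      expected <- env_m0[cand] + env_k[cand] * p$isotope_spacing
      d <- abs(m - expected)
      ok <- d <= p$isotope_delta
      if (any(ok)) {
        cand <- cand[ok]
        d <- d[ok]
        expected <- expected[ok]
        # nearest-assignment: prefer the envelope closest to this peak,
        # but yield a slot when a later peak lies strictly closer to its
        # expected position (that peak is the envelope's true replica)
        for (ci in order(d, env_m0[cand])) {
          e <- cand[ci]
          exp_e <- expected[ci]
          defer <- FALSE
          if (i < n) {
            lo <- findInterval(exp_e - p$isotope_delta, s$mz) + 1L
            hi <- findInterval(exp_e + p$isotope_delta, s$mz)
            later <- seq.int(max(lo, i + 1L), hi)
            if (max(lo, i + 1L) <= hi &&
              min(abs(s$mz[later] - exp_e)) < d[ci]) {
              defer <- TRUE
            }
          }
          if (!defer) {
            env_k[e] <- env_k[e] + 1L
            env_int[e] <- env_int[e] + s$intensity[i]
            joined <- TRUE
            break
          }
        }
      }
    }
    if (!joined) {
      env_m0 <- c(env_m0, m)
      env_k <- c(env_k, 1L)
      env_int <- c(env_int, s$intensity[i])
      open <- c(open, TRUE)
    }
  }
  spectrum(s$cell_id, s$condition, env_m0, env_int)
}

#' Align peaks across cells into a feature matrix
#'
#' Drops peaks outside `[mz_min, mz_max]`, pools the remaining peaks of all
#' cells, sorts by m/z, and cuts greedily into clusters wherever the gap
#' between consecutive pooled peaks exceeds `align_delta`. Each cluster
#' becomes one feature whose consensus m/z is the intensity-weighted mean;
#' a cell's value is the sum of its peaks in the cluster (0 when absent).
#' A cell contributing more than one peak to a cluster is allowed but
#' counted in the `n_multi_peak` attribute.
#'
#' @param spectra List of at least two preprocessed [spectrum()] objects
#'   with unique cell ids and a common pair of condition labels.
#' @param p An [alignment_params()].
#' @return A [feature_matrix()]; attribute `n_multi_peak` counts
#'   (cell, cluster) pairs with more than one contributing peak.
#' @export
align_features <- function(spectra, p = alignment_params()) {
  stopifnot(is.list(spectra), length(spectra) >= 2L)
  cell_ids <- vapply(spectra, function(s) s$cell_id, character(1L))
  conditions <- vapply(spectra, function(s) s$condition, character(1L))
  if (anyDuplicated(cell_ids)) stop("duplicate cell ids across spectra")
  mz <- unlist(lapply(spectra, function(s) s$mz), use.names = FALSE)
  intensity <- unlist(lapply(spectra, function(s) s$intensity),
    use.names = FALSE
  )
  cell <- rep(seq_along(spectra),
    vapply(spectra, function(s) length(s$mz), integer(1L))
  )
  in_range <- mz >= p$mz_min & mz <= p$mz_max
  mz <- mz[in_range]
  intensity <- intensity[in_range]
  cell <- cell[in_range]
  if (length(mz) == 0L) {
    stop("no peaks inside the analysis range [",
      p$mz_min, ", ", p$mz_max, "]")
  }
  ord <- order(mz)
  mz <- mz[ord]
  intensity <- intensity[ord]
  cell <- cell[ord]
  cluster <- cumsum(c(1L, as.integer(diff(mz) > p$align_delta)))
  k <- max(cluster)
  wsum <- vapply(split(intensity, cluster), sum, numeric(1L))
  consensus <- vapply(
    split(seq_along(mz), cluster),
    function(ii) {
      w <- intensity[ii]
      if (sum(w) > 0) sum(mz[ii] * w) / sum(w) else mean(mz[ii])
    },
    numeric(1L)
  )
  values <- matrix(0, nrow = length(spectra), ncol = k)
  idx <- cbind(cell, cluster)
  n_multi <- sum(duplicated(idx))
  for (i in seq_along(mz)) {
    values[cell[i], cluster[i]] <- values[cell[i], cluster[i]] + intensity[i]
  }
  fm <- feature_matrix(values, cell_ids, conditions, consensus)
  attr(fm, "n_multi_peak") <- n_multi
  attr(fm, "cluster_intensity") <- unname(wsum)
  fm
}

#' Run the per-cell preprocessing chain
#'
#' Applies filter -> TIC-normalize -> deisotope to each spectrum and then
#' aligns across cells. The aggregated filter report and the feature count
#' before deisotoping (aligning the normalized but uncollapsed spectra) are
#' returned alongside the matrix, since peak counts may be quoted either
#' way.
#'
#' @param spectra List of raw [spectrum()] objects.
#' @param threshold Intensity threshold for [filter_low_intensity()].
#' @param params An [alignment_params()].
#' @return List with `fm` (the [feature_matrix()]), `filter_report`
#'   (aggregated over cells), and `n_features_pre_deisotope`.
#' @export
preprocess_spectra <- function(spectra, threshold = 1000,
                               params = alignment_params()) {
  filtered <- lapply(spectra, filter_low_intensity, threshold = threshold)
  reports <- lapply(filtered, `[[`, "report")
  n_in <- sum(vapply(reports, `[[`, numeric(1L), "n_peaks_in"))
  n_kept <- sum(vapply(reports, `[[`, numeric(1L), "n_peaks_kept"))
  total_in <- sum(vapply(seq_along(spectra), function(i) {
    sum(spectra[[i]]$intensity)
  }, numeric(1L)))
  total_kept <- sum(vapply(filtered, function(f) {
    sum(f$spectrum$intensity)
  }, numeric(1L)))
  empty <- vapply(filtered, function(f) length(f$spectrum$mz) == 0L,
    logical(1L)
  )
  if (any(empty)) {
    stop(
      "all peaks removed by intensity filter for cell(s): ",
      paste(vapply(filtered[empty], function(f) f$spectrum$cell_id,
        character(1L)
      ), collapse = ", ")
    )
  }
  normalized <- lapply(filtered, function(f) tic_normalize(f$spectrum))
  n_pre <- ncol(align_features(normalized, params)$values)
  deiso <- lapply(normalized, collapse_isotopes, p = params)
  fm <- align_features(deiso, params)
  list(
    fm = fm,
    filter_report = list(
      n_peaks_in = n_in,
      n_peaks_kept = n_kept,
      fraction_peaks_removed = if (n_in > 0) 1 - n_kept / n_in else 0,
      fraction_intensity_retained = if (total_in > 0) {
        total_kept / total_in
      } else {
        1.0
      }
    ),
    n_features_pre_deisotope = n_pre
  )
}
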