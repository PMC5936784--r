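# Statistical layer: per-feature Welch tests, PLS-DA (NIPALS) with
# permutation significance and cross-validated Q2, and hierarchically
# clustered z-scored matrices for heat maps.

#' Welch two-sample t-test for one feature
#'
#' Unequal-variance t statistic with Welch-Satterthwaite degrees of freedom
#' and a two-sided p-value. Degenerate inputs follow explicit conventions:
#' zero variance in both groups with equal means gives p = 1; with unequal
#' means, p = 0 and the result is flagged degenerate.
#'
#' @param a,b Numeric vectors (>= 2 values each).
#' @return List with `t`, `df`, `p`, `degenerate`.
#' @export
t_test_feature <- function(a, b) {
  stopifnot(length(a) >= 2L, length(b) >= 2L)
  na <- length(a)
  nb <- length(b)
  va <- stats::var(a)
  vb <- stats::var(b)
  dm <- mean(a) - mean(b)
  se2 <- va / na + vb / nb
  if (se2 == 0) {
    if (dm == 0) {
      return(list(t = 0, df = NA_real_, p = 1, degenerate = TRUE))
    }
    return(list(
      t = sign(dm) * Inf, df = NA_real_, p = 0, degenerate = TRUE
    ))
  }
  tval <- dm / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  list(
    t = tval, df = df, p = 2 * stats::pt(-abs(tval), df),
    degenerate = FALSE
  )
}

.two_conditions <- function(fm) {
  lv <- sort(unique(fm$conditions), method = "radix")
  if (length(lv) != 2L) {
    stop("expected exactly two condition labels, found ", length(lv))
  }
  lv
}

#' Per-feature differential abundance between two conditions
#'
#' Welch tests each feature and flags significance at raw `alpha` (the
#' conventional per-feature screen for this kind of data); a BH-adjusted
#' column is emitted alongside for users who want FDR control. Features
#' that are constant across all cells get p = 1 and a degenerate flag.
#'
#' @param fm A [feature_matrix()] with exactly two condition labels.
#' @param alpha Raw significance threshold (default 0.05).
#' @param var_equal Use the pooled-variance (Student) test instead of Welch.
#' @return Tibble: `feature_id`, `mz`, group means (named after the two
#'   conditions), `t`, `df`, `p`, `p_adj`, `significant`, `direction`
#'   (condition with the higher mean), `degenerate`. Attribute `counts`
#'   holds `n_significant` and the per-direction split.
#' @export
differential_features <- function(fm, alpha = 0.05, var_equal = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"), alpha >= 0, alpha <= 1)
  lv <- .two_conditions(fm)
  x <- fm$values
  ia <- fm$conditions == lv[1L]
  ib <- fm$conditions == lv[2L]
  na <- sum(ia)
  nb <- sum(ib)
  if (na < 2L || nb < 2L) stop("each condition needs >= 2 cells")
  a <- x[ia, , drop = FALSE]
  b <- x[ib, , drop = FALSE]
  ma <- colMeans(a)
  mb <- colMeans(b)
  va <- colSums(sweep(a, 2L, ma)^2) / (na - 1L)
  vb <- colSums(sweep(b, 2L, mb)^2) / (nb - 1L)
  dm <- ma - mb
  if (var_equal) {
    sp2 <- ((na - 1L) * va + (nb - 1L) * vb) / (na + nb - 2L)
    se2 <- sp2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2L, length(dm))
  } else {
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  }
  degenerate <- se2 == 0
  tval <- ifelse(degenerate, ifelse(dm == 0, 0, sign(dm) * Inf),
    dm / sqrt(se2))
  p <- ifelse(degenerate, ifelse(dm == 0, 1, 0),
    2 * stats::pt(-abs(tval), df))
  significant <- p < alpha
  direction <- ifelse(dm > 0, lv[1L], ifelse(dm < 0, lv[2L], NA_character_))
  res <- tibble::tibble(
    feature_id = fm$feature_ids,
    mz = fm$consensus_mz,
    mean_1 = unname(ma), mean_2 = unname(mb),
    t = unname(tval), df = unname(ifelse(degenerate, NA_real_, df)),
    p = unname(p),
    p_adj = unname(stats::p.adjust(p, method = "BH")),
    significant = unname(significant),
    direction = unname(direction),
    degenerate = unname(degenerate)
  )
  names(res)[names(res) == "mean_1"] <- paste0("mean_", lv[1L])
  names(res)[names(res) == "mean_2"] <- paste0("mean_", lv[2L])
  counts <- list(
    n_significant = sum(significant),
    n_up = stats::setNames(
      c(
        sum(significant & direction == lv[1L], na.rm = TRUE),
        sum(significant & direction == lv[2L], na.rm = TRUE)
      ),
      lv
    )
  )
  attr(res, "counts") <- counts
  res
}

# NIPALS PLS1 on a centred X and centred y; exact single-pass extraction
# per component with deflation of both blocks.
.pls_nipals <- function(xc, yc, ncomp) {
  n <- nrow(xc)
  p <- ncol(xc)
  w_mat <- matrix(0, p, ncomp)
  p_mat <- matrix(0, p, ncomp)
  t_mat <- matrix(0, n, ncomp)
  q <- numeric(ncomp)
  xd <- xc
  yd <- yc
  for (a in seq_len(ncomp)) {
    w <- crossprod(xd, yd)
    wn <- sqrt(sum(w^2))
    if (!is.finite(wn) || wn < 1e-12) {
      stop(sprintf(
        "PLS component %d: no residual covariance left to extract", a
      ))
    }
    w <- w / wn
    tv <- xd %*% w
    tt <- sum(tv^2)
    if (tt < 1e-12) {
      stop(sprintf("PLS component %d: degenerate score vector", a))
    }
    pv <- crossprod(xd, tv) / tt
    qa <- sum(yd * tv) / tt
    xd <- xd - tcrossprod(tv, pv)
    yd <- yd - qa * tv
    w_mat[, a] <- w
    p_mat[, a] <- pv
    t_mat[, a] <- tv
    q[a] <- qa
  }
  list(weights = w_mat, loadings = p_mat, scores = t_mat, q = q)
}

# between/within sum-of-squares ratio on (at most) the first two score
# dimensions — the separation statistic permuted for significance
.separation_statistic <- function(scores, groups) {
  s <- scores[, seq_len(min(2L, ncol(scores))), drop = FALSE]
  mu <- colMeans(s)
  bss <- 0
  wss <- 0
  for (g in unique(groups)) {
    sg <- s[groups == g, , drop = FALSE]
    mg <- colMeans(sg)
    bss <- bss + nrow(sg) * sum((mg - mu)^2)
    wss <- wss + sum(sweep(sg, 2L, mg)^2)
  }
  if (wss == 0) Inf else bss / wss
}

#' Fit a two-group PLS-DA model
#'
#' NIPALS partial least squares of column-mean-centred intensities against
#' a +1/-1 coded group response (no unit-variance scaling by default:
#' TIC-normalised relative intensities are already on a common scale).
#' Scores have zero column means; loadings follow the deflation scheme.
#'
#' @param fm A [feature_matrix()] with exactly two condition labels.
#' @param n_components Number of latent components (default 2); must not
#'   exceed `min(n_cells - 1, n_features)`.
#' @param autoscale Also scale each feature to unit variance before
#'   fitting (constant features are dropped with a warning).
#' @return List of class `plsda` with `scores` (cells x components),
#'   `loadings`, `weights`, `q` (y loadings), `explained_x` and
#'   `explained_y` (fraction of block variance per component),
#'   `separation` (between/within SS ratio of the first two score
#'   dimensions), `conditions`, `y` (the +1/-1 coding), `center`,
#'   `y_mean`, `feature_ids`.
#' @export
plsda_fit <- function(fm, n_components = 2L, autoscale = FALSE) {
  stopifnot(inherits(fm, "feature_matrix"))
  lv <- .two_conditions(fm)
  x <- fm$values
  n <- nrow(x)
  if (n_components > min(n - 1L, ncol(x))) {
    stop(
      "n_components must be <= min(n_cells - 1, n_features) = ",
      min(n - 1L, ncol(x))
    )
  }
  feature_ids <- fm$feature_ids
  scale_sd <- NULL
  if (autoscale) {
    sds <- apply(x, 2L, stats::sd)
    if (any(sds == 0)) {
      warning(sum(sds == 0), " constant feature(s) dropped before scaling")
      x <- x[, sds > 0, drop = FALSE]
      feature_ids <- feature_ids[sds > 0]
      sds <- sds[sds > 0]
    }
    x <- sweep(x, 2L, sds, "/")
    scale_sd <- sds
  }
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  if (sum(xc^2) < 1e-12) {
    stop("feature matrix has no variance across cells")
  }
  y <- ifelse(fm$conditions == lv[1L], 1, -1)
  y_mean <- mean(y)
  yc <- y - y_mean
  fit <- .pls_nipals(xc, yc, n_components)
  ssx <- sum(xc^2)
  ssy <- sum(yc^2)
  explained_x <- vapply(seq_len(n_components), function(a) {
    sum(fit$scores[, a]^2) * sum(fit$loadings[, a]^2) / ssx
  }, numeric(1L))
  explained_y <- vapply(seq_len(n_components), function(a) {
    fit$q[a]^2 * sum(fit$scores[, a]^2) / ssy
  }, numeric(1L))
  structure(
    list(
      scores = fit$scores,
      loadings = fit$loadings,
      weights = fit$weights,
      q = fit$q,
      explained_x = explained_x,
      explained_y = explained_y,
      separation = .separation_statistic(fit$scores, fm$conditions),
      conditions = fm$conditions,
      condition_levels = lv,
      y = y,
      center = center,
      y_mean = y_mean,
      scale_sd = scale_sd,
      feature_ids = feature_ids
    ),
    class = "plsda"
  )
}

#' @export
print.plsda <- function(x, ...) {
  cat(sprintf(
    "<plsda> %d cells, %d components; explained y: %s; separation %.3g\n",
    nrow(x$scores), ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * x$explained_y), collapse = " + "),
    x$separation
  ))
  invisible(x)
}

#' Permutation significance of PLS-DA group separation
#'
#' The observed separation statistic (between/within sum-of-squares ratio
#' of the first two score dimensions) is compared against refits under
#' randomly permuted group labels; `p = (1 + #\{perm >= observed\}) /
#' (1 + n_permutations)`, so the smallest attainable p with 1999
#' permutations is 5e-4 and with 999 permutations 1e-3.
#'
#' @param fm A [feature_matrix()].
#' @param n_components Components per refit (default 2).
#' @param n_permutations Number of label permutations (>= 19; default
#'   1999).
#' @param seed Integer seed controlling the permutations.
#' @return List: `p`, `observed`, `n_permutations`, `permuted` (vector of
#'   permuted statistics).
#' @export
plsda_permutation_test <- function(fm, n_components = 2L,
                                   n_permutations = 1999L, seed = 1L) {
  stopifnot(n_permutations >= 19L)
  lv <- .two_conditions(fm)
  fit <- plsda_fit(fm, n_components)
  observed <- fit$separation
  x <- fm$values
  center <- colMeans(x)
  xc <- sweep(x, 2L, center)
  perm_stats <- withr::with_seed(seed, {
    vapply(seq_len(n_permutations), function(i) {
      yp <- sample(fit$y)
      pf <- tryCatch(
        .pls_nipals(xc, yp - mean(yp), n_components),
        error = function(e) NULL
      )
      if (is.null(pf)) {
        return(NA_real_)
      }
      groups <- ifelse(yp > 0, lv[1L], lv[2L])
      .separation_statistic(pf$scores, groups)
    }, numeric(1L))
  })
  if (all(is.na(perm_stats))) {
    warning("no valid permutation refits; p set to 1")
    return(list(
      p = 1, observed = observed, n_permutations = n_permutations,
      permuted = perm_stats
    ))
  }
  p <- (1 + sum(perm_stats >= observed, na.rm = TRUE)) /
    (1 + n_permutations)
  list(
    p = p, observed = observed, n_permutations = n_permutations,
    permuted = perm_stats
  )
}

#' Cross-validated predictive ability (Q2) of PLS-DA
#'
#' Stratified k-fold cross-validation of the +1/-1 coded response:
#' `Q2 = 1 - PRESS / TSS` over held-out cells, with each fold's TSS taken
#' about its training-set response mean. Q2 above ~0.5 conventionally
#' indicates good predictability; label-shuffled data gives Q2 <= 0 in
#' expectation.
#'
#' @param fm A [feature_matrix()].
#' @param n_components Components (default 2); must be < n training cells.
#' @param folds Number of folds (default 10, capped at the group size).
#' @param seed Integer seed controlling fold assignment.
#' @return Q2 as a single number.
#' @export
plsda_q2 <- function(fm, n_components = 2L, folds = 10L, seed = 1L) {
  stopifnot(folds >= 2L)
  lv <- .two_conditions(fm)
  x <- fm$values
  n <- nrow(x)
  if (n_components > n - 1L) {
    stop("n_components must be <= n_cells - 1")
  }
  y <- ifelse(fm$conditions == lv[1L], 1, -1)
  fold_of <- integer(n)
  withr::with_seed(seed, {
    for (g in lv) {
      ii <- which(fm$conditions == g)
      fold_of[ii] <- sample(rep_len(seq_len(folds), length(ii)))
    }
  })
  press <- 0
  tss <- 0
  for (k in sort(unique(fold_of))) {
    test <- fold_of == k
    if (!any(test)) next
    ytr <- y[!test]
    if (length(unique(ytr)) < 2L) {
      warning("fold ", k, " left a single class in training; refolded out")
      next
    }
    xtr <- x[!test, , drop = FALSE]
    center <- colMeans(xtr)
    ncomp <- min(n_components, nrow(xtr) - 1L)
    fit <- .pls_nipals(
      sweep(xtr, 2L, center), ytr - mean(ytr), ncomp
    )
    # PLS1 regression coefficients in the original (centred) space
    bmat <- fit$weights %*%
      solve(crossprod(fit$loadings, fit$weights), fit$q)
    pred <- sweep(x[test, , drop = FALSE], 2L, center) %*% bmat + mean(ytr)
    press <- press + sum((y[test] - pred)^2)
    tss <- tss + sum((y[test] - mean(ytr))^2)
  }
  if (tss == 0) stop("cross-validation produced no held-out variance")
  1 - press / tss
}

#' Z-scored, hierarchically clustered matrix for heat maps
#'
#' Restricts the matrix to the selected features, z-scores each feature
#' across all cells (so colour encodes deviation from the mean signal over
#' every tested cell), and clusters both features and cells
#' agglomeratively. Constant features become all-zero rows and are placed
#' last, outside the clustering.
#'
#' @param fm A [feature_matrix()].
#' @param features Character vector of feature ids (non-empty subset).
#' @param distance Distance measure for [stats::dist()].
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   Ward).
#' @return List of class `heatmap_data`: `z` (features x cells, in
#'   clustered order), `row_order`, `col_order` (within the selected
#'   subset), `row_hclust`, `col_hclust` (NULL when fewer than 2 usable
#'   rows/columns), `conditions` (per ordered cell).
#' @export
heatmap_data <- function(fm, features, distance = "euclidean",
                         linkage = "ward.D2") {
  stopifnot(inherits(fm, "feature_matrix"), length(features) > 0L)
  idx <- match(features, fm$feature_ids)
  if (anyNA(idx)) {
    stop(
      "unknown feature id(s): ",
      paste(features[is.na(idx)], collapse = ", ")
    )
  }
  m <- t(fm$values[, idx, drop = FALSE]) # features x cells
  rownames(m) <- fm$feature_ids[idx]
  colnames(m) <- fm$cell_ids
  mu <- rowMeans(m)
  sdv <- apply(m, 1L, stats::sd)
  z <- (m - mu) / ifelse(sdv == 0, 1, sdv)
  z[sdv == 0, ] <- 0
  usable <- which(sdv > 0)
  constant <- which(sdv == 0)
  # leaf order within a dendrogram is canonicalised by label rank so the
  # result does not depend on input row/column order
  canonical_order <- function(hc, labels) {
    wts <- match(labels, sort(labels, method = "radix"))
    d <- stats::reorder(stats::as.dendrogram(hc), wts, agglo.FUN = mean)
    stats::order.dendrogram(d)
  }
  row_hclust <- NULL
  if (length(usable) >= 2L) {
    row_hclust <- stats::hclust(
      stats::dist(z[usable, , drop = FALSE], method = distance),
      method = linkage
    )
    row_order <- c(
      usable[canonical_order(row_hclust, rownames(z)[usable])], constant
    )
  } else {
    row_order <- c(usable, constant)
  }
  col_hclust <- NULL
  if (ncol(z) >= 2L) {
    col_hclust <- stats::hclust(
      stats::dist(t(z), method = distance),
      method = linkage
    )
    col_order <- canonical_order(col_hclust, colnames(z))
  } else {
    col_order <- seq_len(ncol(z))
  }
  structure(
    list(
      z = z[row_order, col_order, drop = FALSE],
      row_order = row_order,
      col_order = col_order,
      row_hclust = row_hclust,
      col_hclust = col_hclust,
      conditions = fm$conditions[col_order]
    ),
    class = "heatmap_data"
  )
}
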