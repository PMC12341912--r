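# Representational similarity analysis: multivariate noise normalization,
# pseudotrials, cross-validated squared Euclidean distance time courses,
# windowed dissimilarity matrices, and classical MDS.
#
# Distance convention: SQUARED cross-validated Euclidean distance (the
# cross-validated inner-product estimator has no unbiased square root). It
# has zero expectation when two conditions are identical and may be negative
# in samples.

condition_key <- function(labels) paste(labels$task, labels$category)

#' Multivariate noise normalization (whitening)
#'
#' Estimates the within-condition error covariance per timepoint with
#' analytic shrinkage toward a scaled identity, averages it over timepoints
#' (default scope) or whitens each timepoint with its own estimate, and
#' applies the inverse matrix square root to every trial so that all channels
#' contribute on a common noise scale.
#'
#' @param epochs an [eeg_epochs] object.
#' @param shrinkage "auto" or a value in \[0, 1\].
#' @param scope "time_average" (one whitening matrix from the time-averaged
#'   covariance) or "per_timepoint".
#' @return the whitened `eeg_epochs`, with the whitening matrix (or array)
#'   in attribute `whitening`.
#' @export
noise_normalize <- function(epochs, shrinkage = "auto",
                            scope = c("time_average", "per_timepoint")) {
  scope <- match.arg(scope)
  d <- dim(epochs$data)
  if (d[1] < d[2] + 1) {
    warnf("noise_normalize: only %d trials for %d channels; covariance estimate may be unstable", d[1], d[2])
  }
  resid <- center_within_condition(epochs$data, condition_key(epochs$labels))
  if (scope == "time_average") {
    flat <- aperm(resid, c(1, 3, 2))
    dim(flat) <- c(d[1] * d[3], d[2])
    W <- inv_sqrtm(shrink_cov(flat, shrinkage)$sigma)
    for (ti in seq_len(d[3])) {
      epochs$data[, , ti] <- epochs$data[, , ti] %*% W
    }
    attr(epochs, "whitening") <- W
  } else {
    Ws <- array(NA_real_, c(d[2], d[2], d[3]))
    for (ti in seq_len(d[3])) {
      W <- inv_sqrtm(shrink_cov(resid[, , ti], shrinkage)$sigma)
      epochs$data[, , ti] <- epochs$data[, , ti] %*% W
      Ws[, , ti] <- W
    }
    attr(epochs, "whitening") <- Ws
  }
  epochs
}

# Residuals after removing each condition's per-timepoint mean.
center_within_condition <- function(dat, key) {
  out <- dat
  for (k in unique(key)) {
    ix <- which(key == k)
    mu <- colMeans(dat[ix, , , drop = FALSE])          # channels x time
    out[ix, , ] <- dat[ix, , , drop = FALSE] -
      rep(mu, each = length(ix))
  }
  out
}

#' Average trials into pseudotrials
#'
#' Per condition (task x category), trials are randomly partitioned into
#' `n_pseudo` subsets of near-equal size (differing by at most one) and
#' averaged within each subset, boosting SNR before distance estimation.
#'
#' @param epochs an [eeg_epochs] object.
#' @param n_pseudo number of pseudotrials per condition (default 5).
#' @param seed integer seed.
#' @return an `eeg_epochs` with `n_pseudo` trials per condition.
#' @export
make_pseudotrials <- function(epochs, n_pseudo = 5, seed = 1) {
  key <- condition_key(epochs$labels)
  groups <- split(seq_len(n_trials(epochs)), key)
  small <- lengths(groups) < n_pseudo
  if (any(small)) {
    stopf("make_pseudotrials: condition(s) with fewer than %d trials: %s",
          n_pseudo, paste(names(groups)[small], collapse = ", "))
  }
  d <- dim(epochs$data)
  out_dat <- array(NA_real_, c(length(groups) * n_pseudo, d[2], d[3]))
  out_lab <- epochs$labels[0, , drop = FALSE]
  row <- 0L
  for (g in names(groups)) {
    parts <- with_seed(derive_seed(seed, "pseudo", g), {
      ix <- sample(groups[[g]])
      split(ix, rep_len(seq_len(n_pseudo), length(ix)))
    })
    for (p in parts) {
      row <- row + 1L
      out_dat[row, , ] <- if (length(p) == 1) epochs$data[p, , ] else colMeans(epochs$data[p, , , drop = FALSE])
      out_lab <- rbind(out_lab, epochs$labels[p[1], , drop = FALSE])
    }
  }
  rownames(out_lab) <- NULL
  eeg_epochs(out_dat, epochs$times, epochs$srate, epochs$channels, out_lab, epochs$veog_pair)
}

# Fold loop of the cross-validated squared Euclidean distance for two
# n_pseudo x channels x time pseudotrial arrays: fold k pairs pseudotrial k
# of each condition as the test set, the others form the training means.
cv_dist_folds <- function(pa, pb) {
  k <- dim(pa)[1]
  if (dim(pb)[1] != k) stopf("cv_dist_folds: pseudotrial counts differ (%d vs %d)", k, dim(pb)[1])
  sa <- colSums(pa); sb <- colSums(pb)          # channels x time sums
  d <- 0
  for (f in seq_len(k)) {
    ta <- pa[f, , , drop = TRUE]; tb <- pb[f, , , drop = TRUE]
    tra <- (sa - ta) / (k - 1)
    trb <- (sb - tb) / (k - 1)
    d <- d + colSums((tra - trb) * (ta - tb))
  }
  d / k
}

#' Cross-validated squared Euclidean distance time course
#'
#' Per iteration: the two categories are equalized to the smaller trial
#' count, a whitening matrix is estimated from the training folds (or all
#' trials, or skipped), trials are partitioned into pseudotrials, and each
#' fold's distance is the inner product between the training-mean difference
#' and the held-out pseudotrial difference at every timepoint. Fold-mean
#' distances are averaged over `n_iterations` fresh partitions.
#'
#' @param epochs an [eeg_epochs] object.
#' @param pair length-2 character vector of categories.
#' @param task task to restrict to.
#' @param n_pseudo pseudotrials per condition (default 5; folds = n_pseudo).
#' @param n_iterations number of re-partitions averaged (default 20).
#' @param seed integer seed.
#' @param whiten "train" (noise covariance from training-fold trials within
#'   each iteration, time-averaged before inversion), "all" (single whitening
#'   from every trial), or "none".
#' @param shrinkage shrinkage intensity for the noise covariance.
#' @param correct_only restrict to correct trials.
#' @return object of class `rdm_series`: `times`, `distance` (per timepoint,
#'   averaged over folds and iterations), `by_iteration`, `metadata`.
#' @export
cv_distance_timecourse <- function(epochs, pair, task, n_pseudo = 5,
                                   n_iterations = 20, seed = 1,
                                   whiten = c("train", "all", "none"),
                                   shrinkage = "auto", correct_only = FALSE) {
  whiten <- match.arg(whiten)
  sub <- subset_pair(epochs, pair, task, correct_only)
  eq <- subsample_equal(sub, "category", derive_seed(seed, "equalize"))
  y <- eq$labels$category
  ia <- which(y == pair[1]); ib <- which(y == pair[2])
  if (length(ia) < n_pseudo) stopf("cv_distance_timecourse: need >= %d trials per condition", n_pseudo)
  d <- dim(eq$data)
  dat <- eq$data
  if (whiten == "all") {
    dat <- noise_normalize(eq, shrinkage)$data
  }
  dist_it <- matrix(NA_real_, d[3], n_iterations)
  stats <- if (whiten == "train") whitening_suffstats(dat, ia, ib, shrinkage) else NULL
  for (it in seq_len(n_iterations)) {
    parts_a <- with_seed(derive_seed(seed, "iter", it, "a"),
                         split(sample(ia), rep_len(seq_len(n_pseudo), length(ia))))
    parts_b <- with_seed(derive_seed(seed, "iter", it, "b"),
                         split(sample(ib), rep_len(seq_len(n_pseudo), length(ib))))
    if (whiten == "train") {
      dist_it[, it] <- cv_dist_whitened(dat, parts_a, parts_b, stats)
    } else {
      pa <- pseudo_array(dat, parts_a)
      pb <- pseudo_array(dat, parts_b)
      dist_it[, it] <- cv_dist_folds(pa, pb)
    }
  }
  structure(list(times = eq$times, distance = rowMeans(dist_it),
                 by_iteration = dist_it,
                 metadata = list(pair = pair, task = task, n_pseudo = n_pseudo,
                                 n_iterations = n_iterations, seed = seed,
                                 whiten = whiten, shrinkage = shrinkage)),
            class = "rdm_series")
}

# channels x time mean over the training pseudotrial partitions (mean of the
# per-subset means, matching the fold-mean of pseudotrials).
pseudo_means <- function(dat, parts) {
  acc <- 0
  for (p in parts) acc <- acc + pseudo_mean1(dat, p)
  acc / length(parts)
}

pseudo_mean1 <- function(dat, ix) {
  if (length(ix) == 1) dat[ix, , , drop = TRUE] else colMeans(dat[ix, , , drop = FALSE])
}

pseudo_array <- function(dat, parts) {
  out <- array(NA_real_, c(length(parts), dim(dat)[2], dim(dat)[3]))
  for (i in seq_along(parts)) out[i, , ] <- pseudo_mean1(dat, parts[[i]])
  out
}

# whiten a channels x time matrix, preserving orientation
apply_w <- function(cht, W) W %*% cht

# Sufficient statistics for training-fold noise whitening: per-trial
# time-summed outer products and condition sums, plus a shrinkage intensity
# estimated once from all-trial residuals (the covariance itself is always
# re-estimated from the training folds of each iteration).
whitening_suffstats <- function(dat, ia, ib, shrinkage) {
  d <- dim(dat)
  A <- matrix(NA_real_, d[1], d[2] * d[2])
  for (i in c(ia, ib)) A[i, ] <- tcrossprod(dat[i, , , drop = TRUE])
  if (identical(shrinkage, "auto")) {
    key <- rep("b", d[1]); key[ia] <- "a"
    resid <- center_within_condition(dat, key)
    flat <- aperm(resid, c(1, 3, 2))
    dim(flat) <- c(d[1] * d[3], d[2])
    lambda <- shrink_cov(flat, "auto")$lambda
  } else lambda <- as.numeric(shrinkage)
  list(A = A, lambda = lambda, ch = d[2], nt = d[3])
}

cv_dist_whitened <- function(dat, parts_a, parts_b, stats) {
  ch <- stats$ch; nt <- stats$nt
  k <- length(parts_a)
  msub_a <- lapply(parts_a, function(p) pseudo_mean1(dat, p))
  msub_b <- lapply(parts_b, function(p) pseudo_mean1(dat, p))
  sum_msub_a <- Reduce(`+`, msub_a)
  sum_msub_b <- Reduce(`+`, msub_b)
  sx_a <- lapply(parts_a, function(p) pseudo_mean1(dat, p) * length(p))
  sx_b <- lapply(parts_b, function(p) pseudo_mean1(dat, p) * length(p))
  sumx_a <- Reduce(`+`, sx_a); sumx_b <- Reduce(`+`, sx_b)
  SA_a <- lapply(parts_a, function(p) colSums(stats$A[p, , drop = FALSE]))
  SA_b <- lapply(parts_b, function(p) colSums(stats$A[p, , drop = FALSE]))
  S_a <- Reduce(`+`, SA_a); S_b <- Reduce(`+`, SA_b)
  na <- sum(lengths(parts_a)); nb <- sum(lengths(parts_b))
  dsum <- numeric(nt)
  for (f in seq_len(k)) {
    ma <- na - length(parts_a[[f]]); mb <- nb - length(parts_b[[f]])
    TXa <- sumx_a - sx_a[[f]]; TXb <- sumx_b - sx_b[[f]]
    Sa <- matrix(S_a - SA_a[[f]], ch, ch) - tcrossprod(TXa) / ma
    Sb <- matrix(S_b - SA_b[[f]], ch, ch) - tcrossprod(TXb) / mb
    C <- (Sa + Sb) / ((ma + mb) * nt)
    mu <- mean(diag(C))
    sigma <- (1 - stats$lambda) * C
    diag(sigma) <- diag(sigma) + stats$lambda * mu
    W <- inv_sqrtm(sigma)
    tra <- W %*% ((sum_msub_a - msub_a[[f]]) / (k - 1) - (sum_msub_b - msub_b[[f]]) / (k - 1))
    tst <- W %*% (msub_a[[f]] - msub_b[[f]])
    dsum <- dsum + colSums(tra * tst)
  }
  dsum / k
}

#' Plain (non-cross-validated) squared Euclidean distance time course
#'
#' The squared channel-space distance between the two condition means per
#' timepoint. Positively biased under noise -- provided as the comparison
#' that shows the bias the cross-validated estimator removes.
#' @inheritParams cv_distance_timecourse
#' @return numeric vector of squared distances per timepoint.
#' @export
plain_distance_timecourse <- function(epochs, pair, task) {
  sub <- subset_pair(epochs, pair, task)
  ma <- condition_erp(sub, list(category = pair[1]))
  mb <- condition_erp(sub, list(category = pair[2]))
  colSums((ma - mb)^2)
}

#' @export
print.rdm_series <- function(x, ...) {
  cat(sprintf("<rdm_series> %s vs %s, task %s: %d timepoints x %d iterations\n",
              x$metadata$pair[1], x$metadata$pair[2], x$metadata$task,
              length(x$times), x$metadata$n_iterations))
  cat(sprintf("  peak distance %.3f at %.0f ms (squared cross-validated Euclidean)\n",
              max(x$distance), x$times[which.max(x$distance)]))
  invisible(x)
}

#' Windowed dissimilarity matrix
#'
#' Averages each pair's distance over a window (default 30 ms: 15 ms on
#' either side of the center) and assembles the symmetric, zero-diagonal
#' dissimilarity matrix over the three categories. Negative averages are
#' retained (the cross-validated estimator is signed).
#'
#' @param series named list of `rdm_series`, names like
#'   "bird|nonbird_animal" (pair categories separated by "|").
#' @param center_ms window center (ms).
#' @param half_width_ms half-width (ms, default 15).
#' @return object of class `dissimilarity_matrix`: `matrix`, `center_ms`,
#'   `half_width_ms`.
#' @export
rdm_at_window <- function(series, center_ms, half_width_ms = 15) {
  cats <- unique(unlist(strsplit(names(series), "|", fixed = TRUE)))
  m <- matrix(0, length(cats), length(cats), dimnames = list(cats, cats))
  for (nm in names(series)) {
    s <- series[[nm]]
    pr <- strsplit(nm, "|", fixed = TRUE)[[1]]
    sel <- abs(s$times - center_ms) <= half_width_ms + 1e-9
    if (!any(sel)) {
      stopf("rdm_at_window: window %g +/- %g ms contains no timepoints", center_ms, half_width_ms)
    }
    v <- mean(s$distance[sel])
    m[pr[1], pr[2]] <- v
    m[pr[2], pr[1]] <- v
  }
  structure(list(matrix = m, center_ms = center_ms, half_width_ms = half_width_ms),
            class = "dissimilarity_matrix")
}

#' Classical multidimensional scaling of a (squared) dissimilarity matrix
#'
#' Double-centers the squared-dissimilarity matrix into a Gram matrix and
#' eigendecomposes it; coordinates come from the top-k nonnegative
#' eigenvalues. All eigenvalues are returned so callers can detect
#' dimensionality loss or non-embeddable (negative-spectrum) input. The
#' configuration is determined up to rotation and reflection.
#'
#' @param dissim a `dissimilarity_matrix` (entries are squared distances) or
#'   a plain symmetric matrix of squared distances with zero diagonal.
#' @param k embedding dimension (default 2).
#' @return list: `points` (conditions x k), `eig` (all eigenvalues,
#'   decreasing).
#' @export
classical_mds <- function(dissim, k = 2) {
  D2 <- if (inherits(dissim, "dissimilarity_matrix")) dissim$matrix else as.matrix(dissim)
  if (!isSymmetric(unname(D2), tol = 1e-8)) stopf("classical_mds: matrix must be symmetric")
  if (any(abs(diag(D2)) > 1e-12)) stopf("classical_mds: diagonal must be zero")
  n <- nrow(D2)
  J <- diag(n) - 1 / n
  B <- -0.5 * J %*% D2 %*% J
  e <- eigen((B + t(B)) / 2, symmetric = TRUE)
  if (all(e$values <= 1e-12 * max(abs(e$values), 1))) {
    stopf("classical_mds: no positive eigenvalues; matrix is not embeddable")
  }
  kk <- min(k, sum(e$values > 0))
  pts <- e$vectors[, seq_len(kk), drop = FALSE] %*% diag(sqrt(e$values[seq_len(kk)]), kk)
  if (kk < k) pts <- cbind(pts, matrix(0, n, k - kk))
  rownames(pts) <- rownames(D2)
  list(points = pts, eig = e$values)
}

#' Procrustes-align an MDS solution to a reference configuration
#'
#' Orthogonal (rotation/reflection) alignment for plotting sequences of MDS
#' solutions over timepoints; presentation only, distances are unchanged.
#' @param points,reference conditions x k coordinate matrices.
#' @return aligned coordinate matrix.
#' @export
procrustes_align <- function(points, reference) {
  s <- svd(crossprod(reference, points))
  points %*% s$v %*% t(s$u)
}
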