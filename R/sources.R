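# Template-based functional source statistics: Haufe activation-pattern
# transform of classifier weights, simultaneous least-squares projection onto
# per-area EEG templates, sign-flip bootstrap nulls, Gaussian z / two-sided
# normal p values, and the consecutive-milliseconds significance rule.

#' Transform classifier weights into activation patterns
#'
#' A linear classifier's weights are not interpretable topographies; the
#' forward-model pattern is `Sigma_x w / var(w . x)` with `Sigma_x` the data
#' covariance at each timepoint. On two-class data the pattern equals (up to
#' scale) the ERP difference between the conditions.
#'
#' @param models list of `lda_model` objects, one per timepoint.
#' @param epochs an [eeg_epochs] holding the trials the models were trained
#'   on (or compatible data); its covariance per timepoint defines the
#'   transform.
#' @return object of class `activation_pattern`: `pattern` (channels x
#'   time), `times`, `channels`.
#' @export
weights_to_pattern <- function(models, epochs) {
  d <- dim(epochs$data)
  if (length(models) != d[3]) {
    stopf("weights_to_pattern: %d models but %d timepoints", length(models), d[3])
  }
  pat <- matrix(NA_real_, d[2], d[3])
  for (ti in seq_len(d[3])) {
    w <- models[[ti]]$w
    if (length(w) != d[2]) stopf("weights_to_pattern: weight length %d != %d channels", length(w), d[2])
    X <- epochs$data[, , ti, drop = TRUE]
    Xc <- sweep(X, 2, colMeans(X))
    Sx <- crossprod(Xc) / (d[1] - 1)
    s2 <- drop(crossprod(w, Sx %*% w))     # var of the decision values
    pat[, ti] <- (Sx %*% w) / s2
  }
  rownames(pat) <- epochs$channels
  structure(list(pattern = pat, times = epochs$times, channels = epochs$channels),
            class = "activation_pattern")
}

#' Project pattern time courses onto area templates
#'
#' Per timepoint, solves the simultaneous ordinary least-squares fit of the
#' pattern topography as a linear combination of all area templates,
#' returning one contribution coefficient per area plus the residual
#' fraction of pattern variance.
#'
#' @param pattern an `activation_pattern`, or a channels x time matrix.
#' @param templates areas x channels matrix (rows should be comparable
#'   scale, e.g. unit norm; channel order must match the pattern).
#' @return list: `coefficients` (areas x time), `residual_fraction`
#'   (per timepoint), `times` if available.
#' @export
localize_templates <- function(pattern, templates) {
  pat <- if (inherits(pattern, "activation_pattern")) pattern$pattern else as.matrix(pattern)
  templates <- as.matrix(templates)
  if (ncol(templates) != nrow(pat)) {
    stopf("localize_templates: templates have %d channels but pattern has %d",
          ncol(templates), nrow(pat))
  }
  qrT <- qr(t(templates))
  if (qrT$rank < nrow(templates)) {
    keep <- qrT$pivot[seq_len(qrT$rank)]
    stopf("localize_templates: template matrix is rank deficient; collinear area(s): %s",
          paste(rownames(templates)[setdiff(seq_len(nrow(templates)), keep)], collapse = ", "))
  }
  coef <- qr.coef(qrT, pat)                      # areas x time
  fit <- t(templates) %*% coef
  ss_res <- colSums((pat - fit)^2)
  ss_tot <- colSums(pat^2)
  rownames(coef) <- rownames(templates)
  list(coefficients = coef,
       residual_fraction = ifelse(ss_tot > 0, ss_res / ss_tot, NA_real_),
       times = if (inherits(pattern, "activation_pattern")) pattern$times else NULL)
}

#' Sign-flip bootstrap null for template contributions
#'
#' Each bootstrap draw flips the sign of every participant's pattern
#' independently with probability 0.5 (the within-participant condition-swap
#' null), recomputes the group-mean pattern, and reapplies the template
#' projection. Patterns are normalized to unit Frobenius norm per participant
#' before averaging so no participant dominates.
#'
#' @param patterns list (one per participant) of `activation_pattern` objects
#'   or channels x time matrices.
#' @param templates areas x channels matrix.
#' @param n_boot number of bootstrap draws (default 1000).
#' @param seed integer seed.
#' @param normalize normalize each participant's pattern to unit Frobenius
#'   norm (default TRUE).
#' @return list: `null` (n_boot x areas x time array), `observed` (areas x
#'   time coefficients of the unflipped group mean), `n_boot`, `seed`.
#' @export
signflip_bootstrap_null <- function(patterns, templates, n_boot = 1000, seed = 1,
                                    normalize = TRUE) {
  if (length(patterns) < 2) stopf("signflip_bootstrap_null: need >= 2 participants")
  if (n_boot < 100) warnf("signflip_bootstrap_null: n_boot = %d is very low", n_boot)
  mats <- lapply(patterns, function(p) {
    m <- if (inherits(p, "activation_pattern")) p$pattern else as.matrix(p)
    if (normalize) m / sqrt(sum(m^2)) else m
  })
  np <- length(mats)
  obs <- localize_templates(Reduce(`+`, mats) / np, templates)$coefficients
  nult <- array(NA_real_, c(n_boot, nrow(obs), ncol(obs)))
  with_seed(seed, {
    for (b in seq_len(n_boot)) {
      s <- sample(c(-1, 1), np, replace = TRUE)
      gm <- Reduce(`+`, Map(`*`, mats, s)) / np
      nult[b, , ] <- localize_templates(gm, templates)$coefficients
    }
  })
  list(null = nult, observed = obs, n_boot = n_boot, seed = seed)
}

#' Gaussian z-score and two-sided normal p value against a null sample
#'
#' Fits a Gaussian to the null distribution (mean, SD) and evaluates
#' `z = (observed - mean) / sd` and `p = 2 * (1 - pnorm(|z|))`, floored at
#' the smallest positive double so p stays in (0, 1].
#'
#' @param observed observed statistic (scalar).
#' @param null_samples numeric vector of null draws (>= 2, nonzero variance).
#' @return list `z`, `p`.
#' @export
gaussian_z_pvalue <- function(observed, null_samples) {
  if (length(null_samples) < 2) stopf("gaussian_z_pvalue: need >= 2 null samples")
  s <- sd(null_samples)
  if (s == 0) stopf("gaussian_z_pvalue: null distribution has zero variance")
  z <- (observed - mean(null_samples)) / s
  p <- 2 * (1 - pnorm(abs(z)))
  list(z = z, p = max(p, .Machine$double.xmin))
}

#' Consecutive-significance mask
#'
#' TRUE exactly on maximal runs of `p < p_threshold` lasting at least
#' `min_duration_ms`; shorter sub-threshold runs stay FALSE everywhere.
#'
#' @param p numeric vector of p values over time.
#' @param p_threshold pointwise threshold (default 0.005).
#' @param min_duration_ms minimum run duration in ms (default 15).
#' @param srate sampling rate (Hz) of the p time series.
#' @return logical mask of the same length as `p`.
#' @export
consecutive_significance <- function(p, p_threshold = 0.005, min_duration_ms = 15,
                                     srate) {
  if (srate <= 0) stopf("consecutive_significance: srate must be > 0")
  below <- p < p_threshold
  r <- rle(below)
  dur_ms <- r$lengths * 1000 / srate
  r$values <- r$values & dur_ms >= min_duration_ms
  inverse.rle(r)
}

#' Per-area source contribution statistics
#'
#' Combines the group-mean template projection with its sign-flip bootstrap
#' null: per area and timepoint a Gaussian z and two-sided p (fitted per
#' timepoint), plus the consecutive-milliseconds significance mask.
#'
#' @inheritParams signflip_bootstrap_null
#' @param srate sampling rate of the pattern time axis (Hz).
#' @param p_threshold pointwise threshold for the mask (default 0.005).
#' @param min_duration_ms minimum significant duration (default 15 ms).
#' @return object of class `source_timecourses`: `contribution` (areas x
#'   time), `z`, `p`, `mask` (same shapes), `params`.
#' @export
source_timecourses <- function(patterns, templates, srate, n_boot = 1000,
                               seed = 1, p_threshold = 0.005,
                               min_duration_ms = 15) {
  bs <- signflip_bootstrap_null(patterns, templates, n_boot, seed)
  A <- nrow(bs$observed); Tn <- ncol(bs$observed)
  z <- p <- matrix(NA_real_, A, Tn, dimnames = dimnames(bs$observed))
  for (a in seq_len(A)) for (ti in seq_len(Tn)) {
    zp <- gaussian_z_pvalue(bs$observed[a, ti], bs$null[, a, ti])
    z[a, ti] <- zp$z; p[a, ti] <- zp$p
  }
  mask <- t(apply(p, 1, consecutive_significance, p_threshold = p_threshold,
                  min_duration_ms = min_duration_ms, srate = srate))
  structure(list(contribution = bs$observed, z = z, p = p, mask = mask,
                 params = list(n_boot = n_boot, p_threshold = p_threshold,
                               min_duration_ms = min_duration_ms, seed = seed,
                               srate = srate)),
            class = "source_timecourses")
}

#' @export
print.source_timecourses <- function(x, ...) {
  cat(sprintf("<source_timecourses> %d areas x %d timepoints, %d bootstrap draws\n",
              nrow(x$contribution), ncol(x$contribution), x$params$n_boot))
  act <- rowSums(x$mask)
  for (a in rownames(x$contribution)) {
    cat(sprintf("  %-8s %4d significant samples\n", a, act[a]))
  }
  invisible(x)
}
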