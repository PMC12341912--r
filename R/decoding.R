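# Pairwise linear-discriminant decoding over time: shrinkage LDA,
# equalized-trial 10-fold cross-validation with repetitions, shuffled-label
# baselines, and temporal generalization.

#' Fit a two-class linear discriminant
#'
#' `w` is proportional to `solve(Sigma, mu1 - mu2)` with `Sigma` the pooled
#' within-class covariance, shrunk toward a scaled identity with the analytic
#' (Ledoit-Wolf) intensity by default; `shrinkage = 0` uses the raw pooled
#' covariance with a pseudo-inverse fallback for rank-deficient data. The
#' bias places the decision boundary at the class-mean midpoint; decision
#' value `w . x + b` is positive for the first class. Exact zeros are broken
#' toward the second class.
#'
#' @param X trials x channels matrix.
#' @param y vector of two class labels.
#' @param shrinkage "auto" or a number in \[0, 1\].
#' @param classes optional length-2 vector fixing the class order (first
#'   class maps to positive decision values); defaults to order of
#'   appearance in `y`.
#' @return object of class `lda_model`: `w`, `b`, `classes`, `lambda`,
#'   `means`.
#' @export
fit_lda <- function(X, y, shrinkage = "auto", classes = NULL) {
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- classes %||% unique(y)
  if (length(classes) != 2 || !all(y %in% classes)) {
    stopf("fit_lda: need exactly 2 classes, got %d", length(unique(y)))
  }
  i1 <- y == classes[1]
  if (sum(i1) < 2 || sum(!i1) < 2) stopf("fit_lda: each class needs >= 2 trials")
  mu1 <- colMeans(X[i1, , drop = FALSE])
  mu2 <- colMeans(X[!i1, , drop = FALSE])
  centered <- X
  centered[i1, ] <- sweep(X[i1, , drop = FALSE], 2, mu1)
  centered[!i1, ] <- sweep(X[!i1, , drop = FALSE], 2, mu2)
  if (identical(shrinkage, 0) || identical(shrinkage, 0L)) {
    S <- crossprod(centered) / nrow(X)
    w <- tryCatch(solve(S, mu1 - mu2), error = function(e) MASS::ginv(S) %*% (mu1 - mu2))
    lambda <- 0
  } else {
    sc <- shrink_cov(centered, shrinkage)
    w <- solve(sc$sigma, mu1 - mu2)
    lambda <- sc$lambda
  }
  w <- as.vector(w)
  structure(list(w = w, b = -sum(w * (mu1 + mu2) / 2),
                 classes = classes, lambda = lambda,
                 means = rbind(mu1, mu2)), class = "lda_model")
}

#' Decision values of a fitted discriminant
#' @param model an `lda_model`.
#' @param X trials x channels matrix.
#' @return numeric decision values (positive = first class).
#' @export
decision_values <- function(model, X) {
  as.vector(as.matrix(X) %*% model$w + model$b)
}

#' @export
predict.lda_model <- function(object, newdata, ...) {
  dv <- decision_values(object, newdata)
  # ties at exactly 0 go to the second class
  ifelse(dv > 0, object$classes[1], object$classes[2])
}

# Cross-validation plan shared by timepoint decoding and temporal
# generalization so that identically seeded runs use identical folds.
# Returns, per repetition, the equalized trial indices (into the pair/task
# subset) and a stratified fold assignment.
cv_plan <- function(y, folds, repetitions, seed) {
  classes <- sort(unique(y))
  idx_by_class <- split(seq_along(y), y)
  k <- min(lengths(idx_by_class))
  if (k < folds) {
    lim <- names(idx_by_class)[which.min(lengths(idx_by_class))]
    stopf("decoding: class '%s' has %d trials, fewer than %d folds", lim, k, folds)
  }
  lapply(seq_len(repetitions), function(rep) {
    with_seed(derive_seed(seed, "cvplan", rep), {
      sel <- lapply(idx_by_class, function(ix) if (length(ix) == k) sample(ix) else sample(ix, k))
      fold <- rep(rep_len(seq_len(folds), k), length(classes))
      idx <- unlist(sel, use.names = FALSE)
      list(idx = idx, fold = fold)
    })
  })
}

decode_core <- function(dat, y, times, folds, repetitions, seed, shrinkage,
                        shuffle = FALSE) {
  nt <- length(times)
  plan <- cv_plan(y, folds, repetitions, seed)
  acc <- matrix(0, nt, repetitions)
  for (rep in seq_along(plan)) {
    idx <- plan[[rep]]$idx
    fold <- plan[[rep]]$fold
    yy <- y[idx]
    if (shuffle) {
      yy <- with_seed(derive_seed(seed, "shuffle", rep), sample(yy))
    }
    sub <- dat[idx, , , drop = FALSE]
    hits <- numeric(nt)
    for (f in seq_len(folds)) {
      tr <- fold != f
      te <- !tr
      ytr <- yy[tr]
      yte <- yy[te]
      for (ti in seq_len(nt)) {
        m <- fit_lda(sub[tr, , ti, drop = TRUE], ytr, shrinkage)
        pred <- predict(m, sub[te, , ti, drop = TRUE])
        hits[ti] <- hits[ti] + mean(pred == yte)
      }
    }
    acc[, rep] <- hits / folds
  }
  acc
}

subset_pair <- function(epochs, pair, task, correct_only = FALSE) {
  keep <- epochs$labels$task == task & epochs$labels$category %in% pair
  if (correct_only) keep <- keep & !is.na(epochs$labels$correct) & epochs$labels$correct
  if (!any(keep)) stopf("decoding: no trials for task '%s', pair %s", task, paste(pair, collapse = "/"))
  select_trials(epochs, keep)
}

#' Pairwise decoding accuracy time course
#'
#' For each repetition the two categories are equalized by random
#' subsampling, split into stratified folds, and a shrinkage LDA is trained
#' and tested per timepoint on the channel vector at that timepoint only.
#' Accuracy is averaged over folds, then repetitions.
#'
#' @param epochs an [eeg_epochs] object.
#' @param pair length-2 character vector of categories.
#' @param task task to restrict to ("superordinate" or "basic").
#' @param folds,repetitions cross-validation structure (defaults 10 and 10).
#' @param seed integer seed (folds and subsampling are reproducible from it).
#' @param shrinkage passed to [fit_lda()].
#' @param correct_only restrict to correct trials.
#' @return object of class `decoding_result`: `times`, `accuracy` (mean over
#'   folds x repetitions), `acc_by_rep`, `metadata`.
#' @export
decode_timecourse <- function(epochs, pair, task, folds = 10, repetitions = 10,
                              seed = 1, shrinkage = "auto", correct_only = FALSE) {
  sub <- subset_pair(epochs, pair, task, correct_only)
  acc <- decode_core(sub$data, sub$labels$category, sub$times, folds,
                     repetitions, seed, shrinkage)
  structure(list(times = sub$times, accuracy = rowMeans(acc), acc_by_rep = acc,
                 metadata = list(pair = pair, task = task, folds = folds,
                                 repetitions = repetitions, seed = seed,
                                 shrinkage = shrinkage, shuffled = FALSE)),
            class = "decoding_result")
}

#' Shuffled-label baseline decoding
#'
#' The identical procedure as [decode_timecourse()] with the category labels
#' permuted independently per repetition before splitting, giving the
#' empirical chance distribution.
#' @inheritParams decode_timecourse
#' @return a `decoding_result` with `metadata$shuffled = TRUE`.
#' @export
shuffled_baseline <- function(epochs, pair, task, folds = 10, repetitions = 10,
                              seed = 1, shrinkage = "auto", correct_only = FALSE) {
  sub <- subset_pair(epochs, pair, task, correct_only)
  acc <- decode_core(sub$data, sub$labels$category, sub$times, folds,
                     repetitions, seed, shrinkage, shuffle = TRUE)
  structure(list(times = sub$times, accuracy = rowMeans(acc), acc_by_rep = acc,
                 metadata = list(pair = pair, task = task, folds = folds,
                                 repetitions = repetitions, seed = seed,
                                 shrinkage = shrinkage, shuffled = TRUE)),
            class = "decoding_result")
}

#' @export
print.decoding_result <- function(x, ...) {
  cat(sprintf("<decoding_result> %s vs %s, task %s%s\n",
              x$metadata$pair[1], x$metadata$pair[2], x$metadata$task,
              if (x$metadata$shuffled) " (shuffled baseline)" else ""))
  cat(sprintf("  %d timepoints, %d folds x %d repetitions; peak accuracy %.3f at %.0f ms\n",
              length(x$times), x$metadata$folds, x$metadata$repetitions,
              max(x$accuracy), x$times[which.max(x$accuracy)]))
  invisible(x)
}

#' @export
plot.decoding_result <- function(x, ...) {
  plot(x$times, x$accuracy, type = "l", xlab = "time (ms)", ylab = "accuracy",
       main = sprintf("%s vs %s (%s)", x$metadata$pair[1], x$metadata$pair[2],
                      x$metadata$task), ...)
  abline(h = 0.5, lty = 3)
  invisible(x)
}

#' Temporal generalization matrix
#'
#' Trials are first averaged into coarser time bins ([bin_time()]); a
#' classifier trained at each binned timepoint is then tested at all binned
#' timepoints with the same folds. The diagonal equals a timepoint-wise
#' decoding run on the binned epochs with the same seed.
#'
#' @inheritParams decode_timecourse
#' @param bin_factor time-binning factor applied before decoding (default 4,
#'   i.e. ~4 ms bins at 1-ms sampling).
#' @return object of class `tg_matrix`: `times`, `accuracy` (train x test),
#'   `metadata`.
#' @export
temporal_generalization <- function(epochs, pair, task, bin_factor = 4,
                                    folds = 10, repetitions = 10, seed = 1,
                                    shrinkage = "auto", correct_only = FALSE) {
  binned <- bin_time(epochs, bin_factor)
  sub <- subset_pair(binned, pair, task, correct_only)
  dat <- sub$data
  y <- sub$labels$category
  nt <- length(sub$times)
  plan <- cv_plan(y, folds, repetitions, seed)
  acc <- matrix(0, nt, nt)
  for (rep in seq_along(plan)) {
    idx <- plan[[rep]]$idx
    fold <- plan[[rep]]$fold
    yy <- y[idx]
    subdat <- dat[idx, , , drop = FALSE]
    for (f in seq_len(folds)) {
      tr <- fold != f
      te <- !tr
      models <- lapply(seq_len(nt), function(ti) {
        fit_lda(subdat[tr, , ti, drop = TRUE], yy[tr], shrinkage)
      })
      W <- vapply(models, function(m) m$w, numeric(dim(dat)[2]))
      b <- vapply(models, function(m) m$b, numeric(1))
      cls1 <- models[[1]]$classes[1]
      correct1 <- yy[te] == cls1
      for (t2 in seq_len(nt)) {
        dv <- subdat[te, , t2, drop = TRUE] %*% W
        dv <- sweep(dv, 2, b, "+")          # n_test x n_train
        hit <- (dv > 0) == matrix(correct1, nrow(dv), ncol(dv))
        acc[, t2] <- acc[, t2] + colMeans(hit)
      }
    }
  }
  acc <- acc / (folds * repetitions)
  structure(list(times = sub$times, accuracy = acc,
                 metadata = list(pair = pair, task = task, folds = folds,
                                 repetitions = repetitions, bin_factor = bin_factor,
                                 seed = seed, shrinkage = shrinkage)),
            class = "tg_matrix")
}

#' @export
print.tg_matrix <- function(x, ...) {
  cat(sprintf("<tg_matrix> %s vs %s, task %s: %d x %d train x test accuracies\n",
              x$metadata$pair[1], x$metadata$pair[2], x$metadata$task,
              length(x$times), length(x$times)))
  cat(sprintf("  diagonal peak %.3f at %.0f ms\n",
              max(diag(x$accuracy)), x$times[which.max(diag(x$accuracy))]))
  invisible(x)
}
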