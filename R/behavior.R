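# Behavioral scoring: RT-based trial exclusions, log-linear corrected
# d-prime, Bonferroni-corrected paired comparisons, and the Bayesian
# posterior-overlap probability used for DDM hypothesis tests.

#' Filter behavioral trials
#'
#' Removes anticipatory responses (RT < 200 ms) and trials without any
#' response (no response within the deadline), the standard exclusions for
#' speeded categorization.
#'
#' @param table data.frame with columns `response` and `rt_ms`.
#' @param anticipatory_ms anticipation threshold (ms).
#' @return the filtered table, with attribute `removed` = named counts
#'   c(anticipatory = , no_response = ).
#' @export
filter_trials <- function(table, anticipatory_ms = 200) {
  none <- table$response == "none"
  antic <- !none & !is.na(table$rt_ms) & table$rt_ms < anticipatory_ms
  out <- table[!none & !antic, , drop = FALSE]
  attr(out, "removed") <- c(anticipatory = sum(antic), no_response = sum(none))
  out
}

#' Log-linear corrected d-prime
#'
#' Applies the log-linear correction for extreme rates -- add 0.5 to every
#' response cell and 1 to every denominator -- before computing
#' `qnorm(hit rate) - qnorm(false-alarm rate)`, so the statistic stays finite
#' at 0% or 100% performance.
#'
#' @param hits,misses,false_alarms,correct_rejections non-negative counts.
#' @return d-prime (numeric scalar).
#' @export
dprime_corrected <- function(hits, misses, false_alarms, correct_rejections) {
  counts <- c(hits, misses, false_alarms, correct_rejections)
  if (any(counts < 0)) stopf("dprime_corrected: counts must be non-negative")
  if (hits + misses == 0 || false_alarms + correct_rejections == 0) {
    stopf("dprime_corrected: need at least one signal and one noise trial")
  }
  h <- (hits + 0.5) / (hits + misses + 1)
  fa <- (false_alarms + 0.5) / (false_alarms + correct_rejections + 1)
  qnorm(h) - qnorm(fa)
}

#' Per-task d-prime from a behavior table
#'
#' Signal trials are task targets (animals in the superordinate task, birds
#' in the basic task); a hit is a "yes" response on a target trial, a false
#' alarm a "yes" on a distractor trial. Trials should already be filtered
#' with [filter_trials()].
#' @param table behavior data.frame (single participant, single task or with
#'   a `task` column; computed per task).
#' @return named numeric of d-primes per task.
#' @export
dprime_by_task <- function(table) {
  vapply(split(table, table$task), function(tt) {
    target <- if (tt$task[1] == "superordinate") {
      tt$category %in% c("bird", "nonbird_animal")
    } else tt$category == "bird"
    yes <- tt$response == "yes"
    dprime_corrected(sum(target & yes), sum(target & !yes),
                     sum(!target & yes), sum(!target & !yes))
  }, numeric(1))
}

#' Per-category response rates
#'
#' For target categories the rate of "yes" responses (hit rate); for
#' distractor categories both the false-alarm ("yes") rate and the
#' correct-rejection rate are reported, since "hits" on distractor trials
#' admit either reading.
#' @param table filtered behavior data.frame.
#' @return data.frame: task, category, n, yes_rate, correct_rate.
#' @export
category_rates <- function(table) {
  out <- do.call(rbind, lapply(split(table, list(table$task, table$category), drop = TRUE), function(tt) {
    data.frame(task = tt$task[1], category = tt$category[1], n = nrow(tt),
               yes_rate = mean(tt$response == "yes"),
               correct_rate = mean(tt$correct), stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Bonferroni-corrected paired comparisons
#'
#' Two-sided paired t-tests over participants between named condition pairs,
#' with Cohen's d for paired data and Bonferroni correction at the stated
#' family size (default: the three category pairs).
#'
#' @param values numeric matrix participants x conditions (column names are
#'   condition labels).
#' @param pairs list of length-2 character vectors naming condition columns.
#' @param family_size Bonferroni family size (default `length(pairs)`, the
#'   conventional 3-comparison family when comparing three categories).
#' @return data.frame: one row per pair with estimates, t, df, cohens_d,
#'   p_raw, p_corrected, method.
#' @export
paired_comparisons <- function(values, pairs, family_size = length(pairs)) {
  values <- as.matrix(values)
  if (nrow(values) < 2) stopf("paired_comparisons: need >= 2 participants")
  rows <- lapply(pairs, function(pr) {
    a <- values[, pr[1]]
    b <- values[, pr[2]]
    if (anyNA(a) || anyNA(b)) stopf("paired_comparisons: missing observations for pair %s-%s", pr[1], pr[2])
    d <- a - b
    n <- length(d)
    sd_d <- sd(d)
    if (sd_d == 0) {
      tstat <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else .Machine$double.xmin
      cd <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
    } else {
      tstat <- mean(d) / (sd_d / sqrt(n))
      p <- 2 * pt(-abs(tstat), df = n - 1)
      cd <- mean(d) / sd_d
    }
    data.frame(cond_a = pr[1], cond_b = pr[2],
               mean_a = mean(a), mean_b = mean(b), difference = mean(d),
               t = tstat, df = n - 1, cohens_d = cd,
               p_raw = p, p_corrected = min(1, p * family_size),
               method = sprintf("paired t, Bonferroni x%d", family_size),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Posterior overlap probability P(a > b)
#'
#' The fraction of posterior draws for which condition a exceeds condition b:
#' 0.5 means the posteriors fully overlap, 0 or 1 that they are disjoint.
#' Equal-length chains are compared draw-by-draw (preserving MCMC
#' dependence); unequal lengths fall back to the full cross-product. Ties
#' count 0.5.
#'
#' @param samples_a,samples_b numeric vectors of posterior draws.
#' @return probability in \[0, 1\].
#' @export
posterior_overlap_probability <- function(samples_a, samples_b) {
  if (!length(samples_a) || !length(samples_b)) {
    stopf("posterior_overlap_probability: sample vectors must be nonempty")
  }
  if (length(samples_a) == length(samples_b)) {
    mean((samples_a > samples_b) + 0.5 * (samples_a == samples_b))
  } else {
    o <- outer(samples_a, samples_b, ">") + 0.5 * outer(samples_a, samples_b, "==")
    mean(o)
  }
}
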