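# Epoched EEG data model and epoch-level conditioning operations.

TASKS <- c("superordinate", "basic")
CATEGORIES <- c("bird", "nonbird_animal", "vehicle")

#' Construct an epoched EEG set
#'
#' The common currency of all EEG stages: a trials x channels x timepoints
#' array of microvolt amplitudes together with per-trial condition labels and
#' timing metadata. Latencies are in milliseconds relative to stimulus onset;
#' the default experimental epoch spans -150 to +500 ms.
#'
#' @param data numeric array, trials x channels x timepoints (microvolts).
#' @param times numeric vector of per-timepoint latencies (ms), strictly
#'   increasing with spacing `1000/srate`.
#' @param srate sampling rate in Hz.
#' @param channels character vector of ordered channel labels (authoritative
#'   order; no montage-based reordering is ever applied).
#' @param labels data.frame with one row per trial and columns `task`
#'   (superordinate/basic), `category` (bird/nonbird_animal/vehicle),
#'   `correct` (logical, NA for no response), `rt_ms`, `participant`.
#' @param veog_pair optional character vector of the two vertically placed
#'   eye-channel labels used for artifact screening.
#' @return an object of class `eeg_epochs`.
#' @export
eeg_epochs <- function(data, times, srate, channels, labels, veog_pair = NULL) {
  data <- unclass(data)
  if (length(dim(data)) != 3) stopf("eeg_epochs: data must be a 3-d array (trials x channels x timepoints)")
  labels <- as.data.frame(labels, stringsAsFactors = FALSE)
  if (dim(data)[1] != nrow(labels)) {
    stopf("eeg_epochs: %d trials in data but %d label rows", dim(data)[1], nrow(labels))
  }
  if (dim(data)[2] != length(channels)) {
    stopf("eeg_epochs: %d channels in data but %d channel labels", dim(data)[2], length(channels))
  }
  if (dim(data)[3] != length(times)) {
    stopf("eeg_epochs: %d timepoints in data but %d latencies", dim(data)[3], length(times))
  }
  if (length(times) > 1) {
    dt <- diff(times)
    if (any(dt <= 0)) stopf("eeg_epochs: times must be strictly increasing")
    if (any(abs(dt - 1000 / srate) > 1e-9)) {
      stopf("eeg_epochs: time spacing must equal 1000/srate = %.6f ms", 1000 / srate)
    }
  }
  needed <- c("task", "category")
  miss <- setdiff(needed, names(labels))
  if (length(miss)) stopf("eeg_epochs: labels missing column(s): %s", paste(miss, collapse = ", "))
  bad_task <- !labels$task %in% TASKS
  if (any(bad_task)) stopf("eeg_epochs: unknown task label(s): %s", paste(unique(labels$task[bad_task]), collapse = ", "))
  bad_cat <- !labels$category %in% CATEGORIES
  if (any(bad_cat)) stopf("eeg_epochs: unknown category label(s): %s", paste(unique(labels$category[bad_cat]), collapse = ", "))
  if (!is.null(veog_pair)) {
    if (length(veog_pair) != 2) stopf("eeg_epochs: veog_pair must name exactly two channels")
    miss <- setdiff(veog_pair, channels)
    if (length(miss)) stopf("eeg_epochs: veog channel(s) not present: %s", paste(miss, collapse = ", "))
  }
  if (!"correct" %in% names(labels)) labels$correct <- NA
  if (!"rt_ms" %in% names(labels)) labels$rt_ms <- NA_real_
  if (!"participant" %in% names(labels)) labels$participant <- "p01"
  structure(
    list(data = data, times = as.numeric(times), srate = as.numeric(srate),
         channels = as.character(channels), labels = labels,
         veog_pair = veog_pair),
    class = "eeg_epochs"
  )
}

#' @export
print.eeg_epochs <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<eeg_epochs> %d trials x %d channels x %d timepoints\n", d[1], d[2], d[3]))
  cat(sprintf("  time: %.1f .. %.1f ms @ %g Hz\n", min(x$times), max(x$times), x$srate))
  tab <- table(x$labels$task, x$labels$category)
  print(tab)
  invisible(x)
}

#' @export
dim.eeg_epochs <- function(x) dim(x$data)

n_trials <- function(epochs) dim(epochs$data)[1]

#' Subset trials of an epoch set
#'
#' @param epochs an [eeg_epochs] object.
#' @param idx integer or logical trial index.
#' @return an `eeg_epochs` with the selected trials.
#' @export
select_trials <- function(epochs, idx) {
  eeg_epochs(epochs$data[idx, , , drop = FALSE], epochs$times, epochs$srate,
             epochs$channels, epochs$labels[idx, , drop = FALSE], epochs$veog_pair)
}

#' Baseline-correct epochs
#'
#' Subtracts, per trial and channel, the mean amplitude over the baseline
#' window (default -150..0 ms, a closed interval on sample latencies).
#'
#' @param epochs an [eeg_epochs] object.
#' @param window numeric length-2 (start_ms, end_ms).
#' @return baseline-corrected `eeg_epochs`.
#' @export
baseline_correct <- function(epochs, window = c(-150, 0)) {
  sel <- which(epochs$times >= window[1] & epochs$times <= window[2])
  if (!length(sel)) {
    stopf("baseline_correct: window [%g, %g] ms outside epoch range [%g, %g] ms",
          window[1], window[2], min(epochs$times), max(epochs$times))
  }
  base <- apply(epochs$data[, , sel, drop = FALSE], c(1, 2), mean)
  epochs$data <- epochs$data - as.vector(base) # recycles over the time dimension
  epochs
}

#' Reject epochs with large vertical EOG differences
#'
#' Removes trials whose maximum absolute instantaneous difference between the
#' two eye channels exceeds the threshold (default 150 microvolts). The
#' maximum over the whole epoch is the conservative reduction of the
#' screening rule.
#'
#' @param epochs an [eeg_epochs] with `veog_pair` set.
#' @param threshold_uv rejection threshold in microvolts.
#' @return list with `epochs` (kept trials) and `rejected` (logical mask over
#'   the original trials, TRUE = rejected).
#' @export
reject_eye_epochs <- function(epochs, threshold_uv = 150) {
  if (is.null(epochs$veog_pair)) {
    stopf("reject_eye_epochs: veog_pair is not set; set it on the eeg_epochs object or skip eye rejection")
  }
  i1 <- match(epochs$veog_pair[1], epochs$channels)
  i2 <- match(epochs$veog_pair[2], epochs$channels)
  dif <- abs(epochs$data[, i1, , drop = FALSE] - epochs$data[, i2, , drop = FALSE])
  mx <- apply(dif, 1, max)
  rejected <- mx > threshold_uv
  list(epochs = select_trials(epochs, !rejected), rejected = rejected)
}

#' Randomly equalize trial counts across label groups
#'
#' Subsamples every group (defined by one or more label columns) down to the
#' size of the smallest group, uniformly without replacement, reproducibly
#' from the seed.
#'
#' @param epochs an [eeg_epochs] object.
#' @param grouping character vector of label column names (default "category").
#' @param seed integer seed.
#' @return an `eeg_epochs` with equal group sizes (original trial order kept).
#' @export
subsample_equal <- function(epochs, grouping = "category", seed) {
  miss <- setdiff(grouping, names(epochs$labels))
  if (length(miss)) stopf("subsample_equal: unknown label column(s): %s", paste(miss, collapse = ", "))
  key <- interaction(epochs$labels[grouping], drop = FALSE, lex.order = TRUE)
  counts <- table(key)
  if (any(counts == 0)) {
    stopf("subsample_equal: empty group(s): %s", paste(names(counts)[counts == 0], collapse = ", "))
  }
  if (length(counts) < 2) stopf("subsample_equal: need at least 2 groups, got %d", length(counts))
  k <- min(counts)
  keep <- with_seed(seed, {
    unlist(lapply(split(seq_len(n_trials(epochs)), key), function(ix) {
      if (length(ix) == k) ix else sort(sample(ix, k))
    }), use.names = FALSE)
  })
  select_trials(epochs, sort(keep))
}

#' Average consecutive timepoints into coarser bins
#'
#' Each output sample is the arithmetic mean of `factor` consecutive input
#' samples; trailing samples that do not fill a block are dropped, and binned
#' latencies are block-center means. Used before temporal generalization to
#' reduce the time axis by the bin factor.
#'
#' @param epochs an [eeg_epochs] object.
#' @param factor integer >= 1.
#' @return an `eeg_epochs` with `floor(T/factor)` timepoints.
#' @export
bin_time <- function(epochs, factor) {
  factor <- as.integer(factor)
  if (is.na(factor) || factor < 1) stopf("bin_time: factor must be an integer >= 1")
  if (factor == 1) return(epochs)
  nt <- dim(epochs$data)[3]
  nb <- nt %/% factor
  if (nb < 1) stopf("bin_time: factor %d exceeds the %d available timepoints", factor, nt)
  d <- dim(epochs$data)
  x <- epochs$data[, , seq_len(nb * factor), drop = FALSE]
  dim(x) <- c(d[1] * d[2], factor, nb)
  binned <- colMeans(aperm(x, c(2, 1, 3)))       # (trial*channel) x bins
  dim(binned) <- c(d[1], d[2], nb)
  tm <- epochs$times[seq_len(nb * factor)]
  new_times <- colMeans(matrix(tm, nrow = factor))
  out <- epochs
  out$data <- binned
  out$times <- new_times
  out$srate <- epochs$srate / factor
  out
}

#' Region-of-interest specification
#'
#' @param name ROI name; `roi_defaults()` gives the three standard sets
#'   (occipital, central, frontal).
#' @param electrodes character vector of channel labels.
#' @return an object of class `roi_spec`.
#' @export
roi_spec <- function(name, electrodes) {
  structure(list(name = name, electrodes = as.character(electrodes)), class = "roi_spec")
}

#' Standard ROI electrode sets
#'
#' Occipital (O1 PO3 PO7 Oz O2 PO4 PO8), central (C3 C1 Cz C2 C4) and frontal
#' (AF3 F1 AFz Fz F2 AF4) electrode groups used for ERP difference waves.
#' @return named list of [roi_spec] objects.
#' @export
roi_defaults <- function() {
  list(
    occipital = roi_spec("occipital", c("O1", "PO3", "PO7", "Oz", "O2", "PO4", "PO8")),
    central   = roi_spec("central", c("C3", "C1", "Cz", "C2", "C4")),
    frontal   = roi_spec("frontal", c("AF3", "F1", "AFz", "Fz", "F2", "AF4"))
  )
}

#' Average a channels x time array over an ROI
#'
#' @param erp channels x time matrix with rownames set to channel labels, or
#'   a matrix plus a `channels` argument.
#' @param roi an [roi_spec].
#' @param channels channel labels for the rows of `erp` (defaults to rownames).
#' @return numeric time series (mean over the ROI electrodes).
#' @export
roi_average <- function(erp, roi, channels = rownames(erp)) {
  if (is.null(channels)) stopf("roi_average: channel labels required (rownames or `channels`)")
  idx <- match(roi$electrodes, channels)
  if (anyNA(idx)) {
    stopf("roi_average: unknown electrode(s) %s; available: %s",
          paste(roi$electrodes[is.na(idx)], collapse = ", "),
          paste(channels, collapse = ", "))
  }
  colMeans(erp[idx, , drop = FALSE])
}
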