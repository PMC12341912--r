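# Condition ERPs and differential waveforms.

#' Condition-average ERP
#'
#' Arithmetic mean over the trials matching a selector.
#'
#' @param epochs an [eeg_epochs] object.
#' @param selector named list matched against label columns, e.g.
#'   `list(task = "basic", category = "bird")`, or a logical/integer trial
#'   index.
#' @return channels x time matrix (rownames = channel labels).
#' @export
condition_erp <- function(epochs, selector) {
  idx <- if (is.list(selector)) {
    keep <- rep(TRUE, n_trials(epochs))
    for (col in names(selector)) {
      if (!col %in% names(epochs$labels)) stopf("condition_erp: unknown label column '%s'", col)
      keep <- keep & epochs$labels[[col]] %in% selector[[col]]
    }
    which(keep)
  } else if (is.logical(selector)) which(selector) else as.integer(selector)
  if (!length(idx)) {
    stopf("condition_erp: no trials match selector %s",
          paste(deparse(selector), collapse = ""))
  }
  erp <- apply(epochs$data[idx, , , drop = FALSE], c(2, 3), mean)
  rownames(erp) <- epochs$channels
  erp
}

#' Differential waveform between two condition ERPs
#'
#' @param erp_a,erp_b channels x time matrices of matching shape.
#' @return elementwise `erp_a - erp_b`.
#' @export
differential_waveform <- function(erp_a, erp_b) {
  if (!all(dim(erp_a) == dim(erp_b))) {
    stopf("differential_waveform: shape mismatch (%s vs %s)",
          paste(dim(erp_a), collapse = "x"), paste(dim(erp_b), collapse = "x"))
  }
  erp_a - erp_b
}
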