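# Interchange epoch container: plain-text directory with named datasets.
#
# Layout of `<path>/` (schema_version 1):
#   meta.json   srate, times (ms), channels, veog_pair, dims, data_order
#   labels.tsv  one row per trial: task, category, correct, rt_ms, participant
#   data.tsv    one row per trial, channels*timepoints columns, channel-major
#               within timepoint (column index = channel + (time-1)*n_channels)

EPOCHS_SCHEMA_VERSION <- 1L

#' Write an epoch set to the interchange container
#'
#' @param epochs an [eeg_epochs] object.
#' @param path directory to create/overwrite.
#' @return `path`, invisibly.
#' @export
write_epochs <- function(epochs, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  d <- dim(epochs$data)
  meta <- list(
    schema_version = EPOCHS_SCHEMA_VERSION,
    srate = epochs$srate,
    times = epochs$times,
    channels = epochs$channels,
    veog_pair = epochs$veog_pair,
    dims = d,
    data_order = "channel_major_within_timepoint"
  )
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  lab <- epochs$labels
  lab$correct <- ifelse(is.na(lab$correct), "missing", ifelse(lab$correct, "true", "false"))
  data.table::fwrite(lab, file.path(path, "labels.tsv"), sep = "\t", na = "NA")
  flat <- epochs$data
  dim(flat) <- c(d[1], d[2] * d[3])
  data.table::fwrite(data.table::as.data.table(flat), file.path(path, "data.tsv"),
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Read an epoch set
#'
#' @param path container directory written by [write_epochs()].
#' @param format `"interchange"` (the plain-text container). EEGLAB `.set`
#'   epoch files are not supported by this build.
#' @return an [eeg_epochs] object.
#' @export
read_epochs <- function(path, format = "interchange") {
  format <- match.arg(format, c("interchange", "eeglab_set"))
  if (format == "eeglab_set") {
    stopf("read_epochs: EEGLAB .set reading is not available in this build; convert to the interchange container")
  }
  meta_path <- file.path(path, "meta.json")
  if (!file.exists(meta_path)) stopf("read_epochs: malformed container: missing file meta.json")
  meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
  for (field in c("srate", "times", "channels", "dims")) {
    if (is.null(meta[[field]])) stopf("read_epochs: missing field %s", field)
  }
  lab_path <- file.path(path, "labels.tsv")
  if (!file.exists(lab_path)) stopf("read_epochs: malformed container: missing file labels.tsv")
  lab <- as.data.frame(data.table::fread(lab_path, sep = "\t"))
  if ("correct" %in% names(lab)) {
    lab$correct <- c("true" = TRUE, "false" = FALSE, "missing" = NA)[as.character(lab$correct)]
  }
  dat_path <- file.path(path, "data.tsv")
  if (!file.exists(dat_path)) stopf("read_epochs: malformed container: missing file data.tsv")
  flat <- as.matrix(data.table::fread(dat_path, sep = "\t", header = FALSE))
  d <- as.integer(meta$dims)
  if (!all(dim(flat) == c(d[1], d[2] * d[3]))) {
    stopf("read_epochs: data.tsv has dims %d x %d, expected %d x %d",
          nrow(flat), ncol(flat), d[1], d[2] * d[3])
  }
  dim(flat) <- d
  veog <- meta$veog_pair
  if (length(veog) == 0) veog <- NULL
  eeg_epochs(flat, meta$times, meta$srate, meta$channels, lab, veog)
}
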