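#' Construct a multichannel EEG record
#'
#' An `eeg_record` is the core container of the pipeline: a fixed-rate,
#' multichannel signal block (microvolts) together with its channel labels and
#' seizure annotations. Channel order is preserved as given; no montage
#' re-referencing is performed.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per data row.
#' @param patient_id patient identifier.
#' @param start_time offset of the first sample in seconds (default 0).
#' @param annotations seizure annotation table as returned by
#'   [seizure_annotations()]: a data frame with `onset_s` and `offset_s`
#'   columns in seconds from record start, sorted and non-overlapping.
#'
#' @return An object of class `eeg_record`.
#' @export
eeg_record <- function(data, fs, channel_labels = NULL, patient_id = "P00",
                       start_time = 0, annotations = seizure_annotations()) {
  if (!is.matrix(data) || !is.numeric(data)) {
    stop("`data` must be a numeric channels x samples matrix", call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a single positive sampling rate in Hz", call. = FALSE)
  }
  if (is.null(channel_labels)) {
    channel_labels <- sprintf("CH%02d", seq_len(nrow(data)))
  }
  if (length(channel_labels) != nrow(data)) {
    stop("number of data rows must equal the number of channel labels",
         call. = FALSE)
  }
  if (!all(is.finite(data))) {
    stop("all samples must be finite", call. = FALSE)
  }
  rec <- structure(
    list(patient_id = as.character(patient_id),
         channel_labels = as.character(channel_labels),
         fs = as.numeric(fs),
         data = data,
         start_time = as.numeric(start_time),
         annotations = annotations),
    class = "eeg_record")
  validate_annotations(annotations, duration = record_duration(rec))
  rec
}

#' Record duration in seconds
#' @param record an [eeg_record()].
#' @return duration in seconds.
#' @export
record_duration <- function(record) {
  ncol(record$data) / record$fs
}

#' Build a seizure annotation table
#'
#' @param onset_s numeric vector of seizure onsets, seconds from record start.
#' @param offset_s numeric vector of seizure offsets, seconds from record
#'   start; must satisfy `onset_s < offset_s` elementwise.
#' @return a `data.frame` with columns `onset_s`, `offset_s`, sorted by onset.
#' @export
seizure_annotations <- function(onset_s = numeric(0), offset_s = numeric(0)) {
  if (length(onset_s) != length(offset_s)) {
    stop("onset and offset vectors must have equal length", call. = FALSE)
  }
  ann <- data.frame(onset_s = as.numeric(onset_s),
                    offset_s = as.numeric(offset_s))
  ann <- ann[order(ann$onset_s), , drop = FALSE]
  rownames(ann) <- NULL
  validate_annotations(ann)
  ann
}

# Invariants: 0 <= onset < offset (<= duration when known), sorted,
# non-overlapping. Errors name the offending row.
validate_annotations <- function(ann, duration = NULL) {
  if (nrow(ann) == 0L) return(invisible(ann))
  for (i in seq_len(nrow(ann))) {
    if (!is.finite(ann$onset_s[i]) || !is.finite(ann$offset_s[i]) ||
        ann$onset_s[i] < 0 || ann$offset_s[i] <= ann$onset_s[i]) {
      stop(sprintf("annotation row %d invalid: require 0 <= onset < offset", i),
           call. = FALSE)
    }
    if (!is.null(duration) && ann$offset_s[i] > duration + 1e-9) {
      stop(sprintf("annotation row %d extends past record end (%.1f s)",
                   i, duration), call. = FALSE)
    }
  }
  if (is.unsorted(ann$onset_s)) {
    stop("annotations must be sorted by onset", call. = FALSE)
  }
  if (nrow(ann) > 1L &&
      any(ann$onset_s[-1L] < ann$offset_s[-nrow(ann)])) {
    stop("annotations must be non-overlapping", call. = FALSE)
  }
  invisible(ann)
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> patient %s: %d channels x %d samples @ %g Hz (%.1f s), %d seizure(s)\n",
              x$patient_id, nrow(x$data), ncol(x$data), x$fs,
              record_duration(x), nrow(x$annotations)))
  invisible(x)
}
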