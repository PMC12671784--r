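#' Read seizure annotations from CSV or JSON
#'
#' Accepts a CSV file with header `onset_s,offset_s` or a JSON array of
#' objects with `onset_s`/`offset_s` fields, both in seconds from record
#' start. The result is validated (each offset strictly after its onset,
#' non-overlapping) and sorted by onset, so reading is idempotent under
#' re-serialisation.
#'
#' @param path path to a `.csv` or `.json` annotation file.
#' @return a sorted annotation `data.frame` (see [seizure_annotations()]).
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read annotation file '%s'", path), call. = FALSE)
  }
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    ann <- jsonlite::fromJSON(path)
    if (length(ann) == 0) return(seizure_annotations())
    ann <- as.data.frame(ann)
  } else {
    ann <- utils::read.csv(path)
  }
  if (!all(c("onset_s", "offset_s") %in% names(ann))) {
    stop(sprintf("'%s' must provide onset_s and offset_s columns", path),
         call. = FALSE)
  }
  for (i in seq_len(nrow(ann))) {
    if (!is.finite(ann$onset_s[i]) || !is.finite(ann$offset_s[i]) ||
        ann$offset_s[i] <= ann$onset_s[i] || ann$onset_s[i] < 0) {
      stop(sprintf("annotation row %d of '%s' invalid: require 0 <= onset_s < offset_s",
                   i, path), call. = FALSE)
    }
  }
  seizure_annotations(ann$onset_s, ann$offset_s)
}

#' Write seizure annotations to CSV or JSON
#'
#' @param annotations annotation table (see [seizure_annotations()]).
#' @param path output path; format chosen by extension (`.csv` or `.json`).
#' @return the path, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  validate_annotations(annotations)
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    jsonlite::write_json(annotations, path, digits = NA)
  } else {
    utils::write.csv(annotations, path, row.names = FALSE, quote = FALSE)
  }
  invisible(path)
}
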