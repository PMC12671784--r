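# Minimal EDF/EDF+ signal I/O.
#
# EDF stores a 256-byte fixed header, one 256-byte header block per signal,
# then data records of 16-bit little-endian integers, mapped to physical
# units by a per-signal linear (physical min/max vs digital min/max) scale.
# Seizure annotations are carried in sidecar CSV/JSON files (see
# read_annotations); the EDF+ annotation channel is not used.

edf_pad <- function(x, width) {
  x <- as.character(x)
  if (nchar(x) > width) x <- substr(x, 1, width)
  formatC(x, width = -width, flag = " ")
}

edf_num <- function(x, width) {
  s <- formatC(x, format = "g", digits = 7, width = -1)
  if (nchar(s) > width) s <- substr(s, 1, width)
  edf_pad(s, width)
}

#' Write an EEG record to an EDF file
#'
#' Samples are quantised to 16 bits against each channel's physical range, so
#' a write/read round trip preserves values within one quantisation step.
#' When the sample count is an integer multiple of `fs`, one-second data
#' records are used; otherwise the whole signal is stored as a single record.
#'
#' @param record an [eeg_record()]; all samples must be finite.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_edf <- function(record, path) {
  if (!inherits(record, "eeg_record")) stop("`record` must be an eeg_record")
  x <- record$data
  if (!all(is.finite(x))) stop("record contains non-finite samples", call. = FALSE)
  nc <- nrow(x); ns_total <- ncol(x); fs <- record$fs

  if (fs == round(fs) && ns_total %% fs == 0) {
    n_rec <- ns_total %/% fs
    rec_dur <- 1
    spr <- as.integer(fs)                 # samples per record, per signal
  } else {
    n_rec <- 1L
    rec_dur <- ns_total / fs
    spr <- ns_total
  }

  phys_min <- apply(x, 1, min); phys_max <- apply(x, 1, max)
  flat <- phys_max - phys_min < 1e-12
  phys_min[flat] <- phys_min[flat] - 1
  phys_max[flat] <- phys_max[flat] + 1
  dig_min <- -32768L; dig_max <- 32767L

  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    edf_pad("0", 8),
    edf_pad(record$patient_id, 80),
    edf_pad("cgtnet EEG export", 80),
    edf_pad("01.01.00", 8), edf_pad("00.00.00", 8),
    edf_pad(256 * (nc + 1), 8),
    edf_pad("", 44),
    edf_pad(n_rec, 8),
    edf_num(rec_dur, 8),
    edf_pad(nc, 4))
  writeChar(hdr, con, eos = NULL)
  field <- function(vals, width) {
    writeChar(paste0(vapply(vals, edf_pad, "", width = width), collapse = ""),
              con, eos = NULL)
  }
  field(record$channel_labels, 16)
  field(rep("", nc), 80)                  # transducer
  field(rep("uV", nc), 8)
  writeChar(paste0(vapply(phys_min, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  writeChar(paste0(vapply(phys_max, edf_num, "", width = 8), collapse = ""), con, eos = NULL)
  field(rep(dig_min, nc), 8)
  field(rep(dig_max, nc), 8)
  field(rep("", nc), 80)                  # prefiltering
  field(rep(spr, nc), 8)
  field(rep("", nc), 32)

  scale <- (dig_max - dig_min) / (phys_max - phys_min)
  for (r in seq_len(n_rec)) {
    idx <- ((r - 1L) * spr + 1L):(r * spr)
    for (ch in seq_len(nc)) {
      dig <- as.integer(round((x[ch, idx] - phys_min[ch]) * scale[ch]) + dig_min)
      writeBin(dig, con, size = 2L, endian = "little")
    }
  }
  invisible(path)
}

#' Read an EDF/EDF+ file into an EEG record
#'
#' All signal channels are returned at a single common sampling rate. If
#' channels were stored at differing rates, minority-rate channels are
#' linearly resampled onto the majority-rate grid and a message is emitted.
#'
#' @param path path to an EDF/EDF+ file.
#' @param annotations optional annotation table to attach (EDF carries none
#'   in this dialect).
#' @return an [eeg_record()].
#' @export
read_edf <- function(path, annotations = seizure_annotations()) {
  if (!file.exists(path)) stop(sprintf("cannot read EDF file '%s'", path), call. = FALSE)
  sz <- file.info(path)$size
  if (is.na(sz) || sz < 256) {
    stop(sprintf("'%s' is not a valid EDF file (truncated header)", path), call. = FALSE)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(n) readChar(con, n, useBytes = TRUE)
  rd(8)                                   # version
  patient_id <- trimws(rd(80))
  rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8))
  rd(44)
  n_rec <- as.integer(rd(8))
  rec_dur <- as.numeric(rd(8))
  nc <- as.integer(rd(4))
  if (is.na(nc) || nc < 1L) {
    stop(sprintf("'%s' declares zero signal channels", path), call. = FALSE)
  }
  labels <- trimws(vapply(seq_len(nc), function(i) rd(16), ""))
  rd(80 * nc); rd(8 * nc)
  phys_min <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  phys_max <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dig_min <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  dig_max <- as.numeric(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(80 * nc)
  spr <- as.integer(vapply(seq_len(nc), function(i) rd(8), ""))
  rd(32 * nc)

  expected <- hdr_bytes + 2 * n_rec * sum(spr)
  if (sz < expected) {
    stop(sprintf("'%s' is truncated: %d bytes, expected %d", path, sz, expected),
         call. = FALSE)
  }

  raw <- vector("list", nc)
  for (ch in seq_len(nc)) raw[[ch]] <- numeric(n_rec * spr[ch])
  for (r in seq_len(n_rec)) {
    for (ch in seq_len(nc)) {
      dig <- readBin(con, "integer", n = spr[ch], size = 2L, signed = TRUE,
                     endian = "little")
      raw[[ch]][((r - 1L) * spr[ch] + 1L):(r * spr[ch])] <- dig
    }
  }
  fs_all <- spr / rec_dur
  fs <- as.numeric(names(sort(table(fs_all), decreasing = TRUE))[1])
  n_target <- as.integer(round(n_rec * rec_dur * fs))
  data <- matrix(0, nc, n_target)
  for (ch in seq_len(nc)) {
    phys <- phys_min[ch] + (raw[[ch]] - dig_min[ch]) *
      (phys_max[ch] - phys_min[ch]) / (dig_max[ch] - dig_min[ch])
    if (abs(fs_all[ch] - fs) < 1e-9) {
      data[ch, ] <- phys
    } else {
      message(sprintf("read_edf: channel %s at %g Hz resampled to majority rate %g Hz",
                      labels[ch], fs_all[ch], fs))
      t_src <- (seq_along(phys) - 1) / fs_all[ch]
      t_dst <- (seq_len(n_target) - 1) / fs
      data[ch, ] <- approx(t_src, phys, xout = t_dst, rule = 2)$y
    }
  }
  eeg_record(data, fs = fs, channel_labels = labels, patient_id = patient_id,
             annotations = annotations)
}
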