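#' Write an EEG record to an EDF file
#'
#' Minimal single-signal EDF (European Data Format) writer: 16-bit samples,
#' physical units uV, one data record per second. The physical range is
#' chosen symmetric around zero from the data, so the quantization step is
#' `2 * phys_max / 65534` uV.
#'
#' @param record an [eeg_record()] with integer sampling rate.
#' @param path output file path.
#' @param phys_max physical range bound in uV; default the data's ceiling.
#' @return `path`, invisibly.
#' @export
write_edf <- function(record, path, phys_max = NULL) {
  stopifnot(inherits(record, "eeg_record"))
  fs <- record$fs
  if (fs != round(fs)) stop("EDF writer requires an integer sampling rate",
                            call. = FALSE)
  x <- record$samples
  if (is.null(phys_max)) phys_max <- max(1, ceiling(max(abs(x)) * 1.001))
  dig_max <- 32767L
  n_rec <- ceiling(length(x) / fs)
  if (length(x) < n_rec * fs) x <- c(x, rep(0, n_rec * fs - length(x)))

  pad <- function(s, w) {
    s <- as.character(s)
    if (nchar(s) > w) s <- substr(s, 1L, w)
    formatC(s, width = -w)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad("0", 8), pad("synthetic PSG", 80), pad("sleepstager", 80),
    pad("01.01.00", 8), pad("00.00.00", 8), pad(256 * 2, 8), pad("", 44),
    pad(n_rec, 8), pad(1, 8), pad(1, 4),
    # signal header block (one signal)
    pad(record$channel, 16), pad("synthetic", 80), pad("uV", 8),
    pad(format(-phys_max), 8), pad(format(phys_max), 8),
    pad(-dig_max, 8), pad(dig_max, 8), pad("", 80), pad(fs, 8), pad("", 32))
  writeChar(hdr, con, eos = NULL)
  dig <- as.integer(round(pmin(pmax(x / phys_max, -1), 1) * dig_max))
  writeBin(dig, con, size = 2L, endian = "little")
  invisible(path)
}

#' Read a single channel from an EDF file
#'
#' Reads the EDF header, locates `channel` (or takes the first signal),
#' and returns the samples rescaled to physical units. A file whose size
#' is inconsistent with its header is rejected rather than silently
#' truncated.
#'
#' @param path EDF file path.
#' @param channel channel label to read; default first signal.
#' @return an [eeg_record()].
#' @export
read_edf <- function(path, channel = NULL) {
  if (!file.exists(path)) stop("EDF file not found: ", path, call. = FALSE)
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  version <- rd(8)
  if (!nzchar(version)) stop("not a valid EDF file: ", path, call. = FALSE)
  rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- suppressWarnings(as.integer(rd(8)))
  rd(44)
  n_rec <- suppressWarnings(as.integer(rd(8)))
  rec_dur <- suppressWarnings(as.numeric(rd(8)))
  ns <- suppressWarnings(as.integer(rd(4)))
  if (any(is.na(c(hdr_bytes, n_rec, rec_dur, ns))) || ns < 1L)
    stop("corrupt EDF header: ", path, call. = FALSE)
  fields <- function(w) vapply(seq_len(ns), function(i) rd(w), character(1))
  labels <- fields(16); fields(80); fields(8)
  phys_min <- as.numeric(fields(8)); phys_max <- as.numeric(fields(8))
  dig_min <- as.numeric(fields(8)); dig_max <- as.numeric(fields(8))
  fields(80)
  n_samp <- as.integer(fields(8)); fields(32)

  sig <- if (is.null(channel)) 1L else match(channel, labels)
  if (is.na(sig))
    stop("channel not found in EDF: ", channel,
         " (available: ", paste(labels, collapse = ", "), ")", call. = FALSE)

  expect_bytes <- hdr_bytes + as.double(n_rec) * sum(n_samp) * 2
  if (file.size(path) < expect_bytes)
    stop("truncated EDF file: expected ", expect_bytes, " bytes, found ",
         file.size(path), call. = FALSE)

  per_rec <- sum(n_samp)
  raw <- readBin(con, "integer", n = n_rec * per_rec, size = 2L,
                 signed = TRUE, endian = "little")
  offsets <- cumsum(c(0L, n_samp))[sig]
  idx <- as.vector(outer(offsets + seq_len(n_samp[sig]),
                         (seq_len(n_rec) - 1L) * per_rec, `+`))
  dig <- raw[idx]
  scale <- (phys_max[sig] - phys_min[sig]) / (dig_max[sig] - dig_min[sig])
  x <- (dig - dig_min[sig]) * scale + phys_min[sig]
  fs <- n_samp[sig] / rec_dur
  eeg_record(x, fs, labels[sig])
}

#' Write stage labels to CSV
#'
#' Columns `epoch_index` (0-based) and `stage_string`.
#'
#' @param labels stage labels (character/factor), one per 30-s epoch.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_stage_labels <- function(labels, path) {
  labels <- stage_factor(labels)
  df <- data.frame(epoch_index = seq_along(labels) - 1L,
                   stage_string = as.character(labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read stage labels from CSV
#'
#' @param path CSV with columns `epoch_index`, `stage_string`.
#' @return stage factor ordered by `epoch_index`.
#' @export
read_stage_labels <- function(path) {
  if (!file.exists(path)) stop("label file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("epoch_index", "stage_string")
  if (!all(need %in% names(df)))
    stop("label CSV must have columns epoch_index, stage_string",
         call. = FALSE)
  stage_factor(df$stage_string[order(df$epoch_index)])
}
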