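#' Continuous single-channel EEG record
#'
#' @param samples numeric vector in uV; must be finite.
#' @param fs sampling rate in Hz (> 0).
#' @param channel channel label, e.g. "C4-M1".
#' @return object of class `eeg_record`.
#' @export
eeg_record <- function(samples, fs, channel = "EEG") {
  if (!is.numeric(samples) || any(!is.finite(samples)))
    stop("samples must be finite numeric", call. = FALSE)
  stopifnot(is.numeric(fs), length(fs) == 1L, fs > 0)
  structure(list(samples = as.numeric(samples), fs = fs,
                 channel = as.character(channel)),
            class = "eeg_record")
}

#' @export
print.eeg_record <- function(x, ...) {
  cat(sprintf("<eeg_record> %s: %d samples @ %g Hz (%.1f s)\n",
              x$channel, length(x$samples), x$fs, length(x$samples) / x$fs))
  invisible(x)
}

#' Bandpass filter specification
#'
#' Zero-phase Butterworth bandpass. `order` is the order of the analogue
#' bandpass prototype (default 4, i.e. two poles per band edge); applied
#' forward-backward the effective attenuation is doubled and the group
#' delay is zero.
#'
#' @param low_hz,high_hz band edges in Hz (defaults 0.3 and 35).
#' @param order bandpass filter order (even, default 4).
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(low_hz = 0.3, high_hz = 35, order = 4L) {
  stopifnot(low_hz > 0, high_hz > low_hz, order >= 2, order %% 2 == 0)
  structure(list(low_hz = low_hz, high_hz = high_hz, order = as.integer(order),
                 mode = "zero-phase"),
            class = "filter_spec")
}

#' Resample a record to 256 Hz
#'
#' Polyphase rational resampling (alias-protected FIR), so that every input
#' translates to the canonical 7680 samples per 30-s epoch. Records already
#' at 256 Hz are returned unchanged.
#'
#' @param record an [eeg_record()].
#' @param target_fs target rate (default 256).
#' @return an [eeg_record()] at `target_fs`.
#' @export
resample_to_256 <- function(record, target_fs = 256) {
  stopifnot(inherits(record, "eeg_record"))
  if (record$fs == target_fs) return(record)
  frac <- ratio_approx(target_fs / record$fs)
  y <- signal::resample(record$samples, p = frac[1], q = frac[2])
  n_target <- round(length(record$samples) * target_fs / record$fs)
  if (length(y) > n_target) y <- y[seq_len(n_target)]
  if (length(y) < n_target) y <- c(y, rep(0, n_target - length(y)))
  eeg_record(y, target_fs, record$channel)
}

# Small continued-fraction rational approximation p/q of a ratio.
ratio_approx <- function(x, max_den = 1024L) {
  best <- c(1L, 1L); err <- Inf
  for (q in seq_len(max_den)) {
    p <- round(x * q)
    if (p < 1) next
    e <- abs(x - p / q)
    if (e < err - 1e-15) { best <- c(p, q); err <- e }
    if (err < 1e-12) break
  }
  as.integer(best)
}

#' Zero-phase bandpass filter
#'
#' Butterworth bandpass applied forward and backward (`signal::filtfilt`),
#' giving exactly zero group delay. Realized as a cascade of a high-pass
#' and a low-pass half-filter (order/2 poles each), which is numerically
#' robust for the very low 0.3 Hz edge at 256 Hz.
#'
#' @param record an [eeg_record()].
#' @param spec a [filter_spec()].
#' @return filtered [eeg_record()] of the same length.
#' @export
bandpass_zero_phase <- function(record, spec = filter_spec()) {
  stopifnot(inherits(record, "eeg_record"), inherits(spec, "filter_spec"))
  nyq <- record$fs / 2
  if (spec$high_hz >= nyq || spec$low_hz >= nyq)
    stop("band edges must be below the Nyquist frequency ", nyq, " Hz",
         call. = FALSE)
  half <- spec$order %/% 2L
  hp <- signal::butter(half, spec$low_hz / nyq, type = "high")
  lp <- signal::butter(half, spec$high_hz / nyq, type = "low")
  y <- signal::filtfilt(hp, record$samples)
  y <- signal::filtfilt(lp, y)
  eeg_record(y, record$fs, record$channel)
}

#' Segment a 256 Hz record into labelled 30-s epochs
#'
#' Cuts non-overlapping half-open spans `[i*7680, (i+1)*7680)` (0-based
#' sample coordinates). A trailing partial epoch is discarded with a
#' warning. Labels are attached by epoch index; by default epochs beyond
#' the label vector (or labels beyond the signal) are dropped with a
#' warning, or an error can be requested.
#'
#' @param record an [eeg_record()] at 256 Hz.
#' @param labels optional stage labels, one per epoch (character/factor).
#' @param on_mismatch "drop" (default) drops unmatched epochs/labels with a
#'   warning; "error" fails on any count mismatch.
#' @return object of class `epoch_dataset`: list with `epochs` (n x 7680
#'   matrix), `labels` (stage factor or NULL), `spans` (n x 2 matrix of
#'   0-based half-open sample spans), `class_counts`, `fs`.
#' @export
segment_epochs <- function(record, labels = NULL,
                           on_mismatch = c("drop", "error")) {
  stopifnot(inherits(record, "eeg_record"))
  on_mismatch <- match.arg(on_mismatch)
  if (record$fs != 256)
    stop("segment_epochs expects a 256 Hz record; resample first",
         call. = FALSE)
  epn <- 7680L
  n <- length(record$samples)
  n_ep <- n %/% epn
  if (n %% epn != 0L)
    warning(sprintf("discarding trailing partial epoch (%d samples)",
                    n %% epn))
  if (n_ep == 0L)
    return(epoch_dataset(matrix(numeric(0), 0L, epn), NULL,
                         matrix(integer(0), 0L, 2L)))
  ep <- matrix(record$samples[seq_len(n_ep * epn)], nrow = n_ep, ncol = epn,
               byrow = TRUE)
  spans <- cbind(start = (seq_len(n_ep) - 1L) * epn,
                 end = seq_len(n_ep) * epn)
  if (!is.null(labels)) {
    labels <- stage_factor(labels)
    if (length(labels) != n_ep) {
      if (on_mismatch == "error")
        stop(sprintf("label count (%d) does not match epoch count (%d)",
                     length(labels), n_ep), call. = FALSE)
      k <- min(length(labels), n_ep)
      warning(sprintf(
        "label/epoch count mismatch (%d labels, %d epochs); keeping first %d",
        length(labels), n_ep, k))
      labels <- labels[seq_len(k)]
      ep <- ep[seq_len(k), , drop = FALSE]
      spans <- spans[seq_len(k), , drop = FALSE]
    }
  }
  epoch_dataset(ep, labels, spans)
}

#' Epoch dataset container
#'
#' @param epochs n x 7680 numeric matrix, one 30-s epoch per row.
#' @param labels stage factor of length n, or NULL for unlabelled data.
#' @param spans n x 2 integer matrix of 0-based half-open source spans.
#' @return object of class `epoch_dataset`.
#' @export
epoch_dataset <- function(epochs, labels = NULL, spans = NULL) {
  epochs <- as.matrix(epochs)
  if (ncol(epochs) != 7680L && nrow(epochs) > 0L)
    stop("epochs must have 7680 columns (30 s at 256 Hz)", call. = FALSE)
  if (!is.null(labels)) {
    labels <- stage_factor(labels)
    if (length(labels) != nrow(epochs))
      stop("labels length must match epoch count", call. = FALSE)
  }
  if (is.null(spans))
    spans <- cbind(start = (seq_len(nrow(epochs)) - 1L) * 7680L,
                   end = seq_len(nrow(epochs)) * 7680L)
  cc <- if (is.null(labels)) integer(5) else as.integer(table(labels))
  names(cc) <- stage_levels()
  structure(list(epochs = epochs, labels = labels, spans = spans,
                 class_counts = cc, fs = 256),
            class = "epoch_dataset")
}

#' @export
print.epoch_dataset <- function(x, ...) {
  cat(sprintf("<epoch_dataset> %d epochs of 7680 samples @ 256 Hz\n",
              nrow(x$epochs)))
  if (!is.null(x$labels))
    cat("  class counts:",
        paste(sprintf("%s=%d", names(x$class_counts), x$class_counts),
              collapse = " "), "\n")
  invisible(x)
}

#' Number of epochs in a dataset
#' @param ds an `epoch_dataset`.
#' @return integer count.
#' @export
n_epochs <- function(ds) nrow(ds$epochs)

#' Subset an epoch dataset by row index
#' @param ds an `epoch_dataset`.
#' @param idx integer indices of epochs to keep.
#' @return `epoch_dataset` with the selected epochs.
#' @export
subset_epochs <- function(ds, idx) {
  epoch_dataset(ds$epochs[idx, , drop = FALSE],
                if (!is.null(ds$labels)) ds$labels[idx],
                ds$spans[idx, , drop = FALSE])
}

#' Write an epoch manifest CSV
#'
#' Columns: `epoch_index` (0-based), `start_sample`, `end_sample`
#' (half-open), `stage`.
#'
#' @param ds an `epoch_dataset`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_epoch_manifest <- function(ds, path) {
  df <- data.frame(epoch_index = seq_len(nrow(ds$epochs)) - 1L,
                   start_sample = ds$spans[, 1L],
                   end_sample = ds$spans[, 2L],
                   stage = if (is.null(ds$labels)) NA_character_
                           else as.character(ds$labels))
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
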