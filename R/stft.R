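#' FSST / STFT configuration
#'
#' Short-time Fourier analysis with a Gaussian window, the basis of the
#' Fourier synchrosqueezing transform. The window is
#' `g(t) = exp(-t^2 / (2 sigma_s^2))` with `sigma_s` in seconds; its
#' half-power frequency bandwidth is `Delta = sqrt(2*log(2)) / gamma_g`
#' (Hz) with `gamma_g = 2*pi*sigma_s`, and two signal components are
#' resolvable when separated by at least `d = 2*Delta`.
#'
#' @param window_length odd window length in samples (default 257, ~1 s at
#'   256 Hz).
#' @param hop frame hop in samples (default 32).
#' @param sigma_s Gaussian time-scale in seconds; default spans the window
#'   at +/- 3 sigma.
#' @param fs sampling rate in Hz.
#' @return object of class `fsst_config` with derived fields `gamma_g`,
#'   `bandwidth_hz` (Delta) and `separation_hz` (d).
#' @export
fsst_config <- function(window_length = 257L, hop = 32L, sigma_s = NULL,
                        fs = 256) {
  window_length <- as.integer(window_length)
  if (window_length %% 2L == 0L) stop("window_length must be odd",
                                      call. = FALSE)
  stopifnot(hop >= 1, fs > 0)
  if (is.null(sigma_s)) sigma_s <- window_length / (6 * fs)
  gamma_g <- 2 * pi * sigma_s
  half <- (window_length - 1L) %/% 2L
  tt <- (-half:half) / fs
  g <- exp(-0.5 * (tt / sigma_s)^2)
  dg <- -(tt / sigma_s^2) * g               # d/dt of the window, per second
  structure(list(window_length = window_length, hop = as.integer(hop),
                 sigma_s = sigma_s, gamma_g = gamma_g,
                 bandwidth_hz = sqrt(2 * log(2)) / gamma_g,
                 separation_hz = 2 * sqrt(2 * log(2)) / gamma_g,
                 fs = fs, window = g, dwindow = dg, g0 = 1),
            class = "fsst_config")
}

#' Short-time Fourier transform
#'
#' Frames the signal with the config's Gaussian window and returns the
#' one-sided complex STFT (window-centered phase convention). A second
#' grid computed with the window's time-derivative is attached for
#' instantaneous-frequency estimation.
#'
#' @param epoch numeric signal (a 30-s sleep epoch, or any vector longer
#'   than the window).
#' @param cfg an [fsst_config()].
#' @return object of class `stft_grid`: `V` (complex, freq x frames),
#'   `Vd` (derivative-window STFT), `freq` (Hz), `time` (s), `cfg`.
#' @export
stft <- function(epoch, cfg = fsst_config()) {
  n <- length(epoch)
  L <- cfg$window_length
  if (L >= n) stop("window longer than signal", call. = FALSE)
  hop <- cfg$hop
  half <- (L - 1L) %/% 2L
  n_frames <- (n - L) %/% hop + 1L
  starts <- (seq_len(n_frames) - 1L) * hop
  idx <- outer(seq_len(L), starts, `+`)     # L x n_frames
  X <- matrix(epoch[idx], nrow = L)
  nf <- (L + 1L) %/% 2L
  # window-centered phase: multiply bin b by exp(+2i*pi*(b-1)*half/L)
  phase <- exp(2i * pi * (seq_len(nf) - 1L) * half / L)
  V <- stats::mvfft(X * cfg$window)[seq_len(nf), , drop = FALSE] * phase
  Vd <- stats::mvfft(X * cfg$dwindow)[seq_len(nf), , drop = FALSE] * phase
  structure(list(V = V, Vd = Vd,
                 freq = (seq_len(nf) - 1L) * cfg$fs / L,
                 time = (starts + half) / cfg$fs,
                 cfg = cfg),
            class = "stft_grid")
}

#' Instantaneous-frequency map of an STFT grid
#'
#' The phase-derivative reassignment frequency
#' `omega_hat(eta, t) = Re[ d/dt V / (2i*pi*V) ]`, evaluated through the
#' derivative-window STFT as `eta - Im(V_dg / V) / (2*pi)`. Values are
#' defined only where `|V|` exceeds `threshold`; elsewhere the map is `NA`.
#'
#' @param grid an `stft_grid`.
#' @param threshold magnitude threshold; default `1e-6 * max(|V|)`.
#' @return list with `omega` (Hz, NA where masked) and logical `mask` of
#'   valid cells.
#' @export
inst_freq <- function(grid, threshold = NULL) {
  stopifnot(inherits(grid, "stft_grid"))
  absV <- Mod(grid$V)
  if (is.null(threshold)) threshold <- 1e-6 * max(absV)
  mask <- absV > threshold
  omega <- matrix(NA_real_, nrow(grid$V), ncol(grid$V))
  corr <- Im(grid$Vd[mask] / grid$V[mask]) / (2 * pi)
  omega[mask] <- grid$freq[row(grid$V)[mask]] - corr
  list(omega = omega, mask = mask)
}

#' Fourier synchrosqueezing transform
#'
#' Reassigns each STFT coefficient along the frequency axis only (time is
#' untouched, preserving causality) to the bin nearest its instantaneous
#' frequency, scaling by `1/g(0)`. Both the complex reassigned
#' coefficients and the reassigned energy mass (`|V|^2` moved to target
#' bins, exactly conserved per frame over the unmasked cells) are
#' returned.
#'
#' @param epoch numeric signal.
#' @param cfg an [fsst_config()].
#' @param threshold magnitude threshold passed to [inst_freq()].
#' @return object of class `fsst_grid`: `T` (complex), `energy`
#'   (reassigned `|V|^2` mass), `omega`, `freq`, `time`, `stft` (the
#'   underlying grid), `cfg`.
#' @export
fsst <- function(epoch, cfg = fsst_config(), threshold = NULL) {
  grid <- stft(epoch, cfg)
  iw <- inst_freq(grid, threshold)
  nf <- nrow(grid$V); m <- ncol(grid$V)
  dfreq <- cfg$fs / cfg$window_length
  Tm <- matrix(0 + 0i, nf, m)
  E <- matrix(0, nf, m)
  tgt <- round(iw$omega / dfreq) + 1L
  tgt[tgt < 1L] <- 1L
  tgt[tgt > nf] <- nf
  sel <- which(iw$mask)
  if (length(sel)) {
    flat <- (col(grid$V)[sel] - 1L) * nf + tgt[sel]
    vals <- grid$V[sel] / cfg$g0
    re <- rowsum(Re(vals), flat)
    im <- rowsum(Im(vals), flat)
    en <- rowsum(Mod(grid$V[sel])^2, flat)
    at <- as.integer(rownames(re))
    Tm[at] <- complex(real = re, imaginary = im)
    E[at] <- en
  }
  structure(list(T = Tm, energy = E, omega = iw$omega, mask = iw$mask,
                 freq = grid$freq, time = grid$time, stft = grid, cfg = cfg),
            class = "fsst_grid")
}
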