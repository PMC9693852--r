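#' Continuous wavelet transform configuration
#'
#' Analytic (generalized) Morse mother wavelet with symmetry parameter
#' `gamma` and decay parameter `beta` (time-bandwidth product
#' `gamma * beta`); defaults gamma = 3, beta = 20. Scales form a geometric
#' grid whose implied center frequencies cover `freq_range` at
#' `voices_per_octave` steps per octave.
#'
#' @param gamma Morse symmetry parameter (3 = the symmetric "Airy" family).
#' @param beta Morse decay parameter.
#' @param voices_per_octave scale resolution (default 12).
#' @param freq_range length-2 Hz range the scale grid must cover
#'   (default 0.3-35).
#' @param fs sampling rate in Hz.
#' @return object of class `cwt_config` with the scale grid (`scales`,
#'   ascending) and the corresponding center frequencies (`freqs`, Hz,
#'   descending).
#' @export
cwt_config <- function(gamma = 3, beta = 20, voices_per_octave = 12L,
                       freq_range = c(0.3, 35), fs = 256) {
  stopifnot(gamma > 0, beta > 0, voices_per_octave >= 1,
            freq_range[1] > 0, freq_range[2] > freq_range[1],
            freq_range[2] <= fs / 2)
  n_oct <- log2(freq_range[2] / freq_range[1])
  n_sc <- ceiling(n_oct * voices_per_octave) + 1L
  freqs <- freq_range[2] * 2^(-(seq_len(n_sc) - 1L) / voices_per_octave)
  omega_peak <- (beta / gamma)^(1 / gamma)  # rad/s peak of the Morse wavelet
  scales <- omega_peak / (2 * pi * freqs)   # ascending (freqs descending)
  structure(list(gamma = gamma, beta = beta,
                 voices_per_octave = as.integer(voices_per_octave),
                 freq_range = freq_range, fs = fs,
                 scales = scales, freqs = freqs, omega_peak = omega_peak),
            class = "cwt_config")
}

# Frequency-domain Morse filter bank for signals of length n:
# rows = scales, columns = DFT bins. L2 normalization (sqrt(s) * Psi(s w)).
cwt_filter_bank <- function(cfg, n) {
  omega <- 2 * pi * (seq_len(n) - 1L) / n * cfg$fs   # rad/s, DFT bin freqs
  pos <- omega <= pi * cfg$fs                        # analytic: positive freqs
  lg <- log(2) + (cfg$beta / cfg$gamma) * (1 + log(cfg$gamma / cfg$beta))
  bank <- matrix(0, length(cfg$scales), n)
  for (i in seq_along(cfg$scales)) {
    s <- cfg$scales[i]
    so <- s * omega[pos]
    amp <- exp(lg + cfg$beta * log(pmax(so, .Machine$double.xmin)) -
                 so^cfg$gamma)
    amp[so <= 0] <- 0
    bank[i, pos] <- sqrt(s) * amp
  }
  bank
}

#' Continuous wavelet transform with an analytic Morse wavelet
#'
#' FFT-based implementation: the signal spectrum is multiplied by the
#' scaled wavelet's frequency response at each scale (circular boundary).
#' Coefficients are complex; the transform is linear in the input.
#'
#' @param epoch numeric signal.
#' @param cfg a [cwt_config()].
#' @param bank optional precomputed filter bank (from repeated batch use).
#' @param decimate integer time-decimation factor (must divide the signal
#'   length). The returned columns are the *exact* CWT samples at every
#'   `decimate`-th time point, computed by alias-folding the spectrum
#'   before the inverse FFT; used by the batch imaging path, where the
#'   rendered image cannot resolve the full time grid anyway.
#' @return object of class `cwt_grid`: `W` (complex, scales x time),
#'   `scales`, `freq` (center frequencies, Hz), `time` (s), `cfg`.
#' @export
cwt_morse <- function(epoch, cfg = cwt_config(), bank = NULL, decimate = 1L) {
  n <- length(epoch)
  if (cfg$freq_range[2] > cfg$fs / 2)
    stop("scale grid does not cover the requested band at this sampling rate",
         call. = FALSE)
  decimate <- as.integer(decimate)
  if (decimate < 1L || n %% decimate != 0L)
    stop("decimate must be a positive divisor of the signal length",
         call. = FALSE)
  if (is.null(bank)) bank <- cwt_filter_bank(cfg, n)
  yhat <- fft(epoch)
  prod <- t(bank) * yhat                       # n x n_scales
  if (decimate > 1L) {
    m <- n %/% decimate
    dim(prod) <- c(m, decimate, length(cfg$scales))
    folded <- colSums(aperm(prod, c(2L, 1L, 3L)))  # m x n_scales
    W <- t(stats::mvfft(folded, inverse = TRUE)) / n
    tax <- (seq_len(m) - 1L) * decimate / cfg$fs + 1 / cfg$fs
  } else {
    W <- t(stats::mvfft(prod, inverse = TRUE)) / n
    tax <- seq_len(n) / cfg$fs
  }
  structure(list(W = W, scales = cfg$scales, freq = cfg$freqs,
                 time = tax, cfg = cfg),
            class = "cwt_grid")
}
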