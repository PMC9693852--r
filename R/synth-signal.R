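#' Stage-conditional signal parameters
#'
#' Parameters of the synthetic EEG model. Each stage has a dominant
#' oscillation band and a peak-to-peak amplitude range (uV), following
#' textbook AASM stage descriptions: W alpha (8-12 Hz), N1 theta (4-7 Hz),
#' N2 theta with 11-16 Hz spindle bursts and K-complex transients, N3
#' high-amplitude delta (0.5-2 Hz), REM low-amplitude mixed activity with
#' 2-4 Hz sawtooth trains. A 1/f background noise floor sits `noise_rel_db`
#' below the stage rhythm. All waveform-level parameters are
#' artifact-defined: the clinical study this pipeline is designed around
#' gives no signal-level model of the stages.
#'
#' @param bands named list of length-2 numeric band edges (Hz) per stage.
#' @param amp_pp named list of length-2 peak-to-peak amplitude ranges (uV).
#' @param spindle_band,spindle_amp_pp,spindle_rate spindle frequency band,
#'   amplitude range and expected events per N2 epoch.
#' @param kcomplex_amp_pp,kcomplex_rate K-complex peak-to-peak range and
#'   expected events per N2 epoch.
#' @param noise_exponent exponent of the 1/f^a background noise.
#' @param noise_rel_db background level relative to the rhythm (dB).
#' @param seed integer seed.
#' @return object of class `stage_signal_params`.
#' @export
stage_signal_params <- function(
    bands = list(W = c(8, 12), N1 = c(4, 7), N2 = c(4, 7),
                 N3 = c(0.5, 2), REM = c(2, 4)),
    amp_pp = list(W = c(10, 40), N1 = c(10, 40), N2 = c(20, 60),
                  N3 = c(75, 150), REM = c(10, 40)),
    spindle_band = c(11, 16), spindle_amp_pp = c(20, 40), spindle_rate = 3,
    kcomplex_amp_pp = c(75, 150), kcomplex_rate = 1,
    noise_exponent = 1, noise_rel_db = -10, seed = 1L) {
  for (b in c(bands, list(spindle_band)))
    if (b[1] < 0.3 || b[2] > 35 || b[1] >= b[2])
      stop("band edges must lie inside [0.3, 35] Hz", call. = FALSE)
  stopifnot(all(unlist(amp_pp) > 0), spindle_rate >= 0, kcomplex_rate >= 0,
            all(spindle_amp_pp > 0), all(kcomplex_amp_pp > 0))
  structure(list(bands = bands, amp_pp = amp_pp,
                 spindle_band = spindle_band, spindle_amp_pp = spindle_amp_pp,
                 spindle_rate = spindle_rate,
                 kcomplex_amp_pp = kcomplex_amp_pp, kcomplex_rate = kcomplex_rate,
                 noise_exponent = noise_exponent, noise_rel_db = noise_rel_db,
                 seed = as.integer(seed)),
            class = "stage_signal_params")
}

# Narrowband oscillation with slow AM and FM drift inside `band`.
rhythm_wave <- function(n, fs, band, amp_pp) {
  t <- seq_len(n) / fs
  f0 <- runif(1, band[1], band[2])
  fm_dev <- min(0.1 * diff(band), f0 - band[1], band[2] - f0)
  fm_rate <- runif(1, 0.05, 0.2)
  finst <- f0 + fm_dev * sin(2 * pi * fm_rate * t + runif(1, 0, 2 * pi))
  phase <- 2 * pi * cumsum(finst) / fs
  amp <- runif(1, amp_pp[1], amp_pp[2]) / 2
  am <- 1 + 0.3 * sin(2 * pi * runif(1, 0.1, 0.4) * t + runif(1, 0, 2 * pi))
  amp * am * sin(phase + runif(1, 0, 2 * pi))
}

# 1/f^a background noise, scaled to a target RMS.
pink_noise <- function(n, fs, exponent, rms) {
  w <- rnorm(n)
  wf <- fft(w)
  f <- c(0, seq_len(n - 1)) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]        # mirror for negative freqs
  shape <- c(0, f[-1]^(-exponent / 2))
  x <- Re(fft(wf * shape, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Gaussian-windowed oscillatory burst added in place at a random onset.
add_burst <- function(x, fs, band, amp_pp, dur_range) {
  n <- length(x)
  dur <- runif(1, dur_range[1], dur_range[2])
  m <- max(8L, round(dur * fs))
  if (m >= n) m <- n %/% 2L
  start <- sample.int(n - m, 1L)
  tt <- (seq_len(m) - m / 2) / fs
  env <- exp(-0.5 * (tt / (dur / 6))^2)
  f0 <- runif(1, band[1], band[2])
  amp <- runif(1, amp_pp[1], amp_pp[2]) / 2
  x[start:(start + m - 1L)] <- x[start:(start + m - 1L)] +
    amp * env * sin(2 * pi * f0 * tt + runif(1, 0, 2 * pi))
  x
}

# Biphasic K-complex transient (first derivative of a Gaussian).
add_kcomplex <- function(x, fs, amp_pp) {
  n <- length(x)
  dur <- runif(1, 0.5, 0.8)
  m <- round(dur * fs)
  start <- sample.int(n - m, 1L)
  tt <- (seq_len(m) - m / 2) / fs
  s <- dur / 7
  shape <- -tt * exp(-0.5 * (tt / s)^2)
  shape <- shape / (max(shape) - min(shape))
  x[start:(start + m - 1L)] <- x[start:(start + m - 1L)] +
    runif(1, amp_pp[1], amp_pp[2]) * shape
  x
}

# White noise band-limited to `band`, scaled to a target RMS.
band_noise <- function(n, fs, band, rms) {
  wf <- fft(rnorm(n))
  f <- (seq_len(n) - 1L) * fs / n
  f[f > fs / 2] <- fs - f[f > fs / 2]
  mask <- as.numeric(f >= band[1] & f <= band[2])
  x <- Re(fft(wf * mask, inverse = TRUE)) / n
  x * rms / stats::sd(x)
}

# Band-limited sawtooth train bursts (fundamental f0, harmonics to 35 Hz).
sawtooth_trains <- function(n, fs, band, amp_pp, n_trains) {
  x <- numeric(n)
  for (k in seq_len(n_trains)) {
    f0 <- runif(1, band[1], band[2])
    dur <- runif(1, 2.5, 4)
    m <- round(dur * fs)
    if (m >= n) m <- n %/% 2L
    start <- sample.int(n - m, 1L)
    tt <- seq_len(m) / fs
    nh <- max(1L, floor(35 / f0))
    s <- numeric(m)
    for (h in seq_len(nh))
      s <- s + ((-1)^(h + 1)) * sin(2 * pi * h * f0 * tt) / h
    s <- s / stats::sd(s)                    # unit-RMS train
    env <- sin(pi * seq_len(m) / m)^2       # smooth on/off ramp
    amp <- runif(1, amp_pp[1], amp_pp[2]) / 2
    x[start:(start + m - 1L)] <- x[start:(start + m - 1L)] + amp * env * s
  }
  x
}

#' Synthesize one 30-s epoch of stage-conditional EEG
#'
#' @param stage a single stage label (character or factor).
#' @param fs sampling rate in Hz (>= 128).
#' @param params a [stage_signal_params()].
#' @param seed integer seed; the waveform is a deterministic function of
#'   `(stage, fs, params, seed)`.
#' @return numeric vector of length `30 * fs` (uV).
#' @export
synth_stage_epoch <- function(stage, fs = 256, params = stage_signal_params(),
                              seed = params$seed) {
  stage <- as.character(stage_factor(as.character(stage)))
  if (is.na(stage)) stop("unknown stage", call. = FALSE)
  stopifnot(fs >= 128)
  n <- round(30 * fs)
  with_seed(seed, {
    band <- params$bands[[stage]]
    amp <- params$amp_pp[[stage]]
    x <- switch(stage,
      W  = rhythm_wave(n, fs, band, amp),
      N1 = rhythm_wave(n, fs, band, amp),
      N2 = {
        y <- rhythm_wave(n, fs, band, amp)
        for (k in seq_len(rpois(1, params$spindle_rate)))
          y <- add_burst(y, fs, params$spindle_band, params$spindle_amp_pp,
                         c(0.5, 1.5))
        for (k in seq_len(rpois(1, params$kcomplex_rate)))
          y <- add_kcomplex(y, fs, params$kcomplex_amp_pp)
        # occasional sub-threshold slow waves: real N2 carries some
        # delta activity (< 20% of the epoch), making the N2/N3
        # boundary a continuum rather than a clean separation
        for (k in seq_len(rpois(1, 1)))
          y <- add_burst(y, fs, c(0.75, 2), c(30, 60), c(0.8, 1.4))
        y
      },
      N3 = rhythm_wave(n, fs, band, amp),
      REM = {
        # one amplitude draw per epoch keeps the sawtooth trains dominant
        # over the low-amplitude mixed-frequency background
        app <- runif(1, amp[1], amp[2])
        saw <- sawtooth_trains(n, fs, band, c(app, app),
                               n_trains = sample(6:8, 1L))
        saw + band_noise(n, fs, c(5, 11), rms = 0.08 * app)
      })
    rhythm_rms <- stats::sd(x)
    noise_rms <- rhythm_rms * 10^(params$noise_rel_db / 20)
    x + pink_noise(n, fs, params$noise_exponent, noise_rms)
  })
}

#' Synthesize a full polysomnography recording
#'
#' Simulates a hypnogram from `hyp_spec` and concatenates per-epoch
#' stage-conditional waveforms. Per-epoch seeds are derived from the
#' hypnogram seed, so the whole recording is reproducible from its specs.
#'
#' @param hyp_spec a [hypnogram_spec()].
#' @param sig_params a [stage_signal_params()].
#' @param fs sampling rate in Hz.
#' @param channel channel label stored on the record.
#' @return object of class `synthetic_recording`: list with `record`
#'   (an [eeg_record()]), `hypnogram` (stage factor), and the two specs.
#' @export
synth_recording <- function(hyp_spec, sig_params = stage_signal_params(),
                            fs = 256, channel = "C4-M1") {
  hyp <- simulate_hypnogram(hyp_spec)
  n_ep <- length(hyp)
  samples <- numeric(n_ep * 30 * fs)
  for (i in seq_len(n_ep)) {
    ep_seed <- substream_seed(hyp_spec$seed, "epoch-signal", i)
    idx <- ((i - 1L) * 30 * fs + 1L):(i * 30 * fs)
    samples[idx] <- synth_stage_epoch(hyp[i], fs, sig_params, seed = ep_seed)
  }
  structure(list(record = eeg_record(samples, fs, channel),
                 hypnogram = hyp,
                 hyp_spec = hyp_spec, sig_params = sig_params),
            class = "synthetic_recording")
}
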