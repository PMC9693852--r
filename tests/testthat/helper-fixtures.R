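# Shared fixtures for the test suite. Everything is generated in code.

FS <- 256
EPOCH_N <- 7680L

tone <- function(freq, n = EPOCH_N, fs = FS, amp = 1, phase = 0) {
  amp * sin(2 * pi * freq * seq_len(n) / fs + phase)
}

# Periodogram band power (Welch-free, direct FFT), used as an
# independent spectral oracle.
band_power <- function(x, band, fs = FS) {
  n <- length(x)
  p <- Mod(fft(x))[seq_len(n %/% 2)]^2
  f <- (seq_len(n %/% 2) - 1) * fs / n
  sum(p[f >= band[1] & f <= band[2]])
}

periodogram_peak <- function(x, fs = FS) {
  n <- length(x)
  p <- Mod(fft(x))[2:(n %/% 2)]^2
  f <- (2:(n %/% 2) - 1) * fs / n
  f[which.max(p)]
}

# Tiny labelled image set with controllable class counts; images are
# CWT renders of per-class pure tones (trivially separable classes).
tone_image_set <- function(counts, freqs = c(10, 1, 6, 2.5, 14),
                           seed = 1) {
  stopifnot(length(counts) == 5L)
  labels <- rep(stage_levels(), counts)
  cfg <- cwt_config()
  bank <- sleepstager:::cwt_filter_bank(cfg, EPOCH_N)
  set.seed(seed)
  imgs <- t(vapply(seq_along(labels), function(i) {
    f0 <- freqs[match(labels[i], stage_levels())]
    x <- tone(f0, phase = runif(1, 0, 2 * pi)) + rnorm(EPOCH_N, sd = 0.05)
    g <- cwt_morse(x, cfg, bank = bank, decimate = 30L)
    as.vector(render_tf_image(g, render_config(channels = 1L))[, , 1L])
  }, numeric(224 * 224)))
  structure(list(images = imgs, labels = stage_factor(labels),
                 size = 224L, method = "cwt"),
            class = "tf_image_set")
}

# Naive per-element LSTM step (scalar loops), the independent oracle for
# the vectorized recurrence.
lstm_step_naive <- function(x, h_prev, c_prev, p) {
  H <- p$hidden_size; D <- p$input_size
  sig <- function(z) 1 / (1 + exp(-z))
  h <- numeric(H); cc <- numeric(H)
  for (j in seq_len(H)) {
    af <- p$bf[j]; ai <- p$bi[j]; ao <- p$bo[j]; ag <- p$bc[j]
    for (d in seq_len(D)) {
      af <- af + p$Wf[j, d] * x[d]; ai <- ai + p$Wi[j, d] * x[d]
      ao <- ao + p$Wo[j, d] * x[d]; ag <- ag + p$Wc[j, d] * x[d]
    }
    for (k in seq_len(H)) {
      af <- af + p$Uf[j, k] * h_prev[k]; ai <- ai + p$Ui[j, k] * h_prev[k]
      ao <- ao + p$Uo[j, k] * h_prev[k]; ag <- ag + p$Uc[j, k] * h_prev[k]
    }
    cc[j] <- sig(af) * c_prev[j] + sig(ai) * tanh(ag)
    h[j] <- sig(ao) * tanh(cc[j])
  }
  list(h = h, c = cc)
}
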