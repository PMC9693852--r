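test_that("STFT obeys linearity, tone localization and Parseval", {
  cfg <- fsst_config()
  z <- stft(rep(0, EPOCH_N), cfg)
  expect_true(all(Mod(z$V) == 0))

  g <- stft(tone(10), cfg)
  target_bin <- which.min(abs(g$freq - 10))
  expect_true(all(apply(Mod(g$V), 2, which.max) == target_bin))

  # Parseval: two-sided per-frame energy equals windowed-frame energy * L
  x <- rnorm(EPOCH_N)
  gx <- stft(x, cfg)
  L <- cfg$window_length
  half <- (L - 1L) %/% 2L
  m <- 10L                       # arbitrary interior frame
  start <- (m - 1L) * cfg$hop
  frame <- x[(start + 1L):(start + L)] * cfg$window
  two_sided <- 2 * sum(Mod(gx$V[-1L, m])^2) + Mod(gx$V[1L, m])^2
  expect_equal(two_sided, L * sum(frame^2), tolerance = 1e-2)

  expect_error(stft(rep(0, 100), cfg), "window longer")
})

test_that("instantaneous frequency tracks tones and chirps", {
  cfg <- fsst_config()
  g <- stft(tone(10), cfg)
  iw <- inst_freq(g)
  ridge <- which.min(abs(g$freq - 10))
  near <- (ridge - 1L):(ridge + 1L)
  vals <- iw$omega[near, ]
  expect_lt(max(abs(vals[!is.na(vals)] - 10)), 0.2)

  # linear chirp 2 -> 20 Hz over 30 s
  t <- seq_len(EPOCH_N) / FS
  y <- sin(2 * pi * (2 * t + (18 / 60) * t^2))
  gy <- stft(y, cfg)
  iwy <- inst_freq(gy)
  truef <- 2 + 18 * gy$time / 30
  interior <- 20:(length(gy$time) - 20L)
  err <- vapply(interior, function(m) {
    i <- which.max(Mod(gy$V[, m]))
    iwy$omega[i, m] - truef[m]
  }, numeric(1))
  expect_lt(sqrt(mean(err^2)), 0.5)

  # masked cells carry no numeric output
  z <- stft(c(rep(0, 4000), tone(8, n = 3680)), cfg)
  iz <- inst_freq(z)
  expect_true(all(is.na(iz$omega[!iz$mask])))
  expect_true(any(!iz$mask))
})

test_that("FSST concentrates energy on well-separated ridges", {
  cfg <- fsst_config()
  f <- fsst(tone(5) + tone(15), cfg)
  dfr <- FS / cfg$window_length
  rows <- which(abs(f$freq - 5) <= 2 * dfr + 1e-9 |
                  abs(f$freq - 15) <= 2 * dfr + 1e-9)
  expect_gt(sum(f$energy[rows, ]) / sum(f$energy), 0.90)

  zz <- fsst(rep(0, EPOCH_N), cfg)
  expect_true(all(Mod(zz$T) == 0) && all(zz$energy == 0))
})

test_that("FSST conserves per-frame energy over unmasked cells", {
  cfg <- fsst_config()
  for (s in 1:5) {
    set.seed(s)
    f <- fsst(rnorm(EPOCH_N), cfg)
    v2 <- Mod(f$stft$V)^2
    v2[!f$mask] <- 0
    rel <- abs(colSums(f$energy) - colSums(v2)) / pmax(colSums(v2), 1e-30)
    expect_lt(max(rel), 1e-6)
  }
})

test_that("FSST sharpens spectral entropy of AM-FM modes", {
  cfg <- fsst_config()
  entropy <- function(E) {
    p <- E / sum(E); p <- p[p > 0]; -sum(p * log(p))
  }
  t <- seq_len(EPOCH_N) / FS
  d <- cfg$separation_hz
  for (s in 1:50) {
    set.seed(s)
    # two AM-FM components separated by more than d = 2*Delta
    f1 <- runif(1, 3, 8)
    f2 <- f1 + d + runif(1, 1, 5)
    am1 <- 1 + runif(1, 0.1, 0.3) * sin(2 * pi * runif(1, 0.05, 0.2) * t)
    am2 <- 1 + runif(1, 0.1, 0.3) * sin(2 * pi * runif(1, 0.05, 0.2) * t)
    fm <- 0.3 * sin(2 * pi * 0.1 * t) / (2 * pi * 0.1)
    y <- am1 * sin(2 * pi * (f1 * t + fm)) + am2 * sin(2 * pi * f2 * t)
    fy <- fsst(y, cfg)
    expect_lt(entropy(fy$energy), entropy(Mod(fy$stft$V)^2))
  }
})

test_that("CWT maps tones to the correct scale within one voice", {
  cfg <- cwt_config()
  bank <- sleepstager:::cwt_filter_bank(cfg, EPOCH_N)
  for (f0 in c(1, 4, 10, 20, 34)) {
    w <- cwt_morse(tone(f0), cfg, bank = bank)
    i <- which.max(rowMeans(Mod(w$W)))
    expect_lt(abs(log2(w$freq[i] / f0)) * cfg$voices_per_octave, 1)
  }
  expect_error(cwt_config(freq_range = c(0.3, 200)), "fs/2")
})

test_that("CWT is linear and translation-covariant", {
  cfg <- cwt_config()
  bank <- sleepstager:::cwt_filter_bank(cfg, EPOCH_N)
  set.seed(8)
  y <- rnorm(EPOCH_N)
  w1 <- cwt_morse(y, cfg, bank = bank)
  w3 <- cwt_morse(3 * y, cfg, bank = bank)
  expect_lt(max(Mod(w3$W - 3 * w1$W)), 1e-10 * max(Mod(w1$W)))

  # time shift by m samples shifts coefficients by m columns; interior
  # columns away from the wrap-around edges agree
  m <- 700L
  yl <- c(rep(0, m), y[seq_len(EPOCH_N - m)])
  wl <- cwt_morse(yl, cfg, bank = bank)
  hi <- which(w1$freq >= 2)          # rows whose wavelet support is short
  interior <- 2500:5000
  dev <- Mod(wl$W[hi, interior + m] - w1$W[hi, interior])
  expect_lt(max(dev), 1e-6 * max(Mod(w1$W)))
})

test_that("decimated CWT returns exact samples of the full transform", {
  cfg <- cwt_config()
  bank <- sleepstager:::cwt_filter_bank(cfg, EPOCH_N)
  y <- tone(6) + 0.5 * tone(13)
  full <- cwt_morse(y, cfg, bank = bank)
  dec <- cwt_morse(y, cfg, bank = bank, decimate = 30L)
  expect_lt(max(Mod(dec$W - full$W[, seq(1, EPOCH_N, by = 30)])), 1e-12)
  expect_error(cwt_morse(y, cfg, bank = bank, decimate = 7L), "divisor")
})

test_that("rendering yields bounded, monotone, reproducible images", {
  w <- cwt_morse(synth_stage_epoch("N2", seed = 2), cwt_config())
  img <- render_tf_image(w)
  expect_identical(dim(img), c(224L, 224L, 3L))
  expect_true(all(img >= 0 & img <= 1))
  expect_identical(img, render_tf_image(w))

  expect_warning(z <- render_tf_image(matrix(1, 50, 60)), "all-constant")
  expect_true(all(z == 0))

  # ordering preserved: largest magnitude cell maps to brightest region
  toy <- matrix(c(0.1, 0.9, 0.4, 0.2), 2, 2)
  r <- render_tf_image(toy, render_config(size = 4L, channels = 1L))
  # output row 4 / col 1 samples input cell [2, 1], the 4-cell maximum
  expect_equal(as.vector(r[4, 1, 1]), 1)
  expect_equal(max(r), r[4, 1, 1])
  expect_lt(max(r[1:2, 3:4, 1]), r[4, 1, 1])  # smallest corner stays dim

  # idempotence: min-max of already-[0,1] data with identity resize
  flat <- matrix(runif(16), 4, 4)
  flat[1, 1] <- 0; flat[4, 4] <- 1
  cfgr <- render_config(size = 4L, channels = 1L, log_compress = FALSE)
  once <- render_tf_image(flat, cfgr)
  twice <- render_tf_image(once[, , 1L], cfgr)
  expect_equal(once, twice, tolerance = 1e-12)
})

test_that("batch imaging produces labelled image rows in [0,1]", {
  rec <- synth_recording(hypnogram_spec(5, seed = 21))
  ds <- segment_epochs(rec$record, rec$hypnogram)
  set <- epochs_to_images(ds, "cwt")
  expect_identical(dim(set$images), c(5L, 224L * 224L))
  expect_true(all(set$images >= 0 & set$images <= 1))
  expect_identical(set$labels, rec$hypnogram)
  setf <- epochs_to_images(subset_epochs(ds, 1:2), "fsst")
  expect_identical(dim(setf$images), c(2L, 224L * 224L))
})
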