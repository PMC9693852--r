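test_that("lstm_step matches hand-computed and degenerate cases", {
  # all-zero parameters: gates are 0.5 but tanh(0) = 0, so state stays 0
  p0 <- lstm_params(3, 2, "zero")
  s <- lstm_step(c(1, -2, 0.5), NULL, p0)
  expect_equal(s$h, c(0, 0))
  expect_equal(s$c, c(0, 0))

  # H = 1, D = 1 hand case: open gates, pure candidate write
  p1 <- lstm_params(1, 1, "zero")
  p1$bi <- p1$bf <- p1$bo <- 10
  p1$Wc <- matrix(1, 1, 1)
  s1 <- lstm_step(0.5, NULL, p1)
  g <- 1 / (1 + exp(-10))
  expect_equal(s1$c, g * tanh(0.5), tolerance = 1e-12)
  expect_equal(s1$h, g * tanh(g * tanh(0.5)), tolerance = 1e-12)
  # at gate saturation this is approximately tanh(0.5) / tanh(tanh(0.5))
  expect_equal(s1$c, tanh(0.5), tolerance = 1e-4)
  expect_equal(s1$h, tanh(tanh(0.5)), tolerance = 1e-4)

  expect_error(lstm_step(c(1, 2), NULL, p0), "input size mismatch")
})

test_that("lstm_step equals the naive elementwise oracle", {
  set.seed(3)
  for (rep in seq_len(100)) {
    p <- lstm_params(2, 3, "uniform", seed = rep)
    x <- rnorm(2); h0 <- rnorm(3); c0 <- rnorm(3)
    fast <- lstm_step(x, list(h = h0, c = c0), p)
    slow <- lstm_step_naive(x, h0, c0, p)
    expect_equal(fast$h, slow$h, tolerance = 1e-12)
    expect_equal(fast$c, slow$c, tolerance = 1e-12)
  }
})

test_that("bilstm concatenates causal and anticausal passes", {
  fwd <- lstm_params(4, 3, "uniform", 1)
  bwd <- lstm_params(4, 3, "uniform", 2)
  X <- matrix(rnorm(5 * 4), 5, 4)

  out <- bilstm_forward(X, fwd, bwd)
  expect_identical(dim(out), c(5L, 6L))

  # zero parameters give zero outputs of width 2H
  z <- bilstm_forward(X, lstm_params(4, 3), lstm_params(4, 3))
  expect_true(all(z == 0))

  # reversing time and swapping directions reverses and half-swaps output
  rev_out <- bilstm_forward(X[5:1, ], bwd, fwd)
  expect_equal(out, rev_out[5:1, c(4:6, 1:3)], tolerance = 1e-12)

  # length-1 sequence reduces to two single steps
  x1 <- X[1, , drop = FALSE]
  o1 <- bilstm_forward(x1, fwd, bwd)
  sf <- lstm_step(X[1, ], NULL, fwd)
  sb <- lstm_step(X[1, ], NULL, bwd)
  expect_equal(as.vector(o1), c(sf$h, sb$h), tolerance = 1e-12)

  expect_error(bilstm_forward(list(), fwd, bwd), "empty")
})

test_that("feature_sequence unfolds columns and round-trips", {
  fmap <- array(rnorm(7 * 7 * 64), c(7, 7, 64))
  sq <- feature_sequence(fmap)
  expect_identical(dim(sq), c(7L, 7L * 64L))

  onehot <- array(0, c(3, 5, 2))
  onehot[2, 4, 1] <- 1
  so <- feature_sequence(onehot)
  expect_identical(which(rowSums(so != 0) > 0), 4L)

  # reassembling columns reproduces the feature map
  back <- array(0, dim(fmap))
  for (t in seq_len(7)) back[, t, ] <- array(sq[t, ], c(7, 64))
  expect_identical(back, fmap)
})

test_that("both classifier variants emit normalized, deterministic probs", {
  set.seed(5)
  imgs <- matrix(runif(4 * 224 * 224), 4)
  for (v in c("cnn", "cnn_rnn")) {
    m <- build_sleepnet(sleepnet_config(variant = v, seed = 11))
    p1 <- predict(m, imgs)
    expect_identical(dim(p1), c(4L, 5L))
    expect_equal(rowSums(p1), rep(1, 4), tolerance = 1e-6)
    expect_identical(p1, predict(m, imgs))
  }
})

test_that("compact backbone yields a sequence axis of width >= 4", {
  m <- build_sleepnet(sleepnet_config(seed = 2))
  fw <- sleepstager:::sleepnet_forward(m, matrix(runif(224 * 224), 1))
  d <- fw$cache$fmap_dim
  expect_identical(d[1:3], sleepstager::backbone_spec()$out_shape)
  expect_gte(d[2], 4L)
})

test_that("softmax is invariant to constant logit shifts", {
  z <- matrix(rnorm(15), 3, 5)
  expect_equal(sleepstager:::softmax_rows(z),
               sleepstager:::softmax_rows(z + 100), tolerance = 1e-12)
})

test_that("pretrained adapter without weights errors toward compact", {
  expect_error(backbone_spec("pretrained-adapter"), "compact")
})

test_that("frozen backbone leaves conv weights untouched by training", {
  set.seed(6)
  imgs <- structure(list(images = matrix(runif(20 * 224 * 224), 20),
                         labels = stage_factor(rep(stage_levels(), 4)),
                         size = 224L, method = "cwt"),
                    class = "tf_image_set")
  m <- build_sleepnet(sleepnet_config(variant = "cnn", seed = 3,
                                      freeze_backbone = TRUE))
  conv_before <- m$params$conv
  fit <- train_sleepnet(m, imgs,
                        train_config(max_epochs = 1, batch_size = 10,
                                     seed = 4))
  expect_identical(fit$model$params$conv, conv_before)
  expect_false(identical(fit$model$params$fc, m$params$fc))
})

test_that("checkpoints round-trip weights and reject corruption", {
  m <- build_sleepnet(sleepnet_config(variant = "cnn", seed = 9))
  p <- tempfile(fileext = ".ckpt")
  save_sleepnet(m, p)
  m2 <- load_sleepnet(p)
  expect_equal(weights_hash(m2), weights_hash(m))
  imgs <- matrix(runif(2 * 224 * 224), 2)
  expect_identical(predict(m, imgs), predict(m2, imgs))
  saveRDS(list(format = "other"), p)
  expect_error(load_sleepnet(p), "checkpoint")
  unlink(p)
})

test_that("analytic gradients agree with finite differences", {
  set.seed(12)
  cfg <- sleepnet_config(variant = "cnn_rnn", dropout_cnn = 0,
                         dropout_rnn = 0, hidden_sizes = c(6L, 6L),
                         seed = 13)
  model <- build_sleepnet(cfg)
  imgs <- matrix(runif(2 * 224 * 224), 2)
  y <- c(2L, 5L)
  lossfn <- function(m) {
    f <- sleepstager:::sleepnet_forward(m, imgs, train = FALSE)
    -mean(log(f$probs[cbind(1:2, y)]))
  }
  fw <- sleepstager:::sleepnet_forward(model, imgs, train = TRUE)
  gr <- sleepstager:::sleepnet_backward(model, fw, y)
  eps <- 1e-6
  spots <- list(
    list(get = function(m) m$params$conv[[1]]$W[2, 30],
         set = function(m, v) { m$params$conv[[1]]$W[2, 30] <- v; m },
         g = gr$conv[[1]]$W[2, 30]),
    list(get = function(m) m$params$rnn$l2f$Wc[3, 7],
         set = function(m, v) { m$params$rnn$l2f$Wc[3, 7] <- v; m },
         g = gr$rnn$l2f$Wc[3, 7]),
    list(get = function(m) m$params$fc$W[4, 2],
         set = function(m, v) { m$params$fc$W[4, 2] <- v; m },
         g = gr$fc$W[4, 2]))
  for (sp in spots) {
    v0 <- sp$get(model)
    lp <- lossfn(sp$set(model, v0 + eps))
    lm <- lossfn(sp$set(model, v0 - eps))
    num <- (lp - lm) / (2 * eps)
    expect_equal(sp$g, num, tolerance = 1e-4)
  }
})
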