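fake_image_set <- function(labels, ncol = 16L, seed = 1) {
  set.seed(seed)
  structure(list(images = matrix(runif(length(labels) * ncol),
                                 length(labels)),
                 labels = stage_factor(labels), size = as.integer(sqrt(ncol)),
                 method = "cwt"),
            class = "tf_image_set")
}

test_that("train/test split is disjoint, exhaustive and sized correctly", {
  labs <- sample(rep(stage_levels(), c(300, 150, 400, 70, 80)))
  x <- fake_image_set(labs)
  sp <- split_train_test(x, split_spec(stratified = FALSE, seed = 3))
  expect_length(sp$train_idx, 900L)
  expect_length(sp$test_idx, 100L)
  expect_length(intersect(sp$train_idx, sp$test_idx), 0L)
  expect_setequal(c(sp$train_idx, sp$test_idx), seq_len(1000))

  sp2 <- split_train_test(x, split_spec(stratified = FALSE, seed = 3))
  expect_identical(sp$train_idx, sp2$train_idx)

  st <- split_train_test(x, split_spec(stratified = TRUE, seed = 3))
  expect_length(st$train_idx, 900L)
  for (lv in stage_levels()) {
    n_lv <- sum(labs == lv)
    n_tr <- sum(st$train$labels == lv)
    expect_lte(abs(n_tr - 0.9 * n_lv), 1)
  }

  expect_error(split_train_test(fake_image_set(rep("W", 5))), "too small")
})

test_that("oversampling balances counts without fabricating samples", {
  counts <- c(100, 10, 200, 5, 20)
  labs <- rep(stage_levels(), counts)
  x <- fake_image_set(labs, seed = 5)
  os <- oversample_training(x, seed = 2)
  expect_identical(as.integer(table(os$labels)), rep(200L, 5))

  # every oversampled row exists in the input
  key <- function(m) apply(m, 1, function(r) paste(signif(r, 12),
                                                   collapse = ","))
  expect_true(all(key(os$images) %in% key(x$images)))

  # already balanced input: same multiset of rows
  xb <- fake_image_set(rep(stage_levels(), each = 8), seed = 6)
  osb <- oversample_training(xb, seed = 2)
  expect_identical(sort(key(osb$images)), sort(key(xb$images)))

  x0 <- fake_image_set(rep(c("W", "N1", "N2", "REM"), 5))
  expect_error(oversample_training(x0, 1), "N3")
})

test_that("zero learning rate freezes the loss trace and weights", {
  x <- tone_image_set(c(4, 4, 4, 4, 4), seed = 3)
  # dropout off so the per-epoch mean loss is a pure function of the
  # (frozen) weights
  m <- build_sleepnet(sleepnet_config(variant = "cnn", dropout_cnn = 0,
                                      seed = 1))
  fit <- train_sleepnet(m, x, train_config(learning_rate = 1e-12,
                                           lr_backbone = 1e-12,
                                           max_epochs = 3, batch_size = 10,
                                           seed = 2))
  expect_lt(diff(range(fit$loss)), 1e-6)
  expect_equal(weights_hash(fit$model), weights_hash(m), tolerance = 1e-9)
})

test_that("training is reproducible from the seed", {
  x <- tone_image_set(c(3, 3, 3, 3, 3), seed = 4)
  run <- function() {
    m <- build_sleepnet(sleepnet_config(variant = "cnn", seed = 5))
    train_sleepnet(m, x, train_config(max_epochs = 2, batch_size = 5,
                                      seed = 6))
  }
  f1 <- run(); f2 <- run()
  expect_identical(weights_hash(f1$model), weights_hash(f2$model))
  expect_identical(f1$loss, f2$loss)
})

test_that("separable two-stage problem is learned quickly", {
  # pure 10 Hz (W) vs pure 1 Hz (N3) tones: separability established by
  # the band-power oracle
  x <- tone_image_set(c(100, 0, 0, 100, 0), seed = 7)
  m <- build_sleepnet(sleepnet_config(variant = "cnn", seed = 8))
  fit <- train_sleepnet(m, x, train_config(learning_rate = 5e-3,
                                           lr_backbone = 1e-3,
                                           max_epochs = 10, seed = 9))
  acc <- mean(classify_stages(fit$model, x) == x$labels)
  expect_gte(acc, 0.95)
})

test_that("k-fold partitions are balanced, disjoint and exhaustive", {
  f100 <- sleepstager:::fold_assignments(100, cv_spec(20, seed = 1))
  expect_identical(as.integer(table(f100)), rep(5L, 20))
  f103 <- sleepstager:::fold_assignments(103, cv_spec(20, seed = 1))
  sz <- as.integer(table(f103))
  expect_identical(sum(sz), 103L)
  expect_lte(diff(range(sz)), 1L)
  expect_error(sleepstager:::fold_assignments(10, cv_spec(20)), "fewer")
})

test_that("cross-validation never leaks oversampling into eval folds", {
  labs <- sample(rep(stage_levels(), c(30, 15, 40, 7, 8)))
  x <- fake_image_set(labs, seed = 11)
  seen <- list()
  res <- kfold_cv(x, cv_spec(k = 5, seed = 3),
    train_fn = function(tr) {
      # record oversampled training labels; return a stub model
      os <- oversample_training(tr, seed = 1)
      seen[[length(seen) + 1L]] <<- os$labels
      structure(list(), class = "stub_model")
    },
    eval_fn = function(model, te) {
      # eval folds must carry original, unbalanced labels
      expect_false(length(unique(table(te$labels))) == 1L &&
                     nrow(te$images) >= 10L)
      suppressWarnings(per_class_metrics(
        confusion_matrix(te$labels, sample(te$labels))))
    })
  expect_length(res$per_fold, 5L)
  # each training portion was balanced by the train_fn
  for (s in seen) expect_identical(length(unique(table(s))), 1L)
  # summary means equal direct recomputation from the fold tables
  direct <- rowMeans(vapply(res$per_fold, function(d) d$Snc, numeric(5)))
  expect_equal(res$summary$mean$Snc, direct)
  # fold eval sets partition the data
  expect_identical(sort(unique(res$folds)), 1:5)
})
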