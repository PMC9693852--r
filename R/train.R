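#' Train/test split specification
#'
#' @param train_fraction fraction of epochs used for training
#'   (default 0.9).
#' @param stratified preserve per-class proportions (default TRUE).
#' @param seed integer seed.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(train_fraction = 0.9, stratified = TRUE, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  structure(list(train_fraction = train_fraction, stratified = stratified,
                 seed = as.integer(seed)),
            class = "split_spec")
}

# Core index splitter: returns disjoint, exhaustive train/test indices.
split_indices <- function(labels, n, spec) {
  target <- round(spec$train_fraction * n)
  with_seed(substream_seed(spec$seed, "split"), {
    if (!spec$stratified || is.null(labels)) {
      train <- sort(sample.int(n, target))
    } else {
      labels <- stage_factor(labels)
      train <- integer(0)
      for (lv in levels(labels)) {
        idx <- which(labels == lv)
        k <- round(spec$train_fraction * length(idx))
        if (length(idx)) train <- c(train, sample(idx, min(k, length(idx))))
      }
      # nudge totals to the exact target while staying within one epoch
      # of the per-class fraction
      while (length(train) > target)
        train <- train[-sample.int(length(train), 1L)]
      if (length(train) < target) {
        pool <- setdiff(seq_len(n), train)
        train <- c(train, sample(pool, target - length(train)))
      }
      train <- sort(train)
    }
    list(train = train, test = setdiff(seq_len(n), train))
  })
}

#' Split a dataset into train and test portions
#'
#' Random epoch-level partition: disjoint, exhaustive,
#' `|train| = round(train_fraction * N)`, deterministic given the spec's
#' seed. With `stratified = TRUE` each class's train fraction is within
#' one epoch of `train_fraction`.
#'
#' @param x an `epoch_dataset` or `tf_image_set`.
#' @param spec a [split_spec()].
#' @return list with `train` and `test` (same class as `x`) and the
#'   index vectors `train_idx`, `test_idx`.
#' @export
split_train_test <- function(x, spec = split_spec()) {
  n <- if (inherits(x, "tf_image_set")) nrow(x$images) else n_epochs(x)
  if (n < 10L) stop("dataset too small to honor the split (need >= 10)",
                    call. = FALSE)
  labels <- x$labels
  si <- split_indices(labels, n, spec)
  take <- function(obj, idx) {
    if (inherits(obj, "tf_image_set")) {
      structure(list(images = obj$images[idx, , drop = FALSE],
                     labels = obj$labels[idx], size = obj$size,
                     method = obj$method),
                class = "tf_image_set")
    } else subset_epochs(obj, idx)
  }
  list(train = take(x, si$train), test = take(x, si$test),
       train_idx = si$train, test_idx = si$test)
}

# Index-level random oversampling: duplicates minority-class indices with
# replacement until every class matches the majority count.
oversample_indices <- function(labels, seed) {
  labels <- stage_factor(labels)
  counts <- table(labels)
  if (any(counts == 0))
    stop("cannot oversample: class(es) with zero training epochs: ",
         paste(names(counts)[counts == 0], collapse = ", "), call. = FALSE)
  target <- max(counts)
  with_seed(substream_seed(seed, "oversample"), {
    idx <- unlist(lapply(levels(labels), function(lv) {
      i <- which(labels == lv)
      if (length(i) == target) i
      else c(i, sample(i, target - length(i), replace = TRUE))
    }))
    sample(idx)                      # shuffle class blocks together
  })
}

#' Balance training data by random oversampling
#'
#' Duplicates randomly chosen minority-class samples (with replacement)
#' until every class count equals the majority class count. No sample is
#' fabricated, and evaluation data must never pass through this
#' function.
#'
#' @param x an `epoch_dataset` or `tf_image_set` (training portion only).
#' @param seed integer seed.
#' @return object of the same class with balanced class counts.
#' @export
oversample_training <- function(x, seed = 1L) {
  labels <- x$labels
  if (is.null(labels)) stop("oversampling requires labels", call. = FALSE)
  idx <- oversample_indices(labels, seed)
  if (inherits(x, "tf_image_set")) {
    structure(list(images = x$images[idx, , drop = FALSE],
                   labels = x$labels[idx], size = x$size,
                   method = x$method),
              class = "tf_image_set")
  } else subset_epochs(x, idx)
}

#' Training configuration
#'
#' Stochastic gradient descent with momentum. The backbone learning rate
#' is lower than the head's when fine-tuning transferred feature layers.
#'
#' @param learning_rate head learning rate (default 1e-3).
#' @param lr_backbone backbone learning rate (default 1e-4).
#' @param momentum SGD momentum (default 0.9).
#' @param batch_size mini-batch size (default 32).
#' @param max_epochs training epochs over the data (default 20).
#' @param oversample balance classes by random oversampling inside the
#'   training set (default FALSE).
#' @param seed master seed for shuffling, dropout and oversampling.
#' @param checkpoint_path optional path to write the final checkpoint.
#' @param verbose print per-epoch loss.
#' @return object of class `train_config`.
#' @export
train_config <- function(learning_rate = 1e-3, lr_backbone = 1e-4,
                         momentum = 0.9, batch_size = 32L, max_epochs = 20L,
                         oversample = FALSE, seed = 1L,
                         checkpoint_path = NULL, verbose = FALSE) {
  stopifnot(learning_rate > 0, lr_backbone > 0, momentum >= 0, momentum < 1,
            batch_size >= 1, max_epochs >= 1)
  structure(list(learning_rate = learning_rate, lr_backbone = lr_backbone,
                 momentum = momentum, batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 oversample = oversample, seed = as.integer(seed),
                 checkpoint_path = checkpoint_path, verbose = verbose),
            class = "train_config")
}

# SGD-with-momentum update, walking the gradient structure.
walk_update <- function(p, g, v, lr, mom) {
  if (is.null(g)) return(list(p = p, v = v))
  if (is.list(g)) {
    if (is.null(v) || length(v) < length(g)) {
      v0 <- vector("list", length(g))
      if (!is.null(v)) v0[seq_along(v)] <- v
      v <- v0
    }
    for (k in seq_along(g)) {
      if (is.null(g[[k]])) next     # untrained slot (e.g. pooling layer)
      nm <- names(g)[k]
      key <- if (!is.null(nm) && nzchar(nm)) nm else k
      r <- walk_update(p[[key]], g[[k]], v[[k]], lr, mom)
      p[[key]] <- r$p
      if (!is.null(r$v)) v[[k]] <- r$v
    }
    return(list(p = p, v = v))
  }
  if (is.null(v)) v <- g * 0
  v <- mom * v - lr * g
  list(p = p + v, v = v)
}

#' Train a sleep-stage classifier
#'
#' Mini-batch SGD with momentum on softmax cross-entropy. All randomness
#' (shuffling, dropout, oversampling) fans out from the config seed, so
#' the loss trace and final weights are reproducible.
#'
#' @param model a [build_sleepnet()] model.
#' @param images a `tf_image_set` with labels (training portion).
#' @param cfg a [train_config()].
#' @return list of class `sleepnet_fit`: `model` (trained), `loss`
#'   (per-epoch mean cross-entropy), `cfg`.
#' @export
train_sleepnet <- function(model, images, cfg = train_config()) {
  stopifnot(inherits(model, "sleepnet"), inherits(images, "tf_image_set"))
  if (is.null(images$labels)) stop("training requires labels", call. = FALSE)
  X <- images$images
  y_idx <- as.integer(stage_factor(images$labels))
  if (isTRUE(cfg$oversample)) {
    os <- oversample_indices(images$labels, cfg$seed)
    y_idx <- y_idx[os]
  } else os <- seq_len(nrow(X))
  n <- length(os)
  vel <- NULL
  losses <- numeric(cfg$max_epochs)
  with_seed(substream_seed(cfg$seed, "train-loop"), {
    for (ep in seq_len(cfg$max_epochs)) {
      perm <- sample.int(n)
      ep_loss <- 0; nb <- 0
      for (s in seq(1L, n, by = cfg$batch_size)) {
        e <- min(s + cfg$batch_size - 1L, n)
        bi <- perm[s:e]
        xb <- X[os[bi], , drop = FALSE]
        yb <- y_idx[bi]
        fw <- sleepnet_forward(model, xb, train = TRUE)
        pb <- fw$probs[cbind(seq_along(yb), yb)]
        loss <- -mean(log(pmax(pb, 1e-12)))
        if (!is.finite(loss))
          stop("training aborted: non-finite loss at epoch ", ep,
               " (learning rate too high or degenerate inputs)",
               call. = FALSE)
        ep_loss <- ep_loss + loss; nb <- nb + 1
        grads <- sleepnet_backward(model, fw, yb)
        if (!is.null(grads$conv)) {
          r <- walk_update(model$params["conv"], grads["conv"],
                           vel$conv_v, cfg$lr_backbone, cfg$momentum)
          model$params$conv <- r$p$conv; vel$conv_v <- r$v
        }
        head_keys <- setdiff(names(grads), "conv")
        r <- walk_update(model$params[head_keys], grads[head_keys],
                         vel$head_v, cfg$learning_rate, cfg$momentum)
        model$params[head_keys] <- r$p; vel$head_v <- r$v
      }
      losses[ep] <- ep_loss / nb
      if (cfg$verbose) msg("epoch %d/%d loss %.4f", ep, cfg$max_epochs,
                           losses[ep])
    }
  })
  if (!is.null(cfg$checkpoint_path)) save_sleepnet(model, cfg$checkpoint_path)
  structure(list(model = model, loss = losses, cfg = cfg),
            class = "sleepnet_fit")
}

#' k-fold cross-validation specification
#'
#' @param k number of folds (default 20).
#' @param seed integer seed.
#' @return object of class `cv_spec`.
#' @export
cv_spec <- function(k = 20L, seed = 1L) {
  stopifnot(k >= 2)
  structure(list(k = as.integer(k), seed = as.integer(seed)),
            class = "cv_spec")
}

# Random partition into k folds with sizes differing by at most one.
fold_assignments <- function(n, cv) {
  if (n < cv$k) stop("fewer samples than folds", call. = FALSE)
  base <- n %/% cv$k; extra <- n %% cv$k
  sizes <- rep(base, cv$k) + c(rep(1L, extra), rep(0L, cv$k - extra))
  with_seed(substream_seed(cv$seed, "cv-folds"),
            sample(rep.int(seq_len(cv$k), sizes)))
}

#' k-fold cross-validation driver
#'
#' Randomly partitions the data into `k` folds (pairwise disjoint,
#' exhaustive, sizes differing by at most one). For each fold, the
#' remaining `k - 1` folds are passed to `train_fn` and the held-out fold
#' to `eval_fn`; any oversampling happens inside `train_fn` only, so
#' evaluation folds always carry the original class distribution.
#'
#' @param images a labelled `tf_image_set`.
#' @param cv a [cv_spec()].
#' @param train_fn function(train_images) -> model.
#' @param eval_fn function(model, test_images) -> [per_class_metrics()];
#'   default predicts with the model and computes the metrics.
#' @param verbose print per-fold progress.
#' @return list of class `cv_result`: `per_fold` (per-class metric
#'   tables), `summary` ([cv_summary()]), `folds` (assignment vector).
#' @export
kfold_cv <- function(images, cv = cv_spec(), train_fn, eval_fn = NULL,
                     verbose = FALSE) {
  stopifnot(inherits(images, "tf_image_set"), !is.null(images$labels))
  n <- nrow(images$images)
  fold <- fold_assignments(n, cv)
  if (is.null(eval_fn))
    eval_fn <- function(model, test) {
      suppressWarnings(per_class_metrics(
        confusion_matrix(test$labels, classify_stages(model, test))))
    }
  take <- function(idx) structure(
    list(images = images$images[idx, , drop = FALSE],
         labels = images$labels[idx], size = images$size,
         method = images$method),
    class = "tf_image_set")
  per_fold <- vector("list", cv$k)
  for (f in seq_len(cv$k)) {
    tr <- take(which(fold != f))
    te <- take(which(fold == f))
    model <- train_fn(tr)
    per_fold[[f]] <- eval_fn(model, te)
    if (verbose) msg("fold %d/%d done", f, cv$k)
  }
  structure(list(per_fold = per_fold, summary = cv_summary(per_fold),
                 folds = fold),
            class = "cv_result")
}
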