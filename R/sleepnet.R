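#' Backbone CNN specification
#'
#' The feature-extraction stack mapping a 224 x 224 x 3 image to a
#' 7 x 7 x 64 feature map. The default `compact` backbone is a
#' download-free four-convolution stack (stride-4 stem then three
#' conv+pool blocks). A `pretrained-adapter` backbone loads the
#' feature-extraction layers of an external network from a checkpoint
#' file (cut at its last pooling layer); it is optional and never
#' required — requesting it without a weight file is an error directing
#' back to `compact`.
#'
#' @param kind "compact" or "pretrained-adapter".
#' @param weights_path checkpoint path for the adapter.
#' @return object of class `backbone_spec` with the layer definitions and
#'   the output shape `(7, 7, 64)`.
#' @export
backbone_spec <- function(kind = c("compact", "pretrained-adapter"),
                          weights_path = NULL) {
  kind <- match.arg(kind)
  if (kind == "pretrained-adapter" &&
      (is.null(weights_path) || !file.exists(weights_path)))
    stop("pretrained backbone weights unavailable; use the compact ",
         "backbone (backbone_spec(\"compact\"))", call. = FALSE)
  layers <- list(
    list(type = "conv", k = 5L, stride = 4L, pad = 2L, cin = 3L, cout = 12L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 12L, cout = 16L),
    list(type = "pool", size = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 16L, cout = 32L),
    list(type = "pool", size = 2L),
    list(type = "conv", k = 3L, stride = 1L, pad = 1L, cin = 32L, cout = 64L),
    list(type = "pool", size = 2L))
  structure(list(kind = kind, weights_path = weights_path,
                 layers = layers, out_shape = c(7L, 7L, 64L)),
            class = "backbone_spec")
}

#' Classifier configuration
#'
#' @param variant "cnn" (backbone, dropout, fully connected, softmax) or
#'   "cnn_rnn" (backbone, sequence unfold/flatten, two BiLSTM layers each
#'   followed by dropout, softmax).
#' @param dropout_cnn dropout before the CNN head's fully connected layer.
#' @param dropout_rnn dropout after each BiLSTM layer.
#' @param hidden_sizes BiLSTM hidden sizes, two layers.
#' @param freeze_backbone if TRUE the backbone is not updated during
#'   training (pure feature transfer); default FALSE (fine-tuning).
#' @param seed weight-initialization seed.
#' @return object of class `sleepnet_config`.
#' @export
sleepnet_config <- function(variant = c("cnn_rnn", "cnn"),
                            dropout_cnn = 0.5, dropout_rnn = 0.3,
                            hidden_sizes = c(128L, 128L),
                            freeze_backbone = FALSE, seed = 1L) {
  variant <- match.arg(variant)
  stopifnot(dropout_cnn >= 0, dropout_cnn < 1,
            dropout_rnn >= 0, dropout_rnn < 1,
            length(hidden_sizes) == 2L, all(hidden_sizes >= 1))
  structure(list(variant = variant, dropout_cnn = dropout_cnn,
                 dropout_rnn = dropout_rnn,
                 hidden_sizes = as.integer(hidden_sizes),
                 n_classes = 5L, freeze_backbone = freeze_backbone,
                 seed = as.integer(seed)),
            class = "sleepnet_config")
}

#' Build a sleep-stage classifier
#'
#' Instantiates the weights of the configured architecture (He-normal
#' convolution init, scaled-uniform LSTM init, zero-init head).
#'
#' @param cfg a [sleepnet_config()].
#' @param backbone a [backbone_spec()].
#' @return object of class `sleepnet`.
#' @export
build_sleepnet <- function(cfg = sleepnet_config(),
                           backbone = backbone_spec()) {
  stopifnot(inherits(cfg, "sleepnet_config"),
            inherits(backbone, "backbone_spec"))
  conv <- with_seed(substream_seed(cfg$seed, "conv-init"), {
    lapply(backbone$layers, function(ly) {
      if (ly$type != "conv") return(NULL)
      fan_in <- ly$k^2 * ly$cin
      list(W = matrix(rnorm(ly$cout * fan_in, sd = sqrt(2 / fan_in)),
                      ly$cout, fan_in),
           b = numeric(ly$cout))
    })
  })
  feat_dim <- prod(backbone$out_shape)
  seq_dim <- backbone$out_shape[1] * backbone$out_shape[3]
  params <- list(conv = conv)
  if (cfg$variant == "cnn_rnn") {
    H1 <- cfg$hidden_sizes[1]; H2 <- cfg$hidden_sizes[2]
    params$rnn <- list(
      l1f = lstm_params(seq_dim, H1, "uniform",
                        substream_seed(cfg$seed, "l1f")),
      l1b = lstm_params(seq_dim, H1, "uniform",
                        substream_seed(cfg$seed, "l1b")),
      l2f = lstm_params(2L * H1, H2, "uniform",
                        substream_seed(cfg$seed, "l2f")),
      l2b = lstm_params(2L * H1, H2, "uniform",
                        substream_seed(cfg$seed, "l2b")))
    head_dim <- 2L * H2
  } else {
    head_dim <- feat_dim
  }
  params$fc <- with_seed(substream_seed(cfg$seed, "fc-init"),
    list(W = matrix(rnorm(cfg$n_classes * head_dim, sd = 1 / sqrt(head_dim)),
                    cfg$n_classes, head_dim),
         b = numeric(cfg$n_classes)))
  structure(list(cfg = cfg, backbone = backbone, params = params),
            class = "sleepnet")
}

#' @export
print.sleepnet <- function(x, ...) {
  np <- sum(vapply(rapply(x$params, length, how = "unlist"), sum, 0))
  cat(sprintf("<sleepnet> variant=%s, %d parameters\n", x$cfg$variant, np))
  invisible(x)
}

# Replicate grayscale image rows (N x size^2) to a (size, size, 3, N)
# input array.
images_to_array <- function(images, size = 224L, channels = 3L) {
  a1 <- array(t(images), dim = c(size, size, 1L, nrow(images)))
  a1[, , rep(1L, channels), , drop = FALSE]
}

softmax_rows <- function(z) {
  z <- z - apply(z, 1L, max)
  e <- exp(z)
  e / rowSums(e)
}

# Backbone forward; returns feature map and (optionally) per-layer cache.
backbone_forward <- function(model, X, keep_cache = FALSE) {
  layers <- model$backbone$layers
  cache <- if (keep_cache) vector("list", length(layers))
  cur <- X
  for (li in seq_along(layers)) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      p <- model$params$conv[[li]]
      out <- conv2d_forward(cur, dim(cur), p$W, p$b, ly$k, ly$k,
                            ly$stride, ly$pad)$y
      act <- pmax(out, 0)
      if (keep_cache) cache[[li]] <- list(x = cur, pre = out)
      cur <- act
    } else {
      mp <- maxpool_forward(cur, dim(cur), ly$size)
      if (keep_cache) cache[[li]] <- list(argmax = mp$argmax, xdim = dim(cur))
      cur <- mp$y
    }
  }
  list(fmap = cur, cache = cache)
}

backbone_backward <- function(model, cache, dfmap, need_dx = FALSE) {
  layers <- model$backbone$layers
  grads <- vector("list", length(layers))
  dcur <- dfmap
  for (li in rev(seq_along(layers))) {
    ly <- layers[[li]]
    if (ly$type == "conv") {
      cc <- cache[[li]]
      dcur <- dcur * (cc$pre > 0)           # ReLU gate
      bw <- conv2d_backward(cc$x, dim(cc$x), model$params$conv[[li]]$W,
                            dcur, ly$k, ly$k, ly$stride, ly$pad)
      grads[[li]] <- list(W = bw$dw, b = bw$db)
      if (li > 1L || need_dx) dcur <- bw$dx
    } else {
      dcur <- maxpool_backward(dcur, cache[[li]]$argmax, cache[[li]]$xdim)
    }
  }
  grads
}

#' Unfold a CNN feature map into a sequence of feature vectors
#'
#' Column `t` of the feature map (the image's time axis) becomes sequence
#' element `t`, flattened frequency-major then channel: element `t` is
#' `as.vector(fmap[, t, ])` of length `H_f * C_f`.
#'
#' @param fmap `H_f x W_f x C_f` array.
#' @return `W_f x (H_f * C_f)` matrix.
#' @export
feature_sequence <- function(fmap) {
  stopifnot(length(dim(fmap)) == 3L)
  d <- dim(fmap)
  t(vapply(seq_len(d[2]), function(t) as.vector(fmap[, t, ]),
           numeric(d[1] * d[3])))
}

# Batch version: (H, W, C, N) array -> list of W matrices (N x H*C).
fmap_to_sequence <- function(fmap) {
  d <- dim(fmap)
  A <- aperm(fmap, c(1L, 3L, 2L, 4L))       # H, C, W, N
  lapply(seq_len(d[2]), function(t)
    t(matrix(A[, , t, ], d[1] * d[3], d[4])))
}

sequence_to_fmap_grad <- function(dxs, d) {
  dA <- array(0, c(d[1], d[3], d[2], d[4]))
  for (t in seq_along(dxs)) dA[, , t, ] <- array(t(dxs[[t]]),
                                                 c(d[1], d[3], d[4]))
  aperm(dA, c(1L, 3L, 2L, 4L))
}

dropout_mask <- function(nr, nc, rate) {
  if (rate <= 0) return(NULL)
  matrix(stats::rbinom(nr * nc, 1L, 1 - rate), nr, nc) / (1 - rate)
}

# Full forward pass. `train` enables dropout (masks drawn from the
# current RNG state) and returns the cache for the backward pass.
sleepnet_forward <- function(model, images, train = FALSE) {
  X <- images_to_array(images)
  bb <- backbone_forward(model, X, keep_cache = train)
  fmap <- bb$fmap
  d <- dim(fmap); N <- d[4]
  cfg <- model$cfg
  cache <- list(backbone = bb$cache, fmap_dim = d)
  if (cfg$variant == "cnn") {
    feat <- t(matrix(fmap, prod(d[1:3]), N))
    mask <- if (train) dropout_mask(N, ncol(feat), cfg$dropout_cnn)
    if (!is.null(mask)) feat <- feat * mask
    logits <- feat %*% t(model$params$fc$W) +
      matrix(model$params$fc$b, N, cfg$n_classes, byrow = TRUE)
    cache$feat <- feat; cache$mask <- mask
  } else {
    xs <- fmap_to_sequence(fmap)
    r <- model$params$rnn
    b1 <- bilstm_forward_cache(xs, r$l1f, r$l1b)
    m1 <- if (train) lapply(b1$out, function(o)
      dropout_mask(nrow(o), ncol(o), cfg$dropout_rnn))
    o1 <- if (is.null(m1)) b1$out
          else mapply(function(o, m) if (is.null(m)) o else o * m,
                      b1$out, m1, SIMPLIFY = FALSE)
    b2 <- bilstm_forward_cache(o1, r$l2f, r$l2b)
    T_len <- length(b2$out); H2 <- cfg$hidden_sizes[2]
    summary <- cbind(b2$out[[T_len]][, seq_len(H2), drop = FALSE],
                     b2$out[[1L]][, H2 + seq_len(H2), drop = FALSE])
    m2 <- if (train) dropout_mask(nrow(summary), ncol(summary),
                                  cfg$dropout_rnn)
    if (!is.null(m2)) summary <- summary * m2
    logits <- summary %*% t(model$params$fc$W) +
      matrix(model$params$fc$b, N, cfg$n_classes, byrow = TRUE)
    cache$b1 <- b1; cache$b2 <- b2; cache$m1 <- m1; cache$m2 <- m2
    cache$summary <- summary
  }
  list(probs = softmax_rows(logits), cache = cache)
}

# Gradients of mean cross-entropy w.r.t. all trainable parameters.
sleepnet_backward <- function(model, fw, y_idx) {
  cfg <- model$cfg
  probs <- fw$probs; cache <- fw$cache
  N <- nrow(probs)
  dlogits <- probs
  dlogits[cbind(seq_len(N), y_idx)] <- dlogits[cbind(seq_len(N), y_idx)] - 1
  dlogits <- dlogits / N
  grads <- list()
  if (cfg$variant == "cnn") {
    grads$fc <- list(W = t(dlogits) %*% cache$feat, b = colSums(dlogits))
    dfeat <- dlogits %*% model$params$fc$W
    if (!is.null(cache$mask)) dfeat <- dfeat * cache$mask
    d <- cache$fmap_dim
    dfmap <- array(t(dfeat), d)
  } else {
    grads$fc <- list(W = t(dlogits) %*% cache$summary, b = colSums(dlogits))
    dsummary <- dlogits %*% model$params$fc$W
    if (!is.null(cache$m2)) dsummary <- dsummary * cache$m2
    T_len <- length(cache$b2$out); H2 <- cfg$hidden_sizes[2]
    dout2 <- lapply(cache$b2$out, function(o) matrix(0, nrow(o), ncol(o)))
    dout2[[T_len]][, seq_len(H2)] <- dsummary[, seq_len(H2)]
    dout2[[1L]][, H2 + seq_len(H2)] <- dsummary[, H2 + seq_len(H2)]
    r <- model$params$rnn
    bw2 <- bilstm_backward(dout2, cache$b2$ff$cache, cache$b2$bb$cache,
                           r$l2f, r$l2b)
    do1 <- bw2$dxs
    if (!is.null(cache$m1))
      do1 <- mapply(function(d, m) if (is.null(m)) d else d * m,
                    do1, cache$m1, SIMPLIFY = FALSE)
    bw1 <- bilstm_backward(do1, cache$b1$ff$cache, cache$b1$bb$cache,
                           r$l1f, r$l1b)
    grads$rnn <- list(l1f = bw1$fwd_grads, l1b = bw1$bwd_grads,
                      l2f = bw2$fwd_grads, l2b = bw2$bwd_grads)
    dfmap <- sequence_to_fmap_grad(bw1$dxs, cache$fmap_dim)
  }
  if (!cfg$freeze_backbone)
    grads$conv <- backbone_backward(model, cache$backbone, dfmap)
  grads
}

#' Predict stage probabilities for a batch of images
#'
#' Inference is deterministic: dropout is inactive outside training.
#'
#' @param object a trained `sleepnet`.
#' @param images `tf_image_set` or n x size^2 matrix of grayscale images.
#' @param batch_size mini-batch size for the forward passes.
#' @param ... unused.
#' @return n x 5 matrix of class probabilities (columns `stage_levels()`).
#' @export
predict.sleepnet <- function(object, images, batch_size = 64L, ...) {
  if (inherits(images, "tf_image_set")) images <- images$images
  n <- nrow(images)
  out <- matrix(0, n, object$cfg$n_classes,
                dimnames = list(NULL, stage_levels()))
  for (s in seq(1L, n, by = batch_size)) {
    e <- min(s + batch_size - 1L, n)
    out[s:e, ] <- sleepnet_forward(object, images[s:e, , drop = FALSE])$probs
  }
  out
}

#' Hard stage predictions
#' @param model a trained `sleepnet`.
#' @param images image set or matrix (see [predict.sleepnet()]).
#' @return stage factor of predicted labels.
#' @export
classify_stages <- function(model, images) {
  stage_factor(stage_levels()[max.col(predict(model, images),
                                      ties.method = "first")])
}

#' Save / load a sleepnet checkpoint
#'
#' Versioned container holding the weights, the [sleepnet_config()] and a
#' hash of the backbone layer definitions.
#'
#' @param model a `sleepnet`.
#' @param path checkpoint file path.
#' @return `path` invisibly; `load_sleepnet` returns the model.
#' @export
save_sleepnet <- function(model, path) {
  stopifnot(inherits(model, "sleepnet"))
  obj <- list(format = "sleepnet-checkpoint-1",
              cfg = model$cfg,
              backbone = model$backbone,
              backbone_hash = backbone_hash(model$backbone),
              params = model$params)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_sleepnet
#' @export
load_sleepnet <- function(path) {
  obj <- readRDS(path)
  if (!identical(obj$format, "sleepnet-checkpoint-1"))
    stop("not a sleepnet checkpoint: ", path, call. = FALSE)
  if (!identical(obj$backbone_hash, backbone_hash(obj$backbone)))
    stop("checkpoint backbone hash mismatch", call. = FALSE)
  structure(list(cfg = obj$cfg, backbone = obj$backbone,
                 params = obj$params),
            class = "sleepnet")
}

backbone_hash <- function(backbone) {
  s <- paste(utils::capture.output(utils::str(backbone$layers)),
             collapse = "")
  h <- 0
  for (ch in utf8ToInt(s)) h <- (h * 31 + ch) %% 2147483647
  h
}

#' Digest of model weights
#' @param model a `sleepnet`.
#' @return numeric scalar hash of all weights.
#' @export
weights_hash <- function(model) {
  v <- unlist(rapply(model$params,
                     function(x) if (is.numeric(x)) as.numeric(x) else NULL,
                     how = "unlist"))
  sum(v * rep_len(c(1, pi, exp(1), sqrt(2)), length(v)))
}
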