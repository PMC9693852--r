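#' LSTM gate parameters
#'
#' One LSTM unit's trainable parameters: for each gate (input `i`, forget
#' `f`, output `o`) and the candidate cell update (`c`), an input weight
#' matrix `W_*` (H x D), a recurrent weight matrix `U_*` (H x H) and a
#' bias `b_*` (length H).
#'
#' @param input_size D, input vector length.
#' @param hidden_size H, hidden state length.
#' @param init "zero" or "uniform" (scaled by `1/sqrt(H)`).
#' @param seed seed used for "uniform" init.
#' @return object of class `lstm_params`.
#' @export
lstm_params <- function(input_size, hidden_size, init = c("zero", "uniform"),
                        seed = 1L) {
  init <- match.arg(init)
  D <- as.integer(input_size); H <- as.integer(hidden_size)
  stopifnot(D >= 1, H >= 1)
  mk <- function(nr, nc) {
    if (init == "zero") matrix(0, nr, nc)
    else matrix(runif(nr * nc, -1, 1) / sqrt(H), nr, nc)
  }
  p <- with_seed(seed, {
    p <- list()
    for (g in c("i", "f", "o", "c")) {
      p[[paste0("W", g)]] <- mk(H, D)
      p[[paste0("U", g)]] <- mk(H, H)
      p[[paste0("b", g)]] <- if (init == "zero") numeric(H)
                             else runif(H, -1, 1) / sqrt(H)
    }
    # forget-gate bias of +1: standard trick for gradient flow
    if (init == "uniform") p$bf <- p$bf + 1
    p
  })
  structure(c(p, list(input_size = D, hidden_size = H)),
            class = "lstm_params")
}

sigmoid <- function(x) 1 / (1 + exp(-x))

#' One LSTM time step
#'
#' The gated recurrence
#' \deqn{f_t = \sigma(W_f x_t + U_f h_{t-1} + b_f)}
#' \deqn{i_t = \sigma(W_i x_t + U_i h_{t-1} + b_i)}
#' \deqn{C_t = f_t \odot C_{t-1} + i_t \odot \tanh(W_c x_t + U_c h_{t-1} + b_c)}
#' \deqn{O_t = \sigma(W_o x_t + U_o h_{t-1} + b_o)}
#' \deqn{h_t = O_t \odot \tanh(C_t)}
#' with sigmoid gate activations and tanh cell/output activations.
#'
#' @param x_t input: length-D vector or N x D matrix (batch).
#' @param prev list with `h` and `c` (length-H vectors or N x H matrices);
#'   NULL for the all-zero initial state.
#' @param params an [lstm_params()].
#' @return list with `h`, `c` (and gate activations `i,f,o,g` for
#'   backpropagation).
#' @export
lstm_step <- function(x_t, prev = NULL, params) {
  stopifnot(inherits(params, "lstm_params"))
  X <- if (is.matrix(x_t)) x_t else matrix(x_t, nrow = 1L)
  if (ncol(X) != params$input_size)
    stop("input size mismatch: expected ", params$input_size, ", got ",
         ncol(X), call. = FALSE)
  N <- nrow(X); H <- params$hidden_size
  if (is.null(prev)) prev <- list(h = matrix(0, N, H), c = matrix(0, N, H))
  Hprev <- if (is.matrix(prev$h)) prev$h else matrix(prev$h, nrow = 1L)
  Cprev <- if (is.matrix(prev$c)) prev$c else matrix(prev$c, nrow = 1L)
  if (ncol(Hprev) != H || nrow(Hprev) != N)
    stop("state dimension mismatch", call. = FALSE)
  gate <- function(W, U, b)
    X %*% t(W) + Hprev %*% t(U) + matrix(b, N, H, byrow = TRUE)
  f <- sigmoid(gate(params$Wf, params$Uf, params$bf))
  i <- sigmoid(gate(params$Wi, params$Ui, params$bi))
  g <- tanh(gate(params$Wc, params$Uc, params$bc))
  C <- f * Cprev + i * g
  o <- sigmoid(gate(params$Wo, params$Uo, params$bo))
  h <- o * tanh(C)
  drop1 <- function(m) if (N == 1L && !is.matrix(x_t)) drop(m) else m
  list(h = drop1(h), c = drop1(C), i = i, f = f, o = o, g = g)
}

# Full forward pass over a sequence (list of N x D matrices), returning
# outputs and the cache needed for backpropagation through time.
lstm_forward_cache <- function(xs, params) {
  T_len <- length(xs)
  N <- nrow(xs[[1L]]); H <- params$hidden_size
  hs <- vector("list", T_len); cache <- vector("list", T_len)
  st <- list(h = matrix(0, N, H), c = matrix(0, N, H))
  for (t in seq_len(T_len)) {
    prev <- st
    st <- lstm_step(xs[[t]], prev, params)
    hs[[t]] <- st$h
    cache[[t]] <- list(x = xs[[t]], hprev = prev$h, cprev = prev$c,
                       i = st$i, f = st$f, o = st$o, g = st$g, c = st$c)
  }
  list(hs = hs, cache = cache)
}

# Backpropagation through time. dhs: list of N x H gradients w.r.t. each
# output h_t. Returns parameter gradients and input gradients.
lstm_backward <- function(dhs, cache, params) {
  T_len <- length(cache)
  N <- nrow(dhs[[1L]]); H <- params$hidden_size; D <- params$input_size
  gz <- function(nr, nc) matrix(0, nr, nc)
  grads <- list(Wi = gz(H, D), Wf = gz(H, D), Wo = gz(H, D), Wc = gz(H, D),
                Ui = gz(H, H), Uf = gz(H, H), Uo = gz(H, H), Uc = gz(H, H),
                bi = numeric(H), bf = numeric(H), bo = numeric(H),
                bc = numeric(H))
  dxs <- vector("list", T_len)
  dh_next <- gz(N, H); dc_next <- gz(N, H)
  for (t in rev(seq_len(T_len))) {
    cc <- cache[[t]]
    dh <- dhs[[t]] + dh_next
    tc <- tanh(cc$c)
    dc <- dc_next + dh * cc$o * (1 - tc^2)
    do_ <- dh * tc
    di <- dc * cc$g
    dg <- dc * cc$i
    df <- dc * cc$cprev
    da_i <- di * cc$i * (1 - cc$i)
    da_f <- df * cc$f * (1 - cc$f)
    da_o <- do_ * cc$o * (1 - cc$o)
    da_g <- dg * (1 - cc$g^2)
    grads$Wi <- grads$Wi + t(da_i) %*% cc$x
    grads$Wf <- grads$Wf + t(da_f) %*% cc$x
    grads$Wo <- grads$Wo + t(da_o) %*% cc$x
    grads$Wc <- grads$Wc + t(da_g) %*% cc$x
    grads$Ui <- grads$Ui + t(da_i) %*% cc$hprev
    grads$Uf <- grads$Uf + t(da_f) %*% cc$hprev
    grads$Uo <- grads$Uo + t(da_o) %*% cc$hprev
    grads$Uc <- grads$Uc + t(da_g) %*% cc$hprev
    grads$bi <- grads$bi + colSums(da_i)
    grads$bf <- grads$bf + colSums(da_f)
    grads$bo <- grads$bo + colSums(da_o)
    grads$bc <- grads$bc + colSums(da_g)
    dxs[[t]] <- da_i %*% params$Wi + da_f %*% params$Wf +
      da_o %*% params$Wo + da_g %*% params$Wc
    dh_next <- da_i %*% params$Ui + da_f %*% params$Uf +
      da_o %*% params$Uo + da_g %*% params$Uc
    dc_next <- dc * cc$f
  }
  list(grads = grads, dxs = dxs)
}

#' Bidirectional LSTM over a sequence
#'
#' Runs a causal (forward-time) LSTM and an anticausal LSTM (same
#' recurrence on the time-reversed sequence, its own parameters) and
#' concatenates their outputs position-wise: position `t` carries
#' `[h_t(fwd) ; h'_t(bwd)]`.
#'
#' @param xs T x D matrix (sequence of T vectors), or a list of T
#'   batch matrices (N x D).
#' @param fwd,bwd [lstm_params()] for the two directions.
#' @return T x 2H matrix (or list of N x 2H matrices for batch input).
#' @export
bilstm_forward <- function(xs, fwd, bwd) {
  single <- is.matrix(xs)
  if (single) xs <- lapply(seq_len(nrow(xs)), function(t) xs[t, , drop = FALSE])
  if (length(xs) == 0L) stop("empty sequence", call. = FALSE)
  ff <- lstm_forward_cache(xs, fwd)
  bb <- lstm_forward_cache(rev(xs), bwd)
  T_len <- length(xs)
  out <- lapply(seq_len(T_len), function(t)
    cbind(ff$hs[[t]], bb$hs[[T_len - t + 1L]]))
  if (single) do.call(rbind, out) else out
}

# Batch BiLSTM with cache for training.
bilstm_forward_cache <- function(xs, fwd, bwd) {
  ff <- lstm_forward_cache(xs, fwd)
  bb <- lstm_forward_cache(rev(xs), bwd)
  T_len <- length(xs)
  out <- lapply(seq_len(T_len), function(t)
    cbind(ff$hs[[t]], bb$hs[[T_len - t + 1L]]))
  list(out = out, ff = ff, bb = bb)
}

bilstm_backward <- function(dout, fwd_cache, bwd_cache, fwd, bwd) {
  T_len <- length(dout)
  H <- fwd$hidden_size
  dh_f <- lapply(dout, function(d) d[, seq_len(H), drop = FALSE])
  dh_b <- lapply(rev(dout), function(d)
    d[, H + seq_len(bwd$hidden_size), drop = FALSE])
  bf <- lstm_backward(dh_f, fwd_cache, fwd)
  bb <- lstm_backward(dh_b, bwd_cache, bwd)
  dxs <- lapply(seq_len(T_len), function(t)
    bf$dxs[[t]] + bb$dxs[[T_len - t + 1L]])
  list(dxs = dxs, fwd_grads = bf$grads, bwd_grads = bb$grads)
}
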