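#' Default stage-transition propensities
#'
#' Builds the 5x5 nonnegative transition-weight matrix of the first-order
#' Markov hypnogram model. Self-transition weights are set so that one full
#' cycle (W -> N1 -> N2 -> N3 -> N2 -> REM) lasts on average
#' `mean(cycle_minutes)` minutes at 2 epochs/min, with per-stage dwell times
#' apportioned by the marginal `proportions` (N2 is visited twice per
#' cycle). Off-diagonal mass follows the cyclic routing of normal adult
#' sleep: W feeds N1, N1 deepens to N2, N2 exits to N3 or REM, N3 lightens
#' back to N2, REM ends the cycle in W or N1.
#'
#' Within a cycle each stage's total dwell is split into
#' `bout_fragmentation` separate bouts, reflecting the fragmented bout
#' structure of real hypnograms (bouts of a few minutes, not one
#' uninterrupted block per stage per cycle).
#'
#' @param cycle_minutes length-2 numeric, bounds of the sleep-cycle duration
#'   in minutes (default 90-120).
#' @param proportions 5-vector of target marginal stage fractions.
#' @param bout_fragmentation mean number of bouts a stage's per-cycle dwell
#'   is split into (default 4).
#' @return 5x5 row-stochastic matrix with `stage_levels()` dimnames.
#' @export
default_transition_weights <- function(cycle_minutes = c(90, 120),
                                       proportions = default_stage_proportions(),
                                       bout_fragmentation = 4) {
  stopifnot(length(cycle_minutes) == 2L, all(cycle_minutes > 0),
            length(proportions) == 5L, all(proportions > 0),
            bout_fragmentation >= 1)
  lv <- stage_levels()
  proportions <- proportions / sum(proportions)
  cycle_epochs <- 2 * mean(cycle_minutes)          # 30-s epochs per cycle
  visits <- c(W = 1, N1 = 1, N2 = 2, N3 = 1, REM = 1) * bout_fragmentation
  dwell <- pmax(proportions * cycle_epochs / visits, 1.5)
  p_stay <- 1 - 1 / dwell

  route <- rbind(
    W   = c(0.00, 0.85, 0.05, 0.00, 0.10),
    N1  = c(0.05, 0.00, 0.90, 0.00, 0.05),
    N2  = c(0.07, 0.03, 0.00, 0.45, 0.45),
    N3  = c(0.05, 0.00, 0.95, 0.00, 0.00),
    REM = c(0.60, 0.30, 0.10, 0.00, 0.00)
  )
  P <- route * (1 - p_stay)
  diag(P) <- p_stay
  dimnames(P) <- list(lv, lv)
  P
}

#' Hypnogram simulation specification
#'
#' @param n_epochs nonnegative integer count of 30-s epochs.
#' @param transition_weights 5x5 nonnegative matrix of transition
#'   propensities (rows = from-stage); rows are normalized internally.
#' @param target_proportions optional 5-vector of marginal stage fractions
#'   (must sum to 1); when given, the transition matrix is iteratively
#'   recalibrated so its stationary distribution matches.
#' @param cycle_minutes length-2 bounds of the cycle duration in minutes.
#' @param seed integer seed.
#' @return object of class `hypnogram_spec`.
#' @export
hypnogram_spec <- function(n_epochs,
                           transition_weights = NULL,
                           target_proportions = default_stage_proportions(),
                           cycle_minutes = c(90, 120),
                           seed = 1L) {
  stopifnot(length(n_epochs) == 1L, n_epochs >= 0, n_epochs == floor(n_epochs))
  if (is.null(transition_weights))
    transition_weights <- default_transition_weights(cycle_minutes)
  transition_weights <- as.matrix(transition_weights)
  if (!all(dim(transition_weights) == c(5L, 5L)))
    stop("transition_weights must be 5x5", call. = FALSE)
  if (any(transition_weights < 0) || any(!is.finite(transition_weights)))
    stop("transition_weights must be finite and nonnegative", call. = FALSE)
  if (any(rowSums(transition_weights) <= 0))
    stop("each transition_weights row must have positive sum", call. = FALSE)
  if (!is.null(target_proportions)) {
    stopifnot(length(target_proportions) == 5L, all(target_proportions > 0))
    if (abs(sum(target_proportions) - 1) > 1e-9)
      stop("target_proportions must sum to 1", call. = FALSE)
  }
  structure(list(n_epochs = as.integer(n_epochs),
                 transition_weights = transition_weights,
                 target_proportions = target_proportions,
                 cycle_minutes = cycle_minutes,
                 seed = as.integer(seed)),
            class = "hypnogram_spec")
}

#' Stationary distribution of a row-stochastic matrix
#'
#' Left-eigenvector of the transition matrix for eigenvalue 1, normalized to
#' a probability vector.
#'
#' @param P row-stochastic square matrix.
#' @return numeric probability vector.
#' @export
stationary_distribution <- function(P) {
  P <- P / rowSums(P)
  e <- eigen(t(P))
  i <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, i])
  v <- abs(v)
  v / sum(v)
}

# Multiplicative recalibration of the transition matrix so that its
# stationary distribution matches `target`. Column weights are scaled by
# (target/pi)^damp and rows renormalized; converges in a few dozen
# iterations for sticky sleep-like chains.
calibrate_transition_matrix <- function(P, target, max_iter = 200L,
                                        tol = 1e-10, damp = 0.7) {
  P <- P / rowSums(P)
  target <- target / sum(target)
  for (k in seq_len(max_iter)) {
    pi_k <- stationary_distribution(P)
    if (max(abs(pi_k - target)) < tol) break
    P <- sweep(P, 2L, (target / pi_k)^damp, `*`)
    P <- P / rowSums(P)
  }
  P
}

#' Simulate a hypnogram
#'
#' Samples a first-order Markov chain over the five sleep stages, starting
#' in W. When the spec carries `target_proportions`, the transition matrix
#' is first recalibrated so that its stationary distribution matches them,
#' giving hypnograms with the clinically observed stage imbalance.
#'
#' @param spec a [hypnogram_spec()].
#' @return factor of length `n_epochs` with levels `stage_levels()`.
#' @export
simulate_hypnogram <- function(spec) {
  stopifnot(inherits(spec, "hypnogram_spec"))
  n <- spec$n_epochs
  if (n == 0L) return(stage_factor(character(0)))
  P <- spec$transition_weights / rowSums(spec$transition_weights)
  if (!is.null(spec$target_proportions))
    P <- calibrate_transition_matrix(P, spec$target_proportions)
  cum <- t(apply(P, 1L, cumsum))
  out <- integer(n)
  out[1L] <- 1L                                   # W
  with_seed(substream_seed(spec$seed, "hypnogram"), {
    u <- runif(n)
    for (i in seq_len(n - 1L))
      out[i + 1L] <- findInterval(u[i + 1L], cum[out[i], ]) + 1L
  })
  stage_factor(stage_levels()[out])
}
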