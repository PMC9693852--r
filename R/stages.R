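#' Sleep stage levels
#'
#' The five AASM sleep stages in the package's fixed order and integer
#' encoding: W = 0, N1 = 1, N2 = 2, N3 = 3, REM = 4. Every labelled object in
#' the package uses this ordering.
#'
#' @return character vector `c("W","N1","N2","N3","REM")`.
#' @export
stage_levels <- function() c("W", "N1", "N2", "N3", "REM")

#' Convert labels to a sleep-stage factor
#'
#' @param x character, factor or integer codes (0-4).
#' @return factor with levels `stage_levels()`.
#' @export
stage_factor <- function(x) {
  lv <- stage_levels()
  if (is.numeric(x)) {
    if (any(!is.na(x) & (x < 0 | x > 4 | x != floor(x))))
      stop("integer stage codes must be in 0..4", call. = FALSE)
    return(factor(lv[x + 1L], levels = lv))
  }
  x <- as.character(x)
  bad <- !is.na(x) & !(x %in% lv)
  if (any(bad))
    stop("invalid stage label(s): ", paste(unique(x[bad]), collapse = ", "),
         call. = FALSE)
  factor(x, levels = lv)
}

#' Reference clinical stage distribution
#'
#' Per-stage 30-s epoch counts from the two clinical polysomnography
#' cohorts whose imbalance the synthetic generator emulates (a 20-patient
#' and a 61-patient cohort; 72,496 scored epochs in total). These counts
#' define the default marginal stage proportions of the hypnogram
#' simulator.
#'
#' @return data.frame with columns `cohort`, `patients`, `W`, `N1`, `N2`,
#'   `N3`, `REM`, `total`.
#' @export
stage_distribution_reference <- function() {
  d <- data.frame(
    cohort = c("A", "B"),
    patients = c(20L, 61L),
    W   = c(4826L, 12983L),
    N1  = c(5094L, 5818L),
    N2  = c(4711L, 26091L),
    N3  = c(1568L, 3621L),
    REM = c(1488L, 6296L)
  )
  d$total <- as.integer(rowSums(d[, stage_levels()]))
  d
}

#' Default stage proportions used by the hypnogram simulator
#'
#' Marginal stage fractions of the pooled reference distribution
#' (W 24.57%, N1 15.05%, N2 42.49%, N3 7.16%, REM 10.74%).
#'
#' @return named numeric 5-vector summing to 1.
#' @export
default_stage_proportions <- function() {
  d <- stage_distribution_reference()
  counts <- colSums(d[, stage_levels()])
  counts / sum(counts)
}
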