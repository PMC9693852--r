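#' Confusion matrix for five-stage scoring
#'
#' @param truth,predicted equal-length stage label vectors
#'   (character/factor/integer codes).
#' @return object of class `stage_confusion`: 5 x 5 integer matrix,
#'   rows = true stage, columns = predicted stage.
#' @export
confusion_matrix <- function(truth, predicted) {
  truth <- stage_factor(truth); predicted <- stage_factor(predicted)
  if (length(truth) != length(predicted))
    stop("truth and predicted must have equal length", call. = FALSE)
  if (anyNA(truth) || anyNA(predicted))
    stop("labels contain missing values", call. = FALSE)
  cm <- table(truth = truth, predicted = predicted)
  structure(unclass(cm), class = "stage_confusion")
}

#' @export
print.stage_confusion <- function(x, ...) {
  cat("confusion matrix (rows = truth, cols = predicted), N =", sum(x), "\n")
  print(unclass(x))
  invisible(x)
}

# One-vs-all counts for class c.
ova_counts <- function(cm, c) {
  tp <- cm[c, c]
  fn <- sum(cm[c, ]) - tp
  fp <- sum(cm[, c]) - tp
  tn <- sum(cm) - tp - fn - fp
  c(TP = tp, FP = fp, TN = tn, FN = fn)
}

#' F1 score from sensitivity and precision
#'
#' Harmonic mean `2 * Sn * Pr / (Sn + Pr)`, on whatever scale its inputs
#' share (percent in the package's reports).
#'
#' @param sn,pr sensitivity (recall) and precision.
#' @return F1 on the same scale; `NaN` when `sn + pr == 0`.
#' @export
f1_score <- function(sn, pr) 2 * sn * pr / (sn + pr)

#' Per-class one-versus-all metrics
#'
#' For each stage, the class is taken as positive and the other four
#' pooled as negative; sensitivity `TP/(TP+FN)`, precision `TP/(TP+FP)`,
#' F1, specificity `TN/(FP+TN)` and accuracy `(TP+TN)/N` are reported in
#' percent. When a class was never predicted (`TP+FP = 0`) its precision
#' and F1 are undefined: reported as `NA` with a warning, and counted as
#' 0 in macro-averages.
#'
#' @param cm a [confusion_matrix()].
#' @return data.frame with columns `class`, `Snc`, `Spc`, `Prc`, `F1c`,
#'   `ACCc` (percent), class `per_class_metrics`.
#' @export
per_class_metrics <- function(cm) {
  stopifnot(inherits(cm, "stage_confusion"))
  N <- sum(cm)
  if (N == 0) stop("empty confusion matrix", call. = FALSE)
  out <- lapply(seq_len(5L), function(c) {
    k <- ova_counts(cm, c)
    sn <- if (k["TP"] + k["FN"] > 0) 100 * k["TP"] / (k["TP"] + k["FN"])
          else NA_real_
    pr <- if (k["TP"] + k["FP"] > 0) 100 * k["TP"] / (k["TP"] + k["FP"])
          else NA_real_
    f1 <- if (!is.na(sn) && !is.na(pr) && (sn + pr) > 0) f1_score(sn, pr)
          else NA_real_
    data.frame(class = stage_levels()[c],
               Snc = unname(sn),
               Spc = unname(100 * k["TN"] / (k["FP"] + k["TN"])),
               Prc = unname(pr),
               F1c = unname(f1),
               ACCc = unname(100 * (k["TP"] + k["TN"]) / N))
  })
  res <- do.call(rbind, out)
  if (anyNA(res$Prc))
    warning("class(es) never predicted: ",
            paste(res$class[is.na(res$Prc)], collapse = ", "),
            "; precision/F1 undefined (NA), counted as 0 in macro-averages")
  class(res) <- c("per_class_metrics", "data.frame")
  res
}

#' Overall (macro) metrics
#'
#' Overall accuracy `ACC = 100 * trace / N`, and the unweighted macro
#' averages over the five classes: macro F1 (`MF1`), overall sensitivity
#' (`Sn`) and overall specificity (`Sp`). Undefined per-class values
#' enter the macro averages as 0.
#'
#' @param cm a [confusion_matrix()].
#' @param pcm optional precomputed [per_class_metrics()] for `cm`.
#' @return named list with `ACC`, `MF1`, `Sn`, `Sp` (percent).
#' @export
overall_metrics <- function(cm, pcm = NULL) {
  stopifnot(inherits(cm, "stage_confusion"))
  if (is.null(pcm)) pcm <- suppressWarnings(per_class_metrics(cm))
  zero_na <- function(x) ifelse(is.na(x), 0, x)
  list(ACC = 100 * sum(diag(unclass(cm))) / sum(cm),
       MF1 = mean(zero_na(pcm$F1c)),
       Sn = mean(zero_na(pcm$Snc)),
       Sp = mean(zero_na(pcm$Spc)))
}

#' Macro (unweighted) mean of per-class values
#'
#' @param x numeric vector of per-class metric values.
#' @return their unweighted mean, with `NA` treated as 0.
#' @export
macro_mean <- function(x) mean(ifelse(is.na(x), 0, x))

#' Summarize per-fold metrics across cross-validation folds
#'
#' Per class and metric, the mean and population standard deviation
#' across folds, plus the unweighted across-class average of each metric
#' column (the headline summary numbers).
#'
#' @param per_fold list of [per_class_metrics()] data.frames.
#' @return list with `mean` (5 x 5 data.frame), `sd` (population),
#'   `class_average` (named vector: across-class average of each metric's
#'   fold-mean).
#' @export
cv_summary <- function(per_fold) {
  stopifnot(length(per_fold) >= 1L)
  cols <- c("Snc", "Spc", "Prc", "F1c", "ACCc")
  arr <- simplify2array(lapply(per_fold, function(d)
    as.matrix(d[, cols])))                 # 5 x 5 x n_folds
  pop_sd <- function(v) sqrt(mean((v - mean(v))^2))
  mean_df <- as.data.frame(apply(arr, c(1, 2), mean))
  sd_df <- as.data.frame(apply(arr, c(1, 2), pop_sd))
  mean_df <- cbind(class = stage_levels(), mean_df)
  sd_df <- cbind(class = stage_levels(), sd_df)
  list(mean = mean_df, sd = sd_df,
       class_average = colMeans(mean_df[, cols]))
}

#' Write a metrics report
#'
#' CSV or JSON mirrors of the package's report tables: per-class rows
#' (`Snc`, `Spc`, `Prc`, `F1c`, `ACCc`) plus the overall metrics
#' (`ACC`, `MF1`, `Sn`, `Sp`). CSV values are printed with one decimal
#' (report style); JSON keeps full precision.
#'
#' @param pcm a [per_class_metrics()].
#' @param overall an [overall_metrics()] list.
#' @param path output path; format from extension (".csv" or ".json").
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(pcm, overall, path) {
  if (grepl("\\.json$", path)) {
    jsonlite::write_json(list(per_class = pcm, overall = overall), path,
                         auto_unbox = TRUE, digits = NA, na = "null",
                         dataframe = "rows")
  } else {
    d <- pcm
    d[, -1] <- round(d[, -1], 1)
    utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
    cat("\noverall,ACC,MF1,Sn,Sp\n",
        sprintf(",%.1f,%.1f,%.1f,%.1f\n", overall$ACC, overall$MF1,
                overall$Sn, overall$Sp),
        file = path, append = TRUE, sep = "")
  }
  invisible(path)
}
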