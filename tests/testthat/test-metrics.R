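test_that("confusion matrix counts pairs exactly", {
  perfect <- confusion_matrix(stage_levels(), stage_levels())
  expect_identical(sum(diag(unclass(perfect))), 5L)
  expect_identical(sum(perfect), 5L)

  one <- confusion_matrix("W", "N2")
  expect_identical(unname(unclass(one)["W", "N2"]), 1L)
  expect_identical(sum(one), 1L)

  set.seed(1)
  tr <- sample(stage_levels(), 500, TRUE)
  pr <- sample(stage_levels(), 500, TRUE)
  cm <- confusion_matrix(tr, pr)
  # brute-force pairwise tally oracle
  for (i in 1:5) for (j in 1:5)
    expect_identical(unname(unclass(cm)[i, j]),
                     sum(tr == stage_levels()[i] & pr == stage_levels()[j]))

  expect_error(confusion_matrix(c("W", "N1"), "W"), "equal length")
  expect_error(confusion_matrix("W", "Q"), "invalid stage")
})

test_that("one-vs-all counts satisfy their accounting identities", {
  set.seed(2)
  for (r in 1:20) {
    cm <- confusion_matrix(sample(stage_levels(), 200, TRUE),
                           sample(stage_levels(), 200, TRUE))
    for (c in 1:5) {
      k <- sleepstager:::ova_counts(cm, c)
      expect_identical(unname(k["TP"] + k["FN"]), sum(unclass(cm)[c, ]))
      expect_identical(unname(k["TP"] + k["FP"]), sum(unclass(cm)[, c]))
      expect_identical(unname(sum(k)), sum(cm))
    }
  }
})

test_that("per-class metrics reproduce published worked examples", {
  # printed per-class sensitivity/precision pairs reproduce printed F1
  expect_equal(round(f1_score(85.8, 80.9), 1), 83.3)
  # perfect prediction: every metric 100
  cm <- confusion_matrix(rep(stage_levels(), 3), rep(stage_levels(), 3))
  pcm <- per_class_metrics(cm)
  expect_true(all(as.matrix(pcm[, -1]) == 100))
})

test_that("undefined precision follows the documented policy", {
  # N3 never predicted
  truth <- c("W", "W", "N2", "N3", "REM")
  pred <- c("W", "W", "N2", "N2", "REM")
  cm <- confusion_matrix(truth, pred)
  expect_warning(pcm <- per_class_metrics(cm), "never predicted")
  n3 <- pcm[pcm$class == "N3", ]
  expect_true(is.na(n3$Prc) && is.na(n3$F1c))
  # brute-force one-vs-all cross-check of the defined columns
  expect_equal(n3$Snc, 0)
  expect_equal(n3$Spc, 100)           # no false positives for N3
  expect_equal(n3$ACCc, 100 * 4 / 5)
  ov <- overall_metrics(cm, suppressWarnings(per_class_metrics(cm)))
  # NA enters macro means as zero
  expect_equal(ov$MF1, mean(ifelse(is.na(pcm$F1c), 0, pcm$F1c)))
})

test_that("overall metrics match the published macro averages", {
  expect_equal(round(macro_mean(c(83.3, 44.9, 81.7, 70.2, 69.8)), 1), 70.0)
  expect_equal(round(macro_mean(c(85.3, 44.3, 86.2, 68.9, 75.4)), 1), 72.0)
  expect_equal(round(macro_mean(c(83.8, 57.1, 81.1, 76.3, 80.2)), 1), 75.7)

  cm <- confusion_matrix(rep(stage_levels(), 4), rep(stage_levels(), 4))
  expect_equal(overall_metrics(cm)$ACC, 100)
})

test_that("macro F1 equals its recomputation on random confusions", {
  set.seed(4)
  for (r in 1:100) {
    cm <- confusion_matrix(sample(stage_levels(), 60, TRUE),
                           sample(stage_levels(), 60, TRUE))
    pcm <- suppressWarnings(per_class_metrics(cm))
    ov <- overall_metrics(cm, pcm)
    # independent recomputation from raw one-vs-all counts
    f1s <- vapply(1:5, function(c) {
      k <- sleepstager:::ova_counts(cm, c)
      sn <- 100 * k["TP"] / (k["TP"] + k["FN"])
      pr <- 100 * k["TP"] / (k["TP"] + k["FP"])
      f <- 2 * sn * pr / (sn + pr)
      if (!is.finite(f)) 0 else f
    }, numeric(1))
    expect_equal(ov$MF1, mean(f1s), tolerance = 1e-12)
    expect_equal(ov$ACC, 100 * sum(diag(unclass(cm))) / sum(cm))
  }
})

test_that("metrics are invariant under simultaneous class permutation", {
  set.seed(5)
  tr <- sample(stage_levels(), 300, TRUE)
  pr <- sample(stage_levels(), 300, TRUE)
  perm <- c(N2 = "W", W = "N2", N1 = "REM", REM = "N1", N3 = "N3")
  ov1 <- overall_metrics(confusion_matrix(tr, pr))
  ov2 <- overall_metrics(confusion_matrix(perm[tr], perm[pr]))
  expect_equal(ov1$ACC, ov2$ACC)
  expect_equal(ov1$MF1, ov2$MF1)
  expect_equal(ov1$Sn, ov2$Sn)
  expect_equal(ov1$Sp, ov2$Sp)
})

test_that("cv_summary aggregates folds with population std", {
  mk <- function(snc) {
    structure(data.frame(class = stage_levels(), Snc = snc, Spc = 90,
                         Prc = 80, F1c = 75, ACCc = 85),
              class = c("per_class_metrics", "data.frame"))
  }
  cs <- cv_summary(list(mk(c(80, 60, 82, 75, 81)), mk(c(84, 64, 78, 77, 83))))
  expect_equal(cs$mean$Snc, c(82, 62, 80, 76, 82))
  expect_equal(cs$sd$Snc, c(2, 2, 2, 1, 1))       # population flavor
  expect_equal(unname(cs$class_average["Snc"]), mean(c(82, 62, 80, 76, 82)))

  same <- cv_summary(list(mk(c(80, 60, 82, 75, 81)),
                          mk(c(80, 60, 82, 75, 81))))
  expect_true(all(same$sd$Snc == 0))

  # published 20-fold per-class accuracies average to the headline value
  expect_equal(round(macro_mean(c(92.5, 85.1, 85.7, 96.5, 96.1)), 1), 91.2)
})

test_that("report writers emit parseable CSV and JSON", {
  cm <- confusion_matrix(rep(stage_levels(), 10),
                         sample(rep(stage_levels(), 10)))
  pcm <- suppressWarnings(per_class_metrics(cm))
  ov <- overall_metrics(cm, pcm)
  pj <- tempfile(fileext = ".json"); pc <- tempfile(fileext = ".csv")
  write_metrics_report(pcm, ov, pj)
  write_metrics_report(pcm, ov, pc)
  back <- jsonlite::read_json(pj)
  expect_equal(back$overall$ACC, ov$ACC, tolerance = 1e-9)
  expect_length(back$per_class, 5L)
  lines <- readLines(pc)
  expect_true(any(grepl("^overall", lines)))
  unlink(c(pj, pc))
})
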