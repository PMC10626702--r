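# The three published confusion matrices (lesion vs normal on 80 images)
# used as worked examples throughout.
cm_glcm <- confusion_counts(TP = 40, TN = 39, FP = 0, FN = 1)
cm_glrlm <- confusion_counts(TP = 36, TN = 40, FP = 2, FN = 2)
cm_wavelet <- confusion_counts(TP = 43, TN = 30, FP = 3, FN = 4)

test_that("confusion_matrix tabulates the four cells", {
  truth <- rep(c("lesion", "normal"), each = 40)
  cm <- confusion_matrix(truth, truth, "lesion")
  expect_equal(unclass(cm)[c("TP", "TN", "FP", "FN")],
               list(TP = 40L, TN = 40L, FP = 0L, FN = 0L))
  # inverting every prediction swaps TP<->FN and TN<->FP
  inv <- ifelse(truth == "lesion", "normal", "lesion")
  cmi <- confusion_matrix(truth, inv, "lesion")
  expect_equal(c(cmi$TP, cmi$TN, cmi$FP, cmi$FN), c(0, 0, 40, 40))
  # multi-label positive class membership
  t2 <- c("cyst", "tumor", "abscess", "normal")
  p2 <- c("lesion", "normal", "lesion", "lesion")
  cm2 <- confusion_matrix(t2, p2, positive_class = c("cyst", "tumor", "abscess", "lesion"))
  expect_equal(c(cm2$TP, cm2$TN, cm2$FP, cm2$FN), c(2, 0, 1, 1))
  expect_error(confusion_matrix("a", c("a", "b")), "length mismatch")
})

test_that("metrics reproduce the published worked examples", {
  expect_equal(accuracy(cm_glrlm), 95)
  expect_equal(accuracy(cm_wavelet), 91)          # 91.25 rounds to 91
  expect_equal(accuracy(cm_wavelet, NULL), 91.25)
  expect_equal(accuracy(cm_glcm), 99)             # (40+39)/80 = 98.75
  expect_equal(mcc(cm_wavelet), 0.82)
  expect_equal(specificity(cm_glcm), 100)
  expect_equal(ppv(cm_glcm), 100)
  expect_equal(specificity(cm_glrlm), 95)         # 40/42 = 95.24
  expect_equal(ppv(cm_wavelet), 93)               # 43/46 = 93.48
  expect_equal(sensitivity(cm_glcm), 98)          # 40/41 = 97.56
})

test_that("metric degenerate cases and ranges", {
  expect_equal(accuracy(confusion_counts(0, 0, 3, 5)), 0)
  expect_equal(mcc(confusion_counts(40, 40, 0, 0)), 1)     # perfect
  expect_equal(mcc(confusion_counts(0, 0, 40, 40)), -1)    # inverted
  deg <- mcc(confusion_counts(0, 5, 0, 0))
  expect_equal(as.numeric(deg), 0)
  expect_true(isTRUE(attr(deg, "degenerate")))
  expect_warning(v <- sensitivity(confusion_counts(0, 5, 1, 0)), "undefined")
  expect_true(is.na(v))
  expect_equal(suppressWarnings(sensitivity(confusion_counts(7, 0, 0, 0))), 100)
  expect_error(confusion_counts(0, 0, 0, 0), "empty")

  # MCC of random balanced predictions hovers near 0
  ms <- vapply(1:200, function(s) {
    set.seed(s)
    truth <- rep(c("lesion", "normal"), each = 25)
    pred <- sample(truth)
    mcc(confusion_matrix(truth, pred, "lesion"), digits = NULL)
  }, numeric(1))
  expect_lt(abs(mean(ms)), 0.05)
})

test_that("ROC curve endpoints, ties, and the Mann-Whitney identity", {
  truth <- rep(c("lesion", "normal"), each = 10)
  r <- roc_curve(c(2:11, 1:10 - 10), truth)      # perfectly separated
  expect_equal(auc(r), 1)
  expect_equal(r$points[1, ], data.frame(fpf = 0, tpf = 0))
  expect_equal(unlist(r$points[nrow(r$points), ]), c(fpf = 1, tpf = 1))

  expect_equal(auc(roc_curve(rep(1, 20), truth)), 0.5)  # all ties

  for (seed in 1:10) {
    set.seed(seed)
    n <- 50
    truth <- sample(c("lesion", "normal"), n, replace = TRUE,
                    prob = c(0.6, 0.4))
    if (length(unique(truth)) < 2) next
    scores <- round(rnorm(n), 1)                 # rounding forces ties
    r <- roc_curve(scores, truth)
    expect_equal(auc(r), oracle_auc(scores, truth == "lesion"),
                 tolerance = 1e-12)
    expect_true(all(diff(r$points$fpf) >= 0))
    expect_true(all(diff(r$points$tpf) >= 0))
  }
  expect_error(roc_curve(1:3, rep("lesion", 3)), "both classes")
})

test_that("metrics_report carries rounded and full-precision values", {
  rep_ <- metrics_report(cm_wavelet)
  expect_equal(rep_$AC, 91)
  expect_equal(rep_$full$AC, 91.25)
  expect_equal(rep_$MCC, 0.82)
  expect_equal(rep_$SN, 91)        # 43/47 = 91.49
  expect_equal(rep_$SP, 91)        # 30/33 = 90.91
  expect_equal(rep_$PPV, 93)
})

test_that("evaluate_method runs end to end on a toy table", {
  set.seed(42)
  df <- data.frame(image_id = sprintf("i%02d", 1:60),
                   label = rep(c("cyst", "normal"), each = 30),
                   f1 = c(rnorm(30, 2), rnorm(30, -2)),
                   f2 = rnorm(60), stringsAsFactors = FALSE)
  ev <- evaluate_method(feature_table(df, "toy"), seed = 3)
  expect_s3_class(ev$report, "metrics_report")
  expect_true(ev$roc$auc >= 0 && ev$roc$auc <= 1)
  expect_true(abs(ev$report$full$MCC) <= 1)
  cmp <- compare_methods(list(toy = ev))
  expect_equal(cmp$measure, c("AC", "MCC", "SN", "SP", "PPV", "AUC"))

  ev2 <- evaluate_method(feature_table(df, "toy"), seed = 3, repeats = 3)
  expect_length(ev2$repeat_reports, 3)
  expect_true(all(is.finite(ev2$mean_metrics)))
})
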