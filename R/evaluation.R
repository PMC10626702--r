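#' Confusion matrix for a two-class task
#'
#' The positive class is "abnormal" (lesion present): TP counts rows that are
#' positive in both truth and prediction, TN rows negative in both, FP rows
#' predicted positive but actually negative, FN the reverse.
#'
#' @param truth,predicted equal-length label vectors.
#' @param positive_class label(s) counting as positive; membership is tested
#'   with `%in%`, so a vector like `c("cyst", "tumor", "abscess")` works.
#' @return object of class `"confusion_matrix"`: list with integer
#'   `TP`, `TN`, `FP`, `FN`.
#' @export
confusion_matrix <- function(truth, predicted, positive_class = "lesion") {
  if (length(truth) != length(predicted)) {
    stop(sprintf("length mismatch: %d truth vs %d predicted labels",
                 length(truth), length(predicted)))
  }
  tp_ <- truth %in% positive_class
  pp_ <- predicted %in% positive_class
  structure(list(TP = sum(tp_ & pp_), TN = sum(!tp_ & !pp_),
                 FP = sum(!tp_ & pp_), FN = sum(tp_ & !pp_)),
            class = "confusion_matrix")
}

#' Build a confusion matrix directly from counts
#'
#' Convenience constructor for worked examples where the four cells are given
#' (e.g. a published confusion table) rather than derived from label vectors.
#'
#' @param TP,TN,FP,FN non-negative integer counts, total >= 1.
#' @export
confusion_counts <- function(TP, TN, FP, FN) {
  cells <- c(TP = TP, TN = TN, FP = FP, FN = FN)
  if (any(cells < 0) || any(cells != round(cells))) {
    stop("counts must be non-negative integers")
  }
  if (sum(cells) < 1) stop("empty confusion matrix")
  structure(lapply(as.list(cells), as.integer), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  m <- matrix(c(x$TN, x$FN, x$FP, x$TP), 2, 2,
              dimnames = list(actual = c("negative", "positive"),
                              predicted = c("negative", "positive")))
  print(m)
  invisible(x)
}

cm_total <- function(cm) cm$TP + cm$TN + cm$FP + cm$FN

round_maybe <- function(x, digits) if (is.null(digits)) x else round(x, digits)

#' Classification metrics from a confusion matrix
#'
#' Percent-scale metrics default to the nearest integer percent and MCC to
#' two decimals (the reporting precision of the reference tables); pass
#' `digits = NULL` for full precision.
#'
#' * `accuracy`: `(TP + TN) / (TP + FP + TN + FN) * 100`
#' * `mcc`: `(TP*TN - FP*FN) / sqrt((TP+FP)(TP+FN)(TN+FP)(TN+FN))`, in
#'   `[-1, 1]`; +1 is perfect prediction, 0 no better than chance, -1
#'   complete disagreement. A zero factor in the denominator gives 0 with a
#'   `"degenerate"` attribute set.
#' * `sensitivity`: `TP / (TP + FN) * 100`
#' * `specificity`: `TN / (TN + FP) * 100`
#' * `ppv`: `TP / (TP + FP) * 100`
#'
#' The three rate metrics return a flagged `NA` (with a warning) when their
#' denominator is zero — undefined, not silently 0.
#'
#' @param cm a `"confusion_matrix"`.
#' @param digits rounding digits, or `NULL` for full precision.
#' @return a single numeric value.
#' @export
accuracy <- function(cm, digits = 0) {
  n <- cm_total(cm)
  if (n < 1) stop("empty confusion matrix")
  round_maybe((cm$TP + cm$TN) / n * 100, digits)
}

#' @rdname accuracy
#' @export
mcc <- function(cm, digits = 2) {
  den <- prod(c(cm$TP + cm$FP, cm$TP + cm$FN, cm$TN + cm$FP, cm$TN + cm$FN))
  if (den == 0) {
    out <- 0
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  round_maybe((cm$TP * cm$TN - cm$FP * cm$FN) / sqrt(den), digits)
}

rate_metric <- function(num, den, what, digits) {
  if (den == 0) {
    warning(what, " undefined: zero denominator")
    out <- NA_real_
    attr(out, "degenerate") <- TRUE
    return(out)
  }
  round_maybe(num / den * 100, digits)
}

#' @rdname accuracy
#' @export
sensitivity <- function(cm, digits = 0) {
  rate_metric(cm$TP, cm$TP + cm$FN, "sensitivity", digits)
}

#' @rdname accuracy
#' @export
specificity <- function(cm, digits = 0) {
  rate_metric(cm$TN, cm$TN + cm$FP, "specificity", digits)
}

#' @rdname accuracy
#' @export
ppv <- function(cm, digits = 0) {
  rate_metric(cm$TP, cm$TP + cm$FP, "ppv", digits)
}

#' Full metrics report
#'
#' @inheritParams accuracy
#' @return object of class `"metrics_report"`: rounded `AC`, `MCC`, `SN`,
#'   `SP`, `PPV` plus a `full` sub-list at full precision and the confusion
#'   matrix itself.
#' @export
metrics_report <- function(cm) {
  suppressWarnings(structure(list(
    AC = accuracy(cm), MCC = mcc(cm),
    SN = sensitivity(cm), SP = specificity(cm), PPV = ppv(cm),
    full = list(AC = accuracy(cm, NULL), MCC = mcc(cm, NULL),
                SN = sensitivity(cm, NULL), SP = specificity(cm, NULL),
                PPV = ppv(cm, NULL)),
    confusion = cm
  ), class = "metrics_report"))
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf("AC %s%%  MCC %s  SN %s%%  SP %s%%  PPV %s%%\n",
              x$AC, x$MCC, x$SN, x$SP, x$PPV))
  invisible(x)
}

#' ROC curve and area under it
#'
#' Sweeps a threshold over the distinct decision scores (ties grouped) and
#' records the (false positive fraction, true positive fraction) points from
#' `(0, 0)` to `(1, 1)`. The AUC is the trapezoidal area, which for grouped
#' ties equals the Mann-Whitney probability of correct ranking with half
#' credit for ties (an identity the test suite checks against an O(n^2)
#' pairwise oracle).
#'
#' @param scores finite numeric decision scores (larger = more positive).
#' @param truth label vector.
#' @param positive_class label(s) counting as positive.
#' @return object of class `"roc_curve"`: data frame `points` with columns
#'   `fpf`, `tpf`, and the scalar `auc`.
#' @export
roc_curve <- function(scores, truth, positive_class = "lesion") {
  stopifnot(length(scores) == length(truth), all(is.finite(scores)))
  pos <- truth %in% positive_class
  np <- sum(pos); nn <- sum(!pos)
  if (np == 0 || nn == 0) stop("both classes must be present to sweep a ROC curve")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; p <- pos[o]
  grp <- cumsum(!duplicated(s))                 # tie groups, high to low
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- which(!duplicated(grp, fromLast = TRUE))
  pts <- data.frame(fpf = c(0, fp[last] / nn), tpf = c(0, tp[last] / np))
  auc <- sum(diff(pts$fpf) * (utils::head(pts$tpf, -1) + utils::tail(pts$tpf, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @rdname roc_curve
#' @param curve a `"roc_curve"` object.
#' @export
auc <- function(curve) curve$auc

#' Train, predict and score one feature method end to end
#'
#' Splits a feature table (stratified hold-out), fits the maximum-margin
#' classifier on the training part, predicts the held-out part, and returns
#' the metrics report plus ROC. With `repeats > 1` the split/fit/score cycle
#' is repeated under derived seeds and the full-precision metrics are
#' averaged (a reconstruction of repeated hold-out validation; per-repeat
#' reports are kept).
#'
#' @param table a [feature_table()].
#' @param train_fraction per-class training fraction (default 2/3).
#' @param seed split seed.
#' @param repeats number of seeded repetitions (default 1).
#' @param ... passed to [fit_svm()] (kernel, C, gamma, positive_classes...).
#' @return object of class `"method_evaluation"`: `report`
#'   ([metrics_report()] of the first split), `roc`, `predictions`, `model`,
#'   `method`, and with repeats the `mean_metrics` and `repeat_reports`.
#' @export
evaluate_method <- function(table, train_fraction = 2 / 3, seed = 1L,
                            repeats = 1L, ...) {
  one <- function(sd) {
    sp <- split_dataset(table, train_fraction, seed = sd)
    if (nrow(sp$test) == 0L) stop("empty test split")
    model <- fit_svm(sp$train, ...)
    pred <- predict(model, sp$test)
    cm <- confusion_matrix(pred$truth, pred$predicted,
                           positive_class = model$positive_label)
    list(report = metrics_report(cm),
         roc = roc_curve(pred$score, pred$truth,
                         positive_class = model$positive_label),
         predictions = pred, model = model)
  }
  first <- one(seed)
  out <- c(first, list(method = attr(table, "method")))
  if (repeats > 1L) {
    reps <- lapply(seq_len(repeats), function(k) {
      one((as.integer(seed) + 7919L * (k - 1L)) %% 2147483629L)$report
    })
    out$repeat_reports <- reps
    out$mean_metrics <- colMeans(do.call(rbind, lapply(reps, function(r) {
      unlist(r$full)
    })))
  }
  structure(out, class = "method_evaluation")
}

#' @export
print.method_evaluation <- function(x, ...) {
  cat(sprintf("method %s: ", x$method %||% "?"))
  print(x$report)
  cat(sprintf("AUC %.4f\n", x$roc$auc))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Side-by-side comparison of feature methods
#'
#' @param evaluations named list of `"method_evaluation"` objects.
#' @return data frame with one row per measure (AC, MCC, SN, SP, PPV, AUC)
#'   and one column per method — the layout of the reference evaluation
#'   table.
#' @export
compare_methods <- function(evaluations) {
  cols <- lapply(evaluations, function(ev) {
    r <- ev$report
    c(AC = r$AC, MCC = r$MCC, SN = r$SN, SP = r$SP, PPV = r$PPV,
      AUC = round(ev$roc$auc, 4))
  })
  df <- as.data.frame(cols)
  cbind(measure = rownames(df), df, row.names = NULL)
}
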