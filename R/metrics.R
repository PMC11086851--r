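#' Confusion matrix for MI/MCI classification
#'
#' MI is the positive class: `tp` and `fn` count MI participants, `fp` and
#' `tn` count MCI participants.
#'
#' @param tp,fn,fp,tn Non-negative integer counts.
#' @return An object of class `confusion_matrix`.
#' @export
confusion_matrix <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix counts must be non-negative integers",
         call. = FALSE)
  }
  counts <- as.integer(counts)
  structure(list(tp = counts[1L], fn = counts[2L], fp = counts[3L],
                 tn = counts[4L]), class = "confusion_matrix")
}

#' @export
print.confusion_matrix <- function(x, ...) {
  cat(sprintf("<confusion_matrix> n=%d  TP=%d FN=%d FP=%d TN=%d\n",
              x$tp + x$fn + x$fp + x$tn, x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

# pooled confusion matrix from label vectors (MI positive)
cm_from_predictions <- function(truth, predicted) {
  y <- encode_labels(truth)
  yhat <- encode_labels(predicted)
  stopifnot(length(y) == length(yhat))
  confusion_matrix(tp = sum(y == 1 & yhat == 1),
                   fn = sum(y == 1 & yhat == 0),
                   fp = sum(y == 0 & yhat == 1),
                   tn = sum(y == 0 & yhat == 0))
}

#' Classification metrics from a confusion matrix
#'
#' Accuracy `(TP+TN)/(TP+FP+TN+FN)`, sensitivity `TP/(TP+FN)` (MI
#' detection), specificity `TN/(TN+FP)` (MCI detection) as percentages, and
#' the F1 measure `2 * precision * recall / (precision + recall)` with
#' precision `TP/(TP+FP)` on the unit interval.  A metric whose denominator
#' is zero is returned as `NA` and listed in the `undefined` attribute.
#' Values are unrounded; round only at reporting (percentages to 2
#' decimals, F1 to 3).
#'
#' @param cm A [confusion_matrix()].
#' @return Named list with `accuracy`, `sensitivity`, `specificity`
#'   (percent), `precision` and `f1` (unit interval), class `eval_metrics`.
#' @export
compute_metrics <- function(cm) {
  stopifnot(inherits(cm, "confusion_matrix"))
  n <- cm$tp + cm$fn + cm$fp + cm$tn
  if (n == 0L) stop("empty confusion matrix", call. = FALSE)
  undefined <- character(0)
  sens <- if (cm$tp + cm$fn > 0) cm$tp / (cm$tp + cm$fn) else {
    undefined <- c(undefined, "sensitivity"); NA_real_
  }
  spec <- if (cm$tn + cm$fp > 0) cm$tn / (cm$tn + cm$fp) else {
    undefined <- c(undefined, "specificity"); NA_real_
  }
  prec <- if (cm$tp + cm$fp > 0) cm$tp / (cm$tp + cm$fp) else {
    undefined <- c(undefined, "precision"); NA_real_
  }
  f1 <- if (!is.na(prec) && !is.na(sens) && (prec + sens) > 0) {
    2 * prec * sens / (prec + sens)
  } else {
    undefined <- c(undefined, "f1")
    NA_real_
  }
  structure(list(accuracy = 100 * (cm$tp + cm$tn) / n,
                 sensitivity = 100 * sens, specificity = 100 * spec,
                 precision = prec, f1 = f1, n = n,
                 undefined = undefined),
            class = "eval_metrics")
}

#' @export
print.eval_metrics <- function(x, ...) {
  cat(sprintf(
    "<eval_metrics> n=%d  accuracy %.2f%%  sensitivity %.2f%%  specificity %.2f%%  F1 %.3f\n",
    x$n, x$accuracy, x$sensitivity, x$specificity, x$f1))
  if (length(x$undefined)) {
    cat("  undefined:", paste(x$undefined, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Reconstruct integer confusion matrices from printed metrics
#'
#' Enumerates all integer `(tp, fn, fp, tn)` with `tp+fn+fp+tn = n` whose
#' accuracy, sensitivity and specificity round (2 decimals) to the given
#' percentages.  Useful for recovering the exact counts behind published
#' metric tables; flags non-uniqueness and inconsistency.
#'
#' @param n Total evaluated sample count.
#' @param accuracy,sensitivity,specificity Percentages as printed (2
#'   decimals).
#' @return List with `status` (`"unique"`, `"multiple"` or
#'   `"inconsistent"`), `solutions` (data frame of matching counts with
#'   their exact metrics), and `cm` (the [confusion_matrix()] when unique,
#'   else `NULL`).
#' @export
solve_confusion_matrix <- function(n, accuracy, sensitivity, specificity) {
  if (n < 1) stop("n must be >= 1", call. = FALSE)
  pct <- c(accuracy, sensitivity, specificity)
  if (any(pct < 0 | pct > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  grid <- expand.grid(tp = 0:n, fn = 0:n, tn = 0:n)
  grid <- grid[grid$tp + grid$fn + grid$tn <= n, ]
  grid$fp <- n - grid$tp - grid$fn - grid$tn
  pos <- grid$tp + grid$fn
  neg <- grid$tn + grid$fp
  acc <- 100 * (grid$tp + grid$tn) / n
  sens <- ifelse(pos > 0, 100 * grid$tp / pos, NA_real_)
  spec <- ifelse(neg > 0, 100 * grid$tn / neg, NA_real_)
  tol <- 0.005 + 1e-9   # printed to 2 decimals
  ok <- abs(acc - accuracy) <= tol &
    !is.na(sens) & abs(sens - sensitivity) <= tol &
    !is.na(spec) & abs(spec - specificity) <= tol
  sol <- grid[which(ok), c("tp", "fn", "fp", "tn")]
  rownames(sol) <- NULL
  if (nrow(sol)) {
    m <- lapply(seq_len(nrow(sol)), function(i)
      compute_metrics(confusion_matrix(sol$tp[i], sol$fn[i],
                                       sol$fp[i], sol$tn[i])))
    sol$accuracy <- vapply(m, `[[`, numeric(1), "accuracy")
    sol$sensitivity <- vapply(m, `[[`, numeric(1), "sensitivity")
    sol$specificity <- vapply(m, `[[`, numeric(1), "specificity")
    sol$f1 <- vapply(m, `[[`, numeric(1), "f1")
  }
  status <- if (nrow(sol) == 0L) "inconsistent"
            else if (nrow(sol) == 1L) "unique" else "multiple"
  cm <- if (status == "unique") {
    confusion_matrix(sol$tp[1L], sol$fn[1L], sol$fp[1L], sol$tn[1L])
  }
  list(status = status, solutions = sol, cm = cm)
}

#' Binomial chance-level accuracy threshold
#'
#' For `n` evaluated samples and `c` equiprobable classes, classification
#' errors under the null obey a binomial distribution.  The minimum
#' accuracy significant at level `alpha` is
#' `St(alpha) = binomial quantile(1 - alpha; n, 1/c) * 100 / n`, i.e. the
#' smallest integer success count `z` whose CDF reaches `1 - alpha`,
#' expressed as a percentage.  Also reports the exceedance probability
#' `P(z)` of attaining at least `z` correct predictions by chance.  As `n`
#' grows the threshold approaches the asymptotic chance level `100/c`
#' percent.
#'
#' @param n Sample count (>= 1).
#' @param c Number of classes (default 2).
#' @param alpha Significance level in (0, 1) (default 0.001).
#' @return List of class `significance_spec` with fields `n`, `c`, `alpha`,
#'   `z` (success-count quantile), `threshold` (percent) and `p_z`.
#' @export
chance_threshold <- function(n, c = 2, alpha = 0.001) {
  if (n < 1 || c < 2 || alpha <= 0 || alpha >= 1) {
    stop("require n >= 1, c >= 2 and alpha in (0, 1)", call. = FALSE)
  }
  z <- stats::qbinom(1 - alpha, n, 1 / c)
  structure(list(n = n, c = c, alpha = alpha, z = z,
                 threshold = z * 100 / n,
                 p_z = stats::pbinom(z - 1, n, 1 / c, lower.tail = FALSE)),
            class = "significance_spec")
}

#' @export
print.significance_spec <- function(x, ...) {
  cat(sprintf(
    "<significance_spec> n=%d, c=%d, alpha=%g: accuracy >= %.2f%% is significant (z=%d, P(z)=%.3g)\n",
    x$n, x$c, x$alpha, x$threshold, x$z, x$p_z))
  invisible(x)
}
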