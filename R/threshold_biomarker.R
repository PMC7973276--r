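## Single-analyte linear-threshold biomarkers with leave-one-out evaluation.
## Positive class throughout: "long" progression-free survival.

#' Round half away from zero
#'
#' Presentation rounding used for percentage metrics (89.47 -> 89,
#' 85.5 -> 86), as clinical biomarker tables print them. Base `round()`
#' rounds half to even and is not used for display.
#'
#' @param x Numeric vector.
#' @param digits Decimal digits to keep.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Classification metrics from confusion counts
#'
#' Computes accuracy, positive/negative predictive value, sensitivity and
#' specificity (percent scale) from a 2x2 confusion matrix with "long" PFS
#' as the positive class. A metric with a zero denominator is reported as
#' `NA` (undefined), never fabricated.
#'
#' @param tp,fn,fp,tn Non-negative integer counts: true positives, false
#'   negatives, false positives, true negatives.
#' @return Object of class `binary_metrics`: a list with the five metrics
#'   (full precision, percent scale) and the counts.
#' @export
confusion_metrics <- function(tp, fn, fp, tn) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0) || any(counts != floor(counts))) {
    stop("confusion counts must be non-negative integers")
  }
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero")
  ratio <- function(num, den) if (den == 0) NA_real_ else 100 * num / den
  structure(list(
    accuracy    = 100 * (tp + tn) / n,
    ppv         = ratio(tp, tp + fp),
    npv         = ratio(tn, tn + fn),
    sensitivity = ratio(tp, tp + fn),
    specificity = ratio(tn, tn + fp),
    counts      = counts
  ), class = "binary_metrics")
}

#' @export
print.binary_metrics <- function(x, ...) {
  fmt <- function(v) if (is.na(v)) "-" else sprintf("%d", round_half_up(v))
  cat(sprintf("accuracy %s | ppv %s | npv %s | sensitivity %s | specificity %s\n",
              fmt(x$accuracy), fmt(x$ppv), fmt(x$npv),
              fmt(x$sensitivity), fmt(x$specificity)))
  cat(sprintf("counts: tp=%d fn=%d fp=%d tn=%d\n",
              x$counts["tp"], x$counts["fn"], x$counts["fp"], x$counts["tn"]))
  invisible(x)
}

#' Reconstruct confusion counts from printed sensitivity/specificity
#'
#' Given integer-rounded sensitivity and specificity percentages and the two
#' class sizes, finds the integer confusion matrix consistent with them.
#' Errors if no solution exists or the solution is ambiguous.
#'
#' @param sensitivity,specificity Integer percentages as printed.
#' @param n_pos,n_neg Class sizes (positives = long PFS).
#' @return A `binary_metrics` object for the reconstructed counts.
#' @export
reconstruct_confusion <- function(sensitivity, specificity, n_pos, n_neg) {
  tp <- which(round_half_up(100 * (0:n_pos) / n_pos) == sensitivity) - 1L
  tn <- which(round_half_up(100 * (0:n_neg) / n_neg) == specificity) - 1L
  if (length(tp) != 1L || length(tn) != 1L) {
    stop(sprintf("confusion matrix not uniquely determined (sens %s, spec %s, n=%d/%d)",
                 sensitivity, specificity, n_pos, n_neg))
  }
  confusion_metrics(tp = tp, fn = n_pos - tp, fp = n_neg - tn, tn = tn)
}

.as_ls_labels <- function(labels) {
  labels <- as.character(labels)
  bad <- setdiff(unique(labels), c("long", "short"))
  if (length(bad)) stop("labels must be 'long'/'short'; got: ",
                        paste(bad, collapse = ", "))
  factor(labels, levels = c("long", "short"))
}

#' Fit a single-analyte linear threshold classifier
#'
#' Considers every midpoint between consecutive distinct values, in both
#' orientations, and returns the cutoff that maximizes sensitivity +
#' specificity on the supplied data (Youden-style joint optimization). Ties
#' are broken by higher accuracy, then the smaller threshold, then the
#' high-is-positive orientation, making the fit deterministic.
#'
#' @param values Numeric analyte values, one per sample.
#' @param labels Class labels, `"long"` (positive) or `"short"`.
#' @return Object of class `threshold_rule` with fields `threshold`,
#'   `direction` (`"high_is_positive"` or `"low_is_positive"`), and tie-break
#'   diagnostics. If all values are identical the rule is flagged degenerate
#'   and predicts the majority class.
#' @export
fit_threshold <- function(values, labels) {
  labels <- .as_ls_labels(labels)
  stopifnot(length(values) == length(labels))
  if (length(unique(labels)) < 2L) {
    stop("both classes must be present to fit a threshold")
  }
  n_pos <- sum(labels == "long"); n_neg <- sum(labels == "short")
  sv <- sort(unique(values))
  if (length(sv) < 2L) {
    maj <- if (n_pos >= n_neg) "long" else "short"
    return(structure(list(analyte = NA_character_, threshold = NA_real_,
                          direction = NA_character_, degenerate = TRUE,
                          majority = maj, youden = NA_real_,
                          accuracy = NA_real_),
                     class = "threshold_rule"))
  }
  mids <- (sv[-1] + sv[-length(sv)]) / 2
  best <- NULL
  for (dir_i in c("high_is_positive", "low_is_positive")) {
    for (t in mids) {
      pred_long <- if (dir_i == "high_is_positive") values >= t else values < t
      tp <- sum(pred_long & labels == "long")
      tn <- sum(!pred_long & labels == "short")
      youden <- 100 * tp / n_pos + 100 * tn / n_neg
      acc <- 100 * (tp + tn) / (n_pos + n_neg)
      cand <- list(threshold = t, direction = dir_i,
                   youden = youden, accuracy = acc)
      if (is.null(best) ||
          youden > best$youden + 1e-12 ||
          (abs(youden - best$youden) <= 1e-12 &&
           (acc > best$accuracy + 1e-12 ||
            (abs(acc - best$accuracy) <= 1e-12 && t < best$threshold)))) {
        best <- cand
      }
    }
  }
  structure(c(list(analyte = NA_character_), best,
              list(degenerate = FALSE, majority = NULL)),
            class = "threshold_rule")
}

#' @export
print.threshold_rule <- function(x, ...) {
  if (x$degenerate) {
    cat("degenerate threshold rule: predicts majority class", x$majority, "\n")
  } else {
    cat(sprintf("threshold %g, %s (sens+spec %.1f, accuracy %.1f)\n",
                x$threshold, x$direction, x$youden, x$accuracy))
  }
  invisible(x)
}

#' Predict classes from a threshold rule
#'
#' `high_is_positive` calls a sample "long" when its value is at or above
#' the threshold; `low_is_positive` when strictly below. The two
#' orientations are exact complements, so swapping class labels yields the
#' mirrored rule.
#'
#' @param object A `threshold_rule`.
#' @param values Numeric values to classify.
#' @param ... Unused.
#' @return Factor with levels `long`, `short`.
#' @export
predict.threshold_rule <- function(object, values, ...) {
  if (object$degenerate) {
    return(factor(rep(object$majority, length(values)),
                  levels = c("long", "short")))
  }
  pos <- if (object$direction == "high_is_positive") {
    values >= object$threshold
  } else {
    values < object$threshold
  }
  factor(ifelse(pos, "long", "short"), levels = c("long", "short"))
}

#' Leave-one-out evaluation of a single-analyte threshold biomarker
#'
#' For each of the n samples, fits a threshold on the remaining n-1 and
#' predicts the held-out sample; the n held-out predictions are aggregated
#' into one confusion matrix. A fold whose training data contain one class
#' only predicts that class.
#'
#' @inheritParams fit_threshold
#' @param fold_hook Optional function called as `fold_hook(i, train_idx)`
#'   for each fold; used by tests to audit fold composition.
#' @return List with `metrics` (a [confusion_metrics()] object), `counts`,
#'   and `predictions` (factor of held-out calls, one per sample).
#' @export
loo_evaluate_single <- function(values, labels, fold_hook = NULL) {
  labels <- .as_ls_labels(labels)
  n <- length(values)
  if (n < 3L) stop("leave-one-out evaluation needs at least 3 samples")
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  preds <- factor(rep(NA_character_, n), levels = c("long", "short"))
  for (i in seq_len(n)) {
    tr_lab <- labels[-i]
    if (!is.null(fold_hook)) fold_hook(i, setdiff(seq_len(n), i))
    if (length(unique(tr_lab)) < 2L) {
      preds[i] <- unique(as.character(tr_lab))
    } else {
      rule <- fit_threshold(values[-i], tr_lab)
      preds[i] <- as.character(predict(rule, values[i]))
    }
  }
  tp <- sum(preds == "long" & labels == "long")
  fn <- sum(preds == "short" & labels == "long")
  fp <- sum(preds == "long" & labels == "short")
  tn <- sum(preds == "short" & labels == "short")
  m <- confusion_metrics(tp, fn, fp, tn)
  list(metrics = m, counts = m$counts, predictions = preds)
}

#' Two-sided rank-sum (Mann-Whitney) p-value
#'
#' Exact enumeration when the pooled sample size is at most 25 and the data
#' are tie-free; otherwise the normal approximation with tie-corrected
#' variance and continuity correction.
#'
#' @param a,b Numeric vectors (the two groups).
#' @return Two-sided p-value in \[0, 1\].
#' @export
rank_sum_p <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be non-empty")
  pooled <- c(a, b)
  if (length(unique(pooled)) == 1L) return(1)   # no rank information at all
  ties <- anyDuplicated(pooled) > 0L
  exact <- (length(pooled) <= 25L) && !ties
  suppressWarnings(
    stats::wilcox.test(a, b, exact = exact, correct = TRUE)$p.value
  )
}

#' Per-analyte biomarker summary table
#'
#' For a cohort restricted to the long and short PFS groups, computes for
#' every analyte: the group medians, the full-data threshold, a two-sided
#' rank-sum p-value for the group difference, and the leave-one-out
#' classification metrics. The printed threshold is fit on the full data;
#' all metrics come from the held-out predictions.
#'
#' @param x An `immune_cohort` containing both the long and short groups
#'   (other groups are dropped).
#' @param analytes Analytes to report; defaults to all matrix columns in
#'   their stored order.
#' @return Data frame with columns `analyte, median_long, median_short,
#'   threshold, p_value, accuracy, ppv, npv, sensitivity, specificity`
#'   (metrics at full precision, percent scale). The matrix of per-sample
#'   held-out predictions is attached as attribute `"loo_predictions"`.
#' @export
analyte_table <- function(x, analytes = NULL) {
  stopifnot(inherits(x, "immune_cohort"))
  x <- subset_groups(x, c("long", "short"))
  labels <- .as_ls_labels(x$records$group)
  if (length(unique(labels)) < 2L) stop("cohort must contain both groups")
  if (is.null(analytes)) analytes <- colnames(x$matrix)
  missing <- setdiff(analytes, colnames(x$matrix))
  if (length(missing)) stop("unknown analyte(s): ", paste(missing, collapse = ", "))

  rows <- vector("list", length(analytes))
  preds <- matrix(NA_character_, nrow = nrow(x$matrix), ncol = length(analytes),
                  dimnames = list(rownames(x$matrix), analytes))
  for (j in seq_along(analytes)) {
    a <- analytes[j]
    v <- x$matrix[, a]
    rule <- fit_threshold(v, labels)
    loo <- loo_evaluate_single(v, labels)
    preds[, j] <- as.character(loo$predictions)
    m <- loo$metrics
    rows[[j]] <- data.frame(
      analyte = a,
      median_long  = group_median(v[labels == "long"]),
      median_short = group_median(v[labels == "short"]),
      threshold = rule$threshold,
      p_value = rank_sum_p(v[labels == "long"], v[labels == "short"]),
      accuracy = m$accuracy, ppv = m$ppv, npv = m$npv,
      sensitivity = m$sensitivity, specificity = m$specificity,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "loo_predictions") <- preds
  out
}

#' Write an analyte table as TSV
#'
#' Metric percentages are rounded half-away-from-zero to integers and
#' undefined cells rendered as `-`, matching how such tables are printed.
#'
#' @param tab Data frame from [analyte_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_analyte_table <- function(tab, path) {
  fmt_pct <- function(v) ifelse(is.na(v), "-",
                                sprintf("%d", round_half_up(v)))
  out <- data.frame(
    analyte = tab$analyte,
    median_long = tab$median_long,
    median_short = tab$median_short,
    threshold = ifelse(is.na(tab$threshold), "-", as.character(tab$threshold)),
    p_value = ifelse(is.na(tab$p_value), "-",
                     sprintf("%.4g", tab$p_value)),
    accuracy = fmt_pct(tab$accuracy), ppv = fmt_pct(tab$ppv),
    npv = fmt_pct(tab$npv), sensitivity = fmt_pct(tab$sensitivity),
    specificity = fmt_pct(tab$specificity),
    stringsAsFactors = FALSE
  )
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
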