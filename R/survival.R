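## Kaplan-Meier estimation, the log-rank test with an O/E hazard ratio, and
## expression-quartile stratification. The estimator and test statistics
## come from the survival package; the hazard ratio is the Mantel-Haenszel
## (observed/expected) estimator that accompanies a log-rank comparison,
## not a Cox fit.

#' Kaplan-Meier product-limit estimate
#'
#' @param time Months (non-negative). Zero times are kept but flagged with
#'   a warning rather than dropped.
#' @param event Logical; `TRUE` when the event (progression/death) was
#'   observed, `FALSE` when censored.
#' @return Object of class `km_curve`: data frame `time, n_risk, n_event,
#'   n_censor, surv` (one row per distinct observed time), with `S(0) = 1`
#'   implicit.
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) == length(event), length(time) >= 1)
  if (any(time < 0)) stop("negative survival times")
  if (any(time == 0)) warning("zero survival time(s) retained")
  fit <- survival::survfit(survival::Surv(time, event) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  structure(list(curve = out, n = length(time)), class = "km_curve")
}

#' @export
print.km_curve <- function(x, ...) {
  cat(sprintf("Kaplan-Meier curve, n = %d, %d distinct times\n",
              x$n, nrow(x$curve)))
  print(utils::head(x$curve, 10))
  invisible(x)
}

#' Log-rank test with Mantel-Haenszel hazard ratio
#'
#' Compares two survival arms with the log-rank (Mantel-Haenszel) chi-square
#' test and reports the observed/expected hazard ratio
#' HR = (O_a/E_a)/(O_b/E_b) with its 95% confidence interval
#' exp(log HR +/- 1.96 sqrt(1/E_a + 1/E_b)). Swapping the arms inverts the
#' HR and mirrors the interval; the p-value is unchanged.
#'
#' @param arm_a,arm_b Data frames with columns `time` and `event`
#'   (logical), e.g. the "high" and "low" expression arms.
#' @return Object of class `logrank_result`: `chi2`, `p`, `obs`/`exp` per
#'   arm, `hr`, `ci95`, arm sizes. If an arm has zero expected events the
#'   HR is `NA` (undefined) while the p-value is still computed when
#'   possible.
#' @export
logrank_hr <- function(arm_a, arm_b) {
  for (arm in list(arm_a, arm_b)) {
    stopifnot(is.data.frame(arm), all(c("time", "event") %in% names(arm)))
  }
  time <- c(arm_a$time, arm_b$time)
  event <- c(arm_a$event, arm_b$event)
  grp <- factor(rep(c("a", "b"), c(nrow(arm_a), nrow(arm_b))),
                levels = c("a", "b"))
  if (sum(event) == 0) stop("no events in either arm")
  sd <- survival::survdiff(survival::Surv(time, event) ~ grp)
  obs <- sd$obs; expd <- sd$exp
  chi2 <- sd$chisq
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  if (any(expd == 0) || obs[2] == 0) {
    hr <- NA_real_; ci <- c(NA_real_, NA_real_)
  } else {
    hr <- (obs[1] / expd[1]) / (obs[2] / expd[2])
    se <- sqrt(1 / expd[1] + 1 / expd[2])
    ci <- exp(log(hr) + c(-1, 1) * 1.96 * se)
  }
  structure(list(chi2 = chi2, p = p,
                 obs = stats::setNames(obs, c("a", "b")),
                 exp = stats::setNames(expd, c("a", "b")),
                 hr = hr, ci95 = ci,
                 n = c(a = nrow(arm_a), b = nrow(arm_b))),
            class = "logrank_result")
}

#' @export
print.logrank_result <- function(x, ...) {
  cat(sprintf("log-rank chi2 = %.4f, p = %.4g\n", x$chi2, x$p))
  if (is.na(x$hr)) {
    cat("HR undefined (zero expected or observed events in an arm)\n")
  } else {
    cat(sprintf("HR = %.4f [%.4f-%.4f]\n", x$hr, x$ci95[1], x$ci95[2]))
  }
  invisible(x)
}

#' Top/bottom expression quartile groups
#'
#' Defines "low" and "high" expression arms as the bottom and top quartiles
#' of an expression vector. The per-arm size defaults to n/4 rounded half
#' up (378 samples give 95 per arm); boundary ties are resolved by stable
#' input order.
#'
#' @param expression Named numeric vector (names = sample ids) or plain
#'   vector (indices used as ids).
#' @param n_per_group Optional arm size; must not exceed n/2.
#' @return List with `low` and `high` id vectors and `n_per_group`.
#' @export
quartile_groups <- function(expression, n_per_group = NULL) {
  n <- length(expression)
  if (n < 4L) stop("need at least 4 samples")
  ids <- names(expression)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  if (is.null(n_per_group)) n_per_group <- round_half_up(n / 4)
  if (n_per_group > n / 2) stop("n_per_group exceeds half the cohort")
  ord <- order(expression)               # stable: ties keep input order
  list(low = ids[ord[seq_len(n_per_group)]],
       high = ids[ord[seq.int(n - n_per_group + 1L, n)]],
       n_per_group = n_per_group)
}

#' Extract survival records from a cohort
#'
#' @param x An `immune_cohort`.
#' @param endpoint `"pfs"` or `"os"`.
#' @param use_alt_months Use the alternative (maintenance-adjusted)
#'   parenthetical months where recorded, primary months elsewhere.
#' @return Data frame `sample_id, time, event, group`; `event` is `TRUE`
#'   unless the record is censored.
#' @export
parse_survival_records <- function(x, endpoint = c("pfs", "os"),
                                   use_alt_months = FALSE) {
  stopifnot(inherits(x, "immune_cohort"))
  endpoint <- match.arg(endpoint)
  r <- x$records
  time <- r[[paste0(endpoint, "_months")]]
  cens <- r[[paste0(endpoint, "_censored")]]
  if (use_alt_months) {
    alt <- r[[paste0(endpoint, "_alt")]]
    time <- ifelse(is.na(alt), time, alt)
  }
  if (any(time == 0)) warning("zero survival time(s) retained")
  data.frame(sample_id = r$sample_id, time = time, event = !cens,
             group = r$group, stringsAsFactors = FALSE)
}

#' Expression-quartile log-rank survival screen
#'
#' For each analyte, splits the cohort into top and bottom expression
#' quartiles and compares their survival with [logrank_hr()].
#'
#' @param x An `immune_cohort`.
#' @param analytes Analytes to screen; default all.
#' @param endpoint `"pfs"` or `"os"`.
#' @param n_per_group Optional arm size passed to [quartile_groups()].
#' @param use_alt_months Passed to [parse_survival_records()].
#' @return Data frame `analyte, hr, ci_low, ci_high, chi2, p, n_high,
#'   n_low` (HR is high vs low expression).
#' @export
survival_table <- function(x, analytes = NULL, endpoint = c("pfs", "os"),
                           n_per_group = NULL, use_alt_months = FALSE) {
  stopifnot(inherits(x, "immune_cohort"))
  endpoint <- match.arg(endpoint)
  recs <- parse_survival_records(x, endpoint, use_alt_months)
  if (is.null(analytes)) analytes <- colnames(x$matrix)
  rows <- lapply(analytes, function(a) {
    expr <- stats::setNames(x$matrix[, a], rownames(x$matrix))
    qs <- quartile_groups(expr, n_per_group)
    arm_hi <- recs[match(qs$high, recs$sample_id), c("time", "event")]
    arm_lo <- recs[match(qs$low, recs$sample_id), c("time", "event")]
    lr <- tryCatch(logrank_hr(arm_hi, arm_lo), error = function(e) NULL)
    if (is.null(lr)) {
      data.frame(analyte = a, hr = NA_real_, ci_low = NA_real_,
                 ci_high = NA_real_, chi2 = NA_real_, p = NA_real_,
                 n_high = length(qs$high), n_low = length(qs$low),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(analyte = a, hr = lr$hr, ci_low = lr$ci95[1],
                 ci_high = lr$ci95[2], chi2 = lr$chi2, p = lr$p,
                 n_high = length(qs$high), n_low = length(qs$low),
                 stringsAsFactors = FALSE)
    }
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Convert days to months
#'
#' Helper for registry survival data recorded in days
#' (months = days * 12 / 365.25). Applied only when the caller knows the
#' metadata are in day units.
#'
#' @param days Numeric vector.
#' @return Months.
#' @export
days_to_months <- function(days) days * 12 / 365.25
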