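## Trend, correlation and two-sample statistics used downstream of the
## biomarker stages: a Wilcoxon-type trend test across ordered outcome
## groups, Spearman rank correlations, a median split, Student t tests and
## mean fold changes.

#' Wilcoxon-type trend test across ordered groups
#'
#' Tests for a monotone trend in a continuous variable across k ordered
#' groups. Each group j carries an integer score l_j (by default its
#' position in the stated order, e.g. short = 1, intermediate = 2,
#' long = 3). With midranks R_i over the pooled values, the statistic is
#' T = sum(l(g_i) R_i), standardized by its exact permutation moments
#' E(T) = (N+1)/2 * sum(n_j l_j) and
#' Var(T) = (N+1)/12 * (N sum(n_j l_j^2) - (sum(n_j l_j))^2), with the
#' variance multiplied by the tie correction 1 - sum(t^3 - t)/(N^3 - N).
#' The deviate z = (T - E(T))/sqrt(Var(T)) is referred to the standard
#' normal, two-sided. Reversing the group order negates z and leaves p
#' unchanged.
#'
#' @param values Numeric vector.
#' @param groups Factor (or character coerced in order of first appearance
#'   unless a factor is given) whose *level order* defines the trend
#'   direction, lowest score first.
#' @param scores Optional numeric group scores, one per level; defaults to
#'   `seq_along(levels(groups))`.
#' @return Object of class `trend_result` with `T`, `expected`, `variance`,
#'   `z`, `p`, `scores`, `sizes`, `N`.
#' @export
cuzick_trend <- function(values, groups, scores = NULL) {
  if (!is.factor(groups)) groups <- factor(groups, levels = unique(groups))
  groups <- droplevels(groups)
  k <- nlevels(groups)
  if (k < 2L) stop("need at least two ordered groups")
  if (any(table(groups) == 0L)) stop("every group must be non-empty")
  stopifnot(length(values) == length(groups))
  if (is.null(scores)) scores <- seq_len(k)
  stopifnot(length(scores) == k)

  N <- length(values)
  R <- rank(values)                        # midranks
  l <- scores[as.integer(groups)]
  n_j <- as.numeric(table(groups))
  Tstat <- sum(l * R)
  L1 <- sum(n_j * scores)
  L2 <- sum(n_j * scores^2)
  expected <- (N + 1) / 2 * L1
  tie_tab <- table(values)
  tie_factor <- 1 - sum(tie_tab^3 - tie_tab) / (N^3 - N)
  variance <- (N + 1) / 12 * (N * L2 - L1^2) * tie_factor
  if (variance <= 0) {
    z <- 0; p <- 1
  } else {
    z <- (Tstat - expected) / sqrt(variance)
    p <- 2 * stats::pnorm(-abs(z))
  }
  structure(list(T = Tstat, expected = expected, variance = variance,
                 z = z, p = p, scores = stats::setNames(scores, levels(groups)),
                 sizes = stats::setNames(n_j, levels(groups)), N = N),
            class = "trend_result")
}

#' @export
print.trend_result <- function(x, ...) {
  cat(sprintf("trend across %d ordered groups (N=%d): z = %.4f, p = %.4g\n",
              length(x$sizes), x$N, x$z, x$p))
  invisible(x)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of midranks; the two-sided p-value uses
#' t = r sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom for all n. A perfect
#' correlation (|r| = 1) is reported with its limiting p of 0. If either
#' vector has zero variance the correlation is undefined and returned as
#' `NA`.
#'
#' @param x,y Paired numeric vectors, n >= 3.
#' @return Object of class `corr_pair`: `r`, `p`, `n`.
#' @export
spearman_corr <- function(x, y) {
  stopifnot(length(x) == length(y))
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3L) stop("need at least 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(structure(list(r = NA_real_, p = NA_real_, n = n),
                     class = "corr_pair"))
  }
  r <- stats::cor(rank(x), rank(y))
  if (abs(r) >= 1 - 1e-15) {
    p <- 0
  } else {
    tval <- r * sqrt((n - 2) / (1 - r^2))
    p <- 2 * stats::pt(-abs(tval), df = n - 2)
  }
  structure(list(r = r, p = p, n = n), class = "corr_pair")
}

#' @export
print.corr_pair <- function(x, ...) {
  cat(sprintf("Spearman r = %.4f, p = %.4g (n = %d)\n", x$r, x$p, x$n))
  invisible(x)
}

#' Pairwise Spearman correlation matrices
#'
#' Computes [spearman_corr()] for every row x column analyte pair of a
#' cohort, e.g. gene x gene or gene x cell-type blocks for correlation
#' heat maps.
#'
#' @param x An `immune_cohort`.
#' @param rows,cols Analyte names.
#' @return List of matrices `r`, `p`, `n` (rows x cols). When
#'   `rows == cols` the `r` matrix is symmetric with unit diagonal.
#' @export
correlation_matrix <- function(x, rows, cols = rows) {
  stopifnot(inherits(x, "immune_cohort"))
  missing <- setdiff(c(rows, cols), colnames(x$matrix))
  if (length(missing)) stop("unknown analyte(s): ",
                            paste(missing, collapse = ", "))
  r <- matrix(NA_real_, length(rows), length(cols),
              dimnames = list(rows, cols))
  p <- r; n <- r
  for (i in rows) for (j in cols) {
    cp <- spearman_corr(x$matrix[, i], x$matrix[, j])
    r[i, j] <- cp$r; p[i, j] <- cp$p; n[i, j] <- cp$n
  }
  list(r = r, p = p, n = n)
}

#' Split samples at the median
#'
#' Values strictly below the median go to the low group and strictly above
#' to the high group; values equal to the median are assigned alternately
#' (in input order) to whichever side is currently smaller, low side first
#' on equality, so the two group sizes never differ by more than one.
#'
#' @param values Numeric vector, n >= 2.
#' @param ids Optional identifiers; defaults to indices.
#' @return Object of class `median_split`: `cut`, `low`, `high`.
#' @export
median_split <- function(values, ids = NULL) {
  n <- length(values)
  if (n < 2L) stop("need at least 2 values to split")
  if (is.null(ids)) ids <- seq_len(n)
  stopifnot(length(ids) == n)
  cut <- stats::median(values)
  low <- which(values < cut)
  high <- which(values > cut)
  for (i in which(values == cut)) {
    if (length(low) <= length(high)) low <- c(low, i) else high <- c(high, i)
  }
  structure(list(cut = cut, low = ids[sort(low)], high = ids[sort(high)]),
            class = "median_split")
}

#' Two-tailed Student t-test p-value
#'
#' Unpaired tests use the pooled-variance (classical Student) statistic;
#' paired tests use the one-sample t on the differences. Degenerate
#' zero-variance data follow the convention: equal means give p = 1, and
#' unequal means give the limiting p = 0 (flagged via attribute
#' `"degenerate"`).
#'
#' @param a,b Numeric vectors; with `paired = TRUE` they must align.
#' @param paired Logical.
#' @return Two-sided p-value (numeric scalar), possibly carrying attribute
#'   `degenerate = TRUE`.
#' @export
two_sample_t <- function(a, b, paired = FALSE) {
  if (paired) {
    stopifnot(length(a) == length(b))
    if (length(a) < 2L) stop("need at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      p <- if (mean(d) == 0) 1 else 0
      attr(p, "degenerate") <- TRUE
      return(p)
    }
    return(stats::t.test(a, b, paired = TRUE)$p.value)
  }
  if (length(a) < 2L || length(b) < 2L) stop("need at least 2 values per arm")
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    p <- if (mean(a) == mean(b)) 1 else 0
    attr(p, "degenerate") <- TRUE
    return(p)
  }
  stats::t.test(a, b, var.equal = TRUE)$p.value
}

#' Fold change of mean expression between two analytes or arms
#'
#' Ratio of arithmetic means (numerator over denominator) with a two-tailed
#' Student t-test on the underlying values; the test is paired when both
#' vectors measure the same samples.
#'
#' @param numerator,denominator Numeric vectors of expression values.
#' @param paired Passed to [two_sample_t()].
#' @param center `"mean"` (default) or `"median"` fold.
#' @return Object of class `fold_change`: `fold`, `p`.
#' @export
fold_change <- function(numerator, denominator, paired = FALSE,
                        center = c("mean", "median")) {
  center <- match.arg(center)
  loc <- if (center == "mean") mean else stats::median
  den <- loc(denominator)
  if (den <= 0) stop("denominator ", center, " must be positive")
  structure(list(fold = loc(numerator) / den,
                 p = as.numeric(two_sample_t(numerator, denominator,
                                             paired = paired))),
            class = "fold_change")
}

#' @export
print.fold_change <- function(x, ...) {
  cat(sprintf("fold change %.3g (p = %.4g)\n", x$fold, x$p))
  invisible(x)
}

#' Per-analyte trend table across the full ordered cohort
#'
#' Runs [cuzick_trend()] for each analyte over all samples with a group
#' label, groups ordered short < intermediate < long.
#'
#' @param x An `immune_cohort`.
#' @param analytes Analytes to test; default all.
#' @return Data frame `analyte, z, p, median_short, median_intermediate,
#'   median_long`.
#' @export
trend_table <- function(x, analytes = NULL) {
  stopifnot(inherits(x, "immune_cohort"))
  keep <- x$records$group %in% .GROUP_LEVELS
  groups <- factor(x$records$group[keep],
                   levels = c("short", "intermediate", "long"))
  groups <- droplevels(groups)
  mat <- x$matrix[keep, , drop = FALSE]
  if (is.null(analytes)) analytes <- colnames(mat)
  rows <- lapply(analytes, function(a) {
    tr <- cuzick_trend(mat[, a], groups)
    med <- function(g) if (g %in% levels(groups))
      group_median(mat[groups == g, a]) else NA_real_
    data.frame(analyte = a, z = tr$z, p = tr$p,
               median_short = med("short"),
               median_intermediate = med("intermediate"),
               median_long = med("long"),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
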