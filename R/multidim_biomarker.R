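## Multidimensional biomarker: rank analytes by single-analyte performance,
## exhaustively search analyte subsets with leave-one-out random forests,
## then grid-search hyperparameters on the winning subset. The final model
## emits one signed score per sample in [-1, 1]; long PFS sits below the
## fixed decision threshold 0.

#' Rank analytes by single-analyte predictive performance
#'
#' Sorts analytes by leave-one-out accuracy (descending), then p-value
#' (ascending), keeping the input order for remaining ties, and returns the
#' top k candidates for the multidimensional subset search.
#'
#' @param reports Data frame with columns `analyte`, `accuracy`, `p_value`
#'   (e.g. from [analyte_table()]).
#' @param k Number of candidates to keep (default 5).
#' @return Object of class `analyte_ranking`: the sorted data frame with the
#'   selected candidates in `$top`.
#' @export
rank_analytes <- function(reports, k = 5) {
  stopifnot(all(c("analyte", "accuracy", "p_value") %in% names(reports)))
  usable <- reports[!is.na(reports$accuracy), , drop = FALSE]
  if (k > nrow(usable)) stop("k exceeds the number of rankable analytes")
  ord <- order(-usable$accuracy, usable$p_value)   # stable for residual ties
  ranked <- usable[ord, , drop = FALSE]
  rownames(ranked) <- NULL
  structure(list(ranked = ranked, top = ranked$analyte[seq_len(k)], k = k),
            class = "analyte_ranking")
}

#' @export
print.analyte_ranking <- function(x, ...) {
  cat(sprintf("top %d analytes: %s\n", x$k, paste(x$top, collapse = ", ")))
  invisible(x)
}

#' Random forest hyperparameters
#'
#' @param n_trees Number of trees.
#' @param features_per_split Variables tried at each split (`NULL`: the
#'   forest default `floor(sqrt(p))`, at least 1).
#' @param min_leaf Minimum terminal node size.
#' @param max_depth Maximum tree depth; `Inf` grows trees to purity. Depth d
#'   is enforced as a cap of `2^d` terminal nodes.
#' @return Object of class `forest_params`.
#' @export
forest_params <- function(n_trees = 500, features_per_split = NULL,
                          min_leaf = 1, max_depth = Inf) {
  stopifnot(n_trees >= 1, min_leaf >= 1)
  structure(list(n_trees = n_trees, features_per_split = features_per_split,
                 min_leaf = min_leaf, max_depth = max_depth),
            class = "forest_params")
}

#' Default hyperparameter grid for the final-model search
#'
#' The exhaustive grid crossed in [grid_search()]: trees in
#' \{100, 500, 1000\}, features-per-split over every feasible value for the
#' subset, minimum leaf size 1-3, and depth unlimited/2/3, in that
#' deterministic nesting order.
#'
#' @param n_features Size of the analyte subset.
#' @return List of [forest_params()] objects.
#' @export
forest_grid <- function(n_features) {
  stopifnot(n_features >= 1)
  grid <- list()
  for (depth in c(Inf, 2, 3))
    for (leaf in 1:3)
      for (mtry in seq_len(n_features))
        for (nt in c(100, 500, 1000))
          grid[[length(grid) + 1L]] <-
            forest_params(n_trees = nt, features_per_split = mtry,
                          min_leaf = leaf, max_depth = depth)
  grid
}

.fit_forest <- function(X, y, params, seed) {
  ## degenerate training data: every feature constant carries no split
  ## information, so the "forest" collapses to the class prior (the forest
  ## implementation cannot grow trees there)
  if (all(apply(X, 2, function(v) length(unique(v)) == 1L))) {
    return(structure(list(prior = prop.table(table(y))),
                     class = "constant_forest"))
  }
  mtry <- params$features_per_split
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(X))))
  mtry <- min(mtry, ncol(X))
  maxnodes <- if (is.finite(params$max_depth)) 2L^params$max_depth else NULL
  set.seed(seed)
  randomForest::randomForest(
    x = X, y = y, ntree = params$n_trees, mtry = mtry,
    nodesize = params$min_leaf, maxnodes = maxnodes
  )
}

.forest_score <- function(forest, X) {
  if (inherits(forest, "constant_forest")) {
    p <- forest$prior
    p_short <- if ("short" %in% names(p)) p[["short"]] else 0
    p_long  <- if ("long"  %in% names(p)) p[["long"]]  else 0
    return(rep(p_short - p_long, nrow(X)))
  }
  prob <- stats::predict(forest, X, type = "prob")
  p_short <- if ("short" %in% colnames(prob)) prob[, "short"] else 0
  p_long  <- if ("long"  %in% colnames(prob)) prob[, "long"]  else 0
  unname(p_short - p_long)
}

## Leave-one-out evaluation of a forest specification on X (samples x
## analytes), y in {long, short}. Per-fold seed = seed + fold index so a
## run is bit-reproducible. Returns held-out scores, classes and the error
## count. A one-class training fold predicts the present class with score
## +/- 1.
.loo_forest <- function(X, y, params, seed, fold_hook = NULL) {
  n <- nrow(X)
  scores <- numeric(n)
  for (i in seq_len(n)) {
    if (!is.null(fold_hook)) fold_hook(i, setdiff(seq_len(n), i))
    ytr <- droplevels(y[-i])
    if (nlevels(ytr) < 2L) {
      scores[i] <- if (levels(ytr) == "short") 1 else -1
    } else {
      forest <- .fit_forest(X[-i, , drop = FALSE], ytr, params, seed + i)
      scores[i] <- .forest_score(forest, X[i, , drop = FALSE])
    }
  }
  classes <- factor(ifelse(scores < 0, "long", "short"),
                    levels = c("long", "short"))
  list(scores = stats::setNames(scores, rownames(X)),
       classes = stats::setNames(classes, rownames(X)),
       errors = sum(classes != y))
}

.subset_key <- function(analytes) paste(analytes, collapse = "+")

#' Exhaustive analyte-subset search with leave-one-out random forests
#'
#' Trains a default-hyperparameter random forest on every non-empty subset
#' of the candidate analytes and scores each subset by its leave-one-out
#' misclassification count. The subset with the lowest error wins; ties go
#' to the larger subset, then to the subset whose analytes rank higher in
#' the candidate ordering.
#'
#' @param x An `immune_cohort` (restricted to long + short) or a numeric
#'   matrix of samples x analytes.
#' @param labels Class labels (ignored when `x` is a cohort, where the
#'   `group` column is used).
#' @param candidates Character vector of candidate analytes, best first
#'   (e.g. `rank_analytes(...)$top`).
#' @param defaults Default forest hyperparameters ([forest_params()]).
#' @param seed Master seed; fold seeds are derived from it.
#' @return Object of class `subset_search`: per-subset error counts
#'   (`$loo_errors`, named by `analyte1+analyte2+...`), the winning subset
#'   (`$chosen`), and the candidate list.
#' @export
powerset_select <- function(x, labels = NULL, candidates,
                            defaults = forest_params(), seed = 1) {
  dat <- .as_xy(x, labels, candidates)
  X <- dat$X; y <- dat$y
  k <- length(candidates)
  stopifnot(k >= 1, k <= 8)
  subsets <- list()
  for (m in 1:(2^k - 1)) {
    subsets[[m]] <- candidates[bitwAnd(m, 2^(seq_len(k) - 1)) > 0]
  }
  errors <- integer(length(subsets))
  for (m in seq_along(subsets)) {
    errors[m] <- .loo_forest(X[, subsets[[m]], drop = FALSE], y,
                             defaults, seed)$errors
  }
  names(errors) <- vapply(subsets, .subset_key, character(1))
  ## tie rules: min error; then max size; then lexicographically best ranks
  rank_of <- function(s) sort(match(s, candidates))
  best <- 1L
  for (m in seq_along(subsets)[-1]) {
    if (errors[m] < errors[best]) { best <- m; next }
    if (errors[m] > errors[best]) next
    sz_m <- length(subsets[[m]]); sz_b <- length(subsets[[best]])
    if (sz_m > sz_b) { best <- m; next }
    if (sz_m < sz_b) next
    rm_ <- rank_of(subsets[[m]]); rb <- rank_of(subsets[[best]])
    cmp <- which(rm_ != rb)
    if (length(cmp) && rm_[cmp[1]] < rb[cmp[1]]) best <- m
  }
  structure(list(candidates = candidates, loo_errors = errors,
                 chosen = subsets[[best]], defaults = defaults, seed = seed),
            class = "subset_search")
}

#' @export
print.subset_search <- function(x, ...) {
  cat(sprintf("subset search over %d subsets of {%s}\nchosen: %s (LOO errors %d)\n",
              length(x$loo_errors), paste(x$candidates, collapse = ", "),
              .subset_key(x$chosen), x$loo_errors[.subset_key(x$chosen)]))
  invisible(x)
}

.as_xy <- function(x, labels, analytes) {
  if (inherits(x, "immune_cohort")) {
    x <- subset_groups(x, c("long", "short"))
    labels <- x$records$group
    missing <- setdiff(analytes, colnames(x$matrix))
    if (length(missing)) stop("analyte(s) not in cohort: ",
                              paste(missing, collapse = ", "))
    X <- x$matrix[, analytes, drop = FALSE]
  } else {
    X <- as.matrix(x)[, analytes, drop = FALSE]
    if (is.null(labels)) stop("labels required when x is a matrix")
  }
  list(X = X, y = .as_ls_labels(labels))
}

#' Hyperparameter grid search for the final multidimensional model
#'
#' On the fixed analyte subset, evaluates every grid point by leave-one-out
#' error; the earliest point attaining the minimum wins. The final forest is
#' refit on all samples with the winning hyperparameters, while the reported
#' per-sample scores and classes are the held-out fold scores, which is how
#' the model's performance is evaluated.
#'
#' @inheritParams powerset_select
#' @param subset Analyte subset (e.g. `powerset_select(...)$chosen`).
#' @param grid List of [forest_params()]; defaults to
#'   `forest_grid(length(subset))`.
#' @return Object of class `multidim_model` with the subset, winning
#'   parameters, refit forest, held-out `$scores` in \[-1, 1\] and
#'   `$classes`, confusion counts and [confusion_metrics()].
#' @export
grid_search <- function(x, labels = NULL, subset, grid = NULL, seed = 1) {
  dat <- .as_xy(x, labels, subset)
  X <- dat$X; y <- dat$y
  if (is.null(grid)) grid <- forest_grid(length(subset))
  if (!length(grid)) stop("empty hyperparameter grid")
  errs <- integer(length(grid))
  loos <- vector("list", length(grid))
  for (g in seq_along(grid)) {
    loos[[g]] <- .loo_forest(X, y, grid[[g]], seed)
    errs[g] <- loos[[g]]$errors
  }
  win <- which.min(errs)            # earliest minimum in grid order
  loo <- loos[[win]]
  forest <- .fit_forest(X, y, grid[[win]], seed)
  tp <- sum(loo$classes == "long" & y == "long")
  fn <- sum(loo$classes == "short" & y == "long")
  fp <- sum(loo$classes == "long" & y == "short")
  tn <- sum(loo$classes == "short" & y == "short")
  structure(list(
    subset = subset, params = grid[[win]], grid_errors = errs,
    forest = forest, scores = loo$scores, classes = loo$classes,
    labels = stats::setNames(y, rownames(X)),
    metrics = confusion_metrics(tp, fn, fp, tn), seed = seed
  ), class = "multidim_model")
}

#' @export
print.multidim_model <- function(x, ...) {
  cat(sprintf("multidimensional biomarker on {%s}\n",
              paste(x$subset, collapse = ", ")))
  cat(sprintf("forest: %d trees, mtry %s, min leaf %d, depth %s; LOO errors %d/%d\n",
              x$params$n_trees,
              if (is.null(x$params$features_per_split)) "default"
              else x$params$features_per_split,
              x$params$min_leaf,
              if (is.finite(x$params$max_depth)) x$params$max_depth else "unlimited",
              min(x$grid_errors), length(x$scores)))
  print(x$metrics)
  invisible(x)
}

#' Score samples with a multidimensional biomarker
#'
#' The signed score is `s = P(short) - P(long)`, the difference of the
#' forest's class vote fractions, so `s` lies in \[-1, 1\]. A sample is
#' called "long" when `s < 0` and "short" when `s >= 0` (a split vote goes
#' to short).
#'
#' @param model A `multidim_model`.
#' @param x An `immune_cohort` or numeric matrix containing the model's
#'   analytes.
#' @return Data frame with `sample_id`, `score`, `class`.
#' @export
score_samples <- function(model, x) {
  stopifnot(inherits(model, "multidim_model"))
  X <- if (inherits(x, "immune_cohort")) x$matrix else as.matrix(x)
  missing <- setdiff(model$subset, colnames(X))
  if (length(missing)) stop("analyte(s) missing from data: ",
                            paste(missing, collapse = ", "))
  s <- .forest_score(model$forest, X[, model$subset, drop = FALSE])
  data.frame(sample_id = rownames(X), score = s,
             class = factor(ifelse(s < 0, "long", "short"),
                            levels = c("long", "short")),
             stringsAsFactors = FALSE)
}

#' ROC curve and AUC for signed biomarker scores
#'
#' Sweeps a decision threshold over the distinct scores, treating "short"
#' (the high-score class) as positive, and integrates the curve by the
#' trapezoidal rule.
#'
#' @param scores Numeric scores (higher = more "short"-like).
#' @param labels Class labels `"long"`/`"short"`.
#' @return Object of class `roc_curve`: `$points` (fpr, tpr) and `$auc`.
#' @export
roc_auc <- function(scores, labels) {
  labels <- .as_ls_labels(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  pos <- labels == "short"
  n_pos <- sum(pos); n_neg <- sum(!pos)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  tpr <- vapply(thr, function(t) sum(scores >= t & pos) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores >= t & !pos) / n_neg, numeric(1))
  auc <- sum(diff(fpr) * (tpr[-1] + tpr[-length(tpr)]) / 2)
  structure(list(points = data.frame(fpr = fpr, tpr = tpr), auc = auc),
            class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC curve with %d points, AUC %.4f\n", nrow(x$points), x$auc))
  invisible(x)
}

#' Fit the full multidimensional biomarker from a cohort
#'
#' Convenience wrapper running the complete sequence: single-analyte table,
#' top-k ranking, power-set subset search, hyperparameter grid search, and
#' ROC on the held-out scores.
#'
#' @param x An `immune_cohort` containing the long and short groups.
#' @param top_k Candidates entering the subset search (default 5).
#' @param defaults Default forest hyperparameters for the subset search.
#' @param grid Hyperparameter grid (default [forest_grid()] on the chosen
#'   subset size).
#' @param seed Master seed.
#' @param reports Optional precomputed [analyte_table()].
#' @return List with `reports`, `ranking`, `search`, `model`, `roc`.
#' @export
multidim_biomarker <- function(x, top_k = 5, defaults = forest_params(),
                               grid = NULL, seed = 1, reports = NULL) {
  if (is.null(reports)) reports <- analyte_table(x)
  ranking <- rank_analytes(reports, k = top_k)
  search <- powerset_select(x, candidates = ranking$top,
                            defaults = defaults, seed = seed)
  model <- grid_search(x, subset = search$chosen, grid = grid, seed = seed)
  roc <- roc_auc(model$scores, model$labels)
  list(reports = reports, ranking = ranking, search = search,
       model = model, roc = roc)
}
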