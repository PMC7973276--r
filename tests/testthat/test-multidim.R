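test_that("analyte ranking sorts by accuracy then p-value, stably", {
  rep1 <- data.frame(analyte = c("A", "B", "C", "D"),
                     accuracy = c(70, 80, 80, 60),
                     p_value = c(0.5, 0.5, 0.01, 0.2))
  rk <- rank_analytes(rep1, k = 3)
  expect_equal(rk$top, c("C", "B", "A"))
  expect_equal(rank_analytes(rep1[1, , drop = FALSE], k = 1)$top, "A")
  expect_error(rank_analytes(rep1, k = 9), "exceeds")
})

test_that("power-set search prefers the larger subset on error ties", {
  # two identical constant analytes: every subset has the same LOO error,
  # so the tie rules must pick the full subset
  X <- matrix(5, nrow = 9, ncol = 2, dimnames = list(paste0("s", 1:9),
                                                     c("A", "B")))
  y <- rep(c("long", "short"), c(5, 4))
  ps <- powerset_select(X, y, candidates = c("A", "B"),
                        defaults = forest_params(n_trees = 50), seed = 3)
  expect_length(ps$loo_errors, 3)
  expect_equal(length(unique(ps$loo_errors)), 1L)
  expect_setequal(ps$chosen, c("A", "B"))
})

test_that("power-set search recovers a planted informative analyte", {
  hits <- 0
  for (seed in 1:5) {
    x <- planted_cohort(seed = seed, effect = 2)
    ps <- powerset_select(x, candidates = colnames(x$matrix), seed = seed)
    if ("planted" %in% ps$chosen) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("grid search honors grid order and degenerate ties", {
  X <- matrix(5, nrow = 9, ncol = 1, dimnames = list(paste0("s", 1:9), "A"))
  y <- rep(c("long", "short"), c(5, 4))
  grid <- list(forest_params(n_trees = 50),
               forest_params(n_trees = 100),
               forest_params(n_trees = 150))
  m <- grid_search(X, y, subset = "A", grid = grid, seed = 1)
  expect_equal(length(unique(m$grid_errors)), 1L)
  expect_equal(m$params$n_trees, 50)            # first grid point on a tie
  m1 <- grid_search(X, y, subset = "A", grid = grid[2], seed = 1)
  expect_equal(m1$params$n_trees, 100)          # single-point grid
})

test_that("grid search finds a zero-error point on separable planted data", {
  x <- planted_cohort(seed = 9, effect = 6, n_noise = 1)
  grid <- list(forest_params(n_trees = 100, features_per_split = 1),
               forest_params(n_trees = 500, features_per_split = 1))
  m <- grid_search(x, subset = "planted", grid = grid, seed = 9)
  expect_equal(min(m$grid_errors), 0)
  expect_equal(m$metrics$accuracy, 100)
})

test_that("signed scores live in [-1,1] with the documented decision rule", {
  x <- planted_cohort(seed = 13, effect = 3)
  m <- grid_search(x, subset = "planted",
                   grid = list(forest_params(n_trees = 200)), seed = 13)
  expect_true(all(m$scores >= -1 & m$scores <= 1))
  expect_equal(as.character(m$classes),
               unname(ifelse(m$scores < 0, "long", "short")))
  # long group sits below 0, short above (sign convention)
  lab <- m$labels
  expect_lt(median(m$scores[lab == "long"]), 0)
  expect_gt(median(m$scores[lab == "short"]), 0)
  # scoring new data through the refit forest is bounded too
  sc <- score_samples(m, x)
  expect_true(all(sc$score >= -1 & sc$score <= 1))
  expect_error(score_samples(m, x$matrix[, c("noise1", "noise2")]),
               "missing")
})

test_that("ROC endpoints, AUC and the rank-statistic identity", {
  lab <- rep(c("long", "short"), c(4, 4))
  expect_equal(roc_auc(c(-1, -1, -1, -1, 1, 1, 1, 1), lab)$auc, 1)
  expect_equal(roc_auc(c(1, 1, 1, 1, -1, -1, -1, -1), lab)$auc, 0)
  expect_error(roc_auc(1:4, rep("long", 4)), "both classes")
  # AUC equals the Mann-Whitney U statistic / (n1 n2)
  set.seed(71)
  for (i in 1:20) {
    s <- rnorm(15)
    lab <- sample(rep(c("long", "short"), c(8, 7)))
    r <- roc_auc(s, lab)
    U <- sum(rank(s)[lab == "short"]) - 7 * 8 / 2
    expect_equal(r$auc, U / (7 * 8), tolerance = 1e-12)
    pts <- r$points
    expect_true(all(diff(pts$fpr) >= 0) && all(diff(pts$tpr) >= 0))
  }
  # random scores give chance-level AUC on average
  set.seed(72)
  aucs <- replicate(300, {
    roc_auc(rnorm(19), rep(c("long", "short"), c(11, 8)))$auc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.03)
})

test_that("fold purity and seeded determinism of the forest LOO", {
  x <- planted_cohort(seed = 17, effect = 2, n_noise = 2)
  X <- x$matrix; y <- factor(x$records$group, levels = c("long", "short"))
  seen <- list()
  loo1 <- immunomark:::.loo_forest(X, y, forest_params(n_trees = 100), 17,
                                   fold_hook = function(i, train) {
                                     seen[[length(seen) + 1]] <<- c(i, train)
                                   })
  for (f in seen) expect_false(f[1] %in% f[-1])
  loo2 <- immunomark:::.loo_forest(X, y, forest_params(n_trees = 100), 17)
  expect_identical(loo1$scores, loo2$scores)

  ps1 <- powerset_select(X, y, candidates = colnames(X)[1:3],
                         defaults = forest_params(n_trees = 100), seed = 5)
  ps2 <- powerset_select(X, y, candidates = colnames(X)[1:3],
                         defaults = forest_params(n_trees = 100), seed = 5)
  expect_identical(ps1$loo_errors, ps2$loo_errors)
  expect_identical(ps1$chosen, ps2$chosen)
})

test_that("multidim confusion matrix is consistent with confusion_metrics", {
  x <- planted_cohort(seed = 23, effect = 2)
  m <- grid_search(x, subset = c("planted", "noise1"),
                   grid = list(forest_params(n_trees = 200)), seed = 23)
  cnt <- m$metrics$counts
  ref <- confusion_metrics(unname(cnt["tp"]), unname(cnt["fn"]),
                           unname(cnt["fp"]), unname(cnt["tn"]))
  expect_equal(m$metrics$accuracy, ref$accuracy)
  expect_equal(unname(cnt["tp"] + cnt["fn"]), 11)
  expect_equal(unname(cnt["fp"] + cnt["tn"]), 8)
})
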