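test_that("confusion metric identities hold over an enumeration of matrices", {
  for (tp in 0:7) for (fn in 0:7) for (fp in 0:7) for (tn in 0:7) {
    if (tp + fn + fp + tn == 0) next
    m <- confusion_metrics(tp, fn, fp, tn)
    n <- tp + fn + fp + tn
    expect_equal(m$accuracy, 100 * (tp + tn) / n)
    if (tp + fp == 0) expect_true(is.na(m$ppv))
    else expect_equal(m$ppv, 100 * tp / (tp + fp))
    if (tn + fn == 0) expect_true(is.na(m$npv))
    else expect_equal(m$npv, 100 * tn / (tn + fn))
    if (tp + fn == 0) expect_true(is.na(m$sensitivity))
    else expect_equal(m$sensitivity, 100 * tp / (tp + fn))
    if (tn + fp == 0) expect_true(is.na(m$specificity))
    else expect_equal(m$specificity, 100 * tn / (tn + fp))
  }
  expect_error(confusion_metrics(0, 0, 0, 0), "zero")
})

test_that("perfect classifiers and zero denominators are reported faithfully", {
  m <- confusion_metrics(6, 0, 0, 9)
  expect_true(all(unlist(m[c("accuracy", "ppv", "npv",
                             "sensitivity", "specificity")]) == 100))
  m <- confusion_metrics(0, 5, 0, 5)
  expect_true(is.na(m$ppv))
  expect_equal(m$specificity, 100)
})

test_that("presentation rounding is half away from zero", {
  expect_equal(round_half_up(89.47), 89)
  expect_equal(round_half_up(85.5), 86)
  expect_equal(round_half_up(62.5), 63)
  expect_equal(round_half_up(-0.65, 1), -0.7)
})

test_that("threshold fit separates cleanly separated classes", {
  rule <- fit_threshold(c(1, 2, 3, 10, 11),
                        c("long", "long", "long", "short", "short"))
  expect_equal(rule$threshold, 6.5)
  expect_equal(rule$direction, "low_is_positive")
  expect_equal(rule$youden, 200)
  expect_equal(as.character(predict(rule, c(0, 6.4, 6.6, 100))),
               c("long", "long", "short", "short"))
})

test_that("swapping class labels mirrors the threshold rule", {
  set.seed(21)
  for (i in 1:25) {
    v <- round(rnorm(12), 2)
    lab <- sample(rep(c("long", "short"), c(7, 5)))
    flipped <- ifelse(lab == "long", "short", "long")
    r1 <- fit_threshold(v, lab)
    r2 <- fit_threshold(v, flipped)
    # the two orientations are exact complements of each other
    expect_equal(as.character(predict(r1, v)),
                 ifelse(predict(r2, v) == "long", "short", "long"))
  }
})

test_that("threshold fit agrees with the exhaustive oracle on random instances", {
  set.seed(31)
  for (i in 1:40) {
    n <- sample(5:20, 1)
    v <- round(rnorm(n, sd = 2), 1)          # duplicates likely
    lab <- sample(c("long", "short"), n, replace = TRUE)
    if (length(unique(lab)) < 2 || length(unique(v)) < 2) next
    got <- fit_threshold(v, lab)
    want <- oracle_fit_threshold(v, lab)
    expect_equal(got$threshold, want$threshold)
    expect_equal(got$direction, want$direction)
  }
})

test_that("degenerate all-identical data yield a flagged majority rule", {
  rule <- fit_threshold(rep(3, 7), rep(c("long", "short"), c(4, 3)))
  expect_true(rule$degenerate)
  expect_equal(as.character(predict(rule, c(1, 3, 5))), rep("long", 3))
})

test_that("leave-one-out evaluation never trains on the held-out sample", {
  v <- c(1, 2, 3, 4, 10, 11, 12)
  lab <- rep(c("long", "short"), c(4, 3))
  seen <- list()
  res <- loo_evaluate_single(v, lab, fold_hook = function(i, train) {
    seen[[length(seen) + 1]] <<- list(i = i, train = train)
  })
  expect_length(seen, length(v))
  for (f in seen) {
    expect_false(f$i %in% f$train)
    expect_length(f$train, length(v) - 1)
  }
  # perfectly separated data classify perfectly under LOO
  expect_equal(res$metrics$accuracy, 100)
})

test_that("LOO confusion counts conserve the class sizes", {
  set.seed(41)
  for (i in 1:10) {
    v <- rnorm(19)
    lab <- sample(rep(c("long", "short"), c(11, 8)))
    res <- loo_evaluate_single(v, lab)
    cnt <- res$counts
    expect_equal(unname(cnt["tp"] + cnt["fn"]), 11)
    expect_equal(unname(cnt["fp"] + cnt["tn"]), 8)
  }
})

test_that("LOO accuracy under label-independent values centers near chance", {
  # leave-one-out with a tuned threshold is anti-biased under the null: the
  # held-out accuracy centers near 50%, below the 11/19 majority rate
  set.seed(51)
  v <- rnorm(19)
  acc <- replicate(300, {
    lab <- sample(rep(c("long", "short"), c(11, 8)))
    loo_evaluate_single(v, lab)$metrics$accuracy
  })
  expect_lt(abs(mean(acc) - 50), 5)
  expect_lt(mean(acc), 100 * 11 / 19)
})

test_that("rank-sum p-value handles exact, tied and degenerate branches", {
  # identical multisets: no evidence either way
  expect_equal(rank_sum_p(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(rank_sum_p(rep(5, 4), rep(5, 3)), 1)
  # complete separation at n = 3 vs 3: 2 / C(6,3)
  expect_equal(rank_sum_p(c(1, 2, 3), c(10, 11, 12)), 0.1)
  # exact branch equals full enumeration
  set.seed(61)
  for (i in 1:10) {
    a <- rnorm(6); b <- rnorm(5)
    expect_equal(rank_sum_p(a, b), oracle_rank_sum_p(a, b), tolerance = 1e-12)
  }
  expect_error(rank_sum_p(numeric(0), 1), "non-empty")
})

test_that("analyte table reproduces the expected schema and surfaces planted signal", {
  x <- planted_cohort(seed = 5, effect = 3)
  tab <- analyte_table(x)
  expect_equal(names(tab),
               c("analyte", "median_long", "median_short", "threshold",
                 "p_value", "accuracy", "ppv", "npv", "sensitivity",
                 "specificity"))
  expect_equal(nrow(tab), 5)
  expect_equal(tab$analyte[which.max(tab$accuracy)], "planted")
  preds <- attr(tab, "loo_predictions")
  expect_equal(dim(preds), c(19, 5))

  # constant cohort: no information, majority-rate accuracy, p = 1
  xm <- x$matrix; xm[] <- 7
  xc <- cohort(x$records, xm, x$kinds)
  tab0 <- analyte_table(xc)
  expect_true(all(tab0$p_value == 1))
  expect_true(all(tab0$accuracy == 100 * 11 / 19))
})

test_that("rendered analyte table prints undefined cells as dashes", {
  x <- planted_cohort(seed = 5, effect = 3)
  tab <- analyte_table(x)
  tab$ppv[1] <- NA
  d <- withr::local_tempdir()
  f <- file.path(d, "tab.tsv")
  write_analyte_table(tab, f)
  out <- read.delim(f, colClasses = "character")
  expect_equal(out$ppv[1], "-")
  expect_equal(names(out)[1], "analyte")
})

test_that("printed-style confusion reconstruction recovers unique matrices", {
  m <- reconstruct_confusion(82, 100, 11, 8)
  expect_equal(unname(m$counts), c(9, 2, 0, 8))
  expect_error(reconstruct_confusion(50, 50, 1000, 1000), "uniquely")
})
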