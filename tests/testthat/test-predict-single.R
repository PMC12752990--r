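test_that("AU-ROC matches hand-traced and degenerate cases", {
  expect_equal(auroc(c(0.9, 0.4, 0.6, 0.2), c(1, 1, 0, 0)), 0.75)
  expect_equal(auroc(c(5, 4, 3, 1), c(1, 1, 0, 0)), 1)    # perfect
  expect_equal(auroc(rep(0.3, 6), c(1, 0, 1, 0, 1, 0)), 0.5)  # all ties
  expect_error(auroc(1:3, c(1, 1, 1)), "both classes")
})

test_that("AU-ROC equals the all-pairs concordance oracle", {
  set.seed(41)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    y <- integer(n)
    y[sample.int(n, sample(seq_len(n - 1), 1))] <- 1L
    if (sum(y) == 0 || sum(y) == n) next
    s <- round(runif(n), sample(1:3, 1))  # rounding creates ties
    expect_equal(auroc(s, y), auroc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("AU-PRC matches hand-traced values and the constant-score limit", {
  expect_equal(auprc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 5 / 6)
  expect_equal(auprc(c(9, 8, 7), c(1, 1, 0)), 1)  # perfect ranking
  # all-equal scores collapse to prevalence
  expect_equal(auprc(rep(1, 10), c(rep(1, 3), rep(0, 7))), 0.3)
  expect_error(auprc(1:3, c(0, 0, 0)), "positive")
})

test_that("AU-PRC equals the per-positive precision sum on untied scores", {
  set.seed(42)
  for (rep in 1:60) {
    n <- sample(4:50, 1)
    y <- integer(n)
    y[sample.int(n, sample(seq_len(n - 1), 1))] <- 1L
    if (sum(y) == 0) next
    s <- runif(n)  # continuous, untied almost surely
    expect_equal(auprc(s, y), auprc_oracle(s, y), tolerance = 1e-12)
  }
})

test_that("both metrics are invariant to monotone score transforms", {
  set.seed(43)
  y <- c(rep(1, 8), rep(0, 12))[sample(20)]
  s <- rnorm(20)
  for (f in list(function(x) 3 * x + 2, plogis, function(x) x^3)) {
    expect_equal(auroc(f(s), y), auroc(s, y), tolerance = 1e-12)
    expect_equal(auprc(f(s), y), auprc(s, y), tolerance = 1e-12)
  }
})

test_that("single-region fits find the planted direction and handle nulls", {
  set.seed(44)
  y <- c(rep(1, 15), rep(0, 15))
  x_hyper <- 0.4 + 0.2 * y + rnorm(30, 0, 0.05)
  m <- fit_single_dmr(x_hyper, y)
  expect_gt(m$slope, 0)
  x_null <- runif(30)
  m0 <- fit_single_dmr(x_null, y)
  auc0 <- auroc(predict(m0, x_null), y)
  expect_lt(abs(auc0 - 0.5), 0.25)
  # constant feature: flagged, no slope
  mc <- fit_single_dmr(rep(0.5, 30), y)
  expect_true(mc$constant_feature)
  expect_equal(mc$slope, 0)
  # scaling the feature leaves the ranking (and so the AUC) unchanged
  m10 <- fit_single_dmr(x_hyper * 10, y)
  expect_equal(auroc(predict(m10, x_hyper * 10), y),
               auroc(predict(m, x_hyper), y))
})

test_that("perfect separation is flagged but still ranks correctly", {
  y <- c(1, 1, 1, 0, 0, 0)
  x <- c(0.9, 0.8, 0.85, 0.2, 0.1, 0.15)
  m <- fit_single_dmr(x, y)
  expect_true(m$separated)
  expect_equal(auroc(predict(m, x), y), 1)
})

test_that("bootstrap screening is deterministic, ranks by mean AUC and marks degenerate CIs", {
  set.seed(45)
  y <- c(rep(1, 10), rep(0, 10))
  x <- rbind(strong = 0.3 + 0.4 * y + rnorm(20, 0, 0.01),
             weak = 0.5 + 0.05 * y + rnorm(20, 0, 0.1),
             noise = runif(20))
  colnames(x) <- paste0("S", 1:20)
  scr <- bootstrap_screen(x, y, n_boot = 50, seed = 6)
  expect_equal(scr$all$region[1], "strong")
  # a perfectly separating region has every bootstrap AUC = 1
  expect_true(scr$all$degenerate_ci[scr$all$region == "strong"])
  expect_equal(format_ci(NA, NA, TRUE), "(-, -)")
  scr2 <- bootstrap_screen(x, y, n_boot = 50, seed = 6)
  expect_identical(scr$all, scr2$all)
  # n_boot = 1: the bootstrap mean is that single resample's AUC and
  # the percentile interval is degenerate by construction
  one <- bootstrap_screen(x["weak", , drop = FALSE], y, n_boot = 1,
                          seed = 2)
  expect_true(one$all$degenerate_ci)
  expect_gte(one$all$boot_mean_auroc, 0)
  expect_lte(one$all$boot_mean_auroc, 1)
})

test_that("test-set evaluation guards leakage and matches train metrics on train data", {
  set.seed(46)
  y_tr <- c(rep(1, 8), rep(0, 8))
  x_tr <- rbind(r1 = 0.3 + 0.3 * y_tr + rnorm(16, 0, 0.05))
  colnames(x_tr) <- paste0("T", 1:16)
  scr <- bootstrap_screen(x_tr, y_tr, n_boot = 10, seed = 1)
  expect_error(
    evaluate_on_test(scr, x_tr, y_tr, train_ids = colnames(x_tr),
                     test_ids = colnames(x_tr)[1]),
    "leakage")
  # consistency: evaluating on the training data reproduces train metrics
  ev <- evaluate_on_test(scr, x_tr, y_tr)
  expect_equal(ev$test_auroc, ev$train_auroc)
  expect_equal(ev$test_auprc, ev$train_auprc)
})

test_that("on label-permuted test data the test AUC centres at 0.5", {
  set.seed(47)
  y_tr <- c(rep(1, 10), rep(0, 10))
  x_tr <- rbind(r1 = 0.3 + 0.3 * y_tr + rnorm(20, 0, 0.05))
  colnames(x_tr) <- paste0("T", 1:20)
  scr <- bootstrap_screen(x_tr, y_tr, n_boot = 10, seed = 1)
  x_te <- rbind(r1 = runif(12, 0.3, 0.7))
  colnames(x_te) <- paste0("E", 1:12)
  aucs <- replicate(40, {
    y_perm <- sample(c(rep(1, 5), rep(0, 7)))
    evaluate_on_test(scr, x_te, y_perm)$test_auroc
  })
  expect_lt(abs(mean(aucs) - 0.5), 0.1)
})
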