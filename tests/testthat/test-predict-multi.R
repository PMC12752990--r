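sim_features <- function(n, p, informative = integer(), effect = 2,
                         seed = 1) {
  set.seed(seed)
  X <- matrix(rnorm(n * p), n, p,
              dimnames = list(NULL, paste0("f", seq_len(p))))
  eta <- rowSums(X[, informative, drop = FALSE]) * effect
  y <- as.integer(runif(n) < plogis(eta))
  # guard against degenerate draws
  if (sum(y) < 4) y[sample.int(n, 4)] <- 1L
  if (sum(1 - y) < 4) y[sample.int(n, 4)] <- 0L
  list(X = X, y = y)
}

test_that("lambda at or above lambda_max yields an intercept-only model", {
  d <- sim_features(60, 8, informative = 1:2, seed = 10)
  lmax <- dmrpredict:::lambda_max_l0l2(d$X, d$y, 0.001)
  fit <- fit_l0l2_logistic(d$X, d$y, gamma = 0.001,
                           lambda_grid = c(lmax * 2, lmax * 1.5),
                           cv_folds = 4, seed = 1)
  expect_equal(length(fit$selected), 0)
  expect_true(is.finite(fit$intercept))
})

test_that("at lambda = 0 the solver agrees with a generic ridge-logistic optimiser", {
  d <- sim_features(80, 5, informative = 1:2, seed = 11)
  sol <- dmrpredict:::l0l2_solve(d$X, d$y, lambda = 0, gamma = 0.001)
  obj_mine <- dmrpredict:::l0l2_objective(sol$b0, sol$b, d$X, d$y, 0,
                                          0.001)
  obj_oracle <- ridge_logistic_oracle(d$X, d$y, 1:5, 0.001)
  expect_equal(obj_mine, obj_oracle, tolerance = 1e-6)
})

test_that("the objective is non-increasing across coordinate-descent sweeps", {
  for (s in 1:5) {
    d <- sim_features(50, 10, informative = 1:3, seed = 20 + s)
    lmax <- dmrpredict:::lambda_max_l0l2(d$X, d$y, 0.001)
    cd <- dmrpredict:::l0l2_cd(d$X, d$y, lambda = lmax / 50,
                               gamma = 0.001, b0 = 0,
                               b = numeric(10), track_objective = TRUE)
    expect_true(all(diff(cd$objective_path) <= 1e-10))
  }
})

test_that("support size is non-increasing along the lambda path", {
  d <- sim_features(70, 12, informative = 1:3, seed = 30)
  fit <- fit_l0l2_logistic(d$X, d$y, gamma = 0.001, cv_folds = 4,
                           seed = 2, n_lambda = 25)
  # walk the descending-lambda grid with warm starts: the support can
  # only grow as the L0 weight shrinks
  b0 <- NULL; b <- NULL; sizes <- integer(0)
  for (l in fit$cv_path$lambda) {
    s <- dmrpredict:::l0l2_solve(d$X, d$y, l, 0.001, b0 = b0, b = b)
    b0 <- s$b0; b <- s$b
    sizes <- c(sizes, sum(s$b != 0))
  }
  expect_true(all(diff(sizes) >= 0))
})

test_that("planted informative features are recovered under CV", {
  set.seed(31)
  n <- 200
  X <- matrix(rnorm(n * 53), n, 53,
              dimnames = list(NULL, paste0("f", 1:53)))
  eta <- 2.5 * X[, 1] + 2.5 * X[, 2] - 2.5 * X[, 3]
  y <- as.integer(runif(n) < plogis(eta))
  fit <- fit_l0l2_logistic(X, y, gamma = 0.001, cv_folds = 4, seed = 3)
  expect_true(all(c("f1", "f2", "f3") %in% fit$selected))
})

test_that("the CV-chosen support attains the exhaustive best-subset objective", {
  for (s in 1:3) {
    d <- sim_features(60, 10, informative = 1:2, effect = 1.5,
                      seed = 40 + s)
    fit <- fit_l0l2_logistic(d$X, d$y, gamma = 0.001, cv_folds = 4,
                             seed = s, n_lambda = 20)
    oracle <- best_subset_oracle(d$X, d$y, fit$lambda, fit$gamma)
    expect_lt(fit$objective - oracle, 1e-6)
  }
})

test_that("per-cluster trees pick the informative region from each cluster", {
  set.seed(50)
  n <- 40
  y <- c(rep(1L, 20), rep(0L, 20))
  k <- 4
  regions <- paste0("chr", rep(1:k, each = 5), ":",
                    rep(1:5, k) * 1000, "-", rep(1:5, k) * 1000 + 200)
  x <- matrix(runif(k * 5 * n, 0.2, 0.8), k * 5, n,
              dimnames = list(regions, paste0("S", 1:n)))
  informative <- seq(1, k * 5, by = 5)  # first region of each cluster
  for (r in informative)
    x[r, ] <- 0.3 + 0.35 * y + rnorm(n, 0, 0.02)
  cm <- structure(list(k = k,
                       assignments = setNames(rep(1:k, each = 5),
                                              regions),
                       sizes = rep(5L, k), seed = 1),
                  class = "cluster_model")
  sel <- select_by_tree_per_cluster(x, y, cm, seed = 7)
  expect_setequal(sel, regions[informative])
  prov <- attr(sel, "provenance")
  expect_equal(sort(unique(prov$cluster)), 1:4)
  # decisive fixtures select the same set under a different seed
  sel2 <- select_by_tree_per_cluster(x, y, cm, seed = 99)
  expect_setequal(sel2, sel)
})

test_that("a pure-noise cluster contributes no regions", {
  set.seed(51)
  n <- 30
  y <- rep(c(1L, 0L), each = 15)
  x <- matrix(0.5, 6, n,   # cluster 1 is flat: no split can help
              dimnames = list(paste0("r", 1:6), paste0("S", 1:n)))
  x[4, ] <- 0.3 + 0.4 * y + rnorm(n, 0, 0.02)  # cluster 2 informative
  x[5, ] <- x[4, ] + rnorm(n, 0, 0.1)
  x[6, ] <- runif(n, 0.4, 0.6)
  cm <- structure(list(k = 2,
                       assignments = setNames(c(1, 1, 1, 2, 2, 2),
                                              rownames(x)),
                       sizes = c(3L, 3L), seed = 1),
                  class = "cluster_model")
  expect_warning(sel <- select_by_tree_per_cluster(x, y, cm, seed = 3),
                 "no split")
  expect_equal(attr(sel, "provenance")$cluster, 2)
})

test_that("the forest memorises training data and is seed-deterministic", {
  set.seed(52)
  n <- 30
  y <- rep(c(1L, 0L), each = 15)
  x <- rbind(a = 0.3 + 0.3 * y + rnorm(n, 0, 0.05),
             b = 0.6 - 0.25 * y + rnorm(n, 0, 0.05))
  colnames(x) <- paste0("S", 1:n)
  fm <- fit_forest(x, y, n_trees = 100, seed = 4)
  p <- predict(fm, x)
  expect_gte(mean((p > 0.5) == (y == 1)), 0.5)  # at least majority rate
  fm2 <- fit_forest(x, y, n_trees = 100, seed = 4)
  expect_identical(predict(fm2, x), p)
  xc <- rbind(const = rep(0.5, n)); colnames(xc) <- colnames(x)
  expect_error(fit_forest(xc, y, n_trees = 10, seed = 1), "constant")
})

test_that("multi-model evaluation shares the metric code path and guards leakage", {
  set.seed(53)
  n <- 24
  y <- rep(c(1L, 0L), each = 12)
  x <- rbind(a = 0.3 + 0.3 * y + rnorm(n, 0, 0.04))
  colnames(x) <- paste0("S", 1:n)
  sm <- fit_single_dmr(x["a", ], y)
  probs <- predict(sm, x["a", ])
  fake_model <- structure(list(p = probs), class = "fixed_prob_model")
  assign("predict.fixed_prob_model",
         function(object, newdata, ...) object$p, envir = globalenv())
  on.exit(rm("predict.fixed_prob_model", envir = globalenv()))
  ev <- evaluate_multi(fake_model, x, y)
  expect_equal(ev$test_auroc, auroc(probs, y))
  expect_equal(ev$test_auprc, auprc(probs, y))
  expect_error(evaluate_multi(fake_model, x, y,
                              train_ids = "S1", test_ids = "S1"),
               "leakage")
})
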