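# Multi-probe predictive models.
#
# 1) L0+L2-penalised sparse logistic regression, solved by cyclic
#    coordinate descent with hard-threshold updates plus local swap
#    refinement, with the L0 weight (lambda) chosen by stratified
#    cross-validation over a geometric path; the L2 weight (gamma) is
#    fixed (default 0.001).
# 2) Depth-bounded decision trees per methylation cluster to pick a few
#    representative regions, fed into a random forest.

# penalised objective: mean logistic loss + lambda * ||b||_0 + gamma * ||b||_2^2
l0l2_objective <- function(b0, b, X, y, lambda, gamma) {
  f <- b0 + drop(X %*% b)
  mean(log1p(exp(-ifelse(y == 1, 1, -1) * f))) +
    lambda * sum(b != 0) + gamma * sum(b^2)
}

logistic_loss <- function(b0, b, X, y) {
  f <- b0 + drop(X %*% b)
  mean(log1p(exp(-ifelse(y == 1, 1, -1) * f)))
}

# ridge-penalised logistic refit restricted to a support (Newton)
refit_support <- function(X, y, support, gamma, maxit = 100) {
  k <- length(support)
  n <- length(y)
  Xs <- cbind(1, X[, support, drop = FALSE])
  theta <- rep(0, k + 1)
  pen <- c(0, rep(2 * gamma, k))  # no penalty on the intercept
  for (it in seq_len(maxit)) {
    eta <- drop(Xs %*% theta)
    p <- plogis(eta)
    g <- -crossprod(Xs, y - p) / n + pen * theta
    w <- pmax(p * (1 - p), 1e-10)
    H <- crossprod(Xs * w, Xs) / n + diag(pen, k + 1)
    step <- tryCatch(solve(H, g), error = function(e) g / max(diag(H)))
    # damped Newton keeps the penalised loss monotone
    obj0 <- logistic_loss(theta[1], theta[-1],
                          X[, support, drop = FALSE], y) +
      gamma * sum(theta[-1]^2)
    alpha <- 1
    repeat {
      cand <- theta - alpha * step
      obj1 <- logistic_loss(cand[1], cand[-1],
                            X[, support, drop = FALSE], y) +
        gamma * sum(cand[-1]^2)
      if (obj1 <= obj0 + 1e-12 || alpha < 1e-6) break
      alpha <- alpha / 2
    }
    theta <- theta - alpha * step
    if (sqrt(sum((alpha * step)^2)) < 1e-10) break
  }
  theta
}

# one cyclic coordinate-descent pass to (local) convergence at fixed
# lambda, starting from (b0, b); the linear predictor is maintained
# incrementally so a sweep costs O(n p)
l0l2_cd <- function(X, y, lambda, gamma, b0, b, maxit = 500,
                    track_objective = FALSE) {
  n <- nrow(X); p <- ncol(X)
  L <- 0.25 * colMeans(X^2)
  thresh_scale <- L / 2 + gamma
  denom <- L + 2 * gamma
  f <- b0 + drop(X %*% b)
  obj_path <- if (track_objective)
    l0l2_objective(b0, b, X, y, lambda, gamma) else NULL
  for (it in seq_len(maxit)) {
    delta_max <- 0
    # intercept: damped Newton on the unpenalised 1-d problem
    pr <- plogis(f)
    h0 <- max(mean(pr * (1 - pr)), 1e-10)
    step0 <- mean(y - pr) / h0
    b0 <- b0 + step0
    f <- f + step0
    delta_max <- max(delta_max, abs(step0))
    for (j in seq_len(p)) {
      g <- -mean(X[, j] * (y - plogis(f)))
      t_star <- (L[j] * b[j] - g) / denom[j]
      b_new <- if (thresh_scale[j] * t_star^2 > lambda) t_star else 0
      if (b_new != b[j]) {
        f <- f + X[, j] * (b_new - b[j])
        delta_max <- max(delta_max, abs(b_new - b[j]))
        b[j] <- b_new
      }
    }
    if (track_objective)
      obj_path <- c(obj_path, l0l2_objective(b0, b, X, y, lambda, gamma))
    if (delta_max < 1e-8) break
  }
  # polish: exact ridge refit on the discovered support
  supp <- which(b != 0)
  if (length(supp) > 0) {
    theta <- refit_support(X, y, supp, gamma)
    cand0 <- theta[1]; cand <- numeric(p); cand[supp] <- theta[-1]
    if (l0l2_objective(cand0, cand, X, y, lambda, gamma) <=
        l0l2_objective(b0, b, X, y, lambda, gamma)) {
      b0 <- cand0; b <- cand
    }
  } else {
    b0 <- refit_support(X, y, integer(0), gamma)[1]
  }
  list(b0 = b0, b = b, objective_path = obj_path)
}

# local swap refinement (CDPSI-style). Candidate moves (swap one support
# member for one excluded feature, pure addition, pure deletion) are
# screened by their one-coordinate majorisation gain, and only the most
# promising few are evaluated exactly (ridge refit on the candidate
# support). The best strictly improving move is accepted; repeat until
# stable.
l0l2_swaps <- function(X, y, lambda, gamma, b0, b, max_rounds = 25,
                       top_eval = 8, exact_moves = 80) {
  n <- nrow(X); p <- ncol(X)
  L <- 0.25 * colMeans(X^2)
  gain_scale <- L / 2 + gamma
  denom <- L + 2 * gamma
  eval_support <- function(supp) {
    theta <- refit_support(X, y, supp, gamma)
    cand <- numeric(p); cand[supp] <- theta[-1]
    list(obj = l0l2_objective(theta[1], cand, X, y, lambda, gamma),
         b0 = theta[1], b = cand)
  }
  for (round in seq_len(max_rounds)) {
    obj <- l0l2_objective(b0, b, X, y, lambda, gamma)
    supp <- which(b != 0)
    outside <- setdiff(seq_len(p), supp)
    n_moves <- length(supp) * length(outside) + p
    cands <- list()
    if (n_moves <= exact_moves) {
      # small move set: evaluate every swap, addition and deletion
      for (j in supp) for (k in outside)
        cands[[length(cands) + 1]] <-
          list(supp = sort(c(setdiff(supp, j), k)), score = Inf)
      for (k in outside)
        cands[[length(cands) + 1]] <-
          list(supp = sort(c(supp, k)), score = Inf)
    } else if (length(outside) > 0) {
      # screen swaps (drop j, add k) and pure additions by their
      # one-coordinate majorisation gain; evaluate the best few exactly
      f <- b0 + drop(X %*% b)
      for (j in c(supp, 0L)) {
        f_minus <- if (j > 0L) f - X[, j] * b[j] else f
        drop_cost <- if (j > 0L)
          logistic_loss_f(f_minus, y) - logistic_loss_f(f, y) -
            lambda - gamma * b[j]^2 else 0
        g <- -drop(crossprod(X[, outside, drop = FALSE],
                             y - plogis(f_minus))) / n
        t_star <- -g / denom[outside]
        gain <- gain_scale[outside] * t_star^2 - lambda - drop_cost
        ord <- order(-gain)
        take <- ord[seq_len(min(3, length(ord)))]
        for (k in outside[take])
          cands[[length(cands) + 1]] <-
            list(supp = sort(c(setdiff(supp, j), k)),
                 score = gain[match(k, outside)])
      }
    }
    for (j in supp)  # pure deletions are cheap: evaluate all
      cands[[length(cands) + 1]] <-
        list(supp = setdiff(supp, j), score = Inf)
    if (length(cands) == 0) break
    scores <- vapply(cands, `[[`, 0, "score")
    keep <- unique(c(which(is.infinite(scores)),
                     order(-scores)[seq_len(min(top_eval,
                                                length(cands)))]))
    best <- NULL
    for (i in keep) {
      ev <- eval_support(cands[[i]]$supp)
      if (ev$obj < obj - 1e-12 && (is.null(best) || ev$obj < best$obj))
        best <- ev
    }
    if (is.null(best)) break
    b0 <- best$b0; b <- best$b
  }
  list(b0 = b0, b = b)
}

logistic_loss_f <- function(f, y) {
  mean(log1p(exp(-ifelse(y == 1, 1, -1) * f)))
}

# full solver at one lambda (warm-startable)
l0l2_solve <- function(X, y, lambda, gamma, b0 = NULL, b = NULL,
                       track_objective = FALSE, swaps = TRUE) {
  p <- ncol(X)
  if (is.null(b)) b <- numeric(p)
  if (is.null(b0)) b0 <- qlogis(clip01(mean(y)))
  cd <- l0l2_cd(X, y, lambda, gamma, b0, b,
                track_objective = track_objective)
  sw <- if (swaps) l0l2_swaps(X, y, lambda, gamma, cd$b0, cd$b)
        else list(b0 = cd$b0, b = cd$b)
  list(b0 = sw$b0, b = sw$b, objective_path = cd$objective_path,
       objective = l0l2_objective(sw$b0, sw$b, X, y, lambda, gamma))
}

lambda_max_l0l2 <- function(X, y, gamma) {
  b0 <- qlogis(clip01(mean(y)))
  pr <- plogis(rep(b0, length(y)))
  g <- -colMeans(X * (y - pr))
  L <- 0.25 * colMeans(X^2)
  max((L / 2 + gamma) * g^2 / (L + 2 * gamma)^2)
}

stratified_folds <- function(y, k, seed) {
  with_seed(seed, {
    fold <- integer(length(y))
    for (cl in unique(y)) {
      idx <- sample(which(y == cl))
      fold[idx] <- rep_len(seq_len(k), length(idx))
    }
    fold
  })
}

#' L0+L2-penalised sparse logistic regression with cross-validated
#' penalty
#'
#' Minimises mean logistic loss `+ lambda * ||b||_0 + gamma * ||b||_2^2`
#' by cyclic coordinate descent with hard-threshold updates, exact ridge
#' refits on the active support, and local swap refinement. `lambda` is
#' chosen to minimise mean validation logistic loss over a geometric
#' grid descending from `lambda_max` (the smallest penalty with empty
#' support), by class-stratified cross-validation; the final model is
#' refit on the full training split at the chosen `lambda`.
#'
#' @param X regions x samples matrix or samples x regions matrix
#'   (auto-detected via `labels` length); features are the regions.
#' @param y training labels (0/1 or case/control).
#' @param gamma fixed L2 weight (default 0.001).
#' @param lambda_grid optional explicit grid; default 50 geometric
#'   points over 4 decades below `lambda_max`.
#' @param n_lambda,lambda_decades grid shape when `lambda_grid` is NULL.
#' @param cv_folds number of stratified folds (default 4).
#' @param seed integer seed for fold assignment.
#' @return list of class `sparse_logistic_model`: `selected` (region
#'   ids), `coefficients` (named, nonzero), `intercept`, `lambda`,
#'   `gamma`, `cv_path` (lambda, mean CV loss, support size),
#'   `objective`.
#' @export
fit_l0l2_logistic <- function(X, y, gamma = 0.001, lambda_grid = NULL,
                              n_lambda = 50, lambda_decades = 4,
                              cv_folds = 4, seed = 1) {
  y <- as_binary_labels(y)
  X <- as.matrix(X)
  if (nrow(X) != length(y) && ncol(X) == length(y)) X <- t(X)
  assert_that(nrow(X) == length(y), "X rows must match labels")
  assert_that(min(table(y)) >= cv_folds,
              "need >= cv_folds samples per class")
  features <- colnames(X) %||% paste0("f", seq_len(ncol(X)))
  colnames(X) <- features
  if (is.null(lambda_grid)) {
    lmax <- lambda_max_l0l2(X, y, gamma)
    lambda_grid <- exp(seq(log(lmax * 1.0001),
                           log(lmax * 10^(-lambda_decades)),
                           length.out = n_lambda))
  }
  lambda_grid <- sort(lambda_grid, decreasing = TRUE)
  fold <- stratified_folds(y, cv_folds, seed)
  cv_loss <- matrix(NA_real_, length(lambda_grid), cv_folds)
  for (f in seq_len(cv_folds)) {
    tr <- fold != f; va <- !tr
    b0 <- NULL; b <- NULL
    for (li in seq_along(lambda_grid)) {
      fit <- tryCatch(
        l0l2_solve(X[tr, , drop = FALSE], y[tr], lambda_grid[li], gamma,
                   b0 = b0, b = b),
        error = function(e) NULL)
      if (is.null(fit)) next  # flagged and skipped
      b0 <- fit$b0; b <- fit$b
      cv_loss[li, f] <- logistic_loss(fit$b0, fit$b,
                                      X[va, , drop = FALSE], y[va])
    }
  }
  mean_loss <- rowMeans(cv_loss)
  ok <- which(is.finite(mean_loss))
  assert_that(length(ok) > 0, "no lambda converged in cross-validation")
  best_li <- ok[which.min(mean_loss[ok])]  # ties: larger lambda wins
  # final path refit on the full training data down to the chosen
  # lambda; supports discovered anywhere on the path are candidate
  # subsets and the best objective at the chosen lambda wins
  b0 <- NULL; b <- NULL; final <- NULL
  support_path <- integer(length(lambda_grid))
  seen_supports <- list()
  for (li in seq_along(lambda_grid)) {
    sol <- l0l2_solve(X, y, lambda_grid[li], gamma, b0 = b0, b = b)
    b0 <- sol$b0; b <- sol$b
    support_path[li] <- sum(sol$b != 0)
    seen_supports[[li]] <- which(sol$b != 0)
    if (li == best_li) final <- sol
  }
  lam <- lambda_grid[best_li]
  for (supp in unique(seen_supports)) {
    theta <- refit_support(X, y, supp, gamma)
    cand <- numeric(ncol(X)); cand[supp] <- theta[-1]
    o <- l0l2_objective(theta[1], cand, X, y, lam, gamma)
    if (o < final$objective - 1e-12)
      final <- list(b0 = theta[1], b = cand, objective = o)
  }
  # polish the winner with one more swap pass at the chosen lambda
  sw <- l0l2_swaps(X, y, lam, gamma, final$b0, final$b)
  final <- list(b0 = sw$b0, b = sw$b,
                objective = l0l2_objective(sw$b0, sw$b, X, y, lam,
                                           gamma))
  nz <- which(final$b != 0)
  structure(list(selected = features[nz],
                 coefficients = setNames(final$b[nz], features[nz]),
                 intercept = final$b0, lambda = lambda_grid[best_li],
                 gamma = gamma,
                 cv_path = data.frame(lambda = lambda_grid,
                                      cv_loss = mean_loss,
                                      support = support_path),
                 objective = final$objective, features = features,
                 seed = seed),
            class = "sparse_logistic_model")
}

#' @export
predict.sparse_logistic_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!all(object$features %in% rownames(newdata)) &&
      all(object$features %in% colnames(newdata)))
    newdata <- t(newdata)
  f <- object$intercept
  if (length(object$selected) > 0)
    f <- f + drop(crossprod(newdata[object$selected, , drop = FALSE],
                            object$coefficients))
  plogis(f)
}

#' Select representative regions per cluster with shallow decision trees
#'
#' Fits one depth-bounded classification tree (Gini impurity) per
#' methylation cluster, using only that cluster's regions as features;
#' the regions used at any split node are selected. The union across
#' clusters is returned with per-cluster provenance. A cluster in which
#' no split improves impurity contributes nothing (warning).
#'
#' @param x regions x samples beta matrix (training split).
#' @param y training labels.
#' @param clusters a `cluster_model` from [kmeans_cluster()].
#' @param max_depth tree depth bound (default 2).
#' @param seed integer seed.
#' @return character vector of selected region ids with a `provenance`
#'   attribute (data.frame region, cluster).
#' @export
select_by_tree_per_cluster <- function(x, y, clusters, max_depth = 2,
                                       seed = 1) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  assert_that(ncol(x) == length(y), "x columns must match labels")
  assert_that(all(names(clusters$assignments) %in% rownames(x)),
              "cluster assignments name regions absent from x")
  sel <- list()
  with_seed(seed, {
    for (cl in seq_len(clusters$k)) {
      members <- names(clusters$assignments)[clusters$assignments == cl]
      assert_that(length(members) > 0,
                  paste0("cluster ", cl, " is empty"))
      dat <- as.data.frame(t(x[members, , drop = FALSE]))
      safe <- make.names(members)
      names(dat) <- safe
      dat$.y <- factor(y, levels = c(0, 1))
      fit <- rpart::rpart(.y ~ ., data = dat, method = "class",
                          control = rpart::rpart.control(
                            maxdepth = max_depth, cp = 0.01,
                            minsplit = 5, minbucket = 2,
                            maxsurrogate = 0, maxcompete = 0,
                            xval = 0))
      used <- setdiff(unique(as.character(fit$frame$var)), "<leaf>")
      if (length(used) == 0) {
        warning("cluster ", cl, ": no split improves impurity; ",
                "contributes no regions")
        next
      }
      sel[[length(sel) + 1]] <- data.frame(
        region = members[match(used, safe)], cluster = cl,
        stringsAsFactors = FALSE)
    }
  })
  prov <- do.call(rbind, sel)
  if (is.null(prov))
    prov <- data.frame(region = character(), cluster = integer(),
                       stringsAsFactors = FALSE)
  structure(unique(prov$region), provenance = prov)
}

#' Random forest on selected regions
#'
#' Bagged classification trees on the restricted feature set; predicted
#' probability of case status = fraction of trees voting case.
#'
#' @param x regions x samples beta matrix restricted to (or containing)
#'   the selected regions.
#' @param y training labels.
#' @param selected region ids to use (default: all rows of `x`).
#' @param n_trees forest size (default 500).
#' @param seed integer seed.
#' @return list of class `forest_model`.
#' @export
fit_forest <- function(x, y, selected = rownames(x), n_trees = 500,
                       seed = 1) {
  x <- as.matrix(x)
  y <- as_binary_labels(y)
  assert_that(length(selected) >= 1, "need at least one selected region")
  assert_that(all(selected %in% rownames(x)),
              "selected regions absent from x")
  feat <- t(x[selected, , drop = FALSE])
  const <- apply(feat, 2, var) == 0
  assert_that(!any(const),
              paste0("constant feature(s): ",
                     paste(selected[const], collapse = ", ")))
  colnames(feat) <- make.names(selected)
  fit <- with_seed(seed,
    randomForest::randomForest(x = feat,
                               y = factor(y, levels = c(0, 1)),
                               ntree = n_trees))
  structure(list(forest = fit, selected = selected,
                 feature_names = colnames(feat), n_trees = n_trees,
                 seed = seed),
            class = "forest_model")
}

#' @export
predict.forest_model <- function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  if (!all(object$selected %in% rownames(newdata)) &&
      all(object$selected %in% colnames(newdata)))
    newdata <- t(newdata)
  feat <- t(newdata[object$selected, , drop = FALSE])
  colnames(feat) <- object$feature_names
  unname(predict(object$forest, feat, type = "prob")[, "1"])
}

#' Evaluate a multi-probe model on the held-out test split
#'
#' Applies the leakage guard, then computes AU-ROC / AU-PRC of the
#' model's predicted probabilities on the test samples via the shared
#' metric primitives.
#'
#' @param model a `sparse_logistic_model` or `forest_model` (anything
#'   with a `predict` method returning probabilities).
#' @param x_test regions x samples beta matrix (test split).
#' @param labels_test test labels.
#' @param train_ids,test_ids sample ids for the leakage check.
#' @return list: `test_auroc`, `test_auprc`, `predictions`.
#' @export
evaluate_multi <- function(model, x_test, labels_test,
                           train_ids = NULL, test_ids = NULL) {
  if (!is.null(train_ids) && !is.null(test_ids)) {
    leak <- intersect(train_ids, test_ids)
    assert_that(length(leak) == 0,
                paste0("train/test overlap (leakage): ",
                       paste(leak, collapse = ", ")))
  }
  p <- predict(model, x_test)
  y <- as_binary_labels(labels_test)
  list(test_auroc = auroc(p, y), test_auprc = auprc(p, y),
       predictions = p)
}
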