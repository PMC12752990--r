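# ROC / precision-recall primitives and per-region logistic models with
# bootstrap AU-ROC screening.

#' Area under the ROC curve
#'
#' The probability that a randomly chosen positive outscores a randomly
#' chosen negative, with ties counting one half (Mann-Whitney
#' formulation, computed from midranks).
#'
#' @param scores numeric predictions (higher = more positive).
#' @param labels 0/1 (or logical / case-control factor) truth.
#' @return value in `[0, 1]`.
#' @export
auroc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  assert_that(length(scores) == length(y), "scores/labels length mismatch")
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  assert_that(n1 > 0 && n0 > 0, "both classes must be present")
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Area under the precision-recall curve (average precision)
#'
#' Step-function integral of the precision-recall curve with no
#' interpolation: thresholds sweep the distinct score values from high
#' to low; each threshold contributes its precision times the recall
#' gained there. With all-equal scores this reduces to the prevalence.
#'
#' @inheritParams auroc
#' @return value in `[0, 1]`.
#' @export
auprc <- function(scores, labels) {
  y <- as_binary_labels(labels)
  assert_that(length(scores) == length(y), "scores/labels length mismatch")
  n1 <- sum(y == 1)
  assert_that(n1 > 0, "at least one positive required")
  o <- order(scores, decreasing = TRUE)
  s <- scores[o]; y <- y[o]
  grp_end <- c(s[-1] != s[-length(s)], TRUE)  # last index of each tie group
  tp <- cumsum(y)[grp_end]
  np <- seq_along(y)[grp_end]
  prec <- tp / np
  d_tp <- diff(c(0, tp))
  sum(prec * d_tp) / n1
}

as_binary_labels <- function(labels) {
  if (is.factor(labels)) labels <- as.character(labels)
  if (is.character(labels)) {
    lab <- tolower(labels)
    assert_that(all(lab %in% c("case", "control")),
                "character labels must be case/control")
    return(as.integer(lab == "case"))
  }
  y <- as.integer(labels)
  assert_that(all(y %in% c(0L, 1L)), "labels must be 0/1")
  y
}

#' Fit a single-region logistic model
#'
#' Maximum-likelihood logistic regression of case status on one region's
#' mean methylation. Perfect separation is tolerated: coefficients sit
#' at the optimiser's bound and the model is flagged `separated` (its
#' scores still rank samples correctly). A constant feature is flagged
#' and predicts the prevalence (train AUC 0.5).
#'
#' @param region_betas_train numeric vector, one beta per training
#'   sample.
#' @param labels_train training labels (0/1 or case/control).
#' @return list of class `single_dmr_model`: `intercept`, `slope`,
#'   `separated`, `constant_feature`.
#' @export
fit_single_dmr <- function(region_betas_train, labels_train) {
  y <- as_binary_labels(labels_train)
  x <- as.numeric(region_betas_train)
  assert_that(length(x) == length(y), "feature/labels length mismatch")
  assert_that(sum(y == 1) > 0 && sum(y == 0) > 0,
              "both classes required in training labels")
  if (var(x) == 0)
    return(structure(list(intercept = qlogis(clip01(mean(y))), slope = 0,
                          separated = FALSE, constant_feature = TRUE),
                     class = "single_dmr_model"))
  fit <- suppressWarnings(glm(y ~ x, family = binomial()))
  sep <- !fit$converged || any(abs(coef(fit)) > 1e6) ||
    any(fit$fitted.values > 1 - 1e-8 & y == 1) &&
    any(fit$fitted.values < 1e-8 & y == 0)
  structure(list(intercept = unname(coef(fit)[1]),
                 slope = unname(coef(fit)[2]),
                 separated = isTRUE(sep) || !fit$converged,
                 constant_feature = FALSE),
            class = "single_dmr_model")
}

#' @export
predict.single_dmr_model <- function(object, newdata, ...) {
  plogis(object$intercept + object$slope * as.numeric(newdata))
}

#' Bootstrap AU-ROC screening of single-region models
#'
#' For each region: `n_boot` class-stratified bootstrap resamples of the
#' training set (cases resampled among cases, controls among controls,
#' so both classes always appear); the model is refit on each resample
#' and scored by AU-ROC on that resample (in-bag). Reports the bootstrap
#' mean and the 2.5/97.5 percentile interval; an interval whose
#' bootstrap AUCs are all identical is marked degenerate (printed
#' "(-, -)" in reports). Models are ranked by bootstrap mean AU-ROC.
#'
#' @param x_train regions x samples beta matrix (training split).
#' @param labels_train training labels.
#' @param n_boot bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param top_n how many top-ranked regions to keep in the summary table
#'   (default 20); all regions are returned in `all`.
#' @return list of class `bootstrap_screen`: `table` (top_n rows:
#'   region, train_auroc, train_auprc, boot_mean_auroc, boot_ci_lo/hi,
#'   degenerate_ci), `all`, `models` (per-region
#'   [fit_single_dmr()] fits), `seed`.
#' @export
bootstrap_screen <- function(x_train, labels_train, n_boot = 1000,
                             seed = 1, top_n = 20) {
  x_train <- as.matrix(x_train)
  y <- as_binary_labels(labels_train)
  assert_that(ncol(x_train) == length(y),
              "x_train columns must match labels")
  idx_case <- which(y == 1); idx_ctrl <- which(y == 0)
  assert_that(length(idx_case) >= 2 && length(idx_ctrl) >= 2,
              "need >= 2 samples per class")
  regions <- rownames(x_train) %||% paste0("region", seq_len(nrow(x_train)))
  models <- lapply(seq_len(nrow(x_train)), function(i)
    fit_single_dmr(x_train[i, ], y))
  names(models) <- regions
  boot_idx <- with_seed(seed, replicate(n_boot, c(
    sample(idx_case, length(idx_case), replace = TRUE),
    sample(idx_ctrl, length(idx_ctrl), replace = TRUE)),
    simplify = FALSE))
  rows <- lapply(seq_len(nrow(x_train)), function(i) {
    xi <- x_train[i, ]
    mdl <- models[[i]]
    train_auc <- if (mdl$constant_feature) 0.5
                 else auroc(predict(mdl, xi), y)
    train_ap <- if (mdl$constant_feature) mean(y)
                else auprc(predict(mdl, xi), y)
    aucs <- vapply(boot_idx, function(b) {
      xb <- xi[b]; yb <- y[b]
      if (var(xb) == 0) return(0.5)
      m <- fit_single_dmr(xb, yb)
      auroc(predict(m, xb), yb)
    }, 0)
    degenerate <- max(aucs) - min(aucs) < .Machine$double.eps^0.5
    ci <- if (degenerate) c(NA_real_, NA_real_)
          else unname(quantile(aucs, c(0.025, 0.975), type = 7))
    data.frame(region = regions[i], train_auroc = train_auc,
               train_auprc = train_ap, boot_mean_auroc = mean(aucs),
               boot_ci_lo = ci[1], boot_ci_hi = ci[2],
               degenerate_ci = degenerate, stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab <- tab[order(-tab$boot_mean_auroc, -tab$train_auroc, tab$region), ,
             drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = head(tab, top_n), all = tab, models = models,
                 n_boot = n_boot, seed = seed),
            class = "bootstrap_screen")
}

format_ci <- function(lo, hi, degenerate) {
  ifelse(degenerate, "(-, -)",
         sprintf("(%.3f, %.3f)", lo, hi))
}

#' Evaluate single-region models on the held-out test split
#'
#' Hard-errors if a test sample id also appears in the training ids
#' (leakage guard); otherwise computes AU-ROC and AU-PRC of each model's
#' predicted probabilities on the test samples.
#'
#' @param screen a [bootstrap_screen()] result (or a named list of
#'   `single_dmr_model`s).
#' @param x_test regions x samples beta matrix (test split).
#' @param labels_test test labels.
#' @param train_ids,test_ids sample id vectors used for the leakage
#'   check.
#' @return data.frame: region, test_auroc, test_auprc, merged with the
#'   screening table when available.
#' @export
evaluate_on_test <- function(screen, x_test, labels_test,
                             train_ids = NULL, test_ids = NULL) {
  if (!is.null(train_ids) && !is.null(test_ids)) {
    leak <- intersect(train_ids, test_ids)
    assert_that(length(leak) == 0,
                paste0("train/test overlap (leakage): ",
                       paste(leak, collapse = ", ")))
  }
  models <- if (inherits(screen, "bootstrap_screen")) screen$models
            else screen
  x_test <- as.matrix(x_test)
  y <- as_binary_labels(labels_test)
  use <- intersect(names(models), rownames(x_test))
  assert_that(length(use) > 0, "no shared regions between models and x_test")
  rows <- lapply(use, function(r) {
    p <- predict(models[[r]], x_test[r, ])
    data.frame(region = r, test_auroc = auroc(p, y),
               test_auprc = auprc(p, y), stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, rows)
  if (inherits(screen, "bootstrap_screen"))
    ev <- merge(screen$all, ev, by = "region", sort = FALSE)
  ev
}
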