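# Coverage filtering, beta values, sequencing summaries, PCA and PVCA.

#' Filter CpG sites by coverage
#'
#' Keeps exactly the sites with `total >= min_cov` in every sample and
#' `total <= max_cov` in every sample; a single low- or high-coverage
#' sample disqualifies the site. Kept/removed counts are attached as the
#' `"filter_stats"` attribute. The operation is idempotent.
#'
#' @param m a [meth_counts].
#' @param min_cov minimum reads per CpG required in all samples.
#' @param max_cov maximum reads per CpG tolerated in any sample.
#' @return filtered [meth_counts].
#' @export
filter_cpgs <- function(m, min_cov = 10, max_cov = 500) {
  stopifnot(inherits(m, "meth_counts"))
  assert_that(min_cov <= max_cov, "min_cov > max_cov")
  lo <- apply(m$total, 1, min)
  hi <- apply(m$total, 1, max)
  keep <- lo >= min_cov & hi <= max_cov
  out <- meth_counts(m$sites[keep, , drop = FALSE],
                     m$meth[keep, , drop = FALSE],
                     m$total[keep, , drop = FALSE], m$samples)
  attr(out, "filter_stats") <- c(kept = sum(keep), removed = sum(!keep))
  out
}

#' Per-CpG methylation level (beta value)
#'
#' Elementwise `methylated / total`. Requires a coverage-filtered matrix:
#' any zero total is an error, not an NA.
#'
#' @param m a [meth_counts] with all totals >= 1.
#' @return list of class `beta_matrix` with `sites` (data.frame) and
#'   `beta` (sites x samples numeric matrix in `[0, 1]`).
#' @export
compute_beta <- function(m) {
  stopifnot(inherits(m, "meth_counts"))
  if (any(m$total == 0L)) {
    i <- which(m$total == 0L, arr.ind = TRUE)[1, ]
    stop(sprintf("total = 0 at %s:%d; run filter_cpgs first",
                 m$sites$chrom[i[1]], m$sites$pos[i[1]]), call. = FALSE)
  }
  b <- m$meth / m$total
  dimnames(b) <- dimnames(m$meth)
  structure(list(sites = m$sites, beta = b, samples = m$samples),
            class = "beta_matrix")
}

subset_beta_samples <- function(b, ids) {
  assert_that(all(ids %in% b$samples), "unknown sample id")
  structure(list(sites = b$sites, beta = b$beta[, ids, drop = FALSE],
                 samples = ids), class = "beta_matrix")
}

#' Per-group means of a sequencing summary table
#'
#' Arithmetic mean of each numeric column within each group. Full
#' precision is retained; rounding to a report's printed precision is the
#' caller's concern.
#'
#' @param tbl data.frame with one row per sample, numeric stat columns.
#' @param groups character/factor vector assigning each row to a group.
#' @return data.frame of per-group means, one row per group.
#' @export
summarize_sequencing <- function(tbl, groups) {
  tbl <- as.data.frame(tbl)
  assert_that(length(groups) == nrow(tbl),
              "groups must have one entry per row")
  groups <- as.character(groups)
  assert_that(!anyNA(groups) && all(nzchar(groups)), "empty group label")
  num <- vapply(tbl, is.numeric, TRUE)
  assert_that(any(num), "no numeric columns to summarise")
  out <- lapply(split(seq_len(nrow(tbl)), groups), function(i) {
    assert_that(length(i) >= 1, "empty group")
    colMeans(tbl[i, num, drop = FALSE])
  })
  res <- as.data.frame(do.call(rbind, out))
  res <- cbind(group = rownames(res), res)
  rownames(res) <- NULL
  res
}

#' Principal component analysis of methylation levels
#'
#' Sites constant across all samples are dropped (they carry no variance
#' and break scaling); the rest are standardised to unit variance and
#' decomposed by exact SVD ([stats::prcomp]). Samples are observations.
#'
#' @param b a `beta_matrix` from [compute_beta()].
#' @return list with `scores` (samples x PCs), `loadings`,
#'   `var_fraction` (sums to 1), and `n_sites_used`.
#' @export
run_pca <- function(b) {
  stopifnot(inherits(b, "beta_matrix"))
  assert_that(length(b$samples) >= 2, "PCA needs at least 2 samples")
  x <- t(b$beta)                     # samples x sites
  keep <- matrixStats_colVars(x) > 0
  assert_that(sum(keep) >= 2, "fewer than 2 non-constant sites")
  p <- prcomp(x[, keep, drop = FALSE], center = TRUE, scale. = TRUE)
  vf <- p$sdev^2 / sum(p$sdev^2)
  list(scores = p$x, loadings = p$rotation, var_fraction = vf,
       n_sites_used = sum(keep))
}

# column variances without a matrixStats dependency
matrixStats_colVars <- function(x) {
  n <- nrow(x)
  if (n < 2) return(rep(0, ncol(x)))
  mu <- colMeans(x)
  colSums(x^2) / (n - 1) - mu^2 * n / (n - 1)
}

#' Principal variance component analysis
#'
#' Attributes sample-to-sample methylation variance to known factors:
#' principal components are retained until their cumulative variance
#' reaches `var_threshold`; each retained PC's score vector is fit with a
#' random-effects model (one random intercept per factor, main effects
#' only); the per-PC variance-component fractions are then averaged with
#' eigenvalue weights. Continuous age is binned to whole years so it can
#' act as a grouping factor.
#'
#' @param b a `beta_matrix`.
#' @param sheet a `sample_sheet` covering the same samples.
#' @param factors column names of `sheet` to attribute variance to.
#' @param var_threshold cumulative PC variance to retain (default 0.6).
#' @return list of class `pvca_result`: `fractions` (named, including
#'   `residual`), `per_pc` matrix, `n_pcs`, `eigen_weights`.
#' @export
run_pvca <- function(b, sheet, factors = c("breed", "age_years", "sex",
                                           "setting"),
                     var_threshold = 0.6) {
  stopifnot(inherits(b, "beta_matrix"))
  sheet <- validate_sample_sheet(sheet)
  assert_that(all(b$samples %in% sheet$sample_id),
              "sheet does not cover all samples")
  sheet <- sheet[match(b$samples, sheet$sample_id), , drop = FALSE]
  miss <- setdiff(factors, names(sheet))
  assert_that(length(miss) == 0,
              paste0("factor(s) not in sheet: ", paste(miss, collapse = ", ")))
  fdat <- lapply(factors, function(f) {
    v <- sheet[[f]]
    if (is.numeric(v)) v <- as.integer(round(v))  # bin e.g. age to years
    factor(v)
  })
  names(fdat) <- factors
  single <- vapply(fdat, function(f) nlevels(f) < 2, TRUE)
  if (any(single))
    warning("factor(s) with a single level contribute 0: ",
            paste(factors[single], collapse = ", "))
  use <- factors[!single]
  pca <- run_pca(b)
  ev <- pca$var_fraction
  n_pc <- which(cumsum(ev) >= var_threshold)[1]
  if (is.na(n_pc)) n_pc <- length(ev)
  w <- ev[seq_len(n_pc)] / sum(ev[seq_len(n_pc)])
  per_pc <- matrix(0, n_pc, length(factors) + 1,
                   dimnames = list(paste0("PC", seq_len(n_pc)),
                                   c(factors, "residual")))
  for (i in seq_len(n_pc)) {
    dat <- data.frame(score = pca$scores[, i], fdat,
                      check.names = FALSE)
    if (length(use) == 0) { per_pc[i, "residual"] <- 1; next }
    form <- as.formula(paste("score ~",
                             paste(sprintf("(1 | `%s`)", use),
                                   collapse = " + ")))
    fit <- tryCatch(
      suppressWarnings(suppressMessages(
        lme4::lmer(form, data = dat,
                   control = lme4::lmerControl(check.conv.singular =
                                                 "ignore")))),
      error = function(e) NULL)
    if (is.null(fit)) { per_pc[i, "residual"] <- 1; next }
    vc <- as.data.frame(lme4::VarCorr(fit))
    tot <- sum(vc$vcov)
    for (f in use) {
      row <- vc$grp == f
      if (any(row)) per_pc[i, f] <- sum(vc$vcov[row]) / tot
    }
    per_pc[i, "residual"] <- vc$vcov[vc$grp == "Residual"] / tot
  }
  fractions <- colSums(per_pc * w)
  structure(list(fractions = fractions, per_pc = per_pc, n_pcs = n_pc,
                 eigen_weights = w),
            class = "pvca_result")
}

#' @export
print.pvca_result <- function(x, ...) {
  cat(sprintf("PVCA over %d PCs (eigenvalue-weighted)\n", x$n_pcs))
  f <- sort(x$fractions, decreasing = TRUE)
  for (nm in names(f))
    cat(sprintf("  %-12s %5.1f%%\n", nm, 100 * f[nm]))
  invisible(x)
}
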