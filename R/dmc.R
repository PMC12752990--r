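# Covariate-adjusted per-CpG differential methylation testing with a
# permutation-null false-positive filter.
#
# The test is a binomial logistic regression of per-sample
# (methylated, unmethylated) counts on group + covariates; the group
# term's significance comes from a likelihood-ratio chi-square with 1 df.
# No overdispersion correction is applied by default (per-CpG binomial
# family); the effect size reported alongside is the difference in
# unweighted per-sample mean beta values, in percentage points.

# Build the shared design matrix. Breed is one-hot with levels observed
# in < min_level_n samples pooled into "other" (many rare breeds would
# otherwise make the design singular); age enters as continuous years.
build_design <- function(sheet, covariates, min_level_n = 2) {
  n <- nrow(sheet)
  X <- matrix(1, n, 1, dimnames = list(sheet$sample_id, "intercept"))
  for (cv in covariates) {
    assert_that(cv %in% names(sheet),
                paste0("covariate column missing from sheet: ", cv))
    v <- sheet[[cv]]
    if (is.numeric(v)) {
      col <- matrix(as.numeric(scale(v, scale = FALSE)), ncol = 1,
                    dimnames = list(NULL, cv))
      X <- cbind(X, col)
    } else {
      v <- as.character(v)
      tab <- table(v)
      rare <- names(tab)[tab < min_level_n]
      if (length(rare) > 0) v[v %in% rare] <- "other"
      lev <- sort(unique(v))
      if (length(lev) < 2) next  # constant factor carries no information
      for (l in lev[-1])
        X <- cbind(X, matrix(as.numeric(v == l), ncol = 1,
                             dimnames = list(NULL, paste0(cv, ".", l))))
    }
  }
  # drop linearly dependent columns to keep the IRLS solve well posed
  qrX <- qr(X)
  if (qrX$rank < ncol(X))
    X <- X[, qrX$pivot[seq_len(qrX$rank)], drop = FALSE]
  X
}

# core scan: LRT p-value + meth_diff for every site, given a group
# indicator vector (0/1) and the sample sheet for covariates. The
# reduced (covariate-only) model is label-free, so its per-site
# log-likelihood can be cached across label permutations.
dmc_scan <- function(m, group01, sheet, covariates, ll_cache = NULL) {
  X <- build_design(sheet, covariates)
  g <- matrix(as.numeric(group01), ncol = 1,
              dimnames = list(NULL, "group"))
  Xfull <- cbind(X, g)
  qrX <- qr(Xfull)
  assert_that(qrX$rank == ncol(Xfull),
              "group indicator is confounded with the covariates")
  res <- dmc_lrt_cpp(m$meth, m$total, Xfull, ncol(Xfull) - 1L, ll_cache)
  beta <- ifelse(m$total > 0, m$meth / m$total, NA_real_)
  mean_g1 <- rowMeans(beta[, group01 == 1, drop = FALSE], na.rm = TRUE)
  mean_g0 <- rowMeans(beta[, group01 == 0, drop = FALSE], na.rm = TRUE)
  out <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    strand = m$sites$strand,
                    meth_diff = 100 * (mean_g1 - mean_g0),
                    p = res[, "p"], converged = res[, "converged"] == 1,
                    stringsAsFactors = FALSE)
  attr(out, "ll_reduced") <- res[, "ll_reduced"]
  out
}

#' Covariate-adjusted differential methylation test at one CpG
#'
#' Binomial logistic regression of (methylated, unmethylated) counts on
#' group + covariates; p-value from the likelihood-ratio test of the
#' group term. A degenerate fit yields `p = 1` with `converged = FALSE`
#' rather than an error.
#'
#' @param methylated,total integer count vectors, one entry per sample.
#' @param sheet a `sample_sheet` for these samples (row order matching).
#' @param covariates sheet columns to adjust for (default none).
#' @return list with `p_value`, `meth_diff` (percentage points,
#'   case - control) and `converged`.
#' @export
test_cpg <- function(methylated, total, sheet, covariates = character()) {
  sheet <- validate_sample_sheet(sheet)
  assert_that(length(methylated) == nrow(sheet) &&
                length(total) == nrow(sheet),
              "counts must have one entry per sample")
  assert_that(all(total >= 1), "all totals must be >= 1")
  assert_that(min(table(sheet$group)) >= 2,
              "need >= 2 samples per group")
  m <- meth_counts(data.frame(chrom = "site", pos = 1L, strand = "+"),
                   matrix(as.integer(methylated), 1),
                   matrix(as.integer(total), 1), sheet$sample_id)
  d <- dmc_scan(m, as.integer(sheet$group == "case"), sheet, covariates)
  list(p_value = d$p[1], meth_diff = d$meth_diff[1],
       converged = d$converged[1])
}

#' Call differentially methylated cytosines
#'
#' Tests every site with [test_cpg()]'s model, adjusts p-values by
#' Benjamini-Hochberg over all tested sites, and returns the sites with
#' `q < q_cutoff` and `|meth_diff| > diff_cutoff`, tagged
#' `hyper`/`hypo` by the sign of the case-minus-control difference.
#' Run this on training samples only.
#'
#' @param m filtered [meth_counts].
#' @param sheet matching `sample_sheet`.
#' @param covariates sheet columns to adjust for, e.g.
#'   `c("breed", "age_years")`.
#' @param diff_cutoff minimum absolute methylation difference,
#'   percentage points (default 10).
#' @param q_cutoff BH q-value threshold (default 0.05).
#' @param all_sites return all tested sites (with a `selected` flag)
#'   instead of the selected subset only.
#' @return data.frame of DMC records: chrom, pos, strand, meth_diff, p,
#'   q, direction, converged.
#' @export
call_dmcs <- function(m, sheet, covariates = c("breed", "age_years"),
                      diff_cutoff = 10, q_cutoff = 0.05,
                      all_sites = FALSE) {
  stopifnot(inherits(m, "meth_counts"))
  sheet <- validate_sample_sheet(sheet)
  assert_that(setequal(sheet$sample_id, m$samples),
              "sheet and matrix sample sets differ")
  sheet <- sheet[match(m$samples, sheet$sample_id), , drop = FALSE]
  assert_that(min(table(sheet$group)) >= 2, "need >= 2 samples per group")
  d <- dmc_scan(m, as.integer(sheet$group == "case"), sheet, covariates)
  d$q <- p.adjust(d$p, method = "BH")
  d$direction <- ifelse(d$meth_diff > 0, "hyper", "hypo")
  d$selected <- d$q < q_cutoff & abs(d$meth_diff) > diff_cutoff
  if (all_sites) d else d[d$selected, , drop = FALSE]
}

#' Permutation-null false-positive filter for DMC candidates
#'
#' Shuffles the case/control labels (covariates stay attached to their
#' samples), re-runs the full DMC call per permutation, and counts how
#' often each candidate is re-called under a permuted labelling. A
#' candidate recurring in more than `max_hits` permutations is removed
#' ("detected more than once" at the default `max_hits = 1`).
#'
#' @param m,sheet,covariates as in [call_dmcs()] (same inputs that
#'   produced `dmcs`).
#' @param dmcs result of [call_dmcs()].
#' @param n_perm number of label permutations (default 100).
#' @param max_hits maximum tolerated permutation hit count (default 1).
#' @param seed integer seed for the permutation stream.
#' @param diff_cutoff,q_cutoff thresholds, matching the original call.
#' @param perm_covariates adjust for covariates inside permutation
#'   re-calls too (default TRUE, mirroring the original call).
#' @return list with `dmcs` (retained records, with a `perm_hits`
#'   column) and `ledger` (per-candidate hit counts, n_perm, seed).
#' @export
permutation_filter <- function(m, sheet, covariates = c("breed",
                                                        "age_years"),
                               dmcs, n_perm = 100, max_hits = 1,
                               seed = 1, diff_cutoff = 10,
                               q_cutoff = 0.05, perm_covariates = TRUE) {
  assert_that(n_perm >= 1, "n_perm must be >= 1")
  sheet <- validate_sample_sheet(sheet)
  sheet <- sheet[match(m$samples, sheet$sample_id), , drop = FALSE]
  key <- if (nrow(dmcs) > 0) paste0(dmcs$chrom, ":", dmcs$pos)
         else character(0)
  hits <- setNames(integer(length(key)), key)
  if (length(key) > 0 && max_hits < n_perm) {
    perms <- with_seed(seed, replicate(n_perm, sample(sheet$group),
                                       simplify = FALSE))
    cov_use <- if (perm_covariates) covariates else character()
    ll_cache <- NULL  # covariate-only model is label-free: fit once
    for (p in perms) {
      pd <- dmc_scan(m, as.integer(p == "case"), sheet, cov_use,
                     ll_cache = ll_cache)
      if (is.null(ll_cache)) ll_cache <- attr(pd, "ll_reduced")
      q <- p.adjust(pd$p, method = "BH")
      sel <- q < q_cutoff & abs(pd$meth_diff) > diff_cutoff
      hk <- paste0(pd$chrom[sel], ":", pd$pos[sel])
      found <- key %in% hk
      hits[found] <- hits[found] + 1L
    }
  }
  keep <- hits <= max_hits
  out <- dmcs
  out$perm_hits <- as.integer(hits)
  structure(list(dmcs = out[keep, , drop = FALSE],
                 ledger = list(hits = hits, n_perm = n_perm, seed = seed,
                               max_hits = max_hits)),
            class = "perm_filter_result")
}
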