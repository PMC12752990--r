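# Per-CpG test and permutation filter.

test_that("the per-CpG test matches a pooled chi-square oracle on a clear effect", {
  # cases pooled 90/100 methylated vs controls 50/100
  sheet <- two_group_sheet(2, 2)
  res <- test_cpg(methylated = c(45L, 45L, 25L, 25L),
                  total = c(50L, 50L, 50L, 50L), sheet)
  expect_equal(res$meth_diff, 40)
  expect_lt(res$p_value, 0.001)
  oracle <- chisq.test(matrix(c(90, 10, 50, 50), 2, byrow = TRUE),
                       correct = FALSE)$p.value
  # same direction and magnitude class as the 2x2 chi-square
  expect_lt(res$p_value, oracle * 100)
  expect_lt(abs(log10(res$p_value) - log10(oracle)), 2)
})

test_that("identical groups give a null result and label swap negates the effect", {
  sheet <- two_group_sheet(3, 3)
  res <- test_cpg(c(20L, 22L, 18L, 20L, 22L, 18L), rep(40L, 6), sheet)
  expect_equal(res$meth_diff, 0)
  expect_gt(res$p_value, 0.9)
  swapped <- sheet
  swapped$group <- ifelse(sheet$group == "case", "control", "case")
  a <- test_cpg(c(30L, 28L, 26L, 10L, 12L, 14L), rep(40L, 6), sheet)
  b <- test_cpg(c(30L, 28L, 26L, 10L, 12L, 14L), rep(40L, 6), swapped)
  expect_equal(a$meth_diff, -b$meth_diff)
  expect_equal(a$p_value, b$p_value, tolerance = 1e-6)
})

test_that("call_dmcs applies both thresholds and tags direction", {
  coh <- small_cohort()
  f <- filter_cpgs(coh$counts)
  d <- call_dmcs(f, coh$sheet, covariates = character())
  expect_true(all(d$q < 0.05))
  expect_true(all(abs(d$meth_diff) > 10))
  expect_equal(d$direction, ifelse(d$meth_diff > 0, "hyper", "hypo"))
  # vacuous threshold empties the result
  d2 <- call_dmcs(f, coh$sheet, covariates = character(),
                  diff_cutoff = 100)
  expect_equal(nrow(d2), 0)
  expect_error(call_dmcs(f, coh$sheet, covariates = "no_such_column"),
               "covariate column missing")
})

test_that("BH q-values are monotone in p-values", {
  coh <- small_cohort()
  f <- filter_cpgs(coh$counts)
  d <- call_dmcs(f, coh$sheet, covariates = character(),
                 all_sites = TRUE)
  o <- order(d$p)
  expect_true(all(diff(d$q[o]) >= -1e-12))
  expect_true(all(d$p >= 0 & d$p <= 1))
  expect_true(all(d$q >= 0 & d$q <= 1))
})

test_that("planted CpGs at strong effect are called", {
  coh <- small_cohort()  # delta_beta = 0.2 at 70x
  f <- filter_cpgs(coh$counts)
  d <- call_dmcs(f, coh$sheet, covariates = c("breed", "age_years"))
  tr <- coh$truth$regions
  called <- logical(nrow(tr))
  for (i in seq_len(nrow(tr)))
    called[i] <- any(d$chrom == tr$chrom[i] & d$pos >= tr$start[i] &
                       d$pos <= tr$end[i])
  expect_gte(mean(called), 0.8)
})

test_that("the permutation filter is reproducible, monotone and vacuous at max_hits = n_perm", {
  coh <- small_cohort()
  f <- filter_cpgs(coh$counts)
  d <- call_dmcs(f, coh$sheet, covariates = character())
  a <- permutation_filter(f, coh$sheet, covariates = character(),
                          dmcs = d, n_perm = 8, seed = 5)
  b <- permutation_filter(f, coh$sheet, covariates = character(),
                          dmcs = d, n_perm = 8, seed = 5)
  expect_identical(a$dmcs, b$dmcs)           # bit-for-bit reproducible
  expect_identical(a$ledger$hits, b$ledger$hits)
  expect_true(all(a$ledger$hits >= 0 & a$ledger$hits <= 8))
  # monotone: larger max_hits never removes a previously retained site
  strict <- permutation_filter(f, coh$sheet, covariates = character(),
                               dmcs = d, n_perm = 8, max_hits = 0,
                               seed = 5)
  loose <- permutation_filter(f, coh$sheet, covariates = character(),
                              dmcs = d, n_perm = 8, max_hits = 3,
                              seed = 5)
  expect_true(all(paste(strict$dmcs$chrom, strict$dmcs$pos) %in%
                    paste(loose$dmcs$chrom, loose$dmcs$pos)))
  # identity when max_hits = n_perm
  all_pass <- permutation_filter(f, coh$sheet, covariates = character(),
                                 dmcs = d, n_perm = 8, max_hits = 8,
                                 seed = 5)
  expect_equal(nrow(all_pass$dmcs), nrow(d))
  expect_error(permutation_filter(f, coh$sheet, dmcs = d, n_perm = 0),
               "n_perm")
})

test_that("a site driven by one extreme sample is removed by the filter", {
  # 6 vs 6 samples, one outlier case carries the whole signal: under
  # label permutation the outlier keeps generating hits
  set.seed(30)
  n <- 12
  n_sites <- 800
  total <- matrix(60L, n_sites, n)
  meth <- matrix(rbinom(n_sites * n, 60, 0.5), n_sites, n)
  # outlier sample 1: extreme methylation at site 1
  meth[1, ] <- rbinom(n, 60, 0.5)
  meth[1, 1] <- 60L
  meth[1, 2:6] <- rbinom(5, 60, 0.62)  # mild support from other cases
  m <- tiny_counts(total, meth)
  sheet <- two_group_sheet(6, 6)
  sheet$sample_id <- m$samples
  d <- call_dmcs(m, sheet, covariates = character(), diff_cutoff = 5)
  expect_true(1000L %in% d$pos)  # site 1 (pos 1000) is a candidate
  pf <- permutation_filter(m, sheet, covariates = character(), dmcs = d,
                           n_perm = 60, max_hits = 1, seed = 2,
                           diff_cutoff = 5)
  expect_gt(pf$ledger$hits[["chr1:1000"]], 1)
  expect_false(1000L %in% pf$dmcs$pos)
})
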