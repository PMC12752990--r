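# Shared fixtures and independent oracles for the test suite.
# Heavier simulated cohorts are built once per session and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (!exists(key, envir = .fixture_cache))
    assign(key, builder(), envir = .fixture_cache)
  get(key, envir = .fixture_cache)
}

# small cohort for fast unit tests
small_cohort <- function() {
  cached("small_cohort", function()
    simulate_cohort(sim_config(n_cases = 8, n_controls = 8,
                               n_cpgs = 1500, n_dmrs = 5,
                               n_steroid_dmrs = 2, delta_beta = 0.2,
                               chroms = c("chr1", "chr2", "chrX"),
                               seed = 42)))
}

# hand-built count matrix: explicit sites and counts
tiny_counts <- function(total_rows, meth_rows,
                        chrom = rep("chr1", nrow(total_rows)),
                        pos = seq_len(nrow(total_rows)) * 1000L,
                        samples = paste0("S", seq_len(ncol(total_rows)))) {
  meth_counts(data.frame(chrom = chrom, pos = pos, strand = "+"),
              meth_rows, total_rows, samples)
}

two_group_sheet <- function(n_case, n_control, ...) {
  extra <- list(...)
  d <- data.frame(
    sample_id = c(sprintf("C%02d", seq_len(n_case)),
                  sprintf("N%02d", seq_len(n_control))),
    group = c(rep("case", n_case), rep("control", n_control)),
    stringsAsFactors = FALSE)
  for (nm in names(extra)) d[[nm]] <- extra[[nm]]
  validate_sample_sheet(d)
}

# brute-force interval overlap oracle (1-based inclusive)
overlaps_1bp <- function(a_start, a_end, b_start, b_end) {
  a_start <= b_end && b_start <= a_end
}

any_overlap_oracle <- function(regions, exclusions) {
  vapply(seq_len(nrow(regions)), function(i) {
    any(vapply(seq_len(nrow(exclusions)), function(j) {
      regions$chrom[i] == exclusions$chrom[j] &&
        overlaps_1bp(regions$start[i], regions$end[i],
                     exclusions$start[j], exclusions$end[j])
    }, TRUE))
  }, TRUE)
}

# fraction of truth regions overlapped by at least one called region
recovery_fraction <- function(truth, called) {
  if (nrow(truth) == 0) return(NA_real_)
  if (nrow(called) == 0) return(0)
  mean(any_overlap_oracle(truth, called))
}

# all-pairs AU-ROC oracle: concordant pairs + half ties
auroc_oracle <- function(scores, labels) {
  pos <- scores[labels == 1]; neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (q in neg)
    total <- total + (p > q) + 0.5 * (p == q)
  total / (length(pos) * length(neg))
}

# average precision as the sum over positives of precision at that rank
# (valid for untied scores)
auprc_oracle <- function(scores, labels) {
  o <- order(scores, decreasing = TRUE)
  y <- labels[o]
  ranks <- which(y == 1)
  mean(vapply(ranks, function(r) sum(y[seq_len(r)]) / r, 0))
}

# exhaustive hypergeometric upper tail via the combinatorial sum
hyper_upper_oracle <- function(k_hit, K_ann, n_sel, N_bg) {
  ks <- k_hit:min(K_ann, n_sel)
  sum(choose(K_ann, ks) * choose(N_bg - K_ann, n_sel - ks)) /
    choose(N_bg, n_sel)
}

# ridge-logistic loss minimised by a generic optimiser (oracle for the
# L0L2 solver; independent of the package's IRLS/CD code path)
ridge_logistic_oracle <- function(X, y, support, gamma) {
  k <- length(support)
  obj <- function(theta) {
    f <- theta[1] + if (k > 0)
      drop(X[, support, drop = FALSE] %*% theta[-1]) else 0
    mean(log1p(exp(-ifelse(y == 1, 1, -1) * f))) +
      gamma * sum(theta[-1]^2)
  }
  fit <- optim(rep(0, k + 1), obj, method = "BFGS",
               control = list(maxit = 1000, reltol = 1e-14))
  fit$value
}

# exhaustive best-subset-with-ridge oracle over all supports
best_subset_oracle <- function(X, y, lambda, gamma) {
  p <- ncol(X)
  best <- Inf
  for (mask in 0:(2^p - 1)) {
    supp <- which(bitwAnd(mask, 2^(seq_len(p) - 1)) > 0)
    val <- ridge_logistic_oracle(X, y, supp, gamma) +
      lambda * length(supp)
    if (val < best) best <- val
  }
  best
}
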