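test_that("config validation rejects impossible settings", {
  expect_error(sim_config(delta_beta = 1.2), "delta_beta")
  expect_error(sim_config(hypo_fraction = -0.1), "hypo_fraction")
  expect_error(sim_config(n_cases = 0), "positive")
  expect_error(sim_config(dmr_spacing = 200), "dmr_spacing")
  # more planted regions than fit on the simulated chromosomes
  cfg <- sim_config(n_cpgs = 500, n_dmrs = 400, n_steroid_dmrs = 0,
                    chroms = c("chr1", "chrX"))
  expect_error(simulate_cohort(cfg), "cannot fit|planted")
})

test_that("simulation is a deterministic function of the config", {
  cfg <- sim_config(n_cases = 4, n_controls = 4, n_cpgs = 400,
                    n_dmrs = 3, n_steroid_dmrs = 1, seed = 7)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$counts$meth, b$counts$meth)
  expect_identical(a$counts$total, b$counts$total)
  expect_identical(a$sheet, b$sheet)
  expect_identical(a$truth$regions, b$truth$regions)
  # and does not disturb the caller's RNG stream
  set.seed(99); before <- runif(3)
  set.seed(99); invisible(simulate_cohort(cfg)); after <- runif(3)
  expect_identical(before, after)
})

test_that("null configuration plants nothing and matches the baseline mixture", {
  cfg <- sim_config(n_cases = 10, n_controls = 10, n_cpgs = 4000,
                    n_dmrs = 0, n_steroid_dmrs = 0, delta_beta = 0,
                    sex_effect = 0, age_effect = 0, breed_effect = 0,
                    seed = 3)
  coh <- simulate_cohort(cfg)
  expect_equal(nrow(coh$truth$regions), 0)
  expect_equal(nrow(coh$truth$steroid_regions), 0)
  b <- coh$counts$meth / pmax(coh$counts$total, 1)
  ok <- coh$counts$total > 0
  # grand mean within 3 Monte-Carlo SEs of the mixture mean
  mix <- cfg$baseline_mix
  mu <- sum(mix$weights * mix$shape1 / (mix$shape1 + mix$shape2))
  per_site_mean <- rowSums(b * ok) / rowSums(ok)
  se <- sd(per_site_mean) / sqrt(length(per_site_mean))
  expect_lt(abs(mean(per_site_mean) - mu), 3 * se)
  # case vs control differ only by noise: no site-level mean gap
  case <- coh$sheet$group == "case"
  gap <- rowMeans(b[, case]) - rowMeans(b[, !case])
  expect_lt(abs(mean(gap)), 0.005)
})

test_that("planted hypo regions shift cases down by about delta_beta", {
  cfg <- sim_config(n_cases = 12, n_controls = 12, n_cpgs = 3000,
                    n_dmrs = 12, n_steroid_dmrs = 0, delta_beta = 0.15,
                    hypo_fraction = 1, seed = 5)
  coh <- simulate_cohort(cfg)
  tr <- coh$truth$regions
  b <- coh$counts$meth / pmax(coh$counts$total, 1)
  case <- coh$sheet$group == "case"
  gaps <- vapply(seq_len(nrow(tr)), function(i) {
    rows <- coh$counts$sites$chrom == tr$chrom[i] &
      coh$counts$sites$pos >= tr$start[i] &
      coh$counts$sites$pos <= tr$end[i]
    mean(rowMeans(b[rows, !case, drop = FALSE]) -
           rowMeans(b[rows, case, drop = FALSE]))
  }, 0)
  expect_gt(mean(gaps), 0.15 - 0.03)
  expect_lt(mean(gaps), 0.15 + 0.03)
})

test_that("the sex effect is confined to chrX", {
  cfg <- sim_config(n_cases = 12, n_controls = 12, n_cpgs = 4000,
                    n_dmrs = 0, n_steroid_dmrs = 0, delta_beta = 0,
                    sex_effect = 0.2, age_effect = 0, breed_effect = 0,
                    seed = 11)
  coh <- simulate_cohort(cfg)
  fem <- coh$sheet$sex == "F"
  expect_gte(sum(fem), 3); expect_gte(sum(!fem), 3)
  b <- coh$counts$meth / pmax(coh$counts$total, 1)
  on_x <- coh$counts$sites$chrom == "chrX"
  gap_x <- mean(rowMeans(b[on_x, fem, drop = FALSE]) -
                  rowMeans(b[on_x, !fem, drop = FALSE]))
  gap_auto <- mean(rowMeans(b[!on_x, fem, drop = FALSE]) -
                     rowMeans(b[!on_x, !fem, drop = FALSE]))
  expect_gt(gap_x, 0.1)
  expect_lt(abs(gap_auto), 0.02)
})

test_that("truth regions contain at least dmr_cpg_count CpGs and never overlap", {
  coh <- small_cohort()
  tr <- rbind(as.data.frame(coh$truth$regions)[, 1:3],
              as.data.frame(coh$truth$steroid_regions)[, 1:3])
  cfg_k <- 6
  for (i in seq_len(nrow(tr))) {
    n_in <- sum(coh$counts$sites$chrom == tr$chrom[i] &
                  coh$counts$sites$pos >= tr$start[i] &
                  coh$counts$sites$pos <= tr$end[i])
    expect_gte(n_in, cfg_k)
  }
  if (nrow(tr) > 1) {
    for (i in seq_len(nrow(tr) - 1)) for (j in (i + 1):nrow(tr)) {
      same <- tr$chrom[i] == tr$chrom[j] &&
        overlaps_1bp(tr$start[i], tr$end[i], tr$start[j], tr$end[j])
      expect_false(same)
    }
  }
})

test_that("fixtures round-trip through disk with BED coordinate conversion", {
  coh <- simulate_cohort(sim_config(n_cases = 3, n_controls = 3,
                                    n_cpgs = 300, n_dmrs = 2,
                                    n_steroid_dmrs = 0, seed = 8))
  dir <- withr::local_tempdir()
  man <- write_fixture(coh, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_meth_calls(file.path(dir, man$files$calls),
                          coh$counts$samples)
  expect_identical(back$meth, coh$counts$meth)
  expect_identical(back$total, coh$counts$total)
  sheet <- read_sample_sheet(file.path(dir, "sample_sheet.tsv"))
  expect_identical(sheet$sample_id, coh$sheet$sample_id)
  expect_identical(sheet$group, coh$sheet$group)
  # truth BED is 0-based half-open on disk
  raw <- read.delim(file.path(dir, "truth_regions.bed"), header = FALSE)
  expect_identical(as.integer(raw[[2]]), coh$truth$regions$start - 1L)
  expect_identical(as.integer(raw[[3]]), coh$truth$regions$end)
})

test_that("an empty truth set writes a zero-length BED and a valid manifest", {
  coh <- simulate_cohort(sim_config(n_cases = 3, n_controls = 3,
                                    n_cpgs = 200, n_dmrs = 0,
                                    n_steroid_dmrs = 0, seed = 9))
  dir <- withr::local_tempdir()
  man <- write_fixture(coh, dir)
  bed <- file.path(dir, "truth_regions.bed")
  expect_true(file.exists(bed))
  expect_equal(file.size(bed), 0)
  expect_equal(man$n_samples, 6)
})
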