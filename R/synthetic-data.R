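# Synthetic WGBS cohort with planted differentially methylated regions.
#
# Emulates the statistical structure of a blood case/control bisulfite
# cohort: negative-binomial per-site coverage around a target depth,
# bimodal per-CpG baseline methylation, beta-binomial methylated counts,
# region-level planted case effects (hypo-dominant), steroid-responsive
# regions, a sex effect confined to chrX, and small age/breed covariate
# effects. Every planted region is returned as ground truth.

#' Configuration for the synthetic cohort generator
#'
#' Defaults describe the study conditions the pipeline is designed for:
#' 20 cases vs 19 controls, ~70x target coverage, planted effects of
#' about 10 percentage points with hypomethylation dominating (80%).
#'
#' @param n_cases,n_controls sample counts per group.
#' @param n_cpgs total simulated CpG count (background + planted).
#' @param chroms chromosome names; `"chrX"` (if present) receives the sex
#'   effect and is excluded from planting of disease/steroid regions so
#'   that planted truth survives X-censoring downstream.
#' @param mean_coverage target read depth per CpG (negative-binomial mean).
#' @param coverage_dispersion negative-binomial shape (`size`); smaller is
#'   longer-tailed.
#' @param baseline_mix two-component Beta mixture for per-CpG baseline
#'   methylation: list with `weights`, `shape1`, `shape2` (component 1 =
#'   the methylated mode, component 2 = the unmethylated mode).
#' @param n_dmrs number of planted disease regions.
#' @param dmr_cpg_count CpGs per planted region.
#' @param dmr_spacing bp between consecutive CpGs inside a planted region
#'   (must be <= 100 so members chain at the default merge gap).
#' @param delta_beta planted case-vs-control effect, proportion units.
#' @param hypo_fraction fraction of planted disease regions hypomethylated
#'   in cases.
#' @param n_steroid_dmrs number of planted steroid-responsive regions.
#' @param steroid_effect planted effect tied to the steroid flag,
#'   proportion units.
#' @param sex_effect female-minus-male methylation shift on chrX CpGs,
#'   proportion units.
#' @param age_effect logit-scale slope per year of age applied to a
#'   random 10% of CpGs.
#' @param breed_effect sd of a per-breed logit-scale random shift applied
#'   to a random 5% of CpGs.
#' @param setting_effect logit-scale shift between collection settings
#'   applied to a random 10% of CpGs (0 = no batch effect).
#' @param overdispersion beta-binomial concentration; larger = closer to
#'   binomial. The default 150 corresponds to a between-individual beta
#'   standard deviation of about 0.03 at intermediate methylation,
#'   matching the stability of most CpGs in whole blood of healthy
#'   individuals.
#' @param steroid_prob probability of steroid treatment, named for case
#'   and control.
#' @param seed integer seed; the whole cohort is a deterministic function
#'   of the config.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_cases = 20, n_controls = 19, n_cpgs = 20000,
                       chroms = c("chr1", "chr2", "chr3", "chr4", "chr5",
                                  "chrX"),
                       mean_coverage = 70, coverage_dispersion = 8,
                       baseline_mix = list(weights = c(0.7, 0.3),
                                           shape1 = c(8, 1.5),
                                           shape2 = c(1.5, 8)),
                       n_dmrs = 50, dmr_cpg_count = 6, dmr_spacing = 50,
                       delta_beta = 0.10, hypo_fraction = 0.8,
                       n_steroid_dmrs = 10, steroid_effect = 0.15,
                       sex_effect = 0.15, age_effect = 0.02,
                       breed_effect = 0.3, setting_effect = 0,
                       overdispersion = 150,
                       steroid_prob = c(case = 0.4, control = 0.1),
                       seed = 1) {
  cfg <- list(n_cases = as.integer(n_cases),
              n_controls = as.integer(n_controls),
              n_cpgs = as.integer(n_cpgs), chroms = as.character(chroms),
              mean_coverage = mean_coverage,
              coverage_dispersion = coverage_dispersion,
              baseline_mix = baseline_mix,
              n_dmrs = as.integer(n_dmrs),
              dmr_cpg_count = as.integer(dmr_cpg_count),
              dmr_spacing = as.integer(dmr_spacing),
              delta_beta = delta_beta, hypo_fraction = hypo_fraction,
              n_steroid_dmrs = as.integer(n_steroid_dmrs),
              steroid_effect = steroid_effect, sex_effect = sex_effect,
              age_effect = age_effect, breed_effect = breed_effect,
              setting_effect = setting_effect,
              overdispersion = overdispersion,
              steroid_prob = steroid_prob, seed = as.integer(seed))
  assert_that(cfg$n_cases >= 1 && cfg$n_controls >= 1 && cfg$n_cpgs >= 1,
              "sample and CpG counts must be positive")
  assert_that(cfg$delta_beta >= 0 && cfg$delta_beta < 1,
              "delta_beta must be in [0, 1)")
  assert_that(cfg$hypo_fraction >= 0 && cfg$hypo_fraction <= 1,
              "hypo_fraction must be in [0, 1]")
  assert_that(cfg$dmr_spacing >= 1 && cfg$dmr_spacing <= 100,
              "dmr_spacing must be in [1, 100] bp")
  assert_that(cfg$n_dmrs >= 0 && cfg$n_steroid_dmrs >= 0,
              "region counts must be non-negative")
  assert_that(cfg$mean_coverage > 0 && cfg$coverage_dispersion > 0 &&
                cfg$overdispersion > 0,
              "coverage and dispersion parameters must be positive")
  assert_that(length(cfg$chroms) >= 1, "need at least one chromosome")
  class(cfg) <- "sim_config"
  cfg
}

# breed frequency tables for the two groups (cohort-style demographics:
# controls dominated by a few breeds, cases spread over many)
.breed_tables <- list(
  control = c(toy_poodle = 13, shiba = 3, miniature_dachshund = 3),
  case = c(shiba = 4, pug = 2, toy_poodle = 2, bichon_frise = 1,
           boston_terrier = 1, cavalier = 1, chihuahua = 1,
           miniature_dachshund = 1, french_bulldog = 1,
           golden_retriever = 1, norfolk_terrier = 1, papillon = 1,
           shetland_sheepdog = 1, standard_poodle = 1,
           yorkshire_terrier = 1))

simulate_sheet <- function(cfg) {
  n <- cfg$n_cases + cfg$n_controls
  group <- c(rep("case", cfg$n_cases), rep("control", cfg$n_controls))
  id <- sprintf("%s%02d", ifelse(group == "case", "C", "N"),
                c(seq_len(cfg$n_cases), seq_len(cfg$n_controls)))
  # ages: cases older on average, truncated at 1 year
  age <- ifelse(group == "case",
                rnorm(n, 10.2, 2.02), rnorm(n, 7.79, 3.66))
  age <- round(pmax(age, 1), 1)
  sexp <- ifelse(group == "case", 0.5, 13 / 19)
  sex <- ifelse(runif(n) < sexp, "F", "M")
  neutered <- as.integer(runif(n) < 0.6)
  # breeds: emulate the reference demographics as a multiset — the
  # group's breed composition is scaled to the requested n and sampled
  # without replacement, so rare breeds stay rare instead of clumping
  breed <- character(n)
  for (g in c("case", "control")) {
    tab <- .breed_tables[[g]]
    k <- sum(group == g)
    pool <- rep(names(tab), times = ceiling(tab * k / sum(tab)))
    breed[group == g] <- sample(pool, k, replace = k > length(pool))
  }
  steroid <- as.integer(runif(n) <
                          cfg$steroid_prob[ifelse(group == "case",
                                                  "case", "control")])
  setting <- sample(c("site_A", "site_B"), n, replace = TRUE,
                    prob = c(0.7, 0.3))
  validate_sample_sheet(
    data.frame(sample_id = id, group = group, age_years = age, sex = sex,
               neutered = neutered, breed = breed, steroid = steroid,
               setting = setting, split = "unassigned",
               stringsAsFactors = FALSE),
    where = "simulated sheet")
}

# lay out CpG positions: planted regions first (tight runs of
# dmr_cpg_count CpGs), then background CpGs at random positions kept
# clear of planted spans.
layout_sites <- function(cfg) {
  autosomes <- setdiff(cfg$chroms, "chrX")
  assert_that(length(autosomes) >= 1 || (cfg$n_dmrs + cfg$n_steroid_dmrs) == 0,
              "planted regions need at least one autosome")
  n_regions <- cfg$n_dmrs + cfg$n_steroid_dmrs
  n_planted <- n_regions * cfg$dmr_cpg_count
  assert_that(n_planted <= cfg$n_cpgs,
              sprintf("config asks for %d planted CpGs but only %d CpGs total",
                      n_planted, cfg$n_cpgs))
  # genome span per chromosome sized for ~1 CpG / 150 bp
  per_chrom <- table(factor(
    sample(cfg$chroms, cfg$n_cpgs, replace = TRUE,
           prob = ifelse(cfg$chroms == "chrX", 0.05,
                         0.95 / max(1, length(autosomes)))),
    levels = cfg$chroms))
  chrom_len <- pmax(as.integer(per_chrom) * 150L, 10000L)
  names(chrom_len) <- cfg$chroms
  region_span <- (cfg$dmr_cpg_count - 1L) * cfg$dmr_spacing
  margin <- 300L  # keep background CpGs out of chaining range of planted runs
  regions <- NULL
  if (n_regions > 0) {
    capacity <- sum(pmax(0, floor((chrom_len[autosomes] - 2 * margin) /
                                    (region_span + 2 * margin))))
    assert_that(n_regions <= capacity,
                sprintf("cannot fit %d planted regions on the simulated autosomes (capacity %d); increase n_cpgs or chromosomes",
                        n_regions, as.integer(capacity)))
    # place regions on a jittered grid per chromosome so they never overlap
    slots <- do.call(rbind, lapply(autosomes, function(ch) {
      n_slot <- floor((chrom_len[ch] - 2 * margin) /
                        (region_span + 2 * margin))
      if (n_slot < 1) return(NULL)
      start0 <- margin + (seq_len(n_slot) - 1L) * (region_span + 2L * margin)
      data.frame(chrom = ch, start = as.integer(start0 + margin),
                 stringsAsFactors = FALSE)
    }))
    pick <- slots[sample.int(nrow(slots), n_regions), , drop = FALSE]
    regions <- data.frame(chrom = pick$chrom,
                          start = pick$start,
                          end = pick$start + region_span,
                          stringsAsFactors = FALSE)
  }
  # background positions
  n_bg <- cfg$n_cpgs - n_planted
  bg_per_chrom <- pmax(as.integer(per_chrom) -
                         if (is.null(regions)) 0L else
                           as.integer(table(factor(regions$chrom,
                                                   levels = cfg$chroms))) *
                         cfg$dmr_cpg_count, 0L)
  # renormalise so background total matches exactly
  if (sum(bg_per_chrom) != n_bg && sum(bg_per_chrom) > 0) {
    bg_per_chrom <- as.integer(round(bg_per_chrom * n_bg /
                                       sum(bg_per_chrom)))
    while (sum(bg_per_chrom) != n_bg) {
      i <- which.max(bg_per_chrom)
      bg_per_chrom[i] <- bg_per_chrom[i] + sign(n_bg - sum(bg_per_chrom))
    }
  }
  sites <- vector("list", length(cfg$chroms) + 1L)
  for (ci in seq_along(cfg$chroms)) {
    ch <- cfg$chroms[ci]
    k <- bg_per_chrom[ci]
    if (k <= 0) next
    pos <- sort(sample.int(chrom_len[ch], min(k, chrom_len[ch])))
    if (!is.null(regions)) {
      # background CpGs may fall inside planted spans (they will carry
      # the region effect); just avoid colliding with planted positions
      r <- regions[regions$chrom == ch, , drop = FALSE]
      if (nrow(r) > 0) {
        planted_pos <- unlist(lapply(seq_len(nrow(r)), function(j)
          r$start[j] + (seq_len(cfg$dmr_cpg_count) - 1L) *
            cfg$dmr_spacing))
        pos <- setdiff(pos, planted_pos)
      }
    }
    sites[[ci]] <- data.frame(chrom = ch, pos = pos, planted = NA_integer_,
                              stringsAsFactors = FALSE)
  }
  if (!is.null(regions)) {
    pl <- do.call(rbind, lapply(seq_len(nrow(regions)), function(j)
      data.frame(chrom = regions$chrom[j],
                 pos = regions$start[j] +
                   (seq_len(cfg$dmr_cpg_count) - 1L) * cfg$dmr_spacing,
                 planted = j, stringsAsFactors = FALSE)))
    sites[[length(sites)]] <- pl
  }
  sites <- do.call(rbind, sites)
  sites <- sites[order(sites$chrom, sites$pos), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, regions = regions)
}

#' Simulate a methylation cohort with known truth
#'
#' Draws per-site coverage (negative binomial), per-CpG baseline
#' methylation (bimodal Beta mixture), then beta-binomial methylated
#' counts, shifting the affected group's methylation inside planted
#' regions by `delta_beta` on the logit scale (clipped to `[0.01, 0.99]`).
#' Disease regions share one baseline per region drawn from the mixture
#' component opposite to the planted direction (hypomethylation starts
#' methylated and vice versa), matching the local correlation of real
#' methylomes. The first `n_dmrs` planted runs are disease regions; the
#' next `n_steroid_dmrs` respond to the steroid flag instead.
#'
#' @param config a [sim_config].
#' @return list with elements `counts` (a [meth_counts]), `sheet` (a
#'   `sample_sheet`) and `truth` (list of `regions`, `steroid_regions`
#'   as [region_set]s carrying `delta_beta`, plus the covariate sheet).
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  with_seed(cfg$seed, {
    sheet <- simulate_sheet(cfg)
    lay <- layout_sites(cfg)
    sites <- lay$sites
    n_sites <- nrow(sites)
    n <- nrow(sheet)
    # baseline methylation: mixture draw per background CpG; one draw per
    # planted region, from the component opposite its direction
    comp <- 1L + (runif(n_sites) > cfg$baseline_mix$weights[1])
    p0 <- rbeta(n_sites, cfg$baseline_mix$shape1[comp],
                cfg$baseline_mix$shape2[comp])
    dir_lab <- NULL; ster_dir <- NULL
    if (!is.null(lay$regions)) {
      n_reg <- nrow(lay$regions)
      is_disease <- seq_len(n_reg) <= cfg$n_dmrs
      dirs <- character(n_reg)
      n_dis <- sum(is_disease)
      if (n_dis > 0) {
        n_hypo <- round(cfg$hypo_fraction * n_dis)
        dirs[is_disease] <- sample(c(rep("hypo", n_hypo),
                                     rep("hyper", n_dis - n_hypo)))
      }
      n_st <- n_reg - n_dis
      if (n_st > 0)
        dirs[!is_disease] <- sample(c("hypo", "hyper"), n_st,
                                    replace = TRUE)
      # region baseline: hypo regions start methylated, hyper start low
      reg_base <- ifelse(dirs == "hypo",
                         rbeta(n_reg, cfg$baseline_mix$shape1[1],
                               cfg$baseline_mix$shape2[1]),
                         rbeta(n_reg, cfg$baseline_mix$shape1[2],
                               cfg$baseline_mix$shape2[2]))
      idx <- !is.na(sites$planted)
      jit <- rnorm(sum(idx), 0, 0.1)
      p0[idx] <- plogis(qlogis(clip01(reg_base[sites$planted[idx]])) + jit)
      dir_lab <- dirs
      ster_dir <- dirs[!is_disease]
    }
    p0 <- clip01(p0)
    # per-sample success probabilities on the logit scale
    eta <- matrix(qlogis(p0), n_sites, n, dimnames = list(NULL,
                                                          sheet$sample_id))
    is_case <- sheet$group == "case"
    if (!is.null(lay$regions)) {
      for (j in seq_len(nrow(lay$regions))) {
        # every CpG inside the planted span shifts: the whole domain is
        # differentially methylated, not just the guaranteed members
        rows <- which(sites$chrom == lay$regions$chrom[j] &
                        sites$pos >= lay$regions$start[j] &
                        sites$pos <= lay$regions$end[j])
        sgn <- if (dir_lab[j] == "hyper") 1 else -1
        disease <- j <= cfg$n_dmrs
        affected <- if (disease) is_case else sheet$steroid == 1L
        eff <- if (disease) cfg$delta_beta else cfg$steroid_effect
        if (!any(affected) || eff == 0) next
        p_base <- plogis(eta[rows, affected, drop = FALSE])
        p_new <- clip01(p_base + sgn * eff)
        eta[rows, affected] <- qlogis(p_new)
      }
    }
    # sex effect on chrX: females shifted by sex_effect (proportion units)
    if (cfg$sex_effect != 0 && "chrX" %in% sites$chrom) {
      xr <- which(sites$chrom == "chrX")
      fem <- sheet$sex == "F"
      if (length(xr) > 0 && any(fem)) {
        p_base <- plogis(eta[xr, fem, drop = FALSE])
        eta[xr, fem] <- qlogis(clip01(p_base + cfg$sex_effect))
      }
    }
    # age effect: logit slope on a random 10% of CpGs
    if (cfg$age_effect != 0 && "age_years" %in% names(sheet)) {
      rows <- which(runif(n_sites) < 0.10)
      if (length(rows) > 0) {
        centred <- sheet$age_years - mean(sheet$age_years)
        eta[rows, ] <- eta[rows, ] +
          outer(rep(cfg$age_effect, length(rows)), centred)
      }
    }
    # breed effect: random per-breed shift on a random 5% of CpGs
    if (cfg$breed_effect != 0 && "breed" %in% names(sheet)) {
      rows <- which(runif(n_sites) < 0.05)
      if (length(rows) > 0) {
        breeds <- unique(sheet$breed)
        shift <- setNames(rnorm(length(breeds), 0, cfg$breed_effect),
                          breeds)
        eta[rows, ] <- eta[rows, ] +
          matrix(shift[sheet$breed], length(rows), n, byrow = TRUE)
      }
    }
    # collection-setting batch effect (off by default)
    if (cfg$setting_effect != 0 && "setting" %in% names(sheet)) {
      rows <- which(runif(n_sites) < 0.10)
      if (length(rows) > 0) {
        b <- ifelse(sheet$setting == "site_B", cfg$setting_effect, 0)
        eta[rows, ] <- eta[rows, ] + matrix(b, length(rows), n,
                                            byrow = TRUE)
      }
    }
    p <- clip01(plogis(eta), 0.001, 0.999)
    # counts: NB coverage, beta-binomial methylated reads
    total <- matrix(rnbinom(n_sites * n, mu = cfg$mean_coverage,
                            size = cfg$coverage_dispersion),
                    n_sites, n)
    conc <- cfg$overdispersion
    q <- matrix(rbeta(n_sites * n, p * conc, (1 - p) * conc), n_sites, n)
    meth <- matrix(rbinom(n_sites * n, as.vector(total), as.vector(q)),
                   n_sites, n)
    counts <- meth_counts(
      data.frame(chrom = sites$chrom, pos = sites$pos, strand = "+",
                 stringsAsFactors = FALSE),
      meth, total, sheet$sample_id)
    truth_regions <- region_set()
    steroid_regions <- region_set()
    if (!is.null(lay$regions)) {
      r <- lay$regions
      is_disease <- seq_len(nrow(r)) <= cfg$n_dmrs
      mk <- function(keep, eff) {
        if (!any(keep)) return(region_set())
        rs <- region_set(r$chrom[keep], r$start[keep], r$end[keep],
                         n_dmcs = cfg$dmr_cpg_count,
                         direction = dir_lab[keep], label = "truth")
        rs$delta_beta <- eff
        rs
      }
      truth_regions <- mk(is_disease, cfg$delta_beta)
      steroid_regions <- mk(!is_disease, cfg$steroid_effect)
    }
    structure(list(counts = counts, sheet = sheet,
                   truth = list(regions = truth_regions,
                                steroid_regions = steroid_regions,
                                covariates = sheet)),
              seed = cfg$seed, class = "sim_cohort")
  })
}

#' Write a simulated cohort to disk as plain-text fixtures
#'
#' One methylation-call TSV per sample, a sample-sheet TSV, truth regions
#' as BED (0-based half-open, name = direction, score = delta_beta x
#' 1000) and a JSON manifest listing the files and the seed.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if needed).
#' @return manifest list, invisibly written to `manifest.json`.
#' @export
write_fixture <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  assert_that(dir.exists(dir), paste0("cannot create directory ", dir))
  call_paths <- write_meth_calls(cohort$counts, dir)
  sheet_path <- file.path(dir, "sample_sheet.tsv")
  write_sample_sheet(cohort$sheet, sheet_path)
  write_truth_bed <- function(rs, path) {
    if (nrow(rs) == 0) {
      con <- file(path, "w"); close(con)
      return(path)
    }
    d <- data.frame(chrom = rs$chrom, start = rs$start - 1L, end = rs$end,
                    name = rs$direction,
                    score = as.integer(round((rs$delta_beta %||% 0) * 1000)),
                    strand = ".")
    con <- file(path, "w"); on.exit(close(con))
    if (nrow(d) > 0)
      write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    path
  }
  truth_path <- write_truth_bed(cohort$truth$regions,
                                file.path(dir, "truth_regions.bed"))
  steroid_path <- write_truth_bed(cohort$truth$steroid_regions,
                                  file.path(dir, "truth_steroid.bed"))
  manifest <- list(files = list(calls = basename(call_paths),
                                sample_sheet = basename(sheet_path),
                                truth_regions = basename(truth_path),
                                truth_steroid = basename(steroid_path)),
                   n_samples = length(cohort$counts$samples),
                   n_cpgs = nrow(cohort$counts$sites),
                   seed = attr(cohort, "seed", exact = TRUE))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
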