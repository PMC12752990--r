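# Hold-out splitting and end-to-end orchestration.

#' Pipeline configuration
#'
#' Collects every stage parameter with its standard default: coverage
#' 10-500x, effect cutoff 10 percentage points at q < 0.05, 100 label
#' permutations, 100 bp DMC merge distance with at least 6 members
#' (4 for the looser steroid scan), 4 methylation clusters, 1,000
#' bootstrap resamples, L2 weight 0.001 with 4-fold cross-validation.
#'
#' @param min_cov,max_cov coverage filter bounds.
#' @param diff_cutoff,q_cutoff DMC thresholds.
#' @param covariates DMC adjustment columns.
#' @param n_perm,max_hits permutation filter settings.
#' @param gap,min_dmcs DMC merge distance (bp) and member rule.
#' @param steroid_min_dmcs looser member rule for the confounder scan.
#' @param drop_chroms chromosomes censored from final regions.
#' @param k number of methylation clusters.
#' @param n_boot bootstrap resamples for single-region screening.
#' @param top_n size of the reported single-region table.
#' @param gamma,cv_folds L0L2 settings.
#' @param n_trees forest size.
#' @param tree_depth per-cluster decision-tree depth bound.
#' @param train_counts named per-group training counts
#'   (`c(case =, control =)`) or `NULL` to use `train_fraction`.
#' @param train_fraction training fraction when counts are not given.
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(min_cov = 10, max_cov = 500, diff_cutoff = 10,
                       q_cutoff = 0.05,
                       covariates = c("breed", "age_years"),
                       n_perm = 100, max_hits = 1, gap = 100,
                       min_dmcs = 6, steroid_min_dmcs = 4,
                       drop_chroms = "chrX", k = 4, n_boot = 1000,
                       top_n = 20, gamma = 0.001, cv_folds = 4,
                       n_trees = 500, tree_depth = 2,
                       train_counts = c(case = 16, control = 12),
                       train_fraction = 0.72, seed = 1) {
  cfg <- as.list(environment())
  assert_that(cfg$min_cov <= cfg$max_cov, "min_cov > max_cov")
  assert_that(cfg$q_cutoff > 0 && cfg$q_cutoff <= 1, "bad q_cutoff")
  assert_that(cfg$n_perm >= 1 && cfg$max_hits >= 0, "bad permutation config")
  assert_that(cfg$gap >= 0 && cfg$min_dmcs >= 1, "bad merge config")
  assert_that(cfg$k >= 2, "k must be >= 2")
  assert_that(is.null(cfg$train_counts) ||
                all(c("case", "control") %in% names(cfg$train_counts)),
              "train_counts needs named case and control entries")
  assert_that(cfg$train_fraction > 0 && cfg$train_fraction < 1,
              "train_fraction must be in (0, 1)")
  class(cfg) <- "run_config"
  cfg
}

#' Assign a stratified hold-out split
#'
#' Random assignment stratified by group. Explicit per-group training
#' counts take precedence over the fraction; samples whose `split` is
#' already `train`/`test` are respected and only the `unassigned` rest
#' is allocated. Both classes must end up in both splits.
#'
#' @param sheet a `sample_sheet`.
#' @param train_fraction training fraction (used when `train_counts` is
#'   NULL).
#' @param seed integer seed.
#' @param train_counts named vector `c(case =, control =)` of training
#'   sample counts, or NULL.
#' @return the sheet with `split` filled in.
#' @export
holdout_split <- function(sheet, train_fraction = 0.72, seed = 1,
                          train_counts = NULL) {
  sheet <- validate_sample_sheet(sheet)
  assert_that(is.null(train_counts) ||
                all(c("case", "control") %in% names(train_counts)),
              "train_counts needs named case and control entries")
  assert_that(train_fraction < 1 || !is.null(train_counts),
              "train_fraction = 1 leaves no test set")
  with_seed(seed, {
    for (g in c("case", "control")) {
      rows <- which(sheet$group == g & sheet$split == "unassigned")
      pre_train <- sum(sheet$group == g & sheet$split == "train")
      want <- if (!is.null(train_counts)) train_counts[[g]] - pre_train
              else round(train_fraction * (length(rows) + pre_train +
                           sum(sheet$group == g &
                                 sheet$split == "test"))) - pre_train
      want <- max(0, min(want, length(rows)))
      tr <- if (length(rows) > 0) sample(rows, want) else integer()
      sheet$split[tr] <- "train"
      sheet$split[setdiff(rows, tr)] <- "test"
    }
  })
  tab <- table(sheet$group, sheet$split)
  for (s in c("train", "test"))
    assert_that(s %in% colnames(tab) && all(tab[, s] > 0),
                paste0("a class is absent from the ", s, " split"))
  sheet
}

write_tsv <- function(d, path) {
  write.table(d, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline on a cohort
#'
#' Executes: hold-out split, coverage filter, covariate-adjusted DMC
#' call on the training split, permutation-null filter, DMC merging,
#' confounder-region subtraction and X-censoring, region methylation,
#' k-means clustering, optional term enrichment, single-region models
#' with bootstrap screening, L0L2 and tree+forest multi-probe models,
#' and held-out evaluation. Feature selection and model fitting see
#' training samples only; test methylation is touched only at
#' evaluation. All outputs are written under `out_dir` and checksummed
#' into a manifest; re-running with the same config and seed reproduces
#' identical checksums.
#'
#' @param counts a [meth_counts] for the whole cohort.
#' @param sheet matching `sample_sheet` (pre-assigned splits respected).
#' @param config a [run_config()].
#' @param out_dir output directory.
#' @param genes,term_map optional gene annotation and term map; when
#'   both are given, enrichment runs on the three gene classes.
#' @param do_single,do_multi toggle the model tracks.
#' @return list of class `run_result` with all stage outputs and
#'   `manifest` (config hash, file checksums, seeds, timings, counts).
#' @export
run_pipeline <- function(counts, sheet, config = run_config(),
                         out_dir = tempfile("dmrrun"), genes = NULL,
                         term_map = NULL, do_single = TRUE,
                         do_multi = TRUE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(config$seed, 8)
  timings <- c()
  res <- list(config = config)
  stage <- function(name, expr) {
    t0 <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e)
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE))
    timings[[name]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    out
  }

  sheet <- stage("split", {
    s <- validate_sample_sheet(sheet)
    if (any(s$split == "unassigned"))
      s <- holdout_split(s, train_fraction = config$train_fraction,
                         seed = seeds[1],
                         train_counts = config$train_counts)
    s
  })
  train_ids <- sheet$sample_id[sheet$split == "train"]
  test_ids <- sheet$sample_id[sheet$split == "test"]
  assert_that(length(intersect(train_ids, test_ids)) == 0,
              "train/test overlap")
  for (s in c("train", "test"))
    assert_that(
      all(c("case", "control") %in%
            sheet$group[sheet$split == s]),
      paste0("a class is absent from the ", s, " split"))
  res$sheet <- sheet

  filtered <- stage("filter",
                    filter_cpgs(counts, config$min_cov, config$max_cov))
  res$filter_stats <- attr(filtered, "filter_stats")

  # selection stages consume training samples only
  train_counts_m <- subset_samples(filtered, train_ids)
  train_sheet <- sheet[match(train_ids, sheet$sample_id), , drop = FALSE]

  dmcs <- stage("dmc", call_dmcs(train_counts_m, train_sheet,
                                 covariates = config$covariates,
                                 diff_cutoff = config$diff_cutoff,
                                 q_cutoff = config$q_cutoff))
  res$n_dmc_candidates <- nrow(dmcs)

  pf <- stage("perm_filter",
              permutation_filter(train_counts_m, train_sheet,
                                 covariates = config$covariates,
                                 dmcs = dmcs, n_perm = config$n_perm,
                                 max_hits = config$max_hits,
                                 seed = seeds[2],
                                 diff_cutoff = config$diff_cutoff,
                                 q_cutoff = config$q_cutoff))
  res$dmcs <- pf$dmcs
  res$perm_ledger <- pf$ledger

  candidates <- stage("merge", merge_dmcs(pf$dmcs, gap = config$gap,
                                          min_dmcs = config$min_dmcs,
                                          label = "lymphoma"))
  res$candidate_regions <- candidates

  steroid <- stage("confounder", {
    if ("steroid" %in% names(train_sheet))
      call_confounder_regions(train_counts_m, train_sheet,
                              contrast_flag = "steroid",
                              gap = config$gap,
                              min_dmcs = config$steroid_min_dmcs,
                              diff_cutoff = config$diff_cutoff,
                              q_cutoff = config$q_cutoff)
    else region_set()
  })
  res$steroid_regions <- steroid

  final <- stage("censor", subtract_and_censor(candidates, steroid,
                                               config$drop_chroms))
  res$regions <- final

  beta_all <- stage("beta", compute_beta(filtered))
  region_b <- stage("region_beta", region_beta(beta_all, final))
  res$region_beta <- region_b
  x_train <- region_b[, train_ids, drop = FALSE]
  x_test <- region_b[, test_ids, drop = FALSE]
  y_train <- as.integer(train_sheet$group == "case")
  y_test <- as.integer(sheet$group[match(test_ids,
                                         sheet$sample_id)] == "case")

  if (nrow(final) >= config$k) {
    res$clusters <- stage("cluster",
                          kmeans_cluster(x_train, k = config$k,
                                         seed = seeds[3]))
  }

  if (!is.null(genes) && !is.null(term_map) && nrow(final) > 0) {
    res$gene_links <- stage("gene_map",
                            map_regions_to_genes(final, genes))
    res$enrichment <- stage("enrich", {
      bg <- unique(term_map$gene_id)
      lapply(split(res$gene_links$gene_id, res$gene_links$class),
             function(sel)
               hypergeom_enrich(intersect(unique(sel), bg), bg, term_map))
    })
  }

  if (do_single && nrow(final) > 0) {
    res$single_screen <- stage("single_models",
                               bootstrap_screen(x_train, y_train,
                                                n_boot = config$n_boot,
                                                seed = seeds[4],
                                                top_n = config$top_n))
    res$single_eval <- stage("single_eval",
                             evaluate_on_test(res$single_screen, x_test,
                                              y_test, train_ids,
                                              test_ids))
  }

  if (do_multi && nrow(final) > 0) {
    res$sparse_model <- stage("sparse_model",
                              fit_l0l2_logistic(x_train, y_train,
                                                gamma = config$gamma,
                                                cv_folds = config$cv_folds,
                                                seed = seeds[5]))
    res$sparse_eval <- stage("sparse_eval",
                             evaluate_multi(res$sparse_model, x_test,
                                            y_test, train_ids, test_ids))
    if (!is.null(res$clusters)) {
      sel <- stage("tree_select",
                   select_by_tree_per_cluster(x_train, y_train,
                                              res$clusters,
                                              max_depth = config$tree_depth,
                                              seed = seeds[6]))
      res$tree_selected <- sel
      if (length(sel) > 0) {
        res$forest_model <- stage("forest",
                                  fit_forest(x_train, y_train,
                                             selected = sel,
                                             n_trees = config$n_trees,
                                             seed = seeds[7]))
        res$forest_eval <- stage("forest_eval",
                                 evaluate_multi(res$forest_model, x_test,
                                                y_test, train_ids,
                                                test_ids))
      }
    }
  }

  # persist outputs and checksum them
  files <- character()
  files["sheet"] <- write_tsv(as.data.frame(sheet),
                              file.path(out_dir, "sample_sheet.tsv"))
  files["dmcs"] <- write_tsv(res$dmcs, file.path(out_dir, "dmcs.tsv"))
  files["regions"] <- write_regions_bed(final,
                                        file.path(out_dir, "regions.bed"))
  files["steroid"] <- write_regions_bed(steroid,
                                        file.path(out_dir,
                                                  "steroid_regions.bed"))
  rb <- data.frame(region = rownames(region_b), region_b,
                   check.names = FALSE)
  files["region_beta"] <- write_tsv(rb,
                                    file.path(out_dir, "region_beta.tsv"))
  if (!is.null(res$clusters))
    files["clusters"] <- write_tsv(
      data.frame(region = names(res$clusters$assignments),
                 cluster = res$clusters$assignments),
      file.path(out_dir, "clusters.tsv"))
  if (!is.null(res$single_eval)) {
    tab <- res$single_eval
    tab$boot_ci <- format_ci(tab$boot_ci_lo, tab$boot_ci_hi,
                             tab$degenerate_ci)
    files["single_models"] <- write_tsv(
      tab[, c("region", "train_auroc", "train_auprc", "boot_ci",
              "boot_mean_auroc", "test_auroc", "test_auprc")],
      file.path(out_dir, "single_models.tsv"))
  }
  if (!is.null(res$sparse_model))
    files["sparse_model"] <- write_tsv(
      data.frame(region = res$sparse_model$selected,
                 coefficient = unname(res$sparse_model$coefficients)),
      file.path(out_dir, "sparse_model.tsv"))

  cfg_path <- file.path(out_dir, "config.json")
  cfg_json <- config
  class(cfg_json) <- NULL
  jsonlite::write_json(cfg_json, cfg_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  cks <- tools::md5sum(unname(files))
  names(cks) <- basename(names(cks))
  manifest <- list(
    config_hash = unname(tools::md5sum(cfg_path)),
    seed = config$seed, stage_seeds = seeds,
    checksums = as.list(cks),
    counts = list(n_samples = length(counts$samples),
                  n_train = length(train_ids),
                  n_test = length(test_ids),
                  sites_kept = unname(res$filter_stats["kept"]),
                  dmc_candidates = res$n_dmc_candidates,
                  dmcs_after_perm = nrow(res$dmcs),
                  candidate_regions = nrow(candidates),
                  steroid_regions = nrow(steroid),
                  final_regions = nrow(final)),
    timings = as.list(timings))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  res$manifest <- manifest
  res$out_dir <- out_dir
  class(res) <- "run_result"
  res
}

#' @export
print.run_result <- function(x, ...) {
  cat("dmrpredict run\n")
  cm <- x$manifest$counts
  cat(sprintf("  samples: %d (train %d / test %d)\n", cm$n_samples,
              cm$n_train, cm$n_test))
  cat(sprintf("  sites kept: %s; DMC candidates: %d; after permutation filter: %d\n",
              format(cm$sites_kept, big.mark = ","), cm$dmc_candidates,
              cm$dmcs_after_perm))
  cat(sprintf("  regions: %d candidates -> %d final (steroid regions subtracted: %d)\n",
              cm$candidate_regions, cm$final_regions, cm$steroid_regions))
  if (!is.null(x$sparse_eval))
    cat(sprintf("  L0L2 model: %d regions, test AU-ROC %.3f / AU-PRC %.3f\n",
                length(x$sparse_model$selected),
                x$sparse_eval$test_auroc, x$sparse_eval$test_auprc))
  if (!is.null(x$forest_eval))
    cat(sprintf("  forest model: %d regions, test AU-ROC %.3f / AU-PRC %.3f\n",
                length(x$forest_model$selected),
                x$forest_eval$test_auroc, x$forest_eval$test_auprc))
  invisible(x)
}
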