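# Merge DMCs into regions, subtract confounder regions, censor the X
# chromosome, and compute region-level methylation.

#' Merge DMCs into candidate regions by single-linkage chaining
#'
#' Consecutive DMCs on the same chromosome whose positional distance is
#' at most `gap` bp (inclusive) join one chain; a chain becomes a region
#' spanning its first to last member position. Chains with fewer than
#' `min_dmcs` members are discarded ("more than 5 DMCs" = at least 6 at
#' the default). Direction is the majority sign of member `meth_diff`
#' (ties resolved by the summed difference, then hypo).
#'
#' @param dmcs data.frame of DMC records (from [call_dmcs()] /
#'   [permutation_filter()]).
#' @param gap maximum distance between consecutive member DMCs, bp.
#' @param min_dmcs minimum member count for a chain to be kept.
#' @param label label for the resulting regions.
#' @return A [region_set].
#' @export
merge_dmcs <- function(dmcs, gap = 100, min_dmcs = 6, label = "dmr") {
  if (is.null(dmcs) || nrow(dmcs) == 0) return(region_set())
  d <- dmcs[order(dmcs$chrom, dmcs$pos), , drop = FALSE]
  new_chain <- c(TRUE, d$chrom[-1] != d$chrom[-nrow(d)] |
                   diff(d$pos) > gap)
  chain <- cumsum(new_chain)
  out <- lapply(split(seq_len(nrow(d)), chain), function(i) {
    if (length(i) < min_dmcs) return(NULL)
    md <- d$meth_diff[i]
    n_hyper <- sum(md > 0); n_hypo <- sum(md < 0)
    dir <- if (n_hyper > n_hypo) "hyper"
           else if (n_hypo > n_hyper) "hypo"
           else if (sum(md) > 0) "hyper" else "hypo"
    data.frame(chrom = d$chrom[i[1]], start = min(d$pos[i]),
               end = max(d$pos[i]), n_dmcs = length(i), direction = dir,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(region_set())
  region_set(out$chrom, out$start, out$end, out$n_dmcs, out$direction,
             label)
}

#' Detect confounder-associated regions (e.g. steroid treatment)
#'
#' Re-runs the DMC scan with a binary confounder flag as the contrast
#' and no covariate adjustment, then chains DMCs with the same gap but a
#' looser member-count rule (default "more than three" = at least 4), to
#' comprehensively flag confounded regions for subtraction.
#'
#' @param m filtered [meth_counts] (training samples).
#' @param sheet matching `sample_sheet`.
#' @param contrast_flag 0/1 column of `sheet` to contrast (default
#'   `"steroid"`).
#' @param gap,diff_cutoff,q_cutoff as in the main DMC/DMR calls.
#' @param min_dmcs looser member-count rule (default 4).
#' @return A [region_set] labelled by the flag; empty (with a warning)
#'   if the flag has a single level.
#' @export
call_confounder_regions <- function(m, sheet, contrast_flag = "steroid",
                                    gap = 100, min_dmcs = 4,
                                    diff_cutoff = 10, q_cutoff = 0.05) {
  sheet <- validate_sample_sheet(sheet)
  assert_that(contrast_flag %in% names(sheet),
              paste0("no column ", contrast_flag, " in sheet"))
  flag <- sheet[[contrast_flag]]
  if (length(unique(flag)) < 2 || min(table(flag)) < 2) {
    warning(contrast_flag,
            " has fewer than 2 samples per level; returning empty set")
    return(region_set())
  }
  cs <- sheet
  cs$group <- ifelse(flag == 1, "case", "control")
  dmcs <- call_dmcs(m, cs, covariates = character(),
                    diff_cutoff = diff_cutoff, q_cutoff = q_cutoff)
  merge_dmcs(dmcs, gap = gap, min_dmcs = min_dmcs,
             label = contrast_flag)
}

regions_to_granges <- function(r) {
  GenomicRanges::GRanges(r$chrom,
                         IRanges::IRanges(start = r$start, end = r$end))
}

#' Subtract exclusion regions and censor chromosomes
#'
#' Removes any candidate overlapping an exclusion region by at least one
#' base (intervals are 1-based inclusive, so `chr2:100-300` and
#' `chr2:300-400` overlap), then removes candidates on `drop_chroms`.
#' Order is preserved; no merging is performed.
#'
#' @param candidates,exclusions [region_set]s.
#' @param drop_chroms chromosome names to censor (default `"chrX"`).
#' @return filtered [region_set].
#' @export
subtract_and_censor <- function(candidates, exclusions = region_set(),
                                drop_chroms = "chrX") {
  if (nrow(candidates) == 0) return(candidates)
  keep <- rep(TRUE, nrow(candidates))
  if (!is.null(exclusions) && nrow(exclusions) > 0) {
    ov <- GenomicRanges::findOverlaps(regions_to_granges(candidates),
                                      regions_to_granges(exclusions),
                                      minoverlap = 1L)
    keep[unique(S4Vectors::queryHits(ov))] <- FALSE
  }
  keep <- keep & !(candidates$chrom %in% drop_chroms)
  out <- candidates[keep, , drop = FALSE]
  class(out) <- class(candidates)
  out
}

#' Region-level mean methylation matrix
#'
#' Unweighted mean of member CpG beta values per sample, for each
#' region. Member CpGs are the filtered sites whose position falls
#' inside the region span (1-based inclusive).
#'
#' @param b a `beta_matrix`.
#' @param regions a [region_set].
#' @return numeric matrix regions x samples, rownames
#'   `"chrom:start-end"`.
#' @export
region_beta <- function(b, regions) {
  stopifnot(inherits(b, "beta_matrix"))
  if (nrow(regions) == 0)
    return(matrix(numeric(0), 0, length(b$samples),
                  dimnames = list(NULL, b$samples)))
  gr_sites <- GenomicRanges::GRanges(
    b$sites$chrom, IRanges::IRanges(b$sites$pos, b$sites$pos))
  ov <- GenomicRanges::findOverlaps(regions_to_granges(regions), gr_sites)
  ids <- region_ids(regions)
  out <- matrix(NA_real_, nrow(regions), length(b$samples),
                dimnames = list(ids, b$samples))
  hit <- split(S4Vectors::subjectHits(ov), S4Vectors::queryHits(ov))
  for (qi in names(hit))
    out[as.integer(qi), ] <- colMeans(b$beta[hit[[qi]], , drop = FALSE])
  empty <- !seq_len(nrow(regions)) %in% as.integer(names(hit))
  if (any(empty))
    stop("region(s) with zero member CpGs: ",
         paste(ids[empty], collapse = ", "), call. = FALSE)
  out
}
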