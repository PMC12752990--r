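# k-means clustering of region methylation with WCSS elbow selection;
# region-to-gene assignment and hypergeometric term enrichment.

# best-of-restarts k-means; `extra_centers` lets the elbow scan seed
# k from the k-1 solution so the WCSS curve is non-increasing
kmeans_best <- function(x, k, n_init, seed, extra_centers = NULL) {
  with_seed(seed, {
    best <- NULL
    for (r in seq_len(n_init)) {
      fit <- suppressWarnings(kmeans(x, centers = k, iter.max = 100))
      if (is.null(best) || fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
    if (!is.null(extra_centers) && nrow(extra_centers) == k) {
      fit <- tryCatch(
        suppressWarnings(kmeans(x, centers = extra_centers,
                                iter.max = 100)),
        error = function(e) NULL)
      if (!is.null(fit) && fit$tot.withinss < best$tot.withinss)
        best <- fit
    }
    best
  })
}

#' WCSS elbow curve over a range of cluster counts
#'
#' Runs best-of-`n_init` k-means for each k, seeding each k additionally
#' from the previous solution's centroids plus the point farthest from
#' them (so WCSS is non-increasing in k). The suggested k is the
#' smallest k whose relative WCSS drop to k+1 falls below `drop_ratio`;
#' it is advisory only.
#'
#' @param x regions x samples matrix (e.g. from [region_beta()]).
#' @param k_range candidate cluster counts (default 2:10).
#' @param seed integer seed.
#' @param n_init random restarts per k.
#' @param drop_ratio elbow rule threshold on
#'   `(wcss[k] - wcss[k+1]) / wcss[k]` (default 0.1).
#' @return list with `wcss` (named by k) and `suggested_k`.
#' @export
elbow_wcss <- function(x, k_range = 2:10, seed = 1, n_init = 10,
                       drop_ratio = 0.1) {
  x <- as.matrix(x)
  assert_that(min(k_range) >= 2 && max(k_range) <= nrow(x),
              "k_range must lie in [2, n_regions]")
  seeds <- derive_seeds(seed, length(k_range))
  wcss <- numeric(length(k_range))
  prev <- NULL
  for (i in seq_along(k_range)) {
    k <- k_range[i]
    extra <- NULL
    if (!is.null(prev)) {
      d2 <- rowSums((x - prev$centers[prev$cluster, , drop = FALSE])^2)
      extra <- rbind(prev$centers, x[which.max(d2), , drop = FALSE])
    }
    fit <- kmeans_best(x, k, n_init, seeds[i], extra_centers = extra)
    wcss[i] <- fit$tot.withinss
    prev <- fit
  }
  names(wcss) <- k_range
  suggested <- NA_integer_
  if (length(k_range) >= 2) {
    rel <- (wcss[-length(wcss)] - wcss[-1]) / wcss[-length(wcss)]
    rel[!is.finite(rel)] <- 0
    below <- which(rel < drop_ratio)
    suggested <- if (length(below) > 0) k_range[below[1]]
                 else k_range[length(k_range)]
  }
  list(wcss = wcss, suggested_k = as.integer(suggested))
}

#' k-means clustering of region methylation profiles
#'
#' Lloyd's algorithm with `n_init` seeded restarts on raw beta values
#' (all features share the [0, 1] scale). Cluster labels are renumbered
#' by descending cluster size for stable reporting.
#'
#' @param x regions x samples matrix.
#' @param k number of clusters (default 4).
#' @param seed integer seed.
#' @param n_init random restarts.
#' @param standardize z-score features before clustering (default off).
#' @return list of class `cluster_model`: `k`, `assignments` (named by
#'   region), `centroids`, `wcss`, `sizes`, `seed`.
#' @export
kmeans_cluster <- function(x, k = 4, seed = 1, n_init = 25,
                           standardize = FALSE) {
  x <- as.matrix(x)
  assert_that(k >= 2, "k must be >= 2")
  assert_that(nrow(x) >= k, "fewer regions than clusters")
  xs <- if (standardize) scale(x) else x
  fit <- kmeans_best(xs, k, n_init, seed)
  # relabel by descending size; ties keep original order
  ord <- order(-tabulate(fit$cluster, k), seq_len(k))
  relabel <- integer(k); relabel[ord] <- seq_len(k)
  assign <- relabel[fit$cluster]
  names(assign) <- rownames(x)
  cent <- fit$centers[ord, , drop = FALSE]
  rownames(cent) <- paste0("cluster_", seq_len(k))
  structure(list(k = k, assignments = assign, centroids = cent,
                 wcss = fit$tot.withinss,
                 sizes = as.integer(table(factor(assign,
                                                 levels = seq_len(k)))),
                 seed = seed),
            class = "cluster_model")
}

#' Map regions to genes: overlap, promoter, and adjacency classes
#'
#' A region is linked to a gene as `overlap` if it shares at least one
#' base with the gene body; as `promoter` if it intersects the
#' strand-aware upstream window `[TSS - promoter_bp, TSS)` (TSS
#' exclusive); and as `within_adjacent` if it neither overlaps nor hits
#' a promoter but its distance to the nearest gene is at most
#' `adjacent_bp`. For `within_adjacent`, ties at equal distance are
#' broken by lexical gene id (all tied genes returned when
#' `all_ties = TRUE`).
#'
#' @param regions a [region_set].
#' @param genes gene annotation from [read_gene_bed()] (or equivalent
#'   data.frame).
#' @param promoter_bp upstream promoter window, bp (default 1500).
#' @param adjacent_bp adjacency distance, bp (default 10000).
#' @param all_ties report all equidistant nearest genes.
#' @return data.frame with region, gene_id, class, distance.
#' @export
map_regions_to_genes <- function(regions, genes, promoter_bp = 1500,
                                 adjacent_bp = 10000,
                                 all_ties = FALSE) {
  if (nrow(regions) == 0)
    return(data.frame(region = character(), gene_id = character(),
                      class = character(), distance = integer(),
                      stringsAsFactors = FALSE))
  bad_strand <- !genes$strand %in% c("+", "-")
  if (any(bad_strand))
    warning(sum(bad_strand),
            " gene(s) with unknown strand excluded from promoter logic")
  gr_r <- regions_to_granges(regions)
  gr_g <- GenomicRanges::GRanges(genes$chrom,
                                 IRanges::IRanges(genes$start, genes$end),
                                 strand = ifelse(bad_strand, "*",
                                                 genes$strand))
  ids <- region_ids(regions)
  links <- list()
  ov <- GenomicRanges::findOverlaps(gr_r, gr_g, ignore.strand = TRUE)
  if (length(ov) > 0)
    links$overlap <- data.frame(
      region = ids[S4Vectors::queryHits(ov)],
      gene_id = genes$gene_id[S4Vectors::subjectHits(ov)],
      class = "overlap", distance = 0L, stringsAsFactors = FALSE)
  # promoters: upstream-only, strand-aware, TSS-exclusive
  pg <- which(!bad_strand)
  if (length(pg) > 0 && promoter_bp > 0) {
    plus <- genes$strand[pg] == "+"
    pstart <- ifelse(plus, pmax(genes$start[pg] - promoter_bp, 1L),
                     genes$end[pg] + 1L)
    pend <- ifelse(plus, genes$start[pg] - 1L,
                   genes$end[pg] + promoter_bp)
    ok <- pstart <= pend
    if (any(ok)) {
      gr_p <- GenomicRanges::GRanges(
        genes$chrom[pg][ok], IRanges::IRanges(pstart[ok], pend[ok]))
      ovp <- GenomicRanges::findOverlaps(gr_r, gr_p, ignore.strand = TRUE)
      if (length(ovp) > 0)
        links$promoter <- data.frame(
          region = ids[S4Vectors::queryHits(ovp)],
          gene_id = genes$gene_id[pg][ok][S4Vectors::subjectHits(ovp)],
          class = "promoter", distance = 0L, stringsAsFactors = FALSE)
    }
  }
  # nearest-gene adjacency for regions with no overlap link
  has_overlap <- unique(if (is.null(links$overlap)) character()
                        else links$overlap$region)
  rest <- which(!ids %in% has_overlap)
  if (length(rest) > 0) {
    near <- GenomicRanges::findOverlaps(gr_r[rest], gr_g,
                                        maxgap = adjacent_bp,
                                        ignore.strand = TRUE)
    if (length(near) > 0) {
      q <- S4Vectors::queryHits(near); g <- S4Vectors::subjectHits(near)
      dd <- data.frame(q = q, g = g,
                       dist = GenomicRanges::distance(gr_r[rest][q],
                                                      gr_g[g]))
      dd <- dd[dd$dist <= adjacent_bp & dd$dist > 0, , drop = FALSE]
      if (nrow(dd) > 0) {
        # keep the nearest gene(s) per region; ties broken lexically
        dd$gene_id <- genes$gene_id[dd$g]
        dd <- dd[order(dd$q, dd$dist, dd$gene_id), , drop = FALSE]
        min_d <- tapply(dd$dist, dd$q, min)
        dd <- dd[dd$dist == min_d[as.character(dd$q)], , drop = FALSE]
        if (!all_ties) dd <- dd[!duplicated(dd$q), , drop = FALSE]
        links$within_adjacent <- data.frame(
          region = ids[rest][dd$q], gene_id = dd$gene_id,
          class = "within_adjacent", distance = as.integer(dd$dist),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, links)
  if (is.null(out))
    out <- data.frame(region = character(), gene_id = character(),
                      class = character(), distance = integer(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Hypergeometric term enrichment
#'
#' For each term, tests over-representation of the selected gene list
#' against the background with the upper-tail hypergeometric probability
#' `P(X >= k_hit)`, then adjusts across terms by Benjamini-Hochberg.
#' Terms with no annotated background gene are skipped.
#'
#' @param selected_genes character vector, subset of the background.
#' @param background_genes character vector (the gene universe).
#' @param term_map data.frame(gene_id, term_id), e.g. from
#'   [read_term_map()].
#' @return data.frame: term_id, k_hit, K_ann, n_sel, N_bg, p_value, fdr;
#'   sorted by p.
#' @export
hypergeom_enrich <- function(selected_genes, background_genes, term_map) {
  selected_genes <- unique(selected_genes)
  background_genes <- unique(background_genes)
  assert_that(all(selected_genes %in% background_genes),
              "selected genes must be a subset of the background")
  tm <- term_map[term_map$gene_id %in% background_genes, , drop = FALSE]
  N <- length(background_genes)
  n <- length(selected_genes)
  terms <- split(tm$gene_id, tm$term_id)
  rows <- lapply(names(terms), function(t) {
    ann <- unique(terms[[t]])
    K <- length(ann)
    if (K == 0) return(NULL)
    k <- sum(selected_genes %in% ann)
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = t, k_hit = k, K_ann = K, n_sel = n, N_bg = N,
               p_value = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term_id = character(), k_hit = integer(),
                      K_ann = integer(), n_sel = integer(),
                      N_bg = integer(), p_value = numeric(),
                      fdr = numeric(), stringsAsFactors = FALSE))
  out$fdr <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value, out$term_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}
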