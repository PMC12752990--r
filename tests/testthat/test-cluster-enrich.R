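# archetype matrix: k groups of regions with distinct sample profiles
archetype_matrix <- function(k, per, n_samples, noise = 0.02, seed = 1) {
  set.seed(seed)
  centers <- matrix(runif(k * n_samples, 0.1, 0.9), k, n_samples)
  x <- centers[rep(seq_len(k), each = per), ] +
    rnorm(k * per * n_samples, 0, noise)
  x <- pmin(pmax(x, 0), 1)
  rownames(x) <- paste0("r", seq_len(nrow(x)))
  colnames(x) <- paste0("S", seq_len(n_samples))
  x
}

test_that("WCSS is non-increasing and the elbow finds planted archetypes", {
  x <- archetype_matrix(4, 15, 10, seed = 2)
  e <- elbow_wcss(x, k_range = 2:8, seed = 3)
  expect_true(all(diff(e$wcss) <= 1e-8))
  expect_equal(e$suggested_k, 4L)
  expect_error(elbow_wcss(x, k_range = 2:100), "k_range")
})

test_that("k-means recovers two archetypes up to label swap, deterministically", {
  x <- archetype_matrix(2, 12, 8, seed = 4)
  cm <- kmeans_cluster(x, k = 2, seed = 9)
  truth <- rep(1:2, each = 12)
  agree <- mean(cm$assignments == truth)
  expect_true(agree == 1 || agree == 0)  # exact up to label swap
  cm2 <- kmeans_cluster(x, k = 2, seed = 9)
  expect_identical(cm$assignments, cm2$assignments)
  # duplicated region rows land in the same cluster
  x2 <- rbind(x, dup = x[1, ])
  cm3 <- kmeans_cluster(x2, k = 2, seed = 9)
  expect_equal(unname(cm3$assignments["dup"]),
               unname(cm3$assignments["r1"]))
  # labels are ordered by descending size
  x3 <- archetype_matrix(3, 5, 6, seed = 5)[c(1:5, 6:8, 11:12), ]
  cm4 <- kmeans_cluster(x3, k = 3, seed = 1)
  expect_true(all(diff(cm4$sizes) <= 0))
})

test_that("cluster assignments ignore sample-column order", {
  x <- archetype_matrix(3, 10, 9, seed = 6)
  cm <- kmeans_cluster(x, k = 3, seed = 2)
  perm <- sample(ncol(x))
  cmp <- kmeans_cluster(x[, perm], k = 3, seed = 2)
  # same partition: co-membership matrices agree
  same <- outer(cm$assignments, cm$assignments, "==")
  samep <- outer(cmp$assignments, cmp$assignments, "==")
  expect_true(all(same == samep))
})

genes_fixture <- function() {
  data.frame(chrom = "chr1",
             start = c(10000L, 50000L, 90000L),
             end = c(20000L, 60000L, 99000L),
             gene_id = c("geneA", "geneB", "geneC"),
             strand = c("+", "-", "+"),
             stringsAsFactors = FALSE)
}

test_that("gene mapping classifies overlap, promoter and adjacency", {
  g <- genes_fixture()
  r <- region_set("chr1",
                  c(15000L, 8500L, 8300L, 30000L, 61000L),
                  c(15200L, 8650L, 8400L, 30100L, 61200L))
  links <- map_regions_to_genes(r, g, promoter_bp = 1500,
                                adjacent_bp = 10000)
  get <- function(region)
    links[links$region == region, c("gene_id", "class", "distance")]
  # inside the gene body: overlap at distance 0
  expect_equal(get("chr1:15000-15200")$class, "overlap")
  expect_equal(get("chr1:15000-15200")$distance, 0L)
  # 1,350-1,500 bp upstream of the + strand TSS (10000): promoter
  expect_true("promoter" %in% get("chr1:8500-8650")$class)
  # 1,600 bp upstream: not promoter, but within 10 kb
  cls <- get("chr1:8300-8400")$class
  expect_false("promoter" %in% cls)
  expect_true("within_adjacent" %in% cls)
  # minus-strand gene: upstream is to the right of its end (60000)
  expect_true("promoter" %in% get("chr1:61000-61200")$class)
})

test_that("adjacency ties break lexically and all_ties reports both", {
  g <- data.frame(chrom = "chr1", start = c(1000L, 8500L),
                  end = c(2000L, 9500L),
                  gene_id = c("zgene", "agene"), strand = "+",
                  stringsAsFactors = FALSE)
  r <- region_set("chr1", 5000L, 5500L)  # equidistant from both genes
  one <- map_regions_to_genes(r, g, adjacent_bp = 10000)
  expect_equal(one$gene_id, "agene")
  both <- map_regions_to_genes(r, g, adjacent_bp = 10000,
                               all_ties = TRUE)
  expect_setequal(both$gene_id, c("agene", "zgene"))
})

test_that("hypergeometric enrichment matches the closed-form example", {
  bg <- paste0("g", 1:20)
  sel <- paste0("g", 1:4)
  tm <- data.frame(gene_id = c(paste0("g", 1:5), paste0("g", 1:20)),
                   term_id = c(rep("T1", 5), rep("T2", 20)))
  # T1: N=20, K=5, n=4, k=3 when selection holds g1..g3 of the term
  sel3 <- c("g1", "g2", "g3", "g10")
  out <- hypergeom_enrich(sel3, bg, tm)
  p_expected <- (choose(5, 3) * choose(15, 1) +
                   choose(5, 4) * choose(15, 0)) / choose(20, 4)
  expect_equal(out$p_value[out$term_id == "T1"], p_expected,
               tolerance = 1e-12)
  # saturation: selection = background makes k = K, p = 1
  all_out <- hypergeom_enrich(bg, bg, tm)
  expect_true(all(all_out$p_value == 1))
  # zero hits give p = 1
  none <- hypergeom_enrich(c("g10", "g11"), bg,
                           data.frame(gene_id = c("g1", "g2"),
                                      term_id = "T9"))
  expect_equal(none$p_value, 1)
})

test_that("enrichment equals exhaustive enumeration for small backgrounds", {
  set.seed(12)
  for (rep in 1:20) {
    N <- sample(5:25, 1)
    K <- sample.int(N, 1)
    n <- sample.int(N, 1)
    bg <- paste0("g", seq_len(N))
    tm <- data.frame(gene_id = bg[seq_len(K)], term_id = "T")
    sel <- sample(bg, n)
    out <- hypergeom_enrich(sel, bg, tm)
    k <- sum(sel %in% bg[seq_len(K)])
    expect_equal(out$p_value, hyper_upper_oracle(k, K, n, N),
                 tolerance = 1e-12)
  }
})

test_that("enrichment is invariant to gene order and validates inputs", {
  bg <- paste0("g", 1:15)
  tm <- data.frame(gene_id = bg[c(1:6, 4:9)],
                   term_id = rep(c("A", "B"), each = 6))
  sel <- c("g2", "g4", "g6", "g8")
  a <- hypergeom_enrich(sel, bg, tm)
  b <- hypergeom_enrich(rev(sel), sample(bg), tm)
  expect_equal(a, b)
  expect_error(hypergeom_enrich(c("zz"), bg, tm), "subset")
})
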