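# Containers and on-disk formats.
#
# Internal coordinate convention: 1-based, inclusive, everywhere. Only BED
# readers/writers convert to/from 0-based half-open. Region strings in reports
# ("chr1:100-250") are 1-based inclusive.

#' Construct a per-CpG methylation count matrix
#'
#' The pipeline's raw substrate: an ordered set of CpG sites with paired
#' (methylated, total) read counts per sample. Sites are sorted by
#' (chrom, pos) and must be unique; counts satisfy
#' `0 <= methylated <= total` elementwise. `total = 0` means the site was
#' not observed in that sample and is never imputed.
#'
#' @param sites data.frame with columns `chrom` (character), `pos`
#'   (1-based integer position) and `strand` (`"+"`, `"-"` or `"*"`).
#' @param meth,total integer matrices, sites x samples.
#' @param samples character vector of sample ids (column order).
#' @return An object of class `meth_counts`.
#' @export
meth_counts <- function(sites, meth, total, samples = colnames(total)) {
  sites <- as.data.frame(sites, stringsAsFactors = FALSE)
  assert_that(all(c("chrom", "pos", "strand") %in% names(sites)),
              "sites needs columns chrom, pos, strand")
  meth <- as.matrix(meth); total <- as.matrix(total)
  storage.mode(meth) <- "integer"; storage.mode(total) <- "integer"
  assert_that(nrow(sites) == nrow(meth) && nrow(sites) == nrow(total),
              "sites and count matrices disagree on row count")
  assert_that(ncol(meth) == ncol(total), "meth/total column mismatch")
  if (is.null(samples)) samples <- paste0("S", seq_len(ncol(meth)))
  assert_that(!anyDuplicated(samples), "duplicate sample ids")
  assert_that(all(sites$pos >= 1L), "positions must be >= 1 (1-based)")
  assert_that(all(nzchar(sites$chrom)), "empty chromosome name")
  bad <- which(meth > total | meth < 0L, arr.ind = TRUE)
  if (nrow(bad) > 0) {
    i <- bad[1, 1]; j <- bad[1, 2]
    stop(sprintf("methylated > total (or negative) at %s:%d sample %s",
                 sites$chrom[i], sites$pos[i], samples[j]), call. = FALSE)
  }
  o <- order(sites$chrom, sites$pos)
  sites <- sites[o, , drop = FALSE]
  meth <- meth[o, , drop = FALSE]; total <- total[o, , drop = FALSE]
  key <- paste0(sites$chrom, ":", sites$pos)
  assert_that(!anyDuplicated(key), "duplicate CpG sites")
  rownames(sites) <- NULL
  dimnames(meth) <- dimnames(total) <- list(key, samples)
  structure(list(sites = sites, meth = meth, total = total,
                 samples = samples),
            class = "meth_counts")
}

#' @export
print.meth_counts <- function(x, ...) {
  cat(sprintf("meth_counts: %d CpG sites x %d samples (%d chromosome%s)\n",
              nrow(x$sites), length(x$samples),
              length(unique(x$sites$chrom)),
              if (length(unique(x$sites$chrom)) == 1) "" else "s"))
  invisible(x)
}

#' @export
dim.meth_counts <- function(x) dim(x$meth)

# subset samples (columns), preserving class
subset_samples <- function(m, ids) {
  assert_that(all(ids %in% m$samples), "unknown sample id in subset")
  meth_counts(m$sites, m$meth[, ids, drop = FALSE],
              m$total[, ids, drop = FALSE], ids)
}

meth_call_cols <- c("chrom", "pos", "strand", "context",
                    "methylated_count", "total_count")

#' Read per-sample methylation call tables into one matrix
#'
#' Each file is a tab-separated table with header columns
#' `chrom, pos, strand, context, methylated_count, total_count`
#' (positions 1-based). The union of sites across samples is taken;
#' a site absent from a sample gets `total = 0` (not observed) in that
#' column.
#'
#' @param paths character vector of file paths, one per sample.
#' @param sample_ids ids for the columns; defaults to file base names.
#' @param destrand collapse `-`-strand calls onto the `+`-strand position
#'   of the CpG (pos - 1) and sum counts. Default `FALSE`: sites are kept
#'   as called.
#' @return A [meth_counts] object.
#' @export
read_meth_calls <- function(paths, sample_ids = NULL, destrand = FALSE) {
  assert_that(length(paths) >= 1, "no input files")
  if (is.null(sample_ids))
    sample_ids <- sub("\\.tsv$", "", basename(paths))
  assert_that(length(sample_ids) == length(paths),
              "one sample id per file required")
  per <- lapply(seq_along(paths), function(k) {
    p <- paths[k]
    if (!file.exists(p)) stop("file not found: ", p, call. = FALSE)
    d <- data.table::fread(p, sep = "\t", header = TRUE,
                           data.table = FALSE, showProgress = FALSE)
    miss <- setdiff(meth_call_cols, names(d))
    if (length(miss) > 0)
      stop(sprintf("%s: missing column(s) %s", p,
                   paste(miss, collapse = ", ")), call. = FALSE)
    for (cc in c("chrom", "strand", "context"))
      d[[cc]] <- as.character(d[[cc]])
    bad <- which(!is.finite(d$methylated_count) | !is.finite(d$total_count) |
                   d$methylated_count < 0 | d$methylated_count > d$total_count)
    if (length(bad) > 0)
      stop(sprintf("%s line %d: invalid counts (methylated=%s, total=%s) at %s:%s",
                   p, bad[1] + 1L, d$methylated_count[bad[1]],
                   d$total_count[bad[1]], d$chrom[bad[1]], d$pos[bad[1]]),
           call. = FALSE)
    if (any(d$pos < 1))
      stop(sprintf("%s: non-positive position", p), call. = FALSE)
    if (destrand) {
      neg <- d$strand == "-"
      d$pos[neg] <- d$pos[neg] - 1L
      mc <- rowsum(d[, c("methylated_count", "total_count")],
                   group = paste0(d$chrom, ":", d$pos))
      at <- strsplit(rownames(mc), ":", fixed = TRUE)
      d <- data.frame(chrom = vapply(at, `[`, "", 1),
                      pos = as.integer(vapply(at, `[`, "", 2)),
                      strand = "+",
                      methylated_count = mc$methylated_count,
                      total_count = mc$total_count,
                      stringsAsFactors = FALSE)
    }
    d
  })
  keys <- unique(do.call(rbind, lapply(per, function(d)
    d[, c("chrom", "pos", "strand")])))
  keys <- keys[order(keys$chrom, keys$pos), , drop = FALSE]
  key <- paste0(keys$chrom, ":", keys$pos)
  if (anyDuplicated(key))
    stop("same position appears with two strands; use destrand = TRUE or fix input",
         call. = FALSE)
  n <- nrow(keys)
  meth <- matrix(0L, n, length(paths))
  total <- matrix(0L, n, length(paths))
  for (k in seq_along(per)) {
    idx <- match(paste0(per[[k]]$chrom, ":", per[[k]]$pos), key)
    meth[idx, k] <- as.integer(per[[k]]$methylated_count)
    total[idx, k] <- as.integer(per[[k]]$total_count)
  }
  meth_counts(as.data.frame(keys), meth, total, sample_ids)
}

write_meth_calls <- function(m, dir) {
  paths <- file.path(dir, paste0(m$samples, ".tsv"))
  for (j in seq_along(m$samples)) {
    d <- data.frame(chrom = m$sites$chrom, pos = m$sites$pos,
                    strand = m$sites$strand, context = "CpG",
                    methylated_count = m$meth[, j],
                    total_count = m$total[, j])
    data.table::fwrite(d, paths[j], sep = "\t")
  }
  paths
}

sheet_required <- c("sample_id", "group")
sheet_all <- c("sample_id", "group", "age_years", "sex", "neutered",
               "breed", "steroid", "setting", "split")

#' Read and validate a sample sheet
#'
#' Tab-separated, one row per sample, with columns `sample_id`, `group`
#' (`case`/`control`) and optionally `age_years`, `sex` (`F`/`M`),
#' `neutered` (0/1), `breed`, `steroid` (0/1), `setting`, `split`
#' (`train`/`test`/`unassigned`). Categorical levels are normalised
#' case-insensitively; a missing `split` column means all samples are
#' `unassigned`.
#'
#' @param path file path.
#' @return A validated data.frame of class `sample_sheet`.
#' @export
read_sample_sheet <- function(path) {
  d <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  validate_sample_sheet(d, where = path)
}

#' @rdname read_sample_sheet
#' @param sheet a data.frame with the columns above (in-memory variant).
#' @param where label used in error messages.
#' @export
validate_sample_sheet <- function(sheet, where = "sample sheet") {
  d <- as.data.frame(sheet, stringsAsFactors = FALSE)
  miss <- setdiff(sheet_required, names(d))
  assert_that(length(miss) == 0,
              sprintf("%s: missing column(s) %s", where,
                      paste(miss, collapse = ", ")))
  d$sample_id <- as.character(d$sample_id)
  dup <- d$sample_id[duplicated(d$sample_id)]
  assert_that(length(dup) == 0,
              sprintf("%s: duplicate sample id %s", where, dup[1]))
  d$group <- tolower(as.character(d$group))
  bad <- which(!d$group %in% c("case", "control"))
  assert_that(length(bad) == 0,
              sprintf("%s row %d (%s): group must be case/control, got '%s'",
                      where, bad[1], d$sample_id[bad[1]], d$group[bad[1]]))
  if ("age_years" %in% names(d)) {
    age <- suppressWarnings(as.numeric(d$age_years))
    bad <- which(is.na(age) & !is.na(d$age_years))
    assert_that(length(bad) == 0,
                sprintf("%s row %d (%s): non-numeric age '%s'", where, bad[1],
                        d$sample_id[bad[1]], d$age_years[bad[1]]))
    d$age_years <- age
  }
  if ("sex" %in% names(d)) {
    d$sex <- toupper(substr(as.character(d$sex), 1, 1))
    bad <- which(!d$sex %in% c("F", "M"))
    assert_that(length(bad) == 0,
                sprintf("%s row %d: sex must be F/M", where, bad[1]))
  }
  for (flag in c("neutered", "steroid")) {
    if (flag %in% names(d)) {
      v <- as.integer(d[[flag]])
      assert_that(all(v %in% c(0L, 1L)),
                  sprintf("%s: %s must be 0/1", where, flag))
      d[[flag]] <- v
    }
  }
  if (!"split" %in% names(d)) d$split <- "unassigned"
  d$split <- tolower(as.character(d$split))
  bad <- which(!d$split %in% c("train", "test", "unassigned"))
  assert_that(length(bad) == 0,
              sprintf("%s row %d: split must be train/test/unassigned",
                      where, bad[1]))
  class(d) <- c("sample_sheet", "data.frame")
  d
}

write_sample_sheet <- function(sheet, path) {
  write.table(as.data.frame(sheet), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Construct a region set
#'
#' Genomic intervals (1-based, inclusive) carrying the number of member
#' DMCs, a direction (`hyper`/`hypo`) and a free-text label. The DMR
#' currency of the pipeline.
#'
#' @param chrom,start,end interval coordinates (1-based inclusive).
#' @param n_dmcs member DMC count (0 if unknown).
#' @param direction `"hyper"`, `"hypo"` or `NA`.
#' @param label free-text label.
#' @return data.frame of class `region_set`, sorted, unique intervals.
#' @export
region_set <- function(chrom = character(), start = integer(),
                       end = integer(), n_dmcs = 0L,
                       direction = NA_character_, label = NA_character_) {
  d <- data.frame(chrom = as.character(chrom), start = as.integer(start),
                  end = as.integer(end), stringsAsFactors = FALSE)
  d$n_dmcs <- rep_len(as.integer(n_dmcs), nrow(d))
  d$direction <- rep_len(as.character(direction), nrow(d))
  d$label <- rep_len(as.character(label), nrow(d))
  if (nrow(d) > 0) {
    assert_that(all(d$start <= d$end), "region start > end")
    assert_that(all(d$start >= 1), "regions are 1-based; start >= 1")
    d <- d[order(d$chrom, d$start, d$end), , drop = FALSE]
    key <- paste0(d$chrom, ":", d$start, "-", d$end)
    assert_that(!anyDuplicated(key), "duplicate region")
    rownames(d) <- key
  }
  class(d) <- c("region_set", "data.frame")
  d
}

region_ids <- function(r) {
  if (nrow(r) == 0) return(character(0))
  paste0(r$chrom, ":", r$start, "-", r$end)
}

#' Write a region set as BED
#'
#' Internal 1-based inclusive intervals become 0-based half-open on disk.
#' The name field carries `direction|n_dmcs`; score is `n_dmcs`. Regions
#' are written as-is: overlaps are not merged.
#'
#' @param regions a [region_set].
#' @param path output path.
#' @export
write_regions_bed <- function(regions, path) {
  if (nrow(regions) == 0) {
    con <- file(path, "w"); close(con)
    return(invisible(path))
  }
  d <- data.frame(chrom = regions$chrom,
                  start = regions$start - 1L,
                  end = regions$end,
                  name = paste0(ifelse(is.na(regions$direction), ".",
                                       regions$direction), "|",
                                regions$n_dmcs),
                  score = regions$n_dmcs,
                  strand = ".")
  con <- file(path, "w"); on.exit(close(con))
  if (nrow(d) > 0)
    write.table(d, con, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file as a region set (converting to 1-based inclusive)
#'
#' @param path BED3+ path; column 4, when present and of the form
#'   `direction|n`, is unpacked into direction and DMC count.
#' @param label label to attach to all records.
#' @return A [region_set].
#' @export
read_regions_bed <- function(path, label = NA_character_) {
  if (file.size(path) == 0)
    return(region_set())
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  direction <- NA_character_; n_dmcs <- 0L
  if (ncol(d) >= 4) {
    parts <- strsplit(as.character(d[[4]]), "|", fixed = TRUE)
    direction <- vapply(parts, `[`, "", 1)
    direction[!direction %in% c("hyper", "hypo")] <- NA_character_
    n2 <- suppressWarnings(as.integer(vapply(parts, function(p)
      if (length(p) >= 2) p[2] else NA_character_, "")))
    n_dmcs <- ifelse(is.na(n2), 0L, n2)
  }
  region_set(d[[1]], as.integer(d[[2]]) + 1L, as.integer(d[[3]]),
             n_dmcs = n_dmcs, direction = direction, label = label)
}

#' Read a BED6 gene annotation
#'
#' Columns: chrom, start (0-based), end, gene_id, score, strand.
#' Internally 1-based inclusive; gene ids must be unique.
#'
#' @param path BED6 path.
#' @return data.frame(chrom, start, end, gene_id, strand).
#' @export
read_gene_bed <- function(path) {
  d <- read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  assert_that(ncol(d) >= 6, "gene annotation must be BED6")
  g <- data.frame(chrom = as.character(d[[1]]),
                  start = as.integer(d[[2]]) + 1L,
                  end = as.integer(d[[3]]),
                  gene_id = as.character(d[[4]]),
                  strand = as.character(d[[6]]),
                  stringsAsFactors = FALSE)
  assert_that(all(g$start <= g$end), "gene start > end")
  assert_that(!anyDuplicated(g$gene_id), "duplicate gene_id in annotation")
  g
}

#' Read a flat gene-to-term annotation map
#'
#' Two tab-separated columns: `gene_id`, `term_id` (GAF-style flat map;
#' no ontology propagation is performed).
#'
#' @param path file path.
#' @return data.frame(gene_id, term_id), unique pairs.
#' @export
read_term_map <- function(path) {
  d <- read.delim(path, header = TRUE, stringsAsFactors = FALSE)
  assert_that(all(c("gene_id", "term_id") %in% names(d)),
              "term map needs columns gene_id, term_id")
  unique(d[, c("gene_id", "term_id")])
}
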