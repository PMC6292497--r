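# CpG methylation: per-site levels, genome-wide category fractions,
# region-level 5mC summarisation, two-cluster (k = 2) separation of
# tissue-specific regulatory elements, and association of the clusters
# with gene expression.

#' Per-CpG methylation levels
#'
#' level = methylated reads / total reads. Sites below the coverage
#' floor are excluded (and counted); records with methylated > total are
#' rejected and reported.
#'
#' @param calls data.frame with columns `chrom`, `pos` (0-based),
#'   `strand`, `meth`, `total`, `sample`.
#' @param min_coverage coverage floor (default 5).
#' @return data.frame of retained records with a `level` column;
#'   attributes `n_low_coverage` and `bad_records` (row indices with
#'   meth > total, which are dropped).
#' @export
cpg_methylation_levels <- function(calls, min_coverage = 5) {
  stopifnot(all(c("chrom", "pos", "meth", "total", "sample") %in%
                  names(calls)))
  if (any(calls$meth < 0) || any(calls$total < 0))
    stop("read counts must be non-negative")
  bad <- which(calls$meth > calls$total)
  if (length(bad))
    warning(length(bad), " record(s) with methylated > total rejected")
  ok <- setdiff(seq_len(nrow(calls)), bad)
  calls <- calls[ok, , drop = FALSE]
  low <- calls$total < min_coverage
  out <- calls[!low, , drop = FALSE]
  out$level <- out$meth / out$total
  attr(out, "n_low_coverage") <- sum(low)
  attr(out, "bad_records") <- bad
  out
}

#' Methylation category fractions
#'
#' Fractions of CpG sites in the four canonical categories:
#' zero (exactly 0), low (0, 0.20], medium (0.20, 0.80], high (0.80, 1].
#'
#' @param levels numeric vector of methylation levels in [0, 1].
#' @return named numeric vector of fractions summing to 1.
#' @export
methylation_category_fractions <- function(levels) {
  if (!length(levels)) stop("need at least one level")
  if (any(levels < 0 | levels > 1)) stop("levels must be in [0, 1]")
  cats <- ifelse(levels == 0, "zero",
          ifelse(levels <= 0.20, "low",
          ifelse(levels <= 0.80, "medium", "high")))
  tab <- table(factor(cats, c("zero", "low", "medium", "high")))
  stats::setNames(as.numeric(tab) / length(levels), names(tab))
}

#' Region-level methylation summaries
#'
#' Per-region, per-sample unweighted mean of CpG levels over the CpGs
#' falling inside the region (0-based half-open). Region/sample cells
#' with fewer than `min_cpgs` covered CpGs are NA; regions with no
#' covered CpGs in any sample are dropped and reported.
#'
#' @param records output of [cpg_methylation_levels()].
#' @param regions data.frame (`chrom`, `start`, `end`, `region_id`).
#' @param min_cpgs minimum CpGs per region per sample (default 3).
#' @return regions x samples numeric matrix of mean levels; attribute
#'   "n_cpgs" holds the per-cell CpG counts, attribute "dropped" the
#'   region ids with no coverage anywhere.
#' @export
region_methylation <- function(records, regions, min_cpgs = 3) {
  samples <- sort(unique(records$sample))
  M <- matrix(NA_real_, nrow(regions), length(samples),
              dimnames = list(regions$region_id, samples))
  Ncp <- matrix(0L, nrow(regions), length(samples),
                dimnames = dimnames(M))
  rgr <- GenomicRanges::GRanges(regions$chrom,
    IRanges::IRanges(regions$start + 1L, regions$end))
  cgr <- GenomicRanges::GRanges(records$chrom,
    IRanges::IRanges(records$pos + 1L, records$pos + 1L))
  ov <- GenomicRanges::findOverlaps(cgr, rgr)
  if (length(ov)) {
    ri <- S4Vectors::subjectHits(ov); ci <- S4Vectors::queryHits(ov)
    samp <- factor(records$sample[ci], samples)
    cell <- interaction(ri, samp, drop = FALSE)
    sums <- tapply(records$level[ci], cell, sum)
    ns <- tapply(records$level[ci], cell, length)
    for (nm in names(sums)[!is.na(sums)]) {
      parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
      r <- as.integer(parts[1]); s <- parts[2]
      Ncp[r, s] <- ns[[nm]]
      if (ns[[nm]] >= min_cpgs) M[r, s] <- sums[[nm]] / ns[[nm]]
    }
  }
  dropped <- rownames(M)[rowSums(Ncp) == 0]
  if (length(dropped))
    warning(length(dropped), " region(s) with no covered CpGs dropped")
  keep <- rowSums(Ncp) > 0
  out <- M[keep, , drop = FALSE]
  attr(out, "n_cpgs") <- Ncp[keep, , drop = FALSE]
  attr(out, "dropped") <- dropped
  out
}

#' Two-cluster k-means separation of region methylation profiles
#'
#' Euclidean k-means with k = 2 (k-means++-style multi-start via
#' `nstart`), applied to the regions x samples methylation matrix.
#' Cluster labels are anchored to the defining tissue: cluster 1 is the
#' cluster whose centroid drops most in the defining sample relative to
#' the remaining samples (the tissue-specifically demethylated,
#' "differential" cluster); cluster 2 is the constitutive cluster.
#'
#' @param mat regions x samples numeric matrix (no NAs).
#' @param seed integer seed.
#' @param n_init number of random restarts (default 20).
#' @param defining_sample column name or index anchoring the labels
#'   (default 1).
#' @return list with `labels` (named 1/2 per region), `centroids`
#'   (2 x samples), `withinss` (total within-cluster sum of squares).
#' @export
kmeans2_cluster <- function(mat, seed = 1, n_init = 20, defining_sample = 1) {
  mat <- as.matrix(mat)
  if (nrow(mat) < 2) stop("k = 2 clustering needs at least 2 regions")
  if (anyNA(mat)) stop("matrix contains NAs: filter or impute first")
  if (nrow(unique(mat)) < 2) stop("fewer than 2 distinct rows")
  km <- with_seed(sub_seed(seed, "kmeans2"), {
    stats::kmeans(mat, centers = 2, nstart = n_init, iter.max = 100)
  })
  cen <- km$centers
  if (is.character(defining_sample))
    defining_sample <- match(defining_sample, colnames(mat))
  drop_score <- cen[, defining_sample] -
    rowMeans(cen[, -defining_sample, drop = FALSE])
  ord <- order(drop_score)   # most negative drop first -> cluster 1
  relabel <- integer(2); relabel[ord] <- 1:2
  labels <- stats::setNames(relabel[km$cluster], rownames(mat))
  list(labels = labels, centroids = cen[ord, , drop = FALSE],
       withinss = km$tot.withinss)
}

#' Expression of genes associated with each methylation cluster
#'
#' Compares the expression (level or breadth) of genes associated with
#' cluster-1 versus cluster-2 regions with a two-sided rank-sum test.
#'
#' @param labels named cluster labels (1/2) per region.
#' @param region2gene named character vector: region id -> gene id.
#' @param expression named numeric vector per gene (e.g. mean cRPKM or
#'   number of expressed domains).
#' @return list with `by_cluster` (two numeric vectors) and `p_value`
#'   (NA with a note if a cluster has no associated genes).
#' @export
cluster_expression_association <- function(labels, region2gene, expression) {
  region2gene <- region2gene[names(region2gene) %in% names(labels)]
  gene_vals <- expression[region2gene]
  keep <- !is.na(gene_vals)
  cl <- labels[names(region2gene)][keep]
  vals <- gene_vals[keep]
  by_cluster <- split(unname(vals), cl)
  if (length(by_cluster) < 2 || any(lengths(by_cluster) < 2))
    return(list(by_cluster = by_cluster, p_value = NA_real_,
                note = "a cluster has <2 associated genes: test skipped"))
  list(by_cluster = by_cluster,
       p_value = rank_sum_test(by_cluster[[1]], by_cluster[[2]],
                               "two.sided"))
}

#' Read / write per-CpG call tables
#'
#' TSV with columns `chrom`, `pos` (0-based), `strand`, `meth`, `total`,
#' `sample`.
#'
#' @param path file path.
#' @param calls data.frame to write.
#' @export
read_cpg_tsv <- function(path) read_tsv_table(path)

#' @rdname read_cpg_tsv
#' @export
write_cpg_tsv <- function(calls, path) write_tsv_table(calls, path)
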