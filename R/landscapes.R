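# Regulatory-landscape quantification: peak classification relative to
# gene annotation, GREAT-style regulatory domains, per-gene peak counts,
# size-stratified matching, TSS-distance profiles, bidirectional-promoter
# detection and conservation aggregation.
#
# All internal coordinates are 0-based half-open (BED-native); GTF input
# is converted on read. Peak membership is by midpoint throughout
# (configurable to any-overlap where stated).

#' Construct a genome annotation
#'
#' @param chromosomes data.frame with columns `name`, `length`.
#' @param genes data.frame with columns `gene_id`, `chrom`, `strand`
#'   ("+"/"-"), `start`, `end` (0-based half-open). The TSS is derived:
#'   `start` on "+", `end - 1` on "-".
#' @return A `genome_annotation` list with `chromosomes` and `genes`
#'   (including a `tss` column).
#' @export
genome_annotation <- function(chromosomes, genes) {
  stopifnot(all(c("name", "length") %in% names(chromosomes)),
            all(c("gene_id", "chrom", "strand", "start", "end") %in%
                  names(genes)))
  genes <- as.data.frame(genes, stringsAsFactors = FALSE)
  if (!all(genes$strand %in% c("+", "-")))
    stop("gene strand must be '+' or '-'")
  cl <- stats::setNames(chromosomes$length, chromosomes$name)
  bad <- !(genes$chrom %in% names(cl))
  if (any(bad)) stop("genes on unknown chromosome(s): ",
                     paste(unique(genes$chrom[bad]), collapse = ", "))
  if (any(genes$start < 0 | genes$start >= genes$end |
          genes$end > cl[genes$chrom]))
    stop("gene coordinates out of chromosome bounds")
  if (anyDuplicated(genes$gene_id)) stop("duplicate gene ids")
  genes$tss <- ifelse(genes$strand == "+", genes$start, genes$end - 1L)
  structure(list(chromosomes = as.data.frame(chromosomes), genes = genes),
            class = "genome_annotation")
}

#' Read a gene annotation from GTF
#'
#' Imports `gene` records (or, if absent, the span of each gene's
#' transcripts) from a GTF file and converts to the package's 0-based
#' half-open convention.
#'
#' @param path GTF file path.
#' @param chromosomes data.frame (`name`, `length`); if NULL, lengths are
#'   taken as the maximum annotated end per chromosome.
#' @return A [genome_annotation()].
#' @export
read_gtf_annotation <- function(path, chromosomes = NULL) {
  gr <- rtracklayer::import(path, format = "gtf")
  if ("gene" %in% unique(as.character(gr$type))) {
    gr <- gr[gr$type == "gene"]
  } else {
    gr <- unlist(range(S4Vectors::split(gr, gr$gene_id)))
    gr$gene_id <- names(gr)
  }
  genes <- data.frame(
    gene_id = as.character(gr$gene_id),
    chrom = as.character(GenomicRanges::seqnames(gr)),
    strand = as.character(GenomicRanges::strand(gr)),
    start = GenomicRanges::start(gr) - 1L,   # GTF is 1-based closed
    end = GenomicRanges::end(gr),
    stringsAsFactors = FALSE)
  if (is.null(chromosomes)) {
    agg <- stats::aggregate(end ~ chrom, data = genes, FUN = max)
    chromosomes <- data.frame(name = agg$chrom, length = agg$end)
  }
  genome_annotation(chromosomes, genes)
}

#' Write a gene annotation as GTF
#'
#' @param annotation a [genome_annotation()].
#' @param path output path.
#' @export
write_gtf_annotation <- function(annotation, path) {
  g <- annotation$genes
  lines <- sprintf(
    '%s\tchordcomp\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
    g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  writeLines(lines, path)
  invisible(path)
}

#' Read / write BED6 peak files
#'
#' @param path file path.
#' @param peaks data.frame with columns `chrom`, `start`, `end`,
#'   `peak_id` (and optionally `score`, `strand`).
#' @return `read_peaks_bed()` returns a data.frame with columns `chrom`,
#'   `start`, `end`, `peak_id`, `score`, `strand` (0-based half-open).
#' @export
read_peaks_bed <- function(path) {
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(
    chrom = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr) - 1L,
    end = GenomicRanges::end(gr),
    peak_id = if (!is.null(gr$name)) as.character(gr$name)
              else paste0("peak", seq_along(gr)),
    score = if (!is.null(gr$score)) as.numeric(gr$score) else 0,
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
}

#' @rdname read_peaks_bed
#' @export
write_peaks_bed <- function(peaks, path) {
  score <- if ("score" %in% names(peaks)) peaks$score else 0
  strand <- if ("strand" %in% names(peaks)) peaks$strand else "."
  strand[!strand %in% c("+", "-")] <- "."
  lines <- sprintf("%s\t%d\t%d\t%s\t%g\t%s",
                   peaks$chrom, as.integer(peaks$start),
                   as.integer(peaks$end), peaks$peak_id, score, strand)
  writeLines(lines, path)
  invisible(path)
}

.midpoint <- function(peaks) as.integer(floor((peaks$start + peaks$end) / 2))

# signed distance of position x to the TSS in gene orientation:
# negative = upstream, positive = downstream
.signed_tss_dist <- function(x, tss, strand) {
  ifelse(strand == "+", x - tss, tss - x)
}

#' Classify peaks relative to gene annotation
#'
#' Each peak is assigned exactly one category by the location of its
#' midpoint, with precedence promoter > gene_body > proximal > distal:
#' promoter = within 1 kb upstream to 0.5 kb downstream of some TSS
#' (strand-aware); gene_body = within an annotated gene; proximal =
#' within 5 kb upstream of some TSS; distal = none of the above.
#'
#' @param peaks data.frame (`chrom`, `start`, `end`, `peak_id`).
#' @param annotation a [genome_annotation()].
#' @param promoter_up,promoter_down,proximal_up window sizes in bp.
#' @return the peak data.frame with a `category` factor column.
#' @export
classify_apres <- function(peaks, annotation, promoter_up = 1000,
                           promoter_down = 500, proximal_up = 5000) {
  g <- annotation$genes
  unknown <- setdiff(unique(peaks$chrom), annotation$chromosomes$name)
  if (length(unknown))
    stop("peaks on unknown chromosome(s): ", paste(unknown, collapse = ", "))
  mid <- .midpoint(peaks)
  cat <- character(nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gi <- g[g$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(gi)) { cat[i] <- "distal"; next }
    d <- .signed_tss_dist(mid[i], gi$tss, gi$strand)
    if (any(d >= -promoter_up & d <= promoter_down)) cat[i] <- "promoter"
    else if (any(mid[i] >= gi$start & mid[i] < gi$end)) cat[i] <- "gene_body"
    else if (any(d >= -proximal_up & d < -promoter_up)) cat[i] <- "proximal"
    else cat[i] <- "distal"
  }
  peaks$category <- factor(cat, levels = c("promoter", "gene_body",
                                           "proximal", "distal"))
  peaks
}

#' Distance of each peak to the closest TSS
#'
#' Unsigned distance in bp between the peak midpoint and the nearest
#' annotated TSS on the same chromosome, plus the empirical CDF over all
#' peaks with a defined distance.
#'
#' @inheritParams classify_apres
#' @return list with `distances` (data.frame `peak_id`, `distance`,
#'   `nearest_gene`; NA on gene-less chromosomes, with a warning) and
#'   `cdf` (an `ecdf` over the defined distances).
#' @export
tss_distance <- function(peaks, annotation) {
  g <- annotation$genes
  mid <- .midpoint(peaks)
  dist <- rep(NA_real_, nrow(peaks))
  nearest <- rep(NA_character_, nrow(peaks))
  for (i in seq_len(nrow(peaks))) {
    gi <- g[g$chrom == peaks$chrom[i], , drop = FALSE]
    if (!nrow(gi)) next
    dd <- abs(mid[i] - gi$tss)
    j <- which.min(dd)
    dist[i] <- dd[j]; nearest[i] <- gi$gene_id[j]
  }
  if (anyNA(dist)) warning(sum(is.na(dist)),
                           " peak(s) on gene-less chromosomes: distance NA")
  list(distances = data.frame(peak_id = peaks$peak_id, distance = dist,
                              nearest_gene = nearest,
                              stringsAsFactors = FALSE),
       cdf = stats::ecdf(dist[!is.na(dist)]))
}

#' GREAT-style regulatory domains
#'
#' Every gene gets a basal region (default TSS - 5 kb to TSS + 1 kb,
#' strand-aware; basal regions may overlap) and an extended region: each
#' side grows outward from the basal edge until the nearest other gene's
#' basal-region boundary, the TSS +/- `max_ext` cap, or the chromosome
#' end, whichever comes first. The basal region is always contained in
#' the extended region, even when it overlaps a neighbouring domain.
#'
#' @param annotation a [genome_annotation()].
#' @param basal_up,basal_down basal window in bp up/downstream of the TSS.
#' @param max_ext maximum extension cap, measured from the TSS (default
#'   1 Mb).
#' @return data.frame with one row per gene: `gene_id`, `chrom`,
#'   `basal_start`, `basal_end`, `ext_start`, `ext_end` (0-based
#'   half-open).
#' @export
great_domains <- function(annotation, basal_up = 5000, basal_down = 1000,
                          max_ext = 1e6) {
  g <- annotation$genes
  cl <- stats::setNames(annotation$chromosomes$length,
                        annotation$chromosomes$name)
  plus <- g$strand == "+"
  basal_start <- ifelse(plus, g$tss - basal_up, g$tss - basal_down + 1L)
  basal_end <- ifelse(plus, g$tss + basal_down, g$tss + basal_up + 1L)
  basal_start <- pmax(0L, as.integer(basal_start))
  basal_end <- pmin(as.integer(cl[g$chrom]), as.integer(basal_end))
  ext_start <- ext_end <- integer(nrow(g))
  for (i in seq_len(nrow(g))) {
    same <- which(g$chrom == g$chrom[i])
    same <- setdiff(same, i)
    # left: furthest-right foreign basal edge not beyond our basal start
    left_blocks <- pmin(basal_end[same][basal_start[same] < basal_start[i]],
                        basal_start[i])
    left_stop <- max(0, left_blocks, g$tss[i] - max_ext)
    # right: furthest-left foreign basal edge not before our basal end
    right_blocks <- pmax(basal_start[same][basal_end[same] > basal_end[i]],
                         basal_end[i])
    right_stop <- min(cl[g$chrom[i]], right_blocks, g$tss[i] + max_ext)
    ext_start[i] <- min(basal_start[i], left_stop)
    ext_end[i] <- max(basal_end[i], right_stop)
  }
  data.frame(gene_id = g$gene_id, chrom = g$chrom,
             basal_start = basal_start, basal_end = basal_end,
             ext_start = as.integer(ext_start), ext_end = as.integer(ext_end),
             stringsAsFactors = FALSE)
}

#' Count peaks in each gene's regulatory landscape
#'
#' A peak counts for every gene whose extended GREAT domain contains its
#' midpoint (multi-assignment allowed where domains overlap).
#'
#' @param domains output of [great_domains()].
#' @param peaks data.frame (`chrom`, `start`, `end`, `peak_id`).
#' @return named integer vector of per-gene counts (0 for genes with no
#'   peaks).
#' @export
count_apres_per_gene <- function(domains, peaks) {
  counts <- stats::setNames(integer(nrow(domains)), domains$gene_id)
  if (!nrow(peaks)) return(counts)
  mid <- .midpoint(peaks)
  dgr <- GenomicRanges::GRanges(domains$chrom,
    IRanges::IRanges(domains$ext_start + 1L, domains$ext_end))
  pgr <- GenomicRanges::GRanges(peaks$chrom, IRanges::IRanges(mid + 1L, mid + 1L))
  ov <- GenomicRanges::findOverlaps(pgr, dgr)
  tab <- table(S4Vectors::subjectHits(ov))
  counts[as.integer(names(tab))] <- as.integer(tab)
  counts
}

#' Size-stratified matching of two gene sets
#'
#' Bins region sizes into fixed bins of width `bin_bp`; within each bin
#' populated by both sets, both are down-sampled without replacement to
#' the smaller count. Mirrors size-matched comparisons of regulatory
#' landscapes between species.
#'
#' @param sizesA,sizesB named numeric vectors of per-gene region sizes.
#' @param bin_bp bin width in bp (default 500).
#' @param seed integer seed for the down-sampling.
#' @return list with `A`, `B` (names of retained genes) and `bins`
#'   (per-bin bookkeeping: bin, nA, nB, kept).
#' @export
stratified_match <- function(sizesA, sizesB, bin_bp = 500, seed = 1) {
  if (!length(sizesA) || !length(sizesB)) stop("both size sets must be non-empty")
  if (is.null(names(sizesA))) names(sizesA) <- paste0("A", seq_along(sizesA))
  if (is.null(names(sizesB))) names(sizesB) <- paste0("B", seq_along(sizesB))
  binA <- floor(sizesA / bin_bp)
  binB <- floor(sizesB / bin_bp)
  shared <- intersect(unique(binA), unique(binB))
  if (!length(shared)) stop("no populated shared size bin")
  keepA <- character(0); keepB <- character(0); book <- list()
  with_seed(sub_seed(seed, "stratified_match"), {
    for (b in sort(shared)) {
      ga <- names(sizesA)[binA == b]
      gb <- names(sizesB)[binB == b]
      k <- min(length(ga), length(gb))
      keepA <- c(keepA, if (length(ga) > k) sample(ga, k) else ga)
      keepB <- c(keepB, if (length(gb) > k) sample(gb, k) else gb)
      book[[length(book) + 1L]] <- data.frame(bin = b, nA = length(ga),
                                               nB = length(gb), kept = k)
    }
  })
  list(A = keepA, B = keepB, bins = do.call(rbind, book))
}

#' Per-family minimum and maximum peak counts
#'
#' For each ohnologue family, the lowest and highest per-member peak
#' count; used to contrast the most and least regulatorily complex family
#' members between species (one-sided Mann-Whitney tests on the
#' resulting distributions).
#'
#' @param counts named per-gene counts (e.g. [count_apres_per_gene()]).
#' @param fams a [family_set()].
#' @param species which species' members to use (default: all genes with
#'   counts).
#' @return data.frame `family_id`, `min`, `max`, `n_members`; families
#'   with members missing from `counts` are skipped with a warning.
#' @export
family_min_max_counts <- function(counts, fams, species = NULL) {
  rows <- list(); skipped <- 0L
  for (fid in names(fams$families)) {
    f <- fams$families[[fid]]
    genes <- if (is.null(species)) unlist(f, use.names = FALSE)
             else unlist(f[species], use.names = FALSE)
    if (!length(genes)) next
    if (!all(genes %in% names(counts))) { skipped <- skipped + 1L; next }
    v <- counts[genes]
    rows[[fid]] <- data.frame(family_id = fid, min = min(v), max = max(v),
                              n_members = length(v), stringsAsFactors = FALSE)
  }
  if (skipped) warning(skipped, " family(ies) skipped: missing member counts")
  rbind_rows(rows)
}

#' Detect head-to-head (bidirectional-promoter) gene pairs
#'
#' Adjacent genes on opposite strands in divergent orientation (the
#' minus-strand gene upstream of the plus-strand gene, TSSs facing away
#' from each other) with TSS separation at most `max_sep_bp`. Also
#' returns the TSS-separation values for periodicity inspection. The
#' default threshold is a package choice, not a published value.
#'
#' @param annotation a [genome_annotation()].
#' @param max_sep_bp maximum TSS separation in bp (default 1000).
#' @return list with `pairs` (data.frame `gene_minus`, `gene_plus`,
#'   `separation`) and `separations` (numeric, all divergent adjacent
#'   pairs regardless of threshold).
#' @export
bidirectional_pairs <- function(annotation, max_sep_bp = 1000) {
  g <- annotation$genes
  rows <- list(); seps <- numeric(0)
  for (chrom in unique(g$chrom)) {
    gi <- g[g$chrom == chrom, , drop = FALSE]
    gi <- gi[order(gi$tss, gi$gene_id), , drop = FALSE]
    if (nrow(gi) < 2) next
    for (i in seq_len(nrow(gi) - 1)) {
      a <- gi[i, ]; b <- gi[i + 1, ]
      if (a$strand == "-" && b$strand == "+") {  # divergent: <-- -->
        sep <- b$tss - a$tss
        seps <- c(seps, sep)
        if (sep <= max_sep_bp)
          rows[[length(rows) + 1L]] <- data.frame(
            gene_minus = a$gene_id, gene_plus = b$gene_id,
            separation = sep, stringsAsFactors = FALSE)
      }
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs))
    pairs <- data.frame(gene_minus = character(0), gene_plus = character(0),
                        separation = numeric(0))
  list(pairs = pairs, separations = seps)
}

#' Mean per-base conservation score over peaks
#'
#' Arithmetic mean of per-base scores (e.g. phastCons) within each peak.
#' Bases not covered by the score track are excluded from the mean by
#' default (`missing_as_zero = TRUE` counts them as 0). Peaks entirely
#' uncovered yield NA with a warning.
#'
#' @param peaks data.frame (`chrom`, `start`, `end`, `peak_id`).
#' @param scores bedGraph-like data.frame (`chrom`, `start`, `end`,
#'   `score`), 0-based half-open, non-overlapping intervals.
#' @param groups optional named list: group -> peak ids, for per-group
#'   summaries (mean and interquartile range).
#' @param missing_as_zero treat uncovered bases as score 0.
#' @return list with `peak_means` (data.frame `peak_id`, `mean_score`,
#'   `covered_bp`) and, when `groups` given, `group_summary`.
#' @export
mean_conservation <- function(peaks, scores, groups = NULL,
                              missing_as_zero = FALSE) {
  pgr <- GenomicRanges::GRanges(peaks$chrom,
    IRanges::IRanges(peaks$start + 1L, peaks$end))
  sgr <- GenomicRanges::GRanges(scores$chrom,
    IRanges::IRanges(scores$start + 1L, scores$end), score = scores$score)
  ov <- GenomicRanges::findOverlaps(pgr, sgr)
  wsum <- numeric(nrow(peaks)); wlen <- numeric(nrow(peaks))
  if (length(ov)) {
    qh <- S4Vectors::queryHits(ov); sh <- S4Vectors::subjectHits(ov)
    w <- GenomicRanges::width(GenomicRanges::pintersect(pgr[qh], sgr[sh]))
    agg_sum <- rowsum(w * sgr$score[sh], qh)
    agg_len <- rowsum(w, qh)
    idx <- as.integer(rownames(agg_sum))
    wsum[idx] <- agg_sum[, 1]; wlen[idx] <- agg_len[, 1]
  }
  width <- peaks$end - peaks$start
  mean_score <- if (missing_as_zero) wsum / width
                else ifelse(wlen > 0, wsum / wlen, NA_real_)
  if (any(wlen == 0))
    warning(sum(wlen == 0), " peak(s) entirely uncovered by the score track")
  pm <- data.frame(peak_id = peaks$peak_id, mean_score = mean_score,
                   covered_bp = wlen, stringsAsFactors = FALSE)
  out <- list(peak_means = pm)
  if (!is.null(groups)) {
    out$group_summary <- do.call(rbind, lapply(names(groups), function(gname) {
      v <- pm$mean_score[pm$peak_id %in% groups[[gname]]]
      v <- v[!is.na(v)]
      data.frame(group = gname, n = length(v), mean = mean(v),
                 q25 = unname(stats::quantile(v, 0.25)),
                 q75 = unname(stats::quantile(v, 0.75)),
                 stringsAsFactors = FALSE)
    }))
  }
  out
}
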