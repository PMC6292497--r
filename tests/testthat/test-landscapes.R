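toy_annotation <- function() {
  genome_annotation(
    data.frame(name = c("chr1", "chr2"), length = c(1e6, 5e5)),
    data.frame(gene_id = c("gA", "gB", "gC"),
               chrom = c("chr1", "chr1", "chr2"),
               strand = c("+", "-", "+"),
               start = c(100000, 200000, 50000),
               end = c(110000, 210000, 60000)))
}

test_that("classify_apres follows the window definitions and precedence", {
  ann <- toy_annotation()  # gA TSS 100000 (+), gB TSS 209999 (-)
  peaks <- data.frame(
    chrom = "chr1",
    start = c(99600, 150000 - 100, 96900, 400000, 209999 + 2900),
    end = c(99800, 150000 + 100, 97100, 400200, 209999 + 3100),
    peak_id = paste0("p", 1:5))
  got <- classify_apres(peaks, ann)
  # midpoints: 300 bp upstream of gA TSS; inside gB gene body via chr1
  # 150100? no: 150000 is intergenic -> distal; 3.1 kb upstream of gA;
  # far from everything; 3 kb upstream of gB (upstream = higher coord)
  expect_equal(as.character(got$category),
               c("promoter", "distal", "proximal", "distal", "proximal"))
  inside <- data.frame(chrom = "chr1", start = 204950, end = 205050,
                       peak_id = "pg")   # 5 kb inside gB, 50 kb window ok
  expect_equal(as.character(classify_apres(inside, ann)$category),
               "gene_body")
  # categories partition the peak set
  expect_equal(sum(table(got$category)), nrow(peaks))
  expect_error(classify_apres(data.frame(chrom = "chrX", start = 1, end = 2,
                                         peak_id = "z"), ann),
               "chrX")
})

test_that("tss_distance equals the all-pairs minimum", {
  ann <- toy_annotation()
  set.seed(6)
  peaks <- data.frame(chrom = sample(c("chr1", "chr2"), 40, replace = TRUE),
                      start = sample.int(4e5, 40))
  peaks$end <- peaks$start + 200
  peaks$peak_id <- paste0("p", 1:40)
  res <- tss_distance(peaks, ann)
  g <- ann$genes
  for (i in 1:40) {
    mid <- floor((peaks$start[i] + peaks$end[i]) / 2)
    tsss <- g$tss[g$chrom == peaks$chrom[i]]
    expect_equal(res$distances$distance[i], min(abs(mid - tsss)))
  }
  # peak centred on a TSS -> 0
  z <- tss_distance(data.frame(chrom = "chr1", start = 99900, end = 100100,
                               peak_id = "z"), ann)
  expect_equal(z$distances$distance, 0)
  # CDF steps at the observed distances
  two <- tss_distance(data.frame(chrom = "chr2",
                                 start = c(50090, 50290),
                                 end = c(50110, 50310),
                                 peak_id = c("q1", "q2")), ann)
  expect_equal(two$cdf(c(99, 100, 299, 300)), c(0, 0.5, 0.5, 1))
})

test_that("great_domains matches the stated windows and stops", {
  # lone + gene, TSS 2,000,000 on a 10 Mb chromosome: extension capped at
  # TSS +/- 1 Mb, basal always included
  lone <- genome_annotation(
    data.frame(name = "chr1", length = 1e7),
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 2000000, end = 2005000))
  d <- great_domains(lone)
  expect_equal(c(d$basal_start, d$basal_end), c(1995000, 2001000))
  expect_equal(c(d$ext_start, d$ext_end), c(1000000, 3000000))
  # two + genes: extension stops at the neighbour's basal boundary
  two <- genome_annotation(
    data.frame(name = "chr1", length = 1e7),
    data.frame(gene_id = c("g1", "g2"), chrom = "chr1",
               strand = c("+", "+"),
               start = c(100000, 200000), end = c(101000, 201000)))
  d2 <- great_domains(two)
  expect_equal(d2$ext_end[1], 195000)   # g2 basal start
  expect_equal(d2$ext_start[2], 101000) # g1 basal end
  # TSS 1,000 from the chromosome start: left side clipped at 0
  edge <- genome_annotation(
    data.frame(name = "chr1", length = 1e5),
    data.frame(gene_id = "g1", chrom = "chr1", strand = "+",
               start = 1000, end = 3000))
  d3 <- great_domains(edge)
  expect_equal(d3$basal_start, 0)
  expect_equal(d3$ext_start, 0)
})

test_that("great_domains equals the per-base oracle on random genomes", {
  set.seed(77)
  for (case in 1:100) {
    L <- 30000
    n <- sample(2:5, 1)
    tss <- sort(sample(seq(2000, L - 2000), n))
    strand <- sample(c("+", "-"), n, replace = TRUE)
    glen <- sample(200:800, n, replace = TRUE)
    genes <- data.frame(
      gene_id = paste0("g", seq_len(n)), chrom = "c1", strand = strand,
      start = ifelse(strand == "+", tss, tss - glen + 1),
      end = ifelse(strand == "+", tss + glen, tss + 1))
    ann <- genome_annotation(data.frame(name = "c1", length = L), genes)
    got <- great_domains(ann, basal_up = 1000, basal_down = 300,
                         max_ext = 3000)
    want <- oracle_great(ann, basal_up = 1000, basal_down = 300,
                         max_ext = 3000)
    expect_equal(got$basal_start, want$basal_start)
    expect_equal(got$basal_end, want$basal_end)
    expect_equal(got$ext_start, want$ext_start)
    expect_equal(got$ext_end, want$ext_end)
  }
})

test_that("count_apres_per_gene matches the quadratic brute force", {
  set.seed(15)
  for (case in 1:20) {
    gp <- generate_genome_with_peaks(
      synthetic_config(seed = case, genome_length = 1.5e6),
      n_genes = 20, background_rate = 2)
    dom <- great_domains(gp$annotation)
    cnt <- count_apres_per_gene(dom, gp$peaksA)
    expect_equal(sum(cnt), oracle_count_incidences(dom, gp$peaksA))
  }
  # no peaks -> all zero
  gp <- generate_genome_with_peaks(synthetic_config(seed = 1),
                                   n_genes = 10)
  empty <- gp$peaksA[0, ]
  expect_equal(unname(count_apres_per_gene(great_domains(gp$annotation),
                                           empty)),
               rep(0L, 10))
  # a peak in the overlap of two domains counts for both
  two <- genome_annotation(
    data.frame(name = "c1", length = 1e6),
    data.frame(gene_id = c("g1", "g2"), chrom = "c1", strand = "+",
               start = c(100000, 200000), end = c(101000, 201000)))
  dom2 <- great_domains(two)
  pk <- data.frame(chrom = "c1", start = 150000, end = 150200,
                   peak_id = "shared")
  expect_equal(unname(count_apres_per_gene(dom2, pk)), c(1L, 1L))
})

test_that("planted peak landscapes are recovered exactly", {
  gp <- generate_genome_with_peaks(
    synthetic_config(seed = 5, genome_length = 2e6,
                     peak_density_per_gene = c(A = 3, B = 8)),
    n_genes = 40, fixed_counts = TRUE)
  dom <- great_domains(gp$annotation)
  expect_equal(unname(count_apres_per_gene(dom, gp$peaksA)),
               rep(3L, 40))
  expect_equal(unname(count_apres_per_gene(dom, gp$peaksB)),
               rep(8L, 40))
})

test_that("stratified_match keeps per-bin counts equal", {
  sA <- stats::setNames(c(100, 120, 130, 700, 1200), paste0("a", 1:5))
  sB <- stats::setNames(c(110, 720, 730, 1100, 2400), paste0("b", 1:5))
  m <- stratified_match(sA, sB, bin_bp = 500, seed = 2)
  expect_equal(m$bins$kept, pmin(m$bins$nA, m$bins$nB))
  # bin 0: 3 A vs 1 B -> 1 kept each; bin 1: 1 vs 2 -> 1; bin 2: 1 vs 1
  expect_equal(m$bins$kept, c(1, 1, 1))
  expect_length(m$A, 3); expect_length(m$B, 3)
  # identical multisets are fully retained
  full <- stratified_match(sA, sA, bin_bp = 500)
  expect_setequal(full$A, names(sA))
  expect_error(stratified_match(sA, sB + 1e6), "shared size bin")
  # matched subsets' bin counts equal exactly for random inputs
  set.seed(3)
  r <- stratified_match(runif(200, 0, 5000), runif(150, 0, 5000))
  expect_equal(r$bins$kept, pmin(r$bins$nA, r$bins$nB))
})

test_that("family_min_max_counts summarizes per family", {
  fams <- family_set(data.frame(
    family_id = c("f1", "f1", "f1", "f2"),
    species = c("v", "v", "v", "v"),
    gene_id = c("x1", "x2", "x3", "y1")))
  counts <- c(x1 = 2, x2 = 7, x3 = 11, y1 = 4)
  r <- family_min_max_counts(counts, fams)
  expect_equal(r$min[r$family_id == "f1"], 2)
  expect_equal(r$max[r$family_id == "f1"], 11)
  expect_equal(r$min[r$family_id == "f2"], r$max[r$family_id == "f2"])
  expect_warning(family_min_max_counts(counts[1:2], fams), "skipped")
})

test_that("bidirectional_pairs detects only divergent head-to-head pairs", {
  ann <- genome_annotation(
    data.frame(name = "c1", length = 1e6),
    data.frame(gene_id = c("m1", "p1",   # divergent, 300 bp apart
                           "t1", "t2",   # tandem + strand
                           "c1g", "c2g"),# convergent
               chrom = "c1",
               strand = c("-", "+", "+", "+", "+", "-"),
               start = c(9000, 10300, 50000, 55000, 100000, 103000),
               end = c(10001, 11300, 51000, 56000, 101000, 104000)))
  r <- bidirectional_pairs(ann, max_sep_bp = 1000)
  expect_equal(nrow(r$pairs), 1)
  expect_equal(r$pairs$gene_minus, "m1")
  expect_equal(r$pairs$gene_plus, "p1")
  expect_equal(r$pairs$separation, 300)
  # over-threshold divergent pairs appear in the histogram only
  r2 <- bidirectional_pairs(ann, max_sep_bp = 100)
  expect_equal(nrow(r2$pairs), 0)
  expect_true(300 %in% r2$separations)
})

test_that("mean_conservation averages per-base scores correctly", {
  peaks <- data.frame(chrom = "c1", start = c(100, 300), end = c(200, 400),
                      peak_id = c("p1", "p2"))
  # constant 0.5 track
  const <- data.frame(chrom = "c1", start = 0, end = 1000, score = 0.5)
  expect_equal(mean_conservation(peaks, const)$peak_means$mean_score,
               c(0.5, 0.5))
  # half 0 / half 1 within a peak
  half <- data.frame(chrom = "c1", start = c(100, 150), end = c(150, 200),
                     score = c(0, 1))
  expect_warning(r <- mean_conservation(peaks, half), "uncovered")
  expect_equal(r$peak_means$mean_score[1], 0.5)
  expect_true(is.na(r$peak_means$mean_score[2]))
  # random track equals the brute-force per-base average
  set.seed(19)
  breaks <- sort(sample(100:200, 6))
  track <- data.frame(chrom = "c1", start = c(90, breaks),
                      end = c(breaks, 210),
                      score = round(runif(7), 3))
  got <- mean_conservation(peaks[1, ], track)$peak_means$mean_score
  base_scores <- numeric(0)
  for (x in 100:199) {
    row <- which(track$start <= x & x < track$end)
    base_scores <- c(base_scores, track$score[row])
  }
  expect_equal(got, mean(base_scores))
  # missing-as-zero flag (uncovered-peak warning still raised)
  mz <- suppressWarnings(mean_conservation(peaks, half,
                                           missing_as_zero = TRUE))
  expect_equal(mz$peak_means$mean_score[2], 0)
})
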