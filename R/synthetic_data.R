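# Synthetic-data generators with recorded ground truth. Every analysis
# stage in the package can be exercised on these outputs without any
# external download: a paired two-species developmental expression series
# with a planted divergence minimum, ohnologue families with planted
# post-WGD fates, toy genomes with planted peak landscapes of unequal
# density, bimodally methylated regions, and motif-enriched sequences.
# One master seed spawns an independent named sub-stream per generator.

#' Synthetic-data configuration
#'
#' Bundles and validates the knobs shared by the generators. Defaults
#' describe the "stated world" the bundled tests run in: 2,000 1-to-1
#' orthologues, 200 ohnologue families with 2-4 vertebrate copies, seven
#' developmental stages whose inter-species noise scale has a unique
#' minimum mid-series (the planted phylotypic stage), nine homologous
#' expression domains, a specialization-heavy fate mix, and two
#' well-separated methylation modes.
#'
#' @param seed master integer seed.
#' @param n_genes_1to1 number of 1-to-1 orthologue pairs.
#' @param n_ohno_families number of ohnologue families.
#' @param ohno_copy_distribution probabilities over 2, 3 and 4 vertebrate
#'   copies (sums to 1).
#' @param n_stages number of developmental stages (>= 3).
#' @param divergence_profile per-stage log-normal noise scales (sdlog) of
#'   the inter-species expression divergence; length `n_stages`.
#' @param n_domains number of homologous expression domains (default 9).
#' @param fate_mix probabilities over the fates redundancy,
#'   subfunctionalization, specialization (sums to 1).
#' @param expression_noise_sd sdlog of multiplicative log-normal
#'   expression noise in the fate generator (0 = noise-free).
#' @param genome_length toy chromosome length in bp.
#' @param peak_density_per_gene mean planted peaks per gene for species A
#'   and B (B higher, emulating the vertebrate regulatory expansion).
#' @param methylation_modes the two planted region methylation means
#'   (low, high), separated by >= 0.3.
#' @param binarize_threshold expression on/off threshold (default 5).
#' @return A validated `synthetic_config` list.
#' @export
synthetic_config <- function(seed = 1,
                             n_genes_1to1 = 2000,
                             n_ohno_families = 200,
                             ohno_copy_distribution = c(`2` = 0.5, `3` = 0.3,
                                                        `4` = 0.2),
                             n_stages = 7,
                             divergence_profile = c(0.8, 0.6, 0.4, 0.2,
                                                    0.4, 0.6, 0.8),
                             n_domains = 9,
                             fate_mix = c(redundancy = 0.15,
                                          subfunctionalization = 0.35,
                                          specialization = 0.50),
                             expression_noise_sd = 0,
                             genome_length = 2e6,
                             peak_density_per_gene = c(A = 3, B = 8),
                             methylation_modes = c(low = 0.1, high = 0.9),
                             binarize_threshold = 5) {
  .check_prob(ohno_copy_distribution, "ohno_copy_distribution")
  .check_prob(fate_mix, "fate_mix")
  stopifnot(n_domains >= 2, n_stages >= 1, expression_noise_sd >= 0,
            length(divergence_profile) == n_stages,
            length(methylation_modes) == 2,
            length(peak_density_per_gene) == 2)
  structure(list(seed = seed, n_genes_1to1 = n_genes_1to1,
                 n_ohno_families = n_ohno_families,
                 ohno_copy_distribution = ohno_copy_distribution,
                 n_stages = n_stages, divergence_profile = divergence_profile,
                 n_domains = n_domains, fate_mix = fate_mix,
                 expression_noise_sd = expression_noise_sd,
                 genome_length = genome_length,
                 peak_density_per_gene = peak_density_per_gene,
                 methylation_modes = methylation_modes,
                 binarize_threshold = binarize_threshold),
            class = "synthetic_config")
}

#' Paired two-species developmental expression series
#'
#' Species A gets a log-normal baseline per gene with a mild independent
#' stage effect; species B expression at the homologous stage is the
#' species-A expression times multiplicative log-normal noise whose
#' scale follows `divergence_profile`. The planted stage of minimal
#' divergence is the profile's argmin, and the downstream
#' Jensen-Shannon divergence matrix has its row minima there.
#'
#' @param config a [synthetic_config()]. If a unique minimum is required
#'   (`require_minimum = TRUE`, the default), a flat profile is rejected.
#' @param require_minimum demand a unique strict minimum in the profile.
#' @param stage_effect_sd sdlog of the per-gene per-stage effect in
#'   species A (default 0.1, small against the divergence profile).
#' @return list with `exprA`, `exprB` ([expression_matrix()]s), `pairs`
#'   (geneA/geneB data.frame) and `truth` (planted `min_stage`, profile,
#'   per-stage divergence rank).
#' @export
generate_hourglass_series <- function(config = synthetic_config(),
                                      require_minimum = TRUE,
                                      stage_effect_sd = 0.1) {
  prof <- config$divergence_profile
  if (config$n_stages < 3) stop("need at least 3 stages")
  if (require_minimum) {
    mn <- which(prof == min(prof))
    if (length(mn) != 1)
      stop("divergence_profile has no unique strict minimum; ",
           "supply a profile with exactly one (planted phylotypic stage)")
  }
  n <- config$n_genes_1to1
  genesA <- sprintf("blaG%05d", seq_len(n))
  genesB <- sprintf("dreG%05d", seq_len(n))
  stages <- sprintf("stage%02d", seq_len(config$n_stages))
  out <- with_seed(sub_seed(config$seed, "hourglass"), {
    base <- stats::rlnorm(n, meanlog = 3, sdlog = 1.2)
    A <- base * matrix(stats::rlnorm(n * config$n_stages, 0, stage_effect_sd),
                       n, config$n_stages)
    noise <- matrix(stats::rlnorm(n * config$n_stages, 0,
                                  rep(prof, each = n)), n, config$n_stages)
    list(A = A, B = A * noise)
  })
  dimnames(out$A) <- list(genesA, stages)
  dimnames(out$B) <- list(genesB, stages)
  list(exprA = expression_matrix(out$A, "TPM"),
       exprB = expression_matrix(out$B, "TPM"),
       pairs = data.frame(geneA = genesA, geneB = genesB,
                          stringsAsFactors = FALSE),
       truth = list(min_stage = which.min(prof), profile = prof,
                    divergence_rank = rank(prof, ties.method = "min")))
}

# draw an on/off pattern realisation as continuous expression:
# on = threshold*4, off = threshold*0.1 (unambiguous at zero noise)
.realize_pattern <- function(pattern, thr, noise_sd) {
  v <- ifelse(pattern == 1, thr * 4, thr * 0.1)
  if (noise_sd > 0) v <- v * stats::rlnorm(length(v), 0, noise_sd)
  v
}

#' Ohnologue families with planted post-WGD expression fates
#'
#' Each family has one outgroup gene "on" in all domains and 2-4
#' vertebrate copies whose on/off patterns realise the planted fate:
#' redundancy (all copies on everywhere), subfunctionalization (no copy
#' on everywhere, union covers all domains) or specialization (at least
#' one copy on everywhere and at least one restricted). Additionally,
#' `n_genes_1to1` single-copy families are emitted in which both species
#' share the full-on pattern (the symmetric bias control). Continuous
#' values are on = 4x threshold, off = 0.1x threshold, times log-normal
#' noise of scale `expression_noise_sd`, so binarization at the
#' configured threshold reproduces the planted patterns exactly at zero
#' noise.
#'
#' @param config a [synthetic_config()].
#' @param n_1to1 number of single-copy control families (default
#'   `min(500, config$n_genes_1to1)` to keep the bundle small).
#' @return list with `fams` ([family_set()], species "outgroup" and
#'   "vertebrate"), `exprA`, `exprB` (continuous genes x domains
#'   matrices), `truth` (per-family planted fate, per-member planted
#'   pattern matrix), and `threshold`.
#' @export
generate_fate_families <- function(config = synthetic_config(),
                                   n_1to1 = min(500, config$n_genes_1to1)) {
  nd <- config$n_domains
  thr <- config$binarize_threshold
  doms <- sprintf("domain%01d", seq_len(nd))
  fate_names <- c("redundancy", "subfunctionalization", "specialization")
  with_seed(sub_seed(config$seed, "fates"), {
    n_fam <- config$n_ohno_families
    copies <- sample(as.integer(names(config$ohno_copy_distribution)),
                     n_fam, replace = TRUE,
                     prob = config$ohno_copy_distribution)
    if (any(copies < 2)) stop("fate requested for a 1-copy family")
    fates <- sample(fate_names, n_fam, replace = TRUE,
                    prob = config$fate_mix[fate_names])
    fam_rows <- list(); Arows <- list(); Brows <- list()
    truth_fate <- character(n_fam); patt <- list()
    for (i in seq_len(n_fam)) {
      fid <- sprintf("fam%04d", i)
      k <- copies[i]
      ga <- sprintf("%s_out", fid)
      gb <- sprintf("%s_vrt%d", fid, seq_len(k))
      P <- matrix(0L, k, nd, dimnames = list(gb, doms))
      if (fates[i] == "redundancy") {
        P[] <- 1L
      } else if (fates[i] == "subfunctionalization") {
        # each domain owned by one copy; each copy gets >= 1 domain and
        # (k >= 2 so no copy can own all domains) union covers all
        owner <- integer(nd)
        owner[sample(nd, k)] <- seq_len(k)
        rest <- which(owner == 0)
        owner[rest] <- sample(k, length(rest), replace = TRUE)
        for (j in seq_len(k)) P[j, owner == j] <- 1L
      } else {
        P[1, ] <- 1L   # one copy keeps the full ancestral breadth
        for (j in 2:k) {
          r <- sample(nd - 1, 1)   # retain 1..nd-1 domains: restricted
          P[j, sample(nd, r)] <- 1L
        }
      }
      truth_fate[i] <- fates[i]
      patt[[fid]] <- P
      fam_rows[[i]] <- data.frame(
        family_id = fid,
        species = c("outgroup", rep("vertebrate", k)),
        gene_id = c(ga, gb), stringsAsFactors = FALSE)
      Arows[[ga]] <- .realize_pattern(rep(1L, nd), thr,
                                      config$expression_noise_sd)
      for (j in seq_len(k))
        Brows[[gb[j]]] <- .realize_pattern(P[j, ], thr,
                                           config$expression_noise_sd)
    }
    # symmetric single-copy control families (full-on in both species)
    for (i in seq_len(n_1to1)) {
      fid <- sprintf("sc%05d", i)
      ga <- sprintf("%s_out", fid); gb <- sprintf("%s_vrt", fid)
      fam_rows[[n_fam + i]] <- data.frame(
        family_id = fid, species = c("outgroup", "vertebrate"),
        gene_id = c(ga, gb), stringsAsFactors = FALSE)
      Arows[[ga]] <- .realize_pattern(rep(1L, nd), thr,
                                      config$expression_noise_sd)
      Brows[[gb]] <- .realize_pattern(rep(1L, nd), thr,
                                      config$expression_noise_sd)
    }
    exprA <- do.call(rbind, Arows); colnames(exprA) <- doms
    exprB <- do.call(rbind, Brows); colnames(exprB) <- doms
    list(fams = family_set(do.call(rbind, fam_rows)),
         exprA = expression_matrix(exprA, "cRPKM"),
         exprB = expression_matrix(exprB, "cRPKM"),
         truth = list(fate = stats::setNames(truth_fate,
                                             sprintf("fam%04d",
                                                     seq_len(n_fam))),
                      patterns = patt),
         threshold = thr)
  })
}

#' Toy genomes with planted peak landscapes
#'
#' Places `n_genes` non-overlapping genes on one synthetic chromosome
#' shared by both species, then plants peaks near each gene's TSS with
#' species-specific mean counts (species B denser), plus optional
#' unassigned background peaks. Planted peaks are placed inside the
#' gene's own basal window (within +/-900 bp of the TSS): neighbouring
#' GREAT extensions stop at the basal boundary, so the basal region is
#' the only territory owned by exactly one gene, and per-gene counting
#' recovers the planted counts exactly when background peaks are
#' disabled.
#'
#' @param config a [synthetic_config()].
#' @param n_genes number of genes (default 50).
#' @param fixed_counts use exactly the configured per-gene means as
#'   counts (default FALSE: Poisson-distributed).
#' @param background_rate expected number of background peaks per gene
#'   (default 0).
#' @param gene_spacing_bp distance between consecutive TSSs (default
#'   derived from genome_length; placement is rejected if the genome is
#'   too short).
#' @return list with `annotation` ([genome_annotation()]), `peaksA`,
#'   `peaksB` (BED-like data.frames), and `truth` (per-gene planted peak
#'   counts per species, background peak ids).
#' @export
generate_genome_with_peaks <- function(config = synthetic_config(),
                                       n_genes = 50, fixed_counts = FALSE,
                                       background_rate = 0,
                                       gene_spacing_bp = NULL) {
  L <- config$genome_length
  if (is.null(gene_spacing_bp))
    gene_spacing_bp <- floor(L / (n_genes + 1))
  gene_len <- 2000
  margin <- 900   # peaks placed within +/- margin of the TSS (in basal)
  if (gene_spacing_bp < gene_len + 2 * margin + 2000) {
    placeable <- max(0, floor(L / (gene_len + 2 * margin + 2000)) - 1)
    stop(sprintf(paste0("genome too short to place %d genes without ",
                        "overlap at this density (roughly %d placeable)"),
                 n_genes, placeable))
  }
  with_seed(sub_seed(config$seed, "genome"), {
    tss <- as.integer(seq_len(n_genes) * gene_spacing_bp)
    strand <- sample(c("+", "-"), n_genes, replace = TRUE)
    start <- ifelse(strand == "+", tss, tss - gene_len + 1L)
    end <- ifelse(strand == "+", tss + gene_len, tss + 1L)
    genes <- data.frame(gene_id = sprintf("g%03d", seq_len(n_genes)),
                        chrom = "chrS", strand = strand,
                        start = as.integer(start), end = as.integer(end),
                        stringsAsFactors = FALSE)
    ann <- genome_annotation(data.frame(name = "chrS", length = L), genes)
    make_peaks <- function(mean_count, prefix) {
      counts <- if (fixed_counts) rep(as.integer(round(mean_count)), n_genes)
                else stats::rpois(n_genes, mean_count)
      rows <- list()
      for (i in seq_len(n_genes)) {
        if (!counts[i]) next
        mid <- tss[i] + sample(seq(-margin, margin), counts[i])
        w <- sample(100:400, counts[i], replace = TRUE)
        rows[[i]] <- data.frame(
          chrom = "chrS",
          start = pmax(0L, as.integer(mid - floor(w / 2))),
          end = as.integer(mid + ceiling(w / 2)),
          peak_id = sprintf("%s_g%03d_p%d", prefix, i, seq_len(counts[i])),
          stringsAsFactors = FALSE)
      }
      n_bg <- stats::rpois(1, background_rate * n_genes)
      bg <- NULL
      if (n_bg > 0) {
        mid <- sample.int(L - 1000, n_bg)
        bg <- data.frame(chrom = "chrS", start = as.integer(mid),
                         end = as.integer(mid + 200),
                         peak_id = sprintf("%s_bg_p%d", prefix,
                                           seq_len(n_bg)),
                         stringsAsFactors = FALSE)
      }
      pk <- do.call(rbind, c(rows, list(bg)))
      if (is.null(pk))
        pk <- data.frame(chrom = character(0), start = integer(0),
                         end = integer(0), peak_id = character(0))
      list(peaks = pk, counts = stats::setNames(counts, genes$gene_id),
           background = if (is.null(bg)) character(0) else bg$peak_id)
    }
    A <- make_peaks(config$peak_density_per_gene[1], "spA")
    B <- make_peaks(config$peak_density_per_gene[2], "spB")
    list(annotation = ann, peaksA = A$peaks, peaksB = B$peaks,
         truth = list(countsA = A$counts, countsB = B$counts,
                      backgroundA = A$background, backgroundB = B$background))
  })
}

#' Synthetic methylome over supplied regions
#'
#' Each region is planted as "differential" (low methylation in the
#' defining sample, high elsewhere) or "constitutive" (low everywhere),
#' with means drawn from the two configured modes. CpGs are placed
#' inside each region and per-CpG methylated read counts drawn
#' binomially around the region/sample mean, with coverage at or above
#' the floor.
#'
#' @param config a [synthetic_config()] (modes must be >= 0.3 apart or a
#'   warning is raised).
#' @param regions data.frame (`chrom`, `start`, `end`, `region_id`).
#' @param samples sample names; the first is the defining tissue.
#' @param p_differential probability a region is differential (default
#'   0.5).
#' @param cpgs_per_region mean extra CpGs beyond `min_cpgs` (default 8).
#' @param min_cpgs guaranteed CpGs per region (default 5).
#' @param min_coverage coverage floor (default 5).
#' @return list with `calls` (per-CpG data.frame: chrom, pos, strand,
#'   meth, total, sample) and `truth` (per-region planted cluster:
#'   1 = differential, 2 = constitutive).
#' @export
generate_methylome <- function(config = synthetic_config(), regions,
                               samples = c("hepatic", "neural", "muscle",
                                           "gut"),
                               p_differential = 0.5, cpgs_per_region = 8,
                               min_cpgs = 5, min_coverage = 5) {
  modes <- config$methylation_modes
  if (diff(range(modes)) < 0.3)
    warning("methylation modes closer than 0.3: clusters may be ",
            "unrecoverable")
  if (nrow(regions) < 1) stop("need at least one region")
  with_seed(sub_seed(config$seed, "methylome"), {
    cluster <- ifelse(stats::runif(nrow(regions)) < p_differential, 1L, 2L)
    rows <- list()
    for (i in seq_len(nrow(regions))) {
      ncpg <- min_cpgs + stats::rpois(1, cpgs_per_region)
      span <- regions$end[i] - regions$start[i]
      pos <- regions$start[i] +
        sort(sample.int(span, min(ncpg, span))) - 1L
      for (s in samples) {
        mu <- if (cluster[i] == 1L && s != samples[1]) modes[2] else modes[1]
        mu <- min(max(mu + stats::rnorm(1, 0, 0.03), 0.01), 0.99)
        cov <- min_coverage + stats::rpois(length(pos), 10)
        rows[[length(rows) + 1L]] <- data.frame(
          chrom = regions$chrom[i], pos = pos, strand = "+",
          meth = stats::rbinom(length(pos), cov, mu), total = cov,
          sample = s, region_id = regions$region_id[i],
          stringsAsFactors = FALSE)
      }
    }
    list(calls = do.call(rbind, rows),
         truth = stats::setNames(cluster, regions$region_id))
  })
}

#' Motif-enriched sequence groups
#'
#' Generates sharp PWMs, groups of background sequences at a configured
#' base composition, and plants motif instances (sampled from the PWM)
#' at per-group per-motif insertion rates. One group/motif combination
#' can be enriched by a multiplicative factor.
#'
#' @param config a [synthetic_config()].
#' @param n_groups,seqs_per_group,seq_len_bp shape of the dataset.
#' @param n_motifs number of PWMs (length 8 each).
#' @param base_rate expected motif insertions per sequence (default 0.5).
#' @param enriched_group,enriched_motif index of the enriched
#'   combination (NULL = no enrichment).
#' @param enrichment_factor multiplier on the insertion rate (default 10).
#' @param background base composition (A, C, G, T; default uniform).
#' @return list with `sequences` (named character per group id),
#'   `groups` (group -> sequence ids), `pwms`, and `truth` (planted rate
#'   matrix and insertion positions).
#' @export
generate_motif_dataset <- function(config = synthetic_config(),
                                   n_groups = 3, seqs_per_group = 40,
                                   seq_len_bp = 400, n_motifs = 4,
                                   base_rate = 0.5,
                                   enriched_group = 1, enriched_motif = 1,
                                   enrichment_factor = 10,
                                   background = rep(0.25, 4)) {
  .check_prob(background, "background", tol = 1e-6)
  motif_len <- 8
  if (motif_len >= seq_len_bp) stop("motif length must be < sequence length")
  with_seed(sub_seed(config$seed, "motifs"), {
    pwms <- list()
    for (m in seq_len(n_motifs)) {
      cons <- sample(4, motif_len, replace = TRUE)
      M <- matrix(0.04, 4, motif_len)
      M[cbind(cons, seq_len(motif_len))] <- 0.88
      pwms[[sprintf("motif%d", m)]] <- pwm(M, sprintf("motif%d", m))
    }
    rates <- matrix(base_rate, n_groups, n_motifs,
                    dimnames = list(sprintf("group%d", seq_len(n_groups)),
                                    names(pwms)))
    if (!is.null(enriched_group))
      rates[enriched_group, enriched_motif] <-
        base_rate * enrichment_factor
    seqs <- character(0); groups <- list(); inserts <- list()
    for (g in seq_len(n_groups)) {
      gid <- sprintf("group%d", g)
      ids <- sprintf("%s_seq%03d", gid, seq_len(seqs_per_group))
      for (id in ids) {
        s <- sample(.DNA, seq_len_bp, replace = TRUE, prob = background)
        for (m in seq_len(n_motifs)) {
          n_ins <- stats::rpois(1, rates[g, m])
          for (k in seq_len(n_ins)) {
            at <- sample.int(seq_len_bp - motif_len + 1, 1)
            inst <- vapply(seq_len(motif_len), function(j)
              sample(.DNA, 1, prob = pwms[[m]]$freq[, j]), character(1))
            if (stats::runif(1) < 0.5)
              inst <- rev(c(A = "T", C = "G", G = "C", T = "A")[inst])
            s[at:(at + motif_len - 1)] <- inst
            inserts[[length(inserts) + 1L]] <- data.frame(
              sequence_id = id, motif = names(pwms)[m], offset = at - 1L,
              stringsAsFactors = FALSE)
          }
        }
        seqs[id] <- paste(s, collapse = "")
      }
      groups[[gid]] <- ids
    }
    list(sequences = seqs, groups = groups, pwms = pwms,
         truth = list(rates = rates,
                      insertions = rbind_rows(inserts)))
  })
}

#' Write a synthetic bundle to disk
#'
#' Emits the standard plain-text formats for a full synthetic dataset:
#' expression TSVs, family TSV, GTF + BED6 peaks, CpG TSV, FASTA, JASPAR
#' PWMs and truth-label TSVs. Deterministic for a fixed config seed
#' (byte-identical output).
#'
#' @param config a [synthetic_config()].
#' @param outdir output directory (created if missing).
#' @return invisibly, the vector of files written.
#' @export
write_synthetic_bundle <- function(config = synthetic_config(), outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  f <- function(...) file.path(outdir, sprintf(...))
  written <- character(0)
  hg <- generate_hourglass_series(config)
  write_expression_tsv(hg$exprA, f("exprA.tsv"))
  write_expression_tsv(hg$exprB, f("exprB.tsv"))
  write_tsv_table(hg$pairs, f("pairs.tsv"))
  write_tsv_table(data.frame(stage = seq_along(hg$truth$profile),
                             noise_sd = hg$truth$profile,
                             is_min = seq_along(hg$truth$profile) ==
                               hg$truth$min_stage),
                  f("truth_hourglass.tsv"))
  ft <- generate_fate_families(config)
  write_family_table(ft$fams, f("families.tsv"))
  write_expression_tsv(ft$exprA, f("domains_outgroup.tsv"))
  write_expression_tsv(ft$exprB, f("domains_vertebrate.tsv"))
  write_tsv_table(data.frame(family_id = names(ft$truth$fate),
                             fate = ft$truth$fate),
                  f("truth_fates.tsv"))
  gp <- generate_genome_with_peaks(config)
  write_gtf_annotation(gp$annotation, f("genes.gtf"))
  write_peaks_bed(gp$peaksA, f("peaksA.bed"))
  write_peaks_bed(gp$peaksB, f("peaksB.bed"))
  write_tsv_table(data.frame(gene_id = names(gp$truth$countsA),
                             planted_A = gp$truth$countsA,
                             planted_B = gp$truth$countsB),
                  f("truth_peaks.tsv"))
  regions <- data.frame(chrom = "chrS",
                        start = seq(0, by = 2000,
                                    length.out = 100),
                        end = seq(1000, by = 2000, length.out = 100),
                        region_id = sprintf("r%03d", 1:100))
  me <- generate_methylome(config, regions)
  write_cpg_tsv(me$calls, f("cpg_calls.tsv"))
  write_tsv_table(data.frame(region_id = names(me$truth),
                             planted_cluster = me$truth),
                  f("truth_methylation.tsv"))
  mo <- generate_motif_dataset(config)
  writeLines(paste0(">", names(mo$sequences), "\n", mo$sequences),
             f("sequences.fa"))
  write_jaspar(mo$pwms, f("pwms.jaspar"))
  write_tsv_table(as.data.frame(as.table(mo$truth$rates),
                                stringsAsFactors = FALSE) |>
                    stats::setNames(c("group", "motif", "planted_rate")),
                  f("truth_motifs.tsv"))
  invisible(list.files(outdir, full.names = TRUE))
}
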