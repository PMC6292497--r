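# PWM scanning of regulatory sequences and motif-enrichment z-scores per
# gene group / module / developmental stage. Scanning uses log-odds scores
# against a background composition; a window is a hit when it reaches a
# fixed fraction (default 80%) of the motif's maximum attainable score.

.DNA <- c("A", "C", "G", "T")

#' Construct a position weight matrix
#'
#' @param matrix 4 x L numeric matrix of per-position base frequencies,
#'   rows in A, C, G, T order; columns must sum to 1 (a pseudocount is
#'   added and columns renormalized on construction).
#' @param motif_id identifier.
#' @param pseudocount added to every frequency before renormalization
#'   (default 1e-3), so 0-frequency cells have a finite log-odds.
#' @param background length-4 background composition (default uniform).
#' @param threshold_fraction hit threshold as a fraction of the maximum
#'   attainable log-odds score (default 0.8).
#' @return A `pwm` object: list with the normalized frequency matrix, the
#'   log2-odds score matrix, max score, and scanning parameters.
#' @export
pwm <- function(matrix, motif_id = "motif", pseudocount = 1e-3,
                background = rep(0.25, 4), threshold_fraction = 0.8) {
  m <- as.matrix(matrix)
  if (nrow(m) != 4) stop("PWM must have 4 rows (A, C, G, T)")
  if (ncol(m) < 4) stop("PWM length must be >= 4")
  if (any(m < 0)) stop("PWM frequencies must be non-negative")
  m <- sweep(m + pseudocount, 2, colSums(m + pseudocount), "/")
  rownames(m) <- .DNA
  .check_prob(background, "background", tol = 1e-6)
  score <- log2(m / background)
  structure(list(motif_id = motif_id, freq = m, score = score,
                 max_score = sum(apply(score, 2, max)),
                 length = ncol(m), pseudocount = pseudocount,
                 background = background,
                 threshold_fraction = threshold_fraction),
            class = "pwm")
}

#' Read PWMs from JASPAR-format text
#'
#' Minimal JASPAR parser: records start with `>motif_id [name]`, followed
#' by four lines `A [ n n ... ]` (brackets optional) in A, C, G, T order.
#' Counts are converted to column frequencies.
#'
#' @param path file path.
#' @inheritParams pwm
#' @return A named list of [pwm()] objects.
#' @export
read_jaspar <- function(path, pseudocount = 1e-3,
                        background = rep(0.25, 4), threshold_fraction = 0.8) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  starts <- grep("^>", lines)
  if (!length(starts)) stop("no JASPAR records found in ", path)
  out <- list()
  for (i in seq_along(starts)) {
    hdr <- sub("^>\\s*", "", lines[starts[i]])
    id <- strsplit(hdr, "\\s+")[[1]][1]
    body <- lines[(starts[i] + 1):(starts[i] + 4)]
    rows <- lapply(body, function(l) {
      l <- gsub("^[ACGTacgt]\\s*", "", trimws(l))
      as.numeric(strsplit(gsub("[\\[\\]]", " ", l, perl = TRUE),
                          "\\s+")[[1]] |> (\(v) v[nzchar(v)])())
    })
    counts <- do.call(rbind, rows)
    freq <- sweep(counts, 2, colSums(counts), "/")
    out[[id]] <- pwm(freq, motif_id = id, pseudocount = pseudocount,
                     background = background,
                     threshold_fraction = threshold_fraction)
  }
  out
}

#' Write PWMs as JASPAR-format text
#'
#' @param pwms named list of [pwm()] objects (frequencies are written).
#' @param path file path.
#' @export
write_jaspar <- function(pwms, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in pwms) {
    writeLines(paste0(">", p$motif_id), con)
    for (r in 1:4)
      writeLines(sprintf("%s [ %s ]", .DNA[r],
                         paste(formatC(p$freq[r, ], format = "f", digits = 6),
                               collapse = " ")), con)
  }
  invisible(path)
}

.seq_to_int <- function(s) {
  v <- match(strsplit(toupper(s), "")[[1]], .DNA)  # N and others -> NA
  v
}

# log-odds scores of all L-windows of the integer-coded sequence under the
# score matrix; windows containing non-ACGT bases return NA
.window_scores <- function(iv, score) {
  L <- ncol(score)
  n <- length(iv) - L + 1
  if (n < 1) return(numeric(0))
  tot <- numeric(n)
  for (j in seq_len(L)) {
    sj <- score[, j][iv[j:(j + n - 1)]]
    tot <- tot + sj
  }
  tot
}

#' Scan sequences with a PWM
#'
#' Log-odds scoring of every window on both strands; a window is reported
#' when its score reaches `threshold_fraction * max_score`. Windows that
#' contain non-ACGT characters are skipped. Coordinates are 0-based
#' offsets on the forward strand (for minus-strand hits, the offset of
#' the leftmost base of the matching window on the forward strand).
#'
#' @param sequences named character vector (or `Biostrings::DNAStringSet`)
#'   of DNA sequences.
#' @param pwm a [pwm()] object.
#' @return data.frame with columns `sequence_id`, `offset`, `strand`
#'   ("+"/"-"), `score`. Sequences shorter than the motif yield no rows.
#' @export
scan_pwm <- function(sequences, pwm) {
  stopifnot(inherits(pwm, "pwm"))
  if (methods::is(sequences, "DNAStringSet"))
    sequences <- stats::setNames(as.character(sequences), names(sequences))
  if (is.null(names(sequences)))
    names(sequences) <- paste0("seq", seq_along(sequences))
  thr <- pwm$threshold_fraction * pwm$max_score
  # minus strand = scanning the reverse complement; realised as scanning
  # the forward strand with the reverse-complemented score matrix
  rc_score <- pwm$score[4:1, ncol(pwm$score):1]
  rows <- list()
  for (id in names(sequences)) {
    iv <- .seq_to_int(sequences[[id]])
    for (st in c("+", "-")) {
      sc <- .window_scores(iv, if (st == "+") pwm$score else rc_score)
      hit <- which(!is.na(sc) & sc >= thr)
      if (length(hit))
        rows[[length(rows) + 1L]] <- data.frame(
          sequence_id = id, offset = hit - 1L, strand = st,
          score = sc[hit], stringsAsFactors = FALSE)
    }
  }
  if (!length(rows))
    return(data.frame(sequence_id = character(0), offset = integer(0),
                      strand = character(0), score = numeric(0)))
  out <- do.call(rbind, rows)
  out[order(out$sequence_id, out$offset, out$strand), , drop = FALSE]
}

#' Per-group motif hit counts
#'
#' Counts PWM hits within the regions of each gene group. Overlapping
#' hits all count; a region listed twice in a group is scanned (and
#' counted) twice, with a warning.
#'
#' @param groups named list: group id -> character vector of region ids.
#' @param regions data.frame with columns `region_id`, `chrom`, `start`,
#'   `end` (0-based half-open).
#' @param genome named character vector or `DNAStringSet` of chromosome
#'   sequences.
#' @param pwms named list of [pwm()] objects.
#' @return list with `counts` (group x motif matrix) and `scanned_bp`
#'   (named per-group total region length).
#' @export
motif_count_matrix <- function(groups, regions, genome, pwms) {
  if (methods::is(genome, "DNAStringSet"))
    genome <- stats::setNames(as.character(genome), names(genome))
  ridx <- stats::setNames(seq_len(nrow(regions)), regions$region_id)
  counts <- matrix(0L, length(groups), length(pwms),
                   dimnames = list(names(groups), names(pwms)))
  scanned <- stats::setNames(numeric(length(groups)), names(groups))
  for (g in names(groups)) {
    ids <- groups[[g]]
    if (anyDuplicated(ids))
      warning("group '", g, "' lists duplicated regions: hits double-counted")
    if (!length(ids)) next
    miss <- setdiff(ids, names(ridx))
    if (length(miss)) stop("unknown region id(s): ", paste(miss, collapse = ", "))
    reg <- regions[ridx[ids], , drop = FALSE]
    seqs <- character(nrow(reg))
    for (i in seq_len(nrow(reg))) {
      chrom <- as.character(reg$chrom[i])
      if (!chrom %in% names(genome) ||
          reg$start[i] < 0 || reg$end[i] > nchar(genome[[chrom]]))
        stop("region outside sequence bounds: ", reg$region_id[i])
      seqs[i] <- substr(genome[[chrom]], reg$start[i] + 1, reg$end[i])
    }
    names(seqs) <- make.unique(as.character(reg$region_id))
    scanned[g] <- sum(reg$end - reg$start)
    for (m in names(pwms))
      counts[g, m] <- nrow(scan_pwm(seqs, pwms[[m]]))
  }
  list(counts = counts, scanned_bp = scanned)
}

#' Motif enrichment z-scores
#'
#' Converts per-group hit counts to hits per kb scanned, then
#' standardizes each motif across groups: z = (rate - mean)/sd with the
#' sample standard deviation (n - 1). Motifs with zero rate variance get
#' an all-NA row.
#'
#' @param counts group x motif count matrix.
#' @param scanned_bp per-group scanned base pairs (named or in row order).
#' @return A group x motif z-score matrix; attribute "rates" holds the
#'   per-kb rates.
#' @export
motif_zscores <- function(counts, scanned_bp) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2) stop("need at least 2 groups for z-scores")
  if (!is.null(names(scanned_bp))) scanned_bp <- scanned_bp[rownames(counts)]
  rates <- counts / (scanned_bp / 1000)
  mu <- colMeans(rates)
  sd <- apply(rates, 2, stats::sd)
  z <- sweep(sweep(rates, 2, mu, "-"), 2, sd, "/")
  z[, sd == 0] <- NA_real_
  attr(z, "rates") <- rates
  z
}

#' Sum motif counts into super-family clusters
#'
#' The motif clusters (e.g. the 242 super-families) are an input mapping;
#' counts of member motifs are summed per cluster.
#'
#' @param counts group x motif count matrix.
#' @param cluster_map data.frame with columns `motif_id`, `cluster_id`.
#' @return group x cluster count matrix.
#' @export
collapse_motif_clusters <- function(counts, cluster_map) {
  m <- intersect(colnames(counts), cluster_map$motif_id)
  cl <- cluster_map$cluster_id[match(m, cluster_map$motif_id)]
  t(rowsum(t(counts[, m, drop = FALSE]), group = cl))
}
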