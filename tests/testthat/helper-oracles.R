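# Independent brute-force oracles shared by unit and acceptance tests.
# Each recomputes the target quantity from first principles by a
# different route than the package implementation.

# per-base GREAT oracle: walk outward from the basal edges base by base,
# stopping at a foreign basal base, the TSS +/- max_ext cap, or the
# chromosome end
oracle_great <- function(annotation, basal_up = 5000, basal_down = 1000,
                         max_ext = 1e6) {
  g <- annotation$genes
  L <- annotation$chromosomes$length[1]
  basal <- function(i) {
    if (g$strand[i] == "+") c(g$tss[i] - basal_up, g$tss[i] + basal_down)
    else c(g$tss[i] - basal_down + 1, g$tss[i] + basal_up + 1)
  }
  bs <- t(vapply(seq_len(nrow(g)), basal, numeric(2)))
  bs[, 1] <- pmax(0, bs[, 1]); bs[, 2] <- pmin(L, bs[, 2])
  covered_by_other <- function(i, x) {
    any(bs[-i, 1] <= x & x < bs[-i, 2])
  }
  out <- data.frame(gene_id = g$gene_id, chrom = g$chrom,
                    basal_start = bs[, 1], basal_end = bs[, 2],
                    ext_start = NA_real_, ext_end = NA_real_)
  for (i in seq_len(nrow(g))) {
    x <- bs[i, 1] - 1
    while (x >= 0 && x >= g$tss[i] - max_ext && !covered_by_other(i, x))
      x <- x - 1
    out$ext_start[i] <- x + 1
    x <- bs[i, 2]
    while (x < L && x < g$tss[i] + max_ext && !covered_by_other(i, x))
      x <- x + 1
    out$ext_end[i] <- x
  }
  out
}

# quadratic peak-in-domain incidence count
oracle_count_incidences <- function(domains, peaks) {
  total <- 0L
  for (p in seq_len(nrow(peaks))) {
    mid <- floor((peaks$start[p] + peaks$end[p]) / 2)
    for (d in seq_len(nrow(domains)))
      if (peaks$chrom[p] == domains$chrom[d] &&
          mid >= domains$ext_start[d] && mid < domains$ext_end[d])
        total <- total + 1L
  }
  total
}

# exhaustive PWM scan: score every window on both strands from the
# frequency matrix directly; minus strand scores the reverse-complemented
# window string on the forward matrix
oracle_scan <- function(seqstr, p) {
  bases <- strsplit(toupper(seqstr), "")[[1]]
  L <- ncol(p$freq)
  thr <- p$threshold_fraction * p$max_score
  rc <- function(w) rev(c(A = "T", C = "G", G = "C", T = "A", N = "N")[w])
  sc <- function(w) {
    if (any(!w %in% c("A", "C", "G", "T"))) return(NA_real_)
    sum(vapply(seq_len(L), function(j)
      log2(p$freq[w[j], j] / p$background[match(w[j], c("A","C","G","T"))]),
      numeric(1)))
  }
  hits <- list()
  n <- length(bases) - L + 1
  if (n < 1) return(data.frame(offset = integer(0), strand = character(0)))
  for (o in seq_len(n)) {
    w <- bases[o:(o + L - 1)]
    s1 <- sc(w); s2 <- sc(rc(w))
    if (!is.na(s1) && s1 >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = o - 1L, strand = "+")
    if (!is.na(s2) && s2 >= thr)
      hits[[length(hits) + 1L]] <- data.frame(offset = o - 1L, strand = "-")
  }
  out <- do.call(rbind, hits)
  if (is.null(out)) data.frame(offset = integer(0), strand = character(0))
  else out[order(out$offset, out$strand), , drop = FALSE]
}

# exhaustive upper-tail hypergeometric by enumeration of module-m
# placements over a small universe
oracle_hyper_upper <- function(k, szA, szB, N) {
  sets <- utils::combn(N, szA)
  inB <- seq_len(szB)  # module n occupies the first szB universe slots
  ge <- 0
  for (c in seq_len(ncol(sets)))
    if (sum(sets[, c] %in% inB) >= k) ge <- ge + 1
  ge / ncol(sets)
}

# brute-force NACC for families with single members on both sides:
# plain loops over explicitly computed pairwise Euclidean distances of
# z-scored log2(x+1) profiles
oracle_nacc <- function(exprA, exprB, map, k) {
  zs <- function(M) {
    x <- log2(M + 1)
    t(apply(x, 1, function(r) if (stats::sd(r) == 0) r * 0
            else (r - mean(r)) / stats::sd(r)))
  }
  A <- zs(exprA); B <- zs(exprB)
  ed <- function(u, v) sqrt(sum((u - v)^2))
  res <- numeric(0)
  for (a in names(map)) {
    b <- map[[a]]
    others <- setdiff(names(map), a)
    dA <- sapply(others, function(g) ed(A[a, ], A[g, ]))
    nbrA <- others[order(dA, others)][seq_len(k)]
    A_bar <- mean(sapply(nbrA, function(g) ed(A[a, ], A[g, ])))
    AB_bar <- mean(sapply(nbrA, function(g) ed(B[b, ], B[map[[g]], ])))
    othersB <- setdiff(unname(unlist(map)), b)
    dB <- sapply(othersB, function(g) ed(B[b, ], B[g, ]))
    nbrB <- othersB[order(dB, othersB)][seq_len(k)]
    B_bar <- mean(sapply(nbrB, function(g) ed(B[b, ], B[g, ])))
    inv <- stats::setNames(names(map), unname(unlist(map)))
    BA_bar <- mean(sapply(nbrB, function(g) ed(A[a, ], A[inv[[g]], ])))
    res[a] <- 0.5 * ((AB_bar - A_bar) + (BA_bar - B_bar))
  }
  res
}

# exhaustive 2-partition k-means objective: minimum total within-cluster
# sum of squares over all non-trivial bipartitions
oracle_kmeans2_wss <- function(mat) {
  n <- nrow(mat)
  best <- Inf
  for (code in 1:(2^n - 2)) {
    lab <- as.integer(intToBits(code))[1:n]
    if (!any(lab == 0) || !any(lab == 1)) next
    wss <- 0
    for (cl in 0:1) {
      sub <- mat[lab == cl, , drop = FALSE]
      cen <- colMeans(sub)
      wss <- wss + sum(sweep(sub, 2, cen)^2)
    }
    best <- min(best, wss)
  }
  best
}

# plain Rand index between two labelings
rand_index <- function(a, b) {
  n <- length(a)
  agree <- 0; tot <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    tot <- tot + 1
    if ((a[i] == a[j]) == (b[i] == b[j])) agree <- agree + 1
  }
  agree / tot
}

random_prob_vec <- function(n) {
  v <- stats::runif(n)
  v / sum(v)
}
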