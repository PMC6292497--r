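# Neighbourhood analysis of conserved co-expression (NACC) and
# cross-species comparison of co-expression modules. Module inference
# (WGCNA / Mfuzz) is out of scope: assignments are inputs.

# per-gene z-scored log2(x+1) expression, the default NACC feature space
.nacc_transform <- function(expr) {
  x <- log2(unclass(as.matrix(expr)) + 1)
  mu <- rowMeans(x)
  sd <- apply(x, 1, stats::sd)
  sd[sd == 0] <- 1  # constant genes map to the origin
  (x - mu) / sd
}

.dist_rows <- function(x, metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  if (metric == "euclidean") as.matrix(stats::dist(x))
  else 1 - stats::cor(t(x))
}

#' NACC conserved co-expression score
#'
#' For each family with a single member A in species 1 and members B in
#' species 2, NACC = 1/2 * ((AB - A) + (BA - B)) where A is the mean
#' distance from gene A to its k nearest genes in species-1 expression
#' space, AB the mean species-2 distance from B to the orthologues of
#' those neighbours, and B / BA the reciprocal quantities. Distances are
#' Euclidean on per-gene z-scored log2(x+1) profiles by default. Values
#' near 0 indicate conserved co-expression neighbourhoods; the expected
#' value under random orthology is positive.
#'
#' Candidate neighbours are restricted to genes that carry an orthologue
#' in the other species, and the query gene is excluded from its own
#' neighbour set. Families with several species-2 members average the
#' member-level quantities. Families with fewer than k eligible
#' neighbours are rejected with a reason.
#'
#' @param exprA,exprB genes x samples expression matrices for species 1
#'   and 2 (sample sets need not match).
#' @param fams a [family_set()] whose families have exactly one member in
#'   `spA` and >= 1 member in `spB`; other families are skipped.
#' @param spA,spB species names in the registry (defaults: first two).
#' @param k neighbourhood size (default 20).
#' @param metric "euclidean" (default) or "correlation".
#' @return data.frame with one row per scored family: `family_id`,
#'   `geneA`, `n_members_B`, `A_bar`, `B_bar`, `AB_bar`, `BA_bar`,
#'   `nacc`; skipped families are reported in attribute "skipped".
#' @export
nacc_score <- function(exprA, exprB, fams, spA = fams$species[1],
                       spB = fams$species[2], k = 20,
                       metric = c("euclidean", "correlation")) {
  metric <- match.arg(metric)
  stopifnot(inherits(fams, "family_set"))
  fam_list <- Filter(function(f)
    length(f[[spA]]) == 1L && length(f[[spB]]) >= 1L, fams$families)
  fam_list <- Filter(function(f)
    f[[spA]] %in% rownames(exprA) && all(f[[spB]] %in% rownames(exprB)),
    fam_list)
  if (!length(fam_list)) stop("no eligible families")
  genesA <- vapply(fam_list, function(f) f[[spA]], character(1))
  membersB <- lapply(fam_list, function(f) f[[spB]])
  allB <- unique(unlist(membersB))
  zA <- .nacc_transform(exprA[genesA, , drop = FALSE])
  zB <- .nacc_transform(exprB[allB, , drop = FALSE])
  dA <- .dist_rows(zA, metric)
  dB <- .dist_rows(zB, metric)
  famA <- stats::setNames(names(fam_list), genesA)   # geneA -> family
  famB <- stats::setNames(rep(names(fam_list), lengths(membersB)),
                          unlist(membersB))          # geneB -> family
  rows <- list(); skipped <- list()
  for (i in seq_along(fam_list)) {
    fid <- names(fam_list)[i]
    a <- genesA[i]; bset <- membersB[[i]]
    cand <- setdiff(genesA, a)
    if (length(cand) < k) {
      skipped[[fid]] <- sprintf("only %d eligible neighbours (< k = %d)",
                                length(cand), k)
      next
    }
    # A-side neighbourhood
    da <- dA[a, cand]
    nbrA <- cand[order(da, cand)[seq_len(k)]]
    A_bar <- mean(dA[a, nbrA])
    # orthologues of A's neighbours, measured in species-2 space from B
    orthB <- lapply(nbrA, function(g) membersB[[famA[[g]]]])
    AB_bar <- mean(vapply(bset, function(b)
      mean(vapply(orthB, function(os) mean(dB[b, os]), numeric(1))),
      numeric(1)))
    # B-side neighbourhoods (per member, averaged)
    B_vals <- BA_vals <- numeric(length(bset))
    for (j in seq_along(bset)) {
      b <- bset[j]
      candB <- setdiff(allB, bset)  # exclude the whole family, incl. b
      if (length(candB) < k) {
        skipped[[fid]] <- sprintf("only %d eligible B neighbours (< k = %d)",
                                  length(candB), k)
        B_vals <- NULL
        break
      }
      db <- dB[b, candB]
      nbrB <- candB[order(db, candB)[seq_len(k)]]
      B_vals[j] <- mean(dB[b, nbrB])
      # orthologue (species-1 gene) of each B neighbour's family
      orthA <- genesA[match(famB[nbrB], names(fam_list))]
      BA_vals[j] <- mean(dA[a, orthA])
    }
    if (is.null(B_vals)) next
    B_bar <- mean(B_vals); BA_bar <- mean(BA_vals)
    rows[[fid]] <- data.frame(
      family_id = fid, geneA = a, n_members_B = length(bset),
      A_bar = A_bar, B_bar = B_bar, AB_bar = AB_bar, BA_bar = BA_bar,
      nacc = 0.5 * ((AB_bar - A_bar) + (BA_bar - B_bar)),
      stringsAsFactors = FALSE)
  }
  out <- rbind_rows(rows)
  if (is.null(out)) stop("all families rejected: ",
                         paste(unlist(skipped), collapse = "; "))
  attr(out, "skipped") <- skipped
  attr(out, "k") <- k
  out
}

#' NACC null distribution under randomized orthology
#'
#' Permutes which species-2 member set each species-1 gene is paired
#' with (preserving the family-size structure) and recomputes the mean
#' NACC per permutation. The empirical p-value for the observed mean
#' being LOWER than the null (conserved co-expression) is
#' (1 + #\{null <= observed\}) / (n_permutations + 1).
#'
#' @inheritParams nacc_score
#' @param n_permutations number of orthology permutations (>= 1).
#' @param seed integer seed.
#' @return list with `observed_mean`, `null_means`, `p_value`.
#' @export
nacc_null <- function(exprA, exprB, fams, spA = fams$species[1],
                      spB = fams$species[2], k = 20,
                      metric = "euclidean", n_permutations = 100, seed = 1) {
  stopifnot(n_permutations >= 1)
  obs <- mean(nacc_score(exprA, exprB, fams, spA, spB, k, metric)$nacc)
  fam_list <- Filter(function(f)
    length(f[[spA]]) == 1L && length(f[[spB]]) >= 1L, fams$families)
  nulls <- with_seed(sub_seed(seed, "nacc_null"), {
    vapply(seq_len(n_permutations), function(i) {
      perm <- sample(length(fam_list))
      shuffled <- fam_list
      for (j in seq_along(fam_list))
        shuffled[[j]][[spB]] <- fam_list[[perm[j]]][[spB]]
      f2 <- fams
      f2$families <- shuffled
      mean(nacc_score(exprA, exprB, f2, spA, spB, k, metric)$nacc)
    }, numeric(1))
  })
  list(observed_mean = obs, null_means = nulls,
       p_value = (1 + sum(nulls <= obs)) / (n_permutations + 1))
}

#' Cross-species module overlap (upper-tail hypergeometric tests)
#'
#' Universe = 1-to-1 orthologue pairs whose two genes are both assigned
#' to some module. For every module pair (m of species A, n of species B)
#' the overlap k = number of pairs with the A gene in m and the B gene in
#' n is tested against the hypergeometric upper tail P(X >= k) with the
#' universe's margins.
#'
#' @param assignA,assignB data.frames with columns `gene_id`, `module`.
#' @param pairs data.frame with columns `geneA`, `geneB`.
#' @param adjust add a BH-adjusted column (default TRUE).
#' @return list with matrices `p` (raw upper-tail p), `overlap` (counts),
#'   optional `p_adj`, and `universe_size`.
#' @export
module_overlap_test <- function(assignA, assignB, pairs, adjust = TRUE) {
  mA <- stats::setNames(as.character(assignA$module), assignA$gene_id)
  mB <- stats::setNames(as.character(assignB$module), assignB$gene_id)
  keep <- pairs$geneA %in% names(mA) & pairs$geneB %in% names(mB)
  u <- pairs[keep, , drop = FALSE]
  if (nrow(u) == 0) stop("empty universe: no orthologue pair fully assigned")
  labA <- mA[u$geneA]; labB <- mB[u$geneB]
  modsA <- sort(unique(labA)); modsB <- sort(unique(labB))
  N <- nrow(u)
  ov <- table(factor(labA, modsA), factor(labB, modsB))
  ov <- matrix(as.integer(ov), length(modsA), length(modsB),
               dimnames = list(modsA, modsB))
  szA <- rowSums(ov); szB <- colSums(ov)
  p <- ov
  for (i in seq_along(modsA))
    for (j in seq_along(modsB))
      p[i, j] <- stats::phyper(ov[i, j] - 1, szA[i], N - szA[i], szB[j],
                               lower.tail = FALSE)
  out <- list(p = p, overlap = ov, universe_size = N)
  if (adjust) {
    pa <- p
    pa[] <- stats::p.adjust(as.vector(p), method = "BH")
    out$p_adj <- pa
  }
  out
}

#' Correlation of module motif-enrichment profiles across species
#'
#' Pearson correlation across a shared motif registry between every pair
#' of modules from the two species, plus the best species-B match per
#' species-A module.
#'
#' @param zA,zB module x motif z-score matrices with motif ids as
#'   colnames; the intersection of motif sets (>= 3) is used.
#' @return list with `cor` (modulesA x modulesB Pearson matrix, NA where
#'   a profile has zero variance) and `best` (per-A-module best B module
#'   and correlation).
#' @export
module_motif_correlation <- function(zA, zB) {
  shared <- intersect(colnames(zA), colnames(zB))
  if (length(shared) < 3) stop("need at least 3 shared motifs")
  a <- as.matrix(zA)[, shared, drop = FALSE]
  b <- as.matrix(zB)[, shared, drop = FALSE]
  cm <- matrix(NA_real_, nrow(a), nrow(b),
               dimnames = list(rownames(zA), rownames(zB)))
  for (i in seq_len(nrow(a)))
    for (j in seq_len(nrow(b))) {
      if (stats::sd(a[i, ]) == 0 || stats::sd(b[j, ]) == 0) next  # undefined
      cm[i, j] <- stats::cor(a[i, ], b[j, ])
    }
  best <- data.frame(
    moduleA = rownames(cm) %||% as.character(seq_len(nrow(cm))),
    best_moduleB = apply(cm, 1, function(r)
      if (all(is.na(r))) NA_character_
      else (colnames(cm) %||% as.character(seq_len(ncol(cm))))[which.max(r)]),
    best_cor = apply(cm, 1, function(r)
      if (all(is.na(r))) NA_real_ else max(r, na.rm = TRUE)),
    stringsAsFactors = FALSE, row.names = NULL)
  list(cor = cm, best = best)
}
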