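# Post-WGD paralogue fate analysis: nine-domain binarized comparison of
# outgroup orthologues and vertebrate ohnologues, expression-bias
# histograms, the redundancy / subfunctionalization / specialization
# taxonomy, and its association with regulatory complexity and sequence
# divergence.

.bin_row <- function(bin, gene) {
  if (!gene %in% rownames(bin)) return(NULL)
  unclass(bin)[gene, ]
}

#' Expression-domain bias between outgroup and vertebrate genes
#'
#' For every eligible family, bias = (number of "on" domains in the
#' vertebrate entity) - (number of "on" domains in the outgroup gene).
#' The vertebrate entity depends on `mode`: `single_copy` compares
#' 1-to-1 orthologue pairs; `individual_ohnologue` emits one record per
#' vertebrate family member; `union` ORs the member rows; and
#' `sum_then_binarize` sums the members' raw expression first and
#' binarizes the sum (requires `exprB_raw`).
#'
#' @param binA,binB [binarize()]d genes x domains matrices for the
#'   outgroup and the vertebrate species; identical ordered domain lists
#'   required.
#' @param fams a [family_set()].
#' @param mode one of "single_copy", "individual_ohnologue", "union",
#'   "sum_then_binarize".
#' @param outgroup,vertebrate species names (defaults: registry order).
#' @param exprB_raw raw vertebrate expression matrix (needed for
#'   `sum_then_binarize`); the binarization threshold is taken from
#'   `binB`.
#' @return data.frame with `family_id`, `geneA`, `geneB` (the member,
#'   "union"/"sum" otherwise), `domains_outgroup`, `domains_vertebrate`,
#'   `bias`, `mode`.
#' @export
domain_bias <- function(binA, binB, fams,
                        mode = c("single_copy", "individual_ohnologue",
                                 "union", "sum_then_binarize"),
                        outgroup = fams$species[1],
                        vertebrate = fams$species[2], exprB_raw = NULL) {
  mode <- match.arg(mode)
  if (!identical(colnames(binA), colnames(binB)))
    stop("domain lists of the two binary profiles differ")
  if (mode == "sum_then_binarize" && is.null(exprB_raw))
    stop("sum_then_binarize needs exprB_raw")
  thr <- attr(binB, "threshold") %||% 5
  rows <- list()
  for (fid in names(fams$families)) {
    f <- fams$families[[fid]]
    ga <- f[[outgroup]]; gb <- f[[vertebrate]]
    if (length(ga) != 1L) next
    if (mode == "single_copy" && length(gb) != 1L) next
    if (mode != "single_copy" && length(gb) < 1L) next
    a <- .bin_row(binA, ga)
    if (is.null(a) || !all(gb %in% rownames(binB))) next
    nA <- sum(a)
    if (mode %in% c("single_copy", "individual_ohnologue")) {
      for (g in gb) {
        nB <- sum(.bin_row(binB, g))
        rows[[length(rows) + 1L]] <- data.frame(
          family_id = fid, geneA = ga, geneB = g,
          domains_outgroup = nA, domains_vertebrate = nB,
          bias = nB - nA, mode = mode, stringsAsFactors = FALSE)
      }
    } else {
      if (mode == "union") {
        nB <- sum(apply(unclass(binB)[gb, , drop = FALSE], 2, max))
        lab <- "union"
      } else {
        s <- colSums(unclass(as.matrix(exprB_raw))[gb, , drop = FALSE])
        nB <- sum(s > thr)
        lab <- "sum"
      }
      rows[[length(rows) + 1L]] <- data.frame(
        family_id = fid, geneA = ga, geneB = lab,
        domains_outgroup = nA, domains_vertebrate = nB,
        bias = nB - nA, mode = mode, stringsAsFactors = FALSE)
    }
  }
  out <- rbind_rows(rows)
  if (is.null(out)) stop("no eligible family for mode ", mode)
  out
}

#' Log2 ratio of negative to positive bias counts
#'
#' log2(#negative / #positive) over a set of bias records; zeros are
#' excluded from both counts. A symmetric histogram gives ~0, an excess
#' of restricted vertebrate genes gives a positive value of
#' log2(neg/pos) (more negatives). If one side is empty the result is
#' signed infinity, with a warning.
#'
#' @param bias numeric vector of biases, or a [domain_bias()] data.frame.
#' @return single numeric (possibly +/-Inf).
#' @export
neg_pos_log_ratio <- function(bias) {
  if (is.data.frame(bias)) bias <- bias$bias
  nneg <- sum(bias < 0); npos <- sum(bias > 0)
  if (nneg == 0 || npos == 0) {
    warning("no ", if (nneg == 0) "negative" else "positive",
            " records: ratio is infinite")
    return(if (nneg == 0) -Inf else Inf)
  }
  log2(nneg / npos)
}

#' Classify post-WGD expression fates of ohnologue families
#'
#' Eligibility: the single outgroup member is "on" in all domains AND the
#' union of the vertebrate members is "on" in all domains (the ancestral
#' gene was thus broadly expressed). Fates: `redundancy` = all vertebrate
#' members on in all domains; `subfunctionalization` = no member on in
#' all domains; `specialization` = at least one member on in all domains
#' and at least one not. Specialization members are subtyped:
#' `spec_equal` (all domains retained), `spec_mild` (lost some, more than
#' 2 retained), `spec_strong` (<= 2 retained). Members of redundancy /
#' subfunctionalization families get subtype `full` / `restricted`.
#'
#' @inheritParams domain_bias
#' @return list with `fates` (data.frame `family_id`, `fate`,
#'   `n_members`), `members` (per-member `subtype`, `n_domains_on` and
#'   comma-separated `domains_on`), `frequencies` (fate proportions over
#'   eligible families), and `ineligible` (family ids with reasons).
#' @export
classify_fates <- function(binA, binB, fams, outgroup = fams$species[1],
                           vertebrate = fams$species[2]) {
  if (!identical(colnames(binA), colnames(binB)))
    stop("domain lists of the two binary profiles differ")
  nd <- ncol(binA)
  doms <- colnames(binA) %||% as.character(seq_len(nd))
  fate_rows <- list(); member_rows <- list(); inel <- list()
  for (fid in names(fams$families)) {
    f <- fams$families[[fid]]
    ga <- f[[outgroup]]; gb <- f[[vertebrate]]
    if (length(ga) != 1L || length(gb) < 2L) {
      inel[[fid]] <- "not an ohnologue family (need 1 outgroup, >=2 copies)"
      next
    }
    if (!ga %in% rownames(binA) || !all(gb %in% rownames(binB))) {
      inel[[fid]] <- "missing expression data for a member"
      next
    }
    a <- unclass(binA)[ga, ]
    B <- unclass(binB)[gb, , drop = FALSE]
    if (sum(a) < nd) { inel[[fid]] <- "outgroup gene not on in all domains"; next }
    if (sum(apply(B, 2, max)) < nd) {
      inel[[fid]] <- "union of vertebrate members not on in all domains"; next
    }
    full <- rowSums(B) == nd
    fate <- if (all(full)) "redundancy"
            else if (!any(full)) "subfunctionalization"
            else "specialization"
    subtype <- vapply(seq_along(gb), function(j) {
      n_on <- sum(B[j, ])
      if (fate == "specialization") {
        if (full[j]) "spec_equal"
        else if (n_on > 2) "spec_mild"
        else "spec_strong"
      } else if (fate == "redundancy") "full" else "restricted"
    }, character(1))
    fate_rows[[fid]] <- data.frame(family_id = fid, fate = fate,
                                   n_members = length(gb),
                                   stringsAsFactors = FALSE)
    member_rows[[fid]] <- data.frame(
      family_id = fid, gene_id = gb, fate = fate, subtype = subtype,
      n_domains_on = rowSums(B),
      domains_on = vapply(seq_along(gb), function(j)
        paste(doms[B[j, ] == 1], collapse = ","), character(1)),
      stringsAsFactors = FALSE)
  }
  fates <- rbind_rows(fate_rows)
  members <- rbind_rows(member_rows)
  freq <- if (!is.null(fates))
    prop.table(table(factor(fates$fate, c("redundancy", "subfunctionalization",
                                          "specialization"))))
  else table(factor(character(0), c("redundancy", "subfunctionalization",
                                    "specialization")))
  list(fates = fates, members = members, frequencies = freq,
       ineligible = inel)
}

#' Domain retention among strongly specialized ohnologues
#'
#' Counts, for each expression domain, how many `spec_strong` members
#' (<= 2 retained domains) remain expressed there; a member retaining
#' two domains contributes to both.
#'
#' @param fate_calls output of [classify_fates()].
#' @return named integer vector over domains.
#' @export
specialization_domain_retention <- function(fate_calls) {
  m <- fate_calls$members
  strong <- m[m$subtype == "spec_strong", , drop = FALSE]
  doms <- unlist(strsplit(strong$domains_on, ","))
  table(doms)
}

# Wilcoxon rank-sum with the determinism policy used across the package:
# exact enumeration when both groups are small (<= exact_max) and tie-free,
# normal approximation with continuity correction otherwise.
rank_sum_test <- function(x, y, alternative = "two.sided", exact_max = 25) {
  if (length(unique(c(x, y))) == 1) return(1)  # all-ties: no evidence
  exact <- length(x) <= exact_max && length(y) <= exact_max &&
    !anyDuplicated(c(x, y))
  stats::wilcox.test(x, y, alternative = alternative, exact = exact,
                     correct = TRUE)$p.value
}

#' Peak counts per fate subtype
#'
#' Joins per-gene regulatory-landscape peak counts onto fate-call members
#' and contrasts the specialization subtypes: one-sided rank-sum tests of
#' `spec_mild > spec_equal` and `spec_strong > spec_equal` (restricted
#' copies predicted to carry more peaks).
#'
#' @param fate_calls output of [classify_fates()].
#' @param counts named per-gene peak counts.
#' @return list with `by_subtype` (named list of count vectors) and
#'   `tests` (data.frame `contrast`, `alternative`, `p_value`; NA with a
#'   note when a group has < 2 members).
#' @export
fates_vs_apre_counts <- function(fate_calls, counts) {
  m <- fate_calls$members
  m <- m[m$gene_id %in% names(counts), , drop = FALSE]
  by_sub <- split(counts[m$gene_id], m$subtype)
  contrasts <- list(c("spec_mild", "spec_equal"),
                    c("spec_strong", "spec_equal"))
  tests <- do.call(rbind, lapply(contrasts, function(ct) {
    x <- by_sub[[ct[1]]]; y <- by_sub[[ct[2]]]
    if (length(x) < 2 || length(y) < 2)
      return(data.frame(contrast = paste(ct, collapse = " > "),
                        alternative = "greater", p_value = NA_real_,
                        note = "group size < 2: test skipped",
                        stringsAsFactors = FALSE))
    data.frame(contrast = paste(ct, collapse = " > "),
               alternative = "greater",
               p_value = rank_sum_test(x, y, "greater"), note = "",
               stringsAsFactors = FALSE)
  }))
  list(by_subtype = by_sub, tests = tests)
}

#' Sequence divergence per fate subtype
#'
#' Joins externally supplied per-gene sequence similarity (or dN/dS)
#' values onto fate-call members and tests all pairwise subtype
#' contrasts (two-sided rank-sum by default).
#'
#' @param similarities named numeric vector per vertebrate gene.
#' @param fate_calls output of [classify_fates()].
#' @param alternative passed to the rank-sum test.
#' @return list with `by_subtype`, `tests`, and `n_missing` (members
#'   without a similarity value, dropped).
#' @export
divergence_vs_fate <- function(similarities, fate_calls,
                               alternative = "two.sided") {
  m <- fate_calls$members
  n_missing <- sum(!m$gene_id %in% names(similarities))
  m <- m[m$gene_id %in% names(similarities), , drop = FALSE]
  by_sub <- split(similarities[m$gene_id], m$subtype)
  subs <- names(by_sub)
  tests <- list()
  if (length(subs) >= 2) {
    for (i in seq_len(length(subs) - 1)) for (j in (i + 1):length(subs)) {
      x <- by_sub[[subs[i]]]; y <- by_sub[[subs[j]]]
      p <- if (length(x) < 2 || length(y) < 2) NA_real_
           else rank_sum_test(x, y, alternative)
      tests[[length(tests) + 1L]] <- data.frame(
        groupA = subs[i], groupB = subs[j], alternative = alternative,
        p_value = p, stringsAsFactors = FALSE)
    }
  }
  list(by_subtype = by_sub,
       tests = rbind_rows(tests),
       n_missing = n_missing)
}
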