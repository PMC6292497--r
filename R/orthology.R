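# Gene families: loading, validation and filtering into the relationship
# classes (1-to-1 orthologues, post-WGD ohnologue families) that the
# comparative analyses consume. Family inference itself is out of scope;
# families arrive as a long-format table.

#' Construct a family set
#'
#' @param table data.frame with columns `family_id`, `species`, `gene_id`.
#' @param species optional species registry (character); defaults to the
#'   species present in the table. Rows with species outside the registry
#'   are rejected.
#' @return A `family_set`: list with `families` (named list:
#'   family_id -> list(species -> gene ids)), `species` registry, and
#'   `gene2family` lookup (named character vector).
#' @export
family_set <- function(table, species = NULL) {
  need <- c("family_id", "species", "gene_id")
  if (!all(need %in% names(table)))
    stop("family table needs columns: ", paste(need, collapse = ", "))
  table <- as.data.frame(table, stringsAsFactors = FALSE)
  if (is.null(species)) species <- sort(unique(as.character(table$species)))
  unknown <- setdiff(unique(table$species), species)
  if (length(unknown))
    stop("unknown species outside registry: ", paste(unknown, collapse = ", "))
  if (nrow(table) == 0) {
    warning("empty family table: returning empty family_set")
    return(structure(list(families = list(), species = species,
                          gene2family = character(0)),
                     class = "family_set"))
  }
  # a gene must belong to exactly one family
  g2f <- unique(table[, c("gene_id", "family_id")])
  dup <- unique(g2f$gene_id[duplicated(g2f$gene_id)])
  if (length(dup))
    stop("gene(s) assigned to more than one family: ",
         paste(dup, collapse = ", "))
  fams <- lapply(split(table, table$family_id), function(d)
    lapply(split(as.character(d$gene_id), as.character(d$species)), unique))
  lookup <- stats::setNames(as.character(g2f$family_id), g2f$gene_id)
  structure(list(families = fams, species = species, gene2family = lookup),
            class = "family_set")
}

#' @export
print.family_set <- function(x, ...) {
  cat(sprintf("family_set: %d families, %d genes, species: %s\n",
              length(x$families), length(x$gene2family),
              paste(x$species, collapse = ", ")))
  invisible(x)
}

#' Read a gene-family table
#'
#' TSV with columns `family_id`, `species`, `gene_id`; one row per gene.
#'
#' @inheritParams family_set
#' @param path file path.
#' @return A [family_set()].
#' @export
read_family_table <- function(path, species = NULL) {
  family_set(read_tsv_table(path), species = species)
}

#' @rdname read_family_table
#' @param fams a `family_set`.
#' @export
write_family_table <- function(fams, path) {
  rows <- do.call(rbind, lapply(names(fams$families), function(fid) {
    f <- fams$families[[fid]]
    do.call(rbind, lapply(names(f), function(sp)
      data.frame(family_id = fid, species = sp, gene_id = f[[sp]],
                 stringsAsFactors = FALSE)))
  }))
  if (is.null(rows))
    rows <- data.frame(family_id = character(0), species = character(0),
                       gene_id = character(0))
  write_tsv_table(rows, path)
}

#' Single-copy orthologue pairs
#'
#' Families with exactly one member in each of the two requested species.
#'
#' @param fams a [family_set()].
#' @param spA,spB species names (must be in the registry).
#' @return data.frame with columns `family_id`, `geneA`, `geneB`.
#' @export
one_to_one_pairs <- function(fams, spA, spB) {
  stopifnot(inherits(fams, "family_set"))
  for (sp in c(spA, spB))
    if (!sp %in% fams$species) stop("species not in registry: ", sp)
  keep <- vapply(fams$families, function(f)
    length(f[[spA]]) == 1L && length(f[[spB]]) == 1L, logical(1))
  ids <- names(fams$families)[keep]
  data.frame(
    family_id = ids,
    geneA = vapply(fams$families[ids], function(f) f[[spA]], character(1)),
    geneB = vapply(fams$families[ids], function(f) f[[spB]], character(1)),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' High-confidence ohnologue families
#'
#' Families with exactly one member in the outgroup species and between
#' `min_copies` and `max_copies` members in the vertebrate species
#' (default 2-4, the retention range expected from two rounds of WGD).
#'
#' @param fams a [family_set()].
#' @param outgroup,vertebrate species names.
#' @param min_copies,max_copies vertebrate copy-number bounds.
#' @return A filtered [family_set()] restricted to the two species.
#' @export
ohnologue_families <- function(fams, outgroup, vertebrate,
                               min_copies = 2, max_copies = 4) {
  stopifnot(inherits(fams, "family_set"))
  if (identical(outgroup, vertebrate))
    stop("outgroup and vertebrate species must differ")
  for (sp in c(outgroup, vertebrate))
    if (!sp %in% fams$species) stop("species not in registry: ", sp)
  keep <- vapply(fams$families, function(f) {
    nv <- length(f[[vertebrate]])
    length(f[[outgroup]]) == 1L && nv >= min_copies && nv <= max_copies
  }, logical(1))
  sel <- fams$families[keep]
  sel <- lapply(sel, function(f) f[c(outgroup, vertebrate)])
  genes <- unlist(lapply(sel, unlist), use.names = FALSE)
  fid <- rep(names(sel), vapply(sel, function(f) length(unlist(f)), integer(1)))
  structure(list(families = sel, species = c(outgroup, vertebrate),
                 gene2family = stats::setNames(fid, genes)),
            class = "family_set")
}
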