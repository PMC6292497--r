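# Expression normalisation, binarisation and tissue-specificity scoring.
# All downstream comparative stages consume the containers defined here.

#' Construct an expression matrix
#'
#' A light S3 wrapper around a genes x samples numeric matrix of
#' non-negative expression values (counts, TPM or cRPKM), carrying a units
#' tag. Values must be finite and non-negative; gene and sample identifiers
#' must be unique.
#'
#' @param values numeric matrix with rownames (gene ids) and colnames
#'   (sample ids).
#' @param units character tag, e.g. "counts", "TPM", "cRPKM".
#' @return An object of class `expression_matrix` (a numeric matrix with a
#'   `units` attribute).
#' @export
expression_matrix <- function(values, units = "TPM") {
  values <- as.matrix(values)
  if (!is.numeric(values)) stop("expression values must be numeric")
  if (anyNA(values) || any(!is.finite(values)))
    stop("expression values must be finite")
  if (any(values < 0)) stop("expression values must be non-negative")
  if (is.null(rownames(values)) || anyDuplicated(rownames(values)))
    stop("gene ids (rownames) must be present and unique")
  if (is.null(colnames(values)) || anyDuplicated(colnames(values)))
    stop("sample ids (colnames) must be present and unique")
  attr(values, "units") <- units
  class(values) <- c("expression_matrix", class(values))
  values
}

#' Compute cRPKM (mappability-corrected RPKM)
#'
#' cRPKM = reads / (mappable length in kb) / (library size in millions):
#' reads per kilobase of mappable positions per million mapped reads.
#'
#' @param counts integer genes x samples matrix of read counts.
#' @param mappable_len_bp per-gene mappable length in bp (named or in row
#'   order), all > 0.
#' @param library_sizes per-sample total mapped reads (named or in column
#'   order), all > 0.
#' @return An `expression_matrix` with units "cRPKM".
#' @export
compute_crpkm <- function(counts, mappable_len_bp, library_sizes) {
  counts <- as.matrix(counts)
  if (any(counts < 0)) stop("negative counts are not allowed")
  if (!is.null(names(mappable_len_bp)))
    mappable_len_bp <- mappable_len_bp[rownames(counts)]
  if (!is.null(names(library_sizes)))
    library_sizes <- library_sizes[colnames(counts)]
  if (length(mappable_len_bp) != nrow(counts))
    stop("mappable_len_bp must have one entry per gene")
  if (length(library_sizes) != ncol(counts))
    stop("library_sizes must have one entry per sample")
  bad <- which(!(mappable_len_bp > 0))
  if (length(bad))
    stop("zero or negative mappable length for gene(s): ",
         paste(rownames(counts)[bad], collapse = ", "))
  if (any(library_sizes <= 0)) stop("library sizes must be positive")
  v <- counts / (mappable_len_bp / 1000)
  v <- sweep(v, 2, library_sizes / 1e6, "/")
  expression_matrix(v, units = "cRPKM")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every sample (column) onto the common distribution given by the
#' across-sample mean of order statistics; within-sample ranks are
#' preserved. Ties receive the mean of the reference values over the rank
#' span they occupy, which makes the transform deterministic and
#' idempotent.
#'
#' @param matrix genes x samples numeric matrix (or `expression_matrix`).
#' @return matrix of the same shape and dimnames; `expression_matrix` input
#'   keeps its class and units tag.
#' @export
quantile_normalize <- function(matrix) {
  x <- unclass(as.matrix(matrix))
  if (ncol(x) < 2) stop("quantile normalization needs at least 2 samples")
  if (anyNA(x)) stop("samples with missing values (unequal gene sets) rejected")
  ref <- rowMeans(apply(x, 2, sort))
  out <- apply(x, 2, function(col) {
    lo <- rank(col, ties.method = "min")
    hi <- rank(col, ties.method = "max")
    # mean of the reference over the span of tied ranks
    csum <- cumsum(ref)
    (csum[hi] - c(0, csum)[lo]) / (hi - lo + 1)
  })
  dimnames(out) <- dimnames(x)
  if (inherits(matrix, "expression_matrix"))
    out <- expression_matrix(out, units = attr(matrix, "units"))
  out
}

#' Binarize expression across homologous domains
#'
#' A gene is "on" in a domain iff its normalized expression is strictly
#' greater than `threshold` (default 5, the cRPKM cut-off used for the
#' nine-domain comparisons). The comparison is strict: a value exactly
#' equal to the threshold is "off".
#'
#' @param matrix genes x domains numeric matrix of normalized expression.
#' @param threshold strict cut-off; default 5.
#' @return A `binary_profile`: 0/1 integer matrix with a `threshold`
#'   attribute.
#' @export
binarize <- function(matrix, threshold = 5) {
  x <- unclass(as.matrix(matrix))
  if (any(x < 0)) stop("negative expression values rejected")
  out <- (x > threshold) + 0L
  dimnames(out) <- dimnames(x)
  attr(out, "threshold") <- threshold
  class(out) <- c("binary_profile", class(out))
  out
}

#' Tissue-specificity index tau
#'
#' tau = sum(1 - x_i/max(x)) / (n - 1) over n domains; 0 for perfectly
#' uniform expression, 1 for expression confined to a single domain.
#'
#' @param expression_per_domain non-negative numeric vector, length >= 2.
#' @return A list with `tau`, `n`, and `xhat` (per-domain expression scaled
#'   to max 1), or `NULL` (with a message attribute) for an all-zero input
#'   where tau is undefined.
#' @export
tau_index <- function(expression_per_domain) {
  x <- as.numeric(expression_per_domain)
  n <- length(x)
  if (n < 2) stop("tau needs at least 2 domains")
  if (any(x < 0)) stop("expression must be non-negative")
  if (max(x) == 0) {
    warning("all-zero expression vector: tau undefined, returning NULL")
    return(NULL)
  }
  xhat <- x / max(x)
  list(tau = sum(1 - xhat) / (n - 1), n = n, xhat = xhat)
}

#' Read / write expression matrices as TSV
#'
#' First column `gene_id`, then one column per sample.
#'
#' @param path file path.
#' @param x matrix to write.
#' @param units units tag applied on read.
#' @return `read_expression_tsv()` returns an `expression_matrix`.
#' @export
read_expression_tsv <- function(path, units = "TPM") {
  df <- read_tsv_table(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  expression_matrix(m, units = units)
}

#' @rdname read_expression_tsv
#' @export
write_expression_tsv <- function(x, path) {
  df <- data.frame(gene_id = rownames(x), unclass(as.matrix(x)),
                   check.names = FALSE)
  write_tsv_table(df, path)
}
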