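#' @keywords internal
"_PACKAGE"

# Deterministic sub-stream seeds: one master seed spawns an independent,
# named stream per generator so adding a generator does not perturb others.
# Seeds stay below 2^31-1 (R integers are 32-bit).
sub_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  h <- 0
  for (cp in utf8ToInt(stream)) h <- (h * 31 + cp) %% 1000003
  as.integer((abs(seed) * 1009 + h * 97 + 17) %% 2147483647)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Read / write a tab-separated table
#'
#' Thin wrappers pinning the TSV dialect used throughout the package:
#' header row, tab separator, no quoting, no row names.
#'
#' @param path file path (plain text or gzip).
#' @param x data.frame to write.
#' @return `read_tsv_table()` returns a data.frame.
#' @export
read_tsv_table <- function(path) {
  utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

#' @rdname read_tsv_table
#' @export
write_tsv_table <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared argument check
.check_prob <- function(p, name, tol = 1e-9) {
  if (any(p < 0) || abs(sum(p) - 1) > tol)
    stop(sprintf("'%s' must be non-negative and sum to 1 (got sum %.12f)",
                 name, sum(p)), call. = FALSE)
  invisible(TRUE)
}

# rbind a list of data.frames, returning NULL when the list is empty
# (avoids base::rbind swallowing make.row.names as data)
rbind_rows <- function(rows) {
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) return(NULL)
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}
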