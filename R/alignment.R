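# Alignment container and global column aliasing.

#' Construct an alignment
#'
#' @param matrix character matrix, rows = sequences, columns = sites;
#'   entries in `A C G T N -` (uppercased on input).
#' @param names sequence names (default rownames or `seq1..seqn`).
#' @param invariant_counts optional named numeric vector (`A C G T`) of
#'   monomorphic columns not represented in `matrix` (used by the
#'   variant-only VCF import mode; see [read_vcf_haplotypes()]).
#' @return an object of class `alignment`.
#' @export
alignment <- function(matrix, names = NULL,
                      invariant_counts = c(A = 0, C = 0, G = 0, T = 0)) {
  if (!is.matrix(matrix) || !is.character(matrix)) {
    stop("`matrix` must be a character matrix")
  }
  matrix <- toupper(matrix)
  bad <- !matrix %in% c("A", "C", "G", "T", "N", "-")
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)[1, ]
    stop(sprintf("illegal character '%s' at row %d, column %d",
                 matrix[bad][1], idx[1], idx[2]))
  }
  if (is.null(names)) {
    names <- if (!is.null(rownames(matrix))) rownames(matrix) else
      paste0("seq", seq_len(nrow(matrix)))
  }
  if (length(names) != nrow(matrix)) stop("one name per sequence required")
  rownames(matrix) <- NULL
  structure(
    list(
      names = as.character(names), matrix = matrix,
      alias = NULL, patterns = NULL, pattern_counts = NULL,
      invariant_counts = invariant_counts[c("A", "C", "G", "T")]
    ),
    class = "alignment"
  )
}

#' @export
print.alignment <- function(x, ...) {
  cat(sprintf("alignment: %d sequences x %d sites", nrow(x$matrix), ncol(x$matrix)))
  if (!is.null(x$alias)) cat(sprintf(", %d unique column patterns", ncol(x$patterns)))
  inv <- sum(x$invariant_counts)
  if (isTRUE(inv > 0)) cat(sprintf(" (+%d invariant columns folded in)", inv))
  cat("\n")
  invisible(x)
}

#' Alias identical alignment columns
#'
#' Identifies identical columns so the likelihood is computed once per
#' unique pattern and weighted by multiplicity.  Aliasing is a pure
#' relabeling: the de-aliased likelihood is identical.
#'
#' @param alignment an [alignment()] object.
#' @return the alignment with `alias` (column -> pattern index),
#'   `patterns` (n x P matrix of unique columns) and `pattern_counts`
#'   filled in.
#' @export
alias_columns <- function(alignment) {
  stopifnot(inherits(alignment, "alignment"))
  m <- alignment$matrix
  keys <- apply(m, 2, paste, collapse = "")
  uk <- unique(keys)
  alias <- match(keys, uk)
  first_col <- match(uk, keys)
  alignment$alias <- alias
  alignment$patterns <- m[, first_col, drop = FALSE]
  alignment$pattern_counts <- as.integer(table(factor(alias, levels = seq_along(uk))))
  alignment
}

#' Number of sites (columns) in an alignment
#' @param alignment an [alignment()] object.
#' @return integer.
#' @export
n_sites <- function(alignment) ncol(alignment$matrix)
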