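# Half-open site-interval utilities.
#
# A site-interval set is an integer matrix with two columns, `start`
# (inclusive) and `end` (exclusive), 0-based, sorted, non-overlapping and
# maximally merged (no two rows are adjacent).  The empty set is a 0-row
# matrix.

iv_empty <- function() {
  matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

iv <- function(start, end) {
  m <- cbind(start = as.integer(start), end = as.integer(end))
  iv_normalize(m)
}

# sort, drop empty rows, merge overlapping/adjacent rows
iv_normalize <- function(m) {
  m <- m[m[, 1] < m[, 2], , drop = FALSE]
  if (nrow(m) == 0L) return(iv_empty())
  m <- m[order(m[, 1]), , drop = FALSE]
  out <- m[1, , drop = FALSE]
  if (nrow(m) > 1L) {
    for (i in 2:nrow(m)) {
      k <- nrow(out)
      if (m[i, 1] <= out[k, 2]) {
        out[k, 2] <- max(out[k, 2], m[i, 2])
      } else {
        out <- rbind(out, m[i, , drop = FALSE])
      }
    }
  }
  dimnames(out) <- list(NULL, c("start", "end"))
  out
}

iv_union <- function(a, b) iv_normalize(rbind(a, b))

iv_intersect <- function(a, b) {
  if (nrow(a) == 0L || nrow(b) == 0L) return(iv_empty())
  rows <- list()
  for (i in seq_len(nrow(a))) {
    s <- pmax(a[i, 1], b[, 1])
    e <- pmin(a[i, 2], b[, 2])
    keep <- s < e
    if (any(keep)) rows[[length(rows) + 1L]] <- cbind(s[keep], e[keep])
  }
  if (length(rows) == 0L) return(iv_empty())
  iv_normalize(do.call(rbind, rows))
}

# split at breakpoint b: left = sites < b, right = sites >= b
iv_split <- function(m, b) {
  list(
    left = iv_intersect(m, iv(0L, b)),
    right = iv_intersect(m, iv(b, .Machine$integer.max))
  )
}

iv_contains <- function(m, site) {
  nrow(m) > 0L && any(m[, 1] <= site & site < m[, 2])
}

iv_overlaps <- function(a, b) nrow(iv_intersect(a, b)) > 0L

iv_width <- function(m) if (nrow(m) == 0L) 0L else sum(m[, 2] - m[, 1])

iv_min <- function(m) if (nrow(m) == 0L) NA_integer_ else m[1, 1]

iv_max <- function(m) if (nrow(m) == 0L) NA_integer_ else m[nrow(m), 2] - 1L

# number of eligible breakpoint gaps: gaps strictly inside
# [leftmost, rightmost] ancestral site, Hudson-style
iv_span <- function(m) {
  if (nrow(m) == 0L) return(0L)
  iv_max(m) - iv_min(m)
}
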