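# Full (Felsenstein) likelihood of an alignment given an ARG.
#
# The production path runs in C++: pruning over marginal-tree intervals
# with global column aliasing, per-node scaling, and interval-level caching
# keyed by the site ranges a proposal affects.  An independent plain-tree
# pruning implementation in R (tree_log_likelihood) serves as the external
# oracle: summing its marginal-tree log-likelihoods must reproduce the
# engine's full ARG log-likelihood.

#' ARG log-likelihood of an alignment
#'
#' Computes the full Felsenstein log-likelihood of the ARG: the sum over
#' marginal-tree intervals of the (interval-restricted) standard tree
#' log-likelihoods.  Gaps and `N` are treated as missing data (all-ones
#' tip vectors).
#'
#' @param arg an [new_arg()] object; tip labels must match the alignment
#'   names (tips are matched by position: tip id `i` is alignment row `i`).
#' @param alignment an [alignment()] object with `L` equal to the ARG's.
#' @param model a [substitution_model()].
#' @return log-likelihood (natural log), a finite scalar.
#' @export
arg_log_likelihood <- function(arg, alignment, model) {
  .check_arg_aln(arg, alignment)
  pop <- population_model(theta0 = 1)
  rec <- recombination_model(rho = 0)
  res <- cpp_arg_loglik(.arg_to_cpp(arg), .aln_to_cpp(alignment),
                        .params_to_cpp(pop, rec, model))
  res$loglik
}

.check_arg_aln <- function(arg, alignment) {
  if (ncol(alignment$matrix) != arg$L) {
    stop(sprintf("alignment has %d sites but ARG expects L = %d",
                 ncol(alignment$matrix), arg$L))
  }
  if (nrow(alignment$matrix) != arg$n_tips) {
    stop(sprintf("alignment has %d sequences but ARG has %d tips",
                 nrow(alignment$matrix), arg$n_tips))
  }
  if (!identical(as.character(alignment$names), as.character(arg$tip_labels))) {
    stop("alignment names do not match ARG tip labels")
  }
  invisible(TRUE)
}

#' Plain-tree pruning log-likelihood (reference implementation)
#'
#' Independent R implementation of Felsenstein pruning on a single
#' marginal tree, used as the external oracle for the engine's ARG
#' likelihood.  Vectorized over columns with per-node rescaling.
#'
#' @param tree a [extract_marginal_tree()] result.
#' @param columns character matrix (rows = tips in tip-id order, one
#'   column per site) over `A C G T N -`.
#' @param model a [substitution_model()].
#' @return numeric vector of per-column log-likelihoods.
#' @export
tree_log_likelihood <- function(tree, columns, model) {
  n <- tree$n_tips
  stopifnot(nrow(columns) == n)
  k <- ncol(columns)
  if (k == 0L) return(numeric(0))
  ord <- tree$node_ids[order(tree$heights, tree$node_ids)]
  partial <- vector("list", length(tree$node_ids))
  names(partial) <- tree$node_ids
  slog <- lapply(stats::setNames(tree$node_ids, tree$node_ids),
                 function(i) numeric(k))
  children <- split(
    tree$node_ids[!is.na(tree$parent)],
    tree$parent[!is.na(tree$parent)]
  )
  code <- function(ch) {
    v <- matrix(0, 4, length(ch), dimnames = list(c("A", "C", "G", "T"), NULL))
    known <- ch %in% c("A", "C", "G", "T")
    v[, !known] <- 1
    v[cbind(match(ch[known], c("A", "C", "G", "T")), which(known))] <- 1
    v
  }
  for (id in ord) {
    key <- as.character(id)
    if (id <= n) {
      partial[[key]] <- code(columns[id, ])
    } else {
      kids <- children[[key]]
      acc <- matrix(1, 4, k)
      sl <- numeric(k)
      for (ch in kids) {
        bl <- tree$heights[[key]] - tree$heights[[as.character(ch)]]
        P <- transition_matrix(model, bl)
        acc <- acc * (P %*% partial[[as.character(ch)]])
        sl <- sl + slog[[as.character(ch)]]
      }
      mx <- apply(acc, 2, max)
      scale_cols <- mx > 0 & mx < 1e-240
      if (any(scale_cols)) {
        acc[, scale_cols] <- sweep(acc[, scale_cols, drop = FALSE], 2,
                                   mx[scale_cols], "/")
        sl[scale_cols] <- sl[scale_cols] + log(mx[scale_cols])
      }
      partial[[key]] <- acc
      slog[[key]] <- sl
    }
  }
  root <- as.character(tree$root)
  pi <- as.numeric(unclass(model$freqs))
  lik <- as.numeric(pi %*% partial[[root]])
  log(lik) + slog[[root]]
}

#' Reference ARG log-likelihood via marginal trees
#'
#' Sums interval-restricted plain-tree log-likelihoods over the marginal
#' trees of the ARG; independent of the C++ engine code path.
#'
#' @inheritParams arg_log_likelihood
#' @return log-likelihood scalar.
#' @export
arg_log_likelihood_reference <- function(arg, alignment, model) {
  .check_arg_aln(arg, alignment)
  mt <- marginal_trees(arg)
  total <- 0
  inv <- alignment$invariant_counts
  has_inv <- !is.null(inv) && sum(inv) > 0
  for (entry in mt) {
    sites <- seq.int(entry$interval[1] + 1L, entry$interval[2]) # 1-based cols
    cols <- alignment$matrix[, sites, drop = FALSE]
    keys <- apply(cols, 2, paste, collapse = "")
    tab <- table(keys)
    ucols <- cols[, match(names(tab), keys), drop = FALSE]
    ll <- tree_log_likelihood(entry$tree, ucols, model)
    total <- total + sum(as.integer(tab) * ll)
    if (has_inv) {
      w <- (entry$interval[2] - entry$interval[1]) / arg$L
      const_cols <- matrix(rep(c("A", "C", "G", "T"), each = arg$n_tips),
                           nrow = arg$n_tips)
      llc <- tree_log_likelihood(entry$tree, const_cols, model)
      total <- total + w * sum(inv * llc)
    }
  }
  total
}

# ------------------------------------------------------------------ caching

#' Create a likelihood context with partial-recomputation bookkeeping
#'
#' The context caches one log-likelihood per marginal-tree interval.
#' [mark_dirty()] flags the intervals whose site ranges intersect a
#' perturbation (given as node ids, site intervals, or both) and
#' [recompute()] recomputes only the flagged intervals, counting how many
#' interval evaluations were performed.
#'
#' @param arg,alignment,model as in [arg_log_likelihood()].
#' @return an environment of class `lik_context`.
#' @export
lik_context <- function(arg, alignment, model) {
  .check_arg_aln(arg, alignment)
  if (is.null(arg$material)) arg <- annotate_ancestral_material(arg)
  ctx <- new.env(parent = emptyenv())
  ctx$arg <- arg
  ctx$model <- model
  ctx$aln_cpp <- .aln_to_cpp(alignment)
  ctx$params_cpp <- .params_to_cpp(population_model(1), recombination_model(0), model)
  bps <- sort(unique(arg$nodes$breakpoint[arg$nodes$kind == "recombination"]))
  ctx$starts <- c(0L, bps)
  ctx$ends <- c(bps, arg$L)
  ctx$interval_ll <- rep(NA_real_, length(ctx$starts))
  ctx$dirty <- rep(TRUE, length(ctx$starts))
  ctx$n_interval_evals <- 0L
  class(ctx) <- "lik_context"
  ctx
}

#' Mark nodes and site ranges dirty in a likelihood context
#'
#' Flags every cached interval whose sites intersect either the ancestral
#' material of the named nodes (and hence of all their root-ward ancestors
#' over those sites) or the site intervals given explicitly.
#'
#' @param ctx a [lik_context()].
#' @param nodes integer node ids (optional).
#' @param intervals two-column matrix of half-open 0-based site intervals
#'   (optional).
#' @return the context, invisibly.
#' @export
mark_dirty <- function(ctx, nodes = NULL, intervals = NULL) {
  stopifnot(inherits(ctx, "lik_context"))
  ranges <- if (is.null(intervals)) iv_empty() else
    iv_normalize(cbind(as.integer(intervals[, 1]), as.integer(intervals[, 2])))
  for (id in nodes) {
    if (is.na(id) || id < 1L || id > nrow(ctx$arg$nodes)) {
      stop(sprintf("unknown node id %s", id))
    }
    ranges <- iv_union(ranges, ctx$arg$material[[id]])
  }
  if (nrow(ranges) > 0L) {
    for (i in seq_along(ctx$starts)) {
      if (iv_overlaps(ranges, iv(ctx$starts[i], ctx$ends[i]))) ctx$dirty[i] <- TRUE
    }
  }
  invisible(ctx)
}

#' Recompute dirty intervals and return the ARG log-likelihood
#'
#' Clean cache entries are reused untouched; the context's
#' `n_interval_evals` counter exposes how many interval evaluations the
#' call performed (zero when nothing is dirty).
#'
#' @param ctx a [lik_context()].
#' @return the total log-likelihood.
#' @export
recompute <- function(ctx) {
  stopifnot(inherits(ctx, "lik_context"))
  arg_cpp <- .arg_to_cpp(ctx$arg)
  for (i in which(ctx$dirty)) {
    ctx$interval_ll[i] <- cpp_interval_loglik(
      arg_cpp, ctx$aln_cpp, ctx$params_cpp, ctx$starts[i], ctx$ends[i]
    )
    ctx$n_interval_evals <- ctx$n_interval_evals + 1L
    ctx$dirty[i] <- FALSE
  }
  sum(ctx$interval_ll)
}
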