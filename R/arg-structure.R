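# The ARG data model.
#
# An ARG (ancestral recombination graph) is a rooted, height-directed graph
# over timed nodes.  Tips sit at height 0; coalescent nodes have two
# children and at most one parent; recombination nodes have one child, two
# parents, and a breakpoint b in [1, L-1]: sites with index < b follow
# parent 1, sites >= b follow parent 2 (0-based sites, half-open
# intervals).  Exactly one node, the grand MRCA, has no parent.
#
# Node bookkeeping: `nodes` is a data frame whose row number equals the
# node id.  `material[[id]]` is the ancestral material carried on the
# node's child-side edge (set by annotate_ancestral_material).

.KINDS <- c("tip", "coalescent", "recombination")

#' Construct an ARG from a node table
#'
#' @param nodes data frame with columns `height` (numeric), `kind`
#'   (`"tip"`, `"coalescent"` or `"recombination"`), `child1`, `child2`,
#'   `parent1`, `parent2` (integer node ids or `NA`), `breakpoint`
#'   (integer site in `[1, L-1]` for recombination nodes, `NA` otherwise).
#'   Row number is the node id; tips must occupy rows `1..n_tips`.
#' @param n_tips number of sampled sequences.
#' @param L alignment length in sites.
#' @param tip_labels character vector of length `n_tips`.
#' @return an object of class `arg`.
#' @export
new_arg <- function(nodes, n_tips, L, tip_labels = paste0("t", seq_len(n_tips))) {
  need <- c("height", "kind", "child1", "child2", "parent1", "parent2", "breakpoint")
  missing_cols <- setdiff(need, names(nodes))
  if (length(missing_cols) > 0L) {
    stop("`nodes` lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  nodes <- as.data.frame(nodes)[, need]
  nodes$height <- as.numeric(nodes$height)
  nodes$kind <- as.character(nodes$kind)
  for (col in c("child1", "child2", "parent1", "parent2", "breakpoint")) {
    nodes[[col]] <- as.integer(nodes[[col]])
  }
  nodes$id <- seq_len(nrow(nodes))
  structure(
    list(
      nodes = nodes, n_tips = as.integer(n_tips), L = as.integer(L),
      tip_labels = as.character(tip_labels), material = NULL
    ),
    class = "arg"
  )
}

#' @export
print.arg <- function(x, ...) {
  nrec <- sum(x$nodes$kind == "recombination")
  cat(sprintf(
    "ARG: %d tips, %d nodes (%d recombination), L = %d sites, root height %.6g\n",
    x$n_tips, nrow(x$nodes), nrec, x$L, max(x$nodes$height)
  ))
  invisible(x)
}

#' Number of recombination nodes in an ARG
#' @param arg an [new_arg()] object.
#' @return integer count.
#' @export
n_recombinations <- function(arg) sum(arg$nodes$kind == "recombination")

#' ARG root (grand MRCA) height
#' @param arg an [new_arg()] object.
#' @return numeric height in expected substitutions per site.
#' @export
arg_root_height <- function(arg) max(arg$nodes$height)

.children_of <- function(nodes, id) {
  ch <- c(nodes$child1[id], nodes$child2[id])
  ch[!is.na(ch)]
}

.parents_of <- function(nodes, id) {
  pa <- c(nodes$parent1[id], nodes$parent2[id])
  pa[!is.na(pa)]
}

#' Validate an ARG
#'
#' Checks every structural invariant and returns a character vector of
#' violation descriptions (empty if the ARG is valid).  Diagnostics are
#' returned, never raised, so that proposal code can probe candidate
#' states.
#'
#' @param arg an [new_arg()] object.
#' @return character vector, empty iff valid; each entry names the node id
#'   and the rule broken.
#' @export
validate_arg <- function(arg) {
  v <- character(0)
  nd <- arg$nodes
  n <- nrow(nd)
  if (length(arg$tip_labels) != arg$n_tips) {
    v <- c(v, sprintf("tip_labels has length %d, expected n_tips = %d",
                      length(arg$tip_labels), arg$n_tips))
  }
  for (i in seq_len(n)) {
    k <- nd$kind[i]
    if (!k %in% .KINDS) {
      v <- c(v, sprintf("node %d: unknown kind '%s'", i, k))
      next
    }
    if (!is.finite(nd$height[i]) || nd$height[i] < 0) {
      v <- c(v, sprintf("node %d: height must be finite and >= 0", i))
    }
    nch <- length(.children_of(nd, i))
    npa <- length(.parents_of(nd, i))
    if (k == "tip") {
      if (i > arg$n_tips) v <- c(v, sprintf("node %d: tip outside rows 1..n_tips", i))
      if (nd$height[i] != 0) v <- c(v, sprintf("node %d: tip height must be 0", i))
      if (nch != 0L) v <- c(v, sprintf("node %d: tip must have 0 children", i))
      if (npa != 1L) v <- c(v, sprintf("node %d: tip must have exactly 1 parent", i))
    } else if (k == "coalescent") {
      if (nch != 2L) v <- c(v, sprintf("node %d: coalescent must have 2 children", i))
      if (npa > 1L) v <- c(v, sprintf("node %d: coalescent must have <= 1 parent", i))
    } else {
      if (nch != 1L) v <- c(v, sprintf("node %d: recombination must have 1 child", i))
      if (npa != 2L) v <- c(v, sprintf("node %d: recombination must have 2 parents", i))
      bp <- nd$breakpoint[i]
      if (is.na(bp) || bp < 1L || bp > arg$L - 1L) {
        v <- c(v, sprintf("node %d: breakpoint must lie in [1, L-1]", i))
      }
    }
    for (p in .parents_of(nd, i)) {
      if (p < 1L || p > n) {
        v <- c(v, sprintf("node %d: parent %d does not exist", i, p))
      } else {
        if (nd$height[p] <= nd$height[i]) {
          v <- c(v, sprintf("node %d: parent %d not strictly higher", i, p))
        }
        if (!i %in% .children_of(nd, p)) {
          v <- c(v, sprintf("node %d: parent %d does not list it as child", i, p))
        }
      }
    }
    for (ch in .children_of(nd, i)) {
      if (ch < 1L || ch > n) {
        v <- c(v, sprintf("node %d: child %d does not exist", i, ch))
      } else if (!i %in% .parents_of(nd, ch)) {
        v <- c(v, sprintf("node %d: child %d does not list it as parent", i, ch))
      }
    }
  }
  roots <- which(vapply(seq_len(n), function(i) length(.parents_of(nd, i)) == 0L, logical(1)))
  if (length(roots) != 1L) {
    v <- c(v, sprintf("expected exactly one parentless node (grand MRCA), found %d (%s)",
                      length(roots), paste(roots, collapse = ",")))
  }
  # connectivity: every node reachable from tips by parent edges, and every
  # non-tip reachable from the root by child edges
  if (length(v) == 0L) {
    seen <- rep(FALSE, n)
    frontier <- seq_len(arg$n_tips)
    seen[frontier] <- TRUE
    while (length(frontier) > 0L) {
      nxt <- unique(unlist(lapply(frontier, function(i) .parents_of(nd, i))))
      nxt <- nxt[!seen[nxt]]
      seen[nxt] <- TRUE
      frontier <- nxt
    }
    if (!all(seen)) {
      v <- c(v, sprintf("nodes not connected to the tips: %s",
                        paste(which(!seen), collapse = ",")))
    }
  }
  v
}

# routed parent of node `id` at 0-based `site`
.route_parent <- function(nd, id, site) {
  if (nd$kind[id] == "recombination") {
    if (site < nd$breakpoint[id]) nd$parent1[id] else nd$parent2[id]
  } else {
    nd$parent1[id]
  }
}

#' Extract the marginal tree at a site
#'
#' Routes each tip root-ward, choosing parent 1 at recombination nodes when
#' `site < breakpoint` and parent 2 otherwise, then suppresses unary nodes
#' (summing branch segments).  The returned tree's root is the marginal
#' MRCA of the sample at that site.
#'
#' @param arg an [new_arg()] object.
#' @param site 0-based site index in `[0, L)`.
#' @return an object of class `marginal_tree` with fields `site`, `tmrca`,
#'   `heights` (named by ARG node id), `parent` (tree parent, by ARG node
#'   id), `node_ids` (ARG ids of retained nodes) and `tip_labels`.
#' @export
extract_marginal_tree <- function(arg, site) {
  site <- as.integer(site)
  if (is.na(site) || site < 0L || site >= arg$L) {
    stop(sprintf("site %d out of range [0, %d)", site, arg$L))
  }
  nd <- arg$nodes
  n <- nrow(nd)
  # count routed children per node
  child_count <- integer(n)
  active <- rep(FALSE, n)
  for (tip in seq_len(arg$n_tips)) {
    id <- tip
    active[id] <- TRUE
    repeat {
      p <- .route_parent(nd, id, site)
      if (is.na(p)) break
      child_count[p] <- child_count[p] + 1L
      if (active[p]) break  # already walked from p upward
      active[p] <- TRUE
      id <- p
    }
  }
  binary <- active & child_count == 2L
  keep <- which(binary | (seq_len(n) <= arg$n_tips))
  parent <- stats::setNames(rep(NA_integer_, length(keep)), keep)
  for (id in keep) {
    p <- .route_parent(nd, id, site)
    while (!is.na(p) && !binary[p]) p <- .route_parent(nd, p, site)
    parent[as.character(id)] <- p
  }
  root <- keep[is.na(parent)]
  structure(
    list(
      site = site,
      tmrca = nd$height[root],
      node_ids = keep,
      heights = stats::setNames(nd$height[keep], keep),
      parent = parent,
      root = root,
      n_tips = arg$n_tips,
      tip_labels = arg$tip_labels
    ),
    class = "marginal_tree"
  )
}

#' Convert a marginal tree to an ape "phylo"
#'
#' Branch lengths are in expected substitutions per site; suppressed unary
#' nodes never appear.
#'
#' @param tree a [extract_marginal_tree()] result.
#' @return an [ape::as.phylo] object with a `node.height` attribute.
#' @export
marginal_tree_to_phylo <- function(tree) {
  n <- tree$n_tips
  internal <- setdiff(tree$node_ids, seq_len(n))
  # root must get phylo number n + 1
  internal <- c(tree$root, setdiff(internal, tree$root))
  phylo_num <- stats::setNames(
    c(seq_len(n), n + seq_along(internal)),
    c(seq_len(n), internal)
  )
  nonroot <- tree$node_ids[tree$node_ids != tree$root]
  edge <- cbind(
    phylo_num[as.character(tree$parent[as.character(nonroot)])],
    phylo_num[as.character(nonroot)]
  )
  edge_len <- tree$heights[as.character(tree$parent[as.character(nonroot)])] -
    tree$heights[as.character(nonroot)]
  phy <- structure(
    list(
      edge = unname(edge),
      edge.length = unname(edge_len),
      tip.label = tree$tip_labels,
      Nnode = length(internal)
    ),
    class = "phylo"
  )
  phy <- ape::reorder.phylo(phy, "cladewise")
  attr(phy, "node.height") <- unname(c(
    tree$heights[as.character(seq_len(n))],
    tree$heights[as.character(internal)]
  ))
  phy
}

#' @export
print.marginal_tree <- function(x, ...) {
  cat(sprintf(
    "marginal tree at site %d: %d tips, TMRCA = %.6g\n  %s\n",
    x$site, x$n_tips, x$tmrca, marginal_tree_newick(x)
  ))
  invisible(x)
}

#' Newick string of a marginal tree (branch lengths in subs/site)
#' @param tree a [extract_marginal_tree()] result.
#' @param digits significant digits for branch lengths.
#' @return character scalar.
#' @export
marginal_tree_newick <- function(tree, digits = 10) {
  children <- split(
    tree$node_ids[!is.na(tree$parent)],
    tree$parent[!is.na(tree$parent)]
  )
  rec <- function(id) {
    h <- tree$heights[[as.character(id)]]
    if (id <= tree$n_tips) {
      lab <- tree$tip_labels[id]
    } else {
      kids <- sort(children[[as.character(id)]])
      lab <- paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")")
    }
    p <- tree$parent[[as.character(id)]]
    if (is.na(p)) {
      paste0(lab, ";")
    } else {
      bl <- tree$heights[[as.character(p)]] - h
      paste0(lab, ":", sprintf("%.*g", digits, bl))
    }
  }
  rec(tree$root)
}

# canonical signature for tree identity (topology + heights, exact)
.tree_signature <- function(tree) {
  children <- split(
    tree$node_ids[!is.na(tree$parent)],
    tree$parent[!is.na(tree$parent)]
  )
  rec <- function(id) {
    if (id <= tree$n_tips) {
      sprintf("%d", id)
    } else {
      kids <- children[[as.character(id)]]
      parts <- sort(vapply(kids, rec, character(1)))
      sprintf("(%s):%.17g", paste(parts, collapse = ","),
              tree$heights[[as.character(id)]])
    }
  }
  rec(tree$root)
}

#' All marginal trees of an ARG
#'
#' Partitions `[0, L)` at the recombination breakpoints, extracts the
#' marginal tree of each interval, and merges adjacent intervals whose
#' trees are identical in topology and heights (e.g. across trivial or
#' non-ancestral breakpoints).
#'
#' @param arg an [new_arg()] object.
#' @return list of entries `list(interval = c(start, end), tree = <marginal_tree>)`;
#'   the intervals partition `[0, L)` exactly.
#' @export
marginal_trees <- function(arg) {
  bps <- sort(unique(arg$nodes$breakpoint[arg$nodes$kind == "recombination"]))
  starts <- c(0L, bps)
  ends <- c(bps, arg$L)
  out <- list()
  prev_sig <- NULL
  for (i in seq_along(starts)) {
    if (starts[i] >= ends[i]) next  # duplicate breakpoints collapse
    tr <- extract_marginal_tree(arg, starts[i])
    sig <- .tree_signature(tr)
    if (!is.null(prev_sig) && identical(sig, prev_sig)) {
      out[[length(out)]]$interval[2] <- ends[i]
    } else {
      out[[length(out) + 1L]] <- list(interval = c(starts[i], ends[i]), tree = tr)
    }
    prev_sig <- sig
  }
  out
}

# material on the edge from `child` to parent slot `slot` (1 or 2)
.edge_material <- function(arg, child, slot) {
  m <- arg$material[[child]]
  if (arg$nodes$kind[child] == "recombination") {
    parts <- iv_split(m, arg$nodes$breakpoint[child])
    if (slot == 1L) parts$left else parts$right
  } else {
    m
  }
}

#' Annotate ancestral material
#'
#' Computes, for every node, the set of sites on its child-side edge that
#' are ancestral to at least one sampled sequence: tips carry `[0, L)`, a
#' coalescent node carries the union of its children's edge materials, and
#' a recombination node's material is split at its breakpoint across its
#' two parent edges.  Idempotent.
#'
#' @param arg an [new_arg()] object (structurally valid).
#' @return the ARG with `material` filled in (a list of interval matrices
#'   indexed by node id).
#' @export
annotate_ancestral_material <- function(arg) {
  nd <- arg$nodes
  n <- nrow(nd)
  ord <- order(nd$height, nd$id)
  material <- vector("list", n)
  for (id in ord) {
    if (nd$kind[id] == "tip") {
      material[[id]] <- iv(0L, arg$L)
    } else if (nd$kind[id] == "recombination") {
      # material on the single child-side edge (split if the child is
      # itself a recombination node)
      arg$material <- material
      u <- nd$child1[id]
      slot <- which(c(nd$parent1[u], nd$parent2[u]) == id)[1]
      material[[id]] <- .edge_material(arg, u, slot)
    } else {
      arg$material <- material  # .edge_material reads from arg
      ch <- c(nd$child1[id], nd$child2[id])
      m <- iv_empty()
      for (u in unique(ch)) {
        slots <- which(c(nd$parent1[u], nd$parent2[u]) == id)
        for (s in slots) m <- iv_union(m, .edge_material(arg, u, s))
      }
      material[[id]] <- m
    }
  }
  arg$material <- material
  arg
}

#' Enumerate recombination breakpoints with detectability classes
#'
#' One record per recombination node.  Classes:
#' * `detectable` — the breakpoint splits the edge's ancestral material and
#'   the two recombination-created lineages do not immediately rejoin;
#' * `trivial` — the two lineages coalesce with each other before any other
#'   branch (both parent slots attach to one coalescent node), so no
#'   marginal-tree topology is affected;
#' * `non_ancestral` — the breakpoint falls outside the edge's ancestral
#'   material (all material on one side), so no sampled site is affected.
#'
#' `non_ancestral` takes precedence when both degeneracies apply.
#'
#' @param arg an annotated ARG (see [annotate_ancestral_material()]).
#' @return data frame with columns `node`, `site` (0-based breakpoint),
#'   `height`, `class`; zero rows if the ARG has no recombinations.
#' @export
enumerate_breakpoints <- function(arg) {
  if (is.null(arg$material)) arg <- annotate_ancestral_material(arg)
  nd <- arg$nodes
  recs <- which(nd$kind == "recombination")
  out <- data.frame(
    node = integer(0), site = integer(0), height = numeric(0),
    class = character(0)
  )
  for (r in recs) {
    b <- nd$breakpoint[r]
    m <- arg$material[[r]]
    left <- iv_split(m, b)$left
    right <- iv_split(m, b)$right
    cls <- if (nrow(left) == 0L || nrow(right) == 0L) {
      "non_ancestral"
    } else if (nd$parent1[r] == nd$parent2[r]) {
      "trivial"
    } else {
      "detectable"
    }
    out <- rbind(out, data.frame(node = r, site = b, height = nd$height[r], class = cls))
  }
  out
}

#' TMRCA profile of a single ARG
#'
#' The marginal-tree root height as a step function over `[0, L)`;
#' adjacent intervals with equal TMRCA are merged.
#'
#' @param arg an [new_arg()] object.
#' @return data frame with columns `start`, `end` (0-based, half-open) and
#'   `tmrca`.
#' @export
tmrca_profile_of_arg <- function(arg) {
  mt <- marginal_trees(arg)
  start <- vapply(mt, function(x) x$interval[1], numeric(1))
  end <- vapply(mt, function(x) x$interval[2], numeric(1))
  tm <- vapply(mt, function(x) x$tree$tmrca, numeric(1))
  # merge adjacent equal TMRCAs (distinct trees can share a root height)
  keep <- c(TRUE, diff(tm) != 0)
  grp <- cumsum(keep)
  data.frame(
    start = as.integer(tapply(start, grp, min)),
    end = as.integer(tapply(end, grp, max)),
    tmrca = as.numeric(tapply(tm, grp, function(x) x[1])),
    row.names = NULL
  )
}
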