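# Hand-built ARG fixtures and small helpers shared across test files.

# two tips coalescing at height h
two_tip_arg <- function(h = 0.3, L = 10L, labels = c("a", "b")) {
  new_arg(data.frame(
    height = c(0, 0, h), kind = c("tip", "tip", "coalescent"),
    child1 = c(NA, NA, 1L), child2 = c(NA, NA, 2L),
    parent1 = c(3L, 3L, NA), parent2 = NA_integer_, breakpoint = NA_integer_
  ), n_tips = 2, L = L, tip_labels = labels)
}

# three tips A,B,C with one recombination on C's branch (breakpoint 5,
# L = 10): sites < 5 route C's lineage above the (A,B) ancestor, sites >= 5
# join A's branch.  Expected marginal trees: ((A,B),C) at site 0 with
# TMRCA 0.4, ((A,C),B) at site 9 with TMRCA 0.3.
three_tip_recomb_arg <- function() {
  new_arg(data.frame(
    height = c(0, 0, 0, 0.1, 0.2, 0.3, 0.4),
    kind = c("tip", "tip", "tip", "recombination", rep("coalescent", 3)),
    child1 = c(NA, NA, NA, 3L, 1L, 5L, 6L),
    child2 = c(NA, NA, NA, NA, 4L, 2L, 4L),
    parent1 = c(5L, 6L, 4L, 7L, 6L, 7L, NA),
    parent2 = c(NA, NA, NA, 5L, NA, NA, NA),
    breakpoint = c(NA, NA, NA, 5L, NA, NA, NA)
  ), n_tips = 3, L = 10, tip_labels = c("A", "B", "C"))
}

# two tips with one trivial recombination: the two recombination-created
# lineages coalesce with each other (node 4 -> node 5 via both slots)
# before joining anything else
trivial_recomb_arg <- function(L = 10L, b = 5L) {
  new_arg(data.frame(
    height = c(0, 0, 0.3, 0.5, 0.8),
    kind = c("tip", "tip", "recombination", "coalescent", "coalescent"),
    child1 = c(NA, NA, 1L, 3L, 4L),
    child2 = c(NA, NA, NA, 3L, 2L),
    parent1 = c(3L, 5L, 4L, 5L, NA),
    parent2 = c(NA, NA, 4L, NA, NA),
    breakpoint = c(NA, NA, b, NA, NA)
  ), n_tips = 2, L = L, tip_labels = c("a", "b"))
}

# three tips with a nested recombination whose breakpoint (2) falls outside
# its edge's ancestral material [5, 10): class non_ancestral.  The outer
# recombination (node 4, breakpoint 5) is detectable.
nested_nonancestral_arg <- function() {
  new_arg(data.frame(
    height = c(0, 0, 0, 0.1, 0.2, 0.3, 0.4, 0.5, 0.6),
    kind = c("tip", "tip", "tip", "recombination", "recombination",
             rep("coalescent", 4)),
    child1 = c(NA, NA, NA, 3L, 4L, 5L, 6L, 5L, 7L),
    child2 = c(NA, NA, NA, NA, NA, 1L, 4L, 2L, 8L),
    parent1 = c(6L, 8L, 4L, 7L, 8L, 7L, 9L, 9L, NA),
    parent2 = c(NA, NA, NA, 5L, 6L, NA, NA, NA, NA),
    breakpoint = c(NA, NA, NA, 5L, 2L, NA, NA, NA, NA)
  ), n_tips = 3, L = 10, tip_labels = c("A", "B", "C"))
}

# insert an undetectable pair onto a recombination-free ARG: a trivial
# recombination (breakpoint b1) on the root's higher child edge, and a
# nested non-ancestral recombination (breakpoint b2) on the left split
# lineage, which carries only sites [0, b1).  Marginal trees are unchanged
# everywhere.
add_undetectable_recombs <- function(arg, b1, b2) {
  stopifnot(b2 >= b1)  # b2 outside the [0, b1) material
  nd <- arg$nodes
  root <- which(is.na(nd$parent1) & is.na(nd$parent2) & nd$kind != "tip")
  v <- nd$child1[root]
  if (nd$height[nd$child2[root]] > nd$height[v]) v <- nd$child2[root]
  hv <- nd$height[v]
  hroot <- nd$height[root]
  h1 <- hv + 0.25 * (hroot - hv)   # trivial recombination r1
  h2 <- hv + 0.50 * (hroot - hv)   # nested non-ancestral r2
  h3 <- hv + 0.65 * (hroot - hv)   # rejoin of r2 (c2)
  h4 <- hv + 0.85 * (hroot - hv)   # rejoin of r1 (c1)
  n <- nrow(nd)
  r1 <- n + 1L; r2 <- n + 2L; c2 <- n + 3L; c1 <- n + 4L
  add <- data.frame(
    height = c(h1, h2, h3, h4),
    kind = c("recombination", "recombination", "coalescent", "coalescent"),
    child1 = c(v, r1, r2, c2),
    child2 = c(NA, NA, r2, r1),
    parent1 = c(r2, c2, c1, root),
    parent2 = c(c1, c2, NA, NA),
    breakpoint = c(b1, b2, NA, NA)
  )
  slot <- if (nd$child1[root] == v) "child1" else "child2"
  nd[[slot]][root] <- c1
  nd$parent1[v] <- r1
  out <- rbind(nd[, names(add)], add)
  annotate_ancestral_material(
    new_arg(out, n_tips = arg$n_tips, L = arg$L, tip_labels = arg$tip_labels)
  )
}

# canonical signature of the marginal tree at a site (topology + heights)
tree_sig <- function(arg, site) {
  recoal:::.tree_signature(extract_marginal_tree(arg, site))
}

# replica of the backward simulator that also accumulates its own
# generative log-density, used as an independent oracle for arg_log_prior
sim_with_density <- function(n, L, theta, rho) {
  rec_base <- (rho / theta) / (L - 1)
  height <- rep(0, n); kind <- rep("tip", n)
  child1 <- child2 <- parent1 <- parent2 <- bp <- rep(NA_integer_, n)
  add_node <- function(h, k, c1, c2, b) {
    height[[length(height) + 1]] <<- h; kind[[length(kind) + 1]] <<- k
    child1[[length(child1) + 1]] <<- c1; child2[[length(child2) + 1]] <<- c2
    parent1[[length(parent1) + 1]] <<- NA_integer_
    parent2[[length(parent2) + 1]] <<- NA_integer_
    bp[[length(bp) + 1]] <<- b; length(height)
  }
  set_parent <- function(node, slot, p) {
    if (slot == 1L) parent1[[node]] <<- p else parent2[[node]] <<- p
  }
  lin <- lapply(seq_len(n), function(i) list(node = i, slot = 1L,
                                             mat = recoal:::iv(0L, L)))
  t <- 0; ld <- 0
  while (length(lin) > 1) {
    k <- length(lin)
    spans <- vapply(lin, function(l) recoal:::iv_span(l$mat), numeric(1))
    rec_tot <- rec_base * sum(spans)
    coal_rate <- k * (k - 1) / theta
    tot <- rec_tot + coal_rate
    dt <- stats::rexp(1, tot)
    t <- t + dt
    ld <- ld - tot * dt
    if (stats::runif(1) < coal_rate / tot) {
      ld <- ld + log(2 / theta)
      pair <- sample.int(k, 2)
      a <- lin[[pair[1]]]; b2 <- lin[[pair[2]]]
      id <- add_node(t, "coalescent", a$node, b2$node, NA_integer_)
      set_parent(a$node, a$slot, id)
      set_parent(b2$node, b2$slot, id)
      lin <- c(lin[-pair], list(list(node = id, slot = 1L,
                                     mat = recoal:::iv_union(a$mat, b2$mat))))
    } else {
      ld <- ld + log(rec_base)
      i <- sample.int(k, 1, prob = spans)
      l <- lin[[i]]
      brk <- recoal:::iv_min(l$mat) + sample.int(recoal:::iv_span(l$mat), 1)
      id <- add_node(t, "recombination", l$node, NA_integer_, brk)
      set_parent(l$node, l$slot, id)
      parts <- recoal:::iv_split(l$mat, brk)
      lin <- c(lin[-i], list(list(node = id, slot = 1L, mat = parts$left),
                             list(node = id, slot = 2L, mat = parts$right)))
    }
  }
  nodes <- data.frame(height = height, kind = kind, child1 = child1,
                      child2 = child2, parent1 = parent1, parent2 = parent2,
                      breakpoint = bp)
  arg <- annotate_ancestral_material(new_arg(nodes, n_tips = n, L = L))
  list(arg = arg, logdens = ld)
}

# tiny phased VCF written to a temp file; returns the path
write_test_vcf <- function(lines_gt, samples = c("S1", "S2")) {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    lines_gt
  ), path)
  path
}
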