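# Backward-time simulation of neutral ARGs under the coalescent with
# recombination, and sequence simulation along the ARG.
#
# Event rates are exactly those of arg_log_prior (shared convention), so
# the simulator doubles as the sampling oracle for the prior density.

#' Simulation specification
#'
#' Defaults follow the package's reference study conditions: 10 sequences
#' of 10,000 sites under the standard neutral coalescent with
#' `theta = 0.02` and `rho = 1.0`, sequences evolved under F84 with
#' empirically common settings (equal base frequencies, transition
#' excess `kappa = 1.5`).
#'
#' @param n number of samples, `>= 2`.
#' @param L number of sites, `>= 1`.
#' @param theta scaled population size `2 N mu`, `> 0`.
#' @param rho scaled recombination rate `2 N r`, `>= 0`.
#' @param growth exponential population growth rate (0 = constant size).
#' @param model a [substitution_model()] for sequence simulation.
#' @param emit_non_ancestral if `TRUE`, recombination events are also
#'   generated on gaps outside each lineage's ancestral span (such events
#'   are invisible to inference; useful for demonstrating undetectable
#'   breakpoint classes).
#' @return object of class `simulation_spec`.
#' @export
simulation_spec <- function(n = 10, L = 10000, theta = 0.02, rho = 1.0,
                            growth = 0,
                            model = substitution_model("F84", kappa = 1.5),
                            emit_non_ancestral = FALSE) {
  stopifnot(n >= 2, L >= 1, theta > 0, rho >= 0)
  structure(
    list(n = as.integer(n), L = as.integer(L), theta = theta, rho = rho,
         growth = growth, model = model,
         emit_non_ancestral = isTRUE(emit_non_ancestral)),
    class = "simulation_spec"
  )
}

#' Simulate an ARG under the coalescent with recombination
#'
#' Backward-time simulation: lineages coalesce at pairwise rate
#' `2/theta(t)` and recombine at per-lineage rate
#' `(rho/theta0) * span/(L-1)`, where `span` counts the inter-site gaps
#' strictly inside the lineage's ancestral material.  Simulation tracks
#' ancestral material per lineage and stops at the grand MRCA.
#'
#' @param spec a [simulation_spec()].
#' @param seed optional integer seed (uses the global RNG stream when
#'   `NULL`).
#' @return a valid, annotated [new_arg()] object.
#' @export
simulate_arg <- function(spec = simulation_spec(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- spec$n
  L <- spec$L
  theta <- spec$theta
  g <- spec$growth
  rec_base <- if (L > 1) (spec$rho / theta) / (L - 1) else 0
  # growing node table
  height <- rep(0, n)
  kind <- rep("tip", n)
  child1 <- child2 <- parent1 <- parent2 <- bp <- rep(NA_integer_, n)
  add_node <- function(h, k, c1, c2, b) {
    height[[length(height) + 1]] <<- h
    kind[[length(kind) + 1]] <<- k
    child1[[length(child1) + 1]] <<- c1
    child2[[length(child2) + 1]] <<- c2
    parent1[[length(parent1) + 1]] <<- NA_integer_
    parent2[[length(parent2) + 1]] <<- NA_integer_
    bp[[length(bp) + 1]] <<- b
    length(height)
  }
  set_parent <- function(node, slot, p) {
    if (slot == 1L) parent1[[node]] <<- p else parent2[[node]] <<- p
  }
  # lineages: node id, parent slot to fill, material
  lin <- lapply(seq_len(n), function(i) list(node = i, slot = 1L, mat = iv(0L, L)))
  t <- 0
  while (length(lin) > 1) {
    k <- length(lin)
    spans <- vapply(lin, function(l) {
      if (spec$emit_non_ancestral) L - 1 else iv_span(l$mat)
    }, numeric(1))
    rec_tot <- rec_base * sum(spans)
    # waiting time to next coalescence (time-inhomogeneous when growing)
    coal_rate0 <- k * (k - 1) / theta
    tc <- if (g == 0) {
      t + stats::rexp(1, coal_rate0)
    } else {
      E <- stats::rexp(1)
      t + log1p(E * g * exp(-g * t) / coal_rate0) / g
    }
    tr <- if (rec_tot > 0) t + stats::rexp(1, rec_tot) else Inf
    if (tc <= tr) {
      t <- tc
      pair <- sample.int(k, 2)
      a <- lin[[pair[1]]]
      b2 <- lin[[pair[2]]]
      id <- add_node(t, "coalescent", a$node, b2$node, NA_integer_)
      set_parent(a$node, a$slot, id)
      set_parent(b2$node, b2$slot, id)
      newlin <- list(node = id, slot = 1L, mat = iv_union(a$mat, b2$mat))
      lin <- c(lin[-pair], list(newlin))
    } else {
      t <- tr
      i <- sample.int(k, 1, prob = spans)
      l <- lin[[i]]
      brk <- if (spec$emit_non_ancestral) {
        sample.int(L - 1, 1)
      } else {
        iv_min(l$mat) + sample.int(iv_span(l$mat), 1)
      }
      id <- add_node(t, "recombination", l$node, NA_integer_, brk)
      set_parent(l$node, l$slot, id)
      parts <- iv_split(l$mat, brk)
      lin <- c(lin[-i],
               list(list(node = id, slot = 1L, mat = parts$left),
                    list(node = id, slot = 2L, mat = parts$right)))
    }
  }
  nodes <- data.frame(
    height = height, kind = kind, child1 = child1, child2 = child2,
    parent1 = parent1, parent2 = parent2, breakpoint = bp
  )
  arg <- new_arg(nodes, n_tips = n, L = L)
  annotate_ancestral_material(arg)
}

# sample successor states for a vector of current states after time t
.mutate_states <- function(states, t, model) {
  if (length(states) == 0L) return(states)
  P <- transition_matrix(model, t)
  cp <- t(apply(P, 1, cumsum))
  u <- stats::runif(length(states))
  rowSums(u > cp[states, , drop = FALSE]) + 1L
}

#' Simulate nucleotide sequences along an ARG
#'
#' Root states are drawn from the model's stationary frequencies and
#' mutated down every edge of the ARG; at a recombination node sites below
#' the breakpoint descend from parent 1, the rest from parent 2.  Because
#' mutation paths are simulated per ARG edge, marginal trees that share
#' edges share the same realized mutations, so linked sites are correlated
#' exactly as the ARG dictates.  With `per_interval = TRUE` each marginal
#' tree is instead simulated independently with fresh randomness (the
#' classical one-tree-at-a-time pipeline).
#'
#' @param arg a valid [new_arg()] object.
#' @param model a [substitution_model()].
#' @param seed optional integer seed.
#' @param per_interval simulate each marginal-tree interval independently.
#' @return an [alignment()] with one row per tip, names = tip labels.
#' @export
simulate_sequences <- function(arg, model, seed = NULL, per_interval = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  bases <- c("A", "C", "G", "T")
  pi <- as.numeric(unclass(model$freqs))
  n <- arg$n_tips
  L <- arg$L
  if (per_interval) {
    out <- matrix("", n, L)
    for (entry in marginal_trees(arg)) {
      sites <- seq.int(entry$interval[1] + 1L, entry$interval[2])
      out[, sites] <- .simulate_on_tree(entry$tree, length(sites), model)
    }
    return(alignment(out, names = arg$tip_labels))
  }
  nd <- arg$nodes
  ord <- order(-nd$height, nd$id)
  states <- matrix(0L, nrow(nd), L)
  for (id in ord) {
    if (is.na(nd$parent1[id]) && (nd$kind[id] != "recombination")) {
      states[id, ] <- sample.int(4, L, replace = TRUE, prob = pi)
      next
    }
    if (nd$kind[id] == "recombination") {
      b <- nd$breakpoint[id]
      p1 <- nd$parent1[id]
      p2 <- nd$parent2[id]
      left <- seq_len(b)
      right <- setdiff(seq_len(L), left)
      states[id, left] <- .mutate_states(states[p1, left],
                                         nd$height[p1] - nd$height[id], model)
      states[id, right] <- .mutate_states(states[p2, right],
                                          nd$height[p2] - nd$height[id], model)
    } else {
      p <- nd$parent1[id]
      states[id, ] <- .mutate_states(states[p, ],
                                     nd$height[p] - nd$height[id], model)
    }
  }
  m <- matrix(bases[states[seq_len(n), , drop = FALSE]], n, L)
  alignment(m, names = arg$tip_labels)
}

# independent simulation of k sites down one marginal tree
.simulate_on_tree <- function(tree, k, model) {
  pi <- as.numeric(unclass(model$freqs))
  bases <- c("A", "C", "G", "T")
  ord <- tree$node_ids[order(-tree$heights, tree$node_ids)]
  states <- list()
  for (id in ord) {
    key <- as.character(id)
    p <- tree$parent[[key]]
    if (is.na(p)) {
      states[[key]] <- sample.int(4, k, replace = TRUE, prob = pi)
    } else {
      bl <- tree$heights[[as.character(p)]] - tree$heights[[key]]
      states[[key]] <- .mutate_states(states[[as.character(p)]], bl, model)
    }
  }
  out <- matrix("", tree$n_tips, k)
  for (i in seq_len(tree$n_tips)) out[i, ] <- bases[states[[as.character(i)]]]
  out
}
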