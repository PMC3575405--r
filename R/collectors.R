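# Collectors over sampled states: breakpoint space-time density, TMRCA
# profile, per-site consensus trees, effective sample size.
#
# All collectors are order-insensitive and exactly mergeable: merging two
# accumulators equals accumulating the concatenated sample streams.

#' Create a 2-D breakpoint density accumulator
#'
#' Bins recombination breakpoints of sampled ARGs by sequence position
#' (axis 1) and node height (axis 2).  Heights above the top bin edge are
#' clamped into the top bin.
#'
#' @param L sequence length (site bins cover `[0, L)`).
#' @param max_height top of the time axis.
#' @param site_bins,time_bins bin counts.
#' @return object of class `breakpoint_density`.
#' @export
breakpoint_density_2d <- function(L, max_height, site_bins = 100, time_bins = 50) {
  structure(
    list(
      site_breaks = seq(0, L, length.out = site_bins + 1),
      time_breaks = seq(0, max_height, length.out = time_bins + 1),
      counts = matrix(0L, site_bins, time_bins),
      n_args = 0L
    ),
    class = "breakpoint_density"
  )
}

#' Add one sampled ARG to a breakpoint density
#'
#' Each recombination node adds one count to the bin of
#' (breakpoint site, node height).
#'
#' @param density a [breakpoint_density_2d()].
#' @param arg a sampled ARG.
#' @return the updated density.
#' @export
collect_breakpoints <- function(density, arg) {
  nd <- arg$nodes
  recs <- which(nd$kind == "recombination")
  for (r in recs) {
    i <- findInterval(nd$breakpoint[r], density$site_breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
    j <- findInterval(nd$height[r], density$time_breaks,
                      rightmost.closed = TRUE, all.inside = TRUE)
    density$counts[i, j] <- density$counts[i, j] + 1L
  }
  density$n_args <- density$n_args + 1L
  density
}

#' Merge two breakpoint densities (identical binning required)
#' @param a,b accumulators from [breakpoint_density_2d()].
#' @return merged accumulator.
#' @export
merge_breakpoint_density <- function(a, b) {
  stopifnot(identical(a$site_breaks, b$site_breaks),
            identical(a$time_breaks, b$time_breaks))
  a$counts <- a$counts + b$counts
  a$n_args <- a$n_args + b$n_args
  a
}

#' Write a breakpoint density as TSV (site_bin, time_bin, count)
#'
#' Bin coordinates are reported 1-based.
#'
#' @param density accumulator.
#' @param path output file.
#' @export
write_breakpoint_density <- function(density, path) {
  df <- expand.grid(site_bin = seq_len(nrow(density$counts)),
                    time_bin = seq_len(ncol(density$counts)))
  df$count <- as.integer(density$counts[as.matrix(df)])
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Create a TMRCA profile accumulator
#'
#' Stores, per grid site, the marginal TMRCA of each sampled ARG so that
#' posterior means and quantiles can be summarized.
#'
#' @param sites 0-based site grid at which TMRCA is recorded.
#' @return object of class `tmrca_accumulator`.
#' @export
tmrca_accumulator <- function(sites) {
  structure(list(sites = as.integer(sites), samples = list()),
            class = "tmrca_accumulator")
}

#' Add one sampled ARG's TMRCA profile to an accumulator
#' @param acc a [tmrca_accumulator()].
#' @param arg a sampled ARG.
#' @return the updated accumulator.
#' @export
collect_tmrca <- function(acc, arg) {
  prof <- tmrca_profile_of_arg(arg)
  idx <- findInterval(acc$sites, prof$start)
  acc$samples[[length(acc$samples) + 1L]] <- prof$tmrca[idx]
  acc
}

#' Merge two TMRCA accumulators (identical site grids required)
#' @param a,b accumulators.
#' @return merged accumulator.
#' @export
merge_tmrca <- function(a, b) {
  stopifnot(identical(a$sites, b$sites))
  a$samples <- c(a$samples, b$samples)
  a
}

#' Summarize a TMRCA accumulator
#'
#' @param acc a [tmrca_accumulator()] with at least one sample.
#' @param probs lower/upper quantiles of the credible band.
#' @return data frame with columns `site` (0-based), `mean`, `lower`,
#'   `upper`.
#' @export
tmrca_profile <- function(acc, probs = c(0.025, 0.975)) {
  stopifnot(length(acc$samples) > 0)
  m <- do.call(rbind, acc$samples)
  data.frame(
    site = acc$sites,
    mean = colMeans(m),
    lower = apply(m, 2, stats::quantile, probs[1]),
    upper = apply(m, 2, stats::quantile, probs[2]),
    row.names = NULL
  )
}

#' Write a posterior TMRCA profile as TSV (site, mean, q025, q975)
#'
#' Sites are reported 1-based.
#'
#' @param acc a [tmrca_accumulator()] with samples.
#' @param path output file.
#' @param probs credible-band quantiles.
#' @export
write_tmrca_band <- function(acc, path, probs = c(0.025, 0.975)) {
  prof <- tmrca_profile(acc, probs)
  out <- data.frame(site = prof$site + 1L, mean = prof$mean,
                    q025 = prof$lower, q975 = prof$upper)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# clade key: sorted tip ids joined
.clades_of <- function(tree) {
  children <- split(
    tree$node_ids[!is.na(tree$parent)],
    tree$parent[!is.na(tree$parent)]
  )
  out <- list()
  rec <- function(id) {
    if (id <= tree$n_tips) return(id)
    tips <- sort(unlist(lapply(children[[as.character(id)]], rec)))
    out[[paste(tips, collapse = ",")]] <<- list(
      tips = tips, height = tree$heights[[as.character(id)]]
    )
    tips
  }
  rec(tree$root)
  out
}

#' Majority-rule consensus tree over marginal trees
#'
#' Retains clades appearing in strictly more than half of the trees
#' (clades at exactly 0.5 are dropped); clade support is the fraction of
#' trees containing the clade and node heights are means over the
#' supporting trees.
#'
#' @param trees list of [extract_marginal_tree()] results with identical
#'   tip sets.
#' @return object of class `consensus_tree`: data frame `clades` (tips,
#'   support, mean_height) and `tip_labels`.
#' @export
consensus_tree_at_site <- function(trees) {
  stopifnot(length(trees) >= 1)
  n <- trees[[1]]$n_tips
  labs <- trees[[1]]$tip_labels
  for (tr in trees) {
    if (tr$n_tips != n || !identical(tr$tip_labels, labs)) {
      stop("all trees must share one tip set")
    }
  }
  counts <- new.env(parent = emptyenv())
  heights <- new.env(parent = emptyenv())
  for (tr in trees) {
    cls <- .clades_of(tr)
    for (key in names(cls)) {
      counts[[key]] <- (if (is.null(counts[[key]])) 0L else counts[[key]]) + 1L
      heights[[key]] <- c(if (is.null(heights[[key]])) numeric(0) else heights[[key]],
                          cls[[key]]$height)
    }
  }
  keys <- ls(counts)
  support <- vapply(keys, function(k) counts[[k]] / length(trees), numeric(1))
  keep <- support > 0.5
  clades <- data.frame(
    tips = keys[keep],
    support = support[keep],
    mean_height = vapply(keys[keep], function(k) mean(heights[[k]]), numeric(1)),
    row.names = NULL
  )
  clades <- clades[order(-vapply(strsplit(clades$tips, ","), length, numeric(1))), ]
  structure(list(clades = clades, tip_labels = labs, n_trees = length(trees)),
            class = "consensus_tree")
}

#' Newick string of a consensus tree with clade supports in comments
#' @param ct a [consensus_tree_at_site()] result.
#' @return character scalar (supports as `[&support=..]` comments).
#' @export
consensus_newick <- function(ct) {
  n <- length(ct$tip_labels)
  clades <- ct$clades
  sets <- lapply(strsplit(clades$tips, ","), as.integer)
  ord <- order(vapply(sets, length, numeric(1)))
  build <- function(tips) {
    # largest retained proper sub-clades of `tips`, greedily (majority-rule
    # clades are pairwise compatible, so this is well defined)
    rest <- tips
    parts <- list()
    for (i in rev(ord)) {
      s <- sets[[i]]
      if (length(s) < length(tips) && all(s %in% rest)) {
        parts[[length(parts) + 1L]] <- s
        rest <- setdiff(rest, s)
      }
    }
    for (t in rest) parts[[length(parts) + 1L]] <- t
    inner <- vapply(parts, function(p) {
      if (length(p) == 1L) ct$tip_labels[p] else {
        j <- which(clades$tips == paste(sort(p), collapse = ","))
        sprintf("%s[&support=%.3f]", build(p), clades$support[j])
      }
    }, character(1))
    paste0("(", paste(inner, collapse = ","), ")")
  }
  paste0(build(seq_len(n)), ";")
}

#' Effective sample size of an MCMC trace
#'
#' `N / (1 + 2 sum_k gamma_k)` with the initial monotone positive sequence
#' truncation of the autocorrelation sum.
#'
#' @param x numeric trace of length `>= 10`, non-constant.
#' @return estimated ESS.
#' @export
effective_sample_size <- function(x) {
  n <- length(x)
  if (n < 10) stop("trace too short (need >= 10 values)")
  if (stats::sd(x) == 0) stop("constant trace: ESS undefined")
  rho <- as.numeric(stats::acf(x, lag.max = min(n - 2, 5000), plot = FALSE)$acf)
  # Geyer pairs: Gamma_m = rho_{2m} + rho_{2m+1}; keep while positive,
  # enforce monotone nonincreasing, then tau = -1 + 2 * sum(Gamma)
  m_max <- floor(length(rho) / 2)
  if (m_max < 1) return(n)
  gam <- rho[2 * seq_len(m_max) - 1] + rho[2 * seq_len(m_max)]
  nonpos <- which(gam <= 0)
  if (length(nonpos) > 0) gam <- gam[seq_len(nonpos[1] - 1)]
  if (length(gam) > 1) gam <- cummin(gam)
  tau <- -1 + 2 * sum(gam)
  tau <- max(tau, .Machine$double.eps)
  n / tau
}
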