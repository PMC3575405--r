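# Collectors: breakpoint density, TMRCA profiles, consensus trees, ESS.

test_that("breakpoint density bins, conserves counts and merges exactly", {
  dens <- breakpoint_density_2d(L = 1000, max_height = 1, site_bins = 10,
                                time_bins = 5)
  arg0 <- simulate_arg(simulation_spec(n = 4, L = 1000, theta = 1, rho = 0),
                       seed = 1)
  expect_equal(sum(collect_breakpoints(dens, arg0)$counts), 0)

  triv <- trivial_recomb_arg(L = 1000L, b = 105L)  # height 0.3, site 105
  d1 <- collect_breakpoints(dens, triv)
  expect_equal(sum(d1$counts), 1)
  expect_equal(d1$counts[2, 2], 1L)  # site bin (100,200], time bin (0.2,0.4]

  # heights above the top edge clamp into the top bin
  high <- triv
  high$nodes$height <- high$nodes$height * 10
  d2 <- collect_breakpoints(dens, high)
  expect_equal(d2$counts[2, 5], 1L)

  set.seed(2)
  args <- replicate(6, simulate_arg(
    simulation_spec(n = 5, L = 1000, theta = 1, rho = 2)), simplify = FALSE)
  total <- sum(vapply(args, n_recombinations, numeric(1)))
  dall <- Reduce(collect_breakpoints, args, dens)
  expect_equal(sum(dall$counts), total)
  da <- Reduce(collect_breakpoints, args[1:3], dens)
  db <- Reduce(collect_breakpoints, args[4:6], dens)
  expect_equal(merge_breakpoint_density(da, db)$counts, dall$counts)

  path <- tempfile(fileext = ".tsv")
  write_breakpoint_density(dall, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_equal(sum(tab$count), total)
})

test_that("TMRCA accumulator reproduces degenerate and two-state cases", {
  arg <- simulate_arg(simulation_spec(n = 5, L = 100, theta = 1, rho = 1),
                      seed = 3)
  acc <- tmrca_accumulator(seq(0, 99, by = 10))
  for (i in 1:4) acc <- collect_tmrca(acc, arg)
  prof <- tmrca_profile(acc)
  expect_true(all(prof$lower == prof$upper))      # identical samples: no band
  expect_equal(prof$mean[1], extract_marginal_tree(arg, 0)$tmrca)

  a <- two_tip_arg(0.2, L = 100)
  b <- two_tip_arg(0.6, L = 100)
  acc2 <- collect_tmrca(collect_tmrca(tmrca_accumulator(c(0, 50)), a), b)
  prof2 <- tmrca_profile(acc2, probs = c(0, 1))
  expect_equal(prof2$mean, rep(0.4, 2))
  expect_equal(prof2$lower, rep(0.2, 2))
  expect_equal(prof2$upper, rep(0.6, 2))

  merged <- merge_tmrca(collect_tmrca(tmrca_accumulator(c(0, 50)), a),
                        collect_tmrca(tmrca_accumulator(c(0, 50)), b))
  expect_equal(tmrca_profile(merged, probs = c(0, 1)), prof2)

  path <- tempfile(fileext = ".tsv")
  write_tmrca_band(acc2, path)
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  expect_named(tab, c("site", "mean", "q025", "q975"))
  expect_equal(tab$site, c(1L, 51L))  # 1-based user-facing sites
})

test_that("majority-rule consensus counts clades, supports, mean heights", {
  arg <- simulate_arg(simulation_spec(n = 5, L = 60, theta = 1, rho = 0),
                      seed = 4)
  same <- replicate(3, extract_marginal_tree(arg, 0), simplify = FALSE)
  ct <- consensus_tree_at_site(same)
  expect_true(all(ct$clades$support == 1))
  expect_equal(nrow(ct$clades), 4)  # n - 1 internal clades

  # 3 trees, clade {1,2} in two of them -> support 2/3, retained
  args <- lapply(c(11, 12, 13), function(s) {
    simulate_arg(simulation_spec(n = 4, L = 10, theta = 1, rho = 0), seed = s)
  })
  trees <- lapply(args, extract_marginal_tree, site = 0)
  keys <- lapply(trees, function(tr) names(recoal:::.clades_of(tr)))
  ct2 <- consensus_tree_at_site(trees)
  counts <- table(unlist(keys))
  for (i in seq_len(nrow(ct2$clades))) {
    key <- ct2$clades$tips[i]
    expect_equal(ct2$clades$support[i], unname(counts[key]) / 3)
    expect_gt(ct2$clades$support[i], 0.5)
  }
  # supports cross-checked against ape's clade frequencies
  phys <- lapply(trees, marginal_tree_to_phylo)
  pp <- ape::prop.part(phys)
  labs <- attr(pp, "labels")
  for (i in seq_along(pp)) {
    tipset <- paste(sort(match(labs[pp[[i]]], trees[[1]]$tip_labels)),
                    collapse = ",")
    freq <- attr(pp, "number")[i] / 3
    if (freq > 0.5 && length(pp[[i]]) < 4) {
      expect_true(tipset %in% ct2$clades$tips)
    }
  }

  # conflicting clades at exactly 0.5 are dropped (strict majority)
  mk <- function(p1, p2) {
    nd <- data.frame(
      height = c(0, 0, 0, 0, 0.1, 0.2, 0.4),
      kind = c(rep("tip", 4), rep("coalescent", 3)),
      child1 = c(NA, NA, NA, NA, p1[1], p2[1], 5L),
      child2 = c(NA, NA, NA, NA, p1[2], p2[2], 6L),
      parent1 = NA_integer_, parent2 = NA_integer_, breakpoint = NA_integer_
    )
    nd$parent1[p1] <- 5L; nd$parent1[p2] <- 6L
    nd$parent1[5:6] <- 7L
    extract_marginal_tree(new_arg(nd, n_tips = 4, L = 10), 0)
  }
  ta <- mk(c(1L, 2L), c(3L, 4L))
  tb <- mk(c(1L, 3L), c(2L, 4L))
  ct3 <- consensus_tree_at_site(list(ta, ta, tb, tb))
  # both cherry partitions sit at exactly 0.5 and are dropped; only the
  # root clade (present in every tree) survives
  expect_identical(ct3$clades$tips, "1,2,3,4")

  t1 <- trees[[1]]
  expect_error(consensus_tree_at_site(list(t1, extract_marginal_tree(
    simulate_arg(simulation_spec(n = 5, L = 10, theta = 1, rho = 0), seed = 1), 0
  ))), "tip set")

  nwk <- consensus_newick(ct)
  expect_match(nwk, "support=1.000", fixed = TRUE)
  expect_match(nwk, ";$")
})

test_that("effective sample size is calibrated on iid and AR(1) traces", {
  set.seed(5)
  x <- stats::rnorm(1e4)
  expect_gt(effective_sample_size(x), 0.9e4)
  expect_lt(effective_sample_size(x), 1.1e4)

  phi <- 0.9
  y <- as.numeric(stats::arima.sim(list(ar = phi), 1e5))
  target <- 1e5 * (1 - phi) / (1 + phi)
  expect_lt(abs(effective_sample_size(y) - target) / target, 0.2)

  expect_error(effective_sample_size(stats::rnorm(5)), "too short")
  expect_error(effective_sample_size(rep(1, 100)), "constant")
})
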