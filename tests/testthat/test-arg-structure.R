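# ARG data model: validation, marginal-tree extraction, ancestral material,
# breakpoint enumeration.

test_that("validation accepts a minimal ARG and names broken rules", {
  expect_identical(validate_arg(two_tip_arg(0.3)), character(0))

  bad_height <- two_tip_arg(0.3)
  bad_height$nodes$height[3] <- -0.1
  v <- validate_arg(bad_height)
  expect_true(any(grepl("node 3", v) & grepl("height", v)))

  # a recombination node given two children
  bad_arity <- new_arg(data.frame(
    height = c(0, 0, 0.2, 0.5),
    kind = c("tip", "tip", "recombination", "coalescent"),
    child1 = c(NA, NA, 1L, 3L), child2 = c(NA, NA, 2L, 3L),
    parent1 = c(3L, 3L, 4L, NA), parent2 = c(NA, NA, 4L, NA),
    breakpoint = c(NA, NA, 5L, NA)
  ), n_tips = 2, L = 10)
  v <- validate_arg(bad_arity)
  expect_true(any(grepl("node 3", v) & grepl("1 child", v)))

  disconnected <- two_tip_arg(0.3)
  disconnected$nodes$parent1[2] <- NA
  expect_gt(length(validate_arg(disconnected)), 0)
})

test_that("marginal tree of a recombination-free ARG is the ARG itself", {
  arg <- simulate_arg(simulation_spec(n = 6, L = 50, theta = 1, rho = 0), seed = 2)
  tr0 <- extract_marginal_tree(arg, 0)
  expect_equal(tr0$tmrca, arg_root_height(arg))
  expect_identical(tree_sig(arg, 0), tree_sig(arg, 49))
  mt <- marginal_trees(arg)
  expect_length(mt, 1)
  expect_equal(mt[[1]]$interval, c(0, 50))
})

test_that("hand-built 3-tip recombinant ARG yields the expected marginal trees", {
  arg <- three_tip_recomb_arg()
  expect_identical(validate_arg(arg), character(0))
  t0 <- extract_marginal_tree(arg, 0)
  t9 <- extract_marginal_tree(arg, 9)
  # site 0: ((A,B),C) with root at 0.4 and (A,B) ancestor at 0.3
  expect_equal(t0$tmrca, 0.4)
  expect_identical(marginal_tree_newick(t0), "(C:0.4,(A:0.3,B:0.3):0.1);")
  # site 9: ((A,C),B) with root at 0.3 and (A,C) ancestor at 0.2
  expect_equal(t9$tmrca, 0.3)
  expect_identical(marginal_tree_newick(t9), "(B:0.3,(A:0.2,C:0.2):0.1);")
  # sites on each side of the breakpoint agree with their representative
  expect_identical(tree_sig(arg, 4), tree_sig(arg, 0))
  expect_identical(tree_sig(arg, 5), tree_sig(arg, 9))
  mt <- marginal_trees(arg)
  expect_length(mt, 2)
  expect_equal(mt[[1]]$interval, c(0, 5))
  expect_equal(mt[[2]]$interval, c(5, 10))
  expect_error(extract_marginal_tree(arg, 10), "out of range")
})

test_that("marginal_trees partitions [0, L) and matches per-site extraction", {
  set.seed(4)
  for (rep in 1:3) {
    arg <- simulate_arg(simulation_spec(n = 5, L = 120, theta = 1, rho = 3))
    mt <- marginal_trees(arg)
    starts <- vapply(mt, function(x) x$interval[1], numeric(1))
    ends <- vapply(mt, function(x) x$interval[2], numeric(1))
    expect_equal(starts[1], 0)
    expect_equal(ends[length(ends)], arg$L)
    if (length(mt) > 1) expect_equal(starts[-1], ends[-length(ends)])
    for (site in seq(0, arg$L - 1, by = 7)) {
      entry <- mt[[max(which(starts <= site))]]
      expect_identical(tree_sig(arg, site),
                       recoal:::.tree_signature(entry$tree))
    }
  }
})

test_that("every marginal tree is binary and ultrametric with n_tips leaves", {
  set.seed(9)
  arg <- simulate_arg(simulation_spec(n = 7, L = 80, theta = 1, rho = 2))
  for (site in c(0, 25, 79)) {
    tr <- extract_marginal_tree(arg, site)
    expect_equal(sum(tr$node_ids <= tr$n_tips), 7)
    # binary: n - 1 retained internal nodes
    expect_equal(length(tr$node_ids), 2 * 7 - 1)
    expect_true(all(tr$heights[as.character(seq_len(7))] == 0))
    phy <- marginal_tree_to_phylo(tr)
    expect_true(ape::is.binary(phy))
    expect_true(ape::is.ultrametric(phy, tol = 1e-10))
  }
})

test_that("ancestral-material annotation follows tips, unions and splits", {
  arg <- annotate_ancestral_material(three_tip_recomb_arg())
  expect_equal(arg$material[[1]], recoal:::iv(0L, 10L))  # tip edge carries [0, L)
  # recombination node 4 splits C's material at 5 across its parent edges
  expect_equal(recoal:::.edge_material(arg, 4L, 1L), recoal:::iv(0L, 5L))
  expect_equal(recoal:::.edge_material(arg, 4L, 2L), recoal:::iv(5L, 10L))
  # node 5 = coal(A, C-right): union of [0,10) and [5,10)
  expect_equal(arg$material[[5]], recoal:::iv(0L, 10L))
  # idempotence
  again <- annotate_ancestral_material(arg)
  expect_identical(arg$material, again$material)
})

test_that("material of a recombination above a recombination is the split edge", {
  arg <- annotate_ancestral_material(nested_nonancestral_arg())
  expect_equal(arg$material[[5]], recoal:::iv(5L, 10L))
})

test_that("at every level each uncoalesced site is covered by >= 2 edges", {
  set.seed(11)
  arg <- simulate_arg(simulation_spec(n = 5, L = 40, theta = 1, rho = 2))
  nd <- arg$nodes
  prof <- tmrca_profile_of_arg(arg)
  heights <- sort(nd$height[nd$kind != "tip"])
  probe <- (heights[-1] + heights[-length(heights)]) / 2
  probe <- c(heights[1] / 2, probe)
  for (h in probe) {
    for (site in seq(0L, arg$L - 1L, by = 5L)) {
      cover <- 0L
      for (id in seq_len(nrow(nd))) {
        slots <- if (nd$kind[id] == "recombination") 1:2 else 1
        for (s in slots) {
          p <- if (s == 1) nd$parent1[id] else nd$parent2[id]
          if (is.na(p)) next
          if (nd$height[id] < h && h < nd$height[p] &&
              recoal:::iv_contains(recoal:::.edge_material(arg, id, s), site)) {
            cover <- cover + 1L
          }
        }
      }
      tm <- prof$tmrca[max(which(prof$start <= site))]
      if (h < tm) expect_gte(cover, 2L) else expect_gte(cover, 1L)
    }
  }
})

test_that("breakpoints are enumerated with detectability classes", {
  arg0 <- simulate_arg(simulation_spec(n = 4, L = 30, theta = 1, rho = 0), seed = 1)
  expect_equal(nrow(enumerate_breakpoints(arg0)), 0)

  triv <- trivial_recomb_arg()
  expect_identical(validate_arg(triv), character(0))
  bp <- enumerate_breakpoints(triv)
  expect_equal(bp$class, "trivial")
  expect_equal(bp$site, 5)

  nested <- nested_nonancestral_arg()
  expect_identical(validate_arg(nested), character(0))
  bp <- enumerate_breakpoints(nested)
  expect_setequal(bp$class, c("detectable", "non_ancestral"))
  expect_equal(bp$class[bp$node == 5], "non_ancestral")
})

test_that("trivial and non-ancestral breakpoints leave marginal trees unchanged", {
  triv <- trivial_recomb_arg(L = 10L, b = 5L)
  expect_identical(tree_sig(triv, 4), tree_sig(triv, 5))
  expect_length(marginal_trees(triv), 1)

  nested <- nested_nonancestral_arg()
  # both sides of the non-ancestral breakpoint (2) are identical ...
  expect_identical(tree_sig(nested, 1), tree_sig(nested, 2))
  # ... while the detectable breakpoint (5) changes the tree
  expect_false(identical(tree_sig(nested, 4), tree_sig(nested, 5)))
})

test_that("TMRCA profile is a step function matching per-site marginal roots", {
  set.seed(13)
  arg <- simulate_arg(simulation_spec(n = 5, L = 60, theta = 1, rho = 2))
  prof <- tmrca_profile_of_arg(arg)
  expect_equal(prof$start[1], 0)
  expect_equal(prof$end[nrow(prof)], arg$L)
  for (site in seq(0, arg$L - 1, by = 3)) {
    expect_equal(extract_marginal_tree(arg, site)$tmrca,
                 prof$tmrca[max(which(prof$start <= site))])
  }
  arg0 <- simulate_arg(simulation_spec(n = 5, L = 60, theta = 1, rho = 0))
  expect_equal(nrow(tmrca_profile_of_arg(arg0)), 1)
})
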