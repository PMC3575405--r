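# Felsenstein likelihood on ARGs: aliasing, engine vs independent R oracle,
# brute-force state sums, missing data, and the dirty/recompute contract.

model_f84 <- substitution_model("F84", base_frequencies(c(0.3, 0.2, 0.3, 0.2)),
                                kappa = 2)

test_that("column aliasing groups identical columns and leaves L intact", {
  m <- matrix(c("A", "A", "A", "A", "C",
                "C", "C", "C", "C", "G"), nrow = 2, byrow = TRUE)
  aln <- alias_columns(alignment(m))
  expect_equal(ncol(aln$patterns), 2)
  expect_equal(sort(aln$pattern_counts), c(1L, 4L))
  expect_equal(sum(aln$pattern_counts), 5)

  distinct <- alias_columns(alignment(matrix(c("A", "C", "G", "T",
                                               "C", "G", "T", "A"),
                                             nrow = 2, byrow = TRUE)))
  expect_equal(ncol(distinct$patterns), 4)
})

test_that("aliased likelihood equals a direct per-column computation", {
  set.seed(21)
  arg <- simulate_arg(simulation_spec(n = 6, L = 50, theta = 0.05, rho = 0))
  aln <- simulate_sequences(arg, model_f84)
  tree <- extract_marginal_tree(arg, 0)
  direct <- sum(tree_log_likelihood(tree, aln$matrix, model_f84))
  expect_equal(arg_log_likelihood(arg, aln, model_f84), direct,
               tolerance = 1e-9)
})

test_that("two identical tips at a vanishing coalescence height give log(pi)", {
  arg <- two_tip_arg(1e-9, L = 1)
  aln <- alignment(matrix("A", 2, 1), names = c("a", "b"))
  expect_equal(arg_log_likelihood(arg, aln, model_f84),
               log(model_f84$freqs[["A"]]), tolerance = 1e-6)
})

test_that("pruning equals the exhaustive sum over internal state assignments", {
  # 1-site, 3-tip tree: sum over all 4^2 internal states of products of
  # P(t) entries and stationary frequencies
  arg <- new_arg(data.frame(
    height = c(0, 0, 0, 0.2, 0.5),
    kind = c("tip", "tip", "tip", "coalescent", "coalescent"),
    child1 = c(NA, NA, NA, 1L, 4L), child2 = c(NA, NA, NA, 2L, 3L),
    parent1 = c(4L, 4L, 5L, 5L, NA), parent2 = NA_integer_,
    breakpoint = NA_integer_
  ), n_tips = 3, L = 1, tip_labels = c("a", "b", "c"))
  obs <- c(A = 1L, C = 2L, G = 3L)  # a=A, b=C, c=G
  pi <- as.numeric(unclass(model_f84$freqs))
  P_a <- transition_matrix(model_f84, 0.2)
  P_int <- transition_matrix(model_f84, 0.3)
  P_c <- transition_matrix(model_f84, 0.5)
  brute <- 0
  for (root_state in 1:4) {
    for (mid_state in 1:4) {
      brute <- brute + pi[root_state] *
        P_int[root_state, mid_state] * P_a[mid_state, 1] * P_a[mid_state, 2] *
        P_c[root_state, 3]
    }
  }
  aln <- alignment(matrix(c("A", "C", "G"), 3, 1), names = c("a", "b", "c"))
  expect_equal(arg_log_likelihood(arg, aln, model_f84), log(brute),
               tolerance = 1e-12)
  expect_equal(sum(tree_log_likelihood(extract_marginal_tree(arg, 0),
                                       aln$matrix, model_f84)),
               log(brute), tolerance = 1e-12)
})

test_that("column likelihoods sum to one over all possible tip assignments", {
  set.seed(22)
  arg <- simulate_arg(simulation_spec(n = 4, L = 2, theta = 0.5, rho = 0))
  tree <- extract_marginal_tree(arg, 0)
  bases <- c("A", "C", "G", "T")
  cols <- as.matrix(expand.grid(bases, bases, bases, bases,
                                stringsAsFactors = FALSE))
  ll <- tree_log_likelihood(tree, t(cols), model_f84)
  expect_equal(sum(exp(ll)), 1, tolerance = 1e-10)
})

test_that("gaps and N are treated as missing data", {
  arg <- two_tip_arg(0.4, L = 3)
  aln <- alignment(matrix(c("N", "-", "A",
                            "N", "N", "N"), 2, 3, byrow = TRUE),
                   names = c("a", "b"))
  # fully missing columns contribute 0; the A/N column contributes log pi_A
  expect_equal(arg_log_likelihood(arg, aln, model_f84),
               log(model_f84$freqs[["A"]]), tolerance = 1e-12)
})

test_that("engine ARG likelihood equals the marginal-tree pruning oracle", {
  set.seed(23)
  for (rep in 1:5) {
    arg <- simulate_arg(simulation_spec(n = sample(3:7, 1), L = 300,
                                        theta = 0.03, rho = 3))
    aln <- simulate_sequences(arg, model_f84)
    expect_equal(arg_log_likelihood(arg, aln, model_f84),
                 arg_log_likelihood_reference(arg, aln, model_f84),
                 tolerance = 1e-9)
  }
})

test_that("permuting columns within one marginal interval preserves the likelihood", {
  set.seed(24)
  repeat {
    arg <- simulate_arg(simulation_spec(n = 5, L = 200, theta = 0.05, rho = 2))
    mt <- marginal_trees(arg)
    if (length(mt) >= 2) break
  }
  aln <- simulate_sequences(arg, model_f84)
  base <- arg_log_likelihood(arg, aln, model_f84)
  iv1 <- mt[[1]]$interval
  cols <- seq.int(iv1[1] + 1L, iv1[2])
  perm <- aln
  perm$matrix[, cols] <- perm$matrix[, rev(cols)]
  perm <- alias_columns(perm)
  expect_equal(arg_log_likelihood(arg, perm, model_f84), base, tolerance = 1e-9)
})

test_that("independent JC pruning agrees with phangorn on a fixed tree", {
  set.seed(25)
  arg <- simulate_arg(simulation_spec(n = 5, L = 40, theta = 0.1, rho = 0))
  aln <- simulate_sequences(arg, substitution_model("F84", kappa = 0))
  jc <- substitution_model("TN93", base_frequencies(rep(0.25, 4)),
                           alpha_R = 1, alpha_Y = 1)
  mine <- sum(tree_log_likelihood(extract_marginal_tree(arg, 0), aln$matrix, jc))
  phy <- marginal_tree_to_phylo(extract_marginal_tree(arg, 0))
  dat <- phangorn::phyDat(aln$matrix)
  names(dat) <- aln$names
  fit <- phangorn::pml(phy, dat)
  expect_equal(mine, fit$logLik, tolerance = 1e-6)
})

test_that("likelihood context recomputes only dirty intervals", {
  set.seed(26)
  arg <- simulate_arg(simulation_spec(n = 5, L = 150, theta = 0.05, rho = 2))
  aln <- simulate_sequences(arg, model_f84)
  ctx <- lik_context(arg, aln, model_f84)
  full <- recompute(ctx)
  expect_equal(full, arg_log_likelihood(arg, aln, model_f84), tolerance = 1e-9)
  evals <- ctx$n_interval_evals
  expect_equal(recompute(ctx), full)          # cached value returned ...
  expect_equal(ctx$n_interval_evals, evals)   # ... with zero evaluations
  mark_dirty(ctx, intervals = cbind(0L, 10L))
  expect_equal(recompute(ctx), full, tolerance = 1e-12)
  expect_gt(ctx$n_interval_evals, evals)
  mark_dirty(ctx, nodes = 1L)
  expect_equal(recompute(ctx), full, tolerance = 1e-12)
  expect_error(mark_dirty(ctx, nodes = 999L), "unknown node")
})

test_that("label or length mismatches are rejected", {
  arg <- two_tip_arg(0.3, L = 5)
  aln <- alignment(matrix("A", 2, 4), names = c("a", "b"))
  expect_error(arg_log_likelihood(arg, aln, model_f84), "sites")
  aln2 <- alignment(matrix("A", 2, 5), names = c("x", "y"))
  expect_error(arg_log_likelihood(arg, aln2, model_f84), "labels")
})
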