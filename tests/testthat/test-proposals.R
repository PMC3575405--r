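# Proposal kernels: auto-rejection, Hastings ratios with computable forms,
# reversibility of the reversible-jump pair, and dirty-set validity.

pop1 <- population_model(1)
rec1 <- recombination_model(1)
model1 <- substitution_model("F84", kappa = 2)

test_that("removing a recombination from a recombination-free ARG auto-rejects", {
  arg <- simulate_arg(simulation_spec(n = 4, L = 20, theta = 1, rho = 0), seed = 1)
  set.seed(1)
  p <- propose_kernel(arg, "remove_recombination", pop1, rec1, model1)
  expect_false(p$ok)
})

test_that("whole-ARG scaling has Hastings ratio d * log(m)", {
  arg <- simulate_arg(simulation_spec(n = 5, L = 30, theta = 1, rho = 1), seed = 2)
  d <- sum(arg$nodes$kind != "tip")
  set.seed(3)
  for (i in 1:5) {
    p <- propose_kernel(arg, "arg_scale", pop1, rec1, model1)
    m <- p$arg$nodes$height[p$arg$nodes$kind != "tip"][1] /
      arg$nodes$height[arg$nodes$kind != "tip"][1]
    expect_equal(p$log_hr, d * log(m), tolerance = 1e-10)
    # heights scale jointly, breakpoints are untouched
    expect_equal(p$arg$nodes$height, arg$nodes$height * m, tolerance = 1e-12)
    expect_identical(p$arg$nodes$breakpoint, arg$nodes$breakpoint)
  }
})

test_that("scalar multiplier moves have Hastings ratio log(m)", {
  arg <- simulate_arg(simulation_spec(n = 4, L = 20, theta = 1, rho = 1), seed = 4)
  set.seed(5)
  p <- propose_kernel(arg, "scalar_theta", pop1, rec1, model1)
  expect_equal(p$log_hr, log(p$theta / 1), tolerance = 1e-12)
  p2 <- propose_kernel(arg, "scalar_rho", pop1, rec1, model1)
  expect_equal(p2$log_hr, log(p2$rho / 1), tolerance = 1e-12)
})

test_that("height moves respect parent/child bounds and have zero Hastings ratio", {
  set.seed(6)
  arg <- simulate_arg(simulation_spec(n = 6, L = 40, theta = 1, rho = 2))
  for (i in 1:50) {
    p <- propose_kernel(arg, "node_height", pop1, rec1, model1)
    expect_true(p$ok)
    expect_identical(p$log_hr, 0)
    expect_identical(validate_arg(p$arg), character(0))
  }
})

test_that("regraft and reversible-jump proposals always yield valid ARGs", {
  set.seed(7)
  for (rep in 1:30) {
    arg <- simulate_arg(simulation_spec(n = 5, L = 30, theta = 1, rho = 2))
    for (kern in c("subtree_regraft", "add_recombination",
                   "remove_recombination", "breakpoint_shift")) {
      p <- propose_kernel(arg, kern, pop1, rec1, model1)
      if (p$ok) expect_identical(validate_arg(p$arg), character(0))
    }
  }
})

test_that("a birth followed by its exact inverse death restores the state", {
  set.seed(8)
  n_round <- 0
  for (rep in 1:200) {
    arg <- simulate_arg(simulation_spec(n = 4, L = 20, theta = 1, rho = 1))
    pb <- propose_kernel(arg, "add_recombination", pop1, rec1, model1)
    if (!pb$ok) next
    for (try in 1:60) {
      pd <- propose_kernel(pb$arg, "remove_recombination", pop1, rec1, model1)
      if (!pd$ok) next
      a0 <- arg$nodes
      a2 <- pd$arg$nodes
      same <- nrow(a0) == nrow(a2) &&
        isTRUE(all.equal(sort(a0$height), sort(a2$height), tolerance = 1e-14)) &&
        identical(sort(a0$breakpoint), sort(a2$breakpoint))
      if (same) {
        # marginal trees identical at every breakpoint-delimited site
        for (s in c(0L, arg$L %/% 2L, arg$L - 1L)) {
          expect_identical(tree_sig(arg, s), tree_sig(pd$arg, s))
        }
        expect_equal(pb$log_hr + pd$log_hr, 0, tolerance = 1e-9)
        n_round <- n_round + 1
        break
      }
    }
    if (n_round >= 25) break
  }
  expect_gte(n_round, 25)
})

test_that("dirty sets are supersets of the affected sites (fuzzed audit)", {
  model <- substitution_model("F84", kappa = 2)
  arg <- simulate_arg(simulation_spec(n = 6, L = 500, theta = 0.05, rho = 2),
                      seed = 9)
  aln <- simulate_sequences(arg, model, seed = 10)
  params <- recoal:::.params_to_cpp(
    population_model(0.05), recombination_model(2), model,
    prior_spec(theta = list(sampled = TRUE), rho = list(sampled = TRUE),
               sub = list(sampled = TRUE, lo = 0.01, hi = 50))
  )
  w <- unname(kernel_weights(TRUE, TRUE, TRUE, TRUE))
  cfg <- c(recoal:::.default_tuning(0.05),
           list(weights = w, n_steps = 0, sample_interval = 0,
                arg_sample_interval = 0, burnin = 0, audit_interval = 0,
                temperature = 1, tune = FALSE, step_offset = 0))
  set.seed(11)
  fz <- recoal:::cpp_fuzz_audit(recoal:::.arg_to_cpp(arg),
                                recoal:::.aln_to_cpp(aln), params, cfg,
                                500L, w)
  expect_gt(fz$n_evaluated, 100)
  expect_lt(fz$max_abs_diff, 1e-9)
})

test_that("prior-only sampling with all kernels matches direct simulation", {
  # reduced-scale version of the full validation battery
  pop <- population_model(1)
  rec <- recombination_model(1)
  fit <- run_prior_mcmc(n = 5, L = 100, pop = pop, rec = rec,
    config = run_config(chain_length = 1e5, sample_interval = 100,
                        burnin_fraction = 0.2, seed = 12, audit_interval = 0))
  tr <- fit$trace[fit$trace$step > 2e4, ]
  set.seed(13)
  sims <- t(replicate(700, {
    a <- simulate_arg(simulation_spec(n = 5, L = 100, theta = 1, rho = 1))
    c(n_recombinations(a), arg_root_height(a))
  }))
  expect_gt(suppressWarnings(stats::ks.test(tr$n_recomb, sims[, 1]))$p.value, 0.01)
  expect_gt(suppressWarnings(stats::ks.test(tr$root_height, sims[, 2]))$p.value, 0.01)
})
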