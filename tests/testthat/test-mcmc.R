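# Chain mechanics: determinism, caching audits, Metropolis coupling,
# restart-from-best, convergence heuristic.

make_dataset <- function(seed = 101, n = 6, L = 400) {
  model <- substitution_model("F84", kappa = 2)
  arg <- simulate_arg(simulation_spec(n = n, L = L, theta = 0.02, rho = 1),
                      seed = seed)
  list(aln = simulate_sequences(arg, model, seed = seed + 1), model = model)
}

test_that("a zero-length chain returns a header-only log", {
  d <- make_dataset()
  fit <- run_mcmc(d$aln, population_model(0.02), recombination_model(1),
                  d$model, run_config(chain_length = 0, seed = 1))
  expect_equal(nrow(fit$trace), 0)
  expect_named(fit$trace, c("step", "loglik", "logprior", "theta", "rho",
                            "sub1", "sub2", "n_recomb", "root_height"))
})

test_that("fixed seed gives bit-identical traces and sampled ARGs", {
  d <- make_dataset()
  cfg <- run_config(chain_length = 5000, sample_interval = 100, seed = 7,
                    priors = prior_spec(theta = list(sampled = TRUE),
                                        rho = list(sampled = TRUE)))
  f1 <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model, cfg)
  f2 <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model, cfg)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$arg_samples, f2$arg_samples)
})

test_that("cached likelihood and prior agree with from-scratch recomputation", {
  d <- make_dataset(111)
  fit <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model,
                  run_config(chain_length = 2e4, sample_interval = 100,
                             audit_interval = 5, seed = 3,
                             priors = prior_spec(theta = list(sampled = TRUE),
                                                 rho = list(sampled = TRUE))))
  expect_lt(fit$audit[["loglik"]], 1e-9)
  expect_lt(fit$audit[["logprior"]], 1e-9)
})

test_that("Metropolis-coupled runs sample only the cold chain and swap states", {
  d <- make_dataset(121)
  fit <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model,
                  run_config(chain_length = 1e4, sample_interval = 100,
                             n_chains = 3, swap_interval = 200, seed = 5,
                             priors = prior_spec(theta = list(sampled = TRUE))))
  expect_equal(nrow(fit$trace), 100)
  expect_false(is.na(fit$swap_rate))
  expect_gte(fit$swap_rate, 0)
})

test_that("swaps between identical states are always accepted", {
  set.seed(1)
  for (i in 1:10) expect_true(mc3_swap_accept(-100, -100, 1, 1.1))
})

test_that("restart_from_best seeds a new run with the stored best ARG", {
  d <- make_dataset(131)
  fit <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model,
                  run_config(chain_length = 4000, sample_interval = 100, seed = 9))
  expect_false(is.null(fit$best_arg))
  expect_gt(fit$best_step, 0)
  rb <- restart_from_best(fit)
  expect_identical(validate_arg(rb$init_arg), character(0))
  fit2 <- run_mcmc(d$aln, rb$pop, rb$rec, rb$model, rb$config,
                   init_arg = rb$init_arg)
  expect_equal(nrow(fit2$trace), nrow(fit$trace))

  empty <- fit
  empty$best_arg <- NULL
  expect_error(restart_from_best(empty), "no stored ARGs")
})

test_that("the convergence heuristic reports quartile means and a verdict", {
  d <- make_dataset(141)
  fit <- run_mcmc(d$aln, population_model(0.02), recombination_model(1), d$model,
                  run_config(chain_length = 2e4, sample_interval = 100, seed = 11))
  cc <- convergence_check(fit)
  expect_length(cc$means, 4)
  expect_type(cc$converged, "logical")
})

test_that("rejected proposals leave the state bit-exactly unchanged", {
  # force universal rejection: only recombination births are proposed but
  # rho is fixed at zero, so the prior vetoes every proposal
  arg <- simulate_arg(simulation_spec(n = 5, L = 50, theta = 1, rho = 0),
                      seed = 15)
  w <- kernel_weights()
  w[] <- 0
  w["add_recombination"] <- 1
  fit <- run_prior_mcmc(n = 5, L = 50, pop = population_model(1),
                        rec = recombination_model(0),
                        config = run_config(chain_length = 500,
                                            sample_interval = 100,
                                            kernel_weights = w, seed = 15,
                                            tune = FALSE, audit_interval = 0))
  expect_equal(sum(fit$acceptance$accepted), 0)
  # the chain state never moved
  expect_equal(length(unique(fit$trace$root_height)), 1)
})
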