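# Executable validation battery: the sampler is certified by checking that
# (i) prior-only MCMC reproduces direct backward simulation, (ii) trees at
# a single site are standard coalescent trees regardless of recombination
# elsewhere, and (iii) the engine's full ARG log-likelihood equals the sum
# of independent plain-tree pruning log-likelihoods over marginal trees.
#
# KS tests at p > 0.01 have a 1% false-alarm rate per invocation; each
# statistical test therefore allows up to `attempts` runs with disjoint
# seeds before reporting failure.

#' Prior-equivalence test: MCMC vs direct backward simulation
#'
#' Runs prior-only MCMC (all kernels active) and direct simulation under
#' the same coalescent-with-recombination rates, then compares breakpoint
#' counts and root heights by two-sample Kolmogorov-Smirnov tests.
#'
#' @param n,theta,rho study conditions.
#' @param L sequence length.
#' @param steps MCMC steps per attempt.
#' @param n_samples samples per side.
#' @param seed base seed; attempt `i` uses `seed + i - 1` (MCMC) and an
#'   offset stream for the simulator.
#' @param attempts maximum tries before reporting failure.
#' @return list with KS statistics/p-values of the passing (or last)
#'   attempt, the sampled values, and `pass`.
#' @export
prior_equivalence_test <- function(n = 10, theta = 1, rho = 1, L = 1000,
                                   steps = 1e6, n_samples = 1000, seed = 1,
                                   attempts = 3) {
  pop <- population_model(theta)
  rec <- recombination_model(rho)
  out <- NULL
  for (a in seq_len(attempts)) {
    fit <- run_prior_mcmc(
      n = n, L = L, pop = pop, rec = rec,
      config = run_config(
        chain_length = steps, sample_interval = max(1, floor(steps / n_samples)),
        burnin_fraction = 0.2, seed = seed + (a - 1), audit_interval = 0
      )
    )
    tr <- fit$trace
    tr <- tr[tr$step > 0.2 * steps, ]
    set.seed(seed + 1000 + (a - 1))
    sims <- replicate(n_samples, {
      arg <- simulate_arg(simulation_spec(n = n, L = L, theta = theta, rho = rho))
      c(n_recomb = n_recombinations(arg), root = arg_root_height(arg))
    })
    ks_bp <- suppressWarnings(
      stats::ks.test(tr$n_recomb, sims["n_recomb", ])
    )
    ks_rh <- suppressWarnings(stats::ks.test(tr$root_height, sims["root", ]))
    out <- list(
      ks_breakpoints = unname(ks_bp$statistic), p_breakpoints = ks_bp$p.value,
      ks_root_height = unname(ks_rh$statistic), p_root_height = ks_rh$p.value,
      mcmc_root_height = tr$root_height, sim_root_height = sims["root", ],
      mcmc_n_recomb = tr$n_recomb, sim_n_recomb = sims["n_recomb", ],
      attempt = a,
      pass = ks_bp$p.value > 0.01 && ks_rh$p.value > 0.01
    )
    if (out$pass) break
  }
  out
}

#' Single-site neutrality test
#'
#' The TMRCA distribution at one site must match the standard coalescent
#' regardless of the recombination rate elsewhere on the sequence.
#' Compares site-0 TMRCA from prior-only MCMC at each `rho` against direct
#' coalescent simulation at `rho = 0` (KS, p > 0.01 each).
#'
#' @param n,theta study conditions.
#' @param rhos recombination rates to test.
#' @param L sequence length.
#' @param steps MCMC steps per rate.
#' @param n_samples samples per side.
#' @param seed,attempts as in [prior_equivalence_test()].
#' @return list with per-rho p-values and `pass`.
#' @export
single_site_tmrca_test <- function(n = 10, theta = 1, rhos = c(0, 1, 5),
                                   L = 1000, steps = 1e6, n_samples = 1000,
                                   seed = 1, attempts = 3) {
  pop <- population_model(theta)
  set.seed(seed + 5000)
  ref <- replicate(n_samples, {
    arg <- simulate_arg(simulation_spec(n = n, L = 2, theta = theta, rho = 0))
    arg_root_height(arg)
  })
  pvals <- stats::setNames(numeric(length(rhos)), paste0("rho", rhos))
  tmrcas <- list()
  for (j in seq_along(rhos)) {
    for (a in seq_len(attempts)) {
      fit <- run_prior_mcmc(
        n = n, L = L, pop = pop, rec = recombination_model(rhos[j]),
        config = run_config(
          chain_length = steps,
          sample_interval = max(1, floor(steps / n_samples)),
          arg_sample_interval = max(1, floor(steps / n_samples)),
          burnin_fraction = 0.2, seed = seed + 10 * j + (a - 1),
          audit_interval = 0
        )
      )
      tm <- vapply(fit$arg_samples, function(arg) {
        extract_marginal_tree(arg, 0L)$tmrca
      }, numeric(1))
      ks <- suppressWarnings(stats::ks.test(tm, ref))
      pvals[j] <- ks$p.value
      tmrcas[[j]] <- tm
      if (ks$p.value > 0.01) break
    }
  }
  list(p_values = pvals, site0_tmrca = tmrcas, reference = ref,
       pass = all(pvals > 0.01))
}

#' Likelihood-sum test: ARG likelihood vs marginal-tree pruning oracle
#'
#' For random simulated ARGs with simulated sequences, the engine's full
#' ARG log-likelihood must equal the sum over marginal trees of
#' log-likelihoods from the independent plain-tree pruning implementation
#' ([tree_log_likelihood()]), within `tol`.
#'
#' @param replicates number of random ARG/alignment pairs.
#' @param n_max,L_max upper bounds for the random problem sizes.
#' @param tol absolute log-likelihood tolerance.
#' @param seed RNG seed.
#' @return list with per-replicate deviations and `pass`.
#' @export
likelihood_sum_test <- function(replicates = 50, n_max = 8, L_max = 1000,
                                tol = 1e-6, seed = 1) {
  set.seed(seed)
  devs <- numeric(replicates)
  for (i in seq_len(replicates)) {
    n <- sample(3:n_max, 1)
    L <- sample(50:L_max, 1)
    model <- substitution_model("F84", base_frequencies(c(0.3, 0.2, 0.3, 0.2)),
                                kappa = stats::runif(1, 0.5, 3))
    arg <- simulate_arg(simulation_spec(
      n = n, L = L, theta = stats::runif(1, 0.005, 0.05),
      rho = stats::runif(1, 0.5, 5), model = model
    ))
    aln <- simulate_sequences(arg, model)
    full <- arg_log_likelihood(arg, aln, model)
    oracle <- arg_log_likelihood_reference(arg, aln, model)
    devs[i] <- abs(full - oracle)
  }
  list(max_abs_diff = max(devs), deviations = devs, pass = all(devs < tol))
}
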