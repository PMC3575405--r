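# The Metropolis-Hastings-Green chain over ARGs, with optional Metropolis
# coupling across heated chains.

#' Run configuration
#'
#' @param chain_length total number of MCMC steps, `> 0` (0 allowed for a
#'   header-only run).
#' @param sample_interval steps between trace samples.
#' @param arg_sample_interval steps between stored ARG samples (post
#'   burn-in); defaults to `10 * sample_interval`.
#' @param burnin_fraction fraction of the chain discarded as burn-in
#'   (kernel auto-tuning is active only during burn-in).
#' @param n_chains number of Metropolis-coupled chains (1 = plain MCMC).
#' @param temp_lambda geometric temperature-ladder increment: chain `i`
#'   runs at temperature `(1 + temp_lambda)^(i-1)`.
#' @param swap_interval steps between proposed chain swaps.
#' @param priors a [prior_spec()]; parameters with `sampled = TRUE` are
#'   estimated.
#' @param kernel_weights named weights over proposal kernels
#'   (see [kernel_weights()]); `NULL` = defaults derived from the priors.
#' @param tune auto-tune kernel windows toward 0.234 acceptance during
#'   burn-in.
#' @param audit_interval audit cached likelihood/prior against a
#'   from-scratch recomputation every this many trace samples (0 = off).
#' @param seed integer seed; every source of randomness in the run derives
#'   from it.
#' @param output_prefix optional path prefix; when set, [run_mcmc()]
#'   writes `<prefix>.trace.tsv` and run metadata JSON.
#' @return object of class `run_config`.
#' @export
run_config <- function(chain_length = 1e5, sample_interval = 100,
                       arg_sample_interval = NULL, burnin_fraction = 0.5,
                       n_chains = 1, temp_lambda = 0.1, swap_interval = 100,
                       priors = prior_spec(), kernel_weights = NULL,
                       tune = TRUE, audit_interval = 10, seed = 1,
                       output_prefix = NULL) {
  if (chain_length < 0) stop("chain_length must be >= 0")
  if (n_chains < 1) stop("n_chains must be >= 1")
  if (burnin_fraction < 0 || burnin_fraction >= 1) {
    stop("burnin_fraction must be in [0, 1)")
  }
  if (is.null(arg_sample_interval)) arg_sample_interval <- 10 * sample_interval
  structure(
    list(
      chain_length = chain_length, sample_interval = sample_interval,
      arg_sample_interval = arg_sample_interval,
      burnin_fraction = burnin_fraction, n_chains = n_chains,
      temp_lambda = temp_lambda, swap_interval = swap_interval,
      priors = priors, kernel_weights = kernel_weights, tune = tune,
      audit_interval = audit_interval, seed = seed,
      output_prefix = output_prefix
    ),
    class = "run_config"
  )
}

.cfg_to_cpp <- function(config, tuning, weights, n_steps, burnin, temperature,
                        step_offset = 0, arg_sample_interval = NULL) {
  c(tuning, list(
    weights = unname(weights),
    n_steps = n_steps,
    sample_interval = config$sample_interval,
    arg_sample_interval = if (is.null(arg_sample_interval))
      config$arg_sample_interval else arg_sample_interval,
    burnin = burnin,
    audit_interval = config$audit_interval,
    temperature = temperature,
    tune = config$tune,
    step_offset = step_offset
  ))
}

.trace_df <- function(mat) {
  df <- as.data.frame(mat)
  names(df) <- c("step", "loglik", "logprior", "theta", "rho",
                 "sub1", "sub2", "n_recomb", "root_height")
  df
}

# distance-based ultrametric starting tree (UPGMA on raw mismatch fractions)
.initial_arg <- function(alignment, theta) {
  m <- alignment$matrix
  n <- nrow(m)
  L <- ncol(m)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ok <- m[i, ] %in% c("A", "C", "G", "T") & m[j, ] %in% c("A", "C", "G", "T")
      p <- if (any(ok)) mean(m[i, ok] != m[j, ok]) else 0
      d[i, j] <- d[j, i] <- p
    }
  }
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  k <- n - 1
  nodes <- data.frame(
    height = c(rep(0, n), pmax(hc$height / 2, 1e-8 * seq_len(k))),
    kind = c(rep("tip", n), rep("coalescent", k)),
    child1 = NA_integer_, child2 = NA_integer_,
    parent1 = NA_integer_, parent2 = NA_integer_,
    breakpoint = NA_integer_
  )
  # make heights strictly increasing to satisfy parent-above-child
  for (i in seq_len(k)) {
    lo <- 0
    for (s in 1:2) {
      ch <- hc$merge[i, s]
      id <- if (ch < 0) -ch else n + ch
      lo <- max(lo, nodes$height[id])
    }
    nodes$height[n + i] <- max(nodes$height[n + i], lo * (1 + 1e-6) + 1e-10)
    for (s in 1:2) {
      ch <- hc$merge[i, s]
      id <- if (ch < 0) -ch else n + ch
      if (s == 1) nodes$child1[n + i] <- id else nodes$child2[n + i] <- id
      nodes$parent1[id] <- n + i
    }
  }
  arg <- new_arg(nodes, n_tips = n, L = L, tip_labels = alignment$names)
  annotate_ancestral_material(arg)
}

#' Run the MCMC sampler
#'
#' Samples ARGs (and any parameters flagged `sampled` in the config's
#' priors) from the posterior given an alignment, or from the
#' coalescent-with-recombination prior when `alignment` is `NULL`.
#' With `n_chains > 1` additional heated chains run at geometric
#' temperatures and exchange states by the standard coupled-chain
#' acceptance ratio; only the cold chain is sampled.
#'
#' Fixed seed and single thread give bit-identical traces.
#'
#' @param alignment an [alignment()] or `NULL` for prior-only sampling.
#' @param pop a [population_model()] (initial `theta0` when sampled).
#' @param rec a [recombination_model()] (initial `rho` when sampled).
#' @param model a [substitution_model()].
#' @param config a [run_config()].
#' @param init_arg optional starting ARG; default is a UPGMA tree from the
#'   data, or a prior simulation when `alignment` is `NULL`.
#' @return object of class `recoal_fit`: `trace` (data frame),
#'   `arg_samples` (list of sampled ARGs with `$step`, `$theta`, `$rho`),
#'   `acceptance` (per-kernel counts), `best_arg`/`best_step` (maximum
#'   data-likelihood sample), `audit` (max cached-vs-scratch deviations),
#'   `final_state`, and the inputs needed to restart.
#' @export
run_mcmc <- function(alignment = NULL, pop, rec,
                     model = substitution_model("F84", kappa = 2),
                     config = run_config(), init_arg = NULL) {
  stopifnot(inherits(config, "run_config"))
  set.seed(config$seed)
  prior_only <- is.null(alignment)
  if (!prior_only && is.null(alignment$alias)) alignment <- alias_columns(alignment)
  if (is.null(init_arg)) {
    if (prior_only) {
      stop("prior-only runs need `init_arg` (or use run_prior_mcmc())")
    }
    init_arg <- .initial_arg(alignment, pop$theta0)
  }
  .run_mcmc_impl(alignment, pop, rec, model, config, init_arg)
}

#' Run prior-only MCMC for a sample size and sequence length
#'
#' Convenience wrapper around [run_mcmc()] with no data: the chain's
#' stationary distribution is the coalescent-with-recombination prior
#' itself, which is how the sampler is validated against direct backward
#' simulation.
#'
#' @param n number of tips.
#' @param L number of sites.
#' @inheritParams run_mcmc
#' @return a `recoal_fit` (see [run_mcmc()]).
#' @export
run_prior_mcmc <- function(n, L, pop, rec, config = run_config()) {
  set.seed(config$seed)
  init <- simulate_arg(simulation_spec(
    n = n, L = L, theta = pop$theta0, rho = rec$rho, growth = pop$growth
  ))
  .run_mcmc_impl(NULL, pop, rec, substitution_model("F84", kappa = 2),
                 config, init)
}

.run_mcmc_impl <- function(alignment, pop, rec, model, config, init_arg) {
  prior_only <- is.null(alignment)
  if (!prior_only) .check_arg_aln(init_arg, alignment)
  priors <- config$priors
  weights <- config$kernel_weights
  if (is.null(weights)) {
    weights <- kernel_weights(
      theta_sampled = priors$theta$sampled, rho_sampled = priors$rho$sampled,
      sub_sampled = priors$sub$sampled, rho_positive = rec$rho > 0
    )
  }
  if (model$family == "TN93" && priors$sub$sampled) {
    weights["scalar_sub2"] <- weights["scalar_sub1"]
  }
  aln_cpp <- if (prior_only) NULL else .aln_to_cpp(alignment)
  tuning <- .default_tuning(pop$theta0)
  burnin <- floor(config$chain_length * config$burnin_fraction)
  n_chains <- config$n_chains
  temps <- (1 + config$temp_lambda)^(seq_len(n_chains) - 1)

  run_segment <- function(state, n_steps, temperature, step_offset, burnin_left,
                          tuning, sample = TRUE) {
    params <- .params_to_cpp(
      population_model(state$theta, pop$growth),
      recombination_model(state$rho),
      state$model, priors
    )
    cfg <- .cfg_to_cpp(config, tuning, weights, n_steps,
                       burnin = burnin_left, temperature = temperature,
                       step_offset = step_offset,
                       arg_sample_interval =
                         if (sample) config$arg_sample_interval else 0)
    if (!sample) cfg$sample_interval <- 0
    cpp_run_mcmc(.arg_to_cpp(state$arg), aln_cpp, params, cfg)
  }
  mk_state <- function() {
    list(arg = init_arg, theta = pop$theta0, rho = rec$rho, model = model)
  }
  upd_state <- function(state, res) {
    state$arg <- .arg_from_cpp(res$final, init_arg$tip_labels)
    state$theta <- res$final_theta
    state$rho <- res$final_rho
    m <- state$model
    if (m$family == "F84") {
      m <- substitution_model("F84", m$freqs, kappa = res$final_kappa)
    } else {
      m <- substitution_model("TN93", m$freqs, alpha_R = res$final_alpha_R,
                              alpha_Y = res$final_alpha_Y)
    }
    state$model <- m
    list(state = state, loglik = res$final_loglik, logprior = res$final_logprior)
  }

  if (n_chains == 1) {
    state <- mk_state()
    res <- run_segment(state, config$chain_length, 1, 0, burnin, tuning)
    fit <- .collect_fit(res, config, init_arg$tip_labels, alignment, pop, rec,
                        model)
    return(fit)
  }

  # Metropolis coupling: chains advance in swap_interval segments and then
  # propose one adjacent-temperature exchange
  chains <- replicate(n_chains, mk_state(), simplify = FALSE)
  posts <- rep(NA_real_, n_chains)
  done <- 0
  pieces <- list()
  accept <- rep(0L, length(.KERNELS))
  proposed <- rep(0L, length(.KERNELS))
  audits <- c(0, 0)
  n_swap_acc <- 0L
  n_swap <- 0L
  best <- list(arg = NULL, step = -1, loglik = -Inf)
  while (done < config$chain_length) {
    seg <- min(config$swap_interval, config$chain_length - done)
    for (i in seq_len(n_chains)) {
      res <- run_segment(chains[[i]], seg, temps[i], done,
                         burnin_left = max(0, burnin - done), tuning,
                         sample = (i == 1))
      u <- upd_state(chains[[i]], res)
      chains[[i]] <- u$state
      posts[i] <- u$loglik + u$logprior
      if (i == 1) {
        pieces[[length(pieces) + 1]] <- res
        accept <- accept + res$accepted
        proposed <- proposed + res$proposed
        audits <- pmax(audits, c(res$audit_max_loglik_diff,
                                 res$audit_max_logprior_diff))
        if (res$best_loglik > best$loglik && !is.null(res$best_arg)) {
          best <- list(arg = res$best_arg, step = res$best_step,
                       loglik = res$best_loglik)
        }
      }
    }
    done <- done + seg
    if (n_chains >= 2) {
      i <- sample.int(n_chains - 1, 1)
      n_swap <- n_swap + 1L
      log_a <- (1 / temps[i] - 1 / temps[i + 1]) * (posts[i + 1] - posts[i])
      if (log_a >= 0 || stats::runif(1) < exp(log_a)) {
        tmp <- chains[[i]]
        chains[[i]] <- chains[[i + 1]]
        chains[[i + 1]] <- tmp
        posts[c(i, i + 1)] <- posts[c(i + 1, i)]
        n_swap_acc <- n_swap_acc + 1L
      }
    }
  }
  trace <- do.call(rbind, lapply(pieces, function(p) p$trace))
  arg_samples <- do.call(c, lapply(pieces, function(p) p$arg_samples))
  res <- list(
    trace = trace, arg_samples = arg_samples, accepted = accept,
    proposed = proposed, final = .arg_to_cpp(chains[[1]]$arg),
    final_theta = chains[[1]]$theta, final_rho = chains[[1]]$rho,
    final_kappa = chains[[1]]$model$kappa,
    final_alpha_R = chains[[1]]$model$alpha_R,
    final_alpha_Y = chains[[1]]$model$alpha_Y,
    final_loglik = posts[1], final_logprior = NA_real_,
    best_arg = best$arg, best_step = best$step, best_loglik = best$loglik,
    audit_max_loglik_diff = audits[1], audit_max_logprior_diff = audits[2],
    tuning = tuning
  )
  fit <- .collect_fit(res, config, init_arg$tip_labels, alignment, pop, rec,
                      model)
  fit$swap_rate <- if (n_swap > 0) n_swap_acc / n_swap else NA_real_
  fit
}

.collect_fit <- function(res, config, tip_labels, alignment, pop, rec, model) {
  trace <- .trace_df(res$trace)
  samples <- lapply(res$arg_samples, function(s) {
    a <- .arg_from_cpp(s, tip_labels)
    a$step <- s$step
    a$theta <- s$theta
    a$rho <- s$rho
    a
  })
  fit <- structure(
    list(
      trace = trace,
      arg_samples = samples,
      acceptance = data.frame(
        kernel = .KERNELS, proposed = res$proposed, accepted = res$accepted,
        rate = ifelse(res$proposed > 0, res$accepted / res$proposed, NA)
      ),
      best_arg = if (!is.null(res$best_arg))
        .arg_from_cpp(res$best_arg, tip_labels) else NULL,
      best_step = res$best_step,
      best_loglik = res$best_loglik,
      audit = c(loglik = res$audit_max_loglik_diff,
                logprior = res$audit_max_logprior_diff),
      final_state = list(
        arg = .arg_from_cpp(res$final, tip_labels),
        theta = res$final_theta, rho = res$final_rho
      ),
      tuning = res$tuning,
      config = config, pop = pop, rec = rec, model = model
    ),
    class = "recoal_fit"
  )
  if (!is.null(config$output_prefix)) {
    utils::write.table(
      trace, paste0(config$output_prefix, ".trace.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    meta <- list(
      seed = config$seed, chain_length = config$chain_length,
      n_chains = config$n_chains, sample_interval = config$sample_interval,
      package_version = as.character(utils::packageVersion("recoal"))
    )
    jsonlite::write_json(meta, paste0(config$output_prefix, ".meta.json"),
                         auto_unbox = TRUE)
  }
  fit
}

#' @export
print.recoal_fit <- function(x, ...) {
  cat(sprintf(
    "recoal MCMC fit: %d trace samples, %d stored ARGs\n",
    nrow(x$trace), length(x$arg_samples)
  ))
  if (nrow(x$trace) > 0) {
    post <- x$trace[x$trace$step > max(x$trace$step) * x$config$burnin_fraction, ]
    if (nrow(post) > 0) {
      cat(sprintf(
        "  post-burn-in means: theta = %.4g, rho = %.4g, breakpoints = %.2f, root height = %.4g\n",
        mean(post$theta), mean(post$rho), mean(post$n_recomb),
        mean(post$root_height)
      ))
    }
  }
  invisible(x)
}

#' Propose a Metropolis-coupled swap between two chains
#'
#' Standard coupled-chain exchange: accept with probability
#' `min(1, exp((1/T_i - 1/T_j) (logpost_j - logpost_i)))`.  Exposed for
#' testing; [run_mcmc()] performs swaps internally.
#'
#' @param logpost_i,logpost_j unheated log-posteriors of the two states.
#' @param temp_i,temp_j their temperatures.
#' @return `TRUE` if the swap is accepted (consumes one uniform draw).
#' @export
mc3_swap_accept <- function(logpost_i, logpost_j, temp_i, temp_j) {
  log_a <- (1 / temp_i - 1 / temp_j) * (logpost_j - logpost_i)
  log_a >= 0 || stats::runif(1) < exp(log_a)
}

#' Restart configuration from the best ARG of a previous run
#'
#' Returns the inputs for a new run initialized at the stored
#' maximum-data-likelihood ARG of `fit` (ties resolved to the earliest
#' step when recorded).
#'
#' @param fit a `recoal_fit` with at least one stored best ARG.
#' @return list with `init_arg`, `pop`, `rec`, `model`, `config` ready to
#'   pass to [run_mcmc()].
#' @export
restart_from_best <- function(fit) {
  if (is.null(fit$best_arg)) stop("no stored ARGs: run with data and sampling enabled")
  list(init_arg = fit$best_arg, pop = fit$pop, rec = fit$rec,
       model = fit$model, config = fit$config)
}

#' Quartile-based convergence heuristic
#'
#' Compares mean and standard deviation of the data-likelihood trace
#' between adjacent quartiles of the post-burn-in samples.  Advisory only.
#'
#' @param fit a `recoal_fit`.
#' @param tol relative tolerance on adjacent-quartile mean differences (in
#'   units of the pooled SD).
#' @return list with per-quartile means/SDs and a logical `converged`.
#' @export
convergence_check <- function(fit, tol = 0.5) {
  tr <- fit$trace
  post <- tr[tr$step > max(tr$step) * fit$config$burnin_fraction, ]
  x <- post$loglik
  if (length(x) < 8) stop("too few post-burn-in samples")
  q <- cut(seq_along(x), 4, labels = FALSE)
  mns <- tapply(x, q, mean)
  sds <- tapply(x, q, stats::sd)
  pooled <- stats::sd(x)
  ok <- all(abs(diff(mns)) < tol * max(pooled, .Machine$double.eps))
  list(means = mns, sds = sds, converged = ok)
}
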