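# Coalescent-with-recombination prior density over ARGs.
#
# Time is measured in expected substitutions per site.  With k extant
# lineages at time t the total coalescence rate is k(k-1)/theta(t) (each
# specific pair coalesces at rate 2/theta(t)); each lineage recombines at
# rate (rho/theta0) * span/(L-1), where span is the number of inter-site
# gaps strictly inside the lineage's ancestral material
# [leftmost, rightmost] (Hudson-style: breakpoints outside ancestral
# material are unidentifiable).  The simulator draws events from exactly
# these rates, so prior density and simulator are consistent by
# construction.

#' Population-size model
#'
#' `theta(t) = theta0 * exp(-growth * t)` looking back in time; `growth = 0`
#' gives the constant-size model.
#'
#' @param theta0 scaled population size `2 N mu` at sampling time, `> 0`.
#' @param growth exponential growth rate per unit time (0 for constant).
#' @return object of class `population_model`.
#' @export
population_model <- function(theta0, growth = 0) {
  if (!is.numeric(theta0) || theta0 <= 0) stop("`theta0` must be > 0")
  structure(list(kind = if (growth == 0) "constant" else "exponential_growth",
                 theta0 = theta0, growth = growth),
            class = "population_model")
}

#' Recombination model
#'
#' A single scaled recombination rate `rho = 2 N r`, constant across sites
#' and over time.
#'
#' @param rho scaled recombination rate, `>= 0`.
#' @return object of class `recombination_model`.
#' @export
recombination_model <- function(rho) {
  if (!is.numeric(rho) || rho < 0) stop("`rho` must be >= 0")
  structure(list(rho = rho), class = "recombination_model")
}

#' Log-density of an ARG under the coalescent with recombination
#'
#' Pure-R implementation (the MCMC engine carries its own identical
#' computation in C++; the two are cross-checked in the test suite).
#' Returns `-Inf` for ARGs containing a recombination when `rho = 0`, or
#' whose breakpoints fall outside the recombining edge's eligible gaps.
#'
#' @param arg a valid [new_arg()] object (annotated automatically).
#' @param pop a [population_model()].
#' @param rec a [recombination_model()].
#' @return log-density (natural log).
#' @export
arg_log_prior <- function(arg, pop, rec) {
  stopifnot(inherits(pop, "population_model"), inherits(rec, "recombination_model"))
  v <- validate_arg(arg)
  if (length(v) > 0) stop("invalid ARG: ", v[1])
  if (is.null(arg$material)) arg <- annotate_ancestral_material(arg)
  nd <- arg$nodes
  L <- arg$L
  theta0 <- pop$theta0
  g <- pop$growth
  rec_const <- if (L > 1) (rec$rho / theta0) / (L - 1) else 0
  ord <- order(nd$height, nd$id)
  ord <- ord[nd$kind[ord] != "tip"]
  lp <- 0
  t0 <- 0
  k <- arg$n_tips
  span_sum <- arg$n_tips * (L - 1)
  edge_span <- function(u, id) {
    slots <- which(c(nd$parent1[u], nd$parent2[u]) == id)
    sum(vapply(slots, function(s) iv_span(.edge_material(arg, u, s)), numeric(1)))
  }
  for (id in ord) {
    # the process stops at the grand MRCA: any event after the lineage
    # count first reaches 1 lies outside the state space
    if (k <= 1) return(-Inf)
    t1 <- nd$height[id]
    dt <- t1 - t0
    coal_int <- if (g == 0) k * (k - 1) / theta0 * dt else
      k * (k - 1) / (theta0 * g) * (exp(g * t1) - exp(g * t0))
    lp <- lp - coal_int - rec_const * span_sum * dt
    if (nd$kind[id] == "coalescent") {
      lp <- lp + log(2) - (log(theta0) - g * t1)
      for (u in unique(c(nd$child1[id], nd$child2[id]))) {
        span_sum <- span_sum - edge_span(u, id)
      }
      if (!is.na(nd$parent1[id])) span_sum <- span_sum + iv_span(arg$material[[id]])
      k <- k - 1
    } else {
      m <- arg$material[[id]]
      b <- nd$breakpoint[id]
      eligible <- nrow(m) > 0 && iv_min(m) < b && b <= iv_max(m)
      if (!eligible || rec_const <= 0) return(-Inf)
      lp <- lp + log(rec_const)
      parts <- iv_split(m, b)
      span_sum <- span_sum - iv_span(m) + iv_span(parts$left) + iv_span(parts$right)
      k <- k + 1
    }
    t0 <- t1
  }
  unname(lp)
}

#' Prior specification for sampled scalar parameters
#'
#' Defaults: `theta` and `rho` get uniform-on-log (Jeffreys-like) priors on
#' configurable bounds; the substitution parameter (`kappa` for F84) gets a
#' uniform prior.  `sampled = FALSE` holds a parameter fixed.
#'
#' @param theta,rho,sub each a list `list(sampled=, lo=, hi=)`.
#' @return object of class `prior_spec`.
#' @export
prior_spec <- function(theta = list(sampled = FALSE, lo = 1e-6, hi = 1e2),
                       rho = list(sampled = FALSE, lo = 1e-4, hi = 1e4),
                       sub = list(sampled = FALSE, lo = 0, hi = 100)) {
  fill <- function(x, d) utils::modifyList(d, x)
  structure(
    list(
      theta = fill(theta, list(sampled = FALSE, lo = 1e-6, hi = 1e2)),
      rho = fill(rho, list(sampled = FALSE, lo = 1e-4, hi = 1e4)),
      sub = fill(sub, list(sampled = FALSE, lo = 0, hi = 100))
    ),
    class = "prior_spec"
  )
}

#' Joint log-prior of the sampled scalar parameters
#'
#' Sum of independent log-densities: normalized log-uniform
#' `1/(x log(hi/lo))` for `theta` and `rho`, uniform for the substitution
#' parameter.  Fixed (`sampled = FALSE`) parameters contribute 0.
#' Out-of-support values give `-Inf`.
#'
#' @param theta,rho,sub_param current parameter values.
#' @param priors a [prior_spec()].
#' @return log-density scalar.
#' @export
parameter_log_prior <- function(theta, rho, sub_param = NULL,
                                priors = prior_spec()) {
  lp <- 0
  logunif <- function(x, b) {
    if (x < b$lo || x > b$hi) return(-Inf)
    -log(x) - log(log(b$hi / b$lo))
  }
  if (priors$theta$sampled) lp <- lp + logunif(theta, priors$theta)
  if (priors$rho$sampled) lp <- lp + logunif(rho, priors$rho)
  if (priors$sub$sampled && !is.null(sub_param)) {
    b <- priors$sub
    lp <- lp + if (sub_param < b$lo || sub_param > b$hi) -Inf else -log(b$hi - b$lo)
  }
  lp
}
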