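# Coalescent-with-recombination prior density: closed forms, the
# simulator-as-density oracle, growth via the time transformation, and the
# engine's internal computation.

test_that("two-tip constant-size density matches the closed form", {
  pop <- population_model(0.7)
  rec <- recombination_model(0)
  for (t in c(0.1, 0.5, 2)) {
    expect_equal(arg_log_prior(two_tip_arg(t), pop, rec),
                 log(2 / 0.7) - 2 * t / 0.7, tolerance = 1e-12)
  }
})

test_that("rho = 0 forbids recombination nodes", {
  pop <- population_model(1)
  triv <- trivial_recomb_arg()
  expect_identical(arg_log_prior(triv, pop, recombination_model(0)), -Inf)
  expect_gt(arg_log_prior(triv, pop, recombination_model(1)), -Inf)
})

test_that("breakpoints outside eligible gaps have zero density", {
  nested <- nested_nonancestral_arg()  # node 5 splits outside its material
  expect_identical(
    arg_log_prior(nested, population_model(1), recombination_model(1)), -Inf
  )
})

test_that("events above the grand MRCA lie outside the state space", {
  # trivial recombination tower above the point where both tips coalesced
  tower <- new_arg(data.frame(
    height = c(0, 0, 0.3, 0.6, 0.9),
    kind = c("tip", "tip", "coalescent", "recombination", "coalescent"),
    child1 = c(NA, NA, 1L, 3L, 4L),
    child2 = c(NA, NA, 2L, NA, 4L),
    parent1 = c(3L, 3L, 4L, 5L, NA),
    parent2 = c(NA, NA, NA, 5L, NA),
    breakpoint = c(NA, NA, NA, 5L, NA)
  ), n_tips = 2, L = 10)
  expect_identical(validate_arg(tower), character(0))
  expect_identical(
    arg_log_prior(tower, population_model(1), recombination_model(1)), -Inf
  )
})

test_that("prior density equals the generative density of the simulator", {
  set.seed(31)
  pop <- population_model(1)
  rec <- recombination_model(1.5)
  for (i in 1:40) {
    s <- sim_with_density(4, 6, 1, 1.5)
    expect_equal(arg_log_prior(s$arg, pop, rec), s$logdens, tolerance = 1e-9)
  }
})

test_that("R and C++ prior computations agree on recombinant ARGs", {
  set.seed(32)
  pop <- population_model(0.5)
  rec <- recombination_model(2)
  model <- substitution_model("F84")
  for (i in 1:10) {
    arg <- simulate_arg(simulation_spec(n = 5, L = 40, theta = 0.5, rho = 2))
    lpR <- arg_log_prior(arg, pop, rec)
    lpC <- recoal:::cpp_arg_log_prior(
      recoal:::.arg_to_cpp(arg), recoal:::.params_to_cpp(pop, rec, model)
    )
    expect_equal(lpR, lpC, tolerance = 1e-10)
  }
})

test_that("two-tip root height is exponential under the prior (PIT uniform)", {
  set.seed(33)
  theta <- 0.8
  roots <- replicate(1500, arg_root_height(
    simulate_arg(simulation_spec(n = 2, L = 2, theta = theta, rho = 0))
  ))
  pit <- stats::pexp(roots, rate = 2 / theta)
  expect_gt(suppressWarnings(stats::ks.test(pit, "punif"))$p.value, 0.01)
})

test_that("exponential growth uses the exact integrated rate", {
  g <- 3
  theta0 <- 1
  pop <- population_model(theta0, growth = g)
  rec <- recombination_model(0)
  for (t in c(0.2, 0.7)) {
    # rate at s is 2 e^{g s}/theta0; integral has closed form
    expected <- log(2 / theta0) + g * t - 2 * (exp(g * t) - 1) / (theta0 * g)
    expect_equal(arg_log_prior(two_tip_arg(t), pop, rec), expected,
                 tolerance = 1e-10)
    # cross-check the integral numerically
    quad <- stats::integrate(function(s) 2 * exp(g * s) / theta0, 0, t)$value
    expect_equal(expected, log(2 / theta0) + g * t - quad, tolerance = 1e-8)
  }
})

test_that("parameter priors are normalized and respect their support", {
  pr <- prior_spec(theta = list(sampled = TRUE, lo = 0.01, hi = 10),
                   rho = list(sampled = TRUE, lo = 0.1, hi = 100),
                   sub = list(sampled = TRUE, lo = 0, hi = 20))
  expect_identical(parameter_log_prior(0.001, 1, 2, pr), -Inf)
  expect_identical(parameter_log_prior(1, 1000, 2, pr), -Inf)
  expect_identical(parameter_log_prior(1, 1, 30, pr), -Inf)
  # uniform component: equal density at any two in-support values
  d1 <- parameter_log_prior(1, 1, 3, pr) - parameter_log_prior(1, 1, 17, pr)
  expect_equal(d1, 0)
  # log-uniform density is 1/(x log(hi/lo)), and integrates to 1
  x <- 2.5
  expect_equal(parameter_log_prior(x, 1, 2, pr) -
                 parameter_log_prior(1, 1, 2, pr),
               log((1 / (x * log(10 / 0.01))) / (1 / (1 * log(10 / 0.01)))))
  mass <- stats::integrate(function(v) 1 / (v * log(10 / 0.01)), 0.01, 10)$value
  expect_equal(mass, 1, tolerance = 1e-6)
})

test_that("simulator mean root height matches the coalescent closed form", {
  set.seed(34)
  n <- 10
  roots <- replicate(800, arg_root_height(
    simulate_arg(simulation_spec(n = n, L = 2, theta = 1, rho = 0))
  ))
  target <- 1 * (1 - 1 / n)
  se <- stats::sd(roots) / sqrt(length(roots))
  expect_lt(abs(mean(roots) - target), 3 * se)
})
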