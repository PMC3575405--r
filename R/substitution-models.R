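# Nucleotide substitution models: F84 and TN93.
#
# Both models are time-reversible with stationary frequencies pi and one
# (F84) or two (TN93) transition/transversion parameters.  The generator is
# normalized so that one unit of branch length equals one expected
# substitution per site at stationarity; all node heights in the package are
# therefore in units of expected substitutions per site.

.BASES <- c("A", "C", "G", "T")

#' Stationary base frequencies
#'
#' @param freqs numeric vector of length 4 (A, C, G, T order), each in
#'   (0, 1) and summing to 1 within `1e-12`.
#' @return a named numeric vector of class `base_frequencies`.
#' @export
base_frequencies <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (length(freqs) != 4L || any(!is.finite(freqs))) {
    stop("`freqs` must be four finite numbers (A, C, G, T)")
  }
  if (any(freqs <= 0) || any(freqs >= 1)) {
    stop("each base frequency must lie strictly in (0, 1)")
  }
  if (abs(sum(freqs) - 1) > 1e-12) {
    stop("base frequencies must sum to 1 within 1e-12")
  }
  structure(stats::setNames(freqs, .BASES), class = "base_frequencies")
}

#' Construct a nucleotide substitution model
#'
#' `family = "F84"` takes a single transition-excess parameter `kappa`
#' (Felsenstein's convention): the within-purine transition rate is
#' `(1 + kappa/pi_R)` and the within-pyrimidine rate `(1 + kappa/pi_Y)`
#' relative to a transversion rate of 1, where `pi_R = pi_A + pi_G` and
#' `pi_Y = pi_C + pi_T`.  `kappa = 0` reduces to F81 (equal-rate).
#' `family = "TN93"` takes the purine- and pyrimidine-transition rates
#' `alpha_R` and `alpha_Y` directly, relative to the transversion rate
#' `beta = 1`.  F84 is the TN93 sub-case with
#' `alpha_R = 1 + kappa/pi_R`, `alpha_Y = 1 + kappa/pi_Y`.
#'
#' The generator is rescaled so the expected substitution rate at
#' stationarity is exactly 1, making branch lengths interpretable as
#' expected substitutions per site.
#'
#' The transition/transversion *ratio* (expected transitions over expected
#' transversions at stationarity) implied by the parameters is stored in
#' `$ts_tv`.
#'
#' @param family `"F84"` or `"TN93"`.
#' @param freqs stationary frequencies, see [base_frequencies()].
#' @param kappa F84 transition-excess parameter, `>= 0`.
#' @param alpha_R,alpha_Y TN93 transition rates (relative to transversion
#'   rate 1), `> 0`.
#' @return an object of class `substitution_model`.
#' @export
substitution_model <- function(family = c("F84", "TN93"),
                               freqs = base_frequencies(rep(0.25, 4)),
                               kappa = 2, alpha_R = NULL, alpha_Y = NULL) {
  family <- match.arg(family)
  if (!inherits(freqs, "base_frequencies")) freqs <- base_frequencies(freqs)
  piR <- freqs[["A"]] + freqs[["G"]]
  piY <- freqs[["C"]] + freqs[["T"]]
  if (family == "F84") {
    if (!is.numeric(kappa) || length(kappa) != 1L || kappa < 0) {
      stop("`kappa` must be a single number >= 0")
    }
    aR <- 1 + kappa / piR
    aY <- 1 + kappa / piY
  } else {
    if (is.null(alpha_R) || is.null(alpha_Y)) {
      stop("TN93 requires `alpha_R` and `alpha_Y`")
    }
    if (alpha_R <= 0 || alpha_Y <= 0) stop("TN93 rates must be > 0")
    aR <- alpha_R
    aY <- alpha_Y
    kappa <- NA_real_
  }
  # expected substitution rate of the unnormalized generator (beta = 1)
  mu <- 2 * freqs[["A"]] * freqs[["G"]] * aR +
    2 * freqs[["C"]] * freqs[["T"]] * aY +
    2 * piR * piY
  ts <- 2 * freqs[["A"]] * freqs[["G"]] * aR + 2 * freqs[["C"]] * freqs[["T"]] * aY
  tv <- 2 * piR * piY
  structure(
    list(
      family = family, freqs = freqs, kappa = kappa,
      alpha_R = aR, alpha_Y = aY, beta = 1,
      rate_norm = mu, ts_tv = ts / tv
    ),
    class = "substitution_model"
  )
}

#' @export
print.substitution_model <- function(x, ...) {
  cat(sprintf(
    "%s substitution model\n  freqs (ACGT): %s\n  alpha_R = %.4g, alpha_Y = %.4g, beta = 1 (pre-normalization)\n  ts/tv ratio = %.4g\n",
    x$family, paste(sprintf("%.4f", x$freqs), collapse = " "),
    x$alpha_R, x$alpha_Y, x$ts_tv
  ))
  invisible(x)
}

#' Normalized rate matrix (generator) of a substitution model
#'
#' Rows sum to zero and the expected substitution rate at stationarity,
#' `-sum(pi_i * Q_ii)`, equals 1.
#'
#' @param model a [substitution_model()].
#' @return a 4x4 matrix with dimnames A, C, G, T.
#' @export
rate_matrix <- function(model) {
  stopifnot(inherits(model, "substitution_model"))
  p <- unclass(model$freqs)
  aR <- model$alpha_R / model$rate_norm
  aY <- model$alpha_Y / model$rate_norm
  b <- 1 / model$rate_norm
  Q <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  for (i in 1:4) {
    for (j in 1:4) {
      if (i == j) next
      purines <- c(1L, 3L)
      both_pur <- i %in% purines && j %in% purines
      both_pyr <- !(i %in% purines) && !(j %in% purines)
      rate <- if (both_pur) aR else if (both_pyr) aY else b
      Q[i, j] <- rate * p[j]
    }
  }
  diag(Q) <- -rowSums(Q)
  Q
}

#' Transition-probability matrix P(t)
#'
#' Closed-form spectral solution for the TN93 family (F84 included as a
#' sub-case).  Satisfies `P(0) = I`, row sums 1, detailed balance
#' `pi_i P_ij = pi_j P_ji`, and Chapman-Kolmogorov `P(s) P(t) = P(s + t)`.
#'
#' @param model a [substitution_model()].
#' @param t branch length, `>= 0`, in expected substitutions per site.
#' @return a 4x4 stochastic matrix with dimnames A, C, G, T.
#' @export
transition_matrix <- function(model, t) {
  stopifnot(inherits(model, "substitution_model"))
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0) {
    stop("branch length `t` must be a single finite number >= 0")
  }
  p <- unclass(model$freqs)
  piR <- p[["A"]] + p[["G"]]
  piY <- p[["C"]] + p[["T"]]
  aR <- model$alpha_R / model$rate_norm
  aY <- model$alpha_Y / model$rate_norm
  b <- 1 / model$rate_norm
  e2 <- exp(-b * t)
  e3 <- exp(-(piR * aR + piY * b) * t)
  e4 <- exp(-(piY * aY + piR * b) * t)
  P <- matrix(0, 4, 4, dimnames = list(.BASES, .BASES))
  # purines (A = 1, G = 3)
  P["A", "A"] <- p[["A"]] + p[["A"]] * piY / piR * e2 + p[["G"]] / piR * e3
  P["A", "G"] <- p[["G"]] + p[["G"]] * piY / piR * e2 - p[["G"]] / piR * e3
  P["G", "G"] <- p[["G"]] + p[["G"]] * piY / piR * e2 + p[["A"]] / piR * e3
  P["G", "A"] <- p[["A"]] + p[["A"]] * piY / piR * e2 - p[["A"]] / piR * e3
  P["A", "C"] <- P["G", "C"] <- p[["C"]] * (1 - e2)
  P["A", "T"] <- P["G", "T"] <- p[["T"]] * (1 - e2)
  # pyrimidines (C = 2, T = 4)
  P["C", "C"] <- p[["C"]] + p[["C"]] * piR / piY * e2 + p[["T"]] / piY * e4
  P["C", "T"] <- p[["T"]] + p[["T"]] * piR / piY * e2 - p[["T"]] / piY * e4
  P["T", "T"] <- p[["T"]] + p[["T"]] * piR / piY * e2 + p[["C"]] / piY * e4
  P["T", "C"] <- p[["C"]] + p[["C"]] * piR / piY * e2 - p[["C"]] / piY * e4
  P["C", "A"] <- P["T", "A"] <- p[["A"]] * (1 - e2)
  P["C", "G"] <- P["T", "G"] <- p[["G"]] * (1 - e2)
  P
}

#' Check stationarity of a model's transition matrices
#'
#' Returns `TRUE` iff `pi %*% P(t) == pi` within `1e-10` for
#' `t = 0.01, 0.1, 1`.
#'
#' @param model a [substitution_model()].
#' @return logical scalar.
#' @export
stationary_check <- function(model) {
  p <- as.numeric(unclass(model$freqs))
  for (t in c(0.01, 0.1, 1)) {
    if (max(abs(p %*% transition_matrix(model, t) - p)) > 1e-10) return(FALSE)
  }
  TRUE
}

#' Empirical base frequencies of an alignment
#'
#' Counts A/C/G/T over all rows, ignoring gaps and Ns; zero counts get a
#' pseudo-count of 1 so frequencies remain strictly positive.
#'
#' @param alignment an [alignment()] object or character matrix.
#' @return a [base_frequencies()] vector.
#' @export
empirical_base_freqs <- function(alignment) {
  m <- if (inherits(alignment, "alignment")) alignment$matrix else alignment
  counts <- vapply(.BASES, function(b) sum(m == b), numeric(1))
  if (any(counts == 0)) counts <- counts + 1
  base_frequencies(counts / sum(counts))
}
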