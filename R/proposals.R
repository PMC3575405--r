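# R surface over the engine's proposal kernels.
#
# Each kernel perturbs the current chain state and reports a
# Hastings(-Green) log-ratio and the set of site ranges whose marginal
# trees the perturbation can affect (the dirty set used for partial
# likelihood recomputation).  The kernels themselves run in C++; this
# wrapper exposes single draws for testing and diagnostics.

.KERNELS <- c(
  "node_height", "root_scale", "subtree_regraft", "add_recombination",
  "remove_recombination", "breakpoint_shift", "arg_scale",
  "scalar_theta", "scalar_rho", "scalar_sub1", "scalar_sub2"
)

#' Default proposal-kernel weights
#'
#' ARG kernels get weight 1, scalar kernels weight 0.5 (set to 0 for
#' parameters that are not sampled).
#'
#' @param theta_sampled,rho_sampled,sub_sampled whether each scalar is
#'   estimated.
#' @param rho_positive whether recombination kernels are active (disable
#'   when `rho` is fixed at zero).
#' @return named numeric vector over the kernel names.
#' @export
kernel_weights <- function(theta_sampled = FALSE, rho_sampled = FALSE,
                           sub_sampled = FALSE, rho_positive = TRUE) {
  w <- stats::setNames(c(1, 1, 1, 1, 1, 1, 1, 0.5, 0.5, 0.5, 0.5), .KERNELS)
  if (!rho_positive) {
    w[c("add_recombination", "remove_recombination", "breakpoint_shift")] <- 0
  }
  if (!theta_sampled) w["scalar_theta"] <- 0
  if (!rho_sampled) w["scalar_rho"] <- 0
  if (!sub_sampled) w[c("scalar_sub1", "scalar_sub2")] <- 0
  w["scalar_sub2"] <- 0 # used only for TN93's second rate
  w
}

.default_tuning <- function(theta) {
  list(
    win_height = theta / 2, f_root = 0.5, f_arg = 0.2, f_scalar = 0.7,
    geom_p = 0.05
  )
}

#' Draw a single proposal from one kernel
#'
#' Mainly for testing and diagnostics; the run loop applies kernels
#' internally.  Uses the global RNG stream.
#'
#' @param arg current ARG.
#' @param kernel kernel name (see `kernel_weights()` for the list).
#' @param pop,rec,model current evolutionary model.
#' @param tuning optional tuning list (window sizes).
#' @return a list of class `arg_proposal`: `ok` (FALSE = auto-reject),
#'   `arg` (proposed ARG), `log_hr`, `dirty` (site-interval matrix),
#'   `kernel`, and proposed scalar values.
#' @export
propose_kernel <- function(arg, kernel, pop, rec,
                           model = substitution_model("F84", kappa = 2),
                           tuning = NULL) {
  kid <- match(kernel, .KERNELS)
  if (is.na(kid)) stop("unknown kernel: ", kernel)
  if (is.null(tuning)) tuning <- .default_tuning(pop$theta0)
  res <- cpp_propose(.arg_to_cpp(arg),
                     .params_to_cpp(pop, rec, model),
                     kid - 1L, tuning)
  out <- list(
    ok = res$ok,
    arg = if (res$ok) .arg_from_cpp(res$arg, arg$tip_labels) else NULL,
    log_hr = res$log_hr,
    dirty = res$dirty,
    structural = res$structural,
    kernel = kernel,
    theta = res$theta, rho = res$rho,
    kappa = res$kappa, alpha_R = res$alpha_R, alpha_Y = res$alpha_Y
  )
  class(out) <- "arg_proposal"
  out
}
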