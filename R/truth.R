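#' Generating parameters for a synthetic CEE
#'
#' Bundles the parameters of the two-state generative model used by the
#' synthetic-data module: log-scale baseline `lambda0` and non-negative
#' enhancement `lambda1` of the response mean, phase-specific probabilities
#' `p_pre`, `p_exp`, `p_post` of a block being in the enhanced state, and (for
#' movement) the per-state Ornstein-Uhlenbeck velocity parameters. In the
#' enhanced movement state directional persistence decreases and velocity
#' variation increases, so both `beta_ou` and `sigma_ou` must be larger than
#' in the baseline state.
#'
#' @param lambda0 Log-scale baseline level of the response mean.
#' @param lambda1 Log-scale enhancement, must be >= 0.
#' @param p_pre,p_exp,p_post Probabilities in \[0, 1\] that a block of the
#'   corresponding phase is in the enhanced state.
#' @param beta_ou Length-2 vector `c(baseline, enhanced)` of OU velocity
#'   mean-reversion rates (1/s); enhanced must exceed baseline. Only used by
#'   the movement generator.
#' @param sigma_ou Length-2 vector `c(baseline, enhanced)` of OU velocity
#'   diffusion scales; enhanced must exceed baseline.
#' @param obs_sd Observation standard deviation for the truncated-normal
#'   count family.
#' @return An object of class `"cee_truth"`.
#' @seealso [default_truth()] for the calibrated per-metric defaults.
#' @export
cee_truth <- function(lambda0 = 0, lambda1 = 0,
                      p_pre = 0.1, p_exp = 0.5, p_post = 0.3,
                      beta_ou = NULL, sigma_ou = NULL, obs_sd = NULL) {
  if (!is.finite(lambda0)) stop("lambda0 must be finite")
  if (!is.finite(lambda1) || lambda1 < 0) stop("lambda1 must be >= 0")
  p <- c(p_pre, p_exp, p_post)
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("phase probabilities must lie in [0, 1]")
  if (!is.null(beta_ou)) {
    if (length(beta_ou) != 2L || length(sigma_ou) != 2L)
      stop("beta_ou and sigma_ou must be length-2 c(baseline, enhanced)")
    if (any(beta_ou <= 0) || any(sigma_ou <= 0))
      stop("OU parameters must be positive")
    if (beta_ou[2] < beta_ou[1] || sigma_ou[2] < sigma_ou[1])
      stop("enhanced state must have beta_ou and sigma_ou >= baseline state")
  }
  structure(list(lambda0 = lambda0, lambda1 = lambda1,
                 p_pre = p_pre, p_exp = p_exp, p_post = p_post,
                 beta_ou = beta_ou, sigma_ou = sigma_ou, obs_sd = obs_sd),
            class = "cee_truth")
}

#' Calibrated default generating parameters per response metric
#'
#' Defaults are calibrated to the ranges typical of baseline common-dolphin
#' CEE data: group speeds of roughly 8-25 km/h, subgroup counts of 1-6, and
#' whistle counts of 0-100 per 5 s block.
#'
#' * `"whistle"`: truncated-normal family, baseline mean 5 whistles per block,
#'   six-fold enhancement (enhanced mean 30), observation sd 4.
#' * `"subgroup"`: Poisson family, baseline mean 2 subgroups, two-fold
#'   enhancement.
#' * `"movement"`: switching OU velocity with baseline `beta_ou` 0.1 /s
#'   (10 s directional decorrelation time) and `sigma_ou` 1.03 (stationary
#'   mean speed about 10.4 km/h) and a two-fold enhancement of both (5 s
#'   decorrelation, mean speed about 14.7 km/h).
#'
#' All three share phase probabilities `p_pre = 0.1`, `p_exp = 0.5`,
#' `p_post = 0.3`: an occasional enhanced block at baseline, a substantial
#' exposure response, partial persistence afterwards.
#'
#' @param metric One of `"whistle"`, `"subgroup"`, `"movement"`.
#' @return A [cee_truth()] object.
#' @export
default_truth <- function(metric = c("whistle", "subgroup", "movement")) {
  metric <- match.arg(metric)
  switch(metric,
    whistle = cee_truth(lambda0 = log(5), lambda1 = log(6), obs_sd = 4),
    subgroup = cee_truth(lambda0 = log(2), lambda1 = log(2)),
    movement = cee_truth(lambda0 = 0, lambda1 = 0,
                         beta_ou = c(0.1, 0.2), sigma_ou = c(1.03, 2.06))
  )
}

#' @export
print.cee_truth <- function(x, ...) {
  cat("CEE generating parameters\n")
  cat(sprintf("  lambda0 = %.3f, lambda1 = %.3f\n", x$lambda0, x$lambda1))
  cat(sprintf("  p(enhanced): pre %.2f, exposure %.2f, post %.2f\n",
              x$p_pre, x$p_exp, x$p_post))
  if (!is.null(x$beta_ou))
    cat(sprintf("  OU: beta %.3g/%.3g 1/s, sigma %.3g/%.3g (baseline/enhanced)\n",
                x$beta_ou[1], x$beta_ou[2], x$sigma_ou[1], x$sigma_ou[2]))
  if (!is.null(x$obs_sd)) cat(sprintf("  obs_sd = %.3g\n", x$obs_sd))
  invisible(x)
}

truth_p <- function(truth) {
  c(pre = truth$p_pre, exposure = truth$p_exp, post = truth$p_post)
}

# draw the per-block enhanced-state indicator, independently per block
draw_z <- function(schedule, truth) {
  p <- truth_p(truth)[as.integer(schedule$phase)]
  rbinom(schedule$n_blocks, 1L, p)
}
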