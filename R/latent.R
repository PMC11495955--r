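#' Fit the two-state latent behavioural-response model
#'
#' Fits, per response variable, a Bayesian two-state model in which each 5 s
#' block `t` is in a baseline (`z_t = 0`) or enhanced (`z_t = 1`) state, the
#' response mean follows the log link `log(mean_t) = lambda0 + lambda1 z_t`
#' with `lambda1 >= 0`, and `z_t ~ Bernoulli(p_phase[t])` with independent
#' flat U(0, 1) priors on the pre-exposure, exposure and post-exposure
#' probabilities. Priors are flat U(-30, 30) on `lambda0` and U(0, 30) on
#' `lambda1` (and on the truncated-normal observation sd).
#'
#' Observation families:
#' * `"poisson"` — small counts (number of subgroups);
#' * `"trunc_normal"` — non-negative continuous counts (whistles per block):
#'   normal with state-specific mean `exp(lambda0 + lambda1 z)` truncated at
#'   zero (the location parameter is the pre-truncation mean);
#' * `"normal_movement"` — block velocities under the switching OU
#'   correlated-random-walk transition; a single shared indicator `z_t`
#'   multiplies both the persistence-rate enhancement (`lambda1_beta`) and
#'   the velocity-variation enhancement (`lambda1_sigma`), so the enhanced
#'   state has less directional persistence and more velocity variation.
#'
#' Sampling is Metropolis-within-Gibbs: exact Gibbs draws for each `z_t`
#' (its full conditional is the two-term mixture weight, see
#' [z_full_conditional()]), conjugate `Beta(1 + n1, 1 + n0)` draws for each
#' `p_phase` given the states of that phase, and adaptive random-walk
#' Metropolis for the lambda (and sd) parameters with the adaptation frozen
#' after burn-in. Unobserved blocks contribute no likelihood; their states
#' are drawn from the phase prior, so missingness widens the `p_phase`
#' posterior without biasing it. Identical `seed` and configuration give
#' identical draws.
#'
#' @param data A `"cee_blocks"` series (count families) or `"cee_blockvel"`
#'   velocities (movement family), both carrying their schedule as an
#'   attribute (see [simulate_counts()], [blockify_track()]).
#' @param family Observation family, see Details.
#' @param iters Post-burn-in iterations per chain (default 100000; reduce for
#'   quick runs).
#' @param burnin Burn-in iterations per chain (default 100000).
#' @param chains Number of chains (default 3).
#' @param seed Integer seed; chain `c` uses `seed + c - 1`.
#' @param schedule Optional schedule if `data` lacks the attribute.
#' @return An object of class `"cee_fit"` with `draws` (list of per-chain
#'   matrices of `lambda`/`obs_sd`/`p_phase` draws), `accept` rates, `psrf`
#'   values, family, schedule, data and MCMC configuration. Methods:
#'   [summary.cee_fit()], `coef()`, [plot.cee_fit()], plus [phase_mean()]
#'   and [response_probability()].
#' @examples
#' sched <- make_phase_schedule(120, 120, 120, 5)
#' y <- simulate_counts(sched, "poisson", default_truth("subgroup"), seed = 1)
#' fit <- fit_latent_state(y, "poisson", iters = 2000, burnin = 2000, seed = 1)
#' coef(fit)
#' @export
fit_latent_state <- function(data,
                             family = c("poisson", "trunc_normal",
                                        "normal_movement"),
                             iters = 100000, burnin = 100000, chains = 3,
                             seed = 1, schedule = attr(data, "schedule")) {
  family <- match.arg(family)
  stopifnot_schedule(schedule)
  if (iters < 1 || burnin < 0 || chains < 1) stop("invalid MCMC configuration")
  fam_code <- match(family, c("poisson", "trunc_normal", "normal_movement")) - 1L

  n <- schedule$n_blocks
  phase <- as.integer(schedule$phase) - 1L
  if (family == "normal_movement") {
    if (!inherits(data, "cee_blockvel"))
      stop("normal_movement family expects a 'cee_blockvel' data.frame")
    if (nrow(data) != n) stop("data does not match the schedule grid")
    obs <- data$observed & is.finite(data$vx) & is.finite(data$vy)
    ltype <- integer(n)                 # 0 none, 1 transition, 2 stationary
    ltype[obs] <- 2L
    prev_ok <- c(FALSE, obs[-n])
    ltype[obs & prev_ok] <- 1L
    vcx <- ifelse(obs, data$vx, 0); vcy <- ifelse(obs, data$vy, 0)
    vpx <- c(0, data$vx[-n]); vpy <- c(0, data$vy[-n])
    vpx[ltype != 1L] <- 0; vpy[ltype != 1L] <- 0
    y <- numeric(n); obs_flag <- obs
    has_data <- ltype > 0L
  } else {
    if (!inherits(data, "cee_blocks"))
      stop("count families expect a 'cee_blocks' data.frame")
    if (nrow(data) != n) stop("data does not match the schedule grid")
    obs_flag <- data$observed & !is.na(data$value)
    if (any(data$value[obs_flag] < 0)) stop("observed values must be >= 0")
    y <- ifelse(obs_flag, data$value, 0)
    vcx <- vcy <- vpx <- vpy <- numeric(n)
    ltype <- integer(n)
    has_data <- obs_flag
  }
  for (ph in levels(schedule$phase)) {
    if (!any(has_data[schedule$phase == ph]))
      stop(sprintf("phase '%s' has no observed blocks", ph))
  }

  par_names <- switch(family,
    poisson = c("lambda0", "lambda1"),
    trunc_normal = c("lambda0", "lambda1", "obs_sd"),
    normal_movement = c("lambda0_beta", "lambda1_beta",
                        "lambda0_sigma", "lambda1_sigma"))
  lo <- switch(family,
    poisson = c(-30, 0), trunc_normal = c(-30, 0, 0),
    normal_movement = c(-30, 0, -30, 0))
  hi <- switch(family,
    poisson = c(30, 30), trunc_normal = c(30, 30, 30),
    normal_movement = c(30, 30, 30, 30))
  all_names <- c(par_names, c("p_pre", "p_exp", "p_post"))

  draws <- vector("list", chains)
  accept <- matrix(NA_real_, chains, length(par_names),
                   dimnames = list(NULL, par_names))
  for (ch in seq_len(chains)) {
    set.seed(seed + ch - 1L)
    init <- init_theta(family, y, obs_flag, data, lo, hi)
    res <- .latent_mcmc_cpp(fam_code, y, obs_flag, vcx, vcy, vpx, vpy,
                            ltype, phase, schedule$block_dur,
                            as.integer(iters), as.integer(burnin),
                            init, runif(3),
                            lo, hi, rep(0.2, length(par_names)))
    colnames(res$draws) <- all_names
    draws[[ch]] <- res$draws
    accept[ch, ] <- res$accept_rate[seq_along(par_names)]
  }

  fit <- structure(list(draws = draws, par_names = all_names,
                        family = family, schedule = schedule, data = data,
                        accept = accept,
                        mcmc = list(iters = iters, burnin = burnin,
                                    chains = chains, seed = seed)),
                   class = "cee_fit")
  fit$psrf <- tryCatch(psrf(fit), error = function(e) NULL)
  fit
}

# overdispersed, numerically sane starting values inside the prior support
init_theta <- function(family, y, obs_flag, data, lo, hi) {
  clamp <- function(x, l, h) pmin(pmax(x, l + 1e-6), h - 1e-6)
  if (family == "normal_movement") {
    tau2 <- max(var(c(data$vx[obs_flag], data$vy[obs_flag]), na.rm = TRUE),
                1e-4)
    l0b <- runif(1, log(0.03), log(1.5))
    l0s <- log(sqrt(tau2 * 2 * exp(l0b))) + runif(1, -1, 1)
    init <- c(l0b, runif(1, 0, 1.5), l0s, runif(1, 0, 1.5))
  } else {
    m <- mean(y[obs_flag])
    centre <- log(max(m, 0.05))
    init <- c(centre + runif(1, -2, 2), runif(1, 0, 2))
    if (family == "trunc_normal") {
      s <- max(sd(y[obs_flag]), 0.2)
      init <- c(init, s * exp(runif(1, -1, 1)))
    }
  }
  clamp(init, lo, hi)
}

#' Full conditional probability that a block is in the enhanced state
#'
#' Given the phase probability `p` and the current model parameters, the
#' Gibbs weight for `z_t = 1` is `p f(y | enhanced) / (p f(y | enhanced) +
#' (1 - p) f(y | baseline))`. For an unobserved block (`NA`) the likelihood
#' terms cancel and the prior `p` is returned.
#'
#' @param y Observed block value(s); `NA` for unobserved. For the movement
#'   family, a length-2 velocity `c(vx, vy)`.
#' @param p Phase probability of the enhanced state, in \[0, 1\].
#' @param params Named list of parameters: `lambda0`, `lambda1`, plus
#'   `obs_sd` (trunc_normal) or `lambda0_beta`, `lambda1_beta`,
#'   `lambda0_sigma`, `lambda1_sigma`, `v_prev`, `delta` (movement).
#' @param family Observation family as in [fit_latent_state()].
#' @return Probability (vectorised over `y` for the count families).
#' @examples
#' z_full_conditional(3, 0.5, list(lambda0 = 0, lambda1 = log(4)), "poisson")
#' @export
z_full_conditional <- function(y, p,
                               params,
                               family = c("poisson", "trunc_normal",
                                          "normal_movement")) {
  family <- match.arg(family)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (family == "normal_movement") {
    if (anyNA(y)) return(p)
    b0 <- exp(params$lambda0_beta); b1 <- exp(params$lambda0_beta + params$lambda1_beta)
    s0 <- exp(params$lambda0_sigma); s1 <- exp(params$lambda0_sigma + params$lambda1_sigma)
    l1 <- ou_block_loglik(y, params$v_prev, b1, s1, params$delta)
    l0 <- ou_block_loglik(y, params$v_prev, b0, s0, params$delta)
  } else {
    mu0 <- exp(params$lambda0)
    mu1 <- exp(params$lambda0 + params$lambda1)
    if (family == "poisson") {
      if (!is.null(params$obs_sd)) stop("obs_sd is not a poisson parameter")
      l0 <- dpois(y, mu0, log = TRUE)
      l1 <- dpois(y, mu1, log = TRUE)
    } else {
      sdv <- params$obs_sd
      if (is.null(sdv) || sdv <= 0) stop("trunc_normal requires obs_sd > 0")
      l0 <- dnorm(y, mu0, sdv, log = TRUE) - pnorm(mu0 / sdv, log.p = TRUE)
      l1 <- dnorm(y, mu1, sdv, log = TRUE) - pnorm(mu1 / sdv, log.p = TRUE)
    }
  }
  a <- log(p) + l1
  b <- log1p(-p) + l0
  m <- pmax(a, b)
  out <- exp(a - m) / (exp(a - m) + exp(b - m))
  out[is.na(y[seq_along(out)])] <- p
  # p = 0 or 1 make log terms -Inf; resolve directly
  out[p == 0] <- 0
  out[p == 1] <- 1
  out
}

pooled_draws <- function(fit) do.call(rbind, fit$draws)

#' Posterior phase mean of a response variable
#'
#' For the count families the phase mean is `exp(lambda0 + lambda1 p_phase)`,
#' evaluated per posterior draw. For the movement family the block-level
#' speed takes one of two values (baseline/enhanced, via [derive_speed()]);
#' the phase mean per draw is the mixture mean `(1 - p) s0 + p s1`, and the
#' reported sd combines the posterior spread of that mean with the
#' block-level mixture dispersion (the dominant term, since blocks switch
#' state within a phase).
#'
#' @param fit A `"cee_fit"`.
#' @param phase `"pre"`, `"exposure"` or `"post"`.
#' @param units For the movement family, `"mps"` (default) or `"kmh"`.
#' @return A list with `mean` and `sd` (response scale; speed for movement).
#' @export
phase_mean <- function(fit, phase = c("pre", "exposure", "post"),
                       units = c("mps", "kmh")) {
  phase <- match.arg(phase)
  units <- match.arg(units)
  d <- pooled_draws(fit)
  p <- d[, c(pre = "p_pre", exposure = "p_exp", post = "p_post")[[phase]]]
  if (fit$family == "normal_movement") {
    s0 <- derive_speed(exp(d[, "lambda0_beta"]), exp(d[, "lambda0_sigma"]))
    s1 <- derive_speed(exp(d[, "lambda0_beta"] + d[, "lambda1_beta"]),
                       exp(d[, "lambda0_sigma"] + d[, "lambda1_sigma"]))
    k <- if (units == "kmh") 3.6 else 1
    s0 <- k * s0; s1 <- k * s1
    m <- (1 - p) * s0 + p * s1
    v_block <- (1 - p) * s0^2 + p * s1^2 - m^2
    list(mean = mean(m), sd = sqrt(mean(v_block) + var(m)))
  } else {
    m <- exp(d[, "lambda0"] + d[, "lambda1"] * p)
    list(mean = mean(m), sd = sd(m))
  }
}

#' Separation between two posterior samples
#'
#' The directional proportion `Pr[a > b]` is computed over paired draws (ties
#' split equally); the statistic is the larger of the two directions, so it
#' equals 0.5 when the two distributions are identical and 1 when they are
#' disjoint.
#'
#' @param a,b Numeric vectors of equal length (posterior draws).
#' @return A list with `p` (in \[0.5, 1\]), `direction` (`"increase"` if
#'   `Pr[a > b]` wins, else `"decrease"`) and `p_gt` (`Pr[a > b]` itself).
#' @examples
#' separation_probability(runif(1e4, 0.6, 1), runif(1e4, 0, 0.4))$p  # 1
#' @export
separation_probability <- function(a, b) {
  if (length(a) != length(b) || length(a) == 0)
    stop("a and b must be non-empty and of equal length")
  p_gt <- mean(a > b) + 0.5 * mean(a == b)
  if (p_gt >= 0.5) list(p = p_gt, direction = "increase", p_gt = p_gt)
  else list(p = 1 - p_gt, direction = "decrease", p_gt = p_gt)
}

#' Probability of response or persistence
#'
#' Degree of separation between the posterior distributions of the
#' exposure-phase (`"response"`) or post-exposure-phase (`"persistence"`)
#' enhancement probability and the pre-exposure one: the proportion of MCMC
#' iterations in which one exceeds the other, folded to the winning
#' direction. 0.5 means the distributions are identical, 1 means disjoint; a
#' change is declared detected when the probability exceeds 0.9 (see
#' [detect_change()]).
#'
#' @param fit A `"cee_fit"`.
#' @param comparison `"response"` (exposure vs pre) or `"persistence"` (post
#'   vs pre).
#' @return As [separation_probability()].
#' @export
response_probability <- function(fit,
                                 comparison = c("response", "persistence")) {
  comparison <- match.arg(comparison)
  d <- pooled_draws(fit)
  a <- d[, if (comparison == "response") "p_exp" else "p_post"]
  separation_probability(a, d[, "p_pre"])
}

#' Detection rule for a phase change
#'
#' A change in the phase-specific enhancement probabilities is declared
#' detected when the response (or persistence) probability strictly exceeds
#' 0.9.
#'
#' @param p Probability in \[0, 1\].
#' @return Logical.
#' @export
detect_change <- function(p) {
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  p > 0.9
}

#' Potential scale reduction factor (Gelman-Rubin)
#'
#' Split-free between/within-chain variance ratio
#' `sqrt(((n - 1)/n W + B/n) / W)` per parameter; values near 1 indicate the
#' chains have mixed, and parameters above 1.05 are conventionally flagged.
#'
#' @param x A `"cee_fit"` or a list of at least two equal-length draw
#'   matrices with common columns.
#' @return Named numeric vector of PSRF values per parameter.
#' @export
psrf <- function(x) {
  chains <- if (inherits(x, "cee_fit")) x$draws else x
  if (!is.list(chains) || length(chains) < 2)
    stop("psrf requires at least 2 chains")
  n <- nrow(chains[[1]])
  if (any(vapply(chains, nrow, 0L) != n)) stop("chains must have equal length")
  pars <- colnames(chains[[1]])
  out <- vapply(pars, function(pn) {
    draws <- vapply(chains, function(ch) ch[, pn], numeric(n))
    W <- mean(apply(draws, 2, var))
    B <- n * var(colMeans(draws))
    if (W <= 0) return(1)
    sqrt(((n - 1) / n * W + B / n) / W)
  }, 0)
  names(out) <- pars
  out
}

#' @export
print.cee_fit <- function(x, ...) {
  cat(sprintf("Two-state latent response model (%s family)\n", x$family))
  cat(sprintf("  %d chains x %d iterations (burn-in %d), seed %d\n",
              x$mcmc$chains, x$mcmc$iters, x$mcmc$burnin, x$mcmc$seed))
  print(round(coef(x), 3))
  invisible(x)
}

#' @export
coef.cee_fit <- function(object, ...) colMeans(pooled_draws(object))

#' Summarise a latent-state fit
#'
#' @param object A `"cee_fit"`.
#' @param ... Unused.
#' @return A `"summary.cee_fit"` list: posterior parameter table (mean, sd,
#'   central 95% interval, PSRF), phase means (speed in km/h for the movement
#'   family), and the response/persistence probabilities with directions and
#'   detection flags.
#' @export
summary.cee_fit <- function(object, ...) {
  d <- pooled_draws(object)
  tab <- t(apply(d, 2, function(col)
    c(mean = mean(col), sd = sd(col),
      `2.5%` = unname(quantile(col, 0.025)),
      `97.5%` = unname(quantile(col, 0.975)))))
  if (!is.null(object$psrf)) tab <- cbind(tab, psrf = object$psrf)
  units <- if (object$family == "normal_movement") "kmh" else "mps"
  pm <- lapply(c(pre = "pre", exposure = "exposure", post = "post"),
               function(ph) phase_mean(object, ph, units = units))
  resp <- response_probability(object, "response")
  pers <- response_probability(object, "persistence")
  structure(list(family = object$family, coef = tab, phase_means = pm,
                 response = resp, persistence = pers,
                 detected_exposure = detect_change(resp$p),
                 detected_post = detect_change(pers$p),
                 mcmc = object$mcmc),
            class = "summary.cee_fit")
}

#' @export
print.summary.cee_fit <- function(x, ...) {
  cat(sprintf("Two-state latent response model (%s family)\n\n", x$family))
  print(round(x$coef, 3))
  un <- if (x$family == "normal_movement") " (km/h)" else ""
  cat(sprintf("\nPhase means%s:\n", un))
  for (ph in names(x$phase_means))
    cat(sprintf("  %-9s %.2f (sd %.2f)\n", ph,
                x$phase_means[[ph]]$mean, x$phase_means[[ph]]$sd))
  cat(sprintf("\np(response)    = %.3f (%s)%s\n", x$response$p,
              x$response$direction,
              if (x$detected_exposure) "  * detected" else ""))
  cat(sprintf("p(persistence) = %.3f (%s)%s\n", x$persistence$p,
              x$persistence$direction,
              if (x$detected_post) "  * detected" else ""))
  invisible(x)
}

#' Trace plots for a latent-state fit
#'
#' @param x A `"cee_fit"`.
#' @param pars Parameters to plot (default all).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.cee_fit <- function(x, pars = x$par_names, ...) {
  old <- par(mfrow = c(length(pars), 1), mar = c(2, 4, 1, 1))
  on.exit(par(old))
  for (pn in pars) {
    plot(x$draws[[1]][, pn], type = "l", ylab = pn, xlab = "", ...)
    if (length(x$draws) > 1)
      for (ch in 2:length(x$draws))
        lines(x$draws[[ch]][, pn], col = ch)
  }
  invisible(x)
}
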