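#' Simulate a focal-subgroup movement track
#'
#' Generates a 2D track by integrating an Ornstein-Uhlenbeck velocity process
#' `dv = -beta_ou v dt + sigma_ou dW` whose parameters switch between a
#' baseline and an enhanced regime according to the per-block latent state
#' `z`, drawn independently per block as Bernoulli(p_phase). The velocity
#' transition uses the exact OU discretisation
#' `v(t+dt) = e^(-beta dt) v(t) + N(0, sigma^2/(2 beta) (1 - e^(-2 beta dt)))`
#' per component; positions accumulate by Euler integration at the sampling
#' cadence `dt` (default 1 s, the photogrammetry cadence).
#'
#' @param schedule A [make_phase_schedule()] object.
#' @param truth A [cee_truth()] with `beta_ou` and `sigma_ou` set.
#' @param dt Track sampling interval in seconds; must divide `block_dur`.
#' @param seed Optional integer seed.
#' @return A list with `track` (data.frame `time_s`, `x_m`, `y_m` of class
#'   `"cee_track"`) and `z` (integer vector of per-block latent states).
#' @examples
#' sched <- make_phase_schedule(600, 600, 600, 5)
#' sim <- simulate_track(sched, default_truth("movement"), seed = 1)
#' head(sim$track)
#' @export
simulate_track <- function(schedule, truth, dt = 1, seed = NULL) {
  stopifnot_schedule(schedule)
  if (is.null(truth$beta_ou))
    stop("truth must carry beta_ou and sigma_ou (see default_truth('movement'))")
  if (any(truth$beta_ou <= 0) || any(truth$sigma_ou <= 0))
    stop("OU parameters must be positive")
  if (dt <= 0 || abs(schedule$block_dur / dt - round(schedule$block_dur / dt)) > 1e-9)
    stop("dt must be positive and divide block_dur")
  if (!is.null(seed)) set.seed(seed)

  z <- draw_z(schedule, truth)
  total <- schedule$n_blocks * schedule$block_dur
  times <- seq(0, total, by = dt)
  n_step <- length(times) - 1L
  # regime per step: the block containing the step's start time
  blk <- pmin(floor(times[-length(times)] / schedule$block_dur) + 1L,
              schedule$n_blocks)
  beta <- truth$beta_ou[z[blk] + 1L]
  sigma <- truth$sigma_ou[z[blk] + 1L]
  a <- exp(-beta * dt)
  step_sd <- sqrt(sigma^2 / (2 * beta) * (1 - a^2))

  vx <- vy <- numeric(n_step + 1L)
  tau0 <- truth$sigma_ou[z[1] + 1L] / sqrt(2 * truth$beta_ou[z[1] + 1L])
  vx[1] <- rnorm(1, 0, tau0)
  vy[1] <- rnorm(1, 0, tau0)
  ex <- rnorm(n_step)
  ey <- rnorm(n_step)
  for (k in seq_len(n_step)) {
    vx[k + 1L] <- a[k] * vx[k] + step_sd[k] * ex[k]
    vy[k + 1L] <- a[k] * vy[k] + step_sd[k] * ey[k]
  }
  x <- c(0, cumsum(vx[-length(vx)] * dt))
  y <- c(0, cumsum(vy[-length(vy)] * dt))
  track <- structure(data.frame(time_s = times, x_m = x, y_m = y),
                     class = c("cee_track", "data.frame"))
  list(track = track, z = z)
}

#' Simulate block-scale velocities from the switching AR(1) observation model
#'
#' Draws per-block velocities directly from the exact block-scale AR(1) form
#' of the switching OU process: `v_t = rho_t v_(t-1) + N(0, tau_t^2 (1 -
#' rho_t^2))` per component, with `rho_t = exp(-beta_(z_t) block_dur)` and
#' `tau_t^2 = sigma_(z_t)^2 / (2 beta_(z_t))`. This is the observation model
#' the movement family of [fit_latent_state()] assumes, so it is the
#' appropriate generator for parameter-recovery experiments; use
#' [simulate_track()] + [blockify_track()] for track-level realism.
#'
#' @inheritParams simulate_track
#' @return A data.frame (`block`, `vx`, `vy`, `observed`) of class
#'   `"cee_blockvel"`, with the latent states in `attr(, "z")` and the
#'   schedule in `attr(, "schedule")`.
#' @export
simulate_block_velocities <- function(schedule, truth, seed = NULL) {
  stopifnot_schedule(schedule)
  if (is.null(truth$beta_ou)) stop("truth must carry beta_ou and sigma_ou")
  if (!is.null(seed)) set.seed(seed)
  z <- draw_z(schedule, truth)
  n <- schedule$n_blocks
  beta <- truth$beta_ou[z + 1L]
  sigma <- truth$sigma_ou[z + 1L]
  rho <- exp(-beta * schedule$block_dur)
  tau2 <- sigma^2 / (2 * beta)
  vx <- vy <- numeric(n)
  vx[1] <- rnorm(1, 0, sqrt(tau2[1]))
  vy[1] <- rnorm(1, 0, sqrt(tau2[1]))
  ex <- rnorm(n)
  ey <- rnorm(n)
  for (t in 2:n) {
    s <- sqrt(tau2[t] * (1 - rho[t]^2))
    vx[t] <- rho[t] * vx[t - 1L] + s * ex[t]
    vy[t] <- rho[t] * vy[t - 1L] + s * ey[t]
  }
  out <- data.frame(block = seq_len(n), vx = vx, vy = vy, observed = TRUE)
  structure(out, class = c("cee_blockvel", "data.frame"),
            schedule = schedule, z = z)
}

#' Simulate a block series of counts
#'
#' Block means follow the two-state log-link model `exp(lambda0 + lambda1
#' z_t)` with `z_t ~ Bernoulli(p_phase)`. The `"poisson"` family produces
#' non-negative integers (subgroup counts); the `"trunc_normal"` family
#' produces continuous values drawn from a normal distribution with the
#' state-specific mean, truncated at zero (whistle counts). When
#' `obs_interval` is set (subgroup protocol: 120 s), a value is drawn only at
#' observation instants and copied to the intervening blocks, reproducing the
#' tiled structure of field subgroup data.
#'
#' @inheritParams simulate_track
#' @param family `"trunc_normal"` or `"poisson"`.
#' @param obs_sd Observation sd for `"trunc_normal"`; defaults to
#'   `truth$obs_sd`.
#' @param obs_interval Observation spacing in seconds, or `NULL` to draw every
#'   block.
#' @return A data.frame (`block`, `phase`, `value`, `observed`) of class
#'   `"cee_blocks"` with the schedule and latent states as attributes.
#' @examples
#' sched <- make_phase_schedule(600, 600, 600, 5)
#' sg <- simulate_counts(sched, "poisson", default_truth("subgroup"),
#'                       obs_interval = 120, seed = 2)
#' table(sg$value[sg$phase == "pre"])
#' @export
simulate_counts <- function(schedule, family = c("trunc_normal", "poisson"),
                            truth, obs_sd = truth$obs_sd,
                            obs_interval = NULL, seed = NULL) {
  stopifnot_schedule(schedule)
  family <- match.arg(family)
  if (family == "trunc_normal" && (is.null(obs_sd) || obs_sd <= 0))
    stop("trunc_normal family requires obs_sd > 0")
  if (!is.null(seed)) set.seed(seed)
  z <- draw_z(schedule, truth)
  mu <- exp(truth$lambda0 + truth$lambda1 * z)
  n <- schedule$n_blocks

  draw_at <- seq_len(n)
  if (!is.null(obs_interval)) {
    if (obs_interval <= 0 ||
        abs(obs_interval / schedule$block_dur -
            round(obs_interval / schedule$block_dur)) > 1e-9)
      stop("obs_interval must be a positive multiple of block_dur")
    step <- as.integer(round(obs_interval / schedule$block_dur))
    draw_at <- seq(1L, n, by = step)
  }
  value <- rep(NA_real_, n)
  value[draw_at] <- switch(family,
    poisson = rpois(length(draw_at), mu[draw_at]),
    trunc_normal = rtnorm0(length(draw_at), mu[draw_at], obs_sd)
  )
  if (!is.null(obs_interval)) {
    idx <- findInterval(seq_len(n), draw_at)
    value <- value[draw_at[idx]]
  }
  out <- data.frame(block = seq_len(n), phase = schedule$phase,
                    value = value, observed = TRUE)
  structure(out, class = c("cee_blocks", "data.frame"),
            schedule = schedule, z = z, family = family)
}

# normal(mean, sd) truncated to [0, Inf), inverse-CDF sampler
rtnorm0 <- function(n, mean, sd) {
  p0 <- pnorm(0, mean, sd)
  u <- runif(n, p0, 1)
  qnorm(u, mean, sd)
}

#' Apply a missingness policy to a block series
#'
#' Two field protocols are emulated. `"pre_change_30s"` (subgroup counts):
#' the timing of a change in the tiled subgroup series is only known to the
#' 2 min observation grid, so the 30 s (six 5 s blocks) immediately preceding
#' each value change are marked unobserved to encode timing uncertainty.
#' `"random_blocks"` (early-year whistle counts): each block is observed
#' independently with probability `f`. `"none"` is the identity.
#'
#' @param series A `"cee_blocks"` data.frame.
#' @param policy `"none"`, `"pre_change_30s"` or `"random_blocks"`.
#' @param f Probability a block remains observed under `"random_blocks"`.
#' @param seed Optional integer seed (only `"random_blocks"` draws).
#' @return The series with `observed` updated and `value` set to `NA` on
#'   unobserved blocks.
#' @export
apply_missingness <- function(series,
                              policy = c("none", "pre_change_30s",
                                         "random_blocks"),
                              f = 1, seed = NULL) {
  policy <- match.arg(policy)
  if (!inherits(series, "cee_blocks")) stop("expected a 'cee_blocks' series")
  if (policy == "none") return(series)
  schedule <- attr(series, "schedule")
  if (policy == "pre_change_30s") {
    n_miss <- as.integer(round(30 / schedule$block_dur))
    v <- series$value
    changed <- which(diff(v) != 0) + 1L   # block where the new value appears
    drop <- unique(unlist(lapply(changed, function(b)
      seq.int(max(1L, b - n_miss), b - 1L))))
    series$observed[drop] <- FALSE
  } else {
    if (f < 0 || f > 1) stop("f must lie in [0, 1]")
    if (!is.null(seed)) set.seed(seed)
    series$observed <- series$observed & (runif(nrow(series)) < f)
  }
  series$value[!series$observed] <- NA_real_
  series
}

#' Simulate a complete synthetic CEE dataset
#'
#' Generates every data stream of one CEE under the standard design: a 1 Hz
#' focal-subgroup track from the switching OU movement model, a
#' truncated-normal whistle-count series (optionally thinned to a random
#' fraction of blocks), a Poisson subgroup-count series tiled on the 2 min
#' observation grid with the 30 s pre-change blocks unobserved, and an MFAS
#' ping log (mock, i.e. computed but flagged untransmitted, for control CEEs).
#'
#' @param schedule A [make_phase_schedule()]; default three 10 min phases in
#'   5 s blocks.
#' @param truths Named list of [cee_truth()] objects for `whistle`,
#'   `subgroup` and `movement`; defaults from [default_truth()].
#' @param cee_type `"mfas_sim"` (source level 212 dB), `"mfas_navy"` (215 dB)
#'   or `"control"` (mock pings).
#' @param whistle_f Fraction of whistle blocks observed (1 = all).
#' @param source_pos Sonar source position `c(x, y)` in metres in the track
#'   frame.
#' @param seed Integer seed; the whole dataset is reproducible from it.
#' @return A list of class `"cee_data"`: `track`, `z_move`, `whistle`,
#'   `subgroup`, `pings`, `truths`, `schedule`, `cee_type`, `seed`.
#' @examples
#' cee <- simulate_cee(seed = 42)
#' summary(cee$pings$spl_db)
#' @export
simulate_cee <- function(schedule = make_phase_schedule(),
                         truths = list(whistle = default_truth("whistle"),
                                       subgroup = default_truth("subgroup"),
                                       movement = default_truth("movement")),
                         cee_type = c("mfas_sim", "mfas_navy", "control"),
                         whistle_f = 1,
                         source_pos = c(1500, 0),
                         seed = NULL) {
  cee_type <- match.arg(cee_type)
  if (!is.null(seed)) set.seed(seed)
  mv <- simulate_track(schedule, truths$movement)
  whistle <- simulate_counts(schedule, "trunc_normal", truths$whistle)
  if (whistle_f < 1)
    whistle <- apply_missingness(whistle, "random_blocks", f = whistle_f)
  subgroup <- simulate_counts(schedule, "poisson", truths$subgroup,
                              obs_interval = 120)
  subgroup <- apply_missingness(subgroup, "pre_change_30s")
  sl <- if (cee_type == "mfas_navy") 215 else 212
  pings <- simulate_pings(schedule, mv$track, source_pos = source_pos,
                          source_level = sl,
                          transmitted = cee_type != "control")
  structure(list(track = mv$track, z_move = mv$z, whistle = whistle,
                 subgroup = subgroup, pings = pings, truths = truths,
                 schedule = schedule, cee_type = cee_type, seed = seed),
            class = "cee_data")
}

#' @export
print.cee_data <- function(x, ...) {
  cat(sprintf("Synthetic CEE (%s): %d blocks of %g s\n", x$cee_type,
              x$schedule$n_blocks, x$schedule$block_dur))
  cat(sprintf("  track: %d positions; whistle blocks observed: %d/%d; pings: %d\n",
              nrow(x$track), sum(x$whistle$observed), nrow(x$whistle),
              nrow(x$pings)))
  invisible(x)
}
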