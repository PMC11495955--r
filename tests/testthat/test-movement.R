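test_that("blockify recovers a constant velocity exactly and covers a 1 Hz track", {
  sched <- make_phase_schedule(600, 600, 600, 5)
  tr <- data.frame(time_s = 0:1800, x_m = 2 * (0:1800), y_m = 0)
  bv <- blockify_track(tr, sched)
  expect_equal(nrow(bv), 360L)
  expect_true(all(bv$observed))
  expect_true(all(bv$vx == 2))
  expect_true(all(bv$vy == 0))
  expect_equal(mean(sqrt(bv$vx^2 + bv$vy^2)), 2)
})

test_that("track gaps mark the overlapped blocks unobserved", {
  sched <- make_phase_schedule(600, 600, 600, 5)
  t <- 0:1800
  keep <- t < 300 | t >= 360   # 60 s gap
  tr <- data.frame(time_s = t[keep], x_m = 2 * t[keep], y_m = 0)
  bv <- blockify_track(tr, sched)
  inside <- which(sched$block_start >= 302 & sched$block_start < 358)
  expect_true(all(!bv$observed[inside]))
  outside <- which(sched$block_start < 295 | sched$block_start >= 365)
  expect_true(all(bv$observed[outside]))
  expect_error(blockify_track(data.frame(time_s = 5000:5100, x_m = 0, y_m = 0),
                              sched), "outside")
  expect_error(blockify_track(data.frame(time_s = c(0, 0, 1), x_m = 0, y_m = 0),
                              sched), "increasing")
})

test_that("OU block log-likelihood matches the bivariate normal closed form", {
  beta <- 0.2; sigma <- 0.5; delta <- 5
  rho <- exp(-1)
  tau2 <- sigma^2 / (2 * beta)          # 0.625
  s2 <- tau2 * (1 - rho^2)
  ll <- ou_block_loglik(c(0, 0), c(0, 0), beta, sigma, delta)
  expect_equal(ll, -2 * (0.5 * log(2 * pi * s2)), tolerance = 1e-12)
  # isotropy: swapping x and y leaves the density unchanged
  expect_equal(ou_block_loglik(c(1, -2), c(0.5, 0.2), beta, sigma, delta),
               ou_block_loglik(c(-2, 1), c(0.2, 0.5), beta, sigma, delta))
  # large beta*delta: independent of v_prev, tends to iid N(0, tau2)
  ll_far <- ou_block_loglik(c(1, 1), c(50, -50), 5, sigma, delta)
  expect_equal(ll_far, sum(dnorm(c(1, 1), 0, sqrt(sigma^2 / 10), log = TRUE)),
               tolerance = 1e-6)
  expect_error(ou_block_loglik(c(0, 0), c(0, 0), -1, sigma, delta), "positive")
})

test_that("derived speed follows the stationary Rayleigh mean", {
  expect_equal(derive_speed(0.5, 1.0), sqrt(pi / 2), tolerance = 1e-12)
  expect_equal(derive_speed(0.5, 1.0), 1.2533, tolerance = 1e-4)
  # decreasing in beta, invariant under (beta, sigma) -> (4 beta, 2 sigma)
  b <- seq(0.05, 2, length.out = 20)
  expect_true(all(diff(derive_speed(b, 1)) < 0))
  expect_equal(derive_speed(0.1, 0.7), derive_speed(0.4, 1.4))
  expect_error(derive_speed(0, 1), "positive")
})

test_that("grid-search ML on a blockified single-regime track recovers the parameters", {
  # independent oracle: profile the AR(1)/OU likelihood of the blockified
  # velocities over a (beta, sigma) grid and compare the argmax to the truth
  sched <- make_phase_schedule(20000, 20000, 10000, 5)   # 1e4 blocks
  truth_b <- 0.2; truth_s <- 0.5
  tr <- cee_truth(beta_ou = c(truth_b, truth_b + 1e-9),
                  sigma_ou = c(truth_s, truth_s + 1e-9))
  sim <- simulate_track(sched, tr, dt = 1, seed = 21)
  bv <- blockify_track(sim$track, sched)
  vc <- cbind(bv$vx[-1], bv$vy[-1])
  vp <- cbind(bv$vx[-nrow(bv)], bv$vy[-nrow(bv)])
  grid_b <- seq(0.1, 0.35, by = 0.005)
  grid_s <- seq(0.3, 0.8, by = 0.005)
  ll <- outer(grid_b, grid_s, Vectorize(function(b, s) {
    rho <- exp(-b * 5)
    v <- s^2 / (2 * b) * (1 - rho^2)
    sum(dnorm(vc, rho * vp, sqrt(v), log = TRUE))
  }))
  best <- arrayInd(which.max(ll), dim(ll))
  expect_lt(abs(grid_b[best[1]] - truth_b) / truth_b, 0.15)
  expect_lt(abs(grid_s[best[2]] - truth_s) / truth_s, 0.15)
})
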