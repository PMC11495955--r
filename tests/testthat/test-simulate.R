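test_that("single-regime OU track reproduces the closed-form autocorrelation and speed", {
  # both regimes identical: beta 0.2/s, sigma 0.5 -> lag-5s velocity
  # autocorrelation e^(-1), mean speed sigma sqrt(pi/(4 beta)). Integrate at
  # dt = 0.1 s so finite differences are effectively instantaneous velocities.
  sched <- make_phase_schedule(4000, 4000, 2000, 5)   # 1e4 s, 1e5 steps
  tr <- cee_truth(beta_ou = c(0.2, 0.2 + 1e-9), sigma_ou = c(0.5, 0.5 + 1e-9))
  sim <- simulate_track(sched, tr, dt = 0.1, seed = 11)
  v <- diff(sim$track$x_m) / 0.1
  n <- length(v)
  lag <- 50                                           # 5 s
  r5 <- cor(v[1:(n - lag)], v[(lag + 1):n])
  expect_lt(abs(r5 - exp(-1)), 0.04)
  vy <- diff(sim$track$y_m) / 0.1
  speed <- mean(sqrt(v^2 + vy^2))
  expect_equal(speed, 0.5 * sqrt(pi / (4 * 0.2)), tolerance = 0.03)
})

test_that("track simulation is deterministic under a seed and validates inputs", {
  sched <- tiny_schedule()
  tr <- default_truth("movement")
  a <- simulate_track(sched, tr, seed = 7)
  b <- simulate_track(sched, tr, seed = 7)
  expect_identical(a, b)
  expect_error(simulate_track(sched, default_truth("subgroup")), "beta_ou")
  bad <- tr; bad$beta_ou <- c(-0.1, 0.2)
  expect_error(simulate_track(sched, bad), "positive")
  expect_error(simulate_track(sched, tr, dt = 3), "dt")
})

test_that("Poisson block means follow the log-link model", {
  sched <- make_phase_schedule(20000, 20000, 10000, 5)  # 1e4 blocks
  # lambda1 = 0: overall mean 2
  y0 <- simulate_counts(sched, "poisson", cee_truth(lambda0 = log(2)), seed = 5)
  se <- sqrt(2 / nrow(y0))
  expect_lt(abs(mean(y0$value) - 2), 3 * se)
  # p_exp = 1: exposure mean e^2
  y1 <- simulate_counts(sched, "poisson",
                        cee_truth(lambda0 = 0, lambda1 = 2, p_exp = 1),
                        seed = 6)
  ye <- y1$value[y1$phase == "exposure"]
  expect_lt(abs(mean(ye) - exp(2)), 3 * sqrt(exp(2) / length(ye)))
  # phase means converge to exp(lambda0 + lambda1 p_phase) for p in (0, 1)
  tr <- cee_truth(lambda0 = log(2), lambda1 = log(3), p_pre = 0.3)
  y2 <- simulate_counts(sched, "poisson", tr, seed = 7)
  yp <- y2$value[y2$phase == "pre"]
  expected <- (1 - 0.3) * 2 + 0.3 * 6   # mixture mean
  expect_lt(abs(mean(yp) - expected), 4 * sd(yp) / sqrt(length(yp)))
})

test_that("truncated-normal counts are non-negative and integers for poisson", {
  sched <- tiny_schedule()
  yt <- simulate_counts(sched, "trunc_normal",
                        cee_truth(lambda0 = log(0.5)), obs_sd = 5, seed = 8)
  expect_gte(min(yt$value), 0)
  yp <- simulate_counts(sched, "poisson", default_truth("subgroup"), seed = 8)
  expect_true(all(yp$value == round(yp$value) & yp$value >= 0))
  expect_error(simulate_counts(sched, "trunc_normal", cee_truth(), obs_sd = 0),
               "obs_sd")
})

test_that("subgroup values are tiled between 2 min observations", {
  sched <- make_phase_schedule(600, 600, 600, 5)
  y <- simulate_counts(sched, "poisson", default_truth("subgroup"),
                       obs_interval = 120, seed = 9)
  # 24 blocks per 2 min window share one value
  idx <- split(seq_len(360), rep(seq_len(15), each = 24))
  for (w in idx) expect_length(unique(y$value[w]), 1L)
})

test_that("missingness policies mark the specified blocks", {
  sched <- make_phase_schedule(600, 600, 600, 5)
  v <- rep(2, 360); v[100:360] <- 3   # one change, appearing at block 100
  ser <- blocks_from_values(v, sched)
  out <- apply_missingness(ser, "pre_change_30s")
  expect_equal(which(!out$observed), 94:99)
  expect_true(all(is.na(out$value[94:99])))
  # constant series untouched
  con <- apply_missingness(blocks_from_values(rep(2, 360), sched),
                           "pre_change_30s")
  expect_true(all(con$observed))
  # random thinning keeps about f of the blocks
  rb <- apply_missingness(ser, "random_blocks", f = 0.5, seed = 1)
  expect_lt(abs(sum(rb$observed) - 180), 3 * sqrt(360 * 0.25))
  expect_identical(apply_missingness(ser, "none"), ser)
})

test_that("a complete synthetic CEE is reproducible and internally consistent", {
  cee1 <- simulate_cee(seed = 42)
  cee2 <- simulate_cee(seed = 42)
  expect_identical(cee1$track, cee2$track)
  expect_identical(cee1$whistle$value, cee2$whistle$value)
  expect_identical(cee1$pings, cee2$pings)
  expect_equal(nrow(cee1$pings), 24L)
  expect_true(all(cee1$pings$transmitted))
  ctrl <- simulate_cee(seed = 43, cee_type = "control")
  expect_false(any(ctrl$pings$transmitted))
  # received levels in a plausible band for a source at 1.5 km
  expect_true(all(cee1$pings$spl_db > 100 & cee1$pings$spl_db < 170))
})
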