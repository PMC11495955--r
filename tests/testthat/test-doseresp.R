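fake_dr <- function(alpha0, beta, kappa = 0, sigma = 0.2,
                    rl_ref = 160, v1_bar = 13) {
  n <- max(length(alpha0), length(beta), length(kappa))
  d <- cbind(alpha0 = rep_len(alpha0, n), beta = rep_len(beta, n),
             kappa = rep_len(kappa, n), sigma_eps = rep_len(sigma, n))
  structure(list(draws = d, rl_ref = rl_ref, v1_bar = v1_bar,
                 include_speed = TRUE), class = "cee_doseresp")
}

test_that("prediction is the centred linear form, clipped to [0, 1]", {
  f <- fake_dr(alpha0 = 0.5, beta = 0.01, kappa = 0)
  # centring identity: at (rl_ref, v1_bar) predictions are the alpha0 draws
  expect_equal(predict(f, rl = 160, v1 = 13), unname(f$draws[, "alpha0"]))
  expect_equal(unique(predict(f, rl = 150)), 0.4)
  expect_equal(unique(predict(fake_dr(1.2, 0), rl = 150)), 1)
  expect_equal(unique(predict(fake_dr(-0.2, 0), rl = 160)), 0)
})

test_that("sign probability counts directional draws and splits zero ties", {
  f <- fake_dr(0.5, beta = c(-1, 2, 3, 4))
  expect_equal(sign_probability(f, "beta", "gt0"), 0.75)
  expect_equal(sign_probability(f, "beta", "lt0"), 0.25)
  f0 <- fake_dr(0.5, beta = c(-1, 0, 0, 1))
  expect_equal(sign_probability(f0, "beta", "gt0"), 0.5)
  expect_error(sign_probability(f, "gamma"))
})

test_that("input validation rejects malformed covariate tables", {
  tab <- simulate_response_table(n = 14, seed = 1)
  expect_error(fit_exposure_response(tab[1:2, ]), "3 CEEs")
  bad <- tab; bad$p_response_move[1] <- 1.4
  expect_error(fit_exposure_response(bad), "0, 1")
  expect_error(fit_exposure_response(tab[, 1:2]), "column")
})

test_that("the regression recovers a positive RL slope and is deterministic", {
  tab <- simulate_response_table(n = 14, alpha0 = 0.7, beta = 0.02,
                                 kappa = 0, sigma_eps = 0.15, seed = 101)
  fit <- fit_exposure_response(tab, iters = 6000, burnin = 3000, seed = 3)
  fit2 <- fit_exposure_response(tab, iters = 6000, burnin = 3000, seed = 3)
  expect_identical(fit$draws, fit2$draws)
  b <- fit$draws[, "beta"]
  expect_lt(abs(mean(b) - 0.02), 2 * sd(b))
  expect_true(all(fit$draws[, "sigma_eps"] > 0 & fit$draws[, "sigma_eps"] < 1))
})

test_that("dropping the speed term reduces to the simple regression", {
  tab <- simulate_response_table(n = 14, alpha0 = 0.6, beta = 0.015,
                                 kappa = 0, sigma_eps = 0.15, seed = 102)
  full <- fit_exposure_response(tab, include_speed = TRUE,
                                iters = 6000, burnin = 3000, seed = 4)
  slim <- fit_exposure_response(tab, include_speed = FALSE,
                                iters = 6000, burnin = 3000, seed = 4)
  expect_true(all(slim$draws[, "kappa"] == 0))
  expect_false("kappa" %in% names(coef(slim)))
  # with kappa = 0 in truth the two beta posteriors agree
  db <- abs(mean(full$draws[, "beta"]) - mean(slim$draws[, "beta"]))
  expect_lt(db, 2 * sqrt(sd(full$draws[, "beta"])^2 + sd(slim$draws[, "beta"])^2))
})

test_that("the truncated likelihood handles probabilities piled near 1", {
  set.seed(103)
  tab <- data.frame(cee_id = sprintf("c%02d", 1:12),
                    p_response_move = runif(12, 0.93, 1),
                    rl_max_db = runif(12, 110, 158),
                    v1_kmh = runif(12, 9, 18))
  fit <- fit_exposure_response(tab, include_speed = FALSE,
                               iters = 6000, burnin = 3000, seed = 5)
  expect_true(all(is.finite(fit$draws)))
  expect_true(all(predict(fit, rl = 170) <= 1))
  # a plain Gaussian fit cannot see the truncation: the truncated model puts
  # the latent trend line above it (mass beyond 1 explains the pile-up)
  ols <- coef(lm(p_response_move ~ I(rl_max_db - 160), data = tab))[[1]]
  expect_gt(mean(fit$draws[, "alpha0"]), ols)
})

test_that("residuals and fitted values decompose the observed probabilities", {
  tab <- simulate_response_table(n = 10, seed = 104)
  fit <- fit_exposure_response(tab, iters = 3000, burnin = 2000, seed = 6)
  expect_equal(fitted(fit) + residuals(fit), tab$p_response_move)
})
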