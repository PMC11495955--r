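# Independent dense-grid quadrature oracle for the two-state Poisson model.
#
# With the latent states summed out analytically, the marginal likelihood of a
# block series factorises over blocks:
#   L(l0, l1, p) = prod_t [ p_phase[t] f(y_t | l0 + l1) + (1 - p_phase[t]) f(y_t | l0) ]
# so conditional on (l0, l1) the three phase probabilities are independent and
# each integrates over a 1-D grid. Posterior means are then exact up to grid
# resolution. Everything here uses base densities directly and shares no code
# with the package sampler.
quad_oracle_poisson <- function(y, phase, observed = rep(TRUE, length(y)),
                                l0_grid = seq(-4, 3, by = 0.04),
                                l1_grid = seq(0, 5, by = 0.04),
                                n_p = 200) {
  keep <- observed & !is.na(y)
  y <- y[keep]
  phase <- phase[keep]
  p_grid <- (seq_len(n_p) - 0.5) / n_p   # midpoint rule on (0, 1)
  phases <- c("pre", "exposure", "post")

  n0 <- length(l0_grid)
  n1 <- length(l1_grid)
  w <- matrix(0, n0, n1)                 # marginal weight per (l0, l1)
  ep <- array(0, c(n0, n1, 3))           # E[p_ph | l0, l1]
  for (i in seq_len(n0)) {
    mu0 <- exp(l0_grid[i])
    f0 <- dpois(y, mu0)
    for (j in seq_len(n1)) {
      mu1 <- exp(l0_grid[i] + l1_grid[j])
      f1 <- dpois(y, mu1)
      m_ph <- e_ph <- numeric(3)
      for (k in 1:3) {
        idx <- which(phase == phases[k])
        # L_ph(p) over the p grid, product across that phase's blocks
        lp <- rep(1, n_p)
        for (t in idx) lp <- lp * (p_grid * f1[t] + (1 - p_grid) * f0[t])
        m_ph[k] <- mean(lp)
        e_ph[k] <- mean(p_grid * lp) / m_ph[k]
      }
      w[i, j] <- prod(m_ph)
      ep[i, j, ] <- e_ph
    }
  }
  tot <- sum(w)
  # flag if mass leaks to the grid edge (oracle grid too narrow)
  edge <- sum(w[c(1, n0), ]) + sum(w[, n1])
  if (edge / tot > 1e-4) warning("oracle grid may be too narrow")
  list(lambda0 = sum(w * l0_grid) / tot,
       lambda1 = sum(w * rep(l1_grid, each = n0)) / tot,
       p_pre = sum(w * ep[, , 1]) / tot,
       p_exp = sum(w * ep[, , 2]) / tot,
       p_post = sum(w * ep[, , 3]) / tot)
}

# toy 9-block Poisson series: 3 blocks per phase
toy_poisson_series <- function() {
  sched <- make_phase_schedule(15, 15, 15, 5)
  df <- data.frame(block = 1:9,
                   phase = sched$phase,
                   value = c(1, 1, 2, 6, 7, 7, 2, 1, 1),
                   observed = TRUE)
  structure(df, class = c("cee_blocks", "data.frame"), schedule = sched)
}
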