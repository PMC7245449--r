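# a 10-node tree graph used by the full-conditional checks
tree_graph <- function() {
  edges <- rbind(c(1, 2), c(1, 3), c(2, 4), c(2, 5), c(3, 6), c(3, 7),
                 c(4, 8), c(5, 9), c(6, 10))
  build_adjacency(edges, 10)
}

test_that("CAR full conditional agrees with finite differences of the joint density", {
  g <- tree_graph()
  set.seed(21)
  phi <- rnorm(10)
  tau <- 2.3
  eps <- 1e-5
  for (i in 1:10) {
    fc <- car_full_conditional(phi, i, g, tau)
    # gradient of the joint log-density at the conditional mean is zero
    at_mean <- phi; at_mean[i] <- fc$mean
    up <- at_mean; up[i] <- fc$mean + eps
    dn <- at_mean; dn[i] <- fc$mean - eps
    grad <- (oracle_car_logdens(up, g, tau) -
               oracle_car_logdens(dn, g, tau)) / (2 * eps)
    expect_lt(abs(grad), 1e-6)
    # curvature matches the conditional variance
    curv <- (oracle_car_logdens(up, g, tau) +
               oracle_car_logdens(dn, g, tau) -
               2 * oracle_car_logdens(at_mean, g, tau)) / eps^2
    expect_equal(-1 / curv, fc$variance, tolerance = 1e-4)
  }
  # simple cases: symmetric neighbours average to zero; m_i = 4 with
  # tau = 1 gives variance 1/4
  g2 <- build_adjacency(rbind(c(1, 2), c(1, 3)), 3)
  expect_equal(car_full_conditional(c(9, 0.2, -0.2), 1, g2, 5)$mean, 0)
  g3 <- build_adjacency(rbind(c(1, 2), c(1, 3), c(1, 4), c(1, 5)), 5)
  expect_equal(car_full_conditional(rnorm(5), 1, g3, 1)$variance, 0.25)
  # isolated node falls back to the exchangeable prior
  gi <- suppressWarnings(build_adjacency(cbind(1, 2), 3))
  expect_equal(car_full_conditional(c(1, 2, 3), 3, gi, 4),
               list(mean = 0, variance = 0.25))
})

test_that("RW1 full conditional matches the tridiagonal-precision oracle", {
  J <- 5
  set.seed(22)
  gamma <- rnorm(J)
  tau <- 3.1
  D <- diff(diag(J))          # (J-1) x J first-difference matrix
  Q <- tau * t(D) %*% D       # RW1 structure (precision) matrix
  for (j in 1:J) {
    fc <- rw1_full_conditional(gamma, j, tau)
    mu <- -sum(Q[j, -j] * gamma[-j]) / Q[j, j]
    expect_equal(fc$mean, mu, tolerance = 1e-12)
    expect_equal(fc$variance, 1 / Q[j, j], tolerance = 1e-12)
  }
  expect_equal(rw1_full_conditional(c(0, 5, 0), 2, 1),
               list(mean = 0, variance = 0.5))
  expect_equal(rw1_full_conditional(c(1, 0.3), 1, 2),
               list(mean = 0.3, variance = 0.5))
  expect_error(rw1_full_conditional(0.5, 1, 1),
               class = "nutrimap_model_error")
})

test_that("precision Gibbs updates have the conjugate shape and rate", {
  # all effects zero draws from Gamma(shape + r/2, hyper_rate)
  g <- tree_graph()
  d0 <- precision_gibbs_update(rep(0, 10), "car", g)
  expect_equal(attr(d0, "shape"), 0.5 + 9 / 2)
  expect_equal(attr(d0, "rate"), 0.0005)
  # iid block with sum nu^2 = 2 over 4 cells
  d1 <- precision_gibbs_update(c(1, 1, 0, 0), "iid")
  expect_equal(attr(d1, "shape"), 0.5 + 2)
  expect_equal(attr(d1, "rate"), 0.0005 + 1)
  # rw1 rank is J - 1
  d2 <- precision_gibbs_update(c(0.1, 0.4, 0.2), "rw1")
  expect_equal(attr(d2, "shape"), 0.5 + 1)
  expect_equal(attr(d2, "rate"), 0.0005 + (0.3^2 + 0.2^2) / 2)
  # empirical mean of many draws matches shape/rate within 3 MC SEs
  set.seed(23)
  draws <- replicate(1e5, as.numeric(precision_gibbs_update(c(1, 1, 0, 0),
                                                            "iid")))
  shp <- 2.5; rt <- 1.0005
  se <- sqrt(shp / rt^2) / sqrt(1e5)
  expect_lt(abs(mean(draws) - shp / rt), 3 * se)
})

test_that("Metropolis block updates accept null proposals and keep sum-to-zero", {
  g <- make_district_graph(6, "grid")
  set.seed(24)
  panel <- simulate_counts(simulate_truth(g, 2, seed = 1), 40, seed = 2)
  state <- list(alpha = -2, phi = rnorm(6), gamma = rnorm(2),
                nu = matrix(0, 6, 2), tau_phi = 5, tau_gamma = 5, tau_nu = 5)
  state$phi <- state$phi - mean(state$phi)
  state$gamma <- state$gamma - mean(state$gamma)
  # zero-width proposal equals the current state: always accepted
  for (blk in c("alpha", "phi", "gamma", "nu")) {
    upd <- metropolis_update_block(state, blk, panel, g, proposal_sd = 0)
    expect_equal(upd$acceptance, 1)
  }
  # sum-to-zero holds after the recentred sweeps
  upd <- metropolis_update_block(state, "phi", panel, g, proposal_sd = 0.3)
  expect_lt(abs(sum(upd$state$phi)), 1e-10)
  upd <- metropolis_update_block(upd$state, "gamma", panel, g,
                                 proposal_sd = 0.3)
  expect_lt(abs(sum(upd$state$gamma)), 1e-10)
  # recentring moves the level into alpha: linear predictor preserved
  eta0 <- state$alpha + matrix(state$phi, 6, 2)
  st2 <- metropolis_update_block(state, "phi", panel, g, 0)$state
  eta1 <- st2$alpha + matrix(st2$phi, 6, 2)
  expect_equal(eta0, eta1, tolerance = 1e-12)
  bad <- state; bad$alpha <- Inf
  expect_error(metropolis_update_block(bad, "alpha", panel, g, 0.1),
               class = "nutrimap_sampler_fault")
})

test_that("Gelman-Rubin matches an independent formula and flags divergence", {
  set.seed(25)
  chains <- list(rnorm(500), rnorm(500, 0.5), rnorm(500, -0.4))
  expect_gt(oracle_gelman_rubin(chains), 1)  # floor inactive here
  expect_equal(gelman_rubin(chains), oracle_gelman_rubin(chains),
               tolerance = 1e-10)
  same <- list(rnorm(300)); same[[2]] <- same[[1]]
  expect_equal(gelman_rubin(same), 1, tolerance = 1e-8)
  apart <- list(rnorm(300, 0, 0.1), rnorm(300, 50, 0.1))
  expect_gt(gelman_rubin(apart), 10)
  expect_error(gelman_rubin(list(rnorm(10))),
               class = "nutrimap_diagnostic_error")
})

test_that("batch-means MC error behaves like iid sampling theory", {
  set.seed(26)
  # iid draws: MC error ~ sd/sqrt(N), within 20% on average
  rel <- replicate(40, {
    x <- rnorm(3000)
    mc_error(x) / (sd(x) / sqrt(3000))
  })
  expect_lt(abs(mean(rel) - 1), 0.2)
  expect_equal(mc_error(rep(3.7, 1000)), 0)
  # doubling N shrinks the error by about 1/sqrt(2)
  ratio <- replicate(40, {
    x <- rnorm(8000)
    mc_error(x[1:4000]) / mc_error(x)
  })
  expect_equal(mean(ratio), sqrt(2), tolerance = 0.15)
  expect_error(mc_error(rnorm(10)), class = "nutrimap_diagnostic_error")
})

test_that("DIC reduces to the plug-in deviance for a degenerate posterior", {
  g <- make_district_graph(4, "grid")
  panel <- count_panel(matrix(c(5, 2, 8, 1, 4, 3, 7, 2), 4, 2),
                       matrix(20, 4, 2))
  p_const <- matrix(rep(c(0.2, 0.15, 0.35, 0.1), 2), nrow = 30,
                    ncol = 8, byrow = TRUE)
  fake <- structure(list(draws = list(list(pi = p_const)), panel = panel),
                    class = "car_st_fit")
  res <- dic(fake)
  expect_equal(res$pD, 0, tolerance = 1e-10)
  # deviance agrees with a direct log-likelihood evaluation
  dev_hand <- -2 * sum(dbinom(panel$Y, panel$n,
                              matrix(p_const[1, ], 4, 2), log = TRUE))
  expect_equal(res$dic, dev_hand, tolerance = 1e-10)
})

test_that("the interaction term inflates pD on interaction-free data", {
  g <- make_district_graph(9, "grid")
  tr <- simulate_truth(g, 3, alpha = qlogis(0.15), tau_nu = 1e8, seed = 31)
  panel <- simulate_counts(tr, 150, seed = 32)
  base_cfg <- mcmc_config(n_chains = 2, burn_in = 500, n_keep = 800,
                          thin = 1, seed = 5, max_iter = 4000,
                          components = c("spatial", "temporal"))
  full_cfg <- mcmc_config(n_chains = 2, burn_in = 500, n_keep = 800,
                          thin = 1, seed = 5, max_iter = 4000)
  f_base <- suppressWarnings(fit_spacetime(panel, g, base_cfg))
  f_full <- suppressWarnings(fit_spacetime(panel, g, full_cfg))
  expect_gt(f_full$pD, f_base$pD)
})

test_that("exceedance probabilities count draws with a strict 0.8 rule", {
  panel <- count_panel(matrix(1, 2, 2), matrix(10, 2, 2))
  draws <- matrix(0.03, nrow = 1000, ncol = 4)
  fake <- structure(list(draws = list(list(pi = draws)), panel = panel),
                    class = "car_st_fit")
  e <- exceedance_probability(fake, 1, 1, 0.05, "below")
  expect_equal(e$probability, 1)
  expect_true(e$significant)
  draws2 <- draws; draws2[1:500, 1] <- 0.07
  fake2 <- structure(list(draws = list(list(pi = draws2)), panel = panel),
                     class = "car_st_fit")
  e2 <- exceedance_probability(fake2, 1, 1, 0.05, "below")
  expect_equal(e2$probability, 0.5)
  expect_false(e2$significant)
  # exactly 800/1000 draws satisfying the event is NOT significant
  draws3 <- draws; draws3[1:200, 1] <- 0.07
  fake3 <- structure(list(draws = list(list(pi = draws3)), panel = panel),
                     class = "car_st_fit")
  e3 <- exceedance_probability(fake3, 1, 1, 0.05, "below")
  expect_equal(e3$probability, 0.8)
  expect_false(e3$significant)
})

test_that("degenerate panels are rejected and empty data shrink to zero", {
  g1 <- suppressWarnings(build_adjacency(matrix(integer(0), 0, 2), 1))
  p1 <- count_panel(matrix(0, 1, 1), matrix(5, 1, 1))
  expect_error(fit_spacetime(p1, g1, mcmc_config()),
               class = "nutrimap_model_error")
  # graph/panel size mismatch caught before sampling
  g2 <- make_district_graph(6, "grid")
  p2 <- count_panel(matrix(0, 4, 2), matrix(5, 4, 2))
  expect_error(fit_spacetime(p2, g2, mcmc_config()),
               class = "nutrimap_model_error")
  # all-zero counts: posterior medians near zero everywhere
  p3 <- count_panel(matrix(0, 6, 2), matrix(80, 6, 2))
  cfg <- mcmc_config(n_chains = 2, burn_in = 500, n_keep = 500, thin = 1,
                     seed = 2, max_iter = 2000)
  f3 <- suppressWarnings(fit_spacetime(p3, g2, cfg))
  expect_true(all(f3$summary$median < 0.03))
})

test_that("chains satisfy sum-to-zero, healthy acceptance and recover small-panel truth", {
  g <- make_district_graph(16, "grid")
  tr <- simulate_truth(g, 3, alpha = qlogis(0.12), seed = 41)
  panel <- simulate_counts(tr, 120, seed = 42)
  cfg <- mcmc_config(n_chains = 2, burn_in = 1000, n_keep = 1500, thin = 1,
                     seed = 3, max_iter = 9000)
  fit <- suppressWarnings(fit_spacetime(panel, g, cfg))
  for (ch in fit$draws) {
    expect_lt(abs(sum(ch$state$phi)), 1e-10)
    expect_lt(abs(sum(ch$state$gamma)), 1e-10)
  }
  expect_true(all(fit$acceptance >= 0.1 & fit$acceptance <= 0.7))
  expect_gt(cor(fit$summary$median, as.vector(tr$pi)), 0.8)
  # credibility intervals are ordered
  expect_true(all(fit$summary$bci_low <= fit$summary$median &
                    fit$summary$median <= fit$summary$bci_high))
  # tidiers
  expect_s3_class(tidy(fit), "tbl_df")
  expect_equal(nrow(tidy(fit)), 48)
  gl <- glance(fit)
  expect_true(all(c("dic", "pD", "max_rhat", "converged") %in% names(gl)))
  expect_s3_class(autoplot(fit), "ggplot")
})

test_that("an unobserved district is smoothed between its neighbours", {
  # path graph 1-2-3; district 2 never sampled; spatial-only model
  g <- build_adjacency(rbind(c(1, 2), c(2, 3)), 3)
  Y <- rbind(c(120, 118), c(0, 0), c(40, 42))
  n <- rbind(c(400, 400), c(0, 0), c(400, 400))
  panel <- count_panel(Y, n)
  cfg <- mcmc_config(n_chains = 2, burn_in = 1000, n_keep = 2000, thin = 1,
                     seed = 4, max_iter = 8000, components = "spatial")
  fit <- suppressWarnings(fit_spacetime(panel, g, cfg))
  med <- matrix(fit$summary$median, 3, 2)
  expect_true(all(med[2, ] < med[1, ] + 0.02))
  expect_true(all(med[2, ] > med[3, ] - 0.02))
})

test_that("holdout validation is seed-reproducible and degenerates cleanly", {
  g <- make_district_graph(9, "grid")
  tr <- simulate_truth(g, 3, alpha = qlogis(0.15), seed = 51)
  panel <- simulate_counts(tr, 100, seed = 52)
  cfg <- mcmc_config(n_chains = 2, burn_in = 500, n_keep = 800, thin = 1,
                     seed = 6, max_iter = 4000)
  v1 <- suppressWarnings(holdout_validation(panel, g, cfg, 0.2, seed = 9))
  v2 <- suppressWarnings(holdout_validation(panel, g, cfg, 0.2, seed = 9))
  expect_equal(v1$table$district_id, v2$table$district_id)
  expect_equal(v1$table$predicted, v2$table$predicted)
  expect_gt(v1$correlation, 0)
  v0 <- suppressWarnings(holdout_validation(panel, g, cfg, 0, seed = 9))
  expect_equal(nrow(v0$table), 0)
})

test_that("held-out cells are covered by their posterior-predictive intervals", {
  g <- make_district_graph(52, "grid")
  tr <- simulate_truth(g, 5, alpha = qlogis(0.11), seed = 55)
  panel <- simulate_counts(tr, 60, seed = 56)
  cfg <- mcmc_config(n_chains = 2, burn_in = 1000, n_keep = 1500, thin = 1,
                     seed = 8, max_iter = 9000)
  v <- suppressWarnings(holdout_validation(panel, g, cfg, 0.1, seed = 57))
  expect_equal(nrow(v$table), 26)
  expect_gte(v$coverage, 0.85)
  expect_lte(v$coverage, 1)
  expect_gt(v$correlation, 0.3)
})

test_that("posteriors are insensitive to the hyperprior when data are rich", {
  g <- make_district_graph(9, "grid")
  tr <- simulate_truth(g, 3, alpha = qlogis(0.15), seed = 61)
  panel <- simulate_counts(tr, 900, seed = 62)
  cfg <- mcmc_config(n_chains = 2, burn_in = 800, n_keep = 1200, thin = 1,
                     seed = 7, max_iter = 6000)
  sens <- suppressWarnings(
    prior_sensitivity(panel, g, cfg,
                      alt_hypers = list(c(shape = 1, rate = 0.01))))
  expect_lt(sens$max_abs_change, 0.01)
})
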