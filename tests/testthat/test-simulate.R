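test_that("district graphs have the documented shape and are reproducible", {
  g4 <- make_district_graph(4, "grid")
  expect_true(all(lengths(g4$nb) == 2))       # 2x2 rook lattice
  g52 <- make_district_graph(52, "grid")
  expect_equal(g52$n_edges, 87)               # 4x13 lattice: 3*13 + 4*12
  expect_equal(g52$n_components, 1L)
  gr1 <- make_district_graph(30, "random_planar", seed = 5)
  gr2 <- make_district_graph(30, "random_planar", seed = 5)
  expect_identical(gr1$nb, gr2$nb)
  expect_equal(gr1$n_components, 1L)          # Gabriel graph is connected
  expect_equal(length(gr1$isolated), 0L)
})

test_that("simulated truths respect the generating structure", {
  g <- make_district_graph(20, "grid")
  tr <- simulate_truth(g, 5, alpha = qlogis(0.1), seed = 2)
  expect_lt(abs(sum(tr$phi)), 1e-10)
  expect_lt(abs(sum(tr$gamma)), 1e-10)
  expect_equal(tr$pi,
               plogis(tr$alpha + matrix(tr$phi, 20, 5) +
                        matrix(tr$gamma, 20, 5, byrow = TRUE) + tr$nu),
               tolerance = 1e-12)
  # degenerate interaction noise: pi driven by the margins only
  tr0 <- simulate_truth(g, 5, alpha = qlogis(0.1), tau_nu = 1e10, seed = 2)
  margins <- plogis(tr0$alpha + matrix(tr0$phi, 20, 5) +
                      matrix(tr0$gamma, 20, 5, byrow = TRUE))
  expect_equal(tr0$pi, margins, tolerance = 1e-4)
  # alpha = logit(0.1) with all effects off gives pi = 0.10 everywhere
  trc <- simulate_truth(g, 5, alpha = qlogis(0.1), tau_phi = 1e12,
                        tau_gamma = 1e12, tau_nu = 1e12, seed = 3)
  expect_equal(max(abs(trc$pi - 0.1)), 0, tolerance = 1e-4)
  # random-walk increment variance matches 1/tau_gamma
  incs <- unlist(lapply(1:2000, function(s)
    diff(simulate_truth(g, 5, tau_gamma = 25, seed = s)$gamma +
           0)))  # gamma is recentred; increments are unaffected
  v <- var(incs)
  se <- sqrt(2 / length(incs)) * (1 / 25)
  expect_lt(abs(v - 1 / 25), 3 * se)
  expect_identical(simulate_truth(g, 5, seed = 9)$pi,
                   simulate_truth(g, 5, seed = 9)$pi)
})

test_that("binomial count simulation has the right moments and edge cases", {
  g <- make_district_graph(4, "grid")
  tr <- simulate_truth(g, 2, seed = 1)
  n <- matrix(c(0, 10, 20, 30, 40, 0, 5, 8), 4, 2)
  p <- simulate_counts(tr, n, seed = 2)
  expect_true(all(p$Y[n == 0] == 0))
  expect_true(all(p$Y <= p$n))
  trf <- tr; trf$pi[] <- 1
  expect_equal(simulate_counts(trf, n, seed = 3)$Y, n, ignore_attr = TRUE)
  # mean of Y/n over replicates at pi = 0.2, n = 100
  tr2 <- tr; tr2$pi[] <- 0.2
  ys <- sapply(1:2000, function(s) simulate_counts(tr2, 100, seed = s)$Y[1, 1])
  se <- sqrt(0.2 * 0.8 / 100) / sqrt(2000)
  expect_lt(abs(mean(ys) / 100 - 0.2), 3 * se)
})

test_that("sample-size allocation reproduces sparse district-wave cells", {
  g <- make_district_graph(52, "grid")
  n <- simulate_sample_sizes(g, seed = 3)
  expect_equal(colSums(n), c(2079, 1500, 2925, 3772, 3740))
  expect_gt(sum(n < 20), 50)  # many small cells, the motivation for smoothing
  expect_identical(n, simulate_sample_sizes(g, seed = 3))
})

test_that("simulated children close the loop from truth to survey estimates", {
  g <- make_district_graph(12, "grid")
  ref <- make_reference_fixture()
  truths <- list(
    stunting = simulate_truth(g, 2, alpha = qlogis(0.15), seed = 1),
    thinness = simulate_truth(g, 2, alpha = qlogis(0.05), seed = 2),
    obesity = simulate_truth(g, 2, alpha = qlogis(0.14), seed = 3))
  kids <- simulate_children(truths, c(2500, 2500), ref, seed = 4,
                            missing_frac = 0)
  expect_true(all(!is.na(kids$weight_kg) & !is.na(kids$height_cm)))
  expect_true(all(kids$age_months >= 0 & kids$age_months < 60))
  expect_true(all(kids$design_weight > 0))
  # bitwise reproducibility
  kids2 <- simulate_children(truths, c(2500, 2500), ref, seed = 4,
                             missing_frac = 0)
  expect_identical(kids, kids2)
  # survey loop: classify then estimate; within 3 design SEs in >= 90%
  z <- classify_nutrition(flag_implausible(compute_zscores(kids, ref)))
  est <- weighted_prevalence(z, stunted, by = c("district_id", "wave"))
  tru <- tibble::tibble(district_id = rep(1:12, 2),
                        wave = rep(1:2, each = 12),
                        pi = as.vector(truths$stunting$pi))
  m <- dplyr::left_join(est, tru, by = c("district_id", "wave"))
  zdev <- abs(m$p_hat - m$pi) / pmax(m$se, 1e-6)
  expect_gte(mean(zdev <= 3), 0.9)
  # missingness fraction respected
  kids3 <- simulate_children(truths, c(1000, 1000), ref, seed = 5,
                             missing_frac = 0.2)
  fr <- mean(is.na(kids3$height_cm))
  expect_gt(fr, 0.12); expect_lt(fr, 0.28)
  # infeasible prevalence pair rejected
  bad <- truths
  bad$thinness$pi[] <- 0.6
  bad$obesity$pi[] <- 0.6
  expect_error(simulate_children(bad, c(100, 100), ref, seed = 1),
               class = "nutrimap_format_error")
})

test_that("a covariate association raises the Rao-Scott rejection rate", {
  g <- make_district_graph(8, "grid")
  ref <- make_reference_fixture()
  truths <- list(
    stunting = simulate_truth(g, 2, alpha = qlogis(0.12), seed = 11),
    thinness = simulate_truth(g, 2, alpha = qlogis(0.05), seed = 12),
    obesity = simulate_truth(g, 2, alpha = qlogis(0.14), seed = 13))
  kids <- simulate_children(
    truths, c(2500, 2500), ref, seed = 14, missing_frac = 0,
    covariate_assoc = list(covariate = "income", category = "<R2500",
                           outcome = "stunted", odds_ratio = 2.5))
  z <- classify_nutrition(flag_implausible(compute_zscores(kids, ref)))
  tst <- rao_scott_chi2(z, stunted, income)
  expect_lt(tst$p_value, 0.01)
  # marginal (no-association) mode stays near the null
  kids0 <- simulate_children(truths, c(2500, 2500), ref, seed = 14,
                             missing_frac = 0)
  z0 <- classify_nutrition(flag_implausible(compute_zscores(kids0, ref)))
  tst0 <- rao_scott_chi2(z0, stunted, income)
  expect_gt(tst0$p_value, 0.01)
})

test_that("the reference fixture is monotone, smooth and invertible", {
  ref <- make_reference_fixture()
  for (ind in unique(ref$indicator)) for (s in c("male", "female")) {
    blk <- ref[ref$indicator == ind & ref$sex == s, ]
    expect_true(all(diff(blk$M) > 0))
    expect_true(all(blk$S >= 0.05 & blk$S <= 0.2))
    expect_true(all(blk$L >= -2 & blk$L <= 2))
  }
  # grid-point interpolation returns exact rows
  row <- ref[ref$indicator == "bmi_for_age" & ref$sex == "male" &
               ref$index_value == 24, ]
  got <- interpolate_lms(ref, "bmi_for_age", "male", 24)
  expect_equal(got$M, row$M)
  # round trip through the inverse transform
  par <- interpolate_lms(ref, "weight_for_length", "female", 67.3)
  x <- lms_inverse(1.5, par$L, par$M, par$S)
  expect_equal(lms_zscore(x, par$L, par$M, par$S), 1.5, tolerance = 1e-10)
})
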