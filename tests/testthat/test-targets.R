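fake_fit <- function(pi_draws_by_cell, I, J, outcome = "stunting") {
  panel <- count_panel(matrix(0, I, J), matrix(0, I, J), outcome = outcome)
  structure(list(draws = list(list(pi = pi_draws_by_cell)), panel = panel),
            class = "car_st_fit")
}

test_that("interim fractions follow the configured pro-rating rule", {
  expect_equal(required_interim_fraction(rule = "constant"), 0.17)
  expect_equal(required_interim_fraction(0.40, 2012, 2025, 2017, "linear"),
               0.40 * 5 / 13, tolerance = 1e-12)
  expect_equal(round(required_interim_fraction(0.40, 2012, 2025, 2017,
                                               "linear"), 4), 0.1538)
  expect_equal(required_interim_fraction(0.40, 2012, 2025, 2017, "geometric"),
               1 - 0.6^(5 / 13), tolerance = 1e-12)
  expect_equal(round(required_interim_fraction(0.40, 2012, 2025, 2017,
                                               "geometric"), 4), 0.1784)
  expect_error(required_interim_fraction(0.4, 2025, 2012, 2017, "linear"),
               class = "nutrimap_format_error")
})

test_that("the stunting reduction target counts posterior draws correctly", {
  # all draws: 0.10 -> 0.08 is a 20% reduction, above 17%
  draws <- cbind(matrix(0.10, 500, 1), matrix(0.08, 500, 1))
  f <- fake_fit(draws, 1, 2)
  a <- assess_stunting_target(f, 1, 1, 2, 0.17)
  expect_true(a$met)
  expect_equal(a$exceedance_prob, 1)
  # no change at all: reduction 0, probability 0
  same <- cbind(matrix(0.1, 500, 1), matrix(0.1, 500, 1))
  a2 <- assess_stunting_target(fake_fit(same, 1, 2), 1, 1, 2, 0.17)
  expect_false(a2$met)
  expect_equal(a2$exceedance_prob, 0)
  # mixture with 83% of draws above the fraction
  base <- matrix(0.10, 1000, 1)
  interim <- matrix(c(rep(0.08, 830), rep(0.10, 170)), 1000, 1)
  a3 <- assess_stunting_target(fake_fit(cbind(base, interim), 1, 2),
                               1, 1, 2, 0.17)
  expect_equal(a3$exceedance_prob, 0.83)
  expect_true(a3$significant)
  # zero-baseline draws are excluded with a warning
  zb <- cbind(matrix(c(0, rep(0.1, 99)), 100, 1), matrix(0.05, 100, 1))
  expect_warning(a4 <- assess_stunting_target(fake_fit(zb, 1, 2),
                                              1, 1, 2, 0.17),
                 "zero baseline")
  expect_equal(a4$exceedance_prob, 1)
})

test_that("the wasting target is median-based with a strict significance rule", {
  f <- fake_fit(matrix(0.03, 1000, 2), 1, 2, "wasting")
  a <- assess_wasting_target(f, 1, 2)
  expect_true(a$met && a$significant)
  expect_equal(a$exceedance_prob, 1)
  f2 <- fake_fit(matrix(0.07, 1000, 2), 1, 2, "wasting")
  a2 <- assess_wasting_target(f2, 1, 2)
  expect_false(a2$met)
  expect_equal(a2$exceedance_prob, 0)
  # exactly 80% of draws below: met on the median but not significant
  d3 <- matrix(c(rep(0.03, 800), rep(0.07, 200)), 1000, 2)
  a3 <- assess_wasting_target(fake_fit(d3, 1, 2, "wasting"), 1, 2)
  expect_true(a3$met)
  expect_equal(a3$exceedance_prob, 0.8)
  expect_false(a3$significant)
})

test_that("the obesity no-increase target includes ties as satisfying", {
  same <- matrix(0.12, 600, 2)
  a <- assess_obesity_target(fake_fit(same, 1, 2, "obesity"), 1, 1, 2)
  expect_true(a$met)
  expect_equal(a$exceedance_prob, 1)
  inc <- cbind(matrix(0.10, 600, 1), matrix(0.12, 600, 1))
  a2 <- assess_obesity_target(fake_fit(inc, 1, 2, "obesity"), 1, 1, 2)
  expect_false(a2$met)
  expect_equal(a2$exceedance_prob, 0)
})

test_that("national roll-ups use integer rounding and are internally consistent", {
  expect_equal(summarize_targets(rep(c(TRUE, FALSE), c(43, 9)))$percent, 83)
  expect_equal(summarize_targets(rep(c(TRUE, FALSE), c(0, 52)))$percent, 0)
  s <- summarize_targets(rep(c(TRUE, FALSE), c(17, 35)))
  expect_equal(s$count + sum(!rep(c(TRUE, FALSE), c(17, 35))), 52)
  # monotone in the count
  pcts <- sapply(0:52, function(k)
    summarize_targets(rep(c(TRUE, FALSE), c(k, 52 - k)))$percent)
  expect_true(all(diff(pcts) >= 0))
})

test_that("district-level assessment rolls up and agrees with exceedance_probability", {
  set.seed(71)
  I <- 6; J <- 2
  draws <- matrix(runif(400 * I * J, 0.01, 0.09), 400, I * J)
  f <- fake_fit(draws, I, J, "wasting")
  tab <- assess_who_targets(f, "wasting", interim_wave = 2)
  expect_equal(nrow(tab), I)
  expect_equal(attr(tab, "count"), sum(tab$met))
  for (i in seq_len(I)) {
    ep <- exceedance_probability(f, i, 2, 0.05, "below")
    expect_equal(tab$exceedance_prob[i], ep$probability)
  }
  # 6 of 52 districts increasing leaves 46 meeting the obesity target
  base <- matrix(0.10, 300, 52)
  interim <- base
  interim[, 1:6] <- 0.15
  f2 <- fake_fit(cbind(base, interim), 52, 2, "obesity")
  tab2 <- assess_who_targets(f2, "obesity", baseline_wave = 1,
                             interim_wave = 2)
  expect_equal(attr(tab2, "count"), 46)
  # raising the interim fraction never increases stunting attainment
  set.seed(72)
  d3 <- matrix(plogis(rnorm(300 * 8 * 2, qlogis(0.1), 0.4)), 300, 16)
  f3 <- fake_fit(d3, 8, 2)
  counts <- sapply(c(0.05, 0.17, 0.30), function(fr)
    attr(assess_who_targets(f3, "stunting", baseline_wave = 1,
                            interim_wave = 2, fraction = fr), "count"))
  expect_true(all(diff(counts) <= 0))
})
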