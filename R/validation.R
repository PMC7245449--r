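#' Out-of-sample validation by random cell holdout
#'
#' Randomly masks a fraction of the non-empty district-wave cells
#' (setting their denominators to zero so they contribute no
#' likelihood), refits the model, and compares the held-out observed
#' prevalences `Y/n` with their purely model-smoothed posterior
#' predictions.
#'
#' @param panel A [count_panel()].
#' @param graph A [build_adjacency()] graph.
#' @param config An [mcmc_config()].
#' @param fraction Fraction of non-empty cells to hold out (default 0.1).
#' @param seed Integer seed for the mask (reproducible).
#' @return List with `table` (district, wave, observed crude
#'   prevalence, posterior median prediction with its 95% credibility
#'   interval, the 95% posterior-predictive interval for the crude
#'   prevalence, and a covered flag against the predictive interval),
#'   `rmse`, `correlation`, `coverage`, and the refitted model `fit`.
#'   With `fraction = 0` the table is empty and the fit uses all data.
#' @export
holdout_validation <- function(panel, graph, config, fraction = 0.1, seed) {
  stopifnot(!missing(seed), fraction >= 0, fraction < 1)
  nonempty <- which(panel$n > 0)
  n_mask <- floor(fraction * length(nonempty))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  mask <- if (n_mask > 0) sort(sample(nonempty, n_mask)) else integer(0)
  panel2 <- panel
  Y_obs <- panel$Y[mask]
  n_obs <- panel$n[mask]
  panel2$Y[mask] <- 0
  panel2$n[mask] <- 0
  fit <- fit_spacetime(panel2, graph, config)
  if (length(mask) == 0) {
    return(list(table = tibble::tibble(district_id = integer(0),
                                       wave = integer(0),
                                       observed = numeric(0),
                                       predicted = numeric(0),
                                       bci_low = numeric(0),
                                       bci_high = numeric(0),
                                       ppi_low = numeric(0),
                                       ppi_high = numeric(0),
                                       covered = logical(0)),
                rmse = NA_real_, correlation = NA_real_,
                coverage = NA_real_, fit = fit))
  }
  ij <- arrayInd(mask, dim(panel$n))
  cell_cols <- (ij[, 2] - 1) * panel$I + ij[, 1]
  pooled <- do.call(rbind, lapply(fit$draws, `[[`, "pi"))
  pred <- apply(pooled[, cell_cols, drop = FALSE], 2, quantile,
                probs = c(0.5, 0.025, 0.975), names = FALSE)
  obs <- Y_obs / n_obs
  # coverage is judged against the posterior-predictive interval of the
  # crude prevalence Y/n, which carries the binomial sampling noise of
  # the held-out cell on top of the posterior uncertainty in pi
  set.seed(seed + 1L)
  ppi <- vapply(seq_along(mask), function(k) {
    ystar <- rbinom(nrow(pooled), n_obs[k], pooled[, cell_cols[k]])
    quantile(ystar / n_obs[k], c(0.025, 0.975), names = FALSE)
  }, numeric(2))
  tbl <- tibble::tibble(
    district_id = ij[, 1], wave = ij[, 2], observed = obs,
    predicted = pred[1, ], bci_low = pred[2, ], bci_high = pred[3, ],
    ppi_low = ppi[1, ], ppi_high = ppi[2, ],
    covered = obs >= ppi[1, ] & obs <= ppi[2, ])
  list(table = tbl,
       rmse = sqrt(mean((tbl$observed - tbl$predicted)^2)),
       correlation = if (sd(tbl$observed) > 0 && sd(tbl$predicted) > 0)
         cor(tbl$observed, tbl$predicted) else NA_real_,
       coverage = mean(tbl$covered), fit = fit)
}

#' Sensitivity of posterior prevalence to the precision hyperprior
#'
#' Refits the model under alternative Gamma(shape, rate) hyperpriors on
#' the random-effect precisions and reports, for each alternative, the
#' largest absolute change in the posterior median prevalence across
#' all district-wave cells. When the data dominate the likelihood the
#' changes should be small; with sparse data they expose how much the
#' smoothing leans on the prior.
#'
#' @param panel A [count_panel()].
#' @param graph A [build_adjacency()] graph.
#' @param config Baseline [mcmc_config()].
#' @param alt_hypers List of `c(shape =, rate =)` alternatives.
#' @return Tibble with `shape`, `rate`, `max_abs_change`,
#'   `mean_abs_change` relative to the baseline fit.
#' @export
prior_sensitivity <- function(panel, graph, config, alt_hypers) {
  stopifnot(length(alt_hypers) >= 1)
  base <- fit_spacetime(panel, graph, config)
  rows <- lapply(alt_hypers, function(h) {
    cfg <- config
    cfg$hyper_shape <- unname(h[["shape"]])
    cfg$hyper_rate <- unname(h[["rate"]])
    alt <- fit_spacetime(panel, graph, cfg)
    d <- abs(alt$summary$median - base$summary$median)
    tibble::tibble(shape = cfg$hyper_shape, rate = cfg$hyper_rate,
                   max_abs_change = max(d), mean_abs_change = mean(d))
  })
  dplyr::bind_rows(rows)
}
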