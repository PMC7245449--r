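#' Gelman-Rubin potential scale reduction factor
#'
#' Classic two-or-more-chain convergence diagnostic: with `m` chains of
#' `N` draws each, within-chain variance `W` (mean of the chain
#' variances) and between-chain variance `B = N * var(chain means)`,
#' \deqn{\hat R = \sqrt{\frac{(N-1)/N \, W + B/N}{W}}.}
#' Values near 1 indicate the chains are sampling the same
#' distribution.
#'
#' @param chains List of numeric vectors of equal length (>= 2 chains).
#' @return Scalar \eqn{\hat R}.
#' @export
gelman_rubin <- function(chains) {
  if (!is.list(chains) || length(chains) < 2) {
    abort("gelman_rubin(): need at least two chains.",
          class = "nutrimap_diagnostic_error")
  }
  N <- unique(lengths(chains))
  if (length(N) != 1) {
    abort("gelman_rubin(): chains must have equal length.",
          class = "nutrimap_diagnostic_error")
  }
  W <- mean(vapply(chains, var, 0))
  B <- N * var(vapply(chains, mean, 0))
  if (W < .Machine$double.eps) return(if (B < .Machine$double.eps) 1 else Inf)
  # values below 1 arise only from the (N-1)/N finite-sample factor;
  # floor at 1 so agreement between chains reads as exactly 1
  max(1, sqrt(((N - 1) / N * W + B / N) / W))
}

#' Batch-means Monte Carlo standard error of a posterior mean
#'
#' Splits the draws into consecutive batches and reports the standard
#' error of the batch means: a Monte Carlo error estimate that remains
#' valid under the autocorrelation of MCMC output. The sampler's
#' stopping rule requires this to be below 5% of the posterior SD for
#' every monitored parameter.
#'
#' @param draws Numeric vector of (possibly autocorrelated) draws.
#' @param batch_size Draws per batch; defaults to `floor(N / 30)` so at
#'   least 20 batches are formed. An error is raised below 20 batches.
#' @return Scalar Monte Carlo standard error.
#' @export
mc_error <- function(draws, batch_size = NULL) {
  N <- length(draws)
  if (is.null(batch_size)) batch_size <- max(1L, floor(N / 30))
  n_batch <- N %/% batch_size
  if (n_batch < 20) {
    abort("mc_error(): fewer than 20 batches; provide more draws or a smaller batch size.",
          class = "nutrimap_diagnostic_error")
  }
  use <- draws[seq_len(n_batch * batch_size)]
  bm <- colMeans(matrix(use, nrow = batch_size))
  sd(bm) / sqrt(n_batch)
}

# deviance of the binomial panel at given cell probabilities
panel_deviance <- function(panel, p) {
  keep <- panel$n > 0
  -2 * sum(dbinom(panel$Y[keep], panel$n[keep], p[keep], log = TRUE))
}

dic_from_chains <- function(chains, panel) {
  pooled <- do.call(rbind, lapply(chains, `[[`, "pi"))
  keep <- as.vector(panel$n > 0)
  Yv <- as.vector(panel$Y)[keep]
  nv <- as.vector(panel$n)[keep]
  lch <- sum(lchoose(nv, Yv))
  pm <- pooled[, keep, drop = FALSE]
  # deviance per draw, vectorized over cells
  dev <- -2 * (as.vector(log(pm) %*% Yv) +
               as.vector(log1p(-pm) %*% (nv - Yv)) + lch)
  dbar <- mean(dev)
  # plug-in deviance at the posterior mean of the cell logits
  eta_bar <- colMeans(qlogis(pooled))
  dhat <- panel_deviance(panel, matrix(plogis(eta_bar), panel$I, panel$J))
  pD <- dbar - dhat
  list(dic = dbar + pD, pD = pD, dbar = dbar, dhat = dhat)
}

#' Deviance information criterion of a space-time fit
#'
#' `DIC = Dbar + pD` with `pD = Dbar - D(theta_bar)`: the posterior
#' mean deviance plus the effective number of parameters, where the
#' plug-in deviance is evaluated at the posterior mean of the cell
#' logits. Deviance is `-2 x` the binomial log-likelihood over cells
#' with `n > 0`.
#'
#' @param fit A [fit_spacetime()] result.
#' @return Tibble with `dic`, `pD`, `dbar`, `dhat`.
#' @export
dic <- function(fit) {
  stopifnot(inherits(fit, "car_st_fit"))
  res <- dic_from_chains(fit$draws, fit$panel)
  tibble::tibble(dic = res$dic, pD = res$pD, dbar = res$dbar,
                 dhat = res$dhat)
}

#' Posterior exceedance probability for a district-wave prevalence
#'
#' The fraction of pooled posterior draws for which the prevalence lies
#' below (or above) a policy threshold. Following the convention for
#' posterior classification in disease mapping, a probability strictly
#' greater than 0.8 is flagged significant; exactly 0.8 is not.
#'
#' @param fit A [fit_spacetime()] result.
#' @param district District index.
#' @param wave Wave index.
#' @param threshold Prevalence threshold.
#' @param direction `"below"` for P(pi < threshold), `"above"` for
#'   P(pi > threshold).
#' @return Tibble with `probability` and `significant`.
#' @export
exceedance_probability <- function(fit, district, wave, threshold,
                                   direction = c("below", "above")) {
  direction <- match.arg(direction)
  draws <- pi_draws(fit, district, wave)
  p <- if (direction == "below") mean(draws < threshold)
       else mean(draws > threshold)
  tibble::tibble(probability = p, significant = p > 0.8)
}
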