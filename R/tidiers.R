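# broom-style tidiers and ggplot2 methods for fitted objects

#' Tidy a space-time fit
#'
#' One row per district-wave with the posterior median smoothed
#' prevalence and its 95% Bayesian credibility interval.
#'
#' @param x A [fit_spacetime()] result.
#' @param ... Unused.
#' @return Tibble with `outcome`, `district_id`, `wave`, `median`,
#'   `bci_low`, `bci_high`, `mean`, `sd`, `n`, `Y`.
#' @method tidy car_st_fit
#' @export
tidy.car_st_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a space-time fit
#'
#' @param x A [fit_spacetime()] result.
#' @param ... Unused.
#' @return Tibble with `dic`, `pD`, `max_rhat`, `converged`,
#'   `n_chains`, `n_draws`, `total_iter`.
#' @method glance car_st_fit
#' @export
glance.car_st_fit <- function(x, ...) {
  tibble::tibble(
    dic = x$dic, pD = x$pD,
    max_rhat = max(x$diagnostics$rhat, na.rm = TRUE),
    converged = x$converged,
    n_chains = length(x$draws),
    n_draws = nrow(x$draws[[1]]$pi),
    total_iter = x$total_iter)
}

#' Heatmap of posterior median smoothed prevalence
#'
#' District-by-wave tile map of the posterior median prevalence: the
#' tabular analogue of the choropleth series usually drawn from such
#' fits.
#'
#' @param object A [fit_spacetime()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot car_st_fit
#' @export
autoplot.car_st_fit <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = factor(.data$wave),
                                  y = factor(.data$district_id),
                                  fill = .data$median)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "Posterior\nmedian", labels = NULL) +
    ggplot2::labs(x = "Survey wave", y = "District",
                  title = sprintf("Smoothed %s prevalence",
                                  object$panel$outcome)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Observed vs fitted prevalence for a space-time fit
#'
#' Scatter of crude `Y/n` against the posterior median for cells with
#' data, with the identity line: the standard model-adequacy display.
#'
#' @param fit A [fit_spacetime()] result.
#' @return A ggplot object.
#' @export
plot_observed_fitted <- function(fit) {
  d <- dplyr::filter(tidy(fit), .data$n > 0)
  d$observed <- d$Y / d$n
  ggplot2::ggplot(d, ggplot2::aes(x = .data$observed, y = .data$median)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2) +
    ggplot2::labs(x = "Observed prevalence (Y/n)",
                  y = "Posterior median prevalence",
                  title = sprintf("Observed vs fitted: %s",
                                  fit$panel$outcome)) +
    ggplot2::theme_minimal()
}

#' Temporal trend of smoothed prevalence
#'
#' Per-district trajectories of the posterior median prevalence over
#' waves, with the national (unweighted district) mean overlaid.
#'
#' @param fit A [fit_spacetime()] result.
#' @return A ggplot object.
#' @export
plot_wave_trend <- function(fit) {
  d <- tidy(fit)
  m <- dplyr::summarise(dplyr::group_by(d, .data$wave),
                        median = mean(.data$median), .groups = "drop")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$wave, y = .data$median,
                                  group = .data$district_id)) +
    ggplot2::geom_line(alpha = 0.2) +
    ggplot2::geom_line(data = m, ggplot2::aes(group = NULL),
                       colour = "red", linewidth = 1) +
    ggplot2::labs(x = "Survey wave", y = "Posterior median prevalence",
                  title = sprintf("District trajectories: %s",
                                  fit$panel$outcome)) +
    ggplot2::theme_minimal()
}

#' Bar chart of district target exceedance probabilities
#'
#' @param assessment Output of [assess_who_targets()].
#' @return A ggplot object.
#' @export
plot_target_probabilities <- function(assessment) {
  ggplot2::ggplot(assessment,
                  ggplot2::aes(x = stats::reorder(.data$district_id,
                                                  .data$exceedance_prob),
                               y = .data$exceedance_prob,
                               fill = .data$significant)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.8, linetype = 2) +
    ggplot2::labs(x = "District", y = "Exceedance probability") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank())
}
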