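# WHO 2025 global nutrition target assessment from posterior draws:
# a 40% relative reduction in stunting from the 2012 baseline, wasting
# reduced to and held below 5%, and no increase in childhood obesity.
# Assessment at an interim wave uses a pro-rated "necessary" fraction
# of the total stunting reduction.

#' Required interim fraction of the 2025 stunting-reduction target
#'
#' How much of the total relative reduction must be achieved by an
#' interim year. Rules: `"constant"` returns the conventional
#' 17% figure used for the 2012-to-2017 interim assessment of the 40%
#' target; `"linear"` pro-rates the total reduction linearly in time;
#' `"geometric"` assumes a constant annual reduction rate
#' (`1 - (1 - total)^(elapsed/horizon)`).
#'
#' @param total_reduction Total relative reduction required by the
#'   target year (default 0.40).
#' @param baseline_year,target_year,interim_year Calendar years with
#'   `baseline < interim <= target`.
#' @param rule `"constant"`, `"linear"` or `"geometric"`.
#' @param constant Value returned under `"constant"` (default 0.17).
#' @return Scalar fraction in (0, 1).
#' @export
required_interim_fraction <- function(total_reduction = 0.40,
                                      baseline_year = 2012,
                                      target_year = 2025,
                                      interim_year = 2017,
                                      rule = c("constant", "linear",
                                               "geometric"),
                                      constant = 0.17) {
  rule <- match.arg(rule)
  if (!(baseline_year < interim_year && interim_year <= target_year)) {
    abort("required_interim_fraction(): need baseline < interim <= target.",
          class = "nutrimap_format_error")
  }
  frac_time <- (interim_year - baseline_year) / (target_year - baseline_year)
  switch(rule,
         constant = constant,
         linear = total_reduction * frac_time,
         geometric = 1 - (1 - total_reduction)^frac_time)
}

#' Assess the stunting relative-reduction target for one district
#'
#' The district meets the target when the posterior median of the
#' relative reduction `(pi_base - pi_interim) / pi_base` between the
#' baseline and interim waves is at least `fraction`; the exceedance
#' probability is the posterior probability of that event. Draws with
#' `pi_base = 0` leave the relative reduction undefined and are
#' excluded (with a warning).
#'
#' @param fit A [fit_spacetime()] result for the stunting panel.
#' @param district District index.
#' @param baseline_wave,interim_wave Wave indices.
#' @param fraction Required relative reduction
#'   (see [required_interim_fraction()]).
#' @return Tibble with `met`, `exceedance_prob`, `significant`
#'   (probability strictly greater than 0.8).
#' @export
assess_stunting_target <- function(fit, district, baseline_wave,
                                   interim_wave, fraction = 0.17) {
  pb <- pi_draws(fit, district, baseline_wave)
  pi_ <- pi_draws(fit, district, interim_wave)
  ok <- pb > 0
  if (!all(ok)) {
    warn(sprintf("District %d: %d draws with zero baseline prevalence excluded.",
                 district, sum(!ok)))
    pb <- pb[ok]; pi_ <- pi_[ok]
  }
  red <- (pb - pi_) / pb
  prob <- mean(red >= fraction)
  tibble::tibble(met = median(red) >= fraction, exceedance_prob = prob,
                 significant = prob > 0.8)
}

#' Assess the wasting <5% target for one district
#'
#' Met when the posterior median prevalence at the assessment wave is
#' below `threshold`; the exceedance probability is `P(pi < threshold)`
#' and is significant when strictly greater than 0.8.
#'
#' @param fit A [fit_spacetime()] result for the wasting panel.
#' @param district District index.
#' @param wave Assessment wave.
#' @param threshold Prevalence threshold (default 0.05).
#' @return Tibble with `met`, `exceedance_prob`, `significant`.
#' @export
assess_wasting_target <- function(fit, district, wave, threshold = 0.05) {
  draws <- pi_draws(fit, district, wave)
  prob <- mean(draws < threshold)
  tibble::tibble(met = median(draws) < threshold, exceedance_prob = prob,
                 significant = prob > 0.8)
}

#' Assess the no-obesity-increase target for one district
#'
#' Met when the posterior median prevalence at the interim wave does
#' not exceed the posterior median at the baseline wave ("no increase"
#' includes equality); the exceedance probability is
#' `P(pi_interim <= pi_base)`.
#'
#' @param fit A [fit_spacetime()] result for the obesity panel.
#' @param district District index.
#' @param baseline_wave,interim_wave Wave indices.
#' @return Tibble with `met`, `exceedance_prob`, `significant`.
#' @export
assess_obesity_target <- function(fit, district, baseline_wave,
                                  interim_wave) {
  pb <- pi_draws(fit, district, baseline_wave)
  pi_ <- pi_draws(fit, district, interim_wave)
  prob <- mean(pi_ <= pb)
  tibble::tibble(met = median(pi_) <= median(pb), exceedance_prob = prob,
                 significant = prob > 0.8)
}

#' National roll-up of per-district target attainment
#'
#' @param flags Logical vector of length `I`: whether each district met
#'   the target.
#' @param I Number of districts (default `length(flags)`).
#' @return Tibble with `count` (districts meeting the target) and
#'   `percent` (`round(100 * count / I)` to the nearest integer).
#' @export
summarize_targets <- function(flags, I = length(flags)) {
  stopifnot(length(flags) == I)
  count <- sum(flags, na.rm = TRUE)
  tibble::tibble(count = count, percent = round(100 * count / I))
}

#' Full WHO-2025 target assessment for a fitted outcome
#'
#' Applies the outcome's target rule to every district and appends a
#' national summary: stunting uses the relative-reduction rule between
#' `baseline_wave` and `interim_wave`; wasting (thinness) the <5%
#' threshold at `interim_wave`; obesity the no-increase rule.
#'
#' @param fit A [fit_spacetime()] result.
#' @param target `"stunting"`, `"wasting"` or `"obesity"`.
#' @param baseline_wave,interim_wave Wave indices (defaults: waves 3
#'   and 5, the 2012 and 2017 panels).
#' @param fraction Stunting interim reduction fraction.
#' @param threshold Wasting prevalence threshold.
#' @return Tibble with one row per district (`district_id`, `met`,
#'   `exceedance_prob`, `significant`) carrying attributes `count` and
#'   `percent` from [summarize_targets()].
#' @export
assess_who_targets <- function(fit, target = c("stunting", "wasting",
                                               "obesity"),
                               baseline_wave = 3, interim_wave = 5,
                               fraction = 0.17, threshold = 0.05) {
  target <- match.arg(target)
  rows <- lapply(seq_len(fit$panel$I), function(i) {
    r <- switch(target,
                stunting = assess_stunting_target(fit, i, baseline_wave,
                                                  interim_wave, fraction),
                wasting = assess_wasting_target(fit, i, interim_wave,
                                                threshold),
                obesity = assess_obesity_target(fit, i, baseline_wave,
                                                interim_wave))
    dplyr::bind_cols(tibble::tibble(district_id = i), r)
  })
  out <- dplyr::bind_rows(rows)
  roll <- summarize_targets(out$met, fit$panel$I)
  attr(out, "count") <- roll$count
  attr(out, "percent") <- roll$percent
  out
}
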