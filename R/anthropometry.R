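#' LMS transformation of an anthropometric measurement to a z-score
#'
#' Converts a raw measurement `x` to a reference z-score given the
#' Box-Cox power (`L`), median (`M`) and coefficient of variation (`S`)
#' of the reference distribution at the child's age (or length) and sex:
#' \deqn{z = \frac{(x/M)^L - 1}{L\,S} \quad (L \neq 0), \qquad
#'       z = \frac{\log(x/M)}{S} \quad (L = 0).}
#' The log branch is the analytic limit of the power branch as `L` tends
#' to zero, so the transform is continuous in `L`.
#'
#' @param x Measurement (height in cm, weight in kg, or BMI). Vectorised.
#' @param L,M,S Reference parameters; `M` and `S` must be strictly positive.
#' @return Numeric vector of z-scores.
#' @examples
#' lms_zscore(11, L = 1, M = 10, S = 0.1) # (11/10 - 1)/0.1 = 1
#' @export
lms_zscore <- function(x, L, M, S) {
  n <- max(length(x), length(L), length(M), length(S))
  x <- rep_len(x, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  bad <- !is.na(x) & !is.na(M) & !is.na(S) & (x <= 0 | M <= 0 | S <= 0)
  if (any(bad)) {
    abort("lms_zscore(): x, M and S must all be strictly positive.",
          class = "nutrimap_invalid_measurement")
  }
  z <- ifelse(abs(L) < 1e-12,
              log(x / M) / S,
              ((x / M)^L - 1) / (L * S))
  z
}

#' Invert the LMS transform
#'
#' Returns the measurement whose z-score equals `z` under the given
#' reference parameters; the exact inverse of [lms_zscore()].
#'
#' @inheritParams lms_zscore
#' @param z Target z-score.
#' @return Measurement on the original scale.
#' @export
lms_inverse <- function(z, L, M, S) {
  n <- max(length(z), length(L), length(M), length(S))
  z <- rep_len(z, n); L <- rep_len(L, n); M <- rep_len(M, n); S <- rep_len(S, n)
  ifelse(abs(L) < 1e-12,
         M * exp(S * z),
         M * (1 + L * S * z)^(1 / L))
}

#' Interpolate reference L, M, S at an arbitrary age or length
#'
#' Reference tables tabulate L, M and S at discrete values of the
#' indexing variable (age in months, or length in cm for
#' weight-for-length). Each parameter is interpolated linearly between
#' the bracketing rows; a query on a grid point returns that row
#' verbatim.
#'
#' @param reference Reference tibble with columns `indicator`, `sex`,
#'   `index_value`, `L`, `M`, `S` (see [make_reference_fixture()]).
#' @param indicator One of `"height_for_age"`, `"weight_for_length"`,
#'   `"bmi_for_age"`.
#' @param sex `"male"` or `"female"` (vectorised with `at`).
#' @param at Value(s) of the indexing variable to interpolate at.
#' @return Tibble with columns `L`, `M`, `S`, one row per query.
#' @export
interpolate_lms <- function(reference, indicator, sex, at) {
  n <- max(length(sex), length(at))
  sex <- rep_len(sex, n); at <- rep_len(at, n)
  out <- matrix(NA_real_, n, 3, dimnames = list(NULL, c("L", "M", "S")))
  for (s in unique(sex)) {
    block <- reference[reference$indicator == indicator & reference$sex == s, ]
    if (nrow(block) < 2L) {
      abort(sprintf("No reference rows for indicator '%s', sex '%s'.",
                    indicator, s), class = "nutrimap_range_error")
    }
    block <- block[order(block$index_value), ]
    idx <- which(sex == s)
    q <- at[idx]
    rng <- range(block$index_value)
    if (any(q < rng[1] - 1e-9 | q > rng[2] + 1e-9, na.rm = TRUE)) {
      abort(sprintf(
        "interpolate_lms(): query outside reference range [%g, %g] for %s/%s.",
        rng[1], rng[2], indicator, s), class = "nutrimap_range_error")
    }
    for (p in c("L", "M", "S")) {
      out[idx, p] <- stats::approx(block$index_value, block[[p]],
                                   xout = q, rule = 1)$y
    }
  }
  tibble::as_tibble(out)
}

#' Compute height-for-age and weight-based z-scores for child records
#'
#' For each record, the height-for-age z-score (HAZ) is computed from
#' height against the `height_for_age` reference at the child's sex and
#' age. The weight-based z-score follows the age-dependent convention
#' for under-fives: weight-for-length (indexed by length in cm) for
#' children under 24 months, and BMI-for-age (BMI = weight / (height in
#' m)^2) for children 24 months and older. Missing measurements yield a
#' missing z-score with the corresponding validity flag set to `FALSE`;
#' no error is thrown for missingness.
#'
#' @param records Tibble of child records with columns `age_months`,
#'   `sex`, `weight_kg`, `height_cm` (other columns are carried through).
#' @param reference Reference table as in [interpolate_lms()].
#' @return The input tibble with added columns `haz`, `weight_based_z`,
#'   `indicator_used` (`"weight_for_length"` or `"bmi_for_age"`),
#'   `haz_valid` and `weight_z_valid`.
#' @export
compute_zscores <- function(records, reference) {
  stopifnot(all(c("age_months", "sex", "weight_kg", "height_cm") %in%
                  names(records)))
  records <- tibble::as_tibble(records)
  age <- records$age_months
  sex <- records$sex
  h <- records$height_cm
  w <- records$weight_kg
  under2 <- age < 24

  haz <- rep(NA_real_, nrow(records))
  ok_h <- !is.na(h) & h > 0 & !is.na(age) & !is.na(sex)
  if (any(ok_h)) {
    par <- interpolate_lms(reference, "height_for_age", sex[ok_h], age[ok_h])
    haz[ok_h] <- lms_zscore(h[ok_h], par$L, par$M, par$S)
  }

  wz <- rep(NA_real_, nrow(records))
  # weight-for-length needs both weight and a measured length
  ok_wfl <- under2 & !is.na(w) & w > 0 & ok_h
  if (any(ok_wfl)) {
    par <- interpolate_lms(reference, "weight_for_length", sex[ok_wfl],
                           h[ok_wfl])
    wz[ok_wfl] <- lms_zscore(w[ok_wfl], par$L, par$M, par$S)
  }
  ok_bmi <- !under2 & !is.na(w) & w > 0 & ok_h
  if (any(ok_bmi)) {
    bmi <- w[ok_bmi] / (h[ok_bmi] / 100)^2
    par <- interpolate_lms(reference, "bmi_for_age", sex[ok_bmi], age[ok_bmi])
    wz[ok_bmi] <- lms_zscore(bmi, par$L, par$M, par$S)
  }

  records$haz <- haz
  records$weight_based_z <- wz
  records$indicator_used <- ifelse(under2, "weight_for_length", "bmi_for_age")
  records$haz_valid <- !is.na(haz)
  records$weight_z_valid <- !is.na(wz)
  records
}

#' Flag biologically implausible z-scores
#'
#' Marks z-scores outside fixed absolute limits as invalid so they are
#' excluded from downstream prevalence estimation. Defaults: |HAZ| > 6
#' or |weight-based z| > 5 is implausible. Setting a limit to `Inf`
#' leaves the corresponding flags unchanged.
#'
#' @param zscores Output of [compute_zscores()].
#' @param haz_limit,weight_limit Absolute plausibility limits.
#' @return `zscores` with `haz_valid` / `weight_z_valid` updated.
#' @export
flag_implausible <- function(zscores, haz_limit = 6, weight_limit = 5) {
  zscores$haz_valid <- zscores$haz_valid &
    !is.na(zscores$haz) & abs(zscores$haz) <= haz_limit
  zscores$weight_z_valid <- zscores$weight_z_valid &
    !is.na(zscores$weight_based_z) &
    abs(zscores$weight_based_z) <= weight_limit
  zscores
}

#' Classify nutritional status from z-scores
#'
#' Applies the under-five cut-offs: stunted if HAZ < -2; thin/wasted if
#' the weight-based z-score (weight-for-length under 2 years, BMI-for-age
#' at 2 years and older) is < -2; obese if the weight-based z-score is
#' at least +2 at every age (the boundary is included uniformly). The same
#' threshold logic applies regardless of which reference produced the
#' z-score. Invalid or missing z-scores yield `NA` flags.
#'
#' @param zscores Output of [compute_zscores()] (optionally after
#'   [flag_implausible()]).
#' @return `zscores` with added logical columns `stunted`, `thin_wasted`,
#'   `obese`.
#' @export
classify_nutrition <- function(zscores) {
  haz <- ifelse(zscores$haz_valid, zscores$haz, NA_real_)
  wz <- ifelse(zscores$weight_z_valid, zscores$weight_based_z, NA_real_)
  zscores$stunted <- haz < -2
  zscores$thin_wasted <- wz < -2
  zscores$obese <- wz >= 2
  zscores
}
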