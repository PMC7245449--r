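#' Synthetic LMS growth-reference table
#'
#' Builds a smooth, fully synthetic LMS reference covering
#' height-for-age and BMI-for-age over 0--60 months and
#' weight-for-length over 45--120 cm, for both sexes. The curves are
#' plausible in shape and scale (median height rising from ~50 to
#' ~102 cm, median weight-for-length from ~3 to ~29 kg) but are NOT the
#' WHO growth standards: they exist so the full pipeline is testable
#' without bundling external reference data. Real WHO tables in the same
#' CSV layout can be supplied anywhere a `reference` argument is taken.
#'
#' Within each (indicator, sex) block the median `M` is strictly
#' increasing in the indexing variable, `S` lies in \[0.05, 0.2\] and `L`
#' in \[-2, 2\], so both LMS formula branches are exercised.
#'
#' @param age_step Grid step in months for the age-indexed indicators.
#' @param length_step Grid step in cm for weight-for-length.
#' @return Tibble with columns `indicator`, `sex`, `index_value`,
#'   `L`, `M`, `S`.
#' @export
make_reference_fixture <- function(age_step = 1, length_step = 1) {
  ages <- seq(0, 60, by = age_step)
  lens <- seq(35, 130, by = length_step)
  blocks <- list()
  for (sex in c("male", "female")) {
    fem <- sex == "female"
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      indicator = "height_for_age", sex = sex, index_value = ages,
      L = rep(1, length(ages)),
      M = (50 - 1 * fem) + 60 * (1 - exp(-ages / 30)),
      S = 0.05 + 0.01 * ages / 60
    )
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      indicator = "bmi_for_age", sex = sex, index_value = ages,
      L = -1.5 + ages / 60,
      M = (15 - 0.3 * fem) + 1.5 * ages / 60,
      S = 0.08 + 0.04 * ages / 60
    )
    blocks[[length(blocks) + 1L]] <- tibble::tibble(
      indicator = "weight_for_length", sex = sex, index_value = lens,
      L = -0.2 - 0.8 * (lens - 35) / 95,
      M = (3.2 - 0.1 * fem) * (lens / 50)^2.5,
      S = 0.08 + 0.03 * (lens - 35) / 95
    )
  }
  dplyr::bind_rows(blocks)
}

#' Read / write a reference table CSV
#'
#' CSV layout: `indicator`, `sex`, `index_value`, `L`, `M`, `S`.
#'
#' @param path File path.
#' @param reference Reference tibble.
#' @return `read_reference_csv()` returns the reference tibble;
#'   `write_reference_csv()` returns `path` invisibly.
#' @export
read_reference_csv <- function(path) {
  ref <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           indicator = "c", sex = "c", index_value = "d",
                           L = "d", M = "d", S = "d"))
  if (any(ref$M <= 0) || any(ref$S <= 0)) {
    abort("Reference table: M and S must be strictly positive.",
          class = "nutrimap_format_error")
  }
  ref
}

#' @rdname read_reference_csv
#' @export
write_reference_csv <- function(reference, path) {
  readr::write_csv(reference, path)
  invisible(path)
}
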