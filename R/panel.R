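#' District-by-wave binomial count panel
#'
#' Container for the space-time model's data: an `I x J` matrix of
#' outcome numerators `Y` and denominators `n` (children measured), one
#' row per district and one column per survey wave. Missing
#' district-waves are encoded as `n = 0` and contribute no likelihood;
#' their prevalence is inferred purely by smoothing.
#'
#' @param Y,n Numeric `I x J` matrices with `0 <= Y <= n`.
#' @param outcome Outcome label (e.g. `"stunting"`).
#' @param wave_labels Optional vector of wave labels (e.g. survey years).
#' @return An object of class `count_panel`.
#' @export
count_panel <- function(Y, n, outcome = "outcome", wave_labels = NULL) {
  Y <- as.matrix(Y); n <- as.matrix(n)
  stopifnot(all(dim(Y) == dim(n)))
  if (any(n < 0) || any(Y < 0) || any(Y > n)) {
    abort("count_panel(): need 0 <= Y <= n and n >= 0 in every cell.",
          class = "nutrimap_format_error")
  }
  if (is.null(wave_labels)) wave_labels <- seq_len(ncol(Y))
  structure(list(Y = Y, n = n, I = nrow(Y), J = ncol(Y),
                 outcome = outcome, wave_labels = wave_labels),
            class = "count_panel")
}

#' @export
print.count_panel <- function(x, ...) {
  cat(sprintf("count_panel '%s': %d districts x %d waves, %d empty cells\n",
              x$outcome, x$I, x$J, sum(x$n == 0)))
  invisible(x)
}

#' Build a count panel from survey prevalence estimates
#'
#' Converts design-based prevalence estimates to binomial pseudo-counts
#' for the space-time model: the weighted prevalence for each
#' district-wave is applied to that cell's sample-size total, `Y =
#' round(p_hat * n)` clamped to `[0, n]`. District-waves absent from
#' the estimates get `n = 0` (missing cell).
#'
#' @param prevalence Tibble with columns `district_id`, `wave`, `p_hat`.
#' @param sizes Tibble with columns `district_id`, `wave`, `n`.
#' @param I,J Panel dimensions (default: maxima observed in `sizes`).
#' @inheritParams count_panel
#' @return A [count_panel()].
#' @export
build_count_panel <- function(prevalence, sizes, I = NULL, J = NULL,
                              outcome = "outcome", wave_labels = NULL) {
  if (any(prevalence$p_hat < 0 | prevalence$p_hat > 1, na.rm = TRUE)) {
    abort("build_count_panel(): p_hat outside [0, 1].",
          class = "nutrimap_format_error")
  }
  if (is.null(I)) I <- max(sizes$district_id)
  if (is.null(J)) J <- max(sizes$wave)
  nm <- matrix(0, I, J)
  nm[cbind(sizes$district_id, sizes$wave)] <- sizes$n
  pm <- matrix(0, I, J)
  prev <- prevalence[!is.na(prevalence$p_hat), ]
  pm[cbind(prev$district_id, prev$wave)] <- prev$p_hat
  Y <- pmin(pmax(round(pm * nm), 0), nm)
  count_panel(Y, nm, outcome = outcome, wave_labels = wave_labels)
}

#' @method as_tibble count_panel
#' @export
as_tibble.count_panel <- function(x, ...) {
  tibble::tibble(
    district_id = rep(seq_len(x$I), times = x$J),
    wave = rep(seq_len(x$J), each = x$I),
    Y = as.vector(x$Y), n = as.vector(x$n))
}

#' Read / write a count panel CSV
#'
#' Long CSV layout: `district_id`, `wave`, `Y`, `n`; missing
#' district-waves may simply be absent (read back as `n = 0`).
#'
#' @param path File path.
#' @param panel A [count_panel()].
#' @param I,J Optional panel dimensions.
#' @inheritParams count_panel
#' @return `read_panel_csv()` returns a `count_panel`;
#'   `write_panel_csv()` returns `path` invisibly.
#' @export
read_panel_csv <- function(path, I = NULL, J = NULL, outcome = "outcome") {
  d <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(district_id = "i", wave = "i",
                                               Y = "d", n = "d"))
  if (is.null(I)) I <- max(d$district_id)
  if (is.null(J)) J <- max(d$wave)
  Y <- matrix(0, I, J); nm <- matrix(0, I, J)
  Y[cbind(d$district_id, d$wave)] <- d$Y
  nm[cbind(d$district_id, d$wave)] <- d$n
  count_panel(Y, nm, outcome = outcome)
}

#' @rdname read_panel_csv
#' @export
write_panel_csv <- function(panel, path) {
  readr::write_csv(tibble::as_tibble(panel), path)
  invisible(path)
}
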