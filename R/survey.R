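# Design-based estimation for stratified two-stage cluster samples.
# Variances are Taylor-linearized over PSU totals within strata (the
# standard "with replacement" first-stage approximation).

# cluster-total variance of a linearized score vector u (n x p matrix)
# returns list(V = p x p matrix, n_psu, n_strata, single_psu)
svy_score_vcov <- function(u, stratum, psu) {
  u <- as.matrix(u)
  key <- paste(stratum, psu, sep = "\r")
  z <- rowsum(u, key)                       # PSU totals
  str_of_psu <- vapply(strsplit(rownames(z), "\r", fixed = TRUE), `[`, "", 1L)
  V <- matrix(0, ncol(u), ncol(u))
  single <- FALSE
  for (h in unique(str_of_psu)) {
    zh <- z[str_of_psu == h, , drop = FALSE]
    nh <- nrow(zh)
    if (nh < 2L) { single <- TRUE; next }   # lone PSU: no variance contribution
    zc <- sweep(zh, 2, colMeans(zh))
    V <- V + nh / (nh - 1) * crossprod(zc)
  }
  list(V = V, n_psu = nrow(z), n_strata = length(unique(str_of_psu)),
       single_psu = single)
}

logit_ci <- function(p, se, df, conf_level = 0.95) {
  if (is.na(p) || is.na(se) || se == 0 || p <= 0 || p >= 1) {
    return(c(p, p))
  }
  tcrit <- qt(1 - (1 - conf_level) / 2, df = max(df, 1))
  l <- qlogis(p)
  se_l <- se / (p * (1 - p))
  plogis(l + c(-1, 1) * tcrit * se_l)
}

#' Survey-weighted prevalence with design-based standard errors
#'
#' Estimates the prevalence of a binary outcome as the weighted mean
#' \eqn{\hat p = \sum w y / \sum w} over records with a non-missing
#' outcome, with a Taylor-linearized standard error that accounts for
#' clustering (PSUs) within strata, and a 95% confidence interval
#' computed on the logit scale and back-transformed (so it stays inside
#' \[0, 1\]). Degrees of freedom are the number of PSUs minus the number
#' of strata. Also reports the weighted total of positive records
#' (the extrapolated population count).
#'
#' @param data Tibble of records.
#' @param outcome Unquoted logical column (e.g. `stunted`). `NA` values
#'   are excluded as invalid.
#' @param by Optional unquoted column(s) defining estimation domains,
#'   e.g. `c(wave, age_band)`.
#' @param weight,stratum,psu Names (strings) of the design columns.
#' @param conf_level Confidence level for the interval.
#' @return Tibble with one row per domain: the `by` columns plus
#'   `p_hat`, `se`, `ci_low`, `ci_high`, `n_valid`, `weighted_total`
#'   (weighted count of positives) and `se_reliable` (`FALSE` when some
#'   stratum contributed a single PSU).
#' @export
weighted_prevalence <- function(data, outcome, by = NULL,
                                weight = "design_weight",
                                stratum = "stratum_id", psu = "psu_id",
                                conf_level = 0.95) {
  data <- tibble::as_tibble(data)
  y_all <- dplyr::pull(data, {{ outcome }})
  keep <- !is.na(y_all)
  if (!any(keep)) {
    abort("weighted_prevalence(): no valid records in domain.",
          class = "nutrimap_estimation_error")
  }
  data$..y <- as.numeric(y_all)
  data <- data[keep, , drop = FALSE]
  one_domain <- function(d, key) {
    y <- d$..y
    w <- d[[weight]]
    if (any(w <= 0)) abort("Design weights must be strictly positive.",
                           class = "nutrimap_format_error")
    W <- sum(w)
    p <- sum(w * y) / W
    u <- w * (y - p) / W
    vc <- svy_score_vcov(u, d[[stratum]], d[[psu]])
    se <- sqrt(max(vc$V[1, 1], 0))
    df <- vc$n_psu - vc$n_strata
    ci <- logit_ci(p, se, df, conf_level)
    tibble::tibble(p_hat = p, se = se, ci_low = ci[1], ci_high = ci[2],
                   n_valid = nrow(d), weighted_total = sum(w * y),
                   se_reliable = !vc$single_psu)
  }
  data |>
    dplyr::group_by(dplyr::across({{ by }})) |>
    dplyr::group_modify(one_domain) |>
    dplyr::ungroup()
}

#' Survey-weighted population total of positive records
#'
#' Extrapolated count of children with the outcome: the sum of design
#' weights over valid positive records, optionally by domain.
#'
#' @inheritParams weighted_prevalence
#' @return Tibble with the `by` columns plus `weighted_total` and
#'   `n_positive`.
#' @export
weighted_total <- function(data, outcome, by = NULL,
                           weight = "design_weight") {
  data <- tibble::as_tibble(data)
  y <- dplyr::pull(data, {{ outcome }})
  data$..y <- !is.na(y) & y
  data$..w <- data[[weight]]
  data |>
    dplyr::group_by(dplyr::across({{ by }})) |>
    dplyr::summarise(weighted_total = sum(.data$..w[.data$..y]),
                     n_positive = sum(.data$..y), .groups = "drop")
}

# replace NA covariate values by an explicit "Missing" category
explicit_missing <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- "Missing"
  x
}

#' Rao-Scott corrected chi-square test of independence
#'
#' Weighted Pearson chi-square test of independence between two
#' categorical variables under a complex (weighted, clustered,
#' stratified) design, using the Rao-Scott second-order (Satterthwaite)
#' correction referenced to an F distribution. The uncorrected weighted
#' Pearson statistic is \eqn{X^2_P = n \sum_{rc} (\hat p_{rc} - \hat
#' p_{r\cdot}\hat p_{\cdot c})^2 / (\hat p_{r\cdot}\hat p_{\cdot c})};
#' the correction divides by the mean generalized design effect
#' \eqn{\bar\delta (1 + a^2)} and adjusts the degrees of freedom by the
#' coefficient of variation \eqn{a^2} of the design-effect eigenvalues.
#' Missing values in either variable form an explicit "Missing"
#' category, matching the tabulation convention for covariates with
#' incomplete ascertainment.
#'
#' @param data Tibble of records.
#' @param row_var,col_var Unquoted categorical columns.
#' @inheritParams weighted_prevalence
#' @return One-row tibble: `statistic` (F statistic), `ndf`, `ddf`,
#'   `p_value`, `chisq` (uncorrected weighted Pearson X^2), `df`
#'   (nominal (R-1)(C-1)), `delta_bar`, `a2`, `n`.
#' @export
rao_scott_chi2 <- function(data, row_var, col_var,
                           weight = "design_weight",
                           stratum = "stratum_id", psu = "psu_id") {
  data <- tibble::as_tibble(data)
  r <- explicit_missing(dplyr::pull(data, {{ row_var }}))
  c_ <- explicit_missing(dplyr::pull(data, {{ col_var }}))
  w <- data[[weight]]
  rl <- sort(unique(r)); cl <- sort(unique(c_))
  R <- length(rl); C <- length(cl)
  if (R < 2 || C < 2) {
    abort("rao_scott_chi2(): both variables need >= 2 observed levels.",
          class = "nutrimap_test_error")
  }
  n <- length(r)
  ri <- match(r, rl); ci <- match(c_, cl)
  cell <- (ri - 1L) * C + ci              # row-major cell index
  RC <- R * C
  delta <- matrix(0, n, RC)
  delta[cbind(seq_len(n), cell)] <- 1
  W <- sum(w)
  p <- colSums(w * delta) / W             # weighted cell proportions
  prow <- rowSums(matrix(p, R, C, byrow = TRUE))
  pcol <- colSums(matrix(p, R, C, byrow = TRUE))
  if (any(prow <= 0) || any(pcol <= 0)) {
    abort("rao_scott_chi2(): degenerate table (empty margin).",
          class = "nutrimap_test_error")
  }
  p0 <- as.vector(t(outer(prow, pcol)))   # independence, row-major
  X2 <- n * sum((p - p0)^2 / p0)

  # linearized covariance of the cell-proportion vector
  u <- (w / W) * sweep(delta, 2, p)
  vc <- svy_score_vcov(u, data[[stratum]], data[[psu]])
  V <- vc$V
  V0 <- (diag(p) - tcrossprod(p)) / n

  # Jacobian of h_rc = p_rc - p_r. * p_.c (row-major cell order)
  H <- matrix(0, RC, RC)
  for (a in seq_len(RC)) {
    ra <- (a - 1L) %/% C + 1L; ca <- (a - 1L) %% C + 1L
    for (b in seq_len(RC)) {
      rb <- (b - 1L) %/% C + 1L; cb <- (b - 1L) %% C + 1L
      H[a, b] <- (a == b) - (ra == rb) * pcol[ca] - (ca == cb) * prow[ra]
    }
  }
  Vh <- H %*% V %*% t(H)
  V0h <- H %*% V0 %*% t(H)
  d <- (R - 1) * (C - 1)
  ev <- eigen(MASS::ginv(V0h) %*% Vh, only.values = TRUE)$values
  ev <- sort(Re(ev), decreasing = TRUE)[seq_len(d)]
  ev <- pmax(ev, 0)
  delta_bar <- mean(ev)
  a2 <- if (delta_bar > 0) sum((ev - delta_bar)^2) / (d * delta_bar^2) else 0
  nu <- d / (1 + a2)
  Fstat <- if (delta_bar > 0) X2 / (delta_bar * (1 + a2)) / nu else 0
  ddf <- nu * (vc$n_psu - vc$n_strata)
  pval <- if (Fstat <= 0) 1 else pf(Fstat, nu, ddf, lower.tail = FALSE)
  tibble::tibble(statistic = Fstat, ndf = nu, ddf = ddf, p_value = pval,
                 chisq = X2, df = d, delta_bar = delta_bar, a2 = a2, n = n)
}

#' Survey-weighted two-way tabulation of a covariate by outcome status
#'
#' For each level of a (binary) outcome, the weighted distribution of a
#' covariate's categories with design-based confidence intervals --
#' i.e. column proportions in the covariate-by-outcome table. Each cell
#' proportion is estimated via [weighted_prevalence()] on the indicator
#' of category membership within the outcome level, so the cells sum to
#' 1 within each outcome level. Missing covariate values form an
#' explicit "Missing" category.
#'
#' @param data Tibble of records.
#' @param covariate Unquoted categorical column.
#' @param outcome Unquoted logical column; `NA` outcomes are dropped.
#' @inheritParams weighted_prevalence
#' @return Tibble with `outcome_level`, `category`, `p_hat`, `se`,
#'   `ci_low`, `ci_high`, `n_valid`.
#' @export
two_way_prevalence_table <- function(data, covariate, outcome,
                                     weight = "design_weight",
                                     stratum = "stratum_id",
                                     psu = "psu_id") {
  data <- tibble::as_tibble(data)
  y <- dplyr::pull(data, {{ outcome }})
  cv <- explicit_missing(dplyr::pull(data, {{ covariate }}))
  keep <- !is.na(y)
  data <- data[keep, ]; y <- y[keep]; cv <- cv[keep]
  cats <- sort(unique(cv))
  out <- list()
  for (lev in sort(unique(y))) {
    sub <- data[y == lev, ]
    sub_cv <- cv[y == lev]
    for (k in cats) {
      sub$..ind <- sub_cv == k
      est <- weighted_prevalence(sub, .data$..ind, weight = weight,
                                 stratum = stratum, psu = psu)
      out[[length(out) + 1L]] <- tibble::tibble(
        outcome_level = lev, category = k,
        p_hat = est$p_hat, se = est$se,
        ci_low = est$ci_low, ci_high = est$ci_high, n_valid = est$n_valid)
    }
  }
  dplyr::bind_rows(out)
}
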