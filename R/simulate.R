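# Synthetic-data generators emulating the structure of a national
# multiround panel survey: a district contiguity graph, the space-time
# model's forward simulation, and child-level records from a stratified
# two-stage cluster design with design weights and Table-1-style
# covariates. Everything is seeded and bitwise reproducible.

#' Generate a synthetic district adjacency graph
#'
#' Stands in for the contiguity structure of the 52 district councils.
#' Styles: `"grid"` builds a rook-adjacent lattice (rows chosen as the
#' largest divisor of `I` not exceeding `sqrt(I)`, falling back to a
#' trimmed near-square lattice when `I` is prime), always connected;
#' `"random_planar"` builds the Gabriel graph of `I` uniform random
#' points in the unit square (planar and connected by construction,
#' since it contains the Euclidean minimum spanning tree).
#'
#' @param I Number of districts (>= 4). Default 52.
#' @param style `"grid"` or `"random_planar"`.
#' @param seed Integer seed (needed for `"random_planar"`).
#' @return A [build_adjacency()] graph.
#' @export
make_district_graph <- function(I = 52, style = c("grid", "random_planar"),
                                seed = 1) {
  style <- match.arg(style)
  stopifnot(I >= 4)
  if (style == "grid") {
    divs <- which(I %% seq_len(floor(sqrt(I))) == 0)
    r <- if (length(divs)) max(divs) else floor(sqrt(I))
    cc <- ceiling(I / r)
    # nodes numbered row-major over an r x cc lattice, trimmed to I
    edges <- NULL
    for (node in seq_len(I)) {
      row <- (node - 1) %/% cc + 1
      col <- (node - 1) %% cc + 1
      if (col < cc && node + 1 <= I) edges <- rbind(edges, c(node, node + 1))
      if (row < r && node + cc <= I) edges <- rbind(edges, c(node, node + cc))
    }
    return(build_adjacency(edges, I))
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  x <- runif(I); y <- runif(I)
  edges <- NULL
  for (i in seq_len(I - 1)) for (j in (i + 1):I) {
    cx <- (x[i] + x[j]) / 2; cy <- (y[i] + y[j]) / 2
    r2 <- (x[i] - cx)^2 + (y[i] - cy)^2
    d2 <- (x - cx)^2 + (y - cy)^2
    d2[c(i, j)] <- Inf
    if (all(d2 > r2)) edges <- rbind(edges, c(i, j))  # Gabriel edge
  }
  build_adjacency(edges, I)
}

#' Simulate space-time model parameters and true prevalences
#'
#' Forward counterpart of the space-time model: spatial effects are
#' drawn from the intrinsic CAR structure via Gaussian increments with
#' variance `1/tau_phi` along a BFS spanning forest of the graph and
#' then recentred to sum to zero (the intrinsic prior is improper --
#' any draw is defined only up to level, and recentring fixes the same
#' gauge as the fitted model); isolated districts draw exchangeable
#' `N(0, 1/tau_phi)`. Temporal effects follow a recentred Gaussian
#' random walk with increment variance `1/tau_gamma`, and the
#' interaction is iid `N(0, 1/tau_nu)`. True prevalences are
#' `plogis(alpha + phi_i + gamma_j + nu_ij)`.
#'
#' @param graph A [build_adjacency()] graph.
#' @param J Number of waves (default 5).
#' @param alpha Intercept on the logit scale (default `qlogis(0.1)`).
#' @param tau_phi,tau_gamma,tau_nu True precisions (> 0).
#' @param gamma_trend Optional length-J deterministic drift (logit
#'   scale) added to the temporal walk before recentring, used to
#'   emulate a secular national trend; `NULL` for a pure random walk.
#' @param seed Integer seed.
#' @return Object of class `sim_truth`: list with `alpha`, `phi`,
#'   `gamma`, `nu`, `pi` (`I x J`), the `tau`s, `graph`, `J`, `seed`.
#' @export
simulate_truth <- function(graph, J = 5, alpha = qlogis(0.1),
                           tau_phi = 10, tau_gamma = 40, tau_nu = 40,
                           gamma_trend = NULL, seed = 1) {
  stopifnot(tau_phi > 0, tau_gamma > 0, tau_nu > 0, J >= 2)
  if (!is.null(gamma_trend)) stopifnot(length(gamma_trend) == J)
  I <- graph$n_nodes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  phi <- numeric(I)
  forest <- spanning_forest(graph)
  if (nrow(forest)) {
    for (k in seq_len(nrow(forest))) {
      phi[forest[k, "child"]] <- phi[forest[k, "parent"]] +
        rnorm(1, 0, 1 / sqrt(tau_phi))
    }
  }
  iso <- graph$isolated
  if (length(iso)) phi[iso] <- rnorm(length(iso), 0, 1 / sqrt(tau_phi))
  phi <- phi - mean(phi)
  gamma <- cumsum(c(0, rnorm(J - 1, 0, 1 / sqrt(tau_gamma))))
  if (!is.null(gamma_trend)) gamma <- gamma + gamma_trend
  gamma <- gamma - mean(gamma)
  nu <- matrix(rnorm(I * J, 0, 1 / sqrt(tau_nu)), I, J)
  eta <- alpha + matrix(phi, I, J) + matrix(gamma, I, J, byrow = TRUE) + nu
  structure(list(alpha = alpha, phi = phi, gamma = gamma, nu = nu,
                 pi = plogis(eta), tau_phi = tau_phi,
                 tau_gamma = tau_gamma, tau_nu = tau_nu,
                 graph = graph, J = J, seed = seed),
            class = "sim_truth")
}

#' Simulate binomial counts from true prevalences
#'
#' `Y_ij ~ Binomial(n_ij, pi_ij)`, seeded. Cells with `n_ij = 0` get
#' `Y_ij = 0` (missing district-waves).
#'
#' @param truth A [simulate_truth()] object.
#' @param n_matrix `I x J` matrix of denominators (or a scalar,
#'   recycled).
#' @param seed Integer seed.
#' @param outcome Outcome label for the panel.
#' @return A [count_panel()].
#' @export
simulate_counts <- function(truth, n_matrix, seed = 1, outcome = "outcome") {
  I <- nrow(truth$pi); J <- ncol(truth$pi)
  if (length(n_matrix) == 1) n_matrix <- matrix(n_matrix, I, J)
  n_matrix <- as.matrix(n_matrix)
  stopifnot(all(dim(n_matrix) == c(I, J)), all(n_matrix >= 0))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  Y <- matrix(rbinom(I * J, as.vector(n_matrix), as.vector(truth$pi)), I, J)
  count_panel(Y, n_matrix, outcome = outcome)
}

#' Simulate realistic district-wave sample-size totals
#'
#' Allocates each wave's valid-measurement total across districts by a
#' multinomial draw with unequal district shares (squared-exponential
#' tilted, so a few metropolitan-like districts dominate), producing
#' the many small and occasional zero cells that motivate smoothing.
#'
#' @param graph A [build_adjacency()] graph (for `I`).
#' @param per_wave_totals Valid measurements per wave.
#' @param seed Integer seed.
#' @param concentration Dirichlet-like concentration of the district
#'   shares; smaller values give more unequal districts.
#' @return `I x J` integer matrix of denominators.
#' @export
simulate_sample_sizes <- function(graph, per_wave_totals = c(2079, 1500,
                                                             2925, 3772,
                                                             3740),
                                  seed = 1, concentration = 1.2) {
  I <- graph$n_nodes
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  shares <- rgamma(I, shape = concentration, rate = 1)
  shares <- shares / sum(shares)
  J <- length(per_wave_totals)
  n <- matrix(0L, I, J)
  for (j in seq_len(J)) {
    n[, j] <- as.integer(stats::rmultinom(1, per_wave_totals[j], shares))
  }
  n
}

table1_covariates <- function(n) {
  draw <- function(levels, probs) sample(levels, n, TRUE, probs)
  tibble::tibble(
    ethnicity = draw(c("African", "Coloured", "Asian/Indian", "White"),
                     c(0.86, 0.12, 0.01, 0.01)),
    birth_weight = draw(c("LBW", "NBW", "HBW", "Missing"),
                        c(0.09, 0.74, 0.03, 0.14)),
    income = draw(c("<R2500", ">=R2500"), c(0.45, 0.55)),
    hunger = draw(c("Never", "Seldom", "Sometimes", "Often", "Always"),
                  c(0.66, 0.10, 0.18, 0.05, 0.01)),
    environment = draw(c("Rural formal", "Tribal authority",
                         "Urban formal", "Urban informal"),
                       c(0.09, 0.46, 0.35, 0.10)),
    mother_bmi = draw(c("Underweight", "Normal", "Overweight", "Obese",
                        "Missing"), c(0.02, 0.31, 0.24, 0.29, 0.14)),
    mother_age = draw(c("<20", "20-24", "25-34", "35-44", "45+", "Missing"),
                      c(0.07, 0.24, 0.40, 0.16, 0.02, 0.11)),
    mother_edu = draw(c("None", "Primary", "Secondary", "Tertiary",
                        "Missing"), c(0.02, 0.10, 0.66, 0.07, 0.15)),
    father_edu = draw(c("None", "Primary", "Secondary", "Tertiary",
                        "Missing"), c(0.01, 0.40, 0.45, 0.05, 0.09)))
}

#' Simulate child-level survey records from true prevalences
#'
#' Generates one row per child-wave mimicking a stratified two-stage
#' cluster panel: children are allocated to districts (strata) by a
#' multinomial draw over configurable shares, nested into PSUs within
#' district, and given design weights (inverse inclusion probability
#' scaled to a national under-five population, with lognormal
#' variability). Ages are uniform on \[0, 60) months, sex is 50/50, and
#' anthropometry is generated by inverting the LMS transform from
#' normal z-draws whose means (and, for the weight-based score, SD) are
#' chosen so that the classification prevalences match the true
#' district-wave prevalences: for stunting, `P(HAZ < -2) = pi`; for the
#' weight-based score the mean and SD jointly match `P(z < -2)` to the
#' thinness prevalence and `P(z >= 2)` to the obesity prevalence.
#' Covariates are drawn marginally from Table-1-like frequencies; an
#' optional association shifts one outcome's prevalence by an odds
#' ratio within one covariate category (for power checks of the
#' association tests).
#'
#' @param truths Named list of [simulate_truth()] objects with elements
#'   `stunting`, `thinness`, `obesity` on the same graph and `J`.
#' @param per_wave_sizes Children sampled per wave (default the panel's
#'   published totals, 3254 rising to 4710).
#' @param reference Reference table (default [make_reference_fixture()]).
#' @param seed Integer seed.
#' @param psus_per_district PSUs (clusters) per district per wave.
#' @param weight_cv Lognormal coefficient of variation of the design
#'   weights.
#' @param missing_frac Probability each of weight and height is missing.
#' @param district_shares Optional length-I district allocation shares.
#' @param covariate_assoc Optional list `(covariate=, category=,
#'   outcome=, odds_ratio=)` inducing a covariate-outcome association.
#' @param population_total National under-five population the weights
#'   expand to.
#' @return Tibble of child records: `child_id`, `wave`, `district_id`,
#'   `stratum_id`, `psu_id`, `design_weight`, `age_months`, `sex`,
#'   `weight_kg`, `height_cm`, plus covariate columns.
#' @export
simulate_children <- function(truths, per_wave_sizes = c(3254, 3543, 3842,
                                                         4495, 4710),
                              reference = make_reference_fixture(),
                              seed = 1, psus_per_district = 6,
                              weight_cv = 0.3, missing_frac = 0.05,
                              district_shares = NULL,
                              covariate_assoc = NULL,
                              population_total = 5.5e6) {
  stopifnot(all(c("stunting", "thinness", "obesity") %in% names(truths)))
  I <- nrow(truths$stunting$pi)
  J <- ncol(truths$stunting$pi)
  stopifnot(length(per_wave_sizes) == J)
  if (any(truths$thinness$pi + truths$obesity$pi >= 1)) {
    abort("simulate_children(): thinness + obesity prevalence >= 1 in some cell.",
          class = "nutrimap_format_error")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  if (is.null(district_shares)) {
    district_shares <- rgamma(I, shape = 2, rate = 1)
    district_shares <- district_shares / sum(district_shares)
  }
  waves <- list()
  for (j in seq_len(J)) {
    n_j <- per_wave_sizes[j]
    district <- sample(seq_len(I), n_j, TRUE, district_shares)
    psu_no <- sample(seq_len(psus_per_district), n_j, TRUE)
    base_w <- population_total / n_j
    w <- base_w * exp(rnorm(n_j, -weight_cv^2 / 2, weight_cv))
    age <- runif(n_j, 0, 60 - 1e-9)
    sex <- sample(c("male", "female"), n_j, TRUE)

    p_st <- truths$stunting$pi[cbind(district, j)]
    p_th <- truths$thinness$pi[cbind(district, j)]
    p_ob <- truths$obesity$pi[cbind(district, j)]
    cov <- table1_covariates(n_j)
    if (!is.null(covariate_assoc)) {
      exposed <- cov[[covariate_assoc$covariate]] == covariate_assoc$category
      o <- covariate_assoc$odds_ratio
      tgt <- switch(covariate_assoc$outcome, stunted = "p_st",
                    thin_wasted = "p_th", obese = "p_ob")
      p <- get(tgt)
      p[exposed] <- p[exposed] * o / (1 - p[exposed] + p[exposed] * o)
      assign(tgt, p)
    }
    # stunting: haz ~ N(mu, 1) with P(haz < -2) = p_st
    mu_h <- -2 - qnorm(p_st)
    haz <- pmin(pmax(rnorm(n_j, mu_h, 1), -4.5), 4.5)
    # weight z: N(mu, sd) matching both tails
    sd_w <- 4 / (qnorm(1 - p_ob) - qnorm(p_th))
    mu_w <- 2 - sd_w * qnorm(1 - p_ob)
    wz <- pmin(pmax(rnorm(n_j, mu_w, sd_w), -4.5), 4.5)

    par_h <- interpolate_lms(reference, "height_for_age", sex, age)
    height <- lms_inverse(haz, par_h$L, par_h$M, par_h$S)
    under2 <- age < 24
    weight <- numeric(n_j)
    if (any(under2)) {
      par_w <- interpolate_lms(reference, "weight_for_length", sex[under2],
                               height[under2])
      weight[under2] <- lms_inverse(wz[under2], par_w$L, par_w$M, par_w$S)
    }
    if (any(!under2)) {
      par_b <- interpolate_lms(reference, "bmi_for_age", sex[!under2],
                               age[!under2])
      bmi <- lms_inverse(wz[!under2], par_b$L, par_b$M, par_b$S)
      weight[!under2] <- bmi * (height[!under2] / 100)^2
    }
    height[runif(n_j) < missing_frac] <- NA_real_
    weight[runif(n_j) < missing_frac] <- NA_real_

    waves[[j]] <- dplyr::bind_cols(
      tibble::tibble(
        child_id = sprintf("w%d_%06d", j, seq_len(n_j)),
        wave = j, district_id = district,
        stratum_id = sprintf("d%02d", district),
        psu_id = sprintf("d%02d_p%d", district, psu_no),
        design_weight = w, age_months = age, sex = sex,
        weight_kg = weight, height_cm = height),
      cov)
  }
  dplyr::bind_rows(waves)
}

#' Read / write child-record CSVs
#'
#' One row per child-wave with the column layout produced by
#' [simulate_children()]; missing measurements are empty cells.
#'
#' @param path File path.
#' @param records Child-record tibble.
#' @return `read_children_csv()` returns the tibble;
#'   `write_children_csv()` returns `path` invisibly.
#' @export
read_children_csv <- function(path) {
  readr::read_csv(path, show_col_types = FALSE,
                  col_types = readr::cols(
                    child_id = "c", wave = "i", district_id = "i",
                    stratum_id = "c", psu_id = "c", design_weight = "d",
                    age_months = "d", sex = "c", weight_kg = "d",
                    height_cm = "d", .default = "c"))
}

#' @rdname read_children_csv
#' @export
write_children_csv <- function(records, path) {
  readr::write_csv(records, path)
  invisible(path)
}
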