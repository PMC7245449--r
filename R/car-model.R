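# Bayesian hierarchical binomial space-time model:
#   Y_kij ~ Binomial(n_ij, pi_kij)
#   logit(pi_kij) = alpha + phi_i + gamma_j + nu_ij
# phi: intrinsic CAR over the district adjacency graph, gamma: first-order
# random walk over waves, nu: iid interaction; precisions tau_phi,
# tau_gamma, tau_nu ~ Gamma(0.5, 0.0005) (shape-rate, i.e. inverse gamma
# on the variances); alpha has an improper flat prior with sum-to-zero
# recentring of phi and gamma for identifiability. One model per outcome.

#' Full conditional of an intrinsic CAR spatial effect
#'
#' Under the intrinsic CAR prior with binary common-boundary weights,
#' the conditional distribution of district `i`'s effect given the rest
#' is normal with mean the average of its neighbours' effects and
#' variance `1 / (tau_phi * m_i)` where `m_i` is the neighbour count.
#' An isolated district falls back to the exchangeable `N(0, 1/tau_phi)`.
#'
#' @param phi Numeric vector of current spatial effects.
#' @param i District index.
#' @param graph A [build_adjacency()] graph.
#' @param tau_phi Spatial precision (> 0).
#' @return List with `mean` and `variance`.
#' @export
car_full_conditional <- function(phi, i, graph, tau_phi) {
  nbi <- graph$nb[[i]]
  if (length(nbi) == 0L) {
    return(list(mean = 0, variance = 1 / tau_phi))
  }
  list(mean = mean(phi[nbi]), variance = 1 / (tau_phi * length(nbi)))
}

#' Full conditional of a first-order random-walk temporal effect
#'
#' The RW1 prior treats adjacent waves as neighbours on a path graph:
#' an interior wave's effect is conditionally normal around the mean of
#' its two temporal neighbours with variance `1 / (2 tau_gamma)`; an
#' endpoint has its single neighbour as mean and variance
#' `1 / tau_gamma`.
#'
#' @param gamma Numeric vector of current temporal effects (length J >= 2).
#' @param j Wave index.
#' @param tau_gamma Temporal precision (> 0).
#' @return List with `mean` and `variance`.
#' @export
rw1_full_conditional <- function(gamma, j, tau_gamma) {
  J <- length(gamma)
  if (J < 2) abort("rw1_full_conditional(): need J >= 2 waves.",
                   class = "nutrimap_model_error")
  stopifnot(j >= 1, j <= J)
  if (j == 1) {
    list(mean = gamma[2], variance = 1 / tau_gamma)
  } else if (j == J) {
    list(mean = gamma[J - 1], variance = 1 / tau_gamma)
  } else {
    list(mean = (gamma[j - 1] + gamma[j + 1]) / 2,
         variance = 1 / (2 * tau_gamma))
  }
}

# quadratic form and rank of a random-effect block under its structure
effect_quadform <- function(effects, structure = c("car", "rw1", "iid"),
                            graph = NULL) {
  structure <- match.arg(structure)
  if (structure == "car") {
    stopifnot(!is.null(graph))
    e <- graph_edges(graph)
    q <- if (nrow(e)) sum((effects[e[, 1]] - effects[e[, 2]])^2) else 0
    # isolated nodes carry a proper N(0, 1/tau) term: full-rank contribution
    iso <- graph$isolated
    q <- q + sum(effects[iso]^2)
    n_iso <- length(iso)
    # components among non-isolated nodes
    comp_noniso <- graph$n_components - n_iso
    r <- (graph$n_nodes - n_iso - comp_noniso) + n_iso
    list(q = q, rank = r)
  } else if (structure == "rw1") {
    list(q = sum(diff(effects)^2), rank = length(effects) - 1L)
  } else {
    list(q = sum(effects^2), rank = length(effects))
  }
}

#' Conjugate Gibbs draw for a random-effect precision
#'
#' With a Gamma(shape, rate) hyperprior on the precision, the full
#' conditional is Gamma(shape + r/2, rate + q/2) where `q` is the
#' structure-specific quadratic form (CAR: sum over neighbour pairs of
#' squared differences, plus squared effects of isolated nodes; RW1: sum
#' of squared increments; iid: sum of squares) and `r` its rank (CAR:
#' nodes minus connected components, isolated nodes counting full rank;
#' RW1: J - 1; iid: the block size).
#'
#' @param effects Numeric vector (or matrix for iid) of current effects.
#' @param structure `"car"`, `"rw1"` or `"iid"`.
#' @param graph Required when `structure = "car"`.
#' @param hyper_shape,hyper_rate Gamma hyperprior parameters
#'   (defaults 0.5 and 0.0005).
#' @return A single precision draw, with attributes `shape` and `rate`
#'   of the full-conditional Gamma.
#' @export
precision_gibbs_update <- function(effects, structure = c("car", "rw1", "iid"),
                                   graph = NULL, hyper_shape = 0.5,
                                   hyper_rate = 0.0005) {
  qf <- effect_quadform(as.vector(effects), structure, graph)
  shape <- hyper_shape + qf$rank / 2
  rate <- hyper_rate + qf$q / 2
  draw <- rgamma(1, shape = shape, rate = rate)
  attr(draw, "shape") <- shape
  attr(draw, "rate") <- rate
  draw
}

# log-posterior of a model state (up to a constant), used by the
# reference Metropolis implementation and by tests
logpost_state <- function(state, panel, graph) {
  eta <- state$alpha +
    matrix(state$phi, panel$I, panel$J) +
    matrix(state$gamma, panel$I, panel$J, byrow = TRUE) +
    state$nu
  lik <- sum(ifelse(panel$n > 0,
                    panel$Y * eta - panel$n * log1p(exp(pmin(eta, 700))), 0))
  qf_phi <- effect_quadform(state$phi, "car", graph)
  qf_gam <- effect_quadform(state$gamma, "rw1")
  pri <- -state$tau_phi / 2 * qf_phi$q -
    state$tau_gamma / 2 * qf_gam$q -
    state$tau_nu / 2 * sum(state$nu^2)
  lik + pri
}

#' One random-walk Metropolis sweep over a parameter block
#'
#' Reference (pure R) implementation of the sampler's location updates:
#' each scalar component of the block receives a Gaussian random-walk
#' proposal accepted with probability `min(1, exp(delta log-posterior))`.
#' After a `phi` or `gamma` sweep the block is recentred to sum to zero,
#' with the removed mean absorbed into `alpha` (which carries an
#' improper flat prior), leaving the linear predictor unchanged.
#'
#' @param state List with `alpha`, `phi`, `gamma`, `nu`, `tau_phi`,
#'   `tau_gamma`, `tau_nu`.
#' @param block One of `"alpha"`, `"phi"`, `"gamma"`, `"nu"`.
#' @param panel A [count_panel()].
#' @param graph A [build_adjacency()] graph.
#' @param proposal_sd Random-walk proposal standard deviation.
#' @return List with the updated `state` and the block `acceptance` rate.
#' @export
metropolis_update_block <- function(state, block, panel, graph, proposal_sd) {
  lp0 <- logpost_state(state, panel, graph)
  if (!is.finite(lp0)) {
    abort("metropolis_update_block(): non-finite log-posterior at state.",
          class = "nutrimap_sampler_fault")
  }
  acc <- 0L; tot <- 0L
  try_move <- function(new_state) {
    lp1 <- logpost_state(new_state, panel, graph)
    if (log(runif(1)) < lp1 - lp0) list(state = new_state, lp = lp1, acc = TRUE)
    else list(state = state, lp = lp0, acc = FALSE)
  }
  if (block == "alpha") {
    s2 <- state; s2$alpha <- state$alpha + rnorm(1, 0, proposal_sd)
    mv <- try_move(s2); state <- mv$state; lp0 <- mv$lp
    acc <- acc + mv$acc; tot <- tot + 1L
  } else if (block == "phi") {
    for (i in seq_len(panel$I)) {
      s2 <- state; s2$phi[i] <- state$phi[i] + rnorm(1, 0, proposal_sd)
      mv <- try_move(s2); state <- mv$state; lp0 <- mv$lp
      acc <- acc + mv$acc; tot <- tot + 1L
    }
    m <- mean(state$phi)
    state$phi <- state$phi - m
    state$alpha <- state$alpha + m
  } else if (block == "gamma") {
    for (j in seq_len(panel$J)) {
      s2 <- state; s2$gamma[j] <- state$gamma[j] + rnorm(1, 0, proposal_sd)
      mv <- try_move(s2); state <- mv$state; lp0 <- mv$lp
      acc <- acc + mv$acc; tot <- tot + 1L
    }
    m <- mean(state$gamma)
    state$gamma <- state$gamma - m
    state$alpha <- state$alpha + m
  } else if (block == "nu") {
    for (i in seq_len(panel$I)) for (j in seq_len(panel$J)) {
      s2 <- state; s2$nu[i, j] <- state$nu[i, j] + rnorm(1, 0, proposal_sd)
      mv <- try_move(s2); state <- mv$state; lp0 <- mv$lp
      acc <- acc + mv$acc; tot <- tot + 1L
    }
  } else {
    abort("Unknown block.", class = "nutrimap_model_error")
  }
  list(state = state, acceptance = acc / tot)
}

#' MCMC configuration for the space-time model
#'
#' @param n_chains Number of chains (default 2).
#' @param burn_in Burn-in iterations per chain (default 10000), during
#'   which proposal scales adapt towards a ~44% acceptance rate.
#' @param n_keep Post-burn-in draws retained per chain per run segment.
#' @param thin Thinning interval (default 10).
#' @param seed Integer seed; chain c uses `seed + 1000 * c`.
#' @param proposal_sds Named initial random-walk proposal SDs for the
#'   `alpha`, `phi`, `gamma`, `nu` blocks.
#' @param adapt Adapt proposal scales during burn-in only (default TRUE;
#'   adaptation is frozen afterwards to preserve ergodicity).
#' @param hyper_shape,hyper_rate Gamma hyperprior on the three
#'   precisions (defaults 0.5 and 0.0005).
#' @param rhat_limit Gelman-Rubin convergence threshold (default 1.1).
#' @param mc_error_frac Required Monte Carlo error as a fraction of the
#'   posterior SD for every monitored parameter (default 0.05).
#' @param max_iter Cap on total post-burn-in iterations per chain before
#'   the fit is flagged non-converged (default 200000).
#' @param components Model components to include; the full model uses
#'   all of `"spatial"`, `"temporal"`, `"interaction"`.
#' @return List of class `mcmc_config`.
#' @export
mcmc_config <- function(n_chains = 2, burn_in = 10000, n_keep = 10000,
                        thin = 10, seed = 1,
                        proposal_sds = c(alpha = 0.05, phi = 0.3,
                                         gamma = 0.1, nu = 0.5),
                        adapt = TRUE, hyper_shape = 0.5, hyper_rate = 0.0005,
                        rhat_limit = 1.1, mc_error_frac = 0.05,
                        max_iter = 200000,
                        components = c("spatial", "temporal", "interaction")) {
  stopifnot(burn_in > 0, n_keep > 0, thin >= 1, n_chains >= 1,
            hyper_shape > 0, hyper_rate > 0)
  structure(list(n_chains = n_chains, burn_in = burn_in, n_keep = n_keep,
                 thin = thin, seed = seed, proposal_sds = proposal_sds,
                 adapt = adapt, hyper_shape = hyper_shape,
                 hyper_rate = hyper_rate, rhat_limit = rhat_limit,
                 mc_error_frac = mc_error_frac, max_iter = max_iter,
                 components = components),
            class = "mcmc_config")
}

run_chain_segment <- function(panel, graph, config, state, n_iter, thin,
                              adapt, prop_sd, rank_phi, use, save = TRUE) {
  car_st_mcmc_cpp(panel$Y, panel$n, lapply(graph$nb, function(v) v - 1L),
                  n_iter, thin, state$alpha, state$phi, state$gamma,
                  state$nu, state$tau_phi, state$tau_gamma, state$tau_nu,
                  prop_sd, adapt, config$hyper_shape, config$hyper_rate,
                  rank_phi, use[["spatial"]], use[["temporal"]],
                  use[["interaction"]], save)
}

#' Fit the Bayesian binomial space-time model
#'
#' Runs `n_chains` Metropolis-within-Gibbs chains with overdispersed
#' starting values, discards the burn-in (during which proposal scales
#' adapt), and keeps thinned draws of the monitored parameters: the
#' intercept `alpha`, the three precisions, and every district-wave
#' prevalence `pi`. After the initial run, sampling is extended in
#' segments until the Gelman-Rubin statistic is below `rhat_limit` and
#' the batch-means Monte Carlo error of every monitored parameter is
#' below `mc_error_frac` of its posterior SD, or the iteration cap is
#' reached -- in which case the fit is returned flagged
#' `converged = FALSE` rather than failing silently.
#'
#' @param panel A [count_panel()].
#' @param graph A [build_adjacency()] graph with `n_nodes == panel$I`.
#' @param config An [mcmc_config()].
#' @return An object of class `car_st_fit`: list with `draws` (per
#'   chain: `pi` draws matrix with `I*J` columns in column-major
#'   district-within-wave order, `alpha`, `tau_phi`, `tau_gamma`,
#'   `tau_nu`), `summary` (per-cell posterior median and 95% credibility
#'   interval), `diagnostics` (mean, SD, MC error, Rhat per monitored
#'   parameter), `dic`, `pD`, `acceptance`, `converged`, plus the inputs.
#' @export
fit_spacetime <- function(panel, graph, config = mcmc_config()) {
  stopifnot(inherits(panel, "count_panel"), inherits(graph, "district_graph"))
  if (panel$I != graph$n_nodes) {
    abort("fit_spacetime(): panel and graph disagree on the number of districts.",
          class = "nutrimap_model_error")
  }
  if (panel$I < 2 || panel$J < 2) {
    abort("fit_spacetime(): need at least 2 districts and 2 waves (CAR/RW1 undefined).",
          class = "nutrimap_model_error")
  }
  use <- c(spatial = "spatial" %in% config$components,
           temporal = "temporal" %in% config$components,
           interaction = "interaction" %in% config$components)
  qf0 <- effect_quadform(rep(0, panel$I), "car", graph)
  rank_phi <- qf0$rank

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)

  p_obs <- sum(panel$Y) / max(sum(panel$n), 1)
  p_obs <- min(max(p_obs, 0.01), 0.99)

  chains <- vector("list", config$n_chains)
  acc <- NULL
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + 1000L * ch)
    # overdispersed starting values
    state <- list(
      alpha = qlogis(p_obs) + rnorm(1, 0, 1),
      phi = if (use["spatial"]) rnorm(panel$I, 0, 0.2) else rep(0, panel$I),
      gamma = if (use["temporal"]) rnorm(panel$J, 0, 0.2) else rep(0, panel$J),
      nu = if (use["interaction"]) matrix(rnorm(panel$I * panel$J, 0, 0.2),
                                          panel$I, panel$J)
           else matrix(0, panel$I, panel$J),
      tau_phi = exp(runif(1, 0, 4)), tau_gamma = exp(runif(1, 0, 4)),
      tau_nu = exp(runif(1, 0, 4)))
    state$phi <- state$phi - mean(state$phi)
    state$gamma <- state$gamma - mean(state$gamma)
    prop_sd <- as.numeric(config$proposal_sds[c("alpha", "phi", "gamma", "nu")])
    # burn-in (adaptive)
    seg <- run_chain_segment(panel, graph, config, state, config$burn_in,
                             config$burn_in, config$adapt, prop_sd,
                             rank_phi, use, save = FALSE)
    state <- seg$state
    prop_sd <- seg$prop_sd
    # sampling (adaptation frozen)
    seg <- run_chain_segment(panel, graph, config, state,
                             config$n_keep * config$thin, config$thin,
                             FALSE, prop_sd, rank_phi, use)
    chains[[ch]] <- list(pi = seg$pi, alpha = seg$alpha,
                         tau_phi = seg$tau_phi, tau_gamma = seg$tau_gamma,
                         tau_nu = seg$tau_nu, state = seg$state,
                         prop_sd = seg$prop_sd)
    acc <- rbind(acc, seg$acc_rate)
  }

  total_iter <- config$n_keep * config$thin
  repeat {
    diag_tbl <- fit_diagnostics(chains, panel, config)
    ok <- all(diag_tbl$rhat < config$rhat_limit, na.rm = TRUE) &&
      all(diag_tbl$mc_error <= config$mc_error_frac * diag_tbl$sd |
            diag_tbl$sd < 1e-12, na.rm = TRUE)
    if (ok || total_iter >= config$max_iter) break
    # extend every chain by another segment
    for (ch in seq_len(config$n_chains)) {
      set.seed(config$seed + 1000L * ch + total_iter)
      seg <- run_chain_segment(panel, graph, config, chains[[ch]]$state,
                               config$n_keep * config$thin, config$thin,
                               FALSE, chains[[ch]]$prop_sd, rank_phi, use)
      chains[[ch]]$pi <- rbind(chains[[ch]]$pi, seg$pi)
      chains[[ch]]$alpha <- c(chains[[ch]]$alpha, seg$alpha)
      chains[[ch]]$tau_phi <- c(chains[[ch]]$tau_phi, seg$tau_phi)
      chains[[ch]]$tau_gamma <- c(chains[[ch]]$tau_gamma, seg$tau_gamma)
      chains[[ch]]$tau_nu <- c(chains[[ch]]$tau_nu, seg$tau_nu)
      chains[[ch]]$state <- seg$state
    }
    total_iter <- total_iter + config$n_keep * config$thin
  }
  converged <- ok
  if (!converged) {
    warn("fit_spacetime(): iteration cap reached before convergence criteria; fit flagged non-converged.")
  }

  pooled <- do.call(rbind, lapply(chains, `[[`, "pi"))
  cell_q <- apply(pooled, 2, quantile, probs = c(0.5, 0.025, 0.975),
                  names = FALSE)
  summary_tbl <- tibble::tibble(
    outcome = panel$outcome,
    district_id = rep(seq_len(panel$I), times = panel$J),
    wave = rep(seq_len(panel$J), each = panel$I),
    median = cell_q[1, ], bci_low = cell_q[2, ], bci_high = cell_q[3, ],
    mean = colMeans(pooled),
    sd = apply(pooled, 2, sd),
    n = as.vector(panel$n), Y = as.vector(panel$Y))

  dic_res <- dic_from_chains(chains, panel)
  fit <- structure(
    list(draws = chains, summary = summary_tbl, diagnostics = diag_tbl,
         dic = dic_res$dic, pD = dic_res$pD,
         acceptance = colMeans(acc), converged = converged,
         total_iter = total_iter, panel = panel, graph = graph,
         config = config),
    class = "car_st_fit")
  fit
}

# monitored-parameter diagnostics: alpha, taus, all pi cells
fit_diagnostics <- function(chains, panel, config) {
  monitors <- c(list(alpha = lapply(chains, `[[`, "alpha"),
                     tau_phi = lapply(chains, `[[`, "tau_phi"),
                     tau_gamma = lapply(chains, `[[`, "tau_gamma"),
                     tau_nu = lapply(chains, `[[`, "tau_nu")))
  IJ <- panel$I * panel$J
  pi_names <- sprintf("pi[%d,%d]", rep(seq_len(panel$I), times = panel$J),
                      rep(seq_len(panel$J), each = panel$I))
  rows <- vector("list", 4 + IJ)
  k <- 0L
  for (nm in names(monitors)) {
    k <- k + 1L
    rows[[k]] <- diag_row(nm, monitors[[nm]])
  }
  for (c_ in seq_len(IJ)) {
    k <- k + 1L
    rows[[k]] <- diag_row(pi_names[c_],
                          lapply(chains, function(ch) ch$pi[, c_]))
  }
  dplyr::bind_rows(rows)
}

diag_row <- function(name, chain_list) {
  pooled <- unlist(chain_list, use.names = FALSE)
  rh <- if (length(chain_list) >= 2) gelman_rubin(chain_list) else NA_real_
  # MC error of the pooled posterior-mean estimate: per-chain batch-means
  # SEs combined as the SE of the average of independent chain means
  ses <- vapply(chain_list, function(ch)
    tryCatch(mc_error(ch), error = function(e) NA_real_), 0)
  mce <- sqrt(sum(ses^2)) / length(ses)
  tibble::tibble(parameter = name, mean = mean(pooled), sd = sd(pooled),
                 mc_error = mce, rhat = rh)
}

#' @export
print.car_st_fit <- function(x, ...) {
  cat(sprintf(
    "car_st_fit '%s': %d districts x %d waves, %d chains x %d draws\n",
    x$panel$outcome, x$panel$I, x$panel$J, length(x$draws),
    nrow(x$draws[[1]]$pi)))
  cat(sprintf("  DIC %.1f (pD %.1f); converged: %s; max Rhat %.3f\n",
              x$dic, x$pD, x$converged, max(x$diagnostics$rhat, na.rm = TRUE)))
  invisible(x)
}

# pooled posterior draws of pi for one district (all waves) or one cell
pi_draws <- function(fit, district, wave = NULL) {
  I <- fit$panel$I
  pooled <- do.call(rbind, lapply(fit$draws, `[[`, "pi"))
  if (is.null(wave)) {
    pooled[, (seq_len(fit$panel$J) - 1) * I + district, drop = FALSE]
  } else {
    pooled[, (wave - 1) * I + district]
  }
}
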