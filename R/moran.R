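# Moran's I spatial autocorrelation with row-standardized weights
# (w_ij = 1/m_i over the neighbours of i), the convention of standard
# geospatial screening tools. Isolated nodes are excluded from the
# statistic's sums but remain part of the graph.

moran_core <- function(zx, zy, graph) {
  act <- setdiff(seq_len(graph$n_nodes), graph$isolated)
  n <- length(act)
  sw <- n  # each active row of the row-standardized weight matrix sums to 1
  num <- 0
  for (i in act) {
    num <- num + zx[i] * mean(zy[graph$nb[[i]]])
  }
  list(n = n, sw = sw, num = num, act = act)
}

#' Moran's I spatial autocorrelation
#'
#' \eqn{I = (n / \sum_{ij} w_{ij}) \sum_{ij} w_{ij} z_i z_j / \sum_i
#' z_i^2} with centred values \eqn{z} and row-standardized weights. The
#' statistic is invariant to affine transforms of the values.
#'
#' @param values Numeric vector, one value per graph node.
#' @param graph A [build_adjacency()] graph.
#' @return Scalar Moran's I.
#' @export
morans_i <- function(values, graph) {
  stopifnot(length(values) == graph$n_nodes)
  act <- setdiff(seq_len(graph$n_nodes), graph$isolated)
  z <- values - mean(values[act])
  if (sd(values[act]) == 0) {
    abort("morans_i(): values are constant; statistic undefined.",
          class = "nutrimap_constant_error")
  }
  mc <- moran_core(z, z, graph)
  (mc$n / mc$sw) * mc$num / sum(z[act]^2)
}

#' Bivariate Moran's I between two variables
#'
#' \eqn{I_{xy} = (n/\sum w) \sum_{ij} w_{ij} z^{(x)}_i z^{(y)}_j /
#' \sqrt{\sum_i z^{(x)2}_i \sum_i z^{(y)2}_i}}: the spatial
#' cross-correlation between `x` at a node and `y` at its neighbours.
#' With `y = x` it reduces to the univariate [morans_i()].
#'
#' @param x,y Numeric vectors, one value per node.
#' @inheritParams morans_i
#' @return Scalar bivariate Moran's I.
#' @export
bivariate_morans_i <- function(x, y, graph) {
  stopifnot(length(x) == graph$n_nodes, length(y) == graph$n_nodes)
  act <- setdiff(seq_len(graph$n_nodes), graph$isolated)
  if (sd(x[act]) == 0 || sd(y[act]) == 0) {
    abort("bivariate_morans_i(): constant input; statistic undefined.",
          class = "nutrimap_constant_error")
  }
  zx <- x - mean(x[act])
  zy <- y - mean(y[act])
  mc <- moran_core(zx, zy, graph)
  (mc$n / mc$sw) * mc$num / sqrt(sum(zx[act]^2) * sum(zy[act]^2))
}

#' Permutation pseudo p-value for a spatial statistic
#'
#' Two-sided permutation inference: node values are randomly permuted
#' `n_perm` times and the pseudo p-value is \eqn{(1 + \#\{|I_{perm}|
#' \ge |I_{obs}|\}) / (n_{perm} + 1)}. Seeded and reproducible.
#'
#' @param stat_fn Function `(values, graph) -> scalar`, e.g. [morans_i()],
#'   or a wrapper around [bivariate_morans_i()] that permutes one margin.
#' @param values Numeric vector passed to `stat_fn`.
#' @param graph A [build_adjacency()] graph.
#' @param n_perm Number of permutations (>= 99).
#' @param seed Integer RNG seed (mandatory, for reproducibility).
#' @return Tibble with `observed`, `p_value`, `n_perm`.
#' @export
permutation_pvalue <- function(stat_fn, values, graph, n_perm = 999, seed) {
  stopifnot(n_perm >= 99, !missing(seed))
  obs <- stat_fn(values, graph)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  exceed <- 0L
  for (b in seq_len(n_perm)) {
    ip <- abs(stat_fn(sample(values), graph))
    if (ip >= abs(obs)) exceed <- exceed + 1L
  }
  tibble::tibble(observed = obs, p_value = (1 + exceed) / (n_perm + 1),
                 n_perm = n_perm)
}

# save/restore the global RNG state so seeded helpers do not disturb
# the caller's stream
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Moran screening report for the three malnutrition outcomes
#'
#' Univariate Moran's I (with permutation p-values) for each outcome's
#' district-level prevalence at a given wave, plus bivariate Moran's I
#' for each outcome pair: the pre-modelling screen used to decide
#' whether outcomes share spatial structure or warrant separate models.
#'
#' @param prev_matrix Numeric matrix, districts x outcomes (columns
#'   named by outcome).
#' @param graph A [build_adjacency()] graph.
#' @param n_perm Permutations for the pseudo p-values.
#' @param seed Integer seed.
#' @return Tibble with `type` ("univariate"/"bivariate"), `var_x`,
#'   `var_y`, `moran_i`, `p_value`.
#' @export
moran_screen <- function(prev_matrix, graph, n_perm = 999, seed) {
  prev_matrix <- as.matrix(prev_matrix)
  outs <- colnames(prev_matrix)
  if (is.null(outs)) outs <- paste0("outcome", seq_len(ncol(prev_matrix)))
  rows <- list()
  for (k in seq_along(outs)) {
    pp <- permutation_pvalue(morans_i, prev_matrix[, k], graph,
                             n_perm = n_perm, seed = seed + k)
    rows[[length(rows) + 1L]] <- tibble::tibble(
      type = "univariate", var_x = outs[k], var_y = outs[k],
      moran_i = pp$observed, p_value = pp$p_value)
  }
  if (length(outs) > 1) {
    for (k in seq_along(outs)) for (l in seq_along(outs)) {
      if (l <= k) next
      yfix <- prev_matrix[, l]
      stat <- function(v, g) bivariate_morans_i(v, yfix, g)
      pp <- permutation_pvalue(stat, prev_matrix[, k], graph,
                               n_perm = n_perm, seed = seed + 100 + 10 * k + l)
      rows[[length(rows) + 1L]] <- tibble::tibble(
        type = "bivariate", var_x = outs[k], var_y = outs[l],
        moran_i = pp$observed, p_value = pp$p_value)
    }
  }
  dplyr::bind_rows(rows)
}
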