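# Independent oracle implementations used to cross-check the package.
# These are deliberately written as naive loops over the textbook
# formulas, sharing no code with the implementations they verify.

# row-standardized weight matrix of a district_graph
oracle_weight_matrix <- function(graph) {
  n <- graph$n_nodes
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    nb <- graph$nb[[i]]
    if (length(nb)) W[i, nb] <- 1 / length(nb)
  }
  W
}

# naive O(n^2) Moran's I (univariate when y missing)
oracle_moran <- function(x, graph, y = NULL) {
  act <- setdiff(seq_len(graph$n_nodes), graph$isolated)
  W <- oracle_weight_matrix(graph)
  zx <- x - mean(x[act])
  zy <- if (is.null(y)) zx else y - mean(y[act])
  num <- 0; S0 <- 0
  for (i in act) for (j in act) {
    num <- num + W[i, j] * zx[i] * zy[j]
    S0 <- S0 + W[i, j]
  }
  den <- if (is.null(y)) sum(zx[act]^2) else
    sqrt(sum(zx[act]^2) * sum(zy[act]^2))
  (length(act) / S0) * num / den
}

# textbook stratified-cluster Taylor-linearization SE of a weighted
# proportion
oracle_prevalence_se <- function(y, w, stratum, psu) {
  p <- sum(w * y) / sum(w)
  W <- sum(w)
  v <- 0
  for (h in unique(stratum)) {
    in_h <- stratum == h
    psus <- unique(psu[in_h])
    nh <- length(psus)
    if (nh < 2) next
    zk <- sapply(psus, function(k) {
      idx <- in_h & psu == k
      sum(w[idx] * (y[idx] - p)) / W
    })
    v <- v + nh / (nh - 1) * sum((zk - mean(zk))^2)
  }
  sqrt(v)
}

# independently coded Rao-Scott second-order corrected test
oracle_rao_scott <- function(r, c_, w, stratum, psu) {
  rl <- sort(unique(r)); cl <- sort(unique(c_))
  R <- length(rl); C <- length(cl); RC <- R * C
  n <- length(r)
  W <- sum(w)
  p <- numeric(RC)
  for (a in seq_len(RC)) {
    ra <- rl[(a - 1) %/% C + 1]; ca <- cl[(a - 1) %% C + 1]
    p[a] <- sum(w[r == ra & c_ == ca]) / W
  }
  prow <- sapply(rl, function(x) sum(p[((match(x, rl) - 1) * C + 1):(match(x, rl) * C)]))
  pcol <- sapply(seq_len(C), function(j) sum(p[seq(j, RC, by = C)]))
  X2 <- 0
  for (a in seq_len(RC)) {
    p0 <- prow[(a - 1) %/% C + 1] * pcol[(a - 1) %% C + 1]
    X2 <- X2 + n * (p[a] - p0)^2 / p0
  }
  # linearized covariance of cell proportions, cluster totals by hand
  V <- matrix(0, RC, RC)
  n_psu <- 0
  for (h in unique(stratum)) {
    psus <- unique(psu[stratum == h])
    n_psu <- n_psu + length(psus)
    nh <- length(psus)
    if (nh < 2) next
    zmat <- sapply(psus, function(k) {
      idx <- stratum == h & psu == k
      u <- numeric(RC)
      for (a in seq_len(RC)) {
        ra <- rl[(a - 1) %/% C + 1]; ca <- cl[(a - 1) %% C + 1]
        del <- as.numeric(r[idx] == ra & c_[idx] == ca)
        u[a] <- sum(w[idx] * (del - p[a])) / W
      }
      u
    })
    zc <- zmat - rowMeans(zmat)
    V <- V + nh / (nh - 1) * zc %*% t(zc)
  }
  V0 <- (diag(p) - p %*% t(p)) / n
  H <- matrix(0, RC, RC)
  for (a in seq_len(RC)) for (b in seq_len(RC)) {
    ra <- (a - 1) %/% C + 1; ca <- (a - 1) %% C + 1
    rb <- (b - 1) %/% C + 1; cb <- (b - 1) %% C + 1
    H[a, b] <- (a == b) - (ra == rb) * pcol[ca] - (ca == cb) * prow[ra]
  }
  d <- (R - 1) * (C - 1)
  ev <- sort(Re(eigen(MASS::ginv(H %*% V0 %*% t(H)) %*% (H %*% V %*% t(H)),
                      only.values = TRUE)$values), decreasing = TRUE)[1:d]
  ev <- pmax(ev, 0)
  db <- mean(ev)
  a2 <- sum((ev - db)^2) / (d * db^2)
  nu <- d / (1 + a2)
  Fs <- X2 / (db * (1 + a2)) / nu
  ddf <- nu * (n_psu - length(unique(stratum)))
  list(statistic = Fs, p_value = pf(Fs, nu, ddf, lower.tail = FALSE),
       chisq = X2)
}

# joint log-density of the intrinsic CAR pairwise-difference prior,
# including the exchangeable term for isolated nodes
oracle_car_logdens <- function(phi, graph, tau) {
  s <- 0
  for (i in seq_len(graph$n_nodes)) {
    nb <- graph$nb[[i]]
    if (!length(nb)) { s <- s - tau / 2 * phi[i]^2; next }
    for (j in nb) if (j > i) s <- s - tau / 2 * (phi[i] - phi[j])^2
  }
  s
}

# RW1 joint log-density (up to a constant)
oracle_rw1_logdens <- function(gamma, tau) {
  -tau / 2 * sum(diff(gamma)^2)
}

# Gelman-Rubin computed by a separate algebraic route
oracle_gelman_rubin <- function(chains) {
  m <- length(chains); N <- length(chains[[1]])
  means <- sapply(chains, mean)
  W <- sum(sapply(chains, function(ch) sum((ch - mean(ch))^2))) / (m * (N - 1))
  B <- N / (m - 1) * sum((means - mean(means))^2)
  sqrt(((N - 1) / N * W + B / N) / W)
}

# a small clustered survey fixture with two strata
make_clustered_fixture <- function(seed = 42, n_per_psu = 25) {
  set.seed(seed)
  d <- expand.grid(stratum_id = c("s1", "s2"), psu_id_num = 1:4,
                   rec = seq_len(n_per_psu))
  d$psu_id <- paste(d$stratum_id, d$psu_id_num, sep = "_")
  n <- nrow(d)
  d$design_weight <- exp(rnorm(n, 0, 0.4)) * 100
  cluster_eff <- rnorm(8)[match(d$psu_id, unique(d$psu_id))]
  d$y <- runif(n) < plogis(-1 + cluster_eff)
  d$grp <- sample(c("a", "b"), n, TRUE, c(0.5, 0.5))
  tibble::as_tibble(d)
}

# grid-quadrature posterior for the 2-district spatial-only toy model,
# with the precision integrated out analytically under Gamma(a, b)
oracle_toy_quadrature <- function(Y, n, a = 0.5, b = 5e-4,
                                  A = seq(-4, 1, length.out = 500),
                                  d = seq(-2, 2, length.out = 4001)) {
  Y1 <- sum(Y[1, ]); n1 <- sum(n[1, ])
  Y2 <- sum(Y[2, ]); n2 <- sum(n[2, ])
  grid <- expand.grid(A = A, d = d)
  u1 <- grid$A + grid$d; u2 <- grid$A - grid$d
  ll <- Y1 * u1 - n1 * log1p(exp(u1)) + Y2 * u2 - n2 * log1p(exp(u2))
  lp <- ll - (a + 0.5) * log(b + 2 * grid$d^2)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  c(p1 = sum(w * plogis(u1)), p2 = sum(w * plogis(u2)))
}
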