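# Independent literal-formula oracles used to validate the implementation.
# These deliberately use naive loops / enumeration, never the package's own
# code paths.

# P_i = 1 - sum_s (k_is / k_i)^2, literal double loop
pc_oracle <- function(W, comm) {
  n <- nrow(W)
  sapply(seq_len(n), function(i) {
    ki <- sum(W[i, ])
    if (ki == 0) return(0)
    s <- 0
    for (g in unique(comm)) s <- s + (sum(W[i, comm == g]) / ki)^2
    1 - s
  })
}

# z_i against own-module mean and population SD of within-module strength
mdz_oracle <- function(W, comm) {
  n <- nrow(W)
  within <- sapply(seq_len(n), function(i) sum(W[i, comm == comm[i]]))
  z <- numeric(n)
  for (g in unique(comm)) {
    idx <- which(comm == g)
    if (length(idx) < 2) next
    mu <- mean(within[idx])
    sig <- sqrt(sum((within[idx] - mu)^2) / length(idx))
    if (sig > 0) z[idx] <- (within[idx] - mu) / sig
  }
  z
}

# Q = (1/2m) sum_ij [w_ij - gamma k_i k_j / 2m] delta(c_i, c_j), literal
modularity_oracle <- function(W, comm, gamma = 1) {
  m2 <- sum(W)
  k <- rowSums(W)
  q <- 0
  for (i in seq_len(nrow(W))) for (j in seq_len(nrow(W)))
    if (comm[i] == comm[j]) q <- q + W[i, j] - gamma * k[i] * k[j] / m2
  q / m2
}

# AMI with E[MI] by literal hypergeometric summation via lchoose
ami_oracle <- function(u, v) {
  tab <- table(u, v)
  N <- sum(tab)
  a <- rowSums(tab); b <- colSums(tab)
  ent <- function(p) { p <- p[p > 0]; -sum(p * log(p)) }
  mi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    nij <- tab[i, j]
    if (nij > 0) mi <- mi + nij / N * log(N * nij / (a[i] * b[j]))
  }
  emi <- 0
  for (i in seq_along(a)) for (j in seq_along(b)) {
    for (nij in max(1, a[i] + b[j] - N):min(a[i], b[j])) {
      if (nij < max(1, a[i] + b[j] - N)) next
      lp <- lchoose(b[j], nij) + lchoose(N - b[j], a[i] - nij) - lchoose(N, a[i])
      emi <- emi + nij / N * log(N * nij / (a[i] * b[j])) * exp(lp)
    }
  }
  denom <- mean(c(ent(a / N), ent(b / N))) - emi
  if (abs(denom) < 1e-12) return(0)
  as.numeric((mi - emi) / denom)
}

# all set partitions of n elements as restricted-growth strings (rows)
enumerate_partitions <- function(n) {
  out <- list()
  rec <- function(prefix, mx) {
    if (length(prefix) == n) { out[[length(out) + 1]] <<- prefix; return() }
    for (g in seq_len(mx + 1)) rec(c(prefix, g), max(mx, g))
  }
  rec(integer(0), 0L)
  do.call(rbind, out)
}

# exhaustive modularity maximum over all partitions (n <= 8)
exhaustive_best_q <- function(W, gamma = 1) {
  parts <- enumerate_partitions(nrow(W))
  max(apply(parts, 1, function(p) modularity_oracle(W, p, gamma)))
}

# random symmetric nonnegative weighted graph with zero diagonal
random_graph <- function(n, density = 0.5) {
  W <- matrix(0, n, n)
  up <- upper.tri(W)
  w <- ifelse(runif(sum(up)) < density, runif(sum(up)), 0)
  W[up] <- w
  W <- W + t(W)
  W
}

# 2-parameter logistic MLE by iterated grid refinement (independent of glm)
logistic_grid_mle <- function(y, x, b0_range = c(-10, 10), b1_range = c(-10, 10),
                              rounds = 8, grid_n = 41) {
  negll <- function(b0, b1) {
    eta <- b0 + b1 * x
    softplus <- ifelse(eta > 30, eta, log1p(exp(eta)))
    -sum(y * eta - softplus)
  }
  ctr <- c(mean(b0_range), mean(b1_range))
  half <- c(diff(b0_range) / 2, diff(b1_range) / 2)
  for (r in seq_len(rounds)) {
    g0 <- seq(ctr[1] - half[1], ctr[1] + half[1], length.out = grid_n)
    g1 <- seq(ctr[2] - half[2], ctr[2] + half[2], length.out = grid_n)
    vals <- outer(g0, g1, Vectorize(negll))
    ix <- which(vals == min(vals), arr.ind = TRUE)[1, ]
    ctr <- c(g0[ix[1]], g1[ix[2]])
    half <- half * 2.5 / (grid_n - 1)
  }
  list(coef = ctr, loglik = -negll(ctr[1], ctr[2]))
}

# quick planted 4-block weighted SBM adjacency on n nodes
sbm_graph <- function(n = 80, blocks = 4, p_in = 0.9, p_out = 0.1,
                      w_in = 1, w_out = 0.3) {
  lab <- rep(seq_len(blocks), length.out = n)
  W <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    same <- lab[i] == lab[j]
    if (runif(1) < (if (same) p_in else p_out))
      W[i, j] <- W[j, i] <- if (same) w_in else w_out
  }
  list(W = W, labels = lab)
}
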