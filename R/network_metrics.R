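check_adjacency <- function(W) {
  if (!is.matrix(W) || nrow(W) != ncol(W))
    stop("W must be a square matrix", call. = FALSE)
  if (any(!is.finite(W)))
    stop("W contains non-finite weights", call. = FALSE)
  if (any(W < 0))
    stop("W contains negative weights; apply positive_part() first", call. = FALSE)
  if (max(abs(W - t(W))) > 1e-10)
    stop("W must be symmetric", call. = FALSE)
  invisible(W)
}

check_partition <- function(c, n) {
  c <- as.integer(c)
  if (length(c) != n) stop("partition length does not match node count", call. = FALSE)
  if (anyNA(c)) stop("partition contains NA assignments", call. = FALSE)
  c
}

#' Participation coefficient on a positive weighted graph
#'
#' For node i with total positive strength \eqn{\kappa_i} and strength
#' \eqn{\kappa_{is}} into community s, the participation coefficient is
#' \eqn{P_i = 1 - \sum_s (\kappa_{is}/\kappa_i)^2} (Guimera-Amaral). A node
#' with all strength inside its own community scores 0; a node spreading
#' strength evenly over M communities scores \eqn{1 - 1/M}. Isolated nodes
#' (zero strength) score 0 by convention.
#'
#' @param W nonnegative symmetric weighted adjacency matrix, zero diagonal.
#' @param community integer community label per node.
#' @return numeric vector of participation coefficients, one per node.
#' @export
participation_coefficient <- function(W, community) {
  check_adjacency(W)
  n <- nrow(W)
  comm <- check_partition(community, n)
  k <- rowSums(W)
  M <- outer(comm, sort(unique(comm)), "==") + 0   # n x C indicator
  Ks <- W %*% M                                    # strength into each community
  pc <- 1 - rowSums((Ks / ifelse(k > 0, k, 1))^2)
  pc[k == 0] <- 0
  as.numeric(pc)
}

#' Within-module degree z-score
#'
#' Standardizes each node's within-community strength against the mean and
#' population (divide-by-n) standard deviation of within-community strength
#' over the nodes of its own community. Nodes in singleton communities, or
#' communities where the spread is zero, score 0.
#'
#' @inheritParams participation_coefficient
#' @return numeric vector of module-degree z-scores, one per node.
#' @export
module_degree_zscore <- function(W, community) {
  check_adjacency(W)
  n <- nrow(W)
  comm <- check_partition(community, n)
  M <- outer(comm, sort(unique(comm)), "==") + 0
  Ks <- W %*% M
  within <- Ks[cbind(seq_len(n), match(comm, sort(unique(comm))))]
  z <- numeric(n)
  for (g in unique(comm)) {
    idx <- which(comm == g)
    if (length(idx) < 2) next
    mu <- mean(within[idx])
    sig <- sqrt(mean((within[idx] - mu)^2))
    if (sig > 0) z[idx] <- (within[idx] - mu) / sig
  }
  z
}

#' Newman-Girvan modularity of a partition
#'
#' \eqn{Q = \frac{1}{2m}\sum_{ij}\left[w_{ij} - \gamma \frac{k_i k_j}{2m}\right]
#' \delta(c_i, c_j)} with \eqn{2m = \sum_{ij} w_{ij}} and resolution
#' \eqn{\gamma}. The null-model term includes the i = j pairs, so a single
#' all-encompassing community scores exactly 0 at \eqn{\gamma = 1}.
#'
#' @inheritParams participation_coefficient
#' @param gamma resolution parameter (default 1).
#' @return modularity value.
#' @export
modularity_q <- function(W, community, gamma = 1) {
  check_adjacency(W)
  n <- nrow(W)
  comm <- check_partition(community, n)
  m2 <- sum(W)
  if (m2 <= 0) stop("total edge weight is zero; modularity undefined", call. = FALSE)
  k <- rowSums(W)
  win <- sum(W * outer(comm, comm, "=="))
  null <- sum(tapply(k, comm, sum)^2) / m2
  (win - gamma * null) / m2
}

louvain_local_move <- function(W, gamma, comm) {
  # one round of local moving on the (possibly aggregated) graph W, whose
  # diagonal carries self-loop weight; returns updated labels + move count
  n <- nrow(W)
  m2 <- sum(W)
  k <- rowSums(W)
  tot <- as.numeric(rowsum(k, comm)[as.character(sort(unique(comm))), ])
  names(tot) <- sort(unique(comm))
  moved <- 0L
  for (i in sample.int(n)) {
    ci <- as.character(comm[i])
    wi <- W[i, ]
    wi[i] <- 0
    links <- rowsum(wi, comm)
    link_comms <- rownames(links)
    tot[ci] <- tot[ci] - k[i]
    gain0 <- (if (ci %in% link_comms) links[ci, 1] else 0) - gamma * k[i] * tot[ci] / m2
    # first strictly improving candidate in shuffled order
    cand <- setdiff(link_comms[links[, 1] > 0], ci)
    if (length(cand) > 1) cand <- cand[sample.int(length(cand))]
    new_c <- ci
    for (cc in cand) {
      gain <- links[cc, 1] - gamma * k[i] * tot[cc] / m2
      if (gain > gain0 + 1e-12) { new_c <- cc; break }
    }
    tot[new_c] <- tot[new_c] + k[i]
    if (new_c != ci) {
      comm[i] <- as.integer(new_c)
      moved <- moved + 1L
    }
  }
  list(comm = comm, moved = moved)
}

#' Weighted Louvain community detection
#'
#' Two-phase modularity maximization: repeated single-node moves (visiting
#' nodes in an order shuffled by `seed`, accepting the first strictly
#' improving move), then aggregation of communities into super-nodes with
#' self-loops, iterated until a full pass makes no improving move.
#' Modularity is non-decreasing across passes and the result is
#' deterministic given the seed.
#'
#' @param W nonnegative symmetric weighted adjacency, zero diagonal, at
#'   least one positive edge.
#' @param gamma resolution parameter (default 1, as used for the per-subject
#'   partitions).
#' @param seed integer seed controlling the node visiting order.
#' @return list with `partition` (integer labels, contiguous from 1), `q`
#'   (modularity of the returned partition), `n_communities`, `gamma`,
#'   `seed`, `n_passes` (number of aggregation levels run).
#' @export
louvain <- function(W, gamma = 1, seed = 1L) {
  check_adjacency(W)
  if (sum(W) <= 0) stop("W has no positive edge; Louvain undefined", call. = FALSE)
  n <- nrow(W)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(as.integer(seed))

  Wl <- W
  membership <- seq_len(n)  # original node -> current super-node
  n_passes <- 0L
  repeat {
    comm <- seq_len(nrow(Wl))
    total_moves <- 0L
    repeat {
      st <- louvain_local_move(Wl, gamma, comm)
      comm <- st$comm
      total_moves <- total_moves + st$moved
      if (st$moved == 0L) break
    }
    if (total_moves == 0L && n_passes > 0L) break
    n_passes <- n_passes + 1L
    relab <- match(comm, sort(unique(comm)))
    membership <- relab[membership]
    nc <- max(relab)
    if (nc == nrow(Wl) && total_moves == 0L) break
    # aggregate: W2[a, b] = total weight between communities a and b
    Ind <- outer(relab, seq_len(nc), "==") + 0
    Wl <- t(Ind) %*% Wl %*% Ind
    if (nc == 1L) break
  }
  partition <- match(membership, sort(unique(membership)))
  list(partition = partition,
       q = modularity_q(W, partition, gamma),
       n_communities = max(partition),
       gamma = gamma, seed = as.integer(seed), n_passes = n_passes)
}

entropy_nat <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

#' Adjusted mutual information between two partitions
#'
#' Chance-corrected agreement: \eqn{AMI = (MI - E[MI]) / (\bar H - E[MI])}
#' where \eqn{E[MI]} is the expected mutual information under the
#' permutation (hypergeometric) model of Vinh et al. and \eqn{\bar H} is,
#' by default, the arithmetic mean of the two partition entropies
#' (`normalization = "max"` uses the larger entropy instead). Returns 0
#' when the denominator vanishes (e.g. one partition is a single cluster).
#'
#' @param u,v integer/factor label vectors over the same node set.
#' @param normalization `"mean"` (default) or `"max"`.
#' @return AMI value (1 for identical non-trivial partitions).
#' @export
adjusted_mutual_information <- function(u, v, normalization = c("mean", "max")) {
  normalization <- match.arg(normalization)
  if (length(u) != length(v))
    stop("partitions are over different node sets (lengths differ)", call. = FALSE)
  if (anyNA(u) || anyNA(v)) stop("partitions contain NA labels", call. = FALSE)
  tab <- table(u, v)
  N <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  Hu <- entropy_nat(a / N)
  Hv <- entropy_nat(b / N)
  nz <- which(tab > 0, arr.ind = TRUE)
  nij <- tab[nz]
  mi <- sum(nij / N * log(nij * N / (a[nz[, 1]] * b[nz[, 2]])))
  emi <- 0
  for (i in seq_along(a)) {
    for (j in seq_along(b)) {
      lo <- max(1, a[i] + b[j] - N)
      hi <- min(a[i], b[j])
      if (hi < lo) next
      nn <- lo:hi
      emi <- emi + sum(nn / N * log(N * nn / (a[i] * b[j])) *
                         stats::dhyper(nn, a[i], N - a[i], b[j]))
    }
  }
  denom <- switch(normalization, mean = mean(c(Hu, Hv)), max = max(Hu, Hv)) - emi
  if (abs(denom) < 1e-12) return(0)
  (mi - emi) / denom
}
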