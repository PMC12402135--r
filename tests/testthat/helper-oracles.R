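# Independent brute-force oracles used across test files. These deliberately
# avoid the package's implementation paths (and igraph where the package
# uses igraph).

oracle_betas <- function(x) {
  n <- ncol(x)
  b <- matrix(0, n, n)
  for (i in seq_len(n)) {
    z <- x[, -i, drop = FALSE]
    b[-i, i] <- solve(t(z) %*% z, t(z) %*% x[, i])
  }
  b
}

oracle_modularity <- function(a, part, gamma = 1) {
  a <- (a + t(a)) / 2
  a[a < 0] <- 0
  diag(a) <- 0
  m2 <- sum(a)
  if (m2 == 0) return(0)
  k <- rowSums(a)
  q <- 0
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(nrow(a))) {
      if (part[i] == part[j]) {
        q <- q + a[i, j] - gamma * k[i] * k[j] / m2
      }
    }
  }
  q / m2
}

# all-pairs shortest paths by explicit breadth-first search
oracle_bfs_distances <- function(a) {
  a <- ((a + t(a)) > 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  d <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    d[s, s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (w in which(a[v, ] == 1)) {
        if (is.infinite(d[s, w])) {
          d[s, w] <- d[s, v] + 1
          queue <- c(queue, w)
        }
      }
    }
  }
  d
}

oracle_node_metrics <- function(a, part) {
  a <- ((a + t(a)) > 0) * 1
  diag(a) <- 0
  n <- nrow(a)
  k <- wmd <- p <- cc <- numeric(n)
  for (i in seq_len(n)) {
    nb <- which(a[i, ] == 1)
    k[i] <- length(nb)
    wmd[i] <- sum(part[nb] == part[i])
    if (k[i] > 0) {
      acc <- 0
      for (m in unique(part)) acc <- acc + (sum(part[nb] == m) / k[i])^2
      p[i] <- 1 - acc
    }
    if (k[i] >= 2) {
      links <- 0
      for (u in nb) for (v in nb) if (u < v && a[u, v] == 1) links <- links + 1
      cc[i] <- 2 * links / (k[i] * (k[i] - 1))
    }
  }
  z <- numeric(n)
  for (m in unique(part)) {
    idx <- which(part == m)
    s <- stats::sd(wmd[idx])
    if (length(idx) >= 2 && !is.na(s) && s > 0) {
      z[idx] <- (wmd[idx] - mean(wmd[idx])) / s
    }
  }
  list(degree = k, wmd = wmd, wmd_z = z, participation = p, clustering = cc)
}

oracle_neighbourhood_efficiency <- function(a, i) {
  a <- ((a + t(a)) > 0) * 1
  diag(a) <- 0
  nb <- which(a[i, ] == 1)
  if (length(nb) < 2) return(0)
  sub <- a[nb, nb, drop = FALSE]
  d <- oracle_bfs_distances(sub)
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (length(nb) * (length(nb) - 1))
}

random_adjacency <- function(n, p = 0.3, seed = 1) {
  set.seed(seed)
  a <- matrix(stats::rbinom(n * n, 1, p), n, n)
  a <- ((a + t(a)) > 0) * 1
  diag(a) <- 0
  a
}

# small planted panel shared by several tests (kept deliberately small)
small_planted_spec <- function(seed = 11) {
  simulation_spec(
    n_rois = 15, n_subjects = 6, n_sessions = 2, n_timepoints = 220,
    community_assignment = rep(1:3, each = 5),
    rho_within = 0.6, rho_between = 0.05, ar_coefficient = 0.3,
    noise_sd = 0.3, seed = seed
  )
}
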