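two_cliques <- function(k = 4) {
  n <- 2 * k
  a <- matrix(0, n, n)
  a[1:k, 1:k] <- 1
  a[(k + 1):n, (k + 1):n] <- 1
  diag(a) <- 0
  a
}

test_that("Louvain separates disconnected cliques and merges at gamma 0", {
  a <- two_cliques(4)
  res <- louvain_once(a, gamma = 1, seed = 1)
  expect_equal(length(unique(res$partition)), 2)
  expect_equal(unname(res$partition[1:4]), rep(res$partition[[1]], 4))

  ring <- matrix(0, 27, 27)
  for (i in 1:27) ring[i, i %% 27 + 1] <- ring[i %% 27 + 1, i] <- 1
  res0 <- louvain_once(ring, gamma = 0, seed = 1)
  expect_equal(length(unique(res0$partition)), 1)

  expect_error(louvain_once(matrix(numeric(0), 0, 0)), "empty")
})

test_that("returned Q equals the brute-force modularity oracle", {
  for (seed in 1:3) {
    a <- random_adjacency(12, 0.35, seed = seed)
    for (g in c(0.5, 1, 1.4)) {
      res <- louvain_once(a, gamma = g, seed = seed)
      expect_equal(res$q, oracle_modularity(a, res$partition, g),
                   tolerance = 1e-10)
    }
  }
  # weighted with negative entries: optimization sees the clipped graph
  w <- random_adjacency(10, 0.4, seed = 9) * matrix(runif(100, -1, 1), 10)
  w <- (w + t(w)) / 2; diag(w) <- 0
  res <- louvain_once(w, gamma = 1, seed = 2)
  expect_equal(res$q, oracle_modularity(w, res$partition, 1),
               tolerance = 1e-10)
})

test_that("consensus of a stable graph is that partition with binary agreement", {
  a <- two_cliques(4)
  sol <- consensus_partition(a, gamma = 1, n_init = 25, seed = 3)
  expect_equal(length(unique(sol$partition)), 2)
  expect_true(all(sol$agreement %in% c(0, 1)))
  expect_equal(sol$q, oracle_modularity(a, sol$partition, 1),
               tolerance = 1e-10)
})

test_that("consensus recovers a planted 3-block adjacency and is deterministic", {
  set.seed(8)
  part0 <- rep(1:3, each = 6)
  p_in <- 0.85; p_out <- 0.1
  n <- length(part0)
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (part0[i] == part0[j]) p_in else p_out
      a[i, j] <- a[j, i] <- rbinom(1, 1, p)
    }
  }
  s1 <- consensus_partition(a, gamma = 1, n_init = 60, seed = 5)
  s2 <- consensus_partition(a, gamma = 1, n_init = 60, seed = 5)
  expect_identical(s1[c("partition", "q", "agreement")],
                   s2[c("partition", "q", "agreement")])
  expect_equal(mclust::adjustedRandIndex(s1$partition, part0), 1)
})

test_that("agreement is invariant to community relabeling across runs", {
  parts <- rbind(c(1, 1, 2, 2), c(2, 2, 1, 1), c(1, 1, 1, 2))
  d1 <- convorg:::agreement_matrix(parts)
  relab <- rbind(c(5, 5, 9, 9), c(7, 7, 3, 3), c(2, 2, 2, 8))
  expect_equal(d1, convorg:::agreement_matrix(relab))
  expect_true(isSymmetric(d1))
  expect_true(all(d1 >= 0 & d1 <= 1))
})

test_that("silhouette scores follow the definition", {
  # perfect separation: within-weight 1 (distance 0), between 0 (distance 1)
  w <- two_cliques(3)
  part <- rep(1:2, each = 3)
  s <- silhouette_scores(w, part)
  expect_equal(unname(s), rep(1, 6))

  # a_i == b_i gives 0
  w2 <- matrix(0.5, 4, 4); diag(w2) <- 0
  s2 <- silhouette_scores(w2, c(1, 1, 2, 2))
  expect_equal(unname(s2), rep(0, 4))

  # 5-node hand example, exhaustive computation
  w3 <- matrix(0, 5, 5)
  w3[1, 2] <- w3[2, 1] <- 0.8
  w3[1, 3] <- w3[3, 1] <- 0.6
  w3[2, 3] <- w3[3, 2] <- 0.7
  w3[4, 5] <- w3[5, 4] <- 0.9
  w3[3, 4] <- w3[4, 3] <- 0.2
  part3 <- c(1, 1, 1, 2, 2)
  s3 <- silhouette_scores(w3, part3)
  d <- 1 - w3; diag(d) <- NA
  hand <- numeric(5)
  for (i in 1:5) {
    own <- setdiff(which(part3 == part3[i]), i)
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(unique(part3), part3[i]),
                    function(cm) mean(d[i, part3 == cm]), numeric(1)))
    hand[i] <- (b - a) / max(a, b)
  }
  expect_equal(unname(s3), hand, tolerance = 1e-12)

  # singleton community scores zero; single community errors
  s4 <- silhouette_scores(w3, c(1, 1, 1, 1, 2))
  expect_equal(unname(s4[5]), 0)
  expect_error(silhouette_scores(w3, rep(1, 5)), "single community")
})

test_that("gamma sweep bookkeeping, argmax and planted recovery", {
  set.seed(12)
  part0 <- rep(1:3, each = 6)
  n <- length(part0)
  a <- matrix(0, n, n)
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      p <- if (part0[i] == part0[j]) 0.9 else 0.08
      a[i, j] <- a[j, i] <- rbinom(1, 1, p)
    }
  }
  w <- a * 0.8
  gammas <- seq(0.4, 1.6, by = 0.2)
  sw <- gamma_sweep(a, w, gammas = gammas, n_init = 40, seed = 6)
  expect_equal(nrow(sw$sweep), length(gammas) * 2)
  conf <- ifelse(is.na(sw$sweep$confidence), -Inf, sw$sweep$confidence)
  expect_true(all(sw$solution$confidence >= conf))
  expect_equal(mclust::adjustedRandIndex(sw$solution$partition, part0), 1)
  expect_type(sw$partitions_identical, "logical")
  # representative solution is the smallest gamma among the ties
  expect_equal(min(sw$best$gamma), sw$solution$gamma)
})
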