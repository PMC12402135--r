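#' Single Louvain partition at resolution gamma
#'
#' One seeded run of Louvain modularity optimization. The adjacency is
#' symmetrized as (A + t(A))/2; negative weights (possible in a normalized
#' weighted connectivity matrix) are clipped to zero for the optimization,
#' which requires non-negative weights.
#'
#' @param adjacency square matrix, zero diagonal; binary or weighted.
#' @param gamma resolution parameter (>= 0). Values below 1 favour fewer,
#'   larger communities; above 1, more and smaller.
#' @param seed integer seed making the run deterministic.
#' @return list with `partition` (integer labels, contiguous from 1) and
#'   `q` (Newman-Girvan modularity of the partition at this gamma).
#' @export
louvain_once <- function(adjacency, gamma = 1, seed = 1L) {
  stopifnot(is.matrix(adjacency), nrow(adjacency) == ncol(adjacency))
  if (nrow(adjacency) == 0) abort("empty graph")
  m <- (adjacency + t(adjacency)) / 2
  m[m < 0] <- 0
  diag(m) <- 0
  g <- igraph::graph_from_adjacency_matrix(m, mode = "undirected",
                                           weighted = TRUE, diag = FALSE)
  if (igraph::ecount(g) == 0) {
    part <- seq_len(nrow(m))
    names(part) <- rownames(adjacency)
    return(list(partition = part, q = 0))
  }
  set.seed(seed)
  cl <- igraph::cluster_louvain(g, resolution = gamma)
  part <- as.integer(igraph::membership(cl))
  part <- as.integer(factor(part, levels = unique(part)))
  names(part) <- rownames(adjacency)
  q <- igraph::modularity(g, part, resolution = gamma,
                          weights = igraph::E(g)$weight)
  list(partition = part, q = q)
}

agreement_matrix <- function(parts) {
  # parts: n_init x N matrix of labels
  n <- ncol(parts)
  d <- matrix(0, n, n)
  for (k in seq_len(nrow(parts))) {
    d <- d + outer(parts[k, ], parts[k, ], `==`)
  }
  d / nrow(parts)
}

#' Consensus community detection
#'
#' Runs Louvain `n_init` times with derived seeds, builds the agreement
#' matrix of co-assignment frequencies, zeroes entries at or below `tau`,
#' and re-clusters the thresholded agreement matrix, iterating until all
#' runs return one identical partition. The `tau` threshold keeps only node
#' pairs co-assigned in strictly more than `tau` of the runs.
#'
#' @inheritParams louvain_once
#' @param n_init number of seeded Louvain initializations.
#' @param tau agreement threshold in (0, 1); default 0.95.
#' @param weights optional weighted matrix used for silhouette scores
#'   (normalized to \eqn{[-1, 1]}); default: the adjacency itself.
#' @param max_iter consensus iteration cap.
#' @return an object of class `community_solution`: partition, gamma,
#'   q (modularity of the consensus partition on the original adjacency),
#'   agreement matrix of the first stage, per-node silhouettes and their
#'   mean (`confidence`; `NA` when the partition has one community).
#' @export
consensus_partition <- function(adjacency, gamma = 1, n_init = 1000,
                                tau = 0.95, seed = 1L, weights = NULL,
                                max_iter = 50L) {
  stopifnot(n_init >= 1, tau > 0, tau < 1)
  n <- nrow(adjacency)
  run_all <- function(mat, seed0) {
    t(vapply(seq_len(n_init),
             function(k) louvain_once(mat, gamma, seed = seed0 + k - 1L)$partition,
             integer(n)))
  }
  parts <- run_all(adjacency, seed)
  agreement <- agreement_matrix(parts)
  diag(agreement) <- 1
  cur <- agreement
  final <- NULL
  for (it in seq_len(max_iter)) {
    identical_runs <- all(apply(parts, 1, function(p) {
      all(outer(p, p, `==`) == outer(parts[1, ], parts[1, ], `==`))
    }))
    if (identical_runs) {
      final <- parts[1, ]
      break
    }
    thr <- cur
    thr[thr <= tau] <- 0
    diag(thr) <- 0
    parts <- run_all(thr, seed + it * n_init)
    nxt <- agreement_matrix(parts)
    diag(nxt) <- 1
    if (identical(nxt, cur)) {
      abort(sprintf(
        "consensus did not converge after %d iterations (gamma = %g, tau = %g): agreement matrix is cycling",
        it, gamma, tau))
    }
    cur <- nxt
  }
  if (is.null(final)) {
    abort(sprintf("consensus did not converge within max_iter = %d (gamma = %g)",
                  max_iter, gamma))
  }
  final <- as.integer(factor(final, levels = unique(final)))
  names(final) <- rownames(adjacency)
  q <- louvain_q(adjacency, final, gamma)
  w <- if (is.null(weights)) adjacency else weights
  sil <- if (length(unique(final)) >= 2) {
    silhouette_scores(w, final)
  } else {
    setNames(rep(NA_real_, n), names(final))
  }
  structure(
    list(gamma = gamma, partition = final, q = q, agreement = agreement,
         silhouettes = sil, confidence = mean(sil), n_init = n_init,
         tau = tau, seed = seed),
    class = "community_solution"
  )
}

# modularity of a fixed partition on the (clipped, symmetrized) matrix
louvain_q <- function(adjacency, partition, gamma = 1) {
  m <- (adjacency + t(adjacency)) / 2
  m[m < 0] <- 0
  diag(m) <- 0
  tw <- sum(m) / 2
  if (tw == 0) return(0)
  k <- rowSums(m)
  same <- outer(partition, partition, `==`)
  sum((m - gamma * outer(k, k) / (2 * tw)) * same) / (2 * tw)
}

#' @export
print.community_solution <- function(x, ...) {
  cat(sprintf(
    "<community_solution> gamma = %g: %d communities, Q = %.3f, confidence = %s\n",
    x$gamma, length(unique(x$partition)), x$q,
    ifelse(is.na(x$confidence), "NA", sprintf("%.3f", x$confidence))
  ))
  invisible(x)
}

#' Per-node silhouette scores on connectivity-derived distances
#'
#' Distance between nodes is `1 - w` on the normalized weighted
#' connectivity matrix (weight 1, i.e. strongest connectivity, maps to
#' distance 0). For node i, `a_i` is the mean distance to the other members
#' of its community and `b_i` the minimum over other communities of the
#' mean distance to that community; the score is
#' `(b_i - a_i) / max(a_i, b_i)`, in \eqn{[-1, 1]}. A node alone in its
#' community scores 0.
#'
#' @param weighted_adjacency weighted connectivity, entries in
#'   \eqn{[-1, 1]} (asymmetric input is averaged with its transpose).
#' @param partition integer community labels covering all nodes; at least
#'   two communities.
#' @return named numeric vector of per-node scores.
#' @export
silhouette_scores <- function(weighted_adjacency, partition) {
  n <- nrow(weighted_adjacency)
  stopifnot(length(partition) == n)
  comms <- unique(partition)
  if (length(comms) < 2) {
    abort("silhouette undefined for a single community; supply a partition with >= 2 communities")
  }
  w <- (weighted_adjacency + t(weighted_adjacency)) / 2
  d <- 1 - w
  diag(d) <- NA
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(partition == partition[i])
    own <- setdiff(own, i)
    if (length(own) == 0) { s[i] <- 0; next }
    a <- mean(d[i, own])
    b <- min(vapply(setdiff(comms, partition[i]), function(cm) {
      mean(d[i, partition == cm])
    }, numeric(1)))
    s[i] <- if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }
  setNames(s, rownames(weighted_adjacency))
}

#' Resolution sweep with consensus clustering and silhouette selection
#'
#' For every gamma on the grid, runs consensus clustering on the binary and
#' on the weighted connectivity matrix; silhouettes (and hence the network
#' assignment confidence score, their mean) are always evaluated on the
#' weighted matrix. The best solution maximizes confidence; ties are
#' reported in full and resolved to the smallest gamma (binary matrix
#' first) for the representative solution.
#'
#' @param binary,weighted aligned N x N connectivity matrices.
#' @param gammas resolution grid; default 0 to 2 in steps of 0.1.
#' @inheritParams consensus_partition
#' @return object of class `gamma_sweep`: `sweep` tibble (gamma, matrix,
#'   n_communities, q, confidence, partition list-column), `best`
#'   (all argmax rows), `solution` (representative [consensus_partition]
#'   solution) and `partitions_identical` — whether the binary and weighted
#'   best partitions coincide.
#' @export
gamma_sweep <- function(binary, weighted, gammas = seq(0, 2, by = 0.1),
                        n_init = 1000, tau = 0.95, seed = 1L) {
  stopifnot(all(dim(binary) == dim(weighted)))
  grid <- tidyr::expand_grid(matrix = c("binary", "weighted"), gamma = gammas)
  sols <- purrr::pmap(grid, function(matrix, gamma) {
    mat <- if (matrix == "binary") binary else weighted
    consensus_partition(mat, gamma = gamma, n_init = n_init, tau = tau,
                        seed = seed, weights = weighted)
  })
  sweep_tbl <- grid |>
    dplyr::mutate(
      n_communities = purrr::map_int(sols, ~ length(unique(.x$partition))),
      q = purrr::map_dbl(sols, "q"),
      confidence = purrr::map_dbl(sols, "confidence"),
      partition = purrr::map(sols, "partition")
    ) |>
    dplyr::arrange(.data$gamma, .data$matrix)
  conf <- ifelse(is.na(sweep_tbl$confidence), -Inf, sweep_tbl$confidence)
  best_rows <- sweep_tbl[conf == max(conf), ]
  rep_row <- best_rows |>
    dplyr::arrange(.data$gamma, .data$matrix) |>
    dplyr::slice(1)
  rep_sol <- sols[[which(grid$matrix == rep_row$matrix &
                           grid$gamma == rep_row$gamma)]]
  same_partition <- function(p1, p2) {
    all(outer(p1, p1, `==`) == outer(p2, p2, `==`))
  }
  by_type <- lapply(c("binary", "weighted"), function(mt) {
    rows <- sweep_tbl[sweep_tbl$matrix == mt, ]
    cf <- ifelse(is.na(rows$confidence), -Inf, rows$confidence)
    rows$partition[[which.max(cf)]]
  })
  structure(
    list(sweep = sweep_tbl, best = best_rows, solution = rep_sol,
         partitions_identical = same_partition(by_type[[1]], by_type[[2]]),
         n_init = n_init, tau = tau, seed = seed),
    class = "gamma_sweep"
  )
}

#' @export
print.gamma_sweep <- function(x, ...) {
  cat(sprintf(
    "<gamma_sweep> %d (gamma, matrix) cells; best confidence %.3f at gamma = %s (%s); binary/weighted best partitions %s\n",
    nrow(x$sweep), max(x$best$confidence),
    paste(unique(x$best$gamma), collapse = ", "),
    paste(unique(x$best$matrix), collapse = "+"),
    if (x$partitions_identical) "identical" else "differ"
  ))
  invisible(x)
}
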