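#' Degree-preserving rewired null ensemble
#'
#' Generates random networks by double-edge swaps that preserve every
#' node's degree exactly, the standard null model for validating community
#' structure against chance.
#'
#' @param binary adjacency (symmetrized before rewiring).
#' @param n ensemble size.
#' @param swaps_per_edge attempted swaps per edge per member.
#' @param seed integer seed; member k uses seed + k - 1.
#' @param symmetrize passed to [symmetrize_adjacency()].
#' @return object of class `null_ensemble`: list of 0/1 adjacency matrices
#'   (`members`), plus the generating parameters.
#' @export
rewire_null_ensemble <- function(binary, n = 1000, swaps_per_edge = 10,
                                 seed = 1L, symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  g <- as_igraph_undirected(a)
  if (igraph::ecount(g) < 2) abort("need at least 2 edges to rewire")
  niter <- swaps_per_edge * igraph::ecount(g)
  deg0 <- igraph::degree(g)
  members <- lapply(seq_len(n), function(k) {
    set.seed(seed + k - 1L)
    gr <- igraph::rewire(g, igraph::keeping_degseq(niter = niter))
    m <- as.matrix(igraph::as_adjacency_matrix(gr, sparse = FALSE))
    stopifnot(all(rowSums(m) == deg0))  # construction invariant
    dimnames(m) <- dimnames(a)
    m
  })
  structure(
    list(members = members, n = n, swaps_per_edge = swaps_per_edge,
         seed = seed, degree_sequence = deg0),
    class = "null_ensemble"
  )
}

#' @export
print.null_ensemble <- function(x, ...) {
  cat(sprintf("<null_ensemble> %d degree-preserving rewirings of a %d-node graph\n",
              x$n, length(x$degree_sequence)))
  invisible(x)
}

#' Compare a real network's metrics against a null ensemble
#'
#' For each metric the null distribution over the ensemble is tested
#' against the real value with a one-sample t-test (dof = n - 1). Network
#' level: optimized modularity Q (Louvain re-run per member with a derived
#' seed) and characteristic path length (largest component when a member is
#' disconnected). Node level: within-module degree and participation under
#' the real partition, one test per node. P-values are Bonferroni-adjusted
#' across all rows when `bonferroni = TRUE`. A zero-variance null
#' distribution falls back to exact comparison (t = 0 or +/-Inf sentinel).
#'
#' @param binary real adjacency.
#' @param ensemble a [rewire_null_ensemble()] result.
#' @param partition community labels of the real network.
#' @param alpha significance level after correction.
#' @param bonferroni adjust across rows?
#' @param gamma resolution for the per-member Louvain Q.
#' @param symmetrize passed through to the metric functions.
#' @return tibble: metric, node (NA for network level), real, null_mean,
#'   null_sd, t, dof, p, direction ("above"/"below"/"equal"), significant.
#' @export
null_comparison <- function(binary, ensemble, partition, alpha = 0.01,
                            bonferroni = TRUE, gamma = 1,
                            symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  if (length(ensemble$members) == 0) abort("empty null ensemble")
  a <- symmetrize_adjacency(binary, symmetrize)
  labels <- rownames(a)
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(nrow(a)))

  real_q <- louvain_once(a, gamma, seed = ensemble$seed)$q
  real_cpl <- as.numeric(characteristic_path_length(a, largest_component = TRUE))
  real_nm <- node_degree_metrics(a, partition)

  null_q <- vapply(seq_along(ensemble$members), function(k) {
    louvain_once(ensemble$members[[k]], gamma,
                 seed = ensemble$seed + 31L * k)$q
  }, numeric(1))
  null_cpl <- vapply(ensemble$members, function(m) {
    as.numeric(characteristic_path_length(m, largest_component = TRUE))
  }, numeric(1))
  null_nm <- lapply(ensemble$members, function(m) {
    node_degree_metrics(m, partition)
  })
  null_wmd <- do.call(rbind, lapply(null_nm, function(d) d$wmd))
  null_part <- do.call(rbind, lapply(null_nm, function(d) d$participation))

  one_test <- function(metric, node, real, nulls) {
    mu <- mean(nulls); s <- sd(nulls); nn <- length(nulls)
    if (s == 0) {
      eq <- isTRUE(all.equal(mu, real))
      t <- if (eq) 0 else Inf * sign(mu - real)
      p <- if (eq) 1 else 0
    } else {
      t <- (mu - real) / (s / sqrt(nn))
      p <- 2 * pt(-abs(t), df = nn - 1L)
    }
    tibble::tibble(metric = metric, node = node, real = real, null_mean = mu,
                   null_sd = s, t = t, dof = nn - 1L, p = p,
                   direction = dplyr::case_when(real > mu ~ "above",
                                                real < mu ~ "below",
                                                TRUE ~ "equal"))
  }
  rows <- dplyr::bind_rows(
    one_test("modularity_q", NA_character_, real_q, null_q),
    one_test("cpl", NA_character_, real_cpl, null_cpl),
    purrr::map_dfr(seq_along(labels), function(i) {
      one_test("wmd", labels[i], real_nm$wmd[i], null_wmd[, i])
    }),
    purrr::map_dfr(seq_along(labels), function(i) {
      one_test("participation", labels[i], real_nm$participation[i],
               null_part[, i])
    })
  )
  rows$p_adj <- if (bonferroni) pmin(1, rows$p * nrow(rows)) else rows$p
  rows$significant <- rows$p_adj < alpha
  rows
}
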