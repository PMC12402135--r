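#' Neighbourhood efficiency of one node
#'
#' The efficiency of the neighbourhood G_i is the mean inverse
#' shortest-path length over ordered pairs of the neighbours of i, with i
#' itself removed. By default shortest paths are restricted to the induced
#' neighbourhood subgraph (the Latora-Marchiori convention); with
#' `paths_within = FALSE` paths may route through the rest of the graph
#' (still excluding i). Unreachable pairs contribute 0; fewer than two
#' neighbours give efficiency 0. The value is 1 iff the neighbourhood is a
#' clique and 0 iff it induces no edges.
#'
#' @param binary undirected (or symmetrized) 0/1 adjacency.
#' @param node label or index.
#' @param paths_within restrict shortest paths to the neighbourhood
#'   subgraph?
#' @param symmetrize passed to [symmetrize_adjacency()].
#' @return scalar efficiency in \eqn{[0, 1]}.
#' @export
neighbourhood_efficiency <- function(binary, node, paths_within = TRUE,
                                     symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  labs <- rownames(a) %||% sprintf("V%d", seq_len(nrow(a)))
  if (is.character(node)) node <- match(node, labs)
  if (is.na(node) || node < 1 || node > nrow(a)) abort("node absent from graph")
  nbrs <- which(a[node, ] != 0)
  ni <- length(nbrs)
  if (ni < 2) return(0)
  if (paths_within) {
    sub <- a[nbrs, nbrs, drop = FALSE]
    g <- as_igraph_undirected(sub)
    d <- igraph::distances(g)
  } else {
    keep <- setdiff(seq_len(nrow(a)), node)
    g <- as_igraph_undirected(a[keep, keep, drop = FALSE])
    pos <- match(nbrs, keep)
    d <- igraph::distances(g, v = pos, to = pos)
  }
  inv <- 1 / d
  inv[!is.finite(inv)] <- 0
  diag(inv) <- 0
  sum(inv) / (ni * (ni - 1))
}

#' Targeted attack on a node set
#'
#' Removing a node severs all its connections; the impact is summarized by
#' the mean neighbourhood efficiency over the attacked set (lower means
#' poorer communication among the removed nodes' neighbours).
#'
#' @inheritParams neighbourhood_efficiency
#' @param nodes labels or indices of the attacked set.
#' @return list of class `targeted_attack`: per-node efficiencies tibble
#'   and `le_target`, their mean.
#' @export
targeted_attack <- function(binary, nodes, paths_within = TRUE,
                            symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  if (length(nodes) == 0) abort("attacked set is empty")
  a <- symmetrize_adjacency(binary, symmetrize)
  labs <- rownames(a) %||% sprintf("V%d", seq_len(nrow(a)))
  idx <- if (is.character(nodes)) match(nodes, labs) else as.integer(nodes)
  if (anyNA(idx)) abort("attacked set contains nodes absent from the graph")
  eff <- vapply(idx, function(i) {
    neighbourhood_efficiency(a, i, paths_within = paths_within)
  }, numeric(1))
  structure(
    list(efficiencies = tibble::tibble(node = labs[idx], efficiency = eff),
         le_target = mean(eff)),
    class = "targeted_attack"
  )
}

#' Random-attack null distribution of local efficiency
#'
#' Draws `n` random sets of `set_size` nodes (without replacement within a
#' draw) from `pool`, computes each draw's mean neighbourhood efficiency,
#' and, when a targeted value is supplied, tests the null distribution
#' against it with a one-sample t-test (dof = n - 1).
#'
#' @inheritParams neighbourhood_efficiency
#' @param set_size nodes removed per simulated attack.
#' @param n number of simulations.
#' @param pool labels or indices to draw from; default all nodes. Use the
#'   cortical members of the converging organization for the restricted
#'   condition.
#' @param seed RNG seed.
#' @param le_target targeted-attack local efficiency to test against.
#' @return list of class `attack_null`: `null_le` (length n), `t`, `dof`,
#'   `p`, `null_mean`, `null_sd`, `seed`.
#' @export
random_attack_null <- function(binary, set_size, n = 10000, pool = NULL,
                               seed = 1L, le_target = NULL,
                               paths_within = TRUE,
                               symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  labs <- rownames(a) %||% sprintf("V%d", seq_len(nrow(a)))
  if (is.null(pool)) pool <- seq_len(nrow(a))
  if (is.character(pool)) pool <- match(pool, labs)
  if (anyNA(pool)) abort("pool contains nodes absent from the graph")
  if (length(pool) < set_size) abort("pool smaller than the attacked set size")
  # neighbourhood efficiency depends only on the node, so precompute once
  eff <- setNames(vapply(pool, function(i) {
    neighbourhood_efficiency(a, i, paths_within = paths_within)
  }, numeric(1)), pool)
  set.seed(seed)
  null_le <- vapply(seq_len(n), function(k) {
    mean(eff[as.character(sample(pool, set_size))])
  }, numeric(1))
  t <- dof <- p <- NA_real_
  if (!is.null(le_target)) {
    dof <- n - 1L
    s <- sd(null_le)
    if (s == 0) {
      eq <- isTRUE(all.equal(mean(null_le), le_target))
      t <- if (eq) 0 else Inf * sign(mean(null_le) - le_target)
      p <- if (eq) 1 else 0
    } else {
      tt <- t.test(null_le, mu = le_target)
      t <- unname(tt$statistic); p <- tt$p.value
    }
  }
  structure(
    list(null_le = null_le, t = t, dof = dof, p = p,
         null_mean = mean(null_le), null_sd = sd(null_le), seed = seed,
         set_size = set_size, n = n),
    class = "attack_null"
  )
}

#' Restrict a connectome to its converging organization
#'
#' The attack universe: all subcortical nodes plus every cortical node with
#' at least one bidirectional subcortical edge, and all (symmetrized) edges
#' among them — cortico-cortical, subcortico-subcortical and
#' cortico-subcortical alike.
#'
#' @param C directed binary whole-brain matrix.
#' @param cortical_idx,subcortical_idx disjoint label/index sets.
#' @param symmetrize rule for the retained edges.
#' @return list: `adjacency` (symmetrized subgraph), `cortical`,
#'   `subcortical` (labels of retained nodes).
#' @export
converging_subgraph <- function(C, cortical_idx, subcortical_idx,
                                symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  labs <- rownames(C) %||% sprintf("V%d", seq_len(nrow(C)))
  rownames(C) <- colnames(C) <- labs
  if (is.numeric(cortical_idx)) cortical_idx <- labs[cortical_idx]
  if (is.numeric(subcortical_idx)) subcortical_idx <- labs[subcortical_idx]
  inc <- bidirectional_graph(C, cortical_idx, subcortical_idx)
  keep_ctx <- rownames(inc)[rowSums(inc) > 0]
  keep <- c(keep_ctx, subcortical_idx)
  adj <- symmetrize_adjacency(C[keep, keep, drop = FALSE], symmetrize)
  list(adjacency = adj, cortical = keep_ctx, subcortical = subcortical_idx)
}

#' Full attack analysis
#'
#' Targeted attack on the subcortical set, plus unrestricted (all-node) and
#' restricted (cortical-only) random-attack null distributions with
#' one-sample tests against the targeted local efficiency.
#'
#' @inheritParams random_attack_null
#' @param subcortical_nodes the targeted set (labels or indices).
#' @param cortical_pool pool for the restricted condition; default all
#'   non-targeted nodes.
#' @return object of class `attack_report`.
#' @export
attack_analysis <- function(binary, subcortical_nodes, n = 10000,
                            cortical_pool = NULL, seed = 1L,
                            paths_within = TRUE,
                            symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  labs <- rownames(a) %||% sprintf("V%d", seq_len(nrow(a)))
  rownames(a) <- colnames(a) <- labs
  tg <- targeted_attack(a, subcortical_nodes, paths_within = paths_within)
  if (is.null(cortical_pool)) {
    idx <- if (is.character(subcortical_nodes)) {
      match(subcortical_nodes, labs)
    } else subcortical_nodes
    cortical_pool <- labs[-idx]
  }
  unres <- random_attack_null(a, set_size = nrow(tg$efficiencies), n = n,
                              pool = NULL, seed = seed,
                              le_target = tg$le_target,
                              paths_within = paths_within)
  restr <- random_attack_null(a, set_size = nrow(tg$efficiencies), n = n,
                              pool = cortical_pool, seed = seed + 1L,
                              le_target = tg$le_target,
                              paths_within = paths_within)
  structure(
    list(targeted = tg, unrestricted = unres, restricted = restr,
         n = n, seed = seed),
    class = "attack_report"
  )
}

#' @export
print.attack_report <- function(x, ...) {
  cat(sprintf(
    "<attack_report> LE(target) = %.3f vs null %.3f (+/-%.3f) [t = %.2f] and restricted %.3f (+/-%.3f) [t = %.2f], %d sims\n",
    x$targeted$le_target, x$unrestricted$null_mean, x$unrestricted$null_sd,
    x$unrestricted$t, x$restricted$null_mean, x$restricted$null_sd,
    x$restricted$t, x$n
  ))
  invisible(x)
}
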