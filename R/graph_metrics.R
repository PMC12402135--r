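#' Node-level graph metrics
#'
#' Degree, within-module degree (WMD) and its z-score, participation
#' coefficient, local clustering coefficient and connection density
#' (degree per voxel) on the symmetrized undirected graph. The WMD z-score
#' standardizes a node's within-module degree against the other members of
#' its module; a module whose members all have equal within-degree has zero
#' spread and the z-score is defined as 0. An isolated node has
#' participation 0.
#'
#' @param binary directed or undirected 0/1 adjacency.
#' @param partition integer community labels covering all nodes. The
#'   community context matters: participation with respect to subcortical
#'   communities only and with respect to whole-brain communities are two
#'   different calls with different partitions.
#' @param parcellation optional [parcellation] supplying `voxel_count`
#'   (required for connection density).
#' @param symmetrize `"or"` (edge if either direction significant, default)
#'   or `"and"` (strict bidirectional).
#' @return tibble: label, community, degree, wmd, wmd_z, participation,
#'   clustering, density.
#' @export
node_degree_metrics <- function(binary, partition, parcellation = NULL,
                                symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  n <- nrow(a)
  stopifnot(length(partition) == n)
  labels <- rownames(a)
  if (is.null(labels)) labels <- sprintf("V%d", seq_len(n))
  k <- rowSums(a)
  wmd <- vapply(seq_len(n), function(i) sum(a[i, partition == partition[i]]),
                numeric(1))
  wmd_z <- numeric(n)
  for (m in unique(partition)) {
    idx <- which(partition == m)
    mu <- mean(wmd[idx]); s <- sd(wmd[idx])
    if (length(idx) < 2 || is.na(s) || s == 0) {
      wmd_z[idx] <- 0
    } else {
      wmd_z[idx] <- (wmd[idx] - mu) / s
    }
  }
  p <- participation(a, partition, symmetrize = "or")
  g <- as_igraph_undirected(a)
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  dens <- rep(NA_real_, n)
  if (!is.null(parcellation)) {
    vc <- parcellation$voxel_count[match(labels, parcellation$label)]
    if (anyNA(vc)) abort("missing voxel counts for connection density")
    dens <- k / vc
  }
  tibble::tibble(
    label = labels, community = as.integer(partition), degree = as.numeric(k),
    wmd = as.numeric(wmd), wmd_z = wmd_z, participation = p,
    clustering = cc, density = dens
  )
}

#' Participation coefficient
#'
#' `P_i = 1 - sum_m (k_im / k_i)^2` over the communities of the supplied
#' partition; 0 for isolated nodes (all of a connected node's edges inside
#' its own community also give 0, a fully even spread approaches 1).
#'
#' @inheritParams node_degree_metrics
#' @return numeric vector of per-node coefficients in \eqn{[0, 1]}.
#' @export
participation <- function(binary, partition, symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  k <- rowSums(a)
  p <- numeric(nrow(a))
  for (i in seq_len(nrow(a))) {
    if (k[i] == 0) next
    kim <- vapply(unique(partition), function(m) sum(a[i, partition == m]),
                  numeric(1))
    p[i] <- 1 - sum((kim / k[i])^2)
  }
  setNames(p, rownames(a))
}

#' Newman-Girvan modularity of a given partition
#'
#' Direct evaluation (no optimization) of the modularity index at
#' resolution gamma on the symmetrized graph. Values near 0 indicate
#' random-like structure, values near 1 a strong community structure.
#'
#' @inheritParams node_degree_metrics
#' @param gamma resolution parameter.
#' @return scalar Q.
#' @export
modularity_q <- function(binary, partition, gamma = 1,
                         symmetrize = c("or", "and")) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  tw <- sum(a) / 2
  if (tw == 0) return(0)
  k <- rowSums(a)
  same <- outer(partition, partition, `==`)
  sum((a - gamma * outer(k, k) / (2 * tw)) * same) / (2 * tw)
}

#' Characteristic path length
#'
#' Mean shortest-path length over all pairs of distinct nodes, unit edge
#' lengths, undirected. Errors on a disconnected graph unless
#' `largest_component = TRUE`, which restricts the average to the largest
#' connected component (recorded via attribute `component_size`).
#'
#' @inheritParams node_degree_metrics
#' @param largest_component fall back to the largest component?
#' @return scalar lambda, with attribute `component_size`.
#' @export
characteristic_path_length <- function(binary, symmetrize = c("or", "and"),
                                       largest_component = FALSE) {
  symmetrize <- match.arg(symmetrize)
  a <- symmetrize_adjacency(binary, symmetrize)
  g <- as_igraph_undirected(a)
  comp <- igraph::components(g)
  if (comp$no > 1) {
    if (!largest_component) {
      abort(paste0("graph is disconnected (", comp$no, " components); use ",
                   "largest_component = TRUE to average within the largest component"))
    }
    keep <- which(comp$membership == which.max(comp$csize))
    g <- igraph::induced_subgraph(g, keep)
  }
  d <- igraph::distances(g)
  lambda <- mean(d[upper.tri(d)])
  attr(lambda, "component_size") <- igraph::vcount(g)
  lambda
}

#' Classify nodes into hub types
#'
#' A node is a connector hub when its participation coefficient exceeds 0.5
#' and its WMD z-score is positive; a non-hub connector when only
#' participation exceeds 0.5; a provincial hub when only the z-score is
#' positive; a non-hub otherwise. Boundaries are non-strict on the low side
#' (P = 0.5 or z = 0 never qualifies).
#'
#' @param p participation coefficients.
#' @param z WMD z-scores, aligned with `p`.
#' @param labels optional node labels.
#' @param p_threshold,z_threshold classification thresholds.
#' @return tibble: label, participation, wmd_z, type; attribute
#'   `percentages` holds the per-type percentage breakdown (also available
#'   via [hub_type_percentages()]).
#' @export
classify_nodes <- function(p, z, labels = names(p), p_threshold = 0.5,
                           z_threshold = 0) {
  stopifnot(length(p) == length(z))
  if (is.null(labels)) labels <- sprintf("V%d", seq_along(p))
  type <- dplyr::case_when(
    p > p_threshold & z > z_threshold ~ "connector_hub",
    p > p_threshold ~ "non_hub_connector",
    z > z_threshold ~ "provincial_hub",
    TRUE ~ "non_hub"
  )
  out <- tibble::tibble(label = labels, participation = unname(p),
                        wmd_z = unname(z),
                        type = factor(type, levels = c(
                          "connector_hub", "non_hub_connector",
                          "provincial_hub", "non_hub")))
  attr(out, "percentages") <- hub_type_percentages(out)
  out
}

#' @rdname classify_nodes
#' @param classified output of [classify_nodes()].
#' @export
hub_type_percentages <- function(classified) {
  classified |>
    dplyr::count(.data$type, .drop = FALSE) |>
    dplyr::mutate(percentage = 100 * .data$n / sum(.data$n),
                  connector = .data$type %in% c("connector_hub",
                                                "non_hub_connector"))
}

#' Two-sample comparison of node metrics between groups
#'
#' Pooled-variance two-sample t-tests (equal but unknown variances) per
#' metric column, e.g. subcortex versus cortex.
#'
#' @param metrics_a,metrics_b tibbles as from [node_degree_metrics()].
#' @param metrics metric columns to compare.
#' @param alpha significance level.
#' @return tibble: metric, mean_a, mean_b, t, dof, p, significant.
#' @export
compare_groups <- function(metrics_a, metrics_b,
                           metrics = c("degree", "wmd", "wmd_z",
                                       "participation", "clustering",
                                       "density"),
                           alpha = 0.01) {
  if (nrow(metrics_a) < 2 || nrow(metrics_b) < 2) {
    abort("both groups need at least 2 nodes")
  }
  purrr::map_dfr(metrics, function(mc) {
    xa <- metrics_a[[mc]]; xb <- metrics_b[[mc]]
    if (is.null(xa) || is.null(xb) || all(is.na(xa)) || all(is.na(xb))) {
      return(tibble::tibble(metric = mc, mean_a = NA_real_, mean_b = NA_real_,
                            t = NA_real_, dof = NA_integer_, p = NA_real_,
                            significant = NA))
    }
    if (sd(xa) == 0 && sd(xb) == 0) {
      eq <- isTRUE(all.equal(mean(xa), mean(xb)))
      return(tibble::tibble(metric = mc, mean_a = mean(xa), mean_b = mean(xb),
                            t = if (eq) 0 else Inf * sign(mean(xa) - mean(xb)),
                            dof = length(xa) + length(xb) - 2L,
                            p = if (eq) 1 else 0, significant = !eq))
    }
    tt <- t.test(xa, xb, var.equal = TRUE)
    tibble::tibble(metric = mc, mean_a = mean(xa), mean_b = mean(xb),
                   t = unname(tt$statistic),
                   dof = as.integer(tt$parameter), p = tt$p.value,
                   significant = tt$p.value < alpha)
  })
}
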