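#' Tidy a group connectivity result into an edge table
#'
#' @param x a [group_rfx()] result.
#' @param significant_only keep only significant directed edges?
#' @param ... unused.
#' @return tibble: from, to, t, weight, significant.
#' @export
tidy.connectivity_result <- function(x, significant_only = TRUE, ...) {
  n <- nrow(x$binary)
  labs <- rownames(x$binary) %||% sprintf("V%d", seq_len(n))
  idx <- which(row(x$binary) != col(x$binary), arr.ind = TRUE)
  out <- tibble::tibble(
    from = labs[idx[, 1]], to = labs[idx[, 2]],
    t = x$t_matrix[idx], weight = x$weighted[idx],
    significant = x$binary[idx] == 1L
  )
  if (significant_only) out <- dplyr::filter(out, .data$significant)
  out
}

#' @export
glance.connectivity_result <- function(x, ...) {
  n <- nrow(x$binary)
  tibble::tibble(
    n_rois = n, n_subjects = x$dof + 1L, dof = x$dof,
    n_edges = sum(x$binary),
    edge_density = sum(x$binary) / (n * (n - 1)),
    alpha = x$alpha, n_comparisons = x$n_comparisons
  )
}

#' @export
tidy.community_solution <- function(x, ...) {
  tibble::tibble(
    label = names(x$partition) %||% sprintf("V%d", seq_along(x$partition)),
    community = unname(x$partition),
    silhouette = unname(x$silhouettes)
  )
}

#' @export
glance.community_solution <- function(x, ...) {
  tibble::tibble(
    gamma = x$gamma, n_communities = length(unique(x$partition)),
    q = x$q, confidence = x$confidence, n_init = x$n_init, tau = x$tau
  )
}

#' @export
tidy.attack_report <- function(x, ...) {
  x$targeted$efficiencies
}

#' @export
glance.attack_report <- function(x, ...) {
  tibble::tibble(
    le_target = x$targeted$le_target,
    null_mean = x$unrestricted$null_mean, null_sd = x$unrestricted$null_sd,
    t_random = x$unrestricted$t, p_random = x$unrestricted$p,
    restricted_mean = x$restricted$null_mean,
    restricted_sd = x$restricted$null_sd,
    t_restricted = x$restricted$t, p_restricted = x$restricted$p,
    n_simulations = x$n
  )
}
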