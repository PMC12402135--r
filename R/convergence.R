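#' Bidirectional cortico-subcortical convergence graph
#'
#' An edge c(r, s) = 1 requires significant influence in both directions
#' (strict AND of the directed binary matrix) between cortical node r and
#' subcortical node s — the "dual dyad" motif rationale. Only
#' cortico-subcortical pairs are retained.
#'
#' @param C directed binary N x N connectivity matrix.
#' @param cortical_idx,subcortical_idx disjoint index (or label) sets.
#' @return cortical x subcortical 0/1 incidence matrix with dimnames.
#' @export
bidirectional_graph <- function(C, cortical_idx, subcortical_idx) {
  if (is.character(cortical_idx)) cortical_idx <- match(cortical_idx, rownames(C))
  if (is.character(subcortical_idx)) subcortical_idx <- match(subcortical_idx, rownames(C))
  if (length(intersect(cortical_idx, subcortical_idx))) {
    abort("cortical and subcortical index sets overlap")
  }
  b <- (C != 0) & (t(C) != 0)
  out <- b[cortical_idx, subcortical_idx, drop = FALSE] * 1L
  labs <- rownames(C)
  if (!is.null(labs)) {
    dimnames(out) <- list(labs[cortical_idx], labs[subcortical_idx])
  }
  out
}

#' Per-subcortical convergence counts
#'
#' The absolute number of distinct cortical ROIs converging onto each
#' subcortical ROI through bidirectional connections.
#'
#' @param graph cortical x subcortical incidence matrix
#'   (see [bidirectional_graph()]).
#' @return tibble: sub_label, n_converging.
#' @export
convergence_counts <- function(graph) {
  tibble::tibble(
    sub_label = colnames(graph) %||% sprintf("S%d", seq_len(ncol(graph))),
    n_converging = as.integer(colSums(graph != 0))
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Proportion convergence over cortical pairs
#'
#' For each unordered cortical pair (i, j), counts the subcortical targets
#' onto which both converge (joint absence does not count), then normalizes
#' by the grand total so the proportions sum to 1 whenever any shared
#' target exists.
#'
#' @inheritParams convergence_counts
#' @return tibble: i, j (labels), shared (raw count), o (proportion).
#' @export
proportion_convergence <- function(graph) {
  m <- (graph != 0) * 1L
  labs <- rownames(m) %||% sprintf("C%d", seq_len(nrow(m)))
  s <- m %*% t(m)
  pr <- t(combn(nrow(m), 2))
  shared <- s[pr]
  tot <- sum(shared)
  if (tot == 0) {
    warn("no cortical pair shares a subcortical target; all proportions zero")
  }
  tibble::tibble(
    i = labs[pr[, 1]], j = labs[pr[, 2]],
    shared = as.integer(shared),
    o = if (tot == 0) rep(0, length(shared)) else shared / tot
  )
}

#' Bilateral Euclidean distance between two ROIs
#'
#' An ROI merges its left- and right-hemisphere parcels; the distance
#' between two bilateral ROIs averages the within-hemisphere centroid
#' distances. When one ROI is medial (single centroid, e.g. cerebellar
#' vermis), its centroid is paired with each of the other ROI's centroids
#' and the distances averaged.
#'
#' @param parc a [parcellation].
#' @param i,j ROI labels or row indices.
#' @return distance in mm.
#' @export
roi_distance <- function(parc, i, j) {
  if (is.character(i)) i <- match(i, parc$label)
  if (is.character(j)) j <- match(j, parc$label)
  cents <- function(k) {
    c1 <- c(parc$x1[k], parc$y1[k], parc$z1[k])
    if (anyNA(c1)) abort(sprintf("missing centroid for ROI '%s'", parc$label[k]))
    c2 <- c(parc$x2[k], parc$y2[k], parc$z2[k])
    if (anyNA(c2)) list(c1) else list(c1, c2)
  }
  a <- cents(i); b <- cents(j)
  if (length(a) == 2 && length(b) == 2) {
    mean(c(sqrt(sum((a[[1]] - b[[1]])^2)), sqrt(sum((a[[2]] - b[[2]])^2))))
  } else {
    mean(unlist(lapply(a, function(u) {
      vapply(b, function(v) sqrt(sum((u - v)^2)), numeric(1))
    })))
  }
}

#' Pairwise convergence table with distances and FS/FD classes
#'
#' Joins the proportion-convergence pairs with bilateral distances and
#' classifies each pair as functionally similar (FS: both nodes in the
#' same resting-state network) or functionally diverse (FD).
#'
#' @inheritParams convergence_counts
#' @param parc [parcellation] covering the cortical nodes of `graph`.
#' @return tibble: i, j, shared, o, distance, rsn_i, rsn_j, class.
#' @export
convergence_pairs <- function(graph, parc) {
  pairs <- proportion_convergence(graph)
  ii <- match(pairs$i, parc$label)
  jj <- match(pairs$j, parc$label)
  if (anyNA(ii) || anyNA(jj)) abort("parcellation does not cover all cortical nodes")
  pairs$distance <- vapply(seq_len(nrow(pairs)),
                           function(k) roi_distance(parc, ii[k], jj[k]),
                           numeric(1))
  pairs$rsn_i <- parc$rsn[ii]
  pairs$rsn_j <- parc$rsn[jj]
  pairs$class <- ifelse(pairs$rsn_i == pairs$rsn_j, "FS", "FD")
  pairs
}

#' Binned FS/FD distance distributions with normal fits
#'
#' Pairs are binned by distance into `bin_width`-mm bins anchored at 0 and
#' the proportion convergence summed per bin and class. Normal parameters
#' per class come either from the O-weighted mean and standard deviation of
#' the pair-level distances (`fit = "moments"`, the default) or from an
#' amplitude-free Gaussian least-squares fit to the binned histogram
#' evaluated at the bin labels `bin_width, 2 bin_width, ...`
#' (`fit = "lsq"`).
#'
#' @param pairs tibble from [convergence_pairs()].
#' @param bin_width bin width in mm.
#' @param max_distance span of the bin grid; `NULL` (default) uses the
#'   maximum observed pair distance. Distances beyond the grid fall into
#'   the last bin.
#' @param fit `"moments"` or `"lsq"`.
#' @return object of class `fs_fd_distributions`: `binned` tibble (bin,
#'   lower, upper, fs_weight, fd_weight), `fits` tibble (class, mu, sigma,
#'   weight, method), and the input `pairs`.
#' @export
fs_fd_distributions <- function(pairs, bin_width = 8, max_distance = NULL,
                                fit = c("moments", "lsq")) {
  fit <- match.arg(fit)
  if (is.null(max_distance)) max_distance <- max(pairs$distance)
  n_bins <- max(1L, ceiling(max_distance / bin_width))
  bin <- pmin(floor(pairs$distance / bin_width) + 1L, n_bins)
  wsum <- function(cls) {
    as.numeric(tapply(ifelse(pairs$class == cls, pairs$o, 0),
                      factor(bin, levels = seq_len(n_bins)), sum,
                      default = 0))
  }
  binned <- tibble::tibble(
    bin = seq_len(n_bins),
    lower = (seq_len(n_bins) - 1) * bin_width,
    upper = seq_len(n_bins) * bin_width,
    fs_weight = wsum("FS"),
    fd_weight = wsum("FD")
  )
  fit_class <- function(cls) {
    w_pairs <- ifelse(pairs$class == cls, pairs$o, 0)
    tot <- sum(w_pairs)
    if (tot == 0) {
      warn(sprintf("class %s has zero total weight; normal fit omitted", cls))
      return(tibble::tibble(class = cls, mu = NA_real_, sigma = NA_real_,
                            weight = 0, method = fit))
    }
    if (fit == "moments") {
      mu <- sum(pairs$distance * w_pairs) / tot
      sg <- sqrt(sum(w_pairs * (pairs$distance - mu)^2) / tot)
    } else {
      x <- binned$upper
      w <- if (cls == "FS") binned$fs_weight else binned$fd_weight
      mu0 <- sum(x * w) / sum(w)
      sg0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
      obj <- function(p) sum((w - p[1] * exp(-(x - p[2])^2 / (2 * p[3]^2)))^2)
      opt <- optim(c(max(w), mu0, sg0), obj,
                   control = list(maxit = 20000, reltol = 1e-14))
      mu <- opt$par[2]; sg <- abs(opt$par[3])
    }
    tibble::tibble(class = cls, mu = mu, sigma = sg, weight = tot,
                   method = fit)
  }
  structure(
    list(binned = binned,
         fits = dplyr::bind_rows(fit_class("FS"), fit_class("FD")),
         pairs = pairs, bin_width = bin_width),
    class = "fs_fd_distributions"
  )
}

#' @export
print.fs_fd_distributions <- function(x, ...) {
  f <- x$fits
  cat(sprintf(
    "<fs_fd_distributions> %d bins of %g mm; FS N(%.2f, %.2f^2), FD N(%.2f, %.2f^2) [%s]\n",
    nrow(x$binned), x$bin_width, f$mu[f$class == "FS"], f$sigma[f$class == "FS"],
    f$mu[f$class == "FD"], f$sigma[f$class == "FD"], f$method[1]
  ))
  invisible(x)
}

#' Paired bin-wise test of FD versus FS convergence strength
#'
#' Paired t-test of the per-bin summed proportion convergence, FD minus FS,
#' over the common bin grid (dof = number of bins - 1). A constant non-zero
#' difference across bins has zero variance and is reported as an infinite
#' t sentinel.
#'
#' @param distributions an [fs_fd_distributions()] object.
#' @return tibble with t, dof, p, mean_difference, n_bins.
#' @export
fs_fd_paired_test <- function(distributions) {
  b <- distributions$binned
  if (nrow(b) < 2) abort("need at least 2 bins for a paired test")
  d <- b$fd_weight - b$fs_weight
  if (sd(d) == 0) {
    t <- if (mean(d) == 0) 0 else Inf * sign(mean(d))
    p <- if (mean(d) == 0) 1 else 0
    return(tibble::tibble(t = t, dof = nrow(b) - 1L, p = p,
                          mean_difference = mean(d), n_bins = nrow(b)))
  }
  tt <- t.test(b$fd_weight, b$fs_weight, paired = TRUE)
  tibble::tibble(t = unname(tt$statistic), dof = as.integer(tt$parameter),
                 p = tt$p.value, mean_difference = mean(d),
                 n_bins = nrow(b))
}

#' Network-level primary/association convergence percentages
#'
#' Counts the bidirectional convergence edges received by each subcortical
#' network from primary-class (VIS, SOM, CER) versus association-class
#' (DAN, VAN, LIM, CON, DMN) cortical nodes, and reports the percentage
#' split. Networks receiving no connections are reported with `NA`
#' percentages.
#'
#' @inheritParams convergence_counts
#' @param cortical_class named character vector mapping cortical node
#'   labels to `"primary"`/`"association"`.
#' @param subcortical_network named character vector mapping subcortical
#'   node labels to their network (e.g. THA, BGN, SLN).
#' @return tibble: sub_network, n_primary, n_association, pct_primary,
#'   pct_association.
#' @export
network_level_convergence <- function(graph, cortical_class,
                                      subcortical_network) {
  edges <- which(graph != 0, arr.ind = TRUE)
  ctx <- rownames(graph)[edges[, 1]]
  sub <- colnames(graph)[edges[, 2]]
  tab <- tibble::tibble(
    sub_network = unname(subcortical_network[sub]),
    cls = unname(cortical_class[ctx])
  )
  nets <- unique(unname(subcortical_network))
  out <- purrr::map_dfr(nets, function(nw) {
    npr <- sum(tab$sub_network == nw & tab$cls == "primary")
    nas <- sum(tab$sub_network == nw & tab$cls == "association")
    tot <- npr + nas
    tibble::tibble(
      sub_network = nw, n_primary = npr, n_association = nas,
      pct_primary = if (tot > 0) 100 * npr / tot else NA_real_,
      pct_association = if (tot > 0) 100 * nas / tot else NA_real_
    )
  })
  out
}
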