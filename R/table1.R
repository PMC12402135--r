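#' Load the packaged table of converging cortical regions
#'
#' The package ships a table of the 27 subcortical ROIs and the cortical
#' ROIs whose resting-state functional connectivity with them is
#' bidirectionally significant at the group level, with the bilateral parcel
#' centroids (MNI mm), resting-state-network labels and group t-values as
#' printed. Repeated cortical names with distinct centroids are distinct
#' ROIs; cortical node identity is keyed on the centroid tuple, so an entry
#' printed under two subcortical rows with the same centroids is one node.
#'
#' @param path optional path to an alternative table in the same format;
#'   default is the packaged file.
#' @return an object of class `table1_fixture`: a list with
#'   \describe{
#'     \item{edges}{tibble of converging (cortical, subcortical) pairs with
#'       centroids, RSN, subcortical network and t-value,}
#'     \item{subcortical}{tibble of the 27 subcortical ROIs with their
#'       network (THA/BGN/SLN) and printed convergence count,}
#'     \item{cortical}{[parcellation] of the distinct converging cortical
#'       ROIs (one row per distinct centroid tuple),}
#'     \item{incidence}{cortical x subcortical 0/1 convergence matrix.}
#'   }
#' @export
load_table1 <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "table1_convergence.tsv",
                        package = "convorg", mustWork = TRUE)
  }
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = "NA")
  need <- c("sub_index", "sub_label", "sub_network", "n_converging",
            "cortical_label", "rsn", "x1", "y1", "z1", "x2", "y2", "z2",
            "t_value")
  if (!identical(names(raw), need)) abort("convergence table has unexpected columns")

  subcortical <- raw |>
    dplyr::distinct(.data$sub_index, .data$sub_label, .data$sub_network,
                    .data$n_converging) |>
    dplyr::arrange(.data$sub_index) |>
    tibble::as_tibble()
  if (nrow(subcortical) != 27L) abort("expected 27 subcortical ROIs")

  edges <- raw |>
    dplyr::filter(!is.na(.data$cortical_label)) |>
    tibble::as_tibble()
  edges$roi_key <- with(edges, paste(x1, y1, z1, x2, y2, z2))

  # internal consistency ("checksum"): edge rows must reproduce the printed
  # convergence count of every subcortical ROI, and a cortical node must
  # carry one RSN label.
  cnt <- dplyr::count(edges, .data$sub_label, name = "n_edges")
  chk <- dplyr::left_join(subcortical, cnt, by = "sub_label")
  chk$n_edges[is.na(chk$n_edges)] <- 0L
  if (!all(chk$n_edges == chk$n_converging)) {
    abort("convergence table is corrupt: edge rows do not match printed counts")
  }
  rsn_chk <- edges |>
    dplyr::group_by(.data$roi_key) |>
    dplyr::summarise(n_rsn = dplyr::n_distinct(.data$rsn), .groups = "drop")
  if (any(rsn_chk$n_rsn > 1L)) {
    abort("convergence table is corrupt: inconsistent RSN within a cortical node")
  }
  if (!all(is.finite(edges$x1) & is.finite(edges$y1) & is.finite(edges$z1))) {
    abort("convergence table is corrupt: non-finite first centroid")
  }

  distinct_ctx <- edges |>
    dplyr::distinct(.data$roi_key, .keep_all = TRUE) |>
    dplyr::arrange(.data$sub_index, .data$cortical_label)
  ctx_label <- sprintf("CTX%02d_%s", seq_len(nrow(distinct_ctx)),
                       gsub("[^A-Za-z0-9]+", "", distinct_ctx$cortical_label))
  key_to_label <- setNames(ctx_label, distinct_ctx$roi_key)
  edges$cortical_id <- unname(key_to_label[edges$roi_key])

  ctx_class <- ifelse(distinct_ctx$rsn == "CER", "cerebellar", "cortical")
  cortical <- parcellation(
    label = ctx_label, class = ctx_class, rsn = distinct_ctx$rsn,
    x1 = distinct_ctx$x1, y1 = distinct_ctx$y1, z1 = distinct_ctx$z1,
    x2 = distinct_ctx$x2, y2 = distinct_ctx$y2, z2 = distinct_ctx$z2
  )
  cortical$printed_label <- distinct_ctx$cortical_label

  incidence <- matrix(0L, nrow(cortical), 27L,
                      dimnames = list(cortical$label, subcortical$sub_label))
  incidence[cbind(match(edges$cortical_id, cortical$label),
                  match(edges$sub_label, subcortical$sub_label))] <- 1L

  structure(
    list(edges = edges, subcortical = subcortical, cortical = cortical,
         incidence = incidence),
    class = "table1_fixture"
  )
}

#' @export
print.table1_fixture <- function(x, ...) {
  cat(sprintf(
    "<table1_fixture> %d converging edges, %d distinct cortical ROIs, 27 subcortical ROIs\n",
    sum(x$incidence), nrow(x$cortical)
  ))
  invisible(x)
}

#' Convergence and distance analysis of the packaged table
#'
#' Runs the convergence statistics end to end on the packaged table of
#' converging cortical regions: per-ROI convergence counts, network-level
#' primary/association percentages, proportion convergence over cortical
#' pairs, bilateral distances, the functionally-similar/diverse (FS/FD)
#' binned distributions with normal fits, and the paired bin-wise test.
#'
#' @param bin_width histogram bin width in mm (default 8).
#' @param max_distance distance spanned by the bin grid, mm. The default
#'   168 mm covers the full extent of the cortical sheet (21 bins of 8 mm);
#'   `NULL` uses the maximum observed pair distance instead.
#' @param fit normal-fit method passed to [fs_fd_distributions()].
#' @return a list of class `table1_analysis` with elements `counts`,
#'   `network_level`, `pairs`, `distributions`, `paired_test`.
#' @export
run_table1_analysis <- function(bin_width = 8, max_distance = 168,
                                fit = c("lsq", "moments")) {
  fit <- match.arg(fit)
  fx <- load_table1()
  counts <- convergence_counts(fx$incidence)
  nl <- network_level_convergence(
    fx$incidence,
    cortical_class = setNames(fx$cortical$network_class, fx$cortical$label),
    subcortical_network = setNames(fx$subcortical$sub_network,
                                   fx$subcortical$sub_label)
  )
  pairs <- convergence_pairs(fx$incidence, fx$cortical)
  dist <- fs_fd_distributions(pairs, bin_width = bin_width,
                              max_distance = max_distance, fit = fit)
  test <- fs_fd_paired_test(dist)
  structure(
    list(counts = counts, network_level = nl, pairs = pairs,
         distributions = dist, paired_test = test),
    class = "table1_analysis"
  )
}
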