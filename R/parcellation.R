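#' Build a parcellation table
#'
#' A parcellation is a tibble with one row per region of interest (ROI). An
#' ROI is a bilateral pair of atlas parcels merged into one node; medial
#' regions (e.g. cerebellar vermis) carry a single centroid and leave the
#' second centroid as `NA`. The resting-state-network class splits the eight
#' cortical networks into primary (VIS, SOM, CER) and association
#' (DAN, VAN, LIM, CON, DMN) systems.
#'
#' @param label character, unique ROI labels.
#' @param class one of `"cortical"`, `"cerebellar"`, `"subcortical"` per ROI.
#' @param rsn resting-state network label; required (one of VIS, SOM, DAN,
#'   VAN, LIM, CON, DMN, CER) for cortical and cerebellar ROIs, may be `NA`
#'   or a subcortical community label (THA, BGN, SLN) for subcortical ROIs.
#' @param x1,y1,z1 left-hemisphere (or medial) centroid, MNI mm.
#' @param x2,y2,z2 right-hemisphere centroid, `NA` for medial ROIs.
#' @param voxel_count positive integer region size (2 mm isotropic voxels);
#'   optional (`NA` allowed) but required by connection-density metrics.
#' @return a tibble of class `parcellation` with a derived `network_class`
#'   column (`primary`/`association`/`not_applicable`).
#' @export
parcellation <- function(label, class, rsn,
                         x1, y1, z1, x2 = NA_real_, y2 = NA_real_,
                         z2 = NA_real_, voxel_count = NA_integer_) {
  out <- tibble::tibble(
    label = as.character(label),
    class = as.character(class),
    rsn = as.character(rsn),
    x1 = as.numeric(x1), y1 = as.numeric(y1), z1 = as.numeric(z1),
    x2 = as.numeric(x2), y2 = as.numeric(y2), z2 = as.numeric(z2),
    voxel_count = as.integer(voxel_count)
  )
  out$network_class <- rsn_class(out$rsn)
  validate_parcellation(out)
}

validate_parcellation <- function(x) {
  if (anyDuplicated(x$label)) {
    abort(paste0("duplicated ROI labels: ",
                 paste(unique(x$label[duplicated(x$label)]), collapse = ", ")))
  }
  bad_class <- setdiff(unique(x$class),
                       c("cortical", "cerebellar", "subcortical"))
  if (length(bad_class)) {
    abort(paste0("unknown ROI class: ", paste(bad_class, collapse = ", ")))
  }
  ctx <- x$class %in% c("cortical", "cerebellar")
  bad_rsn <- ctx & (is.na(x$rsn) | !(x$rsn %in% CORTICAL_RSNS))
  if (any(bad_rsn)) {
    abort(paste0("cortical/cerebellar ROIs must carry one of the 8 cortical ",
                 "network labels; offending: ",
                 paste(x$label[bad_rsn], collapse = ", ")))
  }
  has_c1 <- complete.cases(x[, c("x1", "y1", "z1")])
  partial2 <- rowSums(is.na(x[, c("x2", "y2", "z2")])) %in% c(1L, 2L)
  if (any(partial2)) {
    abort(paste0("second centroid must be fully present or fully absent: ",
                 paste(x$label[partial2], collapse = ", ")))
  }
  if (any(!has_c1 & complete.cases(x[, c("x2", "y2", "z2")]))) {
    abort("an ROI cannot have a second centroid without a first")
  }
  if (any(!is.na(x$voxel_count) & x$voxel_count < 1L)) {
    abort("voxel_count must be >= 1")
  }
  class(x) <- c("parcellation", class(tibble::tibble()))
  x
}

#' Read or write a parcellation table (TSV)
#'
#' @param path file path. Columns: label, class, rsn, x1, y1, z1,
#'   x2, y2, z2, voxel_count (tab-separated, header row).
#' @return `read_parcellation()` returns a validated [parcellation] tibble;
#'   `write_parcellation()` returns `path` invisibly.
#' @export
read_parcellation <- function(path) {
  raw <- utils::read.delim(path, check.names = FALSE, na.strings = c("NA", ""))
  need <- c("label", "class", "rsn", "x1", "y1", "z1")
  miss <- setdiff(need, names(raw))
  if (length(miss)) {
    abort(paste0("parcellation file missing columns: ",
                 paste(miss, collapse = ", ")))
  }
  for (col in c("x2", "y2", "z2")) if (is.null(raw[[col]])) raw[[col]] <- NA_real_
  if (is.null(raw$voxel_count)) raw$voxel_count <- NA_integer_
  parcellation(raw$label, raw$class, raw$rsn, raw$x1, raw$y1, raw$z1,
               raw$x2, raw$y2, raw$z2, raw$voxel_count)
}

#' @rdname read_parcellation
#' @param parc a [parcellation] tibble.
#' @export
write_parcellation <- function(parc, path) {
  cols <- c("label", "class", "rsn", "x1", "y1", "z1", "x2", "y2", "z2",
            "voxel_count")
  utils::write.table(as.data.frame(parc)[, cols], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}
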