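#' Construct a multi-subject, multi-session time-series panel
#'
#' A panel holds one ROI-by-time matrix per (subject, session); all matrices
#' share the same ROI columns in the same order. Matrices are stored
#' time x ROI (one row per time point).
#'
#' @param data nested list: `data[[subject]][[session]]` is a numeric
#'   time x ROI matrix. Subject and session names are taken from the list
#'   names.
#' @param roi_labels character vector of ROI labels (column order).
#' @param tr_seconds repetition time in seconds (positive).
#' @return an object of class `ts_panel`.
#' @export
ts_panel <- function(data, roi_labels, tr_seconds = 0.72) {
  stopifnot(is.list(data), length(data) >= 1, tr_seconds > 0)
  subjects <- names(data)
  if (is.null(subjects) || any(subjects == "")) {
    abort("data must be a named list keyed by subject id")
  }
  sessions <- names(data[[1]])
  n_roi <- length(roi_labels)
  for (s in subjects) {
    if (!identical(names(data[[s]]), sessions)) {
      abort("all subjects must have the same sessions, in the same order")
    }
    for (ses in sessions) {
      m <- data[[s]][[ses]]
      if (!is.matrix(m) || !is.numeric(m)) {
        abort(sprintf("entry (%s, %s) is not a numeric matrix", s, ses))
      }
      if (ncol(m) != n_roi) {
        abort(sprintf("entry (%s, %s) has %d columns, expected %d ROIs",
                      s, ses, ncol(m), n_roi))
      }
      colnames(data[[s]][[ses]]) <- roi_labels
    }
  }
  structure(
    list(data = data, subject_ids = subjects, session_ids = sessions,
         roi_labels = as.character(roi_labels), tr_seconds = tr_seconds),
    class = "ts_panel"
  )
}

#' @export
print.ts_panel <- function(x, ...) {
  cat(sprintf(
    "<ts_panel> %d subjects x %d sessions, %d ROIs, TR = %gs\n",
    length(x$subject_ids), length(x$session_ids), length(x$roi_labels),
    x$tr_seconds
  ))
  invisible(x)
}

#' Read a time-series panel from delimited text files
#'
#' Each file is a tab- or comma-separated time x ROI matrix with a header
#' row of ROI labels and one row per time point. All files must agree on
#' the ROI set; columns are reordered to the first file's (or the supplied)
#' label order, so on-disk column order never matters.
#'
#' @param files a data frame with columns `subject`, `session`, `path`.
#' @param roi_labels optional character vector fixing the ROI order; default
#'   is the column order of the first file.
#' @param tr_seconds repetition time in seconds.
#' @return a [ts_panel].
#' @export
read_panel <- function(files, roi_labels = NULL, tr_seconds = 0.72) {
  stopifnot(all(c("subject", "session", "path") %in% names(files)))
  read_one <- function(path) {
    first <- readLines(path, n = 1L)
    sep <- if (grepl("\t", first)) "\t" else ","
    raw <- tryCatch(
      utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                        colClasses = "numeric"),
      error = function(e) abort(sprintf(
        "ragged matrix or non-numeric cells in '%s': %s", path, conditionMessage(e)))
    )
    as.matrix(raw)
  }
  mats <- lapply(files$path, read_one)
  if (is.null(roi_labels)) roi_labels <- colnames(mats[[1]])
  mats <- lapply(seq_along(mats), function(k) {
    m <- mats[[k]]
    miss <- setdiff(roi_labels, colnames(m))
    extra <- setdiff(colnames(m), roi_labels)
    if (length(miss) || length(extra)) {
      abort(sprintf("unknown or missing ROI labels in '%s': %s",
                    files$path[k], paste(c(miss, extra), collapse = ", ")))
    }
    m[, roi_labels, drop = FALSE]
  })
  data <- list()
  for (k in seq_len(nrow(files))) {
    s <- as.character(files$subject[k]); ses <- as.character(files$session[k])
    data[[s]][[ses]] <- mats[[k]]
  }
  ts_panel(data, roi_labels, tr_seconds)
}

#' Write a panel to TSV files (one per subject-session)
#'
#' @param panel a [ts_panel].
#' @param dir output directory (created if absent).
#' @return invisibly, a tibble with columns subject, session, path.
#' @export
write_panel <- function(panel, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  idx <- tidyr::expand_grid(subject = panel$subject_ids,
                            session = panel$session_ids)
  idx$path <- file.path(dir, sprintf("%s_%s.tsv", idx$subject, idx$session))
  for (k in seq_len(nrow(idx))) {
    m <- panel$data[[idx$subject[k]]][[idx$session[k]]]
    utils::write.table(m, idx$path[k], sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(idx)
}
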