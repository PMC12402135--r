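#' Plot a resolution sweep
#'
#' Confidence (mean silhouette) and number of communities per gamma and
#' matrix type.
#'
#' @param object a [gamma_sweep()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.gamma_sweep <- function(object, ...) {
  df <- object$sweep |>
    tidyr::pivot_longer(c("confidence", "n_communities"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$gamma, y = .data$value,
                                   colour = .data$matrix)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(ggplot2::vars(.data$quantity), scales = "free_y",
                        ncol = 1) +
    ggplot2::labs(x = expression(gamma), y = NULL, colour = "matrix") +
    ggplot2::theme_minimal()
}

#' Plot FS/FD binned distance distributions with their normal fits
#'
#' @param object an [fs_fd_distributions()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.fs_fd_distributions <- function(object, ...) {
  b <- object$binned |>
    tidyr::pivot_longer(c("fs_weight", "fd_weight"), names_to = "class",
                        values_to = "weight") |>
    dplyr::mutate(class = ifelse(.data$class == "fs_weight", "FS", "FD"))
  curves <- purrr::pmap_dfr(object$fits, function(class, mu, sigma, weight,
                                                  method) {
    if (is.na(mu)) return(tibble::tibble())
    x <- seq(0, max(object$binned$upper), length.out = 200)
    amp <- max(object$binned[[if (class == "FS") "fs_weight" else "fd_weight"]])
    tibble::tibble(class = class, x = x,
                   y = amp * exp(-(x - mu)^2 / (2 * sigma^2)))
  })
  ggplot2::ggplot(b, ggplot2::aes(x = .data$upper - object$bin_width / 2,
                                  y = .data$weight)) +
    ggplot2::geom_col(fill = "grey70", width = object$bin_width * 0.9) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(x = .data$x, y = .data$y),
                       colour = "steelblue") +
    ggplot2::facet_wrap(ggplot2::vars(.data$class), ncol = 1) +
    ggplot2::labs(x = "pair distance (mm)", y = "summed proportion convergence") +
    ggplot2::theme_minimal()
}

#' Plot an attack report
#'
#' Null local-efficiency distributions with the targeted value marked.
#'
#' @param object an [attack_analysis()] result.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.attack_report <- function(object, ...) {
  df <- dplyr::bind_rows(
    tibble::tibble(condition = "random", le = object$unrestricted$null_le),
    tibble::tibble(condition = "restricted random", le = object$restricted$null_le)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$le)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey70") +
    ggplot2::geom_vline(xintercept = object$targeted$le_target,
                        colour = "firebrick") +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition), ncol = 1) +
    ggplot2::labs(x = "local efficiency", y = "simulations") +
    ggplot2::theme_minimal()
}

#' Bar chart of per-subcortical convergence counts
#'
#' @param counts tibble from [convergence_counts()].
#' @return a ggplot object.
#' @export
plot_convergence_counts <- function(counts) {
  ggplot2::ggplot(counts, ggplot2::aes(
    x = stats::reorder(.data$sub_label, .data$n_converging),
    y = .data$n_converging)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "converging cortical ROIs") +
    ggplot2::theme_minimal()
}
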