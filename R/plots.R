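#' Heatmap of a functional connectivity matrix
#'
#' @param object An [fc_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.fc_matrix <- function(object, ...) {
  V <- as_fc_values(object)
  df <- tibble::tibble(
    i = rep(seq_len(nrow(V)), times = ncol(V)),
    j = rep(seq_len(ncol(V)), each = nrow(V)),
    fc = as.vector(V)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$j, y = .data$i,
                                   fill = .data$fc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "FC")
}

#' Objective trace and per-repetition optima of a sigma fit
#'
#' @param object A `fic_fit` object.
#' @param ... Unused.
#' @return A ggplot object: evaluated (sigma, 1-SSIM) points coloured by
#'   repetition, with vertical lines at the per-repetition optima.
#' @export
autoplot.fic_fit <- function(object, ...) {
  tr <- dplyr::bind_rows(object$trace)
  ggplot2::ggplot(tr, ggplot2::aes(x = .data$sigma, y = .data$objective,
                                   colour = factor(.data$rep))) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_vline(data = object$per_rep,
                        ggplot2::aes(xintercept = .data$sigma_hat,
                                     colour = factor(.data$rep)),
                        linetype = 2, show.legend = FALSE) +
    ggplot2::labs(x = expression(sigma), y = "1 - SSIM",
                  colour = "repetition")
}

#' Radar-style plot of RSN overlap scores
#'
#' @param overlap Tibble from [rsn_overlap()].
#' @return A ggplot object (polar bar chart of Jaccard indices).
#' @export
plot_rsn_overlap <- function(overlap) {
  ggplot2::ggplot(overlap, ggplot2::aes(x = .data$network,
                                        y = .data$jaccard)) +
    ggplot2::geom_col(width = 0.9) +
    ggplot2::coord_polar() +
    ggplot2::ylim(0, max(overlap$jaccard) * 1.1 + 1e-9) +
    ggplot2::labs(x = NULL, y = "Jaccard")
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
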