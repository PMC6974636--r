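#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a match report over its peak list
#'
#' Stem plot of the queried ions: calculated m/z on the x axis, ppm error
#' on the y axis, detected ions filled. A quick visual check that every
#' expected species was found inside tolerance.
#'
#' @param object A `match_report` from [screen_species()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot match_report
#' @export
autoplot.match_report <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$ppm_plot <- ifelse(df$detected, df$ppm, 0)
  tol <- attr(object, "tol_ppm")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$ppm_plot,
                                   shape = .data$detected,
                                   colour = .data$species)) +
    ggplot2::geom_hline(yintercept = c(-tol, tol), linetype = "dashed",
                        colour = "grey50") +
    ggplot2::geom_hline(yintercept = 0, colour = "grey80") +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 4)) +
    ggplot2::labs(x = "calculated m/z", y = "mass error (ppm)",
                  shape = "detected", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a fragment ladder
#'
#' @param object A `fragment_ladder` from [y_ion_ladder()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fragment_ladder
#' @export
autoplot.fragment_ladder <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- paste0("y", df$index)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$index)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          colour = "grey70") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$rearranged), size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label), hjust = -0.3,
                       size = 3) +
    ggplot2::labs(x = "m/z (z = 1)", y = "fragment index n",
                  colour = "rearranged") +
    ggplot2::theme_minimal()
}

#' Plot a simulated or observed peak list
#'
#' @param peaks A `peaklist` (or data frame with `mz`).
#' @param truth Optional ground-truth tibble from [simulate_peaklist()];
#'   true peaks are then coloured by species.
#' @return A ggplot object.
#' @export
plot_peaklist <- function(peaks, truth = NULL) {
  df <- tibble::as_tibble(as_peaklist(peaks))
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$mz, y = .data$intensity)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$mz, yend = 0),
                          colour = "grey40") +
    ggplot2::labs(x = "m/z", y = "intensity") +
    ggplot2::theme_minimal()
  if (!is.null(truth)) {
    tr <- truth[truth$kind == "true" & truth$included, ]
    p <- p + ggplot2::geom_segment(
      data = tr,
      ggplot2::aes(x = .data$mz, xend = .data$mz, y = Inf, yend = 0,
                   colour = .data$species),
      alpha = 0.25, linewidth = 2, inherit.aes = FALSE
    )
  }
  p
}
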