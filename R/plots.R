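# ggplot2 helpers for the main result types.

#' Plot per-sample circRNA totals by region and condition
#'
#' @param totals Tibble from [circ_totals_per_sample()] with region and
#'   condition columns.
#' @return A ggplot.
#' @export
plot_circ_totals <- function(totals) {
  ggplot2::ggplot(totals, ggplot2::aes(x = .data$region, y = .data$total,
                                       fill = .data$condition)) +
    ggplot2::geom_boxplot(outlier.shape = 21, alpha = 0.8) +
    ggplot2::labs(x = NULL, y = "circRNA total (per million mapped reads)",
                  fill = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the mismatch spectrum of the editing index
#'
#' A-to-G should dominate when the signal is real editing rather than
#' noise.
#'
#' @param spectrum Tibble from [mismatch_spectrum()] (optionally several
#'   samples/regions row-bound).
#' @return A ggplot.
#' @export
plot_mismatch_spectrum <- function(spectrum) {
  ggplot2::ggplot(spectrum,
                  ggplot2::aes(x = .data$mismatch, y = .data$index_percent)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "mismatch type (transcribed orientation)",
                  y = "editing index (%)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Plot seed sites on a circular sequence
#'
#' Positions of the reported sites around the circle, junction-spanning
#' sites highlighted.
#'
#' @param sites Tibble from [scan_seed_sites()].
#' @param circle_len Circle length (nt).
#' @return A ggplot.
#' @export
plot_seed_sites <- function(sites, circle_len) {
  ggplot2::ggplot(sites,
                  ggplot2::aes(x = .data$position, y = 1,
                               shape = .data$spans_junction,
                               colour = .data$site_class)) +
    ggplot2::geom_point(size = 3) +
    ggplot2::scale_x_continuous(limits = c(0, circle_len)) +
    ggplot2::scale_shape_manual(values = c(`FALSE` = 16, `TRUE` = 17)) +
    ggplot2::labs(x = "position on circle (nt)", y = NULL,
                  colour = "site class", shape = "spans junction") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

#' Autoplot a qPCR standard curve
#'
#' @param object A `circ_std_curve`.
#' @param ... Unused.
#' @return A ggplot of Cq against log10 copies with the fitted line.
#' @export
#' @method autoplot circ_std_curve
autoplot.circ_std_curve <- function(object, ...) {
  d <- object$model$model
  ggplot2::ggplot(tibble(log10_copies = d$lc, cq = d$cq),
                  ggplot2::aes(x = .data$log10_copies, y = .data$cq)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(slope = object$slope,
                         intercept = object$intercept,
                         colour = "steelblue") +
    ggplot2::labs(x = "log10(copies)", y = "Cq",
                  subtitle = sprintf("slope %.3f, efficiency %.2f",
                                     object$slope, object$efficiency)) +
    ggplot2::theme_minimal()
}
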