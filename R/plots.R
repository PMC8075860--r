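#' Plot clone VAFs of one sample
#'
#' Bar chart of the reported clones' variant allele frequencies,
#' labelled by length and insertion site, trailing clones marked.
#'
#' @param object An `itd_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itd_result <- function(object, ...) {
  clones <- object$clones
  if (nrow(clones) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no ITDs") +
             ggplot2::theme_void())
  }
  clones <- dplyr::mutate(
    clones,
    label = sprintf("%d bp @ %d%s", .data$length_estimate, .data$ref_pos,
                    ifelse(.data$trailing, " (trailing)", ""))
  )
  ggplot2::ggplot(clones,
                  ggplot2::aes(x = stats::reorder(.data$label, -.data$vaf),
                               y = .data$vaf, fill = .data$trailing)) +
    ggplot2::geom_col() +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%g%%", 100 * v)) +
    ggplot2::labs(x = NULL, y = "VAF", fill = "trailing",
                  title = object$sample) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30,
                                                       hjust = 1))
}

#' Plot measured versus expected VAF of a dilution series
#'
#' Log-log scatter of measured against expected VAF with the identity
#' line; the fitted R-squared is shown in the subtitle.
#'
#' @param object An `itd_linearity`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.itd_linearity <- function(object, ...) {
  dat <- dplyr::filter(object$data, .data$expected > 0, .data$measured > 0)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$expected,
                                    y = .data$measured)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey50") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "expected VAF", y = "measured VAF",
                  subtitle = sprintf("R² = %.6f (n = %d)",
                                     object$r_squared, object$n)) +
    ggplot2::theme_minimal()
}

#' Plot clone trajectories across serial samples
#'
#' VAF of each tracked clone over the sampled timepoints on a log scale,
#' coloured by category (persisting / lost / gained / transient), the
#' display used for following measurable residual disease clone by
#' clone. Timepoints where a clone was not detected are dropped from its
#' line.
#'
#' @param trajectories Trajectory tibble from [track_clones()].
#' @return A ggplot object.
#' @export
plot_clone_trajectories <- function(trajectories) {
  dat <- dplyr::filter(trajectories, !is.na(.data$vaf))
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$timepoint, y = .data$vaf,
                               group = .data$clone_id,
                               colour = .data$category,
                               shape = .data$category)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "VAF", colour = "clone", shape = "clone") +
    ggplot2::theme_minimal()
}
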