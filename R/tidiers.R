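#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy an ITD calling result
#'
#' @param x An `itd_result`.
#' @param ... Unused.
#' @return The clone tibble, one row per reported clone.
#' @export
tidy.itd_result <- function(x, ...) {
  x$clones
}

#' One-row summary of an ITD calling result
#'
#' @param x An `itd_result`.
#' @param ... Unused.
#' @return The sample summary tibble.
#' @export
glance.itd_result <- function(x, ...) {
  x$summary
}

#' Tidy a VAF linearity fit
#'
#' @param x An `itd_linearity`.
#' @param ... Unused.
#' @return A tibble of the expected/measured pairs with fitted values
#'   and residuals.
#' @export
tidy.itd_linearity <- function(x, ...) {
  fitted <- x$intercept + x$slope * x$data$expected
  dplyr::mutate(x$data, fitted = fitted,
                residual = .data$measured - fitted)
}

#' One-row summary of a VAF linearity fit
#'
#' @param x An `itd_linearity`.
#' @param ... Unused.
#' @return A tibble with `r_squared`, `slope`, `intercept` and `n`.
#' @export
glance.itd_linearity <- function(x, ...) {
  tibble::tibble(r_squared = x$r_squared, slope = x$slope,
                 intercept = x$intercept, n = x$n)
}
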