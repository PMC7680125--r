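#' Plot a fitted Hill binding curve
#'
#' Points are the titration measurements; the line is the fitted Hill
#' curve on a log-friendly concentration axis.
#'
#' @param object A [fit_hill()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.hill_fit <- function(object, ...) {
  dat <- object$data
  grid <- tibble::tibble(
    concentration = seq(0, max(dat$concentration), length.out = 200)
  )
  grid$fraction_bound <- hill_curve(grid$concentration, object$kd, object$h)
  ggplot2::ggplot(dat, ggplot2::aes(.data$concentration, .data$fraction_bound)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_line(data = grid, colour = "firebrick") +
    ggplot2::labs(
      x = "[remodeler] (nM)", y = "fraction bound",
      title = sprintf("Hill fit: K_D = %.3g nM, H = %.3g, R² = %.3f",
                      object$kd, object$h, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a fitted time course and its initial-rate tangent
#'
#' @param object A [fit_initial_rate()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.rate_fit <- function(object, ...) {
  dat <- object$data
  p <- ggplot2::ggplot(dat, ggplot2::aes(.data$time, .data$signal)) +
    ggplot2::geom_point()
  if (object$method == "exponential") {
    grid <- tibble::tibble(time = seq(0, max(dat$time), length.out = 200))
    grid$signal <- object$plateau * (1 - exp(-object$k * grid$time))
    p <- p + ggplot2::geom_line(data = grid, colour = "firebrick")
  }
  p +
    ggplot2::geom_abline(intercept = 0, slope = object$v0,
                         linetype = "dashed", colour = "grey40") +
    ggplot2::labs(x = "time (s)", y = "signal (nM)",
                  title = sprintf("v0 = %.3g ± %.3g nM/s", object$v0,
                                  object$se)) +
    ggplot2::theme_minimal()
}

#' Plot a +1-aligned metagene profile
#'
#' Overlays the two conditions' mean dyad densities on the shared
#' +1-anchored axis, the standard way repositioning shows up as peak
#' displacement.
#'
#' @param object A [metagene_profile()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metagene_profile <- function(object, ...) {
  long <- tidyr::pivot_longer(object$profile, c("mean_a", "mean_b"),
                              names_to = "condition", values_to = "density")
  long$condition <- c(mean_a = "A", mean_b = "B")[long$condition]
  ggplot2::ggplot(long, ggplot2::aes(.data$offset, .data$density,
                                     colour = .data$condition)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "offset from +1 dyad (bp)",
                  y = "mean normalized dyad density",
                  title = sprintf("metagene profile (%d genes)", object$n_genes)) +
    ggplot2::theme_minimal()
}

#' Histogram of TSS-signed shifts by nucleosome position
#'
#' @param shift_results A [run_shift_analysis()] tibble.
#' @param positions Position indices to facet over (default 1:4).
#' @return A ggplot.
#' @export
plot_shift_distribution <- function(shift_results, positions = 1:4) {
  d <- dplyr::filter(shift_results, .data$position_index %in% positions,
                     !is.na(.data$shift))
  ggplot2::ggplot(d, ggplot2::aes(.data$shift, fill = .data$significant)) +
    ggplot2::geom_histogram(binwidth = 1) +
    ggplot2::facet_wrap(~position_index,
                        labeller = ggplot2::as_labeller(function(x) paste0("+", x))) +
    ggplot2::labs(x = "TSS-signed shift (bp)", y = "nucleosome pairs") +
    ggplot2::theme_minimal()
}
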