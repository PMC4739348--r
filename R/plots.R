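## ggplot2 views of the pipeline's result types.

#' Map a population, optionally shaded by local social context
#'
#' Points at each plant's coordinates. With `shade_radius` given, point
#' fill shows the local hermaphrodite frequency at that radius (plants with
#' no neighbor are hollow); otherwise points are colored by sex.
#'
#' @param map population map tibble.
#' @param shade_radius optional radius (m) for local-frequency shading.
#' @return a ggplot.
#' @export
plot_population <- function(map, shade_radius = NULL) {
  check_population_map(map)
  if (is.null(shade_radius)) {
    p <- ggplot2::ggplot(map, ggplot2::aes(.data$x, .data$y, color = .data$sex)) +
      ggplot2::geom_point(size = 2)
  } else {
    prof <- neighborhood_profiles(map, radii = shade_radius)
    d <- dplyr::left_join(map, dplyr::select(prof, "plant_id", "local_freq"),
                          by = "plant_id")
    p <- ggplot2::ggplot(d, ggplot2::aes(.data$x, .data$y, fill = .data$local_freq)) +
      ggplot2::geom_point(shape = 21, size = 2.5) +
      ggplot2::scale_fill_gradient(
        low = "grey95", high = "grey10", na.value = "white",
        name = sprintf("herm. freq.\n(r = %g m)", shade_radius)
      )
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "x (m)", y = "y (m)") +
    ggplot2::theme_minimal()
}

#' Variance of local hermaphrodite frequency against spatial scale
#'
#' The contraction-of-variance curve: sample variance of the local
#' frequency at each radius.
#'
#' @param summary a [scale_summary()] table.
#' @return a ggplot.
#' @export
plot_scale_variance <- function(summary) {
  stopifnot(all(c("radius", "var_freq") %in% names(summary)))
  ggplot2::ggplot(summary, ggplot2::aes(.data$radius, .data$var_freq)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "radius (m)", y = "variance of local hermaphrodite frequency") +
    ggplot2::theme_minimal()
}

#' Standardized sex/context covariance against spatial scale
#'
#' @param cov_profile a [covariance_profile()] table.
#' @param convention `"correlation"` or `"pii"` standardization.
#' @return a ggplot.
#' @export
plot_covariance_profile <- function(cov_profile,
                                    convention = c("correlation", "pii")) {
  col <- std_column(convention)
  d <- dplyr::mutate(cov_profile, C_std = .data[[col]])
  ggplot2::ggplot(d, ggplot2::aes(.data$radius, .data$C_std)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, color = "grey50") +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "radius (m)",
                  y = "variance-standardized covariance C'") +
    ggplot2::theme_minimal()
}

#' @method autoplot socsel_corr
#' @export
autoplot.socsel_corr <- function(object, ...) {
  d <- tidy(object)
  d2 <- dplyr::rename(d, radius1 = "radius2", radius2 = "radius1")
  diag_d <- tibble::tibble(radius1 = object$radii, radius2 = object$radii,
                           estimate = 1)
  all_d <- dplyr::bind_rows(
    dplyr::select(d, "radius1", "radius2", "estimate"),
    dplyr::select(d2, "radius1", "radius2", "estimate"),
    diag_d
  )
  ggplot2::ggplot(all_d, ggplot2::aes(factor(.data$radius1), factor(.data$radius2),
                                      fill = .data$estimate)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "grey95", high = "grey10",
                                 limits = c(0, 1), name = "r") +
    ggplot2::labs(x = "radius (m)", y = "radius (m)") +
    ggplot2::coord_equal() +
    ggplot2::theme_minimal()
}

#' @method autoplot socsel_perm
#' @export
autoplot.socsel_perm <- function(object, bins = 30, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(.data$C_std)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey75", color = "white") +
    ggplot2::geom_vline(xintercept = object$observed, color = "black",
                        linewidth = 0.8) +
    ggplot2::labs(
      x = sprintf("C_std under label permutation (r = %g m)", object$radius),
      y = "count",
      subtitle = sprintf("observed %.3f, p = %.3g", object$observed, object$p_value)
    ) +
    ggplot2::theme_minimal()
}

#' Critical social gradient threshold curve
#'
#' @param thresholds a [selection_thresholds()] table.
#' @return a ggplot.
#' @export
plot_thresholds <- function(thresholds) {
  stopifnot(all(c("radius", "beta_S_star") %in% names(thresholds)))
  ggplot2::ggplot(thresholds, ggplot2::aes(.data$radius, .data$beta_S_star)) +
    ggplot2::geom_line(color = "grey60") +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "radius (m)",
                  y = expression("critical social gradient " * beta[S]^"*")) +
    ggplot2::theme_minimal()
}
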