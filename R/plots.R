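#' Plot a fitted DCC detection model over the calibration data
#'
#' Per-cell colocalization ratios (points), per-protein means (diamonds) and
#' the fitted expected-ratio curve over the oligomeric state.
#'
#' @param object A `"dcc_fit"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dcc_fit
#' @export
autoplot.dcc_fit <- function(object, ...) {
  dat <- object$data
  means <- dat |>
    dplyr::group_by(.data$n) |>
    dplyr::summarise(pd = mean(.data$pd), .groups = "drop")
  curve_n <- seq(1, object$n_max, by = 0.05)
  curve <- tibble::tibble(
    n = curve_n,
    pd = vapply(curve_n, function(nn) {
      # fractional n only for display: interpolate the integer model
      lo <- floor(nn); hi <- ceiling(nn); w <- nn - lo
      e <- dcc_expected(unique(c(lo, hi)), object$p, object$m)
      if (lo == hi) e[1] else (1 - w) * e[1] + w * e[2]
    }, 1))
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$n, y = .data$pd)) +
    ggplot2::geom_jitter(width = 0.08, height = 0, alpha = 0.4, size = 1) +
    ggplot2::geom_line(data = curve, color = "black") +
    ggplot2::geom_point(data = means, shape = 5, size = 3, stroke = 1) +
    ggplot2::scale_x_continuous(breaks = seq_len(object$n_max)) +
    ggplot2::labs(x = "oligomeric state n",
                  y = "colocalization ratio",
                  title = sprintf("DCC %s model: p = %.2f%s, R² = %.2f",
                                  object$model, object$p,
                                  if (!is.null(object$m))
                                    sprintf(", m = %.2f", object$m) else "",
                                  object$r_squared)) +
    ggplot2::theme_minimal()
}

#' Plot mismatch coefficients per candidate oligomeric state
#'
#' Bootstrap mean of the mismatch coefficient with its confidence interval
#' for each candidate state; the inferred state is the minimum.
#'
#' @param object A `"dcc_classification"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dcc_classification
#' @export
autoplot.dcc_classification <- function(object, ...) {
  st <- object$states
  ggplot2::ggplot(st, ggplot2::aes(x = .data$n, y = .data$m2_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$m2_lo, ymax = .data$m2_hi),
                           width = 0.15) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = st[st$n == object$n_star, ],
                        color = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = st$n) +
    ggplot2::labs(x = "candidate oligomeric state n",
                  y = expression(M^2),
                  title = sprintf("inferred state n* = %d", object$n_star)) +
    ggplot2::theme_minimal()
}

#' Plot a radial distribution profile
#'
#' @param profile Output of [rdf()].
#' @param baseline Independence level drawn as a dashed line.
#' @return A ggplot object.
#' @export
plot_rdf <- function(profile, baseline = 1) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$r_min + (.data$r_max - .data$r_min) / 2,
                                        y = .data$g)) +
    ggplot2::geom_step() +
    ggplot2::geom_hline(yintercept = baseline, linetype = "dashed") +
    ggplot2::labs(x = "distance r (nm)", y = "g(r)") +
    ggplot2::theme_minimal()
}

#' Plot the adjacent-state separation surface
#'
#' @param surface Output of [sensitivity_surface()].
#' @return A ggplot heat map of the minimal adjacent-state gap over (m, p).
#' @export
plot_sensitivity <- function(surface) {
  ggplot2::ggplot(surface, ggplot2::aes(x = .data$p, y = .data$m,
                                        fill = .data$separation)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "recall rate p", y = "double-loss m",
                  fill = "min gap") +
    ggplot2::theme_minimal()
}
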