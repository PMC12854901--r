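#' Plot a Gaussian-sum fit over its histogram
#'
#' Reproduces the standard segmentation diagnostic: the intensity-weighted
#' histogram, each fitted Gaussian component, their sum, and vertical lines
#' at the mean + 3 SD thresholds of the first (nucleus) and second
#' (condensate) components.
#'
#' @param object A `gmm_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot gmm_fit
#' @export
autoplot.gmm_fit <- function(object, ...) {
  hist_df <- object$hist$data
  x_grid <- seq(min(hist_df$bin_center), max(hist_df$bin_center),
                length.out = 512)
  comp_df <- purrr::map_dfr(seq_len(nrow(object$components)), function(i) {
    cmp <- object$components[i, ]
    tibble::tibble(
      component = sprintf("component %d", i),
      x = x_grid,
      y = cmp$weight * exp(-(x_grid - cmp$mean)^2 / (2 * cmp$sd^2))
    )
  })
  sum_df <- tibble::tibble(x = x_grid, y = predict(object, x_grid))
  thr <- object$components$mean[1:2] + 3 * object$components$sd[1:2]
  ggplot2::ggplot(hist_df, ggplot2::aes(x = .data$bin_center, y = .data$weight)) +
    ggplot2::geom_col(fill = "grey80", width = object$hist$bin_width) +
    ggplot2::geom_line(
      data = comp_df,
      ggplot2::aes(x = .data$x, y = .data$y, colour = .data$component)
    ) +
    ggplot2::geom_line(data = sum_df, ggplot2::aes(x = .data$x, y = .data$y),
                       linewidth = 0.8) +
    ggplot2::geom_vline(xintercept = thr, linetype = "dashed") +
    ggplot2::labs(
      x = "intensity (a.u.)", y = "normalised weight",
      title = sprintf("k = %d, adjusted R² = %.4f",
                      object$k, object$adjusted_r_square)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a normalised FRAP trace
#'
#' @param object A [normalize_frap()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot frap_trace
#' @export
autoplot.frap_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$frame, y = .data$normalised)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(
      xintercept = attr(object, "n_prebleach") + 0.5, linetype = "dashed"
    ) +
    ggplot2::labs(x = "frame", y = "normalised intensity") +
    ggplot2::theme_minimal()
}

#' Concentration-dependence panels of a series analysis
#'
#' One panel per metric (volume fraction, mean condensate volume, dense- and
#' dilute-phase concentration) against total concentration, with per-image
#' points and the binned mean with an SEM ribbon.
#'
#' @param object A [run_series()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot series_report
#' @export
autoplot.series_report <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$table,
    cols = dplyr::all_of(c("volume_fraction", "mean_condensate_volume",
                           "c_den", "c_dil")),
    names_to = "metric", values_to = "value"
  )
  prof <- purrr::imap_dfr(object$profiles, function(p, m) {
    dplyr::mutate(p, metric = m)
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$c_tot, y = .data$value)) +
    ggplot2::geom_point(alpha = 0.6, size = 0.9) +
    ggplot2::geom_ribbon(
      data = prof,
      ggplot2::aes(
        x = .data$bin_center, y = .data$mean,
        ymin = .data$mean - .data$sem, ymax = .data$mean + .data$sem
      ),
      alpha = 0.3, fill = "steelblue"
    ) +
    ggplot2::geom_line(
      data = prof,
      ggplot2::aes(x = .data$bin_center, y = .data$mean),
      colour = "steelblue"
    ) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(
      x = expression(C[tot] ~ "(a.u.)"), y = NULL,
      subtitle = sprintf("verdict: %s", object$verdict$verdict)
    ) +
    ggplot2::theme_minimal()
}

#' Plot a two-channel transect profile
#'
#' @param profile A [transect_profile()] tibble.
#' @return A ggplot object.
#' @export
plot_transect <- function(profile) {
  chans <- setdiff(names(profile), c("step", "y", "x", "distance"))
  long <- tidyr::pivot_longer(profile, dplyr::all_of(chans),
                              names_to = "channel", values_to = "intensity")
  ggplot2::ggplot(long, ggplot2::aes(
    x = .data$distance, y = .data$intensity, colour = .data$channel
  )) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "distance (µm)", y = "intensity (a.u.)") +
    ggplot2::theme_minimal()
}
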