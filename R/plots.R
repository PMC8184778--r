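#' Plot a beat with its derivatives
#'
#' Three stacked panels in the conventional layout: the V5 trace, the
#' smoothed first derivative, and the smoothed second derivative, with any
#' supplied landmarks marked on the trace.
#'
#' @param object A `twv_derivs` (or a beat, which is differentiated first).
#' @param landmarks Optional `twv_landmarks` to overlay (x relative to Q;
#'   supply `q_ms` to place them).
#' @param q_ms Absolute Q time used to place landmark overlays.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twv_derivs <- function(object, landmarks = NULL, q_ms = 0, ...) {
  long <- tidyr::pivot_longer(
    as_tibble(object)[, c("time_ms", "y", "d1", "d2")],
    c("y", "d1", "d2"), names_to = "panel", values_to = "value"
  )
  long$panel <- factor(long$panel, levels = c("y", "d1", "d2"),
                       labels = c("V5 (mV)", "1st derivative (mV/ms)",
                                  "2nd derivative (mV/ms²)"))
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_ms, y = .data$value)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::labs(x = "time (ms)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(landmarks)) {
    lm <- as_tibble(landmarks)
    lm$time_ms <- lm$x_ms + q_ms
    lm$panel <- factor("V5 (mV)", levels = levels(long$panel))
    p <- p +
      ggplot2::geom_point(data = lm,
                          ggplot2::aes(x = .data$time_ms, y = .data$y_mv),
                          colour = "navy") +
      ggplot2::geom_text(data = lm,
                         ggplot2::aes(x = .data$time_ms, y = .data$y_mv,
                                      label = .data$landmark),
                         vjust = -0.8, size = 2.8, colour = "navy")
  }
  p
}

#' @export
autoplot.twv_beat <- function(object, ...) {
  autoplot(beat_derivatives(object), ...)
}

#' Plot a GPA fit
#'
#' Aligned configurations as a scatter with the mean shape drawn as a
#' connected polyline.
#'
#' @param object A `twv_gpa`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twv_gpa <- function(object, ...) {
  mean_path <- object$mean_shape
  mean_path$landmark <- factor(mean_path$landmark, levels = object$landmarks)
  aligned <- object$aligned
  if (!"group" %in% names(aligned)) aligned$group <- "all"
  ggplot2::ggplot(aligned, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$group),
                        alpha = 0.5, size = 1) +
    ggplot2::geom_path(data = mean_path[order(mean_path$landmark), ],
                       colour = "black") +
    ggplot2::geom_point(data = mean_path, colour = "black", size = 2) +
    ggplot2::geom_text(data = mean_path,
                       ggplot2::aes(label = .data$landmark),
                       vjust = -0.9, size = 2.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, colour = "group") +
    ggplot2::theme_minimal()
}

#' Plot a thin-plate-spline deformation grid
#'
#' The warped grid with source landmarks (red), target landmarks (green)
#' and displacement arrows (blue), the conventional morphometric
#' deformation display.
#'
#' @param object A `twv_tps`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twv_tps <- function(object, ...) {
  g <- object$grid
  d <- object$displacements
  ggplot2::ggplot() +
    ggplot2::geom_path(data = g, ggplot2::aes(x = .data$x, y = .data$y,
                                              group = .data$row),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_path(data = g, ggplot2::aes(x = .data$x, y = .data$y,
                                              group = .data$col),
                       colour = "grey60", linewidth = 0.3) +
    ggplot2::geom_segment(data = d,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "blue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm"))) +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$x0, y = .data$y0),
                        colour = "red") +
    ggplot2::geom_point(data = d, ggplot2::aes(x = .data$x1, y = .data$y1),
                        colour = "darkgreen") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot shape PCA icons
#'
#' For each retained component: the mean shape (red) and the icon displaced
#' by `c_sd` standard deviations along the component (green), joined by
#' arrows.
#'
#' @param object A `twv_shape_pca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.twv_shape_pca <- function(object, ...) {
  mu <- object$mean_shape
  icons <- object$icons
  both <- left_join(icons, mu, by = "landmark", suffix = c("", "_mean"))
  ggplot2::ggplot(both) +
    ggplot2::geom_segment(ggplot2::aes(x = .data$x_mean, y = .data$y_mean,
                                       xend = .data$x, yend = .data$y),
                          colour = "blue",
                          arrow = ggplot2::arrow(length = ggplot2::unit(1.5, "mm"))) +
    ggplot2::geom_point(ggplot2::aes(x = .data$x_mean, y = .data$y_mean),
                        colour = "red") +
    ggplot2::geom_point(ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "darkgreen") +
    ggplot2::facet_wrap(~component) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot per-landmark group means with confidence ellipses
#'
#' The two-group landmark summary display: per-group mean landmark
#' positions with their Hotelling 95% confidence ellipses.
#'
#' @param cases Per-case landmark tibble (`case_id`, `group`, `landmark`,
#'   `x`, `y`).
#' @param level Ellipse confidence level (default 0.95).
#' @return A ggplot object.
#' @export
plot_landmark_ellipses <- function(cases, level = 0.95) {
  ell <- purrr::map(intersect(twv_landmark_names(), unique(cases$landmark)),
                    function(lm) {
    purrr::map(unique(cases$group), function(g) {
      sub <- cases[cases$landmark == lm & cases$group == g, ]
      tryCatch(confidence_ellipse(cbind(sub$x, sub$y), level = level,
                                  landmark = lm, group = g),
               twaveshape_error = function(e) NULL)
    }) %>% list_rbind()
  }) %>% list_rbind()
  theta <- seq(0, 2 * pi, length.out = 90)
  paths <- ell %>%
    group_by(.data$landmark, .data$group) %>%
    dplyr::reframe(
      x = .data$center_x + .data$a * cos(theta) * cos(.data$angle) -
        .data$b * sin(theta) * sin(.data$angle),
      y = .data$center_y + .data$a * cos(theta) * sin(.data$angle) +
        .data$b * sin(theta) * cos(.data$angle)
    )
  ggplot2::ggplot() +
    ggplot2::geom_point(data = cases,
                        ggplot2::aes(x = .data$x, y = .data$y,
                                     colour = .data$group),
                        alpha = 0.35, size = 1) +
    ggplot2::geom_path(data = paths,
                       ggplot2::aes(x = .data$x, y = .data$y,
                                    colour = .data$group,
                                    group = interaction(.data$landmark, .data$group)),
                       linetype = "dashed") +
    ggplot2::geom_point(data = ell,
                        ggplot2::aes(x = .data$center_x, y = .data$center_y,
                                     colour = .data$group), size = 2) +
    ggplot2::labs(x = "x (Bazett-corrected ms from Q)", y = "y (mV)") +
    ggplot2::theme_minimal()
}
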