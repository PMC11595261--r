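#' Plot a radial projection
#'
#' Draws the unit circle, the anchor positions with gene labels, the
#' projected sample points colored by response label, and optionally a
#' dashed sector-region boundary.
#'
#' @param object A `radviz_projection` from [project()].
#' @param region Optional [sector_region()] to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.radviz_projection <- function(object, region = NULL, ...) {
  layout <- attr(object, "layout")
  circ <- tibble::tibble(t = seq(0, 2 * pi, length.out = 181))
  anchors <- tibble::tibble(gene = layout$genes,
                            x = cos(layout$angles), y = sin(layout$angles))
  p <- ggplot2::ggplot() +
    ggplot2::geom_path(data = circ,
                       ggplot2::aes(x = cos(.data$t), y = sin(.data$t)),
                       color = "grey70") +
    ggplot2::geom_point(data = anchors, ggplot2::aes(x = .data$x, y = .data$y),
                        shape = 15, size = 2.5, color = "grey30") +
    ggplot2::geom_text(data = anchors,
                       ggplot2::aes(x = 1.12 * .data$x, y = 1.12 * .data$y,
                                    label = .data$gene), size = 3) +
    ggplot2::coord_equal(xlim = c(-1.3, 1.3), ylim = c(-1.3, 1.3)) +
    ggplot2::theme_minimal() +
    ggplot2::labs(x = NULL, y = NULL, color = "response")
  if (!is.null(region)) {
    arc <- region_arc(region, layout)
    tt <- seq(arc[["start"]], arc[["start"]] + arc[["width"]],
              length.out = 60)
    wedge <- tibble::tibble(
      x = c(region$r_min * cos(tt[1]), cos(tt), region$r_min * cos(rev(tt))),
      y = c(region$r_min * sin(tt[1]), sin(tt), region$r_min * sin(rev(tt)))
    )
    p <- p + ggplot2::geom_path(data = wedge,
                                ggplot2::aes(x = .data$x, y = .data$y),
                                linetype = "dashed", color = "grey40")
  }
  if (nrow(object)) {
    p <- p + ggplot2::geom_point(
      data = object,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$label),
      size = 2, alpha = 0.85) +
      ggplot2::scale_color_manual(values = c(
        sensitive = "#d73027", resistant = "#4575b4", unknown = "grey55"))
  }
  p
}

#' Plot every step of a cascade over a cohort
#'
#' Re-enacts the elimination: step `i` shows only the samples still in play
#' when that step ran, projected on the step's layout, with the step's
#' region(s) dashed.
#'
#' @param data Expression cohort tibble.
#' @param cascade A fitted `rv_cascade`.
#' @param renormalize Passed to [apply_cascade()].
#' @return A named list of ggplot objects, one per step.
#' @export
plot_cascade_steps <- function(data, cascade, renormalize = FALSE) {
  data <- as_cohort(data)
  result <- apply_cascade(data, cascade, renormalize = renormalize)
  plots <- list()
  for (i in seq_along(cascade$steps)) {
    s <- cascade$steps[[i]]
    in_play <- is.na(result$decided_at_step) | result$decided_at_step >= i
    proj <- project(data[in_play, ], s$normalization, s$layout)
    p <- autoplot.radviz_projection(proj, region = s$regions[[1L]]) +
      ggplot2::ggtitle(sprintf("step %d: call %s in %s–%s", i,
                               names(s$regions)[1L],
                               s$regions[[1L]]$anchor_a,
                               s$regions[[1L]]$anchor_b))
    if (length(s$regions) > 1L) {
      arc2 <- s$regions[[2L]]
      arc <- region_arc(arc2, s$layout)
      tt <- seq(arc[["start"]], arc[["start"]] + arc[["width"]],
                length.out = 60)
      wedge <- tibble::tibble(
        x = c(arc2$r_min * cos(tt[1]), cos(tt), arc2$r_min * cos(rev(tt))),
        y = c(arc2$r_min * sin(tt[1]), sin(tt), arc2$r_min * sin(rev(tt))))
      p <- p + ggplot2::geom_path(data = wedge,
                                  ggplot2::aes(x = .data$x, y = .data$y),
                                  linetype = "dotdash", color = "grey40")
    }
    plots[[paste0("step", i)]] <- p
  }
  plots
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
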