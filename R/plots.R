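#' Plot a per-spot signal on the tissue coordinates
#'
#' @param coords Spot-by-2 coordinate matrix.
#' @param values Per-spot numeric vector (e.g. one gene's expression, a
#'   pseudo-expression surface, or a Fourier mode).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
plot_spots <- function(coords, values, title = NULL) {
  df <- data.frame(x = coords[, 1], y = coords[, 2], value = values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$value)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Ranked score curve of an SVG analysis
#'
#' Shows every gene's score in rank order with the knee-point cutoff line;
#' called genes are highlighted.
#'
#' @param object An `svg_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot svg_result
#' @export
autoplot.svg_result <- function(object, ...) {
  tbl <- object$table[order(object$table$rank), ]
  ggplot2::ggplot(tbl, ggplot2::aes(x = .data$rank, y = .data$gftscore,
                                    colour = .data$is_svg)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = object$cutoff_score, linetype = 2) +
    ggplot2::labs(x = "rank", y = "score", colour = "SVG") +
    ggplot2::theme_minimal()
}

#' Spot maps of the detected functional tissue units
#'
#' One panel per FTU: membership of each spot in the unit's high-expression
#' set.
#'
#' @param object An `ftu_result`.
#' @param coords Spot-by-2 coordinate matrix (rows named by spot ID).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ftu_result
#' @export
autoplot.ftu_result <- function(object, coords, ...) {
  rows <- lapply(seq_along(object$spot_sets), function(k) {
    data.frame(
      x = coords[, 1], y = coords[, 2],
      ftu = paste0("FTU", k),
      member = rownames(coords) %in% object$spot_sets[[k]]
    )
  })
  df <- do.call(rbind, rows)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   colour = .data$member)) +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::facet_wrap(~ftu) +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = "in FTU") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
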