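# ggplot2 visualisations of result objects.

#' Plot a persistence diagram or barcode
#'
#' @param object a [rips_persistence()] diagram.
#' @param type `"diagram"` (birth/death scatter with the diagonal) or
#'   `"barcode"` (one horizontal bar per interval).
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.persistence_diagram <- function(object, type = c("diagram", "barcode"),
                                         ...) {
  type <- match.arg(type)
  df <- tibble::as_tibble(object) |>
    dplyr::mutate(homology = paste0("H", .data$dimension))
  if (type == "diagram") {
    ggplot2::ggplot(df, ggplot2::aes(.data$birth, .data$death,
                                     colour = .data$homology)) +
      ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2,
                           colour = "grey60") +
      ggplot2::geom_point(alpha = 0.7) +
      ggplot2::labs(x = "birth [µm]", y = "death [µm]",
                    colour = NULL) +
      ggplot2::theme_minimal()
  } else {
    df <- df |>
      dplyr::arrange(.data$dimension, .data$birth) |>
      dplyr::mutate(bar = dplyr::row_number())
    ggplot2::ggplot(df, ggplot2::aes(y = .data$bar, colour = .data$homology)) +
      ggplot2::geom_segment(ggplot2::aes(x = .data$birth, xend = .data$death,
                                         yend = .data$bar)) +
      ggplot2::labs(x = "filtration value [µm]", y = NULL,
                    colour = NULL) +
      ggplot2::theme_minimal() +
      ggplot2::theme(axis.text.y = ggplot2::element_blank())
  }
}

#' Plot permutation feature importances
#'
#' @param object a [permutation_importance()] result.
#' @param top_n number of top-ranked features to show.
#' @param ... unused.
#' @return A ggplot object: mean balanced-accuracy drop per feature with
#'   +/- 1 sd bars, coloured by feature family.
#' @export
autoplot.papilla_importance <- function(object, top_n = 10L, ...) {
  df <- utils::head(object$importances, top_n)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$mean_drop,
    y = stats::reorder(.data$feature, .data$mean_drop),
    fill = .data$family)) +
    ggplot2::geom_col() +
    ggplot2::geom_errorbarh(ggplot2::aes(
      xmin = .data$mean_drop - .data$sd_drop,
      xmax = .data$mean_drop + .data$sd_drop), height = 0.25) +
    ggplot2::labs(x = "balanced-accuracy drop when permuted", y = NULL,
                  fill = NULL,
                  title = sprintf("Permutation importance (%s task)",
                                  object$task)) +
    ggplot2::theme_minimal()
}

#' Plot a papillae map
#'
#' @param object a [map_papillae()] result.
#' @param ... unused.
#' @return A ggplot object: detected papilla positions in the surface plane,
#'   coloured by predicted type and sized by confidence.
#' @export
autoplot.papillae_map <- function(object, ...) {
  ggplot2::ggplot(object$detections,
                  ggplot2::aes(.data$x, .data$y, colour = .data$type,
                               size = .data$confidence)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::scale_size(range = c(1, 4), limits = c(0, 1)) +
    ggplot2::labs(x = "x [µm]", y = "y [µm]", colour = NULL,
                  title = sprintf("Papillae map: %s", object$surface_id)) +
    ggplot2::theme_minimal()
}
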