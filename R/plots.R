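#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an evaluation's per-origin classification breakdown
#'
#' Stacked bars of classification-label weight by origin category — the
#' ring breakdown view of how reads from KO genes, non-KO genes and
#' intergenic regions were annotated.
#'
#' @param object An `annotation_eval`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.annotation_eval <- function(object, ...) {
  d <- object$by_origin |>
    dplyr::group_by(.data$origin) |>
    dplyr::mutate(fraction = .data$weight / sum(.data$weight)) |>
    dplyr::ungroup()
  ggplot2::ggplot(d, ggplot2::aes(x = .data$origin, y = .data$fraction,
                                  fill = .data$label)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "read origin", y = "weight fraction",
                  fill = "classification") +
    ggplot2::theme_minimal()
}

#' Plot a functional profile
#'
#' Bars of estimated copy number (if present) or length-normalized
#' counts per KO.
#'
#' @param object A `functional_profile`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.functional_profile <- function(object, ...) {
  ycol <- if ("copy_number" %in% names(object)) "copy_number" else "norm_count"
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = stats::reorder(.data$ko_id,
                                                  -.data[[ycol]]),
                               y = .data[[ycol]])) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "KO", y = gsub("_", " ", ycol)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Plot inter-protocol against inter-sample profile distances
#'
#' @param object A `protocol_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.protocol_comparison <- function(object, ...) {
  d <- dplyr::bind_rows(
    dplyr::transmute(object$inter_protocol, kind = "inter-protocol",
                     distance = .data$distance),
    dplyr::transmute(object$inter_sample, kind = "inter-sample",
                     distance = .data$distance)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$kind, y = .data$distance)) +
    ggplot2::geom_boxplot() +
    ggplot2::labs(x = NULL, y = "Jensen-Shannon distance") +
    ggplot2::theme_minimal()
}

#' Ranked per-KO recall with confidence band
#'
#' Reproduces the ranked-recall view: KOs ordered from highest to lowest
#' mean recall with their 95% confidence intervals.
#'
#' @param ko_stats Output of [per_ko_recall()].
#' @return A ggplot.
#' @export
plot_recall_by_ko <- function(ko_stats) {
  d <- dplyr::mutate(ko_stats, rank = dplyr::row_number(
    dplyr::desc(.data$mean_recall)))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rank, y = .data$mean_recall)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_lower,
                                      ymax = .data$ci_upper),
                         fill = "darkgreen", alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "KO rank", y = "mean recall") +
    ggplot2::ylim(0, 1) +
    ggplot2::theme_minimal()
}
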