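#' Plot parameter-vs-opening-angle curves
#'
#' Faceted curves of the predicted spinopelvic parameters against the
#' osteotomy opening angle.
#'
#' @param object A `bpo_prediction` tibble.
#' @param parameters Parameter columns to show.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bpo_prediction
#' @export
autoplot.bpo_prediction <- function(object,
                                    parameters = c(
                                      "sva_mm", "pi_deg", "pt_deg",
                                      "tpa_deg", "pi_minus_ll_deg"
                                    ),
                                    ...) {
  df <- as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(parameters),
      names_to = "parameter", values_to = "value"
    )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$oa_deg, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(
      x = "opening angle (deg)", y = NULL,
      title = "Predicted spinopelvic parameters vs osteotomy opening angle"
    )
}

#' Plot muscle stretch-ratio curves
#'
#' One stretch-ratio curve per muscle segment, with the isometric line at 1.
#'
#' @param object A `bpo_muscle_curve` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot bpo_muscle_curve
#' @export
autoplot.bpo_muscle_curve <- function(object, ...) {
  df <- as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$oa_deg, y = .data$stretch_ratio, colour = .data$segment
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "opening angle (deg)", y = "stretch ratio",
      title = "Muscle stretch ratio vs osteotomy opening angle"
    )
}
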