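#' Plot a simulated season
#'
#' Cumulative runoff and erosion over the season, with the daily
#' precipitation series beneath — the standard way seasonal
#' calibration fits are inspected.
#'
#' @param object A `season_result` from [simulate_season()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.season_result <- function(object, ...) {
  df <- tibble(
    date = rep(object$date, 3),
    value = c(object$precip_mm,
              cumsum(object$runoff_mm),
              cumsum(object$soil_loss_kg_ha)),
    series = rep(c("precipitation (mm/day)",
                   "cumulative runoff (mm)",
                   "cumulative erosion (kg/ha)"),
                 each = nrow(object))
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$date, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~series, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL, title = "Simulated season") +
    ggplot2::theme_minimal()
}

#' Plot a mitigation-corrected exposure series
#'
#' Daily unmitigated and mitigated stream concentrations on a log
#' scale, marking the (possibly shifted) seasonal maxima.
#'
#' @param object A `pec_series` from [pec_mitigation()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.pec_series <- function(object, ...) {
  df <- tidyr::pivot_longer(
    as_tibble(object)[c("date", "pec_nomiti_ug_l", "pec_mitigated_ug_l")],
    -"date", names_to = "series", values_to = "pec"
  )
  df$series <- ifelse(df$series == "pec_nomiti_ug_l",
                      "no mitigation", "mitigated")
  ggplot2::ggplot(dplyr::filter(df, .data$pec > 0),
                  ggplot2::aes(x = .data$date, y = .data$pec,
                               colour = .data$series)) +
    ggplot2::geom_point() +
    ggplot2::geom_line() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = NULL, y = "PECsw (µg/L)", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot seasonal runoff sensitivity to the curve number
#'
#' @param x A sensitivity table from [runoff_sensitivity()].
#' @return A ggplot object.
#' @export
plot_runoff_sensitivity <- function(x) {
  require_columns(x, c("cn", "total_runoff_mm"))
  ggplot2::ggplot(x, ggplot2::aes(x = .data$cn, y = .data$total_runoff_mm)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "curve number", y = "seasonal runoff (mm)") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
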