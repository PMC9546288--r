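#' Simulate runoff and erosion over a season of daily weather
#'
#' Drives the curve-number runoff relation and the MUSS soil-loss
#' equation through a daily precipitation series with a single fixed
#' CN for the whole season: for each day
#' `Q = runoff_depth(P, cn)` and, on runoff days,
#' `Xe = event_soil_loss(Q, Q / n_segments(P), plot)`. No
#' antecedent-moisture CN adjustment, evapotranspiration, snow or
#' irrigation is applied; the simulator targets seasonal totals, not
#' the magnitude of individual events.
#'
#' @param weather Data frame with columns `date` and `precip_mm`
#'   (strictly increasing dates, non-negative depths); see
#'   [read_weather()].
#' @param plot A [field_plot()] supplying the CN and MUSS factors.
#' @param ia_ratio Initial abstraction ratio passed to [runoff_depth()].
#' @return A tibble of class `season_result` with columns `date`,
#'   `precip_mm`, `runoff_mm`, `soil_loss_kg_ha`; seasonal totals via
#'   [season_totals()] / [glance()].
#' @examples
#' w <- tibble::tibble(date = as.Date("2019-06-01") + 0:2,
#'                     precip_mm = c(0, 26, 4))
#' pl <- field_plot(0.0054, k = 0.12, ls = 0.9, c = 16.2, cn = 74)
#' simulate_season(w, pl)
#' @export
simulate_season <- function(weather, plot, ia_ratio = 0.2) {
  stopifnot(inherits(plot, "field_plot"))
  weather <- validate_weather(weather)
  p <- weather$precip_mm
  q <- runoff_depth(p, plot$cn, ia_ratio)
  loss_t <- numeric(length(p))
  wet <- q > 0
  if (any(wet)) {
    qp <- peak_runoff_rate(q[wet], p[wet])
    loss_t[wet] <- event_soil_loss(q[wet], qp, plot)
  }
  out <- tibble(
    date = weather$date,
    precip_mm = p,
    runoff_mm = q,
    soil_loss_kg_ha = soil_loss_per_area(loss_t, plot$area_ha)
  )
  structure(out, class = c("season_result", class(out)), plot = plot)
}

#' Seasonal totals of a simulated season
#'
#' @param x A `season_result` from [simulate_season()].
#' @return One-row tibble: `total_runoff_mm`, `total_erosion_kg_ha`,
#'   `total_erosion_t_ha`, `n_runoff_events`, `n_days`.
#' @export
season_totals <- function(x) {
  stopifnot(inherits(x, "season_result"))
  tibble(
    total_runoff_mm = sum(x$runoff_mm),
    total_erosion_kg_ha = sum(x$soil_loss_kg_ha),
    total_erosion_t_ha = sum(x$soil_loss_kg_ha) / 1000,
    n_runoff_events = sum(x$runoff_mm > 0),
    n_days = nrow(x)
  )
}

#' @rdname season_totals
#' @param ... Unused.
#' @export
glance.season_result <- function(x, ...) season_totals(x)

#' Sensitivity of seasonal totals to the curve number
#'
#' Re-simulates one season under a set of candidate CNs and tabulates
#' the seasonal runoff and erosion totals. Because seasonal runoff is
#' nondecreasing in CN this table is the basis for inverse CN
#' calibration, and because MUSS is linear in `C` the erosion column
#' scales exactly with the plot's C-factor.
#'
#' @inheritParams simulate_season
#' @param cn_values Numeric vector of curve numbers to evaluate.
#' @return Tibble with one row per CN, in the order given:
#'   `cn`, `total_runoff_mm`, `total_erosion_kg_ha`.
#' @export
runoff_sensitivity <- function(weather, plot, cn_values, ia_ratio = 0.2) {
  check_numeric(cn_values, "cn_values")
  weather <- validate_weather(weather)
  purrr::map_dfr(cn_values, function(cn) {
    pl <- plot
    pl$cn <- cn
    tot <- season_totals(simulate_season(weather, pl, ia_ratio))
    tibble(cn = cn,
           total_runoff_mm = tot$total_runoff_mm,
           total_erosion_kg_ha = tot$total_erosion_kg_ha)
  })
}

validate_weather <- function(weather) {
  weather <- as_tibble(weather)
  require_columns(weather, c("date", "precip_mm"))
  if (nrow(weather) == 0) abort("`weather` must contain at least one day.")
  if (anyNA(weather$precip_mm) || any(weather$precip_mm < 0)) {
    bad <- which(is.na(weather$precip_mm) | weather$precip_mm < 0)
    abort(paste0("Negative or missing `precip_mm` at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  d <- as.Date(weather$date)
  if (anyNA(d)) abort("`date` column contains unparseable dates.")
  if (nrow(weather) > 1 && any(diff(d) <= 0)) {
    abort(paste0("Dates must be strictly increasing; first violation at row ",
                 which(diff(d) <= 0)[1] + 1, "."))
  }
  weather$date <- d
  weather
}
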