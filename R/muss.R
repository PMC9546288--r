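#' Number of 2-mm precipitation segments in a day
#'
#' Daily rainfall is segmented into hourly 2-mm steps, one segment per
#' hour, capped at the 24 hours of the day:
#' `n = min(24, ceiling(P / 2))`. The segment count distributes a daily
#' runoff volume over the day and so sets the uniform peak runoff rate
#' used by the MUSS equation and the stream-dilution PEC equation. A
#' 19.9 mm day yields `n = 10`.
#'
#' @param precip Daily precipitation depth(s) in mm, `> 0`.
#' @return Integer segment counts in `1:24`.
#' @export
n_segments <- function(precip) {
  check_numeric(precip, "precip")
  if (any(precip <= 0)) abort("`precip` must be > 0 to segment a day.")
  as.integer(pmin(24, ceiling(precip / 2)))
}

#' Uniform daily peak runoff rate
#'
#' Surrogate peak storm runoff rate `qp` (mm/h) obtained by spreading
#' the daily runoff volume uniformly over the day's 2-mm rain segments:
#' `qp = Vr / n_segments(P)`. By construction `qp * n = Vr`.
#'
#' @param runoff Daily runoff volume `Vr` in mm, `>= 0`.
#' @param precip Daily precipitation in mm, `> 0`.
#' @return Peak runoff rate(s) in mm/h.
#' @examples
#' peak_runoff_rate(1.6, 19.9)  # 0.16 mm/h
#' @export
peak_runoff_rate <- function(runoff, precip) {
  check_numeric(runoff, "runoff")
  if (any(runoff < 0)) abort("`runoff` must be >= 0.")
  runoff / n_segments(precip)
}

#' Define a field plot with its erosion factors
#'
#' Bundles the plot geometry and (M)USLE factors consumed by
#' [event_soil_loss()] and [simulate_season()]: area `A` (ha), soil
#' erodibility `K`, length-slope `LS`, cover-management `C`,
#' conservation practice `P`, plus the seasonal runoff curve number.
#' The C-factor is deliberately not clamped to `<= 1`: seasonal
#' calibration against measured eroded masses can push it well above
#' one because it absorbs everything the other factors do not.
#'
#' @param area_ha Plot area in hectares, `> 0`.
#' @param k,ls,c,p Dimensionless MUSS factors, `>= 0`.
#' @param cn Runoff curve number in (30, 100].
#' @param slope_pct Plot slope in percent (metadata only).
#' @return An object of class `field_plot`.
#' @examples
#' field_plot(area_ha = 0.0054, k = 0.12, ls = 0.9, c = 16.2, cn = 74)
#' @export
field_plot <- function(area_ha, k, ls, c, p = 1, cn, slope_pct = NA_real_) {
  for (nm in c("area_ha", "k", "ls", "c", "p", "cn")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || is.na(v)) {
      abort(paste0("`", nm, "` must be a single non-missing number."))
    }
  }
  if (area_ha <= 0) abort("`area_ha` must be > 0.")
  if (any(c(k, ls, c, p) < 0)) abort("MUSS factors must be >= 0.")
  if (cn <= 30 || cn > 100) abort("`cn` must lie in (30, 100].")
  structure(
    list(area_ha = area_ha, k = k, ls = ls, c = c, p = p,
         cn = cn, slope_pct = slope_pct),
    class = "field_plot"
  )
}

#' @export
print.field_plot <- function(x, ...) {
  cat("<field_plot> ", format(x$area_ha), " ha",
      if (!is.na(x$slope_pct)) paste0(", slope ", x$slope_pct, "%"), "\n",
      "  CN ", format(x$cn),
      " | K ", format(x$k), "  LS ", format(x$ls),
      "  C ", format(x$c), "  P ", format(x$p), "\n", sep = "")
  invisible(x)
}

#' MUSS event soil loss
#'
#' Small-watershed Modified USLE (MUSS) estimate of the soil mass
#' eroded by one runoff event:
#' `Xe = 0.79 (Vr qp)^0.65 A^0.009 K LS C P` (tonnes/event), driven by
#' the runoff volume `Vr` (mm) and peak runoff rate `qp` (mm/h) rather
#' than rainfall erosivity. `Xe` is exactly linear in each of the
#' `K`, `LS`, `C` and `P` factors and zero whenever `Vr` is zero.
#'
#' @param vr Event runoff volume in mm, `>= 0`.
#' @param qp Peak runoff rate in mm/h, `>= 0`.
#' @param plot A [field_plot()].
#' @return Soil loss in tonnes per event (whole plot).
#' @examples
#' pl <- field_plot(0.0072, k = 0.12, ls = 1.05, c = 7.17, cn = 80)
#' event_soil_loss(4.38, peak_runoff_rate(4.38, 26), pl)
#' @export
event_soil_loss <- function(vr, qp, plot) {
  stopifnot(inherits(plot, "field_plot"))
  check_numeric(vr, "vr")
  check_numeric(qp, "qp")
  if (any(vr < 0) || any(qp < 0)) abort("`vr` and `qp` must be >= 0.")
  0.79 * (vr * qp)^0.65 * plot$area_ha^0.009 *
    plot$k * plot$ls * plot$c * plot$p
}

#' Convert a whole-plot soil loss to a per-area loss
#'
#' @param tonnes Soil loss in tonnes per event or season.
#' @param area_ha Plot area in hectares.
#' @return Loss in kg/ha.
#' @export
soil_loss_per_area <- function(tonnes, area_ha) {
  if (any(area_ha <= 0)) abort("`area_ha` must be > 0.")
  tonnes / area_ha * 1000
}
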