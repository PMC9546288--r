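#' Calibrate the seasonal curve number against a measured runoff total
#'
#' Inverse estimation of the season-wide CN: because the seasonal
#' runoff total is continuous and nondecreasing in CN, the fit is the
#' smallest integer CN whose simulated total reaches *at least* the
#' measured total (the convention used when report tables print
#' integer CNs). A continuous CN solving the total exactly is also
#' computed for diagnostics where one exists.
#'
#' @inheritParams simulate_season
#' @param measured_runoff_mm Measured seasonal runoff total, mm, `>= 0`.
#' @param cn_range Integer search bounds (default 30 to 100).
#' @return The fitted integer CN (numeric scalar). Attributes
#'   `continuous` (exact-matching CN or `NA`) and `simulated_total_mm`
#'   carry the diagnostics; [calibrate_season()] returns them tidily.
#' @export
calibrate_cn <- function(weather, plot, measured_runoff_mm,
                         cn_range = c(30, 100), ia_ratio = 0.2) {
  check_numeric(measured_runoff_mm, "measured_runoff_mm")
  if (measured_runoff_mm < 0) abort("`measured_runoff_mm` must be >= 0.")
  weather <- validate_weather(weather)
  lo <- as.integer(ceiling(cn_range[1]))
  hi <- as.integer(floor(cn_range[2]))
  # the seasonal runoff total depends on the plot only through its CN
  total_at <- function(cn) sum(runoff_depth(weather$precip_mm, cn, ia_ratio))
  if (measured_runoff_mm == 0) {
    warn("Measured runoff total is 0; returning the lower search bound.")
    return(structure(as.numeric(lo), continuous = NA_real_,
                     simulated_total_mm = total_at(lo)))
  }
  top <- total_at(hi)
  if (top < measured_runoff_mm) {
    abort(paste0("Measured runoff total ", format(measured_runoff_mm),
                 " mm is unattainable: CN ", hi, " yields only ",
                 format(round(top, 3)), " mm."))
  }
  # exploit monotonicity: scan the integer grid for the first total >= target
  grid <- lo:hi
  totals <- vapply(grid, total_at, numeric(1))
  idx <- which(totals >= measured_runoff_mm)[1]
  fit <- grid[idx]
  cont <- NA_real_
  if (idx > 1) {
    f <- function(cn) total_at(cn) - measured_runoff_mm
    cont <- tryCatch(uniroot(f, c(grid[idx - 1], fit), tol = 1e-8)$root,
                     error = function(e) NA_real_)
  } else if (abs(totals[idx] - measured_runoff_mm) < 1e-9) {
    cont <- as.numeric(fit)
  }
  structure(as.numeric(fit), continuous = cont,
            simulated_total_mm = totals[idx])
}

#' Calibrate the MUSS C-factor against a measured eroded mass
#'
#' Because MUSS soil loss is exactly linear in the cover-management
#' factor `C`, the seasonal inverse is closed-form:
#' `C = measured / simulated(C = 1)`, where the simulation uses the
#' plot's (typically already calibrated) curve number. The fitted
#' C-factor is not restricted to `<= 1` — it absorbs whatever the other
#' factors miss.
#'
#' @inheritParams simulate_season
#' @param measured_erosion_kg_ha Measured seasonal eroded mass, kg/ha.
#' @return The fitted C-factor (numeric scalar) with attribute
#'   `simulated_at_c1_kg_ha`.
#' @export
calibrate_c_factor <- function(weather, plot, measured_erosion_kg_ha,
                               ia_ratio = 0.2) {
  check_numeric(measured_erosion_kg_ha, "measured_erosion_kg_ha")
  if (measured_erosion_kg_ha < 0) abort("`measured_erosion_kg_ha` must be >= 0.")
  pl <- plot
  pl$c <- 1
  base <- season_totals(simulate_season(weather, pl, ia_ratio))$total_erosion_kg_ha
  if (base <= 0) {
    if (measured_erosion_kg_ha == 0) {
      return(structure(0, simulated_at_c1_kg_ha = 0))
    }
    abort("No erosive events at C = 1: the C-factor cannot be calibrated.")
  }
  structure(measured_erosion_kg_ha / base, simulated_at_c1_kg_ha = base)
}

#' Calibrate CN and C-factor for one season
#'
#' Two-step inverse fit mirroring the season-wise parameter-estimation
#' strategy: first the CN most suitable for the measured seasonal
#' runoff total (smallest integer CN reaching at least the target),
#' then, holding that CN, the MUSS C-factor that exactly reproduces
#' the measured seasonal eroded mass.
#'
#' @inheritParams calibrate_cn
#' @param measured_erosion_kg_ha Measured seasonal eroded mass, kg/ha.
#' @return An object of class `season_fit`; see [tidy.season_fit()]
#'   and [glance.season_fit()].
#' @export
calibrate_season <- function(weather, plot, measured_runoff_mm,
                             measured_erosion_kg_ha,
                             cn_range = c(30, 100), ia_ratio = 0.2) {
  cn_fit <- calibrate_cn(weather, plot, measured_runoff_mm, cn_range, ia_ratio)
  pl <- plot
  pl$cn <- as.numeric(cn_fit)
  c_fit <- calibrate_c_factor(weather, pl, measured_erosion_kg_ha, ia_ratio)
  pl$c <- as.numeric(c_fit)
  sim <- season_totals(simulate_season(weather, pl, ia_ratio))
  structure(
    list(
      fitted_cn = as.numeric(cn_fit),
      fitted_cn_continuous = attr(cn_fit, "continuous"),
      fitted_c = as.numeric(c_fit),
      plot = pl,
      simulated = sim,
      targets = tibble(runoff_mm = measured_runoff_mm,
                       erosion_kg_ha = measured_erosion_kg_ha)
    ),
    class = "season_fit"
  )
}

#' @export
print.season_fit <- function(x, ...) {
  cat("<season_fit>\n",
      "  CN ", format(x$fitted_cn),
      " (continuous ", format(round(x$fitted_cn_continuous, 2)), ")",
      " | C-factor ", format(signif(x$fitted_c, 4)), "\n",
      "  runoff  sim ", format(round(x$simulated$total_runoff_mm, 2)),
      " mm vs measured ", format(x$targets$runoff_mm), " mm\n",
      "  erosion sim ", format(round(x$simulated$total_erosion_kg_ha, 1)),
      " kg/ha vs measured ", format(x$targets$erosion_kg_ha), " kg/ha\n",
      sep = "")
  invisible(x)
}

#' Tidy a seasonal calibration fit
#'
#' @param x A `season_fit` from [calibrate_season()].
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per fitted parameter
#'   (`cn`, `c_factor`). `glance()`: a one-row tibble with the fitted
#'   parameters and the simulated vs target seasonal totals.
#' @export
tidy.season_fit <- function(x, ...) {
  tibble(
    term = c("cn", "c_factor"),
    estimate = c(x$fitted_cn, x$fitted_c),
    estimate_continuous = c(x$fitted_cn_continuous, x$fitted_c)
  )
}

#' @rdname tidy.season_fit
#' @export
glance.season_fit <- function(x, ...) {
  tibble(
    fitted_cn = x$fitted_cn,
    fitted_c = x$fitted_c,
    sim_runoff_mm = x$simulated$total_runoff_mm,
    target_runoff_mm = x$targets$runoff_mm,
    sim_erosion_kg_ha = x$simulated$total_erosion_kg_ha,
    target_erosion_kg_ha = x$targets$erosion_kg_ha,
    n_runoff_events = x$simulated$n_runoff_events
  )
}
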