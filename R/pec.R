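#' FOCUS stream scenario constants
#'
#' Constants of the stream-dilution correction: `fa`, the fraction of
#' the upstream catchment that is treated (and mitigated); `basf`, the
#' baseflow per unit contributing area (L/m2/day); and `raindr`, the
#' fraction of leaching routed into baseflow. Defaults are the FOCUS
#' stream values (0.208, 0.2, 0.1).
#'
#' @param fa Fraction of upstream area treated, in (0, 1].
#' @param basf Baseflow, L/m2/day, `>= 0`.
#' @param raindr Fraction of leaching entering baseflow, in \[0, 1\].
#' @return An object of class `scenario_config`.
#' @export
scenario_config <- function(fa = 0.208, basf = 0.2, raindr = 0.1) {
  if (!is.numeric(fa) || fa <= 0 || fa > 1) abort("`fa` must be in (0, 1].")
  if (!is.numeric(basf) || basf < 0) abort("`basf` must be >= 0.")
  if (!is.numeric(raindr) || raindr < 0 || raindr > 1) {
    abort("`raindr` must be in [0, 1].")
  }
  structure(list(fa = fa, basf = basf, raindr = raindr),
            class = "scenario_config")
}

#' @export
print.scenario_config <- function(x, ...) {
  cat("<scenario_config> fa ", x$fa, " | BASF ", x$basf,
      " L/m2/d | raindr ", x$raindr, "\n", sep = "")
  invisible(x)
}

#' Fractional reduction of the runoff pesticide mass flux
#'
#' `fr = (RFLX_nomiti - RFLX_miti) / RFLX_nomiti`, the day-wise
#' fraction of pesticide mass flux removed by the mitigation measure.
#' When both fluxes are zero the reduction is defined as 0.
#'
#' @param nomiti,miti Runoff mass fluxes (mg/m2/day) without and with
#'   mitigation; `miti` must not exceed `nomiti`. Vectorized.
#' @return Fractions in \[0, 1\].
#' @examples
#' fraction_flux_reduction(1.3e-2, 4.6e-5)  # 0.9965
#' @export
fraction_flux_reduction <- function(nomiti, miti) {
  fractional_reduction(nomiti, miti, "flux")
}

#' Fractional reduction of the runoff water volume
#'
#' `fv = (RUNF_nomiti - RUNF_miti) / RUNF_nomiti`; conventions as in
#' [fraction_flux_reduction()].
#'
#' @param nomiti,miti Runoff volumes (L/m2/day) without and with
#'   mitigation. Vectorized.
#' @return Fractions in \[0, 1\].
#' @examples
#' fraction_volume_reduction(1.6, 0.2)  # 0.875
#' @export
fraction_volume_reduction <- function(nomiti, miti) {
  fractional_reduction(nomiti, miti, "volume")
}

fractional_reduction <- function(nomiti, miti, what) {
  check_numeric(nomiti, "nomiti")
  check_numeric(miti, "miti")
  if (any(miti < 0) || any(nomiti < 0)) abort("Fluxes must be >= 0.")
  if (any(miti > nomiti + 1e-12)) {
    abort(paste0("Mitigated ", what,
                 " exceeds the unmitigated one; the correction assumes ",
                 "mitigation cannot increase it."))
  }
  ifelse(nomiti > 0, (nomiti - miti) / nomiti, 0)
}

#' Unmitigated edge-of-field stream concentration
#'
#' Dilution estimate of the daily surface-water concentration in the
#' edge-of-field stream from the field-scale model output:
#' `PECsw = (RFLX / n * fa) / (BASF/24 + raindr * INFLMON/24 + RUNF / n)`
#' with `n = n_segments(precip)` spreading the daily fluxes over the
#' day's 2-mm rain segments. Fluxes are per m2 of contributing area;
#' the quotient is mg/L and is returned as ug/L.
#'
#' @param rflx Daily runoff pesticide mass flux, mg/m2/day.
#' @param runf Daily runoff volume, L/m2/day.
#' @param inflmon Monthly mean leaching flux, L/m2/day.
#' @param precip Daily precipitation, mm (`> 0` on runoff days).
#' @param config A [scenario_config()].
#' @return Concentration(s) in ug/L.
#' @examples
#' pec_unmitigated(1.3e-2, 1.6, 1.3, 19.9)  # ~1.6 ug/L
#' @export
pec_unmitigated <- function(rflx, runf, inflmon, precip,
                            config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  check_numeric(rflx, "rflx")
  check_numeric(runf, "runf")
  check_numeric(inflmon, "inflmon")
  if (any(rflx < 0) || any(runf < 0) || any(inflmon < 0)) {
    abort("Fluxes must be >= 0.")
  }
  n <- n_segments(precip)
  denom <- config$basf / 24 + config$raindr * inflmon / 24 + runf / n
  if (any(denom <= 0)) abort("Zero dilution denominator: no water flow.")
  mg_l <- (rflx / n * config$fa) / denom
  1000 * mg_l
}

#' Upstream-catchment-corrected mitigated concentration
#'
#' Rescales an unmitigated stream concentration for a mitigation
#' measure applied only on the treated fraction `fa` of the upstream
#' catchment:
#' `PEC_mit = PEC_nomiti * (1 - fr) / (1 - fa * fv)`.
#' The numerator removes the mitigated pesticide mass; the denominator
#' restores the runoff water that the untreated 1 - fa of the
#' catchment still delivers.
#'
#' @param pec_nomiti Unmitigated concentration(s), ug/L.
#' @param fr Fractional mass-flux reduction, \[0, 1\].
#' @param fv Fractional volume reduction, \[0, 1\].
#' @param config A [scenario_config()] (only `fa` is used).
#' @return Mitigated concentration(s), ug/L.
#' @examples
#' pec_mitigated(1.61, fr = 0.9965, fv = 0.875)  # ~7e-3 ug/L
#' @export
pec_mitigated <- function(pec_nomiti, fr, fv, config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  check_numeric(pec_nomiti, "pec_nomiti")
  check_numeric(fr, "fr")
  check_numeric(fv, "fv")
  if (any(fr < 0 | fr > 1) || any(fv < 0 | fv > 1)) {
    abort("`fr` and `fv` must lie in [0, 1].")
  }
  if (any(config$fa * fv >= 1)) abort("`fa * fv` must be < 1.")
  pec_nomiti * (1 - fr) / (1 - config$fa * fv)
}

#' Day-wise mitigation correction of a stream exposure series
#'
#' Applies the full correction chain to paired daily exposure series
#' (without and with mitigation, sharing dates and weather): on each
#' day with unmitigated runoff it computes the fractional reductions
#' `fr` and `fv`, the unmitigated dilution concentration, and the
#' catchment-corrected mitigated concentration. Days without
#' unmitigated runoff carry zero concentration from this pathway.
#'
#' @param nomiti,miti Exposure tables with columns `date`,
#'   `rflx_mg_m2_d`, `runf_L_m2_d`, `infl_L_m2_d`, `precip_mm` (see
#'   [read_exposure()]); dates must align.
#' @param config A [scenario_config()].
#' @return A tibble of class `pec_series` with per-day columns `fr`,
#'   `fv`, `pec_nomiti_ug_l`, `pec_mitigated_ug_l`.
#' @export
pec_mitigation <- function(nomiti, miti, config = scenario_config()) {
  nomiti <- validate_exposure(nomiti)
  miti <- validate_exposure(miti)
  if (nrow(nomiti) != nrow(miti) || !all(nomiti$date == miti$date)) {
    abort("`nomiti` and `miti` must cover identical dates.")
  }
  out <- tibble(
    date = nomiti$date,
    precip_mm = nomiti$precip_mm,
    runoff_day = nomiti$runf_L_m2_d > 0,
    fr = 0, fv = 0,
    pec_nomiti_ug_l = 0, pec_mitigated_ug_l = 0
  )
  rd <- out$runoff_day
  if (any(rd)) {
    out$fr[rd] <- fraction_flux_reduction(nomiti$rflx_mg_m2_d[rd],
                                          miti$rflx_mg_m2_d[rd])
    out$fv[rd] <- fraction_volume_reduction(nomiti$runf_L_m2_d[rd],
                                            miti$runf_L_m2_d[rd])
    out$pec_nomiti_ug_l[rd] <- pec_unmitigated(
      nomiti$rflx_mg_m2_d[rd], nomiti$runf_L_m2_d[rd],
      nomiti$infl_L_m2_d[rd], nomiti$precip_mm[rd], config
    )
    out$pec_mitigated_ug_l[rd] <- pec_mitigated(
      out$pec_nomiti_ug_l[rd], out$fr[rd], out$fv[rd], config
    )
  }
  structure(out, class = c("pec_series", class(out)))
}

#' Global maximum of a mitigated concentration series
#'
#' The mitigation correction can shift the day of the seasonal maximum
#' as well as shrink it; this returns the mitigated maximum with its
#' date (and the unmitigated maximum for comparison).
#'
#' @param x A `pec_series` from [pec_mitigation()].
#' @return A one-row tibble (`date`, `pec_mitigated_ug_l`,
#'   `date_nomiti`, `pec_nomiti_ug_l`); zero rows if the series has no
#'   runoff days.
#' @export
pec_max <- function(x) {
  stopifnot(inherits(x, "pec_series"))
  rd <- dplyr::filter(x, .data$runoff_day)
  if (nrow(rd) == 0) {
    return(tibble(date = as.Date(character()), pec_mitigated_ug_l = numeric(),
                  date_nomiti = as.Date(character()), pec_nomiti_ug_l = numeric()))
  }
  i <- which.max(rd$pec_mitigated_ug_l)
  j <- which.max(rd$pec_nomiti_ug_l)
  tibble(
    date = rd$date[i], pec_mitigated_ug_l = rd$pec_mitigated_ug_l[i],
    date_nomiti = rd$date[j], pec_nomiti_ug_l = rd$pec_nomiti_ug_l[j]
  )
}
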