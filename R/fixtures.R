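#' Packaged field-trial reference tables
#'
#' Three small tables transcribed from the published evaluation of the
#' Belgian maize mitigation trials (seasons 2013, 2018, 2019) that the
#' package's worked examples and tests analyze:
#'
#' * `trial_totals()` — measured seasonal runoff totals (mm), eroded
#'   masses (kg/ha) and event-wise precipitation-weighted mean CNs,
#'   per trial and treatment. Treatments: conventional tillage (CvT),
#'   conservation tillage via subsoiling (CsT), micro-dams (MD), and
#'   in 2013 two micro-dam devices (disc and drum plow) on CvT.
#' * `season_fits()` — season-wise calibrated CNs and MUSS C-factors
#'   with simulated vs measured seasonal totals, per trial and
#'   treatment.
#' * `trial_plots()` — the per-trial MUSS parameterization (area,
#'   slope, K, LS, P) of the plots.
#'
#' @return A tibble.
#' @examples
#' trial_totals()
#' @export
trial_totals <- function() {
  read_fixture("field_trial_totals.csv")
}

#' @rdname trial_totals
#' @export
season_fits <- function() {
  read_fixture("season_calibration_fits.csv")
}

#' @rdname trial_totals
#' @export
trial_plots <- function() {
  read_fixture("trial_plot_factors.csv")
}

read_fixture <- function(name) {
  path <- system.file("extdata", name, package = "cnmuss", mustWork = TRUE)
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}
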