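#' Percent reduction of a quantity by a treatment
#'
#' `100 * (control - treated) / control`, the reduction statistic used
#' throughout the trial report tables for runoff volumes, eroded
#' masses and derived concentrations. Values are kept at full
#' precision; report views round to integers via [report_round()].
#'
#' @param control,treated Quantities on the same scale; `control > 0`,
#'   `treated >= 0`. Vectorized.
#' @return Percent reductions (may be negative if `treated > control`).
#' @examples
#' percent_reduction(9.7, 3.3)    # 66%
#' percent_reduction(2371, 62)    # 97.4%
#' @export
percent_reduction <- function(control, treated) {
  check_numeric(control, "control")
  check_numeric(treated, "treated")
  if (any(control <= 0)) abort("`control` must be > 0 for a percent reduction.")
  if (any(treated < 0)) abort("`treated` must be >= 0.")
  100 * (control - treated) / control
}

#' Curve-number reduction in points and percent
#'
#' @param control_cn,treated_cn Curve numbers. Vectorized.
#' @return Tibble with columns `points` (`control - treated`) and
#'   `percent` (`100 * points / control`).
#' @examples
#' cn_point_reduction(80, 75)  # 5 points, 6.25%
#' @export
cn_point_reduction <- function(control_cn, treated_cn) {
  check_numeric(control_cn, "control_cn")
  check_numeric(treated_cn, "treated_cn")
  pts <- control_cn - treated_cn
  tibble(points = pts, percent = 100 * pts / control_cn)
}

#' Relative C-factor of a treatment
#'
#' Ratio of the treated to the control cover-management factor and the
#' corresponding relative reduction `1 - ratio`. The reduction may be
#' negative: a treatment that suppresses runoff strongly can force the
#' calibrated C-factor *up* to reproduce the (less-reduced) eroded
#' mass from less runoff.
#'
#' @param control_c,treated_c C-factors; `control_c > 0`. Vectorized.
#' @return Tibble with columns `ratio` and `reduction`.
#' @examples
#' relative_c_factor(7.17, 2.33)  # ratio 0.32, reduction 0.68
#' @export
relative_c_factor <- function(control_c, treated_c) {
  check_numeric(control_c, "control_c")
  check_numeric(treated_c, "treated_c")
  if (any(control_c <= 0)) abort("`control_c` must be > 0.")
  ratio <- treated_c / control_c
  tibble(ratio = ratio, reduction = 1 - ratio)
}

#' Population standard deviation
#'
#' Standard deviation with divisor `n` (not `n - 1`). The trial report
#' tables quote their "(± sd)" values in this convention, which is the
#' appropriate one when the listed comparisons are the entire set
#' being summarized rather than a sample from a larger population.
#'
#' @param x Numeric vector.
#' @return The population SD; 0 for a single value.
#' @export
sd_pop <- function(x) {
  check_numeric(x, "x")
  sqrt(mean((x - mean(x))^2))
}

#' Summarize a set of treatment reductions
#'
#' Mean and population standard deviation over a set of pairwise
#' reduction values (CN points, percent reductions, or relative
#' C-factor reductions), mirroring the "mean (± sd)" summary blocks of
#' the trial report tables.
#'
#' @param values Numeric vector of reductions, one per treatment pair.
#' @param label Optional comparison label (e.g. `"MD+CvT vs CvT"`).
#' @param unit Optional unit tag (`"points"`, `"%"`, `"relative"`).
#' @return One-row tibble: `label`, `n`, `mean`, `sd`, `unit`.
#' @examples
#' reduction_summary(c(5, 7, 1, 5, 3, 5), "MD+CvT vs CvT", "points")
#' @export
reduction_summary <- function(values, label = NA_character_, unit = NA_character_) {
  check_numeric(values, "values")
  tibble(
    label = label,
    n = length(values),
    mean = mean(values),
    sd = sd_pop(values),
    unit = unit
  )
}

#' Round a value the way the report tables print it
#'
#' Integers for depths (mm), masses (kg/ha), CNs and percentages; two
#' decimals for relative C-factors; one decimal for summary SDs.
#'
#' @param x Numeric vector.
#' @param what One of `"integer"`, `"relative"`, `"sd"`.
#' @return Rounded values.
#' @export
report_round <- function(x, what = c("integer", "relative", "sd")) {
  what <- match.arg(what)
  switch(what,
    integer = round(x),
    relative = round(x, 2),
    sd = round(x, 1)
  )
}
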