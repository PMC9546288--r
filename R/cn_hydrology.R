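#' Potential maximum retention from a curve number
#'
#' Converts an SCS runoff curve number (CN) to the potential maximum
#' retention `S` (mm) via the metric form `S = 25400 / CN - 254`. `S`
#' is strictly decreasing in CN, with `S = 0` at `CN = 100` (fully
#' impervious limit).
#'
#' @param cn Numeric vector of curve numbers, `0 < cn <= 100`.
#' @return Numeric vector of retention depths in mm.
#' @examples
#' retention_from_cn(c(100, 74, 50))
#' @export
retention_from_cn <- function(cn) {
  check_numeric(cn, "cn")
  if (any(cn <= 0 | cn > 100)) {
    abort("`cn` must lie in (0, 100].")
  }
  25400 / cn - 254
}

#' SCS curve-number runoff depth for a daily precipitation event
#'
#' Direct runoff `Q` (mm) from event precipitation `P` (mm) under the
#' SCS curve-number relation: no runoff until `P` exceeds the initial
#' abstraction `Ia = ia_ratio * S`, then
#' `Q = (P - Ia)^2 / (P - Ia + S)`. This encodes the assumption that a
#' fixed fraction of storm rainfall infiltrates (or is intercepted)
#' before Hortonian runoff starts.
#'
#' @param precip Numeric vector of precipitation depths in mm, `>= 0`.
#' @param cn Curve number(s), recycled against `precip`.
#' @param ia_ratio Initial abstraction as a fraction of `S`. The SCS
#'   default 0.2 is used throughout the package.
#' @return Runoff depths in mm, bounded by `0 <= Q <= precip`.
#' @examples
#' runoff_depth(26, cn = 82)      # 3.12 mm
#' runoff_depth(5, cn = 65)       # below initial abstraction: 0
#' @export
runoff_depth <- function(precip, cn, ia_ratio = 0.2) {
  check_numeric(precip, "precip")
  if (any(precip < 0)) abort("`precip` must be >= 0.")
  check_ia_ratio(ia_ratio)
  s <- retention_from_cn(cn)
  ia <- ia_ratio * s
  q <- ifelse(precip > ia, (precip - ia)^2 / (precip - ia + s), 0)
  pmin(q, precip)
}

#' Back-calculate a curve number from an observed rainfall-runoff pair
#'
#' Closed-form inversion of the SCS relation: given `P` and measured
#' `Q > 0`, solves the quadratic in the retention `S` and returns
#' `CN = 25400 / (S + 254)`. For the standard `ia_ratio = 0.2` the
#' root reduces to `S = 5 (P + 2Q - sqrt(4 Q^2 + 5 P Q))`.
#'
#' Events with zero measured runoff carry no information about the CN
#' (any CN whose abstraction exceeds `P` explains them); they return
#' `NA` and should be excluded from averaging.
#'
#' @inheritParams runoff_depth
#' @param runoff Measured runoff depths in mm; must not exceed `precip`.
#' @return Curve numbers; `NA` where `runoff` is zero (not invertible).
#' @examples
#' invert_cn(26, 4.38)   # the 26 mm -> 4.38 mm control-plot event: CN 84.5
#' invert_cn(26, runoff_depth(26, 82))  # round trip: 82
#' @export
invert_cn <- function(precip, runoff, ia_ratio = 0.2) {
  check_numeric(precip, "precip")
  check_numeric(runoff, "runoff")
  if (any(precip <= 0)) abort("`precip` must be > 0 to invert a CN.")
  if (any(runoff < 0)) abort("`runoff` must be >= 0.")
  if (any(runoff > precip + 1e-12)) {
    abort("`runoff` cannot exceed `precip`.")
  }
  check_ia_ratio(ia_ratio)
  n <- max(length(precip), length(runoff))
  p <- rep_len(precip, n)
  q <- rep_len(runoff, n)
  r <- ia_ratio
  # (P - rS)^2 = Q (P - rS + S)  =>  r^2 S^2 - (2rP + (1-r)Q) S + P(P - Q) = 0;
  # the smaller root keeps P - rS >= 0.
  b <- 2 * r * p + (1 - r) * q
  disc <- pmax(b^2 - 4 * r^2 * p * (p - q), 0)
  s <- (b - sqrt(disc)) / (2 * r^2)
  out <- 25400 / (s + 254)
  out[q == 0] <- NA_real_
  out
}

#' Precipitation-weighted mean curve number
#'
#' Seasonal average of event-wise curve numbers, each event weighted by
#' its precipitation depth so that large storms dominate the estimate.
#'
#' @param precip Event precipitation depths (the weights), mm.
#' @param cn Event-wise curve numbers; `NA` pairs are dropped.
#' @return A single weighted mean CN.
#' @examples
#' weighted_mean_cn(c(10, 30), c(70, 80))  # 77.5
#' @export
weighted_mean_cn <- function(precip, cn) {
  check_numeric(precip, "precip")
  check_numeric(cn, "cn")
  if (length(precip) != length(cn)) {
    abort("`precip` and `cn` must have the same length.")
  }
  keep <- !is.na(precip) & !is.na(cn)
  precip <- precip[keep]
  cn <- cn[keep]
  if (length(cn) == 0) abort("No events available to average.")
  if (any(precip <= 0)) abort("Weights `precip` must be > 0.")
  sum(precip * cn) / sum(precip)
}

#' Event-wise curve numbers for a trial event table
#'
#' Adds a back-calculated CN to each row of an event table (see
#' [read_events()] for the schema). QC-excluded events and events with
#' zero runoff are retained in the output but flagged non-invertible;
#' neither group enters [mean_event_cn()].
#'
#' @param events Data frame with columns `precip_mm`, `runoff_mm` and
#'   logical/0-1 `excluded`.
#' @inheritParams runoff_depth
#' @return The input as a tibble with columns `cn` and `invertible`.
#' @export
event_curve_numbers <- function(events, ia_ratio = 0.2) {
  events <- as_tibble(events)
  require_columns(events, c("precip_mm", "runoff_mm", "excluded"))
  cn <- rep(NA_real_, nrow(events))
  ok <- events$runoff_mm > 0 & events$precip_mm > 0
  cn[ok] <- invert_cn(events$precip_mm[ok], events$runoff_mm[ok], ia_ratio)
  dplyr::mutate(events,
    cn = cn,
    invertible = !is.na(cn) & !as.logical(.data$excluded)
  )
}

#' Precipitation-weighted mean CN of a trial event table
#'
#' @inheritParams event_curve_numbers
#' @param quiet Suppress the message listing dropped events.
#' @return One weighted mean CN over non-excluded, invertible events.
#' @export
mean_event_cn <- function(events, ia_ratio = 0.2, quiet = FALSE) {
  ev <- event_curve_numbers(events, ia_ratio)
  dropped <- sum(!ev$invertible)
  if (dropped > 0 && !quiet) {
    message(dropped, " event(s) excluded from CN averaging (QC flag or zero runoff).")
  }
  ev <- dplyr::filter(ev, .data$invertible)
  weighted_mean_cn(ev$precip_mm, ev$cn)
}

check_numeric <- function(x, name) {
  if (!is.numeric(x) || length(x) == 0 || anyNA(x)) {
    abort(paste0("`", name, "` must be numeric and free of NA."))
  }
  invisible(x)
}

check_ia_ratio <- function(ia_ratio) {
  if (!is.numeric(ia_ratio) || length(ia_ratio) != 1 ||
      ia_ratio <= 0 || ia_ratio >= 1) {
    abort("`ia_ratio` must be a single value in (0, 1).")
  }
  invisible(ia_ratio)
}

require_columns <- function(df, cols) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0("Missing required column(s): ", paste(missing, collapse = ", "), "."))
  }
  invisible(df)
}
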