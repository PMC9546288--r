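#' Read and write daily weather tables
#'
#' Weather CSVs carry two columns, `date` (ISO-8601) and `precip_mm`;
#' dates must be strictly increasing and depths non-negative.
#' Malformed files are rejected with the offending row number.
#'
#' @param path File path.
#' @return `read_weather()`: a weather tibble. `write_weather()`:
#'   `path`, invisibly.
#' @export
read_weather <- function(path) {
  df <- read_csv_strict(path, c("date", "precip_mm"))
  validate_weather(df)
}

#' @rdname read_weather
#' @param x Weather table to write.
#' @export
write_weather <- function(x, path) {
  readr::write_csv(validate_weather(x), path)
  invisible(path)
}

#' Read and write per-event trial tables
#'
#' Event CSVs carry one row per observed runoff/erosion event:
#' `date, precip_mm, runoff_mm, erosion_kg_ha, excluded` with
#' `excluded` in {0, 1} (QC flag, e.g. an overflowing collection
#' reservoir). Flagged rows are parsed but excluded from all
#' statistics downstream. Runoff may not exceed precipitation.
#'
#' @param path File path.
#' @return `read_events()`: an event tibble. `write_events()`:
#'   `path`, invisibly.
#' @export
read_events <- function(path) {
  df <- read_csv_strict(path, c("date", "precip_mm", "runoff_mm",
                                "erosion_kg_ha", "excluded"))
  validate_events(df)
}

#' @rdname read_events
#' @param x Event table to write.
#' @export
write_events <- function(x, path) {
  readr::write_csv(validate_events(x), path)
  invisible(path)
}

validate_events <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("date", "precip_mm", "runoff_mm",
                        "erosion_kg_ha", "excluded"))
  if (!all(df$excluded %in% c(0, 1, TRUE, FALSE))) {
    abort("`excluded` must be 0/1.")
  }
  bad <- which(df$runoff_mm > df$precip_mm + 1e-9)
  if (length(bad) > 0) {
    abort(paste0("`runoff_mm` exceeds `precip_mm` at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  if (any(df$precip_mm < 0) || any(df$runoff_mm < 0) ||
      any(df$erosion_kg_ha < 0)) {
    abort("Depths and masses must be >= 0.")
  }
  df$date <- as.Date(df$date)
  df$excluded <- as.integer(df$excluded)
  df
}

#' Read and write daily exposure tables
#'
#' Exposure CSVs carry the field-scale model outputs the stream
#' correction consumes, one row per day:
#' `date, rflx_mg_m2_d, runf_L_m2_d, infl_L_m2_d, precip_mm`.
#' Raw PRZM output reports the mass flux in g/cm2/day; pass
#' `rflx_units = "g_cm2_day"` to convert on read (factor 1e7).
#'
#' @param path File path.
#' @param rflx_units Units of the mass-flux column in the file.
#' @return `read_exposure()`: an exposure tibble. `write_exposure()`:
#'   `path`, invisibly.
#' @export
read_exposure <- function(path, rflx_units = c("mg_m2_day", "g_cm2_day")) {
  rflx_units <- match.arg(rflx_units)
  df <- read_csv_strict(path, c("date", "rflx_mg_m2_d", "runf_L_m2_d",
                                "infl_L_m2_d", "precip_mm"))
  if (rflx_units == "g_cm2_day") {
    df$rflx_mg_m2_d <- df$rflx_mg_m2_d * 1e7
  }
  validate_exposure(df)
}

#' @rdname read_exposure
#' @param x Exposure table to write.
#' @export
write_exposure <- function(x, path) {
  readr::write_csv(validate_exposure(x), path)
  invisible(path)
}

validate_exposure <- function(df) {
  df <- as_tibble(df)
  require_columns(df, c("date", "rflx_mg_m2_d", "runf_L_m2_d",
                        "infl_L_m2_d", "precip_mm"))
  num <- c("rflx_mg_m2_d", "runf_L_m2_d", "infl_L_m2_d", "precip_mm")
  for (nm in num) {
    bad <- which(is.na(df[[nm]]) | df[[nm]] < 0)
    if (length(bad) > 0) {
      abort(paste0("Negative or missing `", nm, "` at row(s) ",
                   paste(utils::head(bad, 5), collapse = ", "), "."))
    }
  }
  bad <- which(df$runf_L_m2_d > 0 & df$precip_mm <= 0)
  if (length(bad) > 0) {
    abort(paste0("Runoff without precipitation at row(s) ",
                 paste(utils::head(bad, 5), collapse = ", "), "."))
  }
  df$date <- as.Date(df$date)
  df
}

#' Read a whitespace-delimited daily model-output table
#'
#' Thin convenience reader for PRZM-style daily output: a header line
#' naming at least `YEAR MONTH DAY` plus any of `PRCP RUNF RFLX INFL`,
#' whitespace-separated. Columns are mapped by name onto the exposure
#' schema (`PRCP` cm -> `precip_mm`; `RFLX` g/cm2/day -> mg/m2/day).
#' Bit-exact compatibility with PRZM file dialects is not promised.
#'
#' @param path File path.
#' @param inflmon If `TRUE` (default), `INFL` is replaced by its
#'   monthly mean, the `INFLMON` quantity the dilution equation uses.
#' @return An exposure tibble as from [read_exposure()].
#' @export
read_przm_daily <- function(path, inflmon = TRUE) {
  df <- utils::read.table(path, header = TRUE, check.names = TRUE)
  require_columns(df, c("YEAR", "MONTH", "DAY"))
  get0c <- function(nm) if (nm %in% names(df)) df[[nm]] else 0
  out <- tibble(
    date = as.Date(sprintf("%04d-%02d-%02d", df$YEAR, df$MONTH, df$DAY)),
    rflx_mg_m2_d = get0c("RFLX") * 1e7,
    runf_L_m2_d = get0c("RUNF"),
    infl_L_m2_d = get0c("INFL"),
    precip_mm = get0c("PRCP") * 10
  )
  if (inflmon) {
    out <- out |>
      dplyr::group_by(ym = format(.data$date, "%Y-%m")) |>
      dplyr::mutate(infl_L_m2_d = mean(.data$infl_L_m2_d)) |>
      dplyr::ungroup() |>
      dplyr::select(-"ym")
  }
  validate_exposure(out)
}

read_csv_strict <- function(path, cols) {
  if (!file.exists(path)) abort(paste0("File not found: ", path))
  df <- readr::read_csv(path, show_col_types = FALSE,
                        progress = FALSE, col_types = readr::cols())
  require_columns(df, cols)
  num <- setdiff(cols, c("date", "excluded"))
  for (nm in num) {
    if (!is.numeric(df[[nm]])) {
      first_bad <- which(is.na(suppressWarnings(as.numeric(df[[nm]]))))[1]
      abort(paste0("Non-numeric value in `", nm, "` at row ", first_bad, "."))
    }
  }
  df
}
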