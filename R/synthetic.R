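#' Design of a synthetic mitigation trial
#'
#' Specifies a trial in which several tillage/mitigation treatments
#' share one rainfall season and differ only in their true curve
#' number and MUSS C-factor — the way the field trials encode
#' treatment effects. Rainfall follows a wet-day Bernoulli process
#' with gamma-distributed depths, the simplest generator reproducing
#' episodic 5–20+ mm events; optional multiplicative lognormal noise
#' emulates volumetric sampling error on the "measured" quantities.
#'
#' @param treatments Data frame with columns `label`, `cn`, `c_factor`;
#'   the first row (or the row labelled `"control"`/`"CvT"`) is the
#'   control.
#' @param n_days Season length in days (default 180, an April–October
#'   cropping season).
#' @param wet_prob Daily wet-day probability in \[0, 1\] (default 0.15).
#' @param gamma_shape,gamma_scale Gamma parameters of wet-day depths in
#'   mm (defaults 0.8 and 12: mean 9.6 mm, occasional 30+ mm storms).
#' @param noise_cv Relative (coefficient-of-variation) measurement
#'   noise on runoff and erosion; default 0 so parameter-recovery is
#'   exact.
#' @param seed Integer seed; every generated artifact records it.
#' @param start Season start date.
#' @return An object of class `trial_design`.
#' @export
trial_design <- function(treatments, n_days = 180, wet_prob = 0.15,
                         gamma_shape = 0.8, gamma_scale = 12,
                         noise_cv = 0, seed = 1L,
                         start = as.Date("2019-04-01")) {
  treatments <- as_tibble(treatments)
  require_columns(treatments, c("label", "cn", "c_factor"))
  if (nrow(treatments) < 1) abort("At least one treatment is required.")
  if (anyDuplicated(treatments$label)) abort("Treatment labels must be unique.")
  if (wet_prob < 0 || wet_prob > 1) abort("`wet_prob` must be in [0, 1].")
  if (gamma_shape <= 0 || gamma_scale <= 0) {
    abort("Gamma parameters must be > 0.")
  }
  if (noise_cv < 0) abort("`noise_cv` must be >= 0.")
  structure(
    list(treatments = treatments, n_days = as.integer(n_days),
         wet_prob = wet_prob, gamma_shape = gamma_shape,
         gamma_scale = gamma_scale, noise_cv = noise_cv,
         seed = as.integer(seed), start = as.Date(start)),
    class = "trial_design"
  )
}

#' Generate a daily weather series from a trial design
#'
#' Wet days are Bernoulli(`wet_prob`); depths on wet days are
#' Gamma(`gamma_shape`, scale = `gamma_scale`) mm. Reproducible for a
#' fixed seed (drawn in an isolated RNG scope, so the caller's RNG
#' state is untouched).
#'
#' @param design A [trial_design()].
#' @return Weather tibble (`date`, `precip_mm`) with attribute `seed`.
#' @export
generate_weather <- function(design) {
  stopifnot(inherits(design, "trial_design"))
  precip <- withr::with_seed(design$seed, {
    wet <- rbinom(design$n_days, 1, design$wet_prob)
    depth <- rgamma(design$n_days, shape = design$gamma_shape,
                    scale = design$gamma_scale)
    wet * depth
  })
  structure(
    tibble(date = design$start + seq_len(design$n_days) - 1,
           precip_mm = precip),
    seed = design$seed
  )
}

#' Generate a complete synthetic mitigation trial
#'
#' Simulates every treatment of the design over one shared weather
#' series at its true (CN, C-factor), producing per-treatment daily
#' event tables and seasonal totals, optionally perturbed by
#' multiplicative lognormal measurement noise (mean-1, relative SD
#' `noise_cv`). The ground truth travels with the result so that
#' calibration and comparison stages can be tested end to end.
#'
#' @inheritParams generate_weather
#' @param plot A [field_plot()] template; its `cn` and `c` are
#'   overridden per treatment.
#' @return An object of class `mitigation_trial`: list with `weather`,
#'   `events` (per-treatment daily tables), `totals` (one row per
#'   treatment with true parameters and measured totals), `design`.
#' @export
generate_trial <- function(design, plot) {
  stopifnot(inherits(design, "trial_design"), inherits(plot, "field_plot"))
  weather <- generate_weather(design)
  tr <- design$treatments
  # mean-1 multiplicative lognormal noise; an independent stream per treatment
  noise <- function(n, k) {
    if (design$noise_cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + design$noise_cv^2))
    withr::with_seed(design$seed + 1000L * k,
                     rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog))
  }
  events <- list()
  rows <- list()
  for (i in seq_len(nrow(tr))) {
    pl <- plot
    pl$cn <- tr$cn[i]
    pl$c <- tr$c_factor[i]
    sim <- simulate_season(weather, pl)
    f <- noise(2 * nrow(sim), i)
    ev <- tibble(
      date = sim$date, precip_mm = sim$precip_mm,
      runoff_mm = pmin(sim$runoff_mm * f[seq_len(nrow(sim))], sim$precip_mm),
      erosion_kg_ha = sim$soil_loss_kg_ha * f[nrow(sim) + seq_len(nrow(sim))],
      excluded = 0L
    )
    events[[tr$label[i]]] <- ev
    tot <- season_totals(sim)
    rows[[i]] <- tibble(
      label = tr$label[i], cn_true = tr$cn[i], c_true = tr$c_factor[i],
      runoff_mm = tot$total_runoff_mm,
      erosion_kg_ha = tot$total_erosion_kg_ha,
      measured_runoff_mm = sum(ev$runoff_mm),
      measured_erosion_kg_ha = sum(ev$erosion_kg_ha),
      n_runoff_events = tot$n_runoff_events
    )
  }
  totals <- dplyr::bind_rows(rows)
  structure(
    list(weather = weather, events = events, totals = totals,
         design = design, plot = plot, seed = design$seed),
    class = "mitigation_trial"
  )
}

#' @export
print.mitigation_trial <- function(x, ...) {
  cat("<mitigation_trial> seed ", x$seed, ", ",
      nrow(x$totals), " treatment(s), ",
      x$design$n_days, " days\n", sep = "")
  print(x$totals)
  invisible(x)
}
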