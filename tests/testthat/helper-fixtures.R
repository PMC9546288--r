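# Shared builders for small deterministic inputs.

make_plot <- function(cn = 80, c = 7.17, area_ha = 0.0072,
                      k = 0.12, ls = 1.05, p = 1) {
  field_plot(area_ha = area_ha, k = k, ls = ls, c = c, p = p, cn = cn)
}

make_weather <- function(precip, start = as.Date("2019-05-01")) {
  tibble::tibble(date = start + seq_along(precip) - 1, precip_mm = precip)
}

# a short wet season with a mix of dry days, small and large storms
wet_weather <- function() {
  make_weather(c(0, 26, 0, 12, 40, 0, 0, 8, 19.9, 0, 33, 5))
}

two_treatment_design <- function(seed = 11, noise_cv = 0, ...) {
  trial_design(
    tibble::tibble(label = c("CvT", "MD"),
                   cn = c(80, 75), c_factor = c(7.17, 7.14)),
    seed = seed, noise_cv = noise_cv, ...
  )
}
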