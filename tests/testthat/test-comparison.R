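test_that("percent reductions reproduce the printed trial columns", {
  # 2019 runoff, micro-dams on conventional tillage: 9.7 -> 3.3 mm
  expect_equal(report_round(percent_reduction(9.7, 3.3)), 66)
  # 2018 erosion, conservation tillage: 2371 -> 62 kg/ha
  expect_equal(round(percent_reduction(2371, 62), 1), 97.4)
  expect_equal(report_round(percent_reduction(2371, 62)), 97)
  expect_equal(percent_reduction(5, 5), 0)
  expect_error(percent_reduction(0, 1), "> 0")
  expect_error(percent_reduction(1, -1), ">= 0")
})

test_that("percent reduction is antitone in the treated value and scale-invariant", {
  withr::with_seed(9, {
    for (i in 1:30) {
      ctrl <- runif(1, 0.5, 100)
      tr <- sort(runif(2, 0, ctrl))
      expect_gte(percent_reduction(ctrl, tr[1]), percent_reduction(ctrl, tr[2]))
      a <- runif(1, 0.1, 10)
      expect_equal(percent_reduction(a * ctrl, a * tr[1]),
                   percent_reduction(ctrl, tr[1]), tolerance = 1e-12)
    }
  })
})

test_that("CN reductions are reported in points and percent", {
  r <- cn_point_reduction(80, 75)
  expect_equal(r$points, 5)
  expect_equal(r$percent, 6.25)
  r2 <- cn_point_reduction(74, 67)
  expect_equal(r2$points, 7)
  expect_equal(round(r2$percent, 2), 9.46)
  expect_equal(cn_point_reduction(70, 70)$points, 0)
})

test_that("relative C-factors allow increases (negative reduction)", {
  r <- relative_c_factor(7.17, 2.33)
  expect_equal(report_round(r$ratio, "relative"), 0.32)
  expect_equal(report_round(r$reduction, "relative"), 0.68)
  # drum plow on the 16% slope: C rises from 0.74 to 0.79
  r2 <- relative_c_factor(0.74, 0.79)
  expect_equal(report_round(r2$ratio, "relative"), 1.07)
  expect_lt(r2$reduction, 0)
  expect_equal(relative_c_factor(2, 2)$reduction, 0)
  expect_error(relative_c_factor(0, 1), "> 0")
})

test_that("summary blocks use the population-SD convention of the report tables", {
  # micro-dams on conventional tillage, six season-wise CN point deltas
  md_points <- c(5, 7, 1, 5, 3, 5)
  s <- reduction_summary(md_points, "MD+CvT vs CvT", "points")
  expect_equal(report_round(s$mean), 4)
  expect_equal(report_round(s$sd, "sd"), 1.9)
  # the sample-SD convention would print 2.1 — only divisor n reproduces 1.9
  expect_equal(round(sd(md_points), 1), 2.1)
  expect_equal(s$sd, sqrt(mean((md_points - mean(md_points))^2)))
  # conservation-tillage percent deltas
  cst_pct <- c(17.5, 100 * 8 / 74, 100 * 9 / 81, 100 * 8 / 79)
  s2 <- reduction_summary(cst_pct)
  expect_equal(round(s2$mean, 2), 12.39)
  expect_equal(report_round(s2$mean), 12)
  expect_equal(report_round(s2$sd, "sd"), 3.0)
  # single pair: sd is exactly 0
  expect_equal(reduction_summary(4.2)$sd, 0)
  expect_error(reduction_summary(numeric()), "numeric")
})

test_that("season-fit summary blocks reproduce the printed means and SDs", {
  fits <- season_fits()
  cvt <- dplyr::filter(fits, treatment == "CvT")
  md <- dplyr::filter(fits, grepl("MD\\+CvT|plow", treatment))
  md <- dplyr::left_join(md, dplyr::select(cvt, trial, cn_c = cn, c_c = c_factor),
                         by = "trial")
  # CN points: 4 (+-1.9); percent: 6 (+-2.5)
  pts <- reduction_summary(cn_point_reduction(md$cn_c, md$cn)$points)
  expect_equal(pts$n, 6)
  expect_equal(report_round(pts$mean), 4)
  expect_equal(report_round(pts$sd, "sd"), 1.9)
  pct <- reduction_summary(cn_point_reduction(md$cn_c, md$cn)$percent)
  expect_equal(report_round(pct$mean), 6)
  expect_equal(report_round(pct$sd, "sd"), 2.5)
  # relative C-factor reduction for micro-dams: 0.10 (+-0.15)
  crel <- reduction_summary(relative_c_factor(md$c_c, md$c_factor)$reduction)
  expect_equal(report_round(crel$mean, "relative"), 0.10)
  expect_equal(report_round(crel$sd, "relative"), 0.15)
  # conservation tillage vs conventional: 10 (+-2.5) points, 12 (+-3.0) %
  cst <- dplyr::filter(fits, treatment == "CsT")
  cst <- dplyr::left_join(cst, dplyr::select(cvt, trial, cn_c = cn, c_c = c_factor),
                          by = "trial")
  cst_red <- cn_point_reduction(cst$cn_c, cst$cn)
  expect_equal(report_round(reduction_summary(cst_red$points)$mean), 10)
  expect_equal(report_round(reduction_summary(cst_red$points)$sd, "sd"), 2.5)
  expect_equal(report_round(reduction_summary(cst_red$percent)$mean), 12)
  expect_equal(report_round(reduction_summary(cst_red$percent)$sd, "sd"), 3.0)
  # C-factor reduction for conservation tillage: 0.48 (+-0.19)
  cst_c <- reduction_summary(relative_c_factor(cst$c_c, cst$c_factor)$reduction)
  expect_equal(report_round(cst_c$mean, "relative"), 0.48)
  expect_equal(report_round(cst_c$sd, "relative"), 0.19)
})
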