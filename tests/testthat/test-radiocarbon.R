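# F14C arithmetic, calibration, combinability, contamination solver.

test_that("age <-> F14C conversions are mutual inverses", {
  expect_equal(f14c_from_age(0), 1.0)
  # frozen closed form: F = 0.5 -> t = 8033 * ln 2 = 5567.995...
  expect_equal(age_from_f14c(0.5), 8033 * log(2), tolerance = 1e-12)
  for (t in c(100, 5568, 13900, 40000)) {
    expect_lt(abs(age_from_f14c(f14c_from_age(t)) - t), 1e-9)
  }
  expect_error(age_from_f14c(0), "positive")
  expect_error(radiocarbon_date("X", 1000, 0), "sigma")
})

test_that("calibration on the identity curve matches the Gaussian closed form", {
  curve <- synthetic_identity_curve(0, 25000, by = 5, sigma_curve = 10)
  d <- radiocarbon_date("T", 5000, 40)
  cal <- calibrate(d, curve, rounding = 1)
  sd_tot <- sqrt(40^2 + 10^2)

  # posterior mass conservation
  expect_lt(abs(sum(cal$posterior) - 1), 1e-9)
  # single HPD interval ~ age +/- z * sd_tot, z for central 95.4%
  expect_identical(nrow(cal$ranges_2sigma), 1L)
  z <- qnorm(1 - (1 - 0.954) / 2)
  expect_lt(abs(cal$ranges_2sigma$older - (5000 + z * sd_tot)), 3)
  expect_lt(abs(cal$ranges_2sigma$younger - (5000 - z * sd_tot)), 3)
  # interval mass within 0.5% of nominal on the 1-yr grid
  expect_lt(abs(sum(cal$ranges_1sigma$mass) - 0.683), 0.005)
  expect_lt(abs(sum(cal$ranges_2sigma$mass) - 0.954), 0.005)
  # median at the mode for a symmetric posterior
  expect_lt(abs(cal$median - 5000), 2)
  # median inside the 2-sigma envelope
  expect_true(cal$median <= max(cal$ranges_2sigma$older) &&
              cal$median >= min(cal$ranges_2sigma$younger))

  # degenerate limit: tiny sigma collapses onto the true age
  cal0 <- calibrate(radiocarbon_date("T", 5000, 1),
                    synthetic_identity_curve(4900, 5100, by = 1, sigma_curve = 0.5),
                    rounding = 1)
  expect_lt(abs(cal0$median - 5000), 1.5)

  expect_error(calibrate(radiocarbon_date("T", 27000, 200), curve), "edge|span")
})

test_that("range endpoints round outward and central mode is available", {
  curve <- synthetic_identity_curve(0, 25000, by = 5, sigma_curve = 10)
  cal10 <- calibrate(radiocarbon_date("T", 5003, 40), curve, rounding = 10)
  expect_true(all(cal10$ranges_2sigma$older %% 10 == 0))
  expect_true(all(cal10$ranges_2sigma$younger %% 10 == 0))
  cal1 <- calibrate(radiocarbon_date("T", 5003, 40), curve, rounding = 1)
  expect_gte(cal10$ranges_2sigma$older, cal1$ranges_2sigma$older)
  expect_lte(cal10$ranges_2sigma$younger, cal1$ranges_2sigma$younger)
  calc <- calibrate(radiocarbon_date("T", 5003, 40), curve, rounding = 1,
                    range_style = "central")
  expect_lt(abs(calc$ranges_2sigma$older - cal1$ranges_2sigma$older), 5)
})

test_that("a wiggly curve yields multi-interval HPD ranges", {
  # plateau-and-reversal curve: two calendar windows share one 14C age
  grid <- seq(1000, 3000, by = 1)
  mu <- 2000 + 150 * sin((grid - 1000) / 120 + 1)
  curve <- calibration_curve(grid, mu, rep(15, length(grid)))
  cal <- calibrate(radiocarbon_date("W", 2000, 20), curve, rounding = 1)
  expect_gt(nrow(cal$ranges_2sigma), 1L)
  expect_lt(abs(sum(cal$posterior) - 1), 1e-9)
})

test_that("median_separation reports magnitude and sign", {
  curve <- synthetic_identity_curve(0, 25000, by = 5, sigma_curve = 5)
  a <- calibrate(radiocarbon_date("A", 350, 1), curve, rounding = 1)
  b <- calibrate(radiocarbon_date("B", 100, 1), curve, rounding = 1)
  ms <- median_separation(a, b)
  expect_equal(ms$years, 250, tolerance = 0.01)
  expect_gt(ms$signed, 0)
  expect_equal(median_separation(a, a)$years, 0)
})

test_that("ward_wilson_combine applies the chi-square homogeneity rule", {
  d1 <- radiocarbon_date("A", 13900, 50)
  expect_true(ward_wilson_combine(list(d1, d1))$combinable)
  expect_equal(ward_wilson_combine(list(d1, d1))$chi2, 0)

  # 280 14C-yr apart with sigmas 50 and 35: chi2 = 280^2/(50^2+35^2) = 21.05
  d2 <- radiocarbon_date("B", 13620, 35)
  ww <- ward_wilson_combine(list(d1, d2))
  expect_equal(ww$chi2, 280^2 / (50^2 + 35^2), tolerance = 1e-9)
  expect_false(ww$combinable)
  # pooled mean is the inverse-variance weighted mean (independent arithmetic)
  w <- c(1 / 50^2, 1 / 35^2)
  expect_equal(ww$pooled_age, sum(w * c(13900, 13620)) / sum(w))

  # three dates within 1 sigma of each other combine
  dd <- list(radiocarbon_date("A", 13900, 50), radiocarbon_date("B", 13930, 50),
             radiocarbon_date("C", 13880, 50))
  expect_true(ward_wilson_combine(dd)$combinable)
  expect_error(ward_wilson_combine(list(d1)), "at least 2")
})

test_that("required_contamination inverts the mixing model", {
  expect_equal(required_contamination(13900, 13900)$c, 0)
  # linear mixing on the F scale: F_true .5, F_obs .55, F_cont 1 -> 10%
  r <- required_contamination(age_from_f14c(0.5), age_from_f14c(0.55))
  expect_equal(r$percent, 10, tolerance = 1e-9)
  # observed older than truth with a modern contaminant: inconsistent direction
  r <- required_contamination(13900, 14500)
  expect_false(r$consistent)
  expect_lt(r$c, 0)
  expect_error(required_contamination(0, 100, f_contaminant = 1), "undefined")
})

test_that("round trip: required_contamination recovers simulate_c14's fraction", {
  for (c_ in c(0.001, 0.005, 0.02, 0.1, 0.2)) {
    d <- simulate_c14(13900, c_, contaminant_f14c = 1.0, measurement_sigma = 0)
    expect_lt(abs(required_contamination(13900, d)$c - c_), 1e-10)
  }
})

test_that("curve files and date tables round-trip through their readers", {
  dir <- withr_tempdir()
  cpath <- file.path(dir, "curve.14c")
  writeLines(c("# comment", "CAL BP, 14C age, sigma",
               "100, 180, 8", "200,  260,9", "300,330, 10"), cpath)
  cv <- read_calibration_curve(cpath)
  expect_equal(cv$cal_bp, c(100, 200, 300))
  expect_equal(cv$mu, c(180, 260, 330))
  # whitespace dialect
  writeLines(c("100 180 8", "200 260 9"), cpath)
  expect_equal(read_calibration_curve(cpath)$sigma_curve, c(8, 9))

  dpath <- file.path(dir, "dates.csv")
  writeLines(c("lab_code,age_bp,sigma", "L1,13900,48", "L2,13620,35"), dpath)
  dates <- read_c14_table(dpath)
  expect_identical(names(dates), c("L1", "L2"))
  expect_equal(dates$L1$f14c, exp(-13900 / 8033))
})
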