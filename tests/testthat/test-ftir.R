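make_gaussian_spectrum <- function(center = 1724, sigma = 10, amp = 1,
                                   wn = seq(650, 4000, by = 1.9), offset = 0) {
  ftir_spectrum(wn, offset + amp * exp(-(wn - center)^2 / (2 * sigma^2)))
}

test_that("spectra are stored ascending and validated", {
  wn <- seq(650, 4000, by = 1)
  s <- ftir_spectrum(rev(wn), rev(wn) * 0 + 1)
  expect_equal(s$wavenumbers, wn)

  expect_error(ftir_spectrum(1:3, 1:2), "length")
  expect_error(ftir_spectrum(1000, 0.5), "at least 2")
  expect_error(ftir_spectrum(c(1000, 1000, 1001), c(1, 2, 3)), "monotone")
})

test_that("read_spectrum handles CSV/TSV, comments and orientation", {
  wn <- seq(650, 4000, by = 1)
  ab <- 0.1 + 0.5 * exp(-(wn - 1724)^2 / 200)

  csv <- tempfile(fileext = ".csv")
  writeLines(c("# instrument export", paste(wn, ab, sep = ",")), csv)
  s <- read_spectrum(csv)
  expect_length(s$wavenumbers, 3351L)
  expect_equal(s$absorbance, ab)

  # descending file yields the identical ascending spectrum
  desc <- tempfile(fileext = ".csv")
  writeLines(paste(rev(wn), rev(ab), sep = ","), desc)
  s2 <- read_spectrum(desc)
  expect_equal(s2$wavenumbers, s$wavenumbers)
  expect_equal(s2$absorbance, s$absorbance)

  one <- tempfile(fileext = ".csv")
  writeLines("1000,0.5", one)
  expect_error(read_spectrum(one), "at least 2")

  bad <- tempfile(fileext = ".csv")
  writeLines(c("1000,0.5", "1001,abc", "1002,0.7"), bad)
  expect_error(read_spectrum(bad), "non-numeric")

  dup <- tempfile(fileext = ".tsv")
  writeLines(paste(c(1000, 1000, 1002), c(1, 2, 3), sep = "\t"), dup)
  expect_error(read_spectrum(dup), "duplicate")
})

test_that("offset baseline correction zeroes the window minimum", {
  wn <- seq(650, 4000, by = 1.9)
  s <- ftir_spectrum(wn, -0.02 + 0.3 * exp(-(wn - 1650)^2 / 600))
  corr <- baseline_correct(s, method = "offset")
  win <- corr$wavenumbers >= 1500 & corr$wavenumbers <= 1800
  expect_equal(min(corr$absorbance[win]), 0)
  # original untouched
  expect_lt(min(s$absorbance), 0)

  # already non-negative with window minimum 0: unchanged
  s0 <- ftir_spectrum(wn, pmax(0, 0.3 * exp(-(wn - 1650)^2 / 600) - 1e-6))
  expect_equal(baseline_correct(s0, method = "offset")$absorbance, s0$absorbance)

  expect_error(baseline_correct(s, window = c(100, 200)), "outside")
})

test_that("linear baseline correction recovers band areas under drift", {
  clean <- gen_spectrum(seed = 1, pha_fraction = 0.44, baseline_offset = 0,
                        baseline_slope = 0, noise_sd = 0)
  drift <- gen_spectrum(seed = 1, pha_fraction = 0.44, baseline_offset = 0.05,
                        baseline_slope = 3e-5, noise_sd = 0)
  corr <- baseline_correct(drift$spectrum, method = "linear")
  a_clean <- integrate_region(clean$spectrum, region_carbonyl())
  a_corr <- integrate_region(corr, region_carbonyl())
  expect_lt(abs(a_corr - a_clean) / a_clean, 0.01)
})

test_that("region integration is exact on rectangles and Gaussians", {
  wn <- seq(650, 4000, by = 1)
  flat <- ftir_spectrum(wn, rep(1, length(wn)))
  expect_equal(integrate_region(flat, region_carbonyl()), 58, tolerance = 1e-9)
  expect_equal(integrate_region(ftir_spectrum(wn, rep(0, length(wn))),
                                region_amide1()), 0)

  # Gaussian band fully inside a region matches amp * sigma * sqrt(2*pi)
  g <- make_gaussian_spectrum(center = 1724, sigma = 10, amp = 0.8)
  area <- integrate_region(g, ftir_region(1600, 1850))
  expect_lt(abs(area - 0.8 * 10 * sqrt(2 * pi)) / area, 0.001)

  expect_error(integrate_region(flat, ftir_region(100, 200)), "overlap")
})

test_that("integration is linear and additive over touching regions", {
  wn <- seq(650, 4000, by = 1.9)
  set.seed(161)
  s1 <- ftir_spectrum(wn, runif(length(wn)))
  s2 <- ftir_spectrum(wn, runif(length(wn)))
  comb <- ftir_spectrum(wn, 2.5 * s1$absorbance + 0.3 * s2$absorbance)
  r <- ftir_region(1580, 1763)
  expect_equal(integrate_region(comb, r),
               2.5 * integrate_region(s1, r) + 0.3 * integrate_region(s2, r),
               tolerance = 1e-9)

  expect_equal(integrate_region(s1, region_amide1()) +
                 integrate_region(s1, region_carbonyl()),
               integrate_region(s1, ftir_region(1580, 1763)),
               tolerance = 1e-9)
})

test_that("C:A 1 ratio is scale- and orientation-invariant", {
  g <- gen_spectrum(seed = 2, pha_fraction = 0.3)
  s <- g$spectrum
  r0 <- ca1_ratio(s)$ratio
  scaled <- ftir_spectrum(s$wavenumbers, 3.7 * s$absorbance)
  expect_equal(ca1_ratio(scaled)$ratio, r0, tolerance = 1e-12)
  flipped <- ftir_spectrum(rev(s$wavenumbers), rev(s$absorbance))
  expect_equal(ca1_ratio(flipped)$ratio, r0, tolerance = 1e-12)
})

test_that("carbonyl peak detection flags PHA-positive spectra only", {
  pos <- ca1_ratio(gen_spectrum(seed = 3, pha_fraction = 0.3)$spectrum)
  expect_true(pos$pha_positive)
  expect_lt(abs(pos$carbonyl_peak_cm1 - 1724), 1.9)

  neg <- ca1_ratio(gen_spectrum(seed = 3, pha_fraction = 0, noise_sd = 0)$spectrum)
  expect_false(neg$pha_positive)
  expect_lt(neg$ratio, 0.05)

  wn <- seq(650, 4000, by = 1.9)
  expect_error(ca1_ratio(ftir_spectrum(wn, rep(0, length(wn)))), "amide")
})

test_that("per-hour normalization supports both rate definitions", {
  rr <- ratio_rate(c(4, 10), c(0.2, 0.5), stationary_onset = 10)
  expect_equal(rr$rate, 0.05)
  expect_equal(rr$rate_slope, 0.3 / 6)

  # constant-zero series
  expect_equal(ratio_rate(c(2, 4, 6), c(0, 0, 0), 4)$rate, 0)

  # linear growth r * t: slope definition recovers r exactly
  tt <- seq(2, 20, by = 2)
  rr2 <- ratio_rate(tt, 0.031 * tt, stationary_onset = 10)
  expect_equal(rr2$rate_slope, 0.031, tolerance = 1e-12)
  expect_equal(rr2$rate, 0.031)  # ratio/time coincides for a through-origin line

  expect_error(ratio_rate(c(2, 4), c(0.1, 0.2), 10), "stationary")
})

test_that("ratio-to-PHA calibration is explicit about validity", {
  expect_equal(calibrate_ratio_to_pha(0.5, 40, 0)$pha_pct_cdw, 20)
  expect_true(calibrate_ratio_to_pha(0.5, 40, 0)$valid)
  over <- calibrate_ratio_to_pha(1.25, 40, 0)
  expect_equal(over$pha_pct_cdw, 50)
  expect_false(over$valid)
  expect_equal(calibrate_ratio_to_pha(0, 40, 5)$pha_pct_cdw, 5)
  expect_false(calibrate_ratio_to_pha(0.5)$calibrated)
})
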