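test_that("phi is the log accessibility ratio", {
  expect_equal(phi(2, 2), 0)
  expect_equal(phi(2 * exp(1), 2), 1)
  expect_equal(phi(5, 2), log(2.5)) # ~0.9163
  expect_error(phi(-1, 2), "positive")
  expect_error(phi(2, 0), "positive")
  ## identity on ratios: phi(x e^y, x) = y
  for (x in c(0.1, 1, 7)) for (y in c(-2, 0.5, 3)) {
    expect_equal(phi(x * exp(y), x), y)
  }
})

test_that("accessibility profiles mask undefined residues", {
  pr <- accessibility_profile(1:4, c(1, 2, NA, 0), c(1, 1, 1, 1))
  expect_equal(pr$phi[1:2], c(0, log(2)))
  expect_true(all(is.na(pr$phi[3:4])))
})

test_that("depth calibration recovers the reference constants", {
  ## noiseless points generated from the measured constants -> exact refit
  cs <- gen_calibration_points(3.5, 0.37, phis = seq(0, 2.5, length.out = 6))
  fit <- calibrate_depth(cs)
  expect_equal(fit$a, 3.5, tolerance = 1e-9)
  expect_equal(fit$b, 0.37, tolerance = 1e-9)

  ## two points define the line exactly
  fit2 <- calibrate_depth(data.frame(phi = c(0, 1), depth = c(0.37, 3.87)))
  expect_equal(fit2$a, 3.5)
  expect_equal(max(abs(fit2$residuals)), 0, tolerance = 1e-12)

  ## seeded noisy recovery within 10%
  cs3 <- gen_calibration_points(3.5, 0.37, phis = seq(0.1, 2.5, length.out = 8),
                                noise_sd = 0.3, seed = 11)
  fit3 <- calibrate_depth(cs3)
  expect_lt(abs(fit3$a - 3.5) / 3.5, 0.10)

  expect_error(calibrate_depth(data.frame(phi = c(1, 1), depth = c(1, 2))),
               "degenerate|distinct")
})

test_that("depth conversion is the affine calibration map", {
  cal <- reference_depth_calibration()
  expect_equal(depth_from_phi(0, cal), 0.37)
  expect_equal(depth_from_phi(2.18, cal), 3.5 * 2.18 + 0.37) # 8.0 A
  ## affine identity d(a) + d(b) - b0 = d(a + b)
  expect_equal(depth_from_phi(1.1, cal) + depth_from_phi(0.7, cal) - cal$b,
               depth_from_phi(1.8, cal))
  expect_equal(tidy(calibrate_depth(gen_calibration_points(
    3.5, 0.37, phis = c(0, 1, 2))))$estimate, c(3.5, 0.37))
})

test_that("periodicity fit recovers the helical period", {
  pr <- gen_accessibility_profile(11, period = 3.6, phase = 0.8, amplitude = 1)
  fit <- fit_periodicity(pr)
  expect_equal(fit$period, 3.6, tolerance = 1e-3)
  expect_true(fit$identifiable)

  ## constant profile: amplitude ~ 0 and unidentifiable period
  fit0 <- fit_periodicity(data.frame(residue = 1:10, phi = rep(0.5, 10)))
  expect_lt(fit0$amplitude, 1e-6)
  expect_false(fit0$identifiable)

  ## noisy recovery (SNR 5): period within 0.2 of 3.6
  prn <- gen_accessibility_profile(15, period = 3.6, amplitude = 1,
                                   noise_sd = 0.2, seed = 4)
  fitn <- fit_periodicity(prn)
  expect_lt(abs(fitn$period - 3.6), 0.2)
  expect_error(fit_periodicity(data.frame(residue = 1:3, phi = rnorm(3))),
               ">= 5")
})

test_that("helical wheel puts accessibility maxima on one face", {
  ## ideal amphipathic profile: maxima fall on the lipid-facing face
  pr <- gen_accessibility_profile(15, period = 3.6, phase = 0)
  hw <- helical_wheel(pr)
  top3 <- hw$residue[order(-hw$phi)][1:3]
  expect_true(all(hw$face[hw$residue %in% top3] == "lipid"))
  bottom3 <- hw$residue[order(hw$phi)][1:3]
  expect_true(all(hw$face[hw$residue %in% bottom3] == "solvent"))

  ## rotating the phase by pi swaps the face labels
  fit <- fit_periodicity(pr)
  fit2 <- fit
  fit2$phase <- fit$phase + pi
  hw2 <- helical_wheel(pr, fit2)
  defined <- !is.na(hw$face)
  expect_true(all(hw$face[defined] != hw2$face[defined]))
})

test_that("measured-geometry profiles separate residues 4/5 from 6/10/13", {
  ## phase chosen so residues 6, 10, 13 sit near maxima (lipid face) and
  ## 4, 5 on the solvent face, as in the measured profile
  ph <- -2 * pi * 10 / 3.6 # residue 10 at a maximum
  pr <- gen_accessibility_profile(15, period = 3.6, phase = ph)
  hw <- helical_wheel(pr)
  expect_true(all(hw$face[hw$residue %in% c(6, 10, 13)] == "lipid"))
  expect_true(all(hw$face[hw$residue %in% c(4, 5)] == "solvent"))
})

test_that("spin-dilution distance estimation round-trips the generator", {
  for (r in c(9, 13, 21)) {
    est <- estimate_distance(gen_pair_spectrum(r, 2, 1, seed = 5))
    expect_lt(abs(est$r_center - r), 1)
    expect_gt(est$interacting_fraction, 0.9)
  }
  ## partially interacting population (the liposome-bound regime)
  est <- estimate_distance(gen_pair_spectrum(13, 2, 0.15, seed = 5))
  expect_gte(est$interacting_fraction, 0.10)
  expect_lte(est$interacting_fraction, 0.20)
  ## no interaction: fraction ~ 0, flagged beyond sensitivity
  est0 <- estimate_distance(gen_pair_spectrum(13, 2, 0, seed = 5))
  expect_lt(est0$interacting_fraction, 0.05)
  expect_true(est0$beyond_sensitivity)
})

test_that("distance estimation is invariant to overall amplitude scaling", {
  pr <- gen_pair_spectrum(13, 2, 0.6, seed = 8)
  est1 <- estimate_distance(pr)
  pr2 <- pr
  pr2$spectra$full_labeled <- 37 * pr2$spectra$full_labeled
  pr2$spectra$spin_diluted <- 37 * pr2$spectra$spin_diluted
  est2 <- estimate_distance(pr2)
  expect_equal(est1$r_center, est2$r_center, tolerance = 1e-6)
  expect_equal(est1$interacting_fraction, est2$interacting_fraction,
               tolerance = 1e-6)
})

test_that("distance estimation rejects mismatched field grids", {
  pr <- gen_pair_spectrum(13, 2, 1, seed = 1)
  bad <- pr$spectra
  bad$field <- bad$field^1.001 # non-uniform
  expect_error(estimate_distance(bad), "uniform")
})
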