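test_that("estimate_noise recovers an injected noise level", {
  sp <- pc_spectrum(noise_sigma = 0.4, seed = 13, calibrate = FALSE,
                    baseline = FALSE)
  # oracle: time-domain sigma 0.4 maps to sd 0.4 * sqrt(sum w_j^2) in the
  # spectrum under the unscaled forward transform; w is the 1.5 Hz window
  dt <- 1 / (14.98 * 324)
  w2 <- sum(exp(-2 * pi * 1.5 * (0:3881) * dt))
  expected <- 0.4 * sqrt(w2)
  expect_lt(abs(estimate_noise(sp, c(7, 10)) / expected - 1), 0.05)
  expect_lt(abs(estimate_noise(sp, "auto") / expected - 1), 0.05)

  # noise-free spectrum: sigma negligible relative to the signal (the
  # residual structure is the Lorentzian tail, about 1e-7 of the apex, so
  # the bound is relative, not absolute zero)
  sp0 <- pc_spectrum(calibrate = FALSE, baseline = FALSE)
  expect_lt(estimate_noise(sp0, c(7, 10)), 1e-6 * max(sp0$real))

  # documented hazard: a region containing a large peak inflates sigma
  expect_gt(estimate_noise(sp, c(-0.05, 0.05)),
            2 * estimate_noise(sp, c(7, 10)))

  expect_error(estimate_noise(sp, c(7, 7.0001)),
               class = "pnmr_validation_error")
})

test_that("pick_peaks applies the 3:1 presence rule", {
  sp <- pc_spectrum()   # noise-free, single PC peak
  h <- max(sp$real)
  expect_error(pick_peaks(sp, 0), class = "pnmr_validation_error")
  # height 10 sigma -> picked
  expect_equal(nrow(pick_peaks(sp, h / 10)), 1L)
  # height 2.9 sigma with min_snr 3 -> not picked
  expect_equal(nrow(pick_peaks(sp, h / 2.9)), 0L)
})

test_that("pick_peaks false positives on pure noise are rare", {
  for (s in 1:3) {
    fid <- synthesize_fid(lipid_composition(c(PC = 1)),
                          default_resonances(), acq(), mass_mg = 1e-9,
                          noise_sigma = 0.4, seed = 40 + s)
    sp <- process_spectrum(fid, phase = c(0, 0), calibrate = FALSE)
    picks <- pick_peaks(sp, estimate_noise(sp, "auto"))
    expect_lt(nrow(picks), 5L)
  }
})

test_that("noise-free single Lorentzian is recovered to 0.5%", {
  sp <- pc_spectrum()     # natural 2.0 Hz + lb 1.5 Hz -> fwhm 3.5 Hz
  fit <- fit_lineshapes(sp, pick_peaks(sp, noise_floor(sp)), "lorentzian")
  expect_true(fit$converged)
  pk <- fit$peaks
  expect_equal(nrow(pk), 1L)
  expect_lt(abs(pk$center_ppm), 0.001)
  expect_lt(abs(pk$fwhm_hz / 3.5 - 1), 0.005)
  # closed form: unit-height Lorentzian area = height * (pi/2) * fwhm
  expect_lt(abs(pk$area / (pk$height * (pi / 2) * pk$fwhm_hz) - 1), 1e-9)
  # against the independent numerical integral of the spectrum, compared
  # over a common window (a Lorentzian keeps ~1.6% of its area beyond
  # 20 linewidths, so the closed form must be windowed too)
  num <- integrate_region(sp, -0.2, 0.2)
  part <- lineshape_area_window(pk$height, pk$fwhm_hz, pk$eta, 0.2 * 324)
  expect_lt(abs(part / num - 1), 0.005)
})

test_that("0.025 ppm doublets are resolved with areas within 10%", {
  for (sep in c(0.1, 0.05, 0.025)) {
    sp <- doublet_spectrum(sep, frac_minor = 0.5)
    fit <- fit_lineshapes(sp, pick_peaks(sp, noise_floor(sp)),
                          "lorentzian")
    expect_equal(nrow(fit$peaks), 2L)
    true_area <- integrate_region(sp, 2 - 0.3, 2 + sep + 0.3) / 2
    expect_true(all(abs(fit$peaks$area / true_area - 1) < 0.10))
  }
})

test_that("a collapsed doublet is flagged degenerate, total area kept", {
  sp <- doublet_spectrum(0.001, frac_minor = 0.5)
  sigma <- noise_floor(sp)
  init <- pick_peaks(sp, sigma)
  # picking cannot separate 0.001 ppm; force a two-component init
  init2 <- rbind(init, init)
  init2$center_ppm <- c(2.0, 2.001)
  init2$height <- init2$height / 2
  fit <- fit_lineshapes(sp, init2, "lorentzian")
  expect_true(any(fit$peaks$degenerate))
  expect_equal(nrow(fit$peaks), 1L)
  pk <- fit$peaks
  total <- integrate_region(sp, pk$center_ppm - 0.3, pk$center_ppm + 0.3)
  part <- lineshape_area_window(pk$height, pk$fwhm_hz, pk$eta, 0.3 * 324)
  expect_lt(abs(part / total - 1), 0.01)
})

test_that("fit validation and invariances", {
  sp <- pc_spectrum()
  init <- pick_peaks(sp, noise_floor(sp))
  expect_error(fit_lineshapes(sp, init[0, ]),
               class = "pnmr_validation_error")
  expect_error(fit_lineshapes(sp, rbind(init, init)),
               class = "pnmr_validation_error")
  raw <- pc_spectrum(baseline = FALSE, calibrate = FALSE)
  raw$phased <- FALSE
  expect_error(fit_lineshapes(raw, init), class = "pnmr_validation_error")

  # uniform intensity scaling: heights and areas scale, shape does not
  fit1 <- fit_lineshapes(sp, init, "lorentzian")
  sp2 <- sp
  sp2$real <- 3.7 * sp2$real
  init2 <- init
  init2$height <- 3.7 * init2$height
  fit2 <- fit_lineshapes(sp2, init2, "lorentzian")
  expect_equal(fit2$peaks$height / fit1$peaks$height, 3.7,
               tolerance = 1e-4)
  expect_equal(fit2$peaks$area / fit1$peaks$area, 3.7, tolerance = 1e-4)
  expect_equal(fit2$peaks$center_ppm, fit1$peaks$center_ppm,
               tolerance = 1e-6)
  expect_equal(fit2$peaks$fwhm_hz, fit1$peaks$fwhm_hz, tolerance = 1e-4)
})

test_that("adding a real component never increases the residual", {
  sp <- doublet_spectrum(0.05, frac_minor = 0.3)
  sigma <- noise_floor(sp)
  both <- pick_peaks(sp, sigma)
  expect_equal(nrow(both), 2L)
  one <- both[which.max(both$height), ]
  rms1 <- fit_lineshapes(sp, one, "lorentzian")$residual_rms
  rms2 <- fit_lineshapes(sp, both, "lorentzian")$residual_rms
  expect_lte(rms2, rms1 * (1 + 1e-9))
})

test_that("analytic areas match numerical integration for isolated peaks", {
  # equal-abundance classes with well-separated single resonances, so
  # every +-20 linewidth window holds one peak and only faint tails
  comp <- lipid_composition(c(PC = 0.2, SM = 0.2, LPI = 0.2, PA = 0.2,
                              LPA = 0.2))
  fid <- synthesize_fid(comp, default_resonances(), acq(), mass_mg = 8,
                        noise_sigma = 0, seed = 6)
  sp <- process_spectrum(fid, phase = c(0, 0))
  fit <- fit_lineshapes(sp, pick_peaks(sp, noise_floor(sp)), "lorentzian")
  pk <- fit$peaks
  expect_equal(nrow(pk), 5L)
  for (i in seq_len(nrow(pk))) {
    win <- 20 * pk$fwhm_hz[i] / 324
    num <- integrate_region(sp, pk$center_ppm[i] - win,
                            pk$center_ppm[i] + win)
    part <- lineshape_area_window(pk$height[i], pk$fwhm_hz[i], pk$eta[i],
                                  20 * pk$fwhm_hz[i])
    expect_lt(abs(part / num - 1), 0.01)
  }
})
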