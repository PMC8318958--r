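test_that("exponential apodization: identity, weights and additivity", {
  fid <- synthesize_fid(lipid_composition(c(PC = 1)),
                        default_resonances(), acq(), mass_mg = 4,
                        noise_sigma = 0.4, seed = 7)
  expect_identical(apodize_exponential(fid, 0)$samples, fid$samples)
  # weight at t = 0 is exactly 1
  expect_identical(apodize_exponential(fid, 10)$samples[1], fid$samples[1])
  expect_error(apodize_exponential(fid, -1),
               class = "pnmr_validation_error")
  # additivity: lb1 then lb2 == lb1 + lb2
  a <- apodize_exponential(apodize_exponential(fid, 0.7), 0.8)
  b <- apodize_exponential(fid, 1.5)
  expect_equal(a$samples, b$samples, tolerance = 1e-12)
})

test_that("1.5 Hz broadening adds to the 2 Hz natural width (3.5 Hz)", {
  # oracle: convolution theorem — exponential decay rates add, so the
  # processed linewidth is natural 2.0 + lb 1.5 Hz
  sp <- pc_spectrum(lb = 1.5, calibrate = FALSE, baseline = FALSE)
  fit <- fit_lineshapes(baseline_correct(sp),
                        pick_peaks(sp, noise_floor(sp)), "lorentzian")
  expect_lt(abs(fit$peaks$fwhm_hz[1] / 3.5 - 1), 0.01)
})

test_that("zero filling pads, refuses truncation, keeps the integral", {
  fid <- synthesize_fid(lipid_composition(c(PC = 1)),
                        default_resonances(), acq(), mass_mg = 4,
                        noise_sigma = 0, seed = 1)
  n0 <- length(fid$samples)
  expect_equal(n0, 3882L)
  expect_equal(length(zero_fill(fid)$samples), 32768L)
  expect_identical(zero_fill(fid, n0)$samples, fid$samples)
  expect_error(zero_fill(fid, n0 - 1), class = "pnmr_validation_error")

  # declared convention: sum(real) * axis step (Hz) is invariant under
  # zero filling (unscaled forward transform, first point halved)
  int_of <- function(n) {
    sp <- fourier_transform(zero_fill(apodize_exponential(fid, 1.5), n))
    sum(sp$real) * (sp$params$sw * sp$params$observe_freq / length(sp$real))
  }
  expect_equal(int_of(4096), int_of(32768), tolerance = 1e-9)
})

test_that("fourier transform places components at their ppm", {
  params <- acq()
  res <- data.frame(lipid_class = c("PC", "PA"),
                    center_ppm = c(0, 5.3), fwhm_hz = 2,
                    relative_weight = 1)
  fid <- synthesize_fid(lipid_composition(c(PC = 0.5, PA = 0.5)), res,
                        params, mass_mg = 8, noise_sigma = 0, seed = 1)
  sp <- fourier_transform(zero_fill(apodize_exponential(fid)))
  expect_equal(length(sp$real), 32768L)
  expect_true(all(diff(sp$axis_ppm) < 0))   # downfield first
  step <- 14.98 / 32768
  # apexes within one axis step of the true centers
  for (cen in res$center_ppm) {
    sel <- abs(sp$axis_ppm - cen) < 0.05
    apex <- sp$axis_ppm[sel][which.max(sp$real[sel])]
    expect_lt(abs(apex - cen), step + 1e-12)
  }
})

test_that("phase correction and autophase behave as declared", {
  sp <- pc_spectrum(calibrate = FALSE, baseline = FALSE)
  expect_equal(phase_correct(sp, 0, 0)$real, sp$real)

  # rotate the raw FID by +30 degrees; autophase must undo it
  fid <- synthesize_fid(lipid_composition(c(PC = 1)),
                        default_resonances(), acq(), mass_mg = 8,
                        noise_sigma = 0.1, seed = 3)
  fid$samples <- fid$samples * exp(complex(imaginary = 30 * pi / 180))
  spec <- fourier_transform(zero_fill(apodize_exponential(fid)))
  ap <- autophase(spec)
  ph <- attr(ap, "autophase")
  phi0 <- (ph$phi0 + 180) %% 360 - 180
  expect_lt(abs(phi0 - (-30)), 1)
  # negative excursions below 1% of total area after autophasing; checked
  # noise-free, since noise itself contributes symmetric negative area
  fid0 <- synthesize_fid(lipid_composition(c(PC = 1)),
                         default_resonances(), acq(), mass_mg = 8,
                         noise_sigma = 0, seed = 3)
  fid0$samples <- fid0$samples * exp(complex(imaginary = 55 * pi / 180))
  ap0 <- autophase(fourier_transform(zero_fill(apodize_exponential(fid0))))
  expect_lt(abs(sum(pmin(ap0$real, 0))) / sum(ap0$real), 0.01)
})

test_that("baseline correction removes injected offsets and ramps", {
  sp <- pc_spectrum(noise_sigma = 0.4, seed = 5, calibrate = FALSE,
                    baseline = FALSE)
  h <- max(sp$real)
  c0 <- 0.02 * h
  off <- sp
  off$real <- off$real + c0
  corr <- baseline_correct(off)
  expect_lt(abs(stats::median(corr$real) - stats::median(sp$real)),
            0.05 * c0)

  ramp <- sp
  ramp$real <- ramp$real + seq(0, c0, length.out = length(sp$real))
  corr2 <- baseline_correct(ramp)
  resid <- corr2$real - sp$real
  expect_lt(stats::median(abs(resid)), 0.05 * c0)

  unphased <- sp
  unphased$phased <- FALSE
  expect_error(baseline_correct(unphased),
               class = "pnmr_validation_error")
})

test_that("ppm calibration pins PC at 0.00 and is idempotent", {
  # simulate a 0.05 ppm miscalibration by shifting every resonance
  sp <- pc_spectrum(centers_shift = 0.05, calibrate = FALSE)
  cal <- calibrate_ppm(sp)
  sel <- abs(cal$axis_ppm) < 0.2
  apex <- cal$axis_ppm[sel][which.max(cal$real[sel])]
  expect_identical(apex, 0)
  expect_lt(abs(cal$calibration - 0.05), 14.98 / 32768)

  step <- 14.98 / 32768
  cal2 <- calibrate_ppm(cal)
  expect_lt(max(abs(cal2$axis_ppm - cal$axis_ppm)), step)

  expect_error(calibrate_ppm(cal, ref_ppm = 20),
               class = "pnmr_validation_error")
  # no signal in the window -> calibration error
  empty <- pc_spectrum(centers_shift = 3, calibrate = FALSE)
  expect_error(calibrate_ppm(empty), class = "pnmr_calibration_error")
})

test_that("full chain puts every true resonance at a local maximum", {
  scen <- simulate_scenario(seed = 2, noise_sigma = 0)
  sp <- process_spectrum(scen$fid, phase = c(0, 0))
  step <- 14.98 / 32768
  res <- scen$resonances[scen$resonances$lipid_class %in%
                           scen$truth$lipid_class, ]
  # calibration may have shifted the whole axis; undo it for comparison
  centers <- res$center_ppm - sp$calibration
  for (cen in centers) {
    near <- which(abs(sp$axis_ppm - cen) <= 1.5 * step)
    has_max <- vapply(near, function(i)
      sp$real[i] >= sp$real[i - 1] && sp$real[i] >= sp$real[i + 1],
      logical(1))
    expect_true(any(has_max))
  }
})
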