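test_that("synthesize_fid validates inputs and is deterministic", {
  comp <- lipid_composition(c(PC = 0.5, PE = 0.5))
  res <- default_resonances()

  f1 <- synthesize_fid(comp, res, acq(), mass_mg = 4, noise_sigma = 0.4,
                       seed = 11)
  f2 <- synthesize_fid(comp, res, acq(), mass_mg = 4, noise_sigma = 0.4,
                       seed = 11)
  expect_identical(f1$samples, f2$samples)
  f3 <- synthesize_fid(comp, res, acq(), mass_mg = 4, noise_sigma = 0.4,
                       seed = 12)
  expect_false(identical(f1$samples, f3$samples))

  expect_error(synthesize_fid(comp, res, acq(), mass_mg = -1),
               class = "pnmr_validation_error")
  expect_error(
    synthesize_fid(comp, res[res$lipid_class != "PE", ], acq()),
    class = "pnmr_validation_error")
  # seed restoration: simulation must not disturb the session RNG stream
  set.seed(99); before <- rnorm(3)
  set.seed(99); invisible(synthesize_fid(comp, res, acq(), seed = 5))
  expect_identical(rnorm(3), before)
})

test_that("single-component FID yields one peak at 0.00 ppm", {
  sp <- pc_spectrum()
  sigma <- max(estimate_noise(sp, "auto"), 1e-12 * max(sp$real))
  picks <- pick_peaks(sp, sigma)
  expect_equal(nrow(picks), 1L)
  expect_lt(abs(picks$center_ppm), 14.98 / 32768 + 1e-9)
})

test_that("S/N scales linearly with mass at fixed noise", {
  snr_of <- function(mass, seed) {
    fid <- synthesize_fid(lipid_composition(c(PC = 1)),
                          default_resonances(), acq(), mass_mg = mass,
                          noise_sigma = 0.4, seed = seed)
    sp <- process_spectrum(fid, phase = c(0, 0), calibrate = FALSE)
    max(sp$real) / estimate_noise(sp, "auto")
  }
  # oracle: S/N is linear in signal amplitude at fixed noise, so the
  # 8 mg / 4 mg ratio is 2
  r <- snr_of(8, seed = 21) / snr_of(4, seed = 21)
  expect_lt(abs(r / 2 - 1), 0.05)
})

test_that("cardiolipin contributes two phosphorus per molecule", {
  res <- default_resonances()
  fid <- synthesize_fid(lipid_composition(c(PC = 0.5, CL = 0.5)), res,
                        acq(), mass_mg = 8, noise_sigma = 0, seed = 1)
  sp <- process_spectrum(fid, phase = c(0, 0), calibrate = FALSE)
  cl_area <- integrate_region(sp, 3.2, 3.4)
  pc_area <- integrate_region(sp, -0.1, 0.1)
  expect_lt(abs(cl_area / pc_area - 2), 0.02)
})

test_that("noise-free peak areas are linear in mass through the pipeline", {
  area_at <- function(mass) {
    fid <- synthesize_fid(lipid_composition(c(PC = 0.7, PA = 0.3)),
                          default_resonances(), acq(), mass_mg = mass,
                          noise_sigma = 0, seed = 1)
    sp <- process_spectrum(fid, phase = c(0, 0), calibrate = FALSE)
    fit <- fit_lineshapes(sp, pick_peaks(sp, noise_floor(sp)),
                          "lorentzian")
    sort(fit$peaks$area)
  }
  a4 <- area_at(4)
  a8 <- area_at(8)
  expect_equal(length(a4), 2L)
  expect_true(all(abs(a8 / a4 - 2) < 0.01))
})

test_that("concentration shifts follow the declared directions", {
  model <- concentration_shift_model()
  res <- default_resonances()

  expect_equal(apply_concentration_shifts(res, model, 4), res)

  r1 <- apply_concentration_shifts(res, model, 1)
  r32 <- apply_concentration_shifts(res, model, 32)
  pe1 <- r1$center_ppm[r1$lipid_class == "PE"]
  pe32 <- r32$center_ppm[r32$lipid_class == "PE"]
  expect_true(all(pe32 > pe1))              # PE downfield with mass
  for (cl in c("PA", "LPA")) {
    expect_true(all(r32$center_ppm[r32$lipid_class == cl] <
                      r1$center_ppm[r1$lipid_class == cl]))
  }
  for (cl in c("LPC", "PC"))                 # concentration-independent
    expect_equal(r1$center_ppm[r1$lipid_class == cl],
                 r32$center_ppm[r32$lipid_class == cl])

  expect_error(concentration_shift_model(slope = c(PE = -0.01)),
               class = "pnmr_validation_error")
})

test_that("ageing model transfers PC to LPC with exact conservation", {
  comp <- default_composition()
  model <- ageing_model()

  expect_equal(apply_ageing(comp, model, 0), comp)

  ratio_at <- function(hours) {
    f <- apply_ageing(comp, model, hours)$fractions
    f[["LPC"]] / f[["PC"]]
  }
  gain <- ratio_at(21 * 24) / ratio_at(48) - 1
  expect_equal(gain, 0.55, tolerance = 1e-9)
  # monotone non-decreasing ratio over time
  hrs <- seq(0, 1500, by = 100)
  expect_true(all(diff(vapply(hrs, ratio_at, numeric(1))) >= 0))
  # total phosphorus conserved exactly
  p_total <- function(c)
    sum(c$fractions * c$phosphorus_per_molecule[names(c$fractions)])
  aged <- apply_ageing(comp, model, 500)
  expect_equal(p_total(aged), p_total(comp), tolerance = 1e-12)

  no_pc <- lipid_composition(c(PE = 0.6, PA = 0.4))
  expect_error(apply_ageing(no_pc, model, 10),
               class = "pnmr_validation_error")
})

test_that("adduct offsets perturb LPA/PA/PI/PE but never PC", {
  model <- adduct_model()
  res <- rbind(default_resonances(),
               data.frame(lipid_class = "PI", center_ppm = 1.05,
                          fwhm_hz = 2, relative_weight = 1))

  na <- apply_adducts(res, model, "Na+", 10)
  expect_equal(na$center_ppm[na$lipid_class == "PC"],
               res$center_ppm[res$lipid_class == "PC"])
  for (cl in c("PE", "PA", "LPA", "PI"))
    expect_false(any(na$center_ppm[na$lipid_class == cl] ==
                       res$center_ppm[res$lipid_class == cl]))

  expect_equal(apply_adducts(res, model, "guanidinium", 0), res)
  # guanidinium offsets scale with added mass
  g10 <- apply_adducts(res, model, "guanidinium", 10)
  g50 <- apply_adducts(res, model, "guanidinium", 50)
  d10 <- g10$center_ppm - res$center_ppm
  d50 <- g50$center_ppm - res$center_ppm
  expect_equal(d50, 5 * d10)

  expect_error(apply_adducts(res, model, "K+"),
               class = "pnmr_validation_error")
  expect_error(adduct_model(list("Na+" = c(PC = 0.1))),
               class = "pnmr_validation_error")
})
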