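# Shared fixtures. Everything is generated in code; no binary files ship
# with the package.

# default acquisition; small zero-fill keeps most tests fast while the
# acceptance tests use the full 32768-point chain
acq <- function(...) acquisition_params(...)

# noise-free single-class FID, processed without autophase (the simulator
# emits zero-phase FIDs) for speed
pc_spectrum <- function(mass_mg = 8, noise_sigma = 0, seed = 1,
                        centers_shift = 0, lb = 1.5, zf = 32768,
                        baseline = TRUE, calibrate = TRUE) {
  res <- default_resonances()
  res$center_ppm <- res$center_ppm + centers_shift
  fid <- synthesize_fid(lipid_composition(c(PC = 1)), res, acq(),
                        mass_mg = mass_mg, noise_sigma = noise_sigma,
                        seed = seed)
  process_spectrum(fid, lb = lb, zf = zf, phase = c(0, 0),
                   baseline = baseline, calibrate = calibrate)
}

# two-Lorentzian noise-free spectrum with controllable separation and the
# minor component's fractional area; centered near 2 ppm, away from other
# library intervals
doublet_spectrum <- function(sep_ppm, frac_minor = 0.5, fwhm_hz = 2.0,
                             lb = 1.5, zf = 32768) {
  res <- data.frame(
    lipid_class = c("PC", "PA"),
    center_ppm = c(2.0, 2.0 + sep_ppm),
    fwhm_hz = fwhm_hz, relative_weight = 1)
  comp <- lipid_composition(c(PC = 1 - frac_minor, PA = frac_minor))
  fid <- synthesize_fid(comp, res, acq(), mass_mg = 8, noise_sigma = 0,
                        seed = 1)
  process_spectrum(fid, lb = lb, zf = zf, phase = c(0, 0),
                   calibrate = FALSE)
}

# hand-built quant_report for qc tests
fake_report <- function(classes, areas, centers = NULL, snr = 100) {
  if (is.null(centers)) {
    lib <- load_default_library()
    mids <- (lib$ppm_low + lib$ppm_high) / 2
    centers <- vapply(classes, function(cl) {
      i <- which(lib$lipid_class == cl)
      if (length(i)) mids[i[1]] else 3.3
    }, numeric(1))
  }
  rows <- data.frame(lipid_class = classes, center_ppm = centers,
                     area = areas, snr = snr, flags = "",
                     mol_pct = 100 * areas / sum(areas),
                     stringsAsFactors = FALSE)
  peaks <- rows
  peaks$excluded <- FALSE
  structure(list(rows = rows, peaks = peaks, basis = "per_phosphorus",
                 total_area = sum(areas), noise_sigma = 1,
                 provenance = list(library_version = "test")),
            class = "quant_report")
}

# default library augmented with a synthetic cardiolipin interval matching
# the simulator's placeholder resonance (the 1D shift library has no CL
# interval; this exists only to exercise per-molecule accounting)
library_with_cl <- function() {
  lib <- as.data.frame(load_default_library())
  shift_library(rbind(lib, data.frame(
    lipid_class = "CL", ppm_low = 3.25, ppm_high = 3.35,
    provenance = "synthetic placeholder for tests", ambiguous = FALSE)),
    version = "test+CL")
}
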