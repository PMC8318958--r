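#' Deconvolve and quantify a processed spectrum
#'
#' Noise estimation, peak picking, lineshape fitting and report building in
#' one call — the analysis half of the pipeline, applied to an already
#' processed (phased, baseline-corrected, calibrated) spectrum.
#'
#' @param spec a processed `nmr_spectrum`.
#' @param library a [shift_library()].
#' @param shape_mode lineshape family (see [fit_lineshapes()]).
#' @param min_snr peak-picking / presence S/N threshold.
#' @param basis mol% basis (see [build_report()]).
#' @param tolerance assignment tolerance (ppm).
#' @param min_frac_pct reporting threshold, % of total area.
#' @param keep_low_snr retain flagged low-S/N rows?
#' @param tie_widths share one linewidth per fit window (see
#'   [fit_lineshapes()]).
#' @return list with `report` (`quant_report`), `fit` (`fit_result`) and
#'   `sigma` (noise estimate actually used, floored for noise-free input).
#' @export
analyze_spectrum <- function(spec, library = load_default_library(),
                             shape_mode = "pseudo_voigt", min_snr = 3,
                             basis = "per_phosphorus", tolerance = 0.02,
                             min_frac_pct = 0.01, keep_low_snr = FALSE,
                             tie_widths = FALSE) {
  sigma <- noise_floor(spec)
  init <- pick_peaks(spec, sigma, min_snr)
  if (nrow(init) == 0)
    abort("no peaks above the S/N threshold", "pnmr_empty_report_error")
  fit <- fit_lineshapes(spec, init, shape_mode, tie_widths = tie_widths)
  report <- build_report(fit, library, sigma, basis = basis,
                         tolerance = tolerance, min_frac_pct = min_frac_pct,
                         min_snr = min_snr, keep_low_snr = keep_low_snr,
                         override_convergence = TRUE)
  list(report = report, fit = fit, sigma = sigma)
}

#' Run the full pipeline on an FID
#'
#' Process (apodize, zero fill, transform, phase, baseline, calibrate) then
#' analyze (pick, fit, assign, filter, quantify).
#'
#' @param fid an `nmr_fid`.
#' @param library a [shift_library()].
#' @param lb,zf,phase processing parameters (see [process_spectrum()]).
#' @param ... further arguments passed to [analyze_spectrum()].
#' @return as [analyze_spectrum()], plus the processed `spectrum`.
#' @export
run_pipeline <- function(fid, library = load_default_library(), lb = 1.5,
                         zf = 32768, phase = "auto", ...) {
  spec <- process_spectrum(fid, lb = lb, zf = zf, phase = phase)
  out <- analyze_spectrum(spec, library, ...)
  out$spectrum <- spec
  out
}
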