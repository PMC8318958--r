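#' Sample-ageing (hydrolysis) check
#'
#' The LPC:PC area ratio is the hydrolysis index: base-mediated ester
#' hydrolysis converts PC to LPC while the sample ages in solvent, and the
#' index rises roughly 50-60% between 48 hours and 21 days. The flag trips
#' when the index grows by at least `threshold_gain` (fractional) between
#' two reports of the same sample. The index is scale-invariant, so reports
#' need not share an intensity scale.
#'
#' @param report_t0,report_t1 `quant_report`s at the earlier/later age; both
#'   must contain PC (LPC may be absent, giving index 0).
#' @param threshold_gain fractional increase that trips the flag
#'   (default 0.5).
#' @return list with `hydrolysis_index_t0`, `hydrolysis_index_t1`, `gain`
#'   (fractional; `Inf` when LPC appears de novo) and `hydrolysis_flag`.
#' @export
hydrolysis_check <- function(report_t0, report_t1, threshold_gain = 0.5) {
  idx <- function(report) {
    r <- report$rows
    pc <- r$area[r$lipid_class == "PC"]
    if (!length(pc)) abort_validation("report does not contain PC")
    lpc <- r$area[r$lipid_class == "LPC"]
    if (!length(lpc)) 0 else sum(lpc) / sum(pc)
  }
  i0 <- idx(report_t0)
  i1 <- idx(report_t1)
  gain <- if (i0 == 0) { if (i1 > 0) Inf else 0 } else i1 / i0 - 1
  list(hydrolysis_index_t0 = i0, hydrolysis_index_t1 = i1, gain = gain,
       hydrolysis_flag = gain >= threshold_gain)
}

#' Minimum sample mass for a target signal-to-noise ratio
#'
#' S/N is proportional to sample mass at fixed noise, so log10(S/N) versus
#' log10(mass) is a line of slope 1. The intercept is estimated by least
#' squares over the supplied observations and the mass at which the line
#' predicts `target_snr` (3 by default; log10(3) = 0.477 is the reference
#' line on an S/N plot) is returned. Exact on perfectly proportional data.
#'
#' @param snr_at_mass data.frame with columns `mass_mg` and `snr`.
#' @param target_snr presence threshold (default 3).
#' @return list with `min_mass_mg`, `log10_target` and the fitted
#'   `log10_intercept`.
#' @export
estimate_min_mass <- function(snr_at_mass, target_snr = 3) {
  ok <- snr_at_mass$snr > 0 & snr_at_mass$mass_mg > 0
  if (!any(ok)) abort("no positive S/N observations",
                      "pnmr_estimation_error")
  b <- mean(log10(snr_at_mass$snr[ok]) - log10(snr_at_mass$mass_mg[ok]))
  list(min_mass_mg = 10^(log10(target_snr) - b),
       log10_target = log10(target_snr), log10_intercept = b)
}

#' Chemical-shift drift check and adduct warning
#'
#' Measures, per lipid class, how far the fitted centers sit from the
#' library interval midpoints. Within each class, detected rows and library
#' intervals are sorted downfield-first and paired by rank (robust when a
#' uniform adduct offset pushes a resonance into a neighbouring interval of
#' the same class); the class drift is the mean paired offset. The adduct
#' warning trips when at least two of LPA, PA, PI and PE drift beyond
#' `warn_ppm` while PC sits at 0.00 ppm — the signature of inconsistent
#' counter-ion handling between samples.
#'
#' @param report a `quant_report` (assign with a generous tolerance when
#'   adduct drift is suspected).
#' @param library a [shift_library()].
#' @param warn_ppm per-class drift that counts toward the warning
#'   (default 0.03 ppm).
#' @return list with `drift` (data.frame `lipid_class`, `drift_ppm`) and
#'   `adduct_warning`.
#' @export
drift_check <- function(report, library, warn_ppm = 0.03) {
  pk <- report$peaks[!report$peaks$excluded &
                       report$peaks$lipid_class != "unassigned", ,
                     drop = FALSE]
  if (nrow(pk) == 0) abort_validation("report has no assigned peaks")
  mids <- lib_midpoints(library)
  drift <- do.call(rbind, lapply(split(pk, pk$lipid_class), function(d) {
    m <- sort(mids[library$lipid_class == d$lipid_class[1]],
              decreasing = TRUE)
    cen <- sort(d$center_ppm, decreasing = TRUE)
    k <- min(length(m), length(cen))
    data.frame(lipid_class = d$lipid_class[1],
               drift_ppm = mean(cen[seq_len(k)] - m[seq_len(k)]),
               stringsAsFactors = FALSE)
  }))
  rownames(drift) <- NULL
  pc_ok <- TRUE
  if ("PC" %in% drift$lipid_class)
    pc_ok <- abs(drift$drift_ppm[drift$lipid_class == "PC"]) < 0.005
  n_off <- sum(drift$lipid_class %in% c("LPA", "PA", "PI", "PE") &
                 abs(drift$drift_ppm) > warn_ppm)
  list(drift = drift, adduct_warning = pc_ok && n_off >= 2)
}

#' Assemble a QC result
#'
#' Bundles the diagnostics into one record. The optimal-mass window is the
#' constant (4, 16) mg guidance for mixed lipid samples, attached as
#' metadata rather than computed.
#'
#' @param hydrolysis optional output of [hydrolysis_check()].
#' @param drift optional output of [drift_check()].
#' @param min_mass optional output of [estimate_min_mass()].
#' @return object of class `qc_result`.
#' @export
qc_result <- function(hydrolysis = NULL, drift = NULL, min_mass = NULL) {
  structure(list(
    hydrolysis_index = hydrolysis$hydrolysis_index_t1 %||% NA_real_,
    hydrolysis_gain = hydrolysis$gain %||% NA_real_,
    hydrolysis_flag = hydrolysis$hydrolysis_flag %||% NA,
    shift_drift = drift$drift %||% NULL,
    adduct_warning = drift$adduct_warning %||% NA,
    min_mass_estimate = min_mass$min_mass_mg %||% NA_real_,
    optimal_mass_window = c(4, 16)), class = "qc_result")
}

#' @export
print.qc_result <- function(x, ...) {
  cat("<qc_result>\n")
  cat(sprintf("  hydrolysis index %.4g (gain %.3g, flag %s)\n",
              x$hydrolysis_index, x$hydrolysis_gain, x$hydrolysis_flag))
  cat(sprintf("  adduct warning: %s\n", x$adduct_warning))
  cat(sprintf("  min mass for S/N 3: %.3g mg; optimal window %g-%g mg\n",
              x$min_mass_estimate, x$optimal_mass_window[1],
              x$optimal_mass_window[2]))
  invisible(x)
}
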