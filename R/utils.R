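#' @keywords internal
"_PACKAGE"

# Canonical lipid-class vocabulary. CL carries two phosphorus nuclei per
# molecule; every other class carries one.
LIPID_CLASSES <- c("PC", "LPC", "PE", "PE-plasmalogen", "PS", "PA", "LPA",
                   "PI", "LPI", "PG", "SM", "CL", "UNK1", "UNK2")

# Busy assignment region: several headgroups (PE-plasmalogen, PE x2, PS, LPC)
# resonate between these bounds.
BUSY_REGION <- c(0.45, 0.60)

abort <- function(msg, class) {
  stop(structure(class = c(class, "pnmr_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

abort_validation <- function(msg) abort(msg, "pnmr_validation_error")
abort_format <- function(msg) abort(msg, "pnmr_format_error")
abort_config <- function(msg) abort(msg, "pnmr_config_error")

#' Evaluate code with a temporary RNG seed
#'
#' Runs `code` under `set.seed(seed)` and restores the caller's RNG state
#' afterwards, so simulator determinism never leaks into user sessions.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    stats::runif(1)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

# ppm <-> Hz: observe_freq is in MHz, so 1 ppm == observe_freq Hz.
ppm_to_hz <- function(ppm, observe_freq) ppm * observe_freq
hz_to_ppm <- function(hz, observe_freq) hz / observe_freq

#' Analytic lineshapes
#'
#' Unit-height Lorentzian, Gaussian and pseudo-Voigt profiles evaluated on a
#' ppm axis with the width given in Hz, plus their closed-form areas
#' (intensity x Hz). The pseudo-Voigt is the convex height-domain mixture
#' `eta * Lorentzian + (1 - eta) * Gaussian` sharing one FWHM.
#'
#' @param x ppm axis.
#' @param center peak center (ppm).
#' @param fwhm_hz full width at half maximum (Hz).
#' @param height apex intensity.
#' @param eta Lorentzian fraction in `[0, 1]` (1 = pure Lorentzian).
#' @param observe_freq spectrometer frequency (MHz), to convert Hz to ppm.
#' @return intensity vector (`pseudo_voigt`) or a scalar area
#'   (`lineshape_area`).
#' @export
pseudo_voigt <- function(x, center, fwhm_hz, height, eta, observe_freq) {
  w <- fwhm_hz / observe_freq            # FWHM in ppm
  u <- (x - center) / (w / 2)
  lor <- 1 / (1 + u^2)
  gau <- exp(-log(2) * u^2)
  height * (eta * lor + (1 - eta) * gau)
}

#' @rdname pseudo_voigt
#' @export
lineshape_area <- function(height, fwhm_hz, eta) {
  lor <- height * (pi / 2) * fwhm_hz
  gau <- height * fwhm_hz * sqrt(pi / (4 * log(2)))
  eta * lor + (1 - eta) * gau
}

#' @rdname pseudo_voigt
#' @param half_hz half-width of the integration window (Hz), centered on
#'   the peak. A Lorentzian carries about 1.6% of its area beyond
#'   20 linewidths, so window-limited comparisons must use this partial
#'   form rather than the total [lineshape_area()].
#' @export
lineshape_area_window <- function(height, fwhm_hz, eta, half_hz) {
  lor <- height * fwhm_hz * atan(2 * half_hz / fwhm_hz)
  erf <- function(z) 2 * stats::pnorm(z * sqrt(2)) - 1
  gau <- height * fwhm_hz * sqrt(pi / (4 * log(2))) *
    erf(2 * sqrt(log(2)) * half_hz / fwhm_hz)
  eta * lor + (1 - eta) * gau
}

# md5 of a character scalar (base R has no string digest; go through a file)
hash_string <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(x, f)
  unname(tools::md5sum(f))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
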