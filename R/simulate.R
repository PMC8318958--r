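#' Acquisition parameters for a 1D 31P experiment
#'
#' Defaults mirror a quantitative 1D acquisition on an 800 MHz instrument
#' (31P observe frequency 324 MHz): spectral width 14.98 ppm, 3882 complex
#' points, inverse-gated decoupling with an 8.4 s recovery delay (metadata
#' only; partial saturation is not modelled). The carrier is placed so the
#' window spans roughly -4 to +11 ppm around PC at 0.
#'
#' @param observe_freq 31P observe frequency (MHz).
#' @param sw spectral width (ppm).
#' @param n_complex acquired complex points.
#' @param carrier_ppm center of the spectral window (ppm).
#' @param recovery_delay overall recovery delay (s; metadata).
#' @param temperature sample temperature (K; metadata).
#' @return object of class `acq_params`.
#' @export
acquisition_params <- function(observe_freq = 324, sw = 14.98,
                               n_complex = 3882, carrier_ppm = 3.49,
                               recovery_delay = 8.4, temperature = 293) {
  if (observe_freq <= 0) abort_validation("observe_freq must be > 0")
  if (sw <= 0) abort_validation("sw must be > 0")
  if (n_complex < 2) abort_validation("n_complex must be >= 2")
  structure(list(observe_freq = observe_freq, sw = sw,
                 n_complex = as.integer(n_complex),
                 carrier_ppm = carrier_ppm,
                 recovery_delay = recovery_delay,
                 temperature = temperature),
            class = "acq_params")
}

# dwell time in seconds: 1 / spectral width in Hz
dwell_time <- function(params) 1 / ppm_to_hz(params$sw, params$observe_freq)

#' Lipid-class composition
#'
#' Mol fractions per lipid class plus the phosphorus count per molecule
#' (cardiolipin, CL, carries two 31P nuclei; every other class one).
#'
#' @param fractions named numeric vector of mol fractions summing to 1.
#' @param phosphorus optional named integer override of phosphorus counts.
#' @return object of class `lipid_composition`.
#' @export
lipid_composition <- function(fractions, phosphorus = NULL) {
  if (is.null(names(fractions)) || any(!nzchar(names(fractions))))
    abort_validation("fractions must be a named vector")
  if (any(fractions < 0)) abort_validation("fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    abort_validation("fractions must sum to 1")
  p <- stats::setNames(ifelse(names(fractions) == "CL", 2L, 1L),
                       names(fractions))
  if (!is.null(phosphorus)) p[names(phosphorus)] <- as.integer(phosphorus)
  if (any(p <= 0)) abort_validation("phosphorus counts must be positive")
  structure(list(fractions = fractions, phosphorus_per_molecule = p),
            class = "lipid_composition")
}

#' Default ten-class composition
#'
#' A lecithin-like mixture covering the ten classes with intervals in the
#' default shift library: PC-dominated, PE-rich, with minor lyso and
#' unidentified components. Fractions are mol fractions.
#'
#' @return a [lipid_composition()].
#' @export
default_composition <- function() {
  lipid_composition(c(PC = 0.30, PE = 0.22, PG = 0.10, UNK1 = 0.08,
                      PA = 0.07, SM = 0.06, LPI = 0.05, UNK2 = 0.05,
                      LPC = 0.04, LPA = 0.03))
}

#' Default resonance table
#'
#' One resonance per library interval, centered on the interval midpoint,
#' with a 2.0 Hz natural linewidth (narrow CUBO lines; chosen so the 1.5 Hz
#' processing line broadening is non-negligible). PE splits its phosphorus
#' over its four intervals (weights 0.30/0.30/0.25/0.15 downfield to
#' upfield, emulating unequal conformer populations); PG splits equally over
#' its two intervals. CL has no library interval; it is given a synthetic
#' placeholder resonance at 3.30 ppm in a signal-free region.
#'
#' @param library a [shift_library()]; defaults to the packaged library.
#' @param fwhm_hz natural linewidth before apodization (Hz).
#' @return data.frame with columns `lipid_class`, `center_ppm`, `fwhm_hz`,
#'   `relative_weight`.
#' @export
default_resonances <- function(library = load_default_library(),
                               fwhm_hz = 2.0) {
  mid <- lib_midpoints(library)
  res <- data.frame(lipid_class = library$lipid_class,
                    center_ppm = mid, fwhm_hz = fwhm_hz,
                    relative_weight = 1, stringsAsFactors = FALSE)
  pe <- res$lipid_class == "PE"
  if (sum(pe) == 4L) res$relative_weight[pe] <- c(0.30, 0.30, 0.25, 0.15)
  pg <- res$lipid_class == "PG"
  res$relative_weight[pg] <- 1 / sum(pg)
  rbind(res, data.frame(lipid_class = "CL", center_ppm = 3.30,
                        fwhm_hz = fwhm_hz, relative_weight = 1,
                        stringsAsFactors = FALSE))
}

validate_resonances <- function(resonances, composition) {
  classes <- names(composition$fractions)
  have <- unique(resonances$lipid_class)
  miss <- setdiff(classes[composition$fractions > 0], have)
  if (length(miss))
    abort_validation(paste("no resonance spec for class(es):",
                           paste(miss, collapse = ", ")))
  if (any(resonances$fwhm_hz <= 0)) abort_validation("fwhm must be > 0")
  for (cl in intersect(classes, have)) {
    w <- resonances$relative_weight[resonances$lipid_class == cl]
    if (abs(sum(w) - 1) > 1e-9)
      abort_validation(paste0("relative_weights for ", cl, " must sum to 1"))
  }
  invisible(TRUE)
}

#' Synthesize a free induction decay
#'
#' Builds `s(t_j) = sum_k a_k exp(i 2 pi nu_k t_j - pi fwhm_k t_j) + e_j`
#' with `t_j = j * dwell`, where `nu_k` is the resonance center converted to
#' a Hz offset from the carrier and the amplitude is
#' `a_k = mass_mg * fraction(class) * phosphorus_per_molecule(class) *
#' relative_weight`. `e_j` is stationary complex white Gaussian noise with
#' standard deviation `noise_sigma` per channel, drawn deterministically
#' from `seed`. Signal scales linearly with mass at fixed noise, so S/N is
#' proportional to sample mass.
#'
#' The default `noise_sigma` (0.4) anchors a 1 mg sample of a mid-sized
#' (about 6 mol%) class at S/N of about 3 after default processing, matching
#' the minimum-mass behaviour the simulator is meant to emulate.
#'
#' @param composition a [lipid_composition()].
#' @param resonances resonance table (see [default_resonances()]).
#' @param params an [acquisition_params()].
#' @param mass_mg sample mass (mg); peak amplitudes are proportional to it.
#' @param noise_sigma time-domain noise standard deviation per channel.
#' @param seed integer RNG seed; the FID is bitwise reproducible.
#' @return object of class `nmr_fid`: complex `samples`, `params`, `history`.
#' @export
synthesize_fid <- function(composition, resonances,
                           params = acquisition_params(), mass_mg = 8,
                           noise_sigma = 0.4, seed = 1L) {
  if (mass_mg <= 0) abort_validation("mass_mg must be > 0")
  if (noise_sigma < 0) abort_validation("noise_sigma must be >= 0")
  validate_resonances(resonances, composition)
  res <- resonances[resonances$lipid_class %in%
                      names(composition$fractions), , drop = FALSE]
  dt <- dwell_time(params)
  t <- (seq_len(params$n_complex) - 1) * dt
  s <- complex(real = numeric(params$n_complex),
               imaginary = numeric(params$n_complex))
  for (k in seq_len(nrow(res))) {
    cl <- res$lipid_class[k]
    a <- mass_mg * composition$fractions[[cl]] *
      composition$phosphorus_per_molecule[[cl]] * res$relative_weight[k]
    if (a == 0) next
    nu <- ppm_to_hz(res$center_ppm[k] - params$carrier_ppm,
                    params$observe_freq)
    s <- s + a * exp(complex(imaginary = 2 * pi * nu * t) -
                       pi * res$fwhm_hz[k] * t)
  }
  if (noise_sigma > 0) {
    eps <- with_seed(seed, complex(
      real = stats::rnorm(params$n_complex, sd = noise_sigma),
      imaginary = stats::rnorm(params$n_complex, sd = noise_sigma)))
    s <- s + eps
  }
  new_fid(s, params,
          history = sprintf("synthesize_fid(mass=%g, noise=%g, seed=%d)",
                            mass_mg, noise_sigma, as.integer(seed)))
}

new_fid <- function(samples, params, history = character()) {
  if (length(samples) < 2) abort_validation("FID needs >= 2 samples")
  structure(list(samples = as.complex(samples), params = params,
                 history = history), class = "nmr_fid")
}

#' @export
print.nmr_fid <- function(x, ...) {
  cat(sprintf("<nmr_fid> %d complex points, sw %.2f ppm @ %.0f MHz\n",
              length(x$samples), x$params$sw, x$params$observe_freq))
  if (length(x$history)) cat(" history:", paste(x$history, collapse = " -> "),
                             "\n")
  invisible(x)
}

#' Concentration-dependent shift drift model
#'
#' Some headgroup shifts drift with sample concentration relative to the PC
#' reference: PE moves downfield with increasing mass, PA and LPA upfield,
#' while LPC and PI are concentration-independent. Drift is modelled as a
#' fixed ppm offset per doubling of mass about a reference mass.
#'
#' @param slope named vector, ppm per doubling of mass (positive =
#'   downfield).
#' @param mass_ref mass (mg) at which all offsets vanish.
#' @return object of class `conc_shift_model`.
#' @export
concentration_shift_model <- function(slope = c(PE = 0.01, PA = -0.01,
                                                LPA = -0.01),
                                      mass_ref = 4) {
  s <- slope
  if ("PE" %in% names(s) && s[["PE"]] <= 0)
    abort_validation("PE slope must be > 0 (downfield with mass)")
  for (cl in c("PA", "LPA"))
    if (cl %in% names(s) && s[[cl]] >= 0)
      abort_validation(paste(cl, "slope must be < 0 (upfield with mass)"))
  s[c("PC", "LPC", "PI")] <- 0
  structure(list(slope = s, mass_ref = mass_ref),
            class = "conc_shift_model")
}

#' Apply concentration-dependent shifts to a resonance table
#'
#' Each center moves by `slope(class) * log2(mass_mg / mass_ref)`; PC and
#' other classes without a slope are unchanged.
#'
#' @param resonances resonance table.
#' @param model a [concentration_shift_model()].
#' @param mass_mg sample mass (mg).
#' @return shifted resonance table.
#' @export
apply_concentration_shifts <- function(resonances, model, mass_mg) {
  if (mass_mg <= 0) abort_validation("mass_mg must be > 0")
  off <- model$slope[resonances$lipid_class]
  off[is.na(off)] <- 0
  resonances$center_ppm <- resonances$center_ppm +
    off * log2(mass_mg / model$mass_ref)
  resonances
}

#' Sample-ageing (PC hydrolysis) model
#'
#' Base-mediated ester hydrolysis converts PC to LPC while the sample sits
#' in solvent, so the LPC:PC ratio grows with sample age. The model is
#' anchored at two time points: the ratio at `t_late_days` exceeds the ratio
#' at `t_ref_hours` by the fractional `ratio_gain` (default 0.55, the middle
#' of the observed 50-60% window). Between anchors the ratio grows linearly
#' in time; no exponential kinetics are claimed.
#'
#' @param t_ref_hours reference age (hours).
#' @param t_late_days late age (days).
#' @param ratio_gain fractional LPC:PC increase between the anchors.
#' @return object of class `ageing_model`.
#' @export
ageing_model <- function(t_ref_hours = 48, t_late_days = 21,
                         ratio_gain = 0.55) {
  if (ratio_gain < 0) abort_validation("ratio_gain must be >= 0")
  if (t_late_days * 24 <= t_ref_hours)
    abort_validation("t_late must exceed t_ref")
  structure(list(t_ref_hours = t_ref_hours, t_late_days = t_late_days,
                 ratio_gain = ratio_gain), class = "ageing_model")
}

#' Age a composition by PC -> LPC hydrolysis
#'
#' Transfers material from PC to LPC so that the LPC:PC mol ratio grows
#' linearly in time from its value in `composition` (taken as the t = 0
#' state), with slope fixed so the ratio at `t_late_days` exceeds the ratio
#' at `t_ref_hours` by exactly `ratio_gain`. Total phosphorus is conserved
#' exactly; all other classes are untouched. A composition without LPC has
#' ratio 0 at all times under this parameterization (multiplicative growth
#' from zero), and is returned unchanged.
#'
#' @param composition a [lipid_composition()] containing PC.
#' @param model an [ageing_model()].
#' @param age_hours sample age (hours), >= 0.
#' @return aged [lipid_composition()].
#' @export
apply_ageing <- function(composition, model, age_hours) {
  if (age_hours < 0) abort_validation("age_hours must be >= 0")
  f <- composition$fractions
  if (!"PC" %in% names(f) || f[["PC"]] <= 0)
    abort_validation("composition must contain PC with fraction > 0")
  r0 <- if ("LPC" %in% names(f)) f[["LPC"]] / f[["PC"]] else 0
  if (age_hours == 0 || r0 == 0) return(composition)
  t_late <- model$t_late_days * 24
  denom <- t_late - (1 + model$ratio_gain) * model$t_ref_hours
  if (denom <= 0) abort_validation("ageing anchors are inconsistent")
  slope <- model$ratio_gain * r0 / denom
  r_t <- r0 + slope * age_hours
  total <- f[["PC"]] + f[["LPC"]]
  f[["PC"]] <- total / (1 + r_t)
  f[["LPC"]] <- total * r_t / (1 + r_t)
  lipid_composition(f, composition$phosphorus_per_molecule)
}

#' Adduct shift-offset model
#'
#' Counter-ions electrostatically associated with phosphate headgroups
#' (triethylammonium, sodium, guanidinium) perturb 31P shifts of LPA, PA, PI
#' and PE relative to PC, which is pinned at 0.00 ppm as the calibration
#' reference. TEA+ and Na+ apply fixed per-class offsets; guanidinium
#' offsets scale linearly with the added mass (mg) and do not all share the
#' direction of the other adducts.
#'
#' @param offsets named list of named numeric vectors, one per adduct.
#'   `TEA+`/`Na+` entries are ppm; `guanidinium` entries are ppm per mg.
#' @return object of class `adduct_model`.
#' @export
adduct_model <- function(offsets = list(
    "TEA+" = c(PE = 0.02, PA = -0.03, LPA = -0.03, PI = 0.02),
    "Na+" = c(PE = 0.05, PA = -0.05, LPA = -0.06, PI = 0.04),
    "guanidinium" = c(PE = 0.002, PA = -0.0015, LPA = 0.002, PI = -0.001))) {
  for (ad in names(offsets))
    if ("PC" %in% names(offsets[[ad]]) && offsets[[ad]][["PC"]] != 0)
      abort_validation("PC offset must be 0 (calibration reference)")
  structure(list(offsets = offsets), class = "adduct_model")
}

#' Apply adduct shift offsets to a resonance table
#'
#' @param resonances resonance table.
#' @param model an [adduct_model()].
#' @param adduct one of the adducts in `model`.
#' @param amount_mg added salt mass (mg); scales guanidinium offsets, and an
#'   amount of 0 is the identity for every adduct.
#' @return shifted resonance table.
#' @export
apply_adducts <- function(resonances, model, adduct, amount_mg = 10) {
  if (!adduct %in% names(model$offsets))
    abort_validation(paste("unknown adduct:", adduct))
  if (amount_mg < 0) abort_validation("amount_mg must be >= 0")
  if (amount_mg == 0) return(resonances)
  off <- model$offsets[[adduct]]
  delta <- off[resonances$lipid_class]
  delta[is.na(delta)] <- 0
  if (adduct == "guanidinium") delta <- delta * amount_mg
  resonances$center_ppm <- resonances$center_ppm + delta
  resonances
}

#' Simulate a complete scenario
#'
#' Convenience wrapper: ages the composition, applies concentration and
#' adduct shift perturbations to the resonance table, and synthesizes the
#' FID. This is the one-call fixture generator used by the test-suite and
#' the CLI.
#'
#' @param composition a [lipid_composition()] (default ten-class mixture).
#' @param resonances resonance table (default library midpoints).
#' @param params an [acquisition_params()].
#' @param mass_mg sample mass (mg).
#' @param age_hours sample age (hours); 0 disables ageing.
#' @param adduct optional adduct name; `NULL` disables adduct offsets.
#' @param adduct_mg added salt mass (mg).
#' @param noise_sigma time-domain noise sd per channel.
#' @param seed RNG seed.
#' @param conc_model,ageing,adducts model objects (defaults as documented).
#' @return list with the `fid` and a `truth` data.frame of per-class mol
#'   fractions (per phosphorus) used as ground truth in tests.
#' @export
simulate_scenario <- function(composition = default_composition(),
                              resonances = default_resonances(),
                              params = acquisition_params(),
                              mass_mg = 8, age_hours = 0, adduct = NULL,
                              adduct_mg = 10, noise_sigma = 0.4, seed = 1L,
                              conc_model = concentration_shift_model(),
                              ageing = ageing_model(),
                              adducts = adduct_model()) {
  if (age_hours > 0)
    composition <- apply_ageing(composition, ageing, age_hours)
  res <- apply_concentration_shifts(resonances, conc_model, mass_mg)
  if (!is.null(adduct))
    res <- apply_adducts(res, adducts, adduct, adduct_mg)
  fid <- synthesize_fid(composition, res, params, mass_mg = mass_mg,
                        noise_sigma = noise_sigma, seed = seed)
  p_weight <- composition$fractions *
    composition$phosphorus_per_molecule[names(composition$fractions)]
  truth <- data.frame(lipid_class = names(composition$fractions),
                      mol_frac = as.numeric(composition$fractions),
                      p_frac = as.numeric(p_weight / sum(p_weight)),
                      stringsAsFactors = FALSE)
  list(fid = fid, truth = truth, resonances = res,
       composition = composition)
}
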