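FID_FORMAT <- "pnmrlipids-fid"
SPEC_FORMAT <- "pnmrlipids-spectrum"
IO_VERSION <- 1L

#' Read a 1D Bruker data directory
#'
#' Minimal, read-only support for the classic 1D Bruker layout: a text
#' `acqus` parameter file plus a binary `fid` of interleaved real/imaginary
#' points. Parsed parameters: `TD` (total points, twice the complex count),
#' `SW` (spectral width, ppm), `SFO1` (observe frequency, MHz), `BYTORDA`
#' (byte order: 0 little-endian, 1 big-endian) and `DTYPA` (0 = int32,
#' 2 = float64). The carrier is taken from `O1`/`BF1` when present.
#' Unknown optional fields are ignored with a warning-level log message.
#'
#' @param path directory containing `acqus` and `fid`.
#' @return an `nmr_fid`.
#' @export
read_bruker_dir <- function(path) {
  acqus <- file.path(path, "acqus")
  fidfile <- file.path(path, "fid")
  if (!file.exists(acqus)) abort_format("missing acqus parameter file")
  if (!file.exists(fidfile)) abort_format("missing fid binary")
  lines <- readLines(acqus, warn = FALSE)
  get_par <- function(name, mandatory = TRUE, default = NULL) {
    m <- grep(sprintf("^##\\$%s=", name), lines, value = TRUE)
    if (!length(m)) {
      if (mandatory)
        abort_format(sprintf("acqus is missing mandatory parameter %s",
                             name))
      return(default)
    }
    as.numeric(sub("^##\\$[A-Za-z0-9]+=\\s*", "", m[1]))
  }
  td <- get_par("TD")
  sw <- get_par("SW")
  sfo1 <- get_par("SFO1")
  bytorda <- get_par("BYTORDA", FALSE, 0)
  dtypa <- get_par("DTYPA", FALSE, 0)
  o1 <- get_par("O1", FALSE, NA)
  bf1 <- get_par("BF1", FALSE, NA)
  endian <- if (bytorda == 0) "little" else "big"
  what <- if (dtypa == 2) "double" else "integer"
  size <- if (dtypa == 2) 8L else 4L
  expected_bytes <- td * size
  if (file.size(fidfile) < expected_bytes)
    abort_format(sprintf(
      "fid holds %d bytes but TD=%d requires %d (truncated file?)",
      file.size(fidfile), as.integer(td), as.integer(expected_bytes)))
  raw <- readBin(fidfile, what, n = td, size = size, endian = endian,
                 signed = TRUE)
  samples <- complex(real = raw[seq(1, td, by = 2)],
                     imaginary = raw[seq(2, td, by = 2)])
  carrier <- if (is.finite(o1) && is.finite(bf1)) o1 / bf1 else sw / 2
  params <- acquisition_params(observe_freq = sfo1, sw = sw,
                               n_complex = td / 2, carrier_ppm = carrier)
  new_fid(samples, params,
          history = sprintf("read_bruker_dir(%s)", path))
}

# Companion writer for the minimal Bruker dialect above. Used to build
# round-trip fixtures in tests; not part of the supported surface.
write_bruker_dir <- function(fid, path, byte_order = c("little", "big")) {
  byte_order <- match.arg(byte_order)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  p <- fid$params
  td <- 2L * length(fid$samples)
  writeLines(c("##TITLE= pnmrlipids synthetic acquisition",
               sprintf("##$TD= %d", td),
               sprintf("##$SW= %.6f", p$sw),
               sprintf("##$SFO1= %.6f", p$observe_freq),
               sprintf("##$BF1= %.6f", p$observe_freq),
               sprintf("##$O1= %.6f", p$carrier_ppm * p$observe_freq),
               sprintf("##$BYTORDA= %d",
                       if (byte_order == "little") 0L else 1L),
               "##$DTYPA= 0",
               "##$UNUSED_CUSTOM= 42",
               "##END="),
             file.path(path, "acqus"))
  inter <- as.integer(round(rbind(Re(fid$samples), Im(fid$samples))))
  writeBin(inter, file.path(path, "fid"), size = 4L, endian = byte_order)
  invisible(path)
}

fid_params_list <- function(p)
  list(observe_freq = p$observe_freq, sw = p$sw, n_complex = p$n_complex,
       carrier_ppm = p$carrier_ppm, recovery_delay = p$recovery_delay,
       temperature = p$temperature)

#' JSON FID dump: lossless write/read round trip
#'
#' Self-describing dialect carrying the complex samples, acquisition
#' parameters and processing history, with a mandatory format/version
#' header. Unknown extra keys are ignored with a warning; a version
#' mismatch is an explicit error.
#'
#' @param fid an `nmr_fid`.
#' @param path file path.
#' @return `write_fid_json` returns `path` invisibly; `read_fid_json`
#'   returns an `nmr_fid`.
#' @export
write_fid_json <- function(fid, path) {
  jsonlite::write_json(
    list(format = FID_FORMAT, version = IO_VERSION,
         params = fid_params_list(fid$params),
         history = fid$history,
         real = Re(fid$samples), imag = Im(fid$samples)),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

check_dump <- function(x, expect_format, path) {
  if (is.null(x$version))
    abort_format(sprintf("%s: missing version field", path))
  if (x$version != IO_VERSION)
    abort_format(sprintf("%s: version %s not supported (expected %d)",
                         path, x$version, IO_VERSION))
  if (!identical(x$format, expect_format))
    abort_format(sprintf("%s: format '%s', expected '%s'", path,
                         x$format %||% "?", expect_format))
  known <- switch(expect_format,
    "pnmrlipids-fid" = c("format", "version", "params", "history", "real",
                         "imag"),
    "pnmrlipids-spectrum" = c("format", "version", "params", "history",
                              "real", "imag", "axis_ppm", "phased",
                              "baseline_corrected", "calibration"))
  extra <- setdiff(names(x), known)
  if (length(extra))
    message(sprintf("[pnmrlipids] ignoring unknown keys in %s: %s", path,
                    paste(extra, collapse = ", ")))
  invisible(TRUE)
}

#' @rdname write_fid_json
#' @export
read_fid_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$format, SPEC_FORMAT))
    abort_format(sprintf(
      "%s is a processed spectrum, not an FID", path))
  check_dump(x, FID_FORMAT, path)
  params <- do.call(acquisition_params, x$params)
  new_fid(complex(real = x$real, imaginary = x$imag), params,
          history = as.character(x$history))
}

#' JSON dump of a processed spectrum
#' @param spec an `nmr_spectrum`.
#' @param path file path.
#' @return `write_spectrum_json` returns `path` invisibly;
#'   `read_spectrum_json` returns an `nmr_spectrum`.
#' @export
write_spectrum_json <- function(spec, path) {
  jsonlite::write_json(
    list(format = SPEC_FORMAT, version = IO_VERSION,
         params = fid_params_list(spec$params), history = spec$history,
         real = spec$real, imag = spec$imag, axis_ppm = spec$axis_ppm,
         phased = spec$phased,
         baseline_corrected = spec$baseline_corrected,
         calibration = spec$calibration),
    path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_spectrum_json
#' @export
read_spectrum_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(x$format, FID_FORMAT))
    abort_format(sprintf(
      "%s is a raw FID; processing required before fitting", path))
  check_dump(x, SPEC_FORMAT, path)
  structure(list(real = x$real, imag = x$imag, axis_ppm = x$axis_ppm,
                 params = do.call(acquisition_params, x$params),
                 phased = isTRUE(x$phased),
                 baseline_corrected = isTRUE(x$baseline_corrected),
                 calibration = x$calibration,
                 history = as.character(x$history)),
            class = "nmr_spectrum")
}

#' Scenario / run configuration
#'
#' A JSON-serializable record of everything a run needs: composition, mass,
#' age, adduct, noise, seed, and processing/fit/quantify parameters.
#' Serialization round-trips byte-identically
#' (serialize - parse - serialize).
#'
#' @param composition named list/vector of mol fractions.
#' @param mass_mg,age_hours,adduct,adduct_mg,noise_sigma,seed scenario
#'   parameters (see [simulate_scenario()]).
#' @param lb,zf processing parameters.
#' @param shape_mode,min_snr fit parameters.
#' @param min_frac_pct,basis,tolerance quantification parameters.
#' @param library_path optional path to a shift-library TSV.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(composition = as.list(default_composition()$fractions),
                       mass_mg = 8, age_hours = 0, adduct = NULL,
                       adduct_mg = 10, noise_sigma = 0.4, seed = 1L,
                       lb = 1.5, zf = 32768, shape_mode = "pseudo_voigt",
                       min_snr = 3, min_frac_pct = 0.01,
                       basis = "per_phosphorus", tolerance = 0.02,
                       library_path = NULL) {
  structure(list(composition = composition, mass_mg = mass_mg,
                 age_hours = age_hours, adduct = adduct,
                 adduct_mg = adduct_mg, noise_sigma = noise_sigma,
                 seed = as.integer(seed), lb = lb, zf = as.integer(zf),
                 shape_mode = shape_mode, min_snr = min_snr,
                 min_frac_pct = min_frac_pct, basis = basis,
                 tolerance = tolerance, library_path = library_path),
            class = "run_config")
}

config_json <- function(config)
  jsonlite::toJSON(unclass(config), auto_unbox = TRUE, digits = NA,
                   null = "null", pretty = TRUE)

#' @rdname run_config
#' @param path config file path.
#' @export
write_config <- function(config, path) {
  writeLines(config_json(config), path)
  invisible(path)
}

#' @rdname run_config
#' @export
read_config <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  x$composition <- as.list(x$composition)
  args <- x[intersect(names(x), names(formals(run_config)))]
  do.call(run_config, args)
}

config_hash <- function(config) hash_string(as.character(config_json(config)))
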