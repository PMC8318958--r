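#' Signal-to-noise ratio of a fitted peak
#'
#' Defined as fitted apex height divided by the spectrum noise standard
#' deviation.
#'
#' @param height fitted peak height (or a vector of heights).
#' @param sigma noise standard deviation, > 0.
#' @return `height / sigma`.
#' @export
compute_snr <- function(height, sigma) {
  if (sigma <= 0) abort_validation("sigma must be > 0")
  height / sigma
}

flag_str <- function(...) {
  f <- c(...)
  if (!length(f)) "" else paste(f, collapse = ";")
}

#' Apply presence and reporting filters to quantification rows
#'
#' Two rules gate what is reported. (1) Integrations below a noise threshold
#' of 0.01% of the total 31P signal are flagged `below_threshold` and
#' excluded. (2) Rows with S/N below 3:1 are not regarded as genuine: they
#' are flagged `low_snr` and excluded by default (`keep_low_snr = TRUE`
#' retains them, still flagged). Mol% is renormalized over the survivors.
#'
#' @param rows data.frame with at least `area` and `snr` columns.
#' @param min_frac_pct area threshold as a percentage of total area
#'   (default 0.01).
#' @param min_snr minimum S/N (default 3).
#' @param keep_low_snr retain (flagged) rows failing the S/N rule?
#' @return `rows` with updated `flags`, logical `excluded` and renormalized
#'   `mol_pct`.
#' @export
apply_reporting_filters <- function(rows, min_frac_pct = 0.01, min_snr = 3,
                                    keep_low_snr = FALSE) {
  total <- sum(rows$area)
  if (!(total > 0)) abort_validation("total area must be > 0")
  if (is.null(rows$flags)) rows$flags <- ""
  below <- rows$area / total < min_frac_pct / 100
  low <- rows$snr < min_snr
  rows$flags <- mapply(function(f, b, l) {
    add <- c(if (b) "below_threshold", if (l) "low_snr")
    flag_str(c(setdiff(strsplit(f, ";")[[1]], c("below_threshold", "low_snr")),
               add))
  }, rows$flags, below, low)
  rows$excluded <- below | (low & !keep_low_snr)
  if (all(rows$excluded)) abort("all rows excluded by reporting filters",
                                "pnmr_empty_report_error")
  rows$mol_pct <- 0
  keep <- !rows$excluded
  rows$mol_pct[keep] <- 100 * rows$area[keep] / sum(rows$area[keep])
  rows
}

#' Build a lipid-class quantification report
#'
#' Assigns every fitted peak to a lipid class through the shift library,
#' applies the presence/reporting filters, sums multi-resonance classes
#' (PE's four resonances, PG's two intervals) into one row each, and
#' expresses class abundances as mol% of the reported total. Peaks matching
#' no interval are reported with flag `unassigned`; peaks in the busy
#' 0.45-0.60 ppm region keep flag `ambiguous_region`.
#'
#' Basis: `per_phosphorus` (default) reports shares of total phosphorus,
#' which is what the spectrum measures; `per_molecule` divides cardiolipin's
#' area by its two 31P nuclei before computing mol%, so abundances are per
#' molecule.
#'
#' @param fit a `fit_result` from [fit_lineshapes()].
#' @param library a [shift_library()].
#' @param sigma noise standard deviation used for S/N.
#' @param basis `"per_phosphorus"` or `"per_molecule"`.
#' @param tolerance assignment tolerance (ppm) passed to [assign_peak()].
#' @param min_frac_pct,min_snr,keep_low_snr see [apply_reporting_filters()].
#' @param override_convergence proceed even if the fit did not converge.
#' @return object of class `quant_report`: `rows` (one per reported class,
#'   columns `lipid_class`, `center_ppm`, `area`, `mol_pct`, `snr`, `flags`),
#'   `peaks` (the per-peak table with assignments), `basis`, `total_area`,
#'   `noise_sigma`, `provenance`.
#' @export
build_report <- function(fit, library, sigma,
                         basis = c("per_phosphorus", "per_molecule"),
                         tolerance = 0.02, min_frac_pct = 0.01, min_snr = 3,
                         keep_low_snr = FALSE,
                         override_convergence = FALSE) {
  basis <- match.arg(basis)
  if (!fit$converged && !override_convergence)
    abort_validation("fit did not converge (set override_convergence=TRUE to proceed)")
  pk <- fit$peaks
  if (nrow(pk) == 0) abort("fit contains no peaks", "pnmr_empty_report_error")
  pk$lipid_class <- "unassigned"
  pk$lib_mid <- NA_real_
  pk$flags <- ""
  for (i in seq_len(nrow(pk))) {
    m <- assign_peak(pk$center_ppm[i], library, tolerance)
    fl <- character()
    if (nrow(m) == 0) fl <- "unassigned"
    else {
      pk$lipid_class[i] <- m$lipid_class[1]
      pk$lib_mid[i] <- m$midpoint[1]
      if (m$ambiguous[1]) fl <- "ambiguous_region"
    }
    if (pk$degenerate[i]) fl <- c(fl, "degenerate_fit")
    pk$flags[i] <- flag_str(fl)
  }
  pk$snr <- compute_snr(pk$height, sigma)
  pk <- apply_reporting_filters(pk, min_frac_pct, min_snr, keep_low_snr)
  kept <- pk[!pk$excluded, , drop = FALSE]
  # per-class aggregation (unassigned peaks stay as their own rows)
  key <- ifelse(kept$lipid_class == "unassigned",
                paste0("unassigned@", format(kept$center_ppm, digits = 5)),
                kept$lipid_class)
  rows <- do.call(rbind, lapply(split(kept, key), function(d) {
    area <- sum(d$area)
    data.frame(
      lipid_class = d$lipid_class[1],
      center_ppm = sum(d$center_ppm * d$area) / area,
      area = area,
      snr = sum(d$snr * d$area) / area,
      flags = flag_str(unique(unlist(strsplit(d$flags, ";")))),
      stringsAsFactors = FALSE)
  }))
  if (basis == "per_molecule") {
    p_count <- ifelse(rows$lipid_class == "CL", 2, 1)
    rows$area_per_molecule <- rows$area / p_count
    rows$mol_pct <- 100 * rows$area_per_molecule /
      sum(rows$area_per_molecule)
  } else {
    rows$mol_pct <- 100 * rows$area / sum(rows$area)
  }
  rows <- rows[order(-rows$center_ppm), , drop = FALSE]
  rownames(rows) <- NULL
  structure(list(rows = rows, peaks = pk, basis = basis,
                 total_area = sum(fit$peaks$area), noise_sigma = sigma,
                 provenance = list(
                   library_version = attr(library, "version") %||%
                     "unversioned",
                   shape_mode = fit$shape_mode %||% NA_character_,
                   tolerance = tolerance, min_frac_pct = min_frac_pct,
                   min_snr = min_snr)),
            class = "quant_report")
}

#' @export
print.quant_report <- function(x, ...) {
  cat(sprintf("<quant_report> basis=%s, sigma=%.4g, library %s\n",
              x$basis, x$noise_sigma, x$provenance$library_version))
  print.data.frame(x$rows, digits = 4, ...)
  invisible(x)
}

report_table <- function(report) {
  df <- report$rows
  df$basis <- report$basis
  df$library_version <- report$provenance$library_version
  df[, c("lipid_class", "center_ppm", "area", "mol_pct", "snr", "flags",
         "basis", "library_version")]
}

#' Write a quantification report
#'
#' CSV holds the flat class table (columns `lipid_class`, `center_ppm`,
#' `area`, `mol_pct`, `snr`, `flags`, `basis`, `library_version`); JSON
#' additionally embeds provenance and the per-peak table.
#'
#' @param report a `quant_report`.
#' @param path output file.
#' @param format `"csv"` or `"json"` (default from file extension).
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path,
                         format = c("auto", "csv", "json")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json"
              else "csv"
  if (format == "csv") {
    utils::write.csv(report_table(report), path, row.names = FALSE)
  } else {
    jsonlite::write_json(
      list(rows = report_table(report), peaks = report$peaks,
           basis = report$basis, total_area = report$total_area,
           noise_sigma = report$noise_sigma,
           provenance = report$provenance),
      path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(path)
}

#' Read a JSON quantification report
#' @param path file written by [write_report()] in JSON format.
#' @return a `quant_report`.
#' @export
read_report_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  rows <- as.data.frame(x$rows)
  structure(list(rows = rows[, setdiff(names(rows),
                                       c("basis", "library_version"))],
                 peaks = as.data.frame(x$peaks), basis = x$basis,
                 total_area = x$total_area, noise_sigma = x$noise_sigma,
                 provenance = x$provenance),
            class = "quant_report")
}
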