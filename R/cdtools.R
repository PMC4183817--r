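# Circular dichroism computations: mean residue ellipticity, single-
# wavelength (222 nm) helicity estimation, reference-spectrum subtraction,
# thermal melts and refolding, plus a basis-spectrum synthetic generator.

#' CD spectrum container
#'
#' @param wavelengths Wavelengths in nm (185-260).
#' @param signal Ellipticity values, either raw millidegrees or mean
#'   residue ellipticity (deg cm^2 dmol^-1 residue^-1); state which via
#'   `units`.
#' @param units `"mdeg"` or `"mre"`.
#' @param concentration Molar protein concentration (required to convert
#'   mdeg to MRE).
#' @param path_length Cuvette path length, cm.
#' @param n_residues Residues per protein molecule.
#' @param temperature Sample temperature, degrees C.
#' @return An object of class `cd_spectrum`.
#' @export
cd_spectrum <- function(wavelengths, signal, units = c("mdeg", "mre"),
                        concentration = NA, path_length = NA,
                        n_residues = NA, temperature = NA) {
  units <- match.arg(units)
  if (length(wavelengths) != length(signal)) {
    stop("wavelengths and signal must have the same length")
  }
  if (any(wavelengths < 170 | wavelengths > 300)) {
    stop("wavelengths outside the far-UV CD range")
  }
  structure(
    list(wavelengths = wavelengths, signal = signal, units = units,
         concentration = concentration, path_length = path_length,
         n_residues = n_residues, temperature = temperature),
    class = "cd_spectrum"
  )
}

#' Convert a millidegree spectrum to mean residue ellipticity
#'
#' MRE = theta_mdeg / (10 * c * N * l) with molar concentration c,
#' residue count N and path length l in cm; units
#' deg cm^2 dmol^-1 residue^-1.
#'
#' @param spectrum A `cd_spectrum` in millidegrees with complete
#'   concentration/path/residue metadata.
#' @return A `cd_spectrum` with `units = "mre"`.
#' @export
to_mre <- function(spectrum) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  if (spectrum$units == "mre") return(spectrum)
  meta <- c(spectrum$concentration, spectrum$path_length, spectrum$n_residues)
  if (any(is.na(meta)) || any(meta <= 0)) {
    stop("concentration, path_length and n_residues must all be known and positive")
  }
  out <- spectrum
  out$signal <- spectrum$signal /
    (10 * spectrum$concentration * spectrum$n_residues * spectrum$path_length)
  out$units <- "mre"
  out
}

# Temperature-dependent endpoint MRE values at 222 nm for the single-
# wavelength helicity method: a full helix of N residues and a random coil.
mre222_helix <- function(n_residues, temperature_C) {
  -40000 * (1 - 2.5 / n_residues) + 100 * temperature_C
}
mre222_coil <- function(temperature_C) {
  640 - 45 * temperature_C
}

#' Helical fraction from the 222 nm mean residue ellipticity
#'
#' Single-wavelength estimate using the amide n-pi* transition:
#' f_H = (MRE222 - MRE_coil) / (MRE_helix - MRE_coil), with the
#' chain-length- and temperature-corrected endpoints
#' MRE_helix = -40000 (1 - 2.5/N) + 100 T and MRE_coil = 640 - 45 T
#' (T in degrees C).  Values outside `[0, 1]` are clipped with a
#' warning.
#'
#' @param mre222 Mean residue ellipticity at 222 nm.
#' @param n_residues Number of residues (>= 10).
#' @param temperature Temperature, degrees C.
#' @return Helical fraction in `[0, 1]`.
#' @export
helicity_from_mre222 <- function(mre222, n_residues, temperature = 10) {
  if (n_residues < 10) stop("n_residues must be >= 10")
  th <- mre222_helix(n_residues, temperature)
  tc <- mre222_coil(temperature)
  f <- (mre222 - tc) / (th - tc)
  if (any(f < 0 | f > 1)) {
    warning("helicity outside [0, 1]; clipped")
    f <- pmin(pmax(f, 0), 1)
  }
  f
}

#' Subtract a reference spectrum (same molar concentration)
#'
#' Pointwise subtraction in millidegrees, used to isolate the SAH
#' contribution of a composite construct by removing the spectrum of the
#' matching construct without the insert, measured at the same molar
#' concentration.  No interpolation is performed: the wavelength grids
#' must match exactly.
#'
#' @param sample,reference `cd_spectrum` objects in millidegrees on the
#'   same wavelength grid; molar concentrations must agree within 5%.
#' @return A `cd_spectrum` in millidegrees whose `n_residues` is the
#'   residue-count difference (sample minus reference), for downstream
#'   MRE conversion of the isolated insert.
#' @export
subtract_reference <- function(sample, reference) {
  stopifnot(inherits(sample, "cd_spectrum"), inherits(reference, "cd_spectrum"))
  if (sample$units != "mdeg" || reference$units != "mdeg") {
    stop("subtraction operates on millidegree spectra")
  }
  if (length(sample$wavelengths) != length(reference$wavelengths) ||
      any(sample$wavelengths != reference$wavelengths)) {
    stop("wavelength grids differ; no implicit interpolation")
  }
  if (!is.na(sample$concentration) && !is.na(reference$concentration)) {
    rel <- abs(sample$concentration - reference$concentration) /
      reference$concentration
    if (rel > 0.05) {
      stop("molar concentrations differ by more than 5%")
    }
  }
  out <- sample
  out$signal <- sample$signal - reference$signal
  if (!is.na(sample$n_residues) && !is.na(reference$n_residues)) {
    out$n_residues <- sample$n_residues - reference$n_residues
  }
  out
}

#' Thermal melt curve
#'
#' @param temperatures Temperatures in degrees C, strictly monotone.
#' @param mre222 Mean residue ellipticity at 222 nm at each temperature.
#' @param direction `"heating"` or `"cooling"`.
#' @return An object of class `melt_curve`.
#' @export
melt_curve <- function(temperatures, mre222,
                       direction = c("heating", "cooling")) {
  direction <- match.arg(direction)
  if (length(temperatures) != length(mre222)) {
    stop("temperatures and mre222 must have the same length")
  }
  d <- diff(temperatures)
  if (!(all(d > 0) || all(d < 0))) {
    stop("temperatures must be strictly monotone")
  }
  structure(list(temperatures = temperatures, mre222 = mre222,
                 direction = direction),
            class = "melt_curve")
}

#' Normalise a melt curve to its value at 10 degrees C
#'
#' @param curve A `melt_curve` containing a point at 10 C (or within
#'   1 C of it; the nearest such point is the reference).
#' @return A `melt_curve` with `mre222` divided by the reference value,
#'   so the reference point is exactly 1.
#' @export
normalize_melt <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  i <- which.min(abs(curve$temperatures - 10))
  if (abs(curve$temperatures[i] - 10) > 1) {
    stop("no temperature point within 1 C of 10 C")
  }
  ref <- curve$mre222[i]
  if (abs(ref) < 1e-12) stop("reference value at 10 C is ~0; cannot normalise")
  out <- curve
  out$mre222 <- curve$mre222 / ref
  out
}

#' Refolding fraction after thermal denaturation
#'
#' Percentage of the original (pre-melt) 222 nm signal magnitude
#' recovered after cooling back to the reference temperature.
#'
#' @param before,after MRE222 values at the same temperature before
#'   melting and after refolding.
#' @return Percent recovery.
#' @export
refolding_fraction <- function(before, after) {
  if (sign(before) != sign(after)) {
    warning("sign inversion between before and after values")
  }
  100 * abs(after) / abs(before)
}

#' Classify a melt as cooperative or non-cooperative
#'
#' Fits both a two-state sigmoid (baselines + midpoint Tm + width) and a
#' straight line to the melt, and scores the difference in BIC.  A melt
#' is called cooperative when the sigmoid is decisively preferred
#' (delta BIC > 10) and the fitted 10-90% transition width is below
#' 20 degrees C; SAH domains, which melt gradually, fail one or both.
#'
#' @param curve A `melt_curve` with at least 20 temperature points.
#' @return List with `class` (`"cooperative"` or `"non_cooperative"`),
#'   `score` (BIC_line - BIC_sigmoid), `tm`, `transition_width` (10-90%,
#'   degrees C).
#' @export
melt_cooperativity <- function(curve) {
  stopifnot(inherits(curve, "melt_curve"))
  Tv <- curve$temperatures
  y <- curve$mre222
  n <- length(Tv)
  if (n < 20) stop("need at least 20 temperature points")
  lin <- stats::lm(y ~ Tv)
  bic_line <- stats::BIC(lin)
  sig <- try(minpack.lm::nlsLM(
    y ~ yf + (yu - yf) / (1 + exp((tm - Tv) / w)),
    start = list(yf = y[1], yu = y[n], tm = mean(range(Tv)), w = 5),
    lower = c(yf = -Inf, yu = -Inf, tm = min(Tv), w = 0.1),
    upper = c(yf = Inf, yu = Inf, tm = max(Tv), w = 200),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  ), silent = TRUE)
  if (inherits(sig, "try-error")) {
    warning("sigmoid fit failed; classifying as non-cooperative")
    return(list(class = "non_cooperative", score = NA_real_,
                tm = NA_real_, transition_width = NA_real_))
  }
  score <- bic_line - stats::BIC(sig)
  cf <- stats::coef(sig)
  width <- 2 * log(9) * unname(cf["w"])  # 10-90% width of the logistic
  cls <- if (score > 10 && width < 20) "cooperative" else "non_cooperative"
  list(class = cls, score = score, tm = unname(cf["tm"]),
       transition_width = width)
}

# Basis spectra (185-260 nm) for the synthetic generator, read from the
# shipped table.  The curves are smooth synthetic constructions with the
# canonical features (helix: double minima at 208/222 nm, positive band
# at ~192 nm; sheet: single minimum near 217 nm; coil: deep minimum near
# 198 nm), anchored so that the helix and coil values at 222 nm equal the
# helicity estimator's endpoints at N = Inf, T = 0 C.
cd_basis <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "cd_basis_synthetic.csv",
                          package = "sahspring")
      if (path == "") path <- file.path("inst", "extdata",
                                        "cd_basis_synthetic.csv")
      cache <<- utils::read.csv(path, comment.char = "#")
    }
    cache
  }
})

#' Synthesise a CD spectrum as a mixture of basis spectra
#'
#' Generates an MRE spectrum f_H * helix + f_S * sheet + f_C * coil +
#' noise from shipped synthetic basis curves.  The helix and coil basis
#' values at 222 nm are anchored to the endpoints used by
#' [helicity_from_mre222()] (with the chain-length correction applied to
#' the helix and the temperature offsets applied to both), so at zero
#' noise and zero sheet fraction the estimator recovers the input helix
#' fraction exactly.
#'
#' @param helix_fraction,sheet_fraction Fractions in `[0, 1]` with sum
#'   at most 1; the remainder is coil.
#' @param noise_sd Gaussian noise added to the MRE values.
#' @param n_residues Residues per molecule (helix endpoint correction).
#' @param temperature Temperature, degrees C.
#' @param concentration,path_length Sample metadata carried along.
#' @return A `cd_spectrum` in MRE units.
#' @export
synth_spectrum <- function(helix_fraction, sheet_fraction = 0,
                           noise_sd = 0, n_residues = 98,
                           temperature = 10,
                           concentration = 1e-5, path_length = 0.1) {
  if (helix_fraction < 0 || sheet_fraction < 0 ||
      helix_fraction + sheet_fraction > 1) {
    stop("fractions must be >= 0 and sum to at most 1")
  }
  coil_fraction <- 1 - helix_fraction - sheet_fraction
  b <- cd_basis()
  # offset the shipped curves so the 222 nm anchors match the estimator's
  # endpoints for this chain length and temperature
  i222 <- which(b$wavelength_nm == 222)
  helix <- b$helix + (mre222_helix(n_residues, temperature) - b$helix[i222])
  coil <- b$coil + (mre222_coil(temperature) - b$coil[i222])
  mre <- helix_fraction * helix + sheet_fraction * b$sheet +
    coil_fraction * coil
  if (noise_sd > 0) mre <- mre + stats::rnorm(length(mre), sd = noise_sd)
  cd_spectrum(b$wavelength_nm, mre, units = "mre",
              concentration = concentration, path_length = path_length,
              n_residues = n_residues, temperature = temperature)
}

#' Read and write CD spectra as CSV
#'
#' CSV with a `#`-prefixed metadata header (`units`, `conc_M`,
#' `path_cm`, `n_residues`, `temp_C`) and columns `wavelength_nm`,
#' `signal`.
#'
#' @param spectrum A `cd_spectrum`.
#' @param path File path.
#' @export
write_cd_spectrum <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "cd_spectrum"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf(
    "# units: %s\n# conc_M: %g\n# path_cm: %g\n# n_residues: %g\n# temp_C: %g",
    spectrum$units, spectrum$concentration, spectrum$path_length,
    spectrum$n_residues, spectrum$temperature), con)
  utils::write.table(
    data.frame(wavelength_nm = spectrum$wavelengths,
               signal = spectrum$signal),
    con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_cd_spectrum
#' @export
read_cd_spectrum <- function(path) {
  lines <- readLines(path)
  hdr <- lines[startsWith(lines, "#")]
  meta <- yaml::yaml.load(paste(sub("^# ?", "", hdr), collapse = "\n"))
  df <- utils::read.csv(text = lines[!startsWith(lines, "#")])
  cd_spectrum(df$wavelength_nm, df$signal,
              units = if (is.null(meta$units)) "mdeg" else meta$units,
              concentration = meta$conc_M %||% NA,
              path_length = meta$path_cm %||% NA,
              n_residues = meta$n_residues %||% NA,
              temperature = meta$temp_C %||% NA)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
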