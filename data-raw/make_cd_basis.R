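# Builds the synthetic CD basis-spectrum table shipped in
# inst/extdata/cd_basis_synthetic.csv.  The curves are smooth Gaussian-band
# constructions (not digitised measurements) with the canonical far-UV
# features of the three secondary-structure classes, vertically anchored so
# that helix(222 nm) = -40000 and coil(222 nm) = +640 (the helicity
# estimator's endpoints at N = Inf, T = 0 C).

wl <- 185:260
g <- function(center, width) exp(-(wl - center)^2 / (2 * width^2))

helix <- -36000 * g(222, 5.2) - 34000 * g(208, 4.6) + 65000 * g(191.5, 5.5)
sheet <- -18500 * g(217, 6.5) + 30000 * g(196, 5.5)
coil <- -42000 * g(197.5, 6.5) + 700 * g(228, 25)

i222 <- which(wl == 222)
helix <- helix + (-40000 - helix[i222])
coil <- coil + (640 - coil[i222])

tab <- data.frame(wavelength_nm = wl,
                  helix = round(helix, 1),
                  sheet = round(sheet, 1),
                  coil = round(coil, 1))

out <- file.path("inst", "extdata", "cd_basis_synthetic.csv")
con <- file(out, "w")
writeLines(c(
  "# Synthetic far-UV CD basis spectra (mean residue ellipticity,",
  "# deg cm^2 dmol^-1 residue^-1) for the spectrum generator.  Smooth",
  "# Gaussian-band constructions, not digitised reference data; helix and",
  "# coil are anchored at 222 nm to the single-wavelength helicity",
  "# estimator endpoints (N = Inf, T = 0 C).  Built by data-raw/make_cd_basis.R."),
  con)
write.csv(tab, con, row.names = FALSE, quote = FALSE)
close(con)
cat("wrote", out, "\n")
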