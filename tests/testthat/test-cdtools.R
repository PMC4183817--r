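# Circular dichroism computations and the basis-spectrum generator.

test_that("MRE conversion is the standard per-residue normalisation", {
  s <- cd_spectrum(c(208, 222), c(-20, -20), "mdeg",
                   concentration = 1e-5, path_length = 0.1, n_residues = 98)
  m <- to_mre(s)
  # -20 / (10 * 1e-5 * 98 * 0.1)
  expect_equal(m$signal, c(-20408.16, -20408.16), tolerance = 1e-4)
  expect_equal(m$units, "mre")

  z <- to_mre(cd_spectrum(222, 0, "mdeg", 1e-5, 0.1, 98))
  expect_equal(z$signal, 0)

  # linear: doubling the concentration halves the MRE
  s2 <- s; s2$concentration <- 2e-5
  expect_equal(to_mre(s2)$signal, m$signal / 2)

  expect_error(to_mre(cd_spectrum(222, -20, "mdeg")), "must all be known")
})

test_that("helicity endpoints and the 67% reference case invert exactly", {
  th_h <- -40000 * (1 - 2.5 / 98) + 100 * 10
  th_c <- 640 - 45 * 10
  expect_equal(helicity_from_mre222(th_c, 98, 10), 0)
  expect_equal(helicity_from_mre222(th_h, 98, 10), 1)
  mre67 <- th_c + 0.67 * (th_h - th_c)
  expect_equal(helicity_from_mre222(mre67, 98, 10), 0.67)
  expect_error(helicity_from_mre222(-20000, 5, 10), ">= 10")
  expect_warning(f <- helicity_from_mre222(-60000, 98, 10), "clipped")
  expect_equal(f, 1)
})

test_that("generator and estimator are mutually consistent", {
  for (fh in seq(0.2, 0.9, by = 0.1)) {
    sp <- synth_spectrum(fh, noise_sd = 0)
    i222 <- which(sp$wavelengths == 222)
    est <- helicity_from_mre222(sp$signal[i222], sp$n_residues,
                                sp$temperature)
    expect_equal(est, fh, tolerance = 0.03)
  }
  # pure helix shows the canonical double minima
  sp <- synth_spectrum(1)
  y <- sp$signal
  w <- sp$wavelengths
  locmin <- w[which(diff(sign(diff(y))) == 2) + 1]
  expect_true(all(c(222) %in% locmin) || which.min(y) == which(w == 222))
  expect_true(any(abs(locmin - 208) <= 1))
  # all-zero fractions give the coil basis (minimum near 198 nm)
  sp0 <- synth_spectrum(0)
  expect_lt(abs(w[which.min(sp0$signal)] - 198), 2)
  expect_error(synth_spectrum(0.7, 0.5), "sum to at most 1")
})

test_that("reference subtraction isolates an inserted helix", {
  denom <- function(s) 10 * s$concentration * s$n_residues * s$path_length
  helix <- synth_spectrum(1, n_residues = 97)
  sheetish <- synth_spectrum(0, sheet_fraction = 0.8, n_residues = 445)
  # composite construct: reference signal plus the insert's contribution,
  # in measured millidegrees at the same molar concentration
  ref_mdeg <- cd_spectrum(sheetish$wavelengths,
                          sheetish$signal * denom(sheetish), "mdeg",
                          concentration = 1e-5, path_length = 0.1,
                          n_residues = 445)
  comp_mdeg <- cd_spectrum(helix$wavelengths,
                           ref_mdeg$signal + helix$signal * denom(helix),
                           "mdeg", concentration = 1e-5, path_length = 0.1,
                           n_residues = 445 + 97)
  d <- subtract_reference(comp_mdeg, ref_mdeg)
  expect_equal(d$n_residues, 97)
  expect_equal(to_mre(d)$signal, helix$signal, tolerance = 1e-9)

  # subtracting a spectrum from itself is identically zero
  self <- subtract_reference(ref_mdeg, ref_mdeg)
  expect_true(all(self$signal == 0))

  # mismatched grids and concentrations are refused
  shifted <- ref_mdeg
  shifted$wavelengths <- shifted$wavelengths + 1
  expect_error(subtract_reference(comp_mdeg, shifted), "grids differ")
  diluted <- ref_mdeg
  diluted$concentration <- 2e-5
  expect_error(subtract_reference(comp_mdeg, diluted), "concentrations")
})

test_that("melt normalisation anchors the 10 C point at 1", {
  Tv <- seq(10, 85, by = 1)
  const <- melt_curve(Tv, rep(-30000, length(Tv)))
  expect_true(all(normalize_melt(const)$mre222 == 1))

  lin <- melt_curve(Tv, seq(2, 1, length.out = length(Tv)) * -30000)
  nl <- normalize_melt(lin)
  expect_equal(nl$mre222[1], 1)
  expect_equal(nl$mre222[length(Tv)], 0.5)

  # invariant under uniform scaling
  scaled <- melt_curve(Tv, lin$mre222 * 3.7)
  expect_equal(normalize_melt(scaled)$mre222, nl$mre222)

  # cooling curves normalise the same way
  cool <- melt_curve(rev(Tv), rev(lin$mre222), direction = "cooling")
  expect_equal(normalize_melt(cool)$mre222[length(Tv)], 1)

  expect_error(normalize_melt(melt_curve(seq(20, 85, 1),
                                         rnorm(66, -3e4, 1))), "10 C")
  expect_error(melt_curve(c(10, 20, 15), c(1, 2, 3)), "monotone")
})

test_that("refolding fraction compares 222 nm magnitudes", {
  expect_equal(refolding_fraction(-32000, -32000), 100)
  expect_equal(refolding_fraction(-32000, -0.8 * 32000), 80)
  expect_equal(suppressWarnings(refolding_fraction(-32000, 0)), 0)
  expect_warning(refolding_fraction(-32000, 5000), "sign")
})

test_that("melt cooperativity separates sigmoidal from gradual melts", {
  set.seed(7)
  Tv <- seq(10, 85, by = 1)
  sig <- -30000 + 25000 / (1 + exp((50 - Tv) / 2)) +
    rnorm(length(Tv), sd = 300)
  res <- melt_cooperativity(melt_curve(Tv, sig))
  expect_equal(res$class, "cooperative")
  expect_equal(res$tm, 50, tolerance = 0.05)
  expect_lt(res$transition_width, 20)

  lin <- -30000 + 200 * (Tv - 10) + rnorm(length(Tv), sd = 300)
  expect_equal(melt_cooperativity(melt_curve(Tv, lin))$class,
               "non_cooperative")

  noise <- rnorm(length(Tv), sd = 500)
  expect_equal(melt_cooperativity(melt_curve(Tv, noise))$class,
               "non_cooperative")

  expect_error(melt_cooperativity(melt_curve(1:10 + 9, rnorm(10))),
               "at least 20")
})

test_that("CD spectrum files round trip with metadata", {
  sp <- synth_spectrum(0.67, noise_sd = 0)
  path <- withr::local_tempfile(fileext = ".csv")
  write_cd_spectrum(sp, path)
  rt <- read_cd_spectrum(path)
  expect_equal(rt$signal, sp$signal, tolerance = 1e-6)
  expect_equal(rt$units, "mre")
  expect_equal(rt$n_residues, 98)
  expect_equal(rt$temperature, 10)
})
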