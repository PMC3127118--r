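test_that("read_spectrum parses, sorts, and validates two-column files", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# comment", "300,0.0", "346,1.0", "400,0.1"), f)
  s <- read_spectrum(f, "emission")
  expect_s3_class(s, "emission_spectrum")
  expect_equal(s$wavelength_nm, c(300, 346, 400))
  expect_equal(s$intensity_au, c(0, 1, 0.1))

  # out-of-order rows are sorted to the same point set
  writeLines(c("400 0.1", "300 0.0", "346 1.0"), f)
  s2 <- read_spectrum(f, "emission")
  expect_equal(s2$wavelength_nm, s$wavelength_nm)
  expect_equal(s2$intensity_au, s$intensity_au)

  writeLines(c("300 0.0", "abc 1.0", "400 0.1"), f)
  expect_error(read_spectrum(f, "emission"), "line 2")
  writeLines("# only a comment", f)
  expect_error(read_spectrum(f, "emission"), "no data")
  writeLines(c("300 0", "300 1", "400 0", "410 0"), f)
  expect_error(read_spectrum(f, "emission"), "duplicated")
})

test_that("write_spectrum round-trips through read_spectrum", {
  f <- withr::local_tempfile(fileext = ".txt")
  s <- gen_emission_spectrum(config = NULL)
  write_spectrum(s, f)
  s2 <- read_spectrum(f, "emission")
  expect_equal(s2$wavelength_nm, s$wavelength_nm, tolerance = 1e-6)
  expect_equal(s2$intensity_au, s$intensity_au, tolerance = 1e-6)
})

test_that("extract_features recovers analytic band parameters", {
  # Gaussian: FWHH = 2 sigma sqrt(2 ln 2); sigma = 23.35 gives 54.99 nm
  sigma <- 23.35
  s <- gaussian_spectrum(346, sigma, seq(200, 500, 0.5))
  ft <- extract_features(s)
  expect_equal(ft$lambda_max_nm, 346, tolerance = 1e-3)
  expect_equal(ft$fwhh_nm, 2 * sigma * sqrt(2 * log(2)), tolerance = 0.05)

  # symmetric triangle peaking at 350 with half-max width 40
  grid <- seq(300, 400, 0.5)
  tri <- emission_spectrum(grid, pmax(0, 1 - abs(grid - 350) / 40))
  ft2 <- extract_features(tri)
  expect_equal(ft2$lambda_max_nm, 350, tolerance = 1e-9)
  expect_equal(ft2$fwhh_nm, 40, tolerance = 1e-9)
})

test_that("extract_features errors on truncated or crossing-free bands", {
  grid <- seq(300, 360, 0.5)  # maximum at the red boundary
  ramp <- emission_spectrum(grid, seq_along(grid))
  expect_error(extract_features(ramp), "boundary")
  # peak present but signal never falls to half maximum on the red side
  s <- emission_spectrum(seq(300, 400, 1),
                         0.6 + 0.4 * exp(-(seq(300, 400, 1) - 350)^2 / 200))
  expect_error(extract_features(s), "crossing")
})

test_that("features are invariant to intensity scaling and refine with the grid", {
  s1 <- gaussian_spectrum(346, 23.35, seq(250, 450, 0.5))
  s2 <- gaussian_spectrum(346, 23.35, seq(250, 450, 0.5), scale = 1e4)
  f1 <- extract_features(s1); f2 <- extract_features(s2)
  expect_equal(f1$lambda_max_nm, f2$lambda_max_nm, tolerance = 1e-12)
  expect_equal(f1$fwhh_nm, f2$fwhh_nm, tolerance = 1e-12)
  # error against the closed form shrinks as the grid is refined
  fw_true <- 2 * 23.35 * sqrt(2 * log(2))
  errs <- vapply(c(4, 2, 1, 0.5), function(h) {
    abs(extract_features(gaussian_spectrum(346, 23.35,
                                           seq(250, 450, h)))$fwhh_nm -
          fw_true)
  }, numeric(1))
  expect_lt(errs[length(errs)], errs[1])
  expect_lt(errs[length(errs)], 0.01)
})

test_that("default synthetic band reproduces the native Trp emission features", {
  ft <- extract_features(gen_emission_spectrum(config = NULL))
  expect_lt(abs(ft$lambda_max_nm - 346), 1)
  expect_lt(abs(ft$fwhh_nm - 55), 2)
})

test_that("inner-filter correction is exact, monotone and identity at zero", {
  expect_equal(inner_filter_correct(100, 0, 0), 100)
  expect_equal(inner_filter_correct(100, 0.1, 0.1), 100 * 10^0.1,
               tolerance = 1e-12)
  # optically thin regime: A_ex < 0.1 means at most a ~12.2 percent effect
  expect_lt(inner_filter_correct(1, 0.1, 0), 1.123)
  A <- seq(0, 0.5, 0.05)
  expect_true(all(diff(inner_filter_correct(100, A, 0)) > 0))
  expect_true(all(diff(inner_filter_correct(100, 0, A)) > 0))
  expect_error(inner_filter_correct(100, -0.1, 0), "non-negative")
})

test_that("baseline subtraction is pointwise and validates grids", {
  s <- gaussian_spectrum(346, 20, seq(300, 400, 1))
  expect_equal(suppressWarnings(subtract_baseline(s, s))$intensity_au,
               rep(0, length(s$wavelength_nm)))
  zero <- emission_spectrum(seq(290, 410, 1),
                            rep(0, length(seq(290, 410, 1))))
  expect_equal(subtract_baseline(s, zero)$intensity_au, s$intensity_au)
  # band + constant offset minus constant blank = pure band
  grid <- seq(300, 400, 1)
  band <- exp(-(grid - 346)^2 / 800)
  withoff <- emission_spectrum(grid, band + 5)
  blank <- emission_spectrum(grid, rep(5, length(grid)))
  expect_equal(subtract_baseline(withoff, blank)$intensity_au, band,
               tolerance = 1e-12)
  far <- emission_spectrum(seq(500, 600, 1), rep(1, 101))
  expect_error(subtract_baseline(s, far), "cover")
})

test_that("trp decomposition solves the nested additive system", {
  # three homologues with 1, 2 and 3 Trp residues; totals are row sums of
  # the per-residue efficiencies
  eff <- trp_decomposition(
    c(pOBP = 1, `GCC-bOBP` = 3.15, bOBP = 5.03),
    list(pOBP = "W17", `GCC-bOBP` = c("W17", "W133"),
         bOBP = c("W17", "W133", "W64")))
  expect_equal(eff[["W17"]], 1, tolerance = 1e-9)
  expect_equal(eff[["W133"]], 2.15, tolerance = 1e-9)
  expect_equal(eff[["W64"]], 1.88, tolerance = 1e-9)

  # successive differences on a 1, 2, 3 chain
  eff2 <- trp_decomposition(c(a = 1, b = 2, c = 3),
                            list(a = "x", b = c("x", "y"),
                                 c = c("x", "y", "z")))
  expect_equal(unname(eff2), c(1, 1, 1))

  # identical singleton sets: shared efficiency 1
  eff3 <- trp_decomposition(c(a = 1, b = 1, c = 1),
                            list(a = "w", b = "w", c = "w"))
  expect_equal(unname(eff3), 1)

  expect_error(
    trp_decomposition(c(a = 1, b = 2),
                      list(a = c("x", "y"), b = c("y", "z"))),
    "nested")
  expect_warning(
    trp_decomposition(c(a = 2, b = 1),
                      list(a = "x", b = c("x", "y"))),
    "negative")
})

test_that("trp decomposition re-summation reproduces the input totals", {
  totals <- c(p1 = 0.7, p2 = 2.9, p3 = 3.4)
  sets <- list(p1 = "A", p2 = c("A", "B"), p3 = c("A", "B", "C"))
  eff <- trp_decomposition(totals, sets)
  resum <- vapply(sets, function(s) sum(eff[s]), numeric(1))
  expect_equal(unname(resum), unname(totals), tolerance = 1e-12)
})
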