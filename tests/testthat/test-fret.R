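test_that("intensity- and lifetime-based efficiencies follow the ratio forms", {
  expect_equal(efficiency_from_intensity(100, 100), 0)
  expect_equal(efficiency_from_intensity(100, 0), 1)
  expect_equal(efficiency_from_intensity(100, 40), 0.6)
  expect_error(efficiency_from_intensity(100, 120), "enhancement")

  expect_equal(efficiency_from_lifetime(6.85, 6.85), 0)
  expect_equal(efficiency_from_lifetime(3.425, 6.85), 0.5)
  # donor quenched from a 6.85 ns average to 2.8 ns: E close to 0.6
  expect_equal(efficiency_from_lifetime(2.8, 6.85), 1 - 2.8 / 6.85,
               tolerance = 1e-12)
  expect_equal(round(efficiency_from_lifetime(2.8, 6.85), 1), 0.6)
  expect_error(efficiency_from_lifetime(7, 6.85), "exceeds")
})

test_that("overlap integral has the delta-donor limit and linearity", {
  flat_eps <- absorbance_spectrum(seq(250, 550, 1), rep(2e4, 301))
  # narrow donor at 400 nm: J tends to eps * lambda0^4
  Js <- vapply(c(2, 1, 0.5, 0.25), function(sig) {
    overlap_integral(gaussian_spectrum(400, sig, seq(380, 420, 0.05)),
                     flat_eps)
  }, numeric(1))
  expect_equal(Js[4], 2e4 * 400^4, tolerance = 1e-4)
  expect_true(all(abs(Js - 2e4 * 400^4) / (2e4 * 400^4) < 0.01))

  donor <- gaussian_spectrum(346, 23, seq(250, 450, 0.5))
  acc <- absorbance_spectrum(seq(300, 450, 1),
                             1.5e4 * exp(-(seq(300, 450, 1) - 380)^2 / 900))
  J1 <- overlap_integral(donor, acc)
  acc2 <- absorbance_spectrum(acc$wavelength_nm, 2 * acc$epsilon_M_cm)
  expect_equal(overlap_integral(donor, acc2), 2 * J1, tolerance = 1e-12)
  donor2 <- emission_spectrum(donor$wavelength_nm, 7 * donor$intensity_au)
  expect_equal(overlap_integral(donor2, acc), J1, tolerance = 1e-12)

  far <- absorbance_spectrum(seq(600, 700, 1), rep(1e4, 101))
  expect_warning(J0 <- overlap_integral(donor, far), "overlap")
  expect_equal(J0, 0)
})

test_that("overlap integral converges under grid refinement", {
  acc_fun <- function(l) 2e4 * exp(-(l - 380)^2 / (2 * 25^2))
  J_at <- function(h) {
    overlap_integral(gaussian_spectrum(346, 23, seq(250, 480, h)),
                     absorbance_spectrum(seq(250, 480, h),
                                         acc_fun(seq(250, 480, h))))
  }
  errs <- abs(c(J_at(4), J_at(2), J_at(1)) - J_at(0.25))
  expect_lt(errs[3], errs[1])
  expect_lt(errs[3] / J_at(0.25), 1e-4)
})

test_that("forster_radius obeys the sixth-root law and inverts exactly", {
  kappa2 <- 2 / 3; phi <- 0.1; n <- 1.33
  # choose J so that R0 = 50 A, then re-evaluate forward
  J50 <- (50 / 0.2108)^6 * n^4 / (kappa2 * phi)
  expect_equal(forster_radius(J50, kappa2, phi, n), 50, tolerance = 1e-10)
  expect_equal(forster_radius(2^6 * J50, kappa2, phi, n), 100,
               tolerance = 1e-10)
  expect_lt(forster_radius(J50, kappa2, 1e-18, n), 0.1)
  expect_error(forster_radius(-1, kappa2, phi, n), "positive")
})

test_that("distance_from_E is the standard Forster inversion", {
  expect_equal(distance_from_E(0.5, 50), 50)
  # E = 0.6 with R0 = 50 A gives 46.7 A (not larger than R0)
  expect_equal(distance_from_E(0.6, 50), 50 * (0.4 / 0.6)^(1 / 6),
               tolerance = 1e-12)
  expect_equal(distance_from_E(0.6, 50), 46.73, tolerance = 1e-3)
  E <- seq(0.05, 0.95, 0.05)
  expect_true(all(diff(distance_from_E(E, 50)) < 0))
  expect_error(distance_from_E(1, 50), "inside")
  expect_error(distance_from_E(0, 50), "inside")
})

test_that("distance and efficiency round-trip to 1e-12", {
  E <- seq(0.01, 0.99, 0.001)
  R <- distance_from_E(E, 50)
  expect_equal(efficiency_from_distance(R, 50), E, tolerance = 1e-12)
})

test_that("kappa2_from_structure inverts the Forster chain", {
  # constructed so that kappa2 = 2/3 exactly
  n <- 1.33; phi <- 0.1
  J <- (50 / 0.2108)^6 * n^4 / ((2 / 3) * phi)
  E <- efficiency_from_distance(42, 50)
  k2 <- kappa2_from_structure(E, 42, J, phi, n)
  expect_equal(as.numeric(k2), 2 / 3, tolerance = 1e-10)

  # crystal distance far below the free-rotation expectation: kappa2 tiny
  k2_restricted <- kappa2_from_structure(0.6, 12, J, phi, n)
  expect_lt(as.numeric(k2_restricted), 0.01)
  expect_equal(attr(k2_restricted, "flag"), "restricted_rotation")
  # halving the quantum yield doubles kappa2
  expect_equal(as.numeric(kappa2_from_structure(0.6, 12, J, phi / 2, n)),
               2 * as.numeric(k2_restricted), tolerance = 1e-12)
})

test_that("forster_radius and kappa2_from_structure are mutually inverse", {
  set.seed(99)
  for (i in 1:1000) {
    phi <- runif(1, 0.02, 0.9)
    n <- runif(1, 1.3, 1.5)
    J <- 10^runif(1, 12, 16)
    k2_true <- runif(1, 0.05, 4)
    R0 <- forster_radius(J, k2_true, phi, n)
    E <- runif(1, 0.05, 0.95)
    R <- distance_from_E(E, R0)
    k2_back <- kappa2_from_structure(E, R, J, phi, n)
    expect_equal(as.numeric(k2_back), k2_true, tolerance = 1e-8)
  }
})

test_that("comparative quantum yield scales with integral and absorbance", {
  s <- gaussian_spectrum(346, 23, seq(250, 450, 0.5))
  expect_equal(comparative_quantum_yield(s, 0.05, s, 0.05, 0.14), 0.14)
  half <- emission_spectrum(s$wavelength_nm, s$intensity_au / 2)
  expect_equal(comparative_quantum_yield(half, 0.05, s, 0.05, 0.14), 0.07)
  # protein donor vs Trp-in-water reference: integral ratio 5/7 at equal
  # absorbance takes the 0.14 reference yield to 0.1
  samp <- gen_emission_spectrum(total_au = 5, config = NULL)
  ref <- gen_emission_spectrum(lambda_max_nm = 352, fwhh_nm = 61,
                               total_au = 7, config = NULL)
  expect_equal(comparative_quantum_yield(samp, 0.05, ref, 0.05, 0.14), 0.1,
               tolerance = 1e-6)
  expect_warning(comparative_quantum_yield(s, 0.5, s, 0.05, 0.14), "thin")
  expect_error(comparative_quantum_yield(s, 0.05, s, 0, 0.14), "positive")
})

test_that("fret_result validates its bundle", {
  r <- fret_result(E = 0.6, R0_A = 50, R_A = 46.7, kappa2 = 2 / 3,
                   phi_D = 0.1)
  expect_s3_class(r, "fret_result")
  expect_error(fret_result(E = 1.2), "0, 1")
  expect_error(fret_result(E = 0.5, kappa2 = 5), "kappa2")
  expect_error(fret_result(E = 0.5, phi_D = 0), "phi_D")
})
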