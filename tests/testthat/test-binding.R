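test_that("bound_complex matches hand-derived quadratic values", {
  expect_equal(bound_complex(5, 0, 5), 0)
  # stoichiometric limit: saturating ligand, vanishing Kd
  expect_equal(bound_complex(5, 50, 1e-9), 5, tolerance = 1e-6)
  expect_equal(bound_complex(5, 5, 5), (15 - sqrt(125)) / 2,
               tolerance = 1e-12)
  expect_equal(bound_complex(5, 5, 5), 1.9098, tolerance = 1e-4)
  # 90.1 percent saturation at 50 uM total ligand, P0 = Kd = 5 uM
  expect_equal(bound_complex(5, 50, 5), 4.505, tolerance = 1e-3)
  expect_error(bound_complex(-1, 5, 5), "non-negative")
  expect_error(bound_complex(5, 5, 0), "positive")
})

test_that("bound_complex agrees with a bisection oracle to 1e-10", {
  set.seed(42)
  for (i in 1:1000) {
    P0 <- runif(1, 0.1, 100)
    L0 <- runif(1, 0.01, 200)
    Kd <- 10^runif(1, -2, 2)
    expect_equal(bound_complex(P0, L0, Kd), bisect_bound(P0, L0, Kd),
                 tolerance = 1e-10)
  }
})

test_that("bound_complex is monotone and has the hyperbolic dilute limit", {
  L0 <- seq(0, 100, 1)
  expect_true(all(diff(bound_complex(5, L0, 5)) >= 0))
  P0 <- seq(0.1, 50, 0.5)
  expect_true(all(diff(bound_complex(P0, 20, 5)) >= 0))
  Kd <- seq(0.1, 50, 0.5)
  expect_true(all(diff(bound_complex(5, 20, Kd)) <= 0))
  # P0 <= Kd/100: bound fraction approaches L0/(Kd + L0) within 1 percent
  Kd <- 10; P0 <- Kd / 100
  L0 <- seq(0.5, 100, 0.5)
  fb <- bound_complex(P0, L0, Kd) / P0
  hyp <- L0 / (Kd + L0)
  expect_true(all(abs(fb - hyp) / hyp < 0.01))
})

test_that("model_signal has the correct channel limits", {
  expect_equal(model_signal(0, 5, 5, "donor_quench", F_ref = 100,
                            E_app = 0.6), 100)
  # acceptor saturation
  expect_equal(model_signal(5000, 5, 1e-9, "acceptor_enhance", F_ref = 0,
                            F_inf = 80), 80, tolerance = 1e-6)
  # 60 percent maximal quench at full saturation leaves 40 percent signal
  expect_equal(model_signal(1e6, 5, 1e-9, "donor_quench", F_ref = 100,
                            E_app = 0.6), 40, tolerance = 1e-4)
})

test_that("fit_binding round-trips noiseless data and rescales cleanly", {
  for (ch in c("direct_ligand", "donor_quench", "acceptor_enhance")) {
    s <- gen_titration(Kd_uM = 5, P0_uM = 5, channel = ch, config = NULL)
    f <- fit_binding(s)
    expect_equal(f$Kd_uM, 5, tolerance = 1e-6)
  }
  # uniform signal rescaling leaves Kd unchanged, scales amplitudes
  s <- gen_titration(Kd_uM = 5, channel = "acceptor_enhance", config = NULL)
  s2 <- titration_series(s$L0_uM, s$signal_au * 1000, s$P0_uM, s$channel)
  f1 <- fit_binding(s); f2 <- fit_binding(s2)
  expect_equal(f2$Kd_uM, f1$Kd_uM, tolerance = 1e-6)
  expect_equal(f2$F_inf_au, 1000 * f1$F_inf_au, tolerance = 1e-4)
})

test_that("hyperbola model is available and matches depletion when P0 << Kd", {
  s <- gen_titration(Kd_uM = 50, P0_uM = 0.05, channel = "direct_ligand",
                     L0_uM = seq(0, 500, 50), config = NULL)
  fh <- fit_binding(s, model = "hyperbola")
  expect_equal(fh$Kd_uM, 50, tolerance = 0.01)
})

test_that("constant signal is rejected as non-identifiable", {
  s <- titration_series(seq(0, 50, 5), rep(100, 11), 5, "donor_quench")
  expect_error(fit_binding(s), "non-identifiable")
})

test_that("joint donor+acceptor fit shares Kd sensibly", {
  dn <- gen_titration(Kd_uM = 4.8, channel = "donor_quench", config = NULL)
  ac <- gen_titration(Kd_uM = 4.8, channel = "acceptor_enhance",
                      config = NULL)
  jf <- fit_binding_joint(dn, ac)
  expect_equal(jf$Kd_uM, 4.8, tolerance = 1e-6)
  # channels simulated with different true Kd: shared fit lands between
  dn2 <- gen_titration(Kd_uM = 5.0, channel = "donor_quench", config = NULL)
  ac2 <- gen_titration(Kd_uM = 4.6, channel = "acceptor_enhance",
                       config = NULL)
  jf2 <- fit_binding_joint(dn2, ac2)
  expect_gt(jf2$Kd_uM, 4.6)
  expect_lt(jf2$Kd_uM, 5.0)
  # joint and per-channel estimates agree within joint standard error
  cfg <- generator_config(11)
  dn3 <- gen_titration(Kd_uM = 4.8, channel = "donor_quench", config = cfg)
  ac3 <- gen_titration(Kd_uM = 4.8, channel = "acceptor_enhance",
                       config = generator_config(12))
  jf3 <- fit_binding_joint(dn3, ac3)
  for (f in jf3$independent)
    expect_lt(abs(f$Kd_uM - jf3$Kd_uM),
              3 * sqrt(f$se[["Kd_uM"]]^2 + jf3$se[["Kd_uM"]]^2))
})

test_that("kd_vs_denaturant tabulates conditions and flags weak amplitudes", {
  cfgs <- lapply(1:4, generator_config)
  amps <- c(100, 80, 60, 35)
  conds <- c(0, 1, 2, 2.5)
  series <- Map(function(a, cond, cfg)
    gen_titration(Kd_uM = 5, channel = "acceptor_enhance", F_inf = a,
                  condition = cond, config = cfg),
    amps, conds, cfgs)
  tab <- kd_vs_denaturant(series)
  expect_equal(nrow(tab), 4)
  expect_false(any(tab$unreliable))
  # amplitudes decreasing with condition: monotone F_inf column
  expect_true(all(diff(tab$F_inf_au) < 0))
  expect_true(all(abs(tab$Kd_uM - 5) < 1))

  # a denatured condition (no saturable amplitude) is flagged, not fatal
  flat <- titration_series(seq(0, 50, 5),
                           100 + seq(0, 50, 5) * 0,
                           5, "acceptor_enhance", condition = 4)
  tab2 <- kd_vs_denaturant(c(series, list(flat)))
  expect_true(tab2$unreliable[5])
  expect_false(any(tab2$unreliable[1:4]))
})
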