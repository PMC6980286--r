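test_that("Parker AIF is zero pre-bolus, obeys the plasma conversion, and matches a fine-grid oracle", {
  g <- default_grid()
  aif <- parker_aif(g, bolus_arrival = 10, hct = 0.4)
  expect_lt(abs(aif$cb[1]), 1e-6)            # t = 0 < arrival
  expect_lt(max(abs(aif$cb_fine[g$t_fine < 10])), 1e-6)
  expect_equal(aif$cp, aif$cb / 0.6)
  # peak location/height against direct closed-form evaluation on a 10x
  # finer grid than the 0.1 s sampling used here
  t_coarse <- seq(0, 60, by = 0.1)
  gp <- time_grid(n_frames = length(t_coarse), dt = 0.1)
  ap <- parker_aif(gp, bolus_arrival = 0, hct = 0.4)
  t_fine <- seq(0, 60, by = 0.01)
  cb_fine <- oracle_parker(t_fine)
  expect_lt(abs(max(ap$cb) - max(cb_fine)) / max(cb_fine), 0.005)
  expect_lt(abs(t_coarse[which.max(ap$cb)] - t_fine[which.max(cb_fine)]), 0.1)
  expect_error(parker_aif(g, hct = 1), "hct")
  expect_error(parker_aif(g, bolus_arrival = 1e4), "scan window")
})

test_that("Patlak forward model: degenerate cases, boxcar closed form, linearity", {
  g <- default_grid()
  aif <- default_aif()
  expect_equal(patlak_forward(tk_params(0, 0), aif), rep(0, g$n_frames))
  expect_equal(patlak_forward(tk_params(0, 0.1), aif), 0.1 * aif$cp)
  # boxcar Cp = 1 mM: C(t) = ktrans*t/60 + vp
  bx <- boxcar_aif()
  C <- patlak_forward(tk_params(0.1, 0.05), bx)
  expect_equal(C, 0.1 * g$t / 60 + 0.05, tolerance = 1e-12)
  # linearity in (ktrans, vp)
  p1 <- patlak_forward(tk_params(0.2, 0.1), aif)
  p2 <- patlak_forward(tk_params(0.05, 0.3), aif)
  mix <- patlak_forward(tk_params(2 * 0.2 + 0.05, 2 * 0.1 + 0.3), aif)
  expect_equal(mix, 2 * p1 + p2, tolerance = 1e-12)
  expect_error(tk_params(-0.1, 0.1), "ktrans")
})

test_that("ETK forward model: limits, boxcar closed form, Patlak convergence", {
  g <- default_grid()
  aif <- default_aif()
  expect_equal(etk_forward(tk_params(0, 0.3, 0.6), aif), 0.3 * aif$cp)
  expect_equal(etk_forward(tk_params(0.2, 0.3, 0), aif), 0.3 * aif$cp)
  # boxcar closed form C(t) = vp + ve (1 - exp(-ktrans t / (60 ve)))
  bx <- boxcar_aif()
  kt <- 0.3; vp <- 0.05; ve <- 0.4
  C <- etk_forward(tk_params(kt, vp, ve), bx)
  expect_equal(C, vp + ve * (1 - exp(-kt * g$t / (60 * ve))), tolerance = 1e-3)
  # approaches Patlak as backflux vanishes (ve -> 1 at small ktrans)
  pat <- patlak_forward(tk_params(0.05, 0.02), aif)
  d99 <- max(abs(etk_forward(tk_params(0.05, 0.02, 0.99), aif) - pat))
  d50 <- max(abs(etk_forward(tk_params(0.05, 0.02, 0.50), aif) - pat))
  expect_lt(d99, d50)
  # non-negativity over a parameter sweep
  for (kt in c(0, 0.1, 0.8)) for (ve in c(0.01, 0.5, 1)) {
    expect_gte(min(etk_forward(tk_params(kt, 0.05, ve), aif)), 0)
  }
})

test_that("Patlak fit is an exact inverse of the forward model and behaves under noise", {
  aif <- default_aif()
  f <- patlak_fit(patlak_forward(tk_params(0.12, 0.04), aif), aif)
  expect_equal(f$params$ktrans, 0.12, tolerance = 1e-10)
  expect_equal(f$params$vp, 0.04, tolerance = 1e-10)
  # round trip across a parameter sweep
  for (kt in c(0, 0.01, 0.4, 0.8)) for (vp in c(0, 0.3, 0.6)) {
    fr <- patlak_fit(patlak_forward(tk_params(kt, vp), aif), aif)
    expect_equal(fr$params$ktrans, kt, tolerance = 1e-10)
    expect_equal(fr$params$vp, vp, tolerance = 1e-10)
  }
  z <- patlak_fit(rep(0, 50), aif)
  expect_equal(z$params$ktrans, 0)
  expect_equal(z$residual_norm, 0)
  # 500 noisy replicates: mean estimate within 3 standard errors of truth
  clean <- patlak_forward(tk_params(0.1, 0.05), aif)
  reps <- simulate_noisy_profiles(clean, sigma = 0.005, n_realizations = 500L,
                                  seed = 7L)
  est <- apply(reps[1, , ], 2, function(y) {
    f <- patlak_fit(y, aif); c(f$params$ktrans, f$params$vp)
  })
  for (i in 1:2) {
    se <- sd(est[i, ]) / sqrt(500)
    expect_lt(abs(mean(est[i, ]) - c(0.1, 0.05)[i]), 3 * se)
  }
  # degenerate AIF
  flat <- aif_curve(default_grid(), cp = rep(0, 50))
  expect_error(patlak_fit(clean, flat), "singular")
})

test_that("ETK fit recovers noiseless parameters and flags unidentifiable ve", {
  aif <- default_aif()
  f <- etk_fit(etk_forward(tk_params(0.2, 0.05, 0.4), aif), aif)
  expect_lt(abs(f$params$ktrans - 0.2) / 0.2, 1e-3)
  expect_lt(abs(f$params$vp - 0.05) / 0.05, 1e-3)
  expect_lt(abs(f$params$ve - 0.4) / 0.4, 1e-3)
  expect_true(f$converged)
  # sweep over the stated recoverable region
  for (kt in c(0.01, 0.3)) for (vp in c(0.01, 0.4)) for (ve in c(0.1, 0.9)) {
    fr <- etk_fit(etk_forward(tk_params(kt, vp, ve), aif), aif)
    expect_lt(abs(fr$params$ktrans - kt) / kt, 1e-3)
    expect_lt(abs(fr$params$vp - vp) / vp, 1e-3)
    expect_lt(abs(fr$params$ve - ve) / ve, 1e-3)
  }
  # ktrans = 0: vp recovered, ve flagged
  f0 <- etk_fit(0.3 * aif$cp, aif)
  expect_lt(f0$params$ktrans, 1e-4)
  expect_lt(abs(f0$params$vp - 0.3), 1e-3)
  expect_true("ve_unidentifiable" %in% f0$identifiability_flags)
})

test_that("ETK Monte-Carlo estimates are finite and reproducible under a fixed seed", {
  aif <- default_aif()
  m1 <- mc_bias_uncertainty("etk", c(0.1, 0.4), c(0.05, 0.3), aif,
                            n_reps = 20L, seed = 3L)
  m2 <- mc_bias_uncertainty("etk", c(0.1, 0.4), c(0.05, 0.3), aif,
                            n_reps = 20L, seed = 3L)
  expect_identical(m1$est_ktrans, m2$est_ktrans)
  expect_true(all(is.finite(m1$bias_ktrans)))
  expect_true(all(is.finite(m1$unc_vp)))
})
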