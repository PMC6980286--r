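# Small-scale reconstruction tests; full-scale behavior is exercised by the
# acceptance suite.

small_setup <- function(model = "patlak", shape = c(24L, 24L), n_frames = 20L,
                        R = 1, n_coils = 4L, snr = Inf, mask_seed = 2L) {
  g <- tk_cache(paste0("grid", n_frames), time_grid(n_frames, 5))
  aif <- tk_cache(paste0("aif", n_frames), parker_aif(g))
  dro <- build_dro(shape, aif, seed = 4, model = model)
  coils <- gaussian_coil_maps(shape, n_coils)
  mask <- gocart_mask(shape, n_frames, R, seed = mask_seed)
  kt <- apply_forward(dro$conc, dro$tissue, coils, mask)
  if (is.finite(snr)) kt <- add_noise(kt, snr, seed = 11L)
  list(g = g, aif = aif, dro = dro, coils = coils, kt = kt)
}

test_that("Gaussian k-space filter: DC weight, monotonicity, coarse limit", {
  W <- tkdce:::gaussian_filter_weights(c(32, 32), 50)
  oy <- floor(32 / 2) + 1
  expect_equal(W[oy, oy], 1)
  # monotone non-increasing along rays from the origin
  expect_true(all(diff(W[oy, oy:32]) <= 0))
  expect_true(all(diff(W[oy:32, oy]) <= 0))
  # at 100% every weight >= exp(-1/2), applied as written
  W100 <- tkdce:::gaussian_filter_weights(c(32, 32), 100)
  expect_true(all(W100 >= exp(-0.5) - 1e-12))
  K <- matrix(complex(real = rnorm(32 * 32), imaginary = rnorm(32 * 32)), 32, 32)
  expect_equal(gaussian_kspace_filter(K, 100), K * W100)
  expect_error(gaussian_kspace_filter(K, 0), "k_sigma_pct")
  # 0.1% width acts like a spatial mean
  img <- matrix(runif(32 * 32), 32, 32)
  filt <- Re(tkdce:::ifft2c(gaussian_kspace_filter(tkdce:::fft2c(img), 0.1)))
  expect_lt(max(abs(filt - mean(img))) / mean(img), 0.01)
})

test_that("multiscale schedule levels increase from 0.1 to 100 percent", {
  s <- multiscale_schedule()
  expect_equal(s$k_sigma_levels[1], 0.1)
  expect_equal(s$k_sigma_levels[s$n_levels], 100)
  expect_true(all(diff(s$k_sigma_levels) > 0))
})

# Patlak dictionary on the short 20-frame grid used by the small recon tests
patlak_dict_short <- function() {
  tk_cache("patlak_dict20", {
    lib <- build_library("patlak", aif = tk_cache("aif20", parker_aif(tk_cache("grid20", time_grid(20, 5)))))
    ksvd_learn(lib, r = 20L, q = 2L, n_iters = 5L, seed = 1L)$dictionary
  })
}

test_that("dictionary recon at R = 1 reproduces a Patlak phantom to machine level", {
  st <- small_setup("patlak")
  dict <- patlak_dict_short()
  cfg <- recon_config(dict, q = 2)
  expect_error(recon_config(dict, q = 200), "q")
  rec <- reconstruct_dictionary(st$kt, st$dro$tissue, st$coils, cfg)
  expect_lt(max(abs(rec$C - st$dro$conc)), 1e-6)
  # constraint invariant: C = U V exactly, rows at most q-sparse
  expect_equal(rec$C, as.matrix(rec$U %*% dict$V))
  expect_true(all(Matrix::rowSums(rec$U != 0) <= 2))
  # data-consistency cost collapses relative to the initial iterate
  expect_lt(tail(rec$cost_trace, 1), 1e-6 * max(rec$cost_trace[1], 1e-300) + 1e-12)
})

test_that("hard data consistency holds at the final scale level", {
  st <- small_setup("patlak", R = 4)
  dict <- patlak_dict_short()
  rec <- reconstruct_dictionary(st$kt, st$dro$tissue, st$coils,
                                recon_config(dict, q = 2))
  # one data-consistency update of the final C at full scale: sampled
  # entries must carry the measured data exactly
  S <- conc_to_signal(rec$C, st$dro$tissue)
  d <- dim(st$kt$b)
  for (c in seq_len(d[4])) {
    for (t in c(1L, d[3])) {
      K <- tkdce:::fft2c(matrix(S[, t], d[1], d[2]) * st$coils$maps[, , c])
      mt <- st$kt$mask$mask[, , t]
      K[mt] <- st$kt$b[, , t, c][mt]          # the final-level update
      expect_equal(K[mt], st$kt$b[, , t, c][mt])
    }
  }
  expect_true(length(rec$level_change_iters) >= 1)
})

test_that("tFD with lambda = 0 at R = 1 matches the least-squares reconstruction", {
  st <- small_setup("patlak")
  r0 <- reconstruct_tfd(st$kt, st$dro$tissue, st$coils,
                        tfd_config(0, max_iters = 30))
  C_zf <- tkdce:::init_concentration(st$kt, st$dro$tissue, st$coils)
  expect_lt(max(abs(r0$C - C_zf)), 1e-6)
  expect_true(r0$converged)
})

test_that("large tFD weights drive the series toward temporal constancy", {
  st <- small_setup("patlak", R = 4)
  sc <- max(abs(st$kt$b))
  r0 <- reconstruct_tfd(st$kt, st$dro$tissue, st$coils,
                        tfd_config(0, max_iters = 10))
  rL <- reconstruct_tfd(st$kt, st$dro$tissue, st$coils,
                        tfd_config(1e6 * sc, rho = 1e3 * sc, max_iters = 60))
  v0 <- mean(apply(Re(r0$S), 1, var))
  vL <- mean(apply(Re(rL$S), 1, var))
  expect_lt(vL, 0.01 * v0)
})

test_that("tFD ADMM reaches its stopping tolerance with decreasing primal residual", {
  st <- small_setup("patlak", shape = c(12L, 12L), n_frames = 8L, R = 4,
                    n_coils = 2L, snr = 30)
  sc <- max(abs(st$kt$b))
  r <- reconstruct_tfd(st$kt, st$dro$tissue, st$coils,
                       tfd_config(0.05 * sc, tol = 1e-7, max_iters = 6000))
  expect_true(r$converged)
  expect_lt(tail(r$change_trace, 1), 1e-7)
  expect_lt(tail(r$primal_trace, 1), r$primal_trace[1])
})

test_that("lambda tuning returns the grid argmin of the ROI nRMSE", {
  st <- small_setup("patlak", R = 4, snr = 30)
  roi <- as.vector(st$dro$roi_masks$tumor_rim | st$dro$roi_masks$tumor_core)
  sc <- max(abs(st$kt$b))
  # single-element grid returns that element
  t1 <- tune_tfd_lambda(st$kt, st$dro$tissue, st$coils, st$dro$conc, roi,
                        0.1 * sc, max_iters = 15)
  expect_equal(t1$lambda, 0.1 * sc)
  grid <- sc * c(1e-3, 3e-2, 3)
  t3 <- tune_tfd_lambda(st$kt, st$dro$tissue, st$coils, st$dro$conc, roi,
                        grid, max_iters = 25)
  expect_equal(t3$nrmse[which(grid == t3$lambda)], min(t3$nrmse))
  expect_error(tune_tfd_lambda(st$kt, st$dro$tissue, st$coils, st$dro$conc,
                               roi, numeric(0)), "empty")
})
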