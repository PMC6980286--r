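test_that("library row counts, ordering, and exact agreement with forward-model calls", {
  aif <- default_aif()
  lib <- patlak_library()
  expect_equal(dim(lib$Z), c(4941L, 50L))
  # spot-check rows against direct forward calls (exact equality)
  set.seed(11)
  for (i in sample(nrow(lib$Z), 20)) {
    p <- lib$params[i, ]
    expect_identical(lib$Z[i, ], patlak_forward(tk_params(p$ktrans, p$vp), aif))
  }
  expect_equal(lib$Z[1, ], rep(0, 50))       # (ktrans, vp) = (0, 0)
  # small ETK grid: count is the product of level counts; ve varies fastest
  sm <- param_grid(ktrans = c(0, 0.1, 0.05), vp = c(0, 0.02, 0.01),
                   ve = c(0.2, 0.6))
  libe <- build_library("etk", sm, aif)
  expect_equal(nrow(libe$Z), 3L * 3L * 2L)
  expect_equal(libe$params$ve[1:2], c(0.2, 0.6))
  expect_equal(libe$params$ktrans[1:6], rep(0, 6))
  for (i in seq_len(nrow(libe$Z))) {
    p <- libe$params[i, ]
    expect_identical(libe$Z[i, ],
                     etk_forward(tk_params(p$ktrans, p$vp, p$ve), aif))
  }
  expect_error(build_library("etk", param_grid(), aif), "ve")
})

test_that("the Patlak library has numerical rank 2", {
  sv <- svd(patlak_library()$Z, nu = 0, nv = 0)$d
  expect_lt(sv[3] / sv[1], 1e-12)
})

test_that("k-SVD captures an exact low-rank library and returns unit-norm atoms", {
  # rows are random positive combinations of 2 fixed orthonormal vectors
  N <- 20L
  b1 <- sin(seq_len(N)); b1 <- b1 / sqrt(sum(b1^2))
  b2 <- cos(seq_len(N)); b2 <- b2 - sum(b2 * b1) * b1; b2 <- b2 / sqrt(sum(b2^2))
  set.seed(5)
  W <- matrix(runif(200, 0.1, 2), 100, 2)
  Z <- W %*% rbind(b1, b2)
  res <- ksvd_learn(Z, r = 10L, q = 2L, n_iters = 5L, seed = 2L)
  expect_equal(rowSums(res$dictionary$V^2), rep(1, 10), tolerance = 1e-12)
  err <- approximation_errors(Z, res$dictionary, q = 2L)
  expect_lt(err$max_err, 1e-18)              # percent of squared norm
  # codes: every row at most q-sparse, and U V reproduces Z
  U <- as.matrix(res$codes$U)
  expect_true(all(rowSums(U != 0) <= 2L))
  expect_lt(max(abs(U %*% res$dictionary$V - Z)), 1e-10)
})

test_that("k-SVD is reproducible for a fixed seed and its objective does not increase", {
  set.seed(9)
  Z <- matrix(rnorm(600), 60, 10) %*% matrix(rnorm(100), 10, 10)
  r1 <- ksvd_learn(Z, r = 8L, q = 2L, n_iters = 8L, seed = 4L)
  r2 <- ksvd_learn(Z, r = 8L, q = 2L, n_iters = 8L, seed = 4L)
  expect_identical(r1$dictionary$V, r2$dictionary$V)
  obj <- r1$dictionary$objective
  expect_true(all(diff(obj) <= 1e-8 * obj[1]))
  r3 <- ksvd_learn(Z, r = 8L, q = 2L, n_iters = 8L, seed = 5L)
  expect_false(identical(r1$dictionary$V, r3$dictionary$V))
  expect_error(ksvd_learn(Z, r = 8L, q = 9L, n_iters = 2L, seed = 1L), "q")
})

test_that("OMP matches exhaustive best-subset least squares on near-orthogonal dictionaries", {
  set.seed(21)
  for (case in 1:200) {
    V <- t(qr.Q(qr(matrix(rnorm(40), 8, 5))))   # 5 orthonormal atoms in R^8
    z <- rnorm(8)
    res <- omp_project(z, V, q = 2L)
    r_omp <- sqrt(sum((z - res$approx)^2))
    expect_equal(r_omp, oracle_best_subset(z, V, 2L), tolerance = 1e-10)
  }
})

test_that("OMP: single-atom signals, zero rows, orthogonal residuals, monotone in q", {
  set.seed(3)
  V <- matrix(rnorm(50), 5, 10)
  V <- V / sqrt(rowSums(V^2))
  res <- omp_project(3.7 * V[4, ], V, q = 2L)
  U <- as.matrix(res$codes$U)
  expect_equal(U[1, 4], 3.7, tolerance = 1e-12)
  expect_equal(sum(U != 0), 1L)
  expect_equal(as.vector(res$approx), 3.7 * V[4, ], tolerance = 1e-12)
  z0 <- omp_project(rep(0, 10), V, q = 2L)
  expect_equal(sum(z0$codes$U != 0), 0L)
  expect_equal(as.vector(z0$approx), rep(0, 10))
  # residual orthogonal to selected atoms; residual non-increasing in q and
  # never worse than the best single atom
  Z <- matrix(rnorm(80), 8, 10)
  prev <- rep(Inf, 8)
  for (q in 1:4) {
    pr <- omp_project(Z, V, q)
    Uq <- as.matrix(pr$codes$U)
    resid <- Z - pr$approx
    for (i in 1:8) {
      sel <- which(Uq[i, ] != 0)
      expect_true(length(sel) <= q)
      if (length(sel)) {
        expect_lt(max(abs(resid[i, , drop = FALSE] %*% t(V[sel, , drop = FALSE]))), 1e-10)
      }
    }
    rn <- sqrt(rowSums(resid^2))
    expect_true(all(rn <= prev + 1e-12))
    prev <- rn
    if (q == 1) {
      best1 <- apply(Z, 1, function(z) {
        min(apply(V, 1, function(v) sqrt(sum((z - sum(z * v) * v)^2))))
      })
      expect_equal(rn, best1, tolerance = 1e-10)
    }
  }
})

test_that("approximation errors: exact representations, zero-row handling, q-monotonicity", {
  set.seed(13)
  V <- t(qr.Q(qr(matrix(rnorm(60), 12, 5))))
  W <- matrix(0, 30, 5)
  W[cbind(1:30, sample(5, 30, TRUE))] <- runif(30, 0.5, 2)
  W[cbind(1:30, sample(5, 30, TRUE))] <- runif(30, 0.5, 2)
  Z <- rbind(W %*% V, 0)                     # last row zero
  err <- approximation_errors(Z, V, q = 2L)
  expect_lt(err$max_err, 1e-24)
  expect_equal(err$n_excluded_zero_rows, 1L)
  expect_true(is.na(err$per_row[31]))
  expect_lte(err$mu_err, err$max_err)
  # increasing q never increases the error statistics
  Zr <- matrix(rnorm(300), 30, 10)
  Vr <- matrix(rnorm(60), 6, 10); Vr <- Vr / sqrt(rowSums(Vr^2))
  errs <- sapply(1:4, function(q) {
    e <- approximation_errors(Zr, Vr, q)
    c(e$mu_err, e$max_err)
  })
  expect_true(all(diff(errs[1, ]) <= 1e-9))
  expect_true(all(diff(errs[2, ]) <= 1e-9))
  expect_error(approximation_errors(matrix(0, 3, 10), Vr, 2L), "zero")
})

test_that("Patlak dictionary at q = 1 leaves large errors but q = 2 is exact", {
  dict <- patlak_dictionary()
  lib <- patlak_library()
  e1 <- approximation_errors(lib, dict, q = 1L)
  e2 <- approximation_errors(lib, dict, q = 2L)
  # single atoms leave a measurable modeling error (brute-force evaluation
  # gives ~0.4% worst case), ~27 orders of magnitude above the q = 2 floor
  expect_gt(e1$max_err, 0.1)
  expect_gt(e1$max_err, 1e20 * e2$max_err)
  expect_lt(e2$max_err, 1e-24)
})
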