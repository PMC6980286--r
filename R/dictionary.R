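# Kinetic-model library generation, k-SVD dictionary learning, and
# orthogonal matching pursuit (OMP) q-sparse projection.
#
# Row ordering convention for libraries: ktrans varies slowest, then vp,
# then ve fastest (Patlak rows: ktrans slowest, vp fastest).

#' Kinetic parameter grid
#'
#' @param ktrans `c(start, stop, step)` in 1/min; default `c(0, 0.8, 0.01)`
#'   (81 levels).
#' @param vp `c(start, stop, step)` as a fraction; default `c(0, 0.60, 0.01)`
#'   (61 levels).
#' @param ve vector of ve levels (fractions), or `NULL` for the Patlak
#'   model. The ETK default is `seq(0.01, 1, 0.01)` (100 levels).
#' @return an object of class `tk_param_grid` with the expanded level
#'   vectors.
#' @export
param_grid <- function(ktrans = c(0, 0.8, 0.01), vp = c(0, 0.60, 0.01),
                       ve = NULL) {
  expand_range <- function(x, name) {
    if (length(x) == 3L) {
      if (x[3] <= 0) stop(sprintf("`%s` step must be > 0", name), call. = FALSE)
      seq(x[1], x[2], by = x[3])
    } else as.numeric(x)
  }
  kt <- expand_range(ktrans, "ktrans")
  vpl <- expand_range(vp, "vp")
  if (length(kt) == 0L || length(vpl) == 0L) stop("empty parameter grid", call. = FALSE)
  structure(list(ktrans = kt, vp = vpl, ve = if (is.null(ve)) NULL else as.numeric(ve)),
            class = "tk_param_grid")
}

#' Default parameter grid for a kinetic model
#'
#' Patlak: 81 ktrans x 61 vp = 4941 combinations; ETK: 81 x 61 x 100 ve
#' levels = 494,100 combinations.
#'
#' @param model `"patlak"` or `"etk"`.
#' @return a [param_grid()].
#' @export
default_param_grid <- function(model = c("patlak", "etk")) {
  model <- match.arg(model)
  if (model == "patlak") param_grid() else param_grid(ve = seq(0.01, 1, by = 0.01))
}

#' Simulate a library of concentration-time profiles
#'
#' Evaluates the chosen kinetic model at every grid combination, producing
#' the `l x N` library matrix `Z`. Rows reproduce the corresponding
#' [patlak_forward()] / [etk_forward()] calls exactly (identical quadrature
#' and arithmetic).
#'
#' @param model `"patlak"` or `"etk"`.
#' @param grid a [param_grid()]; defaults to [default_param_grid()].
#' @param aif a `tk_aif`.
#' @param time a [time_grid()]; defaults to the AIF's grid.
#' @return an object of class `tk_library`: `Z` (l x N, mM), `params`
#'   (data.frame of row parameters), `grid`, `time`, `model`.
#' @export
build_library <- function(model = c("patlak", "etk"),
                          grid = NULL, aif, time = aif$grid) {
  model <- match.arg(model)
  if (is.null(grid)) grid <- default_param_grid(model)
  stopifnot(inherits(grid, "tk_param_grid"), inherits(aif, "tk_aif"))
  if (model == "etk" && is.null(grid$ve)) {
    stop("ETK library requires ve levels in the grid", call. = FALSE)
  }
  kt <- grid$ktrans; vp <- grid$vp
  cp <- aif$cp
  N <- time$n_frames
  intcp <- aif_cum_integral(aif, time)
  if (model == "patlak") {
    ktv <- rep(kt, each = length(vp))
    vpv <- rep(vp, times = length(kt))
    Z <- outer(vpv, cp) + outer(ktv / 60, intcp)
    params <- data.frame(ktrans = ktv, vp = vpv, ve = NA_real_)
  } else {
    ve <- grid$ve
    nve <- length(ve); nvp <- length(vp)
    l <- length(kt) * nvp * nve
    Z <- matrix(0, l, N)
    vp_block <- outer(rep(vp, each = nve), cp)  # (nvp*nve) x N
    for (i in seq_along(kt)) {
      # convolution term for each ve at this ktrans (kep = ktrans/ve)
      Gi <- matrix(0, nve, N)
      if (kt[i] > 0) {
        for (k in seq_len(nve)) {
          # ve = 0 collapses to C = vp * Cp (analytic limit), as in etk_forward
          if (ve[k] > 0) Gi[k, ] <- etk_conv(kt[i] / (60 * ve[k]), aif, time)
        }
      }
      block <- vp_block + kt[i] / 60 * Gi[rep(seq_len(nve), times = nvp), ]
      Z[((i - 1) * nvp * nve + 1):(i * nvp * nve), ] <- block
    }
    params <- data.frame(ktrans = rep(kt, each = nvp * nve),
                         vp = rep(rep(vp, each = nve), times = length(kt)),
                         ve = rep(ve, times = length(kt) * nvp))
  }
  structure(list(Z = Z, params = params, grid = grid, time = time,
                 model = model, aif = aif),
            class = "tk_library")
}

#' @export
print.tk_library <- function(x, ...) {
  cat(sprintf("tk_library (%s): %d profiles x %d frames\n",
              x$model, nrow(x$Z), ncol(x$Z)))
  invisible(x)
}

# ---- batched OMP ---------------------------------------------------------

# Vectorized symmetric k x k least-squares solves (k <= 3) used by the
# batched OMP; falls back to per-row QR when the closed form is
# ill-conditioned. Returns the coefficient matrix (m x k).
solve_gram <- function(G, S, H) {
  m <- nrow(S); k <- ncol(S)
  gs <- function(a, b) G[cbind(S[, a], S[, b])]
  hs <- function(a) H[cbind(seq_len(m), S[, a])]
  if (k == 1L) {
    return(matrix(hs(1) / gs(1, 1), ncol = 1))
  }
  if (k == 2L) {
    g11 <- gs(1, 1); g22 <- gs(2, 2); g12 <- gs(1, 2)
    h1 <- hs(1); h2 <- hs(2)
    det <- g11 * g22 - g12^2
    ok <- det > 1e-13 * g11 * g22
    c1 <- ifelse(ok, (g22 * h1 - g12 * h2) / det, h1 / g11)
    c2 <- ifelse(ok, (g11 * h2 - g12 * h1) / det, 0)
    return(cbind(c1, c2, deparse.level = 0))
  }
  if (k == 3L) {
    g11 <- gs(1, 1); g22 <- gs(2, 2); g33 <- gs(3, 3)
    g12 <- gs(1, 2); g13 <- gs(1, 3); g23 <- gs(2, 3)
    h1 <- hs(1); h2 <- hs(2); h3 <- hs(3)
    A11 <- g22 * g33 - g23^2
    A12 <- g13 * g23 - g12 * g33
    A13 <- g12 * g23 - g13 * g22
    A22 <- g11 * g33 - g13^2
    A23 <- g12 * g13 - g11 * g23
    A33 <- g11 * g22 - g12^2
    det <- g11 * A11 + g12 * A12 + g13 * A13
    scale <- g11 * g22 * g33
    bad <- which(!(det > 1e-12 * pmax(scale, .Machine$double.xmin)))
    c1 <- (A11 * h1 + A12 * h2 + A13 * h3) / det
    c2 <- (A12 * h1 + A22 * h2 + A23 * h3) / det
    c3 <- (A13 * h1 + A23 * h2 + A33 * h3) / det
    out <- cbind(c1, c2, c3, deparse.level = 0)
    for (p in bad) {
      Gp <- G[S[p, ], S[p, ], drop = FALSE]
      out[p, ] <- qr.coef(qr(Gp), c(h1[p], h2[p], h3[p]))
      out[p, is.na(out[p, ])] <- 0
    }
    return(out)
  }
  out <- matrix(0, m, k)
  for (p in seq_len(m)) {
    Gp <- G[S[p, ], S[p, ], drop = FALSE]
    hp <- H[p, S[p, ]]
    cf <- qr.coef(qr(Gp), hp)
    cf[is.na(cf)] <- 0
    out[p, ] <- cf
  }
  out
}

# Batched OMP on one chunk of rows. V is r x N with (near) unit-norm atoms.
# Returns selected-index matrix S (m x q, 0 = unused), coefficient matrix
# (m x q), and the number of atoms actually used per row.
omp_chunk <- function(Z, V, q, G = V %*% t(V)) {
  m <- nrow(Z); r <- nrow(V)
  H <- Z %*% t(V)
  z2 <- rowSums(Z^2)
  S <- matrix(0L, m, q)
  Cf <- matrix(0, m, q)
  nsel <- integer(m)
  active <- z2 > 0
  corr <- H
  for (k in seq_len(q)) {
    if (!any(active)) break
    absC <- abs(corr)
    if (k > 1L) {
      # mask already-selected atoms
      for (kk in seq_len(k - 1L)) {
        sel_prev <- S[, kk]
        has <- sel_prev > 0L
        absC[cbind(which(has), sel_prev[has])] <- -1
      }
    }
    idx <- which(active)
    sel <- max.col(absC[idx, , drop = FALSE], ties.method = "first")
    best <- absC[cbind(idx, sel)]
    # stop rows whose residual has no meaningful correlation left
    keep <- best > 1e-12 * sqrt(pmax(z2[idx], .Machine$double.xmin))
    idx <- idx[keep]; sel <- sel[keep]
    active <- replace(logical(m), idx, TRUE)
    if (length(idx) == 0L) break
    S[cbind(idx, k)] <- sel
    nsel[idx] <- k
    Cf[idx, seq_len(k)] <- solve_gram(G, S[idx, seq_len(k), drop = FALSE],
                                      H[idx, , drop = FALSE])
    # residual correlations: H - U G restricted to active rows
    Usp <- Matrix::sparseMatrix(
      i = rep(idx, k), j = as.vector(S[idx, seq_len(k), drop = FALSE]),
      x = as.vector(Cf[idx, seq_len(k), drop = FALSE]), dims = c(m, r))
    corr[idx, ] <- H[idx, , drop = FALSE] - as.matrix(Usp[idx, , drop = FALSE] %*% G)
    # shortcut residual energy; floor at machine precision
    proj <- rowSums(Cf[idx, seq_len(k), drop = FALSE] *
                      matrix(H[cbind(rep(idx, k),
                                     as.vector(S[idx, seq_len(k), drop = FALSE]))],
                             ncol = k))
    res2 <- pmax(z2[idx] - proj, 0)
    done <- res2 <= 1e-26 * z2[idx]
    active[idx[done]] <- FALSE
  }
  list(S = S, Cf = Cf, nsel = nsel)
}

#' OMP q-sparse projection onto a dictionary
#'
#' Projects each row of `profiles` onto at most `q` atoms of the dictionary
#' chosen greedily by residual correlation (ties broken toward the lowest
#' atom index), with the coefficients re-solved by least squares at every
#' step, so the final residual is orthogonal to the selected atoms. Zero
#' rows receive zero codes.
#'
#' @param profiles numeric matrix (m x N) of profiles.
#' @param dict a `tk_dictionary` (see [ksvd_learn()]) or an atom matrix
#'   (r x N) with unit-norm rows.
#' @param q sparsity bound, `q <= min(r, N)`.
#' @param chunk_size rows processed per block (memory control).
#' @return list with `codes` (a `tk_sparse_codes`: sparse `U` of size m x r
#'   and `q`) and `approx` (m x N matrix `U %*% V`).
#' @export
omp_project <- function(profiles, dict, q, chunk_size = 20000L) {
  V <- if (inherits(dict, "tk_dictionary")) dict$V else dict
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  r <- nrow(V); N <- ncol(V)
  if (ncol(profiles) != N) stop("profile length must match dictionary atoms", call. = FALSE)
  if (q > min(r, N)) stop("`q` must not exceed min(r, N)", call. = FALSE)
  m <- nrow(profiles)
  G <- V %*% t(V)
  ii <- integer(0); jj <- integer(0); xx <- numeric(0)
  approx <- matrix(0, m, N)
  starts <- seq(1L, m, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, m)
    res <- omp_chunk(profiles[s:e, , drop = FALSE], V, q, G)
    sel <- res$S > 0L
    if (any(sel)) {
      rows <- row(res$S)[sel] + (s - 1L)
      ii <- c(ii, rows)
      jj <- c(jj, res$S[sel])
      xx <- c(xx, res$Cf[sel])
      Usp <- Matrix::sparseMatrix(i = row(res$S)[sel], j = res$S[sel],
                                  x = res$Cf[sel], dims = c(e - s + 1L, r))
      approx[s:e, ] <- as.matrix(Usp %*% V)
    }
  }
  U <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(m, r))
  codes <- structure(list(U = U, q = q), class = "tk_sparse_codes")
  list(codes = codes, approx = approx)
}

# ---- k-SVD ---------------------------------------------------------------

#' k-SVD dictionary learning
#'
#' Learns `r` unit-norm temporal basis functions such that every library
#' profile is approximated by a `q`-sparse linear combination, by
#' alternating batched-OMP sparse coding with sequential rank-1 atom/
#' coefficient updates (alternating least-squares form of the per-atom SVD
#' step). Atoms that end up unused or duplicated are replaced by the
#' currently worst-represented profile. Zero library rows are dropped
#' before learning (they are exactly representable by the zero code).
#'
#' @param lib a `tk_library` or a plain profile matrix (l x N).
#' @param r number of atoms (default 100).
#' @param q sparsity level used during learning.
#' @param n_iters number of k-SVD iterations (default 30).
#' @param seed integer seed controlling the initialization (atoms start
#'   from a random sample of distinct non-zero, normalized library rows).
#' @param normalize train on unit-norm profile rows (default `TRUE`). OMP
#'   atom selection is scale-invariant per row, so normalization leaves the
#'   sparse-coding structure unchanged but makes the atom updates weight
#'   every enhancement shape equally -- matching the row-normalized
#'   approximation-error metric used for sparsity selection, instead of
#'   letting high-amplitude profiles dominate.
#' @return list with `dictionary` (class `tk_dictionary`: `V` r x N with
#'   unit-norm rows, `r`, `source_model`, `q_recommended`, `objective`
#'   trace on the training rows) and `codes` (class `tk_sparse_codes`:
#'   sparse `U` of size l x r from a final coding pass on the original
#'   library rows; zero rows get zero codes).
#' @export
ksvd_learn <- function(lib, r = 100L, q, n_iters = 30L, seed = 1L,
                       normalize = TRUE) {
  Z_all <- if (inherits(lib, "tk_library")) lib$Z else as.matrix(lib)
  model <- if (inherits(lib, "tk_library")) lib$model else "custom"
  if (q > r) stop("`q` must not exceed the number of atoms `r`", call. = FALSE)
  nz <- rowSums(Z_all^2) > 0
  Z <- Z_all[nz, , drop = FALSE]
  if (normalize) Z <- Z / sqrt(rowSums(Z^2))
  n <- nrow(Z); N <- ncol(Z)
  if (r >= n) stop("`r` must be smaller than the number of non-zero profiles", call. = FALSE)
  init_idx <- with_seed(seed, sample.int(n, r))
  V <- Z[init_idx, , drop = FALSE]
  V <- V / sqrt(rowSums(V^2))
  objective <- numeric(n_iters)
  U <- NULL
  for (it in seq_len(n_iters)) {
    G <- V %*% t(V)
    enc <- omp_chunk(Z, V, q, G)
    Usel <- enc$S > 0L
    # dense coefficient matrix: fast column updates during the atom sweep
    U <- matrix(0, n, r)
    U[cbind(row(enc$S)[Usel], enc$S[Usel])] <- enc$Cf[Usel]
    Rres <- Z - U %*% V
    objective[it] <- sum(Rres^2)
    # sequential atom updates (deterministic order)
    for (j in seq_len(r)) {
      uj <- U[, j]
      I <- which(uj != 0)
      if (length(I) == 0L) next
      E <- Rres[I, , drop = FALSE] + outer(uj[I], V[j, ])
      v <- as.vector(crossprod(uj[I], E))
      nv <- sqrt(sum(v^2))
      if (nv == 0) next
      v <- v / nv
      if (v[which.max(abs(v))] < 0) v <- -v   # deterministic sign
      u <- as.vector(E %*% v)
      Rres[I, ] <- E - outer(u, v)
      V[j, ] <- v
      U[I, j] <- u
    }
    # replace unused / duplicated atoms by worst-represented profiles
    use_count <- colSums(U != 0)
    Gv <- V %*% t(V)
    dup <- rep(FALSE, r)
    for (j in seq_len(r)) {
      if (j > 1L && any(abs(Gv[j, seq_len(j - 1L)]) > 1 - 1e-10)) dup[j] <- TRUE
    }
    bad <- which(use_count == 0L | dup)
    if (length(bad)) {
      worst <- order(rowSums(Rres^2), decreasing = TRUE)
      taken <- 0L
      for (j in bad) {
        taken <- taken + 1L
        if (taken > n) break
        row_w <- Z[worst[taken], ]
        nw <- sqrt(sum(row_w^2))
        if (nw == 0) next
        V[j, ] <- row_w / nw
        U[, j] <- 0
      }
    }
  }
  dict <- structure(
    list(V = V, r = r, source_model = model,
         q_recommended = if (model == "patlak") 2L else if (model == "etk") 3L else q,
         q_train = q, n_iters = n_iters, seed = seed, objective = objective),
    class = "tk_dictionary")
  # final coding pass on the original (unnormalized) rows, all l of them
  codes <- omp_project(Z_all, dict, q)$codes
  list(dictionary = dict, codes = codes)
}

#' @export
print.tk_dictionary <- function(x, ...) {
  cat(sprintf("tk_dictionary: %d atoms x %d frames (source: %s, recommended q = %d)\n",
              x$r, ncol(x$V), x$source_model, x$q_recommended))
  invisible(x)
}

#' Dictionary approximation-error statistics
#'
#' Per-profile normalized error of the q-sparse OMP approximation,
#' `100 * ||z - z_qsp||^2 / ||z||^2` (percent). Zero-norm rows are excluded
#' from the statistics and counted separately.
#'
#' @param lib a `tk_library` or profile matrix.
#' @param dict a `tk_dictionary` or atom matrix.
#' @param q sparsity level.
#' @param chunk_size rows per block.
#' @return list of class `tk_approx_errors`: `mu_err`, `max_err` (percent),
#'   `per_row` (percent, `NA` for zero rows), `n_excluded_zero_rows`.
#' @export
approximation_errors <- function(lib, dict, q, chunk_size = 20000L) {
  Z <- if (inherits(lib, "tk_library")) lib$Z else as.matrix(lib)
  V <- if (inherits(dict, "tk_dictionary")) dict$V else dict
  if (ncol(Z) != ncol(V)) stop("library and dictionary must share the time axis", call. = FALSE)
  m <- nrow(Z)
  G <- V %*% t(V)
  per_row <- rep(NA_real_, m)
  starts <- seq(1L, m, by = chunk_size)
  for (s in starts) {
    e <- min(s + chunk_size - 1L, m)
    Zc <- Z[s:e, , drop = FALSE]
    res <- omp_chunk(Zc, V, q, G)
    sel <- res$S > 0L
    approx <- matrix(0, e - s + 1L, ncol(Z))
    if (any(sel)) {
      Usp <- Matrix::sparseMatrix(i = row(res$S)[sel], j = res$S[sel],
                                  x = res$Cf[sel], dims = c(e - s + 1L, nrow(V)))
      approx <- as.matrix(Usp %*% V)
    }
    z2 <- rowSums(Zc^2)
    r2 <- rowSums((Zc - approx)^2)
    nzc <- z2 > 0
    per_row[(s:e)[nzc]] <- 100 * r2[nzc] / z2[nzc]
  }
  ok <- !is.na(per_row)
  if (!any(ok)) stop("all library rows are zero", call. = FALSE)
  structure(list(mu_err = mean(per_row[ok]), max_err = max(per_row[ok]),
                 per_row = per_row, n_excluded_zero_rows = sum(!ok)),
            class = "tk_approx_errors")
}

#' @export
print.tk_approx_errors <- function(x, ...) {
  cat(sprintf("approximation error: mean %.3g %%, max %.3g %% (%d zero rows excluded)\n",
              x$mu_err, x$max_err, x$n_excluded_zero_rows))
  invisible(x)
}
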