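# Error statistics: Monte-Carlo bias/uncertainty of kinetic parameter
# estimates, Bland-Altman agreement, and normalized RMS error.

#' Monte-Carlo bias and uncertainty of kinetic parameter estimates
#'
#' For every point of a (ktrans, vp) grid slice, generates noisy
#' concentration profiles (additive white Gaussian noise in the
#' concentration domain), optionally replaces each realization by its
#' q-sparse OMP projection onto a dictionary, fits the kinetic model, and
#' aggregates the estimates into bias (mean estimate minus truth) and
#' uncertainty (population standard deviation of the estimates) maps. For
#' the ETK model the slice is taken at a fixed `ve`. Noise realizations are
#' seeded per grid point, so runs with identical seeds are paired across
#' pipelines.
#'
#' @param model `"patlak"` or `"etk"`.
#' @param ktrans_values,vp_values grid-slice levels (1/min, fraction).
#' @param aif a `tk_aif`.
#' @param ve_fixed fixed ve for the ETK slice (default 0.6).
#' @param sigma noise standard deviation in mM (default 0.005).
#' @param n_reps Monte-Carlo realizations per grid point (default 500).
#' @param pipeline `"raw_noise"` (fit the noisy profiles) or `"q_sparse"`
#'   (fit the q-sparse projections of the same noisy profiles).
#' @param dict,q dictionary and sparsity level for the `"q_sparse"`
#'   pipeline.
#' @param seed integer base seed.
#' @return object of class `tk_bias_maps`: `bias_ktrans`, `unc_ktrans`,
#'   `bias_vp`, `unc_vp` (matrices `length(ktrans_values)` x
#'   `length(vp_values)`), plus the raw estimate arrays `est_ktrans`,
#'   `est_vp` (`[i, j, rep]`) for paired comparisons.
#' @export
mc_bias_uncertainty <- function(model = c("patlak", "etk"),
                                ktrans_values, vp_values, aif,
                                ve_fixed = 0.6, sigma = 0.005,
                                n_reps = 500L,
                                pipeline = c("raw_noise", "q_sparse"),
                                dict = NULL, q = NULL, seed = 1L) {
  model <- match.arg(model)
  pipeline <- match.arg(pipeline)
  if (pipeline == "q_sparse" && (is.null(dict) || is.null(q))) {
    stop("`dict` and `q` are required for the q_sparse pipeline", call. = FALSE)
  }
  grid <- aif$grid
  nk <- length(ktrans_values); nv <- length(vp_values)
  est_kt <- array(NA_real_, c(nk, nv, n_reps))
  est_vp <- array(NA_real_, c(nk, nv, n_reps))
  X <- cbind(aif_cum_integral(aif, grid) / 60, aif$cp)
  XtXinv_Xt <- solve(crossprod(X), t(X))
  for (i in seq_len(nk)) {
    for (j in seq_len(nv)) {
      p <- tk_params(ktrans_values[i], vp_values[j],
                     if (model == "etk") ve_fixed else NA_real_)
      clean <- if (model == "etk") etk_forward(p, aif, grid)
               else patlak_forward(p, aif, grid)
      reps <- simulate_noisy_profiles(clean, sigma, n_reps,
                                      seed = seed + (i - 1L) * nv + (j - 1L))
      Y <- t(reps[1, , ])                   # n_reps x N
      if (pipeline == "q_sparse") {
        Y <- omp_project(Y, dict, q)$approx
      }
      if (model == "patlak") {
        B <- Y %*% t(XtXinv_Xt)             # n_reps x 2
        est_kt[i, j, ] <- B[, 1]
        est_vp[i, j, ] <- B[, 2]
      } else {
        for (rr in seq_len(n_reps)) {
          ft <- etk_fit(Y[rr, ], aif, grid)
          est_kt[i, j, rr] <- ft$params$ktrans
          est_vp[i, j, rr] <- ft$params$vp
        }
      }
    }
  }
  mu_kt <- apply(est_kt, c(1, 2), mean)
  mu_vp <- apply(est_vp, c(1, 2), mean)
  pop_sd <- function(a) apply(a, c(1, 2), function(x) sqrt(mean((x - mean(x))^2)))
  structure(
    list(bias_ktrans = mu_kt - matrix(ktrans_values, nk, nv),
         unc_ktrans = pop_sd(est_kt),
         bias_vp = mu_vp - matrix(vp_values, nk, nv, byrow = TRUE),
         unc_vp = pop_sd(est_vp),
         est_ktrans = est_kt, est_vp = est_vp,
         ktrans_values = ktrans_values, vp_values = vp_values,
         model = model, pipeline = pipeline, sigma = sigma,
         n_reps = n_reps, seed = seed),
    class = "tk_bias_maps")
}

#' Bland-Altman agreement statistics
#'
#' Differences are `estimates - reference`; limits of agreement are
#' `mu +/- 1.96 sigma` with `sigma` the population standard deviation of
#' the differences.
#'
#' @param estimates,reference numeric vectors of equal length (>= 2).
#' @return object of class `tk_bland_altman`: `mu`, `sigma`, `loa`
#'   (length-2 vector), `n_points`, `differences`.
#' @export
bland_altman <- function(estimates, reference) {
  if (length(estimates) != length(reference)) {
    stop("`estimates` and `reference` must have equal length", call. = FALSE)
  }
  if (length(estimates) < 2L) stop("need at least 2 points", call. = FALSE)
  d <- estimates - reference
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  structure(list(mu = mu, sigma = sigma,
                 loa = c(mu - 1.96 * sigma, mu + 1.96 * sigma),
                 n_points = length(d), differences = d),
            class = "tk_bland_altman")
}

#' @export
print.tk_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mu = %.4g, sigma = %.4g, LoA [%.4g, %.4g] (n = %d)\n",
              x$mu, x$sigma, x$loa[1], x$loa[2], x$n_points))
  invisible(x)
}

#' Normalized root-mean-square error (percent)
#'
#' `100 * ||x - ref||_2 / ||ref||_2` over the (optional) region of
#' interest.
#'
#' @param x,ref numeric arrays of identical shape.
#' @param roi optional logical mask applied to both.
#' @return scalar percent error.
#' @export
nrmse <- function(x, ref, roi = NULL) {
  if (!is.null(roi)) {
    x <- x[roi]; ref <- ref[roi]
  }
  denom <- sqrt(sum(ref^2))
  if (denom == 0) stop("reference norm is zero over the ROI", call. = FALSE)
  100 * sqrt(sum((x - ref)^2)) / denom
}

#' Fit kinetic parameter maps pixel-by-pixel
#'
#' Patlak fits are solved for all pixels at once (the model is linear); ETK
#' fits loop over the requested pixels with [etk_fit()].
#'
#' @param C concentration matrix (M x N).
#' @param aif a `tk_aif`.
#' @param model `"patlak"` or `"etk"`.
#' @param roi optional logical mask (length M); pixels outside are `NA`.
#' @return list with `ktrans`, `vp`, `ve` vectors (length M).
#' @export
fit_parameter_maps <- function(C, aif, model = c("patlak", "etk"), roi = NULL) {
  model <- match.arg(model)
  grid <- aif$grid
  M <- nrow(C)
  if (is.null(roi)) roi <- rep(TRUE, M)
  roi <- as.vector(roi)
  kt <- rep(NA_real_, M); vp <- rep(NA_real_, M); ve <- rep(NA_real_, M)
  if (model == "patlak") {
    X <- cbind(aif_cum_integral(aif, grid) / 60, aif$cp)
    B <- C[roi, , drop = FALSE] %*% X %*% solve(crossprod(X))
    kt[roi] <- B[, 1]; vp[roi] <- B[, 2]
  } else {
    idx <- which(roi)
    for (p in idx) {
      ft <- etk_fit(C[p, ], aif, grid)
      kt[p] <- ft$params$ktrans; vp[p] <- ft$params$vp; ve[p] <- ft$params$ve
    }
  }
  list(ktrans = kt, vp = vp, ve = ve)
}
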