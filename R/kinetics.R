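# Kinetic models: Parker population AIF, Patlak and extended Tofts-Kety
# (ETK) forward models, and their parameter-estimation inverses.
#
# Unit conventions (used throughout the package):
#   * time grids are in seconds; Ktrans is in 1/min, so every forward model
#     applies the factor 1/60 internally;
#   * concentrations are in mM; vp and ve are dimensionless fractions.

#' Uniform acquisition time grid
#'
#' @param n_frames number of time frames (default 50).
#' @param dt frame spacing in seconds (default 5, i.e. a 250 s scan).
#' @return an object of class `tk_grid` with fields `n_frames`, `dt`, `t`
#'   (seconds, starting at 0), and the oversampled grid `t_fine` at `dt/10`
#'   used for convolution quadrature.
#' @export
time_grid <- function(n_frames = 50L, dt = 5) {
  stopifnot_scalar(n_frames, "n_frames", lower = 2)
  stopifnot_scalar(dt, "dt", lower = .Machine$double.eps)
  n_frames <- as.integer(n_frames)
  t <- seq(0, by = dt, length.out = n_frames)
  t_fine <- seq(0, t[n_frames], by = dt / 10)
  structure(
    list(n_frames = n_frames, dt = dt, t = t, t_fine = t_fine,
         fine_per_frame = 10L,
         frame_idx_fine = seq(1L, length(t_fine), by = 10L)),
    class = "tk_grid")
}

#' Parker population AIF constants
#'
#' Population-averaged constants of the Parker functional form (two
#' Gaussians plus a sigmoid-modulated exponential washout), in minutes / mM
#' units. All values are exposed so alternates can be supplied to
#' [parker_aif()].
#'
#' @return named list of constants.
#' @export
parker_constants <- function() {
  list(A1 = 0.809, A2 = 0.330,      # mM * min (Gaussian areas)
       T1 = 0.17046, T2 = 0.365,    # min (Gaussian centres)
       sigma1 = 0.0563, sigma2 = 0.132,  # min (Gaussian widths)
       alpha = 1.050,               # mM (washout amplitude)
       beta = 0.1685,               # 1/min (washout rate)
       s = 38.078,                  # 1/min (sigmoid steepness)
       tau = 0.483)                 # min (sigmoid centre)
}

# Closed-form Parker blood concentration (mM); t in seconds after bolus
# arrival; vectorized.
parker_cb_closed_form <- function(t_s, consts = parker_constants()) {
  tm <- t_s / 60
  g1 <- consts$A1 / (consts$sigma1 * sqrt(2 * pi)) *
    exp(-(tm - consts$T1)^2 / (2 * consts$sigma1^2))
  g2 <- consts$A2 / (consts$sigma2 * sqrt(2 * pi)) *
    exp(-(tm - consts$T2)^2 / (2 * consts$sigma2^2))
  wash <- consts$alpha * exp(-consts$beta * tm) /
    (1 + exp(-consts$s * (tm - consts$tau)))
  g1 + g2 + wash
}

#' Parker population arterial input function
#'
#' Blood concentration is zero before `bolus_arrival` and follows the Parker
#' closed form afterwards; plasma concentration is `cb / (1 - hct)`.
#'
#' @param grid a [time_grid()].
#' @param bolus_arrival bolus arrival time in seconds (default 10 s, i.e.
#'   frame 2 of the default grid, so frame 0 is pre-contrast).
#' @param hct hematocrit fraction in `[0, 1)` (default 0.4).
#' @param constants list of Parker constants, see [parker_constants()].
#' @return an object of class `tk_aif` with blood (`cb`) and plasma (`cp`)
#'   concentration sampled on the frame grid and on the `dt/10` fine grid.
#' @export
parker_aif <- function(grid, bolus_arrival = 10, hct = 0.4,
                       constants = parker_constants()) {
  stopifnot(inherits(grid, "tk_grid"))
  if (!is.numeric(hct) || hct < 0 || hct >= 1) {
    stop("`hct` must be a fraction in [0, 1)", call. = FALSE)
  }
  stopifnot_scalar(bolus_arrival, "bolus_arrival", lower = 0)
  if (bolus_arrival >= grid$t[grid$n_frames] + grid$dt) {
    stop("`bolus_arrival` must lie within the scan window", call. = FALSE)
  }
  eval_cb <- function(t_s) {
    cb <- numeric(length(t_s))
    on_t <- t_s >= bolus_arrival
    cb[on_t] <- parker_cb_closed_form(t_s[on_t] - bolus_arrival, constants)
    cb
  }
  cb_fine <- eval_cb(grid$t_fine)
  cb <- cb_fine[grid$frame_idx_fine]
  structure(
    list(cb = cb, cp = cb / (1 - hct), hct = hct,
         bolus_arrival = bolus_arrival,
         cb_fine = cb_fine, cp_fine = cb_fine / (1 - hct),
         grid = grid, model = "parker", constants = constants),
    class = "tk_aif")
}

#' Construct an AIF from explicit concentration samples
#'
#' Utility for user-supplied or idealized input functions (for example a
#' boxcar). Exactly one of `cb` or `cp` must be given on the frame grid; the
#' fine grid is filled by linear interpolation.
#'
#' @param grid a [time_grid()].
#' @param cb blood concentration (mM), length `n_frames`.
#' @param cp plasma concentration (mM), length `n_frames`.
#' @param hct hematocrit fraction.
#' @param bolus_arrival nominal arrival time in seconds (metadata only).
#' @return a `tk_aif` object.
#' @export
aif_curve <- function(grid, cb = NULL, cp = NULL, hct = 0.4,
                      bolus_arrival = 0) {
  stopifnot(inherits(grid, "tk_grid"))
  if (is.null(cb) == is.null(cp)) {
    stop("supply exactly one of `cb` or `cp`", call. = FALSE)
  }
  if (!is.numeric(hct) || hct < 0 || hct >= 1) {
    stop("`hct` must be a fraction in [0, 1)", call. = FALSE)
  }
  if (is.null(cb)) cb <- cp * (1 - hct)
  if (length(cb) != grid$n_frames) {
    stop("curve length must equal `grid$n_frames`", call. = FALSE)
  }
  cb_fine <- stats::approx(grid$t, cb, xout = grid$t_fine, rule = 2)$y
  structure(
    list(cb = cb, cp = cb / (1 - hct), hct = hct,
         bolus_arrival = bolus_arrival,
         cb_fine = cb_fine, cp_fine = cb_fine / (1 - hct),
         grid = grid, model = "custom", constants = NULL),
    class = "tk_aif")
}

#' Kinetic parameter set
#'
#' @param ktrans volume transfer constant (1/min), `>= 0`.
#' @param vp fractional plasma volume in `[0, 1]`.
#' @param ve fractional extravascular-extracellular volume in `[0, 1]`;
#'   `NA` for the Patlak model.
#' @return an object of class `tk_params`.
#' @export
tk_params <- function(ktrans, vp, ve = NA_real_) {
  if (!is.finite(ktrans) || ktrans < 0) stop("`ktrans` must be >= 0", call. = FALSE)
  if (!is.finite(vp) || vp < 0 || vp > 1) stop("`vp` must lie in [0, 1]", call. = FALSE)
  if (!is.na(ve) && (ve < 0 || ve > 1)) stop("`ve` must lie in [0, 1]", call. = FALSE)
  structure(list(ktrans = ktrans, vp = vp, ve = ve), class = "tk_params")
}

# Running integral of cp (mM * s) at frame times, computed on the fine grid
# so forward models and linear fits share identical quadrature.
aif_cum_integral <- function(aif, grid = aif$grid) {
  cumtrapz1(grid$t_fine, aif$cp_fine)[grid$frame_idx_fine]
}

# Exponential convolution integral(0,t) cp(tau) exp(-kep_s (t - tau)) dtau
# (mM * s) at frame times, trapezoidal quadrature on the fine grid via a
# first-order recursive filter. kep_s in 1/s.
etk_conv <- function(kep_s, aif, grid = aif$grid) {
  if (kep_s == 0) return(aif_cum_integral(aif, grid))
  dtf <- grid$t_fine[2] - grid$t_fine[1]
  a <- exp(-kep_s * dtf)
  cpf <- aif$cp_fine
  n <- length(cpf)
  bq <- 0.5 * dtf * (cpf[-1] + a * cpf[-n])
  y <- c(0, stats::filter(bq, a, method = "recursive"))
  y[grid$frame_idx_fine]
}

#' Patlak forward model
#'
#' `C(t) = Ktrans * integral(0,t) Cp + vp * Cp(t)` with Ktrans in 1/min and
#' time in seconds (the 1/60 conversion is internal). Linear in
#' `(ktrans, vp)`.
#'
#' @param p a [tk_params()] (the `ve` field is ignored).
#' @param aif a `tk_aif`.
#' @param grid a [time_grid()]; defaults to the AIF's grid.
#' @return concentration profile (mM), length `n_frames`.
#' @export
patlak_forward <- function(p, aif, grid = aif$grid) {
  stopifnot(inherits(p, "tk_params"), inherits(aif, "tk_aif"))
  p$ktrans / 60 * aif_cum_integral(aif, grid) + p$vp * aif$cp
}

#' Extended Tofts-Kety forward model
#'
#' `C(t) = vp Cp(t) + Ktrans conv(Cp, exp(-(Ktrans/ve) t))` with rate
#' constant `kep = ktrans / ve` (1/min). Both `ktrans = 0` and `ve = 0`
#' collapse to `C = vp * Cp` (analytic limits), which keeps the full
#' parameter grid usable.
#'
#' @inheritParams patlak_forward
#' @return concentration profile (mM), length `n_frames`.
#' @export
etk_forward <- function(p, aif, grid = aif$grid) {
  stopifnot(inherits(p, "tk_params"), inherits(aif, "tk_aif"))
  if (is.na(p$ve)) stop("`ve` is required for the ETK model", call. = FALSE)
  if (p$ktrans == 0 || p$ve == 0) return(p$vp * aif$cp)
  kep_s <- p$ktrans / (60 * p$ve)
  p$vp * aif$cp + p$ktrans / 60 * etk_conv(kep_s, aif, grid)
}

#' Linear least-squares Patlak fit
#'
#' The Patlak model is linear in its parameters; the fit regresses the
#' profile on the design columns `[integral(Cp)/60, Cp]`, sharing quadrature
#' with [patlak_forward()] so noiseless round trips are exact.
#'
#' @param profile concentration profile (mM), length `n_frames`.
#' @param aif a `tk_aif`.
#' @param grid a [time_grid()].
#' @return a `tk_fit` list: `params` ([tk_params()]), `residual_norm` (mM),
#'   `converged`, `identifiability_flags`.
#' @export
patlak_fit <- function(profile, aif, grid = aif$grid) {
  stopifnot(inherits(aif, "tk_aif"), length(profile) == grid$n_frames)
  X <- cbind(aif_cum_integral(aif, grid) / 60, aif$cp)
  qx <- qr(X)
  if (qx$rank < 2L) {
    stop("singular Patlak design (degenerate AIF)", call. = FALSE)
  }
  beta <- qr.coef(qx, profile)
  res <- profile - X %*% beta
  structure(
    list(params = structure(list(ktrans = beta[[1]], vp = beta[[2]], ve = NA_real_),
                            class = "tk_params"),
         residual_norm = sqrt(sum(res^2)), converged = TRUE,
         identifiability_flags = character(0)),
    class = "tk_fit")
}

#' Bounded nonlinear least-squares ETK fit
#'
#' Levenberg-Marquardt on `(ktrans, vp, ve)` with bounds
#' `ktrans in [0, 1.5]` 1/min, `vp in [0, 1]`, `ve in [1e-3, 1]`.
#' Auto-initialization uses the Patlak fit plus `ve = 0.3`; one restart from
#' a perturbed initialization is attempted on non-convergence. When
#' `ktrans` is essentially zero, `ve` carries no information and is flagged
#' as unidentifiable rather than trusted.
#'
#' @inheritParams patlak_fit
#' @param init `"auto"` or a [tk_params()] starting point.
#' @return a `tk_fit` list, see [patlak_fit()].
#' @export
etk_fit <- function(profile, aif, grid = aif$grid, init = "auto") {
  stopifnot(inherits(aif, "tk_aif"), length(profile) == grid$n_frames)
  lower <- c(0, 0, 1e-3)
  upper <- c(1.5, 1, 1)
  intcp <- aif_cum_integral(aif, grid)
  resid_fun <- function(th) {
    kep_s <- th[1] / (60 * th[3])
    conv <- if (th[1] == 0) intcp else etk_conv(kep_s, aif, grid)
    th[2] * aif$cp + th[1] / 60 * conv - profile
  }
  start <- if (identical(init, "auto")) {
    pf <- patlak_fit(profile, aif, grid)
    c(min(max(pf$params$ktrans, 1e-3), 1.4),
      min(max(pf$params$vp, 1e-3), 0.99), 0.3)
  } else {
    stopifnot(inherits(init, "tk_params"))
    pmin(pmax(c(init$ktrans, init$vp, init$ve), lower + 1e-6), upper - 1e-6)
  }
  run_lm <- function(th0) {
    minpack.lm::nls.lm(
      par = th0, lower = lower, upper = upper, fn = resid_fun,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-14,
                                           ptol = 1e-14, gtol = 0))
  }
  fit <- run_lm(start)
  converged <- fit$info %in% 1:4
  if (!converged) {
    alt <- pmin(pmax(start * c(1.5, 0.7, 1) + c(0.02, 0.01, 0.2), lower), upper)
    fit2 <- run_lm(alt)
    if (fit2$info %in% 1:4 || fit2$deviance < fit$deviance) {
      fit <- fit2
      converged <- fit$info %in% 1:4
    }
  }
  th <- fit$par
  flags <- character(0)
  if (th[1] < 1e-4) flags <- c(flags, "ve_unidentifiable")
  if (!converged) flags <- c(flags, "non_convergence")
  structure(
    list(params = structure(list(ktrans = th[1], vp = th[2], ve = th[3]),
                            class = "tk_params"),
         residual_norm = sqrt(fit$deviance), converged = converged,
         identifiability_flags = flags),
    class = "tk_fit")
}

#' @export
print.tk_fit <- function(x, ...) {
  p <- x$params
  cat(sprintf("tk_fit: ktrans = %.5g 1/min, vp = %.5g, ve = %s\n",
              p$ktrans, p$vp,
              if (is.na(p$ve)) "-" else sprintf("%.5g", p$ve)))
  cat(sprintf("  residual norm %.3g mM; converged: %s%s\n",
              x$residual_norm, x$converged,
              if (length(x$identifiability_flags))
                paste0("; flags: ", paste(x$identifiability_flags, collapse = ", "))
              else ""))
  invisible(x)
}
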