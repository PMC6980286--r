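# Synthetic brain-tumor digital reference object (DRO) and the
# concentration-domain Monte-Carlo noisy-profile generator.

# Smooth random field in [0, 1]: white noise low-passed with a Gaussian
# k-space window. Consumes the current RNG stream (callers seed it).
smooth_field <- function(ny, nx, k_sigma_frac = 0.08) {
  noise <- matrix(stats::rnorm(ny * nx), ny, nx)
  W <- gaussian_filter_weights(c(ny, nx), 100 * k_sigma_frac)
  f <- Re(ifft2c(fft2c(noise) * W))
  rng <- range(f)
  if (diff(rng) == 0) return(matrix(0.5, ny, nx))
  (f - rng[1]) / diff(rng)
}

# Batched ETK/Patlak profile evaluation for per-pixel parameter vectors.
model_profiles <- function(ktrans, vp, ve, aif, grid, model = "etk") {
  m <- length(ktrans)
  C <- outer(vp, aif$cp)
  if (model == "patlak") {
    C <- C + outer(ktrans / 60, aif_cum_integral(aif, grid))
    return(C)
  }
  on <- which(ktrans > 0 & ve > 0)
  for (p in on) {
    C[p, ] <- vp[p] * aif$cp +
      ktrans[p] / 60 * etk_conv(ktrans[p] / (60 * ve[p]), aif, grid)
  }
  C
}

#' Build a synthetic brain-tumor digital reference object
#'
#' A parametric 2-D phantom with an elliptical brain, a heterogeneous
#' enhancing tumor rim, a necrotic core, a vessel region, and
#' non-enhancing normal tissue (intact blood-brain barrier: ktrans = 0).
#' Per-pixel concentration profiles are generated from the stored kinetic
#' parameter maps with the chosen model, so every profile equals the
#' corresponding forward-model call by construction. The generative chain to
#' k-space (SPGR signal, coil weighting, FFT, noise) is applied by
#' [apply_forward()] / [add_noise()].
#'
#' Default rim parameter ranges: ktrans 0.05-0.30 1/min, vp 0.02-0.10,
#' ve 0.2-0.6 with smooth spatial heterogeneity; vessel vp = 0.5; T1
#' 1.0-1.6 s; all values lie inside the default library grid.
#'
#' @param shape `c(ny, nx)` (default 96 x 96).
#' @param aif a `tk_aif` (default Parker AIF on the default grid).
#' @param seed integer seed for the heterogeneity fields.
#' @param model `"etk"` (default) or `"patlak"` generative kinetic model.
#' @return object of class `tk_dro` with per-pixel parameter maps
#'   (`ktrans_map`, `vp_map`, `ve_map`, matrices), `tissue`
#'   ([tissue_maps()]), `conc` (M x N concentration, column-major pixel
#'   order), `roi_masks` (tumor_rim, tumor_core, vessel, normal,
#'   background), `time`, `aif`, `model`, `seed`.
#' @export
build_dro <- function(shape = c(96, 96), aif = NULL, seed = 1L,
                      model = c("etk", "patlak")) {
  model <- match.arg(model)
  ny <- shape[1]; nx <- shape[2]
  grid <- if (is.null(aif)) time_grid() else aif$grid
  if (is.null(aif)) aif <- parker_aif(grid)
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  brain <- ((yy - cy) / (0.42 * ny))^2 + ((xx - cx) / (0.36 * nx))^2 <= 1
  r_out <- 0.16 * min(ny, nx); r_core <- 0.07 * min(ny, nx)
  ty <- cy + 0.14 * ny; tx <- cx - 0.12 * nx
  rt2 <- (yy - ty)^2 + (xx - tx)^2
  tumor_core <- rt2 <= r_core^2
  tumor_rim <- rt2 <= r_out^2 & !tumor_core
  vy <- cy - 0.22 * ny; vx <- cx + 0.10 * nx
  vessel <- (yy - vy)^2 + (xx - vx)^2 <= (0.035 * min(ny, nx))^2
  tumor_core <- tumor_core & brain; tumor_rim <- tumor_rim & brain
  vessel <- vessel & brain & !tumor_rim & !tumor_core
  normal <- brain & !tumor_rim & !tumor_core & !vessel
  fields <- with_seed(seed, list(
    f_kt = smooth_field(ny, nx), f_vp = smooth_field(ny, nx),
    f_ve = smooth_field(ny, nx), f_t1 = smooth_field(ny, nx),
    f_m0 = smooth_field(ny, nx)))
  ktrans <- matrix(0, ny, nx); vp <- matrix(0, ny, nx); ve <- matrix(0.01, ny, nx)
  ktrans[tumor_rim] <- 0.05 + 0.25 * fields$f_kt[tumor_rim]
  vp[tumor_rim] <- 0.02 + 0.08 * fields$f_vp[tumor_rim]
  ve[tumor_rim] <- 0.2 + 0.4 * fields$f_ve[tumor_rim]
  ktrans[tumor_core] <- 0.005; vp[tumor_core] <- 0.01; ve[tumor_core] <- 0.2
  vp[vessel] <- 0.5
  t1 <- matrix(0, ny, nx)
  t1[brain] <- 1.0 + 0.6 * fields$f_t1[brain]
  m0 <- matrix(0, ny, nx)
  m0[brain] <- 1000 * (0.8 + 0.4 * fields$f_m0[brain])
  r10 <- matrix(0, ny, nx)
  r10[brain] <- 1 / t1[brain]
  tissue <- tissue_maps(as.vector(m0), as.vector(r10))
  conc <- model_profiles(as.vector(ktrans), as.vector(vp), as.vector(ve),
                         aif, grid, model)
  conc[!as.vector(brain), ] <- 0
  structure(
    list(ktrans_map = ktrans, vp_map = vp, ve_map = ve, t1_map = t1,
         tissue = tissue, conc = conc,
         roi_masks = list(tumor_rim = tumor_rim, tumor_core = tumor_core,
                          vessel = vessel, normal = normal,
                          background = !brain),
         shape = c(ny, nx), time = grid, aif = aif, model = model,
         seed = seed),
    class = "tk_dro")
}

#' @export
print.tk_dro <- function(x, ...) {
  cat(sprintf("tk_dro (%s): %d x %d, %d frames; tumor rim %d px, core %d px\n",
              x$model, x$shape[1], x$shape[2], x$time$n_frames,
              sum(x$roi_masks$tumor_rim), sum(x$roi_masks$tumor_core)))
  invisible(x)
}

#' Monte-Carlo noisy concentration profiles
#'
#' Adds i.i.d. zero-mean white Gaussian noise directly in the concentration
#' domain, `z^n(t) = z(t) + n(t)`, the noise model used for the
#' sparsity-selection simulations (default sigma 0.005 mM, 500
#' realizations).
#'
#' @param profiles matrix (m x N) of clean profiles (a single profile may be
#'   given as a vector).
#' @param sigma noise standard deviation (mM).
#' @param n_realizations number of Monte-Carlo realizations.
#' @param seed integer seed.
#' @return numeric array `[m, N, n_realizations]`.
#' @export
simulate_noisy_profiles <- function(profiles, sigma = 0.005,
                                    n_realizations = 500L, seed = 1L) {
  if (is.null(dim(profiles))) profiles <- matrix(profiles, nrow = 1)
  if (sigma < 0) stop("`sigma` must be >= 0", call. = FALSE)
  m <- nrow(profiles); N <- ncol(profiles)
  out <- with_seed(seed, {
    noise <- array(stats::rnorm(m * N * n_realizations, sd = sigma),
                   c(m, N, n_realizations))
    array(rep(as.vector(profiles), n_realizations), c(m, N, n_realizations)) + noise
  })
  out
}
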