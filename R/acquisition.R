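# Multicoil Cartesian acquisition: forward model A = Fu * Sm * T, GOCART
# style golden-angle undersampling masks, coil-map estimation, noise
# injection, and bolus-arrival estimation.
#
# FFT convention: unitary, centered. The k-space origin sits at array index
# (floor(ny/2) + 1, floor(nx/2) + 1) (0-based: ny/2, nx/2).

#' Synthetic smooth coil sensitivity maps
#'
#' Gaussian-profile sensitivities centered on a ring around the object with
#' a smooth linear phase, normalized so the sum-of-squares magnitude is 1
#' everywhere.
#'
#' @param shape `c(ny, nx)`.
#' @param n_coils number of receiver coils (default 8).
#' @return object of class `tk_coil_maps`: complex array
#'   `maps[ny, nx, n_coils]` with unit sum-of-squares, and `n_coils`.
#' @export
gaussian_coil_maps <- function(shape, n_coils = 8L) {
  ny <- shape[1]; nx <- shape[2]
  yy <- matrix(seq_len(ny), ny, nx)
  xx <- matrix(seq_len(nx), ny, nx, byrow = TRUE)
  cy <- (ny + 1) / 2; cx <- (nx + 1) / 2
  rad <- 0.62 * max(ny, nx)
  width <- 0.8 * max(ny, nx)
  maps <- array(0i, c(ny, nx, n_coils))
  for (c in seq_len(n_coils)) {
    th <- 2 * pi * (c - 1) / n_coils
    my <- cy + rad * sin(th); mx <- cx + rad * cos(th)
    mag <- exp(-((yy - my)^2 + (xx - mx)^2) / (2 * width^2))
    ph <- 2 * pi * 0.05 * ((yy - cy) * sin(th) + (xx - cx) * cos(th)) / max(ny, nx)
    maps[, , c] <- mag * exp(1i * ph)
  }
  sos <- sqrt(apply(abs(maps)^2, c(1, 2), sum))
  for (c in seq_len(n_coils)) maps[, , c] <- maps[, , c] / sos
  structure(list(maps = maps, n_coils = n_coils), class = "tk_coil_maps")
}

#' Golden-angle Cartesian (GOCART-style) undersampling mask
#'
#' Frame 0 (the pre-contrast frame) is always fully sampled. Later frames
#' draw points from Cartesian radial spokes whose angles advance by the
#' golden angle (111.246 degrees), with randomized selection of points along
#' each spoke, until `ceiling(M / R)` distinct locations are collected. The
#' k-space origin is always included.
#'
#' @param shape `c(ky, kx)` matrix size.
#' @param n_frames number of time frames.
#' @param R nominal acceleration factor, `>= 1`.
#' @param seed integer seed (masks are reproducible bit-for-bit).
#' @return object of class `tk_mask`: logical array `mask[ky, kx, n_frames]`,
#'   `R_nominal`, `seed`.
#' @export
gocart_mask <- function(shape, n_frames, R, seed = 1L) {
  ny <- shape[1]; nx <- shape[2]
  M <- ny * nx
  if (R < 1) stop("`R` must be >= 1", call. = FALSE)
  if (R > M) stop("`R` exceeds the number of k-space locations", call. = FALSE)
  mask <- array(R == 1, c(ny, nx, n_frames))
  mask[, , 1] <- TRUE
  if (R > 1 && n_frames > 1L) {
    target <- ceiling(M / R)
    oy <- floor(ny / 2) + 1L; ox <- floor(nx / 2) + 1L
    ga <- 111.246 * pi / 180
    rmax <- sqrt((ny / 2)^2 + (nx / 2)^2)
    tt <- seq(-rmax, rmax, by = 0.5)
    spoke_counter <- 0L
    with_seed(seed, {
      for (f in 2:n_frames) {
        fm <- matrix(FALSE, ny, nx)
        fm[oy, ox] <- TRUE
        count <- 1L
        while (count < target) {
          th <- spoke_counter * ga
          spoke_counter <- spoke_counter + 1L
          py <- round(oy + tt * sin(th)); px <- round(ox + tt * cos(th))
          ok <- py >= 1 & py <= ny & px >= 1 & px <= nx
          pts <- unique(cbind(py[ok], px[ok]))
          keep <- sample.int(nrow(pts), ceiling(nrow(pts) / 2))
          for (p in keep) {
            if (!fm[pts[p, 1], pts[p, 2]]) {
              fm[pts[p, 1], pts[p, 2]] <- TRUE
              count <- count + 1L
              if (count >= target) break
            }
          }
        }
        mask[, , f] <- fm
      }
    })
  }
  structure(list(mask = mask, R_nominal = R, seed = seed, shape = c(ny, nx)),
            class = "tk_mask")
}

#' Multicoil forward model A C = Fu Sm T C
#'
#' Maps a concentration series through the SPGR transform, coil
#' sensitivities, unitary centered 2-D FFT per frame, and mask selection.
#' Unsampled entries of the returned k-space array are zero.
#'
#' @param C concentration matrix (M x N) in pixel-major (column-of-image)
#'   order.
#' @param maps a [tissue_maps()].
#' @param coils a `tk_coil_maps`.
#' @param mask a `tk_mask`.
#' @param k an [spgr_constants()].
#' @return object of class `tk_ktdata`: complex `b[ky, kx, N, n_coils]`
#'   (zero where unsampled), `mask`, `coils`, `shape`, `noise_sigma`.
#' @export
apply_forward <- function(C, maps, coils, mask, k = spgr_constants()) {
  ny <- mask$shape[1]; nx <- mask$shape[2]
  N <- dim(mask$mask)[3]
  if (nrow(C) != ny * nx || ncol(C) != N) stop("shape mismatch", call. = FALSE)
  S <- conc_to_signal(C, maps, k)
  b <- kt_forward_linear(array(as.complex(S), c(ny, nx, N)), coils, mask)
  structure(list(b = b, mask = mask, coils = coils, shape = c(ny, nx),
                 n_coils = coils$n_coils, noise_sigma = 0, snr = Inf),
            class = "tk_ktdata")
}

#' Linear part of the forward model (and its adjoint)
#'
#' `kt_forward_linear` applies coil weighting, the unitary centered FFT per
#' frame, and the sampling mask to a complex image series;
#' `kt_adjoint_linear` is its exact adjoint (conjugate coil maps and inverse
#' FFT of the zero-filled data).
#'
#' @param x complex image series `[ny, nx, N]`.
#' @param coils a `tk_coil_maps`.
#' @param mask a `tk_mask`.
#' @return `kt_forward_linear`: complex array `[ny, nx, N, n_coils]`;
#'   `kt_adjoint_linear`: complex array `[ny, nx, N]`.
#' @export
kt_forward_linear <- function(x, coils, mask) {
  d <- dim(x); ny <- d[1]; nx <- d[2]; N <- d[3]
  nc <- coils$n_coils
  out <- array(0i, c(ny, nx, N, nc))
  for (c in seq_len(nc)) {
    mc <- coils$maps[, , c]
    for (t in seq_len(N)) {
      kf <- fft2c(x[, , t] * mc)
      kf[!mask$mask[, , t]] <- 0i
      out[, , t, c] <- kf
    }
  }
  out
}

#' @param y complex k-t array `[ny, nx, N, n_coils]`.
#' @rdname kt_forward_linear
#' @export
kt_adjoint_linear <- function(y, coils, mask) {
  d <- dim(y); ny <- d[1]; nx <- d[2]; N <- d[3]; nc <- d[4]
  out <- array(0i, c(ny, nx, N))
  for (c in seq_len(nc)) {
    mcc <- Conj(coils$maps[, , c])
    for (t in seq_len(N)) {
      kf <- y[, , t, c]
      kf[!mask$mask[, , t]] <- 0i
      out[, , t] <- out[, , t] + mcc * ifft2c(kf)
    }
  }
  out
}

#' Estimate coil sensitivity maps by sum of squares
#'
#' Averages the sampled k-space over time per coil, reconstructs the
#' time-collapsed coil images, and normalizes by the sum-of-squares
#' magnitude. Pixels without signal are set to zero and excluded from the
#' support.
#'
#' @param kt a `tk_ktdata`.
#' @param support_frac support threshold as a fraction of the peak
#'   sum-of-squares magnitude (default 0.05).
#' @return a `tk_coil_maps` with an extra `support` field.
#' @export
estimate_coil_maps <- function(kt, support_frac = 0.05) {
  d <- dim(kt$b); ny <- d[1]; nx <- d[2]; N <- d[3]; nc <- d[4]
  counts <- apply(kt$mask$mask, c(1, 2), sum)
  imgs <- array(0i, c(ny, nx, nc))
  for (c in seq_len(nc)) {
    kavg <- apply(kt$b[, , , c, drop = FALSE], c(1, 2), sum)
    kavg <- ifelse(counts > 0, kavg / counts, 0i)
    imgs[, , c] <- ifft2c(matrix(kavg, ny, nx))
  }
  sos <- sqrt(apply(abs(imgs)^2, c(1, 2), sum))
  support <- sos > support_frac * max(sos)
  maps <- array(0i, c(ny, nx, nc))
  for (c in seq_len(nc)) {
    maps[, , c] <- ifelse(support, imgs[, , c] / sos, 0i)
  }
  structure(list(maps = maps, n_coils = nc, support = support),
            class = "tk_coil_maps")
}

#' Add complex Gaussian noise to k-t data
#'
#' Adds i.i.d. complex Gaussian noise to every sampled location of every
#' channel. The noise level is `sigma = peak / snr`, where `peak` is the
#' maximum of the coil-combined (sum-of-squares) pre-contrast image and
#' `sigma` is the standard deviation of each real/imaginary component.
#'
#' @param kt a `tk_ktdata`.
#' @param snr signal-to-noise ratio; `Inf` returns the data unchanged.
#' @param seed integer seed.
#' @return the noisy `tk_ktdata` (with `noise_sigma`, `snr` recorded).
#' @export
add_noise <- function(kt, snr, seed = 1L) {
  if (!is.finite(snr)) return(kt)
  if (snr <= 0) stop("`snr` must be > 0", call. = FALSE)
  d <- dim(kt$b); ny <- d[1]; nx <- d[2]; nc <- d[4]
  base <- array(0i, c(ny, nx, nc))
  for (c in seq_len(nc)) base[, , c] <- ifft2c(kt$b[, , 1, c])
  peak <- max(sqrt(apply(abs(base)^2, c(1, 2), sum)))
  sigma <- peak / snr
  kt$b <- with_seed(seed, {
    noise <- array(complex(real = stats::rnorm(length(kt$b), sd = sigma),
                           imaginary = stats::rnorm(length(kt$b), sd = sigma)),
                   dim = d)
    sampled <- array(kt$mask$mask, d)   # recycle mask over the coil axis
    kt$b + noise * sampled
  })
  kt$noise_sigma <- sigma
  kt$snr <- snr
  kt
}

#' Estimate bolus arrival from the k-space-center time series
#'
#' The frequently sampled k-space origin magnitude is regressed over the
#' region of maximum slope; the intersection of that line with the baseline
#' level gives the bolus arrival time.
#'
#' @param center_signal length-N numeric series (magnitude of the k-space
#'   origin over time).
#' @param ref_frame library reference arrival frame (0-based; default 2,
#'   matching the 10 s default arrival on the 5 s grid).
#' @return list with `arrival` (continuous frame units), `arrival_frame`
#'   (integer, 0-based) and `shift` (frames relative to `ref_frame`).
#' @export
estimate_bolus_arrival <- function(center_signal, ref_frame = 2L) {
  s <- as.numeric(center_signal)
  N <- length(s)
  if (N < 5L) stop("series too short", call. = FALSE)
  b0 <- mean(s[1:3]); sd0 <- stats::sd(s[1:3])
  rng <- max(s) - b0
  if (!(max(s) > b0 + max(5 * sd0, 1e-6 * max(abs(b0), 1)) ) || rng <= 0) {
    stop("no enhancement detected in the center k-space series", call. = FALSE)
  }
  d <- diff(s)
  dmax <- max(d)
  if (dmax <= 0) stop("no enhancement detected in the center k-space series", call. = FALSE)
  m <- which.max(d)
  # contiguous run of steep slopes around the maximum
  lo <- m; hi <- m
  while (lo > 1L && d[lo - 1L] >= 0.5 * dmax) lo <- lo - 1L
  while (hi < N - 1L && d[hi + 1L] >= 0.5 * dmax) hi <- hi + 1L
  w <- lo:(hi + 1L)                 # frame indices (1-based) on the upslope
  x <- w - 1                        # 0-based frame units
  fit <- stats::lm.fit(cbind(1, x), s[w])
  a <- fit$coefficients[1]; slope <- fit$coefficients[2]
  arrival <- (b0 - a) / slope
  arrival <- min(max(arrival, 0), N - 1)
  af <- as.integer(round(arrival))
  list(arrival = as.numeric(arrival), arrival_frame = af,
       shift = af - as.integer(ref_frame))
}

#' Correct a bolus-arrival mismatch to the library time axis
#'
#' Positive `shift` (data bolus later than the library) drops the leading
#' frames and repeats the final frame; negative `shift` pads zeros at the
#' start and omits the last frames, mirroring the pad/omit delay correction
#' used before reconstruction.
#'
#' @param X matrix (M x N) or vector of time profiles.
#' @param shift integer frame shift.
#' @return corrected series with unchanged dimensions.
#' @export
correct_bolus_delay <- function(X, shift) {
  vec <- is.null(dim(X))
  if (vec) X <- matrix(X, nrow = 1)
  N <- ncol(X)
  shift <- as.integer(shift)
  if (shift != 0L) {
    if (abs(shift) >= N) stop("shift exceeds the scan window", call. = FALSE)
    if (shift > 0L) {
      X <- cbind(X[, (shift + 1L):N, drop = FALSE],
                 matrix(X[, N], nrow(X), shift))
    } else {
      X <- cbind(matrix(0, nrow(X), -shift),
                 X[, 1:(N + shift), drop = FALSE])
    }
  }
  if (vec) X[1, ] else X
}
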