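# Spoiled gradient-echo (SPGR) signal model: concentration <-> signal
# mapping and DESPOT1 pre-contrast T1/M0 estimation.

#' SPGR acquisition constants
#'
#' @param tr repetition time in seconds (default 0.006).
#' @param flip_deg flip angle in degrees, in (0, 90) (default 15).
#' @param r1 contrast-agent relaxivity in 1/(s mM) (default 4.5; typical of
#'   gadobenate at 3T, configurable).
#' @return an object of class `tk_spgr`.
#' @export
spgr_constants <- function(tr = 0.006, flip_deg = 15, r1 = 4.5) {
  stopifnot_scalar(tr, "tr", lower = 1e-6)
  stopifnot_scalar(flip_deg, "flip_deg", lower = 1e-6, upper = 90 - 1e-9)
  stopifnot_scalar(r1, "r1", lower = 1e-9)
  structure(list(tr = tr, flip_deg = flip_deg, flip_rad = flip_deg * pi / 180,
                 r1 = r1), class = "tk_spgr")
}

#' Pre-contrast tissue maps
#'
#' @param m0 equilibrium magnetization (arbitrary units), length M.
#' @param r10 pre-contrast R1 = 1/T1 (1/s), length M.
#' @param s0 measured pre-contrast signal; defaults to the SPGR baseline
#'   predicted from `m0` and `r10` (in which case the baseline-correction
#'   term of the signal model vanishes).
#' @param k an [spgr_constants()] used when predicting `s0`.
#' @return an object of class `tk_tissue_maps` with `m0`, `r10`, `s0`, and
#'   the `support` mask (`m0 > 0`).
#' @export
tissue_maps <- function(m0, r10, s0 = NULL, k = spgr_constants()) {
  stopifnot(length(m0) == length(r10))
  support <- is.finite(m0) & m0 > 0 & is.finite(r10) & r10 > 0
  if (is.null(s0)) s0 <- spgr_baseline(m0, r10, k)
  stopifnot(length(s0) == length(m0))
  structure(list(m0 = as.numeric(m0), r10 = as.numeric(r10),
                 s0 = as.numeric(s0), support = support),
            class = "tk_tissue_maps")
}

# Model-predicted pre-contrast signal.
spgr_baseline <- function(m0, r10, k) {
  E0 <- exp(-k$tr * r10)
  m0 * sin(k$flip_rad) * (1 - E0) / (1 - cos(k$flip_rad) * E0)
}

#' Map concentration to SPGR signal
#'
#' Steady-state SPGR equation with a baseline-consistency correction: the
#' additive term `s0 - baseline(m0, r10)` guarantees that zero concentration
#' reproduces the measured pre-contrast signal exactly, even when `s0`
#' disagrees with the `(m0, r10)`-predicted baseline.
#'
#' @param C concentration matrix (M pixels x N frames, mM).
#' @param maps a [tissue_maps()].
#' @param k an [spgr_constants()].
#' @return signal matrix (M x N); zero outside the tissue support.
#' @export
conc_to_signal <- function(C, maps, k = spgr_constants()) {
  if (is.null(dim(C))) C <- matrix(C, nrow = 1)
  stopifnot(inherits(maps, "tk_tissue_maps"), nrow(C) == length(maps$m0))
  if (any(!is.finite(C))) stop("non-finite concentrations", call. = FALSE)
  ca <- cos(k$flip_rad); sa <- sin(k$flip_rad)
  E <- exp(-k$tr * (maps$r10 + k$r1 * C))   # recycles r10 down columns
  S <- maps$m0 * sa * (1 - E) / (1 - ca * E) +
    (maps$s0 - spgr_baseline(maps$m0, maps$r10, k))
  S[!maps$support, ] <- 0
  S
}

#' Map SPGR signal to concentration
#'
#' Exact algebraic inverse of [conc_to_signal()]: the post-contrast
#' longitudinal relaxation factor `E = exp(-TR * R1(t))` is recovered from
#' the baseline-shifted signal, the real part of `-log(E)/TR` gives `R1(t)`,
#' and `c = (R1(t) - R10) / r1`. Unphysical signals whose `E` would be
#' non-positive (at or beyond saturation) are clamped to `1e-9` and flagged
#' rather than producing NaN.
#'
#' @param S signal matrix (M x N).
#' @param maps a [tissue_maps()].
#' @param k an [spgr_constants()].
#' @return concentration matrix (M x N, mM) with attribute `clamped`
#'   (logical matrix of clamped entries). Zero outside the tissue support.
#' @export
signal_to_conc <- function(S, maps, k = spgr_constants()) {
  if (is.null(dim(S))) S <- matrix(S, nrow = 1)
  stopifnot(inherits(maps, "tk_tissue_maps"), nrow(S) == length(maps$m0))
  ca <- cos(k$flip_rad); sa <- sin(k$flip_rad)
  y <- S - maps$s0 + spgr_baseline(maps$m0, maps$r10, k)
  msa <- maps$m0 * sa
  E <- (msa - y) / (msa - ca * y)
  clamped <- is.finite(E) & E <= 0
  E[clamped] <- 1e-9
  E[!is.finite(E)] <- 1      # outside support: m0 = 0 makes E 0/0
  R1 <- -log(E) / k$tr
  C <- (R1 - maps$r10) / k$r1
  C[!maps$support, ] <- 0
  clamped[!maps$support, ] <- FALSE
  attr(C, "clamped") <- clamped
  C
}

#' DESPOT1 T1 / M0 estimation from multi-flip-angle SPGR images
#'
#' Linearized SPGR regression of `S/sin(a)` on `S/tan(a)` across flip
#' angles; the slope equals `exp(-TR * R1)` and the intercept gives `M0`.
#' Pixels with non-positive signals or slope outside (0, 1) are flagged
#' invalid and excluded (`NA` in the maps).
#'
#' @param signals matrix (M pixels x n_angles) of SPGR signal images.
#' @param flips_deg flip angles in degrees (>= 2 distinct values).
#' @param tr repetition time in seconds.
#' @return list with `m0`, `r10`, `t1` (seconds) and logical `valid`.
#' @export
despot1_fit <- function(signals, flips_deg, tr) {
  if (is.null(dim(signals))) signals <- matrix(signals, nrow = 1)
  na <- length(flips_deg)
  if (na < 2L || length(unique(flips_deg)) < 2L) {
    stop("need at least two distinct flip angles", call. = FALSE)
  }
  stopifnot(ncol(signals) == na)
  a <- flips_deg * pi / 180
  Y <- sweep(signals, 2, sin(a), "/")
  X <- sweep(signals, 2, tan(a), "/")
  xbar <- rowMeans(X); ybar <- rowMeans(Y)
  sxx <- rowSums((X - xbar)^2)
  sxy <- rowSums((X - xbar) * (Y - ybar))
  slope <- sxy / sxx
  valid <- apply(signals > 0, 1L, all) & is.finite(slope) &
    slope > 0 & slope < 1
  t1 <- ifelse(valid, -tr / log(slope), NA_real_)
  m0 <- ifelse(valid, (ybar - slope * xbar) / (1 - slope), NA_real_)
  list(m0 = m0, r10 = 1 / t1, t1 = t1, valid = valid)
}
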