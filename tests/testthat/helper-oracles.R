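# Independent oracles used to freeze expected values; these never call the
# implementation paths they check.

# Direct evaluation of the Parker population curve (mM) at times t seconds
# after bolus arrival; written independently of parker_aif().
oracle_parker <- function(t_s, hct = 0.4) {
  tm <- t_s / 60
  g <- function(A, T, s) A / (s * sqrt(2 * pi)) * exp(-(tm - T)^2 / (2 * s^2))
  g(0.809, 0.17046, 0.0563) + g(0.330, 0.365, 0.132) +
    1.050 * exp(-0.1685 * tm) / (1 + exp(-38.078 * (tm - 0.483)))
}

# Exhaustive best-q-subset least squares: returns the minimal residual
# 2-norm over all atom subsets of size <= q.
oracle_best_subset <- function(z, V, q) {
  r <- nrow(V)
  best <- sqrt(sum(z^2))
  for (k in seq_len(q)) {
    subsets <- utils::combn(r, k)
    for (j in seq_len(ncol(subsets))) {
      Vs <- t(V[subsets[, j], , drop = FALSE])
      fit <- qr.resid(qr(Vs), z)
      best <- min(best, sqrt(sum(fit^2)))
    }
  }
  best
}

# Direct SPGR signal equation (single values), independent transcription.
oracle_spgr <- function(c, m0, r10, s0, tr, flip_deg, r1) {
  a <- flip_deg * pi / 180
  E <- exp(-tr * (r10 + r1 * c))
  E0 <- exp(-tr * r10)
  m0 * sin(a) * (1 - E) / (1 - cos(a) * E) +
    (s0 - m0 * sin(a) * (1 - E0) / (1 - cos(a) * E0))
}
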