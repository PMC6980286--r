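# Internal helpers shared across modules.

#' Evaluate an expression with a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite integer", call. = FALSE)
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Cumulative trapezoidal integral
#'
#' @param t strictly increasing sample locations.
#' @param y values at `t`.
#' @return vector of the running integral, same length as `t`, starting at 0.
#' @keywords internal
cumtrapz1 <- function(t, y) {
  n <- length(t)
  if (n == 0L) return(numeric(0))
  c(0, cumsum(0.5 * diff(t) * (y[-1] + y[-n])))
}

# fftshift / ifftshift for matrices (centered-origin FFT convention).
fftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(ceiling(d[1] / 2)) + floor(d[1] / 2), seq_len(floor(d[1] / 2)))
  j <- c(seq_len(ceiling(d[2] / 2)) + floor(d[2] / 2), seq_len(floor(d[2] / 2)))
  x[i, j, drop = FALSE]
}

ifftshift2 <- function(x) {
  d <- dim(x)
  i <- c(seq_len(floor(d[1] / 2)) + ceiling(d[1] / 2), seq_len(ceiling(d[1] / 2)))
  j <- c(seq_len(floor(d[2] / 2)) + ceiling(d[2] / 2), seq_len(ceiling(d[2] / 2)))
  x[i, j, drop = FALSE]
}

# Unitary centered 2-D FFT and inverse. Origin at floor(n/2)+1 (0-based n/2).
fft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x))) / sqrt(length(x))
}

ifft2c <- function(x) {
  fftshift2(stats::fft(ifftshift2(x), inverse = TRUE)) / sqrt(length(x))
}

stopifnot_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < lower || x > upper) {
    stop(sprintf("`%s` must be a single finite number in [%g, %g]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}
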