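# Internal numerical primitives shared by the input-function and kinetics code.
# All convolution work happens on a fine uniform grid (default 1 s spacing),
# where the exponential convolution of a piecewise-linear curve has a closed
# form per step and reduces to a linear recurrence (evaluated in C by
# stats::filter).

#' @noRd
is_uniform_grid <- function(t, tol = 1e-9) {
  d <- diff(t)
  length(d) > 0L && all(d > 0) && (max(d) - min(d)) < tol * max(d)
}

# y(t) = integral_0^t x(s) exp(-lambda (t - s)) ds for x sampled on a uniform
# grid with spacing dt, x treated as piecewise linear. Exact for piecewise-
# linear input; lambda = 0 degenerates to the cumulative trapezoid.
#' @noRd
conv_exp <- function(x, dt, lambda) {
  n <- length(x)
  if (n < 2L) return(numeric(n))
  if (lambda * dt < 1e-12) {
    return(c(0, cumsum((x[-1] + x[-n]) / 2 * dt)))
  }
  E <- exp(-lambda * dt)
  a <- (1 - E) / lambda
  b <- (1 - E * (1 + lambda * dt)) / (lambda^2 * dt)
  dx <- x[-1] - x[-n]
  inc <- x[-1] * a - dx * b
  c(0, as.numeric(stats::filter(inc, E, method = "recursive")))
}

#' @noRd
cumtrapz_ <- function(t, y) {
  n <- length(t)
  c(0, cumsum((y[-1] + y[-n]) / 2 * diff(t)))
}

# Average a finely sampled instantaneous curve over each acquisition frame,
# via its cumulative integral (frame boundaries need not be grid points).
#' @noRd
frame_average_ <- function(t_min, y, start_min, end_min) {
  Y <- cumtrapz_(t_min, y)
  Ys <- stats::approx(t_min, Y, xout = start_min, rule = 2)$y
  Ye <- stats::approx(t_min, Y, xout = end_min, rule = 2)$y
  (Ye - Ys) / (end_min - start_min)
}

# Linear interpolation through the origin with flat extrapolation past the
# last sample: the convention used for sparse late arterial samples.
#' @noRd
interp_from_zero <- function(t_sample, y_sample, t_out) {
  stats::approx(c(0, t_sample), c(0, y_sample), xout = t_out, rule = 2)$y
}

# Evaluate an expression with a temporary RNG seed, restoring caller state.
#' @noRd
with_seed_ <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Derive a bounded child seed from a base seed and integer tags (R integers
# are 32-bit, so everything stays below 2^31 - 1).
#' @noRd
derive_seed <- function(seed, ...) {
  tags <- c(...)
  x <- as.double(seed) %% 2147483629
  for (k in tags) {
    x <- (x * 48271 + as.double(k) * 9679 + 1) %% 2147483629
  }
  as.integer(x) + 1L
}
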