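#' Arterial blood-sample series
#'
#' Container for one subject/session's arterial samples: whole-blood activity
#' at each sample time, optionally the measured total plasma activity, and a
#' measured parent (unmetabolized tracer) fraction for the metabolite subset.
#'
#' @param subject Subject identifier.
#' @param session Session label, one of `"baseline"`, `"D0+6"`, `"D0+35"`.
#' @param time_min Sample times in minutes post-injection, strictly
#'   increasing and non-negative.
#' @param blood_kBq_per_mL Whole-blood activity concentration per sample.
#' @param plasma_kBq_per_mL Optional total plasma activity per sample (`NA`
#'   where not measured); needed to fit the plasma-over-blood line unless
#'   precomputed ratios are supplied to [fit_plasma_over_blood()].
#' @param parent_fraction Measured parent fraction in `[0, 1]`, `NA` where
#'   not measured (by default only the 5, 25, 40, 50 min samples carry one).
#' @param sample_volume_ul Sample volume, metadata only.
#' @return A data frame of class `blood_samples` with one row per sample.
#' @export
blood_samples <- function(subject, session, time_min, blood_kBq_per_mL,
                          plasma_kBq_per_mL = NA_real_,
                          parent_fraction = NA_real_,
                          sample_volume_ul = 200) {
  session <- match.arg(session, c("baseline", "D0+6", "D0+35"))
  n <- length(time_min)
  if (n == 0L) stop("at least one sample is required")
  if (any(time_min < 0)) stop("sample times must be non-negative")
  if (any(diff(time_min) <= 0)) stop("sample times must be strictly increasing")
  if (length(blood_kBq_per_mL) != n)
    stop("blood_kBq_per_mL must have one value per sample time")
  if (any(blood_kBq_per_mL < 0, na.rm = TRUE)) stop("activities must be >= 0")
  pf <- rep_len(as.numeric(parent_fraction), n)
  if (any(pf < 0 | pf > 1, na.rm = TRUE))
    stop("measured parent fractions must lie in [0, 1]")
  pl <- rep_len(as.numeric(plasma_kBq_per_mL), n)
  if (any(pl < 0, na.rm = TRUE)) stop("activities must be >= 0")
  out <- data.frame(
    subject = as.character(subject), session = session,
    time_min = as.numeric(time_min),
    blood_kBq_per_mL = as.numeric(blood_kBq_per_mL),
    plasma_kBq_per_mL = pl, parent_fraction = pf
  )
  attr(out, "sample_volume_ul") <- sample_volume_ul
  class(out) <- c("blood_samples", "data.frame")
  out
}

#' Session metadata
#'
#' Injected dose and body weight for one imaging session; both enter the
#' standardized uptake value and the cross-session input-function rescaling.
#'
#' @param subject Subject identifier.
#' @param session Session label.
#' @param dose_MBq Injected dose in MBq, strictly positive.
#' @param weight_g Body weight in grams, strictly positive.
#' @return A list of class `session_meta`.
#' @export
session_meta <- function(subject, session, dose_MBq, weight_g) {
  if (!is.finite(dose_MBq) || dose_MBq <= 0) stop("dose_MBq must be > 0")
  if (!is.finite(weight_g) || weight_g <= 0) stop("weight_g must be > 0")
  structure(list(subject = as.character(subject),
                 session = as.character(session),
                 dose_MBq = as.numeric(dose_MBq),
                 weight_g = as.numeric(weight_g)),
            class = "session_meta")
}

#' Fit the plateau-biexponential parent-fraction model
#'
#' The plasma parent fraction is taken as exactly 1 up to a `begin` time
#' (negligible metabolites early on) and as a continuous biexponential decay
#' afterwards:
#' `pf(t) = a1 * exp(-b1 (t - begin)) + (1 - a1) * exp(-b2 (t - begin))`,
#' so the amplitudes sum to one and the curve is continuous at `begin`.
#' The three free parameters `(a1, b1, b2)` are estimated by constrained
#' least squares (`a1` in `[0, 1]`, rates non-negative) from the metabolite
#' subset of the samples, with several deterministic starts.
#'
#' @param samples A [blood_samples()] object (rows with a non-`NA`
#'   `parent_fraction` are used), or a data frame with columns `time_min` and
#'   `parent_fraction`.
#' @param begin Plateau end time in minutes; must precede the measured
#'   metabolite samples. Default 0.75 min.
#' @return A `parent_fraction_model` with elements `begin`, `a1`, `b1`,
#'   `a2`, `b2`, `rss` and `n`. Evaluate it with `predict(model, t)`.
#' @export
fit_parent_fraction <- function(samples, begin = 0.75) {
  if (!is.finite(begin) || begin < 0) stop("begin must be a non-negative time")
  t <- samples$time_min
  f <- samples$parent_fraction
  keep <- !is.na(f)
  t <- t[keep]; f <- f[keep]
  if (any(f < 0 | f > 1)) stop("measured parent fractions must lie in [0, 1]")
  use <- t > begin
  if (sum(use) < 2L)
    stop("insufficient data: need at least 2 metabolite samples after 'begin'")
  t <- t[use]; f <- f[use]
  tau <- t - begin

  sse <- function(p) {
    pred <- p[1] * exp(-p[2] * tau) + (1 - p[1]) * exp(-p[3] * tau)
    sum((f - pred)^2)
  }
  starts <- rbind(
    c(0.5, 0.0, 0.0),
    c(0.6, 0.4, 0.02),
    c(0.5, 1.0, 0.01),
    c(0.9, 0.1, 0.001),
    c(0.3, 2.0, 0.05)
  )
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- tryCatch(
      stats::nlminb(starts[i, ], sse,
                    lower = c(0, 0, 0), upper = c(1, 50, 50)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$objective < best$objective))
      best <- fit
  }
  if (is.null(best)) stop("parent-fraction fit failed from every start")
  p <- best$par
  structure(list(begin = begin, a1 = p[1], b1 = p[2],
                 a2 = 1 - p[1], b2 = p[3],
                 rss = best$objective, n = length(f)),
            class = "parent_fraction_model")
}

#' @param object A `parent_fraction_model`.
#' @param t Times in minutes.
#' @param ... Unused.
#' @rdname fit_parent_fraction
#' @export
predict.parent_fraction_model <- function(object, t, ...) {
  tau <- pmax(t - object$begin, 0)
  out <- object$a1 * exp(-object$b1 * tau) + object$a2 * exp(-object$b2 * tau)
  out[t <= object$begin] <- 1
  pmin(pmax(out, 0), 1)
}

#' Fit the straight-line plasma-over-blood ratio
#'
#' The ratio of total plasma to whole-blood activity is modeled as a straight
#' line in time, fitted by ordinary least squares to the per-sample ratios.
#'
#' @param samples A [blood_samples()] object with both `plasma_kBq_per_mL`
#'   and `blood_kBq_per_mL` present for at least two samples, or a data frame
#'   with columns `time_min` and `ratio` (precomputed ratios).
#' @param window_min Scan window over which the fitted line is checked for
#'   positivity; a non-positive value anywhere raises a warning and sets
#'   `nonpositive = TRUE` on the model.
#' @return A `plasma_over_blood_model` with elements `alpha` (intercept),
#'   `beta` (slope per minute), `nonpositive` and `n`.
#' @export
fit_plasma_over_blood <- function(samples, window_min = c(0, 60)) {
  if (!is.null(samples$ratio)) {
    t <- samples$time_min
    r <- samples$ratio
  } else {
    ok <- !is.na(samples$plasma_kBq_per_mL) & !is.na(samples$blood_kBq_per_mL) &
      samples$blood_kBq_per_mL > 0
    t <- samples$time_min[ok]
    r <- samples$plasma_kBq_per_mL[ok] / samples$blood_kBq_per_mL[ok]
  }
  if (length(r) < 2L)
    stop("insufficient data: need at least 2 plasma/blood ratio points")
  fit <- stats::lm.fit(cbind(1, t), r)
  alpha <- unname(fit$coefficients[1])
  beta <- unname(fit$coefficients[2])
  ends <- alpha + beta * window_min
  nonpos <- any(ends <= 0)
  if (nonpos)
    warning("fitted plasma-over-blood line is non-positive inside the scan window")
  structure(list(alpha = alpha, beta = beta,
                 nonpositive = nonpos, n = length(r)),
            class = "plasma_over_blood_model")
}

#' @param object A `plasma_over_blood_model`.
#' @param t Times in minutes.
#' @param ... Unused.
#' @rdname fit_plasma_over_blood
#' @export
predict.plasma_over_blood_model <- function(object, t, ...) {
  object$alpha + object$beta * t
}

#' @export
print.parent_fraction_model <- function(x, ...) {
  cat(sprintf(
    "Parent-fraction model: plateau 1 up to %.3g min, then %.3f*exp(-%.4g t') + %.3f*exp(-%.4g t')\n",
    x$begin, x$a1, x$b1, x$a2, x$b2))
  cat(sprintf("  fitted to %d samples, RSS = %.3g\n", x$n, x$rss))
  invisible(x)
}

#' @export
print.plasma_over_blood_model <- function(x, ...) {
  cat(sprintf("Plasma-over-blood line: ratio(t) = %.4f + %.5f * t [min]\n",
              x$alpha, x$beta))
  if (x$nonpositive) cat("  WARNING: line non-positive inside the scan window\n")
  invisible(x)
}
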