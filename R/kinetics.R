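#' Regional time-activity curve
#'
#' One region's frame-averaged, decay-corrected activity concentration over
#' an acquisition schedule.
#'
#' @param values Activity concentration (kBq/mL), one value per frame.
#' @param schedule A [frame_schedule()].
#' @param subject,session,region,side Optional identifiers (`side` is
#'   `"left"`, `"right"` or `"unpaired"`).
#' @return A list of class `tac`.
#' @export
tac <- function(values, schedule, subject = NA_character_,
                session = NA_character_, region = NA_character_,
                side = NA_character_) {
  if (!inherits(schedule, "frame_schedule")) stop("schedule must be a frame_schedule")
  if (length(values) != nrow(schedule))
    stop("need exactly one activity value per frame")
  if (!all(is.finite(values))) stop("activity values must be finite")
  structure(list(subject = subject, session = session, region = region,
                 side = side, schedule = schedule,
                 values = as.numeric(values),
                 negative_flag = any(values < 0)),
            class = "tac")
}

#' @noRd
check_coverage <- function(aif, schedule) {
  if (max(schedule$end_s) / 60 > max(aif$time_min) + 1e-9)
    stop("frame schedule extends past the input-function grid")
  if (!is_uniform_grid(aif$time_min))
    stop("input-function grid must be uniform for convolution")
}

#' Forward one-tissue compartment model
#'
#' Simulates the tissue curve of the reversible one-tissue compartment model
#' `dC_T/dt = K1 C_p - k2 C_T`, i.e. the convolution
#' `C_T(t) = K1 (C_p (*) exp(-k2 t))`, evaluated exactly for a
#' piecewise-linear input on the fine grid and then averaged over each
#' acquisition frame.
#'
#' @param K1 Delivery rate constant, mL cm^-3 min^-1, `>= 0`.
#' @param k2 Tissue efflux rate constant, min^-1, `> 0`.
#' @param aif An [input_function()].
#' @param schedule A [frame_schedule()] contained in the grid.
#' @return A [tac()] of frame-averaged values.
#' @export
solve_1tc_tac <- function(K1, k2, aif, schedule) {
  if (K1 < 0) stop("K1 must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  check_coverage(aif, schedule)
  dt <- aif$time_min[2] - aif$time_min[1]
  fine <- K1 * conv_exp(aif$plasma_kBq_per_mL, dt, k2)
  vals <- frame_average_(aif$time_min, fine, schedule$start_s / 60,
                         schedule$end_s / 60)
  tac(vals, schedule)
}

# Macro-parameter decomposition of the 2TC impulse response:
# C_T = phi1 (C_p (*) e^{-theta1 t}) + phi2 (C_p (*) e^{-theta2 t}).
#' @noRd
two_tc_macro <- function(K1, k2, k3, k4) {
  s <- k2 + k3 + k4
  disc <- sqrt(max(s^2 - 4 * k2 * k4, 0))
  theta1 <- (s + disc) / 2
  theta2 <- (s - disc) / 2
  if (theta1 - theta2 < 1e-12) {
    # coincident eigenvalues: nudge apart (measure-zero configuration)
    theta1 <- theta1 + 1e-10
  }
  phi1 <- K1 * (theta1 - k3 - k4) / (theta1 - theta2)
  phi2 <- K1 * (k3 + k4 - theta2) / (theta1 - theta2)
  list(theta1 = theta1, theta2 = theta2, phi1 = phi1, phi2 = phi2)
}

#' Forward two-tissue compartment model
#'
#' @inheritParams solve_1tc_tac
#' @param k3,k4 Exchange rate constants with the second (specific) tissue
#'   compartment, min^-1, `>= 0`.
#' @return A [tac()] of frame-averaged values.
#' @export
solve_2tc_tac <- function(K1, k2, k3, k4, aif, schedule) {
  if (K1 < 0 || k3 < 0 || k4 < 0) stop("rate constants must be >= 0")
  if (k2 <= 0) stop("k2 must be > 0")
  check_coverage(aif, schedule)
  dt <- aif$time_min[2] - aif$time_min[1]
  m <- two_tc_macro(K1, k2, k3, k4)
  fine <- m$phi1 * conv_exp(aif$plasma_kBq_per_mL, dt, m$theta1) +
    m$phi2 * conv_exp(aif$plasma_kBq_per_mL, dt, m$theta2)
  vals <- frame_average_(aif$time_min, fine, schedule$start_s / 60,
                         schedule$end_s / 60)
  tac(vals, schedule)
}

#' Kinetic fit result
#'
#' Uniform result record across all quantification methods. `vt` is present
#' for plasma-input methods (`LP`, `1TC`, `2TC`), `bp`/`dvr` for
#' reference-tissue methods (`LR`, `SRTM`), with `dvr = bp + 1` identically.
#' Failures are recorded as flags, never raised as errors, so cohort runs
#' always complete.
#'
#' @param model One of `"LP"`, `"1TC"`, `"2TC"`, `"LR"`, `"SRTM"`, `"SUV"`.
#' @param parameters Named list of fitted micro-parameters.
#' @param vt,bp,dvr Derived macro-parameters (use `NA` where not defined).
#' @param wrss Weighted residual sum of squares.
#' @param iterations Optimizer iteration count.
#' @param converged Logical optimizer status.
#' @param failed Logical failure flag.
#' @param failure_reason Short reason string when `failed`.
#' @param diagnostics Optional named list of extra diagnostics.
#' @return A list of class `kinetic_fit`.
#' @export
kinetic_fit_result <- function(model, parameters = list(), vt = NA_real_,
                               bp = NA_real_, dvr = NA_real_, wrss = NA_real_,
                               iterations = NA_integer_, converged = NA,
                               failed = FALSE, failure_reason = NA_character_,
                               diagnostics = list()) {
  model <- match.arg(model, c("LP", "1TC", "2TC", "LR", "SRTM", "SUV"))
  if (model %in% c("LR", "SRTM") && is.finite(bp) && is.na(dvr)) dvr <- bp + 1
  if (is.finite(bp) && is.finite(dvr) && abs(dvr - (bp + 1)) > 1e-12)
    stop("dvr must equal bp + 1")
  structure(list(model = model, parameters = parameters, vt = vt, bp = bp,
                 dvr = dvr, wrss = wrss, iterations = iterations,
                 converged = converged, failed = failed,
                 failure_reason = failure_reason, diagnostics = diagnostics),
            class = "kinetic_fit")
}

#' @export
print.kinetic_fit <- function(x, ...) {
  cat(sprintf("%s fit: ", x$model))
  if (x$failed) {
    cat(sprintf("FAILED (%s)\n", x$failure_reason))
    return(invisible(x))
  }
  if (is.finite(x$vt)) cat(sprintf("V_T = %.4g  ", x$vt))
  if (is.finite(x$bp)) cat(sprintf("BP_ND = %.4g  DVR = %.4g  ", x$bp, x$dvr))
  if (length(x$parameters))
    cat(paste(sprintf("%s=%.4g", names(x$parameters),
                      unlist(x$parameters)), collapse = " "))
  cat(sprintf("  WRSS = %.3g\n", x$wrss))
  invisible(x)
}

#' @noRd
fit_weights <- function(schedule, weights = c("duration", "uniform")) {
  weights <- match.arg(weights)
  w <- if (weights == "duration") schedule$dur_min else rep(1, nrow(schedule))
  w / sum(w)
}

#' Fit the one-tissue compartment model
#'
#' Weighted nonlinear least squares of the frame-averaged one-tissue model
#' against a measured time-activity curve. For fixed `k2` the model is
#' linear in `K1`, so `K1` is profiled out in closed form and the search is
#' one-dimensional in `log k2`, run from five log-spaced starts within the
#' bounds `K1` in `[0, 10]`, `k2` in `[1e-4, 10]`. `V_T = K1 / k2`.
#'
#' @param tac_obj A [tac()].
#' @param aif An [input_function()] covering the schedule.
#' @param weights `"duration"` (frame-duration weights, the default) or
#'   `"uniform"`.
#' @return A [kinetic_fit_result()] with model `"1TC"`. Non-convergence and
#'   degenerate (all-zero) curves are reported via the failure flag.
#' @export
fit_1tc <- function(tac_obj, aif, weights = "duration") {
  schedule <- tac_obj$schedule
  if (nrow(schedule) < 4L) stop("need at least 4 frames")
  check_coverage(aif, schedule)
  y <- tac_obj$values
  if (all(y == 0))
    return(kinetic_fit_result("1TC", failed = TRUE,
                              failure_reason = "degenerate"))
  w <- fit_weights(schedule, weights)
  dt <- aif$time_min[2] - aif$time_min[1]
  Cp <- aif$plasma_kBq_per_mL
  s0 <- schedule$start_s / 60
  e0 <- schedule$end_s / 60

  profile_k1 <- function(k2) {
    B <- frame_average_(aif$time_min, conv_exp(Cp, dt, k2), s0, e0)
    den <- sum(w * B * B)
    K1 <- if (den > 0) sum(w * B * y) / den else 0
    K1 <- min(max(K1, 0), 10)
    list(K1 = K1, B = B)
  }
  obj <- function(logk2) {
    p <- profile_k1(exp(logk2))
    sum(w * (y - p$K1 * p$B)^2)
  }
  starts <- log(10^seq(-3, 0.5, length.out = 5))
  best <- NULL
  iters <- 0L
  any_conv <- FALSE
  for (s in starts) {
    fit <- tryCatch(stats::nlminb(s, obj, lower = log(1e-4), upper = log(10)),
                    error = function(e) NULL)
    if (is.null(fit)) next
    iters <- iters + fit$iterations
    if (fit$convergence == 0) any_conv <- TRUE
    if (is.null(best) || fit$objective < best$objective) best <- fit
  }
  if (is.null(best))
    return(kinetic_fit_result("1TC", failed = TRUE,
                              failure_reason = "non-convergence"))
  k2 <- exp(best$par)
  p <- profile_k1(k2)
  kinetic_fit_result("1TC",
                     parameters = list(K1 = p$K1, k2 = k2),
                     vt = p$K1 / k2, wrss = best$objective,
                     iterations = iters, converged = any_conv,
                     failed = !any_conv,
                     failure_reason = if (any_conv) NA_character_ else
                       "non-convergence")
}

#' Fit the two-tissue compartment model
#'
#' Levenberg-Marquardt weighted least squares over `(K1, k2, k3, k4)` with
#' positivity bounds, run from several starts;
#' `V_T = (K1/k2) (1 + k3/k4)`. This model class is known to be fragile for
#' this tracer, so the failure flag is set not only on non-convergence but
#' also when identifying parameters are pinned at a bound or when the
#' relative standard error of `V_T` (delta method on the fit covariance)
#' exceeds 100%. A `k3` estimate at its lower bound of zero is the nested
#' one-tissue solution and is not treated as a failure.
#'
#' @inheritParams fit_1tc
#' @return A [kinetic_fit_result()] with model `"2TC"`.
#' @export
fit_2tc <- function(tac_obj, aif, weights = "duration") {
  schedule <- tac_obj$schedule
  if (nrow(schedule) < 4L) stop("need at least 4 frames")
  check_coverage(aif, schedule)
  y <- tac_obj$values
  if (all(y == 0))
    return(kinetic_fit_result("2TC", failed = TRUE,
                              failure_reason = "degenerate"))
  w <- fit_weights(schedule, weights)
  dt <- aif$time_min[2] - aif$time_min[1]
  Cp <- aif$plasma_kBq_per_mL
  s0 <- schedule$start_s / 60
  e0 <- schedule$end_s / 60
  model_fun <- function(K1, k2, k3, k4) {
    m <- two_tc_macro(K1, k2, k3, k4)
    fine <- m$phi1 * conv_exp(Cp, dt, m$theta1) +
      m$phi2 * conv_exp(Cp, dt, m$theta2)
    frame_average_(aif$time_min, fine, s0, e0)
  }
  lower <- c(K1 = 1e-6, k2 = 1e-4, k3 = 0, k4 = 1e-4)
  upper <- c(K1 = 10, k2 = 10, k3 = 5, k4 = 5)
  starts <- list(
    c(K1 = 0.1, k2 = 0.1, k3 = 0.01, k4 = 0.01),
    c(K1 = 0.1, k2 = 0.2, k3 = 0.05, k4 = 0.05),
    c(K1 = 0.5, k2 = 0.5, k3 = 0.1, k4 = 0.02)
  )
  best <- NULL
  iters <- 0L
  for (st in starts) {
    fit <- tryCatch(suppressWarnings(minpack.lm::nlsLM(
      y ~ model_fun(K1, k2, k3, k4),
      start = as.list(st), lower = lower, upper = upper,
      weights = w,
      control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit)) next
    iters <- iters + fit$convInfo$finIter
    if (is.null(best) || stats::deviance(fit) < stats::deviance(best)) best <- fit
  }
  if (is.null(best))
    return(kinetic_fit_result("2TC", failed = TRUE,
                              failure_reason = "non-convergence"))
  p <- as.list(stats::coef(best))
  ratio <- if (p$k3 <= 1e-8) 0 else p$k3 / p$k4
  vt <- (p$K1 / p$k2) * (1 + ratio)
  # delta-method relative standard error of V_T
  rse <- tryCatch({
    V <- stats::vcov(best)
    g <- c((1 / p$k2) * (1 + ratio),
           -(p$K1 / p$k2^2) * (1 + ratio),
           if (p$k3 <= 1e-8) 0 else p$K1 / (p$k2 * p$k4),
           if (p$k3 <= 1e-8) 0 else -p$K1 * p$k3 / (p$k2 * p$k4^2))
    sqrt(max(drop(t(g) %*% V %*% g), 0)) / vt
  }, error = function(e) NA_real_)
  tol <- 1e-6
  pinned <- (p$k2 <= lower["k2"] * (1 + tol)) ||
    (p$K1 >= upper["K1"] * (1 - tol)) ||
    (p$k2 >= upper["k2"] * (1 - tol)) ||
    (p$k3 >= upper["k3"] * (1 - tol)) ||
    (p$k4 >= upper["k4"] * (1 - tol)) ||
    (p$k3 > 1e-4 && p$k4 <= lower["k4"] * (1 + tol))
  failed <- pinned || (is.finite(rse) && rse > 1)
  reason <- if (pinned) "boundary-pinned" else
    if (is.finite(rse) && rse > 1) "vt-rse>100%" else NA_character_
  kinetic_fit_result("2TC", parameters = p, vt = vt,
                     wrss = stats::deviance(best), iterations = iters,
                     converged = TRUE, failed = failed,
                     failure_reason = reason,
                     diagnostics = list(vt_rse = rse))
}

# integral of the frame curve to each frame mid-time, trapezoid through the
# origin on the mid-time samples
#' @noRd
frame_integral_to_mid <- function(mid_min, values) {
  cumtrapz_(c(0, mid_min), c(0, values))[-1]
}

#' Logan graphical analysis with plasma input
#'
#' Ordinary least squares on the Logan linearization: for frames with
#' mid-time at or past `t_star`,
#' `int_0^t C_T / C_T(t)` is regressed on `int_0^t C_p / C_T(t)`.
#' The late-time slope estimates the total volume of distribution `V_T`; the
#' intercept is reported as a diagnostic. The plasma integral is computed by
#' trapezoid on the fine grid, the tissue integral by trapezoid on the frame
#' mid-times (with zero activity at time zero).
#'
#' @inheritParams fit_1tc
#' @param t_star Start of the linear window, minutes (default 15).
#' @return A [kinetic_fit_result()] with model `"LP"`. Frames with
#'   non-positive tissue activity in the window are dropped with a warning;
#'   fewer than 3 usable frames sets the failure flag.
#' @export
logan_vt <- function(tac_obj, aif, t_star = 15) {
  schedule <- tac_obj$schedule
  mid <- schedule$mid_min
  y_all <- tac_obj$values
  int_ct <- frame_integral_to_mid(mid, y_all)
  int_cp_fine <- cumtrapz_(aif$time_min, aif$plasma_kBq_per_mL)
  int_cp <- stats::approx(aif$time_min, int_cp_fine, xout = mid, rule = 2)$y
  use <- mid >= t_star
  if (sum(use) < 3L)
    return(kinetic_fit_result("LP", failed = TRUE,
                              failure_reason = "too-few-frames"))
  pos <- use & y_all > 0
  if (any(use & !pos)) {
    warning("dropping frames with non-positive tissue activity from the Logan window")
    if (sum(pos) < 3L)
      return(kinetic_fit_result("LP", failed = TRUE,
                                failure_reason = "nonpositive-tac"))
  }
  x <- int_cp[pos] / y_all[pos]
  yy <- int_ct[pos] / y_all[pos]
  fit <- stats::lm.fit(cbind(1, x), yy)
  kinetic_fit_result("LP",
                     parameters = list(intercept = unname(fit$coefficients[1])),
                     vt = unname(fit$coefficients[2]),
                     wrss = sum(fit$residuals^2),
                     iterations = 0L, converged = TRUE,
                     diagnostics = list(n_points = sum(pos)))
}

#' @noRd
default_k2a_grid <- function(n = 100) {
  exp(seq(log(0.006), log(0.6), length.out = n))
}

#' Precompute SRTM basis functions for a reference curve
#'
#' The simplified reference tissue model is solved by basis functions: for
#' each candidate efflux rate `k2a`, the convolution of the (finely
#' interpolated) reference curve with `exp(-k2a t)` is frame-averaged once
#' and reused across all target regions sharing the reference. Precomputing
#' the basis makes whole-cohort SRTM runs cheap.
#'
#' @param ref_tac Reference-region [tac()].
#' @param k2a_grid Candidate `k2a` values, min^-1; default 100 log-spaced
#'   values in `[0.006, 0.6]`.
#' @param grid Fine interpolation grid, minutes.
#' @return An object passed to [fit_srtm()]'s `basis` argument.
#' @export
srtm_basis <- function(ref_tac, k2a_grid = default_k2a_grid(),
                       grid = default_grid()) {
  schedule <- ref_tac$schedule
  ref_fine <- interp_from_zero(schedule$mid_min, ref_tac$values, grid)
  dt <- grid[2] - grid[1]
  s0 <- schedule$start_s / 60
  e0 <- schedule$end_s / 60
  B <- vapply(k2a_grid, function(k2a) {
    frame_average_(grid, conv_exp(ref_fine, dt, k2a), s0, e0)
  }, numeric(nrow(schedule)))
  basis_at <- function(k2a) {
    frame_average_(grid, conv_exp(ref_fine, dt, k2a), s0, e0)
  }
  list(k2a_grid = k2a_grid, B = B, ref_values = ref_tac$values,
       schedule = schedule, basis_at = basis_at)
}

#' Fit the simplified reference tissue model (basis functions)
#'
#' Fits `C_T = R1 C_ref + (k2 - R1 k2a) (C_ref (*) exp(-k2a t))` by weighted
#' linear least squares at each `k2a` on a log-spaced grid, followed by a
#' golden-section refinement of `k2a` around the best grid point.
#' `BP_ND = k2 / k2a - 1` (negative values are admitted -- near-absent
#' specific binding plus noise can push the target's distribution volume
#' below the reference's), and `DVR = BP_ND + 1`.
#'
#' @param tac_obj Target-region [tac()].
#' @param ref_tac Reference-region [tac()] on the same schedule (ignored if
#'   `basis` is supplied).
#' @param basis Optional precomputed [srtm_basis()].
#' @param weights `"duration"` or `"uniform"`.
#' @return A [kinetic_fit_result()] with model `"SRTM"` and parameters
#'   `R1`, `k2`, `k2a`. A best basis at the grid boundary is recorded in the
#'   diagnostics as `boundary = TRUE`.
#' @export
fit_srtm <- function(tac_obj, ref_tac = NULL, basis = NULL,
                     weights = "duration") {
  if (is.null(basis)) {
    if (is.null(ref_tac)) stop("supply either ref_tac or a precomputed basis")
    if (all(ref_tac$values == 0)) stop("reference curve is all zero")
    basis <- srtm_basis(ref_tac)
  }
  schedule <- basis$schedule
  if (!isTRUE(all.equal(schedule$mid_min, tac_obj$schedule$mid_min)))
    stop("target and reference must share the frame schedule")
  y <- tac_obj$values
  if (all(y == 0))
    return(kinetic_fit_result("SRTM", failed = TRUE,
                              failure_reason = "degenerate"))
  w <- fit_weights(schedule, weights)
  cref <- basis$ref_values
  sw <- sqrt(w)
  solve_one <- function(Bcol) {
    X <- cbind(cref, Bcol) * sw
    yw <- y * sw
    fit <- stats::lm.fit(X, yw)
    list(theta = fit$coefficients, rss = sum(fit$residuals^2))
  }
  k2a_grid <- basis$k2a_grid
  rss <- vapply(seq_along(k2a_grid), function(j) solve_one(basis$B[, j])$rss,
                0)
  j <- which.min(rss)
  # local refinement between the neighbours of the best grid point
  lo <- k2a_grid[max(j - 1L, 1L)]
  hi <- k2a_grid[min(j + 1L, length(k2a_grid))]
  k2a <- k2a_grid[j]
  if (hi > lo) {
    opt <- stats::optimize(function(k) solve_one(basis$basis_at(k))$rss,
                           interval = c(lo, hi), tol = 1e-6)
    if (opt$objective <= rss[j]) k2a <- opt$minimum
  }
  sol <- solve_one(if (k2a %in% k2a_grid) basis$B[, j] else basis$basis_at(k2a))
  R1 <- unname(sol$theta[1])
  k2 <- unname(sol$theta[2]) + R1 * k2a
  bp <- k2 / k2a - 1
  kinetic_fit_result("SRTM",
                     parameters = list(R1 = R1, k2 = k2, k2a = k2a),
                     bp = bp, dvr = bp + 1, wrss = sol$rss,
                     iterations = length(k2a_grid), converged = TRUE,
                     diagnostics = list(
                       boundary = j %in% c(1L, length(k2a_grid))))
}

#' Logan reference-tissue graphical analysis
#'
#' Ordinary least squares of `int_0^t C_T / C_T(t)` on
#' `(int_0^t C_ref + C_ref(t) / k2_prime) / C_T(t)` over frames with
#' mid-time at or past `t_star`; the slope is the distribution volume ratio
#' `DVR` and `BP_ND = DVR - 1`. When `k2_prime` is omitted the
#' `C_ref / k2_prime` term is dropped (late-time approximation) and the
#' diagnostics record `k2_prime_omitted = TRUE`.
#'
#' @inheritParams fit_srtm
#' @param k2_prime Reference-region efflux rate, min^-1, or `NULL` to use
#'   the late-time approximation.
#' @param t_star Start of the linear window, minutes (default 15).
#' @return A [kinetic_fit_result()] with model `"LR"`.
#' @export
logan_ref_dvr <- function(tac_obj, ref_tac, k2_prime = NULL, t_star = 15) {
  if (all(ref_tac$values == 0)) stop("reference curve is all zero")
  schedule <- tac_obj$schedule
  if (!isTRUE(all.equal(schedule$mid_min, ref_tac$schedule$mid_min)))
    stop("target and reference must share the frame schedule")
  if (!is.null(k2_prime) && k2_prime <= 0) stop("k2_prime must be > 0")
  mid <- schedule$mid_min
  y_all <- tac_obj$values
  int_ct <- frame_integral_to_mid(mid, y_all)
  int_cref <- frame_integral_to_mid(mid, ref_tac$values)
  num <- if (is.null(k2_prime)) int_cref else
    int_cref + ref_tac$values / k2_prime
  use <- mid >= t_star
  if (sum(use) < 3L)
    return(kinetic_fit_result("LR", failed = TRUE,
                              failure_reason = "too-few-frames"))
  pos <- use & y_all > 0
  if (any(use & !pos)) {
    warning("dropping frames with non-positive tissue activity from the Logan window")
    if (sum(pos) < 3L)
      return(kinetic_fit_result("LR", failed = TRUE,
                                failure_reason = "nonpositive-tac"))
  }
  x <- num[pos] / y_all[pos]
  yy <- int_ct[pos] / y_all[pos]
  fit <- stats::lm.fit(cbind(1, x), yy)
  dvr <- unname(fit$coefficients[2])
  kinetic_fit_result("LR",
                     parameters = list(intercept = unname(fit$coefficients[1])),
                     bp = dvr - 1, dvr = dvr,
                     wrss = sum(fit$residuals^2), iterations = 0L,
                     converged = TRUE,
                     diagnostics = list(k2_prime_omitted = is.null(k2_prime),
                                        n_points = sum(pos)))
}

#' Standardized uptake value of a time-activity curve
#'
#' Frame-duration-weighted mean concentration over the frames whose mid-time
#' falls inside the window, converted to SUV with the session's dose and
#' weight via [compute_suv()].
#'
#' @param tac_obj A [tac()] in kBq/mL.
#' @param meta A [session_meta()].
#' @param window_min Two-element window in minutes, default `c(0, 60)`.
#' @param convention SUV convention, see [compute_suv()].
#' @return A single SUV value.
#' @export
suv_summary <- function(tac_obj, meta, window_min = c(0, 60),
                        convention = "as-printed") {
  mid <- tac_obj$schedule$mid_min
  inside <- mid >= window_min[1] & mid <= window_min[2]
  if (!any(inside)) stop("no frame mid-times inside the window")
  dur <- tac_obj$schedule$dur_min[inside]
  mean_kBq <- sum(tac_obj$values[inside] * dur) / sum(dur)
  compute_suv(mean_kBq * 1000, meta$dose_MBq * 1e6, meta$weight_g,
              convention = convention)
}

#' Binding potential to distribution volume ratio
#'
#' `DVR = BP_ND + 1`; the shift avoids negative numbers when summarizing
#' regions whose binding potential is negative at baseline.
#'
#' @param bp Non-displaceable binding potential (may be negative).
#' @return The distribution volume ratio.
#' @export
bp_to_dvr <- function(bp) bp + 1
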