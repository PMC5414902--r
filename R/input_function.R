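#' Arterial input function container
#'
#' Holds the metabolite-corrected plasma parent activity together with the
#' companion whole-blood curve on a shared fine time grid. Activity is zero
#' at `t = 0` (tracer injected as a bolus at the scan start).
#'
#' @param time_min Strictly increasing time grid in minutes, starting at 0.
#' @param plasma_kBq_per_mL Plasma parent (unmetabolized tracer) activity.
#' @param blood_kBq_per_mL Companion whole-blood activity.
#' @param provenance One of `"measured"`, `"session-derived"`,
#'   `"mean-derived"`.
#' @param meta Optional [session_meta()] describing the session the curve
#'   belongs to (required downstream for cross-session rescaling of a mean
#'   input function).
#' @return A list of class `input_function`.
#' @export
input_function <- function(time_min, plasma_kBq_per_mL, blood_kBq_per_mL,
                           provenance = c("measured", "session-derived",
                                          "mean-derived"),
                           meta = NULL) {
  provenance <- match.arg(provenance)
  n <- length(time_min)
  if (n < 2L || any(diff(time_min) <= 0))
    stop("time grid must be strictly increasing with at least 2 points")
  if (length(plasma_kBq_per_mL) != n || length(blood_kBq_per_mL) != n)
    stop("plasma and blood curves must share the time grid")
  if (!all(is.finite(plasma_kBq_per_mL)) || !all(is.finite(blood_kBq_per_mL)))
    stop("input-function values must be finite")
  if (any(plasma_kBq_per_mL < -1e-12) || any(blood_kBq_per_mL < -1e-12))
    stop("input-function values must be >= 0")
  if (time_min[1] != 0) stop("time grid must start at 0")
  if (abs(plasma_kBq_per_mL[1]) > 1e-9 || abs(blood_kBq_per_mL[1]) > 1e-9)
    stop("activity at t = 0 must be 0")
  structure(list(time_min = as.numeric(time_min),
                 plasma_kBq_per_mL = pmax(as.numeric(plasma_kBq_per_mL), 0),
                 blood_kBq_per_mL = pmax(as.numeric(blood_kBq_per_mL), 0),
                 provenance = provenance,
                 meta = meta),
            class = "input_function")
}

#' @export
print.input_function <- function(x, ...) {
  cat(sprintf("Input function (%s): %d points over [0, %.1f] min, peak %.3g kBq/mL\n",
              x$provenance, length(x$time_min), max(x$time_min),
              max(x$plasma_kBq_per_mL)))
  invisible(x)
}

#' Assemble a metabolite-corrected arterial input function
#'
#' Interpolates the discrete whole-blood samples to a fine grid (linear
#' through the origin, flat extrapolation past the last sample), multiplies
#' by the fitted plasma-over-blood line to obtain total plasma activity, and
#' multiplies by the fitted parent-fraction curve to obtain the plasma
#' parent activity -- the arterial input function used for kinetic modeling.
#'
#' @param samples A [blood_samples()] object.
#' @param pf A `parent_fraction_model` from [fit_parent_fraction()].
#' @param pob A `plasma_over_blood_model` from [fit_plasma_over_blood()].
#' @param grid Time grid in minutes (default [default_grid()]); must cover
#'   the sample time range.
#' @param meta Optional [session_meta()] attached to the result.
#' @return An [input_function()] with provenance `"measured"`.
#' @export
build_aif <- function(samples, pf, pob, grid = default_grid(), meta = NULL) {
  if (any(diff(grid) <= 0)) stop("grid must be strictly increasing")
  if (max(grid) < max(samples$time_min) - 1e-9)
    stop("grid must cover the sample time range")
  blood <- interp_from_zero(samples$time_min, samples$blood_kBq_per_mL, grid)
  ratio <- predict(pob, grid)
  if (any(ratio <= 0))
    stop("plasma-over-blood ratio non-positive inside the scan window")
  plasma_total <- blood * ratio
  parent <- plasma_total * predict(pf, grid)
  input_function(grid, parent, blood, provenance = "measured", meta = meta)
}

#' Standardized uptake value
#'
#' Two conventions are provided. `"as-printed"` divides the concentration by
#' both the injected dose and the body weight,
#' `SUV = C / (dose * weight)`; `"conventional"` is the textbook definition
#' `SUV = C * weight / dose`. The package default is `"as-printed"`
#' throughout, and the choice also determines the cross-session
#' input-function rescaling factor in [normalize_aif_to_session()].
#'
#' @param concentration_Bq_per_mL Activity concentration, Bq/mL.
#' @param dose_Bq Injected dose in Bq, strictly positive.
#' @param weight_g Body weight in grams, strictly positive.
#' @param convention `"as-printed"` or `"conventional"`.
#' @return SUV value(s), same length as `concentration_Bq_per_mL`.
#' @examples
#' compute_suv(9250, 37e6, 250) # 1e-6, as-printed
#' compute_suv(9250, 37e6, 250, convention = "conventional") # 0.0625
#' @export
compute_suv <- function(concentration_Bq_per_mL, dose_Bq, weight_g,
                        convention = c("as-printed", "conventional")) {
  convention <- match.arg(convention)
  if (!is.finite(dose_Bq) || dose_Bq <= 0) stop("dose must be > 0")
  if (!is.finite(weight_g) || weight_g <= 0) stop("weight must be > 0")
  if (convention == "as-printed")
    concentration_Bq_per_mL / (dose_Bq * weight_g)
  else
    concentration_Bq_per_mL * weight_g / dose_Bq
}

# Scalar mapping source-session concentrations to target-session
# concentrations under the assumption that the input function is invariant
# in SUV units across sessions.
#' @noRd
suv_scale_factor <- function(source_meta, target_meta,
                             convention = c("as-printed", "conventional")) {
  convention <- match.arg(convention)
  if (convention == "as-printed")
    (target_meta$dose_MBq * target_meta$weight_g) /
      (source_meta$dose_MBq * source_meta$weight_g)
  else
    (target_meta$dose_MBq / target_meta$weight_g) /
      (source_meta$dose_MBq / source_meta$weight_g)
}

#' Derive an input function for a session without blood sampling
#'
#' In the study design, arterial blood is sampled only at the final session;
#' input functions for the earlier sessions are derived by rescaling that
#' session's curve under the assumption that the input function, expressed
#' in SUV units, is invariant across sessions of the same animal. Under the
#' `"as-printed"` SUV convention the rescaling factor is
#' `(dose_target * weight_target) / (dose_source * weight_source)`; under
#' the `"conventional"` one the weight ratio inverts.
#'
#' Rescaling factors compose exactly, so deriving A from B and then C from A
#' equals deriving C from B directly (the operation acts as a group action on
#' a subject's sessions); a session-derived curve is therefore accepted as a
#' source as well.
#'
#' @param source An [input_function()].
#' @param source_meta,target_meta [session_meta()] for the source and target
#'   sessions. Unless the source is mean-derived, both must belong to the
#'   same subject.
#' @param convention SUV convention, see [compute_suv()].
#' @return An [input_function()] with provenance `"session-derived"` and the
#'   target session's metadata attached.
#' @export
normalize_aif_to_session <- function(source, source_meta, target_meta,
                                     convention = c("as-printed",
                                                    "conventional")) {
  convention <- match.arg(convention)
  if (!inherits(source, "input_function")) stop("source must be an input_function")
  if (source$provenance != "mean-derived" &&
      !identical(source_meta$subject, target_meta$subject))
    stop("source and target sessions must belong to the same subject")
  s <- suv_scale_factor(source_meta, target_meta, convention)
  input_function(source$time_min,
                 source$plasma_kBq_per_mL * s,
                 source$blood_kBq_per_mL * s,
                 provenance = "session-derived",
                 meta = target_meta)
}

#' Cohort mean arterial input function
#'
#' Each measured input function is resampled to the common default grid and
#' min--max rescaled to `[0, 1]`; the rescaled curves are averaged pointwise,
#' and the average is restored to concentration units by the mean of the
#' individual `max - min` amplitudes. The mean injected dose and mean weight
#' of the contributing sessions are attached as the mean curve's metadata,
#' for subsequent dose/weight rescaling to individual sessions.
#'
#' @param aifs List of at least two [input_function()]s, all with provenance
#'   `"measured"`.
#' @param metas List of matching [session_meta()] objects.
#' @param grid Common grid for resampling; default [default_grid()].
#' @return An [input_function()] with provenance `"mean-derived"`.
#' @export
build_mean_aif <- function(aifs, metas, grid = default_grid()) {
  if (length(aifs) < 2L)
    stop("insufficient data: need at least 2 input functions")
  if (length(metas) != length(aifs))
    stop("need one session_meta per input function")
  if (!all(vapply(aifs, function(a) a$provenance, "") == "measured"))
    stop("all input functions entering the mean must be measured")
  resample <- function(a, what) {
    stats::approx(a$time_min, a[[what]], xout = grid, rule = 2)$y
  }
  P <- vapply(aifs, resample, numeric(length(grid)), what = "plasma_kBq_per_mL")
  B <- vapply(aifs, resample, numeric(length(grid)), what = "blood_kBq_per_mL")
  amp <- apply(P, 2, function(x) max(x) - min(x))
  if (any(amp <= 0)) stop("degenerate input: flat input function (max = min)")
  mins <- apply(P, 2, min)
  scaled <- sweep(sweep(P, 2, mins, "-"), 2, amp, "/")
  mean_shape <- rowMeans(scaled)
  plasma <- mean_shape * mean(amp) + mean(mins)
  # companion blood curve: same per-curve normalization so the plasma/blood
  # relationship of the average is preserved on the plasma amplitude scale
  blood <- rowMeans(sweep(sweep(B, 2, mins, "-"), 2, amp, "/")) * mean(amp) +
    mean(mins)
  meta <- session_meta(
    subject = "cohort-mean",
    session = metas[[1]]$session,
    dose_MBq = mean(vapply(metas, function(m) m$dose_MBq, 0)),
    weight_g = mean(vapply(metas, function(m) m$weight_g, 0))
  )
  plasma[1] <- 0
  blood[1] <- 0
  input_function(grid, pmax(plasma, 0), pmax(blood, 0),
                 provenance = "mean-derived", meta = meta)
}
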