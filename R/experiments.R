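# Cohort-level simulation experiments: parameter recovery, longitudinal
# effect detection and type-I control of the bilateral rule. These functions
# re-run the measurement pipeline (input-function reconstruction from blood
# tables, cross-session rescaling, kinetic fitting) on freshly generated
# cohorts, so every rate they report exercises the same code paths as a real
# analysis.

#' Rebuild per-session input functions for one subject from blood samples
#'
#' Fits the parent-fraction and plasma-over-blood models to the subject's
#' final-session blood table, assembles the measured input function, and
#' derives input functions for the other sessions by dose/weight rescaling.
#'
#' @param blood A [blood_samples()] object (final session).
#' @param metas Named list of [session_meta()] per session label; must
#'   include the blood session.
#' @param begin Parent-fraction plateau end, minutes.
#' @param grid Fine grid.
#' @param convention SUV convention used for the rescaling.
#' @return Named list of [input_function()]s per session label.
#' @export
rebuild_session_aifs <- function(blood, metas, begin = 0.75,
                                 grid = default_grid(),
                                 convention = "as-printed") {
  pf <- fit_parent_fraction(blood, begin = begin)
  pob <- fit_plasma_over_blood(blood)
  src_session <- blood$session[1]
  src_meta <- metas[[src_session]]
  measured <- build_aif(blood, pf, pob, grid = grid, meta = src_meta)
  out <- list()
  for (sess in names(metas)) {
    out[[sess]] <- if (sess == src_session) measured else
      normalize_aif_to_session(measured, src_meta, metas[[sess]],
                               convention = convention)
  }
  out
}

#' @noRd
tacs_to_matrix <- function(tacs_df, sched_n) {
  # long table -> list of per-(region,side) value vectors, assuming frames
  # are stored in order within each label block
  split(tacs_df$kBq_per_mL,
        paste(tacs_df$region, tacs_df$side, sep = ":"))
}

#' Estimate regional V_T across a simulated cohort
#'
#' Generates the requested sessions of a synthetic cohort, reconstructs each
#' blood-sampled subject's input functions from its blood table, and fits
#' the chosen plasma-input model to every regional curve.
#'
#' @param spec A [cohort_spec()].
#' @param sessions Sessions to model.
#' @param regions Region table subset (default all in `spec`).
#' @param method `"logan"` (fast graphical analysis) or `"1tc"`.
#' @param t_star Logan start time, minutes.
#' @param subjects Subject indices; defaults to the blood-sampled subset.
#' @return Data frame with columns `subject`, `session`, `region`, `side`,
#'   `vt`.
#' @export
cohort_vt_estimates <- function(spec, sessions = c("baseline", "D0+6"),
                                regions = NULL, method = c("logan", "1tc"),
                                t_star = 15,
                                subjects = seq_len(spec$n_with_blood)) {
  method <- match.arg(method)
  if (is.null(regions)) regions <- spec$regions
  blood_only <- setdiff("D0+35", sessions)
  bundle <- simulate_cohort(spec, subjects = subjects,
                            sessions = unique(c(sessions, "D0+35")),
                            regions = regions,
                            blood_only_sessions = blood_only)
  sched <- default_frame_schedule()
  rows <- vector("list", length(subjects) * length(sessions) * nrow(regions))
  ri <- 0L
  for (si in subjects) {
    subj_id <- sprintf("rat%02d", si)
    bl <- bundle$blood[bundle$blood$subject == subj_id, , drop = FALSE]
    class(bl) <- c("blood_samples", "data.frame")
    metas <- list()
    for (sess in unique(c(sessions, "D0+35"))) {
      sm <- bundle$sessions[bundle$sessions$subject == subj_id &
                              bundle$sessions$session == sess, ]
      metas[[sess]] <- session_meta(subj_id, sess, sm$dose_MBq, sm$weight_g)
    }
    aifs <- rebuild_session_aifs(bl, metas, begin = spec$pf_truth$begin)
    for (sess in sessions) {
      sub_tacs <- bundle$tacs[bundle$tacs$subject == subj_id &
                                bundle$tacs$session == sess, , drop = FALSE]
      curves <- tacs_to_matrix(sub_tacs, nrow(sched))
      for (j in seq_len(nrow(regions))) {
        lab <- paste(regions$region[j], regions$side[j], sep = ":")
        tc <- tac(curves[[lab]], sched, subject = subj_id, session = sess,
                  region = regions$region[j], side = regions$side[j])
        fit <- if (method == "logan")
          logan_vt(tc, aifs[[sess]], t_star = t_star)
        else fit_1tc(tc, aifs[[sess]])
        ri <- ri + 1L
        rows[[ri]] <- data.frame(subject = subj_id, session = sess,
                                 region = regions$region[j],
                                 side = regions$side[j],
                                 vt = if (fit$failed) NA_real_ else fit$vt)
      }
    }
  }
  do.call(rbind, rows[seq_len(ri)])
}

#' Bilateral detection rates over repeated simulated cohorts
#'
#' Repeats the generate-and-analyze experiment `n_runs` times with distinct
#' derived seeds and records, per region, whether the session contrast was
#' bilaterally significant (paired t-test, both sides below `alpha`).
#'
#' @param spec A [cohort_spec()]; its seed is re-derived per run.
#' @param n_runs Number of simulated cohorts.
#' @param regions Character vector of region names to test (bilateral
#'   tissue regions).
#' @param earlier,later Session labels contrasted.
#' @param alpha Significance level.
#' @param method Plasma-input model for the V_T estimates.
#' @param seed Base seed for the run sequence.
#' @return List with `rates` (named detection proportion per region) and
#'   `hits` (logical matrix runs x regions).
#' @export
bilateral_detection_rates <- function(spec, n_runs = 100,
                                      regions = c("hippocampus", "amygdala",
                                                  "temporal_cortex",
                                                  "thalamus", "brainstem"),
                                      earlier = "baseline", later = "D0+6",
                                      alpha = 0.01, method = "logan",
                                      seed = spec$seed) {
  reg_tab <- spec$regions[spec$regions$region %in% regions, , drop = FALSE]
  hits <- matrix(NA, n_runs, length(regions),
                 dimnames = list(NULL, regions))
  for (r in seq_len(n_runs)) {
    spec_r <- spec
    spec_r$seed <- derive_seed(seed, 11L, r)
    est <- cohort_vt_estimates(spec_r, sessions = c(earlier, later),
                               regions = reg_tab, method = method)
    for (rg in regions) {
      p_sides <- vapply(c("left", "right"), function(sd) {
        e <- est[est$region == rg & est$side == sd, ]
        ve <- e$vt[e$session == earlier][order(e$subject[e$session == earlier])]
        vl <- e$vt[e$session == later][order(e$subject[e$session == later])]
        ok <- !is.na(ve) & !is.na(vl)
        if (sum(ok) < 2L) return(NA_real_)
        paired_t_test(ve[ok], vl[ok])$p_value
      }, 0)
      hits[r, rg] <- bilateral_significance(p_sides[1], p_sides[2], alpha)
    }
  }
  list(rates = colMeans(hits, na.rm = TRUE), hits = hits)
}

#' Group-mean percent change of a region across repeated cohorts
#'
#' For each simulated cohort, estimates the percent change of the group-mean
#' regional V_T between two sessions (sides and subjects averaged per
#' session) with the chosen plasma-input model.
#'
#' @inheritParams bilateral_detection_rates
#' @param region Region name.
#' @return Numeric vector of percent changes, one per run.
#' @export
percent_change_runs <- function(spec, n_runs = 50, region = "hippocampus",
                                earlier = "baseline", later = "D0+6",
                                method = "1tc", seed = spec$seed) {
  reg_tab <- spec$regions[spec$regions$region == region, , drop = FALSE]
  vapply(seq_len(n_runs), function(r) {
    spec_r <- spec
    spec_r$seed <- derive_seed(seed, 13L, r)
    est <- cohort_vt_estimates(spec_r, sessions = c(earlier, later),
                               regions = reg_tab, method = method)
    means <- tapply(est$vt, est$session, mean, na.rm = TRUE)
    percent_change(means[[earlier]], means[[later]])
  }, 0)
}
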