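#' Default region label table
#'
#' Twenty-nine atlas labels: thirteen bilateral tissue regions (26 labels)
#' plus three ventricle labels. Ventricles are excluded from whole-brain
#' summaries by default.
#'
#' @return Data frame with columns `region`, `side`, `is_ventricle`.
#' @export
default_region_table <- function() {
  tissue <- c("hippocampus", "amygdala", "temporal_cortex", "thalamus",
              "frontal_cortex", "parietal_cortex", "occipital_cortex",
              "entorhinal_cortex", "striatum", "hypothalamus", "septum",
              "cerebellum", "brainstem")
  out <- rbind(
    data.frame(region = rep(tissue, each = 2),
               side = rep(c("left", "right"), length(tissue)),
               is_ventricle = FALSE),
    data.frame(region = c("lateral_ventricle", "lateral_ventricle",
                          "third_ventricle"),
               side = c("left", "right", "unpaired"),
               is_ventricle = TRUE)
  )
  out
}

#' Default true V_T multipliers per session
#'
#' Session multipliers applied to each region's baseline total volume of
#' distribution. The acute (D0+6) multipliers for the hypothesized regions
#' encode approximate doublings in the temporal/limbic regions and
#' near-stability in the brainstem; the chronic (D0+35) multipliers apply
#' the corresponding partial-return decreases to the acute levels.
#'
#' @return Data frame with columns `region`, `baseline`, `D0+6`, `D0+35`.
#' @export
default_vt_multipliers <- function() {
  m6 <- c(hippocampus = 2.18, amygdala = 1.86, temporal_cortex = 1.94,
          thalamus = 1.79, frontal_cortex = 1.50, parietal_cortex = 1.40,
          occipital_cortex = 1.35, entorhinal_cortex = 1.60,
          striatum = 1.45, hypothalamus = 1.40, septum = 1.45,
          cerebellum = 1.25, brainstem = 1.17,
          lateral_ventricle = 1.00, third_ventricle = 1.00)
  drop35 <- c(hippocampus = 0.53, amygdala = 0.44, temporal_cortex = 0.47,
              thalamus = 0.44, frontal_cortex = 0.45, parietal_cortex = 0.45,
              occipital_cortex = 0.45, entorhinal_cortex = 0.45,
              striatum = 0.45, hypothalamus = 0.45, septum = 0.45,
              cerebellum = 0.45, brainstem = 0.31,
              lateral_ventricle = 0.00, third_ventricle = 0.00)
  data.frame(region = names(m6), baseline = 1,
             `D0+6` = unname(m6),
             `D0+35` = unname(m6 * (1 - drop35)),
             check.names = FALSE)
}

#' Default input-function template parameters
#'
#' Linear rise from zero to a peak at `t_peak`, then a tri-exponential
#' decay continuous at the peak. Amplitude fractions sum to one.
#'
#' @return Named list of template parameters.
#' @export
default_template_params <- function() {
  list(t_peak = 0.5, peak_kBq_per_mL = 100,
       fractions = c(0.65, 0.25, 0.10),
       lambda_per_min = c(4, 0.5, 0.02))
}

#' Parametric template arterial input function
#'
#' @param params Template parameters, see [default_template_params()]; all
#'   must be non-negative and the curve non-negative on the grid.
#' @param grid Time grid in minutes.
#' @return An [input_function()] (whole-blood companion set equal to the
#'   plasma curve divided by a unit ratio; the generator replaces it).
#' @export
make_template_aif <- function(params = default_template_params(),
                              grid = default_grid()) {
  with(params, {
    if (t_peak <= 0 || peak_kBq_per_mL < 0 || any(fractions < 0) ||
        any(lambda_per_min < 0))
      stop("template parameters must be non-negative (t_peak > 0)")
    if (abs(sum(fractions) - 1) > 1e-9)
      stop("amplitude fractions must sum to 1")
    y <- ifelse(grid <= t_peak,
                peak_kBq_per_mL * grid / t_peak,
                peak_kBq_per_mL *
                  colSums(fractions * exp(-outer(lambda_per_min,
                                                 pmax(grid - t_peak, 0)))))
    if (any(y < 0)) stop("template curve must be non-negative")
    input_function(grid, y, y, provenance = "measured")
  })
}

#' Synthetic cohort specification
#'
#' Complete ground-truth description of a simulated longitudinal cohort:
#' study design (subjects, sessions, regions, schedules), kinetic truth
#' (baseline `V_T`, per-session multipliers, fixed `K1`), biological
#' variability (between-subject baseline spread, per-side response
#' heterogeneity after the insult), blood-side truth (input-function
#' template, parent-fraction and plasma-over-blood models), measurement
#' noise, dosimetry, and the seed that fully determines every draw.
#'
#' @param n_subjects Number of subjects (default 9).
#' @param n_with_blood Number of subjects with measured final-session
#'   arterial blood (default 7; the remainder exercise the
#'   reference-region-only and mean-input-function paths).
#' @param sessions Session labels in temporal order.
#' @param regions Region label table, see [default_region_table()].
#' @param multipliers Per-region per-session true `V_T` multipliers
#'   relative to baseline, see [default_vt_multipliers()].
#' @param baseline_vt Baseline tissue `V_T` level (arbitrary units; only
#'   ratios are compared downstream).
#' @param ventricle_vt Baseline `V_T` assigned to ventricle labels.
#' @param baseline_sdlog Between-subject lognormal spread of baseline `V_T`
#'   (shared across regions within subject).
#' @param response_sdlog Lognormal spread of each post-insult multiplier,
#'   drawn independently per subject, region, side and session: hemispheric
#'   asymmetry of the inflammatory response.
#' @param K1 Fixed delivery rate constant used for every region.
#' @param noise_cov Gaussian frame-noise coefficient of variation
#'   (sd = `noise_cov` x frame value, floor-clamped at 0).
#' @param template Input-function template parameters.
#' @param amp_sdlog Lognormal between-subject jitter of the input-function
#'   amplitude.
#' @param pf_truth True parent-fraction model parameters
#'   (`begin`, `a1`, `b1`, `b2`).
#' @param pob_truth True plasma-over-blood line (`alpha`, `beta`).
#' @param dose_mean_MBq,dose_sd_MBq Injected dose distribution.
#' @param weight_mean_g Mean body weight per session (growing trajectory).
#' @param weight_sdlog Between-subject lognormal weight jitter (shared
#'   across sessions).
#' @param seed Integer seed determining all outputs.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_subjects = 9, n_with_blood = 7,
                        sessions = c("baseline", "D0+6", "D0+35"),
                        regions = default_region_table(),
                        multipliers = default_vt_multipliers(),
                        baseline_vt = 1.0, ventricle_vt = 0.3,
                        baseline_sdlog = 0.10, response_sdlog = 0.15,
                        K1 = 0.1, noise_cov = 0.05,
                        template = default_template_params(),
                        amp_sdlog = 0.10,
                        pf_truth = list(begin = 0.75, a1 = 0.6, b1 = 0.4,
                                        b2 = 0.02),
                        pob_truth = list(alpha = 1.25, beta = 0.003),
                        dose_mean_MBq = 37, dose_sd_MBq = 3,
                        weight_mean_g = c(baseline = 244, `D0+6` = 260,
                                          `D0+35` = 320),
                        weight_sdlog = 0.08,
                        seed = 1L) {
  if (n_with_blood > n_subjects) stop("n_with_blood cannot exceed n_subjects")
  if (any(multipliers[, sessions[sessions %in% names(multipliers)]] <= 0))
    stop("multipliers must be > 0")
  tissue <- multipliers$region[!multipliers$region %in%
                                 c("lateral_ventricle", "third_ventricle")]
  m6 <- multipliers[multipliers$region %in% tissue, "D0+6"]
  if ("brainstem" %in% tissue && length(m6) > 1) {
    bs <- multipliers[multipliers$region == "brainstem", "D0+6"]
    if (abs(bs - 1) > min(abs(m6 - 1)))
      stop("brainstem D0+6 multiplier must be closest to 1 among tissue regions")
  }
  structure(list(
    n_subjects = n_subjects, n_with_blood = n_with_blood,
    sessions = sessions, regions = regions, multipliers = multipliers,
    baseline_vt = baseline_vt, ventricle_vt = ventricle_vt,
    baseline_sdlog = baseline_sdlog, response_sdlog = response_sdlog,
    K1 = K1, noise_cov = noise_cov, template = template,
    amp_sdlog = amp_sdlog, pf_truth = pf_truth, pob_truth = pob_truth,
    dose_mean_MBq = dose_mean_MBq, dose_sd_MBq = dose_sd_MBq,
    weight_mean_g = weight_mean_g, weight_sdlog = weight_sdlog,
    seed = as.integer(seed)), class = "cohort_spec")
}

#' Null-cohort specification
#'
#' Identical truth in every session (all multipliers 1, no response
#' heterogeneity): measurement noise is the only source of change, for
#' type-I-error studies of the significance rules.
#'
#' @param seed Integer seed.
#' @param ... Further arguments passed to [cohort_spec()].
#' @return A `cohort_spec`.
#' @export
null_cohort_spec <- function(seed = 1L, ...) {
  m <- default_vt_multipliers()
  m[["D0+6"]] <- 1
  m[["D0+35"]] <- 1
  cohort_spec(multipliers = m, response_sdlog = 0, seed = seed, ...)
}

# subject-level latent variables, deterministic given (spec$seed, subject)
#' @noRd
subject_truth <- function(spec, si) {
  with_seed_(derive_seed(spec$seed, 1L, si), {
    list(
      baseline_mult = exp(stats::rnorm(1, 0, spec$baseline_sdlog)),
      amp_mult = exp(stats::rnorm(1, 0, spec$amp_sdlog)),
      weight_mult = exp(stats::rnorm(1, 0, spec$weight_sdlog))
    )
  })
}

#' Generate one synthetic session
#'
#' Draws the session's dose and weight, scales the subject's input-function
#' template by the dose-weight factor (the input function is invariant in
#' SUV units across a subject's sessions by construction), derives the
#' whole-blood and total-plasma curves from the true parent-fraction and
#' plasma-over-blood models, reads off the arterial samples at the default
#' 13 times (parent fractions at the 4 metabolite times), simulates each
#' region's time-activity curve with the one-tissue forward model
#' (`K1` fixed, `k2 = K1 / V_T_true`) and adds floor-clamped Gaussian frame
#' noise. All draws are keyed to (`spec$seed`, subject, session, label) so
#' outputs are reproducible label-by-label regardless of which regions are
#' requested.
#'
#' @param spec A [cohort_spec()].
#' @param subject Subject index in `1:n_subjects`.
#' @param session Session label present in `spec$sessions`.
#' @param regions Optional subset of `spec$regions` (a data frame of the
#'   same shape) to simulate; `NULL` for all, a zero-row table for blood
#'   and metadata only.
#' @return List with `blood` (a [blood_samples()] or `NULL` for sessions or
#'   subjects without sampling), `tacs` (long data frame), `meta`
#'   ([session_meta()]), and `truth` (true parameters per label plus the
#'   session scale factor).
#' @export
generate_session <- function(spec, subject, session, regions = NULL) {
  si <- as.integer(subject)
  if (si < 1L || si > spec$n_subjects) stop("unknown subject index")
  ki <- match(session, spec$sessions)
  if (is.na(ki)) stop("unknown session label")
  if (is.null(regions)) regions <- spec$regions
  subj <- subject_truth(spec, si)
  subj_id <- sprintf("rat%02d", si)

  meta <- with_seed_(derive_seed(spec$seed, 2L, si, ki), {
    dose <- max(stats::rnorm(1, spec$dose_mean_MBq, spec$dose_sd_MBq),
                spec$dose_mean_MBq / 4)
    session_meta(subj_id, session, dose,
                 spec$weight_mean_g[[session]] * subj$weight_mult)
  })

  # true parent plasma input: template scaled so the curve is an exact
  # SUV-scaled copy across the subject's sessions (as-printed convention)
  ref <- session_meta(subj_id, session, spec$dose_mean_MBq, 250)
  s_k <- suv_scale_factor(ref, meta) * subj$amp_mult
  grid <- default_grid()
  template <- make_template_aif(spec$template, grid)
  parent <- template$plasma_kBq_per_mL * s_k
  pf_true <- structure(list(begin = spec$pf_truth$begin, a1 = spec$pf_truth$a1,
                            b1 = spec$pf_truth$b1, a2 = 1 - spec$pf_truth$a1,
                            b2 = spec$pf_truth$b2, rss = 0, n = 0L),
                       class = "parent_fraction_model")
  pf_vals <- predict(pf_true, grid)
  plasma_total <- parent / pf_vals
  pob_vals <- spec$pob_truth$alpha + spec$pob_truth$beta * grid
  blood_fine <- plasma_total / pob_vals
  aif_true <- input_function(grid, parent, blood_fine,
                             provenance = "measured", meta = meta)

  blood <- NULL
  if (session == "D0+35" && si <= spec$n_with_blood) {
    ts <- default_arterial_times()
    tm <- default_metabolite_times()
    pf_s <- rep(NA_real_, length(ts))
    pf_s[match(tm, ts)] <- predict(pf_true, tm)
    blood <- blood_samples(
      subj_id, session, ts,
      blood_kBq_per_mL = stats::approx(grid, blood_fine, xout = ts)$y,
      plasma_kBq_per_mL = stats::approx(grid, plasma_total, xout = ts)$y,
      parent_fraction = pf_s)
  }

  sched <- default_frame_schedule()
  mults <- spec$multipliers
  n_lab <- nrow(regions)
  vt_true <- numeric(n_lab)
  values <- matrix(0, nrow(sched), n_lab)
  label_index <- match(paste(regions$region, regions$side),
                       paste(spec$regions$region, spec$regions$side))
  for (j in seq_len(n_lab)) {
    rg <- regions$region[j]
    vent <- regions$is_ventricle[j]
    base <- if (vent) spec$ventricle_vt else spec$baseline_vt
    mult <- mults[match(rg, mults$region), session]
    if (is.na(mult)) stop(sprintf("no multiplier for region '%s'", rg))
    draw_seed <- derive_seed(spec$seed, 3L, si, ki, label_index[j])
    draws <- with_seed_(draw_seed, {
      j_resp <- if (!vent && session != "baseline" && spec$response_sdlog > 0)
        exp(stats::rnorm(1, 0, spec$response_sdlog)) else 1
      eps <- stats::rnorm(nrow(sched))
      list(j_resp = j_resp, eps = eps)
    })
    vt <- base * subj$baseline_mult * mult * draws$j_resp
    vt_true[j] <- vt
    ct <- solve_1tc_tac(spec$K1, spec$K1 / vt, aif_true, sched)$values
    if (spec$noise_cov > 0)
      ct <- pmax(ct + draws$eps * spec$noise_cov * ct, 0)
    values[, j] <- ct
  }
  tacs <- if (n_lab > 0) data.frame(
    subject = subj_id, session = session,
    region = rep(regions$region, each = nrow(sched)),
    side = rep(regions$side, each = nrow(sched)),
    frame_start_s = rep(sched$start_s, n_lab),
    frame_end_s = rep(sched$end_s, n_lab),
    kBq_per_mL = as.vector(values)
  ) else NULL

  list(blood = blood, tacs = tacs, meta = meta,
       truth = list(subject = subj_id, session = session,
                    vt_true = stats::setNames(vt_true,
                      paste(regions$region, regions$side, sep = ":")),
                    K1 = spec$K1, scale = s_k,
                    dose_MBq = meta$dose_MBq, weight_g = meta$weight_g,
                    aif_true = aif_true))
}

#' Simulate a cohort in memory
#'
#' Runs [generate_session()] over the requested subjects and sessions and
#' binds the results into a bundle of long tables plus the ground-truth
#' records. `simulate_cohort()` is the workhorse behind
#' [generate_cohort()]'s file bundle and the package's experiments.
#'
#' @param spec A [cohort_spec()].
#' @param subjects Integer subject indices (default all).
#' @param sessions Session labels (default all in `spec`).
#' @param regions Region subset as in [generate_session()]; sessions listed
#'   in `blood_only_sessions` are generated without time-activity curves.
#' @param blood_only_sessions Sessions for which only blood and metadata are
#'   needed (speeds up experiments that model a subset of sessions).
#' @return List with `tacs`, `blood`, `sessions` (data frames), `truth`
#'   (list per subject x session) and `manifest`.
#' @export
simulate_cohort <- function(spec, subjects = seq_len(spec$n_subjects),
                            sessions = spec$sessions, regions = NULL,
                            blood_only_sessions = character(0)) {
  tac_list <- list(); blood_list <- list(); meta_rows <- list()
  truth <- list()
  empty_regions <- spec$regions[0, , drop = FALSE]
  for (si in subjects) {
    for (sess in sessions) {
      regs <- if (sess %in% blood_only_sessions) empty_regions else regions
      g <- generate_session(spec, si, sess, regions = regs)
      key <- paste0(g$truth$subject, "|", sess)
      truth[[key]] <- g$truth
      if (!is.null(g$tacs)) tac_list[[key]] <- g$tacs
      if (!is.null(g$blood)) blood_list[[key]] <- as.data.frame(g$blood)
      meta_rows[[key]] <- data.frame(subject = g$meta$subject, session = sess,
                                     dose_MBq = g$meta$dose_MBq,
                                     weight_g = g$meta$weight_g)
    }
  }
  tacs <- if (length(tac_list)) do.call(rbind, c(tac_list, make.row.names = FALSE)) else NULL
  blood <- if (length(blood_list)) do.call(rbind, c(blood_list, make.row.names = FALSE)) else NULL
  sessions_df <- do.call(rbind, c(meta_rows, make.row.names = FALSE))
  manifest <- list(
    n_subjects = length(subjects), sessions = sessions,
    n_region_labels = if (is.null(regions)) nrow(spec$regions) else nrow(regions),
    n_tissue_labels = sum(!(if (is.null(regions)) spec$regions else regions)$is_ventricle),
    subjects_with_blood = sum(subjects <= spec$n_with_blood),
    seed = spec$seed
  )
  list(tacs = tacs, blood = blood, sessions = sessions_df, truth = truth,
       manifest = manifest)
}

#' Write a synthetic cohort bundle to disk
#'
#' Writes `tacs.csv`, `blood.csv`, `sessions.csv`, `truth.json` and
#' `manifest.json` (seed and spec hash) to a directory.
#'
#' @param spec A [cohort_spec()].
#' @param dir Output directory.
#' @param overwrite Refuse to write into an existing non-empty directory
#'   unless `TRUE`.
#' @return Invisibly, the manifest list.
#' @export
generate_cohort <- function(spec, dir, overwrite = FALSE) {
  if (dir.exists(dir) && length(list.files(dir)) > 0 && !overwrite)
    stop(sprintf("output directory '%s' is not empty (use overwrite = TRUE)",
                 dir))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  bundle <- simulate_cohort(spec)
  utils::write.csv(bundle$tacs, file.path(dir, "tacs.csv"), row.names = FALSE)
  utils::write.csv(bundle$blood, file.path(dir, "blood.csv"),
                   row.names = FALSE)
  utils::write.csv(bundle$sessions, file.path(dir, "sessions.csv"),
                   row.names = FALSE)
  truth_slim <- lapply(bundle$truth, function(tr) {
    tr$aif_true <- NULL
    tr
  })
  jsonlite::write_json(truth_slim, file.path(dir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  spec_json <- jsonlite::toJSON(spec[setdiff(names(spec), "regions")],
                                auto_unbox = TRUE, digits = NA, force = TRUE)
  tmp <- tempfile(); writeLines(spec_json, tmp)
  manifest <- c(bundle$manifest,
                list(spec_md5 = unname(tools::md5sum(tmp))))
  unlink(tmp)
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(manifest)
}
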