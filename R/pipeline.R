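#' Study configuration
#'
#' Validated configuration for [run_pipeline()]. Defaults follow the study
#' conventions: brainstem reference region, ventricles excluded from
#' summaries, as-printed SUV convention, Logan start time 15 min, and the
#' Logan-reference `k2_prime` taken as the session's median SRTM-derived
#' reference efflux.
#'
#' @param tac_table,blood_table,sessions_table Paths to the input tables
#'   (`blood_table` may be `NULL` when only reference-region models and SUV
#'   are requested).
#' @param output_dir Directory for the report bundle.
#' @param models Character vector among `"LP"`, `"1TC"`, `"2TC"`, `"LR"`,
#'   `"SRTM"`, `"SUV"`. The two-tissue model is available but not part of
#'   the default list (it fails frequently for this tracer).
#' @param reference_region Reference region for `LR`/`SRTM`.
#' @param suv_convention `"as-printed"` or `"conventional"`.
#' @param t_star Logan start time, minutes.
#' @param k2_prime `"srtm-median"`, a number (min^-1), or `NA` to use the
#'   late-time Logan-reference approximation.
#' @param suv_window SUV averaging window, minutes.
#' @param alpha Significance level for the group report.
#' @param aggregation `"mean-of-sides"` or `"per-side"`.
#' @param exclusions Regions excluded from whole-brain summaries.
#' @param seed Seed recorded in the run manifest (the pipeline itself is
#'   deterministic).
#' @return A list of class `study_config`.
#' @export
study_config <- function(tac_table, sessions_table, blood_table = NULL,
                         output_dir = tempfile("tspoquant-run-"),
                         models = c("LP", "1TC", "LR", "SRTM", "SUV"),
                         reference_region = "brainstem",
                         suv_convention = "as-printed",
                         t_star = 15, k2_prime = "srtm-median",
                         suv_window = c(0, 60), alpha = 0.05,
                         aggregation = "mean-of-sides",
                         exclusions = default_exclusions(), seed = 1L) {
  if (length(models) == 0L) stop("model list must be non-empty")
  models <- match.arg(models, c("LP", "1TC", "2TC", "LR", "SRTM", "SUV"),
                      several.ok = TRUE)
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  suv_convention <- match.arg(suv_convention,
                              c("as-printed", "conventional"))
  aggregation <- match.arg(aggregation, c("mean-of-sides", "per-side"))
  structure(list(tac_table = tac_table, blood_table = blood_table,
                 sessions_table = sessions_table, output_dir = output_dir,
                 models = models, reference_region = reference_region,
                 suv_convention = suv_convention, t_star = t_star,
                 k2_prime = k2_prime, suv_window = suv_window,
                 alpha = alpha, aggregation = aggregation,
                 exclusions = exclusions, seed = as.integer(seed)),
            class = "study_config")
}

#' Load a study configuration from a YAML file
#' @param path YAML file with fields named as in [study_config()].
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file not found: %s", path))
  y <- yaml::read_yaml(path)
  known <- names(formals(study_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown))
    stop(sprintf("unknown config field(s): %s", paste(unknown, collapse = ", ")))
  if (!is.null(y$suv_window)) y$suv_window <- as.numeric(y$suv_window)
  do.call(study_config, y)
}

#' @noRd
metric_for_model <- function(model) {
  switch(model, LP = "V_T", `1TC` = "V_T", `2TC` = "V_T",
         LR = "DVR", SRTM = "DVR", SUV = "SUV")
}

#' Run the full quantification workflow
#'
#' For each blood-sampled subject, builds the measured final-session input
#' function and derives the earlier sessions' input functions by
#' dose/weight rescaling; builds the cohort mean input function from the
#' measured ones and rescales it to every session of subjects without blood
#' sampling. Then runs the requested models on every regional curve
#' (failures are recorded per fit, never fatal), aggregates regions, and
#' writes `results.csv`, `group_report.csv`, a Markdown summary, and a run
#' log with the configuration hash.
#'
#' @param config A [study_config()].
#' @return Invisibly, a list with `results` (long table including a
#'   `failure_reason` column), `group_report`, `aif_provenance` and the
#'   output paths.
#' @export
run_pipeline <- function(config) {
  inputs <- read_tables(list(tacs = config$tac_table,
                             blood = config$blood_table,
                             sessions = config$sessions_table))
  tacs <- inputs$tacs
  sess_df <- inputs$sessions
  aif_models <- intersect(config$models, c("LP", "1TC", "2TC"))
  if (length(aif_models) && is.null(inputs$blood))
    stop("configuration error: plasma-input models requested but no blood table given")
  dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE)
  log_lines <- character(0)
  logf <- function(fmt, ...) {
    log_lines <<- c(log_lines, sprintf(fmt, ...))
  }

  subjects <- unique(tacs$subject)
  sessions <- unique(tacs$session)
  meta_of <- function(subj, sess) {
    row <- sess_df[sess_df$subject == subj & sess_df$session == sess, ]
    if (nrow(row) != 1L)
      stop(sprintf("missing session metadata for %s / %s", subj, sess))
    session_meta(subj, sess, row$dose_MBq, row$weight_g)
  }

  # --- input functions ------------------------------------------------
  aifs <- list() # aifs[[subject]][[session]]
  if (length(aif_models)) {
    blood <- inputs$blood
    blood_subjects <- intersect(subjects, unique(blood$subject))
    measured <- list(); measured_metas <- list()
    for (subj in blood_subjects) {
      bl <- blood[blood$subject == subj, , drop = FALSE]
      class(bl) <- c("blood_samples", "data.frame")
      metas <- stats::setNames(lapply(sessions, meta_of, subj = subj),
                               sessions)
      aifs[[subj]] <- rebuild_session_aifs(bl, metas,
                                           convention = config$suv_convention)
      src <- bl$session[1]
      measured[[subj]] <- aifs[[subj]][[src]]
      measured_metas[[subj]] <- metas[[src]]
      logf("aif %s: measured at %s, derived for %s", subj, src,
           paste(setdiff(sessions, src), collapse = ", "))
    }
    no_blood <- setdiff(subjects, blood_subjects)
    if (length(no_blood)) {
      if (length(measured) < 2L)
        stop("configuration error: subjects without blood need a cohort mean input function (>= 2 measured)")
      mean_aif <- build_mean_aif(unname(measured), unname(measured_metas))
      for (subj in no_blood) {
        aifs[[subj]] <- stats::setNames(lapply(sessions, function(sess) {
          normalize_aif_to_session(mean_aif, mean_aif$meta,
                                   meta_of(subj, sess),
                                   convention = config$suv_convention)
        }), sessions)
        logf("aif %s: derived from cohort mean input function", subj)
      }
    }
  }

  # --- per-region fits -------------------------------------------------
  sched_of <- function(sub) frame_schedule(sub$frame_start_s[order(sub$frame_start_s)],
                                           sub$frame_end_s[order(sub$frame_start_s)])
  res_rows <- list()
  ref_models <- intersect(config$models, c("LR", "SRTM"))
  for (subj in subjects) {
    for (sess in sessions) {
      st <- tacs[tacs$subject == subj & tacs$session == sess, , drop = FALSE]
      if (nrow(st) == 0L) next
      labels <- unique(st[, c("region", "side")])
      first <- st[st$region == labels$region[1] & st$side == labels$side[1], ]
      sched <- sched_of(first)
      curves <- split(st$kBq_per_mL, paste(st$region, st$side, sep = ":"))
      get_tac <- function(i) tac(curves[[paste(labels$region[i],
                                               labels$side[i], sep = ":")]],
                                 sched, subj, sess, labels$region[i],
                                 labels$side[i])
      meta <- meta_of(subj, sess)
      aif <- if (length(aif_models)) aifs[[subj]][[sess]] else NULL

      ref_tac_obj <- NULL; basis <- NULL; srtm_fits <- NULL
      if (length(ref_models)) {
        ref_rows <- labels$region == config$reference_region
        if (!any(ref_rows))
          stop(sprintf("reference region '%s' absent for %s / %s",
                       config$reference_region, subj, sess))
        ref_vals <- rowMeans(vapply(which(ref_rows),
                                    function(i) get_tac(i)$values,
                                    numeric(nrow(sched))))
        ref_tac_obj <- tac(ref_vals, sched, subj, sess,
                           config$reference_region, "unpaired")
        basis <- srtm_basis(ref_tac_obj)
      }
      if (length(ref_models) &&
          ("SRTM" %in% config$models ||
             identical(config$k2_prime, "srtm-median"))) {
        srtm_fits <- lapply(seq_len(nrow(labels)), function(i) {
          if (labels$region[i] == config$reference_region) return(NULL)
          fit_srtm(get_tac(i), basis = basis)
        })
      }
      k2p <- if (length(ref_models) &&
                 identical(config$k2_prime, "srtm-median")) {
        k2s <- vapply(srtm_fits, function(f) {
          if (is.null(f) || f$failed || f$parameters$R1 <= 0) return(NA_real_)
          f$parameters$k2 / f$parameters$R1
        }, 0)
        stats::median(k2s, na.rm = TRUE)
      } else if (is.numeric(config$k2_prime)) config$k2_prime else NULL

      for (i in seq_len(nrow(labels))) {
        tc <- get_tac(i)
        for (model in config$models) {
          if (model %in% ref_models &&
              labels$region[i] == config$reference_region) next
          fit <- switch(model,
            LP = logan_vt(tc, aif, t_star = config$t_star),
            `1TC` = fit_1tc(tc, aif),
            `2TC` = fit_2tc(tc, aif),
            LR = suppressWarnings(
              logan_ref_dvr(tc, ref_tac_obj, k2_prime = k2p,
                            t_star = config$t_star)),
            SRTM = srtm_fits[[i]],
            SUV = NULL)
          if (model == "SUV") {
            val <- suv_summary(tc, meta, window_min = config$suv_window,
                               convention = config$suv_convention)
            fit <- kinetic_fit_result("SUV", converged = TRUE)
            value <- val
          } else {
            value <- switch(metric_for_model(model), V_T = fit$vt,
                            DVR = fit$dvr)
          }
          failed <- isTRUE(fit$failed)
          res_rows[[length(res_rows) + 1L]] <- data.frame(
            subject = subj, session = sess, region = labels$region[i],
            side = labels$side[i], model = model,
            metric = metric_for_model(model),
            value = if (failed) NA_real_ else value,
            failure_reason = if (failed) fit$failure_reason else "",
            stringsAsFactors = FALSE)
          logf("fit %s %s %s/%s %s: %s", subj, sess, labels$region[i],
               labels$side[i], model,
               if (failed) paste0("FAILED ", fit$failure_reason) else "ok")
        }
      }
    }
  }
  results <- do.call(rbind, res_rows)

  # --- group report ----------------------------------------------------
  pairs <- list()
  ord <- intersect(c("baseline", "D0+6", "D0+35"), sessions)
  if (length(ord) >= 2) {
    for (i in seq_len(length(ord) - 1L))
      pairs <- c(pairs, list(c(ord[i], ord[i + 1L])))
    if (length(ord) == 3) pairs <- c(pairs, list(c(ord[1], ord[3])))
  }
  tissue <- results[!(results$region %in% config$exclusions), , drop = FALSE]
  report <- do.call(rbind, lapply(pairs, function(pr) {
    compare_sessions(tissue, pr[1], pr[2], alpha = config$alpha)
  }))
  summary_tab <- aggregate_regions(results, pairing = config$aggregation,
                                   exclusions = config$exclusions)

  # --- outputs ---------------------------------------------------------
  paths <- list(
    results = file.path(config$output_dir, "results.csv"),
    group_report = file.path(config$output_dir, "group_report.csv"),
    summary = file.path(config$output_dir, "summary.md"),
    log = file.path(config$output_dir, "run.log"),
    manifest = file.path(config$output_dir, "manifest.json"))
  utils::write.csv(results, paths$results, row.names = FALSE)
  if (!is.null(report))
    utils::write.csv(report, paths$group_report, row.names = FALSE)
  writeLines(format_summary_md(summary_tab, report), paths$summary)
  writeLines(log_lines, paths$log)
  cfg <- unclass(config)
  cfg_json <- jsonlite::toJSON(cfg, auto_unbox = TRUE, digits = NA,
                               force = TRUE, null = "null")
  tmp <- tempfile(); writeLines(cfg_json, tmp)
  jsonlite::write_json(list(config = cfg, seed = config$seed,
                            config_md5 = unname(tools::md5sum(tmp)),
                            n_fits = nrow(results),
                            n_failed = sum(results$failure_reason != "")),
                       paths$manifest, auto_unbox = TRUE, digits = NA)
  unlink(tmp)
  invisible(list(results = results, group_report = report,
                 summary = summary_tab, paths = paths))
}

# Markdown summary mirroring the mean +/- sd per session / percent change /
# significance-marker table layout.
#' @noRd
format_summary_md <- function(summary_tab, report) {
  lines <- c("# Group summary", "")
  for (model in unique(summary_tab$model)) {
    st <- summary_tab[summary_tab$model == model, ]
    metric <- st$metric[1]
    lines <- c(lines, sprintf("## %s (%s)", model, metric), "",
               "| region | session | mean ± sd (n) | failures |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(st))) {
      lines <- c(lines, sprintf("| %s | %s | %.3g ± %.3g (%d) | %d |",
                                st$region[i], st$session[i], st$mean[i],
                                st$sd[i], st$n[i], st$n_failed[i]))
    }
    if (!is.null(report)) {
      rp <- report[report$model == model, ]
      if (nrow(rp)) {
        lines <- c(lines, "",
                   "| region | contrast | % change | bilateral (t) | bilateral (U) |",
                   "|---|---|---|---|---|")
        for (i in seq_len(nrow(rp))) {
          mark <- function(x) if (is.na(x)) "?" else if (x) "**" else ""
          lines <- c(lines, sprintf(
            "| %s | %s → %s | %+.1f%% %s | %s | %s |",
            rp$region[i], rp$earlier[i], rp$later[i], rp$percent_change[i],
            "", mark(rp$bilateral_t[i]), mark(rp$bilateral_u[i])))
        }
      }
    }
    lines <- c(lines, "")
  }
  lines
}
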