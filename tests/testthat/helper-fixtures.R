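# Shared fixtures, built in code at test time.

default_times_13 <- function() default_arterial_times()

# Blood-sample table following the study's 13-point schedule, with values
# supplied or derived from simple closed forms.
make_blood <- function(blood = NULL, plasma = NULL, pf = NULL,
                       subject = "ratX", session = "D0+35") {
  ts <- default_times_13()
  if (is.null(blood)) blood <- 100 * exp(-0.1 * ts) + 5
  if (is.null(plasma)) plasma <- blood * 1.3
  pf_col <- rep(NA_real_, length(ts))
  if (!is.null(pf)) pf_col[match(default_metabolite_times(), ts)] <- pf
  blood_samples(subject, session, ts, blood, plasma, pf_col)
}

# A smooth measured-style input function from the template generator.
template_aif <- function() make_template_aif()

# Small, fast cohort spec: fewer subjects/regions for unit tests.
mini_spec <- function(seed = 1, noise_cov = 0.05, n_subjects = 3,
                      n_with_blood = 3,
                      regions = c("hippocampus", "brainstem",
                                  "lateral_ventricle")) {
  spec <- cohort_spec(seed = seed, noise_cov = noise_cov,
                      n_subjects = n_subjects, n_with_blood = n_with_blood)
  spec$regions <- spec$regions[spec$regions$region %in% regions, ]
  spec
}

rel_err <- function(est, truth) abs(est - truth) / abs(truth)
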