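# Kinetic quantification: forward models, compartmental fits, graphical
# analyses, reference-tissue methods, SUV summaries.

sched <- default_frame_schedule()

test_that("one-tissue forward model matches closed forms and an ODE oracle", {
  aif <- template_aif()
  # K1 = 0 -> identically zero
  expect_equal(solve_1tc_tac(0, 0.1, aif, sched)$values, rep(0, 20))

  # constant plasma: C_T(t) = (K1/k2) c (1 - exp(-k2 t)); compare the
  # instantaneous closed form frame-averaged analytically (10 ms grid so the
  # unavoidable one-step onset ramp is negligible against the step input)
  grid <- default_grid(dt_s = 0.01)
  cvals <- rep(5, length(grid)); cvals[1] <- 0
  cp <- input_function(grid, cvals, cvals)
  got <- solve_1tc_tac(0.1, 0.05, cp, sched)$values
  K1 <- 0.1; k2 <- 0.05; cc <- 5
  inst_int <- function(t) (K1 / k2) * cc * (t + (exp(-k2 * t) - 1) / k2)
  want <- (inst_int(sched$end_s / 60) - inst_int(sched$start_s / 60)) /
    sched$dur_min
  expect_lt(max(abs(got - want) / want), 1e-3)

  # independent stiff ODE integration
  skip_if_not_installed("deSolve")
  cp_fun <- approxfun(aif$time_min, aif$plasma_kBq_per_mL, rule = 2)
  rhs <- function(t, y, p) list(0.1 * cp_fun(t) - 0.05 * y)
  ode <- deSolve::lsoda(c(C = 0), times = aif$time_min, func = rhs,
                        parms = NULL, rtol = 1e-10, atol = 1e-12)
  fine_ode <- ode[, "C"]
  fine_pkg <- 0.1 * tspoquant:::conv_exp(aif$plasma_kBq_per_mL,
                                         aif$time_min[2], 0.05)
  idx <- aif$time_min > 1
  expect_lt(max(abs(fine_pkg[idx] - fine_ode[idx]) / fine_ode[idx]), 1e-3)
})

test_that("one-tissue fit recovers noiseless parameters and flags degeneracy", {
  aif <- template_aif()
  t1 <- solve_1tc_tac(0.1, 0.05, aif, sched)
  f <- fit_1tc(t1, aif)
  expect_false(f$failed)
  expect_lt(rel_err(f$parameters$K1, 0.1), 0.01)
  expect_lt(rel_err(f$parameters$k2, 0.05), 0.01)
  expect_lt(rel_err(f$vt, 2.0), 0.01)

  zero <- tac(rep(0, 20), sched)
  fz <- fit_1tc(zero, aif)
  expect_true(fz$failed)
  expect_identical(fz$failure_reason, "degenerate")
  expect_true(is.na(fz$vt))
})

test_that("one-tissue fit is robust to frame noise (seeded Monte Carlo)", {
  aif <- template_aif()
  clean <- solve_1tc_tac(0.1, 0.05, aif, sched)$values
  set.seed(101)
  errs <- replicate(100, {
    noisy <- pmax(clean + rnorm(20, 0, 0.05 * clean), 0)
    rel_err(fit_1tc(tac(noisy, sched), aif)$vt, 2.0)
  })
  expect_lt(median(errs), 0.10)
})

test_that("two-tissue fit recovers V_T and nests the one-tissue model", {
  aif <- template_aif()
  t2 <- solve_2tc_tac(0.1, 0.2, 0.05, 0.05, aif, sched)
  f2 <- fit_2tc(t2, aif)
  expect_false(f2$failed)
  expect_lt(rel_err(f2$vt, 1.0), 0.02)

  # k3 = k4 = 0 truth: 2TC fit must reproduce the 1TC V_T
  t1 <- solve_1tc_tac(0.1, 0.05, aif, sched)
  f1 <- fit_2tc(t1, aif)
  expect_lt(rel_err(f1$vt, 2.0), 0.02)

  fz <- fit_2tc(tac(rep(0, 20), sched), aif)
  expect_true(fz$failed)
  expect_identical(fz$failure_reason, "degenerate")
})

test_that("Logan slope is exact for proportional curves", {
  # plasma curve piecewise linear between the frame mid-times, tissue curve
  # exactly twice the plasma curve at the mid-times
  grid <- default_grid()
  mids <- sched$mid_min
  knot_vals <- 100 * exp(-0.08 * mids) + 10
  cp_fine <- approx(c(0, mids), c(0, knot_vals), xout = grid, rule = 2)$y
  aif <- input_function(grid, cp_fine, cp_fine)
  tc <- tac(2 * knot_vals, sched)
  f <- logan_vt(tc, aif, t_star = 0)
  expect_equal(f$vt, 2.0, tolerance = 1e-12)
  expect_equal(f$parameters$intercept, 0, tolerance = 1e-9)
})

test_that("Logan analysis recovers V_T from compartmental curves", {
  aif <- template_aif()
  f1 <- logan_vt(solve_1tc_tac(0.1, 0.05, aif, sched), aif, t_star = 15)
  expect_lt(rel_err(f1$vt, 2.0), 0.02)
  f2 <- logan_vt(solve_2tc_tac(0.1, 0.2, 0.05, 0.05, aif, sched), aif,
                 t_star = 20)
  expect_lt(rel_err(f2$vt, 1.0), 0.05)
  # too few late frames -> failure flag, not an error
  ff <- logan_vt(solve_1tc_tac(0.1, 0.05, aif, sched), aif, t_star = 55)
  expect_true(ff$failed)
})

test_that("Logan V_T agrees with the compartmental fit on noiseless curves", {
  aif <- template_aif()
  for (k2 in c(0.05, 0.2)) {
    tc <- solve_1tc_tac(0.1, k2, aif, sched)
    vt_lp <- logan_vt(tc, aif, t_star = 15)$vt
    vt_1tc <- fit_1tc(tc, aif)$vt
    expect_lt(rel_err(vt_lp, vt_1tc), 0.02)
    expect_lt(rel_err(vt_lp, 0.1 / k2), 0.02)
  }
})

test_that("SRTM returns exact zero binding for target == reference", {
  aif <- template_aif()
  ref <- solve_1tc_tac(0.1, 0.05, aif, sched)
  f <- fit_srtm(ref, ref)
  expect_lt(abs(f$bp), 1e-6)
  expect_equal(f$parameters$R1, 1, tolerance = 1e-6)
  expect_equal(f$dvr, f$bp + 1)
})

test_that("SRTM recovers binding potential from simulated region pairs", {
  aif <- template_aif()
  ref <- solve_1tc_tac(0.1, 0.05, aif, sched)
  tgt <- solve_1tc_tac(0.1, 0.05 / (1 + 1.0), aif, sched)
  f <- fit_srtm(tgt, ref)
  expect_lt(rel_err(f$bp, 1.0), 0.03)
  expect_lt(rel_err(f$dvr, 2.0), 0.03)
  expect_identical(f$dvr, f$bp + 1)
  expect_error(fit_srtm(tgt, tac(rep(0, 20), sched)), "all zero")
})

test_that("Logan reference method is exact on identity and recovers DVR", {
  aif <- template_aif()
  ref <- solve_1tc_tac(0.1, 0.05, aif, sched)
  ident <- logan_ref_dvr(ref, ref, k2_prime = 0.123, t_star = 10)
  expect_lt(abs(ident$dvr - 1), 1e-6)

  tgt <- solve_1tc_tac(0.1, 0.025, aif, sched)
  f <- logan_ref_dvr(tgt, ref, k2_prime = 0.05, t_star = 15)
  expect_lt(rel_err(f$dvr, 2.0), 0.03)
  # cross-method consistency with plasma-input V_T ratio
  vt_ratio <- fit_1tc(tgt, aif)$vt / fit_1tc(ref, aif)$vt
  expect_lt(rel_err(f$dvr, vt_ratio), 0.05)
  # late-time variant records the omission
  f2 <- logan_ref_dvr(tgt, ref, k2_prime = NULL, t_star = 15)
  expect_true(f2$diagnostics$k2_prime_omitted)
})

test_that("reference-method DVRs agree across SRTM and Logan reference", {
  aif <- template_aif()
  ref <- solve_1tc_tac(0.1, 0.05, aif, sched)
  for (bp in c(0.5, 1.0)) {
    tgt <- solve_1tc_tac(0.1, 0.05 / (1 + bp), aif, sched)
    dvr_srtm <- fit_srtm(tgt, ref)$dvr
    dvr_lr <- logan_ref_dvr(tgt, ref, k2_prime = 0.05, t_star = 15)$dvr
    expect_lt(rel_err(dvr_lr, dvr_srtm), 0.05)
  }
})

test_that("V_T estimates are invariant under joint curve rescaling", {
  aif <- template_aif()
  tc <- solve_1tc_tac(0.1, 0.05, aif, sched)
  base_lp <- logan_vt(tc, aif, 15)$vt
  base_1tc <- fit_1tc(tc, aif)$vt
  for (s in c(10, 0.1)) {
    aif_s <- input_function(aif$time_min, aif$plasma_kBq_per_mL * s,
                            aif$blood_kBq_per_mL * s, provenance = "measured")
    tc_s <- tac(tc$values * s, sched)
    expect_equal(logan_vt(tc_s, aif_s, 15)$vt, base_lp, tolerance = 1e-9)
    expect_equal(fit_1tc(tc_s, aif_s)$vt, base_1tc, tolerance = 1e-6)
  }
})

test_that("SUV summaries weight frames by duration", {
  sched2 <- frame_schedule(c(0, 20), c(20, 60))
  meta <- session_meta("r", "baseline", 37, 250)
  tc <- tac(c(3, 6), sched2)
  # weighted mean (20 s x 3 + 40 s x 6) / 60 s = 5 kBq/mL before scaling
  got <- suv_summary(tc, meta, window_min = c(0, 1))
  expect_equal(got, compute_suv(5 * 1000, 37e6, 250))
  # constant curve reduces to compute_suv of the constant
  tc2 <- tac(c(4, 4), sched2)
  expect_equal(suv_summary(tc2, meta, window_min = c(0, 1)),
               compute_suv(4000, 37e6, 250))
  expect_error(suv_summary(tc2, meta, window_min = c(50, 60)), "window")
})

test_that("group-level SUV roughly doubles when V_T doubles", {
  m <- default_vt_multipliers()
  m[["D0+6"]][m$region != "brainstem" &
                !m$region %in% default_exclusions()] <- 2
  m[["D0+6"]][m$region == "brainstem"] <- 1
  m[["D0+35"]] <- 1
  spec <- cohort_spec(seed = 21, multipliers = m)
  spec$regions <- spec$regions[spec$regions$region == "hippocampus", ]
  bundle <- simulate_cohort(spec, subjects = 1:7,
                            sessions = c("baseline", "D0+6"))
  suvs <- sapply(split(bundle$tacs,
                       paste(bundle$tacs$subject, bundle$tacs$session,
                             bundle$tacs$side)), function(df) {
    meta_row <- bundle$sessions[bundle$sessions$subject == df$subject[1] &
                                  bundle$sessions$session == df$session[1], ]
    suv_summary(tac(df$kBq_per_mL, sched),
                session_meta(df$subject[1], df$session[1],
                             meta_row$dose_MBq, meta_row$weight_g))
  })
  sess <- sub("^\\S+ (\\S+) \\S+$", "\\1", names(suvs))
  ratio <- mean(suvs[sess == "D0+6"]) / mean(suvs[sess == "baseline"])
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("binding potential converts to DVR by a unit shift", {
  expect_identical(bp_to_dvr(0), 1)
  expect_identical(bp_to_dvr(-0.2), 0.8)
  expect_equal(bp_to_dvr(1.18), 2.18)
})
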