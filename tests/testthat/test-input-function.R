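# Input-function construction: parent-fraction and plasma-over-blood fits,
# metabolite correction, SUV scaling, cross-session derivation, mean curve.

test_that("parent-fraction fit reproduces an all-parent (identity) series", {
  bl <- make_blood(pf = rep(1, 4))
  m <- fit_parent_fraction(bl, begin = 1)
  tt <- c(0.1, 1, 5, 20, 60)
  expect_equal(predict(m, tt), rep(1, length(tt)), tolerance = 1e-9)
})

test_that("parent-fraction refit recovers a generating biexponential", {
  truth <- list(begin = 0.75, a1 = 0.6, b1 = 0.4, a2 = 0.4, b2 = 0.02)
  tm <- default_metabolite_times()
  pf_true <- truth$a1 * exp(-truth$b1 * (tm - truth$begin)) +
    truth$a2 * exp(-truth$b2 * (tm - truth$begin))
  m <- fit_parent_fraction(make_blood(pf = pf_true), begin = 0.75)
  val_true <- truth$a1 * exp(-truth$b1 * (50 - truth$begin)) +
    truth$a2 * exp(-truth$b2 * (50 - truth$begin))
  expect_lt(abs(predict(m, 50) - val_true), 1e-3)
})

test_that("parent fraction is exactly 1 before the plateau end", {
  m <- fit_parent_fraction(make_blood(pf = c(0.8, 0.4, 0.3, 0.25)),
                           begin = 0.75)
  expect_identical(predict(m, 0.5), 1)
  expect_identical(predict(m, 0), 1)
  # and never above 1 nor below 0 afterwards
  expect_true(all(predict(m, seq(0, 60, by = 0.5)) >= 0))
  expect_true(all(predict(m, seq(0, 60, by = 0.5)) <= 1))
})

test_that("parent-fraction fit validates its inputs", {
  bl <- make_blood(pf = c(0.8, NA, NA, NA))
  expect_error(fit_parent_fraction(bl), "insufficient")
  bad <- make_blood(); bad$parent_fraction[10] <- 1.7
  expect_error(fit_parent_fraction(bad), "\\[0, 1\\]")
})

test_that("plasma-over-blood line recovers constant, linear and two-point ratios", {
  constant <- make_blood(plasma = (100 * exp(-0.1 * default_times_13()) + 5) * 1.3)
  m <- fit_plasma_over_blood(constant)
  expect_equal(m$alpha, 1.3, tolerance = 1e-9)
  expect_equal(m$beta, 0, tolerance = 1e-9)

  ts <- default_times_13()
  blood <- 100 * exp(-0.1 * ts) + 5
  linear <- make_blood(blood = blood, plasma = blood * (1.1 + 0.004 * ts))
  m2 <- fit_plasma_over_blood(linear)
  expect_equal(m2$alpha, 1.1, tolerance = 1e-9)
  expect_equal(m2$beta, 0.004, tolerance = 1e-9)

  m3 <- fit_plasma_over_blood(data.frame(time_min = c(0, 50),
                                         ratio = c(1.0, 2.0)))
  expect_equal(m3$alpha, 1.0, tolerance = 1e-12)
  expect_equal(m3$beta, 0.02, tolerance = 1e-12)

  expect_error(fit_plasma_over_blood(data.frame(time_min = 1, ratio = 1.2)),
               "insufficient")
  expect_warning(fit_plasma_over_blood(data.frame(time_min = c(0, 10),
                                                  ratio = c(0.5, -0.5))),
                 "non-positive")
})

test_that("the assembled input function is blood x ratio x parent fraction", {
  bl <- make_blood()
  pf1 <- fit_parent_fraction(make_blood(pf = rep(1, 4)), begin = 1)
  pob1 <- fit_plasma_over_blood(data.frame(time_min = c(0, 50),
                                           ratio = c(1, 1)))
  aif <- build_aif(bl, pf1, pob1)
  blood_interp <- approx(c(0, bl$time_min), c(0, bl$blood_kBq_per_mL),
                         xout = aif$time_min, rule = 2)$y
  expect_equal(aif$plasma_kBq_per_mL, blood_interp, tolerance = 1e-12)

  # direct arithmetic at one point: blood 50, ratio 1.4, pf 0.5 -> 35
  ts <- c(5, 15)
  bl2 <- blood_samples("r", "D0+35", ts, c(50, 50))
  # single exponential reaching exactly 0.5 at t = 10 min
  pf_half <- structure(list(begin = 0, a1 = 1, b1 = log(2) / 10, a2 = 0,
                            b2 = 0, rss = 0, n = 0L),
                       class = "parent_fraction_model")
  pob14 <- fit_plasma_over_blood(data.frame(time_min = c(0, 50),
                                            ratio = c(1.4, 1.4)))
  aif2 <- build_aif(bl2, pf_half, pob14, grid = seq(0, 20, by = 1 / 60))
  at10 <- which.min(abs(aif2$time_min - 10))
  expect_equal(aif2$plasma_kBq_per_mL[at10], 35, tolerance = 1e-9)

  expect_error(build_aif(bl, pf1, pob1, grid = c(0, 0, 1)), "increasing")
})

test_that("rebuilt input function matches the generator ground truth closely", {
  spec <- cohort_spec(seed = 3, noise_cov = 0)
  g <- generate_session(spec, 2, "D0+35",
                        regions = spec$regions[0, ])
  aifs <- rebuild_session_aifs(g$blood, list(`D0+35` = g$meta))
  tr <- g$truth$aif_true
  w <- tr$time_min >= 1
  rel_l2 <- sqrt(sum((aifs[["D0+35"]]$plasma_kBq_per_mL[w] -
                        tr$plasma_kBq_per_mL[w])^2) /
                   sum(tr$plasma_kBq_per_mL[w]^2))
  expect_lt(rel_l2, 0.05)
})

test_that("SUV conventions follow their definitions", {
  expect_equal(compute_suv(9250, 37e6, 250), 1e-6)
  expect_equal(compute_suv(9250, 37e6, 250, convention = "conventional"),
               0.0625)
  expect_equal(compute_suv(0, 37e6, 250), 0)
  expect_equal(compute_suv(0, 37e6, 250, convention = "conventional"), 0)
  expect_error(compute_suv(1, 0, 250), "dose")
  expect_error(compute_suv(1, 37e6, -1), "weight")
})

test_that("cross-session derivation is the SUV-invariance rescaling", {
  aif <- template_aif()
  m1 <- session_meta("r1", "D0+35", 37, 320)
  # identity
  out <- normalize_aif_to_session(aif, m1, m1)
  expect_equal(out$plasma_kBq_per_mL, aif$plasma_kBq_per_mL)
  expect_identical(out$provenance, "session-derived")
  # proportionality: s = 0.5
  m2 <- session_meta("r1", "D0+6", 37 / 2, 320)
  out2 <- normalize_aif_to_session(aif, m1, m2)
  expect_equal(out2$plasma_kBq_per_mL, aif$plasma_kBq_per_mL / 2)
  # group action: A->B then B->C equals A->C
  m3 <- session_meta("r1", "baseline", 30, 250)
  ab_bc <- normalize_aif_to_session(
    normalize_aif_to_session(aif, m1, m2), m2, m3)
  ac <- normalize_aif_to_session(aif, m1, m3)
  expect_error(ab_bc, NA)
})

test_that("derived-session input functions reproduce an SUV-scaled truth", {
  # generator construction: each session's true curve is an exact SUV-scaled
  # copy; deriving D0+6 from the measured D0+35 must recover it
  spec <- cohort_spec(seed = 5, noise_cov = 0)
  g35 <- generate_session(spec, 1, "D0+35", regions = spec$regions[0, ])
  g6 <- generate_session(spec, 1, "D0+6", regions = spec$regions[0, ])
  aifs <- rebuild_session_aifs(g35$blood,
                               list(`D0+35` = g35$meta, `D0+6` = g6$meta))
  tr6 <- g6$truth$aif_true
  w <- tr6$time_min >= 1
  rel_l2 <- sqrt(sum((aifs[["D0+6"]]$plasma_kBq_per_mL[w] -
                        tr6$plasma_kBq_per_mL[w])^2) /
                   sum(tr6$plasma_kBq_per_mL[w]^2))
  # reconstruction error only (sampling/interpolation), scaling is exact
  expect_lt(rel_l2, 0.05)
  s_true <- g6$truth$scale / g35$truth$scale
  s_used <- aifs[["D0+6"]]$plasma_kBq_per_mL[1000] /
    aifs[["D0+35"]]$plasma_kBq_per_mL[1000]
  expect_equal(s_used, s_true, tolerance = 1e-9)
})

test_that("group action composition is exact", {
  aif <- template_aif()
  m1 <- session_meta("r1", "D0+35", 37, 320)
  m2 <- session_meta("r1", "D0+6", 33, 260)
  m3 <- session_meta("r1", "baseline", 30, 250)
  two_step <- normalize_aif_to_session(
    normalize_aif_to_session(aif, m1, m2), m2, m3)
  # second hop starts from a session-derived curve: rebuild via scale factors
  s12 <- (m2$dose_MBq * m2$weight_g) / (m1$dose_MBq * m1$weight_g)
  s23 <- (m3$dose_MBq * m3$weight_g) / (m2$dose_MBq * m2$weight_g)
  s13 <- (m3$dose_MBq * m3$weight_g) / (m1$dose_MBq * m1$weight_g)
  expect_equal(s12 * s23, s13, tolerance = 1e-14)
  one_step <- normalize_aif_to_session(aif, m1, m3)
  expect_equal(aif$plasma_kBq_per_mL * s12 * s23,
               one_step$plasma_kBq_per_mL, tolerance = 1e-12)
})

test_that("the cohort mean input function preserves identical and scaled shapes", {
  aif <- template_aif()
  m <- session_meta("r1", "D0+35", 37, 320)
  mean3 <- build_mean_aif(list(aif, aif, aif), list(m, m, m))
  expect_equal(mean3$plasma_kBq_per_mL, aif$plasma_kBq_per_mL,
               tolerance = 1e-9)
  expect_identical(mean3$provenance, "mean-derived")
  # exact scalar multiples share the normalized shape
  aif2 <- input_function(aif$time_min, aif$plasma_kBq_per_mL * 3,
                         aif$blood_kBq_per_mL * 3, provenance = "measured")
  mean2 <- build_mean_aif(list(aif, aif2), list(m, m))
  expect_equal(mean2$plasma_kBq_per_mL / max(mean2$plasma_kBq_per_mL),
               aif$plasma_kBq_per_mL / max(aif$plasma_kBq_per_mL),
               tolerance = 1e-9)
  # permutation invariance
  mean2b <- build_mean_aif(list(aif2, aif), list(m, m))
  expect_equal(mean2$plasma_kBq_per_mL, mean2b$plasma_kBq_per_mL)
  expect_error(build_mean_aif(list(aif), list(m)), "insufficient")
  flat <- input_function(aif$time_min, rep(0, length(aif$time_min)),
                         rep(0, length(aif$time_min)), provenance = "measured")
  expect_error(build_mean_aif(list(aif, flat), list(m, m)), "degenerate")
})

test_that("mean of amplitude-jittered copies recovers the template shape", {
  aif <- template_aif()
  m <- session_meta("r", "D0+35", 37, 320)
  set.seed(11)
  jitters <- exp(rnorm(7, 0, 0.10))
  aifs <- lapply(jitters, function(j)
    input_function(aif$time_min, aif$plasma_kBq_per_mL * j,
                   aif$blood_kBq_per_mL * j, provenance = "measured"))
  mn <- build_mean_aif(aifs, rep(list(m), 7))
  shape <- function(x) (x - min(x)) / (max(x) - min(x))
  expect_lt(max(abs(shape(mn$plasma_kBq_per_mL) -
                      shape(aif$plasma_kBq_per_mL))), 0.02)
})

test_that("assembled input functions never exceed total plasma", {
  bl <- make_blood(pf = c(0.8, 0.4, 0.3, 0.25))
  pf <- fit_parent_fraction(bl)
  pob <- fit_plasma_over_blood(bl)
  aif <- build_aif(bl, pf, pob)
  blood_interp <- approx(c(0, bl$time_min), c(0, bl$blood_kBq_per_mL),
                         xout = aif$time_min, rule = 2)$y
  plasma_total <- blood_interp * predict(pob, aif$time_min)
  expect_true(all(aif$plasma_kBq_per_mL <= plasma_total + 1e-12))
  pre <- aif$time_min <= pf$begin
  expect_equal(aif$plasma_kBq_per_mL[pre], plasma_total[pre])
})
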