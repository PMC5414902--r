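# Group-level statistics and longitudinal comparison conventions.

test_that("percent change is relative to the earlier time point", {
  expect_equal(percent_change(1.00, 2.18), 118)
  expect_equal(percent_change(5, 5), 0)
  expect_equal(round(percent_change(2.18, 1.025)), -53)
  expect_error(percent_change(0, 1), "zero")
})

test_that("percent changes in the two directions are reciprocal", {
  set.seed(4)
  for (i in 1:20) {
    a <- runif(1, 0.5, 3); b <- runif(1, 0.5, 3)
    p_ab <- percent_change(a, b); p_ba <- percent_change(b, a)
    expect_equal((1 + p_ab / 100) * (1 + p_ba / 100), 1, tolerance = 1e-12)
  }
})

test_that("bilateral rule requires both sides below alpha, strictly", {
  expect_true(bilateral_significance(0.01, 0.04, 0.05))
  expect_false(bilateral_significance(0.01, 0.06, 0.05))
  expect_false(bilateral_significance(0.05, 0.05, 0.05))
})

test_that("bilateral flag is monotone in alpha", {
  set.seed(8)
  for (i in 1:50) {
    p <- runif(2); a <- runif(1)
    if (bilateral_significance(p[1], p[2], a))
      expect_true(bilateral_significance(p[1], p[2], min(a * 1.5, 1)))
  }
})

test_that("paired t-test handles shifts, identity and symmetric differences", {
  before <- c(1.0, 1.2, 0.9, 1.1, 1.05)
  set.seed(2)
  after <- before + 1 + rnorm(5, 0, 1e-4)
  res <- paired_t_test(before, after)
  expect_lt(res$p_value, 1e-6)
  expect_false(res$degenerate)

  same <- paired_t_test(before, before)
  expect_true(same$degenerate)
  expect_equal(same$p_value, 1)

  sym <- paired_t_test(rep(0, 4), c(1, -1, 1, -1))
  expect_equal(sym$statistic, 0, tolerance = 1e-12)
  expect_equal(sym$p_value, 1, tolerance = 1e-12)

  expect_error(paired_t_test(1:3, 1:4), "length")
})

test_that("exact Mann-Whitney enumeration matches known and oracle values", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)
  expect_identical(res$method, "exact-enumeration")

  ident <- mann_whitney_u(c(2, 5, 9), c(2, 5, 9))
  expect_equal(ident$p_value, 1)

  expect_error(mann_whitney_u(numeric(0), 1:3), "non-empty")
})

test_that("exact enumeration agrees with wilcox.test for all small sizes", {
  # independent oracle: stats::wilcox.test exact p (tie-free data)
  set.seed(31)
  for (na in 2:5) {
    for (nb in 2:5) {
      a <- sample(seq(1, 100), na)
      b <- sample(setdiff(seq(1, 100), a), nb)
      mine <- mann_whitney_u(a, b)$p_value
      oracle <- wilcox.test(a, b, exact = TRUE)$p.value
      expect_equal(mine, oracle, tolerance = 1e-12,
                   info = sprintf("na=%d nb=%d", na, nb))
    }
  }
})

test_that("normal approximation tracks the exact test at moderate size", {
  set.seed(17)
  a <- rnorm(8); b <- rnorm(8, 0.5)
  exact <- mann_whitney_u(a, b, exact_max = 8)$p_value
  approx <- mann_whitney_u(a, b, exact_max = 0)$p_value
  expect_lt(abs(exact - approx), 0.02)
})

test_that("coefficient of variation uses the sample standard deviation", {
  expect_equal(coefficient_of_variation(c(2, 2, 2))$cov_percent, 0)
  res <- coefficient_of_variation(c(1, 2, 3))
  expect_equal(res$cov_percent, 50)
  expect_true(res$flagged)
  expect_false(coefficient_of_variation(c(10, 11, 10.5))$flagged)
  expect_error(coefficient_of_variation(c(-1, 1)), "zero mean")
  expect_error(coefficient_of_variation(3), "at least 2")
})

test_that("correlation is the Pearson product-moment coefficient", {
  x <- c(1, 2, 3, 4, 5)
  expect_equal(correlation_r(x, 2 * x + 1), 1)
  expect_equal(correlation_r(x, -x), -1)
  set.seed(9)
  u <- rnorm(30); v <- 0.5 * u + rnorm(30)
  direct <- cov(u, v) / (sd(u) * sd(v))
  expect_lt(abs(correlation_r(u, v) - direct), 1e-12)
  expect_error(correlation_r(rep(1, 5), 1:5), "zero variance")
})

test_that("region aggregation averages sides, excludes ventricles, counts failures", {
  tab <- data.frame(
    subject = "r1", session = "baseline", region = "hippocampus",
    side = c("left", "right"), model = "1TC", metric = "V_T",
    value = c(1, 3))
  agg <- aggregate_regions(tab, pairing = "mean-of-sides")
  expect_equal(agg$mean, 2)

  # default 29-label set reduces to 26 labels / 13 regions after exclusion
  regs <- default_region_table()
  tab29 <- data.frame(subject = "r1", session = "baseline",
                      region = regs$region, side = regs$side,
                      model = "1TC", metric = "V_T", value = 1)
  expect_equal(nrow(tab29), 29)
  agg29 <- aggregate_regions(tab29, pairing = "per-side")
  expect_equal(nrow(agg29), 26)
  expect_equal(length(unique(aggregate_regions(tab29)$region)), 13)

  # failed fit contributes to the failure count, not the mean
  tab3 <- data.frame(subject = c("r1", "r2", "r3"), session = "baseline",
                     region = "thalamus", side = "left", model = "1TC",
                     metric = "V_T", value = c(2, NA, 4))
  agg3 <- aggregate_regions(tab3, pairing = "per-side")
  expect_equal(agg3$mean, 3)
  expect_equal(agg3$n_failed, 1)
  expect_equal(agg3$n, 2)
})

test_that("session comparison applies the bilateral rule and percent change", {
  set.seed(5)
  subjects <- sprintf("r%d", 1:7)
  mk <- function(session, mult, sd_noise = 0.02) {
    do.call(rbind, lapply(c("left", "right"), function(side)
      data.frame(subject = subjects, session = session,
                 region = "hippocampus", side = side, model = "1TC",
                 metric = "V_T",
                 value = mult * exp(rnorm(7, 0, sd_noise)))))
  }
  tab <- rbind(mk("baseline", 1), mk("D0+6", 2.2))
  cmp <- compare_sessions(tab, "baseline", "D0+6", alpha = 0.01)
  expect_equal(nrow(cmp), 1)
  expect_true(cmp$bilateral_t)
  expect_lt(abs(cmp$percent_change - 120), 15)
  # reversing the contrast reports the reciprocal-direction change
  rev <- compare_sessions(tab, "D0+6", "baseline", alpha = 0.01)
  expect_equal((1 + cmp$percent_change / 100) * (1 + rev$percent_change / 100),
               1, tolerance = 0.01)
})

test_that("a no-change contrast is not flagged", {
  set.seed(6)
  subjects <- sprintf("r%d", 1:7)
  tab <- do.call(rbind, lapply(c("baseline", "D0+6"), function(sess)
    do.call(rbind, lapply(c("left", "right"), function(side)
      data.frame(subject = subjects, session = sess, region = "brainstem",
                 side = side, model = "1TC", metric = "V_T",
                 value = exp(rnorm(7, 0, 0.05)))))))
  cmp <- compare_sessions(tab, "baseline", "D0+6", alpha = 0.01)
  expect_false(cmp$bilateral_t)
})
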