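#' Percent change relative to the earlier time point
#'
#' @param earlier,later Values at the earlier and later session; `earlier`
#'   must be non-zero.
#' @return `100 * (later - earlier) / earlier`. Decreases are negative;
#'   reports may quote magnitudes.
#' @examples
#' percent_change(1, 2.18) # +118
#' @export
percent_change <- function(earlier, later) {
  if (any(earlier == 0)) stop("undefined change: earlier value is zero")
  100 * (later - earlier) / earlier
}

#' Bilateral significance rule
#'
#' A change in a paired structure counts as significant only when it is
#' significant on both the left and the right side, with strict
#' inequalities at the boundary.
#'
#' @param p_left,p_right Per-side p-values in `[0, 1]`.
#' @param alpha Significance level.
#' @return Logical flag.
#' @export
bilateral_significance <- function(p_left, p_right, alpha) {
  stopifnot(all(p_left >= 0 & p_left <= 1), all(p_right >= 0 & p_right <= 1))
  p_left < alpha & p_right < alpha
}

#' Paired t-test with degenerate-difference handling
#'
#' Two-sided paired t-test on within-subject differences. Zero-variance
#' differences (including the identical-vectors case) cannot support a t
#' statistic; they are reported with `p = 1` and `degenerate = TRUE` rather
#' than as an error, so cohort summaries always complete.
#'
#' @param before,after Paired value vectors of equal length `>= 2`.
#' @return List with `statistic`, `p_value`, `df`, `degenerate`.
#' @export
paired_t_test <- function(before, after) {
  if (length(before) != length(after)) stop("paired vectors differ in length")
  if (length(before) < 2L) stop("need at least 2 pairs")
  d <- after - before
  if (stats::sd(d) == 0)
    return(list(statistic = if (all(d == 0)) 0 else NA_real_,
                p_value = 1, df = length(d) - 1L, degenerate = TRUE))
  tt <- stats::t.test(after, before, paired = TRUE)
  list(statistic = unname(tt$statistic), p_value = tt$p.value,
       df = unname(tt$parameter), degenerate = FALSE)
}

#' @noRd
u_statistic <- function(a, b) {
  sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
}

#' Mann-Whitney U test (exact by enumeration for small groups)
#'
#' Two-sided test of location. When the smaller group has at most
#' `exact_max` observations the null distribution of U is obtained by full
#' enumeration of all assignments of the pooled values to the two groups
#' (a permutation test, valid with ties); otherwise the normal
#' approximation with tie correction and continuity correction is used.
#'
#' @param group_a,group_b Non-empty numeric vectors.
#' @param exact_max Enumeration threshold on `min(n_a, n_b)` (default 8).
#' @return List with `U` (for `group_a`), `p_value`, `method`.
#' @export
mann_whitney_u <- function(group_a, group_b, exact_max = 8) {
  if (length(group_a) == 0L || length(group_b) == 0L)
    stop("both groups must be non-empty")
  n1 <- length(group_a); n2 <- length(group_b)
  U <- u_statistic(group_a, group_b)
  centre <- n1 * n2 / 2
  if (min(n1, n2) <= exact_max) {
    pooled <- c(group_a, group_b)
    idx <- utils::combn(n1 + n2, n1)
    extreme_obs <- abs(U - centre)
    count <- sum(apply(idx, 2, function(ii) {
      abs(u_statistic(pooled[ii], pooled[-ii]) - centre) >= extreme_obs - 1e-9
    }))
    p <- count / ncol(idx)
    return(list(U = U, p_value = p, method = "exact-enumeration"))
  }
  N <- n1 + n2
  ties <- table(c(group_a, group_b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  sigma <- sqrt(n1 * n2 / 12 * ((N + 1) - tie_term))
  z <- (abs(U - centre) - 0.5) / sigma
  p <- min(2 * stats::pnorm(-max(z, 0)), 1)
  list(U = U, p_value = p, method = "normal-approximation")
}

#' Coefficient of variation
#'
#' @param values Numeric vector, `n >= 2`, non-zero mean.
#' @param flag_threshold Report-level gate: values at or above this CoV (in
#'   percent) are flagged as exceeding expected normal biological variation.
#' @return List with `cov_percent` (100 * sample sd / mean) and `flagged`.
#' @export
coefficient_of_variation <- function(values, flag_threshold = 20) {
  if (length(values) < 2L) stop("need at least 2 values")
  m <- mean(values)
  if (m == 0) stop("undefined: zero mean")
  cv <- 100 * stats::sd(values) / m
  list(cov_percent = cv, flagged = cv >= flag_threshold)
}

#' Pearson correlation coefficient
#'
#' Product-moment correlation: the covariance of the two variables divided
#' by the product of their standard deviations.
#'
#' @param x,y Equal-length vectors, `n >= 3`, each with non-zero variance.
#' @return The correlation coefficient.
#' @export
correlation_r <- function(x, y) {
  if (length(x) != length(y)) stop("vectors differ in length")
  if (length(x) < 3L) stop("need at least 3 observations")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined: zero variance")
  stats::cor(x, y)
}

#' Default ventricle exclusion list
#' @return Character vector of region names excluded from whole-brain
#'   summaries.
#' @export
default_exclusions <- function() c("lateral_ventricle", "third_ventricle")

#' Aggregate a region result table
#'
#' Summarizes a long results table (one row per subject, session, region,
#' side, model and metric) into per-region group means. Failed fits must be
#' encoded as `NA` values -- they are excluded from means and counted, never
#' treated as zeros. With `pairing = "mean-of-sides"` the left and right
#' values of each subject are averaged before group statistics (the
#' convention for group mean plots); `"per-side"` keeps sides separate as
#' required by the bilateral-significance rule.
#'
#' @param table Data frame with columns `subject`, `session`, `region`,
#'   `side`, `model`, `metric`, `value`.
#' @param pairing `"mean-of-sides"` or `"per-side"`.
#' @param exclusions Regions removed before summarizing (default the
#'   ventricle labels).
#' @return Data frame with group `mean`, `sd`, `n` and `n_failed` per
#'   (session, model, metric, region) and, for `"per-side"`, side.
#' @export
aggregate_regions <- function(table,
                              pairing = c("mean-of-sides", "per-side"),
                              exclusions = default_exclusions()) {
  pairing <- match.arg(pairing)
  if (nrow(table) == 0L) stop("empty result table")
  table <- table[!(table$region %in% exclusions), , drop = FALSE]
  if (pairing == "mean-of-sides") {
    key <- c("subject", "session", "region", "model", "metric")
    subj <- stats::aggregate(value ~ subject + session + region + model + metric,
                             data = table, FUN = mean, na.rm = TRUE,
                             na.action = stats::na.pass)
    subj$value[is.nan(subj$value)] <- NA_real_
    table <- subj
    group_key <- value ~ session + region + model + metric
  } else {
    group_key <- value ~ session + region + side + model + metric
  }
  agg <- function(f) stats::aggregate(group_key, data = table, FUN = f,
                                      na.action = stats::na.pass)
  out <- agg(function(v) mean(v, na.rm = TRUE))
  names(out)[names(out) == "value"] <- "mean"
  out$sd <- agg(function(v) stats::sd(v[!is.na(v)]))$value
  out$n <- agg(function(v) sum(!is.na(v)))$value
  out$n_failed <- agg(function(v) sum(is.na(v)))$value
  out$mean[is.nan(out$mean)] <- NA_real_
  out
}

#' Longitudinal session comparison with the bilateral rule
#'
#' For each region, compares paired subject values between two sessions on
#' each side with a paired t-test and a Mann-Whitney U test, applies the
#' bilateral-significance rule per test, and reports the percent change of
#' the group mean (sides averaged within subject first) relative to the
#' earlier session. Subjects missing either session's value for a side are
#' dropped listwise for that side.
#'
#' @param table Long results table as in [aggregate_regions()], restricted
#'   by the caller to one model/metric or not (comparisons are computed per
#'   model and metric).
#' @param earlier,later Session labels to compare.
#' @param alpha Significance level for the bilateral flags.
#' @return Data frame with one row per (model, metric, region): per-side
#'   p-values for both tests, bilateral flags, and the percent change of
#'   the group mean.
#' @export
compare_sessions <- function(table, earlier, later, alpha = 0.05) {
  stopifnot(all(c(earlier, later) %in% table$session))
  combos <- unique(table[, c("model", "metric", "region")])
  rows <- lapply(seq_len(nrow(combos)), function(i) {
    cb <- combos[i, ]
    sub <- table[table$model == cb$model & table$metric == cb$metric &
                   table$region == cb$region, , drop = FALSE]
    side_p <- function(side, test) {
      ss <- sub[sub$side == side, , drop = FALSE]
      se <- ss[ss$session == earlier, , drop = FALSE]
      sl <- ss[ss$session == later, , drop = FALSE]
      subs <- intersect(se$subject, sl$subject)
      ve <- se$value[match(subs, se$subject)]
      vl <- sl$value[match(subs, sl$subject)]
      ok <- !is.na(ve) & !is.na(vl)
      if (sum(ok) < 2L) return(NA_real_)
      if (test == "t") paired_t_test(ve[ok], vl[ok])$p_value
      else mann_whitney_u(ve[ok], vl[ok])$p_value
    }
    p_t <- c(left = side_p("left", "t"), right = side_p("right", "t"))
    p_u <- c(left = side_p("left", "u"), right = side_p("right", "u"))
    bil <- function(p) {
      if (any(is.na(p))) NA else bilateral_significance(p[1], p[2], alpha)
    }
    means <- tapply(sub$value[sub$session %in% c(earlier, later)],
                    sub$session[sub$session %in% c(earlier, later)],
                    mean, na.rm = TRUE)
    pc <- if (!is.na(means[earlier]) && means[earlier] != 0)
      percent_change(means[[earlier]], means[[later]]) else NA_real_
    data.frame(model = cb$model, metric = cb$metric, region = cb$region,
               earlier = earlier, later = later,
               p_t_left = p_t[1], p_t_right = p_t[2],
               p_u_left = p_u[1], p_u_right = p_u[2],
               bilateral_t = bil(p_t), bilateral_u = bil(p_u),
               percent_change = pc, alpha = alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
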