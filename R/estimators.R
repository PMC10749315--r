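new_estimate <- function(method, beta, se, n_snp, pval = NULL) {
  pval <- pval %||% normal_pval(beta, se)
  tibble::tibble(
    method = method, beta = beta, se = se,
    ci_low = beta - Z95 * se, ci_high = beta + Z95 * se,
    pval = pval, n_snp = as.integer(n_snp),
    or = exp(beta), or_lci = exp(beta - Z95 * se), or_uci = exp(beta + Z95 * se)
  )
}

# exposure beta, outcome beta, outcome weight triple used by every estimator
pair_xyw <- function(pairs) {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) == 0) abort("no kept harmonized pairs")
  if (any(pairs$se_out <= 0) || any(pairs$se_exp <= 0)) {
    abort("kept pairs must have strictly positive standard errors")
  }
  list(x = pairs$beta_exp, y = pairs$beta_out, w = 1 / pairs$se_out^2,
       ids = pairs$variant_id, se_exp = pairs$se_exp, se_out = pairs$se_out)
}

#' Wald ratio for a single instrument
#'
#' The single-variant causal estimate `beta_out / beta_exp` with the
#' first-order standard error `|se_out / beta_exp|` and a two-sided normal
#' p-value. This is the building block the multi-instrument estimators
#' aggregate.
#'
#' @param pair A one-row harmonized pair table (see [harmonize()]).
#' @return A one-row estimate tibble (`method = "wald"`).
#' @export
wald_ratio <- function(pair) {
  d <- pair_xyw(pair)
  if (length(d$x) != 1) abort("wald_ratio expects exactly one kept pair")
  if (d$x == 0) abort("undefined ratio: exposure beta is zero")
  new_estimate("wald", d$y / d$x, abs(d$se_out / d$x), 1L)
}

#' Inverse-variance-weighted estimate
#'
#' Weighted regression of outcome betas on exposure betas through the
#' origin with weights `1/se_out^2` — the inverse-variance-weighted
#' meta-analysis of per-variant Wald ratios. Under
#' `model = "multiplicative_re"` (the default) the standard error is
#' inflated by `max(1, sqrt(Q / (n - 1)))`, leaving the point estimate
#' unchanged; `"fixed"` reports the unscaled standard error.
#'
#' @param pairs Harmonized pairs; a single kept pair delegates to
#'   [wald_ratio()].
#' @param model `"multiplicative_re"` or `"fixed"`.
#' @return A one-row estimate tibble with attribute `"q"` holding Cochran's
#'   Q of the fit.
#' @export
mr_ivw <- function(pairs, model = c("multiplicative_re", "fixed")) {
  model <- match.arg(model)
  d <- pair_xyw(pairs)
  n <- length(d$x)
  if (n == 1) return(wald_ratio(kept_pairs(pairs)))
  sxx <- sum(d$w * d$x^2)
  beta <- sum(d$w * d$x * d$y) / sxx
  se <- sqrt(1 / sxx)
  q <- sum(d$w * (d$y - beta * d$x)^2)
  if (model == "multiplicative_re") se <- se * max(1, sqrt(q / (n - 1)))
  est <- new_estimate(if (model == "fixed") "ivw_fixed" else "ivw_re",
                      beta, se, n)
  attr(est, "q") <- q
  est
}

#' MR-Egger regression
#'
#' Weighted regression of outcome betas on exposure betas with a free
#' intercept (weights `1/se_out^2`), after orienting every pair so the
#' exposure beta is non-negative. The slope is the pleiotropy-robust causal
#' estimate; a nonzero intercept indicates directional pleiotropy, so the
#' intercept's p-value is the pleiotropy test. Standard errors are scaled
#' by `max(1, sqrt(Q_egger / (n - 2)))`.
#'
#' @param pairs Harmonized pairs; at least 3 kept pairs required.
#' @return A two-row estimate tibble (`egger_slope`, `egger_intercept`)
#'   with attribute `"q"` holding the Egger residual Q.
#' @export
mr_egger <- function(pairs) {
  d <- pair_xyw(pairs)
  n <- length(d$x)
  if (n < 3) abort("insufficient instruments for Egger (need >= 3)")
  flip <- sign(d$x) < 0
  x <- abs(d$x)
  y <- ifelse(flip, -d$y, d$y)
  w <- d$w
  # closed-form weighted least squares with intercept
  sw <- sum(w); swx <- sum(w * x); swy <- sum(w * y)
  swxx <- sum(w * x^2); swxy <- sum(w * x * y)
  det <- sw * swxx - swx^2
  if (det <= 0) abort("degenerate design: exposure betas carry no spread")
  slope <- (sw * swxy - swx * swy) / det
  intercept <- (swxx * swy - swx * swxy) / det
  q <- sum(w * (y - intercept - slope * x)^2)
  scale <- max(1, sqrt(q / (n - 2)))
  se_slope <- sqrt(sw / det) * scale
  se_intercept <- sqrt(swxx / det) * scale
  est <- dplyr::bind_rows(
    new_estimate("egger_slope", slope, se_slope, n),
    new_estimate("egger_intercept", intercept, se_intercept, n)
  )
  attr(est, "q") <- q
  est
}

# interpolated weighted median with exact-tie aggregation; tie merging makes
# the estimate exactly invariant to duplicating every instrument
weighted_median_point <- function(ratios, weights) {
  agg <- rowsum(weights, group = ratios)
  r <- as.numeric(rownames(agg))
  w <- as.numeric(agg) / sum(weights)
  o <- order(r)
  r <- r[o]; w <- w[o]
  s <- cumsum(w) - w / 2
  if (length(r) == 1) return(r)
  approx(s, r, xout = 0.5, rule = 2, ties = "ordered")$y
}

#' Weighted-median estimate
#'
#' The weighted median of the per-variant Wald ratios, with weights
#' proportional to the inverse variance of each ratio
#' (`beta_exp^2 / se_out^2`). The estimate is consistent as long as at
#' least half of the total weight comes from valid instruments. The median
#' uses the midpoint convention (cumulative weight minus half the
#' variant's own weight, linearly interpolated at 0.5); exact ties in the
#' ratio are pooled. The standard error comes from a seeded parametric
#' bootstrap resampling both betas from their normal sampling
#' distributions.
#'
#' @param pairs Harmonized pairs; at least 3 kept pairs required.
#' @param n_boot Bootstrap replicates for the standard error (default 1000).
#' @param seed RNG seed for the bootstrap (the caller's RNG state is left
#'   untouched).
#' @return A one-row estimate tibble (`method = "weighted_median"`).
#' @export
mr_weighted_median <- function(pairs, n_boot = 1000, seed = 1) {
  d <- pair_xyw(pairs)
  n <- length(d$x)
  if (n < 3) abort("insufficient instruments for weighted median (need >= 3)")
  if (n_boot < 2) abort("n_boot must be at least 2")
  ratios <- d$y / d$x
  weights <- d$x^2 / d$se_out^2
  point <- weighted_median_point(ratios, weights)
  boots <- with_preserved_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      xs <- rnorm(n, d$x, d$se_exp)
      ys <- rnorm(n, d$y, d$se_out)
      weighted_median_point(ys / xs, xs^2 / d$se_out^2)
    }, numeric(1))
  })
  new_estimate("weighted_median", point, stats::sd(boots), n)
}

#' Cochran's Q heterogeneity test
#'
#' `Q = sum_i w_i (ratio_i - beta)^2` with `w_i = beta_exp^2 / se_out^2`,
#' referred to a chi-square distribution. For an IVW-style estimate the
#' degrees of freedom are `n - 1`; for an Egger slope the residuals are
#' taken about the two-parameter Egger fit and the degrees of freedom are
#' `n - 2`.
#'
#' @param pairs Harmonized pairs with at least 2 kept rows.
#' @param estimate Optional one-row estimate tibble; when omitted (or an
#'   IVW/Wald estimate) the fixed-effect IVW slope is used.
#' @return A tibble `q`, `df`, `pval`.
#' @export
cochran_q <- function(pairs, estimate = NULL) {
  d <- pair_xyw(pairs)
  n <- length(d$x)
  if (n < 2) abort("Cochran's Q needs at least 2 instruments")
  method <- if (is.null(estimate)) "ivw" else estimate$method[1]
  if (identical(method, "egger_slope") || identical(method, "egger")) {
    q <- attr(mr_egger(pairs), "q")
    df <- n - 2L
  } else {
    beta <- if (is.null(estimate)) {
      sum(d$w * d$x * d$y) / sum(d$w * d$x^2)
    } else {
      estimate$beta[1]
    }
    q <- sum(d$w * (d$y - beta * d$x)^2)
    df <- n - 1L
  }
  tibble::tibble(q = q, df = as.integer(df),
                 pval = clamp_pval(pchisq(q, df, lower.tail = FALSE)))
}

#' Leave-one-out analysis
#'
#' Refits the IVW estimate once per instrument with that instrument
#' removed. When every leave-one-out confidence interval lies on the same
#' side of zero, no single instrument drives the overall result.
#'
#' @param pairs Harmonized pairs; at least 3 kept pairs required.
#' @param model IVW model passed through to [mr_ivw()].
#' @return A tibble with one row per excluded instrument (`excluded_id`
#'   plus the estimate columns); attribute `"all_same_side"` is `TRUE` when
#'   all intervals exclude zero on a common side.
#' @export
leave_one_out <- function(pairs, model = "multiplicative_re") {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) < 3) abort("leave-one-out needs at least 3 instruments")
  rows <- purrr::map_dfr(seq_len(nrow(pairs)), function(i) {
    est <- mr_ivw(pairs[-i, ], model = model)
    dplyr::bind_cols(tibble::tibble(excluded_id = pairs$variant_id[i]), est)
  })
  same_side <- all(rows$ci_high < 0) || all(rows$ci_low > 0)
  structure(rows, all_same_side = same_side)
}

# leave-one-out IVW (fixed-effect) predictions, vectorized over instruments
loo_predictions <- function(x, y, w) {
  sxy <- sum(w * x * y)
  sxx <- sum(w * x^2)
  denom <- sxx - w * x^2
  if (any(denom <= 0)) abort("degenerate variance in leave-one-out fit")
  beta_loo <- (sxy - w * x * y) / denom
  beta_loo * x
}

#' MR-PRESSO global pleiotropy test and outlier detection
#'
#' The observed global statistic is the sum of leave-one-out-predicted
#' standardized squared residuals: each instrument's outcome beta is
#' compared with the fixed-effect IVW prediction computed without that
#' instrument, standardized by its outcome variance. Its null distribution
#' is built by parametric simulation (`beta_out* ~ N(prediction, se_out)`),
#' and the global p-value is the empirical tail proportion with a
#' `1/(n_sim + 1)` continuity correction. Per-instrument outlier p-values
#' are the tail proportions of each instrument's simulated residual
#' distribution, Bonferroni-adjusted across instruments; instruments with
#' adjusted p below `outlier_alpha` are flagged.
#'
#' @param pairs Harmonized pairs; at least 4 kept pairs required.
#' @param n_sim Number of simulated datasets (>= 100; default 1000).
#' @param seed RNG seed (caller's RNG state preserved).
#' @param outlier_alpha Significance level for the Bonferroni-adjusted
#'   per-instrument test (default 0.05).
#' @return A list of class `mr_presso`: `global_rss_obs`, `global_pval`,
#'   `outlier_ids`, `outliers` (per-instrument tibble), `n_sim`, `seed`.
#' @export
mr_presso <- function(pairs, n_sim = 1000, seed = 1, outlier_alpha = 0.05) {
  d <- pair_xyw(pairs)
  n <- length(d$x)
  if (n < 4) abort("MR-PRESSO needs at least 4 instruments")
  if (n_sim < 100) abort("n_sim must be at least 100")
  pred <- loo_predictions(d$x, d$y, d$w)
  res2_obs <- d$w * (d$y - pred)^2
  rss_obs <- sum(res2_obs)

  sims <- with_preserved_seed(seed, {
    ystar <- matrix(rnorm(n_sim * n, mean = rep(pred, each = n_sim),
                          sd = rep(d$se_out, each = n_sim)),
                    nrow = n_sim)
    res2 <- matrix(0, n_sim, n)
    for (s in seq_len(n_sim)) {
      ps <- loo_predictions(d$x, ystar[s, ], d$w)
      res2[s, ] <- d$w * (ystar[s, ] - ps)^2
    }
    res2
  })
  rss_star <- rowSums(sims)
  global_pval <- (1 + sum(rss_star >= rss_obs)) / (n_sim + 1)

  p_outlier <- (1 + colSums(sims >= rep(res2_obs, each = n_sim))) / (n_sim + 1)
  p_adj <- pmin(1, p_outlier * n)
  outliers <- tibble::tibble(variant_id = d$ids, residual2 = res2_obs,
                             pval = p_outlier, pval_bonferroni = p_adj,
                             outlier = p_adj < outlier_alpha)
  structure(list(global_rss_obs = rss_obs, global_pval = global_pval,
                 outlier_ids = d$ids[p_adj < outlier_alpha],
                 outliers = outliers, n_sim = as.integer(n_sim),
                 seed = as.integer(seed)),
            class = "mr_presso")
}

#' @export
print.mr_presso <- function(x, ...) {
  cat("MR-PRESSO global test\n")
  cat(sprintf("  observed RSS: %.4f   global p: %.4g   (%d simulations)\n",
              x$global_rss_obs, x$global_pval, x$n_sim))
  if (length(x$outlier_ids) > 0) {
    cat("  outliers:", paste(x$outlier_ids, collapse = ", "), "\n")
  } else {
    cat("  no outliers detected\n")
  }
  invisible(x)
}

#' Funnel-plot coordinates
#'
#' @param pairs Harmonized pairs (kept rows are used; an empty kept set
#'   yields an empty table).
#' @return A tibble `variant_id`, `ratio`, `precision` (`1/se_ratio`, with
#'   `se_ratio = |se_out / beta_exp|`).
#' @export
funnel_data <- function(pairs) {
  pairs <- kept_pairs(pairs)
  if (nrow(pairs) == 0) {
    return(tibble::tibble(variant_id = character(), ratio = numeric(),
                          precision = numeric()))
  }
  tibble::tibble(variant_id = pairs$variant_id,
                 ratio = pairs$beta_out / pairs$beta_exp,
                 precision = abs(pairs$beta_exp / pairs$se_out))
}

#' Full single-pair MR analysis
#'
#' Runs the IVW (multiplicative random effects), MR-Egger and
#' weighted-median estimators on one harmonized exposure-outcome pair
#' table, together with the sensitivity battery: Cochran's Q (IVW and
#' Egger), leave-one-out, funnel coordinates, and optionally MR-PRESSO.
#'
#' @param pairs Harmonized pairs from [harmonize()].
#' @param n_boot Bootstrap replicates for the weighted-median SE.
#' @param seed RNG seed for bootstrap and MR-PRESSO.
#' @param presso Run MR-PRESSO (needs >= 4 instruments)?
#' @param presso_n_sim Simulations for MR-PRESSO.
#' @param exposure,outcome Optional trait labels stored in the result.
#' @return An object of class `mr_fit` with elements `estimates` (tibble),
#'   `heterogeneity`, `loo`, `funnel`, `presso`, `pairs`, `exposure`,
#'   `outcome`. Use [tidy()][generics::tidy] / [glance()][generics::glance]
#'   / [autoplot()][ggplot2::autoplot] on it.
#' @export
mr_analysis <- function(pairs, n_boot = 1000, seed = 1, presso = TRUE,
                        presso_n_sim = 1000,
                        exposure = "exposure", outcome = "outcome") {
  pairs <- kept_pairs(pairs)
  n <- nrow(pairs)
  if (n == 0) abort("no kept harmonized pairs")
  if (n == 1) {
    est <- wald_ratio(pairs)
    return(structure(list(estimates = est, heterogeneity = NULL, loo = NULL,
                          funnel = funnel_data(pairs), presso = NULL,
                          pairs = pairs, exposure = exposure,
                          outcome = outcome),
                     class = "mr_fit"))
  }
  ivw <- mr_ivw(pairs)
  ests <- ivw
  het <- cochran_q(pairs)
  het$method <- "ivw"
  if (n >= 3) {
    egg <- mr_egger(pairs)
    wm <- mr_weighted_median(pairs, n_boot = n_boot, seed = seed)
    ests <- dplyr::bind_rows(ivw, egg, wm)
    het_e <- cochran_q(pairs, egg[egg$method == "egger_slope", ])
    het_e$method <- "egger"
    het <- dplyr::bind_rows(het, het_e)
  }
  loo <- if (n >= 3) leave_one_out(pairs) else NULL
  pres <- if (presso && n >= 4) {
    mr_presso(pairs, n_sim = presso_n_sim, seed = seed)
  } else {
    NULL
  }
  structure(list(estimates = ests, heterogeneity = het, loo = loo,
                 funnel = funnel_data(pairs), presso = pres, pairs = pairs,
                 exposure = exposure, outcome = outcome),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, ...) {
  cat(sprintf("MR analysis: %s -> %s (%d instruments)\n",
              x$exposure, x$outcome, x$estimates$n_snp[1]))
  print(dplyr::select(x$estimates, "method", "beta", "se", "or",
                      "or_lci", "or_uci", "pval"))
  invisible(x)
}
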