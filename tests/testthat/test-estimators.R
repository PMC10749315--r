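test_that("wald ratio arithmetic and degenerate cases", {
  p <- make_pairs(beta_exp = 0.1, beta_out = 0.05, se_out = 0.02)
  w <- wald_ratio(p)
  expect_equal(w$beta, 0.5)
  expect_equal(w$se, 0.2)
  expect_equal(w$ci_low, 0.5 - 1.96 * 0.2)
  expect_equal(w$or, exp(0.5))

  null <- wald_ratio(make_pairs(0.1, 0, se_out = 0.02))
  expect_equal(null$beta, 0)
  expect_equal(null$pval, 1)

  expect_error(wald_ratio(make_pairs(0, 0.05)), "zero")
})

test_that("first-order wald SE agrees with the numeric delta method for strong instruments", {
  withr::local_seed(13)
  # second-order delta SE adds the term (beta_out * se_exp / beta_exp^2)^2
  for (i in 1:100) {
    beta_exp <- runif(1, 0.05, 0.2) * sample(c(-1, 1), 1)
    se_exp <- abs(beta_exp) / runif(1, 12, 40)  # |beta_exp|/se_exp > 10
    beta_out <- runif(1, -0.9, 0.9) * beta_exp  # |ratio| below 1
    se_out <- se_exp * runif(1, 2.5, 10)        # outcome GWAS noisier
    w <- wald_ratio(make_pairs(beta_exp, beta_out, se_exp, se_out))
    se2 <- sqrt(se_out^2 / beta_exp^2 +
                  beta_out^2 * se_exp^2 / beta_exp^4)
    expect_lt(abs(w$se - se2) / se2, 0.1)
  }
})

test_that("IVW reproduces consensus, matches WLS oracle, handles RE inflation", {
  cons <- make_pairs(c(0.1, 0.2), c(0.05, 0.1), se_out = 0.02)
  est <- mr_ivw(cons)
  expect_equal(est$beta, 0.5, tolerance = 1e-12)
  expect_equal(attr(est, "q"), 0, tolerance = 1e-20)

  withr::local_seed(17)
  pairs <- make_pairs(beta_exp = rnorm(20, 0, 0.1),
                      beta_out = rnorm(20, 0, 0.05),
                      se_out = runif(20, 0.01, 0.05))
  fit <- lm(beta_out ~ 0 + beta_exp, data = pairs,
            weights = 1 / pairs$se_out^2)
  est_f <- mr_ivw(pairs, model = "fixed")
  expect_equal(est_f$beta, unname(coef(fit)), tolerance = 1e-10)

  # multiplicative RE: same point estimate, SE inflated by sqrt(Q/(n-1)),
  # never below the fixed-effect SE
  est_re <- mr_ivw(pairs, model = "multiplicative_re")
  expect_equal(est_re$beta, est_f$beta)
  q <- attr(est_f, "q")
  expect_equal(est_re$se, est_f$se * max(1, sqrt(q / 19)), tolerance = 1e-12)
  expect_gte(est_re$se, est_f$se)

  # a single pair collapses to the wald ratio exactly
  one <- make_pairs(0.1, 0.05, se_out = 0.02)
  expect_equal(mr_ivw(one)$beta, wald_ratio(one)$beta)
  expect_equal(mr_ivw(one)$se, wald_ratio(one)$se)
})

test_that("Egger recovers an exact linear law and matches the WLS oracle", {
  x <- c(0.05, 0.1, 0.15, 0.2)
  exact <- make_pairs(x, 0.02 + 0.5 * x, se_out = 1e-6)
  egg <- mr_egger(exact)
  slope <- egg[egg$method == "egger_slope", ]
  inter <- egg[egg$method == "egger_intercept", ]
  expect_equal(slope$beta, 0.5, tolerance = 1e-6)
  expect_equal(inter$beta, 0.02, tolerance = 1e-6)
  expect_lt(inter$se, 1e-4)

  withr::local_seed(19)
  pairs <- make_pairs(beta_exp = abs(rnorm(15, 0.1, 0.05)) + 0.01,
                      beta_out = rnorm(15, 0, 0.05),
                      se_out = runif(15, 0.01, 0.05))
  fit <- lm(beta_out ~ beta_exp, data = pairs, weights = 1 / pairs$se_out^2)
  egg2 <- mr_egger(pairs)
  expect_equal(egg2$beta[egg2$method == "egger_slope"],
               unname(coef(fit)["beta_exp"]), tolerance = 1e-10)
  expect_equal(egg2$beta[egg2$method == "egger_intercept"],
               unname(coef(fit)["(Intercept)"]), tolerance = 1e-10)

  expect_error(mr_egger(make_pairs(c(0.1, 0.2), c(0.05, 0.1))),
               "insufficient")
})

test_that("Egger orientation flip leaves the fit invariant", {
  withr::local_seed(29)
  pairs <- random_pairs(20, theta = 0.4)
  flipped <- pairs
  flipped$beta_exp <- -flipped$beta_exp
  flipped$beta_out <- -flipped$beta_out
  expect_equal(mr_egger(pairs)$beta, mr_egger(flipped)$beta,
               tolerance = 1e-12)
})

test_that("Egger with intercept forced to zero is IVW", {
  # algebraic identity checked on data: constrained WLS through the origin
  withr::local_seed(37)
  pairs <- make_pairs(abs(rnorm(10, 0.1, 0.03)), rnorm(10, 0.04, 0.02),
                      se_out = runif(10, 0.01, 0.03))
  fit0 <- lm(beta_out ~ 0 + beta_exp, data = pairs,
             weights = 1 / pairs$se_out^2)
  expect_equal(mr_ivw(pairs, "fixed")$beta, unname(coef(fit0)),
               tolerance = 1e-10)
})

test_that("weighted median: symmetric case, duplication invariance, determinism", {
  p <- make_pairs(c(0.1, 0.1, 0.1), c(0.04, 0.05, 0.06), se_out = 0.02)
  wm <- mr_weighted_median(p, n_boot = 50, seed = 1)
  expect_equal(wm$beta, 0.5, tolerance = 1e-12)

  withr::local_seed(41)
  pairs <- random_pairs(15, theta = 0.3, se_out = runif(15, 0.01, 0.05))
  a <- mr_weighted_median(pairs, n_boot = 10, seed = 3)
  dup <- dplyr::bind_rows(pairs, pairs)
  b <- mr_weighted_median(dup, n_boot = 10, seed = 3)
  expect_equal(a$beta, b$beta, tolerance = 1e-12)

  c1 <- mr_weighted_median(pairs, n_boot = 200, seed = 99)
  c2 <- mr_weighted_median(pairs, n_boot = 200, seed = 99)
  expect_identical(c1$se, c2$se)

  expect_error(mr_weighted_median(pairs, n_boot = 1), "n_boot")
})

test_that("weighted median resists 30% invalid instruments where IVW is biased", {
  withr::local_seed(43)
  theta <- 0.5
  reps <- 60
  n <- 30
  wm <- numeric(reps); ivw <- numeric(reps)
  for (r in seq_len(reps)) {
    gamma <- rep(0.06, n)
    invalid <- seq_len(n) <= 9          # 30% invalid, one-sided pleiotropy
    pleio <- ifelse(invalid, 0.06, 0)   # shifts those ratios by +1.0
    pairs <- make_pairs(
      beta_exp = rnorm(n, gamma, 0.002),
      beta_out = rnorm(n, theta * gamma + pleio, 0.006),
      se_exp = 0.002, se_out = 0.006
    )
    wm[r] <- mr_weighted_median(pairs, n_boot = 2, seed = r)$beta
    ivw[r] <- mr_ivw(pairs)$beta
  }
  # residual finite-sample bias of the weighted median stays within the
  # estimator's own Monte-Carlo spread; IVW absorbs the pleiotropy head-on
  expect_lt(abs(mean(wm) - theta), 3 * sd(wm))
  expect_gt(abs(mean(ivw) - theta), 5 * abs(mean(wm) - theta))
})

test_that("Cochran's Q: homogeneity, additivity, degrees of freedom", {
  cons <- make_pairs(c(0.1, 0.2, 0.3), c(0.05, 0.1, 0.15), se_out = 0.02)
  q0 <- cochran_q(cons)
  expect_equal(q0$q, 0, tolerance = 1e-20)
  expect_equal(q0$pval, 1)
  expect_equal(q0$df, 2L)

  # one planted outlier dominates Q; removing it removes its contribution
  out <- make_pairs(c(0.1, 0.2, 0.3, 0.1), c(0.05, 0.1, 0.15, 0.15),
                    se_out = 0.02)
  q1 <- cochran_q(out, mr_ivw(out, "fixed"))
  b_fixed <- mr_ivw(out, "fixed")$beta
  d <- (out$beta_exp^2 / out$se_out^2) *
    (out$beta_out / out$beta_exp - b_fixed)^2
  expect_equal(q1$q, sum(d), tolerance = 1e-10)
  expect_gt(d[4] / q1$q, 0.5)

  # egger-style Q uses n - 2 degrees of freedom
  withr::local_seed(47)
  pairs <- random_pairs(10, 0.4)
  qe <- cochran_q(pairs, mr_egger(pairs)[1, ])
  expect_equal(qe$df, 8L)
})

test_that("Q follows its chi-square reference under homogeneity", {
  withr::local_seed(53)
  reps <- 500
  df <- 19
  qs <- replicate(reps, {
    pairs <- random_pairs(20, theta = 0.4, se_exp = 1e-6)
    cochran_q(pairs)$q
  })
  # mean of chi-square(df) is df, variance 2 df
  mcse <- sqrt(2 * df / reps)
  expect_lt(abs(mean(qs) - df), 3 * mcse)
})

test_that("leave-one-out enumerates instruments and isolates outliers", {
  cons <- make_pairs(c(0.1, 0.2, 0.3, 0.15), c(0.05, 0.1, 0.15, 0.075),
                     se_out = 0.02)
  loo <- leave_one_out(cons)
  expect_equal(nrow(loo), 4)
  expect_equal(loo$beta, rep(0.5, 4), tolerance = 1e-12)

  withr::local_seed(59)
  pairs <- random_pairs(12, theta = 0.5, se_out = 0.01)
  pairs$beta_out[5] <- pairs$beta_out[5] + 0.2   # planted outlier
  loo2 <- leave_one_out(pairs)
  # the row excluding the outlier is the farthest from the consensus of rows
  dev <- abs(loo2$beta - median(loo2$beta))
  expect_equal(loo2$excluded_id[which.max(dev)], pairs$variant_id[5])
})

test_that("MR-PRESSO flags a planted pleiotropic outlier, deterministically", {
  withr::local_seed(61)
  pairs <- random_pairs(20, theta = 0.5, se_out = 0.02)
  pairs$beta_out[7] <- pairs$beta_out[7] + 10 * pairs$se_out[7]
  pr <- mr_presso(pairs, n_sim = 500, seed = 4)
  expect_true(pairs$variant_id[7] %in% pr$outlier_ids)
  expect_lt(pr$global_pval, 0.05)

  pr2 <- mr_presso(pairs, n_sim = 500, seed = 4)
  expect_identical(pr$global_rss_obs, pr2$global_rss_obs)
  expect_identical(pr$global_pval, pr2$global_pval)
  expect_identical(pr$outliers$pval, pr2$outliers$pval)

  expect_error(mr_presso(pairs[1:3, ]), "at least 4")
  expect_error(mr_presso(pairs, n_sim = 50), "at least 100")
})

test_that("MR-PRESSO global p is well calibrated under the null", {
  withr::local_seed(67)
  reps <- 120
  ps <- replicate(reps, {
    pairs <- random_pairs(15, theta = 0.4, se_exp = 1e-6)
    mr_presso(pairs, n_sim = 150, seed = sample.int(1e6, 1))$global_pval
  })
  # simulation p-values live on a 1/(n_sim+1) grid, so ties are expected
  expect_gt(suppressWarnings(stats::ks.test(ps, "punif")$p.value), 0.01)
})

test_that("funnel data is the ratio/precision transform", {
  p <- make_pairs(0.1, 0.05, se_out = 0.02)
  fd <- funnel_data(p)
  expect_equal(fd$ratio, wald_ratio(p)$beta)
  expect_equal(fd$precision, 0.1 / 0.02)

  empty <- make_pairs(0.1, 0.05)
  empty$status <- "dropped_palindromic"
  expect_equal(nrow(funnel_data(empty)), 0)

  # symmetric data: no association between ratio and precision
  withr::local_seed(71)
  pairs <- random_pairs(300, theta = 0.4, se_out = runif(300, 0.01, 0.06))
  fd2 <- funnel_data(pairs)
  fit <- lm(ratio ~ precision, data = fd2)
  expect_gt(summary(fit)$coefficients["precision", 4], 0.01)
})

test_that("mr_analysis assembles estimates, sensitivity and tidiers", {
  withr::local_seed(73)
  pairs <- random_pairs(25, theta = -0.4)
  fit <- mr_analysis(pairs, n_boot = 50, presso_n_sim = 150, seed = 2,
                     exposure = "edu", outcome = "psoriasis")
  expect_s3_class(fit, "mr_fit")
  expect_setequal(fit$estimates$method,
                  c("ivw_re", "egger_slope", "egger_intercept",
                    "weighted_median"))
  td <- tidy(fit)
  expect_equal(td$exposure[1], "edu")
  gl <- glance(fit)
  expect_equal(gl$n_snp, 25L)
  expect_true(is.finite(gl$presso_global_pval))
  expect_s3_class(autoplot(fit), "ggplot")
  expect_s3_class(plot_funnel(fit), "ggplot")
  expect_s3_class(plot_loo(fit), "ggplot")

  single <- mr_analysis(pairs[1, ])
  expect_equal(single$estimates$method, "wald")
})
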