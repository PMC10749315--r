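#' Convert an odds ratio to a log odds ratio
#'
#' Binary-outcome effects are combined on the additive log-odds scale, so
#' published odds ratios are converted with the natural logarithm before
#' entering the product-of-coefficients decomposition.
#'
#' @param or_value Odds ratio(s), strictly positive.
#' @return `log(or_value)`.
#' @export
logor <- function(or_value) {
  if (any(!is.finite(or_value)) || any(or_value <= 0)) {
    abort("odds ratios must be strictly positive")
  }
  log(or_value)
}

#' Back-derive a log-scale standard error from a 95% odds-ratio CI
#'
#' `(log(uci) - log(lci)) / (2 * 1.96)` — the inverse of building a Wald
#' 95% interval on the log-odds scale.
#'
#' @param lci,uci Lower and upper 95% confidence limits, `0 < lci < uci`.
#' @return The standard error of the log odds ratio.
#' @export
se_from_ci <- function(lci, uci) {
  if (any(lci <= 0) || any(uci <= lci)) {
    abort("confidence limits must satisfy 0 < lci < uci")
  }
  (log(uci) - log(lci)) / (2 * Z95)
}

#' Product-of-coefficients mediation decomposition
#'
#' Decomposes a total effect `beta_total` of an exposure on an outcome into
#' an indirect component through a mediator, `indirect = beta_xm * beta_my`
#' (exposure-to-mediator times mediator-to-outcome), and a direct
#' component, `direct = beta_total - indirect`, on the additive
#' (linear/log-odds) scale. The proportion mediated is
#' `indirect / beta_total`, which may legitimately fall outside \[0, 1\]
#' and is reported as computed.
#'
#' First-order delta-method variances, treating the three estimates as
#' independent:
#' \deqn{Var(indirect) = \beta_1^2 se_2^2 + \beta_2^2 se_1^2}
#' \deqn{Var(prop) = Var(indirect)/\beta_0^2 +
#'   (\beta_1\beta_2)^2 se_0^2 / \beta_0^4}
#' The proportion's variance includes the `beta_total` sampling-error term;
#' 95% limits use the 1.96 multiplier.
#'
#' @param beta_total,se_total Total effect of the exposure on the outcome
#'   and its SE (log odds for binary outcomes).
#' @param beta_xm,se_xm Effect of the exposure on the mediator and its SE.
#' @param beta_my,se_my Effect of the mediator on the outcome and its SE.
#' @return A tibble of class `mr_mediation` (vectorized over rows):
#'   the six inputs plus `indirect`, `se_indirect`, `direct`, `proportion`,
#'   `se_proportion`, `prop_ci_low`, `prop_ci_high`.
#' @export
product_of_coefficients <- function(beta_total, se_total, beta_xm, se_xm,
                                    beta_my, se_my) {
  if (any(c(se_total, se_xm, se_my) <= 0)) {
    abort("all standard errors must be strictly positive")
  }
  indirect <- beta_xm * beta_my
  var_indirect <- beta_xm^2 * se_my^2 + beta_my^2 * se_xm^2
  zero_total <- beta_total == 0
  if (any(zero_total)) {
    warn("beta_total is zero: proportion mediated undefined (set to NA)")
  }
  b0 <- ifelse(zero_total, NA_real_, beta_total)
  proportion <- indirect / b0
  var_prop <- var_indirect / b0^2 + indirect^2 * se_total^2 / b0^4
  out <- tibble::tibble(
    beta_total = beta_total, se_total = se_total,
    beta_xm = beta_xm, se_xm = se_xm,
    beta_my = beta_my, se_my = se_my,
    indirect = indirect, se_indirect = sqrt(var_indirect),
    direct = beta_total - indirect,
    proportion = proportion, se_proportion = sqrt(var_prop),
    prop_ci_low = proportion - Z95 * sqrt(var_prop),
    prop_ci_high = proportion + Z95 * sqrt(var_prop)
  )
  class(out) <- c("mr_mediation", class(tibble::tibble()))
  out
}

#' Two-step Mendelian randomization
#'
#' Runs the full instrument-selection and estimation pipeline three times —
#' exposure to outcome (total effect, exposure instruments), exposure to
#' mediator (exposure instruments), mediator to outcome (mediator
#' instruments) — and feeds the three IVW estimates into
#' [product_of_coefficients()].
#'
#' @param exposure,mediator,outcome `mr_sumstats` tibbles.
#' @param ld Optional `ld_ref` used to clump each instrument set.
#' @param p_threshold Instrument significance threshold (default `5e-8`).
#' @param window_kb,r2_max Clumping parameters (defaults 10000 kb, 0.001).
#' @param exclude_outcome_p Optional threshold for removing
#'   outcome-associated instruments from each leg; `NULL` (default) skips
#'   the exclusion.
#' @param seed Seed for the weighted-median bootstrap inside each leg.
#' @param estimator Which estimate carries each leg into the decomposition;
#'   IVW with multiplicative random effects by default.
#' @return An `mr_mediation` tibble (one row) with attribute `"legs"`: a
#'   named list of the three leg estimate tibbles and instrument counts.
#' @export
two_step_mr <- function(exposure, mediator, outcome, ld = NULL,
                        p_threshold = 5e-8, window_kb = 10000,
                        r2_max = 0.001, exclude_outcome_p = NULL,
                        seed = 1, estimator = "ivw_re") {
  leg <- function(from, to, label, exclude_in = NULL) {
    iv <- select_significant(from, p_threshold)
    if (length(iv) == 0) {
      abort(sprintf("no instruments for the %s leg", label))
    }
    if (!is.null(ld)) {
      iv <- clump(iv, from, ld, window_kb = window_kb, r2_max = r2_max)
    }
    if (!is.null(exclude_outcome_p)) {
      iv <- exclude_outcome_associated(iv, to, exclude_outcome_p)
    }
    if (length(iv) == 0) {
      abort(sprintf("no instruments survive for the %s leg", label))
    }
    pairs <- harmonize(
      dplyr::filter(tibble::as_tibble(from), .data$variant_id %in% iv),
      to
    )
    kept <- kept_pairs(pairs)
    if (nrow(kept) == 0) {
      abort(sprintf("no harmonized instruments for the %s leg", label))
    }
    est <- if (nrow(kept) == 1) {
      wald_ratio(kept)
    } else {
      switch(estimator,
             ivw_re = mr_ivw(kept),
             ivw_fixed = mr_ivw(kept, model = "fixed"),
             weighted_median = mr_weighted_median(kept, seed = seed),
             abort(sprintf("unknown estimator '%s'", estimator)))
    }
    list(estimate = est, n_snp = nrow(kept))
  }
  total <- leg(exposure, outcome, "exposure->outcome")
  xm <- leg(exposure, mediator, "exposure->mediator")
  my <- leg(mediator, outcome, "mediator->outcome")
  res <- product_of_coefficients(
    total$estimate$beta, total$estimate$se,
    xm$estimate$beta, xm$estimate$se,
    my$estimate$beta, my$estimate$se
  )
  attr(res, "legs") <- list(total = total, exposure_mediator = xm,
                            mediator_outcome = my)
  res
}

#' Write a mediation result table as TSV
#'
#' Mirrors the usual published layout: odds ratios with 95% limits for the
#' exposure-to-mediator and mediator-to-outcome legs, then the proportion
#' mediated with its SE and 95% limits.
#'
#' @param result An `mr_mediation` tibble (one or more rows).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mediation <- function(result, path) {
  out <- dplyr::mutate(
    tibble::as_tibble(result),
    or_xm = exp(.data$beta_xm),
    or_xm_lci = exp(.data$beta_xm - Z95 * .data$se_xm),
    or_xm_uci = exp(.data$beta_xm + Z95 * .data$se_xm),
    or_my = exp(.data$beta_my),
    or_my_lci = exp(.data$beta_my - Z95 * .data$se_my),
    or_my_uci = exp(.data$beta_my + Z95 * .data$se_my)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}
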