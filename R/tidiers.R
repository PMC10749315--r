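#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy an MR fit into one row per estimator
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A tibble with `exposure`, `outcome`, `method`, `beta`, `se`,
#'   confidence limits, odds-ratio scale columns and `pval`.
#' @method tidy mr_fit
#' @export
tidy.mr_fit <- function(x, ...) {
  dplyr::mutate(x$estimates, exposure = x$exposure, outcome = x$outcome,
                .before = 1)
}

#' One-row summary of an MR fit
#'
#' @param x An `mr_fit` object.
#' @param ... Unused.
#' @return A one-row tibble: instrument count, IVW estimate and p, Egger
#'   intercept p (pleiotropy test), Cochran's Q and its p, MR-PRESSO global
#'   p, and whether all leave-one-out intervals share a sign.
#' @method glance mr_fit
#' @export
glance.mr_fit <- function(x, ...) {
  est <- x$estimates
  pick <- function(m, col) {
    v <- est[[col]][est$method %in% m]
    if (length(v) == 0) NA_real_ else v[1]
  }
  het <- x$heterogeneity
  tibble::tibble(
    exposure = x$exposure, outcome = x$outcome,
    n_snp = est$n_snp[1],
    beta_ivw = pick(c("ivw_re", "ivw_fixed", "wald"), "beta"),
    pval_ivw = pick(c("ivw_re", "ivw_fixed", "wald"), "pval"),
    egger_intercept_pval = pick("egger_intercept", "pval"),
    q = if (is.null(het)) NA_real_ else het$q[het$method == "ivw"][1],
    q_pval = if (is.null(het)) NA_real_ else het$pval[het$method == "ivw"][1],
    presso_global_pval = if (is.null(x$presso)) NA_real_ else x$presso$global_pval,
    loo_all_same_side = if (is.null(x$loo)) NA else attr(x$loo, "all_same_side")
  )
}

#' Tidy a mediation decomposition
#'
#' @param x An `mr_mediation` tibble.
#' @param ... Unused.
#' @return The underlying tibble in long form: one row per quantity
#'   (`total`, `indirect`, `direct`, `proportion`) with estimate and SE.
#' @method tidy mr_mediation
#' @export
tidy.mr_mediation <- function(x, ...) {
  x <- tibble::as_tibble(x)
  purrr::map_dfr(seq_len(nrow(x)), function(i) {
    r <- x[i, ]
    tibble::tibble(
      row = i,
      term = c("total", "indirect", "direct", "proportion"),
      estimate = c(r$beta_total, r$indirect, r$direct, r$proportion),
      std.error = c(r$se_total, r$se_indirect, NA_real_, r$se_proportion)
    )
  })
}

#' One-row summary of a mediation decomposition
#'
#' @param x An `mr_mediation` tibble (typically one row).
#' @param ... Unused.
#' @return A tibble with the proportion mediated, its SE and 95% limits.
#' @method glance mr_mediation
#' @export
glance.mr_mediation <- function(x, ...) {
  dplyr::select(tibble::as_tibble(x), "proportion", "se_proportion",
                "prop_ci_low", "prop_ci_high")
}

#' Tidy an MR-PRESSO report into the per-instrument outlier table
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return The per-instrument tibble with raw and Bonferroni-adjusted
#'   outlier p-values.
#' @method tidy mr_presso
#' @export
tidy.mr_presso <- function(x, ...) x$outliers

#' One-row summary of an MR-PRESSO report
#'
#' @param x An `mr_presso` object.
#' @param ... Unused.
#' @return A tibble with the observed global RSS, global p-value, outlier
#'   count and simulation settings.
#' @method glance mr_presso
#' @export
glance.mr_presso <- function(x, ...) {
  tibble::tibble(global_rss_obs = x$global_rss_obs,
                 global_pval = x$global_pval,
                 n_outliers = length(x$outlier_ids),
                 n_sim = x$n_sim, seed = x$seed)
}
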