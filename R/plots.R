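#' @importFrom ggplot2 autoplot ggplot aes geom_point geom_errorbar
#'   geom_errorbarh geom_abline geom_vline geom_hline labs theme_bw
#' @export
ggplot2::autoplot

#' Scatter plot of a single-pair MR fit
#'
#' Per-variant exposure and outcome effects with their error bars, overlaid
#' with the fitted IVW, Egger and weighted-median lines.
#'
#' @param object An `mr_fit` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mr_fit
#' @export
autoplot.mr_fit <- function(object, ...) {
  pairs <- object$pairs
  est <- object$estimates
  lines <- dplyr::filter(est, .data$method %in%
                           c("ivw_re", "ivw_fixed", "wald",
                             "egger_slope", "weighted_median"))
  intercept <- est$beta[est$method == "egger_intercept"]
  lines$intercept <- ifelse(lines$method == "egger_slope",
                            if (length(intercept)) intercept else 0, 0)
  ggplot(pairs, aes(x = .data$beta_exp, y = .data$beta_out)) +
    geom_errorbar(aes(ymin = .data$beta_out - .data$se_out,
                      ymax = .data$beta_out + .data$se_out),
                  colour = "grey70", width = 0) +
    geom_errorbarh(aes(xmin = .data$beta_exp - .data$se_exp,
                       xmax = .data$beta_exp + .data$se_exp),
                   colour = "grey70", height = 0) +
    geom_point(size = 1.5) +
    geom_abline(data = lines,
                aes(slope = .data$beta, intercept = .data$intercept,
                    colour = .data$method)) +
    labs(x = sprintf("SNP effect on %s", object$exposure),
         y = sprintf("SNP effect on %s", object$outcome),
         colour = NULL) +
    theme_bw()
}

#' Funnel plot of per-variant ratio estimates
#'
#' Instrument precision against the Wald ratio; asymmetry about the pooled
#' estimate suggests directional pleiotropy.
#'
#' @param fit An `mr_fit` object, or a harmonized pair table.
#' @return A ggplot object.
#' @export
plot_funnel <- function(fit) {
  if (inherits(fit, "mr_fit")) {
    dat <- fit$funnel
    ivw <- fit$estimates$beta[fit$estimates$method %in%
                                c("ivw_re", "ivw_fixed", "wald")][1]
  } else {
    dat <- funnel_data(fit)
    ivw <- mr_ivw(fit)$beta
  }
  ggplot(dat, aes(x = .data$ratio, y = .data$precision)) +
    geom_point() +
    geom_vline(xintercept = ivw, linetype = "dashed") +
    labs(x = "per-variant causal estimate (Wald ratio)",
         y = "precision (1 / SE of ratio)") +
    theme_bw()
}

#' Leave-one-out forest plot
#'
#' One IVW estimate per excluded instrument with its 95% interval; a
#' result that survives every exclusion has all intervals on one side of
#' zero.
#'
#' @param fit An `mr_fit` object with a leave-one-out table.
#' @return A ggplot object.
#' @export
plot_loo <- function(fit) {
  stopifnot(inherits(fit, "mr_fit"))
  if (is.null(fit$loo)) abort("fit has no leave-one-out table")
  dat <- dplyr::arrange(fit$loo, .data$beta)
  dat$excluded_id <- factor(dat$excluded_id, levels = dat$excluded_id)
  ggplot(dat, aes(x = .data$beta, y = .data$excluded_id)) +
    geom_point() +
    geom_errorbarh(aes(xmin = .data$ci_low, xmax = .data$ci_high),
                   height = 0) +
    geom_vline(xintercept = 0, linetype = "dashed") +
    labs(x = "IVW estimate with instrument excluded", y = NULL) +
    theme_bw()
}
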