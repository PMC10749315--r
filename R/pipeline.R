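#' Bonferroni-corrected significance threshold
#'
#' @param alpha Family-wise error rate in (0, 1) (default 0.05).
#' @param m Number of tests (>= 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 1) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  alpha / m
}

#' Fisher's combined probability test
#'
#' Combines independent p-values through `X = -2 * sum(log(p))`, referred
#' to a chi-square distribution with `2k` degrees of freedom.
#'
#' @param pvals Non-empty numeric vector of p-values in (0, 1].
#' @return The combined p-value.
#' @export
fisher_combined_p <- function(pvals) {
  if (length(pvals) == 0) abort("no p-values supplied")
  if (any(!is.finite(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    abort("p-values must lie in (0, 1]")
  }
  x <- -2 * sum(log(pvals))
  clamp_pval(pchisq(x, df = 2 * length(pvals), lower.tail = FALSE))
}

#' Significance tier of an MR estimate
#'
#' `significant` when `pval < alpha / bonferroni_m`, `nominal` when below
#' `alpha` but not the corrected threshold, `ns` otherwise.
#'
#' @param pval P-value(s).
#' @param bonferroni_m Number of estimates in the family.
#' @param alpha Nominal level (default 0.05).
#' @return Character vector of tiers.
#' @export
assign_tier <- function(pval, bonferroni_m, alpha = 0.05) {
  thr <- bonferroni_threshold(alpha, bonferroni_m)
  dplyr::case_when(
    pval < thr ~ "significant",
    pval < alpha ~ "nominal",
    TRUE ~ "ns"
  )
}

resolve_stats <- function(x, trait_type = "continuous") {
  if (inherits(x, "mr_sumstats")) return(x)
  if (is.character(x) && length(x) == 1) {
    return(read_sumstats(x, trait_type = trait_type))
  }
  abort("each trait must be an mr_sumstats object or a file path")
}

#' Run a batch of exposure x outcome (x mediator) MR analyses
#'
#' For every exposure-outcome pair: significance selection, optional LD
#' clumping, removal of outcome-associated instruments, harmonization,
#' MR-PRESSO outlier removal, then the IVW / Egger / weighted-median
#' estimates with the sensitivity battery and a Bonferroni significance
#' tier. For every exposure-mediator-outcome triple, a two-step mediation
#' decomposition. Per-pair failures are logged in the manifest and skipped;
#' the batch only fails when every pair fails. Deterministic given `seed`.
#'
#' @param config A named list (or path to a YAML file) with elements:
#'   `exposures`, `outcomes`, and optionally `mediators` — named lists of
#'   `mr_sumstats` objects or file paths; optional `ld` (an `ld_ref` or
#'   `list(variants=, edges=)` paths); optional scalars `p_select`
#'   (default `5e-8`), `window_kb` (10000), `r2_max` (0.001),
#'   `outcome_exclusion_p` (`5e-8`), `alpha` (0.05), `bonferroni_m`
#'   (defaults to the number of exposure-outcome pairs), `n_boot` (1000),
#'   `presso_n_sim` (1000), `presso` (TRUE), `seed` (1), `output_dir`
#'   (write TSV tables and a JSON manifest when set).
#' @return A list of class `mr_batch`: `results` (one row per pair and
#'   method with tier), `mediation` (one row per triple), `fits` (named
#'   list of `mr_fit`), `manifest` (thresholds, seed, failures).
#' @export
run_batch <- function(config) {
  if (is.character(config) && length(config) == 1) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config), !is.null(config$exposures),
            !is.null(config$outcomes))
  cfg <- utils::modifyList(
    list(p_select = 5e-8, window_kb = 10000, r2_max = 0.001,
         outcome_exclusion_p = 5e-8, alpha = 0.05, n_boot = 1000,
         presso_n_sim = 1000, presso = TRUE, seed = 1,
         mediators = list(), ld = NULL, output_dir = NULL,
         bonferroni_m = NULL),
    config
  )
  exposures <- purrr::map(cfg$exposures, resolve_stats)
  outcomes <- purrr::map(cfg$outcomes, resolve_stats,
                         trait_type = "binary")
  mediators <- purrr::map(cfg$mediators, resolve_stats)
  ld <- cfg$ld
  if (is.list(ld) && !inherits(ld, "ld_ref")) {
    ld <- read_ld_reference(ld$variants, ld$edges)
  }
  m <- cfg$bonferroni_m %||% (length(exposures) * length(outcomes))

  fits <- list()
  failures <- list()
  instruments <- list()
  results <- list()

  for (e in names(exposures)) {
    iv <- select_significant(exposures[[e]], cfg$p_select)
    if (!is.null(ld) && length(iv) > 0) {
      iv <- clump(iv, exposures[[e]], ld,
                  window_kb = cfg$window_kb, r2_max = cfg$r2_max)
    }
    instruments[[e]] <- iv
    for (o in names(outcomes)) {
      key <- paste(e, o, sep = "->")
      fit <- tryCatch({
        if (length(iv) == 0) abort("no significant instruments")
        keep <- exclude_outcome_associated(iv, outcomes[[o]],
                                           cfg$outcome_exclusion_p)
        if (length(keep) == 0) abort("all instruments outcome-associated")
        pairs <- harmonize(
          dplyr::filter(tibble::as_tibble(exposures[[e]]),
                        .data$variant_id %in% keep),
          outcomes[[o]]
        )
        pairs <- kept_pairs(pairs)
        if (nrow(pairs) == 0) abort("no harmonized instruments")
        if (cfg$presso && nrow(pairs) >= 4) {
          pres <- mr_presso(pairs, n_sim = cfg$presso_n_sim, seed = cfg$seed)
          if (length(pres$outlier_ids) > 0) {
            pairs <- dplyr::filter(pairs,
                                   !.data$variant_id %in% pres$outlier_ids)
          }
        }
        mr_analysis(pairs, n_boot = cfg$n_boot, seed = cfg$seed,
                    presso = cfg$presso, presso_n_sim = cfg$presso_n_sim,
                    exposure = e, outcome = o)
      }, error = function(err) err)
      if (inherits(fit, "error")) {
        failures[[key]] <- conditionMessage(fit)
        next
      }
      fits[[key]] <- fit
      res <- dplyr::mutate(fit$estimates, exposure = e, outcome = o,
                           .before = 1)
      results[[key]] <- res
    }
  }
  if (length(fits) == 0 && length(failures) > 0) {
    abort(paste0("every exposure-outcome pair failed; first error: ",
                 failures[[1]]))
  }
  results <- dplyr::bind_rows(results)
  results$tier <- assign_tier(results$pval, m, cfg$alpha)

  mediation <- list()
  for (e in names(exposures)) {
    for (md in names(mediators)) {
      for (o in names(outcomes)) {
        key <- paste(e, md, o, sep = "->")
        res <- tryCatch(
          two_step_mr(exposures[[e]], mediators[[md]], outcomes[[o]],
                      ld = ld, p_threshold = cfg$p_select,
                      window_kb = cfg$window_kb, r2_max = cfg$r2_max,
                      seed = cfg$seed),
          error = function(err) err
        )
        if (inherits(res, "error")) {
          failures[[key]] <- conditionMessage(res)
          next
        }
        mediation[[key]] <- dplyr::mutate(tibble::as_tibble(res),
                                          exposure = e, mediator = md,
                                          outcome = o, .before = 1)
      }
    }
  }
  mediation <- dplyr::bind_rows(mediation)

  manifest <- list(
    seed = cfg$seed,
    thresholds = list(p_select = cfg$p_select, window_kb = cfg$window_kb,
                      r2_max = cfg$r2_max,
                      outcome_exclusion_p = cfg$outcome_exclusion_p,
                      alpha = cfg$alpha, bonferroni_m = m,
                      significant_below = bonferroni_threshold(cfg$alpha, m)),
    n_pairs = length(fits),
    instruments = purrr::map_int(instruments, length),
    failures = failures
  )
  out <- structure(list(results = results, mediation = mediation,
                        fits = fits, manifest = manifest),
                   class = "mr_batch")
  if (!is.null(cfg$output_dir)) {
    dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    write_mr_results(results, file.path(cfg$output_dir, "mr_results.tsv"))
    if (nrow(mediation) > 0) {
      write_mediation(mediation, file.path(cfg$output_dir, "mediation.tsv"))
    }
    jsonlite::write_json(manifest, file.path(cfg$output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA)
  }
  out
}

#' Write an MR result table as TSV
#'
#' Columns mirror the usual published layout: exposure, outcome, number of
#' SNPs, method, beta, SE, OR with 95% limits, p-value (plus the
#' significance tier when present).
#'
#' @param results The `results` tibble of an [run_batch()] output (or any
#'   estimate tibble with `exposure`/`outcome` columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mr_results <- function(results, path) {
  cols <- intersect(c("exposure", "outcome", "n_snp", "method", "beta",
                      "se", "or", "or_lci", "or_uci", "pval", "tier"),
                    names(results))
  readr::write_tsv(dplyr::select(results, dplyr::all_of(cols)), path,
                   progress = FALSE)
  invisible(path)
}

#' @export
print.mr_batch <- function(x, ...) {
  cat(sprintf("MR batch: %d pair(s), %d mediation triple(s), %d failure(s)\n",
              x$manifest$n_pairs,
              if (is.null(x$mediation)) 0L else nrow(x$mediation),
              length(x$manifest$failures)))
  print(x$results)
  invisible(x)
}
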