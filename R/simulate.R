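#' Generating parameters for a synthetic summary-statistics scenario
#'
#' Describes an instrument -> exposure -> (mediator ->) outcome structural
#' model from which GWAS summary statistics are drawn directly, at their
#' theoretical sampling distributions — the setting two-sample MR theory
#' assumes, with no individual-level genotypes involved. The total effect
#' is always `theta_total = direct + theta_xm * theta_my`.
#'
#' @param theta_xm True exposure-to-mediator effect (default 0.41).
#' @param theta_my True mediator-to-outcome effect, log-odds scale
#'   (default -0.60).
#' @param direct True direct exposure-to-outcome effect (default -0.13);
#'   the defaults give a total effect of -0.376 with about 65% mediated,
#'   the magnitude of a strong income-type mediation signal.
#' @param n_instruments Number of exposure instruments (default 100).
#' @param n_med_instruments Number of mediator-specific instruments
#'   (default 100): variants with a direct mediator effect and no exposure
#'   effect, which supply the mediator-to-outcome leg of two-step MR.
#' @param n_null Additional null variants with no effect anywhere, for
#'   exercising significance selection (default 50).
#' @param per_variant_r2 Expected exposure variance explained per
#'   instrument (default 0.001; with the default sample sizes this puts
#'   instruments comfortably past genome-wide significance).
#' @param pleiotropy_mode `"none"`, `"balanced"` (direct outcome effects
#'   drawn from `N(0, pleiotropy_sd)`), or `"directional"`
#'   (`N(pleiotropy_sd, pleiotropy_sd/2)`, so `pleiotropy_sd` is the mean
#'   shift).
#' @param pleiotropy_sd Pleiotropy scale (default 0).
#' @param invalid_fraction Fraction of instruments with an extra direct
#'   mediator effect (default 0); must be below 0.5 unless `force = TRUE`
#'   (the weighted median breaks down past half the weight).
#' @param invalid_sd Scale of the invalid instruments' extra effect.
#' @param maf_range Uniform range for minor-allele frequencies.
#' @param n_exp,n_med,n_out GWAS sample sizes (defaults 50000, 30000,
#'   30000 — consortium-scale studies shrunk to desk scale).
#' @param case_fraction Case fraction of the binary outcome GWAS (default
#'   0.1); outcome SEs scale as
#'   `1/sqrt(2 maf (1-maf) n case_fraction (1-case_fraction))`.
#' @param ld_block_size Variants per LD block (default 1 = no LD).
#' @param ld_rho Within-block r-squared (default 0).
#' @param seed RNG seed; generation is fully deterministic given the truth.
#' @param force Allow `invalid_fraction >= 0.5`.
#' @return A list of class `sim_truth`.
#' @export
sim_truth <- function(theta_xm = 0.41, theta_my = -0.60, direct = -0.13,
                      n_instruments = 100, n_med_instruments = 100,
                      n_null = 50,
                      per_variant_r2 = 0.001,
                      pleiotropy_mode = c("none", "balanced", "directional"),
                      pleiotropy_sd = 0, invalid_fraction = 0,
                      invalid_sd = 0.05, maf_range = c(0.05, 0.5),
                      n_exp = 50000, n_med = 30000, n_out = 30000,
                      case_fraction = 0.1, ld_block_size = 1, ld_rho = 0,
                      seed = 1, force = FALSE) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_instruments >= 1, n_med_instruments >= 0, n_null >= 0,
            per_variant_r2 > 0,
            pleiotropy_sd >= 0, invalid_fraction >= 0, invalid_fraction < 1,
            maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            n_exp > 0, n_med > 0, n_out > 0,
            case_fraction > 0, case_fraction < 1,
            ld_block_size >= 1, ld_rho >= 0, ld_rho < 1)
  if (invalid_fraction >= 0.5 && !force) {
    abort(paste0("invalid_fraction >= 0.5 breaks the weighted-median ",
                 "validity assumption; pass force = TRUE to generate anyway"))
  }
  structure(list(
    theta_xm = theta_xm, theta_my = theta_my, direct = direct,
    theta_total = direct + theta_xm * theta_my,
    n_instruments = as.integer(n_instruments),
    n_med_instruments = as.integer(n_med_instruments),
    n_null = as.integer(n_null),
    per_variant_r2 = per_variant_r2, pleiotropy_mode = pleiotropy_mode,
    pleiotropy_sd = pleiotropy_sd, invalid_fraction = invalid_fraction,
    invalid_sd = invalid_sd, maf_range = maf_range,
    n_exp = as.integer(n_exp), n_med = as.integer(n_med),
    n_out = as.integer(n_out), case_fraction = case_fraction,
    ld_block_size = as.integer(ld_block_size), ld_rho = ld_rho,
    seed = as.integer(seed)
  ), class = "sim_truth")
}

#' Simulate exposure, mediator and outcome GWAS summary statistics
#'
#' Draws per-variant summary statistics directly from their sampling
#' distributions under the structural model of a [sim_truth()]:
#' instrument effects `gamma_j` have fixed magnitude and random sign,
#' scaled so each instrument explains exactly `per_variant_r2` of the
#' exposure variance;
#' exposure betas are `gamma_j` plus noise with
#' `se = 1/sqrt(2 maf (1-maf) n_exp)`; mediator betas are
#' `theta_xm * gamma_j + delta_j` plus an extra direct effect for invalid
#' instruments, plus noise, where `delta_j` is nonzero only for the
#' mediator-specific instruments; outcome betas (log-odds scale) are
#' `theta_total * gamma_j + theta_my * delta_j` plus the mediated share of
#' invalid effects plus pleiotropy plus noise, with outcome SEs deflated
#' by the case fraction. Null variants carry no effects anywhere. LD is block-constant
#' r-squared `ld_rho` over consecutive `ld_block_size`-variant blocks on
#' one chromosome, variants spaced 10 kb apart.
#'
#' @param truth A `sim_truth` object.
#' @return A list: `exposure`, `mediator`, `outcome` (`mr_sumstats`),
#'   `ld` (`ld_ref`), and `truth` (with the invalid-instrument IDs
#'   recorded in `truth$invalid_ids`).
#' @export
simulate_sumstats <- function(truth) {
  stopifnot(inherits(truth, "sim_truth"))
  with_preserved_seed(truth$seed, {
    j_inst <- truth$n_instruments
    j_med <- truth$n_med_instruments
    j_all <- j_inst + j_med + truth$n_null
    ids <- sprintf("rs%05d", seq_len(j_all))
    maf <- runif(j_all, truth$maf_range[1], truth$maf_range[2])
    het <- 2 * maf * (1 - maf)

    # fixed magnitude, random sign: per-variant r2 is exactly per_variant_r2
    magnitude <- sqrt(truth$per_variant_r2 / het)
    gamma <- rep(0, j_all)
    gamma[seq_len(j_inst)] <- sample(c(-1, 1), j_inst, replace = TRUE) *
      magnitude[seq_len(j_inst)]
    # mediator instruments drawn at the same noncentrality (expected
    # chi-square) as exposure instruments, so selection behaves alike in
    # both GWAS regardless of their sample sizes
    med_idx <- j_inst + seq_len(j_med)
    delta <- rep(0, j_all)
    if (j_med > 0) {
      delta[med_idx] <- sample(c(-1, 1), j_med, replace = TRUE) *
        magnitude[med_idx] * sqrt(truth$n_exp / truth$n_med)
    }

    n_invalid <- floor(truth$invalid_fraction * j_inst)
    invalid <- rep(FALSE, j_all)
    if (n_invalid > 0) invalid[sample(seq_len(j_inst), n_invalid)] <- TRUE
    alpha <- ifelse(invalid, rnorm(j_all, 0, truth$invalid_sd), 0)

    pleio <- rep(0, j_all)
    if (truth$pleiotropy_mode != "none" && truth$pleiotropy_sd > 0) {
      pleio[seq_len(j_inst)] <- switch(
        truth$pleiotropy_mode,
        balanced = rnorm(j_inst, 0, truth$pleiotropy_sd),
        directional = rnorm(j_inst, truth$pleiotropy_sd,
                            truth$pleiotropy_sd / 2)
      )
    }

    se_exp <- 1 / sqrt(het * truth$n_exp)
    se_med <- 1 / sqrt(het * truth$n_med)
    se_out <- 1 / sqrt(het * truth$n_out *
                         truth$case_fraction * (1 - truth$case_fraction))

    beta_exp <- rnorm(j_all, gamma, se_exp)
    beta_med <- rnorm(j_all, truth$theta_xm * gamma + delta + alpha, se_med)
    beta_out <- rnorm(j_all,
                      truth$theta_total * gamma + truth$theta_my * delta +
                        truth$theta_my * alpha + pleio,
                      se_out)

    # one chromosome, 10 kb spacing; LD structure lives entirely in r2
    block <- (seq_len(j_all) - 1) %/% truth$ld_block_size
    pos <- 1e6 + (seq_len(j_all) - 1) * 1e4
    chrom <- rep("1", j_all)
    r2 <- diag(1, j_all)
    if (truth$ld_block_size > 1 && truth$ld_rho > 0) {
      same_block <- outer(block, block, "==")
      r2[same_block] <- truth$ld_rho
      diag(r2) <- 1
    }

    # alternate effect/other alleles, avoiding palindromic pairs
    allele_pairs <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))
    pick <- ((seq_len(j_all) - 1) %% 4) + 1
    ea <- vapply(allele_pairs[pick], `[`, character(1), 1)
    oa <- vapply(allele_pairs[pick], `[`, character(1), 2)

    mk <- function(beta, se, n, name, type) {
      as_sumstats(tibble::tibble(
        variant_id = ids, chrom = chrom, pos = as.integer(pos),
        effect_allele = ea, other_allele = oa, eaf = maf,
        beta = beta, se = se, pval = normal_pval(beta, se), n = n
      ), trait_name = name, trait_type = type)
    }
    out_truth <- truth
    out_truth$invalid_ids <- ids[invalid]
    list(
      exposure = mk(beta_exp, se_exp, truth$n_exp, "exposure", "continuous"),
      mediator = mk(beta_med, se_med, truth$n_med, "mediator", "continuous"),
      outcome = mk(beta_out, se_out, truth$n_out, "outcome", "binary"),
      ld = ld_reference(ids, r2, chrom, pos),
      truth = out_truth
    )
  })
}

scenario_truths <- function(seed) {
  list(
    null = sim_truth(theta_xm = 0, theta_my = 0, direct = 0, seed = seed),
    strong_mediation = sim_truth(theta_xm = 0.41, theta_my = -0.60,
                                 direct = 0, seed = seed),
    directional_pleiotropy = sim_truth(pleiotropy_mode = "directional",
                                       pleiotropy_sd = 0.02, seed = seed),
    weak_instruments = sim_truth(n_instruments = 30, n_null = 20,
                                 per_variant_r2 = 5e-5, n_exp = 3000,
                                 n_med = 3000, n_out = 3000, seed = seed)
  )
}

#' Materialize a named synthetic scenario as text fixtures
#'
#' Writes exposure/mediator/outcome summary statistics as TSV, the LD
#' reference as a variant table plus edge list, and a JSON sidecar with
#' the generating truth, into `out_dir`.
#'
#' @param scenario_name One of `"null"` (no causal effects),
#'   `"strong_mediation"` (full mediation, direct effect 0),
#'   `"directional_pleiotropy"`, `"weak_instruments"`.
#' @param out_dir Output directory (created if needed).
#' @param seed RNG seed for the scenario.
#' @return Invisibly, a named character vector of the written paths.
#' @export
write_fixture <- function(scenario_name, out_dir, seed = 1) {
  truths <- scenario_truths(seed)
  if (!scenario_name %in% names(truths)) {
    abort(paste0("unknown scenario '", scenario_name, "'; options: ",
                 paste(names(truths), collapse = ", ")))
  }
  sim <- simulate_sumstats(truths[[scenario_name]])
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    exposure = file.path(out_dir, "exposure.tsv"),
    mediator = file.path(out_dir, "mediator.tsv"),
    outcome = file.path(out_dir, "outcome.tsv"),
    ld_variants = file.path(out_dir, "ld_variants.tsv"),
    ld_edges = file.path(out_dir, "ld_edges.tsv"),
    truth = file.path(out_dir, "truth.json")
  )
  write_sumstats(sim$exposure, paths[["exposure"]])
  write_sumstats(sim$mediator, paths[["mediator"]])
  write_sumstats(sim$outcome, paths[["outcome"]])
  write_ld_reference(sim$ld, paths[["ld_variants"]], paths[["ld_edges"]])
  truth_list <- unclass(sim$truth)
  jsonlite::write_json(truth_list, paths[["truth"]], auto_unbox = TRUE,
                       digits = NA)
  invisible(paths)
}
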