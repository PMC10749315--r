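# in-code fixtures shared across the suite

# minimal summary-statistics tibble; alleles default to non-palindromic A/G
make_stats <- function(beta, se, pval = NULL, ids = NULL,
                       effect_allele = "A", other_allele = "G",
                       eaf = NA_real_, chrom = "1", pos = NULL,
                       n = 10000L, trait_name = "trait",
                       trait_type = "continuous") {
  k <- length(beta)
  as_sumstats(tibble::tibble(
    variant_id = ids %||% sprintf("rs%03d", seq_len(k)),
    chrom = rep_len(chrom, k),
    pos = pos %||% as.integer(seq_len(k) * 1e4),
    effect_allele = rep_len(effect_allele, k),
    other_allele = rep_len(other_allele, k),
    eaf = rep_len(eaf, k),
    beta = beta, se = se,
    pval = pval %||% pmax(2 * pnorm(-abs(beta / se)), .Machine$double.xmin),
    n = rep_len(n, k)
  ), trait_name = trait_name, trait_type = trait_type)
}

# harmonized pair table straight from numbers, all status kept
make_pairs <- function(beta_exp, beta_out, se_exp = 0.02, se_out = 0.02,
                       ids = NULL) {
  k <- length(beta_exp)
  tibble::tibble(
    variant_id = ids %||% sprintf("rs%03d", seq_len(k)),
    beta_exp = beta_exp, se_exp = rep_len(se_exp, k),
    eaf_exp = NA_real_,
    beta_out = beta_out, se_out = rep_len(se_out, k),
    eaf_out = NA_real_,
    flipped = FALSE, status = "kept"
  )
}

# draw a pair table from the standard instrument model with known slope
random_pairs <- function(n, theta, se_exp = 0.005, se_out = 0.03,
                         gamma_scale = 0.06) {
  gamma <- sample(c(-1, 1), n, TRUE) * gamma_scale
  make_pairs(
    beta_exp = rnorm(n, gamma, se_exp),
    beta_out = rnorm(n, theta * gamma, se_out),
    se_exp = se_exp, se_out = se_out
  )
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# independent pairwise check that a clump result is a legal greedy solution:
# no retained pair conflicts, every dropped candidate conflicts with a
# retained candidate of better (smaller) p-value
clump_is_valid <- function(retained, candidates, stats, ld, window_kb,
                           r2_max) {
  conflicts <- function(a, b) {
    ia <- match(a, ld$variant_ids); ib <- match(b, ld$variant_ids)
    ld$chrom[ia] == ld$chrom[ib] &&
      abs(ld$pos[ia] - ld$pos[ib]) <= window_kb * 1000 &&
      ld$r2[ia, ib] > r2_max
  }
  pv <- function(id) stats$pval[match(id, stats$variant_id)]
  for (a in retained) for (b in retained) {
    if (a != b && conflicts(a, b)) return(FALSE)
  }
  dropped <- setdiff(candidates, retained)
  for (d in dropped) {
    better <- retained[
      pv(retained) < pv(d) |
        (pv(retained) == pv(d) & retained < d)
    ]
    if (!any(vapply(better, conflicts, logical(1), b = d))) return(FALSE)
  }
  TRUE
}
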