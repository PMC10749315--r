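test_that("read_sumstats parses, validates and filters delimited text", {
  path <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    SNP = c("rs1", "rs2", "rs3"), chrom = "1", pos = c(100L, 200L, 300L),
    A1 = c("A", "C", "G"), A2 = c("G", "T", "A"),
    freq = c(0.2, 0.3, 0.4), b = c(0.1, -0.2, 0.05),
    se = c(0.02, 0.05, 0.01), p = c(1e-6, 1e-4, 1e-7), N = 5000L
  ), path)
  ss <- read_sumstats(path, trait_name = "exp", column_map = c(
    variant_id = "SNP", effect_allele = "A1", other_allele = "A2",
    eaf = "freq", beta = "b", se = "se", pval = "p", n = "N"
  ))
  expect_s3_class(ss, "mr_sumstats")
  expect_equal(nrow(ss), 3)
  expect_equal(ss$variant_id, c("rs1", "rs2", "rs3"))
  expect_equal(trait_type(ss), "continuous")

  # an indel row is dropped with a warning, not an error
  df <- tibble::tibble(
    variant_id = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "AT", "C"), other_allele = c("G", "A", "T"),
    beta = 0.1, se = 0.01
  )
  expect_warning(ss2 <- as_sumstats(df), "dropped 1")
  expect_equal(ss2$variant_id, c("rs1", "rs3"))

  # missing mandatory column and duplicate IDs are fatal
  expect_error(as_sumstats(df[, -2]), "missing mandatory")
  expect_error(as_sumstats(dplyr::mutate(df, variant_id = "rs1")), "rs1")
})

test_that("missing p-values are imputed from the normal tail of beta/se", {
  df <- tibble::tibble(
    variant_id = c("rs1", "rs2"), effect_allele = "A", other_allele = "G",
    beta = c(1.959964, 1), se = c(1, 0.5)
  )
  ss <- as_sumstats(df)
  expect_equal(ss$pval, 2 * pnorm(-abs(df$beta / df$se)), tolerance = 1e-12)
  expect_equal(ss$pval[1], 0.05, tolerance = 1e-6)
})

test_that("harmonize resolves every allele orientation", {
  exp <- make_stats(beta = rep(0.1, 6), se = 0.02,
                    ids = sprintf("rs%d", 1:6),
                    effect_allele = c("A", "A", "A", "A", "A", "A"),
                    other_allele  = c("G", "G", "G", "G", "G", "G"))
  # outcome orientations: same, swapped, strand-complement, complement
  # swapped, incompatible alleles, and one variant absent handled by
  # intersection
  out <- as_sumstats(tibble::tibble(
    variant_id = sprintf("rs%d", 1:5),
    effect_allele = c("A", "G", "T", "C", "A"),
    other_allele  = c("G", "A", "C", "T", "C"),
    beta = 0.05, se = 0.01
  ))
  h <- harmonize(exp, out)
  expect_equal(nrow(h), 5)
  expect_equal(h$status, c("kept", "kept", "kept", "kept",
                           "dropped_incompatible"))
  expect_equal(h$flipped, c(FALSE, TRUE, FALSE, TRUE, FALSE))
  expect_equal(h$beta_out, c(0.05, -0.05, 0.05, -0.05, 0.05))
  expect_equal(h$beta_exp, rep(0.1, 5))

  expect_error(harmonize(make_stats(0.1, 0.02, ids = "rsX"), out),
               "no overlapping")
})

test_that("palindromic variants are kept only with concordant extreme EAFs", {
  grid <- tibble::tibble(
    eaf_exp = c(0.10, 0.10, 0.45, 0.10, 0.90, 0.90),
    eaf_out = c(0.12, 0.90, 0.45, 0.55, 0.88, 0.12),
    expect  = c("kept", "dropped_palindromic", "dropped_palindromic",
                "dropped_palindromic", "kept", "dropped_palindromic")
  )
  for (i in seq_len(nrow(grid))) {
    exp <- make_stats(0.1, 0.02, effect_allele = "A", other_allele = "T",
                      eaf = grid$eaf_exp[i])
    out <- make_stats(0.05, 0.01, effect_allele = "A", other_allele = "T",
                      eaf = grid$eaf_out[i])
    h <- harmonize(exp, out, palindrome_eaf_window = 0.08)
    expect_equal(h$status, grid$expect[i],
                 label = sprintf("eaf pair (%.2f, %.2f)",
                                 grid$eaf_exp[i], grid$eaf_out[i]))
  }

  # letter-swapped palindromic variant: aligned (negated) before EAF test
  exp <- make_stats(0.1, 0.02, effect_allele = "A", other_allele = "T",
                    eaf = 0.10)
  out <- make_stats(0.05, 0.01, effect_allele = "T", other_allele = "A",
                    eaf = 0.88)
  h <- harmonize(exp, out)
  expect_equal(h$status, "kept")
  expect_true(h$flipped)
  expect_equal(h$beta_out, -0.05)

  # missing EAF: dropped by default, kept when configured permissive
  exp <- make_stats(0.1, 0.02, effect_allele = "C", other_allele = "G")
  out <- make_stats(0.05, 0.01, effect_allele = "C", other_allele = "G")
  expect_equal(harmonize(exp, out)$status, "dropped_palindromic")
  expect_equal(
    harmonize(exp, out, drop_palindromic_without_eaf = FALSE)$status,
    "kept"
  )
})

test_that("harmonization is idempotent, sign-symmetric and conserving", {
  withr::local_seed(7)
  k <- 40
  alle <- list(c("A", "G"), c("C", "T"), c("A", "T"), c("C", "G"))
  pick <- sample(1:4, k, TRUE)
  exp <- make_stats(rnorm(k, 0, 0.1), 0.02,
                    effect_allele = sapply(alle[pick], `[`, 1),
                    other_allele = sapply(alle[pick], `[`, 2),
                    eaf = runif(k, 0.05, 0.45))
  # outcome: same variants, randomly swapped orientation
  swap <- sample(c(TRUE, FALSE), k, TRUE)
  out_tbl <- tibble::as_tibble(exp)
  out_tbl$beta <- rnorm(k, 0, 0.05)
  tmp_ea <- ifelse(swap, out_tbl$other_allele, out_tbl$effect_allele)
  tmp_oa <- ifelse(swap, out_tbl$effect_allele, out_tbl$other_allele)
  out_tbl$effect_allele <- tmp_ea
  out_tbl$other_allele <- tmp_oa
  out_tbl$beta <- ifelse(swap, -out_tbl$beta, out_tbl$beta)
  out_tbl$eaf <- ifelse(swap, 1 - out_tbl$eaf, out_tbl$eaf)
  out <- as_sumstats(out_tbl)

  h <- harmonize(exp, out)
  # conservation: every shared variant is accounted for exactly once
  expect_equal(nrow(h), k)
  expect_setequal(unique(h$status),
                  intersect(c("kept", "dropped_palindromic",
                              "dropped_incompatible"), h$status))

  # sign symmetry: negating outcome betas and swapping outcome alleles
  # leaves every kept (beta_exp, beta_out) pair unchanged
  flip_tbl <- tibble::as_tibble(out)
  flip_tbl$beta <- -flip_tbl$beta
  flip_tbl$eaf <- 1 - flip_tbl$eaf
  ea <- flip_tbl$effect_allele
  flip_tbl$effect_allele <- flip_tbl$other_allele
  flip_tbl$other_allele <- ea
  h2 <- harmonize(exp, as_sumstats(flip_tbl))
  expect_equal(kept_pairs(h2)$beta_out, kept_pairs(h)$beta_out)
  expect_equal(h2$status, h$status)

  # idempotence: re-harmonizing an already aligned pair changes nothing
  kept <- kept_pairs(h)
  exp2 <- dplyr::semi_join(tibble::as_tibble(exp),
                           kept, by = "variant_id")
  out2 <- exp2
  out2$beta <- kept$beta_out
  out2$se <- kept$se_out
  out2$eaf <- kept$eaf_out
  h3 <- harmonize(as_sumstats(exp2), as_sumstats(out2))
  expect_equal(h3$beta_out, kept$beta_out)
  expect_false(any(h3$flipped))
})

test_that("sumstats round-trip through TSV unchanged", {
  path <- withr::local_tempfile(fileext = ".tsv")
  ss <- make_stats(c(0.1, -0.2), c(0.02, 0.03), eaf = c(0.2, 0.4))
  write_sumstats(ss, path)
  back <- read_sumstats(path, trait_name = trait_name(ss))
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(ss))
})
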