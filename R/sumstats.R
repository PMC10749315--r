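#' GWAS summary-statistics tables
#'
#' A summary-statistics object is a tibble with one row per variant and the
#' columns `variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, carrying the trait name and trait type
#' (`"continuous"` or `"binary"`) as attributes. For binary traits the betas
#' are log odds ratios, so that effects combine additively.
#'
#' @param x A data frame with (at least) `variant_id`, `effect_allele`,
#'   `other_allele`, `beta` and `se` columns. `chrom`, `pos`, `eaf`, `pval`
#'   and `n` are optional; a missing `pval` column is imputed from the
#'   two-sided normal tail of `|beta/se|`.
#' @param trait_name Label for the trait.
#' @param trait_type `"continuous"` (betas in SD units) or `"binary"`
#'   (betas on the log-odds scale).
#'
#' @details Rows violating the per-variant invariants are dropped with a
#'   warning giving the count: alleles must be single bases in A/C/G/T and
#'   distinct (indels and multi-allelic records are excluded), `se > 0`,
#'   `pval` in (0, 1], and `eaf` strictly inside (0, 1) when present.
#'   Duplicated `variant_id`s are an error, not a filter.
#'
#' @return A tibble of class `mr_sumstats`, row order preserved.
#' @export
as_sumstats <- function(x, trait_name = "trait",
                        trait_type = c("continuous", "binary")) {
  trait_type <- match.arg(trait_type)
  mandatory <- c("variant_id", "effect_allele", "other_allele", "beta", "se")
  missing_cols <- setdiff(mandatory, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("missing mandatory column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  x <- tibble::as_tibble(x)
  for (col in c("chrom", "pos", "eaf", "pval", "n")) {
    if (!col %in% names(x)) x[[col]] <- NA
  }
  x <- dplyr::mutate(
    x,
    variant_id = as.character(.data$variant_id),
    chrom = as.character(.data$chrom),
    pos = as.integer(.data$pos),
    effect_allele = toupper(as.character(.data$effect_allele)),
    other_allele = toupper(as.character(.data$other_allele)),
    eaf = as.numeric(.data$eaf),
    beta = as.numeric(.data$beta),
    se = as.numeric(.data$se),
    pval = as.numeric(.data$pval),
    n = as.integer(.data$n)
  )
  if (all(is.na(x$pval))) {
    x$pval <- normal_pval(x$beta, x$se)
  }

  dup <- x$variant_id[duplicated(x$variant_id)]
  if (length(dup) > 0) {
    abort(paste0("duplicate variant_id: ", paste(unique(dup), collapse = ", ")))
  }

  bases <- c("A", "C", "G", "T")
  ok <- x$effect_allele %in% bases &
    x$other_allele %in% bases &
    x$effect_allele != x$other_allele &
    !is.na(x$beta) & is.finite(x$beta) &
    !is.na(x$se) & x$se > 0 &
    !is.na(x$pval) & x$pval > 0 & x$pval <= 1 &
    (is.na(x$eaf) | (x$eaf > 0 & x$eaf < 1))
  if (any(!ok)) {
    warn(sprintf("dropped %d record(s) failing variant invariants (%s)",
                 sum(!ok), trait_name))
    x <- x[ok, , drop = FALSE]
  }

  x <- dplyr::select(x, "variant_id", "chrom", "pos", "effect_allele",
                     "other_allele", "eaf", "beta", "se", "pval", "n")
  structure(x,
            trait_name = trait_name, trait_type = trait_type,
            class = c("mr_sumstats", class(tibble::tibble())))
}

#' Read GWAS summary statistics from delimited text
#'
#' Reads a tab- or comma-delimited file with a header, renames columns
#' according to `column_map`, and validates the result with [as_sumstats()].
#'
#' @param path File path.
#' @param trait_name,trait_type Passed to [as_sumstats()].
#' @param column_map Optional named character vector mapping canonical names
#'   to file column names, e.g. `c(variant_id = "SNP", beta = "b")`.
#'   Unmapped canonical names are looked up verbatim.
#' @param delim Field delimiter; guessed from the file when `NULL`.
#' @return An `mr_sumstats` tibble.
#' @export
read_sumstats <- function(path, trait_name = basename(path),
                          trait_type = c("continuous", "binary"),
                          column_map = NULL, delim = NULL) {
  trait_type <- match.arg(trait_type)
  if (is.null(delim)) {
    first <- readLines(path, n = 1L)
    delim <- if (grepl("\t", first)) "\t" else ","
  }
  raw <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  if (!is.null(column_map)) {
    bad <- setdiff(unname(column_map), names(raw))
    if (length(bad) > 0) {
      abort(paste0("mapped column(s) absent from file: ",
                   paste(bad, collapse = ", ")))
    }
    for (canon in names(column_map)) {
      names(raw)[names(raw) == column_map[[canon]]] <- canon
    }
  }
  as_sumstats(raw, trait_name = trait_name, trait_type = trait_type)
}

#' Write summary statistics as tab-delimited text
#'
#' @param stats An `mr_sumstats` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sumstats <- function(stats, path) {
  readr::write_tsv(tibble::as_tibble(stats), path, progress = FALSE)
  invisible(path)
}

#' Trait metadata accessors
#' @param stats An `mr_sumstats` tibble.
#' @return The trait name or trait type string.
#' @export
trait_name <- function(stats) attr(stats, "trait_name") %||% "trait"

#' @rdname trait_name
#' @export
trait_type <- function(stats) attr(stats, "trait_type") %||% "continuous"

#' Align outcome effect alleles to the exposure orientation
#'
#' For every variant shared between the two GWAS, resolves allele
#' orientation through the standard ladder: exact match (kept as is),
#' swapped alleles (outcome beta negated and EAF reflected), strand
#' complement (realigned), complement-and-swap (realigned and negated).
#' Palindromic variants (A/T or C/G) cannot be resolved by allele letters,
#' so they are kept only when both effect-allele frequencies fall on the
#' same side of 0.5 and both lie outside `0.5 +/- palindrome_eaf_window`;
#' otherwise their status is `dropped_palindromic`. Irreconcilable allele
#' sets get status `dropped_incompatible`.
#'
#' @param exposure,outcome `mr_sumstats` tibbles.
#' @param palindrome_eaf_window Half-width of the ambiguous EAF band around
#'   0.5 (default 0.08, i.e. ambiguous when EAF is inside \[0.42, 0.58\]).
#' @param drop_palindromic_without_eaf Drop palindromic variants when either
#'   EAF is missing (default `TRUE`, the conservative choice); if `FALSE`
#'   they are aligned by allele letters assuming both GWAS report the same
#'   strand.
#' @return A tibble with one row per shared variant, in exposure order:
#'   `variant_id`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `flipped`, `status` (`kept`, `dropped_palindromic`,
#'   `dropped_incompatible`). `flipped = TRUE` records that `beta_out` was
#'   negated relative to the source file.
#' @export
harmonize <- function(exposure, outcome, palindrome_eaf_window = 0.08,
                      drop_palindromic_without_eaf = TRUE) {
  shared <- intersect(exposure$variant_id, outcome$variant_id)
  if (length(shared) == 0) abort("no overlapping variants")

  exp_df <- dplyr::filter(tibble::as_tibble(exposure),
                          .data$variant_id %in% shared)
  out_df <- tibble::as_tibble(outcome)[match(exp_df$variant_id,
                                             outcome$variant_id), ]

  ea_e <- exp_df$effect_allele; oa_e <- exp_df$other_allele
  ea_o <- out_df$effect_allele; oa_o <- out_df$other_allele
  beta_out <- out_df$beta
  eaf_out <- out_df$eaf

  pal <- is_palindromic(ea_e, oa_e)
  same <- ea_o == ea_e & oa_o == oa_e
  swapped <- ea_o == oa_e & oa_o == ea_e
  comp_same <- complement_alleles(ea_o) == ea_e & complement_alleles(oa_o) == oa_e
  comp_swapped <- complement_alleles(ea_o) == oa_e & complement_alleles(oa_o) == ea_e

  status <- rep("dropped_incompatible", length(shared))
  flipped <- rep(FALSE, length(shared))

  # non-palindromic ladder; for palindromic variants "swapped" and
  # "comp_same" coincide, so only the letter alignment is taken from it
  align_flip <- !pal & (swapped | comp_swapped)
  align_keep <- !pal & (same | comp_same)
  status[align_keep | align_flip] <- "kept"
  flipped[align_flip] <- TRUE
  beta_out[align_flip] <- -beta_out[align_flip]
  eaf_out[align_flip] <- 1 - eaf_out[align_flip]

  # palindromic: align by letters first, then disambiguate strand by EAF
  pal_same <- pal & same
  pal_swap <- pal & swapped
  beta_out[pal_swap] <- -beta_out[pal_swap]
  eaf_out[pal_swap] <- 1 - eaf_out[pal_swap]
  flipped[pal_swap] <- TRUE
  pal_aligned <- pal_same | pal_swap

  eaf_exp <- exp_df$eaf
  has_eaf <- !is.na(eaf_exp) & !is.na(eaf_out)
  w <- palindrome_eaf_window
  unambiguous <- has_eaf &
    abs(eaf_exp - 0.5) > w & abs(eaf_out - 0.5) > w &
    sign(eaf_exp - 0.5) == sign(eaf_out - 0.5)
  if (drop_palindromic_without_eaf) {
    status[pal_aligned] <- ifelse(unambiguous[pal_aligned],
                                  "kept", "dropped_palindromic")
  } else {
    status[pal_aligned] <- ifelse(!has_eaf[pal_aligned] | unambiguous[pal_aligned],
                                  "kept", "dropped_palindromic")
  }

  dropped <- status != "kept"
  flipped[dropped] <- FALSE

  tibble::tibble(
    variant_id = exp_df$variant_id,
    beta_exp = exp_df$beta, se_exp = exp_df$se, eaf_exp = eaf_exp,
    beta_out = beta_out, se_out = out_df$se, eaf_out = eaf_out,
    flipped = flipped, status = status
  )
}

#' Keep only harmonized pairs usable for estimation
#' @param pairs Output of [harmonize()].
#' @return The `kept` rows.
#' @export
kept_pairs <- function(pairs) {
  if ("status" %in% names(pairs)) {
    dplyr::filter(pairs, .data$status == "kept")
  } else {
    pairs
  }
}

#' Write a harmonized pair table as TSV
#' @param pairs Output of [harmonize()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_harmonized <- function(pairs, path) {
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}
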