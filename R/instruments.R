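#' LD reference panels
#'
#' A small in-memory LD reference: a square symmetric r-squared matrix over
#' a set of variants plus their chromosome and position, used only for
#' greedy clumping. Construct one directly from a matrix, or read it from
#' the text formats emitted by [write_ld_reference()].
#'
#' @param variant_ids Character vector of variant IDs (matrix order).
#' @param r2 Square symmetric matrix in \[0, 1\] with unit diagonal.
#' @param chrom Chromosome per variant.
#' @param pos 1-based position per variant.
#' @return A list of class `ld_ref`.
#' @export
ld_reference <- function(variant_ids, r2, chrom, pos) {
  k <- length(variant_ids)
  r2 <- as.matrix(r2)
  if (!all(dim(r2) == k)) abort("r2 must be a square matrix over variant_ids")
  if (length(chrom) != k || length(pos) != k) {
    abort("chrom and pos must have one entry per variant")
  }
  if (any(r2 < 0 | r2 > 1)) abort("r2 values must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-8) abort("r2 matrix must be symmetric")
  if (any(abs(diag(r2) - 1) > 1e-8)) abort("r2 diagonal must be 1")
  dimnames(r2) <- list(variant_ids, variant_ids)
  structure(list(variant_ids = as.character(variant_ids), r2 = r2,
                 chrom = as.character(chrom), pos = as.integer(pos)),
            class = "ld_ref")
}

#' Read an LD reference from a variant table and an r2 edge list
#'
#' @param variant_path TSV with columns `variant_id`, `chrom`, `pos`.
#' @param edge_path TSV with columns `id1`, `id2`, `r2`; unlisted pairs are
#'   taken as r2 = 0.
#' @return An `ld_ref` object.
#' @export
read_ld_reference <- function(variant_path, edge_path) {
  variants <- readr::read_tsv(variant_path, show_col_types = FALSE,
                              progress = FALSE)
  edges <- readr::read_tsv(edge_path, show_col_types = FALSE, progress = FALSE)
  ids <- as.character(variants$variant_id)
  k <- length(ids)
  r2 <- diag(1, k)
  dimnames(r2) <- list(ids, ids)
  if (nrow(edges) > 0) {
    i <- match(as.character(edges$id1), ids)
    j <- match(as.character(edges$id2), ids)
    keep <- !is.na(i) & !is.na(j)
    r2[cbind(i[keep], j[keep])] <- edges$r2[keep]
    r2[cbind(j[keep], i[keep])] <- edges$r2[keep]
  }
  ld_reference(ids, r2, variants$chrom, variants$pos)
}

#' Write an LD reference as a variant table plus r2 edge list
#'
#' @param ld An `ld_ref` object.
#' @param variant_path,edge_path Output paths. Only off-diagonal entries
#'   with r2 > 0 are written to the edge list.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_ld_reference <- function(ld, variant_path, edge_path) {
  readr::write_tsv(tibble::tibble(variant_id = ld$variant_ids,
                                  chrom = ld$chrom, pos = ld$pos),
                   variant_path, progress = FALSE)
  idx <- which(upper.tri(ld$r2) & ld$r2 > 0, arr.ind = TRUE)
  readr::write_tsv(tibble::tibble(id1 = ld$variant_ids[idx[, 1]],
                                  id2 = ld$variant_ids[idx[, 2]],
                                  r2 = ld$r2[idx]),
                   edge_path, progress = FALSE)
  invisible(c(variant_path, edge_path))
}

#' Select genome-wide-significant variants
#'
#' @param stats An `mr_sumstats` tibble.
#' @param p_threshold Significance threshold (default `5e-8`).
#' @return Variant IDs with `pval < p_threshold`, ordered by ascending
#'   p-value with ties broken lexicographically; empty when none survive.
#' @export
select_significant <- function(stats, p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold <= 1)
  hits <- dplyr::filter(tibble::as_tibble(stats), .data$pval < p_threshold)
  hits <- dplyr::arrange(hits, .data$pval, .data$variant_id)
  hits$variant_id
}

#' Greedy LD clumping
#'
#' Repeatedly retains the remaining candidate with the smallest exposure
#' p-value (ties broken by variant ID) and removes every remaining
#' candidate on the same chromosome within `window_kb` of it whose r2 with
#' it exceeds `r2_max`. The result does not depend on the input order of
#' `candidates`.
#'
#' @param candidates Variant IDs to thin.
#' @param stats Exposure `mr_sumstats` (for p-values).
#' @param ld An `ld_ref` covering the candidates.
#' @param window_kb Clumping window in kilobases (default 10000).
#' @param r2_max LD threshold (default 0.001).
#' @param missing_ld What to do with candidates absent from `ld`:
#'   `"drop"` them with a warning (default) or `"error"`.
#' @return Retained variant IDs in selection order.
#' @export
clump <- function(candidates, stats, ld, window_kb = 10000, r2_max = 0.001,
                  missing_ld = c("drop", "error")) {
  missing_ld <- match.arg(missing_ld)
  absent <- setdiff(candidates, ld$variant_ids)
  if (length(absent) > 0) {
    if (missing_ld == "error") {
      abort(paste0("candidate(s) missing from LD reference: ",
                   paste(absent, collapse = ", ")))
    }
    warn(sprintf("dropping %d candidate(s) missing from LD reference",
                 length(absent)))
    candidates <- setdiff(candidates, absent)
  }
  if (length(candidates) == 0) return(character())

  info <- tibble::tibble(
    variant_id = candidates,
    pval = stats$pval[match(candidates, stats$variant_id)],
    chrom = ld$chrom[match(candidates, ld$variant_ids)],
    pos = ld$pos[match(candidates, ld$variant_ids)]
  )
  if (anyNA(info$pval)) abort("candidate(s) missing from summary statistics")
  info <- dplyr::arrange(info, .data$pval, .data$variant_id)

  retained <- character()
  remaining <- info
  while (nrow(remaining) > 0) {
    top <- remaining[1, ]
    retained <- c(retained, top$variant_id)
    r2_with_top <- ld$r2[match(remaining$variant_id, ld$variant_ids),
                         match(top$variant_id, ld$variant_ids)]
    conflict <- remaining$chrom == top$chrom &
      abs(remaining$pos - top$pos) <= window_kb * 1000 &
      r2_with_top > r2_max
    conflict[1] <- TRUE
    remaining <- remaining[!conflict, , drop = FALSE]
  }
  retained
}

#' Remove instruments already associated with the outcome
#'
#' Instruments whose outcome p-value falls below `p_threshold` are removed
#' (they plausibly violate the exclusion-restriction assumption);
#' instruments absent from the outcome GWAS are kept and flagged.
#'
#' @param instruments Variant IDs.
#' @param outcome Outcome `mr_sumstats`.
#' @param p_threshold Removal threshold (default `5e-8`).
#' @return The surviving IDs in the original order, with the removed IDs in
#'   attribute `"removed"` and unmatched IDs in attribute `"unmatched"`.
#' @export
exclude_outcome_associated <- function(instruments, outcome,
                                       p_threshold = 5e-8) {
  stopifnot(p_threshold > 0, p_threshold < 1)
  p_out <- outcome$pval[match(instruments, outcome$variant_id)]
  removed <- instruments[!is.na(p_out) & p_out < p_threshold]
  unmatched <- instruments[is.na(p_out)]
  if (length(removed) > 0) {
    inform(sprintf("removed %d outcome-associated instrument(s): %s",
                   length(removed), paste(removed, collapse = ", ")))
  }
  kept <- setdiff(instruments, removed)
  structure(kept, removed = removed, unmatched = unmatched)
}

#' Instrument strength: variance explained and F-statistic
#'
#' Per-variant variance explained is summed over the instruments and turned
#' into the joint F-statistic
#' `F = (R2 / K) / ((1 - R2) / (N - K - 1))`,
#' with `K` the number of instruments and `N` the (conservative) smallest
#' per-variant sample size. `F > 10` is the conventional threshold above
#' which weak-instrument bias is considered negligible.
#'
#' @param stats Exposure `mr_sumstats`.
#' @param instruments Variant IDs (non-empty, present in `stats`).
#' @param r2_method Per-variant variance-explained estimator:
#'   `"z_n"` (default), `z^2 / (z^2 + n - 2)` with `z = beta/se`, needing no
#'   allele frequency; or `"eaf_beta"`, `2 * eaf * (1 - eaf) * beta^2` for
#'   standardized continuous traits.
#' @return A one-row tibble: `k`, `n`, `r2_total`, `f_stat`, `strong`
#'   (logical, `f_stat > 10`).
#' @export
instrument_strength <- function(stats, instruments,
                                r2_method = c("z_n", "eaf_beta")) {
  r2_method <- match.arg(r2_method)
  if (length(instruments) == 0) abort("no instruments supplied")
  idx <- match(instruments, stats$variant_id)
  if (anyNA(idx)) {
    abort(paste0("instrument(s) absent from summary statistics: ",
                 paste(instruments[is.na(idx)], collapse = ", ")))
  }
  sub <- tibble::as_tibble(stats)[idx, ]
  if (anyNA(sub$n)) abort("per-variant sample size n required for F-statistic")
  r2 <- switch(
    r2_method,
    z_n = {
      z2 <- (sub$beta / sub$se)^2
      z2 / (z2 + sub$n - 2)
    },
    eaf_beta = {
      if (anyNA(sub$eaf)) {
        abort(paste0("eaf missing for: ",
                     paste(sub$variant_id[is.na(sub$eaf)], collapse = ", ")))
      }
      2 * sub$eaf * (1 - sub$eaf) * sub$beta^2
    }
  )
  k <- length(instruments)
  n_min <- min(sub$n)
  r2_total <- sum(r2)
  f_stat <- (r2_total / k) / ((1 - r2_total) / (n_min - k - 1))
  tibble::tibble(k = k, n = n_min, r2_total = r2_total,
                 f_stat = f_stat, strong = f_stat > 10)
}
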