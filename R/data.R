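#' Published two-step MR summary rows for education and autoimmune disease
#'
#' Summary estimates transcribed from a published two-step Mendelian
#' randomization study of education-related exposures (cognitive
#' performance, educational attainment, highest-level math class completed,
#' self-reported math ability), mediators (household income, smoking, BMI)
#' and autoimmune-disease outcomes: the total effect of each exposure on
#' each outcome (log odds and SE, where the study reported it), the
#' odds-ratio estimates with 95% limits for the exposure-to-mediator and
#' mediator-to-outcome legs, and the study's own proportion mediated with
#' its delta-method SE and 95% limits. Used as a worked example and as a
#' cross-check that [product_of_coefficients()] reproduces the published
#' arithmetic.
#'
#' @return A tibble with one row per exposure-mediator-outcome triple.
#' @export
published_mediation_rows <- function() {
  path <- system.file("extdata", "education_autoimmune_mediation.tsv",
                      package = "mrmediate", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}
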