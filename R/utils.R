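#' @importFrom rlang abort warn inform .data %||%
#' @importFrom stats pnorm pchisq qnorm rnorm runif approx median lm coef setNames
#' @importFrom utils head
NULL

# smallest representable two-sided p; keeps pval inside (0, 1]
clamp_pval <- function(p) pmin(pmax(p, .Machine$double.xmin), 1)

# two-sided normal p for an estimate/SE pair
normal_pval <- function(beta, se) clamp_pval(2 * pnorm(-abs(beta / se)))

Z95 <- 1.96

complement_alleles <- function(a) chartr("ACGT", "TGCA", a)

is_palindromic <- function(a1, a2) a1 == complement_alleles(a2)

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_preserved_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
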