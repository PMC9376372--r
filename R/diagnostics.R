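#' Per-SNP variance explained
#'
#' Converts a marginal association into the fraction of trait variance it
#' explains via the t-statistic transform: with `t = beta / se`, `R2 =
#' t^2 / (t^2 + n - 2)`. Used on the observed scale for both the
#' continuous exposures and the binary outcomes; it is the inverse of the
#' single-instrument F formula (`F = R2 (n - 2) / (1 - R2)` gives
#' `R2 = F / (F + n - 2)`).
#'
#' @param beta,se Effect estimate and its standard error (`se > 0`).
#' @param n Sample size (`n > 2`).
#' @return Variance explained, in `[0, 1)`. Vectorised.
#' @export
snp_r2 <- function(beta, se, n) {
  if (any(se <= 0)) stop("se must be > 0")
  if (any(n <= 2)) stop("n must be > 2")
  t2 <- (beta / se)^2
  t2 / (t2 + n - 2)
}

#' Steiger directionality test
#'
#' Tests whether the instruments explain more variance in the exposure
#' than in the outcome, supporting the assumed exposure-to-outcome causal
#' direction. Both R-squared values are converted to correlations and
#' compared on the Fisher-z scale:
#' `z = (atanh(r_exp) - atanh(r_out)) / sqrt(1/(n_exp - 3) + 1/(n_out - 3))`,
#' with a two-sided normal p-value. A tie (`r2_exp == r2_out`) is reported
#' as not-correct with `p = 1`.
#'
#' @param r2_exp,r2_out Variance explained in exposure and outcome, in
#'   `[0, 1)`.
#' @param n_exp,n_out Sample sizes (`> 3`).
#' @return A `steiger_result` list: `r2_exposure`, `r2_outcome`,
#'   `correct_direction` (`r2_exp > r2_out`), `zstat`, `pval`.
#' @export
steiger_test <- function(r2_exp, n_exp, r2_out, n_out) {
  stopifnot(r2_exp >= 0, r2_out >= 0, n_exp > 3, n_out > 3)
  if (r2_exp >= 1 || r2_out >= 1) stop("r2 must be < 1")
  z <- (atanh(sqrt(r2_exp)) - atanh(sqrt(r2_out))) /
    sqrt(1 / (n_exp - 3) + 1 / (n_out - 3))
  structure(
    list(r2_exposure = r2_exp, r2_outcome = r2_out,
         correct_direction = r2_exp > r2_out,
         zstat = z, pval = 2 * stats::pnorm(-abs(z))),
    class = "steiger_result"
  )
}

#' Statistical power of an MR test on a binary outcome
#'
#' Normal-approximation power for a two-sided test at level `alpha`: with
#' case fraction `K = n_cases / n_outcome`, the non-centrality is
#' `|ln OR| sqrt(n_outcome R2 K (1 - K))` and
#' `power = Phi(ncp - z_(1 - alpha/2))`. At `OR = 1` this is exactly
#' `alpha / 2`. Monotone increasing in `|ln OR|`, `r2` and `n_outcome`.
#'
#' @param or_ Causal odds ratio per SD of exposure (`> 0`).
#' @param r2 Exposure variance explained by the instruments, in `(0, 1)`.
#' @param n_outcome Total outcome sample size.
#' @param n_cases Outcome case count (`0 < n_cases < n_outcome`).
#' @param alpha Two-sided type-I error rate (default 0.05).
#' @return Power, in `(0, 1)`.
#' @export
power_binary <- function(or_, r2, n_outcome, n_cases, alpha = 0.05) {
  stopifnot(or_ > 0, r2 > 0, r2 < 1, alpha > 0, alpha < 1)
  K <- n_cases / n_outcome
  if (K <= 0 || K >= 1) stop("case fraction must lie strictly in (0, 1)")
  ncp <- abs(log(or_)) * sqrt(n_outcome * r2 * K * (1 - K))
  stats::pnorm(ncp - stats::qnorm(1 - alpha / 2))
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up false-discovery-rate adjustment across the family of exposures
#' screened against one outcome. Thin wrapper over
#' `stats::p.adjust(method = "BH")`, kept as a named seam so the FDR family
#' definition lives in one place.
#'
#' @param pvals Numeric vector of p-values in `(0, 1]`.
#' @return Adjusted p-values in the original order; `>=` the input
#'   elementwise, capped at 1. Empty input gives empty output.
#' @export
bh_fdr <- function(pvals) {
  if (length(pvals) == 0L) return(numeric(0))
  stopifnot(all(pvals > 0 & pvals <= 1))
  stats::p.adjust(pvals, method = "BH")
}
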