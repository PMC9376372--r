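ALLELE_COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic_pair <- function(a1, a2) {
  ok <- a1 %in% names(ALLELE_COMPLEMENT) & a2 %in% names(ALLELE_COMPLEMENT)
  ok & unname(ALLELE_COMPLEMENT[a1]) == a2
}

#' Harmonize exposure and outcome effect alleles
#'
#' Aligns each outcome record to its exposure record's effect-allele
#' orientation so the per-SNP effects refer to the same allele:
#'
#' * same allele pair, same orientation: kept unchanged;
#' * same pair, swapped orientation: outcome beta negated and
#'   `eaf_out` replaced by `1 - eaf_out` (`flipped`);
#' * complementary-strand pair (e.g. A/G vs T/C): outcome alleles
#'   complemented, then the two rules above;
#' * palindromic pair (A/T or G/C): strand cannot be resolved from alleles,
#'   so after label alignment the SNP is kept only if both allele
#'   frequencies fall on the same side of 0.5 and both lie outside the
#'   ambiguity band `0.5 +/- palindrome_eaf_tol`; otherwise it is dropped
#'   (`dropped_palindromic`);
#' * anything irreconcilable (including indel alleles): `dropped_mismatch`.
#'
#' @param exp_records,out_records Summary-statistic data frames matched by
#'   `snp_id` (rows of either side without a partner are ignored).
#' @param palindrome_eaf_tol Half-width of the frequency ambiguity band
#'   around 0.5 (default 0.08, i.e. band 0.42-0.58).
#' @param strict Drop all palindromic SNPs regardless of frequency.
#' @return A `harmonized_set`: a data frame with one row per matched SNP
#'   (`snp_id`, `beta_exp`, `se_exp`, `eaf_exp`, `beta_out`, `se_out`,
#'   `eaf_out`, `flag`), flag one of `kept`, `flipped`,
#'   `dropped_palindromic`, `dropped_mismatch`; attributes `exposure`,
#'   `outcome`, `n_exp`, `n_out`. Estimators use only the rows with flag
#'   `kept` or `flipped` (see [harmonized_kept()]).
#' @export
harmonize <- function(exp_records, out_records, palindrome_eaf_tol = 0.08,
                      strict = FALSE) {
  if (anyDuplicated(exp_records$snp_id)) {
    stop("duplicated snp_id in exposure records")
  }
  if (anyDuplicated(out_records$snp_id)) {
    stop("duplicated snp_id in outcome records")
  }
  ids <- intersect(exp_records$snp_id, out_records$snp_id)
  e <- exp_records[match(ids, exp_records$snp_id), , drop = FALSE]
  o <- out_records[match(ids, out_records$snp_id), , drop = FALSE]
  n <- length(ids)
  flag <- character(n)
  beta_out <- o$beta
  eaf_out <- o$eaf

  e_ea <- toupper(e$effect_allele); e_oa <- toupper(e$other_allele)
  o_ea <- toupper(o$effect_allele); o_oa <- toupper(o$other_allele)

  for (i in seq_len(n)) {
    pair_e <- c(e_ea[i], e_oa[i])
    pair_o <- c(o_ea[i], o_oa[i])
    snv <- all(nchar(c(pair_e, pair_o)) == 1L) &&
      all(c(pair_e, pair_o) %in% names(ALLELE_COMPLEMENT))
    if (!snv) {
      flag[i] <- "dropped_mismatch"  # indels and non-ACGT codes excluded
      next
    }
    pal <- is_palindromic_pair(pair_e[1], pair_e[2])
    if (!pal && !setequal(pair_e, pair_o)) {
      # try the other strand before declaring a mismatch
      pair_o <- unname(ALLELE_COMPLEMENT[pair_o])
    }
    if (!setequal(pair_e, pair_o)) {
      flag[i] <- "dropped_mismatch"
      next
    }
    flipped <- pair_o[1] == pair_e[2]
    if (flipped) {
      beta_out[i] <- -beta_out[i]
      eaf_out[i] <- 1 - eaf_out[i]
    }
    if (pal) {
      if (strict) {
        flag[i] <- "dropped_palindromic"
        next
      }
      fe <- e$eaf[i]; fo <- eaf_out[i]
      same_side <- sign(fe - 0.5) == sign(fo - 0.5) && fe != 0.5 && fo != 0.5
      outside <- abs(fe - 0.5) > palindrome_eaf_tol &&
        abs(fo - 0.5) > palindrome_eaf_tol
      if (!(same_side && outside)) {
        flag[i] <- "dropped_palindromic"
        next
      }
    }
    flag[i] <- if (flipped) "flipped" else "kept"
  }

  out <- data.frame(
    snp_id = ids,
    beta_exp = e$beta, se_exp = e$se, eaf_exp = e$eaf,
    beta_out = beta_out, se_out = o$se, eaf_out = eaf_out,
    flag = flag,
    stringsAsFactors = FALSE
  )
  structure(out,
            exposure = e$trait_id[1] %||% NA_character_,
            outcome = o$trait_id[1] %||% NA_character_,
            n_exp = if (n > 0L) e$n[1] else NA_real_,
            n_out = if (n > 0L) o$n[1] else NA_real_,
            class = c("harmonized_set", "data.frame"))
}

#' Usable rows of a harmonized set
#'
#' @param h A `harmonized_set` from [harmonize()].
#' @return The rows flagged `kept` or `flipped`, i.e. those entering
#'   estimation.
#' @export
harmonized_kept <- function(h) {
  out <- h[h$flag %in% c("kept", "flipped"), , drop = FALSE]
  rownames(out) <- NULL
  out
}
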