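#' Instrument-selection configuration
#'
#' Thresholds for the four-step instrument QC funnel: genome-wide
#' significance with a MAF floor, greedy LD clumping, proxy substitution
#' for instruments absent from the outcome, and the weak-instrument
#' F-statistic filter.
#'
#' @param p_threshold Genome-wide significance cutoff; SNPs with
#'   `pval < p_threshold` pass (strict inequality). Default `5e-8`.
#' @param maf_min Minor-allele-frequency floor; `min(eaf, 1 - eaf)` must
#'   exceed it. Default 0.01.
#' @param clump_r2 LD threshold for clumping; a SNP within the window whose
#'   r-squared with the index SNP is `>= clump_r2` is removed. Default 0.001.
#' @param clump_window_kb Clump window half-width in kilobases around the
#'   index SNP (10,000 kb = 10,000,000 bp), inclusive. Default 10000.
#' @param proxy_min_r2 Minimum LD r-squared for a proxy SNP. Default 0.8.
#' @param use_proxies Set `FALSE` to disable proxy search entirely.
#' @param f_min Weak-instrument floor: instruments with per-SNP F below this
#'   are removed. Default 10.
#' @return A `selection_config` list.
#' @export
selection_config <- function(p_threshold = 5e-8, maf_min = 0.01,
                             clump_r2 = 0.001, clump_window_kb = 10000,
                             proxy_min_r2 = 0.8, use_proxies = TRUE,
                             f_min = 10) {
  stopifnot(p_threshold > 0, p_threshold <= 1, maf_min >= 0, maf_min < 0.5,
            clump_r2 >= 0, clump_r2 <= 1, clump_window_kb > 0,
            proxy_min_r2 >= 0, proxy_min_r2 <= 1, f_min >= 0)
  structure(
    list(p_threshold = p_threshold, maf_min = maf_min, clump_r2 = clump_r2,
         clump_window_kb = clump_window_kb, proxy_min_r2 = proxy_min_r2,
         use_proxies = isTRUE(use_proxies), f_min = f_min),
    class = "selection_config"
  )
}

#' Genome-wide significance and MAF filter
#'
#' Retains exactly the records with `pval < p_threshold` (strict) and
#' `min(eaf, 1 - eaf) > maf_min`, preserving input order.
#'
#' @param records Summary-statistic data frame.
#' @param cfg A [selection_config()].
#' @return The filtered data frame (possibly empty).
#' @export
filter_significant <- function(records, cfg = selection_config()) {
  maf <- pmin(records$eaf, 1 - records$eaf)
  keep <- records$pval < cfg$p_threshold & maf > cfg$maf_min
  out <- records[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' PLINK-style clumping: repeatedly take the remaining record with the
#' lowest p-value as the index SNP (ties broken by chromosome, position,
#' then SNP id) and remove all remaining records on the same chromosome
#' within `clump_window_kb` kilobases whose r-squared with the index is at
#' least `clump_r2`. SNPs absent from the LD panel are treated as unlinked
#' and retained, with a warning.
#'
#' @param records Summary-statistic data frame.
#' @param ld An [ld_panel()].
#' @param cfg A [selection_config()].
#' @return The retained records, in input order, with attribute
#'   `"removed"`: a data frame naming each removed SNP and its index SNP.
#' @export
clump_snps <- function(records, ld, cfg = selection_config()) {
  n <- nrow(records)
  if (n == 0L) {
    attr(records, "removed") <- data.frame(snp_id = character(),
                                           index_snp = character())
    return(records)
  }
  absent <- !(records$snp_id %in% ld$snp_ids)
  if (any(absent)) {
    warning(sprintf("%d SNP(s) absent from the LD panel treated as unlinked: %s",
                    sum(absent),
                    paste(utils::head(records$snp_id[absent], 5), collapse = ", ")))
  }
  ord <- order(records$pval, records$chrom, records$pos, records$snp_id)
  window_bp <- cfg$clump_window_kb * 1000
  alive <- rep(TRUE, n)
  kept <- logical(n)
  removed_by <- rep(NA_character_, n)
  for (i in ord) {
    if (!alive[i]) next
    kept[i] <- TRUE
    alive[i] <- FALSE
    cand <- which(alive &
                    records$chrom == records$chrom[i] &
                    abs(records$pos - records$pos[i]) <= window_bp)
    if (length(cand) > 0L) {
      r2 <- ld_r2(ld, records$snp_id[i], records$snp_id[cand])
      drop <- cand[!is.na(r2) & r2 >= cfg$clump_r2]
      alive[drop] <- FALSE
      removed_by[drop] <- records$snp_id[i]
    }
  }
  out <- records[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "removed") <- data.frame(
    snp_id = records$snp_id[!kept],
    index_snp = removed_by[!kept],
    stringsAsFactors = FALSE
  )
  out
}

#' Find an LD proxy for an instrument absent from the outcome
#'
#' Returns the outcome-present SNP with maximal r-squared to `snp_id`,
#' provided that r-squared is at least `proxy_min_r2`; ties are broken by
#' smaller basepair distance, then lexicographic SNP id. Returns
#' `NA_character_` when no candidate qualifies or when `snp_id` is not in
#' the LD panel.
#'
#' @param snp_id Identifier of the missing instrument.
#' @param outcome_snps Character vector of SNP ids present in the outcome.
#' @param ld An [ld_panel()].
#' @param cfg A [selection_config()].
#' @return A single SNP id or `NA_character_`.
#' @export
find_proxy <- function(snp_id, outcome_snps, ld, cfg = selection_config()) {
  i <- match(snp_id, ld$snp_ids)
  if (is.na(i)) return(NA_character_)
  cand <- setdiff(intersect(outcome_snps, ld$snp_ids), snp_id)
  if (length(cand) == 0L) return(NA_character_)
  j <- match(cand, ld$snp_ids)
  r2 <- ld$r2[i, j]
  ok <- r2 >= cfg$proxy_min_r2
  if (!any(ok)) return(NA_character_)
  cand <- cand[ok]
  j <- j[ok]
  r2 <- r2[ok]
  dist <- ifelse(ld$chrom[j] == ld$chrom[i],
                 abs(ld$pos[j] - ld$pos[i]), Inf)
  cand[order(-r2, dist, cand)][1]
}

#' Instrument-strength F statistic
#'
#' `F = R2 (n - k - 1) / (k (1 - R2))`, where `R2` is the exposure variance
#' explained by the instruments, `n` the exposure sample size and `k` the
#' number of instruments. Values below 10 conventionally flag weak
#' instruments.
#'
#' @param r2 Variance explained, in `[0, 1)`.
#' @param n Exposure sample size; must exceed `k + 1`.
#' @param k Number of instruments, `>= 1`.
#' @return The (vectorised) F value, nonnegative.
#' @export
f_statistic <- function(r2, n, k) {
  if (any(r2 < 0 | r2 >= 1)) stop("r2 must lie in [0, 1)")
  if (any(k < 1)) stop("k must be >= 1")
  if (any(n <= k + 1)) stop("n must exceed k + 1")
  r2 * (n - k - 1) / (k * (1 - r2))
}

#' Select instruments for one exposure
#'
#' The full QC funnel: significance/MAF filter, greedy LD clumping, lookup
#' of each instrument in the outcome with proxy substitution for absent
#' SNPs, and removal of weak instruments (per-SNP F below `f_min`). Per-SNP
#' variance explained uses [snp_r2()]; the set-level `r2_exposure` is their
#' sum over retained instruments and `f_stat` applies the F formula at the
#' set level.
#'
#' When a proxy is used, the exposure-side statistics remain those of the
#' original instrument; only the outcome-side row comes from the proxy
#' (reported under the original instrument's id and alleles, assuming the
#' proxy tags the same haplotype).
#'
#' @param exposure_records,outcome_records Summary-statistic data frames.
#' @param ld An [ld_panel()].
#' @param cfg A [selection_config()].
#' @return An `instrument_set` list: `exposure`, `records` (exposure side),
#'   `outcome_records` (matched, proxy-substituted), `k`, `r2_exposure`,
#'   `f_stat`, `proxies` (data frame of substitutions), and `attrition`
#'   (named counts per funnel step; input = retained + sum of removals).
#'   `k = 0` is a valid, typed empty result, not an error.
#' @export
select_instruments <- function(exposure_records, outcome_records, ld,
                               cfg = selection_config()) {
  n_in <- nrow(exposure_records)
  sig <- filter_significant(exposure_records, cfg)
  clumped <- clump_snps(sig, ld, cfg)

  present <- clumped$snp_id %in% outcome_records$snp_id
  proxies <- data.frame(snp_id = character(), proxy_id = character(),
                        r2 = numeric(), stringsAsFactors = FALSE)
  out_rows <- rep(NA_integer_, nrow(clumped))
  out_rows[present] <- match(clumped$snp_id[present], outcome_records$snp_id)
  if (cfg$use_proxies && any(!present)) {
    for (i in which(!present)) {
      pid <- find_proxy(clumped$snp_id[i], outcome_records$snp_id, ld, cfg)
      if (!is.na(pid)) {
        out_rows[i] <- match(pid, outcome_records$snp_id)
        proxies <- rbind(proxies, data.frame(
          snp_id = clumped$snp_id[i], proxy_id = pid,
          r2 = ld_r2(ld, clumped$snp_id[i], pid), stringsAsFactors = FALSE))
      }
    }
  }
  matched <- !is.na(out_rows)
  exp_m <- clumped[matched, , drop = FALSE]
  out_m <- outcome_records[out_rows[matched], , drop = FALSE]
  # proxy outcome rows are re-labelled with the instrument's identity
  out_m$snp_id <- exp_m$snp_id
  out_m$chrom <- exp_m$chrom
  out_m$pos <- exp_m$pos

  r2_snp <- if (nrow(exp_m) > 0L) {
    snp_r2(exp_m$beta, exp_m$se, exp_m$n)
  } else numeric(0)
  f_snp <- if (nrow(exp_m) > 0L) {
    f_statistic(r2_snp, exp_m$n, 1L)
  } else numeric(0)
  strong <- f_snp >= cfg$f_min
  exp_f <- exp_m[strong, , drop = FALSE]
  out_f <- out_m[strong, , drop = FALSE]
  r2_f <- r2_snp[strong]
  rownames(exp_f) <- rownames(out_f) <- NULL

  k <- nrow(exp_f)
  r2_total <- sum(r2_f)
  attrition <- c(
    input = n_in,
    removed_not_significant = n_in - nrow(sig),
    removed_clumped = nrow(sig) - nrow(clumped),
    removed_no_outcome_match = nrow(clumped) - nrow(exp_m),
    removed_weak_f = nrow(exp_m) - k,
    retained = k
  )
  structure(
    list(
      exposure = if (n_in > 0L) exposure_records$trait_id[1] else NA_character_,
      records = exp_f,
      outcome_records = out_f,
      k = k,
      r2_exposure = r2_total,
      f_stat = if (k > 0L) f_statistic(r2_total, exp_f$n[1], k) else NA_real_,
      snp_r2 = stats::setNames(r2_f, exp_f$snp_id),
      proxies = proxies,
      attrition = attrition
    ),
    class = "instrument_set"
  )
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> exposure '%s': k = %d, r2 = %.4g, F = %.4g\n",
              x$exposure, x$k, x$r2_exposure, x$f_stat))
  a <- x$attrition
  cat(sprintf("  attrition: %d in; -%d p/MAF, -%d clump, -%d unmatched, -%d weak F; %d kept\n",
              a[["input"]], a[["removed_not_significant"]],
              a[["removed_clumped"]], a[["removed_no_outcome_match"]],
              a[["removed_weak_f"]], a[["retained"]]))
  invisible(x)
}
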