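#' Run the full MR screen: many exposures against each outcome
#'
#' For every exposure x outcome pair: instrument selection
#' ([select_instruments()]), allele harmonization ([harmonize()]), method
#' routing ([select_method()]) with the primary estimate (Wald ratio for a
#' single instrument, IVW otherwise) and, where more than three instruments
#' survive, the sensitivity suite; then the diagnostics columns (exposure
#' and outcome variance explained, set-level F statistic, Steiger
#' directionality, binary-outcome power). Raw p-values are FDR-adjusted
#' per outcome across all exposures that produced an estimate, and rows are
#' ranked by adjusted then raw p-value. Exposures with zero surviving
#' instruments are reported in a skip list, never raised as errors. The
#' whole run is a pure function of its inputs and `seed`.
#'
#' @param exposures Named list of exposure summary-statistic data frames
#'   (names are the exposure ids).
#' @param outcomes List of outcomes, primary first; each element a list
#'   with `stats` (summary-statistic data frame) and `meta`
#'   (a [trait_meta()], used for the power calculation).
#' @param ld An [ld_panel()] shared by all lookups.
#' @param selection A [selection_config()].
#' @param palindrome_eaf_tol Passed to [harmonize()].
#' @param seed Master seed; per-pair seeds for the bootstrap/simulation
#'   estimators are derived from it deterministically.
#' @param n_boot,presso_n_sim Resampling sizes for the sensitivity suite.
#' @return An `mr_screen` object: `tables` (one ranked screen data frame
#'   per outcome, columns as in [write_screen_table()]), `sensitivity`
#'   (per outcome, per exposure: the full estimator list where the suite
#'   ran), `skipped` (data frame of exposure/outcome/reason), and `log`
#'   (per outcome: the FDR family size `m` and per-exposure attrition).
#' @export
run_screen <- function(exposures, outcomes, ld,
                       selection = selection_config(),
                       palindrome_eaf_tol = 0.08, seed = 1,
                       n_boot = 1000, presso_n_sim = 1000) {
  stopifnot(length(exposures) >= 1, length(outcomes) >= 1,
            !is.null(names(exposures)))
  tables <- list()
  sensitivity <- list()
  skipped <- data.frame(exposure = character(), outcome = character(),
                        reason = character(), stringsAsFactors = FALSE)
  log <- list()
  for (o in seq_along(outcomes)) {
    out <- outcomes[[o]]
    meta <- out$meta
    oid <- meta$trait_id
    rows <- list()
    sens_o <- list()
    attr_o <- list()
    for (e in seq_along(exposures)) {
      eid <- names(exposures)[e]
      pair_seed <- seed + 7919L * o + e
      sel <- select_instruments(exposures[[e]], out$stats, ld, selection)
      attr_o[[eid]] <- sel$attrition
      if (sel$k == 0L) {
        skipped <- rbind(skipped, data.frame(
          exposure = eid, outcome = oid,
          reason = "no instruments survived selection",
          stringsAsFactors = FALSE))
        next
      }
      h <- harmonize(sel$records, sel$outcome_records,
                     palindrome_eaf_tol = palindrome_eaf_tol)
      hk <- harmonized_kept(h)
      k <- nrow(hk)
      if (k == 0L) {
        skipped <- rbind(skipped, data.frame(
          exposure = eid, outcome = oid,
          reason = "no instruments survived harmonization",
          stringsAsFactors = FALSE))
        next
      }
      # diagnostics are recomputed on the final (harmonized) instrument set
      n_exp <- attr(h, "n_exp")
      n_out <- attr(h, "n_out")
      r2_exp <- sum(snp_r2(hk$beta_exp, hk$se_exp, n_exp))
      r2_out <- sum(snp_r2(hk$beta_out, hk$se_out, n_out))
      f <- f_statistic(r2_exp, n_exp, k)
      plan <- select_method(k)
      primary <- if (k == 1L) {
        mr_wald_ratio(hk$beta_exp, hk$se_exp, hk$beta_out, hk$se_out)
      } else {
        mr_ivw(hk)
      }
      if (length(plan) > 1L) {
        sens_o[[eid]] <- list(
          ivw = primary,
          weighted_median = mr_weighted_median(hk, n_boot = n_boot,
                                               seed = pair_seed),
          mode = mr_mode(hk, n_boot = n_boot, seed = pair_seed + 1L),
          egger = mr_egger(hk),
          presso = mr_presso(hk, n_sim = presso_n_sim,
                             seed = pair_seed + 2L)
        )
      }
      st <- steiger_test(r2_exp, n_exp, r2_out, n_out)
      pw <- power_binary(primary$or_, r2_exp, meta$n_total, meta$n_cases)
      rows[[eid]] <- data.frame(
        exposure = eid, outcome = oid, method = primary$method, snp_n = k,
        or = primary$or_, or_ci_low = primary$ci_low,
        or_ci_high = primary$ci_high,
        r2_exposure = r2_exp, r2_outcome = r2_out,
        pval = primary$pval, pval_adj = NA_real_, power = pw, f_stat = f,
        steiger_correct = st$correct_direction, steiger_pval = st$pval,
        stringsAsFactors = FALSE
      )
    }
    tab <- do.call(rbind, rows)
    if (!is.null(tab) && nrow(tab) > 0L) {
      tab$pval_adj <- bh_fdr(tab$pval)  # family = exposures tested vs this outcome
      tab <- tab[order(tab$pval_adj, tab$pval), , drop = FALSE]
      rownames(tab) <- NULL
    }
    tables[[oid]] <- tab
    sensitivity[[oid]] <- sens_o
    log[[oid]] <- list(fdr_family_m = if (is.null(tab)) 0L else nrow(tab),
                       attrition = attr_o)
  }
  structure(
    list(tables = tables, sensitivity = sensitivity, skipped = skipped,
         log = log, seed = seed),
    class = "mr_screen"
  )
}

#' @export
print.mr_screen <- function(x, ...) {
  cat(sprintf("<mr_screen> %d outcome(s), seed %d\n", length(x$tables),
              x$seed))
  for (oid in names(x$tables)) {
    tab <- x$tables[[oid]]
    m <- x$log[[oid]]$fdr_family_m
    hits <- if (is.null(tab)) 0L else sum(tab$pval_adj < 0.05)
    cat(sprintf("  %s: m = %d exposures tested, %d with adjusted p < 0.05\n",
                oid, m, hits))
  }
  if (nrow(x$skipped) > 0L) {
    cat(sprintf("  skipped: %d exposure-outcome pair(s)\n", nrow(x$skipped)))
  }
  invisible(x)
}

#' Export a forest-table summary of a screen
#'
#' Writes the columns needed to draw a forest plot (exposure, method, SNP
#' count, OR with its 95% CI, raw and adjusted p) for the top-ranked rows.
#'
#' @param rows A screen data frame (one element of `run_screen()$tables`).
#' @param path Output TSV path.
#' @param top_n Keep the best `top_n` rows by adjusted then raw p
#'   (default 15).
#' @return The exported data frame, invisibly.
#' @export
export_forest <- function(rows, path, top_n = 15) {
  stopifnot(nrow(rows) > 0L)
  rows <- rows[order(rows$pval_adj, rows$pval), , drop = FALSE]
  rows <- utils::head(rows, top_n)
  out <- rows[, c("exposure", "outcome", "method", "snp_n", "or",
                  "or_ci_low", "or_ci_high", "pval", "pval_adj")]
  fmt <- out
  for (cc in c("pval", "pval_adj")) {
    fmt[[cc]] <- formatC(out[[cc]], format = "e", digits = 12)
  }
  utils::write.table(fmt, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(out)
}
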