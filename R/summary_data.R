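#' @title GWAS summary-statistic records and their invariants
#' @description Internal canonical schema: one row per SNP-trait association
#' with columns `snp_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#' `eaf`, `beta`, `se`, `pval`, `n`, `trait_id`. Betas are log-odds for binary
#' traits and SD units for continuous traits; positions are 1-based basepairs.
#' @name summary-stats-schema
NULL

SUMMARY_COLS <- c(
  "snp_id", "chrom", "pos", "effect_allele", "other_allele",
  "eaf", "beta", "se", "pval", "n", "trait_id"
)

#' Trait metadata
#'
#' Describes one trait (exposure or outcome): sample size and, for binary
#' traits, the case count, as in the study-design table of a GWAS catalogue.
#'
#' @param trait_id Short identifier used in summary-stat files.
#' @param trait_type `"continuous"` or `"binary"`.
#' @param n_total Total sample size.
#' @param n_cases Case count; 0 for continuous traits.
#' @param label Free-text description.
#' @return A `trait_meta` list.
#' @export
trait_meta <- function(trait_id, trait_type = c("continuous", "binary"),
                       n_total, n_cases = 0L, label = "") {
  trait_type <- match.arg(trait_type)
  n_total <- as.integer(n_total)
  n_cases <- as.integer(n_cases)
  if (n_cases > n_total) stop("n_cases must not exceed n_total")
  if (trait_type == "binary" && n_cases < 1L) {
    stop("binary traits need at least one case")
  }
  structure(
    list(trait_id = trait_id, trait_type = trait_type,
         n_total = n_total, n_cases = n_cases, label = label),
    class = "trait_meta"
  )
}

# Row-wise invariant check; returns character(0) if the row is valid.
row_problems <- function(df) {
  probs <- rep("", nrow(df))
  bad <- function(cond, msg) {
    cond[is.na(cond)] <- TRUE
    probs[cond & probs == ""] <<- msg
  }
  bad(!is.finite(df$beta), "non-numeric beta")
  bad(!is.finite(df$se), "non-numeric se")
  bad(df$se <= 0, "se must be > 0")
  bad(!is.finite(df$eaf) | df$eaf < 0 | df$eaf > 1, "eaf outside [0, 1]")
  bad(!is.finite(df$pval) | df$pval <= 0 | df$pval > 1, "pval outside (0, 1]")
  bad(!is.finite(df$n) | df$n <= 0, "n must be > 0")
  bad(toupper(df$effect_allele) == toupper(df$other_allele),
      "effect and other allele identical")
  bad(is.na(df$snp_id) | df$snp_id == "", "missing snp_id")
  probs
}

#' Read GWAS summary statistics from a tab-separated file
#'
#' Parses a TSV with a header into the internal summary-statistic schema and
#' validates every row. Source files with FinnGen-, Neale- or other dialects
#' are mapped onto the internal column names through `col_map`. Rows that
#' violate an invariant (non-positive SE, p-value outside (0,1], identical
#' alleles, ...) are rejected with a line-numbered report; the run continues
#' as long as the rejected fraction stays below `max_reject_frac`. Alleles
#' are upper-cased on input; indel alleles (length > 1) are accepted here and
#' excluded later at harmonization.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param meta Optional [trait_meta()]; its `trait_id` overrides any trait
#'   column and its `n_total` fills a missing `n` column.
#' @param col_map Named character vector mapping internal names (names) to
#'   file column names (values), e.g. `c(snp_id = "rsids", pval = "p")`.
#'   Unmapped internal names are looked up verbatim.
#' @param max_reject_frac Abort if more than this fraction of rows is
#'   rejected (default 0.01).
#' @return A data frame in the internal schema with attribute `"rejected"`:
#'   a data frame of line numbers and reasons for every rejected row, so that
#'   rows in = rows parsed + rows rejected.
#' @export
read_summary_stats <- function(path, meta = NULL, col_map = NULL,
                               max_reject_frac = 0.01) {
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  lookup <- stats::setNames(SUMMARY_COLS, SUMMARY_COLS)
  if (!is.null(col_map)) lookup[names(col_map)] <- col_map
  optional <- c("trait_id", if (!is.null(meta)) "n")
  needed <- setdiff(SUMMARY_COLS, optional)
  missing <- needed[!(lookup[needed] %in% names(raw))]
  if (length(missing) > 0L) {
    stop("missing mandatory column(s): ",
         paste(sprintf("%s (looked for '%s')", missing, lookup[missing]),
               collapse = ", "))
  }
  get_col <- function(nm, default = NA_character_) {
    if (lookup[[nm]] %in% names(raw)) raw[[lookup[[nm]]]] else
      rep(default, nrow(raw))
  }
  df <- data.frame(
    snp_id = get_col("snp_id"),
    chrom = as.character(get_col("chrom")),
    pos = suppressWarnings(as.integer(get_col("pos"))),
    effect_allele = toupper(get_col("effect_allele")),
    other_allele = toupper(get_col("other_allele")),
    eaf = suppressWarnings(as.numeric(get_col("eaf"))),
    beta = suppressWarnings(as.numeric(get_col("beta"))),
    se = suppressWarnings(as.numeric(get_col("se"))),
    pval = suppressWarnings(as.numeric(get_col("pval"))),
    n = suppressWarnings(as.numeric(get_col("n"))),
    trait_id = get_col("trait_id", default = NA_character_),
    stringsAsFactors = FALSE
  )
  if (!is.null(meta)) {
    df$trait_id <- meta$trait_id
    df$n[is.na(df$n)] <- meta$n_total
  }
  probs <- row_problems(df)
  rejected <- data.frame(
    line = which(probs != "") + 1L,  # +1 for the header line
    snp_id = df$snp_id[probs != ""],
    reason = probs[probs != ""],
    stringsAsFactors = FALSE
  )
  if (nrow(rejected) > max_reject_frac * nrow(df)) {
    stop(sprintf("%d of %d rows rejected (> %.1f%% allowed); first: line %d (%s)",
                 nrow(rejected), nrow(df), 100 * max_reject_frac,
                 rejected$line[1], rejected$reason[1]))
  }
  out <- df[probs == "", , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' LD panel: pairwise r-squared lookup
#'
#' A small in-memory stand-in for an external LD reference panel (e.g. the
#' European 1000 Genomes samples): a symmetric matrix of squared correlations
#' with unit diagonal, plus per-SNP positions for window arithmetic.
#'
#' @param snp_ids Character vector of SNP identifiers.
#' @param chrom,pos Per-SNP chromosome and 1-based basepair position.
#' @param r2 Symmetric numeric matrix of squared correlations in `[0, 1]`
#'   with unit diagonal, in the order of `snp_ids`.
#' @return An `ld_panel` object.
#' @export
ld_panel <- function(snp_ids, chrom, pos, r2) {
  r2 <- as.matrix(r2)
  stopifnot(length(snp_ids) == nrow(r2), nrow(r2) == ncol(r2),
            length(chrom) == length(snp_ids), length(pos) == length(snp_ids))
  if (any(r2 < 0 | r2 > 1)) stop("LD r2 entries must lie in [0, 1]")
  if (max(abs(r2 - t(r2))) > 1e-12) stop("LD r2 matrix must be symmetric")
  if (max(abs(diag(r2) - 1)) > 1e-12) stop("LD r2 diagonal must be 1")
  dimnames(r2) <- list(snp_ids, snp_ids)
  structure(
    list(snp_ids = as.character(snp_ids), chrom = as.character(chrom),
         pos = as.integer(pos), r2 = r2),
    class = "ld_panel"
  )
}

#' @export
print.ld_panel <- function(x, ...) {
  cat(sprintf("<ld_panel> %d SNPs on %d chromosome(s)\n",
              length(x$snp_ids), length(unique(x$chrom))))
  invisible(x)
}

#' Look up pairwise LD
#'
#' @param panel An [ld_panel()].
#' @param a,b SNP identifiers. Pairs where either SNP is absent from the
#'   panel return `NA`.
#' @return Numeric vector of r-squared values (vectorised over `a`/`b`).
#' @export
ld_r2 <- function(panel, a, b) {
  n <- max(length(a), length(b))
  ia <- rep_len(match(a, panel$snp_ids), n)
  ib <- rep_len(match(b, panel$snp_ids), n)
  out <- rep(NA_real_, n)
  ok <- !is.na(ia) & !is.na(ib)
  out[ok] <- panel$r2[cbind(ia[ok], ib[ok])]
  out
}

#' Read / write an LD panel as plain text
#'
#' The on-disk form is a TSV edge list (`snp_a`, `snp_b`, `r2`; absent pairs
#' are 0) plus a positions TSV (`snp_id`, `chrom`, `pos`).
#'
#' @param edge_path,pos_path Paths to the edge-list and positions files.
#' @return [read_ld_panel()] returns an [ld_panel()];
#'   [write_ld_panel()] returns `invisible(NULL)`.
#' @export
read_ld_panel <- function(edge_path, pos_path) {
  pos <- utils::read.delim(pos_path, stringsAsFactors = FALSE,
                           colClasses = c("character", "character", "integer"))
  edges <- utils::read.delim(edge_path, stringsAsFactors = FALSE)
  m <- diag(1, nrow(pos))
  dimnames(m) <- list(pos$snp_id, pos$snp_id)
  if (nrow(edges) > 0L) {
    ia <- match(edges$snp_a, pos$snp_id)
    ib <- match(edges$snp_b, pos$snp_id)
    if (anyNA(ia) || anyNA(ib)) stop("edge list references unknown SNP ids")
    m[cbind(ia, ib)] <- edges$r2
    m[cbind(ib, ia)] <- edges$r2
  }
  ld_panel(pos$snp_id, pos$chrom, pos$pos, m)
}

#' @param panel An [ld_panel()] to serialise.
#' @rdname read_ld_panel
#' @export
write_ld_panel <- function(panel, edge_path, pos_path) {
  pos <- data.frame(snp_id = panel$snp_ids, chrom = panel$chrom,
                    pos = panel$pos, stringsAsFactors = FALSE)
  utils::write.table(pos, pos_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  idx <- which(upper.tri(panel$r2) & panel$r2 > 0, arr.ind = TRUE)
  edges <- data.frame(
    snp_a = panel$snp_ids[idx[, 1]],
    snp_b = panel$snp_ids[idx[, 2]],
    r2 = panel$r2[idx],
    stringsAsFactors = FALSE
  )
  utils::write.table(edges, edge_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(NULL)
}

SCREEN_COLS <- c(
  "exposure", "outcome", "method", "snp_n", "or", "or_ci_low", "or_ci_high",
  "r2_exposure", "r2_outcome", "pval", "pval_adj", "power", "f_stat",
  "steiger_correct", "steiger_pval"
)
SCREEN_SCI_COLS <- c("r2_exposure", "r2_outcome", "pval", "pval_adj",
                     "steiger_pval")

#' Write a screening result table
#'
#' Serialises screen rows to a TSV whose columns follow the published
#' per-exposure MR report layout (exposure, method, SNP N, OR and CI, the
#' exposure/outcome variance explained, raw and FDR-adjusted p, power, the
#' instrument F statistic, and the Steiger direction call with its p-value).
#' P-values and R-squared columns are written in scientific notation.
#'
#' @param rows Data frame of screen rows (as produced by [run_screen()]).
#' @param path Output path.
#' @param sort_by_adj Sort rows by adjusted then raw p-value before writing.
#' @return `invisible(path)`.
#' @export
write_screen_table <- function(rows, path, sort_by_adj = FALSE) {
  stopifnot(nrow(rows) > 0L)
  rows <- as.data.frame(rows)[, SCREEN_COLS]
  if (sort_by_adj) rows <- rows[order(rows$pval_adj, rows$pval), , drop = FALSE]
  out <- rows
  for (cc in SCREEN_SCI_COLS) {
    out[[cc]] <- ifelse(is.na(rows[[cc]]), "NA",
                        formatC(rows[[cc]], format = "e", digits = 12))
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @param path Path to a file written by [write_screen_table()].
#' @rdname write_screen_table
#' @export
read_screen_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  df$steiger_correct <- as.logical(df$steiger_correct)
  df
}
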