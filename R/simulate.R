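#' Simulation configuration for synthetic GWAS summary statistics
#'
#' Defines one exposure/outcome pair generated directly at the
#' summary-statistic level under the standard two-sample MR sampling model.
#' Defaults emulate the study shapes this package targets: a continuous
#' flow-cytometry exposure measured in a cohort of 3,757, a rare binary
#' outcome with 1,873 cases among 38,243, and per-exposure instruments
#' explaining 6% of exposure variance in total (the median of the screened
#' exposures' reported values).
#'
#' @param n_snps Total SNPs in the region set.
#' @param n_blocks LD blocks (contiguous, roughly equal size); must be at
#'   least `n_instruments`.
#' @param within_block_rho Pairwise LD r-squared within a block, in
#'   `[0, 1)`.
#' @param n_exposure Exposure GWAS sample size.
#' @param n_outcome,n_cases Outcome GWAS total and case counts.
#' @param n_instruments True causal instruments (one per block, the block
#'   lead SNP).
#' @param instrument_r2_total Total exposure variance explained by the
#'   instruments (`< 1`).
#' @param true_beta Causal effect of the exposure on the outcome, log-OR
#'   per SD of exposure.
#' @param pleiotropy_mode `"none"`, `"balanced"` (zero-mean direct effects
#'   on instruments), `"directional"` (mean `pleiotropy_mean`), or
#'   `"outlier"` (a single instrument carries a direct effect of size
#'   `pleiotropy_mean`).
#' @param pleiotropy_sd,pleiotropy_mean Direct-effect distribution
#'   parameters (log-OR per allele).
#' @param palindrome_fraction Fraction of SNPs given palindromic (A/T or
#'   G/C) allele pairs.
#' @param flip_fraction Fraction of non-palindromic SNPs whose outcome
#'   record is written in the opposite allele orientation.
#' @param seed RNG seed; generation is fully reproducible from it.
#' @param chrom Chromosome label for the region.
#' @param snp_prefix Prefix for generated SNP ids.
#' @param exposure_id,outcome_id Trait identifiers.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_snps = 30, n_blocks = 10, within_block_rho = 0.5,
                       n_exposure = 3757, n_outcome = 38243, n_cases = 1873,
                       n_instruments = 3, instrument_r2_total = 0.06,
                       true_beta = 0,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "outlier"),
                       pleiotropy_sd = 0.02, pleiotropy_mean = 0,
                       palindrome_fraction = 0.2, flip_fraction = 0.2,
                       seed = 1, chrom = "1", snp_prefix = "rs",
                       exposure_id = "exposure", outcome_id = "outcome") {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  stopifnot(n_instruments <= n_blocks, n_blocks <= n_snps,
            instrument_r2_total >= 0, instrument_r2_total < 1,
            within_block_rho >= 0, within_block_rho < 1,
            palindrome_fraction >= 0, palindrome_fraction <= 1,
            flip_fraction >= 0, flip_fraction <= 1,
            n_cases >= 1, n_cases < n_outcome)
  structure(
    list(n_snps = n_snps, n_blocks = n_blocks,
         within_block_rho = within_block_rho, n_exposure = n_exposure,
         n_outcome = n_outcome, n_cases = n_cases,
         n_instruments = n_instruments,
         instrument_r2_total = instrument_r2_total, true_beta = true_beta,
         pleiotropy_mode = pleiotropy_mode, pleiotropy_sd = pleiotropy_sd,
         pleiotropy_mean = pleiotropy_mean,
         palindrome_fraction = palindrome_fraction,
         flip_fraction = flip_fraction, seed = seed, chrom = chrom,
         snp_prefix = snp_prefix, exposure_id = exposure_id,
         outcome_id = outcome_id),
    class = "sim_config"
  )
}

NONPALINDROMIC_PAIRS <- rbind(
  c("A", "C"), c("A", "G"), c("C", "A"), c("C", "T"),
  c("G", "A"), c("G", "T"), c("T", "C"), c("T", "G")
)
PALINDROMIC_PAIRS <- rbind(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))

# Block-correlated standard-normal noise: pairwise correlation `cor_` within
# each block (the genotype correlation sqrt(r2) carried into the estimates).
block_noise <- function(block, cor_) {
  z <- stats::rnorm(length(block))
  if (cor_ <= 0) return(z)
  zc <- stats::rnorm(max(block))[block]
  sqrt(cor_) * zc + sqrt(1 - cor_) * z
}

# Deterministic geometry and genetics of the region: frequencies, alleles,
# block structure, instrument effects. All draws happen under cfg$seed.
sim_core <- function(cfg) {
  local_seed(cfg$seed, {
    n <- cfg$n_snps
    block <- sort(rep_len(seq_len(cfg$n_blocks), n))
    lead <- match(seq_len(cfg$n_blocks), block)
    inst <- lead[seq_len(cfg$n_instruments)]
    is_inst <- seq_len(n) %in% inst

    p <- stats::runif(n, 0.05, 0.5)
    # instrument frequencies stay clear of the palindrome ambiguity band
    p[is_inst] <- stats::runif(cfg$n_instruments, 0.05, 0.40)
    het <- 2 * p * (1 - p)

    n_pal <- round(cfg$palindrome_fraction * n)
    pal_idx <- if (n_pal > 0) sample.int(n, n_pal) else integer(0)
    alleles <- NONPALINDROMIC_PAIRS[
      sample.int(nrow(NONPALINDROMIC_PAIRS), n, replace = TRUE), ,
      drop = FALSE]
    if (n_pal > 0) {
      alleles[pal_idx, ] <- PALINDROMIC_PAIRS[
        sample.int(nrow(PALINDROMIC_PAIRS), n_pal, replace = TRUE), ,
        drop = FALSE]
    }

    # standardized instrument effects scaled to the total R2 budget; shares
    # are kept within +/-20% of equal so every planted instrument clears
    # genome-wide significance when the budget is realistic for its count
    share <- stats::runif(cfg$n_instruments, 0.8, 1.2)
    share <- share / sum(share)
    gamma_std <- sqrt(cfg$instrument_r2_total * share)
    gamma <- numeric(n)
    gamma[inst] <- gamma_std / sqrt(het[inst])

    # marginal exposure effects: instruments carry gamma; block mates of an
    # instrument carry the LD-attenuated echo (genotype correlation
    # sqrt(r2)); all other SNPs are null
    mu_x <- numeric(n)
    mu_x[inst] <- gamma[inst]
    g_corr <- sqrt(cfg$within_block_rho)
    for (b in seq_len(cfg$n_instruments)) {
      mates <- setdiff(which(block == b), inst[b])
      mu_x[mates] <- g_corr * gamma_std[b] / sqrt(het[mates])
    }

    alpha <- numeric(n)
    if (cfg$pleiotropy_mode == "balanced") {
      alpha[inst] <- stats::rnorm(cfg$n_instruments, 0, cfg$pleiotropy_sd)
    } else if (cfg$pleiotropy_mode == "directional") {
      alpha[inst] <- stats::rnorm(cfg$n_instruments, cfg$pleiotropy_mean,
                                  cfg$pleiotropy_sd)
    } else if (cfg$pleiotropy_mode == "outlier") {
      alpha[inst[cfg$n_instruments]] <- cfg$pleiotropy_mean
    }

    n_flip <- round(cfg$flip_fraction * n)
    flippable <- setdiff(seq_len(n), pal_idx)
    flip_idx <- if (n_flip > 0 && length(flippable) > 0) {
      sample(flippable, min(n_flip, length(flippable)))
    } else integer(0)

    sex <- 1 / sqrt(het * cfg$n_exposure)
    beta_x <- mu_x + sex * block_noise(block, g_corr)

    ids <- paste0(cfg$snp_prefix, seq_len(n))
    pos <- as.integer((block - 1) * 2e7 +
                        (seq_len(n) - lead[block] + 1) * 1e4)
    r2m <- outer(block, block, function(a, b) {
      ifelse(a == b, cfg$within_block_rho, 0)
    })
    diag(r2m) <- 1

    list(
      ids = ids, block = block, p = p, het = het, alleles = alleles,
      pal_idx = pal_idx, flip_idx = flip_idx, inst = inst, gamma = gamma,
      mu_x = mu_x, alpha = alpha, g_corr = g_corr, pos = pos,
      exposure = data.frame(
        snp_id = ids, chrom = cfg$chrom, pos = pos,
        effect_allele = alleles[, 1], other_allele = alleles[, 2],
        eaf = p, beta = beta_x, se = sex,
        pval = 2 * stats::pnorm(-abs(beta_x / sex)),
        n = cfg$n_exposure, trait_id = cfg$exposure_id,
        stringsAsFactors = FALSE
      ),
      ld = ld_panel(ids, rep(cfg$chrom, n), pos, r2m)
    )
  })
}

# Outcome summary statistics for a given outcome shape, from the same
# genetic region. Orientation flips are applied to the written records.
sim_outcome <- function(core, cfg, n_outcome, n_cases, outcome_id, seed) {
  local_seed(seed, {
    K <- n_cases / n_outcome
    sey <- 1 / sqrt(core$het * n_outcome * K * (1 - K))
    mu_y <- cfg$true_beta * core$mu_x + core$alpha
    beta_y <- mu_y + sey * block_noise(core$block, core$g_corr)
    out <- data.frame(
      snp_id = core$ids, chrom = cfg$chrom, pos = core$pos,
      effect_allele = core$alleles[, 1], other_allele = core$alleles[, 2],
      eaf = core$p, beta = beta_y, se = sey,
      pval = 2 * stats::pnorm(-abs(beta_y / sey)),
      n = n_outcome, trait_id = outcome_id,
      stringsAsFactors = FALSE
    )
    fi <- core$flip_idx
    if (length(fi) > 0) {
      out$effect_allele[fi] <- core$alleles[fi, 2]
      out$other_allele[fi] <- core$alleles[fi, 1]
      out$beta[fi] <- -out$beta[fi]
      out$eaf[fi] <- 1 - out$eaf[fi]
    }
    out
  })
}

#' Generate a synthetic exposure/outcome summary-statistic pair
#'
#' Draws GWAS summary statistics directly at the summary level: allele
#' frequencies uniform on (0.05, 0.5); contiguous LD blocks with
#' exchangeable within-block r-squared; positive instrument effects scaled
#' so the standardized effects sum to `instrument_r2_total`; exposure
#' estimates `N(mu_x, sex)` with `sex = 1 / sqrt(2 p (1-p) n_exposure)`;
#' outcome log-OR estimates `N(true_beta * mu_x + alpha, sey)` with the
#' rare-outcome approximation `sey = 1 / sqrt(2 p (1-p) N K (1-K))`; direct
#' effects `alpha` per `pleiotropy_mode`. Non-lead SNPs in an instrument's
#' block carry the LD-attenuated marginal echo of the instrument, so
#' clumping has real work to do. Allele labels include palindromic pairs
#' and orientation flips between the two files per the configured
#' fractions.
#'
#' @param cfg A [sim_config()].
#' @return List with `exposure` and `outcome` summary-statistic data
#'   frames, `ld` (an [ld_panel()]), and `truth` (a `sim_truth` list:
#'   `true_beta`, `instrument_ids`, `gamma`, `alpha`, `flipped_ids`,
#'   `palindromic_ids`, `seed`).
#' @export
sim_gwas <- function(cfg = sim_config()) {
  core <- sim_core(cfg)
  # prime-spaced offset keeps the outcome RNG stream disjoint from the
  # exposure streams of nearby seeds
  outcome <- sim_outcome(core, cfg, cfg$n_outcome, cfg$n_cases,
                         cfg$outcome_id, (cfg$seed + 499979L) %% .Machine$integer.max)
  list(
    exposure = core$exposure,
    outcome = outcome,
    ld = core$ld,
    truth = structure(
      list(true_beta = cfg$true_beta,
           instrument_ids = core$ids[core$inst],
           gamma = stats::setNames(core$gamma[core$inst],
                                   core$ids[core$inst]),
           alpha = stats::setNames(core$alpha[core$inst],
                                   core$ids[core$inst]),
           flipped_ids = core$ids[core$flip_idx],
           palindromic_ids = core$ids[core$pal_idx],
           seed = cfg$seed),
      class = "sim_truth"
    )
  )
}

#' Generate a whole synthetic screening study
#'
#' Emulates the screen's data layout: many exposures measured in one
#' cohort, each with its own instrument region (distinct chromosomes),
#' tested against one or more shared binary outcomes. The first `n_causal`
#' exposures have causal effect `true_beta`; the rest are null. Exposure
#' statistics are drawn once per exposure and shared across outcomes.
#'
#' @param n_exposures Number of exposures.
#' @param n_causal Number of causal exposures (the first ones).
#' @param true_beta Causal log-OR per SD for the causal exposures.
#' @param causal_r2 Optional total instrument R-squared for the causal
#'   exposures only (the protective traits the target study identified were
#'   unusually strongly instrumented, R2 ~ 0.24-0.30); `NULL` keeps the
#'   template value for every exposure.
#' @param outcome_shapes List of `c(n_outcome, n_cases)` pairs, primary
#'   first; the defaults are the three outcome shapes of the target study
#'   (case fractions ~0.049, ~0.00107, ~0.000393).
#' @param cfg Template [sim_config()] supplying the per-exposure region
#'   parameters; its `true_beta`, `seed`, `chrom`, ids and outcome shape
#'   are overridden per exposure/outcome.
#' @param seed Master seed; per-exposure and per-outcome seeds are derived
#'   from it with prime-spaced offsets.
#' @return List: `exposures` (named list of summary-stat data frames),
#'   `outcomes` (list, one per shape, each a single pooled
#'   summary-statistic data frame), `ld` (pooled [ld_panel()]),
#'   `outcome_meta` (list of [trait_meta()]), `causal_ids` (exposure names
#'   with true effects), `seed`.
#' @export
sim_screen <- function(n_exposures = 20, n_causal = 3,
                       true_beta = log(0.67), causal_r2 = NULL,
                       outcome_shapes = list(c(38243, 1873),
                                             c(217288, 232),
                                             c(386783, 152)),
                       cfg = sim_config(), seed = 1) {
  stopifnot(n_causal <= n_exposures)
  exposures <- list()
  out_parts <- lapply(outcome_shapes, function(...) list())
  ld_parts <- list()
  for (e in seq_len(n_exposures)) {
    ecfg <- cfg
    ecfg$true_beta <- if (e <= n_causal) true_beta else 0
    if (e <= n_causal && !is.null(causal_r2)) {
      ecfg$instrument_r2_total <- causal_r2
    }
    ecfg$seed <- (seed + 104729L * e) %% .Machine$integer.max
    ecfg$chrom <- as.character(e)
    ecfg$snp_prefix <- sprintf("rs%d_", e)
    ecfg$exposure_id <- sprintf("trait_%02d", e)
    core <- sim_core(ecfg)
    exposures[[ecfg$exposure_id]] <- core$exposure
    ld_parts[[e]] <- core$ld
    for (o in seq_along(outcome_shapes)) {
      sh <- outcome_shapes[[o]]
      out_parts[[o]][[e]] <- sim_outcome(
        core, ecfg, sh[1], sh[2], sprintf("outcome_%d", o),
        (ecfg$seed + 499979L * o) %% .Machine$integer.max)
    }
  }
  ld <- ld_panel(
    unlist(lapply(ld_parts, `[[`, "snp_ids")),
    unlist(lapply(ld_parts, `[[`, "chrom")),
    unlist(lapply(ld_parts, `[[`, "pos")),
    as.matrix(Matrix_bdiag(lapply(ld_parts, `[[`, "r2")))
  )
  list(
    exposures = exposures,
    outcomes = lapply(out_parts, function(p) do.call(rbind, p)),
    ld = ld,
    outcome_meta = lapply(seq_along(outcome_shapes), function(o) {
      sh <- outcome_shapes[[o]]
      trait_meta(sprintf("outcome_%d", o), "binary", sh[1], sh[2])
    }),
    causal_ids = sprintf("trait_%02d", seq_len(n_causal)),
    seed = seed
  )
}

# Minimal block-diagonal assembly (dense; panels here are small).
Matrix_bdiag <- function(mats) {
  sizes <- vapply(mats, nrow, integer(1))
  n <- sum(sizes)
  out <- matrix(0, n, n)
  at <- 0L
  for (m in mats) {
    idx <- at + seq_len(nrow(m))
    out[idx, idx] <- m
    at <- at + nrow(m)
  }
  out
}

#' Write the named fixture suite used by the tests and documentation
#'
#' Produces six small named scenarios, each as exposure/outcome TSVs, an LD
#' panel (edge list + positions), and a ground-truth JSON sidecar:
#' `clean-2-snp` (two valid instruments, the screen's modal shape),
#' `clean-10-snp` (ten valid instruments), `planted-outlier` (one
#' instrument with a large direct outcome effect), `directional-pleiotropy`
#' (instruments share a mean direct effect), `palindrome-heavy` (half the
#' SNPs palindromic, two instruments forced into the frequency ambiguity
#' band), and `proxy-needed` (one instrument deleted from the outcome file,
#' a block mate in high LD available as proxy).
#'
#' @param out_dir Writable directory.
#' @param seed Base seed; each fixture's own seed is recorded in the
#'   manifest and its truth sidecar.
#' @return Data frame manifest (fixture name, seed, file paths), invisibly
#'   written as `manifest.tsv` too.
#' @export
make_fixture_suite <- function(out_dir, seed = 20260101) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfgs <- list(
    `clean-2-snp` = sim_config(n_snps = 6, n_blocks = 2, n_instruments = 2,
                               instrument_r2_total = 0.0421,
                               true_beta = log(0.71),
                               palindrome_fraction = 0, flip_fraction = 0,
                               seed = seed + 1),
    `clean-10-snp` = sim_config(n_snps = 30, n_blocks = 10,
                                n_instruments = 10,
                                instrument_r2_total = 0.2,
                                true_beta = log(0.67), seed = seed + 2),
    `planted-outlier` = sim_config(n_snps = 30, n_blocks = 10,
                                   n_instruments = 10,
                                   instrument_r2_total = 0.2,
                                   true_beta = 0,
                                   pleiotropy_mode = "outlier",
                                   pleiotropy_mean = 0.3,
                                   palindrome_fraction = 0,
                                   flip_fraction = 0, seed = seed + 3),
    `directional-pleiotropy` = sim_config(n_snps = 30, n_blocks = 10,
                                          n_instruments = 10,
                                          instrument_r2_total = 0.2,
                                          true_beta = 0,
                                          pleiotropy_mode = "directional",
                                          pleiotropy_mean = 0.05,
                                          pleiotropy_sd = 0.02,
                                          palindrome_fraction = 0,
                                          flip_fraction = 0,
                                          seed = seed + 4),
    `palindrome-heavy` = sim_config(n_snps = 20, n_blocks = 5,
                                    n_instruments = 5,
                                    instrument_r2_total = 0.08,
                                    palindrome_fraction = 0.5,
                                    flip_fraction = 0, seed = seed + 5),
    `proxy-needed` = sim_config(n_snps = 12, n_blocks = 3,
                                n_instruments = 3,
                                instrument_r2_total = 0.06,
                                within_block_rho = 0.9,
                                palindrome_fraction = 0, flip_fraction = 0,
                                seed = seed + 6)
  )
  rows <- list()
  for (nm in names(cfgs)) {
    cfg <- cfgs[[nm]]
    sim <- sim_gwas(cfg)
    extra <- list()
    if (nm == "palindrome-heavy") {
      # force two palindromic instruments into the ambiguity band so
      # harmonization must drop exactly them
      amb <- intersect(sim$truth$instrument_ids, sim$truth$palindromic_ids)
      amb <- utils::head(amb, 2)
      if (length(amb) == 0) {  # make two instruments palindromic first
        amb <- utils::head(sim$truth$instrument_ids, 2)
        i_e <- match(amb, sim$exposure$snp_id)
        sim$exposure$effect_allele[i_e] <- "A"
        sim$exposure$other_allele[i_e] <- "T"
        i_o <- match(amb, sim$outcome$snp_id)
        sim$outcome$effect_allele[i_o] <- "A"
        sim$outcome$other_allele[i_o] <- "T"
      }
      i_e <- match(amb, sim$exposure$snp_id)
      i_o <- match(amb, sim$outcome$snp_id)
      sim$exposure$eaf[i_e] <- 0.5
      sim$outcome$eaf[i_o] <- 0.5
      extra$ambiguous_ids <- amb
    }
    if (nm == "proxy-needed") {
      # delete the outcome row of the SNP selection actually picks, so the
      # proxy path is exercised regardless of which block mate wins the clump
      gone <- select_instruments(sim$exposure, sim$outcome,
                                 sim$ld)$records$snp_id[1]
      sim$outcome <- sim$outcome[sim$outcome$snp_id != gone, , drop = FALSE]
      extra$missing_from_outcome <- gone
    }
    base <- file.path(out_dir, nm)
    paths <- c(exposure = paste0(base, ".exposure.tsv"),
               outcome = paste0(base, ".outcome.tsv"),
               ld_edges = paste0(base, ".ld.tsv"),
               ld_pos = paste0(base, ".pos.tsv"),
               truth = paste0(base, ".truth.json"))
    utils::write.table(sim$exposure, paths[["exposure"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    utils::write.table(sim$outcome, paths[["outcome"]], sep = "\t",
                       quote = FALSE, row.names = FALSE)
    write_ld_panel(sim$ld, paths[["ld_edges"]], paths[["ld_pos"]])
    truth <- c(sim$truth[c("true_beta", "instrument_ids", "gamma", "alpha",
                           "flipped_ids", "palindromic_ids", "seed")], extra)
    truth$gamma <- as.list(truth$gamma)  # keep SNP names in the JSON
    truth$alpha <- as.list(truth$alpha)
    jsonlite::write_json(truth, paths[["truth"]], auto_unbox = TRUE,
                         digits = NA)
    rows[[nm]] <- data.frame(fixture = nm, seed = cfg$seed,
                             t(paths), stringsAsFactors = FALSE)
  }
  manifest <- do.call(rbind, rows)
  rownames(manifest) <- NULL
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest
}
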