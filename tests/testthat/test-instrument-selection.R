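test_that("significance filter applies strict p and symmetric MAF boundaries", {
  df <- make_stats(paste0("rs", 1:4), beta = rep(0.1, 4), se = rep(0.01, 4))
  df$pval <- c(4.9e-8, 5e-8, 1e-9, 1e-9)
  df$eaf <- c(0.3, 0.3, 0.995, 0.012)
  got <- filter_significant(df)
  # rs2: p exactly at the threshold is excluded; rs3: MAF 0.005 <= 0.01
  expect_equal(got$snp_id, c("rs1", "rs4"))
})

test_that("significance filter agrees with a brute-force re-filter on a planted fixture", {
  set.seed(401)
  n <- 100
  df <- make_stats(paste0("rs", 1:n), beta = rnorm(n, 0, 0.05),
                   se = runif(n, 0.01, 0.03))
  df$pval <- runif(n, 1e-7, 1)
  df$eaf <- runif(n, 0.005, 0.995)
  planted <- sample(n, 7)
  df$pval[planted] <- runif(7, 1e-20, 1e-9)
  df$eaf[planted] <- runif(7, 0.1, 0.5)
  got <- filter_significant(df)
  oracle <- df$snp_id[df$pval < 5e-8 & pmin(df$eaf, 1 - df$eaf) > 0.01]
  expect_setequal(got$snp_id, oracle)
  expect_true(all(df$snp_id[planted] %in% got$snp_id))
  expect_equal(got$snp_id, df$snp_id[df$snp_id %in% oracle])  # order preserved
})

test_that("clumping keeps the best SNP of a linked clump and respects the window", {
  r2 <- matrix(0.9, 3, 3); diag(r2) <- 1
  df <- make_stats(c("a", "b", "c"), beta = c(0.1, 0.2, 0.15),
                   se = rep(0.01, 3), pos = c(1e5, 2e5, 3e5))
  df$pval <- c(1e-10, 1e-30, 1e-20)
  got <- clump_snps(df, make_ld(c("a", "b", "c"), r2, pos = df$pos))
  expect_equal(got$snp_id, "b")
  expect_equal(attr(got, "removed")$index_snp, c("b", "b"))

  # same LD but 20,000 kb apart: outside the 10,000 kb window, both survive
  far <- make_stats(c("a", "b"), beta = c(0.1, 0.2), se = rep(0.01, 2),
                    pos = c(1e5, 1e5 + 2e7))
  far$pval <- c(1e-10, 1e-30)
  r2f <- matrix(c(1, 0.9, 0.9, 1), 2)
  gotf <- clump_snps(far, make_ld(c("a", "b"), r2f, pos = far$pos))
  expect_setequal(gotf$snp_id, c("a", "b"))
})

test_that("clumping satisfies the exhaustive pairwise oracle and is idempotent", {
  # 5-SNP toy with mixed LD
  ids <- paste0("rs", 1:5)
  r2 <- diag(5)
  r2[1, 2] <- r2[2, 1] <- 0.8
  r2[1, 3] <- r2[3, 1] <- 0.05
  r2[3, 4] <- r2[4, 3] <- 0.3
  r2[2, 5] <- r2[5, 2] <- 0.0005  # below the clump threshold
  df <- make_stats(ids, beta = c(0.2, 0.1, 0.15, 0.12, 0.11),
                   se = rep(0.01, 5), pos = (1:5) * 1e5)
  df$pval <- c(1e-12, 1e-9, 1e-15, 1e-8, 1e-10)
  ld <- make_ld(ids, r2, pos = df$pos)
  cfg <- selection_config()
  got <- clump_snps(df, ld, cfg)

  # oracle: every retained pair is compatible; every removed SNP is linked
  # (within window, r2 >= threshold) to a retained SNP with a better p
  win <- cfg$clump_window_kb * 1000
  linked <- function(i, j) {
    df$chrom[i] == df$chrom[j] && abs(df$pos[i] - df$pos[j]) <= win &&
      r2[i, j] >= cfg$clump_r2
  }
  kept_idx <- match(got$snp_id, ids)
  for (i in kept_idx) for (j in kept_idx) {
    if (i < j) expect_false(linked(i, j))
  }
  for (i in setdiff(seq_along(ids), kept_idx)) {
    expect_true(any(vapply(kept_idx, function(j) {
      linked(i, j) && df$pval[j] < df$pval[i]
    }, logical(1))))
  }
  expect_equal(clump_snps(got, ld, cfg)$snp_id, got$snp_id)  # idempotent

  # property check across random LD fixtures under a fixed seed
  set.seed(402)
  for (rep in 1:10) {
    m <- 8
    z <- matrix(rnorm(m * 3), m)
    rr <- cov2cor(z %*% t(z) + diag(m))^2
    dd <- make_stats(paste0("s", 1:m), beta = rnorm(m, 0, 0.1),
                     se = rep(0.01, m), pos = sample.int(3e7, m))
    dd$pval <- runif(m, 1e-30, 1e-8)
    ldp <- make_ld(paste0("s", 1:m), rr, pos = dd$pos)
    out <- clump_snps(dd, ldp)
    out2 <- clump_snps(out, ldp)
    expect_equal(out2$snp_id, out$snp_id)
    ki <- match(out$snp_id, dd$snp_id)
    for (i in ki) for (j in ki) {
      if (i != j && abs(dd$pos[i] - dd$pos[j]) <= 1e7) {
        expect_lt(rr[i, j], 0.001)
      }
    }
  }
})

test_that("SNPs absent from the LD panel are retained as unlinked, with a warning", {
  df <- make_stats(c("a", "b"), beta = c(0.1, 0.2), se = rep(0.01, 2),
                   pos = c(1e5, 2e5))
  df$pval <- c(1e-10, 1e-12)
  ld <- make_ld("a", matrix(1, 1, 1), pos = 1e5)
  expect_warning(got <- clump_snps(df, ld), "absent")
  expect_setequal(got$snp_id, c("a", "b"))
})

test_that("proxy search honours the r2 floor and its tie-break order", {
  ids <- c("x", "p1", "p2", "p3")
  r2 <- diag(4)
  r2[1, 2] <- r2[2, 1] <- 0.95
  r2[1, 3] <- r2[3, 1] <- 0.85
  r2[1, 4] <- r2[4, 1] <- 0.85
  ld <- make_ld(ids, r2, pos = c(1e5, 2e5, 1e5 + 5e3, 1e5 + 5e4))
  expect_equal(find_proxy("x", c("p1", "p2", "p3"), ld), "p1")
  # best candidate below the floor -> none
  weak <- diag(2); weak[1, 2] <- weak[2, 1] <- 0.79
  ldw <- make_ld(c("x", "p1"), weak, pos = c(1e5, 2e5))
  expect_identical(find_proxy("x", "p1", ldw), NA_character_)
  # equal r2: nearer candidate wins (p2 at 5 kb vs p3 at 50 kb)
  expect_equal(find_proxy("x", c("p2", "p3"), ld), "p2")
  # unknown SNP -> none
  expect_identical(find_proxy("nope", c("p1"), ld), NA_character_)
})

test_that("F statistic reproduces published worked values and its monotonicities", {
  expect_equal(f_statistic(0.0421, 3757, 2), 82.46, tolerance = 0.005)
  expect_equal(f_statistic(0.296, 3757, 1), 1578.89, tolerance = 0.005)
  expect_equal(f_statistic(0, 1000, 1), 0)
  # strictly increasing in r2; strictly decreasing in k
  r2s <- seq(0.01, 0.3, by = 0.01)
  expect_true(all(diff(f_statistic(r2s, 3757, 2)) > 0))
  ks <- 1:10
  expect_true(all(diff(f_statistic(0.05, 3757, ks)) < 0))
  expect_error(f_statistic(1, 100, 1), "r2")
  expect_error(f_statistic(0.5, 3, 2), "n")
})

test_that("select_instruments keeps planted instruments and accounts for every SNP", {
  sim <- sim_gwas(sim_config(n_snps = 12, n_blocks = 3, n_instruments = 3,
                             instrument_r2_total = 0.08,
                             palindrome_fraction = 0, flip_fraction = 0,
                             seed = 403))
  sel <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  expect_s3_class(sel, "instrument_set")
  expect_equal(sel$k, 3L)
  # one survivor per planted block (possibly a high-LD mate of the lead)
  blk <- function(ids) sim$ld$pos[match(ids, sim$ld$snp_ids)] %/% 2e7
  expect_setequal(blk(sel$records$snp_id), blk(sim$truth$instrument_ids))
  a <- sel$attrition
  expect_equal(a[["input"]],
               a[["retained"]] + a[["removed_not_significant"]] +
                 a[["removed_clumped"]] + a[["removed_no_outcome_match"]] +
                 a[["removed_weak_f"]])
  expect_equal(sel$r2_exposure, sum(sel$snp_r2))
  expect_equal(sel$f_stat,
               f_statistic(sel$r2_exposure, sel$records$n[1], sel$k))
})

test_that("weak instruments fall to the F floor and zero survivors is a typed result", {
  # a relaxed p threshold lets a weak SNP (t = 2 => per-SNP F = 4) through
  # the significance step so the F filter has work to do
  df <- make_stats(c("strong", "weak"), beta = c(0.12, 0.02),
                   se = c(0.016, 0.01), pos = c(1e5, 3e7))
  out <- df; out$trait_id <- "mg"
  ld <- make_ld(df$snp_id, diag(2), pos = df$pos)
  cfg <- selection_config(p_threshold = 0.1)
  sel <- select_instruments(df, out, ld, cfg)
  expect_equal(sel$records$snp_id, "strong")
  expect_equal(sel$attrition[["removed_weak_f"]], 1)

  none <- select_instruments(df[df$pval > 1e-300 & df$pval > 2, ], out, ld)
  expect_equal(none$k, 0L)
  expect_s3_class(none, "instrument_set")
})

test_that("an instrument absent from the outcome is rescued through its proxy", {
  sim <- sim_gwas(sim_config(n_snps = 12, n_blocks = 3, n_instruments = 3,
                             within_block_rho = 0.9,
                             palindrome_fraction = 0, flip_fraction = 0,
                             seed = 404))
  sel0 <- select_instruments(sim$exposure, sim$outcome, sim$ld)
  gone <- sel0$records$snp_id[1]
  out2 <- sim$outcome[sim$outcome$snp_id != gone, , drop = FALSE]
  sel <- select_instruments(sim$exposure, out2, sim$ld)
  expect_equal(sel$k, 3L)
  expect_equal(sel$proxies$snp_id, gone)
  expect_gte(sel$proxies$r2, 0.8)
  # outcome-side stats come from the proxy row, relabelled
  prow <- sim$outcome[sim$outcome$snp_id == sel$proxies$proxy_id, ]
  srow <- sel$outcome_records[sel$outcome_records$snp_id == gone, ]
  expect_equal(srow$beta, prow$beta)
  expect_equal(srow$se, prow$se)
  # with proxies disabled the instrument is lost instead
  selnp <- select_instruments(sim$exposure, out2, sim$ld,
                              selection_config(use_proxies = FALSE))
  expect_equal(selnp$k, 2L)
  expect_equal(selnp$attrition[["removed_no_outcome_match"]], 1)
})
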