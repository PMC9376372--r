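test_that("Wald ratio arithmetic and delta-method SEs are exact", {
  w <- mr_wald_ratio(0.1, 0.02, -0.05, 0.01)
  expect_equal(w$beta, -0.5)
  expect_equal(w$se, 0.1)
  expect_equal(w$or_, exp(-0.5))
  # null numerator
  w0 <- mr_wald_ratio(0.1, 0.02, 0, 0.01)
  expect_equal(w0$beta, 0)
  expect_equal(w0$or_, 1)
  # second-order SE equals the closed-form delta oracle
  w2 <- mr_wald_ratio(0.1, 0.02, -0.05, 0.01, second_order = TRUE)
  expect_equal(w2$se, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.02^2 / 0.1^4))
  expect_gt(w2$se, w$se)
  expect_error(mr_wald_ratio(0, 0.02, 0.1, 0.01), "bx")
})

test_that("IVW pools identical evidence as expected and rejects k = 1", {
  h <- make_h(bx = c(0.1, 0.1), sex = c(0.02, 0.02),
              by = c(0.05, 0.05), sey = c(0.01, 0.01))
  est <- mr_ivw(h)
  single <- mr_wald_ratio(0.1, 0.02, 0.05, 0.01)
  expect_equal(est$beta, single$beta)
  expect_equal(est$se, single$se / sqrt(2))  # Q = 0 floors at fixed effect
  expect_error(mr_ivw(make_h(0.1, 0.02, 0.05, 0.01)), "k = 1")
  expect_error(mr_ivw(make_h(c(0, 0.1), c(0.02, 0.02), c(0.1, 0.1),
                             c(0.01, 0.01))), "bx = 0")
  # the IVW formula at k = 1 degenerates to the Wald ratio
  r <- 0.05 / 0.1
  w1 <- 0.1^2 / 0.01^2
  expect_equal(sum(w1 * r) / sum(w1), single$beta)
  expect_equal(1 / sqrt(sum(w1)), single$se)
})

test_that("IVW equals the zero-intercept WLS oracle on a 3-SNP fixture", {
  h <- make_h(bx = c(0.12, 0.08, 0.15), sex = rep(0.02, 3),
              by = c(0.05, 0.02, 0.07), sey = c(0.012, 0.01, 0.015))
  est <- mr_ivw(h)
  fit <- lm(beta_out ~ beta_exp - 1, data = h, weights = 1 / h$se_out^2)
  expect_equal(est$beta, unname(coef(fit)), tolerance = 1e-10)
  sig <- summary(fit)$sigma
  expect_equal(est$se_fixed, unname(sqrt(vcov(fit)[1, 1])) / sig,
               tolerance = 1e-10)
  expect_equal(est$se_random, est$se_fixed * max(1, sig), tolerance = 1e-10)
})

test_that("MR-Egger recovers an exact line and matches the free-intercept WLS oracle", {
  bx <- c(0.05, 0.1, 0.15, 0.2, 0.25)
  exact <- make_h(bx = bx, sex = rep(0.02, 5), by = 0.05 + 0.3 * bx,
                  sey = rep(0.01, 5))
  eg <- mr_egger(exact)
  expect_equal(eg$slope$beta, 0.3, tolerance = 1e-10)
  expect_equal(eg$intercept$beta, 0.05, tolerance = 1e-10)

  set.seed(407)
  bx2 <- c(-0.12, 0.08, 0.15, -0.2, 0.1, 0.18)
  h <- make_h(bx = bx2, sex = rep(0.02, 6),
              by = 0.02 + 0.4 * bx2 + rnorm(6, 0, 0.02),
              sey = runif(6, 0.01, 0.03))
  eg2 <- mr_egger(h)
  # oracle: orient bx >= 0, then weighted lm with free intercept
  s <- sign(bx2)
  fit <- lm(I(h$beta_out * s) ~ I(h$beta_exp * s), weights = 1 / h$se_out^2)
  expect_equal(eg2$slope$beta, unname(coef(fit)[2]), tolerance = 1e-10)
  expect_equal(eg2$intercept$beta, unname(coef(fit)[1]), tolerance = 1e-10)
  sig <- summary(fit)$sigma
  expect_equal(eg2$slope$se,
               unname(sqrt(vcov(fit)[2, 2])) / sig * max(1, sig),
               tolerance = 1e-10)
  # k < 3 is a typed skip, not an error
  na <- mr_egger(make_h(c(0.1, 0.2), c(0.02, 0.02), c(0.1, 0.1),
                        c(0.01, 0.01)))
  expect_s3_class(na$slope, "mr_not_applicable")
})

test_that("weighted median reduces to the plain median and interpolates by weight", {
  # equal weights, ratios {1, 2, 9} -> plain median 2
  h <- make_h(bx = rep(1, 3), sex = rep(0.01, 3), by = c(1, 2, 9),
              sey = rep(1, 3))
  expect_equal(mr_weighted_median(h, n_boot = 50, seed = 1)$beta, 2)
  # weights (0.6, 0.2, 0.2) on ratios (1, 2, 3): cumulative standardized
  # weights minus half own weight are (0.3, 0.7, 0.9); 0.5 crosses between
  # the first two -> 1 + (0.5 - 0.3) / (0.7 - 0.3) = 1.5
  w <- c(0.6, 0.2, 0.2)
  h2 <- make_h(bx = sqrt(w), sex = rep(0.001, 3),
               by = c(1, 2, 3) * sqrt(w), sey = rep(1, 3))
  expect_equal(mr_weighted_median(h2, n_boot = 50, seed = 1)$beta, 1.5)
  expect_s3_class(mr_weighted_median(make_h(1, 0.01, 1, 1)),
                  "mr_not_applicable")
})

test_that("weighted median resists invalid instruments better than IVW", {
  # 40% of instruments carry a positive direct effect under a null causal
  # effect; averaged over replicates the weighted median is less biased
  set.seed(408)
  bias_wm <- bias_ivw <- numeric(30)
  for (r in 1:30) {
    k <- 10
    gamma <- runif(k, 0.08, 0.15)
    alpha <- c(rep(0, 6), rep(0.15, 4))
    h <- make_h(bx = rnorm(k, gamma, 0.0298), sex = rep(0.0298, k),
                by = rnorm(k, alpha, 0.043), sey = rep(0.043, k))
    bias_wm[r] <- mr_weighted_median(h, n_boot = 20, seed = r)$beta
    bias_ivw[r] <- mr_ivw(h)$beta
  }
  expect_lt(mean(abs(bias_wm)), mean(abs(bias_ivw)))
})

test_that("mode estimators follow the smoothed-density argmax", {
  # degenerate density: all ratios equal
  h0 <- make_h(bx = rep(0.1, 4), sex = rep(0.01, 4), by = rep(0.05, 4),
               sey = rep(0.01, 4))
  m0 <- mr_mode(h0, n_boot = 20, seed = 1)
  expect_equal(m0$weighted$beta, 0.5)
  expect_equal(m0$simple$beta, 0.5)
  # a tight cluster beats a lone outlier under equal weights
  ratios <- c(0.30, 0.31, 0.29, 2.0)
  h1 <- make_h(bx = rep(1, 4), sex = rep(0.01, 4), by = ratios,
               sey = rep(1, 4))
  m1 <- mr_mode(h1, n_boot = 20, seed = 1)
  expect_lt(abs(m1$simple$beta - 0.30), 0.05)
  expect_lt(abs(m1$weighted$beta - 0.30), 0.05)
  # independent grid oracle for the simple mode
  bw <- 0.9 * min(sd(ratios), mad(ratios)) * 4^(-1 / 5)
  grid <- seq(-0.5, 2.5, length.out = 8192)
  dens <- sapply(grid, function(g) mean(dnorm((g - ratios) / bw)))
  expect_equal(m1$simple$beta, grid[which.max(dens)], tolerance = 2e-3)
  # 10x weight on the outlier pulls the weighted mode to it
  h2 <- make_h(bx = c(1, 1, 1, sqrt(10)), sex = rep(0.01, 4),
               by = c(0.30, 0.31, 0.29, 2.0 * sqrt(10)), sey = rep(1, 4))
  m2 <- mr_mode(h2, n_boot = 20, seed = 1)
  expect_lt(abs(m2$weighted$beta - 2.0), 0.05)
  expect_lt(abs(m2$simple$beta - 0.30), 0.05)
  # k < 3 is a typed skip
  expect_s3_class(mr_mode(make_h(1, 0.01, 1, 1))$simple, "mr_not_applicable")
})

test_that("MR-PRESSO flags a planted outlier and its correction helps", {
  set.seed(409)
  k <- 10
  gamma <- runif(k, 0.08, 0.15)
  bx <- rnorm(k, gamma, 0.0298)
  by <- rnorm(k, 0.3 * gamma, 0.043)
  by[k] <- by[k] + 0.5  # gross direct effect on one SNP
  h <- make_h(bx = bx, sex = rep(0.0298, k), by = by, sey = rep(0.043, k))
  pr <- mr_presso(h, n_sim = 1000, seed = 2)
  expect_true(pr$applicable)
  expect_lt(pr$global_pval, 0.05)
  expect_true(pr$outlier_flags[k])
  expect_equal(sum(pr$outlier_flags), 1L)
  expect_equal(pr$corrected$method, "presso_outlier_corrected")
  raw <- mr_ivw(h)
  expect_lt(abs(pr$corrected$beta - 0.3), abs(raw$beta - 0.3))
  expect_true(!is.null(pr$distortion_pval))
  # k = 3 input: typed not-applicable, pipeline continues
  na <- mr_presso(make_h(c(0.1, 0.2, 0.3), rep(0.02, 3), rep(0.05, 3),
                         rep(0.01, 3)))
  expect_false(na$applicable)
})

test_that("PRESSO's global test is calibrated on clean data", {
  rej <- logical(200)
  for (r in 1:200) {
    sim <- sim_gwas(sim_config(n_snps = 10, n_blocks = 10,
                               n_instruments = 10, within_block_rho = 0,
                               true_beta = log(0.8),
                               palindrome_fraction = 0, flip_fraction = 0,
                               seed = 20000 + 97 * r))
    hk <- harmonized_kept(harmonize(sim$exposure, sim$outcome))
    rej[r] <- mr_presso(hk, n_sim = 500, seed = r)$global_pval < 0.05
  }
  # binomial 95% band around 0.05 at 200 replicates
  expect_gte(sum(rej), qbinom(0.025, 200, 0.05))
  expect_lte(sum(rej), qbinom(0.975, 200, 0.05))
})

test_that("bootstrap and simulation estimators reproduce bit-for-bit from the seed", {
  set.seed(410)
  h <- make_h(bx = runif(6, 0.08, 0.2), sex = rep(0.02, 6),
              by = rnorm(6, 0.05, 0.02), sey = runif(6, 0.01, 0.03))
  expect_identical(mr_weighted_median(h, n_boot = 100, seed = 7)$se,
                   mr_weighted_median(h, n_boot = 100, seed = 7)$se)
  expect_false(identical(mr_weighted_median(h, n_boot = 100, seed = 7)$se,
                         mr_weighted_median(h, n_boot = 100, seed = 8)$se))
  p1 <- mr_presso(h, n_sim = 200, seed = 7)
  p2 <- mr_presso(h, n_sim = 200, seed = 7)
  expect_identical(p1$global_pval, p2$global_pval)
  m1 <- mr_mode(h, n_boot = 100, seed = 7)
  m2 <- mr_mode(h, n_boot = 100, seed = 7)
  expect_identical(m1$weighted$se, m2$weighted$se)
})

test_that("all estimators are equivariant under exposure-unit rescaling", {
  set.seed(411)
  h <- make_h(bx = runif(8, 0.08, 0.2), sex = rep(0.02, 8),
              by = rnorm(8, 0.05, 0.03), sey = runif(8, 0.01, 0.03))
  cc <- 2.5
  hs <- h
  hs$beta_exp <- h$beta_exp * cc
  hs$se_exp <- h$se_exp * cc
  expect_equal(mr_ivw(hs)$beta, mr_ivw(h)$beta / cc, tolerance = 1e-12)
  expect_equal(mr_egger(hs)$slope$beta, mr_egger(h)$slope$beta / cc,
               tolerance = 1e-12)
  expect_equal(mr_egger(hs)$intercept$beta, mr_egger(h)$intercept$beta,
               tolerance = 1e-12)
  expect_equal(mr_weighted_median(hs, n_boot = 50, seed = 3)$beta,
               mr_weighted_median(h, n_boot = 50, seed = 3)$beta / cc,
               tolerance = 1e-8)
  ms <- mr_mode(hs, n_boot = 20, seed = 3)
  m <- mr_mode(h, n_boot = 20, seed = 3)
  expect_equal(ms$weighted$beta, m$weighted$beta / cc, tolerance = 1e-8)
  expect_equal(ms$simple$beta, m$simple$beta / cc, tolerance = 1e-8)
  w <- mr_wald_ratio(h$beta_exp[1] * cc, h$se_exp[1] * cc, h$beta_out[1],
                     h$se_out[1])
  expect_equal(w$beta, mr_wald_ratio(h$beta_exp[1], h$se_exp[1],
                                     h$beta_out[1], h$se_out[1])$beta / cc)
})

test_that("the method plan routes by instrument count", {
  expect_identical(select_method(0), character(0))
  expect_identical(select_method(1), "wald_ratio")
  expect_identical(select_method(2), "ivw")
  expect_identical(select_method(3), "ivw")
  expect_setequal(select_method(5),
                  c("ivw", "weighted_median", "weighted_mode", "simple_mode",
                    "egger", "mr_presso"))
})
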