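Z95 <- 1.959964  # two-sided 95% normal quantile, used for all CIs

mr_estimate <- function(method, k, beta, se, pval = NULL) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  structure(
    list(method = method, k = as.integer(k), beta = beta, se = se,
         pval = pval, or_ = exp(beta),
         ci_low = exp(beta - Z95 * se), ci_high = exp(beta + Z95 * se)),
    class = "mr_estimate"
  )
}

#' @export
print.mr_estimate <- function(x, ...) {
  cat(sprintf("<mr_estimate> %s (k = %d): beta = %.4g (SE %.4g), OR = %.3f [%.3f, %.3f], p = %.3g\n",
              x$method, x$k, x$beta, x$se, x$or_, x$ci_low, x$ci_high, x$pval))
  invisible(x)
}

# Pull the aligned effect vectors out of a harmonized set (kept rows only)
# or accept a plain data.frame carrying the same columns.
mr_inputs <- function(h) {
  if (inherits(h, "harmonized_set")) h <- harmonized_kept(h)
  stopifnot(all(c("beta_exp", "se_exp", "beta_out", "se_out") %in% names(h)))
  list(bx = h$beta_exp, sex = h$se_exp, by = h$beta_out, sey = h$se_out,
       k = nrow(h))
}

mr_na <- function(method, k, reason) {
  structure(
    list(method = method, k = as.integer(k), beta = NA_real_, se = NA_real_,
         pval = NA_real_, or_ = NA_real_, ci_low = NA_real_,
         ci_high = NA_real_, reason = reason),
    class = c("mr_not_applicable", "mr_estimate")
  )
}

#' Wald ratio causal estimate from a single instrument
#'
#' `beta = by / bx`, the outcome effect scaled by the exposure effect. The
#' default standard error is the first-order delta method `sey / |bx|`;
#' `second_order = TRUE` adds the exposure-side uncertainty,
#' `sqrt(sey^2 / bx^2 + by^2 sex^2 / bx^4)`.
#'
#' @param bx,sex Exposure effect and its SE.
#' @param by,sey Outcome effect and its SE.
#' @param second_order Use the second-order delta-method SE.
#' @return An `mr_estimate`.
#' @export
mr_wald_ratio <- function(bx, sex, by, sey, second_order = FALSE) {
  if (bx == 0) stop("Wald ratio undefined for bx = 0")
  beta <- by / bx
  se <- if (second_order) {
    sqrt(sey^2 / bx^2 + by^2 * sex^2 / bx^4)
  } else {
    sey / abs(bx)
  }
  mr_estimate("wald_ratio", 1L, beta, se)
}

#' Inverse-variance-weighted causal estimate
#'
#' Meta-analyses the per-SNP Wald ratios `by_j / bx_j` with weights
#' `w_j = bx_j^2 / sey_j^2` (equivalently a zero-intercept weighted
#' regression of `by` on `bx`). The fixed-effect SE is `1 / sqrt(sum w)`;
#' the multiplicative-random-effects SE scales it by
#' `max(1, sqrt(Q / (k - 1)))` with `Q` the Cochran heterogeneity statistic
#' of the ratios. The default (`model = "auto"`) reports the
#' random-effects SE, which floors at the fixed-effect value when
#' heterogeneity is at or below its expectation; both SEs are kept on the
#' result (`se_fixed`, `se_random`).
#'
#' @param h A `harmonized_set` (kept rows are used) or a data frame with
#'   columns `beta_exp`, `se_exp`, `beta_out`, `se_out`.
#' @param model `"auto"` (random effects, floored), `"fixed"`, or
#'   `"random"`.
#' @return An `mr_estimate` with extra fields `se_fixed`, `se_random`, `Q`,
#'   `Q_pval`.
#' @export
mr_ivw <- function(h, model = c("auto", "fixed", "random")) {
  model <- match.arg(model)
  d <- mr_inputs(h)
  if (d$k < 2L) stop("IVW needs at least 2 SNPs; route k = 1 to mr_wald_ratio")
  if (any(d$bx == 0)) {
    stop("IVW undefined: bx = 0 for SNP index ", which(d$bx == 0)[1])
  }
  ratio <- d$by / d$bx
  w <- d$bx^2 / d$sey^2
  beta <- sum(w * ratio) / sum(w)
  se_fixed <- 1 / sqrt(sum(w))
  Q <- sum(w * (ratio - beta)^2)
  phi <- max(1, sqrt(Q / (d$k - 1)))
  se_random <- se_fixed * phi
  se <- switch(model, fixed = se_fixed, random = se_fixed * sqrt(Q / (d$k - 1)),
               auto = se_random)
  est <- mr_estimate("ivw", d$k, beta, se)
  est$se_fixed <- se_fixed
  est$se_random <- se_random
  est$Q <- Q
  est$Q_pval <- stats::pchisq(Q, df = d$k - 1, lower.tail = FALSE)
  est
}

#' MR-Egger regression
#'
#' Weighted least squares of the outcome effects on the exposure effects
#' with a free intercept and weights `1 / sey^2`, after orienting all
#' exposure effects nonnegative (the sign of `by_j` flips with `bx_j`).
#' The slope is the pleiotropy-adjusted causal estimate; the intercept
#' estimates directional pleiotropy (its average direct effect). Standard
#' errors use a multiplicative overdispersion parameter floored at 1, and
#' p-values use the t distribution on `k - 2` degrees of freedom.
#'
#' @inheritParams mr_ivw
#' @return List with elements `slope` and `intercept`, both `mr_estimate`s
#'   (method `"egger"` / `"egger_intercept"`). For `k < 3` a typed
#'   not-applicable result is returned instead of an error.
#' @export
mr_egger <- function(h) {
  d <- mr_inputs(h)
  if (d$k < 3L) {
    return(list(slope = mr_na("egger", d$k, "needs k >= 3"),
                intercept = mr_na("egger_intercept", d$k, "needs k >= 3")))
  }
  flip <- sign(d$bx)
  flip[flip == 0] <- 1
  x <- d$bx * flip
  y <- d$by * flip
  w <- 1 / d$sey^2
  sw <- sum(w)
  xb <- sum(w * x) / sw
  yb <- sum(w * y) / sw
  sxx <- sum(w * (x - xb)^2)
  slope <- sum(w * (x - xb) * (y - yb)) / sxx
  inter <- yb - slope * xb
  resid <- y - inter - slope * x
  sigma2 <- sum(w * resid^2) / (d$k - 2)
  infl <- max(1, sigma2)  # overdispersion floored at 1
  se_slope <- sqrt(infl / sxx)
  se_inter <- sqrt(infl * (1 / sw + xb^2 / sxx))
  p_slope <- 2 * stats::pt(-abs(slope / se_slope), df = d$k - 2)
  p_inter <- 2 * stats::pt(-abs(inter / se_inter), df = d$k - 2)
  list(
    slope = mr_estimate("egger", d$k, slope, se_slope, pval = p_slope),
    intercept = mr_estimate("egger_intercept", d$k, inter, se_inter,
                            pval = p_inter)
  )
}

# Weighted-median point estimate: cumulative weights with the
# half-own-weight convention, linear interpolation at 0.5.
weighted_median_point <- function(ratio, w) {
  o <- order(ratio)
  r <- ratio[o]
  w <- w[o] / sum(w)
  s <- cumsum(w) - w / 2
  if (0.5 <= s[1]) return(r[1])
  if (0.5 >= s[length(s)]) return(r[length(r)])
  stats::approx(s, r, xout = 0.5, ties = "ordered")$y
}

# Parametric bootstrap SE shared by the median and mode estimators:
# resample (bx, by) from normals at their SEs and re-apply `point_fun`.
bootstrap_se <- function(d, point_fun, n_boot, seed) {
  local_seed(seed, {
    ests <- vapply(seq_len(n_boot), function(b) {
      bx <- stats::rnorm(d$k, d$bx, d$sex)
      by <- stats::rnorm(d$k, d$by, d$sey)
      point_fun(bx, by)
    }, numeric(1))
    stats::sd(ests)
  })
}

#' Weighted-median causal estimate
#'
#' The value at which the cumulative instrument weight of the sorted
#' per-SNP ratio estimates crosses one half (weights
#' `w_j = bx_j^2 / sey_j^2`, standardized, with the half-own-weight
#' convention and linear interpolation). Consistent when at least half the
#' weight comes from valid instruments. The SE is the standard deviation of
#' parametric-bootstrap re-estimates.
#'
#' @inheritParams mr_ivw
#' @param n_boot Bootstrap replicates for the SE (default 1000).
#' @param seed RNG seed for the bootstrap; results are reproducible
#'   bit-for-bit given the seed.
#' @return An `mr_estimate`, or a typed not-applicable result for `k < 3`.
#' @export
mr_weighted_median <- function(h, n_boot = 1000, seed = 1) {
  d <- mr_inputs(h)
  if (d$k < 3L) return(mr_na("weighted_median", d$k, "needs k >= 3"))
  point <- weighted_median_point(d$by / d$bx, d$bx^2 / d$sey^2)
  se <- bootstrap_se(d, function(bx, by) {
    weighted_median_point(by / bx, bx^2 / d$sey^2)
  }, n_boot, seed)
  mr_estimate("weighted_median", d$k, point, se)
}

# Mode of a Gaussian-kernel-smoothed density over the ratio estimates,
# evaluated on a fine grid. h0 is the modified rule-of-thumb bandwidth
# based on the median absolute deviation.
mode_point <- function(ratio, w, bandwidth_factor) {
  if (max(ratio) - min(ratio) < .Machine$double.eps^0.5) return(ratio[1])
  k <- length(ratio)
  h0 <- 0.9 * min(stats::sd(ratio), stats::mad(ratio)) * k^(-1 / 5)
  if (h0 <= 0) h0 <- 0.9 * stats::sd(ratio) * k^(-1 / 5)
  bw <- bandwidth_factor * h0
  grid <- seq(min(ratio) - 3 * bw, max(ratio) + 3 * bw, length.out = 1024)
  dens <- vapply(grid, function(g) sum(w * stats::dnorm((g - ratio) / bw)),
                 numeric(1))
  grid[which.max(dens)]
}

#' Mode-based causal estimates (weighted and simple)
#'
#' The mode of a Gaussian-kernel-smoothed density over the per-SNP ratio
#' estimates: the simple mode uses unit weights, the weighted mode uses
#' `w_j = bx_j^2 / sey_j^2`. Consistent when the largest group of
#' instruments sharing a ratio value is valid. The bandwidth is
#' `bandwidth_factor` times the modified (MAD-based) rule-of-thumb
#' bandwidth `0.9 min(sd, mad) k^(-1/5)`; the estimate is
#' bandwidth-sensitive, so the factor is exposed. SEs by parametric
#' bootstrap.
#'
#' @inheritParams mr_weighted_median
#' @param bandwidth_factor Multiplier on the rule-of-thumb bandwidth
#'   (default 1).
#' @return List with elements `weighted` and `simple`, both `mr_estimate`s
#'   (methods `"weighted_mode"`, `"simple_mode"`), or typed not-applicable
#'   results for `k < 3`.
#' @export
mr_mode <- function(h, bandwidth_factor = 1, n_boot = 1000, seed = 1) {
  d <- mr_inputs(h)
  if (d$k < 3L) {
    return(list(weighted = mr_na("weighted_mode", d$k, "needs k >= 3"),
                simple = mr_na("simple_mode", d$k, "needs k >= 3")))
  }
  stopifnot(bandwidth_factor > 0)
  w_ivw <- d$bx^2 / d$sey^2
  unit <- rep(1, d$k)
  pt_w <- mode_point(d$by / d$bx, w_ivw / sum(w_ivw), bandwidth_factor)
  pt_s <- mode_point(d$by / d$bx, unit / d$k, bandwidth_factor)
  se_w <- bootstrap_se(d, function(bx, by) {
    w <- bx^2 / d$sey^2
    mode_point(by / bx, w / sum(w), bandwidth_factor)
  }, n_boot, seed)
  se_s <- bootstrap_se(d, function(bx, by) {
    mode_point(by / bx, unit / d$k, bandwidth_factor)
  }, n_boot, seed + 1L)
  list(
    weighted = mr_estimate("weighted_mode", d$k, pt_w, se_w),
    simple = mr_estimate("simple_mode", d$k, pt_s, se_s)
  )
}

# Leave-one-out IVW slopes for every SNP at once.
loo_slopes <- function(ratio, w) {
  (sum(w * ratio) - w * ratio) / (sum(w) - w)
}

#' MR-PRESSO: pleiotropy residual sum of squares and outlier test
#'
#' Global test: the observed residual sum of squares
#' `RSS = sum_j (by_j - bhat_(-j) bx_j)^2`, with `bhat_(-j)` the
#' leave-one-out IVW slope, is compared with its null distribution from
#' `n_sim` parametric simulations (`bx*`, `by*` drawn from normals at the
#' observed SEs around the fitted values). Outlier test: each SNP's
#' observed squared residual is compared with its simulated distribution;
#' per-SNP p-values are Bonferroni-corrected over `k`, and SNPs below `sig`
#' are flagged. The corrected estimate is IVW after removing flagged
#' outliers, and the distortion p-value compares the raw-vs-corrected shift
#' against removals of random SNP subsets of the same size.
#'
#' @inheritParams mr_weighted_median
#' @param n_sim Parametric simulations for the null distributions
#'   (default 1000).
#' @param sig Significance threshold for flagging outliers after Bonferroni
#'   correction (default 0.05).
#' @return A `presso_result` list: `global_rss_obs`, `global_pval`,
#'   `outlier_flags`, `outlier_pvals` (Bonferroni-corrected),
#'   `corrected` (an `mr_estimate` or `NULL`), `distortion_pval`, `n_sim`,
#'   `seed`. For `k < 4` a typed not-applicable result.
#' @export
mr_presso <- function(h, n_sim = 1000, seed = 1, sig = 0.05) {
  d <- mr_inputs(h)
  if (d$k < 4L) {
    return(structure(list(applicable = FALSE, k = d$k,
                          reason = "needs k >= 4"),
                     class = "presso_result"))
  }
  k <- d$k
  ratio <- d$by / d$bx
  w <- d$bx^2 / d$sey^2
  b_loo <- loo_slopes(ratio, w)
  resid_obs <- d$by - b_loo * d$bx
  rss_obs <- sum(resid_obs^2)

  local_seed(seed, {
    bx_s <- matrix(stats::rnorm(n_sim * k, rep(d$bx, each = n_sim),
                                rep(d$sex, each = n_sim)), n_sim, k)
    by_s <- matrix(stats::rnorm(n_sim * k, rep(b_loo * d$bx, each = n_sim),
                                rep(d$sey, each = n_sim)), n_sim, k)
    r_s <- by_s / bx_s
    w_s <- bx_s^2 / matrix(d$sey^2, n_sim, k, byrow = TRUE)
    swr <- rowSums(w_s * r_s)
    sw <- rowSums(w_s)
    b_loo_s <- (swr - w_s * r_s) / (sw - w_s)
    resid_s <- by_s - b_loo_s * bx_s
    rss_s <- rowSums(resid_s^2)
    global_pval <- (1 + sum(rss_s >= rss_obs)) / (1 + n_sim)

    p_snp <- (1 + colSums(resid_s^2 >= matrix(resid_obs^2, n_sim, k,
                                              byrow = TRUE))) / (1 + n_sim)
    p_bonf <- pmin(1, p_snp * k)
    flags <- p_bonf < sig

    corrected <- NULL
    distortion_pval <- NULL
    if (any(flags) && sum(!flags) >= 2L) {
      keep <- data.frame(beta_exp = d$bx[!flags], se_exp = d$sex[!flags],
                         beta_out = d$by[!flags], se_out = d$sey[!flags])
      corrected <- mr_ivw(keep)
      corrected$method <- "presso_outlier_corrected"
      beta_raw <- sum(w * ratio) / sum(w)
      d_obs <- (beta_raw - corrected$beta) / abs(corrected$beta)
      n_out <- sum(flags)
      d_null <- vapply(seq_len(n_sim), function(s) {
        drop <- sample.int(k, n_out)
        b_s <- sum((w * ratio)[-drop]) / sum(w[-drop])
        (beta_raw - b_s) / abs(b_s)
      }, numeric(1))
      distortion_pval <- (1 + sum(abs(d_null) >= abs(d_obs))) / (1 + n_sim)
    }

    structure(
      list(applicable = TRUE, k = k, global_rss_obs = rss_obs,
           global_pval = global_pval, outlier_flags = flags,
           outlier_pvals = p_bonf, corrected = corrected,
           distortion_pval = distortion_pval, n_sim = n_sim, seed = seed),
      class = "presso_result"
    )
  })
}

#' @export
print.presso_result <- function(x, ...) {
  if (!isTRUE(x$applicable)) {
    cat(sprintf("<presso_result> not applicable (k = %d: %s)\n", x$k, x$reason))
    return(invisible(x))
  }
  cat(sprintf("<presso_result> k = %d, global RSS = %.4g, global p = %.3g, %d outlier(s)\n",
              x$k, x$global_rss_obs, x$global_pval, sum(x$outlier_flags)))
  invisible(x)
}

#' Method-selection rule
#'
#' One instrument: Wald ratio. More than one: IVW. More than three: IVW
#' plus the sensitivity suite (weighted median, weighted mode, simple mode,
#' MR-Egger, MR-PRESSO), whose estimators tolerate some invalid instruments
#' at the cost of power.
#'
#' @param k Instrument count (`>= 0`).
#' @return Character vector of method names; empty for `k = 0`.
#' @export
select_method <- function(k) {
  stopifnot(k >= 0)
  if (k == 0) return(character(0))
  if (k == 1) return("wald_ratio")
  if (k <= 3) return("ivw")
  c("ivw", "weighted_median", "weighted_mode", "simple_mode", "egger",
    "mr_presso")
}
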