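# The five MR causal-effect estimators.

.z975 <- stats::qnorm(0.975)

# Build one row of the standard MR result table (beta scale + OR transform).
.mr_result <- function(method, n_snp, beta, se, pval = NULL, crit = .z975) {
  if (is.null(pval)) pval <- 2 * stats::pnorm(-abs(beta / se))
  ci_low <- beta - crit * se
  ci_high <- beta + crit * se
  data.frame(method = method, n_snp = as.integer(n_snp),
             beta = beta, se = se, ci_low = ci_low, ci_high = ci_high,
             pval = pval, or = exp(beta), or_ci_low = exp(ci_low),
             or_ci_high = exp(ci_high), stringsAsFactors = FALSE)
}

.check_hset <- function(hset, min_snp = 1) {
  stopifnot(is.data.frame(hset))
  need <- c("beta_exp", "se_exp", "beta_out", "se_out")
  if (!all(need %in% names(hset)))
    stop("harmonized set must carry columns ", paste(need, collapse = ", "))
  if (nrow(hset) < min_snp)
    stop("estimator requires at least ", min_snp, " instrument(s), got ",
         nrow(hset))
  invisible(hset)
}

#' Wald ratio estimate for a single variant
#'
#' `beta = beta_out / beta_exp`. The default standard error is the
#' first-order delta approximation `se_out / |beta_exp|`; the second-order
#' form additionally carries the exposure-side uncertainty,
#' `sqrt(se_out^2/beta_exp^2 + beta_out^2 se_exp^2 / beta_exp^4)`.
#'
#' @param pair One-row harmonized pair (or a harmonized set; vectorized).
#' @param second_order Use the second-order delta-method SE.
#' @return An MR result data.frame (one row per pair).
#' @export
wald_ratio <- function(pair, second_order = FALSE) {
  .check_hset(pair, 1)
  if (any(pair$beta_exp == 0))
    stop("wald_ratio: beta_exp is zero for ",
         pair$variant_id[pair$beta_exp == 0][1])
  b <- pair$beta_out / pair$beta_exp
  se <- pair$se_out / abs(pair$beta_exp)
  if (second_order)
    se <- sqrt(pair$se_out^2 / pair$beta_exp^2 +
                 pair$beta_out^2 * pair$se_exp^2 / pair$beta_exp^4)
  res <- .mr_result("wald_ratio", 1L, b, se)
  if ("variant_id" %in% names(pair)) res$variant_id <- pair$variant_id
  res
}

#' Inverse-variance-weighted estimate
#'
#' Meta-analyses the per-variant Wald ratios with weights
#' `w_j = beta_exp_j^2 / se_out_j^2` (first-order ratio variance, the usual
#' two-sample convention: exposure-side uncertainty is ignored). Equivalent
#' to weighted least squares of `beta_out` on `beta_exp` through the origin
#' with weights `1/se_out^2`. The fixed-effect SE is `(sum w)^(-1/2)`; the
#' multiplicative-random-effects model inflates it by
#' `max(1, sqrt(Q/(J-1)))`, never shrinking below the fixed-effect SE.
#' P-values are two-sided normal.
#'
#' @param hset A `harmonized_set` with at least 2 pairs.
#' @param model `"fixed"` or `"mre"`.
#' @return One-row MR result data.frame.
#' @export
mr_ivw <- function(hset, model = c("fixed", "mre")) {
  model <- match.arg(model)
  .check_hset(hset, 2)
  if (any(hset$beta_exp == 0))
    stop("mr_ivw: beta_exp is zero for ",
         hset$variant_id[hset$beta_exp == 0][1])
  ratio <- hset$beta_out / hset$beta_exp
  w <- hset$beta_exp^2 / hset$se_out^2
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  if (model == "mre") {
    q <- sum(w * (ratio - beta)^2)
    se <- se * max(1, sqrt(q / (nrow(hset) - 1)))
  }
  .mr_result(if (model == "fixed") "ivw_fixed" else "ivw_mre",
             nrow(hset), beta, se)
}

# Orient pairs so every exposure effect is non-negative (joint sign flip
# leaves the causal estimate unchanged but is required for Egger).
.orient <- function(hset) {
  neg <- hset$beta_exp < 0
  hset$beta_exp[neg] <- -hset$beta_exp[neg]
  hset$beta_out[neg] <- -hset$beta_out[neg]
  hset
}

#' MR-Egger regression
#'
#' Weighted least squares of outcome effects on exposure effects with a free
#' intercept (weights `1/se_out^2`), after orienting all exposure effects to
#' be non-negative. The slope estimates the causal effect; the intercept
#' estimates the average directional (horizontal) pleiotropic effect, valid
#' under the InSIDE assumption. Standard errors are inflated by
#' `max(1, sqrt(Q_egger/(J-2)))`; p-values use the t distribution with J-2
#' degrees of freedom, two-sided.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @return List with elements `result` (slope as MR result row) and
#'   `pleiotropy` (data.frame: `intercept`, `se`, `pval`).
#' @export
mr_egger <- function(hset) {
  .check_hset(hset, 3)
  h <- .orient(hset)
  x <- h$beta_exp; y <- h$beta_out; w <- 1 / h$se_out^2
  if (stats::var(x) == 0)
    stop("mr_egger: degenerate design (all exposure effects equal after orientation)")
  J <- length(x)
  fit <- stats::lm(y ~ x, weights = w)
  sm <- suppressWarnings(summary(fit))  # exact fits warn harmlessly
  cf <- sm$coefficients
  sigma <- sm$sigma                     # sqrt(Q_egger / (J - 2))
  scale <- 1 / min(1, sigma)            # floor the dispersion at 1
  slope <- cf["x", "Estimate"]
  slope_se <- cf["x", "Std. Error"] * scale
  int <- cf["(Intercept)", "Estimate"]
  int_se <- cf["(Intercept)", "Std. Error"] * scale
  tcrit <- stats::qt(0.975, df = J - 2)
  res <- .mr_result("egger", J, slope, slope_se,
                    pval = 2 * stats::pt(-abs(slope / slope_se), df = J - 2),
                    crit = tcrit)
  ple <- data.frame(intercept = int, se = int_se,
                    pval = 2 * stats::pt(-abs(int / int_se), df = J - 2))
  list(result = res, pleiotropy = ple)
}

# Weighted-median interpolation rule on ratio estimates.
.weighted_median_point <- function(ratio, w) {
  ord <- order(ratio)
  b <- ratio[ord]
  ws <- w[ord] / sum(w)
  s <- cumsum(ws) - ws / 2
  stats::approx(s, b, xout = 0.5, rule = 2, ties = "ordered")$y
}

# Parametric bootstrap shared by the median and mode estimators: resample
# effect pairs from normals at the observed values, re-estimate, return SD.
.bootstrap_se <- function(hset, point_fun, n_boot, seed) {
  if (n_boot <= 0) return(NA_real_)
  if (is.null(seed))
    stop("a seed is required when bootstrapping (reproducibility contract)")
  J <- nrow(hset)
  est <- withr_seed(seed, {
    vapply(seq_len(n_boot), function(i) {
      be <- stats::rnorm(J, hset$beta_exp, hset$se_exp)
      bo <- stats::rnorm(J, hset$beta_out, hset$se_out)
      point_fun(bo / be, be^2 / hset$se_out^2)
    }, numeric(1))
  })
  stats::sd(est)
}

# Evaluate under a local RNG state without touching the caller's stream.
withr_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Weighted-median estimate
#'
#' Consistent when variants carrying at least half of the weight are valid
#' instruments. Ratios are sorted; with normalized weights `w_j` the
#' cumulative midpoint is `s_j = sum_{k<j} w_k + w_j/2`, and the estimate is
#' the linear interpolation of the ratio over `s` at 0.5. The SE is the
#' standard deviation of the estimate over `n_boot` parametric-bootstrap
#' replicates (effect pairs resampled from normals at their observed values);
#' the p-value is two-sided normal.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; required when `n_boot > 0`.
#' @return One-row MR result data.frame.
#' @export
mr_weighted_median <- function(hset, n_boot = 1000, seed = NULL) {
  .check_hset(hset, 3)
  ratio <- hset$beta_out / hset$beta_exp
  w <- hset$beta_exp^2 / hset$se_out^2
  beta <- .weighted_median_point(ratio, w)
  se <- .bootstrap_se(hset, .weighted_median_point, n_boot, seed)
  .mr_result("weighted_median", nrow(hset), beta, se)
}

# Mode of the ratio density: Gaussian KDE on a 512-point grid spanning
# [min - h, max + h], modified-Silverman bandwidth.
.mode_point <- function(ratio, w, phi = 1, weighted = TRUE) {
  J <- length(ratio)
  if (!weighted) w <- rep(1, J)
  w <- w / sum(w)
  s <- stats::sd(ratio)
  m <- stats::mad(ratio)
  h <- phi * 0.9 * min(s, m) * J^(-1 / 5)
  if (!is.finite(h) || h <= 0) {
    # degenerate bandwidth (identical or majority-identical ratios):
    # return the ratio value carrying the most weight
    agg <- tapply(w, ratio, sum)
    return(as.numeric(names(agg)[which.max(agg)]))
  }
  grid <- seq(min(ratio) - h, max(ratio) + h, length.out = 512)
  dens <- as.vector(stats::dnorm(outer(grid, ratio, "-"), sd = h) %*% w)
  grid[which.max(dens)]
}

#' Mode-based estimate (simple or weighted)
#'
#' The estimate is the mode of the kernel density of the per-variant ratio
#' estimates: consistent when the largest homogeneous cluster of variants is
#' valid. The simple mode weights all variants equally; the weighted mode
#' uses the inverse-variance weights. Bandwidth is the modified Silverman
#' rule `phi * 0.9 * min(sd, MAD) * J^(-1/5)`; the density is evaluated on a
#' 512-point grid over `[min - h, max + h]`. When all ratios coincide the
#' common ratio is returned. SE by the same parametric bootstrap as the
#' weighted median; p two-sided normal.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param weighted Weighted (`TRUE`) or simple (`FALSE`) mode.
#' @param phi Bandwidth multiplier (default 1).
#' @param n_boot Bootstrap replicates (default 1000).
#' @param seed RNG seed for the bootstrap; required when `n_boot > 0`.
#' @return One-row MR result data.frame.
#' @export
mr_mode <- function(hset, weighted = TRUE, phi = 1, n_boot = 1000,
                    seed = NULL) {
  .check_hset(hset, 3)
  ratio <- hset$beta_out / hset$beta_exp
  w <- hset$beta_exp^2 / hset$se_out^2
  beta <- .mode_point(ratio, w, phi = phi, weighted = weighted)
  se <- .bootstrap_se(hset,
                      function(r, wt) .mode_point(r, wt, phi = phi,
                                                  weighted = weighted),
                      n_boot, seed)
  .mr_result(if (weighted) "weighted_mode" else "simple_mode",
             nrow(hset), beta, se)
}
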