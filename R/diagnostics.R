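# Heterogeneity, pleiotropy and sensitivity diagnostics.

#' Cochran's Q heterogeneity test
#'
#' For the IVW model, `Q = sum w_j (ratio_j - beta_ivw)^2` with the IVW
#' weights and `J - 1` degrees of freedom. For the Egger model, Q is the
#' weighted residual sum of squares around the Egger line (weights
#' `1/se_out^2`) with `J - 2` degrees of freedom. The p-value is the
#' upper tail of the chi-square distribution at Q.
#'
#' @param hset A `harmonized_set` (J >= 2 for `"ivw"`, J >= 3 for
#'   `"egger"`).
#' @param method `"ivw"` or `"egger"`.
#' @return Data.frame with `method`, `Q`, `df`, `pval`.
#' @export
cochran_q <- function(hset, method = c("ivw", "egger")) {
  method <- match.arg(method)
  .check_hset(hset, if (method == "ivw") 2 else 3)
  J <- nrow(hset)
  if (method == "ivw") {
    ratio <- hset$beta_out / hset$beta_exp
    w <- hset$beta_exp^2 / hset$se_out^2
    beta <- sum(w * ratio) / sum(w)
    q <- sum(w * (ratio - beta)^2)
    df <- J - 1
  } else {
    h <- .orient(hset)
    w <- 1 / h$se_out^2
    fit <- stats::lm(beta_out ~ beta_exp, data = h, weights = w)
    q <- sum(w * stats::residuals(fit)^2)
    df <- J - 2
  }
  data.frame(method = method, Q = q, df = as.integer(df),
             pval = stats::pchisq(q, df, lower.tail = FALSE),
             stringsAsFactors = FALSE)
}

#' Egger intercept test for horizontal pleiotropy
#'
#' The intercept component of [mr_egger()], exposed separately because the
#' pipeline branches on its p-value: directional pleiotropy at p below the
#' chosen level triggers MR-PRESSO outlier correction.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @return Data.frame with `intercept`, `se`, `pval`.
#' @export
egger_intercept_test <- function(hset) mr_egger(hset)$pleiotropy

#' Single-SNP (per-variant Wald ratio) analysis
#'
#' One Wald ratio per instrument, in set order; the resulting betas are the
#' "b scores" consumed by functional-variant prioritization.
#'
#' @param hset A `harmonized_set`.
#' @return Data.frame of per-variant MR results with a `variant_id` column.
#' @export
single_snp <- function(hset) {
  .check_hset(hset, 1)
  res <- wald_ratio(hset)
  res$method <- "wald_ratio"
  res[, c("variant_id", setdiff(names(res), "variant_id"))]
}

#' Leave-one-out sensitivity analysis
#'
#' Re-estimates the fixed-effect IVW slope with each instrument excluded in
#' turn. The `drives` flag marks exclusions that change the estimate's sign
#' or move its p-value across the `alpha` boundary relative to the full-set
#' estimate.
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param alpha Significance boundary for the drive flag.
#' @return Data.frame: `excluded_id`, `n_snp`, `beta`, `se`, `pval`,
#'   `drives`.
#' @export
leave_one_out <- function(hset, alpha = 0.05) {
  .check_hset(hset, 3)
  full <- mr_ivw(hset, "fixed")
  rows <- lapply(seq_len(nrow(hset)), function(j) {
    r <- mr_ivw(hset[-j, , drop = FALSE], "fixed")
    data.frame(excluded_id = hset$variant_id[j], n_snp = r$n_snp,
               beta = r$beta, se = r$se, pval = r$pval,
               drives = sign(r$beta) != sign(full$beta) ||
                 (r$pval < alpha) != (full$pval < alpha),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Data products behind the standard MR plots
#'
#' Builds the tables underlying the scatter, funnel and forest displays:
#' per-variant effect pairs with the fitted line of each estimator (origin
#' lines for all but MR-Egger, which keeps its intercept), the funnel
#' coordinates (Wald ratio against inverse ratio-SE, with each method's
#' vertical), and forest tables for the single-SNP and leave-one-out
#' analyses.
#'
#' @param hset A `harmonized_set`.
#' @param fit An [mr_fit()] on the same set.
#' @param loo Optional precomputed [leave_one_out()] table.
#' @return List with `scatter`, `lines`, `funnel`, `forest_single`,
#'   `forest_loo`.
#' @export
plot_data <- function(hset, fit, loo = NULL) {
  stopifnot(inherits(fit, "mr_fit"))
  h <- .orient(hset)
  scatter <- data.frame(variant_id = h$variant_id,
                        beta_exp = h$beta_exp, se_exp = h$se_exp,
                        beta_out = h$beta_out, se_out = h$se_out,
                        stringsAsFactors = FALSE)
  r <- fit$results
  lines_tab <- data.frame(method = r$method, slope = r$beta,
                          intercept = ifelse(r$method == "egger",
                                             fit$pleiotropy$intercept, 0),
                          stringsAsFactors = FALSE)
  ratio <- hset$beta_out / hset$beta_exp
  funnel <- data.frame(variant_id = hset$variant_id, ratio = ratio,
                       precision = abs(hset$beta_exp) / hset$se_out,
                       stringsAsFactors = FALSE)
  if (is.null(loo)) loo <- leave_one_out(hset)
  list(scatter = scatter, lines = lines_tab, funnel = funnel,
       forest_single = single_snp(hset), forest_loo = loo)
}
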