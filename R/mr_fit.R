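# The mr_fit estimator suite object and its S3 methods.

#' Fit the full suite of MR estimators
#'
#' Runs the five two-sample MR estimators on a harmonized instrument set —
#' inverse-variance weighted (fixed effect; the multiplicative-random-effects
#' variant is added when Cochran's Q is significant), MR-Egger, weighted
#' median, simple mode and weighted mode — together with the heterogeneity
#' and pleiotropy diagnostics. Following the direction-consistency rule, the
#' suite carries a `consistent` flag (all five causal estimates share sign)
#' and a `significant` flag (consistency and all five p-values below
#' `alpha`).
#'
#' @param hset A `harmonized_set` with at least 3 pairs.
#' @param seed RNG seed for the bootstrap SEs (required).
#' @param n_boot Bootstrap replicates for the median/mode SEs.
#' @param phi Mode bandwidth multiplier.
#' @param alpha Significance level for the flags and the Q-triggered MRE
#'   model (default 0.05).
#' @return An object of class `mr_fit` with components `results` (one row
#'   per method), `heterogeneity`, `pleiotropy`, `consistent`,
#'   `significant`, `hset`, `seed`.
#' @seealso [mr_ivw()], [mr_egger()], [mr_weighted_median()], [mr_mode()],
#'   [cochran_q()], [mr_presso()]
#' @examples
#' sim <- simulate_pair(sim_config(n_variants = 30, n_instruments = 30,
#'                                 theta = 0.7, seed = 7))
#' h <- harmonize(sim$exposure, sim$outcome)
#' fit <- mr_fit(h, seed = 7, n_boot = 100)
#' fit
#' coef(fit)
#' @export
mr_fit <- function(hset, seed, n_boot = 1000, phi = 1, alpha = 0.05) {
  .check_hset(hset, 3)
  if (missing(seed)) stop("mr_fit: a seed is required")
  het_ivw <- cochran_q(hset, "ivw")
  het_egger <- cochran_q(hset, "egger")
  eg <- mr_egger(hset)
  core <- rbind(
    mr_ivw(hset, "fixed"),
    eg$result,
    mr_weighted_median(hset, n_boot = n_boot, seed = seed),
    mr_mode(hset, weighted = FALSE, phi = phi, n_boot = n_boot,
            seed = seed + 1L),
    mr_mode(hset, weighted = TRUE, phi = phi, n_boot = n_boot,
            seed = seed + 2L)
  )
  results <- core
  if (het_ivw$pval < alpha)
    results <- rbind(results, mr_ivw(hset, "mre"))
  consistent <- length(unique(sign(core$beta))) == 1 && all(core$beta != 0)
  significant <- consistent && all(core$pval < alpha)
  structure(list(results = results,
                 heterogeneity = rbind(het_ivw, het_egger),
                 pleiotropy = eg$pleiotropy,
                 consistent = consistent, significant = significant,
                 alpha = alpha, hset = hset, seed = seed,
                 n_boot = n_boot, phi = phi),
            class = "mr_fit")
}

#' @export
print.mr_fit <- function(x, digits = 4, ...) {
  cat("Two-sample MR fit: ", attr(x$hset, "exposure_label"), " -> ",
      attr(x$hset, "outcome_label"), " (", nrow(x$hset),
      " instruments)\n\n", sep = "")
  tab <- x$results[, c("method", "n_snp", "beta", "se", "pval", "or",
                       "or_ci_low", "or_ci_high")]
  print(format(tab, digits = digits), row.names = FALSE)
  cat("\nDirection-consistent across the five methods: ",
      x$consistent, "; all p < ", x$alpha, ": ", x$significant, "\n",
      sep = "")
  invisible(x)
}

#' @export
coef.mr_fit <- function(object, ...) {
  stats::setNames(object$results$beta, object$results$method)
}

#' @export
confint.mr_fit <- function(object, parm, level = 0.95, ...) {
  r <- object$results
  if (level != 0.95) {
    crit <- ifelse(r$method == "egger",
                   stats::qt(1 - (1 - level) / 2, df = r$n_snp - 2),
                   stats::qnorm(1 - (1 - level) / 2))
    lo <- r$beta - crit * r$se
    hi <- r$beta + crit * r$se
  } else { lo <- r$ci_low; hi <- r$ci_high }
  m <- cbind(lo, hi)
  dimnames(m) <- list(r$method,
                      sprintf("%.1f %%", c((1 - level) / 2,
                                           1 - (1 - level) / 2) * 100))
  if (!missing(parm)) m <- m[parm, , drop = FALSE]
  m
}

#' @export
summary.mr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.mr_fit")
}

#' @export
print.summary.mr_fit <- function(x, digits = 4, ...) {
  f <- x$fit
  print(f, digits = digits)
  cat("\nHeterogeneity:\n")
  print(format(f$heterogeneity, digits = digits), row.names = FALSE)
  cat("\nEgger intercept (horizontal pleiotropy): ",
      format(f$pleiotropy$intercept, digits = digits), " (SE ",
      format(f$pleiotropy$se, digits = digits), ", p = ",
      format(f$pleiotropy$pval, digits = digits), ")\n", sep = "")
  a <- attr(f$hset, "audit")
  if (!is.null(a))
    cat("\nHarmonization audit: ", a$n_retained, "/", a$n_input,
        " instruments retained (", a$n_ambiguous, " ambiguous, ",
        a$n_missing, " missing from outcome)\n", sep = "")
  invisible(x)
}

#' @export
residuals.mr_fit <- function(object, ...) {
  h <- object$hset
  ivw <- object$results$beta[object$results$method == "ivw_fixed"]
  ratio <- h$beta_out / h$beta_exp
  w <- h$beta_exp^2 / h$se_out^2
  stats::setNames(sqrt(w) * (ratio - ivw), h$variant_id)
}

#' Scatter plot of instrument effects with fitted MR lines
#'
#' Exposure effects against outcome effects (oriented so exposure effects
#' are non-negative), with one fitted line per estimator: through the origin
#' for all methods except MR-Egger, whose intercept is drawn.
#'
#' @param x An `mr_fit`.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.mr_fit <- function(x, ...) {
  pd <- plot_data(x$hset, x)
  sc <- pd$scatter
  graphics::plot(sc$beta_exp, sc$beta_out,
                 xlab = paste("SNP effect on", attr(x$hset, "exposure_label")),
                 ylab = paste("SNP effect on", attr(x$hset, "outcome_label")),
                 pch = 19, ...)
  graphics::segments(sc$beta_exp, sc$beta_out - .z975 * sc$se_out,
                     sc$beta_exp, sc$beta_out + .z975 * sc$se_out,
                     col = "grey70")
  lines_tab <- pd$lines
  for (i in seq_len(nrow(lines_tab)))
    graphics::abline(lines_tab$intercept[i], lines_tab$slope[i],
                     col = i + 1, lty = i)
  graphics::legend("topleft", legend = lines_tab$method,
                   col = seq_len(nrow(lines_tab)) + 1,
                   lty = seq_len(nrow(lines_tab)), cex = 0.8, bty = "n")
  invisible(x)
}
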