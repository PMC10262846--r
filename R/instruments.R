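# Instrument selection and exposure/outcome harmonization.

#' Genome-wide significance filter
#'
#' Retains records with `pval` strictly below the threshold (the conventional
#' genome-wide level 5e-8 by default; a record at exactly the threshold is
#' not retained).
#'
#' @param table A [summary_table()].
#' @param p_threshold Significance threshold.
#' @return The filtered `summary_table` (possibly empty).
#' @export
filter_genome_wide <- function(table, p_threshold = 5e-8) {
  stopifnot(inherits(table, "summary_table"))
  keep <- table$pval < p_threshold
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Greedy LD clumping
#'
#' Repeatedly takes the remaining record with the smallest p-value as an
#' index variant and discards all remaining records on the same chromosome
#' within `window_kb` kilobases of it whose r-squared with the index exceeds
#' `r2_threshold`. Ties at equal p are broken by chromosome, then position,
#' then variant id, so the output does not depend on input row order.
#' Variants absent from the LD matrix are treated as unlinked and counted in
#' the `"clump_summary"` attribute.
#'
#' @param table A [summary_table()] (typically already significance-filtered).
#' @param ld Symmetric r-squared matrix with variant-id dimnames
#'   (see [read_ld_matrix()]).
#' @param window_kb Half-window in kb around the index variant (default
#'   5000, i.e. a 10 Mb span).
#' @param r2_threshold Records with r2 strictly greater than this are pruned.
#' @return `summary_table` of index variants in selection order.
#' @export
clump <- function(table, ld, window_kb = 5000, r2_threshold = 0.01) {
  stopifnot(inherits(table, "summary_table"))
  validate_ld_matrix(ld)
  in_ld <- table$variant_id %in% rownames(ld)
  n_unlinked <- sum(!in_ld)
  ord <- order(table$pval, table$chrom, table$pos, table$variant_id)
  pool <- table[ord, , drop = FALSE]
  kept <- integer(0)
  alive <- rep(TRUE, nrow(pool))
  for (i in seq_len(nrow(pool))) {
    if (!alive[i]) next
    kept <- c(kept, i)
    idx <- pool$variant_id[i]
    cand <- which(alive & seq_len(nrow(pool)) > i &
                    pool$chrom == pool$chrom[i] &
                    abs(pool$pos - pool$pos[i]) <= window_kb * 1000)
    if (length(cand) > 0 && idx %in% rownames(ld)) {
      cid <- pool$variant_id[cand]
      known <- cid %in% colnames(ld)
      r2 <- rep(0, length(cand))
      r2[known] <- ld[idx, cid[known]]
      alive[cand[r2 > r2_threshold]] <- FALSE
    }
  }
  out <- pool[kept, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "clump_summary") <- list(n_input = nrow(table),
                                     n_index = nrow(out),
                                     n_pruned = nrow(table) - nrow(out),
                                     n_missing_from_ld = n_unlinked)
  out
}

#' Variance in the exposure explained by a variant
#'
#' Computes, per variant,
#' \deqn{R^2 = \frac{2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2}
#'   {2\,\mathrm{EAF}(1-\mathrm{EAF})\beta^2 +
#'    2\,\mathrm{EAF}(1-\mathrm{EAF})\,N\,\mathrm{SE}(\beta)^2}}
#' Symmetric in EAF versus 1-EAF; zero when beta is zero. Missing EAF is an
#' error: callers must drop such records or supply a frequency, never impute
#' silently.
#'
#' @param record A `summary_table` or data.frame with columns `eaf`, `beta`,
#'   `se`, `n` (vectorized over rows).
#' @return Numeric vector of per-variant R-squared values in `[0,1)`.
#' @export
explained_variance <- function(record) {
  eaf <- record$eaf; beta <- record$beta; se <- record$se; n <- record$n
  if (any(is.na(eaf)))
    stop("explained_variance: missing EAF for ",
         record$variant_id[is.na(eaf)][1],
         "; drop the record or supply its effect-allele frequency")
  if (any(eaf <= 0 | eaf >= 1)) stop("explained_variance: EAF outside (0,1)")
  if (any(n <= 2)) stop("explained_variance: n must exceed 2")
  v <- 2 * eaf * (1 - eaf)
  num <- v * beta^2
  num / (num + v * n * se^2)
}

#' Instrument-strength F statistic
#'
#' `F = R2 * (N - 2) / (1 - R2)`. With the cumulative R-squared of the
#' selected instrument set this is the set-level strength measure; per-variant
#' R-squared gives the per-variant F. Instruments are conventionally retained
#' when `F > 10`.
#'
#' @param r2 Explained variance, in `[0, 1)`.
#' @param n Sample size (> 2).
#' @return F statistic (vectorized).
#' @export
f_statistic <- function(r2, n) {
  if (any(r2 < 0 | r2 >= 1)) stop("f_statistic: r2 must lie in [0, 1)")
  if (any(n <= 2)) stop("f_statistic: n must exceed 2")
  r2 * (n - 2) / (1 - r2)
}

#' Strength filter on instruments
#'
#' Drops variants whose per-variant F statistic (from [explained_variance()]
#' and [f_statistic()]) is at or below `f_min`. Records with missing EAF are
#' dropped and counted, never imputed.
#'
#' @param table A `summary_table`.
#' @param f_min Minimum F (strict; default 10).
#' @return Filtered `summary_table` with a `"strength_summary"` attribute.
#' @export
filter_strength <- function(table, f_min = 10) {
  stopifnot(inherits(table, "summary_table"))
  has_eaf <- !is.na(table$eaf)
  f <- rep(NA_real_, nrow(table))
  if (any(has_eaf))
    f[has_eaf] <- f_statistic(explained_variance(table[has_eaf, , drop = FALSE]),
                              table$n[has_eaf])
  keep <- has_eaf & f > f_min
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "strength_summary") <- list(n_input = nrow(table),
                                        n_kept = sum(keep),
                                        n_weak = sum(has_eaf & !(f > f_min)),
                                        n_missing_eaf = sum(!has_eaf))
  out
}

.complement <- c(A = "T", T = "A", C = "G", G = "C")

.is_palindromic <- function(ea, oa) .complement[ea] == oa

#' Harmonize exposure and outcome effects onto a common effect allele
#'
#' For each exposure instrument found in the outcome table (directly, or via
#' a proxy with r-squared at least `proxy_r2_min`):
#' \itemize{
#'   \item identical allele pair: kept as-is;
#'   \item swapped alleles: outcome beta negated, outcome EAF complemented;
#'   \item strand flip (allele complements): complemented, then the two rules
#'     above apply;
#'   \item palindromic variants (A/T or C/G; strand flips are undetectable
#'     from alleles): retained only when both studies' effect-allele
#'     frequencies lie on the same side of 0.5 and both minor-allele
#'     frequencies are below `maf_threshold`; otherwise dropped as ambiguous;
#'   \item instruments absent from the outcome with no eligible proxy are
#'     dropped.
#' }
#' Every input instrument is accounted for in the audit: retained + dropped
#' ambiguous + dropped missing + dropped incompatible equals the input count.
#'
#' @param exposure Instrument-filtered `summary_table` for the exposure.
#' @param outcome `summary_table` for the outcome.
#' @param maf_threshold Palindrome-inference MAF threshold (default 0.3).
#' @param proxy_table Optional data.frame `(iv_id, proxy_id, r2, ea_map,
#'   oa_map)`: `proxy_id` is looked up in the outcome, with `ea_map` the
#'   proxy allele tagging the instrument's effect allele.
#' @param proxy_r2_min Minimum proxy r-squared (default 0.8).
#' @return A `harmonized_set`: data.frame with columns `variant_id`,
#'   `beta_exp`, `se_exp`, `beta_out`, `se_out`, `eaf_exp`, `eaf_out`,
#'   `palindromic`, `proxy_of`, plus `exposure_label`, `outcome_label` and
#'   `audit` attributes.
#' @export
harmonize <- function(exposure, outcome, maf_threshold = 0.3,
                      proxy_table = NULL, proxy_r2_min = 0.8) {
  stopifnot(inherits(exposure, "summary_table"),
            inherits(outcome, "summary_table"))
  if (anyDuplicated(exposure$variant_id) || anyDuplicated(outcome$variant_id))
    stop("harmonize: duplicate variant_id in input table")
  audit <- list(n_input = nrow(exposure), n_retained = 0L, n_flipped = 0L,
                n_strand_corrected = 0L, n_ambiguous = 0L, n_missing = 0L,
                n_incompatible = 0L, n_proxied = 0L)
  out_idx <- match(exposure$variant_id, outcome$variant_id)
  rows <- vector("list", nrow(exposure))
  for (i in seq_len(nrow(exposure))) {
    ev <- exposure[i, ]
    proxy_of <- NA_character_
    if (is.na(out_idx[i])) {
      ov <- NULL
      if (!is.null(proxy_table)) {
        cand <- proxy_table[proxy_table$iv_id == ev$variant_id &
                              proxy_table$r2 >= proxy_r2_min, , drop = FALSE]
        cand <- cand[cand$proxy_id %in% outcome$variant_id, , drop = FALSE]
        if (nrow(cand) > 0) {
          cand <- cand[order(-cand$r2, cand$proxy_id), , drop = FALSE]
          ov <- outcome[match(cand$proxy_id[1], outcome$variant_id), ]
          # express the proxy's alleles in instrument-allele space
          map <- c(toupper(cand$ea_map[1]), toupper(cand$oa_map[1]))
          if (ov$effect_allele == map[1] && ov$other_allele == map[2]) {
            ov$effect_allele <- ev$effect_allele
            ov$other_allele <- ev$other_allele
          } else if (ov$effect_allele == map[2] && ov$other_allele == map[1]) {
            ov$effect_allele <- ev$other_allele
            ov$other_allele <- ev$effect_allele
          } else ov <- NULL
          if (!is.null(ov)) proxy_of <- cand$proxy_id[1]
        }
      }
      if (is.null(ov)) { audit$n_missing <- audit$n_missing + 1L; next }
    } else ov <- outcome[out_idx[i], ]

    pal <- .is_palindromic(ev$effect_allele, ev$other_allele)
    b_out <- ov$beta; eaf_out <- ov$eaf
    if (pal) {
      # strand cannot be resolved from alleles; infer orientation from EAF
      ok <- !is.na(ev$eaf) && !is.na(eaf_out) &&
        pmin(ev$eaf, 1 - ev$eaf) < maf_threshold &&
        pmin(eaf_out, 1 - eaf_out) < maf_threshold &&
        sign(ev$eaf - 0.5) == sign(eaf_out - 0.5)
      if (!ok) { audit$n_ambiguous <- audit$n_ambiguous + 1L; next }
    } else {
      oa <- c(ov$effect_allele, ov$other_allele)
      ea <- c(ev$effect_allele, ev$other_allele)
      if (identical(oa, ea)) {
        # aligned
      } else if (identical(oa, rev(ea))) {
        b_out <- -b_out
        if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
        audit$n_flipped <- audit$n_flipped + 1L
      } else {
        oc <- unname(.complement[oa])
        if (identical(oc, ea)) {
          audit$n_strand_corrected <- audit$n_strand_corrected + 1L
        } else if (identical(oc, rev(ea))) {
          b_out <- -b_out
          if (!is.na(eaf_out)) eaf_out <- 1 - eaf_out
          audit$n_strand_corrected <- audit$n_strand_corrected + 1L
          audit$n_flipped <- audit$n_flipped + 1L
        } else { audit$n_incompatible <- audit$n_incompatible + 1L; next }
      }
    }
    if (!is.na(proxy_of)) audit$n_proxied <- audit$n_proxied + 1L
    rows[[i]] <- data.frame(variant_id = ev$variant_id,
                            beta_exp = ev$beta, se_exp = ev$se,
                            beta_out = b_out, se_out = ov$se,
                            eaf_exp = ev$eaf, eaf_out = eaf_out,
                            palindromic = pal, proxy_of = proxy_of,
                            stringsAsFactors = FALSE)
  }
  pairs <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(pairs))
    pairs <- data.frame(variant_id = character(0), beta_exp = numeric(0),
                        se_exp = numeric(0), beta_out = numeric(0),
                        se_out = numeric(0), eaf_exp = numeric(0),
                        eaf_out = numeric(0), palindromic = logical(0),
                        proxy_of = character(0), stringsAsFactors = FALSE)
  audit$n_retained <- nrow(pairs)
  rownames(pairs) <- NULL
  structure(pairs,
            exposure_label = attr(exposure, "trait_label"),
            outcome_label = attr(outcome, "trait_label"),
            audit = audit,
            class = c("harmonized_set", "data.frame"))
}

#' Assemble a harmonized set directly from aligned effect pairs
#'
#' Convenience constructor used by simulations and tests when exposure and
#' outcome effects are already expressed on a common effect allele.
#'
#' @param variant_id,beta_exp,se_exp,beta_out,se_out Per-variant vectors.
#' @param eaf_exp,eaf_out Optional effect-allele frequencies.
#' @param exposure_label,outcome_label Metadata.
#' @return A `harmonized_set`.
#' @export
harmonized_set <- function(variant_id, beta_exp, se_exp, beta_out, se_out,
                           eaf_exp = NA_real_, eaf_out = NA_real_,
                           exposure_label = "exposure",
                           outcome_label = "outcome") {
  stopifnot(all(se_exp > 0), all(se_out > 0))
  if (anyDuplicated(variant_id)) stop("harmonized_set: duplicate variant_id")
  pairs <- data.frame(variant_id = as.character(variant_id),
                      beta_exp = beta_exp, se_exp = se_exp,
                      beta_out = beta_out, se_out = se_out,
                      eaf_exp = eaf_exp, eaf_out = eaf_out,
                      palindromic = FALSE, proxy_of = NA_character_,
                      stringsAsFactors = FALSE)
  structure(pairs, exposure_label = exposure_label,
            outcome_label = outcome_label,
            audit = list(n_input = nrow(pairs), n_retained = nrow(pairs),
                         n_flipped = 0L, n_strand_corrected = 0L,
                         n_ambiguous = 0L, n_missing = 0L,
                         n_incompatible = 0L, n_proxied = 0L),
            class = c("harmonized_set", "data.frame"))
}

#' @export
print.harmonized_set <- function(x, ...) {
  cat("Harmonized MR instrument set: ", attr(x, "exposure_label"), " -> ",
      attr(x, "outcome_label"), "\n", sep = "")
  a <- attr(x, "audit")
  cat("  ", nrow(x), " pairs retained of ", a$n_input, " instruments (",
      a$n_flipped, " flipped, ", a$n_ambiguous, " ambiguous, ",
      a$n_missing, " missing, ", a$n_proxied, " via proxy)\n", sep = "")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}
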