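# Synthetic GWAS summary-data generator with known ground truth.
#
# Emulates the statistical structure a two-sample MR analysis assumes: true
# instrument effects on the exposure, a causal effect theta carrying them to
# the outcome, optional horizontal pleiotropy (balanced, directional, or
# correlated with instrument strength, i.e. InSIDE-violating), LD-block
# structure, palindromic alleles, and planted outliers.

#' Simulation configuration
#'
#' Defaults describe the regime two-sample MR presumes: a large exposure
#' GWAS (`n_exp = 3e5`, biobank scale) against a considerably smaller
#' disease outcome GWAS (`n_out = 2.5e4`, case-control scale), so
#' outcome-side noise dominates the ratio estimates — the condition under
#' which first-order inverse-variance weights are appropriate. Instrument
#' effects around 0.08 on the log-odds scale give exposure z-scores near 28,
#' so true instruments clear the genome-wide p < 5e-8 filter and the F > 10
#' strength filter by construction.
#'
#' @param n_variants Total variants per table.
#' @param n_instruments Number of true instruments (gamma != 0).
#' @param theta True causal effect, log-odds scale.
#' @param pleiotropy_mode `"none"`, `"balanced"`, `"directional"` or
#'   `"inside_violated"` (direct effects correlated 0.5 with instrument
#'   strength).
#' @param pleio_mean,pleio_sd Mean and SD of the direct (pleiotropic)
#'   effects where applicable.
#' @param pleio_fraction Fraction of instruments carrying a pleiotropic
#'   effect (default 1).
#' @param gamma_mean,gamma_sd Distribution of true instrument effects.
#' @param n_exp,n_out GWAS sample sizes; per-variant SEs follow the standard
#'   approximation `se = 1/sqrt(2 N eaf (1-eaf))`.
#' @param maf_low,maf_high Minor-allele-frequency range.
#' @param ld_blocks Optional list of `c(size, r2)` pairs; block members get
#'   correlated summary statistics and positions inside the clumping window.
#' @param palindromic_fraction Fraction of variants given A/T or C/G allele
#'   pairs.
#' @param swap_fraction Fraction of outcome records stored with effect/other
#'   alleles swapped (beta negated, EAF complemented) — a pure
#'   representation change that harmonization must undo.
#' @param outlier_ids Variant ids whose outcome effect is displaced by
#'   `10 * se_out` (planted pleiotropic outliers).
#' @param seed Mandatory RNG seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_variants = 200, n_instruments = 50, theta = 0.7,
                       pleiotropy_mode = c("none", "balanced", "directional",
                                           "inside_violated"),
                       pleio_mean = 0.1, pleio_sd = 0.05,
                       pleio_fraction = 1,
                       gamma_mean = 0.08, gamma_sd = 0.02,
                       n_exp = 3e5, n_out = 2.5e4,
                       maf_low = 0.1, maf_high = 0.5,
                       ld_blocks = NULL, palindromic_fraction = 0,
                       swap_fraction = 0.2, outlier_ids = character(0),
                       seed) {
  pleiotropy_mode <- match.arg(pleiotropy_mode)
  if (missing(seed)) stop("sim_config: a seed is mandatory")
  stopifnot(n_instruments <= n_variants, maf_low > 0, maf_high <= 0.5,
            pleio_fraction >= 0, pleio_fraction <= 1,
            palindromic_fraction >= 0, palindromic_fraction <= 1)
  structure(list(n_variants = n_variants, n_instruments = n_instruments,
                 theta = theta, pleiotropy_mode = pleiotropy_mode,
                 pleio_mean = pleio_mean, pleio_sd = pleio_sd,
                 pleio_fraction = pleio_fraction,
                 gamma_mean = gamma_mean, gamma_sd = gamma_sd,
                 n_exp = n_exp, n_out = n_out,
                 maf_low = maf_low, maf_high = maf_high,
                 ld_blocks = ld_blocks,
                 palindromic_fraction = palindromic_fraction,
                 swap_fraction = swap_fraction,
                 outlier_ids = as.character(outlier_ids), seed = seed),
            class = "sim_config")
}

#' Simulate a paired exposure/outcome summary-statistics set
#'
#' Draws true instrument effects `gamma_j ~ N(gamma_mean, gamma_sd)` and
#' direct effects `alpha_j` per the pleiotropy mode, then observed effects
#' `beta_exp_j ~ N(gamma_j, se_exp_j)` and
#' `beta_out_j ~ N(theta gamma_j + alpha_j, se_out_j)`, with SEs from the
#' standard `1/sqrt(2 N eaf (1-eaf))` scaling. Non-instruments have
#' `gamma = 0`. LD blocks share a common noise factor (loading `sqrt(r2)`)
#' and tag the block head's effect attenuated by `sqrt(r2)`, producing
#' correlated p-values; block members sit within the clumping window on two
#' synthetic chromosomes. Variants in `outlier_ids` have `10 * se_out` added
#' to their outcome effect. Identical config and seed give byte-identical
#' output.
#'
#' @param config A [sim_config()].
#' @return List: `exposure` and `outcome` ([summary_table()]s), `truth`
#'   (per-variant gamma, alpha, instrument/outlier flags; `theta` and the
#'   config as attributes), `ld` (block-structured r-squared matrix).
#' @export
simulate_pair <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cf <- config
  withr_seed(cf$seed, {
    nv <- cf$n_variants
    ids <- sprintf("rs%06d", seq_len(nv))

    # block assignment: configured blocks first, then singletons
    sizes <- if (is.null(cf$ld_blocks)) integer(0)
             else vapply(cf$ld_blocks, `[`, numeric(1), 1)
    r2s <- if (is.null(cf$ld_blocks)) numeric(0)
           else vapply(cf$ld_blocks, `[`, numeric(1), 2)
    n_in_blocks <- sum(sizes)
    if (n_in_blocks > nv) stop("simulate_pair: LD blocks exceed n_variants")
    singles <- if (n_in_blocks < nv)
      seq.int(n_in_blocks + 1, nv) + 1000L else integer(0)
    block_id <- c(rep(seq_along(sizes), times = sizes), singles)
    block_r2 <- c(r2s, rep(0, length(singles)))
    head_of_block <- !duplicated(block_id)

    # layout: alternate blocks over 2 chromosomes, members 100 kb apart,
    # 20 Mb between consecutive blocks on a chromosome
    ublocks <- unique(block_id)
    chrom_of <- rep(c("1", "2"), length.out = length(ublocks))
    start_of <- stats::setNames(numeric(length(ublocks)), ublocks)
    nxt <- c(`1` = 1e6, `2` = 1e6)
    for (k in seq_along(ublocks)) {
      start_of[k] <- nxt[chrom_of[k]]
      nxt[chrom_of[k]] <- nxt[chrom_of[k]] + 2e7
    }
    chrom <- chrom_of[match(block_id, ublocks)]
    within <- stats::ave(seq_len(nv), block_id, FUN = seq_along) - 1
    pos <- start_of[match(block_id, ublocks)] + within * 1e5

    # alleles and frequencies
    maf <- stats::runif(nv, cf$maf_low, cf$maf_high)
    eaf <- ifelse(stats::runif(nv) < 0.5, maf, 1 - maf)
    pal <- stats::runif(nv) < cf$palindromic_fraction
    pal_pairs <- list(c("A", "T"), c("T", "A"), c("C", "G"), c("G", "C"))
    npal_pairs <- list(c("A", "G"), c("A", "C"), c("G", "A"), c("G", "T"),
                       c("C", "A"), c("C", "T"), c("T", "G"), c("T", "C"))
    pick <- function(pool, n) pool[sample.int(length(pool), n, replace = TRUE)]
    alleles <- vector("list", nv)
    alleles[pal] <- pick(pal_pairs, sum(pal))
    alleles[!pal] <- pick(npal_pairs, sum(!pal))
    ea <- vapply(alleles, `[`, character(1), 1)
    oa <- vapply(alleles, `[`, character(1), 2)

    se_exp <- 1 / sqrt(2 * cf$n_exp * eaf * (1 - eaf))
    se_out <- 1 / sqrt(2 * cf$n_out * eaf * (1 - eaf))

    # truth: instruments are the heads of the first blocks (then singletons)
    inst <- rep(FALSE, nv)
    inst[which(head_of_block)[seq_len(min(cf$n_instruments,
                                          sum(head_of_block)))]] <- TRUE
    gamma <- rep(0, nv)
    gamma[inst] <- stats::rnorm(sum(inst), cf$gamma_mean, cf$gamma_sd)
    # tag effects within instrument-headed blocks, attenuated by sqrt(r2)
    r2v <- block_r2[match(block_id, ublocks)]
    r2v[is.na(r2v)] <- 0
    for (b in ublocks[ublocks <= 1000L]) {
      members <- which(block_id == b)
      h <- members[1]
      if (length(members) > 1 && gamma[h] != 0)
        gamma[members[-1]] <- sqrt(r2v[members[-1]]) * gamma[h]
    }

    alpha <- rep(0, nv)
    w_inst <- which(inst)
    if (cf$pleiotropy_mode != "none" && length(w_inst) > 0) {
      n_pl <- round(cf$pleio_fraction * length(w_inst))
      pl <- w_inst[seq_len(n_pl)]
      if (cf$pleiotropy_mode == "balanced") {
        alpha[pl] <- stats::rnorm(n_pl, 0, cf$pleio_sd)
      } else if (cf$pleiotropy_mode == "directional") {
        alpha[pl] <- stats::rnorm(n_pl, cf$pleio_mean, cf$pleio_sd)
      } else { # inside_violated: corr(gamma, alpha) = 0.5
        zg <- (gamma[pl] - cf$gamma_mean) / cf$gamma_sd
        alpha[pl] <- cf$pleio_mean +
          cf$pleio_sd * (0.5 * zg + sqrt(0.75) * stats::rnorm(n_pl))
      }
    }

    # correlated noise within blocks (shared factor, loading sqrt(r2))
    block_noise_e <- stats::rnorm(length(ublocks))
    block_noise_o <- stats::rnorm(length(ublocks))
    bi <- match(block_id, ublocks)
    ze <- sqrt(r2v) * block_noise_e[bi] +
      sqrt(1 - r2v) * stats::rnorm(nv)
    zo <- sqrt(r2v) * block_noise_o[bi] +
      sqrt(1 - r2v) * stats::rnorm(nv)

    beta_exp <- gamma + se_exp * ze
    beta_out <- cf$theta * gamma + alpha + se_out * zo
    outlier <- ids %in% cf$outlier_ids
    beta_out[outlier] <- beta_out[outlier] + 10 * se_out[outlier]

    p_exp <- 2 * stats::pnorm(-abs(beta_exp / se_exp))
    p_out <- 2 * stats::pnorm(-abs(beta_out / se_out))
    p_exp <- pmax(p_exp, .Machine$double.xmin)
    p_out <- pmax(p_out, .Machine$double.xmin)

    exposure <- summary_table(data.frame(
      variant_id = ids, chrom = chrom, pos = pos,
      effect_allele = ea, other_allele = oa, eaf = eaf,
      beta = beta_exp, se = se_exp, pval = p_exp, n = cf$n_exp,
      stringsAsFactors = FALSE), trait_label = "synthetic_exposure",
      ancestry_label = "synthetic")

    # outcome: a fraction of records stored with alleles swapped
    swap <- stats::runif(nv) < cf$swap_fraction & !pal
    out_df <- data.frame(
      variant_id = ids, chrom = chrom, pos = pos,
      effect_allele = ifelse(swap, oa, ea),
      other_allele = ifelse(swap, ea, oa),
      eaf = ifelse(swap, 1 - eaf, eaf),
      beta = ifelse(swap, -beta_out, beta_out),
      se = se_out, pval = p_out, n = cf$n_out,
      stringsAsFactors = FALSE)
    outcome <- summary_table(out_df, trait_label = "synthetic_outcome",
                             ancestry_label = "synthetic")

    # LD matrix: within-block entries at the block r2, else 0
    ld <- diag(1, nv)
    dimnames(ld) <- list(ids, ids)
    for (b in ublocks[ublocks <= 1000L]) {
      members <- which(block_id == b)
      if (length(members) > 1) {
        r <- block_r2[match(b, ublocks)]
        ld[members, members] <- r
        diag(ld)[members] <- 1
      }
    }
    diag(ld) <- 1

    truth <- data.frame(variant_id = ids, gamma = gamma, alpha = alpha,
                        instrument = inst, outlier = outlier,
                        stringsAsFactors = FALSE)
    attr(truth, "theta") <- cf$theta
    attr(truth, "config") <- cf
    list(exposure = exposure, outcome = outcome, truth = truth, ld = ld)
  })
}

# Default sequence-class labels, Sei-style (40 classes).
.seq_class_labels <- c(
  paste0("PC", 1:4), paste0("L", 1:8), paste0("E", 1:12),
  paste0("TF", 1:5), "CTCF", "P", paste0("HET", 1:5), paste0("TN", 1:4))

#' Simulate a sequence-class score table
#'
#' Background scores drawn from `N(0, 0.1)`; spiked entries are set exactly,
#' so downstream max-absolute summaries and top-class labels are known by
#' construction. Deterministic under the seed.
#'
#' @param variant_ids Character vector of variants to score.
#' @param n_classes Number of score columns (default 40).
#' @param spike_spec Optional named list `variant_id -> list(class, value)`
#'   (or a list of such with multiple entries per variant).
#' @param seed Mandatory RNG seed.
#' @return Data.frame: `variant_id` plus `n_classes` named numeric columns.
#' @export
simulate_seq_class_table <- function(variant_ids, n_classes = 40,
                                     spike_spec = NULL, seed) {
  if (missing(seed)) stop("simulate_seq_class_table: a seed is mandatory")
  labels <- if (n_classes == 40) .seq_class_labels
            else paste0("SC", seq_len(n_classes))
  withr_seed(seed, {
    m <- matrix(stats::rnorm(length(variant_ids) * n_classes, 0, 0.1),
                nrow = length(variant_ids), ncol = n_classes)
    colnames(m) <- labels
    rownames(m) <- variant_ids
    if (!is.null(spike_spec)) {
      for (v in names(spike_spec)) {
        sp <- spike_spec[[v]]
        cl <- as.character(sp[[1]])
        if (!cl %in% labels)
          stop("simulate_seq_class_table: unknown class '", cl, "'")
        if (!v %in% variant_ids)
          stop("simulate_seq_class_table: unknown variant '", v, "'")
        m[v, cl] <- as.numeric(sp[[2]])
      }
    }
    data.frame(variant_id = variant_ids, m, stringsAsFactors = FALSE,
               row.names = NULL, check.names = FALSE)
  })
}
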