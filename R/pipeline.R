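# End-to-end experiment orchestration: selection -> harmonization -> the
# estimator suite -> diagnostics -> (conditional) MR-PRESSO -> outputs, with
# a reproducible run manifest.

#' Run configuration for a full MR experiment
#'
#' Inputs may be file paths (read through [read_summary_stats()] /
#' [read_ld_matrix()]) or in-memory objects. All thresholds default to the
#' conventional values: genome-wide significance 5e-8, clumping r2 0.01 in a
#' 5,000-kb window, palindrome-inference MAF 0.3, proxy r2 0.8, instrument
#' strength F > 10, significance level 0.05.
#'
#' @param exposure,outcome `summary_table`s or file paths.
#' @param exposure_dialect,outcome_dialect Dialects for path inputs.
#' @param ld LD matrix or path (square TSV or long triples).
#' @param proxy_table Optional proxy data.frame or path.
#' @param p_threshold,clump_r2,window_kb,maf_threshold,proxy_r2,f_min,alpha
#'   Pipeline thresholds.
#' @param presso_mode `"auto"` runs MR-PRESSO only when the Egger intercept
#'   p-value falls below `alpha`; `"always"` and `"never"` override.
#' @param presso_n_sim,n_boot Simulation sizes.
#' @param seed Mandatory seed governing every stochastic step.
#' @param output_dir Where result tables and the manifest are written.
#' @return A `mr_run_config` list.
#' @export
mr_run_config <- function(exposure, outcome, ld = NULL, proxy_table = NULL,
                          exposure_dialect = "generic",
                          outcome_dialect = "generic",
                          p_threshold = 5e-8, clump_r2 = 0.01,
                          window_kb = 5000, maf_threshold = 0.3,
                          proxy_r2 = 0.8, f_min = 10, alpha = 0.05,
                          presso_mode = c("auto", "always", "never"),
                          presso_n_sim = 1000, n_boot = 1000,
                          seed, output_dir) {
  presso_mode <- match.arg(presso_mode)
  if (missing(seed)) stop("mr_run_config: a seed is mandatory")
  if (missing(output_dir)) stop("mr_run_config: output_dir is required")
  stopifnot(p_threshold > 0, clump_r2 > 0, window_kb > 0, maf_threshold > 0,
            proxy_r2 > 0, f_min > 0, alpha > 0)
  structure(list(exposure = exposure, outcome = outcome, ld = ld,
                 proxy_table = proxy_table,
                 exposure_dialect = exposure_dialect,
                 outcome_dialect = outcome_dialect,
                 p_threshold = p_threshold, clump_r2 = clump_r2,
                 window_kb = window_kb, maf_threshold = maf_threshold,
                 proxy_r2 = proxy_r2, f_min = f_min, alpha = alpha,
                 presso_mode = presso_mode, presso_n_sim = presso_n_sim,
                 n_boot = n_boot, seed = seed, output_dir = output_dir),
            class = "mr_run_config")
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run one complete MR experiment
#'
#' Executes significance filtering, LD clumping, instrument-strength
#' filtering, harmonization, the five-estimator suite, Cochran's Q for both
#' models, the Egger intercept test, MR-PRESSO (when triggered by the
#' intercept p-value, or forced), single-SNP and leave-one-out analyses and
#' the plot data products. All tables are written to the configured output
#' directory (`ivs.tsv`, `harmonized.tsv`, `mr_results.tsv`,
#' `heterogeneity.tsv`, `pleiotropy.tsv`, `presso.json`, `single_snp.tsv`,
#' `loo.tsv`, `scatter.tsv`, `funnel.tsv`) together with `manifest.json`
#' echoing every threshold, the seed and per-stage variant counts. Identical
#' config and seed reproduce identical outputs.
#'
#' @param config An [mr_run_config()].
#' @return Invisibly, a list with the fitted objects, tables and manifest.
#' @export
run_mr_experiment <- function(config) {
  stopifnot(inherits(config, "mr_run_config"))
  cf <- config
  dir.create(cf$output_dir, showWarnings = FALSE, recursive = TRUE)

  exposure <- .stage("read_exposure",
    if (is.character(cf$exposure))
      read_summary_stats(cf$exposure, dialect = cf$exposure_dialect)
    else cf$exposure)
  outcome <- .stage("read_outcome",
    if (is.character(cf$outcome))
      read_summary_stats(cf$outcome, dialect = cf$outcome_dialect)
    else cf$outcome)
  ld <- .stage("read_ld",
    if (is.character(cf$ld)) read_ld_matrix(cf$ld) else cf$ld)
  proxies <- .stage("read_proxies",
    if (is.character(cf$proxy_table))
      utils::read.table(cf$proxy_table, header = TRUE, sep = "\t",
                        stringsAsFactors = FALSE)
    else cf$proxy_table)

  counts <- list(exposure_variants = nrow(exposure),
                 outcome_variants = nrow(outcome))

  sig <- .stage("filter_genome_wide",
                filter_genome_wide(exposure, cf$p_threshold))
  counts$genome_wide_significant <- nrow(sig)
  clumped <- .stage("clump",
    if (is.null(ld)) sig
    else clump(sig, ld, window_kb = cf$window_kb, r2_threshold = cf$clump_r2))
  counts$after_clumping <- nrow(clumped)
  strong <- .stage("filter_strength", filter_strength(clumped, cf$f_min))
  counts$strong_instruments <- nrow(strong)
  if (nrow(strong) == 0)
    stop("pipeline: empty instrument set after filters", call. = FALSE)

  hset <- .stage("harmonize",
                 harmonize(strong, outcome, maf_threshold = cf$maf_threshold,
                           proxy_table = proxies,
                           proxy_r2_min = cf$proxy_r2))
  counts$harmonized_pairs <- nrow(hset)
  if (nrow(hset) < 3)
    stop("pipeline: fewer than 3 harmonized pairs", call. = FALSE)

  fit <- .stage("mr_fit",
                mr_fit(hset, seed = cf$seed, n_boot = cf$n_boot,
                       alpha = cf$alpha))
  intercept <- fit$pleiotropy
  run_presso <- cf$presso_mode == "always" ||
    (cf$presso_mode == "auto" && intercept$pval < cf$alpha)
  presso <- NULL
  if (run_presso && nrow(hset) >= 4)
    presso <- .stage("mr_presso",
                     mr_presso(hset, n_sim = cf$presso_n_sim,
                               seed = cf$seed + 10L, alpha = cf$alpha))
  ss <- .stage("single_snp", single_snp(hset))
  loo <- .stage("leave_one_out", leave_one_out(hset, alpha = cf$alpha))
  pd <- .stage("plot_data", plot_data(hset, fit, loo = loo))

  od <- cf$output_dir
  write_table(as.data.frame(strong), file.path(od, "ivs.tsv"))
  write_table(as.data.frame(hset), file.path(od, "harmonized.tsv"))
  write_table(fit$results, file.path(od, "mr_results.tsv"))
  write_table(fit$heterogeneity, file.path(od, "heterogeneity.tsv"))
  write_table(fit$pleiotropy, file.path(od, "pleiotropy.tsv"))
  write_table(ss, file.path(od, "single_snp.tsv"))
  write_table(loo, file.path(od, "loo.tsv"))
  write_table(pd$scatter, file.path(od, "scatter.tsv"))
  write_table(pd$funnel, file.path(od, "funnel.tsv"))
  if (!is.null(presso)) {
    pj <- list(rss_obs = presso$rss_obs, global_p = presso$global_p,
               per_snp_p = as.list(presso$per_snp_p),
               outliers = presso$outliers,
               distortion_p = presso$distortion_p,
               corrected = as.list(presso$corrected),
               n_sim = presso$n_sim, seed = presso$seed)
    jsonlite::write_json(pj, file.path(od, "presso.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         na = "null", pretty = TRUE)
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("tsmr")),
    thresholds = cf[c("p_threshold", "clump_r2", "window_kb",
                      "maf_threshold", "proxy_r2", "f_min", "alpha")],
    presso_mode = cf$presso_mode, presso_n_sim = cf$presso_n_sim,
    n_boot = cf$n_boot, seed = cf$seed,
    exposure_label = attr(exposure, "trait_label"),
    outcome_label = attr(outcome, "trait_label"),
    stage_counts = counts,
    harmonization_audit = attr(hset, "audit"),
    presso_ran = !is.null(presso),
    consistent = fit$consistent, significant = fit$significant,
    output_files = sort(setdiff(list.files(od), "manifest.json")))
  manifest$output_md5 <- as.list(
    tools::md5sum(file.path(od, manifest$output_files)))
  names(manifest$output_md5) <- manifest$output_files
  jsonlite::write_json(manifest, file.path(od, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  invisible(list(instruments = strong, hset = hset, fit = fit,
                 presso = presso, single_snp = ss, loo = loo,
                 plot_data = pd, manifest = manifest))
}

#' Prioritize functional variants across completed runs
#'
#' Merges the instrument sets of one or more completed experiments (their
#' output directories, read back from `single_snp.tsv`), attaches b scores
#' and sequence-class scores, applies the threshold filter and writes the
#' ranked table (`prioritized.tsv`) and the long-format variant-by-class
#' heatmap table (`heatmap.tsv`).
#'
#' @param run_dirs Named character vector of completed run directories.
#' @param seq_class_table Score table (data.frame or TSV path; `variant_id`
#'   plus 40 class columns).
#' @param sei_min,b_min,top_k Selection parameters (see
#'   [select_functional()]).
#' @param output_dir Output directory.
#' @return Invisibly, list with `merged`, `scores`, `selected`.
#' @export
run_prioritization <- function(run_dirs, seq_class_table, sei_min = 1.0,
                               b_min = 0.5, top_k = NULL, output_dir) {
  stopifnot(length(run_dirs) >= 1, !is.null(names(run_dirs)))
  if (is.character(seq_class_table))
    seq_class_table <- utils::read.table(seq_class_table, header = TRUE,
                                         sep = "\t", check.names = FALSE,
                                         stringsAsFactors = FALSE)
  ss_tables <- lapply(run_dirs, function(d) {
    p <- file.path(d, "single_snp.tsv")
    if (!file.exists(p))
      stop("run_prioritization: missing single-SNP table for run '",
           names(run_dirs)[run_dirs == d][1], "' (", p, ")")
    utils::read.table(p, header = TRUE, sep = "\t",
                      stringsAsFactors = FALSE)
  })
  merged <- merge_iv_sets(lapply(ss_tables, `[[`, "variant_id"))
  scores <- attach_scores(merged, ss_tables, seq_class_table)
  selected <- select_functional(scores, sei_min = sei_min, b_min = b_min,
                                top_k = top_k)
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  write_table(selected, file.path(output_dir, "prioritized.tsv"))
  write_table(scores, file.path(output_dir, "variant_scores.tsv"))
  if (nrow(selected) > 0)
    write_table(heatmap_table(seq_class_table, selected$variant_id),
                file.path(output_dir, "heatmap.tsv"))
  invisible(list(merged = merged, scores = scores, selected = selected))
}
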