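# Functional instrument-variant prioritization: merge IV sets across
# experiments, attach b scores (single-SNP Wald betas) and sequence-class
# perturbation scores, filter and rank.

#' Merge instrument sets across experiments
#'
#' Union of variant ids with per-variant provenance; duplicates collapse and
#' accumulate the labels of every contributing experiment.
#'
#' @param sets Named list of character vectors of variant ids.
#' @return Data.frame `variant_id`, `sources` (comma-separated labels),
#'   `n_sources`, ordered by variant id.
#' @export
merge_iv_sets <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 1, !is.null(names(sets)))
  long <- data.frame(
    variant_id = unlist(sets, use.names = FALSE),
    source = rep(names(sets), lengths(sets)),
    stringsAsFactors = FALSE)
  ids <- sort(unique(long$variant_id))
  src <- vapply(ids, function(v)
    paste(unique(long$source[long$variant_id == v]), collapse = ","),
    character(1))
  data.frame(variant_id = ids, sources = unname(src),
             n_sources = vapply(strsplit(src, ","), length, integer(1)),
             stringsAsFactors = FALSE)
}

#' Attach b scores and sequence-class scores to merged instruments
#'
#' The b score of a variant is its single-SNP Wald beta; a variant selected
#' in several experiments takes the beta of largest absolute value, sign
#' preserved. The sequence-class (Sei-style) score is the maximum absolute
#' value across the 40 per-class scores, with the class attaining it
#' recorded. Variants absent from the score table are kept but flagged
#' unscored.
#'
#' @param merged Output of [merge_iv_sets()].
#' @param single_snp_tables Named list (per experiment, names matching the
#'   merge labels) of [single_snp()] tables (columns `variant_id`, `beta`).
#' @param seq_class_table Data.frame: first column `variant_id`, then exactly
#'   40 numeric class columns.
#' @return Data.frame of variant scores: `variant_id`, `b_score`,
#'   `sei_score`, `top_class`, `sources`, `n_sources`, `scored`.
#' @export
attach_scores <- function(merged, single_snp_tables, seq_class_table) {
  if (ncol(seq_class_table) != 41)
    stop("attach_scores: sequence-class table must have variant_id + 40 ",
         "score columns, got ", ncol(seq_class_table) - 1)
  num_ok <- vapply(seq_class_table[-1], is.numeric, logical(1))
  if (!all(num_ok))
    stop("attach_scores: non-numeric score column at position ",
         which(!num_ok)[1] + 1)
  score_mat <- as.matrix(seq_class_table[, -1, drop = FALSE])
  storage.mode(score_mat) <- "double"
  rownames(score_mat) <- seq_class_table[[1]]
  classes <- colnames(seq_class_table)[-1]

  b_score <- vapply(seq_len(nrow(merged)), function(i) {
    v <- merged$variant_id[i]
    labs <- strsplit(merged$sources[i], ",")[[1]]
    bs <- unlist(lapply(labs, function(l) {
      tab <- single_snp_tables[[l]]
      if (is.null(tab)) return(numeric(0))
      tab$beta[tab$variant_id == v]
    }))
    if (length(bs) == 0) return(NA_real_)
    bs[which.max(abs(bs))]
  }, numeric(1))

  idx <- match(merged$variant_id, rownames(score_mat))
  scored <- !is.na(idx)
  sei <- rep(NA_real_, nrow(merged))
  top <- rep(NA_character_, nrow(merged))
  if (any(scored)) {
    sub <- abs(score_mat[idx[scored], , drop = FALSE])
    k <- apply(sub, 1, which.max)
    sei[scored] <- sub[cbind(seq_len(nrow(sub)), k)]
    top[scored] <- classes[k]
  }
  data.frame(variant_id = merged$variant_id, b_score = b_score,
             sei_score = sei, top_class = top, sources = merged$sources,
             n_sources = merged$n_sources, scored = scored,
             stringsAsFactors = FALSE)
}

#' Threshold-and-rank selection of candidate functional variants
#'
#' Retains variants with sequence-class score strictly above `sei_min` and
#' absolute b score strictly above `b_min`; ranks by sequence-class score
#' descending, then absolute b score descending, then variant id; optionally
#' truncates to the top k. Unscored variants can never be selected. Raising
#' either threshold never adds a variant.
#'
#' @param scores Output of [attach_scores()].
#' @param sei_min Sequence-class score threshold (default 1).
#' @param b_min Absolute b-score threshold (default 0.5).
#' @param top_k Optional cap on the number of returned variants.
#' @return The selected rows of `scores`, ranked.
#' @export
select_functional <- function(scores, sei_min = 1.0, b_min = 0.5,
                              top_k = NULL) {
  stopifnot(nrow(scores) >= 1)
  keep <- !is.na(scores$sei_score) & !is.na(scores$b_score) &
    scores$sei_score > sei_min & abs(scores$b_score) > b_min
  out <- scores[keep, , drop = FALSE]
  out <- out[order(-out$sei_score, -abs(out$b_score), out$variant_id), ,
             drop = FALSE]
  if (!is.null(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Long-format variant-by-class score table (heatmap layout)
#'
#' @param seq_class_table Wide score table (`variant_id` + 40 class columns).
#' @param variant_ids Optional subset/ordering of variants.
#' @return Data.frame `variant_id`, `class`, `score`.
#' @export
heatmap_table <- function(seq_class_table, variant_ids = NULL) {
  ids <- seq_class_table[[1]]
  if (!is.null(variant_ids)) {
    seq_class_table <- seq_class_table[match(variant_ids, ids), ,
                                       drop = FALSE]
    ids <- variant_ids
  }
  classes <- colnames(seq_class_table)[-1]
  data.frame(variant_id = rep(ids, each = length(classes)),
             class = rep(classes, times = length(ids)),
             score = as.vector(t(as.matrix(seq_class_table[, -1]))),
             stringsAsFactors = FALSE)
}
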