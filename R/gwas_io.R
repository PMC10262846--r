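# Reading, validating and writing GWAS summary statistics in delimited text.

# Column synonym tables per dialect. Names are canonical fields; values are the
# header names (first match wins, case-insensitive).
.dialect_columns <- list(
  ieu_flat = list(
    variant_id = c("SNP", "rsid"), chrom = c("chr", "chromosome"),
    pos = c("position", "pos", "bp"),
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = c("eaf", "effect_allele_freq"), beta = "beta", se = "se",
    pval = c("pval", "p"), n = c("samplesize", "n")
  ),
  gwas_ssf = list(
    variant_id = c("rsid", "variant_id"), chrom = "chromosome",
    pos = "base_pair_location",
    effect_allele = "effect_allele", other_allele = "other_allele",
    eaf = "effect_allele_frequency", beta = "beta", se = "standard_error",
    pval = c("p_value", "neg_log10_p_value"), n = c("n", "sample_size")
  ),
  finngen = list(
    variant_id = c("rsids", "rsid"), chrom = c("#chrom", "chrom"),
    pos = "pos",
    effect_allele = "alt", other_allele = "ref",
    eaf = c("af_alt", "maf"), beta = "beta", se = "sebeta",
    pval = "pval", n = c("n", "n_samples")
  ),
  generic = list(
    variant_id = c("SNP", "variant_id", "rsid", "id", "marker"),
    chrom = c("CHR", "chrom", "chromosome"),
    pos = c("POS", "position", "bp", "base_pair_location"),
    effect_allele = c("EA", "effect_allele", "alt", "A1"),
    other_allele = c("OA", "other_allele", "ref", "A2"),
    eaf = c("EAF", "eaf", "freq", "effect_allele_frequency"),
    beta = c("BETA", "beta", "b"),
    se = c("SE", "se", "standard_error"),
    pval = c("P", "pval", "p_value", "pvalue"),
    n = c("N", "n", "samplesize", "sample_size")
  )
)

.required_fields <- c("variant_id", "chrom", "pos", "effect_allele",
                      "other_allele", "eaf", "beta", "se", "pval", "n")

#' Construct a summary-statistics table
#'
#' Bundles per-variant GWAS association records for a single trait into a
#' validated `summary_table` (a `data.frame` with metadata attributes).
#' Coordinates are 1-based; the genome build is metadata only.
#'
#' @param records A data.frame with columns `variant_id`, `chrom`, `pos`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`.
#'   `eaf` may be `NA` (missing frequency is tolerated; downstream steps that
#'   need it reject explicitly).
#' @param trait_label,ancestry_label Free-text metadata.
#' @param n_convention Either `"per_variant"` or `"study_level"`; records
#'   which sample-size convention the source used.
#' @return A `summary_table` object.
#' @export
summary_table <- function(records, trait_label = "trait",
                          ancestry_label = "unspecified",
                          n_convention = "per_variant") {
  records <- as.data.frame(records, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.required_fields, names(records))
  if (length(missing_cols) > 0)
    stop("summary_table: missing column(s): ", paste(missing_cols, collapse = ", "))
  records <- records[, .required_fields]
  records$variant_id <- as.character(records$variant_id)
  records$chrom <- as.character(records$chrom)
  records$effect_allele <- toupper(as.character(records$effect_allele))
  records$other_allele <- toupper(as.character(records$other_allele))
  for (cc in c("pos", "eaf", "beta", "se", "pval", "n"))
    records[[cc]] <- as.numeric(records[[cc]])
  if (anyDuplicated(records$variant_id))
    stop("summary_table: duplicate variant_id: ",
         records$variant_id[duplicated(records$variant_id)][1])
  bad <- !is.finite(records$se) | records$se <= 0 |
    !is.finite(records$pval) | records$pval <= 0 | records$pval > 1 |
    !is.finite(records$beta) |
    records$effect_allele == records$other_allele |
    !records$effect_allele %in% c("A", "C", "G", "T") |
    !records$other_allele %in% c("A", "C", "G", "T")
  if (any(bad))
    stop("summary_table: ", sum(bad), " record(s) violate invariants ",
         "(se>0, 0<pval<=1, valid distinct alleles); first: ",
         records$variant_id[bad][1])
  eaf_bad <- !is.na(records$eaf) & (records$eaf <= 0 | records$eaf >= 1)
  if (any(eaf_bad)) stop("summary_table: eaf outside (0,1) for ",
                         records$variant_id[eaf_bad][1])
  rownames(records) <- NULL
  structure(records,
            trait_label = trait_label, ancestry_label = ancestry_label,
            n_convention = n_convention,
            class = c("summary_table", "data.frame"))
}

#' Read GWAS summary statistics
#'
#' Parses a delimited (tab or comma) summary-statistics file into a
#' [summary_table()]. Column names are resolved through per-dialect synonym
#' tables; an explicit `column_map` always takes precedence. Rows failing
#' type coercion or the record invariants (`se > 0`, `0 < p <= 1`, valid
#' distinct A/C/G/T alleles) are excluded and counted in the parse summary
#' (attribute `"parse_summary"`). P-values of exactly 0 are clamped to the
#' smallest positive normal double, with a clamp count. Alleles are
#' upper-cased; an out-of-range allele frequency is set to missing.
#'
#' @param path Path to the file.
#' @param dialect One of `"generic"`, `"ieu_flat"`, `"gwas_ssf"`,
#'   `"finngen"`. The GWAS-SSF dialect accepts `neg_log10_p_value` and
#'   converts it to a p-value. FinnGen release files carry no sample-size
#'   column; supply one via `column_map` or `n_default`.
#' @param column_map Optional named character vector mapping canonical field
#'   names (`variant_id`, `chrom`, `pos`, `effect_allele`, `other_allele`,
#'   `eaf`, `beta`, `se`, `pval`, `n`) to header names in the file.
#' @param trait_label,ancestry_label,n_convention Metadata passed to
#'   [summary_table()].
#' @param n_default Study-level sample size used when the file has no `n`
#'   column.
#' @return A `summary_table`; attribute `"parse_summary"` holds the counts of
#'   rows read, kept, dropped and p-values clamped.
#' @export
read_summary_stats <- function(path, dialect = c("generic", "ieu_flat",
                                                 "gwas_ssf", "finngen"),
                               column_map = NULL,
                               trait_label = "trait",
                               ancestry_label = "unspecified",
                               n_convention = "per_variant",
                               n_default = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("read_summary_stats: file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0) stop("read_summary_stats: empty file: ", path)
  sep <- if (grepl("\t", first)) "\t" else ","
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "", check.names = FALSE,
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  header <- names(raw)
  syn <- .dialect_columns[[dialect]]
  resolve <- function(field) {
    if (!is.null(column_map) && field %in% names(column_map)) {
      cand <- column_map[[field]]
      if (!cand %in% header)
        stop("read_summary_stats: mapped column '", cand, "' for field '",
             field, "' not present in file")
      return(cand)
    }
    hit <- syn[[field]][tolower(syn[[field]]) %in% tolower(header)]
    if (length(hit) == 0) return(NA_character_)
    header[match(tolower(hit[1]), tolower(header))]
  }
  cols <- vapply(.required_fields, resolve, character(1))
  neglog_p <- FALSE
  if (!is.na(cols[["pval"]]) &&
      tolower(cols[["pval"]]) == "neg_log10_p_value") neglog_p <- TRUE
  if (is.na(cols[["n"]]) && !is.null(n_default)) {
    raw[[".n_default"]] <- as.character(n_default)
    cols[["n"]] <- ".n_default"
    n_convention <- "study_level"
  }
  absent <- .required_fields[is.na(cols)]
  absent <- setdiff(absent, "eaf")  # missing EAF column is tolerated
  if (length(absent) > 0)
    stop("read_summary_stats: cannot resolve required column(s): ",
         paste(absent, collapse = ", "), " (dialect '", dialect,
         "'; supply column_map)")

  df <- data.frame(variant_id = raw[[cols[["variant_id"]]]],
                   chrom = raw[[cols[["chrom"]]]],
                   stringsAsFactors = FALSE)
  num <- function(field) suppressWarnings(as.numeric(raw[[cols[[field]]]]))
  df$pos <- num("pos")
  df$effect_allele <- toupper(raw[[cols[["effect_allele"]]]])
  df$other_allele <- toupper(raw[[cols[["other_allele"]]]])
  df$eaf <- if (is.na(cols[["eaf"]])) NA_real_ else num("eaf")
  df$beta <- num("beta")
  df$se <- num("se")
  df$pval <- num("pval")
  if (neglog_p) df$pval <- 10^(-df$pval)
  df$n <- num("n")

  n_read <- nrow(df)
  clamped <- !is.na(df$pval) & df$pval == 0
  df$pval[clamped] <- .Machine$double.xmin
  if (any(clamped))
    warning("read_summary_stats: ", sum(clamped),
            " zero p-value(s) clamped to the smallest positive normal double")
  df$eaf[!is.na(df$eaf) & (df$eaf <= 0 | df$eaf >= 1)] <- NA_real_
  keep <- is.finite(df$pos) & is.finite(df$beta) &
    is.finite(df$se) & df$se > 0 &
    is.finite(df$pval) & df$pval > 0 & df$pval <= 1 &
    is.finite(df$n) & df$n > 0 &
    df$effect_allele %in% c("A", "C", "G", "T") &
    df$other_allele %in% c("A", "C", "G", "T") &
    df$effect_allele != df$other_allele &
    !is.na(df$variant_id) & nzchar(df$variant_id)
  dropped <- sum(!keep)
  df <- df[keep, , drop = FALSE]
  if (nrow(df) == 0)
    stop("read_summary_stats: zero parsable rows in ", path)
  out <- summary_table(df, trait_label = trait_label,
                       ancestry_label = ancestry_label,
                       n_convention = n_convention)
  attr(out, "parse_summary") <- list(n_read = n_read, n_kept = nrow(df),
                                     n_dropped = dropped,
                                     n_pval_clamped = sum(clamped))
  out
}

#' Write a tabular result as TSV
#'
#' Tab-separated output with a header row, floats rendered with 15
#' significant digits (sufficient for value-preserving round trips), rows in
#' the order given. An empty table yields a header-only file.
#'
#' @param table A data.frame (or `summary_table`).
#' @param path Output path; the parent directory must exist.
#' @export
write_table <- function(table, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("write_table: directory does not exist: ", dir)
  df <- as.data.frame(table, stringsAsFactors = FALSE)
  for (cc in names(df)) {
    if (is.numeric(df[[cc]]) && !is.integer(df[[cc]]))
      df[[cc]] <- vapply(df[[cc]], function(v)
        if (is.na(v)) NA_character_ else format(v, digits = 15),
        character(1))
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(NULL)
}

#' Read an LD matrix
#'
#' Accepts either a square TSV whose first column and header carry variant
#' ids, or a long-format table of triples `(id1, id2, r2)`. Returns a
#' symmetric numeric matrix with unit diagonal and variant ids as dimnames.
#'
#' @param path Path to the file.
#' @return A symmetric r-squared matrix.
#' @export
read_ld_matrix <- function(path) {
  raw <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(raw) == 3 && all(tolower(names(raw)) %in%
                            c("id1", "id2", "r2"))) {
    ids <- sort(unique(c(raw[[1]], raw[[2]])))
    m <- diag(1, length(ids))
    dimnames(m) <- list(ids, ids)
    i <- match(raw[[1]], ids); j <- match(raw[[2]], ids)
    m[cbind(i, j)] <- raw[[3]]
    m[cbind(j, i)] <- raw[[3]]
    diag(m) <- 1
  } else {
    ids <- raw[[1]]
    m <- as.matrix(raw[, -1, drop = FALSE])
    rownames(m) <- ids
    storage.mode(m) <- "double"
  }
  validate_ld_matrix(m)
  m
}

#' @rdname read_ld_matrix
#' @param m A candidate LD matrix.
#' @export
validate_ld_matrix <- function(m) {
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("LD matrix must be square")
  if (is.null(rownames(m)) || is.null(colnames(m)) ||
      !identical(rownames(m), colnames(m)))
    stop("LD matrix must carry identical row/column variant ids")
  if (any(m < 0 | m > 1, na.rm = TRUE)) stop("LD r2 values must lie in [0,1]")
  if (max(abs(m - t(m))) > 1e-8) stop("LD matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-8) stop("LD matrix diagonal must be 1")
  invisible(TRUE)
}

#' @export
print.summary_table <- function(x, ...) {
  cat("GWAS summary table: ", attr(x, "trait_label"),
      " (", attr(x, "ancestry_label"), "), ",
      nrow(x), " variants\n", sep = "")
  ps <- attr(x, "parse_summary")
  if (!is.null(ps))
    cat("  parsed ", ps$n_kept, "/", ps$n_read, " rows (",
        ps$n_dropped, " dropped, ", ps$n_pval_clamped,
        " p-values clamped)\n", sep = "")
  print(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("  ... ", nrow(x) - 5, " more rows\n", sep = "")
  invisible(x)
}
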