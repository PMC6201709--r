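# Core data containers: feature-by-sample omics matrices, clinical survival
# tables, segmented copy-number calls, gene models and gene-set collections.

#' Construct an omics matrix
#'
#' The central container of the package: a numeric matrix with features
#' (genes, or engineered features) in rows and samples in columns, tagged with
#' the omics layer it came from and its normalization state. Copy-number
#' values are kept on the log2(copy number) - 1 scale throughout, so 0 means
#' diploid and 1 means a four-copy amplification.
#'
#' @param values Numeric matrix, rows = features, columns = samples. Must
#'   carry unique, non-empty dimnames.
#' @param omics_kind `"expression"` or `"cna"`.
#' @param normalized Normalization state: `"raw"`, `"zscore"` or `"log2cn"`.
#' @return An object of class `OmicsMatrix` (a numeric matrix with
#'   attributes `omics_kind` and `normalized`).
#' @examples
#' m <- omics_matrix(matrix(rnorm(6), 3, 2,
#'   dimnames = list(c("g1", "g2", "g3"), c("s1", "s2"))))
#' omics_kind(m)
#' @export
omics_matrix <- function(values,
                         omics_kind = c("expression", "cna"),
                         normalized = c("raw", "zscore", "log2cn")) {
  omics_kind <- match.arg(omics_kind)
  normalized <- match.arg(normalized)
  if (!is.matrix(values) || !is.numeric(values)) {
    stopf("`values` must be a numeric matrix")
  }
  fid <- rownames(values)
  sid <- colnames(values)
  if (is.null(fid) || is.null(sid)) {
    stopf("`values` must have row names (features) and column names (samples)")
  }
  if (anyDuplicated(fid)) {
    stopf("duplicate feature ids: %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  if (anyDuplicated(sid)) {
    stopf("duplicate sample ids: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "))
  }
  structure(values,
            omics_kind = omics_kind,
            normalized = normalized,
            class = c("OmicsMatrix", "matrix", "array"))
}

#' @rdname omics_matrix
#' @param x An `OmicsMatrix`.
#' @export
omics_kind <- function(x) attr(x, "omics_kind")

#' @rdname omics_matrix
#' @export
normalization <- function(x) attr(x, "normalized")

#' @rdname omics_matrix
#' @export
feature_ids <- function(x) rownames(x)

#' @rdname omics_matrix
#' @export
sample_ids <- function(x) colnames(x)

#' @export
print.OmicsMatrix <- function(x, ...) {
  cat(sprintf("OmicsMatrix: %d features x %d samples [%s, %s]\n",
              nrow(x), ncol(x), omics_kind(x), normalization(x)))
  invisible(x)
}

# rebuild an OmicsMatrix with new values but the same metadata
restamp <- function(values, template, normalized = normalization(template)) {
  omics_matrix(values, omics_kind = omics_kind(template),
               normalized = normalized)
}

#' Construct a clinical survival table
#'
#' Per-sample event-free survival (EFS) and overall survival (OS) endpoints,
#' times in days with right-censoring indicators (1 = event, 0 = censored).
#'
#' @param df Data frame with columns `sample_id`, `efs_time`, `efs_event`,
#'   `os_time`, `os_event`.
#' @return The validated data frame with class `SurvivalTable` prepended.
#' @export
survival_table <- function(df) {
  needed <- c("sample_id", "efs_time", "efs_event", "os_time", "os_event")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stopf("clinical table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)[needed]
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) {
    stopf("duplicate sample ids in clinical table")
  }
  for (col in c("efs_time", "os_time")) {
    if (any(!is.finite(df[[col]]) | df[[col]] < 0)) {
      stopf("column `%s` must be finite and non-negative", col)
    }
  }
  for (col in c("efs_event", "os_event")) {
    if (!all(df[[col]] %in% c(0, 1))) {
      stopf("column `%s` must contain only 0 (censored) or 1 (event)", col)
    }
  }
  class(df) <- c("SurvivalTable", "data.frame")
  df
}

# align a SurvivalTable to a set of sample ids, erroring on absentees
align_survival <- function(surv, ids) {
  idx <- match(ids, surv$sample_id)
  if (anyNA(idx)) {
    stopf("samples missing from clinical table: %s",
          paste(utils::head(ids[is.na(idx)], 5), collapse = ", "))
  }
  surv[idx, , drop = FALSE]
}

#' Construct a gene-model table
#'
#' Gene bodies as 1-based inclusive intervals, used to project segmented
#' copy-number calls onto genes.
#'
#' @param df Data frame with columns `gene_id`, `chrom`, `start`, `end` and
#'   optionally `strand` (`+`, `-` or `.`; default `.`).
#' @return Validated data frame with class `GeneModels`.
#' @export
gene_models <- function(df) {
  needed <- c("gene_id", "chrom", "start", "end")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stopf("gene model table is missing column(s): %s",
          paste(missing, collapse = ", "))
  }
  df <- as.data.frame(df)
  if (is.null(df$strand)) df$strand <- "."
  df <- df[c(needed, "strand")]
  df$gene_id <- as.character(df$gene_id)
  df$chrom <- as.character(df$chrom)
  if (anyDuplicated(df$gene_id)) stopf("duplicate gene ids in annotation")
  if (any(df$start > df$end)) stopf("gene with start > end in annotation")
  if (!all(df$strand %in% c("+", "-", "."))) {
    stopf("strand must be one of '+', '-', '.'")
  }
  class(df) <- c("GeneModels", "data.frame")
  df
}
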