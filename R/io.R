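# Readers and writers for the plain-text formats the pipeline touches:
# expression TSV, SEG, BED gene annotation, clinical TSV and GMT gene sets.
# Readers preserve input order and never impute: malformed values are errors.

#' Read a gene-by-sample expression matrix from TSV
#'
#' Expects a tab-separated file with a header row of sample ids and the first
#' column holding feature (gene) ids; genes in rows.
#'
#' @param path Path to the TSV file.
#' @return An [omics_matrix()] with `omics_kind = "expression"` and
#'   `normalized = "raw"`.
#' @export
read_expression_matrix <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1 || !grepl("\t", lines[[1]])) {
    stopf("%s: missing tab-separated header row of sample ids", path)
  }
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 2) stopf("%s: expected at least one sample column", path)
  fid <- df[[1]]
  if (anyDuplicated(fid)) {
    stopf("%s: duplicate feature id(s): %s", path,
          paste(unique(fid[duplicated(fid)]), collapse = ", "))
  }
  sid <- colnames(df)[-1]
  vals <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    bad <- which(is.na(num) , arr.ind = TRUE)[1, ]
    stopf("%s: non-numeric value '%s' at feature '%s', sample '%s'",
          path, vals[bad[1], bad[2]], fid[bad[1]], sid[bad[2]])
  }
  dimnames(num) <- list(fid, sid)
  omics_matrix(num, omics_kind = "expression", normalized = "raw")
}

#' Write an omics matrix as TSV
#'
#' Inverse of [read_expression_matrix()]: first column `feature_id`, then one
#' column per sample. Full double precision is retained so a write/read round
#' trip reproduces values to better than 1e-12.
#'
#' @param m An `OmicsMatrix`.
#' @param path Output path.
#' @export
write_omics_matrix <- function(m, path) {
  df <- data.frame(feature_id = rownames(m),
                   format(unclass(m), digits = 17, trim = TRUE,
                          scientific = TRUE),
                   check.names = FALSE)
  colnames(df) <- c("feature_id", colnames(m))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read segmented copy-number calls (SEG format)
#'
#' Standard SEG columns: sample, chromosome, start, end, optional number of
#' probes, segment mean. Coordinates are kept 1-based inclusive as in the
#' UCSC SEG dialect. Segment means are assumed to already be on the
#' log2(copy number) - 1 scale (0 = diploid); set `scale = "absolute"` if the
#' file stores absolute copy numbers instead.
#'
#' @param path Path to the SEG file.
#' @param scale `"log2ratio"` (default, values used as-is) or `"absolute"`
#'   (values transformed by `log2(cn) - 1`).
#' @param header Whether the file has a header line (default `TRUE`).
#' @return Data frame with columns `sample_id`, `chrom`, `start`, `end`,
#'   `segment_mean`, one row per input segment in input order.
#' @export
read_seg <- function(path, scale = c("log2ratio", "absolute"), header = TRUE) {
  scale <- match.arg(scale)
  df <- utils::read.delim(path, header = header, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) == 5) {
    colnames(df) <- c("sample_id", "chrom", "start", "end", "segment_mean")
  } else if (ncol(df) == 6) {
    colnames(df) <- c("sample_id", "chrom", "start", "end", "num_probes",
                      "segment_mean")
  } else {
    stopf("%s: SEG files have 5 or 6 tab-separated columns, found %d",
          path, ncol(df))
  }
  out <- data.frame(sample_id = as.character(df$sample_id),
                    chrom = as.character(df$chrom),
                    start = suppressWarnings(as.integer(df$start)),
                    end = suppressWarnings(as.integer(df$end)),
                    segment_mean =
                      suppressWarnings(as.numeric(df$segment_mean)),
                    stringsAsFactors = FALSE)
  if (anyNA(out$start) || anyNA(out$end)) {
    stopf("%s: non-integer segment coordinates", path)
  }
  if (anyNA(out$segment_mean)) {
    bad <- which(is.na(out$segment_mean))[1]
    stopf("%s: non-numeric segment mean '%s' on data line %d",
          path, df$segment_mean[bad], bad)
  }
  if (any(out$start > out$end)) {
    bad <- which(out$start > out$end)[1]
    stopf("%s: segment with start > end on data line %d (%d > %d)",
          path, bad, out$start[bad], out$end[bad])
  }
  if (any(!nzchar(out$chrom))) stopf("%s: empty chromosome field", path)
  if (scale == "absolute") {
    if (any(out$segment_mean <= 0)) {
      stopf("%s: absolute copy numbers must be positive", path)
    }
    out$segment_mean <- log2(out$segment_mean) - 1
  }
  out
}

#' Write segments in SEG format
#'
#' @param segments Data frame as returned by [read_seg()].
#' @param path Output path.
#' @export
write_seg <- function(segments, path) {
  df <- data.frame(sample = segments$sample_id, chrom = segments$chrom,
                   start = segments$start, end = segments$end,
                   segment_mean = format(segments$segment_mean, digits = 17,
                                         trim = TRUE))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-sample clinical survival table from TSV
#'
#' Expects columns `sample_id`, `efs_time`, `efs_event`, `os_time`,
#' `os_event`; times in days, events coded 1 = event, 0 = censored. Samples
#' absent from an omics matrix are permitted; joins happen later by id.
#'
#' @param path Path to the TSV file.
#' @return A [survival_table()].
#' @export
read_clinical <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE)
  if (nrow(df) == 0) {
    warnf("%s: clinical file has a header but no samples", path)
  }
  survival_table(df)
}

#' Write a clinical survival table as TSV
#'
#' @param surv A `SurvivalTable`.
#' @param path Output path.
#' @export
write_clinical <- function(surv, path) {
  utils::write.table(as.data.frame(surv), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene coordinates from BED
#'
#' BED input is 0-based half-open; coordinates are converted to 1-based
#' inclusive internally so they are directly comparable with SEG segments.
#' Column 4 is the gene id, column 6 (if present) the strand.
#'
#' @param path Path to the BED file (no header).
#' @return A [gene_models()] table.
#' @export
read_gene_bed <- function(path) {
  df <- utils::read.delim(path, header = FALSE, sep = "\t",
                          check.names = FALSE, colClasses = "character")
  if (ncol(df) < 4) {
    stopf("%s: gene BED needs at least 4 columns (chrom, start, end, name)",
          path)
  }
  start0 <- suppressWarnings(as.integer(df[[2]]))
  end0 <- suppressWarnings(as.integer(df[[3]]))
  if (anyNA(start0) || anyNA(end0)) stopf("%s: non-integer coordinates", path)
  gene_models(data.frame(
    gene_id = df[[4]],
    chrom = df[[1]],
    start = start0 + 1L,  # BED 0-based half-open -> 1-based inclusive
    end = end0,
    strand = if (ncol(df) >= 6) df[[6]] else ".",
    stringsAsFactors = FALSE))
}

#' Write gene models as BED
#'
#' Converts the internal 1-based inclusive coordinates back to BED's 0-based
#' half-open convention.
#'
#' @param genes A `GeneModels` table.
#' @param path Output path.
#' @export
write_gene_bed <- function(genes, path) {
  df <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id,
                   0L, genes$strand)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}

#' Read a gene-set collection (GMT format)
#'
#' Each line is `name<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate
#' genes within a set are removed; set order and gene order are otherwise
#' preserved.
#'
#' @param path Path to the GMT file.
#' @return A named list of character vectors of gene ids, with a
#'   `descriptions` attribute (named character vector).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- vapply(fields, length, integer(1)) < 3
  if (any(short)) {
    stopf("%s: GMT line %d has fewer than 3 tab-separated fields",
          path, which(short)[1])
  }
  names_ <- vapply(fields, `[[`, character(1), 1)
  if (anyDuplicated(names_)) {
    stopf("%s: duplicate gene-set name(s): %s", path,
          paste(unique(names_[duplicated(names_)]), collapse = ", "))
  }
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- names_
  if (any(lengths(sets) == 0)) stopf("%s: empty gene set", path)
  descr <- vapply(fields, `[[`, character(1), 2)
  names(descr) <- names_
  attr(sets, "descriptions") <- descr
  sets
}
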