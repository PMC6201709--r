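# Per-layer normalization, segment-to-gene projection, univariate Cox
# screening and stacking of the two omics layers into the integration input.

#' Floor and log-transform an FPKM expression matrix
#'
#' RNA-seq FPKM values contain exact zeros that break a log transform.
#' Rather than adding an arbitrary pseudocount, the detection floor is
#' estimated from the data: for each sample take its smallest nonzero value,
#' let U be the largest and L the smallest of these per-sample minima, then
#' replace every value below U by L and take log2. Every sample's zeros end
#' up at the global floor L, below any reliably detected value.
#'
#' @param m An expression `OmicsMatrix` of raw, non-negative FPKM values.
#' @return The log2-transformed `OmicsMatrix` (still `normalized = "raw"`;
#'   z-scoring is a separate step), with attributes `floor_L` and `floor_U`
#'   recording the thresholds actually used.
#' @export
floor_log_fpkm <- function(m) {
  if (omics_kind(m) != "expression") stopf("expected an expression matrix")
  if (any(m < 0)) stopf("FPKM values must be non-negative")
  per_sample_min <- apply(unclass(m), 2, function(v) {
    nz <- v[v > 0]
    if (!length(nz)) NA_real_ else min(nz)
  })
  if (anyNA(per_sample_min)) {
    stopf("sample(s) with all-zero expression: %s",
          paste(colnames(m)[is.na(per_sample_min)], collapse = ", "))
  }
  U <- max(per_sample_min)
  L <- min(per_sample_min)
  vals <- unclass(m)
  vals[vals < U] <- L
  vals <- log2(vals)
  out <- restamp(vals, m)
  attr(out, "floor_L") <- L
  attr(out, "floor_U") <- U
  out
}

#' Z-score each feature across samples
#'
#' Centers and scales every row by its own mean and population standard
#' deviation (denominator n). Constant rows carry no information and are set
#' to all-zero with a warning.
#'
#' @param m An `OmicsMatrix`.
#' @return The z-scored `OmicsMatrix` (`normalized = "zscore"`).
#' @export
zscore_by_gene <- function(m) {
  vals <- unclass(m)
  mu <- rowMeans(vals)
  centered <- vals - mu
  sd_pop <- sqrt(rowMeans(centered^2))
  const <- sd_pop == 0
  if (any(const)) {
    warnf("%d constant feature(s) set to zero (no variance): %s",
          sum(const),
          paste(utils::head(rownames(m)[const], 5), collapse = ", "))
    sd_pop[const] <- 1
  }
  restamp(centered / sd_pop, m, normalized = "zscore")
}

#' Project segmented copy-number calls onto genes
#'
#' Builds the gene-by-sample CNA matrix: a gene's value in a sample is the
#' length-weighted mean of the segment means of all segments overlapping the
#' gene body. Genes with no overlapping segment are diploid (0 on the
#' log2(copy number) - 1 scale). Weighting by overlap length makes the value
#' reduce to the segment mean in the common fully-contained case and is
#' deterministic for genes spanning a breakpoint.
#'
#' @param segments Data frame of segments as from [read_seg()], on the
#'   log2(copy number) - 1 scale.
#' @param genes A [gene_models()] table.
#' @param samples Character vector of sample ids defining the columns
#'   (defaults to the samples present in `segments`, in order of first
#'   appearance).
#' @return A CNA `OmicsMatrix` (`normalized = "log2cn"`).
#' @export
cna_gene_matrix <- function(segments, genes, samples = NULL) {
  if (nrow(genes) == 0) stopf("gene list is empty")
  if (is.null(samples)) samples <- unique(segments$sample_id)
  unknown <- !(segments$chrom %in% unique(genes$chrom))
  if (any(unknown)) {
    warnf("skipping %d segment(s) on chromosome(s) absent from annotation: %s",
          sum(unknown),
          paste(unique(segments$chrom[unknown]), collapse = ", "))
    segments <- segments[!unknown, , drop = FALSE]
  }
  vals <- matrix(0, nrow(genes), length(samples),
                 dimnames = list(genes$gene_id, samples))
  seg_by_sample <- split(seq_len(nrow(segments)), segments$sample_id)
  for (s in samples) {
    idx <- seg_by_sample[[s]]
    if (is.null(idx)) next
    seg <- segments[idx, , drop = FALSE]
    for (gi in seq_len(nrow(genes))) {
      on_chrom <- seg$chrom == genes$chrom[gi]
      if (!any(on_chrom)) next
      ov_start <- pmax(seg$start[on_chrom], genes$start[gi])
      ov_end <- pmin(seg$end[on_chrom], genes$end[gi])
      ov_len <- ov_end - ov_start + 1L
      hit <- ov_len > 0
      if (!any(hit)) next
      w <- ov_len[hit]
      vals[gi, s] <- sum(w * seg$segment_mean[on_chrom][hit]) / sum(w)
    }
  }
  omics_matrix(vals, omics_kind = "cna", normalized = "log2cn")
}

#' Screen features by univariate Cox regression on EFS and OS
#'
#' Fits a univariate proportional-hazards model of each feature against
#' event-free survival and against overall survival, and keeps features whose
#' score-test p-value falls below `alpha` for either endpoint. No multiple-
#' testing correction is applied at this stage; the raw threshold acts as a
#' permissive pre-filter ahead of the autoencoder.
#'
#' @param m An `OmicsMatrix`; all its samples must appear in `surv`.
#' @param surv A [survival_table()].
#' @param alpha Per-endpoint significance threshold (default 0.05).
#' @return List with `matrix` (the `OmicsMatrix` restricted to kept rows) and
#'   `report` (data frame: `feature_id`, `p_efs`, `p_os`, `kept`).
#' @export
cox_screen_features <- function(m, surv, alpha = 0.05) {
  assert_prob(alpha, "alpha")
  cl <- align_survival(surv, colnames(m))
  vals <- unclass(m)
  endpoints <- list(
    efs = list(time = cl$efs_time, event = cl$efs_event),
    os = list(time = cl$os_time, event = cl$os_event))
  pmat <- matrix(NA_real_, nrow(m), 2,
                 dimnames = list(rownames(m), names(endpoints)))
  for (ep in names(endpoints)) {
    e <- endpoints[[ep]]
    if (sum(e$event == 1) < 2) {
      warnf("endpoint %s has fewer than 2 events; skipped in screening",
            toupper(ep))
      next
    }
    pmat[, ep] <- cox_score_test_matrix(vals, e$time, e$event)$p_value
  }
  kept <- (ifelse(is.na(pmat[, "efs"]), FALSE, pmat[, "efs"] < alpha) |
             ifelse(is.na(pmat[, "os"]), FALSE, pmat[, "os"] < alpha))
  report <- data.frame(feature_id = rownames(m),
                       p_efs = pmat[, "efs"], p_os = pmat[, "os"],
                       kept = unname(kept), row.names = NULL)
  list(matrix = restamp(vals[kept, , drop = FALSE], m), report = report)
}

#' Stack expression and CNA layers into one matrix
#'
#' Concatenates the z-scored expression rows and the CNA rows over the
#' samples present in both layers. Feature ids are prefixed `GE:` / `CNA:`
#' so a gene measured on both layers yields two distinct rows; sample order
#' follows the expression matrix.
#'
#' @param expr Expression `OmicsMatrix` (z-scored).
#' @param cna CNA `OmicsMatrix`.
#' @return The stacked `OmicsMatrix` with a `row_omics` attribute recording
#'   each row's layer of origin.
#' @export
stack_omics <- function(expr, cna) {
  shared <- intersect(colnames(expr), colnames(cna))
  if (length(shared) < 2) {
    stopf("expression and CNA share %d sample(s); need at least 2",
          length(shared))
  }
  shared <- colnames(expr)[colnames(expr) %in% shared]  # expression order
  top <- unclass(expr)[, shared, drop = FALSE]
  bottom <- unclass(cna)[, shared, drop = FALSE]
  rownames(top) <- paste0("GE:", rownames(top))
  rownames(bottom) <- paste0("CNA:", rownames(bottom))
  vals <- rbind(top, bottom)
  out <- omics_matrix(vals, omics_kind = "expression", normalized = "zscore")
  attr(out, "row_omics") <- c(rep("expression", nrow(top)),
                              rep("cna", nrow(bottom)))
  out
}
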