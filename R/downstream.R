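# Downstream comparison of the subtypes: per-gene differential expression by
# Student's t-test with BH FDR, direction-consistent intersection across
# cohorts, and hypergeometric overrepresentation analysis against GMT gene
# sets.

#' Differential expression between G1 and G2 by Student's t-test
#'
#' Two-sided equal-variance (pooled) t-test per gene, with BH FDR across
#' genes. Direction is the sign of mean(G1) - mean(G2). Genes with zero
#' pooled variance are uninformative and get p = 1 with a flag.
#'
#' @param m An expression `OmicsMatrix`.
#' @param labels G1/G2 labels (`SubtypeAssignment` or vector).
#' @param fdr_cut Significance threshold on the adjusted p-value
#'   (default 0.05).
#' @param group1,group2 The two label values compared (defaults `"G1"`,
#'   `"G2"`).
#' @return Data frame: `gene`, `t`, `p`, `fdr`, `direction` (+1 up in G1,
#'   -1 down), `mean_diff`, `zero_variance`, `significant`.
#' @export
ttest_de <- function(m, labels, fdr_cut = 0.05,
                     group1 = "G1", group2 = "G2") {
  y <- resolve_labels(labels, colnames(m))
  i1 <- y == group1
  i2 <- y == group2
  n1 <- sum(i1)
  n2 <- sum(i2)
  if (n1 < 2 || n2 < 2) stopf("each group needs at least 2 samples")
  vals <- unclass(m)
  m1 <- rowMeans(vals[, i1, drop = FALSE])
  m2 <- rowMeans(vals[, i2, drop = FALSE])
  ss1 <- rowSums((vals[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((vals[, i2, drop = FALSE] - m2)^2)
  df <- n1 + n2 - 2
  pooled_var <- (ss1 + ss2) / df
  zero_var <- pooled_var == 0
  se <- sqrt(pooled_var * (1 / n1 + 1 / n2))
  t <- ifelse(zero_var, 0, (m1 - m2) / ifelse(se == 0, 1, se))
  p <- ifelse(zero_var, 1, 2 * stats::pt(abs(t), df, lower.tail = FALSE))
  fdr <- bh_fdr(p)
  data.frame(gene = rownames(vals), t = t, p = p, fdr = fdr,
             direction = ifelse(m1 - m2 >= 0, 1L, -1L),
             mean_diff = m1 - m2, zero_variance = zero_var,
             significant = fdr < fdr_cut, row.names = NULL)
}

#' Intersect differential-expression results across cohorts
#'
#' Genes called significant in both tables with the same direction, split
#' into up- and downregulated (in G1) sets.
#'
#' @param de_train,de_valid Data frames from [ttest_de()].
#' @param fdr_cut Threshold applied to both tables (default 0.05).
#' @return List with character vectors `up` and `down`, plus `universe`
#'   (genes tested in both cohorts).
#' @export
intersect_de <- function(de_train, de_valid, fdr_cut = 0.05) {
  universe <- intersect(de_train$gene, de_valid$gene)
  if (!length(universe)) stopf("the two DE tables share no genes")
  pick <- function(de, dir) {
    de$gene[de$fdr < fdr_cut & de$direction == dir & de$gene %in% universe]
  }
  list(up = intersect(pick(de_train, 1L), pick(de_valid, 1L)),
       down = intersect(pick(de_train, -1L), pick(de_valid, -1L)),
       universe = universe)
}

#' Hypergeometric overrepresentation test for one gene set
#'
#' Exact upper-tail hypergeometric probability of observing at least the
#' seen overlap between a hit list and a gene set, both restricted to the
#' universe of tested genes.
#'
#' @param gene_set Character vector of gene ids in the set.
#' @param hits Character vector of significant genes; must lie within
#'   `universe`.
#' @param universe Character vector of all tested genes.
#' @return List: `overlap` (count), `set_size` (after restriction to the
#'   universe), `p_value`, `enrichment_ratio` (observed / expected overlap).
#' @export
ora_hypergeometric <- function(gene_set, hits, universe) {
  universe <- unique(universe)
  hits <- unique(hits)
  if (!length(hits)) stopf("empty hit list")
  if (!all(hits %in% universe)) stopf("hits must be a subset of the universe")
  set_in <- unique(gene_set[gene_set %in% universe])
  overlap <- sum(hits %in% set_in)
  N <- length(universe)
  K <- length(set_in)
  n <- length(hits)
  p <- if (K == 0) 1 else
    stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  expected <- K * n / N
  list(overlap = overlap, set_size = K, p_value = p,
       enrichment_ratio = if (expected > 0) overlap / expected else NA_real_)
}

#' Overrepresentation analysis across a gene-set collection
#'
#' Runs [ora_hypergeometric()] for every set in a GMT collection and adjusts
#' the p-values by BH FDR.
#'
#' @param collection Named list of gene sets as from [read_gmt()].
#' @param hits,universe As in [ora_hypergeometric()].
#' @return Data frame sorted by p-value: `set`, `description`, `set_size`,
#'   `overlap`, `enrichment_ratio`, `p`, `fdr`.
#' @export
ora_collection <- function(collection, hits, universe) {
  descr <- attr(collection, "descriptions")
  rows <- lapply(names(collection), function(nm) {
    r <- ora_hypergeometric(collection[[nm]], hits, universe)
    data.frame(set = nm,
               description = if (!is.null(descr)) descr[[nm]] else "",
               set_size = r$set_size, overlap = r$overlap,
               enrichment_ratio = r$enrichment_ratio, p = r$p_value)
  })
  out <- do.call(rbind, rows)
  out$fdr <- bh_fdr(out$p)
  out[order(out$p), , drop = FALSE]
}
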