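# Synthetic multi-cohort generator: two latent subtypes with divergent
# exponential survival, informative genes carrying mean shifts on the
# expression layer (attenuated on the copy-number layer), and the cohort
# topology of the study design — a training cohort with both layers, an
# internal cohort with copy number only, and an external cohort with
# expression only.

#' Simulation configuration
#'
#' Defaults mirror the study design this package models: 190 training
#' samples with both omics layers, 190 internal-validation samples with copy
#' number only, 176 external-validation samples with expression only, two
#' subtypes of equal prevalence with strongly divergent survival
#' (hazard ratio 4 for G1), informative features shifted by 3 standard
#' deviations on the expression layer and half that on the copy-number
#' layer, and roughly 30% right-censoring.
#'
#' @param n_train,n_internal_cna,n_external_expr Cohort sizes.
#' @param n_genes_expr,n_genes_cna Features per layer.
#' @param frac_informative Fraction of features carrying the subtype signal.
#' @param informative_overlap Fraction of informative CNA genes whose
#'   expression counterpart is also informative, making cross-omics transfer
#'   learnable (default 0.5).
#' @param subtype_prevalence P(subtype G1).
#' @param latent_separation Mean shift of informative expression features, in
#'   within-subtype standard deviations.
#' @param cna_signal_scale CNA shift relative to the expression shift.
#' @param hazard_ratio_g1 Hazard ratio of subtype G1 versus G2 (> 0; > 1
#'   makes G1 the worse-prognosis subtype).
#' @param baseline_median_survival Median survival of subtype G2 in days.
#' @param censor_rate Target marginal fraction of censored samples.
#' @param seed Integer master seed.
#' @return List of class `sim_config`.
#' @export
sim_config <- function(n_train = 190, n_internal_cna = 190,
                       n_external_expr = 176, n_genes_expr = 2000,
                       n_genes_cna = 500, frac_informative = 0.05,
                       informative_overlap = 0.5,
                       subtype_prevalence = 0.5, latent_separation = 3,
                       cna_signal_scale = 0.5, hazard_ratio_g1 = 4,
                       baseline_median_survival = 1500, censor_rate = 0.3,
                       seed = 1) {
  cfg <- list(n_train = n_train, n_internal_cna = n_internal_cna,
              n_external_expr = n_external_expr,
              n_genes_expr = n_genes_expr, n_genes_cna = n_genes_cna,
              frac_informative = frac_informative,
              informative_overlap = informative_overlap,
              subtype_prevalence = subtype_prevalence,
              latent_separation = latent_separation,
              cna_signal_scale = cna_signal_scale,
              hazard_ratio_g1 = hazard_ratio_g1,
              baseline_median_survival = baseline_median_survival,
              censor_rate = censor_rate, seed = as.integer(seed))
  if (any(unlist(cfg[1:5]) <= 0)) stopf("counts must be positive")
  assert_prob(cfg$subtype_prevalence, "subtype_prevalence")
  assert_prob(cfg$censor_rate, "censor_rate")
  if (cfg$hazard_ratio_g1 <= 0) stopf("hazard_ratio_g1 must be positive")
  class(cfg) <- "sim_config"
  cfg
}

# Solve for the censoring-time rate that yields the target marginal censoring
# fraction under exponential event and censoring times:
# P(censored) = p * rc/(rc + r1) + (1-p) * rc/(rc + r2).
calibrate_censor_rate <- function(cfg) {
  r2 <- log(2) / cfg$baseline_median_survival
  r1 <- r2 * cfg$hazard_ratio_g1
  p <- cfg$subtype_prevalence
  target <- cfg$censor_rate
  f <- function(rc) p * rc / (rc + r1) + (1 - p) * rc / (rc + r2) - target
  sol <- tryCatch(
    stats::uniroot(f, lower = 1e-12, upper = 1e6, tol = 1e-12),
    error = function(e) NULL)
  if (is.null(sol)) stopf("censoring calibration infeasible for this config")
  sol$root
}

# Draw one cohort's survival endpoints. The two endpoints share the subtype
# effect but have independent noise; EFS events are generated to precede OS.
draw_survival <- function(ids, subtype, cfg) {
  r2 <- log(2) / cfg$baseline_median_survival
  rate <- ifelse(subtype == "G1", r2 * cfg$hazard_ratio_g1, r2)
  rc <- calibrate_censor_rate(cfg)
  draw_endpoint <- function() {
    t_event <- stats::rexp(length(ids), rate)
    t_cens <- stats::rexp(length(ids), rc)
    data.frame(time = pmin(t_event, t_cens),
               event = as.integer(t_event <= t_cens))
  }
  efs <- draw_endpoint()
  os <- draw_endpoint()
  survival_table(data.frame(sample_id = ids,
                            efs_time = efs$time, efs_event = efs$event,
                            os_time = os$time, os_event = os$event))
}

# Feature matrix: unit-Gaussian noise with +/- shift/2 per subtype on the
# informative rows, so the between-subtype separation is `shift` SDs.
draw_layer <- function(gene_ids, ids, subtype, informative, shift, signs) {
  vals <- matrix(stats::rnorm(length(gene_ids) * length(ids)),
                 length(gene_ids), length(ids),
                 dimnames = list(gene_ids, ids))
  sgn <- ifelse(subtype == "G1", 0.5, -0.5)
  vals[informative, ] <- vals[informative, , drop = FALSE] +
    outer(signs * shift, sgn)
  vals
}

#' Simulate the four-cohort study layout
#'
#' Draws training (expression + CNA), internal (CNA only) and external
#' (expression only) cohorts from one generative model: each sample belongs
#' to subtype G1 or G2; informative genes are mean-shifted between subtypes;
#' event and censoring times are independent exponentials with the G1 hazard
#' multiplied by `hazard_ratio_g1` and the censoring rate calibrated to the
#' target censoring fraction. Fully reproducible from `cfg$seed`.
#'
#' @param cfg A [sim_config()].
#' @return List with elements `train_expr`, `train_cna`, `internal_cna`,
#'   `external_expr` (each an `OmicsMatrix`), `clinical` (one
#'   [survival_table()] covering all cohorts), `truth` (named character
#'   vector of planted subtypes), `informative_expr`, `informative_cna`
#'   (gene id vectors) and `config`.
#' @export
simulate_cohorts <- function(cfg = sim_config()) {
  with_seed(cfg$seed, {
    expr_genes <- sprintf("EG%04d", seq_len(cfg$n_genes_expr))
    cna_genes <- sprintf("CG%04d", seq_len(cfg$n_genes_cna))
    n_inf_e <- max(1, round(cfg$frac_informative * cfg$n_genes_expr))
    n_inf_c <- max(1, round(cfg$frac_informative * cfg$n_genes_cna))
    # a configurable fraction of informative CNA genes mirror an informative
    # expression gene at the same index (a "shared" driver measured on both
    # layers), so cross-omics label transfer is learnable
    n_shared <- min(round(cfg$informative_overlap * n_inf_c), n_inf_e,
                    cfg$n_genes_cna)
    shared_idx <- sample(seq_len(min(cfg$n_genes_expr, cfg$n_genes_cna)),
                         n_shared)
    inf_e <- expr_genes[c(shared_idx,
                          sample(setdiff(seq_len(cfg$n_genes_expr),
                                         shared_idx),
                                 n_inf_e - n_shared))]
    inf_c <- cna_genes[c(shared_idx,
                         sample(setdiff(seq_len(cfg$n_genes_cna),
                                        shared_idx),
                                max(0, n_inf_c - n_shared)))]
    sign_e <- stats::setNames(sample(c(-1, 1), n_inf_e, replace = TRUE),
                              inf_e)
    # shared informative genes keep the expression sign on the CNA layer
    sign_c <- stats::setNames(sample(c(-1, 1), length(inf_c), replace = TRUE),
                              inf_c)
    sign_c[cna_genes[shared_idx]] <- sign_e[expr_genes[shared_idx]]

    make_ids <- function(prefix, n) sprintf("%s%03d", prefix, seq_len(n))
    cohorts <- list(train = make_ids("TR", cfg$n_train),
                    internal = make_ids("IN", cfg$n_internal_cna),
                    external = make_ids("EX", cfg$n_external_expr))
    truth <- list()
    clin <- list()
    for (nm in names(cohorts)) {
      ids <- cohorts[[nm]]
      z <- ifelse(stats::runif(length(ids)) < cfg$subtype_prevalence,
                  "G1", "G2")
      truth[[nm]] <- stats::setNames(z, ids)
      clin[[nm]] <- draw_survival(ids, z, cfg)
    }
    shift_c <- cfg$latent_separation * cfg$cna_signal_scale
    out <- list(
      train_expr = omics_matrix(
        draw_layer(expr_genes, cohorts$train, truth$train, inf_e,
                   cfg$latent_separation, sign_e),
        omics_kind = "expression", normalized = "raw"),
      train_cna = omics_matrix(
        draw_layer(cna_genes, cohorts$train, truth$train, inf_c,
                   shift_c, sign_c),
        omics_kind = "cna", normalized = "log2cn"),
      internal_cna = omics_matrix(
        draw_layer(cna_genes, cohorts$internal, truth$internal, inf_c,
                   shift_c, sign_c),
        omics_kind = "cna", normalized = "log2cn"),
      external_expr = omics_matrix(
        draw_layer(expr_genes, cohorts$external, truth$external, inf_e,
                   cfg$latent_separation, sign_e),
        omics_kind = "expression", normalized = "raw"),
      clinical = survival_table(do.call(rbind, unname(
        lapply(clin, as.data.frame)))),
      truth = do.call(c, unname(truth)),
      informative_expr = inf_e, informative_cna = inf_c,
      config = cfg)
    out
  })
}

#' Lay out synthetic gene models along chromosomes
#'
#' Places `n_genes` gene bodies of fixed length with fixed intergenic gaps on
#' consecutive synthetic chromosomes.
#'
#' @param gene_ids Character vector of gene ids.
#' @param gene_length,gap Gene body length and intergenic gap in bp.
#' @param genes_per_chrom Genes per synthetic chromosome.
#' @return A [gene_models()] table.
#' @export
simulate_gene_models <- function(gene_ids, gene_length = 1000, gap = 1000,
                                 genes_per_chrom = 100) {
  n <- length(gene_ids)
  chrom <- paste0("chr", (seq_len(n) - 1) %/% genes_per_chrom + 1)
  pos_on_chrom <- (seq_len(n) - 1) %% genes_per_chrom
  start <- pos_on_chrom * (gene_length + gap) + 1L
  gene_models(data.frame(gene_id = gene_ids, chrom = chrom,
                         start = start, end = start + gene_length - 1L,
                         strand = "+", stringsAsFactors = FALSE))
}

#' Emit SEG records that reconstruct a CNA matrix exactly
#'
#' Writes one segment per gene per sample spanning exactly the gene body
#' with the gene's matrix value as the segment mean, so projecting the
#' segments back through [cna_gene_matrix()] recovers the matrix to
#' floating-point accuracy.
#'
#' @param cna A CNA `OmicsMatrix`.
#' @param genes A [gene_models()] table covering the matrix rows.
#' @return Data frame of segments in [read_seg()] layout.
#' @export
simulate_seg_records <- function(cna, genes) {
  idx <- match(rownames(cna), genes$gene_id)
  if (anyNA(idx)) stopf("gene model(s) missing for some CNA rows")
  g <- genes[idx, , drop = FALSE]
  n_genes <- nrow(cna)
  samples <- colnames(cna)
  data.frame(
    sample_id = rep(samples, each = n_genes),
    chrom = rep(g$chrom, length(samples)),
    start = rep(g$start, length(samples)),
    end = rep(g$end, length(samples)),
    segment_mean = as.vector(unclass(cna)),
    stringsAsFactors = FALSE)
}
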