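# Normalization, segment-to-gene projection, Cox screening and stacking.

mk <- function(vals, kind = "expression", norm = "raw") {
  if (is.null(dimnames(vals))) {
    dimnames(vals) <- list(sprintf("g%d", seq_len(nrow(vals))),
                           sprintf("s%d", seq_len(ncol(vals))))
  }
  omics_matrix(vals, omics_kind = kind, normalized = norm)
}

test_that("FPKM flooring follows the per-sample nonzero-minimum rule", {
  # per-sample nonzero minima are (4, 2): U = 4, L = 2; the 0 and the 2 are
  # both below U and floored to 2
  m <- mk(matrix(c(0, 4, 2, 8), 2, 2))
  out <- floor_log_fpkm(m)
  expect_equal(matrix(as.numeric(out), 2, 2), matrix(c(1, 2, 1, 3), 2, 2))
  expect_equal(attr(out, "floor_L"), 2)
  expect_equal(attr(out, "floor_U"), 4)
})

test_that("FPKM flooring leaves an all-ones matrix at zero", {
  out <- floor_log_fpkm(mk(matrix(1, 3, 4)))
  expect_true(all(unclass(out) == 0))
})

test_that("FPKM flooring rejects all-zero samples and negative values", {
  m <- mk(matrix(c(0, 0, 1, 2), 2, 2))
  expect_error(floor_log_fpkm(m), "all-zero")
  expect_error(floor_log_fpkm(mk(matrix(c(-1, 1, 1, 1), 2, 2))),
               "non-negative")
})

test_that("z-scoring centers and scales rows with the population SD", {
  m <- mk(matrix(c(1, 2, 3), 1, 3))
  out <- zscore_by_gene(m)
  expect_equal(unname(unclass(out)[1, ]), c(-1.2247, 0, 1.2247),
               tolerance = 1e-3)
  expect_identical(normalization(out), "zscore")

  set.seed(7)
  big <- zscore_by_gene(mk(matrix(rnorm(200, 5, 3), 10, 20)))
  expect_lt(max(abs(rowMeans(unclass(big)))), 1e-8)
  expect_lt(max(abs(sqrt(rowMeans(unclass(big)^2)) - 1)), 1e-6)
})

test_that("constant rows z-score to zero with a warning", {
  m <- mk(matrix(c(5, 5, 5, 1, 2, 3), 2, 3, byrow = TRUE))
  expect_warning(out <- zscore_by_gene(m), "constant")
  expect_true(all(unclass(out)[1, ] == 0))
})

test_that("z-scoring is idempotent", {
  set.seed(8)
  m <- mk(matrix(rnorm(60, 2, 4), 6, 10))
  once <- zscore_by_gene(m)
  twice <- zscore_by_gene(once)
  expect_lt(max(abs(unclass(once) - unclass(twice))), 1e-8)
})

test_that("gene-level CNA values follow the length-weighted overlap mean", {
  genes <- gene_models(data.frame(gene_id = "G1", chrom = "chr1",
                                  start = 101, end = 200))
  # fully contained in one amplified segment
  seg <- data.frame(sample_id = "S1", chrom = "chr1", start = 1, end = 1000,
                    segment_mean = 1)
  m <- cna_gene_matrix(seg, genes, "S1")
  expect_equal(unclass(m)["G1", "S1"], 1)
  expect_identical(omics_kind(m), "cna")
  # diploid segment
  seg$segment_mean <- 0
  expect_equal(unclass(cna_gene_matrix(seg, genes, "S1"))["G1", "S1"], 0)
  # gene split 50/50 between an amplified and a diploid segment
  seg2 <- data.frame(sample_id = "S1", chrom = "chr1",
                     start = c(1, 151), end = c(150, 400),
                     segment_mean = c(1, 0))
  expect_equal(unclass(cna_gene_matrix(seg2, genes, "S1"))["G1", "S1"], 0.5)
})

test_that("gene-level CNA agrees with a per-base average on random toys", {
  set.seed(21)
  for (rep in 1:20) {
    gene <- data.frame(gene_id = "G", chrom = "chr1",
                       start = sample(1:400, 1), end = 0)
    gene$end <- gene$start + sample(50:400, 1)
    n_seg <- sample(1:4, 1)
    starts <- sort(sample(1:900, n_seg))
    ends <- pmin(starts + sample(30:300, n_seg, replace = TRUE), 1000)
    # drop overlaps between consecutive segments
    if (n_seg > 1) ends[-n_seg] <- pmin(ends[-n_seg], starts[-1] - 1)
    ok <- starts <= ends
    seg <- data.frame(sample_id = "S1", chrom = "chr1",
                      start = starts[ok], end = ends[ok],
                      segment_mean = round(rnorm(sum(ok)), 2))
    m <- cna_gene_matrix(seg, gene_models(gene), "S1")
    expect_equal(unclass(m)["G", "S1"], brute_cna_gene_value(seg, gene),
                 tolerance = 1e-12)
  }
})

test_that("CNA projection warns on unknown chromosomes, errors on no genes", {
  genes <- gene_models(data.frame(gene_id = "G1", chrom = "chr1",
                                  start = 1, end = 100))
  seg <- data.frame(sample_id = "S1", chrom = c("chr1", "chrMT"),
                    start = 1, end = 100, segment_mean = c(0.5, 2))
  expect_warning(m <- cna_gene_matrix(seg, genes, "S1"), "chrMT")
  expect_equal(unclass(m)["G1", "S1"], 0.5)
  expect_error(cna_gene_matrix(seg, genes[0, ], "S1"), "empty")
})

make_clin <- function(ids, time_e, ev_e, time_o = time_e, ev_o = ev_e) {
  survival_table(data.frame(sample_id = ids, efs_time = time_e,
                            efs_event = ev_e, os_time = time_o,
                            os_event = ev_o))
}

test_that("Cox screening keeps prognostic features and drops constants", {
  set.seed(31)
  n <- 120
  risk <- rnorm(n)
  t_ev <- rexp(n, exp(1.2 * risk))       # strongly prognostic hazard
  surv <- make_clin(sprintf("s%d", 1:n), pmin(t_ev, 3),
                    as.integer(t_ev <= 3))
  vals <- rbind(risk, matrix(5, 1, n), matrix(rnorm(3 * n), 3, n))
  rownames(vals) <- c("signal", "constant", "n1", "n2", "n3")
  colnames(vals) <- surv$sample_id
  res <- cox_screen_features(mk(vals), surv, alpha = 0.05)
  expect_true(res$report$kept[res$report$feature_id == "signal"])
  expect_false(res$report$kept[res$report$feature_id == "constant"])
  expect_equal(res$report$p_efs[res$report$feature_id == "constant"], 1)
  expect_identical(rownames(res$matrix),
                   res$report$feature_id[res$report$kept])
})

test_that("Cox screening is invariant to positive rescaling of a feature", {
  set.seed(32)
  n <- 80
  x <- rnorm(n)
  surv <- make_clin(sprintf("s%d", 1:n), rexp(n, exp(0.5 * x)),
                    rbinom(n, 1, 0.8))
  vals <- rbind(a = x, b = 17 * x)
  colnames(vals) <- surv$sample_id
  res <- cox_screen_features(mk(vals), surv)
  expect_equal(res$report$p_efs[1], res$report$p_efs[2], tolerance = 1e-10)
  expect_identical(res$report$kept[1], res$report$kept[2])
})

test_that("screening detects a hazard-ratio-3 feature with high power", {
  set.seed(33)
  hits <- 0
  reps <- 100
  for (r in seq_len(reps)) {
    n <- 200
    x <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.2 * 3^x)
    t_c <- rexp(n, 0.09)                  # about 30% censoring
    surv <- make_clin(sprintf("s%d", 1:n), pmin(t_ev, t_c),
                      as.integer(t_ev <= t_c))
    vals <- matrix(x, 1, n, dimnames = list("f", surv$sample_id))
    res <- cox_screen_features(mk(vals), surv)
    hits <- hits + res$report$kept[1]
  }
  expect_gte(hits / reps, 0.95)
})

test_that("stacking prefixes layers and intersects samples", {
  e <- mk(matrix(rnorm(12), 3, 4,
                 dimnames = list(c("G1", "G2", "G3"),
                                 c("a", "b", "c", "d"))),
          norm = "raw")
  e <- zscore_by_gene(e)
  cn <- mk(matrix(rnorm(8), 2, 4,
                  dimnames = list(c("G1", "G9"), c("b", "c", "d", "z"))),
           kind = "cna", norm = "log2cn")
  st <- stack_omics(e, cn)
  expect_identical(dim(unclass(st)), c(5L, 3L))
  expect_identical(sample_ids(st), c("b", "c", "d"))  # expression order
  expect_true(all(c("GE:G1", "CNA:G1") %in% feature_ids(st)))
  expect_identical(attr(st, "row_omics"),
                   c(rep("expression", 3), rep("cna", 2)))

  disjoint <- mk(matrix(rnorm(4), 2, 2,
                        dimnames = list(c("G1", "G2"), c("x", "y"))),
                 kind = "cna")
  expect_error(stack_omics(e, disjoint), "at least 2")
})
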