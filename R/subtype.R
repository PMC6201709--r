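# K-means subtyping of the selected latent features, choice of the cluster
# number by three criteria (prognostic C-index, silhouette, Calinski-
# Harabasz), and orientation of the two clusters so that G1 is the
# worse-prognosis (ultra-high-risk) subtype.

#' K-means clustering of latent features
#'
#' Lloyd's algorithm, best of `n_restarts` random initializations by
#' within-cluster sum of squares, deterministic given the seed.
#'
#' @param x Numeric matrix, samples in rows (e.g.
#'   [latent_selected_values()]).
#' @param k Number of clusters (2 <= k <= number of samples).
#' @param seed Integer seed.
#' @param n_restarts Number of random restarts (default 50).
#' @return List of class `SubtypeAssignment`: `labels` (named integer vector
#'   of cluster indices), `k`, `centers`, `wcss`, `seed`.
#' @export
kmeans_cluster <- function(x, k, seed = 1, n_restarts = 50) {
  if (k < 2) stopf("k must be at least 2")
  if (k > nrow(x)) stopf("k (%d) exceeds the number of samples (%d)",
                         k, nrow(x))
  fit <- with_seed(seed, {
    if (k == nrow(x)) {
      # every point its own cluster; kmeans() rejects this boundary case
      list(cluster = seq_len(nrow(x)), centers = x, tot.withinss = 0)
    } else {
      suppressWarnings(stats::kmeans(x, centers = k, nstart = n_restarts,
                                     iter.max = 100, algorithm = "Lloyd"))
    }
  })
  labels <- stats::setNames(as.integer(fit$cluster), rownames(x))
  structure(list(labels = labels, k = as.integer(k), centers = fit$centers,
                 wcss = fit$tot.withinss, seed = as.integer(seed)),
            class = "SubtypeAssignment")
}

#' Mean silhouette width
#'
#' Average silhouette over all samples, Euclidean distances, via
#' `cluster::silhouette`.
#'
#' @param x Numeric matrix, samples in rows.
#' @param labels Integer cluster labels.
#' @return Scalar mean silhouette width in \[-1, 1\].
#' @export
silhouette_score <- function(x, labels) {
  sil <- cluster::silhouette(as.integer(factor(labels)), stats::dist(x))
  mean(sil[, "sil_width"])
}

#' Calinski-Harabasz criterion
#'
#' Ratio of between- to within-cluster dispersion,
#' `(B/(k-1)) / (W/(n-k))`, where B and W are the between- and within-
#' cluster sums of squared Euclidean distances from the respective means.
#'
#' @inheritParams silhouette_score
#' @return Scalar score; larger favours the clustering.
#' @export
calinski_harabasz <- function(x, labels) {
  labels <- as.integer(factor(labels))
  n <- nrow(x)
  k <- length(unique(labels))
  if (k < 2 || k >= n) stopf("need 2 <= k < n for the Calinski-Harabasz score")
  grand <- colMeans(x)
  W <- 0
  B <- 0
  for (g in unique(labels)) {
    xi <- x[labels == g, , drop = FALSE]
    ci <- colMeans(xi)
    W <- W + sum(sweep(xi, 2, ci)^2)
    B <- B + nrow(xi) * sum((ci - grand)^2)
  }
  (B / (k - 1)) / (W / (n - k))
}

# Risk score of a clustering for the C-index criterion: each sample inherits
# the negated restricted-mean survival of its cluster, so members of clusters
# with worse survival get higher risk. Generalizes the two-cluster rule
# (worse cluster = 1, better = 0) to any k.
cluster_risk_score <- function(labels, time, event) {
  rmst <- vapply(sort(unique(labels)), function(g) {
    sel <- labels == g
    restricted_mean_survival(time[sel], event[sel], tau = max(time))
  }, 0)
  names(rmst) <- sort(unique(labels))
  -rmst[as.character(labels)]
}

#' Choose the number of clusters
#'
#' Clusters the samples at every k in `k_range` and scores each clustering on
#' three criteria: Harrell's C-index of the cluster-risk assignment against
#' EFS (and, reported alongside, OS), mean silhouette width, and the
#' Calinski-Harabasz score. The chosen k is the majority winner across the
#' three criteria; ties are broken in favour of the EFS C-index winner.
#'
#' @param x Numeric matrix, samples in rows.
#' @param surv A [survival_table()] covering the row names of `x`.
#' @param k_range Candidate cluster numbers (default `2:6`).
#' @param seed Integer seed (each k uses a seed derived from it).
#' @param n_restarts Restarts per k (default 50).
#' @return List with `k` (chosen), `metrics` (data frame per k:
#'   `c_index_efs`, `c_index_os`, `silhouette`, `calinski_harabasz`) and
#'   `assignment` (the `SubtypeAssignment` at the chosen k).
#' @export
select_k <- function(x, surv, k_range = 2:6, seed = 1, n_restarts = 50) {
  cl <- align_survival(surv, rownames(x))
  rows <- list()
  assigns <- list()
  for (k in k_range) {
    if (k >= nrow(x)) {
      warnf("k = %d infeasible for %d samples; skipped", k, nrow(x))
      next
    }
    a <- kmeans_cluster(x, k, seed = derive_seed(seed, paste0("k", k)),
                        n_restarts = n_restarts)
    risk <- cluster_risk_score(a$labels, cl$efs_time, cl$efs_event)
    rows[[as.character(k)]] <- data.frame(
      k = k,
      c_index_efs = concordance_index(risk, cl$efs_time,
                                      cl$efs_event)$c_index,
      c_index_os = concordance_index(
        cluster_risk_score(a$labels, cl$os_time, cl$os_event),
        cl$os_time, cl$os_event)$c_index,
      silhouette = silhouette_score(x, a$labels),
      calinski_harabasz = calinski_harabasz(x, a$labels))
    assigns[[as.character(k)]] <- a
  }
  if (!length(rows)) stopf("no feasible k in the requested range")
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  winners <- c(
    c_index = metrics$k[which.max(metrics$c_index_efs)],
    silhouette = metrics$k[which.max(metrics$silhouette)],
    calinski_harabasz = metrics$k[which.max(metrics$calinski_harabasz)])
  tab <- table(winners)
  top <- as.integer(names(tab)[tab == max(tab)])
  chosen <- if (length(top) == 1) top else winners[["c_index"]]
  list(k = chosen, metrics = metrics,
       assignment = assigns[[as.character(chosen)]], winners = winners)
}

#' Orient two clusters as G1 (worse prognosis) and G2
#'
#' Relabels a two-cluster assignment so that the cluster with the lower
#' restricted-mean event-free survival — the worse Kaplan-Meier curve — is
#' called `G1` and the other `G2`. Comparing restricted means rather than
#' raw event rates avoids confounding by unequal follow-up.
#'
#' @param assign A `SubtypeAssignment` with `k = 2`.
#' @param surv A [survival_table()].
#' @return The assignment with `labels` recoded to `"G1"`/`"G2"` (named
#'   character vector).
#' @export
orient_labels <- function(assign, surv) {
  if (assign$k != 2) stopf("orientation is defined for k = 2 only")
  cl <- align_survival(surv, names(assign$labels))
  ids <- sort(unique(assign$labels))
  rmst <- vapply(ids, function(g) {
    sel <- assign$labels == g
    restricted_mean_survival(cl$efs_time[sel], cl$efs_event[sel],
                             tau = max(cl$efs_time))
  }, 0)
  if (rmst[1] == rmst[2]) {
    warnf("clusters have identical restricted-mean survival; labelling the %s",
          "lower cluster index G1")
    worse <- ids[1]
  } else {
    worse <- ids[which.min(rmst)]
  }
  assign$labels <- stats::setNames(
    ifelse(assign$labels == worse, "G1", "G2"), names(assign$labels))
  assign
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same samples;
#' 1 = identical partitions (up to label permutation), 0 = chance.
#'
#' @param a,b Label vectors of equal length.
#' @return Scalar ARI.
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  max_idx <- (sum_a + sum_b) / 2
  if (max_idx == expected) return(1)
  (sum_ij - expected) / (max_idx - expected)
}
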