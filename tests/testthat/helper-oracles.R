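# Independent reference implementations used as oracles. These are written
# as literal, brute-force transcriptions of textbook definitions and stay
# deliberately naive so they share no code with the package internals.

# Harrell's C by exhaustive double loop over ordered pairs.
brute_cindex <- function(risk, time, event) {
  conc <- 0
  comp <- 0
  n <- length(risk)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      if (time[i] < time[j] && event[i] == 1) {
        comp <- comp + 1
        if (risk[i] > risk[j]) conc <- conc + 1
        if (risk[i] == risk[j]) conc <- conc + 0.5
      }
    }
  }
  list(c_index = conc / comp, comparable = comp, concordant = conc)
}

# AUC by exhaustive positive/negative pair counting.
brute_auc <- function(scores, truth) {
  pos <- scores[as.logical(truth)]
  neg <- scores[!as.logical(truth)]
  total <- 0
  for (p in pos) for (q in neg) {
    total <- total + (p > q) + 0.5 * (p == q)
  }
  total / (length(pos) * length(neg))
}

# Upper-tail hypergeometric p by enumerating every possible hit draw.
brute_hyper_p <- function(set_size, n_hits, universe_size, observed) {
  draws <- utils::combn(universe_size, n_hits)
  in_set <- seq_len(set_size)  # wlog the first set_size elements are the set
  overlaps <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(overlaps >= observed)
}

# Calinski-Harabasz from the definition, all distances written out.
brute_ch <- function(x, labels) {
  n <- nrow(x)
  k <- length(unique(labels))
  grand <- colMeans(x)
  b <- 0
  w <- 0
  for (g in unique(labels)) {
    rows <- which(labels == g)
    centroid <- colMeans(x[rows, , drop = FALSE])
    b <- b + length(rows) * sum((centroid - grand)^2)
    for (i in rows) w <- w + sum((x[i, ] - centroid)^2)
  }
  (b / (k - 1)) / (w / (n - k))
}

# Mean silhouette width from the definition with explicit pair distances.
brute_silhouette <- function(x, labels) {
  n <- nrow(x)
  d <- as.matrix(stats::dist(x))
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- setdiff(which(labels == labels[i]), i)
    a <- if (length(own)) mean(d[i, own]) else 0
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(d[i, labels == g])
    }, 0))
    s[i] <- if (length(own)) (b - a) / max(a, b) else 0
  }
  mean(s)
}

# Per-base gene-level copy number: average the segment value over every base
# of the gene body, 0 where no segment covers a base.
brute_cna_gene_value <- function(segments, gene) {
  base_vals <- rep(NA_real_, gene$end - gene$start + 1)
  for (s in seq_len(nrow(segments))) {
    if (segments$chrom[s] != gene$chrom) next
    lo <- max(segments$start[s], gene$start)
    hi <- min(segments$end[s], gene$end)
    if (lo > hi) next
    base_vals[(lo - gene$start + 1):(hi - gene$start + 1)] <-
      segments$segment_mean[s]
  }
  if (all(is.na(base_vals))) 0 else mean(base_vals, na.rm = TRUE)
}

# Breslow partial log-likelihood of a univariate Cox model, written out.
brute_cox_loglik <- function(beta, x, time, event) {
  ll <- 0
  for (i in which(event == 1)) {
    risk_set <- which(time >= time[i])
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk_set])))
  }
  ll
}

# Two-group log-rank chi-square from the observed-minus-expected table.
brute_logrank_chisq <- function(group, time, event) {
  o_minus_e <- 0
  v <- 0
  for (t_ev in sort(unique(time[event == 1]))) {
    at_risk <- time >= t_ev
    n <- sum(at_risk)
    n1 <- sum(at_risk & group == 1)
    d <- sum(time == t_ev & event == 1)
    d1 <- sum(time == t_ev & event == 1 & group == 1)
    o_minus_e <- o_minus_e + d1 - d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  o_minus_e^2 / v
}

# random survival data with exponential event and censoring times
random_surv <- function(n, event_rate = 1, censor_rate = 0.5) {
  t_ev <- stats::rexp(n, event_rate)
  t_c <- stats::rexp(n, censor_rate)
  list(time = pmin(t_ev, t_c), event = as.integer(t_ev <= t_c))
}

# small labelled OmicsMatrix for classifier tests
toy_omics <- function(values, kind = "expression") {
  omics_matrix(values, omics_kind = kind)
}

# flatten / unflatten autoencoder parameters for finite differencing
ae_flatten <- function(model) {
  unlist(c(lapply(model$weights, as.vector),
           lapply(model$biases, as.vector)))
}

ae_unflatten <- function(model, theta) {
  pos <- 1
  for (i in seq_along(model$weights)) {
    len <- length(model$weights[[i]])
    model$weights[[i]][] <- theta[pos:(pos + len - 1)]
    pos <- pos + len
  }
  for (i in seq_along(model$biases)) {
    len <- length(model$biases[[i]])
    model$biases[[i]][] <- theta[pos:(pos + len - 1)]
    pos <- pos + len
  }
  model
}
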