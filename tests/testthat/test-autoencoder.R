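# Autoencoder: loss, forward pass, gradients, training, encoding and the
# survival-based selection of bottleneck features.

rand_omics <- function(n_feat, n_samp, seed = 1) {
  withr::with_seed(seed, {
    omics_matrix(matrix(rnorm(n_feat * n_samp), n_feat, n_samp,
                        dimnames = list(sprintf("f%d", seq_len(n_feat)),
                                        sprintf("s%d", seq_len(n_samp)))))
  })
}

test_that("Pseudo-Huber loss evaluates its closed form", {
  x <- c(1, -2, 0.5)
  expect_equal(pseudo_huber_loss(x, x), 0)
  expect_equal(pseudo_huber_loss(3, 0, delta = 1), sqrt(10) - 1)
  expect_error(pseudo_huber_loss(1, 1, delta = 0), "positive")
  # non-negative on random inputs, zero only at equality
  set.seed(61)
  for (r in 1:10) {
    a <- rnorm(5)
    b <- rnorm(5)
    expect_gt(pseudo_huber_loss(a, b, delta = runif(1, 0.1, 3)), 0)
  }
})

test_that("Pseudo-Huber interpolates quadratic and linear regimes", {
  for (delta in c(0.5, 1, 2)) {
    r_small <- 1e-3 * delta
    ratio_q <- pseudo_huber_loss(r_small, 0, delta) / (r_small^2 / 2)
    expect_equal(ratio_q, 1, tolerance = 0.01)
    r_big <- 1e3 * delta
    ratio_l <- pseudo_huber_loss(r_big, 0, delta) / (delta * r_big)
    expect_equal(ratio_l, 1, tolerance = 0.01)
  }
})

test_that("forward pass composes tanh layers as specified", {
  m <- ae_init(4, ae_config(hidden = c(3, 2, 3), seed = 2))
  # all-zero parameters: tanh(0) = 0 everywhere
  zero <- m
  zero$weights <- lapply(zero$weights, function(w) w * 0)
  fw <- ae_forward(zero, matrix(rnorm(8), 2, 4))
  expect_true(all(fw$reconstruction == 0))
  expect_true(all(fw$bottleneck == 0))

  # 1-1-1 toy with W = 1, b = 0: bottleneck = tanh(0.5)
  toy <- ae_init(1, ae_config(hidden = 1, seed = 3))
  toy$weights <- list(matrix(1), matrix(1))
  toy$biases <- list(0, 0)
  fw1 <- ae_forward(toy, matrix(0.5))
  expect_equal(fw1$bottleneck[1, 1], tanh(0.5), tolerance = 1e-12)
  expect_equal(fw1$reconstruction[1, 1], tanh(0.5))  # linear output layer

  expect_error(ae_forward(m, matrix(0, 1, 7)), "expects 4")
})

test_that("the default architecture yields a 100-wide bottleneck", {
  m <- ae_init(30, ae_config(seed = 4))
  expect_identical(m$layer_sizes, c(30L, 500L, 100L, 500L, 30L))
  fw <- ae_forward(m, matrix(rnorm(5 * 30), 5, 30))
  expect_identical(dim(fw$bottleneck), c(5L, 100L))
  expect_identical(dim(fw$reconstruction), c(5L, 30L))
})

test_that("analytic gradients match central finite differences", {
  set.seed(62)
  cfg <- ae_config(hidden = 3, delta = 0.8, l1 = 1e-3, l2 = 1e-2, seed = 5)
  model <- ae_init(5, cfg)              # a 5-3-5 network
  x <- matrix(rnorm(4 * 5), 4, 5)
  g <- prognae:::ae_gradients(model, x)
  analytic <- c(unlist(lapply(g$weights, as.vector)),
                unlist(lapply(g$biases, as.vector)))
  theta <- ae_flatten(model)
  eps <- 1e-6
  numeric_g <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (prognae:::ae_objective(ae_unflatten(model, up), x) -
       prognae:::ae_objective(ae_unflatten(model, dn), x)) / (2 * eps)
  }, 0)
  rel <- abs(analytic - numeric_g) / pmax(abs(numeric_g), 1e-8)
  expect_lt(max(rel), 1e-5)
})

test_that("tanh output layers are also differentiated correctly", {
  set.seed(63)
  cfg <- ae_config(hidden = 3, output_activation = "tanh", seed = 6)
  model <- ae_init(4, cfg)
  x <- matrix(rnorm(3 * 4) * 0.5, 3, 4)
  g <- prognae:::ae_gradients(model, x)
  analytic <- c(unlist(lapply(g$weights, as.vector)),
                unlist(lapply(g$biases, as.vector)))
  theta <- ae_flatten(model)
  eps <- 1e-6
  numeric_g <- vapply(seq_along(theta), function(i) {
    up <- theta; up[i] <- up[i] + eps
    dn <- theta; dn[i] <- dn[i] - eps
    (prognae:::ae_objective(ae_unflatten(model, up), x) -
       prognae:::ae_objective(ae_unflatten(model, dn), x)) / (2 * eps)
  }, 0)
  expect_lt(max(abs(analytic - numeric_g) / pmax(abs(numeric_g), 1e-8)),
            1e-5)
})

test_that("training reduces the loss on low-rank data, is seed-stable", {
  # rank-2 data: 20 features driven by 2 factors
  set.seed(64)
  factors <- matrix(rnorm(2 * 60), 2, 60)
  load <- matrix(rnorm(20 * 2), 20, 2)
  vals <- load %*% factors + 0.05 * matrix(rnorm(20 * 60), 20, 60)
  dimnames(vals) <- list(sprintf("f%d", 1:20), sprintf("s%d", 1:60))
  m <- omics_matrix(vals)
  cfg <- ae_config(hidden = c(8, 2, 8), learning_rate = 1e-3, epochs = 200,
                   seed = 7)
  fit <- ae_train(m, cfg)
  expect_lt(fit$training_log$loss[nrow(fit$training_log)],
            fit$training_log$loss[2])
  # determinism: bit-identical weights under the same seed
  fit2 <- ae_train(m, cfg)
  expect_identical(fit$weights, fit2$weights)
  expect_identical(fit$biases, fit2$biases)
})

test_that("a zero learning rate leaves the model at initialization", {
  m <- rand_omics(6, 40, seed = 65)
  cfg <- ae_config(hidden = 3, learning_rate = 0, epochs = 3, seed = 8)
  fit <- ae_train(m, cfg)
  init <- ae_init(6, cfg)
  expect_identical(fit$weights, init$weights)
})

test_that("encoding maps per sample and enforces feature identity", {
  m <- rand_omics(10, 25, seed = 66)
  cfg <- ae_config(hidden = c(6, 4, 6), epochs = 2, seed = 9)
  fit <- ae_train(m, cfg)
  lat <- ae_encode(fit, m)
  expect_identical(dim(lat$values), c(25L, 4L))
  expect_identical(lat$sample_ids, sample_ids(m))
  expect_false(any(lat$selected))

  # permuting samples permutes rows identically
  perm <- sample(ncol(m))
  m_perm <- omics_matrix(unclass(m)[, perm], omics_kind = "expression")
  lat_perm <- ae_encode(fit, m_perm)
  expect_equal(lat_perm$values, lat$values[perm, ])

  wrong <- rand_omics(10, 5, seed = 67)
  rownames(wrong) <- paste0("x", 1:10)
  expect_error(ae_encode(fit, omics_matrix(unclass(wrong))),
               "feature mismatch")
})

test_that("a trained bottleneck recovers a planted rank-1 factor", {
  set.seed(68)
  factor1 <- rnorm(80)
  load <- rnorm(12)
  vals <- outer(load, factor1) + 0.1 * matrix(rnorm(12 * 80), 12, 80)
  dimnames(vals) <- list(sprintf("f%d", 1:12), sprintf("s%d", 1:80))
  fit <- ae_train(omics_matrix(vals),
                  ae_config_adequate(hidden = c(6, 2, 6), seed = 10))
  lat <- ae_encode(fit, omics_matrix(vals))
  cors <- abs(cor(lat$values, factor1))
  expect_gte(max(cors), 0.8)
})

test_that("latent survival selection keeps planted signal, drops constants", {
  set.seed(69)
  n <- 200
  subtype <- rbinom(n, 1, 0.5)
  t_ev <- rexp(n, 0.1 * 4^subtype)
  t_c <- rexp(n, 0.05)
  surv <- survival_table(data.frame(
    sample_id = sprintf("s%d", 1:n),
    efs_time = pmin(t_ev, t_c), efs_event = as.integer(t_ev <= t_c),
    os_time = pmin(t_ev, t_c), os_event = as.integer(t_ev <= t_c)))
  lat <- structure(list(
    values = cbind(AE1 = subtype + rnorm(n, sd = 0.1),
                   AE2 = rep(2, n),           # constant -> excluded
                   AE3 = rnorm(n)),
    sample_ids = surv$sample_id,
    selected = rep(FALSE, 3)), class = "LatentMatrix")
  rownames(lat$values) <- surv$sample_id
  expect_warning(out <- select_prognostic_latent(lat, surv), "constant")
  expect_true(out$selected[1])
  expect_false(out$selected[2])
  expect_true(out$screen_report$degenerate[2])

  # all-noise latent space at tiny alpha: selection must refuse
  lat$values[, 1] <- rnorm(n)
  expect_error(
    suppressWarnings(select_prognostic_latent(lat, surv, alpha = 1e-6)),
    "inspect")
})

test_that("a latent subtype indicator with HR 4 is selected reliably", {
  set.seed(70)
  hits <- 0
  reps <- 60
  for (r in seq_len(reps)) {
    n <- 200
    subtype <- rbinom(n, 1, 0.5)
    t_ev <- rexp(n, 0.1 * 4^subtype)
    t_c <- rexp(n, 0.06)
    surv <- survival_table(data.frame(
      sample_id = sprintf("s%d", 1:n),
      efs_time = pmin(t_ev, t_c), efs_event = as.integer(t_ev <= t_c),
      os_time = pmin(t_ev, t_c), os_event = as.integer(t_ev <= t_c)))
    lat <- structure(list(values = cbind(AE1 = subtype + rnorm(n, sd = .2)),
                          sample_ids = surv$sample_id,
                          selected = FALSE), class = "LatentMatrix")
    rownames(lat$values) <- surv$sample_id
    got <- tryCatch(select_prognostic_latent(lat, surv)$selected[1],
                    error = function(e) FALSE)
    hits <- hits + got
  }
  expect_gte(hits / reps, 0.95)
})

test_that("the Cox-based latent selection variant runs", {
  set.seed(71)
  n <- 80
  surv <- survival_table(data.frame(
    sample_id = sprintf("s%d", 1:n), efs_time = rexp(n),
    efs_event = rbinom(n, 1, 0.8), os_time = rexp(n),
    os_event = rbinom(n, 1, 0.8)))
  lat <- structure(list(values = matrix(rnorm(n * 3), n, 3,
                                        dimnames = list(surv$sample_id,
                                                        paste0("AE", 1:3))),
                        sample_ids = surv$sample_id,
                        selected = rep(FALSE, 3)), class = "LatentMatrix")
  out <- tryCatch(select_prognostic_latent(lat, surv, alpha = 0.9,
                                           method = "cox"),
                  error = function(e) NULL)
  expect_true(is.null(out) || any(out$selected))
})
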