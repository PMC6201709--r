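# Fully connected autoencoder for multi-omics integration. The default
# architecture is input-500-100-500-input with tanh hidden units; the
# 100-unit bottleneck activations become the integrated features. Training
# minimizes the mean (over samples) Pseudo-Huber reconstruction loss plus
# elementwise L1/L2 penalties on the weights, by seeded minibatch gradient
# descent. Everything is plain matrix algebra so runs are reproducible
# bit-for-bit from the seed.

#' Autoencoder configuration
#'
#' @param hidden Hidden layer widths, symmetric with an odd count; the middle
#'   layer is the bottleneck (default `c(500, 100, 500)`).
#' @param delta Pseudo-Huber transition scale \eqn{\delta} (> 0). Residuals
#'   much smaller than `delta` are penalized quadratically, much larger ones
#'   linearly. Default 1, matching unit-variance (z-scored) inputs.
#' @param l1,l2 Weight penalty coefficients (loss adds
#'   `l1 * sum(|W|) + l2 * sum(W^2)`; biases are not penalized).
#' @param learning_rate Gradient-descent step size.
#' @param epochs Number of passes over the training samples.
#' @param batch_size Minibatch size; a final partial batch is used as-is.
#' @param output_activation `"linear"` (default) or `"tanh"`. Z-scored inputs
#'   are unbounded, which a tanh output unit cannot reconstruct; the linear
#'   default removes that ceiling while `"tanh"` applies the same squashing
#'   to every layer.
#' @param seed Integer seed governing initialization and batch shuffling.
#' @return A list of class `ae_config`.
#' @export
ae_config <- function(hidden = c(500, 100, 500), delta = 1,
                      l1 = 1e-4, l2 = 1e-3, learning_rate = 1e-6,
                      epochs = 10, batch_size = 32,
                      output_activation = c("linear", "tanh"), seed = 1) {
  output_activation <- match.arg(output_activation)
  if (length(hidden) %% 2 == 0) {
    stopf("`hidden` must have an odd number of layers (middle = bottleneck)")
  }
  if (delta <= 0) stopf("`delta` must be positive")
  if (l1 < 0 || l2 < 0) stopf("regularization coefficients must be >= 0")
  structure(list(hidden = as.integer(hidden), delta = delta, l1 = l1,
                 l2 = l2, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size),
                 output_activation = output_activation,
                 seed = as.integer(seed)),
            class = "ae_config")
}

#' Training profile with an adequate optimization budget
#'
#' The historical defaults (`learning_rate = 1e-6`, `epochs = 10`) describe a
#' very short training schedule under which freshly initialized weights
#' barely move; this preset raises the budget to `learning_rate = 1e-3`,
#' `epochs = 200` for work where the reconstruction actually needs to
#' converge, e.g. the synthetic-recovery experiments.
#'
#' @param ... Overrides passed on to [ae_config()].
#' @export
ae_config_adequate <- function(...) {
  args <- list(...)
  defaults <- list(learning_rate = 1e-3, epochs = 200)
  do.call(ae_config, utils::modifyList(defaults, args))
}

#' Pseudo-Huber reconstruction loss
#'
#' \deqn{L(x, x') = \sum_k \delta^2 (\sqrt{1 + ((x_k - x'_k)/\delta)^2} - 1)}
#' summed over the input dimensions: quadratic (r^2/2) for small residuals r,
#' linear (delta * |r|) for large ones, with continuous derivatives of all
#' orders.
#'
#' @param x,x_prime Input and reconstruction vectors of equal length.
#' @param delta Transition scale (> 0).
#' @return The non-negative scalar loss.
#' @export
pseudo_huber_loss <- function(x, x_prime, delta = 1) {
  if (delta <= 0) stopf("`delta` must be positive")
  if (length(x) != length(x_prime)) stopf("x and x_prime lengths differ")
  r <- (x - x_prime) / delta
  sum(delta^2 * (sqrt(1 + r^2) - 1))
}

# Glorot-uniform initialization of one weight matrix (fan_in x fan_out).
glorot <- function(fan_in, fan_out) {
  limit <- sqrt(6 / (fan_in + fan_out))
  matrix(stats::runif(fan_in * fan_out, -limit, limit), fan_in, fan_out)
}

#' Initialize an autoencoder model
#'
#' @param d_in Input dimension (number of stacked features).
#' @param config An [ae_config()].
#' @return List of class `ae_model` with `weights`, `biases`, `layer_sizes`,
#'   `config`, `feature_ids` (filled by [ae_train()]) and `training_log`.
#' @export
ae_init <- function(d_in, config = ae_config()) {
  sizes <- c(as.integer(d_in), config$hidden, as.integer(d_in))
  with_seed(config$seed, {
    weights <- lapply(seq_len(length(sizes) - 1), function(i) {
      glorot(sizes[i], sizes[i + 1])
    })
  })
  biases <- lapply(sizes[-1], function(k) numeric(k))
  structure(list(weights = weights, biases = biases, layer_sizes = sizes,
                 config = config, feature_ids = NULL,
                 training_log = data.frame()),
            class = "ae_model")
}

#' Forward pass
#'
#' Propagates a batch through the network: `tanh(x %*% W_i + b_i)` on every
#' hidden layer and the configured activation on the output layer.
#'
#' @param model An `ae_model`.
#' @param x Matrix of inputs, samples in rows (a vector is treated as one
#'   sample).
#' @return List with `reconstruction` (samples x d_in), `bottleneck`
#'   (samples x bottleneck width) and `activations` (all layer outputs,
#'   inputs first).
#' @export
ae_forward <- function(model, x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (ncol(x) != model$layer_sizes[1]) {
    stopf("input has %d features but the model expects %d",
          ncol(x), model$layer_sizes[1])
  }
  k <- length(model$weights)
  acts <- vector("list", k + 1)
  acts[[1]] <- x
  for (i in seq_len(k)) {
    z <- acts[[i]] %*% model$weights[[i]]
    z <- z + rep(model$biases[[i]], each = nrow(z))
    if (i < k || model$config$output_activation == "tanh") {
      acts[[i + 1]] <- tanh(z)
    } else {
      acts[[i + 1]] <- z
    }
  }
  mid <- (k %/% 2) + 1  # activations index of the middle hidden layer
  list(reconstruction = acts[[k + 1]], bottleneck = acts[[mid]],
       activations = acts)
}

# Total objective on a batch: mean-per-sample Pseudo-Huber + weight penalties.
ae_objective <- function(model, x) {
  fw <- ae_forward(model, x)
  r <- (x - fw$reconstruction) / model$config$delta
  sum(model$config$delta^2 * (sqrt(1 + r^2) - 1)) / nrow(x) +
    ae_penalty(model)
}

# Backpropagation of the batch objective. Returns gradients for every weight
# matrix and bias vector, plus the batch's mean reconstruction loss (a free
# by-product of the forward pass). The L1 subgradient at 0 is taken as 0
# (sign(0) = 0). With `include_penalty = FALSE` the penalty terms are left
# out so the caller can fold them into the update step.
ae_gradients <- function(model, x, include_penalty = TRUE) {
  cfg <- model$config
  fw <- ae_forward(model, x)
  acts <- fw$activations
  k <- length(model$weights)
  B <- nrow(x)
  # d(mean pseudo-huber)/d(reconstruction)
  resid <- fw$reconstruction - x
  root <- sqrt(1 + (resid / cfg$delta)^2)
  delta_out <- (resid / root) / B
  recon_loss <- sum(cfg$delta^2 * (root - 1)) / B
  gw <- vector("list", k)
  gb <- vector("list", k)
  d <- delta_out
  for (i in rev(seq_len(k))) {
    if (i < k || cfg$output_activation == "tanh") {
      d <- d * (1 - acts[[i + 1]]^2)
    }
    gw[[i]] <- crossprod(acts[[i]], d)
    if (include_penalty) {
      gw[[i]] <- gw[[i]] + cfg$l1 * sign(model$weights[[i]]) +
        2 * cfg$l2 * model$weights[[i]]
    }
    gb[[i]] <- colSums(d)
    if (i > 1) d <- tcrossprod(d, model$weights[[i]])
  }
  list(weights = gw, biases = gb, recon_loss = recon_loss)
}

# penalty part of the objective at the current weights
ae_penalty <- function(model) {
  model$config$l1 * sum(vapply(model$weights, function(w) sum(abs(w)), 0)) +
    model$config$l2 * sum(vapply(model$weights, function(w) sum(w^2), 0))
}

#' Train the autoencoder
#'
#' Seeded minibatch gradient descent on the batch objective (mean Pseudo-
#' Huber reconstruction loss plus weight penalties). Samples are reshuffled
#' every epoch; the final partial batch is used. Two runs with the same data
#' and configuration produce bit-identical weights.
#'
#' @param data An `OmicsMatrix` (features x samples), e.g. the stacked and
#'   screened multi-omics matrix; samples become training rows.
#' @param config An [ae_config()].
#' @return A trained `ae_model`; `training_log` holds the full-data objective
#'   after each epoch (epoch 0 = at initialization).
#' @export
ae_train <- function(data, config = ae_config()) {
  x <- t(unclass(data))  # samples in rows
  model <- ae_init(ncol(x), config)
  model$feature_ids <- rownames(data)
  dimnames(x) <- NULL   # keep weight matrices free of inherited dimnames
  n <- nrow(x)
  lr <- config$learning_rate
  log_loss <- numeric(config$epochs + 1)
  log_loss[1] <- ae_objective(model, x)
  with_seed(config$seed + 1L, {
    for (epoch in seq_len(config$epochs)) {
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_recon <- 0
      for (s in starts) {
        idx <- ord[s:min(s + config$batch_size - 1, n)]
        g <- ae_gradients(model, x[idx, , drop = FALSE],
                          include_penalty = FALSE)
        epoch_recon <- epoch_recon + g$recon_loss * length(idx)
        for (i in seq_along(model$weights)) {
          w <- model$weights[[i]]
          # data gradient plus the L2 (decay) and L1 penalty gradients
          model$weights[[i]] <- w * (1 - 2 * lr * config$l2) -
            lr * (g$weights[[i]] + config$l1 * sign(w))
          model$biases[[i]] <- model$biases[[i]] - lr * g$biases[[i]]
        }
      }
      # running loss: minibatch reconstruction losses averaged over the
      # epoch, plus the penalty at the epoch's final weights
      log_loss[epoch + 1] <- epoch_recon / n + ae_penalty(model)
      if (!is.finite(log_loss[epoch + 1])) {
        stopf("non-finite training loss at epoch %d; lower the learning rate",
              epoch)
      }
    }
  })
  model$training_log <- data.frame(epoch = 0:config$epochs, loss = log_loss)
  model
}

#' Encode samples into bottleneck features
#'
#' @param model A trained `ae_model`.
#' @param data An `OmicsMatrix` with exactly the features (ids and order) the
#'   model was trained on.
#' @return A `LatentMatrix`: list with `values` (samples x bottleneck width,
#'   latent features named `AE1`, `AE2`, ...), `sample_ids` and `selected`
#'   (logical mask, all `FALSE` until [select_prognostic_latent()]).
#' @export
ae_encode <- function(model, data) {
  if (!is.null(model$feature_ids) &&
      !identical(rownames(data), model$feature_ids)) {
    missing <- setdiff(model$feature_ids, rownames(data))
    extra <- setdiff(rownames(data), model$feature_ids)
    stopf("feature mismatch with the training matrix (missing: %s; extra: %s)",
          paste(utils::head(missing, 3), collapse = ","),
          paste(utils::head(extra, 3), collapse = ","))
  }
  fw <- ae_forward(model, t(unclass(data)))
  vals <- fw$bottleneck
  dimnames(vals) <- list(colnames(data), paste0("AE", seq_len(ncol(vals))))
  structure(list(values = vals, sample_ids = colnames(data),
                 selected = rep(FALSE, ncol(vals))),
            class = "LatentMatrix")
}

#' Select survival-associated latent features
#'
#' Dichotomizes each latent feature at its median across samples and runs a
#' two-group log-rank test against EFS and against OS; a feature is selected
#' when either endpoint's p-value falls below `alpha`. With
#' `method = "cox"`, a univariate Cox score test on the continuous feature
#' is used instead of median dichotomization.
#'
#' @param latent A `LatentMatrix` from [ae_encode()].
#' @param surv A [survival_table()] covering all encoded samples.
#' @param alpha Per-endpoint threshold (default 0.05).
#' @param method `"logrank_median"` (default) or `"cox"`.
#' @return The `LatentMatrix` with its `selected` mask updated and a
#'   `screen_report` element (data frame of per-feature p-values).
#' @export
select_prognostic_latent <- function(latent, surv, alpha = 0.05,
                                     method = c("logrank_median", "cox")) {
  method <- match.arg(method)
  assert_prob(alpha, "alpha")
  cl <- align_survival(surv, latent$sample_ids)
  p <- matrix(1, ncol(latent$values), 2,
              dimnames = list(colnames(latent$values), c("efs", "os")))
  degenerate <- logical(ncol(latent$values))
  for (j in seq_len(ncol(latent$values))) {
    v <- latent$values[, j]
    if (method == "logrank_median") {
      grp <- v > stats::median(v)
      if (all(grp) || !any(grp)) {
        degenerate[j] <- TRUE
        next
      }
      p[j, "efs"] <- logrank_two_group(grp, cl$efs_time, cl$efs_event)$p_value
      p[j, "os"] <- logrank_two_group(grp, cl$os_time, cl$os_event)$p_value
    } else {
      if (stats::var(v) == 0) {
        degenerate[j] <- TRUE
        next
      }
      p[j, "efs"] <- cox_univariate(v, cl$efs_time, cl$efs_event)$p_value
      p[j, "os"] <- cox_univariate(v, cl$os_time, cl$os_event)$p_value
    }
  }
  if (any(degenerate)) {
    warnf("%d constant latent feature(s) excluded from selection",
          sum(degenerate))
  }
  selected <- !degenerate & (p[, "efs"] < alpha | p[, "os"] < alpha)
  if (!any(selected)) {
    stopf(paste("no latent feature is survival-associated at alpha = %g;",
                "inspect autoencoder training"), alpha)
  }
  latent$selected <- unname(selected)
  latent$screen_report <- data.frame(feature = colnames(latent$values),
                                     p_efs = p[, "efs"], p_os = p[, "os"],
                                     degenerate = degenerate,
                                     selected = unname(selected),
                                     row.names = NULL)
  latent
}

#' Extract the selected latent feature matrix
#'
#' @param latent A `LatentMatrix` after [select_prognostic_latent()].
#' @return Numeric matrix, samples x selected features.
#' @export
latent_selected_values <- function(latent) {
  latent$values[, latent$selected, drop = FALSE]
}
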