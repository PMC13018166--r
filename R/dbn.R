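dbn_activations <- c("sigmoid", "relu", "leaky_relu", "swish")
dbn_optimizers <- c("sgd", "adam", "rmsprop", "nadam")
dbn_batch_sizes <- c(2L, 4L, 8L, 16L, 32L, 64L)

#' Deep Belief Network configuration
#'
#' Domains follow the hyperparameter search space: hidden layer widths in
#' `[2, 500]`, dropout in `[0, 0.5]` (0 disables dropout, for ablation; the
#' tuned range is 0.20-0.50), batch size one of 2/4/8/16/32/64, epochs in
#' `[50, 200]`. `learning_rate = 0` is admitted so that no-update runs can
#' be exercised.
#'
#' @param hidden_layer_sizes integer vector of hidden-layer widths.
#' @param dropout_rate dropout probability on hidden activations during
#'   fine-tuning.
#' @param activation hidden activation: sigmoid, relu, leaky_relu or swish.
#' @param optimizer sgd, adam, rmsprop or nadam.
#' @param learning_rate non-negative step size.
#' @param batch_size mini-batch size.
#' @param epochs fine-tuning epochs.
#' @param seed integer RNG seed governing initialization, shuffling, dropout.
#' @return a `dbn_config`.
#' @export
dbn_config <- function(hidden_layer_sizes = c(33L), dropout_rate = 0.30,
                       activation = "relu", optimizer = "adam",
                       learning_rate = 0.003, batch_size = 4L,
                       epochs = 100L, seed = 1L) {
  hidden_layer_sizes <- as.integer(hidden_layer_sizes)
  if (length(hidden_layer_sizes) == 0) {
    stop_hcadbn("at least one hidden layer is required", "hcadbn_config_error")
  }
  if (any(hidden_layer_sizes < 2L | hidden_layer_sizes > 500L)) {
    stop_hcadbn("hidden layer sizes must lie in [2, 500]",
                "hcadbn_config_error")
  }
  if (dropout_rate < 0 || dropout_rate > 0.5) {
    stop_hcadbn("dropout_rate must lie in [0, 0.5]", "hcadbn_config_error")
  }
  if (!activation %in% dbn_activations) {
    stop_hcadbn(sprintf("unknown activation '%s'", activation),
                "hcadbn_config_error")
  }
  if (!optimizer %in% dbn_optimizers) {
    stop_hcadbn(sprintf("unknown optimizer '%s'", optimizer),
                "hcadbn_config_error")
  }
  if (!(as.integer(batch_size) %in% dbn_batch_sizes)) {
    stop_hcadbn("batch_size must be one of 2, 4, 8, 16, 32, 64",
                "hcadbn_config_error")
  }
  if (learning_rate < 0) {
    stop_hcadbn("learning_rate must be non-negative", "hcadbn_config_error")
  }
  epochs <- as.integer(epochs)
  if (epochs < 50L || epochs > 200L) {
    stop_hcadbn("epochs must lie in [50, 200]", "hcadbn_config_error")
  }
  structure(list(hidden_layer_sizes = hidden_layer_sizes,
                 dropout_rate = dropout_rate, activation = activation,
                 optimizer = optimizer, learning_rate = learning_rate,
                 batch_size = as.integer(batch_size), epochs = epochs,
                 seed = assert_seed(seed)),
            class = "dbn_config")
}

#' Named DBN configuration presets
#'
#' `hca_initial` is the configuration found by the hill-climbing search
#' (single 33-unit RBM layer, dropout 0.2, ReLU, Adam, batch 2, learning
#' rate 0.003); `final_tuned` is the manually stabilized variant (batch 4,
#' dropout 0.30). Epochs default to 100, the midpoint of the tuned 50-200
#' range.
#'
#' @param name `"hca_initial"` or `"final_tuned"`.
#' @param seed integer RNG seed.
#' @param epochs fine-tuning epochs.
#' @return a `dbn_config`.
#' @export
dbn_preset <- function(name = c("final_tuned", "hca_initial"), seed = 1L,
                       epochs = 100L) {
  name <- match.arg(name)
  switch(name,
    hca_initial = dbn_config(hidden_layer_sizes = 33L, dropout_rate = 0.2,
                             activation = "relu", optimizer = "adam",
                             learning_rate = 0.003, batch_size = 2L,
                             epochs = epochs, seed = seed),
    final_tuned = dbn_config(hidden_layer_sizes = 33L, dropout_rate = 0.30,
                             activation = "relu", optimizer = "adam",
                             learning_rate = 0.003, batch_size = 4L,
                             epochs = epochs, seed = seed)
  )
}

#' Hidden-layer activation functions
#'
#' sigmoid(x); relu max(0, x); leaky_relu with slope 0.01 on the negative
#' side; swish x * sigmoid(x).
#'
#' @param kind activation name.
#' @param x numeric vector or matrix.
#' @return transformed values of the same shape.
#' @export
activation_fn <- function(kind, x) {
  switch(kind,
    sigmoid = sigmoid(x),
    relu = pmax(x, 0),
    leaky_relu = ifelse(x > 0, x, 0.01 * x),
    swish = x * sigmoid(x),
    stop_hcadbn(sprintf("unknown activation '%s'", kind),
                "hcadbn_config_error")
  )
}

activation_grad <- function(kind, x) {
  switch(kind,
    sigmoid = { s <- sigmoid(x); s * (1 - s) },
    relu = (x > 0) * 1,
    leaky_relu = ifelse(x > 0, 1, 0.01),
    swish = { s <- sigmoid(x); s + x * s * (1 - s) }
  )
}

#' Greedy layer-wise RBM pre-training of a DBN stack
#'
#' Trains one RBM per configured hidden layer with Contrastive Divergence:
#' the first on the `[0,1]` features, each subsequent one on the hidden
#' conditional probabilities of the layer below. Trained weights and hidden
#' biases are copied verbatim into the feed-forward stack; the supervised
#' head is initialized near zero and left unfitted.
#'
#' @param features numeric matrix in `[0,1]` (rows = samples).
#' @param config a `dbn_config`.
#' @param rbm_config an `rbm_train_config`; its seed is re-derived per layer.
#' @return an unfitted `dbn_model`.
#' @export
pretrain_stack <- function(features, config, rbm_config = rbm_train_config()) {
  features <- as.matrix(features)
  if (nrow(features) == 0) {
    stop_hcadbn("cannot pre-train on empty data", "hcadbn_empty_data_error")
  }
  layers <- vector("list", length(config$hidden_layer_sizes))
  rbms <- vector("list", length(config$hidden_layer_sizes))
  input <- features
  for (l in seq_along(config$hidden_layer_sizes)) {
    layer_cfg <- rbm_config
    layer_cfg$seed <- derive_seed(rbm_config$seed, l)
    fit <- pretrain_rbm(input, config$hidden_layer_sizes[l], layer_cfg)
    layers[[l]] <- list(W = fit$params$W, b = fit$params$b)
    rbms[[l]] <- fit
    input <- rbm_hidden_conditional(input, fit$params)
  }
  old <- .Random.seed_exists()
  set.seed(derive_seed(config$seed, 97L))
  n_last <- config$hidden_layer_sizes[length(config$hidden_layer_sizes)]
  head <- list(w = stats::rnorm(n_last, sd = 0.01), b = 0)
  .Random.seed_restore(old)
  structure(list(layers = layers, head = head, config = config,
                 input_dim = ncol(features), fitted = FALSE,
                 pretraining = rbms),
            class = "dbn_model")
}

#' @export
print.dbn_model <- function(x, ...) {
  cat(sprintf("<dbn_model> %d -> %s -> 1 (%s, %s)%s\n", x$input_dim,
              paste(x$config$hidden_layer_sizes, collapse = " -> "),
              x$config$activation, x$config$optimizer,
              if (x$fitted) " [fitted]" else " [unfitted head]"))
  invisible(x)
}

## Forward pass keeping pre-activations and activations for backprop.
## Dropout (inverted scaling) applies to hidden activations only and only
## when training = TRUE; it draws from the current RNG stream.
dbn_forward_full <- function(model, X, training = FALSE) {
  X <- if (is.matrix(X)) X else matrix(X, nrow = 1)
  if (ncol(X) != model$input_dim) {
    stop_hcadbn("feature dimension does not match model input",
                "hcadbn_dimension_error")
  }
  act <- model$config$activation
  keep <- 1 - if (training) model$config$dropout_rate else 0
  A <- X
  n_layers <- length(model$layers)
  Zs <- vector("list", n_layers)
  masks <- vector("list", n_layers)
  As <- vector("list", n_layers + 1)
  As[[1]] <- X
  for (l in seq_len(n_layers)) {
    Z <- sweep(A %*% model$layers[[l]]$W, 2, model$layers[[l]]$b, "+")
    A <- activation_fn(act, Z)
    if (training && keep < 1) {
      mask <- matrix(stats::runif(length(A)) < keep, nrow = nrow(A)) / keep
      A <- A * mask
      masks[[l]] <- mask
    }
    Zs[[l]] <- Z
    As[[l + 1]] <- A
  }
  z_out <- as.numeric(A %*% model$head$w) + model$head$b
  score <- sigmoid(z_out)
  list(score = score, z_out = z_out, Zs = Zs, As = As, masks = masks)
}

#' Forward pass through a DBN
#'
#' Hidden layers use the configured activation; the output unit is a
#' sigmoid, so the return value is the probability of the high-yield class.
#' Dropout masks are applied (with inverted scaling) only when
#' `training = TRUE`.
#'
#' @param model a `dbn_model`.
#' @param x feature vector of length p, or a matrix of rows.
#' @param training apply dropout (default FALSE).
#' @return numeric vector of class-1 probabilities.
#' @export
dbn_forward <- function(model, x, training = FALSE) {
  dbn_forward_full(model, x, training)$score
}

## Binary cross-entropy loss and full parameter gradients for one batch.
## Returns per-sample-mean gradients in the flat order:
## layer1 W, layer1 b, ..., head w, head b.
dbn_gradients <- function(model, X, y, training = FALSE) {
  fwd <- dbn_forward_full(model, X, training)
  B <- nrow(if (is.matrix(X)) X else matrix(X, nrow = 1))
  eps <- 1e-12
  s <- pmin(pmax(fwd$score, eps), 1 - eps)
  loss <- -mean(y * log(s) + (1 - y) * log(1 - s))
  dz_out <- (fwd$score - y) / B                 # d loss / d z_out
  A_last <- fwd$As[[length(fwd$As)]]
  g_head_w <- as.numeric(crossprod(A_last, dz_out))
  g_head_b <- sum(dz_out)
  dA <- outer(dz_out, model$head$w)
  grads <- vector("list", length(model$layers))
  act <- model$config$activation
  for (l in rev(seq_along(model$layers))) {
    if (!is.null(fwd$masks[[l]])) dA <- dA * fwd$masks[[l]]
    dZ <- dA * activation_grad(act, fwd$Zs[[l]])
    grads[[l]] <- list(W = crossprod(fwd$As[[l]], dZ), b = colSums(dZ))
    if (l > 1) dA <- dZ %*% t(model$layers[[l]]$W)
  }
  list(loss = loss, layer_grads = grads,
       head_grads = list(w = g_head_w, b = g_head_b))
}

new_optimizer_state <- function() list(t = 0L, slots = list())

#' One optimizer update on a list of parameter arrays
#'
#' Standard update rules: `sgd` is plain gradient descent; `adam` and
#' `nadam` use bias-corrected first/second moments (beta1 = 0.9,
#' beta2 = 0.999, eps = 1e-8); `rmsprop` uses a rho = 0.9 squared-gradient
#' accumulator.
#'
#' @param kind optimizer name.
#' @param params list of numeric arrays.
#' @param gradients list of arrays with matching shapes.
#' @param state optimizer state from a previous call, or
#'   `new_optimizer_state()`-shaped NULL on the first call.
#' @param learning_rate step size.
#' @return list with updated `params` and `state`.
#' @export
optimizer_step <- function(kind, params, gradients, state = NULL,
                           learning_rate = 0.001) {
  if (!kind %in% dbn_optimizers) {
    stop_hcadbn(sprintf("unknown optimizer '%s'", kind),
                "hcadbn_config_error")
  }
  if (is.null(state)) state <- new_optimizer_state()
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8; rho <- 0.9
  state$t <- state$t + 1L
  t <- state$t
  for (i in seq_along(params)) {
    g <- gradients[[i]]
    if (any(dim(g) %||% length(g) != (dim(params[[i]]) %||%
                                      length(params[[i]])))) {
      stop_hcadbn("gradient shape does not match parameter shape",
                  "hcadbn_dimension_error")
    }
    slot <- if (length(state$slots) >= i) state$slots[[i]] else NULL
    if (kind == "sgd") {
      params[[i]] <- params[[i]] - learning_rate * g
    } else if (kind %in% c("adam", "nadam")) {
      if (is.null(slot)) slot <- list(m = g * 0, v = g * 0)
      slot$m <- b1 * slot$m + (1 - b1) * g
      slot$v <- b2 * slot$v + (1 - b2) * g^2
      m_hat <- slot$m / (1 - b1^t)
      v_hat <- slot$v / (1 - b2^t)
      step <- if (kind == "adam") {
        m_hat
      } else {
        b1 * m_hat + (1 - b1) * g / (1 - b1^t)
      }
      params[[i]] <- params[[i]] - learning_rate * step / (sqrt(v_hat) + eps)
    } else if (kind == "rmsprop") {
      if (is.null(slot)) slot <- list(acc = g * 0)
      slot$acc <- rho * slot$acc + (1 - rho) * g^2
      params[[i]] <- params[[i]] - learning_rate * g / (sqrt(slot$acc) + eps)
    }
    state$slots[[i]] <- slot %||% list()
  }
  list(params = params, state = state)
}

flatten_model_params <- function(model) {
  out <- list()
  for (l in seq_along(model$layers)) {
    out[[length(out) + 1]] <- model$layers[[l]]$W
    out[[length(out) + 1]] <- model$layers[[l]]$b
  }
  out[[length(out) + 1]] <- model$head$w
  out[[length(out) + 1]] <- model$head$b
  out
}

unflatten_model_params <- function(model, flat) {
  k <- 1
  for (l in seq_along(model$layers)) {
    model$layers[[l]]$W <- flat[[k]]; k <- k + 1
    model$layers[[l]]$b <- flat[[k]]; k <- k + 1
  }
  model$head$w <- flat[[k]]
  model$head$b <- flat[[k + 1]]
  model
}

#' Supervised fine-tuning of a pre-trained DBN
#'
#' Minimizes binary cross-entropy by mini-batch backpropagation through the
#' stack and sigmoid head, with the configured optimizer, batch size and
#' epoch count. The per-epoch training loss is the sample-weighted mean of
#' the mini-batch losses observed during that epoch (the exact per-sample
#' mean at the parameters each batch saw); validation loss, when a validation set
#' is given, is computed at each epoch end without dropout. Deterministic
#' given the configuration seed.
#'
#' @param model an unfitted `dbn_model` from [pretrain_stack()].
#' @param train a `labeled_dataset` containing both classes.
#' @param validation optional `labeled_dataset` for the validation trace.
#' @return list with `model` (fitted) and `trace` (data frame of epoch,
#'   train_loss, validation_loss).
#' @export
fine_tune <- function(model, train, validation = NULL) {
  stopifnot(inherits(model, "dbn_model"), inherits(train, "labeled_dataset"))
  if (length(unique(train$labels)) < 2) {
    stop_hcadbn("fine-tuning requires both classes in the training set",
                "hcadbn_single_class_error")
  }
  cfg <- model$config
  n <- length(train$labels)
  old <- .Random.seed_exists()
  set.seed(derive_seed(cfg$seed, 211L))
  state <- NULL
  train_loss <- numeric(cfg$epochs)
  val_loss <- rep(NA_real_, cfg$epochs)
  for (epoch in seq_len(cfg$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = cfg$batch_size)
    batch_losses <- numeric(length(starts))
    batch_sizes <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + cfg$batch_size - 1, n)]
      gr <- dbn_gradients(model, train$features[idx, , drop = FALSE],
                          train$labels[idx], training = TRUE)
      if (!is.finite(gr$loss)) {
        .Random.seed_restore(old)
        stop_hcadbn("non-finite training loss", "hcadbn_training_error")
      }
      batch_losses[s] <- gr$loss
      batch_sizes[s] <- length(idx)
      flat_g <- c(unlist(lapply(gr$layer_grads, function(g) list(g$W, g$b)),
                         recursive = FALSE),
                  list(gr$head_grads$w, gr$head_grads$b))
      upd <- optimizer_step(cfg$optimizer, flatten_model_params(model),
                            flat_g, state, cfg$learning_rate)
      model <- unflatten_model_params(model, upd$params)
      state <- upd$state
    }
    # sample-weighted so the epoch loss is the exact per-sample mean
    train_loss[epoch] <- sum(batch_losses * batch_sizes) / n
    if (!is.null(validation)) {
      vs <- dbn_forward(model, validation$features, training = FALSE)
      eps <- 1e-12
      vs <- pmin(pmax(vs, eps), 1 - eps)
      val_loss[epoch] <- -mean(validation$labels * log(vs) +
                                 (1 - validation$labels) * log(1 - vs))
    }
  }
  .Random.seed_restore(old)
  model$fitted <- TRUE
  list(model = model,
       trace = data.frame(epoch = seq_len(cfg$epochs),
                          train_loss = train_loss,
                          validation_loss = val_loss))
}

#' Predict yield classes from a fitted DBN
#'
#' @param object a fitted `dbn_model`.
#' @param features numeric matrix of scaled predictors.
#' @param threshold score cut-off; label 1 iff score >= threshold.
#' @param ... unused.
#' @return list with `labels` (0/1 integer) and `scores` (class-1
#'   probabilities, for ROC analysis).
#' @export
predict.dbn_model <- function(object, features, threshold = 0.5, ...) {
  if (!isTRUE(object$fitted)) {
    stop_hcadbn("model head has not been fine-tuned; call fine_tune() first",
                "hcadbn_state_error")
  }
  scores <- dbn_forward(object, features, training = FALSE)
  list(labels = as.integer(scores >= threshold), scores = scores)
}

#' Pre-train and fine-tune a DBN in one call
#'
#' Convenience wrapper: greedy RBM pre-training on the training features
#' followed by supervised fine-tuning.
#'
#' @param train a `labeled_dataset` with features in `[0,1]`.
#' @param config a `dbn_config`.
#' @param rbm_config an `rbm_train_config`.
#' @param validation optional `labeled_dataset`.
#' @return as [fine_tune()].
#' @export
train_dbn <- function(train, config = dbn_preset("final_tuned"),
                      rbm_config = rbm_train_config(seed = config$seed),
                      validation = NULL) {
  model <- pretrain_stack(train$features, config, rbm_config)
  fine_tune(model, train, validation)
}
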