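#' Restricted Boltzmann Machine parameters
#'
#' Holds the parameter set theta = {W, a, b}: pairwise weights `W` (visible
#' x hidden), visible biases `a` and hidden biases `b`. Visible units accept
#' real values in `[0,1]` interpreted as Bernoulli means (min-max-scaled
#' traits); hidden units are binary.
#'
#' @param W numeric matrix, m visible x n hidden.
#' @param a numeric vector of m visible biases.
#' @param b numeric vector of n hidden biases.
#' @return an `rbm_params` object.
#' @export
rbm_params <- function(W, a, b) {
  W <- as.matrix(W)
  if (length(a) != nrow(W) || length(b) != ncol(W)) {
    stop_hcadbn("rbm_params shapes inconsistent", "hcadbn_dimension_error")
  }
  if (!all(is.finite(W)) || !all(is.finite(a)) || !all(is.finite(b))) {
    stop_hcadbn("rbm_params entries must be finite", "hcadbn_validation_error")
  }
  structure(list(W = W, a = as.numeric(a), b = as.numeric(b)),
            class = "rbm_params")
}

#' @export
print.rbm_params <- function(x, ...) {
  cat(sprintf("<rbm_params> %d visible x %d hidden\n",
              nrow(x$W), ncol(x$W)))
  invisible(x)
}

#' RBM training configuration for Contrastive Divergence
#'
#' @param cd_steps number of Gibbs steps K in CD-K (default 1).
#' @param learning_rate positive step size.
#' @param batch_size mini-batch size.
#' @param epochs full passes over the data.
#' @param seed integer RNG seed.
#' @param init_scale SD of the Normal(0, init_scale) weight initialization.
#' @param mean_field_visible use visible probabilities instead of samples in
#'   the Gibbs chain (default FALSE: sampled).
#' @return an `rbm_train_config`.
#' @export
rbm_train_config <- function(cd_steps = 1, learning_rate = 0.01,
                             batch_size = 8, epochs = 30, seed = 1,
                             init_scale = 0.01, mean_field_visible = FALSE) {
  stopifnot(cd_steps >= 1, learning_rate >= 0, batch_size >= 1, epochs >= 0,
            init_scale > 0)
  structure(list(cd_steps = as.integer(cd_steps),
                 learning_rate = learning_rate,
                 batch_size = as.integer(batch_size),
                 epochs = as.integer(epochs), seed = assert_seed(seed),
                 init_scale = init_scale,
                 mean_field_visible = isTRUE(mean_field_visible)),
            class = "rbm_train_config")
}

#' Serialize RBM parameters to a shape-annotated JSON artifact
#'
#' @param params an `rbm_params`.
#' @param path file path.
#' @return `read_rbm_params` returns the reconstructed `rbm_params`.
#' @export
write_rbm_params <- function(params, path) {
  stopifnot(inherits(params, "rbm_params"))
  jsonlite::write_json(
    list(shape = dim(params$W), W = as.numeric(params$W),
         a = params$a, b = params$b),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_rbm_params
#' @export
read_rbm_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rbm_params(matrix(p$W, p$shape[1], p$shape[2]), p$a, p$b)
}

check_rbm_shapes <- function(v, h, params) {
  if (length(v) != nrow(params$W) || length(h) != ncol(params$W)) {
    stop_hcadbn("configuration shape does not match rbm_params",
                "hcadbn_dimension_error")
  }
}

#' RBM energy of a joint configuration
#'
#' E(v, h) = -sum_i a_i v_i - sum_j b_j h_j - sum_ij v_i w_ij h_j.
#'
#' @param v visible configuration (binary or `[0,1]` vector of length m).
#' @param h hidden configuration (binary vector of length n).
#' @param params an `rbm_params`.
#' @return scalar energy.
#' @export
rbm_energy <- function(v, h, params) {
  check_rbm_shapes(v, h, params)
  -sum(params$a * v) - sum(params$b * h) -
    as.numeric(t(v) %*% params$W %*% h)
}

rbm_enumeration_guard <- function(params, limit = 20L) {
  m <- nrow(params$W); n <- ncol(params$W)
  if (m + n > limit) {
    stop_hcadbn(sprintf(
      "exact enumeration refused: m + n = %d exceeds %d units", m + n, limit),
      "hcadbn_intractable_enumeration_error")
  }
  invisible(c(m = m, n = n))
}

## Log of the unnormalized marginal weight of each visible state
## ("negative free energy"): a.v + sum_j log(1 + exp(b_j + v.W_j)).
rbm_log_unnorm_visible <- function(V, params) {
  act <- sweep(V %*% params$W, 2, params$b, "+")
  softplus <- pmax(act, 0) + log1p(exp(-abs(act)))  # overflow-safe
  as.numeric(V %*% params$a) + rowSums(softplus)
}

#' Exact RBM partition function by enumeration
#'
#' Z = sum over all 2^(m+n) binary configurations of exp(-E), computed in
#' log space (marginalizing the hidden layer analytically per visible state
#' and log-sum-exp over visible states). Refuses models with m + n > 20.
#'
#' @param params an `rbm_params` with m + n <= 20.
#' @param log return log(Z) instead of Z.
#' @return scalar partition function (or its log).
#' @export
rbm_partition_function <- function(params, log = FALSE) {
  mn <- rbm_enumeration_guard(params)
  V <- binary_states(mn[["m"]])
  lz <- logsumexp(rbm_log_unnorm_visible(V, params))
  if (log) lz else exp(lz)
}

#' Exact joint probability of a configuration
#'
#' P(v, h) = exp(-E(v, h)) / Z via the Boltzmann distribution; only defined
#' for models small enough to enumerate (m + n <= 20).
#'
#' @inheritParams rbm_energy
#' @return probability in `[0,1]`.
#' @export
rbm_joint_probability <- function(v, h, params) {
  rbm_enumeration_guard(params)
  exp(-rbm_energy(v, h, params) - rbm_partition_function(params, log = TRUE))
}

#' Hidden-layer conditional activation probabilities
#'
#' With no intra-layer connections, hidden units are conditionally
#' independent: P(h_j = 1 | v) = sigmoid(b_j + sum_i v_i w_ij).
#'
#' @param v visible vector of length m, or a batch matrix (rows = cases).
#' @param params an `rbm_params`.
#' @return probability vector of length n (or batch matrix).
#' @export
rbm_hidden_conditional <- function(v, params) {
  V <- if (is.matrix(v)) v else matrix(v, nrow = 1)
  if (ncol(V) != nrow(params$W)) {
    stop_hcadbn("visible vector length does not match rbm_params",
                "hcadbn_dimension_error")
  }
  p <- sigmoid(sweep(V %*% params$W, 2, params$b, "+"))
  if (is.matrix(v)) p else as.numeric(p)
}

#' Visible-layer conditional activation probabilities
#'
#' P(v_i = 1 | h) = sigmoid(a_i + sum_j h_j w_ij).
#'
#' @param h hidden vector of length n, or a batch matrix (rows = cases).
#' @param params an `rbm_params`.
#' @return probability vector of length m (or batch matrix).
#' @export
rbm_visible_conditional <- function(h, params) {
  H <- if (is.matrix(h)) h else matrix(h, nrow = 1)
  if (ncol(H) != ncol(params$W)) {
    stop_hcadbn("hidden vector length does not match rbm_params",
                "hcadbn_dimension_error")
  }
  p <- sigmoid(sweep(H %*% t(params$W), 2, params$a, "+"))
  if (is.matrix(h)) p else as.numeric(p)
}

sample_bernoulli <- function(p) {
  u <- stats::runif(length(p))
  out <- (u < p) * 1
  if (is.matrix(p)) matrix(out, nrow = nrow(p)) else out
}

#' One block Gibbs sampling step
#'
#' Samples h from P(h | v), then v' from P(v | h) (or takes the visible
#' mean field when `mean_field_visible` is set). Uses the current R RNG
#' stream; seed it with `set.seed()` for reproducible chains.
#'
#' @param v visible state vector or batch matrix.
#' @param params an `rbm_params`.
#' @param mean_field_visible return visible probabilities instead of samples.
#' @return list with `v_new`, `h_sample`, `h_prob`, `v_prob`.
#' @export
rbm_gibbs_step <- function(v, params, mean_field_visible = FALSE) {
  h_prob <- rbm_hidden_conditional(v, params)
  h_sample <- sample_bernoulli(h_prob)
  v_prob <- rbm_visible_conditional(h_sample, params)
  v_new <- if (mean_field_visible) v_prob else sample_bernoulli(v_prob)
  list(v_new = v_new, h_sample = h_sample, h_prob = h_prob, v_prob = v_prob)
}

#' One Contrastive Divergence CD-K parameter update
#'
#' The positive (data) phase uses hidden probabilities; the negative
#' (reconstruction) phase runs K Gibbs steps from the data. Updates are
#' averaged over the mini-batch:
#' `dW = lr * (<v h>_data - <v h>_recon) / batch_size`, analogously for the
#' biases.
#'
#' @param batch mini-batch matrix (rows = cases, values in `[0,1]`).
#' @param params an `rbm_params`.
#' @param config an `rbm_train_config` (uses `cd_steps`, `learning_rate`,
#'   `mean_field_visible`).
#' @return updated `rbm_params`.
#' @export
cd_k_update <- function(batch, params, config) {
  batch <- if (is.matrix(batch)) batch else matrix(batch, nrow = 1)
  if (any(batch < 0 | batch > 1)) {
    stop_hcadbn("CD batch values must lie in [0,1]", "hcadbn_validation_error")
  }
  B <- nrow(batch)
  ph0 <- rbm_hidden_conditional(batch, params)
  vk <- batch
  for (k in seq_len(config$cd_steps)) {
    step <- rbm_gibbs_step(vk, params, config$mean_field_visible)
    vk <- step$v_new
  }
  phk <- rbm_hidden_conditional(vk, params)
  lr <- config$learning_rate
  rbm_params(
    W = params$W + lr * (crossprod(batch, ph0) - crossprod(vk, phk)) / B,
    a = params$a + lr * colMeans(batch - vk),
    b = params$b + lr * colMeans(ph0 - phk)
  )
}

#' Exact log-likelihood gradient by enumeration
#'
#' Gradient of the mean marginal log-likelihood `mean_rows log P(v)` with
#' respect to theta, computed exactly: the data term averages conditional
#' hidden activations over the data rows; the model term enumerates all
#' visible states (m + n <= 20). Serves as the oracle against which CD-K
#' updates are checked.
#'
#' @param params an `rbm_params`.
#' @param data matrix of visible configurations (rows = cases).
#' @return list with `dW`, `da`, `db` matching the shapes of theta.
#' @export
rbm_exact_gradient <- function(params, data) {
  rbm_enumeration_guard(params)
  data <- if (is.matrix(data)) data else matrix(data, nrow = 1)
  B <- nrow(data)
  ph_data <- rbm_hidden_conditional(data, params)
  V <- binary_states(nrow(params$W))
  lw <- rbm_log_unnorm_visible(V, params)
  pv <- exp(lw - logsumexp(lw))
  ph_model <- rbm_hidden_conditional(V, params)
  list(
    dW = crossprod(data, ph_data) / B - crossprod(V * pv, ph_model),
    da = colMeans(data) - as.numeric(t(V) %*% pv),
    db = colMeans(ph_data) - as.numeric(t(ph_model) %*% pv)
  )
}

#' Exact mean log-likelihood of visible data under an RBM
#'
#' @param params an `rbm_params` with m + n <= 20.
#' @param data matrix of visible configurations.
#' @return mean over rows of log P(v).
#' @export
rbm_loglik <- function(params, data) {
  rbm_enumeration_guard(params)
  data <- if (is.matrix(data)) data else matrix(data, nrow = 1)
  lz <- rbm_partition_function(params, log = TRUE)
  mean(rbm_log_unnorm_visible(data, params)) - lz
}

#' Pre-train an RBM with Contrastive Divergence
#'
#' Initializes W ~ Normal(0, init_scale) with zero biases, then runs
#' `epochs` passes of mini-batch CD-K over shuffled data. Reconstruction
#' error (mean squared error between each batch and its one-pass mean-field
#' reconstruction) is tracked per epoch for monitoring; it is not a training
#' objective.
#'
#' @param data matrix of visible data in `[0,1]` (rows = cases).
#' @param n_hidden number of hidden units.
#' @param config an `rbm_train_config`.
#' @return list with `params` (trained `rbm_params`) and
#'   `reconstruction_error` (numeric vector, one entry per epoch).
#' @export
pretrain_rbm <- function(data, n_hidden, config = rbm_train_config()) {
  data <- as.matrix(data)
  if (nrow(data) == 0) {
    stop_hcadbn("cannot pre-train on empty data", "hcadbn_empty_data_error")
  }
  if (any(data < 0 | data > 1)) {
    stop_hcadbn("pre-training data must lie in [0,1]",
                "hcadbn_validation_error")
  }
  m <- ncol(data)
  old <- .Random.seed_exists()
  set.seed(config$seed)
  params <- rbm_params(
    W = matrix(stats::rnorm(m * n_hidden, sd = config$init_scale),
               m, n_hidden),
    a = rep(0, m), b = rep(0, n_hidden)
  )
  recon <- numeric(config$epochs)
  n <- nrow(data)
  for (epoch in seq_len(config$epochs)) {
    ord <- sample.int(n)
    starts <- seq(1, n, by = config$batch_size)
    errs <- numeric(length(starts))
    for (s in seq_along(starts)) {
      idx <- ord[starts[s]:min(starts[s] + config$batch_size - 1, n)]
      batch <- data[idx, , drop = FALSE]
      params <- cd_k_update(batch, params, config)
      vrec <- rbm_visible_conditional(
        rbm_hidden_conditional(batch, params), params)
      errs[s] <- mean((batch - vrec)^2)
    }
    recon[epoch] <- mean(errs)
  }
  .Random.seed_restore(old)
  list(params = params, reconstruction_error = recon)
}
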