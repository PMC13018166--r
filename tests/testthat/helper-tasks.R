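# Shared fixtures, all generated in code.

# Synthetic yield task, preprocessed the way the pipeline does it:
# sqrt transform, stratified split, min-max scaling on train statistics.
make_yield_task <- function(n = 159, seed = 11, split_seed = seed + 1,
                            noise_sd = 0.25, train_fraction = 0.8) {
  g <- generate_trait_table(generator_spec(n = n, seed = seed,
                                           noise_sd = noise_sd))
  tt <- hcadbn:::transform_predictors(g$table, "sqrt")
  ds <- dataset_from_table(tt)
  sp <- stratified_split(ds, train_fraction, seed = split_seed)
  sc <- suppressWarnings(fit_minmax(sp$train$features))
  list(
    train = labeled_dataset(apply_minmax(sp$train$features, sc),
                            sp$train$labels, ds$feature_codes),
    test = labeled_dataset(apply_minmax(sp$test$features, sc),
                           sp$test$labels, ds$feature_codes),
    ds = ds, ground_truth = g$ground_truth
  )
}

# Linearly separable 2-feature task in [0,1]^2 with a margin.
make_separable_task <- function(n = 200, seed = 5, margin = 0.1) {
  set.seed(seed)
  x1 <- runif(n); x2 <- runif(n)
  y <- as.integer(x1 + x2 > 1)
  keep <- abs(x1 + x2 - 1) > margin
  labeled_dataset(cbind(f1 = x1[keep], f2 = x2[keep]), y[keep])
}

# A DBN model built directly from given/random weights (no pre-training),
# for gradient checks and predictor-construction tests.
make_raw_dbn <- function(p, sizes, activation = "relu", seed = 1,
                         scale = 0.5, fitted = TRUE,
                         dropout_rate = 0, optimizer = "sgd") {
  set.seed(seed)
  layers <- list()
  d <- p
  for (s in sizes) {
    layers[[length(layers) + 1]] <- list(
      W = matrix(rnorm(d * s, sd = scale), d, s),
      b = rnorm(s, sd = scale))
    d <- s
  }
  cfg <- dbn_config(hidden_layer_sizes = sizes, dropout_rate = dropout_rate,
                    activation = activation, optimizer = optimizer,
                    learning_rate = 0.01, batch_size = 4, epochs = 50,
                    seed = seed)
  structure(list(layers = layers,
                 head = list(w = rnorm(d, sd = scale), b = rnorm(1, sd = scale)),
                 config = cfg, input_dim = p, fitted = fitted,
                 pretraining = NULL),
            class = "dbn_model")
}

# Central-finite-difference gradient of the BCE loss w.r.t. every model
# parameter; independent oracle for the analytic backprop gradients.
numeric_dbn_gradients <- function(model, X, y, eps = 1e-6) {
  loss_at <- function(flat) {
    hcadbn:::dbn_gradients(hcadbn:::unflatten_model_params(model, flat),
                           X, y)$loss
  }
  flat <- hcadbn:::flatten_model_params(model)
  lapply(seq_along(flat), function(k) {
    g <- flat[[k]]
    for (i in seq_along(flat[[k]])) {
      up <- flat; up[[k]][i] <- up[[k]][i] + eps
      dn <- flat; dn[[k]][i] <- dn[[k]][i] - eps
      g[i] <- (loss_at(up) - loss_at(dn)) / (2 * eps)
    }
    g
  })
}

# Write a small trait-table CSV (all 27 schema columns) and return the path.
write_tiny_csv <- function(n = 3, seed = 1, drop_col = NULL,
                           mangle = NULL, path = tempfile(fileext = ".csv")) {
  g <- generate_trait_table(generator_spec(n = max(n, 20), seed = seed))
  df <- g$table$data[seq_len(n), , drop = FALSE]
  if (!is.null(drop_col)) df[[drop_col]] <- NULL
  df <- format(df, digits = 15, trim = TRUE, scientific = FALSE)
  if (!is.null(mangle)) df[[mangle]][1] <- "oops"
  utils::write.table(df, path, sep = ",", row.names = FALSE, quote = FALSE)
  path
}

binary_states_mat <- function(k) hcadbn:::binary_states(k)
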