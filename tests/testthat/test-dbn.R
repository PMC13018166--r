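test_that("configuration domains are enforced and presets match", {
  expect_error(dbn_config(hidden_layer_sizes = 1), class = "hcadbn_config_error")
  expect_error(dbn_config(hidden_layer_sizes = 501), class = "hcadbn_config_error")
  expect_error(dbn_config(dropout_rate = 0.6), class = "hcadbn_config_error")
  expect_error(dbn_config(batch_size = 3), class = "hcadbn_config_error")
  expect_error(dbn_config(epochs = 20), class = "hcadbn_config_error")
  expect_error(dbn_config(activation = "tanh"), class = "hcadbn_config_error")
  expect_error(dbn_config(optimizer = "adagrad"), class = "hcadbn_config_error")

  hi <- dbn_preset("hca_initial")
  expect_equal(hi$hidden_layer_sizes, 33L)
  expect_equal(hi$dropout_rate, 0.2)
  expect_equal(hi$activation, "relu")
  expect_equal(hi$optimizer, "adam")
  expect_equal(hi$batch_size, 2L)
  expect_equal(hi$learning_rate, 0.003)
  ft <- dbn_preset("final_tuned")
  expect_equal(ft$dropout_rate, 0.30)
  expect_equal(ft$batch_size, 4L)
  expect_equal(ft$hidden_layer_sizes, 33L)
})

test_that("activation functions follow their definitions", {
  expect_equal(activation_fn("relu", c(-2, 0, 3)), c(0, 0, 3))
  expect_equal(activation_fn("sigmoid", 0), 0.5)
  expect_equal(activation_fn("leaky_relu", c(-1, 2)), c(-0.01, 2))
  expect_equal(activation_fn("swish", 0), 0)
  expect_equal(activation_fn("swish", 30), 30 / (1 + exp(-30)))
  expect_error(activation_fn("tanh", 1), class = "hcadbn_config_error")
})

test_that("greedy pre-training chains layer shapes and copies RBM weights", {
  set.seed(61)
  X <- matrix(runif(40 * 26), 40, 26)
  cfg1 <- dbn_config(hidden_layer_sizes = 33L, seed = 2)
  rbm_cfg <- rbm_train_config(epochs = 3, seed = 5)
  m1 <- pretrain_stack(X, cfg1, rbm_cfg)
  expect_equal(dim(m1$layers[[1]]$W), c(26L, 33L))
  expect_false(m1$fitted)
  # exact weight transfer from the trained RBM
  expect_identical(m1$layers[[1]]$W, m1$pretraining[[1]]$params$W)
  expect_identical(m1$layers[[1]]$b, m1$pretraining[[1]]$params$b)

  cfg2 <- dbn_config(hidden_layer_sizes = c(4L, 3L), seed = 2)
  m2 <- pretrain_stack(X, cfg2, rbm_cfg)
  expect_equal(dim(m2$layers[[1]]$W), c(26L, 4L))
  expect_equal(dim(m2$layers[[2]]$W), c(4L, 3L))

  m1b <- pretrain_stack(X, cfg1, rbm_cfg)
  expect_identical(m1$layers, m1b$layers)
  expect_identical(m1$head, m1b$head)
})

test_that("forward pass is a sigmoid-headed network with inverted dropout", {
  m <- make_raw_dbn(3, c(2), seed = 71)
  m$layers[[1]]$W[] <- 0; m$layers[[1]]$b[] <- 0
  m$head$w[] <- 0; m$head$b <- 0
  expect_equal(dbn_forward(m, c(0.2, 0.9, 0.4)), 0.5)

  m2 <- make_raw_dbn(3, c(5), seed = 72)
  x <- matrix(runif(30), 10, 3)
  s_inf <- dbn_forward(m2, x, training = FALSE)
  set.seed(1)
  s_tr <- dbn_forward(m2, x, training = TRUE)  # dropout_rate 0
  expect_identical(s_inf, s_tr)
  expect_true(all(s_inf > 0 & s_inf < 1))
  expect_error(dbn_forward(m2, matrix(0, 2, 4)),
               class = "hcadbn_dimension_error")
})

test_that("backprop gradients match central finite differences", {
  set.seed(81)
  X <- matrix(runif(18), 6, 3)
  y <- c(0, 1, 1, 0, 1, 0)
  for (act in c("sigmoid", "relu", "leaky_relu", "swish")) {
    m <- make_raw_dbn(3, c(2), activation = act, seed = 82)
    an <- hcadbn:::dbn_gradients(m, X, y)
    flat_an <- c(unlist(lapply(an$layer_grads, function(g) list(g$W, g$b)),
                        recursive = FALSE),
                 list(an$head_grads$w, an$head_grads$b))
    num <- numeric_dbn_gradients(m, X, y)
    for (k in seq_along(num)) {
      denom <- pmax(abs(num[[k]]), 1e-3)
      expect_lt(max(abs(flat_an[[k]] - num[[k]]) / denom), 1e-5,
                label = sprintf("%s slot %d rel err", act, k))
    }
  }
})

test_that("optimizer updates follow the canonical rules", {
  p <- list(matrix(1, 2, 2))
  z <- list(matrix(0, 2, 2))
  for (kind in c("sgd", "adam", "rmsprop", "nadam")) {
    out <- optimizer_step(kind, p, z, NULL, 0.1)
    expect_equal(out$params[[1]], p[[1]], info = kind)
  }
  # adam first step is approximately the learning rate (bias correction)
  out <- optimizer_step("adam", list(0), list(1), NULL, 0.1)
  expect_equal(out$params[[1]], -0.1, tolerance = 1e-6)
  # sgd exact rule
  out2 <- optimizer_step("sgd", list(2), list(0.5), NULL, 0.1)
  expect_equal(out2$params[[1]], 1.95)
  # distinct optimizers produce distinct trajectories on the same gradients
  traj <- lapply(c("adam", "rmsprop", "nadam", "sgd"), function(kind) {
    pars <- list(c(0.5, -0.5)); st <- NULL
    for (i in 1:5) {
      upd <- optimizer_step(kind, pars, list(c(1, -2) * i), st, 0.05)
      pars <- upd$params; st <- upd$state
    }
    pars[[1]]
  })
  expect_equal(anyDuplicated(sapply(traj, paste, collapse = ",")), 0L)
  expect_error(optimizer_step("adagrad", p, z, NULL, 0.1),
               class = "hcadbn_config_error")
  expect_error(optimizer_step("sgd", p, list(matrix(0, 3, 2)), NULL, 0.1),
               class = "hcadbn_dimension_error")
})

test_that("fine-tuning learns a separable task and respects zero lr", {
  ds <- make_separable_task(n = 260, seed = 91)
  cfg <- dbn_config(hidden_layer_sizes = 8L, dropout_rate = 0,
                    activation = "relu", optimizer = "adam",
                    learning_rate = 0.01, batch_size = 8, epochs = 60,
                    seed = 7)
  fit <- train_dbn(ds, cfg, rbm_train_config(epochs = 5, seed = 7))
  pred <- predict(fit$model, ds$features)
  expect_gte(mean(pred$labels == ds$labels), 0.95)
  expect_lte(fit$trace$train_loss[nrow(fit$trace)], fit$trace$train_loss[1])

  cfg0 <- dbn_config(hidden_layer_sizes = 8L, dropout_rate = 0,
                     learning_rate = 0, batch_size = 8, epochs = 50,
                     seed = 7)
  m0 <- pretrain_stack(ds$features, cfg0, rbm_train_config(epochs = 2, seed = 7))
  f0 <- fine_tune(m0, ds)
  expect_identical(f0$model$layers, m0$layers)
  expect_identical(f0$model$head, m0$head)
  expect_equal(diff(range(f0$trace$train_loss)), 0, tolerance = 1e-12)

  one_class <- labeled_dataset(ds$features, rep(0L, length(ds$labels)))
  expect_error(fine_tune(m0, one_class), class = "hcadbn_single_class_error")
})

test_that("the trained pipeline is bit-reproducible under a fixed seed", {
  task <- make_yield_task(n = 100, seed = 19)
  cfg <- dbn_preset("final_tuned", seed = 5, epochs = 50)
  f1 <- train_dbn(task$train, cfg, rbm_train_config(epochs = 5, seed = 5))
  f2 <- train_dbn(task$train, cfg, rbm_train_config(epochs = 5, seed = 5))
  s1 <- predict(f1$model, task$test$features)$scores
  s2 <- predict(f2$model, task$test$features)$scores
  expect_identical(s1, s2)
})

test_that("prediction thresholds scores and requires a fitted head", {
  m <- make_raw_dbn(2, c(3), seed = 14, fitted = TRUE)
  # direct threshold semantics on raw scores
  scores <- c(0.49, 0.5, 0.51)
  expect_equal(as.integer(scores >= 0.5), c(0L, 1L, 1L))
  X <- matrix(runif(20), 10, 2)
  p0 <- predict(m, X, threshold = 0)
  expect_true(all(p0$labels == 1L))
  p1 <- predict(m, X, threshold = 1)
  expect_true(all(p1$labels == 0L))
  m$fitted <- FALSE
  expect_error(predict(m, X), class = "hcadbn_state_error")
})

test_that("the fine-tuned DBN clearly beats majority class on the yield task", {
  task <- make_yield_task(n = 159, seed = 11)
  fit <- train_dbn(task$train, dbn_preset("final_tuned", seed = 3))
  pred <- predict(fit$model, task$test$features)
  acc <- mean(pred$labels == task$test$labels)
  majority <- max(mean(task$test$labels), 1 - mean(task$test$labels))
  expect_gte(acc, majority + 0.10)
})
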