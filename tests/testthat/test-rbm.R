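test_that("energy evaluates the bilinear form", {
  z <- rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0))
  for (v in list(c(0, 0), c(1, 0), c(1, 1))) {
    expect_equal(rbm_energy(v, c(1, 0), z), 0)
  }
  one <- rbm_params(matrix(1, 1, 1), 1, 1)
  expect_equal(rbm_energy(1, 1, one), -3)
  # zero visible layer leaves only the hidden bias term
  p <- make_tiny_rbm(2, 3, seed = 8)$params
  h <- c(1, 0, 1)
  expect_equal(rbm_energy(c(0, 0), h, p), -sum(p$b * h))
  expect_error(rbm_energy(c(1, 0, 0), h, p), class = "hcadbn_dimension_error")
})

test_that("partition function enumerates exactly and guards size", {
  z22 <- rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0))
  expect_equal(rbm_partition_function(z22), 16)
  # single informative visible bias: Z = (1 + e^a) * 2^n
  p <- rbm_params(matrix(0, 1, 1), log(3), 0)
  expect_equal(rbm_partition_function(p), 8, tolerance = 1e-12)
  big <- rbm_params(matrix(0, 13, 12), rep(0, 13), rep(0, 12))
  expect_error(rbm_partition_function(big),
               class = "hcadbn_intractable_enumeration_error")
})

test_that("joint probabilities normalize and follow the energy ordering", {
  z11 <- rbm_params(matrix(0, 1, 1), 0, 0)
  for (v in 0:1) for (h in 0:1) {
    expect_equal(rbm_joint_probability(v, h, z11), 0.25)
  }
  fix <- make_tiny_rbm(3, 3, seed = 17)
  expect_equal(sum(fix$states$probability), 1, tolerance = 1e-10)
  # lowest-energy state is the mode
  energies <- apply(fix$states, 1, function(row) {
    rbm_energy(as.numeric(row[1:3]), as.numeric(row[4:6]), fix$params)
  })
  expect_equal(which.min(energies), which.max(fix$states$probability))
  # duality: log P + log Z = -E
  lz <- rbm_partition_function(fix$params, log = TRUE)
  expect_equal(log(fix$states$probability) + lz, -energies,
               tolerance = 1e-10)
})

test_that("sigmoid conditionals agree with Bayes on the enumerated joint", {
  z <- rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0))
  expect_equal(rbm_hidden_conditional(c(1, 0), z), c(0.5, 0.5))
  expect_equal(rbm_visible_conditional(c(0, 1), z), c(0.5, 0.5))
  p10 <- rbm_params(matrix(0, 1, 1), 0, 10)
  expect_equal(rbm_hidden_conditional(0, p10), 1 / (1 + exp(-10)))

  fix <- make_tiny_rbm(3, 3, seed = 23)
  st <- fix$states
  V <- binary_states_mat(3)
  H <- binary_states_mat(3)
  for (vi in seq_len(nrow(V))) {
    v <- V[vi, ]
    rows <- st$v1 == v[1] & st$v2 == v[2] & st$v3 == v[3]
    joint_v <- st[rows, ]
    cond_bayes <- joint_v$probability / sum(joint_v$probability)
    ph <- rbm_hidden_conditional(v, fix$params)
    cond_formula <- apply(as.matrix(joint_v[, c("h1", "h2", "h3")]), 1,
                          function(h) prod(ph^h * (1 - ph)^(1 - h)))
    expect_equal(cond_bayes, unname(cond_formula), tolerance = 1e-10)
  }
})

test_that("gibbs sampling saturates, reproduces, and mixes to the joint", {
  sat <- rbm_params(matrix(0, 2, 2), c(50, 50), c(50, 50))
  set.seed(1)
  step <- rbm_gibbs_step(c(0, 0), sat)
  expect_equal(step$v_new, c(1, 1))
  set.seed(9); s1 <- rbm_gibbs_step(c(1, 0), make_tiny_rbm(2, 2, 3)$params)
  set.seed(9); s2 <- rbm_gibbs_step(c(1, 0), make_tiny_rbm(2, 2, 3)$params)
  expect_identical(s1, s2)

  # many parallel chains, long burn-in: empirical (v, h) frequencies match
  # the enumerated joint within 3 Monte-Carlo SEs
  fix <- make_tiny_rbm(2, 2, seed = 31)
  n_chains <- 4000
  set.seed(77)
  v <- matrix(rbinom(n_chains * 2, 1, 0.5), n_chains, 2)
  h <- NULL
  for (i in 1:100) {
    out <- rbm_gibbs_step(v, fix$params)
    v <- out$v_new
    h <- out$h_sample
  }
  # state of the pair (v, h) after h ~ P(h|v): resample h once more for the
  # terminal v so (v, h) is a joint draw
  h <- hcadbn:::sample_bernoulli(rbm_hidden_conditional(v, fix$params))
  key <- paste(v[, 1], v[, 2], h[, 1], h[, 2])
  st <- fix$states
  for (r in seq_len(nrow(st))) {
    p_true <- st$probability[r]
    p_emp <- mean(key == paste(st$v1[r], st$v2[r], st$h1[r], st$h2[r]))
    se <- sqrt(p_true * (1 - p_true) / n_chains)
    expect_lt(abs(p_emp - p_true), 3 * se + 1e-9)
  }
})

test_that("CD updates vanish at zero learning rate and push biases sensibly", {
  p <- make_tiny_rbm(2, 2, seed = 5)$params
  cfg0 <- rbm_train_config(learning_rate = 0, seed = 1)
  set.seed(2)
  expect_equal(cd_k_update(matrix(c(1, 0), 1, 2), p, cfg0), p,
               tolerance = 1e-15)
  # visible unit always on: its bias gradient is positive in expectation
  p1 <- rbm_params(matrix(0, 1, 1), 0, 0)
  cfg <- rbm_train_config(learning_rate = 0.1, seed = 1)
  set.seed(3)
  for (i in 1:200) p1 <- cd_k_update(matrix(1, 4, 1), p1, cfg)
  expect_gt(p1$a, 0.5)
  expect_error(cd_k_update(matrix(2, 1, 2), p, cfg),
               class = "hcadbn_validation_error")
})

test_that("exact gradient matches finite differences and symmetry", {
  fix <- make_tiny_rbm(2, 2, seed = 13)
  data <- rbind(c(1, 0), c(0, 1), c(1, 1))
  gr <- rbm_exact_gradient(fix$params, data)
  eps <- 1e-6
  num_grad <- function(get, set) {
    p_up <- set(fix$params, get(fix$params) + eps)
    p_dn <- set(fix$params, get(fix$params) - eps)
    (rbm_loglik(p_up, data) - rbm_loglik(p_dn, data)) / (2 * eps)
  }
  for (i in 1:2) for (j in 1:2) {
    nij <- num_grad(function(p) p$W[i, j],
                    function(p, v) { p$W[i, j] <- v; p })
    expect_equal(gr$dW[i, j], nij, tolerance = 1e-5)
  }
  for (i in 1:2) {
    expect_equal(gr$da[i],
                 num_grad(function(p) p$a[i],
                          function(p, v) { p$a[i] <- v; p }),
                 tolerance = 1e-5)
    expect_equal(gr$db[i],
                 num_grad(function(p) p$b[i],
                          function(p, v) { p$b[i] <- v; p }),
                 tolerance = 1e-5)
  }
  # all visible states equiprobable + zero parameters -> zero gradient
  z <- rbm_params(matrix(0, 2, 2), c(0, 0), c(0, 0))
  gz <- rbm_exact_gradient(z, binary_states_mat(2))
  expect_equal(gz$dW, matrix(0, 2, 2))
  expect_equal(gz$da, c(0, 0))
  expect_equal(gz$db, c(0, 0))
})

test_that("the gradient vanishes at the 1x1 maximum-likelihood point", {
  # one visible unit, data mean 0.75; profile over the visible bias with
  # W = b = 0: ML solution is a = logit(0.75)
  data <- matrix(c(1, 1, 1, 0), 4, 1)
  opt <- optimize(function(a) {
    -rbm_loglik(rbm_params(matrix(0, 1, 1), a, 0), data)
  }, c(-5, 5), tol = 1e-10)
  expect_equal(opt$minimum, qlogis(0.75), tolerance = 1e-4)
  gr <- rbm_exact_gradient(rbm_params(matrix(0, 1, 1), opt$minimum, 0), data)
  expect_equal(gr$da, 0, tolerance = 1e-6)
})

test_that("pre-training reduces reconstruction error deterministically", {
  # data drawn from a known 2-visible RBM
  fix <- make_tiny_rbm(2, 2, seed = 41, scale = 2)
  st <- fix$states
  vstates <- unique(st[, c("v1", "v2")])
  pv <- tapply(st$probability, paste(st$v1, st$v2), sum)
  set.seed(55)
  draws <- sample(names(pv), 300, replace = TRUE, prob = pv)
  data <- do.call(rbind, lapply(strsplit(draws, " "), as.numeric))

  cfg <- rbm_train_config(epochs = 25, learning_rate = 0.1, seed = 12)
  fit <- pretrain_rbm(data, n_hidden = 3, cfg)
  expect_length(fit$reconstruction_error, 25)
  expect_lt(fit$reconstruction_error[25], fit$reconstruction_error[1])

  fit2 <- pretrain_rbm(data, n_hidden = 3, cfg)
  expect_identical(fit$params, fit2$params)

  cfg0 <- rbm_train_config(epochs = 0, seed = 12)
  init <- pretrain_rbm(data, n_hidden = 3, cfg0)
  set.seed(cfg0$seed)
  expect_equal(init$params$W, matrix(rnorm(6, sd = 0.01), 2, 3))
  expect_equal(init$params$a, c(0, 0))
  expect_error(pretrain_rbm(data[0, , drop = FALSE], 2, cfg),
               class = "hcadbn_empty_data_error")
})
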