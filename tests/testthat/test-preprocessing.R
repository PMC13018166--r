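# Fixed fixture vector; the D'Agostino and Jarque-Bera expectations were
# computed independently with scipy.stats (normaltest / jarque_bera).
normality_fixture <- c(
  5.391074, 4.101581, 2.74461, 4.142665, 3.764525, 4.4345, 4.654347,
  2.28662, 0.176266, 0.518712, 1.057873, 3.352418, 4.851261, 4.547543,
  -1.472565, 2.407311, 3.093583, 3.996585, -0.292573, -0.280021, 4.320285,
  4.563816, 4.18853, 1.991557, 6.770472, 0.209689, 2.181806, 3.404115,
  1.473999, 5.393002, 0.0414, 1.590657, 2.362436, 3.866373, 1.987727,
  2.739908, 3.715336, 2.468183, 1.962735, 3.148237)

test_that("omnibus moment tests match an independent implementation", {
  dk <- dagostino_k2_test(normality_fixture)
  expect_equal(dk$statistic, 0.8319643847, tolerance = 1e-9)
  expect_equal(dk$p_value, 0.6596920179, tolerance = 1e-9)
  jb <- jarque_bera_test(normality_fixture)
  expect_equal(jb$statistic, 0.8863859293, tolerance = 1e-9)
  expect_equal(jb$p_value, 0.6419833150, tolerance = 1e-9)
})

test_that("the five-test battery separates normal from exponential data", {
  set.seed(101)
  rep_norm <- assess_normality(rnorm(500))
  expect_equal(rep_norm$composite_score, 5L)
  rep_exp <- assess_normality(rexp(500))
  expect_equal(rep_exp$composite_score, 0L)
  expect_true(all(rep_norm$tests$p_value >= 0 & rep_norm$tests$p_value <= 1))
  expect_equal(nrow(rep_norm$tests), 5L)
  expect_error(assess_normality(rep(3, 50)),
               class = "hcadbn_degenerate_input_error")
  expect_error(assess_normality(rnorm(7)), class = "hcadbn_validation_error")
})

test_that("transforms have their closed forms and domains", {
  expect_equal(apply_transform(c(0, 25, 57), transform_spec("sqrt")),
               c(0, 5, sqrt(57)))
  x <- rnorm(20)
  expect_identical(apply_transform(x, transform_spec("identity")), x)
  # Box-Cox at lambda = 0 is the natural log
  xp <- rexp(50) + 0.1
  expect_equal(apply_transform(xp, transform_spec("box_cox", lambda = 0)),
               log(xp), tolerance = 1e-12)
  expect_error(apply_transform(c(1, -2, 3), transform_spec("sqrt")),
               regexp = "index 2", class = "hcadbn_domain_error")
  # zero minimum triggers the unit shift for log/reciprocal
  spec <- fit_transform(c(0, 1, 4), "log")
  expect_equal(spec$shift, 1)
  expect_equal(apply_transform(c(0, 1, 4), spec), log(c(1, 2, 5)))
})

test_that("every transform is rank-preserving on its domain", {
  set.seed(7)
  x <- rexp(60) + 0.05
  for (kind in c("identity", "log", "sqrt", "reciprocal", "box_cox",
                 "yeo_johnson")) {
    spec <- fit_transform(x, kind)
    y <- apply_transform(x, spec)
    expect_equal(order(y), order(x), info = kind)
    expect_length(y, length(x))
  }
})

test_that("transform selection prefers sqrt on squared-normal data", {
  # at this scale the sqrt image (half-normal) still passes several tests
  # while the raw chi-square(1) magnitudes fail all five
  set.seed(21)
  x <- rnorm(50)^2
  sel <- select_transform(x, candidates = c("identity", "sqrt"))
  expect_equal(sel$spec$kind, "sqrt")
  expect_gt(sel$reports$composite_score[1],
            sel$reports$composite_score[sel$reports$kind == "identity"])
})

test_that("selection falls back by domain and breaks ties to simplicity", {
  set.seed(22)
  xneg <- rnorm(100)  # contains negatives
  sel <- select_transform(xneg, candidates = c("log", "sqrt", "yeo_johnson"))
  expect_equal(sel$spec$kind, "yeo_johnson")
  # already-normal positive data: identity wins the tie over sqrt
  xn <- rnorm(300, mean = 100, sd = 1)
  sel2 <- select_transform(xn, candidates = c("identity", "sqrt"))
  expect_equal(sel2$spec$kind, "identity")
  expect_error(select_transform(xneg, candidates = c("log", "sqrt")),
               class = "hcadbn_selection_error")
  expect_error(select_transform(xn, candidates = character()),
               class = "hcadbn_config_error")
})

test_that("min-max scaling maps train to [0,1], clips test, idempotent", {
  st <- fit_minmax(cbind(a = c(2, 4, 6)))
  expect_equal(as.numeric(apply_minmax(cbind(a = c(2, 4, 6)), st)),
               c(0, 0.5, 1))
  expect_equal(as.numeric(apply_minmax(cbind(a = 8), st)), 1)
  expect_equal(as.numeric(apply_minmax(cbind(a = 0), st)), 0)
  expect_warning(st2 <- fit_minmax(cbind(b = c(3, 3, 3))), "constant")
  expect_equal(as.numeric(apply_minmax(cbind(b = c(3, 3, 3)), st2)),
               c(0, 0, 0))
  # idempotence on in-range data: scaled data rescaled with unit state
  set.seed(3)
  X <- matrix(runif(40, 2, 9), 20, 2)
  st3 <- fit_minmax(X)
  once <- apply_minmax(X, st3)
  unit <- fit_minmax(once)
  expect_equal(apply_minmax(once, unit), once, tolerance = 1e-12)
})

test_that("VIF matches the correlation-inverse oracle and flags collinearity", {
  set.seed(31)
  n <- 400
  X <- cbind(x1 = rnorm(n), x2 = rnorm(n), x3 = rnorm(n), x4 = rnorm(n))
  vif <- compute_vif(X)
  expect_true(all(vif > 0.9 & vif < 1.2))
  # brute-force oracle: diagonal of the inverse correlation matrix
  oracle <- diag(solve(stats::cor(X)))
  expect_equal(unname(vif), unname(oracle), tolerance = 1e-8)

  X2 <- cbind(X[, 1:2], x3 = X[, 1] + rnorm(n, sd = 0.05))
  vif2 <- compute_vif(X2)
  expect_gt(vif2["x1"], 10)
  expect_gt(vif2["x3"], 10)
  oracle2 <- diag(solve(stats::cor(X2)))
  expect_equal(unname(vif2), unname(oracle2), tolerance = 1e-8)

  X3 <- cbind(X[, 1:2], dup = X[, 1])
  expect_true(is.infinite(compute_vif(X3)["dup"]))

  X4 <- cbind(X[, 1:2], const = 1)
  expect_error(compute_vif(X4), class = "hcadbn_degenerate_input_error")
  expect_warning(v4 <- compute_vif(X4, drop_constant = TRUE), "const")
  expect_true(is.na(v4["const"]) && !anyNA(v4[c("x1", "x2")]))
})

test_that("descriptive statistics follow the interpolated-quartile convention", {
  schema <- trait_schema(data.frame(code = c("A", "KW"),
                                    name = c("a", "kw"), unit = c("u", "g"),
                                    role = c("predictor", "target")))
  tab <- trait_table(data.frame(A = c(1, 2, 3, 4, 5), KW = c(7, 7, 7, 7, 7)),
                     schema)
  d <- describe_traits(tab)
  a <- d[d$trait == "A", ]
  expect_equal(a$mean, 3); expect_equal(a$median, 3)
  expect_equal(a$q1, 2); expect_equal(a$q3, 4)
  expect_equal(a$sd, sd(1:5))
  tab1 <- trait_table(data.frame(A = c(7, NA, NA, NA, NA),
                                 KW = c(1, 1, 1, 1, 1)), schema)
  d1 <- describe_traits(tab1)
  expect_equal(d1[d1$trait == "A", "count"], 1L)
  expect_true(is.na(d1[d1$trait == "A", "sd"]))
})

test_that("residual diagnostics report homoscedasticity checks", {
  set.seed(41)
  X <- matrix(rnorm(300), 100, 3)
  y <- X %*% c(1, -0.5, 0.2) + rnorm(100)
  d <- residual_diagnostics(as.numeric(y), X)
  expect_setequal(d$test, c("white_special", "goldfeld_quandt",
                            "jarque_bera_residuals"))
  expect_true(all(d$p_value >= 0 & d$p_value <= 1))
})
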