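## Central moments about the mean; biased (population) versions, as used by
## the classical skewness/kurtosis normality statistics.
central_moment <- function(x, k) mean((x - mean(x))^k)

## D'Agostino (1970) transformed skewness z-statistic.
dagostino_skew_z <- function(x) {
  n <- length(x)
  b1 <- central_moment(x, 3) / central_moment(x, 2)^1.5
  y <- b1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  w2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(0.5 * log(w2))
  alpha <- sqrt(2 / (w2 - 1))
  delta * asinh(y / alpha)
}

## Anscombe-Glynn (1983) transformed kurtosis z-statistic.
anscombe_kurt_z <- function(x) {
  n <- length(x)
  b2 <- central_moment(x, 4) / central_moment(x, 2)^2
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - eb2) / sqrt(vb2)
  sqrtb1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  a <- 6 + 8 / sqrtb1 * (2 / sqrtb1 + sqrt(1 + 4 / sqrtb1^2))
  term1 <- 1 - 2 / (9 * a)
  denom <- 1 + xk * sqrt(2 / (a - 4))
  term2 <- sign(denom) * (abs((1 - 2 / a) / abs(denom)))^(1 / 3)
  (term1 - term2) / sqrt(2 / (9 * a))
}

#' D'Agostino's K-squared omnibus normality test
#'
#' Combines the transformed skewness and kurtosis z-statistics into
#' K2 = z_skew^2 + z_kurt^2, referred to a chi-squared distribution with
#' 2 degrees of freedom.
#'
#' @param x numeric vector, n >= 8.
#' @return list with `statistic` and `p_value`.
#' @export
dagostino_k2_test <- function(x) {
  if (length(x) < 8) {
    stop_hcadbn("D'Agostino K^2 requires n >= 8", "hcadbn_validation_error")
  }
  k2 <- dagostino_skew_z(x)^2 + anscombe_kurt_z(x)^2
  list(statistic = k2, p_value = stats::pchisq(k2, df = 2, lower.tail = FALSE))
}

#' Jarque-Bera normality test
#'
#' JB = n/6 * (S^2 + (K - 3)^2 / 4) with biased sample skewness S and
#' kurtosis K, referred to chi-squared with 2 degrees of freedom.
#'
#' @param x numeric vector.
#' @return list with `statistic` and `p_value`.
#' @export
jarque_bera_test <- function(x) {
  n <- length(x)
  s <- central_moment(x, 3) / central_moment(x, 2)^1.5
  k <- central_moment(x, 4) / central_moment(x, 2)^2
  jb <- n / 6 * (s^2 + (k - 3)^2 / 4)
  list(statistic = jb, p_value = stats::pchisq(jb, df = 2, lower.tail = FALSE))
}

#' Assess normality of a sample with a five-test battery
#'
#' Runs Anderson-Darling, D'Agostino K-squared, Kolmogorov-Smirnov (Lilliefors
#' form, since mean and SD are estimated from the sample), Jarque-Bera and
#' Shapiro-Wilk. The composite score is the number of tests that do not
#' reject normality at `alpha`; the mean p-value is reported alongside as a
#' tie-breaking diagnostic.
#'
#' @param x numeric vector, n >= 8, non-constant.
#' @param alpha rejection level (default 0.05).
#' @return a `normality_report`: list with `tests` (data frame of statistic
#'   and p-value per test), `composite_score`, `mean_p`.
#' @export
assess_normality <- function(x, alpha = 0.05) {
  x <- as.numeric(x)
  if (length(x) < 8) {
    stop_hcadbn("normality battery requires n >= 8", "hcadbn_validation_error")
  }
  if (stats::sd(x) == 0) {
    stop_hcadbn("constant vector: normality is undefined",
                "hcadbn_degenerate_input_error")
  }
  ad <- nortest::ad.test(x)
  dk <- dagostino_k2_test(x)
  ks <- nortest::lillie.test(x)
  jb <- jarque_bera_test(x)
  sw <- stats::shapiro.test(if (length(x) > 5000) x[seq_len(5000)] else x)
  tests <- data.frame(
    test = c("anderson_darling", "dagostino_k2", "kolmogorov_smirnov",
             "jarque_bera", "shapiro_wilk"),
    statistic = c(unname(ad$statistic), dk$statistic, unname(ks$statistic),
                  jb$statistic, unname(sw$statistic)),
    p_value = c(ad$p.value, dk$p_value, ks$p.value, jb$p_value, sw$p.value),
    stringsAsFactors = FALSE
  )
  structure(list(tests = tests,
                 composite_score = sum(tests$p_value > alpha),
                 mean_p = mean(tests$p_value),
                 alpha = alpha),
            class = "normality_report")
}

#' @export
print.normality_report <- function(x, ...) {
  cat(sprintf("<normality_report> composite score %d/5 (alpha = %.2f)\n",
              x$composite_score, x$alpha))
  print(x$tests, row.names = FALSE)
  invisible(x)
}

## Number of data-fitted parameters per transform kind (tie-break in
## select_transform); the zero-shift offset is deterministic, not fitted.
transform_n_params <- function(kind) {
  if (kind %in% c("box_cox", "yeo_johnson")) 1L else 0L
}

#' Specify a variable transform
#'
#' @param kind one of `identity`, `log`, `sqrt`, `reciprocal`, `box_cox`,
#'   `yeo_johnson`.
#' @param lambda fitted power parameter (Box-Cox / Yeo-Johnson only).
#' @param shift offset added before log/reciprocal when zeros are present.
#' @return a `transform_spec`.
#' @export
transform_spec <- function(kind, lambda = NULL, shift = 0) {
  kinds <- c("identity", "log", "sqrt", "reciprocal", "box_cox",
             "yeo_johnson")
  if (!kind %in% kinds) {
    stop_hcadbn(sprintf("unknown transform kind '%s'", kind),
                "hcadbn_config_error")
  }
  structure(list(kind = kind, lambda = lambda, shift = shift),
            class = "transform_spec")
}

#' Fit a transform to a vector
#'
#' For log/reciprocal a shift of 1 is applied when the minimum is exactly 0;
#' strictly negative input is a domain violation for log, sqrt, reciprocal
#' and Box-Cox. Power-transform lambdas are fitted by profile maximum
#' likelihood (via \pkg{car}).
#'
#' @param x numeric vector.
#' @param kind transform kind (see [transform_spec()]).
#' @return fitted `transform_spec`.
#' @export
fit_transform <- function(x, kind) {
  mn <- min(x)
  shift <- 0
  if (kind %in% c("log", "reciprocal")) {
    if (mn < 0) {
      stop_hcadbn(sprintf("%s transform undefined for negative input", kind),
                  "hcadbn_domain_error")
    }
    if (mn == 0) shift <- 1
  }
  if (kind == "sqrt" && mn < 0) {
    stop_hcadbn("sqrt transform undefined for negative input",
                "hcadbn_domain_error")
  }
  lambda <- NULL
  if (kind == "box_cox") {
    if (mn <= 0) {
      stop_hcadbn("Box-Cox requires strictly positive input",
                  "hcadbn_domain_error")
    }
    pt <- car::powerTransform(x ~ 1, family = "bcPower")
    lambda <- unname(pt$lambda)
  }
  if (kind == "yeo_johnson") {
    pt <- car::powerTransform(x ~ 1, family = "yjPower")
    lambda <- unname(pt$lambda)
  }
  transform_spec(kind, lambda = lambda, shift = shift)
}

#' Apply a fitted transform elementwise
#'
#' Monotone on its domain for every supported kind (reciprocal is applied
#' with a sign flip, -1/x, to preserve rank order).
#'
#' @param x numeric vector.
#' @param spec a `transform_spec`.
#' @return transformed vector of the same length.
#' @export
apply_transform <- function(x, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  xs <- x + spec$shift
  bad <- switch(spec$kind,
    log = which(xs <= 0), reciprocal = which(xs <= 0),
    sqrt = which(xs < 0), box_cox = which(xs <= 0),
    integer(0)
  )
  if (length(bad) > 0) {
    stop_hcadbn(sprintf("%s transform domain violated at index %d (value %g)",
                        spec$kind, bad[1], x[bad[1]]),
                "hcadbn_domain_error")
  }
  switch(spec$kind,
    identity = x,
    log = log(xs),
    sqrt = sqrt(xs),
    reciprocal = -1 / xs,
    box_cox = as.numeric(car::bcPower(xs, lambda = spec$lambda)),
    yeo_johnson = as.numeric(car::yjPower(xs, lambda = spec$lambda))
  )
}

#' Select the transform that best normalizes a vector
#'
#' Fits every candidate whose domain is satisfied, scores the transformed
#' vector with [assess_normality()], and returns the candidate with the
#' highest composite score. Ties go to the candidate with the fewest fitted
#' parameters, then to candidate-list order.
#'
#' @param x numeric vector.
#' @param candidates character vector of transform kinds.
#' @param alpha normality rejection level.
#' @return list with `spec` (winning `transform_spec`) and `reports`
#'   (data frame ranking all valid candidates).
#' @export
select_transform <- function(x, candidates = c("identity", "log", "sqrt",
                                               "reciprocal", "box_cox",
                                               "yeo_johnson"),
                             alpha = 0.05) {
  if (length(candidates) == 0) {
    stop_hcadbn("no candidate transforms supplied", "hcadbn_config_error")
  }
  rows <- list()
  specs <- list()
  for (i in seq_along(candidates)) {
    kind <- candidates[i]
    spec <- tryCatch(fit_transform(x, kind),
                     hcadbn_domain_error = function(e) NULL)
    if (is.null(spec)) next
    y <- tryCatch(apply_transform(x, spec),
                  hcadbn_domain_error = function(e) NULL)
    if (is.null(y)) next
    rep <- tryCatch(assess_normality(y, alpha),
                    hcadbn_degenerate_input_error = function(e) NULL)
    if (is.null(rep)) next
    specs[[kind]] <- spec
    rows[[kind]] <- data.frame(
      kind = kind, composite_score = rep$composite_score,
      mean_p = rep$mean_p, n_params = transform_n_params(kind),
      candidate_order = i, stringsAsFactors = FALSE
    )
  }
  if (length(rows) == 0) {
    stop_hcadbn("every candidate transform violated its domain",
                "hcadbn_selection_error")
  }
  ranking <- do.call(rbind, rows)
  ord <- order(-ranking$composite_score, ranking$n_params,
               ranking$candidate_order)
  ranking <- ranking[ord, , drop = FALSE]
  rownames(ranking) <- NULL
  list(spec = specs[[ranking$kind[1]]], reports = ranking)
}

#' Fit min-max scaling statistics on training features
#'
#' Constant features (max equal to min) map to all zeros, with a warning.
#'
#' @param train_features numeric matrix.
#' @return a `scaler_state` with per-feature `min` and `max`.
#' @export
fit_minmax <- function(train_features) {
  train_features <- as.matrix(train_features)
  mins <- apply(train_features, 2, min)
  maxs <- apply(train_features, 2, max)
  const <- which(maxs == mins)
  if (length(const) > 0) {
    warning(sprintf("constant feature(s) mapped to 0 under min-max: %s",
                    paste(colnames(train_features)[const] %||% const,
                          collapse = ", ")))
  }
  structure(list(min = mins, max = maxs), class = "scaler_state")
}

#' Apply min-max scaling
#'
#' Maps each feature with the training min/max to `[0,1]`; out-of-range
#' values (unseen data) are clipped to the unit interval.
#'
#' @param features numeric matrix.
#' @param state a `scaler_state` from [fit_minmax()].
#' @return scaled matrix with all values in `[0,1]`.
#' @export
apply_minmax <- function(features, state) {
  stopifnot(inherits(state, "scaler_state"))
  features <- as.matrix(features)
  rng <- state$max - state$min
  rng[rng == 0] <- 1  # constant feature: (x - min)/1 = 0
  scaled <- sweep(sweep(features, 2, state$min, "-"), 2, rng, "/")
  pmin(pmax(scaled, 0), 1)
}

#' Variance inflation factors
#'
#' VIF_j = 1 / (1 - R^2_j), where R^2_j comes from the ordinary least squares
#' regression of feature j on all other features (intercept included).
#' Perfect collinearity is reported as `Inf` rather than an error.
#'
#' @param features numeric matrix, n rows > p columns.
#' @param codes feature names (defaults to column names).
#' @param drop_constant drop constant features (with a warning, reporting
#'   `NA` for them) instead of erroring.
#' @return named numeric vector of VIFs, each >= 1 (or `Inf`).
#' @export
compute_vif <- function(features, codes = colnames(features),
                        drop_constant = FALSE) {
  features <- as.matrix(features)
  if (is.null(codes)) codes <- paste0("V", seq_len(ncol(features)))
  const <- apply(features, 2, stats::sd) == 0
  if (any(const)) {
    if (!drop_constant) {
      stop_hcadbn("VIF undefined with a constant feature",
                  "hcadbn_degenerate_input_error")
    }
    warning(sprintf("dropping constant feature(s) from VIF: %s",
                    paste(codes[const], collapse = ", ")))
    kept <- compute_vif(features[, !const, drop = FALSE], codes[!const])
    out <- stats::setNames(rep(NA_real_, length(codes)), codes)
    out[names(kept)] <- kept
    return(out)
  }
  p <- ncol(features)
  n <- nrow(features)
  if (n <= p) {
    stop_hcadbn("VIF requires more observations than features",
                "hcadbn_validation_error")
  }
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, features[, -j, drop = FALSE]),
                         features[, j])
    rss <- sum(fit$residuals^2)
    tss <- sum((features[, j] - mean(features[, j]))^2)
    r2 <- 1 - rss / tss
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  stats::setNames(vif, codes)
}

#' Descriptive statistics per trait
#'
#' Count excludes missing cells; SD is the sample (n-1) standard deviation;
#' quartiles use linear interpolation between order statistics
#' (`stats::quantile` type 7, the spreadsheet convention).
#'
#' @param table a `trait_table`.
#' @return data frame with one row per schema trait: count, mean, sd, min,
#'   q1, median, q3, max. SD is `NA` when fewer than two values remain.
#' @export
describe_traits <- function(table) {
  stopifnot(inherits(table, "trait_table"))
  rows <- lapply(table$schema$code, function(code) {
    x <- table$data[[code]]
    x <- x[!is.na(x)]
    if (length(x) == 0) {
      return(data.frame(trait = code, count = 0L, mean = NA_real_,
                        sd = NA_real_, min = NA_real_, q1 = NA_real_,
                        median = NA_real_, q3 = NA_real_, max = NA_real_))
    }
    q <- stats::quantile(x, c(0.25, 0.5, 0.75), type = 7, names = FALSE)
    data.frame(trait = code, count = length(x), mean = mean(x),
               sd = if (length(x) > 1) stats::sd(x) else NA_real_,
               min = min(x), q1 = q[1], median = q[2], q3 = q[3],
               max = max(x), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Regression residual diagnostics
#'
#' Descriptive checks used alongside the preprocessing chain: White's test
#' (special form: squared residuals on fitted values and their squares) and
#' the Goldfeld-Quandt test for homoscedasticity, plus Jarque-Bera on the
#' residuals. These are reported, never used to gate the pipeline.
#'
#' @param y numeric response vector.
#' @param features numeric predictor matrix.
#' @return data frame of test statistics and p-values.
#' @export
residual_diagnostics <- function(y, features) {
  df <- data.frame(y = y, features)
  fit <- stats::lm(y ~ ., data = df)
  white <- lmtest::bptest(fit, ~ fitted(fit) + I(fitted(fit)^2))
  gq <- lmtest::gqtest(fit)
  jb <- jarque_bera_test(stats::residuals(fit))
  data.frame(
    test = c("white_special", "goldfeld_quandt", "jarque_bera_residuals"),
    statistic = c(unname(white$statistic), unname(gq$statistic),
                  jb$statistic),
    p_value = c(white$p.value, gq$p.value, jb$p_value),
    stringsAsFactors = FALSE
  )
}
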