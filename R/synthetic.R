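#' Marginal targets emulated by the synthetic generator
#'
#' Per-trait mean, SD, minimum and maximum of the field dataset's
#' descriptive statistics, used as the default marginal targets of
#' [generate_trait_table()]. `integer` flags count-valued traits that are
#' rounded after sampling; `design` flags the Treatment/PN design columns,
#' which are laid out cyclically rather than sampled.
#'
#' @return data frame with columns code, mean, sd, min, max, integer,
#'   design.
#' @export
trait_marginal_targets <- function() {
  t2 <- rbind(
    # code      mean    sd     min    max    int design
    c("Treatment", 4.50, 2.30,  1.00,   8.00, 1, 1),
    c("PN",       10.50, 5.78,  1.00,  20.00, 1, 1),
    c("PH",       66.90, 8.75, 41.50,  89.50, 0, 0),
    c("NOL",      11.98, 1.14, 10.00,  15.00, 1, 0),
    c("NON",      12.27, 1.20, 10.00,  15.00, 1, 0),
    c("NOC",       1.01, 0.08,  1.00,   2.00, 1, 0),
    c("NOT",       9.55, 3.36,  3.00,  17.00, 1, 0),
    c("PHC",      21.43, 4.64, 11.00,  35.00, 0, 0),
    c("LL",       25.61, 3.51, 17.50,  33.20, 0, 0),
    c("LB",        2.95, 0.44,  1.90,   4.50, 0, 0),
    c("EWS",      69.13, 30.79, 13.00, 199.00, 0, 0),
    c("EWOS",     51.87, 23.04,  0.00, 126.00, 0, 0),
    c("EL",        4.14, 0.93,  0.00,   6.50, 0, 0),
    c("EW",        4.42, 4.02,  0.00,  54.00, 0, 0),
    c("RE",       20.83, 6.52,  0.00,  36.00, 1, 0),
    c("KR",       12.71, 2.63,  0.00,  16.00, 1, 0),
    c("Ch1",       7.60, 4.13,  2.10,  26.90, 0, 0),
    c("Ch2",       9.84, 6.61,  2.00,  29.80, 0, 0),
    c("Ch3",      10.85, 7.13,  2.00,  39.90, 0, 0),
    c("Ch4",      17.34, 11.53,  2.10,  48.10, 0, 0),
    c("Ch5",      12.20, 7.37,  2.10,  35.40, 0, 0),
    c("CT1",      61.88, 4.01, 54.20,  72.55, 0, 0),
    c("CT2",      57.55, 3.67, 50.88,  68.60, 0, 0),
    c("CT3",      52.57, 2.62, 47.15,  64.50, 0, 0),
    c("CT4",      51.47, 6.13, 42.15,  74.80, 0, 0),
    c("CT5",      55.55, 5.72, 46.30,  73.80, 0, 0)
  )
  data.frame(code = t2[, 1], mean = as.numeric(t2[, 2]),
             sd = as.numeric(t2[, 3]), min = as.numeric(t2[, 4]),
             max = as.numeric(t2[, 5]), integer = t2[, 6] == "1",
             design = t2[, 7] == "1", stringsAsFactors = FALSE)
}

## Mean and SD of a Normal(mu, sigma) truncated to [a, b].
truncnorm_moments <- function(mu, sigma, a, b) {
  al <- (a - mu) / sigma; be <- (b - mu) / sigma
  z <- stats::pnorm(be) - stats::pnorm(al)
  dphi <- stats::dnorm(al) - stats::dnorm(be)
  m <- mu + sigma * dphi / z
  v <- sigma^2 * (1 + (al * stats::dnorm(al) - be * stats::dnorm(be)) / z -
                    (dphi / z)^2)
  c(mean = m, sd = sqrt(max(v, 0)))
}

## Underlying (mu, sigma) whose [a,b]-truncation matches a target mean/SD;
## keeps the generated marginals on target even where truncation bites.
truncnorm_match <- function(target_mean, target_sd, a, b) {
  obj <- function(par) {
    mu <- par[1]; sigma <- exp(par[2])
    # keep the optimizer away from degenerate corners where the [a,b] mass
    # underflows (some discrete traits have truncnorm-unattainable moments)
    if (stats::pnorm(b, mu, sigma) - stats::pnorm(a, mu, sigma) < 1e-10) {
      return(1e6)
    }
    mom <- truncnorm_moments(mu, sigma, a, b)
    if (!all(is.finite(mom))) return(1e6)
    (mom["mean"] - target_mean)^2 / target_sd^2 +
      (mom["sd"] - target_sd)^2 / target_sd^2
  }
  fit <- stats::optim(c(target_mean, log(target_sd)), obj,
                      method = "Nelder-Mead",
                      control = list(maxit = 500, reltol = 1e-10))
  c(mu = fit$par[1], sigma = exp(fit$par[2]))
}

## Truncated-normal quantile: map uniform draws through the inverse CDF.
qtruncnorm <- function(u, mu, sigma, a, b) {
  pa <- stats::pnorm(a, mu, sigma); pb <- stats::pnorm(b, mu, sigma)
  p <- pmin(pmax(pa + u * (pb - pa), 1e-15), 1 - 1e-15)
  pmin(pmax(stats::qnorm(p, mu, sigma), a), b)
}

#' Specification for the synthetic trait-table generator
#'
#' The generator emulates the structure the pipeline assumes: Table-style
#' marginal summaries per trait (truncated normals moment-matched to the
#' target mean/SD/min/max), a strongly collinear ear-weight pair
#' (EWOS = alpha * EWS + noise, driving their variance inflation factors
#' above 10), repeated-measure correlation across the five chlorophyll and
#' canopy-temperature stages (Gaussian AR(1) copula, rho = 0.6), and a
#' learnable signal: a latent yield score formed from the ear traits (EWS,
#' EWOS, EL, EW, RE, KR) plus Gaussian noise, mapped affinely to kernel
#' weight on the gram scale (mean 16.23, SD 11.41, clipped to [0, 57]), so
#' the 25 g threshold yields roughly a 78/22 low/high split.
#'
#' @param n sample count (>= 20).
#' @param seed integer RNG seed.
#' @param noise_sd SD of the latent signal noise relative to the unit-SD
#'   score: 0 makes classes perfectly predictable from ear traits, large
#'   values destroy learnability. The default 0.25 puts the Bayes-optimal
#'   accuracy of the task near 0.93, the regime the classifier attains on
#'   the real field data.
#' @param signal_weights named weights of the ear traits in the latent
#'   score.
#' @param ewos_alpha slope of the EWOS-on-EWS collinearity block.
#' @param ewos_noise_sd SD of the EWOS residual noise (grams).
#' @param ar_rho AR(1) correlation of the staged Ch/CT measurements.
#' @param kw_mean,kw_sd,kw_range affine calibration of kernel weight.
#' @param threshold class boundary in grams.
#' @param targets marginal target table, defaults to
#'   [trait_marginal_targets()].
#' @return a `generator_spec`.
#' @export
generator_spec <- function(n = 159L, seed = 1L, noise_sd = 0.25,
                           signal_weights = c(EWS = 0.30, EWOS = 0.30,
                                              EL = 0.10, EW = 0.05,
                                              RE = 0.15, KR = 0.10),
                           ewos_alpha = 0.75, ewos_noise_sd = 5.3,
                           ar_rho = 0.6,
                           kw_mean = 16.23, kw_sd = 11.41,
                           kw_range = c(0, 57), threshold = 25,
                           targets = trait_marginal_targets()) {
  if (n < 20) {
    stop_hcadbn("generator requires n >= 20", "hcadbn_validation_error")
  }
  if (noise_sd < 0 || ewos_noise_sd < 0 || kw_sd <= 0 ||
      any(targets$sd <= 0)) {
    stop_hcadbn("spread parameters must be positive",
                "hcadbn_validation_error")
  }
  if (abs(ar_rho) >= 1) {
    stop_hcadbn("ar_rho must lie in (-1, 1)", "hcadbn_validation_error")
  }
  structure(list(n = as.integer(n), seed = assert_seed(seed),
                 noise_sd = noise_sd, signal_weights = signal_weights,
                 ewos_alpha = ewos_alpha, ewos_noise_sd = ewos_noise_sd,
                 ar_rho = ar_rho, kw_mean = kw_mean, kw_sd = kw_sd,
                 kw_range = kw_range, threshold = threshold,
                 targets = targets),
            class = "generator_spec")
}

#' Generate a synthetic trait table with known ground truth
#'
#' See [generator_spec()] for the statistical structure. Deterministic given
#' the spec (including its seed).
#'
#' @param spec a `generator_spec`.
#' @return list with `table` (a `trait_table` including the KW column) and
#'   `ground_truth` (data frame of per-sample latent score, kernel weight
#'   and class label).
#' @export
generate_trait_table <- function(spec = generator_spec()) {
  stopifnot(inherits(spec, "generator_spec"))
  old <- .Random.seed_exists()
  set.seed(spec$seed)
  n <- spec$n
  tg <- spec$targets
  cols <- list()

  # design columns: 8 treatments x 20 tagged plants, cyclic
  cols$Treatment <- rep(1:8, each = 20, length.out = n)
  cols$PN <- rep(1:20, length.out = n)

  matched <- lapply(seq_len(nrow(tg)), function(i) {
    truncnorm_match(tg$mean[i], tg$sd[i], tg$min[i], tg$max[i])
  })
  names(matched) <- tg$code
  draw_trait <- function(code, u = stats::runif(n)) {
    i <- match(code, tg$code)
    x <- qtruncnorm(u, matched[[code]]["mu"], matched[[code]]["sigma"],
                    tg$min[i], tg$max[i])
    if (tg$integer[i]) x <- round(x)
    x
  }

  # independent continuous / count traits
  for (code in c("PH", "NOL", "NON", "NOC", "NOT", "PHC", "LL", "LB",
                 "EWS", "EL", "EW", "RE", "KR")) {
    cols[[code]] <- draw_trait(code)
  }

  # collinearity block: EWOS tracks EWS closely (VIF >> 10 for the pair)
  i_ewos <- match("EWOS", tg$code)
  ewos_intercept <- tg$mean[i_ewos] - spec$ewos_alpha * tg$mean[match("EWS", tg$code)]
  cols$EWOS <- pmin(pmax(
    ewos_intercept + spec$ewos_alpha * cols$EWS +
      stats::rnorm(n, 0, spec$ewos_noise_sd),
    tg$min[i_ewos]), tg$max[i_ewos])

  # staged repeated measures: Gaussian AR(1) copula across the 5 stages
  for (prefix in c("Ch", "CT")) {
    z <- stats::rnorm(n)
    for (s in 1:5) {
      if (s > 1) {
        z <- spec$ar_rho * z +
          sqrt(1 - spec$ar_rho^2) * stats::rnorm(n)
      }
      cols[[paste0(prefix, s)]] <- draw_trait(paste0(prefix, s),
                                              u = stats::pnorm(z))
    }
  }

  # latent yield score from ear traits -> kernel weight in grams
  w <- spec$signal_weights
  zscore <- function(code) {
    i <- match(code, tg$code)
    (cols[[code]] - tg$mean[i]) / tg$sd[i]
  }
  score <- Reduce(`+`, Map(function(code, wt) wt * zscore(code),
                           names(w), w))
  if (stats::sd(score) > 0) {
    score <- (score - mean(score)) / stats::sd(score)
  }  # all-zero weights: flat score, labels carry no trait signal
  g <- score + stats::rnorm(n, 0, spec$noise_sd)
  g <- (g - mean(g)) / stats::sd(g)
  kw <- pmin(pmax(spec$kw_mean + spec$kw_sd * g, spec$kw_range[1]),
             spec$kw_range[2])
  cols$KW <- kw
  .Random.seed_restore(old)

  schema <- default_trait_schema()
  data <- as.data.frame(cols)[, schema$code]
  list(table = trait_table(data, schema),
       ground_truth = data.frame(latent_score = score, kw = kw,
                                 class = as.integer(kw >= spec$threshold)))
}

#' Tiny RBM fixture with exact enumerated state probabilities
#'
#' Draws a random parameter set with at most 6 total units and tabulates
#' every joint configuration with its exact Boltzmann probability — the
#' oracle against which conditional and sampling code is checked.
#'
#' @param m visible units.
#' @param n hidden units (m + n <= 6).
#' @param seed integer RNG seed.
#' @param scale SD of the random parameter draw (0 gives the uniform
#'   zero-parameter model).
#' @return list with `params` (an `rbm_params`) and `states` (data frame:
#'   one row per configuration, visible columns v1..vm, hidden h1..hn, and
#'   `probability` summing to 1).
#' @export
make_tiny_rbm <- function(m, n, seed = 1L, scale = 1) {
  if (m + n > 6) {
    stop_hcadbn("tiny RBM fixtures are limited to m + n <= 6",
                "hcadbn_intractable_enumeration_error")
  }
  old <- .Random.seed_exists()
  set.seed(assert_seed(seed))
  params <- rbm_params(
    W = matrix(stats::rnorm(m * n, sd = scale), m, n),
    a = stats::rnorm(m, sd = scale / 2),
    b = stats::rnorm(n, sd = scale / 2)
  )
  .Random.seed_restore(old)
  V <- binary_states(m)
  H <- binary_states(n)
  grid <- expand.grid(vi = seq_len(nrow(V)), hi = seq_len(nrow(H)))
  probs <- mapply(function(vi, hi) {
    rbm_joint_probability(V[vi, ], H[hi, ], params)
  }, grid$vi, grid$hi)
  states <- cbind(
    as.data.frame(V[grid$vi, , drop = FALSE]) |>
      stats::setNames(paste0("v", seq_len(m))),
    as.data.frame(H[grid$hi, , drop = FALSE]) |>
      stats::setNames(paste0("h", seq_len(n)))
  )
  states$probability <- probs
  list(params = params, states = states)
}
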