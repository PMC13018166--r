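#' Hyperparameter search space for the hill climb
#'
#' Domains mirror the tuned ranges: hidden units 2-500 (step 4 moves),
#' learning rate multiplicative x2 / /2 moves inside `[1e-4, 1e-1]`,
#' dropout 0.20-0.50 in 0.05 steps, batch size over 2/4/8/16/32/64, all
#' four activations and optimizers, epochs over 50/100/150/200. Setting
#' `max_layers > 1` enables add-a-layer / drop-a-layer moves.
#'
#' @param units_range integer lower/upper bound on hidden-layer width.
#' @param units_step additive step for width moves.
#' @param lr_range learning-rate bounds (moves are x2 and /2).
#' @param dropout_range dropout bounds.
#' @param dropout_step additive dropout step.
#' @param batch_sizes admissible batch sizes, ordered.
#' @param activations admissible activations.
#' @param optimizers admissible optimizers.
#' @param epochs_grid admissible epoch counts.
#' @param max_layers maximum stack depth explored.
#' @return a `search_space`.
#' @export
search_space <- function(units_range = c(2L, 500L), units_step = 4L,
                         lr_range = c(1e-4, 1e-1),
                         dropout_range = c(0.20, 0.50), dropout_step = 0.05,
                         batch_sizes = dbn_batch_sizes,
                         activations = dbn_activations,
                         optimizers = dbn_optimizers,
                         epochs_grid = c(50L, 100L, 150L, 200L),
                         max_layers = 1L) {
  structure(list(units_range = as.integer(units_range),
                 units_step = as.integer(units_step),
                 lr_range = lr_range, dropout_range = dropout_range,
                 dropout_step = dropout_step,
                 batch_sizes = as.integer(batch_sizes),
                 activations = activations, optimizers = optimizers,
                 epochs_grid = as.integer(epochs_grid),
                 max_layers = as.integer(max_layers)),
            class = "search_space")
}

#' Draw a random candidate configuration
#'
#' Uniform per dimension (log-uniform for the learning rate); widths are
#' drawn on the step grid anchored at the lower bound. Uses the current RNG
#' stream.
#'
#' @param space a `search_space`.
#' @param seed optional integer seed; when given the draw is deterministic.
#' @return a `candidate`: list with `config` (a `dbn_config`) and `fitness`
#'   (`NA` until evaluated).
#' @export
random_candidate <- function(space, seed = NULL) {
  if (!is.null(seed)) {
    old <- .Random.seed_exists()
    set.seed(assert_seed(seed))
    on.exit(.Random.seed_restore(old))
  }
  pick <- function(x) x[sample.int(length(x), 1)]  # scalar-safe sample
  n_layers <- sample.int(space$max_layers, 1)
  grid <- seq(space$units_range[1], space$units_range[2],
              by = space$units_step)
  sizes <- grid[sample.int(length(grid), n_layers, replace = TRUE)]
  dropout_grid <- seq(space$dropout_range[1], space$dropout_range[2],
                      by = space$dropout_step)
  lr <- exp(stats::runif(1, log(space$lr_range[1]), log(space$lr_range[2])))
  cfg <- dbn_config(
    hidden_layer_sizes = sizes,
    dropout_rate = pick(dropout_grid),
    activation = pick(space$activations),
    optimizer = pick(space$optimizers),
    learning_rate = lr,
    batch_size = pick(space$batch_sizes),
    epochs = pick(space$epochs_grid),
    seed = 1L
  )
  candidate(cfg)
}

#' @rdname random_candidate
#' @param config a `dbn_config`.
#' @param fitness evaluated fitness, or `NA`.
#' @export
candidate <- function(config, fitness = NA_real_) {
  stopifnot(inherits(config, "dbn_config"))
  structure(list(config = config, fitness = fitness), class = "candidate")
}

## Key identifying a configuration (used for fitness memoisation and
## self-exclusion in neighborhoods).
config_key <- function(config) {
  paste(paste(config$hidden_layer_sizes, collapse = "-"),
        sprintf("%.4f", config$dropout_rate), config$activation,
        config$optimizer, sprintf("%.8g", config$learning_rate),
        config$batch_size, config$epochs, sep = "|")
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Enumerate the neighborhood of a candidate
#'
#' One-dimension-at-a-time moves, in deterministic order: width +/- step on
#' each layer (plus add/drop a layer when the space allows depth > 1),
#' dropout +/- 0.05, learning rate x2 and /2, adjacent batch sizes, every
#' alternative activation, every alternative optimizer, adjacent epoch grid
#' points. Moves leaving the domain are dropped; the candidate itself never
#' appears in its own neighborhood.
#'
#' @param cand a `candidate`.
#' @param space a `search_space`.
#' @return list of unevaluated `candidate`s.
#' @export
candidate_neighbors <- function(cand, space) {
  cfg <- cand$config
  out <- list()
  push <- function(new_cfg) {
    if (is.null(new_cfg)) return(invisible(NULL))
    out[[length(out) + 1]] <<- candidate(new_cfg)
    invisible(NULL)
  }
  mutate <- function(...) {
    args <- list(...)
    f <- cfg
    for (nm in names(args)) f[[nm]] <- args[[nm]]
    tryCatch(dbn_config(f$hidden_layer_sizes, f$dropout_rate, f$activation,
                        f$optimizer, f$learning_rate, f$batch_size,
                        f$epochs, f$seed),
             hcadbn_config_error = function(e) NULL)
  }
  # layer widths
  for (l in seq_along(cfg$hidden_layer_sizes)) {
    for (delta in c(space$units_step, -space$units_step)) {
      sizes <- cfg$hidden_layer_sizes
      sizes[l] <- sizes[l] + delta
      if (sizes[l] >= space$units_range[1] &&
          sizes[l] <= space$units_range[2]) {
        push(mutate(hidden_layer_sizes = sizes))
      }
    }
  }
  # stack depth
  if (space$max_layers > length(cfg$hidden_layer_sizes)) {
    last <- cfg$hidden_layer_sizes[length(cfg$hidden_layer_sizes)]
    push(mutate(hidden_layer_sizes = c(cfg$hidden_layer_sizes, last)))
  }
  if (length(cfg$hidden_layer_sizes) > 1) {
    push(mutate(hidden_layer_sizes =
                  cfg$hidden_layer_sizes[-length(cfg$hidden_layer_sizes)]))
  }
  # dropout
  for (delta in c(space$dropout_step, -space$dropout_step)) {
    d <- round(cfg$dropout_rate + delta, 10)
    if (d >= space$dropout_range[1] - 1e-9 &&
        d <= space$dropout_range[2] + 1e-9) {
      push(mutate(dropout_rate = clamp(d, space$dropout_range[1],
                                       space$dropout_range[2])))
    }
  }
  # learning rate
  for (factor in c(2, 0.5)) {
    lr <- cfg$learning_rate * factor
    if (lr >= space$lr_range[1] && lr <= space$lr_range[2]) {
      push(mutate(learning_rate = lr))
    }
  }
  # batch size (adjacent grid points)
  bi <- match(cfg$batch_size, space$batch_sizes)
  if (!is.na(bi)) {
    if (bi < length(space$batch_sizes)) {
      push(mutate(batch_size = space$batch_sizes[bi + 1]))
    }
    if (bi > 1) push(mutate(batch_size = space$batch_sizes[bi - 1]))
  }
  # activation / optimizer alternatives
  for (a in setdiff(space$activations, cfg$activation)) {
    push(mutate(activation = a))
  }
  for (o in setdiff(space$optimizers, cfg$optimizer)) {
    push(mutate(optimizer = o))
  }
  # epochs (adjacent grid points)
  ei <- match(cfg$epochs, space$epochs_grid)
  if (!is.na(ei)) {
    if (ei < length(space$epochs_grid)) {
      push(mutate(epochs = space$epochs_grid[ei + 1]))
    }
    if (ei > 1) push(mutate(epochs = space$epochs_grid[ei - 1]))
  }
  self <- config_key(cfg)
  Filter(function(cd) config_key(cd$config) != self, out)
}

#' Validation-accuracy fitness of a candidate configuration
#'
#' Pre-trains and fine-tunes a DBN under the candidate configuration on the
#' training set and scores accuracy on the validation set. The evaluation
#' seed is fixed (overriding the candidate's own seed) so that fitness is a
#' deterministic function of the configuration within one search. A training
#' failure (non-finite loss) yields fitness 0 with a warning rather than an
#' abort.
#'
#' @param cand a `candidate`.
#' @param train,validation `labeled_dataset`s; validation must contain both
#'   classes.
#' @param eval_seed fixed seed used for every evaluation in a search.
#' @param rbm_config an `rbm_train_config` for the pre-training stage.
#' @return fitness in `[0,1]`.
#' @export
evaluate_fitness <- function(cand, train, validation, eval_seed = 1L,
                             rbm_config = rbm_train_config(seed = eval_seed)) {
  if (length(validation$labels) == 0 ||
      length(unique(validation$labels)) < 2) {
    stop_hcadbn("validation set must be non-empty with both classes",
                "hcadbn_validation_error")
  }
  cfg <- cand$config
  cfg$seed <- assert_seed(eval_seed)
  fit <- tryCatch(
    train_dbn(train, cfg, rbm_config),
    hcadbn_training_error = function(e) NULL
  )
  if (is.null(fit)) {
    warning("candidate training diverged (non-finite loss); fitness 0")
    return(0)
  }
  pred <- predict(fit$model, validation$features)
  mean(pred$labels == validation$labels)
}

#' Steepest-ascent hill climb over DBN configurations
#'
#' Starting from a random candidate (per restart), evaluates the full
#' neighborhood each iteration and moves to the best neighbor only when it
#' strictly improves fitness (ties broken by deterministic neighbor order).
#' Stops at a local optimum, or when `patience` consecutive iterations bring
#' no improvement, or at `max_iterations`. Fitness values are memoised per
#' configuration, so the trace is re-evaluable under the fixed evaluation
#' seed.
#'
#' @param space a `search_space`.
#' @param train,validation `labeled_dataset`s used by the default fitness
#'   (ignored when `fitness_fn` is given).
#' @param seed integer seed controlling the random start(s).
#' @param max_iterations maximum climb iterations per restart.
#' @param patience consecutive non-improving iterations tolerated.
#' @param n_restarts independent climbs; the best result is returned.
#' @param fitness_fn optional deterministic function `config -> fitness`
#'   replacing the DBN training fitness (surrogate landscapes, testing).
#' @param eval_seed fixed seed for [evaluate_fitness()].
#' @param rbm_config pre-training configuration for the default fitness.
#' @return list with `best` (evaluated `candidate`) and `trace` (a
#'   `search_trace` data frame: restart, iteration, config key, fitness,
#'   accepted flag, stop reason).
#' @export
hill_climb <- function(space, train = NULL, validation = NULL, seed = 1L,
                       max_iterations = 25L, patience = Inf,
                       n_restarts = 1L, fitness_fn = NULL, eval_seed = 1L,
                       rbm_config = rbm_train_config(seed = eval_seed)) {
  stopifnot(max_iterations >= 1)
  seed <- assert_seed(seed)
  if (is.null(fitness_fn)) {
    if (is.null(train) || is.null(validation)) {
      stop_hcadbn("supply train and validation sets or a fitness_fn",
                  "hcadbn_config_error")
    }
    fitness_fn <- function(config) {
      evaluate_fitness(candidate(config), train, validation, eval_seed,
                       rbm_config)
    }
  }
  cache <- new.env(parent = emptyenv())
  n_evals <- 0L
  fitness_of <- function(config) {
    key <- config_key(config)
    if (!is.null(cache[[key]])) return(cache[[key]])
    n_evals <<- n_evals + 1L
    val <- fitness_fn(config)
    cache[[key]] <- val
    val
  }
  rows <- list()
  log_row <- function(restart, iteration, config, fitness, accepted) {
    rows[[length(rows) + 1]] <<- data.frame(
      restart = restart, iteration = iteration,
      config = config_key(config), fitness = fitness,
      accepted = accepted, stringsAsFactors = FALSE)
  }
  best_overall <- NULL
  stop_reason <- character(n_restarts)
  for (r in seq_len(n_restarts)) {
    current <- random_candidate(space, seed = derive_seed(seed, r))
    current$fitness <- fitness_of(current$config)
    log_row(r, 0L, current$config, current$fitness, TRUE)
    reason <- "max_iterations"
    for (it in seq_len(max_iterations)) {
      nbrs <- candidate_neighbors(current, space)
      if (length(nbrs) == 0) { reason <- "local_optimum"; break }
      fits <- vapply(nbrs, function(nb) fitness_of(nb$config), numeric(1))
      for (j in seq_along(nbrs)) {
        log_row(r, it, nbrs[[j]]$config, fits[j], FALSE)
      }
      best_j <- which.max(fits)  # first index on ties
      if (fits[best_j] > current$fitness) {
        current <- candidate(nbrs[[best_j]]$config, fits[best_j])
        log_row(r, it, current$config, current$fitness, TRUE)
      } else {
        reason <- "local_optimum"
        break
      }
      if (it >= patience) { reason <- "patience"; break }
    }
    stop_reason[r] <- reason
    if (is.null(best_overall) || current$fitness > best_overall$fitness) {
      best_overall <- current
    }
  }
  trace <- do.call(rbind, rows)
  attr(trace, "n_evaluations") <- n_evals
  attr(trace, "stop_reason") <- stop_reason
  class(trace) <- c("search_trace", "data.frame")
  list(best = best_overall, trace = trace)
}

#' @export
print.search_trace <- function(x, ...) {
  acc <- x[x$accepted, , drop = FALSE]
  cat(sprintf(
    "<search_trace> %d evaluations, %d accepted moves, stop: %s\n",
    attr(x, "n_evaluations"), nrow(acc) - length(unique(x$restart)),
    paste(attr(x, "stop_reason"), collapse = ", ")))
  invisible(x)
}
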