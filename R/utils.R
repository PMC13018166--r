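#' @keywords internal
"_PACKAGE"

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Round half away from zero
#'
#' Display rounding used throughout reports: 0.857 -> 0.86, 0.9375 -> 0.94.
#' Base [round()] rounds half to even, which does not match the tabulated
#' two-decimal convention, so half-up is applied explicitly.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded half away from zero.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

## Numerically stable log(sum(exp(x)))
logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## All 2^k binary configurations as a (2^k x k) 0/1 matrix, row-major order
## with the last column fastest (state i is the binary expansion of i - 1).
binary_states <- function(k) {
  if (k == 0L) return(matrix(0, nrow = 1L, ncol = 0L))
  idx <- 0:(2^k - 1)
  m <- sapply(rev(seq_len(k)), function(bit) (idx %/% 2^(bit - 1)) %% 2)
  matrix(as.numeric(m), nrow = 2^k, ncol = k)
}

stop_hcadbn <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "hcadbn_error")))
}

assert_seed <- function(seed) {
  if (length(seed) != 1 || !is.finite(seed) || seed != as.integer(seed)) {
    stop_hcadbn("`seed` must be a single integer", "hcadbn_config_error")
  }
  as.integer(seed)
}

## Deterministic per-stage seed derivation from one global seed so pipeline
## stages can be re-run in isolation; documented in the manifest.
derive_seed <- function(seed, stage_index) {
  as.integer((as.numeric(seed) * 1000 + 7 * stage_index) %% 2147483647)
}
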