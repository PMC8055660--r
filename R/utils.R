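#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble tibble as_tibble
#' @importFrom Rcpp evalCpp
#' @useDynLib falffprog, .registration = TRUE
NULL

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. All randomness in the package funnels through this.
with_seed <- function(seed, code) {
  if (!is.null(old <- get0(".Random.seed", globalenv(), mode = "integer"))) {
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  force(code)
}

# Deterministic fan-out of one master seed into per-task sub-seeds. The rule is
# fixed so that subject i always receives the same sub-seed regardless of how
# many other subjects exist or in what order they are generated.
derive_seed <- function(seed, index, stream = 0L) {
  (as.double(seed) * 48271 + as.double(index) * 7919 + as.double(stream) * 104729) %%
    2147483587 + 1
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != as.integer(x)) {
    abort(sprintf("`%s` must be a single integer >= %d.", name, min),
          class = "falffprog_config_error")
  }
  as.integer(x)
}

check_number <- function(x, name, min = -Inf, max = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x > max) {
    abort(sprintf("`%s` must be a single number in [%s, %s].", name, min, max),
          class = "falffprog_config_error")
  }
  as.double(x)
}

#' Clamp a prediction to a test's dynamic range
#'
#' Predictions outside the known range of a bounded score (for example a
#' proportion-correct measure in \[0, 1\]) are rounded to the nearest edge of
#' that range. Idempotent.
#'
#' @param value Numeric vector of finite values.
#' @param range Length-2 numeric, the closed dynamic range (default `c(0, 1)`).
#' @return `value` with every element clamped into `range`.
#' @examples
#' clamp_prediction(c(-0.02, 0.5, 1.05))
#' @export
clamp_prediction <- function(value, range = c(0, 1)) {
  stopifnot(is.numeric(value), all(is.finite(value)),
            length(range) == 2L, range[1] <= range[2])
  pmin(pmax(value, range[1]), range[2])
}
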