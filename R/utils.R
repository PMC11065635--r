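# Internal helpers shared across modules.

#' Run code with a temporary RNG seed
#'
#' Evaluates \code{code} with the global RNG seeded to \code{seed}, then
#' restores the previous RNG state so callers never perturb each other.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic per-component sub-seed derived from (root seed, component name).
# Adding a new generator component never perturbs the stream of another.
# Arithmetic stays below 2^31 so the result is a valid R integer seed.
stream_seed <- function(seed, component) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(component))
  h <- 0
  for (ch in utf8ToInt(component)) h <- (h * 131 + ch) %% 1000000007
  as.integer((abs(seed) %% 1000003) * 2011 + h %% 100000) %% 2147483647L
}

# stopifnot() with a formatted message
fail_if <- function(cond, fmt, ...) {
  if (cond) stop(sprintf(fmt, ...), call. = FALSE)
  invisible(TRUE)
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= min && x == round(x)
}

is_range <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 2L && all(is.finite(x)) && all(x >= min) &&
    x[1] <= x[2] && all(x == round(x))
}
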