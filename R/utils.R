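# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
# `seed = NULL` leaves the current RNG stream untouched.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    abort("`seed` must be a single number or NULL.", class = "dyadsync_input_error")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed) %% .Machine$integer.max)
  force(code)
}

stop_input <- function(msg) abort(msg, class = "dyadsync_input_error")
stop_format <- function(msg) abort(msg, class = "dyadsync_format_error")

# Single scalar checks used by parameter constructors.
check_scalar <- function(x, name, lower = -Inf, upper = Inf, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x)) {
    stop_input(sprintf("`%s` must be a single non-missing number.", name))
  }
  if (x < lower || x > upper) {
    stop_input(sprintf("`%s` must be in [%s, %s], got %s.", name, lower, upper, x))
  }
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_input(sprintf("`%s` must be a whole number, got %s.", name, x))
  }
  invisible(x)
}
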