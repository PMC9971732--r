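#' @keywords internal
"_PACKAGE"

# Condition helpers -----------------------------------------------------------

np_stop <- function(msg, class, ...) {
  stop(errorCondition(msg, ..., class = c(class, "netpharm_error")))
}

np_validation_error <- function(msg, ...) {
  np_stop(msg, "netpharm_validation_error", ...)
}

# Run `code` with a temporarily seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that results
# are reproducible without clobbering the session RNG.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# Derive a stage-specific sub-seed from a single pipeline seed.  Offsets are
# fixed per stage name so adding a stage never shifts another stage's stream.
stage_seed <- function(seed, stage) {
  offsets <- c(
    fixtures = 101L, epc = 211L, mcode = 307L, tf = 401L,
    ora = 503L, expand = 601L, ppi = 701L, sets = 809L, library = 907L
  )
  if (!stage %in% names(offsets)) {
    np_validation_error(sprintf("unknown pipeline stage '%s'", stage))
  }
  (as.integer(seed) %% 2000000L) * 1000L + offsets[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# sample() treats a length-1 numeric x as 1:x; this variant never does
sample_vec <- function(x, size, replace = FALSE) {
  x[sample.int(length(x), size, replace = replace)]
}

assert_scalar_number <- function(x, name, lo = -Inf, hi = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lo || x > hi) {
    np_validation_error(sprintf(
      "'%s' must be a single number in [%s, %s]", name, format(lo), format(hi)
    ))
  }
  invisible(x)
}
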