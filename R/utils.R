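# Internal helpers: classed errors and local seeding.

vd_error <- function(type, msg, call = sys.call(-1)) {
  stop(errorCondition(msg,
    class = c(paste0("validisc_error_", type), "validisc_error", "error", "condition"),
    call = call
  ))
}

vd_warning <- function(type, msg) {
  warning(warningCondition(msg,
    class = c(paste0("validisc_warning_", type), "validisc_warning", "warning", "condition")
  ))
}

# Evaluate expr with the RNG seeded at `seed`, restoring the caller's RNG
# state afterwards. seed = NULL runs in the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    vd_error("bad_argument", "`seed` must be a single integer or NULL")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

# Derive `n` reproducible sub-seeds from a master seed (or from the ambient
# stream when seed is NULL). Sub-seeds stay within 32-bit integer range.
spawn_seeds <- function(n, seed = NULL) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

check_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != floor(x)) {
    vd_error("bad_argument", sprintf("`%s` must be a single integer >= %d", name, min))
  }
  as.integer(x)
}
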