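#' @keywords internal
"_PACKAGE"

# Internal argument checks -----------------------------------------------

stop_if_not <- function(cond, msg, call. = FALSE) {
  if (!isTRUE(cond)) stop(msg, call. = call.)
}

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_na = FALSE) {
  if (allow_na && length(x) == 1L && is.na(x)) return(invisible(x))
  stop_if_not(is.numeric(x) && length(x) == 1L && is.finite(x),
              sprintf("`%s` must be a single finite number", name))
  stop_if_not(x >= lower && x <= upper,
              sprintf("`%s` must be in [%s, %s]", name, lower, upper))
  invisible(x)
}

check_probability <- function(x, name) check_number(x, name, 0, 1)

# Derive independent per-unit seeds from a master seed, each below 2^31.
# sample.int under the master seed gives a reproducible stream that does
# not collide trivially across n.
derive_seeds <- function(seed, n) {
  stop_if_not(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
              "`seed` must be a single integer")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max, n)
}

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Run expr with a local RNG state seeded by `seed`, restoring the caller's
# stream afterwards so generators are pure functions of (params, seed).
with_seed <- function(seed, expr) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(as.integer(seed))
  expr
}
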