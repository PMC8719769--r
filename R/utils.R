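# Internal helpers shared across modules.

# Run `code` under a temporary RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(code)
}

# Derive a child seed from a parent seed; stays well below 2^31.
derive_seed <- function(seed, k) {
  (as.integer(seed) %% 1000003L) * 1009L + as.integer(k) %% 1009L
}

is_count <- function(x) {
  length(x) == 1 && is.numeric(x) && is.finite(x) && x >= 1 && x == floor(x)
}

# Binary mask checks: 0/1 integer or logical content.
assert_binary_mask <- function(x, what = "mask") {
  v <- as.vector(x)
  if (!all(v %in% c(0, 1))) {
    abort(sprintf("%s must be binary (0/1); found other values", what))
  }
  invisible(TRUE)
}

assert_same_dim <- function(a, b, what = c("a", "b")) {
  da <- dim(a) %||% length(a)
  db <- dim(b) %||% length(b)
  if (!identical(as.integer(da), as.integer(db))) {
    abort(sprintf(
      "%s (%s) and %s (%s) must have identical dimensions",
      what[1], paste(da, collapse = "x"), what[2], paste(db, collapse = "x")
    ))
  }
  invisible(TRUE)
}

`%||%` <- function(x, y) if (is.null(x)) y else x
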