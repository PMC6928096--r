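## internal validation and RNG helpers

stop_invalid <- function(what, msg) {
  stop(sprintf("invalid %s: %s", what, msg), call. = FALSE)
}

check_positive <- function(x, name, what) {
  if (!is.numeric(x) || length(x) < 1L || any(!is.finite(x)) || any(x <= 0))
    stop_invalid(what, sprintf("'%s' must be finite and > 0", name))
  invisible(x)
}

check_fraction <- function(x, name, what, open_upper = FALSE) {
  ok <- is.numeric(x) && all(is.finite(x)) && all(x >= 0) &&
    all(if (open_upper) x < 1 else x <= 1)
  if (!ok)
    stop_invalid(what, sprintf("'%s' must lie in [0,%s]", name,
                               if (open_upper) "1)" else "1]"))
  invisible(x)
}

## Evaluate `expr` under a deterministic RNG state derived from `seed`,
## restoring the caller's RNG state afterwards.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

## Spawn a per-stage seed from a top-level seed. Keeps results inside
## 32-bit integer range for set.seed().
derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + 11 * k) %% 2147483629)
}

pkg_version <- function() {
  as.character(utils::packageVersion("turpeval"))
}
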