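# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards, so library functions that take
#' a `seed` argument never perturb user-level random streams.
#' @noRd
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# locale-independent ordering of subject identifiers; all deterministic
# tie-breaks in the package go through this
.idOrder <- function(ids) order(ids, method = "radix")

.sortIDs <- function(ids) ids[.idOrder(ids)]

.assertString <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x)) {
    stop(sprintf("'%s' must be a single non-missing character string", what),
         call. = FALSE)
  }
  invisible(x)
}

.assertCount <- function(x, what, min = 0L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min ||
      x != floor(x)) {
    stop(sprintf("'%s' must be a single integer >= %d", what, min),
         call. = FALSE)
  }
  invisible(as.integer(x))
}

.assertFraction <- function(x, what, maxExclusive = 1) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x >= maxExclusive) {
    stop(sprintf("'%s' must be in [0, %g)", what, maxExclusive),
         call. = FALSE)
  }
  invisible(as.numeric(x))
}
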