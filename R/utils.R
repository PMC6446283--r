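#' @keywords internal
"_PACKAGE"

# Deterministic 31-bit string hash (polynomial rolling hash). Used to derive
# independent sub-seeds from a master seed plus a context key, so that cohorts
# are extensible (adding subjects never reshuffles existing sessions).
hash31 <- function(key) {
  bytes <- utf8ToInt(enc2utf8(key))
  h <- 0
  for (b in bytes) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Derive a reproducible sub-seed
#'
#' Combines a master seed with a context key (e.g. `"S03/V2/noise"`) into an
#' integer seed below 2^31. The same (seed, key) pair always yields the same
#' sub-seed; distinct keys decorrelate the streams.
#'
#' @param seed Integer master seed.
#' @param key Character context key.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, key) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.character(key))
  hash31(paste0(format(seed, scientific = FALSE), "|", key))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring the
# caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

stop_invalid <- function(...) stop(..., call. = FALSE)

check_scalar <- function(x, name, positive = FALSE, nonneg = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    stop_invalid(name, " must be a finite numeric scalar")
  }
  if (positive && x <= 0) stop_invalid(name, " must be > 0 (got ", x, ")")
  if (nonneg && x < 0) stop_invalid(name, " must be >= 0 (got ", x, ")")
  invisible(x)
}
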