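# Internal helpers shared across modules.

#' Evaluate an expression under a temporary RNG state
#'
#' Seeds the RNG, runs `expr`, and restores the caller's RNG state so that
#' seeded package functions never perturb the user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

#' Derive a per-stage seed from a global seed
#'
#' Stable string hash (polynomial rolling hash mod 2^31 - 1) combined with the
#' global seed so that pipeline stages can be rerun in isolation yet remain
#' reproducible from one number.
#' @noRd
derive_seed <- function(seed, stage) {
  h <- 0
  for (code in utf8ToInt(stage)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer((as.numeric(seed) + h) %% 2147483647)
}

#' @noRd
stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' @noRd
assert_prob <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x <= 0 || x >= 1) {
    stopf("`%s` must be a single number in (0, 1)", name)
  }
  invisible(x)
}
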