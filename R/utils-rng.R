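#' Evaluate an expression under a local random seed
#'
#' Runs \code{expr} with the global RNG state set from \code{seed} and
#' restores the caller's RNG state afterwards, so no operation in the
#' package leaks into (or depends on) the session's random stream.
#'
#' @param seed Integer scalar seed.
#' @param expr Expression to evaluate.
#' @return The value of \code{expr}.
#' @export
#' @examples
#' a <- withSeed(1, rnorm(3))
#' b <- withSeed(1, rnorm(3))
#' identical(a, b)
withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Deterministically maps a master seed plus a character tag (and optional
#' index) to a new seed in \code{[0, 2^31 - 1]}. Used so that every stage of
#' a pipeline run draws from an independent, reproducible stream while all
#' randomness still flows from one master seed.
#'
#' @param seed Integer master seed.
#' @param tag Character scalar naming the consumer.
#' @param index Optional non-negative integer (e.g. replicate number).
#' @return Integer seed.
#' @export
#' @examples
#' deriveSeed(1L, "bootstrap")
#' deriveSeed(1L, "bootstrap", 7)
deriveSeed <- function(seed, tag, index = 0L) {
  stopifnot(is.character(tag), length(tag) == 1L)
  h <- 0
  for (v in utf8ToInt(tag)) h <- (h * 131 + v) %% 2147483647
  as.integer((abs(as.numeric(seed)) %% 2147483647 * 48271 + h * 69621 +
                as.numeric(index) * 16807) %% 2147483647)
}
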