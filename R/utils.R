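# Internal helpers: seeding, argument checks.

#' Evaluate an expression under a temporary RNG seed
#'
#' Runs `expr` with the RNG seeded at `seed`, then restores the previous
#' global RNG state, so seeded operations do not perturb the caller's
#' random stream.  A `NULL` seed evaluates `expr` with the current stream.
#'
#' @param seed integer scalar or `NULL`.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage-specific seed from a master seed
#'
#' Combines a master seed with a stage label through a small string hash so
#' that each pipeline stage draws from its own reproducible stream.  Adding
#' new stages never shifts the seeds of existing ones.
#'
#' @param master integer master seed.
#' @param label character stage label, e.g. `"sim2/orthog/K5"`.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' derive_seed(1, "sim1/normal") != derive_seed(1, "sim1/nb")
derive_seed <- function(master, label) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(label),
            length(label) == 1L)
  h <- 0
  for (ch in utf8ToInt(label)) h <- (h * 31 + ch) %% 1000003
  as.integer((abs(master) * 1009 + h * 2017 + 13) %% 2147483646)
}

# stop() with sprintf-style formatting, no call in the message
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) &&
  x >= 1 && x == round(x)
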