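# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that library code never perturbs the
#' caller's RNG stream.
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
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

#' Derive a reproducible sub-seed from a master seed and a string tag
#'
#' Every source of randomness in the package draws its seed through this
#' counter-free scheme, so a single master seed determines an entire run
#' while independent stages (subjects, epochs, folds, ...) get distinct
#' streams. The result always lies in `[1, 2^31 - 2]`.
#'
#' @param seed integer master seed.
#' @param ... components (coerced to character) identifying the stage.
#' @return an integer seed.
#' @export
#' @examples
#' derive_seed(42, "subject", "sub_003")
derive_seed <- function(seed, ...) {
  key <- paste(vapply(list(...), as.character, character(1)), collapse = "/")
  # 31-multiplier polynomial hash over (seed, key) modulo the Mersenne
  # prime 2^31 - 1; all intermediates stay below 2^53 so the arithmetic
  # is exact in doubles
  h <- abs(as.numeric(seed)) %% 2147483647
  for (ch in utf8ToInt(key)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h %% 2147483646 + 1)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

# zero-padded id strings: "sub_007" etc.
pad_id <- function(prefix, i, width = 3) {
  sprintf("%s_%0*d", prefix, width, i)
}
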