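# Internal helpers shared across modules.

#' Round half away from zero at a fixed number of decimals
#'
#' Base [round()] rounds half to even; published comparative tables in
#' this field round half up, so report formatting uses this helper.
#' A small epsilon guards against values such as 11.15 being stored as
#' 11.14999... in binary floating point.
#'
#' @param x numeric vector.
#' @param digits integer, decimal places (default 0).
#' @return numeric vector rounded half-up to `digits` decimals.
#' @examples
#' round_half_up(c(0.5, 1.25, 2.345), c(0, 1, 2))
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`,
# restoring the caller's .Random.seed afterwards.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  expr
}

# The 20 standard amino-acid one-letter codes.
AA_ALPHABET20 <- c("A","C","D","E","F","G","H","I","K","L",
                   "M","N","P","Q","R","S","T","V","W","Y")

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
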