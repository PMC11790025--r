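#' Round half away from zero
#'
#' Base `round()` rounds half to even, so 16.25 becomes 16.2; prevalence
#' percentages are conventionally reported with halves rounded up (8.75 ->
#' 8.8, 16.25 -> 16.3). Used wherever a printed percentage is produced.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 1).
#' @return Numeric vector rounded half away from zero.
#' @export
#' @examples
#' round_half_up(c(8.75, 16.25), 1)
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# Derive a reproducible substream seed from a master seed and a stream index.
# Streams are keyed by (offset + index) so that adding cells, sites, or frames
# never perturbs the draws of existing ones. Result stays below 2^31.
substream_seed <- function(seed, id) {
  # arithmetic in doubles (exact below 2^53), reduced before coercion
  as.integer(((as.double(seed) %% 2147483647) * 69069 +
                as.double(id)) %% 2147483647)
}

# Evaluate `expr` under a dedicated RNG substream, restoring the caller's
# RNG state afterwards.
with_substream <- function(seed, id, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, id))
  force(expr)
}

# scalar validators
assert_scalar_num <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (strict && x <= min) {
    stop(sprintf("`%s` must be > %g", name, min), call. = FALSE)
  }
  if (!strict && x < min) {
    stop(sprintf("`%s` must be >= %g", name, min), call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
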