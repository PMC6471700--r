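#' @keywords internal
"_PACKAGE"

# Derive a reproducible child seed from a base seed and an integer offset.
# Keeps results in [1, 2^31 - 2] so they are valid R integer seeds.
derive_seed <- function(base, offset) {
  as.integer((as.numeric(base) %% 2147483647 * 48271 + 1103515245 * offset) %% 2147483646 + 1)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

clip255 <- function(x) pmin(pmax(x, 0), 255)

quantize8 <- function(x) round(clip255(x))

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_count <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x) && x == round(x) && x > 0

# Pearson correlation that tolerates constant inputs (returns 0).
safe_cor <- function(a, b) {
  if (stats::sd(a) == 0 || stats::sd(b) == 0) return(0)
  stats::cor(as.vector(a), as.vector(b))
}
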