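#' @keywords internal
"_PACKAGE"

# Derive a reproducible substream seed from a root seed and a stream name.
# Keeps every derived seed inside the 32-bit signed-integer range.
substream_seed <- function(seed, name) {
  stopifnot(is.character(name), length(name) == 1L)
  chars <- utf8ToInt(name)
  h <- 0
  for (c in chars) h <- (h * 131 + c) %% 2147483647
  as.integer((as.numeric(seed) %% 2147483647 * 48271 + h) %% 2147483647)
}

with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(substream_seed(seed, name))
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  force(expr)
}

stop2 <- function(...) stop(..., call. = FALSE)

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop2(sprintf("'%s' must be a single finite number", name))
  invisible(x)
}
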