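## internal helpers shared across modules

stopf <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Round values to IEEE single precision
#'
#' Rounds every element of a numeric array to the nearest representable
#' 32-bit float (round-trip through a 4-byte binary representation),
#' returning doubles that carry only single-precision information.  Used to
#' emulate single-precision pipelines, since R has no native float type.
#'
#' @param x numeric vector/array.
#' @return numeric of the same shape, each element rounded to float32.
#' @export
round_f32 <- function(x) {
  d <- dim(x)
  y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
               what = "numeric", n = length(x), size = 4L)
  dim(y) <- d
  y
}

## smallest power of two >= n
next_pow2 <- function(n) {
  p <- 1L
  while (p < n) p <- p * 2L
  p
}

## bytes per element for the supported on-disk dtypes
dtype_size <- function(dtype) {
  switch(dtype,
         float32 = 4L,
         float64 = 8L,
         stopf("unknown dtype '%s' (expected float32 or float64)", dtype))
}

precision_dtype <- function(precision) {
  switch(precision, single = "float32", double = "float64",
         stopf("unknown precision '%s'", precision))
}

check_count <- function(x, name, min = 1L) {
  if (length(x) != 1L || !is.finite(x) || x < min || x != round(x))
    stopf("'%s' must be a single integer >= %d", name, min)
  as.integer(x)
}

check_positive <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x <= 0)
    stopf("'%s' must be a single positive number", name)
  as.numeric(x)
}
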