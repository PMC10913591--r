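#' Round values onto a reduced-precision storage grid
#'
#' `roundFloat32` round-trips doubles through IEEE 754 binary32 (C `float`),
#' giving the exact nearest-representable float32 value of each element.
#' `roundFloat16` quantizes to IEEE 754 binary16 (half precision) with
#' round-to-nearest-even, including subnormals below 2^-14 and overflow to
#' infinity beyond 65504. Arithmetic elsewhere in the package always runs in
#' double; these grids define what a reduced-precision weight store can hold.
#'
#' @param x numeric vector or matrix.
#' @return `x` with every element replaced by its nearest representable
#'   value in the target format (dimensions preserved).
#' @examples
#' roundFloat16(0.1)   # 0.0999755859375
#' roundFloat32(0.1) - 0.1
#' @export
roundFloat32 <- function(x) getBackend()$castF32(x)

#' @rdname roundFloat32
#' @export
roundFloat16 <- function(x) {
  y <- roundFloat32(x)   # half is a subset of float; go through binary32 first
  out <- y
  fin <- is.finite(y) & y != 0
  if (any(fin)) {
    ax <- abs(y[fin])
    p <- floor(log2(ax))
    p <- pmax(p, -14)                 # subnormal regime: fixed quantum 2^-24
    q <- 2^(p - 10)                   # ulp at this exponent (10 mantissa bits)
    r <- round(ax / q) * q            # round() is round-half-to-even
    r[r > 65504] <- Inf               # largest finite half
    out[fin] <- sign(y[fin]) * r
  }
  attributes(out) <- attributes(x)
  out
}

# Internal: snap a numeric array onto the storage grid of a dtype tag.
quantizeToDtype <- function(x, dtype) {
  switch(dtype,
         f64 = x,
         f32 = roundFloat32(x),
         f16 = roundFloat16(x),
         stop("unsupported dtype '", dtype, "'", call. = FALSE))
}

#' Cast a weight matrix to another storage precision
#'
#' Re-tags the matrix and rounds every entry onto the target grid. Casting
#' to the current dtype is the identity; widening (for example f32 to f64)
#' preserves all values exactly.
#'
#' @param W a [WeightMatrix].
#' @param dtype target precision, one of `"f64"`, `"f32"`, `"f16"`.
#' @return a [WeightMatrix] with the new dtype tag.
#' @examples
#' W <- weightMatrix(matrix(0.1, 2, 2))
#' weightDtype(castPrecision(W, "f32"))
#' @export
castPrecision <- function(W, dtype = c("f64", "f32", "f16")) {
  stopifnot(methods::is(W, "WeightMatrix"))
  dtype <- match.arg(dtype)
  if (dtype == W@dtype) return(W)
  methods::initialize(W, data = quantizeToDtype(W@data, dtype), dtype = dtype)
}

#' Nominal storage footprint of a weight matrix
#'
#' Element count times the byte width of the dtype tag (8 for f64, 4 for
#' f32, 2 for f16) -- the memory a native typed array of this matrix would
#' occupy, independent of how the host language stores it.
#'
#' @param W a [WeightMatrix].
#' @return integer-valued numeric byte count.
#' @examples
#' nominalBytes(weightMatrix(matrix(0, 10, 10)))  # 800
#' @export
nominalBytes <- function(W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  width <- c(f64 = 8, f32 = 4, f16 = 2)[[W@dtype]]
  length(W@data) * width
}
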