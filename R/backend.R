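#' @title Array backend facade
#'
#' @description All kernel and framework code allocates and manipulates
#' arrays through a small table of primitive operations (allocate, random
#' fill, boolean-mask and integer-mesh indexing, axis accumulation, clipping,
#' elementwise arithmetic, precision cast). Modules never call an array
#' library directly, so an accelerated backend can be registered and swapped
#' in without touching kernel or model code. One standard CPU backend is
#' registered at load time.
#'
#' Accumulation contract: every summation primitive accumulates in double
#' precision, adding contributions in ascending source-index order. Under
#' this contract adding an exact-zero term never changes the accumulator, so
#' subset (indexed) summation is bitwise equal to full (product) summation
#' in f64 -- the equivalence the optimized kernels rely on.
#'
#' @param name backend name, e.g. `"cpu"`.
#' @return `getBackend` returns the named backend's operation table (a list
#'   of functions); `listBackends` returns the names of registered backends.
#' @examples
#' bk <- getBackend("cpu")
#' bk$zeros(3)
#' @name backend
NULL

.backends <- new.env(parent = emptyenv())

#' @rdname backend
#' @param ops named list of primitive operations implementing the facade.
#' @export
registerBackend <- function(name, ops) {
  stopifnot(is.character(name), length(name) == 1L, is.list(ops))
  assign(name, ops, envir = .backends)
  invisible(name)
}

#' @rdname backend
#' @export
getBackend <- function(name = "cpu") {
  if (!exists(name, envir = .backends, inherits = FALSE)) {
    stop("unknown backend '", name, "'; registered: ",
         paste(listBackends(), collapse = ", "), call. = FALSE)
  }
  get(name, envir = .backends, inherits = FALSE)
}

#' @rdname backend
#' @export
listBackends <- function() ls(.backends)

# The standard CPU backend. Loops run over whole vectors/rows so each
# iteration is a vectorized primitive; the loop order fixes the accumulation
# order required by the contract above.
.cpuBackend <- function() {
  list(
    name = "cpu",

    zeros = function(n) numeric(n),
    fill  = function(n, value) rep(as.numeric(value), n),
    runif = function(n, min = 0, max = 1) stats::runif(n, min, max),
    rnorm = function(n, mean = 0, sd = 1) stats::rnorm(n, mean, sd),

    # out[j] = sum over r in rows (ascending) of data[r, j]
    rowAccum = function(data, rows) {
      out <- numeric(ncol(data))
      for (r in rows) out <- out + data[r, ]
      out
    },
    # out[i] = sum over c in cols (ascending) of data[i, c]
    colAccum = function(data, cols) {
      out <- numeric(nrow(data))
      for (c in cols) out <- out + data[, c]
      out
    },
    # out[j] = sum over all rows r of data[r, j] * w[r]
    weightedRowAccum = function(data, w) {
      out <- numeric(ncol(data))
      for (r in seq_len(nrow(data))) out <- out + data[r, ] * w[r]
      out
    },
    # out[i] = sum over all cols c of data[i, c] * w[c]
    weightedColAccum = function(data, w) {
      out <- numeric(nrow(data))
      for (c in seq_len(ncol(data))) out <- out + data[, c] * w[c]
      out
    },

    meshAdd = function(data, rows, cols, inc) {
      data[rows, cols] <- data[rows, cols] + inc
      data
    },
    meshClip = function(data, rows, cols, lo, hi) {
      data[rows, cols] <- pmin(pmax(data[rows, cols], lo), hi)
      data
    },
    clipAll = function(data, lo, hi) {
      out <- pmin(pmax(data, lo), hi)
      dim(out) <- dim(data)
      out
    },

    scaleRows = function(data, f) data * f,            # recycles down columns
    scaleCols = function(data, f) data * rep(f, each = nrow(data)),
    transpose = function(data) t(data),

    castF32 = function(x) {
      n <- length(x)
      y <- readBin(writeBin(as.numeric(x), raw(), size = 4L),
                   what = "numeric", n = n, size = 4L)
      attributes(y) <- attributes(x)
      y
    }
  )
}

.onLoad <- function(libname, pkgname) {
  bk <- .cpuBackend()
  registerBackend("cpu", bk)
  invisible(NULL)
}
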