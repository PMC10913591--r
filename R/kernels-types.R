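#' Construct a spike vector
#'
#' @param values logical (or coercible) vector of per-neuron firing states.
#' @return a [SpikeVector].
#' @examples
#' spikeVector(c(TRUE, FALSE, TRUE))
#' @export
spikeVector <- function(values) {
  v <- as.logical(values)
  new("SpikeVector", values = v, active = which(v))
}

#' @rdname spikeVector
#' @param sv a [SpikeVector].
#' @export
activeIndices <- function(sv) {
  stopifnot(methods::is(sv, "SpikeVector"))
  sv@active
}

#' @rdname spikeVector
#' @export
spikeValues <- function(sv) {
  stopifnot(methods::is(sv, "SpikeVector"))
  sv@values
}

setMethod("show", "SpikeVector", function(object) {
  cat(sprintf("SpikeVector of %d neurons, %d active (%.2f%%)\n",
              length(object@values), length(object@active),
              100 * mean(object@values)))
})

setMethod("length", "SpikeVector", function(x) length(x@values))

#' Construct a tagged weight matrix
#'
#' @param data numeric matrix. For `layout = "dst_major"` rows index the
#'   destination population (shape D x S); for `"src_major"` rows index the
#'   source population (shape S x D).
#' @param layout storage orientation, `"dst_major"` or `"src_major"`.
#' @param dtype storage precision grid; values are rounded onto it.
#' @return a [WeightMatrix].
#' @examples
#' weightMatrix(matrix(0, 4, 2), layout = "dst_major")
#' @export
weightMatrix <- function(data, layout = c("dst_major", "src_major"),
                         dtype = c("f64", "f32", "f16")) {
  layout <- match.arg(layout)
  dtype <- match.arg(dtype)
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (layout == "dst_major") {
    D <- nrow(data); S <- ncol(data)
  } else {
    S <- nrow(data); D <- ncol(data)
  }
  new("WeightMatrix", data = quantizeToDtype(data, dtype), layout = layout,
      dtype = dtype, srcSize = as.integer(S), dstSize = as.integer(D))
}

#' Weight-matrix accessors
#'
#' @param W a [WeightMatrix].
#' @return `weightData` the raw storage matrix; `matrixLayout` the layout
#'   tag; `weightDtype` the precision tag; `srcSize`/`dstSize` the population
#'   sizes; `weightEntry` the semantic entry W\[d, s\] independent of layout.
#' @examples
#' W <- weightMatrix(matrix(1:6, 2, 3), layout = "src_major")
#' weightEntry(W, d = 2, s = 1)
#' @export
weightData <- function(W) { stopifnot(methods::is(W, "WeightMatrix")); W@data }

#' @rdname weightData
#' @export
matrixLayout <- function(W) { stopifnot(methods::is(W, "WeightMatrix")); W@layout }

#' @rdname weightData
#' @export
weightDtype <- function(W) { stopifnot(methods::is(W, "WeightMatrix")); W@dtype }

#' @rdname weightData
#' @export
srcSize <- function(W) { stopifnot(methods::is(W, "WeightMatrix")); W@srcSize }

#' @rdname weightData
#' @export
dstSize <- function(W) { stopifnot(methods::is(W, "WeightMatrix")); W@dstSize }

#' @rdname weightData
#' @param d,s destination and source neuron indices (1-based).
#' @export
weightEntry <- function(W, d, s) {
  stopifnot(methods::is(W, "WeightMatrix"))
  if (W@layout == "dst_major") W@data[d, s] else W@data[s, d]
}

setMethod("show", "WeightMatrix", function(object) {
  cat(sprintf("WeightMatrix S=%d -> D=%d, layout=%s, dtype=%s (%d entries)\n",
              object@srcSize, object@dstSize, object@layout, object@dtype,
              length(object@data)))
})

#' Flip the storage orientation of a weight matrix
#'
#' Physically transposes the storage into the opposite layout and flips the
#' layout tag. The semantic weights W\[d, s\] are unchanged, so every kernel
#' returns identical (f64) results on the transposed matrix.
#'
#' @param W a [WeightMatrix].
#' @return a [WeightMatrix] with the opposite layout.
#' @examples
#' W <- weightMatrix(matrix(1:6, 3, 2), layout = "dst_major")
#' matrixLayout(transposeLayout(W))
#' @export
transposeLayout <- function(W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  bk <- getBackend()
  newLayout <- if (W@layout == "dst_major") "src_major" else "dst_major"
  new("WeightMatrix", data = bk$transpose(W@data), layout = newLayout,
      dtype = W@dtype, srcSize = W@srcSize, dstSize = W@dstSize)
}

#' Build an index mesh from pre- and post-synaptic spike vectors
#'
#' Returns the rectangular mesh addressing exactly the physical entries
#' (destination row x source column for `dst_major`, source row x destination
#' column for `src_major`) of the weight pairs with a spike on both sides.
#' Because spike vectors are boolean, a (pre, post) pair can occur at most
#' once per mesh, so mesh increments never alias.
#'
#' @param pre source-side [SpikeVector].
#' @param post destination-side [SpikeVector].
#' @param layout layout of the matrix the mesh will address.
#' @return an [IndexMesh].
#' @examples
#' meshFromSpikes(spikeVector(c(TRUE, FALSE)), spikeVector(c(FALSE, TRUE)),
#'                layout = "dst_major")
#' @export
meshFromSpikes <- function(pre, post, layout = c("dst_major", "src_major")) {
  layout <- match.arg(layout)
  stopifnot(methods::is(pre, "SpikeVector"), methods::is(post, "SpikeVector"))
  if (layout == "dst_major")
    new("IndexMesh", rows = post@active, cols = pre@active)
  else
    new("IndexMesh", rows = pre@active, cols = post@active)
}

#' @rdname meshFromSpikes
#' @param mesh an [IndexMesh].
#' @export
meshSize <- function(mesh) {
  stopifnot(methods::is(mesh, "IndexMesh"))
  length(mesh@rows) * length(mesh@cols)
}

#' @rdname meshFromSpikes
#' @export
meshRows <- function(mesh) { stopifnot(methods::is(mesh, "IndexMesh")); mesh@rows }

#' @rdname meshFromSpikes
#' @export
meshCols <- function(mesh) { stopifnot(methods::is(mesh, "IndexMesh")); mesh@cols }

setMethod("show", "IndexMesh", function(object) {
  cat(sprintf("IndexMesh %d x %d (%d entries)\n", length(object@rows),
              length(object@cols), meshSize(object)))
})

#' Spike-history ring buffer
#'
#' @param depth number of steps L to retain.
#' @param size population size N.
#' @return an empty [SpikeHistory].
#' @examples
#' h <- spikeHistory(depth = 3, size = 5)
#' h <- pushSpikes(h, spikeVector(rep(FALSE, 5)))
#' historyLength(h)
#' @export
spikeHistory <- function(depth, size) {
  new("SpikeHistory", depth = as.integer(depth), buffer = list(),
      size = as.integer(size))
}

#' @rdname spikeHistory
#' @param hist a [SpikeHistory].
#' @param sv the current step's [SpikeVector]; becomes slot 1.
#' @export
pushSpikes <- function(hist, sv) {
  stopifnot(methods::is(hist, "SpikeHistory"), methods::is(sv, "SpikeVector"),
            length(sv@values) == hist@size)
  buf <- c(list(sv), hist@buffer)
  if (length(buf) > hist@depth) buf <- buf[seq_len(hist@depth)]
  methods::initialize(hist, buffer = buf)
}

#' @rdname spikeHistory
#' @param lag steps back in time; 0 is the current step.
#' @export
spikesAtLag <- function(hist, lag) {
  stopifnot(methods::is(hist, "SpikeHistory"))
  idx <- lag + 1L
  if (idx < 1L || idx > length(hist@buffer))
    stop("insufficient spike history for lag ", lag, call. = FALSE)
  hist@buffer[[idx]]
}

#' @rdname spikeHistory
#' @export
historyLength <- function(hist) {
  stopifnot(methods::is(hist, "SpikeHistory"))
  length(hist@buffer)
}
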