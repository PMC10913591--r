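#' @import methods
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' Binary spike vector with cached active-index list
#'
#' Per-neuron boolean firing state for one simulation step. The sorted
#' positions of the active (spiking) neurons are cached at construction, so
#' indexed kernels never rescan the boolean vector.
#'
#' @slot values logical vector of length N, `TRUE` where the neuron fired.
#' @slot active integer vector, the ascending positions of the `TRUE` entries.
#' @examples
#' sv <- spikeVector(c(TRUE, FALSE, TRUE))
#' activeIndices(sv)
#' @name SpikeVector-class
#' @aliases SpikeVector
#' @exportClass SpikeVector
setClass("SpikeVector",
  representation(values = "logical", active = "integer"),
  validity = function(object) {
    if (anyNA(object@values)) return("spike values must not contain NA")
    if (!identical(object@active, which(object@values)))
      return("cached active indices do not match the boolean values")
    TRUE
  })

#' Dense synaptic weight matrix with layout and precision tags
#'
#' A dense 2-D weight array connecting a source population of size S to a
#' destination population of size D. The semantic entry W\[d, s\] is the
#' weight from source neuron s to destination neuron d; the `layout` tag
#' records whether storage is destination-major (D x S) or source-major
#' (S x D). The `dtype` tag records the storage precision grid (f64, f32 or
#' f16): values are kept on that grid while arithmetic runs in double.
#'
#' @slot data numeric matrix; shape (D, S) for `dst_major`, (S, D) for
#'   `src_major`.
#' @slot layout `"dst_major"` or `"src_major"`.
#' @slot dtype `"f64"`, `"f32"` or `"f16"`.
#' @slot srcSize,dstSize integer population sizes S and D.
#' @examples
#' W <- weightMatrix(matrix(1:6, 3, 2), layout = "dst_major")
#' dstSize(W)
#' @name WeightMatrix-class
#' @aliases WeightMatrix
#' @exportClass WeightMatrix
setClass("WeightMatrix",
  representation(data = "matrix", layout = "character", dtype = "character",
                 srcSize = "integer", dstSize = "integer"),
  validity = function(object) {
    if (!object@layout %in% c("dst_major", "src_major"))
      return("layout must be 'dst_major' or 'src_major'")
    if (!object@dtype %in% c("f64", "f32", "f16"))
      return("dtype must be one of 'f64', 'f32', 'f16'")
    want <- if (object@layout == "dst_major")
      c(object@dstSize, object@srcSize) else c(object@srcSize, object@dstSize)
    if (!identical(dim(object@data), as.integer(want)))
      return(sprintf("data shape (%d, %d) inconsistent with layout '%s' and sizes S=%d, D=%d",
                     nrow(object@data), ncol(object@data), object@layout,
                     object@srcSize, object@dstSize))
    TRUE
  })

#' Rectangular index mesh addressing a weight submatrix
#'
#' The cross product of an ascending row-index list and an ascending
#' column-index list, addressing exactly the `|rows| * |cols|` entries of a
#' matrix that a sparse update touches.
#'
#' @slot rows,cols ascending integer indices (1-based) into the physical
#'   storage of the matrix the mesh was built for.
#' @examples
#' m <- meshFromSpikes(spikeVector(c(TRUE, FALSE)),
#'                     spikeVector(c(FALSE, TRUE)), layout = "dst_major")
#' meshSize(m)
#' @name IndexMesh-class
#' @aliases IndexMesh
#' @exportClass IndexMesh
setClass("IndexMesh",
  representation(rows = "integer", cols = "integer"),
  validity = function(object) {
    if (is.unsorted(object@rows, strictly = TRUE) && length(object@rows) > 1)
      return("mesh rows must be strictly ascending")
    if (is.unsorted(object@cols, strictly = TRUE) && length(object@cols) > 1)
      return("mesh cols must be strictly ascending")
    if (length(object@rows) && min(object@rows) < 1L)
      return("mesh rows must be positive")
    if (length(object@cols) && min(object@cols) < 1L)
      return("mesh cols must be positive")
    TRUE
  })

#' Row-compressed sparse weights (source-major)
#'
#' Sparse fallback storage for very low connection densities. Orientation is
#' fixed to source-major row compression so gathering the rows of the active
#' source neurons walks contiguous storage, mirroring the dense layout
#' optimization.
#'
#' @slot mat a `Matrix::dgRMatrix` of shape (S, D).
#' @slot srcSize,dstSize integer population sizes.
#' @name SparseWeights-class
#' @aliases SparseWeights
#' @exportClass SparseWeights
setClass("SparseWeights",
  representation(mat = "ANY", srcSize = "integer", dstSize = "integer"),
  validity = function(object) {
    if (!methods::is(object@mat, "RsparseMatrix"))
      return("sparse storage must be a row-compressed (RsparseMatrix) matrix")
    if (!identical(dim(object@mat), c(object@srcSize, object@dstSize)))
      return("sparse matrix shape must be (srcSize, dstSize)")
    TRUE
  })

#' Ring buffer of recent spike vectors
#'
#' Keeps the last `depth` spike vectors of one population; slot 1 is the
#' current step, slot 2 one step back, and so on. Used to bundle spikes from
#' multiple time steps for multi-lag plasticity.
#'
#' @slot depth maximum number of retained steps L.
#' @slot buffer list of [SpikeVector] objects, most recent first.
#' @slot size population size N.
#' @name SpikeHistory-class
#' @aliases SpikeHistory
#' @exportClass SpikeHistory
setClass("SpikeHistory",
  representation(depth = "integer", buffer = "list", size = "integer"),
  validity = function(object) {
    if (object@depth < 1L) return("depth must be >= 1")
    if (length(object@buffer) > object@depth)
      return("buffer longer than depth")
    for (sv in object@buffer) {
      if (!methods::is(sv, "SpikeVector")) return("buffer entries must be SpikeVector")
      if (length(sv@values) != object@size) return("buffer entry of wrong size")
    }
    TRUE
  })

#' Globally ordered behavior schedule
#'
#' The flat execution order of one simulation step: every behavior attached
#' anywhere in the network, sorted by its integer priority key, ties broken
#' by component registration order.
#'
#' @slot keys numeric priority keys in non-decreasing order.
#' @slot componentNames character, owning component of each entry.
#' @slot behaviorNames character, name of each behavior.
#' @slot entries list of `(component, behavior)` pairs in execution order.
#' @name BehaviorSchedule-class
#' @aliases BehaviorSchedule
#' @exportClass BehaviorSchedule
setClass("BehaviorSchedule",
  representation(keys = "numeric", componentNames = "character",
                 behaviorNames = "character", entries = "list"),
  validity = function(object) {
    n <- length(object@keys)
    if (length(object@entries) != n || length(object@componentNames) != n ||
        length(object@behaviorNames) != n)
      return("schedule slots have inconsistent lengths")
    if (is.unsorted(object@keys)) return("schedule keys must be non-decreasing")
    TRUE
  })

#' Micro-benchmark timing record
#'
#' Raw per-repetition durations of one operation under test, after a number
#' of untimed warmup executions, together with summary statistics.
#'
#' @slot label description of the timed operation.
#' @slot repetitions,warmup counts of timed and untimed runs.
#' @slot durations numeric vector of per-repetition wall times in seconds.
#' @name TimingRecord-class
#' @aliases TimingRecord
#' @exportClass TimingRecord
setClass("TimingRecord",
  representation(label = "character", repetitions = "integer",
                 warmup = "integer", durations = "numeric"),
  validity = function(object) {
    if (length(object@durations) != object@repetitions)
      return("durations length must equal repetitions")
    if (any(object@durations < 0)) return("durations must be nonnegative")
    TRUE
  })
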