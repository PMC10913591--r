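# Weight storage inside a synapse group's state.
#
# The reference-model behaviors keep the weight matrix as a raw matrix
# (`Wdata`) with its layout/dtype tags (`Wlayout`, `Wdtype`) directly in the
# synapse group's state environment and update it with subassignments into
# that environment. R updates an environment-bound matrix in place when it
# is unshared, so a mesh STDP step touches only the addressed entries
# instead of copying the full matrix -- the memory-access pattern the
# indexed kernels exist for. The arithmetic is identical to the
# value-semantic kernels ([stdpMesh()], [clipMesh()], ...), which remain
# the specification and the oracles in the tests.

#' Access the weights of a synapse group
#'
#' `synapseWeights` wraps the state-held weight storage of a reference
#' model's synapse group as a [WeightMatrix]; `setSynapseWeights` replaces
#' the storage. Note that holding on to the returned object shares the
#' underlying matrix, so the next in-place model update will transparently
#' copy once (R's copy-on-write); the returned snapshot stays unchanged.
#'
#' @param sg a `SynapseGroup` whose state holds `Wdata`/`Wlayout`/`Wdtype`.
#' @return a [WeightMatrix].
#' @export
synapseWeights <- function(sg) {
  st <- sg$state
  if (is.null(st$Wdata))
    stop("synapse group '", sg$uniqueName, "' has no weight storage",
         call. = FALSE)
  sizes <- .stateSizes(st)
  methods::new("WeightMatrix", data = st$Wdata, layout = st$Wlayout,
               dtype = st$Wdtype, srcSize = sizes[1], dstSize = sizes[2])
}

#' @rdname synapseWeights
#' @param W a [WeightMatrix] to install.
#' @export
setSynapseWeights <- function(sg, W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  sg$state$Wdata <- weightData(W)
  sg$state$Wlayout <- matrixLayout(W)
  sg$state$Wdtype <- weightDtype(W)
  invisible(sg)
}

.stateSizes <- function(st) {
  d <- dim(st$Wdata)
  if (st$Wlayout == "src_major") c(d[1], d[2]) else c(d[2], d[1])
}

# Indexed or product transmission straight off the state-held storage
# (read-only, no copy). Same accumulation contract as the kernel layer.
.stateSynapticInput <- function(st, srcSpikes, impl, bk) {
  if (impl == "indexed") {
    active <- which(srcSpikes)
    if (st$Wlayout == "src_major") bk$rowAccum(st$Wdata, active)
    else bk$colAccum(st$Wdata, active)
  } else {
    v <- as.numeric(srcSpikes)
    if (st$Wlayout == "src_major") bk$weightedRowAccum(st$Wdata, v)
    else bk$weightedColAccum(st$Wdata, v)
  }
}

# Subassign a block of the state-held weight matrix without copying it.
# A plain `st$Wdata[rows, cols] <- value` inside a function forces R to
# copy the whole matrix (the fetched binding is referenced twice during the
# replacement call); evaluating the replacement expression inside the state
# environment itself updates the unshared matrix in place, exactly like a
# top-level assignment. If the matrix is genuinely shared (someone holds a
# snapshot), R still copies once, preserving value semantics.
.envSubassign <- function(st, rows, cols, value) {
  st$.block <- value
  if (is.null(rows)) {
    eval(substitute(Wdata[, c] <- .block, list(c = cols)), st)
  } else if (is.null(cols)) {
    eval(substitute(Wdata[r, ] <- .block, list(r = rows)), st)
  } else {
    eval(substitute(Wdata[r, c] <- .block, list(r = rows, c = cols)), st)
  }
  rm(".block", envir = st)
  invisible(NULL)
}

# In-place mesh increment + masked clip on the state-held storage:
# add, snap to the dtype grid, clamp -- the same value sequence as
# stdpMesh followed by clipMesh.
.stateMeshAddClip <- function(st, preIdx, postIdx, inc, wMin, wMax) {
  if (!length(preIdx) || !length(postIdx)) return(invisible(NULL))
  if (st$Wlayout == "src_major") { rows <- preIdx; cols <- postIdx }
  else { rows <- postIdx; cols <- preIdx }
  block <- st$Wdata[rows, cols, drop = FALSE] + inc
  block <- quantizeToDtype(block, st$Wdtype)
  .envSubassign(st, rows, cols, pmin(pmax(block, wMin), wMax))
}
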