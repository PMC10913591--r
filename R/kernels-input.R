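#' Synaptic transmission kernels
#'
#' Both kernels compute the per-destination-neuron input
#' `out[d] = sum_s W[d, s] * src[s]` for a boolean source spike vector.
#'
#' `synapticInputProduct` is the naive oracle: a full matrix-vector product
#' that multiplies every weight by the (0/1) spike value, touching all S x D
#' entries. `synapticInputIndexed` exploits the binary spikes: it gathers
#' only the rows (source-major) or columns (destination-major) of the active
#' source neurons and sums them, skipping all multiplications. Under the
#' backend's ascending-order double-accumulation contract the two are
#' bitwise identical in f64, because the skipped terms are exact zeros.
#'
#' @param W a [WeightMatrix].
#' @param src source-side [SpikeVector] of length `srcSize(W)`.
#' @return numeric vector of length `dstSize(W)`.
#' @examples
#' W <- weightMatrix(matrix(c(1, 3, 5, 2, 4, 6), 3, 2), layout = "dst_major")
#' src <- spikeVector(c(TRUE, FALSE))
#' synapticInputProduct(W, src)
#' synapticInputIndexed(W, src)
#' @export
synapticInputProduct <- function(W, src) {
  checkSrc(W, src)
  bk <- getBackend()
  v <- as.numeric(src@values)
  if (W@layout == "src_major") bk$weightedRowAccum(W@data, v)
  else bk$weightedColAccum(W@data, v)
}

#' @rdname synapticInputProduct
#' @export
synapticInputIndexed <- function(W, src) {
  checkSrc(W, src)
  bk <- getBackend()
  if (W@layout == "src_major") bk$rowAccum(W@data, src@active)
  else bk$colAccum(W@data, src@active)
}

checkSrc <- function(W, src) {
  stopifnot(methods::is(W, "WeightMatrix"), methods::is(src, "SpikeVector"))
  if (length(src@values) != W@srcSize)
    stop("spike vector length ", length(src@values),
         " does not match srcSize ", W@srcSize, call. = FALSE)
  invisible(TRUE)
}

#' Sparse weight storage and transmission
#'
#' `sparseWeights` compresses a dense [WeightMatrix] into row-compressed
#' source-major sparse storage (only nonzero entries kept).
#' `randomSparseWeights` draws a random sparse matrix at a target density.
#' `sparseSynapticInput` gathers the stored rows of the active source
#' neurons and accumulates them, matching `synapticInputIndexed` on the
#' densified matrix bitwise in f64. `densify` reconstructs the dense matrix.
#'
#' @param W a [WeightMatrix] to compress.
#' @return `sparseWeights`/`randomSparseWeights` a [SparseWeights];
#'   `sparseSynapticInput` a numeric vector of length D; `densify` a
#'   [WeightMatrix] (src_major, f64); `sparseDensity` the stored-entry
#'   fraction.
#' @examples
#' W <- weightMatrix(diag(3), layout = "src_major")
#' Wsp <- sparseWeights(W)
#' sparseSynapticInput(Wsp, spikeVector(c(TRUE, FALSE, FALSE)))
#' @export
sparseWeights <- function(W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  dense <- if (W@layout == "src_major") W@data else getBackend()$transpose(W@data)
  m <- methods::as(methods::as(Matrix::Matrix(dense, sparse = TRUE),
                               "generalMatrix"), "RsparseMatrix")
  new("SparseWeights", mat = m, srcSize = W@srcSize, dstSize = W@dstSize)
}

#' @rdname sparseWeights
#' @param srcSize,dstSize population sizes S and D.
#' @param density fraction of entries that are nonzero.
#' @export
randomSparseWeights <- function(srcSize, dstSize, density) {
  stopifnot(density >= 0, density <= 1)
  dense <- matrix(0, srcSize, dstSize)
  n <- length(dense)
  keep <- which(stats::runif(n) < density)
  dense[keep] <- stats::runif(length(keep))
  sparseWeights(weightMatrix(dense, layout = "src_major"))
}

#' @rdname sparseWeights
#' @param Wsp a [SparseWeights].
#' @param src source-side [SpikeVector].
#' @export
sparseSynapticInput <- function(Wsp, src) {
  stopifnot(methods::is(Wsp, "SparseWeights"), methods::is(src, "SpikeVector"))
  if (length(src@values) != Wsp@srcSize)
    stop("spike vector length does not match srcSize", call. = FALSE)
  m <- Wsp@mat
  out <- numeric(Wsp@dstSize)
  p <- m@p; j <- m@j; x <- m@x
  for (r in src@active) {               # ascending source rows
    span <- seq.int(p[r] + 1L, length.out = p[r + 1L] - p[r])
    if (length(span)) {
      cols <- j[span] + 1L
      out[cols] <- out[cols] + x[span]  # distinct columns within one row
    }
  }
  out
}

#' @rdname sparseWeights
#' @export
densify <- function(Wsp) {
  stopifnot(methods::is(Wsp, "SparseWeights"))
  weightMatrix(as.matrix(Wsp@mat), layout = "src_major")
}

#' @rdname sparseWeights
#' @export
sparseDensity <- function(Wsp) {
  stopifnot(methods::is(Wsp, "SparseWeights"))
  length(Wsp@mat@x) / (as.numeric(Wsp@srcSize) * Wsp@dstSize)
}

setMethod("show", "SparseWeights", function(object) {
  cat(sprintf("SparseWeights S=%d -> D=%d, density %.4f%%\n", object@srcSize,
              object@dstSize, 100 * sparseDensity(object)))
})
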