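#' Neuron-wise synaptic weight normalization
#'
#' `normalizeAfferent` rescales every destination neuron's incoming weights
#' so that their sum equals `target` (default 1); `normalizeEfferent` does
#' the same for every source neuron's outgoing weights. Neurons whose weight
#' sum is exactly zero are left untouched -- dividing by zero would destroy
#' the row. Sums are accumulated through the backend facade in ascending
#' index order, so the result is identical across storage layouts.
#'
#' Keeping the total afferent weight constant is a standard stabilizer for
#' Hebbian rules; running it only every k-th iteration (see
#' [intervalNormalization()]) amortizes its dense cost.
#'
#' @param W a [WeightMatrix].
#' @param target the per-neuron weight sum after normalization.
#' @return the updated [WeightMatrix].
#' @examples
#' W <- weightMatrix(matrix(c(1, 3), 1, 2), layout = "dst_major")
#' weightData(normalizeAfferent(W))  # 0.25 0.75
#' @export
normalizeAfferent <- function(W, target = 1) {
  stopifnot(methods::is(W, "WeightMatrix"))
  bk <- getBackend()
  if (W@layout == "dst_major") {
    sums <- bk$weightedColAccum(W@data, rep(1, ncol(W@data)))  # per-dst row sums
    f <- ifelse(sums == 0, 1, target / sums)
    data <- bk$scaleRows(W@data, f)
  } else {
    sums <- bk$weightedRowAccum(W@data, rep(1, nrow(W@data)))  # per-dst col sums
    f <- ifelse(sums == 0, 1, target / sums)
    data <- bk$scaleCols(W@data, f)
  }
  methods::initialize(W, data = quantizeToDtype(data, W@dtype))
}

#' @rdname normalizeAfferent
#' @export
normalizeEfferent <- function(W, target = 1) {
  stopifnot(methods::is(W, "WeightMatrix"))
  bk <- getBackend()
  if (W@layout == "src_major") {
    sums <- bk$weightedColAccum(W@data, rep(1, ncol(W@data)))  # per-src row sums
    f <- ifelse(sums == 0, 1, target / sums)
    data <- bk$scaleRows(W@data, f)
  } else {
    sums <- bk$weightedRowAccum(W@data, rep(1, nrow(W@data)))  # per-src col sums
    f <- ifelse(sums == 0, 1, target / sums)
    data <- bk$scaleCols(W@data, f)
  }
  methods::initialize(W, data = quantizeToDtype(data, W@dtype))
}

#' Per-neuron weight sums
#'
#' @param W a [WeightMatrix].
#' @return `afferentSums` the incoming-weight sum of every destination
#'   neuron (length D); `efferentSums` the outgoing-weight sum of every
#'   source neuron (length S).
#' @export
afferentSums <- function(W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  bk <- getBackend()
  if (W@layout == "dst_major") bk$weightedColAccum(W@data, rep(1, ncol(W@data)))
  else bk$weightedRowAccum(W@data, rep(1, nrow(W@data)))
}

#' @rdname afferentSums
#' @export
efferentSums <- function(W) {
  stopifnot(methods::is(W, "WeightMatrix"))
  bk <- getBackend()
  if (W@layout == "src_major") bk$weightedColAccum(W@data, rep(1, ncol(W@data)))
  else bk$weightedRowAccum(W@data, rep(1, nrow(W@data)))
}
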