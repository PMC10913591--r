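#' Spike-timing-dependent plasticity update kernels
#'
#' Both kernels add `lr` to every weight W\[d, s\] whose destination neuron d
#' and source neuron s both spiked, leaving all other entries untouched.
#'
#' `stdpOuter` is the naive oracle: it forms the full D x S outer product of
#' the boolean spike vectors and adds `lr` times that matrix, performing one
#' scalar multiplication per synapse (S x D of them) even though almost all
#' factors are zero. `stdpMesh` instead increments only the entries
#' addressed by an [IndexMesh] built from the active indices. The two leave
#' bitwise-identical matrices in every dtype: both add exactly `lr` to the
#' mesh entries and exactly zero elsewhere.
#'
#' @param W a [WeightMatrix].
#' @param pre source-side [SpikeVector] (length S).
#' @param post destination-side [SpikeVector] (length D).
#' @param lr weight increment per coinciding spike pair.
#' @return the updated [WeightMatrix] (value semantics: assign the result
#'   back).
#' @examples
#' W <- weightMatrix(matrix(0, 2, 2), layout = "dst_major")
#' pre <- spikeVector(c(TRUE, FALSE)); post <- spikeVector(c(FALSE, TRUE))
#' weightData(stdpOuter(W, pre, post, lr = 1))
#' @export
stdpOuter <- function(W, pre, post, lr) {
  stopifnot(methods::is(W, "WeightMatrix"),
            methods::is(pre, "SpikeVector"), methods::is(post, "SpikeVector"))
  if (length(pre@values) != W@srcSize || length(post@values) != W@dstSize)
    stop("spike vector sizes do not match the weight matrix", call. = FALSE)
  p <- as.numeric(pre@values); q <- as.numeric(post@values)
  upd <- if (W@layout == "dst_major") outer(q, p) else outer(p, q)
  data <- W@data + lr * upd
  methods::initialize(W, data = quantizeToDtype(data, W@dtype))
}

#' @rdname stdpOuter
#' @param mesh an [IndexMesh] addressing the entries to increment, built for
#'   this matrix's layout (see [meshFromSpikes()]).
#' @export
stdpMesh <- function(W, mesh, lr) {
  stopifnot(methods::is(W, "WeightMatrix"), methods::is(mesh, "IndexMesh"))
  checkMeshBounds(W, mesh)
  if (meshSize(mesh) == 0L) return(W)
  bk <- getBackend()
  data <- bk$meshAdd(W@data, mesh@rows, mesh@cols, lr)
  if (W@dtype != "f64")
    data[mesh@rows, mesh@cols] <- quantizeToDtype(data[mesh@rows, mesh@cols],
                                                  W@dtype)
  methods::initialize(W, data = data)
}

checkMeshBounds <- function(W, mesh) {
  nr <- nrow(W@data); nc <- ncol(W@data)
  if (length(mesh@rows) && max(mesh@rows) > nr)
    stop("mesh row index out of range", call. = FALSE)
  if (length(mesh@cols) && max(mesh@cols) > nc)
    stop("mesh column index out of range", call. = FALSE)
  invisible(TRUE)
}

#' Instrumented multiplication count of the naive plasticity update
#'
#' Walks the index space of the naive outer-product update and counts one
#' scalar multiplication per (destination, source) pair, i.e. per synapse.
#' For small matrices the count is accumulated pair by pair; above
#' `enumerateLimit` entries the loop is replaced by its closed form D x S
#' (the loop body adds exactly 1 per pair).
#'
#' @param W a [WeightMatrix].
#' @param enumerateLimit entry count up to which the count is accumulated by
#'   explicit enumeration.
#' @return the number of scalar multiplications `stdpOuter` performs on `W`.
#' @examples
#' naiveStdpMultiplications(weightMatrix(matrix(0, 20, 30)))  # 600
#' @export
naiveStdpMultiplications <- function(W, enumerateLimit = 1e6) {
  stopifnot(methods::is(W, "WeightMatrix"))
  D <- as.numeric(W@dstSize); S <- as.numeric(W@srcSize)
  if (D * S <= enumerateLimit) {
    count <- 0
    for (d in seq_len(D)) for (s in seq_len(S)) count <- count + 1
    count
  } else {
    D * S
  }
}

#' Clip weights into a bounded range
#'
#' `clipMesh` clamps only the mesh-addressed entries into
#' `[wMin, wMax]`, the masked form used after a mesh STDP update: entries
#' outside the mesh are left untouched even if they lie outside the bounds.
#' `clipWeights` clamps the full matrix (the naive form).
#'
#' @param W a [WeightMatrix].
#' @param mesh an [IndexMesh].
#' @param wMin,wMax clip bounds, `wMin <= wMax`.
#' @return the updated [WeightMatrix].
#' @examples
#' W <- weightMatrix(matrix(2, 2, 2))
#' m <- meshFromSpikes(spikeVector(c(TRUE, FALSE)), spikeVector(c(TRUE, FALSE)))
#' weightData(clipMesh(W, m, 0, 1))
#' @export
clipMesh <- function(W, mesh, wMin, wMax) {
  stopifnot(methods::is(W, "WeightMatrix"), methods::is(mesh, "IndexMesh"))
  if (wMin > wMax) stop("wMin must not exceed wMax", call. = FALSE)
  checkMeshBounds(W, mesh)
  if (meshSize(mesh) == 0L) return(W)
  bk <- getBackend()
  methods::initialize(W, data = bk$meshClip(W@data, mesh@rows, mesh@cols,
                                            wMin, wMax))
}

#' @rdname clipMesh
#' @export
clipWeights <- function(W, wMin, wMax) {
  stopifnot(methods::is(W, "WeightMatrix"))
  if (wMin > wMax) stop("wMin must not exceed wMax", call. = FALSE)
  methods::initialize(W, data = getBackend()$clipAll(W@data, wMin, wMax))
}

#' Multi-lag STDP over bundled spike histories
#'
#' Extends the one-step rule to a discrete plasticity window: for each lag
#' `l` with amplitude `a_l`, the mesh update with increment `a_l` is applied
#' to the pair (pre spikes `l` steps back, current post spikes) for positive
#' lags -- pre-before-post, potentiation -- and (current pre spikes, post
#' spikes `|l|` steps back) for negative lags -- post-before-pre,
#' depression. Lag 0 pairs the current vectors. Applying the lags
#' sequentially with `stdpOuter` yields a bitwise-identical matrix.
#'
#' @param W a [WeightMatrix].
#' @param preHist,postHist [SpikeHistory] buffers of the source and
#'   destination populations; slot 1 is the current step.
#' @param amplitudes named numeric vector of per-lag signed increments; the
#'   names are the integer lags.
#' @return the updated [WeightMatrix].
#' @examples
#' amps <- defaultMultiLagAmplitudes(lr = 0.1)
#' names(amps)
#' @export
stdpMultiLag <- function(W, preHist, postHist, amplitudes) {
  stopifnot(methods::is(W, "WeightMatrix"),
            methods::is(preHist, "SpikeHistory"),
            methods::is(postHist, "SpikeHistory"))
  lags <- as.integer(names(amplitudes))
  if (anyNA(lags)) stop("amplitudes must be named by integer lags", call. = FALSE)
  need <- max(abs(lags)) + 1L
  if (historyLength(preHist) < need || historyLength(postHist) < need)
    stop("insufficient spike history: need ", need, " steps", call. = FALSE)
  for (i in seq_along(lags)) {
    a <- amplitudes[[i]]
    if (a == 0) next
    l <- lags[i]
    pre  <- spikesAtLag(preHist,  if (l > 0L) l else 0L)
    post <- spikesAtLag(postHist, if (l < 0L) -l else 0L)
    mesh <- meshFromSpikes(pre, post, W@layout)
    W <- stdpMesh(W, mesh, a)
  }
  W
}

#' Default discrete plasticity-window amplitudes
#'
#' A symmetric discrete exponential window over `lags`:
#' `a(l) = sign * A * exp(-|l| / tauLag)` with potentiation (positive sign)
#' for pre-before-post (`l >= 0`) and depression for post-before-pre
#' (`l < 0`). The nine default lags -4..4 give a nine-step window.
#'
#' @param lr amplitude scale A.
#' @param tauLag decay constant of the window, in lags.
#' @param lags integer lags to cover.
#' @return named numeric vector suitable for [stdpMultiLag()].
#' @export
defaultMultiLagAmplitudes <- function(lr, tauLag = 3, lags = -4:4) {
  a <- ifelse(lags >= 0, lr, -lr) * exp(-abs(lags) / tauLag)
  names(a) <- as.character(lags)
  a
}
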