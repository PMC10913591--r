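#' Noise input behaviors
#'
#' Write the per-step external drive into the group's `input` state
#' variable (overwriting last step's value). `noiseInputUniform` draws
#' i.i.d. uniform values on `[0, high]`; `noiseInputNormal` draws normal
#' values. Draws come from the owning group's random stream.
#'
#' @param high upper bound of the uniform drive.
#' @return a `Behavior`.
#' @export
noiseInputUniform <- function(high) {
  behavior(
    setup = function(g, self) g$state$input <- neuronVector(g, "zeros"),
    step = function(g, self) {
      bk <- getBackend(g$net$backendName)
      g$state$input <- drawFrom(g$rng, function() bk$runif(g$size, 0, high))
    },
    params = list(high = high), name = "uniform_noise_input")
}

#' @rdname noiseInputUniform
#' @param mean,sd moments of the normal drive.
#' @export
noiseInputNormal <- function(mean, sd) {
  behavior(
    setup = function(g, self) g$state$input <- neuronVector(g, "zeros"),
    step = function(g, self) {
      bk <- getBackend(g$net$backendName)
      g$state$input <- drawFrom(g$rng, function() bk$rnorm(g$size, mean, sd))
    },
    params = list(mean = mean, sd = sd), name = "normal_noise_input")
}

#' Leaky integrate-and-fire neuron behavior
#'
#' Per step: rotate the spike buffers (`spikesOld <- spikes`), then
#' `v <- v + leak * (vRest - v) + I_syn + input`, emit spikes where
#' `v >= vThreshold` (inclusive), reset those to `vReset`, and clear the
#' synaptic input accumulator for the next step. Setup creates `v` at
#' `vRest` and all-false spike buffers, so at the first iteration
#' `spikesOld` is all false (no pre-simulation history).
#'
#' @param params a [lifParams()] list.
#' @return a `Behavior`.
#' @export
lifNeuron <- function(params = lifParams()) {
  behavior(
    setup = function(g, self) {
      g$state$v <- neuronVector(g, "value", value = params$vRest)
      g$state$spikes <- rep(FALSE, g$size)
      g$state$spikesOld <- rep(FALSE, g$size)
      g$state$I_syn <- neuronVector(g, "zeros")
      if (is.null(g$state$input)) g$state$input <- neuronVector(g, "zeros")
    },
    step = function(g, self) {
      st <- g$state
      st$spikesOld <- st$spikes
      v <- st$v + params$leak * (params$vRest - st$v) + st$I_syn + st$input
      spk <- v >= params$vThreshold
      v[spk] <- params$vReset
      st$v <- v
      st$spikes <- spk
      st$I_syn <- numeric(g$size)
    },
    params = params, name = "lif_neuron")
}

#' Izhikevich neuron behavior
#'
#' One Euler step (dt = 1 model-time unit) of the quadratic two-variable
#' model; see [izhikevichParams()]. Setup places every neuron at the
#' resting equilibrium `v = -70, u = b * v` of the default parameters.
#'
#' @param params an [izhikevichParams()] list.
#' @param vInit initial membrane potential.
#' @return a `Behavior`.
#' @export
izhikevichNeuron <- function(params = izhikevichParams(), vInit = -70) {
  behavior(
    setup = function(g, self) {
      g$state$v <- neuronVector(g, "value", value = vInit)
      g$state$u <- params$b * g$state$v
      g$state$spikes <- rep(FALSE, g$size)
      g$state$spikesOld <- rep(FALSE, g$size)
      g$state$I_syn <- neuronVector(g, "zeros")
      if (is.null(g$state$input)) g$state$input <- neuronVector(g, "zeros")
    },
    step = function(g, self) {
      st <- g$state
      st$spikesOld <- st$spikes
      v <- st$v; u <- st$u
      I <- st$I_syn + st$input
      v1 <- v + 0.04 * v * v + 5 * v + 140 - u + I
      u1 <- u + params$a * (params$b * v - u)
      spk <- v1 >= params$spikeCutoff
      v1[spk] <- params$c
      u1[spk] <- u1[spk] + params$d
      st$v <- v1
      st$u <- u1
      st$spikes <- spk
      st$I_syn <- numeric(g$size)
    },
    params = params, name = "izhikevich_neuron")
}

#' Dense recurrent weight initialization behavior
#'
#' Creates the synapse group's state-held weight storage: uniform weights
#' on `[0, maxWeight]`, drawn from the synapse group's random stream in a
#' canonical source-major order before any transpose, so the semantic
#' weights depend only on the seed, never on the storage layout.
#'
#' @param layout storage orientation.
#' @param maxWeight upper bound of the initial uniform weights.
#' @return a `Behavior`.
#' @export
weightInit <- function(layout = c("src_major", "dst_major"), maxWeight = 1) {
  layout <- match.arg(layout)
  behavior(
    setup = function(sg, self) {
      bk <- getBackend(sg$net$backendName)
      S <- sg$src$size; D <- sg$dst$size
      vals <- drawFrom(sg$rng,
                       function() bk$runif(as.numeric(S) * D, 0, maxWeight))
      m <- matrix(vals, S, D)                      # canonical src-major
      if (layout == "dst_major") m <- bk$transpose(m)
      st <- sg$state
      st$Wdata <- quantizeToDtype(m, sg$net$dtype)
      st$Wlayout <- layout
      st$Wdtype <- sg$net$dtype
    },
    params = list(layout = layout, maxWeight = maxWeight),
    name = "weight_init")
}

#' Dirac synaptic transmission behavior
#'
#' Delivers the full weight of every synapse whose source neuron spiked
#' this step as an instantaneous pulse, accumulating into the destination
#' group's `I_syn` (contributions from multiple afferent synapse groups
#' sum). The source group's neuron behavior must run under a smaller key so
#' the current step's spikes are available. `impl` selects the optimized
#' indexed-summation kernel or the naive matrix-vector product; both
#' compute the same mathematics (bitwise, in f64).
#'
#' @param impl `"indexed"` or `"product"`.
#' @return a `Behavior`.
#' @export
diracSynapse <- function(impl = c("indexed", "product")) {
  impl <- match.arg(impl)
  behavior(
    step = function(sg, self) {
      bk <- getBackend(sg$net$backendName)
      inp <- .stateSynapticInput(sg$state, sg$src$state$spikes, impl, bk)
      sg$dst$state$I_syn <- sg$dst$state$I_syn + inp
    },
    params = list(impl = impl), name = paste0("dirac_synapse_", impl))
}

#' One-step STDP behavior with clipping
#'
#' Pairs the source group's previous-step spikes with the destination
#' group's current spikes: every such (pre, post) coincidence increments
#' W\[d, s\] by the learning rate, then the weights are clipped into
#' `[wMin, wMax]`. `impl = "mesh"` updates and clips only the index-mesh
#' entries, in place; `impl = "outer"` is the naive full outer-product
#' update followed by a full-matrix clip. Both leave identical weights.
#'
#' @param params a [plasticityParams()] list.
#' @param impl `"mesh"` or `"outer"`.
#' @return a `Behavior`.
#' @export
oneStepStdp <- function(params = plasticityParams(),
                        impl = c("mesh", "outer")) {
  impl <- match.arg(impl)
  behavior(
    step = function(sg, self) {
      st <- sg$state
      if (impl == "mesh") {
        .stateMeshAddClip(st, which(sg$src$state$spikesOld),
                          which(sg$dst$state$spikes),
                          params$learningRate, params$wMin, params$wMax)
      } else {
        W <- synapseWeights(sg)
        W <- stdpOuter(W, spikeVector(sg$src$state$spikesOld),
                       spikeVector(sg$dst$state$spikes),
                       params$learningRate)
        W <- clipWeights(W, params$wMin, params$wMax)
        st$Wdata <- weightData(W)
      }
    },
    params = c(params, list(impl = impl)),
    name = paste0("one_step_stdp_", impl))
}

#' Trace STDP behavior
#'
#' The standard trace rule: per-neuron eligibility traces decay by
#' `exp(-1/tau)` each step and gain +1 at spikes; every postsynaptic spike
#' potentiates its row of W by `aPlus` times the presynaptic traces, every
#' presynaptic spike depresses its column by `aMinus` times the
#' postsynaptic traces; touched entries are clipped into `[wMin, wMax]`.
#' The pairwise weight change for a single pre spike followed by a post
#' spike Delta steps later is `aPlus * exp(-Delta/tauPre)`, and
#' `-aMinus * exp(-Delta/tauPost)` for the reverse order. Updates write in
#' place into the state-held weight storage.
#'
#' @param params a [traceParams()] list.
#' @param clip a [plasticityParams()] list supplying `wMin`/`wMax`.
#' @return a `Behavior`.
#' @export
traceStdp <- function(params = traceParams(), clip = plasticityParams()) {
  decayPre <- exp(-1 / params$tauPre)
  decayPost <- exp(-1 / params$tauPost)
  behavior(
    setup = function(sg, self) {
      sg$state$xPre <- numeric(sg$src$size)
      sg$state$xPost <- numeric(sg$dst$size)
    },
    step = function(sg, self) {
      st <- sg$state
      pre <- sg$src$state$spikes
      post <- sg$dst$state$spikes
      xPre <- st$xPre * decayPre
      xPre[pre] <- xPre[pre] + 1
      xPost <- st$xPost * decayPost
      xPost[post] <- xPost[post] + 1
      st$xPre <- xPre
      st$xPost <- xPost
      dstMajor <- st$Wlayout == "dst_major"
      dt <- st$Wdtype
      postIdx <- which(post)
      if (length(postIdx)) {       # potentiation: dst rows gain aPlus * xPre
        if (dstMajor) {
          blk <- st$Wdata[postIdx, , drop = FALSE] +
            params$aPlus * rep(xPre, each = length(postIdx))
          .envSubassign(st, postIdx, NULL,
                        pmin(pmax(quantizeToDtype(blk, dt),
                                  clip$wMin), clip$wMax))
        } else {
          blk <- st$Wdata[, postIdx, drop = FALSE] + params$aPlus * xPre
          .envSubassign(st, NULL, postIdx,
                        pmin(pmax(quantizeToDtype(blk, dt),
                                  clip$wMin), clip$wMax))
        }
      }
      preIdx <- which(pre)
      if (length(preIdx)) {        # depression: src cols lose aMinus * xPost
        if (dstMajor) {
          blk <- st$Wdata[, preIdx, drop = FALSE] - params$aMinus * xPost
          .envSubassign(st, NULL, preIdx,
                        pmin(pmax(quantizeToDtype(blk, dt),
                                  clip$wMin), clip$wMax))
        } else {
          blk <- st$Wdata[preIdx, , drop = FALSE] -
            params$aMinus * rep(xPost, each = length(preIdx))
          .envSubassign(st, preIdx, NULL,
                        pmin(pmax(quantizeToDtype(blk, dt),
                                  clip$wMin), clip$wMax))
        }
      }
    },
    params = c(params, clip), name = "trace_stdp")
}

#' Interval weight-normalization behavior
#'
#' Runs [normalizeAfferent()] on the synapse group's weights whenever the
#' network iteration counter is a multiple of `normInterval`; a no-op on
#' all other iterations. With the counter convention used here (first step
#' sees iteration 1), 300 iterations at interval 100 normalize exactly 3
#' times, at iterations 100, 200 and 300.
#'
#' @param params a [plasticityParams()] list supplying `normInterval`.
#' @param target per-neuron afferent weight sum after normalization.
#' @return a `Behavior`.
#' @export
intervalNormalization <- function(params = plasticityParams(), target = 1) {
  behavior(
    step = function(sg, self) {
      if (sg$net$iteration %% params$normInterval == 0L) {
        setSynapseWeights(sg, normalizeAfferent(synapseWeights(sg),
                                                target = target))
        sg$state$normCount <- (sg$state$normCount %||% 0L) + 1L
      }
    },
    params = c(params, list(target = target)), name = "interval_normalization")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
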