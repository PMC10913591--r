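#' Build a reference network model
#'
#' Constructs one of the two reference models on a single N-neuron
#' population with a dense recurrent all-to-all synapse group (the diagonal
#' is kept):
#'
#' * `"lif_onestep"`: LIF neurons driven by uniform noise, Dirac synaptic
#'   transmission, one-step STDP with masked clipping.
#' * `"izhikevich_trace"`: Izhikevich neurons driven by normal noise, Dirac
#'   transmission, standard trace STDP.
#'
#' Behavior keys: 1 noise input, 2 neuron dynamics, 3 synaptic
#' transmission, 4 plasticity, 5 interval normalization (off by default),
#' recorders from 1000. `impl = "optimized"` uses indexed transmission, a
#' source-major weight layout and the in-place mesh STDP update;
#' `impl = "naive"` uses the full matrix-vector product, a
#' destination-major layout and the outer-product STDP update. With the
#' same seed and dtype `"f64"` the two produce bit-identical spike rasters.
#'
#' Size-invariant parameterization: initial weights are uniform on
#' `[0, weightScale / N]` and the per-coincidence plasticity increments
#' (`learningRate`, and `aPlus`/`aMinus` for the trace rule) are divided by
#' N as well. Both the total recurrent drive per neuron and its growth
#' under learning are then independent of the population size, so activity
#' stays noise-driven with comparable firing rates across sizes -- the
#' regime the models are specified in. Clip bounds are applied as given.
#'
#' @param kind `"lif_onestep"` or `"izhikevich_trace"`.
#' @param n population size N (>= 1).
#' @param seed master seed of the network.
#' @param impl `"optimized"` or `"naive"`.
#' @param dtype weight storage precision.
#' @param neuronParams a [lifParams()] or [izhikevichParams()] list; model
#'   defaults when `NULL`.
#' @param plasticity a [plasticityParams()] list (increment scaled by 1/N).
#' @param trace a [traceParams()] list (amplitudes scaled by 1/N; trace
#'   model only).
#' @param withNormalization attach the interval-normalization behavior.
#' @param recordSpikes attach a cadence-1 spike recorder.
#' @param weightScale scale of the initial uniform weights (divided by N).
#' @return an initialized `Network`; the spike recorder (if any) is
#'   `net$recorders[[1]]`.
#' @examples
#' net <- buildReferenceModel("lif_onestep", n = 50, seed = 1)
#' simulateIterations(net, 10)
#' meanFiringFraction(net$recorders[[1]])
#' @export
buildReferenceModel <- function(kind = c("lif_onestep", "izhikevich_trace"),
                                n, seed = 42L,
                                impl = c("optimized", "naive"),
                                dtype = c("f64", "f32", "f16"),
                                neuronParams = NULL,
                                plasticity = plasticityParams(),
                                trace = traceParams(),
                                withNormalization = FALSE,
                                recordSpikes = TRUE,
                                weightScale = 0.5) {
  kind <- match.arg(kind)
  impl <- match.arg(impl)
  dtype <- match.arg(dtype)
  stopifnot(n >= 1)

  net <- newNetwork(seed = seed, dtype = dtype,
                    name = paste0(kind, "_", impl))
  ng <- addNeuronGroup(net, size = n, name = "exc", tags = c("exc", kind))
  sg <- addSynapseGroup(net, src = ng, dst = ng, name = "recurrent",
                        tags = c("recurrent", "GLU"))
  layout <- if (impl == "optimized") "src_major" else "dst_major"
  scaled <- plasticity
  scaled$learningRate <- plasticity$learningRate / n

  if (kind == "lif_onestep") {
    np <- neuronParams %||% lifParams()
    attachBehavior(ng, 1, noiseInputUniform(np$noiseHigh))
    attachBehavior(ng, 2, lifNeuron(np))
    attachBehavior(sg, 4, oneStepStdp(scaled,
                                      impl = if (impl == "optimized") "mesh"
                                             else "outer"))
  } else {
    np <- neuronParams %||% izhikevichParams()
    scaledTrace <- trace
    scaledTrace$aPlus <- trace$aPlus / n
    scaledTrace$aMinus <- trace$aMinus / n
    attachBehavior(ng, 1, noiseInputNormal(np$noiseMean, np$noiseSd))
    attachBehavior(ng, 2, izhikevichNeuron(np))
    attachBehavior(sg, 4, traceStdp(scaledTrace, clip = plasticity))
  }
  attachBehavior(sg, 3, diracSynapse(if (impl == "optimized") "indexed"
                                     else "product"))
  attachBehavior(sg, 0, weightInit(layout, maxWeight = weightScale / n))
  if (withNormalization)
    attachBehavior(sg, 5, intervalNormalization(plasticity))
  if (recordSpikes)
    addRecorder(net, ng, "spikes", cadence = 1L)

  initializeNetwork(net)
  net
}
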