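#' Leaky integrate-and-fire parameters
#'
#' Discrete-time LIF dynamics: each step the membrane potential moves a
#' fraction `leak` of the way back to `vRest`, integrates the synaptic
#' input and a per-step uniform noise drive on `[0, noiseHigh]`, spikes when
#' it reaches `vThreshold` (threshold inclusive) and resets to `vReset`.
#'
#' The default `noiseHigh = 0.165` makes an isolated neuron with the default
#' membrane parameters fire in about 1% of steps, the sparse-activity regime
#' the indexed kernels are designed for.
#'
#' @param vRest resting potential (model units).
#' @param vReset post-spike reset potential; `vReset <= vRest < vThreshold`.
#' @param vThreshold firing threshold.
#' @param leak per-step leak fraction, in (0, 1].
#' @param noiseHigh upper bound of the per-step uniform input.
#' @return named list of validated parameters.
#' @export
lifParams <- function(vRest = 0, vReset = 0, vThreshold = 1, leak = 0.1,
                      noiseHigh = 0.165) {
  stopifnot(vReset <= vRest, vRest < vThreshold, leak > 0, leak <= 1,
            noiseHigh >= 0)
  list(vRest = vRest, vReset = vReset, vThreshold = vThreshold, leak = leak,
       noiseHigh = noiseHigh)
}

#' Izhikevich neuron parameters
#'
#' Two-variable quadratic neuron model: `v' = 0.04 v^2 + 5 v + 140 - u + I`
#' and `u' = a (b v - u)`, integrated with one Euler step of one model-time
#' unit per iteration; a spike is emitted when `v >= spikeCutoff`, then
#' `v <- c` and `u <- u + d`. Defaults are the regular-spiking values
#' (a = 0.02, b = 0.2, c = -65, d = 8). `noiseSd = 7` makes an isolated
#' neuron fire in about 1% of steps under the per-step normal input drive.
#'
#' @param a recovery time scale.
#' @param b recovery sensitivity to v.
#' @param c post-spike reset potential (mV scale); must lie below
#'   `spikeCutoff`.
#' @param d post-spike recovery increment.
#' @param spikeCutoff spike detection threshold, 30 by convention.
#' @param noiseMean,noiseSd moments of the per-step normal input.
#' @return named list of validated parameters.
#' @export
izhikevichParams <- function(a = 0.02, b = 0.2, c = -65, d = 8,
                             spikeCutoff = 30, noiseMean = 0, noiseSd = 7) {
  stopifnot(a > 0, b > 0, c < spikeCutoff, noiseSd >= 0)
  list(a = a, b = b, c = c, d = d, spikeCutoff = spikeCutoff,
       noiseMean = noiseMean, noiseSd = noiseSd)
}

#' Plasticity parameters
#'
#' @param learningRate weight increment per pre/post spike coincidence.
#' @param wMin,wMax hard clip bounds, `wMin <= wMax`.
#' @param normInterval iterations between weight normalizations.
#' @return named list of validated parameters.
#' @export
plasticityParams <- function(learningRate = 0.001, wMin = 0, wMax = 1,
                             normInterval = 100L) {
  stopifnot(wMin <= wMax, normInterval >= 1)
  list(learningRate = learningRate, wMin = wMin, wMax = wMax,
       normInterval = as.integer(normInterval))
}

#' Trace STDP parameters
#'
#' Exponentially decaying per-neuron eligibility traces: each step the
#' traces decay by `exp(-1/tau)` and gain +1 at spikes; a postsynaptic
#' spike potentiates by `aPlus` times the presynaptic trace, a presynaptic
#' spike depresses by `aMinus` times the postsynaptic trace.
#'
#' @param tauPre,tauPost trace decay time constants in steps.
#' @param aPlus,aMinus potentiation and depression amplitudes.
#' @return named list of validated parameters.
#' @export
traceParams <- function(tauPre = 20, tauPost = 20, aPlus = 0.001,
                        aMinus = 0.001) {
  stopifnot(tauPre > 0, tauPost > 0, aPlus >= 0, aMinus >= 0)
  list(tauPre = tauPre, tauPost = tauPost, aPlus = aPlus, aMinus = aMinus)
}
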