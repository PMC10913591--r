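# Small in-code fixtures shared across test files.

randomInstance <- function(sizeCap = 200L, spikeRate = 0.01,
                           layout = NULL) {
  S <- sample.int(sizeCap, 1)
  D <- sample.int(sizeCap, 1)
  if (is.null(layout)) layout <- sample(c("dst_major", "src_major"), 1)
  dims <- if (layout == "dst_major") c(D, S) else c(S, D)
  list(W = weightMatrix(matrix(runif(S * D), dims[1], dims[2]),
                        layout = layout),
       src = spikeVector(runif(S) < spikeRate),
       dst = spikeVector(runif(D) < spikeRate),
       S = S, D = D, layout = layout)
}

# Probe behavior that appends its label to a shared trace environment.
probeBehavior <- function(traceEnv, label) {
  behavior(
    setup = function(comp, self)
      traceEnv$setupTrace <- c(traceEnv$setupTrace, label),
    step = function(comp, self)
      traceEnv$stepTrace <- c(traceEnv$stepTrace, label),
    name = paste0("probe_", label))
}

# Reference STDP pair protocol: isolated pre spike at t0 and post spike at
# t0 + delta (or reverse), returning the weight change of the single
# synapse. Used to measure the plasticity window shape.
tracePairDeltaW <- function(delta, params = traceParams(),
                            clip = plasticityParams(wMin = -1, wMax = 1)) {
  net <- newNetwork(seed = 1)
  pre <- addNeuronGroup(net, 1, name = "pre")
  post <- addNeuronGroup(net, 1, name = "post")
  sg <- addSynapseGroup(net, pre, post)
  forceSpikes <- behavior(
    setup = function(g, self) {
      g$state$spikes <- FALSE
      g$state$spikesOld <- FALSE
    },
    step = function(g, self)
      g$state$spikes <- g$net$iteration %in% self$params$at,
    params = list(at = integer(0)), name = "forced_spikes")
  bPre <- forceSpikes$copy(); bPost <- forceSpikes$copy()
  t0 <- 5L
  if (delta >= 0) {
    bPre$params$at <- t0
    bPost$params$at <- t0 + delta
  } else {
    bPost$params$at <- t0
    bPre$params$at <- t0 - delta
  }
  attachBehavior(pre, 1, bPre)
  attachBehavior(post, 1, bPost)
  winit <- behavior(setup = function(s, self)
    setSynapseWeights(s, weightMatrix(matrix(0, 1, 1), dtype = s$net$dtype)),
    name = "weight_init")
  attachBehavior(sg, 2, winit)
  attachBehavior(sg, 3, traceStdp(params, clip))
  initializeNetwork(net)
  simulateIterations(net, t0 + abs(delta) + 1L)
  weightData(synapseWeights(sg))[1, 1]
}
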