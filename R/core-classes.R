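# Mutable framework objects. Reference Classes give the pass-by-reference
# semantics a stateful simulation needs (behaviors mutate the state of the
# component they are attached to); the kernel layer stays value-semantic.

.Behavior <- setRefClass("Behavior",
  fields = list(
    key = "numeric", params = "list",
    setupFun = "ANY", stepFun = "ANY", owner = "ANY",
    tags = "character", uniqueName = "character"),
  methods = list(
    show = function() {
      cat(sprintf("Behavior '%s' (key %s)%s\n", uniqueName,
                  if (length(key)) format(key) else "unattached",
                  if (length(tags)) paste0(" tags: ", paste(tags, collapse = ",")) else ""))
    }))

.NeuronGroup <- setRefClass("NeuronGroup",
  fields = list(
    size = "integer", state = "environment",
    afferent = "list", efferent = "list",
    behaviors = "list", tags = "character", uniqueName = "character",
    regIndex = "integer", rng = "ANY", net = "ANY"),
  methods = list(
    show = function() {
      cat(sprintf("NeuronGroup '%s': %d neurons, %d behaviors, state {%s}\n",
                  uniqueName, size, length(behaviors),
                  paste(ls(state), collapse = ", ")))
    }))

.SynapseGroup <- setRefClass("SynapseGroup",
  fields = list(
    src = "ANY", dst = "ANY", state = "environment",
    behaviors = "list", tags = "character", uniqueName = "character",
    regIndex = "integer", rng = "ANY", net = "ANY"),
  methods = list(
    show = function() {
      cat(sprintf("SynapseGroup '%s': %s -> %s, %d behaviors\n", uniqueName,
                  src$uniqueName, dst$uniqueName, length(behaviors)))
    }))

.Recorder <- setRefClass("Recorder",
  fields = list(
    component = "ANY", varName = "character", cadence = "integer",
    buffer = "list", iterations = "integer",
    tags = "character", uniqueName = "character"),
  methods = list(
    show = function() {
      cat(sprintf("Recorder '%s': %s$%s every %d iteration(s), %d snapshots\n",
                  uniqueName, component$uniqueName, varName, cadence,
                  length(buffer)))
    }))

.Network <- setRefClass("Network",
  fields = list(
    components = "list", neuronGroups = "list", synapseGroups = "list",
    behaviors = "list", recorders = "list",
    iteration = "integer", backendName = "character", dtype = "character",
    masterSeed = "integer", isInitialized = "logical",
    tags = "character", uniqueName = "character",
    regIndex = "integer", rng = "ANY"),
  methods = list(
    show = function() {
      cat(sprintf(paste0("Network '%s' (seed %d, dtype %s, backend %s)\n",
                         "  %d neuron group(s), %d synapse group(s), ",
                         "%d recorder(s), iteration %d\n"),
                  uniqueName, masterSeed, dtype, backendName,
                  length(neuronGroups), length(synapseGroups),
                  length(recorders), iteration))
    }))

.NeuronGroupView <- setRefClass("NeuronGroupView",
  fields = list(parent = "ANY", mask = "logical", size = "integer"),
  methods = list(
    show = function() {
      cat(sprintf("NeuronGroupView of '%s': %d of %d neurons\n",
                  parent$uniqueName, size, parent$size))
    }))
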