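#' Create an empty simulation network
#'
#' The network owns all neuron groups, synapse groups, network-level
#' behaviors and recorders, advances the iteration counter, and fixes the
#' computation backend, the weight storage precision and the master seed.
#' Every component receives its own random stream derived from the master
#' seed and its registration index, so runs are bit-reproducible and adding
#' a component (for example a recorder) never perturbs the draws of the
#' others.
#'
#' @param seed integer master seed.
#' @param dtype weight storage precision, `"f64"`, `"f32"` or `"f16"`.
#' @param backend name of a registered backend (see [registerBackend()]).
#' @param name unique name of the network.
#' @param tags character labels for tag lookup.
#' @return a `Network` reference object.
#' @examples
#' net <- newNetwork(seed = 1)
#' ng <- addNeuronGroup(net, size = 10)
#' @export
newNetwork <- function(seed = 42L, dtype = c("f64", "f32", "f16"),
                       backend = "cpu", name = "network",
                       tags = character()) {
  dtype <- match.arg(dtype)
  getBackend(backend)  # errors on unknown backend
  seed <- as.integer(seed)
  net <- .Network$new(
    components = list(), neuronGroups = list(), synapseGroups = list(),
    behaviors = list(), recorders = list(),
    iteration = 0L, backendName = backend, dtype = dtype,
    masterSeed = seed, isInitialized = FALSE,
    tags = as.character(tags), uniqueName = name,
    regIndex = 1L, rng = NULL)
  net$rng <- rngStream(deriveSeed(seed, 1L))
  net$components <- list(net)
  net
}

registerComponent <- function(net, comp) {
  comp$regIndex <- length(net$components) + 1L
  comp$rng <- rngStream(deriveSeed(net$masterSeed, comp$regIndex))
  comp$net <- net
  net$components <- c(net$components, list(comp))
  invisible(comp)
}

#' Add a neuron population to a network
#'
#' @param net a `Network`.
#' @param size neuron count N.
#' @param name unique name; autogenerated when `NULL`.
#' @param tags character labels.
#' @return the new `NeuronGroup` reference object.
#' @export
addNeuronGroup <- function(net, size, name = NULL, tags = character()) {
  stopifnot(size >= 1)
  g <- .NeuronGroup$new(
    size = as.integer(size), state = new.env(parent = baseenv()),
    afferent = list(), efferent = list(), behaviors = list(),
    tags = as.character(tags),
    uniqueName = if (is.null(name))
      paste0("neurons_", length(net$neuronGroups) + 1L) else name,
    regIndex = 0L, rng = NULL, net = NULL)
  registerComponent(net, g)
  net$neuronGroups <- c(net$neuronGroups, list(g))
  g
}

#' Connect two neuron populations with a synapse group
#'
#' The group is entered into the efferent registry of its source and the
#' afferent registry of its destination, under each of its tags and under
#' `"all"`, keeping both registries consistent with the group's `src`/`dst`
#' references.
#'
#' @param net a `Network`.
#' @param src,dst source and destination `NeuronGroup`s.
#' @param name unique name; autogenerated when `NULL`.
#' @param tags character labels.
#' @return the new `SynapseGroup` reference object.
#' @export
addSynapseGroup <- function(net, src, dst, name = NULL, tags = character()) {
  sg <- .SynapseGroup$new(
    src = src, dst = dst, state = new.env(parent = baseenv()),
    behaviors = list(), tags = as.character(tags),
    uniqueName = if (is.null(name))
      paste0("synapses_", length(net$synapseGroups) + 1L) else name,
    regIndex = 0L, rng = NULL, net = NULL)
  registerComponent(net, sg)
  net$synapseGroups <- c(net$synapseGroups, list(sg))
  for (tg in unique(c("all", sg$tags))) {
    dst$afferent[[tg]] <- c(dst$afferent[[tg]], list(sg))
    src$efferent[[tg]] <- c(src$efferent[[tg]], list(sg))
  }
  sg
}

#' Define a behavior module
#'
#' A behavior couples a `setup` hook (run exactly once, before the first
#' step) and a `step` hook (run exactly once per iteration) to the component
#' it is attached to. Both hooks receive the owning component and the
#' behavior object itself, so parameters live on the behavior and state on
#' the component.
#'
#' @param step function(component, behavior) applying the per-iteration
#'   dynamics; may be `NULL` for setup-only behaviors.
#' @param setup function(component, behavior) creating the variables the
#'   behavior needs; may be `NULL`.
#' @param params named list of parameters, available as `behavior$params`.
#' @param name descriptive name used in schedules and error reports.
#' @param tags character labels for tag lookup.
#' @return a `Behavior` reference object.
#' @examples
#' b <- behavior(step = function(comp, self) invisible(NULL), name = "noop")
#' @export
behavior <- function(step = NULL, setup = NULL, params = list(),
                     name = "behavior", tags = character()) {
  stopifnot(is.null(step) || is.function(step),
            is.null(setup) || is.function(setup))
  .Behavior$new(key = numeric(0), params = params, setupFun = setup,
                stepFun = step, owner = NULL, tags = as.character(tags),
                uniqueName = name)
}

#' Attach a behavior to a component under a priority key
#'
#' Keys must be unique per component; across components they form the
#' global execution order (ties resolved by component registration order).
#'
#' @param component a `Network`, `NeuronGroup` or `SynapseGroup`.
#' @param key numeric priority key, unique on this component.
#' @param b a `Behavior`.
#' @return `b`, invisibly.
#' @export
attachBehavior <- function(component, key, b) {
  stopifnot(is.numeric(key), length(key) == 1L)
  id <- format(key)
  if (id %in% names(component$behaviors))
    stop("behavior key ", id, " already used on component '",
         component$uniqueName, "'", call. = FALSE)
  b$key <- key
  b$owner <- component
  component$behaviors[[id]] <- b
  invisible(b)
}

#' Build the global behavior schedule of a network
#'
#' Collects every behavior attached to any component and sorts it by its
#' priority key; keys are global across neuron groups, synapse groups and
#' the network. Equal keys on different components run in component
#' registration order, so repeated builds give the identical order.
#'
#' @param net a `Network`.
#' @return a [BehaviorSchedule].
#' @export
buildSchedule <- function(net) {
  keys <- numeric(0); compIdx <- integer(0)
  compNames <- character(0); behNames <- character(0)
  entries <- list()
  for (comp in net$components) {
    for (b in comp$behaviors) {
      keys <- c(keys, b$key)
      compIdx <- c(compIdx, comp$regIndex)
      compNames <- c(compNames, comp$uniqueName)
      behNames <- c(behNames, b$uniqueName)
      entries <- c(entries, list(list(component = comp, behavior = b)))
    }
  }
  ord <- order(keys, compIdx)
  new("BehaviorSchedule", keys = keys[ord], componentNames = compNames[ord],
      behaviorNames = behNames[ord], entries = entries[ord])
}

#' @rdname buildSchedule
#' @param schedule a [BehaviorSchedule].
#' @export
scheduleKeys <- function(schedule) {
  stopifnot(methods::is(schedule, "BehaviorSchedule"))
  schedule@keys
}

setMethod("show", "BehaviorSchedule", function(object) {
  cat(sprintf("BehaviorSchedule with %d entries\n", length(object@keys)))
  if (length(object@keys))
    cat(sprintf("  [%s] %s :: %s\n", format(object@keys),
                object@componentNames, object@behaviorNames), sep = "")
})

setMethod("length", "BehaviorSchedule", function(x) length(x@keys))

#' Initialize a network
#'
#' Runs every behavior's setup hook exactly once, in global schedule order,
#' and sets the iteration counter to 0. Initializing twice is an error (a
#' silent re-initialization would silently reset learned state).
#'
#' @param net a `Network`.
#' @return `net`, invisibly.
#' @export
initializeNetwork <- function(net) {
  if (net$isInitialized)
    stop("network '", net$uniqueName, "' is already initialized", call. = FALSE)
  sched <- buildSchedule(net)
  for (e in sched@entries) {
    b <- e$behavior
    if (!is.null(b$setupFun)) {
      tryCatch(b$setupFun(e$component, b), error = function(err) {
        stop("setup of behavior '", b$uniqueName, "' on component '",
             e$component$uniqueName, "' failed: ", conditionMessage(err),
             call. = FALSE)
      })
    }
  }
  net$iteration <- 0L
  net$isInitialized <- TRUE
  invisible(net)
}

#' Advance the simulation
#'
#' Executes `n` time steps. The iteration counter is incremented at the
#' start of each step, so the first executed step observes `iteration == 1`
#' and interval work gated on `iteration %% k == 0` fires at steps k, 2k,
#' ... Each step runs every step hook exactly once in global schedule order.
#'
#' @param net an initialized `Network`.
#' @param n number of iterations; `n = 0` leaves all state unchanged.
#' @return `net`, invisibly.
#' @export
simulateIterations <- function(net, n) {
  if (!net$isInitialized)
    stop("network must be initialized before simulation", call. = FALSE)
  stopifnot(n >= 0)
  sched <- buildSchedule(net)
  for (i in seq_len(n)) {
    net$iteration <- net$iteration + 1L
    for (e in sched@entries) {
      b <- e$behavior
      if (!is.null(b$stepFun)) {
        tryCatch(b$stepFun(e$component, b), error = function(err) {
          stop("step of behavior '", b$uniqueName, "' on component '",
               e$component$uniqueName, "' failed at iteration ",
               net$iteration, ": ", conditionMessage(err), call. = FALSE)
        })
      }
    }
  }
  invisible(net)
}

#' Create a population-size state vector
#'
#' Allocates a per-neuron array of the group's size on the network backend,
#' filled according to `init`. Random fills draw from the group's own
#' random stream.
#'
#' @param group a `NeuronGroup`.
#' @param init fill mode.
#' @param value constant for `init = "value"`.
#' @param min,max bounds for `init = "uniform"`.
#' @param mean,sd moments for `init = "normal"`.
#' @return numeric vector of length `group$size`.
#' @export
neuronVector <- function(group, init = c("zeros", "uniform", "normal", "value"),
                         value = 0, min = 0, max = 1, mean = 0, sd = 1) {
  init <- match.arg(init)
  bk <- getBackend(group$net$backendName)
  n <- group$size
  switch(init,
         zeros = bk$zeros(n),
         value = bk$fill(n, value),
         uniform = drawFrom(group$rng, function() bk$runif(n, min, max)),
         normal = drawFrom(group$rng, function() bk$rnorm(n, mean, sd)))
}

#' Create the weight matrix of a synapse group
#'
#' Allocates the dense (src, dst)-shaped weight matrix in the requested
#' layout with the network's dtype. Random fills draw from the synapse
#' group's own random stream and are laid out in a canonical source-major
#' order before any physical transpose, so the semantic weights W\[d, s\]
#' depend only on the seed, never on the requested storage layout.
#'
#' @param synapse a `SynapseGroup`.
#' @param layout storage orientation.
#' @param init fill mode.
#' @param value constant for `init = "value"`.
#' @param min,max bounds for `init = "uniform"`.
#' @return a [WeightMatrix].
#' @export
synapseMatrix <- function(synapse, layout = c("dst_major", "src_major"),
                          init = c("zeros", "uniform", "value"),
                          value = 0, min = 0, max = 1) {
  layout <- match.arg(layout)
  init <- match.arg(init)
  bk <- getBackend(synapse$net$backendName)
  S <- synapse$src$size; D <- synapse$dst$size
  n <- as.numeric(S) * D
  vals <- switch(init,
                 zeros = bk$zeros(n),
                 value = bk$fill(n, value),
                 uniform = drawFrom(synapse$rng,
                                    function() bk$runif(n, min, max)))
  canonical <- weightMatrix(matrix(vals, S, D), layout = "src_major",
                            dtype = synapse$net$dtype)
  if (layout == "dst_major") transposeLayout(canonical) else canonical
}

#' Find components and behaviors by tag
#'
#' Scans the network's components in registration order, then each
#' component's behaviors, and returns exactly the entities carrying `tag`.
#'
#' @param net a `Network`.
#' @param tag character tag.
#' @return list of matching entities (possibly empty).
#' @export
findByTag <- function(net, tag) {
  hits <- list()
  for (comp in net$components) {
    if (tag %in% comp$tags) hits <- c(hits, list(comp))
    for (b in comp$behaviors)
      if (tag %in% b$tags) hits <- c(hits, list(b))
  }
  hits
}

#' Masked view of a neuron group
#'
#' Exposes the state arrays of the masked subset; writes go through to the
#' parent group's state on exactly the masked positions.
#'
#' @param group a `NeuronGroup`.
#' @param mask logical vector of length `group$size`.
#' @return a `NeuronGroupView`.
#' @examples
#' net <- newNetwork(seed = 1); g <- addNeuronGroup(net, 4)
#' g$state$v <- numeric(4)
#' sub <- subgroup(g, c(TRUE, TRUE, FALSE, FALSE))
#' setStateVar(sub, "v", 1)
#' getStateVar(g, "v")
#' @export
subgroup <- function(group, mask) {
  mask <- as.logical(mask)
  if (length(mask) != group$size)
    stop("mask length ", length(mask), " does not match group size ",
         group$size, call. = FALSE)
  .NeuronGroupView$new(parent = group, mask = mask, size = sum(mask))
}

#' Read or write a component state variable
#'
#' For groups and synapse groups this accesses the state namespace
#' directly; for a [subgroup()] view it reads and writes only the masked
#' positions of the parent's array.
#'
#' @param x a `NeuronGroup`, `SynapseGroup` or `NeuronGroupView`.
#' @param name state variable name.
#' @param value replacement value (recycled over the masked positions for a
#'   view).
#' @return `getStateVar` returns the (masked) values.
#' @export
getStateVar <- function(x, name) {
  if (methods::is(x, "NeuronGroupView")) {
    full <- get(name, envir = x$parent$state, inherits = FALSE)
    full[x$mask]
  } else {
    get(name, envir = x$state, inherits = FALSE)
  }
}

#' @rdname getStateVar
#' @export
setStateVar <- function(x, name, value) {
  if (methods::is(x, "NeuronGroupView")) {
    full <- get(name, envir = x$parent$state, inherits = FALSE)
    full[x$mask] <- value
    assign(name, full, envir = x$parent$state)
  } else {
    assign(name, value, envir = x$state)
  }
  invisible(value)
}
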