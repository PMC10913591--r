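#' Record a state variable during simulation
#'
#' Attaches a recorder behavior (default key 1000 upward, so it runs after
#' the model dynamics of a step) that snapshots
#' `component$state[[varName]]` every `cadence` iterations, together with
#' the iteration number. After T iterations at cadence k the buffer holds
#' exactly `floor(T / k)` snapshots. Buffers live where the network's
#' arrays live; export to files happens only on explicit flush.
#'
#' @param net a `Network`.
#' @param component the component whose state is recorded.
#' @param varName state variable name (e.g. `"spikes"`, `"v"`).
#' @param cadence record every k-th iteration.
#' @param key priority key of the recording behavior; autogenerated when
#'   `NULL`.
#' @return the `Recorder` reference object.
#' @export
addRecorder <- function(net, component, varName, cadence = 1L, key = NULL) {
  stopifnot(cadence >= 1)
  rec <- .Recorder$new(
    component = component, varName = varName, cadence = as.integer(cadence),
    buffer = list(), iterations = integer(0),
    tags = c("recorder", varName),
    uniqueName = paste0("recorder_", length(net$recorders) + 1L, "_",
                        component$uniqueName, ".", varName))
  if (is.null(key)) key <- 1000 + length(net$recorders)
  b <- behavior(
    step = function(comp, self) {
      if (net$iteration %% rec$cadence == 0L) {
        rec$buffer <- c(rec$buffer,
                        list(get(rec$varName, envir = rec$component$state,
                                 inherits = FALSE)))
        rec$iterations <- c(rec$iterations, net$iteration)
      }
    },
    name = rec$uniqueName, tags = rec$tags)
  attachBehavior(net, key, b)
  net$recorders <- c(net$recorders, list(rec))
  rec
}

#' Recorder accessors
#'
#' @param rec a `Recorder`.
#' @return `recordedValues` the list of snapshots; `recordedIterations` the
#'   iteration number of each snapshot; `recorderLength` the buffer length.
#' @export
recordedValues <- function(rec) rec$buffer

#' @rdname recordedValues
#' @export
recordedIterations <- function(rec) rec$iterations

#' @rdname recordedValues
#' @export
recorderLength <- function(rec) length(rec$buffer)

#' @rdname recordedValues
#' @export
clearRecorder <- function(rec) {
  rec$buffer <- list()
  rec$iterations <- integer(0)
  invisible(rec)
}

#' Spike raster from a spike recorder
#'
#' Converts a recorder of a boolean `spikes` variable into the raster
#' representation: one row per emitted spike, with the (1-based) iteration,
#' the neuron group name, and the 0-based neuron index.
#'
#' @param rec a `Recorder` whose snapshots are logical vectors.
#' @return `data.frame(iteration, neuron_group, neuron_index)`.
#' @export
rasterFromRecorder <- function(rec) {
  iters <- integer(0); idx <- integer(0)
  for (i in seq_along(rec$buffer)) {
    sp <- which(rec$buffer[[i]]) - 1L
    if (length(sp)) {
      iters <- c(iters, rep(rec$iterations[i], length(sp)))
      idx <- c(idx, sp)
    }
  }
  data.frame(iteration = iters,
             neuron_group = rep(rec$component$uniqueName, length(iters)),
             neuron_index = idx, stringsAsFactors = FALSE)
}

#' Mean per-step firing fraction from a spike recorder
#'
#' @param rec a `Recorder` of a boolean spike variable.
#' @return the mean over recorded steps of the fraction of neurons firing.
#' @export
meanFiringFraction <- function(rec) {
  if (!length(rec$buffer)) return(NA_real_)
  mean(vapply(rec$buffer, mean, numeric(1)))
}
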