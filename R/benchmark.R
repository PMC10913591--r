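#' Time an operation with warmup
#'
#' Runs `warmup` untimed executions (to exclude allocation and cache
#' effects), then `reps` timed executions of `op`, recording wall-clock
#' duration per repetition. A backend that queues asynchronous device work
#' must complete it before each clock stop; the shipped CPU backend is
#' synchronous.
#'
#' @param op zero-argument function under test.
#' @param reps number of timed repetitions (default 1000).
#' @param warmup number of untimed executions before timing.
#' @param label description used in reports and errors.
#' @return a [TimingRecord].
#' @examples
#' tr <- timeOp(function() sum(1:100), reps = 5, warmup = 1)
#' timingSummary(tr)
#' @export
timeOp <- function(op, reps = 1000L, warmup = 10L, label = "op") {
  stopifnot(is.function(op), reps >= 1)
  run <- function() {
    tryCatch(op(), error = function(e)
      stop("timed operation '", label, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  for (i in seq_len(warmup)) run()
  durations <- numeric(reps)
  for (i in seq_len(reps)) {
    t0 <- proc.time()[["elapsed"]]
    run()
    durations[i] <- proc.time()[["elapsed"]] - t0
  }
  new("TimingRecord", label = label, repetitions = as.integer(reps),
      warmup = as.integer(warmup), durations = durations)
}

#' @rdname timeOp
#' @param tr a [TimingRecord].
#' @return `timingSummary` returns named statistics (mean, median, sd, min)
#'   recomputed from the raw durations.
#' @export
timingSummary <- function(tr) {
  stopifnot(methods::is(tr, "TimingRecord"))
  c(mean = mean(tr@durations), median = stats::median(tr@durations),
    sd = if (length(tr@durations) > 1) stats::sd(tr@durations) else 0,
    min = min(tr@durations))
}

setMethod("show", "TimingRecord", function(object) {
  s <- timingSummary(object)
  cat(sprintf("TimingRecord '%s': %d reps (+%d warmup), mean %.3g s, median %.3g s\n",
              object@label, object@repetitions, object@warmup,
              s[["mean"]], s[["median"]]))
})

#' Run a model benchmark grid
#'
#' Builds and simulates every cell of the grid (model kind x implementation
#' x population size x dtype x backend) for `replicates` independent runs
#' of `steps` iterations each, recording the total simulation wall time and
#' the mean per-step firing fraction. Replicate r uses seed
#' `masterSeed + r`, identical across cells, so naive and optimized cells
#' see the same random conditions. A cell failing (for example out of
#' memory) is recorded with status `"failed"` and the grid continues.
#'
#' @param kinds model kinds, see [buildReferenceModel()].
#' @param impls implementations, subset of `c("optimized", "naive")`.
#' @param sizes population sizes.
#' @param dtypes weight precisions.
#' @param backends backend names.
#' @param steps iterations per run (default 300).
#' @param replicates independent runs per cell (default 10).
#' @param masterSeed base seed.
#' @return a data.frame with one row per cell x replicate: columns `model`,
#'   `implementation`, `N`, `dtype`, `backend`, `replicate`, `steps`,
#'   `total_seconds`, `mean_firing_fraction`, `status`.
#' @export
runGrid <- function(kinds = "lif_onestep",
                    impls = c("optimized", "naive"),
                    sizes = 1000L, dtypes = "f64", backends = "cpu",
                    steps = 300L, replicates = 10L, masterSeed = 42L) {
  grid <- expand.grid(model = kinds, implementation = impls, N = sizes,
                      dtype = dtypes, backend = backends,
                      replicate = seq_len(replicates),
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  rows <- vector("list", nrow(grid))
  for (i in seq_len(nrow(grid))) {
    g <- grid[i, ]
    res <- tryCatch({
      net <- buildReferenceModel(g$model, n = g$N,
                                 seed = masterSeed + g$replicate,
                                 impl = g$implementation, dtype = g$dtype)
      t0 <- proc.time()[["elapsed"]]
      simulateIterations(net, steps)
      elapsed <- proc.time()[["elapsed"]] - t0
      list(seconds = elapsed,
           firing = meanFiringFraction(net$recorders[[1]]),
           status = "ok")
    }, error = function(e) list(seconds = NA_real_, firing = NA_real_,
                                status = "failed"))
    rows[[i]] <- data.frame(g, steps = steps, total_seconds = res$seconds,
                            mean_firing_fraction = res$firing,
                            status = res$status, stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Speed-up ratios relative to the slowest grid cell
#'
#' Aggregates the replicate times of each cell to a mean and divides the
#' slowest cell's mean by each cell's mean, so the slowest cell has ratio
#' 1 and every other cell reports how many times faster it ran. Ratios are
#' invariant to rescaling all times by a constant.
#'
#' @param results a [runGrid()] results data.frame.
#' @return a data.frame of cells with columns `mean_seconds` and `speedup`.
#' @export
speedupTable <- function(results) {
  ok <- results[results$status == "ok", , drop = FALSE]
  if (!nrow(ok)) stop("no successful grid cells", call. = FALSE)
  cells <- stats::aggregate(
    total_seconds ~ model + implementation + N + dtype + backend,
    data = ok, FUN = mean)
  names(cells)[names(cells) == "total_seconds"] <- "mean_seconds"
  cells$speedup <- max(cells$mean_seconds) / cells$mean_seconds
  cells[order(-cells$mean_seconds), , drop = FALSE]
}

#' Kernel-pair equivalence sweeps
#'
#' Runs the randomized equivalence sweeps the optimized kernels assert:
#' indexed summation against the matrix-vector product (f64 and f32), mesh
#' STDP against the outer-product STDP, multi-lag STDP against sequential
#' outer applications, and sparse transmission against the densified
#' indexed kernel. Each trial draws a random weight matrix (size up to
#' `sizeCap`) and random spike vectors at `spikeRate`.
#'
#' @param trials number of random instances per pair.
#' @param sizeCap maximum population size per instance.
#' @param spikeRate per-neuron spike probability.
#' @param seed RNG seed for the sweep.
#' @return a data.frame with one row per kernel pair: `pair`, `trials`,
#'   `max_abs_diff`, `max_rel_diff`, `exact` (TRUE iff max_abs_diff == 0).
#' @export
verifyEquivalence <- function(trials = 1000L, sizeCap = 200L,
                              spikeRate = 0.01, seed = 1L) {
  report <- function(pair, maxAbs, maxRel)
    data.frame(pair = pair, trials = trials, max_abs_diff = maxAbs,
               max_rel_diff = maxRel, exact = maxAbs == 0,
               stringsAsFactors = FALSE)
  withSeed(seed, {
    prodAbs <- prodRel <- 0; prod32Abs <- prod32Rel <- 0
    meshAbs <- lagAbs <- sparseAbs <- 0
    for (t in seq_len(trials)) {
      S <- sample.int(sizeCap, 1); D <- sample.int(sizeCap, 1)
      layout <- sample(c("dst_major", "src_major"), 1)
      dims <- if (layout == "dst_major") c(D, S) else c(S, D)
      W <- weightMatrix(matrix(stats::runif(S * D), dims[1], dims[2]),
                        layout = layout)
      src <- spikeVector(stats::runif(S) < spikeRate)
      dst <- spikeVector(stats::runif(D) < spikeRate)

      a <- synapticInputProduct(W, src)
      b <- synapticInputIndexed(W, src)
      d <- abs(a - b)
      prodAbs <- max(prodAbs, d)
      prodRel <- max(prodRel, ifelse(a == 0, 0, d / abs(a)))

      W32 <- castPrecision(W, "f32")
      a32 <- synapticInputProduct(W32, src)
      b32 <- synapticInputIndexed(W32, src)
      d32 <- abs(a32 - b32)
      prod32Abs <- max(prod32Abs, d32)
      prod32Rel <- max(prod32Rel, ifelse(a32 == 0, 0, d32 / abs(a32)))

      lr <- stats::runif(1)
      Wo <- stdpOuter(W, src, dst, lr)
      Wm <- stdpMesh(W, meshFromSpikes(src, dst, layout), lr)
      meshAbs <- max(meshAbs, abs(weightData(Wo) - weightData(Wm)))

      hp <- pushSpikes(pushSpikes(spikeHistory(2, S),
                                  spikeVector(stats::runif(S) < spikeRate)),
                       src)
      hq <- pushSpikes(pushSpikes(spikeHistory(2, D),
                                  spikeVector(stats::runif(D) < spikeRate)),
                       dst)
      amps <- defaultMultiLagAmplitudes(lr, lags = -1:1)
      Wl <- stdpMultiLag(W, hp, hq, amps)
      Ws <- W
      for (l in names(amps)) {
        li <- as.integer(l)
        Ws <- stdpOuter(Ws, spikesAtLag(hp, max(li, 0L)),
                        spikesAtLag(hq, max(-li, 0L)), amps[[l]])
      }
      lagAbs <- max(lagAbs, abs(weightData(Wl) - weightData(Ws)))

      Wsp <- randomSparseWeights(S, D, density = 0.1)
      sp <- sparseSynapticInput(Wsp, src)
      de <- synapticInputIndexed(densify(Wsp), src)
      sparseAbs <- max(sparseAbs, abs(sp - de))
    }
    rbind(report("indexed_vs_product_f64", prodAbs, prodRel),
          report("indexed_vs_product_f32", prod32Abs, prod32Rel),
          report("mesh_vs_outer_stdp", meshAbs, meshAbs),
          report("multilag_vs_sequential", lagAbs, lagAbs),
          report("sparse_vs_dense_indexed", sparseAbs, sparseAbs))
  })
}
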