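#' Read and validate a run configuration
#'
#' Configurations are structured YAML with sections `network` (model kind,
#' population size, dtype, backend, seed, iterations, implementation),
#' optional parameter-override sections `model`, `plasticity`, `trace`, an
#' optional `grid` section for benchmarks, optional `recorders` specs and
#' an `output_dir`. Validation happens before any allocation; unknown keys
#' are rejected with a message naming the section and key.
#'
#' @param path path to a YAML configuration file.
#' @return a validated configuration list of class `snnConfig`.
#' @export
readRunConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  validateRunConfig(raw, source = path)
}

#' @rdname readRunConfig
#' @param config a configuration list (as parsed from YAML).
#' @param source label used in error messages.
#' @export
validateRunConfig <- function(config, source = "config") {
  bad <- function(...) stop(source, ": ", ..., call. = FALSE)
  checkKeys <- function(x, allowed, section) {
    unknown <- setdiff(names(x), allowed)
    if (length(unknown))
      bad("unknown key '", unknown[1], "' in section '", section, "'")
  }
  if (!is.list(config)) bad("configuration must be a mapping")
  checkKeys(config, c("network", "model", "plasticity", "trace", "grid",
                      "recorders", "output_dir"), "top level")
  net <- config$network %||% list()
  checkKeys(net, c("model", "n", "dtype", "backend", "seed", "iterations",
                   "implementation", "with_normalization", "weight_scale"),
            "network")
  defaults <- list(model = "lif_onestep", n = 1000L, dtype = "f64",
                   backend = "cpu", seed = 42L, iterations = 300L,
                   implementation = "optimized", with_normalization = FALSE,
                   weight_scale = 0.5)
  net <- utils::modifyList(defaults, net)
  if (!net$model %in% c("lif_onestep", "izhikevich_trace"))
    bad("network.model must be 'lif_onestep' or 'izhikevich_trace'")
  if (!net$dtype %in% c("f64", "f32", "f16"))
    bad("network.dtype must be one of f64, f32, f16")
  if (!net$implementation %in% c("optimized", "naive"))
    bad("network.implementation must be 'optimized' or 'naive'")
  if (!is.numeric(net$n) || net$n < 1) bad("network.n must be >= 1")
  if (!is.numeric(net$iterations) || net$iterations < 0)
    bad("network.iterations must be >= 0")
  net$n <- as.integer(net$n); net$seed <- as.integer(net$seed)
  net$iterations <- as.integer(net$iterations)

  checkKeys(config$model %||% list(),
            c("v_rest", "v_reset", "v_threshold", "leak", "noise_high",
              "a", "b", "c", "d", "spike_cutoff", "noise_mean", "noise_sd"),
            "model")
  checkKeys(config$plasticity %||% list(),
            c("learning_rate", "w_min", "w_max", "norm_interval"),
            "plasticity")
  checkKeys(config$trace %||% list(),
            c("tau_pre", "tau_post", "a_plus", "a_minus"), "trace")
  grid <- config$grid %||% list()
  checkKeys(grid, c("kinds", "impls", "sizes", "dtypes", "steps",
                    "replicates"), "grid")
  for (r in config$recorders %||% list())
    checkKeys(r, c("variable", "cadence", "file"), "recorders")

  out <- list(network = net, model = config$model %||% list(),
              plasticity = config$plasticity %||% list(),
              trace = config$trace %||% list(), grid = grid,
              recorders = config$recorders %||% list(),
              output_dir = config$output_dir %||% "snnkit_out")
  class(out) <- "snnConfig"
  out
}

#' @rdname readRunConfig
#' @export
writeRunConfig <- function(config, path) {
  stopifnot(inherits(config, "snnConfig"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Map snake_case config overrides onto the parameter constructors.
configNeuronParams <- function(cfg) {
  m <- cfg$model
  if (cfg$network$model == "lif_onestep") {
    lifParams(vRest = m$v_rest %||% 0, vReset = m$v_reset %||% 0,
              vThreshold = m$v_threshold %||% 1, leak = m$leak %||% 0.1,
              noiseHigh = m$noise_high %||% 0.165)
  } else {
    izhikevichParams(a = m$a %||% 0.02, b = m$b %||% 0.2, c = m$c %||% -65,
                     d = m$d %||% 8, spikeCutoff = m$spike_cutoff %||% 30,
                     noiseMean = m$noise_mean %||% 0,
                     noiseSd = m$noise_sd %||% 7)
  }
}

configPlasticityParams <- function(cfg) {
  p <- cfg$plasticity
  plasticityParams(learningRate = p$learning_rate %||% 0.001,
                   wMin = p$w_min %||% 0, wMax = p$w_max %||% 1,
                   normInterval = p$norm_interval %||% 100L)
}

configTraceParams <- function(cfg) {
  p <- cfg$trace
  traceParams(tauPre = p$tau_pre %||% 20, tauPost = p$tau_post %||% 20,
              aPlus = p$a_plus %||% 0.001, aMinus = p$a_minus %||% 0.001)
}

#' Build and run a simulation from a configuration
#'
#' Builds the configured reference model, attaches any extra configured
#' recorders, simulates the configured number of iterations (logging one
#' line per 100 iterations unless `verbose = FALSE`), and writes the spike
#' raster plus any recorder exports into the output directory using atomic
#' writes.
#'
#' @param config an `snnConfig` (see [readRunConfig()]).
#' @param outputDir override of the configured output directory.
#' @param verbose log progress every 100 iterations.
#' @return invisibly, a list with the network and the paths written.
#' @export
runFromConfig <- function(config, outputDir = NULL, verbose = TRUE) {
  stopifnot(inherits(config, "snnConfig"))
  nc <- config$network
  net <- buildReferenceModel(nc$model, n = nc$n, seed = nc$seed,
                             impl = nc$implementation, dtype = nc$dtype,
                             neuronParams = configNeuronParams(config),
                             plasticity = configPlasticityParams(config),
                             trace = configTraceParams(config),
                             withNormalization = isTRUE(nc$with_normalization),
                             weightScale = nc$weight_scale)
  extra <- list()
  for (r in config$recorders) {
    if (identical(r$variable, "spikes")) next  # raster recorder is built in
    rec <- addRecorder(net, net$neuronGroups[[1]], r$variable,
                       cadence = as.integer(r$cadence %||% 1L))
    extra <- c(extra, list(list(rec = rec,
                                file = r$file %||% paste0(r$variable, ".csv"))))
  }
  total <- nc$iterations
  done <- 0L
  while (done < total) {
    chunk <- min(100L, total - done)
    simulateIterations(net, chunk)
    done <- done + chunk
    if (verbose) {
      sg <- net$synapseGroups[[1]]
      message(sprintf("iteration %d/%d: firing %.4f, mean weight %.6g",
                      done, total,
                      mean(net$neuronGroups[[1]]$state$spikes),
                      mean(sg$state$Wdata)))
    }
  }
  dir <- outputDir %||% config$output_dir
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rasterPath <- file.path(dir, "raster.csv")
  writeRasterCsv(rasterFromRecorder(net$recorders[[1]]), rasterPath)
  paths <- rasterPath
  for (e in extra) {
    p <- file.path(dir, e$file)
    writeRecorderCsv(e$rec, p)
    paths <- c(paths, p)
  }
  invisible(list(network = net, paths = paths))
}

#' Generate a random spike-vector fixture
#'
#' @param n neuron count.
#' @param p per-neuron independent spike probability in \[0, 1\].
#' @param seed RNG seed.
#' @return a [SpikeVector].
#' @examples
#' spikeCount <- length(activeIndices(genSpikeVector(1000, 0.01, seed = 1)))
#' @export
genSpikeVector <- function(n, p, seed = 1L) {
  if (!is.numeric(p) || p < 0 || p > 1)
    stop("spike probability p must lie in [0, 1]", call. = FALSE)
  spikeVector(withSeed(seed, stats::runif(n) < p))
}

#' Generate a random weight-matrix fixture
#'
#' @param srcSize,dstSize population sizes S and D.
#' @param layout storage orientation.
#' @param distribution `"uniform01"`, `"zeros"` or `"value"`.
#' @param dtype storage precision tag.
#' @param value constant for `distribution = "value"`.
#' @param seed RNG seed.
#' @return a [WeightMatrix].
#' @export
genWeightMatrix <- function(srcSize, dstSize,
                            layout = c("dst_major", "src_major"),
                            distribution = c("uniform01", "zeros", "value"),
                            dtype = c("f64", "f32", "f16"), value = 0,
                            seed = 1L) {
  layout <- match.arg(layout)
  distribution <- match.arg(distribution)
  dtype <- match.arg(dtype)
  n <- as.numeric(srcSize) * dstSize
  vals <- switch(distribution,
                 uniform01 = withSeed(seed, stats::runif(n)),
                 zeros = numeric(n),
                 value = rep(as.numeric(value), n))
  dims <- if (layout == "dst_major") c(dstSize, srcSize)
          else c(srcSize, dstSize)
  weightMatrix(matrix(vals, dims[1], dims[2]), layout = layout, dtype = dtype)
}
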