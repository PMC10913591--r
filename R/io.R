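#' Atomic CSV export
#'
#' Writes to a temporary file in the target directory and renames it into
#' place, so an interrupted run never leaves a truncated file.
#'
#' @param df data.frame to write.
#' @param path destination path.
#' @param headerLines optional `#`-prefixed comment lines written before
#'   the column header.
#' @return `path`, invisibly.
#' @export
writeCsvAtomic <- function(df, path, headerLines = NULL) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  tmp <- tempfile(pattern = ".snnkit_", tmpdir = dirname(path),
                  fileext = ".csv")
  con <- file(tmp, open = "wt")
  ok <- FALSE
  tryCatch({
    if (length(headerLines)) writeLines(paste0("# ", headerLines), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
    ok <- TRUE
  }, finally = {
    close(con)
    if (!ok) unlink(tmp)
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not move temporary file into place at ", path, call. = FALSE)
  }
  invisible(path)
}

#' Write a spike raster CSV
#'
#' One row per spike with columns `iteration,neuron_group,neuron_index`;
#' neuron indices are 0-based and iteration numbers 1-based, as stated in
#' the file's comment line. With zero iterations the file holds the header
#' only.
#'
#' @param raster a data.frame from [rasterFromRecorder()].
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeRasterCsv <- function(raster, path) {
  writeCsvAtomic(raster, path,
                 headerLines = "neuron_index is 0-based; iteration is 1-based")
}

#' @rdname writeRasterCsv
#' @export
readRasterCsv <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Export recorder snapshots as CSV
#'
#' Scalar snapshots become one `iteration,value` row per record; vector
#' snapshots one wide row per record (`iteration,v1,...,vN`).
#'
#' @param rec a `Recorder`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeRecorderCsv <- function(rec, path) {
  vals <- recordedValues(rec)
  iters <- recordedIterations(rec)
  if (!length(vals)) {
    df <- data.frame(iteration = integer(0))
  } else if (length(vals[[1]]) == 1L) {
    df <- data.frame(iteration = iters, value = unlist(vals))
  } else {
    m <- do.call(rbind, lapply(vals, as.numeric))
    colnames(m) <- paste0("v", seq_len(ncol(m)))
    df <- data.frame(iteration = iters, m)
  }
  writeCsvAtomic(df, path)
}

#' Weight snapshot export and import
#'
#' Plain-text snapshot of a [WeightMatrix]: comment lines carry the layout,
#' dtype and population sizes, followed by the storage matrix as CSV rows.
#' `readWeightSnapshot` reconstructs an identical object.
#'
#' @param W a [WeightMatrix].
#' @param path destination path.
#' @return `writeWeightSnapshot` returns `path` invisibly;
#'   `readWeightSnapshot` the reconstructed [WeightMatrix].
#' @export
writeWeightSnapshot <- function(W, path) {
  stopifnot(methods::is(W, "WeightMatrix"))
  df <- as.data.frame(weightData(W))
  names(df) <- paste0("c", seq_len(ncol(df)))
  writeCsvAtomic(df, path, headerLines = c(
    paste0("layout: ", matrixLayout(W)),
    paste0("dtype: ", weightDtype(W)),
    paste0("src_size: ", srcSize(W)),
    paste0("dst_size: ", dstSize(W))))
}

#' @rdname writeWeightSnapshot
#' @export
readWeightSnapshot <- function(path) {
  lines <- readLines(path, n = 10L)
  meta <- lines[startsWith(lines, "# ")]
  field <- function(key) {
    hit <- meta[startsWith(meta, paste0("# ", key, ":"))]
    if (!length(hit)) stop("snapshot missing field '", key, "'", call. = FALSE)
    trimws(sub(paste0("# ", key, ":"), "", hit[1], fixed = TRUE))
  }
  data <- as.matrix(utils::read.csv(path, comment.char = "#"))
  dimnames(data) <- NULL
  weightMatrix(data, layout = field("layout"), dtype = field("dtype"))
}

#' Write spike-vector or weight-matrix fixtures
#'
#' @param spec a list with fields `kind` (`"spike_vector"` or
#'   `"weight_matrix"`), sizes, `p` or `distribution`, `dtype`, `seed`.
#' @param path destination path.
#' @return `path`, invisibly.
#' @export
writeFixture <- function(spec, path) {
  kind <- spec$kind %||% stop("fixture spec needs a 'kind'", call. = FALSE)
  if (kind == "spike_vector") {
    sv <- genSpikeVector(spec$n %||% 1000L, spec$p %||% 0.01,
                         seed = spec$seed %||% 1L)
    writeCsvAtomic(data.frame(neuron_index = seq_along(spikeValues(sv)) - 1L,
                              spike = as.integer(spikeValues(sv))), path)
  } else if (kind == "weight_matrix") {
    W <- genWeightMatrix(spec$src_size %||% 100L, spec$dst_size %||% 100L,
                         layout = spec$layout %||% "dst_major",
                         distribution = spec$distribution %||% "uniform01",
                         dtype = spec$dtype %||% "f64",
                         seed = spec$seed %||% 1L)
    writeWeightSnapshot(W, path)
  } else {
    stop("unknown fixture kind '", kind, "'", call. = FALSE)
  }
  invisible(path)
}
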