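#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the global RNG state, seeds it with `seed`, evaluates `expr`, and
#' restores the previous state, so surrounding code never observes the draw.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @examples
#' a <- withSeed(1, runif(3))
#' b <- withSeed(1, runif(3))
#' identical(a, b)
#' @export
withSeed <- function(seed, expr) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed))
  expr
}

#' Independent reproducible random-number streams
#'
#' Each stream carries its own generator state. Components of a network own
#' one stream each, seeded deterministically from the master seed and the
#' component's registration index, so adding an extra component (for example
#' a recorder) never perturbs the random draws of the others.
#'
#' @param seed integer seed for the stream.
#' @return an object of class `rngStream`.
#' @examples
#' s <- rngStream(7)
#' drawFrom(s, function() runif(2))
#' @export
rngStream <- function(seed) {
  e <- new.env(parent = emptyenv())
  e$state <- withSeed(seed, get(".Random.seed", envir = globalenv()))
  class(e) <- "rngStream"
  e
}

#' @rdname rngStream
#' @param stream an `rngStream`.
#' @param fun zero-argument function performing the random draws.
#' @export
drawFrom <- function(stream, fun) {
  stopifnot(inherits(stream, "rngStream"))
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  assign(".Random.seed", stream$state, envir = genv)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  res <- fun()
  stream$state <- get(".Random.seed", envir = genv, inherits = FALSE)
  res
}

# Deterministic per-component seed below 2^31, derived from the master seed
# and the component's registration index.
deriveSeed <- function(master, index) {
  as.integer((as.numeric(master) * 7919 + as.numeric(index) * 104729 + 1) %%
               2147483629)
}
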