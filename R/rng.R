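#' Independent reproducible random-number streams
#'
#' All stochastic components of the simulator (drift process, camera noise)
#' draw from their own L'Ecuyer-CMRG substream derived from a single session
#' seed, so adding or removing one noise source never perturbs the draws of
#' another and every run is bit-reproducible from its seed.
#'
#' @param seed integer session seed.
#' @param n number of independent streams to derive.
#' @return list of `rng_stream` objects.
#' @export
rng_streams <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed), n >= 1)
  old <- get_rs()
  on.exit(set_rs(old), add = TRUE)
  set.seed(as.integer(seed %% .Machine$integer.max), kind = "L'Ecuyer-CMRG")
  s <- get_rs()
  streams <- vector("list", n)
  for (i in seq_len(n)) {
    s <- parallel::nextRNGStream(s)
    streams[[i]] <- new_stream(s)
  }
  streams
}

new_stream <- function(state) {
  e <- new.env(parent = emptyenv())
  e$state <- state
  class(e) <- "rng_stream"
  e
}

get_rs <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

set_rs <- function(s) {
  if (is.null(s)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", s, envir = globalenv())
  }
}

#' Evaluate an expression under a private RNG stream
#'
#' Swaps the stream's state into the session RNG, evaluates `expr`, stores
#' the advanced state back and restores whatever RNG state was active before.
#' With `stream = NULL` the expression simply uses the current RNG.
#'
#' @param stream an `rng_stream` or NULL.
#' @param expr expression performing random draws.
#' @return the value of `expr`.
#' @export
with_stream <- function(stream, expr) {
  if (is.null(stream)) {
    return(expr)
  }
  stopifnot(inherits(stream, "rng_stream"))
  old <- get_rs()
  set_rs(stream$state)
  on.exit({
    stream$state <- get_rs()
    set_rs(old)
  }, add = TRUE)
  expr
}
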