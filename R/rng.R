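#' Self-contained random number streams
#'
#' All stochastic components of the package (synthetic data generation,
#' augmentation draws, weight initialisation, batch shuffling) draw from
#' explicit stream objects rather than the global R RNG, so that a single
#' root seed fans out deterministically and no function has hidden global
#' state. A stream owns a private Mersenne-Twister state; drawing from it
#' never disturbs `.Random.seed` as left by the caller.
#'
#' @param seed integer seed for the stream.
#' @return An object of class `rng_stream`.
#' @examples
#' s <- rng_stream(1)
#' r_unif(s, 3)
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  e <- new.env(parent = emptyenv())
  old <- .save_global_seed()
  set.seed(as.integer(seed))
  e$state <- get(".Random.seed", envir = globalenv())
  .restore_global_seed(old)
  e$seed <- as.integer(seed)
  class(e) <- "rng_stream"
  e
}

#' @export
print.rng_stream <- function(x, ...) {
  cat("<rng_stream seed=", x$seed, ">\n", sep = "")
  invisible(x)
}

.save_global_seed <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
  else NULL
}

.restore_global_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
  invisible(NULL)
}

#' Evaluate an expression using a stream's RNG state
#'
#' @param stream an [rng_stream()].
#' @param expr expression to evaluate; any RNG use inside is charged to the
#'   stream.
#' @return The value of `expr`.
#' @keywords internal
with_stream <- function(stream, expr) {
  stopifnot(inherits(stream, "rng_stream"))
  old <- .save_global_seed()
  assign(".Random.seed", stream$state, envir = globalenv())
  on.exit({
    stream$state <- get(".Random.seed", envir = globalenv())
    .restore_global_seed(old)
  })
  expr
}

#' @rdname rng_stream
#' @param n,min,max,mean,sd as in [stats::runif()] / [stats::rnorm()].
#' @export
r_unif <- function(stream, n, min = 0, max = 1) {
  with_stream(stream, stats::runif(n, min, max))
}

#' @rdname rng_stream
#' @export
r_norm <- function(stream, n, mean = 0, sd = 1) {
  with_stream(stream, stats::rnorm(n, mean, sd))
}

#' @rdname rng_stream
#' @param x,size,replace as in [sample()] (a scalar `x` draws from `1:x`).
#' @export
r_sample <- function(stream, x, size = NULL, replace = FALSE) {
  if (is.null(size))
    size <- if (length(x) == 1 && is.numeric(x) && x >= 1) x else length(x)
  with_stream(stream, sample(x, size, replace = replace))
}

#' Derive a child seed from a root seed and a purpose key
#'
#' A single run seed fans out to independent per-purpose streams (data,
#' augmentation, initialisation, batching). The derivation is a fixed integer
#' hash so the same root seed always yields the same family of streams; all
#' derived seeds stay below 2^31.
#'
#' @param seed integer root seed.
#' @param key character purpose label.
#' @return integer child seed.
#' @export
fork_seed <- function(seed, key) {
  h <- sum(utf8ToInt(key) * seq_along(utf8ToInt(key)))
  as.integer((as.numeric(seed) * 48271 + h * 16807 + 12345) %% 2147483647)
}
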