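#' @useDynLib classm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats quantile rbeta rnorm runif rpois cov dist setNames
#' @importFrom utils read.csv write.csv
NULL

#' Independent reproducible random-number streams
#'
#' Several components (H-channel vs E-channel augmentation, per-slide
#' simulation, batch sampling) must draw from independent streams so that
#' consuming extra numbers in one place does not perturb another. A stream
#' owns a private copy of R's Mersenne-Twister state; drawing from it swaps
#' its state in, runs `expr`, and restores the caller's state.
#'
#' @param seed integer seed; must be below 2^31.
#' @return an object of class `rng_stream`.
#' @export
rng_stream <- function(seed) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
  env <- new.env(parent = emptyenv())
  old <- get_rng_state()
  set.seed(as.integer(seed %% .Machine$integer.max))
  env$state <- .Random.seed
  set_rng_state(old)
  structure(list(env = env, seed = seed), class = "rng_stream")
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", state, envir = globalenv())
  }
}

#' Evaluate an expression using a stream's private RNG state
#' @param rng an [rng_stream()].
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @export
with_rng <- function(rng, expr) {
  stopifnot(inherits(rng, "rng_stream"))
  old <- get_rng_state()
  set_rng_state(rng$env$state)
  on.exit({
    rng$env$state <- get_rng_state()
    set_rng_state(old)
  })
  expr
}

#' Derive a child stream deterministically from a parent stream
#' @param rng parent stream.
#' @param ... ignored.
#' @return a new `rng_stream`.
#' @export
child_stream <- function(rng, ...) {
  rng_stream(with_rng(rng, sample.int(.Machine$integer.max - 1L, 1L)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_classm <- function(msg, class) {
  stop(structure(class = c(class, "classm_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Angular difference between two unit vectors, in degrees
#' @param a,b numeric vectors of equal length.
#' @return angle in degrees in `[0, 180]`.
#' @export
angle_between_deg <- function(a, b) {
  ca <- sum(a * b) / sqrt(sum(a^2) * sum(b^2))
  acos(clip(ca, -1, 1)) * 180 / pi
}
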