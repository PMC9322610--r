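#' Evaluate code with a temporary RNG seed
#'
#' Runs \code{code} with the global random number generator seeded to
#' \code{seed}, then restores the caller's RNG state, so package functions
#' are deterministic without clobbering the user's random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of \code{code}.
#' @keywords internal
with_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a stage seed from a master seed
#'
#' Expands one master seed into independent per-stage seeds by hashing the
#' stage name, so individual pipeline stages can be re-run reproducibly.
#' The result is always a positive integer below 2^31.
#'
#' @param master integer master seed.
#' @param stage character stage name, e.g. \code{"dataset"}.
#' @return integer seed.
#' @export
#' @examples
#' derive_seed(1, "dataset")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes) * 131) %% 2147483647
  as.integer((abs(as.numeric(master)) * 7919 + h * 104729 + 1) %% 2147483629)
}

#' Clip values to the unit interval
#' @param x numeric vector or matrix.
#' @return object of the same shape with values in [0, 1].
#' @export
clip01 <- function(x) {
  x[x < 0] <- 0
  x[x > 1] <- 1
  x
}

## smallest signed angular difference a - b, wrapped to (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  d[d > pi] <- d[d > pi] - 2 * pi
  d
}

`%||%` <- function(a, b) if (is.null(a)) b else a
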