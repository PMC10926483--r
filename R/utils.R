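# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_invalid <- function(...) {
  stop(structure(class = c("optomotr_invalid_input", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards so library code never perturbs user RNG.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}

# Derive a stream seed from a root seed, staying inside 32-bit integer range.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 1103L + stream * 12821L) %% 2147483647
}

#' Unwrap a wrapped angle series
#'
#' Removes artificial jumps of about \eqn{2\pi} from an angle sequence stored
#' modulo \eqn{2\pi} (e.g. a trackball heading column), so that successive
#' differences are always in \eqn{(-\pi, \pi]}.
#'
#' @param theta numeric vector of angles in radians.
#' @return numeric vector of the same length with continuous (unwrapped) angles.
#' @export
unwrap_angle <- function(theta) {
  if (length(theta) < 2L) return(theta)
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  theta[1L] + c(0, cumsum(d))
}
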