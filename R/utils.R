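#' Sign function with sgn(0) = +1
#'
#' The readout nonlinearity of the model. The value at exactly 0 is a
#' measure-zero event for Gaussian inputs; it is fixed to +1 so that all
#' simulations are deterministic given the weights.
#'
#' @param x numeric vector.
#' @return numeric vector of -1/+1.
#' @export
sgn <- function(x) ifelse(x >= 0, 1, -1)

#' Derive independent child seeds from a root seed
#'
#' One root seed is expanded into per-component seeds so that, e.g., pattern
#' generation and learning noise are independently reproducible.
#'
#' @param seed integer root seed.
#' @param n number of child seeds.
#' @return integer vector of length `n`.
#' @export
child_seeds <- function(seed, n) {
  stopifnot(is.numeric(seed), length(seed) == 1, n >= 1)
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  sample.int(.Machine$integer.max - 1L, n)
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_count <- function(x, name, min = 1) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < min || x != floor(x))
    stop_invalid("`%s` must be a single integer >= %d", name, min)
  as.integer(x)
}

check_pm1 <- function(z, name = "zhat") {
  if (!all(z %in% c(-1, 1)))
    stop_invalid("`%s` must contain only -1 and +1", name)
  invisible(z)
}
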