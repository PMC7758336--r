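#' Generate a random classification task
#'
#' Draws `P` input patterns for each of the two pathways, with entries i.i.d.
#' standard normal, and random binary targets. The first pathway has `N_x`
#' inputs, the second `N_y` (set `N_y = 0` for the single-pathway model; all
#' downstream operations accept the same ensemble type). Each target entry is
#' an independent fair draw from {-1, +1}.
#'
#' The returned ensemble carries a trivial repetition schedule (every pattern
#' presented once, in index order); use [make_repetition_schedule()] and
#' [set_schedule()] to train some patterns more than others.
#'
#' @param P number of patterns (>= 1).
#' @param N_x first-pathway input dimension (>= 1).
#' @param N_y second-pathway input dimension (>= 0).
#' @param N_z number of readout units (>= 1).
#' @param seed integer seed; identical seed and dimensions reproduce the
#'   ensemble bit-for-bit.
#' @return an object of class `pattern_ensemble`: a list with matrices `X`
#'   (P x N_x), `Y` (P x N_y), `Zhat` (P x N_z, entries -1/+1), integer vector
#'   `repeats`, presentation `order`, scalar `nbar`, and `seed`.
#' @examples
#' ens <- generate_patterns(P = 10, N_x = 50, N_y = 50, N_z = 1, seed = 1)
#' dim(ens$X)
#' @export
generate_patterns <- function(P, N_x, N_y = 0, N_z = 1, seed = 1) {
  P <- check_count(P, "P")
  N_x <- check_count(N_x, "N_x")
  N_y <- check_count(N_y, "N_y", min = 0)
  N_z <- check_count(N_z, "N_z")
  old <- get0(".Random.seed", envir = globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  X <- matrix(rnorm(P * N_x), nrow = P, ncol = N_x)
  Y <- matrix(rnorm(P * N_y), nrow = P, ncol = N_y)
  Zhat <- matrix(sgn(runif(P * N_z) - 0.5), nrow = P, ncol = N_z)
  new_pattern_ensemble(X, Y, Zhat, repeats = rep(1L, P), order = seq_len(P),
                       seed = as.integer(seed))
}

new_pattern_ensemble <- function(X, Y, Zhat, repeats, order, seed = NA_integer_) {
  ens <- structure(
    list(X = X, Y = Y, Zhat = Zhat, repeats = as.integer(repeats),
         order = as.integer(order), nbar = mean(repeats), seed = seed),
    class = "pattern_ensemble")
  validate_pattern_ensemble(ens)
}

validate_pattern_ensemble <- function(ens) {
  P <- nrow(ens$X)
  if (P < 1 || ncol(ens$X) < 1) stop_invalid("X must be P x N_x with P, N_x >= 1")
  if (nrow(ens$Y) != P || nrow(ens$Zhat) != P)
    stop_invalid("X, Y, Zhat must have the same number of rows")
  if (ncol(ens$Zhat) < 1) stop_invalid("N_z must be >= 1")
  check_pm1(ens$Zhat, "Zhat")
  if (length(ens$repeats) != P || any(ens$repeats < 1))
    stop_invalid("repeats must be length P with entries >= 1")
  if (!isTRUE(all.equal(ens$nbar, mean(ens$repeats))))
    stop_invalid("nbar must equal mean(repeats)")
  if (any(ens$order < 1 | ens$order > P))
    stop_invalid("presentation order indices out of range")
  tab <- tabulate(ens$order, nbins = P)
  if (!all(tab == ens$repeats))
    stop_invalid("presentation order inconsistent with repeats")
  ens
}

#' @export
print.pattern_ensemble <- function(x, ...) {
  cat(sprintf(
    "pattern_ensemble: P = %d, N_x = %d, N_y = %d, N_z = %d\n",
    nrow(x$X), ncol(x$X), ncol(x$Y), ncol(x$Zhat)))
  cat(sprintf("  presentations = %d, mean repeats (nbar) = %.3f, seed = %s\n",
              length(x$order), x$nbar, format(x$seed)))
  invisible(x)
}

#' Build a repetition schedule
#'
#' Returns the per-pattern repetition counts and the presentation order in
#' which patterns are trained. Patterns are presented in index order; each
#' pattern listed in `special` is presented `special[[i]]` times, either
#' consecutively (`default_gap = 0`) or with `default_gap` other patterns
#' interleaved between successive presentations (spaced repetition).
#'
#' @param P number of patterns.
#' @param special named list or vector mapping pattern index to repetition
#'   count (indices in 1..P, counts >= 1).
#' @param default_gap number of interleaved patterns between repetitions.
#' @return list with integer vectors `repeats` (length P) and `order`.
#' @examples
#' make_repetition_schedule(3, special = c("2" = 5))$order
#' make_repetition_schedule(4, special = c("1" = 2), default_gap = 1)$order
#' @export
make_repetition_schedule <- function(P, special = list(), default_gap = 0) {
  P <- check_count(P, "P")
  default_gap <- check_count(default_gap, "default_gap", min = 0)
  idx <- as.integer(names(special))
  cnt <- as.integer(unlist(special, use.names = FALSE))
  if (length(special) > 0) {
    if (any(is.na(idx)) || any(idx < 1 | idx > P))
      stop_invalid("special indices must be named and lie in [1, %d]", P)
    if (any(cnt < 1)) stop_invalid("repetition counts must be >= 1")
  }
  repeats <- rep(1L, P)
  repeats[idx] <- cnt
  order <- integer(0)
  # pending[[k]]: c(pattern, remaining, countdown-to-next-presentation)
  pending <- list()
  emit <- function(mu) {
    order <<- c(order, mu)
    if (length(pending) > 0) {
      keep <- logical(length(pending))
      for (k in seq_along(pending)) {
        pending[[k]][3] <<- pending[[k]][3] - 1L
        while (pending[[k]][3] <= 0L && pending[[k]][2] > 0L) {
          order <<- c(order, pending[[k]][1])
          pending[[k]][2] <<- pending[[k]][2] - 1L
          pending[[k]][3] <<- as.integer(default_gap)
          if (default_gap > 0) break
        }
        keep[k] <- pending[[k]][2] > 0L
      }
      pending <<- pending[keep]
    }
  }
  for (mu in seq_len(P)) {
    if (repeats[mu] > 1L) {
      if (default_gap == 0) {
        order <- c(order, rep(mu, repeats[mu]))
      } else {
        order <- c(order, mu)
        pending[[length(pending) + 1L]] <-
          c(mu, repeats[mu] - 1L, as.integer(default_gap))
      }
    } else {
      emit(mu)
    }
  }
  # flush any repetitions still pending at the end of the sequence
  for (p in pending) order <- c(order, rep(p[1], p[2]))
  list(repeats = repeats, order = as.integer(order))
}

#' Attach a repetition schedule to an ensemble
#'
#' @param ensemble a [pattern_ensemble][generate_patterns].
#' @param schedule result of [make_repetition_schedule()].
#' @return the ensemble with updated `repeats`, `order`, and `nbar`.
#' @export
set_schedule <- function(ensemble, schedule) {
  stopifnot(inherits(ensemble, "pattern_ensemble"))
  new_pattern_ensemble(ensemble$X, ensemble$Y, ensemble$Zhat,
                       repeats = schedule$repeats, order = schedule$order,
                       seed = ensemble$seed)
}

#' Save / load a pattern ensemble
#'
#' Ensembles are stored as a single RDS container holding the matrices,
#' schedule, and seed.
#'
#' @param ensemble a pattern ensemble.
#' @param path file path.
#' @return `read_ensemble` returns the validated ensemble.
#' @export
write_ensemble <- function(ensemble, path) {
  stopifnot(inherits(ensemble, "pattern_ensemble"))
  saveRDS(ensemble, path)
  invisible(path)
}

#' @rdname write_ensemble
#' @export
read_ensemble <- function(path) {
  validate_pattern_ensemble(readRDS(path))
}
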