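#' Stationary input statistics of the sequentially trained model
#'
#' In the stationary regime of sequential training, the total summed input to
#' a readout unit for a fresh random pattern is Gaussian with variance
#' `sigma_u^2 = sigma_w^2 + sigma_h^2`, where `sigma_h^2 = beta^2 / alpha` is
#' the stationary variance of the slow-pathway current (an
#' Ornstein-Uhlenbeck balance of Hebbian kicks against decay) and `sigma_w^2`
#' is fixed by requiring that margin updates neither grow nor shrink the fast
#' weights on average. That balance condition reduces to
#'
#'   (kappa^2 + 2 sigma_h^2 - sigma_u^2) Phi(kappa / sigma_u)
#'     + kappa sigma_u phi(kappa / sigma_u) = 0,
#'
#' a one-dimensional root-finding problem. The probability that a random
#' pattern triggers a supervised update is then `q = Phi(kappa / sigma_u)`,
#' and the fast-pathway current of a stored pattern drifts to zero at rate
#' `q` per `N_x` subsequent patterns while diffusing to variance `sigma_w^2`.
#'
#' @param alpha,beta Hebbian rates (`beta = 0` recovers the single-pathway
#'   model; `alpha > 0` is required whenever `beta > 0`).
#' @param kappa margin.
#' @return list with `sigma_u`, `sigma_w2`, `sigma_h2`, and update
#'   probability `q`.
#' @export
stationary_input_stats <- function(alpha = 1, beta = 0, kappa = 1) {
  stopifnot(kappa > 0, beta >= 0, alpha >= 0)
  if (beta > 0 && alpha <= 0)
    stop_invalid("alpha must be > 0 when beta > 0 (unbounded slow weights)")
  sigma_h2 <- if (beta > 0) beta^2 / alpha else 0
  f <- function(s) {
    c <- kappa / s
    (kappa^2 + 2 * sigma_h2 - s^2) * pnorm(c) + kappa * s * dnorm(c)
  }
  lo <- sqrt(kappa^2 + 2 * sigma_h2)      # f(lo) > 0
  hi <- lo
  while (f(hi) > 0) hi <- hi * 2
  sigma_u <- uniroot(f, c(lo, hi), tol = 1e-12)$root
  list(sigma_u = sigma_u, sigma_w2 = sigma_u^2 - sigma_h2,
       sigma_h2 = sigma_h2, q = pnorm(kappa / sigma_u))
}

#' Theoretical single-pathway forgetting curve
#'
#' Drift-diffusion evaluation of the recall error at normalized lag
#' `tau = (P - nu) / N_x`. Immediately after training, the stored pattern's
#' summed input equals the margin (or exceeds it, if no update was needed);
#' each subsequent pattern shrinks that signal by a factor `(1 - q/N_x)` on
#' average and adds Gaussian diffusion, so after a lag `tau` the signal is
#' Gaussian with mean `s0 exp(-q tau)` and variance
#' `sigma_u^2 (1 - exp(-2 q tau))`. The error is the Gaussian probability
#' that the signal has crossed zero, averaged over the initial condition.
#'
#' @param tau nonnegative normalized lag (vectorized).
#' @param kappa margin.
#' @param rel_tol quadrature relative tolerance.
#' @return error probabilities in `[0, 0.5]`; 0 at `tau = 0`, 0.5 as
#'   `tau -> Inf`.
#' @examples
#' theoretical_error_single(c(0, 0.5, 2))
#' @export
theoretical_error_single <- function(tau, kappa = 1, rel_tol = 1e-6) {
  if (any(tau < 0)) stop_invalid("tau must be >= 0")
  st <- stationary_input_stats(beta = 0, kappa = kappa)
  vapply(tau, function(tt)
    dd_error(tt, st, sigma_h2 = 0, b_h = 1, c_n = 0, kappa = kappa,
             rel_tol = rel_tol), numeric(1))
}

#' Theoretical two-pathway forgetting curve
#'
#' Extends the drift-diffusion picture with the slow pathway: during training,
#' `n_ratio = n_nu / nbar` consecutive repetitions add `sqrt(2) beta n_ratio`
#' to the slow-pathway current along the target; after training that
#' component decays at rate `alpha / (N_y nbar)` per pattern (i.e.
#' `exp(-alpha tau / ratio)` over a lag `tau`, for `nbar` near 1) while
#' diffusing back to its stationary variance `beta^2 / alpha`. The fast
#' pathway tops the total current up to the margin at the first repetition
#' and then drifts and diffuses as in the single-pathway model.
#'
#' Valid when repeated patterns are a vanishing fraction of the schedule, so
#' that subsequent training is dominated by once-presented patterns.
#'
#' @param tau nonnegative normalized lag `(P - nu)/N_x` (vectorized).
#' @param ratio `N_y / N_x`.
#' @param alpha,beta Hebbian rates.
#' @param n_ratio repetition factor `n_nu / nbar` of the tested pattern
#'   (vectorized; recycled against `tau`).
#' @param kappa margin.
#' @param rel_tol quadrature relative tolerance.
#' @return error probabilities in `[0, 0.5]`.
#' @examples
#' theoretical_error_two_pathway(1, ratio = 1, alpha = 1, beta = 1,
#'                               n_ratio = 10)
#' @export
theoretical_error_two_pathway <- function(tau, ratio = 1, alpha = 1, beta = 1,
                                          n_ratio = 1, kappa = 1,
                                          rel_tol = 1e-6) {
  if (any(tau < 0)) stop_invalid("tau must be >= 0")
  stopifnot(ratio > 0, all(n_ratio > 0))
  st <- stationary_input_stats(alpha = alpha, beta = beta, kappa = kappa)
  n <- max(length(tau), length(n_ratio))
  tau <- rep_len(tau, n); n_ratio <- rep_len(n_ratio, n)
  mapply(function(tt, nr) {
    b_h <- exp(-alpha * tt / ratio)
    dd_error(tt, st, sigma_h2 = st$sigma_h2, b_h = b_h,
             c_n = sqrt(2) * beta * nr, kappa = kappa, rel_tol = rel_tol)
  }, tau, n_ratio, USE.NAMES = FALSE)
}

# Core drift-diffusion error integral.
#
# Initial condition (target taken as +1 w.l.o.g.): stationary currents
# m_p ~ N(0, sigma_w^2), h_p ~ N(0, sigma_h^2) independent; if
# m_p + h_p < kappa the supervised step sets the fast current to
# kappa - h_p, otherwise it is left at m_p; the Hebbian repetitions then add
# c_n to the slow current. After a lag tau the recalled signal is
#   m0 * b_m + (h_p + c_n) * b_h + N(0, V_m + V_h),
# with b_m = exp(-q tau), V_m = sigma_w^2 (1 - b_m^2),
# V_h = sigma_h^2 (1 - b_h^2). The error is P(signal < 0).
dd_error <- function(tau, st, sigma_h2, b_h, c_n, kappa, rel_tol = 1e-6) {
  b_m <- exp(-st$q * tau)
  V <- st$sigma_w2 * (1 - b_m^2) + sigma_h2 * (1 - b_h^2)
  s_w <- sqrt(st$sigma_w2)
  if (V <= 0) return(0)  # tau = 0: trained to margin, untouched afterward
  sv <- sqrt(V)
  if (sigma_h2 < 1e-14) {
    # single-pathway: h frozen at 0, m0 = kappa w.p. q, else the tail of m_p
    p1 <- st$q * pnorm(-kappa * b_m / sv)
    p2 <- integrate(function(m) dnorm(m, 0, s_w) * pnorm(-m * b_m / sv),
                    kappa, Inf, rel.tol = rel_tol)$value
    return(p1 + p2)
  }
  s_h <- sqrt(sigma_h2)
  inner <- function(hp) {
    thr <- kappa - hp
    hterm <- (hp + c_n) * b_h
    # branch 1: supervised update fired, fast current jumped to kappa - hp
    p1 <- pnorm(thr / s_w) * pnorm(-(thr * b_m + hterm) / sv)
    # branch 2: margin already satisfied, fast current left at m_p > thr
    p2 <- integrate(function(m) dnorm(m, 0, s_w) *
                      pnorm(-(m * b_m + hterm) / sv),
                    thr, Inf, rel.tol = rel_tol, stop.on.error = FALSE)$value
    p1 + p2
  }
  # standardized slow-pathway variable keeps the quadrature well-scaled for
  # any sigma_h
  integrate(function(t) dnorm(t) * vapply(s_h * t, inner, numeric(1)),
            -Inf, Inf, rel.tol = rel_tol)$value
}

#' Tabulate a theory curve
#'
#' @param tau grid of normalized lags.
#' @param ratio,alpha,beta,n_ratio two-pathway parameters; with `beta = 0`
#'   the single-pathway curve is returned.
#' @param kappa margin.
#' @return data frame with columns `tau`, `error`, `method` (class
#'   `theory_curve`).
#' @export
theory_curve <- function(tau, ratio = 1, alpha = 1, beta = 0, n_ratio = 1,
                         kappa = 1) {
  err <- if (beta == 0) theoretical_error_single(tau, kappa)
         else theoretical_error_two_pathway(tau, ratio, alpha, beta, n_ratio,
                                            kappa)
  structure(data.frame(tau = tau, error = err,
                       method = "numeric_drift_diffusion"),
            class = c("theory_curve", "data.frame"))
}
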