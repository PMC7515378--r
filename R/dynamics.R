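# Deterministic signal generators used as fixtures and sweep sources:
# periodic repetition, uniform noise, the logistic map, the simplified
# Lorenz flow, and the Caputo fractional-difference Henon map.

#' Periodic signal
#'
#' Cyclic repetition of a short value sequence, truncated to length n.
#'
#' @param values numeric vector, one period (non-empty).
#' @param n output length, `>= 1`.
#' @return numeric vector of length n.
#' @examples
#' periodic_signal(1:5, 12)
#' @export
periodic_signal <- function(values, n) {
  if (length(values) < 1L) stop("empty period", call. = FALSE)
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  rep_len(as.numeric(values), n)
}

#' Uniform random signal
#'
#' I.i.d. uniform samples; the stochastic fixture the deterministic
#' generators are compared against.
#'
#' @param n output length.
#' @param seed optional RNG seed for reproducibility.
#' @param min,max range of the uniform distribution.
#' @return numeric vector of length n.
#' @export
random_signal <- function(n, seed = NULL, min = 0, max = 1) {
  if (!is.null(seed)) set.seed(seed)
  stats::runif(n, min, max)
}

#' Logistic-map time series
#'
#' Iterates `x <- mu * x * (1 - x)`, discards a transient, and returns n
#' samples. The orbit stays in `[0, 1]` for `mu` in `(0, 4]`. The default
#' start `x0 = 0.3` avoids measure-zero degenerate orbits; `x0 = 0.5` maps
#' straight to the superstable point (and to 0 at mu = 4), so it triggers a
#' warning.
#'
#' @param mu map parameter in `(0, 4]`.
#' @param n samples returned.
#' @param x0 initial condition in `(0, 1)`.
#' @param transient iterations discarded before sampling.
#' @return numeric vector of length n.
#' @export
logistic_series <- function(mu, n, x0 = 0.3, transient = 1000L) {
  if (x0 <= 0 || x0 >= 1) stop("x0 must lie in (0, 1)", call. = FALSE)
  if (mu <= 0 || mu > 4) stop("mu must lie in (0, 4]", call. = FALSE)
  if (x0 == 0.5) warning("x0 = 0.5 starts on a degenerate orbit")
  x <- x0
  for (i in seq_len(transient)) x <- mu * x * (1 - x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    x <- mu * x * (1 - x)
    out[i] <- x
  }
  out
}

#' Lyapunov exponent of the logistic map
#'
#' Orbit average of `ln |mu * (1 - 2x)|` after a transient. Near
#' superstable orbits the derivative can underflow to zero; its magnitude
#' is clamped at the smallest positive double so the average stays finite
#' (and strongly negative), rather than -Inf.
#'
#' @inheritParams logistic_series
#' @param n orbit points averaged.
#' @return estimated Lyapunov exponent (nats per iteration).
#' @examples
#' logistic_lyapunov(4, n = 1e4) # ~ ln 2
#' @export
logistic_lyapunov <- function(mu, n = 1e4L, x0 = 0.3, transient = 1000L) {
  orbit <- logistic_series(mu, n, x0 = x0, transient = transient)
  deriv <- pmax(abs(mu * (1 - 2 * orbit)), .Machine$double.xmin)
  mean(log(deriv))
}

lorenz_rhs <- function(t, state, parms) {
  c_par <- parms[["c"]]
  list(c(
    10 * (state[2L] - state[1L]),
    (24 - 4 * c_par) * state[1L] - state[1L] * state[3L] + c_par * state[2L],
    state[1L] * state[2L] - 8 * state[3L] / 3
  ))
}

#' Simplified Lorenz system time series
#'
#' Integrates the three-variable flow
#' `x1' = 10(x2 - x1); x2' = (24 - 4c)x1 - x1 x3 + c x2; x3' = x1 x2 - 8 x3/3`
#' with fixed-step fourth-order Runge-Kutta and returns the x1 component
#' sampled at every step after the transient. `c = 2` gives the chaotic
#' regime used as the continuous-flow fixture.
#'
#' @param c_par bifurcation parameter c.
#' @param n samples returned.
#' @param h integration step (time units).
#' @param transient steps discarded.
#' @param initial length-3 initial state.
#' @return numeric vector of length n (the x1 component).
#' @export
simplified_lorenz_series <- function(c_par, n, h = 0.01, transient = 10000L,
                                     initial = c(0.3, 0.2, 0.1)) {
  if (h <= 0) stop("h must be > 0", call. = FALSE)
  stopifnot(length(initial) == 3L, n >= 1L, transient >= 0L)
  times <- seq(0, by = h, length.out = transient + n + 1L)
  out <- deSolve::ode(y = c(x1 = initial[1L], x2 = initial[2L], x3 = initial[3L]),
                      times = times, func = lorenz_rhs,
                      parms = list(c = c_par), method = "rk4")
  states <- out[-1L, -1L, drop = FALSE] # drop t = 0 row and time column
  if (!all(is.finite(states)) || max(abs(states)) > 1e6)
    stop("integration blow-up: trajectory left |state| <= 1e6", call. = FALSE)
  states[(transient + 1L):(transient + n), 1L]
}

#' Caputo fractional-difference memory kernel
#'
#' `phi(k) = Gamma(k + nu) / (Gamma(nu) * Gamma(k + 1))`, evaluated by the
#' multiplicative recurrence `phi(0) = 1, phi(k) = phi(k-1) * (k - 1 + nu)/k`
#' for numerical stability over long memories. For nu = 1 the kernel is
#' identically 1; for nu < 1 it decreases in k.
#'
#' @param nu fractional order in `(0, 1]`.
#' @param kmax largest lag.
#' @return numeric vector `phi(0..kmax)`, length `kmax + 1`.
#' @export
caputo_kernel <- function(nu, kmax) {
  if (nu <= 0 || nu > 1) stop("nu must lie in (0, 1]", call. = FALSE)
  phi <- numeric(kmax + 1L)
  phi[1L] <- 1
  k <- seq_len(kmax)
  if (kmax >= 1L) phi[-1L] <- cumprod((k - 1 + nu) / k)
  phi
}

#' Fractional-order Henon map time series
#'
#' Evaluates the discrete convolution solution of the Caputo
#' fractional-difference Henon map:
#' `x_i = x0 + sum_{j=1..i} phi(i-j) * (1 - a x_{j-1}^2 + y_{j-1} - x_{j-1})`
#' (and the analogous y update with increment `b x_{j-1} - y_{j-1}`), with
#' the memory kernel of [caputo_kernel()]. At nu = 1 the kernel is
#' identically 1 and the sum telescopes to the classic Henon map, which is
#' then evaluated by the equivalent one-step recurrence in O(n). For nu < 1
#' the memory is full and the cost O(n^2); n is capped at 5000 by default
#' (`allow_long = TRUE` lifts the cap).
#'
#' @param a,b bifurcation parameters.
#' @param nu fractional difference order in `(0, 1]`.
#' @param n samples returned.
#' @param x0,y0 initial conditions.
#' @param allow_long permit n > 5000.
#' @return numeric vector `x(1..n)`.
#' @export
fractional_henon_series <- function(a, b, nu = 1, n, x0 = 0.1, y0 = 0.1,
                                    allow_long = FALSE) {
  if (n < 1L) stop("n must be >= 1", call. = FALSE)
  if (nu == 1) return(henon_classic(a, b, n, x0, y0)) # kernel == 1 telescopes
  if (n > 5000L && !allow_long)
    stop("n > 5000 needs allow_long = TRUE (full-memory O(n^2) evaluation)",
         call. = FALSE)
  henon_convolution(a, b, nu, n, x0, y0)
}

# integer-order limit: phi(k) = 1 for all k collapses the convolution to the
# one-step recurrence, O(n) instead of O(n^2)
henon_classic <- function(a, b, n, x0, y0) {
  x <- numeric(n)
  xp <- x0; yp <- y0
  for (i in seq_len(n)) {
    xi <- 1 - a * xp^2 + yp
    yi <- b * xp
    if (!is.finite(xi) || abs(xi) > 1e6)
      stop(sprintf("trajectory unbounded at step %d", i), call. = FALSE)
    x[i] <- xi
    xp <- xi; yp <- yi
  }
  x
}

henon_convolution <- function(a, b, nu, n, x0, y0) {
  phi <- caputo_kernel(nu, n - 1L)
  x <- numeric(n); y <- numeric(n)
  fx <- numeric(n); fy <- numeric(n) # per-step increments f(x_{j-1}, y_{j-1})
  xp <- x0; yp <- y0
  for (i in seq_len(n)) {
    fx[i] <- 1 - a * xp^2 + yp - xp
    fy[i] <- b * xp - yp
    kern <- phi[i:1L]
    xi <- x0 + sum(kern * fx[1:i])
    yi <- y0 + sum(kern * fy[1:i])
    if (!is.finite(xi) || !is.finite(yi) || abs(xi) > 1e6 || abs(yi) > 1e6)
      stop(sprintf("trajectory unbounded at step %d", i), call. = FALSE)
    x[i] <- xi; y[i] <- yi
    xp <- xi; yp <- yi
  }
  x
}
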