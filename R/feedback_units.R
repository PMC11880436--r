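# ODE models of the physical units that compute an approximate time
# derivative via integral feedback: the idealized linear integral-feedback
# pair, negative autoregulation (molecular), a Maxwell viscoelastic element
# (mechanical) and an RC memristor element (nanofluidic). All four adapt
# perfectly: their steady response to a constant input returns to the set
# point, and their transient response encodes the input's derivative.

#' Integral-feedback unit parameters
#'
#' The linear pair
#' \deqn{\tau_u \dot u = -u + k (s(t) - m), \qquad \tau_m \dot m = u - u_0:}
#' the integrating species \eqn{m} accumulates the deviation of \eqn{u} from
#' its set point \eqn{u_0} and feeds it back, so \eqn{u} adapts perfectly to
#' constant \eqn{s} and responds transiently (derivative-like, ramp gain
#' \eqn{k \cdot \tau_m / k = \tau_m}) to changes.
#'
#' @param tau_u,tau_m Positive timescales.
#' @param k Positive gain.
#' @param u0 Set point.
#' @return Object of class `integral_feedback_params`.
#' @export
integral_feedback_params <- function(tau_u = 1, tau_m = 1, k = 1, u0 = 0) {
  stopifnot(tau_u > 0, tau_m > 0, k > 0)
  structure(list(tau_u = tau_u, tau_m = tau_m, k = k, u0 = u0),
            class = "integral_feedback_params")
}

#' Simulate the integral-feedback unit
#'
#' Integrates the linear pair with `deSolve::lsoda`, initialized at the
#' fixed point for `s_trace[1]` (so a constant input yields the flat
#' solution \eqn{u \equiv u_0} exactly).
#'
#' @param params [integral_feedback_params()].
#' @param s_trace Input signal sampled every `dt` (piecewise-linear).
#' @param dt Sampling step.
#' @param x0 Optional initial state `c(u, m)` (overrides the fixed point;
#'   use `c(k/tau_u, m0)` for an impulse response).
#' @return Tibble with `t`, `s`, `u`, `m`.
#' @export
simulate_integral_feedback <- function(params, s_trace, dt, x0 = NULL) {
  stopifnot(inherits(params, "integral_feedback_params"))
  times <- (seq_along(s_trace) - 1L) * dt
  s_fun <- stats::approxfun(times, s_trace, rule = 2)
  with(params, {
    x0 <- x0 %||% c(u = u0, m = s_trace[1] - u0 / k)
    rhs <- function(t, x, parms) {
      list(c((-x[1] + k * (s_fun(t) - x[2])) / tau_u,
             (x[1] - u0) / tau_m))
    }
    sol <- deSolve::lsoda(x0, times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    tibble::tibble(t = times, s = s_trace, u = sol[, 2L], m = sol[, 3L])
  })
}

#' Negative-autoregulation unit parameters
#'
#' The molecular realization: an activated species \eqn{u} produced from the
#' strain/dimer signal \eqn{s} at rate \eqn{k_a}, deactivated by a slowly
#' accumulating regulator \eqn{m} at rate \eqn{k_i} through a saturating
#' term \eqn{u/(u_s + u)}, and a downstream linker \eqn{l} transcribed
#' through the threshold nonlinearity \eqn{g}:
#' \deqn{\tau_u \dot u = -u + k_a s - k_i m \frac{u}{u_s + u}, \quad
#'   \tau_m \dot m = u - u_0, \quad \tau_l \dot l = g(u - u_0).}
#' For \eqn{u \gg u_s} the saturating term is ~1 and the loop linearizes to
#' the integral-feedback unit.
#'
#' @param tau_u,tau_m,tau_l Positive timescales.
#' @param k_a,k_i Production and deactivation rates (> 0).
#' @param u_s Small saturation threshold (> 0).
#' @param u0 Baseline for regulator production.
#' @param theta_g Threshold of the transcription nonlinearity `g`.
#' @return Object of class `autoregulation_params`.
#' @export
autoregulation_params <- function(tau_u = 1, tau_m = 1, tau_l = 10,
                                  k_a = 1, k_i = 1, u_s = 0.01, u0 = 1,
                                  theta_g = 0) {
  stopifnot(tau_u > 0, tau_m > 0, tau_l > 0, k_a > 0, k_i > 0, u_s > 0,
            theta_g >= 0)
  structure(list(tau_u = tau_u, tau_m = tau_m, tau_l = tau_l, k_a = k_a,
                 k_i = k_i, u_s = u_s, u0 = u0, theta_g = theta_g),
            class = "autoregulation_params")
}

#' Simulate the negative-autoregulation unit
#'
#' Integrates the nonlinear triple. Initialized at the fixed point for
#' `s_trace[1]` (where \eqn{u = u_0} and
#' \eqn{m = (k_a s - u_0)(u_s + u_0)/(k_i u_0)}), with \eqn{l(0) = 0}.
#' If \eqn{u} falls to zero the control loop breaks; the result carries a
#' `u_floor_hit` flag (and a warning) in that case.
#'
#' @param params [autoregulation_params()].
#' @param s_trace Input sampled every `dt`.
#' @param dt Sampling step.
#' @return Tibble with `t`, `s`, `u`, `m`, `l`; attribute `u_floor_hit`.
#' @export
simulate_autoregulation <- function(params, s_trace, dt) {
  stopifnot(inherits(params, "autoregulation_params"))
  times <- (seq_along(s_trace) - 1L) * dt
  s_fun <- stats::approxfun(times, s_trace, rule = 2)
  with(params, {
    m0 <- (k_a * s_trace[1] - u0) * (u_s + u0) / (k_i * u0)
    rhs <- function(t, x, parms) {
      u <- x[1]
      list(c((-u + k_a * s_fun(t) - k_i * x[2] * u / (u_s + u)) / tau_u,
             (u - u0) / tau_m,
             threshold_linear(u - u0, theta_g) / tau_l))
    }
    sol <- deSolve::lsoda(c(u = u0, m = m0, l = 0), times, rhs, parms = NULL,
                          rtol = 1e-10, atol = 1e-12)
    out <- tibble::tibble(t = times, s = s_trace, u = sol[, 2L],
                          m = sol[, 3L], l = sol[, 4L])
    hit <- any(out$u <= 0)
    if (hit) {
      warning("u reached 0: the autoregulation control loop is broken",
              call. = FALSE)
    }
    attr(out, "u_floor_hit") <- hit
    out
  })
}

#' Maxwell viscoelastic unit parameters
#'
#' Spring (modulus `k_spring`) and dashpot (viscosity `eta_dash`) in series;
#' the stress obeys \eqn{\dot u/k + u/\eta = \dot s} with strain input
#' \eqn{s}. For a constant strain rate,
#' \eqn{u(t) = \eta \dot s (1 - e^{-kt/\eta})}: the stress tracks the strain
#' rate (gain \eqn{\eta}) after the relaxation time \eqn{\eta/k}.
#'
#' @param k_spring Hookean modulus (> 0).
#' @param eta_dash Newtonian viscosity (> 0).
#' @return Object of class `maxwell_params`.
#' @export
maxwell_params <- function(k_spring = 1, eta_dash = 1) {
  stopifnot(k_spring > 0, eta_dash > 0)
  structure(list(k_spring = k_spring, eta_dash = eta_dash),
            class = "maxwell_params")
}

#' RC memristor unit parameters
#'
#' Capacitor and memristor in series; the current obeys
#' \eqn{R\dot u + u/C = \dot s} with voltage input \eqn{s}. For a constant
#' voltage ramp, \eqn{u(t) = C\dot s(1 - e^{-t/RC})}: the current tracks
#' the voltage rate (gain \eqn{C}) after the relaxation time \eqn{RC}.
#' Identical dynamics to the Maxwell unit under the mapping
#' \eqn{k \leftrightarrow 1/R}, \eqn{\eta \leftrightarrow C} (matched
#' relaxation times \eqn{\eta/k = RC} and gains \eqn{\eta = C}).
#'
#' @param R Resistance (> 0).
#' @param C Capacitance (> 0).
#' @return Object of class `rc_params`.
#' @export
rc_params <- function(R = 1, C = 1) {
  stopifnot(R > 0, C > 0)
  structure(list(R = R, C = C), class = "rc_params")
}

# Exact exponential stepping for the first-order unit
#   du/dt = -a u + gain * a * sdot(t)
# with sdot piecewise-constant per step (exact for piecewise-linear s):
# shared by the Maxwell (a = k/eta, gain = eta) and RC (a = 1/RC, gain = C)
# units. No differentiation noise: segment slopes are used directly.
.simulate_first_order <- function(a, gain, s_trace, dt, u0 = 0) {
  n <- length(s_trace)
  sdot <- diff(s_trace) / dt
  decay <- exp(-a * dt)
  u <- numeric(n)
  u[1] <- u0
  for (i in seq_len(n - 1L)) {
    u[i + 1L] <- u[i] * decay + gain * sdot[i] * (1 - decay)
  }
  u
}

#' Simulate the Maxwell unit
#'
#' Exact per-segment integration of \eqn{\dot u/k + u/\eta = \dot s} for a
#' piecewise-linear strain trace (segment slopes supplied exactly, no
#' numerical differentiation).
#'
#' @param params [maxwell_params()].
#' @param strain_trace Strain sampled every `dt` (piecewise-linear).
#' @param dt Sampling step.
#' @param u0 Initial stress.
#' @return Tibble with `t`, `s` (strain) and `u` (stress).
#' @export
simulate_maxwell <- function(params, strain_trace, dt, u0 = 0) {
  stopifnot(inherits(params, "maxwell_params"))
  a <- params$k_spring / params$eta_dash
  u <- .simulate_first_order(a, params$eta_dash, strain_trace, dt, u0 = u0)
  tibble::tibble(t = (seq_along(strain_trace) - 1L) * dt,
                 s = strain_trace, u = u)
}

#' Simulate the RC unit
#'
#' Exact per-segment integration of \eqn{R\dot u + u/C = \dot s} for a
#' piecewise-linear voltage trace.
#'
#' @param params [rc_params()].
#' @param voltage_trace Voltage sampled every `dt` (piecewise-linear).
#' @param dt Sampling step.
#' @param u0 Initial current.
#' @return Tibble with `t`, `s` (voltage) and `u` (current).
#' @export
simulate_rc <- function(params, voltage_trace, dt, u0 = 0) {
  stopifnot(inherits(params, "rc_params"))
  a <- 1 / (params$R * params$C)
  u <- .simulate_first_order(a, params$C, voltage_trace, dt, u0 = u0)
  tibble::tibble(t = (seq_along(voltage_trace) - 1L) * dt,
                 s = voltage_trace, u = u)
}

#' Drive a physical unit as a TCL synapse
#'
#' Runs the unit under the sawtooth protocol (warm-up cycles first), passes
#' its output through the threshold nonlinearity, and integrates one cycle
#' at periodic steady state: the same contract as [weight_update_cycle()],
#' with the unit's own dynamics in place of the kernel convolution. The
#' unit's ramp gain (\eqn{\tau_m}, \eqn{\eta} or \eqn{C}) multiplies the
#' recovered amplitude; with unit gain and scale separation,
#' \eqn{\Delta w/\epsilon \approx A}.
#'
#' @param params One of [integral_feedback_params()], [maxwell_params()],
#'   [rc_params()] or [autoregulation_params()].
#' @param protocol A [sawtooth_protocol()].
#' @param theta_g Threshold of the nonlinearity.
#' @param epsilon Learning rate.
#' @param n_warmup Warm-up cycles before the measured one.
#' @return The weight increment \eqn{\Delta w}.
#' @export
unit_as_synapse <- function(params, protocol, theta_g, epsilon = 1,
                            n_warmup = 2L) {
  stopifnot(inherits(protocol, "sawtooth_protocol"))
  tr <- .protocol_trace(protocol, n_cycles = n_warmup + 1L)
  sim <- if (inherits(params, "integral_feedback_params")) {
    simulate_integral_feedback(params, tr$s, protocol$dt)
  } else if (inherits(params, "maxwell_params")) {
    simulate_maxwell(params, tr$s, protocol$dt)
  } else if (inherits(params, "rc_params")) {
    simulate_rc(params, tr$s, protocol$dt)
  } else if (inherits(params, "autoregulation_params")) {
    simulate_autoregulation(params, tr$s, protocol$dt)
  } else {
    stop("unrecognized unit parameter object", call. = FALSE)
  }
  u_dev <- if (inherits(params, "integral_feedback_params") ||
               inherits(params, "autoregulation_params")) {
    sim$u - params$u0   # deviation from the set point drives the update
  } else {
    sim$u
  }
  per_n <- round(protocol$period / protocol$dt)
  idx <- (n_warmup * per_n + 1L):length(u_dev)
  g <- threshold_linear(u_dev[idx], theta_g)
  epsilon * pracma::trapz(tr$t[idx], g)
}
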