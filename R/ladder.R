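# Reversible ladder Markov-chain model of a synapse's memory kernel.
# 2 x m grid of states; gamma = r_cw / r_ccw sets the intrinsic circulation
# around the perimeter (gamma = 1: detailed balance), and the vertical
# (rung) rates are tilted by the synaptic current s so that vertical
# circulation increases with s. The output u is the occupancy of one rail;
# its step response yields the memory kernel, and the Schnakenberg entropy
# production gives the dissipation rate in units of kT.

#' Build a ladder Markov chain
#'
#' Constructs the 2-row, `m`-column grid of the sensory-adaptation type.
#' States are indexed bottom row left to right (1..m), then top row left to
#' right (m+1..2m); the perimeter counterclockwise orientation runs right
#' along the bottom rail, up the right rung, left along the top rail and
#' down the left rung.
#'
#' The top row is the "active" rail with energy \eqn{E(i) = c (x_i - s)}
#' relative to the bottom (\eqn{x_i = (i - (m+1)/2)\,\delta} the centered
#' column coordinate): rung `i` carries rates
#' \deqn{r^i_{up} = v\,e^{+c (s - x_i)/2}, \qquad
#'       r^i_{down} = v\,e^{-c (s - x_i)/2},}
#' so the up/down ratio \eqn{e^{c(s - x_i)}} increases with the signal and
#' crosses 1 at the column \eqn{x \approx s}. Horizontal rates combine the
#' Boltzmann factor of that energy (only the top row's energy varies with
#' column) with a non-equilibrium drive of strength `gamma`: bottom
#' `i+1 -> i` at `base_rate` vs `gamma * base_rate` back; top `i -> i+1`
#' at `base_rate * exp(-c delta/2)` vs `gamma * base_rate * exp(c delta/2)`
#' back. Every elementary square then has cycle affinity
#' \eqn{\ln \gamma^{-2}}, independent of `s`: the chain satisfies detailed
#' balance iff `gamma = 1`, for every constant signal. For `gamma < 1` the
#' drive implements the integral feedback of adaptation — active states
#' are pushed rightward (uphill) toward columns where activity is
#' suppressed, inactive states leftward — so the rail occupancy responds
#' to signal steps and then re-adapts, the more completely the smaller
#' `gamma`.
#'
#' @param m Number of columns (>= 2); the chain has `2 m` states.
#' @param gamma Clockwise/counterclockwise drive ratio, in (0, 1]; 1 is
#'   equilibrium, smaller values dissipate more.
#' @param base_rate Horizontal rate scale (> 0).
#' @param coupling_strength Signal coupling `c` in the exponential tilt.
#' @param s Synaptic current (dimensionless input).
#' @param vertical_rate Geometric-mean rung rate (defaults to `base_rate`).
#' @param delta Column spacing of the activity offsets, in signal units.
#'
#' @return An object of class `ladder_chain`: list with the rate matrix `Q`
#'   (`Q[a, b]` = rate a to b), the generator `G` (`dp/dt = G p`), an edge
#'   table, and the construction parameters.
#' @export
build_ladder <- function(m = 5L, gamma = 1, base_rate = 1,
                         coupling_strength = 1, s = 0,
                         vertical_rate = base_rate, delta = 1) {
  if (m < 2) stop("m must be at least 2", call. = FALSE)
  if (!(gamma > 0 && gamma <= 1)) stop("gamma must lie in (0, 1]", call. = FALSE)
  if (base_rate <= 0 || vertical_rate <= 0 || delta <= 0) {
    stop("rates and delta must be positive", call. = FALSE)
  }
  n <- 2L * m
  bot <- seq_len(m)
  top <- m + seq_len(m)
  Q <- matrix(0, n, n)
  edges <- list()
  add_edge <- function(a, b, r_ab, r_ba, type) {
    Q[a, b] <<- r_ab
    Q[b, a] <<- r_ba
    edges[[length(edges) + 1L]] <<- tibble::tibble(
      from = a, to = b, rate_fwd = r_ab, rate_rev = r_ba, type = type)
  }
  cc <- coupling_strength
  # Drive orientation implements the negative feedback of adaptation:
  # active (top) states are driven rightward — uphill, toward columns where
  # activity is suppressed — and inactive (bottom) states leftward.
  # bottom rail (energy flat): driven direction is leftward
  for (i in seq_len(m - 1L)) {
    add_edge(bot[i + 1L], bot[i], base_rate, gamma * base_rate, "horizontal")
  }
  # top rail (energy increases with x): driven direction is rightward,
  # uphill; rates carry the Boltzmann factor of the column energy
  eb <- exp(cc * delta / 2)
  for (i in seq_len(m - 1L)) {
    add_edge(top[i], top[i + 1L], base_rate / eb, gamma * base_rate * eb,
             "horizontal")
  }
  # rungs: activity flips with crossing structure, fixed geometric mean
  x_col <- (seq_len(m) - (m + 1) / 2) * delta
  for (i in seq_len(m)) {
    tilt <- exp(cc * (s - x_col[i]) / 2)
    add_edge(bot[i], top[i], vertical_rate * tilt, vertical_rate / tilt,
             "vertical")
  }
  G <- t(Q)
  diag(G) <- -rowSums(Q)
  structure(
    list(m = as.integer(m), n = n, gamma = gamma, base_rate = base_rate,
         coupling_strength = coupling_strength, s = s,
         vertical_rate = vertical_rate, delta = delta,
         Q = Q, G = G, edges = dplyr::bind_rows(edges),
         bottom = bot, top = top, x_col = x_col),
    class = "ladder_chain"
  )
}

#' @export
print.ladder_chain <- function(x, ...) {
  cat(sprintf("<ladder_chain> 2 x %d states, gamma = %g, s = %g\n",
              x$m, x$gamma, x$s))
  invisible(x)
}

# rebuild only the generator at a new signal value (geometry unchanged)
.ladder_at <- function(chain, s) {
  build_ladder(chain$m, chain$gamma, chain$base_rate,
               chain$coupling_strength, s, chain$vertical_rate, chain$delta)
}

#' Stationary distribution of the chain
#'
#' Direct dense null-space solve of the generator (one row replaced by the
#' normalization); the chains here are small (tens of states), so no
#' iterative machinery is needed.
#'
#' @param chain A [build_ladder()] chain.
#' @param s Optional signal value at which to evaluate (default the chain's
#'   own `s`).
#' @return Probability vector over the `2 m` states.
#' @export
steady_state <- function(chain, s = chain$s) {
  if (s != chain$s) chain <- .ladder_at(chain, s)
  n <- chain$n
  A <- chain$G
  A[n, ] <- 1
  b <- c(rep(0, n - 1L), 1)
  p <- tryCatch(solve(A, b), error = function(e) {
    stop("generator is numerically reducible; cannot solve steady state",
         call. = FALSE)
  })
  if (any(p < -1e-12)) {
    stop("steady-state solve produced negative occupancies", call. = FALSE)
  }
  pmax(p, 0) / sum(pmax(p, 0))
}

#' Integrate the master equation
#'
#' Solves \eqn{dp/dt = G(s(t)) p} with a stiff-capable adaptive solver
#' (`deSolve::lsoda`). The signal trace is held piecewise-constant between
#' samples (rebuilding only the rung rates).
#'
#' @param chain A [build_ladder()] chain.
#' @param s_trace Numeric vector of signal values sampled every `dt` (a
#'   scalar is treated as a constant signal).
#' @param dt Sampling step of `s_trace` and of the returned trajectory.
#' @param T Total integration time (default `(length(s_trace) - 1) * dt`).
#' @param p0 Initial occupancy (default: steady state at `s_trace[1]`).
#' @param rtol,atol Solver tolerances.
#' @return Tibble with `t`, occupancies `p1..p2m`, and the rail output `u`.
#' @export
propagate <- function(chain, s_trace, dt, T = NULL, p0 = NULL,
                      rtol = 1e-10, atol = 1e-12) {
  if (length(s_trace) == 1L) {
    T <- T %||% 10 / chain$base_rate
    s_fun <- function(t) s_trace
  } else {
    T <- T %||% ((length(s_trace) - 1L) * dt)
    s_fun <- stats::approxfun((seq_along(s_trace) - 1L) * dt, s_trace,
                              method = "constant", rule = 2)
  }
  p0 <- p0 %||% steady_state(chain, s = s_fun(0))
  times <- seq(0, T, by = dt)
  # piecewise-constant generator: cache per unique signal value
  cache <- new.env(parent = emptyenv())
  gen_at <- function(s) {
    key <- format(s, digits = 15)
    if (is.null(cache[[key]])) cache[[key]] <- .ladder_at(chain, s)$G
    cache[[key]]
  }
  rhs <- function(t, p, parms) list(as.numeric(gen_at(s_fun(t)) %*% p))
  sol <- deSolve::lsoda(p0, times, rhs, parms = NULL, rtol = rtol, atol = atol)
  P <- sol[, -1L, drop = FALSE]
  total <- rowSums(P)
  if (max(abs(total - 1)) > 1e-8) {
    stop("probability not conserved: decrease dt or tighten tolerances",
         call. = FALSE)
  }
  colnames(P) <- paste0("p", seq_len(chain$n))
  out <- tibble::as_tibble(P)
  dplyr::mutate(out, t = sol[, 1L],
                u = rowSums(P[, chain$top, drop = FALSE]),
                .before = 1L)
}

#' Rail occupancy output
#'
#' The synapse's update signal \eqn{u}: total occupancy of the top rail.
#'
#' @param chain A [build_ladder()] chain.
#' @param p Occupancy vector.
#' @return Scalar in `[0, 1]`.
#' @export
ladder_output <- function(chain, p) {
  stopifnot(length(p) == chain$n)
  sum(p[chain$top])
}

#' Schnakenberg entropy production
#'
#' \deqn{\sigma = \sum_{(a,b)} (r_{ab} p_a - r_{ba} p_b)
#'   \ln\frac{r_{ab} p_a}{r_{ba} p_b}}
#' summed over unordered connected state pairs; the dissipation rate in
#' units of kT per unit time. Always >= 0 (log-sum inequality); zero at
#' steady state iff detailed balance holds. The horizontal/vertical
#' decomposition is attached as attributes `"horizontal"` and `"vertical"`.
#'
#' @param chain A [build_ladder()] chain.
#' @param p Occupancy vector (strictly positive on connected states).
#' @return Scalar entropy production rate, with decomposition attributes.
#' @export
entropy_production <- function(chain, p) {
  stopifnot(length(p) == chain$n)
  e <- chain$edges
  if (any(p[e$from] <= 0) || any(p[e$to] <= 0)) {
    stop("zero occupancy on a connected edge: entropy production undefined",
         call. = FALSE)
  }
  fwd <- e$rate_fwd * p[e$from]
  rev <- e$rate_rev * p[e$to]
  terms <- (fwd - rev) * log(fwd / rev)
  sigma <- sum(terms)
  attr(sigma, "horizontal") <- sum(terms[e$type == "horizontal"])
  attr(sigma, "vertical") <- sum(terms[e$type == "vertical"])
  sigma
}

#' Vertical circulation (current dipole)
#'
#' The column-position first moment of the stationary rung currents,
#' \eqn{C_v = \sum_i x_i J^{up}_i} with \eqn{x_i} the centered column
#' coordinate: the signed vertical circulation pattern the signal coupling
#' drives. (The plain sum of rung currents is identically zero at steady
#' state by conservation of rail occupancy.) Increasing `s` increases
#' \eqn{C_v}.
#'
#' @param chain A [build_ladder()] chain.
#' @param p Occupancy vector (default: the chain's steady state).
#' @return Scalar circulation.
#' @export
vertical_circulation <- function(chain, p = steady_state(chain)) {
  e <- chain$edges
  v <- e[e$type == "vertical", ]
  j_up <- v$rate_fwd * p[v$from] - v$rate_rev * p[v$to]
  sum(chain$x_col * j_up)
}

#' Extract the memory kernel from the chain's step response
#'
#' Applies a small step `delta_s` to the signal from the steady state at
#' the chain's operating point, integrates the master equation, and reads
#' the kernel from the rail output: for a step input,
#' \eqn{u(t) = u(0) + \delta s \int_0^t K}, so
#' \eqn{K(t) = \dot u(t)/\delta s}. The derivative is evaluated exactly
#' from the master-equation right-hand side (no finite differencing). The
#' raw linear-response kernel is returned: its `area` is the steady-state
#' susceptibility \eqn{du_{ss}/ds} (which shrinks as the chain adapts more
#' completely, i.e. as `gamma` decreases) and its `moment1` the derivative
#' gain. Set `normalize = TRUE` to rescale to unit gain
#' (\eqn{|{-\int t K dt}| = 1}); the raw gain is then in
#' `params$raw_gain`.
#'
#' @param chain A [build_ladder()] chain.
#' @param delta_s Step size (linear-response regime).
#' @param dt Output sampling step.
#' @param T Response length to record (default `40 / base_rate`).
#' @param normalize Rescale to unit derivative gain (default `FALSE`).
#' @return A [memory_kernel()] with `family = "ladder"`.
#' @export
extract_kernel <- function(chain, delta_s = 0.05, dt = 0.02, T = NULL,
                           normalize = FALSE) {
  T <- T %||% (40 / chain$base_rate)
  s0 <- chain$s
  p0 <- steady_state(chain, s = s0)
  stepped <- .ladder_at(chain, s0 + delta_s)
  times <- seq(0, T, by = dt)
  rhs <- function(t, p, parms) list(as.numeric(stepped$G %*% p))
  sol <- deSolve::lsoda(p0, times, rhs, parms = NULL,
                        rtol = 1e-10, atol = 1e-12)
  P <- sol[, -1L, drop = FALSE]
  # du/dt = sum over the rail of (G p); exact, no differencing noise
  dP <- P %*% t(stepped$G)
  K <- rowSums(dP[, chain$top, drop = FALSE]) / delta_s
  if (max(abs(K)) < 1e-12) {
    stop("step response below numerical noise; increase delta_s", call. = FALSE)
  }
  m1 <- -pracma::trapz(times, times * K)
  vals <- if (normalize) K / abs(m1) else K
  t_peak <- times[which.max(abs(vals))]
  tau_K <- max(t_peak, pracma::trapz(times, times * abs(vals)) /
                         pracma::trapz(times, abs(vals)))
  memory_kernel(times, vals, tau_K = tau_K, family = "ladder",
                params = list(gamma = chain$gamma, m = chain$m,
                              delta_s = delta_s, raw_gain = m1,
                              s0 = s0, normalized = normalize))
}

#' Dissipation versus learning-offset trade-off
#'
#' For each `gamma`: build the chain at the operating point `s_mean`,
#' compute the steady-state Schnakenberg entropy production, extract the
#' raw memory kernel, run the single-synapse amplitude sweep, and measure
#' the deviation from the ideal contrastive update. A single learning-rate
#' calibration is shared across the whole grid: \eqn{\epsilon} is set to
#' the inverse derivative gain of the most dissipative (smallest `gamma`)
#' chain, the best differentiator available, so every chain is judged
#' against the same ideal \eqn{\Delta w/\epsilon = A} rule. Each sweep's
#' threshold is self-calibrated to the geometric mean of that chain's slow-
#' and fast-ramp response levels at the reference amplitude. Reported per
#' `gamma`: the fitted linear-portion intercept normalized by the mean
#' signal (`normalized_offset`, the Eq-13-style offset per unit
#' \eqn{\bar s}) and the full deviation
#' \eqn{|\Delta w/\epsilon - A|/\bar s} at the reference amplitude
#' (`error_at_ref`). Greater dissipation (smaller `gamma`) buys a smaller
#' offset.
#'
#' @param gammas Vector of circulation ratios in (0, 1].
#' @param m,base_rate,coupling_strength,vertical_rate,delta Chain geometry
#'   (see [build_ladder()]).
#' @param s_mean Operating-point mean signal of the sweep protocol.
#' @param tau_f,tau_s Protocol timescales (chain time units).
#' @param amplitudes Sweep amplitudes (default: 16 values log-spaced over
#'   [0.1, 0.8] of `s_mean`... kept well inside the chain's linear range).
#' @param dt Kernel / protocol sampling step.
#' @param delta_s Extraction step size.
#' @return Tibble of class `tcl_dissipation_curve` with columns `gamma`,
#'   `sigma`, `kernel_area` (raw susceptibility), `gain` (raw derivative
#'   gain), `slope`, `offset` (fit-based, may be `NA`), and
#'   `normalized_offset`.
#' @export
dissipation_offset_curve <- function(gammas, m = 5L, base_rate = 0.5,
                                     coupling_strength = 1,
                                     vertical_rate = 4 * base_rate,
                                     delta = 0.7,
                                     s_mean = 0.5, tau_f = 60, tau_s = 600,
                                     amplitudes = NULL, dt = 0.05,
                                     delta_s = 0.1) {
  amplitudes <- amplitudes %||%
    exp(seq(log(0.1 * s_mean), log(0.8 * s_mean), length.out = 12))
  A_ref <- exp(mean(log(range(amplitudes))))
  chain_at <- function(g) {
    build_ladder(m = m, gamma = g, base_rate = base_rate,
                 coupling_strength = coupling_strength, s = s_mean,
                 vertical_rate = vertical_rate, delta = delta)
  }
  kernels <- purrr::map(gammas, function(g) {
    extract_kernel(chain_at(g), delta_s = delta_s, dt = dt,
                   T = 50 / base_rate)
  })
  # common calibration: the most dissipative chain is the best
  # differentiator; its gain defines the shared learning-rate convention
  gain_ref <- kernels[[which.min(gammas)]]$moment1
  rows <- purrr::map(seq_along(gammas), function(i) {
    g <- gammas[i]
    chain <- chain_at(g)
    p_ss <- steady_state(chain)
    sigma <- as.numeric(entropy_production(chain, p_ss))
    kern_raw <- kernels[[i]]
    kern <- memory_kernel(kern_raw$t, kern_raw$values / gain_ref,
                          tau_K = kern_raw$tau_K, family = "ladder",
                          params = kern_raw$params)
    # threshold: geometric mean of the end-of-ramp |u| levels at A_ref
    cal <- sawtooth_protocol(A_ref, s_mean = s_mean, tau_f = tau_f,
                             tau_s = tau_s, dt = dt)
    tr <- .protocol_trace(cal, n_cycles = 3L)
    u <- .convolve_raw(kern, tr$s)
    per_n <- round(cal$period / cal$dt)
    i_fast <- 2L * per_n + round(tau_f / dt) + 1L
    u_fast <- abs(u[i_fast])
    u_slow <- abs(u[3L * per_n])
    theta <- sqrt(max(u_fast, 1e-12) * max(u_slow, 1e-12))
    cfg <- synapse_config(kern, theta_g = theta, epsilon = 1)
    template <- sawtooth_protocol(amplitude = max(amplitudes),
                                  s_mean = s_mean, tau_f = tau_f,
                                  tau_s = tau_s, dt = dt)
    sweep <- amplitude_sweep(cfg, template, amplitudes)
    pr_ref <- sawtooth_protocol(A_ref, s_mean = s_mean, tau_f = tau_f,
                                tau_s = tau_s, dt = dt)
    dw_ref <- weight_update_cycle(cfg, pr_ref)
    off <- attr(sweep, "offset")
    tibble::tibble(
      gamma = g, sigma = sigma,
      kernel_area = kern_raw$area, gain = kern_raw$moment1,
      slope = attr(sweep, "slope"), offset = off,
      normalized_offset = abs(dw_ref - A_ref) / s_mean
    )
  })
  out <- dplyr::bind_rows(rows)
  class(out) <- c("tcl_dissipation_curve", class(out))
  out
}

#' @export
#' @method autoplot tcl_dissipation_curve
autoplot.tcl_dissipation_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$sigma,
                                       y = .data$normalized_offset)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = factor(.data$gamma))) +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(sigma ~ "(kT per unit time)"),
                  y = "normalized offset",
                  colour = expression(gamma),
                  title = "Dissipation cost of contrastive learning")
}

#' @export
#' @method glance ladder_chain
glance.ladder_chain <- function(x, ...) {
  p <- steady_state(x)
  tibble::tibble(
    m = x$m, n_states = x$n, gamma = x$gamma, s = x$s,
    sigma = as.numeric(entropy_production(x, p)),
    u = ladder_output(x, p),
    vertical_circulation = vertical_circulation(x, p)
  )
}
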