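# Single-synapse Temporal Contrastive Learning engine: sawtooth protocols,
# the threshold nonlinearity g, the per-cycle weight update, and the
# amplitude-sweep analyses (dynamic range, offset).

#' Sawtooth presentation protocol
#'
#' The periodic synaptic-current drive: a fast linear rise from the free
#' value to the clamped value over `tau_f`, followed by a slow linear fall
#' back over `tau_s`. `amplitude` is \eqn{A = s^{clamped} - s^{free}} and
#' `s_mean` the average of the two.
#'
#' @param amplitude Signal amplitude \eqn{A}.
#' @param s_mean Mean signal level \eqn{\bar s} (average of clamped and free).
#' @param tau_f Fast (rise) timescale, > 0.
#' @param tau_s Slow (fall) timescale, > 0.
#' @param dt Sampling step.
#' @param n_cycles Number of cycles to simulate when a trace is needed.
#'
#' @return An object of class `sawtooth_protocol`.
#' @export
sawtooth_protocol <- function(amplitude, s_mean = 0, tau_f = 0.1, tau_s = 1,
                              dt = 5e-4, n_cycles = 3L) {
  if (!all(is.finite(c(amplitude, s_mean, tau_f, tau_s, dt))) ||
      tau_f <= 0 || tau_s <= 0 || dt <= 0 || n_cycles < 1) {
    stop("invalid sawtooth protocol parameters", call. = FALSE)
  }
  structure(
    list(amplitude = amplitude, s_mean = s_mean, tau_f = tau_f, tau_s = tau_s,
         period = tau_f + tau_s, dt = dt, n_cycles = as.integer(n_cycles)),
    class = "sawtooth_protocol"
  )
}

#' @export
print.sawtooth_protocol <- function(x, ...) {
  cat(sprintf(
    "<sawtooth_protocol> A = %g, s_mean = %g, tau_f = %g, tau_s = %g, dt = %g\n",
    x$amplitude, x$s_mean, x$tau_f, x$tau_s, x$dt))
  invisible(x)
}

#' Evaluate the sawtooth signal
#'
#' Piecewise-linear periodic signal: rising branch
#' \eqn{A t/\tau_f + \bar s - A/2} for \eqn{0 \le t \le \tau_f}, falling
#' branch \eqn{\bar s + A/2 - A (t-\tau_f)/\tau_s} for
#' \eqn{\tau_f < t \le \tau_f + \tau_s}, then periodic.
#'
#' @param protocol A [sawtooth_protocol()].
#' @param t Time(s), >= 0; vectorized.
#' @return Signal value(s) at `t`.
#' @export
sawtooth_signal <- function(protocol, t) {
  stopifnot(inherits(protocol, "sawtooth_protocol"), all(t >= 0))
  A <- protocol$amplitude
  tm <- t %% protocol$period
  ifelse(
    tm <= protocol$tau_f,
    A * tm / protocol$tau_f + protocol$s_mean - A / 2,
    protocol$s_mean + A / 2 - A * (tm - protocol$tau_f) / protocol$tau_s
  )
}

# full sampled trace over n_cycles periods (including t = 0)
.protocol_trace <- function(protocol, n_cycles = protocol$n_cycles) {
  t <- seq(0, n_cycles * protocol$period, by = protocol$dt)
  list(t = t, s = sawtooth_signal(protocol, t))
}

#' Threshold-linear nonlinearity g
#'
#' \eqn{g(u) = u} when \eqn{|u| \ge \theta_g}, else 0: suppresses the small
#' update signals generated by the slow relaxation ramp while passing the
#' large signals from the fast clamping ramp, which is what turns the
#' kernel-convolved sawtooth into a contrastive update.
#'
#' @param u Numeric input (vectorized).
#' @param theta_g Non-negative threshold.
#' @return `u` with sub-threshold magnitudes zeroed.
#' @export
threshold_linear <- function(u, theta_g) {
  stopifnot(theta_g >= 0)
  ifelse(abs(u) >= theta_g, u, 0)
}

#' Synapse configuration
#'
#' Bundles the threshold \eqn{\theta_g}, learning rate \eqn{\epsilon} and
#' memory kernel that define a TCL synapse.
#'
#' @param kernel A [memory_kernel()].
#' @param theta_g Non-negative threshold of the nonlinearity.
#' @param epsilon Positive learning rate.
#' @return An object of class `synapse_config`.
#' @export
synapse_config <- function(kernel, theta_g = 0, epsilon = 1) {
  stopifnot(inherits(kernel, "memory_kernel"))
  if (theta_g < 0 || epsilon <= 0) {
    stop("need theta_g >= 0 and epsilon > 0", call. = FALSE)
  }
  structure(list(kernel = kernel, theta_g = theta_g, epsilon = epsilon),
            class = "synapse_config")
}

#' Per-cycle TCL weight update
#'
#' Simulates the synapse through warm-up cycles of the sawtooth until the
#' convolution reaches its periodic steady state, then integrates
#' \eqn{\Delta w = \epsilon \int_{period} g(u(t)) dt} over one full cycle,
#' where \eqn{u = K * s} and \eqn{g} is the threshold nonlinearity.
#'
#' @param config A [synapse_config()].
#' @param protocol A [sawtooth_protocol()].
#' @param n_warmup Warm-up cycles before the measured cycle (>= 1; the kernel
#'   support must fit inside them).
#' @return The weight increment \eqn{\Delta w} (divide by
#'   `config$epsilon` for the normalized update \eqn{\Delta w/\epsilon}).
#' @export
weight_update_cycle <- function(config, protocol, n_warmup = 2L) {
  stopifnot(inherits(config, "synapse_config"),
            inherits(protocol, "sawtooth_protocol"))
  kernel <- config$kernel
  if (abs(protocol$dt - kernel$dt) > 1e-9 * kernel$dt) {
    stop("protocol dt must match kernel dt", call. = FALSE)
  }
  if (kernel$t_max > n_warmup * protocol$period) {
    stop("protocol warm-up shorter than kernel support: increase n_warmup ",
         "or the protocol period", call. = FALSE)
  }
  tr <- .protocol_trace(protocol, n_cycles = n_warmup + 1L)
  u <- .convolve_raw(kernel, tr$s)
  per_n <- round(protocol$period / protocol$dt)
  idx <- (n_warmup * per_n + 1L):(length(u))
  g <- threshold_linear(u[idx], config$theta_g)
  config$epsilon * pracma::trapz(tr$t[idx], g)
}

#' Amplitude sweep of the per-cycle update
#'
#' Computes \eqn{\Delta w/\epsilon} for each amplitude of a sawtooth template
#' and characterizes the result: the compliant region where the update tracks
#' the amplitude (\eqn{|\Delta w/\epsilon - A| \le} `rel_tol` \eqn{\cdot A}),
#' and a least-squares line over the detected linear portion of the curve.
#'
#' @param config A [synapse_config()].
#' @param template A [sawtooth_protocol()] whose amplitude is swept.
#' @param amplitudes Strictly increasing positive amplitudes.
#' @param rel_tol Compliance tolerance for the `A_min`/`A_max` detection.
#' @param n_warmup Warm-up cycles passed to [weight_update_cycle()].
#'
#' @return A tibble of class `tcl_sweep` with columns `amplitude` and
#'   `delta_w_over_eps`, plus attributes `A_min`, `A_max`, `slope`, `offset`,
#'   `linear_region` (logical index) and the generating parameters. Use
#'   [glance()] for the scalar summary and [dynamic_range()] / [fit_offset()]
#'   for the derived quantities.
#' @export
amplitude_sweep <- function(config, template, amplitudes, rel_tol = 0.1,
                            n_warmup = 2L) {
  if (length(amplitudes) == 0) stop("empty amplitude list", call. = FALSE)
  if (is.unsorted(amplitudes, strictly = TRUE)) {
    stop("amplitudes must be strictly increasing", call. = FALSE)
  }
  dw <- purrr::map_dbl(amplitudes, function(A) {
    pr <- template
    pr$amplitude <- A
    weight_update_cycle(config, pr, n_warmup = n_warmup) / config$epsilon
  })
  out <- tibble::tibble(amplitude = amplitudes, delta_w_over_eps = dw)
  lin <- .linear_region(amplitudes, dw)
  fit <- if (sum(lin) >= 3) {
    stats::coef(stats::lm(dw[lin] ~ amplitudes[lin]))
  } else {
    c(NA_real_, NA_real_)
  }
  comp <- .compliant_run(amplitudes, dw, rel_tol)
  attr(out, "A_min") <- comp$A_min
  attr(out, "A_max") <- comp$A_max
  attr(out, "slope") <- unname(fit[2])
  attr(out, "offset") <- unname(fit[1])
  attr(out, "linear_region") <- lin
  attr(out, "rel_tol") <- rel_tol
  attr(out, "theta_g") <- config$theta_g
  attr(out, "s_mean") <- template$s_mean
  attr(out, "tau_f") <- template$tau_f
  attr(out, "tau_s") <- template$tau_s
  attr(out, "kernel_area") <- config$kernel$area
  class(out) <- c("tcl_sweep", class(out))
  out
}

# Longest run of consecutive points whose local secant slope is within 10%
# of the global median secant slope (the "linear portion" of the curve).
.linear_region <- function(x, y) {
  n <- length(x)
  if (n < 3) return(rep(FALSE, n))
  sl <- diff(y) / diff(x)
  med <- stats::median(sl)
  # a flat all-zero curve (everything sub-threshold) has no linear portion
  if (!is.finite(med) || med == 0) return(rep(FALSE, n))
  ok <- abs(sl - med) <= 0.1 * abs(med)
  ok[!is.finite(ok)] <- FALSE
  # segment i covers points i and i+1; find the longest run of TRUE segments
  best <- .longest_run(ok)
  keep <- rep(FALSE, n)
  if (!is.null(best)) keep[best[1]:(best[2] + 1L)] <- TRUE
  keep
}

# longest contiguous TRUE run; returns c(start, end) indices or NULL
.longest_run <- function(ok) {
  if (!any(ok)) return(NULL)
  r <- rle(ok)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  true_runs <- which(r$values)
  i <- true_runs[which.max(r$lengths[true_runs])]
  c(starts[i], ends[i])
}

.compliant_run <- function(A, dw, rel_tol) {
  ok <- abs(dw - A) <= rel_tol * A
  run <- .longest_run(ok)
  if (is.null(run)) {
    list(A_min = NA_real_, A_max = NA_real_)
  } else {
    list(A_min = A[run[1]], A_max = A[run[2]])
  }
}

#' Dynamic range of a compliant amplitude sweep
#'
#' Ratio \eqn{A_{max}/A_{min}} of the endpoints of the largest contiguous
#' amplitude interval on which \eqn{|\Delta w/\epsilon - A| \le}
#' `rel_tol` \eqn{\cdot A}. Returns 0 when no amplitude is compliant. The
#' protocol timescales bound this ratio by \eqn{\tau_s/\tau_f}.
#'
#' @param sweep A [amplitude_sweep()] result.
#' @param rel_tol Compliance tolerance (default the sweep's own).
#' @return The dynamic range (>= 1), or 0 for an empty compliant region.
#' @export
dynamic_range <- function(sweep, rel_tol = attr(sweep, "rel_tol") %||% 0.1) {
  stopifnot(inherits(sweep, "tcl_sweep"))
  comp <- .compliant_run(sweep$amplitude, sweep$delta_w_over_eps, rel_tol)
  if (is.na(comp$A_min)) 0 else comp$A_max / comp$A_min
}

#' Offset of the linear portion of a sweep
#'
#' The y-intercept of the least-squares line fitted over the detected linear
#' portion of \eqn{\Delta w/\epsilon} versus \eqn{A}. For zero-area kernels
#' in the scale-separated regime this is ~0; kernels with area \eqn{I \ne 0}
#' produce an offset predicted by [predicted_offset()].
#'
#' @param sweep A [amplitude_sweep()] result.
#' @return The fitted intercept.
#' @export
fit_offset <- function(sweep) {
  stopifnot(inherits(sweep, "tcl_sweep"))
  off <- attr(sweep, "offset")
  if (is.null(off) || is.na(off)) {
    stop("no linear region detected in sweep; cannot fit an offset",
         call. = FALSE)
  }
  off
}

#' Predicted contrastive-update offset for a non-zero-area kernel
#'
#' Small-area, small-\eqn{\tau_K}, large-\eqn{\tau_s} limit of the deviation
#' from the ideal contrastive rule:
#' \deqn{\epsilon^{-1}\Delta w = (s^{clamped} - s^{free}) +
#'   \frac{\tau_f I}{2}(s^{free} + s^{clamped}),}
#' i.e. the offset is \eqn{(\tau_f I/2)(s^{free} + s^{clamped})}.
#'
#' @param tau_f Fast protocol timescale.
#' @param I Kernel area.
#' @param s_free,s_clamped Free and clamped signal levels.
#' @return The predicted y-intercept of the \eqn{\Delta w/\epsilon} vs
#'   \eqn{A} line.
#' @export
predicted_offset <- function(tau_f, I, s_free, s_clamped) {
  tau_f * I / 2 * (s_free + s_clamped)
}

#' Choose the threshold maximizing the dynamic range
#'
#' Grid search over candidate thresholds \eqn{\theta_g}: for each candidate,
#' runs a standard amplitude sweep up to `A_abs_max` and measures the
#' dynamic range; returns the candidate with the largest range (ties break
#' to the smaller threshold; deterministic given the grid). The useful
#' candidates lie between the slow-ramp and fast-ramp plateau levels of
#' \eqn{|u|} at the maximal amplitude, \eqn{M_1 A_{max}/\tau_s} and
#' \eqn{M_1 A_{max}/\tau_f}, and the search grid is geometric between
#' slightly-widened versions of those bounds (so the chosen threshold scales
#' linearly with `A_abs_max`).
#'
#' @param kernel A [memory_kernel()].
#' @param tau_f,tau_s Protocol timescales.
#' @param A_abs_max Largest amplitude the synapse must handle (> 0).
#' @param s_mean Mean signal level of the standard sweep (default 0).
#' @param dt Simulation step (default kernel dt).
#' @param n_theta Number of threshold candidates.
#' @param n_amp Number of sweep amplitudes per candidate.
#' @param rel_tol Compliance tolerance.
#' @param A_abs_min Smallest amplitude of the operating range; defaults to
#'   `A_abs_max / (3 tau_s / tau_f)`, comfortably below the widest window
#'   the timescales allow. Set it to the bottom of the amplitude range you
#'   actually care about to resolve ties between equally wide windows.
#' @return The selected threshold \eqn{\theta_g > 0}.
#' @export
choose_threshold <- function(kernel, tau_f, tau_s, A_abs_max, s_mean = 0,
                             dt = kernel$dt, n_theta = 15L, n_amp = 24L,
                             rel_tol = 0.1, A_abs_min = NULL) {
  stopifnot(inherits(kernel, "memory_kernel"), A_abs_max > 0,
            tau_f > 0, tau_s > 0)
  A_abs_min <- A_abs_min %||% (A_abs_max / (3 * tau_s / tau_f))
  stopifnot(A_abs_min > 0, A_abs_min < A_abs_max)
  gain <- abs(kernel$moment1)
  # the synapse is linear, so the search runs on amplitudes normalized by
  # A_abs_max; the winning threshold is scaled back at the end, making the
  # choice exactly covariant under a rescaling of all signal levels
  scale <- A_abs_max
  r <- A_abs_min / A_abs_max
  th_lo <- gain * r / tau_s
  th_hi <- gain / tau_f * 1.5
  cand <- exp(seq(log(th_lo), log(th_hi), length.out = n_theta))
  amps <- exp(seq(log(r), log(1), length.out = n_amp))
  template <- sawtooth_protocol(amplitude = 1, s_mean = s_mean / scale,
                                tau_f = tau_f, tau_s = tau_s, dt = dt)
  ranges <- purrr::map_dbl(cand, function(th) {
    cfg <- synapse_config(kernel, theta_g = th, epsilon = 1)
    dynamic_range(amplitude_sweep(cfg, template, amps, rel_tol = rel_tol))
  })
  best <- max(ranges)
  if (best <= 0) {
    # no compliant window anywhere: fall back to the geometric mean of the
    # slow/fast plateau levels at the top amplitude
    return(scale * gain * sqrt(1 / (tau_f * tau_s)))
  }
  # the range objective is flat near its optimum; take the geometric center
  # of the near-optimal plateau rather than an arbitrary grid argmax
  sel <- cand[ranges >= 0.95 * best]
  scale * exp(mean(log(sel)))
}

#' Write a sweep to CSV
#'
#' Two columns, `A` and `delta_w_over_eps`, matching the sweep contract.
#'
#' @param sweep A [amplitude_sweep()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sweep_csv <- function(sweep, path) {
  stopifnot(inherits(sweep, "tcl_sweep"))
  readr::write_csv(
    tibble::tibble(A = sweep$amplitude,
                   delta_w_over_eps = sweep$delta_w_over_eps),
    path
  )
  invisible(path)
}

#' @export
#' @method tidy tcl_sweep
#' @importFrom generics tidy
tidy.tcl_sweep <- function(x, ...) {
  tibble::tibble(
    amplitude = x$amplitude,
    delta_w_over_eps = x$delta_w_over_eps,
    linear_region = attr(x, "linear_region"),
    compliant = abs(x$delta_w_over_eps - x$amplitude) <=
      (attr(x, "rel_tol") %||% 0.1) * x$amplitude
  )
}

#' @export
#' @method glance tcl_sweep
glance.tcl_sweep <- function(x, ...) {
  tibble::tibble(
    A_min = attr(x, "A_min"),
    A_max = attr(x, "A_max"),
    dynamic_range = dynamic_range(x),
    slope = attr(x, "slope"),
    offset = attr(x, "offset"),
    theta_g = attr(x, "theta_g"),
    s_mean = attr(x, "s_mean"),
    tau_f = attr(x, "tau_f"),
    tau_s = attr(x, "tau_s"),
    kernel_area = attr(x, "kernel_area")
  )
}

#' @export
#' @method autoplot tcl_sweep
autoplot.tcl_sweep <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$amplitude,
                                   y = .data$delta_w_over_eps)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::geom_point(ggplot2::aes(colour = .data$compliant)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "amplitude A", y = expression(Delta * w / epsilon),
                  colour = "compliant",
                  title = "Per-cycle TCL update vs signal amplitude")
}
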