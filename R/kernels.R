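# Memory kernels K(t): the implicit non-equilibrium memory of a synapse.
# A kernel is sampled on a uniform grid t = 0, dt, ..., t_max; its convolution
# with the synaptic current s(t) produces the update signal u(t). Kernels with
# zero area I = integral K dt have zero DC gain and act as finite-timescale
# derivative operators with gain M1 = -integral t K(t) dt.

#' Construct a sampled memory kernel
#'
#' Low-level constructor for a `memory_kernel` object: a linear-response
#' kernel \eqn{K(t)} sampled on the uniform grid \eqn{0, dt, \ldots, t_{max}}.
#' Most users should call [make_feedback_kernel()], [make_sine_kernel()] or
#' [make_biphasic_kernel()] instead.
#'
#' @param t Numeric vector of sample times (uniform, starting at 0).
#' @param values Kernel samples \eqn{K(t)} (units 1/time).
#' @param tau_K Characteristic timescale of the kernel (time units).
#' @param family Character tag recording the generating family.
#' @param params Named list of generating parameters (kept for serialization).
#'
#' @return An object of class `memory_kernel`: a list with elements `t`,
#'   `values`, `dt`, `t_max`, `tau_K`, `area` (trapezoidal quadrature of the
#'   samples), `moment1` (the derivative gain \eqn{-\int t K dt}), `family`
#'   and `params`.
#' @export
memory_kernel <- function(t, values, tau_K, family = "custom", params = list()) {
  stopifnot(is.numeric(t), is.numeric(values), length(t) == length(values),
            length(t) >= 3)
  dt <- t[2] - t[1]
  if (any(abs(diff(t) - dt) > 1e-9 * dt)) {
    stop("kernel grid must be uniform", call. = FALSE)
  }
  if (!is.finite(tau_K) || tau_K <= 0) {
    stop("tau_K must be a positive time", call. = FALSE)
  }
  structure(
    list(
      t = t,
      values = values,
      dt = dt,
      t_max = t[length(t)],
      tau_K = tau_K,
      area = pracma::trapz(t, values),
      moment1 = -pracma::trapz(t, t * values),
      family = family,
      params = params
    ),
    class = "memory_kernel"
  )
}

#' @export
print.memory_kernel <- function(x, ...) {
  cat(sprintf(
    "<memory_kernel: %s>\n  tau_K = %g, dt = %g, t_max = %g (%d samples)\n  area I = %.4g, derivative gain M1 = %.4g\n",
    x$family, x$tau_K, x$dt, x$t_max, length(x$values), x$area, x$moment1
  ))
  invisible(x)
}

#' @export
#' @method as_tibble memory_kernel
#' @importFrom tibble as_tibble
as_tibble.memory_kernel <- function(x, ...) {
  tibble::tibble(t = x$t, K = x$values)
}

#' Memory kernel from integral feedback control
#'
#' Closed-form impulse-response kernel of the two-variable integral feedback
#' unit (a controlled species \eqn{u} relaxing on \eqn{\tau_u} and an
#' integrating species \eqn{m} on \eqn{\tau_m} with gain \eqn{k}):
#' \deqn{K(t) = e^{-bt}\left(\cosh(\omega t) - \frac{b}{\omega}\sinh(\omega t)\right),
#'   \quad b = \frac{1}{2\tau_u},\ \omega = \sqrt{b^2 - k/(\tau_u\tau_m)}.}
#' When \eqn{\omega^2 < 0} the same analytic function continues to
#' \eqn{e^{-bt}(\cos|\omega|t - (b/|\omega|)\sin|\omega|t)} (the underdamped
#' branch); at \eqn{\omega = 0} it is \eqn{e^{-bt}(1 - bt)}. In all branches
#' \eqn{K(0) = 1} and the kernel integrates to zero (perfect adaptation of
#' the feedback loop).
#'
#' @param tau_u Relaxation time of the controlled variable (> 0).
#' @param tau_m Integration time of the feedback variable (> 0).
#' @param k Feedback gain (> 0).
#' @param dt Sampling step (> 0).
#' @param t_max Support length; defaults to 8 times the slowest decay time.
#'
#' @return A [memory_kernel()] with `family = "feedback"`.
#' @seealso [simulate_integral_feedback()] for the ODE pair whose impulse
#'   response this kernel is (up to the physical scale \eqn{k/\tau_u}).
#' @export
make_feedback_kernel <- function(tau_u, tau_m, k, dt, t_max = NULL) {
  if (!all(is.finite(c(tau_u, tau_m, k, dt))) ||
      tau_u <= 0 || tau_m <= 0 || k <= 0 || dt <= 0) {
    stop("tau_u, tau_m, k and dt must be positive", call. = FALSE)
  }
  b <- 1 / (2 * tau_u)
  disc <- b^2 - k / (tau_u * tau_m)
  # slowest relaxation rate sets the characteristic timescale
  tau_K <- if (disc > 0) 1 / (b - sqrt(disc)) else 1 / b
  if (is.null(t_max)) t_max <- 8 * tau_K
  if (t_max <= 0) stop("t_max must be positive", call. = FALSE)
  t <- seq(0, t_max, by = dt)
  vals <- if (abs(disc) < 1e-14 / tau_u^2) {
    exp(-b * t) * (1 - b * t)
  } else if (disc > 0) {
    w <- sqrt(disc)
    exp(-b * t) * (cosh(w * t) - (b / w) * sinh(w * t))
  } else {
    w <- sqrt(-disc)
    exp(-b * t) * (cos(w * t) - (b / w) * sin(w * t))
  }
  memory_kernel(t, vals, tau_K = tau_K, family = "feedback",
                params = list(tau_u = tau_u, tau_m = tau_m, k = k))
}

#' Single-period sinusoidal memory kernel
#'
#' \eqn{K(t) = \sin(2\pi t/\tau_K)} for \eqn{0 \le t \le \tau_K} and zero
#' elsewhere: a compact-support, non-monotonic, exactly zero-area kernel.
#' This is the kernel family used by the layered-network trainer.
#'
#' @param tau_K Kernel period (support length, > dt).
#' @param dt Sampling step.
#' @param unit_gain If `TRUE`, rescale so the derivative gain
#'   \eqn{-\int t K dt = 1} (the raw sine has gain \eqn{\tau_K^2/(2\pi)}),
#'   making the convolution approximate \eqn{\dot s} with unit prefactor.
#'
#' @return A [memory_kernel()] with `family = "sine"`.
#' @export
make_sine_kernel <- function(tau_K, dt, unit_gain = FALSE) {
  if (!all(is.finite(c(tau_K, dt))) || dt <= 0 || tau_K <= dt) {
    stop("need tau_K > dt > 0", call. = FALSE)
  }
  t <- seq(0, tau_K, by = dt)
  vals <- sin(2 * pi * t / tau_K)
  if (unit_gain) {
    m1 <- -pracma::trapz(t, t * vals)
    vals <- vals / m1
  }
  memory_kernel(t, vals, tau_K = tau_K, family = "sine",
                params = list(tau_K = tau_K, unit_gain = unit_gain))
}

#' Biphasic exponential-polynomial memory kernel
#'
#' The minimal sign-changing kernel family
#' \eqn{K(t) = e^{-t/\tau_K}(c_0 + c_1 t)}: a decaying exponential times a
#' degree-1 polynomial. The two coefficients are solved exactly on the
#' quadrature grid from two linear constraints: the trapezoidal area equals
#' `target_area`, and the derivative gain \eqn{-\int t K dt} equals 1, so
#' that in the derivative-operator regime the convolution returns
#' \eqn{\dot s} with unit prefactor and the per-cycle weight update recovers
#' the contrastive amplitude directly. `target_area = 0` gives the canonical
#' non-monotonic kernel (continuous-time relation \eqn{c_1 = -c_0/\tau_K},
#' one sign change at \eqn{t \approx \tau_K}).
#'
#' @param tau_K Decay timescale of the exponential envelope.
#' @param target_area Desired kernel area \eqn{I} (dimensionless); 0 for the
#'   canonical adapted kernel.
#' @param dt Sampling step.
#' @param t_max Support; must be at least `5 * tau_K` so the exponential tail
#'   is captured. Default `10 * tau_K`.
#'
#' @return A [memory_kernel()] with `family = "biphasic"`. Its `area` matches
#'   `target_area` to machine precision by construction.
#' @export
make_biphasic_kernel <- function(tau_K, target_area = 0, dt = tau_K / 50,
                                 t_max = 10 * tau_K) {
  if (!all(is.finite(c(tau_K, target_area, dt, t_max))) ||
      tau_K <= 0 || dt <= 0) {
    stop("tau_K and dt must be positive", call. = FALSE)
  }
  if (t_max < 5 * tau_K) {
    stop("t_max must be at least 5 * tau_K to capture the tail", call. = FALSE)
  }
  t <- seq(0, t_max, by = dt)
  e <- exp(-t / tau_K)
  # grid moments of the two basis functions e^{-t/tau} and t e^{-t/tau}
  T0 <- pracma::trapz(t, e)
  T1 <- pracma::trapz(t, t * e)
  T2 <- pracma::trapz(t, t^2 * e)
  A <- rbind(c(T0, T1), c(-T1, -T2))
  rhs <- c(target_area, 1)
  if (abs(det(A)) < 1e-14 * tau_K^4) {
    stop("infeasible kernel normalization: constraint system is singular",
         call. = FALSE)
  }
  cf <- solve(A, rhs)
  vals <- e * (cf[1] + cf[2] * t)
  memory_kernel(t, vals, tau_K = tau_K, family = "biphasic",
                params = list(tau_K = tau_K, target_area = target_area,
                              c0 = cf[1], c1 = cf[2]))
}

#' Kernel area (trapezoidal quadrature)
#'
#' The integrated area \eqn{I = \int_0^\infty K(t) dt} of a sampled kernel.
#' Zero-area kernels have zero response to constant signals (perfect
#' adaptation); non-zero area produces an offset in the contrastive update
#' proportional to the mean signal.
#'
#' @param kernel A [memory_kernel()].
#' @return The trapezoidal quadrature of the samples (dimensionless).
#' @export
kernel_area <- function(kernel) {
  stopifnot(inherits(kernel, "memory_kernel"))
  pracma::trapz(kernel$t, kernel$values)
}

# Fast internal causal convolution. Returns a numeric vector the length of
# `signal`; the first (n_k - 1) entries are NA (warm-up: the kernel support
# has not yet filled with signal history). Trapezoid end-weights make the DC
# gain equal the trapezoidal kernel area exactly.
.convolve_raw <- function(kernel, signal) {
  w <- kernel$values * kernel$dt
  n_k <- length(w)
  w[1] <- w[1] / 2
  w[n_k] <- w[n_k] / 2
  as.numeric(stats::filter(signal, w, method = "convolution", sides = 1))
}

#' Convolve a memory kernel with a sampled signal
#'
#' Causal discrete convolution \eqn{u(t) = \int_0^{t_{max}} K(\tau)
#' s(t-\tau) d\tau} evaluated by trapezoidal quadrature on the shared grid.
#' The first `t_max` of output (one kernel support) is warm-up: the history
#' window is incomplete there and the values are marked invalid.
#'
#' @param kernel A [memory_kernel()].
#' @param signal Numeric vector, uniformly sampled at `dt`.
#' @param dt Sampling step of `signal`; must equal the kernel's `dt` unless
#'   `resample = TRUE`, in which case the kernel is linearly resampled.
#' @param resample Allow resampling the kernel onto the signal grid.
#'
#' @return A tibble with columns `t`, `s`, `u` and logical `warmup`; `u` is
#'   `NA` where `warmup` is `TRUE`.
#' @export
convolve_kernel <- function(kernel, signal, dt = kernel$dt, resample = FALSE) {
  stopifnot(inherits(kernel, "memory_kernel"), is.numeric(signal))
  if (abs(dt - kernel$dt) > 1e-9 * kernel$dt) {
    if (!resample) {
      stop("signal dt does not match kernel dt (set resample = TRUE)",
           call. = FALSE)
    }
    t_new <- seq(0, kernel$t_max, by = dt)
    kernel <- memory_kernel(
      t_new,
      stats::approx(kernel$t, kernel$values, xout = t_new, rule = 2)$y,
      tau_K = kernel$tau_K, family = kernel$family, params = kernel$params
    )
  }
  if (length(signal) <= length(kernel$values)) {
    stop("signal must be longer than the kernel support", call. = FALSE)
  }
  u <- .convolve_raw(kernel, signal)
  t <- (seq_along(signal) - 1) * dt
  tibble::tibble(t = t, s = signal, u = u, warmup = is.na(u) | t < kernel$t_max)
}

#' Write / read a kernel as a two-column CSV
#'
#' Serializes the sampled kernel to a CSV with columns `t` and `K`
#' (`write_kernel_csv`), or reads one back (`read_kernel_csv`). Metadata
#' (timescale, family) travels separately via [kernel_params_json()].
#'
#' @param kernel A [memory_kernel()].
#' @param path File path.
#' @param tau_K Timescale to attach on read (defaults to the time of the
#'   absolute sample maximum, a crude but serviceable estimate).
#' @return `write_kernel_csv` returns `path` invisibly; `read_kernel_csv`
#'   returns a [memory_kernel()].
#' @export
write_kernel_csv <- function(kernel, path) {
  stopifnot(inherits(kernel, "memory_kernel"))
  readr::write_csv(tibble::tibble(t = kernel$t, K = kernel$values), path)
  invisible(path)
}

#' @rdname write_kernel_csv
#' @export
read_kernel_csv <- function(path, tau_K = NULL) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  if (!all(c("t", "K") %in% names(df))) {
    stop("kernel CSV must have columns t and K", call. = FALSE)
  }
  if (is.null(tau_K)) {
    tau_K <- max(df$t[which.max(abs(df$K))], df$t[2])
  }
  memory_kernel(df$t, df$K, tau_K = tau_K, family = "csv")
}

#' JSON parameter descriptor for a kernel
#'
#' Round-trippable JSON description of a kernel's generating family and
#' parameters. `kernel_from_json()` rebuilds the kernel by calling the
#' matching constructor (only generated families can be rebuilt).
#'
#' @param kernel A [memory_kernel()].
#' @param dt,t_max Grid to use when rebuilding.
#' @return `kernel_params_json` returns a JSON string; `kernel_from_json`
#'   a [memory_kernel()].
#' @export
kernel_params_json <- function(kernel) {
  stopifnot(inherits(kernel, "memory_kernel"))
  jsonlite::toJSON(
    c(list(family = kernel$family, dt = kernel$dt, t_max = kernel$t_max),
      kernel$params),
    auto_unbox = TRUE, digits = NA
  )
}

#' @rdname kernel_params_json
#' @param json JSON string produced by `kernel_params_json()`.
#' @export
kernel_from_json <- function(json, dt = NULL, t_max = NULL) {
  p <- jsonlite::fromJSON(json)
  dt <- dt %||% p$dt
  t_max <- t_max %||% p$t_max
  switch(
    p$family,
    feedback = make_feedback_kernel(p$tau_u, p$tau_m, p$k, dt = dt,
                                    t_max = t_max),
    sine = make_sine_kernel(p$tau_K, dt = dt,
                            unit_gain = isTRUE(p$unit_gain)),
    biphasic = make_biphasic_kernel(p$tau_K, p$target_area, dt = dt,
                                    t_max = t_max),
    stop("cannot rebuild kernel family '", p$family, "' from parameters",
         call. = FALSE)
  )
}

#' @export
#' @method autoplot memory_kernel
#' @importFrom ggplot2 autoplot
autoplot.memory_kernel <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$t, y = .data$K)) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed", colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "t", y = "K(t)",
      title = sprintf("%s kernel (tau_K = %g, area = %.3g)",
                      object$family, object$tau_K, object$area)
    )
}

#' @export
#' @method glance memory_kernel
#' @importFrom generics glance
glance.memory_kernel <- function(x, ...) {
  tibble::tibble(
    family = x$family,
    tau_K = x$tau_K,
    dt = x$dt,
    t_max = x$t_max,
    n = length(x$values),
    area = x$area,
    moment1 = x$moment1,
    l1_norm = pracma::trapz(x$t, abs(x$values))
  )
}
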