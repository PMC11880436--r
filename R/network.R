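# Energy-based layered network trained by Temporal Contrastive Learning.
# Nodes carry internal state x with activation eta(x) = clip(x, 0, 1);
# symmetric weights couple adjacent layers only. Training drives the output
# nodes with a sawtooth nudge beta(t) toward the one-hot label; each synapse
# then updates from the kernel-convolved, thresholded trace of its own
# synaptic current eta_n * eta_m.

#' Layered energy network
#'
#' Builds an input/hidden/output network with symmetric couplings between
#' adjacent layers (no lateral or skip connections), biases on the free
#' (hidden and output) nodes, and activation \eqn{\eta(x)} = clip(x, 0, 1).
#' The network state minimizes the Hopfield-like energy
#' \deqn{E(x) = \tfrac12\sum_n x_n^2 - \tfrac12\sum_{n,m} w_{nm}\eta_n\eta_m
#'   - \sum_n b_n \eta_n,}
#' where the double sum runs over ordered pairs (each undirected edge counted
#' twice). Weights initialize zero-mean uniform scaled by 1/sqrt(fan-in).
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param seed Integer seed for the weight initialization.
#' @param init_scale Multiplier on the 1/sqrt(fan-in) initialization width.
#'
#' @return An object of class `energy_network`: list with weight matrices
#'   `w1` (`n_in x n_hidden`), `w2` (`n_hidden x n_out`) and biases `b_h`,
#'   `b_o`.
#' @export
energy_network <- function(n_in, n_hidden, n_out, seed = 1L, init_scale = 1) {
  stopifnot(n_in >= 1, n_hidden >= 1, n_out >= 1)
  draw <- .with_seed(seed, {
    list(
      w1 = matrix(stats::runif(n_in * n_hidden, -1, 1) / sqrt(n_in) * init_scale,
                  n_in, n_hidden),
      w2 = matrix(stats::runif(n_hidden * n_out, -1, 1) / sqrt(n_hidden) * init_scale,
                  n_hidden, n_out)
    )
  })
  structure(
    list(n_in = as.integer(n_in), n_hidden = as.integer(n_hidden),
         n_out = as.integer(n_out),
         w1 = draw$w1, w2 = draw$w2,
         b_h = rep(0, n_hidden), b_o = rep(0, n_out)),
    class = "energy_network"
  )
}

# evaluate a block with a local RNG state, restoring the caller's stream
.with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

#' @export
print.energy_network <- function(x, ...) {
  cat(sprintf("<energy_network> %d-%d-%d, %d weights + %d biases\n",
              x$n_in, x$n_hidden, x$n_out,
              length(x$w1) + length(x$w2), length(x$b_h) + length(x$b_o)))
  invisible(x)
}

.eta <- function(x) pmin(pmax(x, 0), 1)

#' Network energy
#'
#' Evaluates \eqn{E(x)} for a full state assignment. The coupling sum runs
#' over ordered node pairs, so each undirected edge contributes
#' \eqn{-w_{nm}\eta_n\eta_m} once after the 1/2 prefactor.
#'
#' @param net An [energy_network()].
#' @param states List with numeric `input`, `hidden`, `output` state vectors.
#' @return The scalar energy.
#' @export
network_energy <- function(net, states) {
  stopifnot(inherits(net, "energy_network"))
  if (length(states$input) != net$n_in ||
      length(states$hidden) != net$n_hidden ||
      length(states$output) != net$n_out) {
    stop("state sizes do not match the network", call. = FALSE)
  }
  x <- c(states$input, states$hidden, states$output)
  e_in <- .eta(states$input); e_h <- .eta(states$hidden)
  e_o <- .eta(states$output)
  sum(x^2) / 2 -
    sum(e_in * (net$w1 %*% e_h)) -
    sum(e_h * (net$w2 %*% e_o)) -
    sum(net$b_h * e_h) - sum(net$b_o * e_o)
}

#' Nudged energy
#'
#' \eqn{F = E + (\beta/2)\sum_o (x_o - v_o)^2}: the training objective that
#' softly pulls the output states toward the one-hot label with nudge
#' strength \eqn{\beta}.
#'
#' @inheritParams network_energy
#' @param label_onehot One-hot target vector for the output layer.
#' @param beta Nudge strength (>= 0).
#' @return The scalar nudged energy.
#' @export
nudged_energy <- function(net, states, label_onehot, beta) {
  stopifnot(beta >= 0, length(label_onehot) == net$n_out)
  network_energy(net, states) +
    beta / 2 * sum((states$output - label_onehot)^2)
}

#' Relax the free nodes to an energy minimum
#'
#' Damped synchronous fixed-point iteration on the hidden and output states
#' with the inputs clamped: each free node moves a fraction `lambda` toward
#' its conditional minimizer given its neighbors (which coincides with
#' gradient descent on \eqn{F} in the interior of the clip domain and
#' handles the clip boundaries without chatter). Iterates until the largest
#' state change is below `tol` or `max_iter` is reached.
#'
#' @param net An [energy_network()].
#' @param input Clamped input state vector (length `n_in`).
#' @param label_onehot One-hot label, used when `beta > 0`.
#' @param beta Nudge strength.
#' @param x_init Optional warm-start list with `hidden`, `output`.
#' @param lambda Damping factor in (0, 1].
#' @param tol Convergence tolerance on the max state change.
#' @param max_iter Iteration cap; non-convergence is flagged, not fatal.
#'
#' @return List with `hidden`, `output` state vectors, `converged` flag and
#'   `iterations` used.
#' @export
relax <- function(net, input, label_onehot = NULL, beta = 0, x_init = NULL,
                  lambda = 0.5, tol = 1e-6, max_iter = 2000L) {
  stopifnot(inherits(net, "energy_network"), length(input) == net$n_in)
  if (beta > 0 && is.null(label_onehot)) {
    stop("label_onehot required when beta > 0", call. = FALSE)
  }
  e_in <- .eta(input)
  x_h <- x_init$hidden %||% rep(0, net$n_hidden)
  x_o <- x_init$output %||% rep(0, net$n_out)
  drive_in <- crossprod(net$w1, e_in)  # constant over the relaxation
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    e_h <- .eta(x_h); e_o <- .eta(x_o)
    tgt_h <- .eta(drive_in + net$w2 %*% e_o + net$b_h)
    tgt_o <- if (beta > 0) {
      .eta((crossprod(net$w2, e_h) + net$b_o + beta * label_onehot) / (1 + beta))
    } else {
      .eta(crossprod(net$w2, e_h) + net$b_o)
    }
    d_h <- lambda * (tgt_h - x_h)
    d_o <- lambda * (tgt_o - x_o)
    x_h <- x_h + d_h
    x_o <- x_o + d_o
    if (max(abs(d_h), abs(d_o)) < tol) {
      converged <- TRUE
      break
    }
  }
  list(hidden = as.numeric(x_h), output = as.numeric(x_o),
       converged = converged, iterations = it)
}

#' Classify an input
#'
#' Relaxes the network at \eqn{\beta = 0} and returns the index of the
#' maximally activated output node (1-based; exact ties break to the lowest
#' index).
#'
#' @param net An [energy_network()].
#' @param input Input state vector.
#' @param ... Passed to [relax()].
#' @return Integer class index in `1:n_out`.
#' @export
infer <- function(net, input, ...) {
  st <- relax(net, input, beta = 0, ...)
  which.max(st$output)
}

#' @export
predict.energy_network <- function(object, newdata, ...) {
  stopifnot(is.matrix(newdata), ncol(newdata) == object$n_in)
  purrr::map_int(seq_len(nrow(newdata)),
                 function(i) as.integer(infer(object, newdata[i, ], ...)))
}

#' Sawtooth nudge schedule
#'
#' Discretization of the training protocol \eqn{\beta(t)}: a sawtooth that
#' rises 0 to `beta_max` over `tau_f` and falls back over `tau_s`. A fixed
#' fraction of the relaxation steps is allocated to the fast ramp (denser
#' per unit time), since that segment carries the contrastive signal.
#'
#' @param beta_max Peak nudge strength, in (0, 1).
#' @param tau_f,tau_s Fast and slow protocol timescales.
#' @param steps_per_cycle Relaxation points per sawtooth cycle.
#' @param fast_frac Fraction of steps on the fast ramp.
#' @param cycles_per_example Sawtooth cycles presented per training example.
#' @param relax_tol,relax_max_iter,lambda Relaxation controls (see [relax()]).
#' @return An object of class `nudge_schedule` with the step times `times`
#'   (in `[0, period)`) and nudge values `betas`.
#' @export
nudge_schedule <- function(beta_max = 0.5, tau_f = 0.1, tau_s = 0.9,
                           steps_per_cycle = 60L, fast_frac = 0.4,
                           cycles_per_example = 1L,
                           relax_tol = 1e-6, relax_max_iter = 2000L,
                           lambda = 0.5) {
  if (beta_max <= 0 || beta_max >= 1) {
    stop("beta_max must lie in (0, 1)", call. = FALSE)
  }
  n_f <- max(6L, round(fast_frac * steps_per_cycle))
  n_s <- max(6L, steps_per_cycle - n_f)
  t_fast <- seq(0, tau_f, length.out = n_f + 1L)
  t_slow <- seq(tau_f, tau_f + tau_s, length.out = n_s + 1L)
  times <- c(t_fast, t_slow[-1L])
  times <- times[-length(times)]  # t = period aliases t = 0 of the next cycle
  betas <- ifelse(times <= tau_f,
                  beta_max * times / tau_f,
                  beta_max * (1 - (times - tau_f) / tau_s))
  structure(
    list(beta_max = beta_max, tau_f = tau_f, tau_s = tau_s,
         period = tau_f + tau_s, times = times, betas = betas,
         cycles_per_example = as.integer(cycles_per_example),
         relax_tol = relax_tol, relax_max_iter = as.integer(relax_max_iter),
         lambda = lambda),
    class = "nudge_schedule"
  )
}

# synaptic-current layout: columns are w1 edges (column-major), w2 edges,
# hidden biases, output biases (biases read a constant-ON unit, eta = 1)
.syn_layout <- function(net) {
  n1 <- net$n_in * net$n_hidden
  n2 <- net$n_hidden * net$n_out
  list(
    w1 = seq_len(n1),
    w2 = n1 + seq_len(n2),
    b_h = n1 + n2 + seq_len(net$n_hidden),
    b_o = n1 + n2 + net$n_hidden + seq_len(net$n_out),
    total = n1 + n2 + net$n_hidden + net$n_out
  )
}

.syn_currents <- function(net, e_in, e_h, e_o) {
  c(as.numeric(outer(e_in, e_h)), as.numeric(outer(e_h, e_o)), e_h, e_o)
}

#' Record per-synapse current traces over one nudge cycle
#'
#' Steps \eqn{\beta} through one sawtooth cycle; at each step the free nodes
#' relax (warm-started from the previous step, quasi-static drive) and the
#' synaptic current \eqn{s_{nm} = \eta_n \eta_m} of every synapse (and
#' \eqn{s_n = \eta_n} for every bias) is recorded.
#'
#' @param net An [energy_network()].
#' @param input Clamped input vector.
#' @param label_onehot One-hot label driving the nudge.
#' @param schedule A [nudge_schedule()].
#' @return List with `times` (within-cycle times), matrix `s` (steps x
#'   synapses), the free-state relaxation `free`, a `layout` describing the
#'   columns, and `converged` (all relaxations converged).
#' @export
record_protocol <- function(net, input, label_onehot, schedule) {
  stopifnot(inherits(schedule, "nudge_schedule"))
  lay <- .syn_layout(net)
  n_t <- length(schedule$times)
  S <- matrix(NA_real_, n_t, lay$total)
  free <- relax(net, input, beta = 0, lambda = schedule$lambda,
                tol = schedule$relax_tol, max_iter = schedule$relax_max_iter)
  st <- free
  all_conv <- free$converged
  e_in <- .eta(input)
  for (j in seq_len(n_t)) {
    st <- relax(net, input, label_onehot, beta = schedule$betas[j],
                x_init = st, lambda = schedule$lambda,
                tol = schedule$relax_tol, max_iter = schedule$relax_max_iter)
    all_conv <- all_conv && st$converged
    S[j, ] <- .syn_currents(net, e_in, .eta(st$hidden), .eta(st$output))
  }
  list(times = schedule$times, s = S, free = free, layout = lay,
       period = schedule$period, converged = all_conv)
}

# Periodic piecewise-linear resampling of the recorded traces onto the
# kernel grid: interpolation weights are shared across synapses, so the
# resampling is a pair of matrix operations.
.resample_traces <- function(rec, dt) {
  tt <- c(rec$times, rec$period)          # close the cycle
  S <- rbind(rec$s, rec$s[1L, ])
  t_fine <- seq(0, rec$period - dt / 2, by = dt)
  j <- findInterval(t_fine, tt, rightmost.closed = TRUE)
  alpha <- (t_fine - tt[j]) / (tt[j + 1L] - tt[j])
  S[j, , drop = FALSE] * (1 - alpha) + S[j + 1L, , drop = FALSE] * alpha
}

#' Apply one TCL update from recorded traces
#'
#' For every synapse: tile the recorded periodic current trace over warm-up
#' cycles plus one measured cycle, convolve with the synapse kernel,
#' threshold, and integrate over the measured cycle
#' (\eqn{\Delta w = \epsilon\int g(K * s) dt}). The single shared increment
#' per undirected edge keeps the couplings exactly symmetric; biases update
#' through the same rule with \eqn{s_n = \eta_n}.
#'
#' @param net An [energy_network()].
#' @param rec Traces from [record_protocol()].
#' @param config A [synapse_config()]; `theta_layers` can override its
#'   threshold per group.
#' @param theta_layers Optional named list with thresholds `w1`, `w2`, `b`
#'   (layer-dependent nonlinearity); defaults to `config$theta_g` for all.
#' @param n_warmup Warm-up cycles before the measured one.
#' @return The updated network, with the increment vector attached as
#'   attribute `"delta"` (layout order of [record_protocol()]).
#' @export
tcl_update <- function(net, rec, config, theta_layers = NULL, n_warmup = 2L) {
  stopifnot(inherits(config, "synapse_config"))
  kernel <- config$kernel
  dt <- kernel$dt
  if (kernel$t_max > n_warmup * rec$period) {
    stop("kernel support exceeds the warm-up cycles", call. = FALSE)
  }
  S1 <- .resample_traces(rec, dt)
  n_per <- nrow(S1)
  S <- do.call(rbind, c(rep(list(S1), n_warmup + 1L),
                        list(S1[1L, , drop = FALSE])))
  w <- kernel$values * dt
  w[1] <- w[1] / 2
  w[length(w)] <- w[length(w)] / 2
  U <- stats::filter(S, w, method = "convolution", sides = 1)
  idx <- (n_warmup * n_per + 1L):nrow(S)
  U <- as.matrix(unclass(U))[idx, , drop = FALSE]
  lay <- rec$layout
  th <- rep(config$theta_g, lay$total)
  if (!is.null(theta_layers)) {
    if (!is.null(theta_layers$w1)) th[lay$w1] <- theta_layers$w1
    if (!is.null(theta_layers$w2)) th[lay$w2] <- theta_layers$w2
    if (!is.null(theta_layers$b)) th[c(lay$b_h, lay$b_o)] <- theta_layers$b
  }
  G <- U * (abs(U) >= rep(th, each = nrow(U)))
  wts <- rep(dt, nrow(G)); wts[1] <- dt / 2; wts[length(wts)] <- dt / 2
  delta <- config$epsilon * as.numeric(crossprod(G, wts))
  net$w1 <- net$w1 + matrix(delta[lay$w1], net$n_in, net$n_hidden)
  net$w2 <- net$w2 + matrix(delta[lay$w2], net$n_hidden, net$n_out)
  net$b_h <- net$b_h + delta[lay$b_h]
  net$b_o <- net$b_o + delta[lay$b_o]
  attr(net, "delta") <- delta
  net
}

#' Explicit Equilibrium-Propagation reference update
#'
#' The two-phase contrastive increment
#' \eqn{\Delta w_{nm} = \epsilon(s^{nudge}_{nm} - s^{free}_{nm})} computed
#' from explicit free (\eqn{\beta = 0}) and nudged (\eqn{\beta =
#' \beta_{max}}) relaxations. Returned, not applied: it is the reference
#' the implicit TCL update is validated against.
#'
#' @param net An [energy_network()].
#' @param input Clamped input vector.
#' @param label_onehot One-hot label.
#' @param beta_max Nudge strength of the clamped phase.
#' @param epsilon Learning rate.
#' @param ... Passed to [relax()].
#' @return Numeric increment vector in the layout of [record_protocol()].
#' @export
ep_reference_update <- function(net, input, label_onehot, beta_max,
                                epsilon = 1, ...) {
  e_in <- .eta(input)
  free <- relax(net, input, beta = 0, ...)
  nudged <- relax(net, input, label_onehot, beta = beta_max, x_init = free, ...)
  s_free <- .syn_currents(net, e_in, .eta(free$hidden), .eta(free$output))
  s_nudge <- .syn_currents(net, e_in, .eta(nudged$hidden), .eta(nudged$output))
  epsilon * (s_nudge - s_free)
}

#' Train a network by Temporal Contrastive Learning
#'
#' Loops over examples and epochs; for each example the nudge sawtooth runs
#' `cycles_per_example` cycles and each cycle's recorded traces produce one
#' TCL weight update. Train (and optionally test) classification error is
#' logged per epoch. Fully deterministic given `seed` (which only controls
#' the example shuffling).
#'
#' @param net An [energy_network()].
#' @param train List with matrix `x` (examples x features) and integer
#'   labels `y` in `1:n_out` (see [task_matrices()]).
#' @param schedule A [nudge_schedule()].
#' @param config A [synapse_config()] (its `epsilon` is the learning rate).
#' @param epochs Maximum training epochs.
#' @param seed Integer seed for example shuffling.
#' @param test Optional held-out list like `train`.
#' @param theta_layers Optional per-layer thresholds (see [tcl_update()]).
#' @param shuffle Reshuffle examples each epoch.
#' @param stop_at_zero Stop once the training error reaches 0.
#'
#' @return An object of class `tcl_fit`: list with the trained `net`, a
#'   per-epoch `metrics` tibble (`epoch`, `train_error`, `test_error`),
#'   `epochs_run` and the configuration objects. [tidy()] returns the error
#'   curve, [glance()] the one-row summary.
#' @export
train_tcl <- function(net, train, schedule, config, epochs = 20L, seed = 1L,
                      test = NULL, theta_layers = NULL, shuffle = TRUE,
                      stop_at_zero = TRUE) {
  stopifnot(is.matrix(train$x), length(train$y) == nrow(train$x))
  n <- nrow(train$x)
  onehots <- diag(net$n_out)
  err <- function(d) {
    if (is.null(d)) return(NA_real_)
    pred <- predict(net, d$x, lambda = schedule$lambda,
                    tol = schedule$relax_tol,
                    max_iter = schedule$relax_max_iter)
    mean(pred != d$y)
  }
  metrics <- vector("list", epochs)
  orders <- .with_seed(seed, {
    lapply(seq_len(epochs), function(e) if (shuffle) sample.int(n) else seq_len(n))
  })
  epochs_run <- 0L
  for (e in seq_len(epochs)) {
    for (i in orders[[e]]) {
      v <- onehots[train$y[i], ]
      for (cyc in seq_len(schedule$cycles_per_example)) {
        rec <- record_protocol(net, train$x[i, ], v, schedule)
        net <- tcl_update(net, rec, config, theta_layers = theta_layers)
      }
    }
    epochs_run <- e
    tr_err <- err(train)
    te_err <- err(test)
    metrics[[e]] <- tibble::tibble(epoch = e, train_error = tr_err,
                                   test_error = te_err)
    if (stop_at_zero && tr_err == 0) break
  }
  structure(
    list(net = net, metrics = dplyr::bind_rows(metrics[seq_len(epochs_run)]),
         epochs_run = epochs_run, schedule = schedule, config = config,
         seed = seed),
    class = "tcl_fit"
  )
}

#' @export
print.tcl_fit <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  cat(sprintf(
    "<tcl_fit> %d epoch(s); final train error %.3f%s\n",
    x$epochs_run, last$train_error,
    if (is.na(last$test_error)) "" else sprintf(", test error %.3f",
                                                last$test_error)))
  invisible(x)
}

#' @export
#' @method tidy tcl_fit
tidy.tcl_fit <- function(x, ...) {
  tidyr::pivot_longer(x$metrics, cols = c("train_error", "test_error"),
                      names_to = "set", values_to = "error") |>
    dplyr::mutate(set = sub("_error$", "", .data$set)) |>
    dplyr::filter(!is.na(.data$error))
}

#' @export
#' @method glance tcl_fit
glance.tcl_fit <- function(x, ...) {
  last <- x$metrics[nrow(x$metrics), ]
  tibble::tibble(
    epochs_run = x$epochs_run,
    final_train_error = last$train_error,
    final_test_error = last$test_error,
    reached_zero = last$train_error == 0
  )
}

#' @export
#' @method autoplot tcl_fit
autoplot.tcl_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$epoch, y = .data$error,
                               colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "epoch", y = "classification error",
                  title = "TCL training curve")
}

#' Cosine similarity between two update vectors
#'
#' Convenience metric for comparing a per-cycle TCL increment with the
#' explicit Equilibrium-Propagation reference on the same example.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Cosine of the angle between `a` and `b` (NA if either is zero).
#' @export
cosine_similarity <- function(a, b) {
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) return(NA_real_)
  sum(a * b) / (na * nb)
}
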