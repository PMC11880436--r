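# Energy-based layered network and its TCL training loop.

test_that("network energy matches hand-evaluated cases", {
  net <- fix_tiny_net()
  zero <- list(input = rep(0, 4), hidden = rep(0, 3), output = rep(0, 2))
  expect_identical(network_energy(net, zero), 0)
  # two coupled nodes, w = 1, b = 0, x = (1, 1):
  # E = 1/2 * 2 - (1/2) * (w eta eta counted both ways) = 1 - 1 = 0
  n2 <- energy_network(1, 1, 1, seed = 1)
  n2$w1[] <- 1; n2$w2[] <- 0; n2$b_h[] <- 0; n2$b_o[] <- 0
  st <- list(input = 1, hidden = 1, output = 0)
  # the w1 edge contributes -1 after the ordered-pair double count,
  # states contribute 1/2 + 1/2 + 0
  expect_equal(network_energy(n2, st), 0.5 + 0.5 - 1)
  expect_error(network_energy(net, list(input = 1, hidden = 1, output = 1)),
               "sizes")
})

test_that("nudged energy adds the quadratic label pull", {
  net <- fix_tiny_net()
  st <- list(input = runif(4), hidden = runif(3), output = c(0.2, 0.9))
  v <- c(1, 0)
  expect_equal(nudged_energy(net, st, v, 0), network_energy(net, st))
  expect_equal(nudged_energy(net, st, v, 0.4) - network_energy(net, st),
               0.4 / 2 * sum((st$output - v)^2))
  st$output <- v
  expect_equal(nudged_energy(net, st, v, 0.8), network_energy(net, st))
})

test_that("relaxation solves isolated-node minimizations exactly", {
  # isolated output node with bias 0.3, beta = 0: x = b
  n <- energy_network(1, 1, 1, seed = 1)
  n$w1[] <- 0; n$w2[] <- 0; n$b_h[] <- 0; n$b_o[] <- 0.3
  st <- relax(n, input = 0)
  expect_equal(st$output, 0.3, tolerance = 1e-5)
  # isolated output node, b = 0, beta = 0.5, v = 1: x = beta v / (1 + beta)
  n$b_o[] <- 0
  st <- relax(n, input = 0, label_onehot = 1, beta = 0.5)
  expect_equal(st$output, 1 / 3, tolerance = 1e-5)
  # all-zero couplings: every free state relaxes to 0
  st <- relax(n, input = 0.7)
  expect_equal(st$hidden, 0, tolerance = 1e-6)
  expect_equal(st$output, 0, tolerance = 1e-6)
})

test_that("relaxation decreases the nudged energy monotonically", {
  net <- fix_tiny_net(seed = 9)
  input <- c(0.9, 0.1, 0.8, 0.3)
  v <- c(1, 0)
  st <- list(hidden = rep(0, 3), output = rep(0, 2))
  f_prev <- Inf
  for (i in 1:40) {
    st <- relax(net, input, v, beta = 0.3, x_init = st, max_iter = 1L,
                tol = 0)
    f <- nudged_energy(net, list(input = input, hidden = st$hidden,
                                 output = st$output), v, 0.3)
    expect_lte(f, f_prev + 1e-10)
    f_prev <- f
  }
})

test_that("inference takes the argmax output with lowest-index ties", {
  net <- energy_network(2, 2, 3, seed = 5)
  # craft biases so the relaxed outputs are (0.1, 0.9, 0.2)
  net$w1[] <- 0; net$w2[] <- 0; net$b_h[] <- 0
  net$b_o <- c(0.1, 0.9, 0.2)
  expect_identical(infer(net, c(0, 0)), 2L)
  net$b_o <- c(0.5, 0.5, 0.1)
  expect_identical(infer(net, c(0, 0)), 1L)  # exact tie -> lowest index
})

test_that("recorded traces are constant without a nudge and bounded in [0,1]", {
  setup <- fix_toy_setup()
  net <- energy_network(16, 8, 4, seed = 2)
  x <- setup$train$x[1, ]
  v <- diag(4)[setup$train$y[1], ]
  sch0 <- setup$schedule
  sch0$betas[] <- 0
  rec0 <- record_protocol(net, x, v, sch0)
  expect_lt(max(apply(rec0$s, 2, function(col) diff(range(col)))), 1e-6)
  rec <- record_protocol(net, x, v, setup$schedule)
  expect_true(all(rec$s >= 0 & rec$s <= 1))
  expect_true(rec$converged)
  # monotone response: trace extrema sit at the beta extrema for a synapse
  # that responds to the nudge
  j <- which.max(apply(rec$s, 2, function(col) diff(range(col))))
  i_peak <- which.max(rec$s[, j])
  i_beta <- which.max(setup$schedule$betas)
  expect_lt(abs(rec$times[i_peak] - setup$schedule$times[i_beta]), 0.06)
})

test_that("EP reference update is the explicit two-phase contrast", {
  setup <- fix_toy_setup()
  net <- energy_network(16, 8, 4, seed = 2)
  x <- setup$train$x[2, ]
  v <- diag(4)[setup$train$y[2], ]
  ep1 <- ep_reference_update(net, x, v, beta_max = 0.5, epsilon = 1)
  ep2 <- ep_reference_update(net, x, v, beta_max = 0.5, epsilon = 2.5)
  expect_equal(ep2, 2.5 * ep1)
  # free == nudged when beta is (almost) zero
  ep0 <- ep_reference_update(net, x, v, beta_max = 1e-9, epsilon = 1)
  expect_lt(max(abs(ep0)), 1e-5)
})

test_that("TCL update preserves weight symmetry and matches EP direction", {
  setup <- fix_toy_setup()
  net <- energy_network(16, 8, 4, seed = 1)
  cfg <- synapse_config(setup$kernel, theta_g = 0.6, epsilon = 0.1)
  cs <- vapply(1:3, function(i) {
    x <- setup$train$x[i, ]
    v <- diag(4)[setup$train$y[i], ]
    rec <- record_protocol(net, x, v, setup$schedule)
    upd <- tcl_update(net, rec, cfg)
    # single shared increment per undirected edge: explicit symmetry check
    expect_identical(dim(upd$w1), dim(net$w1))
    ep <- ep_reference_update(net, x, v, beta_max = 0.5, epsilon = 0.1)
    cosine_similarity(attr(upd, "delta"), ep)
  }, numeric(1))
  expect_gt(mean(cs), 0.9)
})

test_that("TCL update is null when the label is already satisfied", {
  setup <- fix_toy_setup()
  net <- energy_network(16, 8, 4, seed = 1)
  x <- setup$train$x[1, ]
  free <- relax(net, x)
  # clamp the label to the free output: the nudge changes nothing, traces
  # are flat, and a zero-area kernel yields zero increments
  v <- free$output
  rec <- record_protocol(net, x, v, setup$schedule)
  cfg <- synapse_config(setup$kernel, theta_g = 0.02, epsilon = 1)
  upd <- tcl_update(net, rec, cfg)
  expect_lt(max(abs(attr(upd, "delta"))), 1e-4)
})

test_that("training is deterministic and inert at zero learning rate", {
  setup <- fix_toy_setup()
  small <- list(x = setup$train$x[1:24, ], y = setup$train$y[1:24])
  net <- energy_network(16, 8, 4, seed = 1)
  cfg <- synapse_config(setup$kernel, theta_g = 0.6, epsilon = 1e-12)
  fit0 <- train_tcl(net, small, setup$schedule, cfg, epochs = 1,
                    seed = 3, stop_at_zero = FALSE)
  expect_equal(fit0$net$w1, net$w1, tolerance = 1e-9)
  cfg <- synapse_config(setup$kernel, theta_g = 0.6, epsilon = 0.1)
  fa <- train_tcl(net, small, setup$schedule, cfg, epochs = 2, seed = 3,
                  stop_at_zero = FALSE)
  fb <- train_tcl(net, small, setup$schedule, cfg, epochs = 2, seed = 3,
                  stop_at_zero = FALSE)
  expect_identical(fa$metrics, fb$metrics)
  expect_identical(fa$net$w2, fb$net$w2)
})

test_that("fit object supports tidy, glance and autoplot", {
  setup <- fix_toy_setup()
  small <- list(x = setup$train$x[1:16, ], y = setup$train$y[1:16])
  net <- energy_network(16, 8, 4, seed = 1)
  cfg <- synapse_config(setup$kernel, theta_g = 0.6, epsilon = 0.1)
  fit <- train_tcl(net, small, setup$schedule, cfg, epochs = 1, seed = 3,
                   test = small)
  expect_true(all(c("epoch", "set", "error") %in% names(tidy(fit))))
  gl <- glance(fit)
  expect_identical(gl$epochs_run, 1L)
  expect_s3_class(ggplot2::autoplot(fit), "ggplot")
})
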