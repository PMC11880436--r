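# Ladder Markov chain: construction, master-equation dynamics, entropy
# production and kernel extraction.

test_that("equilibrium chain satisfies the Kolmogorov cycle criterion", {
  ch <- build_ladder(5, gamma = 1, s = 0.3)
  # product of forward over backward rates around every elementary square
  for (i in 1:4) {
    a <- ch$bottom[i]; b <- ch$bottom[i + 1]
    ta <- ch$top[i]; tb <- ch$top[i + 1]
    fwd <- ch$Q[a, b] * ch$Q[b, tb] * ch$Q[tb, ta] * ch$Q[ta, a]
    rev <- ch$Q[a, ta] * ch$Q[ta, tb] * ch$Q[tb, b] * ch$Q[b, a]
    expect_equal(fwd / rev, 1, tolerance = 1e-12)
  }
  # gamma < 1 breaks every square by the same affinity ln(gamma^-2)
  ch2 <- build_ladder(5, gamma = 0.4, s = 0.3)
  for (i in 1:4) {
    a <- ch2$bottom[i]; b <- ch2$bottom[i + 1]
    ta <- ch2$top[i]; tb <- ch2$top[i + 1]
    fwd <- ch2$Q[a, ta] * ch2$Q[ta, tb] * ch2$Q[tb, b] * ch2$Q[b, a]
    rev <- ch2$Q[a, b] * ch2$Q[b, tb] * ch2$Q[tb, ta] * ch2$Q[ta, a]
    expect_equal(fwd / rev, 1 / 0.4^2, tolerance = 1e-12)
  }
  expect_error(build_ladder(1), "at least 2")
  expect_error(build_ladder(5, gamma = 0), "gamma")
})

test_that("generator columns conserve probability", {
  ch <- build_ladder(4, gamma = 0.3, s = 0.5)
  expect_lt(max(abs(colSums(ch$G))), 1e-12)
  # off-diagonal entries match the rate table
  e <- ch$edges
  for (r in seq_len(nrow(e))) {
    expect_identical(ch$G[e$to[r], e$from[r]], e$rate_fwd[r])
  }
})

test_that("steady state is uniform for the fully symmetric equilibrium chain", {
  # gamma = 1 with no coupling: all rates equal in both directions
  ch <- build_ladder(5, gamma = 1, coupling_strength = 1e-12, s = 0)
  p <- steady_state(ch)
  expect_equal(p, rep(1 / 10, 10), tolerance = 1e-10)
  expect_equal(sum(steady_state(build_ladder(5, 0.2, s = 0.4))), 1)
})

test_that("propagation conserves and stays positive, converging to steady state", {
  ch <- build_ladder(5, gamma = 0.3, s = 0)
  p0 <- rep(c(0.15, 0.05), each = 5)
  traj <- propagate(ch, 0, dt = 0.05, T = 60, p0 = p0)
  P <- as.matrix(traj[, paste0("p", 1:10)])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P > -1e-10))
  expect_equal(as.numeric(P[nrow(P), ]), steady_state(ch), tolerance = 1e-8)
  expect_equal(traj$u, rowSums(P[, 6:10]))
})

test_that("entropy production is zero at detailed balance, positive otherwise", {
  ch1 <- build_ladder(5, gamma = 1, s = 0)
  expect_lt(abs(as.numeric(entropy_production(ch1, steady_state(ch1)))),
            1e-10)
  # detailed balance holds at gamma = 1 for any constant signal
  ch1s <- build_ladder(5, gamma = 1, s = 0.6)
  expect_lt(abs(as.numeric(entropy_production(ch1s, steady_state(ch1s)))),
            1e-10)
  ch05 <- build_ladder(5, gamma = 0.5, s = 0)
  sig <- entropy_production(ch05, steady_state(ch05))
  expect_gt(as.numeric(sig), 0)
  expect_equal(as.numeric(sig),
               attr(sig, "horizontal") + attr(sig, "vertical"))
  expect_error(entropy_production(ch05, c(rep(0, 5), rep(0.2, 5))),
               "occupancy")
})

test_that("entropy production is non-negative for arbitrary occupancies", {
  set.seed(21)
  for (i in 1:8) {
    ch <- build_ladder(sample(3:6, 1), gamma = runif(1, 0.05, 1),
                       s = runif(1, -0.5, 0.5),
                       vertical_rate = runif(1, 0.5, 3))
    p <- rexp(ch$n); p <- p / sum(p)
    expect_gte(as.numeric(entropy_production(ch, p)), 0)
  }
})

test_that("dissipation decreases monotonically with gamma", {
  sig <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(g) {
    ch <- build_ladder(5, gamma = g, s = 0)
    as.numeric(entropy_production(ch, steady_state(ch)))
  }, numeric(1))
  expect_true(all(diff(sig) < 0))
  expect_lt(sig[5], 1e-10)
})

test_that("rail output is a bounded occupancy sum", {
  ch <- build_ladder(5, gamma = 0.3, s = 0.2)
  expect_equal(ladder_output(ch, rep(0.1, 10)), 0.5)
  p <- steady_state(ch)
  expect_gte(ladder_output(ch, p), 0)
  expect_lte(ladder_output(ch, p), 1)
})

test_that("vertical circulation increases with the signal when driven", {
  for (g in c(0.2, 0.5)) {
    cv <- vapply(c(0, 0.3, 0.6), function(s) {
      vertical_circulation(build_ladder(5, gamma = g, s = s))
    }, numeric(1))
    expect_true(all(diff(cv) > 0))
  }
  # at equilibrium there are no stationary currents at all
  expect_equal(vertical_circulation(build_ladder(5, gamma = 1, s = 0.3)), 0,
               tolerance = 1e-12)
})

test_that("extracted kernel is monotone at equilibrium, biphasic when driven", {
  k1 <- extract_kernel(build_ladder(5, gamma = 1, s = 0), delta_s = 0.05,
                       dt = 0.05, T = 30)
  big1 <- abs(k1$values) > 1e-4 * max(abs(k1$values))
  expect_identical(sum(diff(sign(k1$values[big1])) != 0), 0L)
  k05 <- extract_kernel(build_ladder(5, gamma = 0.05, s = 0), delta_s = 0.05,
                        dt = 0.05, T = 30)
  big <- abs(k05$values) > 1e-4 * max(abs(k05$values))
  expect_identical(sum(diff(sign(k05$values[big])) != 0), 1L)
  # adaptation: the driven chain's response area is smaller
  expect_lt(abs(k05$area), abs(k1$area))
})

test_that("kernel extraction is in the linear-response regime", {
  ch <- build_ladder(5, gamma = 0.2, s = 0)
  k1 <- extract_kernel(ch, delta_s = 0.05, dt = 0.05, T = 30)
  k2 <- extract_kernel(ch, delta_s = 0.025, dt = 0.05, T = 30)
  expect_lt(max(abs(k1$values - k2$values)) / max(abs(k1$values)), 0.01)
})

test_that("kernel area shrinks monotonically as the drive strengthens", {
  areas <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(g) {
    abs(extract_kernel(build_ladder(5, gamma = g, s = 0), delta_s = 0.05,
                       dt = 0.05, T = 40)$area)
  }, numeric(1))
  expect_true(all(diff(areas) > 0))  # area grows with gamma
})

test_that("dissipation-offset curve is reproducible and monotone", {
  gammas <- c(0.05, 0.2, 1)
  c1 <- dissipation_offset_curve(gammas, tau_f = 30, tau_s = 300, dt = 0.1,
                                 amplitudes = exp(seq(log(0.05), log(0.4),
                                                      length.out = 8)))
  c2 <- dissipation_offset_curve(gammas, tau_f = 30, tau_s = 300, dt = 0.1,
                                 amplitudes = exp(seq(log(0.05), log(0.4),
                                                      length.out = 8)))
  expect_identical(c1$normalized_offset, c2$normalized_offset)
  ord <- order(c1$sigma)  # increasing dissipation
  expect_true(all(diff(c1$normalized_offset[ord]) < 0))
  expect_s3_class(ggplot2::autoplot(c1), "ggplot")
})
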