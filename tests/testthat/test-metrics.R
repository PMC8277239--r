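test_that("volley grouping follows the gap criterion", {
  sp <- data.frame(id = c(1, 2, 1), t = c(10, 10.5, 40))
  v <- detect_volleys(sp, period_hint = 25)
  expect_equal(nrow(v), 2)
  expect_equal(v$count, c(2, 1))
  expect_equal(v$t_first[1], 10)

  # both spikes of a double-spiking neuron belong to the cycle's volley
  sp2 <- data.frame(id = c(1, 2, 1), t = c(10, 10.5, 12))
  v2 <- detect_volleys(sp2, 25)
  expect_equal(nrow(v2), 1)
  expect_equal(v2$max_mult, 2)
  expect_equal(v2$n_neurons, 2)

  expect_equal(nrow(detect_volleys(sp[0, ], 25)), 0)
  expect_error(detect_volleys(sp, -1), "positive")
})

test_that("periodogram locates a pure tone within one bin", {
  t <- seq(0, 3000, by = 0.5)
  x <- sin(2 * pi * 40 * t / 1000)
  sp <- lfp_spectrum(t, x, transient = 500)
  expect_lt(abs(sp$f_dom - 40), sp$df)
  flat <- lfp_spectrum(t, rep(1, length(t)), transient = 500)
  expect_true(flat$flat)
  expect_true(is.na(flat$f_dom))
})

test_that("spectral peak and inter-volley interval agree for a clean rhythm", {
  net <- tiny_ing(cv = 0.1, n = 200)
  sim <- simulate_network(net, 2200)
  sp <- lfp_spectrum(sim$time, sim$lfp[, "I"], transient = 500)
  v <- detect_volleys(pop_spikes(sim, "I"), 1000 / sp$f_dom, t_min = 500)
  expect_lt(abs(sp$f_dom - volley_frequency(v)), sp$df)
})

test_that("phase dispersion is zero for synchrony and grows with heterogeneity", {
  sim0 <- simulate_network(tiny_ing(cv = 0, n = 60), 600)
  v0 <- detect_volleys(pop_spikes(sim0, "I"), 25, t_min = 200)
  expect_lt(phase_dispersion(v0), 1e-3)

  disp <- vapply(c(0.05, 0.1, 0.15), function(cv) {
    sim <- simulate_network(tiny_ing(cv = cv, n = 200), 900)
    v <- detect_volleys(pop_spikes(sim, "I"), 25, t_min = 300)
    phase_dispersion(v)
  }, 0)
  expect_true(all(diff(disp) > 0))
})
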