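test_that("Gaussian quantile biases are symmetric, ordered and recover the CV", {
  # degenerate and single-neuron cases
  expect_equal(gaussian_bias_quantiles(20.4, 0, 5), rep(20.4, 5))
  expect_equal(gaussian_bias_quantiles(7.3, 0.25, 1), 7.3)

  b <- gaussian_bias_quantiles(15.8, 0.1, 1001)
  expect_false(is.unsorted(b))
  # exact symmetry about the mean (quantile ranks are symmetric)
  expect_equal(mean(b), 15.8, tolerance = 1e-12)
  expect_equal(b + rev(b), rep(2 * 15.8, 1001))

  # moment recovery at large n
  b <- gaussian_bias_quantiles(15.8, 0.1, 10000)
  expect_equal(sd(b) / mean(b), 0.1, tolerance = 0.02)

  # deterministic: repeated calls bit-identical
  expect_identical(b, gaussian_bias_quantiles(15.8, 0.1, 10000))

  expect_error(gaussian_bias_quantiles(1, 5, 1000), "negative bias")
})

test_that("Lorentzian quantile drives hit the analytic quantiles", {
  expect_equal(lorentzian_bias_quantiles(20, 3, 5)[3], 20)
  # tan(+-pi/4) = +-1 gives center +- half-width at n = 3
  expect_equal(lorentzian_bias_quantiles(20, 3, 3), c(17, 20, 23))

  eta <- lorentzian_bias_quantiles(-5, 1, 5000)
  expect_false(is.unsorted(eta))
  # interquartile half-range equals the half-width
  iqr_half <- diff(quantile(eta, c(0.25, 0.75), names = FALSE)) / 2
  expect_equal(iqr_half, 1, tolerance = 0.02)

  # heavy tail: the extreme quantile grows without bound with n
  m <- vapply(c(101, 1001, 10001),
              function(n) max(lorentzian_bias_quantiles(0, 1, n)), 0)
  expect_true(all(diff(m) > 0))
  expect_gt(m[3] / m[1], 50)
})

test_that("random Gaussian bias draws are seeded, positive and recover the CV", {
  a <- gaussian_bias_sample(3.6, 0.167, 200, seed = 42)
  b <- gaussian_bias_sample(3.6, 0.167, 200, seed = 42)
  expect_identical(a, b)
  expect_true(all(a >= 0))
  expect_equal(gaussian_bias_sample(3.6, 0, 200, seed = 1), rep(3.6, 200))
  big <- gaussian_bias_sample(3.6, 0.167, 1e5, seed = 7)
  expect_equal(sd(big) / mean(big), 0.167, tolerance = 0.01)
  expect_error(gaussian_bias_sample(3.6, 0.1, 0, seed = 1), "positive")
})

test_that("clock trains are periodic and reject overlapping pulses", {
  tr <- clock_train(25, 100)
  expect_equal(tr$onsets, c(0, 25, 50, 75, 100))
  expect_error(clock_train(25, 100, duration = 30), "overlap")
})

test_that("synthesized clock train matches a homogeneous clock network", {
  # a cv = 0 ING network spikes perfectly synchronously; the conductance
  # train it would deliver equals the synthesized periodic train
  net <- tiny_ing(cv = 0, n = 50)
  sim <- simulate_network(net, 600)
  sp <- pop_spikes(sim, "I")
  v <- detect_volleys(sp, 25, t_min = 200)
  expect_true(all(v$t_last - v$t_first <= sim$dt))
  period <- mean(diff(v$t_first))
  tr <- clock_train(period, 300, t_first = 0)
  tgrid <- seq(0, 280, by = 0.05)
  w_net <- double_exp_waveform(tgrid, v$t_first - v$t_first[1] + 3, 6e-2,
                               0.5, 5)
  w_syn <- double_exp_waveform(tgrid, tr$onsets + 3, 6e-2, 0.5, 5)
  expect_lt(max(abs(w_net - w_syn)), 1e-3 * max(w_syn))
})
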