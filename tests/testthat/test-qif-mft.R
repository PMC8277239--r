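# Exact mean-field reduction: fixed points, limit cycles, adjoint imPRC,
# finite-amplitude PRCs on the reduced system.

ing_fixed_point <- function(p) {
  # stationary state: V = -Delta/(2 pi tau r); V^2 + eta - tau*J*r = (pi tau r)^2
  g <- function(r) {
    V <- -p$delta_i / (2 * pi * p$tau_i * r)
    V^2 + p$eta_i - p$tau_i * p$J_ii * r - (pi * p$tau_i * r)^2
  }
  r <- stats::uniroot(g, c(1e-6, 5), tol = 1e-14)$root
  V <- -p$delta_i / (2 * pi * p$tau_i * r)
  s1 <- p$tau1 * p$J_ii * r / (p$tau2 - p$tau1)
  s2 <- p$tau2 * p$J_ii * r / (p$tau2 - p$tau1)
  c(r = r, V = V, s1 = s1, s2 = s2)
}

test_that("the algebraic stationary state annihilates the vector field", {
  p <- mf_params("ING")
  fp <- ing_fixed_point(p)
  expect_lt(max(abs(mf_rhs(fp, p))), 1e-10)
})

test_that("the quiescent limit is recovered for weak heterogeneity and negative drive", {
  p <- mf_params("ING", eta_i = -4, delta_i = 1e-6, J_ii = 0.01)
  # V -> -sqrt(-eta), r -> 0
  g <- function(r) {
    V <- -p$delta_i / (2 * pi * p$tau_i * r)
    V^2 + p$eta_i - p$tau_i * p$J_ii * r - (pi * p$tau_i * r)^2
  }
  r <- stats::uniroot(g, c(1e-12, 1), tol = 1e-14)$root
  V <- -p$delta_i / (2 * pi * p$tau_i * r)
  expect_lt(r, 1e-3)
  expect_equal(V, -2, tolerance = 1e-3)
})

test_that("the reference parameters sustain a limit cycle with a reproducible period", {
  p <- mf_params("ING")
  lc <- find_limit_cycle(p)
  expect_gt(lc$period, 5); expect_lt(lc$period, 20)
  # doubling the integration tolerance moves the period by < 1e-4 T
  lc2 <- find_limit_cycle(p, rtol = 2e-8, atol = 2e-10)
  expect_lt(abs(lc2$period - lc$period), 1e-4 * lc$period)
  # anchor is the s-peak: s is maximal at phase 0
  s <- lc$states[, "s2"] - lc$states[, "s1"]
  expect_gte(s[1] + 1e-6, max(s) - 0.01 * diff(range(s)))
})

test_that("strong heterogeneity quenches the oscillation (Hopf side)", {
  p <- mf_params("PING", eta_i = -5, delta_e = 12, delta_i = 12)
  expect_error(find_limit_cycle(p), "non-oscillatory")
})

test_that("Hopf side agrees with the Jacobian spectrum at the fixed point", {
  for (delta in c(3, 9)) {
    p <- mf_params("ING", delta_i = delta, J_ii = 8)
    fp <- ing_fixed_point(p)
    lead <- max(Re(eigen(mf_jacobian(fp, p))$values))
    osc <- !inherits(tryCatch(find_limit_cycle(p), error = function(e) e),
                     "error")
    expect_equal(osc, lead > 0)
  }
})

test_that("adjoint normalization holds and the imPRC is type II", {
  p <- mf_params("ING")
  lc <- find_limit_cycle(p)
  im <- adjoint_imprc(lc)
  expect_lt(imprc_normalization_error(im, lc), 1e-6)
  expect_lt(min(im$V), 0)
  expect_gt(max(im$V), 0)
})

test_that("finite differences of the reduced-system fmPRC converge to the imPRC", {
  p <- mf_params("ING")
  lc <- find_limit_cycle(p)
  im <- adjoint_imprc(lc)
  phs <- c(0.3, 0.5)
  z_ref <- approx(im$phase, im$V, xout = phs)$y
  err <- vapply(c(0.05, 0.1, 0.2), function(dv) {
    fp <- emft_fmprc(lc, dv, phases = phs)
    fm <- emft_fmprc(lc, -dv, phases = phs)
    max(abs((fp$dphi - fm$dphi) / (2 * dv) - z_ref))
  }, 0)
  expect_true(all(err < 0.05 * max(abs(z_ref))))
})

test_that("perturbations change the within-network inhibition paradoxically", {
  p <- mf_params("ING")
  lc <- find_limit_cycle(p)
  ref <- emft_fmprc(lc, 1e-9, phases = 0.4, with_inhibition = TRUE)
  exc <- emft_fmprc(lc, 3, phases = 0.4, with_inhibition = TRUE)
  inh <- emft_fmprc(lc, -3, phases = 0.4, with_inhibition = TRUE)
  expect_gt(exc$inh_integral, ref$inh_integral)
  expect_lt(inh$inh_integral, ref$inh_integral)
})

test_that("the paradoxical imPRC component grows with heterogeneity", {
  maps <- regime_and_response_maps(data.frame(delta_i = c(1, 2, 3)),
                                   mf_params("ING"))
  expect_true(all(maps$label == "oscillatory"))
  expect_true(all(diff(maps$max_paradox_imprc) > 0))
  expect_true(all(maps$max_paradox_imprc > 0))
})

test_that("the PING reduction oscillates and its imPRC is paradoxical", {
  p <- mf_params("PING")
  lc <- find_limit_cycle(p)
  expect_gt(lc$period, 2)
  im <- adjoint_imprc(lc)
  expect_lt(imprc_normalization_error(im, lc), 1e-6)
  # voltage components of both populations change sign over the cycle
  expect_lt(min(im$VE), 0); expect_gt(max(im$VE), 0)
})
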