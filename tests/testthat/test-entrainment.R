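# Clock-forced runs, relative-phase series and synchronization typing on
# small networks.

test_that("zero clock weight leaves the network at its natural frequency", {
  net <- tiny_ing(cv = 0.1, n = 150)
  f_nat <- natural_frequency(net, t_sim = 1300)
  ent <- simulate_entrained(net, f_clock = f_nat + 6, W_ext = 0, t_end = 2500)
  cls <- classify_sync(ent$sim, ent$f_clock, ent$onsets, ent$tau_d)
  expect_equal(cls$f_dom, f_nat, tolerance = 0.03)
  expect_equal(cls$sync_type, 1L)
})

test_that("strong forcing at small detuning locks 1:1 (type 3)", {
  net <- tiny_ing(cv = 0.15, n = 150, mean_current = 13)
  f_nat <- natural_frequency(net, t_sim = 1300)
  ent <- simulate_entrained(net, f_clock = f_nat + 0.5, W_ext = 0.6,
                            n_source = 1, t_end = 3000)
  cls <- classify_sync(ent$sim, ent$f_clock, ent$onsets, ent$tau_d)
  expect_equal(cls$sync_type, 3L)
  expect_equal(cls$f_dom, ent$f_clock, tolerance = 0.03)
  expect_lte(cls$silent_fraction, 0.02)   # rare cycle-binning artifacts
  expect_lt(cls$var_phase, 1e-4)
  ph <- relative_phase_series(ent$sim, ent$onsets, ent$tau_d)
  obs <- ph$Phi[!ph$silent]
  expect_lt(max(obs) - min(obs), 0.02)
})

test_that("silent clock cycles carry the sentinel phase value 2", {
  # subthreshold network: never spikes, every cycle is silent
  net <- ing_network(mean_current = 1, cv = 0, n = 20)
  ent <- simulate_entrained(net, f_clock = 40, W_ext = 0, t_end = 1500)
  ph <- relative_phase_series(ent$sim, ent$onsets, ent$tau_d)
  expect_true(all(ph$silent))
  expect_true(all(ph$Phi == 2))
  cls <- classify_sync(ent$sim, ent$f_clock, ent$onsets, ent$tau_d)
  expect_equal(cls$silent_fraction, 1)
})

test_that("heterogeneity tightens phase locking across the desk-scale diagram", {
  # coarse two-by-two probe of the full diagram machinery
  pd <- phase_diagram(cv_grid = c(0.05, 0.15), df_grid = c(1, 3),
                      net_for = function(I, cv)
                        ing_network(I, cv, 150, W = 3e-2 * 500 / 150),
                      target_f = 44, W_ext = 0.6, n_source = 1,
                      t_end = 2500, cal_tol = 0.3)
  expect_false(any(pd$flagged))
  expect_true(all(!is.na(pd$sync_type)))
  # phase locking stays at least as tight with heterogeneity (weak
  # monotonicity at desk scale)
  v05 <- mean(pd$var_phase[pd$cv == 0.05])
  v15 <- mean(pd$var_phase[pd$cv == 0.15])
  expect_lte(v15, v05 + 1e-3)
})
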