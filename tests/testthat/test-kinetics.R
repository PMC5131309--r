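# 0D reaction-network tests: closed forms for each pathway, an
# independent RK4 oracle for full trajectories, and property tests for
# non-negativity, conservation, and the heparin monotonicity.

test_that("activation omega is the normalized additive agonist sum", {
  p <- kinetics_params()
  expect_equal(activation_omega(batch_state(ADP = 0, TxA2 = 0, T = 0), p), 0)
  expect_equal(activation_omega(batch_state(ADP = p$crit_ADP), p), 1)
  a <- batch_state(ADP = 0.4 * p$crit_ADP)
  b <- batch_state(TxA2 = 0.3 * p$crit_TxA2, T = 0.2 * p$crit_T)
  ab <- batch_state(ADP = 0.4 * p$crit_ADP, TxA2 = 0.3 * p$crit_TxA2,
                    T = 0.2 * p$crit_T)
  expect_equal(activation_omega(ab, p),
               activation_omega(a, p) + activation_omega(b, p))
})

test_that("subthreshold agonists leave resting platelets exactly constant", {
  # freeze agonist generation so Omega stays below threshold
  p <- kinetics_params(phi_AT = 1e-300, phi_RT = 1e-300,
                       beta_TxA2 = 1e-300, lambda_ADP = 1e-300)
  c0 <- batch_state(ADP = 0.3 * p$crit_ADP, TxA2 = 0.3 * p$crit_TxA2,
                    T = 0.39 * p$crit_T)
  expect_equal(platelet_activation_rate(c0, 0, p), 0)
  traj <- integrate_batch(c0, 5, p)
  expect_equal(traj$states[, "RP"], rep(c0[["RP"]], nrow(traj$states)))
})

test_that("supra-threshold activation decays RP exponentially", {
  # hold Omega = 2 via thrombin with every feedback pathway disabled
  p <- kinetics_params(phi_AT = 1e-300, phi_RT = 1e-300, k_cat = 0,
                       lambda_ADP = 1e-300, beta_TxA2 = 1e-300)
  c0 <- batch_state(T = 2 * p$crit_T, ADP = 0, TxA2 = 0)
  traj <- integrate_batch(c0, 2, p, rtol = 1e-10)
  expect_lt(max(abs(traj$states[, "RP"] -
                      c0[["RP"]] * exp(-2 * traj$times / p$t_act))) /
              c0[["RP"]], 1e-6)
  # platelet number conserved through the conversion
  expect_equal(traj$states[, "RP"] + traj$states[, "AP"],
               rep(c0[["RP"]] + c0[["AP"]], length(traj$times)),
               tolerance = 1e-12)
})

test_that("activation rate increases with shear stress", {
  p <- kinetics_params(k_shear = 1e-3, alpha_shear = 1.2)
  c0 <- batch_state()
  rates <- vapply(c(0, 0.5, 1, 2, 4),
                  function(tau) platelet_activation_rate(c0, tau, p),
                  numeric(1))
  expect_true(all(diff(rates) > 0))
})

test_that("agonist kinetics follow their closed forms", {
  p <- kinetics_params()
  # pure first-order ADP decay
  c0 <- batch_state(ADP = 1e6, T = 0, TxA2 = 0, AP = 0, RP = 1e10,
                    PT = 1e-12)
  traj <- integrate_batch(c0, 60, p, rtol = 1e-10)
  expect_equal(traj$states[, "ADP"], 1e6 * exp(-p$k1_ADP * traj$times),
               tolerance = 1e-6)
  # TxA2 relaxes to its synthesis/inhibition fixed point
  s <- agonist_sources(batch_state(AP = 1e12, TxA2 = 0), 0, p)
  tx_star <- p$beta_TxA2 * 1e12 / p$k1_TxA2
  expect_equal(agonist_sources(batch_state(AP = 1e12, TxA2 = tx_star),
                               0, p)[["TxA2"]], 0, tolerance = 1e-20)
  expect_gt(s[["TxA2"]], 0)
})

test_that("thrombin generation vanishes without substrate or platelets", {
  p <- kinetics_params()
  expect_equal(thrombin_sources(batch_state(PT = 1e-30), p)[["T"]], 0,
               tolerance = 1e-15)
  no_plt <- batch_state(RP = 0, AP = 0)
  expect_equal(thrombin_sources(no_plt, p)[["T"]], 0)
})

test_that("thrombin generated balances prothrombin consumed", {
  p <- kinetics_params(k_cat = 0)   # disable inhibition for the ledger
  c0 <- batch_state(RP = 1e14, AP = 1e13, ADP = 0, TxA2 = 0, T = 0)
  traj <- integrate_batch(c0, 10, p, rtol = 1e-9)
  n <- nrow(traj$states)
  dT <- unname(traj$states[n, "T"] - traj$states[1, "T"])
  dPT <- unname(traj$states[1, "PT"] - traj$states[n, "PT"])
  expect_gt(dT, 0)
  expect_equal(dPT, p$c_PT_per_U * dT, tolerance = 1e-6)
})

test_that("griffith template rate has its boundary and scaling behaviour", {
  p <- kinetics_params()
  expect_equal(griffith_inhibition_rate(0, 2.8e-6, 0.1, p), 0)
  expect_equal(griffith_inhibition_rate(100, 0, 0.1, p), 0)
  r1 <- griffith_inhibition_rate(50, 2.8e-6, 0.1, p)
  r3 <- griffith_inhibition_rate(50, 2.8e-6, 0.3, p)
  expect_equal(r3 / r1, 3, tolerance = 1e-12)   # linear catalysis
  expect_equal(griffith_inhibition_rate(50, 2.8e-6, 0, p), 0)
})

test_that("assemble_sources composes the pathways consistently", {
  p <- kinetics_params()
  z <- batch_state(RP = 0, AP = 0, ADP = 0, TxA2 = 0, PT = 1e-30, T = 0,
                   AT = 1e-30)
  expect_true(all(abs(assemble_sources(z, 0, p)) < 1e-20))
  # RP loss equals AP gain when only activation is active
  c0 <- batch_state(T = 3 * p$crit_T)
  s <- assemble_sources(c0, 0, p)
  expect_equal(s[["RP"]] + s[["AP"]], 0)
  # finite-difference sign structure: raising ADP above threshold
  # accelerates RP loss
  above <- batch_state(ADP = 1.5 * p$crit_ADP)
  higher <- batch_state(ADP = 2.5 * p$crit_ADP)
  expect_lt(assemble_sources(higher, 0, p)[["RP"]],
            assemble_sources(above, 0, p)[["RP"]])
})

test_that("trajectories match an independent RK4 oracle to 1e-6", {
  p <- kinetics_params()
  set.seed(42)
  for (rep in 1:2) {
    c0 <- random_batch_state()
    t_end <- 3
    traj <- integrate_batch(c0, t_end, p, rtol = 1e-9)
    orc <- rk4_batch(c0, t_end, p, n = 15000L)
    idx <- round(seq(1, 15001L, length.out = length(traj$times)))
    ref <- orc[idx, ]
    scale <- apply(abs(ref), 2, max)
    scale[scale == 0] <- 1
    err <- max(abs(traj$states - ref) / rep(scale, each = nrow(ref)))
    expect_lt(err, 1e-6)
  }
})

test_that("non-negativity is preserved for random initial states", {
  p <- kinetics_params()
  set.seed(7)
  for (rep in 1:100) {
    c0 <- random_batch_state()
    traj <- integrate_batch(c0, 1, p, rtol = 1e-5,
                            times = c(0, 0.25, 0.5, 1))
    expect_true(all(traj$states >= 0))
  }
})

test_that("steady thrombin is non-increasing in heparin", {
  # constant platelet source of thrombin against template inhibition
  finals <- vapply(c(0.05, 0.1, 0.3, 0.6), function(h) {
    p <- kinetics_params(heparin = h, lambda_ADP = 1e-300,
                         beta_TxA2 = 1e-300)
    c0 <- batch_state(RP = 1e13, AP = 1e12, T = 0, PT = 1.1e-6)
    traj <- integrate_batch(c0, 15, p, rtol = 1e-7,
                            times = c(0, 5, 10, 15))
    traj$states[nrow(traj$states), "T"]
  }, numeric(1))
  expect_true(all(diff(finals) <= 0))
  expect_lt(finals[4], finals[1])
})

test_that("deposited species attached to the state feed the sources", {
  p <- kinetics_params()
  plain <- batch_state(AP = 1e12)
  with_dep <- batch_state(AP = 1e12, APd = 5e14)
  s0 <- assemble_sources(plain, 0, p)
  s1 <- assemble_sources(with_dep, 0, p)
  expect_gt(s1[["T"]], s0[["T"]])
  expect_gt(s1[["TxA2"]], s0[["TxA2"]])
})
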