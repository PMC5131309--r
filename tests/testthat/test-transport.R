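# Species-solver tests: transported-constant invariance, mass ledgers,
# diffusion maximum principle, the deposition/cleaning/stabilization
# laws, and the thrombus update.

make_channel_setup <- function(u_in = 0.02, n = 12, trans = inert_transport()) {
  g <- build_channel(0.004, 0.001, n)
  fl <- solve_steady_flow(g, matrix(0, g$nx, g$ny), flow_params(), u_in,
                          steady_tol = 1e-8)
  list(grid = g, flow = fl, kin = inert_kinetics(), trans = trans,
       species = species_init(g), thrombus = thrombus_init(g))
}

test_that("effective diffusivity follows D_l + nu_t/Sc", {
  expect_equal(effective_diffusivity(1e-11, 0, 0.9), 1e-11)
  expect_equal(effective_diffusivity(1e-11, 9e-7, 0.9), 1e-11 + 1e-6)
  nu <- seq(0, 1e-6, length.out = 10)
  expect_true(all(diff(effective_diffusivity(1e-11, nu, 0.9)) > 0))
  expect_error(effective_diffusivity(1e-11, 0, -1), "Sc")
  expect_error(effective_diffusivity(0, 0, 0.9), "D_l")
})

test_that("a uniform field is transported invariantly", {
  s <- make_channel_setup()
  dt <- transport_dt_stable(s$grid, s$flow, s$trans)
  st <- transport_step(s$grid, s$flow, s$species, s$thrombus, s$kin,
                       s$trans, dt, nsteps = 200L)
  fluid <- s$grid$cell_type == CELL_TYPES[["FLUID"]]
  for (sp in SPECIES_FREE) {
    f <- st$species$C[, , sp]
    ref <- s$species$inlet[[sp]]
    if (ref == 0) expect_equal(max(abs(f[fluid])), 0) else
      expect_lt(max(abs(f[fluid] - ref)) / ref, 1e-12)
  }
})

test_that("advected mass is conserved to the ledger tolerance", {
  s <- make_channel_setup()
  # inject a blob of excess platelets mid-channel
  s$species$C[20:30, 4:8, "RP"] <- 5e14
  inv0 <- freestream_platelet_inventory(s$grid, s$species)
  dt <- transport_dt_stable(s$grid, s$flow, s$trans)
  st <- transport_step(s$grid, s$flow, s$species, s$thrombus, s$kin,
                       s$trans, dt, nsteps = 500L)
  inv1 <- freestream_platelet_inventory(s$grid, st$species)
  resid <- st$inflow - st$outflow - (inv1 - inv0)
  expect_lt(abs(resid) / (inv0 + st$inflow), 1e-10)
})

test_that("pure diffusion in a closed box relaxes to the mean", {
  g <- build_closed_box(10, 10, dx = 1e-4)
  fl <- init_flow(g, 0)
  kin <- inert_kinetics()
  trans <- inert_transport(D_l = c(RP = 1e-8, AP = 1e-8, ADP = 1e-8,
                                   TxA2 = 1e-8, PT = 1e-8, T = 1e-8,
                                   AT = 1e-8))
  sp <- species_init(g, inlet = c(RP = 0, AP = 0, ADP = 0, TxA2 = 0,
                                  PT = 0, T = 0, AT = 0))
  sp$C[3:5, 3:5, "RP"] <- 1e14
  th <- thrombus_init(g)
  dt <- transport_dt_stable(g, fl, trans)
  mean0 <- mean(sp$C[, , "RP"])
  var_prev <- stats::var(as.numeric(sp$C[, , "RP"]))
  for (k in 1:5) {
    st <- transport_step(g, fl, sp, th, kin, trans, dt, nsteps = 50L)
    sp <- st$species
    v <- stats::var(as.numeric(sp$C[, , "RP"]))
    expect_lt(v, var_prev)
    var_prev <- v
  }
  expect_equal(mean(sp$C[, , "RP"]), mean0, tolerance = 1e-12)
  expect_lt(max(sp$C[, , "RP"]) - min(sp$C[, , "RP"]), 0.05e14)
})

test_that("transport rejects unstable time steps", {
  s <- make_channel_setup()
  expect_error(transport_step(s$grid, s$flow, s$species, s$thrombus,
                              s$kin, s$trans, dt = 10), "stability")
})

test_that("deposition fluxes follow the saturating wall law", {
  s <- make_channel_setup(trans = transport_params())
  df <- deposition_fluxes(s$grid, s$species, s$thrombus, s$trans)
  expect_gt(nrow(df), 0)
  r <- df[1, ]
  RP <- unname(s$species$C[r$ix, r$iy, "RP"])
  AP <- unname(s$species$C[r$ix, r$iy, "AP"])
  expect_equal(r$j_RP, s$trans$k_rpd_b * RP)   # virgin wall: s = 0
  expect_equal(r$j_AP, s$trans$k_apd_b * AP)
  # doubling the near-wall concentration doubles the flux
  s2 <- s
  s2$species$C[r$ix, r$iy, "AP"] <- 2 * AP
  df2 <- deposition_fluxes(s2$grid, s2$species, s2$thrombus, s2$trans)
  expect_equal(df2$j_AP[1], 2 * r$j_AP)
  # saturated monolayer shuts the wall flux off
  s3 <- s
  Aw <- s3$thrombus$rwall_area[r$ix, r$iy]
  s3$species$Cd[r$ix, r$iy, "RPd"] <-
    s3$trans$M_inf * Aw / (s3$grid$dx * s3$grid$dy)
  df3 <- deposition_fluxes(s3$grid, s3$species, s3$thrombus, s3$trans)
  expect_equal(df3$j_RP[1], 0)
  expect_equal(df3$j_AP[1], 0)
  # zero concentration, zero flux
  s4 <- s
  s4$species$C[, , "RP"] <- 0; s4$species$C[, , "AP"] <- 0
  df4 <- deposition_fluxes(s4$grid, s4$species, s4$thrombus, s4$trans)
  expect_true(all(df4$j_RP == 0) && all(df4$j_AP == 0))
})

test_that("kernel deposition conserves platelet number and respects phi_max", {
  s <- make_channel_setup(u_in = 0.01,
                          trans = transport_params(k_rpd_b = 1e-4,
                                                   k_apd_b = 1e-4,
                                                   k_clean = 1e-300))
  dt <- transport_dt_stable(s$grid, s$flow, s$trans)
  tot0 <- freestream_platelet_inventory(s$grid, s$species) +
    deposited_inventory(s$grid, s$species)
  st <- transport_step(s$grid, s$flow, s$species, s$thrombus, s$kin,
                       s$trans, dt, nsteps = 400L)
  tot1 <- freestream_platelet_inventory(s$grid, st$species) +
    deposited_inventory(s$grid, st$species)
  expect_lt(abs(st$inflow - st$outflow - (tot1 - tot0)) /
              (tot0 + st$inflow), 1e-10)
  expect_gt(deposited_inventory(s$grid, st$species), 0)
  expect_true(all(st$thrombus$phi <= s$trans$phi_max + 1e-12))
  expect_true(all(st$species$C >= 0) && all(st$species$Cd >= 0))
})

test_that("cleaning follows the thresholded excess-stress law", {
  tr <- transport_params()
  expect_equal(cleaning_rates(1e14, 1e14, tr$tau_sc_b, TRUE, tr), 0)
  expect_equal(cleaning_rates(1e14, 1e14, 0.5 * tr$tau_sc, FALSE, tr), 0)
  r1 <- cleaning_rates(1e14, 0, 2 * tr$tau_sc_b, TRUE, tr)
  expect_equal(r1, tr$k_clean * 1 * 1e14)
  taus <- seq(0, 5, length.out = 20)
  rates <- cleaning_rates(1e14, 1e14, taus, FALSE, tr)
  expect_true(all(diff(rates) >= 0))
})

test_that("stabilized platelets are immune to shear cleaning", {
  # high-shear channel: deposits form, clean, but APs only grows
  g <- build_channel(0.003, 0.001, 10)
  fl <- solve_steady_flow(g, matrix(0, g$nx, g$ny), flow_params(), 0.1,
                          steady_tol = 1e-8)
  trans <- transport_params(k_apd_b = 1e-4, k_rpd_b = 1e-5,
                            tau_sc_b = 0.3, k_clean = 5, k_stab = 0.5)
  sp <- species_init(g)
  th <- thrombus_init(g)
  kin <- inert_kinetics()
  dt <- transport_dt_stable(g, fl, trans)
  aps_prev <- 0
  for (k in 1:4) {
    st <- transport_step(g, fl, sp, th, kin, trans, dt, nsteps = 200L)
    sp <- st$species; th <- st$thrombus
    aps <- sum(sp$Cd[, , "APs"])
    expect_gte(aps, aps_prev)
    aps_prev <- aps
  }
  expect_gt(aps_prev, 0)
})

test_that("stabilization converts AP_d to AP_s conservatively", {
  tr <- transport_params()
  expect_equal(stabilization_rate(0, tr), 0)
  expect_equal(stabilization_rate(2e14, tr), tr$k_stab * 2e14)
  # closed-box kernel run: APd decays as exp(-k_stab t), sum conserved
  g <- build_closed_box(6, 6, dx = 1e-4)
  fl <- init_flow(g, 0)
  trans <- inert_transport(k_stab = 0.5)
  sp <- species_init(g, inlet = c(RP = 0, AP = 0, ADP = 0, TxA2 = 0,
                                  PT = 0, T = 0, AT = 0))
  sp$Cd[3, 3, "APd"] <- 1e15
  th <- thrombus_init(g)
  th$active[3, 3] <- 2L
  dt <- 1e-3
  st <- transport_step(g, fl, sp, th, inert_kinetics(), trans, dt,
                       nsteps = 1000L)   # t = 1 s
  apd <- unname(st$species$Cd[3, 3, "APd"])
  aps <- unname(st$species$Cd[3, 3, "APs"])
  expect_equal(apd, 1e15 * exp(-0.5 * 1), tolerance = 1e-3)
  expect_equal(apd + aps, 1e15, tolerance = 1e-12)
})

test_that("update_thrombus computes phi and extends the active mask", {
  g <- build_crevice_channel(1e-3, 5e-4, 5e-4, 5e-3, 8)
  tr <- transport_params()
  sp <- species_init(g)
  th <- thrombus_init(g)
  expect_true(all(th$phi == 0))
  expect_equal(sum(th$active == 1L), sum(th$rwall_area > 0))
  # fill one cavity cell to capacity
  i <- g$meta$i_cav[1]; j <- 1L
  sp$Cd[i, j, "APd"] <- tr$phi_max / tr$V_p
  th2 <- update_thrombus(g, sp, th, tr)
  expect_equal(th2$phi[i, j], tr$phi_max)
  # its fluid neighbours are now deposition-active
  for (sd in 1:4) {
    ii <- i + c(-1, 1, 0, 0)[sd]; jj <- j + c(0, 0, -1, 1)[sd]
    if (ii >= 1 && ii <= g$nx && jj >= 1 && jj <= g$ny &&
        g$cell_type[ii, jj] == CELL_TYPES[["FLUID"]])
      expect_gt(th2$active[ii, jj], 0)
  }
})

test_that("kernel reaction terms agree with the 0D integrator", {
  # single closed cell, no transport: the kernel's semi-analytic update
  # must track integrate_batch on the same parameters
  g <- build_closed_box(6, 6, dx = 1e-4)
  fl <- init_flow(g, 0)
  kin <- kinetics_params()
  trans <- inert_transport()
  c0 <- batch_state(RP = 2e14, AP = 5e12, ADP = 3e6, TxA2 = 1e5,
                    PT = 1.1e-6, T = 50, AT = 2.844e-6)
  sp <- species_init(g, inlet = c0)
  th <- thrombus_init(g)
  t_end <- 2
  st <- transport_step(g, fl, sp, th, kin, trans, dt = 2e-4,
                       nsteps = as.integer(t_end / 2e-4))
  ref <- integrate_batch(c0, t_end, kin, rtol = 1e-10)
  got <- st$species$C[3, 3, ]
  want <- ref$states[nrow(ref$states), ]
  for (s in SPECIES_FREE) {
    scale <- max(abs(want[[s]]), 1e-12 * max(abs(c0)))
    expect_lt(abs(got[[s]] - want[[s]]) / scale, 5e-3)
  }
})
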