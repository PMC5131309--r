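# Driver-level tests: scenario derivation, rate scaling, checkpoint
# round-trips, resume determinism, and the conservation ledger on a
# small, fast configuration.

fast_config <- function(duration = 4, ...) {
  scenario_config(
    geometry = list(preset = "crevice_channel", channel_h = 1e-3,
                    crevice_w = 1e-3, crevice_d = 2.5e-4, length = 4e-3,
                    n_across = 8),
    u_in = 0.05, duration = duration, output_interval = 1,
    flow_update_interval = 2, ...)
}

test_that("scale_reaction_rates touches exactly the four constants", {
  tr <- transport_params()
  sc <- scale_reaction_rates(tr, 30)
  expect_equal(sc$k_ra, 30 * tr$k_ra)
  expect_equal(sc$k_aa, 30 * tr$k_aa)
  expect_equal(sc$k_rpd_b, 30 * tr$k_rpd_b)
  expect_equal(sc$k_apd_b, 30 * tr$k_apd_b)
  expect_equal(sc$chi_applied, 30)
  untouched <- setdiff(names(tr), c("k_ra", "k_aa", "k_rpd_b", "k_apd_b",
                                    "chi_applied"))
  expect_identical(tr[untouched], sc[untouched])
  expect_identical(scale_reaction_rates(tr, 1)[names(tr)], tr[names(tr)])
  expect_error(scale_reaction_rates(tr, 0.5), "chi")
})

test_that("reported time is chi times simulated time", {
  cfg <- fast_config(duration = 2, chi = 30)
  res <- run_simulation(cfg)
  expect_equal(res$series$time_reported, 30 * res$series$time_sim)
  # simulated 12.5 min maps to 6.25 h under chi = 30
  expect_equal(30 * 12.5 * 60, 6.25 * 3600)
})

test_that("make_scenario derives the documented variants", {
  base <- fast_config()
  expect_identical(make_scenario("baseline", base), base)
  hep <- make_scenario("heparin_bolus", base)
  expect_equal(hep$heparin, 0.3)
  same <- setdiff(names(base), c("heparin", "label"))
  expect_identical(base[same], hep[same])
  coat <- make_scenario("surface_coating", base)
  k0 <- formals(transport_params)$k_apd_b
  t0 <- formals(transport_params)$tau_sc_b
  expect_equal(coat$transport$k_apd_b, k0 / 10)
  expect_equal(coat$transport$tau_sc_b, t0 / 10)
  sw <- make_scenario("flow_sweep", base)
  expect_named(sw, c("low", "nominal", "high"))
  expect_equal(vapply(sw, function(s) s$u_in, numeric(1)) / base$u_in,
               c(low = 2.0 / 4.5, nominal = 1, high = 6.0 / 4.5))
  expect_error(make_scenario("nonsense", base), "unknown")
})

test_that("coating override divides an explicit k_apd_b too", {
  base <- fast_config(transport = list(k_apd_b = 4e-6, tau_sc_b = 1.0))
  coat <- make_scenario("surface_coating", base)
  expect_equal(coat$transport$k_apd_b, 4e-7)
  expect_equal(coat$transport$tau_sc_b, 0.1)
})

test_that("zero platelet inlet yields zero deposit", {
  cfg <- fast_config(duration = 2,
                     inlet = inlet_concentrations(RP = 0, AP_frac = 0))
  res <- run_simulation(cfg)
  expect_equal(max(res$series$deposit_total), 0)
  expect_true(all(res$thrombus$phi == 0))
})

test_that("the platelet ledger closes at every output step", {
  res <- run_simulation(fast_config(duration = 4))
  expect_true(all(abs(res$series$ledger_residual) < 1e-8))
  expect_gt(res$series$deposit_total[nrow(res$series)], 0)
})

test_that("repeated runs are bit-identical", {
  cfg <- fast_config(duration = 3)
  r1 <- run_simulation(cfg)
  r2 <- run_simulation(cfg)
  expect_identical(r1$series, r2$series)
  expect_identical(r1$species$C, r2$species$C)
  expect_identical(r1$thrombus$phi, r2$thrombus$phi)
})

test_that("checkpoint round-trip is bit-exact", {
  cfg <- fast_config(duration = 2)
  ck <- tempfile()
  res <- run_simulation(cfg, checkpoint_path = ck)
  b <- checkpoint_load(ck)
  expect_identical(b$species$C, res$species$C)
  expect_identical(b$species$Cd, res$species$Cd)
  expect_identical(b$thrombus$phi, res$thrombus$phi)
  expect_identical(b$thrombus$active, res$thrombus$active)
  expect_identical(b$flow$u, res$flow$u)
  expect_identical(b$flow$p, res$flow$p)
})

test_that("resuming from a checkpoint reproduces the straight run", {
  cfg4 <- fast_config(duration = 4)
  straight <- run_simulation(cfg4)
  ck <- tempfile()
  run_simulation(fast_config(duration = 2), checkpoint_path = ck)
  resumed <- run_simulation(cfg4, resume_from = ck)
  expect_identical(straight$series, resumed$series)
  expect_identical(straight$species$C, resumed$species$C)
  expect_identical(straight$thrombus$phi, resumed$thrombus$phi)
})

test_that("corrupted or mismatched checkpoints error loudly", {
  ck <- tempfile()
  writeLines(c("not-a-checkpoint", "1 2 3"), ck)
  expect_error(checkpoint_load(ck), "schema")
  run_simulation(fast_config(duration = 1), checkpoint_path = ck)
  lines <- readLines(ck)
  truncated <- tempfile()
  writeLines(lines[1:3], truncated)
  expect_error(checkpoint_load(truncated), "checkpoint")
})

test_that("time compression is consistent in the transport-limited regime", {
  # chi = 30 for t versus chi = 1 for 30 t: with surface Damkohler >> 1
  # the deposition flux is supply-limited, so the compressed run must
  # reproduce the uncompressed deposit (the rationale for rescaling the
  # four deposition constants)
  mk <- function(chi, dur) scenario_config(
    geometry = list(preset = "crevice_channel", channel_h = 1e-3,
                    crevice_w = 1e-3, crevice_d = 2.5e-4, length = 4e-3,
                    n_across = 8),
    u_in = 0.05, duration = dur, chi = chi, output_interval = dur,
    transport = list(k_rpd_b = 1e-4, k_apd_b = 1e-4, k_ra = 1e-300,
                     k_aa = 1e-300, k_clean = 1e-300, k_stab = 1e-300),
    kinetics = list(phi_AT = 1e-300, phi_RT = 1e-300, k_cat = 0,
                    beta_TxA2 = 1e-300, lambda_ADP = 1e-300))
  d30 <- tail(run_simulation(mk(30, 2))$series$deposit_total, 1)
  d1 <- tail(run_simulation(mk(1, 60))$series$deposit_total, 1)
  expect_lt(abs(d30 - d1) / d1, 0.10)
})

test_that("the packaged example config parses to the default scenario", {
  path <- system.file("extdata", "baseline_config.json", package = "hemoclot")
  expect_true(nzchar(path))
  cfg <- read_config(path)
  def <- scenario_config()
  expect_equal(cfg$geometry, def$geometry)
  expect_equal(cfg$u_in, def$u_in)
  expect_equal(cfg$chi, def$chi)
  expect_equal(cfg$inlet, def$inlet)
})

test_that("configs round-trip through the text format", {
  cfg <- fast_config(duration = 2, heparin = 0.3,
                     transport = list(k_aa = 1e-4),
                     kinetics = list(crit_T = 55))
  path <- tempfile(fileext = ".json")
  write_config(cfg, path)
  back <- read_config(path)
  expect_equal(back$geometry$preset, cfg$geometry$preset)
  expect_equal(back$u_in, cfg$u_in)
  expect_equal(back$heparin, 0.3)
  expect_equal(back$transport$k_aa, 1e-4)
  expect_equal(back$kinetics$crit_T, 55)
  expect_equal(unname(back$inlet), unname(cfg$inlet))
})

test_that("run_simulation writes a results bundle when asked", {
  outdir <- file.path(tempdir(), "hemoclot-test-out")
  cfg <- fast_config(duration = 2, outdir = outdir)
  run_simulation(cfg)
  expect_true(file.exists(file.path(outdir, "series.csv")))
  expect_true(file.exists(file.path(outdir, "final_fields.vtk")))
  expect_true(file.exists(file.path(outdir, "manifest.json")))
  s <- utils::read.csv(file.path(outdir, "series.csv"))
  expect_equal(nrow(s), 2L)
  man <- jsonlite::read_json(file.path(outdir, "manifest.json"))
  expect_gt(man$damkohler$AP_surface, 1)
  unlink(outdir, recursive = TRUE)
})

test_that("the CLI runs a config end to end", {
  cfgfile <- tempfile(fileext = ".json")
  outdir <- file.path(tempdir(), "hemoclot-cli-out")
  write_config(fast_config(duration = 2), cfgfile)
  expect_output(hemoclot_cli(c("run", cfgfile, outdir)), "hemoclot_result")
  expect_true(file.exists(file.path(outdir, "series.csv")))
  expect_output(hemoclot_cli(c("postprocess", outdir)), "final deposit")
  unlink(outdir, recursive = TRUE)
  expect_message(hemoclot_cli(character(0)), "usage")
})
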