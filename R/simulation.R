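# Scenario configuration, reaction-rate time scaling, the coupled
# time-stepping driver, checkpointing, and scenario presets.
#
# Separation of scales: deposition evolves over tens of seconds while
# the flow relaxes in fractions of a second, so the flow is held frozen
# between thrombus updates and re-solved to quasi-steady state when the
# deposit has grown appreciably (or on a fixed cadence).  The whole loop
# is single-threaded and free of random numbers: identical
# configurations give bit-identical outputs.

#' Scenario configuration
#'
#' @param geometry named list selecting a preset and its dimensions:
#'   `list(preset = "channel", length =, height =, n_across =)`,
#'   `list(preset = "crevice_channel", channel_h =, crevice_w =,
#'   crevice_d =, length =, n_across =)`, or
#'   `list(preset = "backward_facing_step", inlet_h =, outlet_h =,
#'   step_x =, length =, n_across =)`.
#' @param u_in uniform inlet velocity (m/s).
#' @param inlet inlet concentrations, see [inlet_concentrations()].
#' @param heparin circulating heparin level (nmol/m^3).
#' @param duration simulated time (s); reported time is
#'   `chi * duration`.
#' @param chi reaction-rate time-scale factor applied to the four
#'   deposition constants (k_ra, k_aa, k_rpd_b, k_apd_b); simulation
#'   output times are reported multiplied by `chi`.
#' @param kinetics,transport,flow named lists of overrides passed to
#'   [kinetics_params()], [transport_params()], [flow_params()].
#' @param output_interval simulated seconds between time-series rows.
#' @param flow_update_interval re-solve the quasi-steady flow at least
#'   this often (simulated s).
#' @param flow_dphi_trigger re-solve the flow earlier when max |phi -
#'   phi at last flow solve| exceeds this.
#' @param dt_safety safety factor on the transport stability limit.
#' @param outdir optional output directory for CSV/VTK/manifest files.
#' @param label scenario label used in outputs.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(geometry = list(preset = "crevice_channel",
                                            channel_h = 1e-3,
                                            crevice_w = 1e-3,
                                            crevice_d = 2e-4,
                                            length = 5e-3,
                                            n_across = 20),
                            u_in = 0.1,
                            inlet = inlet_concentrations(),
                            heparin = 0.1,
                            duration = 60,
                            chi = 30,
                            kinetics = list(),
                            transport = list(),
                            flow = list(),
                            output_interval = 1,
                            flow_update_interval = 5,
                            flow_dphi_trigger = 0.08,
                            dt_safety = 0.8,
                            outdir = NULL,
                            label = "baseline") {
  stopifnot(duration > 0, chi >= 1, u_in >= 0, all(inlet >= 0),
            heparin >= 0, output_interval > 0, flow_update_interval > 0)
  structure(list(geometry = geometry, u_in = u_in, inlet = inlet,
                 heparin = heparin, duration = duration, chi = chi,
                 kinetics = kinetics, transport = transport, flow = flow,
                 output_interval = output_interval,
                 flow_update_interval = flow_update_interval,
                 flow_dphi_trigger = flow_dphi_trigger,
                 dt_safety = dt_safety, outdir = outdir, label = label),
            class = "scenario_config")
}

#' Build the grid of a scenario
#' @param config a [scenario_config()].
#' @return A [grid2d].
#' @export
build_scenario_grid <- function(config) {
  gm <- config$geometry
  switch(gm$preset,
         channel = build_channel(gm$length, gm$height, gm$n_across),
         crevice_channel = build_crevice_channel(gm$channel_h, gm$crevice_w,
                                                 gm$crevice_d, gm$length,
                                                 gm$n_across),
         backward_facing_step = build_backward_facing_step(gm$inlet_h,
                                                           gm$outlet_h,
                                                           gm$step_x,
                                                           gm$length,
                                                           gm$n_across),
         stop("unknown geometry preset: ", gm$preset))
}

#' Scale the deposition reaction rates by the time-compression factor
#'
#' Multiplies exactly the four platelet deposition constants `k_ra`,
#' `k_aa`, `k_rpd_b`, `k_apd_b` by `chi`; every other parameter is
#' untouched.  The factor is recorded so output time axes can be
#' rescaled (`reported time = chi * simulated time`).
#'
#' @param trans a [transport_params()].
#' @param chi scale factor, >= 1.
#' @return Scaled `transport_params` with `chi_applied` updated.
#' @export
scale_reaction_rates <- function(trans, chi) {
  if (!is.finite(chi) || chi < 1) stop("chi must be >= 1")
  trans$k_ra <- trans$k_ra * chi
  trans$k_aa <- trans$k_aa * chi
  trans$k_rpd_b <- trans$k_rpd_b * chi
  trans$k_apd_b <- trans$k_apd_b * chi
  trans$chi_applied <- trans$chi_applied * chi
  trans
}

#' Derive scenario variants
#'
#' `baseline` returns the base configuration unchanged;
#' `heparin_bolus` raises circulating heparin from 0.1 to 0.3 nmol/m^3
#' (everything else identical); `surface_coating` divides the
#' platelet-surface deposition rate `k_apd_b` and the platelet-surface
#' cleaning stress `tau_sc_b` by 10 (a low-thrombogenicity coating);
#' `flow_sweep` returns three configurations with inlet velocities in
#' the ratio 2.0 : 4.5 : 6.0 relative to nominal.
#'
#' @param kind one of `"baseline"`, `"flow_sweep"`, `"heparin_bolus"`,
#'   `"surface_coating"`.
#' @param base a [scenario_config()].
#' @return A `scenario_config`, or a named list of three for
#'   `flow_sweep`.
#' @export
make_scenario <- function(kind, base = scenario_config()) {
  switch(kind,
         baseline = base,
         heparin_bolus = {
           cfg <- base
           cfg$heparin <- 0.3
           cfg$label <- paste0(base$label, "+heparin_bolus")
           cfg
         },
         surface_coating = {
           cfg <- base
           tr <- cfg$transport
           tr$k_apd_b <- (if (is.null(tr$k_apd_b))
             formals(transport_params)$k_apd_b else tr$k_apd_b) / 10
           tr$tau_sc_b <- (if (is.null(tr$tau_sc_b))
             formals(transport_params)$tau_sc_b else tr$tau_sc_b) / 10
           cfg$transport <- tr
           cfg$label <- paste0(base$label, "+coating")
           cfg
         },
         flow_sweep = {
           ratios <- c(low = 2.0 / 4.5, nominal = 1.0, high = 6.0 / 4.5)
           out <- lapply(names(ratios), function(nm) {
             cfg <- base
             cfg$u_in <- base$u_in * ratios[[nm]]
             cfg$label <- paste0(base$label, "+flow_", nm)
             cfg
           })
           names(out) <- names(ratios)
           out
         },
         stop("unknown scenario kind: ", kind))
}

# resolved parameter bundle of a scenario
resolve_params <- function(config) {
  kin_args <- config$kinetics
  kin_args$heparin <- config$heparin
  kin <- do.call(kinetics_params, kin_args)
  trans <- do.call(transport_params, config$transport)
  trans_scaled <- scale_reaction_rates(trans, config$chi)
  fp <- do.call(flow_params, config$flow)
  list(kin = kin, trans = trans, trans_scaled = trans_scaled, flow = fp)
}

#' Run a coupled thrombosis simulation
#'
#' Fixed operator-splitting loop: quasi-steady flow (with the current
#' porous-thrombus drag) -> species transport/reaction -> surface
#' deposition -> cleaning/stabilization -> thrombus update.  Emits a
#' time series of inventories and burden metrics together with a
#' platelet-number conservation ledger.
#'
#' @param config a [scenario_config()].
#' @param resume_from optional checkpoint path to resume from.
#' @param checkpoint_path optional path: a checkpoint is (re)written at
#'   every output step.
#' @param verbose print progress lines.
#' @return A list of class `hemoclot_result`: `config`, `grid`,
#'   resolved `params`, final `flow`/`species`/`thrombus`, and `series`
#'   (data.frame, one row per output time).
#' @export
run_simulation <- function(config, resume_from = NULL,
                           checkpoint_path = NULL, verbose = FALSE) {
  grid <- build_scenario_grid(config)
  prm <- resolve_params(config)
  n_out <- as.integer(round(config$duration / config$output_interval))
  if (n_out < 1L) stop("duration shorter than output_interval")

  if (is.null(resume_from)) {
    species <- species_init(grid, config$inlet)
    thrombus <- thrombus_init(grid)
    flow <- solve_steady_flow(grid, thrombus$phi, prm$flow, config$u_in)
    state <- list(k_out = 0L, inflow = 0, outflow = 0,
                  inv_free0 = freestream_platelet_inventory(grid, species),
                  inv_dep0 = deposited_inventory(grid, species),
                  phi_flow = thrombus$phi, t_last_flow = 0,
                  series = list())
  } else {
    ck <- checkpoint_load(resume_from)
    species <- ck$species; thrombus <- ck$thrombus; flow <- ck$flow
    flow$masks <- flow_masks(grid)   # masks are derived, not serialized
    state <- ck$state
  }
  tau <- cell_shear_stress(grid, flow, prm$flow$mu_f)

  while (state$k_out < n_out) {
    t0 <- state$k_out * config$output_interval
    t1 <- (state$k_out + 1L) * config$output_interval
    # flow refresh: on cadence or when the deposit grew appreciably
    dphi <- max(abs(thrombus$phi - state$phi_flow))
    if ((t0 - state$t_last_flow) >= config$flow_update_interval - 1e-9 ||
        dphi > config$flow_dphi_trigger) {
      # warm restart: the porous-drag change since the last solve is
      # localized, so a capped, looser re-solve suffices (the projection
      # keeps the field exactly divergence-free regardless)
      flow <- solve_steady_flow(grid, thrombus$phi, prm$flow, config$u_in,
                                flow0 = flow, steady_tol = 1e-7,
                                max_iters = 3000L)
      tau <- cell_shear_stress(grid, flow, prm$flow$mu_f)
      state$phi_flow <- thrombus$phi
      state$t_last_flow <- t0
    }
    dt_lim <- transport_dt_stable(grid, flow, prm$trans_scaled,
                                  safety = config$dt_safety)
    nsteps <- max(1L, as.integer(ceiling((t1 - t0) / dt_lim)))
    dt <- (t1 - t0) / nsteps
    step <- transport_step(grid, flow, species, thrombus, prm$kin,
                           prm$trans_scaled, dt, nsteps, tau = tau)
    species <- step$species; thrombus <- step$thrombus
    state$inflow <- state$inflow + step$inflow
    state$outflow <- state$outflow + step$outflow
    state$k_out <- state$k_out + 1L

    inv_free <- freestream_platelet_inventory(grid, species)
    inv_dep <- deposited_inventory(grid, species)
    resid <- state$inflow - state$outflow -
      (inv_free - state$inv_free0) - (inv_dep - state$inv_dep0)
    denom <- state$inv_free0 + abs(state$inflow) + abs(state$outflow)
    fl_mask <- grid$cell_type == CELL_TYPES[["FLUID"]]
    row <- data.frame(
      time_sim = t1,
      time_reported = config$chi * t1,
      inflow = state$inflow, outflow = state$outflow,
      inventory_free = inv_free, inventory_dep = inv_dep,
      ledger_residual = resid / denom,
      deposit_total = inv_dep,
      phi_peak = max(thrombus$phi),
      n_crit = as.numeric(sum(thrombus$phi >= prm$trans_scaled$phi_crit)),
      percent_volume = regional_thrombus_percent(thrombus$phi, fl_mask,
                                                 prm$trans_scaled$phi_max,
                                                 grid))
    state$series[[state$k_out]] <- row
    if (verbose)
      message(sprintf("t = %5.1f s  deposit = %.4g  phi_peak = %.3f  ledger = %.2e",
                      t1, inv_dep, max(thrombus$phi), row$ledger_residual))
    if (!is.null(checkpoint_path))
      checkpoint_save(list(species = species, thrombus = thrombus,
                           flow = flow, state = state), checkpoint_path)
  }

  series <- do.call(rbind, state$series)
  rownames(series) <- NULL
  res <- structure(list(config = config, grid = grid, params = prm,
                        flow = flow, species = species, thrombus = thrombus,
                        series = series),
                   class = "hemoclot_result")
  if (!is.null(config$outdir)) write_result_bundle(res, config$outdir)
  res
}

#' @export
print.hemoclot_result <- function(x, ...) {
  n <- nrow(x$series)
  cat(sprintf("hemoclot_result: '%s', %g simulated s (%g reported s, chi = %g)\n",
              x$config$label, x$series$time_sim[n], x$series$time_reported[n],
              x$config$chi))
  cat(sprintf("  final deposit: %.4g PLT/m depth (%.3f%% of fluid volume)\n",
              x$series$deposit_total[n], x$series$percent_volume[n]))
  cat(sprintf("  peak phi: %.3f, critical cells: %d, worst ledger residual: %.2e\n",
              x$series$phi_peak[n], x$series$n_crit[n],
              max(abs(x$series$ledger_residual))))
  invisible(x)
}

# write CSV series + VTK fields + resolved-config manifest
write_result_bundle <- function(res, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(res$series, file.path(outdir, "series.csv"),
                   row.names = FALSE)
  fields <- list(phi = res$thrombus$phi,
                 RP = res$species$C[, , "RP"], AP = res$species$C[, , "AP"],
                 T = res$species$C[, , "T"],
                 p = res$flow$p)
  write_vtk(res$grid, file.path(outdir, "final_fields.vtk"), fields)
  manifest <- list(label = res$config$label,
                   chi = res$config$chi,
                   u_in = res$config$u_in,
                   heparin = res$config$heparin,
                   duration_sim = res$config$duration,
                   duration_reported = res$config$duration * res$config$chi,
                   damkohler = scenario_damkohler(res))
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(outdir)
}

# surface Damkohler numbers of the scenario (reaction vs diffusive supply)
scenario_damkohler <- function(res) {
  tr <- res$params$trans_scaled
  L <- res$grid$ny * res$grid$dy
  list(RP_surface = damkohler_number(tr$k_rpd_b, L,
                                     D = tr$D_l[["RP"]], kind = "surface"),
       AP_surface = damkohler_number(tr$k_apd_b, L,
                                     D = tr$D_l[["AP"]], kind = "surface"))
}

# ---- checkpointing -------------------------------------------------------

CHECKPOINT_VERSION <- "hemoclot-checkpoint-1"

# doubles serialized with %.17g round-trip IEEE values exactly, so a
# resumed run reproduces the uninterrupted one bit for bit
.fmt_vec <- function(x) paste(sprintf("%.17g", as.numeric(x)), collapse = " ")

#' Save a simulation checkpoint (plain text)
#'
#' @param bundle list with `species`, `thrombus`, `flow`, `state` as
#'   assembled by [run_simulation()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
checkpoint_save <- function(bundle, path) {
  con <- file(path, "w")
  on.exit(close(con))
  wv <- function(name, x, dims) {
    writeLines(sprintf("%s %s", name, paste(dims, collapse = " ")), con)
    writeLines(.fmt_vec(x), con)
  }
  writeLines(CHECKPOINT_VERSION, con)
  sp <- bundle$species; th <- bundle$thrombus; fl <- bundle$flow
  st <- bundle$state
  wv("C", sp$C, dim(sp$C))
  wv("Cd", sp$Cd, dim(sp$Cd))
  wv("inlet", sp$inlet, length(sp$inlet))
  wv("phi", th$phi, dim(th$phi))
  wv("active", th$active, dim(th$active))
  wv("rwall_area", th$rwall_area, dim(th$rwall_area))
  wv("u", fl$u, dim(fl$u))
  wv("v", fl$v, dim(fl$v))
  wv("p", fl$p, dim(fl$p))
  wv("u_in", fl$u_in, 1L)
  wv("scalars", c(st$k_out, st$inflow, st$outflow, st$inv_free0,
                  st$inv_dep0, st$t_last_flow), 6L)
  wv("phi_flow", st$phi_flow, dim(st$phi_flow))
  nrows <- length(st$series)
  writeLines(sprintf("series %d", nrows), con)
  if (nrows > 0) {
    writeLines(paste(names(st$series[[1L]]), collapse = " "), con)
    for (r in st$series) writeLines(.fmt_vec(as.numeric(r)), con)
  }
  invisible(path)
}

#' Load a simulation checkpoint
#'
#' @param path checkpoint file written by [checkpoint_save()].
#' @return The restored bundle; errors on schema mismatch or a
#'   truncated/corrupted file.
#' @export
checkpoint_load <- function(path) {
  lines <- readLines(path)
  if (length(lines) < 1L || lines[1L] != CHECKPOINT_VERSION)
    stop("checkpoint schema mismatch: expected ", CHECKPOINT_VERSION)
  pos <- 2L
  rd <- function() {
    if (pos + 1L > length(lines))
      stop("corrupted checkpoint: truncated file")
    hdr <- strsplit(lines[pos], " ", fixed = TRUE)[[1L]]
    vals <- as.numeric(strsplit(lines[pos + 1L], " ", fixed = TRUE)[[1L]])
    dims <- as.integer(hdr[-1L])
    if (length(vals) != prod(dims))
      stop("corrupted checkpoint: field ", hdr[1L], " has ", length(vals),
           " values, expected ", prod(dims))
    pos <<- pos + 2L
    if (length(dims) > 1L) array(vals, dim = dims) else vals
  }
  C <- rd(); Cd <- rd(); inlet <- rd(); phi <- rd(); active <- rd()
  rwall <- rd(); u <- rd(); v <- rd(); p <- rd(); u_in <- rd()
  sc <- rd(); phi_flow <- rd()
  if (pos > length(lines)) stop("corrupted checkpoint: truncated file")
  hdr <- strsplit(lines[pos], " ", fixed = TRUE)[[1L]]
  if (hdr[1L] != "series") stop("corrupted checkpoint: missing series block")
  nrows <- as.integer(hdr[2L])
  series <- list()
  if (nrows > 0) {
    cols <- strsplit(lines[pos + 1L], " ", fixed = TRUE)[[1L]]
    for (r in seq_len(nrows)) {
      vals <- as.numeric(strsplit(lines[pos + 1L + r], " ", fixed = TRUE)[[1L]])
      df <- as.data.frame(as.list(vals))
      names(df) <- cols
      series[[r]] <- df
    }
  }
  names(inlet) <- SPECIES_FREE
  dimnames(C) <- list(NULL, NULL, SPECIES_FREE)
  dimnames(Cd) <- list(NULL, NULL, SPECIES_DEP)
  storage.mode(active) <- "integer"
  species <- structure(list(C = C, Cd = Cd, inlet = inlet),
                       class = "species_state")
  thrombus <- structure(list(phi = phi, active = active, rwall_area = rwall),
                        class = "thrombus_state")
  flow <- structure(list(u = u, v = v, p = p, u_in = u_in, masks = NULL,
                         div_max = 0), class = "flow_state")
  state <- list(k_out = as.integer(sc[1L]), inflow = sc[2L], outflow = sc[3L],
                inv_free0 = sc[4L], inv_dep0 = sc[5L], t_last_flow = sc[6L],
                phi_flow = phi_flow, series = series)
  list(species = species, thrombus = thrombus, flow = flow, state = state)
}
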