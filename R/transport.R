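# Species transport, surface deposition, cleaning, stabilization, and
# the thrombus volume-fraction update.  The per-step work is done by the
# compiled kernel (src/cdr_kernel.cpp); this file holds the parameter
# containers, state constructors, and pure-R reference implementations
# of the deposition/cleaning/stabilization laws used by the tests.

#' Transport and deposition parameters
#'
#' @param D_l named numeric vector of laminar (molecular/effective)
#'   diffusivities (m^2/s) for the seven free-stream species, in
#'   [SPECIES_FREE] order.  Platelet diffusivities default to a
#'   shear-enhanced effective value.
#' @param Sc turbulent Schmidt number relating eddy diffusivity to eddy
#'   viscosity (`D_t = nu_t / Sc`).
#' @param k_rpd_b,k_apd_b resting/activated platelet-surface deposition
#'   rate constants (m/s) on virgin reactive wall.
#' @param k_ra,k_aa resting/activated platelet-thrombus deposition rate
#'   constants (m/s) onto already-deposited platelets.
#' @param tau_sc platelet-platelet cleavage (shear cleaning)
#'   characteristic stress (Pa); 1.5 Pa = 15 dyne/cm^2.
#' @param tau_sc_b platelet-surface cleavage characteristic stress (Pa).
#' @param k_clean cleaning rate scale (1/s) multiplying the excess-stress
#'   factor `max(0, tau/tau* - 1)`.
#' @param k_stab stabilization rate (1/s), AP_d -> AP_s.
#' @param M_inf wall monolayer capacity (PLT/m^2).
#' @param V_p single-platelet volume (m^3).
#' @param phi_max packing limit of the deposited-platelet bed.
#' @param phi_crit volume fraction at which deposition propagates to
#'   adjacent cells.
#' @param eps_agg residual platelet-thrombus aggregation efficiency
#'   where the local agonist sum is below its activation threshold;
#'   stable incorporation into a growing aggregate requires agonist
#'   support, so sub-threshold capture is strongly reduced.
#' @return A list of class `transport_params`.
#' @export
transport_params <- function(D_l = c(RP = 2e-8, AP = 2e-8,
                                     ADP = 2.5e-10, TxA2 = 2.5e-10,
                                     PT = 3.3e-11, T = 4.2e-11,
                                     AT = 3.5e-11),
                             Sc = 0.9,
                             k_rpd_b = 1e-6, k_apd_b = 1e-6,
                             k_ra = 5e-6, k_aa = 1e-3,
                             tau_sc = 1.5, tau_sc_b = 0.45,
                             k_clean = 10, k_stab = 0.01,
                             M_inf = 7e10, V_p = 1.1e-17,
                             phi_max = 0.8, phi_crit = 0.9 * phi_max,
                             eps_agg = 0.02) {
  if (!all(SPECIES_FREE %in% names(D_l)))
    stop("D_l must be named for all seven free-stream species")
  D_l <- D_l[SPECIES_FREE]
  p <- list(D_l = D_l, Sc = Sc, k_rpd_b = k_rpd_b, k_apd_b = k_apd_b,
            k_ra = k_ra, k_aa = k_aa, tau_sc = tau_sc, tau_sc_b = tau_sc_b,
            k_clean = k_clean, k_stab = k_stab, M_inf = M_inf, V_p = V_p,
            phi_max = phi_max, phi_crit = phi_crit, eps_agg = eps_agg,
            chi_applied = 1)
  if (!is.finite(p$eps_agg) || p$eps_agg < 0 || p$eps_agg > 1)
    stop("eps_agg must lie in [0, 1]")
  for (nm in c("Sc", "k_rpd_b", "k_apd_b", "k_ra", "k_aa", "tau_sc",
               "tau_sc_b", "k_clean", "k_stab", "M_inf", "V_p",
               "phi_max", "phi_crit"))
    if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
      stop(sprintf("%s must be positive", nm))
  if (any(!is.finite(D_l)) || any(D_l <= 0))
    stop("diffusivities must be positive")
  if (p$phi_crit > p$phi_max) stop("phi_crit must not exceed phi_max")
  structure(p, class = "transport_params")
}

#' Effective species diffusivity
#'
#' `D = D_l + nu_t / Sc`: molecular diffusivity plus the turbulent
#' contribution scaled by the Schmidt number.  Laminar desk-scale runs
#' use `nu_t = 0`.
#'
#' @param D_l laminar diffusivity (m^2/s), > 0.
#' @param nu_t turbulent eddy viscosity (m^2/s), >= 0.
#' @param Sc Schmidt number, > 0.
#' @return Effective diffusivity (m^2/s).
#' @export
effective_diffusivity <- function(D_l, nu_t = 0, Sc = 0.9) {
  if (any(!is.finite(Sc)) || any(Sc <= 0)) stop("Sc must be positive")
  if (any(!is.finite(D_l)) || any(D_l <= 0)) stop("D_l must be positive")
  if (any(!is.finite(nu_t)) || any(nu_t < 0)) stop("nu_t must be >= 0")
  D_l + nu_t / Sc
}

#' Initialize the species fields
#'
#' Free-stream fields start filled with the inlet composition (the
#' device primed with blood); deposited fields start at zero.
#'
#' @param grid a [grid2d].
#' @param inlet named vector of the seven inlet concentrations; defaults
#'   to the standard inlet column (resting platelets 3.0e14 PLT/m^3,
#'   activated 1 percent of resting, agonists zero).
#' @return A list of class `species_state` with arrays `C`
#'   (`nx` x `ny` x 7) and `Cd` (`nx` x `ny` x 3).
#' @export
species_init <- function(grid, inlet = inlet_concentrations()) {
  stopifnot(all(SPECIES_FREE %in% names(inlet)))
  inlet <- inlet[SPECIES_FREE]
  nx <- grid$nx; ny <- grid$ny
  C <- array(0, dim = c(nx, ny, 7L), dimnames = list(NULL, NULL, SPECIES_FREE))
  fluid <- grid$cell_type == CELL_TYPES[["FLUID"]]
  for (s in seq_len(7L)) {
    sl <- matrix(0, nx, ny)
    sl[fluid] <- inlet[[s]]
    C[, , s] <- sl
  }
  Cd <- array(0, dim = c(nx, ny, 3L), dimnames = list(NULL, NULL, SPECIES_DEP))
  structure(list(C = C, Cd = Cd, inlet = inlet), class = "species_state")
}

#' Standard inlet concentrations
#'
#' The inlet boundary column: resting platelets 3.0e14 PLT/m^3,
#' activated platelets 1 percent of resting, agonists zero, prothrombin
#' 1.1e-6 and antithrombin 2.844e-6 (configured units), thrombin zero.
#'
#' @param RP resting platelet count density (PLT/m^3).
#' @param AP_frac activated fraction of the inlet platelet pool.
#' @param PT,AT prothrombin/antithrombin inlet levels.
#' @return Named numeric vector over [SPECIES_FREE].
#' @export
inlet_concentrations <- function(RP = 3.0e14, AP_frac = 0.01,
                                 PT = 1.1e-6, AT = 2.844e-6) {
  c(RP = RP, AP = AP_frac * RP, ADP = 0, TxA2 = 0, PT = PT, T = 0, AT = AT)
}

#' Initialize the thrombus state
#'
#' Zero deposit everywhere; the deposition-active mask starts as the
#' cells owning reactive wall faces (code 1); cells activated later by
#' propagation carry code 2.
#'
#' @param grid a [grid2d].
#' @return A list of class `thrombus_state` with `phi`, `active`, and
#'   the per-cell reactive wall area `rwall_area` (m^2 per unit depth).
#' @export
thrombus_init <- function(grid) {
  nx <- grid$nx; ny <- grid$ny
  area <- c(grid$dy, grid$dy, grid$dx, grid$dx)
  rwall <- matrix(0, nx, ny)
  for (s in 1:4) rwall <- rwall + grid$reactive[, , s] * area[s]
  active <- matrix(0L, nx, ny)
  active[rwall > 0] <- 1L
  structure(list(phi = matrix(0, nx, ny), active = active,
                 rwall_area = rwall), class = "thrombus_state")
}

# merged parameter list handed to the compiled kernel
kernel_params <- function(kin, trans) {
  c(unclass(kin),
    unclass(trans)[c("k_rpd_b", "k_apd_b", "k_ra", "k_aa", "tau_sc",
                     "tau_sc_b", "k_clean", "k_stab", "M_inf", "V_p",
                     "phi_max", "phi_crit", "eps_agg")])
}

#' Stable transport step for the species solver
#'
#' Combined advective/diffusive positivity limit for the explicit
#' upwind scheme.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state`.
#' @param trans a [transport_params()].
#' @param safety multiplicative safety factor.
#' @return Time step (s).
#' @export
transport_dt_stable <- function(grid, flow, trans, safety = 0.8) {
  umax <- max(abs(flow$u)); vmax <- max(abs(flow$v))
  Dmax <- max(trans$D_l)
  safety / (umax / grid$dx + vmax / grid$dy +
              2 * Dmax * (1 / grid$dx^2 + 1 / grid$dy^2) + 1e-30)
}

#' Advance the species and thrombus state
#'
#' Runs `nsteps` inner steps of the compiled kernel at fixed flow:
#' upwind advection-diffusion with inlet Dirichlet / outlet advective
#' outflow, the reaction network, surface deposition, shear cleaning,
#' stabilization, and the volume-fraction/propagation update, in that
#' fixed operator-splitting order.
#'
#' @param grid a [grid2d].
#' @param flow a `flow_state` (divergence-free).
#' @param species a `species_state`.
#' @param thrombus a `thrombus_state`.
#' @param kin a [kinetics_params()].
#' @param trans a [transport_params()] (already chi-scaled if desired).
#' @param dt inner time step (s); checked against
#'   [transport_dt_stable()].
#' @param nsteps number of inner steps.
#' @param tau optional precomputed cell shear-stress matrix (Pa);
#'   computed from `flow` when `NULL`.
#' @param mu_f viscosity used when computing `tau` (Pa s).
#' @return List with updated `species`, `thrombus`, and the platelet
#'   ledger increments `inflow`/`outflow` (PLT per unit depth) over the
#'   call.
#' @export
transport_step <- function(grid, flow, species, thrombus, kin, trans,
                           dt, nsteps = 1L, tau = NULL,
                           mu_f = flow_params()$mu_f) {
  dt_max <- transport_dt_stable(grid, flow, trans, safety = 1.0)
  if (dt > dt_max * 1.000001)
    stop(sprintf("dt = %g exceeds transport stability limit %g s (use dt <= %g)",
                 dt, dt_max, transport_dt_stable(grid, flow, trans)))
  if (is.null(tau)) tau <- cell_shear_stress(grid, flow, mu_f)
  res <- cdr_kernel(species$C, species$Cd, thrombus$phi, thrombus$active,
                    flow$u, flow$v, grid$cell_type, thrombus$rwall_area,
                    tau, as.numeric(species$inlet), as.numeric(trans$D_l),
                    kernel_params(kin, trans),
                    grid$dx, grid$dy, dt, as.integer(nsteps))
  species$C <- array(res$C, dim = dim(species$C), dimnames = dimnames(species$C))
  species$Cd <- array(res$Cd, dim = dim(species$Cd),
                      dimnames = dimnames(species$Cd))
  thrombus$phi <- res$phi
  thrombus$active <- res$active
  list(species = species, thrombus = thrombus,
       inflow = res$inflow, outflow = res$outflow)
}

# ---- pure-R reference laws (mirrored in the kernel) ----------------------

#' Surface deposition fluxes (reference implementation)
#'
#' Instantaneous deposition fluxes (PLT/(m^2 s)) for every
#' deposition-active cell: on reactive wall, the virgin-surface flux
#' `k_*pd_b * C * (1 - s)` saturating with monolayer coverage `s`, plus
#' platelet-thrombus deposition `k_ra/k_aa * C` weighted by coverage,
#' by the *activated* fraction of the substrate deposit (activation is
#' what renders deposited platelets adhesive), and by faces shared with
#' critically thrombosed neighbours, with the packing headroom factor
#' `1 - phi/phi_max`.  Fluxes remove free-stream platelets and create
#' the matching deposited species (number conserving).
#'
#' @param grid a [grid2d].
#' @param species a `species_state`.
#' @param thrombus a `thrombus_state`.
#' @param trans a [transport_params()].
#' @param kin a [kinetics_params()] supplying the agonist thresholds
#'   for the aggregation gate.
#' @return data.frame with `ix, iy, j_RP, j_AP` (fluxes per unit
#'   reference area) and the per-cell total deposition rates
#'   `rate_RP, rate_AP` (PLT/(m^3 s)).
#' @export
deposition_fluxes <- function(grid, species, thrombus, trans,
                              kin = kinetics_params()) {
  V <- grid$dx * grid$dy
  act <- which(thrombus$active > 0L, arr.ind = TRUE)
  if (!nrow(act))
    return(data.frame(ix = integer(0), iy = integer(0), j_RP = numeric(0),
                      j_AP = numeric(0), rate_RP = numeric(0),
                      rate_AP = numeric(0)))
  s_cov <- surface_capacity_used(grid, species, thrombus, trans)
  out <- data.frame(ix = act[, 1L], iy = act[, 2L])
  n <- nrow(out)
  jr <- ja <- rr <- ra <- numeric(n)
  ct <- grid$cell_type
  dep_sum <- species$Cd[, , "RPd"] + species$Cd[, , "APd"] +
    species$Cd[, , "APs"]
  w_act <- matrix(0, grid$nx, grid$ny)
  pos <- dep_sum > 0
  w_act[pos] <- (species$Cd[, , "APd"][pos] + species$Cd[, , "APs"][pos]) /
    dep_sum[pos]
  for (r in seq_len(n)) {
    i <- out$ix[r]; j <- out$iy[r]
    Aw <- thrombus$rwall_area[i, j]
    s <- s_cov[i, j]
    At <- 0
    for (sd in 1:4) {
      ii <- i + SIDE_OFFSETS[sd, 1L]; jj <- j + SIDE_OFFSETS[sd, 2L]
      if (ii >= 1L && ii <= grid$nx && jj >= 1L && jj <= grid$ny &&
          ct[ii, jj] == CELL_TYPES[["FLUID"]] &&
          thrombus$phi[ii, jj] >= trans$phi_crit)
        At <- At + (if (sd <= 2L) grid$dy else grid$dx) * w_act[ii, jj]
    }
    head <- max(0, 1 - thrombus$phi[i, j] / trans$phi_max)
    RP <- species$C[i, j, "RP"]; AP <- species$C[i, j, "AP"]
    omega <- species$C[i, j, "ADP"] / kin$crit_ADP +
      species$C[i, j, "TxA2"] / kin$crit_TxA2 +
      species$C[i, j, "T"] / kin$crit_T
    f_agg <- if (omega >= 1) 1 else trans$eps_agg
    jr[r] <- trans$k_rpd_b * RP * (1 - s)
    ja[r] <- trans$k_apd_b * AP * (1 - s)
    rr[r] <- (trans$k_rpd_b * (1 - s) * Aw +
                trans$k_ra * (s * w_act[i, j] * Aw + At) * head * f_agg) *
      RP / V
    ra[r] <- (trans$k_apd_b * (1 - s) * Aw +
                trans$k_aa * (s * w_act[i, j] * Aw + At) * head * f_agg) *
      AP / V
  }
  out$j_RP <- jr; out$j_AP <- ja; out$rate_RP <- rr; out$rate_AP <- ra
  out
}

#' Monolayer capacity consumed per wall cell
#'
#' Fraction `s` in \[0, 1\] of the wall monolayer capacity consumed,
#' computed from the deposited inventory of the cell relative to
#' `M_inf` times its reactive wall area (so cleaning that removes
#' deposited platelets frees capacity consistently).
#'
#' @param grid a [grid2d].
#' @param species a `species_state`.
#' @param thrombus a `thrombus_state`.
#' @param trans a [transport_params()].
#' @return Matrix `nx` x `ny`; 0 where there is no reactive wall.
#' @export
surface_capacity_used <- function(grid, species, thrombus, trans) {
  V <- grid$dx * grid$dy
  dep <- species$Cd[, , "RPd"] + species$Cd[, , "APd"] + species$Cd[, , "APs"]
  s <- matrix(0, grid$nx, grid$ny)
  w <- thrombus$rwall_area > 0
  s[w] <- pmin(1, dep[w] * V / (trans$M_inf * thrombus$rwall_area[w]))
  s
}

#' Shear cleaning rates (reference implementation)
#'
#' `rate = k_clean * max(0, tau/tau* - 1) * ([RP_d] + [AP_d])` with
#' `tau* = tau_sc_b` for platelets on the biomaterial surface and
#' `tau_sc` for platelet-on-platelet layers.  Stabilized platelets
#' (`AP_s`) are never removed; cleaned platelets re-enter the free
#' stream in their pre-deposition state.
#'
#' @param RPd,APd deposited concentrations (PLT/m^3).
#' @param tau_local local shear stress (Pa), >= 0.
#' @param on_surface logical: platelets sit on the biomaterial surface
#'   (else on other platelets).
#' @param trans a [transport_params()].
#' @return Total removal rate (PLT/(m^3 s)), split pro rata between RPd
#'   and APd by the caller.
#' @export
cleaning_rates <- function(RPd, APd, tau_local, on_surface, trans) {
  stopifnot(all(tau_local >= 0))
  tau_star <- ifelse(on_surface, trans$tau_sc_b, trans$tau_sc)
  trans$k_clean * pmax(0, tau_local / tau_star - 1) * (RPd + APd)
}

#' Stabilization rate (reference implementation)
#'
#' Constant-rate conversion of freshly deposited activated platelets to
#' the stable, shear-resistant clot: `rate = k_stab * [AP_d]`.
#'
#' @param APd deposited activated platelet concentration (PLT/m^3).
#' @param trans a [transport_params()].
#' @return Conversion rate (PLT/(m^3 s)).
#' @export
stabilization_rate <- function(APd, trans) {
  stopifnot(all(APd >= 0))
  trans$k_stab * APd
}

#' Recompute the thrombus state from the deposited fields
#'
#' `phi = ([RP_d] + [AP_d] + [AP_s]) * V_p` clipped at `phi_max`; the
#' deposition-active mask is extended to the 4-neighbours of every cell
#' at or above `phi_crit` (deterministic row-major sweep).
#'
#' @param grid a [grid2d].
#' @param species a `species_state`.
#' @param thrombus a `thrombus_state`.
#' @param trans a [transport_params()].
#' @return Updated `thrombus_state`.
#' @export
update_thrombus <- function(grid, species, thrombus, trans) {
  dep <- species$Cd[, , "RPd"] + species$Cd[, , "APd"] + species$Cd[, , "APs"]
  phi <- pmin(dep * trans$V_p, trans$phi_max)
  active <- thrombus$active
  crit <- which(phi >= trans$phi_crit & grid$cell_type == CELL_TYPES[["FLUID"]],
                arr.ind = TRUE)
  if (nrow(crit)) {
    for (r in seq_len(nrow(crit))) {
      for (sd in 1:4) {
        ii <- crit[r, 1L] + SIDE_OFFSETS[sd, 1L]
        jj <- crit[r, 2L] + SIDE_OFFSETS[sd, 2L]
        if (ii >= 1L && ii <= grid$nx && jj >= 1L && jj <= grid$ny &&
            grid$cell_type[ii, jj] == CELL_TYPES[["FLUID"]] &&
            active[ii, jj] == 0L)
          active[ii, jj] <- 2L
      }
    }
  }
  thrombus$phi <- phi
  thrombus$active <- active
  thrombus
}

#' Total deposited platelet inventory (PLT per unit depth)
#'
#' @param grid a [grid2d].
#' @param species a `species_state`.
#' @return Scalar count.
#' @export
deposited_inventory <- function(grid, species) {
  sum(species$Cd) * grid$dx * grid$dy
}

#' Total free-stream platelet inventory (PLT per unit depth)
#'
#' @param grid a [grid2d].
#' @param species a `species_state`.
#' @return Scalar count.
#' @export
freestream_platelet_inventory <- function(grid, species) {
  (sum(species$C[, , "RP"]) + sum(species$C[, , "AP"])) * grid$dx * grid$dy
}
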