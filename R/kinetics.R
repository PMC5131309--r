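# Pointwise (0D) reaction network: platelet activation by an agonist
# threshold, agonist release/synthesis with first-order inhibition,
# thrombin generation on platelet membranes gated by prothrombin, and
# heparin-catalyzed antithrombin inhibition of thrombin (template
# kinetics).
#
# Unit conventions (all configurable; see the methods vignette):
#   platelets         PLT/m^3
#   ADP, TxA2         nmol/m^3
#   thrombin          U/m^3
#   prothrombin, AT   as-configured amounts (inlet defaults carried
#                     through verbatim); linked to thrombin units by the
#                     explicit conversion constants c_PT_per_U, c_AT_per_U.

SPECIES_FREE <- c("RP", "AP", "ADP", "TxA2", "PT", "T", "AT")
SPECIES_DEP <- c("RPd", "APd", "APs")

#' Kinetic parameters of the platelet/agonist network
#'
#' Every constant of the reaction network, exposed so that values
#' transcribed from the source literature drop in directly.  Defaults
#' are the package's reference set (documented, with provenance, in the
#' methods vignette).
#'
#' @param t_act characteristic platelet activation time (s) once the
#'   combined agonist level crosses its critical threshold.
#' @param crit_ADP,crit_TxA2,crit_T critical agonist concentrations
#'   (units of the corresponding species) entering the weighted agonist
#'   sum.
#' @param lambda_ADP ADP released per newly activated platelet
#'   (nmol/PLT).
#' @param beta_TxA2 TxA2 synthesis rate per activated platelet
#'   (nmol/(PLT s)).
#' @param k1_ADP,k1_TxA2 first-order inhibition rate constants (1/s).
#' @param phi_AT,phi_RT thrombin generation rates per activated/resting
#'   platelet (U/(PLT s)).
#' @param c_PT_per_U prothrombin consumed per unit thrombin generated
#'   (configured amount per U).
#' @param c_AT_per_U antithrombin consumed per unit thrombin
#'   neutralized.
#' @param K_PT half-saturation prothrombin level gating thrombin
#'   generation (rate -> 0 as PT -> 0).
#' @param k_cat,K_T,K_AT template-model constants of heparin-catalyzed
#'   thrombin inactivation; the rate is
#'   `k_cat*H*T*AT / (K_T*K_AT + K_T*AT + K_AT*T)`.
#' @param k_uncat optional uncatalyzed first-order thrombin decay (1/s),
#'   default 0 (heparin-only inhibition).
#' @param heparin circulating heparin level (nmol/m^3); baseline 0.1.
#' @param k_shear,alpha_shear shear-activation power law
#'   `k_shear * tau^alpha_shear` (1/s with tau in Pa); `k_shear = 0`
#'   disables shear activation.
#' @param activate_deposited_rp whether deposited resting platelets
#'   activate at the same agonist-driven rate as free ones.
#' @return A list of class `kinetics_params`.
#' @export
kinetics_params <- function(t_act = 1.0,
                            crit_ADP = 2e6, crit_TxA2 = 6e5, crit_T = 100,
                            lambda_ADP = 2.4e-8,
                            beta_TxA2 = 9.5e-12,
                            k1_ADP = 0.0161, k1_TxA2 = 0.0161,
                            phi_AT = 7e-11, phi_RT = 7e-13,
                            c_PT_per_U = 1e-9, c_AT_per_U = 1e-12,
                            K_PT = 5.5e-8,
                            k_cat = 7500, K_T = 10, K_AT = 1.5e-6,
                            k_uncat = 0,
                            heparin = 0.1,
                            k_shear = 0, alpha_shear = 1,
                            activate_deposited_rp = TRUE) {
  p <- list(t_act = t_act, crit_ADP = crit_ADP, crit_TxA2 = crit_TxA2,
            crit_T = crit_T, lambda_ADP = lambda_ADP,
            beta_TxA2 = beta_TxA2, k1_ADP = k1_ADP, k1_TxA2 = k1_TxA2,
            phi_AT = phi_AT, phi_RT = phi_RT,
            c_PT_per_U = c_PT_per_U, c_AT_per_U = c_AT_per_U,
            K_PT = K_PT, k_cat = k_cat, K_T = K_T, K_AT = K_AT,
            k_uncat = k_uncat, heparin = heparin,
            k_shear = k_shear, alpha_shear = alpha_shear,
            activate_deposited_rp = isTRUE(activate_deposited_rp))
  pos <- c("t_act", "crit_ADP", "crit_TxA2", "crit_T", "lambda_ADP",
           "beta_TxA2", "k1_ADP", "k1_TxA2", "c_PT_per_U", "c_AT_per_U",
           "K_PT", "K_T", "K_AT")
  for (nm in pos) if (!is.finite(p[[nm]]) || p[[nm]] <= 0)
    stop(sprintf("%s must be positive", nm))
  nneg <- c("phi_AT", "phi_RT", "k_cat", "k_uncat", "heparin", "k_shear")
  for (nm in nneg) if (!is.finite(p[[nm]]) || p[[nm]] < 0)
    stop(sprintf("%s must be non-negative", nm))
  structure(p, class = "kinetics_params")
}

#' A 0D batch state
#'
#' Named concentration vector for the seven free-stream species, with
#' optional deposited-species levels (held constant by the batch
#' integrator but contributing to agonist and thrombin generation).
#'
#' @param RP,AP resting/activated platelets (PLT/m^3).
#' @param ADP,TxA2 agonists (nmol/m^3).
#' @param PT,T,AT prothrombin, thrombin (U/m^3), antithrombin.
#' @param RPd,APd,APs deposited species (PLT/m^3), optional.
#' @return Named numeric vector of length 7 with attribute `deposited`.
#' @export
batch_state <- function(RP = 3.0e14, AP = 0.01 * RP, ADP = 0, TxA2 = 0,
                        PT = 1.1e-6, T = 0, AT = 2.844e-6,
                        RPd = 0, APd = 0, APs = 0) {
  x <- c(RP = RP, AP = AP, ADP = ADP, TxA2 = TxA2, PT = PT, T = T, AT = AT)
  if (any(!is.finite(x)) || any(x < 0))
    stop("concentrations must be finite and non-negative")
  dep <- c(RPd = RPd, APd = APd, APs = APs)
  if (any(!is.finite(dep)) || any(dep < 0))
    stop("deposited concentrations must be finite and non-negative")
  attr(x, "deposited") <- dep
  x
}

.dep_of <- function(c) {
  dep <- attr(c, "deposited")
  if (is.null(dep)) c(RPd = 0, APd = 0, APs = 0) else dep
}

#' Weighted agonist sum
#'
#' `Omega = [ADP]/crit_ADP + [TxA2]/crit_TxA2 + [T]/crit_T`; resting
#' platelets activate on the time scale `t_act/Omega` once
#' `Omega >= 1`.
#'
#' @param c a [batch_state()] (or any named vector with `ADP`, `TxA2`,
#'   `T`).
#' @param params a [kinetics_params()].
#' @return Dimensionless Omega.
#' @export
activation_omega <- function(c, params = kinetics_params()) {
  unname(c[["ADP"]] / params$crit_ADP + c[["TxA2"]] / params$crit_TxA2 +
           c[["T"]] / params$crit_T)
}

#' Platelet activation rate
#'
#' `rate = [RP] * (k_agonist + k_shear * tau^alpha_shear)` with
#' `k_agonist = Omega/t_act` when `Omega >= 1`, else 0.  The RP loss
#' equals the AP gain: activation converts platelet state and never
#' creates platelets.
#'
#' @param c a [batch_state()].
#' @param tau shear stress (Pa), >= 0.
#' @param params a [kinetics_params()].
#' @return Activation rate (PLT/(m^3 s)).
#' @export
platelet_activation_rate <- function(c, tau = 0, params = kinetics_params()) {
  stopifnot(tau >= 0)
  omega <- activation_omega(c, params)
  k_ag <- if (omega >= 1) omega / params$t_act else 0
  k_sh <- if (params$k_shear > 0 && tau > 0)
    params$k_shear * tau^params$alpha_shear else 0
  unname(c[["RP"]] * (k_ag + k_sh))
}

#' Agonist source terms
#'
#' `S_ADP = lambda_ADP * activation_rate - k1_ADP*[ADP]` (granule
#' release on RP -> AP conversion, first-order inhibition);
#' `S_TxA2 = beta_TxA2 * [AP_eff] - k1_TxA2*[TxA2]` (synthesis by
#' activated platelets, free plus deposited).
#'
#' @param c a [batch_state()].
#' @param activation_rate total RP -> AP conversion rate
#'   (PLT/(m^3 s)), free plus deposited.
#' @param params a [kinetics_params()].
#' @return Named vector `c(ADP = ..., TxA2 = ...)`.
#' @export
agonist_sources <- function(c, activation_rate, params = kinetics_params()) {
  dep <- .dep_of(c)
  ap_eff <- c[["AP"]] + dep[["APd"]]
  c(ADP = params$lambda_ADP * activation_rate - params$k1_ADP * c[["ADP"]],
    TxA2 = params$beta_TxA2 * ap_eff - params$k1_TxA2 * c[["TxA2"]])
}

#' Thrombin generation and prothrombin consumption
#'
#' Thrombin is synthesized from prothrombin on platelet phospholipid
#' membranes: `gen = (phi_AT*[AP_eff] + phi_RT*[RP_eff]) * PT/(PT+K_PT)`
#' so the rate vanishes with the substrate.  Prothrombin is consumed in
#' proportion through the configured unit conversion.
#'
#' @param c a [batch_state()].
#' @param params a [kinetics_params()].
#' @return Named vector `c(T = gen, PT = -c_PT_per_U * gen)`.
#' @export
thrombin_sources <- function(c, params = kinetics_params()) {
  dep <- .dep_of(c)
  ap_eff <- c[["AP"]] + dep[["APd"]]
  rp_eff <- c[["RP"]] + dep[["RPd"]]
  gate <- c[["PT"]] / (c[["PT"]] + params$K_PT)
  gen <- (params$phi_AT * ap_eff + params$phi_RT * rp_eff) * gate
  c(T = gen, PT = -params$c_PT_per_U * gen)
}

#' Heparin-catalyzed thrombin inactivation rate (template model)
#'
#' `rate = k_cat*H*[T]*[AT] / (K_T*K_AT + K_T*[AT] + K_AT*[T])`, plus an
#' optional uncatalyzed first-order term `k_uncat*[T]` (default 0).
#' Thrombin and antithrombin are consumed together (1:1 through the
#' configured unit conversion).
#'
#' @param T_ thrombin concentration (U/m^3).
#' @param AT antithrombin concentration.
#' @param heparin circulating heparin (nmol/m^3).
#' @param params a [kinetics_params()].
#' @return Thrombin consumption rate (U/(m^3 s)).
#' @export
griffith_inhibition_rate <- function(T_, AT, heparin = NULL,
                                     params = kinetics_params()) {
  if (is.null(heparin)) heparin <- params$heparin
  stopifnot(T_ >= 0, AT >= 0, heparin >= 0)
  denom <- params$K_T * params$K_AT + params$K_T * AT + params$K_AT * T_
  params$k_cat * heparin * T_ * AT / denom + params$k_uncat * T_
}

#' Full source vector for the seven free-stream species
#'
#' Composes activation, agonist, thrombin and inhibition kinetics into
#' `S_i` (d\[C_i\]/dt).  Platelet number is conserved exactly across the
#' RP/AP conversion (`S_RP + S_AP = 0` when only activation acts).
#'
#' @param c a [batch_state()].
#' @param tau shear stress (Pa).
#' @param params a [kinetics_params()].
#' @return Named numeric vector of length 7 in [SPECIES_FREE] order.
#' @export
assemble_sources <- function(c, tau = 0, params = kinetics_params()) {
  dep <- .dep_of(c)
  r_free <- platelet_activation_rate(c, tau, params)
  omega <- activation_omega(c, params)
  k_ag <- if (omega >= 1) omega / params$t_act else 0
  k_sh <- if (params$k_shear > 0 && tau > 0)
    params$k_shear * tau^params$alpha_shear else 0
  r_dep <- if (params$activate_deposited_rp)
    dep[["RPd"]] * (k_ag + k_sh) else 0
  ag <- agonist_sources(c, r_free + r_dep, params)
  th <- thrombin_sources(c, params)
  inh <- griffith_inhibition_rate(c[["T"]], c[["AT"]], params$heparin, params)
  out <- c(RP = -r_free,
           AP = r_free,
           ADP = ag[["ADP"]],
           TxA2 = ag[["TxA2"]],
           PT = th[["PT"]],
           T = th[["T"]] - inh,
           AT = -params$c_AT_per_U * inh)
  out
}

# ---- stiff-capable batch integrator --------------------------------------

# numerical Jacobian of the source vector (central differences would
# straddle the activation threshold; forward differences keep the
# perturbed state on the same side for states away from Omega = 1)
.num_jac <- function(c, tau, params, f0) {
  n <- length(c)
  J <- matrix(0, n, n)
  for (k in seq_len(n)) {
    h <- max(abs(c[[k]]), 1e-3) * 1e-7
    cp <- c
    cp[[k]] <- cp[[k]] + h
    J[, k] <- (assemble_sources(cp, tau, params) - f0) / h
  }
  J
}

# one L-stable two-stage Rosenbrock (ROS2) step, gamma = 1 + 1/sqrt(2).
# Species scales differ by ~20 orders of magnitude, so the stage systems
# are solved in diagonally scaled variables z = y/s.
.ros2_step <- function(y, h, tau, params, J, s) {
  gam <- 1 + 1 / sqrt(2)
  n <- length(y)
  Jz <- J * outer(1 / s, s)
  A <- diag(n) - h * gam * Jz
  f1 <- assemble_sources(y, tau, params)
  k1 <- tryCatch(s * solve(A, f1 / s), error = function(e) NULL)
  if (is.null(k1)) return(NULL)          # singular stage: reject the step
  y2 <- y + h * k1
  attributes(y2) <- attributes(y)
  y2[y2 < 0] <- 0
  f2 <- assemble_sources(y2, tau, params)
  k2 <- tryCatch(s * solve(A, (f2 - 2 * k1) / s), error = function(e) NULL)
  if (is.null(k2)) return(NULL)
  out <- y + h * (1.5 * k1 + 0.5 * k2)
  attributes(out) <- attributes(y)
  out
}

#' Integrate a batch reaction network
#'
#' Advances `dC/dt = S(C)` for the seven free-stream species with an
#' L-stable second-order Rosenbrock scheme and step-doubling error
#' control.  Deposited species attached to `c0` are held constant but
#' feed the agonist/thrombin sources.  Concentrations remain
#' non-negative (steps that would undershoot are retried; residual
#' negatives below the absolute tolerance are clamped).
#'
#' @param c0 initial [batch_state()].
#' @param t_end final time (s), > 0.
#' @param params a [kinetics_params()].
#' @param tau constant shear stress (Pa).
#' @param times output times (s); default 101 equispaced points
#'   including 0 and `t_end`.  Steps land exactly on output times.
#' @param rtol,atol relative/absolute local error tolerances; `atol` is
#'   per-species (scaled by the initial magnitudes when `NULL`).
#' @return A list with `times` and `states` (matrix, rows = times,
#'   columns = species).
#' @export
integrate_batch <- function(c0, t_end, params = kinetics_params(), tau = 0,
                            times = NULL, rtol = 1e-8, atol = NULL) {
  if (!is.finite(t_end) || t_end <= 0) stop("t_end must be positive")
  if (is.null(times)) times <- seq(0, t_end, length.out = 101L)
  times <- sort(unique(c(0, times)))
  if (max(times) > t_end + 1e-12) stop("output times exceed t_end")
  # characteristic magnitudes per species: floors for the error weights
  # and the diagonal scaling (species that start at zero still need a
  # sane scale or the scaled Jacobian degenerates)
  floors <- pmax(abs(c0), c(RP = 1e12, AP = 1e10, ADP = 1e4, TxA2 = 1e3,
                            PT = 1e-8, T = 0.1, AT = 1e-8))
  if (is.null(atol)) atol <- floors * 1e-10
  y <- c0
  out <- matrix(NA_real_, length(times), length(SPECIES_FREE),
                dimnames = list(NULL, SPECIES_FREE))
  out[1L, ] <- as.numeric(y)
  t <- 0
  h <- t_end / 1000
  for (m in seq_along(times)[-1L]) {
    t_target <- times[m]
    sing_fails <- 0L
    while (t < t_target - 1e-14 * t_end) {
      h <- min(h, t_target - t)
      f0 <- assemble_sources(y, tau, params)
      # near the activation threshold the finite-difference Jacobian
      # straddles the rate jump and can make the stage system singular;
      # ROS2 is a W-method, so falling back to J = 0 (explicit) after
      # repeated singular rejections is legitimate -- step control still
      # governs the accuracy
      J <- if (sing_fails >= 2L) matrix(0, length(y), length(y)) else
        .num_jac(y, tau, params, f0)
      s <- pmax(abs(y), 1e-3 * floors)
      y_big <- .ros2_step(y, h, tau, params, J, s)
      y_half <- if (is.null(y_big)) NULL else
        .ros2_step(y, h / 2, tau, params, J, s)
      y_small <- if (is.null(y_half)) NULL else
        .ros2_step(y_half, h / 2, tau, params, J, s)
      if (is.null(y_small)) {
        sing_fails <- sing_fails + 1L
        h <- h / 2
        if (h < 1e-14 * t_end)
          stop("integrator failure: singular stage system at t = ", t)
        next
      }
      sing_fails <- 0L
      err <- max(abs(y_big - y_small) / (atol + rtol * pmax(abs(y), abs(y_small))))
      err <- err / 3  # second-order step-doubling estimate
      if (is.finite(err) && err <= 1) {
        y_new <- y_small
        neg <- y_new < 0
        if (any(y_new < -atol)) {        # significant undershoot: retry
          h <- h / 2
          if (h < 1e-14 * t_end)
            stop("integrator failure: step size underflow at t = ", t)
          next
        }
        y_new[neg] <- 0
        attributes(y_new) <- attributes(y)
        y <- y_new
        t <- t + h
        h <- h * min(4, max(0.2, 0.85 * err^(-1 / 3)))
      } else {
        h <- h / 2
        if (h < 1e-14 * t_end)
          stop("integrator failure: step size underflow at t = ", t,
               " (last valid state retained in output)")
      }
    }
    out[m, ] <- as.numeric(y)
  }
  list(times = times, states = out)
}
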