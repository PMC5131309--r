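---
title: "hemoclot: model, numerics, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{hemoclot: model, numerics, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The model

`hemoclot` simulates device-related thrombosis as a multi-constituent
continuum: an incompressible Newtonian fluid phase (plasma plus red
cells) interacting with a porous solid phase (the deposited-platelet
bed), coupled to a ten-species convection–diffusion–reaction (CDR)
network for platelets and their biochemical agonists.

## Hemodynamics

The fluid phase obeys incompressible continuity and momentum equations
with a momentum sink exerted by the thrombus,

$$\rho_f \left( \partial_t \mathbf{v}_f + \mathbf{v}_f \cdot \nabla
\mathbf{v}_f \right) = -\nabla p + \mu_f \nabla^2 \mathbf{v}_f
- C_2\, f(\phi)\, (\mathbf{v}_f - \mathbf{v}_T),$$

where $\phi$ is the deposited-platelet volume fraction,
$f(\phi) = \phi(1 + 6.5\phi)$ is the hindrance function of a densely
packed particle assemblage, $C_2 = 2\times10^9\ \mathrm{kg/(m^3 s)}$,
$\mu_f = 3.5$ cP, and $\rho_{f0} = 1060\ \mathrm{kg/m^3}$. Only static
(stator-like) walls are modelled, so $\mathbf{v}_T = 0$. The eddy
viscosity slot (`nu_t` in `flow_params()`) is retained but zero: the
desk-scale runs are laminar (channel Reynolds numbers of order 10).
The mixture density is held at $\rho_{f0}$: the $\rho(\phi)$ relation
of the source model is not reproducible from the text, and thrombosed
regions are nearly stagnant, so the momentum effect is negligible.

## Species network

Seven free-stream species are advected and diffused: resting and
activated platelets (RP, AP), the released agonist ADP, the synthesized
agonist TxA2, prothrombin (PT), thrombin (T), and antithrombin (AT).
Three deposited species (RP$_d$, AP$_d$, AP$_s$) have rate equations
only. The mechanisms:

1. **Activation.** The weighted agonist sum
   $\Omega = [\mathrm{ADP}]/c_{\mathrm{ADP}} +
   [\mathrm{TxA2}]/c_{\mathrm{TxA2}} + [T]/c_T$ converts RP to AP at
   rate $\Omega/t_{act}$ once $\Omega \ge 1$ (below threshold the
   resting pool is exactly constant); an optional shear power law
   $k_s \tau^{\alpha}$ adds to the rate (off by default — the source
   names shear as an agonist but gives no form).
2. **Agonist generation.** ADP is released at $\lambda_{\mathrm{ADP}}$
   per newly activated platelet; TxA2 is synthesized by activated
   platelets (free and deposited) at $\beta_{\mathrm{TxA2}}$ per
   platelet; both are inhibited by first-order constants $k_1$.
   Thrombin is generated on platelet membranes at
   $\varphi_{AT}[\mathrm{AP}] + \varphi_{RT}[\mathrm{RP}]$, gated by
   $[\mathrm{PT}]/([\mathrm{PT}] + K_{PT})$ so the rate vanishes with
   the substrate, consuming prothrombin through an explicit unit
   conversion.
3. **Deposition.** Platelet–surface adhesion is a surface flux
   $k_{rpd,b}[\mathrm{RP}](1-s)$, $k_{apd,b}[\mathrm{AP}](1-s)$ on
   reactive walls, saturating with the monolayer coverage
   $s = N_d V_{cell} / (M_\infty A_{wall}) \le 1$. Coverage is derived
   from the deposited inventory itself, so cleaning frees capacity
   consistently. Platelet–thrombus deposition ($k_{ra}, k_{aa}$) acts
   on covered wall and on faces shared with critically thrombosed
   neighbours, weighted by the *activated fraction* of the substrate
   deposit and by the packing headroom $1-\phi/\phi_{max}$.
4. **Propagation.** When a cell reaches
   $\phi_{crit} = 0.9\,\phi_{max}$, its 4-neighbours become
   deposition-active (deterministic row-major sweep).
5. **Cleaning.** Shear removes unstabilized deposits at
   $k_{clean}\max(0, \tau/\tau^* - 1)$, with $\tau^* = \tau_{sc,b}$ for
   platelets on the biomaterial and $\tau_{sc} = 15$ dyne/cm² for
   platelet-on-platelet layers. The *surface-exposed* stress is used:
   the maximum of the cell's own and its fluid neighbours'
   shear-stress magnitude. This matters — as a cell thromboses, its
   porous drag stagnates the flow inside it, and a purely cell-local
   stress would shelter the deposit from the washing it causes.
   Cleaned platelets re-enter the free stream in their pre-deposition
   state.
6. **Inhibition.** Thrombin is inactivated by antithrombin under
   heparin catalysis with the template-model rate
   $k_{cat} H [T][AT] / (K_T K_{AT} + K_T[AT] + K_{AT}[T])$,
   consuming AT 1:1 through a unit conversion. The rate is linear in
   heparin and *saturates in thrombin* — at high $[T]$ the removal
   capacity approaches $k_{cat} H [AT]/K_{AT}$, which is what makes
   thrombin generation an ignition switch (below).
7. **Stabilization.** AP$_d$ converts to the shear-immune AP$_s$ at the
   constant rate $k_{stab}$.
8. **Thrombus–fluid interaction.** $\phi = (RP_d + AP_d + AP_s)V_p$
   feeds the drag coefficient $C_2 f(\phi)$ at the next flow update.

Effective diffusivity is $D = D_l + \nu_t/\mathrm{Sc}$ with
$\mathrm{Sc} = 0.9$ (the turbulent term is a retained, inactive hook).

## Time-scale compression

Clinical deposition takes hours; resolving it directly is prohibitive.
Following the source model, the four deposition constants
$k_{ra}, k_{aa}, k_{rpd,b}, k_{apd,b}$ — and only those — are scaled by
$\chi = 30$ (`scale_reaction_rates()`), and all reported output times
are multiplied by $\chi$. This is defensible because the surface
Damköhler numbers are large (deposition is transport-limited, so
speeding the kinetics barely changes the flux); `run_simulation()`
records them in the run manifest.

# Numerics

* **Flow.** Fractional-step (projection) scheme on a staggered (MAC)
  grid: first-order upwind advection, explicit viscous diffusion, and
  the Darcy sink folded *inside* the projection — with
  $b = 1/(1 + \Delta t\, C_2 f(\phi)/\rho)$ the corrected velocity is
  $u = b(u^* - \tfrac{\Delta t}{\rho}\nabla p)$, giving a
  variable-coefficient Poisson equation $\nabla\!\cdot(b\nabla p)$
  solved by a cached sparse Cholesky factorization. This recovers the
  exact steady Darcy–Brinkman balance (the plug-flow pressure gradient
  matches $C_2 f(\phi) U$ to a few times $10^{-5}$ in the tests) and is
  unconditionally stable in the drag term, which reaches
  $\sim 10^{10}\ \mathrm{kg/(m^3 s)}$ at $\phi_{max}$.
* **Quasi-steady flow.** Deposition time scales are much longer than
  flow relaxation, so the flow is held frozen and re-solved to steady
  state (warm-started) on a cadence or when
  $\max|\Delta\phi| > 0.02$ since the last solve.
* **Species.** Finite-volume upwind advection and central diffusion,
  explicit in time under a combined positivity/CFL limit; reactions use
  exact exponential updates for the linear pathways (activation
  transfer, agonist decay/relaxation, deposition, cleaning,
  stabilization) and explicit limited updates for thrombin, so every
  inter-species transfer is exactly conservative and positivity is
  preserved by construction. The per-step splitting order is fixed:
  transport → volumetric reactions → surface fluxes → cleaning →
  stabilization → φ/propagation update.
* **Wall shear.** Two-point one-sided quadratic gradient
  $\tau = \mu(9u_1 - u_2)/(3\Delta n)$, exact for parabolic profiles;
  one-point fallback beside stair-step corners.
* **0D integrator.** `integrate_batch()` is an L-stable two-stage
  Rosenbrock (ROS2, $\gamma = 1 + 1/\sqrt2$) with step-doubling error
  control, solved in diagonally scaled variables (species magnitudes
  span twenty orders). The activation threshold makes the
  finite-difference Jacobian discontinuous; since ROS2 is a W-method,
  the integrator falls back to an explicit (zero-Jacobian) step after
  repeated singular stage systems, with step control still governing
  accuracy. Characteristic per-species scale floors weight both the
  error norm and the scaling.
* **Determinism.** Single-threaded, no random numbers, fixed row-major
  sweeps; repeated runs agree bit-for-bit, and checkpoints (plain text,
  `%.17g`, which round-trips IEEE doubles exactly) resume to
  bit-identical results.

# The synthetic world and its calibration

All geometries are generated programmatically: a straight channel, a
backward-facing step, and a **crevice channel** — a channel with a
rectangular cavity in the lower wall emulating the stagnant
bearing-crevice region of a rotary blood pump. Only the cavity walls
are platelet-adhesive in the crevice preset, mirroring the localized
susceptibility of the bearing region.

The paper-anchored constants are used exactly (viscosity, density,
$C_2$, hindrance, Sc, $\tau_{sc}$, $\chi$, inlet concentrations,
heparin levels, the coating factor, the flow-rate ratios). Every other
rate constant lives in references that print none of them, so the
package fixes its own reference set, chosen **once** so that the
desk-scale surrogate reproduces the qualitative regime of the device
study inside the stated world (a 60-second simulated run at
$\chi = 30$ on a grid of a few thousand cells):

* The thrombin loop is an **ignition switch**: pre-ignition, the slow
  platelet–surface flux builds a monolayer whose activated fraction
  generates thrombin; ignition occurs where generation outruns the
  saturated inhibition capacity plus advective washout, converting the
  local resting pool and starting rapid aggregation. Baseline heparin
  (0.1 nmol/m³) ignites in tens of seconds; the bolus (0.3 nmol/m³)
  triples the inhibition capacity and delays or prevents ignition —
  the heparin effect in this model acts on the trigger, not on the
  mechanics of an established clot.
* Platelet dispersion is set to a device-scale shear-enhanced value
  ($2\times10^{-8}\ \mathrm{m^2/s}$): the cavity vortex is a closed
  streamline region, so platelet supply crosses it diffusively, and a
  molecular-scale coefficient would starve deposition at desk scale
  entirely. Biochemical species keep molecular-scale diffusivities.
* The cleaning thresholds sit inside the measured shear distribution of
  the crevice preset at the nominal flow, so the flow-rate sweep
  discriminates: at low flow the cavity is entirely below threshold, at
  high flow most of the floor is scrubbed, and the channel-wall stress
  straddles $\tau_{sc}$ so an escaping clot is confined at nominal and
  high flow but not at low flow.

What a green scenario test establishes — and what it does not: the
surrogate reproduces the *mechanisms* (stagnation-localized deposition,
slow-then-fast growth after a critical deposit, washing equilibrium on
exposed surfaces, suppression by heparin and surface chemistry, and the
flow-rate ordering of the final burden). It does not reproduce the
source study's numbers: those were produced on a proprietary 3D pump
geometry at 9000 RPM with a turbulence model, none of which exist
here. No quantitative value from that study is asserted by the tests.

## The frozen reference calibration

The package defaults (all user-overridable) were fixed once, after
pilot exploration of the crevice surrogate, and are not tuned per
scenario — every scenario study derives from the same set by exactly
the documented intervention:

* geometry: channel 1 mm high and 5 mm long, 1 mm x 0.2 mm cavity,
  20 cells across the channel (50 µm cells, grid 100 x 24); nominal
  inlet speed 0.1 m/s (Re ≈ 30, laminar);
* diffusivities (m²/s): platelets 2e-8 (device-scale shear-enhanced
  dispersion), ADP/TxA2 2.5e-10, prothrombin 3.3e-11, thrombin
  4.2e-11, antithrombin 3.5e-11;
* deposition velocities (m/s, before χ): k_rpd_b = k_apd_b = 1e-6
  (surface adhesion), k_ra = 5e-6, k_aa = 1e-3 (aggregation onto
  activated thrombus), sub-threshold aggregation efficiency
  eps_agg = 0.02;
* cleaning: k_clean = 10 s⁻¹, τ_sc = 1.5 Pa (printed source value),
  τ_sc,b = 0.45 Pa — chosen inside the measured shear distribution of
  the cavity floor so the washing response discriminates the three
  flow rates; stabilization k_stab = 0.01 s⁻¹;
* activation thresholds: c_ADP = 2e6 nmol/m³ (2 µM),
  c_TxA2 = 6e5 nmol/m³, c_T = 100 U/m³; t_act = 1 s;
* thrombin loop: phi_AT = 7e-11, phi_RT = 7e-13 U/(PLT s),
  k_cat = 7500, K_T = 10 U/m³, K_AT = 1.5e-6, unit conversions
  c_PT_per_U = 1e-9, c_AT_per_U = 1e-12. With these, the baseline
  heparin level ignites the crevice within seconds (generation on the
  accumulating monolayer outruns the saturated inhibition capacity)
  while the 3x capacity of the bolus prevents ignition for the whole
  run; antithrombin consumption is negligible over the simulated hour,
  so the switch does not decay by local antithrombin starvation.

Two interpretation choices deserve emphasis because pilots showed the
scenario physics collapse without them: platelet–thrombus aggregation
is weighted by the activated fraction of the substrate deposit *and*
gated by the local agonist threshold (below Ω = 1 only `eps_agg` of
the capture efficiency remains). Without the first, resting platelets
aggregate regardless of biochemistry; without the second, the
activated fraction is self-amplifying at any heparin level (each
activated landing raises the weight), and anticoagulation has no
pathway to act on. Both are documented model commitments, not fits to
any quantitative target.

# Degenerate inputs and tie-breaks

Closed boxes (no inlet/outlet) are legal test domains; the pressure is
then pinned at one cell and the Poisson right-hand side projected onto
the compatible space. Zero inlet velocity and zero fields are exact
fixed points of both solvers. Outlet backflow advects the interior
value (zero-gradient). Stair-step corners use the one-point wall-shear
form. Deposition transfers are capped so $\phi$ cannot exceed
$\phi_{max}$ even within a single step; cleaning and stabilization use
exact exponential factors so deposits cannot go negative.

# Known limitations

No plasma skimming or near-wall platelet enrichment; no
rotating-frame/impeller mechanics ($\mathbf{v}_T = 0$); no turbulence
closure; thrombus is rigid and non-embolizing; the coagulation cascade
beyond prothrombin/thrombin/ATIII (factors V–XII, fibrin, vWF) is out
of scope; stair-step walls bias near-wall shear at corners by design
(documented fallbacks); and the Table 1 unit system is carried as
configuration without physiological reinterpretation.
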