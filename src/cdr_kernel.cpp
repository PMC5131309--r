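// Hot loop of the species solver: finite-volume upwind
// advection-diffusion of the seven free-stream species, pointwise
// reaction network, surface deposition with monolayer saturation and
// thrombus-phase growth, shear cleaning, stabilization, and the
// deposited-volume-fraction / propagation-mask update.
//
// All transfers between species are exact (amount removed == amount
// added), so the platelet-number ledger closes to rounding error.
// Sweeps are row-major (x fastest) and single-threaded: runs are
// bit-reproducible.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int FLUID = 0, SOLID = 1, INLET = 2, OUTLET = 3;
// species indices in the free-stream block
static const int iRP = 0, iAP = 1, iADP = 2, iTx = 3, iPT = 4, iT = 5, iAT = 6;
// deposited block
static const int iRPd = 0, iAPd = 1, iAPs = 2;

struct Pars {
  double t_act, crit_ADP, crit_TxA2, crit_T;
  double lambda_ADP, beta_TxA2, k1_ADP, k1_TxA2;
  double phi_AT, phi_RT, c_PT_per_U, c_AT_per_U, K_PT;
  double k_cat, K_T, K_AT, k_uncat, heparin, k_shear, alpha_shear;
  bool act_dep;
  double k_rpd_b, k_apd_b, k_ra, k_aa;
  double tau_sc, tau_sc_b, k_clean, k_stab;
  double M_inf, V_p, phi_max, phi_crit, eps_agg;
};

static Pars read_pars(const List& par) {
  Pars p;
  p.t_act = par["t_act"]; p.crit_ADP = par["crit_ADP"];
  p.crit_TxA2 = par["crit_TxA2"]; p.crit_T = par["crit_T"];
  p.lambda_ADP = par["lambda_ADP"]; p.beta_TxA2 = par["beta_TxA2"];
  p.k1_ADP = par["k1_ADP"]; p.k1_TxA2 = par["k1_TxA2"];
  p.phi_AT = par["phi_AT"]; p.phi_RT = par["phi_RT"];
  p.c_PT_per_U = par["c_PT_per_U"]; p.c_AT_per_U = par["c_AT_per_U"];
  p.K_PT = par["K_PT"]; p.k_cat = par["k_cat"]; p.K_T = par["K_T"];
  p.K_AT = par["K_AT"]; p.k_uncat = par["k_uncat"];
  p.heparin = par["heparin"]; p.k_shear = par["k_shear"];
  p.alpha_shear = par["alpha_shear"];
  p.act_dep = as<bool>(par["activate_deposited_rp"]);
  p.k_rpd_b = par["k_rpd_b"]; p.k_apd_b = par["k_apd_b"];
  p.k_ra = par["k_ra"]; p.k_aa = par["k_aa"];
  p.tau_sc = par["tau_sc"]; p.tau_sc_b = par["tau_sc_b"];
  p.k_clean = par["k_clean"]; p.k_stab = par["k_stab"];
  p.M_inf = par["M_inf"]; p.V_p = par["V_p"];
  p.phi_max = par["phi_max"]; p.phi_crit = par["phi_crit"];
  p.eps_agg = par["eps_agg"];
  return p;
}

// [[Rcpp::export]]
List cdr_kernel(NumericVector C_, NumericVector Cd_, NumericMatrix phi_,
                IntegerMatrix active_, NumericMatrix u, NumericMatrix v,
                IntegerMatrix celltype, NumericMatrix rwall_area,
                NumericMatrix tau, NumericVector c_in, NumericVector Dvec,
                List par, double dx, double dy, double dt, int nsteps) {
  NumericVector C = clone(C_);
  NumericVector Cd = clone(Cd_);
  NumericMatrix phi = clone(phi_);
  IntegerMatrix active = clone(active_);
  IntegerVector dimC = C.attr("dim");
  const int nx = dimC[0], ny = dimC[1];
  const int ncell = nx * ny;
  const Pars p = read_pars(par);
  const double V = dx * dy;               // cell volume per unit depth

  std::vector<double> Cold(static_cast<size_t>(ncell) * 7);
  double inflow = 0.0, outflow = 0.0;     // platelet counts (RP + AP)

  auto ct = [&](int i, int j) -> int {
    if (i < 0 || i >= nx || j < 0 || j >= ny) return SOLID;
    return celltype(i, j);
  };
  auto idx = [&](int i, int j, int s) -> int { return i + nx * (j + ny * s); };

  // precompute the face table of every fluid cell once per call: the
  // geometry and cell classification are fixed while the flow is frozen
  struct Face {
    int nidx;        // neighbour cell index (fluid), or -1
    int kind;        // 0 fluid-fluid, 1 inlet, 2 outlet
    double qa;       // outward normal velocity * face area (filled later)
    double da;       // diffusive area / spacing factor
  };
  struct CellF {
    int c;           // cell index i + nx*j
    int nf;
    Face face[4];
  };
  std::vector<CellF> cells;
  cells.reserve(static_cast<size_t>(ncell));
  const double *up = u.begin();
  const double *vp = v.begin();
  const int ustride = nx + 1;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (celltype(i, j) != FLUID) continue;
      CellF cf; cf.c = i + nx * j; cf.nf = 0;
      const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
      for (int f = 0; f < 4; ++f) {
        const int nt = ct(i + di[f], j + dj[f]);
        if (nt == SOLID) continue;
        Face fc;
        double vel, area, sgn;
        if (f == 0) { area = dy; vel = up[i + ustride * j]; sgn = -1.0; }
        else if (f == 1) { area = dy; vel = up[i + 1 + ustride * j]; sgn = 1.0; }
        else if (f == 2) { area = dx; vel = vp[i + nx * j]; sgn = -1.0; }
        else { area = dx; vel = vp[i + nx * (j + 1)]; sgn = 1.0; }
        fc.qa = sgn * vel * area;
        fc.nidx = (i + di[f]) + nx * (j + dj[f]);
        if (nt == FLUID) {
          fc.kind = 0;
          fc.da = area / (di[f] != 0 ? dx : dy);
        } else {
          fc.kind = (nt == INLET) ? 1 : 2;
          fc.da = 0.0;
        }
        cf.face[cf.nf++] = fc;
      }
      cells.push_back(cf);
    }
  }

  double *Cp = C.begin();
  // constant-argument decay factors, hoisted out of the cell loop
  const double eADP = std::exp(-p.k1_ADP * dt);
  const double eTx = std::exp(-p.k1_TxA2 * dt);
  const double fstab = (p.k_stab > 0.0) ? 1.0 - std::exp(-p.k_stab * dt) : 0.0;

  for (int step = 0; step < nsteps; ++step) {
    // ---- 1. advection-diffusion of free-stream species -----------------
    std::copy(Cp, Cp + static_cast<size_t>(ncell) * 7, Cold.begin());
    const double dtV = dt / V;
    for (size_t ci = 0; ci < cells.size(); ++ci) {
      const CellF &cf = cells[ci];
      for (int s = 0; s < 7; ++s) {
        const double D = Dvec[s];
        const double *Co = &Cold[static_cast<size_t>(ncell) * s];
        const double cc = Co[cf.c];
        double net = 0.0;                 // outward flux sum (amount/s/depth)
        for (int f = 0; f < cf.nf; ++f) {
          const Face &fc = cf.face[f];
          const double q = fc.qa;
          if (fc.kind == 0) {
            const double cn = Co[fc.nidx];
            net += (q > 0 ? q * cc : q * cn) - D * fc.da * (cn - cc);
          } else if (fc.kind == 1) {      // inlet: advective only
            const double adv = (q > 0 ? q * cc : q * c_in[s]);
            net += adv;
            if (s <= iAP) inflow += -adv * dt;
          } else {                        // outlet: zero-gradient upwind
            net += q * cc;
            if (s <= iAP) outflow += q * cc * dt;
          }
        }
        Cp[cf.c + ncell * s] = cc - dtV * net;
      }
    }

    // ---- 2. pointwise reactions ----------------------------------------
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (celltype(i, j) != FLUID) continue;
        double RP = C[idx(i, j, iRP)], AP = C[idx(i, j, iAP)];
        double ADP = C[idx(i, j, iADP)], Tx = C[idx(i, j, iTx)];
        double PT = C[idx(i, j, iPT)], T = C[idx(i, j, iT)];
        double AT = C[idx(i, j, iAT)];
        double RPd = Cd[idx(i, j, iRPd)], APd = Cd[idx(i, j, iAPd)];
        double APs = Cd[idx(i, j, iAPs)];
        // activation: threshold agonist sum + shear power law
        const double omega = ADP / p.crit_ADP + Tx / p.crit_TxA2 + T / p.crit_T;
        double k_act = (omega >= 1.0) ? omega / p.t_act : 0.0;
        if (p.k_shear > 0.0 && tau(i, j) > 0.0)
          k_act += p.k_shear * std::pow(tau(i, j), p.alpha_shear);
        double dRP = 0.0, dRPd = 0.0;
        if (k_act > 0.0) {
          const double fr = 1.0 - std::exp(-k_act * dt);
          dRP = RP * fr; RP -= dRP; AP += dRP;
          if (p.act_dep) { dRPd = RPd * fr; RPd -= dRPd; APd += dRPd; }
        }
        // ADP: exact first-order decay + granule release on activation
        ADP = ADP * eADP + p.lambda_ADP * (dRP + dRPd);
        // TxA2: synthesis by activated platelets (free + deposited),
        // exact linear relaxation over the step
        const double ap_eff = AP + APd;
        Tx = Tx * eTx + (p.beta_TxA2 * ap_eff / p.k1_TxA2) * (1.0 - eTx);
        // thrombin generation gated by prothrombin
        double gen = (p.phi_AT * ap_eff + p.phi_RT * (RP + RPd)) *
          (PT / (PT + p.K_PT));
        if (gen > 0.0) {
          const double gmax = PT / (p.c_PT_per_U * dt);
          if (gen > gmax) gen = gmax;
          T += gen * dt;
          PT -= p.c_PT_per_U * gen * dt;
          if (PT < 0.0) PT = 0.0;
        }
        // heparin-catalyzed (template) thrombin inactivation, 1:1 with AT
        if (T > 0.0 && AT > 0.0) {
          double rg = p.k_cat * p.heparin * T * AT /
            (p.K_T * p.K_AT + p.K_T * AT + p.K_AT * T) + p.k_uncat * T;
          const double rmax = std::min(T / dt, AT / (p.c_AT_per_U * dt));
          if (rg > rmax) rg = rmax;
          T -= rg * dt;
          AT -= p.c_AT_per_U * rg * dt;
          if (T < 0.0) T = 0.0;
          if (AT < 0.0) AT = 0.0;
        }

        // ---- 3. surface deposition (active cells) ----------------------
        // Platelet-thrombus aggregation needs an *activated* substrate:
        // the thrombus-growth term is weighted by the activated fraction
        // of the deposit it lands on (activation is what renders
        // deposited platelets adhesive).
        const int act = active(i, j);
        if (act > 0) {
          const double Aw = rwall_area(i, j);
          const double depsum = RPd + APd + APs;
          const double wact = depsum > 0.0 ? (APd + APs) / depsum : 0.0;
          double scov = 0.0;
          if (Aw > 0.0) {
            scov = depsum * V / (p.M_inf * Aw);
            if (scov > 1.0) scov = 1.0;
          }
          // faces shared with critically thrombosed neighbours, weighted
          // by the neighbour deposit's activated fraction
          double At = 0.0;
          const int dif[4] = {-1, 1, 0, 0}, djf[4] = {0, 0, -1, 1};
          for (int f = 0; f < 4; ++f) {
            const int ii = i + dif[f], jj = j + djf[f];
            if (ct(ii, jj) != FLUID || phi(ii, jj) < p.phi_crit) continue;
            const double nd = Cd[idx(ii, jj, iRPd)] + Cd[idx(ii, jj, iAPd)] +
              Cd[idx(ii, jj, iAPs)];
            const double wn = nd > 0.0 ?
              (Cd[idx(ii, jj, iAPd)] + Cd[idx(ii, jj, iAPs)]) / nd : 0.0;
            At += (f < 2 ? dy : dx) * wn;
          }
          const double head = 1.0 - phi(i, j) / p.phi_max;
          if (head > 0.0 && (Aw > 0.0 || At > 0.0)) {
            // stable incorporation into a growing aggregate needs local
            // agonist support: below the activation threshold only a
            // small residual efficiency eps_agg remains
            const double f_agg = (omega >= 1.0) ? 1.0 : p.eps_agg;
            const double kR = (p.k_rpd_b * (1.0 - scov) * Aw +
                               p.k_ra * (scov * wact * Aw + At) * head * f_agg) / V;
            const double kA = (p.k_apd_b * (1.0 - scov) * Aw +
                               p.k_aa * (scov * wact * Aw + At) * head * f_agg) / V;
            double tr = RP * (1.0 - std::exp(-kR * dt));
            double ta = AP * (1.0 - std::exp(-kA * dt));
            const double headN = (p.phi_max - phi(i, j)) / p.V_p;
            const double tot = tr + ta;
            if (tot > headN && tot > 0.0) {
              const double sc = headN / tot;
              tr *= sc; ta *= sc;
            }
            RP -= tr; RPd += tr;
            AP -= ta; APd += ta;
          }
        }

        // ---- 4. shear cleaning (stabilized APs is immune) ---------------
        // Erosion acts on the exposed surface of the deposit: the bed
        // interior is sheltered (porous drag stagnates it), so the
        // relevant stress is the largest of the cell's own and its
        // fluid neighbours' shear.
        if (RPd + APd > 0.0 && p.k_clean > 0.0) {
          const double tau_star = (rwall_area(i, j) > 0.0) ? p.tau_sc_b
                                                           : p.tau_sc;
          double tau_loc = tau(i, j);
          const int dic[4] = {-1, 1, 0, 0}, djc[4] = {0, 0, -1, 1};
          for (int f = 0; f < 4; ++f) {
            const int ii = i + dic[f], jj = j + djc[f];
            if (ct(ii, jj) == FLUID && tau(ii, jj) > tau_loc)
              tau_loc = tau(ii, jj);
          }
          const double excess = tau_loc / tau_star - 1.0;
          if (excess > 0.0) {
            const double fr = 1.0 - std::exp(-p.k_clean * excess * dt);
            const double cr = RPd * fr, ca = APd * fr;
            RPd -= cr; RP += cr;
            APd -= ca; AP += ca;
          }
        }

        // ---- 5. stabilization ------------------------------------------
        if (APd > 0.0 && fstab > 0.0) {
          const double st = APd * fstab;
          APd -= st; APs += st;
        }

        C[idx(i, j, iRP)] = RP; C[idx(i, j, iAP)] = AP;
        C[idx(i, j, iADP)] = ADP; C[idx(i, j, iTx)] = Tx;
        C[idx(i, j, iPT)] = PT; C[idx(i, j, iT)] = T;
        C[idx(i, j, iAT)] = AT;
        Cd[idx(i, j, iRPd)] = RPd; Cd[idx(i, j, iAPd)] = APd;
        Cd[idx(i, j, iAPs)] = APs;
        // ---- 6a. volume fraction ---------------------------------------
        phi(i, j) = (RPd + APd + APs) * p.V_p;
      }
    }

    // ---- 6b. propagation: activate neighbours of critical cells --------
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        if (celltype(i, j) != FLUID || phi(i, j) < p.phi_crit) continue;
        const int di[4] = {-1, 1, 0, 0}, dj[4] = {0, 0, -1, 1};
        for (int f = 0; f < 4; ++f) {
          const int ii = i + di[f], jj = j + dj[f];
          if (ct(ii, jj) == FLUID && active(ii, jj) == 0)
            active(ii, jj) = 2;
        }
      }
    }
  }

  return List::create(_["C"] = C, _["Cd"] = Cd, _["phi"] = phi,
                      _["active"] = active,
                      _["inflow"] = inflow, _["outflow"] = outflow);
}
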