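#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Explicit finite-volume/upwind step for the transported thermal scalar on a
// cell-centred cylindrical lattice (axial i, radial j, angular l).
//
// Velocity is prescribed: a quasi-steady axial profile per segment (upstream
// of the catheter tip / downstream of it), scaled each step by the pulsatile
// flow, plus a local buoyant drift of cold fluid (downward, -y) with speed
// beta * (Tb - T). All transport coefficients are chosen by the caller so
// that the total outflow coefficient per cell stays below 1: the update is
// then a convex combination and the scalar obeys the maximum principle
// exactly (lumen temperatures never leave [Ti, Tb]).
//
// Injection enters as a volumetric source at the catheter outlet cells,
// applied implicitly: T <- (T + a*Ti) / (1 + a), a = q dt / V, which is
// unconditionally bounded and carries the mixed-inflow energy flux.
//
// Index convention: idx = i + nz*(j + nr*l); slabs 1..(i_src-1) (1-based)
// use the upstream mask/profile, slabs >= i_src the downstream ones.
// [[Rcpp::export]]
List advance_scalar_cpp(int nz, int nr, int nth,
                        double dz, double dr, double dth,
                        NumericVector r,
                        IntegerMatrix mask_up, IntegerMatrix mask_down,
                        NumericMatrix u_up, NumericMatrix u_down,
                        int i_src,
                        NumericVector q_flow, double q_inf,
                        IntegerVector src_ring, IntegerVector src_sector,
                        NumericVector src_q,
                        double t_inf, double t_blood,
                        NumericVector d_trans, double d_ax,
                        double beta, double drift_v0, NumericVector theta,
                        double dt, IntegerVector store_steps,
                        int accum_start) {
  const int nsteps = q_flow.size();
  const int ncell = nz * nr * nth;
  const int isrc0 = i_src - 1;  // first downstream slab, 0-based
  std::vector<double> T(ncell, t_blood), Tn(ncell, t_blood);
  std::vector<double> sinth(nth), costh(nth);
  for (int l = 0; l < nth; ++l) {
    sinth[l] = std::sin(theta[l]);
    costh[l] = std::cos(theta[l]);
  }
  const int nstore = store_steps.size();
  NumericVector snaps((R_xlen_t)ncell * nstore);
  int next_store = 0;
  double lumen_min = t_blood, lumen_max = t_blood;
  double out_num = 0.0, out_den = 0.0;

  // per-cell mask/velocity lookups
  auto mask_at = [&](int i, int j, int l) -> int {
    return (i < isrc0) ? mask_up(j, l) : mask_down(j, l);
  };

  const int nsrc = src_q.size();
  std::vector<int> src_idx(nsrc);
  std::vector<double> src_a(nsrc);
  // per-(j,l) source flow at the transition slab, for the flux bookkeeping
  std::vector<double> q_cell(nr * nth, 0.0);
  for (int s = 0; s < nsrc; ++s) {
    int j = src_ring[s] - 1, l = src_sector[s] - 1;
    src_idx[s] = isrc0 + nz * (j + nr * l);
    double vol = r[j] * dr * dth * dz;
    src_a[s] = src_q[s] * dt / vol;
    q_cell[j + nr * l] += src_q[s];
  }
  std::vector<double> Ecell(nr * nth, 0.0);

  for (int k = 0; k < nsteps; ++k) {
    const double qc = q_flow[k];
    const double qd = qc + q_inf;
    // Transition slab (first downstream slab): the axial flux jumps from
    // qc distributed over the upstream profile to qc + q_inf over the
    // downstream one. The per-cell mismatch E = F_out - F_in - q is a
    // transverse redistribution within the slab: donor cells (E < 0)
    // export at their own temperature, receivers (E > 0) import at the
    // flux-weighted donor-pool temperature. This keeps the scheme globally
    // energy-conservative and the update a convex combination.
    double pool_w = 0.0, pool_wt = 0.0;
    for (int l = 0; l < nth; ++l)
      for (int j = 0; j < nr; ++j) {
        const int c = j + nr * l;
        if (mask_down(j, l) != 0) { Ecell[c] = 0.0; continue; }
        const double A = r[j] * dr * dth;
        const double fin = (mask_up(j, l) == 0) ? u_up(j, l) * qc * A : 0.0;
        const double fout = u_down(j, l) * qd * A;
        const double E = fout - fin - q_cell[c];
        Ecell[c] = E;
        if (E < 0.0) {
          pool_w += -E;
          pool_wt += -E * T[isrc0 + nz * c];
        }
      }
    const double t_pool = (pool_w > 0.0) ? pool_wt / pool_w : t_blood;
    for (int l = 0; l < nth; ++l) {
      const int lp = (l + 1) % nth, lm = (l + nth - 1) % nth;
      for (int j = 0; j < nr; ++j) {
        const double rj = r[j];
        const double rfp = (j + 1) * dr, rfm = j * dr;
        const double arc = rj * dth;
        for (int i = 0; i < nz; ++i) {
          const int idx = i + nz * (j + nr * l);
          if (mask_at(i, j, l) != 0) { Tn[idx] = T[idx]; continue; }
          const double Tc = T[idx];
          const double D = d_trans[i];
          double acc = Tc;
          // axial advection (flow is non-negative; donor is the upstream cell)
          if (i == isrc0) {
            const double A = rj * dr * dth, vol = A * dz;
            const double fin = (mask_up(j, l) == 0) ? u_up(j, l) * qc * A : 0.0;
            const double Tup = (fin > 0.0) ? T[idx - 1] : Tc;
            const double Ep = (Ecell[j + nr * l] > 0.0) ? Ecell[j + nr * l] : 0.0;
            acc += dt / vol * (fin * (Tup - Tc) + Ep * (t_pool - Tc));
          } else {
            const double u = (i < isrc0) ? u_up(j, l) * qc : u_down(j, l) * qd;
            double Tup;
            if (i == 0) Tup = t_blood;
            else Tup = (mask_at(i - 1, j, l) == 0) ? T[idx - 1] : Tc;
            acc += u * dt / dz * (Tup - Tc);
          }
          // radial diffusion (zero flux into walls/solids; face r=0 has no area)
          double fr = 0.0;
          if (j + 1 < nr && mask_at(i, j + 1, l) == 0)
            fr += rfp * (T[idx + nz] - Tc);
          if (j > 0 && mask_at(i, j - 1, l) == 0)
            fr -= rfm * (Tc - T[idx - nz]);
          acc += D * dt / (rj * dr * dr) * fr;
          // angular diffusion, periodic, blocked at solids
          double fth = 0.0;
          if (mask_at(i, j, lp) == 0) fth += T[i + nz * (j + nr * lp)] - Tc;
          if (mask_at(i, j, lm) == 0) fth += T[i + nz * (j + nr * lm)] - Tc;
          acc += D * dt / (arc * arc) * fth;
          // axial diffusion; inlet ghost held at blood temperature
          double fz = 0.0;
          if (i == 0) fz += t_blood - Tc;
          else if (mask_at(i - 1, j, l) == 0) fz += T[idx - 1] - Tc;
          if (i + 1 < nz && mask_at(i + 1, j, l) == 0) fz += T[idx + 1] - Tc;
          acc += d_ax * dt / (dz * dz) * fz;
          // Buoyant drift of infusate-rich fluid toward -y at speed
          // drift_v0 + beta*(Tb - T): a P-proportional settling term plus a
          // uniform plume-downdraft component (the bulk current the sinking
          // plume drags with it), without which the slow-sinking dilute
          // tail of the plume would artificially linger on its release
          // line. First-order upwinding of this term would smear
          // the thin end-hole cold core at a rate comparable to the
          // physical diffusivity, so the transverse drift fluxes use a
          // van Leer flux-limited second-order scheme (with a divergence
          // correction so uniform fields are preserved); a final clamp to
          // [Ti, Tb] enforces the maximum principle.
          {
            auto Tat = [&](int jj, int ll) { return T[i + nz * (jj + nr * ll)]; };
            auto open = [&](int jj, int ll) {
              return jj >= 0 && jj < nr && mask_at(i, jj, ll) == 0;
            };
            // skip locally uniform neighbourhoods: all drift fluxes cancel
            double dmax = 0.0;
            if (open(j - 1, l)) dmax = std::max(dmax, std::fabs(Tat(j - 1, l) - Tc));
            if (open(j + 1, l)) dmax = std::max(dmax, std::fabs(Tat(j + 1, l) - Tc));
            if (open(j, lm)) dmax = std::max(dmax, std::fabs(Tat(j, lm) - Tc));
            if (open(j, lp)) dmax = std::max(dmax, std::fabs(Tat(j, lp) - Tc));
            if (dmax < 1e-4) goto drift_done;
            {
            auto vr_at = [&](int jj, int ll) {
              return -(drift_v0 + beta * (t_blood - Tat(jj, ll))) * sinth[ll];
            };
            auto vth_at = [&](int jj, int ll) {
              return -(drift_v0 + beta * (t_blood - Tat(jj, ll))) * costh[ll];
            };
            auto limited = [&](double Td, double Tdd, double Tu) {
              // van Leer limiter on the donor-side slope ratio
              const double d1 = Tdd - Td, d0 = Td - Tu;
              if (d1 == 0.0) return Td;
              const double rr = d0 / d1;
              const double psi = (rr <= 0.0) ? 0.0 : 2.0 * rr / (1.0 + rr);
              return Td + 0.5 * psi * d1;
            };
            double fsum = 0.0, div = 0.0;
            // radial faces (outer j+1/2, inner j-1/2); blocked at walls/solids
            for (int s = 0; s < 2; ++s) {
              const int ja = (s == 0) ? j : j - 1;      // inner cell of face
              const int jb = ja + 1;                    // outer cell of face
              if (!open(ja, l) || !open(jb, l)) continue;
              const double rf = (s == 0) ? rfp : rfm;
              const double vf = 0.5 * (vr_at(ja, l) + vr_at(jb, l));
              int jd = (vf > 0.0) ? ja : jb;            // donor
              int jdd = (vf > 0.0) ? jb : ja;
              int ju = (vf > 0.0) ? ja - 1 : jb + 1;    // donor-upstream
              double Tf = open(ju, l) ? limited(Tat(jd, l), Tat(jdd, l), Tat(ju, l))
                                      : Tat(jd, l);
              const double sgn = (s == 0) ? 1.0 : -1.0; // outward positive
              fsum -= sgn * vf * Tf * rf / (rj * dr);
              div -= sgn * vf * rf / (rj * dr);
            }
            // angular faces (l+1/2 with lp, l-1/2 with lm), periodic
            for (int s = 0; s < 2; ++s) {
              const int la = (s == 0) ? l : lm;
              const int lb = (s == 0) ? lp : l;
              if (!open(j, la) || !open(j, lb)) continue;
              const double vf = 0.5 * (vth_at(j, la) + vth_at(j, lb));
              int ld = (vf > 0.0) ? la : lb;
              int ldd = (vf > 0.0) ? lb : la;
              int lu = (vf > 0.0) ? (la + nth - 1) % nth : (lb + 1) % nth;
              double Tf = open(j, lu) ? limited(Tat(j, ld), Tat(j, ldd), Tat(j, lu))
                                      : Tat(j, ld);
              const double sgn = (s == 0) ? 1.0 : -1.0;
              fsum -= sgn * vf * Tf / arc;
              div -= sgn * vf / arc;
            }
            acc += dt * (fsum - div * Tc);
            }
          }
          drift_done:
          if (acc < t_inf) acc = t_inf;
          if (acc > t_blood) acc = t_blood;
          Tn[idx] = acc;
        }
      }
    }
    // implicit injection sources at the outlet slab
    for (int s = 0; s < nsrc; ++s) {
      const int idx = src_idx[s];
      Tn[idx] = (Tn[idx] + src_a[s] * t_inf) / (1.0 + src_a[s]);
    }
    // scalar bounds over open cells (all steps: the scheme is bounded)
    for (int l = 0; l < nth; ++l)
      for (int j = 0; j < nr; ++j)
        for (int i = 0; i < nz; ++i) {
          if (mask_at(i, j, l) != 0) continue;
          const double v = Tn[i + nz * (j + nr * l)];
          if (v < lumen_min) lumen_min = v;
          if (v > lumen_max) lumen_max = v;
        }
    // flux-weighted outlet temperature over the accumulation window
    if (k + 1 >= accum_start) {
      const int i = nz - 1;
      for (int l = 0; l < nth; ++l)
        for (int j = 0; j < nr; ++j) {
          if (mask_down(j, l) != 0) continue;
          const double w = u_down(j, l) * qd * r[j] * dr * dth * dt;
          out_num += w * Tn[i + nz * (j + nr * l)];
          out_den += w;
        }
    }
    T.swap(Tn);
    if (next_store < nstore && store_steps[next_store] == k + 1) {
      std::copy(T.begin(), T.end(),
                snaps.begin() + (R_xlen_t)ncell * next_store);
      ++next_store;
    }
  }

  snaps.attr("dim") = IntegerVector::create(nz, nr, nth, nstore);
  return List::create(_["snapshots"] = snaps,
                      _["lumen_min"] = lumen_min,
                      _["lumen_max"] = lumen_max,
                      _["outlet_num"] = out_num,
                      _["outlet_den"] = out_den);
}
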