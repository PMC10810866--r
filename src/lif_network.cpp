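// Vectorized Euler-Maruyama integrator for the two-population CA1
// leaky integrate-and-fire network with conductance-based biexponential
// synapses.  Units: mV, ms, pF, nS, pA.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

namespace {

struct SynClass {
  double gpeak, tau_r, tau_d, erev, norm;
  int delay_steps;
};

SynClass make_syn(const NumericVector& p, double dt) {
  SynClass s;
  s.gpeak = p[0];
  s.tau_r = p[1];
  s.tau_d = p[2];
  s.erev = p[3];
  s.delay_steps = std::max(1, (int)std::lround(p[4] / dt));
  // normalize the biexponential so its maximum equals gpeak
  double tpk = std::log(s.tau_d / s.tau_r) * s.tau_r * s.tau_d /
               (s.tau_d - s.tau_r);
  s.norm = 1.0 / (std::exp(-tpk / s.tau_d) - std::exp(-tpk / s.tau_r));
  return s;
}

}  // namespace

// [[Rcpp::export(name = ".lif_simulate_cpp")]]
List lif_simulate(int n_steps, double dt,
                  NumericVector pop_e, NumericVector pop_i,
                  NumericVector syn_ee, NumericVector syn_ie,
                  NumericVector syn_ei, NumericVector syn_ii,
                  IntegerVector ee_idx, IntegerVector ee_ptr,
                  IntegerVector ie_idx, IntegerVector ie_ptr,
                  IntegerVector ei_idx, IntegerVector ei_ptr,
                  IntegerVector ii_idx, IntegerVector ii_ptr,
                  NumericVector drive_amp, NumericVector drive_center,
                  double drive_sd, double sigma_mV, double v_init_sd) {
  const int NE = ee_ptr.size() - 1;
  const int NI = ii_ptr.size() - 1;

  // population constants: C, gL, EL, Vth, Vreset, ref_ms
  const double Ce = pop_e[0], gLe = pop_e[1], ELe = pop_e[2],
               Vthe = pop_e[3], Vre = pop_e[4];
  const int ref_e = std::max(1, (int)std::lround(pop_e[5] / dt));
  const double Ci = pop_i[0], gLi = pop_i[1], ELi = pop_i[2],
               Vthi = pop_i[3], Vri = pop_i[4];
  const int ref_i = std::max(1, (int)std::lround(pop_i[5] / dt));

  SynClass see = make_syn(syn_ee, dt), sie = make_syn(syn_ie, dt),
           sei = make_syn(syn_ei, dt), sii = make_syn(syn_ii, dt);

  // membrane noise scaled for a stationary voltage SD of sigma_mV
  const double sigw_e = sigma_mV * std::sqrt(2.0 * gLe / Ce);
  const double sigw_i = sigma_mV * std::sqrt(2.0 * gLi / Ci);
  const double sqdt = std::sqrt(dt);

  std::vector<double> Ve(NE), Vi(NI);
  std::vector<int> refe(NE, 0), refi(NI, 0);
  for (int i = 0; i < NE; ++i) Ve[i] = ELe + v_init_sd * norm_rand();
  for (int i = 0; i < NI; ++i) Vi[i] = ELi + v_init_sd * norm_rand();

  // synaptic state: decay/rise pair per incoming class
  std::vector<double> eAd(NE, 0), eAr(NE, 0), eGd(NE, 0), eGr(NE, 0);
  std::vector<double> iAd(NI, 0), iAr(NI, 0), iGd(NI, 0), iGr(NI, 0);

  // delay ring buffers (column-major: column = step slot)
  std::vector<double> bufEE((size_t)NE * see.delay_steps, 0.0);
  std::vector<double> bufEI((size_t)NE * sei.delay_steps, 0.0);
  std::vector<double> bufIE((size_t)NI * sie.delay_steps, 0.0);
  std::vector<double> bufII((size_t)NI * sii.delay_steps, 0.0);

  NumericVector lfp_ampa(n_steps), lfp_gaba(n_steps);
  IntegerVector count_e(n_steps), count_i(n_steps);
  std::vector<int> sp_e_id, sp_i_id;
  std::vector<double> sp_e_t, sp_i_t;

  const bool has_drive = drive_amp.size() == NE;

  const double dEEd = 1.0 - dt / see.tau_d, dEEr = 1.0 - dt / see.tau_r;
  const double dEId = 1.0 - dt / sei.tau_d, dEIr = 1.0 - dt / sei.tau_r;
  const double dIEd = 1.0 - dt / sie.tau_d, dIEr = 1.0 - dt / sie.tau_r;
  const double dIId = 1.0 - dt / sii.tau_d, dIIr = 1.0 - dt / sii.tau_r;

  for (int t = 0; t < n_steps; ++t) {
    const double now = t * dt;

    // deliver delayed arrivals, then decay synaptic states
    if (NE > 0) {
      double* col = &bufEE[(size_t)(t % see.delay_steps) * NE];
      for (int i = 0; i < NE; ++i) {
        if (col[i] != 0.0) { eAd[i] += col[i]; eAr[i] += col[i]; col[i] = 0.0; }
        eAd[i] *= dEEd; eAr[i] *= dEEr;
      }
      col = &bufEI[(size_t)(t % sei.delay_steps) * NE];
      for (int i = 0; i < NE; ++i) {
        if (col[i] != 0.0) { eGd[i] += col[i]; eGr[i] += col[i]; col[i] = 0.0; }
        eGd[i] *= dEId; eGr[i] *= dEIr;
      }
    }
    if (NI > 0) {
      double* col = &bufIE[(size_t)(t % sie.delay_steps) * NI];
      for (int i = 0; i < NI; ++i) {
        if (col[i] != 0.0) { iAd[i] += col[i]; iAr[i] += col[i]; col[i] = 0.0; }
        iAd[i] *= dIEd; iAr[i] *= dIEr;
      }
      col = &bufII[(size_t)(t % sii.delay_steps) * NI];
      for (int i = 0; i < NI; ++i) {
        if (col[i] != 0.0) { iGd[i] += col[i]; iGr[i] += col[i]; col[i] = 0.0; }
        iGd[i] *= dIId; iGr[i] *= dIIr;
      }
    }

    double sumA = 0.0, sumG = 0.0;

    // excitatory population
    for (int i = 0; i < NE; ++i) {
      const double gA = see.gpeak * see.norm * (eAd[i] - eAr[i]);
      const double gG = sei.gpeak * sei.norm * (eGd[i] - eGr[i]);
      const double iA = gA * (see.erev - Ve[i]);
      const double iG = gG * (sei.erev - Ve[i]);
      sumA += std::fabs(iA);
      sumG += std::fabs(iG);
      if (refe[i] > 0) { --refe[i]; Ve[i] = Vre; continue; }
      double iext = 0.0;
      if (has_drive && drive_amp[i] != 0.0) {
        const double u = (now - drive_center[i]) / drive_sd;
        iext = drive_amp[i] * std::exp(-0.5 * u * u);
      }
      double dV = dt * (gLe * (ELe - Ve[i]) + iA + iG + iext) / Ce;
      if (sigw_e > 0) dV += sigw_e * sqdt * norm_rand();
      Ve[i] += dV;
      if (!R_FINITE(Ve[i]) || std::fabs(Ve[i]) > 500.0)
        stop("numerical blow-up in E unit %d at step %d (t = %.1f ms)",
             i + 1, t + 1, now);
      if (Ve[i] >= Vthe) {
        Ve[i] = Vre;
        refe[i] = ref_e;
        ++count_e[t];
        sp_e_id.push_back(i + 1);
        sp_e_t.push_back(now);
        {
          const int col = (t + see.delay_steps) % see.delay_steps;
          double* b = &bufEE[(size_t)col * NE];
          for (int k = ee_ptr[i]; k < ee_ptr[i + 1]; ++k) b[ee_idx[k]] += 1.0;
        }
        if (NI > 0) {
          const int col = (t + sie.delay_steps) % sie.delay_steps;
          double* b = &bufIE[(size_t)col * NI];
          for (int k = ie_ptr[i]; k < ie_ptr[i + 1]; ++k) b[ie_idx[k]] += 1.0;
        }
      }
    }

    // inhibitory population
    for (int i = 0; i < NI; ++i) {
      const double gA = sie.gpeak * sie.norm * (iAd[i] - iAr[i]);
      const double gG = sii.gpeak * sii.norm * (iGd[i] - iGr[i]);
      const double iA = gA * (sie.erev - Vi[i]);
      const double iG = gG * (sii.erev - Vi[i]);
      if (refi[i] > 0) { --refi[i]; Vi[i] = Vri; continue; }
      double dV = dt * (gLi * (ELi - Vi[i]) + iA + iG) / Ci;
      if (sigw_i > 0) dV += sigw_i * sqdt * norm_rand();
      Vi[i] += dV;
      if (!R_FINITE(Vi[i]) || std::fabs(Vi[i]) > 500.0)
        stop("numerical blow-up in I unit %d at step %d (t = %.1f ms)",
             i + 1, t + 1, now);
      if (Vi[i] >= Vthi) {
        Vi[i] = Vri;
        refi[i] = ref_i;
        ++count_i[t];
        sp_i_id.push_back(i + 1);
        sp_i_t.push_back(now);
        {
          const int col = (t + sei.delay_steps) % sei.delay_steps;
          double* b = &bufEI[(size_t)col * NE];
          for (int k = ei_ptr[i]; k < ei_ptr[i + 1]; ++k) b[ei_idx[k]] += 1.0;
        }
        {
          const int col = (t + sii.delay_steps) % sii.delay_steps;
          double* b = &bufII[(size_t)col * NI];
          for (int k = ii_ptr[i]; k < ii_ptr[i + 1]; ++k) b[ii_idx[k]] += 1.0;
        }
      }
    }

    lfp_ampa[t] = sumA;
    lfp_gaba[t] = sumG;
  }

  return List::create(
      _["spikes_e"] = DataFrame::create(_["unit"] = wrap(sp_e_id),
                                        _["t_ms"] = wrap(sp_e_t)),
      _["spikes_i"] = DataFrame::create(_["unit"] = wrap(sp_i_id),
                                        _["t_ms"] = wrap(sp_i_t)),
      _["count_e"] = count_e, _["count_i"] = count_i,
      _["lfp_ampa"] = lfp_ampa, _["lfp_gaba"] = lfp_gaba);
}
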