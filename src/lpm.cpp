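// Core integrator for the closed-loop lumped-parameter circulation.
//
// State layout (volumes in mL, flows in mL/s):
//   y[0..3]   chamber volumes RA, RV, LA, LV
//   y[4..11]  segment stored volumes AO, SAT, SAR, SVN, PAS, PAT, PCP, PVN
//   y[12]     q_ao : flow through the aortic R/L branch (AO -> SAT)
//   y[13]     q_p  : pump branch flow (LV -> AO), present only when pump on
//
// Volume derivatives are written as (inflow - outflow) per node, so the sum
// of all volume derivatives is identically zero and RK4 preserves total
// blood volume to round-off.
//
// Parameter vector layout (see R/params.R, flatten_params()):
//   [0..19]  4 chambers x (Emax, Emin, V0, onset_frac, ts)
//   [20..51] 8 segments x (R, C, L, V0)
//   [52..54] valve R_open, R_closed, transition width (mmHg)
//   [55]     T (s), [56] TBV (mL)
//   [57]     pump flag (0/1)
//   [58..67] Ka, Kb, Kc, R_in, L_in, R_out, L_out, suction thr, suction gain,
//            speed (rpm)

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

static const int N_CH = 4, N_SEG = 8;

// normalized activation in [0,1]: cosine rise over ts, cosine fall over ts/2,
// peak (end-systole) at phase onset + ts
static inline double activation(double t, double T, double onset_frac,
                                double ts) {
  double u = t / T - onset_frac;
  double tau = u - std::floor(u); // periodic phase in [0, 1)
  tau *= T; // seconds since activation onset
  double tr = 0.5 * ts;
  if (tau < ts) return 0.5 * (1.0 - std::cos(M_PI * tau / ts));
  if (tau < ts + tr) return 0.5 * (1.0 + std::cos(M_PI * (tau - ts) / tr));
  return 0.0;
}

// [[Rcpp::export(name = ".elastance_cpp")]]
NumericVector elastance_cpp(NumericVector t, double Emax, double Emin,
                            double onset_frac, double ts, double T) {
  int n = t.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i)
    out[i] = Emin + (Emax - Emin) * activation(t[i], T, onset_frac, ts);
  return out;
}

static inline double valve_R(double dP, double Ro, double Rc, double w) {
  double z = dP / w;
  if (z > 40.0) return Ro;
  if (z < -40.0) return Rc;
  return Ro + (Rc - Ro) / (1.0 + std::exp(z));
}

// [[Rcpp::export(name = ".valve_flow_cpp")]]
NumericVector valve_flow_cpp(NumericVector dP, double Ro, double Rc,
                             double w) {
  int n = dP.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) out[i] = dP[i] / valve_R(dP[i], Ro, Rc, w);
  return out;
}

struct Model {
  double Emax[N_CH], Emin[N_CH], V0[N_CH], onset[N_CH], ts[N_CH];
  double R[N_SEG], C[N_SEG], L[N_SEG], Vu[N_SEG];
  double vRo, vRc, vW;
  double T, TBV;
  bool pump;
  double Ka, Kb, Kc, Rin, Lin, Rout, Lout, thr, gain, speed;
  int nstate;

  void init(const NumericVector &p) {
    for (int c = 0; c < N_CH; ++c) {
      Emax[c] = p[5 * c]; Emin[c] = p[5 * c + 1]; V0[c] = p[5 * c + 2];
      onset[c] = p[5 * c + 3]; ts[c] = p[5 * c + 4];
    }
    for (int s = 0; s < N_SEG; ++s) {
      R[s] = p[20 + 4 * s]; C[s] = p[21 + 4 * s]; L[s] = p[22 + 4 * s];
      Vu[s] = p[23 + 4 * s];
    }
    vRo = p[52]; vRc = p[53]; vW = p[54];
    T = p[55]; TBV = p[56];
    pump = p[57] > 0.5;
    Ka = p[58]; Kb = p[59]; Kc = p[60];
    Rin = p[61]; Lin = p[62]; Rout = p[63]; Lout = p[64];
    thr = p[65]; gain = p[66]; speed = p[67];
    nstate = 13 + (pump ? 1 : 0);
  }

  // chamber/segment pressures for a given state
  void pressures(double t, const double *y, double *Pch, double *Pseg) const {
    for (int c = 0; c < N_CH; ++c) {
      double E = Emin[c] + (Emax[c] - Emin[c]) *
                               activation(t, T, onset[c], ts[c]);
      Pch[c] = E * (y[c] - V0[c]);
    }
    for (int s = 0; s < N_SEG; ++s) Pseg[s] = (y[4 + s] - Vu[s]) / C[s];
  }

  void rhs(double t, const double *y, double *dy) const {
    double Pch[N_CH], Pseg[N_SEG];
    pressures(t, y, Pch, Pseg);
    const double Pra = Pch[0], Prv = Pch[1], Pla = Pch[2], Plv = Pch[3];
    const double Pao = Pseg[0], Psat = Pseg[1], Psar = Pseg[2],
                 Psvn = Pseg[3], Ppas = Pseg[4], Ppat = Pseg[5],
                 Ppcp = Pseg[6], Ppvn = Pseg[7];

    // valves
    double d_tv = Pra - Prv, d_pv = Prv - Ppas, d_mv = Pla - Plv,
           d_av = Plv - Pao;
    double q_tv = d_tv / valve_R(d_tv, vRo, vRc, vW);
    double q_pv = d_pv / valve_R(d_pv, vRo, vRc, vW);
    double q_mv = d_mv / valve_R(d_mv, vRo, vRc, vW);
    double q_av = d_av / valve_R(d_av, vRo, vRc, vW);

    // resistive inter-segment branches (exit resistance of each segment)
    double q_ao = y[12];                 // AO -> SAT (inductive)
    double q_sat = (Psat - Psar) / R[1];
    double q_sar = (Psar - Psvn) / R[2];
    double q_svn = (Psvn - Pra) / R[3];
    double q_pas = (Ppas - Ppat) / R[4];
    double q_pat = (Ppat - Ppcp) / R[5];
    double q_pcp = (Ppcp - Ppvn) / R[6];
    double q_pvn = (Ppvn - Pla) / R[7];

    double q_p = 0.0;
    if (pump) {
      q_p = y[13];
      // odd quadratic extension (Q|Q|) so the loss term resists reverse flow
      double H = Ka * q_p * std::fabs(q_p) + Kb * q_p * speed +
                 Kc * speed * speed;
      double Rin_eff = Rin + (Plv < thr ? gain * (thr - Plv) : 0.0);
      dy[13] = (Plv - Pao + H - (Rin_eff + Rout) * q_p) / (Lin + Lout);
    }

    // chambers: RA, RV, LA, LV
    dy[0] = q_svn - q_tv;
    dy[1] = q_tv - q_pv;
    dy[2] = q_pvn - q_mv;
    dy[3] = q_mv - q_av - q_p;
    // segments: AO, SAT, SAR, SVN, PAS, PAT, PCP, PVN
    dy[4] = q_av + q_p - q_ao;
    dy[5] = q_ao - q_sat;
    dy[6] = q_sat - q_sar;
    dy[7] = q_sar - q_svn;
    dy[8] = q_pv - q_pas;
    dy[9] = q_pas - q_pat;
    dy[10] = q_pat - q_pcp;
    dy[11] = q_pcp - q_pvn;
    // aortic inductive branch
    dy[12] = (Pao - Psat - R[0] * q_ao) / L[0];
  }
};

// [[Rcpp::export(name = ".lpm_rhs_cpp")]]
NumericVector lpm_rhs_cpp(double t, NumericVector y, NumericVector p) {
  Model m; m.init(p);
  if (y.size() != m.nstate) stop("state length must be %d", m.nstate);
  for (int i = 0; i < y.size(); ++i)
    if (!std::isfinite(y[i])) stop("non-finite state entry %d", i + 1);
  NumericVector dy(m.nstate);
  m.rhs(t, REAL(y), REAL(dy));
  return dy;
}

// [[Rcpp::export(name = ".lpm_simulate_cpp")]]
List lpm_simulate_cpp(NumericVector p, NumericVector y0, double t_end,
                      double dt, double fs) {
  Model m; m.init(p);
  const int ns = m.nstate;
  if (y0.size() != ns) stop("initial state must have length %d", ns);

  const int nout = (int)std::floor(t_end * fs + 1e-9) + 1;
  NumericVector time(nout);
  NumericMatrix vol(nout, N_CH + N_SEG), prs(nout, N_CH + N_SEG),
      flow(nout, 6); // q_tv q_pv q_mv q_av q_ao q_pump
  LogicalVector suction(nout);

  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(ns), k2(ns), k3(ns), k4(ns), yt(ns);
  double Pch[N_CH], Pseg[N_SEG];

  const long nstep = (long)std::ceil(t_end / dt - 1e-9);
  const double h = t_end / (double)nstep;
  int iout = 0;
  long next_out = 0; // output at t = iout / fs

  for (long step = 0; step <= nstep; ++step) {
    double t = step * h;
    // emit output samples that fall at/before current t
    while (iout < nout && (double)iout / fs <= t + 1e-12) {
      m.pressures(t, y.data(), Pch, Pseg);
      time[iout] = (double)iout / fs;
      for (int c = 0; c < N_CH; ++c) { vol(iout, c) = y[c]; prs(iout, c) = Pch[c]; }
      for (int s = 0; s < N_SEG; ++s) {
        vol(iout, N_CH + s) = y[4 + s]; prs(iout, N_CH + s) = Pseg[s];
      }
      double d_tv = Pch[0] - Pch[1], d_pv = Pch[1] - Pseg[4],
             d_mv = Pch[2] - Pch[3], d_av = Pch[3] - Pseg[0];
      flow(iout, 0) = d_tv / valve_R(d_tv, m.vRo, m.vRc, m.vW);
      flow(iout, 1) = d_pv / valve_R(d_pv, m.vRo, m.vRc, m.vW);
      flow(iout, 2) = d_mv / valve_R(d_mv, m.vRo, m.vRc, m.vW);
      flow(iout, 3) = d_av / valve_R(d_av, m.vRo, m.vRc, m.vW);
      flow(iout, 4) = y[12];
      flow(iout, 5) = m.pump ? y[13] : 0.0;
      suction[iout] = m.pump && Pch[3] < m.thr;
      ++iout;
    }
    if (step == nstep) break;

    // classic RK4 step
    m.rhs(t, y.data(), k1.data());
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * h * k1[i];
    m.rhs(t + 0.5 * h, yt.data(), k2.data());
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + 0.5 * h * k2[i];
    m.rhs(t + 0.5 * h, yt.data(), k3.data());
    for (int i = 0; i < ns; ++i) yt[i] = y[i] + h * k3[i];
    m.rhs(t + h, yt.data(), k4.data());
    for (int i = 0; i < ns; ++i)
      y[i] += h / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    static const char *nodes[12] = {"RA", "RV", "LA", "LV", "AO", "SAT",
                                    "SAR", "SVN", "PAS", "PAT", "PCP", "PVN"};
    for (int i = 0; i < 12; ++i) {
      if (!std::isfinite(y[i]))
        stop("solver blow-up: non-finite volume at node %s, t = %.4f s",
             nodes[i], t);
      if (y[i] < 0.0)
        stop("non-physiological state: negative volume at node %s, t = %.4f s",
             nodes[i], t);
    }
    (void)next_out;
  }

  return List::create(_["time"] = time, _["volumes"] = vol,
                      _["pressures"] = prs, _["flows"] = flow,
                      _["suction"] = suction,
                      _["final_state"] = NumericVector(y.begin(), y.end()));
}
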