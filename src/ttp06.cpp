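// Right-hand side of the Ten Tusscher-Panfilov (2006) human endocardial
// ventricular cell model with I_Kr carried by the five-state Markov chain
// instead of the original two-gate Hodgkin-Huxley formulation.
//
// Units: time ms, voltage mV, currents pA/pF, concentrations mM.
// State layout (22):
//   0 V, 1 Nai, 2 Ki, 3 Cai, 4 CaSR, 5 CaSS,
//   6 m, 7 h, 8 j, 9 d, 10 f, 11 f2, 12 fCass, 13 r, 14 s, 15 xs,
//   16 Rbar, 17-21 Markov occupancies C1, C2, C3, O, I.
// mrates: 24 numbers, (a, b, v0) for k12, k21, k23, k32, k34, k43, k45,
// k54 in that order; rate(V) = a * exp(b * (V + v0)).

#include <Rcpp.h>
using namespace Rcpp;

static const double Rgas = 8314.472;     // J/(kmol K)
static const double Frdy = 96485.3415;   // C/mol
static const double Temp = 310.0;        // K
static const double Ko = 5.4, Nao = 140.0, Cao = 2.0;
static const double Vc = 0.016404, Vsr = 0.001094, Vss = 0.00005468;
static const double Cm = 0.185;
static const double Bufc = 0.2, Kbufc = 0.001;
static const double Bufsr = 10.0, Kbufsr = 0.3;
static const double Bufss = 0.4, Kbufss = 0.00025;
static const double Vmaxup = 0.006375, Kup = 0.00025;
static const double Vrel = 0.102, k1p = 0.15, k2p = 0.045, k3 = 0.060,
                    k4 = 0.005, EC = 1.5, maxsr = 2.5, minsr = 1.0;
static const double Vleak = 0.00036, Vxfer = 0.0038;
static const double pKNa = 0.03;
static const double GNa = 14.838, GK1 = 5.405, GbNa = 0.00029,
                    GbCa = 0.000592, GpCa = 0.1238, KpCa = 0.0005,
                    GpK = 0.0146, GCaL = 0.00003980;
static const double Gto_endo = 0.073, GKs_endo = 0.392;
static const double knak = 2.724, KmK = 1.0, KmNa = 40.0;
static const double knaca = 1000.0, KmNai = 87.5, KmCa = 1.38,
                    ksat = 0.1, ncagam = 0.35, alpha_naca = 2.5;

// [[Rcpp::export(name = ".ttp06_rhs_cpp")]]
List ttp06_rhs_cpp(NumericVector y, NumericVector mrates,
                   double g_Kr, double istim) {
  if (y.size() != 22) stop("state vector must have length 22");
  if (mrates.size() != 24) stop("mrates must have length 24");

  const double V = y[0], Nai = y[1], Ki = y[2], Cai = y[3], CaSR = y[4],
               CaSS = y[5], m = y[6], h = y[7], j = y[8], d = y[9],
               f = y[10], f2 = y[11], fCass = y[12], r = y[13], s = y[14],
               xs = y[15], Rbar = y[16];
  for (int i = 0; i < 22; ++i)
    if (!R_finite(y[i]))
      stop("non-finite state variable at index %d", i + 1);

  const double RTF = Rgas * Temp / Frdy;
  const double EK = RTF * log(Ko / Ki);
  const double ENa = RTF * log(Nao / Nai);
  const double EKs = RTF * log((Ko + pKNa * Nao) / (Ki + pKNa * Nai));
  const double ECa = 0.5 * RTF * log(Cao / Cai);

  // fast sodium current
  const double INa = GNa * m * m * m * h * j * (V - ENa);

  // L-type calcium current (GHK-like driving term; series-expansion guard
  // at the V = 15 mV singularity)
  const double zfrt = 2.0 * (V - 15.0) / RTF;
  double ICaL;
  if (fabs(zfrt) < 1e-6) {
    ICaL = GCaL * d * f * f2 * fCass * 2.0 * Frdy *
           (0.25 * CaSS * (1.0 + zfrt) - Cao) * (1.0 + 0.5 * zfrt);
  } else {
    ICaL = GCaL * d * f * f2 * fCass * 2.0 * Frdy * zfrt *
           (0.25 * CaSS * exp(zfrt) - Cao) / (exp(zfrt) - 1.0);
  }

  // transient outward, slow delayed rectifier (endocardial parameters)
  const double Ito = Gto_endo * r * s * (V - EK);
  const double IKs = GKs_endo * xs * xs * (V - EKs);

  // rapid delayed rectifier through the Markov open state
  const double pO = y[20];
  const double IKr = g_Kr * sqrt(Ko / 5.4) * pO * (V - EK);

  // inward rectifier
  const double aK1 = 0.1 / (1.0 + exp(0.06 * (V - EK - 200.0)));
  const double bK1 = (3.0 * exp(0.0002 * (V - EK + 100.0)) +
                      exp(0.1 * (V - EK - 10.0))) /
                     (1.0 + exp(-0.5 * (V - EK)));
  const double IK1 = GK1 * sqrt(Ko / 5.4) * aK1 / (aK1 + bK1) * (V - EK);

  // exchangers, pumps, backgrounds
  const double vfrt = V / RTF;
  const double INaCa = knaca *
      (exp(ncagam * vfrt) * Nai * Nai * Nai * Cao -
       exp((ncagam - 1.0) * vfrt) * Nao * Nao * Nao * Cai * alpha_naca) /
      ((KmNai * KmNai * KmNai + Nao * Nao * Nao) * (KmCa + Cao) *
       (1.0 + ksat * exp((ncagam - 1.0) * vfrt)));
  const double INaK = knak * (Ko / (Ko + KmK)) * (Nai / (Nai + KmNa)) /
      (1.0 + 0.1245 * exp(-0.1 * vfrt) + 0.0353 * exp(-vfrt));
  const double IpCa = GpCa * Cai / (KpCa + Cai);
  const double IpK = GpK * (V - EK) / (1.0 + exp((25.0 - V) / 5.98));
  const double IbNa = GbNa * (V - ENa);
  const double IbCa = GbCa * (V - ECa);

  const double Iion = IK1 + Ito + IKr + IKs + ICaL + INaK + INa + IbNa +
                      INaCa + IbCa + IpK + IpCa;

  NumericVector dy(22);
  dy[0] = -(Iion + istim);

  // gate kinetics
  const double minf = 1.0 / pow(1.0 + exp((-56.86 - V) / 9.03), 2.0);
  const double am = 1.0 / (1.0 + exp((-60.0 - V) / 5.0));
  const double bm = 0.1 / (1.0 + exp((V + 35.0) / 5.0)) +
                    0.1 / (1.0 + exp((V - 50.0) / 200.0));
  const double taum = am * bm;

  const double hinf = 1.0 / pow(1.0 + exp((V + 71.55) / 7.43), 2.0);
  double ah, bh, aj, bj;
  if (V >= -40.0) {
    ah = 0.0;
    bh = 0.77 / (0.13 * (1.0 + exp(-(V + 10.66) / 11.1)));
    aj = 0.0;
    bj = 0.6 * exp(0.057 * V) / (1.0 + exp(-0.1 * (V + 32.0)));
  } else {
    ah = 0.057 * exp(-(V + 80.0) / 6.8);
    bh = 2.7 * exp(0.079 * V) + 3.1e5 * exp(0.3485 * V);
    aj = (-2.5428e4 * exp(0.2444 * V) - 6.948e-6 * exp(-0.04391 * V)) *
         (V + 37.78) / (1.0 + exp(0.311 * (V + 79.23)));
    bj = 0.02424 * exp(-0.01052 * V) /
         (1.0 + exp(-0.1378 * (V + 40.14)));
  }
  const double tauh = 1.0 / (ah + bh);
  const double tauj = 1.0 / (aj + bj);
  const double jinf = hinf;

  const double dinf = 1.0 / (1.0 + exp((-8.0 - V) / 7.5));
  const double ad = 1.4 / (1.0 + exp((-35.0 - V) / 13.0)) + 0.25;
  const double bd = 1.4 / (1.0 + exp((V + 5.0) / 5.0));
  const double gd = 1.0 / (1.0 + exp((50.0 - V) / 20.0));
  const double taud = ad * bd + gd;

  const double finf = 1.0 / (1.0 + exp((V + 20.0) / 7.0));
  const double tauf = 1102.5 * exp(-pow(V + 27.0, 2.0) / 225.0) +
                      200.0 / (1.0 + exp((13.0 - V) / 10.0)) +
                      180.0 / (1.0 + exp((V + 30.0) / 10.0)) + 20.0;

  const double f2inf = 0.67 / (1.0 + exp((V + 35.0) / 7.0)) + 0.33;
  const double tauf2 = 562.0 * exp(-pow(V + 27.0, 2.0) / 240.0) +
                       31.0 / (1.0 + exp((25.0 - V) / 10.0)) +
                       80.0 / (1.0 + exp((V + 30.0) / 10.0));

  const double css_ratio = CaSS / 0.05;
  const double fCassinf = 0.6 / (1.0 + css_ratio * css_ratio) + 0.4;
  const double taufCass = 80.0 / (1.0 + css_ratio * css_ratio) + 2.0;

  const double rinf = 1.0 / (1.0 + exp((20.0 - V) / 6.0));
  const double taur = 9.5 * exp(-pow(V + 40.0, 2.0) / 1800.0) + 0.8;
  // endocardial s gate
  const double sinf = 1.0 / (1.0 + exp((V + 28.0) / 5.0));
  const double taus = 1000.0 * exp(-pow(V + 67.0, 2.0) / 1000.0) + 8.0;

  const double xsinf = 1.0 / (1.0 + exp((-5.0 - V) / 14.0));
  const double axs = 1400.0 / sqrt(1.0 + exp((5.0 - V) / 6.0));
  const double bxs = 1.0 / (1.0 + exp((V - 35.0) / 15.0));
  const double tauxs = axs * bxs + 80.0;

  dy[6] = (minf - m) / taum;
  dy[7] = (hinf - h) / tauh;
  dy[8] = (jinf - j) / tauj;
  dy[9] = (dinf - d) / taud;
  dy[10] = (finf - f) / tauf;
  dy[11] = (f2inf - f2) / tauf2;
  dy[12] = (fCassinf - fCass) / taufCass;
  dy[13] = (rinf - r) / taur;
  dy[14] = (sinf - s) / taus;
  dy[15] = (xsinf - xs) / tauxs;

  // calcium subsystem
  const double kcasr = maxsr - (maxsr - minsr) /
                       (1.0 + (EC / CaSR) * (EC / CaSR));
  const double k1 = k1p / kcasr;
  const double k2 = k2p * kcasr;
  dy[16] = -k2 * CaSS * Rbar + k4 * (1.0 - Rbar);
  const double O_ryr = k1 * CaSS * CaSS * Rbar /
                       (k3 + k1 * CaSS * CaSS);
  const double Irel = Vrel * O_ryr * (CaSR - CaSS);
  const double Ileak = Vleak * (CaSR - Cai);
  const double Iup = Vmaxup / (1.0 + (Kup * Kup) / (Cai * Cai));
  const double Ixfer = Vxfer * (CaSS - Cai);

  const double bufc = 1.0 / (1.0 + Bufc * Kbufc /
                             ((Cai + Kbufc) * (Cai + Kbufc)));
  const double bufsr = 1.0 / (1.0 + Bufsr * Kbufsr /
                              ((CaSR + Kbufsr) * (CaSR + Kbufsr)));
  const double bufss = 1.0 / (1.0 + Bufss * Kbufss /
                              ((CaSS + Kbufss) * (CaSS + Kbufss)));

  dy[3] = bufc * ((Ileak - Iup) * Vsr / Vc + Ixfer -
                  (IbCa + IpCa - 2.0 * INaCa) * Cm / (2.0 * Vc * Frdy));
  dy[4] = bufsr * (Iup - Irel - Ileak);
  dy[5] = bufss * (-ICaL * Cm / (2.0 * Vss * Frdy) +
                   Irel * Vsr / Vss - Ixfer * Vc / Vss);

  dy[1] = -(INa + IbNa + 3.0 * INaK + 3.0 * INaCa) * Cm / (Vc * Frdy);
  dy[2] = -(istim + IK1 + Ito + IKr + IKs + IpK - 2.0 * INaK) * Cm /
          (Vc * Frdy);

  // Markov I_Kr occupancies: dp/dt = Q(V) p on the linear chain
  double k[8];
  for (int t = 0; t < 8; ++t)
    k[t] = mrates[3 * t] * exp(mrates[3 * t + 1] * (V + mrates[3 * t + 2]));
  const double p1 = y[17], p2 = y[18], p3 = y[19], p4 = y[20], p5 = y[21];
  // k order: k12 k21 k23 k32 k34 k43 k45 k54
  dy[17] = -k[0] * p1 + k[1] * p2;
  dy[18] = k[0] * p1 - (k[1] + k[2]) * p2 + k[3] * p3;
  dy[19] = k[2] * p2 - (k[3] + k[4]) * p3 + k[5] * p4;
  dy[20] = k[4] * p3 - (k[5] + k[6]) * p4 + k[7] * p5;
  dy[21] = k[6] * p4 - k[7] * p5;

  NumericVector currents = NumericVector::create(
      _["INa"] = INa, _["IK1"] = IK1, _["Ito"] = Ito, _["IKr"] = IKr,
      _["IKs"] = IKs, _["ICaL"] = ICaL, _["INaCa"] = INaCa,
      _["INaK"] = INaK, _["IpCa"] = IpCa, _["IpK"] = IpK,
      _["IbNa"] = IbNa, _["IbCa"] = IbCa, _["Istim"] = istim);
  return List::create(_["dy"] = dy, _["currents"] = currents);
}
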