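// O'Hara-Rudy dynamic (ORd) human ventricular action potential model,
// endocardial variant, with per-current maximal-conductance scaling hooks.
// Fixed-step integration (forward Euler for V, concentrations and CaMK;
// Rush-Larsen exponential updates for all gating variables, which have
// dx/dt = (xinf - x)/taux form).
//
// State layout (NY = 41):
//  0 v      1 nai    2 nass   3 ki     4 kss    5 cai    6 cass
//  7 cansr  8 cajsr  9 m     10 hf    11 hs    12 j     13 hsp   14 jp
// 15 mL    16 hL    17 hLp   18 a     19 iF    20 iS    21 ap    22 iFp
// 23 iSp   24 d     25 ff    26 fs    27 fcaf  28 fcas  29 jca   30 nca
// 31 ffp   32 fcafp 33 xrf   34 xrs   35 xs1   36 xs2   37 xk1
// 38 Jrelnp 39 Jrelp 40 CaMKt
//
// Scaling layout (NG = 9): INa, INaL, ICaL, Ito, IKr, IKs, IK1, INaCa, INaK.
// Current output layout (NC = 13):
//  INa, INaL, ICaL, Ito, IKr, IKs, IK1, INaCa (i+ss), INaK,
//  IKb, INab, ICab, IpCa.

#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

#define NY 41
#define NG 9
#define NC 13

// physical constants and cell geometry
static const double nao = 140.0, cao = 1.8, ko = 5.4;
static const double Rgas = 8314.0, Temp = 310.0, Frdy = 96485.0;
static const double Lcell = 0.01, rad = 0.0011;
static const double pi_ = 3.14;
static const double vcell = 1000.0 * pi_ * rad * rad * Lcell;
static const double Ageo  = 2.0 * pi_ * rad * rad + 2.0 * pi_ * rad * Lcell;
static const double Acap  = 2.0 * Ageo;
static const double vmyo = 0.68 * vcell, vnsr = 0.0552 * vcell,
                    vjsr = 0.0048 * vcell, vss = 0.02 * vcell;

// Core evaluation: fills derivatives dy (valid for non-gate states and, for
// gates, set to (inf - y)/tau), gate inf/tau arrays (indices 9..39), and
// membrane currents. Gates are indices 9..39 inclusive.
static void ord_compute(const double *y, const double *g, double Istim,
                        double *dy, double *ginf, double *gtau, double *cur) {
  const double v = y[0], nai = y[1], nass = y[2], ki = y[3], kss = y[4],
               cai = y[5], cass = y[6], cansr = y[7], cajsr = y[8];
  const double m = y[9], hf = y[10], hs = y[11], jg = y[12], hsp = y[13],
               jp = y[14], mL = y[15], hL = y[16], hLp = y[17], a = y[18],
               iF = y[19], iS = y[20], ap = y[21], iFp = y[22], iSp = y[23],
               d = y[24], ff = y[25], fs = y[26], fcaf = y[27], fcas = y[28],
               jca = y[29], nca = y[30], ffp = y[31], fcafp = y[32],
               xrf = y[33], xrs = y[34], xs1 = y[35], xs2 = y[36],
               xk1 = y[37], Jrelnp = y[38], Jrelp = y[39], CaMKt = y[40];

  // CaMK
  const double KmCaMK = 0.15, aCaMK = 0.05, bCaMK = 0.00068,
               CaMKo = 0.05, KmCaM = 0.0015;
  const double CaMKb = CaMKo * (1.0 - CaMKt) / (1.0 + KmCaM / cass);
  const double CaMKa = CaMKb + CaMKt;
  dy[40] = aCaMK * CaMKb * (CaMKb + CaMKt) - bCaMK * CaMKt;

  // reversal potentials
  const double rtf = Rgas * Temp / Frdy;
  const double ENa = rtf * std::log(nao / nai);
  const double EK  = rtf * std::log(ko / ki);
  const double PKNa = 0.01833;
  const double EKs = rtf * std::log((ko + PKNa * nao) / (ki + PKNa * nai));

  // guarded v for GHK-type driving forces (removable singularity at v = 0)
  const double vg = (std::fabs(v) < 1e-6) ? 1e-6 : v;
  const double vfrt = vg * Frdy / (Rgas * Temp);
  const double vffrt = vg * Frdy * Frdy / (Rgas * Temp);

  // INa (fast sodium)
  ginf[9] = 1.0 / (1.0 + std::exp(-(v + 39.57) / 9.871));
  gtau[9] = 1.0 / (6.765 * std::exp((v + 11.64) / 34.77) +
                   8.552 * std::exp(-(v + 77.42) / 5.955));
  const double hss = 1.0 / (1.0 + std::exp((v + 82.90) / 6.086));
  ginf[10] = hss;
  gtau[10] = 1.0 / (1.432e-5 * std::exp(-(v + 1.196) / 6.285) +
                    6.149 * std::exp((v + 0.5096) / 20.27));
  ginf[11] = hss;
  gtau[11] = 1.0 / (0.009794 * std::exp(-(v + 17.95) / 28.05) +
                    0.3343 * std::exp((v + 5.730) / 56.66));
  const double Ahf = 0.99, Ahs = 1.0 - Ahf;
  const double h = Ahf * hf + Ahs * hs;
  ginf[12] = hss;
  gtau[12] = 2.038 + 1.0 / (0.02136 * std::exp(-(v + 100.6) / 8.281) +
                            0.3052 * std::exp((v + 0.9941) / 38.45));
  ginf[13] = 1.0 / (1.0 + std::exp((v + 89.1) / 6.086));
  gtau[13] = 3.0 * gtau[11];
  const double hp = Ahf * hf + Ahs * hsp;
  ginf[14] = hss;
  gtau[14] = 1.46 * gtau[12];
  const double GNa = 75.0;
  const double fINap = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double INa = g[0] * GNa * (v - ENa) * m * m * m *
                     ((1.0 - fINap) * h * jg + fINap * hp * jp);

  // INaL (late sodium)
  ginf[15] = 1.0 / (1.0 + std::exp(-(v + 42.85) / 5.264));
  gtau[15] = gtau[9];
  ginf[16] = 1.0 / (1.0 + std::exp((v + 87.61) / 7.488));
  gtau[16] = 200.0;
  ginf[17] = 1.0 / (1.0 + std::exp((v + 93.81) / 7.488));
  gtau[17] = 3.0 * 200.0;
  const double GNaL = 0.0075; // endo
  const double fINaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double INaL = g[1] * GNaL * (v - ENa) * mL *
                      ((1.0 - fINaLp) * hL + fINaLp * hLp);

  // Ito (transient outward potassium)
  ginf[18] = 1.0 / (1.0 + std::exp(-(v - 14.34) / 14.82));
  gtau[18] = 1.0515 /
             (1.0 / (1.2089 * (1.0 + std::exp(-(v - 18.4099) / 29.3814))) +
              3.5 / (1.0 + std::exp((v + 100.0) / 29.3814)));
  const double iss = 1.0 / (1.0 + std::exp((v + 43.94) / 5.711));
  const double delta_epi = 1.0; // endo
  ginf[19] = iss;
  gtau[19] = delta_epi *
             (4.562 + 1.0 / (0.3933 * std::exp(-(v + 100.0) / 100.0) +
                             0.08004 * std::exp((v + 50.0) / 16.59)));
  ginf[20] = iss;
  gtau[20] = delta_epi *
             (23.62 + 1.0 / (0.001416 * std::exp(-(v + 96.52) / 59.05) +
                             1.780e-8 * std::exp((v + 114.1) / 8.079)));
  const double AiF = 1.0 / (1.0 + std::exp((v - 213.6) / 151.2));
  const double AiS = 1.0 - AiF;
  const double ito_i = AiF * iF + AiS * iS;
  ginf[21] = 1.0 / (1.0 + std::exp(-(v - 24.34) / 14.82));
  gtau[21] = gtau[18];
  const double dti_develop =
      1.354 + 1.0e-4 / (std::exp((v - 167.4) / 15.89) +
                        std::exp(-(v - 12.23) / 0.2154));
  const double dti_recover = 1.0 - 0.5 / (1.0 + std::exp((v + 70.0) / 20.0));
  ginf[22] = iss;
  gtau[22] = dti_develop * dti_recover * gtau[19];
  ginf[23] = iss;
  gtau[23] = dti_develop * dti_recover * gtau[20];
  const double ito_ip = AiF * iFp + AiS * iSp;
  const double Gto = 0.02; // endo
  const double fItop = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Ito = g[3] * Gto * (v - EK) *
                     ((1.0 - fItop) * a * ito_i + fItop * ap * ito_ip);

  // ICaL / ICaNa / ICaK
  ginf[24] = 1.0 / (1.0 + std::exp(-(v + 3.940) / 4.230));
  gtau[24] = 0.6 + 1.0 / (std::exp(-0.05 * (v + 6.0)) +
                          std::exp(0.09 * (v + 14.0)));
  const double fss = 1.0 / (1.0 + std::exp((v + 19.58) / 3.696));
  ginf[25] = fss;
  gtau[25] = 7.0 + 1.0 / (0.0045 * std::exp(-(v + 20.0) / 10.0) +
                          0.0045 * std::exp((v + 20.0) / 10.0));
  ginf[26] = fss;
  gtau[26] = 1000.0 + 1.0 / (0.000035 * std::exp(-(v + 5.0) / 4.0) +
                             0.000035 * std::exp((v + 5.0) / 6.0));
  const double Aff = 0.6, Afs = 1.0 - Aff;
  const double f = Aff * ff + Afs * fs;
  ginf[27] = fss;
  gtau[27] = 7.0 + 1.0 / (0.04 * std::exp(-(v - 4.0) / 7.0) +
                          0.04 * std::exp((v - 4.0) / 7.0));
  ginf[28] = fss;
  gtau[28] = 100.0 + 1.0 / (0.00012 * std::exp(-v / 3.0) +
                            0.00012 * std::exp(v / 7.0));
  const double Afcaf = 0.3 + 0.6 / (1.0 + std::exp((v - 10.0) / 10.0));
  const double Afcas = 1.0 - Afcaf;
  const double fca = Afcaf * fcaf + Afcas * fcas;
  ginf[29] = fss;
  gtau[29] = 75.0;
  const double ktaup = 2.5;
  ginf[31] = fss;
  gtau[31] = ktaup * gtau[25];
  const double fp = Aff * ffp + Afs * fs;
  ginf[32] = fss;
  gtau[32] = ktaup * gtau[27];
  const double fcap = Afcaf * fcafp + Afcas * fcas;
  const double Kmn = 0.002, k2n = 1000.0;
  const double km2n = jca * 1.0;
  const double t4 = (1.0 + Kmn / cass) * (1.0 + Kmn / cass) *
                    (1.0 + Kmn / cass) * (1.0 + Kmn / cass);
  const double anca = 1.0 / (k2n / km2n + t4);
  // dnca = anca*k2n - nca*km2n  ->  inf = anca*k2n/km2n, tau = 1/km2n
  ginf[30] = anca * k2n / km2n;
  gtau[30] = 1.0 / km2n;
  const double e2v = std::exp(2.0 * vfrt), e1v = std::exp(vfrt);
  const double PhiCaL = 4.0 * vffrt * (cass * e2v - 0.341 * cao) / (e2v - 1.0);
  const double PhiCaNa = vffrt * (0.75 * nass * e1v - 0.75 * nao) / (e1v - 1.0);
  const double PhiCaK = vffrt * (0.75 * kss * e1v - 0.75 * ko) / (e1v - 1.0);
  const double PCa = 0.0001 * g[2]; // endo
  const double PCap = 1.1 * PCa;
  const double PCaNa = 0.00125 * PCa, PCaK = 3.574e-4 * PCa;
  const double PCaNap = 0.00125 * PCap, PCaKp = 3.574e-4 * PCap;
  const double fICaLp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double gate_np = d * (f * (1.0 - nca) + jca * fca * nca);
  const double gate_p = d * (fp * (1.0 - nca) + jca * fcap * nca);
  const double ICaL =
      (1.0 - fICaLp) * PCa * PhiCaL * gate_np + fICaLp * PCap * PhiCaL * gate_p;
  const double ICaNa = (1.0 - fICaLp) * PCaNa * PhiCaNa * gate_np +
                       fICaLp * PCaNap * PhiCaNa * gate_p;
  const double ICaK = (1.0 - fICaLp) * PCaK * PhiCaK * gate_np +
                      fICaLp * PCaKp * PhiCaK * gate_p;

  // IKr
  const double xrss = 1.0 / (1.0 + std::exp(-(v + 8.337) / 6.789));
  ginf[33] = xrss;
  gtau[33] = 12.98 + 1.0 / (0.3652 * std::exp((v - 31.66) / 3.869) +
                            4.123e-5 * std::exp(-(v - 47.78) / 20.38));
  ginf[34] = xrss;
  gtau[34] = 1.865 + 1.0 / (0.06629 * std::exp((v - 34.70) / 7.355) +
                            1.128e-5 * std::exp(-(v - 29.74) / 25.94));
  const double Axrf = 1.0 / (1.0 + std::exp((v + 54.81) / 38.21));
  const double Axrs = 1.0 - Axrf;
  const double xr = Axrf * xrf + Axrs * xrs;
  const double rkr = 1.0 / (1.0 + std::exp((v + 55.0) / 75.0)) *
                     1.0 / (1.0 + std::exp((v - 10.0) / 30.0));
  const double GKr = 0.046;
  const double IKr = g[4] * GKr * std::sqrt(ko / 5.4) * xr * rkr * (v - EK);

  // IKs
  const double xs1ss = 1.0 / (1.0 + std::exp(-(v + 11.60) / 8.932));
  ginf[35] = xs1ss;
  gtau[35] = 817.3 + 1.0 / (2.326e-4 * std::exp((v + 48.28) / 17.80) +
                            0.001292 * std::exp(-(v + 210.0) / 230.0));
  ginf[36] = xs1ss;
  gtau[36] = 1.0 / (0.01 * std::exp((v - 50.0) / 20.0) +
                    0.0193 * std::exp(-(v + 66.54) / 31.0));
  const double KsCa = 1.0 + 0.6 / (1.0 + std::pow(3.8e-5 / cai, 1.4));
  const double GKs = 0.0034;
  const double IKs = g[5] * GKs * KsCa * xs1 * xs2 * (v - EKs);

  // IK1
  ginf[37] = 1.0 / (1.0 + std::exp(-(v + 2.5538 * ko + 144.59) /
                                   (1.5692 * ko + 3.8115)));
  gtau[37] = 122.2 / (std::exp(-(v + 127.2) / 20.36) +
                      std::exp((v + 236.8) / 69.33));
  const double rk1 = 1.0 / (1.0 + std::exp((v + 105.8 - 2.6 * ko) / 9.493));
  const double GK1 = 0.1908;
  const double IK1 = g[6] * GK1 * std::sqrt(ko) * rk1 * xk1 * (v - EK);

  // INaCa (sodium-calcium exchanger), myoplasmic and subspace components
  const double kna1 = 15.0, kna2 = 5.0, kna3 = 88.12;
  const double kasymm = 12.5, wna = 6.0e4, wca = 6.0e4, wnaca = 5.0e3;
  const double kcaon = 1.5e6, kcaoff = 5.0e3;
  const double qna = 0.5224, qca = 0.1670;
  const double hca = std::exp(qca * v * Frdy / (Rgas * Temp));
  const double hna = std::exp(qna * v * Frdy / (Rgas * Temp));
  const double KmCaAct = 150.0e-6;
  const double zca = 2.0, zna = 1.0;
  const double Gncx = 0.0008 * g[7];
  double INaCa_i, INaCa_ss;
  {
    const double h1 = 1.0 + nai / kna3 * (1.0 + hna);
    const double h2 = (nai * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nai / kna1 * (1.0 + nai / kna2);
    const double h5 = nai * nai / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon;
    const double k2 = kcaoff;
    const double k3p = h9 * wca;
    const double k3pp = h8 * wnaca;
    const double k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4 = k4p + k4pp;
    const double k5 = kcaoff;
    const double k6 = h6 * cai * kcaon;
    const double k7 = h5 * h2 * wna;
    const double k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double s = x1 + x2 + x3 + x4;
    const double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    const double allo = 1.0 / (1.0 + (KmCaAct / cai) * (KmCaAct / cai));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_i = 0.8 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }
  {
    const double h1 = 1.0 + nass / kna3 * (1.0 + hna);
    const double h2 = (nass * hna) / (kna3 * h1);
    const double h3 = 1.0 / h1;
    const double h4 = 1.0 + nass / kna1 * (1.0 + nass / kna2);
    const double h5 = nass * nass / (h4 * kna1 * kna2);
    const double h6 = 1.0 / h4;
    const double h7 = 1.0 + nao / kna3 * (1.0 + 1.0 / hna);
    const double h8 = nao / (kna3 * hna * h7);
    const double h9 = 1.0 / h7;
    const double h10 = kasymm + 1.0 + nao / kna1 * (1.0 + nao / kna2);
    const double h11 = nao * nao / (h10 * kna1 * kna2);
    const double h12 = 1.0 / h10;
    const double k1 = h12 * cao * kcaon;
    const double k2 = kcaoff;
    const double k3p = h9 * wca;
    const double k3pp = h8 * wnaca;
    const double k3 = k3p + k3pp;
    const double k4p = h3 * wca / hca;
    const double k4pp = h2 * wnaca;
    const double k4 = k4p + k4pp;
    const double k5 = kcaoff;
    const double k6 = h6 * cass * kcaon;
    const double k7 = h5 * h2 * wna;
    const double k8 = h8 * h11 * wna;
    const double x1 = k2 * k4 * (k7 + k6) + k5 * k7 * (k2 + k3);
    const double x2 = k1 * k7 * (k4 + k5) + k4 * k6 * (k1 + k8);
    const double x3 = k1 * k3 * (k7 + k6) + k8 * k6 * (k2 + k3);
    const double x4 = k2 * k8 * (k4 + k5) + k3 * k5 * (k1 + k8);
    const double s = x1 + x2 + x3 + x4;
    const double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    const double allo = 1.0 / (1.0 + (KmCaAct / cass) * (KmCaAct / cass));
    const double JncxNa = 3.0 * (E4 * k7 - E1 * k8) + E3 * k4pp - E2 * k3pp;
    const double JncxCa = E2 * k2 - E1 * k1;
    INaCa_ss = 0.2 * Gncx * allo * (zna * JncxNa + zca * JncxCa);
  }

  // INaK (sodium-potassium pump)
  double INaK;
  {
    const double k1p = 949.5, k1m = 182.4, k2p = 687.2, k2m = 39.4;
    const double k3p = 1899.0, k3m = 79300.0, k4p = 639.0, k4m = 40.0;
    const double Knai0 = 9.073, Knao0 = 27.78, delta = -0.1550;
    const double Knai =
        Knai0 * std::exp(delta * v * Frdy / (3.0 * Rgas * Temp));
    const double Knao =
        Knao0 * std::exp((1.0 - delta) * v * Frdy / (3.0 * Rgas * Temp));
    const double Kki = 0.5, Kko = 0.3582;
    const double MgADP = 0.05, MgATP = 9.8, Kmgatp = 1.698e-7;
    const double Hc = 1.0e-7, eP = 4.2, Khp = 1.698e-7, Knap = 224.0,
                 Kxkur = 292.0;
    const double P = eP / (1.0 + Hc / Khp + nai / Knap + ki / Kxkur);
    const double c_nai = 1.0 + nai / Knai, c_nao = 1.0 + nao / Knao;
    const double c_ki = 1.0 + ki / Kki, c_ko = 1.0 + ko / Kko;
    const double a1 = (k1p * std::pow(nai / Knai, 3.0)) /
                      (c_nai * c_nai * c_nai + c_ki * c_ki - 1.0);
    const double b1 = k1m * MgADP;
    const double a2 = k2p;
    const double b2 = (k2m * std::pow(nao / Knao, 3.0)) /
                      (c_nao * c_nao * c_nao + c_ko * c_ko - 1.0);
    const double a3 = (k3p * std::pow(ko / Kko, 2.0)) /
                      (c_nao * c_nao * c_nao + c_ko * c_ko - 1.0);
    const double b3 = (k3m * P * Hc) / (1.0 + MgATP / Kmgatp);
    const double a4 = (k4p * MgATP / Kmgatp) / (1.0 + MgATP / Kmgatp);
    const double b4 = (k4m * std::pow(ki / Kki, 2.0)) /
                      (c_nai * c_nai * c_nai + c_ki * c_ki - 1.0);
    const double x1 = a4 * a1 * a2 + b2 * b4 * b3 + a2 * b4 * b3 + b3 * a1 * a2;
    const double x2 = b2 * b1 * b4 + a1 * a2 * a3 + a3 * b1 * b4 + a2 * a3 * b4;
    const double x3 = a2 * a3 * a4 + b3 * b2 * b1 + b2 * b1 * a4 + a3 * a4 * b1;
    const double x4 = b4 * b3 * b2 + a3 * a4 * a1 + b2 * a4 * a1 + b3 * b2 * a1;
    const double s = x1 + x2 + x3 + x4;
    const double E1 = x1 / s, E2 = x2 / s, E3 = x3 / s, E4 = x4 / s;
    const double zk = 1.0;
    const double JnakNa = 3.0 * (E1 * a3 - E2 * b3);
    const double JnakK = 2.0 * (E4 * b1 - E3 * a1);
    const double Pnak = 30.0 * g[8]; // endo
    INaK = Pnak * (zna * JnakNa + zk * JnakK);
  }

  // background and pump currents (fixed, not drug targets)
  const double xkb = 1.0 / (1.0 + std::exp(-(v - 14.48) / 18.34));
  const double GKb = 0.003; // endo
  const double IKb = GKb * xkb * (v - EK);
  const double PNab = 3.75e-10;
  const double INab = PNab * vffrt * (nai * e1v - nao) / (e1v - 1.0);
  const double PCab = 2.5e-8;
  const double ICab =
      PCab * 4.0 * vffrt * (cai * e2v - 0.341 * cao) / (e2v - 1.0);
  const double GpCa = 0.0005;
  const double IpCa = GpCa * cai / (0.0005 + cai);

  // diffusion fluxes between subspace and myoplasm
  const double JdiffNa = (nass - nai) / 2.0;
  const double JdiffK = (kss - ki) / 2.0;
  const double Jdiff = (cass - cai) / 0.2;

  // SR calcium release (RyR), endo (no cell-type multiplier)
  const double bt = 4.75, a_rel = 0.5 * bt;
  const double csqn8 = std::pow(1.5 / cajsr, 8.0);
  const double Jrel_inf = a_rel * (-ICaL) / (1.0 + csqn8);
  double tau_rel = bt / (1.0 + 0.0123 / cajsr);
  if (tau_rel < 0.001) tau_rel = 0.001;
  ginf[38] = Jrel_inf;
  gtau[38] = tau_rel;
  const double btp = 1.25 * bt, a_relp = 0.5 * btp;
  const double Jrel_infp = a_relp * (-ICaL) / (1.0 + csqn8);
  double tau_relp = btp / (1.0 + 0.0123 / cajsr);
  if (tau_relp < 0.001) tau_relp = 0.001;
  ginf[39] = Jrel_infp;
  gtau[39] = tau_relp;
  const double fJrelp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Jrel = (1.0 - fJrelp) * Jrelnp + fJrelp * Jrelp;

  // SR calcium uptake (SERCA) and translocation
  const double Jupnp = 0.004375 * cai / (cai + 0.00092);
  const double Jupp = 2.75 * 0.004375 * cai / (cai + 0.00092 - 0.00017);
  const double fJupp = 1.0 / (1.0 + KmCaMK / CaMKa);
  const double Jleak = 0.0039375 * cansr / 15.0;
  const double Jup = (1.0 - fJupp) * Jupnp + fJupp * Jupp - Jleak;
  const double Jtr = (cansr - cajsr) / 100.0;

  // concentration derivatives (endo buffer parameters)
  const double cmdnmax = 0.05, kmcmdn = 0.00238, trpnmax = 0.07,
               kmtrpn = 0.0005, BSRmax = 0.047, KmBSR = 0.00087,
               BSLmax = 1.124, KmBSL = 0.0087, csqnmax = 10.0, kmcsqn = 0.8;
  dy[1] = -(INa + INaL + 3.0 * INaCa_i + 3.0 * INaK + INab) * Acap /
              (Frdy * vmyo) +
          JdiffNa * vss / vmyo;
  dy[2] = -(ICaNa + 3.0 * INaCa_ss) * Acap / (Frdy * vss) - JdiffNa;
  // stimulus carried by K+ (Istim here positive = depolarizing)
  dy[3] = -(Ito + IKr + IKs + IK1 + IKb - Istim - 2.0 * INaK) * Acap /
              (Frdy * vmyo) +
          JdiffK * vss / vmyo;
  dy[4] = -ICaK * Acap / (Frdy * vss) - JdiffK;
  const double d1 = kmcmdn + cai, d2 = kmtrpn + cai;
  const double Bcai =
      1.0 / (1.0 + cmdnmax * kmcmdn / (d1 * d1) +
             trpnmax * kmtrpn / (d2 * d2));
  dy[5] = Bcai * (-(IpCa + ICab - 2.0 * INaCa_i) * Acap / (2.0 * Frdy * vmyo) -
                  Jup * vnsr / vmyo + Jdiff * vss / vmyo);
  const double d3 = KmBSR + cass, d4 = KmBSL + cass;
  const double Bcass =
      1.0 / (1.0 + BSRmax * KmBSR / (d3 * d3) + BSLmax * KmBSL / (d4 * d4));
  dy[6] = Bcass * (-(ICaL - 2.0 * INaCa_ss) * Acap / (2.0 * Frdy * vss) +
                   Jrel * vjsr / vss - Jdiff);
  dy[7] = Jup - Jtr * vjsr / vnsr;
  const double d5 = kmcsqn + cajsr;
  const double Bcajsr = 1.0 / (1.0 + csqnmax * kmcsqn / (d5 * d5));
  dy[8] = Bcajsr * (Jtr - Jrel);

  // membrane potential (Cm = 1 uF/cm^2; currents per unit capacitance)
  const double Itot = INa + INaL + ICaL + ICaNa + ICaK + Ito + IKr + IKs +
                      IK1 + INaCa_i + INaCa_ss + INaK + INab + IKb + IpCa +
                      ICab;
  dy[0] = -Itot + Istim;

  // gate derivatives for the rhs interface
  for (int i = 9; i <= 39; ++i) dy[i] = (ginf[i] - y[i]) / gtau[i];

  if (cur != nullptr) {
    cur[0] = INa; cur[1] = INaL; cur[2] = ICaL; cur[3] = Ito; cur[4] = IKr;
    cur[5] = IKs; cur[6] = IK1; cur[7] = INaCa_i + INaCa_ss; cur[8] = INaK;
    cur[9] = IKb; cur[10] = INab; cur[11] = ICab; cur[12] = IpCa;
  }
}

// single hybrid step (Rush-Larsen gates, forward Euler otherwise), in place
static inline void ord_step(double *y, const double *g, double Istim,
                            double dt, double *dy, double *ginf,
                            double *gtau) {
  ord_compute(y, g, Istim, dy, ginf, gtau, nullptr);
  y[0] += dt * dy[0];
  for (int i = 1; i <= 8; ++i) y[i] += dt * dy[i];
  y[40] += dt * dy[40];
  for (int i = 9; i <= 39; ++i)
    y[i] = ginf[i] + (y[i] - ginf[i]) * std::exp(-dt / gtau[i]);
}

static const char *STATE_NAMES[NY] = {
    "v", "nai", "nass", "ki", "kss", "cai", "cass", "cansr", "cajsr",
    "m", "hf", "hs", "j", "hsp", "jp", "mL", "hL", "hLp",
    "a", "iF", "iS", "ap", "iFp", "iSp",
    "d", "ff", "fs", "fcaf", "fcas", "jca", "nca", "ffp", "fcafp",
    "xrf", "xrs", "xs1", "xs2", "xk1", "Jrelnp", "Jrelp", "CaMKt"};

static const char *CURRENT_NAMES[NC] = {
    "INa", "INaL", "ICaL", "Ito", "IKr", "IKs", "IK1", "INaCa", "INaK",
    "IKb", "INab", "ICab", "IpCa"};

// [[Rcpp::export]]
CharacterVector ord_state_names_cpp() {
  CharacterVector out(NY);
  for (int i = 0; i < NY; ++i) out[i] = STATE_NAMES[i];
  return out;
}

// [[Rcpp::export]]
CharacterVector ord_current_names_cpp() {
  CharacterVector out(NC);
  for (int i = 0; i < NC; ++i) out[i] = CURRENT_NAMES[i];
  return out;
}

// [[Rcpp::export]]
List ord_rates_cpp(NumericVector state, NumericVector scaling, double istim) {
  if (state.size() != NY) stop("state must have %d components", NY);
  if (scaling.size() != NG) stop("scaling must have %d components", NG);
  double dy[NY], ginf[NY], gtau[NY], cur[NC];
  ord_compute(REAL(state), REAL(scaling), istim, dy, ginf, gtau, cur);
  NumericVector d(NY), cc(NC);
  for (int i = 0; i < NY; ++i) d[i] = dy[i];
  for (int i = 0; i < NC; ++i) cc[i] = cur[i];
  d.attr("names") = ord_state_names_cpp();
  cc.attr("names") = ord_current_names_cpp();
  return List::create(_["derivatives"] = d, _["currents"] = cc);
}

// Paced single-cell run. Records voltage every `record_every` steps for the
// final `record_beats` beats; optionally records the 13 currents too.
// [[Rcpp::export]]
List ord_run_cpp(NumericVector state0, NumericVector scaling, int n_beats,
                 double bcl, double dt, double stim_amp, double stim_dur,
                 int record_beats, int record_every, bool record_currents) {
  if (state0.size() != NY) stop("state must have %d components", NY);
  if (scaling.size() != NG) stop("scaling must have %d components", NG);
  if (record_beats > n_beats) record_beats = n_beats;
  double y[NY];
  for (int i = 0; i < NY; ++i) y[i] = state0[i];
  double dy[NY], ginf[NY], gtau[NY], cur[NC];

  const int steps_per_beat = (int)std::lround(bcl / dt);
  const int stim_steps = (int)std::lround(stim_dur / dt);
  const int first_rec_beat = n_beats - record_beats;
  const int rec_per_beat = (steps_per_beat + record_every - 1) / record_every;
  const int n_rec = record_beats * rec_per_beat + 1;

  NumericVector t_out(n_rec), v_out(n_rec);
  NumericMatrix cur_out =
      record_currents ? NumericMatrix(n_rec, NC) : NumericMatrix(1, 1);
  IntegerVector beat_start_idx(record_beats);

  int ri = 0;
  for (int b = 0; b < n_beats; ++b) {
    const bool rec = (b >= first_rec_beat);
    if (rec) beat_start_idx[b - first_rec_beat] = ri + 1; // 1-based for R
    for (int s = 0; s < steps_per_beat; ++s) {
      const double tt = (double)b * bcl + s * dt;
      if (rec && (s % record_every == 0)) {
        t_out[ri] = tt;
        v_out[ri] = y[0];
        if (record_currents) {
          ord_compute(y, REAL(scaling), 0.0, dy, ginf, gtau, cur);
          for (int c = 0; c < NC; ++c) cur_out(ri, c) = cur[c];
        }
        ++ri;
      }
      const double Istim = (s < stim_steps) ? stim_amp : 0.0;
      ord_step(y, REAL(scaling), Istim, dt, dy, ginf, gtau);
      if (!std::isfinite(y[0]))
        stop("integration failure (non-finite voltage) at t = %.3f ms",
             tt + dt);
    }
  }
  t_out[ri] = (double)n_beats * bcl;
  v_out[ri] = y[0];
  if (record_currents) {
    ord_compute(y, REAL(scaling), 0.0, dy, ginf, gtau, cur);
    for (int c = 0; c < NC; ++c) cur_out(ri, c) = cur[c];
  }

  NumericVector yf(NY);
  for (int i = 0; i < NY; ++i) yf[i] = y[i];
  yf.attr("names") = ord_state_names_cpp();
  List out = List::create(
      _["t"] = t_out, _["v"] = v_out, _["beat_start_idx"] = beat_start_idx,
      _["final_state"] = yf,
      _["currents"] = record_currents ? (SEXP)cur_out : R_NilValue);
  return out;
}

// Short run used by the capture test / threshold bisection: returns max V
// reached within t_max ms of a single stimulus.
// [[Rcpp::export]]
double ord_peak_cpp(NumericVector state0, NumericVector scaling,
                    double stim_amp, double stim_dur, double dt,
                    double t_max) {
  double y[NY];
  for (int i = 0; i < NY; ++i) y[i] = state0[i];
  double dy[NY], ginf[NY], gtau[NY];
  const int n_steps = (int)std::lround(t_max / dt);
  const int stim_steps = (int)std::lround(stim_dur / dt);
  double vmax = y[0];
  for (int s = 0; s < n_steps; ++s) {
    const double Istim = (s < stim_steps) ? stim_amp : 0.0;
    ord_step(y, REAL(scaling), Istim, dt, dy, ginf, gtau);
    if (!std::isfinite(y[0])) stop("integration failure in capture test");
    if (y[0] > vmax) vmax = y[0];
  }
  return vmax;
}

// ---------------------------------------------------------------------------
// Monodomain tissue stepper: operator splitting with per-node ionic update
// (the hybrid step above) followed by a backward-Euler diffusion solve
//   (M + c K) V_new = M V*,
// where M is the lumped FEM mass vector, K the stiffness matrix (CSC arrays
// from R's Matrix package) and c = 1000 * dt / (beta * Cm) closes the units
// between S/cm, uF/cm^2 and ms. The system is symmetric positive definite
// and strongly diagonally dominant (c*K is a small perturbation of M), so a
// Jacobi-preconditioned conjugate gradient with warm start converges in a
// handful of iterations.
// ---------------------------------------------------------------------------

static int cg_solve(int n, const int *Kp, const int *Ki, const double *Kx,
                    const double *M, double c, const double *b, double *x,
                    double tol, int maxit, double *r, double *z, double *p,
                    double *q) {
  // A x = b with A = diag(M) + c*K ; x holds the warm start on entry
  // r = b - A x
  for (int i = 0; i < n; ++i) r[i] = b[i] - M[i] * x[i];
  for (int col = 0; col < n; ++col)
    for (int idx = Kp[col]; idx < Kp[col + 1]; ++idx)
      r[Ki[idx]] -= c * Kx[idx] * x[col];
  double bnorm = 0.0;
  for (int i = 0; i < n; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0.0) bnorm = 1.0;
  double rz = 0.0;
  for (int i = 0; i < n; ++i) {
    z[i] = r[i] / M[i];
    p[i] = z[i];
    rz += r[i] * z[i];
  }
  for (int it = 0; it < maxit; ++it) {
    double rn = 0.0;
    for (int i = 0; i < n; ++i) rn += r[i] * r[i];
    if (std::sqrt(rn) <= tol * bnorm) return it;
    for (int i = 0; i < n; ++i) q[i] = M[i] * p[i];
    for (int col = 0; col < n; ++col) {
      const double pc = p[col];
      if (pc != 0.0)
        for (int idx = Kp[col]; idx < Kp[col + 1]; ++idx)
          q[Ki[idx]] += c * Kx[idx] * pc;
    }
    double pq = 0.0;
    for (int i = 0; i < n; ++i) pq += p[i] * q[i];
    const double alpha = rz / pq;
    for (int i = 0; i < n; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * q[i];
    }
    double rz_new = 0.0;
    for (int i = 0; i < n; ++i) {
      z[i] = r[i] / M[i];
      rz_new += r[i] * z[i];
    }
    const double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < n; ++i) p[i] = z[i] + beta * p[i];
  }
  return -1;
}

// [[Rcpp::export]]
List monodomain_run_cpp(NumericMatrix states, NumericMatrix scalings,
                        IntegerVector Kp, IntegerVector Ki, NumericVector Kx,
                        NumericVector Mlump, double diff_coef, int n_beats,
                        double bcl, double dt, double stim_amp,
                        double stim_dur, IntegerVector stim_nodes,
                        int record_beats, int record_every, double act_thresh,
                        double cg_tol, int cg_maxit) {
  const int n = states.ncol();
  if (states.nrow() != NY) stop("states must be %d x n_nodes", NY);
  if (scalings.nrow() != NG || scalings.ncol() != n)
    stop("scalings must be %d x n_nodes", NG);
  if (record_beats > n_beats) record_beats = n_beats;

  std::vector<double> Y(states.begin(), states.end()); // column-major, NY*n
  std::vector<double> V(n), Vstar(n), Vprev(n);
  std::vector<double> r(n), z(n), p(n), q(n);
  std::vector<char> is_stim(n, 0);
  for (int k = 0; k < stim_nodes.size(); ++k) is_stim[stim_nodes[k] - 1] = 1;

  const int steps_per_beat = (int)std::lround(bcl / dt);
  const int stim_steps = (int)std::lround(stim_dur / dt);
  const int first_rec_beat = n_beats - record_beats;
  const int rec_per_beat = (steps_per_beat + record_every - 1) / record_every;
  const int n_rec = record_beats * rec_per_beat + 1;

  NumericVector t_out(n_rec);
  NumericMatrix v_out(n_rec, n);
  IntegerVector beat_start_idx(record_beats);
  // activation time (first upward crossing of act_thresh) per node per beat
  NumericMatrix act(n_beats, n);
  std::fill(act.begin(), act.end(), NA_REAL);

  double dy[NY], ginf[NY], gtau[NY];
  const double c = diff_coef * dt; // diff_coef = 1000 / (beta * Cm)

  int ri = 0;
  for (int b = 0; b < n_beats; ++b) {
    const bool rec = (b >= first_rec_beat);
    if (rec) beat_start_idx[b - first_rec_beat] = ri + 1;
    std::vector<char> activated(n, 0);
    for (int s = 0; s < steps_per_beat; ++s) {
      const double tt = (double)b * bcl + s * dt;
      if (rec && (s % record_every == 0)) {
        t_out[ri] = tt;
        for (int i = 0; i < n; ++i) v_out(ri, i) = Y[(size_t)i * NY];
        ++ri;
      }
      // ionic step per node
      const double amp = (s < stim_steps) ? stim_amp : 0.0;
      for (int i = 0; i < n; ++i) {
        double *yi = &Y[(size_t)i * NY];
        Vprev[i] = yi[0];
        const double Istim = is_stim[i] ? amp : 0.0;
        ord_step(yi, &scalings(0, i), Istim, dt, dy, ginf, gtau);
        if (!std::isfinite(yi[0]))
          stop("integration failure at node %d, t = %.3f ms", i + 1, tt);
        Vstar[i] = yi[0];
      }
      // implicit diffusion: (M + cK) V = M V*
      for (int i = 0; i < n; ++i) {
        r[i] = Mlump[i] * Vstar[i]; // reuse r as rhs
        V[i] = Vstar[i];            // warm start
      }
      const int it = cg_solve(n, INTEGER(Kp), INTEGER(Ki), REAL(Kx),
                              REAL(Mlump), c, r.data(), V.data(), cg_tol,
                              cg_maxit, z.data(), p.data(), q.data(),
                              Vstar.data());
      if (it < 0)
        stop("diffusion solve failed to converge at beat %d step %d", b + 1,
             s + 1);
      for (int i = 0; i < n; ++i) {
        if (!activated[i] && Vprev[i] < act_thresh && V[i] >= act_thresh) {
          act(b, i) = tt + dt - (double)b * bcl;
          activated[i] = 1;
        }
        Y[(size_t)i * NY] = V[i];
      }
    }
  }
  t_out[ri] = (double)n_beats * bcl;
  for (int i = 0; i < n; ++i) v_out(ri, i) = Y[(size_t)i * NY];

  NumericMatrix Yf(NY, n);
  std::copy(Y.begin(), Y.end(), Yf.begin());
  return List::create(_["t"] = t_out, _["v"] = v_out,
                      _["beat_start_idx"] = beat_start_idx,
                      _["activation"] = act, _["final_states"] = Yf);
}
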