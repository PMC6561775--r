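#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Face positions use 0-based row-major linear indices for the 4x4 grid.
// PERM[k][x] is the opposing-face position contacted by position x when the
// opposing face is rotated by k*90 degrees. Each map is an involution; the
// 90-degree map fixes the main diagonal (positions 1, 6, 11, 16 in 1-based
// numbering) and the 270-degree map fixes the anti-diagonal.
static int PERM[4][16];
static bool perm_ready = false;

static void init_perms() {
  if (perm_ready) return;
  for (int x = 0; x < 16; ++x) {
    int r = x / 4 + 1, c = x % 4 + 1;
    PERM[0][x] = (4 - r) * 4 + (c - 1); // (5-r, c)
    PERM[1][x] = (c - 1) * 4 + (r - 1); // (c, r)
    PERM[2][x] = (r - 1) * 4 + (4 - c); // (r, 5-c)
    PERM[3][x] = (4 - c) * 4 + (4 - r); // (5-c, 5-r)
  }
  perm_ready = true;
}

// minimum over the four rotations of the 16-contact energy sum
static double iface_energy(const int* f1, const int* f2, const double* B) {
  double best = R_PosInf;
  for (int k = 0; k < 4; ++k) {
    double e = 0.0;
    for (int x = 0; x < 16; ++x) e += B[f1[x] + 20 * f2[PERM[k][x]]];
    if (e < best) best = e;
  }
  return best;
}

// [[Rcpp::export]]
IntegerMatrix cpp_rotation_partners() {
  init_perms();
  IntegerMatrix out(16, 4);
  for (int k = 0; k < 4; ++k)
    for (int x = 0; x < 16; ++x) out(x, k) = PERM[k][x] + 1;
  return out;
}

// seqs: N x 32 matrix of 0-based residue indices; B: 20 x 20 energies (kT).
// Returns N x 4: E_AA, E_BB, E_AB after canonical relabelling (E_AA <= E_BB),
// with column 4 = 1 if the faces were swapped.
// [[Rcpp::export]]
NumericMatrix cpp_ensemble_energies(const IntegerMatrix& seqs,
                                    const NumericMatrix& B) {
  init_perms();
  const int n = seqs.nrow();
  if (seqs.ncol() != 32) stop("sequences must have 32 residues");
  NumericMatrix out(n, 4);
  std::vector<int> fa(16), fb(16);
  const double* b = &B(0, 0);
  for (int i = 0; i < n; ++i) {
    for (int x = 0; x < 16; ++x) {
      fa[x] = seqs(i, x);
      fb[x] = seqs(i, 16 + x);
    }
    double eaa = iface_energy(fa.data(), fa.data(), b);
    double ebb = iface_energy(fb.data(), fb.data(), b);
    double eab = iface_energy(fa.data(), fb.data(), b);
    bool swap = eaa > ebb;
    out(i, 0) = swap ? ebb : eaa;
    out(i, 1) = swap ? eaa : ebb;
    out(i, 2) = eab;
    out(i, 3) = swap ? 1.0 : 0.0;
  }
  return out;
}

struct Phen {
  double c, P1, P2, P2s, Pfib, Pori;
};

// Equilibrium phenotype at total concentration phi (units of c0) from the
// three interface energies: statistical weights a_ij = exp(-E_ij)/omega,
// transfer-matrix eigenvalues lambda+- = a_AB +- sqrt(a_AA a_BB), and the
// monomer concentration c solving
//   phi = A+ c/(1 - lambda+ c)^2 - A- c/(1 - lambda- c)^2,
// found by bisection on (0, min(phi, 1/lambda+)) where the right side is
// monotone increasing with a unique root.
static Phen phenotype_kernel(double EAA, double EBB, double EAB, double phi,
                             double omega) {
  double aAA = std::exp(-EAA) / omega;
  double aBB = std::exp(-EBB) / omega;
  double aAB = std::exp(-EAB) / omega;
  double s = std::sqrt(aAA * aBB);
  double lp = aAB + s, lm = aAB - s;
  double Ap = (aAA + aBB + 2.0 * s) / (4.0 * s);
  double Am = (aAA + aBB - 2.0 * s) / (4.0 * s);
  double lo = 0.0, hi = std::min(phi, (1.0 - 1e-12) / lp);
  for (int it = 0; it < 200; ++it) {
    double mid = 0.5 * (lo + hi);
    double t1 = 1.0 - lp * mid, t2 = 1.0 - lm * mid;
    double f = Ap * mid / (t1 * t1) - Am * mid / (t2 * t2) - phi;
    if (f > 0.0) hi = mid; else lo = mid;
  }
  Phen p;
  p.c = 0.5 * (lo + hi);
  p.P1 = p.c / phi;
  double C2 = 0.5 * p.c * p.c * (aAA + 2.0 * aAB + aBB);
  p.P2 = 2.0 * C2 / phi;
  p.Pfib = 1.0 - p.P1 - p.P2;
  if (p.Pfib < 0.0) p.Pfib = 0.0;
  p.P2s = p.P2 * aAA / (aAA + aBB + 2.0 * aAB);
  // oriented-fibril tail: sum_{n>=3} n x^n = x^3 (3 - 2x) / (1 - x)^2
  double x = p.c * aAB;
  double t = 1.0 - x;
  p.Pori = x * x * x * (3.0 - 2.0 * x) / (t * t) / (aAB * phi);
  return p;
}

// [[Rcpp::export]]
NumericVector cpp_solve_monomer(const NumericVector& aAA,
                                const NumericVector& aBB,
                                const NumericVector& aAB, double phi) {
  const int n = aAA.size();
  NumericVector out(n);
  for (int i = 0; i < n; ++i) {
    Phen p = phenotype_kernel(-std::log(aAA[i]), -std::log(aBB[i]),
                              -std::log(aAB[i]), phi, 1.0);
    out[i] = p.c;
  }
  return out;
}

// E: N x 3 canonical energies (kT). Returns N x 6:
// c, P1, P2, P2_star, P_fib, P_ori.
// [[Rcpp::export]]
NumericMatrix cpp_phenotypes(const NumericMatrix& E, double phi,
                             double omega) {
  const int n = E.nrow();
  NumericMatrix out(n, 6);
  for (int i = 0; i < n; ++i) {
    Phen p = phenotype_kernel(E(i, 0), E(i, 1), E(i, 2), phi, omega);
    out(i, 0) = p.c;
    out(i, 1) = p.P1;
    out(i, 2) = p.P2;
    out(i, 3) = p.P2s;
    out(i, 4) = p.Pfib;
    out(i, 5) = p.Pori;
  }
  return out;
}

static double scheme_score(const Phen& p, int scheme) {
  switch (scheme) {
    case 0: return 0.0;      // neutral
    case 1: return p.P2s;    // dimer
    case 2: return -p.Pfib;  // anti_fibril
    case 3: return p.Pfib;   // fibril
    case 4: return p.Pori;   // oriented_fibril
  }
  return 0.0;
}

// Metropolis chain over 32-residue sequences under the strong-selection
// weak-mutation sampler. Draw order per generation, using R's RNG stream:
// for each site 1..32 one uniform decides mutation (< u); each mutating site
// draws one more uniform mapped through the cumulative pi to a replacement
// residue (which may equal the current one); if the fitness exponent
// 2*Ne_sigma*(score_new - score_old) is negative, one final uniform decides
// acceptance. Rejected proposals record a second copy of the current state.
// [[Rcpp::export]]
List cpp_run_mcmc(const IntegerVector& start, const NumericMatrix& B,
                  int scheme, double ne_sigma, double phi, double omega,
                  double u, const NumericVector& pi_cum, int generations) {
  init_perms();
  if (start.size() != 32) stop("start sequence must have 32 residues");
  const double* b = &B(0, 0);
  std::vector<int> cur(32), prop(32);
  for (int x = 0; x < 32; ++x) cur[x] = start[x];

  auto energies3 = [&](const std::vector<int>& s, double* e) {
    e[0] = iface_energy(&s[0], &s[0], b);
    e[1] = iface_energy(&s[16], &s[16], b);
    e[2] = iface_energy(&s[0], &s[16], b);
  };
  auto canon = [](double* e, bool* swapped) {
    *swapped = e[0] > e[1];
    if (*swapped) std::swap(e[0], e[1]);
  };

  double ecur[3];
  bool sw_cur;
  energies3(cur, ecur);
  canon(ecur, &sw_cur);
  Phen pcur = phenotype_kernel(ecur[0], ecur[1], ecur[2], phi, omega);
  double score_cur = scheme_score(pcur, scheme);

  IntegerMatrix seqs(generations, 32);
  NumericMatrix ener(generations, 3);
  NumericMatrix phen(generations, 6);
  LogicalVector accepted(generations);
  LogicalVector relabelled(generations);

  for (int g = 0; g < generations; ++g) {
    bool changed = false;
    for (int x = 0; x < 32; ++x) {
      prop[x] = cur[x];
      if (unif_rand() < u) {
        double d = unif_rand();
        int j = 0;
        while (j < 19 && d > pi_cum[j]) ++j;
        if (j != prop[x]) changed = true;
        prop[x] = j;
      }
    }
    double eprop[3];
    bool sw_prop;
    Phen pprop;
    double score_prop;
    if (changed) {
      energies3(prop, eprop);
      canon(eprop, &sw_prop);
      pprop = phenotype_kernel(eprop[0], eprop[1], eprop[2], phi, omega);
      score_prop = scheme_score(pprop, scheme);
    } else {
      for (int k = 0; k < 3; ++k) eprop[k] = ecur[k];
      sw_prop = sw_cur;
      pprop = pcur;
      score_prop = score_cur;
    }
    double expo = 2.0 * ne_sigma * (score_prop - score_cur);
    bool acc = expo >= 0.0 || unif_rand() < std::exp(expo);
    if (acc) {
      cur = prop;
      for (int k = 0; k < 3; ++k) ecur[k] = eprop[k];
      sw_cur = sw_prop;
      pcur = pprop;
      score_cur = score_prop;
    }
    for (int x = 0; x < 32; ++x) seqs(g, x) = cur[x] + 1;
    ener(g, 0) = ecur[0];
    ener(g, 1) = ecur[1];
    ener(g, 2) = ecur[2];
    phen(g, 0) = pcur.c;
    phen(g, 1) = pcur.P1;
    phen(g, 2) = pcur.P2;
    phen(g, 3) = pcur.P2s;
    phen(g, 4) = pcur.Pfib;
    phen(g, 5) = pcur.Pori;
    accepted[g] = acc;
    relabelled[g] = sw_cur;
  }
  return List::create(_["sequences"] = seqs, _["energies"] = ener,
                      _["phenotypes"] = phen, _["accepted"] = accepted,
                      _["relabelled"] = relabelled);
}
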