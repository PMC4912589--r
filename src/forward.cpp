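#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Canonical parameter layout (51 entries, age-specific transitions):
//   1..4    survival logit intercepts, states 1..4
//   5..8    survival logit slopes (per age class)
//   9..29   multinomial-logit eta, from "with parents": ages 1..7,
//           destinations {1,2,3} (reference = 4), destination fastest
//   30..41  from "with siblings": ages 2..7, destinations {2,3} (ref 4)
//   42..47  from "independent/nonbreeder": ages 2..7, destination {3} (ref 4)
//   48..51  resighting probability, states 1..4 (probability scale)
// The age-constant model variant is expanded to this layout in R before the
// call, so the kernel sees one shape only.

static const int N_STATE = 5;   // 4 living + dead
static const int N_AGE = 7;

// Fill per-age 5x5 transition matrices M[a][from][to] combining survival
// and multinomial-logit transitions. Rows for states unreachable at an age
// (siblings/independent at age 1) reuse the age-2 coefficients; they carry
// no likelihood mass.
static void build_transition(const NumericVector& par,
                             double M[N_AGE][N_STATE][N_STATE]) {
  double phi[4][N_AGE];
  for (int s = 0; s < 4; ++s)
    for (int a = 0; a < N_AGE; ++a)
      phi[s][a] = 1.0 / (1.0 + std::exp(-(par[s] + par[s + 4] * (a + 1))));

  for (int a = 0; a < N_AGE; ++a) {
    double psi[4][4];
    for (int i = 0; i < 4; ++i)
      for (int j = 0; j < 4; ++j) psi[i][j] = 0.0;

    // from parents: eta at 8 + a*3 + d (0-based), dests 0,1,2, ref 3
    {
      double eta[3];
      for (int d = 0; d < 3; ++d) eta[d] = par[8 + a * 3 + d];
      double mx = 0.0;
      for (int d = 0; d < 3; ++d) if (eta[d] > mx) mx = eta[d];
      double denom = std::exp(-mx);
      for (int d = 0; d < 3; ++d) denom += std::exp(eta[d] - mx);
      for (int d = 0; d < 3; ++d) psi[0][d] = std::exp(eta[d] - mx) / denom;
      psi[0][3] = std::exp(-mx) / denom;
    }
    // from siblings and from independent/nonbreeder: estimable ages 2..7
    int aa = (a == 0) ? 1 : a;  // age-1 row reuses age-2 coefficients
    {
      double eta[2];
      for (int d = 0; d < 2; ++d) eta[d] = par[29 + (aa - 1) * 2 + d];
      double mx = 0.0;
      for (int d = 0; d < 2; ++d) if (eta[d] > mx) mx = eta[d];
      double denom = std::exp(-mx);
      for (int d = 0; d < 2; ++d) denom += std::exp(eta[d] - mx);
      psi[1][1] = std::exp(eta[0] - mx) / denom;
      psi[1][2] = std::exp(eta[1] - mx) / denom;
      psi[1][3] = std::exp(-mx) / denom;
    }
    {
      double eta = par[41 + (aa - 1)];
      double mx = eta > 0 ? eta : 0.0;
      double denom = std::exp(-mx) + std::exp(eta - mx);
      psi[2][2] = std::exp(eta - mx) / denom;
      psi[2][3] = std::exp(-mx) / denom;
    }
    psi[3][3] = 1.0;  // breeder absorbing

    for (int s = 0; s < 4; ++s) {
      for (int t = 0; t < 4; ++t)
        M[a][s][t] = phi[s][a] * psi[s][t];
      M[a][s][4] = 1.0 - phi[s][a];
    }
    for (int t = 0; t < 4; ++t) M[a][4][t] = 0.0;
    M[a][4][4] = 1.0;
  }
}

// [[Rcpp::export]]
double cpp_forward_loglik(NumericVector par, IntegerMatrix obs,
                          IntegerVector len, NumericVector count) {
  double M[N_AGE][N_STATE][N_STATE];
  build_transition(par, M);
  double p[4];
  for (int s = 0; s < 4; ++s) p[s] = par[47 + s];
  for (int s = 0; s < 4; ++s)
    if (p[s] < 0.0 || p[s] > 1.0) return R_NegInf;

  const int n = obs.nrow();
  double total = 0.0;
  double alpha[N_STATE], anew[N_STATE];

  for (int i = 0; i < n; ++i) {
    // conditioned on first capture: alive, with parents, at age 1
    for (int s = 0; s < N_STATE; ++s) alpha[s] = 0.0;
    alpha[0] = 1.0;
    double ll = 0.0;
    const int L = len[i];
    for (int t = 1; t < L; ++t) {
      int age = t <= N_AGE ? t : N_AGE;  // age class at previous occasion
      for (int s2 = 0; s2 < N_STATE; ++s2) {
        double acc = 0.0;
        for (int s = 0; s < N_STATE; ++s) acc += alpha[s] * M[age - 1][s][s2];
        anew[s2] = acc;
      }
      int o = obs(i, t);
      if (o > 0) {
        for (int s2 = 0; s2 < N_STATE; ++s2) alpha[s2] = 0.0;
        alpha[o - 1] = anew[o - 1] * p[o - 1];
      } else {
        for (int s2 = 0; s2 < 4; ++s2) alpha[s2] = anew[s2] * (1.0 - p[s2]);
        alpha[4] = anew[4];
      }
      double c = 0.0;
      for (int s2 = 0; s2 < N_STATE; ++s2) c += alpha[s2];
      if (!(c > 0.0)) return R_NegInf;
      ll += std::log(c);
      for (int s2 = 0; s2 < N_STATE; ++s2) alpha[s2] /= c;
    }
    total += count[i] * ll;
  }
  return total;
}
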