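// Three-state triangular Bloch-McConnell propagation for off-resonance
// R1rho.  States: GS, ES1, ES2, each carrying (Mx, My, Mz) -> 9x9 evolution
// matrix.  R1rho at each (spin-lock power, offset) grid point is obtained by
// propagating the initial magnetization via eigendecomposition of the
// generator, projecting onto the alignment axis at each delay, and fitting a
// mono-exponential (log-linear) decay.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

static const double TWO_PI = 6.283185307179586476925286766559;

// first-order rate i->j from the pairwise exchange rate kex = kf + kb and
// the equilibrium populations: k_{i->j} = kex * p_j / (p_i + p_j)
static inline double rate_fwd(double kex, double pi_, double pj) {
  double s = pi_ + pj;
  return (s > 0.0) ? kex * pj / s : 0.0;
}

// build the 9x9 generator at one grid point (all rates in rad/s or s^-1)
static arma::mat bm_generator(double p1, double p2,
                              double k1, double k2, double k12,
                              double dw1, double dw2,
                              double r1, double r2,
                              double w1, double om_gs) {
  double p0 = 1.0 - p1 - p2;
  double om[3] = {om_gs, om_gs + dw1, om_gs + dw2};
  double pop[3] = {p0, p1, p2};

  // pairwise forward rates: k[i][j] = rate i -> j
  double kmat[3][3] = {{0, 0, 0}, {0, 0, 0}, {0, 0, 0}};
  kmat[0][1] = rate_fwd(k1, pop[0], pop[1]);
  kmat[1][0] = rate_fwd(k1, pop[1], pop[0]);
  kmat[0][2] = rate_fwd(k2, pop[0], pop[2]);
  kmat[2][0] = rate_fwd(k2, pop[2], pop[0]);
  kmat[1][2] = rate_fwd(k12, pop[1], pop[2]);
  kmat[2][1] = rate_fwd(k12, pop[2], pop[1]);

  arma::mat L(9, 9, arma::fill::zeros);
  for (int i = 0; i < 3; ++i) {
    int o = 3 * i;
    L(o + 0, o + 0) = -r2;
    L(o + 0, o + 1) = -om[i];
    L(o + 1, o + 0) = om[i];
    L(o + 1, o + 1) = -r2;
    L(o + 1, o + 2) = -w1;
    L(o + 2, o + 1) = w1;
    L(o + 2, o + 2) = -r1;
    double kout = 0.0;
    for (int j = 0; j < 3; ++j) {
      if (j == i) continue;
      kout += kmat[i][j];
      int oj = 3 * j;
      for (int c = 0; c < 3; ++c) L(o + c, oj + c) += kmat[j][i];
    }
    for (int c = 0; c < 3; ++c) L(o + c, o + c) -= kout;
  }
  return L;
}

// log-linear mono-exponential rate: -slope of log(signal) vs delay
static double loglin_rate(const arma::vec& t, const arma::vec& s) {
  std::vector<double> tv, lv;
  for (arma::uword i = 0; i < t.n_elem; ++i) {
    if (s(i) > 0.0) { tv.push_back(t(i)); lv.push_back(std::log(s(i))); }
  }
  int n = (int)tv.size();
  if (n < 2) return NA_REAL;
  double mt = 0, ml = 0;
  for (int i = 0; i < n; ++i) { mt += tv[i]; ml += lv[i]; }
  mt /= n; ml /= n;
  double sxx = 0, sxy = 0;
  for (int i = 0; i < n; ++i) {
    sxx += (tv[i] - mt) * (tv[i] - mt);
    sxy += (tv[i] - mt) * (lv[i] - ml);
  }
  if (sxx <= 0) return NA_REAL;
  return -sxy / sxx;
}

// [[Rcpp::export]]
arma::vec bm_r1rho_cpp(double p1, double p2,
                       double k1, double k2, double k12,
                       double dw1_ppm, double dw2_ppm,
                       double r1, double r2,
                       const arma::vec& power_hz, const arma::vec& offset_hz,
                       const arma::vec& delays, double larmor_mhz,
                       int align_mode, double align_thresh) {
  // align_mode: 0 = auto (kex/|dw| rule), 1 = ground state, 2 = average state
  const arma::uword npts = power_hz.n_elem;
  arma::vec out(npts);

  double dw1 = dw1_ppm * larmor_mhz * TWO_PI;   // ppm -> rad/s
  double dw2 = dw2_ppm * larmor_mhz * TWO_PI;
  double p0 = 1.0 - p1 - p2;

  // initial-alignment rule: based on kex/|dw| of the major excited state
  bool use_avg;
  if (align_mode == 1) use_avg = false;
  else if (align_mode == 2) use_avg = true;
  else {
    double kmaj, dwmaj;
    if (p1 >= p2) { kmaj = k1; dwmaj = dw1; } else { kmaj = k2; dwmaj = dw2; }
    if (p1 <= 0.0 && p2 <= 0.0) use_avg = false;
    else if (std::fabs(dwmaj) <= 0.0) use_avg = true;
    else use_avg = (kmaj / std::fabs(dwmaj)) > align_thresh;
  }

  for (arma::uword g = 0; g < npts; ++g) {
    double w1 = TWO_PI * power_hz(g);
    double om_gs = TWO_PI * offset_hz(g);
    double om_align = use_avg ? (p0 * om_gs + p1 * (om_gs + dw1) +
                                 p2 * (om_gs + dw2))
                              : om_gs;
    double weff = std::sqrt(w1 * w1 + om_align * om_align);
    double st = (weff > 0) ? w1 / weff : 0.0;
    double ct = (weff > 0) ? om_align / weff : 1.0;

    arma::mat L = bm_generator(p1, p2, k1, k2, k12, dw1, dw2, r1, r2,
                               w1, om_gs);
    arma::vec m0(9, arma::fill::zeros);
    double pop[3] = {p0, p1, p2};
    for (int i = 0; i < 3; ++i) {
      m0(3 * i + 0) = pop[i] * st;
      m0(3 * i + 2) = pop[i] * ct;
    }

    arma::cx_vec eval;
    arma::cx_mat evec;
    arma::eig_gen(eval, evec, L);
    arma::cx_vec c = arma::solve(evec, arma::cx_vec(m0, arma::vec(9, arma::fill::zeros)));

    // projection axis: alignment axis replicated across states
    arma::cx_rowvec proj(9, arma::fill::zeros);
    for (int i = 0; i < 3; ++i) {
      proj(3 * i + 0) = st;
      proj(3 * i + 2) = ct;
    }
    arma::cx_rowvec w = proj * evec;   // signal(t) = sum_k w_k c_k e^{l_k t}

    arma::vec sig(delays.n_elem);
    for (arma::uword d = 0; d < delays.n_elem; ++d) {
      std::complex<double> s(0.0, 0.0);
      for (int k = 0; k < 9; ++k) {
        s += w(k) * c(k) * std::exp(eval(k) * delays(d));
      }
      sig(d) = s.real();
    }
    out(g) = loglin_rate(delays, sig);
  }
  return out;
}
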