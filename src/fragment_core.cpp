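// Hot paths of the fragment transformation alignment: 3-point Kabsch
// superposition and the m x n triplet-pair grid with its pairwise
// transform-consistency distances.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Least-squares rigid superposition (rotation + translation, reflection
// corrected) of the 3 ordered atoms of P onto Q.  P, Q are 3x3 with atom
// rows (N, CA, C).  Returns R (3x3), t (3), residual = RMSD of R*p + t vs q.
static void kabsch3(const arma::mat &P, const arma::mat &Q,
                    arma::mat &R, arma::vec &t, double &residual) {
  arma::rowvec pc = arma::mean(P, 0);
  arma::rowvec qc = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pc;
  arma::mat Qc = Q.each_row() - qc;
  arma::mat H = Pc.t() * Qc; // 3x3 cross-covariance
  arma::mat U, V;
  arma::vec s;
  arma::svd(U, s, V, H);
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  D(2, 2) = (d < 0.0) ? -1.0 : 1.0;
  R = V * D * U.t();
  t = qc.t() - R * pc.t();
  double ss = 0.0;
  for (int a = 0; a < 3; ++a) {
    arma::vec mapped = R * P.row(a).t() + t;
    arma::vec diff = mapped - Q.row(a).t();
    ss += arma::dot(diff, diff);
  }
  residual = std::sqrt(ss / 3.0);
}

List kabsch3_cpp(const arma::mat &P, const arma::mat &Q) {
  arma::mat R;
  arma::vec t;
  double residual;
  kabsch3(P, Q, R, t, residual);
  return List::create(_["rotation"] = R, _["translation"] = t,
                      _["residual"] = residual);
}

// RMSD over the 3 ordered atoms between (R*sigma + t) and tau.
// sigma, tau are rows of a flattened m x 9 triplet matrix.
static inline double trip_dist(const double *Rm, const double *tv,
                               const double *sig, const double *tau) {
  double ss = 0.0;
  for (int a = 0; a < 3; ++a) {
    const double x = sig[3 * a], y = sig[3 * a + 1], z = sig[3 * a + 2];
    const double mx = Rm[0] * x + Rm[3] * y + Rm[6] * z + tv[0];
    const double my = Rm[1] * x + Rm[4] * y + Rm[7] * z + tv[1];
    const double mz = Rm[2] * x + Rm[5] * y + Rm[8] * z + tv[2];
    const double dx = mx - tau[3 * a], dy = my - tau[3 * a + 1],
                 dz = mz - tau[3 * a + 2];
    ss += dx * dx + dy * dy + dz * dz;
  }
  return std::sqrt(ss / 3.0);
}

double pair_distance_cpp(const arma::mat &R, const arma::vec &t,
                         const arma::mat &sigma, const arma::mat &tau) {
  double Rm[9], tv[3], sig[9], ta[9];
  for (int c = 0; c < 3; ++c)
    for (int r = 0; r < 3; ++r) Rm[3 * c + r] = R(r, c);
  for (int r = 0; r < 3; ++r) tv[r] = t(r);
  for (int a = 0; a < 3; ++a)
    for (int c = 0; c < 3; ++c) {
      sig[3 * a + c] = sigma(a, c);
      ta[3 * a + c] = tau(a, c);
    }
  return trip_dist(Rm, tv, sig, ta);
}

// Build the full grid of triplet-pair transforms and the edge list of the
// single-linkage graph.  qtrip: m x 9 (N,CA,C xyz per row), ttrip: n x 9.
// A grid node (i,j) survives if its superposition residual <= resid_max.
// An edge joins nodes a=(i,j), b=(k,l) with i!=k, j!=l whose symmetrized
// distance max(D_kl^ij, D_ij^kl) < d0, where D_kl^ij = RMSD(M_ij sigma_k,
// tau_l) over the 3 ordered atoms.
List grid_align_cpp(const arma::mat &qtrip, const arma::mat &ttrip,
                    double d0, double resid_max) {
  const int m = qtrip.n_rows, n = ttrip.n_rows;
  std::vector<int> qi, tj;
  std::vector<double> resid;
  std::vector<double> rots; // 9 per pair, column-major
  std::vector<double> trans;
  arma::mat P(3, 3), Q(3, 3), R;
  arma::vec t;
  double residual;
  for (int i = 0; i < m; ++i) {
    for (int a = 0; a < 3; ++a)
      for (int c = 0; c < 3; ++c) P(a, c) = qtrip(i, 3 * a + c);
    for (int j = 0; j < n; ++j) {
      for (int a = 0; a < 3; ++a)
        for (int c = 0; c < 3; ++c) Q(a, c) = ttrip(j, 3 * a + c);
      kabsch3(P, Q, R, t, residual);
      if (residual <= resid_max) {
        qi.push_back(i + 1);
        tj.push_back(j + 1);
        resid.push_back(residual);
        for (int c = 0; c < 3; ++c)
          for (int r = 0; r < 3; ++r) rots.push_back(R(r, c));
        for (int r = 0; r < 3; ++r) trans.push_back(t(r));
      }
    }
  }
  const int K = (int)qi.size();
  // CA-only lower-bound screen: 3*RMSD^2 >= d_CA^2, so d_CA >= sqrt(3)*d0
  // implies RMSD >= d0.
  const double ca_cut2 = 3.0 * d0 * d0;
  std::vector<int> ea, eb;
  std::vector<double> ed;
  const double *q9 = qtrip.memptr(); // column-major m x 9
  const double *t9 = ttrip.memptr();
  // copy row-major flattened triplets for cache-friendly access
  std::vector<double> qf(9 * m), tf(9 * n);
  for (int i = 0; i < m; ++i)
    for (int c = 0; c < 9; ++c) qf[9 * i + c] = q9[c * m + i];
  for (int j = 0; j < n; ++j)
    for (int c = 0; c < 9; ++c) tf[9 * j + c] = t9[c * n + j];
  for (int a = 0; a < K; ++a) {
    const double *Ra = &rots[9 * a];
    const double *ta = &trans[3 * a];
    const int ia = qi[a], ja = tj[a];
    for (int b = a + 1; b < K; ++b) {
      if (qi[b] == ia || tj[b] == ja) continue;
      const double *sigb = &qf[9 * (qi[b] - 1)];
      const double *taub = &tf[9 * (tj[b] - 1)];
      // screen on the CA atom (index 1)
      const double x = sigb[3], y = sigb[4], z = sigb[5];
      const double mx = Ra[0] * x + Ra[3] * y + Ra[6] * z + ta[0];
      const double my = Ra[1] * x + Ra[4] * y + Ra[7] * z + ta[1];
      const double mz = Ra[2] * x + Ra[5] * y + Ra[8] * z + ta[2];
      const double dx = mx - taub[3], dy = my - taub[4], dz = mz - taub[5];
      if (dx * dx + dy * dy + dz * dz >= ca_cut2) continue;
      const double d1 = trip_dist(Ra, ta, sigb, taub);
      if (d1 >= d0) continue;
      const double d2 = trip_dist(&rots[9 * b], &trans[3 * b],
                                  &qf[9 * (ia - 1)], &tf[9 * (ja - 1)]);
      const double dmax = (d1 > d2) ? d1 : d2;
      if (dmax < d0) {
        ea.push_back(a + 1);
        eb.push_back(b + 1);
        ed.push_back(dmax);
      }
    }
  }
  arma::cube rot_out(3, 3, K);
  arma::mat tr_out(3, K);
  for (int k = 0; k < K; ++k) {
    for (int c = 0; c < 3; ++c)
      for (int r = 0; r < 3; ++r) rot_out(r, c, k) = rots[9 * k + 3 * c + r];
    for (int r = 0; r < 3; ++r) tr_out(r, k) = trans[3 * k + r];
  }
  return List::create(
      _["qi"] = qi, _["tj"] = tj, _["residual"] = resid,
      _["rotations"] = rot_out, _["translations"] = tr_out,
      _["edge_a"] = ea, _["edge_b"] = eb, _["edge_d"] = ed);
}

// ---- .Call glue and registration (hand-written) ----

extern "C" SEXP _fragsite_kabsch3_cpp(SEXP PSEXP, SEXP QSEXP) {
  BEGIN_RCPP
  Rcpp::RObject out;
  Rcpp::traits::input_parameter<const arma::mat &>::type P(PSEXP);
  Rcpp::traits::input_parameter<const arma::mat &>::type Q(QSEXP);
  out = Rcpp::wrap(kabsch3_cpp(P, Q));
  return out;
  END_RCPP
}

extern "C" SEXP _fragsite_pair_distance_cpp(SEXP RSEXP, SEXP tSEXP,
                                            SEXP sSEXP, SEXP uSEXP) {
  BEGIN_RCPP
  Rcpp::RObject out;
  Rcpp::traits::input_parameter<const arma::mat &>::type R(RSEXP);
  Rcpp::traits::input_parameter<const arma::vec &>::type t(tSEXP);
  Rcpp::traits::input_parameter<const arma::mat &>::type s(sSEXP);
  Rcpp::traits::input_parameter<const arma::mat &>::type u(uSEXP);
  out = Rcpp::wrap(pair_distance_cpp(R, t, s, u));
  return out;
  END_RCPP
}

extern "C" SEXP _fragsite_grid_align_cpp(SEXP qSEXP, SEXP tSEXP, SEXP dSEXP,
                                         SEXP rSEXP) {
  BEGIN_RCPP
  Rcpp::RObject out;
  Rcpp::traits::input_parameter<const arma::mat &>::type q(qSEXP);
  Rcpp::traits::input_parameter<const arma::mat &>::type tt(tSEXP);
  Rcpp::traits::input_parameter<double>::type d0(dSEXP);
  Rcpp::traits::input_parameter<double>::type rmax(rSEXP);
  out = Rcpp::wrap(grid_align_cpp(q, tt, d0, rmax));
  return out;
  END_RCPP
}

static const R_CallMethodDef CallEntries[] = {
    {"_fragsite_kabsch3_cpp", (DL_FUNC)&_fragsite_kabsch3_cpp, 2},
    {"_fragsite_pair_distance_cpp", (DL_FUNC)&_fragsite_pair_distance_cpp, 4},
    {"_fragsite_grid_align_cpp", (DL_FUNC)&_fragsite_grid_align_cpp, 4},
    {NULL, NULL, 0}};

extern "C" void R_init_fragsite(DllInfo *dll) {
  R_registerRoutines(dll, NULL, CallEntries, NULL, NULL);
  R_useDynamicSymbols(dll, FALSE);
}
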