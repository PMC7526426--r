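// Numerical core: Kabsch superposition, Needleman-Wunsch dynamic programming
// with an opening-only gap model, and the TM-score fragment search.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

static const double NEG = -1e30;

struct RigidT {
  arma::mat33 R;
  arma::vec3 t;
};

// Rigid transform mapping Q onto P (least squares, reflections excluded).
static RigidT kabsch_transform(const arma::mat& P, const arma::mat& Q) {
  arma::rowvec pc = arma::mean(P, 0);
  arma::rowvec qc = arma::mean(Q, 0);
  arma::mat Pc = P.each_row() - pc;
  arma::mat Qc = Q.each_row() - qc;
  arma::mat H = Qc.t() * Pc;  // 3x3 covariance
  arma::mat U, V;
  arma::vec s;
  if (!arma::svd(U, s, V, H)) stop("SVD failed in superposition");
  double d = arma::det(V * U.t());
  arma::mat D = arma::eye(3, 3);
  if (d < 0) D(2, 2) = -1.0;  // flip smallest singular direction
  RigidT out;
  out.R = V * D * U.t();
  out.t = pc.t() - out.R * qc.t();
  return out;
}

static double rmsd_under(const arma::mat& P, const arma::mat& Q, const RigidT& T) {
  arma::mat Qm = Q * T.R.t();
  Qm.each_row() += T.t.t();
  arma::mat diff = P - Qm;
  return std::sqrt(arma::accu(diff % diff) / P.n_rows);
}

// [[Rcpp::export]]
List cpp_kabsch(const arma::mat& P, const arma::mat& Q) {
  if (P.n_rows != Q.n_rows) stop("point sets differ in size");
  if (P.n_rows < 3) stop("underdetermined superposition: need at least 3 points");
  RigidT T = kabsch_transform(P, Q);
  return List::create(_["rotation"] = arma::mat(T.R), _["translation"] = arma::vec(T.t),
                      _["rmsd"] = rmsd_under(P, Q, T),
                      _["n_points"] = (int)P.n_rows);
}

// Global alignment maximising sum of matched scores plus gap_open per gap
// opening (extension free). Traceback tie-break: match > gap-in-second
// (advance i) > gap-in-first (advance j). Returns 1-based matched pairs.
// [[Rcpp::export]]
IntegerMatrix cpp_nwdp(const NumericMatrix& S, double gap_open) {
  int n1 = S.nrow(), n2 = S.ncol();
  if (n1 == 0 || n2 == 0) return IntegerMatrix(0, 2);
  // state 0 = M (match), 1 = Ix (gap in second, i advances), 2 = Iy
  std::vector<std::vector<double>> M(n1 + 1, std::vector<double>(n2 + 1, NEG));
  std::vector<std::vector<double>> Ix = M, Iy = M;
  std::vector<std::vector<signed char>> pM(n1 + 1, std::vector<signed char>(n2 + 1, -1));
  std::vector<std::vector<signed char>> pIx = pM, pIy = pM;
  M[0][0] = 0.0;
  auto best3 = [](double a, double b, double c, signed char& arg) {
    // preference on ties: M (a) > Ix (b) > Iy (c)
    double m = a; arg = 0;
    if (b > m) { m = b; arg = 1; }
    if (c > m) { m = c; arg = 2; }
    return m;
  };
  for (int i = 0; i <= n1; ++i) {
    for (int j = 0; j <= n2; ++j) {
      if (i > 0 && j > 0) {
        signed char a;
        double m = best3(M[i - 1][j - 1], Ix[i - 1][j - 1], Iy[i - 1][j - 1], a);
        if (m > NEG / 2) { M[i][j] = m + S(i - 1, j - 1); pM[i][j] = a; }
      }
      if (i > 0) {
        signed char a;
        double m = best3(M[i - 1][j] + gap_open, Ix[i - 1][j], Iy[i - 1][j] + gap_open, a);
        if (m > NEG / 2) { Ix[i][j] = m; pIx[i][j] = a; }
      }
      if (j > 0) {
        signed char a;
        double m = best3(M[i][j - 1] + gap_open, Ix[i][j - 1] + gap_open, Iy[i][j - 1], a);
        if (m > NEG / 2) { Iy[i][j] = m; pIy[i][j] = a; }
      }
    }
  }
  signed char state;
  best3(M[n1][n2], Ix[n1][n2], Iy[n1][n2], state);
  std::vector<std::pair<int, int>> pairs;
  int i = n1, j = n2;
  while (i > 0 || j > 0) {
    signed char prev;
    if (state == 0) {
      pairs.push_back(std::make_pair(i, j));
      prev = pM[i][j]; --i; --j;
    } else if (state == 1) {
      prev = pIx[i][j]; --i;
    } else {
      prev = pIy[i][j]; --j;
    }
    state = prev;
  }
  IntegerMatrix out(pairs.size(), 2);
  for (size_t k = 0; k < pairs.size(); ++k) {
    out(pairs.size() - 1 - k, 0) = pairs[k].first;
    out(pairs.size() - 1 - k, 1) = pairs[k].second;
  }
  return out;
}

static double tm_sum(const arma::vec& d, double d0, double Lnorm) {
  double s = 0.0;
  for (arma::uword k = 0; k < d.n_elem; ++k) {
    double r = d[k] / d0;
    s += 1.0 / (1.0 + r * r);
  }
  return s / Lnorm;
}

static arma::vec pair_dists(const arma::mat& Pm, const arma::mat& Qm, const RigidT& T) {
  arma::mat Qt = Qm * T.R.t();
  Qt.each_row() += T.t.t();
  arma::mat diff = Pm - Qt;
  return arma::sqrt(arma::sum(diff % diff, 1));
}

// TM-score maximisation over superpositions seeded on contiguous mapped
// fragments of lengths {m, m/2, m/4} (>= 4), each refined by re-superposing
// on pairs closer than max(d0, 4.5) until stable (<= max_refine iterations).
// idx1/idx2: 1-based residue indices of the mapped pairs.
// [[Rcpp::export]]
List cpp_tm_search(const arma::mat& P, const arma::mat& Q,
                   const IntegerVector& idx1, const IntegerVector& idx2,
                   double Lnorm, double d0, int max_refine = 20) {
  int m = idx1.size();
  if (m != idx2.size()) stop("mapping index vectors differ in length");
  if (m < 3) stop("mapping too small for superposition (need >= 3 pairs)");
  arma::mat Pm(m, 3), Qm(m, 3);
  for (int k = 0; k < m; ++k) {
    Pm.row(k) = P.row(idx1[k] - 1);
    Qm.row(k) = Q.row(idx2[k] - 1);
  }
  double d_cut = std::max(d0, 4.5);
  std::vector<int> lens;
  for (int l : {m, m / 2, m / 4}) {
    int li = std::max(l, std::min(4, m));
    if (li >= 3 && std::find(lens.begin(), lens.end(), li) == lens.end())
      lens.push_back(li);
  }
  double best = -1.0;
  RigidT bestT;
  for (int len : lens) {
    int step = std::max(len / 2, 1);
    std::vector<int> starts;
    for (int s = 0; s + len <= m; s += step) starts.push_back(s);
    if (starts.empty() || starts.back() != m - len) starts.push_back(m - len);
    for (int s : starts) {
      RigidT T = kabsch_transform(Pm.rows(s, s + len - 1), Qm.rows(s, s + len - 1));
      arma::uvec prev_sel;
      for (int it = 0; it <= max_refine; ++it) {
        arma::vec d = pair_dists(Pm, Qm, T);
        double sc = tm_sum(d, d0, Lnorm);
        if (sc > best) { best = sc; bestT = T; }
        arma::uvec sel = arma::find(d < d_cut);
        if (sel.n_elem < 3) break;
        if (prev_sel.n_elem == sel.n_elem && arma::all(prev_sel == sel)) break;
        T = kabsch_transform(Pm.rows(sel), Qm.rows(sel));
        prev_sel = sel;
      }
    }
  }
  return List::create(_["score"] = best, _["rotation"] = arma::mat(bestT.R),
                      _["translation"] = arma::vec(bestT.t));
}

// Score matrix 1/(1 + (d/d0)^2) with X2 moved by (R, t) first.
// [[Rcpp::export]]
arma::mat cpp_score_matrix(const arma::mat& X1, const arma::mat& X2,
                           const arma::mat& R, const arma::vec& t, double d0) {
  arma::mat X2t = X2 * R.t();
  X2t.each_row() += t.t();
  arma::mat out(X1.n_rows, X2t.n_rows);
  for (arma::uword i = 0; i < X1.n_rows; ++i) {
    for (arma::uword j = 0; j < X2t.n_rows; ++j) {
      double dx = X1(i, 0) - X2t(j, 0);
      double dy = X1(i, 1) - X2t(j, 1);
      double dz = X1(i, 2) - X2t(j, 2);
      double r2 = (dx * dx + dy * dy + dz * dz) / (d0 * d0);
      out(i, j) = 1.0 / (1.0 + r2);
    }
  }
  return out;
}

// Best ungapped diagonal threading: offset o maximising the TM-score of the
// mapping {(j + o, j)} scored under its own whole-fragment superposition.
// [[Rcpp::export]]
List cpp_gapless_seed(const arma::mat& P, const arma::mat& Q,
                      double Lnorm, double d0, int min_overlap = 4) {
  int L1 = P.n_rows, L2 = Q.n_rows;
  double best = -1.0;
  int best_off = 0;
  for (int o = -(L2 - min_overlap); o <= L1 - min_overlap; ++o) {
    int j_lo = std::max(0, -o);
    int j_hi = std::min(L2 - 1, L1 - 1 - o);
    int m = j_hi - j_lo + 1;
    if (m < std::max(3, min_overlap)) continue;
    arma::mat Pm(m, 3), Qm(m, 3);
    for (int k = 0; k < m; ++k) {
      Pm.row(k) = P.row(j_lo + k + o);
      Qm.row(k) = Q.row(j_lo + k);
    }
    RigidT T = kabsch_transform(Pm, Qm);
    double sc = tm_sum(pair_dists(Pm, Qm, T), d0, Lnorm);
    if (sc > best) { best = sc; best_off = o; }
  }
  return List::create(_["offset"] = best_off, _["score"] = best);
}
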