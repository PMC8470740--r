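// Numerical kernels that dominate runtime: the Debye double sum over atom
// pairs, per-frame minimum inter-residue distances, and all-pairs Kabsch RMSD.
// Coordinates are in nm throughout, matching the R-side convention.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// Ensemble-averaged Debye intensity.
// coords: frames x atoms x 3 array, w: per-atom scattering weights,
// q: momentum transfer grid (nm^-1). I(q) = < sum_ij w_i w_j sinc(q r_ij) >.
// [[Rcpp::export]]
NumericVector cpp_debye(NumericVector coords, NumericVector w, NumericVector q) {
  IntegerVector dims = coords.attr("dim");
  const int nf = dims[0], na = dims[1];
  const int nq = q.size();
  const double *cd = coords.begin();
  NumericVector I(nq);
  double wsq = 0.0;
  for (int i = 0; i < na; ++i) wsq += w[i] * w[i];

  std::vector<double> acc(nq, 0.0);
  for (int f = 0; f < nf; ++f) {
    for (int i = 0; i < na - 1; ++i) {
      const double xi = cd[f + (size_t)nf * (i + (size_t)na * 0)];
      const double yi = cd[f + (size_t)nf * (i + (size_t)na * 1)];
      const double zi = cd[f + (size_t)nf * (i + (size_t)na * 2)];
      for (int j = i + 1; j < na; ++j) {
        const double dx = xi - cd[f + (size_t)nf * (j + (size_t)na * 0)];
        const double dy = yi - cd[f + (size_t)nf * (j + (size_t)na * 1)];
        const double dz = zi - cd[f + (size_t)nf * (j + (size_t)na * 2)];
        const double r = std::sqrt(dx * dx + dy * dy + dz * dz);
        const double ww = 2.0 * w[i] * w[j];
        for (int k = 0; k < nq; ++k) {
          const double x = q[k] * r;
          acc[k] += (x < 1e-12) ? ww : ww * std::sin(x) / x;
        }
      }
    }
  }
  for (int k = 0; k < nq; ++k) I[k] = wsq + acc[k] / nf;
  return I;
}

// Minimum inter-residue atom-atom distance matrix for one frame.
// xyz: atoms x 3 matrix, resid: 1-based residue index per atom.
// [[Rcpp::export]]
NumericMatrix cpp_res_min_dist(NumericMatrix xyz, IntegerVector resid) {
  const int na = xyz.nrow();
  int nr = 0;
  for (int i = 0; i < na; ++i) nr = std::max(nr, resid[i]);
  NumericMatrix md(nr, nr);
  std::fill(md.begin(), md.end(), R_PosInf);
  for (int i = 0; i < nr; ++i) md(i, i) = 0.0;
  for (int i = 0; i < na - 1; ++i) {
    const int ri = resid[i] - 1;
    for (int j = i + 1; j < na; ++j) {
      const int rj = resid[j] - 1;
      if (ri == rj) continue;
      const double dx = xyz(i, 0) - xyz(j, 0);
      const double dy = xyz(i, 1) - xyz(j, 1);
      const double dz = xyz(i, 2) - xyz(j, 2);
      const double d = std::sqrt(dx * dx + dy * dy + dz * dz);
      if (d < md(ri, rj)) { md(ri, rj) = d; md(rj, ri) = d; }
    }
  }
  return md;
}

// All-pairs minimum-RMSD matrix after optimal superposition (Kabsch via SVD).
// coords: frames x atoms x 3 array restricted to the selection of interest.
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_rmsd(NumericVector coords) {
  IntegerVector dims = coords.attr("dim");
  const int nf = dims[0], na = dims[1];
  const double *cd = coords.begin();

  // centered per-frame coordinate blocks (na x 3) and squared norms
  std::vector<arma::mat> P(nf);
  std::vector<double> ssq(nf);
  for (int f = 0; f < nf; ++f) {
    arma::mat M(na, 3);
    for (int k = 0; k < 3; ++k)
      for (int i = 0; i < na; ++i)
        M(i, k) = cd[f + (size_t)nf * (i + (size_t)na * k)];
    M.each_row() -= arma::mean(M, 0);
    P[f] = M;
    ssq[f] = arma::accu(M % M);
  }

  NumericMatrix R(nf, nf);
  arma::mat U, V;
  arma::vec s;
  for (int a = 0; a < nf - 1; ++a) {
    for (int b = a + 1; b < nf; ++b) {
      arma::mat H = P[a].t() * P[b];
      arma::svd(U, s, V, H);
      double d = arma::det(V * U.t());
      double tr = s(0) + s(1) + ((d < 0) ? -s(2) : s(2));
      double msd = (ssq[a] + ssq[b] - 2.0 * tr) / na;
      double r = (msd > 0) ? std::sqrt(msd) : 0.0;
      R(a, b) = r;
      R(b, a) = r;
    }
  }
  return R;
}
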