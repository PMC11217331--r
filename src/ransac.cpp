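// RANSAC plane fitting for per-plot ground segmentation.
//
// Each iteration draws n_samples points (without replacement, via R's RNG so
// results are reproducible under set.seed), fits their total-least-squares
// plane (smallest eigenvector of the 3x3 scatter matrix), and counts points
// within the distance threshold. The best candidate (maximal inlier count,
// first such on ties) is refit by least squares on its inliers.
//
// For speed the candidate fits are collected first and the inlier counting
// runs as chunked matrix products (plots hold ~80k points and the default
// is 10,000 iterations; a naive per-iteration loop is ~5x slower).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

// TLS plane through a point subset: returns false if the subset is
// degenerate (collinear / coincident: two near-zero eigenvalues).
static bool tls_plane(const arma::mat& pts, const arma::uvec& idx,
                      arma::vec3& normal, double& offset) {
  arma::mat sub = pts.rows(idx);
  arma::rowvec ctr = arma::mean(sub, 0);
  sub.each_row() -= ctr;
  arma::mat33 cov = sub.t() * sub;
  arma::vec eigval;
  arma::mat eigvec;
  if (!arma::eig_sym(eigval, eigvec, cov)) return false;
  // eigenvalues ascending; a plane exists iff the middle one is non-negligible
  double scale = eigval(2) > 0 ? eigval(2) : 1.0;
  if (eigval(1) <= 1e-12 * scale) return false;
  normal = eigvec.col(0);
  double nrm = arma::norm(normal);
  if (nrm == 0) return false;
  normal /= nrm;
  offset = -arma::dot(normal, ctr.t());
  return true;
}

// Partial Fisher-Yates draw of k indices from 0..n-1 using R's RNG.
static void draw_sample(arma::uvec& pool, arma::uvec& out, int k) {
  int n = pool.n_elem;
  for (int i = 0; i < k; ++i) {
    int j = i + (int)(unif_rand() * (n - i));
    if (j >= n) j = n - 1;
    std::swap(pool[i], pool[j]);
    out[i] = pool[i];
  }
}

// [[Rcpp::export(name = ".ransac_plane_cpp")]]
List ransac_plane_cpp(const arma::mat& pts, int n_samples, int iterations,
                      double distance) {
  const arma::uword n = pts.n_rows;
  if (n < 3) stop("RANSAC needs at least 3 points");
  int k = std::min<arma::uword>(n_samples, n);
  if (k < 3) k = 3;

  arma::uvec pool = arma::regspace<arma::uvec>(0, n - 1);
  arma::uvec samp(k);

  // phase 1: candidate models (normals as columns, offsets as a row)
  arma::mat normals(3, iterations);
  arma::rowvec offsets(iterations);
  arma::uword n_cand = 0;
  GetRNGstate();
  for (int it = 0; it < iterations; ++it) {
    draw_sample(pool, samp, k);
    arma::vec3 nrm;
    double d;
    if (!tls_plane(pts, samp, nrm, d)) continue;
    normals.col(n_cand) = nrm;
    offsets(n_cand) = d;
    ++n_cand;
  }
  PutRNGstate();
  if (n_cand == 0)
    return List::create(Named("ok") = false);

  // phase 2: chunked inlier counting; first maximal count wins ties
  const arma::uword chunk = std::max<arma::uword>(1, 8000000 / n);
  arma::uword best = 0, best_count = 0;
  for (arma::uword c0 = 0; c0 < n_cand; c0 += chunk) {
    arma::uword c1 = std::min(c0 + chunk, n_cand) - 1;
    arma::mat res = pts * normals.cols(c0, c1);
    res.each_row() += offsets.subvec(c0, c1);
    for (arma::uword c = 0; c <= c1 - c0; ++c) {
      const double* r = res.colptr(c);
      arma::uword count = 0;
      for (arma::uword i = 0; i < n; ++i)
        if (std::abs(r[i]) <= distance) ++count;
      if (count > best_count) { best_count = count; best = c0 + c; }
    }
  }

  arma::vec3 nrm = normals.col(best);
  double d = offsets(best);

  // phase 3: refit by TLS on the winning candidate's inliers, iterated to a
  // fixed point (the refit changes the inlier set, so repeat until stable)
  arma::uvec inl = arma::find(arma::abs(pts * nrm + d) <= distance);
  for (int r = 0; r < 10 && inl.n_elem >= 3; ++r) {
    arma::vec3 nrm2;
    double d2;
    if (!tls_plane(pts, inl, nrm2, d2)) break;
    arma::uvec inl2 = arma::find(arma::abs(pts * nrm2 + d2) <= distance);
    bool stable = (inl2.n_elem == inl.n_elem) && arma::all(inl2 == inl);
    nrm = nrm2;
    d = d2;
    inl = inl2;
    if (stable) break;
  }
  // canonical orientation: upward (positive z component) normal
  if (nrm(2) < 0 || (nrm(2) == 0 && (nrm(0) < 0 || (nrm(0) == 0 && nrm(1) < 0)))) {
    nrm = -nrm;
    d = -d;
  }
  LogicalVector inlier(n, false);
  for (arma::uword i = 0; i < inl.n_elem; ++i) inlier[inl(i)] = true;
  return List::create(Named("ok") = true,
                      Named("normal") = NumericVector::create(nrm(0), nrm(1), nrm(2)),
                      Named("offset") = d,
                      Named("inliers") = inlier);
}
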