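// Variable-projection (separable NNLS) fitting of the IVIM biexponential.
//
// For fixed decay rates (Dstar, D) the model S(b) = th1 e^{-b Dstar} +
// th2 e^{-b D} is linear in the non-negative amplitudes th = (S0 f,
// S0 (1-f)); the inner problem has a closed form (2x2 normal equations with
// boundary clamping).  The outer 2D problem over (log D, log Dstar) is
// solved per voxel by a coarse log-grid search (Gram matrices precomputed
// once, shared by all voxels) followed by Nelder-Mead refinement from the
// best starts, with Dstar >= sep * D enforced to prevent label switching.
// Deterministic: no RNG anywhere.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace arma;

namespace {

struct Inner {
  double th1, th2, rss;
};

// closed-form non-negative LS for amplitudes given Gram entries and
// cross-products with the data
inline Inner inner_from_gram(double a11, double a12, double a22,
                             double b1, double b2, double yy) {
  double det = a11 * a22 - a12 * a12;
  double th1 = 0, th2 = 0;
  if (det > 1e-300) {
    th1 = (a22 * b1 - a12 * b2) / det;
    th2 = (a11 * b2 - a12 * b1) / det;
  }
  if (th1 < 0 || th2 < 0 || det <= 1e-300) {
    double t2 = std::max(b2 / a22, 0.0);
    double r2 = yy - 2 * t2 * b2 + t2 * t2 * a22;
    double t1 = std::max(b1 / a11, 0.0);
    double r1 = yy - 2 * t1 * b1 + t1 * t1 * a11;
    if (r2 <= r1) { th1 = 0; th2 = t2; } else { th1 = t1; th2 = 0; }
  }
  Inner res;
  res.th1 = th1; res.th2 = th2;
  res.rss = yy - 2 * (th1 * b1 + th2 * b2) + th1 * th1 * a11 +
            2 * th1 * th2 * a12 + th2 * th2 * a22;
  if (res.rss < 0) res.rss = 0;
  return res;
}

struct Objective {
  const double* b;
  const double* y;
  int nb;
  double yy;
  double ld_lo, ld_hi, ls_lo, ls_hi, lsep;

  Inner solve(double dstar, double d) const {
    double a11 = 0, a12 = 0, a22 = 0, b1 = 0, b2 = 0;
    for (int i = 0; i < nb; ++i) {
      double e1 = std::exp(-b[i] * dstar), e2 = std::exp(-b[i] * d);
      a11 += e1 * e1; a12 += e1 * e2; a22 += e2 * e2;
      b1 += e1 * y[i]; b2 += e2 * y[i];
    }
    return inner_from_gram(a11, a12, a22, b1, b2, yy);
  }
  void clamp(double& x1, double& x2) const {
    x1 = std::min(std::max(x1, ld_lo), ld_hi);
    x2 = std::min(std::max(x2, ls_lo), ls_hi);
    if (x2 < x1 + lsep) x2 = std::min(x1 + lsep, ls_hi);
  }
  // x1 = log D, x2 = log Dstar, projected into the admissible region
  double eval(double x1, double x2) const {
    clampv(x1, x2);
    return solve(std::exp(x2), std::exp(x1)).rss;
  }
  void clampv(double& x1, double& x2) const { clamp(x1, x2); }
};

// 2D Nelder-Mead with projection onto the box/separation constraints
void nelder_mead_once(const Objective& obj, double& x1, double& x2,
                      double& fv, int maxit, double tol, double step) {
  double px[3] = {x1, x1 + step, x1};
  double py[3] = {x2, x2, x2 + step};
  double pf[3];
  for (int i = 0; i < 3; ++i) pf[i] = obj.eval(px[i], py[i]);
  for (int it = 0; it < maxit; ++it) {
    int lo = 0, hi = 0;
    for (int i = 1; i < 3; ++i) {
      if (pf[i] < pf[lo]) lo = i;
      if (pf[i] > pf[hi]) hi = i;
    }
    if (hi == lo) break;
    if (pf[hi] - pf[lo] <= tol * (std::abs(pf[lo]) + 1e-300)) break;
    int mid = 3 - lo - hi;
    double cx = (px[lo] + px[mid]) / 2, cy = (py[lo] + py[mid]) / 2;
    double rx = cx + (cx - px[hi]), ry = cy + (cy - py[hi]);
    double fr = obj.eval(rx, ry);
    if (fr < pf[lo]) {
      double ex = cx + 2 * (cx - px[hi]), ey = cy + 2 * (cy - py[hi]);
      double fe = obj.eval(ex, ey);
      if (fe < fr) { px[hi] = ex; py[hi] = ey; pf[hi] = fe; }
      else { px[hi] = rx; py[hi] = ry; pf[hi] = fr; }
    } else if (fr < pf[mid]) {
      px[hi] = rx; py[hi] = ry; pf[hi] = fr;
    } else {
      double kx = cx + 0.5 * (px[hi] - cx), ky = cy + 0.5 * (py[hi] - cy);
      double fk = obj.eval(kx, ky);
      if (fk < pf[hi]) { px[hi] = kx; py[hi] = ky; pf[hi] = fk; }
      else {
        for (int i = 0; i < 3; ++i) {
          if (i == lo) continue;
          px[i] = px[lo] + 0.5 * (px[i] - px[lo]);
          py[i] = py[lo] + 0.5 * (py[i] - py[lo]);
          pf[i] = obj.eval(px[i], py[i]);
        }
      }
    }
  }
  int lo = 0;
  for (int i = 1; i < 3; ++i) if (pf[i] < pf[lo]) lo = i;
  x1 = px[lo]; x2 = py[lo]; fv = pf[lo];
}

// restarted Nelder-Mead: fresh simplexes of shrinking size around the
// running optimum guard against premature simplex collapse
void nelder_mead(const Objective& obj, double& x1, double& x2, double& fv,
                 int maxit, double tol) {
  const double steps[3] = {0.15, 0.02, 0.002};
  fv = obj.eval(x1, x2);
  for (int r = 0; r < 3; ++r) {
    double nx = x1, ny = x2, nf;
    nelder_mead_once(obj, nx, ny, nf, maxit, tol, steps[r]);
    if (nf < fv) { fv = nf; x1 = nx; x2 = ny; }
  }
}

}  // namespace

// Fit IVIM to each column of Y (nb x nvox).  Returns 7 x nvox matrix:
// rows f, D, Dstar, S0, resid (residual norm), valid flag, degenerate flag.
// [[Rcpp::export(name = ".cpp_fit_ivim")]]
arma::mat cpp_fit_ivim(const arma::mat& Y, const arma::vec& b,
                       double dmin, double dmax, double smin, double smax,
                       double sep, int ngrid, int nstarts, int maxit) {
  const uword nv = Y.n_cols;
  const int nb = b.n_elem;
  mat out(7, nv, fill::zeros);
  const double ld_lo = std::log(dmin), ld_hi = std::log(dmax);
  const double ls_lo = std::log(smin), ls_hi = std::log(smax);
  const double lsep = std::log(sep);
  vec ldg = linspace(ld_lo, ld_hi, ngrid);
  vec lsg = linspace(ls_lo, ls_hi, ngrid);
  // exponential tables and admissible-pair Gram entries, voxel-independent
  mat E2(nb, ngrid), E1(nb, ngrid);
  for (int i = 0; i < ngrid; ++i) {
    E2.col(i) = exp(-b * std::exp(ldg(i)));   // tissue term at D = exp(ldg)
    E1.col(i) = exp(-b * std::exp(lsg(i)));   // fast term at D* = exp(lsg)
  }
  std::vector<int> pi, pj;
  std::vector<double> pa11, pa12, pa22;
  for (int i = 0; i < ngrid; ++i) {           // i: D index
    for (int j = 0; j < ngrid; ++j) {         // j: Dstar index
      if (lsg(j) < ldg(i) + lsep) continue;
      pi.push_back(i); pj.push_back(j);
      pa22.push_back(dot(E2.col(i), E2.col(i)));
      pa11.push_back(dot(E1.col(j), E1.col(j)));
      pa12.push_back(dot(E1.col(j), E2.col(i)));
    }
  }
  const size_t npair = pi.size();
  vec bd(ngrid), bs(ngrid);
  for (uword v = 0; v < nv; ++v) {
    vec y = Y.col(v);
    double yy = dot(y, y);
    if (yy <= 0 || !y.is_finite() || y(0) <= 0) continue;  // invalid voxel
    // per-voxel cross products with each grid exponential
    for (int i = 0; i < ngrid; ++i) {
      bd(i) = dot(E2.col(i), y);
      bs(i) = dot(E1.col(i), y);
    }
    // coarse grid: keep the nstarts best admissible nodes
    std::vector<std::pair<double, size_t>> best(npair);
    for (size_t p = 0; p < npair; ++p) {
      Inner in = inner_from_gram(pa11[p], pa12[p], pa22[p], bs(pj[p]),
                                 bd(pi[p]), yy);
      best[p] = {in.rss, p};
    }
    int ns = std::min<size_t>(nstarts, npair);
    std::partial_sort(best.begin(), best.begin() + ns, best.end());
    Objective obj{b.memptr(), y.memptr(), nb, yy, ld_lo, ld_hi,
                  ls_lo, ls_hi, lsep};
    double bx = ldg(pi[best[0].second]), by = lsg(pj[best[0].second]),
           bf = best[0].first;
    for (int s = 0; s < ns; ++s) {
      double x1 = ldg(pi[best[s].second]), x2 = lsg(pj[best[s].second]), fv;
      nelder_mead(obj, x1, x2, fv, maxit, 1e-14);
      if (fv < bf) { bf = fv; bx = x1; by = x2; }
    }
    obj.clamp(bx, by);
    double d = std::exp(bx), dstar = std::exp(by);
    Inner in = obj.solve(dstar, d);
    double s0 = in.th1 + in.th2;
    if (!(s0 > 0)) continue;
    double f = in.th1 / s0;
    // monoexponential decays can be represented with all weight on the
    // fast compartment; relabel so the tissue term carries them
    if (f >= 1 - 1e-3 && dstar <= dmax) {
      d = dstar;
      dstar = std::min(std::max(sep * d, smin), smax);
      in = obj.solve(dstar, d);
      if (in.th1 + in.th2 > 0) {
        s0 = in.th1 + in.th2;
        f = in.th1 / s0;
      }
    }
    out(0, v) = f;
    out(1, v) = d;
    out(2, v) = dstar;
    out(3, v) = s0;
    out(4, v) = std::sqrt(in.rss);
    out(5, v) = 1;                                     // valid
    out(6, v) = (f <= 1e-3 || f >= 1 - 1e-3) ? 1 : 0;  // D*/D degenerate
  }
  return out;
}
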