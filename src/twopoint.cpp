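#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Two-point rf/LOD/phase for every marker pair of a CP full-sib family.
// Genotypes coded 0 = AA, 1 = AB, 2 = BB, -1 = missing (ref/alt axis).
// Mirrors the generative likelihood in R/twopoint.R; kept in C++ because a
// default run evaluates ~260k pairs x 4 phases x ~90 likelihood points.

static inline void gt_alleles(int gt, int a[2]) {
  a[0] = (gt == 2) ? 1 : 0;
  a[1] = (gt == 0) ? 0 : 1;
}

// log-likelihood of the 3x3 count table under r and per-parent phase
static double loglik(const double cnt[3][3],
                     const int mi[2], const int mj[2],
                     const int pi_[2], const int pj[2],
                     int phase_m, int phase_p, double r) {
  double P[3][3] = {{0}};
  const double rec = r / 2.0, par = (1.0 - r) / 2.0;
  for (int u = 0; u < 2; ++u) for (int v = 0; v < 2; ++v) {
    double pm = ((u ^ phase_m) == v) ? par : rec;
    for (int s = 0; s < 2; ++s) for (int t = 0; t < 2; ++t) {
      double pp = ((s ^ phase_p) == t) ? par : rec;
      P[mi[u] + pi_[s]][mj[v] + pj[t]] += pm * pp;
    }
  }
  double ll = 0.0;
  for (int a = 0; a < 3; ++a) for (int b = 0; b < 3; ++b) {
    if (cnt[a][b] > 0) {
      double p = P[a][b];
      ll += cnt[a][b] * std::log(p > 1e-300 ? p : 1e-300);
    }
  }
  return ll;
}

// golden-section maximisation of loglik in r over [lo, hi]
static double golden(const double cnt[3][3], const int mi[2], const int mj[2],
                     const int pi_[2], const int pj[2], int pm, int pp,
                     double lo, double hi, double tol, double *ll_out) {
  const double gr = 0.5 * (std::sqrt(5.0) - 1.0);
  double a = lo, b = hi;
  double c = b - gr * (b - a), d = a + gr * (b - a);
  double fc = loglik(cnt, mi, mj, pi_, pj, pm, pp, c);
  double fd = loglik(cnt, mi, mj, pi_, pj, pm, pp, d);
  while (b - a > tol) {
    if (fc > fd) { b = d; d = c; fd = fc; c = b - gr * (b - a);
                   fc = loglik(cnt, mi, mj, pi_, pj, pm, pp, c); }
    else         { a = c; c = d; fc = fd; d = a + gr * (b - a);
                   fd = loglik(cnt, mi, mj, pi_, pj, pm, pp, d); }
  }
  double r = 0.5 * (a + b);
  *ll_out = loglik(cnt, mi, mj, pi_, pj, pm, pp, r);
  return r;
}

// [[Rcpp::export]]
List cpp_two_point_all(IntegerMatrix geno, IntegerVector mat_gt,
                       IntegerVector pat_gt) {
  const int m = geno.nrow(), n = geno.ncol();
  NumericMatrix rf(m, m), lod(m, m), info(m, m);
  IntegerMatrix nim(m, m), ph_m_out(m, m), ph_p_out(m, m);
  std::fill(rf.begin(), rf.end(), 0.5);
  std::fill(ph_m_out.begin(), ph_m_out.end(), -1);
  std::fill(ph_p_out.begin(), ph_p_out.end(), -1);

  for (int i = 0; i < m; ++i) {
    rf(i, i) = 0.0;
    int ai[2], aj[2], bi[2], bj[2];
    gt_alleles(mat_gt[i], ai);
    gt_alleles(pat_gt[i], bi);
    for (int j = i + 1; j < m; ++j) {
      bool het_m = mat_gt[i] == 1 && mat_gt[j] == 1;
      bool het_p = pat_gt[i] == 1 && pat_gt[j] == 1;
      if (!het_m && !het_p) continue;  // no informative parent: rf 0.5, lod 0

      double cnt[3][3] = {{0}};
      int n_complete = 0;
      for (int k = 0; k < n; ++k) {
        int gi = geno(i, k), gj = geno(j, k);
        if (gi >= 0 && gj >= 0) { cnt[gi][gj] += 1.0; ++n_complete; }
      }
      nim(i, j) = nim(j, i) = n_complete * ((int)het_m + (int)het_p);
      if (n_complete == 0) continue;

      gt_alleles(mat_gt[j], aj);
      gt_alleles(pat_gt[j], bj);
      double best_ll = -INFINITY, best_r = 0.5;
      int best_pm = -1, best_pp = -1;
      for (int pm = 0; pm <= (het_m ? 1 : 0); ++pm) {
        for (int pp = 0; pp <= (het_p ? 1 : 0); ++pp) {
          // coarse grid then golden-section polish (log-lik unimodal in r)
          double gbest = -INFINITY; double rbest = 0.0;
          for (double r = 0.0; r <= 0.5001; r += 0.01) {
            double rr = r > 0.5 ? 0.5 : r;
            double ll = loglik(cnt, ai, aj, bi, bj, pm, pp, rr);
            if (ll > gbest) { gbest = ll; rbest = rr; }
          }
          double lo = rbest - 0.01 < 0.0 ? 0.0 : rbest - 0.01;
          double hi = rbest + 0.01 > 0.5 ? 0.5 : rbest + 0.01;
          double ll_ref;
          double r_ref = golden(cnt, ai, aj, bi, bj, pm, pp, lo, hi, 1e-6,
                                &ll_ref);
          if (ll_ref < gbest) { ll_ref = gbest; r_ref = rbest; }
          if (ll_ref > best_ll + 1e-12) {
            best_ll = ll_ref; best_r = r_ref; best_pm = pm; best_pp = pp;
          }
        }
      }
      double ll_half = loglik(cnt, ai, aj, bi, bj,
                              best_pm < 0 ? 0 : best_pm,
                              best_pp < 0 ? 0 : best_pp, 0.5);
      double l = (best_ll - ll_half) / std::log(10.0);
      rf(i, j) = rf(j, i) = best_r;
      lod(i, j) = lod(j, i) = l > 0 ? l : 0.0;
      ph_m_out(i, j) = ph_m_out(j, i) = het_m ? best_pm : -1;
      ph_p_out(i, j) = ph_p_out(j, i) = het_p ? best_pp : -1;

      // observed information about r at the MLE (negative curvature of the
      // log-likelihood; one-sided near the boundaries)
      const double h = 1e-3;
      int pm0 = best_pm < 0 ? 0 : best_pm, pp0 = best_pp < 0 ? 0 : best_pp;
      double r0 = best_r, curv;
      if (r0 < h) r0 = h;
      if (r0 > 0.5 - h) r0 = 0.5 - h;
      curv = -(loglik(cnt, ai, aj, bi, bj, pm0, pp0, r0 + h) -
               2.0 * loglik(cnt, ai, aj, bi, bj, pm0, pp0, r0) +
               loglik(cnt, ai, aj, bi, bj, pm0, pp0, r0 - h)) / (h * h);
      info(i, j) = info(j, i) = curv > 0 ? curv : 0.0;
    }
  }
  return List::create(_["rf"] = rf, _["lod"] = lod,
                      _["n_informative"] = nim, _["info"] = info,
                      _["phase_mat"] = ph_m_out, _["phase_pat"] = ph_p_out);
}
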