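#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Three-state F2 hidden chain: 1 = AA, 2 = AB, 3 = BB (0-based 0,1,2 here).
// Prior 1/4 : 1/2 : 1/4. Transitions from recombination fraction r via two
// independent meioses. Emissions: correct call 1 - eps, each wrong call
// eps/2, missing/pseudomarker uninformative.

static inline void transition(double r, double T[3][3]) {
  double s = 1.0 - r;
  T[0][0] = s * s;      T[0][1] = 2.0 * r * s;      T[0][2] = r * r;
  T[1][0] = r * s;      T[1][1] = s * s + r * r;    T[1][2] = r * s;
  T[2][0] = r * r;      T[2][1] = 2.0 * r * s;      T[2][2] = s * s;
}

// obs: n x P integer matrix, 0 = no observation, 1/2/3 = AA/AB/BB.
// rf: length P-1 recombination fractions between adjacent grid positions.
// Returns numeric vector of length n*P*3 (dim n, P, 3): posterior
// P(state | all observations on the chromosome) by scaled forward-backward.
// [[Rcpp::export]]
NumericVector fb_genoprob_cpp(IntegerMatrix obs, NumericVector rf,
                              double error_prob) {
  const int n = obs.nrow(), P = obs.ncol();
  if (P > 1 && rf.size() != P - 1) stop("rf length must be P - 1");
  NumericVector out(static_cast<R_xlen_t>(n) * P * 3);
  const double prior[3] = {0.25, 0.5, 0.25};
  std::vector<double> alpha(P * 3), beta(P * 3), emis(P * 3);

  for (int i = 0; i < n; ++i) {
    // emissions for plant i
    for (int p = 0; p < P; ++p) {
      int o = obs(i, p);
      for (int s = 0; s < 3; ++s) {
        if (o == 0) emis[p * 3 + s] = 1.0;
        else emis[p * 3 + s] = (o - 1 == s) ? (1.0 - error_prob) : (error_prob / 2.0);
      }
    }
    // forward with scaling
    double T[3][3];
    std::vector<double> scale(P);
    double tot = 0.0;
    for (int s = 0; s < 3; ++s) { alpha[s] = prior[s] * emis[s]; tot += alpha[s]; }
    scale[0] = tot;
    for (int s = 0; s < 3; ++s) alpha[s] /= tot;
    for (int p = 1; p < P; ++p) {
      transition(rf[p - 1], T);
      tot = 0.0;
      for (int s = 0; s < 3; ++s) {
        double a = 0.0;
        for (int t = 0; t < 3; ++t) a += alpha[(p - 1) * 3 + t] * T[t][s];
        a *= emis[p * 3 + s];
        alpha[p * 3 + s] = a;
        tot += a;
      }
      scale[p] = tot;
      for (int s = 0; s < 3; ++s) alpha[p * 3 + s] /= tot;
    }
    // backward
    for (int s = 0; s < 3; ++s) beta[(P - 1) * 3 + s] = 1.0;
    for (int p = P - 2; p >= 0; --p) {
      transition(rf[p], T);
      for (int s = 0; s < 3; ++s) {
        double b = 0.0;
        for (int t = 0; t < 3; ++t)
          b += T[s][t] * emis[(p + 1) * 3 + t] * beta[(p + 1) * 3 + t];
        beta[p * 3 + s] = b / scale[p + 1];
      }
    }
    // posterior
    for (int p = 0; p < P; ++p) {
      double norm = 0.0, post[3];
      for (int s = 0; s < 3; ++s) {
        post[s] = alpha[p * 3 + s] * beta[p * 3 + s];
        norm += post[s];
      }
      for (int s = 0; s < 3; ++s)
        out[i + static_cast<R_xlen_t>(n) * (p + static_cast<R_xlen_t>(P) * s)] =
          post[s] / norm;
    }
  }
  out.attr("dim") = IntegerVector::create(n, P, 3);
  return out;
}

// Binary-trait single-locus EM scan over one block of positions.
// probs: n x P x 3 posterior genotype probabilities (as from fb_genoprob_cpp).
// y: 0/1 phenotype vector (1 = R). At each position maximizes
//   sum_i log sum_g w_ig pi_g^y_i (1 - pi_g)^(1 - y_i)
// over the penetrances pi by EM. Returns lod (P), pi (P x 3), niter (P),
// and the null log-likelihood.
// [[Rcpp::export]]
List scan_binary_em_cpp(NumericVector probs, IntegerVector y, double tol,
                        int max_iter) {
  IntegerVector dim = probs.attr("dim");
  const int n = dim[0], P = dim[1];
  if (y.size() != n) stop("phenotype length mismatch");
  int ny1 = 0;
  for (int i = 0; i < n; ++i) {
    if (y[i] != 0 && y[i] != 1) stop("phenotype must be binary 0/1");
    ny1 += y[i];
  }
  const double pnull = static_cast<double>(ny1) / n;
  double ll0 = 0.0;
  if (ny1 > 0) ll0 += ny1 * std::log(pnull);
  if (ny1 < n) ll0 += (n - ny1) * std::log(1.0 - pnull);

  NumericVector lod(P);
  NumericMatrix pi_out(P, 3);
  IntegerVector niter(P);
  const double LN10 = std::log(10.0);

  // degenerate phenotype: both models saturate, LOD identically 0
  if (ny1 == 0 || ny1 == n) {
    for (int p = 0; p < P; ++p)
      for (int s = 0; s < 3; ++s) pi_out(p, s) = pnull;
    return List::create(_["lod"] = lod, _["pi"] = pi_out,
                        _["niter"] = niter, _["null_ll"] = ll0);
  }

  std::vector<double> w(n * 3);
  for (int p = 0; p < P; ++p) {
    for (int s = 0; s < 3; ++s)
      for (int i = 0; i < n; ++i)
        w[s * n + i] = probs[i + static_cast<R_xlen_t>(n) * (p + static_cast<R_xlen_t>(P) * s)];

    // init: w-weighted phenotype mean per genotype, kept off the boundary
    double pi[3];
    for (int s = 0; s < 3; ++s) {
      double num = 0.0, den = 0.0;
      for (int i = 0; i < n; ++i) { num += w[s * n + i] * y[i]; den += w[s * n + i]; }
      double v = den > 0 ? num / den : pnull;
      pi[s] = std::min(std::max(v, 1e-3), 1.0 - 1e-3);
    }

    double ll_prev = -INFINITY, ll = 0.0;
    int it = 0;
    for (it = 0; it < max_iter; ++it) {
      double num[3] = {0, 0, 0}, den[3] = {0, 0, 0};
      ll = 0.0;
      for (int i = 0; i < n; ++i) {
        double z[3], tot = 0.0;
        for (int s = 0; s < 3; ++s) {
          double b = y[i] ? pi[s] : 1.0 - pi[s];
          z[s] = w[s * n + i] * b;
          tot += z[s];
        }
        ll += std::log(tot);
        for (int s = 0; s < 3; ++s) {
          double zi = z[s] / tot;
          num[s] += zi * y[i];
          den[s] += zi;
        }
      }
      for (int s = 0; s < 3; ++s) {
        double v = den[s] > 0 ? num[s] / den[s] : pnull;
        pi[s] = std::min(std::max(v, 1e-12), 1.0 - 1e-12);
      }
      if (ll - ll_prev < tol && it > 0) break;
      ll_prev = ll;
    }
    // one final log-likelihood at the last pi
    double llf = 0.0;
    for (int i = 0; i < n; ++i) {
      double tot = 0.0;
      for (int s = 0; s < 3; ++s)
        tot += w[s * n + i] * (y[i] ? pi[s] : 1.0 - pi[s]);
      llf += std::log(tot);
    }
    lod[p] = (llf - ll0) / LN10;
    if (lod[p] < -1e-6) stop("negative LOD: EM fell below the null model");
    if (lod[p] < 0) lod[p] = 0.0;
    for (int s = 0; s < 3; ++s) pi_out(p, s) = pi[s];
    niter[p] = it + 1;
  }
  return List::create(_["lod"] = lod, _["pi"] = pi_out,
                      _["niter"] = niter, _["null_ll"] = ll0);
}

// Genome-wide maximum LOD for a batch of permuted phenotypes.
// probs_list: one n x P x 3 probability array per chromosome.
// yperm: n x n_perm matrix of permuted 0/1 phenotypes (columns = replicates).
// Returns the maximum LOD over all positions for each replicate.
// [[Rcpp::export]]
NumericVector perm_max_lod_cpp(List probs_list, IntegerMatrix yperm,
                               double tol, int max_iter) {
  const int n_perm = yperm.ncol();
  NumericVector maxima(n_perm);
  for (int r = 0; r < n_perm; ++r) {
    IntegerVector y = yperm(_, r);
    double mx = 0.0;
    for (int b = 0; b < probs_list.size(); ++b) {
      NumericVector probs = probs_list[b];
      List fit = scan_binary_em_cpp(probs, y, tol, max_iter);
      NumericVector lod = fit["lod"];
      for (int p = 0; p < lod.size(); ++p) if (lod[p] > mx) mx = lod[p];
    }
    maxima[r] = mx;
  }
  return maxima;
}
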