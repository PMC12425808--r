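#include <Rcpp.h>
using namespace Rcpp;

// Generic forward-filter / stochastic-traceback engine for the threading
// HMMs.  The chain of bins is partitioned into segments; within a segment
// the state space (size K_s) is fixed and every between-bin transition is
// the same rank-one stochastic kernel
//     T(i -> j) = a_i * delta_ij + r_i * w_j ,   a_i + r_i = 1, sum_j w_j = 1,
// which is the Li-Stephens structure (stay on the current state, or
// recombine and re-join according to w).  The transition into the first
// bin of a segment is one of:
//   btype 0: chain start (use `init`),
//   btype 1: deterministic remap of the previous states (map[i] in 1..K,
//            0 = state dies),
//   btype 2: forced jump: T(i -> j) = w_j of the new segment.
// Optional per-bin log-emission vectors multiply the filter.
//
// mode 0 samples a path from the exact posterior by stochastic traceback
// (using R's RNG) and returns its log posterior density; mode 1 returns
// the log posterior density of `given_path`; mode 2 does both on the
// shared forward filter (path/logq = sampled, logq_given = scored).

static double traceback(const std::vector<std::vector<double> >& F,
                        const IntegerVector& seg_of_bin,
                        const std::vector<NumericVector>& A,
                        const std::vector<NumericVector>& Rv,
                        const std::vector<NumericVector>& W,
                        const IntegerVector& btype,
                        const std::vector<IntegerVector>& M,
                        bool sample, const IntegerVector& given,
                        IntegerVector& path) {
  const int B = F.size();
  double logq = 0.0;
  {
    int s = seg_of_bin[B - 1] - 1;
    int K = A[s].size();
    int j;
    if (sample) {
      double u = unif_rand(), c = 0.0;
      j = K - 1;
      for (int k = 0; k < K; ++k) { c += F[B - 1][k]; if (u <= c) { j = k; break; } }
    } else {
      j = given[B - 1] - 1;
    }
    if (j < 0 || j >= K || F[B - 1][j] <= 0.0) return R_NegInf;
    path[B - 1] = j + 1;
    logq += std::log(F[B - 1][j]);
  }
  std::vector<double> p;
  for (int l = B - 1; l >= 1; --l) {
    int s = seg_of_bin[l] - 1;
    int j = path[l] - 1;
    const std::vector<double>& fp = F[l - 1];
    int Kp = fp.size();
    p.assign(Kp, 0.0);
    if (seg_of_bin[l] == seg_of_bin[l - 1]) {
      for (int i = 0; i < Kp; ++i) p[i] = fp[i] * Rv[s][i] * W[s][j];
      p[j] += fp[j] * A[s][j];
    } else if (btype[s] == 1) {
      for (int i = 0; i < Kp; ++i) if (M[s][i] == j + 1) p[i] = fp[i];
    } else {
      for (int i = 0; i < Kp; ++i) p[i] = fp[i] * W[s][j];
    }
    double z = 0.0;
    for (int i = 0; i < Kp; ++i) z += p[i];
    if (!(z > 0.0)) return R_NegInf;
    int i;
    if (sample) {
      double u = unif_rand() * z, c = 0.0;
      i = Kp - 1;
      for (int k = 0; k < Kp; ++k) { c += p[k]; if (u <= c) { i = k; break; } }
    } else {
      i = given[l - 1] - 1;
    }
    if (i < 0 || i >= Kp || p[i] <= 0.0) return R_NegInf;
    path[l - 1] = i + 1;
    logq += std::log(p[i] / z);
  }
  return logq;
}

// [[Rcpp::export]]
List hmm_pass(IntegerVector seg_of_bin, List seg_a, List seg_r, List seg_w,
              IntegerVector btype, List bmap, NumericVector init,
              IntegerVector emit_of_bin, List emits, int mode,
              IntegerVector given_path) {
  const int B = seg_of_bin.size();
  const int S = seg_a.size();
  std::vector<std::vector<double> > F(B);
  std::vector<NumericVector> A(S), Rv(S), W(S);
  std::vector<IntegerVector> M(S);
  for (int s = 0; s < S; ++s) {
    A[s] = as<NumericVector>(seg_a[s]);
    Rv[s] = as<NumericVector>(seg_r[s]);
    W[s] = as<NumericVector>(seg_w[s]);
    if (btype[s] == 1) M[s] = as<IntegerVector>(bmap[s]);
  }
  double loglik = 0.0;
  bool dead = false;

  for (int l = 0; l < B; ++l) {
    int s = seg_of_bin[l] - 1;
    int K = A[s].size();
    std::vector<double> f(K, 0.0);
    if (l == 0) {
      for (int j = 0; j < K; ++j) f[j] = init[j];
    } else if (seg_of_bin[l] == seg_of_bin[l - 1]) {
      const std::vector<double>& fp = F[l - 1];
      double m = 0.0;
      for (int i = 0; i < K; ++i) m += Rv[s][i] * fp[i];
      for (int j = 0; j < K; ++j) f[j] = A[s][j] * fp[j] + m * W[s][j];
    } else {
      const std::vector<double>& fp = F[l - 1];
      int Kp = fp.size();
      if (btype[s] == 1) {
        for (int i = 0; i < Kp; ++i) {
          int j = M[s][i];
          if (j > 0) f[j - 1] += fp[i];
        }
      } else if (btype[s] == 2) {
        double tot = 0.0;
        for (int i = 0; i < Kp; ++i) tot += fp[i];
        for (int j = 0; j < K; ++j) f[j] = W[s][j] * tot;
      } else {
        stop("invalid boundary type");
      }
    }
    if (emit_of_bin[l] > 0) {
      NumericVector e = as<NumericVector>(emits[emit_of_bin[l] - 1]);
      for (int j = 0; j < K; ++j) f[j] *= std::exp(e[j]);
    }
    double z = 0.0;
    for (int j = 0; j < K; ++j) z += f[j];
    if (!(z > 0.0)) { dead = true; break; }
    for (int j = 0; j < K; ++j) f[j] /= z;
    loglik += std::log(z);
    F[l] = f;
  }

  IntegerVector path(B);
  if (dead) {
    return List::create(_["path"] = path, _["logq"] = R_NegInf,
                        _["logq_given"] = R_NegInf,
                        _["loglik"] = R_NegInf);
  }
  double logq = NA_REAL, logq_given = NA_REAL;
  if (mode == 0 || mode == 2) {
    logq = traceback(F, seg_of_bin, A, Rv, W, btype, M, true, given_path,
                     path);
  }
  if (mode == 1) {
    logq = traceback(F, seg_of_bin, A, Rv, W, btype, M, false, given_path,
                     path);
    if (!R_FINITE(logq)) path = given_path;
  }
  if (mode == 2) {
    IntegerVector path2(B);
    logq_given = traceback(F, seg_of_bin, A, Rv, W, btype, M, false,
                           given_path, path2);
  }
  return List::create(_["path"] = path, _["logq"] = logq,
                      _["logq_given"] = logq_given, _["loglik"] = loglik);
}
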