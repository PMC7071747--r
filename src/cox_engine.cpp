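#include <Rcpp.h>
using namespace Rcpp;

// Risk-set machinery for weighted, influence-trimmed Cox partial likelihood.
//
// All routines assume rows sorted by time in INCREASING order; the R wrappers
// sort once per fit and map per-subject outputs back.  Covariates are centered
// by the wrappers before exponentiation; the trimming map A(t, z_j) =
// max(0, M - min(M, t * eref_j)) is evaluated with eref_j = exp(beta_ref' z_j)
// computed on the ORIGINAL covariate scale (M is selected on that scale too),
// so the engine takes eref as data.  Ties share risk sets (Breslow).

static inline double amap(double t, double eref, double M) {
  double u = t * eref;            // overflow -> Inf -> fully trimmed
  if (!(u < M)) return 0.0;
  return M - u;
}

// start of the tie block containing i (closed risk-set condition t_j >= t_i)
static inline int tie_start(const NumericVector& time, int i) {
  int s = i;
  while (s > 0 && time[s - 1] == time[i]) --s;
  return s;
}

// [[Rcpp::export(name = ".cox_score_info_cpp")]]
List cox_score_info_cpp(NumericVector time, IntegerVector status, NumericMatrix Z,
                        NumericVector beta, NumericVector w, NumericVector ew,
                        bool trimmed, double M, NumericVector eref) {
  const int n = time.size(), p = Z.ncol();
  NumericVector score(p);
  NumericMatrix info(p, p);
  std::vector<double> exb(n), s1(p);
  NumericMatrix s2(p, p);
  for (int j = 0; j < n; ++j) {
    double lp = 0.0;
    for (int q = 0; q < p; ++q) lp += beta[q] * Z(j, q);
    exb[j] = std::exp(lp);
  }
  bool ok = true;
  double bad_time = NA_REAL;
  for (int i = 0; i < n; ++i) {
    if (status[i] != 1 || ew[i] == 0.0) continue;
    const double ti = time[i];
    double s0 = 0.0;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int j = tie_start(time, i); j < n; ++j) {
      double wj = w[j] * exb[j];
      if (trimmed) wj *= amap(ti, eref[j], M);
      if (wj <= 0.0) continue;
      s0 += wj;
      for (int q = 0; q < p; ++q) {
        const double zq = Z(j, q);
        s1[q] += wj * zq;
        for (int r = 0; r <= q; ++r) s2(q, r) += wj * zq * Z(j, r);
      }
    }
    if (s0 <= 0.0) { ok = false; bad_time = ti; break; }
    for (int q = 0; q < p; ++q) {
      const double zbq = s1[q] / s0;
      score[q] += ew[i] * (Z(i, q) - zbq);
      for (int r = 0; r <= q; ++r) {
        const double v = ew[i] * (s2(q, r) / s0 - zbq * (s1[r] / s0));
        info(q, r) += v;
        if (r != q) info(r, q) += v;
      }
    }
  }
  return List::create(_["score"] = score, _["information"] = info,
                      _["ok"] = ok, _["bad_time"] = bad_time);
}

// Per-subject residuals for the sandwich variance, plus the observed
// information, at a fixed beta.  type 0 = score (martingale form): subject i's
// weighted contribution to every risk set it belongs to, accumulated over
// event times t_k <= t_i.  type 1 = direct (closed form with the correction
// indexed by k: t_k >= t_i and weight product w_i A(t_i,z_k) w_k A(t_k,z_k)).
// [[Rcpp::export(name = ".cox_residuals_cpp")]]
List cox_residuals_cpp(NumericVector time, IntegerVector status, NumericMatrix Z,
                       NumericVector beta, NumericVector w, NumericVector ew,
                       bool trimmed, double M, NumericVector eref, int type) {
  const int n = time.size(), p = Z.ncol();
  std::vector<double> exb(n);
  for (int j = 0; j < n; ++j) {
    double lp = 0.0;
    for (int q = 0; q < p; ++q) lp += beta[q] * Z(j, q);
    exb[j] = std::exp(lp);
  }
  // pass 1: per-event S0 and zbar, and the information matrix
  std::vector<int> ev;
  for (int i = 0; i < n; ++i)
    if (status[i] == 1 && ew[i] != 0.0) ev.push_back(i);
  const int ne = (int)ev.size();
  std::vector<double> S0(ne);
  NumericMatrix zbar(ne, p), info(p, p);
  std::vector<double> s1(p);
  NumericMatrix s2(p, p);
  bool ok = true;
  double bad_time = NA_REAL;
  for (int e = 0; e < ne && ok; ++e) {
    const int i = ev[e];
    const double ti = time[i];
    double s0 = 0.0;
    std::fill(s1.begin(), s1.end(), 0.0);
    std::fill(s2.begin(), s2.end(), 0.0);
    for (int j = tie_start(time, i); j < n; ++j) {
      double wj = w[j] * exb[j];
      if (trimmed) wj *= amap(ti, eref[j], M);
      if (wj <= 0.0) continue;
      s0 += wj;
      for (int q = 0; q < p; ++q) {
        const double zq = Z(j, q);
        s1[q] += wj * zq;
        for (int r = 0; r <= q; ++r) s2(q, r) += wj * zq * Z(j, r);
      }
    }
    if (s0 <= 0.0) { ok = false; bad_time = ti; break; }
    S0[e] = s0;
    for (int q = 0; q < p; ++q) {
      zbar(e, q) = s1[q] / s0;
      for (int r = 0; r <= q; ++r) {
        const double v = ew[i] * (s2(q, r) / s0 - (s1[q] / s0) * (s1[r] / s0));
        info(q, r) += v;
        if (r != q) info(r, q) += v;
      }
    }
  }
  NumericMatrix resid(n, p);
  if (ok) {
    for (int i = 0; i < n; ++i) {
      const double ti = time[i];
      if (status[i] == 1 && ew[i] != 0.0)
        for (int e = 0; e < ne; ++e)
          if (ev[e] == i)
            for (int q = 0; q < p; ++q)
              resid(i, q) += ew[i] * (Z(i, q) - zbar(e, q));
      for (int e = 0; e < ne; ++e) {
        const int k = ev[e];
        const double tk = time[k];
        if (type == 0) {                      // score residual: events with t_k <= t_i
          if (tk > ti) continue;
          double a_ik = trimmed ? amap(tk, eref[i], M) : 1.0;  // A(t_k, z_i)
          if (a_ik <= 0.0) continue;
          const double c = ew[k] * w[i] * a_ik * exb[i] / S0[e];
          for (int q = 0; q < p; ++q)
            resid(i, q) -= c * (Z(i, q) - zbar(e, q));
        } else {                              // direct form: events with t_k >= t_i
          if (tk < ti) continue;
          double a_ik = trimmed ? amap(ti, eref[k], M) : 1.0;  // A(t_i, z_k)
          if (a_ik <= 0.0) continue;
          const double c = w[i] * a_ik * ew[k] * exb[k] / S0[e];
          for (int q = 0; q < p; ++q)
            resid(i, q) -= c * (zbar(e, q) - Z(k, q));
        }
      }
    }
  }
  return List::create(_["residuals"] = resid, _["information"] = info,
                      _["ok"] = ok, _["bad_time"] = bad_time);
}
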