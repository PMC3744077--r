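#include <Rcpp.h>
#include <cmath>

using namespace Rcpp;

// Sliding-window fit of the three-stage intercalation template to a
// normalised six-feature series (columns: w_i, w_j, w_k, a_ij, a_jk, a_ki;
// angles already divided by 180 deg, areas by the dataset median contact
// area).  Five features follow a free linear transition; a_ij follows a
// linear decay reaching zero at the relative time t2 and staying zero.
// Per feature the free endpoints are fitted by least squares; the error is
//   d = sum_f w_mse[f] * MSE_f + sum_f w_par[f] * dev_f
// with dev_f the mean absolute deviation of the two fitted endpoints from
// the ideal endpoints.  For each admissible start frame the best (minimum
// d) window length is returned.

static void scoreTriple(const double* F, int T, int nfeat_stride,
                        const int* valid, int min_dur, int max_dur,
                        double t2, const double* is, const double* ie,
                        const double* wm, const double* wp,
                        std::vector<double>& bestd,
                        std::vector<int>& bestL) {
  std::vector<bool> ok(T);
  for (int t = 0; t < T; ++t) {
    bool o = true;
    for (int f = 0; f < 6; ++f)
      if (!R_finite(F[t + f * nfeat_stride])) { o = false; break; }
    ok[t] = o;
  }
  for (int t0 = 0; t0 + min_dur <= T; ++t0) {
    bestd[t0] = NA_REAL; bestL[t0] = -1;
    if (!valid[t0]) continue;
    for (int L = min_dur; L <= max_dur && t0 + L <= T; ++L) {
      bool allok = true;
      for (int t = t0; t < t0 + L; ++t) if (!ok[t]) { allok = false; break; }
      if (!allok) break;
      const double t1 = t0 + L - 1;
      double d = 0.0;
      for (int f = 0; f < 6; ++f) {
        const double* col = F + f * nfeat_stride;
        double Su = 0, Suu = 0, Sy = 0, Suy = 0, Syy = 0, Sbb = 0, Syb = 0;
        for (int t = t0; t < t0 + L; ++t) {
          const double u = (t - t0) / (t1 - t0);
          const double y = col[t];
          Su += u; Suu += u * u; Sy += y; Suy += u * y; Syy += y * y;
          if (f == 3) {
            const double b = (u < t2) ? (1.0 - u / t2) : 0.0;
            Sbb += b * b; Syb += y * b;
          }
        }
        double mse, p0, p1;
        if (f == 3) {
          const double q = (Sbb > 0) ? (Syb / Sbb) : 0.0;
          mse = std::max(0.0, (Syy - q * Syb) / L);
          p0 = q; p1 = 0.0;
        } else {
          const double den = L * Suu - Su * Su;
          const double b = (den > 0) ? (L * Suy - Su * Sy) / den : 0.0;
          const double a = (Sy - b * Su) / L;
          mse = std::max(0.0, (Syy - a * Sy - b * Suy) / L);
          p0 = a; p1 = a + b;
        }
        const double dev = 0.5 * (std::fabs(p0 - is[f]) +
                                  std::fabs(p1 - ie[f]));
        d += wm[f] * mse + wp[f] * dev;
      }
      if (bestL[t0] < 0 || d < bestd[t0]) { bestd[t0] = d; bestL[t0] = L; }
    }
  }
  for (int t0 = std::max(T - min_dur + 1, 0); t0 < T; ++t0) {
    bestd[t0] = NA_REAL; bestL[t0] = -1;
  }
}

// Batch candidate extraction: features of nTrip triples stacked along rows
// (triple q occupies rows q*T .. q*T+T-1); returns the local minima of the
// per-start best error d over consecutive admissible starts as candidate
// events (columns: triple index, start, end, d).
// [[Rcpp::export(name = ".detect_candidates_cpp")]]
NumericMatrix detect_candidates_cpp(NumericMatrix F, LogicalVector valid,
                                    int nTrip, int T, int min_dur,
                                    int max_dur, double t2,
                                    NumericVector ideal_start,
                                    NumericVector ideal_end,
                                    NumericVector w_mse,
                                    NumericVector w_par) {
  if (F.nrow() != nTrip * T) stop("feature matrix has wrong row count");
  std::vector<double> outTrip, outStart, outEnd, outD;
  std::vector<double> bestd(T);
  std::vector<int> bestL(T);
  const int stride = F.nrow();
  for (int q = 0; q < nTrip; ++q) {
    const double* Fq = REAL(F) + (size_t)q * T;
    const int* vq = LOGICAL(valid) + (size_t)q * T;
    scoreTriple(Fq, T, stride, vq, min_dur, max_dur, t2,
                ideal_start.begin(), ideal_end.begin(), w_mse.begin(),
                w_par.begin(), bestd, bestL);
    // local minima of d over the subsequence of scored starts
    std::vector<int> starts;
    for (int t = 0; t < T; ++t)
      if (bestL[t] > 0 && R_finite(bestd[t])) starts.push_back(t);
    const int n = starts.size();
    for (int s = 0; s < n; ++s) {
      const double d = bestd[starts[s]];
      const double dPrev = (s > 0) ? bestd[starts[s - 1]] : R_PosInf;
      const double dNext = (s + 1 < n) ? bestd[starts[s + 1]] : R_PosInf;
      if (d < dPrev && d <= dNext) {
        outTrip.push_back(q + 1);
        outStart.push_back(starts[s]);
        outEnd.push_back(starts[s] + bestL[starts[s]] - 1);
        outD.push_back(d);
      }
    }
  }
  NumericMatrix out(outTrip.size(), 4);
  for (size_t r = 0; r < outTrip.size(); ++r) {
    out(r, 0) = outTrip[r]; out(r, 1) = outStart[r];
    out(r, 2) = outEnd[r]; out(r, 3) = outD[r];
  }
  return out;
}

// [[Rcpp::export(name = ".score_windows_cpp")]]
NumericMatrix score_windows_cpp(NumericMatrix F, LogicalVector valid_start,
                                int min_dur, int max_dur, double t2,
                                NumericVector ideal_start,
                                NumericVector ideal_end,
                                NumericVector w_mse, NumericVector w_par) {
  const int T = F.nrow();
  if (F.ncol() != 6) stop("feature matrix must have 6 columns");
  if (min_dur < 3) stop("minimum window length is 3 frames");
  if (t2 <= 0 || t2 > 1) stop("t2 must lie in (0, 1]");

  // frames where every feature is finite
  std::vector<bool> ok(T);
  for (int t = 0; t < T; ++t) {
    bool o = true;
    for (int f = 0; f < 6; ++f)
      if (!R_finite(F(t, f))) { o = false; break; }
    ok[t] = o;
  }

  NumericMatrix out(T, 2);  // columns: best d, best duration (frames)
  std::fill(out.begin(), out.end(), NA_REAL);

  for (int t0 = 0; t0 + min_dur <= T; ++t0) {
    if (!valid_start[t0]) continue;
    double bestd = NA_REAL; int bestL = -1;
    for (int L = min_dur; L <= max_dur && t0 + L <= T; ++L) {
      bool allok = true;
      for (int t = t0; t < t0 + L; ++t) if (!ok[t]) { allok = false; break; }
      if (!allok) break;  // longer windows contain the same bad frame
      const double t1 = t0 + L - 1;
      double d = 0.0;
      for (int f = 0; f < 6; ++f) {
        double Su = 0, Suu = 0, Sy = 0, Suy = 0, Syy = 0, Sb = 0, Sbb = 0,
               Syb = 0;
        for (int t = t0; t < t0 + L; ++t) {
          const double u = (t - t0) / (t1 - t0);
          const double y = F(t, f);
          Su += u; Suu += u * u; Sy += y; Suy += u * y; Syy += y * y;
          if (f == 3) {
            const double b = (u < t2) ? (1.0 - u / t2) : 0.0;
            Sb += b; Sbb += b * b; Syb += y * b;
          }
        }
        double mse, p0, p1;
        if (f == 3) {
          const double q = (Sbb > 0) ? (Syb / Sbb) : 0.0;
          mse = std::max(0.0, (Syy - q * Syb) / L);
          p0 = q; p1 = 0.0;
        } else {
          const double den = L * Suu - Su * Su;
          const double b = (den > 0) ? (L * Suy - Su * Sy) / den : 0.0;
          const double a = (Sy - b * Su) / L;
          mse = std::max(0.0, (Syy - a * Sy - b * Suy) / L);
          p0 = a; p1 = a + b;
        }
        const double dev = 0.5 * (std::fabs(p0 - ideal_start[f]) +
                                  std::fabs(p1 - ideal_end[f]));
        d += w_mse[f] * mse + w_par[f] * dev;
      }
      if (!R_finite(bestd) || d < bestd) { bestd = d; bestL = L; }
    }
    if (bestL > 0) { out(t0, 0) = bestd; out(t0, 1) = bestL; }
  }
  return out;
}
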