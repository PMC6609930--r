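#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Compiled transfer functions (must mirror the R closures in transfer.R):
// 0 = identity; 1 = piecewise 0 / x^2 / 2*sqrt(x - 3/4).
static inline double phi_eval(int code, double x) {
  if (code == 0) return x;
  if (x < 0.0) return 0.0;
  if (x <= 1.0) return x * x;
  return 2.0 * std::sqrt(x - 0.75);
}

// Projections of a length-n vector onto the competition vectors,
// divided by the squared norms: out_k = (e_k . v) / (k + k^2), k = 1..n-1.
static inline void project_comp(const std::vector<double>& v, int n,
                                std::vector<double>& out) {
  double cum = 0.0;
  for (int k = 1; k < n; ++k) {
    cum += v[k - 1];
    out[k - 1] = (cum - k * v[k]) / (double)(k + k * k);
  }
}

// Reconstruction r_i = -(i-1) X_{i-2(0-based)} + sum_{l>=i} X_l + mC.
static inline void reconstruct(const std::vector<double>& X, int n, double mC,
                               std::vector<double>& r) {
  double suff = 0.0;
  for (int i = n; i >= 1; --i) {           // 1-based population index
    if (i <= n - 1) suff += X[i - 1];
    double lead = (i >= 2) ? -(double)(i - 1) * X[i - 2] : 0.0;
    r[i - 1] = lead + suff + mC;
  }
}

// First population whose value crosses `bound`; ties broken by largest
// overshoot, then lowest index. Returns 0 if none crossed (1-based otherwise).
static inline int crossing_choice(const std::vector<double>& r, int n,
                                  double bound) {
  int best = 0;
  double over = -1.0;
  for (int i = 0; i < n; ++i) {
    double o = r[i] - bound;
    if (o >= 0.0 && o > over) { over = o; best = i + 1; }
  }
  return best;
}

// ---------------------------------------------------------------------------
// Full rate network (linear when both transfer codes are 0): Euler-Maruyama.
// Noise draws per step: excitatory populations in index order, then the
// inhibitory population. Optional pre-drawn standard-normal noise
// (noiseE: n x nsteps, noiseI: nsteps) for shared-noise comparisons.
// [[Rcpp::export]]
List sim_network_cpp(int n, double tau, double tauI, double s, double c,
                     double g, NumericVector I, double II, double sigma,
                     double sigmaI, int phiCode, int phiICode,
                     NumericVector r0, double rI0, double dt, int nsteps,
                     Nullable<NumericMatrix> noiseE = R_NilValue,
                     Nullable<NumericVector> noiseI = R_NilValue) {
  NumericMatrix rates(nsteps + 1, n);
  NumericVector rI(nsteps + 1);
  bool shared = noiseE.isNotNull();
  NumericMatrix NE;
  NumericVector NI;
  if (shared) {
    NE = NumericMatrix(noiseE);
    NI = NumericVector(noiseI);
    if (NE.nrow() != n || NE.ncol() < nsteps || NI.size() < nsteps)
      stop("shared noise has wrong dimensions");
  }
  std::vector<double> r(r0.begin(), r0.end()), rn(n);
  double ri = rI0;
  for (int i = 0; i < n; ++i) rates(0, i) = r[i];
  rI[0] = rI0;
  const double se = sigma * std::sqrt(dt) / tau;
  const double si = sigmaI * std::sqrt(dt) / tauI;
  for (int t = 0; t < nsteps; ++t) {
    double sum = 0.0;
    for (int i = 0; i < n; ++i) sum += r[i];
    double driveI = phi_eval(phiICode, g / n * sum + II);
    for (int i = 0; i < n; ++i) {
      double eps = shared ? NE(i, t) : norm_rand();
      rn[i] = r[i] + dt / tau * (-r[i] + phi_eval(phiCode, s * r[i] - c * ri + I[i]))
              + se * eps;
    }
    double epsI = shared ? NI[t] : norm_rand();
    ri += dt / tauI * (-ri + driveI) + si * epsI;
    r = rn;
    for (int i = 0; i < n; ++i) rates(t + 1, i) = r[i];
    rI[t + 1] = ri;
  }
  return List::create(_["rates"] = rates, _["r_inh"] = rI);
}

// ---------------------------------------------------------------------------
// Linear multi-alternative DDM: n independent population noise streams are
// drawn each step and projected onto the competition vectors, so that
//   dX_k = dt (e_k.I) / (tau (k + k^2)) + sigma sqrt(dt) (e_k.eta) / (tau (k + k^2)).
// A decision fires at the first step where any reconstructed coordinate
// -(i-1) X_{i-1} + sum_{l>=i} X_l + mC reaches theta.
// Returns ntrials x 2 matrix (choice, rt); choice 0 = undecided (rt = t_max).
// If path is requested (single trial), also the X trajectory.
// [[Rcpp::export]]
List ddm_trials_cpp(int n, double tau, NumericVector I, double sigma,
                    double theta, double mC, double dt, int nsteps,
                    NumericVector x0, int ntrials, bool returnPath = false,
                    Nullable<NumericMatrix> noise = R_NilValue) {
  NumericMatrix out(ntrials, 2);
  bool shared = noise.isNotNull();
  NumericMatrix NE;
  if (shared) {
    NE = NumericMatrix(noise);
    if (NE.nrow() != n || NE.ncol() < nsteps) stop("shared noise has wrong dimensions");
    if (ntrials != 1) stop("shared noise supports a single trial");
  }
  std::vector<double> Iv(I.begin(), I.end()), driftX(n - 1), eta(n),
      proj(n - 1), X(n - 1), rvec(n);
  project_comp(Iv, n, driftX);
  for (int k = 0; k < n - 1; ++k) driftX[k] *= dt / tau;
  const double sfac = sigma * std::sqrt(dt) / tau;
  NumericMatrix path;
  if (returnPath) path = NumericMatrix(nsteps + 1, n - 1);
  for (int tr = 0; tr < ntrials; ++tr) {
    for (int k = 0; k < n - 1; ++k) X[k] = x0[k];
    if (returnPath) for (int k = 0; k < n - 1; ++k) path(0, k) = X[k];
    int choice = 0;
    double rt = nsteps * dt;
    for (int t = 0; t < nsteps; ++t) {
      for (int i = 0; i < n; ++i) eta[i] = shared ? NE(i, t) : norm_rand();
      project_comp(eta, n, proj);
      for (int k = 0; k < n - 1; ++k) X[k] += driftX[k] + sfac * proj[k];
      if (returnPath) for (int k = 0; k < n - 1; ++k) path(t + 1, k) = X[k];
      reconstruct(X, n, mC, rvec);
      int ch = crossing_choice(rvec, n, theta);
      if (ch > 0) {
        choice = ch;
        rt = (t + 1) * dt;
        if (returnPath) {
          // truncate path at decision
          NumericMatrix p2(t + 2, n - 1);
          for (int u = 0; u <= t + 1; ++u)
            for (int k = 0; k < n - 1; ++k) p2(u, k) = path(u, k);
          path = p2;
        }
        break;
      }
    }
    out(tr, 0) = choice;
    out(tr, 1) = rt;
  }
  if (returnPath) return List::create(_["trials"] = out, _["path"] = path);
  return List::create(_["trials"] = out);
}

// ---------------------------------------------------------------------------
// MSPRT family. Evidence increments dy_i = I_i dt + sigma sqrt(dt) eta_i.
// The common mode M_C of the log-posteriors starts at 0 and is integrated in
// one of two ways (`update`):
//   1 (euler): Euler-Maruyama step of its ODE, dM_C = mean(dy) - sum(w * dy)
//      with softmax weights w at the pre-step state. This is the same
//      integration scheme as every other simulator here; the discrete
//      integral of the log-normalizer then lacks its Ito drift, so M_C stays
//      near 0 at zero coherence and the moving bound theta - M_C stays near
//      theta.
//   0 (exact): closed form M_C = mean(y) - logsumexp(y) + log(n); the rule
//      is then the posterior criterion exp(L_i) >= exp(theta)/n.
// Models (`mode`):
//   0 (Bayesian): log-posterior route; decision when the competition part of
//     the integrated log-posterior reaches theta - M_C(t).
//   1 (moving-threshold DDM): decision variables X_k accumulated from the
//     projected increments; same moving bound. Algebraically identical to
//     mode 0 under either update scheme.
//   2 (fixed-threshold DDM): same X_k; constant bound theta.
// Returns ntrials x 3 (choice, rt, posterior at decision; NA if undecided);
// the reported posterior is always the exactly normalized one.
// [[Rcpp::export]]
List msprt_trials_cpp(int n, NumericVector I, double sigma, double theta,
                      double dt, int nsteps, int mode, int ntrials,
                      int update = 1, bool returnPath = false,
                      Nullable<NumericMatrix> noise = R_NilValue) {
  NumericMatrix out(ntrials, 3);
  bool shared = noise.isNotNull();
  NumericMatrix NE;
  if (shared) {
    NE = NumericMatrix(noise);
    if (NE.nrow() != n || NE.ncol() < nsteps) stop("shared noise has wrong dimensions");
    if (ntrials != 1) stop("shared noise supports a single trial");
  }
  const double sfac = sigma * std::sqrt(dt);
  const double logn = std::log((double)n);
  std::vector<double> y(n), dy(n), w(n), L(n), Leul(n), X(n - 1), proj(n - 1),
      rvec(n);
  NumericMatrix ypath, Lpath;
  NumericVector mcpath;
  if (returnPath) {
    ypath = NumericMatrix(nsteps + 1, n);
    Lpath = NumericMatrix(nsteps + 1, n);
    mcpath = NumericVector(nsteps + 1);
  }
  for (int tr = 0; tr < ntrials; ++tr) {
    std::fill(y.begin(), y.end(), 0.0);
    std::fill(X.begin(), X.end(), 0.0);
    std::fill(Leul.begin(), Leul.end(), 0.0);
    double mc_eul = 0.0;
    int choice = 0, laststep = nsteps;
    double rt = nsteps * dt, posterior = NA_REAL;
    if (returnPath) {
      for (int i = 0; i < n; ++i) { ypath(0, i) = 0.0; Lpath(0, i) = -logn; }
      mcpath[0] = 0.0;
    }
    for (int t = 0; t < nsteps; ++t) {
      if (update == 1 && mode != 2) {
        // softmax weights at the pre-step state (Euler-Maruyama)
        double m = y[0];
        for (int i = 1; i < n; ++i) if (y[i] > m) m = y[i];
        double se = 0.0;
        for (int i = 0; i < n; ++i) { w[i] = std::exp(y[i] - m); se += w[i]; }
        for (int i = 0; i < n; ++i) w[i] /= se;
      }
      double mean_dy = 0.0, wdy = 0.0;
      for (int i = 0; i < n; ++i) {
        double eps = shared ? NE(i, t) : norm_rand();
        dy[i] = I[i] * dt + sfac * eps;
        y[i] += dy[i];
        mean_dy += dy[i];
        if (update == 1 && mode != 2) wdy += w[i] * dy[i];
      }
      mean_dy /= n;
      if (update == 1 && mode != 2) mc_eul += mean_dy - wdy;
      int ch = 0;
      double lse = 0.0, ymean = 0.0;
      bool have_lse = false;
      if (update == 0 || returnPath) {
        // quantities needed for the exact rule or the recorded path
        double m = y[0];
        for (int i = 1; i < n; ++i) if (y[i] > m) m = y[i];
        double se = 0.0;
        for (int i = 0; i < n; ++i) { se += std::exp(y[i] - m); ymean += y[i]; }
        lse = m + std::log(se);
        ymean /= n;
        have_lse = true;
      }
      double MC = (update == 1) ? mc_eul : (ymean - lse + logn);
      if (mode == 0) {
        if (update == 1) {
          // integrated log-posterior: dL_i = dy_i - sum(w * dy)
          for (int i = 0; i < n; ++i) Leul[i] += dy[i] - wdy;
          ch = crossing_choice(Leul, n, theta);
        } else {
          for (int i = 0; i < n; ++i) L[i] = y[i] - lse;
          project_comp(L, n, proj);
          reconstruct(proj, n, 0.0, rvec);
          ch = crossing_choice(rvec, n, theta - MC);
        }
      } else if (mode == 1) {
        project_comp(dy, n, proj);
        for (int k = 0; k < n - 1; ++k) X[k] += proj[k];
        reconstruct(X, n, 0.0, rvec);
        ch = crossing_choice(rvec, n, theta - MC);
      } else {
        // fixed threshold: the reconstruction of the accumulated projected
        // increments is y - mean(y), so the rule is y_i - mean(y) >= theta
        // (largest-overshoot tie-break == argmax of y)
        double ysum = 0.0, ymax = y[0];
        int imax = 0;
        for (int i = 0; i < n; ++i) {
          ysum += y[i];
          if (y[i] > ymax) { ymax = y[i]; imax = i; }
        }
        if (ymax - ysum / n >= theta) ch = imax + 1;
      }
      if (returnPath) {
        for (int i = 0; i < n; ++i) {
          ypath(t + 1, i) = y[i];
          Lpath(t + 1, i) = y[i] - lse;
        }
        mcpath[t + 1] = MC;
      }
      if (ch > 0) {
        choice = ch;
        rt = (t + 1) * dt;
        if (!have_lse) {
          double m = y[0];
          for (int i = 1; i < n; ++i) if (y[i] > m) m = y[i];
          double se = 0.0;
          for (int i = 0; i < n; ++i) se += std::exp(y[i] - m);
          lse = m + std::log(se);
        }
        posterior = std::exp(y[ch - 1] - lse);
        laststep = t + 1;
        break;
      }
    }
    out(tr, 0) = choice;
    out(tr, 1) = rt;
    out(tr, 2) = posterior;
    if (returnPath && laststep < nsteps) {
      NumericMatrix y2(laststep + 1, n), L2(laststep + 1, n);
      NumericVector mc2(laststep + 1);
      for (int u = 0; u <= laststep; ++u) {
        for (int i = 0; i < n; ++i) { y2(u, i) = ypath(u, i); L2(u, i) = Lpath(u, i); }
        mc2[u] = mcpath[u];
      }
      ypath = y2; Lpath = L2; mcpath = mc2;
    }
  }
  if (returnPath)
    return List::create(_["trials"] = out, _["y"] = ypath, _["L"] = Lpath,
                        _["M_C"] = mcpath);
  return List::create(_["trials"] = out);
}

// ---------------------------------------------------------------------------
// Quadratic normal form for n >= 3 alternatives:
//   tau dX_k = [ a (e_k.Ibar)/(k+k^2)
//              + b/(2(k+k^2)) ( sum_{j<k}(j+j^2)X_j^2 - k(k^2-1)X_k^2
//                               + 2(k+k^2) X_k sum_{j>k} X_j ) ] dt
//              + sigma sqrt(dt) (e_k.eta)/(k+k^2).
// Decision on reconstructed coordinates: R0 + epsilon * recon_i >= theta when
// thresholdOnRates, else recon_i >= theta. |X| exceeding `cap` stops the trial
// (status -1); undecided at nsteps is status 0, decided is status 1.
// Returns ntrials x 3 (choice, rt, status) and optional single-trial path.
// [[Rcpp::export]]
List nf_trials_cpp(int n, double tau, double a, double b, NumericVector Ibar,
                   double sigma, double epsilon, double R0, double theta,
                   bool thresholdOnRates, double dt, int nsteps, double cap,
                   NumericVector x0, int ntrials, bool returnPath = false,
                   Nullable<NumericMatrix> noise = R_NilValue) {
  NumericMatrix out(ntrials, 3);
  bool shared = noise.isNotNull();
  NumericMatrix NE;
  if (shared) {
    NE = NumericMatrix(noise);
    if (NE.nrow() != n || NE.ncol() < nsteps) stop("shared noise has wrong dimensions");
    if (ntrials != 1) stop("shared noise supports a single trial");
  }
  std::vector<double> Iv(Ibar.begin(), Ibar.end()), projI(n - 1), eta(n),
      proj(n - 1), X(n - 1), suf(n - 1), w(n - 1), rvec(n);
  project_comp(Iv, n, projI);
  const double sfac = sigma * std::sqrt(dt) / tau;
  NumericMatrix path;
  if (returnPath) path = NumericMatrix(nsteps + 1, n - 1);
  for (int tr = 0; tr < ntrials; ++tr) {
    for (int k = 0; k < n - 1; ++k) X[k] = x0[k];
    if (returnPath) for (int k = 0; k < n - 1; ++k) path(0, k) = X[k];
    int choice = 0, status = 0, laststep = nsteps;
    double rt = nsteps * dt;
    for (int t = 0; t < nsteps; ++t) {
      // drift at current X: suf[k-1] = sum_{j>k} X_j, prefix = sum_{j<k} (j+j^2) X_j^2
      suf[n - 2] = 0.0;
      for (int k = n - 3; k >= 0; --k) suf[k] = suf[k + 1] + X[k + 1];
      double prefix = 0.0;
      for (int k = 1; k <= n - 1; ++k) {
        double kk = (double)(k + k * k);
        double quad = prefix - (double)k * ((double)k * k - 1.0) * X[k - 1] * X[k - 1]
                      + 2.0 * kk * X[k - 1] * suf[k - 1];
        w[k - 1] = a * projI[k - 1] + b / (2.0 * kk) * quad;
        prefix += kk * X[k - 1] * X[k - 1];
      }
      for (int i = 0; i < n; ++i) eta[i] = shared ? NE(i, t) : norm_rand();
      project_comp(eta, n, proj);
      bool capped = false;
      for (int k = 0; k < n - 1; ++k) {
        X[k] += dt / tau * w[k] + sfac * proj[k];
        if (std::fabs(X[k]) > cap) capped = true;
      }
      if (returnPath) for (int k = 0; k < n - 1; ++k) path(t + 1, k) = X[k];
      reconstruct(X, n, 0.0, rvec);
      int ch;
      if (thresholdOnRates) {
        for (int i = 0; i < n; ++i) rvec[i] = R0 + epsilon * rvec[i];
        ch = crossing_choice(rvec, n, theta);
      } else {
        ch = crossing_choice(rvec, n, theta);
      }
      if (ch > 0) {
        choice = ch; status = 1; rt = (t + 1) * dt; laststep = t + 1;
        break;
      }
      if (capped) {
        status = -1; rt = (t + 1) * dt; laststep = t + 1;
        break;
      }
    }
    out(tr, 0) = choice;
    out(tr, 1) = rt;
    out(tr, 2) = status;
    if (returnPath && laststep < nsteps) {
      NumericMatrix p2(laststep + 1, n - 1);
      for (int u = 0; u <= laststep; ++u)
        for (int k = 0; k < n - 1; ++k) p2(u, k) = path(u, k);
      path = p2;
    }
  }
  if (returnPath) return List::create(_["trials"] = out, _["path"] = path);
  return List::create(_["trials"] = out);
}
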