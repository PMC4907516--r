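// Steady-state drivers for the oxygen and VEGF fields.
//
// These reproduce, iteration for iteration, the R-level composition of the
// step operations (advect -> belts-to-CAPs -> diffuse -> consume -> rescale
// belts for oxygen; synthesize -> diffuse -> decay for VEGF), but run the
// explicit dt_flux integration loop in compiled code so that re-equilibrating
// the fields after every occlusion event stays cheap. Consistency with the R
// reference path is asserted in the test suite.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// convergence bookkeeping: max relative per-cell change below tol for
// `window` consecutive iterations
static inline double rel_delta(const std::vector<double>& a,
                               const std::vector<double>& b,
                               double floor_scale) {
  double m = 0.0;
  for (size_t i = 0; i < a.size(); ++i) {
    double denom = std::max(std::fabs(b[i]), floor_scale);
    double d = std::fabs(a[i] - b[i]) / denom;
    if (d > m) m = d;
  }
  return m;
}

// [[Rcpp::export]]
List oxygen_ss_cpp(NumericVector tension0, NumericVector volume,
                   IntegerVector pin_idx, NumericVector pin_val,
                   IntegerVector consume_idx,
                   IntegerVector ci, IntegerVector cj, NumericVector karea,
                   NumericVector belt_vol0, NumericVector belt_geom,
                   IntegerVector belt_cap,
                   IntegerVector seg_off, IntegerVector seg_n,
                   IntegerVector seg_up_pool, IntegerVector seg_down_pool,
                   NumericVector seg_share, NumericVector seg_inlet_vol,
                   NumericVector seg_frac, int n_pools,
                   double v_max, double k_m, double alpha,
                   double dt, double tol, int window, int max_iter) {
  const int n_cells = tension0.size();
  const int n_edges = ci.size();
  const int n_segs = seg_n.size();
  const int n_belts = belt_vol0.size();

  std::vector<double> C(tension0.begin(), tension0.end());
  std::vector<double> C_prev(n_cells);
  std::vector<double> belts(belt_vol0.begin(), belt_vol0.end());
  std::vector<double> pool(std::max(n_pools, 1));
  std::vector<double> dvol(n_cells);
  // which cells are chain-fed CAPs, and their pre-diffusion volumes
  std::vector<double> cap_pre(n_cells);
  std::vector<char> cap_fed(n_cells, 0);
  for (int b = 0; b < n_belts; ++b) cap_fed[belt_cap[b]] = 1;

  double injected = 0, discharged = 0, consumed = 0;
  int consec = 0, it = 0;
  bool converged = false;
  // fraction of each junction pool taken by chain-carrying branches; the
  // remainder (slow chainless branches) is tallied as discharge
  std::vector<double> pool_take(std::max(n_pools, 1), 0.0);
  for (int s = 0; s < n_segs; ++s)
    if (seg_up_pool[s] >= 0) pool_take[seg_up_pool[s]] += seg_share[s];
  for (int p = 0; p < n_pools; ++p)
    if (pool_take[p] > 1.0) pool_take[p] = 1.0;

  // Anderson acceleration over coarse samples of the iteration: every
  // `accel_every` plain iterations record (state, residual); once the window
  // is full, take the least-squares combination minimizing the residual and
  // jump there. Plain iterations alone decide convergence; belts are
  // rescaled to stay consistent with jumped CAP tensions.
  const int accel_every = 80;
  const int AA = 7;               // history depth
  std::vector<std::vector<double>> hx(AA, std::vector<double>(n_cells));
  std::vector<std::vector<double>> hf(AA, std::vector<double>(n_cells));
  std::vector<double> x_before(n_cells);
  int hist = 0, snap_age = 0;

  for (it = 1; it <= max_iter; ++it) {
    std::copy(C.begin(), C.end(), C_prev.begin());
    injected = discharged = consumed = 0;

    // --- advection: pool outgoing volumes, shift, refill first belts.
    // The truncated last belt passes its content downstream; the overshoot
    // fraction of the penultimate belt passes through it in the same step.
    std::fill(pool.begin(), pool.end(), 0.0);
    for (int s = 0; s < n_segs; ++s) {
      int off = seg_off[s], n = seg_n[s];
      double out = belts[off + n - 1] +
        (1.0 - seg_frac[s]) * belts[off + n - 2];
      if (seg_down_pool[s] >= 0) pool[seg_down_pool[s]] += out;
      else discharged += out;
    }
    for (int p = 0; p < n_pools; ++p)
      discharged += pool[p] * (1.0 - pool_take[p]);
    for (int s = 0; s < n_segs; ++s) {
      int off = seg_off[s], n = seg_n[s];
      belts[off + n - 1] = seg_frac[s] * belts[off + n - 2];
      for (int b = n - 2; b >= 1; --b) belts[off + b] = belts[off + b - 1];
      if (seg_up_pool[s] < 0) {
        belts[off] = seg_inlet_vol[s];
        injected += seg_inlet_vol[s];
      } else {
        belts[off] = pool[seg_up_pool[s]] * seg_share[s];
      }
    }

    // --- belts to CAPs (pre-diffusion volumes -> tensions)
    std::fill(cap_pre.begin(), cap_pre.end(), 0.0);
    for (int b = 0; b < n_belts; ++b) cap_pre[belt_cap[b]] += belts[b];
    for (int c = 0; c < n_cells; ++c)
      if (cap_fed[c]) C[c] = cap_pre[c] / (alpha * volume[c]);

    // --- diffusion on the contact graph
    std::fill(dvol.begin(), dvol.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      double f = karea[e] * (C[ci[e]] - C[cj[e]]) * dt;
      dvol[ci[e]] -= f;
      dvol[cj[e]] += f;
    }
    for (int c = 0; c < n_cells; ++c) C[c] += dvol[c] / volume[c];
    for (int p = 0; p < pin_idx.size(); ++p) C[pin_idx[p]] = pin_val[p];

    // --- Michaelis-Menten consumption (MC, OT)
    for (int k = 0; k < consume_idx.size(); ++k) {
      int c = consume_idx[k];
      double rate = v_max * C[c] / (k_m + C[c]);
      double dc = std::min(C[c], rate * dt);
      C[c] -= dc;
      consumed += alpha * dc * volume[c];
    }

    // --- CAP post/pre ratio back onto belts
    for (int b = 0; b < n_belts; ++b) {
      int c = belt_cap[b];
      double pre = cap_pre[c];
      if (pre > 0) belts[b] *= alpha * C[c] * volume[c] / pre;
    }

    double delta = rel_delta(C, C_prev, 0.1);
    consec = (delta < tol) ? consec + 1 : 0;
    if (consec >= window) { converged = true; break; }

    ++snap_age;
    if (snap_age == accel_every) {
      snap_age = 0;
      if (hist < AA) {
        std::copy(C_prev.begin(), C_prev.end(), hx[hist].begin());
        for (int c = 0; c < n_cells; ++c) hf[hist][c] = C[c] - C_prev[c];
        ++hist;
      }
      if (hist == AA) {
        // minimize || f_last - sum_g gamma_g (f_last - ... ) || via the
        // difference formulation: (dF' dF) gamma = dF' f_last
        const int m = AA - 1;
        double G[AA][AA], rhsv[AA], gamma[AA];
        for (int a = 0; a < m; ++a) {
          for (int b2 = 0; b2 < m; ++b2) G[a][b2] = 0.0;
          rhsv[a] = 0.0;
        }
        for (int c = 0; c < n_cells; ++c) {
          double fl = hf[m][c];
          for (int a = 0; a < m; ++a) {
            double dfa = hf[a + 1][c] - hf[a][c];
            rhsv[a] += dfa * fl;
            for (int b2 = 0; b2 <= a; ++b2)
              G[a][b2] += dfa * (hf[b2 + 1][c] - hf[b2][c]);
          }
        }
        for (int a = 0; a < m; ++a)
          for (int b2 = a + 1; b2 < m; ++b2) G[a][b2] = G[b2][a];
        // Gaussian elimination with small ridge
        double ridge = 0.0;
        for (int a = 0; a < m; ++a) ridge += G[a][a];
        ridge = ridge / m * 1e-10 + 1e-300;
        for (int a = 0; a < m; ++a) G[a][a] += ridge;
        bool ok = true;
        for (int a = 0; a < m && ok; ++a) {
          int piv = a;
          for (int r2 = a + 1; r2 < m; ++r2)
            if (std::fabs(G[r2][a]) > std::fabs(G[piv][a])) piv = r2;
          if (std::fabs(G[piv][a]) < 1e-300) { ok = false; break; }
          if (piv != a) {
            for (int c2 = 0; c2 < m; ++c2) std::swap(G[a][c2], G[piv][c2]);
            std::swap(rhsv[a], rhsv[piv]);
          }
          for (int r2 = a + 1; r2 < m; ++r2) {
            double fac = G[r2][a] / G[a][a];
            for (int c2 = a; c2 < m; ++c2) G[r2][c2] -= fac * G[a][c2];
            rhsv[r2] -= fac * rhsv[a];
          }
        }
        if (ok) {
          for (int a = m - 1; a >= 0; --a) {
            double s = rhsv[a];
            for (int c2 = a + 1; c2 < m; ++c2) s -= G[a][c2] * gamma[c2];
            gamma[a] = s / G[a][a];
          }
          // x* = (x_m + f_m) - sum gamma_a [ (x_{a+1}+f_{a+1}) - (x_a+f_a) ]
          double jump_mag = 0.0;
          std::copy(C.begin(), C.end(), x_before.begin());
          for (int c = 0; c < n_cells; ++c) {
            double xs = hx[m][c] + hf[m][c];
            for (int a = 0; a < m; ++a)
              xs -= gamma[a] * ((hx[a + 1][c] + hf[a + 1][c]) -
                                (hx[a][c] + hf[a][c]));
            if (xs < 0) xs = 0;
            jump_mag = std::max(jump_mag, std::fabs(xs - C[c]));
            C[c] = xs;
          }
          for (int c = 0; c < n_cells; ++c) {
            double scale = 1.0;
            if (cap_fed[c] && x_before[c] > 1e-12) scale = C[c] / x_before[c];
            x_before[c] = scale;
          }
          for (int b = 0; b < n_belts; ++b) belts[b] *= x_before[belt_cap[b]];
          for (int p = 0; p < pin_idx.size(); ++p) C[pin_idx[p]] = pin_val[p];
          consec = 0;
        }
        hist = 0;
      }
    }
    if (it % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (!converged)
    stop("oxygen steady state not reached in %d iterations", max_iter);

  return List::create(_["tension"] = NumericVector(C.begin(), C.end()),
                      _["belt_vol"] = NumericVector(belts.begin(), belts.end()),
                      _["iterations"] = it,
                      _["converged"] = converged,
                      _["injected"] = injected,
                      _["discharged"] = discharged,
                      _["consumed"] = consumed);
}

// [[Rcpp::export]]
List vegf_ss_cpp(NumericVector vegf0, NumericVector volume,
                 IntegerVector pin_idx,
                 NumericVector drive, NumericVector basal,
                 IntegerVector ci, IntegerVector cj, NumericVector karea,
                 double k_dec, double v_sat,
                 double dt, double tol, int window, int max_iter) {
  const int n_cells = vegf0.size();
  const int n_edges = ci.size();
  std::vector<double> V(vegf0.begin(), vegf0.end());
  std::vector<double> V_prev(n_cells);
  std::vector<double> dvol(n_cells);
  std::vector<char> pinned(n_cells, 0);
  for (int p = 0; p < pin_idx.size(); ++p) pinned[pin_idx[p]] = 1;
  const double decay = 1.0 - k_dec * dt;

  int consec = 0, it = 0;
  bool converged = false;
  // Anderson acceleration over coarse samples (see the oxygen driver); plain
  // iterations alone decide convergence
  const int accel_every = 80;
  const int AA = 7;
  std::vector<std::vector<double>> hx(AA, std::vector<double>(n_cells));
  std::vector<std::vector<double>> hf(AA, std::vector<double>(n_cells));
  int hist = 0, snap_age = 0;
  for (it = 1; it <= max_iter; ++it) {
    std::copy(V.begin(), V.end(), V_prev.begin());
    // synthesis: basal everywhere (non-FAZ) + saturating hypoxic drive
    for (int c = 0; c < n_cells; ++c) {
      double sat = 1.0 - V[c] / v_sat;
      if (sat < 0) sat = 0;
      V[c] += (basal[c] + drive[c] * sat) * dt;
    }
    // diffusion
    std::fill(dvol.begin(), dvol.end(), 0.0);
    for (int e = 0; e < n_edges; ++e) {
      double f = karea[e] * (V[ci[e]] - V[cj[e]]) * dt;
      dvol[ci[e]] -= f;
      dvol[cj[e]] += f;
    }
    for (int c = 0; c < n_cells; ++c) V[c] += dvol[c] / volume[c];
    // first-order decay, pinned FAZ sink, non-negativity
    for (int c = 0; c < n_cells; ++c) {
      if (pinned[c]) { V[c] = 0.0; continue; }
      V[c] *= decay;
      if (V[c] < 0) V[c] = 0;
    }
    double delta = rel_delta(V, V_prev, 0.05);
    consec = (delta < tol) ? consec + 1 : 0;
    if (consec >= window) { converged = true; break; }

    ++snap_age;
    if (snap_age == accel_every) {
      snap_age = 0;
      if (hist < AA) {
        std::copy(V_prev.begin(), V_prev.end(), hx[hist].begin());
        for (int c = 0; c < n_cells; ++c) hf[hist][c] = V[c] - V_prev[c];
        ++hist;
      }
      if (hist == AA) {
        const int m = AA - 1;
        double G[AA][AA], rhsv[AA], gamma[AA];
        for (int a = 0; a < m; ++a) {
          for (int b2 = 0; b2 < m; ++b2) G[a][b2] = 0.0;
          rhsv[a] = 0.0;
        }
        for (int c = 0; c < n_cells; ++c) {
          double fl = hf[m][c];
          for (int a = 0; a < m; ++a) {
            double dfa = hf[a + 1][c] - hf[a][c];
            rhsv[a] += dfa * fl;
            for (int b2 = 0; b2 <= a; ++b2)
              G[a][b2] += dfa * (hf[b2 + 1][c] - hf[b2][c]);
          }
        }
        for (int a = 0; a < m; ++a)
          for (int b2 = a + 1; b2 < m; ++b2) G[a][b2] = G[b2][a];
        double ridge = 0.0;
        for (int a = 0; a < m; ++a) ridge += G[a][a];
        ridge = ridge / m * 1e-10 + 1e-300;
        for (int a = 0; a < m; ++a) G[a][a] += ridge;
        bool ok = true;
        for (int a = 0; a < m && ok; ++a) {
          int piv = a;
          for (int r2 = a + 1; r2 < m; ++r2)
            if (std::fabs(G[r2][a]) > std::fabs(G[piv][a])) piv = r2;
          if (std::fabs(G[piv][a]) < 1e-300) { ok = false; break; }
          if (piv != a) {
            for (int c2 = 0; c2 < m; ++c2) std::swap(G[a][c2], G[piv][c2]);
            std::swap(rhsv[a], rhsv[piv]);
          }
          for (int r2 = a + 1; r2 < m; ++r2) {
            double fac = G[r2][a] / G[a][a];
            for (int c2 = a; c2 < m; ++c2) G[r2][c2] -= fac * G[a][c2];
            rhsv[r2] -= fac * rhsv[a];
          }
        }
        if (ok) {
          for (int a = m - 1; a >= 0; --a) {
            double s = rhsv[a];
            for (int c2 = a + 1; c2 < m; ++c2) s -= G[a][c2] * gamma[c2];
            gamma[a] = s / G[a][a];
          }
          for (int c = 0; c < n_cells; ++c) {
            double xs = hx[m][c] + hf[m][c];
            for (int a = 0; a < m; ++a)
              xs -= gamma[a] * ((hx[a + 1][c] + hf[a + 1][c]) -
                                (hx[a][c] + hf[a][c]));
            if (xs < 0) xs = 0;
            V[c] = xs;
          }
          for (int p = 0; p < pin_idx.size(); ++p) V[pin_idx[p]] = 0.0;
          consec = 0;
        }
        hist = 0;
      }
    }
    if (it % 20000 == 0) Rcpp::checkUserInterrupt();
  }
  if (!converged)
    stop("VEGF steady state not reached in %d iterations", max_iter);
  return List::create(_["vegf"] = NumericVector(V.begin(), V.end()),
                      _["iterations"] = it,
                      _["converged"] = converged);
}
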