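// Compiled simulation loop. Mirrors the R reference phases in dynamics.R,
// consuming R's random stream in the identical documented order:
// death (one uniform per live site, column-major), birth (one uniform per
// candidate vacancy, column-major; parent picked by cumulative fitness over
// live neighbours in up/down/left/right order), mutation (one uniform per
// unset locus per live site, column-major).
#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline int popcount9(int code) {
  int n = 0;
  for (int b = 0; b < 9; ++b) n += (code >> b) & 1;
  return n;
}

// [[Rcpp::export]]
List cpp_run(IntegerMatrix lat0, List kernels, NumericVector par,
             IntegerVector class_tab, int n_steps) {
  const int nr = lat0.nrow(), nc = lat0.ncol(), n = nr * nc;
  // par: A1 A2 A3 | r1 r2 r3 | c1 c2 c3 | cL d mu w_base eps | p_death alpha mut_rate
  const double *A = &par[0], *rdrug = &par[3], *cost = &par[6];
  const double cL = par[9], dmg = par[10], mu = par[11], w_base = par[12],
               eps = par[13], p_death = par[14], alpha = par[15], mut_rate = par[16];

  std::vector<int> lat(n);
  for (int i = 0; i < n; ++i) lat[i] = lat0[i];  // NA_INTEGER = vacant

  // kernels: weights matrices, factor order GF1 GF2 GF3 LACTATE (bits 0..3)
  std::vector<NumericMatrix> kw;
  std::vector<int> krad;
  for (int f = 0; f < 4; ++f) {
    NumericMatrix w = kernels[f];
    kw.push_back(w);
    krad.push_back((w.nrow() - 1) / 2);
  }

  std::vector<double> field(4 * n, 0.0), wfit(n);
  std::vector<int> old(n);
  std::vector<unsigned char> prodcache(n, 0);  // cached production bits 0..3
  NumericMatrix metrics(n_steps, 8);

  // add (sign = +1) or remove (sign = -1) one producer's kernel for factor f
  auto stamp = [&](int f, int r, int c, double sign) {
    const int rad = krad[f], kside = 2 * rad + 1;
    const double *w = &kw[f](0, 0);
    double *fld = &field[f * n];
    const int djlo = std::max(-rad, -c), djhi = std::min(rad, nc - 1 - c);
    const int dilo = std::max(-rad, -r), dihi = std::min(rad, nr - 1 - r);
    for (int dj = djlo; dj <= djhi; ++dj) {
      const double *wc = w + (dj + rad) * kside + rad;
      double *fc = fld + (c + dj) * nr + r;
      if (sign > 0) { for (int di = dilo; di <= dihi; ++di) fc[di] += wc[di]; }
      else          { for (int di = dilo; di <= dihi; ++di) fc[di] -= wc[di]; }
    }
  };

  for (int step = 0; step < n_steps; ++step) {
    // 1. concentration fields from current producer occupancy, updated
    //    incrementally: only sites whose production bits changed since the
    //    previous step touch the fields
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        const int code = lat[i];
        const unsigned char now = (code == NA_INTEGER) ? 0 : (unsigned char)(code & 15);
        const unsigned char was = prodcache[i];
        if (now == was) continue;
        for (int f = 0; f < 4; ++f) {
          const int bn = (now >> f) & 1, bw = (was >> f) & 1;
          if (bn != bw) stamp(f, r, c, bn ? 1.0 : -1.0);
        }
        prodcache[i] = now;
      }
    }

    // 2. fitness map (same term order as the R implementation)
    for (int i = 0; i < n; ++i) {
      const int code = lat[i];
      if (code == NA_INTEGER) { wfit[i] = NA_REAL; continue; }
      double wv = w_base;
      wv += ((code >> 4) & 1) ? A[0] * rdrug[0] * field[i] : 0.0;
      wv += ((code >> 5) & 1) ? A[1] * rdrug[1] * field[n + i] : 0.0;
      wv += ((code >> 6) & 1) ? A[2] * rdrug[2] * field[2 * n + i] : 0.0;
      wv -= ((code >> 0) & 1) ? cost[0] : 0.0;
      wv -= ((code >> 1) & 1) ? cost[1] : 0.0;
      wv -= ((code >> 2) & 1) ? cost[2] : 0.0;
      wv -= ((code >> 3) & 1) ? cL : 0.0;
      wv -= ((code >> 7) & 1) ? 0.0 : dmg * field[3 * n + i];
      wv -= mu * popcount9(code);
      wfit[i] = (wv > eps) ? wv : eps;
    }

    // 3. death: baseline + immune elimination
    for (int i = 0; i < n; ++i) {
      const int code = lat[i];
      if (code == NA_INTEGER) continue;
      const double u = R::unif_rand();
      const double p_imm = ((code >> 8) & 1) ? 0.0 : alpha * popcount9(code) / 9.0;
      const double p = 1.0 - (1.0 - p_death) * (1.0 - p_imm);
      if (u < p) { lat[i] = NA_INTEGER; wfit[i] = NA_REAL; }
    }

    // 4. synchronous birth into vacancies (parents from pre-fill occupancy)
    std::copy(lat.begin(), lat.end(), old.begin());
    for (int c = 0; c < nc; ++c) {
      for (int r = 0; r < nr; ++r) {
        const int i = c * nr + r;
        if (old[i] != NA_INTEGER) continue;
        int nb[4]; int m = 0;
        if (r > 0      && old[i - 1]  != NA_INTEGER) nb[m++] = i - 1;   // up
        if (r < nr - 1 && old[i + 1]  != NA_INTEGER) nb[m++] = i + 1;   // down
        if (c > 0      && old[i - nr] != NA_INTEGER) nb[m++] = i - nr;  // left
        if (c < nc - 1 && old[i + nr] != NA_INTEGER) nb[m++] = i + nr;  // right
        if (m == 0) continue;
        const double u = R::unif_rand();
        double w[4];
        bool all_floor = true;
        for (int k = 0; k < m; ++k) {
          w[k] = wfit[nb[k]];
          if (w[k] > eps) all_floor = false;
        }
        if (all_floor) for (int k = 0; k < m; ++k) w[k] = 1.0;
        double tot = 0.0;
        for (int k = 0; k < m; ++k) tot += w[k];
        double acc = 0.0;
        for (int k = 0; k < m; ++k) {
          acc += w[k];
          if (u * tot < acc) { lat[i] = old[nb[k]]; break; }
        }
      }
    }

    // 5. one-way mutation of every live cell
    if (mut_rate > 0.0) {
      for (int i = 0; i < n; ++i) {
        int code = lat[i];
        if (code == NA_INTEGER) continue;
        for (int b = 0; b < 9; ++b) {
          if (!((code >> b) & 1) && R::unif_rand() < mut_rate)
            code |= (1 << b);
        }
        lat[i] = code;
      }
    }

    // 6. metrics on the resulting lattice
    int live = 0, cls_n[5] = {0, 0, 0, 0, 0};
    long mut_sum = 0;
    for (int i = 0; i < n; ++i) {
      const int code = lat[i];
      if (code == NA_INTEGER) continue;
      ++live;
      ++cls_n[class_tab[code]];
      mut_sum += popcount9(code);
    }
    metrics(step, 0) = step + 1;
    metrics(step, 1) = live;
    for (int k = 0; k < 5; ++k)
      metrics(step, 2 + k) = live ? (double)cls_n[k] / live : NA_REAL;
    metrics(step, 7) = live ? (double)mut_sum / live / 9.0 : NA_REAL;
  }

  IntegerMatrix latf(nr, nc);
  for (int i = 0; i < n; ++i) latf[i] = lat[i];
  return List::create(_["metrics"] = metrics, _["lattice"] = latf);
}
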