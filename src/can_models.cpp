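// Inner loops of the continuous attractor network simulators.

#include <Rcpp.h>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Rate dynamics of an inhibitory-sheet grid network:
//   f_{t+1} = f_t + (1/rho) * (-f_t + [J + f_t.W + gamma * s * cos(phi - phibar)]_+)
// W is passed with W(j, i) = weight from unit j onto unit i.
// Returns rates at every `keep_every`-th step after `stab_steps` stabilization
// iterations at zero velocity (random initial state supplied by caller).
// [[Rcpp::export(name = ".sheet_dynamics")]]
List sheet_dynamics(NumericMatrix W, NumericVector f0, NumericVector phibar,
                    NumericVector speed, NumericVector heading, double J,
                    double gamma, double rho, double rate_floor, int stab_steps,
                    int keep_every) {
  const int N = W.nrow();
  if (W.ncol() != N) stop("W must be square");
  if (f0.size() != N || phibar.size() != N) stop("state size mismatch");
  const int T = speed.size();
  if (heading.size() != T) stop("speed/heading length mismatch");
  if (keep_every < 1) stop("keep_every must be >= 1");

  // float copy of W, stored so that row j (contiguous) holds W(j, .)
  std::vector<float> Wf((size_t)N * N);
  for (int j = 0; j < N; ++j)
    for (int i = 0; i < N; ++i) Wf[(size_t)j * N + i] = (float)W(j, i);

  std::vector<double> f(N), v(N);
  std::vector<double> cosb(N), sinb(N);
  for (int i = 0; i < N; ++i) {
    f[i] = f0[i];
    cosb[i] = std::cos(phibar[i]);
    sinb[i] = std::sin(phibar[i]);
  }

  const double invrho = 1.0 / rho;
  const int n_keep = T / keep_every;
  NumericMatrix rates(N, n_keep);
  int kept = 0;

  auto step = [&](double inx, double iny) {
    // v = J + f.W + gamma*s*cos(phi - phibar), rectified
    for (int i = 0; i < N; ++i) v[i] = J + inx * cosb[i] + iny * sinb[i];
    for (int j = 0; j < N; ++j) {
      const double fj = f[j];
      if (fj == 0.0) continue;
      const float* wrow = &Wf[(size_t)j * N];
      for (int i = 0; i < N; ++i) v[i] += fj * wrow[i];
    }
    for (int i = 0; i < N; ++i) {
      double u = v[i] > 0.0 ? v[i] : 0.0;
      f[i] += invrho * (u - f[i]);
    }
  };

  for (int t = 0; t < stab_steps; ++t) {
    step(0.0, 0.0);
    if (t % 500 == 0) Rcpp::checkUserInterrupt();
  }
  for (int t = 0; t < T; ++t) {
    double g = gamma * speed[t];
    step(g * std::cos(heading[t]), g * std::sin(heading[t]));
    if ((t + 1) % keep_every == 0 && kept < n_keep) {
      for (int i = 0; i < N; ++i) {
        double r = f[i];
        rates(i, kept) = (r < rate_floor) ? 0.0 : r;
      }
      ++kept;
    }
    if (t % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericVector fout(N);
  for (int i = 0; i < N; ++i) fout[i] = f[i];
  return List::create(_["rates"] = rates, _["state"] = fout);
}

// Twisted-torus (and untwisted square-torus) attractor with divisive
// normalization:
//   w_ij = I * exp(-||c_i - c_j + v||^2 / sigma^2) - Tshift
//   b_i  = a_i + sum_j a_j w_ij
//   a'   = (1 - tau) * b + tau * b / mean(b),  clipped at 0
// Distances are computed as the minimum over periodic copies: the 7 offsets
// of the twisted torus or the 9 offsets of the unit square torus. The velocity
// shift v (already scaled by the gain) is shared across pairs at each frame.
// The recurrent drive is scaled by `norm` (the caller passes N_ref / N) so
// the published kernel constants remain stable across network sizes.
// [[Rcpp::export(name = ".torus_dynamics")]]
List torus_dynamics(NumericMatrix cells, NumericMatrix vel, NumericVector a0,
                    double intensity, double sigma, double tshift, double tau,
                    bool twisted, int stab_steps, double norm) {
  const int N = cells.nrow();
  const int T = vel.nrow();
  if (a0.size() != N) stop("initial state size mismatch");

  const double SQ3_2 = 0.8660254037844386;
  std::vector<double> offx, offy;
  if (twisted) {
    double ox[7] = {0, -1, 1, -0.5, 0.5, -0.5, 0.5};
    double oy[7] = {0, 0, 0, SQ3_2, SQ3_2, -SQ3_2, -SQ3_2};
    offx.assign(ox, ox + 7);
    offy.assign(oy, oy + 7);
  } else {
    for (int dx = -1; dx <= 1; ++dx)
      for (int dy = -1; dy <= 1; ++dy) {
        offx.push_back(dx);
        offy.push_back(dy);
      }
  }
  const int n_off = (int)offx.size();

  // pairwise base differences c_i - c_j
  std::vector<float> dx((size_t)N * N), dy((size_t)N * N);
  for (int i = 0; i < N; ++i)
    for (int j = 0; j < N; ++j) {
      dx[(size_t)i * N + j] = (float)(cells(i, 0) - cells(j, 0));
      dy[(size_t)i * N + j] = (float)(cells(i, 1) - cells(j, 1));
    }

  std::vector<double> a(N), b(N);
  for (int i = 0; i < N; ++i) a[i] = a0[i];

  NumericMatrix rates(N, T);
  NumericMatrix bump(T, 2);
  const float inv_s2 = (float)(1.0 / (sigma * sigma));
  const float fI = (float)intensity, fT = (float)tshift;

  auto advance = [&](double vx, double vy) {
    const float fvx = (float)vx, fvy = (float)vy;
    for (int i = 0; i < N; ++i) {
      const float* dxr = &dx[(size_t)i * N];
      const float* dyr = &dy[(size_t)i * N];
      double acc = 0;
      for (int j = 0; j < N; ++j) {
        float best = 1e30f;
        const float bx = dxr[j] + fvx, by = dyr[j] + fvy;
        for (int o = 0; o < n_off; ++o) {
          float ex = bx + (float)offx[o], ey = by + (float)offy[o];
          float d2 = ex * ex + ey * ey;
          if (d2 < best) best = d2;
        }
        float w = fI * std::exp(-best * inv_s2) - fT;
        acc += a[j] * w;
      }
      b[i] = a[i] + norm * acc;
    }
    double mean_b = 0;
    for (int i = 0; i < N; ++i) mean_b += b[i];
    mean_b /= N;
    if (mean_b == 0) mean_b = 1;
    for (int i = 0; i < N; ++i) {
      double ai = (1.0 - tau) * b[i] + tau * b[i] / mean_b;
      // clip at zero but let NaN from unstable parameters propagate
      a[i] = ai > 0 ? ai : (ai == ai ? 0 : ai);
    }
  };

  for (int t = 0; t < stab_steps; ++t) {
    advance(0.0, 0.0);
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }

  // bump phase via the dual-lattice circle coordinates: on the twisted torus
  // (periods (1,0) and (1/2, sqrt(3)/2)) the pair u = 2pi (x - y/sqrt(3)),
  // v = 2pi 2y/sqrt(3) is single-valued; on the square torus u = 2pi x,
  // v = 2pi y
  const double TWO_PI = 6.283185307179586;
  const double SQ3 = 1.7320508075688772;
  for (int t = 0; t < T; ++t) {
    advance(vel(t, 0), vel(t, 1));
    double cx = 0, sx = 0, cy = 0, sy = 0;
    for (int i = 0; i < N; ++i) {
      rates(i, t) = a[i];
      double thx = twisted
                       ? TWO_PI * (cells(i, 0) - cells(i, 1) / SQ3)
                       : TWO_PI * cells(i, 0);
      double thy = twisted ? TWO_PI * 2.0 * cells(i, 1) / SQ3
                           : TWO_PI * cells(i, 1);
      cx += a[i] * std::cos(thx);
      sx += a[i] * std::sin(thx);
      cy += a[i] * std::cos(thy);
      sy += a[i] * std::sin(thy);
    }
    double phx = std::atan2(sx, cx), phy = std::atan2(sy, cy);
    bump(t, 0) = phx < 0 ? phx + TWO_PI : phx;
    bump(t, 1) = phy < 0 ? phy + TWO_PI : phy;
    if (t % 200 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["rates"] = rates, _["bump"] = bump);
}
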