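#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Crank-Nicolson integration of the Fokker-Planck equation for
//   dX = drift * dt + dW,   X(0) = 0,
// with symmetric, linearly collapsing absorbing boundaries
//   b(t) = scale * (B0 - tB * t), clamped one spatial cell above zero.
// Unit diffusion coefficient (sigma_g is absorbed into drift/bound params).
//
// Returns defective first-passage densities at the upper ("correct" when
// drift > 0 means toward the correct choice) and lower bounds on a uniform
// time grid, plus the absorbed masses and residual survival mass.
//
// Mass accounting: per-step loss of interior probability is attributed to
// the two boundaries in proportion to the diffusive boundary fluxes
// (J = D * p_adjacent / dx with D = 1/2, since p = 0 on the boundary node).
// When the bound collapses past grid cells, their mass is absorbed on the
// side matching the sign of the decision variable.

// [[Rcpp::export]]
List fpt_solve_cpp(double drift, double B0, double tB, double scale,
                   double dt, double dx, double horizon,
                   double mass_tol = 1e-8, int max_half_cells = 0) {
  if (B0 <= 0.0 || scale <= 0.0) stop("bound height must be positive");
  if (dt <= 0.0 || dx <= 0.0) stop("dt and dx must be positive");
  const double b0 = scale * B0;
  int half = (int)std::ceil(b0 / dx);
  if (half < 2) half = 2;
  // optional cap on spatial resolution (dx stretches for very tall bounds)
  if (max_half_cells > 1 && half > max_half_cells) half = max_half_cells;
  const double dxe = b0 / half;     // adjusted so the bound starts on a node
  const int center = half;
  const int M = 2 * half + 1;       // nodes 0..2*half

  // bound must not cross more than one spatial cell per time step
  if (scale * tB * dt > dxe * (1.0 + 1e-9))
    stop("resolution error: bound crosses more than one spatial cell per step (scale*tB*dt = %f > dx = %f)",
         scale * tB * dt, dxe);

  const int N = (int)std::ceil(horizon / dt);
  NumericVector g_up(N + 1), g_lo(N + 1);

  std::vector<double> p(M, 0.0), rhs(M, 0.0), cp(M, 0.0);
  p[center] = 1.0 / dxe;            // delta initial condition

  // theta scheme: fully implicit (theta = 1) Rannacher startup smooths the
  // delta initial condition, then Crank-Nicolson (theta = 1/2)
  const double ca = dt / (2.0 * dxe * dxe);      // D * dt / dx^2, D = 1/2
  const double cb = drift * dt / (2.0 * dxe);
  const int n_startup = 4;

  double cum_up = 0.0, cum_lo = 0.0;
  int k = half;                     // absorbing nodes at center +/- k

  double w_last = 0.5;              // fallback flux split

  for (int n = 1; n <= N; ++n) {
    const double t_new = n * dt;
    double b_new = scale * (B0 - tB * t_new);
    int k_new = (int)std::lround(b_new / dxe);
    if (k_new < 1) k_new = 1;       // bound floor: one cell above zero
    if (k_new > k) k_new = k;       // bound is non-increasing

    // collapse steps re-introduce a boundary discontinuity; treat them
    // (like the startup) fully implicitly to avoid CN oscillations
    const double theta = (n <= n_startup || k_new < k) ? 1.0 : 0.5;
    const double dlo = -theta * (ca + cb);       // implicit sub-diagonal
    const double dup = -theta * (ca - cb);       // implicit super-diagonal
    const double dmid = 1.0 + 2.0 * theta * ca;
    const double ra = (1.0 - theta) * ca, rb = (1.0 - theta) * cb;

    // collapse: absorb mass in cells swept past by the shrinking bound,
    // split by the sign of the decision variable
    if (k_new < k) {
      double sweep_up = 0.0, sweep_lo = 0.0;
      for (int j = center + k_new; j <= center + k - 1; ++j) {
        sweep_up += p[j] * dxe; p[j] = 0.0;
      }
      for (int j = center - k + 1; j <= center - k_new; ++j) {
        sweep_lo += p[j] * dxe; p[j] = 0.0;
      }
      cum_up += sweep_up; cum_lo += sweep_lo;
      g_up[n] += sweep_up / dt; g_lo[n] += sweep_lo / dt;
      k = k_new;
    }

    const int jlo = center - k + 1, jhi = center + k - 1;   // interior
    double mass_before = 0.0;
    for (int j = jlo; j <= jhi; ++j) mass_before += p[j];
    mass_before *= dxe;
    if (mass_before <= 0.0) { break; }

    // RHS of Crank-Nicolson (boundary nodes are zero)
    for (int j = jlo; j <= jhi; ++j) {
      double up = (j + 1 <= jhi) ? p[j + 1] : 0.0;
      double lo = (j - 1 >= jlo) ? p[j - 1] : 0.0;
      rhs[j] = (1.0 - 2.0 * ra) * p[j] + (ra - rb) * up + (ra + rb) * lo;
    }

    // Thomas algorithm on the interior window
    cp[jlo] = dup / dmid;
    rhs[jlo] = rhs[jlo] / dmid;
    for (int j = jlo + 1; j <= jhi; ++j) {
      double m = dmid - dlo * cp[j - 1];
      cp[j] = dup / m;
      rhs[j] = (rhs[j] - dlo * rhs[j - 1]) / m;
    }
    p[jhi] = rhs[jhi];
    for (int j = jhi - 1; j >= jlo; --j) p[j] = rhs[j] - cp[j] * p[j + 1];
    for (int j = jlo; j <= jhi; ++j) if (p[j] < 0.0) p[j] = 0.0;

    double mass_after = 0.0;
    for (int j = jlo; j <= jhi; ++j) mass_after += p[j];
    mass_after *= dxe;

    double loss = mass_before - mass_after;
    if (loss < 0.0) loss = 0.0;
    const double ju = p[jhi], jl = p[jlo];
    const double w_up = (ju + jl > 0.0) ? ju / (ju + jl) : w_last;
    w_last = w_up;
    cum_up += loss * w_up; cum_lo += loss * (1.0 - w_up);
    g_up[n] += loss * w_up / dt; g_lo[n] += loss * (1.0 - w_up) / dt;

    if (mass_after < mass_tol) break;
  }

  double survival = 1.0 - cum_up - cum_lo;
  if (survival < 0.0) survival = 0.0;

  return List::create(_["g_up"] = g_up, _["g_lo"] = g_lo,
                      _["p_up"] = cum_up, _["p_lo"] = cum_lo,
                      _["survival"] = survival,
                      _["dt"] = dt, _["dx"] = dxe, _["n_steps"] = N);
}

// Euler-Maruyama path simulation of the same process; Monte-Carlo oracle
// for the solver and the generator behind synthetic observers. Uses R's RNG
// so results are reproducible with set.seed(). choice: +1 upper, -1 lower,
// 0 not absorbed within the horizon (rt = NA).

// [[Rcpp::export]]
List em_sample_cpp(double drift, double B0, double tB, double scale,
                   int n, double dt, double horizon, double sigma = 1.0) {
  if (B0 <= 0.0 || scale <= 0.0) stop("bound height must be positive");
  if (sigma <= 0.0) stop("diffusion coefficient must be positive");
  const int nmax = (int)std::ceil(horizon / dt);
  const double sdt = sigma * std::sqrt(dt);
  IntegerVector choice(n);
  NumericVector rt(n);
  for (int i = 0; i < n; ++i) {
    double x = 0.0;
    int ch = 0; double t_abs = NA_REAL;
    for (int s = 0; s < nmax; ++s) {
      const double t = s * dt;
      double b = scale * (B0 - tB * t);
      if (b <= 0.0) {   // fully collapsed: forced absorption by sign
        ch = (x > 0.0) ? 1 : (x < 0.0 ? -1 : (unif_rand() < 0.5 ? 1 : -1));
        t_abs = t;
        break;
      }
      const double x_old = x;
      x += drift * dt + sdt * norm_rand();
      double b_next = scale * (B0 - tB * (t + dt));
      if (b_next < 0.0) b_next = 0.0;
      if (x >= b_next)  { ch = 1;  t_abs = t + dt; break; }
      if (x <= -b_next) { ch = -1; t_abs = t + dt; break; }
      // Brownian-bridge correction for undetected within-step crossings
      const double s2dt = sdt * sdt;
      const double pu = std::exp(-2.0 * (b - x_old) * (b_next - x) / s2dt);
      if (unif_rand() < pu) { ch = 1; t_abs = t + dt; break; }
      const double pl = std::exp(-2.0 * (b + x_old) * (b_next + x) / s2dt);
      if (unif_rand() < pl) { ch = -1; t_abs = t + dt; break; }
    }
    choice[i] = ch;
    rt[i] = t_abs;
  }
  return List::create(_["choice"] = choice, _["rt"] = rt);
}
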