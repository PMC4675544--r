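#include <Rcpp.h>
#include <cmath>
#include <vector>
using namespace Rcpp;

// Periodic wrap onto [0, L). Same expression as the R-level ring_wrap() so
// compiled and interpreted paths agree to the last bit.
static inline double wrapL(double x, double L) {
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L; // guard against x/L rounding exactly to an integer
  return y;
}

// Odd alignment response G(u) = (u + sign(u))/2, G(0) = 0.
static inline double gfun(double u) {
  if (u > 0.0) return 0.5 * (u + 1.0);
  if (u < 0.0) return 0.5 * (u - 1.0);
  return 0.0;
}

static inline double ring_dist(double a, double b, double L) {
  double d = std::fabs(a - b);
  return (d > L - d) ? (L - d) : d;
}

// Minimal-image signed displacement from a to b on the ring, in (-L/2, L/2].
static inline double ring_disp(double a, double b, double L) {
  double dx = b - a;
  return dx - L * std::nearbyint(dx / L);
}

// Neighbour sums of u over {j != i : ring_dist(x_i, x_j) <= delta}, optionally
// restricted to moving particles. Uses a cell list when the ring is wide
// enough for one; O(N^2) fallback otherwise.
static void neighbour_sums(const std::vector<double>& x,
                           const std::vector<double>& u,
                           const std::vector<char>* mov,
                           double L, double delta,
                           std::vector<double>& sum, std::vector<int>& cnt) {
  const int N = (int)x.size();
  std::fill(sum.begin(), sum.end(), 0.0);
  std::fill(cnt.begin(), cnt.end(), 0);
  double ncell_d = std::floor(L / delta);
  // more cells than a few per particle buys nothing; also avoids huge
  // allocations when delta << L
  int ncell = (ncell_d > 4.0 * N) ? 4 * N : (int)ncell_d;
  if (ncell >= 3 && N > 16) {
    double cw = L / ncell;
    std::vector<std::vector<int> > cells(ncell);
    std::vector<int> ci(N);
    for (int i = 0; i < N; i++) {
      int c = (int)(x[i] / cw);
      if (c >= ncell) c = ncell - 1;
      if (c < 0) c = 0;
      ci[i] = c;
      cells[c].push_back(i);
    }
    for (int i = 0; i < N; i++) {
      int c = ci[i];
      for (int dc = -1; dc <= 1; dc++) {
        int cc = (c + dc + ncell) % ncell;
        const std::vector<int>& cell = cells[cc];
        for (size_t k = 0; k < cell.size(); k++) {
          int j = cell[k];
          if (j == i) continue;
          if (mov && !(*mov)[j]) continue;
          if (ring_dist(x[i], x[j], L) <= delta) { sum[i] += u[j]; cnt[i]++; }
        }
      }
    }
  } else {
    for (int i = 0; i < N; i++)
      for (int j = 0; j < N; j++) {
        if (j == i) continue;
        if (mov && !(*mov)[j]) continue;
        if (ring_dist(x[i], x[j], L) <= delta) { sum[i] += u[j]; cnt[i]++; }
      }
  }
}

static inline double draw_xi(bool noise_uniform, double sigma, double half) {
  return noise_uniform ? R::runif(-half, half) : R::rnorm(0.0, sigma);
}

// Synchronous / asynchronous alignment family.
// model: 0 = czirok, 1 = individual_choice, 2 = buhl.
// Draw protocol per synchronous step: N choice uniforms, then (single-neighbour
// mode only) N pick uniforms, then N noise variates, all in particle order.
// Every model in the family consumes the same blocks so that different models
// can be coupled on a common random-number stream.
// [[Rcpp::export]]
List sim_align_cpp(NumericVector x0, NumericVector u0,
                   double L, double v, double delta, double dt,
                   double sigma, bool noise_uniform,
                   int model, double alpha,
                   bool async, bool single_neighbor,
                   int n_steps, int sample_every, bool store_states) {
  const int N = x0.size();
  const double half = sigma * std::sqrt(3.0); // eta/2 for U[-eta/2, eta/2]
  const double sqdt = std::sqrt(dt);
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end());
  std::vector<double> xn(N), un(N), sum(N), m(N), choice(N), pick(N), xi(N);
  std::vector<int> cnt(N), nbr;

  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sphi(n_samp);
  NumericMatrix sx, su;
  if (store_states) { sx = NumericMatrix(n_samp, N); su = NumericMatrix(n_samp, N); }
  int isamp = 0;
  double t = 0.0;
  {
    double s = 0.0; for (int i = 0; i < N; i++) s += u[i];
    st[0] = 0.0; sphi[0] = s / N;
    if (store_states) for (int i = 0; i < N; i++) { sx(0, i) = x[i]; su(0, i) = u[i]; }
    isamp = 1;
  }

  for (int step = 1; step <= n_steps; step++) {
    if (!async) {
      for (int i = 0; i < N; i++) choice[i] = unif_rand();
      if (single_neighbor) for (int i = 0; i < N; i++) pick[i] = unif_rand();
      for (int i = 0; i < N; i++) xi[i] = draw_xi(noise_uniform, sigma, half);
      if (!single_neighbor) {
        neighbour_sums(x, u, NULL, L, delta, sum, cnt);
        for (int i = 0; i < N; i++) {
          if (model == 2) m[i] = (cnt[i] > 0) ? sum[i] / cnt[i] : 0.0;
          else            m[i] = (sum[i] + u[i]) / (cnt[i] + 1);
        }
      } else {
        for (int i = 0; i < N; i++) {
          nbr.clear();
          for (int j = 0; j < N; j++)
            if (j != i && ring_dist(x[i], x[j], L) <= delta) nbr.push_back(j);
          if (nbr.empty()) m[i] = (model == 2) ? 0.0 : u[i];
          else m[i] = u[nbr[(int)std::floor(pick[i] * nbr.size())]];
        }
      }
      for (int i = 0; i < N; i++) {
        xn[i] = wrapL(x[i] + v * u[i] * dt, L);
        if (model == 1 && choice[i] < alpha)
          un[i] = u[i];                                      // retain exactly
        else if (model == 2)
          un[i] = alpha * u[i] + (1.0 - alpha) * gfun(m[i]) + xi[i];
        else
          un[i] = u[i] + (gfun(m[i]) - u[i]) * dt + sqdt * xi[i];
      }
      x.swap(xn); u.swap(un);
    } else {
      // Asynchronous: N sequential sub-updates of randomly chosen particles.
      // Draw order per sub-update: index, choice, [pick if neighbours], noise.
      for (int k = 0; k < N; k++) {
        int i = (int)std::floor(unif_rand() * N); if (i >= N) i = N - 1;
        double ch = unif_rand();
        double mi;
        if (!single_neighbor) {
          double s = 0.0; int c = 0;
          for (int j = 0; j < N; j++)
            if (j != i && ring_dist(x[i], x[j], L) <= delta) { s += u[j]; c++; }
          if (model == 2) mi = (c > 0) ? s / c : 0.0;
          else            mi = (s + u[i]) / (c + 1);
        } else {
          nbr.clear();
          for (int j = 0; j < N; j++)
            if (j != i && ring_dist(x[i], x[j], L) <= delta) nbr.push_back(j);
          if (nbr.empty()) mi = (model == 2) ? 0.0 : u[i];
          else mi = u[nbr[(int)std::floor(unif_rand() * nbr.size())]];
        }
        double z = draw_xi(noise_uniform, sigma, half);
        x[i] = wrapL(x[i] + v * u[i] * dt, L);
        if (model == 1 && ch < alpha) { /* retain exactly */ }
        else if (model == 2) u[i] = alpha * u[i] + (1.0 - alpha) * gfun(mi) + z;
        else u[i] = u[i] + (gfun(mi) - u[i]) * dt + sqdt * z;
      }
    }
    t += dt;
    if (step % sample_every == 0) {
      double s = 0.0; for (int i = 0; i < N; i++) s += u[i];
      st[isamp] = t; sphi[isamp] = s / N;
      if (store_states) for (int i = 0; i < N; i++) { sx(isamp, i) = x[i]; su(isamp, i) = u[i]; }
      isamp++;
    }
  }

  List out = List::create(_["t"] = st, _["phi"] = sphi);
  if (store_states) { out["x"] = sx; out["u"] = su; }
  return out;
}

// One-dimensional three-zone model, asynchronous by construction.
// Per time step: N sub-updates; each draws a particle index, and, if that
// particle has neighbours within delta, a neighbour index.
// [[Rcpp::export]]
List sim_bode_cpp(NumericVector x0, NumericVector u0,
                  double L, double v, double delta, double r2, double dt,
                  int n_steps, int sample_every, bool store_states) {
  const int N = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end());
  std::vector<int> nbr;
  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sphi(n_samp);
  NumericMatrix sx, su;
  if (store_states) { sx = NumericMatrix(n_samp, N); su = NumericMatrix(n_samp, N); }
  int isamp = 0; double t = 0.0;
  {
    double s = 0.0; for (int i = 0; i < N; i++) s += u[i];
    st[0] = 0.0; sphi[0] = s / N;
    if (store_states) for (int i = 0; i < N; i++) { sx(0, i) = x[i]; su(0, i) = u[i]; }
    isamp = 1;
  }
  for (int step = 1; step <= n_steps; step++) {
    for (int k = 0; k < N; k++) {
      int i = (int)std::floor(unif_rand() * N); if (i >= N) i = N - 1;
      nbr.clear();
      for (int j = 0; j < N; j++)
        if (j != i && ring_dist(x[i], x[j], L) <= delta) nbr.push_back(j);
      if (!nbr.empty()) {
        int kk = nbr[(int)std::floor(unif_rand() * nbr.size())];
        double d = ring_dist(x[i], x[kk], L);
        if (d <= r2) {
          u[i] = gfun(u[kk]);
        } else {
          double dx = ring_disp(x[i], x[kk], L);
          double s = (dx > 0) - (dx < 0);
          u[i] = gfun(s * (d - r2) / (delta - r2));
        }
      }
      x[i] = wrapL(x[i] + v * u[i] * dt, L);
    }
    t += dt;
    if (step % sample_every == 0) {
      double s = 0.0; for (int i = 0; i < N; i++) s += u[i];
      st[isamp] = t; sphi[isamp] = s / N;
      if (store_states) for (int i = 0; i < N; i++) { sx(isamp, i) = x[i]; su(isamp, i) = u[i]; }
      isamp++;
    }
  }
  List out = List::create(_["t"] = st, _["phi"] = sphi);
  if (store_states) { out["x"] = sx; out["u"] = su; }
  return out;
}

// Pause-and-go model. Draw protocol per step: N event uniforms (stop/start
// tests), N alignment-choice uniforms, N noise variates, in particle order.
// Transition probabilities use the exact exponential mapping 1 - exp(-k dt).
// Headings update only at stand->walk transitions (or every step for walkers
// when realign is TRUE); particles moving after the transition advance.
// [[Rcpp::export]]
List sim_png_cpp(NumericVector x0, NumericVector u0, LogicalVector mov0,
                 double L, double v, double delta, double dt,
                 double sigma, bool noise_uniform,
                 double k_walk, double k_stand0, double k_stand1,
                 int n_c_moving, double a0, double a1, bool realign,
                 int n_steps, int sample_every, bool store_states) {
  const int N = x0.size();
  const double half = sigma * std::sqrt(3.0);
  const double sqdt = std::sqrt(dt);
  const double p_stop = 1.0 - std::exp(-k_walk * dt);
  const double p_start0 = 1.0 - std::exp(-k_stand0 * dt);
  const double p_start1 = 1.0 - std::exp(-k_stand1 * dt);
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end());
  std::vector<char> mov(N), movn(N);
  for (int i = 0; i < N; i++) mov[i] = mov0[i] ? 1 : 0;
  std::vector<double> sum(N), ev(N), ch(N), xi(N);
  std::vector<int> cnt(N);

  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sphi(n_samp), sphim(n_samp);
  IntegerVector snm(n_samp);
  NumericMatrix sx, su;
  LogicalMatrix sm;
  if (store_states) {
    sx = NumericMatrix(n_samp, N); su = NumericMatrix(n_samp, N);
    sm = LogicalMatrix(n_samp, N);
  }
  int isamp = 0; double t = 0.0;

  // record a sample of the current state
  #define PNG_RECORD do { \
    double sa = 0.0, smv = 0.0; int nm = 0; \
    for (int i = 0; i < N; i++) { sa += u[i]; if (mov[i]) { smv += u[i]; nm++; } } \
    st[isamp] = t; sphi[isamp] = sa / N; \
    sphim[isamp] = (nm > 0) ? smv / nm : 0.0; snm[isamp] = nm; \
    if (store_states) for (int i = 0; i < N; i++) { \
      sx(isamp, i) = x[i]; su(isamp, i) = u[i]; sm(isamp, i) = (bool)mov[i]; } \
    isamp++; \
  } while (0)

  PNG_RECORD;

  for (int step = 1; step <= n_steps; step++) {
    neighbour_sums(x, u, &mov, L, delta, sum, cnt);
    for (int i = 0; i < N; i++) ev[i] = unif_rand();
    for (int i = 0; i < N; i++) ch[i] = unif_rand();
    for (int i = 0; i < N; i++) xi[i] = draw_xi(noise_uniform, sigma, half);
    for (int i = 0; i < N; i++) {
      if (mov[i]) movn[i] = (ev[i] < p_stop) ? 0 : 1;
      else {
        double ps = (cnt[i] >= n_c_moving) ? p_start1 : p_start0;
        movn[i] = (ev[i] < ps) ? 1 : 0;
      }
      bool starter = (!mov[i] && movn[i]) || (realign && mov[i] && movn[i]);
      if (starter) {
        double mi = (cnt[i] > 0) ? sum[i] / cnt[i] : 0.0;
        double a = a0 + a1 * std::fabs(mi);
        if (a < 0.0) a = 0.0;
        if (a > 1.0) a = 1.0;
        if (ch[i] < a) u[i] = u[i] + (gfun(mi) - u[i]) * dt + sqdt * xi[i];
        else u[i] = u[i] + sqdt * xi[i];
      }
      if (movn[i]) x[i] = wrapL(x[i] + v * u[i] * dt, L);
    }
    mov.swap(movn);
    t += dt;
    if (step % sample_every == 0) PNG_RECORD;
  }
  #undef PNG_RECORD

  List out = List::create(_["t"] = st, _["phi"] = sphi,
                          _["phi_moving"] = sphim, _["n_moving"] = snm);
  if (store_states) { out["x"] = sx; out["u"] = su; out["moving"] = sm; }
  return out;
}

// Escape-and-pursuit social force for one particle, 2D periodic box.
// Strict Heaviside gates (H(0) = 0): pursuit collects front & receding
// neighbours, escape collects back & approaching ones; each class is
// normalised by its own count.
static void ep_force(const std::vector<double>& px, const std::vector<double>& py,
                     const std::vector<double>& vx, const std::vector<double>& vy,
                     int i, double box, double Rint, double chie, double chip,
                     double& fx, double& fy) {
  const int N = (int)px.size();
  double sex = 0, sey = 0, spx = 0, spy = 0;
  int ne = 0, np = 0;
  for (int j = 0; j < N; j++) {
    if (j == i) continue;
    double dx = ring_disp(px[i], px[j], box);
    double dy = ring_disp(py[i], py[j], box);
    double r = std::sqrt(dx * dx + dy * dy);
    if (r == 0.0 || r > Rint) continue;
    double rhx = dx / r, rhy = dy / r;
    double pu = vx[i] * rhx + vy[i] * rhy;              // front (>0) / behind (<0)
    double pdu = (vx[j] - vx[i]) * rhx + (vy[j] - vy[i]) * rhy; // receding (>0) / approaching (<0)
    if (pu > 0.0 && pdu > 0.0) { spx += pdu * rhx; spy += pdu * rhy; np++; }
    else if (pu < 0.0 && pdu < 0.0) { sex += pdu * rhx; sey += pdu * rhy; ne++; }
  }
  fx = 0.0; fy = 0.0;
  if (np > 0) { fx += chip * spx / np; fy += chip * spy / np; }
  if (ne > 0) { fx += chie * sex / ne; fy += chie * sey / ne; }
}

// [[Rcpp::export]]
List sim_ep_cpp(NumericVector px0, NumericVector py0,
                NumericVector vx0, NumericVector vy0,
                double box, double v, double gamma, double D,
                double chie, double chip, double Rint, double dt,
                int n_steps, int sample_every, bool store_states) {
  const int N = px0.size();
  const double sq = std::sqrt(2.0 * D * dt);
  std::vector<double> px(px0.begin(), px0.end()), py(py0.begin(), py0.end());
  std::vector<double> vx(vx0.begin(), vx0.end()), vy(vy0.begin(), vy0.end());
  std::vector<double> fx(N), fy(N);
  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sux(n_samp), suy(n_samp);
  NumericMatrix spx, spy, svx, svy;
  if (store_states) {
    spx = NumericMatrix(n_samp, N); spy = NumericMatrix(n_samp, N);
    svx = NumericMatrix(n_samp, N); svy = NumericMatrix(n_samp, N);
  }
  int isamp = 0; double t = 0.0;
  #define EP_RECORD do { \
    double ax = 0, ay = 0; \
    for (int i = 0; i < N; i++) { ax += vx[i]; ay += vy[i]; } \
    st[isamp] = t; sux[isamp] = ax / N; suy[isamp] = ay / N; \
    if (store_states) for (int i = 0; i < N; i++) { \
      spx(isamp, i) = px[i]; spy(isamp, i) = py[i]; \
      svx(isamp, i) = vx[i]; svy(isamp, i) = vy[i]; } \
    isamp++; \
  } while (0)
  EP_RECORD;
  for (int step = 1; step <= n_steps; step++) {
    for (int i = 0; i < N; i++)
      ep_force(px, py, vx, vy, i, box, Rint, chie, chip, fx[i], fy[i]);
    for (int i = 0; i < N; i++) {
      double nx = norm_rand(), ny = norm_rand();
      double ux = vx[i], uy = vy[i];
      px[i] = wrapL(px[i] + v * ux * dt, box);
      py[i] = wrapL(py[i] + v * uy * dt, box);
      vx[i] = ux + (-gamma * ux + fx[i]) * dt + sq * nx;
      vy[i] = uy + (-gamma * uy + fy[i]) * dt + sq * ny;
    }
    t += dt;
    if (step % sample_every == 0) EP_RECORD;
  }
  #undef EP_RECORD
  List out = List::create(_["t"] = st, _["phi_x"] = sux, _["phi_y"] = suy);
  if (store_states) {
    out["x"] = spx; out["y"] = spy; out["ux"] = svx; out["uy"] = svy;
  }
  return out;
}

// 1D escape-and-pursuit force on the ring (diagnostic variant).
static double ep_force_1d(const std::vector<double>& x, const std::vector<double>& u,
                          int i, double L, double Rint, double chie, double chip) {
  const int N = (int)x.size();
  double se = 0, sp = 0; int ne = 0, np = 0;
  for (int j = 0; j < N; j++) {
    if (j == i) continue;
    double dx = ring_disp(x[i], x[j], L);
    double r = std::fabs(dx);
    if (r == 0.0 || r > Rint) continue;
    double rh = (dx > 0) ? 1.0 : -1.0;
    double pu = u[i] * rh;
    double pdu = (u[j] - u[i]) * rh;
    if (pu > 0.0 && pdu > 0.0) { sp += pdu * rh; np++; }
    else if (pu < 0.0 && pdu < 0.0) { se += pdu * rh; ne++; }
  }
  double f = 0.0;
  if (np > 0) f += chip * sp / np;
  if (ne > 0) f += chie * se / ne;
  return f;
}

// [[Rcpp::export]]
List sim_ep1d_cpp(NumericVector x0, NumericVector u0,
                  double L, double v, double gamma, double D,
                  double chie, double chip, double Rint, double dt,
                  int n_steps, int sample_every, bool store_states) {
  const int N = x0.size();
  const double sq = std::sqrt(2.0 * D * dt);
  std::vector<double> x(x0.begin(), x0.end()), u(u0.begin(), u0.end());
  std::vector<double> f(N);
  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sphi(n_samp);
  NumericMatrix sx, su;
  if (store_states) { sx = NumericMatrix(n_samp, N); su = NumericMatrix(n_samp, N); }
  int isamp = 0; double t = 0.0;
  {
    double s = 0; for (int i = 0; i < N; i++) s += u[i];
    st[0] = 0.0; sphi[0] = s / N;
    if (store_states) for (int i = 0; i < N; i++) { sx(0, i) = x[i]; su(0, i) = u[i]; }
    isamp = 1;
  }
  for (int step = 1; step <= n_steps; step++) {
    for (int i = 0; i < N; i++) f[i] = ep_force_1d(x, u, i, L, Rint, chie, chip);
    for (int i = 0; i < N; i++) {
      double z = norm_rand();
      double ui = u[i];
      x[i] = wrapL(x[i] + v * ui * dt, L);
      u[i] = ui + (-gamma * ui + f[i]) * dt + sq * z;
    }
    t += dt;
    if (step % sample_every == 0) {
      double s = 0; for (int i = 0; i < N; i++) s += u[i];
      st[isamp] = t; sphi[isamp] = s / N;
      if (store_states) for (int i = 0; i < N; i++) { sx(isamp, i) = x[i]; su(isamp, i) = u[i]; }
      isamp++;
    }
  }
  List out = List::create(_["t"] = st, _["phi"] = sphi);
  if (store_states) { out["x"] = sx; out["u"] = su; }
  return out;
}

// Euler-Maruyama path of d phi = F(phi) dt + sqrt(2 D(phi)) dW for the named
// drift families used as estimator oracles.
// drift kinds: 0 zero, 1 constant(c), 2 ou(theta): -theta*phi,
//              3 double_well(a, b): a*phi - b*phi^3.
// diffusion: constant D0 (0 allowed).
// [[Rcpp::export]]
List synth_sde_cpp(int drift_kind, NumericVector dpar, double D0,
                   double phi0, int n_steps, double dt, int sample_every) {
  double phi = phi0;
  const double sq = std::sqrt(2.0 * D0 * dt);
  const int n_samp = n_steps / sample_every + 1;
  NumericVector st(n_samp), sphi(n_samp);
  st[0] = 0.0; sphi[0] = phi;
  int isamp = 1; double t = 0.0;
  for (int step = 1; step <= n_steps; step++) {
    double F;
    switch (drift_kind) {
      case 1: F = dpar[0]; break;
      case 2: F = -dpar[0] * phi; break;
      case 3: F = dpar[0] * phi - dpar[1] * phi * phi * phi; break;
      default: F = 0.0;
    }
    double z = (D0 > 0.0) ? norm_rand() : 0.0;
    phi += F * dt + sq * z;
    t += dt;
    if (step % sample_every == 0) { st[isamp] = t; sphi[isamp] = phi; isamp++; }
  }
  return List::create(_["t"] = st, _["phi"] = sphi);
}
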