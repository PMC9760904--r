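// Time integration engine for the subcellular-element crawling-cell model.
//
// Per Euler step (explicit, time increment dt):
//   1. driver update: either the prescribed traveling wave (concentration,
//      two-state friction) or one reaction-diffusion step with the MPS
//      Laplacian plus the stimulus schedule,
//   2. coupling update: actuator elongations from the chemical field and,
//      for the RD driver, relaxation of the stick-slip friction,
//   3. conservative forces (bond springs + triangle-area penalty),
//   4. velocity solve of [diag(zeta) + xi W] v = F per component,
//   5. position update r += v dt.
//
// The velocity system is symmetric positive definite with a fixed sparsity
// pattern; it is solved by Jacobi-preconditioned conjugate gradients warm
// started from the previous step's velocities (relative residual 1e-12),
// with a dense direct solve as fallback.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

namespace {

struct Graph {
  int N, E;
  std::vector<int> bi, bj;        // bond endpoints (0-based)
  std::vector<double> rest;       // bond rest lengths
  std::vector<double> wdiag;      // xi * sum of incident rest lengths
  std::vector<std::vector<std::pair<int, double>>> adj; // (j, xi*l_ij)
};

void matvec(const Graph& g, const std::vector<double>& zeta,
            const std::vector<double>& x, std::vector<double>& y) {
  for (int i = 0; i < g.N; ++i) {
    double s = (zeta[i] + g.wdiag[i]) * x[i];
    for (auto& e : g.adj[i]) s -= e.second * x[e.first];
    y[i] = s;
  }
}

// Jacobi-PCG; returns relative residual achieved. x is the warm start.
double pcg(const Graph& g, const std::vector<double>& zeta,
           const std::vector<double>& b, std::vector<double>& x,
           double rtol, int maxit) {
  const int N = g.N;
  std::vector<double> r(N), z(N), p(N), Ap(N);
  double bnorm = 0;
  for (int i = 0; i < N; ++i) bnorm += b[i] * b[i];
  bnorm = std::sqrt(bnorm);
  if (bnorm == 0) { std::fill(x.begin(), x.end(), 0.0); return 0.0; }
  matvec(g, zeta, x, Ap);
  double rnorm2 = 0;
  for (int i = 0; i < N; ++i) { r[i] = b[i] - Ap[i]; rnorm2 += r[i] * r[i]; }
  double target = rtol * bnorm;
  if (std::sqrt(rnorm2) <= target) return std::sqrt(rnorm2) / bnorm;
  double rz = 0;
  for (int i = 0; i < N; ++i) {
    z[i] = r[i] / (zeta[i] + g.wdiag[i]);
    rz += r[i] * z[i];
    p[i] = z[i];
  }
  for (int it = 0; it < maxit; ++it) {
    matvec(g, zeta, p, Ap);
    double pAp = 0;
    for (int i = 0; i < N; ++i) pAp += p[i] * Ap[i];
    if (pAp <= 0) break;
    double alpha = rz / pAp;
    rnorm2 = 0;
    for (int i = 0; i < N; ++i) {
      x[i] += alpha * p[i];
      r[i] -= alpha * Ap[i];
      rnorm2 += r[i] * r[i];
    }
    if (std::sqrt(rnorm2) <= target) return std::sqrt(rnorm2) / bnorm;
    double rz_new = 0;
    for (int i = 0; i < N; ++i) {
      z[i] = r[i] / (zeta[i] + g.wdiag[i]);
      rz_new += r[i] * z[i];
    }
    double beta = rz_new / rz;
    rz = rz_new;
    for (int i = 0; i < N; ++i) p[i] = z[i] + beta * p[i];
  }
  return std::sqrt(rnorm2) / bnorm;
}

void solve_direct(const Graph& g, const std::vector<double>& zeta,
                  const std::vector<double>& fx, const std::vector<double>& fy,
                  std::vector<double>& vx, std::vector<double>& vy) {
  arma::mat A(g.N, g.N, arma::fill::zeros);
  for (int i = 0; i < g.N; ++i) {
    A(i, i) = zeta[i] + g.wdiag[i];
    for (auto& e : g.adj[i]) A(i, e.first) = -e.second;
  }
  arma::vec bx(g.N), by(g.N);
  for (int i = 0; i < g.N; ++i) { bx(i) = fx[i]; by(i) = fy[i]; }
  arma::vec sx = arma::solve(A, bx, arma::solve_opts::likely_sympd);
  arma::vec sy = arma::solve(A, by, arma::solve_opts::likely_sympd);
  for (int i = 0; i < g.N; ++i) { vx[i] = sx(i); vy[i] = sy(i); }
}

// exact = true forces the dense direct solve (used at snapshot steps so the
// recorded states carry the force-free identity to machine precision)
void solve_velocities_step(const Graph& g, const std::vector<double>& zeta,
                           const std::vector<double>& fx,
                           const std::vector<double>& fy,
                           std::vector<double>& vx, std::vector<double>& vy,
                           bool exact) {
  if (exact) { solve_direct(g, zeta, fx, fy, vx, vy); return; }
  double r1 = pcg(g, zeta, fx, vx, 1e-12, 40 * g.N);
  double r2 = pcg(g, zeta, fy, vy, 1e-12, 40 * g.N);
  if (r1 > 1e-10 || r2 > 1e-10) solve_direct(g, zeta, fx, fy, vx, vy);
}

inline double h_zeta_f(double z, double zsl, double zst, double eps) {
  return -0.5 * std::tanh((z - zst) / eps) - 0.5 * std::tanh((z - zsl) / eps);
}
inline double h_v_f(double v, double vstar) {
  double s2 = (v / vstar) * (v / vstar);
  return s2 / (1 + s2) - 0.5;
}
inline double h_V_f(double V, double sigmaV, double Vstar) {
  return 0.5 * std::tanh(sigmaV * (V - Vstar));
}

} // namespace

// [[Rcpp::export]]
List cpp_simulate(NumericMatrix pos0, IntegerMatrix bonds, NumericVector rest,
                  IntegerMatrix tris, List par) {
  const int N = pos0.nrow(), E = bonds.nrow(), F = tris.nrow();

  // mechanics
  const double kappa = par["kappa"], xi = par["xi"];
  const double sigma_area = par["sigma_area"];
  const double zeta_slip = par["zeta_slip"], zeta_stick = par["zeta_stick"];
  // integration
  const double dt = par["dt"];
  const long n_steps = (long)(double)par["n_steps"];
  const int stride_steps = par["stride_steps"];
  const int neighbor_every = par["neighbor_every"];
  // driver: 0 = prescribed wave, 1 = reaction-diffusion
  const int driver = par["driver"];
  const int activator0 = par["activator"];          // 0-based
  const bool uniform_zeta = par["uniform_zeta"];
  // wave driver
  const double c0 = par["c0"], omega = par["omega"], qw = par["qw"];
  const double psi_zeta = par["psi_zeta"];
  const double wave_sign = par["wave_sign"];        // +1 leftward, -1 literal
  NumericVector ell_amp = par["ell_amp"];           // per-bond l_V or l_c
  // RD driver
  const double DU = par["D_U"], DV = par["D_V"];
  const double alpha = par["alpha"], beta = par["beta"];
  const double KK = par["K_K"], KP = par["K_P"];
  const double Sprod = par["S"], gamma_ = par["gamma"], mu = par["mu"];
  const double re = par["r_e"], lambda = par["lambda"];
  const double I_excite = par["I_excite"];
  const int stim_mode = par["stim_mode"];           // 0 periodic, 1 random, 2 none
  const double stim_interval = par["stim_interval"];
  // coupling (RD driver)
  const double a_sens = par["a"], Av = par["A_v"], tau_zeta = par["tau_zeta"];
  const double eps_zeta = par["eps_zeta"], vstar = par["v_star"];
  const double sigmaV = par["sigma_V"], Vstar = par["V_star"];
  const double zeta0 = par["zeta_init_value"];

  Graph g;
  g.N = N; g.E = E;
  g.bi.resize(E); g.bj.resize(E); g.rest.resize(E);
  g.wdiag.assign(N, 0.0); g.adj.assign(N, {});
  for (int e = 0; e < E; ++e) {
    g.bi[e] = bonds(e, 0); g.bj[e] = bonds(e, 1); g.rest[e] = rest[e];
    double w = xi * rest[e];
    g.adj[g.bi[e]].push_back({g.bj[e], w});
    g.adj[g.bj[e]].push_back({g.bi[e], w});
    g.wdiag[g.bi[e]] += w; g.wdiag[g.bj[e]] += w;
  }

  std::vector<double> px(N), py(N);
  for (int i = 0; i < N; ++i) { px[i] = pos0(i, 0); py[i] = pos0(i, 1); }
  std::vector<double> vx_prev(N, 0.0), vy_prev(N, 0.0);
  std::vector<double> U(N, Sprod / gamma_), V(N, 0.0);
  std::vector<double> zeta(N, uniform_zeta ? zeta_stick : zeta0);
  std::vector<double> vx(N, 0.0), vy(N, 0.0);
  std::vector<double> fx(N), fy(N), ell_act(E, 0.0);
  std::vector<double> conc(N, 0.0);                  // wave concentration

  // rest triangle areas (for collapse warning threshold)
  std::vector<int> t1v(F), t2v(F), t3v(F);
  for (int f = 0; f < F; ++f) { t1v[f] = tris(f,0); t2v[f] = tris(f,1); t3v[f] = tris(f,2); }

  // MPS neighbor pairs (rebuilt every neighbor_every steps)
  std::vector<int> nb_i, nb_j;
  std::vector<double> wpair, ndens(N);
  auto rebuild_neighbors = [&]() {
    nb_i.clear(); nb_j.clear();
    const double margin = 1.2 * re;   // margin so pairs drifting in are caught
    for (int i = 0; i < N; ++i)
      for (int j = i + 1; j < N; ++j) {
        double dx = px[j] - px[i], dy = py[j] - py[i];
        if (dx * dx + dy * dy < margin * margin) { nb_i.push_back(i); nb_j.push_back(j); }
      }
  };

  const int n_snap = (int)(n_steps / stride_steps) + 1;
  NumericVector times(n_snap);
  NumericMatrix X(n_snap, N), Y(n_snap, N), Uo(n_snap, N), Vo(n_snap, N),
                Zo(n_snap, N), TX(n_snap, N), TY(n_snap, N);
  NumericMatrix com(n_snap, 2);
  NumericVector mono_abs(n_snap), trac_scale(n_snap),
                torque_abs(n_snap), torque_scale(n_snap);
  int snap = 0;
  bool aborted = false;
  std::string abort_msg = "";

  const long stim_steps = stim_mode == 2 ? 0 :
    std::max(1L, (long)std::llround(stim_interval / dt));

  for (long step = 0; step <= n_steps; ++step) {   // inclusive: final snapshot at t = n_steps*dt
    const double t = step * dt;

    // --- 1. driver -------------------------------------------------------
    if (driver == 0) {                             // prescribed wave
      const double xstar = px[activator0];
      for (int i = 0; i < N; ++i) {
        double phi = omega * t + wave_sign * qw * (px[i] - xstar);
        conc[i] = c0 * (1.0 - std::cos(phi));
        if (!uniform_zeta) {
          double arg = (phi - psi_zeta) / (2 * M_PI);
          double frac = 2 * M_PI * (arg - std::floor(arg));
          zeta[i] = (frac > 0 && frac <= M_PI) ? zeta_slip : zeta_stick;
        }
      }
      for (int e = 0; e < E; ++e)
        ell_act[e] = ell_amp[e] * 0.5 * (conc[g.bi[e]] + conc[g.bj[e]]);
    } else {                                       // reaction-diffusion
      if (stim_mode != 2 && step % stim_steps == 0) {
        int el = activator0;
        if (stim_mode == 1) {
          el = (int)std::floor(unif_rand() * N);
          if (el >= N) el = N - 1;
        }
        U[el] -= I_excite; V[el] += I_excite;
      }
      if (step % neighbor_every == 0) rebuild_neighbors();
      // MPS weights and number densities from current positions
      const size_t P = nb_i.size();
      wpair.assign(P, 0.0);
      std::fill(ndens.begin(), ndens.end(), 0.0);
      for (size_t p = 0; p < P; ++p) {
        int i = nb_i[p], j = nb_j[p];
        double dx = px[j] - px[i], dy = py[j] - py[i];
        double r = std::sqrt(dx * dx + dy * dy);
        if (r > 0 && r < re) {
          double w = re / r - 1.0;
          wpair[p] = w; ndens[i] += w; ndens[j] += w;
        }
      }
      double meanU = 0, meanV2 = 0;
      for (int i = 0; i < N; ++i) { meanU += U[i]; meanV2 += V[i] * V[i]; }
      meanU /= N; meanV2 /= N;
      std::vector<double> dU(N, 0.0), dV(N, 0.0);
      const double fac = 4.0 / lambda;
      for (size_t p = 0; p < P; ++p) {
        if (wpair[p] == 0) continue;
        int i = nb_i[p], j = nb_j[p];
        double nij = 0.5 * (ndens[i] + ndens[j]);
        double k = fac * wpair[p] / nij;
        dU[i] += k * (U[j] - U[i]); dU[j] += k * (U[i] - U[j]);
        dV[i] += k * (V[j] - V[i]); dV[j] += k * (V[i] - V[j]);
      }
      for (int i = 0; i < N; ++i) {
        if (ndens[i] == 0) {
          aborted = true;
          abort_msg = "isolated element in MPS kernel: " + std::to_string(i + 1);
          break;
        }
        double ex = alpha * U[i] * V[i] * V[i] / (KK + meanV2)
                  - beta * U[i] * V[i] / (KP + meanU);
        double GU = -ex + Sprod - gamma_ * U[i];
        double GV =  ex - mu * V[i];
        dU[i] = dt * (DU * dU[i] + GU);
        dV[i] = dt * (DV * dV[i] + GV);
      }
      if (aborted) break;
      for (int i = 0; i < N; ++i) { U[i] += dU[i]; V[i] += dV[i]; }

      // --- 2. coupling: actuator + friction relaxation -------------------
      for (int e = 0; e < E; ++e)
        ell_act[e] = ell_amp[e] * std::tanh(a_sens * 0.5 * (V[g.bi[e]] + V[g.bj[e]]));
      if (!uniform_zeta) {
        for (int i = 0; i < N; ++i) {
          double speed = std::sqrt(vx[i] * vx[i] + vy[i] * vy[i]);
          double dz = (h_zeta_f(zeta[i], zeta_slip, zeta_stick, eps_zeta)
                       - Av * h_v_f(speed, vstar)
                       - (1 - Av) * h_V_f(V[i], sigmaV, Vstar)) / tau_zeta;
          zeta[i] += dt * dz;
          if (zeta[i] < 0.5 * zeta_slip) zeta[i] = 0.5 * zeta_slip;
          if (zeta[i] > 2.0 * zeta_stick) zeta[i] = 2.0 * zeta_stick;
        }
      }
    }

    // --- 3. conservative forces -----------------------------------------
    std::fill(fx.begin(), fx.end(), 0.0);
    std::fill(fy.begin(), fy.end(), 0.0);
    for (int e = 0; e < E; ++e) {
      int i = g.bi[e], j = g.bj[e];
      double dx = px[j] - px[i], dy = py[j] - py[i];
      double r = std::sqrt(dx * dx + dy * dy);
      // strain-normalized spring: constant kappa / l_ij (actuator shifts the free length)
      double fmag = kappa / g.rest[e] * (r - g.rest[e] - ell_act[e]) / r;
      fx[i] += fmag * dx; fy[i] += fmag * dy;
      fx[j] -= fmag * dx; fy[j] -= fmag * dy;
    }
    if (sigma_area > 0) {
      for (int f = 0; f < F; ++f) {
        int i = t1v[f], j = t2v[f], k = t3v[f];
        double S = 0.5 * ((px[j] - px[i]) * (py[k] - py[i])
                        - (px[k] - px[i]) * (py[j] - py[i]));
        if (std::abs(S) < 1e-8) {
          aborted = true;
          abort_msg = "degenerate triangle " + std::to_string(f + 1);
          break;
        }
        double coef = 2.0 * sigma_area / (S * S * S);
        fx[i] += coef * 0.5 * (py[j] - py[k]);
        fy[i] += coef * 0.5 * (px[k] - px[j]);
        fx[j] += coef * 0.5 * (py[k] - py[i]);
        fy[j] += coef * 0.5 * (px[i] - px[k]);
        fx[k] += coef * 0.5 * (py[i] - py[j]);
        fy[k] += coef * 0.5 * (px[j] - px[i]);
      }
      if (aborted) break;
    }

    // --- 4. velocity solve ----------------------------------------------
    // warm start: linear extrapolation from the two previous solutions
    for (int i = 0; i < N; ++i) {
      double ex = 2 * vx[i] - vx_prev[i], ey = 2 * vy[i] - vy_prev[i];
      vx_prev[i] = vx[i]; vy_prev[i] = vy[i];
      vx[i] = ex; vy[i] = ey;
    }
    solve_velocities_step(g, zeta, fx, fy, vx, vy,
                          step % stride_steps == 0);

    // --- snapshot --------------------------------------------------------
    if (step % stride_steps == 0 && snap < n_snap) {
      double cx = 0, cy = 0;
      for (int i = 0; i < N; ++i) { cx += px[i]; cy += py[i]; }
      cx /= N; cy /= N;
      double sfx = 0, sfy = 0, sabs = 0, storq = 0, sscale = 0;
      for (int i = 0; i < N; ++i) {
        double tx = zeta[i] * vx[i], ty = zeta[i] * vy[i];
        double rxc = px[i] - cx, ryc = py[i] - cy;
        sfx += tx; sfy += ty;
        sabs += std::sqrt(tx * tx + ty * ty);
        storq += rxc * ty - ryc * tx;
        sscale += std::sqrt(rxc * rxc + ryc * ryc) * std::sqrt(tx * tx + ty * ty);
        X(snap, i) = px[i]; Y(snap, i) = py[i];
        Uo(snap, i) = driver == 0 ? conc[i] : U[i];
        Vo(snap, i) = driver == 0 ? conc[i] : V[i];
        Zo(snap, i) = zeta[i];
        TX(snap, i) = tx; TY(snap, i) = ty;
      }
      times[snap] = t;
      com(snap, 0) = cx; com(snap, 1) = cy;
      mono_abs[snap] = std::sqrt(sfx * sfx + sfy * sfy);
      trac_scale[snap] = sabs;
      torque_abs[snap] = std::abs(storq);
      torque_scale[snap] = sscale;
      ++snap;
    }

    // --- 5. position update ---------------------------------------------
    bool bad = false;
    for (int i = 0; i < N; ++i) {
      px[i] += vx[i] * dt; py[i] += vy[i] * dt;
      if (!std::isfinite(px[i]) || !std::isfinite(py[i]) ||
          !std::isfinite(U[i]) || !std::isfinite(V[i])) bad = true;
    }
    if (bad) { aborted = true; abort_msg = "non-finite state (numerical blow-up)"; break; }

    if (step % 200000 == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(
    _["times"] = times, _["snapshots"] = snap,
    _["x"] = X, _["y"] = Y, _["U"] = Uo, _["V"] = Vo, _["zeta"] = Zo,
    _["trac_x"] = TX, _["trac_y"] = TY, _["com"] = com,
    _["mono_abs"] = mono_abs, _["trac_scale"] = trac_scale,
    _["torque_abs"] = torque_abs, _["torque_scale"] = torque_scale,
    _["aborted"] = aborted, _["abort_msg"] = abort_msg);
}
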