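#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Mass-action / zero-order / saturable-insertion flux evaluation shared by the
// well-mixed and spatial integrators. Reaction kinds:
//   0 = mass action (1 or 2 reactants), flux = rate * y[r1] (* y[r2])
//   1 = zero order, flux = rate (constant source/sink, e.g. constant insertion)
//   2 = saturable insertion, flux = rate * max(0, cap - sum_j w_j * y_j)
// `rate` already carries any statistical multiplicity factor.

struct ReactionSet {
  int n;
  std::vector<int> kind, r1, r2;
  std::vector<double> rate, cap;
  // saturable weights, per reaction (empty for other kinds)
  std::vector< std::vector<int> > w_idx;
  std::vector< std::vector<double> > w_val;
  // stoichiometry, per reaction
  std::vector< std::vector<int> > st_idx;
  std::vector< std::vector<double> > st_val;
};

static ReactionSet build_reactions(List rxn) {
  ReactionSet rs;
  IntegerVector kind = rxn["kind"], r1 = rxn["r1"], r2 = rxn["r2"];
  NumericVector rate = rxn["rate"], cap = rxn["cap"];
  List wi = rxn["w_idx"], wv = rxn["w_val"], si = rxn["st_idx"], sv = rxn["st_val"];
  rs.n = kind.size();
  rs.kind.assign(kind.begin(), kind.end());
  rs.r1.assign(r1.begin(), r1.end());
  rs.r2.assign(r2.begin(), r2.end());
  rs.rate.assign(rate.begin(), rate.end());
  rs.cap.assign(cap.begin(), cap.end());
  rs.w_idx.resize(rs.n); rs.w_val.resize(rs.n);
  rs.st_idx.resize(rs.n); rs.st_val.resize(rs.n);
  for (int j = 0; j < rs.n; ++j) {
    IntegerVector a = si[j]; NumericVector b = sv[j];
    rs.st_idx[j].assign(a.begin(), a.end());
    rs.st_val[j].assign(b.begin(), b.end());
    if (rs.kind[j] == 2) {
      IntegerVector c = wi[j]; NumericVector d = wv[j];
      rs.w_idx[j].assign(c.begin(), c.end());
      rs.w_val[j].assign(d.begin(), d.end());
    }
  }
  return rs;
}

static inline void add_fluxes(const ReactionSet &rs, const double *y, double *dy,
                              int S) {
  for (int s = 0; s < S; ++s) dy[s] = 0.0;
  for (int j = 0; j < rs.n; ++j) {
    double flux;
    switch (rs.kind[j]) {
    case 0:
      flux = rs.rate[j] * y[rs.r1[j]];
      if (rs.r2[j] >= 0) flux *= y[rs.r2[j]];
      break;
    case 1:
      flux = rs.rate[j];
      break;
    default: {
      double occ = 0.0;
      const std::vector<int> &wi = rs.w_idx[j];
      const std::vector<double> &wv = rs.w_val[j];
      for (size_t q = 0; q < wi.size(); ++q) occ += wv[q] * y[wi[q]];
      double room = rs.cap[j] - occ;
      flux = room > 0.0 ? rs.rate[j] * room : 0.0;
    }
    }
    const std::vector<int> &ti = rs.st_idx[j];
    const std::vector<double> &tv = rs.st_val[j];
    for (size_t q = 0; q < ti.size(); ++q) dy[ti[q]] += tv[q] * flux;
  }
}

// [[Rcpp::export]]
List rk4_integrate_cpp(List rxn, NumericVector y0, double dt, double t_end,
                       int out_every, IntegerVector stop_idx,
                       NumericVector stop_weight, double stop_value,
                       IntegerVector clamp_idx) {
  ReactionSet rs = build_reactions(rxn);
  const int S = y0.size();
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> k1(S), k2(S), k3(S), k4(S), tmp(S);

  long nsteps = (long)std::ceil(t_end / dt - 1e-9);
  long nout = nsteps / out_every + 1;
  NumericMatrix out(nout, S);
  NumericVector tout(nout);
  for (int s = 0; s < S; ++s) out(0, s) = y[s];
  tout[0] = 0.0;
  long row = 1;
  bool use_stop = stop_idx.size() > 0;
  double ymax = 0.0;
  for (int s = 0; s < S; ++s) ymax = std::max(ymax, std::fabs(y[s]));
  bool stopped = false;

  int ncl = clamp_idx.size();
  for (long step = 1; step <= nsteps; ++step) {
    add_fluxes(rs, y.data(), k1.data(), S);
    for (int q = 0; q < ncl; ++q) k1[clamp_idx[q]] = 0.0;
    for (int s = 0; s < S; ++s) tmp[s] = y[s] + 0.5 * dt * k1[s];
    add_fluxes(rs, tmp.data(), k2.data(), S);
    for (int q = 0; q < ncl; ++q) k2[clamp_idx[q]] = 0.0;
    for (int s = 0; s < S; ++s) tmp[s] = y[s] + 0.5 * dt * k2[s];
    add_fluxes(rs, tmp.data(), k3.data(), S);
    for (int q = 0; q < ncl; ++q) k3[clamp_idx[q]] = 0.0;
    for (int s = 0; s < S; ++s) tmp[s] = y[s] + dt * k3[s];
    add_fluxes(rs, tmp.data(), k4.data(), S);
    for (int q = 0; q < ncl; ++q) k4[clamp_idx[q]] = 0.0;
    for (int s = 0; s < S; ++s)
      y[s] += dt / 6.0 * (k1[s] + 2.0 * k2[s] + 2.0 * k3[s] + k4[s]);

    if (step % 200 == 0 || step == nsteps) {
      for (int s = 0; s < S; ++s) {
        if (!std::isfinite(y[s]) || y[s] < -1e-7 * std::max(1.0, ymax))
          stop("integration unstable at t = %f (species %d = %g); reduce dt",
               step * dt, s + 1, y[s]);
      }
    }
    if (step % out_every == 0 && row < nout) {
      for (int s = 0; s < S; ++s) out(row, s) = y[s];
      tout[row] = step * dt;
      ++row;
      if (use_stop) {
        double v = 0.0;
        for (int q = 0; q < stop_idx.size(); ++q)
          v += stop_weight[q] * y[stop_idx[q]];
        if (v <= stop_value) { stopped = true; break; }
      }
    }
  }
  if (row < nout) {
    out = out(Range(0, row - 1), _);
    tout = tout[Range(0, row - 1)];
  }
  return List::create(_["times"] = tout, _["conc"] = out,
                      _["stopped_early"] = stopped);
}

// ---------------------------------------------------------------------------
// Spatial (3D voxel grid) reaction-diffusion integrator.
// State layout: y[s * V + v] for species s in voxel v; voxel v = ix + nx*(iy + ny*iz).
// Diffusion: explicit central differences, no-flux boundaries, applied inside
// each RK4 stage together with the local reaction fluxes. Reactions of kind
// 1/2 (insertion) are restricted to membrane voxels.

static inline void spatial_rhs(const ReactionSet &rs, const double *y, double *dy,
                               int S, int V, int nx, int ny, int nz,
                               const double *dcoef, const int *mem,
                               const int *ecm, const int *rmask,
                               double inv_h2, std::vector<double> &yv,
                               std::vector<double> &dv) {
  // reactions voxel by voxel; reactions over immobile species are restricted
  // to the voxels that can contain them (membrane patch / ECM layer)
  for (int v = 0; v < V; ++v) {
    for (int s = 0; s < S; ++s) yv[s] = y[(size_t)s * V + v];
    for (int s = 0; s < S; ++s) dv[s] = 0.0;
    for (int j = 0; j < rs.n; ++j) {
      if (rmask[j] == 1 && !mem[v]) continue;
      if (rmask[j] == 2 && !ecm[v]) continue;
      if (rs.kind[j] != 0 && !mem[v]) continue;
      double flux;
      switch (rs.kind[j]) {
      case 0:
        flux = rs.rate[j] * yv[rs.r1[j]];
        if (rs.r2[j] >= 0) flux *= yv[rs.r2[j]];
        break;
      case 1:
        flux = rs.rate[j];
        break;
      default: {
        double occ = 0.0;
        for (size_t q = 0; q < rs.w_idx[j].size(); ++q)
          occ += rs.w_val[j][q] * yv[rs.w_idx[j][q]];
        double room = rs.cap[j] - occ;
        flux = room > 0.0 ? rs.rate[j] * room : 0.0;
      }
      }
      for (size_t q = 0; q < rs.st_idx[j].size(); ++q)
        dv[rs.st_idx[j][q]] += rs.st_val[j][q] * flux;
    }
    for (int s = 0; s < S; ++s) dy[(size_t)s * V + v] = dv[s];
  }
  // diffusion for mobile species
  for (int s = 0; s < S; ++s) {
    double D = dcoef[s];
    if (D <= 0.0) continue;
    const double *ys = y + (size_t)s * V;
    double *dys = dy + (size_t)s * V;
    double c = D * inv_h2;
    for (int iz = 0; iz < nz; ++iz)
      for (int iy = 0; iy < ny; ++iy)
        for (int ix = 0; ix < nx; ++ix) {
          int v = ix + nx * (iy + ny * iz);
          double self = ys[v], lap = 0.0;
          if (ix > 0)      lap += ys[v - 1] - self;
          if (ix < nx - 1) lap += ys[v + 1] - self;
          if (iy > 0)      lap += ys[v - nx] - self;
          if (iy < ny - 1) lap += ys[v + nx] - self;
          if (iz > 0)      lap += ys[v - nx * ny] - self;
          if (iz < nz - 1) lap += ys[v + nx * ny] - self;
          dys[v] += c * lap;
        }
  }
}

// [[Rcpp::export]]
List spatial_integrate_cpp(List rxn, NumericMatrix y0, IntegerVector dims,
                           NumericVector dcoef, IntegerVector membrane,
                           IntegerVector ecm, IntegerVector reaction_mask,
                           double voxel, double dt, double t_end, int out_every,
                           NumericVector snapshot_times) {
  ReactionSet rs = build_reactions(rxn);
  const int S = y0.nrow(), V = y0.ncol();
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  if (nx * ny * nz != V) stop("grid dims do not match state");
  std::vector<double> y((size_t)S * V);
  for (int s = 0; s < S; ++s)
    for (int v = 0; v < V; ++v) y[(size_t)s * V + v] = y0(s, v);
  size_t N = y.size();
  std::vector<double> k1(N), k2(N), k3(N), k4(N), tmp(N), yv(S), dv(S);
  std::vector<int> mem(membrane.begin(), membrane.end());
  std::vector<int> ecmv(ecm.begin(), ecm.end());
  std::vector<int> rmask(reaction_mask.begin(), reaction_mask.end());
  double inv_h2 = 1.0 / (voxel * voxel);

  long nsteps = (long)std::ceil(t_end / dt - 1e-9);
  long nout = nsteps / out_every + 1;
  NumericMatrix totals(nout, S); // voxel-mean concentration per species
  NumericVector tout(nout);
  for (int s = 0; s < S; ++s) {
    double acc = 0.0;
    for (int v = 0; v < V; ++v) acc += y[(size_t)s * V + v];
    totals(0, s) = acc / V;
  }
  tout[0] = 0.0;

  int nsnap = snapshot_times.size();
  List snaps(nsnap);
  std::vector<long> snap_step(nsnap);
  for (int q = 0; q < nsnap; ++q)
    snap_step[q] = (long)std::lround(snapshot_times[q] / dt);

  long row = 1;
  for (long step = 1; step <= nsteps; ++step) {
    spatial_rhs(rs, y.data(), k1.data(), S, V, nx, ny, nz, &dcoef[0], mem.data(), ecmv.data(), rmask.data(), inv_h2, yv, dv);
    for (size_t i = 0; i < N; ++i) tmp[i] = y[i] + 0.5 * dt * k1[i];
    spatial_rhs(rs, tmp.data(), k2.data(), S, V, nx, ny, nz, &dcoef[0], mem.data(), ecmv.data(), rmask.data(), inv_h2, yv, dv);
    for (size_t i = 0; i < N; ++i) tmp[i] = y[i] + 0.5 * dt * k2[i];
    spatial_rhs(rs, tmp.data(), k3.data(), S, V, nx, ny, nz, &dcoef[0], mem.data(), ecmv.data(), rmask.data(), inv_h2, yv, dv);
    for (size_t i = 0; i < N; ++i) tmp[i] = y[i] + dt * k3[i];
    spatial_rhs(rs, tmp.data(), k4.data(), S, V, nx, ny, nz, &dcoef[0], mem.data(), ecmv.data(), rmask.data(), inv_h2, yv, dv);
    for (size_t i = 0; i < N; ++i)
      y[i] += dt / 6.0 * (k1[i] + 2.0 * k2[i] + 2.0 * k3[i] + k4[i]);

    if (step % 500 == 0 || step == nsteps) {
      for (size_t i = 0; i < N; ++i)
        if (!std::isfinite(y[i]))
          stop("spatial integration produced non-finite field at t = %f", step * dt);
    }
    if (step % out_every == 0 && row < nout) {
      for (int s = 0; s < S; ++s) {
        double acc = 0.0;
        for (int v = 0; v < V; ++v) acc += y[(size_t)s * V + v];
        totals(row, s) = acc / V;
      }
      tout[row] = step * dt;
      ++row;
    }
    for (int q = 0; q < nsnap; ++q)
      if (snap_step[q] == step) {
        NumericMatrix f(S, V);
        for (int s = 0; s < S; ++s)
          for (int v = 0; v < V; ++v) f(s, v) = y[(size_t)s * V + v];
        snaps[q] = f;
      }
  }
  if (row < nout) {
    totals = totals(Range(0, row - 1), _);
    tout = tout[Range(0, row - 1)];
  }
  NumericMatrix finalf(S, V);
  for (int s = 0; s < S; ++s)
    for (int v = 0; v < V; ++v) finalf(s, v) = y[(size_t)s * V + v];
  return List::create(_["times"] = tout, _["mean_conc"] = totals,
                      _["snapshots"] = snaps, _["final_field"] = finalf);
}
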