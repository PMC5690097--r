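// Dose engines: exact Siddon voxel traversal, deterministic primary-kerma
// ray tracing, and simplified analog Monte Carlo photon transport with
// Woodcock (delta) tracking.  All positions in mm, attenuation
// coefficients passed per cm (converted where applied), energies in keV.

#include <Rcpp.h>
#include <cmath>
#include <random>
#include <vector>

using namespace Rcpp;

struct Grid {
  int n[3];
  double sp[3], org[3], hi[3];
  Grid(IntegerVector dims, NumericVector spacing, NumericVector origin) {
    for (int i = 0; i < 3; ++i) {
      n[i] = dims[i];
      sp[i] = spacing[i];
      org[i] = origin[i];
      hi[i] = org[i] + n[i] * sp[i];
    }
  }
  inline int lin(int i, int j, int k) const {
    return i + n[0] * (j + n[1] * k);
  }
};

// Walk the segment p0 -> p1 through the grid, calling visit(linear_index,
// length_mm) for every traversed voxel.  Exact Siddon/Jacobs traversal.
template <typename F>
static void siddon_walk(const Grid &g, const double p0[3], const double p1[3],
                        F visit) {
  double d[3];
  double seg = 0.0;
  for (int i = 0; i < 3; ++i) {
    d[i] = p1[i] - p0[i];
    seg += d[i] * d[i];
  }
  seg = std::sqrt(seg);
  if (seg <= 0) return;
  // clip parametric range to the grid box
  double t0 = 0.0, t1 = 1.0;
  for (int i = 0; i < 3; ++i) {
    if (std::fabs(d[i]) < 1e-14) {
      if (p0[i] <= g.org[i] || p0[i] >= g.hi[i]) return;
    } else {
      double ta = (g.org[i] - p0[i]) / d[i];
      double tb = (g.hi[i] - p0[i]) / d[i];
      if (ta > tb) std::swap(ta, tb);
      t0 = std::max(t0, ta);
      t1 = std::min(t1, tb);
    }
  }
  if (t0 >= t1) return;
  const double eps = 1e-12;
  double t = t0;
  double pos[3];
  for (int i = 0; i < 3; ++i) pos[i] = p0[i] + (t0 + eps) * d[i];
  int idx[3], step[3];
  double tnext[3], tdelta[3];
  for (int i = 0; i < 3; ++i) {
    idx[i] = (int)std::floor((pos[i] - g.org[i]) / g.sp[i]);
    if (idx[i] < 0) idx[i] = 0;
    if (idx[i] >= g.n[i]) idx[i] = g.n[i] - 1;
    if (d[i] > 0) {
      step[i] = 1;
      tnext[i] = (g.org[i] + (idx[i] + 1) * g.sp[i] - p0[i]) / d[i];
      tdelta[i] = g.sp[i] / d[i];
    } else if (d[i] < 0) {
      step[i] = -1;
      tnext[i] = (g.org[i] + idx[i] * g.sp[i] - p0[i]) / d[i];
      tdelta[i] = -g.sp[i] / d[i];
    } else {
      step[i] = 0;
      tnext[i] = 2.0;
      tdelta[i] = 2.0;
    }
  }
  while (t < t1 - 1e-14) {
    int ax = 0;
    if (tnext[1] < tnext[ax]) ax = 1;
    if (tnext[2] < tnext[ax]) ax = 2;
    double tstop = std::min(tnext[ax], t1);
    double len = (tstop - t) * seg;
    if (len > 0) visit(g.lin(idx[0], idx[1], idx[2]), len);
    t = tstop;
    if (tstop == t1) break;
    idx[ax] += step[ax];
    if (idx[ax] < 0 || idx[ax] >= g.n[ax]) break;
    tnext[ax] += tdelta[ax];
  }
}

// [[Rcpp::export]]
List cpp_siddon(IntegerVector dims, NumericVector spacing,
                NumericVector origin, NumericVector p0, NumericVector p1) {
  Grid g(dims, spacing, origin);
  double a[3] = {p0[0], p0[1], p0[2]}, b[3] = {p1[0], p1[1], p1[2]};
  std::vector<int> vi;
  std::vector<double> vl;
  siddon_walk(g, a, b, [&](int lin, double len) {
    vi.push_back(lin);
    vl.push_back(len);
  });
  return List::create(_["index"] = wrap(vi), _["length_mm"] = wrap(vl));
}

// Deterministic primary-kerma engine.  For every candidate voxel and
// projection: collimation to the detector FOV, ROI-filter path length,
// Beer-Lambert attenuation along the exact Siddon ray, inverse-square
// fluence, and spectral energy-absorption deposition.
// murho, dep: [nE x nLab] mass coefficients (cm^2/g); weights: photons/sr.
// [[Rcpp::export]]
NumericVector cpp_primary_kerma(
    IntegerVector labels, IntegerVector dims, NumericVector spacing,
    NumericVector origin, NumericVector density, NumericMatrix murho,
    NumericMatrix dep, NumericVector energies, NumericVector weights,
    NumericMatrix sources, NumericVector iso, double sdd_mm, double fov_u_mm,
    double fov_v_mm, bool has_filter, NumericVector muf_lin_cm, double tf_mm,
    double ap_r_mm, double ap_u0_mm, double ap_v0_mm,
    IntegerVector candidates) {
  Grid g(dims, spacing, origin);
  const int nE = energies.size(), nLab = murho.ncol();
  const int nproj = sources.nrow(), ncand = candidates.size();
  NumericVector dose(labels.size());
  std::vector<double> rholen(nLab);
  std::vector<double> wE(nE), muf(nE);
  for (int e = 0; e < nE; ++e) {
    wE[e] = weights[e] * energies[e];
    muf[e] = muf_lin_cm[e];
  }
  for (int p = 0; p < nproj; ++p) {
    double src[3] = {sources(p, 0), sources(p, 1), sources(p, 2)};
    double ax[3] = {iso[0] - src[0], iso[1] - src[1], iso[2] - src[2]};
    double rs = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int i = 0; i < 3; ++i) ax[i] /= rs;
    double uh[3] = {ax[1], -ax[0], 0.0};  // z x axis (axis is axial)
    for (int c = 0; c < ncand; ++c) {
      int v = candidates[c];
      int k = v / (g.n[0] * g.n[1]);
      int j = (v / g.n[0]) % g.n[1];
      int i = v % g.n[0];
      double vc[3] = {g.org[0] + (i + 0.5) * g.sp[0],
                      g.org[1] + (j + 0.5) * g.sp[1],
                      g.org[2] + (k + 0.5) * g.sp[2]};
      double d[3] = {vc[0] - src[0], vc[1] - src[1], vc[2] - src[2]};
      double talong = d[0] * ax[0] + d[1] * ax[1] + d[2] * ax[2];
      if (talong <= 1e-9) continue;
      double s = sdd_mm / talong;
      double off[3] = {d[0] * s - ax[0] * sdd_mm, d[1] * s - ax[1] * sdd_mm,
                       d[2] * s - ax[2] * sdd_mm};
      double u = off[0] * uh[0] + off[1] * uh[1];
      double vv = off[2];
      if (std::fabs(u) > fov_u_mm / 2 || std::fabs(vv) > fov_v_mm / 2)
        continue;
      double r2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
      double fpath_cm = 0.0;
      if (has_filter) {
        double du = u - ap_u0_mm, dv = vv - ap_v0_mm;
        if (du * du + dv * dv > ap_r_mm * ap_r_mm) {
          double ct = talong / std::sqrt(r2);
          fpath_cm = tf_mm / ct / 10.0;
        }
      }
      std::fill(rholen.begin(), rholen.end(), 0.0);
      siddon_walk(g, src, vc, [&](int lin, double len) {
        rholen[labels[lin]] += density[lin] * len / 10.0;  // g/cm^2
      });
      int lab = labels[v];
      double r2cm = r2 / 100.0;
      double acc = 0.0;
      for (int e = 0; e < nE; ++e) {
        if (wE[e] <= 0) continue;
        double tau = muf[e] * fpath_cm;
        for (int l = 0; l < nLab; ++l) tau += murho(e, l) * rholen[l];
        acc += wE[e] * std::exp(-tau) * dep(e, lab);
      }
      dose[v] += acc / r2cm;
    }
    Rcpp::checkUserInterrupt();
  }
  return dose;
}

static inline void rotate_dir(double dir[3], double cost, double phi) {
  // rotate dir by polar angle acos(cost) about itself, azimuth phi
  double sint = std::sqrt(std::max(0.0, 1.0 - cost * cost));
  double w[3] = {dir[0], dir[1], dir[2]};
  double a[3];
  if (std::fabs(w[2]) < 0.99) {
    a[0] = -w[1]; a[1] = w[0]; a[2] = 0.0;
  } else {
    a[0] = 1.0; a[1] = 0.0; a[2] = 0.0;
  }
  double an = std::sqrt(a[0] * a[0] + a[1] * a[1] + a[2] * a[2]);
  for (int i = 0; i < 3; ++i) a[i] /= an;
  double b[3] = {w[1] * a[2] - w[2] * a[1], w[2] * a[0] - w[0] * a[2],
                 w[0] * a[1] - w[1] * a[0]};
  double cp = std::cos(phi), sp = std::sin(phi);
  for (int i = 0; i < 3; ++i)
    dir[i] = w[i] * cost + sint * (a[i] * cp + b[i] * sp);
}

// Kahn's algorithm for Klein-Nishina scattered-photon sampling.
// Returns x = E/E'; cost output via reference.
static inline double kahn_sample(double alpha, std::mt19937_64 &rng,
                                 std::uniform_real_distribution<double> &U,
                                 double &cost) {
  for (;;) {
    double r1 = U(rng), r2 = U(rng), r3 = U(rng);
    if (r1 <= (1.0 + 2.0 * alpha) / (9.0 + 2.0 * alpha)) {
      double x = 1.0 + 2.0 * alpha * r2;
      if (r3 <= 4.0 * (1.0 / x - 1.0 / (x * x))) {
        cost = 1.0 - (x - 1.0) / alpha;
        return x;
      }
    } else {
      double x = (1.0 + 2.0 * alpha) / (1.0 + 2.0 * alpha * r2);
      double ct = 1.0 - (x - 1.0) / alpha;
      if (r3 <= 0.5 * (ct * ct + 1.0 / x)) {
        cost = ct;
        return x;
      }
    }
  }
}

// Simplified analog Monte Carlo photon transport under the kerma
// approximation: photoelectric -> local full deposition; incoherent ->
// Klein-Nishina (Kahn) free-electron sampling, transferred energy
// deposited locally; coherent -> Thomson-distribution direction change
// (form-factor-free approximation).  ROI filter applied as an entry
// weight (weighted-attenuation rule).  Woodcock tracking inside the grid.
// Cross-section matrices are on a 1-keV grid 1..150 (row = round(E)-1).
// mode: 0 = full physics, 1 = forced photoelectric (attenuation by total
// mu, full local deposition; scatter disabled).
// [[Rcpp::export]]
List cpp_mc_dose(IntegerVector labels, IntegerVector dims,
                 NumericVector spacing, NumericVector origin,
                 NumericVector density, NumericMatrix mu_tot,
                 NumericMatrix mu_photo, NumericMatrix mu_incoh,
                 NumericVector mumax_cm, NumericVector energies,
                 NumericVector weights, NumericMatrix sources,
                 NumericVector iso, double sdd_mm, double fov_u_mm,
                 double fov_v_mm, bool has_filter, NumericVector muf_lin_cm,
                 double tf_mm, double ap_r_mm, double ap_u0_mm,
                 double ap_v0_mm, double histories, int seed, int nbatch,
                 int mode) {
  Grid g(dims, spacing, origin);
  const int nproj = sources.nrow();
  const int nvox = labels.size();
  const long long N = (long long)histories;
  std::mt19937_64 rng((uint64_t)seed);
  std::uniform_real_distribution<double> U(0.0, 1.0);

  // spectrum CDF
  int nE = energies.size();
  std::vector<double> cdf(nE);
  double sw = 0.0;
  for (int e = 0; e < nE; ++e) { sw += weights[e]; cdf[e] = sw; }
  for (int e = 0; e < nE; ++e) cdf[e] /= sw;

  std::vector<double> edep(nvox, 0.0), bcur(nvox, 0.0), bsum(nvox, 0.0),
      bsq(nvox, 0.0);
  int nlab = mu_tot.ncol();
  NumericMatrix labbatch(nlab, nbatch);  // energy deposited per label/batch

  // per-projection beam frames
  std::vector<double> AX(3 * nproj), UH(3 * nproj);
  for (int p = 0; p < nproj; ++p) {
    double ax[3] = {iso[0] - sources(p, 0), iso[1] - sources(p, 1),
                    iso[2] - sources(p, 2)};
    double rs = std::sqrt(ax[0] * ax[0] + ax[1] * ax[1] + ax[2] * ax[2]);
    for (int i = 0; i < 3; ++i) AX[3 * p + i] = ax[i] / rs;
    UH[3 * p + 0] = AX[3 * p + 1];
    UH[3 * p + 1] = -AX[3 * p + 0];
    UH[3 * p + 2] = 0.0;
  }
  double area_cm2 = (fov_u_mm / 10.0) * (fov_v_mm / 10.0);

  int curbatch = 0;
  for (long long h = 0; h < N; ++h) {
    int newbatch = (int)((h * (long long)nbatch) / N);
    if (newbatch != curbatch) {
      for (int v = 0; v < nvox; ++v) {
        bsum[v] += bcur[v];
        bsq[v] += bcur[v] * bcur[v];
        bcur[v] = 0.0;
      }
      curbatch = newbatch;
    }
    int p = (int)(U(rng) * nproj);
    if (p >= nproj) p = nproj - 1;
    const double *ax = &AX[3 * p], *uh = &UH[3 * p];
    double u = (U(rng) - 0.5) * fov_u_mm, v = (U(rng) - 0.5) * fov_v_mm;
    double det[3];
    for (int i = 0; i < 3; ++i)
      det[i] = sources(p, i) + ax[i] * sdd_mm + uh[i] * u +
               (i == 2 ? v : 0.0);
    double dir[3] = {det[0] - sources(p, 0), det[1] - sources(p, 1),
                     det[2] - sources(p, 2)};
    double rd = std::sqrt(dir[0] * dir[0] + dir[1] * dir[1] +
                          dir[2] * dir[2]);
    for (int i = 0; i < 3; ++i) dir[i] /= rd;
    double ct = dir[0] * ax[0] + dir[1] * ax[1] + dir[2] * ax[2];
    double w = sw * nproj * area_cm2 * ct / ((rd / 10.0) * (rd / 10.0));

    // sample energy
    double r = U(rng);
    int e = (int)(std::lower_bound(cdf.begin(), cdf.end(), r) - cdf.begin());
    if (e >= nE) e = nE - 1;
    double E = energies[e];

    // ROI filter as an entry weight
    if (has_filter) {
      double du = u - ap_u0_mm, dv = v - ap_v0_mm;
      if (du * du + dv * dv > ap_r_mm * ap_r_mm) {
        int ei = (int)std::lround(E) - 1;
        if (ei < 0) ei = 0;
        if (ei > (int)muf_lin_cm.size() - 1) ei = muf_lin_cm.size() - 1;
        w *= std::exp(-muf_lin_cm[ei] * (tf_mm / ct / 10.0));
      }
    }

    double pos[3] = {sources(p, 0), sources(p, 1), sources(p, 2)};
    // advance to grid entry
    double t0 = 0.0, t1 = 1e30;
    bool miss = false;
    for (int i = 0; i < 3; ++i) {
      if (std::fabs(dir[i]) < 1e-14) {
        if (pos[i] <= g.org[i] || pos[i] >= g.hi[i]) { miss = true; break; }
      } else {
        double ta = (g.org[i] - pos[i]) / dir[i];
        double tb = (g.hi[i] - pos[i]) / dir[i];
        if (ta > tb) std::swap(ta, tb);
        t0 = std::max(t0, ta);
        t1 = std::min(t1, tb);
      }
    }
    if (miss || t0 >= t1) continue;
    double tcur = t0 + 1e-9;

    for (;;) {
      int ei = (int)std::lround(E) - 1;
      if (ei < 0) ei = 0;
      if (ei >= (int)mumax_cm.size()) ei = mumax_cm.size() - 1;
      double mumax_mm = mumax_cm[ei] / 10.0;
      double step = -std::log(U(rng)) / mumax_mm;
      tcur += step;
      double x = pos[0] + tcur * dir[0], y = pos[1] + tcur * dir[1],
             z = pos[2] + tcur * dir[2];
      if (x <= g.org[0] || x >= g.hi[0] || y <= g.org[1] || y >= g.hi[1] ||
          z <= g.org[2] || z >= g.hi[2])
        break;  // escaped (grid box is convex)
      int i = (int)((x - g.org[0]) / g.sp[0]);
      int j = (int)((y - g.org[1]) / g.sp[1]);
      int k = (int)((z - g.org[2]) / g.sp[2]);
      int lin = g.lin(i, j, k);
      int lab = labels[lin];
      double mu_mm = mu_tot(ei, lab) * density[lin] / 10.0;
      if (U(rng) * mumax_mm > mu_mm) continue;  // virtual collision
      // real collision
      if (mode == 1) {
        edep[lin] += w * E;
        bcur[lin] += w * E;
        labbatch(lab, curbatch) += w * E;
        break;
      }
      double ph = mu_photo(ei, lab), inc = mu_incoh(ei, lab),
             tot = mu_tot(ei, lab);
      double r2 = U(rng) * tot;
      if (r2 < ph) {
        edep[lin] += w * E;
        bcur[lin] += w * E;
        labbatch(lab, curbatch) += w * E;
        break;
      } else if (r2 < ph + inc) {
        double alpha = E / 510.99895;
        double cost;
        double xk = kahn_sample(alpha, rng, U, cost);
        double Ep = E / xk;
        double dE = E - Ep;
        edep[lin] += w * dE;
        bcur[lin] += w * dE;
        labbatch(lab, curbatch) += w * dE;
        if (Ep < 1.0) {
          edep[lin] += w * Ep;
          bcur[lin] += w * Ep;
          labbatch(lab, curbatch) += w * Ep;
          break;
        }
        E = Ep;
        double phi = 2.0 * M_PI * U(rng);
        // re-anchor the ray at the collision point
        pos[0] = x; pos[1] = y; pos[2] = z; tcur = 1e-9;
        rotate_dir(dir, cost, phi);
      } else {
        // coherent: Thomson angular distribution, no energy loss
        double cost;
        for (;;) {
          double c = 2.0 * U(rng) - 1.0;
          if (U(rng) <= 0.5 * (1.0 + c * c)) { cost = c; break; }
        }
        double phi = 2.0 * M_PI * U(rng);
        pos[0] = x; pos[1] = y; pos[2] = z; tcur = 1e-9;
        rotate_dir(dir, cost, phi);
      }
    }
    if ((h & 0xFFFF) == 0) Rcpp::checkUserInterrupt();
  }
  for (int v = 0; v < nvox; ++v) {
    bsum[v] += bcur[v];
    bsq[v] += bcur[v] * bcur[v];
  }

  NumericVector mean(nvox), relunc(nvox);
  for (int v = 0; v < nvox; ++v) {
    double m = bsum[v] / nbatch;
    double var = std::max(0.0, bsq[v] / nbatch - m * m) /
                 std::max(1, nbatch - 1);
    mean[v] = edep[v] / N;  // energy (keV x weight) per history
    relunc[v] = (edep[v] > 0) ? std::sqrt(var) / m : 0.0;
  }
  return List::create(_["edep_per_history"] = mean,
                      _["rel_uncertainty"] = relunc,
                      _["label_batch"] = labbatch,
                      _["weight_sum"] = sw);
}
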