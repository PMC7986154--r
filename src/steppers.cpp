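// Monte Carlo cores for the IRT and SBS chemistry steppers.
//
// Internal units: nm, ps. All randomness goes through R's RNG so a single
// set.seed() in R makes every run reproducible. Molecules live in flat
// arrays; reactive DNA sinks are static spheres indexed by cell grids over
// the voxel. Histories are batched: one call runs many independent
// primaries, resetting sink damage between them.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static inline double erfc_inv(double q) {
  return ::Rf_qnorm5(0.5 * q, 0.0, 1.0, 0, 0) * M_SQRT1_2;
}

static inline double d_eff(double d, double rc) {
  if (rc == 0.0) return d;
  return rc / expm1(rc / d);
}

static inline double d_eff_inv(double deff, double rc) {
  if (rc == 0.0) return deff;
  if (1.0 + rc / deff <= 0.0) return 1e30;  // attractive: unbounded below |rc|
  return rc / log1p(rc / deff);
}

// ---------------------------------------------------------------------------
struct Scheme {
  int nS;
  std::vector<double> D;
  int nR;
  std::vector<int> ra, rb;
  std::vector<double> Rgeom;    // bare contact radius (overlap tests)
  std::vector<double> Rt;       // transformed contact radius (sampling)
  std::vector<double> Reff;     // asymptotic effective radius
  std::vector<double> kdif, kact, rc, Drel;
  std::vector<int> partial, spin;
  std::vector<double> pacc2;    // kact/(kdif+kact); 1 for totally controlled
  std::vector<double> coef2;    // stage-2 time scale
  std::vector<double> contactP; // contact-reaction probability (Eqs 8-9)
  std::vector<int> prod;        // nR x 3
  std::vector<int> rxn_of;      // nS x nS -> reaction or -1
};

static Scheme buildScheme(List scm) {
  Scheme S;
  NumericVector D = scm["D"];
  S.nS = D.size();
  S.D.assign(D.begin(), D.end());
  IntegerVector ra = scm["ra"], rb = scm["rb"];
  NumericVector Rg = scm["Rgeom"], Reff = scm["Reff"], kdif = scm["kdif"],
    kact = scm["kact"], rc = scm["rc"];
  IntegerVector partial = scm["partial"], spin = scm["spin"];
  IntegerMatrix prod = scm["prod"];
  NumericVector contactP = scm["contactP"];
  S.nR = ra.size();
  S.ra.assign(ra.begin(), ra.end()); S.rb.assign(rb.begin(), rb.end());
  S.Rgeom.assign(Rg.begin(), Rg.end());
  S.Reff.assign(Reff.begin(), Reff.end());
  S.kdif.assign(kdif.begin(), kdif.end());
  S.kact.assign(kact.begin(), kact.end());
  S.rc.assign(rc.begin(), rc.end());
  S.partial.assign(partial.begin(), partial.end());
  S.spin.assign(spin.begin(), spin.end());
  S.contactP.assign(contactP.begin(), contactP.end());
  S.Rt.resize(S.nR); S.Drel.resize(S.nR);
  S.pacc2.resize(S.nR); S.coef2.resize(S.nR);
  S.prod.assign(std::max(3 * S.nR, 1), -1);
  for (int r = 0; r < S.nR; ++r) {
    for (int j = 0; j < 3; ++j) S.prod[3 * r + j] = prod(r, j);
    S.Drel[r] = S.D[S.ra[r]] + S.D[S.rb[r]];
    if (S.partial[r]) {
      S.Rt[r] = d_eff(S.Rgeom[r], S.rc[r]);
      S.pacc2[r] = S.kact[r] / (S.kdif[r] + S.kact[r]);
      double c = S.kdif[r] * S.Rt[r] / (S.kdif[r] + S.kact[r]);
      S.coef2[r] = c * c / S.Drel[r];
    } else {
      S.Rt[r] = S.Reff[r];   // absorbing boundary at the effective radius
      S.pacc2[r] = 1.0;
      S.coef2[r] = 0.0;
    }
  }
  S.rxn_of.assign(S.nS * S.nS, -1);
  for (int r = 0; r < S.nR; ++r) {
    S.rxn_of[S.ra[r] * S.nS + S.rb[r]] = r;
    S.rxn_of[S.rb[r] * S.nS + S.ra[r]] = r;
  }
  return S;
}

// ---------------------------------------------------------------------------
struct Sinks {
  int n = 0;
  std::vector<double> x, y, z;
  std::vector<int> cls;
  std::vector<char> damaged;
  int nCls = 0, nS = 0;
  std::vector<double> Rsink;
  std::vector<double> RmaxSpecies;
  // fine grid (contact / bridge queries)
  double h = 0, cell = 2.0; int ncell = 0;
  std::vector<int> cellStart, entries;
  // coarse grid (IRT candidate thinning)
  double cellC = 4.0; int ncellC = 0;
  std::vector<int> cellStartC, entriesC;
  bool any = false;

  void build(NumericMatrix pos, IntegerVector cls_, NumericMatrix Rs,
             double voxHalf) {
    n = pos.nrow();
    any = n > 0;
    h = voxHalf;
    x.resize(n); y.resize(n); z.resize(n);
    damaged.assign(n, 0);
    cls.assign(cls_.begin(), cls_.end());
    for (int i = 0; i < n; ++i) { x[i]=pos(i,0); y[i]=pos(i,1); z[i]=pos(i,2); }
    nCls = Rs.nrow(); nS = Rs.ncol();
    Rsink.resize(nCls * nS);
    RmaxSpecies.assign(nS, 0.0);
    for (int c = 0; c < nCls; ++c)
      for (int s = 0; s < nS; ++s) {
        Rsink[c * nS + s] = Rs(c, s);
        RmaxSpecies[s] = std::max(RmaxSpecies[s], Rs(c, s));
      }
    if (!any) return;
    auto makeGrid = [&](double csize, int& nc, std::vector<int>& start,
                        std::vector<int>& ent) {
      nc = std::max(1, (int)std::ceil(2.0 * h / csize));
      int nc3 = nc * nc * nc;
      std::vector<int> cnt(nc3, 0), ci(n);
      for (int i = 0; i < n; ++i) {
        int ix = std::min(std::max((int)std::floor((x[i] + h) / csize), 0), nc - 1);
        int iy = std::min(std::max((int)std::floor((y[i] + h) / csize), 0), nc - 1);
        int iz = std::min(std::max((int)std::floor((z[i] + h) / csize), 0), nc - 1);
        ci[i] = (ix * nc + iy) * nc + iz;
        cnt[ci[i]]++;
      }
      start.assign(nc3 + 1, 0);
      for (int c = 0; c < nc3; ++c) start[c + 1] = start[c] + cnt[c];
      ent.resize(n);
      std::vector<int> fill(start.begin(), start.end() - 1);
      for (int i = 0; i < n; ++i) ent[fill[ci[i]]++] = i;
    };
    makeGrid(cell, ncell, cellStart, entries);
    makeGrid(cellC, ncellC, cellStartC, entriesC);
  }
  void reset() { std::fill(damaged.begin(), damaged.end(), 0); }
  inline int clampi(int v) const { return std::min(std::max(v, 0), ncell - 1); }
  template <class F>
  void visit(double px, double py, double pz, double r, F f) const {
    if (!any) return;
    int ix0 = clampi((int)std::floor((px - r + h) / cell));
    int ix1 = clampi((int)std::floor((px + r + h) / cell));
    int iy0 = clampi((int)std::floor((py - r + h) / cell));
    int iy1 = clampi((int)std::floor((py + r + h) / cell));
    int iz0 = clampi((int)std::floor((pz - r + h) / cell));
    int iz1 = clampi((int)std::floor((pz + r + h) / cell));
    double r2 = r * r;
    for (int ix = ix0; ix <= ix1; ++ix)
      for (int iy = iy0; iy <= iy1; ++iy)
        for (int iz = iz0; iz <= iz1; ++iz) {
          int c = (ix * ncell + iy) * ncell + iz;
          for (int e = cellStart[c]; e < cellStart[c + 1]; ++e) {
            int i = entries[e];
            double dx=px-x[i], dy=py-y[i], dz=pz-z[i];
            double d2 = dx*dx+dy*dy+dz*dz;
            if (d2 <= r2) f(i, d2);
          }
        }
  }
  double nearest(double px, double py, double pz, int s, double rmax) const {
    if (!any) return 1e30;
    double best2 = 1e60;
    for (double r = 2.0; ; r *= 2.0) {
      double rr = std::min(r, rmax);
      visit(px, py, pz, rr, [&](int i, double d2) {
        if (!damaged[i] && Rsink[cls[i] * nS + s] > 0.0 && d2 < best2)
          best2 = d2;
      });
      if (best2 <= rr * rr) return std::sqrt(best2);
      if (rr >= rmax) return std::sqrt(best2);
    }
  }
};

// ---------------------------------------------------------------------------
struct State {
  std::vector<double> x, y, z;
  std::vector<int> kind, id;
  std::vector<char> alive;
  int nextId = 0;
  int nAlive = 0;
  int size() const { return (int)kind.size(); }
  int add(int k, double px, double py, double pz) {
    x.push_back(px); y.push_back(py); z.push_back(pz);
    kind.push_back(k); id.push_back(nextId++); alive.push_back(1);
    nAlive++;
    return size() - 1;
  }
  void kill(int i) { if (alive[i]) { alive[i] = 0; nAlive--; } }
};

struct Events {
  std::vector<double> time, x, y, z;
  std::vector<int> hist, type, rxn, ka, kb, sink;
  void push(int h, double t, int ty, int r, int a, int b, int s,
            double px, double py, double pz) {
    hist.push_back(h);
    time.push_back(t); type.push_back(ty); rxn.push_back(r);
    ka.push_back(a); kb.push_back(b); sink.push_back(s);
    x.push_back(px); y.push_back(py); z.push_back(pz);
  }
  List asList() const {
    return List::create(
      _["history"] = IntegerVector(hist.begin(), hist.end()),
      _["time_ps"] = NumericVector(time.begin(), time.end()),
      _["type"] = IntegerVector(type.begin(), type.end()),
      _["reaction"] = IntegerVector(rxn.begin(), rxn.end()),
      _["kind_a"] = IntegerVector(ka.begin(), ka.end()),
      _["kind_b"] = IntegerVector(kb.begin(), kb.end()),
      _["sink"] = IntegerVector(sink.begin(), sink.end()),
      _["x"] = NumericVector(x.begin(), x.end()),
      _["y"] = NumericVector(y.begin(), y.end()),
      _["z"] = NumericVector(z.begin(), z.end()));
  }
};

static inline double dist(const State& st, int i, int j) {
  double dx = st.x[i]-st.x[j], dy = st.y[i]-st.y[j], dz = st.z[i]-st.z[j];
  return std::sqrt(dx*dx + dy*dy + dz*dz);
}

static inline bool inVoxel(const State& st, int i, double h) {
  return std::fabs(st.x[i]) < h && std::fabs(st.y[i]) < h && std::fabs(st.z[i]) < h;
}

// spin-admissibility cache: decided once per unordered id pair
struct SpinCache {
  std::unordered_map<uint64_t, bool> m;
  double w;
  SpinCache(double weight) : w(weight) {}
  bool admissible(int ida, int idb) {
    uint64_t a = (uint64_t)std::min(ida, idb), b = (uint64_t)std::max(ida, idb);
    uint64_t key = (a << 32) | b;
    auto it = m.find(key);
    if (it != m.end()) return it->second;
    bool ok = unif_rand() < w;
    m.emplace(key, ok);
    return ok;
  }
};

static void diffuseAll(State& st, double dt, const Scheme& S) {
  if (dt <= 0) return;
  int n = st.size();
  for (int i = 0; i < n; ++i) {
    if (!st.alive[i]) continue;
    double s = std::sqrt(2.0 * S.D[st.kind[i]] * dt);
    st.x[i] += s * norm_rand();
    st.y[i] += s * norm_rand();
    st.z[i] += s * norm_rand();
  }
}

static void cullEscapes(State& st, double h, double t, Events& ev, int hid) {
  if (h <= 0) return;
  int n = st.size();
  for (int i = 0; i < n; ++i) {
    if (st.alive[i] && !inVoxel(st, i, h)) {
      ev.push(hid, t, 2, -1, st.kind[i], -1, -1, st.x[i], st.y[i], st.z[i]);
      st.kill(i);
    }
  }
}

// place reaction products at the parents' post-diffusion positions:
// one product -> diffusion-weighted encounter point; two -> the parents'
// positions; a third -> the encounter point.
static void placeProducts(State& st, const Scheme& S, int r, int i, int j,
                          double t, Events& ev, int hid) {
  double Dai = S.D[st.kind[i]], Dbj = S.D[st.kind[j]];
  double wa = std::sqrt(Dbj) / (std::sqrt(Dai) + std::sqrt(Dbj));
  double ex = wa * st.x[i] + (1 - wa) * st.x[j];
  double ey = wa * st.y[i] + (1 - wa) * st.y[j];
  double ez = wa * st.z[i] + (1 - wa) * st.z[j];
  int ka = st.kind[i], kb = st.kind[j];
  double px[3], py[3], pz[3];
  int np = 0;
  for (int q = 0; q < 3; ++q) if (S.prod[3*r+q] >= 0) np++;
  if (np == 1) { px[0]=ex; py[0]=ey; pz[0]=ez; }
  else if (np >= 2) {
    px[0]=st.x[i]; py[0]=st.y[i]; pz[0]=st.z[i];
    px[1]=st.x[j]; py[1]=st.y[j]; pz[1]=st.z[j];
    px[2]=ex; py[2]=ey; pz[2]=ez;
  }
  st.kill(i); st.kill(j);
  for (int q = 0; q < np; ++q)
    st.add(S.prod[3*r+q], px[q], py[q], pz[q]);
  ev.push(hid, t, 0, r, ka, kb, -1, ex, ey, ez);
}

// contact sweep: pairs (and radical-sink contacts) inside the reaction
// radius react with the unsuccessful-encounter probability (1 in SBS
// mode), ascending separation, each molecule at most once per sweep.
struct ContactHit { double d; int i, j, rxn, sink; };

static void contactSweep(State& st, const Scheme& S, Sinks& sk, SpinCache& spin,
                         double t, Events& ev, int hid, bool sbsMode) {
  int n = st.size();
  std::vector<ContactHit> hits;
  for (int i = 0; i < n; ++i) {
    if (!st.alive[i]) continue;
    for (int j = i + 1; j < n; ++j) {
      if (!st.alive[j]) continue;
      int r = S.rxn_of[st.kind[i] * S.nS + st.kind[j]];
      if (r < 0) continue;
      double d = dist(st, i, j);
      if (d < S.Rgeom[r]) hits.push_back({d, i, j, r, -1});
    }
    if (sk.any) {
      int s = st.kind[i];
      double rq = sk.RmaxSpecies[s];
      if (rq > 0.0) {
        sk.visit(st.x[i], st.y[i], st.z[i], rq, [&](int si, double d2) {
          if (sk.damaged[si]) return;
          double Rr = sk.Rsink[sk.cls[si] * sk.nS + s];
          if (Rr > 0.0 && d2 < Rr * Rr)
            hits.push_back({std::sqrt(d2), i, -1, -1, si});
        });
      }
    }
  }
  std::sort(hits.begin(), hits.end(),
            [](const ContactHit& a, const ContactHit& b) { return a.d < b.d; });
  for (const auto& hc : hits) {
    if (!st.alive[hc.i]) continue;
    if (hc.sink >= 0) {
      if (sk.damaged[hc.sink]) continue;
      sk.damaged[hc.sink] = 1;
      ev.push(hid, t, 1, -1, st.kind[hc.i], -1, hc.sink,
              st.x[hc.i], st.y[hc.i], st.z[hc.i]);
      st.kill(hc.i);
      continue;
    }
    if (!st.alive[hc.j]) continue;
    int r = hc.rxn;
    if (!sbsMode && S.spin[r] && !spin.admissible(st.id[hc.i], st.id[hc.j]))
      continue;
    double p = sbsMode ? 1.0 : S.contactP[r];
    if (p >= 1.0 || unif_rand() < p)
      placeProducts(st, S, r, hc.i, hc.j, t, ev, hid);
  }
}

// largest transformed separation with reaction probability >= pcut within
// the remaining time
static double cutoffRadius(double Reff, double Rt, double D, double Trem,
                           double pcut) {
  if (Reff <= 0) return 0.0;
  double sD = std::sqrt(4.0 * D * std::max(Trem, 1e-12));
  auto f = [&](double r) { return (Reff / r) * std::erfc((r - Rt) / sD) - pcut; };
  double lo = Rt, hi = Rt + 8.0 * sD;
  if (f(lo) <= 0.0) return Rt;
  if (f(hi) > 0.0) return hi;    // erfc(8) ~ 1e-29: pcut below fp floor
  for (int it = 0; it < 60; ++it) {
    double mid = 0.5 * (lo + hi);
    if (f(mid) > 0.0) lo = mid; else hi = mid;
  }
  return hi;
}

// sample an IRT reaction time for a pair at physical separation d
static double sampleIRT(const Scheme& S, int r, double d) {
  double rc = S.rc[r];
  double r0 = d_eff(d, rc);
  double Rt = S.Rt[r];
  if (r0 < Rt) r0 = Rt;  // overlap that survived a contact draw: at contact
  double u = unif_rand();
  if (u * r0 >= Rt) return R_PosInf;
  double t1 = 0.0;
  if (r0 > Rt) {
    double ei = erfc_inv(u * r0 / Rt);
    double a = (r0 - Rt) / (2.0 * ei);
    t1 = a * a / S.Drel[r];
  }
  if (!S.partial[r]) return t1;
  if (unif_rand() > S.pacc2[r]) return R_PosInf;
  double yv = 0.0;
  do { yv = std::fabs(norm_rand()) * M_SQRT2; } while (yv == 0.0);
  double xx = -std::log(unif_rand()) / yv;
  return t1 + S.coef2[r] * xx * xx;
}

// sink (totally controlled) version; accepting uniform u (u*d < Rr) drawn
// by the caller
static double sampleIRTSink(double d, double Rr, double D, double u) {
  if (d <= Rr) return 0.0;
  double ei = erfc_inv(u * d / Rr);
  double a = (d - Rr) / (2.0 * ei);
  return a * a / D;
}

// ---------------------------------------------------------------------------
// synchronous IRT: sample all pair times, fire the global minimum, diffuse
// every survivor to that time, sweep contacts, resample.
static void runIRT(State& st, const Scheme& S, Sinks& sk, double voxel_half,
                   double t_start, double t_end, double spin_weight,
                   double cutoff_prob, Events& ev, int hid) {
  SpinCache spin(spin_weight);
  double t = t_start;
  std::vector<double> cutPair(S.nR), cutSink(sk.nCls * S.nS);
  while (true) {
    cullEscapes(st, voxel_half, t, ev, hid);
    contactSweep(st, S, sk, spin, t, ev, hid, false);
    if (st.nAlive == 0 || t >= t_end) break;
    double Trem = t_end - t;
    for (int r = 0; r < S.nR; ++r) {
      double c = cutoffRadius(S.Reff[r], S.Rt[r], S.Drel[r], Trem, cutoff_prob);
      cutPair[r] = d_eff_inv(c, S.rc[r]);
    }
    for (int c = 0; c < sk.nCls; ++c)
      for (int s = 0; s < S.nS; ++s) {
        double Rr = sk.Rsink[c * sk.nS + s];
        cutSink[c * S.nS + s] =
          Rr > 0 ? cutoffRadius(Rr, Rr, S.D[s], Trem, cutoff_prob) : 0.0;
      }
    double tmin = R_PosInf;
    int wi = -1, wj = -1, wr = -1, wsink = -1;
    int n = st.size();
    for (int i = 0; i < n; ++i) {
      if (!st.alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!st.alive[j]) continue;
        int r = S.rxn_of[st.kind[i] * S.nS + st.kind[j]];
        if (r < 0) continue;
        double d = dist(st, i, j);
        if (d > cutPair[r]) continue;
        if (S.spin[r] && !spin.admissible(st.id[i], st.id[j])) continue;
        double ts = sampleIRT(S, r, d);
        if (ts < tmin) { tmin = ts; wi = i; wj = j; wr = r; wsink = -1; }
      }
      if (sk.any && sk.RmaxSpecies[st.kind[i]] > 0.0) {
        // Exact per-sink inversion sampling accelerated by geometric
        // thinning over coarse cells: every sink in a cell accepts with
        // probability <= pmax = Rmax/dmin(cell), so the sweep advances
        // with geometric skips and corrects by the exact ratio.
        int s = st.kind[i];
        double Rmax = sk.RmaxSpecies[s];
        double maxcut = 0.0;
        for (int c = 0; c < sk.nCls; ++c)
          maxcut = std::max(maxcut, cutSink[c * S.nS + s]);
        double px = st.x[i], py = st.y[i], pz = st.z[i];
        double Ds = S.D[s];
        int nc = sk.ncellC;
        for (int ix = 0; ix < nc; ++ix) {
          double bx = -sk.h + ix * sk.cellC;
          double dx = std::max({bx - px, px - (bx + sk.cellC), 0.0});
          if (dx > maxcut) continue;
          for (int iy = 0; iy < nc; ++iy) {
            double by = -sk.h + iy * sk.cellC;
            double dy = std::max({by - py, py - (by + sk.cellC), 0.0});
            double dxy2 = dx * dx + dy * dy;
            if (dxy2 > maxcut * maxcut) continue;
            for (int iz = 0; iz < nc; ++iz) {
              int c0 = (ix * nc + iy) * nc + iz;
              int e0 = sk.cellStartC[c0], e1 = sk.cellStartC[c0 + 1];
              if (e0 == e1) continue;
              double bz = -sk.h + iz * sk.cellC;
              double dz = std::max({bz - pz, pz - (bz + sk.cellC), 0.0});
              double dmin2 = dxy2 + dz * dz;
              if (dmin2 > maxcut * maxcut) continue;
              double dmin = std::sqrt(dmin2);
              double pmax = dmin > Rmax ? Rmax / dmin : 1.0;
              double lg = pmax < 1.0 ? std::log1p(-pmax) : 0.0;
              int e = e0;
              while (e < e1) {
                if (pmax < 1.0) {
                  double u = unif_rand();
                  e += (int)std::floor(std::log(u) / lg);
                  if (e >= e1) break;
                }
                int si = sk.entriesC[e];
                ++e;
                if (sk.damaged[si]) continue;
                int cl = sk.cls[si];
                double Rr = sk.Rsink[cl * sk.nS + s];
                if (Rr <= 0.0) continue;
                double ddx = px - sk.x[si], ddy = py - sk.y[si],
                       ddz = pz - sk.z[si];
                double d2 = ddx*ddx + ddy*ddy + ddz*ddz;
                double cut = cutSink[cl * S.nS + s];
                if (d2 > cut * cut) continue;
                double d = std::sqrt(d2);
                double pacc = Rr / std::max(d, Rr);
                double u2 = unif_rand();
                if (u2 * pmax >= pacc) continue;   // never reacts
                double ts = sampleIRTSink(d, Rr, Ds, u2 * pmax);
                if (ts < tmin) { tmin = ts; wi = i; wj = -1; wr = -1; wsink = si; }
              }
            }
          }
        }
      }
    }
    double dt = std::min(tmin, Trem);
    if (!R_FINITE(dt)) dt = Trem;
    diffuseAll(st, dt, S);
    t += dt;
    if (tmin > Trem) { cullEscapes(st, voxel_half, t, ev, hid); break; }
    if (voxel_half > 0) {
      bool gone = (wi >= 0 && !inVoxel(st, wi, voxel_half)) ||
                  (wj >= 0 && !inVoxel(st, wj, voxel_half));
      cullEscapes(st, voxel_half, t, ev, hid);
      if (gone) continue;   // winner escaped before its reaction time
    }
    if (wsink >= 0) {
      if (st.alive[wi] && !sk.damaged[wsink]) {
        sk.damaged[wsink] = 1;
        ev.push(hid, t, 1, -1, st.kind[wi], -1, wsink,
                st.x[wi], st.y[wi], st.z[wi]);
        st.kill(wi);
      }
    } else if (wi >= 0 && st.alive[wi] && st.alive[wj]) {
      placeProducts(st, S, wr, wi, wj, t, ev, hid);
    }
  }
}

// ---------------------------------------------------------------------------
// SBS: dynamic time step with minimum-time-step schedule and Brownian
// bridge compensation; every reaction totally diffusion-controlled.
static inline double schedMin(const std::vector<double>& bounds,
                              const std::vector<double>& steps, double t) {
  for (size_t i = 0; i < bounds.size(); ++i)
    if (t < bounds[i]) return steps[i];
  return steps.back();
}

static inline double dynStep(double r0, double Rt, double D, double omc) {
  double q = omc * r0 / Rt;
  if (q >= 1.0) return R_PosInf;
  double ei = erfc_inv(q);
  double a = (r0 - Rt) / (2.0 * ei);
  return a * a / D;
}

// exact probability that the radial coordinate of a free 3-D Brownian
// bridge from r0 to r1 over dt touches the absorbing radius R (Bessel-3
// bridge, image solution of u = r p); reduces to the familiar
// exp(-(r0-R)(r1-R)/(D dt)) when 4 D dt << r0 r1
static inline double bridgeProb(double r0, double r1, double R, double D,
                                double dt) {
  double x = D * dt;
  double num = std::exp(-(r0 - R) * (r1 - R) / x);
  double far = std::exp(-r0 * r1 / x);
  return (num - far) / (1.0 - far);
}

static void runSBS(State& st, const Scheme& S, Sinks& sk, double voxel_half,
                   double t_start, double t_end,
                   const std::vector<double>& bounds,
                   const std::vector<double>& steps,
                   double confidence, bool bridge, double bridge_cut,
                   Events& ev, int hid) {
  SpinCache spin(1.0);   // unused in SBS mode
  double omc = 1.0 - confidence;
  double eim = erfc_inv(omc);
  double t = t_start;
  std::vector<double> px0, py0, pz0;

  while (true) {
    cullEscapes(st, voxel_half, t, ev, hid);
    contactSweep(st, S, sk, spin, t, ev, hid, true);
    if (st.nAlive == 0 || t >= t_end) break;

    double floorStep = schedMin(bounds, steps, t);
    double tdyn = R_PosInf;
    bool anyReactive = false;
    int n = st.size();
    for (int i = 0; i < n; ++i) {
      if (!st.alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!st.alive[j]) continue;
        int r = S.rxn_of[st.kind[i] * S.nS + st.kind[j]];
        if (r < 0) continue;
        anyReactive = true;
        double d = dist(st, i, j);
        double r0 = d_eff(d, S.rc[r]);
        double Rt = S.Rt[r];
        if (r0 <= Rt) { tdyn = 0.0; continue; }
        double lb = (r0 - Rt) / (2.0 * eim);
        if (lb * lb / S.Drel[r] >= tdyn) continue;
        double ts = dynStep(r0, Rt, S.Drel[r], omc);
        if (ts < tdyn) tdyn = ts;
      }
      if (sk.any && sk.RmaxSpecies[st.kind[i]] > 0.0) {
        anyReactive = true;
        int s = st.kind[i];
        double dn = sk.nearest(st.x[i], st.y[i], st.z[i], s, 12.0);
        if (dn < 1e29) {
          double rq = dn + 2.0;
          sk.visit(st.x[i], st.y[i], st.z[i], rq, [&](int si, double d2) {
            if (sk.damaged[si]) return;
            double Rr = sk.Rsink[sk.cls[si] * sk.nS + s];
            if (Rr <= 0.0) return;
            double d = std::sqrt(d2);
            if (d <= Rr) { tdyn = 0.0; return; }
            double lb = (d - Rr) / (2.0 * eim);
            if (lb * lb / S.D[s] >= tdyn) return;
            double ts = dynStep(d, Rr, S.D[s], omc);
            if (ts < tdyn) tdyn = ts;
          });
        }
      }
    }
    double dt;
    if (!anyReactive) dt = floorStep;
    else dt = std::max(floorStep, tdyn);
    dt = std::min(dt, t_end - t);
    if (dt <= 0) dt = std::min(floorStep, t_end - t);

    px0.assign(st.x.begin(), st.x.end());
    py0.assign(st.y.begin(), st.y.end());
    pz0.assign(st.z.begin(), st.z.end());
    diffuseAll(st, dt, S);
    t += dt;
    cullEscapes(st, voxel_half, t, ev, hid);

    std::vector<ContactHit> hits;
    for (int i = 0; i < n; ++i) {
      if (!st.alive[i]) continue;
      for (int j = i + 1; j < n; ++j) {
        if (!st.alive[j]) continue;
        int r = S.rxn_of[st.kind[i] * S.nS + st.kind[j]];
        if (r < 0) continue;
        double rc = S.rc[r], Rt = S.Rt[r];
        double d1 = dist(st, i, j);
        double e1 = d_eff(d1, rc);
        if (e1 <= Rt) { hits.push_back({d1, i, j, r, -1}); continue; }
        if (!bridge) continue;
        double Ddt = S.Drel[r] * dt;
        // quick skip in the short-step regime where the bridge probability
        // is below 1e-4; in the long-step regime (4 D dt ~ r0 r1) the
        // exact form must be evaluated because far pairs retain R/r mass
        double thr = 9.21 * Ddt;   // -ln(1e-4)
        double sig6 = 6.0 * std::sqrt(2.0 * Ddt);
        double e1m = e1 - Rt;
        bool shortStep = e1 * std::max(e1 - sig6, Rt) > 5.0 * Ddt;
        if (shortStep && e1m * std::max(e1m - sig6, 0.0) > thr) continue;
        double dx0 = px0[i]-px0[j], dy0 = py0[i]-py0[j], dz0 = pz0[i]-pz0[j];
        double d0 = std::sqrt(dx0*dx0 + dy0*dy0 + dz0*dz0);
        double e0 = d_eff(d0, rc);
        if (e0 <= Rt) { hits.push_back({d1, i, j, r, -1}); continue; }
        if (shortStep && e1m * (e0 - Rt) > thr) continue;
        double p = bridgeProb(e0, e1, Rt, S.Drel[r], dt);
        if (unif_rand() < p) hits.push_back({d1, i, j, r, -1});
      }
      if (sk.any && sk.RmaxSpecies[st.kind[i]] > 0.0) {
        int s = st.kind[i];
        double margin = bridge ? 3.1 * std::sqrt(S.D[s] * dt) : 0.0;
        double rq = sk.RmaxSpecies[s] + margin;
        sk.visit(st.x[i], st.y[i], st.z[i], rq, [&](int si, double d2) {
          if (sk.damaged[si]) return;
          double Rr = sk.Rsink[sk.cls[si] * sk.nS + s];
          if (Rr <= 0.0) return;
          double d1 = std::sqrt(d2);
          if (d1 <= Rr) { hits.push_back({d1, i, -1, -1, si}); return; }
          if (!bridge) return;
          double dx0 = px0[i]-sk.x[si], dy0 = py0[i]-sk.y[si],
                 dz0 = pz0[i]-sk.z[si];
          double d0 = std::sqrt(dx0*dx0 + dy0*dy0 + dz0*dz0);
          if (d0 <= Rr) { hits.push_back({d1, i, -1, -1, si}); return; }
          double p = bridgeProb(d0, d1, Rr, S.D[s], dt);
          if (unif_rand() < p) hits.push_back({d1, i, -1, -1, si});
        });
      }
    }
    std::sort(hits.begin(), hits.end(),
              [](const ContactHit& a, const ContactHit& b) { return a.d < b.d; });
    for (const auto& hc : hits) {
      if (!st.alive[hc.i]) continue;
      if (hc.sink >= 0) {
        if (sk.damaged[hc.sink]) continue;
        sk.damaged[hc.sink] = 1;
        ev.push(hid, t, 1, -1, st.kind[hc.i], -1, hc.sink,
                st.x[hc.i], st.y[hc.i], st.z[hc.i]);
        st.kill(hc.i);
      } else if (st.alive[hc.j]) {
        placeProducts(st, S, hc.rxn, hc.i, hc.j, t, ev, hid);
      }
    }
  }
}

// ---------------------------------------------------------------------------
// batched driver: one call runs many independent histories (hist must be
// grouped); sink damage resets between histories.

// [[Rcpp::export]]
List cpp_run_chem(int method, NumericMatrix pos, IntegerVector kind,
                  IntegerVector hist, List scheme, List sinks,
                  double voxel_half, double t_start, double t_end,
                  double spin_weight, double cutoff_prob,
                  NumericVector sched_bounds, NumericVector sched_steps,
                  double confidence, bool bridge, double bridge_cut) {
  RNGScope rngScope;
  Scheme S = buildScheme(scheme);
  Sinks sk;
  {
    NumericMatrix spos = sinks["pos"];
    IntegerVector scls = sinks["cls"];
    NumericMatrix sR = sinks["R"];
    sk.build(spos, scls, sR, voxel_half > 0 ? voxel_half : 1.0);
    if (voxel_half <= 0) sk.any = false;
  }
  std::vector<double> bounds(sched_bounds.begin(), sched_bounds.end());
  std::vector<double> steps(sched_steps.begin(), sched_steps.end());
  Events ev;
  std::vector<int> fh; std::vector<int> fk;
  std::vector<double> fx, fy, fz;
  int nTot = pos.nrow();
  int i0 = 0;
  while (i0 < nTot) {
    int hid = hist[i0];
    int i1 = i0;
    while (i1 < nTot && hist[i1] == hid) ++i1;
    State st;
    for (int i = i0; i < i1; ++i)
      st.add(kind[i], pos(i,0), pos(i,1), pos(i,2));
    sk.reset();
    if (method == 0) {
      runIRT(st, S, sk, voxel_half, t_start, t_end, spin_weight,
             cutoff_prob, ev, hid);
    } else {
      runSBS(st, S, sk, voxel_half, t_start, t_end, bounds, steps,
             confidence, bridge, bridge_cut, ev, hid);
    }
    for (int i = 0; i < st.size(); ++i) if (st.alive[i]) {
      fh.push_back(hid); fk.push_back(st.kind[i]);
      fx.push_back(st.x[i]); fy.push_back(st.y[i]); fz.push_back(st.z[i]);
    }
    i0 = i1;
  }
  return List::create(
    _["events"] = ev.asList(),
    _["final_hist"] = IntegerVector(fh.begin(), fh.end()),
    _["final_kind"] = IntegerVector(fk.begin(), fk.end()),
    _["final_x"] = NumericVector(fx.begin(), fx.end()),
    _["final_y"] = NumericVector(fy.begin(), fy.end()),
    _["final_z"] = NumericVector(fz.begin(), fz.end()));
}

// ---------------------------------------------------------------------------
// two-particle Brownian trials of fixed duration: fraction with no
// encounter (protection-domain confidence check); within-substep passages
// recovered with the reflection-principle bridge on the radial coordinate.
// [[Rcpp::export]]
double cpp_two_particle_nonreact(double r0, double R, double D, double dt,
                                 int n_trials, int n_sub) {
  RNGScope rngScope;
  double h = dt / n_sub;
  double s = std::sqrt(2.0 * D * h);
  int nonreact = 0;
  for (int k = 0; k < n_trials; ++k) {
    double x = r0, y = 0.0, z = 0.0;
    double dprev = r0;
    bool hit = false;
    for (int m = 0; m < n_sub; ++m) {
      x += s * norm_rand(); y += s * norm_rand(); z += s * norm_rand();
      double d = std::sqrt(x*x + y*y + z*z);
      if (d <= R) { hit = true; break; }
      double far = std::exp(-dprev * d / (D * h));
      double p = (std::exp(-(dprev - R) * (d - R) / (D * h)) - far) / (1.0 - far);
      if (unif_rand() < p) { hit = true; break; }
      dprev = d;
    }
    if (!hit) nonreact++;
  }
  return (double)nonreact / n_trials;
}

// pinned 1-D Brownian bridge crossing oracle: paths from a to b over dt
// with variance rate 2D, barrier at 0; returns the crossing fraction.
// [[Rcpp::export]]
double cpp_bridge_mc(double a, double b, double D, double dt,
                     int n_paths, int n_sub) {
  RNGScope rngScope;
  double h = dt / n_sub;
  int crossed = 0;
  for (int k = 0; k < n_paths; ++k) {
    double x = a;
    bool hit = false;
    for (int m = 0; m < n_sub - 1; ++m) {
      double remain = (double)(n_sub - m);
      double mean = x + (b - x) / remain;
      double var = 2.0 * D * h * (remain - 1.0) / remain;
      x = mean + std::sqrt(var) * norm_rand();
      if (x <= 0.0) { hit = true; break; }
    }
    if (hit) crossed++;
  }
  return (double)crossed / n_paths;
}
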