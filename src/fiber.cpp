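// Fibre-bundle packing kernels: segment-segment distances, spatial-hash
// collision detection, repelling-force resolution, and the split/merge pass
// that keeps segment lengths in range and adjacent-segment angles bounded.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>
#include <climits>

using namespace Rcpp;

struct Vec3 {
  double x, y, z;
  Vec3(double x_ = 0, double y_ = 0, double z_ = 0) : x(x_), y(y_), z(z_) {}
  Vec3 operator+(const Vec3& o) const { return Vec3(x + o.x, y + o.y, z + o.z); }
  Vec3 operator-(const Vec3& o) const { return Vec3(x - o.x, y - o.y, z - o.z); }
  Vec3 operator*(double s) const { return Vec3(x * s, y * s, z * s); }
  double dot(const Vec3& o) const { return x * o.x + y * o.y + z * o.z; }
  double norm() const { return std::sqrt(dot(*this)); }
};

// Closest points between segments P0+s*(P1-P0), Q0+t*(Q1-Q0), s,t in [0,1].
// Returns squared distance; writes parameters to sOut/tOut.
static double segSegDist2(const Vec3& P0, const Vec3& P1,
                          const Vec3& Q0, const Vec3& Q1,
                          double& sOut, double& tOut) {
  const Vec3 d1 = P1 - P0, d2 = Q1 - Q0, r = P0 - Q0;
  const double a = d1.dot(d1), e = d2.dot(d2), f = d2.dot(r);
  double s, t;
  const double EPS = 1e-12;
  if (a <= EPS && e <= EPS) { s = t = 0.0; }
  else if (a <= EPS) { s = 0.0; t = std::min(1.0, std::max(0.0, f / e)); }
  else {
    const double c = d1.dot(r);
    if (e <= EPS) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
    else {
      const double b = d1.dot(d2), denom = a * e - b * b;
      s = (denom > EPS) ? std::min(1.0, std::max(0.0, (b * f - c * e) / denom)) : 0.0;
      t = (b * s + f) / e;
      if (t < 0.0) { t = 0.0; s = std::min(1.0, std::max(0.0, -c / a)); }
      else if (t > 1.0) { t = 1.0; s = std::min(1.0, std::max(0.0, (b - c) / a)); }
    }
  }
  const Vec3 cp = (P0 + d1 * s) - (Q0 + d2 * t);
  sOut = s; tOut = t;
  return cp.dot(cp);
}

static double angleBetween(const Vec3& u, const Vec3& v) {
  const double nu = u.norm(), nv = v.norm();
  if (nu < 1e-14 || nv < 1e-14) return 0.0;
  double c = u.dot(v) / (nu * nv);
  c = std::min(1.0, std::max(-1.0, c));
  return std::acos(c);
}

typedef std::vector<Vec3> Poly;

// One split/merge + angle-relaxation sweep cycle on a single polyline.
// Splits segments longer than lmax at their midpoint, merges a too-short
// segment with a neighbour when the combined length fits, and relaxes
// interior vertices whose adjacent-segment angle exceeds maxAng towards the
// midpoint of their neighbours.  Returns true when all constraints hold.
static bool relaxPolyline(Poly& p, double lmin, double lmax, double maxAng,
                          int maxSweeps, bool* topoChanged = 0,
                          double* maxMove = 0) {
  if (topoChanged) *topoChanged = false;
  if (maxMove) *maxMove = 0.0;
  for (int sweep = 0; sweep < maxSweeps; ++sweep) {
    // split overly long segments
    for (size_t i = 0; i + 1 < p.size(); ++i) {
      if ((p[i + 1] - p[i]).norm() > lmax) {
        p.insert(p.begin() + i + 1, (p[i] + p[i + 1]) * 0.5);
        if (topoChanged) *topoChanged = true;
      }
    }
    // merge / repair too-short segments
    for (size_t i = 0; i + 1 < p.size() && p.size() > 2; ++i) {
      const double len = (p[i + 1] - p[i]).norm();
      if (len >= lmin) continue;
      bool merged = false;
      // prefer removing an interior shared vertex when the union fits
      if (i + 2 < p.size()) {
        if ((p[i + 2] - p[i]).norm() <= lmax) {
          p.erase(p.begin() + i + 1); merged = true;
        }
      }
      if (!merged && i > 0) {
        if ((p[i + 1] - p[i - 1]).norm() <= lmax) {
          p.erase(p.begin() + i); merged = true;
        }
      }
      if (!merged && i > 0 && i + 1 < p.size()) {
        // cannot merge: slide the shared vertex to even out lengths
        const Vec3 mid = (p[i - 1] + p[i + 1]) * 0.5;
        if (maxMove) *maxMove = std::max(*maxMove, (mid - p[i]).norm());
        p[i] = mid;
      }
      if (merged && topoChanged) *topoChanged = true;
    }
    // angle relaxation at interior vertices
    bool angOk = true;
    for (size_t i = 1; i + 1 < p.size(); ++i) {
      const double ang = angleBetween(p[i] - p[i - 1], p[i + 1] - p[i]);
      if (ang > maxAng) {
        angOk = false;
        const Vec3 mid = (p[i - 1] + p[i + 1]) * 0.5;
        const Vec3 step = (mid - p[i]) * 0.5;
        if (maxMove) *maxMove = std::max(*maxMove, step.norm());
        p[i] = p[i] + step;
      }
    }
    // verify all constraints
    bool ok = angOk;
    if (ok) {
      for (size_t i = 0; i + 1 < p.size(); ++i) {
        const double len = (p[i + 1] - p[i]).norm();
        if (len < lmin - 1e-9 || len > lmax + 1e-9) { ok = false; break; }
      }
    }
    if (ok) return true;
  }
  return false;
}

struct SegRef { int fiber; int seg; };

static inline int64_t hashKey(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix) * 73856093LL) ^
         (static_cast<int64_t>(iy) * 19349663LL) ^
         (static_cast<int64_t>(iz) * 83492791LL);
}

struct SegBox { Vec3 lo, hi; };

static inline SegBox segBox(const Vec3& a, const Vec3& b, double r) {
  SegBox s;
  s.lo = Vec3(std::min(a.x, b.x) - r, std::min(a.y, b.y) - r,
              std::min(a.z, b.z) - r);
  s.hi = Vec3(std::max(a.x, b.x) + r, std::max(a.y, b.y) + r,
              std::max(a.z, b.z) + r);
  return s;
}

static inline bool boxOverlap(const SegBox& a, const SegBox& b) {
  return a.lo.x <= b.hi.x && b.lo.x <= a.hi.x &&
         a.lo.y <= b.hi.y && b.lo.y <= a.hi.y &&
         a.lo.z <= b.hi.z && b.lo.z <= a.hi.z;
}

static std::vector<Poly> listToPolys(const List& ptsList) {
  std::vector<Poly> polys(ptsList.size());
  for (int f = 0; f < ptsList.size(); ++f) {
    NumericMatrix m = ptsList[f];
    Poly p(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) p[i] = Vec3(m(i, 0), m(i, 1), m(i, 2));
    polys[f] = p;
  }
  return polys;
}

static List polysToList(const std::vector<Poly>& polys) {
  List out(polys.size());
  for (size_t f = 0; f < polys.size(); ++f) {
    NumericMatrix m(polys[f].size(), 3);
    for (size_t i = 0; i < polys[f].size(); ++i) {
      m(i, 0) = polys[f][i].x; m(i, 1) = polys[f][i].y; m(i, 2) = polys[f][i].z;
    }
    out[f] = m;
  }
  return out;
}

// Broad-phase: spatial hash on segment midpoints; cell edge must be at least
// max segment length + 2 * max radius so touching pairs share a neighbourhood.
// Only fibres flagged dirty are queried (their pairs against everything),
// with an AABB prefilter ahead of the exact capsule distance.
static void detectCollisions(const std::vector<Poly>& polys,
                             const std::vector<double>& rad,
                             const std::vector<char>& dirty,
                             double cell,
                             std::vector<std::pair<SegRef, SegRef> >& pairs) {
  pairs.clear();
  std::unordered_map<int64_t, std::vector<SegRef> > grid;
  for (size_t f = 0; f < polys.size(); ++f) {
    for (size_t s = 0; s + 1 < polys[f].size(); ++s) {
      const Vec3 mid = (polys[f][s] + polys[f][s + 1]) * 0.5;
      SegRef ref; ref.fiber = (int)f; ref.seg = (int)s;
      grid[hashKey((int)std::floor(mid.x / cell),
                   (int)std::floor(mid.y / cell),
                   (int)std::floor(mid.z / cell))].push_back(ref);
    }
  }
  for (size_t f = 0; f < polys.size(); ++f) {
    if (!dirty[f]) continue;
    for (size_t s = 0; s + 1 < polys[f].size(); ++s) {
      const SegBox bb = segBox(polys[f][s], polys[f][s + 1], rad[f]);
      const Vec3 mid = (polys[f][s] + polys[f][s + 1]) * 0.5;
      const int cx = (int)std::floor(mid.x / cell);
      const int cy = (int)std::floor(mid.y / cell);
      const int cz = (int)std::floor(mid.z / cell);
      for (int dx = -1; dx <= 1; ++dx)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dz = -1; dz <= 1; ++dz) {
            std::unordered_map<int64_t, std::vector<SegRef> >::const_iterator it =
              grid.find(hashKey(cx + dx, cy + dy, cz + dz));
            if (it == grid.end()) continue;
            for (size_t q = 0; q < it->second.size(); ++q) {
              const SegRef& o = it->second[q];
              if (o.fiber == (int)f) {
                if (o.seg <= (int)s + 2) continue;      // self: skip adjacent
              } else if (dirty[o.fiber]) {
                if (o.fiber < (int)f) continue;         // both dirty: once
              }
              const SegBox ob = segBox(polys[o.fiber][o.seg],
                                       polys[o.fiber][o.seg + 1],
                                       rad[o.fiber]);
              if (!boxOverlap(bb, ob)) continue;
              double st, tt;
              const double d2 = segSegDist2(polys[f][s], polys[f][s + 1],
                                            polys[o.fiber][o.seg],
                                            polys[o.fiber][o.seg + 1], st, tt);
              const double rsum = rad[f] + rad[o.fiber];
              if (d2 < rsum * rsum) {
                SegRef a; a.fiber = (int)f; a.seg = (int)s;
                pairs.push_back(std::make_pair(a, o));
              }
            }
          }
    }
  }
}

// Candidate neighbour pairs within rsum + skin.  Valid until cumulative
// vertex motion exceeds skin / 2 or any fibre changes topology (split/merge
// renumbers segments).  Broad phase: a flat 3D grid; each segment is
// inserted into every cell its inflated AABB covers, pairs are enumerated
// per cell and deduplicated by a canonical-cell rule on the AABB overlap.
static void buildCandidates(const std::vector<Poly>& polys,
                            const std::vector<double>& radFull,
                            double skin,
                            std::vector<std::pair<SegRef, SegRef> >& cand) {
  cand.clear();
  struct Ent {
    int f, s;
    double xlo, xhi, ylo, yhi, zlo, zhi; // AABB inflated by r + skin/2
  };
  std::vector<Ent> ents;
  double xMin = R_PosInf, yMin = R_PosInf, zMin = R_PosInf;
  double xMax = R_NegInf, yMax = R_NegInf, zMax = R_NegInf;
  for (size_t f = 0; f < polys.size(); ++f) {
    const double reach = radFull[f] + 0.5 * skin;
    for (size_t s = 0; s + 1 < polys[f].size(); ++s) {
      const Vec3& a = polys[f][s];
      const Vec3& b = polys[f][s + 1];
      Ent e;
      e.f = (int)f; e.s = (int)s;
      e.xlo = std::min(a.x, b.x) - reach; e.xhi = std::max(a.x, b.x) + reach;
      e.ylo = std::min(a.y, b.y) - reach; e.yhi = std::max(a.y, b.y) + reach;
      e.zlo = std::min(a.z, b.z) - reach; e.zhi = std::max(a.z, b.z) + reach;
      xMin = std::min(xMin, e.xlo); xMax = std::max(xMax, e.xhi);
      yMin = std::min(yMin, e.ylo); yMax = std::max(yMax, e.yhi);
      zMin = std::min(zMin, e.zlo); zMax = std::max(zMax, e.zhi);
      ents.push_back(e);
    }
  }
  const double cell = 3.0;
  const int nxc = std::max(1, (int)std::ceil((xMax - xMin) / cell));
  const int nyc = std::max(1, (int)std::ceil((yMax - yMin) / cell));
  const int nzc = std::max(1, (int)std::ceil((zMax - zMin) / cell));
  const size_t ncell = (size_t)nxc * nyc * nzc;
  std::vector<int> count(ncell + 1, 0);
  struct Rng { int x0, x1, y0, y1, z0, z1; };
  std::vector<Rng> rng(ents.size());
  for (size_t q = 0; q < ents.size(); ++q) {
    Rng& r = rng[q];
    r.x0 = std::min(nxc - 1, std::max(0, (int)((ents[q].xlo - xMin) / cell)));
    r.x1 = std::min(nxc - 1, std::max(0, (int)((ents[q].xhi - xMin) / cell)));
    r.y0 = std::min(nyc - 1, std::max(0, (int)((ents[q].ylo - yMin) / cell)));
    r.y1 = std::min(nyc - 1, std::max(0, (int)((ents[q].yhi - yMin) / cell)));
    r.z0 = std::min(nzc - 1, std::max(0, (int)((ents[q].zlo - zMin) / cell)));
    r.z1 = std::min(nzc - 1, std::max(0, (int)((ents[q].zhi - zMin) / cell)));
    for (int cx = r.x0; cx <= r.x1; ++cx)
      for (int cy = r.y0; cy <= r.y1; ++cy)
        for (int cz = r.z0; cz <= r.z1; ++cz)
          ++count[((size_t)cx * nyc + cy) * nzc + cz + 1];
  }
  for (size_t c = 0; c < ncell; ++c) count[c + 1] += count[c];
  std::vector<int> items(count[ncell]);
  {
    std::vector<int> fill(count.begin(), count.end() - 1);
    for (size_t q = 0; q < ents.size(); ++q)
      for (int cx = rng[q].x0; cx <= rng[q].x1; ++cx)
        for (int cy = rng[q].y0; cy <= rng[q].y1; ++cy)
          for (int cz = rng[q].z0; cz <= rng[q].z1; ++cz)
            items[fill[((size_t)cx * nyc + cy) * nzc + cz]++] = (int)q;
  }
  for (size_t c = 0; c < ncell; ++c) {
    const int ccx = (int)(c / ((size_t)nyc * nzc));
    const int ccy = (int)((c / nzc) % nyc);
    const int ccz = (int)(c % nzc);
    for (int u = count[c]; u < count[c + 1]; ++u) {
      const Ent& A = ents[items[u]];
      for (int v = u + 1; v < count[c + 1]; ++v) {
        const Ent& B = ents[items[v]];
        if (A.f == B.f && std::abs(A.s - B.s) <= 2) continue;
        if (A.xlo > B.xhi || B.xlo > A.xhi) continue;
        if (A.ylo > B.yhi || B.ylo > A.yhi) continue;
        if (A.zlo > B.zhi || B.zlo > A.zhi) continue;
        // canonical cell of the AABB overlap: count the pair once
        const double ox = std::max(A.xlo, B.xlo);
        const double oy = std::max(A.ylo, B.ylo);
        const double oz = std::max(A.zlo, B.zlo);
        const int kx = std::min(nxc - 1, std::max(0, (int)((ox - xMin) / cell)));
        const int ky = std::min(nyc - 1, std::max(0, (int)((oy - yMin) / cell)));
        const int kz = std::min(nzc - 1, std::max(0, (int)((oz - zMin) / cell)));
        if (kx != ccx || ky != ccy || kz != ccz) continue;
        double st, tt;
        const double d2 = segSegDist2(polys[A.f][A.s], polys[A.f][A.s + 1],
                                      polys[B.f][B.s], polys[B.f][B.s + 1],
                                      st, tt);
        const double lim = radFull[A.f] + radFull[B.f] + skin;
        if (d2 < lim * lim) {
          SegRef a, b;
          if (A.f < B.f || (A.f == B.f && A.s < B.s)) {
            a.fiber = A.f; a.seg = A.s; b.fiber = B.f; b.seg = B.s;
          } else {
            a.fiber = B.f; a.seg = B.s; b.fiber = A.f; b.seg = A.s;
          }
          cand.push_back(std::make_pair(a, b));
        }
      }
    }
  }
}

// Force-biased packing: fibre radii are grown in stages from a fraction of
// their final value to the full value; at each stage colliding segment pairs
// are pushed apart along their closest-approach direction (displacements
// tapered along the fibre to keep it smooth) and the length/angle
// constraints are re-established, until the stage is collision-free.
// [[Rcpp::export]]
List cpp_pack_bundle(List ptsList, NumericVector radii,
                     double lmin, double lmax, double maxAngleDeg,
                     int iterationBudget, double marginFrac,
                     int relaxSweeps, bool useGrowth, int polishRounds,
                     double skin) {
  std::vector<Poly> polys = listToPolys(ptsList);
  const int nf = (int)polys.size();
  std::vector<double> radFull(radii.begin(), radii.end());
  const double maxAng = maxAngleDeg * M_PI / 180.0;
  double rmax = 0.0;
  for (int f = 0; f < nf; ++f) rmax = std::max(rmax, radFull[f]);
  const double cell = lmax + 2.0 * rmax + skin;

  for (int f = 0; f < nf; ++f)
    relaxPolyline(polys[f], lmin, lmax, maxAng, 200);

  const double scalesG[] = {0.30, 0.37, 0.44, 0.51, 0.58, 0.65, 0.72,
                            0.79, 0.86, 0.92, 0.97, 1.00};
  const double scales1[] = {1.0};
  const double* scales = useGrowth ? scalesG : scales1;
  const int nScales = useGrowth ? 12 : 1;
  std::vector<std::pair<SegRef, SegRef> > cand, pairs;
  std::vector<char> dirty(nf, 1);
  std::vector<double> rad(nf);
  int iter = 0, ncol = 0;
  bool out = false;
  double accumMove = skin;  // force initial build

  // after the growth stages, gentle smoothing "polish" rounds strip the
  // high-frequency wiggles injected by the collision pushes (followed each
  // time by another resolution pass at full radius)
  for (int phase = 0; phase < nScales + polishRounds && !out; ++phase) {
    const double scale = (phase < nScales) ? scales[phase] : 1.0;
    for (int f = 0; f < nf; ++f) rad[f] = radFull[f] * scale;
    if (phase >= nScales) {
      for (int f = 0; f < nf; ++f) {
        Poly& p = polys[f];
        if (p.size() > 2) {
          Poly q = p;
          for (size_t i = 1; i + 1 < p.size(); ++i)
            q[i] = p[i] + ((p[i - 1] + p[i + 1]) * 0.5 - p[i]) * 0.3;
          p.swap(q);
        }
        relaxPolyline(p, lmin, lmax, maxAng, 100);
      }
      accumMove = skin;
    }
    std::fill(dirty.begin(), dirty.end(), 1);
    int best = INT_MAX, sinceBest = 0;
    double boost = 1.0;
    std::vector<char> roundDirty(nf, 0);
    for (bool done = false; !done && !out;) {
      // repulsion-only sweeps: push colliding pairs apart without the
      // constraint repair fighting back in between
      std::fill(roundDirty.begin(), roundDirty.end(), 0);
      int firstCount = -1;
      for (int inner = 0; inner < 40; ++inner, ++iter) {
        if (iter >= iterationBudget) { out = true; break; }
        if (accumMove > 0.5 * skin) {
          buildCandidates(polys, radFull, skin, cand);
          accumMove = 0.0;
        }
        // narrow phase on the cached candidates: a pair can only newly
        // collide if one of its fibres moved since the last check
        pairs.clear();
        for (size_t p = 0; p < cand.size(); ++p) {
          const SegRef& A = cand[p].first;
          const SegRef& B = cand[p].second;
          if (!dirty[A.fiber] && !dirty[B.fiber]) continue;
          double st, tt;
          const double d2 = segSegDist2(
            polys[A.fiber][A.seg], polys[A.fiber][A.seg + 1],
            polys[B.fiber][B.seg], polys[B.fiber][B.seg + 1], st, tt);
          const double rsum = rad[A.fiber] + rad[B.fiber];
          if (d2 < rsum * rsum) pairs.push_back(cand[p]);
        }
        ncol = (int)pairs.size();
        if (inner == 0) firstCount = ncol;
        if (ncol == 0) break;
        bool jiggle = false;
        if (ncol < best) { best = ncol; sinceBest = 0; boost = 1.0; }
        else if (++sinceBest > 25) { boost = std::min(8.0, boost * 1.5);
                                     sinceBest = 0; jiggle = boost > 2.0; }
        std::vector<std::vector<Vec3> > disp(nf);
        std::vector<std::vector<double> > wsum(nf);
        for (int f = 0; f < nf; ++f) {
          disp[f].assign(polys[f].size(), Vec3());
          wsum[f].assign(polys[f].size(), 0.0);
        }
        for (size_t p = 0; p < pairs.size(); ++p) {
          const SegRef& A = pairs[p].first;
          const SegRef& B = pairs[p].second;
          double s, t;
          const double d2 = segSegDist2(
            polys[A.fiber][A.seg], polys[A.fiber][A.seg + 1],
            polys[B.fiber][B.seg], polys[B.fiber][B.seg + 1], s, t);
          const double d = std::sqrt(d2);
          const double rsum = rad[A.fiber] + rad[B.fiber];
          Vec3 u;
          if (d > 1e-9) {
            const Vec3 ca = polys[A.fiber][A.seg] +
              (polys[A.fiber][A.seg + 1] - polys[A.fiber][A.seg]) * s;
            const Vec3 cb = polys[B.fiber][B.seg] +
              (polys[B.fiber][B.seg + 1] - polys[B.fiber][B.seg]) * t;
            u = (ca - cb) * (1.0 / d);
          } else {
            u = Vec3(0.0, 1.0, 0.0); // coincident axes: deterministic fallback
          }
          const double push = (0.5 * (rsum - d) + marginFrac * rsum) * boost;
          if (jiggle) {
            // opposing pushes on a pinched fibre can cancel exactly; a
            // deterministic jitter breaks such deadlocks
            const int64_t h = hashKey(A.fiber * 131 + A.seg,
                                      B.fiber * 131 + B.seg, iter);
            const double a1 = (double)(h & 0xffff) / 65536.0 * 2.0 * M_PI;
            const double a2 = (double)((h >> 16) & 0xffff) / 65536.0 * M_PI;
            const Vec3 j(std::cos(a1) * std::sin(a2),
                         std::sin(a1) * std::sin(a2), std::cos(a2));
            const double jm = 0.15 * rsum;
            disp[A.fiber][A.seg] = disp[A.fiber][A.seg] + j * jm;
            wsum[A.fiber][A.seg] += 0.0;
            disp[B.fiber][B.seg] = disp[B.fiber][B.seg] - j * jm;
            wsum[B.fiber][B.seg] += 0.0;
          }
          // taper the push along each fibre to keep it smooth
          for (int e = -2; e <= 3; ++e) {
            const double w = (e == 0 || e == 1) ? 1.0 :
                             (e == -1 || e == 2) ? 0.5 : 0.25;
            const int ia = A.seg + e;
            if (ia >= 0 && ia < (int)polys[A.fiber].size()) {
              disp[A.fiber][ia] = disp[A.fiber][ia] + u * (push * w);
              wsum[A.fiber][ia] += w;
            }
            const int ib = B.seg + e;
            if (ib >= 0 && ib < (int)polys[B.fiber].size()) {
              disp[B.fiber][ib] = disp[B.fiber][ib] - u * (push * w);
              wsum[B.fiber][ib] += w;
            }
          }
        }
        std::fill(dirty.begin(), dirty.end(), 0);
        double stepMove = 0.0;
        const double dmax = 0.35;  // cap per-iteration vertex motion
        for (int f = 0; f < nf; ++f) {
          for (size_t i = 0; i < polys[f].size(); ++i) {
            if (wsum[f][i] > 0) {
              Vec3 d = disp[f][i] * (1.0 / wsum[f][i]);
              const double dn = d.norm();
              if (dn > dmax) d = d * (dmax / dn);
              stepMove = std::max(stepMove, std::min(dn, dmax));
              polys[f][i] = polys[f][i] + d;
              dirty[f] = 1;
              roundDirty[f] = 1;
            }
          }
        }
        accumMove += stepMove;
        if (iter % 64 == 0) Rcpp::checkUserInterrupt();
      }
      if (out) break;
      if (firstCount == 0) { done = true; break; }
      // constraint repair on the fibres the round touched
      double mvmax = 0.0;
      bool topo = false;
      std::fill(dirty.begin(), dirty.end(), 0);
      for (int f = 0; f < nf; ++f) {
        if (!roundDirty[f]) continue;
        bool tp; double mv;
        relaxPolyline(polys[f], lmin, lmax, maxAng, 100, &tp, &mv);
        topo = topo || tp;
        mvmax = std::max(mvmax, mv);
        dirty[f] = 1;
      }
      accumMove += mvmax;
      if (topo) accumMove = skin;  // segment renumbering: force rebuild
    }
  }

  // final pass: fully re-establish constraints, then re-verify collisions
  for (int rep = 0; rep < 5 && !out; ++rep) {
    for (int f = 0; f < nf; ++f)
      relaxPolyline(polys[f], lmin, lmax, maxAng, 200);
    std::fill(dirty.begin(), dirty.end(), 1);
    detectCollisions(polys, radFull, dirty, cell, pairs);
    ncol = (int)pairs.size();
    if (ncol == 0) break;
    // small residual overlaps from the final relax: one more repel round
    for (size_t p = 0; p < pairs.size(); ++p) {
      const SegRef& A = pairs[p].first;
      const SegRef& B = pairs[p].second;
      double s, t;
      const double d2 = segSegDist2(
        polys[A.fiber][A.seg], polys[A.fiber][A.seg + 1],
        polys[B.fiber][B.seg], polys[B.fiber][B.seg + 1], s, t);
      const double d = std::sqrt(d2);
      const double rsum = radFull[A.fiber] + radFull[B.fiber];
      Vec3 u(0.0, 1.0, 0.0);
      if (d > 1e-9) {
        const Vec3 ca = polys[A.fiber][A.seg] +
          (polys[A.fiber][A.seg + 1] - polys[A.fiber][A.seg]) * s;
        const Vec3 cb = polys[B.fiber][B.seg] +
          (polys[B.fiber][B.seg + 1] - polys[B.fiber][B.seg]) * t;
        u = (ca - cb) * (1.0 / d);
      }
      const double push = 0.5 * (rsum - d) + marginFrac * rsum;
      for (int e = 0; e < 2; ++e) {
        polys[A.fiber][A.seg + e] = polys[A.fiber][A.seg + e] + u * push;
        polys[B.fiber][B.seg + e] = polys[B.fiber][B.seg + e] - u * push;
      }
    }
  }
  return List::create(_["points"] = polysToList(polys),
                      _["iterations"] = iter,
                      _["collisions"] = ncol);
}

// [[Rcpp::export]]
List cpp_relax_fibers(List ptsList, double lmin, double lmax,
                      double maxAngleDeg, int relaxSweeps) {
  std::vector<Poly> polys = listToPolys(ptsList);
  const double maxAng = maxAngleDeg * M_PI / 180.0;
  LogicalVector ok(polys.size());
  for (size_t f = 0; f < polys.size(); ++f)
    ok[f] = relaxPolyline(polys[f], lmin, lmax, maxAng, relaxSweeps);
  return List::create(_["points"] = polysToList(polys), _["converged"] = ok);
}

// ---- independent brute-force oracle ----------------------------------------
// All-pairs capsule check, with the minimum distance computed by a different
// route than the packing kernel: candidate enumeration over the interior
// critical point and the four clamped edge minimisers of the quadratic
// |P(s) - Q(t)|^2 on the unit square.
static double edgeMin1D(const Vec3& base, const Vec3& dir, const Vec3& point) {
  // min over u in [0,1] of |base + u*dir - point|^2
  const Vec3 w = base - point;
  const double dd = dir.dot(dir);
  double u = (dd > 1e-14) ? -w.dot(dir) / dd : 0.0;
  u = std::min(1.0, std::max(0.0, u));
  const Vec3 v = w + dir * u;
  return v.dot(v);
}

static double oracleDist2(const Vec3& P0, const Vec3& P1,
                          const Vec3& Q0, const Vec3& Q1) {
  const Vec3 d1 = P1 - P0, d2 = Q1 - Q0;
  double best = R_PosInf;
  // interior critical point of the bilinear quadratic
  const double a = d1.dot(d1), b = d1.dot(d2), e = d2.dot(d2);
  const Vec3 r = P0 - Q0;
  const double c = d1.dot(r), f = d2.dot(r);
  const double det = a * e - b * b;
  if (det > 1e-14) {
    const double s = (b * f - c * e) / det;
    const double t = (a * f - b * c) / det;
    if (s >= 0.0 && s <= 1.0 && t >= 0.0 && t <= 1.0) {
      const Vec3 v = (P0 + d1 * s) - (Q0 + d2 * t);
      best = std::min(best, v.dot(v));
    }
  }
  // four edges: s=0, s=1 (vary t); t=0, t=1 (vary s)
  best = std::min(best, edgeMin1D(Q0, d2, P0));
  best = std::min(best, edgeMin1D(Q0, d2, P1));
  best = std::min(best, edgeMin1D(P0, d1, Q0));
  best = std::min(best, edgeMin1D(P0, d1, Q1));
  return best;
}

// [[Rcpp::export]]
List cpp_collisions_bruteforce(List ptsList, NumericVector radii,
                               double tol) {
  std::vector<Poly> polys = listToPolys(ptsList);
  const int nf = (int)polys.size();
  long long count = 0;
  double worst = R_PosInf; // most negative clearance
  for (int f = 0; f < nf; ++f) {
    for (size_t s = 0; s + 1 < polys[f].size(); ++s) {
      for (int g = f; g < nf; ++g) {
        const size_t t0 = (g == f) ? s + 3 : 0;
        for (size_t t = t0; t + 1 < polys[g].size(); ++t) {
          const double d2 = oracleDist2(polys[f][s], polys[f][s + 1],
                                        polys[g][t], polys[g][t + 1]);
          const double clear2 = std::sqrt(d2) - (radii[f] + radii[g]);
          if (clear2 < -tol) ++count;
          if (clear2 < worst) worst = clear2;
        }
      }
    }
    if (f % 16 == 0) Rcpp::checkUserInterrupt();
  }
  return List::create(_["count"] = (double)count, _["minClearance"] = worst);
}

// [[Rcpp::export]]
int cpp_count_collisions(List ptsList, NumericVector radii, double lmax) {
  std::vector<Poly> polys = listToPolys(ptsList);
  std::vector<double> rad(radii.begin(), radii.end());
  double rmax = 0.0;
  for (size_t f = 0; f < rad.size(); ++f) rmax = std::max(rmax, rad[f]);
  std::vector<std::pair<SegRef, SegRef> > pairs;
  std::vector<char> dirty(polys.size(), 1);
  detectCollisions(polys, rad, dirty, lmax + 2.0 * rmax, pairs);
  return (int)pairs.size();
}

// Force-biased packing of the seed circles in the lateral plane: every
// overlapping pair is pushed apart along its centre line by half the
// overlap until the cross-sections are disjoint.
// [[Rcpp::export]]
NumericMatrix cpp_pack_circles(NumericMatrix yz, NumericVector r,
                               int maxIter) {
  const int n = yz.nrow();
  std::vector<double> y(n), z(n);
  for (int i = 0; i < n; ++i) { y[i] = yz(i, 0); z[i] = yz(i, 1); }
  std::vector<double> dy(n), dz(n);
  for (int it = 0; it < maxIter; ++it) {
    std::fill(dy.begin(), dy.end(), 0.0);
    std::fill(dz.begin(), dz.end(), 0.0);
    long ov = 0;
    for (int i = 0; i < n; ++i) {
      for (int j = i + 1; j < n; ++j) {
        const double rs = r[i] + r[j];
        const double ddy = y[i] - y[j], ddz = z[i] - z[j];
        const double d2 = ddy * ddy + ddz * ddz;
        if (d2 >= rs * rs) continue;
        ++ov;
        double d = std::sqrt(d2);
        double uy = 1.0, uz = 0.0;
        if (d > 1e-9) { uy = ddy / d; uz = ddz / d; }
        const double push = 0.5 * (rs - d);
        dy[i] += uy * push; dz[i] += uz * push;
        dy[j] -= uy * push; dz[j] -= uz * push;
      }
    }
    if (ov == 0) break;
    for (int i = 0; i < n; ++i) { y[i] += dy[i]; z[i] += dz[i]; }
    if (it % 256 == 0) Rcpp::checkUserInterrupt();
  }
  NumericMatrix out(n, 2);
  for (int i = 0; i < n; ++i) { out(i, 0) = y[i]; out(i, 1) = z[i]; }
  return out;
}
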