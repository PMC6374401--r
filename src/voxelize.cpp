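// Staircase voxelization of a fibre bundle into a refractive-index grid:
// each voxel centre is assigned by radial distance to the nearest fibre axis
// (axon core / inner myelin / glycerine / outer myelin concentric shells),
// with all fibre diameters shrunk by a configured fraction beforehand.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <unordered_map>
#include <cstdint>

using namespace Rcpp;

namespace {

struct V3 { double x, y, z; };

inline double pointSegDist2(const V3& p, const V3& a, const V3& b) {
  const double dx = b.x - a.x, dy = b.y - a.y, dz = b.z - a.z;
  const double wx = p.x - a.x, wy = p.y - a.y, wz = p.z - a.z;
  const double dd = dx * dx + dy * dy + dz * dz;
  double u = (dd > 1e-14) ? (wx * dx + wy * dy + wz * dz) / dd : 0.0;
  u = std::min(1.0, std::max(0.0, u));
  const double ex = wx - u * dx, ey = wy - u * dy, ez = wz - u * dz;
  return ex * ex + ey * ey + ez * ez;
}

inline int64_t key3(int ix, int iy, int iz) {
  return (static_cast<int64_t>(ix) * 73856093LL) ^
         (static_cast<int64_t>(iy) * 19349663LL) ^
         (static_cast<int64_t>(iz) * 83492791LL);
}

} // namespace

// [[Rcpp::export]]
NumericVector cpp_voxelize(List ptsList, NumericVector radii,
                           double shrinkFraction,
                           double axonFrac, double myelinFrac, double glycFrac,
                           double nAxon, double nMyelin, double nGlyc,
                           double nSurround,
                           NumericVector origin, IntegerVector dims,
                           double voxel) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  NumericVector out(static_cast<R_xlen_t>(nx) * ny * nz, nSurround);

  // shell boundaries as fractions of the shrunk radius r':
  // [0, axonFrac) axon, then myelin, glycerine, myelin out to 1
  const double sheath = 1.0 - axonFrac;
  const double b1 = axonFrac;
  const double b2 = axonFrac + sheath * myelinFrac;
  const double b3 = axonFrac + sheath * (myelinFrac + glycFrac);

  // spatial hash of segments (cell edge >= max reach)
  const int nf = ptsList.size();
  double rmax = 0.0;
  for (int f = 0; f < nf; ++f)
    rmax = std::max(rmax, radii[f] * (1.0 - shrinkFraction));
  double segmax = 0.0;
  std::vector<std::vector<V3> > polys(nf);
  for (int f = 0; f < nf; ++f) {
    NumericMatrix m = ptsList[f];
    polys[f].resize(m.nrow());
    for (int i = 0; i < m.nrow(); ++i) {
      polys[f][i].x = m(i, 0); polys[f][i].y = m(i, 1); polys[f][i].z = m(i, 2);
      if (i > 0) {
        const double dx = polys[f][i].x - polys[f][i - 1].x;
        const double dy = polys[f][i].y - polys[f][i - 1].y;
        const double dz = polys[f][i].z - polys[f][i - 1].z;
        segmax = std::max(segmax, std::sqrt(dx * dx + dy * dy + dz * dz));
      }
    }
  }
  const double cell = std::max(segmax + 2.0 * rmax, voxel * 4.0);
  struct SegId { int f; int s; };
  std::unordered_map<int64_t, std::vector<SegId> > grid;
  for (int f = 0; f < nf; ++f) {
    for (size_t s = 0; s + 1 < polys[f].size(); ++s) {
      const double mx = 0.5 * (polys[f][s].x + polys[f][s + 1].x);
      const double my = 0.5 * (polys[f][s].y + polys[f][s + 1].y);
      const double mz = 0.5 * (polys[f][s].z + polys[f][s + 1].z);
      SegId id; id.f = f; id.s = (int)s;
      grid[key3((int)std::floor(mx / cell), (int)std::floor(my / cell),
                (int)std::floor(mz / cell))].push_back(id);
    }
  }

  for (int k = 0; k < nz; ++k) {
    for (int j = 0; j < ny; ++j) {
      for (int i = 0; i < nx; ++i) {
        V3 p;
        p.x = origin[0] + (i + 0.5) * voxel;
        p.y = origin[1] + (j + 0.5) * voxel;
        p.z = origin[2] + (k + 0.5) * voxel;
        // nearest fibre in units of its shrunk radius
        double bestRel = R_PosInf;
        const int cx = (int)std::floor(p.x / cell);
        const int cy = (int)std::floor(p.y / cell);
        const int cz = (int)std::floor(p.z / cell);
        for (int dx = -1; dx <= 1; ++dx)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dz = -1; dz <= 1; ++dz) {
              std::unordered_map<int64_t, std::vector<SegId> >::const_iterator it =
                grid.find(key3(cx + dx, cy + dy, cz + dz));
              if (it == grid.end()) continue;
              for (size_t q = 0; q < it->second.size(); ++q) {
                const SegId& id = it->second[q];
                const double rp = radii[id.f] * (1.0 - shrinkFraction);
                const double d2 = pointSegDist2(p, polys[id.f][id.s],
                                                polys[id.f][id.s + 1]);
                const double rel = std::sqrt(d2) / rp;
                if (rel < bestRel) bestRel = rel;
              }
            }
        if (bestRel < 1.0) {
          double val;
          if (bestRel < b1) val = nAxon;
          else if (bestRel < b2) val = nMyelin;
          else if (bestRel < b3) val = nGlyc;
          else val = nMyelin;
          out[static_cast<R_xlen_t>(k) * nx * ny +
              static_cast<R_xlen_t>(j) * nx + i] = val;
        }
      }
    }
    if (k % 32 == 0) Rcpp::checkUserInterrupt();
  }
  out.attr("dim") = IntegerVector::create(nx, ny, nz);
  return out;
}
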