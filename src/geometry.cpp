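#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>

using namespace Rcpp;

// Geometry kernel for circular-buffer zonal statistics on polygon layers.
//
// The disk of radius r is represented as a regular inscribed n-gon (default
// n = 256, area deficit ~1e-4 relative). The intersection area between the
// union of a set of simple polygons and that disk polygon is computed exactly
// (up to the n-gon approximation) by a slab decomposition: between two
// consecutive critical y-values (any vertex y or any y where two edges of
// different rings cross) the cross-section of the union is a set of intervals
// whose endpoints are linear in y and whose overlap structure is constant, so
// the union length is linear in y and midpoint evaluation integrates it
// exactly over the slab.

struct Seg {
  double x1, y1, x2, y2;
  int ring; // index of the ring this edge belongs to; disk ring = -1
};

static inline double cross(double ox, double oy, double ax, double ay,
                           double bx, double by) {
  return (ax - ox) * (by - oy) - (ay - oy) * (bx - ox);
}

// y-coordinates where two segments properly intersect (or touch); endpoint
// touches are harmless duplicates of vertex breakpoints.
static void add_intersection_y(const Seg &a, const Seg &b,
                               std::vector<double> &ys) {
  double rx = a.x2 - a.x1, ry = a.y2 - a.y1;
  double sx = b.x2 - b.x1, sy = b.y2 - b.y1;
  double denom = rx * sy - ry * sx;
  double qpx = b.x1 - a.x1, qpy = b.y1 - a.y1;
  if (std::fabs(denom) < 1e-300) return; // parallel/collinear: endpoints cover it
  double t = (qpx * sy - qpy * sx) / denom;
  double u = (qpx * ry - qpy * rx) / denom;
  if (t < 0.0 || t > 1.0 || u < 0.0 || u > 1.0) return;
  ys.push_back(a.y1 + t * ry);
}

// crossings of the horizontal line y = ym with one ring's edges (even-odd)
static void ring_crossings(const std::vector<Seg> &edges, size_t lo, size_t hi,
                           double ym, std::vector<double> &xs) {
  xs.clear();
  for (size_t i = lo; i < hi; ++i) {
    const Seg &e = edges[i];
    bool a = e.y1 > ym, b = e.y2 > ym;
    if (a == b) continue;
    xs.push_back(e.x1 + (ym - e.y1) * (e.x2 - e.x1) / (e.y2 - e.y1));
  }
  std::sort(xs.begin(), xs.end());
}

// [[Rcpp::export]]
double poly_union_area_in_disk_cpp(List polys, double cx, double cy, double r,
                                   int ngon = 256) {
  if (r <= 0) stop("radius must be positive");
  if (ngon < 8) stop("ngon must be at least 8");

  // disk as inscribed regular ngon
  std::vector<double> dx(ngon), dy(ngon);
  for (int k = 0; k < ngon; ++k) {
    double th = 2.0 * M_PI * k / ngon;
    dx[k] = cx + r * std::cos(th);
    dy[k] = cy + r * std::sin(th);
  }

  std::vector<Seg> edges;        // all polygon edges of retained rings
  std::vector<size_t> ring_ofs;  // edges[ring_ofs[i] .. ring_ofs[i+1]) = ring i
  std::vector<double> breaks;

  int nring = 0;
  for (int p = 0; p < polys.size(); ++p) {
    NumericMatrix m = polys[p];
    int nv = m.nrow();
    if (nv < 3) continue;
    // bbox-to-center distance prefilter
    double bx1 = m(0, 0), bx2 = m(0, 0), by1 = m(0, 1), by2 = m(0, 1);
    for (int i = 1; i < nv; ++i) {
      bx1 = std::min(bx1, m(i, 0)); bx2 = std::max(bx2, m(i, 0));
      by1 = std::min(by1, m(i, 1)); by2 = std::max(by2, m(i, 1));
    }
    double ddx = std::max({0.0, bx1 - cx, cx - bx2});
    double ddy = std::max({0.0, by1 - cy, cy - by2});
    if (ddx * ddx + ddy * ddy > r * r) continue;

    ring_ofs.push_back(edges.size());
    for (int i = 0; i < nv; ++i) {
      int j = (i + 1) % nv;
      if (m(i, 0) == m(j, 0) && m(i, 1) == m(j, 1)) continue; // degenerate
      Seg s = {m(i, 0), m(i, 1), m(j, 0), m(j, 1), nring};
      edges.push_back(s);
      breaks.push_back(m(i, 1));
    }
    ++nring;
  }
  if (nring == 0) return 0.0;
  ring_ofs.push_back(edges.size());

  // disk edges (kept separately; its cross-section is one interval)
  std::vector<Seg> disk(ngon);
  double ylo = dy[0], yhi = dy[0];
  for (int k = 0; k < ngon; ++k) {
    int j = (k + 1) % ngon;
    disk[k] = {dx[k], dy[k], dx[j], dy[j], -1};
    breaks.push_back(dy[k]);
    ylo = std::min(ylo, dy[k]);
    yhi = std::max(yhi, dy[k]);
  }

  // pairwise crossings: polygon-polygon (different rings) and polygon-disk
  for (size_t i = 0; i < edges.size(); ++i) {
    for (size_t j = i + 1; j < edges.size(); ++j)
      if (edges[i].ring != edges[j].ring)
        add_intersection_y(edges[i], edges[j], breaks);
    for (int k = 0; k < ngon; ++k)
      add_intersection_y(edges[i], disk[k], breaks);
  }

  breaks.push_back(ylo);
  breaks.push_back(yhi);
  std::sort(breaks.begin(), breaks.end());

  double area = 0.0;
  std::vector<double> xs;
  std::vector<std::pair<double, double>> ivals;
  for (size_t s = 0; s + 1 < breaks.size(); ++s) {
    double y0 = std::max(breaks[s], ylo), y1 = std::min(breaks[s + 1], yhi);
    double h = y1 - y0;
    if (h <= 0) continue;
    double ym = 0.5 * (y0 + y1);

    // disk cross-section
    xs.clear();
    for (int k = 0; k < ngon; ++k) {
      const Seg &e = disk[k];
      bool a = e.y1 > ym, b = e.y2 > ym;
      if (a == b) continue;
      xs.push_back(e.x1 + (ym - e.y1) * (e.x2 - e.x1) / (e.y2 - e.y1));
    }
    if (xs.size() < 2) continue;
    double dlo = *std::min_element(xs.begin(), xs.end());
    double dhi = *std::max_element(xs.begin(), xs.end());

    // clip every ring's even-odd intervals to the disk interval
    ivals.clear();
    for (int rg = 0; rg < nring; ++rg) {
      ring_crossings(edges, ring_ofs[rg], ring_ofs[rg + 1], ym, xs);
      for (size_t i = 0; i + 1 < xs.size(); i += 2) {
        double lo = std::max(xs[i], dlo), hi = std::min(xs[i + 1], dhi);
        if (hi > lo) ivals.push_back({lo, hi});
      }
    }
    if (ivals.empty()) continue;

    // merged union length
    std::sort(ivals.begin(), ivals.end());
    double len = 0.0, curlo = ivals[0].first, curhi = ivals[0].second;
    for (size_t i = 1; i < ivals.size(); ++i) {
      if (ivals[i].first > curhi) {
        len += curhi - curlo;
        curlo = ivals[i].first;
        curhi = ivals[i].second;
      } else {
        curhi = std::max(curhi, ivals[i].second);
      }
    }
    len += curhi - curlo;
    area += len * h;
  }
  return area;
}

// [[Rcpp::export]]
NumericVector poly_union_area_in_disk_multi_cpp(List polys, double cx,
                                                double cy, NumericVector radii,
                                                int ngon = 256) {
  NumericVector out(radii.size());
  for (int i = 0; i < radii.size(); ++i)
    out[i] = poly_union_area_in_disk_cpp(polys, cx, cy, radii[i], ngon);
  return out;
}

// proper self-intersection test between non-adjacent edges of one ring
// [[Rcpp::export]]
bool is_simple_polygon_cpp(NumericMatrix m) {
  int nv = m.nrow();
  if (nv < 3) return false;
  std::vector<Seg> e;
  for (int i = 0; i < nv; ++i) {
    int j = (i + 1) % nv;
    if (m(i, 0) == m(j, 0) && m(i, 1) == m(j, 1)) continue;
    Seg s = {m(i, 0), m(i, 1), m(j, 0), m(j, 1), i};
    e.push_back(s);
  }
  int n = (int)e.size();
  if (n < 3) return false;
  for (int i = 0; i < n; ++i) {
    for (int j = i + 1; j < n; ++j) {
      bool adjacent = (j == i + 1) || (i == 0 && j == n - 1);
      double d1 = cross(e[i].x1, e[i].y1, e[i].x2, e[i].y2, e[j].x1, e[j].y1);
      double d2 = cross(e[i].x1, e[i].y1, e[i].x2, e[i].y2, e[j].x2, e[j].y2);
      double d3 = cross(e[j].x1, e[j].y1, e[j].x2, e[j].y2, e[i].x1, e[i].y1);
      double d4 = cross(e[j].x1, e[j].y1, e[j].x2, e[j].y2, e[i].x2, e[i].y2);
      if (adjacent) {
        // shared endpoint is fine; collinear overlap beyond the endpoint is not
        if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
          // collinear adjacent edges: reject only if they double back
          double ux = e[i].x2 - e[i].x1, uy = e[i].y2 - e[i].y1;
          double vx = e[j].x2 - e[j].x1, vy = e[j].y2 - e[j].y1;
          if (j == i + 1 && ux * vx + uy * vy < 0) return false;
          if (i == 0 && j == n - 1 && ux * vx + uy * vy < 0) return false;
        }
        continue;
      }
      if (((d1 > 0) != (d2 > 0) || d1 == 0 || d2 == 0) &&
          ((d3 > 0) != (d4 > 0) || d3 == 0 || d4 == 0)) {
        // conservative: any contact between non-adjacent edges, including
        // touching, counts as non-simple
        bool straddle1 = (d1 > 0 && d2 < 0) || (d1 < 0 && d2 > 0) || d1 == 0 || d2 == 0;
        bool straddle2 = (d3 > 0 && d4 < 0) || (d3 < 0 && d4 > 0) || d3 == 0 || d4 == 0;
        if (straddle1 && straddle2) {
          // rule out the all-zero (collinear, possibly disjoint) case
          if (d1 == 0 && d2 == 0 && d3 == 0 && d4 == 0) {
            // collinear: overlap iff projections overlap
            double lo1 = std::min(e[i].x1, e[i].x2), hi1 = std::max(e[i].x1, e[i].x2);
            double lo2 = std::min(e[j].x1, e[j].x2), hi2 = std::max(e[j].x1, e[j].x2);
            double vlo1 = std::min(e[i].y1, e[i].y2), vhi1 = std::max(e[i].y1, e[i].y2);
            double vlo2 = std::min(e[j].y1, e[j].y2), vhi2 = std::max(e[j].y1, e[j].y2);
            if (hi1 >= lo2 && hi2 >= lo1 && vhi1 >= vlo2 && vhi2 >= vlo1)
              return false;
          } else {
            return false;
          }
        }
      }
    }
  }
  return true;
}
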