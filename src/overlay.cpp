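#include <Rcpp.h>
#include <algorithm>
#include <vector>

using namespace Rcpp;

// Exact area-of-union / area-of-intersection engine for simple polygons.
//
// Set A is a union of rings (the sausage buffer: overlapping capsule
// polygons). Set B is a collection of "shapes", each itself a union of
// rings (land-use parcels, or a second buffer). We compute
//   area( U A )          and, for every shape S,   area( (U A) n S )
// by vertical slab decomposition: between two consecutive "event"
// x-coordinates (any polygon vertex, any interior crossing of two edges)
// the cross-section structure is combinatorially constant, so the union
// cross-section length is linear in x and the midpoint value integrates
// the slab exactly. No robustness heuristics beyond event deduplication
// are needed because midpoints never coincide with vertices.

namespace {

struct Edge {
  double x0, y0, x1, y1; // x0 < x1
  int ring;              // global ring index
  int shape;             // -1 for set A, else B shape index (0-based)
};

inline double y_at(const Edge& e, double x) {
  return e.y0 + (x - e.x0) * (e.y1 - e.y0) / (e.x1 - e.x0);
}

// union length of intervals given as sorted (lo,hi) pairs
double union_length(std::vector<std::pair<double, double> >& iv) {
  if (iv.empty()) return 0.0;
  std::sort(iv.begin(), iv.end());
  double len = 0.0, lo = iv[0].first, hi = iv[0].second;
  for (size_t i = 1; i < iv.size(); ++i) {
    if (iv[i].first > hi) {
      len += hi - lo;
      lo = iv[i].first;
      hi = iv[i].second;
    } else if (iv[i].second > hi) {
      hi = iv[i].second;
    }
  }
  len += hi - lo;
  return len;
}

// merge sorted interval list in place to disjoint sorted intervals
void normalize(std::vector<std::pair<double, double> >& iv) {
  if (iv.empty()) return;
  std::sort(iv.begin(), iv.end());
  size_t k = 0;
  for (size_t i = 1; i < iv.size(); ++i) {
    if (iv[i].first > iv[k].second) {
      iv[++k] = iv[i];
    } else if (iv[i].second > iv[k].second) {
      iv[k].second = iv[i].second;
    }
  }
  iv.resize(k + 1);
}

double intersect_length(const std::vector<std::pair<double, double> >& a,
                        const std::vector<std::pair<double, double> >& b) {
  double len = 0.0;
  size_t i = 0, j = 0;
  while (i < a.size() && j < b.size()) {
    double lo = std::max(a[i].first, b[j].first);
    double hi = std::min(a[i].second, b[j].second);
    if (hi > lo) len += hi - lo;
    if (a[i].second < b[j].second) ++i; else ++j;
  }
  return len;
}

void build_edges(const NumericVector& x, const NumericVector& y,
                 const IntegerVector& ring_len, const IntegerVector& shape_of_ring,
                 int ring_offset, bool is_b,
                 std::vector<Edge>& edges, std::vector<double>& events) {
  int pos = 0;
  for (int r = 0; r < ring_len.size(); ++r) {
    int n = ring_len[r];
    for (int i = 0; i < n; ++i) {
      int j = (i + 1) % n;
      double xa = x[pos + i], ya = y[pos + i];
      double xb = x[pos + j], yb = y[pos + j];
      events.push_back(xa);
      if (xa == xb) continue; // vertical edges yield no midpoint crossings
      Edge e;
      if (xa < xb) { e.x0 = xa; e.y0 = ya; e.x1 = xb; e.y1 = yb; }
      else         { e.x0 = xb; e.y0 = yb; e.x1 = xa; e.y1 = ya; }
      e.ring = ring_offset + r;
      e.shape = is_b ? shape_of_ring[r] : -1;
      edges.push_back(e);
    }
    pos += n;
  }
}

} // namespace

// [[Rcpp::export]]
List overlay_areas_cpp(NumericVector ax, NumericVector ay, IntegerVector aring_len,
                       NumericVector bx, NumericVector by, IntegerVector bring_len,
                       IntegerVector bshape, int n_shapes) {
  std::vector<Edge> edges;
  std::vector<double> events;
  IntegerVector dummy(0);
  build_edges(ax, ay, aring_len, dummy, 0, false, edges, events);
  build_edges(bx, by, bring_len, bshape, aring_len.size(), true, edges, events);

  const size_t nE = edges.size();
  // pairwise interior crossings (plane-sweep candidate enumeration by x)
  std::vector<size_t> order(nE);
  for (size_t i = 0; i < nE; ++i) order[i] = i;
  std::sort(order.begin(), order.end(), [&](size_t a, size_t b) {
    return edges[a].x0 < edges[b].x0;
  });
  for (size_t oi = 0; oi < nE; ++oi) {
    const Edge& e = edges[order[oi]];
    for (size_t oj = oi + 1; oj < nE; ++oj) {
      const Edge& f = edges[order[oj]];
      if (f.x0 >= e.x1) break;
      if (std::max(e.y0, e.y1) < std::min(f.y0, f.y1) ||
          std::max(f.y0, f.y1) < std::min(e.y0, e.y1)) continue;
      double rx = e.x1 - e.x0, ry = e.y1 - e.y0;
      double sx = f.x1 - f.x0, sy = f.y1 - f.y0;
      double den = rx * sy - ry * sx;
      double scale = (std::abs(rx) + std::abs(ry)) * (std::abs(sx) + std::abs(sy));
      if (std::abs(den) < 1e-12 * scale) continue; // parallel

      double qpx = f.x0 - e.x0, qpy = f.y0 - e.y0;
      double t = (qpx * sy - qpy * sx) / den;
      double u = (qpx * ry - qpy * rx) / den;
      if (t <= 0.0 || t >= 1.0 || u <= 0.0 || u >= 1.0) continue;
      events.push_back(e.x0 + t * rx);
    }
  }

  std::sort(events.begin(), events.end());
  events.erase(std::unique(events.begin(), events.end(),
                           [](double a, double b) { return std::abs(a - b) < 1e-9; }),
               events.end());

  // active-edge sweep over slabs
  std::vector<size_t> by_x0(order); // already sorted by x0
  size_t next_edge = 0;
  std::vector<size_t> active;

  double area_a = 0.0;
  std::vector<double> area_b(n_shapes, 0.0);

  // scratch: crossings grouped by ring
  std::vector<std::pair<int, double> > hits; // (ring, y)
  int n_rings = aring_len.size() + bring_len.size();
  std::vector<int> ring_shape(n_rings, -1);
  for (int r = 0; r < bring_len.size(); ++r)
    ring_shape[aring_len.size() + r] = bshape[r];

  for (size_t s = 0; s + 1 < events.size(); ++s) {
    double x0 = events[s], x1 = events[s + 1];
    double dx = x1 - x0;
    if (dx <= 1e-12) continue;
    double xm = 0.5 * (x0 + x1);

    while (next_edge < nE && edges[by_x0[next_edge]].x0 < xm) {
      active.push_back(by_x0[next_edge]);
      ++next_edge;
    }
    hits.clear();
    size_t k = 0;
    for (size_t ii = 0; ii < active.size(); ++ii) {
      const Edge& e = edges[active[ii]];
      if (e.x1 <= x0) continue; // expired; drop by compaction
      active[k++] = active[ii];
      if (e.x0 < xm && xm < e.x1) hits.push_back({e.ring, y_at(e, xm)});
    }
    active.resize(k);
    if (hits.empty()) continue;
    std::sort(hits.begin(), hits.end());

    // pair crossings per ring (even-odd rule), bucket intervals by set/shape
    std::vector<std::pair<double, double> > iv_a;
    std::vector<std::vector<std::pair<double, double> > > iv_b(n_shapes);
    size_t i = 0;
    while (i < hits.size()) {
      int ring = hits[i].first;
      size_t j = i;
      while (j < hits.size() && hits[j].first == ring) ++j;
      int shp = ring_shape[ring];
      for (size_t p = i; p + 1 < j; p += 2) {
        std::pair<double, double> seg(hits[p].second, hits[p + 1].second);
        if (shp < 0) iv_a.push_back(seg); else iv_b[shp].push_back(seg);
      }
      i = j;
    }
    if (iv_a.empty()) continue;
    normalize(iv_a);
    double la = 0.0;
    for (auto& p : iv_a) la += p.second - p.first;
    area_a += la * dx;
    for (int q = 0; q < n_shapes; ++q) {
      if (iv_b[q].empty()) continue;
      normalize(iv_b[q]);
      area_b[q] += intersect_length(iv_a, iv_b[q]) * dx;
    }
  }

  return List::create(_["area_a"] = area_a,
                      _["area_b"] = NumericVector(area_b.begin(), area_b.end()));
}
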