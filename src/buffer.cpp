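#include <Rcpp.h>
using namespace Rcpp;

// Squared distance from point (px,py) to segment (x1,y1)-(x2,y2)
static inline double dist2_point_segment(double px, double py,
                                         double x1, double y1,
                                         double x2, double y2) {
  double dx = x2 - x1, dy = y2 - y1;
  double len2 = dx * dx + dy * dy;
  double t = 0.0;
  if (len2 > 0.0) {
    t = ((px - x1) * dx + (py - y1) * dy) / len2;
    if (t < 0.0) t = 0.0;
    if (t > 1.0) t = 1.0;
  }
  double qx = x1 + t * dx, qy = y1 + t * dy;
  double ex = px - qx, ey = py - qy;
  return ex * ex + ey * ey;
}

// Cell-center land-cover counts within a buffered segment.
// grid: integer matrix (row 1 = top row), codes 1..n_class.
// Returns counts per code (length n_class) plus total in-buffer cell count,
// and the count of candidate cells whose center falls outside the grid extent
// but inside the buffer (for the in-extent fraction rule).
// [[Rcpp::export]]
NumericVector seg_buffer_counts(double x1, double y1, double x2, double y2,
                                IntegerMatrix grid, double cell, double x0,
                                double y0, double buffer_m, int n_class) {
  int nr = grid.nrow(), nc = grid.ncol();
  double b2 = buffer_m * buffer_m;
  double xmin = std::min(x1, x2) - buffer_m, xmax = std::max(x1, x2) + buffer_m;
  double ymin = std::min(y1, y2) - buffer_m, ymax = std::max(y1, y2) + buffer_m;
  // candidate column range from x, candidate row range from y
  int c_lo = (int)std::floor((xmin - x0) / cell - 0.5);
  int c_hi = (int)std::ceil((xmax - x0) / cell + 0.5);
  // y of row r (1-based, top row): y0 + (nr - r + 0.5) * cell; iterate in index space
  int r_for_ymax = (int)std::floor(nr - (ymax - y0) / cell + 0.5) - 2;
  int r_for_ymin = (int)std::ceil(nr - (ymin - y0) / cell + 0.5) + 2;
  NumericVector out(n_class + 2);
  for (int r = r_for_ymax; r <= r_for_ymin; ++r) {
    double py = y0 + (nr - r + 0.5) * cell; // 1-based row center
    for (int c = c_lo; c <= c_hi; ++c) {
      double px = x0 + (c - 0.5) * cell; // 1-based col center
      if (dist2_point_segment(px, py, x1, y1, x2, y2) <= b2) {
        if (r >= 1 && r <= nr && c >= 1 && c <= nc) {
          int code = grid(r - 1, c - 1);
          if (code >= 1 && code <= n_class) out[code - 1] += 1.0;
          out[n_class] += 1.0; // in-extent, in-buffer
        } else {
          out[n_class + 1] += 1.0; // out-of-extent, in-buffer
        }
      }
    }
  }
  return out;
}

// Batched version: segments given as an n x 4 matrix (x1,y1,x2,y2).
// Returns an n x (n_class + 2) matrix of counts.
// [[Rcpp::export]]
NumericMatrix seg_buffer_counts_many(NumericMatrix segs, IntegerMatrix grid,
                                     double cell, double x0, double y0,
                                     double buffer_m, int n_class) {
  int n = segs.nrow();
  NumericMatrix out(n, n_class + 2);
  for (int i = 0; i < n; ++i) {
    NumericVector cnt = seg_buffer_counts(segs(i, 0), segs(i, 1), segs(i, 2),
                                          segs(i, 3), grid, cell, x0, y0,
                                          buffer_m, n_class);
    for (int j = 0; j < n_class + 2; ++j) out(i, j) = cnt[j];
  }
  return out;
}
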