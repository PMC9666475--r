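#include <Rcpp.h>
using namespace Rcpp;

// Nearest-centre point location on a pointy-top hexagonal lattice.
// Lattice: centre of (col, row) at x = x0 + w*(col + 0.5*(row mod 2)),
// y = y0 + 1.5*R*row, with w = sqrt(3)*R (flat-to-flat width).
// `lookup` maps (row+1, col+1) -> site id (0 = no site kept there).
// A point whose nearest lattice centre is not a kept site gets NA;
// exact ties resolve to the lowest site id among kept candidates.

static inline double centre_x(int col, int row, double x0, double w) {
  return x0 + w * (col + 0.5 * (((row % 2) + 2) % 2));
}

// [[Rcpp::export]]
IntegerVector hex_locate_cpp(NumericVector x, NumericVector y,
                             double x0, double y0, double R,
                             IntegerMatrix lookup) {
  const double w = std::sqrt(3.0) * R;
  const int nrow = lookup.nrow(), ncol = lookup.ncol();
  const int n = x.size();
  IntegerVector out(n, NA_INTEGER);
  // axial neighbour offsets (odd-r offset grid handled via axial coords)
  const int dq[6] = {1, 1, 0, -1, -1, 0};
  const int dr[6] = {0, -1, -1, 0, 1, 1};
  for (int i = 0; i < n; ++i) {
    if (NumericVector::is_na(x[i]) || NumericVector::is_na(y[i])) continue;
    double px = x[i] - x0, py = y[i] - y0;
    // fractional axial coordinates
    double qf = (std::sqrt(3.0) / 3.0 * px - py / 3.0) / R;
    double rf = (2.0 / 3.0 * py) / R;
    // cube rounding
    double sf = -qf - rf;
    double q = std::round(qf), r = std::round(rf), s = std::round(sf);
    double qd = std::fabs(q - qf), rd = std::fabs(r - rf), sd = std::fabs(s - sf);
    if (qd > rd && qd > sd) q = -r - s;
    else if (rd > sd) r = -q - s;
    int q0 = (int)q, r0 = (int)r;
    // examine rounded cell and its six neighbours
    double dbest = R_PosInf; int best_id = NA_INTEGER; bool best_kept = false;
    const double eps = 1e-9 * (R > 1 ? R : 1.0);
    for (int k = -1; k < 6; ++k) {
      int qq = q0, rr = r0;
      if (k >= 0) { qq += dq[k]; rr += dr[k]; }
      int row = rr;
      int col = qq + (rr - (((rr % 2) + 2) % 2)) / 2;
      double cx = centre_x(col, row, 0.0, w);   // px,py already shifted
      double cy = 1.5 * R * row;
      double d = std::hypot(px - cx, py - cy);
      int id = 0;
      bool inside = (row >= 0 && row < nrow && col >= 0 && col < ncol);
      if (inside) id = lookup(row, col);
      bool kept = id > 0;
      if (d < dbest - eps) {
        dbest = d; best_id = kept ? id : NA_INTEGER; best_kept = kept;
      } else if (d <= dbest + eps) {
        // tie: prefer kept sites; among kept, lowest site id
        if (kept && (!best_kept || id < best_id)) { best_id = id; best_kept = true; }
      }
    }
    out[i] = best_id;
  }
  return out;
}
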