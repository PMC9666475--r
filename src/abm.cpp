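#include <Rcpp.h>
using namespace Rcpp;

// Correlated-random-walk agent stepper on a rectangular nest discretised
// by a pointy-top hexagonal lattice. Steps draw a turn angle from a
// wrapped normal and a length from an exponential; each step is traversed
// at constant speed (length / tau) over successive 1/dt-second frames.
// Optional mechanisms: focal-point attraction (FPA), locomotion
// adjustment (LA: context-dependent lambda / sigma / activity), boundary
// effect (BE: turn-magnitude modulation near the primary-module border).
// Uses R's RNG so simulations are reproducible under set.seed().

static int locate_site_c(double px, double py, double R,
                         const IntegerMatrix &lookup) {
  const double w = std::sqrt(3.0) * R;
  const int nrow = lookup.nrow(), ncol = lookup.ncol();
  double qf = (std::sqrt(3.0) / 3.0 * px - py / 3.0) / R;
  double rf = (2.0 / 3.0 * py) / R;
  double sf = -qf - rf;
  double q = std::round(qf), r = std::round(rf), s = std::round(sf);
  double qd = std::fabs(q - qf), rd = std::fabs(r - rf), sd = std::fabs(s - sf);
  if (qd > rd && qd > sd) q = -r - s; else if (rd > sd) r = -q - s;
  int q0 = (int)q, r0 = (int)r;
  const int dq[6] = {1, 1, 0, -1, -1, 0};
  const int dr[6] = {0, -1, -1, 0, 1, 1};
  double dbest = R_PosInf; int best = 0;
  for (int k = -1; k < 6; ++k) {
    int qq = q0, rr = r0;
    if (k >= 0) { qq += dq[k]; rr += dr[k]; }
    int row = rr;
    int col = qq + (rr - (((rr % 2) + 2) % 2)) / 2;
    if (row < 0 || row >= nrow || col < 0 || col >= ncol) continue;
    int id = lookup(row, col);
    if (id <= 0) continue;
    double cx = w * (col + 0.5 * (((row % 2) + 2) % 2));
    double cy = 1.5 * R * row;
    double d = (px - cx) * (px - cx) + (py - cy) * (py - cy);
    if (d < dbest) { dbest = d; best = id; }
  }
  return best;  // 0 when no kept site nearby (should not happen in-rect)
}

// [[Rcpp::export]]
NumericMatrix abm_agent_cpp(int n_frames, double dt,
                            double x, double y, double heading,
                            double xmin, double xmax,
                            double ymin, double ymax,
                            double ox, double oy, double R,
                            IntegerMatrix lookup,
                            IntegerVector prim, int my_module,
                            NumericVector nbx, NumericVector nby,
                            NumericVector dbnd,
                            NumericVector gx, NumericVector gy,
                            bool fpa, bool la, bool be,
                            double w_bias,
                            double lambda_in, double lambda_out,
                            double sigma_in, double sigma_out,
                            double pact_in, double pact_out,
                            double tau, double mean_active_bout,
                            double sigma_be, double trigger_mm) {
  NumericMatrix out(n_frames, 4);  // x, y, heading, active
  double rem = 0.0, spd = 0.0;
  bool active = true;
  const double eps = 1e-9;
  for (int i = 0; i < n_frames; ++i) {
    out(i, 0) = x; out(i, 1) = y; out(i, 2) = heading;
    out(i, 3) = active ? 1.0 : 0.0;
    int site = locate_site_c(x - ox, y - oy, R, lookup);
    bool inside = (site > 0) && (prim[site - 1] == my_module);
    double lambda = (la && !inside) ? lambda_out : lambda_in;
    double sigma  = (la && !inside) ? sigma_out  : sigma_in;
    double pact   = (la && !inside) ? pact_out   : pact_in;
    // two-state activity Markov chain with fixed mean active bout
    if (pact >= 1.0 - eps) { active = true; }
    else if (pact <= eps) { active = false; }
    else {
      double m_a = mean_active_bout;
      double m_i = m_a * (1.0 - pact) / pact;
      if (active) { if (unif_rand() < dt / m_a) { active = false; } }
      else if (unif_rand() < dt / m_i) { active = true; rem = 0.0; }
    }
    if (!active) continue;
    if (rem <= eps) {
      // draw a new step: wrapped-normal turn, exponential length
      double theta = norm_rand() * sigma;
      if (be && site > 0 && dbnd[site - 1] <= trigger_mm) {
        double dot = std::cos(heading) * gx[site - 1] +
                     std::sin(heading) * gy[site - 1];
        double sgn = theta >= 0 ? 1.0 : -1.0;
        if (theta == 0.0) sgn = (unif_rand() < 0.5) ? -1.0 : 1.0;
        if (dot < 0)       theta = sgn * (std::fabs(theta) + sigma_be);
        else if (dot > 0)  theta = sgn * std::max(0.0, std::fabs(theta) - sigma_be);
      }
      heading += theta;
      heading = std::atan2(std::sin(heading), std::cos(heading));
      if (fpa && site > 0 && prim[site - 1] != my_module) {
        double bx = nbx[site - 1] - x, by = nby[site - 1] - y;
        double bn = std::hypot(bx, by);
        if (bn > eps) {
          double vx = (1.0 - w_bias) * std::cos(heading) + w_bias * bx / bn;
          double vy = (1.0 - w_bias) * std::sin(heading) + w_bias * by / bn;
          if (std::fabs(vx) > eps || std::fabs(vy) > eps)
            heading = std::atan2(vy, vx);
        }
      }
      rem = exp_rand() * lambda;
      spd = rem / tau;
    }
    double d = spd * dt;
    if (d > rem) d = rem;
    double hx = std::cos(heading), hy = std::sin(heading);
    double nx = x + d * hx, ny = y + d * hy;
    // specular reflection off the rectangular walls
    for (int guard = 0; guard < 64; ++guard) {
      bool refl = false;
      if (nx < xmin) { nx = 2 * xmin - nx; hx = -hx; refl = true; }
      if (nx > xmax) { nx = 2 * xmax - nx; hx = -hx; refl = true; }
      if (ny < ymin) { ny = 2 * ymin - ny; hy = -hy; refl = true; }
      if (ny > ymax) { ny = 2 * ymax - ny; hy = -hy; refl = true; }
      if (!refl) break;
    }
    nx = std::min(std::max(nx, xmin), xmax);
    ny = std::min(std::max(ny, ymin), ymax);
    x = nx; y = ny;
    heading = std::atan2(hy, hx);
    rem -= d;
  }
  return out;
}
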