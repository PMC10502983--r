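#include <Rcpp.h>
using namespace Rcpp;

// even-odd ray casting; boundary treatment irrelevant here (interior use)
static bool point_in_ring(double px, double py,
                          const NumericVector &rx, const NumericVector &ry) {
  int n = rx.size();
  bool inside = false;
  for (int i = 0, j = n - 1; i < n; j = i++) {
    if (((ry[i] > py) != (ry[j] > py)) &&
        (px < (rx[j] - rx[i]) * (py - ry[i]) / (ry[j] - ry[i]) + rx[i]))
      inside = !inside;
  }
  return inside;
}

// vectorised even-odd containment test
// [[Rcpp::export]]
LogicalVector in_ring_cpp(NumericVector px, NumericVector py,
                          NumericVector rx, NumericVector ry) {
  int n = px.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) out[i] = point_in_ring(px[i], py[i], rx, ry);
  return out;
}

// Linear interpolation of interior NA runs of length <= maxgap bins,
// column-wise; leading/trailing runs and longer runs are left NA. Filled
// bins are flagged 2 (imputed) in the returned status copy.
// [[Rcpp::export]]
List impute_linear_cpp(NumericMatrix d, IntegerMatrix status, int maxgap) {
  NumericMatrix out = clone(d);
  IntegerMatrix st = clone(status);
  const int nr = d.nrow(), nc = d.ncol();
  for (int c = 0; c < nc; ++c) {
    int last = -1;  // index of last finite value
    for (int r = 0; r < nr; ++r) {
      if (NumericVector::is_na(out(r, c))) continue;
      if (last >= 0 && r - last > 1 && r - last - 1 <= maxgap) {
        double v0 = out(last, c), v1 = out(r, c);
        for (int k = last + 1; k < r; ++k) {
          out(k, c) = v0 + (v1 - v0) * double(k - last) / double(r - last);
          st(k, c) = 2;
        }
      }
      last = r;
    }
  }
  return List::create(_["d"] = out, _["status"] = st);
}

// Pairwise distance matrix from trajectory matrices; NA where either fish
// is invalid. Pair order matches utils::combn(n, 2).
// [[Rcpp::export]]
NumericMatrix dist_cpp(NumericMatrix x, NumericMatrix y, NumericMatrix depth,
                       bool use_depth) {
  const int nb = x.nrow(), nf = x.ncol();
  const int np = nf * (nf - 1) / 2;
  NumericMatrix d(nb, np);
  int p = 0;
  for (int i = 0; i < nf - 1; ++i) {
    for (int j = i + 1; j < nf; ++j, ++p) {
      for (int r = 0; r < nb; ++r) {
        double xi = x(r, i), xj = x(r, j);
        if (NumericVector::is_na(xi) || NumericVector::is_na(xj)) {
          d(r, p) = NA_REAL;
          continue;
        }
        double dx = xi - xj, dy = y(r, i) - y(r, j);
        double s = dx * dx + dy * dy;
        if (use_depth) {
          double dz = depth(r, i) - depth(r, j);
          s += dz * dz;
        }
        d(r, p) = std::sqrt(s);
      }
    }
  }
  return d;
}

// Threshold + merge + filter over all pairs in one pass. A bin is active iff
// status > 0 and distance < threshold. Active runs separated by fewer than
// gap_bins inactive bins merge; events need >= min_active active bins.
// Returns 1-based pair index and bin bounds of each retained event.
// [[Rcpp::export]]
List events_cpp(NumericMatrix d, IntegerMatrix status, double threshold,
                int gap_bins, int min_active) {
  const int nb = d.nrow(), np = d.ncol();
  std::vector<int> pair, sbin, ebin, nact;
  for (int p = 0; p < np; ++p) {
    int cs = -1, cl = -1, cn = 0;
    for (int r = 0; r < nb; ++r) {
      double v = d(r, p);
      bool act = status(r, p) > 0 && !NumericVector::is_na(v) && v < threshold;
      if (!act) continue;
      if (cs < 0) { cs = r; cl = r; cn = 1; }
      else if (r - cl - 1 < gap_bins) { cl = r; ++cn; }
      else {
        if (cn >= min_active) {
          pair.push_back(p + 1); sbin.push_back(cs + 1);
          ebin.push_back(cl + 1); nact.push_back(cn);
        }
        cs = r; cl = r; cn = 1;
      }
    }
    if (cs >= 0 && cn >= min_active) {
      pair.push_back(p + 1); sbin.push_back(cs + 1);
      ebin.push_back(cl + 1); nact.push_back(cn);
    }
  }
  return List::create(_["pair"] = wrap(pair), _["s_bin"] = wrap(sbin),
                      _["e_bin"] = wrap(ebin), _["n_bins"] = wrap(nact));
}

// Coordinate-wise medians of fixes per centred 30 s window on the 15 s grid.
// Input must be sorted by fish then time; each fix falls in exactly two
// windows. Returns bins x fish matrices (NA = no fix in window).
// [[Rcpp::export]]
List median_bins_cpp(NumericVector time, IntegerVector fish, NumericVector x,
                     NumericVector y, NumericVector depth, NumericVector temp,
                     double t0, double dt, int n_bins, int n_fish) {
  NumericMatrix mx(n_bins, n_fish), my(n_bins, n_fish),
                md(n_bins, n_fish), mt(n_bins, n_fish);
  std::fill(mx.begin(), mx.end(), NA_REAL);
  std::fill(my.begin(), my.end(), NA_REAL);
  std::fill(md.begin(), md.end(), NA_REAL);
  std::fill(mt.begin(), mt.end(), NA_REAL);
  const int n = time.size();
  std::vector<int> cnt(n_bins), off(n_bins + 1);
  std::vector<int> idx;  // fix index per (bin slot)
  std::vector<double> buf;
  auto median_of = [&](std::vector<double> &v) {
    size_t m = v.size() / 2;
    std::nth_element(v.begin(), v.begin() + m, v.end());
    double hi = v[m];
    if (v.size() % 2 == 1) return hi;
    double lo = *std::max_element(v.begin(), v.begin() + m);
    return 0.5 * (lo + hi);
  };
  int start = 0;
  while (start < n) {
    int f = fish[start];
    int stop = start;
    while (stop < n && fish[stop] == f) ++stop;
    std::fill(cnt.begin(), cnt.end(), 0);
    for (int i = start; i < stop; ++i) {
      double k = (time[i] - t0) / dt;
      int bhi = (int)std::floor(k + 1 + 1e-9);
      for (int b = bhi - 1; b <= bhi; ++b)
        if (b >= 0 && b < n_bins) ++cnt[b];
    }
    off[0] = 0;
    for (int b = 0; b < n_bins; ++b) off[b + 1] = off[b] + cnt[b];
    idx.assign(off[n_bins], 0);
    std::vector<int> pos(off.begin(), off.end() - 1);
    for (int i = start; i < stop; ++i) {
      double k = (time[i] - t0) / dt;
      int bhi = (int)std::floor(k + 1 + 1e-9);
      for (int b = bhi - 1; b <= bhi; ++b)
        if (b >= 0 && b < n_bins) idx[pos[b]++] = i;
    }
    for (int b = 0; b < n_bins; ++b) {
      if (cnt[b] == 0) continue;
      buf.clear();
      for (int q = off[b]; q < off[b + 1]; ++q) buf.push_back(x[idx[q]]);
      mx(b, f - 1) = median_of(buf);
      buf.clear();
      for (int q = off[b]; q < off[b + 1]; ++q) buf.push_back(y[idx[q]]);
      my(b, f - 1) = median_of(buf);
      buf.clear();
      for (int q = off[b]; q < off[b + 1]; ++q) buf.push_back(depth[idx[q]]);
      md(b, f - 1) = median_of(buf);
      buf.clear();
      bool any_t = false;
      for (int q = off[b]; q < off[b + 1]; ++q)
        if (!NumericVector::is_na(temp[idx[q]])) {
          buf.push_back(temp[idx[q]]); any_t = true;
        }
      if (any_t) mt(b, f - 1) = median_of(buf);
    }
    start = stop;
  }
  return List::create(_["x"] = mx, _["y"] = my, _["depth"] = md,
                      _["temp"] = mt);
}

// Correlated random walk with group attraction and radial habitat bias.
//
// All stochastic inputs are pre-drawn in R so that the walk is a pure
// function of its arguments (determinism under a fixed R seed).
//
// Depth dynamics: AR(1) relaxation to a time-varying target with Gaussian
// innovations (drawn from R's RNG), clamped to [lo, hi]. One column per
// fish; innovations are drawn fish-by-fish, step-by-step.
// [[Rcpp::export]]
NumericMatrix depth_cpp(int n_fish, NumericVector d_target, double k_relax,
                        double sd_innov, double lo, double hi) {
  const int n_steps = d_target.size();
  NumericMatrix out(n_steps, n_fish);
  for (int f = 0; f < n_fish; ++f) {
    double h = d_target[0];
    for (int s = 0; s < n_steps; ++s) {
      h = (1 - k_relax) * h + k_relax * d_target[s] + sd_innov * R::norm_rand();
      double hc = h < lo ? lo : (h > hi ? hi : h);
      out(s, f) = hc;
    }
  }
  return out;
}

// group         : n_steps x n_fish 1-based group ids
// speed         : per-step base speed (m/s), shared across fish
// bias          : per-step signed radial bias; >0 pulls toward the lake
//                 centre (offshore), <0 pushes toward the shore
// attraction    : pull toward the current group centroid, in units of the
//                 current base speed
// vmax          : hard cap on realised speed (m/s)
// [[Rcpp::export]]
List walk_cpp(int n_steps, int n_fish, IntegerMatrix group,
              NumericVector speed, NumericVector bias,
              double attraction, double sigma_heading, double dt,
              NumericVector x0, NumericVector y0, NumericVector heading0,
              NumericVector poly_x, NumericVector poly_y,
              double cx, double cy, double vmax, double group_radius) {
  const int n_groups_max = 1 + *std::max_element(group.begin(), group.end());

  NumericMatrix X(n_steps, n_fish), Y(n_steps, n_fish);
  // inscribed-circle radius about (cx, cy): cheap accept test for interior
  double rmin2 = R_PosInf;
  {
    const int nv = poly_x.size();
    for (int i = 0, j = nv - 1; i < nv; j = i++) {
      double ax = poly_x[j], ay = poly_y[j];
      double vx = poly_x[i] - ax, vy = poly_y[i] - ay;
      double L2 = vx * vx + vy * vy;
      double t = L2 > 0 ? std::max(0.0, std::min(1.0,
                 ((cx - ax) * vx + (cy - ay) * vy) / L2)) : 0.0;
      double dx = cx - (ax + t * vx), dy = cy - (ay + t * vy);
      double d2 = dx * dx + dy * dy;
      if (d2 < rmin2) rmin2 = d2;
    }
    rmin2 *= 0.998;  // margin
  }
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> h(heading0.begin(), heading0.end());
  std::vector<double> gx(n_groups_max), gy(n_groups_max);
  std::vector<int> gn(n_groups_max);

  for (int s = 0; s < n_steps; ++s) {
    // group centroids from positions at the start of the step
    std::fill(gx.begin(), gx.end(), 0.0);
    std::fill(gy.begin(), gy.end(), 0.0);
    std::fill(gn.begin(), gn.end(), 0);
    for (int f = 0; f < n_fish; ++f) {
      int g = group(s, f);
      gx[g] += x[f]; gy[g] += y[f]; gn[g]++;
    }
    for (int g = 0; g < n_groups_max; ++g)
      if (gn[g] > 0) { gx[g] /= gn[g]; gy[g] /= gn[g]; }

    const double sp = speed[s], bi = bias[s];
    for (int f = 0; f < n_fish; ++f) {
      h[f] += sigma_heading * R::norm_rand();
      double vx = sp * std::cos(h[f]);
      double vy = sp * std::sin(h[f]);
      // social attraction toward the group centroid
      int g = group(s, f);
      double ax = gx[g] - x[f], ay = gy[g] - y[f];
      double ad = std::sqrt(ax * ax + ay * ay);
      if (ad > group_radius) {   // dead zone: no pull inside the group radius
        vx += attraction * sp * ax / ad;
        vy += attraction * sp * ay / ad;
      }
      // radial habitat bias (unit radial vector away from centre)
      double rx_ = x[f] - cx, ry_ = y[f] - cy;
      double rd = std::sqrt(rx_ * rx_ + ry_ * ry_);
      if (rd > 1.0) {
        vx -= bi * sp * rx_ / rd;
        vy -= bi * sp * ry_ / rd;
      }
      double vnorm = std::sqrt(vx * vx + vy * vy);
      if (vnorm > vmax) { vx *= vmax / vnorm; vy *= vmax / vnorm; }
      double nx = x[f] + dt * vx, ny = y[f] + dt * vy;
      // bounded step: halve the displacement toward the interior point
      double dcx = nx - cx, dcy = ny - cy;
      bool safe = dcx * dcx + dcy * dcy < rmin2;
      int tries = 0;
      while (!safe && !point_in_ring(nx, ny, poly_x, poly_y) && tries < 30) {
        nx = 0.5 * (nx + x[f]);
        ny = 0.5 * (ny + y[f]);
        ++tries;
      }
      if (tries == 30) { nx = x[f]; ny = y[f]; }
      else if (tries > 0) {
        // keep a small interior margin off the boundary
        nx += 0.02 * (x[f] - nx);
        ny += 0.02 * (y[f] - ny);
      }
      x[f] = nx; y[f] = ny;
      X(s, f) = nx; Y(s, f) = ny;
    }
  }
  return List::create(_["x"] = X, _["y"] = Y);
}
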