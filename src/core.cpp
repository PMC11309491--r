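// Core numerics for the cell-alignment model: ellipse pair geometry,
// overlap forces/torques, junction terms and the explicit-Euler engine.
#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <algorithm>
using namespace Rcpp;

static const double TWOPI = 6.28318530717958647692;
static const double PI_ = 3.14159265358979323846;

// ---------------------------------------------------------------- utilities

// minimum image: map displacement component into (-L/2, L/2]
static inline double min_image1(double d, double L) {
  if (!R_FINITE(L)) return d;
  return d - L * std::ceil(d / L - 0.5);
}

static inline double wrap_box(double x, double L) { // into [0, L)
  double y = x - L * std::floor(x / L);
  if (y >= L) y -= L;
  if (y < 0) y = 0;
  return y;
}

static inline double wrap_angle(double a) { // into [0, 2pi)
  double y = a - TWOPI * std::floor(a / TWOPI);
  if (y >= TWOPI) y -= TWOPI;
  if (y < 0) y = 0;
  return y;
}

// [[Rcpp::export]]
NumericVector cpp_min_image(NumericVector d, double L) {
  NumericVector out(d.size());
  for (R_xlen_t k = 0; k < d.size(); ++k) out[k] = min_image1(d[k], L);
  return out;
}

// ------------------------------------------------------- polynomial solvers

// a x^3 + b x^2 + c x + d = 0; real roots into out; returns count
static int solve_cubic_real(double a, double b, double c, double d, double *out) {
  double B = b / a, C = c / a, D = d / a;
  double p = C - B * B / 3.0;
  double q = 2.0 * B * B * B / 27.0 - B * C / 3.0 + D;
  double off = -B / 3.0;
  double disc = q * q / 4.0 + p * p * p / 27.0;
  if (disc > 0) {
    double sq = std::sqrt(disc);
    out[0] = std::cbrt(-q / 2.0 + sq) + std::cbrt(-q / 2.0 - sq) + off;
    return 1;
  }
  double rho = std::sqrt(std::max(0.0, -p * p * p / 27.0));
  if (rho < 1e-300) { out[0] = off; return 1; }
  double cosphi = std::min(1.0, std::max(-1.0, -q / (2.0 * rho)));
  double phi = std::acos(cosphi);
  double t = 2.0 * std::sqrt(-p / 3.0);
  out[0] = t * std::cos(phi / 3.0) + off;
  out[1] = t * std::cos((phi + TWOPI) / 3.0) + off;
  out[2] = t * std::cos((phi + 2.0 * TWOPI) / 3.0) + off;
  return 3;
}

// y^4 + p y^2 + q y + r = 0 (depressed); Ferrari via resolvent cubic
static int solve_quartic_depressed(double p, double q, double r, double *out) {
  int n = 0;
  if (std::fabs(q) < 1e-12 * (1.0 + std::fabs(p) + std::fabs(r))) {
    double disc = p * p - 4.0 * r;
    if (disc < 0) return 0;
    double s = std::sqrt(disc);
    double y2a = (-p + s) / 2.0, y2b = (-p - s) / 2.0;
    if (y2a >= 0) { double t = std::sqrt(y2a); out[n++] = t; out[n++] = -t; }
    if (y2b >= 0) { double t = std::sqrt(y2b); out[n++] = t; out[n++] = -t; }
    return n;
  }
  double mr[3];
  int nm = solve_cubic_real(8.0, 8.0 * p, 2.0 * p * p - 8.0 * r, -q * q, mr);
  double m = mr[0];
  for (int k = 1; k < nm; ++k) if (mr[k] > m) m = mr[k];
  if (m <= 0) return 0;
  double s = std::sqrt(2.0 * m);
  double t1 = p / 2.0 + m + q / (2.0 * s);
  double t2 = p / 2.0 + m - q / (2.0 * s);
  double d1 = s * s - 4.0 * t1;
  double d2 = s * s - 4.0 * t2;
  if (d1 >= 0) { double sd = std::sqrt(d1); out[n++] = (s + sd) / 2.0; out[n++] = (s - sd) / 2.0; }
  if (d2 >= 0) { double sd = std::sqrt(d2); out[n++] = (-s + sd) / 2.0; out[n++] = (-s - sd) / 2.0; }
  return n;
}

// ------------------------------------------------ ellipse pair intersection
//
// Everything is computed in cell i's frame: i axis-aligned at the origin,
// cell j at centre c with relative orientation phi. Points on i's boundary
// are (a_i cos th, b_i sin th); substituting into j's implicit quadratic
// gives f(th) = A cos^2 + B cos sin + C sin^2 + D cos + E sin + F, and the
// Weierstrass substitution t = tan(th/2) turns f = 0 into a quartic in t.

struct PairContact {
  int status;        // 0 none, 1 crossing, 2 containment, 3 coincident
  int K;             // pairs of points (1 or 2)
  int npts;          // 2K
  double pix[4], piy[4], thi[4]; // i-local coords + theta on i (Y-order for i)
  double pjx[4], pjy[4], thj[4]; // j-local coords + theta on j (Y-order for j)
  int contained;     // status 2: 1 = i inside j, 2 = j inside i
  bool tangency;     // a tangential point was discarded
};

struct FCoef { double A, B, C, D, E, F, scale; };

static inline double feval(const FCoef &fc, double th, double *dfout = nullptr) {
  double c = std::cos(th), s = std::sin(th);
  if (dfout)
    *dfout = 2.0 * s * c * (fc.C - fc.A) + fc.B * (c * c - s * s) - fc.D * s + fc.E * c;
  return fc.A * c * c + fc.B * c * s + fc.C * s * s + fc.D * c + fc.E * s + fc.F;
}

static inline double polish_theta(const FCoef &fc, double th) {
  for (int it = 0; it < 4; ++it) {
    double df, f = feval(fc, th, &df);
    if (std::fabs(df) < 1e-14 * fc.scale) break;
    double step = f / df;
    if (std::fabs(step) > 0.5) step = (step > 0 ? 0.5 : -0.5);
    th -= step;
    if (std::fabs(f) < 1e-13 * fc.scale) break;
  }
  return wrap_angle(th);
}

static void compute_pair(double ai, double bi, double aj, double bj,
                         double cx, double cy, double phi, PairContact &pc) {
  pc.status = 0; pc.K = 0; pc.npts = 0; pc.contained = 0; pc.tangency = false;

  // coincident configuration: identical centre, axes and orientation (mod pi)
  double dphi = std::fabs(std::remainder(phi, PI_));
  if (cx * cx + cy * cy < 1e-18 && std::fabs(ai - aj) < 1e-9 &&
      (dphi < 1e-9 || (std::fabs(ai - bi) < 1e-12))) {
    pc.status = 3;
    return;
  }

  double cphi = std::cos(phi), sphi = std::sin(phi);

  // separating-axis quick reject along the centre line: if the centre
  // distance exceeds the sum of the two support radii in that direction,
  // the ellipses are disjoint
  double cn2 = cx * cx + cy * cy;
  if (cn2 > (bi + bj) * (bi + bj)) {
    double cn = std::sqrt(cn2);
    double ux = cx / cn, uy = cy / cn;
    double hi = std::sqrt(ai * ai * ux * ux + bi * bi * uy * uy);
    double vx = cphi * ux + sphi * uy, vy = -sphi * ux + cphi * uy;
    double hj = std::sqrt(aj * aj * vx * vx + bj * bj * vy * vy);
    if (cn > hi + hj) return;
  }

  double ia2 = 1.0 / (aj * aj), ib2 = 1.0 / (bj * bj);
  double m11 = cphi * cphi * ia2 + sphi * sphi * ib2;
  double m22 = sphi * sphi * ia2 + cphi * cphi * ib2;
  double m12 = cphi * sphi * (ia2 - ib2);
  double mcx = m11 * cx + m12 * cy;
  double mcy = m12 * cx + m22 * cy;

  FCoef fc;
  fc.A = m11 * ai * ai;
  fc.B = 2.0 * m12 * ai * bi;
  fc.C = m22 * bi * bi;
  fc.D = -2.0 * mcx * ai;
  fc.E = -2.0 * mcy * bi;
  fc.F = cx * mcx + cy * mcy - 1.0;
  fc.scale = std::max({std::fabs(fc.A), std::fabs(fc.B), std::fabs(fc.C),
                       std::fabs(fc.D), std::fabs(fc.E), std::fabs(fc.F), 1e-30});

  // quartic coefficients in t = tan(th/2)
  double c4 = fc.A - fc.D + fc.F;
  double c3 = -2.0 * fc.B + 2.0 * fc.E;
  double c2 = -2.0 * fc.A + 4.0 * fc.C + 2.0 * fc.F;
  double c1 = 2.0 * fc.B + 2.0 * fc.E;
  double c0 = fc.A + fc.D + fc.F;
  double qs = std::max({std::fabs(c4), std::fabs(c3), std::fabs(c2),
                        std::fabs(c1), std::fabs(c0), 1e-30});

  double cand[12];
  int ncand = 0;
  if (std::fabs(c4) > 1e-9 * qs) {
    double p = c2 / c4 - 3.0 * (c3 / c4) * (c3 / c4) / 8.0;
    double b4 = c3 / c4 / 4.0;
    double q = (c3 / c4) * (c3 / c4) * (c3 / c4) / 8.0 -
               (c3 / c4) * (c2 / c4) / 2.0 + c1 / c4;
    double r = -3.0 * std::pow(c3 / c4, 4) / 256.0 +
               (c2 / c4) * (c3 / c4) * (c3 / c4) / 16.0 -
               (c3 / c4) * (c1 / c4) / 4.0 + c0 / c4;
    double yr[4];
    int ny = solve_quartic_depressed(p, q, r, yr);
    for (int k = 0; k < ny && ncand < 8; ++k)
      cand[ncand++] = 2.0 * std::atan(yr[k] - b4);
  } else if (std::fabs(c3) > 1e-9 * qs) {
    double tr[3];
    int nt = solve_cubic_real(c3, c2, c1, c0, tr);
    for (int k = 0; k < nt && ncand < 8; ++k) cand[ncand++] = 2.0 * std::atan(tr[k]);
  } else if (std::fabs(c2) > 1e-9 * qs) {
    double disc = c1 * c1 - 4.0 * c2 * c0;
    if (disc >= 0) {
      double sd = std::sqrt(disc);
      cand[ncand++] = 2.0 * std::atan((-c1 + sd) / (2.0 * c2));
      cand[ncand++] = 2.0 * std::atan((-c1 - sd) / (2.0 * c2));
    }
  } else if (std::fabs(c1) > 1e-9 * qs) {
    cand[ncand++] = 2.0 * std::atan(-c0 / c1);
  }
  if (std::fabs(c4) < 1e-6 * qs) cand[ncand++] = PI_; // t -> infinity root

  // polish candidates and keep genuine boundary crossings
  double th[8];
  int nth = 0;
  for (int k = 0; k < ncand; ++k) {
    double t = polish_theta(fc, cand[k]);
    if (std::fabs(feval(fc, t)) < 1e-8 * fc.scale && nth < 8) th[nth++] = t;
  }

  // safety-net sign scan for roots the closed form may have missed
  {
    const int NS = 16;
    double fs[NS];
    // incremental rotation avoids NS trig-pair evaluations
    const double cd = 0.92387953251128674, sd = 0.38268343236508978; // 2pi/16
    double cth = 1.0, sth = 0.0;
    for (int k = 0; k < NS; ++k) {
      fs[k] = (fc.A * cth + fc.B * sth + fc.D) * cth +
              (fc.C * sth + fc.E) * sth + fc.F;
      double cn = cth * cd - sth * sd;
      sth = sth * cd + cth * sd;
      cth = cn;
    }
    for (int k = 0; k < NS; ++k) {
      int k2 = (k + 1) % NS;
      if ((fs[k] < 0) == (fs[k2] < 0)) continue;
      double lo = TWOPI * k / NS, hi = TWOPI * (k + 1) / NS;
      bool have = false;
      for (int m = 0; m < nth; ++m) {
        double d = std::fabs(std::remainder(th[m] - (lo + hi) / 2.0, TWOPI));
        if (d < TWOPI / NS) { have = true; break; }
      }
      if (have || nth >= 8) continue;
      double flo = fs[k];
      for (int it = 0; it < 60; ++it) {
        double mid = (lo + hi) / 2.0, fm = feval(fc, mid);
        if ((fm < 0) == (flo < 0)) { lo = mid; flo = fm; } else hi = mid;
      }
      double t = polish_theta(fc, (lo + hi) / 2.0);
      if (std::fabs(feval(fc, t)) < 1e-8 * fc.scale) th[nth++] = t;
    }
  }

  // sort, merge duplicates (tolerance 1e-8 in boundary coordinate)
  std::sort(th, th + nth);
  double uni[8];
  int nu = 0;
  for (int k = 0; k < nth; ++k) {
    if (nu == 0 || th[k] - uni[nu - 1] > 1e-8) uni[nu++] = th[k];
  }
  if (nu >= 2 && (uni[0] + TWOPI) - uni[nu - 1] < 1e-8) --nu; // wrap merge

  // prune tangential points until arc in/out statuses alternate
  while (nu >= 1) {
    bool ok = true;
    int worst = -1;
    double worstdf = 1e300;
    for (int k = 0; k < nu; ++k) {
      int km = (k - 1 + nu) % nu;
      double a1 = uni[km], b1 = uni[k];
      if (k == 0) a1 -= TWOPI;
      double a2 = uni[k], b2 = uni[(k + 1) % nu];
      if (k == nu - 1) b2 += TWOPI;
      if (nu == 1) { a1 = uni[0] - TWOPI; b1 = uni[0]; a2 = uni[0]; b2 = uni[0] + TWOPI; }
      bool in_before = feval(fc, (a1 + b1) / 2.0) < 0;
      bool in_after = feval(fc, (a2 + b2) / 2.0) < 0;
      if (in_before == in_after) {
        ok = false;
        double df;
        feval(fc, uni[k], &df);
        if (std::fabs(df) < worstdf) { worstdf = std::fabs(df); worst = k; }
      }
    }
    if (ok) break;
    for (int k = worst; k < nu - 1; ++k) uni[k] = uni[k + 1];
    --nu;
    pc.tangency = true;
  }
  if (nu % 2 == 1) { --nu; pc.tangency = true; } // defensive: drop stray point
  if (nu > 4) nu = 4;                            // quartic bound

  if (nu == 0) {
    // containment: no transversal crossings but one ellipse inside the other
    bool i_centre_in_j = fc.F < 0;
    bool j_centre_in_i = (cx / ai) * (cx / ai) + (cy / bi) * (cy / bi) < 1.0;
    if (i_centre_in_j || j_centre_in_i) {
      pc.status = 2;
      pc.contained = (feval(fc, 0.0) < 0) ? 1 : 2; // is i's boundary inside j?
    }
    return;
  }

  pc.status = 1;
  pc.npts = nu;
  pc.K = nu / 2;

  // order on cell i: start at the point whose following arc lies inside j
  {
    double b2 = (nu > 1) ? uni[1] : uni[0] + TWOPI;
    bool first_in = feval(fc, (uni[0] + b2) / 2.0) < 0;
    int start = first_in ? 0 : 1;
    for (int k = 0; k < nu; ++k) {
      double t = uni[(start + k) % nu];
      pc.thi[k] = t;
      pc.pix[k] = ai * std::cos(t);
      pc.piy[k] = bi * std::sin(t);
    }
  }

  // order on cell j: same point set, parameterised and paired on j's boundary
  {
    double tj[4];
    int idx[4];
    for (int k = 0; k < nu; ++k) {
      double ux = pc.pix[k] - cx, uy = pc.piy[k] - cy;
      double qx = cphi * ux + sphi * uy;
      double qy = -sphi * ux + cphi * uy;
      tj[k] = wrap_angle(std::atan2(qy / bj, qx / aj));
      idx[k] = k;
    }
    std::sort(idx, idx + nu, [&](int u, int v) { return tj[u] < tj[v]; });
    // inside test for an arc midpoint on j's boundary (point in i's frame)
    auto mid_inside_i = [&](double t1, double t2) {
      double tm = (t1 + t2) / 2.0;
      double px = cx + cphi * (aj * std::cos(tm)) - sphi * (bj * std::sin(tm));
      double py = cy + sphi * (aj * std::cos(tm)) + cphi * (bj * std::sin(tm));
      return (px / ai) * (px / ai) + (py / bi) * (py / bi) < 1.0;
    };
    double t0 = tj[idx[0]];
    double t1 = (nu > 1) ? tj[idx[1]] : t0 + TWOPI;
    int start = mid_inside_i(t0, t1) ? 0 : 1;
    for (int k = 0; k < nu; ++k) {
      int ii = idx[(start + k) % nu];
      pc.thj[k] = tj[ii];
      double ux = pc.pix[ii] - cx, uy = pc.piy[ii] - cy;
      pc.pjx[k] = cphi * ux + sphi * uy;
      pc.pjy[k] = -sphi * ux + cphi * uy;
    }
  }
}

// wrapper taking global cell coordinates (x, y, alpha, r with a=sqrt(r))
static void pair_from_global(double xi, double yi, double ali, double ri,
                             double xj, double yj, double alj, double rj,
                             double L, PairContact &pc) {
  double ai = std::sqrt(ri), bi = 1.0 / ai;
  double aj = std::sqrt(rj), bj = 1.0 / aj;
  double dx = min_image1(xj - xi, L), dy = min_image1(yj - yi, L);
  double ca = std::cos(ali), sa = std::sin(ali);
  double cx = ca * dx + sa * dy;
  double cy = -sa * dx + ca * dy;
  compute_pair(ai, bi, aj, bj, cx, cy, alj - ali, pc);
}

// [[Rcpp::export]]
List cpp_intersect(double xi, double yi, double ali, double ai, double bi,
                   double xj, double yj, double alj, double aj, double bj,
                   double L) {
  PairContact pc;
  double dx = min_image1(xj - xi, L), dy = min_image1(yj - yi, L);
  {
    double ca0 = std::cos(ali), sa0 = std::sin(ali);
    compute_pair(ai, bi, aj, bj, ca0 * dx + sa0 * dy, -sa0 * dx + ca0 * dy,
                 alj - ali, pc);
  }
  if (pc.status == 3) stop("coincident ellipses: degenerate configuration");
  double ca = std::cos(ali), sa = std::sin(ali);
  double cb = std::cos(alj), sb = std::sin(alj);
  NumericMatrix pts(pc.npts, 2), ptsj(pc.npts, 2);
  NumericVector thi(pc.npts), thj(pc.npts);
  for (int k = 0; k < pc.npts; ++k) {
    // points in cell i's periodic image frame (global coords near cell i)
    pts(k, 0) = xi + ca * pc.pix[k] - sa * pc.piy[k];
    pts(k, 1) = yi + sa * pc.pix[k] + ca * pc.piy[k];
    thi[k] = pc.thi[k];
    // same points near cell j's image (for the partner's bookkeeping)
    ptsj(k, 0) = xi + dx + cb * pc.pjx[k] - sb * pc.pjy[k];
    ptsj(k, 1) = yi + dy + sb * pc.pjx[k] + cb * pc.pjy[k];
    thj[k] = pc.thj[k];
  }
  return List::create(
      _["status"] = pc.status, _["K"] = pc.K,
      _["points"] = pts, _["thetas"] = thi,
      _["points_j"] = ptsj, _["thetas_j"] = thj,
      _["contained"] = pc.contained, _["tangency"] = pc.tangency);
}

// ------------------------------------------------------------ overlap area
// polygonal approximation of both boundaries + Sutherland-Hodgman clipping

// [[Rcpp::export]]
double cpp_overlap_area(double xi, double yi, double ali, double ai, double bi,
                        double xj, double yj, double alj, double aj, double bj,
                        double L, int n = 4096) {
  double dx = min_image1(xj - xi, L), dy = min_image1(yj - yi, L);
  double ca = std::cos(ali), sa = std::sin(ali);
  double cx = ca * dx + sa * dy, cy = -sa * dx + ca * dy;
  double phi = alj - ali, cphi = std::cos(phi), sphi = std::sin(phi);

  if (std::hypot(cx, cy) > ai + aj) return 0.0; // bounding circles disjoint

  std::vector<double> sxv(n + 8), syv(n + 8), txv(n + 8), tyv(n + 8);
  std::vector<double> cxv(n), cyv(n);
  int ns = n;
  for (int k = 0; k < n; ++k) {
    double t = TWOPI * k / n;
    sxv[k] = ai * std::cos(t);
    syv[k] = bi * std::sin(t);
    double px = aj * std::cos(t), py = bj * std::sin(t);
    cxv[k] = cx + cphi * px - sphi * py;
    cyv[k] = cy + sphi * px + cphi * py;
  }
  // clip subject (cell i polygon) against each edge of cell j's polygon
  double bx0 = -ai, bx1 = ai, by0 = -bi, by1 = bi; // subject bbox
  for (int e = 0; e < n && ns > 2; ++e) {
    double x1 = cxv[e], y1 = cyv[e];
    double x2 = cxv[(e + 1) % n], y2 = cyv[(e + 1) % n];
    double ex = x2 - x1, ey = y2 - y1;
    // if the whole subject bbox is inside this half-plane, skip the pass
    double c1 = ex * (by0 - y1), c2 = ex * (by1 - y1);
    double d1 = ey * (bx0 - x1), d2 = ey * (bx1 - x1);
    double mn = std::min(c1, c2) - std::max(d1, d2);
    if (mn >= 0) continue; // min over corners of cross >= 0
    int nt = 0;
    double px = sxv[ns - 1], py = syv[ns - 1];
    double pc = ex * (py - y1) - ey * (px - x1);
    for (int k = 0; k < ns; ++k) {
      double qx = sxv[k], qy = syv[k];
      double qc = ex * (qy - y1) - ey * (qx - x1);
      if (qc >= 0) {
        if (pc < 0) {
          double t = pc / (pc - qc);
          txv[nt] = px + t * (qx - px);
          tyv[nt] = py + t * (qy - py);
          ++nt;
        }
        txv[nt] = qx; tyv[nt] = qy; ++nt;
      } else if (pc >= 0) {
        double t = pc / (pc - qc);
        txv[nt] = px + t * (qx - px);
        tyv[nt] = py + t * (qy - py);
        ++nt;
      }
      px = qx; py = qy; pc = qc;
      if (nt > (int)txv.size() - 4) { txv.resize(nt + n); tyv.resize(nt + n); }
    }
    std::swap(sxv, txv); std::swap(syv, tyv);
    ns = nt;
    if (ns > 2) {
      bx0 = bx1 = sxv[0]; by0 = by1 = syv[0];
      for (int k = 1; k < ns; ++k) {
        bx0 = std::min(bx0, sxv[k]); bx1 = std::max(bx1, sxv[k]);
        by0 = std::min(by0, syv[k]); by1 = std::max(by1, syv[k]);
      }
    }
  }
  if (ns < 3) return 0.0;
  double area = 0.0;
  for (int k = 0; k < ns; ++k) {
    int k2 = (k + 1) % ns;
    area += sxv[k] * syv[k2] - sxv[k2] * syv[k];
  }
  return std::fabs(area) / 2.0;
}

// --------------------------------------------------------------- pair scans

// mode 0: broad-phase candidates (bounding circles); mode 1: true overlaps
// [[Rcpp::export]]
IntegerMatrix cpp_pairs(NumericVector x, NumericVector y, NumericVector al,
                        NumericVector r, double L, int mode) {
  int N = x.size();
  std::vector<int> pi, pj;
  for (int i = 0; i < N; ++i) {
    double a_i = std::sqrt(r[i]);
    for (int j = i + 1; j < N; ++j) {
      double a_j = std::sqrt(r[j]);
      double dx = min_image1(x[j] - x[i], L), dy = min_image1(y[j] - y[i], L);
      double rad = a_i + a_j;
      if (dx * dx + dy * dy >= rad * rad) continue;
      if (mode == 1) {
        PairContact pc;
        pair_from_global(x[i], y[i], al[i], r[i], x[j], y[j], al[j], r[j], L, pc);
        if (pc.status != 1 && pc.status != 2 && pc.status != 3) continue;
      }
      pi.push_back(i + 1);
      pj.push_back(j + 1);
    }
  }
  IntegerMatrix out(pi.size(), 2);
  for (size_t k = 0; k < pi.size(); ++k) { out(k, 0) = pi[k]; out(k, 1) = pj[k]; }
  return out;
}

// ------------------------------------------------------- packing fraction

// [[Rcpp::export]]
double cpp_packing_fraction(NumericVector x, NumericVector y, NumericVector al,
                            NumericVector r, double L, int ngrid = 2048) {
  int N = x.size();
  std::vector<char> hit((size_t)ngrid * ngrid, 0);
  double h = L / ngrid;
  for (int i = 0; i < N; ++i) {
    double a = std::sqrt(r[i]), b = 1.0 / a;
    double ca = std::cos(al[i]), sa = std::sin(al[i]);
    int k0 = (int)std::floor((x[i] - a) / h) - 1, k1 = (int)std::ceil((x[i] + a) / h) + 1;
    int m0 = (int)std::floor((y[i] - a) / h) - 1, m1 = (int)std::ceil((y[i] + a) / h) + 1;
    for (int k = k0; k <= k1; ++k) {
      double px = (k + 0.5) * h - x[i];
      int kw = ((k % ngrid) + ngrid) % ngrid;
      for (int m = m0; m <= m1; ++m) {
        double py = (m + 0.5) * h - y[i];
        double ux = (ca * px + sa * py) / a;
        double uy = (-sa * px + ca * py) / b;
        if (ux * ux + uy * uy < 1.0) {
          int mw = ((m % ngrid) + ngrid) % ngrid;
          hit[(size_t)kw * ngrid + mw] = 1;
        }
      }
    }
  }
  size_t cnt = 0;
  for (size_t k = 0; k < hit.size(); ++k) cnt += hit[k];
  return (double)cnt / ((double)ngrid * ngrid);
}

// ---------------------------------------------------------------- junctions

// rows: i, end_i, j, end_j, type (1 fb, 2 ffbb), sep_x, sep_y, dist
// ends coded +1 (front) / -1 (back); i < j; separation from i's endpoint
// [[Rcpp::export]]
NumericMatrix cpp_find_junctions(NumericVector x, NumericVector y,
                                 NumericVector al, NumericVector r,
                                 double lam, double L) {
  int N = x.size();
  std::vector<double> rows;
  for (int i = 0; i < N; ++i) {
    double a_i = std::sqrt(r[i]), cai = std::cos(al[i]), sai = std::sin(al[i]);
    for (int j = i + 1; j < N; ++j) {
      double a_j = std::sqrt(r[j]), caj = std::cos(al[j]), saj = std::sin(al[j]);
      double dx = min_image1(x[j] - x[i], L), dy = min_image1(y[j] - y[i], L);
      double reach = a_i + a_j + lam;
      if (dx * dx + dy * dy >= reach * reach) continue;
      for (int si = -1; si <= 1; si += 2) {
        for (int sj = -1; sj <= 1; sj += 2) {
          double sx = min_image1(dx + sj * a_j * caj - si * a_i * cai, L);
          double sy = min_image1(dy + sj * a_j * saj - si * a_i * sai, L);
          double d = std::hypot(sx, sy);
          if (d < lam) {
            rows.insert(rows.end(), {(double)(i + 1), (double)si, (double)(j + 1),
                                     (double)sj, (si * sj < 0) ? 1.0 : 2.0, sx, sy, d});
          }
        }
      }
    }
  }
  NumericMatrix out(rows.size() / 8, 8);
  for (size_t k = 0; k < rows.size() / 8; ++k)
    for (int c = 0; c < 8; ++c) out(k, c) = rows[8 * k + c];
  colnames(out) = CharacterVector::create("i", "end_i", "j", "end_j", "type",
                                          "sep_x", "sep_y", "dist");
  return out;
}

// ------------------------------------------------------------------ engine

struct Events {
  long containment = 0, clamp_lo = 0, clamp_hi = 0, jitter = 0;
};

// derivatives of the full model at the current state (simultaneous update)
static void compute_derivs(int N, double *x, double *y, double *al, double *r,
                           double nu, double gamma, double rbar, double kappa,
                           double mu, double lam, double L, bool shape_on,
                           bool junctions_on, double *dx, double *dy,
                           double *dal, double *dr, Events &ev) {
  std::vector<double> a(N), b(N), ca(N), sa(N);
  for (int i = 0; i < N; ++i) {
    a[i] = std::sqrt(r[i]);
    b[i] = 1.0 / a[i];
    ca[i] = std::cos(al[i]);
    sa[i] = std::sin(al[i]);
    dx[i] = dy[i] = dal[i] = dr[i] = 0.0;
  }

  PairContact pc;
  for (int i = 0; i < N; ++i) {
    for (int j = i + 1; j < N; ++j) {
      double ddx = min_image1(x[j] - x[i], L), ddy = min_image1(y[j] - y[i], L);
      double rad = a[i] + a[j];
      if (ddx * ddx + ddy * ddy >= rad * rad) continue;
      double cx = ca[i] * ddx + sa[i] * ddy;
      double cy = -sa[i] * ddx + ca[i] * ddy;
      compute_pair(a[i], b[i], a[j], b[j], cx, cy, al[j] - al[i], pc);
      if (pc.status == 3) {
        // coincident: deterministic seeded jitter, retry once
        double ang = unif_rand() * TWOPI;
        x[j] = wrap_box(x[j] + 1e-6 * std::cos(ang), L);
        y[j] = wrap_box(y[j] + 1e-6 * std::sin(ang), L);
        ev.jitter++;
        ddx = min_image1(x[j] - x[i], L);
        ddy = min_image1(y[j] - y[i], L);
        cx = ca[i] * ddx + sa[i] * ddy;
        cy = -sa[i] * ddx + ca[i] * ddy;
        compute_pair(a[i], b[i], a[j], b[j], cx, cy, al[j] - al[i], pc);
        if (pc.status == 3) stop("coincident ellipses persisted after jitter");
      }
      if (pc.status == 1) {
        double roti = 2.0 * r[i] / (r[i] * r[i] + 1.0);
        double rotj = 2.0 * r[j] / (r[j] * r[j] + 1.0);
        double shi = 4.0 * r[i] * r[i] / (r[i] * r[i] + 1.0);
        double shj = 4.0 * r[j] * r[j] / (r[j] * r[j] + 1.0);
        for (int k = 0; k < pc.K; ++k) {
          // translation: -(Y_{2k-1} - Y_{2k})^perp, perp = (x,y) -> (-y,x)
          double vx = pc.pix[2 * k] - pc.pix[2 * k + 1];
          double vy = pc.piy[2 * k] - pc.piy[2 * k + 1];
          double gx = ca[i] * vx - sa[i] * vy; // rotate into global frame
          double gy = sa[i] * vx + ca[i] * vy;
          dx[i] += gy;  // -(-gy) = gy
          dy[i] += -gx;
          dal[i] += roti * ((pc.pix[2 * k + 1] * pc.pix[2 * k + 1] +
                             pc.piy[2 * k + 1] * pc.piy[2 * k + 1]) -
                            (pc.pix[2 * k] * pc.pix[2 * k] +
                             pc.piy[2 * k] * pc.piy[2 * k]));
          if (shape_on)
            dr[i] += shi * (std::sin(2.0 * pc.thi[2 * k]) -
                            std::sin(2.0 * pc.thi[2 * k + 1]));
          // partner cell, using its own ordered points
          double wx = pc.pjx[2 * k] - pc.pjx[2 * k + 1];
          double wy = pc.pjy[2 * k] - pc.pjy[2 * k + 1];
          double cb = std::cos(al[j]), sb = std::sin(al[j]);
          double hx = cb * wx - sb * wy;
          double hy = sb * wx + cb * wy;
          dx[j] += hy;
          dy[j] += -hx;
          dal[j] += rotj * ((pc.pjx[2 * k + 1] * pc.pjx[2 * k + 1] +
                             pc.pjy[2 * k + 1] * pc.pjy[2 * k + 1]) -
                            (pc.pjx[2 * k] * pc.pjx[2 * k] +
                             pc.pjy[2 * k] * pc.pjy[2 * k]));
          if (shape_on)
            dr[j] += shj * (std::sin(2.0 * pc.thj[2 * k]) -
                            std::sin(2.0 * pc.thj[2 * k + 1]));
        }
      } else if (pc.status == 2) {
        // containment fallback: push the contained cell out along the
        // centre difference, speed = containing cell's semi-minor axis
        int m = (pc.contained == 1) ? i : j;
        int nn = (pc.contained == 1) ? j : i;
        double ux = min_image1(x[m] - x[nn], L), uy = min_image1(y[m] - y[nn], L);
        double nrm = std::hypot(ux, uy);
        if (nrm < 1e-12) { ux = std::cos(al[m]); uy = std::sin(al[m]); nrm = 1.0; }
        dx[m] += b[nn] * ux / nrm;
        dy[m] += b[nn] * uy / nrm;
        ev.containment++;
      }
    }
  }

  for (int i = 0; i < N; ++i) {
    dx[i] += nu * ca[i];
    dy[i] += nu * sa[i];
    if (shape_on)
      dr[i] += 16.0 * gamma * (1.0 + rbar * r[i] * r[i] * r[i]) /
               (1.0 + r[i] * r[i]) * (1.0 - r[i] / rbar);
  }

  if (junctions_on && (kappa > 0 || mu > 0)) {
    for (int i = 0; i < N; ++i) {
      for (int j = i + 1; j < N; ++j) {
        double ddx = min_image1(x[j] - x[i], L), ddy = min_image1(y[j] - y[i], L);
        double reach = a[i] + a[j] + lam;
        if (ddx * ddx + ddy * ddy >= reach * reach) continue;
        for (int si = -1; si <= 1; si += 2) {
          for (int sj = -1; sj <= 1; sj += 2) {
            double sx = min_image1(ddx + sj * a[j] * ca[j] - si * a[i] * ca[i], L);
            double sy = min_image1(ddy + sj * a[j] * sa[j] - si * a[i] * sa[i], L);
            if (sx * sx + sy * sy >= lam * lam) continue;
            dx[i] += kappa * sx;
            dy[i] += kappa * sy;
            dx[j] -= kappa * sx;
            dy[j] -= kappa * sy;
            double pref_i = 4.0 * kappa * std::pow(r[i], 1.5) / (r[i] * r[i] + 1.0);
            double pref_j = 4.0 * kappa * std::pow(r[j], 1.5) / (r[j] * r[j] + 1.0);
            dal[i] += pref_i * si * (sx * (-sa[i]) + sy * ca[i]);
            dal[j] += pref_j * sj * ((-sx) * (-sa[j]) + (-sy) * ca[j]);
            double sgn = (si * sj < 0) ? -1.0 : 1.0; // fb aligns, ff/bb anti-aligns
            double sij = std::sin(al[i] - al[j]);
            dal[i] += mu * r[i] / (r[i] * r[i] + 1.0) * sgn * sij;
            dal[j] += mu * r[j] / (r[j] * r[j] + 1.0) * sgn * (-sij);
          }
        }
      }
    }
  }
}

// [[Rcpp::export]]
List cpp_derivs(NumericVector x, NumericVector y, NumericVector al,
                NumericVector r, double nu, double gamma, double rbar,
                double kappa, double mu, double lam, double L,
                bool shape_on, bool junctions_on) {
  int N = x.size();
  std::vector<double> xs(x.begin(), x.end()), ys(y.begin(), y.end());
  std::vector<double> as(al.begin(), al.end()), rs(r.begin(), r.end());
  NumericVector dx(N), dy(N), dal(N), dr(N);
  Events ev;
  compute_derivs(N, xs.data(), ys.data(), as.data(), rs.data(), nu, gamma,
                 rbar, kappa, mu, lam, L, shape_on, junctions_on,
                 REAL(dx), REAL(dy), REAL(dal), REAL(dr), ev);
  return List::create(_["dx"] = dx, _["dy"] = dy, _["dalpha"] = dal,
                      _["dr"] = dr,
                      _["events"] = IntegerVector::create(
                          _["containment"] = ev.containment,
                          _["clamp_lo"] = ev.clamp_lo,
                          _["clamp_hi"] = ev.clamp_hi,
                          _["jitter"] = ev.jitter));
}

// [[Rcpp::export]]
List cpp_simulate(NumericVector x0, NumericVector y0, NumericVector al0,
                  NumericVector r0, double nu, double gamma, double rbar,
                  double kappa, double mu, double lam, double L, double dt,
                  int nsteps, int save_every, bool shape_on, bool junctions_on,
                  double noise_sd) {
  int N = x0.size();
  std::vector<double> x(x0.begin(), x0.end()), y(y0.begin(), y0.end());
  std::vector<double> al(al0.begin(), al0.end()), r(r0.begin(), r0.end());
  std::vector<double> dx(N), dy(N), dal(N), dr(N);
  int nframes = nsteps / save_every + 1;
  NumericMatrix FX(nframes, N), FY(nframes, N), FA(nframes, N), FR(nframes, N);
  NumericVector times(nframes);
  std::vector<double> jrows;
  Events ev;

  auto record = [&](int frame, int stepno) {
    times[frame] = stepno * dt;
    for (int i = 0; i < N; ++i) {
      if (!R_FINITE(x[i]) || !R_FINITE(y[i]) || !R_FINITE(al[i]) || !R_FINITE(r[i]))
        stop("non-finite state at t = %f (cell %d)", stepno * dt, i + 1);
      FX(frame, i) = x[i];
      FY(frame, i) = y[i];
      FA(frame, i) = al[i];
      FR(frame, i) = r[i];
    }
    if (junctions_on) {
      for (int i = 0; i < N; ++i) {
        double a_i = std::sqrt(r[i]);
        for (int j = i + 1; j < N; ++j) {
          double a_j = std::sqrt(r[j]);
          double ddx = min_image1(x[j] - x[i], L), ddy = min_image1(y[j] - y[i], L);
          double reach = a_i + a_j + lam;
          if (ddx * ddx + ddy * ddy >= reach * reach) continue;
          for (int si = -1; si <= 1; si += 2)
            for (int sj = -1; sj <= 1; sj += 2) {
              double sx = min_image1(ddx + sj * a_j * std::cos(al[j]) -
                                     si * a_i * std::cos(al[i]), L);
              double sy = min_image1(ddy + sj * a_j * std::sin(al[j]) -
                                     si * a_i * std::sin(al[i]), L);
              if (sx * sx + sy * sy < lam * lam)
                jrows.insert(jrows.end(),
                             {stepno * dt, (double)(i + 1), (double)si,
                              (double)(j + 1), (double)sj,
                              (si * sj < 0) ? 1.0 : 2.0});
            }
        }
      }
    }
  };

  record(0, 0);
  int frame = 1;
  for (int s = 1; s <= nsteps; ++s) {
    compute_derivs(N, x.data(), y.data(), al.data(), r.data(), nu, gamma, rbar,
                   kappa, mu, lam, L, shape_on, junctions_on, dx.data(),
                   dy.data(), dal.data(), dr.data(), ev);
    for (int i = 0; i < N; ++i) {
      x[i] = wrap_box(x[i] + dt * dx[i], L);
      y[i] = wrap_box(y[i] + dt * dy[i], L);
      double na = al[i] + dt * dal[i];
      if (noise_sd > 0) na += noise_sd * std::sqrt(dt) * norm_rand();
      al[i] = wrap_angle(na);
      if (shape_on) {
        double nr = r[i] + dt * dr[i];
        if (nr < 1.0) { nr = 1.0; ev.clamp_lo++; }
        if (nr > 16.0) { nr = 16.0; ev.clamp_hi++; }
        r[i] = nr;
      }
    }
    if (s % save_every == 0 && frame < nframes) record(frame++, s);
    if (s % 2000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix J(jrows.size() / 6, 6);
  for (size_t k = 0; k < jrows.size() / 6; ++k)
    for (int c = 0; c < 6; ++c) J(k, c) = jrows[6 * k + c];
  colnames(J) = CharacterVector::create("t", "i", "end_i", "j", "end_j", "type");

  return List::create(
      _["times"] = times, _["x"] = FX, _["y"] = FY, _["alpha"] = FA,
      _["r"] = FR, _["junctions"] = J,
      _["events"] = IntegerVector::create(
          _["containment"] = ev.containment, _["clamp_lo"] = ev.clamp_lo,
          _["clamp_hi"] = ev.clamp_hi, _["jitter"] = ev.jitter));
}
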