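#include <Rcpp.h>
using namespace Rcpp;

// 2D zonal shoal dynamics + stimulus-response window simulation.
// All distances in mm, angles in radians, time in frames.
// Uses R's RNG (RNGScope) so set.seed() in R gives reproducible runs.

namespace {

struct Arena {
  int shape;        // 0 = stadium, 1 = ellipse
  double a;         // stadium: half length of central spine
  double r;         // stadium: cap radius (= half width)
  double A, B;      // ellipse semi-axes
};

inline double clampd(double v, double lo, double hi) {
  return v < lo ? lo : (v > hi ? hi : v);
}

// signed distance to wall (positive inside) and inward unit normal
inline void wallInfo(const Arena &ar, double x, double y,
                     double &d, double &nx, double &ny) {
  if (ar.shape == 0) {
    double qx = clampd(x, -ar.a, ar.a);
    double dx = x - qx, dy = y;
    double dd = std::sqrt(dx * dx + dy * dy);
    d = ar.r - dd;
    if (dd > 1e-9) { nx = -dx / dd; ny = -dy / dd; }
    else { nx = 0.0; ny = 0.0; }
  } else {
    double ux = x / ar.A, uy = y / ar.B;
    double rho = std::sqrt(ux * ux + uy * uy);
    d = (1.0 - rho) * std::min(ar.A, ar.B);
    double gx = x / (ar.A * ar.A), gy = y / (ar.B * ar.B);
    double gn = std::sqrt(gx * gx + gy * gy);
    if (gn > 1e-12) { nx = -gx / gn; ny = -gy / gn; }
    else { nx = 0.0; ny = 0.0; }
  }
}

inline double wrapAngle(double a) {
  while (a > M_PI) a -= 2.0 * M_PI;
  while (a < -M_PI) a += 2.0 * M_PI;
  return a;
}

struct ZoneParams {
  double rRep, rAli, rAtt;
  double wAlign, wAttract, wWall, wallDist;
  double wWander;            // weight of the per-frame random steering unit vector
  double noiseSD, turnMax;   // radians
};

// one step of the zonal model; goal[i] >= 0 means fish i steers to
// (gx, gy) ignoring social terms (wall avoidance still applies);
// spd[i] is the per-fish step length for this frame.
void stepFrame(int n, std::vector<double> &x, std::vector<double> &y,
               std::vector<double> &th, const std::vector<double> &spd,
               const std::vector<int> &goal, double gx, double gy,
               const Arena &ar, const ZoneParams &p) {
  std::vector<double> newth(n);
  for (int i = 0; i < n; ++i) {
    double dx = 0.0, dy = 0.0;   // desired direction (unnormalised)
    if (goal[i] == 1) {
      double tx = gx - x[i], ty = gy - y[i];
      double dn = std::sqrt(tx * tx + ty * ty);
      if (dn > 1e-9) { dx = tx / dn; dy = ty / dn; }
    } else {
      double repx = 0.0, repy = 0.0;
      double alx = 0.0, aly = 0.0;
      double atx = 0.0, aty = 0.0;
      bool rep = false;
      for (int j = 0; j < n; ++j) {
        if (j == i) continue;
        double ddx = x[j] - x[i], ddy = y[j] - y[i];
        double dij = std::sqrt(ddx * ddx + ddy * ddy);
        if (dij < 1e-9) continue;
        if (dij < p.rRep) {
          rep = true; repx -= ddx / dij; repy -= ddy / dij;
        } else if (dij < p.rAli) {
          alx += std::cos(th[j]); aly += std::sin(th[j]);
        } else if (dij < p.rAtt) {
          atx += ddx / dij; aty += ddy / dij;
        }
      }
      if (rep) {
        double rn = std::sqrt(repx * repx + repy * repy);
        if (rn > 1e-9) { dx = repx / rn; dy = repy / rn; }
      } else {
        double an = std::sqrt(alx * alx + aly * aly);
        double tn = std::sqrt(atx * atx + aty * aty);
        if (an > 1e-9) { dx += p.wAlign * alx / an; dy += p.wAlign * aly / an; }
        if (tn > 1e-9) { dx += p.wAttract * atx / tn; dy += p.wAttract * aty / tn; }
        if (p.wWander > 0) {            // exploratory steering: the knob the
          double wa = unif_rand() * 2.0 * M_PI;   // alignment weight competes with
          dx += p.wWander * std::cos(wa);
          dy += p.wWander * std::sin(wa);
        }
      }
    }
    // wall avoidance ramps up within wallDist of the boundary
    double wd, wnx, wny;
    wallInfo(ar, x[i], y[i], wd, wnx, wny);
    if (wd < p.wallDist) {
      double wgt = p.wWall * (1.0 - clampd(wd, 0.0, p.wallDist) / p.wallDist);
      dx += wgt * wnx; dy += wgt * wny;
    }
    double dn = std::sqrt(dx * dx + dy * dy);
    double target = (dn > 1e-9) ? std::atan2(dy, dx) : th[i];
    double dth = wrapAngle(target - th[i]);
    dth = clampd(dth, -p.turnMax, p.turnMax);
    newth[i] = wrapAngle(th[i] + dth + norm_rand() * p.noiseSD);
  }
  for (int i = 0; i < n; ++i) {
    th[i] = newth[i];
    double nx_ = x[i] + spd[i] * std::cos(th[i]);
    double ny_ = y[i] + spd[i] * std::sin(th[i]);
    double wd, wnx, wny;
    wallInfo(ar, nx_, ny_, wd, wnx, wny);
    if (wd < 1.0) {                       // hit the wall: project in, reflect
      nx_ += (1.0 - wd) * wnx;
      ny_ += (1.0 - wd) * wny;
      double hx = std::cos(th[i]), hy = std::sin(th[i]);
      double dot = hx * (-wnx) + hy * (-wny);   // outward normal component
      if (dot > 0) {
        hx -= 2.0 * dot * (-wnx);
        hy -= 2.0 * dot * (-wny);
        th[i] = std::atan2(hy, hx);
      }
    }
    x[i] = nx_; y[i] = ny_;
  }
}

Arena arenaFromList(const List &al) {
  Arena ar;
  ar.shape = as<int>(al["shape"]);
  ar.a = as<double>(al["a"]);
  ar.r = as<double>(al["r"]);
  ar.A = as<double>(al["A"]);
  ar.B = as<double>(al["B"]);
  return ar;
}

ZoneParams zoneFromList(const List &pl) {
  ZoneParams p;
  p.rRep = as<double>(pl["rRep"]);
  p.rAli = as<double>(pl["rAli"]);
  p.rAtt = as<double>(pl["rAtt"]);
  p.wAlign = as<double>(pl["wAlign"]);
  p.wAttract = as<double>(pl["wAttract"]);
  p.wWall = as<double>(pl["wWall"]);
  p.wWander = as<double>(pl["wWander"]);
  p.wallDist = as<double>(pl["wallDist"]);
  p.noiseSD = as<double>(pl["noiseSD"]);
  p.turnMax = as<double>(pl["turnMax"]);
  return p;
}

// is the open segment p->q cut by the ellipse (body) of fish k?
bool segmentBlocked(double px, double py, double qx, double qy,
                    double cx, double cy, double phi,
                    double sa, double sb) {
  double cphi = std::cos(phi), sphi = std::sin(phi);
  auto toEll = [&](double ux, double uy, double &ox, double &oy) {
    double rx = ux - cx, ry = uy - cy;
    ox = (cphi * rx + sphi * ry) / sa;
    oy = (-sphi * rx + cphi * ry) / sb;
  };
  double Px, Py, Qx, Qy;
  toEll(px, py, Px, Py);
  toEll(qx, qy, Qx, Qy);
  double Dx = Qx - Px, Dy = Qy - Py;
  double a = Dx * Dx + Dy * Dy;
  double b = Px * Dx + Py * Dy;
  double c = Px * Px + Py * Py - 1.0;
  if (c < 0) return true;                  // start point inside the body
  double disc = b * b - a * c;
  if (disc < 0 || a < 1e-12) return false;
  double sq = std::sqrt(disc);
  double t1 = (-b - sq) / a, t2 = (-b + sq) / a;
  const double eps = 1e-6;
  return (t1 > eps && t1 < 1.0 - eps) || (t2 > eps && t2 < 1.0 - eps);
}

}  // namespace

// [[Rcpp::export]]
List simulate_shoal_cpp(NumericVector x0, NumericVector y0,
                        NumericVector th0, NumericVector speeds,
                        List arenaPrm, List zonePrm, int nFrames) {
  RNGScope scope;
  int n = x0.size();
  Arena ar = arenaFromList(arenaPrm);
  ZoneParams zp = zoneFromList(zonePrm);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> spd(speeds.begin(), speeds.end());
  std::vector<int> goal(n, 0);
  NumericMatrix X(nFrames, n), Y(nFrames, n), TH(nFrames, n);
  for (int i = 0; i < n; ++i) { X(0, i) = x[i]; Y(0, i) = y[i]; TH(0, i) = th[i]; }
  for (int t = 1; t < nFrames; ++t) {
    stepFrame(n, x, y, th, spd, goal, 0.0, 0.0, ar, zp);
    for (int i = 0; i < n; ++i) { X(t, i) = x[i]; Y(t, i) = y[i]; TH(t, i) = th[i]; }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH);
}

// Post-onset response window: zonal dynamics plus the two-channel
// detection model. Private detection requires the stimulus inside the
// binocular sector and an unoccluded line of sight; the per-frame hazard
// is h0 * exp(-d / lambda). Social response scales with the number of
// visible already-responding neighbours and the alignment gain
// (1 + gamma * P_pre). Responders steer straight to the port at
// goalMult x their base speed until within two body lengths.
// [[Rcpp::export]]
List simulate_window_cpp(NumericVector x0, NumericVector y0,
                         NumericVector th0, NumericVector speeds,
                         NumericVector bodyLen,
                         List arenaPrm, List zonePrm,
                         double portx, double porty,
                         double h0, double lambda, double s0,
                         double gammaGain, double goalMult, double Ppre,
                         double binHalf, double fullHalf, double aspect,
                         int nFrames) {
  RNGScope scope;
  int n = x0.size();
  Arena ar = arenaFromList(arenaPrm);
  ZoneParams zp = zoneFromList(zonePrm);
  std::vector<double> x(x0.begin(), x0.end());
  std::vector<double> y(y0.begin(), y0.end());
  std::vector<double> th(th0.begin(), th0.end());
  std::vector<double> base(speeds.begin(), speeds.end());
  std::vector<double> spd(base);
  std::vector<int> mode(n, 0);       // 0 swim, 1 responding, 2 arrived
  std::vector<int> goal(n, 0);
  IntegerVector channel(n, 0);       // 0 none, 1 private, 2 social
  IntegerVector tDetect(n, NA_INTEGER), tArrive(n, NA_INTEGER);
  NumericMatrix X(nFrames, n), Y(nFrames, n), TH(nFrames, n);
  double cosBin = std::cos(binHalf), cosFull = std::cos(fullHalf);
  double gain = 1.0 + gammaGain * Ppre;

  for (int t = 0; t < nFrames; ++t) {
    // detections first, on the current (pre-step) state: a fish facing the
    // stimulus at onset can respond in the first window frame
    int nResp = 0;
    for (int i = 0; i < n; ++i) if (mode[i] > 0) ++nResp;
    for (int i = 0; i < n; ++i) {
      if (mode[i] != 0) continue;
      double dxs = portx - x[i], dys = porty - y[i];
      double dstim = std::sqrt(dxs * dxs + dys * dys);
      double ux = dxs / dstim, uy = dys / dstim;
      double hx = std::cos(th[i]), hy = std::sin(th[i]);
      bool inBin = (hx * ux + hy * uy) >= cosBin;
      bool responded = false;
      if (inBin) {
        bool occ = false;
        for (int j = 0; j < n && !occ; ++j) {
          if (j == i) continue;
          occ = segmentBlocked(x[i], y[i], portx, porty, x[j], y[j], th[j],
                               0.5 * bodyLen[j], 0.5 * aspect * bodyLen[j]);
        }
        if (!occ) {
          double p = std::min(1.0, h0 * std::exp(-dstim / lambda));
          if (unif_rand() < p) {
            mode[i] = 1; channel[i] = 1; tDetect[i] = t + 1;
            responded = true;
          }
        }
      }
      if (!responded && nResp > 0 && s0 > 0) {
        int k = 0;
        for (int j = 0; j < n; ++j) {
          if (j == i || mode[j] == 0 || channel[j] == 0) continue;
          double dxj = x[j] - x[i], dyj = y[j] - y[i];
          double dj = std::sqrt(dxj * dxj + dyj * dyj);
          if (dj < 1e-9) continue;
          if ((hx * dxj + hy * dyj) / dj < cosFull) continue;
          bool occ = false;
          for (int m = 0; m < n && !occ; ++m) {
            if (m == i || m == j) continue;
            occ = segmentBlocked(x[i], y[i], x[j], y[j], x[m], y[m], th[m],
                                 0.5 * bodyLen[m], 0.5 * aspect * bodyLen[m]);
          }
          if (!occ) ++k;
        }
        if (k > 0) {
          double p = std::min(1.0, s0 * k * gain);
          if (unif_rand() < p) {
            mode[i] = 1; channel[i] = 2; tDetect[i] = t + 1;
          }
        }
      }
    }
    for (int i = 0; i < n; ++i) {
      goal[i] = (mode[i] == 1) ? 1 : 0;
      spd[i] = (mode[i] == 1) ? goalMult * base[i]
             : (mode[i] == 2) ? 0.3 : base[i];
    }
    stepFrame(n, x, y, th, spd, goal, portx, porty, ar, zp);
    for (int i = 0; i < n; ++i) {
      if (mode[i] == 1) {
        double dx = portx - x[i], dy = porty - y[i];
        if (std::sqrt(dx * dx + dy * dy) <= 2.0 * bodyLen[i]) {
          mode[i] = 2;
          tArrive[i] = t + 1;
        }
      }
    }
    for (int i = 0; i < n; ++i) { X(t, i) = x[i]; Y(t, i) = y[i]; TH(t, i) = th[i]; }
  }
  return List::create(_["x"] = X, _["y"] = Y, _["theta"] = TH,
                      _["channel"] = channel, _["tDetect"] = tDetect,
                      _["tArrive"] = tArrive);
}
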