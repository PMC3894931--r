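#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <functional>
#include <algorithm>
using namespace Rcpp;

// Fixed-step crowd simulation loop.
//
// One frame: for every agent (in index order) assess group status, select
// the active behaviour from its type and status, evaluate the behaviour
// kernels plus the passive crowd repulsion, and sum the effects into a
// displacement.  All displacements are computed from the same frame's
// state and applied together (synchronous update); the heading becomes the
// direction of the realised displacement.  The run terminates when the
// group centroid's radius reaches the outer circle.
//
// RNG: draws come from R's own stream (unif_rand) in a fixed order --
// per agent: wander turn decision, then optional turn angle, then any
// degenerate-direction draws -- so a run is bit-reproducible under
// set.seed() and matches the pure-R sim_step() draw for draw.

static const double EPS = 1e-12;

static inline double g_lin(double d, double thr) {
  return (d >= thr) ? 0.0 : (thr - d) / thr;
}

static inline void rand_unit(double &ux, double &uy) {
  double ang = (2.0 * M_PI) * unif_rand();
  ux = std::cos(ang);
  uy = std::sin(ang);
}

// [[Rcpp::export]]
List crowd_run_cpp(NumericMatrix pos0, NumericMatrix head0, NumericVector es,
                   LogicalVector informed, NumericVector target_xy,
                   NumericMatrix numbers, double outer_radius,
                   double arms_length, double group_range,
                   double rep_threshold, double theta_max, double turn_prob,
                   double dt, double arrival_band, int max_frames,
                   int log_every, int policy_blend, int wander_persistent,
                   int status_component, int capture_mode,
                   double capture_radius) {
  const int n = pos0.nrow();
  std::vector<double> px(n), py(n), hx(n), hy(n), dx(n), dy(n);
  std::vector<double> wx(n), wy(n);   // persistent wander headings
  std::vector<char> wandered(n, 0);   // did the agent wander last frame?
  for (int i = 0; i < n; ++i) {
    px[i] = pos0(i, 0); py[i] = pos0(i, 1);
    hx[i] = head0(i, 0); hy[i] = head0(i, 1);
    wx[i] = hx[i]; wy[i] = hy[i];
  }

  std::vector<double> dmat((size_t)n * n, 0.0);
  std::vector<int> uf(n), csize(n);
  std::function<int(int)> uf_find = [&](int i) {
    while (uf[i] != i) { uf[i] = uf[uf[i]]; i = uf[i]; }
    return i;
  };
  std::vector<int> log_frames;
  std::vector<double> log_pos;
  bool logging = log_every > 0;
  auto log_now = [&](int f) {
    log_frames.push_back(f);
    for (int i = 0; i < n; ++i) {
      log_pos.push_back(px[i]);
      log_pos.push_back(py[i]);
    }
  };
  if (logging) log_now(0);

  bool terminated = false;
  int number_reached = NA_INTEGER;
  double t_end = NA_REAL, cx_end = NA_REAL, cy_end = NA_REAL;
  double crossing_time = NA_REAL;  // first centroid crossing of the circle
  int frames_done = 0;

  for (int frame = 1; frame <= max_frames; ++frame) {
    // pairwise distances for this frame
    for (int i = 0; i < n; ++i) {
      dmat[(size_t)i * n + i] = 0.0;
      for (int j = i + 1; j < n; ++j) {
        double ddx = px[i] - px[j], ddy = py[i] - py[j];
        double d = std::sqrt(ddx * ddx + ddy * ddy);
        dmat[(size_t)i * n + j] = d;
        dmat[(size_t)j * n + i] = d;
      }
    }

    // group membership: either nearest-neighbour arm's length, or (default)
    // membership of the largest arm's-length-connected component, so that a
    // pair drifting off together still counts as having left the group
    int main_root = -1;
    if (status_component && n > 1) {
      for (int i = 0; i < n; ++i) uf[i] = i;
      for (int i = 0; i < n; ++i)
        for (int j = i + 1; j < n; ++j)
          if (dmat[(size_t)i * n + j] <= arms_length) {
            int ri = uf_find(i), rj = uf_find(j);
            if (ri != rj) uf[rj] = ri;
          }
      std::fill(csize.begin(), csize.end(), 0);
      for (int i = 0; i < n; ++i) csize[uf_find(i)]++;
      int best = -1;
      for (int i = 0; i < n; ++i)
        if (csize[i] > best) { best = csize[i]; main_root = i; }
    }

    for (int a = 0; a < n; ++a) {
      const double *da = &dmat[(size_t)a * n];
      bool in_group;
      if (n == 1) {
        in_group = true;
      } else if (status_component) {
        in_group = uf_find(a) == main_root;
      } else {
        double nearest = R_PosInf;
        for (int i = 0; i < n; ++i)
          if (i != a && da[i] < nearest) nearest = da[i];
        in_group = nearest <= arms_length;
      }

      double E = es[a];
      double ex = 0.0, ey = 0.0;

      bool do_seek = false, do_wander = false, do_kig = false;
      if (informed[a]) {
        if (in_group) {
          do_seek = true;
        } else if (policy_blend) {
          do_seek = true;
          do_kig = true;
        } else {
          do_kig = true;
        }
      } else {
        if (in_group) do_wander = true; else do_kig = true;
      }

      if (do_seek) {
        double vx = target_xy[0] - px[a], vy = target_xy[1] - py[a];
        double nv = std::sqrt(vx * vx + vy * vy);
        double ax, ay;
        if (nv < EPS) {
          rand_unit(ax, ay);
        } else {
          ax = vx / nv; ay = vy / nv;
        }
        ex += E * ax; ey += E * ay;
      }
      if (do_wander) {
        // wander_mode selects the base direction the random turn applies to:
        //   0 ("realised")  - the realised heading, every frame
        //   1 ("persistent")- the agent's own wander heading, evolving only
        //                     through the random turns (re-anchored to the
        //                     realised heading after non-wander frames)
        //   2 ("anchored")  - straight along its own wander heading between
        //                     turns; each turn re-anchors to the realised
        //                     heading before rotating
        double hxa, hya;
        if (wander_persistent == 0) {
          hxa = hx[a]; hya = hy[a];
        } else {
          if (!wandered[a]) { wx[a] = hx[a]; wy[a] = hy[a]; }
          hxa = wx[a]; hya = wy[a];
        }
        double u = unif_rand();
        if (u < turn_prob) {
          if (wander_persistent == 2) { hxa = hx[a]; hya = hy[a]; }
          double ang = -theta_max + (2.0 * theta_max) * unif_rand();
          double ca = std::cos(ang), sa = std::sin(ang);
          double nx = ca * hxa - sa * hya, ny = sa * hxa + ca * hya;
          hxa = nx; hya = ny;
        }
        if (wander_persistent != 0) { wx[a] = hxa; wy[a] = hya; }
        ex += E * hxa; ey += E * hya;
      }
      wandered[a] = do_wander ? 1 : 0;
      if (do_kig) {
        double sx = 0, sy = 0, ox = 0, oy = 0;
        int m = 0;
        for (int i = 0; i < n; ++i)
          if (i != a && da[i] <= group_range) {
            sx += px[i]; sy += py[i]; ox += hx[i]; oy += hy[i]; ++m;
          }
        if (m == 0) {
          // lost agent with no one in perception range: head back towards
          // the rest of the crowd as a whole
          for (int i = 0; i < n; ++i)
            if (i != a) { sx += px[i]; sy += py[i]; ox += hx[i]; oy += hy[i]; ++m; }
        }
        double ax = 0.0, ay = 0.0;
        if (m > 0) {
          double mpx = sx / m, mpy = sy / m;
          double mox = ox / m, moy = oy / m;
          double cx = mpx - px[a], cy = mpy - py[a];
          double nc = std::sqrt(cx * cx + cy * cy);
          double no = std::sqrt(mox * mox + moy * moy);
          if (nc < EPS) {
            if (no < EPS) {
              rand_unit(ax, ay);
            } else {
              ax = mox / no; ay = moy / no;
            }
          } else if (no < EPS) {
            ax = cx / nc; ay = cy / nc;
          } else {
            double c1x = cx / nc, c1y = cy / nc;
            double o1x = mox / no, o1y = moy / no;
            double sxx = c1x + o1x, syy = c1y + o1y;
            double ns = std::sqrt(sxx * sxx + syy * syy);
            if (ns < EPS) { ax = c1x; ay = c1y; }
            else { ax = sxx / ns; ay = syy / ns; }
          }
        }
        ex += E * ax; ey += E * ay;
      }

      // passive repulsion from everybody within the threshold
      double rx = 0.0, ry = 0.0;
      for (int i = 0; i < n; ++i) {
        if (i == a) continue;
        double d = da[i];
        if (d < rep_threshold) {
          double w = g_lin(d, rep_threshold);
          if (d < EPS) {
            double ux, uy;
            rand_unit(ux, uy);
            rx += w * ux; ry += w * uy;
          } else {
            rx += w * (px[a] - px[i]) / d;
            ry += w * (py[a] - py[i]) / d;
          }
        }
      }
      ex += E * rx; ey += E * ry;
      dx[a] = ex; dy[a] = ey;
    }

    // synchronous apply + heading update
    for (int a = 0; a < n; ++a) {
      px[a] += dx[a]; py[a] += dy[a];
      double nd = std::sqrt(dx[a] * dx[a] + dy[a] * dy[a]);
      if (nd > EPS) { hx[a] = dx[a] / nd; hy[a] = dy[a] / nd; }
      if (!R_finite(px[a]) || !R_finite(py[a]))
        stop("numerical failure: non-finite position for agent %d at frame %d",
             a + 1, frame);
    }
    frames_done = frame;
    if (logging && frame % log_every == 0) log_now(frame);

    double cx = 0, cy = 0;
    for (int a = 0; a < n; ++a) { cx += px[a]; cy += py[a]; }
    cx /= n; cy /= n;
    if (ISNA(crossing_time) && std::sqrt(cx * cx + cy * cy) >= outer_radius)
      crossing_time = frame * dt;
    bool done = false;
    int reached = NA_INTEGER;
    if (capture_mode) {
      // run ends when the centroid first comes within capture_radius of a
      // number card; that card is the number reached
      double best = R_PosInf;
      int bi = NA_INTEGER;
      for (int k = 0; k < numbers.nrow(); ++k) {
        double ddx = numbers(k, 0) - cx, ddy = numbers(k, 1) - cy;
        double dd = ddx * ddx + ddy * ddy;
        if (dd < best) { best = dd; bi = k + 1; }
      }
      if (best <= capture_radius * capture_radius) { done = true; reached = bi; }
    } else if (!ISNA(crossing_time)) {
      // run ends at the centroid's circle crossing; the number reached is
      // the nearest card (exact ties break to the lower index)
      double best = R_PosInf;
      for (int k = 0; k < numbers.nrow(); ++k) {
        double ddx = numbers(k, 0) - cx, ddy = numbers(k, 1) - cy;
        double dd = ddx * ddx + ddy * ddy;
        if (dd < best) { best = dd; reached = k + 1; }
      }
      done = true;
    }
    if (done) {
      terminated = true;
      t_end = frame * dt;
      cx_end = cx; cy_end = cy;
      number_reached = reached;
      if (logging && frame % log_every != 0) log_now(frame);
      break;
    }
  }

  LogicalVector arrived(n);
  for (int a = 0; a < n; ++a) {
    double r = std::sqrt(px[a] * px[a] + py[a] * py[a]);
    arrived[a] = r >= outer_radius - arrival_band;
  }
  NumericMatrix pos_final(n, 2), head_final(n, 2);
  for (int i = 0; i < n; ++i) {
    pos_final(i, 0) = px[i]; pos_final(i, 1) = py[i];
    head_final(i, 0) = hx[i]; head_final(i, 1) = hy[i];
  }

  List traj = R_NilValue;
  if (logging) {
    int nl = log_frames.size();
    NumericMatrix lp(nl, 2 * n);
    for (int r = 0; r < nl; ++r)
      for (int c = 0; c < 2 * n; ++c)
        lp(r, c) = log_pos[(size_t)r * 2 * n + c];
    traj = List::create(_["frames"] = wrap(log_frames),
                        _["positions"] = lp);
  }

  return List::create(
    _["terminated"] = terminated,
    _["frames"] = frames_done,
    _["time"] = t_end,
    _["crossing_time"] = crossing_time,
    _["number_reached"] = number_reached,
    _["centroid"] = NumericVector::create(cx_end, cy_end),
    _["arrived"] = arrived,
    _["positions"] = pos_final,
    _["headings"] = head_final,
    _["trajectory"] = traj);
}
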