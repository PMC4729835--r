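#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Exact Gillespie (SSA) evolution of the volume-excluding lattice model.
//
// State: an Lx (dorsoventral) x Ly (axial) lattice, at most one agent per
// site.  Event classes and propensities:
//   move          N * pm   (agent uniform, direction uniform over 4)
//   proliferate   N * pp   (progeny inherits lineage / colour / rare mark)
//   grow_dv       pgd      (one new empty site inserted per axial row,
//                           insertion column uniform on 1..Lx per row;
//                           contents at and beyond the column shift ventrally)
//   grow_ax       pga      (mirror image, one new empty site per dv column)
// Attempts into occupied or out-of-bounds sites are aborted but still consume
// the sampled event.  Boundaries are zero-flux unless `periodic`.
//
// Observers (snapshots, track samples, rare-clone marking) fire at their
// scheduled times inside inter-event intervals, where the state is constant;
// an observer scheduled exactly at an event time sees the pre-event state.
//
// All randomness comes from R's RNG stream (unif_rand / exp_rand), so results
// are bit-reproducible under set.seed().

namespace {

struct Engine {
  int Lx, Ly;
  std::vector<int> X, Y, LIN, COL, RARE; // 1-based site indices
  std::vector<int> occ;                  // (x-1) + (y-1)*Lx -> agent id + 1, or 0
  bool periodic;

  inline int idx(int x, int y) const { return (x - 1) + (y - 1) * Lx; }

  void rebuild_occ() {
    occ.assign((size_t)Lx * Ly, 0);
    for (size_t a = 0; a < X.size(); ++a) occ[idx(X[a], Y[a])] = (int)a + 1;
  }
};

inline int runif_int(int n) { // uniform on 0..n-1
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

} // namespace

// [[Rcpp::export(name = ".engine_run")]]
List engine_run(int Lx, int Ly,
                IntegerVector site_dv, IntegerVector site_ax,
                IntegerVector lineage, IntegerVector colour, IntegerVector rare,
                double pm, double pp, double pga, double pgd,
                double t_end,
                NumericVector sample_times,
                bool periodic,
                double mark_time,
                bool record_events,
                bool track,
                double track_interval) {
  Engine E;
  E.Lx = Lx; E.Ly = Ly; E.periodic = periodic;
  const int n0 = site_dv.size();
  E.X.assign(site_dv.begin(), site_dv.end());
  E.Y.assign(site_ax.begin(), site_ax.end());
  E.LIN.assign(lineage.begin(), lineage.end());
  E.COL.assign(colour.begin(), colour.end());
  E.RARE.assign(rare.begin(), rare.end());
  E.rebuild_occ();

  // observers
  const int ns = sample_times.size();
  int si = 0;
  int ntrack = 0, ti = 0;
  NumericMatrix trk_x, trk_y;
  std::vector<double> ux, uy; // unwrapped positions of the initial agents
  NumericVector first_wrap;
  if (track) {
    ntrack = (int)std::floor(t_end / track_interval + 1e-9) + 1;
    trk_x = NumericMatrix(n0, ntrack);
    trk_y = NumericMatrix(n0, ntrack);
    ux.assign(E.X.begin(), E.X.end());
    uy.assign(E.Y.begin(), E.Y.end());
    first_wrap = NumericVector(n0, R_PosInf);
  }
  bool marked = false;
  int marked_agent = NA_INTEGER;
  double marked_at = NA_REAL;

  List snapshots(ns);

  // event log
  std::vector<double> ev_t;
  std::vector<int> ev_kind, ev_agent, ev_x1, ev_y1, ev_x2, ev_y2;
  std::vector<int> ev_exec;

  long long n_move_exec = 0, n_move_abort = 0;
  long long n_prolif_exec = 0, n_prolif_abort = 0;
  long long n_grow_dv = 0, n_grow_ax = 0;
  double agent_minutes = 0.0;
  bool early_stop = false;

  auto emit_snapshot = [&](double ts) {
    const size_t N = E.X.size();
    IntegerVector sx(N), sy(N), sl(N), sc(N), sr(N), id(N);
    for (size_t a = 0; a < N; ++a) {
      id[a] = (int)a + 1;
      sx[a] = E.X[a]; sy[a] = E.Y[a];
      sl[a] = E.LIN[a]; sc[a] = E.COL[a]; sr[a] = E.RARE[a];
    }
    snapshots[si] = List::create(
      _["time_min"] = ts, _["n_sites_dv"] = E.Lx, _["n_sites_axial"] = E.Ly,
      _["agent_id"] = id, _["site_dv"] = sx, _["site_ax"] = sy,
      _["lineage"] = sl, _["colour"] = sc, _["rare_mark"] = sr);
  };

  auto do_mark = [&](double tm) {
    const int N = (int)E.X.size();
    if (N > 0) {
      int a = runif_int(N);
      E.RARE[a] = 1;
      marked_agent = a + 1;
      marked_at = tm;
      if (record_events) {
        ev_t.push_back(tm); ev_kind.push_back(4); ev_exec.push_back(1);
        ev_agent.push_back(a + 1);
        ev_x1.push_back(E.X[a]); ev_y1.push_back(E.Y[a]);
        ev_x2.push_back(NA_INTEGER); ev_y2.push_back(NA_INTEGER);
      }
    }
    marked = true;
  };

  // process all observer times <= tmax (state is constant on the interval)
  auto advance_observers = [&](double tmax) {
    for (;;) {
      double ts = (si < ns) ? sample_times[si] : R_PosInf;
      double tt = (track && ti < ntrack) ? ti * track_interval : R_PosInf;
      double tm = (!marked && mark_time >= 0) ? mark_time : R_PosInf;
      double tnext = std::min(ts, std::min(tt, tm));
      if (tnext > tmax) break;
      if (tm <= ts && tm <= tt) {
        do_mark(tm);
      } else if (ts <= tt) {
        emit_snapshot(ts); ++si;
      } else {
        for (int a = 0; a < n0; ++a) { trk_x(a, ti) = ux[a]; trk_y(a, ti) = uy[a]; }
        ++ti;
      }
    }
  };

  double t = 0.0;
  for (;;) {
    const int N = (int)E.X.size();
    const double Rtot = N * (pm + pp) + pga + pgd;
    if (Rtot <= 0.0) {
      early_stop = true;
      agent_minutes += N * (t_end - t);
      break;
    }
    const double dt = exp_rand() / Rtot;
    const double tnew = t + dt;
    const double tstop = std::min(tnew, t_end);
    advance_observers(tstop);
    agent_minutes += N * (tstop - t);
    if (tnew >= t_end) { t = t_end; break; }
    t = tnew;

    const double u = unif_rand() * Rtot;
    if (u < N * (pm + pp)) {
      // agent event: move or proliferate
      const bool is_move = u < N * pm;
      const int a = runif_int(N);
      const int dir = runif_int(4);
      static const int DX[4] = { 1, -1, 0, 0 };
      static const int DY[4] = { 0, 0, 1, -1 };
      int tx = E.X[a] + DX[dir];
      int ty = E.Y[a] + DY[dir];
      bool in_bounds = true, wrapped = false;
      if (periodic) {
        if (tx < 1) { tx = E.Lx; wrapped = true; }
        else if (tx > E.Lx) { tx = 1; wrapped = true; }
        if (ty < 1) { ty = E.Ly; wrapped = true; }
        else if (ty > E.Ly) { ty = 1; wrapped = true; }
      } else {
        in_bounds = tx >= 1 && tx <= E.Lx && ty >= 1 && ty <= E.Ly;
      }
      bool exec = in_bounds && E.occ[E.idx(tx, ty)] == 0;
      int ox = E.X[a], oy = E.Y[a];
      if (exec) {
        if (is_move) {
          E.occ[E.idx(ox, oy)] = 0;
          E.X[a] = tx; E.Y[a] = ty;
          E.occ[E.idx(tx, ty)] = a + 1;
          if (track && a < n0) {
            ux[a] += DX[dir]; uy[a] += DY[dir];
            if (wrapped && !R_FINITE(first_wrap[a])) first_wrap[a] = t;
          }
          ++n_move_exec;
        } else {
          E.X.push_back(tx); E.Y.push_back(ty);
          E.LIN.push_back(E.LIN[a]); E.COL.push_back(E.COL[a]);
          E.RARE.push_back(E.RARE[a]);
          E.occ[E.idx(tx, ty)] = (int)E.X.size();
          ++n_prolif_exec;
        }
      } else {
        if (is_move) ++n_move_abort; else ++n_prolif_abort;
      }
      if (record_events) {
        ev_t.push_back(t); ev_kind.push_back(is_move ? 0 : 1);
        ev_exec.push_back(exec ? 1 : 0); ev_agent.push_back(a + 1);
        ev_x1.push_back(ox); ev_y1.push_back(oy);
        ev_x2.push_back(in_bounds ? tx : NA_INTEGER);
        ev_y2.push_back(in_bounds ? ty : NA_INTEGER);
      }
    } else if (u < N * (pm + pp) + pgd) {
      // dorsoventral growth: one new empty site per axial row
      std::vector<int> cut(E.Ly + 1);
      for (int y = 1; y <= E.Ly; ++y) cut[y] = 1 + runif_int(E.Lx);
      for (size_t a = 0; a < E.X.size(); ++a)
        if (E.X[a] >= cut[E.Y[a]]) ++E.X[a];
      ++E.Lx;
      E.rebuild_occ();
      ++n_grow_dv;
      if (record_events) {
        ev_t.push_back(t); ev_kind.push_back(2); ev_exec.push_back(1);
        ev_agent.push_back(NA_INTEGER);
        ev_x1.push_back(E.Lx); ev_y1.push_back(E.Ly);
        ev_x2.push_back(NA_INTEGER); ev_y2.push_back(NA_INTEGER);
      }
    } else {
      // axial growth: one new empty site per dorsoventral column
      std::vector<int> cut(E.Lx + 1);
      for (int x = 1; x <= E.Lx; ++x) cut[x] = 1 + runif_int(E.Ly);
      for (size_t a = 0; a < E.X.size(); ++a)
        if (E.Y[a] >= cut[E.X[a]]) ++E.Y[a];
      ++E.Ly;
      E.rebuild_occ();
      ++n_grow_ax;
      if (record_events) {
        ev_t.push_back(t); ev_kind.push_back(3); ev_exec.push_back(1);
        ev_agent.push_back(NA_INTEGER);
        ev_x1.push_back(E.Lx); ev_y1.push_back(E.Ly);
        ev_x2.push_back(NA_INTEGER); ev_y2.push_back(NA_INTEGER);
      }
    }
  }
  if (early_stop) advance_observers(t_end);

  const size_t N = E.X.size();
  IntegerVector fx(N), fy(N), fl(N), fc(N), fr(N), fid(N);
  for (size_t a = 0; a < N; ++a) {
    fid[a] = (int)a + 1;
    fx[a] = E.X[a]; fy[a] = E.Y[a];
    fl[a] = E.LIN[a]; fc[a] = E.COL[a]; fr[a] = E.RARE[a];
  }
  IntegerMatrix occ_out(E.Lx, E.Ly);
  for (int y = 1; y <= E.Ly; ++y)
    for (int x = 1; x <= E.Lx; ++x)
      occ_out(x - 1, y - 1) = E.occ[E.idx(x, y)];

  List events = R_NilValue;
  if (record_events) {
    events = List::create(
      _["time_min"] = NumericVector(ev_t.begin(), ev_t.end()),
      _["kind"] = IntegerVector(ev_kind.begin(), ev_kind.end()),
      _["executed"] = IntegerVector(ev_exec.begin(), ev_exec.end()),
      _["agent_id"] = IntegerVector(ev_agent.begin(), ev_agent.end()),
      _["x1"] = IntegerVector(ev_x1.begin(), ev_x1.end()),
      _["y1"] = IntegerVector(ev_y1.begin(), ev_y1.end()),
      _["x2"] = IntegerVector(ev_x2.begin(), ev_x2.end()),
      _["y2"] = IntegerVector(ev_y2.begin(), ev_y2.end()));
  }

  List tracks = R_NilValue;
  if (track) {
    tracks = List::create(
      _["x_sites"] = trk_x, _["y_sites"] = trk_y,
      _["sample_interval"] = track_interval,
      _["first_wrap_time"] = first_wrap);
  }

  return List::create(
    _["snapshots"] = snapshots,
    _["final"] = List::create(
      _["time_min"] = t_end, _["n_sites_dv"] = E.Lx, _["n_sites_axial"] = E.Ly,
      _["agent_id"] = fid, _["site_dv"] = fx, _["site_ax"] = fy,
      _["lineage"] = fl, _["colour"] = fc, _["rare_mark"] = fr,
      _["occupancy"] = occ_out),
    _["counts"] = List::create(
      _["move_exec"] = (double)n_move_exec, _["move_abort"] = (double)n_move_abort,
      _["proliferate_exec"] = (double)n_prolif_exec,
      _["proliferate_abort"] = (double)n_prolif_abort,
      _["grow_dv"] = (double)n_grow_dv, _["grow_ax"] = (double)n_grow_ax),
    _["agent_minutes"] = agent_minutes,
    _["events"] = events,
    _["tracks"] = tracks,
    _["marked_agent"] = marked_agent,
    _["marked_at"] = marked_at,
    _["early_stop"] = early_stop);
}
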