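// Coupled monodomain / Purkinje-cable time integrator.
//
// Operator splitting per macro step dt: membrane reaction (two-variable
// model, exact exponential gate update) + junctional (PMJ) resistive
// exchange, then an explicit diffusion substep (possibly sub-cycled for
// stability on fine grids). Tissue lives on a structured nx x ny grid with
// zero-flux boundaries; the Purkinje network is an arbitrary weighted graph
// integrated as a 1D cable. Threshold crossings of the transmembrane
// variable are recorded with linear-in-time interpolation in both
// directions, for both media.
//
// The dimensionless transmembrane variable v maps affinely to millivolts as
// V = vRest + v * (vPeak - vRest); the crossing threshold is passed already
// mapped to v-units.

#include <Rcpp.h>
#include <vector>
#include <cmath>
#include <sstream>
using namespace Rcpp;

namespace {

struct EventLog {
  std::vector<int> medium;   // 0 = tissue, 1 = network
  std::vector<int> node;     // 0-based node index within medium
  std::vector<double> time;  // ms, interpolated crossing time
  std::vector<int> dir;      // +1 ascending, -1 descending
  double last_time = -1e300;

  void push(int med, int nd, double t, int d) {
    medium.push_back(med);
    node.push_back(nd);
    time.push_back(t);
    dir.push_back(d);
    if (t > last_time) last_time = t;
  }
};

inline void crossings(EventLog& ev, int med, int n, const double* vold,
                      const double* vnew, double vth, double t, double dt) {
  for (int i = 0; i < n; ++i) {
    double a = vold[i], b = vnew[i];
    if (a < vth && b >= vth) {
      double f = (vth - a) / (b - a);
      ev.push(med, i, t + f * dt, 1);
    } else if (a >= vth && b < vth) {
      double f = (a - vth) / (a - b);
      ev.push(med, i, t + f * dt, -1);
    }
  }
}

}  // namespace

// [[Rcpp::export(name = ".simCore")]]
List simCore(List tissue, List net, List pmj, List stims, List ctrl) {
  // ---- tissue unpack (nt may be 0: network-only run) ----
  const int nx = as<int>(tissue["nx"]);
  const int ny = as<int>(tissue["ny"]);
  const int nt = nx * ny;
  const double hmm = nt > 0 ? as<double>(tissue["h"]) : 1.0;
  NumericVector vT = clone(as<NumericVector>(tissue["v"]));
  NumericVector hT = clone(as<NumericVector>(tissue["h_gate"]));
  NumericVector DT = as<NumericVector>(tissue["D"]);
  NumericVector tinT = as<NumericVector>(tissue["tau_in"]);
  NumericVector toutT = as<NumericVector>(tissue["tau_out"]);
  NumericVector topT = as<NumericVector>(tissue["tau_open"]);
  NumericVector tclT = as<NumericVector>(tissue["tau_close"]);

  // ---- network unpack (nn may be 0) ----
  const int nn = as<int>(net["n"]);
  NumericVector vN = clone(as<NumericVector>(net["v"]));
  NumericVector hN = clone(as<NumericVector>(net["h_gate"]));
  IntegerVector eFrom = as<IntegerVector>(net["efrom"]);  // 0-based
  IntegerVector eTo = as<IntegerVector>(net["eto"]);
  NumericVector eW = as<NumericVector>(net["ew"]);  // D_edge / len^2, 1/ms
  NumericVector tinN = as<NumericVector>(net["tau_in"]);
  NumericVector toutN = as<NumericVector>(net["tau_out"]);
  NumericVector topN = as<NumericVector>(net["tau_open"]);
  NumericVector tclN = as<NumericVector>(net["tau_close"]);
  const int ne = eFrom.size();

  // ---- PMJ unpack ----
  IntegerVector pTerm = as<IntegerVector>(pmj["term"]);      // net node, 0-based
  IntegerVector pFootPtr = as<IntegerVector>(pmj["fptr"]);   // CSR offsets
  IntegerVector pFootIdx = as<IntegerVector>(pmj["fidx"]);   // tissue nodes
  NumericVector pGNet = as<NumericVector>(pmj["g_net"]);     // 1/ms
  NumericVector pGMyo = as<NumericVector>(pmj["g_myo"]);     // 1/ms (total, split over footprint)
  const int np = pTerm.size();

  // ---- stimuli: matrix (onset, dur, amp, medium) + CSR node lists ----
  NumericMatrix sM = as<NumericMatrix>(stims["spec"]);  // ns x 4
  IntegerVector sPtr = as<IntegerVector>(stims["ptr"]);
  IntegerVector sIdx = as<IntegerVector>(stims["idx"]);
  const int ns = sM.nrow();

  // ---- control ----
  const double t0 = as<double>(ctrl["t0"]);
  const double tEnd = as<double>(ctrl["t_end"]);
  const double dt = as<double>(ctrl["dt"]);
  const int nsub = as<int>(ctrl["nsub"]);          // diffusion subcycles
  const double vth = as<double>(ctrl["vth"]);      // crossing threshold (v units)
  const double vgate = as<double>(ctrl["vgate"]);
  const bool reaction = as<bool>(ctrl["reaction"]);
  const double quiesceGap = as<double>(ctrl["quiesce_gap"]);  // 0 = off
  const double divergeBound = as<double>(ctrl["diverge_bound"]);
  IntegerVector probeT = as<IntegerVector>(ctrl["probe_t"]);  // 0-based tissue nodes
  IntegerVector probeN = as<IntegerVector>(ctrl["probe_n"]);
  const int probeEvery = as<int>(ctrl["probe_every"]);

  const long nSteps = (long)std::llround((tEnd - t0) / dt);

  // precomputed gate decay factors (dt fixed)
  std::vector<double> aOpT(nt), aClT(nt), aOpN(nn), aClN(nn);
  for (int i = 0; i < nt; ++i) {
    aOpT[i] = -std::expm1(-dt / topT[i]);
    aClT[i] = std::exp(-dt / tclT[i]);
  }
  for (int i = 0; i < nn; ++i) {
    aOpN[i] = -std::expm1(-dt / topN[i]);
    aClN[i] = std::exp(-dt / tclN[i]);
  }

  // edge conductances for the tissue grid (face-averaged D / h^2), and for
  // network edges, pre-scaled by the diffusion substep
  const double dts = dt / nsub;
  std::vector<double> wx, wy;  // x-faces: (nx-1)*ny, y-faces: nx*(ny-1)
  if (nt > 0) {
    wx.assign((size_t)(nx > 1 ? (nx - 1) * ny : 0), 0.0);
    wy.assign((size_t)(ny > 1 ? nx * (ny - 1) : 0), 0.0);
    const double inv_h2 = 1.0 / (hmm * hmm);
    if (nx > 1)
      for (int j = 0; j < ny; ++j)
        for (int i = 0; i < nx - 1; ++i) {
          int a = j * nx + i, b = a + 1;
          wx[(size_t)j * (nx - 1) + i] = 0.5 * (DT[a] + DT[b]) * inv_h2 * dts;
        }
    if (ny > 1)
      for (int j = 0; j < ny - 1; ++j)
        for (int i = 0; i < nx; ++i) {
          int a = j * nx + i, b = a + nx;
          wy[(size_t)j * nx + i] = 0.5 * (DT[a] + DT[b]) * inv_h2 * dts;
        }
  }
  std::vector<double> ewS(ne);
  for (int e = 0; e < ne; ++e) ewS[e] = eW[e] * dts;

  std::vector<double> vTold(nt), vNold(nn), lap(std::max(nt, nn), 0.0);
  EventLog ev;
  double lastStimEnd = t0;
  for (int s = 0; s < ns; ++s)
    lastStimEnd = std::max(lastStimEnd, sM(s, 0) + sM(s, 1));

  // probe storage
  const int nProbe = probeT.size() + probeN.size();
  std::vector<double> probeBuf;
  std::vector<double> probeTimes;

  std::string stopped = "end";
  double tStop = tEnd;
  long step = 0;

  for (step = 0; step < nSteps; ++step) {
    const double t = t0 + step * dt;
    std::copy(vT.begin(), vT.end(), vTold.begin());
    std::copy(vN.begin(), vN.end(), vNold.begin());

    // ---- reaction substep ----
    if (reaction) {
      for (int i = 0; i < nt; ++i) {
        double v = vT[i], h = hT[i];
        double dv = h * v * v * (1.0 - v) / tinT[i] - v / toutT[i];
        vT[i] = v + dt * dv;
        hT[i] = (v < vgate) ? h + (1.0 - h) * aOpT[i] : h * aClT[i];
      }
      for (int i = 0; i < nn; ++i) {
        double v = vN[i], h = hN[i];
        double dv = h * v * v * (1.0 - v) / tinN[i] - v / toutN[i];
        vN[i] = v + dt * dv;
        hN[i] = (v < vgate) ? h + (1.0 - h) * aOpN[i] : h * aClN[i];
      }
    }

    // ---- stimuli (transmembrane current injection) ----
    for (int s = 0; s < ns; ++s) {
      if (t >= sM(s, 0) && t < sM(s, 0) + sM(s, 1)) {
        const double add = sM(s, 2) * dt;
        const int med = (int)sM(s, 3);
        for (int k = sPtr[s]; k < sPtr[s + 1]; ++k) {
          if (med == 0)
            vT[sIdx[k]] += add;
          else
            vN[sIdx[k]] += add;
        }
      }
    }

    // ---- PMJ resistive exchange (uses pre-diffusion values) ----
    for (int p = 0; p < np; ++p) {
      const int a = pFootPtr[p], b = pFootPtr[p + 1];
      const int nf = b - a;
      if (nf == 0) continue;
      double vbar = 0.0;
      for (int k = a; k < b; ++k) vbar += vT[pFootIdx[k]];
      vbar /= nf;
      const double I = vN[pTerm[p]] - vbar;  // junctional driving difference
      vN[pTerm[p]] -= dt * pGNet[p] * I;
      const double addM = dt * pGMyo[p] * I / nf;
      for (int k = a; k < b; ++k) vT[pFootIdx[k]] += addM;
    }

    // ---- diffusion substeps (explicit, flux form, zero-flux boundaries) ----
    for (int sub = 0; sub < nsub; ++sub) {
      if (nt > 0 && (nx > 1 || ny > 1)) {
        std::fill(lap.begin(), lap.begin() + nt, 0.0);
        if (nx > 1)
          for (int j = 0; j < ny; ++j) {
            const size_t off = (size_t)j * (nx - 1);
            const int row = j * nx;
            for (int i = 0; i < nx - 1; ++i) {
              const double f = wx[off + i] * (vT[row + i + 1] - vT[row + i]);
              lap[row + i] += f;
              lap[row + i + 1] -= f;
            }
          }
        if (ny > 1)
          for (int j = 0; j < ny - 1; ++j) {
            const size_t off = (size_t)j * nx;
            for (int i = 0; i < nx; ++i) {
              const int a = j * nx + i;
              const double f = wy[off + i] * (vT[a + nx] - vT[a]);
              lap[a] += f;
              lap[a + nx] -= f;
            }
          }
        for (int i = 0; i < nt; ++i) vT[i] += lap[i];
      }
      if (nn > 0 && ne > 0) {
        std::fill(lap.begin(), lap.begin() + nn, 0.0);
        for (int e = 0; e < ne; ++e) {
          const double f = ewS[e] * (vN[eTo[e]] - vN[eFrom[e]]);
          lap[eFrom[e]] += f;
          lap[eTo[e]] -= f;
        }
        for (int i = 0; i < nn; ++i) vN[i] += lap[i];
      }
    }

    // ---- event detection ----
    crossings(ev, 0, nt, vTold.data(), REAL(vT), vth, t, dt);
    crossings(ev, 1, nn, vNold.data(), REAL(vN), vth, t, dt);

    // ---- probes ----
    if (nProbe > 0 && probeEvery > 0 && step % probeEvery == 0) {
      probeTimes.push_back(t + dt);
      for (int k = 0; k < probeT.size(); ++k) probeBuf.push_back(vT[probeT[k]]);
      for (int k = 0; k < probeN.size(); ++k) probeBuf.push_back(vN[probeN[k]]);
    }

    // ---- housekeeping every 400 steps ----
    if (step % 400 == 399) {
      for (int i = 0; i < nt; ++i)
        if (!std::isfinite(vT[i]) || std::fabs(vT[i]) > divergeBound) {
          std::ostringstream msg;
          msg << "state diverged at tissue node " << (i + 1) << ", t = "
              << (t + dt) << " ms";
          stop(msg.str());
        }
      for (int i = 0; i < nn; ++i)
        if (!std::isfinite(vN[i]) || std::fabs(vN[i]) > divergeBound) {
          std::ostringstream msg;
          msg << "state diverged at network node " << (i + 1) << ", t = "
              << (t + dt) << " ms";
          stop(msg.str());
        }
      if (quiesceGap > 0) {
        const double ref = std::max(ev.last_time, lastStimEnd);
        if (t + dt > ref + quiesceGap) {
          stopped = "quiescent";
          tStop = t + dt;
          break;
        }
      }
      Rcpp::checkUserInterrupt();
    }
  }
  if (stopped == "end") tStop = tEnd;

  List probes = R_NilValue;
  if (nProbe > 0 && !probeTimes.empty()) {
    const int nr = (int)probeTimes.size();
    NumericMatrix pm(nr, nProbe);
    for (int r = 0; r < nr; ++r)
      for (int c = 0; c < nProbe; ++c) pm(r, c) = probeBuf[(size_t)r * nProbe + c];
    probes = List::create(_["time"] = NumericVector(probeTimes.begin(), probeTimes.end()),
                          _["v"] = pm);
  }

  return List::create(
      _["events"] = DataFrame::create(
          _["medium"] = IntegerVector(ev.medium.begin(), ev.medium.end()),
          _["node"] = IntegerVector(ev.node.begin(), ev.node.end()),
          _["time"] = NumericVector(ev.time.begin(), ev.time.end()),
          _["dir"] = IntegerVector(ev.dir.begin(), ev.dir.end())),
      _["vT"] = vT, _["hT"] = hT, _["vN"] = vN, _["hN"] = hN,
      _["t_stop"] = tStop, _["stopped"] = stopped, _["probes"] = probes);
}

// Single-cell pacing run: returns threshold crossing times (both directions)
// of the transmembrane variable, for APD/restitution measurement.
// [[Rcpp::export(name = ".cellCrossings")]]
List cellCrossings(double tauIn, double tauOut, double tauOpen, double tauClose,
                   double vgate, double vth, double cl, int beats,
                   double stimAmp, double stimDur, double dt) {
  double v = 0.0, h = 1.0;
  const double tEnd = cl * beats;
  const long n = (long)std::llround(tEnd / dt);
  const double aOp = -std::expm1(-dt / tauOpen);
  const double aCl = std::exp(-dt / tauClose);
  std::vector<double> up, down;
  for (long s = 0; s < n; ++s) {
    const double t = s * dt;
    const double vold = v;
    double dv = h * v * v * (1.0 - v) / tauIn - v / tauOut;
    const double phase = t - cl * std::floor(t / cl);
    if (phase < stimDur) dv += stimAmp;
    v += dt * dv;
    h = (vold < vgate) ? h + (1.0 - h) * aOp : h * aCl;
    if (vold < vth && v >= vth)
      up.push_back(t + dt * (vth - vold) / (v - vold));
    else if (vold >= vth && v < vth)
      down.push_back(t + dt * (vold - vth) / (vold - v));
  }
  return List::create(_["up"] = NumericVector(up.begin(), up.end()),
                      _["down"] = NumericVector(down.begin(), down.end()),
                      _["v_final"] = v, _["h_final"] = h);
}
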