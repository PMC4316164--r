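// Event-driven (discrete) molecular dynamics core.
//
// Particles move ballistically between instantaneous events at the
// discontinuity radii of pairwise step potentials.  Events are kept in a
// binary heap with lazy invalidation through per-particle collision
// counters; velocities are updated at each event so that linear momentum
// is conserved exactly and total energy is conserved exactly across well
// entries/exits (insufficient radial kinetic energy produces an elastic
// bounce).  An Andersen thermostat is realised as Poisson "ghost"
// collisions that resample a particle's velocity from the
// Maxwell-Boltzmann distribution.  All randomness is drawn from R's RNG
// so that set.seed() upstream makes runs bit-reproducible.
//
// Unit system: lengths in Angstrom, masses in amu, energies in kcal/mol,
// k_B = 1 (temperature in kcal/mol).  The implied time unit
// Angstrom * sqrt(amu mol / kcal) is approximately 48.9 fs, the
// conventional ~50 fs DMD time unit.

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

namespace {

struct Pot {
  double hc;                  // hard core (inner wall) radius
  std::vector<double> R;      // shell outer boundaries, ascending
  std::vector<double> E;      // shell energies; beyond R.back() energy is 0
  bool bond;                  // if true, R.back() is an infinite outer wall
};

enum EvType { EV_PAIR = 0, EV_GHOST = 1 };

struct Event {
  double t;
  int type;
  int i, j;            // j = -1 for ghost
  std::uint64_t ci, cj;
  int bidx;            // boundary index: -1 hard core, else index into R
  int dir;             // -1 inward, +1 outward
};

struct EvCmp {
  bool operator()(const Event& a, const Event& b) const {
    if (a.t != b.t) return a.t > b.t;
    if (a.i != b.i) return a.i > b.i;
    return a.j > b.j;
  }
};

class Engine {
public:
  int n;
  std::vector<double> pos, vel, mass, invm;
  std::vector<Pot> pots;
  std::vector<int> pp;        // n*n pair potential index, -1 none
  std::vector<int> hbPot;     // alternative (bonded) potential index, -1 none
  std::vector<int> hbAux;     // auxiliary particle index for formation, -1 none
  std::vector<std::uint8_t> hbFormed;
  std::vector<int> shell;     // current shell index per pair (E.size() = outside)
  std::vector<std::uint64_t> cnt;
  std::priority_queue<Event, std::vector<Event>, EvCmp> q;
  double t = 0.0, epot = 0.0;
  double T, nu, auxMax;
  bool thermo;
  long nEvents = 0, nHbForm = 0, nHbBreak = 0, nBounce = 0;

  inline int at(int i, int j) const { return i * n + j; }

  inline int potIdx(int i, int j) const {
    int k = pp[at(i, j)];
    if (k >= 0 && hbPot[at(i, j)] >= 0 && hbFormed[at(i, j)])
      return hbPot[at(i, j)];
    return k;
  }

  double dist2(int i, int j) const {
    double s = 0.0;
    for (int d = 0; d < 3; ++d) {
      double dd = pos[3 * i + d] - pos[3 * j + d];
      s += dd * dd;
    }
    return s;
  }

  int shellOf(const Pot& p, double r) const {
    int K = (int)p.R.size();
    for (int s = 0; s < K; ++s) if (r < p.R[s]) return s;
    return K; // outside all shells
  }

  void initShells() {
    shell.assign((size_t)n * n, -1);
    epot = 0.0;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int k = potIdx(i, j);
        if (k < 0) continue;
        const Pot& p = pots[k];
        double r = std::sqrt(dist2(i, j));
        int s = shellOf(p, r);
        shell[at(i, j)] = s;
        shell[at(j, i)] = s;
        if (s < (int)p.E.size()) epot += p.E[s];
      }
  }

  // Earliest positive crossing of radius R by the pair's relative motion.
  // inward: from outside (d2 > R^2) moving in; outward: from inside.
  static double tInward(double b, double a, double c2) {
    if (b >= 0.0) return -1.0;          // receding: no inward crossing
    if (c2 <= 0.0) return 0.0;          // approaching and already at/inside
    double disc = b * b - a * c2;
    if (disc <= 0.0) return -1.0;       // closest approach outside R
    return (-b - std::sqrt(disc)) / a;
  }
  static double tOutward(double b, double a, double c2) {
    // c2 = d2 - R^2 < 0 inside; disc > 0 always
    double disc = b * b - a * c2;
    return (-b + std::sqrt(disc)) / a;
  }

  void schedulePair(int i, int j) {
    int k = potIdx(i, j);
    if (k < 0) return;
    const Pot& p = pots[k];
    int s = shell[at(i, j)];
    int K = (int)p.E.size();
    double d[3], w[3];
    for (int dd = 0; dd < 3; ++dd) {
      d[dd] = pos[3 * i + dd] - pos[3 * j + dd];
      w[dd] = vel[3 * i + dd] - vel[3 * j + dd];
    }
    double a = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
    if (a <= 0.0) return;
    double b = d[0] * w[0] + d[1] * w[1] + d[2] * w[2];
    double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];

    double best = -1.0;
    int bBidx = 0, bDir = 0;
    if (s == K) { // outside all shells: only inward crossing of R[K-1]
      double Rb = p.R[K - 1];
      double tt = tInward(b, a, d2 - Rb * Rb);
      if (tt >= 0.0) { best = tt; bBidx = K - 1; bDir = -1; }
    } else {
      // inner boundary of shell s
      double Rin = (s == 0) ? p.hc : p.R[s - 1];
      double ti = tInward(b, a, d2 - Rin * Rin);
      if (ti >= 0.0) { best = ti; bBidx = (s == 0) ? -1 : (s - 1); bDir = -1; }
      // outer boundary
      double Rout = p.R[s];
      double to = tOutward(b, a, d2 - Rout * Rout);
      if (to >= 0.0 && (best < 0.0 || to < best)) { best = to; bBidx = s; bDir = +1; }
    }
    if (best < 0.0) return;
    Event ev;
    ev.t = t + best; ev.type = EV_PAIR; ev.i = i; ev.j = j;
    ev.ci = cnt[i]; ev.cj = cnt[j]; ev.bidx = bBidx; ev.dir = bDir;
    q.push(ev);
  }

  void rescheduleParticle(int i) {
    for (int j = 0; j < n; ++j) {
      if (j == i) continue;
      if (pp[at(std::min(i, j), std::max(i, j))] < 0) continue;
      schedulePair(std::min(i, j), std::max(i, j));
    }
  }

  void advanceAll(double dt) {
    if (dt <= 0.0) return;
    for (int i = 0; i < 3 * n; ++i) pos[i] += vel[i] * dt;
    t += dt;
  }

  void ghostKick(int i) {
    double sd = std::sqrt(T * invm[i]);
    for (int d = 0; d < 3; ++d) vel[3 * i + d] = sd * R::norm_rand();
    cnt[i]++;
    rescheduleParticle(i);
  }

  void scheduleGhost(int i) {
    Event ev;
    ev.t = t + R::exp_rand() / nu;
    ev.type = EV_GHOST; ev.i = i; ev.j = -1;
    ev.ci = 0; ev.cj = 0; ev.bidx = 0; ev.dir = 0;
    q.push(ev);
  }

  // Resolve pair event at boundary radius Rb.  dU is the energy step for
  // crossing in the direction of motion (+inf encoded as wall=true).
  void resolve(const Event& ev) {
    int i = ev.i, j = ev.j;
    int k = potIdx(i, j);
    const Pot& p = pots[k];
    int s = shell[at(i, j)];
    int K = (int)p.E.size();

    double Rb = (ev.bidx < 0) ? p.hc : p.R[ev.bidx];

    // project the pair exactly onto the boundary radius (floating-point
    // guard: prevents drift through discontinuities)
    double d[3];
    double r = 0.0;
    for (int dd = 0; dd < 3; ++dd) {
      d[dd] = pos[3 * i + dd] - pos[3 * j + dd];
      r += d[dd] * d[dd];
    }
    r = std::sqrt(r);
    if (r > 0.0) {
      double corr = 0.5 * (r - Rb) / r;
      for (int dd = 0; dd < 3; ++dd) {
        pos[3 * i + dd] -= corr * d[dd];
        pos[3 * j + dd] += corr * d[dd];
        d[dd] *= Rb / r;
      }
    }
    double u[3] = { d[0] / Rb, d[1] / Rb, d[2] / Rb };
    double vr = 0.0;
    for (int dd = 0; dd < 3; ++dd)
      vr += (vel[3 * i + dd] - vel[3 * j + dd]) * u[dd];
    double mu = 1.0 / (invm[i] + invm[j]);

    bool wall = false;
    double dU = 0.0;
    int sNew = s;
    int kNew = k;
    bool formHb = false, breakHb = false;

    if (ev.dir < 0) {
      if (ev.bidx < 0) { wall = true; }      // hard core
      else {
        // moving inward through R[bidx]: from shell bidx+1 (or K) to bidx
        int hb = hbPot[at(i, j)];
        if (hb >= 0 && !hbFormed[at(i, j)] && s == K && ev.bidx == K - 1) {
          // reaction attempt at the outermost boundary: auxiliary
          // distance condition decides whether the pair switches to the
          // bonded (hydrogen-bond) potential
          int a = hbAux[at(i, j)];
          bool ok = true;
          if (a >= 0) ok = dist2(a, j) <= auxMax * auxMax;
          if (ok) {
            const Pot& ph = pots[hb];
            sNew = (int)ph.E.size() - 1;
            dU = ph.E[sNew];
            kNew = hb; formHb = true;
          } else {
            sNew = s - 1; dU = p.E[sNew];
          }
        } else {
          sNew = ev.bidx;
          double Uold = (s >= K) ? 0.0 : p.E[s];
          dU = p.E[sNew] - Uold;
        }
      }
    } else {
      // moving outward through R[bidx] = R[s]
      if (p.bond && ev.bidx == K - 1) { wall = true; }
      else {
        double Unew = (s + 1 >= K) ? 0.0 : p.E[s + 1];
        dU = Unew - p.E[s];
        sNew = s + 1;
        if (hbFormed[at(i, j)] && ev.bidx == K - 1) breakHb = true;
      }
    }

    double J; // impulse magnitude along u applied to i (and -J to j)
    bool crossed = false;
    if (wall || 0.5 * mu * vr * vr <= dU) {
      J = -2.0 * mu * vr;            // elastic bounce
      nBounce++;
    } else {
      double vr2 = vr * vr - 2.0 * dU / mu;
      double vrNew = (vr >= 0.0 ? 1.0 : -1.0) * std::sqrt(std::max(0.0, vr2));
      J = mu * (vrNew - vr);
      crossed = true;
    }
    for (int dd = 0; dd < 3; ++dd) {
      vel[3 * i + dd] += J * invm[i] * u[dd];
      vel[3 * j + dd] -= J * invm[j] * u[dd];
    }
    if (crossed) {
      epot += dU;
      if (formHb) {
        hbFormed[at(i, j)] = 1; hbFormed[at(j, i)] = 1; nHbForm++;
      }
      if (breakHb) {
        hbFormed[at(i, j)] = 0; hbFormed[at(j, i)] = 0; nHbBreak++;
        // back under the normal potential: outside all shells
        kNew = pp[at(i, j)];
        sNew = (int)pots[kNew].E.size();
      }
      shell[at(i, j)] = sNew; shell[at(j, i)] = sNew;
    }
    cnt[i]++; cnt[j]++;
    rescheduleParticle(i);
    rescheduleParticle(j);
    nEvents++;
  }

  double ekin() const {
    double s = 0.0;
    for (int i = 0; i < n; ++i) {
      double v2 = 0.0;
      for (int d = 0; d < 3; ++d) v2 += vel[3 * i + d] * vel[3 * i + d];
      s += 0.5 * mass[i] * v2;
    }
    return s;
  }

  // smallest (distance - hard core) over interacting pairs
  double minCoreGap() const {
    double g = R_PosInf;
    for (int i = 0; i < n; ++i)
      for (int j = i + 1; j < n; ++j) {
        int k = potIdx(i, j);
        if (k < 0) continue;
        double gg = std::sqrt(dist2(i, j)) - pots[k].hc;
        if (gg < g) g = gg;
      }
    return g;
  }
};

Pot potFromList(const List& L) {
  Pot p;
  p.hc = as<double>(L["hardCore"]);
  p.R = as<std::vector<double>>(L["radii"]);
  p.E = as<std::vector<double>>(L["energies"]);
  p.bond = as<bool>(L["bond"]);
  return p;
}

} // namespace

// [[Rcpp::export]]
List cpp_run_dmd(NumericMatrix pos0, NumericMatrix vel0, NumericVector mass,
                 List potentials, IntegerMatrix pairPot, IntegerMatrix hbPot,
                 IntegerMatrix hbAux, LogicalMatrix hbFormed, double auxMax,
                 double temperature, double ghostRate, bool thermostat,
                 double duration, double sampleInterval) {
  Engine e;
  e.n = pos0.nrow();
  int n = e.n;
  e.pos.resize(3 * n); e.vel.resize(3 * n);
  for (int i = 0; i < n; ++i)
    for (int d = 0; d < 3; ++d) {
      e.pos[3 * i + d] = pos0(i, d);
      e.vel[3 * i + d] = vel0(i, d);
    }
  e.mass = as<std::vector<double>>(mass);
  e.invm.resize(n);
  for (int i = 0; i < n; ++i) {
    if (e.mass[i] <= 0) stop("non-positive mass");
    e.invm[i] = 1.0 / e.mass[i];
  }
  int np = potentials.size();
  e.pots.reserve(np);
  for (int k = 0; k < np; ++k) e.pots.push_back(potFromList(potentials[k]));
  e.pp.resize((size_t)n * n); e.hbPot.resize((size_t)n * n);
  e.hbAux.resize((size_t)n * n); e.hbFormed.resize((size_t)n * n);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < n; ++j) {
      e.pp[e.at(i, j)] = pairPot(i, j) - 1;    // R 1-based; 0 -> none
      e.hbPot[e.at(i, j)] = hbPot(i, j) - 1;
      e.hbAux[e.at(i, j)] = hbAux(i, j) - 1;
      e.hbFormed[e.at(i, j)] = hbFormed(i, j) ? 1 : 0;
    }
  e.T = temperature; e.nu = ghostRate; e.thermo = thermostat;
  e.auxMax = auxMax;
  e.cnt.assign(n, 0);
  e.initShells();

  RNGScope rng;

  // schedule everything
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j)
      if (e.pp[e.at(i, j)] >= 0) e.schedulePair(i, j);
  if (thermostat) {
    if (ghostRate <= 0) stop("ghost rate must be > 0 when thermostat enabled");
    for (int i = 0; i < n; ++i) e.scheduleGhost(i);
  }

  int nFrames = (int)std::floor(duration / sampleInterval + 1e-9) + 1;
  NumericVector fTimes(nFrames), fEpot(nFrames), fEkin(nFrames);
  NumericVector frames((R_xlen_t)nFrames * n * 3);
  frames.attr("dim") = IntegerVector::create(nFrames, n, 3);
  NumericVector velFrames((R_xlen_t)nFrames * n * 3);
  velFrames.attr("dim") = IntegerVector::create(nFrames, n, 3);
  double minGap = R_PosInf;

  int fi = 0;
  double nextSample = 0.0;
  auto record = [&](void) {
    fTimes[fi] = e.t; fEpot[fi] = e.epot; fEkin[fi] = e.ekin();
    for (int i = 0; i < n; ++i)
      for (int d = 0; d < 3; ++d) {
        R_xlen_t ix = (R_xlen_t)fi + (R_xlen_t)nFrames * (i + (R_xlen_t)n * d);
        frames[ix] = e.pos[3 * i + d];
        velFrames[ix] = e.vel[3 * i + d];
      }
    double g = e.minCoreGap();
    if (g < minGap) minGap = g;
    fi++;
  };

  while (true) {
    double tStop = (fi < nFrames) ? nextSample : duration;
    if (e.q.empty() || e.q.top().t >= tStop) {
      if (fi < nFrames) {
        e.advanceAll(nextSample - e.t);
        record();
        nextSample += sampleInterval;
        continue;
      }
      e.advanceAll(duration - e.t);
      break;
    }
    Event ev = e.q.top(); e.q.pop();
    if (ev.type == EV_PAIR &&
        (ev.ci != e.cnt[ev.i] || ev.cj != e.cnt[ev.j])) continue; // stale
    e.advanceAll(ev.t - e.t);
    if (ev.type == EV_GHOST) {
      e.ghostKick(ev.i);
      e.scheduleGhost(ev.i);
      e.nEvents++;
    } else {
      e.resolve(ev);
    }
    if (e.nEvents % 100000 == 0) Rcpp::checkUserInterrupt();
  }

  NumericMatrix posOut(n, 3), velOut(n, 3);
  LogicalMatrix hbOut(n, n);
  for (int i = 0; i < n; ++i) {
    for (int d = 0; d < 3; ++d) {
      posOut(i, d) = e.pos[3 * i + d];
      velOut(i, d) = e.vel[3 * i + d];
    }
    for (int j = 0; j < n; ++j) hbOut(i, j) = e.hbFormed[e.at(i, j)] != 0;
  }
  return List::create(
    _["times"] = fTimes, _["epot"] = fEpot, _["ekin"] = fEkin,
    _["frames"] = frames, _["velFrames"] = velFrames,
    _["pos"] = posOut, _["vel"] = velOut,
    _["hbFormed"] = hbOut, _["nEvents"] = (double)e.nEvents,
    _["nHbForm"] = (double)e.nHbForm, _["nHbBreak"] = (double)e.nHbBreak,
    _["nBounce"] = (double)e.nBounce, _["minCoreGap"] = minGap,
    _["finalEpot"] = e.epot, _["finalEkin"] = e.ekin(),
    _["finalTime"] = e.t);
}

// Earliest crossing of any discontinuity radius of `pot` by the ballistic
// relative motion of two particles.  Returns time = Inf when the relative
// motion never reaches a discontinuity.
// [[Rcpp::export]]
List cpp_next_pair_event(NumericVector x1, NumericVector v1,
                         NumericVector x2, NumericVector v2, List pot) {
  Pot p = potFromList(pot);
  double d[3], w[3];
  for (int dd = 0; dd < 3; ++dd) {
    d[dd] = x1[dd] - x2[dd];
    w[dd] = v1[dd] - v2[dd];
  }
  double a = w[0] * w[0] + w[1] * w[1] + w[2] * w[2];
  double b = d[0] * w[0] + d[1] * w[1] + d[2] * w[2];
  double d2 = d[0] * d[0] + d[1] * d[1] + d[2] * d[2];
  int K = (int)p.E.size();
  double r = std::sqrt(d2);
  int s = 0; { for (s = 0; s < K; ++s) if (r < p.R[s]) break; }
  double best = R_PosInf; double bR = NA_REAL; int bDir = 0;
  if (a > 0.0) {
    if (s == K) {
      double Rb = p.R[K - 1];
      double tt = Engine::tInward(b, a, d2 - Rb * Rb);
      if (tt >= 0.0) { best = tt; bR = Rb; bDir = -1; }
    } else {
      double Rin = (s == 0) ? p.hc : p.R[s - 1];
      double ti = Engine::tInward(b, a, d2 - Rin * Rin);
      if (ti >= 0.0) { best = ti; bR = Rin; bDir = -1; }
      double Rout = p.R[s];
      double to = Engine::tOutward(b, a, d2 - Rout * Rout);
      if (to >= 0.0 && to < best) { best = to; bR = Rout; bDir = +1; }
    }
  }
  return List::create(_["time"] = best, _["radius"] = bR, _["dir"] = bDir,
                      _["kind"] = (bDir == 0) ? "none"
                                 : (bDir < 0 && bR == p.hc) ? "core_reflection"
                                 : (bDir < 0) ? "well_entry" : "well_exit_attempt");
}

// Velocity update for a pair exactly at a discontinuity: energy step dU in
// the direction of motion; wall = TRUE forces an elastic reflection.
// [[Rcpp::export]]
List cpp_resolve_pair_event(NumericVector x1, NumericVector v1, double m1,
                            NumericVector x2, NumericVector v2, double m2,
                            double dU, bool wall) {
  double d[3];
  double r = 0.0;
  for (int dd = 0; dd < 3; ++dd) { d[dd] = x1[dd] - x2[dd]; r += d[dd] * d[dd]; }
  r = std::sqrt(r);
  if (r <= 0.0) stop("coincident particles");
  double u[3] = { d[0] / r, d[1] / r, d[2] / r };
  double vr = 0.0;
  for (int dd = 0; dd < 3; ++dd) vr += (v1[dd] - v2[dd]) * u[dd];
  double mu = 1.0 / (1.0 / m1 + 1.0 / m2);
  double J; bool crossed;
  if (wall || 0.5 * mu * vr * vr <= dU) {
    J = -2.0 * mu * vr; crossed = false;
  } else {
    double vrNew = (vr >= 0.0 ? 1.0 : -1.0) *
      std::sqrt(std::max(0.0, vr * vr - 2.0 * dU / mu));
    J = mu * (vrNew - vr); crossed = true;
  }
  NumericVector w1(3), w2(3);
  for (int dd = 0; dd < 3; ++dd) {
    w1[dd] = v1[dd] + J / m1 * u[dd];
    w2[dd] = v2[dd] - J / m2 * u[dd];
  }
  return List::create(_["v1"] = w1, _["v2"] = w2, _["crossed"] = crossed,
                      _["deltaU"] = crossed ? dU : 0.0);
}
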