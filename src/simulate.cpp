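// Simulation core: one run of the signalling model on a continuous torus.
// All randomness goes through R's RNG so set.seed() on the R side fixes a run.
#include <Rcpp.h>
#include <algorithm>
#include <cmath>
#include <vector>
using namespace Rcpp;

static inline double wrapc(double v, double side) {
  v -= side * std::floor(v / side);
  if (v < 0) v += side;
  if (v >= side) v = 0.0; // fp guard: keep coordinates in [0, side)
  return v;
}

// per-axis wrapped separation
static inline double axdist(double a, double b, double side) {
  double d = std::fabs(a - b);
  return d > side * 0.5 ? side - d : d;
}

static inline double tdist2(double ax, double ay, double bx, double by, double side) {
  double dx = axdist(ax, bx, side), dy = axdist(ay, by, side);
  return dx * dx + dy * dy;
}

// uniform integer on [0, n) from R's unif stream
static inline int runif_int(int n) {
  int k = (int)(unif_rand() * n);
  return k >= n ? n - 1 : k;
}

// signed shortest separation from a to b on one wrapped axis
static inline double axdelta(double a, double b, double side) {
  double d = b - a;
  if (d > side * 0.5) d -= side;
  else if (d < -side * 0.5) d += side;
  return d;
}

// move (x, y) at most `step` towards the target along the wrapped
// shortest path; lands exactly on the target once within reach
static inline bool moveToward(double& x, double& y, double tx, double ty,
                              double step, double side) {
  double dx = axdelta(x, tx, side), dy = axdelta(y, ty, side);
  double d = std::sqrt(dx * dx + dy * dy);
  if (d <= step) { x = tx; y = ty; return true; }
  x = wrapc(x + step * dx / d, side);
  y = wrapc(y + step * dy / d, side);
  return false;
}

// Uniform bucket grid over the torus. Cell size >= query radius, so a 3x3
// block of cells always covers the query disc. Contract: results identical
// to a linear scan (tested against one).
struct Grid {
  double side, cellsz;
  int ncell;
  std::vector< std::vector<int> > cells;

  void init(double side_, double radius) {
    side = side_;
    double r = radius > 1e-9 ? radius : 1e-9;
    ncell = (int)std::floor(side / r);
    if (ncell < 1) ncell = 1;
    if (ncell > 512) ncell = 512;
    cellsz = side / ncell;
    cells.assign((size_t)ncell * ncell, std::vector<int>());
  }
  int cellIndex(double x, double y) const {
    int cx = (int)(x / cellsz); if (cx >= ncell) cx = ncell - 1;
    int cy = (int)(y / cellsz); if (cy >= ncell) cy = ncell - 1;
    return cy * ncell + cx;
  }
  void insert(int id, double x, double y) { cells[cellIndex(x, y)].push_back(id); }
  void remove(int id, double x, double y) {
    std::vector<int>& c = cells[cellIndex(x, y)];
    for (size_t k = 0; k < c.size(); ++k)
      if (c[k] == id) { c[k] = c.back(); c.pop_back(); return; }
  }
};

struct Items {
  std::vector<double> x, y;
  std::vector<int> age;
  std::vector<char> alive;
  std::vector<int> freeSlots, diedThisStep;
  int nAlive, cap, popMax;
  Grid grid;

  void init(double side, double radius, int cap_) {
    nAlive = 0; cap = cap_; popMax = 0;
    grid.init(side, radius);
  }
  void kill(int id) {
    alive[id] = 0; --nAlive;
    grid.remove(id, x[id], y[id]);
    // slot not reusable until end of step: a mid-step rebirth into this slot
    // would let the newborn inherit the dead item's place in the schedule
    diedThisStep.push_back(id);
  }
  int spawn(double px, double py, int a) {
    int id;
    if (!freeSlots.empty()) {
      id = freeSlots.back(); freeSlots.pop_back();
      x[id] = px; y[id] = py; age[id] = a; alive[id] = 1;
    } else {
      id = (int)x.size();
      x.push_back(px); y.push_back(py); age.push_back(a); alive.push_back(1);
    }
    ++nAlive;
    if (nAlive > popMax) popMax = nAlive;
    grid.insert(id, px, py);
    return id;
  }
  void endStep() {
    for (size_t k = 0; k < diedThisStep.size(); ++k) freeSlots.push_back(diedThisStep[k]);
    diedThisStep.clear();
  }
  // nearest live item within radius of (px, py); -1 if none; ties -> lowest id
  int nearest(double px, double py, double radius) const {
    double r2 = radius * radius, best = -1.0;
    int bestId = -1;
    int cx0 = (int)(px / grid.cellsz); if (cx0 >= grid.ncell) cx0 = grid.ncell - 1;
    int cy0 = (int)(py / grid.cellsz); if (cy0 >= grid.ncell) cy0 = grid.ncell - 1;
    int seen[9]; int nseen = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        int cx = (cx0 + dx + grid.ncell) % grid.ncell;
        int cy = (cy0 + dy + grid.ncell) % grid.ncell;
        int ci = cy * grid.ncell + cx;
        bool dup = false;
        for (int k = 0; k < nseen; ++k) if (seen[k] == ci) { dup = true; break; }
        if (dup) continue;
        seen[nseen++] = ci;
        const std::vector<int>& cell = grid.cells[ci];
        for (size_t k = 0; k < cell.size(); ++k) {
          int id = cell[k];
          double d2 = tdist2(px, py, x[id], y[id], grid.side);
          if (d2 <= r2 && (bestId < 0 || d2 < best || (d2 == best && id < bestId))) {
            best = d2; bestId = id;
          }
        }
      }
    }
    return bestId;
  }
  // all live items within radius, via the same 3x3 cell block
  std::vector<int> within(double px, double py, double radius) const {
    std::vector<int> hits;
    double r2 = radius * radius;
    int cx0 = (int)(px / grid.cellsz); if (cx0 >= grid.ncell) cx0 = grid.ncell - 1;
    int cy0 = (int)(py / grid.cellsz); if (cy0 >= grid.ncell) cy0 = grid.ncell - 1;
    int seen[9]; int nseen = 0;
    for (int dx = -1; dx <= 1; ++dx) {
      for (int dy = -1; dy <= 1; ++dy) {
        int cx = (cx0 + dx + grid.ncell) % grid.ncell;
        int cy = (cy0 + dy + grid.ncell) % grid.ncell;
        int ci = cy * grid.ncell + cx;
        bool dup = false;
        for (int k = 0; k < nseen; ++k) if (seen[k] == ci) { dup = true; break; }
        if (dup) continue;
        seen[nseen++] = ci;
        const std::vector<int>& cell = grid.cells[ci];
        for (size_t k = 0; k < cell.size(); ++k)
          if (tdist2(px, py, x[cell[k]], y[cell[k]], grid.side) <= r2)
            hits.push_back(cell[k]);
      }
    }
    return hits;
  }
};

struct Cfg {
  int nS, nR, nSteps, maxAge, nFood, nDisp, capFood, capDisp;
  double side, radius, threshold, eMin, eMax, reproP, stepCost, foodEnergy, moveStep;
  bool itemsNeeded, sequential, realtime, record;
};

// forage from (x, y): consume the nearest sensed food item if reachable this
// step, walk towards it if sensed but out of reach, otherwise take a
// random-heading step
static void forageStep(double& x, double& y, double& gain, Items& food,
                       const Cfg& c);

static Cfg parseCfg(List cfg) {
  Cfg c;
  c.nS = as<int>(cfg["n_signalers"]);
  c.nR = as<int>(cfg["n_receivers"]);
  c.side = as<double>(cfg["arena_side"]);
  c.nSteps = as<int>(cfg["n_steps"]);
  c.radius = as<double>(cfg["neighborhood"]);
  c.threshold = as<double>(cfg["energy_threshold"]);
  c.eMin = as<double>(cfg["init_energy_min"]);
  c.eMax = as<double>(cfg["init_energy_max"]);
  c.nFood = as<int>(cfg["n_food_init"]);
  c.nDisp = as<int>(cfg["n_display_init"]);
  c.reproP = as<double>(cfg["reproduce_prob"]);
  c.maxAge = as<int>(cfg["max_age"]);
  c.stepCost = as<double>(cfg["step_cost"]);
  c.foodEnergy = as<double>(cfg["food_energy"]);
  c.moveStep = as<double>(cfg["move_step"]);
  List fl = cfg["flags"];
  c.itemsNeeded = as<bool>(fl["items_needed"]);
  c.sequential = as<bool>(fl["sequential"]);
  c.realtime = as<bool>(fl["realtime"]);
  c.capFood = as<int>(cfg["food_capacity"]);
  c.capDisp = as<int>(cfg["display_capacity"]);
  c.record = as<bool>(cfg["record"]);
  return c;
}

static void forageStep(double& x, double& y, double& gain, Items& food,
                       const Cfg& c) {
  int it = food.nearest(x, y, c.radius);
  if (it >= 0) {
    if (tdist2(x, y, food.x[it], food.y[it], c.side) <= c.moveStep * c.moveStep) {
      x = food.x[it]; y = food.y[it];
      food.kill(it);
      // items vary in size: exponential yield with mean food_energy keeps
      // display/foraging bouts aperiodic and gives occasional rich finds
      gain = -c.foodEnergy * std::log(unif_rand());
    } else {
      moveToward(x, y, food.x[it], food.y[it], c.moveStep, c.side);
    }
  } else {
    double th = unif_rand() * 2.0 * M_PI;
    x = wrapc(x + c.moveStep * std::cos(th), c.side);
    y = wrapc(y + c.moveStep * std::sin(th), c.side);
  }
}

// [[Rcpp::export]]
List cpp_simulate(List cfgList) {
  Cfg c = parseCfg(cfgList);
  const double half = c.side; (void)half;

  // --- initialization (order of RNG draws is part of the reproducibility contract)
  std::vector<double> sX(c.nS), sY(c.nS), sE(c.nS), hX(c.nS), hY(c.nS);
  std::vector<int> effort(c.nS, 0);
  std::vector<char> sDisp(c.nS, 0);
  for (int i = 0; i < c.nS; ++i) {
    sX[i] = unif_rand() * c.side; sY[i] = unif_rand() * c.side;
    sE[i] = c.eMin + runif_int((int)(c.eMax - c.eMin) + 1);
  }
  // home territories on an even gx x gy grid (5x4 for the default 20)
  int gx = (int)std::ceil(std::sqrt((double)c.nS));
  int gy = c.nS > 0 ? (int)std::ceil((double)c.nS / gx) : 1;
  for (int i = 0; i < c.nS; ++i) {
    hX[i] = (i % gx + 0.5) * c.side / gx;
    hY[i] = (i / gx + 0.5) * c.side / gy;
  }

  std::vector<double> rX(c.nR), rY(c.nR), rE(c.nR);
  IntegerMatrix tour(c.nR, std::max(c.nS, 1));
  std::vector<int> tourPos(c.nR, 0);
  NumericMatrix est(c.nR, c.nS);
  for (int r = 0; r < c.nR; ++r) {
    rX[r] = unif_rand() * c.side; rY[r] = unif_rand() * c.side;
    rE[r] = c.eMin + runif_int((int)(c.eMax - c.eMin) + 1);
    for (int i = 0; i < c.nS; ++i) tour(r, i) = i;
    for (int i = c.nS - 1; i > 0; --i) { // independent shuffled visiting order
      int j = runif_int(i + 1);
      int tmp = tour(r, i); tour(r, i) = tour(r, j); tour(r, j) = tmp;
    }
  }

  Items food, disp;
  food.init(c.side, c.radius, c.capFood);
  disp.init(c.side, c.radius, c.capDisp);
  int ageInit = std::min(100, c.maxAge);
  for (int k = 0; k < c.nFood; ++k)
    food.spawn(unif_rand() * c.side, unif_rand() * c.side, runif_int(ageInit + 1));
  if (c.itemsNeeded)
    for (int k = 0; k < c.nDisp; ++k)
      disp.spawn(unif_rand() * c.side, unif_rand() * c.side, runif_int(ageInit + 1));
  food.popMax = food.nAlive; disp.popMax = disp.nAlive;

  long lost = 0;
  std::vector<int> obsMode(c.nR, 0), obsTerr(c.nR, 0); // 0 none, 1 lek, 2 territory

  // optional per-step history for invariant tests (small runs only)
  LogicalMatrix dispHist(c.record ? c.nSteps : 0, c.record ? c.nS : 0);
  NumericMatrix sEHist(c.record ? c.nSteps : 0, c.record ? c.nS : 0);
  NumericMatrix rEHist(c.record ? c.nSteps : 0, c.record ? c.nR : 0);
  IntegerVector popFood(c.record ? c.nSteps : 0), popDisp(c.record ? c.nSteps : 0);
  IntegerVector nSched(c.record ? c.nSteps : 0), nActed(c.record ? c.nSteps : 0);

  std::vector<int> order;
  const int F0 = c.nS + c.nR;

  for (int t = 0; t < c.nSteps; ++t) {
    // display flags cleared at step start: receivers see only this step's displays
    for (int i = 0; i < c.nS; ++i) sDisp[i] = 0;
    for (int r = 0; r < c.nR; ++r) obsMode[r] = 0;

    const int D0 = F0 + (int)food.x.size();
    order.clear();
    for (int i = 0; i < F0; ++i) order.push_back(i);
    for (size_t k = 0; k < food.x.size(); ++k) if (food.alive[k]) order.push_back(F0 + (int)k);
    for (size_t k = 0; k < disp.x.size(); ++k) if (disp.alive[k]) order.push_back(D0 + (int)k);
    // one uniform permutation over every agent, items included
    for (int i = (int)order.size() - 1; i > 0; --i) {
      int j = runif_int(i + 1);
      int tmp = order[i]; order[i] = order[j]; order[j] = tmp;
    }

    int acted = 0;
    for (size_t oi = 0; oi < order.size(); ++oi) {
      int id = order[oi];
      if (id < c.nS) { // ---- signaler
        int i = id;
        double gain = 0.0;
        if (sE[i] >= c.threshold) {
          // travel home at finite speed; display only once there
          bool atHome = moveToward(sX[i], sY[i], hX[i], hY[i], c.moveStep, c.side);
          if (atHome) {
            if (!c.itemsNeeded) {
              sDisp[i] = 1; ++effort[i];
            } else {
              // secure a display item sensed from the territory; securing
              // and displaying happen within the same step
              int it = disp.nearest(sX[i], sY[i], c.radius);
              if (it >= 0) {
                disp.kill(it);
                sDisp[i] = 1; ++effort[i];
              } else { // energy to burn but nothing to display with
                ++lost;
                double th = unif_rand() * 2.0 * M_PI;
                sX[i] = wrapc(sX[i] + c.moveStep * std::cos(th), c.side);
                sY[i] = wrapc(sY[i] + c.moveStep * std::sin(th), c.side);
              }
            }
          }
        } else {
          forageStep(sX[i], sY[i], gain, food, c);
        }
        sE[i] += gain - c.stepCost;
        if (sE[i] < 0) sE[i] = 0;
        ++acted;
      } else if (id < F0) { // ---- receiver
        int r = id - c.nS;
        double gain = 0.0;
        if (rE[r] < c.threshold) {
          forageStep(rX[r], rY[r], gain, food, c);
        } else if (!c.sequential) {
          // lek: assess every displaying signaler at once; the aggregation
          // is informational, not spatial, so the receiver keeps its own
          // foraging ground rather than crowding onto a shared point
          obsMode[r] = 1;
        } else if (c.nS > 0) {
          // inspect one known territory per time step; move on next step
          // only if the territory holder is not found displaying there
          int k = tour(r, tourPos[r]);
          rX[r] = hX[k]; rY[r] = hY[k];
          obsMode[r] = 2; obsTerr[r] = k;
        }
        rE[r] += gain - c.stepCost;
        if (rE[r] < 0) rE[r] = 0;
        ++acted;
      } else if (id < D0) { // ---- food item
        int k = id - F0;
        if (!food.alive[k]) continue; // consumed earlier this step
        if (++food.age[k] >= c.maxAge) food.kill(k);
        else if (food.nAlive < food.cap && unif_rand() < c.reproP)
          food.spawn(unif_rand() * c.side, unif_rand() * c.side, 0);
        ++acted;
      } else { // ---- display item
        int k = id - D0;
        if (!disp.alive[k]) continue;
        if (++disp.age[k] >= c.maxAge) disp.kill(k);
        else if (disp.nAlive < disp.cap && unif_rand() < c.reproP)
          disp.spawn(unif_rand() * c.side, unif_rand() * c.side, 0);
        ++acted;
      }
    }

    // observation phase: a display spans the whole step, so a receiver that
    // observed this step registers every signaler that displayed in it
    for (int r = 0; r < c.nR; ++r) {
      if (obsMode[r] == 1) {
        for (int i = 0; i < c.nS; ++i) if (sDisp[i]) {
          if (c.realtime) est(r, i) += 1.0; else est(r, i) = (double)effort[i];
        }
      } else if (obsMode[r] == 2) {
        int i = obsTerr[r];
        if (sDisp[i]) {
          if (c.realtime) est(r, i) += 1.0; else est(r, i) = (double)effort[i];
        }
        tourPos[r] = (tourPos[r] + 1) % c.nS; // next territory next step
      }
    }

    food.endStep(); disp.endStep();
    if (food.nAlive > food.popMax) food.popMax = food.nAlive;
    if (disp.nAlive > disp.popMax) disp.popMax = disp.nAlive;

    if (c.record) {
      for (int i = 0; i < c.nS; ++i) { dispHist(t, i) = sDisp[i] != 0; sEHist(t, i) = sE[i]; }
      for (int r = 0; r < c.nR; ++r) rEHist(t, r) = rE[r];
      popFood[t] = food.nAlive; popDisp[t] = disp.nAlive;
      nSched[t] = (int)order.size(); nActed[t] = acted;
    }
  }

  // compact live items for the state snapshot
  auto itemState = [](const Items& it) {
    int n = it.nAlive;
    NumericVector px(n), py(n); IntegerVector pa(n);
    int j = 0;
    for (size_t k = 0; k < it.x.size(); ++k) if (it.alive[k]) {
      px[j] = it.x[k]; py[j] = it.y[k]; pa[j] = it.age[k]; ++j;
    }
    return List::create(_["x"] = px, _["y"] = py, _["age"] = pa);
  };

  List out = List::create(
    _["true_efforts"] = IntegerVector(effort.begin(), effort.end()),
    _["estimates"] = est,
    _["lost_opportunities"] = (double)lost,
    _["signalers"] = List::create(
      _["x"] = NumericVector(sX.begin(), sX.end()),
      _["y"] = NumericVector(sY.begin(), sY.end()),
      _["home_x"] = NumericVector(hX.begin(), hX.end()),
      _["home_y"] = NumericVector(hY.begin(), hY.end()),
      _["energy"] = NumericVector(sE.begin(), sE.end()),
      _["displaying"] = LogicalVector(sDisp.begin(), sDisp.end())),
    _["receivers"] = List::create(
      _["x"] = NumericVector(rX.begin(), rX.end()),
      _["y"] = NumericVector(rY.begin(), rY.end()),
      _["energy"] = NumericVector(rE.begin(), rE.end()),
      _["tour"] = tour,
      _["tour_position"] = IntegerVector(tourPos.begin(), tourPos.end())),
    _["food"] = itemState(food),
    _["display_items"] = itemState(disp),
    _["pop_max"] = IntegerVector::create(_["food"] = food.popMax, _["display"] = disp.popMax));
  if (c.record)
    out["history"] = List::create(
      _["displaying"] = dispHist, _["signaler_energy"] = sEHist,
      _["receiver_energy"] = rEHist, _["pop_food"] = popFood,
      _["pop_display"] = popDisp, _["n_scheduled"] = nSched,
      _["n_acted"] = nActed);
  return out;
}

// Fisher-Yates draw used by the scheduler, exposed for fairness tests.
// [[Rcpp::export]]
IntegerVector cpp_shuffle(int n) {
  IntegerVector p(n);
  for (int i = 0; i < n; ++i) p[i] = i + 1;
  for (int i = n - 1; i > 0; --i) {
    int j = runif_int(i + 1);
    int tmp = p[i]; p[i] = p[j]; p[j] = tmp;
  }
  return p;
}

// Grid-backed neighbourhood query (1-based ids within radius, and the nearest
// id with lowest-index tie-break), for checking the grid against a linear scan.
// [[Rcpp::export]]
List cpp_grid_query(NumericMatrix pts, double cx, double cy, double radius, double side) {
  Items it;
  it.init(side, radius, pts.nrow() + 1);
  for (int k = 0; k < pts.nrow(); ++k)
    it.spawn(wrapc(pts(k, 0), side), wrapc(pts(k, 1), side), 0);
  double qx = wrapc(cx, side), qy = wrapc(cy, side);
  std::vector<int> hits = it.within(qx, qy, radius);
  std::sort(hits.begin(), hits.end());
  for (size_t k = 0; k < hits.size(); ++k) hits[k] += 1;
  int nb = it.nearest(qx, qy, radius);
  return List::create(_["within"] = IntegerVector(hits.begin(), hits.end()),
                      _["nearest"] = nb + 1);
}
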