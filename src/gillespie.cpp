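#include <Rcpp.h>
using namespace Rcpp;

// Continuous-time exclusion-process simulator (Gillespie direct method).
//
// Agents carry a homogeneous attempt rate pm, so inter-event times are
// Exp(N * pm) and the acting agent is chosen uniformly among the N alive
// agents.  A selected agent assigns transition probability
//   model A: T = (1 - n * alpha) / 4
//   model B: T = (1 - alpha)^n / 4
// to each eligible target direction, where n is its occupied-neighbour
// count.  Eligible targets are empty on-lattice neighbour sites plus, under
// flux x-boundaries, the off-domain direction at columns 1 and Lx (the agent
// exits there).  With probability 1 - (#eligible * T) the event is a no-op.
// Moves into occupied sites carry no probability mass (aborting is
// equivalent), so admissibility of alpha guarantees #eligible * T <= 1.
//
// Directions are treated as distinct even when the periodic y-wrap maps two
// of them to the same site (Ly == 2); a direction that maps to the agent's
// own site (Ly == 1) is dropped entirely.
//
// When the total event rate is constant over a sampling interval (no-flux
// boundaries, no replenishment: N never changes), the number of events in
// the interval is drawn as a single Poisson variate and individual event
// times are not tracked -- an exact thinning of the same process.  With
// open boundaries N varies, so the per-event exponential clock is used.
//
// Randomness: one xoshiro256++ stream per call, seeded from R's RNG, so
// results are reproducible under set.seed().  (The hot loop draws 2-3
// variates per event; going through R's RNG for each would dominate the
// run time.)

namespace {

struct Xoshiro {
  uint64_t s[4];
  static uint64_t splitmix(uint64_t &x) {
    x += 0x9e3779b97f4a7c15ULL;
    uint64_t z = x;
    z = (z ^ (z >> 30)) * 0xbf58476d1ce4e5b9ULL;
    z = (z ^ (z >> 27)) * 0x94d049bb133111ebULL;
    return z ^ (z >> 31);
  }
  explicit Xoshiro(uint64_t seed) {
    for (int i = 0; i < 4; ++i) s[i] = splitmix(seed);
  }
  static uint64_t rotl(uint64_t x, int k) {
    return (x << k) | (x >> (64 - k));
  }
  uint64_t next() {
    uint64_t result = rotl(s[0] + s[3], 23) + s[0];
    uint64_t t = s[1] << 17;
    s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
    s[2] ^= t; s[3] = rotl(s[3], 45);
    return result;
  }
  // uniform on [0, 1)
  double unif() { return (next() >> 11) * 0x1.0p-53; }
};

struct Sim {
  int Lx, Ly;
  std::vector<int> grid;            // Lx*Ly, agent slot + 1 or 0
  std::vector<int> col, row, icol;  // per-slot agent fields (1-based)
  std::vector<int> id;
  std::vector<int> alive;           // slots of alive agents
  std::vector<int> pos;             // slot -> index in alive, -1 if dead
  int next_id = 1;
  int col1_count = 0;

  int gidx(int i, int j) const { return (i - 1) * Ly + (j - 1); }

  void add_agent(int i, int j, int i0) {
    col.push_back(i); row.push_back(j); icol.push_back(i0);
    id.push_back(next_id++);
    pos.push_back((int)alive.size());
    alive.push_back((int)col.size() - 1);
    grid[gidx(i, j)] = (int)col.size();
    if (i == 1) col1_count++;
  }

  void remove_agent(int slot) {
    grid[gidx(col[slot], row[slot])] = 0;
    if (col[slot] == 1) col1_count--;
    int p = pos[slot], last = alive.back();
    alive[p] = last; pos[last] = p;
    alive.pop_back(); pos[slot] = -1;
  }

  void move_agent(int slot, int i2, int j2) {
    grid[gidx(col[slot], row[slot])] = 0;
    if (col[slot] == 1) col1_count--;
    col[slot] = i2; row[slot] = j2;
    grid[gidx(i2, j2)] = slot + 1;
    if (i2 == 1) col1_count++;
  }
};

} // namespace

// [[Rcpp::export]]
List abm_gillespie_cpp(int Lx, int Ly, IntegerMatrix agents0,
                       int model, double pm, double alpha,
                       bool flux_x, bool replenish, double replenish_density,
                       NumericVector times) {
  Sim s;
  s.Lx = Lx; s.Ly = Ly;
  s.grid.assign((size_t)Lx * Ly, 0);
  int n0 = agents0.nrow();
  s.col.reserve(n0); s.row.reserve(n0); s.icol.reserve(n0);
  for (int k = 0; k < n0; ++k) {
    int i = agents0(k, 0), j = agents0(k, 1), i0 = agents0(k, 2);
    if (i < 1 || i > Lx || j < 1 || j > Ly)
      stop("agent %d outside the lattice", k + 1);
    if (s.grid[s.gidx(i, j)] != 0)
      stop("exclusion violated in the initial state at site (%d, %d)", i, j);
    s.add_agent(i, j, i0);
  }

  // seed the internal stream from R's RNG (Poisson interval counts also
  // come from R's RNG below)
  uint64_t seed64;
  {
    double u1 = unif_rand(), u2 = unif_rand();
    seed64 = (uint64_t)(u1 * 4294967296.0) << 32 |
             (uint64_t)(u2 * 4294967296.0);
  }
  Xoshiro rng(seed64);

  int need = 0;
  if (replenish)
    need = (int)std::ceil(replenish_density * Ly - 1e-9);

  int K = times.size();
  List snaps(K);
  auto snapshot = [&](int k) {
    int m = (int)s.alive.size();
    IntegerMatrix out(m, 4);
    for (int a = 0; a < m; ++a) {
      int slot = s.alive[a];
      out(a, 0) = s.id[slot]; out(a, 1) = s.col[slot];
      out(a, 2) = s.row[slot]; out(a, 3) = s.icol[slot];
    }
    snaps[k] = out;
  };

  auto top_up = [&]() {
    while (s.col1_count < need) {
      std::vector<int> empty_rows;
      empty_rows.reserve(Ly);
      for (int j = 1; j <= Ly; ++j)
        if (s.grid[s.gidx(1, j)] == 0) empty_rows.push_back(j);
      if (empty_rows.empty()) break;
      int pick = (int)(rng.unif() * empty_rows.size());
      if (pick >= (int)empty_rows.size()) pick = (int)empty_rows.size() - 1;
      s.add_agent(1, empty_rows[pick], 1);
    }
  };

  long long n_events = 0, n_exited = 0;
  int n_initial = n0;

  int tc[4], tr[4]; bool texit[4];

  // one attempted movement event; returns nothing, mutates state
  auto do_event = [&]() {
    int Na = (int)s.alive.size();
    int slot = s.alive[(int)(rng.unif() * Na)];
    int ci = s.col[slot], cj = s.row[slot];

    int n_occ = 0, ne = 0;
    if (ci < Lx) {
      int g = s.grid[s.gidx(ci + 1, cj)];
      if (g) ++n_occ;
      else { tc[ne] = ci + 1; tr[ne] = cj; texit[ne] = false; ++ne; }
    } else if (flux_x) {
      tc[ne] = 0; tr[ne] = 0; texit[ne] = true; ++ne;
    }
    if (ci > 1) {
      int g = s.grid[s.gidx(ci - 1, cj)];
      if (g) ++n_occ;
      else { tc[ne] = ci - 1; tr[ne] = cj; texit[ne] = false; ++ne; }
    } else if (flux_x) {
      tc[ne] = 0; tr[ne] = 0; texit[ne] = true; ++ne;
    }
    if (Ly > 1) {
      int ju = (cj == Ly) ? 1 : cj + 1;
      int jd = (cj == 1) ? Ly : cj - 1;
      int g = s.grid[s.gidx(ci, ju)];
      if (g) ++n_occ;
      else { tc[ne] = ci; tr[ne] = ju; texit[ne] = false; ++ne; }
      g = s.grid[s.gidx(ci, jd)];
      if (g) ++n_occ;
      else { tc[ne] = ci; tr[ne] = jd; texit[ne] = false; ++ne; }
    }

    if (ne == 0) return;
    double T = (model == 0) ? (1.0 - n_occ * alpha) / 4.0
                            : std::pow(1.0 - alpha, (double)n_occ) / 4.0;
    if (T <= 0.0) return;
    double r = rng.unif();
    if (r >= ne * T) return;
    int pick = (int)(r / T);
    if (pick >= ne) pick = ne - 1;

    bool vacated_col1 = (ci == 1);
    if (texit[pick]) {
      s.remove_agent(slot);
      ++n_exited;
    } else {
      if (tc[pick] == 1) vacated_col1 = false; // moved within column 1
      s.move_agent(slot, tc[pick], tr[pick]);
    }
    if (replenish && vacated_col1) top_up();
  };

  bool constant_rate = !flux_x && !replenish;
  double t = 0.0;
  int k = 0;

  if (constant_rate) {
    // N is invariant: draw the exact Poisson number of attempts per
    // sampling interval
    int Na = (int)s.alive.size();
    for (k = 0; k < K; ++k) {
      if (Na > 0 && pm > 0.0) {
        double lambda = Na * pm * (times[k] - t);
        long long n_ev = (long long)R::rpois(lambda);
        for (long long e = 0; e < n_ev; ++e) do_event();
        n_events += n_ev;
      }
      t = times[k];
      snapshot(k);
    }
  } else {
    while (k < K) {
      int Na = (int)s.alive.size();
      if (Na == 0 || pm <= 0.0) {
        for (; k < K; ++k) snapshot(k);
        break;
      }
      double dt = -std::log(1.0 - rng.unif()) / (Na * pm);
      double tnext = t + dt;
      while (k < K && times[k] <= tnext) { snapshot(k); ++k; }
      if (k >= K) break;
      t = tnext;
      ++n_events;
      do_event();
    }
  }

  return List::create(
    _["snapshots"] = snaps,
    _["n_events"] = (double)n_events,
    _["n_exited"] = (double)n_exited,
    _["n_added"] = (double)(s.next_id - 1 - n_initial));
}
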