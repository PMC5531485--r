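// Core update kernel for the hexagonal exclusion-process model.
//
// Sites are indexed (i, j) with 1 <= i <= I (columns) and 1 <= j <= J (rows),
// stored column-major as s = (j - 1) * I + (i - 1) (0-based), which matches an
// R matrix of dimension c(I, J) indexed occ[i, j].
//
// All randomness comes from R's global RNG (unif_rand), so runs are
// reproducible with set.seed() on the R side.

#include <Rcpp.h>
using namespace Rcpp;

// Offsets of the six nearest neighbours on the row-shifted hexagonal lattice.
// Odd rows are shifted half a spacing to the right of even rows, so the
// diagonal neighbours differ by row parity.
static const int EVEN_DI[6] = {-1, 1, -1, 0, -1, 0};
static const int EVEN_DJ[6] = { 0, 0, -1, -1, 1, 1};
static const int ODD_DI[6]  = {-1, 1,  0, 1,  0, 1};
static const int ODD_DJ[6]  = { 0, 0, -1, -1, 1, 1};

// Target of a move from (i, j) in direction dir (0..5); -1 if off-domain.
static inline int nb_site(int i, int j, int dir, int I, int J) {
  int ii, jj;
  if (j % 2 == 0) {
    ii = i + EVEN_DI[dir];
    jj = j + EVEN_DJ[dir];
  } else {
    ii = i + ODD_DI[dir];
    jj = j + ODD_DJ[dir];
  }
  if (ii < 1 || ii > I || jj < 1 || jj > J) return -1;
  return (jj - 1) * I + (ii - 1);
}

static inline int rand_below(int n) {
  int k = (int)(unif_rand() * n);
  return (k >= n) ? n - 1 : k;  // guard against unif_rand() == 1.0
}

struct Lattice {
  int I, J;
  double pm;
  IntegerVector occ;        // working copies (cloned by callers)
  NumericVector pp;
  std::vector<int> cells;   // 0-based site index of every cell

  Lattice(IntegerVector occ_, NumericVector pp_, double pm_, int I_, int J_)
      : I(I_), J(J_), pm(pm_), occ(occ_), pp(pp_) {
    cells.reserve(occ.size());
    for (int s = 0; s < occ.size(); ++s)
      if (occ[s] == 1) cells.push_back(s);
  }

  // One motility attempt on the cell stored at position k in `cells`.
  void motility_attempt(int k) {
    int s = cells[k];
    if (unif_rand() >= pm) return;
    int i = s % I + 1, j = s / I + 1;
    int t = nb_site(i, j, rand_below(6), I, J);
    if (t < 0 || occ[t] == 1) return;  // aborted: off-domain or crowded
    occ[s] = 0;
    occ[t] = 1;
    pp[t] = pp[s];
    pp[s] = NA_REAL;
    cells[k] = t;
  }

  // One proliferation attempt on the cell stored at position k.
  void proliferation_attempt(int k) {
    int s = cells[k];
    double p = pp[s];
    if (unif_rand() >= p) return;
    int i = s % I + 1, j = s / I + 1;
    int t = nb_site(i, j, rand_below(6), I, J);
    if (t < 0 || occ[t] == 1) return;  // aborted
    occ[t] = 1;
    pp[t] = p;  // daughter inherits the mother's value exactly
    cells.push_back(t);
  }

  // One time step: N(t) motility attempts, then N(t) proliferation attempts,
  // selection uniform with replacement over the population at the moment of
  // each draw. If newborns_eligible is false the proliferation selection pool
  // is frozen at its sweep-start size (daughters are appended at the end of
  // `cells`, so restricting the draw range realises the frozen pool).
  void step(bool newborns_eligible) {
    int n0 = (int)cells.size();
    for (int n = 0; n < n0; ++n) motility_attempt(rand_below((int)cells.size()));
    for (int n = 0; n < n0; ++n) {
      int limit = newborns_eligible ? (int)cells.size() : n0;
      proliferation_attempt(rand_below(limit));
    }
  }

  List as_list(int steps) const {
    return List::create(_["occ"] = occ, _["pp"] = pp,
                        _["n"] = (int)cells.size(), _["steps"] = steps);
  }
};

// [[Rcpp::export]]
List cpp_run_steps(IntegerVector occ, NumericVector pp, double pm,
                   int I, int J, int n_steps, bool newborns_eligible) {
  Lattice lat(clone(occ), clone(pp), pm, I, J);
  if (lat.cells.empty() && n_steps > 0)
    stop("cannot advance an empty population: nothing to select");
  for (int s = 0; s < n_steps; ++s) lat.step(newborns_eligible);
  return lat.as_list(n_steps);
}

// Run until the population reaches target_n cells, checking after each
// completed step. Returns reached = false if max_steps was hit first.
// [[Rcpp::export]]
List cpp_run_until(IntegerVector occ, NumericVector pp, double pm,
                   int I, int J, int target_n, int max_steps,
                   bool newborns_eligible) {
  Lattice lat(clone(occ), clone(pp), pm, I, J);
  if (lat.cells.empty())
    stop("cannot advance an empty population: nothing to select");
  int steps = 0;
  while ((int)lat.cells.size() < target_n && steps < max_steps) {
    lat.step(newborns_eligible);
    ++steps;
    if (steps % 256 == 0) Rcpp::checkUserInterrupt();
  }
  List out = lat.as_list(steps);
  out["reached"] = ((int)lat.cells.size() >= target_n);
  return out;
}

// Single motility attempt at site (i, j); the site must be occupied.
// [[Rcpp::export]]
List cpp_attempt_move(IntegerVector occ, NumericVector pp, double pm,
                      int i, int j, int I, int J) {
  Lattice lat(clone(occ), clone(pp), pm, I, J);
  int s = (j - 1) * I + (i - 1);
  if (occ[s] != 1) stop("attempt_move: site (%d, %d) is vacant", i, j);
  int k = (int)(std::find(lat.cells.begin(), lat.cells.end(), s) -
                lat.cells.begin());
  lat.motility_attempt(k);
  return lat.as_list(0);
}

// Single proliferation attempt at site (i, j); the site must be occupied.
// [[Rcpp::export]]
List cpp_attempt_proliferation(IntegerVector occ, NumericVector pp,
                               int i, int j, int I, int J) {
  Lattice lat(clone(occ), clone(pp), 0.0, I, J);
  int s = (j - 1) * I + (i - 1);
  if (occ[s] != 1) stop("attempt_proliferation: site (%d, %d) is vacant", i, j);
  int k = (int)(std::find(lat.cells.begin(), lat.cells.end(), s) -
                lat.cells.begin());
  lat.proliferation_attempt(k);
  return lat.as_list(0);
}

// Squared displacement (in units of delta^2) of n_traj isolated agents after
// n_steps steps each, using the full step kernel (the proliferation sweep runs
// with pp = 0) on an otherwise empty I x J lattice started at its centre.
// [[Rcpp::export]]
NumericVector cpp_isolated_sq_displacement(int n_traj, int n_steps, double pm,
                                           int I, int J) {
  NumericVector out(n_traj);
  int i0 = I / 2 + 1, j0 = J / 2 + 1;
  IntegerVector occ(I * J);
  NumericVector pp(I * J, NA_REAL);
  int s0 = (j0 - 1) * I + (i0 - 1);
  for (int r = 0; r < n_traj; ++r) {
    occ[s0] = 1;
    pp[s0] = 0.0;
    Lattice lat(occ, pp, pm, I, J);  // no clone: buffers reused and reset
    for (int s = 0; s < n_steps; ++s) lat.step(true);
    int sf = lat.cells[0];
    int i1 = sf % I + 1, j1 = sf / I + 1;
    // positions in units of delta: x = (i-1) even rows, (i-1/2) odd rows
    double x0 = (j0 % 2 == 0) ? (i0 - 1.0) : (i0 - 0.5);
    double x1 = (j1 % 2 == 0) ? (i1 - 1.0) : (i1 - 0.5);
    double dy = (j1 - j0) * std::sqrt(3.0) / 2.0;
    out[r] = (x1 - x0) * (x1 - x0) + dy * dy;
    occ[sf] = 0;  // reset for next trajectory
    pp[sf] = NA_REAL;
    if (r % 512 == 0) Rcpp::checkUserInterrupt();
  }
  return out;
}
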