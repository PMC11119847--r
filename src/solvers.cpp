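// Compiled kernels for QUBO minimization: exhaustive Gray-code enumeration
// and multi-restart single-bit-flip Metropolis annealing with a geometric
// cooling schedule and a final zero-temperature quench.
//
// All randomness is drawn from R's RNG, so results are reproducible under
// set.seed().

#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
#include <cstdint>

using namespace Rcpp;

// energy of a state given linear terms, dense couplings and offset
static double stateEnergy(const std::vector<int> &x, const NumericVector &h,
                          const NumericMatrix &J, double offset) {
  const int n = x.size();
  double e = offset;
  for (int i = 0; i < n; ++i) {
    if (!x[i]) continue;
    e += h[i];
    for (int j = i + 1; j < n; ++j)
      if (x[j]) e += J(i, j);
  }
  return e;
}

// lexicographic comparison of two bit states (variable 1 first)
static bool lexLess(uint64_t a, uint64_t b, int n) {
  for (int i = 0; i < n; ++i) {
    int ba = (a >> i) & 1, bb = (b >> i) & 1;
    if (ba != bb) return ba > bb ? false : true;
  }
  return false;
}

struct PoolEntry {
  double e;
  uint64_t state;
};

struct WorseFirst {
  int n;
  explicit WorseFirst(int n_) : n(n_) {}
  bool operator()(const PoolEntry &a, const PoolEntry &b) const {
    if (a.e != b.e) return a.e < b.e;        // max-heap on energy
    return lexLess(a.state, b.state, n);     // keep lex-smaller on ties
  }
};

// [[Rcpp::export(name = ".bruteForceCpp")]]
List bruteForceCpp(NumericVector h, NumericMatrix J, double offset,
                   int top) {
  const int n = h.size();
  if (n > 62) stop("brute force limited to 62 variables");
  const uint64_t total = (n == 0) ? 1ULL : (1ULL << n);
  const uint64_t keep = std::min<uint64_t>(top, total);

  std::priority_queue<PoolEntry, std::vector<PoolEntry>, WorseFirst>
      heap{WorseFirst(n)};

  std::vector<int> x(n, 0);
  double e = offset;
  uint64_t state = 0;
  heap.push({e, state});

  // Gray-code walk: step k flips the bit at the lowest set position of k
  for (uint64_t k = 1; k < total; ++k) {
    int bit = 0;
    while (!((k >> bit) & 1)) ++bit;
    double f = h[bit];
    for (int j = 0; j < n; ++j)
      if (j != bit && x[j]) f += J(bit, j);
    e += (1 - 2 * x[bit]) * f;
    x[bit] = 1 - x[bit];
    state ^= (1ULL << bit);
    if (heap.size() < keep) {
      heap.push({e, state});
    } else {
      const PoolEntry &w = heap.top();
      bool better = e < w.e || (e == w.e && lexLess(state, w.state, n));
      if (better) {
        heap.pop();
        heap.push({e, state});
      }
    }
    if ((k & 0xFFFFF) == 0) Rcpp::checkUserInterrupt();
  }

  std::vector<PoolEntry> entries;
  entries.reserve(heap.size());
  while (!heap.empty()) { entries.push_back(heap.top()); heap.pop(); }
  std::sort(entries.begin(), entries.end(),
            [n](const PoolEntry &a, const PoolEntry &b) {
              if (a.e != b.e) return a.e < b.e;
              return lexLess(a.state, b.state, n);
            });

  const int m = entries.size();
  IntegerMatrix X(m, n);
  NumericVector E(m);
  for (int r = 0; r < m; ++r) {
    E[r] = entries[r].e;
    for (int i = 0; i < n; ++i)
      X(r, i) = (entries[r].state >> i) & 1;
  }
  return List::create(Named("X") = X, Named("H") = E);
}

// [[Rcpp::export(name = ".simulatedAnnealCpp")]]
List simulatedAnnealCpp(NumericVector h, NumericMatrix J, double offset,
                        int restarts, int sweeps, double T0, double Tend,
                        double timeBudget) {
  const int n = h.size();
  RNGScope scope;

  IntegerMatrix X(restarts, n);
  NumericVector E(restarts);
  IntegerVector restartIdx(restarts);

  const double cool = (sweeps > 1)
      ? std::pow(Tend / T0, 1.0 / (sweeps - 1)) : 1.0;

  clock_t start = clock();
  int done = 0;
  for (int r = 0; r < restarts; ++r) {
    if (timeBudget > 0 &&
        double(clock() - start) / CLOCKS_PER_SEC > timeBudget) break;
    std::vector<int> x(n);
    std::vector<double> f(n);   // f[i] = h[i] + sum_j J_ij x_j
    for (int i = 0; i < n; ++i) x[i] = (unif_rand() < 0.5) ? 1 : 0;
    for (int i = 0; i < n; ++i) {
      double fi = h[i];
      for (int j = 0; j < n; ++j)
        if (j != i && x[j]) fi += J(i, j);
      f[i] = fi;
    }
    double e = stateEnergy(x, h, J, offset);

    double T = T0;
    for (int s = 0; s < sweeps; ++s, T *= cool) {
      for (int i = 0; i < n; ++i) {
        double dE = (1 - 2 * x[i]) * f[i];
        if (dE <= 0 || unif_rand() < std::exp(-dE / T)) {
          int delta = 1 - 2 * x[i];
          x[i] = 1 - x[i];
          e += dE;
          for (int j = 0; j < n; ++j)
            if (j != i) f[j] += delta * J(i, j);
        }
      }
    }

    // zero-temperature quench: greedy improving flips to a local minimum
    bool moved = true;
    while (moved) {
      moved = false;
      for (int i = 0; i < n; ++i) {
        double dE = (1 - 2 * x[i]) * f[i];
        if (dE < -1e-12) {
          int delta = 1 - 2 * x[i];
          x[i] = 1 - x[i];
          e += dE;
          for (int j = 0; j < n; ++j)
            if (j != i) f[j] += delta * J(i, j);
          moved = true;
        }
      }
    }

    for (int i = 0; i < n; ++i) X(r, i) = x[i];
    E[r] = e;
    restartIdx[r] = r + 1;
    ++done;
    if ((r & 0x3F) == 0) Rcpp::checkUserInterrupt();
  }

  // copy the completed prefix (a time budget may stop restarts early)
  IntegerMatrix Xout(done, n);
  NumericVector Eout(done);
  IntegerVector Rout(done);
  for (int r = 0; r < done; ++r) {
    Eout[r] = E[r];
    Rout[r] = restartIdx[r];
    for (int i = 0; i < n; ++i) Xout(r, i) = X(r, i);
  }
  return List::create(Named("X") = Xout, Named("H") = Eout,
                      Named("restart") = Rout, Named("completed") = done);
}
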