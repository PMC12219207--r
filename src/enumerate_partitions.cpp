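#include <Rcpp.h>
#include <vector>
#include <cstdint>

// Depth-first enumeration of all nonnegative integer edge-partition count
// vectors that exactly consume the first Zagreb (M1), second Zagreb (M2) and
// forgotten (F) index budgets. The three budgets are linear in the counts
// with positive integer weights, so the search tree is finite; suffix
// min/max ratio windows (M2 and F consumed per unit of M1 over the remaining
// degree pairs) prune branches whose budgets can no longer balance.

namespace {

struct Enumerator {
  int L;
  std::vector<int> w1, w2, wf;          // per-pair weights: a+b, a*b, a^2+b^2
  std::vector<double> lo21, hi21, loF1, hiF1; // suffix ratio windows
  std::vector<int> counts;
  std::vector<int> out;                 // flattened solutions
  R_xlen_t n_sol = 0;
  R_xlen_t max_solutions;
  uint64_t nodes = 0, max_nodes;
  bool truncated = false;

  void dfs(int i, long m1, long m2, long f) {
    if (truncated) return;
    if (++nodes > max_nodes) { truncated = true; return; }
    if (m1 == 0) {
      if (m2 == 0 && f == 0) {
        if (n_sol >= max_solutions) { truncated = true; return; }
        out.insert(out.end(), counts.begin(), counts.end());
        ++n_sol;
      }
      return;
    }
    if (i >= L) return;
    const double dm1 = static_cast<double>(m1);
    if (m2 < dm1 * lo21[i] - 1e-9 || m2 > dm1 * hi21[i] + 1e-9) return;
    if (f  < dm1 * loF1[i] - 1e-9 || f  > dm1 * hiF1[i] + 1e-9) return;
    long ub = m1 / w1[i];
    if (m2 / w2[i] < ub) ub = m2 / w2[i];
    if (f / wf[i] < ub) ub = f / wf[i];
    for (long n = 0; n <= ub; ++n) {
      counts[i] = static_cast<int>(n);
      dfs(i + 1, m1 - n * w1[i], m2 - n * w2[i], f - n * wf[i]);
      if (truncated) break;
    }
    counts[i] = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".cpp_enumerate_partitions")]]
Rcpp::List cpp_enumerate_partitions(Rcpp::IntegerMatrix pairs, int m1, int m2,
                                    int f, double max_solutions,
                                    double max_nodes) {
  const int L = pairs.nrow();
  Enumerator e;
  e.L = L;
  e.max_solutions = static_cast<R_xlen_t>(max_solutions);
  e.max_nodes = static_cast<uint64_t>(max_nodes);
  e.w1.resize(L); e.w2.resize(L); e.wf.resize(L);
  for (int i = 0; i < L; ++i) {
    const int a = pairs(i, 0), b = pairs(i, 1);
    e.w1[i] = a + b;
    e.w2[i] = a * b;
    e.wf[i] = a * a + b * b;
  }
  e.lo21.assign(L, 0.0); e.hi21.assign(L, 0.0);
  e.loF1.assign(L, 0.0); e.hiF1.assign(L, 0.0);
  for (int i = L - 1; i >= 0; --i) {
    const double r21 = static_cast<double>(e.w2[i]) / e.w1[i];
    const double rF1 = static_cast<double>(e.wf[i]) / e.w1[i];
    if (i == L - 1) {
      e.lo21[i] = e.hi21[i] = r21;
      e.loF1[i] = e.hiF1[i] = rF1;
    } else {
      e.lo21[i] = std::min(r21, e.lo21[i + 1]);
      e.hi21[i] = std::max(r21, e.hi21[i + 1]);
      e.loF1[i] = std::min(rF1, e.loF1[i + 1]);
      e.hiF1[i] = std::max(rF1, e.hiF1[i + 1]);
    }
  }
  e.counts.assign(L, 0);
  e.dfs(0, m1, m2, f);
  Rcpp::IntegerMatrix sol(e.n_sol, L);
  for (R_xlen_t s = 0; s < e.n_sol; ++s)
    for (int j = 0; j < L; ++j) sol(s, j) = e.out[s * L + j];
  return Rcpp::List::create(Rcpp::Named("solutions") = sol,
                            Rcpp::Named("truncated") = e.truncated,
                            Rcpp::Named("nodes") = static_cast<double>(e.nodes));
}
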