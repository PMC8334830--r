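#include <Rcpp.h>
#include <queue>
#include <tuple>
#include <vector>
using namespace Rcpp;

// Seeded watershed as a priority flood: voxels are popped in increasing
// priority (gradient magnitude), ties broken by queue insertion order so
// the result is fully deterministic.  Seed voxels keep their labels;
// neighbours inherit the label of the voxel that reached them first.
// 6-neighbourhood.  labels: 0 = unassigned, >0 = seed label.
// [[Rcpp::export]]
IntegerVector cpp_priority_flood(NumericVector priority, IntegerVector seeds,
                                 IntegerVector dims) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n12 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = n12 * n3;
  IntegerVector lab(clone(seeds));

  typedef std::tuple<double, long long, R_xlen_t> Entry; // (prio, seq, idx)
  std::priority_queue<Entry, std::vector<Entry>, std::greater<Entry> > pq;
  long long seq = 0;
  for (R_xlen_t i = 0; i < n; ++i)
    if (lab[i] > 0) pq.push(Entry(priority[i], seq++, i));

  const int d1[6] = {-1, 1, 0, 0, 0, 0};
  const int d2[6] = {0, 0, -1, 1, 0, 0};
  const int d3[6] = {0, 0, 0, 0, -1, 1};

  while (!pq.empty()) {
    Entry e = pq.top();
    pq.pop();
    const R_xlen_t idx = std::get<2>(e);
    const int lb = lab[idx];
    const int i = (int)(idx % n1);
    const int j = (int)((idx / n1) % n2);
    const int k = (int)(idx / n12);
    for (int t = 0; t < 6; ++t) {
      const int ii = i + d1[t], jj = j + d2[t], kk = k + d3[t];
      if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
        continue;
      const R_xlen_t nb = (R_xlen_t)kk * n12 + (R_xlen_t)jj * n1 + ii;
      if (lab[nb] == 0) {
        lab[nb] = lb;
        pq.push(Entry(priority[nb], seq++, nb));
      }
    }
  }
  return lab;
}

// Connected-component labelling of a binary mask, BFS in scan order.
// connectivity: 6 (faces) or 26 (faces+edges+corners).
// [[Rcpp::export]]
IntegerVector cpp_label_components(LogicalVector mask, IntegerVector dims,
                                   int connectivity) {
  const int n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const R_xlen_t n12 = (R_xlen_t)n1 * n2;
  const R_xlen_t n = n12 * n3;
  IntegerVector lab(n, 0);

  std::vector<int> o1, o2, o3;
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        if (a == 0 && b == 0 && c == 0) continue;
        const int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (connectivity == 6 && manh > 1) continue;
        o1.push_back(a);
        o2.push_back(b);
        o3.push_back(c);
      }

  int next = 0;
  std::vector<R_xlen_t> stack;
  for (R_xlen_t s = 0; s < n; ++s) {
    if (!mask[s] || lab[s] != 0) continue;
    ++next;
    lab[s] = next;
    stack.push_back(s);
    while (!stack.empty()) {
      const R_xlen_t idx = stack.back();
      stack.pop_back();
      const int i = (int)(idx % n1);
      const int j = (int)((idx / n1) % n2);
      const int k = (int)(idx / n12);
      for (size_t t = 0; t < o1.size(); ++t) {
        const int ii = i + o1[t], jj = j + o2[t], kk = k + o3[t];
        if (ii < 0 || ii >= n1 || jj < 0 || jj >= n2 || kk < 0 || kk >= n3)
          continue;
        const R_xlen_t nb = (R_xlen_t)kk * n12 + (R_xlen_t)jj * n1 + ii;
        if (mask[nb] && lab[nb] == 0) {
          lab[nb] = next;
          stack.push_back(nb);
        }
      }
    }
  }
  return lab;
}
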