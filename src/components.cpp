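// 3D connected-component labeling of a binary volume by breadth-first
// search under 6-, 18- or 26-neighbourhood adjacency.

#include <Rcpp.h>
#include <vector>
#include <queue>
using namespace Rcpp;

// [[Rcpp::export(name = ".cpp_label_components_3d")]]
IntegerVector cpp_label_components_3d(IntegerVector mask, int d1, int d2,
                                      int d3, int connectivity) {
  IntegerVector labels(mask.size(), 0);
  auto idx = [&](int i, int j, int k) { return i + d1 * (j + d2 * k); };
  int next_label = 0;
  std::queue<std::array<int, 3>> q;
  for (int k = 0; k < d3; ++k) {
    for (int j = 0; j < d2; ++j) {
      for (int i = 0; i < d1; ++i) {
        int p = idx(i, j, k);
        if (mask[p] == 0 || labels[p] != 0) continue;
        ++next_label;
        labels[p] = next_label;
        q.push({i, j, k});
        while (!q.empty()) {
          auto c = q.front();
          q.pop();
          for (int dk = -1; dk <= 1; ++dk) {
            for (int dj = -1; dj <= 1; ++dj) {
              for (int di = -1; di <= 1; ++di) {
                int manh = std::abs(di) + std::abs(dj) + std::abs(dk);
                if (manh == 0) continue;
                if (connectivity == 6 && manh > 1) continue;
                if (connectivity == 18 && manh > 2) continue;
                int ni = c[0] + di, nj = c[1] + dj, nk = c[2] + dk;
                if (ni < 0 || ni >= d1 || nj < 0 || nj >= d2 ||
                    nk < 0 || nk >= d3) continue;
                int np = idx(ni, nj, nk);
                if (mask[np] == 0 || labels[np] != 0) continue;
                labels[np] = next_label;
                q.push({ni, nj, nk});
              }
            }
          }
        }
      }
    }
  }
  labels.attr("dim") = IntegerVector::create(d1, d2, d3);
  return labels;
}
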