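#include <Rcpp.h>
#include <queue>
using namespace Rcpp;

// Connected-component labeling of a binary matrix.
// Components are numbered 1..k in order of first encounter in a
// row-major scan (row 1 left-to-right, then row 2, ...), which fixes
// the "lowest id" tie-break used by remove_largest().
// connectivity: 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label_2d(const IntegerMatrix& mask, int connectivity) {
  const int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  const int dr4[] = {-1, 1, 0, 0};
  const int dc4[] = {0, 0, -1, 1};
  const int dr8[] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc8[] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const int* dr = (connectivity == 4) ? dr4 : dr8;
  const int* dc = (connectivity == 4) ? dc4 : dc8;
  const int nd = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::queue<std::pair<int, int> > q;
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      lab(r, c) = ++next;
      q.push(std::make_pair(r, c));
      while (!q.empty()) {
        std::pair<int, int> p = q.front(); q.pop();
        for (int k = 0; k < nd; ++k) {
          int rr = p.first + dr[k], cc = p.second + dc[k];
          if (rr < 0 || rr >= nr || cc < 0 || cc >= nc) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = next;
            q.push(std::make_pair(rr, cc));
          }
        }
      }
    }
  }
  return lab;
}

// 26-connected labeling of a stacked binary volume (dims H x W x S).
// Numbering follows first encounter scanning slices outermost.
// [[Rcpp::export]]
IntegerVector cc_label_3d(const IntegerVector& vox, int nr, int nc, int ns) {
  IntegerVector lab(vox.size());
  int next = 0;
  std::queue<int> q;
  for (int s = 0; s < ns; ++s) {
    for (int r = 0; r < nr; ++r) {
      for (int c = 0; c < nc; ++c) {
        int i = r + nr * (c + nc * s);
        if (vox[i] == 0 || lab[i] != 0) continue;
        lab[i] = ++next;
        q.push(i);
        while (!q.empty()) {
          int j = q.front(); q.pop();
          int js = j / (nr * nc), jrem = j % (nr * nc);
          int jc = jrem / nr, jr = jrem % nr;
          for (int ds = -1; ds <= 1; ++ds) {
            for (int dc = -1; dc <= 1; ++dc) {
              for (int dr = -1; dr <= 1; ++dr) {
                if (dr == 0 && dc == 0 && ds == 0) continue;
                int rr = jr + dr, cc2 = jc + dc, ss = js + ds;
                if (rr < 0 || rr >= nr || cc2 < 0 || cc2 >= nc ||
                    ss < 0 || ss >= ns) continue;
                int k = rr + nr * (cc2 + nc * ss);
                if (vox[k] != 0 && lab[k] == 0) {
                  lab[k] = next;
                  q.push(k);
                }
              }
            }
          }
        }
      }
    }
  }
  lab.attr("dim") = IntegerVector::create(nr, nc, ns);
  return lab;
}

// Binary median filter with an odd kernel and edge replication:
// out-of-bounds neighbours take the clamped (nearest edge) value, so
// replicated pixels are counted with multiplicity. For a binary image
// the median is the majority vote over kernel*kernel samples.
// [[Rcpp::export]]
IntegerMatrix median_filter_bin(const IntegerMatrix& mask, int kernel) {
  const int nr = mask.nrow(), nc = mask.ncol();
  const int h = kernel / 2, need = (kernel * kernel) / 2 + 1;
  IntegerMatrix out(nr, nc);
  for (int r = 0; r < nr; ++r) {
    for (int c = 0; c < nc; ++c) {
      int ones = 0;
      for (int dr = -h; dr <= h; ++dr) {
        int rr = r + dr;
        if (rr < 0) rr = 0; else if (rr >= nr) rr = nr - 1;
        for (int dc = -h; dc <= h; ++dc) {
          int cc = c + dc;
          if (cc < 0) cc = 0; else if (cc >= nc) cc = nc - 1;
          ones += (mask(rr, cc) != 0);
        }
      }
      out(r, c) = (ones >= need) ? 1 : 0;
    }
  }
  return out;
}
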