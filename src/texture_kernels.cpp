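#include <Rcpp.h>
using namespace Rcpp;

// Co-occurrence counts of quantized levels (NA = unmasked) at offset
// (dr, dc), accumulated over all slices of a [nr x nc x ns] array.
// Ordered counts; symmetrization happens in R.
// [[Rcpp::export(name = ".glcm_counts_cpp")]]
IntegerMatrix glcm_counts_cpp(IntegerVector levels, IntegerVector dims,
                              int dr, int dc, int ng) {
  int nr = dims[0], nc = dims[1], ns = dims[2];
  IntegerMatrix counts(ng, ng);
  for (int k = 0; k < ns; ++k) {
    const int *sl = levels.begin() + (R_xlen_t)k * nr * nc;
    int r0 = std::max(0, -dr), r1 = std::min(nr, nr - dr);
    int c0 = std::max(0, -dc), c1 = std::min(nc, nc - dc);
    for (int c = c0; c < c1; ++c) {
      for (int r = r0; r < r1; ++r) {
        int a = sl[r + c * nr];
        if (a == NA_INTEGER) continue;
        int b = sl[(r + dr) + (c + dc) * nr];
        if (b == NA_INTEGER) continue;
        counts(a - 1, b - 1)++;
      }
    }
  }
  return counts;
}

// Run-length counts p(level, length) for one direction over all slices.
// direction: 0 = rows (0 deg), 1 = columns (90), 2 = anti-diagonals (45),
// 3 = diagonals (135). An NA (unmasked) pixel terminates a run.
// Returned matrix is ng x max(nr, nc); trailing zero columns trimmed in R.
// [[Rcpp::export(name = ".glrlm_counts_cpp")]]
IntegerMatrix glrlm_counts_cpp(IntegerVector levels, IntegerVector dims,
                               int direction, int ng) {
  int nr = dims[0], nc = dims[1], ns = dims[2];
  int lmax = std::max(nr, nc);
  IntegerMatrix counts(ng, lmax);
  for (int k = 0; k < ns; ++k) {
    const int *sl = levels.begin() + (R_xlen_t)k * nr * nc;
    // enumerate line start points and the (dr, dc) step
    std::vector<std::pair<int, int> > starts;
    int dr = 0, dc = 0;
    if (direction == 0) {            // left to right along each row
      dr = 0; dc = 1;
      for (int r = 0; r < nr; ++r) starts.push_back(std::make_pair(r, 0));
    } else if (direction == 1) {     // top to bottom along each column
      dr = 1; dc = 0;
      for (int c = 0; c < nc; ++c) starts.push_back(std::make_pair(0, c));
    } else if (direction == 2) {     // 45 deg: up-right anti-diagonals
      dr = -1; dc = 1;
      for (int r = 0; r < nr; ++r) starts.push_back(std::make_pair(r, 0));
      for (int c = 1; c < nc; ++c) starts.push_back(std::make_pair(nr - 1, c));
    } else {                         // 135 deg: down-right diagonals
      dr = 1; dc = 1;
      for (int r = 0; r < nr; ++r) starts.push_back(std::make_pair(r, 0));
      for (int c = 1; c < nc; ++c) starts.push_back(std::make_pair(0, c));
    }
    for (size_t s = 0; s < starts.size(); ++s) {
      int r = starts[s].first, c = starts[s].second;
      int cur = NA_INTEGER, len = 0;
      while (r >= 0 && r < nr && c >= 0 && c < nc) {
        int v = sl[r + c * nr];
        if (v == cur && v != NA_INTEGER) {
          ++len;
        } else {
          if (cur != NA_INTEGER && len > 0) counts(cur - 1, len - 1)++;
          cur = v;
          len = (v == NA_INTEGER) ? 0 : 1;
        }
        r += dr; c += dc;
      }
      if (cur != NA_INTEGER && len > 0) counts(cur - 1, len - 1)++;
    }
  }
  return counts;
}
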