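#include <Rcpp.h>
using namespace Rcpp;

// Guo-Hall parallel thinning of a binary image until stable.
// [[Rcpp::export]]
LogicalMatrix gh_thin_cpp(LogicalMatrix mask, int max_iter) {
  int nr = mask.nrow(), nc = mask.ncol();
  std::vector<int> p(nr * nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) p[i + j * nr] = mask(i, j) ? 1 : 0;
  auto at = [&](int i, int j) -> int {
    if (i < 0 || j < 0 || i >= nr || j >= nc) return 0;
    return p[i + j * nr];
  };
  std::vector<int> del;
  del.reserve(nr * nc / 8);
  for (int iter = 0; iter < max_iter; ++iter) {
    bool changed = false;
    for (int sub = 0; sub < 2; ++sub) {
      del.clear();
      for (int j = 0; j < nc; ++j) {
        for (int i = 0; i < nr; ++i) {
          if (!p[i + j * nr]) continue;
          int p2 = at(i - 1, j),     p3 = at(i - 1, j + 1);
          int p4 = at(i, j + 1),     p5 = at(i + 1, j + 1);
          int p6 = at(i + 1, j),     p7 = at(i + 1, j - 1);
          int p8 = at(i, j - 1),     p9 = at(i - 1, j - 1);
          int C = ((!p2) && (p3 || p4)) + ((!p4) && (p5 || p6)) +
                  ((!p6) && (p7 || p8)) + ((!p8) && (p9 || p2));
          int N1 = (p9 || p2) + (p3 || p4) + (p5 || p6) + (p7 || p8);
          int N2 = (p2 || p3) + (p4 || p5) + (p6 || p7) + (p8 || p9);
          int N = N1 < N2 ? N1 : N2;
          int m = sub == 0 ? ((p6 || p7 || !p9) && p8)
                           : ((p2 || p3 || !p5) && p4);
          if (C == 1 && N >= 2 && N <= 3 && !m) del.push_back(i + j * nr);
        }
      }
      for (size_t k = 0; k < del.size(); ++k) p[del[k]] = 0;
      if (!del.empty()) changed = true;
    }
    if (!changed) break;
  }
  LogicalMatrix out(nr, nc);
  for (int j = 0; j < nc; ++j)
    for (int i = 0; i < nr; ++i) out(i, j) = p[i + j * nr] != 0;
  return out;
}

// Label every pixel of a size x size grid by its nearest center (Euclidean;
// 1-based labels). Pixel (i, j) sits at coordinates (i + 1, j + 1) in R's
// 1-based row/col convention.
// [[Rcpp::export]]
IntegerMatrix nearest_center_cpp(NumericMatrix centers, int size) {
  int n = centers.nrow();
  std::vector<double> cy(n), cx(n);
  for (int c = 0; c < n; ++c) { cy[c] = centers(c, 0); cx[c] = centers(c, 1); }
  IntegerMatrix lab(size, size);
  int* out = INTEGER(lab);
  for (int j = 0; j < size; ++j) {
    double x = j + 1.0;
    for (int i = 0; i < size; ++i) {
      double y = i + 1.0;
      double best = R_PosInf;
      int arg = 1;
      for (int c = 0; c < n; ++c) {
        double dy = y - cy[c], dx = x - cx[c];
        double d = dy * dy + dx * dx;
        if (d < best) { best = d; arg = c + 1; }
      }
      out[i + j * size] = arg;
    }
  }
  return lab;
}
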