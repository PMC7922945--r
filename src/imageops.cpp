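// Binary-image utilities: connected components with 4- or 8-connectivity,
// Moore boundary tracing, and centre rotation (bilinear or nearest) used by
// the augmentation step.

#include <Rcpp.h>
#include <vector>
#include <queue>
#include <cmath>

using namespace Rcpp;

// [[Rcpp::export]]
IntegerMatrix cc_label(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  if (connectivity != 4 && connectivity != 8) stop("connectivity must be 4 or 8");
  IntegerMatrix lab(H, W);
  int next = 0;
  const int di8[] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dj8[] = {0, 0, -1, 1, -1, 1, -1, 1};
  const int nn = connectivity == 4 ? 4 : 8;
  std::queue<std::pair<int, int>> q;
  for (int j = 0; j < W; ++j)
    for (int i = 0; i < H; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      q.push({i, j});
      while (!q.empty()) {
        auto [ci, cj] = q.front(); q.pop();
        for (int d = 0; d < nn; ++d) {
          int ni = ci + di8[d], nj = cj + dj8[d];
          if (ni < 0 || ni >= H || nj < 0 || nj >= W) continue;
          if (mask(ni, nj) != 0 && lab(ni, nj) == 0) {
            lab(ni, nj) = next;
            q.push({ni, nj});
          }
        }
      }
    }
  lab.attr("n") = next;
  return lab;
}

// Moore-neighbour boundary tracing (8-connected foreground) of the component
// containing the first foreground pixel in column-major scan order.  Returns
// an ordered, closed list of boundary pixel coordinates (row, col), 1-based.
// [[Rcpp::export]]
IntegerMatrix trace_boundary(IntegerMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  int si = -1, sj = -1;
  for (int j = 0; j < W && si < 0; ++j)
    for (int i = 0; i < H; ++i)
      if (mask(i, j) != 0) { si = i; sj = j; break; }
  if (si < 0) stop("empty mask: no boundary to trace");
  // clockwise Moore neighbourhood starting from West
  const int di[] = {0, -1, -1, -1, 0, 1, 1, 1};
  const int dj[] = {-1, -1, 0, 1, 1, 1, 0, -1};
  auto fg = [&](int i, int j) {
    return i >= 0 && i < H && j >= 0 && j < W && mask(i, j) != 0;
  };
  std::vector<std::pair<int, int>> out;
  int ci = si, cj = sj, backtrack = 0;  // came from the West
  for (int iter = 0; iter < 4 * H * W + 8; ++iter) {
    out.push_back({ci, cj});
    int k = (backtrack + 1) % 8, found = -1;
    for (int s = 0; s < 8; ++s) {
      int d = (k + s) % 8;
      if (fg(ci + di[d], cj + dj[d])) { found = d; break; }
    }
    if (found < 0) break;  // isolated pixel
    int ni = ci + di[found], nj = cj + dj[found];
    // next backtrack: direction pointing back to the previous pixel
    backtrack = (found + 4) % 8;
    if (ni == si && nj == sj) break;  // boundary closed
    ci = ni; cj = nj;
  }
  IntegerMatrix res(out.size(), 2);
  for (size_t r = 0; r < out.size(); ++r) {
    res(r, 0) = out[r].first + 1;
    res(r, 1) = out[r].second + 1;
  }
  return res;
}

// Rotate an [H x W x C] stack counter-clockwise (in the y-up physical
// convention) by `angle` degrees about the image centre, zero padding.
// [[Rcpp::export]]
NumericVector rotate_stack(NumericVector img, double angle_deg, bool bilinear) {
  IntegerVector dm = img.attr("dim");
  if (dm.size() != 3) stop("img must be a 3-d array [H, W, C]");
  const int H = dm[0], W = dm[1], C = dm[2];
  NumericVector out(img.size());
  out.attr("dim") = dm;
  const double th = angle_deg * M_PI / 180.0;
  // array row index i grows downwards: a CCW physical rotation is CW in
  // (i, j) index space, so use the transpose of the usual rotation matrix
  const double ct = std::cos(th), st = std::sin(th);
  const double cy = (H - 1) / 2.0, cx = (W - 1) / 2.0;
  for (int c = 0; c < C; ++c) {
    const double* src = img.begin() + (size_t)c * H * W;
    double* dst = out.begin() + (size_t)c * H * W;
    for (int j = 0; j < W; ++j)
      for (int i = 0; i < H; ++i) {
        // inverse map: source coords of output pixel (i, j)
        const double dy = i - cy, dx = j - cx;
        const double sy = ct * dy - st * dx + cy;
        const double sx = st * dy + ct * dx + cx;
        double v = 0.0;
        if (bilinear) {
          const int i0 = (int)std::floor(sy), j0 = (int)std::floor(sx);
          const double fy = sy - i0, fx = sx - j0;
          double acc = 0.0;
          for (int b = 0; b <= 1; ++b)
            for (int a = 0; a <= 1; ++a) {
              const int ii = i0 + a, jj = j0 + b;
              const double wgt = (a ? fy : 1 - fy) * (b ? fx : 1 - fx);
              if (ii >= 0 && ii < H && jj >= 0 && jj < W)
                acc += wgt * src[(size_t)jj * H + ii];
            }
          v = acc;
        } else {
          const int ii = (int)std::lround(sy), jj = (int)std::lround(sx);
          if (ii >= 0 && ii < H && jj >= 0 && jj < W) v = src[(size_t)jj * H + ii];
        }
        dst[(size_t)j * H + i] = v;
      }
  }
  return out;
}
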