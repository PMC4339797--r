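#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Voxel layout follows R's column-major (z, y, x) arrays: linear index
// i = z + nz*(y + ny*x). Neighborhood offsets are built once per call.

static void build_offsets(int connectivity, std::vector<int> &dz,
                          std::vector<int> &dy, std::vector<int> &dx) {
  for (int a = -1; a <= 1; ++a)
    for (int b = -1; b <= 1; ++b)
      for (int c = -1; c <= 1; ++c) {
        int manh = std::abs(a) + std::abs(b) + std::abs(c);
        if (manh == 0) continue;
        if (connectivity == 6 && manh > 1) continue;
        if (connectivity == 18 && manh > 2) continue;
        dz.push_back(a); dy.push_back(b); dx.push_back(c);
      }
}

// Flood-fill labeling of foreground voxels. `fg` is any vector coercible to
// logical; labels 1..count, background 0.
// [[Rcpp::export]]
List label_components_cpp(LogicalVector fg, IntegerVector dim,
                          int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (fg.size() != n) stop("binary array does not match dim");
  std::vector<int> dz, dy, dx;
  build_offsets(connectivity, dz, dy, dx);
  const int noff = (int)dz.size();

  IntegerVector labels(n, 0);
  std::vector<R_xlen_t> stack;
  int count = 0;
  for (R_xlen_t i = 0; i < n; ++i) {
    if (!fg[i] || labels[i] != 0) continue;
    ++count;
    labels[i] = count;
    stack.push_back(i);
    while (!stack.empty()) {
      R_xlen_t cur = stack.back(); stack.pop_back();
      int z = (int)(cur % nz);
      int rest = (int)(cur / nz);
      int y = rest % ny;
      int x = rest / ny;
      for (int k = 0; k < noff; ++k) {
        int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
        if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
          continue;
        R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
        if (fg[j] && labels[j] == 0) {
          labels[j] = count;
          stack.push_back(j);
        }
      }
    }
  }
  return List::create(_["labels"] = labels, _["count"] = count);
}

// Component counts at each threshold (strictly-above binarization), sharing
// one visited buffer across thresholds instead of materializing label arrays.
// [[Rcpp::export]]
IntegerVector sweep_counts_cpp(NumericVector img, IntegerVector dim,
                               NumericVector thresholds, int connectivity) {
  if (connectivity != 6 && connectivity != 18 && connectivity != 26)
    stop("connectivity must be 6, 18 or 26");
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("image does not match dim");
  std::vector<int> dz, dy, dx;
  build_offsets(connectivity, dz, dy, dx);
  const int noff = (int)dz.size();

  IntegerVector counts(thresholds.size());
  std::vector<unsigned char> seen(n);
  std::vector<R_xlen_t> stack;
  for (int t = 0; t < thresholds.size(); ++t) {
    const double th = thresholds[t];
    std::fill(seen.begin(), seen.end(), 0);
    int count = 0;
    for (R_xlen_t i = 0; i < n; ++i) {
      if (seen[i] || !(img[i] > th)) continue;
      ++count;
      seen[i] = 1;
      stack.push_back(i);
      while (!stack.empty()) {
        R_xlen_t cur = stack.back(); stack.pop_back();
        int z = (int)(cur % nz);
        int rest = (int)(cur / nz);
        int y = rest % ny;
        int x = rest / ny;
        for (int k = 0; k < noff; ++k) {
          int zz = z + dz[k], yy = y + dy[k], xx = x + dx[k];
          if (zz < 0 || zz >= nz || yy < 0 || yy >= ny || xx < 0 || xx >= nx)
            continue;
          R_xlen_t j = zz + (R_xlen_t)nz * (yy + (R_xlen_t)ny * xx);
          if (!seen[j] && img[j] > th) {
            seen[j] = 1;
            stack.push_back(j);
          }
        }
      }
    }
    counts[t] = count;
  }
  return counts;
}

// 1-D convolution along one axis of a (z, y, x) array with half-sample
// symmetric ("reflect") boundaries: index -1 maps to 0, n maps to n-1.
// axis: 0 = z, 1 = y, 2 = x. taps has odd length.
// [[Rcpp::export]]
NumericVector conv1d_axis_cpp(NumericVector img, IntegerVector dim,
                              NumericVector taps, int axis) {
  const int nz = dim[0], ny = dim[1], nx = dim[2];
  const R_xlen_t n = (R_xlen_t)nz * ny * nx;
  if (img.size() != n) stop("image does not match dim");
  if (taps.size() % 2 == 0) stop("taps must have odd length");
  if (axis < 0 || axis > 2) stop("axis must be 0, 1 or 2");
  const int h = ((int)taps.size() - 1) / 2;
  const int len = axis == 0 ? nz : (axis == 1 ? ny : nx);
  const R_xlen_t stride =
      axis == 0 ? 1 : (axis == 1 ? (R_xlen_t)nz : (R_xlen_t)nz * ny);

  NumericVector out(n);
  // iterate over all lines along `axis`
  const int n1 = axis == 0 ? ny : nz;
  const int n2 = axis == 2 ? ny : nx;
  for (int b = 0; b < n2; ++b) {
    for (int a = 0; a < n1; ++a) {
      R_xlen_t base;
      if (axis == 0)
        base = (R_xlen_t)nz * (a + (R_xlen_t)ny * b);
      else if (axis == 1)
        base = a + (R_xlen_t)nz * ny * b;        // a = z, b = x
      else
        base = a + (R_xlen_t)nz * b;             // a = z, b = y
      for (int i = 0; i < len; ++i) {
        double acc = 0.0;
        for (int k = -h; k <= h; ++k) {
          int j = i + k;
          if (j < 0) j = -j - 1;
          else if (j >= len) j = 2 * len - 1 - j;
          acc += taps[k + h] * img[base + (R_xlen_t)j * stride];
        }
        out[base + (R_xlen_t)i * stride] = acc;
      }
    }
  }
  return out;
}
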