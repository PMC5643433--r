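#include <Rcpp.h>
#include <algorithm>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Median filter over a rectangular size x size window. Even sizes use the
// asymmetric window [i - size/2 + 1, i + size/2] (so size 8 spans offsets
// -3..+4), matching the documented convention; borders are clamped
// (replicated). Even pixel counts take the midpoint of the two central
// order statistics.
// [[Rcpp::export]]
NumericMatrix cpp_median_filter(NumericMatrix img, int size) {
  int nr = img.nrow(), nc = img.ncol();
  int lo = -(size / 2) + (size % 2 == 0 ? 1 : 0);
  int hi = size / 2;
  NumericMatrix out(nr, nc);
  std::vector<double> buf;
  buf.reserve((size_t)size * size);
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      buf.clear();
      for (int dj = lo; dj <= hi; ++dj) {
        int jj = std::min(std::max(j + dj, 0), nc - 1);
        for (int di = lo; di <= hi; ++di) {
          int ii = std::min(std::max(i + di, 0), nr - 1);
          buf.push_back(img(ii, jj));
        }
      }
      size_t n = buf.size();
      size_t mid = n / 2;
      std::nth_element(buf.begin(), buf.begin() + mid, buf.end());
      double m = buf[mid];
      if (n % 2 == 0) {
        double m2 = *std::max_element(buf.begin(), buf.begin() + mid);
        m = (m + m2) / 2.0;
      }
      out(i, j) = m;
    }
  }
  return out;
}

// 8-connected component labeling of a logical mask; labels are 1..k in
// first-encounter (column-major) order, background is 0.
// [[Rcpp::export]]
IntegerMatrix cpp_label8(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  IntegerMatrix lab(nr, nc);
  std::vector<std::pair<int, int> > stack;
  int next = 0;
  for (int j = 0; j < nc; ++j) {
    for (int i = 0; i < nr; ++i) {
      if (!mask(i, j) || lab(i, j) != 0) continue;
      ++next;
      stack.clear();
      stack.push_back(std::make_pair(i, j));
      lab(i, j) = next;
      while (!stack.empty()) {
        std::pair<int, int> p = stack.back();
        stack.pop_back();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int ii = p.first + di, jj = p.second + dj;
            if (ii < 0 || ii >= nr || jj < 0 || jj >= nc) continue;
            if (mask(ii, jj) && lab(ii, jj) == 0) {
              lab(ii, jj) = next;
              stack.push_back(std::make_pair(ii, jj));
            }
          }
        }
      }
    }
  }
  return lab;
}

// Circular Hough transform on an edge pixel list. For every edge pixel and
// candidate radius, votes are cast along the circle of candidate centres
// (angular step fine enough for <= 1 px arcs, consecutive duplicate cells
// skipped). The per-radius score is the best single accumulator cell
// normalised by the circle circumference 2*pi*r, so a complete
// one-pixel-thick ring scores near 1 and diffuse noise votes score low.
// The centre is refined as the vote-weighted centroid of the 3x3
// neighbourhood of the best cell.
// xs, ys are 1-based pixel coordinates (x = column, y = row).
// [[Rcpp::export]]
List cpp_hough_circle(IntegerVector xs, IntegerVector ys, int w, int h,
                      NumericVector radii) {
  int ne = xs.size();
  double best_score = -1.0, best_cx = NA_REAL, best_cy = NA_REAL,
         best_r = NA_REAL;
  std::vector<int> acc((size_t)w * h);
  for (int ri = 0; ri < radii.size(); ++ri) {
    double r = radii[ri];
    std::fill(acc.begin(), acc.end(), 0);
    int n_ang = std::max(12, (int)std::ceil(2.0 * M_PI * r));
    for (int e = 0; e < ne; ++e) {
      double x = xs[e], y = ys[e];
      int lastx = -1, lasty = -1;
      for (int a = 0; a < n_ang; ++a) {
        double th = 2.0 * M_PI * a / n_ang;
        int cx = (int)std::lround(x - r * std::cos(th));
        int cy = (int)std::lround(y - r * std::sin(th));
        if (cx == lastx && cy == lasty) continue;
        lastx = cx; lasty = cy;
        if (cx < 1 || cx > w || cy < 1 || cy > h) continue;
        ++acc[(size_t)(cx - 1) * h + (cy - 1)];
      }
    }
    // best single cell for this radius
    int top = 0, top_cx = 0, top_cy = 0;
    for (int cx = 1; cx <= w; ++cx) {
      for (int cy = 1; cy <= h; ++cy) {
        int v = acc[(size_t)(cx - 1) * h + (cy - 1)];
        if (v > top) { top = v; top_cx = cx; top_cy = cy; }
      }
    }
    if (top == 0) continue;
    double score = top / (2.0 * M_PI * r);
    if (score > best_score) {
      double s = 0.0, wx = 0.0, wy = 0.0;
      for (int dj = -1; dj <= 1; ++dj) {
        for (int di = -1; di <= 1; ++di) {
          int xx = top_cx + dj, yy = top_cy + di;
          if (xx < 1 || xx > w || yy < 1 || yy > h) continue;
          int v = acc[(size_t)(xx - 1) * h + (yy - 1)];
          s += v; wx += v * xx; wy += v * yy;
        }
      }
      best_score = score;
      best_cx = wx / s;
      best_cy = wy / s;
      best_r = r;
    }
  }
  return List::create(_["cx"] = best_cx, _["cy"] = best_cy,
                      _["r"] = best_r, _["score"] = best_score);
}

// I-DT dispersion-threshold fixation detection on one contiguous gaze
// segment. Grows a window to the minimal duration (span >= min_dur,
// inclusive), rejects it if dispersion (x range + y range) exceeds
// max_disp, otherwise extends while dispersion stays within the threshold
// and emits [start, end] sample indices (1-based).
// [[Rcpp::export]]
IntegerMatrix cpp_idt(NumericVector t, NumericVector x, NumericVector y,
                      double min_dur, double max_disp) {
  int n = t.size();
  std::vector<int> starts, ends;
  const double eps = 1e-9;
  int i = 0;
  while (i < n) {
    // minimal window covering min_dur
    int j = i;
    while (j < n && t[j] - t[i] < min_dur - eps) ++j;
    if (j >= n) break;
    double xmin = x[i], xmax = x[i], ymin = y[i], ymax = y[i];
    for (int k = i + 1; k <= j; ++k) {
      xmin = std::min(xmin, x[k]); xmax = std::max(xmax, x[k]);
      ymin = std::min(ymin, y[k]); ymax = std::max(ymax, y[k]);
    }
    if ((xmax - xmin) + (ymax - ymin) > max_disp + eps) {
      ++i;
      continue;
    }
    while (j + 1 < n) {
      double nxmin = std::min(xmin, x[j + 1]), nxmax = std::max(xmax, x[j + 1]);
      double nymin = std::min(ymin, y[j + 1]), nymax = std::max(ymax, y[j + 1]);
      if ((nxmax - nxmin) + (nymax - nymin) > max_disp + eps) break;
      xmin = nxmin; xmax = nxmax; ymin = nymin; ymax = nymax;
      ++j;
    }
    starts.push_back(i + 1);
    ends.push_back(j + 1);
    i = j + 1;
  }
  IntegerMatrix out(starts.size(), 2);
  for (size_t k = 0; k < starts.size(); ++k) {
    out(k, 0) = starts[k];
    out(k, 1) = ends[k];
  }
  colnames(out) = CharacterVector::create("start", "end");
  return out;
}
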