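#include <Rcpp.h>
#include <cmath>
using namespace Rcpp;

// Non-local-means denoising of an 8-bit greyscale raster.
// h: filter strength; tmpl/search: odd window sizes in pixels.
// Patch distance uses the mean squared difference over the template window;
// weights are exp(-max(d2 - 2*sigma2, 0)/h^2) with sigma2 = 0 (plain NLM).
// [[Rcpp::export]]
NumericMatrix nlm_denoise_cpp(NumericMatrix img, double h, int tmpl, int search) {
  int nr = img.nrow(), nc = img.ncol();
  NumericMatrix out(nr, nc);
  if (h <= 0) {
    std::copy(img.begin(), img.end(), out.begin());
    return out;
  }
  int tr = tmpl / 2, sr = search / 2;
  double h2 = h * h;
  double npatch = (2.0 * tr + 1) * (2.0 * tr + 1);
  for (int i = 0; i < nr; ++i) {
    for (int j = 0; j < nc; ++j) {
      double wsum = 0.0, vsum = 0.0;
      for (int di = -sr; di <= sr; ++di) {
        int ii = i + di;
        if (ii < 0 || ii >= nr) continue;
        for (int dj = -sr; dj <= sr; ++dj) {
          int jj = j + dj;
          if (jj < 0 || jj >= nc) continue;
          // squared patch distance, replicate-padded at borders
          double d2 = 0.0;
          for (int pi = -tr; pi <= tr; ++pi) {
            int a = std::min(std::max(i + pi, 0), nr - 1);
            int b = std::min(std::max(ii + pi, 0), nr - 1);
            for (int pj = -tr; pj <= tr; ++pj) {
              int c = std::min(std::max(j + pj, 0), nc - 1);
              int d = std::min(std::max(jj + pj, 0), nc - 1);
              double diff = img(a, c) - img(b, d);
              d2 += diff * diff;
            }
          }
          d2 /= npatch;
          double w = std::exp(-d2 / h2);
          wsum += w;
          vsum += w * img(ii, jj);
        }
      }
      out(i, j) = vsum / wsum;
    }
  }
  return out;
}

static inline int nb(const LogicalMatrix& m, int i, int j) {
  if (i < 0 || j < 0 || i >= m.nrow() || j >= m.ncol()) return 0;
  return m(i, j) ? 1 : 0;
}

// Zhang-Suen iterative thinning of a binary mask to a 1-px skeleton.
// [[Rcpp::export]]
LogicalMatrix thin_cpp(LogicalMatrix mask) {
  int nr = mask.nrow(), nc = mask.ncol();
  LogicalMatrix m = clone(mask);
  bool changed = true;
  std::vector<std::pair<int, int> > kill;
  while (changed) {
    changed = false;
    for (int pass = 0; pass < 2; ++pass) {
      kill.clear();
      for (int i = 0; i < nr; ++i) {
        for (int j = 0; j < nc; ++j) {
          if (!m(i, j)) continue;
          // neighbours P2..P9 clockwise from north
          int p2 = nb(m, i - 1, j),     p3 = nb(m, i - 1, j + 1);
          int p4 = nb(m, i, j + 1),     p5 = nb(m, i + 1, j + 1);
          int p6 = nb(m, i + 1, j),     p7 = nb(m, i + 1, j - 1);
          int p8 = nb(m, i, j - 1),     p9 = nb(m, i - 1, j - 1);
          int B = p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9;
          if (B < 2 || B > 6) continue;
          int A = (p2 == 0 && p3 == 1) + (p3 == 0 && p4 == 1) +
                  (p4 == 0 && p5 == 1) + (p5 == 0 && p6 == 1) +
                  (p6 == 0 && p7 == 1) + (p7 == 0 && p8 == 1) +
                  (p8 == 0 && p9 == 1) + (p9 == 0 && p2 == 1);
          if (A != 1) continue;
          if (pass == 0) {
            if (p2 * p4 * p6 != 0 || p4 * p6 * p8 != 0) continue;
          } else {
            if (p2 * p4 * p8 != 0 || p2 * p6 * p8 != 0) continue;
          }
          kill.push_back(std::make_pair(i, j));
        }
      }
      for (size_t k = 0; k < kill.size(); ++k)
        m(kill[k].first, kill[k].second) = false;
      if (!kill.empty()) changed = true;
    }
  }
  return m;
}

// Circle Hough transform. edges: binary edge map (rows x cols).
// Votes over centres for each candidate radius; returns the best-voted
// circle with radius in [rmin, rmax] (ties: centre nearest the frame centre).
// Returns c(row, col, radius, votes) or votes = 0 when nothing qualifies.
// [[Rcpp::export]]
NumericVector hough_circle_cpp(LogicalMatrix edges, int rmin, int rmax,
                               int ntheta = 360) {
  int nr = edges.nrow(), nc = edges.ncol();
  std::vector<int> ei, ej;
  for (int i = 0; i < nr; ++i)
    for (int j = 0; j < nc; ++j)
      if (edges(i, j)) { ei.push_back(i); ej.push_back(j); }
  double bestVotes = 0, bestR = 0;
  int bestI = -1, bestJ = -1;
  double bestCdist = 1e18;
  std::vector<double> cs(ntheta), sn(ntheta);
  for (int t = 0; t < ntheta; ++t) {
    double th = 2.0 * M_PI * t / ntheta;
    cs[t] = std::cos(th);
    sn[t] = std::sin(th);
  }
  std::vector<int> acc((size_t)nr * nc);
  for (int r = rmin; r <= rmax; ++r) {
    std::fill(acc.begin(), acc.end(), 0);
    for (size_t k = 0; k < ei.size(); ++k) {
      for (int t = 0; t < ntheta; ++t) {
        int ci = ei[k] + (int)std::lround(r * sn[t]);
        int cj = ej[k] + (int)std::lround(r * cs[t]);
        if (ci >= 0 && ci < nr && cj >= 0 && cj < nc)
          acc[(size_t)ci * nc + cj]++;
      }
    }
    for (int i = 0; i < nr; ++i) {
      for (int j = 0; j < nc; ++j) {
        // normalise votes by circumference so radii compete fairly
        double v = acc[(size_t)i * nc + j] / (double)r;
        double cd = std::hypot(i - (nr - 1) / 2.0, j - (nc - 1) / 2.0);
        if (v > bestVotes + 1e-12 ||
            (std::abs(v - bestVotes) <= 1e-12 && cd < bestCdist)) {
          bestVotes = v;
          bestI = i; bestJ = j; bestR = r; bestCdist = cd;
        }
      }
    }
  }
  return NumericVector::create(bestI + 1.0, bestJ + 1.0, bestR,
                               bestVotes * (bestR > 0 ? bestR : 1.0));
}
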