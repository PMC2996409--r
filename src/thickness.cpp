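#include <Rcpp.h>
#include <vector>
#include <deque>
#include <algorithm>
#include <cmath>
using namespace Rcpp;

// 8-connected component labeling of a binary image.
// Components are numbered by first pixel met in column-major scan order
// (the storage order of R matrices).
// [[Rcpp::export(name = ".cpp_label8")]]
IntegerMatrix cpp_label8(IntegerMatrix mask) {
  const int nx = mask.nrow(), ny = mask.ncol();
  IntegerMatrix lab(nx, ny);
  int next = 0;
  std::deque<std::pair<int, int> > queue;
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      if (mask(i, j) == 0 || lab(i, j) != 0) continue;
      ++next;
      lab(i, j) = next;
      queue.push_back(std::make_pair(i, j));
      while (!queue.empty()) {
        int ci = queue.front().first, cj = queue.front().second;
        queue.pop_front();
        for (int dj = -1; dj <= 1; ++dj) {
          for (int di = -1; di <= 1; ++di) {
            if (di == 0 && dj == 0) continue;
            int qi = ci + di, qj = cj + dj;
            if (qi < 0 || qi >= nx || qj < 0 || qj >= ny) continue;
            if (mask(qi, qj) == 0 || lab(qi, qj) != 0) continue;
            lab(qi, qj) = next;
            queue.push_back(std::make_pair(qi, qj));
          }
        }
      }
    }
  }
  return lab;
}

static const double kEps = 1e-7;

// Redundancy of the inscribed disk at p: it is wholly contained in the disk
// at q whenever |p-q| + d(p) <= d(q).
// A cheap neighbour pass removes most non-ridge pixels (a neighbour that
// dominates p proves containment); survivors get the exact windowed test.
// [[Rcpp::export(name = ".cpp_ridge")]]
LogicalMatrix cpp_ridge(NumericMatrix d) {
  const int nx = d.nrow(), ny = d.ncol();
  LogicalMatrix ridge(nx, ny);
  double dmax = 0.0;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (d(i, j) > dmax) dmax = d(i, j);
  if (dmax <= 0.0) return ridge;

  const double sqrt2 = std::sqrt(2.0);
  for (int j = 0; j < ny; ++j) {
    for (int i = 0; i < nx; ++i) {
      const double dp = d(i, j);
      if (dp <= 0.0) continue;
      // neighbour domination
      bool redundant = false;
      for (int dj = -1; dj <= 1 && !redundant; ++dj) {
        for (int di = -1; di <= 1 && !redundant; ++di) {
          if (di == 0 && dj == 0) continue;
          int qi = i + di, qj = j + dj;
          if (qi < 0 || qi >= nx || qj < 0 || qj >= ny) continue;
          double step = (di != 0 && dj != 0) ? sqrt2 : 1.0;
          if (step + dp <= d(qi, qj) + kEps) redundant = true;
        }
      }
      if (redundant) continue;
      // exact windowed test: a dominating q must satisfy d(q) >= d(p)+|p-q|,
      // hence |p-q| <= dmax - d(p)
      int w = (int)std::ceil(dmax - dp + kEps);
      for (int dj = -w; dj <= w && !redundant; ++dj) {
        int qj = j + dj;
        if (qj < 0 || qj >= ny) continue;
        for (int di = -w; di <= w && !redundant; ++di) {
          if (di == 0 && dj == 0) continue;
          int qi = i + di;
          if (qi < 0 || qi >= nx) continue;
          const double dq = d(qi, qj);
          if (dq <= dp) continue;
          double dist = std::sqrt((double)(di * di + dj * dj));
          if (dist + dp <= dq + kEps) redundant = true;
        }
      }
      if (!redundant) ridge(i, j) = true;
    }
  }
  return ridge;
}

// Local thickness: tau(p) = 2 * max{ d(x) : |p - x| < d(x) }.
// Disks contained in a larger disk contribute nothing to the maximum, so the
// propagation runs over the ridge disks only.
// [[Rcpp::export(name = ".cpp_thickness")]]
NumericMatrix cpp_thickness(NumericMatrix d) {
  const int nx = d.nrow(), ny = d.ncol();
  NumericMatrix tau(nx, ny);
  LogicalMatrix ridge = cpp_ridge(d);

  struct Disk { int i, j; double r; };
  std::vector<Disk> disks;
  for (int j = 0; j < ny; ++j)
    for (int i = 0; i < nx; ++i)
      if (ridge(i, j)) disks.push_back(Disk{i, j, d(i, j)});
  std::sort(disks.begin(), disks.end(),
            [](const Disk &a, const Disk &b) { return a.r > b.r; });

  for (const Disk &dk : disks) {
    const double two_r = 2.0 * dk.r;
    // pixel p belongs to the disk iff |p-x|^2 < r^2; squared pixel-centre
    // distances are integers, r^2 recovers one up to fp error
    const long long rr = (long long)std::llround(dk.r * dk.r);
    const int w = (int)std::ceil(dk.r);
    for (int dj = -w; dj <= w; ++dj) {
      int qj = dk.j + dj;
      if (qj < 0 || qj >= ny) continue;
      for (int di = -w; di <= w; ++di) {
        int qi = dk.i + di;
        if (qi < 0 || qi >= nx) continue;
        long long dist2 = (long long)di * di + (long long)dj * dj;
        if (dist2 < rr && tau(qi, qj) < two_r) tau(qi, qj) = two_r;
      }
    }
  }
  return tau;
}
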