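// Texture-matrix kernels for 3D regions.
//
// All functions take a discretized volume `disc` (integer gray levels
// 1..ng inside the region, 0 outside) with dimensions `dims`, and return
// raw count matrices; feature algebra lives in R where it is testable
// against hand-built matrices.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NDIR = 13;
static const int DIRS[NDIR][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

static inline int idx3(int x, int y, int z, const int* d) {
  return x + d[0] * (y + d[1] * z);
}

// Gray-level co-occurrence matrix, 13 symmetric directions merged.
// [[Rcpp::export]]
NumericMatrix cpp_glcm(IntegerVector disc, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  NumericMatrix m(ng, ng);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int g = disc[idx3(x, y, z, d)];
        if (g <= 0) continue;
        for (int k = 0; k < NDIR; ++k) {
          int xx = x + DIRS[k][0], yy = y + DIRS[k][1], zz = z + DIRS[k][2];
          if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] ||
              zz >= d[2]) continue;
          int g2 = disc[idx3(xx, yy, zz, d)];
          if (g2 <= 0) continue;
          m(g - 1, g2 - 1) += 1.0;
          m(g2 - 1, g - 1) += 1.0;   // symmetric
        }
      }
  return m;
}

// Gray-level run-length matrix, 13 directions merged.
// [[Rcpp::export]]
NumericMatrix cpp_glrlm(IntegerVector disc, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int maxdim = std::max(d[0], std::max(d[1], d[2]));
  NumericMatrix m(ng, maxdim);
  for (int k = 0; k < NDIR; ++k) {
    int dx = DIRS[k][0], dy = DIRS[k][1], dz = DIRS[k][2];
    for (int z = 0; z < d[2]; ++z)
      for (int y = 0; y < d[1]; ++y)
        for (int x = 0; x < d[0]; ++x) {
          int g = disc[idx3(x, y, z, d)];
          if (g <= 0) continue;
          // start of a run only if the previous voxel along dir differs
          int px = x - dx, py = y - dy, pz = z - dz;
          if (px >= 0 && py >= 0 && pz >= 0 && px < d[0] && py < d[1] &&
              pz < d[2] && disc[idx3(px, py, pz, d)] == g) continue;
          int len = 1;
          int xx = x + dx, yy = y + dy, zz = z + dz;
          while (xx >= 0 && yy >= 0 && zz >= 0 && xx < d[0] && yy < d[1] &&
                 zz < d[2] && disc[idx3(xx, yy, zz, d)] == g) {
            ++len; xx += dx; yy += dy; zz += dz;
          }
          m(g - 1, len - 1) += 1.0;
        }
  }
  return m;
}

// Gray-level size-zone matrix (26-connected zones). Column j = zone size j+1.
// [[Rcpp::export]]
NumericMatrix cpp_glszm(IntegerVector disc, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  int n = d[0] * d[1] * d[2];
  std::vector<char> seen(n, 0);
  std::vector<std::pair<int, int> > zones;  // (gray, size)
  std::vector<int> stack;
  int maxzone = 1;
  for (int start = 0; start < n; ++start) {
    if (seen[start] || disc[start] <= 0) continue;
    int g = disc[start];
    int size = 0;
    stack.clear();
    stack.push_back(start);
    seen[start] = 1;
    while (!stack.empty()) {
      int cur = stack.back(); stack.pop_back();
      ++size;
      int cz = cur / (d[0] * d[1]);
      int cy = (cur / d[0]) % d[1];
      int cx = cur % d[0];
      for (int dz = -1; dz <= 1; ++dz)
        for (int dy = -1; dy <= 1; ++dy)
          for (int dx = -1; dx <= 1; ++dx) {
            if (!dx && !dy && !dz) continue;
            int xx = cx + dx, yy = cy + dy, zz = cz + dz;
            if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] ||
                zz >= d[2]) continue;
            int j = idx3(xx, yy, zz, d);
            if (!seen[j] && disc[j] == g) { seen[j] = 1; stack.push_back(j); }
          }
    }
    zones.push_back(std::make_pair(g, size));
    if (size > maxzone) maxzone = size;
  }
  NumericMatrix m(ng, maxzone);
  for (size_t i = 0; i < zones.size(); ++i)
    m(zones[i].first - 1, zones[i].second - 1) += 1.0;
  return m;
}

// Gray-level dependence matrix: dependence = count of 26-neighbours in the
// region with |g - g'| <= alpha. Column j = dependence j (0-based size j+1).
// [[Rcpp::export]]
NumericMatrix cpp_gldm(IntegerVector disc, IntegerVector dims, int ng,
                       int alpha) {
  int d[3] = {dims[0], dims[1], dims[2]};
  NumericMatrix m(ng, 27);  // dependence in 0..26
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int g = disc[idx3(x, y, z, d)];
        if (g <= 0) continue;
        int dep = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] ||
                  zz >= d[2]) continue;
              int g2 = disc[idx3(xx, yy, zz, d)];
              if (g2 > 0 && std::abs(g2 - g) <= alpha) ++dep;
            }
        m(g - 1, dep) += 1.0;
      }
  return m;
}

// Neighbourhood gray-tone difference matrix: per level, voxel count n_i and
// summed absolute difference s_i from the mean of in-region 26-neighbours.
// [[Rcpp::export]]
List cpp_ngtdm(IntegerVector disc, IntegerVector dims, int ng) {
  int d[3] = {dims[0], dims[1], dims[2]};
  NumericVector s(ng), n(ng);
  for (int z = 0; z < d[2]; ++z)
    for (int y = 0; y < d[1]; ++y)
      for (int x = 0; x < d[0]; ++x) {
        int g = disc[idx3(x, y, z, d)];
        if (g <= 0) continue;
        double sum = 0.0; int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              if (!dx && !dy && !dz) continue;
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= d[0] || yy >= d[1] ||
                  zz >= d[2]) continue;
              int g2 = disc[idx3(xx, yy, zz, d)];
              if (g2 > 0) { sum += g2; ++cnt; }
            }
        n[g - 1] += 1.0;
        if (cnt > 0) s[g - 1] += std::fabs(g - sum / cnt);
      }
  return List::create(Named("s") = s, Named("n") = n);
}

// Maximum pairwise distance among points (rows of an n x 3 mm-coordinate
// matrix). Used for the maximum 3D diameter shape feature.
// [[Rcpp::export]]
double cpp_max_pairwise_dist(NumericMatrix pts) {
  double best = 0.0;
  int n = pts.nrow();
  for (int i = 0; i < n; ++i)
    for (int j = i + 1; j < n; ++j) {
      double dx = pts(i, 0) - pts(j, 0);
      double dy = pts(i, 1) - pts(j, 1);
      double dz = pts(i, 2) - pts(j, 2);
      double d2 = dx * dx + dy * dy + dz * dz;
      if (d2 > best) best = d2;
    }
  return std::sqrt(best);
}
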