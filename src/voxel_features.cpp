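// Sliding-window voxel descriptors for habitat clustering.
//
// For each in-mask voxel, the 3x3x3 neighbourhood restricted to the mask
// yields 13 local descriptors: 9 first-order (mean, variance, skewness,
// kurtosis, min, max, range, energy, 8-bin Shannon entropy) and 4 GLCM
// descriptors (contrast, homogeneity, correlation, energy) with 13
// symmetric directions. Histogram/GLCM gray levels are discretized over
// the global in-mask intensity range [gmin, gmax] (8 equal bins), not the
// window range: per-window normalisation makes the texture descriptors a
// pure sampling-noise continuum, while global binning keeps them stable
// and signal-level-sensitive. Voxels with fewer than `min_neighbors`
// in-mask neighbours are excluded.

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static const int NDIR13[13][3] = {
  {1, 0, 0}, {0, 1, 0}, {0, 0, 1},
  {1, 1, 0}, {1, -1, 0}, {1, 0, 1}, {1, 0, -1},
  {0, 1, 1}, {0, 1, -1},
  {1, 1, 1}, {1, 1, -1}, {1, -1, 1}, {1, -1, -1}
};

// [[Rcpp::export]]
List cpp_voxel_features(NumericVector vol, IntegerVector mask,
                        IntegerVector dims, int min_neighbors,
                        double gmin, double gmax) {
  int d0 = dims[0], d1 = dims[1], d2 = dims[2];
  int n = d0 * d1 * d2;
  const int NG = 8;

  std::vector<int> keep_idx;
  std::vector<double> feats;
  keep_idx.reserve(n / 4);

  std::vector<double> w(27);
  std::vector<int> wx(27), wy(27), wz(27);

  for (int z = 0; z < d2; ++z)
    for (int y = 0; y < d1; ++y)
      for (int x = 0; x < d0; ++x) {
        int c = x + d0 * (y + d1 * z);
        if (!mask[c]) continue;
        int cnt = 0;
        for (int dz = -1; dz <= 1; ++dz)
          for (int dy = -1; dy <= 1; ++dy)
            for (int dx = -1; dx <= 1; ++dx) {
              int xx = x + dx, yy = y + dy, zz = z + dz;
              if (xx < 0 || yy < 0 || zz < 0 || xx >= d0 || yy >= d1 ||
                  zz >= d2) continue;
              int j = xx + d0 * (yy + d1 * zz);
              if (!mask[j]) continue;
              w[cnt] = vol[j]; wx[cnt] = dx; wy[cnt] = dy; wz[cnt] = dz;
              ++cnt;
            }
        if (cnt - 1 < min_neighbors) continue;  // center always in-mask

        // first-order descriptors
        double s = 0, mn = w[0], mx = w[0], en = 0;
        for (int i = 0; i < cnt; ++i) {
          s += w[i]; en += w[i] * w[i];
          if (w[i] < mn) mn = w[i];
          if (w[i] > mx) mx = w[i];
        }
        double mu = s / cnt;
        double m2 = 0, m3 = 0, m4 = 0;
        for (int i = 0; i < cnt; ++i) {
          double dlt = w[i] - mu;
          m2 += dlt * dlt; m3 += dlt * dlt * dlt; m4 += dlt * dlt * dlt * dlt;
        }
        m2 /= cnt; m3 /= cnt; m4 /= cnt;
        double sdv = std::sqrt(m2);
        double skew = (sdv > 0) ? m3 / (sdv * sdv * sdv) : 0.0;
        double kurt = (m2 > 0) ? m4 / (m2 * m2) : 0.0;

        // discretize window values over the global in-mask range
        int lvl[27];
        double gr = gmax - gmin;
        for (int i = 0; i < cnt; ++i) {
          int b = (gr > 0) ? (int)((w[i] - gmin) / (gr / NG)) : 0;
          if (b >= NG) b = NG - 1;
          if (b < 0) b = 0;
          lvl[i] = b;
        }

        // 8-bin entropy over the global bins
        double ent = 0.0;
        {
          int hist[NG] = {0};
          for (int i = 0; i < cnt; ++i) ++hist[lvl[i]];
          for (int b = 0; b < NG; ++b)
            if (hist[b]) {
              double p = (double)hist[b] / cnt;
              ent -= p * std::log2(p);
            }
        }

        // window GLCM at the global 8 levels, 13 symmetric directions
        double P[NG][NG] = {{0}};
        double tot = 0.0;
        for (int i = 0; i < cnt; ++i)
          for (int k = 0; k < 13; ++k) {
            int tx = wx[i] + NDIR13[k][0], ty = wy[i] + NDIR13[k][1],
                tz = wz[i] + NDIR13[k][2];
            if (tx < -1 || tx > 1 || ty < -1 || ty > 1 || tz < -1 || tz > 1)
              continue;
            for (int j = 0; j < cnt; ++j)
              if (wx[j] == tx && wy[j] == ty && wz[j] == tz) {
                P[lvl[i]][lvl[j]] += 1.0;
                P[lvl[j]][lvl[i]] += 1.0;
                tot += 2.0;
                break;
              }
          }
        double contrast = 0, homog = 0, genergy = 0, corr = 0;
        if (tot > 0) {
          double mui = 0, mj = 0;
          for (int i = 0; i < NG; ++i)
            for (int j = 0; j < NG; ++j) {
              double p = P[i][j] / tot;
              contrast += p * (i - j) * (i - j);
              homog += p / (1.0 + std::fabs((double)(i - j)));
              genergy += p * p;
              mui += i * p; mj += j * p;
            }
          double vi = 0, vj = 0, cv = 0;
          for (int i = 0; i < NG; ++i)
            for (int j = 0; j < NG; ++j) {
              double p = P[i][j] / tot;
              vi += (i - mui) * (i - mui) * p;
              vj += (j - mj) * (j - mj) * p;
              cv += (i - mui) * (j - mj) * p;
            }
          corr = (vi > 0 && vj > 0) ? cv / std::sqrt(vi * vj) : 1.0;
        } else {
          homog = 1.0; genergy = 1.0; corr = 1.0;
        }

        keep_idx.push_back(c + 1);  // 1-based for R
        double row[13] = {mu, m2, skew, kurt, mn, mx, mx - mn, en, ent,
                          contrast, homog, corr, genergy};
        feats.insert(feats.end(), row, row + 13);
      }

  int nk = (int)keep_idx.size();
  NumericMatrix fm(nk, 13);
  for (int r = 0; r < nk; ++r)
    for (int cix = 0; cix < 13; ++cix)
      fm(r, cix) = feats[r * 13 + cix];
  return List::create(Named("index") = wrap(keep_idx),
                      Named("features") = fm);
}
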