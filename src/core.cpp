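#include <Rcpp.h>
using namespace Rcpp;

// Union-find with path compression for connected-component labelling.
static int uf_find(std::vector<int> &parent, int i) {
  while (parent[i] != i) {
    parent[i] = parent[parent[i]];
    i = parent[i];
  }
  return i;
}

static void uf_union(std::vector<int> &parent, int a, int b) {
  int ra = uf_find(parent, a), rb = uf_find(parent, b);
  if (ra != rb) parent[rb] = ra;
}

// Threshold-free cluster enhancement of a nonnegative 3D map.
// For each voxel v the enhanced value is sum_h e(h)^E * h^H * dh over
// thresholds h = dh, 2*dh, ..., where e(h) is the size of the connected
// component (6-neighbourhood) supporting v at threshold h. Voxels outside
// the mask are ignored and returned as 0.
// [[Rcpp::export]]
NumericVector tfce_cpp(NumericVector map, IntegerVector dims,
                       LogicalVector mask, double E, double H, double dh) {
  const int nx = dims[0], ny = dims[1], nz = dims[2];
  const int n = nx * ny * nz;
  NumericVector out(n);
  double mx = 0.0;
  for (int i = 0; i < n; ++i)
    if (mask[i] && map[i] > mx) mx = map[i];
  if (mx <= 0.0 || dh <= 0.0) return out;

  std::vector<int> parent(n);
  std::vector<int> csize(n);

  for (double h = dh; h <= mx; h += dh) {
    for (int i = 0; i < n; ++i) parent[i] = i;
    // union suprathreshold neighbours along +x, +y, +z
    for (int z = 0; z < nz; ++z)
      for (int y = 0; y < ny; ++y)
        for (int x = 0; x < nx; ++x) {
          int i = x + nx * (y + ny * z);
          if (!mask[i] || map[i] < h) continue;
          if (x + 1 < nx) {
            int j = i + 1;
            if (mask[j] && map[j] >= h) uf_union(parent, i, j);
          }
          if (y + 1 < ny) {
            int j = i + nx;
            if (mask[j] && map[j] >= h) uf_union(parent, i, j);
          }
          if (z + 1 < nz) {
            int j = i + nx * ny;
            if (mask[j] && map[j] >= h) uf_union(parent, i, j);
          }
        }
    std::fill(csize.begin(), csize.end(), 0);
    for (int i = 0; i < n; ++i)
      if (mask[i] && map[i] >= h) csize[uf_find(parent, i)]++;
    const double hH = std::pow(h, H);
    for (int i = 0; i < n; ++i)
      if (mask[i] && map[i] >= h)
        out[i] += std::pow((double)csize[uf_find(parent, i)], E) * hH * dh;
  }
  return out;
}

static double entropy_bits(const std::vector<int> &counts, int total) {
  double hsum = 0.0;
  const double invlog2 = 1.0 / std::log(2.0);
  for (size_t k = 0; k < counts.size(); ++k) {
    if (counts[k] > 0) {
      double p = (double)counts[k] / total;
      hsum -= p * std::log(p) * invlog2;
    }
  }
  return hsum;
}

// Phase transfer entropy between two discretised (0-based) symbol series in
// both directions at lag `lag`:
//   TE(x->y) = H(y_t, y_t') + H(y_t', x_t') - H(y_t') - H(y_t, y_t', x_t')
// with t' = t - lag, plug-in probabilities, log base 2.
// [[Rcpp::export]]
NumericVector te_pair_cpp(IntegerVector x, IntegerVector y, int lag, int nbins) {
  const int n = x.size();
  const int m = n - lag; // number of aligned (t, t') pairs
  const int nb = nbins, nb2 = nbins * nbins, nb3 = nb2 * nbins;
  std::vector<int> c_yp(nb, 0), c_xp(nb, 0);
  std::vector<int> c_ytyp(nb2, 0), c_ypxp(nb2, 0), c_xtxp(nb2, 0), c_xpyp(nb2, 0);
  std::vector<int> c_ytypxp(nb3, 0), c_xtxpyp(nb3, 0);

  for (int t = lag; t < n; ++t) {
    int yt = y[t], yp = y[t - lag], xt = x[t], xp = x[t - lag];
    c_yp[yp]++;
    c_xp[xp]++;
    c_ytyp[yt * nb + yp]++;
    c_ypxp[yp * nb + xp]++;
    c_xtxp[xt * nb + xp]++;
    c_xpyp[xp * nb + yp]++;
    c_ytypxp[(yt * nb + yp) * nb + xp]++;
    c_xtxpyp[(xt * nb + xp) * nb + yp]++;
  }
  double te_xy = entropy_bits(c_ytyp, m) + entropy_bits(c_ypxp, m)
               - entropy_bits(c_yp, m) - entropy_bits(c_ytypxp, m);
  double te_yx = entropy_bits(c_xtxp, m) + entropy_bits(c_xpyp, m)
               - entropy_bits(c_xp, m) - entropy_bits(c_xtxpyp, m);
  return NumericVector::create(te_xy, te_yx);
}
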