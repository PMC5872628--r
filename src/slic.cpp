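#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// SLIC superpixel clustering on a CIELAB raster.
//
// lab: (H*W) x 3 matrix in column-major pixel order (idx = col*H + row),
//      channels in native CIELAB scale (L in 0..100).
// Returns 0-based labels as an H x W integer matrix with contiguous labels
// and connectivity enforced (orphan fragments merged into an adjacent
// superpixel).

static inline int pix(int r, int c, int H) { return c * H + r; }

// [[Rcpp::export(name = ".slic_cpp")]]
IntegerMatrix slic_cpp(NumericMatrix lab, int H, int W, int n_target,
                       double compactness, int max_iter) {
  const int N = H * W;
  double step = std::sqrt((double)N / (double)n_target);
  if (step < 1.0) step = 1.0;

  // --- seed cluster centers on a regular grid ---
  std::vector<double> cr, cc, cL, cA, cB;
  for (double r = step / 2.0; r < H; r += step) {
    for (double c = step / 2.0; c < W; c += step) {
      int ri = (int)r, ci = (int)c;
      // perturb seed to the lowest-gradient position in its 3x3 neighborhood
      int br = ri, bc = ci;
      double bg = R_PosInf;
      for (int dr = -1; dr <= 1; ++dr) {
        for (int dc = -1; dc <= 1; ++dc) {
          int rr = ri + dr, cc2 = ci + dc;
          if (rr < 1 || rr >= H - 1 || cc2 < 1 || cc2 >= W - 1) continue;
          double gx = lab(pix(rr, cc2 + 1, H), 0) - lab(pix(rr, cc2 - 1, H), 0);
          double gy = lab(pix(rr + 1, cc2, H), 0) - lab(pix(rr - 1, cc2, H), 0);
          double g = gx * gx + gy * gy;
          if (g < bg) { bg = g; br = rr; bc = cc2; }
        }
      }
      cr.push_back(br); cc.push_back(bc);
      int p = pix(br, bc, H);
      cL.push_back(lab(p, 0)); cA.push_back(lab(p, 1)); cB.push_back(lab(p, 2));
    }
  }
  int K = (int)cr.size();
  std::vector<int> label(N, -1);
  std::vector<double> dist(N);
  double invS2 = 1.0 / (step * step);
  double m2 = compactness * compactness;

  for (int iter = 0; iter < max_iter; ++iter) {
    std::fill(dist.begin(), dist.end(), R_PosInf);
    for (int k = 0; k < K; ++k) {
      int r0 = std::max(0, (int)(cr[k] - 2 * step));
      int r1 = std::min(H - 1, (int)(cr[k] + 2 * step));
      int c0 = std::max(0, (int)(cc[k] - 2 * step));
      int c1 = std::min(W - 1, (int)(cc[k] + 2 * step));
      for (int c = c0; c <= c1; ++c) {
        for (int r = r0; r <= r1; ++r) {
          int p = pix(r, c, H);
          double dL = lab(p, 0) - cL[k], dA = lab(p, 1) - cA[k],
                 dB = lab(p, 2) - cB[k];
          double dc2 = dL * dL + dA * dA + dB * dB;
          double dr = r - cr[k], dcc = c - cc[k];
          double ds2 = dr * dr + dcc * dcc;
          double D = dc2 + ds2 * invS2 * m2;
          if (D < dist[p]) { dist[p] = D; label[p] = k; }
        }
      }
    }
    // update centers
    std::vector<double> sr(K, 0), sc(K, 0), sL(K, 0), sA(K, 0), sB(K, 0);
    std::vector<int> cnt(K, 0);
    for (int c = 0; c < W; ++c) {
      for (int r = 0; r < H; ++r) {
        int p = pix(r, c, H);
        int k = label[p];
        if (k < 0) continue;
        sr[k] += r; sc[k] += c;
        sL[k] += lab(p, 0); sA[k] += lab(p, 1); sB[k] += lab(p, 2);
        cnt[k]++;
      }
    }
    for (int k = 0; k < K; ++k) {
      if (cnt[k] == 0) continue;
      cr[k] = sr[k] / cnt[k]; cc[k] = sc[k] / cnt[k];
      cL[k] = sL[k] / cnt[k]; cA[k] = sA[k] / cnt[k]; cB[k] = sB[k] / cnt[k];
    }
  }

  // --- enforce connectivity: flood-fill new labels, absorb small orphans ---
  std::vector<int> newlab(N, -1);
  int min_size = std::max(1, (int)(N / (double)K / 4.0));
  int nlab = 0;
  std::vector<int> stack, comp;
  const int dr4[4] = {-1, 1, 0, 0}, dc4[4] = {0, 0, -1, 1};
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      int p0 = pix(r, c, H);
      if (newlab[p0] >= 0) continue;
      int adj = -1;  // an already-labelled neighbor component, for absorption
      comp.clear(); stack.clear();
      stack.push_back(p0); newlab[p0] = nlab; comp.push_back(p0);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int t = 0; t < 4; ++t) {
          int rr = pr + dr4[t], cc2 = pc + dc4[t];
          if (rr < 0 || rr >= H || cc2 < 0 || cc2 >= W) continue;
          int q = pix(rr, cc2, H);
          if (newlab[q] < 0 && label[q] == label[p0]) {
            newlab[q] = nlab; stack.push_back(q); comp.push_back(q);
          } else if (newlab[q] >= 0 && newlab[q] != nlab) {
            adj = newlab[q];
          }
        }
      }
      if ((int)comp.size() < min_size && adj >= 0) {
        for (int p : comp) newlab[p] = adj;
      } else {
        nlab++;
      }
    }
  }
  // compact labels to 0..n-1 (absorption can leave gaps)
  std::vector<int> remap(nlab, -1);
  int nfinal = 0;
  for (int p = 0; p < N; ++p)
    if (remap[newlab[p]] < 0) remap[newlab[p]] = nfinal++;
  IntegerMatrix out(H, W);
  for (int c = 0; c < W; ++c)
    for (int r = 0; r < H; ++r)
      out(r, c) = remap[newlab[pix(r, c, H)]];
  return out;
}

// Connected-component labeling of a binary mask under 4- or 8-connectivity.
// Returns H x W integer labels: 0 = background, components numbered 1..n
// in first-encounter (column-major) order.

// [[Rcpp::export(name = ".label_components_cpp")]]
IntegerMatrix label_components_cpp(IntegerMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);  // zero-initialized
  const int dr8[8] = {-1, 1, 0, 0, -1, -1, 1, 1};
  const int dc8[8] = {0, 0, -1, 1, -1, 1, -1, 1};
  int nn = (connectivity == 8) ? 8 : 4;
  int cur = 0;
  std::vector<int> stack;
  for (int c = 0; c < W; ++c) {
    for (int r = 0; r < H; ++r) {
      if (mask(r, c) == 0 || lab(r, c) != 0) continue;
      cur++;
      lab(r, c) = cur;
      stack.clear();
      stack.push_back(c * H + r);
      while (!stack.empty()) {
        int p = stack.back(); stack.pop_back();
        int pr = p % H, pc = p / H;
        for (int t = 0; t < nn; ++t) {
          int rr = pr + dr8[t], cc = pc + dc8[t];
          if (rr < 0 || rr >= H || cc < 0 || cc >= W) continue;
          if (mask(rr, cc) != 0 && lab(rr, cc) == 0) {
            lab(rr, cc) = cur;
            stack.push_back(cc * H + rr);
          }
        }
      }
    }
  }
  return lab;
}
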