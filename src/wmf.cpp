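#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

// Accelerated guided weighted median filter.
//
// Per output row a joint histogram H(intensity bin, feature bin) of the
// sliding window is maintained, together with a balance counting box
// B(f) = #{I <= cut, feature f} - #{I > cut, feature f} and the cut point
// itself, so the weighted median is found by moving the cut a few bins
// instead of rescanning the window.  A necklace table (circular doubly
// linked ring with a sentinel) over the occupied feature bins lets every
// balance evaluation skip empty bins.
//
// The affinity weights in `gtab` are dyadic rationals (multiples of 2^-30,
// prepared on the R side).  Window sums then stay below 2^53 units, so all
// balance arithmetic here is exact and order-independent; the backend is
// pixel-identical to the naive reference, not merely close.

namespace {

struct Necklace {
  std::vector<int> nxt, prv;
  std::vector<char> in;
  int sent; // sentinel index
  explicit Necklace(int nbins) : nxt(nbins + 1), prv(nbins + 1),
                                 in(nbins, 0), sent(nbins) {
    nxt[sent] = sent;
    prv[sent] = sent;
  }
  void insert(int f) {
    int h = nxt[sent];
    nxt[sent] = f; prv[f] = sent;
    nxt[f] = h;    prv[h] = f;
    in[f] = 1;
  }
  void remove(int f) {
    nxt[prv[f]] = nxt[f];
    prv[nxt[f]] = prv[f];
    in[f] = 0;
  }
};

} // namespace

// [[Rcpp::export(name = ".guided_wmf_accel_cpp")]]
NumericMatrix guided_wmf_accel_cpp(NumericMatrix img, IntegerMatrix ibin,
                                   IntegerMatrix fbin, int radius,
                                   int ni, int nf, NumericVector gtab) {
  const int h = img.nrow(), w = img.ncol();
  NumericMatrix out(h, w);

  std::vector<int> H((size_t)ni * nf, 0); // H[i + ni*f]
  std::vector<int> B(nf, 0), cntF(nf, 0);
  const double *gt = gtab.begin();

  for (int row = 0; row < h; ++row) {
    const int r0 = std::max(0, row - radius);
    const int r1 = std::min(h - 1, row + radius);

    std::fill(H.begin(), H.end(), 0);
    std::fill(B.begin(), B.end(), 0);
    std::fill(cntF.begin(), cntF.end(), 0);
    Necklace ring(nf);
    int cut = 0; // restart the cut at each row start

    // window columns for output column j are max(0,j-r) .. min(w-1,j+r)
    auto add_col = [&](int cc) {
      for (int rr = r0; rr <= r1; ++rr) {
        const int ib = ibin(rr, cc), fb = fbin(rr, cc);
        ++H[ib + (size_t)ni * fb];
        if (++cntF[fb] == 1) ring.insert(fb);
        B[fb] += (ib <= cut) ? 1 : -1;
      }
    };
    auto rm_col = [&](int cc) {
      for (int rr = r0; rr <= r1; ++rr) {
        const int ib = ibin(rr, cc), fb = fbin(rr, cc);
        --H[ib + (size_t)ni * fb];
        B[fb] -= (ib <= cut) ? 1 : -1;
        if (--cntF[fb] == 0) ring.remove(fb);
      }
    };

    for (int cc = 0; cc <= std::min(radius, w - 1); ++cc) add_col(cc);

    for (int col = 0; col < w; ++col) {
      if (col > 0) {
        if (col + radius <= w - 1) add_col(col + radius);
        if (col - radius - 1 >= 0) rm_col(col - radius - 1);
      }
      const int fp = fbin(row, col);

      // balance at the propagated cut, visiting occupied feature bins only
      double b = 0.0;
      for (int f = ring.nxt[ring.sent]; f != ring.sent; f = ring.nxt[f])
        b += B[f] * gt[std::abs(f - fp)];

      // smallest cut with b >= 0
      while (b < 0.0 && cut < ni - 1) {
        ++cut;
        for (int f = ring.nxt[ring.sent]; f != ring.sent; f = ring.nxt[f]) {
          const int hc = H[cut + (size_t)ni * f];
          if (hc) {
            B[f] += 2 * hc;
            b += 2.0 * hc * gt[std::abs(f - fp)];
          }
        }
      }
      while (cut > 0) {
        double wc = 0.0;
        for (int f = ring.nxt[ring.sent]; f != ring.sent; f = ring.nxt[f]) {
          const int hc = H[cut + (size_t)ni * f];
          if (hc) wc += hc * gt[std::abs(f - fp)];
        }
        if (b - 2.0 * wc >= 0.0) {
          for (int f = ring.nxt[ring.sent]; f != ring.sent; f = ring.nxt[f]) {
            const int hc = H[cut + (size_t)ni * f];
            if (hc) B[f] -= 2 * hc;
          }
          b -= 2.0 * wc;
          --cut;
        } else break;
      }

      // representative value: lower median of the window's original values
      // falling in the median bin (selection property: output is a window
      // value; lossless when ni = 256 on 8-bit data)
      const int c0 = std::max(0, col - radius);
      const int c1 = std::min(w - 1, col + radius);
      std::vector<double> sel;
      sel.reserve((size_t)(2 * radius + 1));
      for (int cc2 = c0; cc2 <= c1; ++cc2)
        for (int rr = r0; rr <= r1; ++rr)
          if (ibin(rr, cc2) == cut) sel.push_back(img(rr, cc2));
      const size_t m = sel.size();
      std::nth_element(sel.begin(), sel.begin() + (m - 1) / 2, sel.end());
      out(row, col) = sel[(m - 1) / 2];
    }
  }
  return out;
}
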