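// FFT-based translational scan used by the 2D alignment search.
//
// The R layer prepares rotated/mirrored variants of the query image,
// masked, zero-mean and unit-norm inside a centered circular mask. For a
// stack image I and variant q the masked normalized cross-correlation at
// integer shift s is
//
//   cc(s) = sum_x q(x) I(x + s) / sigma_I(s),
//
// where sigma_I(s)^2 = sum_mask I^2 - (sum_mask I)^2 / npix over the mask
// translated by s. Because q is zero-mean under the mask, this is the
// exact zero-mean unit-norm correlation computed within the mask for every
// shift, so an integer translate of the reference scores exactly 1.
//
// Window sums and correlations are circular FFT products; the shift range
// is restricted to |dx|, |dy| <= max_shift, well below wrap-around. The
// transforms use a small hand-rolled power-of-two FFT with precomputed
// twiddles. Two speedups matter at library scale: correlation maps of real
// images are real, so two variants are packed into one complex inverse
// transform (real and imaginary parts); and only the mask-admissible
// columns of the correlation map are fully inverse-transformed.

#include <RcppArmadillo.h>
#include <complex>
#include <vector>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;
typedef std::complex<double> cxd;

namespace {

// iterative radix-2 FFT for power-of-two lengths
class Pow2FFT {
 public:
  explicit Pow2FFT(int n) : n_(n), scratch_(n) {
    rev_.resize(n_);
    int lg = 0;
    while ((1 << lg) < n_) ++lg;
    for (int i = 0; i < n_; ++i) {
      int r = 0;
      for (int b = 0; b < lg; ++b) {
        if (i & (1 << b)) r |= 1 << (lg - 1 - b);
      }
      rev_[i] = r;
    }
    twf_.resize(n_ / 2);
    twi_.resize(n_ / 2);
    for (int j = 0; j < n_ / 2; ++j) {
      const double a = -2.0 * M_PI * j / n_;
      twf_[j] = cxd(std::cos(a), std::sin(a));
      twi_[j] = std::conj(twf_[j]);
    }
  }

  // in-place transform of x[0], x[stride], ..., x[(n-1)*stride]
  void transform(cxd* x, int stride, bool inverse) const {
    const cxd* tw = inverse ? twi_.data() : twf_.data();
    cxd* s = scratch_.data();
    for (int i = 0; i < n_; ++i) s[i] = x[rev_[i] * stride];
    for (int len = 2; len <= n_; len <<= 1) {
      const int half = len >> 1;
      const int step = n_ / len;
      for (int i = 0; i < n_; i += len) {
        for (int j = 0; j < half; ++j) {
          const cxd u = s[i + j];
          const cxd v = s[i + j + half] * tw[j * step];
          s[i + j] = u + v;
          s[i + j + half] = u - v;
        }
      }
    }
    if (inverse) {
      const double sc = 1.0 / n_;
      for (int i = 0; i < n_; ++i) x[i * stride] = s[i] * sc;
    } else {
      for (int i = 0; i < n_; ++i) x[i * stride] = s[i];
    }
  }

  // full forward 2D transform of an n x n column-major buffer
  void fft2(cxd* buf) const {
    for (int c = 0; c < n_; ++c) transform(buf + c * n_, 1, false);
    for (int r = 0; r < n_; ++r) transform(buf + r, n_, false);
  }

  // inverse 2D transform, completed only for the given rows: all columns
  // are transformed first (stride 1, cache-friendly), then just the
  // selected rows across columns
  void ifft2_rows(cxd* buf, const std::vector<int>& rows) const {
    for (int c = 0; c < n_; ++c) transform(buf + c * n_, 1, true);
    for (size_t k = 0; k < rows.size(); ++k) {
      transform(buf + rows[k], n_, true);
    }
  }

 private:
  int n_;
  std::vector<int> rev_;
  std::vector<cxd> twf_, twi_;
  mutable std::vector<cxd> scratch_;
};

}  // namespace

// variants: n x n x V (masked/normalized query variants)
// stack:    n x n x M raw images
// mask:     n x n 0/1 matrix
// returns:  M x 4 matrix (cc, variant index 1-based, dx, dy); cc = NaN for
//           images with zero variance inside the centered mask
// [[Rcpp::export(name = ".align_scan_cpp")]]
arma::mat align_scan_cpp(const arma::cube& variants, const arma::cube& stack,
                         const arma::mat& mask, const int max_shift) {
  const int n = static_cast<int>(variants.n_rows);
  const int nn = n * n;
  const int V = static_cast<int>(variants.n_slices);
  const uword M = stack.n_slices;
  if ((n & (n - 1)) != 0) Rcpp::stop("image side must be a power of two");
  const double npix = accu(mask);
  const Pow2FFT fft(n);

  // conj(FFT(variant)) and conj(FFT(mask))
  std::vector<std::vector<cxd> > qf(V, std::vector<cxd>(nn));
  for (int v = 0; v < V; ++v) {
    const double* src = variants.slice(v).memptr();
    for (int i = 0; i < nn; ++i) qf[v][i] = cxd(src[i], 0.0);
    fft.fft2(qf[v].data());
    for (int i = 0; i < nn; ++i) qf[v][i] = std::conj(qf[v][i]);
  }
  std::vector<cxd> mf(nn);
  for (int i = 0; i < nn; ++i) {
    mf[i] = cxd(mask.memptr()[i], 0.0);
  }
  fft.fft2(mf.data());
  for (int i = 0; i < nn; ++i) mf[i] = std::conj(mf[i]);

  // admissible shift offsets (wrapped indices), s = idx - max_shift
  const int S = 2 * max_shift + 1;
  std::vector<int> offs(S);
  for (int s = -max_shift; s <= max_shift; ++s) {
    offs[s + max_shift] = (s + n) % n;
  }

  std::vector<cxd> F(nn), F2(nn), W(nn), C(nn);
  mat out(M, 4);
  for (uword m = 0; m < M; ++m) {
    const double* img = stack.slice(m).memptr();
    for (int i = 0; i < nn; ++i) F[i] = cxd(img[i], 0.0);
    fft.fft2(F.data());
    for (int i = 0; i < nn; ++i) F2[i] = cxd(img[i] * img[i], 0.0);
    fft.fft2(F2.data());

    // window sums of I and I^2 under the shifted mask, packed re/im
    for (int i = 0; i < nn; ++i) {
      W[i] = F[i] * mf[i] + cxd(0.0, 1.0) * (F2[i] * mf[i]);
    }
    fft.ifft2_rows(W.data(), offs);
    mat denom(S, S);
    for (int a = 0; a < S; ++a) {
      for (int b = 0; b < S; ++b) {
        const cxd w = W[offs[b] * n + offs[a]];
        const double var = w.imag() - w.real() * w.real() / npix;
        denom(a, b) = var > 1e-20 ? std::sqrt(var) : -1.0;
      }
    }
    if (denom(max_shift, max_shift) < 0) {
      out(m, 0) = datum::nan;
      out(m, 1) = out(m, 2) = out(m, 3) = 0;
      continue;
    }

    double best = -2.0;
    int best_v = 0, best_dx = 0, best_dy = 0;
    for (int v = 0; v < V; v += 2) {
      // pack two real correlation maps into one complex inverse transform
      const bool pair = v + 1 < V;
      if (pair) {
        const cxd* q1 = qf[v].data();
        const cxd* q2 = qf[v + 1].data();
        for (int i = 0; i < nn; ++i) {
          C[i] = F[i] * q1[i] + cxd(0.0, 1.0) * (F[i] * q2[i]);
        }
      } else {
        const cxd* q1 = qf[v].data();
        for (int i = 0; i < nn; ++i) C[i] = F[i] * q1[i];
      }
      fft.ifft2_rows(C.data(), offs);
      for (int a = 0; a < S; ++a) {
        for (int b = 0; b < S; ++b) {
          if (denom(a, b) < 0) continue;
          const cxd c = C[offs[b] * n + offs[a]];
          const double val1 = c.real() / denom(a, b);
          if (val1 > best) {
            best = val1; best_v = v;
            best_dx = a - max_shift; best_dy = b - max_shift;
          }
          if (pair) {
            const double val2 = c.imag() / denom(a, b);
            if (val2 > best) {
              best = val2; best_v = v + 1;
              best_dx = a - max_shift; best_dy = b - max_shift;
            }
          }
        }
      }
    }
    out(m, 0) = best;
    out(m, 1) = best_v + 1;
    out(m, 2) = best_dx;
    out(m, 3) = best_dy;
  }
  return out;
}
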