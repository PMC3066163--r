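#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// 3D FFT of a cube held in column-major (i fastest) order, in place,
// axis by axis via Armadillo's 1D/column FFT.
static void fft3(cx_cube &z, bool inverse) {
  const uword n1 = z.n_rows, n2 = z.n_cols, n3 = z.n_slices;
  // axis 0: view memory as (n1, n2*n3) matrix; fft transforms columns
  {
    cx_mat m(z.memptr(), n1, n2 * n3, false, true);
    if (inverse) m = ifft(m); else m = fft(m);
  }
  // axis 1: per slice, transform rows via transpose
  for (uword k = 0; k < n3; ++k) {
    cx_mat s = z.slice(k).st();
    if (inverse) s = ifft(s); else s = fft(s);
    z.slice(k) = s.st();
  }
  // axis 2: view as (n1*n2, n3); transform rows via transpose
  {
    cx_mat m(z.memptr(), n1 * n2, n3, false, true);
    cx_mat t = m.st();
    if (inverse) t = ifft(t); else t = fft(t);
    m = t.st();
  }
}

// Circular cross-correlation m(s) = sum_x f(x) g(x+s) of mean-subtracted
// subsets, returned as the (2L+1)^3 window of lags centred on zero.
// [[Rcpp::export(name = ".correlate_window_cpp")]]
Rcpp::NumericVector correlate_window(const Rcpp::NumericVector &f,
                                     const Rcpp::NumericVector &g,
                                     const Rcpp::IntegerVector &dims,
                                     const int L) {
  const uword n1 = dims[0], n2 = dims[1], n3 = dims[2];
  const uword N = n1 * n2 * n3;
  double mf = 0, mg = 0;
  for (uword i = 0; i < N; ++i) { mf += f[i]; mg += g[i]; }
  mf /= N; mg /= N;
  cx_cube z(n1, n2, n3);
  std::complex<double> *zp = z.memptr();
  for (uword i = 0; i < N; ++i)
    zp[i] = std::complex<double>(f[i] - mf, g[i] - mg);
  fft3(z, false);
  // F(k) = (Z(k) + conj(Z(-k)))/2 ; G(k) = (Z(k) - conj(Z(-k)))/(2i)
  // store conj(F(k)) * G(k) into z
  cx_cube w(n1, n2, n3);
  for (uword k = 0; k < n3; ++k) {
    const uword kr = (n3 - k) % n3;
    for (uword j = 0; j < n2; ++j) {
      const uword jr = (n2 - j) % n2;
      for (uword i = 0; i < n1; ++i) {
        const uword ir = (n1 - i) % n1;
        const std::complex<double> zk = z(i, j, k);
        const std::complex<double> zr = std::conj(z(ir, jr, kr));
        const std::complex<double> F = 0.5 * (zk + zr);
        const std::complex<double> G =
          std::complex<double>(0.0, -0.5) * (zk - zr);
        w(i, j, k) = std::conj(F) * G;
      }
    }
  }
  fft3(w, true);  // Armadillo ifft includes the 1/N factors
  const int wn = 2 * L + 1;
  Rcpp::NumericVector out(wn * wn * wn);
  for (int c = -L; c <= L; ++c) {
    const uword kc = (uword)((c % (int)n3 + (int)n3) % (int)n3);
    for (int b = -L; b <= L; ++b) {
      const uword jb = (uword)((b % (int)n2 + (int)n2) % (int)n2);
      for (int a = -L; a <= L; ++a) {
        const uword ia = (uword)((a % (int)n1 + (int)n1) % (int)n1);
        out[(a + L) + wn * ((b + L) + wn * (c + L))] =
          w(ia, jb, kc).real();
      }
    }
  }
  out.attr("dim") = Rcpp::IntegerVector::create(wn, wn, wn);
  return out;
}
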