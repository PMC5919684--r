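// Discrete prolate spheroidal (Slepian) sequences.
//
// Uses the standard commuting symmetric tridiagonal matrix whose
// eigenvectors are the DPSS tapers:
//   diag(i)    = ((N-1-2i)/2)^2 * cos(2*pi*W),   i = 0..N-1
//   offdiag(i) = i*(N-i)/2,                      i = 1..N-1
// The top-k eigenpairs are computed with the LAPACK MRRR driver (dstemr),
// which resolves the tightly clustered top eigenvalues reliably even for
// the very long tapers (e.g. N = 262144) needed by high-resolution
// modulation spectra, at O(N k) cost.

#include <Rcpp.h>

extern "C" {
void dstemr_(const char* jobz, const char* range, const int* n, double* d,
             double* e, const double* vl, const double* vu, const int* il,
             const int* iu, int* m, double* w, double* z, const int* ldz,
             const int* nzc, int* isuppz, int* tryrac, double* work,
             const int* lwork, int* iwork, const int* liwork, int* info,
             size_t jobz_len, size_t range_len);
}

using namespace Rcpp;

// [[Rcpp::export(name = ".dpss_cpp")]]
NumericMatrix dpss_cpp(int n, double nw, int k) {
  if (n < 2 || k < 1 || k > n)
    stop("invalid DPSS request (n = %d, k = %d)", n, k);
  if (nw <= 0 || nw >= n / 2.0)
    stop("time-bandwidth product must satisfy 0 < nw < n/2");

  double W = nw / n;
  double c = std::cos(2.0 * M_PI * W);
  std::vector<double> d(n), e(n);  // dstemr wants e of length n
  for (int i = 0; i < n; ++i) {
    double h = (n - 1 - 2.0 * i) / 2.0;
    d[i] = h * h * c;
  }
  for (int i = 1; i < n; ++i) e[i - 1] = (double)i * (n - i) / 2.0;
  e[n - 1] = 0.0;

  const char jobz = 'V', range = 'I';
  const double vl = 0.0, vu = 0.0;
  const int il = n - k + 1, iu = n, ldz = n, nzc = k;
  int m = 0, tryrac = 1, info = 0;
  std::vector<double> w(n);
  NumericMatrix z(n, k);
  std::vector<int> isuppz(2 * k);

  // workspace query
  double wkopt = 0.0;
  int iwkopt = 0, lwork = -1, liwork = -1;
  dstemr_(&jobz, &range, &n, d.data(), e.data(), &vl, &vu, &il, &iu, &m,
          w.data(), z.begin(), &ldz, &nzc, isuppz.data(), &tryrac, &wkopt,
          &lwork, &iwkopt, &liwork, &info, 1, 1);
  if (info != 0) stop("dstemr workspace query failed (info = %d)", info);
  lwork = (int)wkopt;
  liwork = iwkopt;
  std::vector<double> work(lwork);
  std::vector<int> iwork(liwork);
  dstemr_(&jobz, &range, &n, d.data(), e.data(), &vl, &vu, &il, &iu, &m,
          w.data(), z.begin(), &ldz, &nzc, isuppz.data(), &tryrac,
          work.data(), &lwork, iwork.data(), &liwork, &info, 1, 1);
  if (info != 0 || m != k)
    stop("dstemr failed (info = %d, m = %d)", info, m);

  // reorder so taper 0 (largest eigenvalue) comes first; fix polarity by
  // making the element of largest magnitude positive (PSD is invariant to
  // the sign; this just makes results deterministic) and normalize.
  NumericMatrix out(n, k);
  for (int j = 0; j < k; ++j) {
    int src = k - 1 - j;  // ascending eigenvalue order from LAPACK
    double mx = 0.0; int mi = 0;
    for (int i = 0; i < n; ++i) {
      double a = std::fabs(z(i, src));
      if (a > mx) { mx = a; mi = i; }
    }
    double s = z(mi, src) >= 0 ? 1.0 : -1.0;
    double nrm = 0.0;
    for (int i = 0; i < n; ++i) nrm += z(i, src) * z(i, src);
    nrm = std::sqrt(nrm);
    for (int i = 0; i < n; ++i) out(i, j) = s * z(i, src) / nrm;
  }
  return out;
}
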