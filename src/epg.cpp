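#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Extended phase graph recursion for a CPMG train, vectorized over a vector
// of T2 values. Tracks transverse configuration states F(k), k = -K..K, and
// longitudinal states Z(k), k = 0..K (Z(-k) = conj(Z(k))), with relaxation
// and a crusher dephasing shift of one order per half echo spacing and
// mixing by each refocusing pulse (rotation about y, CPMG phase). T1
// regrowth within the train is neglected. Returns n_echoes x n_t2 echo
// magnitudes for unit initial magnetization.
// [[Rcpp::export]]
arma::mat epg_cpmg(const arma::vec& t2, double t1, double flip_deg,
                   int n_echoes, double tau) {
  const uword nt = t2.n_elem;
  const int K = n_echoes + 1;        // truncation order
  const uword nF = 2 * K + 1;        // rows: order -K..K, row K is order 0
  const uword i0 = K;

  rowvec E2 = exp(-tau / 2.0 / t2.t());
  const double E1 = std::exp(-tau / 2.0 / t1);

  const double a = flip_deg * datum::pi / 180.0;
  const double ca = std::cos(a), sa = std::sin(a);
  const double c2 = std::pow(std::cos(a / 2.0), 2);
  const double s2 = std::pow(std::sin(a / 2.0), 2);
  const cx_double e1p(0.0, 1.0);     // exp(i phi), phi = pi/2
  const cx_double e2p(-1.0, 0.0);    // exp(2 i phi)
  const cx_double im(0.0, 1.0);

  cx_mat F(nF, nt, fill::zeros);
  cx_mat Z(K + 1, nt, fill::zeros);
  F.row(i0).fill(cx_double(0.0, -1.0));   // Mxy after ideal 90x excitation

  mat out(n_echoes, nt);

  auto relax_shift = [&]() {
    F.each_row() %= conv_to<cx_rowvec>::from(E2);
    Z *= E1;
    // dephasing shift +1 order: F(k) <- F(k-1), top order discarded
    for (uword r = nF - 1; r >= 1; --r) F.row(r) = F.row(r - 1);
    F.row(0).zeros();
  };

  for (int e = 0; e < n_echoes; ++e) {
    relax_shift();
    cx_mat Fneg = conj(flipud(F));
    cx_mat Zfull = join_cols(conj(flipud(Z.rows(1, K))), Z);  // orders -K..K
    cx_mat Fnew = c2 * F + (e2p * s2) * Fneg - (im * e1p * sa) * Zfull;
    cx_mat Znew = (-0.5 * im * std::conj(e1p) * sa) * F.rows(i0, nF - 1)
                + (0.5 * im * e1p * sa) * Fneg.rows(i0, nF - 1)
                + ca * Zfull.rows(i0, nF - 1);
    F = std::move(Fnew);
    Z = std::move(Znew);
    relax_shift();
    out.row(e) = abs(F.row(i0));
  }
  return out;
}
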