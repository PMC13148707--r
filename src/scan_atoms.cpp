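#include <Rcpp.h>
#include <complex>
#include <vector>

using namespace Rcpp;

// Quasi-periodicity score of a candidate component g on the unit-circle grid:
//   score = | sum_{m=1..N-1} R(m) | / N  with the biased linear lag products
//   R(m) = (1/N) sum_t g(t) conj(g(t+m)),
// collapsed to a single prefix-sum pass:  sum_{s>t} conj(g_s) g_t.
static double qp_score(const std::vector< std::complex<double> > &g) {
  const size_t n = g.size();
  std::complex<double> prefix(0.0, 0.0), S(0.0, 0.0);
  for (size_t s = 1; s < n; ++s) {
    prefix += g[s - 1];
    S += std::conj(g[s]) * prefix;
  }
  return std::abs(S) / (double(n) * double(n));
}

// Score every dictionary atom against the current residual f.
// For atom a the candidate component is c * u_a * Bprod, where u_a is the
// Szego kernel normalised to unit *discrete* norm and c = <f, u_a>.
// Returns per-atom scores and coefficients; argmax selection (with the
// smallest-index tie-break) is done by the R caller.
// [[Rcpp::export]]
List scan_atoms_cpp(ComplexVector f, ComplexVector Bprod, ComplexVector atoms,
                    ComplexVector grid) {
  const int N = f.size();
  const int A = atoms.size();
  NumericVector scores(A);
  ComplexVector coeffs(A);

  std::vector< std::complex<double> > fz(N), bp(N), zz(N), e(N), g(N);
  for (int t = 0; t < N; ++t) {
    fz[t] = std::complex<double>(f[t].r, f[t].i);
    bp[t] = std::complex<double>(Bprod[t].r, Bprod[t].i);
    zz[t] = std::complex<double>(grid[t].r, grid[t].i);
  }

  for (int j = 0; j < A; ++j) {
    const std::complex<double> a(atoms[j].r, atoms[j].i);
    const double amp = std::sqrt(1.0 - std::norm(a));
    double nrm2 = 0.0;
    std::complex<double> csum(0.0, 0.0);
    for (int t = 0; t < N; ++t) {
      e[t] = amp / (1.0 - std::conj(a) * zz[t]);
      nrm2 += std::norm(e[t]);
      csum += fz[t] * std::conj(e[t]);
    }
    const double nrm = std::sqrt(nrm2 / N);
    const std::complex<double> c = (csum / double(N)) / nrm;
    for (int t = 0; t < N; ++t)
      g[t] = c * (e[t] / nrm) * bp[t];
    scores[j] = qp_score(g);
    coeffs[j].r = c.real();
    coeffs[j].i = c.imag();
  }
  return List::create(_["score"] = scores, _["coeff"] = coeffs);
}
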