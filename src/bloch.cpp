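// Bloch-McConnell propagation for linear N-site chemical exchange.
//
// Basis: per-state Cartesian triplets (Mx_i, My_i, Mz_i), i = 1..N, giving a
// 3N-dimensional magnetization vector. Saturation field B1 is applied along x.
// Longitudinal relaxation drives Mz toward zero (no recovery term); the CEST
// observable is normalized against a zero-length-saturation reference.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

// Build the 3N x 3N evolution matrix.
//
// omega: per-state resonance offset from the irradiation frequency (rad/s)
// w1:    nutation frequency of the saturation field (rad/s), along x
// R1:    longitudinal relaxation rate shared by all states (1/s)
// R2:    per-state transverse relaxation rates (1/s)
// K:     N x N first-order exchange generator, K(i,j) = rate j -> i (i != j),
//        diagonal = -colsum, so each column sums to zero (magnetization
//        conservation per Cartesian component).
static mat bm_generator(const vec& omega, double w1, double R1,
                        const vec& R2, const mat& K) {
  const uword N = omega.n_elem;
  mat G(3 * N, 3 * N, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    const uword o = 3 * i;
    // precession about z at omega_i, nutation about x at w1
    G(o,     o    ) = -R2(i);
    G(o,     o + 1) = -omega(i);
    G(o + 1, o    ) =  omega(i);
    G(o + 1, o + 1) = -R2(i);
    G(o + 1, o + 2) = -w1;
    G(o + 2, o + 1) =  w1;
    G(o + 2, o + 2) = -R1;
    for (uword j = 0; j < N; ++j) {
      if (i == j) {
        for (uword c = 0; c < 3; ++c) G(o + c, o + c) += K(i, i);
      } else {
        const uword oj = 3 * j;
        for (uword c = 0; c < 3; ++c) G(o + c, oj + c) += K(i, j);
      }
    }
  }
  return G;
}

// [[Rcpp::export(name = ".bmGeneratorC")]]
arma::mat bmGeneratorC(const arma::vec& omega, double w1, double R1,
                       const arma::vec& R2, const arma::mat& K) {
  return bm_generator(omega, w1, R1, R2, K);
}

// [[Rcpp::export(name = ".propagateC")]]
arma::vec propagateC(const arma::mat& G, const arma::vec& M0, double t) {
  return expmat(G * t) * M0;
}

// Block-diagonal rotation about x by angle theta applied to all states.
static mat pulse_rotation(uword N, double theta) {
  const double c = std::cos(theta), s = std::sin(theta);
  mat P(3 * N, 3 * N, fill::zeros);
  for (uword i = 0; i < N; ++i) {
    const uword o = 3 * i;
    P(o, o) = 1.0;
    P(o + 1, o + 1) = c;  P(o + 1, o + 2) = -s;
    P(o + 2, o + 1) = s;  P(o + 2, o + 2) = c;
  }
  return P;
}

// Simulate one CEST profile: normalized summed Mz after Tsat of saturation,
// at each irradiation offset.
//
// offsets:   irradiation frequencies (Hz, relative to the carrier)
// shifts_hz: per-state resonance positions (Hz, relative to the carrier)
// pops:      per-state equilibrium populations (initial Mz)
// dante:     if true, model a DANTE pulse train (ideal delta pulses of flip
//            angle 2*pi*B1/window, separated by free precession 1/window);
//            otherwise continuous-wave saturation.
// [[Rcpp::export(name = ".cestProfileC")]]
arma::vec cestProfileC(const arma::vec& offsets, const arma::vec& shifts_hz,
                       const arma::vec& pops, const arma::mat& K,
                       double R1, const arma::vec& R2,
                       double B1, double Tsat,
                       bool dante, double window) {
  const uword N = shifts_hz.n_elem;
  const double two_pi = 2.0 * datum::pi;
  vec M0(3 * N, fill::zeros);
  for (uword i = 0; i < N; ++i) M0(3 * i + 2) = pops(i);
  const double I0 = accu(pops);

  vec out(offsets.n_elem);
  const int nper = dante ? (int) std::lround(Tsat * window) : 0;
  mat P;
  if (dante && nper >= 1) P = pulse_rotation(N, two_pi * B1 / window);

  for (uword k = 0; k < offsets.n_elem; ++k) {
    vec omega = two_pi * (shifts_hz - offsets(k));
    vec M;
    if (dante && nper >= 1) {
      // one period: free precession for 1/window, then the delta pulse
      mat U0 = expmat(bm_generator(omega, 0.0, R1, R2, K) * (1.0 / window));
      mat U = P * U0;
      M = M0;
      for (int p = 0; p < nper; ++p) M = U * M;
    } else {
      mat G = bm_generator(omega, two_pi * B1, R1, R2, K);
      M = expmat(G * Tsat) * M0;
    }
    double Iz = 0.0;
    for (uword i = 0; i < N; ++i) Iz += M(3 * i + 2);
    out(k) = Iz / I0;
  }
  return out;
}
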