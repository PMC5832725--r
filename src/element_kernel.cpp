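// Q1/P0 hexahedral element kernel (total Lagrangian, mean dilatation).
// Mirrors the reference R implementation in R/continuum-fe.R; the two
// are cross-checked in the test suite.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static const int VI[6][2] = {{0, 0}, {1, 1}, {2, 2}, {0, 1}, {1, 2}, {0, 2}};

static vec t2v(const mat33& S) {
  vec v(6);
  for (int m = 0; m < 6; ++m) v(m) = S(VI[m][0], VI[m][1]);
  return v;
}

static mat icsym66(const mat33& Ci) {
  mat out(6, 6);
  for (int m = 0; m < 6; ++m)
    for (int n = 0; n < 6; ++n) {
      int i = VI[m][0], j = VI[m][1], k = VI[n][0], l = VI[n][1];
      out(m, n) = 0.5 * (Ci(i, k) * Ci(j, l) + Ci(i, l) * Ci(j, k));
    }
  return out;
}

// [[Rcpp::export(name = ".element_system_cpp")]]
Rcpp::List element_system_cpp(const arma::mat& X, const arma::mat& u,
                              const arma::cube& gradN0,  // 8 x 3 x 8 gp
                              const arma::vec& detJ0,
                              const arma::mat& a0m,      // 8 x 3 (per gp)
                              double kappa, double mu_p, double c_p1,
                              double c_p2,
                              const arma::vec& act_cfac,
                              const arma::vec& act_ufs,
                              bool want_K) {
  // pass 1: kinematics, element dilatation
  cube Fs(3, 3, 8);
  vec Js(8), I4bs(8);
  double V0 = 0.0, Jnum = 0.0;
  for (int g = 0; g < 8; ++g) {
    mat gN = gradN0.slice(g);              // 8 x 3
    mat33 F = eye(3, 3) + u.t() * gN;
    double J = det(F);
    if (J <= 0) Rcpp::stop("element inversion (J <= 0)");
    Fs.slice(g) = F;
    Js(g) = J;
    V0 += detJ0(g);
    Jnum += J * detJ0(g);
  }
  double Theta = Jnum / V0;
  // volumetric potential kappa/4 (J^2 - 1 - 2 ln J)
  double pbar = 0.5 * kappa * (Theta - 1.0 / Theta);

  vec f(24, fill::zeros), gvec(24, fill::zeros);
  mat K;
  if (want_K) K = mat(24, 24, fill::zeros);
  vec lam(8), psi_gp(8);

  for (int g = 0; g < 8; ++g) {
    mat gN = gradN0.slice(g);
    mat33 F = Fs.slice(g);
    double J = Js(g);
    mat33 C = F.t() * F;
    mat33 Ci = inv_sympd(C);
    vec3 a0 = a0m.row(g).t();
    mat33 A = a0 * a0.t();
    double I1 = trace(C);
    double I4 = as_scalar(a0.t() * C * a0);
    double J23 = std::pow(J, -2.0 / 3.0);
    double I1b = J23 * I1, I4b = J23 * I4;
    I4bs(g) = I4b;
    lam(g) = std::sqrt(I4b);
    // C2-smooth tension-only ramp s(x) = x^3/(x^2+eps^2), x = I4b - 1
    double x = I4b - 1.0, sm = 0.0, sm1 = 0.0, sm2 = 0.0;
    const double feps = 0.02;
    if (x > 0.0) {
      double D = x * x + feps * feps;
      sm = x * x * x / D;
      sm1 = (x * x * x * x + 3.0 * feps * feps * x * x) / (D * D);
      sm2 = 2.0 * feps * feps * x * (3.0 * feps * feps - x * x) / (D * D * D);
    }
    double e4 = std::exp(c_p2 * sm * sm);
    if (!std::isfinite(e4)) Rcpp::stop("overflow in exponential fibre term");
    double psi1 = mu_p / 2.0;
    double psi4 = c_p1 * sm * sm1 * e4;
    double psi44 = c_p1 * e4 *
      (sm1 * sm1 + sm * sm2 + 2.0 * c_p2 * sm * sm * sm1 * sm1);
    double psi = psi1 * (I1b - 3.0) + c_p1 / (2.0 * c_p2) * (e4 - 1.0);
    // active contribution through the fibre invariant
    double cf = act_cfac(g);
    if (cf != 0.0) {
      double ufs = act_ufs(g);
      double lm = lam(g);
      double ue = lm - 1.0 - ufs;
      psi += cf * ue * ue;
      psi4 += cf * ue / lm;
      psi44 += cf * (1.0 + ufs) / (2.0 * lm * lm * lm);
    }
    psi_gp(g) = psi;
    mat33 G1 = J23 * (eye(3, 3) - (I1 / 3.0) * Ci);
    mat33 G4 = J23 * (A - (I4 / 3.0) * Ci);
    mat33 S = 2.0 * (psi1 * G1 + psi4 * G4) + pbar * J * Ci;

    // B matrix (6 x 24), engineering shear rows
    mat B(6, 24, fill::zeros);
    for (int a = 0; a < 8; ++a)
      for (int i = 0; i < 3; ++i) {
        int c = 3 * a + i;
        B(0, c) = F(i, 0) * gN(a, 0);
        B(1, c) = F(i, 1) * gN(a, 1);
        B(2, c) = F(i, 2) * gN(a, 2);
        B(3, c) = F(i, 0) * gN(a, 1) + F(i, 1) * gN(a, 0);
        B(4, c) = F(i, 1) * gN(a, 2) + F(i, 2) * gN(a, 1);
        B(5, c) = F(i, 0) * gN(a, 2) + F(i, 2) * gN(a, 0);
      }
    double dV = detJ0(g);
    vec Sv = t2v(S);
    f += B.t() * Sv * dV;
    vec jciv = J * t2v(Ci);
    gvec += B.t() * jciv * dV;

    if (want_K) {
      mat ICs = icsym66(Ci);
      vec civ = t2v(Ci);
      vec dv = t2v(eye(3, 3));
      vec av = t2v(A);
      mat H1 = -J23 / 3.0 * (civ * dv.t() + dv * civ.t()) +
        J23 * I1 / 9.0 * (civ * civ.t()) + J23 * I1 / 3.0 * ICs;
      mat H4 = -J23 / 3.0 * (civ * av.t() + av * civ.t()) +
        J23 * I4 / 9.0 * (civ * civ.t()) + J23 * I4 / 3.0 * ICs;
      vec g4v = t2v(G4);
      mat CC = 4.0 * (psi44 * (g4v * g4v.t()) + psi1 * H1 + psi4 * H4) +
        pbar * J * (civ * civ.t() - 2.0 * ICs);
      K += B.t() * CC * B * dV;
      // geometric stiffness
      mat GS = gN * S * gN.t();   // 8 x 8
      for (int a = 0; a < 8; ++a)
        for (int b = 0; b < 8; ++b)
          for (int i = 0; i < 3; ++i)
            K(3 * a + i, 3 * b + i) += GS(a, b) * dV;
    }
  }
  double dp = 0.5 * kappa * (1.0 + 1.0 / (Theta * Theta));
  if (want_K) K += (dp / V0) * (gvec * gvec.t());

  Rcpp::List out = Rcpp::List::create(
    Rcpp::Named("f") = f,
    Rcpp::Named("pbar") = pbar,
    Rcpp::Named("Theta") = Theta,
    Rcpp::Named("V0") = V0,
    Rcpp::Named("lam") = lam,
    Rcpp::Named("I4b") = I4bs,
    Rcpp::Named("J") = Js,
    Rcpp::Named("psi") = psi_gp);
  if (want_K) out["K"] = K;
  return out;
}
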