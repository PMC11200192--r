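// Per-sample attention cores for the batched training path.
//
// The surrounding projections (X %*% W) are large BLAS calls and stay in R;
// these kernels run the per-(sample, head) softmax-attention blocks and the
// bilinear attention pooling, whose many small operations dominate when
// done at R level. Layouts match the R callers: sequences are stacked
// row-wise, sample b occupying rows [b*L, (b+1)*L).

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

static inline void softmax_rows_inplace(mat &S) {
  for (uword i = 0; i < S.n_rows; ++i) {
    rowvec r = S.row(i);
    r -= r.max();
    r = exp(r);
    S.row(i) = r / accu(r);
  }
}

// Multi-head attention core: Q, K, V are (B*L x d). Returns O (B*L x d)
// and the attention maps stacked as ((B*H*L) x L) for the backward pass.
// [[Rcpp::export]]
Rcpp::List cpp_mhsa_fwd(const arma::mat &Q, const arma::mat &K,
                        const arma::mat &V, int B, int L, int n_heads) {
  const int d = Q.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat O(Q.n_rows, d, fill::zeros);
  mat Astack(B * n_heads * L, L);
  for (int b = 0; b < B; ++b) {
    const uword r0 = b * L, r1 = (b + 1) * L - 1;
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dh, c1 = (h + 1) * dh - 1;
      mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t() * scale;
      softmax_rows_inplace(S);
      O.submat(r0, c0, r1, c1) = S * V.submat(r0, c0, r1, c1);
      Astack.rows((b * n_heads + h) * L, (b * n_heads + h + 1) * L - 1) = S;
    }
  }
  return Rcpp::List::create(Rcpp::Named("O") = O,
                            Rcpp::Named("Astack") = Astack);
}

// Backward of the attention core: dO is the gradient w.r.t. the core
// output (before the output projection). Returns dQ, dK, dV.
// [[Rcpp::export]]
Rcpp::List cpp_mhsa_bwd(const arma::mat &dO, const arma::mat &Q,
                        const arma::mat &K, const arma::mat &V,
                        const arma::mat &Astack, int B, int L, int n_heads) {
  const int d = Q.n_cols;
  const int dh = d / n_heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  mat dQ(Q.n_rows, d, fill::zeros), dK(Q.n_rows, d, fill::zeros),
      dV(Q.n_rows, d, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword r0 = b * L, r1 = (b + 1) * L - 1;
    for (int h = 0; h < n_heads; ++h) {
      const uword c0 = h * dh, c1 = (h + 1) * dh - 1;
      const mat A = Astack.rows((b * n_heads + h) * L,
                                (b * n_heads + h + 1) * L - 1);
      const mat dOh = dO.submat(r0, c0, r1, c1);
      const mat Vh = V.submat(r0, c0, r1, c1);
      mat dA = dOh * Vh.t();
      dV.submat(r0, c0, r1, c1) = A.t() * dOh;
      // softmax backward: dS = (dA - rowsum(dA % A)) % A, then scale
      vec rs = sum(dA % A, 1);
      mat dS = (dA.each_col() - rs) % A * scale;
      dQ.submat(r0, c0, r1, c1) = dS * K.submat(r0, c0, r1, c1);
      dK.submat(r0, c0, r1, c1) = dS.t() * Q.submat(r0, c0, r1, c1);
    }
  }
  return Rcpp::List::create(Rcpp::Named("dQ") = dQ, Rcpp::Named("dK") = dK,
                            Rcpp::Named("dV") = dV);
}

// Bilinear attention pooling core: P (B*Lp x r), Q (B*La x r). Per sample,
// A = row-softmax(P_b Q_b^T / sqrt(r)), M = A Q_b, f = colsum(P_b % M)/Lp.
// [[Rcpp::export]]
Rcpp::List cpp_ban_fwd(const arma::mat &P, const arma::mat &Q, int B, int Lp,
                       int La) {
  const int r = P.n_cols;
  const double scale = 1.0 / std::sqrt((double)r);
  mat f(B, r);
  mat Astack(B * Lp, La);
  mat Mstack(B * Lp, r);
  for (int b = 0; b < B; ++b) {
    const uword p0 = b * Lp, p1 = (b + 1) * Lp - 1;
    const uword a0 = b * La, a1 = (b + 1) * La - 1;
    mat S = P.rows(p0, p1) * Q.rows(a0, a1).t() * scale;
    softmax_rows_inplace(S);
    mat M = S * Q.rows(a0, a1);
    f.row(b) = sum(P.rows(p0, p1) % M, 0) / (double)Lp;
    Astack.rows(p0, p1) = S;
    Mstack.rows(p0, p1) = M;
  }
  return Rcpp::List::create(Rcpp::Named("f") = f,
                            Rcpp::Named("Astack") = Astack,
                            Rcpp::Named("Mstack") = Mstack);
}

// [[Rcpp::export]]
Rcpp::List cpp_ban_bwd(const arma::mat &df, const arma::mat &P,
                       const arma::mat &Q, const arma::mat &Astack,
                       const arma::mat &Mstack, int B, int Lp, int La) {
  const int r = P.n_cols;
  const double scale = 1.0 / std::sqrt((double)r);
  mat dP(P.n_rows, r, fill::zeros), dQ(Q.n_rows, r, fill::zeros);
  for (int b = 0; b < B; ++b) {
    const uword p0 = b * Lp, p1 = (b + 1) * Lp - 1;
    const uword a0 = b * La, a1 = (b + 1) * La - 1;
    const mat A = Astack.rows(p0, p1);
    const mat M = Mstack.rows(p0, p1);
    rowvec dfb = df.row(b) / (double)Lp;
    mat dPb = M.each_row() % dfb;
    mat Pb = P.rows(p0, p1);
    mat dM = Pb.each_row() % dfb;
    mat dA = dM * Q.rows(a0, a1).t();
    mat dQb = A.t() * dM;
    vec rs = sum(dA % A, 1);
    mat dS = (dA.each_col() - rs) % A * scale;
    dP.rows(p0, p1) = dPb + dS * Q.rows(a0, a1);
    dQ.rows(a0, a1) = dQb + dS.t() * P.rows(p0, p1);
  }
  return Rcpp::List::create(Rcpp::Named("dP") = dP, Rcpp::Named("dQ") = dQ);
}

// Row-wise layer normalization, forward and backward.
// [[Rcpp::export]]
Rcpp::List cpp_layernorm_fwd(const arma::mat &X, const arma::rowvec &g,
                             const arma::rowvec &b, double eps) {
  vec mu = mean(X, 1);
  mat xc = X.each_col() - mu;
  vec istd = 1.0 / sqrt(mean(xc % xc, 1) + eps);
  mat xhat = xc.each_col() % istd;
  mat out = xhat.each_row() % g;
  out.each_row() += b;
  return Rcpp::List::create(Rcpp::Named("out") = out,
                            Rcpp::Named("xhat") = xhat,
                            Rcpp::Named("istd") = istd);
}

// [[Rcpp::export]]
Rcpp::List cpp_layernorm_bwd(const arma::mat &dY, const arma::mat &xhat,
                             const arma::vec &istd, const arma::rowvec &g) {
  mat dxhat = dY.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % xhat, 1);
  mat dX = dxhat;
  dX.each_col() -= m1;
  dX -= xhat.each_col() % m2;
  dX.each_col() %= istd;
  rowvec dg = sum(dY % xhat, 0);
  rowvec db = sum(dY, 0);
  return Rcpp::List::create(Rcpp::Named("dX") = dX, Rcpp::Named("dg") = dg,
                            Rcpp::Named("db") = db);
}
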