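// Hot numerical kernels for the three-branch classifier.
//
// Layout contract (shared with the R assembly code): sequence-shaped
// activations are "flat" (B*T) x C matrices whose row (t-1)*B + b holds
// sample b at position t. Armadillo and R are both column-major, so
// matrices cross the boundary without reshaping.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::mat;
using arma::rowvec;
using arma::vec;

static inline mat shifted(const arma::mat& flat, int B, int T, int delta) {
  // time-shifted copy: out row (t-1)*B+b = flat row (t+delta-1)*B+b, zero
  // where t+delta leaves [1, T]; a pure block shift of B*delta rows.
  mat out(flat.n_rows, flat.n_cols, arma::fill::zeros);
  int lo = std::max(0, -delta);          // first valid t-1
  int hi = std::min(T, T - delta);       // one past last valid t-1
  if (hi > lo)
    out.rows(lo * B, hi * B - 1) = flat.rows((lo + delta) * B,
                                             (hi + delta) * B - 1);
  return out;
}

static mat im2col(const arma::mat& flat, int B, int T, int kernel) {
  int half = kernel / 2;
  mat xcol(flat.n_rows, flat.n_cols * kernel);
  for (int k = 0; k < kernel; ++k)
    xcol.cols(k * flat.n_cols, (k + 1) * flat.n_cols - 1) =
      shifted(flat, B, T, k - half);
  return xcol;
}

// [[Rcpp::export(name = ".cpp_conv1d_fwd")]]
List cpp_conv1d_fwd(const arma::mat& flat, int B, int T, const arma::mat& W,
                    const arma::vec& b, int kernel, bool act) {
  mat xcol = im2col(flat, B, T, kernel);
  mat pre = xcol * W;
  pre.each_row() += b.t();
  mat out = act ? mat(arma::clamp(pre, 0.0, arma::datum::inf)) : pre;
  return List::create(_["out"] = out, _["pre"] = pre, _["xcol"] = xcol);
}

// [[Rcpp::export(name = ".cpp_conv1d_bwd")]]
List cpp_conv1d_bwd(const arma::mat& dout, const arma::mat& xcol, const arma::mat& pre,
                    int B, int T, const arma::mat& W, int kernel, bool act) {
  int Call = xcol.n_cols / kernel;
  mat dpre = dout;
  if (act) dpre.elem(arma::find(pre <= 0)).zeros();
  mat dW = xcol.t() * dpre;
  rowvec db = arma::sum(dpre, 0);
  mat dxcol = dpre * W.t();
  int C = Call, half = kernel / 2;
  mat dflat(xcol.n_rows, C, arma::fill::zeros);
  for (int k = 0; k < kernel; ++k) {
    int delta = k - half;
    // inverse scatter of shifted(): dflat row s += dxcol_k row s - delta*B
    int lo = std::max(0, delta);
    int hi = std::min(T, T + delta);
    if (hi > lo)
      dflat.rows(lo * B, hi * B - 1) +=
        dxcol.submat((lo - delta) * B, k * C,
                     (hi - delta) * B - 1, (k + 1) * C - 1);
  }
  return List::create(_["dx"] = dflat, _["dW"] = dW,
                      _["db"] = vec(db.t()));
}

// [[Rcpp::export(name = ".cpp_bn_fwd")]]
List cpp_bn_fwd(const arma::mat& x, const arma::vec& gamma, const arma::vec& beta,
                const arma::vec& run_mean, const arma::vec& run_var, bool training,
                double eps, double mom) {
  rowvec mu, va;
  vec new_mean = run_mean, new_var = run_var;
  if (training) {
    mu = arma::mean(x, 0);
    rowvec m2 = arma::mean(arma::square(x), 0);
    va = m2 - arma::square(mu);
    va.transform([](double v) { return v < 0 ? 0 : v; });
    new_mean = mom * run_mean + (1 - mom) * mu.t();
    new_var = mom * run_var + (1 - mom) * va.t();
  } else {
    mu = run_mean.t();
    va = run_var.t();
  }
  rowvec istd = 1.0 / arma::sqrt(va + eps);
  mat xhat = x;
  xhat.each_row() -= mu;
  xhat.each_row() %= istd;
  mat y = xhat;
  y.each_row() %= gamma.t();
  y.each_row() += beta.t();
  return List::create(_["out"] = y, _["xhat"] = xhat,
                      _["istd"] = vec(istd.t()),
                      _["run_mean"] = new_mean, _["run_var"] = new_var);
}

// [[Rcpp::export(name = ".cpp_bn_bwd")]]
List cpp_bn_bwd(const arma::mat& dy, const arma::mat& xhat, const arma::vec& istd,
                const arma::vec& gamma, bool training) {
  rowvec dgamma = arma::sum(dy % xhat, 0);
  rowvec dbeta = arma::sum(dy, 0);
  mat dx;
  if (!training) {
    dx = dy;
    dx.each_row() %= (gamma % istd).t();
  } else {
    double N = dy.n_rows;
    mat dxhat = dy;
    dxhat.each_row() %= gamma.t();
    rowvec t1 = arma::sum(dxhat, 0) / N;
    rowvec t2 = arma::sum(dxhat % xhat, 0) / N;
    dx = dxhat;
    dx.each_row() -= t1;
    dx -= xhat.each_row() % t2;
    dx.each_row() %= istd.t();
  }
  return List::create(_["dx"] = dx, _["dgamma"] = vec(dgamma.t()),
                      _["dbeta"] = vec(dbeta.t()));
}

// GRU: h_t = (1 - z_t) % g_t + z_t % h_{t-1}
// r, z sigmoid gates; g = tanh(x Wxn + (r % h_{t-1}) Whn + bn)
// [[Rcpp::export(name = ".cpp_gru_fwd")]]
List cpp_gru_fwd(const arma::mat& flat, int B, int T,
                 const arma::mat& Wxr, const arma::mat& Whr, const arma::vec& br,
                 const arma::mat& Wxz, const arma::mat& Whz, const arma::vec& bz,
                 const arma::mat& Wxn, const arma::mat& Whn, const arma::vec& bn) {
  int H = Whr.n_cols;
  mat h(B, H, arma::fill::zeros);
  mat hflat(B * T, H), Rm(B * T, H), Zm(B * T, H), Gm(B * T, H),
      Qm(B * T, H);
  // input projections for every step in three large GEMMs
  mat XR = flat * Wxr;  XR.each_row() += br.t();
  mat XZ = flat * Wxz;  XZ.each_row() += bz.t();
  mat XN = flat * Wxn;  XN.each_row() += bn.t();
  for (int t = 0; t < T; ++t) {
    int a0 = t * B, a1 = (t + 1) * B - 1;
    mat r = 1.0 / (1.0 + arma::exp(-(XR.rows(a0, a1) + h * Whr)));
    mat z = 1.0 / (1.0 + arma::exp(-(XZ.rows(a0, a1) + h * Whz)));
    mat q = r % h;
    mat g = arma::tanh(XN.rows(a0, a1) + q * Whn);
    h = (1.0 - z) % g + z % h;
    hflat.rows(a0, a1) = h;
    Rm.rows(a0, a1) = r;
    Zm.rows(a0, a1) = z;
    Gm.rows(a0, a1) = g;
    Qm.rows(a0, a1) = q;
  }
  return List::create(_["hflat"] = hflat, _["R"] = Rm, _["Z"] = Zm,
                      _["G"] = Gm, _["Q"] = Qm);
}

// [[Rcpp::export(name = ".cpp_gru_bwd")]]
List cpp_gru_bwd(const arma::mat& dhflat, const arma::mat& flat, const arma::mat& hflat,
                 const arma::mat& Rm, const arma::mat& Zm, const arma::mat& Gm,
                 const arma::mat& Qm, int B, int T,
                 const arma::mat& Wxr, const arma::mat& Whr,
                 const arma::mat& Wxz, const arma::mat& Whz,
                 const arma::mat& Wxn, const arma::mat& Whn) {
  int H = Whr.n_cols;
  // hprev laid out flat: rows of step t hold h_{t-1} (zeros at t = 0)
  mat hprevflat(B * T, H, arma::fill::zeros);
  if (T > 1)
    hprevflat.rows(B, B * T - 1) = hflat.rows(0, B * (T - 1) - 1);
  mat dAR(B * T, H), dAZ(B * T, H), dAG(B * T, H);
  mat dh_next(B, H, arma::fill::zeros);
  for (int t = T - 1; t >= 0; --t) {
    int a0 = t * B, a1 = (t + 1) * B - 1;
    mat hprev = hprevflat.rows(a0, a1);
    mat r = Rm.rows(a0, a1);
    mat z = Zm.rows(a0, a1);
    mat g = Gm.rows(a0, a1);
    mat dh = dh_next + dhflat.rows(a0, a1);
    mat daz = (dh % (hprev - g)) % z % (1.0 - z);
    mat dag = (dh % (1.0 - z)) % (1.0 - g % g);
    mat dq = dag * Whn.t();
    mat dar = (dq % hprev) % r % (1.0 - r);
    dh_next = dh % z + dq % r + dar * Whr.t() + daz * Whz.t();
    dAR.rows(a0, a1) = dar;
    dAZ.rows(a0, a1) = daz;
    dAG.rows(a0, a1) = dag;
  }
  // everything not on the recursion path as large GEMMs
  mat dx = dAR * Wxr.t() + dAZ * Wxz.t() + dAG * Wxn.t();
  return List::create(_["dx"] = dx,
                      _["Wxr"] = mat(flat.t() * dAR),
                      _["Whr"] = mat(hprevflat.t() * dAR),
                      _["br"] = vec(arma::sum(dAR, 0).t()),
                      _["Wxz"] = mat(flat.t() * dAZ),
                      _["Whz"] = mat(hprevflat.t() * dAZ),
                      _["bz"] = vec(arma::sum(dAZ, 0).t()),
                      _["Wxn"] = mat(flat.t() * dAG),
                      _["Whn"] = mat(Qm.t() * dAG),
                      _["bn"] = vec(arma::sum(dAG, 0).t()));
}

// Additive attention: e_t = v' tanh(W h_t + b), masked softmax over t,
// context = sum_t alpha_t h_t.
// [[Rcpp::export(name = ".cpp_att_fwd")]]
List cpp_att_fwd(const arma::mat& hflat, int B, int T, const arma::mat& W,
                 const arma::vec& b, const arma::vec& v, const arma::umat& mask) {
  mat U = hflat * W;
  U.each_row() += b.t();
  U = arma::tanh(U);
  vec evec = U * v;
  mat E(B, T);
  std::copy(evec.begin(), evec.end(), E.begin());
  E.elem(arma::find(mask == 0)).fill(-arma::datum::inf);
  vec emax = arma::max(E, 1);
  E.each_col() -= emax;
  mat ex = arma::exp(E);
  vec rs = arma::sum(ex, 1);
  mat alpha = ex.each_col() / rs;
  vec avec(alpha.memptr(), B * T);
  mat wH = hflat.each_col() % avec;
  mat ctx(B, hflat.n_cols, arma::fill::zeros);
  for (int t = 0; t < T; ++t)
    ctx += wH.rows(t * B, (t + 1) * B - 1);
  return List::create(_["ctx"] = ctx, _["alpha"] = alpha, _["U"] = U);
}

// [[Rcpp::export(name = ".cpp_att_bwd")]]
List cpp_att_bwd(const arma::mat& dctx, const arma::mat& hflat, const arma::mat& U,
                 const arma::mat& alpha, int B, int T, const arma::mat& W,
                 const arma::vec& v) {
  int D = hflat.n_cols, A = U.n_cols;
  vec avec(const_cast<double*>(alpha.memptr()), B * T, false);
  mat dcBT(B * T, D);
  for (int t = 0; t < T; ++t) dcBT.rows(t * B, (t + 1) * B - 1) = dctx;
  mat dH1 = dcBT.each_col() % avec;
  vec dalpha_vec = arma::sum(hflat % dcBT, 1);
  mat dalpha(B, T);
  std::copy(dalpha_vec.begin(), dalpha_vec.end(), dalpha.begin());
  vec inner = arma::sum(dalpha % alpha, 1);
  mat dE = alpha % (dalpha.each_col() - inner);
  vec devec(dE.memptr(), B * T);
  mat dU = devec * v.t();
  mat dA = dU % (1.0 - U % U);
  mat dH2 = dA * W.t();
  mat dW = hflat.t() * dA;
  vec db = arma::sum(dA, 0).t();
  vec dv = U.t() * devec;
  (void)A;
  return List::create(_["dh"] = mat(dH1 + dH2), _["dW"] = dW,
                      _["db"] = db, _["dv"] = dv);
}
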