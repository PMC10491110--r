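// Fused linear-block kernels for the conditional viability model.
// Each block is linear -> ReLU -> batch normalization -> dropout; fusing the
// elementwise steps into one call avoids the R-level temporaries that
// dominate mini-batch training time. Large inputs are aliased, not copied.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
using namespace Rcpp;

static arma::mat view(SEXP m) {
  NumericMatrix nm(m);
  return arma::mat(nm.begin(), nm.nrow(), nm.ncol(), false, true);
}

static arma::rowvec rview(SEXP v) {
  NumericVector nv(v);
  return arma::rowvec(nv.begin(), nv.size(), false, true);
}

// mode: 1 = train, 0 = eval. Dropout draws from the R RNG so results are
// reproducible under set.seed(). The caller keeps `inp` for the backward
// pass; only newly computed arrays are returned.
// [[Rcpp::export]]
List block_fwd_cpp(SEXP inp_, SEXP W_, SEXP b_, bool batchnorm,
                   SEXP bng_, SEXP bnb_, SEXP run_mean_, SEXP run_var_,
                   double momentum, double eps, double dropout, int mode,
                   bool keep) {
  const arma::mat inp = view(inp_), W = view(W_);
  const arma::rowvec b = rview(b_);
  const arma::uword n = inp.n_rows;

  arma::mat z = inp * W;
  z.each_row() += b;
  arma::mat r = z;
  r.transform([](double v) { return v > 0 ? v : 0.0; });

  List out_list;
  arma::mat out;
  if (batchnorm) {
    const arma::rowvec bng = rview(bng_), bnb = rview(bnb_);
    arma::rowvec istd;
    if (mode == 1) {
      const arma::rowvec run_mean = rview(run_mean_), run_var = rview(run_var_);
      arma::rowvec mu = arma::mean(r, 0);
      arma::rowvec v = arma::mean(arma::square(r), 0) - arma::square(mu);
      istd = 1.0 / arma::sqrt(v + eps);
      r.each_row() -= mu;                    // r becomes xhat in place
      r.each_row() %= istd;
      out_list["bn_mean"] = (1 - momentum) * run_mean + momentum * mu;
      out_list["bn_var"] = (1 - momentum) * run_var + momentum * v;
    } else {
      istd = 1.0 / arma::sqrt(rview(run_var_) + eps);
      r.each_row() -= rview(run_mean_);
      r.each_row() %= istd;
    }
    if (keep) { out_list["xhat"] = r; out_list["istd"] = istd; }
    out = r;
    out.each_row() %= bng;
    out.each_row() += bnb;
  } else {
    out = std::move(r);
  }

  if (dropout > 0 && mode == 1) {
    RNGScope scope;
    arma::mat mask(n, out.n_cols);
    const double keep_p = 1.0 - dropout;
    for (arma::uword i = 0; i < mask.n_elem; ++i)
      mask(i) = (unif_rand() >= dropout) / keep_p;
    out %= mask;
    if (keep) out_list["mask"] = mask;
  }

  out_list["out"] = out;
  if (keep) out_list["z"] = z;
  return out_list;
}

// [[Rcpp::export]]
List block_bwd_cpp(SEXP dout_, SEXP inp_, SEXP z_, SEXP xhat_, SEXP istd_,
                   SEXP W_, SEXP bng_, bool batchnorm, int mode, SEXP mask_) {
  const arma::mat inp = view(inp_), z = view(z_), W = view(W_);
  arma::mat dout(view(dout_));               // own copy: never write R memory
  if (mask_ != R_NilValue) dout %= view(mask_);

  List grads;
  arma::mat dr;
  if (batchnorm) {
    const arma::mat xhat = view(xhat_);
    const arma::rowvec istd = rview(istd_), bng = rview(bng_);
    grads["dbng"] = arma::sum(dout % xhat, 0);
    grads["dbnb"] = arma::sum(dout, 0);
    if (mode == 1) {
      const double n = static_cast<double>(dout.n_rows);
      arma::mat dxhat = dout;
      dxhat.each_row() %= bng;
      const arma::rowvec s1 = arma::sum(dxhat, 0) / n;
      const arma::rowvec s2 = arma::sum(dxhat % xhat, 0) / n;
      dr = std::move(dxhat);
      dr.each_row() -= s1;
      dr -= xhat.each_row() % s2;
      dr.each_row() %= istd;
    } else {
      dr = dout;
      dr.each_row() %= (bng % istd);
    }
  } else {
    dr = dout;
  }

  arma::mat dz = dr % (z > 0);
  grads["dW"] = inp.t() * dz;
  grads["db"] = arma::sum(dz, 0);
  return List::create(_["dinp"] = dz * W.t(), _["grads"] = grads);
}

// FiLM conditioning: out = gam % h + bet with gam = ce*Wg + bg (or ones) and
// bet = ce*Wb + bb (or zeros), fused to avoid R temporaries.
// [[Rcpp::export]]
List film_fwd_cpp(SEXP h_, SEXP ce_, SEXP gamW_, SEXP gamb_, SEXP betW_,
                  SEXP betb_, bool keep) {
  const arma::mat h = view(h_);
  arma::mat gam, bet;
  if (gamW_ != R_NilValue) {
    gam = view(ce_) * view(gamW_);
    gam.each_row() += rview(gamb_);
  } else {
    gam.ones(h.n_rows, h.n_cols);
  }
  if (betW_ != R_NilValue) {
    bet = view(ce_) * view(betW_);
    bet.each_row() += rview(betb_);
  } else {
    bet.zeros(h.n_rows, h.n_cols);
  }
  arma::mat out = gam % h + bet;
  List res = List::create(_["out"] = out);
  if (keep) res["gam"] = gam;
  return res;
}
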