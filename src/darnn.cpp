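// Dual-attention encoder-decoder recurrent forecaster: fused forward /
// backward pass.  This is a compiled translation of the reference R
// implementation (darnn_forward / darnn_backward); the two are held equal
// by the test suite, and the R version's gradients are verified against
// finite differences.
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace arma;

static void softmax_rows_inplace(mat& e) {
  e.each_col() -= max(e, 1);
  e = exp(e);
  e.each_col() /= sum(e, 1);
}

static mat block_sum(const mat& big, uword B, uword blocks) {
  mat out(B, big.n_cols, fill::zeros);
  for (uword k = 0; k < blocks; ++k) out += big.rows(k * B, k * B + B - 1);
  return out;
}

// [[Rcpp::export]]
Rcpp::List darnn_pass_cpp(Rcpp::List params, Rcpp::NumericVector Xr,
                          arma::mat yhist, arma::vec label,
                          bool want_grad, bool want_alpha) {
  Rcpp::IntegerVector dims = Xr.attr("dim");
  uword B = dims[0], T = dims[1], n = dims[2];
  cube X(Xr.begin(), B, T, n, false);

  mat We = params["We"], Ue = params["Ue"], Wenc = params["Wenc"];
  mat Wd = params["Wd"], Ud = params["Ud"], Wdec = params["Wdec"];
  mat wt = params["wt"], Wy = params["Wy"];
  vec ve = params["ve"], benc = params["benc"], vd = params["vd"];
  vec bdec = params["bdec"], bw = params["bw"], vy = params["vy"];
  double bt = Rcpp::as<double>(params["bt"]);
  double bv = Rcpp::as<double>(params["bv"]);
  uword m = Wenc.n_rows / 4, p = Wdec.n_rows / 4;

  // ---------- encoder ----------
  mat Xstack(B * n, T);
  for (uword k = 0; k < n; ++k) Xstack.rows(k * B, k * B + B - 1) = X.slice(k);
  mat P = Xstack * Ue.t();

  mat h(B, m, fill::zeros), s(B, m, fill::zeros);
  cube Hc(B, m, T);                       // encoder hidden states
  cube M_c(want_grad ? B * n : 0, want_grad ? T : 0, want_grad ? T : 0);
  cube alpha_c(B, n, T), xtil_c(B, n, T);
  cube ei_c(B, m, T), ef_c(B, m, T), eo_c(B, m, T), eg_c(B, m, T);
  cube es_c(B, m, T), ets_c(B, m, T), ehprev_c(B, m, T), esprev_c(B, m, T);

  for (uword t = 0; t < T; ++t) {
    ehprev_c.slice(t) = h;
    esprev_c.slice(t) = s;
    mat q = join_rows(h, s) * We.t();                    // B x T
    mat M = tanh(P + repmat(q, n, 1));                   // (Bn) x T
    mat e = reshape(M * ve, B, n);
    softmax_rows_inplace(e);
    mat xt(B, n);
    for (uword k = 0; k < n; ++k) xt.col(k) = X.slice(k).col(t);
    mat xtil = e % xt;
    mat z = join_rows(xtil, h) * Wenc.t();
    z.each_row() += benc.t();
    mat ii = 1.0 / (1.0 + exp(-z.cols(0, m - 1)));
    mat ff = 1.0 / (1.0 + exp(-z.cols(m, 2 * m - 1)));
    mat oo = 1.0 / (1.0 + exp(-z.cols(2 * m, 3 * m - 1)));
    mat gg = tanh(z.cols(3 * m, 4 * m - 1));
    s = ff % s + ii % gg;
    mat ts = tanh(s);
    h = oo % ts;
    Hc.slice(t) = h;
    if (want_grad) M_c.slice(t) = M;
    alpha_c.slice(t) = e;
    xtil_c.slice(t) = xtil;
    ei_c.slice(t) = ii; ef_c.slice(t) = ff; eo_c.slice(t) = oo;
    eg_c.slice(t) = gg; es_c.slice(t) = s; ets_c.slice(t) = ts;
  }

  // ---------- decoder ----------
  mat Hmat(B * T, m);
  for (uword i = 0; i < T; ++i) Hmat.rows(i * B, i * B + B - 1) = Hc.slice(i);
  mat UH = Hmat * Ud.t();

  mat d(B, p, fill::zeros), sd(B, p, fill::zeros), ct(B, m, fill::zeros);
  cube Md_c(want_grad ? B * T : 0, want_grad ? m : 0, want_grad ? T : 0);
  cube beta_c(B, T, T), ct_c(B, m, T);
  cube di_c(B, p, T), df_c(B, p, T), do_c(B, p, T), dg_c(B, p, T);
  cube dsd_c(B, p, T), dtsd_c(B, p, T), ddprev_c(B, p, T), dsdprev_c(B, p, T);
  mat ytil_m(B, T);

  vec wt_y = vectorise(wt.cols(1, m));
  for (uword t = 0; t < T; ++t) {
    ddprev_c.slice(t) = d;
    dsdprev_c.slice(t) = sd;
    mat qd = join_rows(d, sd) * Wd.t();                  // B x m
    mat Md = tanh(UH + repmat(qd, T, 1));                // (BT) x m
    mat l = reshape(Md * vd, B, T);
    softmax_rows_inplace(l);
    ct.zeros();
    for (uword i = 0; i < T; ++i) {
      mat w = Hc.slice(i);
      w.each_col() %= l.col(i);
      ct += w;
    }
    vec ytil = yhist.col(t) * wt(0, 0) + ct * wt_y + bt;
    mat z = join_rows(ytil, d) * Wdec.t();
    z.each_row() += bdec.t();
    mat ii = 1.0 / (1.0 + exp(-z.cols(0, p - 1)));
    mat ff = 1.0 / (1.0 + exp(-z.cols(p, 2 * p - 1)));
    mat oo = 1.0 / (1.0 + exp(-z.cols(2 * p, 3 * p - 1)));
    mat gg = tanh(z.cols(3 * p, 4 * p - 1));
    sd = ff % sd + ii % gg;
    mat tsd = tanh(sd);
    d = oo % tsd;
    if (want_grad) Md_c.slice(t) = Md;
    beta_c.slice(t) = l;
    ct_c.slice(t) = ct;
    ytil_m.col(t) = ytil;
    di_c.slice(t) = ii; df_c.slice(t) = ff; do_c.slice(t) = oo;
    dg_c.slice(t) = gg; dsd_c.slice(t) = sd; dtsd_c.slice(t) = tsd;
  }

  mat u = join_rows(d, ct) * Wy.t();
  u.each_row() += bw.t();
  vec yhat = u * vy + bv;

  Rcpp::List out;
  out["yhat"] = yhat;
  if (want_alpha) out["alphas"] = alpha_c;
  if (!want_grad) return out;

  double loss = accu(square(yhat - label)) / B;
  out["loss"] = loss;
  vec dyhat = 2.0 * (yhat - label) / B;

  // ---------- backward: output layer ----------
  mat gWy(size(Wy), fill::zeros), gWd(size(Wd), fill::zeros);
  mat gUd(size(Ud), fill::zeros), gWdec(size(Wdec), fill::zeros);
  mat gwt(size(wt), fill::zeros), gWe(size(We), fill::zeros);
  mat gUe(size(Ue), fill::zeros), gWenc(size(Wenc), fill::zeros);
  vec gve(size(ve), fill::zeros), gvd(size(vd), fill::zeros);
  vec gbenc(size(benc), fill::zeros), gbdec(size(bdec), fill::zeros);
  vec gbw(size(bw), fill::zeros), gvy(size(vy), fill::zeros);
  double gbt = 0, gbv = 0;

  gvy = u.t() * dyhat;
  gbv = accu(dyhat);
  mat du = dyhat * vy.t();                               // B x p
  gWy = du.t() * join_rows(d, ct);
  gbw = sum(du, 0).t();
  mat ddc = du * Wy;
  mat dd = ddc.cols(0, p - 1);
  mat dcT_out = ddc.cols(p, p + m - 1);
  mat dsd_g(B, p, fill::zeros);

  cube dH(B, m, T, fill::zeros);
  mat dUH(B * T, m, fill::zeros);

  // ---------- decoder, reversed ----------
  for (uword t = T; t-- > 0;) {
    const mat& ii = di_c.slice(t); const mat& ff = df_c.slice(t);
    const mat& oo = do_c.slice(t); const mat& gg = dg_c.slice(t);
    const mat& tsd = dtsd_c.slice(t);
    mat do_g = dd % tsd;
    mat dsd_tot = dsd_g + dd % oo % (1.0 - square(tsd));
    mat dii = dsd_tot % gg;
    mat dff = dsd_tot % dsdprev_c.slice(t);
    mat dgg = dsd_tot % ii;
    dsd_g = dsd_tot % ff;
    mat dz = join_rows(join_rows(dii % ii % (1.0 - ii), dff % ff % (1.0 - ff)),
                       join_rows(do_g % oo % (1.0 - oo), dgg % (1.0 - square(gg))));
    gWdec += dz.t() * join_rows(ytil_m.col(t), ddprev_c.slice(t));
    gbdec += sum(dz, 0).t();
    mat dinp = dz * Wdec;
    vec dytil = dinp.col(0);
    dd = dinp.cols(1, p);
    // ytil = y_t wt0 + ct wt_y + bt
    gwt(0, 0) += dot(dytil, yhist.col(t));
    gwt.cols(1, m) += (ct_c.slice(t).t() * dytil).t();
    gbt += accu(dytil);
    mat dct = dytil * wt_y.t();                          // B x m
    if (t == T - 1) dct += dcT_out;
    // context backward
    mat dbeta(B, T);
    for (uword i = 0; i < T; ++i) {
      dbeta.col(i) = sum(dct % Hc.slice(i), 1);
      mat w = dct;
      w.each_col() %= beta_c.slice(t).col(i);
      dH.slice(i) += w;
    }
    const mat& beta = beta_c.slice(t);
    mat dl = dbeta;
    dl.each_col() -= sum(dbeta % beta, 1);
    dl %= beta;
    vec dlvec = vectorise(dl);
    const mat& Md = Md_c.slice(t);
    gvd += Md.t() * dlvec;
    mat dAd = (dlvec * vd.t()) % (1.0 - square(Md));
    mat dqd = block_sum(dAd, B, T);
    dUH += dAd;
    gWd += dqd.t() * join_rows(ddprev_c.slice(t), dsdprev_c.slice(t));
    mat dds = dqd * Wd;
    dd += dds.cols(0, p - 1);
    dsd_g += dds.cols(p, 2 * p - 1);
  }
  gUd = dUH.t() * Hmat;
  mat dHmat = dUH * Ud;
  for (uword i = 0; i < T; ++i) dH.slice(i) += dHmat.rows(i * B, i * B + B - 1);

  // ---------- encoder, reversed ----------
  mat dh(B, m, fill::zeros), ds(B, m, fill::zeros);
  mat dP(B * n, T, fill::zeros);
  for (uword t = T; t-- > 0;) {
    const mat& ii = ei_c.slice(t); const mat& ff = ef_c.slice(t);
    const mat& oo = eo_c.slice(t); const mat& gg = eg_c.slice(t);
    const mat& ts = ets_c.slice(t);
    mat dh_tot = dh + dH.slice(t);
    mat do_g = dh_tot % ts;
    mat ds_tot = ds + dh_tot % oo % (1.0 - square(ts));
    mat dii = ds_tot % gg;
    mat dff = ds_tot % esprev_c.slice(t);
    mat dgg = ds_tot % ii;
    ds = ds_tot % ff;
    mat dz = join_rows(join_rows(dii % ii % (1.0 - ii), dff % ff % (1.0 - ff)),
                       join_rows(do_g % oo % (1.0 - oo), dgg % (1.0 - square(gg))));
    gWenc += dz.t() * join_rows(xtil_c.slice(t), ehprev_c.slice(t));
    gbenc += sum(dz, 0).t();
    mat dinp = dz * Wenc;
    mat dxtil = dinp.cols(0, n - 1);
    dh = dinp.cols(n, n + m - 1);
    // attention backward
    mat xt(B, n);
    for (uword k = 0; k < n; ++k) xt.col(k) = X.slice(k).col(t);
    mat dalpha = dxtil % xt;
    const mat& alpha = alpha_c.slice(t);
    mat de = dalpha;
    de.each_col() -= sum(dalpha % alpha, 1);
    de %= alpha;
    vec devec = vectorise(de);
    const mat& M = M_c.slice(t);
    gve += M.t() * devec;
    mat dA = (devec * ve.t()) % (1.0 - square(M));
    mat dq = block_sum(dA, B, n);
    dP += dA;
    gWe += dq.t() * join_rows(ehprev_c.slice(t), esprev_c.slice(t));
    mat dhs = dq * We;
    dh += dhs.cols(0, m - 1);
    ds += dhs.cols(m, 2 * m - 1);
  }
  gUe = dP.t() * Xstack;

  Rcpp::List g;
  g["We"] = gWe; g["Ue"] = gUe; g["ve"] = gve;
  g["Wenc"] = gWenc; g["benc"] = gbenc;
  g["Wd"] = gWd; g["Ud"] = gUd; g["vd"] = gvd;
  g["Wdec"] = gWdec; g["bdec"] = gbdec;
  g["wt"] = gwt; g["bt"] = gbt;
  g["Wy"] = gWy; g["bw"] = gbw; g["vy"] = gvy; g["bv"] = gbv;
  out["grads"] = g;
  return out;
}
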