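// Compiled kernels for the ViT encoder: fused forward / loss / backward for
// the contrastive training step, and a plain forward pass for embedding
// extraction. Mirrors the base-R reference implementation (encForward /
// encBackward), which the test suite uses as an independent oracle.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace arma;

struct LnCache {
  mat xhat;
  vec invstd;
};

static mat layer_norm_fwd(const mat& x, const rowvec& g, const rowvec& b,
                          LnCache& cc, double eps = 1e-5) {
  vec mu = mean(x, 1);
  mat xc = x.each_col() - mu;
  vec v = mean(square(xc), 1);
  cc.invstd = 1.0 / sqrt(v + eps);
  cc.xhat = xc.each_col() % cc.invstd;
  mat y = cc.xhat.each_row() % g;
  y.each_row() += b;
  return y;
}

static mat layer_norm_bwd(const mat& dy, const LnCache& cc, const rowvec& g,
                          rowvec& dg, rowvec& db) {
  dg = sum(dy % cc.xhat, 0);
  db = sum(dy, 0);
  mat dxhat = dy.each_row() % g;
  vec m1 = mean(dxhat, 1);
  vec m2 = mean(dxhat % cc.xhat, 1);
  mat dx = dxhat;
  dx.each_col() -= m1;
  dx -= cc.xhat.each_col() % m2;
  dx.each_col() %= cc.invstd;
  return dx;
}

struct LayerCache {
  LnCache ln1, ln2;
  mat Xn, Q, K, V, O, H0, H, ln2y;
  std::vector<mat> probs;  // one softmax matrix per (subject, head)
};

struct FwdCache {
  std::vector<LayerCache> layers;
  LnCache lnF;
  mat pooled, H1pre, H1, U, Z;
  vec un;
};

static mat get_m(const Rcpp::List& p, const std::string& nm) {
  return Rcpp::as<mat>(p[nm]);
}
static rowvec get_rv(const Rcpp::List& p, const std::string& nm) {
  return Rcpp::as<rowvec>(p[nm]);
}
static std::string lyr(int l, const char* nm) {
  return "L" + std::to_string(l + 1) + "_" + nm;
}

// forward through the trunk (and optionally projection head); fills cache
// when requested
static mat forward_core(const Rcpp::List& params, const mat& tokens, int n,
                        int depth, int heads, bool project, bool withCache,
                        FwdCache& cache, mat& patchEmbOut) {
  const int rowsTot = tokens.n_rows;
  const int P = rowsTot / n;
  mat X = tokens * get_m(params, "patchW");
  X.each_row() += get_rv(params, "patchB");
  mat pos = get_m(params, "posEmb");
  for (int s = 0; s < n; ++s)
    X.rows(s * P, (s + 1) * P - 1) += pos;
  const int w = X.n_cols;
  const int dh = w / heads;
  const double scale = 1.0 / std::sqrt((double)dh);
  if (withCache) cache.layers.resize(depth);

  for (int l = 0; l < depth; ++l) {
    LayerCache tmp;
    LayerCache& cc = withCache ? cache.layers[l] : tmp;
    mat Xn = layer_norm_fwd(X, get_rv(params, lyr(l, "ln1g")),
                            get_rv(params, lyr(l, "ln1b")), cc.ln1);
    mat Q = Xn * get_m(params, lyr(l, "Wq"));
    Q.each_row() += get_rv(params, lyr(l, "bq"));
    mat K = Xn * get_m(params, lyr(l, "Wk"));
    K.each_row() += get_rv(params, lyr(l, "bk"));
    mat V = Xn * get_m(params, lyr(l, "Wv"));
    V.each_row() += get_rv(params, lyr(l, "bv"));
    mat O(rowsTot, w, fill::zeros);
    if (withCache) cc.probs.resize(n * heads);
    for (int s = 0; s < n; ++s) {
      const int r0 = s * P, r1 = (s + 1) * P - 1;
      for (int h = 0; h < heads; ++h) {
        const int c0 = h * dh, c1 = (h + 1) * dh - 1;
        mat S = Q.submat(r0, c0, r1, c1) * K.submat(r0, c0, r1, c1).t();
        S *= scale;
        vec mx = max(S, 1);
        S.each_col() -= mx;
        mat E = exp(S);
        vec rs = sum(E, 1);
        E.each_col() /= rs;
        O.submat(r0, c0, r1, c1) = E * V.submat(r0, c0, r1, c1);
        if (withCache) cc.probs[s * heads + h] = std::move(E);
      }
    }
    mat A = O * get_m(params, lyr(l, "Wo"));
    A.each_row() += get_rv(params, lyr(l, "bo"));
    mat X1 = X + A;
    mat ln2y = layer_norm_fwd(X1, get_rv(params, lyr(l, "ln2g")),
                              get_rv(params, lyr(l, "ln2b")), cc.ln2);
    mat H0 = ln2y * get_m(params, lyr(l, "W1"));
    H0.each_row() += get_rv(params, lyr(l, "b1"));
    mat H = H0 % normcdf(H0);
    mat M = H * get_m(params, lyr(l, "W2"));
    M.each_row() += get_rv(params, lyr(l, "b2"));
    if (withCache) {
      cc.Xn = std::move(Xn); cc.Q = std::move(Q); cc.K = std::move(K);
      cc.V = std::move(V); cc.O = std::move(O); cc.H0 = std::move(H0);
      cc.H = std::move(H); cc.ln2y = std::move(ln2y);
      X = X1 + M;
      // keep X1 via ln2 cache (xhat/invstd suffice for backward)
    } else {
      X = X1 + M;
    }
  }
  LnCache tmpF;
  LnCache& ccF = withCache ? cache.lnF : tmpF;
  mat patchEmb = layer_norm_fwd(X, get_rv(params, "lnFg"),
                                get_rv(params, "lnFb"), ccF);
  patchEmbOut = patchEmb;
  if (!project) return mat();

  mat pooled(n, w);
  for (int s = 0; s < n; ++s)
    pooled.row(s) = mean(patchEmb.rows(s * P, (s + 1) * P - 1), 0);
  mat H1pre = pooled * get_m(params, "projW1");
  H1pre.each_row() += get_rv(params, "projB1");
  mat H1 = clamp(H1pre, 0.0, datum::inf);
  mat U = H1 * get_m(params, "projW2");
  U.each_row() += get_rv(params, "projB2");
  vec un = sqrt(sum(square(U), 1));
  if (un.min() < 1e-12)
    Rcpp::stop("projection produced a (near-)zero vector; cannot normalize");
  mat Z = U.each_col() / un;
  if (withCache) {
    cache.pooled = std::move(pooled);
    cache.H1pre = std::move(H1pre);
    cache.H1 = std::move(H1);
    cache.U = U;
    cache.un = un;
    cache.Z = Z;
  }
  return Z;
}

// [[Rcpp::export(name = ".encForwardCpp")]]
Rcpp::List enc_forward_cpp(Rcpp::List params, const arma::mat& tokens, int n,
                           int depth, int heads, bool project) {
  FwdCache cache;
  mat patchEmb;
  mat Z = forward_core(params, tokens, n, depth, heads, project, false,
                       cache, patchEmb);
  if (!project) return Rcpp::List::create(Rcpp::Named("patchEmb") = patchEmb);
  return Rcpp::List::create(Rcpp::Named("patchEmb") = patchEmb,
                            Rcpp::Named("z") = Z);
}

// fused: forward with cache, InfoNCE loss (positives kPos, negatives from
// the queue), backward to parameter gradients. lossScale multiplies both
// the returned loss's gradient contribution (the loss itself is returned
// unscaled).
// [[Rcpp::export(name = ".encLossGradCpp")]]
Rcpp::List enc_loss_grad_cpp(Rcpp::List params, const arma::mat& tokens,
                             int n, int depth, int heads,
                             const arma::mat& kPos, const arma::mat& negatives,
                             double tau, double lossScale) {
  FwdCache cache;
  mat patchEmb;
  mat Z = forward_core(params, tokens, n, depth, heads, true, true, cache,
                       patchEmb);
  const int B = Z.n_rows;
  const int rowsTot = tokens.n_rows;
  const int P = rowsTot / n;
  const int w = patchEmb.n_cols;
  const int dh = w / heads;
  const double scale = 1.0 / std::sqrt((double)dh);

  // InfoNCE with log-sum-exp stabilization
  vec posLogit = sum(Z % kPos, 1) / tau;
  mat allLogit = join_rows(posLogit, Z * negatives.t() / tau);
  vec mx = max(allLogit, 1);
  vec lse = mx + log(sum(exp(allLogit.each_col() - mx), 1));
  double loss = mean(lse - posLogit);
  mat prob = exp(allLogit.each_col() - lse);
  mat dZ = (kPos.each_col() % (prob.col(0) - 1.0)) +
    prob.cols(1, prob.n_cols - 1) * negatives;
  dZ *= lossScale / (tau * (double)B);

  Rcpp::List g;
  // through L2 normalization
  mat dU = dZ - (cache.Z.each_col() % sum(cache.Z % dZ, 1));
  dU.each_col() /= cache.un;
  g["projB2"] = sum(dU, 0);
  g["projW2"] = cache.H1.t() * dU;
  mat dH1 = dU * get_m(params, "projW2").t();
  dH1 %= conv_to<mat>::from(cache.H1pre > 0);
  g["projB1"] = sum(dH1, 0);
  g["projW1"] = cache.pooled.t() * dH1;
  mat dPooled = dH1 * get_m(params, "projW1").t();
  mat dPatchEmb(rowsTot, w);
  for (int s = 0; s < n; ++s)
    dPatchEmb.rows(s * P, (s + 1) * P - 1) =
      repmat(dPooled.row(s) / (double)P, P, 1);

  rowvec dg, db;
  mat dX = layer_norm_bwd(dPatchEmb, cache.lnF, get_rv(params, "lnFg"),
                          dg, db);
  g["lnFg"] = dg; g["lnFb"] = db;

  for (int l = depth - 1; l >= 0; --l) {
    LayerCache& cc = cache.layers[l];
    // MLP block
    g[lyr(l, "b2")] = sum(dX, 0);
    g[lyr(l, "W2")] = cc.H.t() * dX;
    mat dH = dX * get_m(params, lyr(l, "W2")).t();
    mat dH0 = dH % (normcdf(cc.H0) + cc.H0 % normpdf(cc.H0));
    g[lyr(l, "b1")] = sum(dH0, 0);
    g[lyr(l, "W1")] = cc.ln2y.t() * dH0;
    mat dLn2y = dH0 * get_m(params, lyr(l, "W1")).t();
    mat dX1 = layer_norm_bwd(dLn2y, cc.ln2, get_rv(params, lyr(l, "ln2g")),
                             dg, db);
    g[lyr(l, "ln2g")] = dg; g[lyr(l, "ln2b")] = db;
    dX1 += dX;
    // attention block
    g[lyr(l, "bo")] = sum(dX1, 0);
    g[lyr(l, "Wo")] = cc.O.t() * dX1;
    mat dO = dX1 * get_m(params, lyr(l, "Wo")).t();
    mat dQ(rowsTot, w, fill::zeros), dK(rowsTot, w, fill::zeros),
        dV(rowsTot, w, fill::zeros);
    for (int s = 0; s < n; ++s) {
      const int r0 = s * P, r1 = (s + 1) * P - 1;
      for (int h = 0; h < heads; ++h) {
        const int c0 = h * dh, c1 = (h + 1) * dh - 1;
        const mat& Pr = cc.probs[s * heads + h];
        mat dOs = dO.submat(r0, c0, r1, c1);
        mat dPr = dOs * cc.V.submat(r0, c0, r1, c1).t();
        dV.submat(r0, c0, r1, c1) = Pr.t() * dOs;
        dPr.each_col() -= sum(dPr % Pr, 1);
        mat dS = Pr % dPr;
        dQ.submat(r0, c0, r1, c1) = dS * cc.K.submat(r0, c0, r1, c1) * scale;
        dK.submat(r0, c0, r1, c1) =
          dS.t() * cc.Q.submat(r0, c0, r1, c1) * scale;
      }
    }
    g[lyr(l, "bq")] = sum(dQ, 0);
    g[lyr(l, "bk")] = sum(dK, 0);
    g[lyr(l, "bv")] = sum(dV, 0);
    g[lyr(l, "Wq")] = cc.Xn.t() * dQ;
    g[lyr(l, "Wk")] = cc.Xn.t() * dK;
    g[lyr(l, "Wv")] = cc.Xn.t() * dV;
    mat dXn = dQ * get_m(params, lyr(l, "Wq")).t() +
      dK * get_m(params, lyr(l, "Wk")).t() +
      dV * get_m(params, lyr(l, "Wv")).t();
    mat dXfromLn = layer_norm_bwd(dXn, cc.ln1, get_rv(params, lyr(l, "ln1g")),
                                  dg, db);
    g[lyr(l, "ln1g")] = dg; g[lyr(l, "ln1b")] = db;
    dX = dX1 + dXfromLn;
  }
  mat posGrad(get_m(params, "posEmb").n_rows, dX.n_cols, fill::zeros);
  for (int s = 0; s < n; ++s)
    posGrad += dX.rows(s * P, (s + 1) * P - 1);
  g["posEmb"] = posGrad;
  g["patchB"] = sum(dX, 0);
  g["patchW"] = tokens.t() * dX;

  return Rcpp::List::create(Rcpp::Named("loss") = loss,
                            Rcpp::Named("z") = Z,
                            Rcpp::Named("grads") = g);
}
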