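// MS-TCN++ temporal segmentation model: forward pass, backpropagation and
// Adam training loop. Parameters travel as a flat ordered R list built by
// build_mstcn_pp(); the order here must match the R constructor exactly.
//
// Layout (C channels x T frames everywhere):
//   [bn gamma, bn beta]                                  (if input_batchnorm)
//   prediction-generation stage:
//     in_W (HxD), in_b
//     L dual-dilated layers: Wa0,Wa1,Wa2,ba (dilation 2^l),
//                            Wb0,Wb1,Wb2,bb (dilation 2^(L-1-l)),
//                            Wf (Hx2H), bf
//     out_W (CxH), out_b
//   S-1 refinement stages (input = softmax of previous stage):
//     in_W (HxC), in_b
//     L residual layers: W0,W1,W2,b (dilation 2^l), Wf (HxH), bf
//     out_W, out_b

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;
using namespace arma;

namespace {

struct Par {
  mat W, G, M, V;
  explicit Par(const mat& w) : W(w) {
    G.zeros(size(W)); M.zeros(size(W)); V.zeros(size(W));
  }
};

struct Cfg {
  int L, S, H, C, D;
  bool bn;
  double lr, lambda, tau;
  int epochs, patience;
};

struct Net {
  Cfg cfg;
  std::vector<Par> par;
  vec run_mean, run_var;

  Net(List params, const Cfg& c, vec rmean, vec rvar)
      : cfg(c), run_mean(rmean), run_var(rvar) {
    par.reserve(params.size());
    for (int i = 0; i < params.size(); ++i) {
      par.emplace_back(as<mat>(params[i]));
    }
    if ((int)par.size() != expected_count()) {
      stop("parameter list has wrong length");
    }
  }

  int expected_count() const {
    int n = cfg.bn ? 2 : 0;
    n += 2 + cfg.L * 10 + 2;              // PG stage
    n += (cfg.S - 1) * (2 + cfg.L * 6 + 2);  // refinement stages
    return n;
  }

  List export_params() const {
    List out(par.size());
    for (size_t i = 0; i < par.size(); ++i) out[i] = wrap(par[i].W);
    return out;
  }
};

void dconv_fwd(const mat& X, const mat& W0, const mat& W1, const mat& W2,
               const vec& b, int d, mat& Y) {
  const int T = X.n_cols;
  Y = W1 * X;
  Y.each_col() += b;
  if (T > d) {
    Y.cols(d, T - 1) += W0 * X.cols(0, T - 1 - d);
    Y.cols(0, T - 1 - d) += W2 * X.cols(d, T - 1);
  }
}

void dconv_bwd(const mat& X, const mat& dY, const mat& W0, const mat& W1,
               const mat& W2, mat& dW0, mat& dW1, mat& dW2, mat& db,
               mat& dX, int d) {
  const int T = X.n_cols;
  dW1 += dY * X.t();
  db += sum(dY, 1);
  dX += W1.t() * dY;
  if (T > d) {
    dW0 += dY.cols(d, T - 1) * X.cols(0, T - 1 - d).t();
    dW2 += dY.cols(0, T - 1 - d) * X.cols(d, T - 1).t();
    dX.cols(0, T - 1 - d) += W0.t() * dY.cols(d, T - 1);
    dX.cols(d, T - 1) += W2.t() * dY.cols(0, T - 1 - d);
  }
}

struct DualCache { mat Hin, A, B, Fpre; };
struct RefCache { mat Hin, Z, A; };
struct StageCache {
  mat X, Hfinal, logits, P, logp;
  std::vector<DualCache> dual;
  std::vector<RefCache> ref;
};

struct BnCache { vec mu, inv_std; mat xhat; };

void softmax_logp(const mat& logits, mat& logp, mat& P) {
  rowvec mx = max(logits, 0);
  logp = logits;
  logp.each_row() -= mx;
  rowvec lse = log(sum(exp(logp), 0));
  logp.each_row() -= lse;
  P = exp(logp);
}

// forward one stage; pi = cursor into net.par
void stage_forward(Net& net, size_t& pi, const mat& X, bool is_pg,
                   StageCache& cache) {
  const Cfg& c = net.cfg;
  cache.X = X;
  const mat& inW = net.par[pi].W; const mat& inb = net.par[pi + 1].W;
  pi += 2;
  mat H = inW * X;
  H.each_col() += vec(inb.col(0));
  if (is_pg) {
    cache.dual.resize(c.L);
    for (int l = 0; l < c.L; ++l) {
      DualCache& dc = cache.dual[l];
      dc.Hin = H;
      int d1 = 1 << l;
      int d2 = 1 << (c.L - 1 - l);
      const mat& Wa0 = net.par[pi].W; const mat& Wa1 = net.par[pi + 1].W;
      const mat& Wa2 = net.par[pi + 2].W; const vec ba = net.par[pi + 3].W.col(0);
      const mat& Wb0 = net.par[pi + 4].W; const mat& Wb1 = net.par[pi + 5].W;
      const mat& Wb2 = net.par[pi + 6].W; const vec bb = net.par[pi + 7].W.col(0);
      const mat& Wf = net.par[pi + 8].W; const vec bf = net.par[pi + 9].W.col(0);
      pi += 10;
      dconv_fwd(dc.Hin, Wa0, Wa1, Wa2, ba, d1, dc.A);
      dconv_fwd(dc.Hin, Wb0, Wb1, Wb2, bb, d2, dc.B);
      dc.Fpre = Wf * join_cols(dc.A, dc.B);
      dc.Fpre.each_col() += bf;
      H = dc.Hin + clamp(dc.Fpre, 0.0, datum::inf);
    }
  } else {
    cache.ref.resize(c.L);
    for (int l = 0; l < c.L; ++l) {
      RefCache& rc = cache.ref[l];
      rc.Hin = H;
      int d = 1 << l;
      const mat& W0 = net.par[pi].W; const mat& W1 = net.par[pi + 1].W;
      const mat& W2 = net.par[pi + 2].W; const vec b = net.par[pi + 3].W.col(0);
      const mat& Wf = net.par[pi + 4].W; const vec bf = net.par[pi + 5].W.col(0);
      pi += 6;
      dconv_fwd(rc.Hin, W0, W1, W2, b, d, rc.Z);
      rc.A = clamp(rc.Z, 0.0, datum::inf);
      mat Fo = Wf * rc.A;
      Fo.each_col() += bf;
      H = rc.Hin + Fo;
    }
  }
  cache.Hfinal = H;
  const mat& outW = net.par[pi].W; const vec outb = net.par[pi + 1].W.col(0);
  pi += 2;
  cache.logits = outW * H;
  cache.logits.each_col() += outb;
  softmax_logp(cache.logits, cache.logp, cache.P);
}

// backward one stage given dlogits; returns gradient w.r.t. the stage input
mat stage_backward(Net& net, size_t pi_start, const StageCache& cache,
                   bool is_pg, const mat& dlogits) {
  const Cfg& c = net.cfg;
  size_t pi = pi_start;
  size_t i_in = pi; pi += 2;
  std::vector<size_t> layer_idx(c.L);
  for (int l = 0; l < c.L; ++l) { layer_idx[l] = pi; pi += is_pg ? 10 : 6; }
  size_t i_out = pi;

  net.par[i_out].G += dlogits * cache.Hfinal.t();
  net.par[i_out + 1].G += sum(dlogits, 1);
  mat dH = net.par[i_out].W.t() * dlogits;

  for (int l = c.L - 1; l >= 0; --l) {
    size_t q = layer_idx[l];
    if (is_pg) {
      const DualCache& dc = cache.dual[l];
      int d1 = 1 << l;
      int d2 = 1 << (c.L - 1 - l);
      mat dF = dH % conv_to<mat>::from(dc.Fpre > 0.0);
      net.par[q + 8].G += dF * join_cols(dc.A, dc.B).t();
      net.par[q + 9].G += sum(dF, 1);
      mat dAB = net.par[q + 8].W.t() * dF;
      mat dA = dAB.rows(0, c.H - 1);
      mat dB = dAB.rows(c.H, 2 * c.H - 1);
      mat dHin = dH;  // residual path
      dconv_bwd(dc.Hin, dA, net.par[q].W, net.par[q + 1].W, net.par[q + 2].W,
                net.par[q].G, net.par[q + 1].G, net.par[q + 2].G,
                net.par[q + 3].G, dHin, d1);
      dconv_bwd(dc.Hin, dB, net.par[q + 4].W, net.par[q + 5].W, net.par[q + 6].W,
                net.par[q + 4].G, net.par[q + 5].G, net.par[q + 6].G,
                net.par[q + 7].G, dHin, d2);
      dH = dHin;
    } else {
      const RefCache& rc = cache.ref[l];
      int d = 1 << l;
      net.par[q + 4].G += dH * rc.A.t();
      net.par[q + 5].G += sum(dH, 1);
      mat dA = net.par[q + 4].W.t() * dH;
      mat dZ = dA % conv_to<mat>::from(rc.Z > 0.0);
      mat dHin = dH;  // residual path
      dconv_bwd(rc.Hin, dZ, net.par[q].W, net.par[q + 1].W, net.par[q + 2].W,
                net.par[q].G, net.par[q + 1].G, net.par[q + 2].G,
                net.par[q + 3].G, dHin, d);
      dH = dHin;
    }
  }
  net.par[i_in].G += dH * cache.X.t();
  net.par[i_in + 1].G += sum(dH, 1);
  return net.par[i_in].W.t() * dH;
}

size_t stage_param_offset(const Cfg& c, int s) {
  size_t off = c.bn ? 2 : 0;
  if (s > 0) off += 2 + c.L * 10 + 2;
  if (s > 1) off += (size_t)(s - 1) * (2 + c.L * 6 + 2);
  return off;
}

// forward the whole network; fills caches; returns nothing (caches hold all)
void net_forward(Net& net, const mat& Xraw, bool training,
                 std::vector<StageCache>& caches, BnCache& bnc, mat& Xin) {
  const Cfg& c = net.cfg;
  const double eps = 1e-5, momentum = 0.1;
  if (c.bn) {
    const vec gamma = net.par[0].W.col(0);
    const vec beta = net.par[1].W.col(0);
    vec mu, var;
    if (training) {
      mu = mean(Xraw, 1);
      var = mean(square(Xraw.each_col() - mu), 1);
      net.run_mean = (1 - momentum) * net.run_mean + momentum * mu;
      net.run_var = (1 - momentum) * net.run_var + momentum * var;
    } else {
      mu = net.run_mean;
      var = net.run_var;
    }
    bnc.mu = mu;
    bnc.inv_std = 1.0 / sqrt(var + eps);
    bnc.xhat = Xraw.each_col() - mu;
    bnc.xhat.each_col() %= bnc.inv_std;
    Xin = bnc.xhat.each_col() % gamma;
    Xin.each_col() += beta;
  } else {
    Xin = Xraw;
  }
  caches.resize(c.S);
  size_t pi = c.bn ? 2 : 0;
  stage_forward(net, pi, Xin, true, caches[0]);
  for (int s = 1; s < c.S; ++s) {
    stage_forward(net, pi, caches[s - 1].P, false, caches[s]);
  }
}

// loss value + gradient w.r.t. one stage's logits (cross-entropy +
// lambda * truncated MSE on adjacent log-probability differences,
// previous frame detached)
double stage_loss_grad(const StageCache& sc, const uvec& y, double lambda,
                       double tau, mat& dlogits) {
  const int T = sc.logits.n_cols;
  const int C = sc.logits.n_rows;
  double ce = 0.0;
  dlogits = sc.P / (double)T;
  for (int t = 0; t < T; ++t) {
    ce -= sc.logp(y[t], t);
    dlogits(y[t], t) -= 1.0 / (double)T;
  }
  ce /= (double)T;
  double tmse = 0.0;
  if (T >= 2 && lambda > 0) {
    mat Dlp = sc.logp.cols(1, T - 1) - sc.logp.cols(0, T - 2);
    mat Ab = abs(Dlp);
    mat clamped = min(Ab, mat(size(Ab)).fill(tau));
    double denom = (double)C * (double)(T - 1);
    tmse = accu(square(clamped)) / denom;
    mat dlogp(C, T, fill::zeros);
    dlogp.cols(1, T - 1) =
        (2.0 * lambda / denom) * (Dlp % conv_to<mat>::from(Ab < tau));
    // d(logp)/d(logits) through log-softmax
    rowvec colsum = sum(dlogp, 0);
    dlogits += dlogp - sc.P.each_row() % colsum;
  }
  return ce + lambda * tmse;
}

// full backward; returns total loss
double net_backward(Net& net, const uvec& y, const std::vector<StageCache>& caches,
                    const BnCache& bnc, const mat& Xraw) {
  const Cfg& c = net.cfg;
  double total = 0.0;
  mat dP_next;  // gradient w.r.t. softmax output feeding stage s+1
  mat dXin;
  for (int s = c.S - 1; s >= 0; --s) {
    const StageCache& sc = caches[s];
    mat dlogits;
    total += stage_loss_grad(sc, y, c.lambda, c.tau, dlogits);
    if (s < c.S - 1) {
      // softmax backward from the next stage's input gradient
      rowvec inner = sum(sc.P % dP_next, 0);
      dlogits += sc.P % dP_next - sc.P.each_row() % inner;
    }
    mat dX = stage_backward(net, stage_param_offset(c, s), sc, s == 0, dlogits);
    if (s > 0) dP_next = dX; else dXin = dX;
  }
  if (c.bn) {
    const vec gamma = net.par[0].W.col(0);
    const int T = Xraw.n_cols;
    net.par[0].G += sum(dXin % bnc.xhat, 1);
    net.par[1].G += sum(dXin, 1);
    mat dxhat = dXin.each_col() % gamma;
    // (input gradient itself is discarded; kept for completeness of BN update)
    (void)T;
  }
  return total;
}

void adam_step(Net& net, int t, double lr) {
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  const double c1 = 1.0 - std::pow(b1, t);
  const double c2 = 1.0 - std::pow(b2, t);
  for (auto& p : net.par) {
    p.M = b1 * p.M + (1 - b1) * p.G;
    p.V = b2 * p.V + (1 - b2) * (p.G % p.G);
    p.W -= lr * (p.M / c1) / (sqrt(p.V / c2) + eps);
    p.G.zeros();
  }
}

Cfg parse_cfg(List cfg) {
  Cfg c;
  c.L = as<int>(cfg["L"]); c.S = as<int>(cfg["S"]);
  c.H = as<int>(cfg["hidden_width"]); c.C = as<int>(cfg["n_classes"]);
  c.D = as<int>(cfg["input_dim"]); c.bn = as<bool>(cfg["input_batchnorm"]);
  c.lr = as<double>(cfg["lr"]); c.lambda = as<double>(cfg["lambda_smooth"]);
  c.tau = as<double>(cfg["tau"]);
  c.epochs = as<int>(cfg["epochs"]); c.patience = as<int>(cfg["patience"]);
  return c;
}

}  // namespace

// [[Rcpp::export]]
List cpp_mstcn_forward(List params, List cfg, arma::mat X,
                       arma::vec run_mean, arma::vec run_var) {
  Cfg c = parse_cfg(cfg);
  Net net(params, c, run_mean, run_var);
  std::vector<StageCache> caches;
  BnCache bnc;
  mat Xin;
  net_forward(net, X, false, caches, bnc, Xin);
  List out(c.S);
  for (int s = 0; s < c.S; ++s) out[s] = wrap(mat(caches[s].logits.t()));
  return out;
}

// [[Rcpp::export]]
List cpp_mstcn_lossgrad(List params, List cfg, arma::mat X,
                        arma::uvec y) {
  Cfg c = parse_cfg(cfg);
  Net net(params, c, as<vec>(cfg["run_mean"]), as<vec>(cfg["run_var"]));
  std::vector<StageCache> caches;
  BnCache bnc;
  mat Xin;
  net_forward(net, X, true, caches, bnc, Xin);
  double loss = net_backward(net, y, caches, bnc, X);
  List grads(net.par.size());
  for (size_t i = 0; i < net.par.size(); ++i) grads[i] = wrap(net.par[i].G);
  return List::create(_["loss"] = loss, _["grads"] = grads);
}

// [[Rcpp::export]]
List cpp_mstcn_train(List params, List cfg, List X_train, List y_train,
                     List X_val, List y_val) {
  Cfg c = parse_cfg(cfg);
  Net net(params, c, as<vec>(cfg["run_mean"]), as<vec>(cfg["run_var"]));
  const int n_train = X_train.size();
  const int n_val = X_val.size();
  if (n_train == 0) stop("empty training set");

  std::vector<mat> Xtr(n_train), Xva(n_val);
  std::vector<uvec> ytr(n_train), yva(n_val);
  for (int i = 0; i < n_train; ++i) {
    Xtr[i] = as<mat>(X_train[i]);
    ytr[i] = as<uvec>(y_train[i]);
  }
  for (int i = 0; i < n_val; ++i) {
    Xva[i] = as<mat>(X_val[i]);
    yva[i] = as<uvec>(y_val[i]);
  }

  std::vector<mat> best;
  vec best_rmean = net.run_mean, best_rvar = net.run_var;
  double best_score = -datum::inf;  // val accuracy (or -train loss)
  int best_epoch = 0, bad = 0, adam_t = 0;
  std::vector<double> log_loss, log_val;

  std::vector<StageCache> caches;
  BnCache bnc;
  mat Xin;

  for (int epoch = 1; epoch <= c.epochs; ++epoch) {
    double epoch_loss = 0.0;
    for (int i = 0; i < n_train; ++i) {
      net_forward(net, Xtr[i], true, caches, bnc, Xin);
      double loss = net_backward(net, ytr[i], caches, bnc, Xtr[i]);
      if (!std::isfinite(loss)) stop("non-finite training loss (diverged)");
      epoch_loss += loss;
      adam_step(net, ++adam_t, c.lr);
    }
    epoch_loss /= n_train;

    double score;
    double val_acc = NA_REAL;
    if (n_val > 0) {
      double acc_sum = 0.0;
      for (int i = 0; i < n_val; ++i) {
        net_forward(net, Xva[i], false, caches, bnc, Xin);
        const mat& lg = caches[c.S - 1].logits;
        ucolvec pred = index_max(lg, 0).t();
        acc_sum += (double)accu(pred == yva[i]) / (double)yva[i].n_elem;
      }
      val_acc = acc_sum / n_val;
      score = val_acc;
    } else {
      score = -epoch_loss;
    }
    log_loss.push_back(epoch_loss);
    log_val.push_back(val_acc);

    if (score > best_score + 1e-12) {
      best_score = score;
      best_epoch = epoch;
      best.clear();
      for (auto& p : net.par) best.push_back(p.W);
      best_rmean = net.run_mean;
      best_rvar = net.run_var;
      bad = 0;
    } else {
      ++bad;
      if (bad > c.patience) break;
    }
  }

  List out_params(best.size());
  for (size_t i = 0; i < best.size(); ++i) out_params[i] = wrap(best[i]);
  return List::create(
      _["params"] = out_params,
      _["run_mean"] = wrap(best_rmean),
      _["run_var"] = wrap(best_rvar),
      _["best_epoch"] = best_epoch,
      _["train_loss"] = wrap(log_loss),
      _["val_accuracy"] = wrap(log_val));
}
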