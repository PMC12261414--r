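// Training core for hierarchical attention MIL models.
//
// The computation graph is small and fixed (1-2 dense layers, two nested
// softmax attention levels, linear head), so gradients are derived by hand
// and the whole fit loop lives here; all randomness (batch shuffling) goes
// through R's RNG so fits are reproducible from set.seed() alone.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

enum Mode { CTA = 0, HA = 1, MEAN_POOL = 2, CELL_ATT = 3 };
enum Nonlin { RELU = 0, TANH = 1 };

// Parameter vector layout (all stored as arma::mat):
//  0 Wx1 (d x m), 1 bx1 (d x 1),
//  [2 Wx2 (d x d), 3 bx2 (d x 1)]          when nLayers == 2
//  then w (d x 1), b (1 x 1), v (d x 1), bprime (1 x 1),
//  then head: binary  -> wbar (d x 1), bbar (1 x 1)
//             multi   -> W (C x d),    bhead (C x 1)
struct Net {
  int mode, nLayers, d, m, C, nonlin;
  bool binary;
  int iW2, iB2, iw, ib, iv, ibp, ih1, ih2; // indices into param vector
  int nPar;
};

Net makeNet(const List& cfg) {
  Net net;
  net.mode    = as<int>(cfg["mode"]);
  net.nLayers = as<int>(cfg["nLayers"]);
  net.d       = as<int>(cfg["d"]);
  net.m       = as<int>(cfg["m"]);
  net.C       = as<int>(cfg["C"]);
  net.nonlin  = as<int>(cfg["nonlin"]);
  net.binary  = as<bool>(cfg["binary"]);
  int k = 2;
  if (net.nLayers == 2) { net.iW2 = k++; net.iB2 = k++; } else { net.iW2 = net.iB2 = -1; }
  net.iw = k++; net.ib = k++; net.iv = k++; net.ibp = k++;
  net.ih1 = k++; net.ih2 = k++;
  net.nPar = k;
  return net;
}

std::vector<arma::mat> paramsFromList(const List& par, const Net& net) {
  std::vector<arma::mat> P(net.nPar);
  P[0] = as<arma::mat>(par["Wx1"]);
  P[1] = as<arma::mat>(par["bx1"]);
  if (net.nLayers == 2) {
    P[net.iW2] = as<arma::mat>(par["Wx2"]);
    P[net.iB2] = as<arma::mat>(par["bx2"]);
  }
  P[net.iw]  = as<arma::mat>(par["w"]);
  P[net.ib]  = as<arma::mat>(par["b"]);
  P[net.iv]  = as<arma::mat>(par["v"]);
  P[net.ibp] = as<arma::mat>(par["bprime"]);
  if (net.binary) {
    P[net.ih1] = as<arma::mat>(par["wbar"]);
    P[net.ih2] = as<arma::mat>(par["bbar"]);
  } else {
    P[net.ih1] = as<arma::mat>(par["W"]);
    P[net.ih2] = as<arma::mat>(par["bhead"]);
  }
  return P;
}

List paramsToList(const std::vector<arma::mat>& P, const Net& net) {
  List out;
  out["Wx1"] = P[0];
  out["bx1"] = P[1];
  if (net.nLayers == 2) {
    out["Wx2"] = P[net.iW2];
    out["bx2"] = P[net.iB2];
  }
  out["w"] = P[net.iw];
  out["b"] = P[net.ib];
  out["v"] = P[net.iv];
  out["bprime"] = P[net.ibp];
  if (net.binary) {
    out["wbar"] = P[net.ih1];
    out["bbar"] = P[net.ih2];
  } else {
    out["W"] = P[net.ih1];
    out["bhead"] = P[net.ih2];
  }
  return out;
}

inline arma::vec softmaxVec(const arma::vec& e) {
  arma::vec z = arma::exp(e - e.max());
  return z / arma::accu(z);
}

struct Forward {
  arma::mat Z1, H1, Z2, H;       // encoder intermediates; H is N x d
  std::vector<arma::uvec> groups; // row indices per present type
  std::vector<arma::vec> alphas;  // per present type (CTA/HA)
  arma::mat Ht;                   // d x T, type representations
  arma::vec beta;                 // T
  arma::vec aFlat;                // CELL_ATT weights over all cells
  arma::vec h;                    // d, sample representation
  arma::vec logits;               // C (multi) or 1 (binary)
  arma::vec p;                    // class probabilities, length C
};

void encode(const arma::mat& X, const std::vector<arma::mat>& P,
            const Net& net, Forward& f) {
  f.Z1 = X * P[0].t();
  f.Z1.each_row() += P[1].t();
  if (net.nonlin == RELU) f.H1 = arma::clamp(f.Z1, 0.0, arma::datum::inf);
  else                    f.H1 = arma::tanh(f.Z1);
  if (net.nLayers == 2) {
    f.Z2 = f.H1 * P[net.iW2].t();
    f.Z2.each_row() += P[net.iB2].t();
    if (net.nonlin == RELU) f.H = arma::clamp(f.Z2, 0.0, arma::datum::inf);
    else                    f.H = arma::tanh(f.Z2);
  } else {
    f.H = f.H1;
  }
}

// forward pass for one bag; types are 1-based cell-type ids
void forwardSample(const arma::mat& X, const arma::ivec& types,
                   const std::vector<arma::mat>& P, const Net& net,
                   Forward& f) {
  encode(X, P, net, f);
  const int N = X.n_rows;
  const arma::vec& w = P[net.iw].col(0);
  const double b    = P[net.ib](0, 0);
  const arma::vec& v = P[net.iv].col(0);
  const double bp   = P[net.ibp](0, 0);

  if (net.mode == MEAN_POOL) {
    f.h = arma::mean(f.H, 0).t();
  } else if (net.mode == CELL_ATT) {
    arma::vec e = f.H * w + b;
    f.aFlat = softmaxVec(e);
    f.h = f.H.t() * f.aFlat;
  } else {
    // group rows by present type, preserving first-occurrence order of ids
    std::map<int, std::vector<arma::uword>> byType;
    for (int j = 0; j < N; ++j) byType[types[j]].push_back(j);
    const int T = byType.size();
    f.groups.clear(); f.alphas.clear();
    f.Ht.set_size(net.d, T);
    int t = 0;
    for (auto& kv : byType) {
      arma::uvec idx(kv.second);
      arma::mat Hi = f.H.rows(idx);
      arma::vec alpha;
      if (net.mode == HA) {
        alpha = softmaxVec(Hi * w + b);
      } else { // CTA
        alpha = arma::vec(idx.n_elem, arma::fill::value(1.0 / idx.n_elem));
      }
      f.Ht.col(t) = Hi.t() * alpha;
      f.groups.push_back(idx);
      f.alphas.push_back(alpha);
      ++t;
    }
    f.beta = softmaxVec(f.Ht.t() * v + bp);
    f.h = f.Ht * f.beta;
  }

  if (net.binary) {
    double z = arma::dot(P[net.ih1].col(0), f.h) + P[net.ih2](0, 0);
    double pp = 1.0 / (1.0 + std::exp(-z));
    f.logits = arma::vec{z};
    f.p = arma::vec{1.0 - pp, pp};
  } else {
    arma::vec z = P[net.ih1] * f.h + P[net.ih2].col(0);
    f.logits = z;
    f.p = softmaxVec(z);
  }
}

inline double clampedLog(double x) { return std::log(std::max(x, 1e-12)); }

// loss + gradient accumulation for one bag; y is 0-based class
double backwardSample(const arma::mat& X, const arma::ivec& types, int y,
                      const std::vector<arma::mat>& P, const Net& net,
                      std::vector<arma::mat>& G) {
  Forward f;
  forwardSample(X, types, P, net, f);
  const int N = X.n_rows;
  double loss = -clampedLog(f.p(y));

  // head backward -> dh
  arma::vec dh(net.d);
  if (net.binary) {
    double dz = f.p(1) - (y == 1 ? 1.0 : 0.0);
    dh = dz * P[net.ih1].col(0);
    G[net.ih1].col(0) += dz * f.h;
    G[net.ih2](0, 0)  += dz;
  } else {
    arma::vec dz = f.p;
    dz(y) -= 1.0;
    dh = P[net.ih1].t() * dz;
    G[net.ih1] += dz * f.h.t();
    G[net.ih2].col(0) += dz;
  }

  const arma::vec& w = P[net.iw].col(0);
  const arma::vec& v = P[net.iv].col(0);
  arma::mat dH(N, net.d, arma::fill::zeros);

  if (net.mode == MEAN_POOL) {
    dH.each_row() += (dh / N).t();
  } else if (net.mode == CELL_ATT) {
    const arma::vec& a = f.aFlat;
    arma::vec da = f.H * dh;
    arma::vec de = a % (da - arma::dot(a, da));
    dH += a * dh.t() + de * w.t();
    G[net.iw].col(0) += f.H.t() * de;
    G[net.ib](0, 0)  += arma::accu(de);
  } else {
    const int T = f.groups.size();
    // through beta
    arma::vec dbeta = f.Ht.t() * dh;                       // dL/dbeta
    arma::vec debeta = f.beta % (dbeta - arma::dot(f.beta, dbeta));
    G[net.iv].col(0)  += f.Ht * debeta;
    G[net.ibp](0, 0)  += arma::accu(debeta);
    for (int t = 0; t < T; ++t) {
      arma::vec dhi = f.beta(t) * dh + debeta(t) * v;
      const arma::uvec& idx = f.groups[t];
      arma::mat Hi = f.H.rows(idx);
      const arma::vec& alpha = f.alphas[t];
      if (net.mode == HA) {
        arma::vec dalpha = Hi * dhi;
        arma::vec dealpha = alpha % (dalpha - arma::dot(alpha, dalpha));
        dH.rows(idx) += alpha * dhi.t() + dealpha * w.t();
        G[net.iw].col(0) += Hi.t() * dealpha;
        G[net.ib](0, 0)  += arma::accu(dealpha);
      } else { // CTA: alpha fixed at 1/n_i, no gradient into w,b
        dH.rows(idx) += arma::ones<arma::vec>(idx.n_elem) * (dhi / idx.n_elem).t();
      }
    }
  }

  // encoder backward
  arma::mat dZtop;
  if (net.nonlin == RELU) {
    const arma::mat& Ztop = (net.nLayers == 2) ? f.Z2 : f.Z1;
    dZtop = dH % arma::conv_to<arma::mat>::from(Ztop > 0);
  } else {
    dZtop = dH % (1.0 - arma::square(f.H));
  }
  if (net.nLayers == 2) {
    G[net.iW2] += dZtop.t() * f.H1;
    G[net.iB2].col(0) += arma::sum(dZtop, 0).t();
    arma::mat dH1 = dZtop * P[net.iW2];
    arma::mat dZ1;
    if (net.nonlin == RELU) dZ1 = dH1 % arma::conv_to<arma::mat>::from(f.Z1 > 0);
    else                    dZ1 = dH1 % (1.0 - arma::square(f.H1));
    G[0] += dZ1.t() * X;
    G[1].col(0) += arma::sum(dZ1, 0).t();
  } else {
    G[0] += dZtop.t() * X;
    G[1].col(0) += arma::sum(dZtop, 0).t();
  }
  return loss;
}

} // namespace

// Mini-batch Adam on the cross-entropy objective. samplesX / samplesType are
// parallel lists of per-bag matrices and 1-based type vectors; labels are
// 0-based classes. Batch shuffling uses R's RNG.
// [[Rcpp::export(name = ".fitCpp")]]
List fitCpp(List samplesX, List samplesType, IntegerVector labels,
            List init, List cfg, double lr, int epochs, int batchSize,
            double weightDecay, int patience) {
  Net net = makeNet(cfg);
  std::vector<arma::mat> P = paramsFromList(init, net);
  const int S = samplesX.size();

  std::vector<arma::mat> X(S);
  std::vector<arma::ivec> ty(S);
  for (int s = 0; s < S; ++s) {
    X[s]  = as<arma::mat>(samplesX[s]);
    ty[s] = as<arma::ivec>(samplesType[s]);
  }

  // weight decay applies to weight matrices/vectors, not biases
  std::vector<bool> decay(net.nPar, false);
  decay[0] = true;
  if (net.nLayers == 2) decay[net.iW2] = true;
  decay[net.iw] = decay[net.iv] = decay[net.ih1] = true;

  std::vector<arma::mat> M(net.nPar), V(net.nPar), G(net.nPar);
  for (int k = 0; k < net.nPar; ++k) {
    M[k] = arma::zeros<arma::mat>(P[k].n_rows, P[k].n_cols);
    V[k] = M[k];
    G[k] = M[k];
  }
  const double beta1 = 0.9, beta2 = 0.999, eps = 1e-8;
  long step = 0;
  double bestLoss = arma::datum::inf;
  int since = 0;
  bool ok = true;
  NumericVector trace(epochs, NA_REAL);

  int nBatch = (batchSize <= 0 || batchSize > S) ? S : batchSize;

  for (int ep = 0; ep < epochs && ok; ++ep) {
    // Fisher-Yates shuffle driven by R's RNG
    std::vector<int> ord(S);
    for (int s = 0; s < S; ++s) ord[s] = s;
    for (int s = S - 1; s > 0; --s) {
      int j = (int)std::floor(unif_rand() * (s + 1));
      if (j > s) j = s;
      std::swap(ord[s], ord[j]);
    }
    double epLoss = 0.0;
    for (int start = 0; start < S; start += nBatch) {
      int stop = std::min(start + nBatch, S);
      for (int k = 0; k < net.nPar; ++k) G[k].zeros();
      double bl = 0.0;
      for (int q = start; q < stop; ++q) {
        int s = ord[q];
        bl += backwardSample(X[s], ty[s], labels[s], P, net, G);
      }
      int nb = stop - start;
      epLoss += bl;
      if (!std::isfinite(bl)) { ok = false; break; }
      ++step;
      double c1 = 1.0 - std::pow(beta1, (double)step);
      double c2 = 1.0 - std::pow(beta2, (double)step);
      for (int k = 0; k < net.nPar; ++k) {
        arma::mat g = G[k] / nb;
        if (decay[k] && weightDecay > 0) g += weightDecay * P[k];
        M[k] = beta1 * M[k] + (1.0 - beta1) * g;
        V[k] = beta2 * V[k] + (1.0 - beta2) * (g % g);
        P[k] -= lr * (M[k] / c1) / (arma::sqrt(V[k] / c2) + eps);
      }
    }
    if (!ok) break;
    epLoss /= S;
    trace[ep] = epLoss;
    if (epLoss < bestLoss - 1e-6) { bestLoss = epLoss; since = 0; } else { ++since; }
    if (patience > 0 && since >= patience) break;
  }

  return List::create(_["params"] = paramsToList(P, net),
                      _["ok"] = ok,
                      _["loss"] = trace);
}

// Batched forward pass: class probabilities for each bag (S x C).
// [[Rcpp::export(name = ".predictCpp")]]
NumericMatrix predictCpp(List samplesX, List samplesType, List par, List cfg) {
  Net net = makeNet(cfg);
  std::vector<arma::mat> P = paramsFromList(par, net);
  const int S = samplesX.size();
  NumericMatrix out(S, net.C);
  for (int s = 0; s < S; ++s) {
    Forward f;
    forwardSample(as<arma::mat>(samplesX[s]), as<arma::ivec>(samplesType[s]),
                  P, net, f);
    for (int c = 0; c < net.C; ++c) out(s, c) = f.p(c);
  }
  return out;
}

// Per-cell-type logit contributions beta_i * (head %*% h_i) for each bag.
// Rows: samples; cols: the I cell types (absent types contribute 0).
// Binary head: one slice; multi-class head: C slices stacked as a cube
// flattened to S x (I*C) column-major by class. Used as the fast path for
// importance scores; decompose() in R is the reference implementation.
// [[Rcpp::export(name = ".typeLogitsCpp")]]
NumericMatrix typeLogitsCpp(List samplesX, List samplesType, List par,
                            List cfg, int nTypes) {
  Net net = makeNet(cfg);
  std::vector<arma::mat> P = paramsFromList(par, net);
  const int S = samplesX.size();
  const int nc = net.binary ? 1 : net.C;
  NumericMatrix out(S, nTypes * nc);
  for (int s = 0; s < S; ++s) {
    arma::ivec types = as<arma::ivec>(samplesType[s]);
    Forward f;
    forwardSample(as<arma::mat>(samplesX[s]), types, P, net, f);
    // recover present-type ids in the same sorted order used by forwardSample
    std::set<int> present(types.begin(), types.end());
    int t = 0;
    for (int id : present) {
      arma::vec zi;
      if (net.binary) {
        zi = arma::vec{arma::dot(P[net.ih1].col(0), f.Ht.col(t))};
      } else {
        zi = P[net.ih1] * f.Ht.col(t);
      }
      for (int c = 0; c < nc; ++c)
        out(s, c * nTypes + (id - 1)) = f.beta(t) * zi(c);
      ++t;
    }
  }
  return out;
}
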