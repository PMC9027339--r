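// Compact depthwise-separable CNN for gait-matrix image classification.
//
// Architecture: nBlocks x [3x3 depthwise conv (same padding) -> 1x1
// pointwise conv + bias -> ReLU -> 2x2 max pool], then global average
// pooling and a 2-unit softmax head trained with cross-entropy (binary
// cross-entropy over the 2-class softmax). Pointwise convolutions are the
// FLOP bulk and run as BLAS matrix products; depthwise 3x3 kernels are
// explicit loops. Input side length must be divisible by 2^nBlocks.

#include <RcppArmadillo.h>
#include <random>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;

namespace {

struct Block {
  arma::cube Kd;   // 3 x 3 x Cin
  arma::mat  Wp;   // Cin x Cout
  arma::rowvec bp; // Cout
};

struct Net {
  std::vector<Block> blocks;
  arma::mat Wf;    // Clast x 2
  arma::rowvec bf; // 2
};

struct Cache {
  std::vector<arma::cube> Xin;    // input of each block
  std::vector<arma::cube> D;      // depthwise output
  std::vector<arma::cube> P;      // pointwise pre-activation
  std::vector<arma::ucube> amax;  // pool argmax (0..3 within 2x2)
  arma::vec f;                    // GAP features
  arma::vec p;                    // softmax probabilities
};

void dwForward(const arma::cube& X, const arma::cube& K, arma::cube& Y) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  Y.set_size(H, W, C);
  Y.zeros();
  for (int c = 0; c < C; ++c) {
    const arma::mat& x = X.slice(c);
    const arma::mat& k = K.slice(c);
    arma::mat& y = Y.slice(c);
    for (int dv = -1; dv <= 1; ++dv) {
      for (int du = -1; du <= 1; ++du) {
        const double kv = k(du + 1, dv + 1);
        if (kv == 0.0) continue;
        const int r0 = std::max(0, -du), r1 = std::min(H, H - du);
        const int c0 = std::max(0, -dv), c1 = std::min(W, W - dv);
        y.submat(r0, c0, r1 - 1, c1 - 1) +=
          kv * x.submat(r0 + du, c0 + dv, r1 - 1 + du, c1 - 1 + dv);
      }
    }
  }
}

// Gradients of the depthwise stage; dX accumulation is skipped when
// wantDX is false (first block).
void dwBackward(const arma::cube& X, const arma::cube& K,
                const arma::cube& dY, arma::cube& dK, arma::cube& dX,
                bool wantDX) {
  const int H = X.n_rows, W = X.n_cols, C = X.n_slices;
  if (wantDX) { dX.set_size(H, W, C); dX.zeros(); }
  for (int c = 0; c < C; ++c) {
    const arma::mat& x = X.slice(c);
    const arma::mat& dy = dY.slice(c);
    for (int dv = -1; dv <= 1; ++dv) {
      for (int du = -1; du <= 1; ++du) {
        const int r0 = std::max(0, -du), r1 = std::min(H, H - du);
        const int c0 = std::max(0, -dv), c1 = std::min(W, W - dv);
        const arma::mat xs = x.submat(r0 + du, c0 + dv,
                                      r1 - 1 + du, c1 - 1 + dv);
        const arma::mat dys = dy.submat(r0, c0, r1 - 1, c1 - 1);
        dK(du + 1, dv + 1, c) += arma::accu(xs % dys);
        if (wantDX)
          dX.slice(c).submat(r0 + du, c0 + dv, r1 - 1 + du, c1 - 1 + dv) +=
            K(du + 1, dv + 1, c) * dys;
      }
    }
  }
}

void poolForward(const arma::cube& A, arma::cube& Y, arma::ucube& amax) {
  const int H = A.n_rows, W = A.n_cols, C = A.n_slices;
  const int Ho = H / 2, Wo = W / 2;
  Y.set_size(Ho, Wo, C);
  amax.set_size(Ho, Wo, C);
  for (int c = 0; c < C; ++c)
    for (int j = 0; j < Wo; ++j)
      for (int i = 0; i < Ho; ++i) {
        double best = A(2 * i, 2 * j, c);
        arma::uword arg = 0;
        const double v01 = A(2 * i + 1, 2 * j, c);
        const double v10 = A(2 * i, 2 * j + 1, c);
        const double v11 = A(2 * i + 1, 2 * j + 1, c);
        if (v01 > best) { best = v01; arg = 1; }
        if (v10 > best) { best = v10; arg = 2; }
        if (v11 > best) { best = v11; arg = 3; }
        Y(i, j, c) = best;
        amax(i, j, c) = arg;
      }
}

arma::mat asMat(const arma::cube& X) {
  // HW x C view of a cube (column-major slices are contiguous)
  return arma::mat(const_cast<double*>(X.memptr()),
                   X.n_rows * X.n_cols, X.n_slices, false, true);
}

arma::vec forwardImage(const Net& net, const arma::cube& img, Cache* cache) {
  arma::cube X = img;
  const int nB = net.blocks.size();
  if (cache) {
    cache->Xin.resize(nB); cache->D.resize(nB); cache->P.resize(nB);
    cache->amax.resize(nB);
  }
  for (int b = 0; b < nB; ++b) {
    const Block& bl = net.blocks[b];
    arma::cube D, P, Y;
    arma::ucube amax;
    dwForward(X, bl.Kd, D);
    arma::mat Pm = asMat(D) * bl.Wp;
    Pm.each_row() += bl.bp;
    P = arma::cube(Pm.memptr(), D.n_rows, D.n_cols, bl.Wp.n_cols);
    arma::cube A = P;
    A.transform([](double v) { return v > 0.0 ? v : 0.0; });
    poolForward(A, Y, amax);
    if (cache) {
      cache->Xin[b] = X; cache->D[b] = std::move(D);
      cache->P[b] = std::move(P); cache->amax[b] = std::move(amax);
    }
    X = std::move(Y);
  }
  arma::vec f(X.n_slices);
  const double inv = 1.0 / (X.n_rows * X.n_cols);
  for (arma::uword c = 0; c < X.n_slices; ++c)
    f(c) = arma::accu(X.slice(c)) * inv;
  arma::vec z = net.Wf.t() * f + net.bf.t();
  z -= z.max();
  arma::vec p = arma::exp(z);
  p /= arma::accu(p);
  if (cache) { cache->f = f; cache->p = p; }
  return p;
}

struct Grads {
  std::vector<arma::cube> dKd;
  std::vector<arma::mat> dWp;
  std::vector<arma::rowvec> dbp;
  arma::mat dWf;
  arma::rowvec dbf;
  void init(const Net& net) {
    const int nB = net.blocks.size();
    dKd.resize(nB); dWp.resize(nB); dbp.resize(nB);
    for (int b = 0; b < nB; ++b) {
      dKd[b].zeros(arma::size(net.blocks[b].Kd));
      dWp[b].zeros(arma::size(net.blocks[b].Wp));
      dbp[b].zeros(net.blocks[b].bp.n_elem);
    }
    dWf.zeros(arma::size(net.Wf));
    dbf.zeros(net.bf.n_elem);
  }
};

void backwardImage(const Net& net, const Cache& cache, int y, Grads& g) {
  arma::vec dz = cache.p;
  dz(y) -= 1.0;
  g.dWf += cache.f * dz.t();
  g.dbf += dz.t();
  arma::vec df = net.Wf * dz;

  const int nB = net.blocks.size();
  // gradient wrt the last block's pooled output
  const arma::ucube& amaxL = cache.amax[nB - 1];
  arma::cube dY(amaxL.n_rows, amaxL.n_cols, amaxL.n_slices);
  const double inv = 1.0 / (amaxL.n_rows * amaxL.n_cols);
  for (arma::uword c = 0; c < dY.n_slices; ++c)
    dY.slice(c).fill(df(c) * inv);

  for (int b = nB - 1; b >= 0; --b) {
    const Block& bl = net.blocks[b];
    const arma::cube& P = cache.P[b];
    const arma::ucube& amax = cache.amax[b];
    // unpool through argmax, then ReLU mask
    arma::cube dA(P.n_rows, P.n_cols, P.n_slices, arma::fill::zeros);
    for (arma::uword c = 0; c < dY.n_slices; ++c)
      for (arma::uword j = 0; j < dY.n_cols; ++j)
        for (arma::uword i = 0; i < dY.n_rows; ++i) {
          const arma::uword arg = amax(i, j, c);
          const arma::uword ii = 2 * i + (arg & 1u);
          const arma::uword jj = 2 * j + (arg >> 1);
          if (P(ii, jj, c) > 0.0) dA(ii, jj, c) = dY(i, j, c);
        }
    arma::mat dPm = asMat(dA);
    g.dWp[b] += asMat(cache.D[b]).t() * dPm;
    g.dbp[b] += arma::sum(dPm, 0);
    arma::mat dDm = dPm * bl.Wp.t();
    arma::cube dD(dDm.memptr(), cache.D[b].n_rows, cache.D[b].n_cols,
                  cache.D[b].n_slices);
    arma::cube dX;
    dwBackward(cache.Xin[b], bl.Kd, dD, g.dKd[b], dX, b > 0);
    if (b > 0) dY = std::move(dX);
  }
}

Net initNet(int C0, const IntegerVector& channels, std::mt19937& gen) {
  Net net;
  std::normal_distribution<double> nd(0.0, 1.0);
  int cin = C0;
  for (int b = 0; b < channels.size(); ++b) {
    Block bl;
    const int cout = channels[b];
    const double sdK = std::sqrt(2.0 / 9.0);
    bl.Kd.set_size(3, 3, cin);
    for (arma::uword i = 0; i < bl.Kd.n_elem; ++i) bl.Kd(i) = sdK * nd(gen);
    const double sdW = std::sqrt(2.0 / cin);
    bl.Wp.set_size(cin, cout);
    for (arma::uword i = 0; i < bl.Wp.n_elem; ++i) bl.Wp(i) = sdW * nd(gen);
    bl.bp.zeros(cout);
    net.blocks.push_back(std::move(bl));
    cin = cout;
  }
  const double sdF = std::sqrt(1.0 / cin);
  net.Wf.set_size(cin, 2);
  for (arma::uword i = 0; i < net.Wf.n_elem; ++i) net.Wf(i) = sdF * nd(gen);
  net.bf.zeros(2);
  return net;
}

arma::cube imageAt(const NumericVector& x, int H, int W, int C, int n) {
  const double* src = REAL(x) + (size_t)n * H * W * C;
  return arma::cube(const_cast<double*>(src), H, W, C);  // copies
}

double evalSet(const Net& net, const NumericVector& x, int H, int W, int C,
               const IntegerVector& y, double* accOut) {
  const int N = y.size();
  double loss = 0.0;
  int correct = 0;
  for (int n = 0; n < N; ++n) {
    arma::vec p = forwardImage(net, imageAt(x, H, W, C, n), nullptr);
    loss += -std::log(std::max(p(y[n]), 1e-12));
    if ((p(1) > p(0) ? 1 : 0) == y[n]) ++correct;
  }
  if (accOut) *accOut = (double)correct / N;
  return loss / N;
}

List netToList(const Net& net) {
  const int nB = net.blocks.size();
  List Kd(nB), Wp(nB), bp(nB);
  for (int b = 0; b < nB; ++b) {
    Kd[b] = wrap(net.blocks[b].Kd);
    Wp[b] = wrap(net.blocks[b].Wp);
    bp[b] = wrap(net.blocks[b].bp);
  }
  return List::create(_["Kd"] = Kd, _["Wp"] = Wp, _["bp"] = bp,
                      _["Wf"] = wrap(net.Wf), _["bf"] = wrap(net.bf));
}

Net netFromList(const List& w) {
  Net net;
  List Kd = w["Kd"], Wp = w["Wp"], bp = w["bp"];
  for (int b = 0; b < Kd.size(); ++b) {
    Block bl;
    bl.Kd = as<arma::cube>(Kd[b]);
    bl.Wp = as<arma::mat>(Wp[b]);
    bl.bp = as<arma::rowvec>(bp[b]);
    net.blocks.push_back(std::move(bl));
  }
  net.Wf = as<arma::mat>(w["Wf"]);
  net.bf = as<arma::rowvec>(w["bf"]);
  return net;
}

}  // namespace

// [[Rcpp::export(name = ".cnnTrain")]]
List cnnTrain(NumericVector x, IntegerVector y, IntegerVector channels,
              int epochs, int batchSize, double lr, int seed,
              std::string optimizer, double clipNorm,
              Nullable<NumericVector> valX = R_NilValue,
              Nullable<IntegerVector> valY = R_NilValue,
              bool verbose = false) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("image array must have dim (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  if (N != y.size()) stop("label/image count mismatch");
  const int nB = channels.size();
  if (H % (1 << nB) || W % (1 << nB))
    stop("image side must be divisible by 2^nBlocks");

  std::mt19937 gen(seed);
  Net net = initNet(C, channels, gen);

  // Adam / momentum state mirrors the gradient layout
  Grads m1, m2;
  m1.init(net); m2.init(net);
  const bool adam = optimizer == "adam";
  const double b1 = 0.9, b2 = 0.999, eps = 1e-8;
  long tstep = 0;

  std::vector<int> order(N);
  for (int i = 0; i < N; ++i) order[i] = i;

  NumericVector hLoss(epochs), hAcc(epochs);
  NumericVector hVLoss(epochs, NA_REAL), hVAcc(epochs, NA_REAL);
  bool diverged = false;

  for (int ep = 0; ep < epochs && !diverged; ++ep) {
    std::shuffle(order.begin(), order.end(), gen);
    double epLoss = 0.0;
    int epCorrect = 0;
    for (int start = 0; start < N; start += batchSize) {
      const int bEnd = std::min(start + batchSize, N);
      const int bs = bEnd - start;
      Grads g;
      g.init(net);
      for (int k = start; k < bEnd; ++k) {
        const int n = order[k];
        Cache cache;
        arma::vec p = forwardImage(net, imageAt(x, H, W, C, n), &cache);
        epLoss += -std::log(std::max(p(y[n]), 1e-12));
        if ((p(1) > p(0) ? 1 : 0) == y[n]) ++epCorrect;
        backwardImage(net, cache, y[n], g);
      }
      const double invB = 1.0 / bs;
      double sq = 0.0;
      for (int b = 0; b < nB; ++b) {
        g.dKd[b] *= invB; g.dWp[b] *= invB; g.dbp[b] *= invB;
        sq += arma::accu(arma::square(g.dKd[b])) +
              arma::accu(arma::square(g.dWp[b])) +
              arma::accu(arma::square(g.dbp[b]));
      }
      g.dWf *= invB; g.dbf *= invB;
      sq += arma::accu(arma::square(g.dWf)) + arma::accu(arma::square(g.dbf));
      if (!std::isfinite(sq)) { diverged = true; break; }
      const double gnorm = std::sqrt(sq);
      const double scale = (clipNorm > 0 && gnorm > clipNorm)
                             ? clipNorm / gnorm : 1.0;
      ++tstep;
      auto update = [&](arma::mat& wMat, arma::mat& gm, arma::mat& mm,
                        arma::mat& vm) {
        gm *= scale;
        if (adam) {
          mm = b1 * mm + (1 - b1) * gm;
          vm = b2 * vm + (1 - b2) * arma::square(gm);
          const double bc1 = 1 - std::pow(b1, (double)tstep);
          const double bc2 = 1 - std::pow(b2, (double)tstep);
          wMat -= lr * (mm / bc1) / (arma::sqrt(vm / bc2) + eps);
        } else {  // SGD with momentum 0.9
          mm = 0.9 * mm + gm;
          wMat -= lr * mm;
        }
      };
      for (int b = 0; b < nB; ++b) {
        for (arma::uword s = 0; s < net.blocks[b].Kd.n_slices; ++s)
          update(net.blocks[b].Kd.slice(s), g.dKd[b].slice(s),
                 m1.dKd[b].slice(s), m2.dKd[b].slice(s));
        update(net.blocks[b].Wp, g.dWp[b], m1.dWp[b], m2.dWp[b]);
        arma::mat bpM(net.blocks[b].bp), gbpM(g.dbp[b]),
                  m1bp(m1.dbp[b]), m2bp(m2.dbp[b]);
        update(bpM, gbpM, m1bp, m2bp);
        net.blocks[b].bp = bpM.row(0);
        m1.dbp[b] = m1bp.row(0); m2.dbp[b] = m2bp.row(0);
      }
      update(net.Wf, g.dWf, m1.dWf, m2.dWf);
      arma::mat bfM(net.bf), gbfM(g.dbf), m1bf(m1.dbf), m2bf(m2.dbf);
      update(bfM, gbfM, m1bf, m2bf);
      net.bf = bfM.row(0);
      m1.dbf = m1bf.row(0); m2.dbf = m2bf.row(0);
    }
    hLoss[ep] = epLoss / N;
    hAcc[ep] = (double)epCorrect / N;
    if (!std::isfinite(hLoss[ep])) diverged = true;
    if (valX.isNotNull() && valY.isNotNull() && !diverged) {
      NumericVector vx(valX);
      IntegerVector vy(valY);
      double vacc = 0.0;
      hVLoss[ep] = evalSet(net, vx, H, W, C, vy, &vacc);
      hVAcc[ep] = vacc;
    }
    if (verbose)
      Rcout << "epoch " << ep + 1 << " loss " << hLoss[ep]
            << " acc " << hAcc[ep] << "\n";
    Rcpp::checkUserInterrupt();
  }

  DataFrame hist = DataFrame::create(
      _["epoch"] = seq_len(epochs), _["loss"] = hLoss, _["acc"] = hAcc,
      _["val_loss"] = hVLoss, _["val_acc"] = hVAcc);
  return List::create(_["weights"] = netToList(net), _["history"] = hist,
                      _["diverged"] = diverged);
}

// [[Rcpp::export(name = ".cnnPredict")]]
NumericMatrix cnnPredict(List weights, NumericVector x) {
  IntegerVector dims = x.attr("dim");
  if (dims.size() != 4) stop("image array must have dim (H, W, C, N)");
  const int H = dims[0], W = dims[1], C = dims[2], N = dims[3];
  Net net = netFromList(weights);
  NumericMatrix out(N, 2);
  for (int n = 0; n < N; ++n) {
    arma::vec p = forwardImage(net, imageAt(x, H, W, C, n), nullptr);
    out(n, 0) = p(0);
    out(n, 1) = p(1);
  }
  return out;
}
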