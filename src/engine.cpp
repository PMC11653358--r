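// Tensor engine for the fused CNN: forward, backward and SGD training over a
// compiled layer DAG. Activations for a node are stored as an (rows x N*P)
// matrix, where rows = channels/embedding width and P = spatial positions per
// image (1 for vector nodes). Convolutions run as im2col + GEMM.

#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]
using namespace Rcpp;

enum Kind { K_INPUT = 0, K_CONV = 1, K_BN = 2, K_RELU = 3, K_MAXPOOL = 4,
            K_GAP = 5, K_CONCAT = 6, K_FLATTEN = 7, K_ATTN = 8, K_FC = 9,
            K_SOFTMAX = 10, K_CLASS = 11 };

struct Node {
  int kind;
  std::vector<int> ins;
  int rows, P;                 // output storage
  int inH, inW, inC;           // spatial geometry of (first) input
  int outH, outW;
  int fh, fw, stride, padT, padL, groups, heads;
  int din;                     // fc input width
};

static std::vector<Node> parse_spec(const List& spec) {
  std::vector<Node> nodes(spec.size());
  for (int i = 0; i < spec.size(); ++i) {
    List s = spec[i];
    Node& n = nodes[i];
    n.kind = as<int>(s["kind"]);
    IntegerVector ins = s["ins"];
    n.ins.assign(ins.begin(), ins.end());
    n.rows = as<int>(s["rows"]); n.P = as<int>(s["P"]);
    n.inH = as<int>(s["inH"]); n.inW = as<int>(s["inW"]); n.inC = as<int>(s["inC"]);
    n.outH = as<int>(s["outH"]); n.outW = as<int>(s["outW"]);
    n.fh = as<int>(s["fh"]); n.fw = as<int>(s["fw"]); n.stride = as<int>(s["stride"]);
    n.padT = as<int>(s["padT"]); n.padL = as<int>(s["padL"]);
    n.groups = as<int>(s["groups"]); n.heads = as<int>(s["heads"]);
    n.din = as<int>(s["din"]);
  }
  return nodes;
}

// ---- im2col / col2im ------------------------------------------------------
// col: ((c1-c0)*fh*fw) x (N*outH*outW); row r = (c-c0) + cin*(fy + fh*fx)
// (channel fastest, so patch rows copy contiguously from the activation,
// which is stored (inC) x (N*inH*inW) with spatial index s = y + inH*x).
// The channel range [c0, c1) selects one filter group.

static void im2col(const arma::mat& A, int N, const Node& n, int c0, int c1,
                   arma::mat& col) {
  const int HW = n.inH * n.inW, oHW = n.outH * n.outW, cin = c1 - c0;
  col.zeros((arma::uword)cin * n.fh * n.fw, (arma::uword)N * oHW);
  for (int img = 0; img < N; ++img) {
    const arma::uword in0 = (arma::uword)img * HW, out0 = (arma::uword)img * oHW;
    for (int ox = 0; ox < n.outW; ++ox) {
      for (int oy = 0; oy < n.outH; ++oy) {
        const arma::uword q = out0 + oy + (arma::uword)n.outH * ox;
        const int x0 = ox * n.stride - n.padL, y0 = oy * n.stride - n.padT;
        double* dstc = col.colptr(q);
        for (int fx = 0; fx < n.fw; ++fx) {
          const int x = x0 + fx;
          if (x < 0 || x >= n.inW) continue;
          for (int fy = 0; fy < n.fh; ++fy) {
            const int y = y0 + fy;
            if (y < 0 || y >= n.inH) continue;
            const double* src = A.colptr(in0 + y + (arma::uword)n.inH * x) + c0;
            std::memcpy(dstc + (arma::uword)cin * (fy + n.fh * fx), src,
                        sizeof(double) * cin);
          }
        }
      }
    }
  }
}

static void col2im(const arma::mat& col, int N, const Node& n, int c0, int c1,
                   arma::mat& dA) {
  const int HW = n.inH * n.inW, oHW = n.outH * n.outW, cin = c1 - c0;
  for (int img = 0; img < N; ++img) {
    const arma::uword in0 = (arma::uword)img * HW, out0 = (arma::uword)img * oHW;
    for (int ox = 0; ox < n.outW; ++ox) {
      for (int oy = 0; oy < n.outH; ++oy) {
        const arma::uword q = out0 + oy + (arma::uword)n.outH * ox;
        const int x0 = ox * n.stride - n.padL, y0 = oy * n.stride - n.padT;
        const double* srcc = col.colptr(q);
        for (int fx = 0; fx < n.fw; ++fx) {
          const int x = x0 + fx;
          if (x < 0 || x >= n.inW) continue;
          for (int fy = 0; fy < n.fh; ++fy) {
            const int y = y0 + fy;
            if (y < 0 || y >= n.inH) continue;
            const double* src = srcc + (arma::uword)cin * (fy + n.fh * fx);
            double* dst = dA.colptr(in0 + y + (arma::uword)n.inH * x) + c0;
            for (int c = 0; c < cin; ++c) dst[c] += src[c];
          }
        }
      }
    }
  }
}

// ---- per-node forward state ----------------------------------------------

struct Cache {
  arma::umat argmax;        // maxpool: winning input column/row
  arma::vec bn_invstd, bn_mean;
  std::vector<arma::mat> attn_M, attn_W, attn_Q, attn_K, attn_V, attn_O;
  void clear() {
    argmax.reset(); bn_invstd.reset(); bn_mean.reset();
    attn_M.clear(); attn_W.clear(); attn_Q.clear(); attn_K.clear();
    attn_V.clear(); attn_O.clear();
  }
};

static arma::mat softmax_cols(const arma::mat& Z) {
  arma::rowvec mx = arma::max(Z, 0);
  arma::mat E = arma::exp(Z.each_row() - mx);
  arma::rowvec s = arma::sum(E, 0);
  return E.each_row() / s;
}

// forward one node; acts[i] already computed for inputs
static void forward_node(int idx, const std::vector<Node>& nodes, List& params,
                         std::vector<arma::mat>& acts, std::vector<Cache>& caches,
                         int N, bool train, double bn_mom, bool need_cache) {
  const Node& n = nodes[idx];
  Cache& C = caches[idx];
  switch (n.kind) {
  case K_INPUT: break;
  case K_CONV: {
    List pl = params[idx];
    arma::mat W = as<arma::mat>(pl["W"]);      // (cin/g * fh*fw) x Cout
    arma::vec b = as<arma::vec>(pl["b"]);
    const int Cout = n.rows, g = n.groups;
    const int cing = n.inC / g, cg = Cout / g;
    arma::mat out(Cout, (arma::uword)N * n.outH * n.outW);
    arma::mat col;
    for (int gi = 0; gi < g; ++gi) {
      im2col(acts[n.ins[0]], N, n, gi * cing, (gi + 1) * cing, col);
      out.rows(gi * cg, (gi + 1) * cg - 1) = W.cols(gi * cg, (gi + 1) * cg - 1).t() * col;
    }
    out.each_col() += b;
    acts[idx] = std::move(out);
    break;
  }
  case K_BN: {
    List pl = params[idx];
    arma::vec gam = as<arma::vec>(pl["gamma"]), bet = as<arma::vec>(pl["beta"]);
    arma::vec rm = as<arma::vec>(pl["rmean"]), rv = as<arma::vec>(pl["rvar"]);
    const arma::mat& A = acts[n.ins[0]];
    arma::vec mu, var;
    if (train) {
      mu = arma::mean(A, 1);
      arma::mat D = A.each_col() - mu;
      var = arma::mean(arma::square(D), 1);
      rm = (1.0 - bn_mom) * rm + bn_mom * mu;
      rv = (1.0 - bn_mom) * rv + bn_mom * var;
      pl["rmean"] = rm; pl["rvar"] = rv; params[idx] = pl;
    } else {
      mu = rm; var = rv;
    }
    arma::vec invstd = 1.0 / arma::sqrt(var + 1e-5);
    arma::mat xhat = (A.each_col() - mu).each_col() % invstd;
    acts[idx] = (xhat.each_col() % gam).each_col() + bet;
    if (need_cache) { C.bn_invstd = invstd; C.bn_mean = mu; }
    break;
  }
  case K_RELU:
    acts[idx] = arma::clamp(acts[n.ins[0]], 0.0, arma::datum::inf);
    break;
  case K_MAXPOOL: {
    const arma::mat& A = acts[n.ins[0]];
    const int HW = n.inH * n.inW, oHW = n.outH * n.outW;
    arma::mat out(n.rows, (arma::uword)N * oHW);
    arma::umat am(n.rows, (arma::uword)N * oHW);
    for (int img = 0; img < N; ++img) {
      const arma::uword in0 = (arma::uword)img * HW, out0 = (arma::uword)img * oHW;
      for (int ox = 0; ox < n.outW; ++ox) for (int oy = 0; oy < n.outH; ++oy) {
        const arma::uword q = out0 + oy + (arma::uword)n.outH * ox;
        const int x0 = ox * n.stride - n.padL, y0 = oy * n.stride - n.padT;
        for (int c = 0; c < n.rows; ++c) { out(c, q) = -arma::datum::inf; }
        for (int fx = 0; fx < n.fw; ++fx) {
          const int x = x0 + fx; if (x < 0 || x >= n.inW) continue;
          for (int fy = 0; fy < n.fh; ++fy) {
            const int y = y0 + fy; if (y < 0 || y >= n.inH) continue;
            const arma::uword p = in0 + y + (arma::uword)n.inH * x;
            for (int c = 0; c < n.rows; ++c) {
              if (A(c, p) > out(c, q)) { out(c, q) = A(c, p); am(c, q) = p; }
            }
          }
        }
      }
    }
    acts[idx] = std::move(out);
    if (need_cache) C.argmax = std::move(am);
    break;
  }
  case K_GAP: {
    const arma::mat& A = acts[n.ins[0]];
    const int HW = n.inH * n.inW;
    arma::mat out(n.rows, N);
    for (int img = 0; img < N; ++img) {
      out.col(img) = arma::mean(A.cols((arma::uword)img * HW, (arma::uword)(img + 1) * HW - 1), 1);
    }
    acts[idx] = std::move(out);
    break;
  }
  case K_CONCAT: {
    arma::mat out(n.rows, (arma::uword)N * n.P);
    int r0 = 0;
    for (int j : n.ins) {
      out.rows(r0, r0 + acts[j].n_rows - 1) = acts[j];
      r0 += acts[j].n_rows;
    }
    acts[idx] = std::move(out);
    break;
  }
  case K_FLATTEN:
    acts[idx] = acts[n.ins[0]];
    break;
  case K_ATTN: {
    List pl = params[idx];
    arma::mat Wq = as<arma::mat>(pl["Wq"]), Wk = as<arma::mat>(pl["Wk"]),
              Wv = as<arma::mat>(pl["Wv"]);
    const bool has_o = pl.containsElementNamed("Wo");
    arma::mat Wo;
    if (has_o) Wo = as<arma::mat>(pl["Wo"]);
    const arma::mat& A = acts[n.ins[0]];
    const int m = n.P, emb = n.rows, h = n.heads, dk = emb / h;
    arma::mat out(emb, N);
    if (need_cache) {
      C.attn_M.resize(N); C.attn_W.assign((size_t)N * h, arma::mat());
      C.attn_Q.assign((size_t)N * h, arma::mat());
      C.attn_K.assign((size_t)N * h, arma::mat());
      C.attn_V.assign((size_t)N * h, arma::mat());
      C.attn_O.resize(N);
    }
    for (int img = 0; img < N; ++img) {
      arma::mat M = A.cols((arma::uword)img * m, (arma::uword)(img + 1) * m - 1).t(); // m x emb
      arma::mat O(m, emb);
      for (int hd = 0; hd < h; ++hd) {
        arma::span cs(hd * dk, (hd + 1) * dk - 1);
        arma::mat Q = M * Wq.cols(cs), K = M * Wk.cols(cs), V = M * Wv.cols(cs);
        arma::mat S = Q * K.t() / std::sqrt((double)dk);
        arma::mat Wt = softmax_cols(S.t()).t();   // row-wise softmax
        O.cols(cs) = Wt * V;
        if (need_cache) {
          C.attn_W[(size_t)img * h + hd] = Wt;
          C.attn_Q[(size_t)img * h + hd] = std::move(Q);
          C.attn_K[(size_t)img * h + hd] = std::move(K);
          C.attn_V[(size_t)img * h + hd] = std::move(V);
        }
      }
      if (need_cache) { C.attn_M[img] = std::move(M); C.attn_O[img] = O; }
      arma::mat Of = has_o ? arma::mat(O * Wo) : O;
      out.col(img) = arma::mean(Of, 0).t();       // mean-pool over tokens
    }
    acts[idx] = std::move(out);
    break;
  }
  case K_FC: {
    List pl = params[idx];
    arma::mat W = as<arma::mat>(pl["W"]);  // out x in
    arma::vec b = as<arma::vec>(pl["b"]);
    acts[idx] = W * acts[n.ins[0]];
    acts[idx].each_col() += b;
    break;
  }
  case K_SOFTMAX:
    acts[idx] = softmax_cols(acts[n.ins[0]]);
    break;
  case K_CLASS:
    acts[idx] = acts[n.ins[0]];
    break;
  default: stop("unknown node kind");
  }
}

// backward one node: grads[idx] holds dL/d(out); accumulate into inputs and gradient list
static void backward_node(int idx, const std::vector<Node>& nodes, const List& params,
                          const std::vector<arma::mat>& acts, std::vector<Cache>& caches,
                          std::vector<arma::mat>& grads, List& pgrads, int N) {
  const Node& n = nodes[idx];
  if (grads[idx].n_elem == 0) return;
  const arma::mat& G = grads[idx];
  auto add_grad = [&](int j, const arma::mat& g) {
    if (grads[j].n_elem == 0) grads[j] = g; else grads[j] += g;
  };
  switch (n.kind) {
  case K_INPUT: break;
  case K_CONV: {
    List pl = params[idx];
    arma::mat W = as<arma::mat>(pl["W"]);
    const int Cout = n.rows, g = n.groups, cg = Cout / g, cing = n.inC / g;
    arma::mat dW(W.n_rows, W.n_cols);
    arma::mat dA(n.inC, (arma::uword)N * n.inH * n.inW, arma::fill::zeros);
    arma::mat col;
    for (int gi = 0; gi < g; ++gi) {
      arma::mat Gg = G.rows(gi * cg, (gi + 1) * cg - 1);
      im2col(acts[n.ins[0]], N, n, gi * cing, (gi + 1) * cing, col);
      dW.cols(gi * cg, (gi + 1) * cg - 1) = col * Gg.t();
      col.reset();
      arma::mat dcol = W.cols(gi * cg, (gi + 1) * cg - 1) * Gg;
      col2im(dcol, N, n, gi * cing, (gi + 1) * cing, dA);
    }
    arma::vec db = arma::sum(G, 1);
    pgrads[idx] = List::create(_["W"] = dW, _["b"] = db);
    add_grad(n.ins[0], dA);
    break;
  }
  case K_BN: {
    List pl = params[idx];
    arma::vec gam = as<arma::vec>(pl["gamma"]);
    Cache& C = caches[idx];
    const double Nc = (double)G.n_cols;
    arma::mat xhat = (acts[n.ins[0]].each_col() - C.bn_mean).each_col() % C.bn_invstd;
    arma::vec dgam = arma::sum(G % xhat, 1);
    arma::vec dbet = arma::sum(G, 1);
    // dx = gamma*invstd/Nc * (Nc*G - dbet - xhat*dgam)
    arma::mat dx = G * Nc;
    dx.each_col() -= dbet;
    dx -= xhat.each_col() % dgam;
    xhat.reset();
    dx.each_col() %= (gam % C.bn_invstd) / Nc;
    pgrads[idx] = List::create(_["gamma"] = dgam, _["beta"] = dbet);
    add_grad(n.ins[0], dx);
    break;
  }
  case K_RELU: {
    arma::mat dA = G % arma::conv_to<arma::mat>::from(acts[n.ins[0]] > 0.0);
    add_grad(n.ins[0], dA);
    break;
  }
  case K_MAXPOOL: {
    Cache& C = caches[idx];
    arma::mat dA(n.rows, (arma::uword)N * n.inH * n.inW, arma::fill::zeros);
    for (arma::uword q = 0; q < G.n_cols; ++q)
      for (int c = 0; c < n.rows; ++c)
        dA(c, C.argmax(c, q)) += G(c, q);
    add_grad(n.ins[0], dA);
    break;
  }
  case K_GAP: {
    const int HW = n.inH * n.inW;
    arma::mat dA(n.rows, (arma::uword)N * HW);
    for (int img = 0; img < N; ++img)
      dA.cols((arma::uword)img * HW, (arma::uword)(img + 1) * HW - 1) =
        arma::repmat(G.col(img) / (double)HW, 1, HW);
    add_grad(n.ins[0], dA);
    break;
  }
  case K_CONCAT: {
    int r0 = 0;
    for (int j : n.ins) {
      int rj = (int)acts[j].n_rows;
      add_grad(j, G.rows(r0, r0 + rj - 1));
      r0 += rj;
    }
    break;
  }
  case K_FLATTEN:
    add_grad(n.ins[0], G);
    break;
  case K_ATTN: {
    List pl = params[idx];
    arma::mat Wq = as<arma::mat>(pl["Wq"]), Wk = as<arma::mat>(pl["Wk"]),
              Wv = as<arma::mat>(pl["Wv"]);
    const bool has_o = pl.containsElementNamed("Wo");
    arma::mat Wo;
    if (has_o) Wo = as<arma::mat>(pl["Wo"]);
    Cache& C = caches[idx];
    const int m = n.P, emb = n.rows, h = n.heads, dk = emb / h;
    arma::mat dWq(emb, emb, arma::fill::zeros), dWk(emb, emb, arma::fill::zeros),
              dWv(emb, emb, arma::fill::zeros), dWo;
    if (has_o) dWo.zeros(emb, emb);
    arma::mat dAin(emb, (arma::uword)N * m, arma::fill::zeros);
    for (int img = 0; img < N; ++img) {
      // dL/dOf rows all equal G.col(img)'/m  (mean pool)
      arma::mat dOf = arma::repmat(G.col(img).t() / (double)m, m, 1);
      arma::mat dO;
      if (has_o) {
        dWo += C.attn_O[img].t() * dOf;
        dO = dOf * Wo.t();
      } else dO = dOf;
      const arma::mat& M = C.attn_M[img];
      arma::mat dM(m, emb, arma::fill::zeros);
      for (int hd = 0; hd < h; ++hd) {
        arma::span cs(hd * dk, (hd + 1) * dk - 1);
        const arma::mat& Wt = C.attn_W[(size_t)img * h + hd];
        const arma::mat& Q = C.attn_Q[(size_t)img * h + hd];
        const arma::mat& K = C.attn_K[(size_t)img * h + hd];
        const arma::mat& V = C.attn_V[(size_t)img * h + hd];
        arma::mat dOh = dO.cols(cs);
        arma::mat dV = Wt.t() * dOh;
        arma::mat dWt = dOh * V.t();
        arma::vec rs = arma::sum(dWt % Wt, 1);
        arma::mat dS = (dWt.each_col() - rs) % Wt;
        arma::mat dQ = dS * K / std::sqrt((double)dk);
        arma::mat dK = dS.t() * Q / std::sqrt((double)dk);
        dWq.cols(cs) += M.t() * dQ;
        dWk.cols(cs) += M.t() * dK;
        dWv.cols(cs) += M.t() * dV;
        dM += dQ * Wq.cols(cs).t() + dK * Wk.cols(cs).t() + dV * Wv.cols(cs).t();
      }
      dAin.cols((arma::uword)img * m, (arma::uword)(img + 1) * m - 1) = dM.t();
    }
    List gl = has_o
      ? List::create(_["Wq"] = dWq, _["Wk"] = dWk, _["Wv"] = dWv, _["Wo"] = dWo)
      : List::create(_["Wq"] = dWq, _["Wk"] = dWk, _["Wv"] = dWv);
    pgrads[idx] = gl;
    add_grad(n.ins[0], dAin);
    break;
  }
  case K_FC: {
    List pl = params[idx];
    arma::mat W = as<arma::mat>(pl["W"]);
    pgrads[idx] = List::create(_["W"] = arma::mat(G * acts[n.ins[0]].t()),
                               _["b"] = arma::vec(arma::sum(G, 1)));
    add_grad(n.ins[0], arma::mat(W.t() * G));
    break;
  }
  case K_SOFTMAX: case K_CLASS:
    add_grad(n.ins[0], G);  // not used in training (loss taken at logits)
    break;
  }
}

// build input activation (C x N*HW) for a subset of images from the R array
// X with dims (H, W, C, Ntot)
static arma::mat input_act(const NumericVector& X, int H, int W, int Cc, int Ntot,
                           const std::vector<int>& sel) {
  const int N = (int)sel.size(), HW = H * W;
  arma::mat A(Cc, (arma::uword)N * HW);
  const double* x = X.begin();
  for (int i = 0; i < N; ++i) {
    const arma::uword base = (arma::uword)sel[i] * HW * Cc;
    for (int c = 0; c < Cc; ++c) {
      const double* src = x + base + (arma::uword)c * HW;
      for (int s = 0; s < HW; ++s) A(c, (arma::uword)i * HW + s) = src[s];
    }
  }
  return A;
}

// [[Rcpp::export]]
List nf_forward_cpp(List spec, List params, NumericVector X, IntegerVector dims,
                    int tap, bool train, int chunk) {
  std::vector<Node> nodes = parse_spec(spec);
  const int H = dims[0], W = dims[1], Cc = dims[2], Ntot = dims[3];
  const int L = (int)nodes.size();
  if (tap < 0) tap = L - 1;
  arma::mat result;
  int done = 0;
  while (done < Ntot) {
    const int nb = std::min(chunk, Ntot - done);
    std::vector<int> sel(nb);
    for (int i = 0; i < nb; ++i) sel[i] = done + i;
    std::vector<arma::mat> acts(L);
    std::vector<Cache> caches(L);
    acts[0] = input_act(X, H, W, Cc, Ntot, sel);
    for (int i = 1; i <= tap; ++i)
      forward_node(i, nodes, params, acts, caches, nb, train, 0.1, false);
    arma::mat out = acts[tap].t();  // N x rows (vector nodes); maps: N*P x rows
    if (nodes[tap].P > 1) {
      // flatten map taps to one row per image: (rows*P) per image
      arma::mat flat(nb, (arma::uword)nodes[tap].rows * nodes[tap].P);
      const int P = nodes[tap].P;
      for (int i = 0; i < nb; ++i)
        flat.row(i) = arma::vectorise(acts[tap].cols((arma::uword)i * P,
                                                     (arma::uword)(i + 1) * P - 1)).t();
      out = flat;
    }
    result = result.n_rows ? arma::join_cols(result, out) : out;
    done += nb;
  }
  return List::create(_["act"] = result);
}

// [[Rcpp::export]]
List nf_train_cpp(List spec, List params, NumericVector X, IntegerVector dims,
                  IntegerVector y, int logit_node, IntegerMatrix order,
                  double lr, double momentum, int batch, double bn_mom) {
  std::vector<Node> nodes = parse_spec(spec);
  const int H = dims[0], W = dims[1], Cc = dims[2], Ntot = dims[3];
  const int L = (int)nodes.size(), epochs = order.nrow();
  params = clone(params);  // BN running stats and weights updated in place

  // momentum buffers, same shape as the updatable params
  std::vector<std::vector<arma::mat>> vel(L);
  std::vector<std::vector<std::string>> vkeys(L);
  for (int i = 0; i < L; ++i) {
    if (Rf_isNull(params[i])) continue;
    List pl = params[i];
    CharacterVector nm = pl.names();
    for (int j = 0; j < pl.size(); ++j) {
      std::string key = as<std::string>(nm[j]);
      if (key == "rmean" || key == "rvar") continue;
      arma::mat p = as<arma::mat>(pl[j]);
      vel[i].emplace_back(p.n_rows, p.n_cols, arma::fill::zeros);
      vkeys[i].push_back(key);
    }
  }

  std::vector<double> epoch_loss(epochs), batch_losses;
  for (int e = 0; e < epochs; ++e) {
    double eloss = 0.0; int ecount = 0;
    for (int b0 = 0; b0 < Ntot; b0 += batch) {
      const int nb = std::min(batch, Ntot - b0);
      std::vector<int> sel(nb);
      for (int i = 0; i < nb; ++i) sel[i] = order(e, b0 + i);
      std::vector<arma::mat> acts(L);
      std::vector<Cache> caches(L);
      acts[0] = input_act(X, H, W, Cc, Ntot, sel);
      for (int i = 1; i <= logit_node; ++i)
        forward_node(i, nodes, params, acts, caches, nb, true, bn_mom, true);
      // softmax cross-entropy at the logits
      arma::mat P = softmax_cols(acts[logit_node]);
      double loss = 0.0;
      arma::mat G = P;
      for (int i = 0; i < nb; ++i) {
        const int yi = y[sel[i]];
        loss -= std::log(std::max(P(yi, i), 1e-300));
        G(yi, i) -= 1.0;
      }
      loss /= nb; G /= nb;
      batch_losses.push_back(loss);
      eloss += loss * nb; ecount += nb;
      // backward
      std::vector<arma::mat> grads(L);
      List pgrads(L);
      grads[logit_node] = G;
      for (int i = logit_node; i >= 1; --i) {
        backward_node(i, nodes, params, acts, caches, grads, pgrads, nb);
        // node i's consumers and its own backward are done: release buffers
        grads[i].reset();
        acts[i].reset();
        caches[i].clear();
      }
      // SGD with momentum
      for (int i = 1; i <= logit_node; ++i) {
        if (Rf_isNull(pgrads[i])) continue;
        List pl = params[i], gl = pgrads[i];
        for (size_t j = 0; j < vkeys[i].size(); ++j) {
          const std::string& key = vkeys[i][j];
          if (!gl.containsElementNamed(key.c_str())) continue;
          arma::mat p = as<arma::mat>(pl[key]);
          arma::mat g = as<arma::mat>(gl[key]);
          vel[i][j] = momentum * vel[i][j] - lr * g;
          p += vel[i][j];
          pl[key] = p;
        }
        params[i] = pl;
      }
    }
    epoch_loss[e] = eloss / ecount;
  }
  return List::create(_["params"] = params,
                      _["epoch_loss"] = epoch_loss,
                      _["batch_loss"] = batch_losses);
}

// mean softmax cross-entropy of the full set under current params (train-mode
// batch statistics, no parameter updates) — the epoch-0 reference loss
// [[Rcpp::export]]
double nf_loss_cpp(List spec, List params, NumericVector X, IntegerVector dims,
                   IntegerVector y, int logit_node, int batch) {
  std::vector<Node> nodes = parse_spec(spec);
  const int H = dims[0], W = dims[1], Cc = dims[2], Ntot = dims[3];
  const int L = (int)nodes.size();
  double total = 0.0;
  for (int b0 = 0; b0 < Ntot; b0 += batch) {
    const int nb = std::min(batch, Ntot - b0);
    std::vector<int> sel(nb);
    for (int i = 0; i < nb; ++i) sel[i] = b0 + i;
    std::vector<arma::mat> acts(L);
    std::vector<Cache> caches(L);
    // duplicate params shallowly so running BN stats are not advanced
    List p2 = clone(params);
    acts[0] = input_act(X, H, W, Cc, Ntot, sel);
    for (int i = 1; i <= logit_node; ++i)
      forward_node(i, nodes, p2, acts, caches, nb, true, 0.1, false);
    arma::mat P = softmax_cols(acts[logit_node]);
    for (int i = 0; i < nb; ++i)
      total -= std::log(std::max(P(y[sel[i]], i), 1e-300));
  }
  return total / Ntot;
}
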