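// Convolutional network engine: forward/backward passes, Adam updates.
//
// Architecture (fixed family): four 5x5 "same" convolutions with ReLU,
// each followed by a 3x3 stride-2 valid max-pool and dropout, then a
// fully connected ReLU layer, dropout, and a 2-node softmax output.
// Feature maps are stored spatial-major: fmat (H*W, channels), so im2col
// columns are contiguous and convolutions reduce to GEMM.
//
// Single precision throughout; per-image forward/backward with gradient
// accumulation over the minibatch keeps memory bounded.

// [[Rcpp::depends(RcppArmadillo)]]
#include <RcppArmadillo.h>
#include <random>
using namespace Rcpp;
using namespace arma;

static inline int poolOut(int H) { return (H - 3) / 2 + 1; }

struct NetDims {
    int s, C, fc, nconv;
    int w[4];
    int H[5];   // spatial edge before conv k (H[0]=s) and after pools
    int flat;
};

static NetDims makeDims(IntegerVector d) {
    NetDims nd;
    nd.s = d[0]; nd.C = d[1];
    for (int k = 0; k < 4; ++k) nd.w[k] = d[2 + k];
    nd.fc = d[6];
    nd.nconv = 4;
    nd.H[0] = nd.s;
    for (int k = 0; k < 4; ++k) nd.H[k + 1] = poolOut(nd.H[k]);
    nd.flat = nd.H[4] * nd.H[4] * nd.w[3];
    return nd;
}

// im2col for 5x5 same-padded convolution on a (H*W, Cin) map.
static void im2col5(const fmat& F, int H, int W, fmat& M) {
    int Cin = F.n_cols;
    M.zeros(H * W, Cin * 25);
    for (int ch = 0; ch < Cin; ++ch) {
        const float* src = F.colptr(ch);
        for (int q = 0; q < 25; ++q) {
            int dr = q % 5 - 2, dc = q / 5 - 2;
            float* dst = M.colptr(ch * 25 + q);
            for (int c = 0; c < W; ++c) {
                int cs = c + dc;
                if (cs < 0 || cs >= W) continue;
                int r0 = dr < 0 ? -dr : 0;
                int r1 = dr > 0 ? H - dr : H;
                if (r1 > r0)
                    std::memcpy(dst + (size_t)c * H + r0,
                                src + (size_t)cs * H + r0 + dr,
                                (r1 - r0) * sizeof(float));
            }
        }
    }
}

// Transpose of im2col: scatter-accumulate dM back onto the input map.
static void col2im5(const fmat& dM, int H, int W, fmat& dF) {
    int Cin = dF.n_cols;
    for (int ch = 0; ch < Cin; ++ch) {
        float* dst = dF.colptr(ch);
        for (int q = 0; q < 25; ++q) {
            int dr = q % 5 - 2, dc = q / 5 - 2;
            const float* src = dM.colptr(ch * 25 + q);
            for (int c = 0; c < W; ++c) {
                int cs = c + dc;
                if (cs < 0 || cs >= W) continue;
                int r0 = dr < 0 ? -dr : 0;
                int r1 = dr > 0 ? H - dr : H;
                for (int r = r0; r < r1; ++r)
                    dst[(size_t)cs * H + r + dr] += src[(size_t)c * H + r];
            }
        }
    }
}

// 3x3 stride-2 valid max-pool; records the winning source index.
static void poolFwd(const fmat& A, int H, int W, fmat& P, umat& idx) {
    int H2 = poolOut(H), W2 = poolOut(W), C = A.n_cols;
    P.set_size(H2 * W2, C);
    idx.set_size(H2 * W2, C);
    for (int ch = 0; ch < C; ++ch) {
        const float* a = A.colptr(ch);
        float* p = P.colptr(ch);
        uword* ix = idx.colptr(ch);
        for (int c2 = 0; c2 < W2; ++c2) {
            for (int r2 = 0; r2 < H2; ++r2) {
                int rb = 2 * r2, cb = 2 * c2;
                float best = -std::numeric_limits<float>::infinity();
                int bi = 0;
                for (int dc = 0; dc < 3; ++dc)
                    for (int dr = 0; dr < 3; ++dr) {
                        int k = (cb + dc) * H + rb + dr;
                        if (a[k] > best) { best = a[k]; bi = k; }
                    }
                p[c2 * H2 + r2] = best;
                ix[c2 * H2 + r2] = bi;
            }
        }
    }
}

static void poolBwd(const fmat& dP, const umat& idx, int H, int W, fmat& dA) {
    int C = dP.n_cols;
    dA.zeros(H * W, C);
    for (int ch = 0; ch < C; ++ch) {
        float* da = dA.colptr(ch);
        const float* dp = dP.colptr(ch);
        const uword* ix = idx.colptr(ch);
        for (uword i = 0; i < dP.n_rows; ++i) da[ix[i]] += dp[i];
    }
}

struct Weights {
    fmat Wc[4];      // (Cin*25, Cout)
    frowvec bc[4];
    fmat F1, F2;     // (flat, fc), (fc, 2)
    frowvec bf1, bf2;
};

static fmat asF(SEXP m) {
    NumericMatrix nm(m);
    fmat out(nm.nrow(), nm.ncol());
    for (int j = 0; j < nm.ncol(); ++j)
        for (int i = 0; i < nm.nrow(); ++i)
            out(i, j) = (float)nm(i, j);
    return out;
}
static frowvec asFrow(SEXP v) {
    NumericVector nv(v);
    frowvec out(nv.size());
    for (int i = 0; i < nv.size(); ++i) out(i) = (float)nv[i];
    return out;
}
static NumericMatrix toR(const fmat& m) {
    NumericMatrix out(m.n_rows, m.n_cols);
    for (uword j = 0; j < m.n_cols; ++j)
        for (uword i = 0; i < m.n_rows; ++i)
            out(i, j) = m(i, j);
    return out;
}
static NumericVector toRvec(const frowvec& v) {
    NumericVector out(v.n_elem);
    for (uword i = 0; i < v.n_elem; ++i) out[i] = v(i);
    return out;
}

static Weights unpack(List w) {
    Weights W;
    for (int k = 0; k < 4; ++k) {
        W.Wc[k] = asF(w[2 * k]);
        W.bc[k] = asFrow(w[2 * k + 1]);
    }
    W.F1 = asF(w[8]);  W.bf1 = asFrow(w[9]);
    W.F2 = asF(w[10]); W.bf2 = asFrow(w[11]);
    return W;
}

static List pack(const Weights& W) {
    return List::create(
        _["W1"] = toR(W.Wc[0]), _["b1"] = toRvec(W.bc[0]),
        _["W2"] = toR(W.Wc[1]), _["b2"] = toRvec(W.bc[1]),
        _["W3"] = toR(W.Wc[2]), _["b3"] = toRvec(W.bc[2]),
        _["W4"] = toR(W.Wc[3]), _["b4"] = toRvec(W.bc[3]),
        _["F1"] = toR(W.F1), _["bf1"] = toRvec(W.bf1),
        _["F2"] = toR(W.F2), _["bf2"] = toRvec(W.bf2));
}

// Extract image i of the (s*s*C, n) input as a (s*s, C) map.
static fmat imageMap(const double* X, const NetDims& nd, int i) {
    fmat F(nd.s * nd.s, nd.C);
    const double* base = X + (size_t)i * nd.s * nd.s * nd.C;
    for (int ch = 0; ch < nd.C; ++ch) {
        float* dst = F.colptr(ch);
        const double* src = base + (size_t)ch * nd.s * nd.s;
        for (int k = 0; k < nd.s * nd.s; ++k) dst[k] = (float)src[k];
    }
    return F;
}

struct Cache {
    fmat M[4];     // im2col matrices
    fmat A[4];     // post-ReLU conv outputs
    umat idx[4];   // pool argmax
    fmat mask[4];  // dropout masks applied to pooled maps
    fvec xflat, a5, mask5;
    fvec prob;
};

// Forward pass for one image; `train` enables dropout and cache filling.
static fvec forwardOne(const Weights& W, const NetDims& nd, const fmat& F0,
                       bool train, float drop, std::mt19937* rng,
                       Cache* cc) {
    std::uniform_real_distribution<float> unif(0.0f, 1.0f);
    float keep = 1.0f - drop;
    fmat cur = F0;
    for (int k = 0; k < 4; ++k) {
        int H = nd.H[k];
        fmat M;
        im2col5(cur, H, H, M);
        fmat A = M * W.Wc[k];
        A.each_row() += W.bc[k];
        A.transform([](float v) { return v > 0 ? v : 0.0f; });
        fmat P; umat idx;
        poolFwd(A, H, H, P, idx);
        if (train) {
            fmat mask(P.n_rows, P.n_cols);
            for (uword j = 0; j < mask.n_elem; ++j)
                mask(j) = unif(*rng) < keep ? 1.0f / keep : 0.0f;
            P %= mask;
            cc->M[k] = std::move(M);
            cc->A[k] = std::move(A);
            cc->idx[k] = std::move(idx);
            cc->mask[k] = std::move(mask);
        }
        cur = std::move(P);
    }
    fvec xflat = vectorise(cur);
    fvec z5 = W.F1.t() * xflat + W.bf1.t();
    fvec a5 = z5;
    a5.transform([](float v) { return v > 0 ? v : 0.0f; });
    fvec mask5;
    if (train) {
        mask5.set_size(a5.n_elem);
        for (uword j = 0; j < a5.n_elem; ++j)
            mask5(j) = unif(*rng) < keep ? 1.0f / keep : 0.0f;
        a5 %= mask5;
    }
    fvec logit = W.F2.t() * a5 + W.bf2.t();
    float mx = logit.max();
    fvec ex = exp(logit - mx);
    fvec prob = ex / accu(ex);
    if (train) {
        cc->xflat = std::move(xflat);
        cc->a5 = std::move(a5);
        cc->mask5 = std::move(mask5);
        cc->prob = prob;
    }
    return prob;
}

struct Grads {
    fmat Wc[4]; frowvec bc[4];
    fmat F1, F2; frowvec bf1, bf2;
    void zero(const Weights& W) {
        for (int k = 0; k < 4; ++k) {
            Wc[k].zeros(W.Wc[k].n_rows, W.Wc[k].n_cols);
            bc[k].zeros(W.bc[k].n_elem);
        }
        F1.zeros(W.F1.n_rows, W.F1.n_cols);
        F2.zeros(W.F2.n_rows, W.F2.n_cols);
        bf1.zeros(W.bf1.n_elem);
        bf2.zeros(W.bf2.n_elem);
    }
};

static void backwardOne(const Weights& W, const NetDims& nd, Cache& cc,
                        int y, Grads& G) {
    fvec dlog = cc.prob;
    dlog(y) -= 1.0f;                        // softmax + cross-entropy
    G.F2 += cc.a5 * dlog.t();
    G.bf2 += dlog.t();
    fvec da5 = W.F2 * dlog;
    da5 %= cc.mask5;
    for (uword j = 0; j < da5.n_elem; ++j)
        if (cc.a5(j) <= 0 && cc.mask5(j) != 0) da5(j) = 0;
    // note: a5 was masked after ReLU; mask!=0 and a5==0 means ReLU clipped
    G.F1 += cc.xflat * da5.t();
    G.bf1 += da5.t();
    fvec dxflat = W.F1 * da5;
    int H4 = nd.H[4];
    fmat dP = reshape(dxflat, H4 * H4, nd.w[3]);
    for (int k = 3; k >= 0; --k) {
        int H = nd.H[k];
        dP %= cc.mask[k];
        fmat dA;
        poolBwd(dP, cc.idx[k], H, H, dA);
        dA %= conv_to<fmat>::from(cc.A[k] > 0);
        G.Wc[k] += cc.M[k].t() * dA;
        G.bc[k] += sum(dA, 0);
        if (k > 0) {
            fmat dM = dA * W.Wc[k].t();
            fmat dF;
            dF.zeros(H * H, cc.mask[k - 1].n_cols);
            col2im5(dM, H, H, dF);
            dP = std::move(dF);
        }
    }
}

static void adamStep(fmat& W, fmat& m, fmat& v, const fmat& g, float lr,
                     float b1, float b2, float eps, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    float c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    W -= lr * (m / c1) / (sqrt(v / c2) + eps);
}
static void adamStepRow(frowvec& W, frowvec& m, frowvec& v,
                        const frowvec& g, float lr, float b1, float b2,
                        float eps, int t) {
    m = b1 * m + (1 - b1) * g;
    v = b2 * v + (1 - b2) * square(g);
    float c1 = 1 - std::pow(b1, t), c2 = 1 - std::pow(b2, t);
    W -= lr * (m / c1) / (sqrt(v / c2) + eps);
}

struct AdamState { Weights m, v; int t; };

static Weights zerosLike(const Weights& W) {
    Weights Z;
    for (int k = 0; k < 4; ++k) {
        Z.Wc[k].zeros(W.Wc[k].n_rows, W.Wc[k].n_cols);
        Z.bc[k].zeros(W.bc[k].n_elem);
    }
    Z.F1.zeros(W.F1.n_rows, W.F1.n_cols);
    Z.F2.zeros(W.F2.n_rows, W.F2.n_cols);
    Z.bf1.zeros(W.bf1.n_elem);
    Z.bf2.zeros(W.bf2.n_elem);
    return Z;
}

// [[Rcpp::export(name = ".cnnEpoch")]]
List cnnEpoch(List weights, List mState, List vState, int tStep,
              NumericVector X, IntegerVector y, IntegerVector ord,
              int batchSize, double lr, double beta1, double beta2,
              double eps, double drop, int seed, IntegerVector dims) {
    NetDims nd = makeDims(dims);
    Weights W = unpack(weights);
    Weights M = mState.size() ? unpack(mState) : zerosLike(W);
    Weights V = vState.size() ? unpack(vState) : zerosLike(W);
    const double* Xp = REAL(X);
    std::mt19937 rng((unsigned)seed);
    int n = ord.size();
    double lossSum = 0;
    const float clampEps = 1e-7f;
    for (int b0 = 0; b0 < n; b0 += batchSize) {
        int bs = std::min(batchSize, n - b0);
        Grads G;
        G.zero(W);
        for (int j = 0; j < bs; ++j) {
            int i = ord[b0 + j] - 1;
            fmat F0 = imageMap(Xp, nd, i);
            Cache cc;
            fvec p = forwardOne(W, nd, F0, true, (float)drop, &rng, &cc);
            float yhat = std::min(std::max(p(1), clampEps), 1 - clampEps);
            lossSum += y[i] == 1 ? -std::log(yhat) : -std::log(1 - yhat);
            backwardOne(W, nd, cc, y[i], G);
        }
        float inv = 1.0f / bs;
        ++tStep;
        for (int k = 0; k < 4; ++k) {
            adamStep(W.Wc[k], M.Wc[k], V.Wc[k], G.Wc[k] * inv, (float)lr,
                     (float)beta1, (float)beta2, (float)eps, tStep);
            adamStepRow(W.bc[k], M.bc[k], V.bc[k], G.bc[k] * inv, (float)lr,
                        (float)beta1, (float)beta2, (float)eps, tStep);
        }
        adamStep(W.F1, M.F1, V.F1, G.F1 * inv, (float)lr, (float)beta1,
                 (float)beta2, (float)eps, tStep);
        adamStepRow(W.bf1, M.bf1, V.bf1, G.bf1 * inv, (float)lr,
                    (float)beta1, (float)beta2, (float)eps, tStep);
        adamStep(W.F2, M.F2, V.F2, G.F2 * inv, (float)lr, (float)beta1,
                 (float)beta2, (float)eps, tStep);
        adamStepRow(W.bf2, M.bf2, V.bf2, G.bf2 * inv, (float)lr,
                    (float)beta1, (float)beta2, (float)eps, tStep);
    }
    return List::create(_["weights"] = pack(W), _["m"] = pack(M),
                        _["v"] = pack(V), _["t"] = tStep,
                        _["trainLoss"] = lossSum / n);
}

// [[Rcpp::export(name = ".cnnForward")]]
NumericMatrix cnnForward(List weights, NumericVector X, IntegerVector dims,
                         int n) {
    NetDims nd = makeDims(dims);
    Weights W = unpack(weights);
    const double* Xp = REAL(X);
    NumericMatrix out(n, 2);
    for (int i = 0; i < n; ++i) {
        fmat F0 = imageMap(Xp, nd, i);
        fvec p = forwardOne(W, nd, F0, false, 0.0f, nullptr, nullptr);
        out(i, 0) = p(0);
        out(i, 1) = p(1);
    }
    return out;
}
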