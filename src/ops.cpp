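// Single-precision tensor kernels for the transformer engine.
//
// Activations travel through the encoder as external pointers to
// arma::fmat (float32) so the per-step cost is dominated by sgemm; model
// parameters are kept in double on the R side (master weights) and are
// converted at the call boundary, which is cheap because they are small.
// Gradients returned for parameters are double; gradients for activations
// stay float32. The geometric tail of the network (orthogonal layer, VHS,
// losses) runs in double precision on the R side.
//
// Memory discipline: every activation-sized output is written directly into
// a persistent bump-allocator arena that is recycled once per training step
// (arena_reset()), so the working set stays in warm pages; without this the
// step time is dominated by soft page faults from cold mallocs.

#define ARMA_NO_DEBUG
#include <RcppArmadillo.h>
// [[Rcpp::depends(RcppArmadillo)]]

using namespace Rcpp;
using arma::fmat;
using arma::frowvec;

typedef XPtr<fmat> fptr;

static fmat as_f(SEXP x) {
  if (TYPEOF(x) == EXTPTRSXP) {
    fptr p(x);
    return *p;                      // copy; used only for small params
  }
  NumericMatrix m(x);
  fmat out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// borrow without copying when x is already a float pointer
static const fmat& deref(SEXP x, fmat& scratch) {
  if (TYPEOF(x) == EXTPTRSXP) {
    fptr p(x);
    return *p;
  }
  scratch = as_f(x);
  return scratch;
}

static const size_t kChunkFloats = 16u << 20;  // 64 MB per chunk

struct Arena {
  std::vector<std::unique_ptr<std::vector<float> > > chunks;
  size_t cur_chunk = 0;
  size_t used = 0;
  size_t total_alloc = 0;
  float* alloc(size_t n) {
    total_alloc += n;
    if (chunks.empty()) {
      chunks.emplace_back(new std::vector<float>(std::max(kChunkFloats, n)));
      cur_chunk = 0;
      used = 0;
    }
    if (used + n > chunks[cur_chunk]->size()) {
      ++cur_chunk;
      if (cur_chunk >= chunks.size())
        chunks.emplace_back(new std::vector<float>(std::max(kChunkFloats, n)));
      else if (chunks[cur_chunk]->size() < n)
        chunks[cur_chunk]->resize(n);
      used = 0;
    }
    float* p = chunks[cur_chunk]->data() + used;
    used += n;
    return p;
  }
  void reset() {
    cur_chunk = 0;
    used = 0;
    total_alloc = 0;
  }
};

static Arena g_arena;

// Large local temporaries would otherwise be mmap'd/munmap'd on every call
// by glibc (default threshold 128 KB), paying soft page faults each time;
// raise the threshold so they come from the recycled heap instead.
#ifdef __GLIBC__
#include <malloc.h>
struct MallocTuner {
  MallocTuner() {
    mallopt(M_MMAP_THRESHOLD, 256 * 1024 * 1024);
    mallopt(M_TRIM_THRESHOLD, 256 * 1024 * 1024);
  }
};
static MallocTuner g_malloc_tuner;
#endif

// [[Rcpp::export]]
void arena_reset() { g_arena.reset(); }

// [[Rcpp::export]]
NumericVector arena_stats() {
  return NumericVector::create(
    _["chunks"] = (double)g_arena.chunks.size(),
    _["alloc_floats"] = (double)g_arena.total_alloc);
}

// fresh arena-backed matrix; header freed by the R external-pointer
// finalizer, buffer recycled at the next arena_reset
static fmat* arena_out(size_t r, size_t c) {
  return new fmat(g_arena.alloc(r * c), r, c, false, true);
}

static SEXP own(fmat* m) { return fptr(m, true); }

// persistent (non-arena) tensor: survives arena_reset; used for long-lived
// constants such as interpolation matrices
// [[Rcpp::export]]
SEXP f32_new(NumericMatrix m) {
  fmat* out = new fmat(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out->begin());
  return fptr(out, true);
}

// arena-backed tensor from an R matrix (per-step inputs)
// [[Rcpp::export]]
SEXP f32_new_arena(NumericMatrix m) {
  fmat* out = arena_out(m.nrow(), m.ncol());
  std::copy(m.begin(), m.end(), out->begin());
  return own(out);
}

// [[Rcpp::export]]
NumericMatrix f32_get(SEXP x) {
  fmat s;
  const fmat& m = deref(x, s);
  NumericMatrix out(m.n_rows, m.n_cols);
  std::copy(m.begin(), m.end(), out.begin());
  return out;
}

// [[Rcpp::export]]
IntegerVector f32_dims(SEXP x) {
  fmat s;
  const fmat& m = deref(x, s);
  return IntegerVector::create((int)m.n_rows, (int)m.n_cols);
}

// [[Rcpp::export]]
SEXP f32_gemm(SEXP a, SEXP b, bool ta = false, bool tb = false) {
  fmat sa, sb;
  const fmat& A = deref(a, sa);
  const fmat& B = deref(b, sb);
  size_t r = ta ? A.n_cols : A.n_rows;
  size_t c = tb ? B.n_rows : B.n_cols;
  fmat* out = arena_out(r, c);
  if (!ta && !tb) *out = A * B;
  else if (ta && !tb) *out = A.t() * B;
  else if (!ta && tb) *out = A * B.t();
  else *out = A.t() * B.t();
  return own(out);
}

// gemm returning a double R matrix (parameter gradients)
// [[Rcpp::export]]
NumericMatrix f32_gemm_d(SEXP a, SEXP b, bool ta = false, bool tb = false) {
  fmat sa, sb;
  const fmat& A = deref(a, sa);
  const fmat& B = deref(b, sb);
  fmat res;
  if (!ta && !tb) res = A * B;
  else if (ta && !tb) res = A.t() * B;
  else if (!ta && tb) res = A * B.t();
  else res = A.t() * B.t();
  NumericMatrix out(res.n_rows, res.n_cols);
  std::copy(res.begin(), res.end(), out.begin());
  return out;
}

// fused fully connected layer: a %*% W + bias (bias row-broadcast)
// [[Rcpp::export]]
SEXP f32_linear(SEXP a, SEXP w, SEXP b) {
  fmat sa, sw, sb;
  const fmat& A = deref(a, sa);
  const fmat& W = deref(w, sw);
  const fmat& Bv = deref(b, sb);
  fmat* out = arena_out(A.n_rows, W.n_cols);
  *out = A * W;
  out->each_row() += Bv.row(0);
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_add(SEXP a, SEXP b) {
  fmat sa, sb;
  const fmat& A = deref(a, sa);
  const fmat& B = deref(b, sb);
  fmat* out = arena_out(A.n_rows, A.n_cols);
  *out = A + B;
  return own(out);
}

// [[Rcpp::export]]
void f32_add_inplace(SEXP a, SEXP b) {
  fptr pa(a);
  fmat sb;
  *pa += deref(b, sb);
}

// [[Rcpp::export]]
SEXP f32_scale(SEXP a, double k) {
  fmat sa;
  const fmat& A = deref(a, sa);
  fmat* out = arena_out(A.n_rows, A.n_cols);
  *out = A * (float)k;
  return own(out);
}

// [[Rcpp::export]]
NumericMatrix f32_colsums(SEXP g) {
  fmat s;
  const fmat& G = deref(g, s);
  frowvec cs = arma::sum(G, 0);
  NumericMatrix out(1, G.n_cols);
  for (arma::uword j = 0; j < G.n_cols; ++j) out(0, j) = cs(j);
  return out;
}

// add an N x C table to a (B*N) x C stacked sequence
// [[Rcpp::export]]
SEXP f32_posadd(SEXP a, SEXP p, int B) {
  fmat sa, sp;
  const fmat& A = deref(a, sa);
  const fmat& P = deref(p, sp);
  int N = P.n_rows;
  fmat* out = arena_out(A.n_rows, A.n_cols);
  *out = A;
  for (int b = 0; b < B; ++b)
    out->rows(b * N, (b + 1) * N - 1) += P;
  return own(out);
}

// [[Rcpp::export]]
NumericMatrix f32_posadd_bwd(SEXP g, int N, int B) {
  fmat s;
  const fmat& G = deref(g, s);
  fmat acc(N, G.n_cols, arma::fill::zeros);
  for (int b = 0; b < B; ++b)
    acc += G.rows(b * N, (b + 1) * N - 1);
  NumericMatrix out(N, G.n_cols);
  std::copy(acc.begin(), acc.end(), out.begin());
  return out;
}

// exact GELU x * Phi(x) via erf
// [[Rcpp::export]]
SEXP f32_gelu(SEXP x) {
  fmat s;
  const fmat& X = deref(x, s);
  fmat* out = arena_out(X.n_rows, X.n_cols);
  const float inv_sqrt2 = 0.70710678f;
  const float* xp = X.memptr();
  float* op = out->memptr();
  size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) {
    float v = xp[i];
    op[i] = 0.5f * v * (1.0f + std::erf(v * inv_sqrt2));
  }
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_gelu_bwd(SEXP x, SEXP g) {
  fmat sx, sg;
  const fmat& X = deref(x, sx);
  const fmat& G = deref(g, sg);
  fmat* out = arena_out(X.n_rows, X.n_cols);
  const float inv_sqrt2 = 0.70710678f;
  const float inv_sqrt2pi = 0.39894228f;
  const float* xp = X.memptr();
  const float* gp = G.memptr();
  float* op = out->memptr();
  size_t n = X.n_elem;
  for (size_t i = 0; i < n; ++i) {
    float v = xp[i];
    float Phi = 0.5f * (1.0f + std::erf(v * inv_sqrt2));
    float phi = inv_sqrt2pi * std::exp(-0.5f * v * v);
    op[i] = gp[i] * (Phi + v * phi);
  }
  return own(out);
}

// row-wise layer normalization; returns value and backward stash.
// loops run column-major (contiguous) with per-row accumulator buffers.
// [[Rcpp::export]]
List f32_layernorm(SEXP x, SEXP gain, SEXP bias, double eps = 1e-5) {
  fmat sx, sg, sb;
  const fmat& X = deref(x, sx);
  const fmat& Gn = deref(gain, sg);
  const fmat& Bs = deref(bias, sb);
  int n = X.n_rows, C = X.n_cols;
  fmat* xhat = arena_out(n, C);
  fmat* val = arena_out(n, C);
  fmat* inv = arena_out(n, 1);
  std::vector<float> mu(n, 0.0f), var(n, 0.0f);
  const float* xp = X.memptr();
  for (int j = 0; j < C; ++j) {
    const float* col = xp + (size_t)j * n;
    for (int i = 0; i < n; ++i) mu[i] += col[i];
  }
  for (int i = 0; i < n; ++i) mu[i] /= C;
  for (int j = 0; j < C; ++j) {
    const float* col = xp + (size_t)j * n;
    for (int i = 0; i < n; ++i) {
      float d = col[i] - mu[i];
      var[i] += d * d;
    }
  }
  float* ivp = inv->memptr();
  for (int i = 0; i < n; ++i)
    ivp[i] = 1.0f / std::sqrt(var[i] / C + (float)eps);
  float* xhp = xhat->memptr();
  float* vp = val->memptr();
  for (int j = 0; j < C; ++j) {
    const float* col = xp + (size_t)j * n;
    float* xh = xhp + (size_t)j * n;
    float* vv = vp + (size_t)j * n;
    float gj = Gn(0, j), bj = Bs(0, j);
    for (int i = 0; i < n; ++i) {
      float h = (col[i] - mu[i]) * ivp[i];
      xh[i] = h;
      vv[i] = h * gj + bj;
    }
  }
  return List::create(_["val"] = own(val), _["xhat"] = own(xhat),
                      _["inv"] = own(inv));
}

// [[Rcpp::export]]
List f32_layernorm_bwd(SEXP g, SEXP xhat, SEXP inv, SEXP gain) {
  fmat sg, sx, si, sn;
  const fmat& G = deref(g, sg);
  const fmat& Xh = deref(xhat, sx);
  const fmat& Iv = deref(inv, si);
  const fmat& Gn = deref(gain, sn);
  int n = G.n_rows, C = G.n_cols;
  fmat* dx = arena_out(n, C);
  NumericMatrix dgain(1, C), dbias(1, C);
  const float* gp = G.memptr();
  const float* xhp = Xh.memptr();
  const float* ivp = Iv.memptr();
  std::vector<float> m1(n, 0.0f), m2(n, 0.0f);
  for (int j = 0; j < C; ++j) {
    const float* gc = gp + (size_t)j * n;
    const float* xc = xhp + (size_t)j * n;
    float gj = Gn(0, j);
    double sg1 = 0.0, sb1 = 0.0;
    for (int i = 0; i < n; ++i) {
      float dxh = gc[i] * gj;
      m1[i] += dxh;
      m2[i] += dxh * xc[i];
      sg1 += (double)gc[i] * xc[i];
      sb1 += gc[i];
    }
    dgain(0, j) = sg1;
    dbias(0, j) = sb1;
  }
  for (int i = 0; i < n; ++i) {
    m1[i] /= C;
    m2[i] /= C;
  }
  float* dxp = dx->memptr();
  for (int j = 0; j < C; ++j) {
    const float* gc = gp + (size_t)j * n;
    const float* xc = xhp + (size_t)j * n;
    float* dc = dxp + (size_t)j * n;
    float gj = Gn(0, j);
    for (int i = 0; i < n; ++i)
      dc[i] = ivp[i] * (gc[i] * gj - m1[i] - xc[i] * m2[i]);
  }
  return List::create(_["dx"] = own(dx), _["dgain"] = dgain,
                      _["dbias"] = dbias);
}

// gather-and-concatenate rows (im2col / patch grouping); idx is Nout x K,
// 1-based, NA = zero row. Output column k*C+j is contiguous; the inner loop
// walks it sequentially.
// [[Rcpp::export]]
SEXP f32_gather_cbind(SEXP x, IntegerMatrix idx) {
  fmat s;
  const fmat& X = deref(x, s);
  int C = X.n_cols, K = idx.ncol(), Nout = idx.nrow();
  size_t nin = X.n_rows;
  fmat* out = arena_out(Nout, (size_t)K * C);
  const float* xp = X.memptr();
  float* op = out->memptr();
  for (int k = 0; k < K; ++k) {
    const int* rows = &idx(0, k);
    for (int j = 0; j < C; ++j) {
      const float* xc = xp + (size_t)j * nin;
      float* oc = op + ((size_t)k * C + j) * Nout;
      for (int i = 0; i < Nout; ++i) {
        int r = rows[i];
        oc[i] = (r == NA_INTEGER) ? 0.0f : xc[r - 1];
      }
    }
  }
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_gather_bwd(SEXP g, IntegerMatrix idx, int nrow_in, int C) {
  fmat s;
  const fmat& G = deref(g, s);
  int K = idx.ncol(), Nout = idx.nrow();
  fmat* out = arena_out(nrow_in, C);
  out->zeros();
  const float* gp = G.memptr();
  float* op = out->memptr();
  for (int k = 0; k < K; ++k) {
    const int* rows = &idx(0, k);
    for (int j = 0; j < C; ++j) {
      const float* gc = gp + ((size_t)k * C + j) * Nout;
      float* oc = op + (size_t)j * nrow_in;
      for (int i = 0; i < Nout; ++i) {
        int r = rows[i];
        if (r != NA_INTEGER) oc[r - 1] += gc[i];
      }
    }
  }
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_cbind2(SEXP a, SEXP b) {
  fmat sa, sb;
  const fmat& A = deref(a, sa);
  const fmat& B = deref(b, sb);
  fmat* out = arena_out(A.n_rows, A.n_cols + B.n_cols);
  out->cols(0, A.n_cols - 1) = A;
  out->cols(A.n_cols, A.n_cols + B.n_cols - 1) = B;
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_cols(SEXP x, int from, int to) {
  fmat s;
  const fmat& X = deref(x, s);
  fmat* out = arena_out(X.n_rows, to - from + 1);
  *out = X.cols(from - 1, to - 1);
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_mean_pool(SEXP x, int B, int N) {
  fmat s;
  const fmat& X = deref(x, s);
  fmat* out = arena_out(B, X.n_cols);
  for (int b = 0; b < B; ++b)
    out->row(b) = arma::mean(X.rows(b * N, (b + 1) * N - 1), 0);
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_mean_pool_bwd(SEXP g, int B, int N) {
  fmat s;
  const fmat& G = deref(g, s);
  fmat* out = arena_out((size_t)B * N, G.n_cols);
  for (int b = 0; b < B; ++b) {
    frowvec r = G.row(b) / (float)N;
    out->rows(b * N, (b + 1) * N - 1).each_row() = r;
  }
  return own(out);
}

// per-image interpolation by a fixed (Nout x Nin) matrix (bilinear upsample)
// [[Rcpp::export]]
SEXP f32_interp(SEXP x, SEXP U, int B) {
  fmat sx, su;
  const fmat& X = deref(x, sx);
  const fmat& Um = deref(U, su);
  int Nin = Um.n_cols, Nout = Um.n_rows, C = X.n_cols;
  fmat* out = arena_out((size_t)B * Nout, C);
  for (int b = 0; b < B; ++b)
    out->rows(b * Nout, (b + 1) * Nout - 1) =
      Um * X.rows(b * Nin, (b + 1) * Nin - 1);
  return own(out);
}

// [[Rcpp::export]]
SEXP f32_interp_bwd(SEXP g, SEXP U, int B) {
  fmat sg, su;
  const fmat& G = deref(g, sg);
  const fmat& Um = deref(U, su);
  int Nin = Um.n_cols, Nout = Um.n_rows, C = G.n_cols;
  fmat* out = arena_out((size_t)B * Nin, C);
  for (int b = 0; b < B; ++b)
    out->rows(b * Nin, (b + 1) * Nin - 1) =
      Um.t() * G.rows(b * Nout, (b + 1) * Nout - 1);
  return own(out);
}

// Multi-head scaled-dot-product attention over a stacked batch.
// q: (B*Nq) x (H*dh); k, v: (B*Nk) x (H*dh). Optional per-head relative
// bias table (n_off x H, double) indexed by bias_idx (Nq x Nk, 1-based).
// Returns output and the softmax maps needed for backward (one column per
// (image, head) slice).
// [[Rcpp::export]]
List f32_attention(SEXP q, SEXP k, SEXP v, int B, int H, int dh,
                   Nullable<NumericMatrix> bias = R_NilValue,
                   Nullable<IntegerMatrix> bias_idx = R_NilValue) {
  fmat sq, sk, sv;
  const fmat& Q = deref(q, sq);
  const fmat& K = deref(k, sk);
  const fmat& V = deref(v, sv);
  int Nq = Q.n_rows / B, Nk = K.n_rows / B;
  float scale = 1.0f / std::sqrt((float)dh);
  fmat* out = arena_out(Q.n_rows, Q.n_cols);
  fmat* Aflat = arena_out((size_t)Nq * Nk, (size_t)B * H);
  fmat bmat;
  bool has_bias = bias.isNotNull();
  if (has_bias) {
    NumericMatrix bb(bias.get());
    IntegerMatrix bidx(bias_idx.get());
    bmat.set_size(Nq * Nk, H);
    for (int h = 0; h < H; ++h) {
      float* bc = bmat.colptr(h);
      for (int i = 0; i < Nq * Nk; ++i)
        bc[i] = (float)bb(bidx[i] - 1, h);
    }
  }
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      // softmax map computed in place inside its Aflat column slice
      fmat Ai(Aflat->colptr(b * H + h), Nq, Nk, false, true);
      Ai = Q.submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1) *
           K.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1).t() *
           scale;
      if (has_bias)
        Ai += arma::reshape(bmat.col(h), Nq, Nk);
      for (int i = 0; i < Nq; ++i) {
        float mx = Ai.row(i).max();
        float sum = 0.0f;
        for (int j = 0; j < Nk; ++j) {
          float e = std::exp(Ai(i, j) - mx);
          Ai(i, j) = e;
          sum += e;
        }
        Ai.row(i) /= sum;
      }
      out->submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1) =
        Ai * V.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1);
    }
  }
  return List::create(_["val"] = own(out), _["attn"] = own(Aflat));
}

// [[Rcpp::export]]
List f32_attention_bwd(SEXP g, SEXP q, SEXP k, SEXP v, SEXP attn,
                       int B, int H, int dh,
                       Nullable<IntegerMatrix> bias_idx = R_NilValue,
                       int n_off = 0) {
  fmat sg, sq, sk, sv, sa;
  const fmat& G = deref(g, sg);
  const fmat& Q = deref(q, sq);
  const fmat& K = deref(k, sk);
  const fmat& V = deref(v, sv);
  const fmat& Af = deref(attn, sa);
  int Nq = Q.n_rows / B, Nk = K.n_rows / B;
  float scale = 1.0f / std::sqrt((float)dh);
  fmat* dQ = arena_out(Q.n_rows, Q.n_cols);
  fmat* dK = arena_out(K.n_rows, K.n_cols);
  fmat* dV = arena_out(V.n_rows, V.n_cols);
  bool has_bias = bias_idx.isNotNull();
  IntegerMatrix bidx;
  std::vector<double> db;
  if (has_bias) {
    bidx = IntegerMatrix(bias_idx.get());
    db.assign((size_t)n_off * H, 0.0);
  }
  fmat dA(Nq, Nk), dS(Nq, Nk);
  for (int b = 0; b < B; ++b) {
    for (int h = 0; h < H; ++h) {
      fmat Ai(const_cast<float*>(Af.colptr(b * H + h)), Nq, Nk, false, true);
      fmat gO = G.submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1);
      dV->submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1) =
        Ai.t() * gO;
      dA = gO * V.submat(b * Nk, h * dh, (b + 1) * Nk - 1,
                         (h + 1) * dh - 1).t();
      arma::fvec rs = arma::sum(Ai % dA, 1);
      dS = Ai % (dA.each_col() - rs);
      dQ->submat(b * Nq, h * dh, (b + 1) * Nq - 1, (h + 1) * dh - 1) =
        dS * K.submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1) *
        scale;
      dK->submat(b * Nk, h * dh, (b + 1) * Nk - 1, (h + 1) * dh - 1) =
        dS.t() * Q.submat(b * Nq, h * dh, (b + 1) * Nq - 1,
                          (h + 1) * dh - 1) * scale;
      if (has_bias) {
        const float* p = dS.memptr();
        for (int i = 0; i < Nq * Nk; ++i)
          db[(size_t)h * n_off + (bidx[i] - 1)] += p[i];
      }
    }
  }
  List out = List::create(_["dq"] = own(dQ), _["dk"] = own(dK),
                          _["dv"] = own(dV));
  if (has_bias) {
    NumericMatrix dbias(n_off, H);
    for (int h = 0; h < H; ++h)
      for (int i = 0; i < n_off; ++i)
        dbias(i, h) = db[(size_t)h * n_off + i];
    out["dbias"] = dbias;
  }
  return out;
}
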