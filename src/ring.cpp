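// Fixed-point ring arithmetic over Z_{2^(64*L)}, L = 1..3 limbs.
// Elements are stored little-endian (limb 0 least significant) in raw
// vectors, 8*L bytes per element, elements in column-major matrix order.
// All arithmetic is modulo 2^(64*L); negatives use the two's-complement
// embedding (values above modulus/2 decode as negative).

#include <Rcpp.h>
#include <cstdint>
#include <cmath>
#include <cstring>

using namespace Rcpp;

typedef unsigned __int128 uint128_t;

static const int MAX_LIMBS = 3;

// ---- limb primitives --------------------------------------------------

static inline void limb_add(const uint64_t* a, const uint64_t* b,
                            uint64_t* out, int L) {
  uint128_t carry = 0;
  for (int i = 0; i < L; ++i) {
    uint128_t s = (uint128_t)a[i] + b[i] + carry;
    out[i] = (uint64_t)s;
    carry = s >> 64;
  }
}

static inline void limb_sub(const uint64_t* a, const uint64_t* b,
                            uint64_t* out, int L) {
  uint64_t borrow = 0;
  for (int i = 0; i < L; ++i) {
    uint64_t bi = b[i];
    uint64_t t = a[i] - bi;
    uint64_t br1 = a[i] < bi;
    uint64_t t2 = t - borrow;
    uint64_t br2 = t < borrow;
    out[i] = t2;
    borrow = br1 | br2;
  }
}

static inline void limb_neg(const uint64_t* a, uint64_t* out, int L) {
  uint128_t carry = 1;
  for (int i = 0; i < L; ++i) {
    uint128_t s = (uint128_t)(~a[i]) + carry;
    out[i] = (uint64_t)s;
    carry = s >> 64;
  }
}

// low L limbs of a*b (schoolbook, mod 2^(64L))
static inline void limb_mul(const uint64_t* a, const uint64_t* b,
                            uint64_t* out, int L) {
  uint64_t res[MAX_LIMBS] = {0, 0, 0};
  for (int i = 0; i < L; ++i) {
    uint128_t carry = 0;
    for (int j = 0; j + i < L; ++j) {
      uint128_t cur = (uint128_t)a[i] * b[j] + res[i + j] + carry;
      res[i + j] = (uint64_t)cur;
      carry = cur >> 64;
    }
  }
  for (int i = 0; i < L; ++i) out[i] = res[i];
}

// logical right shift by `bits` (0 <= bits < 64*L)
static inline void limb_shr(const uint64_t* a, int bits, uint64_t* out,
                            int L) {
  int limb_off = bits / 64, bit_off = bits % 64;
  for (int i = 0; i < L; ++i) {
    uint64_t lo = (i + limb_off < L) ? a[i + limb_off] : 0;
    uint64_t hi = (i + limb_off + 1 < L) ? a[i + limb_off + 1] : 0;
    out[i] = (bit_off == 0) ? lo : ((lo >> bit_off) | (hi << (64 - bit_off)));
  }
}

static inline const uint64_t* elem(const RawVector& r, R_xlen_t i, int L) {
  return reinterpret_cast<const uint64_t*>(RAW(r)) + (R_xlen_t)L * i;
}
static inline uint64_t* elem(RawVector& r, R_xlen_t i, int L) {
  return reinterpret_cast<uint64_t*>(RAW(r)) + (R_xlen_t)L * i;
}

static inline R_xlen_t n_elems(const RawVector& r, int L) {
  return r.size() / (8 * L);
}

// ---- xoshiro256** RNG (dealer/party randomness, independent of R's RNG)

struct Xoshiro {
  uint64_t s[4];
};

static inline uint64_t splitmix64(uint64_t& x) {
  x += 0x9E3779B97F4A7C15ULL;
  uint64_t z = x;
  z = (z ^ (z >> 30)) * 0xBF58476D1CE4E5B9ULL;
  z = (z ^ (z >> 27)) * 0x94D049BB133111EBULL;
  return z ^ (z >> 31);
}

static inline uint64_t rotl(uint64_t x, int k) {
  return (x << k) | (x >> (64 - k));
}

static inline uint64_t xoshiro_next(Xoshiro* g) {
  uint64_t* s = g->s;
  uint64_t result = rotl(s[1] * 5, 7) * 9;
  uint64_t t = s[1] << 17;
  s[2] ^= s[0]; s[3] ^= s[1]; s[1] ^= s[2]; s[0] ^= s[3];
  s[2] ^= t; s[3] = rotl(s[3], 45);
  return result;
}

// [[Rcpp::export]]
SEXP rng_create(double seed) {
  Xoshiro* g = new Xoshiro;
  uint64_t sm = (uint64_t)seed;
  for (int i = 0; i < 4; ++i) g->s[i] = splitmix64(sm);
  XPtr<Xoshiro> p(g, true);
  return p;
}

// [[Rcpp::export]]
RawVector ring_random(SEXP rng, int nelem, int nlimbs) {
  XPtr<Xoshiro> g(rng);
  RawVector out((R_xlen_t)8 * nlimbs * nelem);
  uint64_t* o = reinterpret_cast<uint64_t*>(RAW(out));
  for (R_xlen_t i = 0; i < (R_xlen_t)nelem * nlimbs; ++i)
    o[i] = xoshiro_next(g.get());
  return out;
}

// ---- encode / decode ---------------------------------------------------

// [[Rcpp::export]]
RawVector ring_encode(NumericVector x, int frac_bits, int value_bits,
                      int nlimbs) {
  int L = nlimbs;
  R_xlen_t n = x.size();
  RawVector out((R_xlen_t)8 * L * n);
  long double scale = ldexpl(1.0L, frac_bits);
  long double lim = ldexpl(1.0L, value_bits - frac_bits - 1);
  for (R_xlen_t i = 0; i < n; ++i) {
    double v = x[i];
    if (!R_finite(v)) stop("non-finite value cannot be fixed-point encoded");
    if (std::fabs(v) >= (double)lim)
      stop("fixed-point overflow: |%g| exceeds representable range 2^%d",
           v, value_bits - frac_bits - 1);
    long double scaled = (long double)v * scale;
    int64_t iv = (int64_t)llroundl(scaled);
    uint64_t lo = (uint64_t)iv;
    uint64_t ext = (iv < 0) ? ~0ULL : 0ULL;
    uint64_t* e = elem(out, i, L);
    e[0] = lo;
    for (int j = 1; j < L; ++j) e[j] = ext;
  }
  return out;
}

// [[Rcpp::export]]
NumericVector ring_decode(RawVector r, int frac_bits, int nlimbs) {
  int L = nlimbs;
  R_xlen_t n = n_elems(r, L);
  NumericVector out(n);
  long double inv = ldexpl(1.0L, -frac_bits);
  for (R_xlen_t i = 0; i < n; ++i) {
    const uint64_t* e = elem(r, i, L);
    uint64_t w[MAX_LIMBS];
    bool neg = (e[L - 1] >> 63) & 1;
    if (neg) limb_neg(e, w, L); else std::memcpy(w, e, 8 * L);
    long double m = 0.0L;
    for (int j = L - 1; j >= 0; --j) m = m * ldexpl(1.0L, 64) + (long double)w[j];
    out[i] = (double)((neg ? -m : m) * inv);
  }
  return out;
}

// ---- elementwise ring ops ---------------------------------------------

// [[Rcpp::export]]
RawVector ring_add(RawVector a, RawVector b, int nlimbs) {
  if (a.size() != b.size()) stop("ring_add: length mismatch");
  R_xlen_t n = n_elems(a, nlimbs);
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < n; ++i)
    limb_add(elem(a, i, nlimbs), elem(b, i, nlimbs), elem(out, i, nlimbs),
             nlimbs);
  return out;
}

// [[Rcpp::export]]
RawVector ring_sub(RawVector a, RawVector b, int nlimbs) {
  if (a.size() != b.size()) stop("ring_sub: length mismatch");
  R_xlen_t n = n_elems(a, nlimbs);
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < n; ++i)
    limb_sub(elem(a, i, nlimbs), elem(b, i, nlimbs), elem(out, i, nlimbs),
             nlimbs);
  return out;
}

// [[Rcpp::export]]
RawVector ring_neg(RawVector a, int nlimbs) {
  R_xlen_t n = n_elems(a, nlimbs);
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < n; ++i)
    limb_neg(elem(a, i, nlimbs), elem(out, i, nlimbs), nlimbs);
  return out;
}

// [[Rcpp::export]]
RawVector ring_mul(RawVector a, RawVector b, int nlimbs) {
  if (a.size() != b.size()) stop("ring_mul: length mismatch");
  R_xlen_t n = n_elems(a, nlimbs);
  RawVector out(a.size());
  for (R_xlen_t i = 0; i < n; ++i)
    limb_mul(elem(a, i, nlimbs), elem(b, i, nlimbs), elem(out, i, nlimbs),
             nlimbs);
  return out;
}

// multiply every element of a by the single ring element s (no truncation)
// [[Rcpp::export]]
RawVector ring_mul_scalar(RawVector a, RawVector s, int nlimbs) {
  R_xlen_t n = n_elems(a, nlimbs);
  RawVector out(a.size());
  const uint64_t* se = elem(s, 0, nlimbs);
  for (R_xlen_t i = 0; i < n; ++i)
    limb_mul(elem(a, i, nlimbs), se, elem(out, i, nlimbs), nlimbs);
  return out;
}

// a: m x k, b: k x n, both column-major; returns m x n
// [[Rcpp::export]]
RawVector ring_matmul(RawVector a, RawVector b, int m, int k, int n,
                      int nlimbs) {
  int L = nlimbs;
  if (n_elems(a, L) != (R_xlen_t)m * k || n_elems(b, L) != (R_xlen_t)k * n)
    stop("ring_matmul: shape mismatch");
  RawVector out((R_xlen_t)8 * L * m * n);
  std::memset(RAW(out), 0, out.size());
  uint64_t prod[MAX_LIMBS];
  for (int j = 0; j < n; ++j) {
    for (int t = 0; t < k; ++t) {
      const uint64_t* bj = elem(b, (R_xlen_t)j * k + t, L);
      bool bz = true;
      for (int q = 0; q < L; ++q) if (bj[q]) { bz = false; break; }
      if (bz) continue;
      for (int i = 0; i < m; ++i) {
        const uint64_t* ai = elem(a, (R_xlen_t)t * m + i, L);
        uint64_t* oe = elem(out, (R_xlen_t)j * m + i, L);
        limb_mul(ai, bj, prod, L);
        limb_add(oe, prod, oe, L);
      }
    }
  }
  return out;
}

// local probabilistic truncation share: parties 0..P-2 logically shift,
// the last party negates-shifts-negates (two's-complement floor division)
// [[Rcpp::export]]
RawVector ring_trunc_share(RawVector a, int bits, bool last_party,
                           int nlimbs) {
  int L = nlimbs;
  R_xlen_t n = n_elems(a, L);
  RawVector out(a.size());
  uint64_t tmp[MAX_LIMBS], tmp2[MAX_LIMBS];
  for (R_xlen_t i = 0; i < n; ++i) {
    const uint64_t* e = elem(a, i, L);
    uint64_t* o = elem(out, i, L);
    if (last_party) {
      limb_neg(e, tmp, L);
      limb_shr(tmp, bits, tmp2, L);
      limb_neg(tmp2, o, L);
    } else {
      limb_shr(e, bits, o, L);
    }
  }
  return out;
}

// exact public truncation with sign (arithmetic shift of the embedded value)
// [[Rcpp::export]]
RawVector ring_shift_signed(RawVector a, int bits, int nlimbs) {
  int L = nlimbs;
  R_xlen_t n = n_elems(a, L);
  RawVector out(a.size());
  uint64_t tmp[MAX_LIMBS], tmp2[MAX_LIMBS];
  for (R_xlen_t i = 0; i < n; ++i) {
    const uint64_t* e = elem(a, i, L);
    uint64_t* o = elem(out, i, L);
    bool neg = (e[L - 1] >> 63) & 1;
    if (neg) {
      limb_neg(e, tmp, L);
      limb_shr(tmp, bits, tmp2, L);
      limb_neg(tmp2, o, L);
    } else {
      limb_shr(e, bits, o, L);
    }
  }
  return out;
}

// ---- element subsetting (column-major index vectors, 0-based) ---------

// [[Rcpp::export]]
RawVector ring_subset(RawVector a, IntegerVector idx, int nlimbs) {
  int L = nlimbs;
  RawVector out((R_xlen_t)8 * L * idx.size());
  for (R_xlen_t i = 0; i < idx.size(); ++i)
    std::memcpy(elem(out, i, L), elem(a, (R_xlen_t)idx[i], L), 8 * L);
  return out;
}

// [[Rcpp::export]]
RawVector ring_assign(RawVector a, IntegerVector idx, RawVector vals,
                      int nlimbs) {
  int L = nlimbs;
  RawVector out = clone(a);
  for (R_xlen_t i = 0; i < idx.size(); ++i)
    std::memcpy(elem(out, (R_xlen_t)idx[i], L), elem(vals, i, L), 8 * L);
  return out;
}

// ---- fused Beaver multiplication --------------------------------------
//
// One call executes the whole dealer-assisted protocol for a single secure
// product: the dealer draws a, b uniformly, computes c = a*b (matrix or
// elementwise), additively shares the triple; the parties reveal d = x - a
// and e = y - b, combine locally, and locally truncate by `trunc_bits`.
// Keeping this fused avoids R-level overhead in gradient-descent loops; the
// message/round structure is identical to the unfused smcMul path.

static void share_into(const RawVector& secret, List& out_shares, int P,
                       int L, Xoshiro* g, int slot) {
  R_xlen_t bytes = secret.size();
  R_xlen_t n = bytes / (8 * L);
  RawVector acc(bytes);
  std::memset(RAW(acc), 0, bytes);
  for (int p = 0; p < P - 1; ++p) {
    RawVector sh(bytes);
    uint64_t* s = reinterpret_cast<uint64_t*>(RAW(sh));
    for (R_xlen_t i = 0; i < n * L; ++i) s[i] = xoshiro_next(g);
    for (R_xlen_t i = 0; i < n; ++i)
      limb_add(elem(acc, i, L), elem(sh, i, L), elem(acc, i, L), L);
    List slot_list = out_shares[p];
    slot_list[slot] = sh;
  }
  RawVector lastv(bytes);
  for (R_xlen_t i = 0; i < n; ++i)
    limb_sub(elem(secret, i, L), elem(acc, i, L), elem(lastv, i, L), L);
  List slot_list = out_shares[P - 1];
  slot_list[slot] = lastv;
}

// [[Rcpp::export]]
List dealer_triple(SEXP rng, int m, int k, int n, bool elementwise,
                   int nlimbs, int parties) {
  XPtr<Xoshiro> g(rng);
  int L = nlimbs, P = parties;
  R_xlen_t na = (R_xlen_t)m * k;
  R_xlen_t nb = elementwise ? na : (R_xlen_t)k * n;
  RawVector a((R_xlen_t)8 * L * na), b((R_xlen_t)8 * L * nb);
  uint64_t* ap = reinterpret_cast<uint64_t*>(RAW(a));
  uint64_t* bp = reinterpret_cast<uint64_t*>(RAW(b));
  for (R_xlen_t i = 0; i < na * L; ++i) ap[i] = xoshiro_next(g.get());
  for (R_xlen_t i = 0; i < nb * L; ++i) bp[i] = xoshiro_next(g.get());
  RawVector c = elementwise ? ring_mul(a, b, L)
                            : ring_matmul(a, b, m, k, n, L);
  List shares(P);
  for (int p = 0; p < P; ++p) shares[p] = List(3);
  share_into(a, shares, P, L, g.get(), 0);
  share_into(b, shares, P, L, g.get(), 1);
  share_into(c, shares, P, L, g.get(), 2);
  return shares;
}

// plain C++ core of the fused Beaver product (shares as raw-vector lists)
static std::vector<RawVector> beaver_core(Xoshiro* g,
    const std::vector<RawVector>& xs, const std::vector<RawVector>& ys,
    int m, int k, int n, bool elementwise, int L, int trunc_bits) {
  int P = (int)xs.size();
  R_xlen_t na = (R_xlen_t)m * k;
  R_xlen_t nb = elementwise ? na : (R_xlen_t)k * n;
  RawVector a((R_xlen_t)8 * L * na), b((R_xlen_t)8 * L * nb);
  uint64_t* ap = reinterpret_cast<uint64_t*>(RAW(a));
  uint64_t* bp = reinterpret_cast<uint64_t*>(RAW(b));
  for (R_xlen_t i = 0; i < na * L; ++i) ap[i] = xoshiro_next(g);
  for (R_xlen_t i = 0; i < nb * L; ++i) bp[i] = xoshiro_next(g);
  RawVector c = elementwise ? ring_mul(a, b, L)
                            : ring_matmul(a, b, m, k, n, L);
  // share a, b, c among P parties; open d = x - a, e = y - b on the fly
  std::vector<RawVector> aSh(P), bSh(P), cSh(P);
  for (int s = 0; s < 3; ++s) {
    const RawVector& sec = s == 0 ? a : (s == 1 ? b : c);
    std::vector<RawVector>& dst = s == 0 ? aSh : (s == 1 ? bSh : cSh);
    R_xlen_t ne = sec.size() / (8 * L);
    RawVector acc(sec.size());
    std::memset(RAW(acc), 0, acc.size());
    for (int p = 0; p < P - 1; ++p) {
      RawVector sh(sec.size());
      uint64_t* shp = reinterpret_cast<uint64_t*>(RAW(sh));
      for (R_xlen_t i = 0; i < ne * L; ++i) shp[i] = xoshiro_next(g);
      dst[p] = sh;
      acc = ring_add(acc, sh, L);
    }
    dst[P - 1] = ring_sub(sec, acc, L);
  }
  RawVector d = xs[0], e = ys[0];
  d = ring_sub(d, aSh[0], L);
  e = ring_sub(e, bSh[0], L);
  for (int p = 1; p < P; ++p) {
    d = ring_add(d, ring_sub(xs[p], aSh[p], L), L);
    e = ring_add(e, ring_sub(ys[p], bSh[p], L), L);
  }
  RawVector de = elementwise ? ring_mul(d, e, L)
                             : ring_matmul(d, e, m, k, n, L);
  std::vector<RawVector> out(P);
  for (int p = 0; p < P; ++p) {
    RawVector db = elementwise ? ring_mul(d, bSh[p], L)
                               : ring_matmul(d, bSh[p], m, k, n, L);
    RawVector ae = elementwise ? ring_mul(aSh[p], e, L)
                               : ring_matmul(aSh[p], e, m, k, n, L);
    RawVector z = ring_add(cSh[p], ring_add(db, ae, L), L);
    if (p == 0) z = ring_add(z, de, L);
    if (trunc_bits > 0) z = ring_trunc_share(z, trunc_bits, p == P - 1, L);
    out[p] = z;
  }
  return out;
}

// full-batch linear gradient descent on shares of the count-normalised
// Gramian C (p x p) and right-hand side R (p x 1):
// w <- w + (R - C w) * step, `epochs` times; one Beaver product per epoch.
// [[Rcpp::export]]
List smc_lin_gd(SEXP rng, List Cs, List Rs, int p, int epochs,
                RawVector stepEnc, int nlimbs, int frac_bits) {
  XPtr<Xoshiro> g(rng);
  int L = nlimbs, P = Cs.size();
  std::vector<RawVector> Cv(P), Rv(P), w(P);
  for (int q = 0; q < P; ++q) {
    Cv[q] = Cs[q];
    Rv[q] = Rs[q];
    w[q] = RawVector((R_xlen_t)8 * L * p);
    std::memset(RAW(w[q]), 0, w[q].size());
  }
  for (int e = 0; e < epochs; ++e) {
    std::vector<RawVector> z =
      beaver_core(g.get(), Cv, w, p, p, 1, false, L, frac_bits);
    for (int q = 0; q < P; ++q) {
      RawVector u = ring_sub(Rv[q], z[q], L);
      u = ring_mul_scalar(u, stepEnc, L);
      u = ring_trunc_share(u, frac_bits, q == P - 1, L);
      w[q] = ring_add(w[q], u, L);
    }
  }
  List out(P);
  for (int q = 0; q < P; ++q) out[q] = w[q];
  return out;
}

// partitioned-dataflow linear gradient descent: per data block b the local
// (public to its owner) normalised Gramian Cenc[b] multiplies the
// aggregated weights, and the local weight summand is updated with the
// protected local right-hand side Rs[b][party]; the weight aggregation
// happens once per epoch.  Returns the final aggregated weight shares.
// [[Rcpp::export]]
List mhe_lin_gd(List CencBlocks, List RsBlocks, int p, int epochs,
                RawVector stepEnc, int nlimbs, int frac_bits) {
  int L = nlimbs, B = CencBlocks.size();
  List Rs0 = RsBlocks[0];
  int P = Rs0.size();
  std::vector<std::vector<RawVector> > wParts(B), RsV(B);
  std::vector<RawVector> Cenc(B);
  for (int b = 0; b < B; ++b) {
    Cenc[b] = CencBlocks[b];
    List rb = RsBlocks[b];
    wParts[b].resize(P);
    RsV[b].resize(P);
    for (int q = 0; q < P; ++q) {
      RsV[b][q] = rb[q];
      wParts[b][q] = RawVector((R_xlen_t)8 * L * p);
      std::memset(RAW(wParts[b][q]), 0, wParts[b][q].size());
    }
  }
  std::vector<RawVector> wAgg(P);
  for (int e = 0; e <= epochs; ++e) {
    for (int q = 0; q < P; ++q) {
      wAgg[q] = wParts[0][q];
      for (int b = 1; b < B; ++b) wAgg[q] = ring_add(wAgg[q], wParts[b][q], L);
    }
    if (e == epochs) break;
    for (int b = 0; b < B; ++b) {
      for (int q = 0; q < P; ++q) {
        RawVector z = ring_matmul(Cenc[b], wAgg[q], p, p, 1, L);
        z = ring_trunc_share(z, frac_bits, q == P - 1, L);
        RawVector u = ring_sub(RsV[b][q], z, L);
        u = ring_mul_scalar(u, stepEnc, L);
        u = ring_trunc_share(u, frac_bits, q == P - 1, L);
        wParts[b][q] = ring_add(wParts[b][q], u, L);
      }
    }
  }
  List out(P);
  for (int q = 0; q < P; ++q) out[q] = wAgg[q];
  return out;
}

// xs, ys: per-party lists of raw share vectors for x (m x k) and y (k x n
// or m x k if elementwise). Returns per-party shares of trunc(x * y).
// [[Rcpp::export]]
List smc_mul_fused(SEXP rng, List xs, List ys, int m, int k, int n,
                   bool elementwise, int nlimbs, int trunc_bits) {
  int L = nlimbs, P = xs.size();
  List triple = dealer_triple(rng, m, k, n, elementwise, L, P);

  // open d = x - a and e = y - b
  RawVector x0 = xs[0];
  RawVector d(x0.size());
  std::memset(RAW(d), 0, d.size());
  RawVector y0 = ys[0];
  RawVector e(y0.size());
  std::memset(RAW(e), 0, e.size());
  R_xlen_t nd = n_elems(d, L), ne = n_elems(e, L);
  for (int p = 0; p < P; ++p) {
    List tp = triple[p];
    RawVector xp = xs[p], yp = ys[p], apv = tp[0], bpv = tp[1];
    for (R_xlen_t i = 0; i < nd; ++i) {
      uint64_t t[MAX_LIMBS];
      limb_sub(elem(xp, i, L), elem(apv, i, L), t, L);
      limb_add(elem(d, i, L), t, elem(d, i, L), L);
    }
    for (R_xlen_t i = 0; i < ne; ++i) {
      uint64_t t[MAX_LIMBS];
      limb_sub(elem(yp, i, L), elem(bpv, i, L), t, L);
      limb_add(elem(e, i, L), t, elem(e, i, L), L);
    }
  }

  RawVector de = elementwise ? ring_mul(d, e, L)
                             : ring_matmul(d, e, m, k, n, L);
  List out(P);
  for (int p = 0; p < P; ++p) {
    List tp = triple[p];
    RawVector apv = tp[0], bpv = tp[1], cpv = tp[2];
    RawVector db = elementwise ? ring_mul(d, bpv, L)
                               : ring_matmul(d, bpv, m, k, n, L);
    RawVector ae = elementwise ? ring_mul(apv, e, L)
                               : ring_matmul(apv, e, m, k, n, L);
    RawVector z = ring_add(cpv, ring_add(db, ae, L), L);
    if (p == 0) z = ring_add(z, de, L);
    if (trunc_bits > 0) z = ring_trunc_share(z, trunc_bits, p == P - 1, L);
    out[p] = z;
  }
  return out;
}
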