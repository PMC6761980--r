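// Bit-parallel kernels for sequence-to-graph matching and alignment.
//
// Conventions:
//  * bitvectors hold m bits in words of `w` bits each (w <= 64), stored in the
//    low bits of uint64_t; bit j of the whole vector encodes the score step
//    from row j-1 into row j (row -1 being the column's boundary row).
//  * nodes are 0-based here; the R surface is 1-based.
//  * alphabet is encoded 0..3 = A,C,G,T and 4 = N; N never matches anything,
//    including another N.

#include <Rcpp.h>
#include <cstdint>
#include <climits>
#include <vector>
#include <algorithm>

using namespace Rcpp;
typedef uint64_t u64;

static const long SCORE_INF = LONG_MAX / 4;

static inline int popcnt(u64 x) { return __builtin_popcountll(x); }
static inline u64 lowmask(int k) { return (k >= 64) ? ~0ULL : ((1ULL << k) - 1ULL); }

static std::vector<u64> pack_bits(const IntegerVector& bits, int w) {
  int m = bits.size();
  int nw = (m + w - 1) / w;
  std::vector<u64> out(std::max(nw, 1), 0ULL);
  for (int i = 0; i < m; i++)
    if (bits[i]) out[i / w] |= 1ULL << (i % w);
  return out;
}

static IntegerVector unpack_bits(const std::vector<u64>& wv, int m, int w) {
  IntegerVector out(m);
  for (int i = 0; i < m; i++)
    out[i] = (wv[i / w] >> (i % w)) & 1ULL ? 1 : 0;
  return out;
}

// ---------------------------------------------------------------------------
// Shift-And
// ---------------------------------------------------------------------------

// state' = ((state << 1) + 1) AND mask, with carries across w-bit words.
static void nfa_step_words(const std::vector<u64>& st, const std::vector<u64>& mask,
                           int m, int w, std::vector<u64>& out) {
  int nw = (int)st.size();
  out.resize(nw);
  u64 carry = 1ULL;  // the +1 term: a new match may start at every step
  for (int t = 0; t < nw; t++) {
    u64 shifted = ((st[t] << 1) | carry) & lowmask(w);
    carry = (st[t] >> (w - 1)) & 1ULL;
    out[t] = shifted & mask[t];
  }
  int rem = m - (nw - 1) * w;
  out[nw - 1] &= lowmask(rem);
}

// [[Rcpp::export]]
IntegerVector cpp_nfa_step(IntegerVector state, IntegerVector mask, int w) {
  int m = state.size();
  std::vector<u64> st = pack_bits(state, w), mk = pack_bits(mask, w), out;
  nfa_step_words(st, mk, m, w, out);
  return unpack_bits(out, m, w);
}

// Worklist Shift-And over a (possibly cyclic) graph.  If `topo` is non-empty
// the graph is a DAG and a single pass in that order is performed (no
// re-pushes); otherwise a worklist (LIFO stack or FIFO queue) runs to the
// fixed point.  Bit 0 of every node is seeded from the virtual empty
// predecessor state so that in-degree-0 nodes can start matches.
// [[Rcpp::export]]
List cpp_shift_and(int n, IntegerVector labels,
                   IntegerVector out_ptr, IntegerVector out_idx,
                   IntegerVector sidx, int w,
                   IntegerVector topo, bool fifo) {
  int m = sidx.size();
  int nw = (m + w - 1) / w;
  // per-character pattern masks
  std::vector<std::vector<u64>> P(5, std::vector<u64>(nw, 0ULL));
  for (int j = 0; j < m; j++) {
    int c = sidx[j];
    if (c >= 0 && c < 4) P[c][j / w] |= 1ULL << (j % w);
  }
  std::vector<std::vector<u64>> S(n, std::vector<u64>(nw, 0ULL));
  for (int v = 0; v < n; v++) {
    int c = labels[v];
    if (c >= 0 && c < 4 && m > 0 && sidx[0] == c) S[v][0] |= 1ULL;
  }
  IntegerVector pops(n, 0);
  std::vector<u64> cand(nw);

  if (topo.size() > 0) {
    for (int oi = 0; oi < n; oi++) {
      int v = topo[oi];
      pops[v]++;
      for (int e = out_ptr[v]; e < out_ptr[v + 1]; e++) {
        int y = out_idx[e];
        int c = labels[y];
        nfa_step_words(S[v], P[c >= 0 && c < 5 ? c : 4], m, w, cand);
        for (int t = 0; t < nw; t++) S[y][t] |= cand[t];
      }
    }
  } else {
    std::deque<int> L;
    std::vector<char> inq(n, 1);
    for (int v = 0; v < n; v++) L.push_back(v);
    while (!L.empty()) {
      int v;
      if (fifo) { v = L.front(); L.pop_front(); }
      else      { v = L.back();  L.pop_back();  }
      inq[v] = 0;
      pops[v]++;
      for (int e = out_ptr[v]; e < out_ptr[v + 1]; e++) {
        int y = out_idx[e];
        int c = labels[y];
        nfa_step_words(S[v], P[c >= 0 && c < 5 ? c : 4], m, w, cand);
        bool changed = false;
        for (int t = 0; t < nw; t++) {
          u64 nv = S[y][t] | cand[t];
          if (nv != S[y][t]) { S[y][t] = nv; changed = true; }
        }
        if (changed && !inq[y]) { inq[y] = 1; L.push_back(y); }
      }
    }
  }

  LogicalMatrix states(n, m);
  for (int v = 0; v < n; v++)
    for (int j = 0; j < m; j++)
      states(v, j) = (S[v][j / w] >> (j % w)) & 1ULL ? true : false;
  return List::create(_["states"] = states, _["pops"] = pops);
}

// ---------------------------------------------------------------------------
// Myers column step (edlib-style block step with horizontal carry)
// ---------------------------------------------------------------------------

// One w-bit block of the Myers step.  Pv/Mv are the predecessor column's
// positive/negative step vectors, Eq the match mask, hin the horizontal score
// delta entering at the block's top boundary row.  Returns hout at the bottom.
static inline int myers_word(u64& Pv, u64& Mv, u64 Eq, int hin, int kbits) {
  const u64 HB = 1ULL << (kbits - 1);
  const u64 LOW = lowmask(kbits);
  u64 hinNeg = (hin < 0) ? 1ULL : 0ULL;
  u64 Xv = Eq | Mv;
  Eq |= hinNeg;
  u64 Xh = (((Eq & Pv) + Pv) ^ Pv) | Eq;
  u64 Ph = Mv | (~(Xh | Pv) & LOW);
  u64 Mh = Pv & Xh;
  int hout = 0;
  if (Ph & HB) hout = 1;
  if (Mh & HB) hout = -1;
  Ph = (Ph << 1) & LOW;
  Mh = (Mh << 1) & LOW;
  Mh |= hinNeg;
  if (hin > 0) Ph |= 1ULL;
  Pv = (Mh | (~(Xv | Ph) & LOW)) & LOW;
  Mv = Ph & Xv & LOW;
  return hout;
}

static void myers_step_words(const std::vector<u64>& vp, const std::vector<u64>& vn,
                             const std::vector<u64>& eq, int m, int w, int hin,
                             std::vector<u64>& ovp, std::vector<u64>& ovn) {
  int nw = (int)vp.size();
  ovp.resize(nw); ovn.resize(nw);
  int h = hin;
  for (int t = 0; t < nw; t++) {
    int k = std::min(w, m - t * w);
    u64 Pv = vp[t], Mv = vn[t];
    h = myers_word(Pv, Mv, eq[t], h, k);
    ovp[t] = Pv; ovn[t] = Mv;
  }
}

// [[Rcpp::export]]
List cpp_myers_step(IntegerVector vp, IntegerVector vn, IntegerVector mask,
                    int hin, int w) {
  int m = vp.size();
  std::vector<u64> pvp = pack_bits(vp, w), pvn = pack_bits(vn, w),
                   peq = pack_bits(mask, w), ovp, ovn;
  myers_step_words(pvp, pvn, peq, m, w, hin, ovp, ovn);
  return List::create(_["vp"] = unpack_bits(ovp, m, w),
                      _["vn"] = unpack_bits(ovn, m, w));
}

// ---------------------------------------------------------------------------
// Bit-parallel difference masks (the chunked score-difference machinery)
// ---------------------------------------------------------------------------

// For one word of k rows, compute masks over rows j = 0..k-1 of the running
// difference d_j = S^A_j - S^B_j, where d0 is the difference at the virtual
// row above the word:
//   m1:  d_j >= 1   (A strictly above B)
//   m2:  d_j >= 2
//   mm1: d_j <= -1  (B strictly above A)
// Differences are accumulated chunk-parallel: chunks of g = ceil(log2 k)+2
// rows; g rounds of chunk-local totals, a prefix over the <= ceil(k/g) chunk
// sums, and g rounds of row advancement with sign extraction.  Chunk storage
// uses 2g-bit lanes (even/odd chunks in separate accumulators) so the
// arithmetic is exact with guard bits.  d0 is clamped to +-(2k+2): beyond
// that the sign (and the >=2 / <=-2 classification at pick-switch rows)
// cannot change within k rows, so the masks stay exact.
static void diff_masks_word(u64 vpA, u64 vnA, u64 vpB, u64 vnB, int k, long d0in,
                            u64& m1, u64& m2, u64& mm1, int& chunk_rows) {
  long clampv = 2L * k + 2;
  long d0 = std::max(-clampv, std::min(clampv, d0in));
  int e = 0, kk = std::max(k, 2);
  while ((1 << e) < kk) e++;
  int g = e + 2;                       // rows per chunk: log2(k) + 2
  int nch = (k + g - 1) / g;
  chunk_rows = g;

  // phase 1: chunk-local totals of per-row deltas, g-bit fields at bits c*g
  u64 anchor = 0;
  for (int c = 0; c < nch; c++) anchor |= 1ULL << (c * g);
  u64 B1 = 1ULL << (g - 1);
  u64 D1 = anchor * B1;
  for (int t = 0; t < g; t++) {
    D1 += (vpA >> t) & anchor;
    D1 += (vnB >> t) & anchor;
    D1 -= (vnA >> t) & anchor;
    D1 -= (vpB >> t) & anchor;
  }
  long tot[16], anch[16];
  u64 gmask = lowmask(g);
  for (int c = 0; c < nch; c++)
    tot[c] = (long)((D1 >> (c * g)) & gmask) - (long)B1;

  // phase 2: exclusive prefix over the chunk sums (<= 13 of them)
  long acc = d0;
  for (int c = 0; c < nch; c++) { anch[c] = acc; acc += tot[c]; }

  // phase 3: advance all chunks one row per round, extracting sign bits;
  // 2g-bit lanes, even and odd chunks in separate accumulators
  int f = 2 * g;
  u64 B2 = 1ULL << (f - 1);
  m1 = m2 = mm1 = 0;
  for (int p = 0; p < 2; p++) {
    u64 pmask = 0, Dp = 0;
    int q = 0;
    for (int c = p; c < nch; c += 2, q++) {
      pmask |= 1ULL << (q * f);
      Dp |= (u64)((long)B2 + anch[c]) << (q * f);
    }
    if (!pmask) continue;
    for (int t = 0; t < g; t++) {
      int sh = p * g + t;  // source row c*g+t sits sh above lane anchor q*f
      Dp += (vpA >> sh) & pmask;
      Dp += (vnB >> sh) & pmask;
      Dp -= (vnA >> sh) & pmask;
      Dp -= (vpB >> sh) & pmask;
      u64 ge1 = ((Dp - pmask)     >> (f - 1)) & pmask;
      u64 ge2 = ((Dp - 2 * pmask) >> (f - 1)) & pmask;
      u64 ge0 = ( Dp              >> (f - 1)) & pmask;
      m1  |= ge1 << sh;
      m2  |= ge2 << sh;
      mm1 |= (~ge0 & pmask) << sh;
    }
  }
  u64 LOW = lowmask(k);
  m1 &= LOW; m2 &= LOW; mm1 &= LOW;
}

// Elementwise-minimum merge of one word of two columns, assembled from the
// difference masks: picking mask Mp = (B below A), source copy where the pick
// does not switch, and +1/+2 step corrections at rows where it does.
static void merge_word_bp(u64 vpA, u64 vnA, u64 vpB, u64 vnB, int k, long d0,
                          u64& vpO, u64& vnO, int& chunk_rows) {
  u64 m1, m2, mm1;
  diff_masks_word(vpA, vnA, vpB, vnB, k, d0, m1, m2, mm1, chunk_rows);
  u64 LOW = lowmask(k);
  u64 Mp = m1;  // pick B where S^B < S^A; ties pick A
  u64 prevMp  = ((Mp  << 1) | (d0 >= 1  ? 1ULL : 0ULL)) & LOW;
  u64 swAB = Mp & ~prevMp;
  u64 swBA = ~Mp & prevMp & LOW;
  u64 same = LOW & ~(swAB | swBA);
  u64 src_vp = (Mp & vpB) | (~Mp & vpA);
  u64 src_vn = (Mp & vnB) | (~Mp & vnA);
  u64 prevMm1 = ((mm1 << 1) | (d0 <= -1 ? 1ULL : 0ULL)) & LOW;
  u64 prevM2  = ((m2  << 1) | (d0 >= 2  ? 1ULL : 0ULL)) & LOW;
  u64 c0 = same | (swAB & ~prevMm1);
  u64 c1 = (swAB & prevMm1) | (swBA & ~prevM2);
  u64 c2 = swBA & prevM2;
  vpO = ((c0 & src_vp) | (c1 & ~src_vp & ~src_vn) | c2) & LOW;
  vnO = (c0 & src_vn) & LOW;
}

// Multi-word merge; d across word boundaries is carried exactly via popcounts.
static int merge_words_bp(const std::vector<u64>& vpA, const std::vector<u64>& vnA, long sbA,
                          const std::vector<u64>& vpB, const std::vector<u64>& vnB, long sbB,
                          int m, int w,
                          std::vector<u64>& vpO, std::vector<u64>& vnO) {
  int nw = (int)vpA.size();
  vpO.resize(nw); vnO.resize(nw);
  long d = sbA - sbB;
  int g = 0;
  for (int t = 0; t < nw; t++) {
    int k = std::min(w, m - t * w);
    merge_word_bp(vpA[t], vnA[t], vpB[t], vnB[t], k, d, vpO[t], vnO[t], g);
    d += (popcnt(vpA[t]) - popcnt(vnA[t])) - (popcnt(vpB[t]) - popcnt(vnB[t]));
  }
  return g;
}

// [[Rcpp::export]]
List cpp_merge_bitparallel(IntegerVector vpA, IntegerVector vnA, int sbA,
                           IntegerVector vpB, IntegerVector vnB, int sbB,
                           int w) {
  int m = vpA.size();
  std::vector<u64> a = pack_bits(vpA, w), b = pack_bits(vnA, w),
                   c = pack_bits(vpB, w), d = pack_bits(vnB, w), ovp, ovn;
  int g = merge_words_bp(a, b, sbA, c, d, sbB, m, w, ovp, ovn);
  return List::create(_["vp"] = unpack_bits(ovp, m, w),
                      _["vn"] = unpack_bits(ovn, m, w),
                      _["s_before"] = std::min(sbA, sbB),
                      _["chunk_rows"] = g);
}

// Reference merge of one word: decode, take minima, re-encode.
static void merge_words_ref(const std::vector<u64>& vpA, const std::vector<u64>& vnA, long sbA,
                            const std::vector<u64>& vpB, const std::vector<u64>& vnB, long sbB,
                            int m, int w,
                            std::vector<u64>& vpO, std::vector<u64>& vnO) {
  int nw = (int)vpA.size();
  vpO.assign(nw, 0ULL); vnO.assign(nw, 0ULL);
  long sa = sbA, sb = sbB, so = std::min(sbA, sbB);
  for (int j = 0; j < m; j++) {
    int t = j / w, b = j % w;
    sa += ((vpA[t] >> b) & 1ULL) ? 1 : (((vnA[t] >> b) & 1ULL) ? -1 : 0);
    sb += ((vpB[t] >> b) & 1ULL) ? 1 : (((vnB[t] >> b) & 1ULL) ? -1 : 0);
    long mn = std::min(sa, sb);
    if (mn == so + 1) vpO[t] |= 1ULL << b;
    else if (mn == so - 1) vnO[t] |= 1ULL << b;
    so = mn;
  }
}

// ---------------------------------------------------------------------------
// Changed minimum value
// ---------------------------------------------------------------------------

// minChanged(old, new): minimum score of `new` over rows where new < old,
// SCORE_INF if none.  Fast path: difference mask from the chunk machinery,
// then local minima of the new column (step into the row not +1, step out of
// the row not -1), each evaluated by popcount.
static long changed_min_words(const std::vector<u64>& vpo, const std::vector<u64>& vno,
                              const std::vector<u64>& vpn, const std::vector<u64>& vnn,
                              int m, int w, long sb) {
  int nw = (int)vpo.size();
  long d = 0, base = sb, best = SCORE_INF;
  for (int t = 0; t < nw; t++) {
    int k = std::min(w, m - t * w);
    u64 m1, m2, mm1; int g;
    diff_masks_word(vpo[t], vno[t], vpn[t], vnn[t], k, d, m1, m2, mm1, g);
    u64 changed = m1;  // old > new
    if (changed) {
      u64 next_vn0 = (t + 1 < nw) ? (vnn[t + 1] & 1ULL) : 0ULL;
      u64 vn_after = (vnn[t] >> 1) | (next_vn0 << (k - 1));
      u64 cand = changed & ~vpn[t] & ~vn_after;
      while (cand) {
        int j = __builtin_ctzll(cand);
        cand &= cand - 1;
        u64 pre = lowmask(j + 1);
        long sc = base + popcnt(vpn[t] & pre) - popcnt(vnn[t] & pre);
        if (sc < best) best = sc;
      }
    }
    d += (popcnt(vpo[t]) - popcnt(vno[t])) - (popcnt(vpn[t]) - popcnt(vnn[t]));
    base += popcnt(vpn[t]) - popcnt(vnn[t]);
  }
  return best;
}

// [[Rcpp::export]]
double cpp_changed_min(IntegerVector vpo, IntegerVector vno,
                       IntegerVector vpn, IntegerVector vnn,
                       int sb, int w) {
  int m = vpo.size();
  std::vector<u64> a = pack_bits(vpo, w), b = pack_bits(vno, w),
                   c = pack_bits(vpn, w), d = pack_bits(vnn, w);
  long r = changed_min_words(a, b, c, d, m, w, sb);
  return r >= SCORE_INF ? R_PosInf : (double)r;
}

// ---------------------------------------------------------------------------
// Bucket priority queue (m+2 buckets, lazy decrease-key)
// ---------------------------------------------------------------------------

struct BucketQueue {
  std::vector<std::vector<int>> buckets;
  std::vector<int> cur;  // current priority of each node, -1 if absent
  int scan, backward;
  void init(int npri, int n) {
    buckets.assign(npri, {});
    cur.assign(n, -1);
    scan = 0; backward = 0;
  }
  void push(int p, int v) {
    if (p < 0) p = 0;
    if (p >= (int)buckets.size()) p = (int)buckets.size() - 1;
    if (cur[v] != -1 && cur[v] <= p) return;  // larger/equal push: no-op
    cur[v] = p;
    buckets[p].push_back(v);
    if (p < scan) { scan = p; backward++; }
  }
  // returns priority, or -1 when empty; node in *v
  int pop(int* v) {
    while (scan < (int)buckets.size()) {
      std::vector<int>& b = buckets[scan];
      while (!b.empty()) {
        int x = b.back(); b.pop_back();
        if (cur[x] == scan) { cur[x] = -1; *v = x; return scan; }
      }
      scan++;
    }
    return -1;
  }
};

// ---------------------------------------------------------------------------
// Alignment engine (Algorithm 2 + slice driver + DAG specialization)
// ---------------------------------------------------------------------------

// Column of the current slice for every node, single- or multi-word.
struct Cols {
  std::vector<std::vector<u64>> vp, vn;
  std::vector<long> sb;
};

// merge_mode: 0 = bit-parallel, 1 = reference, 2 = both + stop on mismatch
// [[Rcpp::export]]
List cpp_align(int n, IntegerVector labels,
               IntegerVector out_ptr, IntegerVector out_idx,
               IntegerVector sidx, int w, std::string mode,
               IntegerVector topo, bool keep_matrix, int merge_mode) {
  int m = sidx.size();
  bool whole = (mode == "whole");
  bool dag = (topo.size() > 0) && !whole;
  int nslice = whole ? 1 : (m + w - 1) / w;

  IntegerMatrix matrix;
  if (keep_matrix) matrix = IntegerMatrix(n, m);

  std::vector<long> sb(n, 0), send(n, 0);
  IntegerVector slice_max_repops(nslice, 0);
  IntegerVector slice_height(nslice, 0);
  int backward_total = 0;
  long total_pops = 0;

  std::vector<std::vector<u64>> VP(n), VN(n);
  std::vector<u64> cand_vp, cand_vn, mrg_vp, mrg_vn, ref_vp, ref_vn;

  for (int sl = 0; sl < nslice; sl++) {
    int off = whole ? 0 : sl * w;
    int k = whole ? m : std::min(w, m - off);
    int nw = (k + w - 1) / w;
    slice_height[sl] = k;

    // slice-local per-character match masks
    std::vector<std::vector<u64>> P(5, std::vector<u64>(nw, 0ULL));
    for (int j = 0; j < k; j++) {
      int c = sidx[off + j];
      if (c >= 0 && c < 4) P[c][j / w] |= 1ULL << (j % w);
    }

    // Initialize columns to the vertical continuation chain from the node's
    // own S_before, plus the fresh-start candidates of the empty path: an
    // alignment may start at this node at any row r with r-1 leading
    // insertions, worth (r-1) + Delta.  Those candidates lower the chain by
    // one from the first in-slice match row on, exactly when the node's
    // S_before still equals the slice's top row index (no earlier
    // improvement): clear the VP bit at the node's first in-slice match.
    for (int v = 0; v < n; v++) {
      VP[v].assign(nw, 0ULL);
      VN[v].assign(nw, 0ULL);
      for (int t = 0; t < nw; t++) {
        int kk = std::min(w, k - t * w);
        VP[v][t] = lowmask(kk);
      }
      if (sb[v] == (long)off) {
        int c = labels[v];
        const std::vector<u64>& eq = P[c >= 0 && c < 5 ? c : 4];
        for (int t = 0; t < nw; t++)
          if (eq[t]) { VP[v][t] &= ~(eq[t] & (~eq[t] + 1ULL)); break; }
      }
    }

    std::vector<int> repops(n, 0);

    // single edge update: candidate from v, merged into y's column.
    // Returns the changed-min priority (SCORE_INF if nothing improved).
    auto update_edge = [&](int v, int y) -> long {
      long diff = sb[y] - sb[v];
      int hin = (int)std::max(-1L, std::min(1L, diff));
      int c = labels[y];
      const std::vector<u64>& eq = P[c >= 0 && c < 5 ? c : 4];
      myers_step_words(VP[v], VN[v], eq, k, w, hin, cand_vp, cand_vn);
      long sb_cand = sb[v] + hin;
      if (merge_mode == 1) {
        merge_words_ref(VP[y], VN[y], sb[y], cand_vp, cand_vn, sb_cand, k, w, mrg_vp, mrg_vn);
      } else {
        merge_words_bp(VP[y], VN[y], sb[y], cand_vp, cand_vn, sb_cand, k, w, mrg_vp, mrg_vn);
        if (merge_mode == 2) {
          merge_words_ref(VP[y], VN[y], sb[y], cand_vp, cand_vn, sb_cand, k, w, ref_vp, ref_vn);
          for (int t = 0; t < (int)mrg_vp.size(); t++)
            if (mrg_vp[t] != ref_vp[t] || mrg_vn[t] != ref_vn[t])
              stop("bit-parallel merge disagrees with reference merge");
        }
      }
      long cm = changed_min_words(VP[y], VN[y], mrg_vp, mrg_vn, k, w, sb[y]);
      VP[y].swap(mrg_vp);
      VN[y].swap(mrg_vn);
      return cm;
    };

    if (dag) {
      for (int oi = 0; oi < n; oi++) {
        int v = topo[oi];
        total_pops++;
        for (int e = out_ptr[v]; e < out_ptr[v + 1]; e++)
          update_edge(v, out_idx[e]);
      }
    } else {
      BucketQueue Q;
      Q.init(m + w + 3, n);
      for (int v = 0; v < n; v++) Q.push(0, v);
      std::vector<char> seeded(n, 0);
      int v;
      while (Q.pop(&v) >= 0) {
        total_pops++;
        if (!seeded[v]) seeded[v] = 1; else repops[v]++;
        for (int e = out_ptr[v]; e < out_ptr[v + 1]; e++) {
          int y = out_idx[e];
          long cm = update_edge(v, y);
          if (cm < SCORE_INF) Q.push((int)std::max(0L, cm), y);
        }
      }
      backward_total += Q.backward;
      int mx = 0;
      for (int v2 = 0; v2 < n; v2++) mx = std::max(mx, repops[v2]);
      slice_max_repops[sl] = mx;
    }

    // decode, carry S_end into the next slice's S_before
    for (int v = 0; v < n; v++) {
      long s = sb[v];
      for (int t = 0; t < nw; t++)
        s += popcnt(VP[v][t]) - popcnt(VN[v][t]);
      send[v] = s;
      if (keep_matrix) {
        long sc = sb[v];
        for (int j = 0; j < k; j++) {
          sc += ((VP[v][j / w] >> (j % w)) & 1ULL) ? 1 :
                (((VN[v][j / w] >> (j % w)) & 1ULL) ? -1 : 0);
          matrix(v, off + j) = (int)sc;
        }
      }
    }
    sb = send;
  }

  long best = SCORE_INF;
  IntegerVector bottom(n);
  for (int v = 0; v < n; v++) {
    bottom[v] = (int)send[v];
    best = std::min(best, send[v]);
  }

  List out = List::create(
    _["best_score"] = (int)best,
    _["bottom_scores"] = bottom,
    _["n_slices"] = nslice,
    _["slice_height"] = slice_height,
    _["max_repops_per_slice"] = slice_max_repops,
    _["total_pops"] = (double)total_pops,
    _["backward_moves"] = backward_total);
  if (keep_matrix) out["matrix"] = matrix;
  return out;
}
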