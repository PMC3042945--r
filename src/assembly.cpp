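// Overlap-layout-consensus core for long single-end cDNA reads, plus the
// per-base read-cleaning loops. Coordinates are 0-based half-open
// throughout; read indices crossing the R boundary are 1-based.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <array>
#include <algorithm>
#include <functional>
#include <cstdint>
using namespace Rcpp;

static inline int base2i(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static inline char i2base(int i) { return "ACGT"[i]; }

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    int b = base2i(c);
    c = (b < 0) ? 'N' : i2base(3 - b);
  }
  return r;
}

// ---------------------------------------------------------------------------
// Banded global alignment of A against B around the main diagonal.
// Scoring (path choice only): match +1, mismatch -1, gap -2.
// Reports matches and alignment columns (gap columns counted).
// When free_b_end is true the alignment may end at the last row (A consumed)
// in any column, or at the last column (B consumed) in any row; the chosen
// end cell is returned so callers can treat the unconsumed tail of A as an
// overhang. Path (when requested) is the sequence of moves from the origin:
// 0 = diagonal, 1 = up (gap in B), 2 = left (gap in A).
// ---------------------------------------------------------------------------
struct AlnResult {
  bool ok;
  int matches, columns;
  int end_i, end_j;
  std::vector<uint8_t> path;
};

static const int NEG = -1000000000;

static AlnResult band_align(const std::string& A, const std::string& B,
                            int band, bool free_b_end, bool want_path) {
  const int n = (int)A.size(), m = (int)B.size();
  AlnResult res;
  res.ok = false;
  res.matches = 0; res.columns = 0; res.end_i = 0; res.end_j = 0;
  if (n == 0 || m == 0) return res;
  if (band < 1) band = 1;
  // j is constrained to [i - band, i + band]
  const int W = 2 * band + 1;
  std::vector<int> score((size_t)(n + 1) * W, NEG);
  std::vector<uint8_t> move((size_t)(n + 1) * W, 255);
  auto idx = [&](int i, int j) { return (size_t)i * W + (j - (i - band)); };
  auto inband = [&](int i, int j) {
    return j >= 0 && j <= m && j >= i - band && j <= i + band;
  };
  score[idx(0, 0)] = 0;
  for (int j = 1; j <= std::min(m, band); ++j) {
    score[idx(0, j)] = -2 * j;
    move[idx(0, j)] = 2;
  }
  for (int i = 1; i <= n; ++i) {
    int jlo = std::max(0, i - band), jhi = std::min(m, i + band);
    for (int j = jlo; j <= jhi; ++j) {
      int best = NEG; uint8_t mv = 255;
      if (j >= 1 && inband(i - 1, j - 1) && score[idx(i - 1, j - 1)] > NEG) {
        int sc = score[idx(i - 1, j - 1)] + (A[i - 1] == B[j - 1] &&
                                             base2i(A[i - 1]) >= 0 ? 1 : -1);
        if (sc > best) { best = sc; mv = 0; }
      }
      if (inband(i - 1, j) && score[idx(i - 1, j)] > NEG) {
        int sc = score[idx(i - 1, j)] - 2;
        if (sc > best) { best = sc; mv = 1; }
      }
      if (j >= 1 && inband(i, j - 1) && score[idx(i, j - 1)] > NEG) {
        int sc = score[idx(i, j - 1)] - 2;
        if (sc > best) { best = sc; mv = 2; }
      }
      if (mv != 255) { score[idx(i, j)] = best; move[idx(i, j)] = mv; }
    }
  }
  int ei = n, ej = m;
  if (free_b_end) {
    int best = NEG;
    for (int j = std::max(0, n - band); j <= std::min(m, n + band); ++j)
      if (score[idx(n, j)] > best) { best = score[idx(n, j)]; ei = n; ej = j; }
    for (int i = std::max(0, m - band); i <= std::min(n, m + band); ++i)
      if (inband(i, m) && score[idx(i, m)] > best) {
        best = score[idx(i, m)]; ei = i; ej = m;
      }
    if (best == NEG) return res;
  } else {
    if (!inband(n, m) || score[idx(n, m)] == NEG) return res;
  }
  // traceback
  std::vector<uint8_t> rev;
  int i = ei, j = ej, matches = 0, columns = 0;
  while (i > 0 || j > 0) {
    uint8_t mv = move[idx(i, j)];
    if (mv == 255) break;
    rev.push_back(mv);
    ++columns;
    if (mv == 0) {
      if (A[i - 1] == B[j - 1] && base2i(A[i - 1]) >= 0) ++matches;
      --i; --j;
    } else if (mv == 1) --i;
    else --j;
  }
  res.ok = true;
  res.matches = matches;
  res.columns = columns;
  res.end_i = ei;
  res.end_j = ej;
  if (want_path) {
    res.path.assign(rev.rbegin(), rev.rend());
  }
  return res;
}

static inline int band_for(int len) { return 8 + len / 50; }

// ---------------------------------------------------------------------------
// k-mer candidate detection + banded verification of pairwise overlaps.
// Overlap convention: read b (forward) aligned against read a taken on
// `strand` (0 = forward, 1 = reverse complement); `diag` is the coordinate
// on the oriented copy of a at which b[0] sits (may be negative).
// ---------------------------------------------------------------------------
struct KmerEntry {
  uint64_t kmer;
  int32_t read;
  int32_t pos;
  bool operator<(const KmerEntry& o) const {
    if (kmer != o.kmer) return kmer < o.kmer;
    if (read != o.read) return read < o.read;
    return pos < o.pos;
  }
};

template <class Fn>
static void scan_kmers_of(const std::string& s, int k, uint64_t mask,
                          Fn&& fn) {
  uint64_t key = 0;
  int run = 0;
  for (int p = 0; p < (int)s.size(); ++p) {
    int b = base2i(s[p]);
    if (b < 0) { run = 0; key = 0; continue; }
    key = ((key << 2) | (uint64_t)b) & mask;
    if (++run >= k) fn(key, p - k + 1);
  }
}

// [[Rcpp::export]]
DataFrame cpp_find_overlaps(CharacterVector seqs, int k, int min_overlap,
                            double min_identity, int max_occ = 100) {
  const int n = seqs.size();
  std::vector<std::string> fwd(n);
  size_t total_kmers = 0;
  for (int i = 0; i < n; ++i) {
    fwd[i] = as<std::string>(seqs[i]);
    if ((int)fwd[i].size() >= k) total_kmers += fwd[i].size() - k + 1;
  }
  const uint64_t mask = (k >= 32) ? ~0ULL : ((1ULL << (2 * k)) - 1);

  // flat sorted-array k-mer index over the forward strands
  std::vector<KmerEntry> index;
  index.reserve(total_kmers);
  for (int i = 0; i < n; ++i) {
    scan_kmers_of(fwd[i], k, mask, [&](uint64_t key, int pos) {
      index.push_back({key, i, pos});
    });
  }
  std::sort(index.begin(), index.end());

  // direct-indexed bucket table over the high bits: one cache miss per
  // query instead of a full binary search
  const int kbits = std::min(2 * k, 62);
  const int B = std::min(kbits, 22);
  const int shift = kbits - B;
  std::vector<uint32_t> bucket(((size_t)1 << B) + 1, 0);
  for (const auto& e : index) bucket[(e.kmer >> shift) + 1]++;
  for (size_t b = 1; b < bucket.size(); ++b) bucket[b] += bucket[b - 1];

  std::vector<int> out_a, out_b, out_strand, out_diag, out_len;
  std::vector<int> out_as, out_ae, out_bs, out_be;
  std::vector<double> out_id;

  // per-query candidate list: (partner, strand, diag)
  struct Cand {
    int32_t j; int32_t strand; int32_t diag;
    bool operator<(const Cand& o) const {
      if (j != o.j) return j < o.j;
      if (strand != o.strand) return strand < o.strand;
      return diag < o.diag;
    }
  };
  std::vector<Cand> cand;
  for (int i = 0; i < n; ++i) {
    cand.clear();
    std::string rc;
    for (int strand = 0; strand <= 1; ++strand) {
      const std::string& q = (strand == 0) ? fwd[i] : (rc = revcomp(fwd[i]));
      scan_kmers_of(q, k, mask, [&](uint64_t key, int pos) {
        size_t b = (size_t)(key >> shift);
        auto lo = index.begin() + bucket[b];
        auto bend = index.begin() + bucket[b + 1];
        lo = std::lower_bound(lo, bend, KmerEntry{key, 0, 0});
        auto hi = lo;
        while (hi != bend && hi->kmer == key) ++hi;
        if (hi - lo > max_occ) return;  // repeat k-mer
        for (auto it = lo; it != hi; ++it) {
          if (it->read >= i) continue;
          cand.push_back({it->read, strand, pos - it->pos});
        }
      });
    }
    if (cand.empty()) continue;
    std::sort(cand.begin(), cand.end());
    size_t g0 = 0;
    while (g0 < cand.size()) {
      size_t g1 = g0;
      while (g1 < cand.size() && cand[g1].j == cand[g0].j &&
             cand[g1].strand == cand[g0].strand) ++g1;
      int j = cand[g0].j, strand = cand[g0].strand;
      // densest +-3 diagonal cluster within the (j, strand) group
      int best_cnt = 0, best_diag = cand[g0].diag;
      for (size_t a0 = g0, b0 = g0; a0 < g1; ++a0) {
        while (cand[a0].diag - cand[b0].diag > 6) ++b0;
        int cnt = (int)(a0 - b0 + 1);
        if (cnt > best_cnt) {
          best_cnt = cnt;
          best_diag = cand[(a0 + b0) / 2].diag;
        }
      }
      g0 = g1;
      const std::string& qa = (strand == 0) ? fwd[i] : rc;
      const std::string& qb = fwd[j];
      const int La = (int)qa.size(), Lb = (int)qb.size(), dg = best_diag;
      int as = std::max(0, dg), ae = std::min(La, dg + Lb);
      int bs = std::max(0, -dg), be = std::min(Lb, La - dg);
      if (ae - as < min_overlap || be - bs < min_overlap) continue;
      // gapless fast path along the diagonal; the banded DP only runs when
      // the ungapped identity falls short (i.e. indels are in play)
      int m = ae - as, gl_matches = 0;
      for (int x = 0; x < m; ++x) {
        char ca = qa[as + x], cb = qb[bs + x];
        if (ca == cb && base2i(ca) >= 0) ++gl_matches;
      }
      int matches, columns;
      if ((double)gl_matches / m >= min_identity) {
        matches = gl_matches;
        columns = m;
      } else {
        AlnResult r = band_align(qa.substr(as, ae - as),
                                 qb.substr(bs, be - bs),
                                 band_for(ae - as), false, false);
        if (!r.ok) continue;
        matches = r.matches;
        columns = r.columns;
      }
      if (columns < min_overlap) continue;
      double id = (double)matches / (double)columns;
      if (id < min_identity) continue;
      int oas = as, oae = ae;
      if (strand == 1) { oas = La - ae; oae = La - as; }  // back to fwd coords
      out_a.push_back(i + 1); out_b.push_back(j + 1);
      out_strand.push_back(strand); out_diag.push_back(dg);
      out_id.push_back(id); out_len.push_back(columns);
      out_as.push_back(oas); out_ae.push_back(oae);
      out_bs.push_back(bs); out_be.push_back(be);
    }
  }
  return DataFrame::create(
    _["a"] = out_a, _["b"] = out_b, _["strand"] = out_strand,
    _["diag"] = out_diag, _["identity"] = out_id, _["length"] = out_len,
    _["a_start"] = out_as, _["a_end"] = out_ae,
    _["b_start"] = out_bs, _["b_end"] = out_be);
}

// ---------------------------------------------------------------------------
// Greedy layout: weighted union-find over affine coordinate transforms.
// A node transform (flip, off) maps a read-local forward coordinate x to the
// parent frame: X = flip ? off - x : off + x.
// ---------------------------------------------------------------------------
struct Dsu {
  std::vector<int> parent, rnk, flip;
  std::vector<long long> off;
  Dsu(int n) : parent(n), rnk(n, 0), flip(n, 0), off(n, 0) {
    for (int i = 0; i < n; ++i) parent[i] = i;
  }
  // compose: apply t1 then t2
  static void compose(int f1, long long o1, int f2, long long o2,
                      int& f, long long& o) {
    f = f1 ^ f2;
    o = f2 ? (o2 - o1) : (o2 + o1);
  }
  static void invert(int f, long long o, int& fi, long long& oi) {
    if (f) { fi = 1; oi = o; } else { fi = 0; oi = -o; }
  }
  int find(int x, int& f, long long& o) {
    if (parent[x] == x) { f = 0; o = 0; return x; }
    int fp; long long op;
    int r = find(parent[x], fp, op);
    compose(flip[x], off[x], fp, op, flip[x], off[x]);
    parent[x] = r;
    f = flip[x]; o = off[x];
    return r;
  }
};

// [[Rcpp::export]]
List cpp_layout(int n, IntegerVector a, IntegerVector b, IntegerVector strand,
                IntegerVector diag, IntegerVector lengths) {
  Dsu dsu(n);
  const int m = a.size();
  for (int e = 0; e < m; ++e) {
    int ia = a[e] - 1, ib = b[e] - 1;
    int fa, fb; long long oa, ob;
    int ra = dsu.find(ia, fa, oa), rb = dsu.find(ib, fb, ob);
    if (ra == rb) continue;
    // S maps x_b to the frame of a's forward coordinates
    int sf = strand[e];
    long long so = sf ? (long long)lengths[ia] - 1 - diag[e] : (long long)diag[e];
    // G maps root(b) frame -> root(a) frame: invert(Tb) then S then Ta
    int f1, f2; long long o1, o2;
    Dsu::invert(fb, ob, f1, o1);
    Dsu::compose(f1, o1, sf, so, f2, o2);
    Dsu::compose(f2, o2, fa, oa, f1, o1);  // f1,o1 = G
    if (dsu.rnk[ra] < dsu.rnk[rb]) {
      // attach ra under rb with G^{-1}
      int gi; long long ogi;
      Dsu::invert(f1, o1, gi, ogi);
      dsu.parent[ra] = rb; dsu.flip[ra] = gi; dsu.off[ra] = ogi;
    } else {
      dsu.parent[rb] = ra; dsu.flip[rb] = f1; dsu.off[rb] = o1;
      if (dsu.rnk[ra] == dsu.rnk[rb]) ++dsu.rnk[ra];
    }
  }
  IntegerVector root(n), flip(n);
  NumericVector off(n);
  for (int i = 0; i < n; ++i) {
    int f; long long o;
    root[i] = dsu.find(i, f, o) + 1;
    flip[i] = f;
    off[i] = (double)o;
  }
  return List::create(_["root"] = root, _["flip"] = flip, _["off"] = off);
}

// ---------------------------------------------------------------------------
// Progressive per-column-vote consensus within each layout component.
// Votes: A/C/G/T plus gap; the consensus base is the majority among bases,
// ties resolved in favour of the earliest vote at that column; columns whose
// gap votes outnumber all base votes are dropped at finalization. A member
// whose alignment identity against the running consensus falls below
// min_identity is released (the caller turns it into a singleton) and the
// component is re-consed without it.
// ---------------------------------------------------------------------------
struct Column {
  std::array<int, 5> cnt{};  // A C G T gap
  int8_t first = -1;
};

struct ConsOut {
  std::string consensus;
  std::vector<int> start, end;       // per active read, on final consensus
  std::vector<double> identity;
};

static ConsOut build_consensus(const std::vector<std::string>& oriented,
                               const std::vector<long long>& starts,
                               const std::vector<int>& order,
                               double fast_identity) {
  ConsOut out;
  const int nr = (int)order.size();
  out.start.assign(nr, 0);
  out.end.assign(nr, 0);
  out.identity.assign(nr, 1.0);
  std::vector<Column> cols;
  std::vector<char> cur;
  auto vote = [&](size_t c, int what, bool first_only_new) {
    (void)first_only_new;
    if (c >= cols.size()) return;
    cols[c].cnt[what]++;
    if (cols[c].first < 0 && what < 4) cols[c].first = (int8_t)what;
    // refresh consensus char
    int bi = 0;
    for (int t = 1; t < 4; ++t) if (cols[c].cnt[t] > cols[c].cnt[bi]) bi = t;
    if (cols[c].first >= 0 && cols[c].cnt[cols[c].first] == cols[c].cnt[bi])
      bi = cols[c].first;
    cur[c] = i2base(bi);
  };
  auto append_col = [&](char base) {
    Column col;
    int b = base2i(base);
    if (b >= 0) { col.cnt[b] = 1; col.first = (int8_t)b; }
    cols.push_back(col);
    cur.push_back(b >= 0 ? base : 'A');
  };

  for (int oi = 0; oi < nr; ++oi) {
    int r = order[oi];
    const std::string& w = oriented[r];
    long long p = starts[r];
    if (cols.empty()) {
      out.start[oi] = 0;
      out.end[oi] = (int)w.size();
      for (char c : w) append_col(c);
      continue;
    }
    if (p > (long long)cur.size()) p = (long long)cur.size();
    if (p < 0) p = 0;
    if (p == (long long)cur.size()) {
      // no overlap with the consensus built so far; concatenate
      out.start[oi] = (int)p;
      for (char c : w) append_col(c);
      out.end[oi] = (int)cur.size();
      continue;
    }
    // gapless fast path at the laid-out offset
    {
      size_t ov = std::min(w.size(), cur.size() - (size_t)p);
      int gl = 0;
      for (size_t x = 0; x < ov; ++x) {
        if (w[x] == cur[p + x] && base2i(w[x]) >= 0) ++gl;
      }
      if (ov > 0 && (double)gl / ov >= fast_identity) {
        for (size_t x = 0; x < ov; ++x) {
          vote((size_t)p + x, std::max(0, base2i(w[x])), false);
        }
        out.start[oi] = (int)p;
        for (size_t q = ov; q < w.size(); ++q) append_col(w[q]);
        out.end[oi] = (ov < w.size()) ? (int)cur.size() : (int)(p + ov);
        out.identity[oi] = (double)gl / ov;
        continue;
      }
    }
    int band = band_for((int)w.size());
    size_t clen = std::min(cur.size() - (size_t)p, w.size() + (size_t)band);
    std::string C(cur.begin() + p, cur.begin() + p + clen);
    AlnResult r2 = band_align(w, C, band, true, true);
    if (!r2.ok) {
      // degenerate: treat as appended block
      out.start[oi] = (int)cur.size();
      for (char c : w) append_col(c);
      out.end[oi] = (int)cur.size();
      out.identity[oi] = 0.0;
      continue;
    }
    // walk the path, casting votes; leading gaps in the read are positional
    // slack, not deletions - they shift the start without voting
    long long ci = p;  // consensus column
    size_t wi = 0;
    int matches = 0, columns = 0;
    bool started = false;
    long long begin_ci = p;
    for (uint8_t mv : r2.path) {
      if (!started && mv == 2) { ++ci; begin_ci = ci; continue; }
      started = true;
      ++columns;
      if (mv == 0) {
        if (base2i(w[wi]) >= 0 && w[wi] == cur[ci]) ++matches;
        vote((size_t)ci, std::max(0, base2i(w[wi])), false);
        ++ci; ++wi;
      } else if (mv == 1) {  // gap in consensus: read insertion, no column added
        ++wi;
      } else {               // gap in read: deletion vote
        vote((size_t)ci, 4, false);
        ++ci;
      }
    }
    out.start[oi] = (int)begin_ci;
    // overhang: rest of w beyond end_i appended as new columns
    for (size_t q = (size_t)r2.end_i; q < w.size(); ++q) append_col(w[q]);
    out.end[oi] = (r2.end_i < (int)w.size()) ? (int)cur.size() : (int)ci;
    out.identity[oi] = columns > 0 ? (double)matches / columns : 1.0;
  }

  // drop majority-gap columns, remapping coordinates
  std::vector<int> newpos(cols.size() + 1, 0);
  std::string cons;
  for (size_t c = 0; c < cols.size(); ++c) {
    newpos[c] = (int)cons.size();
    int bases = cols[c].cnt[0] + cols[c].cnt[1] + cols[c].cnt[2] + cols[c].cnt[3];
    if (cols[c].cnt[4] > bases) continue;
    cons.push_back(cur[c]);
  }
  newpos[cols.size()] = (int)cons.size();
  for (int oi = 0; oi < nr; ++oi) {
    out.start[oi] = newpos[std::min((size_t)out.start[oi], cols.size())];
    out.end[oi] = newpos[std::min((size_t)out.end[oi], cols.size())];
    if (out.end[oi] <= out.start[oi]) out.end[oi] = std::min(out.start[oi] + 1,
                                                             (int)cons.size());
  }
  out.consensus = cons;
  return out;
}

// [[Rcpp::export]]
List cpp_assemble_components(CharacterVector seqs, IntegerVector comp,
                             IntegerVector flip, NumericVector off,
                             double min_identity, int max_pass = 3) {
  const int n = seqs.size();
  std::vector<std::string> sq(n);
  for (int i = 0; i < n; ++i) sq[i] = as<std::string>(seqs[i]);

  int ncomp = 0;
  for (int i = 0; i < n; ++i) ncomp = std::max(ncomp, comp[i]);
  std::vector<std::vector<int>> members(ncomp);
  for (int i = 0; i < n; ++i) members[comp[i] - 1].push_back(i);

  IntegerVector contig(n, NA_INTEGER), rstart(n, NA_INTEGER),
      rend(n, NA_INTEGER), rstrand(n, NA_INTEGER);
  NumericVector ident(n, NA_REAL);
  LogicalVector released(n, false);
  std::vector<std::string> consensi;
  IntegerVector contig_comp;
  std::vector<int> contig_comp_v;

  for (int c = 0; c < ncomp; ++c) {
    const std::vector<int>& mem = members[c];
    if (mem.empty()) continue;
    if (mem.size() == 1) {
      int i = mem[0];
      consensi.push_back(sq[i]);
      contig_comp_v.push_back(c + 1);
      contig[i] = (int)consensi.size();
      rstart[i] = 0; rend[i] = (int)sq[i].size(); rstrand[i] = 0;
      ident[i] = 1.0;
      continue;
    }
    // orient members into the component frame
    std::vector<std::string> oriented(mem.size());
    std::vector<long long> starts(mem.size());
    std::vector<int> fl(mem.size());
    long long minstart = 0; bool first = true;
    for (size_t t = 0; t < mem.size(); ++t) {
      int i = mem[t];
      fl[t] = flip[i];
      oriented[t] = fl[t] ? revcomp(sq[i]) : sq[i];
      long long o = (long long)off[i];
      starts[t] = fl[t] ? o - ((long long)sq[i].size() - 1) : o;
      if (first || starts[t] < minstart) { minstart = starts[t]; first = false; }
    }
    for (auto& s : starts) s -= minstart;
    std::vector<char> active(mem.size(), 1);
    ConsOut co;
    for (int pass = 0; pass < max_pass; ++pass) {
      std::vector<int> order;
      for (size_t t = 0; t < mem.size(); ++t) if (active[t]) order.push_back((int)t);
      std::stable_sort(order.begin(), order.end(), [&](int x, int y) {
        if (starts[x] != starts[y]) return starts[x] < starts[y];
        return x < y;
      });
      if (order.empty()) break;
      co = build_consensus(oriented, starts, order, min_identity);
      bool changed = false;
      for (size_t q = 0; q < order.size(); ++q) {
        if (co.identity[q] < min_identity) {
          active[order[q]] = 0;
          changed = true;
        }
      }
      if (!changed || pass == max_pass - 1) {
        // record placements for active reads
        int nact = 0;
        for (size_t t = 0; t < mem.size(); ++t) nact += active[t];
        if (nact >= 1) {
          consensi.push_back(co.consensus);
          contig_comp_v.push_back(c + 1);
          int cid = (int)consensi.size();
          for (size_t q = 0; q < order.size(); ++q) {
            int i = mem[order[q]];
            contig[i] = cid;
            rstart[i] = co.start[q];
            rend[i] = co.end[q];
            rstrand[i] = fl[order[q]];
            ident[i] = co.identity[q];
          }
        }
        for (size_t t = 0; t < mem.size(); ++t)
          if (!active[t]) released[mem[t]] = true;
        break;
      }
    }
  }
  contig_comp = wrap(contig_comp_v);
  return List::create(
    _["contig"] = contig, _["start"] = rstart, _["end"] = rend,
    _["strand"] = rstrand, _["identity"] = ident, _["released"] = released,
    _["consensus"] = wrap(consensi), _["contig_comp"] = contig_comp);
}

// ---------------------------------------------------------------------------
// Adapter trimming: scan every alignment offset of the adapter against the
// read; a hit needs >= min_match overlapping bases with a mismatch fraction
// <= max_mismatch_rate. Hits touching the 5' end trim the prefix, hits
// touching the 3' end trim the suffix, and internal full-length hits
// truncate the read at the match start.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_trim_adapter(CharacterVector seqs, std::string adapter,
                      double max_mismatch_rate, int min_match) {
  const int n = seqs.size(), La = (int)adapter.size();
  if (min_match > La) min_match = La;  // short adapters match full-length
  CharacterVector out(n);
  IntegerVector cut5(n), cut3(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    const int Lr = (int)s.size();
    int prefix_cut = 0, suffix_cut = Lr;
    for (int t = -(La - min_match); t <= Lr - min_match; ++t) {
      int lo = std::max(0, t), hi = std::min(Lr, t + La);
      int m = hi - lo;
      if (m < min_match) continue;
      int mm = 0, allowed = (int)(max_mismatch_rate * m);
      bool okhit = true;
      for (int x = lo; x < hi; ++x) {
        if (s[x] != adapter[x - t]) {
          if (++mm > allowed) { okhit = false; break; }
        }
      }
      if (!okhit) continue;
      if (t <= 0) {                      // touches the 5' end
        prefix_cut = std::max(prefix_cut, hi);
      } else if (t + La >= Lr) {         // touches the 3' end
        suffix_cut = std::min(suffix_cut, lo);
      } else {                           // internal full match
        suffix_cut = std::min(suffix_cut, t);
      }
    }
    if (prefix_cut >= suffix_cut) {
      out[r] = "";
      cut5[r] = Lr; cut3[r] = 0;
    } else {
      out[r] = s.substr(prefix_cut, suffix_cut - prefix_cut);
      cut5[r] = prefix_cut;
      cut3[r] = Lr - suffix_cut;
    }
  }
  return List::create(_["sequence"] = out, _["cut5"] = cut5, _["cut3"] = cut3);
}

// ---------------------------------------------------------------------------
// PolyA/T trimming. From each end and for each of A and T: (i) window rule -
// cut at the outermost position p holding the target base such that every
// full window inside [p, end) has a target-base fraction >= min_frac;
// (ii) run rule - terminal pure runs >= min_run are removed. The four
// end/base sweeps repeat until no further bases come off.
// ---------------------------------------------------------------------------
static int tail_cut(const std::string& s, char base, int window, double frac,
                    int min_run) {
  const int n = (int)s.size();
  int cut = n;  // keep [0, cut)
  if (n >= window) {
    // q = smallest window start such that all windows from q on pass
    int count = 0;
    for (int x = n - window; x < n; ++x) count += (s[x] == base);
    int q = n - window + 1;
    for (int i = n - window; i >= 0; --i) {
      if (i < n - window) count += (s[i] == base) - (s[i + window] == base);
      if ((double)count / window >= frac) q = i; else break;
    }
    if (q <= n - window) {
      int p = q;
      while (p < n && s[p] != base) ++p;
      if (p <= n - window) cut = p;
    }
  }
  // terminal pure run on what remains
  int run = 0;
  while (run < cut && s[cut - 1 - run] == base) ++run;
  if (run >= min_run) cut -= run;
  return cut;
}

// [[Rcpp::export]]
List cpp_trim_polyat(CharacterVector seqs, int window, double min_frac,
                     int min_run) {
  const int n = seqs.size();
  CharacterVector out(n);
  IntegerVector polya(n), polyt(n);
  for (int r = 0; r < n; ++r) {
    std::string s = as<std::string>(seqs[r]);
    int removed_a = 0, removed_t = 0;
    bool changed = true;
    while (changed && !s.empty()) {
      changed = false;
      for (char base : {'A', 'T'}) {
        // 3' end
        int cut = tail_cut(s, base, window, min_frac, min_run);
        if (cut < (int)s.size()) {
          int rem = (int)s.size() - cut;
          (base == 'A' ? removed_a : removed_t) += rem;
          s = s.substr(0, cut);
          changed = true;
        }
        if (s.empty()) break;
        // 5' end: operate on the reverse
        std::string rv(s.rbegin(), s.rend());
        cut = tail_cut(rv, base, window, min_frac, min_run);
        if (cut < (int)rv.size()) {
          int rem = (int)rv.size() - cut;
          (base == 'A' ? removed_a : removed_t) += rem;
          s = s.substr(rem);
          changed = true;
        }
        if (s.empty()) break;
      }
    }
    out[r] = s;
    polya[r] = removed_a;
    polyt[r] = removed_t;
  }
  return List::create(_["sequence"] = out, _["polya"] = polya,
                      _["polyt"] = polyt);
}
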