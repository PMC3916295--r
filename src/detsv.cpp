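// Core kernels: read-pair overlap reconstruction, hashed seed placement with
// at most one mismatch, and affine-gap fitting alignment (Gotoh) with a
// deterministic traceback. Sequences are plain char arrays; coordinates are
// 0-based throughout.
#include <Rcpp.h>
#include <cstdint>
#include <algorithm>
#include <vector>
#include <string>
using namespace Rcpp;

static inline char comp_base(char b) {
  switch (b) {
  case 'A': return 'T'; case 'C': return 'G';
  case 'G': return 'C'; case 'T': return 'A';
  case 'a': return 't'; case 'c': return 'g';
  case 'g': return 'c'; case 't': return 'a';
  default:  return 'N';
  }
}

static std::string revcomp(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = comp_base(c);
  return r;
}

// N (or any non-ACGT) never matches, not even against itself.
static inline bool base_match(char a, char b) {
  switch (a) {
  case 'A': case 'C': case 'G': case 'T': return a == b;
  default: return false;
  }
}

// ---------------------------------------------------------------------------
// Fragment reconstruction
// ---------------------------------------------------------------------------

// For each pair, scan every overlap offset i in [0, L - m_min], scoring the
// fraction of matching bases between seq1[i..L) and the prefix of
// revcomp(seq2). Returns the best offset (smallest offset on score ties, i.e.
// the longest overlap), the best score, and the number of offsets reaching
// score 1 (ambiguity flag).
// [[Rcpp::export]]
DataFrame cpp_reconstruct(CharacterVector seq1, CharacterVector seq2, int m_min) {
  const int n = seq1.size();
  if (seq2.size() != n) stop("seq1 and seq2 must have equal length");
  IntegerVector best_offset(n), n_perfect(n);
  NumericVector best_score(n);
  for (int p = 0; p < n; ++p) {
    std::string s1 = as<std::string>(seq1[p]);
    std::string s2 = as<std::string>(seq2[p]);
    const int L = (int) s1.size();
    if ((int) s2.size() != L) stop("reads of pair %d differ in length", p + 1);
    if (m_min < 1 || m_min > L) stop("m_min must be in [1, read length]");
    std::string r2 = revcomp(s2);
    double best = -1.0; int boff = NA_INTEGER; int nperf = 0;
    for (int i = 0; i + m_min <= L; ++i) {
      const int ov = L - i;
      int nm = 0;
      for (int j = 0; j < ov; ++j)
        if (base_match(s1[i + j], r2[j])) ++nm;
      double sc = (double) nm / (double) ov;
      if (sc == 1.0) ++nperf;
      if (sc > best) { best = sc; boff = i; }
    }
    best_offset[p] = boff;
    best_score[p] = best;
    n_perfect[p] = nperf;
  }
  return DataFrame::create(_["offset"] = best_offset,
                           _["score"] = best_score,
                           _["n_perfect"] = n_perfect);
}

// ---------------------------------------------------------------------------
// Seed placement (exhaustive small-genome aligner)
// ---------------------------------------------------------------------------

struct SeedIndex {
  std::vector<std::string> chroms;
  std::vector<int64_t> offset;       // global start of each chromosome
  std::string cat;                   // concatenated genome, '#' separators
  int half;                          // exact-half length used for the index
  std::vector<uint64_t> keys;        // (kmer << 32 | global pos), sorted
};

static inline int base_code(char b) {
  switch (b) {
  case 'A': return 0; case 'C': return 1; case 'G': return 2; case 'T': return 3;
  default: return -1;
  }
}

static bool pack_kmer(const char* s, int k, uint32_t& out) {
  uint32_t v = 0;
  for (int i = 0; i < k; ++i) {
    int c = base_code(s[i]);
    if (c < 0) return false;
    v = (v << 2) | (uint32_t) c;
  }
  out = v;
  return true;
}

static SeedIndex* build_index(const CharacterVector& chrom_seqs, int half) {
  if (half < 4 || half > 15) stop("internal: index half-length out of range");
  SeedIndex* idx = new SeedIndex();
  idx->half = half;
  int64_t pos = 0;
  for (int c = 0; c < chrom_seqs.size(); ++c) {
    std::string s = as<std::string>(chrom_seqs[c]);
    idx->chroms.push_back(s);
    idx->offset.push_back(pos);
    idx->cat += s;
    idx->cat += '#';
    pos += (int64_t) s.size() + 1;
  }
  const std::string& cat = idx->cat;
  idx->keys.reserve(cat.size());
  for (size_t p = 0; p + half <= cat.size(); ++p) {
    uint32_t key;
    if (pack_kmer(cat.data() + p, half, key))
      idx->keys.push_back(((uint64_t) key << 32) | (uint64_t) p);
  }
  std::sort(idx->keys.begin(), idx->keys.end());
  return idx;
}

// Verify a candidate global window start; returns mismatches or -1 if > maxmm
// or the window crosses a chromosome boundary.
static int verify_window(const SeedIndex& idx, int64_t start, const std::string& q,
                         int maxmm) {
  if (start < 0 || start + (int64_t) q.size() > (int64_t) idx.cat.size()) return -1;
  int mm = 0;
  const char* g = idx.cat.data() + start;
  for (size_t i = 0; i < q.size(); ++i) {
    char b = g[i];
    if (b == '#') return -1;
    if (!base_match(q[i], b)) { if (++mm > maxmm) return -1; }
  }
  return mm;
}

// All placements of `q` (forward orientation) in the concatenated genome with
// <= maxmm mismatches, via the pigeonhole split into two exact halves.
static void find_hits(const SeedIndex& idx, const std::string& q, int maxmm,
                      std::vector<std::pair<int64_t,int> >& hits) {
  const int k = (int) q.size();
  const int h = idx.half;
  // candidate window starts from an exact hit of half 1 (at q[0..h)) or
  // half 2 (at q[k-h..k)); with maxmm <= 1 one of the two halves is exact.
  std::vector<int64_t> cand;
  for (int which = 0; which < 2; ++which) {
    const int qoff = (which == 0) ? 0 : k - h;
    uint32_t key;
    if (!pack_kmer(q.data() + qoff, h, key)) continue;
    uint64_t lo = ((uint64_t) key << 32);
    uint64_t hi = lo | 0xFFFFFFFFULL;
    auto it = std::lower_bound(idx.keys.begin(), idx.keys.end(), lo);
    for (; it != idx.keys.end() && *it <= hi; ++it)
      cand.push_back((int64_t)(*it & 0xFFFFFFFFULL) - qoff);
  }
  std::sort(cand.begin(), cand.end());
  cand.erase(std::unique(cand.begin(), cand.end()), cand.end());
  for (int64_t st : cand) {
    int mm = verify_window(idx, st, q, maxmm);
    if (mm >= 0) hits.push_back(std::make_pair(st, mm));
  }
}

static int global_to_chrom(const SeedIndex& idx, int64_t gpos, int64_t& local) {
  int lo = 0, hi = (int) idx.offset.size() - 1;
  while (lo < hi) {
    int mid = (lo + hi + 1) / 2;
    if (idx.offset[mid] <= gpos) lo = mid; else hi = mid - 1;
  }
  local = gpos - idx.offset[lo];
  return lo;
}

// Place each seed on both strands with <= max_mismatch mismatches.
// Returns one row per seed: the number of distinct placements (capped at 2)
// and, when the placement is unique, its chromosome (1-based index), the
// 0-based position of the seed's 5' base in forward coordinates, the strand
// (+1/-1) and the mismatch count.
// [[Rcpp::export]]
DataFrame cpp_seed_align(CharacterVector chrom_seqs, CharacterVector seeds,
                         int max_mismatch) {
  if (chrom_seqs.size() == 0) stop("empty reference");
  if (max_mismatch > 1) stop("max_mismatch > 1 is not supported by the pigeonhole index");
  int k = -1;
  for (int i = 0; i < seeds.size(); ++i) {
    int len = (int) strlen(seeds[i]);
    if (k < 0) k = len;
    if (len != k) stop("all seeds must have equal length");
  }
  if (k < 8) stop("seed length must be >= 8");
  int half = std::min(15, k / 2);
  SeedIndex* idx = build_index(chrom_seqs, half);
  const int n = seeds.size();
  IntegerVector nhits(n), chrom(n), pos5(n), strand(n), mm(n);
  for (int i = 0; i < n; ++i) {
    std::string q = as<std::string>(seeds[i]);
    std::vector<std::pair<int64_t,int> > fwd, rev;
    find_hits(*idx, q, max_mismatch, fwd);
    std::string qrc = revcomp(q);
    find_hits(*idx, qrc, max_mismatch, rev);
    int total = (int) (fwd.size() + rev.size());
    nhits[i] = std::min(total, 2);
    chrom[i] = NA_INTEGER; pos5[i] = NA_INTEGER;
    strand[i] = NA_INTEGER; mm[i] = NA_INTEGER;
    if (total == 1) {
      int64_t gpos; int st; int m;
      if (!fwd.empty()) { gpos = fwd[0].first; st = 1; m = fwd[0].second; }
      else { gpos = rev[0].first; st = -1; m = rev[0].second; }
      int64_t local;
      int ci = global_to_chrom(*idx, gpos, local);
      chrom[i] = ci + 1;
      // on the reverse strand the 5' base of the seed is the rightmost base
      pos5[i] = (int) (st == 1 ? local : local + k - 1);
      strand[i] = st;
      mm[i] = m;
    }
  }
  delete idx;
  return DataFrame::create(_["nhits"] = nhits, _["chrom"] = chrom,
                           _["pos5"] = pos5, _["strand"] = strand,
                           _["mm"] = mm);
}

// Tile every k-mer of every chromosome (step 1) and classify it as uniquely
// alignable (exactly one placement genome-wide with <= max_mismatch,
// counting both strands), multiply alignable, or excluded (contains N).
// [[Rcpp::export]]
DataFrame cpp_unique_alignability(CharacterVector chrom_seqs, int k, int max_mismatch) {
  if (chrom_seqs.size() == 0) stop("empty reference");
  if (k < 8) stop("k must be >= 8");
  int half = std::min(15, k / 2);
  SeedIndex* idx = build_index(chrom_seqs, half);
  const int nc = chrom_seqs.size();
  IntegerVector n_unique(nc), n_multiple(nc), n_total(nc), n_excluded(nc);
  for (int c = 0; c < nc; ++c) {
    const std::string& s = idx->chroms[c];
    if ((int) s.size() < k) { delete idx; stop("k exceeds the length of sequence %d", c + 1); }
    int nu = 0, nm = 0, nex = 0;
    const int ntile = (int) s.size() - k + 1;
    for (int p = 0; p < ntile; ++p) {
      std::string q = s.substr(p, k);
      bool hasN = false;
      for (char b : q) if (base_code(b) < 0) { hasN = true; break; }
      if (hasN) { ++nex; continue; }
      std::vector<std::pair<int64_t,int> > fwd, rev;
      find_hits(*idx, q, max_mismatch, fwd);
      std::string qrc = revcomp(q);
      find_hits(*idx, qrc, max_mismatch, rev);
      size_t total = fwd.size() + rev.size();
      if (total == 1) ++nu; else if (total > 1) ++nm;
    }
    n_unique[c] = nu; n_multiple[c] = nm;
    n_total[c] = ntile; n_excluded[c] = nex;
  }
  delete idx;
  return DataFrame::create(_["n_tiles"] = n_total, _["n_unique"] = n_unique,
                           _["n_multiple"] = n_multiple, _["n_excluded"] = n_excluded);
}

// ---------------------------------------------------------------------------
// Affine-gap global alignment (Gotoh) with a gap-run budget
// ---------------------------------------------------------------------------

// The query always aligns end to end. With free_ends, unaligned subject ends
// cost nothing (fitting alignment); without it, both ends are anchored and
// terminal subject gaps are charged like any other run (strict global). A gap
// of length g costs gap_open + g * gap_ext.
//
// max_runs > 0 caps the number of gap runs (maximal stretches of gap columns
// in either row). A fragment carrying a single SV needs at most two runs
// against its minimal reference (the SV's own gap plus the window-junction
// gap), and the cap keeps the cheap published gap extension (0.5/base) from
// fragmenting the alignment into score-harvesting mosaics. max_runs = 0 means
// unlimited.
//
// Traceback ties are resolved with a fixed precedence (fewer runs, then
// diagonal > gap in query row > gap in subject row, then the smallest end
// column), so the result is deterministic.
//
// Returned ops, one per alignment column:
//   0 = aligned pair (match or mismatch)
//   1 = subject base over a gap in the query row (deleted from query)
//   2 = query base over a gap in the subject row (inserted in query)
//   3 = free subject skip (unaligned subject end; free_ends mode only)
// [[Rcpp::export]]
List cpp_fit_align(std::string query, std::string subject, double match,
                   double mismatch, double gap_open, double gap_ext,
                   bool free_ends, int max_runs) {
  const int n = (int) query.size(), m = (int) subject.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int R = (max_runs > 0) ? max_runs : std::max(n, m);
  const double NEG = -1e18;
  const double openc = gap_open + gap_ext;
  const size_t cells = (size_t)(n + 1) * (m + 1);
  const int NR = R + 1;
  // state layers: for r runs used, M[r] (aligned at cell), X[r] (inside a
  // query-row gap), Y[r] (inside a subject-row gap)
  std::vector<std::vector<double> > M(NR, std::vector<double>(cells, NEG)),
      X(NR, std::vector<double>(cells, NEG)), Y(NR, std::vector<double>(cells, NEG));
  // traceback pointers: predecessor (state, runs) packed as state * NR + runs;
  // -1 = none, -2 = start
  std::vector<std::vector<int16_t> > pM(NR, std::vector<int16_t>(cells, -1)),
      pX(NR, std::vector<int16_t>(cells, -1)), pY(NR, std::vector<int16_t>(cells, -1));
#define IDX(i, j) ((size_t)(i) * (m + 1) + (j))
  const int SM = 0, SX = 1, SY = 2;
  if (free_ends) {
    for (int j = 0; j <= m; ++j) { M[0][IDX(0, j)] = 0.0; pM[0][IDX(0, j)] = -2; }
  } else {
    M[0][IDX(0, 0)] = 0.0; pM[0][IDX(0, 0)] = -2;
    if (R >= 1) {
      for (int j = 1; j <= m; ++j) {
        X[1][IDX(0, j)] = -(gap_open + gap_ext * j);
        pX[1][IDX(0, j)] = (j == 1) ? (int16_t)(-2) : (int16_t)(SX * NR + 1);
      }
    }
  }
  if (R >= 1) {
    for (int i = 1; i <= n; ++i) {
      Y[1][IDX(i, 0)] = -(gap_open + gap_ext * i);
      pY[1][IDX(i, 0)] = (i == 1) ? (int16_t)(-2) : (int16_t)(SY * NR + 1);
    }
  }
  for (int i = 1; i <= n; ++i) {
    const char qc = query[i - 1];
    for (int j = 1; j <= m; ++j) {
      const double sub = base_match(qc, subject[j - 1]) ? match : mismatch;
      for (int r = 0; r <= R; ++r) {
        // M: diagonal continuation from any state with the same run count
        {
          double best = M[r][IDX(i - 1, j - 1)]; int16_t who = (int16_t)(SM * NR + r);
          if (X[r][IDX(i - 1, j - 1)] > best) { best = X[r][IDX(i - 1, j - 1)]; who = (int16_t)(SX * NR + r); }
          if (Y[r][IDX(i - 1, j - 1)] > best) { best = Y[r][IDX(i - 1, j - 1)]; who = (int16_t)(SY * NR + r); }
          if (best > NEG / 2) {
            M[r][IDX(i, j)] = best + sub;
            // in fitting mode row 0 is the free start: mark it for traceback
            pM[r][IDX(i, j)] = (free_ends && i == 1) ? (int16_t)(-2) : who;
          }
        }
        // X: extend with the same run count, or open a new run
        {
          double best = X[r][IDX(i, j - 1)] - gap_ext; int16_t who = (int16_t)(SX * NR + r);
          if (r >= 1) {
            double o1 = M[r - 1][IDX(i, j - 1)] - openc;
            if (o1 > best) { best = o1; who = (int16_t)(SM * NR + (r - 1)); }
            double o2 = Y[r - 1][IDX(i, j - 1)] - openc;
            if (o2 > best) { best = o2; who = (int16_t)(SY * NR + (r - 1)); }
          }
          if (best > NEG / 2) { X[r][IDX(i, j)] = best; pX[r][IDX(i, j)] = who; }
        }
        // Y: extend with the same run count, or open a new run
        {
          double best = Y[r][IDX(i - 1, j)] - gap_ext; int16_t who = (int16_t)(SY * NR + r);
          if (r >= 1) {
            double o1 = M[r - 1][IDX(i - 1, j)] - openc;
            if (o1 > best) { best = o1; who = (int16_t)(SM * NR + (r - 1)); }
            double o2 = X[r - 1][IDX(i - 1, j)] - openc;
            if (o2 > best) { best = o2; who = (int16_t)(SX * NR + (r - 1)); }
          }
          if (best > NEG / 2) { Y[r][IDX(i, j)] = best; pY[r][IDX(i, j)] = who; }
        }
      }
    }
  }
  // best end cell/state: free mode scans the last row (smallest column wins
  // ties; ending inside a charged X gap is never optimal there); anchored
  // mode ends at (n, m) in any state; fewer runs win ties
  double best = NEG; int ej = -1; int estate = SM; int eruns = 0;
  if (free_ends) {
    for (int j = 0; j <= m; ++j)
      for (int r = 0; r <= R; ++r) {
        if (M[r][IDX(n, j)] > best) { best = M[r][IDX(n, j)]; ej = j; estate = SM; eruns = r; }
        if (Y[r][IDX(n, j)] > best) { best = Y[r][IDX(n, j)]; ej = j; estate = SY; eruns = r; }
      }
  } else {
    ej = m;
    for (int r = 0; r <= R; ++r) {
      if (M[r][IDX(n, m)] > best) { best = M[r][IDX(n, m)]; estate = SM; eruns = r; }
      if (X[r][IDX(n, m)] > best) { best = X[r][IDX(n, m)]; estate = SX; eruns = r; }
      if (Y[r][IDX(n, m)] > best) { best = Y[r][IDX(n, m)]; estate = SY; eruns = r; }
    }
  }
  if (best <= NEG / 2) stop("alignment infeasible under the gap-run budget");
  // traceback
  std::vector<int> rops;
  for (int j = ej; j < m; ++j) rops.push_back(3);
  std::reverse(rops.begin(), rops.end());
  int i = n, j = ej, st = estate, r = eruns;
  while (i > 0 || j > 0) {
    int16_t prev;
    if (st == SM) { prev = pM[r][IDX(i, j)]; rops.push_back(0); --i; --j; }
    else if (st == SX) { prev = pX[r][IDX(i, j)]; rops.push_back(1); --j; }
    else { prev = pY[r][IDX(i, j)]; rops.push_back(2); --i; }
    if (prev == -2) break;
    if (prev < 0) stop("internal: traceback failure");
    st = prev / NR; r = prev % NR;
  }
  // remaining subject prefix: free skip in fitting mode (anchored leading
  // gaps are walked by the traceback itself)
  for (int jj = j; jj > 0; --jj) rops.push_back(free_ends ? 3 : 1);
  std::reverse(rops.begin(), rops.end());
  int nmatch = 0;
  {
    int qi = 0, sj = 0;
    for (int op : rops) {
      if (op == 0) { if (base_match(query[qi], subject[sj])) ++nmatch; ++qi; ++sj; }
      else if (op == 2) ++qi;
      else ++sj;
    }
  }
  return List::create(_["score"] = best, _["ops"] = wrap(rops),
                      _["nmatch"] = nmatch);
#undef IDX
}
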