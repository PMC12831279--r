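#include <Rcpp.h>
#include <algorithm>
#include <array>
#include <cctype>
#include <cstdint>
#include <cstring>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// 2-bit DNA encoding; -1 for anything outside ACGT (N never seeds an anchor)
static inline int nt_code(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// 5-bit amino-acid encoding (20 AA + U, X, *, B, Z); -1 otherwise
static inline int aa_code(char c) {
  static const char *alpha = "ACDEFGHIKLMNPQRSTVWYUX*BZ";
  const char *p = std::strchr(alpha, std::toupper((unsigned char)c));
  return p ? (int)(p - alpha) : -1;
}

struct KmerIndex {
  int k;
  bool protein;
  int key_bits;   // width of a packed k-mer key
  int shift;      // key >> shift gives the bucket id
  int bloom_shift;
  std::vector<std::pair<uint64_t, int>> entries; // (key, 0-based pos), sorted
  std::vector<uint32_t> offsets; // bucket start offsets into entries
  std::vector<uint64_t> bloom;   // 1-bit membership prefilter
};

static inline uint64_t key_fingerprint(uint64_t key) {
  return key * 0x9E3779B97F4A7C15ULL;
}

template <int BITS, int (*CODE)(char)>
static void fill_index(const std::string &s, int k, KmerIndex &idx, int stride) {
  const uint64_t mask = (k * BITS >= 64) ? ~0ULL : ((1ULL << (k * BITS)) - 1);
  int n = (int)s.size();
  idx.entries.reserve((n > k ? n - k + 1 : 0) / stride + 1);
  uint64_t key = 0;
  int run = 0; // consecutive valid characters
  for (int i = 0; i < n; ++i) {
    int c = CODE(s[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << BITS) | (uint64_t)c) & mask;
    if (run++ >= k - 1 && (i - k + 1) % stride == 0)
      idx.entries.push_back(std::make_pair(key, i - k + 1));
  }
  std::sort(idx.entries.begin(), idx.entries.end());

  // bucket directory on the key's top bits: O(1) lookups instead of a
  // cache-hostile binary search per query position
  idx.key_bits = std::min(64, k * BITS);
  int bucket_bits = 1;
  while ((1ULL << bucket_bits) < idx.entries.size() + 1 && bucket_bits < 24)
    ++bucket_bits;
  bucket_bits = std::min(bucket_bits, idx.key_bits);
  idx.shift = idx.key_bits - bucket_bits;
  size_t n_buckets = 1ULL << bucket_bits;
  idx.offsets.assign(n_buckets + 1, 0);
  for (auto &e : idx.entries) idx.offsets[(e.first >> idx.shift) + 1]++;
  for (size_t b = 1; b <= n_buckets; ++b) idx.offsets[b] += idx.offsets[b - 1];

  // membership prefilter sized ~8 bits per entry (capped): most query
  // positions are rejected by one cache-friendly bit test
  int bloom_bits = 16;
  while ((1ULL << bloom_bits) < 8 * idx.entries.size() + 1 && bloom_bits < 28)
    ++bloom_bits;
  idx.bloom_shift = 64 - bloom_bits;
  idx.bloom.assign((1ULL << bloom_bits) / 64, 0);
  for (auto &e : idx.entries) {
    uint64_t f = key_fingerprint(e.first) >> idx.bloom_shift;
    idx.bloom[f >> 6] |= (1ULL << (f & 63));
  }
}

struct DiagRun { int qstart, qlast; };

template <int BITS, int (*CODE)(char)>
static IntegerMatrix query_impl(const KmerIndex &idx, const std::string &pat,
                                int max_occ) {
  int k = idx.k;
  // same-diagonal hit runs are merged on the fly (hits arrive in qpos order,
  // so per-diagonal extension is a constant-time hash update) instead of
  // accumulating and sorting every k-mer hit
  std::unordered_map<int64_t, DiagRun> open;
  std::vector<std::array<int, 3>> runs; // qstart, sstart (0-based), len
  auto flush = [&](int64_t diag, const DiagRun &r) {
    runs.push_back({r.qstart, (int)(r.qstart + diag), r.qlast - r.qstart + k});
  };
  const uint64_t mask = (k * BITS >= 64) ? ~0ULL : ((1ULL << (k * BITS)) - 1);
  uint64_t key = 0;
  int run = 0, plen = (int)pat.size();
  for (int i = 0; i < plen; ++i) {
    int c = CODE(pat[i]);
    if (c < 0) { run = 0; key = 0; continue; }
    key = ((key << BITS) | (uint64_t)c) & mask;
    if (++run < k) continue;
    int qpos = i - k + 1;
    uint64_t f = key_fingerprint(key) >> idx.bloom_shift;
    if (!(idx.bloom[f >> 6] & (1ULL << (f & 63)))) continue;
    size_t b = key >> idx.shift;
    size_t lo = idx.offsets[b], hi = idx.offsets[b + 1];
    while (lo < hi && idx.entries[lo].first < key) ++lo;
    size_t end = lo;
    while (end < hi && idx.entries[end].first == key) ++end;
    if ((int)(end - lo) > max_occ) continue; // repetitive seed
    for (size_t it = lo; it < end; ++it) {
      int64_t diag = (int64_t)idx.entries[it].second - qpos;
      auto f2 = open.find(diag);
      if (f2 == open.end()) {
        open.emplace(diag, DiagRun{qpos, qpos});
      } else if (qpos - f2->second.qlast < k) {
        f2->second.qlast = qpos;
      } else {
        flush(diag, f2->second);
        f2->second = DiagRun{qpos, qpos};
      }
    }
  }
  for (auto &kv : open) flush(kv.first, kv.second);
  std::sort(runs.begin(), runs.end(),
            [](const std::array<int, 3> &a, const std::array<int, 3> &b) {
              return a[1] < b[1] || (a[1] == b[1] && a[0] < b[0]);
            });

  IntegerMatrix out((int)runs.size(), 3);
  for (size_t r = 0; r < runs.size(); ++r) {
    out(r, 0) = runs[r][0] + 1; // 1-based for R
    out(r, 1) = runs[r][1] + 1;
    out(r, 2) = runs[r][2];
  }
  colnames(out) = CharacterVector::create("qstart", "sstart", "len");
  return out;
}

// Build a reusable exact k-mer index over a subject sequence. A stride > 1
// samples every stride-th subject k-mer: anchors blur by at most stride-1 bp
// at their ends (gap lengths between anchors stay exact) for a proportional
// cut in index and hit volume.
// [[Rcpp::export]]
SEXP cpp_index_build(std::string subject, int k, bool protein = false,
                     int stride = 1) {
  if (protein) {
    if (k < 2 || k > 12) stop("protein k must be in [2, 12]");
  } else if (k < 4 || k > 31) {
    stop("nucleotide k must be in [4, 31]");
  }
  if (stride < 1 || stride >= k) stop("stride must be in [1, k-1]");
  KmerIndex *idx = new KmerIndex();
  idx->k = k;
  idx->protein = protein;
  if (protein) fill_index<5, aa_code>(subject, k, *idx, stride);
  else fill_index<2, nt_code>(subject, k, *idx, stride);
  XPtr<KmerIndex> ptr(idx, true);
  return ptr;
}

// Maximal exact anchors of a pattern against an indexed subject; 1-based.
// [[Rcpp::export]]
IntegerMatrix cpp_index_query(SEXP xp, std::string pattern, int max_occ = 256) {
  XPtr<KmerIndex> ptr(xp);
  if (ptr->protein) return query_impl<5, aa_code>(*ptr, pattern, max_occ);
  return query_impl<2, nt_code>(*ptr, pattern, max_occ);
}

// [[Rcpp::export]]
std::string cpp_random_dna(int n) {
  static const char bases[] = "ACGT";
  std::string out((size_t)n, 'A');
  GetRNGstate();
  for (int i = 0; i < n; ++i)
    out[i] = bases[(int)(unif_rand() * 4) & 3];
  PutRNGstate();
  return out;
}

// Random in-frame coding sequence: n_codons sense codons (no TAA/TAG/TGA),
// with TGA written at the 1-based codon indices in sec_codons (Sec sites).
// [[Rcpp::export]]
std::string cpp_random_cds(int n_codons, IntegerVector sec_codons) {
  static const char bases[] = "ACGT";
  std::string out(3 * (size_t)n_codons, 'A');
  GetRNGstate();
  for (int i = 0; i < n_codons; ++i) {
    char a, b, c;
    do {
      a = bases[(int)(unif_rand() * 4) & 3];
      b = bases[(int)(unif_rand() * 4) & 3];
      c = bases[(int)(unif_rand() * 4) & 3];
    } while (a == 'T' && ((b == 'A' && (c == 'A' || c == 'G')) ||
                          (b == 'G' && c == 'A')));
    out[3 * i] = a; out[3 * i + 1] = b; out[3 * i + 2] = c;
  }
  PutRNGstate();
  for (int j = 0; j < sec_codons.size(); ++j) {
    int ci = sec_codons[j] - 1;
    if (ci < 0 || ci >= n_codons) stop("sec codon index out of range");
    out[3 * ci] = 'T'; out[3 * ci + 1] = 'G'; out[3 * ci + 2] = 'A';
  }
  return out;
}

// Apply small indels to a sequence. pos is 1-based, sorted, non-overlapping.
// kind: 1 = insertion into the sequence, 0 = deletion from it.
// dialect "truncate" edits bases; "n_fill" overwrites a +/- halfwin window
// with N, keeping length (the placeholder convention for unresolved indels).
// [[Rcpp::export]]
std::string cpp_corrupt_seq(std::string seq, IntegerVector pos,
                            IntegerVector kind, IntegerVector len,
                            std::string dialect, int n_halfwin = 10) {
  int n = pos.size();
  if (kind.size() != n || len.size() != n) stop("pos/kind/len length mismatch");
  if (dialect == "n_fill") {
    for (int i = 0; i < n; ++i) {
      int lo = std::max(0, pos[i] - 1 - n_halfwin);
      int hi = std::min((int)seq.size(), pos[i] - 1 + n_halfwin + 1);
      for (int j = lo; j < hi; ++j) seq[j] = 'N';
    }
    return seq;
  }
  static const char bases[] = "ACGT";
  std::string out;
  out.reserve(seq.size() + 16);
  GetRNGstate();
  size_t cur = 0;
  for (int i = 0; i < n; ++i) {
    size_t p = (size_t)(pos[i] - 1);
    if (p < cur || p > seq.size()) stop("indel positions must be sorted and in range");
    out.append(seq, cur, p - cur);
    if (kind[i] == 1) {
      for (int j = 0; j < len[i]; ++j)
        out.push_back(bases[(int)(unif_rand() * 4) & 3]);
      cur = p;
    } else {
      cur = std::min(seq.size(), p + (size_t)len[i]);
    }
  }
  PutRNGstate();
  out.append(seq, cur, seq.size() - cur);
  return out;
}
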