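#include <Rcpp.h>
#include <cstdint>
#include <deque>
#include <string>
#include <unordered_map>
#include <vector>
using namespace Rcpp;

// ---- base coding ------------------------------------------------------------

static inline int b2(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
  }
  return -1;
}

static inline char comp(char c) {
  switch (c) {
    case 'A': return 'T';
    case 'C': return 'G';
    case 'G': return 'C';
    case 'T': return 'A';
  }
  return 'N';
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string seq) { return revcomp(seq); }

// ---- 64-bit mixing ----------------------------------------------------------

// splitmix64 finalizer: a bijection on 64-bit integers, so hashing the 2-bit
// packed canonical s-mer through it stays collision free for s <= 31.
static inline uint64_t mix64(uint64_t x) {
  x ^= x >> 30;
  x *= 0xbf58476d1ce4e5b9ULL;
  x ^= x >> 27;
  x *= 0x94d049bb133111ebULL;
  x ^= x >> 31;
  return x;
}

// strand-canonical perfect s-mer hash phi
static inline uint64_t smer_hash(const char *p, int s) {
  uint64_t f = 0, r = 0;
  for (int i = 0; i < s; ++i) {
    f = (f << 2) | (uint64_t)b2(p[i]);
    r |= ((uint64_t)(3 - b2(p[i]))) << (2 * i);
  }
  return mix64(f < r ? f : r);
}

// FNV-1a over bytes + finalizer; used as the k-mer hash psi (collisions
// possible, resolved by sequence comparison in the table).
static inline uint64_t str_hash(const std::string &s) {
  uint64_t h = 0xcbf29ce484222325ULL;
  for (char c : s) {
    h ^= (uint64_t)(unsigned char)c;
    h *= 0x100000001b3ULL;
  }
  return mix64(h);
}

static std::string hex64(uint64_t x) {
  char buf[17];
  snprintf(buf, sizeof buf, "%016llx", (unsigned long long)x);
  return std::string(buf);
}

// [[Rcpp::export]]
CharacterVector cpp_smer_hash(CharacterVector smers, int s) {
  CharacterVector out(smers.size());
  for (R_xlen_t i = 0; i < smers.size(); ++i) {
    std::string x = as<std::string>(smers[i]);
    if ((int)x.size() != s) stop("s-mer length %d != s = %d", (int)x.size(), s);
    for (char c : x)
      if (b2(c) < 0) stop("invalid base in s-mer");
    out[i] = hex64(smer_hash(x.c_str(), s));
  }
  return out;
}

// [[Rcpp::export]]
CharacterVector cpp_kmer_hash(CharacterVector kmers) {
  CharacterVector out(kmers.size());
  for (R_xlen_t i = 0; i < kmers.size(); ++i)
    out[i] = hex64(str_hash(as<std::string>(kmers[i])));
  return out;
}

// ---- homopolymer compression ------------------------------------------------

// [[Rcpp::export]]
List cpp_hoco(std::string seq) {
  std::string bases;
  std::vector<int> runs;
  bases.reserve(seq.size());
  size_t i = 0, n = seq.size();
  while (i < n) {
    char c = seq[i];
    size_t j = i + 1;
    while (j < n && seq[j] == c) ++j;
    bases.push_back(c);
    runs.push_back((int)(j - i));
    i = j;
  }
  return List::create(_["bases"] = bases, _["runs"] = runs);
}

// [[Rcpp::export]]
std::string cpp_expand_runs(std::string bases, IntegerVector runs) {
  if ((R_xlen_t)bases.size() != runs.size()) stop("bases/runs length mismatch");
  std::string out;
  for (size_t i = 0; i < bases.size(); ++i)
    out.append((size_t)runs[i], bases[i]);
  return out;
}

// ---- closed syncmer extraction ---------------------------------------------

// Positions (0-based, hoco coords) of closed syncmers in hseq: the k-mer at p
// qualifies iff the hash of its first or last s-mer is <= all other s-mer
// hashes within it (ties qualify).
static void extract_positions(const std::string &h, int k, int s,
                              std::vector<int> &pos) {
  int n = (int)h.size();
  if (n < k) return;
  int ns = n - s + 1;         // number of s-mers
  int w = k - s + 1;          // s-mers per k-mer window
  std::vector<uint64_t> H((size_t)ns);
  for (int i = 0; i < ns; ++i) H[i] = smer_hash(h.c_str() + i, s);
  // sliding window minimum over H with a monotonic deque
  std::deque<int> dq;
  for (int i = 0; i < ns; ++i) {
    while (!dq.empty() && H[dq.back()] > H[i]) dq.pop_back();
    dq.push_back(i);
    int p = i - w + 1;        // window [p, i] complete
    if (p < 0) continue;
    while (dq.front() < p) dq.pop_front();
    uint64_t mn = H[dq.front()];
    if (H[p] == mn || H[p + w - 1] == mn) pos.push_back(p);
  }
}

// [[Rcpp::export]]
IntegerVector cpp_extract_syncmer_positions(std::string hseq, int k, int s) {
  std::vector<int> pos;
  extract_positions(hseq, k, s, pos);
  return wrap(pos);
}

// ---- syncmer table construction --------------------------------------------

struct Entry {
  std::string seq;            // canonical hoco sequence
  uint64_t hash;
  int freq = 0;
};

struct TableBuilder {
  int k, s;
  std::vector<Entry> entries;
  std::vector<std::vector<long long>> runsum;  // per-entry, length k
  std::unordered_map<uint64_t, std::vector<int>> buckets;

  TableBuilder(int k_, int s_) : k(k_), s(s_) {}

  // returns (index 1-based, orient)
  std::pair<int, int> add(const std::string &kmer, const int *runs) {
    std::string rc = revcomp(kmer);
    uint64_t hf = str_hash(kmer), hr = str_hash(rc);
    int orient;
    const std::string *canon;
    if (hf < hr) { orient = 0; canon = &kmer; }
    else if (hr < hf) { orient = 1; canon = &rc; }
    else { // hash tie: break on sequence (odd-k hoco k-mers are never palindromic)
      orient = (rc < kmer) ? 1 : 0;
      canon = orient ? &rc : &kmer;
    }
    uint64_t h = orient ? hr : hf;
    auto &bk = buckets[h];
    int idx = -1;
    for (int e : bk)
      if (entries[(size_t)e].seq == *canon) { idx = e; break; }
    if (idx < 0) {
      idx = (int)entries.size();
      entries.push_back(Entry{*canon, h, 0});
      runsum.emplace_back((size_t)k, 0LL);
      bk.push_back(idx);
    }
    entries[(size_t)idx].freq++;
    auto &rs = runsum[(size_t)idx];
    if (orient == 0)
      for (int j = 0; j < k; ++j) rs[(size_t)j] += runs[j];
    else
      for (int j = 0; j < k; ++j) rs[(size_t)j] += runs[k - 1 - j];
    return {idx + 1, orient};
  }
};

// Build the syncmer table and per-read syncmer vectors from a set of reads.
// Reads are split at N into fragments processed independently; positions are
// 0-based hoco coordinates within the fragment.
// [[Rcpp::export]]
List cpp_build_table(CharacterVector reads, int k, int s) {
  if (s > k || s < 1) stop("require 0 < s <= k");
  if (s > 31) stop("s must be <= 31");
  if (k % 2 == 0) stop("k must be odd");
  TableBuilder tb(k, s);
  std::vector<int> v_read, v_frag, v_index, v_pos, v_orient;
  std::vector<int> f_read, f_id, f_len;

  for (R_xlen_t ri = 0; ri < reads.size(); ++ri) {
    std::string r = as<std::string>(reads[ri]);
    size_t i = 0, n = r.size();
    int frag = 0;
    while (i < n) {
      while (i < n && r[i] == 'N') ++i;
      size_t j = i;
      while (j < n && r[j] != 'N') ++j;
      if (j > i) {
        ++frag;
        // hoco-compress fragment
        std::string bases;
        std::vector<int> runs;
        size_t a = i;
        while (a < j) {
          char c = r[a];
          size_t b = a + 1;
          while (b < j && r[b] == c) ++b;
          bases.push_back(c);
          runs.push_back((int)(b - a));
          a = b;
        }
        f_read.push_back((int)ri + 1);
        f_id.push_back(frag);
        f_len.push_back((int)bases.size());
        std::vector<int> pos;
        extract_positions(bases, k, s, pos);
        for (int p : pos) {
          std::string km = bases.substr((size_t)p, (size_t)k);
          auto io = tb.add(km, runs.data() + p);
          v_read.push_back((int)ri + 1);
          v_frag.push_back(frag);
          v_index.push_back(io.first);
          v_pos.push_back(p);
          v_orient.push_back(io.second);
        }
      }
      i = j;
    }
  }

  int ne = (int)tb.entries.size();
  CharacterVector seqs(ne);
  IntegerVector freq(ne);
  CharacterVector hashes(ne);
  NumericMatrix rsum(k, ne);
  for (int e = 0; e < ne; ++e) {
    seqs[e] = tb.entries[(size_t)e].seq;
    freq[e] = tb.entries[(size_t)e].freq;
    hashes[e] = hex64(tb.entries[(size_t)e].hash);
    for (int j = 0; j < k; ++j) rsum(j, e) = (double)tb.runsum[(size_t)e][(size_t)j];
  }
  return List::create(
      _["seq"] = seqs, _["freq"] = freq, _["hash"] = hashes,
      _["runlen_sum"] = rsum,
      _["vec"] = DataFrame::create(_["read"] = v_read, _["frag"] = v_frag,
                                   _["index"] = v_index, _["pos"] = v_pos,
                                   _["orient"] = v_orient),
      _["frags"] = DataFrame::create(_["read"] = f_read, _["frag"] = f_id,
                                     _["hoco_len"] = f_len));
}
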