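// Fast sequence-containment primitives for discriminative motif discovery.
// Sequences are plain character strings over {A,C,G,T,N,...}; any letter
// outside ACGT (including N) matches no IUPAC code, so masked bases can
// never contribute to a match.

#include <Rcpp.h>
#include <cstdint>
#include <cstring>
#include <vector>
#include <string>

using namespace Rcpp;

// IUPAC nucleotide sets as 4-bit masks: A=1, C=2, G=4, T=8.
static inline int code_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    case 'R': case 'r': return 5;   // A/G
    case 'Y': case 'y': return 10;  // C/T
    case 'S': case 's': return 6;   // C/G
    case 'W': case 'w': return 9;   // A/T
    case 'K': case 'k': return 12;  // G/T
    case 'M': case 'm': return 3;   // A/C
    case 'B': case 'b': return 14;  // C/G/T
    case 'D': case 'd': return 13;  // A/G/T
    case 'H': case 'h': return 11;  // A/C/T
    case 'V': case 'v': return 7;   // A/C/G
    case 'N': case 'n': return 15;
    default: return -1;
  }
}

// Sequence letters: only unambiguous bases can be matched.
static inline int base_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    default: return 0;
  }
}

// Complement of a 4-bit base set (A<->T, C<->G).
static inline int comp_mask(int m) {
  return ((m & 1) ? 8 : 0) | ((m & 2) ? 4 : 0) | ((m & 4) ? 2 : 0) | ((m & 8) ? 1 : 0);
}

struct ShiftAnd {
  // acc[b] has bit j set iff pattern position j accepts a sequence base with
  // 4-bit mask b (b in 0..15; 0 = unmatched letter such as N).
  uint64_t acc[16];
  uint64_t accept_bit;
  int m;
  void build(const std::string &word, bool revcomp) {
    m = (int) word.size();
    for (int b = 0; b < 16; ++b) acc[b] = 0;
    for (int j = 0; j < m; ++j) {
      char c = revcomp ? word[m - 1 - j] : word[j];
      int cm = code_mask(c);
      if (cm < 0) stop("invalid IUPAC letter '%s' in motif word", std::string(1, c));
      if (revcomp) cm = comp_mask(cm);
      for (int b = 1; b < 16; ++b)
        if (cm & b) acc[b] |= (uint64_t(1) << j);
    }
    accept_bit = uint64_t(1) << (m - 1);
  }
};

// Does seq contain an exact IUPAC-compatible match of the pattern(s)?
static inline bool contains_one(const char *s, int n, const ShiftAnd &fwd,
                                const ShiftAnd *rev) {
  uint64_t st1 = 0, st2 = 0;
  for (int i = 0; i < n; ++i) {
    int b = base_mask(s[i]);
    st1 = ((st1 << 1) | 1) & fwd.acc[b];
    if (st1 & fwd.accept_bit) return true;
    if (rev) {
      st2 = ((st2 << 1) | 1) & rev->acc[b];
      if (st2 & rev->accept_bit) return true;
    }
  }
  return false;
}

//' @noRd
// [[Rcpp::export(name = ".iupac_contain")]]
LogicalVector iupac_contain(CharacterVector seqs, std::string word,
                            bool both_strands = true) {
  if (word.size() == 0) stop("empty motif word");
  if (word.size() > 63) stop("motif word longer than 63 bases");
  ShiftAnd fwd, rev;
  fwd.build(word, false);
  if (both_strands) rev.build(word, true);
  int n = seqs.size();
  LogicalVector out(n);
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = (int) std::strlen(s);
    out[i] = contains_one(s, len, fwd, both_strands ? &rev : (ShiftAnd *) 0);
  }
  return out;
}

//' @noRd
// [[Rcpp::export(name = ".iupac_mask")]]
CharacterVector iupac_mask(CharacterVector seqs, std::string word,
                           bool both_strands = true) {
  if (word.size() == 0) stop("empty motif word");
  ShiftAnd fwd, rev;
  fwd.build(word, false);
  if (both_strands) rev.build(word, true);
  int m = fwd.m;
  int n = seqs.size();
  CharacterVector out(n);
  for (int i = 0; i < n; ++i) {
    std::string s = as<std::string>(seqs[i]);
    int len = (int) s.size();
    std::vector<char> hit(len, 0);
    uint64_t st1 = 0, st2 = 0;
    for (int p = 0; p < len; ++p) {
      int b = base_mask(s[p]);
      st1 = ((st1 << 1) | 1) & fwd.acc[b];
      bool match = (st1 & fwd.accept_bit) != 0;
      if (both_strands) {
        st2 = ((st2 << 1) | 1) & rev.acc[b];
        match = match || (st2 & rev.accept_bit) != 0;
      }
      if (match)
        for (int j = p - m + 1; j <= p; ++j) hit[j] = 1;
    }
    for (int p = 0; p < len; ++p)
      if (hit[p]) s[p] = 'N';
    out[i] = s;
  }
  return out;
}

// 2-bit encoding A=0, C=1, G=2, T=3 (so numeric order == lexicographic order).
static inline int base2bit(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return -1;
  }
}

//' @noRd
// [[Rcpp::export(name = ".kmer_seq_counts")]]
IntegerVector kmer_seq_counts(CharacterVector seqs, int k) {
  if (k < 1 || k > 12) stop("k must be in 1..12");
  const int nk = 1 << (2 * k);
  const uint32_t mask = nk - 1;
  // reverse complement lookup for k-mer indices
  std::vector<uint32_t> rc(nk);
  for (int w = 0; w < nk; ++w) {
    uint32_t r = 0, x = (uint32_t) w;
    for (int j = 0; j < k; ++j) {
      r = (r << 2) | (3 - (x & 3));  // complement + reverse
      x >>= 2;
    }
    rc[w] = r;
  }
  IntegerVector counts(nk);
  std::vector<uint8_t> present(nk);
  std::vector<uint32_t> touched;
  touched.reserve(4096);
  int n = seqs.size();
  for (int i = 0; i < n; ++i) {
    const char *s = CHAR(STRING_ELT(seqs, i));
    int len = (int) std::strlen(s);
    touched.clear();
    uint32_t w = 0;
    int run = 0;
    for (int p = 0; p < len; ++p) {
      int b = base2bit(s[p]);
      if (b < 0) { run = 0; continue; }
      w = ((w << 2) | (uint32_t) b) & mask;
      if (++run >= k) {
        if (!present[w]) { present[w] = 1; touched.push_back(w); }
      }
    }
    // both-strand containment: a sequence contains word w iff it contains
    // w or rc(w) on the forward strand; counts[w] == counts[rc(w)] holds.
    for (uint32_t t : touched) {
      counts[t]++;
      uint32_t c = rc[t];
      if (c != t && !present[c]) counts[c]++;
    }
    for (uint32_t t : touched) present[t] = 0;
  }
  return counts;
}
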