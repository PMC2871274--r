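// Seed-and-extend core for three-letter bisulfite alignment.
//
// The index is a plain k-mer occurrence table (counting sort over 2-bit
// codes) on the concatenated converted chromosomes.  Alignment seeds a read
// with m+1 non-overlapping segments, so by pigeonhole every placement with
// at most m mismatches carries at least one exact seed; verification is an
// early-exit Hamming count.  Reads too short to carry m+1 seeds of length k
// fall back to a full sliding-window scan (flagged, never dropped).

#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <string>
#include <cstdint>

using namespace Rcpp;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return 4;  // N and anything else
  }
}

// [[Rcpp::export]]
List cpp_build_index(CharacterVector seqs, int k) {
  if (k < 1 || k > 13)
    stop("seed length k must be in [1, 13]");
  const int nchrom = seqs.size();
  std::vector<int> chrom_start(nchrom + 1, 0);
  size_t total = 0;
  for (int c = 0; c < nchrom; ++c) {
    total += LENGTH(STRING_ELT(seqs, c));
    chrom_start[c + 1] = (int) total;
  }
  RawVector enc((R_xlen_t) total);
  for (int c = 0; c < nchrom; ++c) {
    const char* s = CHAR(STRING_ELT(seqs, c));
    int off = chrom_start[c], len = chrom_start[c + 1] - chrom_start[c];
    for (int i = 0; i < len; ++i) enc[off + i] = (Rbyte) base_code(s[i]);
  }

  const uint32_t mask = (k == 16) ? 0xFFFFFFFFu : ((1u << (2 * k)) - 1u);
  const size_t nbuckets = ((size_t) 1) << (2 * k);
  std::vector<int> cnt(nbuckets + 1, 0);

  // pass 1: count N-free k-mers per chromosome
  for (int c = 0; c < nchrom; ++c) {
    int lo = chrom_start[c], hi = chrom_start[c + 1];
    uint32_t code = 0; int valid = 0;
    for (int i = lo; i < hi; ++i) {
      int b = enc[i];
      if (b > 3) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid >= k) cnt[code + 1]++;
    }
  }
  for (size_t i = 1; i <= nbuckets; ++i) cnt[i] += cnt[i - 1];
  IntegerVector bucket(nbuckets + 1);
  for (size_t i = 0; i <= nbuckets; ++i) bucket[i] = cnt[i];

  IntegerVector pos(cnt[nbuckets]);
  std::vector<int> fill(cnt.begin(), cnt.end() - 1);
  // pass 2: fill positions (ascending per bucket by construction)
  for (int c = 0; c < nchrom; ++c) {
    int lo = chrom_start[c], hi = chrom_start[c + 1];
    uint32_t code = 0; int valid = 0;
    for (int i = lo; i < hi; ++i) {
      int b = enc[i];
      if (b > 3) { valid = 0; code = 0; continue; }
      code = ((code << 2) | (uint32_t) b) & mask;
      if (++valid >= k) pos[fill[code]++] = i - k + 1;
    }
  }

  return List::create(_["k"] = k,
                      _["seq"] = enc,
                      _["chrom_start"] = IntegerVector(chrom_start.begin(), chrom_start.end()),
                      _["bucket"] = bucket,
                      _["pos"] = pos);
}

// Hamming distance with early exit; any code > 3 (N) on either side mismatches.
static inline int verify(const Rbyte* seq, const std::vector<int>& rd,
                         int start, int m) {
  int mm = 0;
  const int n = (int) rd.size();
  for (int i = 0; i < n; ++i) {
    int g = seq[start + i], r = rd[i];
    if (r != g || r > 3) {
      if (++mm > m) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
List cpp_align_batch(CharacterVector reads, List idx, int m, int cap) {
  const int k = as<int>(idx["k"]);
  RawVector enc = idx["seq"];
  IntegerVector chrom_start = idx["chrom_start"];
  IntegerVector bucket = idx["bucket"];
  IntegerVector pos = idx["pos"];
  const int nchrom = chrom_start.size() - 1;
  const uint32_t mask = (1u << (2 * k)) - 1u;
  const Rbyte* seq = RAW(enc);

  std::vector<int> out_read, out_start, out_mm;
  const int nreads = reads.size();
  LogicalVector fallback(nreads, false), capped(nreads, false);

  for (int j = 0; j < nreads; ++j) {
    const char* s = CHAR(STRING_ELT(reads, j));
    const int n = LENGTH(STRING_ELT(reads, j));
    std::vector<int> rd(n);
    for (int i = 0; i < n; ++i) rd[i] = base_code(s[i]);

    std::vector<std::pair<int,int> > hits;  // (global start, mm)
    bool over_cap = false;

    const int seg = (m + 1 > 0) ? n / (m + 1) : n;
    if (seg < k || n == 0) {
      // full scan fallback: read cannot carry m+1 seeds of length k
      fallback[j] = true;
      for (int c = 0; c < nchrom && !over_cap; ++c) {
        int lo = chrom_start[c], hi = chrom_start[c + 1];
        for (int st = lo; st + n <= hi; ++st) {
          int mm = verify(seq, rd, st, m);
          if (mm <= m) {
            hits.push_back(std::make_pair(st, mm));
            if ((int) hits.size() > cap) { over_cap = true; break; }
          }
        }
      }
    } else {
      // candidates are verified straight off the bucket lists (early-exit
      // Hamming is cheaper than deduplicating them first); the few
      // surviving hits are deduplicated below.  A raw count above
      // (m+1)*cap already implies more than cap distinct hits.
      const long raw_cap = (long) (m + 1) * (long) cap + m;
      for (int si = 0; si <= m && !over_cap; ++si) {
        const int soff = si * seg;
        uint32_t code = 0; bool ok = true;
        for (int i = 0; i < k; ++i) {
          int b = rd[soff + i];
          if (b > 3) { ok = false; break; }
          code = (code << 2) | (uint32_t) b;
        }
        if (!ok) continue;  // seed contains N: never indexed
        code &= mask;
        for (int t = bucket[code]; t < bucket[code + 1]; ++t) {
          int st = pos[t] - soff;
          // locate chromosome containing the seed hit
          int lo = 0, hi = nchrom;
          while (hi - lo > 1) {
            int mid = (lo + hi) / 2;
            if (pos[t] >= chrom_start[mid]) lo = mid; else hi = mid;
          }
          if (st < chrom_start[lo] || st + n > chrom_start[lo + 1]) continue;
          int mm = verify(seq, rd, st, m);
          if (mm <= m) {
            hits.push_back(std::make_pair(st, mm));
            if ((long) hits.size() > raw_cap) { over_cap = true; break; }
          }
        }
      }
      std::sort(hits.begin(), hits.end());
      hits.erase(std::unique(hits.begin(), hits.end()), hits.end());
      if ((int) hits.size() > cap) { over_cap = true; hits.resize(cap); }
    }
    if (over_cap) capped[j] = true;
    for (size_t h = 0; h < hits.size(); ++h) {
      out_read.push_back(j + 1);
      out_start.push_back(hits[h].first);
      out_mm.push_back(hits[h].second);
    }
  }

  return List::create(_["read"] = IntegerVector(out_read.begin(), out_read.end()),
                      _["gstart"] = IntegerVector(out_start.begin(), out_start.end()),
                      _["mm"] = IntegerVector(out_mm.begin(), out_mm.end()),
                      _["fallback"] = fallback,
                      _["capped"] = capped);
}

// Asymmetric bisulfite mismatch count in the original alphabet.
// FW polarity: read T over genomic C is a match; RC: read A over genomic G.
// N on either side always mismatches.
// [[Rcpp::export]]
IntegerVector cpp_bs_mismatches(CharacterVector reads, CharacterVector refs,
                                LogicalVector rc) {
  const int n = reads.size();
  if (refs.size() != n || rc.size() != n)
    stop("reads, refs and rc must have equal length");
  IntegerVector out(n);
  for (int j = 0; j < n; ++j) {
    const char* r = CHAR(STRING_ELT(reads, j));
    const char* g = CHAR(STRING_ELT(refs, j));
    const int lr = LENGTH(STRING_ELT(reads, j));
    if (LENGTH(STRING_ELT(refs, j)) != lr)
      stop("read and reference segment differ in length at record %d", j + 1);
    int mm = 0;
    const bool isrc = rc[j];
    for (int i = 0; i < lr; ++i) {
      char rb = r[i], gb = g[i];
      bool match = (rb == gb && rb != 'N');
      if (!match) {
        if (!isrc) match = (rb == 'T' && gb == 'C');
        else       match = (rb == 'A' && gb == 'G');
      }
      if (!match) ++mm;
    }
    out[j] = mm;
  }
  return out;
}

// Per-read methylation extraction over fragment-oriented read/reference pairs.
// At every reference C: read C -> methylated ('M'), read T -> unmethylated
// ('U'), anything else -> no call ('.'); non-C reference positions -> '-'.
// Returns the per-read strings plus long vectors of called sites.
// [[Rcpp::export]]
List cpp_meth_extract(CharacterVector fragReads, CharacterVector fragRefs) {
  const int n = fragReads.size();
  if (fragRefs.size() != n) stop("fragment vectors must have equal length");
  CharacterVector strings(n);
  std::vector<int> s_read, s_pos, s_state;
  std::string buf;
  for (int j = 0; j < n; ++j) {
    const char* r = CHAR(STRING_ELT(fragReads, j));
    const char* g = CHAR(STRING_ELT(fragRefs, j));
    const int lr = LENGTH(STRING_ELT(fragReads, j));
    if (LENGTH(STRING_ELT(fragRefs, j)) != lr)
      stop("read and reference segment differ in length at record %d", j + 1);
    buf.assign(lr, '-');
    for (int i = 0; i < lr; ++i) {
      if (g[i] != 'C') continue;
      if (r[i] == 'C') {
        buf[i] = 'M'; s_read.push_back(j + 1); s_pos.push_back(i + 1); s_state.push_back(1);
      } else if (r[i] == 'T') {
        buf[i] = 'U'; s_read.push_back(j + 1); s_pos.push_back(i + 1); s_state.push_back(0);
      } else {
        buf[i] = '.';
      }
    }
    strings[j] = buf;
  }
  return List::create(_["string"] = strings,
                      _["read"] = IntegerVector(s_read.begin(), s_read.end()),
                      _["fragpos"] = IntegerVector(s_pos.begin(), s_pos.end()),
                      _["state"] = IntegerVector(s_state.begin(), s_state.end()));
}
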