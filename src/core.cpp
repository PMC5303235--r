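// Compiled cores: seeded banded read aligner over a small circular reference
// panel, pileup accumulation, substitution-by-end-distance profiling, and a
// banded global (Needleman-Wunsch) aligner for annotation transfer.
#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <cstdint>
#include <algorithm>

using namespace Rcpp;

static const int BIG = 1000000;

static inline char comp_base(char c) {
  switch (c) {
    case 'A': return 'T'; case 'C': return 'G';
    case 'G': return 'C'; case 'T': return 'A';
    case 'N': return 'N'; default: return 'N';
  }
}

static std::string revcomp(const std::string &s) {
  std::string r(s.rbegin(), s.rend());
  for (auto &c : r) c = comp_base(c);
  return r;
}

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0; case 'C': return 1;
    case 'G': return 2; case 'T': return 3; default: return -1;
  }
}

// Smallest k >= 0 with P(Poisson(err*l) > k) < miss_thres; BWA's -n rule.
static int maxdiff_one(int l, double err, double miss_thres) {
  if (err <= 0.0) return 0;
  double lambda = err * (double)l;
  for (int k = 0; k < 1000; ++k) {
    double tail = R::ppois((double)k, lambda, 0, 0); // P(X > k)
    if (tail < miss_thres) return k;
  }
  return 1000;
}

// [[Rcpp::export]]
IntegerVector cpp_maxdiff(IntegerVector lens, double err, double miss_thres) {
  IntegerVector out(lens.size());
  for (R_xlen_t i = 0; i < lens.size(); ++i)
    out[i] = maxdiff_one(lens[i], err, miss_thres);
  return out;
}

struct Placement {
  int genome;   // 0-based
  int start;    // 0-based, mod L
  int strand;   // +1 / -1
  int edit;
  int gaps;
  int n_wild;   // read bases matched against reference N (no evidence)
  std::string cigar;
};

// Banded, gap-open-capped edit-distance DP of a read (global in read) against
// a reference window (free leading/trailing window bases).  N in the window is
// a wildcard (cost 0), 'X' is an out-of-range sentinel (prohibitive).
// Returns best edit or BIG; fills start offset within window, gap opens, cigar.
struct DPBuf {
  std::vector<int> val;
  std::vector<uint8_t> bp; // backpointer: op(2 bits) | prev_m(2) | prev_g(2)
};

static int band_dp(const std::string &read, const std::string &win, int B,
                   int G, int cap, bool n_free, DPBuf &buf, int &start_off,
                   int &gaps_used, std::string &cigar) {
  const int l = (int)read.size();
  const int W = 2 * B + 1;
  const int M3 = 3;
  const size_t nst = (size_t)(l + 1) * W * (G + 1) * M3;
  if (buf.val.size() < nst) { buf.val.resize(nst); buf.bp.resize(nst); }
  std::fill(buf.val.begin(), buf.val.begin() + nst, BIG);
  auto idx = [&](int i, int d, int g, int m) {
    return (((size_t)i * W + d) * (G + 1) + g) * M3 + m;
  };
  for (int d = 0; d < W; ++d) buf.val[idx(0, d, 0, 0)] = 0;

  for (int i = 0; i <= l; ++i) {
    // D transitions within row i (ref consumed): d ascending
    for (int d = 0; d + 1 < W; ++d) {
      for (int g = 0; g <= G; ++g) {
        for (int m = 0; m < 3; ++m) {
          int v = buf.val[idx(i, d, g, m)];
          if (v + 1 > cap || v >= BIG) continue;
          if (i == 0) continue; // leading ref skip is free via init
          int g2 = g + (m == 2 ? 0 : 1);
          if (g2 > G) continue;
          size_t t = idx(i, d + 1, g2, 2);
          if (v + 1 < buf.val[t]) {
            buf.val[t] = v + 1;
            buf.bp[t] = (uint8_t)(2 | (m << 2) | (g << 4));
          }
        }
      }
    }
    if (i == l) break;
    char rch = read[i];
    for (int d = 0; d < W; ++d) {
      int j = i + d; // window coordinate consumed by M
      char wch = (j < (int)win.size()) ? win[j] : 'X';
      int sub;
      if (wch == 'N') sub = n_free ? 0 : 1;
      else if (wch == 'X') sub = BIG;
      else sub = (wch == rch) ? 0 : 1;
      for (int g = 0; g <= G; ++g) {
        for (int m = 0; m < 3; ++m) {
          int v = buf.val[idx(i, d, g, m)];
          if (v > cap || v >= BIG) continue;
          // M: to (i+1, d)
          if (sub < BIG && v + sub <= cap) {
            size_t t = idx(i + 1, d, g, 0);
            if (v + sub < buf.val[t]) {
              buf.val[t] = v + sub;
              buf.bp[t] = (uint8_t)(0 | (m << 2) | (g << 4));
            }
          }
          // I (read consumed, no ref): to (i+1, d-1); terminal read bases
          // must align as M so end mismatches are never recast as indels
          if (d > 0 && i > 0 && i < l - 1) {
            int g2 = g + (m == 1 ? 0 : 1);
            if (g2 <= G && v + 1 <= cap) {
              size_t t = idx(i + 1, d - 1, g2, 1);
              if (v + 1 < buf.val[t]) {
                buf.val[t] = v + 1;
                buf.bp[t] = (uint8_t)(1 | (m << 2) | (g << 4));
              }
            }
          }
        }
      }
    }
  }
  // best final state; ties prefer fewer gap openings so mismatches are never
  // silently recast as end-adjacent indels
  int best = BIG, bd = -1, bg = -1, bm = -1;
  for (int g = 0; g <= G; ++g)
    for (int d = 0; d < W; ++d)
      for (int m = 0; m < 3; ++m) {
        int v = buf.val[idx(l, d, g, m)];
        if (v < best) { best = v; bd = d; bg = g; bm = m; }
      }
  if (best > cap || best >= BIG) return BIG;
  // traceback
  std::vector<char> ops;
  int i = l, d = bd, g = bg, m = bm;
  while (i > 0 || !(g == 0 && m == 0 && buf.val[idx(i, d, g, m)] == 0)) {
    if (i == 0 && buf.val[idx(i, d, g, m)] == 0 && g == 0 && m == 0) break;
    uint8_t b = buf.bp[idx(i, d, g, m)];
    int op = b & 3, pm = (b >> 2) & 3, pg = (b >> 4) & 3;
    if (op == 0) { ops.push_back('M'); i -= 1; }
    else if (op == 1) { ops.push_back('I'); i -= 1; d += 1; }
    else { ops.push_back('D'); d -= 1; }
    g = pg; m = pm;
    if (i < 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  start_off = d; // j at i=0 equals d
  gaps_used = bg;
  // run-length encode
  std::string cg;
  size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cg += std::to_string(q - p);
    cg += ops[p];
    p = q;
  }
  cigar = cg;
  return best;
}

// Align a pool of reads against a panel of (possibly circular) references.
// Returns every deduplicated placement within maxdiff, with its wildcard
// (reference-N) match count; stratum and mapping-quality logic lives in R.
// [[Rcpp::export]]
List cpp_align_reads(CharacterVector reads, CharacterVector genomes,
                     LogicalVector circular, double err, double miss_thres,
                     int max_gap_opens, int seed_len, bool n_free) {
  const int NG = genomes.size();
  const int NR = reads.size();
  std::vector<std::string> gseq(NG), gext(NG);
  std::vector<int> glen(NG);
  // extension so any window for a start < L is in-range
  const int EXT = 360;
  std::vector<std::unordered_map<uint64_t, std::vector<int>>> index(NG);
  const uint64_t mask = (seed_len >= 32) ? ~0ULL : ((1ULL << (2 * seed_len)) - 1);
  for (int g = 0; g < NG; ++g) {
    gseq[g] = as<std::string>(genomes[g]);
    glen[g] = (int)gseq[g].size();
    gext[g] = gseq[g];
    if (circular[g]) {
      int add = std::min(EXT, glen[g]);
      gext[g] += gseq[g].substr(0, add);
    }
    // k-mer index over the extended sequence
    const std::string &s = gext[g];
    uint64_t h = 0; int run = 0;
    for (int p = 0; p < (int)s.size(); ++p) {
      int c = base_code(s[p]);
      if (c < 0) { run = 0; h = 0; continue; }
      h = ((h << 2) | (uint64_t)c) & mask;
      if (++run >= seed_len) {
        int pos = p - seed_len + 1;
        index[g][h].push_back(pos);
      }
    }
  }

  std::vector<int> out_read, out_genome, out_start, out_strand, out_edit,
      out_gaps, out_wild;
  std::vector<std::string> out_cigar;

  DPBuf buf;
  std::unordered_map<int, int> memo_maxdiff;

  for (int r = 0; r < NR; ++r) {
    std::string fwd = as<std::string>(reads[r]);
    int l = (int)fwd.size();
    if (l < seed_len) continue;
    int k;
    auto it = memo_maxdiff.find(l);
    if (it == memo_maxdiff.end()) { k = maxdiff_one(l, err, miss_thres); memo_maxdiff[l] = k; }
    else k = it->second;
    int B = std::max(k, 1);
    std::string rev = revcomp(fwd);
    const std::string *strands[2] = { &fwd, &rev };

    // per genome: deduped placements
    std::vector<std::vector<Placement>> placements(NG);
    for (int g = 0; g < NG; ++g) {
      const std::string &ext = gext[g];
      int L = glen[g];
      for (int si = 0; si < 2; ++si) {
        const std::string &rd = *strands[si];
        // candidate diagonals via exact seeds at every offset
        std::vector<int> diags;
        uint64_t h = 0; int run = 0;
        for (int p = 0; p < l; ++p) {
          int c = base_code(rd[p]);
          if (c < 0) { run = 0; h = 0; continue; }
          h = ((h << 2) | (uint64_t)c) & mask;
          if (++run >= seed_len) {
            int off = p - seed_len + 1;
            auto hit = index[g].find(h);
            if (hit != index[g].end())
              for (int pos : hit->second) {
                int d0 = pos - off;
                if (circular[g]) {
                  d0 = ((d0 % L) + L) % L;
                } else if (d0 < -B || d0 > (int)ext.size() - 1) continue;
                diags.push_back(d0);
              }
          }
        }
        std::sort(diags.begin(), diags.end());
        diags.erase(std::unique(diags.begin(), diags.end()), diags.end());
        // collapse diagonals within the band (same window finds them)
        std::vector<int> cand;
        for (int d0 : diags)
          if (cand.empty() || d0 - cand.back() > B) cand.push_back(d0);
        std::unordered_map<int, int> seen; // start -> index into placements[g]
        for (int d0 : cand) {
          int ws = d0 - B;
          std::string win;
          if (ws < 0) {
            win.assign((size_t)(-ws), 'X');
            win += ext.substr(0, std::min((size_t)(l + 2 * B + ws), ext.size()));
          } else if (ws < (int)ext.size()) {
            win = ext.substr(ws, l + 2 * B);
          } else continue;
          if ((int)win.size() < l + 2 * B) win.append(l + 2 * B - win.size(), 'X');
          int soff, gaps; std::string cg;
          int e = band_dp(rd, win, B, max_gap_opens, k, n_free, buf, soff,
                          gaps, cg);
          if (e > k || e >= BIG) continue;
          // count read bases matched against reference N (wildcard matches)
          int nwild = 0;
          {
            int j = soff; size_t p2 = 0;
            while (p2 < cg.size()) {
              int num = 0;
              while (p2 < cg.size() && isdigit(cg[p2])) num = num * 10 + (cg[p2++] - '0');
              char op = cg[p2++];
              if (op == 'M') {
                for (int t = 0; t < num; ++t)
                  if (win[j + t] == 'N') ++nwild;
                j += num;
              } else if (op == 'D') j += num;
            }
          }
          int st = ws + soff;
          if (circular[g]) st = ((st % L) + L) % L;
          else if (st < 0) continue;
          int key = st * 2 + si;
          auto sit = seen.find(key);
          if (sit != seen.end()) {
            if (e < placements[g][sit->second].edit)
              placements[g][sit->second] = { g, st, si == 0 ? 1 : -1, e, gaps, nwild, cg };
          } else {
            seen[key] = (int)placements[g].size();
            placements[g].push_back({ g, st, si == 0 ? 1 : -1, e, gaps, nwild, cg });
          }
        }
      }
    }
    // emit every deduplicated placement; uniqueness tiers are computed in R
    for (int g = 0; g < NG; ++g) {
      for (auto &pl : placements[g]) {
        out_read.push_back(r + 1);
        out_genome.push_back(g + 1);
        out_start.push_back(pl.start);
        out_strand.push_back(pl.strand);
        out_edit.push_back(pl.edit);
        out_gaps.push_back(pl.gaps);
        out_wild.push_back(pl.n_wild);
        out_cigar.push_back(pl.cigar);
      }
    }
  }

  DataFrame hits = DataFrame::create(
      _["read"] = out_read, _["genome"] = out_genome, _["start"] = out_start,
      _["strand"] = out_strand, _["edit"] = out_edit, _["gap_opens"] = out_gaps,
      _["n_wild"] = out_wild, _["cigar"] = out_cigar,
      _["stringsAsFactors"] = false);
  return List::create(_["hits"] = hits);
}

// Pileup of oriented reads on one reference of length L.  Counts A,C,G,T,-
// per column plus damage-qualifying observation tallies:
//   dmgA = 'A' from forward reads within `window` of the read's 3' end
//   dmgT = 'T' from reverse reads within `window` of the (original) 3' end
// [[Rcpp::export]]
List cpp_pileup(CharacterVector oriented, IntegerVector starts,
                IntegerVector strands, CharacterVector cigars, int L,
                int window, bool circular) {
  IntegerMatrix counts(5, L); // rows A,C,G,T,-
  IntegerVector dmgA(L), dmgT(L);
  int n = oriented.size();
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(oriented[i]);
    std::string cg = as<std::string>(cigars[i]);
    int pos = starts[i];
    int rp = 0;
    int l = (int)seq.size();
    size_t p = 0;
    while (p < cg.size()) {
      int num = 0;
      while (p < cg.size() && isdigit(cg[p])) num = num * 10 + (cg[p++] - '0');
      char op = cg[p++];
      if (op == 'M') {
        for (int t = 0; t < num; ++t) {
          int col = pos + t;
          if (circular) col %= L;
          if (col < 0 || col >= L) { continue; }
          int c = base_code(seq[rp + t]);
          if (c >= 0) {
            counts(c, col)++;
            int d3 = (strands[i] == 1) ? (l - 1 - (rp + t)) : (rp + t);
            if (d3 < window) {
              if (strands[i] == 1 && c == 0) dmgA[col]++;
              if (strands[i] == -1 && c == 3) dmgT[col]++;
            }
          }
        }
        pos += num; rp += num;
      } else if (op == 'I') {
        rp += num;
      } else if (op == 'D') {
        for (int t = 0; t < num; ++t) {
          int col = pos + t;
          if (circular) col %= L;
          if (col >= 0 && col < L) counts(4, col)++;
        }
        pos += num;
      }
    }
  }
  return List::create(_["counts"] = counts, _["dmgA"] = dmgA, _["dmgT"] = dmgT);
}

// Substitution counts stratified by distance from the read's own 5'/3' ends,
// in read-strand space, against a consensus (N columns excluded).
// Returns 4x4x25 mismatch arrays and 4x25 opportunity arrays per end.
// [[Rcpp::export]]
List cpp_damage_counts(CharacterVector oriented, IntegerVector starts,
                       IntegerVector strands, CharacterVector cigars,
                       std::string consensus, bool circular, int maxd) {
  int L = (int)consensus.size();
  IntegerVector m5(4 * 4 * maxd), m3(4 * 4 * maxd);
  IntegerVector o5(4 * 4 * maxd), o3(4 * 4 * maxd); // opportunities repeated per 'to' for shape; use [from, 0, d]
  IntegerVector op5(4 * maxd), op3(4 * maxd);
  long n_aligned = 0, n_mis = 0;
  int n = oriented.size();
  for (int i = 0; i < n; ++i) {
    std::string seq = as<std::string>(oriented[i]);
    std::string cg = as<std::string>(cigars[i]);
    int pos = starts[i], rp = 0, l = (int)seq.size();
    size_t p = 0;
    while (p < cg.size()) {
      int num = 0;
      while (p < cg.size() && isdigit(cg[p])) num = num * 10 + (cg[p++] - '0');
      char op = cg[p++];
      if (op == 'M') {
        for (int t = 0; t < num; ++t) {
          int col = pos + t;
          if (circular) col %= L;
          if (col < 0 || col >= L) continue;
          char cb = consensus[col];
          if (cb == 'N') continue;
          char rb = seq[rp + t];
          // map to read-strand space
          char from = cb, to = rb;
          int read_pos; // position on the original read, 5'->3'
          if (strands[i] == 1) read_pos = rp + t;
          else { from = comp_base(cb); to = comp_base(rb); read_pos = l - 1 - (rp + t); }
          int fi = base_code(from), ti = base_code(to);
          if (fi < 0 || ti < 0) continue;
          ++n_aligned;
          if (fi != ti) ++n_mis;
          int d5 = read_pos, d3 = l - 1 - read_pos;
          if (d5 < maxd) {
            op5[fi * maxd + d5]++;
            if (fi != ti) m5[(fi * 4 + ti) * maxd + d5]++;
          }
          if (d3 < maxd) {
            op3[fi * maxd + d3]++;
            if (fi != ti) m3[(fi * 4 + ti) * maxd + d3]++;
          }
        }
        pos += num; rp += num;
      } else if (op == 'I') rp += num;
      else if (op == 'D') pos += num;
    }
  }
  return List::create(_["m5"] = m5, _["m3"] = m3, _["op5"] = op5,
                      _["op3"] = op3, _["n_aligned"] = (double)n_aligned,
                      _["n_mismatch"] = (double)n_mis);
}

// Banded global alignment (unit-cost edit distance, unrestricted gaps) of two
// long homologous sequences; N is a wildcard.  Returns edit count and cigar
// (M/I/D with I = base present in `a` only, D = base present in `b` only).
// [[Rcpp::export]]
List cpp_banded_global(std::string a, std::string b, int band) {
  int n = (int)a.size(), m = (int)b.size();
  if (std::abs(n - m) > band)
    stop("length difference %d exceeds band %d; increase the band", std::abs(n - m), band);
  int W = 2 * band + 1;
  std::vector<int> prev(W, BIG), cur(W, BIG);
  std::vector<uint8_t> bp((size_t)(n + 1) * W, 255);
  // j = i + d - band, d in [0, W)
  auto inb = [&](int i, int d) { int j = i + d - band; return j >= 0 && j <= m; };
  for (int d = 0; d < W; ++d) {
    int j = 0 + d - band;
    if (j >= 0 && j <= m) { prev[d] = j; bp[d] = (j == 0) ? 254 : 2; } // leading D's
  }
  for (int i = 1; i <= n; ++i) {
    std::fill(cur.begin(), cur.end(), BIG);
    char ac = a[i - 1];
    for (int d = 0; d < W; ++d) {
      int j = i + d - band;
      if (j < 0 || j > m) continue;
      int best = BIG; uint8_t op = 255;
      if (j > 0) { // M: (i-1, j-1) -> prev row same d
        int v = prev[d];
        if (v < BIG) {
          char bc = b[j - 1];
          int sub = (ac == 'N' || bc == 'N') ? 0 : (ac == bc ? 0 : 1);
          if (v + sub < best) { best = v + sub; op = 0; }
        }
      }
      // I: consume a only: (i-1, j) -> prev row d+1
      if (d + 1 < W && prev[d + 1] < BIG && prev[d + 1] + 1 < best) {
        best = prev[d + 1] + 1; op = 1;
      }
      // D: consume b only: (i, j-1) -> cur row d-1
      if (d - 1 >= 0 && cur[d - 1] < BIG && cur[d - 1] + 1 < best) {
        best = cur[d - 1] + 1; op = 2;
      }
      cur[d] = best;
      bp[(size_t)i * W + d] = op;
    }
    std::swap(prev, cur);
  }
  int dfin = m - n + band;
  if (dfin < 0 || dfin >= W || prev[dfin] >= BIG)
    stop("alignment exceeded the band; increase the band");
  int edit = prev[dfin];
  // traceback
  std::vector<char> ops;
  int i = n, d = dfin;
  while (true) {
    uint8_t op = bp[(size_t)i * W + d];
    if (op == 254) break;
    if (op == 0) { ops.push_back('M'); i -= 1; }
    else if (op == 1) { ops.push_back('I'); i -= 1; d += 1; }
    else if (op == 2) { ops.push_back('D'); d -= 1; }
    else break;
    if (i == 0 && i + d - band == 0) break;
  }
  std::reverse(ops.begin(), ops.end());
  std::string cg; size_t p = 0;
  while (p < ops.size()) {
    size_t q = p;
    while (q < ops.size() && ops[q] == ops[p]) ++q;
    cg += std::to_string(q - p); cg += ops[p];
    p = q;
  }
  return List::create(_["edit"] = edit, _["cigar"] = cg);
}

// [[Rcpp::export]]
CharacterVector cpp_revcomp(CharacterVector x) {
  CharacterVector out(x.size());
  for (R_xlen_t i = 0; i < x.size(); ++i)
    out[i] = revcomp(as<std::string>(x[i]));
  return out;
}
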