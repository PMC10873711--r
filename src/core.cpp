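// Core sequence machinery: canonical k-mer index, seed-and-extend short-read
// mapper with banded edit-distance alignment, paired-end read simulator,
// pileup engine, and k-mer set operations (ancestry painting, divergence,
// homology anchors). Coordinates are 0-based half-open throughout.
#include <Rcpp.h>
#include <unordered_map>
#include <unordered_set>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>
using namespace Rcpp;

static inline int base2int(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}
static const char INT2BASE[4] = {'A', 'C', 'G', 'T'};

static inline char compbase(char c) {
  switch (c) {
  case 'A': case 'a': return 'T';
  case 'C': case 'c': return 'G';
  case 'G': case 'g': return 'C';
  case 'T': case 't': return 'A';
  default: return 'N';
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) c = compbase(c);
  return r;
}

// [[Rcpp::export]]
std::string cpp_revcomp(std::string s) { return revcomp_str(s); }

// ---------------------------------------------------------------------------
// k-mer keys. k <= 31 uses exact 2-bit packing (collision free); larger k uses
// a strand-symmetric polynomial rolling hash (odd multiplier, invertible mod
// 2^64). The canonical key is min(forward, reverse-complement).
// ---------------------------------------------------------------------------
static const uint64_t POLY_B = 0x100000001b3ULL; // odd => invertible mod 2^64

static uint64_t inv64(uint64_t a) {
  uint64_t x = a; // Newton iteration, a odd
  for (int i = 0; i < 6; ++i) x *= 2 - a * x;
  return x;
}

// hash path for k > 31 (separate, with explicit window buffer)
template <typename F>
static void scan_kmers_hash(const std::string& seq, int k, F&& cb) {
  const long L = (long)seq.size();
  if (L < k) return;
  static const uint64_t Binv = inv64(POLY_B);
  uint64_t Bk1 = 1;
  for (int i = 0; i < k - 1; ++i) Bk1 *= POLY_B;
  std::vector<uint8_t> win;
  win.reserve(L > 0 ? (size_t)L : 0);
  // precompute codes, mark ambiguity
  std::vector<int8_t> code(L);
  for (long i = 0; i < L; ++i) code[i] = (int8_t)base2int(seq[i]);
  long i = 0;
  while (i < L) {
    // find next run of >= k unambiguous bases
    while (i < L && code[i] < 0) ++i;
    long j = i;
    while (j < L && code[j] >= 0) ++j;
    if (j - i >= k) {
      uint64_t fh = 0, rh = 0, Bpow = 1;
      for (long t = i; t < i + k; ++t) {
        fh = fh * POLY_B + (uint64_t)(code[t] + 1);
        rh += (uint64_t)(4 - code[t]) * Bpow; // comp codes, reversed order
        Bpow *= POLY_B;
      }
      long pos = i;
      while (true) {
        if (fh <= rh) cb(pos, fh, true); else cb(pos, rh, false);
        if (pos + k >= j) break;
        uint64_t out = (uint64_t)(code[pos] + 1);
        uint64_t in = (uint64_t)(code[pos + k] + 1);
        uint64_t cout = (uint64_t)(4 - code[pos]);
        uint64_t cin = (uint64_t)(4 - code[pos + k]);
        fh = (fh - out * Bk1) * POLY_B + in;
        rh = cin * Bk1 + (rh - cout) * Binv;
        ++pos;
      }
    }
    i = j;
  }
}

template <typename F>
static void scan_kmers_any(const std::string& seq, int k, F&& cb) {
  if (k <= 31) {
    const long L = (long)seq.size();
    if (L < k) return;
    const uint64_t mask = (2 * k == 64) ? ~0ULL : ((1ULL << (2 * k)) - 1);
    uint64_t fwd = 0, rc = 0;
    int run = 0;
    for (long i = 0; i < L; ++i) {
      int b = base2int(seq[i]);
      if (b < 0) { run = 0; fwd = 0; rc = 0; continue; }
      fwd = ((fwd << 2) | (uint64_t)b) & mask;
      rc = (rc >> 2) | ((uint64_t)(3 - b) << (2 * (k - 1)));
      if (++run >= k) {
        long pos = i - k + 1;
        if (fwd <= rc) cb(pos, fwd, true); else cb(pos, rc, false);
      }
    }
  } else {
    scan_kmers_hash(seq, k, cb);
  }
}

// key of a single k-mer string; returns false if ambiguous/short
static bool kmer_key(const std::string& s, int k, uint64_t& key, bool& fwd_canon) {
  if ((int)s.size() != k) return false;
  bool got = false;
  scan_kmers_any(s, k, [&](long, uint64_t kk, bool f) { key = kk; fwd_canon = f; got = true; });
  return got;
}

// ---------------------------------------------------------------------------
// k-mer index
// ---------------------------------------------------------------------------
struct KIndex {
  int k;
  std::vector<std::string> names;
  std::vector<std::string> seqs;
  // value: contig << 40 | pos << 1 | fwd_is_canon
  std::unordered_map<uint64_t, std::vector<uint64_t>> tab;
  size_t npos = 0;
};

// [[Rcpp::export]]
SEXP cpp_build_index(CharacterVector names, CharacterVector seqs, int k) {
  XPtr<KIndex> xp(new KIndex(), true);
  xp->k = k;
  for (int c = 0; c < seqs.size(); ++c) {
    xp->names.push_back(as<std::string>(names[c]));
    xp->seqs.push_back(as<std::string>(seqs[c]));
  }
  for (size_t c = 0; c < xp->seqs.size(); ++c) {
    scan_kmers_any(xp->seqs[c], k, [&](long pos, uint64_t key, bool f) {
      xp->tab[key].push_back(((uint64_t)c << 40) | ((uint64_t)pos << 1) | (f ? 1ULL : 0ULL));
      ++xp->npos;
    });
  }
  return xp;
}

// [[Rcpp::export]]
List cpp_index_info(SEXP xps) {
  XPtr<KIndex> xp(xps);
  size_t nuniq = 0;
  for (auto& kv : xp->tab) if (kv.second.size() == 1) ++nuniq;
  return List::create(_["k"] = xp->k,
                      _["n_contigs"] = (int)xp->seqs.size(),
                      _["n_distinct"] = (double)xp->tab.size(),
                      _["n_unique"] = (double)nuniq,
                      _["n_positions"] = (double)xp->npos);
}

// [[Rcpp::export]]
List cpp_index_lookup(SEXP xps, CharacterVector kmers) {
  XPtr<KIndex> xp(xps);
  List out(kmers.size());
  for (int i = 0; i < kmers.size(); ++i) {
    std::string s = as<std::string>(kmers[i]);
    uint64_t key; bool f;
    std::vector<int> ctg; std::vector<double> pos; std::vector<int> strand;
    if (kmer_key(s, xp->k, key, f)) {
      auto it = xp->tab.find(key);
      if (it != xp->tab.end()) {
        for (uint64_t v : it->second) {
          int c = (int)(v >> 40);
          long p = (long)((v >> 1) & ((1ULL << 39) - 1));
          bool ref_f = v & 1ULL;
          ctg.push_back(c + 1);
          pos.push_back((double)p);
          // strand of the query k-mer relative to the reference occurrence
          strand.push_back((ref_f == f) ? 0 : 1);
        }
      }
    }
    out[i] = DataFrame::create(_["contig"] = ctg, _["pos"] = pos, _["strand"] = strand);
  }
  return out;
}

// ---------------------------------------------------------------------------
// alignment: fast Hamming path, then semi-global DP (unit costs) in a window
// ---------------------------------------------------------------------------
struct Plc {
  int contig; long pos; int strand; int nm; std::string cigar;
};

struct AlnOut { bool ok; long pos; int nm; std::string cigar; };

static AlnOut align_window(const std::string& ref, const std::string& read,
                           long guess, int band, int max_nm) {
  AlnOut res; res.ok = false;
  const long L = (long)ref.size();
  const int m = (int)read.size();
  // fast path: ungapped at the guessed diagonal. Mismatch-only alignments up
  // to 5 edits are accepted directly; a gapped alignment could only beat
  // them for an InDel within ~5 bp of a read end, and InDel-bearing reads
  // otherwise produce large Hamming distances and fall through to the DP.
  if (guess >= 0 && guess + m <= L) {
    int hd = 0;
    for (int i = 0; i < m && hd <= band; ++i)
      if (ref[(size_t)(guess + i)] != read[(size_t)i]) ++hd;
    if (hd <= 5) {
      if (hd > max_nm) return res;
      res.ok = true; res.pos = guess; res.nm = hd;
      res.cigar = std::to_string(m) + "M";
      return res;
    }
  }
  long w0 = guess - band; if (w0 < 0) w0 = 0;
  long w1 = guess + m + band; if (w1 > L) w1 = L;
  const int n = (int)(w1 - w0);
  if (n <= 0) return res;
  // DP (m+1) x (n+1); free leading/trailing gaps on the reference side
  std::vector<uint16_t> D((size_t)(m + 1) * (n + 1));
  auto at = [&](int i, int j) -> uint16_t& { return D[(size_t)i * (n + 1) + j]; };
  for (int j = 0; j <= n; ++j) at(0, j) = 0;
  for (int i = 1; i <= m; ++i) at(i, 0) = (uint16_t)i;
  for (int i = 1; i <= m; ++i) {
    char rb = read[(size_t)(i - 1)];
    for (int j = 1; j <= n; ++j) {
      uint16_t d = (uint16_t)(at(i - 1, j - 1) + (ref[(size_t)(w0 + j - 1)] == rb ? 0 : 1));
      uint16_t u = (uint16_t)(at(i - 1, j) + 1);
      uint16_t l = (uint16_t)(at(i, j - 1) + 1);
      uint16_t best = d < u ? d : u;
      if (l < best) best = l;
      at(i, j) = best;
    }
  }
  int jbest = 0; uint16_t vbest = 65535;
  for (int j = 0; j <= n; ++j)
    if (at(m, j) < vbest) { vbest = at(m, j); jbest = j; }
  if ((int)vbest > max_nm) return res;
  // traceback; on cost ties prefer continuing the current gap op so that a
  // single InDel is not split into cost-equal adjacent gaps
  std::vector<std::pair<char,int>> ops; // reversed
  int i = m, j = jbest;
  char cur = 'M';
  while (i > 0) {
    bool can_d = j > 0 &&
      at(i, j) == at(i - 1, j - 1) + (ref[(size_t)(w0 + j - 1)] == read[(size_t)(i - 1)] ? 0 : 1);
    bool can_i = at(i, j) == at(i - 1, j) + 1;
    bool can_del = j > 0 && at(i, j) == at(i, j - 1) + 1;
    char step;
    if (cur == 'I' && can_i) step = 'I';
    else if (cur == 'D' && can_del) step = 'D';
    else if (can_d) step = 'M';
    else if (can_i) step = 'I';
    else step = 'D';
    if (step == 'M') {
      if (!ops.empty() && ops.back().first == 'M') ops.back().second++;
      else ops.push_back({'M', 1});
      --i; --j;
    } else if (step == 'I') {
      if (!ops.empty() && ops.back().first == 'I') ops.back().second++;
      else ops.push_back({'I', 1});
      --i;
    } else {
      if (!ops.empty() && ops.back().first == 'D') ops.back().second++;
      else ops.push_back({'D', 1});
      --j;
    }
    cur = step;
  }
  res.ok = true; res.pos = w0 + j; res.nm = (int)vbest;
  std::string cg;
  for (auto it = ops.rbegin(); it != ops.rend(); ++it)
    cg += std::to_string(it->second) + it->first;
  res.cigar = cg;
  return res;
}

static void gather_candidates(const KIndex& idx, const std::string& read,
                              int band, int max_nm, size_t max_occ,
                              std::vector<Plc>& out) {
  out.clear();
  const int k = idx.k;
  const int m = (int)read.size();
  if (m < k) return;
  // k-mer keys along the read
  std::vector<long> koff; std::vector<uint64_t> kkey; std::vector<char> kf;
  scan_kmers_any(read, k, [&](long pos, uint64_t key, bool f) {
    koff.push_back(pos); kkey.push_back(key); kf.push_back(f ? 1 : 0);
  });
  if (koff.empty()) return;
  int stride = std::max(10, (m - k) / 6);
  // vote per (contig, strand, banded diagonal); keep first-seen diagonal as
  // the alignment guess for the bucket
  std::unordered_map<uint64_t, std::pair<int,long>> cand; // key -> (votes, diag)
  for (size_t s = 0; s < koff.size(); s += (size_t)stride) {
    size_t si = s;
    auto it = idx.tab.find(kkey[si]);
    if (it == idx.tab.end() || it->second.size() > max_occ) continue;
    for (uint64_t v : it->second) {
      int c = (int)(v >> 40);
      long p = (long)((v >> 1) & ((1ULL << 39) - 1));
      bool ref_f = v & 1ULL;
      bool same = (ref_f == (kf[si] != 0));
      long diag; int strand;
      if (same) { strand = 0; diag = p - koff[si]; }
      else { strand = 1; diag = p - (m - k - koff[si]); }
      long bucket = (diag + 1000000000L) / (band > 0 ? band : 1);
      uint64_t kk = ((uint64_t)c << 44) | ((uint64_t)strand << 43) | (uint64_t)bucket;
      auto ct = cand.find(kk);
      if (ct == cand.end()) cand[kk] = {1, diag};
      else ct->second.first++;
    }
  }
  if (cand.empty()) return;
  std::vector<std::tuple<int,int,int,long>> ordered; // -votes, contig, strand, diag
  for (auto& kv : cand) {
    int c = (int)(kv.first >> 44);
    int strand = (int)((kv.first >> 43) & 1);
    ordered.push_back({-kv.second.first, c, strand, kv.second.second});
  }
  std::sort(ordered.begin(), ordered.end());
  const size_t max_cand = 24;
  std::unordered_set<uint64_t> seen;
  std::string rc;
  for (size_t t = 0; t < ordered.size() && t < max_cand; ++t) {
    int c = std::get<1>(ordered[t]);
    int strand = std::get<2>(ordered[t]);
    long diag = std::get<3>(ordered[t]);
    const std::string& oriented = strand ? (rc.empty() ? (rc = revcomp_str(read)) : rc) : read;
    AlnOut a = align_window(idx.seqs[(size_t)c], oriented, diag, band, max_nm);
    if (!a.ok) continue;
    uint64_t id = ((uint64_t)c << 42) | ((uint64_t)a.pos << 1) | (uint64_t)strand;
    if (seen.count(id)) continue;
    seen.insert(id);
    out.push_back({c, a.pos, strand, a.nm, a.cigar});
  }
  std::sort(out.begin(), out.end(), [](const Plc& a, const Plc& b) {
    if (a.nm != b.nm) return a.nm < b.nm;
    if (a.contig != b.contig) return a.contig < b.contig;
    if (a.pos != b.pos) return a.pos < b.pos;
    return a.strand < b.strand;
  });
}

static inline long read_ref_span(const Plc& p, int m) {
  // reference span length from CIGAR
  long span = 0, num = 0;
  for (char ch : p.cigar) {
    if (ch >= '0' && ch <= '9') num = num * 10 + (ch - '0');
    else { if (ch == 'M' || ch == 'D') span += num; num = 0; }
  }
  (void)m;
  return span;
}

// [[Rcpp::export]]
DataFrame cpp_map_pairs(SEXP xps, CharacterVector reads1, CharacterVector reads2,
                        int band, int max_nm, double ins_mu, double ins_sd,
                        int max_tie_report, int max_occ) {
  XPtr<KIndex> xp(xps);
  const int n = reads1.size();
  const bool paired = reads2.size() == n && n > 0 && !CharacterVector::is_na(reads2[0]);
  int total = paired ? 2 * n : n;
  IntegerVector o_read(total), o_mate(total), o_contig(total), o_pos(total),
    o_strand(total), o_nm(total), o_mapq(total), o_nties(total);
  CharacterVector o_cigar(total), o_alts(total);
  std::vector<Plc> c1, c2;
  double span_hi = ins_mu + 6.0 * ins_sd;

  auto fill = [&](int row, int ridx, int mate, const Plc* p, int nties, int mapq,
                  const std::string& alts) {
    o_read[row] = ridx + 1; o_mate[row] = mate;
    if (p) {
      o_contig[row] = p->contig + 1; o_pos[row] = (int)p->pos;
      o_strand[row] = p->strand; o_nm[row] = p->nm;
      o_cigar[row] = p->cigar; o_mapq[row] = mapq; o_nties[row] = nties;
      o_alts[row] = alts;
    } else {
      o_contig[row] = NA_INTEGER; o_pos[row] = NA_INTEGER; o_strand[row] = NA_INTEGER;
      o_nm[row] = NA_INTEGER; o_cigar[row] = NA_STRING; o_mapq[row] = 0;
      o_nties[row] = 0; o_alts[row] = NA_STRING;
    }
  };

  auto tie_info = [&](const std::vector<Plc>& cc, size_t chosen, int& nties, std::string& alts, int& gap) {
    nties = 0; alts.clear(); gap = 1000;
    if (cc.empty()) return;
    int best = cc[0].nm;
    int second = 1000;
    for (size_t t = 0; t < cc.size(); ++t) {
      if (cc[t].nm == best) ++nties;
      else { second = std::min(second, cc[t].nm); }
      if (cc[t].nm == best && t != chosen && (int)alts.size() < 400 &&
          nties <= max_tie_report + 1) {
        if (!alts.empty()) alts += ";";
        alts += xp->names[(size_t)cc[t].contig] + ":" + std::to_string(cc[t].pos) +
                ":" + (cc[t].strand ? "-" : "+");
      }
    }
    gap = (nties > 1) ? 0 : (second >= 1000 ? 1000 : second - best);
  };

  for (int i = 0; i < n; ++i) {
    std::string r1 = as<std::string>(reads1[i]);
    gather_candidates(*xp, r1, band, max_nm, (size_t)max_occ, c1);
    if (!paired) {
      if (c1.empty()) { fill(i, i, 1, nullptr, 0, 0, ""); continue; }
      int nt, gp; std::string al; tie_info(c1, 0, nt, al, gp);
      int mq = nt > 1 ? 0 : (gp >= 2 ? 60 : 30);
      fill(i, i, 1, &c1[0], nt, mq, al);
      continue;
    }
    std::string r2 = as<std::string>(reads2[i]);
    gather_candidates(*xp, r2, band, max_nm, (size_t)max_occ, c2);
    int m1 = (int)r1.size(), m2 = (int)r2.size();
    size_t pick1 = 0, pick2 = 0;
    bool have1 = !c1.empty(), have2 = !c2.empty();
    int n_best_combo = 0;
    bool picked_proper = false;
    if (have1 && have2) {
      long bestcost = 1L << 40;
      size_t lim1 = std::min<size_t>(c1.size(), 32), lim2 = std::min<size_t>(c2.size(), 32);
      for (size_t a = 0; a < lim1; ++a) for (size_t b = 0; b < lim2; ++b) {
        bool proper = false;
        if (c1[a].contig == c2[b].contig && c1[a].strand != c2[b].strand) {
          long s1 = c1[a].pos, e1 = c1[a].pos + read_ref_span(c1[a], m1);
          long s2 = c2[b].pos, e2 = c2[b].pos + read_ref_span(c2[b], m2);
          long lo = std::min(s1, s2), hi = std::max(e1, e2);
          long fwd_start = c1[a].strand == 0 ? s1 : s2;
          long rev_start = c1[a].strand == 0 ? s2 : s1;
          if (hi - lo <= (long)span_hi && fwd_start <= rev_start) proper = true;
        }
        long cost = 2L * (c1[a].nm + c2[b].nm) - (proper ? 1 : 0);
        if (cost < bestcost) { bestcost = cost; pick1 = a; pick2 = b; n_best_combo = 1; picked_proper = proper; }
        else if (cost == bestcost) {
          ++n_best_combo;
          // lexicographic tie-break: candidates are pre-sorted, keep first
        }
      }
    } else if (have1) { pick1 = 0; }
    else if (have2) { pick2 = 0; }

    int row1 = 2 * i, row2 = 2 * i + 1;
    if (have1) {
      int nt, gp; std::string al; tie_info(c1, pick1, nt, al, gp);
      int mq;
      if (nt > 1) mq = (picked_proper && n_best_combo == 1) ? 20 : 0;
      else mq = gp >= 2 ? 60 : 30;
      fill(row1, i, 1, &c1[pick1], nt, mq, al);
    } else fill(row1, i, 1, nullptr, 0, 0, "");
    if (have2) {
      int nt, gp; std::string al; tie_info(c2, pick2, nt, al, gp);
      int mq;
      if (nt > 1) mq = (picked_proper && n_best_combo == 1) ? 20 : 0;
      else mq = gp >= 2 ? 60 : 30;
      fill(row2, i, 2, &c2[pick2], nt, mq, al);
    } else fill(row2, i, 2, nullptr, 0, 0, "");
  }
  return DataFrame::create(_["read"] = o_read, _["mate"] = o_mate,
                           _["contig"] = o_contig, _["pos"] = o_pos,
                           _["strand"] = o_strand, _["cigar"] = o_cigar,
                           _["nm"] = o_nm, _["mapq"] = o_mapq,
                           _["nties"] = o_nties, _["alts"] = o_alts,
                           _["stringsAsFactors"] = false);
}

// ---------------------------------------------------------------------------
// paired-end read simulator (uses R's RNG; deterministic under set.seed)
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_simulate_reads(std::string seq, int npairs, int read_len,
                        double ins_mu, double ins_sd, double error_rate) {
  const long L = (long)seq.size();
  CharacterVector m1(npairs), m2(npairs);
  IntegerVector pos1(npairs), pos2(npairs), strand1(npairs), strand2(npairs);
  RNGScope scope;
  for (int p = 0; p < npairs; ++p) {
    long ins = (long)std::lround(R::rnorm(ins_mu, ins_sd));
    if (ins < read_len) ins = read_len;
    if (ins > L) ins = L;
    long start = (long)std::floor(R::runif(0, 1) * (double)(L - ins + 1));
    if (start < 0) start = 0;
    if (start > L - ins) start = L - ins;
    std::string left = seq.substr((size_t)start, (size_t)read_len);
    std::string right = revcomp_str(seq.substr((size_t)(start + ins - read_len), (size_t)read_len));
    bool flip = R::runif(0, 1) < 0.5;
    std::string s1 = flip ? right : left;
    std::string s2 = flip ? left : right;
    // substitution errors
    for (std::string* s : {&s1, &s2}) {
      for (size_t t = 0; t < s->size(); ++t) {
        if (R::runif(0, 1) < error_rate) {
          int b = base2int((*s)[t]);
          if (b < 0) continue;
          int nb = (b + 1 + (int)std::floor(R::runif(0, 1) * 3.0)) & 3;
          if (nb == b) nb = (b + 1) & 3;
          (*s)[t] = INT2BASE[nb];
        }
      }
    }
    m1[p] = s1; m2[p] = s2;
    if (!flip) {
      pos1[p] = (int)start; strand1[p] = 0;
      pos2[p] = (int)(start + ins - read_len); strand2[p] = 1;
    } else {
      pos1[p] = (int)(start + ins - read_len); strand1[p] = 1;
      pos2[p] = (int)start; strand2[p] = 0;
    }
  }
  return List::create(_["seq1"] = m1, _["seq2"] = m2, _["pos1"] = pos1,
                      _["strand1"] = strand1, _["pos2"] = pos2, _["strand2"] = strand2);
}

// ---------------------------------------------------------------------------
// pileup
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_pileup(CharacterVector ref_names, CharacterVector ref_seqs,
                IntegerVector contig, IntegerVector pos, IntegerVector strand,
                CharacterVector cigar, IntegerVector mapq, CharacterVector reads,
                int min_mapq) {
  const int nc = ref_seqs.size();
  std::vector<long> clen(nc);
  for (int c = 0; c < nc; ++c) clen[c] = (long)std::string(ref_seqs[c]).size();
  List counts(nc), lowq(nc);
  std::vector<int*> cptr(nc);
  std::vector<int*> lptr(nc);
  for (int c = 0; c < nc; ++c) {
    IntegerMatrix mat(4, (int)clen[c]);
    counts[c] = mat;
    cptr[c] = INTEGER(mat);
    IntegerVector lv((int)clen[c]);
    lowq[c] = lv;
    lptr[c] = INTEGER(lv);
  }
  std::unordered_map<uint64_t, std::unordered_map<std::string, int>> insmap; // contig<<40|pos
  std::unordered_map<uint64_t, int> delmap; // contig<<44 | pos<<8 | len
  const int n = contig.size();
  for (int i = 0; i < n; ++i) {
    if (contig[i] == NA_INTEGER) continue;
    int c = contig[i] - 1;
    long rp = pos[i];
    std::string rd = as<std::string>(reads[i]);
    if (strand[i] == 1) rd = revcomp_str(rd);
    bool low = mapq[i] < min_mapq;
    std::string cg = as<std::string>(cigar[i]);
    long num = 0; size_t ri = 0;
    for (char ch : cg) {
      if (ch >= '0' && ch <= '9') { num = num * 10 + (ch - '0'); continue; }
      if (ch == 'M') {
        for (long t = 0; t < num; ++t) {
          if (rp >= 0 && rp < clen[c]) {
            if (low) lptr[c][rp]++;
            else {
              int b = base2int(rd[ri]);
              if (b >= 0) cptr[c][4 * rp + b]++;
            }
          }
          ++rp; ++ri;
        }
      } else if (ch == 'I') {
        if (!low && rp > 0 && rp <= clen[c]) {
          uint64_t key = ((uint64_t)c << 40) | (uint64_t)(rp - 1);
          insmap[key][rd.substr(ri, (size_t)num)]++;
        }
        ri += (size_t)num;
      } else if (ch == 'D') {
        if (!low && rp > 0 && num < 250) {
          uint64_t key = ((uint64_t)c << 44) | ((uint64_t)(rp - 1) << 8) | (uint64_t)num;
          delmap[key]++;
        }
        rp += num;
      }
      num = 0;
    }
  }
  // flatten indel maps
  std::vector<int> ic, dc; std::vector<double> ip, dp; std::vector<std::string> iseq;
  std::vector<int> dlen, icount, dcount;
  for (auto& kv : insmap) {
    int c = (int)(kv.first >> 40);
    double p = (double)(kv.first & ((1ULL << 40) - 1));
    for (auto& sv : kv.second) {
      ic.push_back(c + 1);
      ip.push_back(p);
      iseq.push_back(sv.first);
      icount.push_back(sv.second);
    }
  }
  for (auto& kv : delmap) {
    dc.push_back((int)(kv.first >> 44) + 1);
    dp.push_back((double)((kv.first >> 8) & ((1ULL << 36) - 1)));
    dlen.push_back((int)(kv.first & 255));
    dcount.push_back(kv.second);
  }
  return List::create(
    _["counts"] = counts, _["lowq"] = lowq,
    _["ins"] = DataFrame::create(_["contig"] = ic, _["pos"] = ip, _["seq"] = iseq,
                                 _["count"] = icount, _["stringsAsFactors"] = false),
    _["del"] = DataFrame::create(_["contig"] = dc, _["pos"] = dp, _["len"] = dlen,
                                 _["count"] = dcount));
}

// ---------------------------------------------------------------------------
// k-mer sets: build, difference, membership painting, divergence, anchors
// ---------------------------------------------------------------------------
typedef std::unordered_set<uint64_t> KSet;

// [[Rcpp::export]]
SEXP cpp_kmerset_build(CharacterVector seqs, int k) {
  XPtr<KSet> xp(new KSet(), true);
  for (int i = 0; i < seqs.size(); ++i) {
    std::string s = as<std::string>(seqs[i]);
    scan_kmers_any(s, k, [&](long, uint64_t key, bool) { xp->insert(key); });
  }
  return xp;
}

// [[Rcpp::export]]
SEXP cpp_kmerset_diff(SEXP xa, SEXP xb) {
  XPtr<KSet> A(xa), B(xb);
  XPtr<KSet> out(new KSet(), true);
  for (uint64_t v : *A) if (!B->count(v)) out->insert(v);
  return out;
}

// [[Rcpp::export]]
double cpp_kmerset_size(SEXP xs) { XPtr<KSet> x(xs); return (double)x->size(); }

// divergence: per contig of X, among k-mers occurring exactly once in that
// contig, the fraction absent from Y (all contigs)
// [[Rcpp::export]]
DataFrame cpp_kmer_divergence(CharacterVector namesX, CharacterVector seqsX,
                              CharacterVector seqsY, int k) {
  KSet Y;
  for (int i = 0; i < seqsY.size(); ++i) {
    std::string s = as<std::string>(seqsY[i]);
    scan_kmers_any(s, k, [&](long, uint64_t key, bool) { Y.insert(key); });
  }
  const int n = seqsX.size();
  NumericVector nuniq(n), nmiss(n), ratio(n);
  for (int i = 0; i < n; ++i) {
    std::unordered_map<uint64_t, int> cnt;
    std::string s = as<std::string>(seqsX[i]);
    scan_kmers_any(s, k, [&](long, uint64_t key, bool) { cnt[key]++; });
    double u = 0, m = 0;
    for (auto& kv : cnt) if (kv.second == 1) {
      ++u;
      if (!Y.count(kv.first)) ++m;
    }
    nuniq[i] = u; nmiss[i] = m;
    ratio[i] = u > 0 ? m / u : NA_REAL;
  }
  return DataFrame::create(_["contig"] = namesX, _["n_unique"] = nuniq,
                           _["n_absent"] = nmiss, _["ratio"] = ratio,
                           _["stringsAsFactors"] = false);
}

// window painting against two donor-specific k-mer sets
// [[Rcpp::export]]
DataFrame cpp_paint_windows(std::string seq, int k, int window, SEXP xp_p, SEXP xp_m) {
  XPtr<KSet> P(xp_p), M(xp_m);
  long L = (long)seq.size();
  int nwin = (int)((L + window - 1) / window);
  NumericVector start(nwin), end(nwin), fp(nwin), fm(nwin), fu(nwin), nk(nwin);
  std::vector<long> np(nwin, 0), nm(nwin, 0), nu(nwin, 0);
  scan_kmers_any(seq, k, [&](long pos, uint64_t key, bool) {
    int w = (int)(pos / window);
    if (P->count(key)) np[w]++;
    else if (M->count(key)) nm[w]++;
    else nu[w]++;
  });
  for (int w = 0; w < nwin; ++w) {
    start[w] = (double)w * window;
    end[w] = std::min<double>(L, (double)(w + 1) * window);
    double tot = (double)(np[w] + nm[w] + nu[w]);
    nk[w] = tot;
    if (tot > 0) { fp[w] = np[w] / tot; fm[w] = nm[w] / tot; fu[w] = nu[w] / tot; }
    else { fp[w] = NA_REAL; fm[w] = NA_REAL; fu[w] = NA_REAL; }
  }
  return DataFrame::create(_["start"] = start, _["end"] = end, _["frac_p"] = fp,
                           _["frac_m"] = fm, _["frac_unassigned"] = fu,
                           _["n_kmers"] = nk);
}

// shared mutually-unique k-mers between two sequences, same orientation only
// [[Rcpp::export]]
DataFrame cpp_homology_anchors(std::string seqA, std::string seqB, int k) {
  std::unordered_map<uint64_t, std::pair<long, int>> A, B; // pos, count; strand in sign
  std::unordered_map<uint64_t, bool> Af, Bf;
  scan_kmers_any(seqA, k, [&](long pos, uint64_t key, bool f) {
    auto it = A.find(key);
    if (it == A.end()) { A[key] = {pos, 1}; Af[key] = f; }
    else it->second.second++;
  });
  scan_kmers_any(seqB, k, [&](long pos, uint64_t key, bool f) {
    auto it = B.find(key);
    if (it == B.end()) { B[key] = {pos, 1}; Bf[key] = f; }
    else it->second.second++;
  });
  std::vector<double> pa, pb;
  for (auto& kv : A) {
    if (kv.second.second != 1) continue;
    auto it = B.find(kv.first);
    if (it == B.end() || it->second.second != 1) continue;
    if (Af[kv.first] != Bf[kv.first]) continue; // orientation flip: skip
    pa.push_back((double)kv.second.first);
    pb.push_back((double)it->second.first);
  }
  // sort by position in A
  std::vector<size_t> ord(pa.size());
  for (size_t i = 0; i < ord.size(); ++i) ord[i] = i;
  std::sort(ord.begin(), ord.end(), [&](size_t x, size_t y) { return pa[x] < pa[y]; });
  NumericVector oa(pa.size()), ob(pa.size());
  for (size_t i = 0; i < ord.size(); ++i) { oa[i] = pa[ord[i]]; ob[i] = pb[ord[i]]; }
  return DataFrame::create(_["posA"] = oa, _["posB"] = ob);
}
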