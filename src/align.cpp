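#include <Rcpp.h>
#include <unordered_map>
#include <cstdint>
using namespace Rcpp;

// Affine-gap Smith-Waterman over A/C/G/T/N. N never matches.
// Query (read) indexes rows, target (reference/allele) indexes columns.
// CIGAR ops: M consumes both, I consumes query only, D consumes target only.
// Traceback byte: bits 0-1 H-source (0 stop, 1 diag, 2 E/left, 3 F/up),
// bit 2 E opened from H, bit 3 F opened from H.

static inline bool base_match(char a, char b) {
  return a == b && a != 'N' && a != 'n';
}

// [[Rcpp::export(name = ".sw_align_cpp")]]
List sw_align_cpp(std::string query, std::string target,
                  int match = 2, int mismatch = 4,
                  int gap_open = 4, int gap_ext = 2) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("empty sequence");
  if ((double)(n + 1) * (double)(m + 1) > 2.5e8)
    stop("alignment matrix too large (%d x %d)", n, m);
  const int NEG = -1000000000;
  std::vector<int> Hprev(m + 1, 0), Hcur(m + 1, 0);
  std::vector<int> Eprev(m + 1, NEG), Ecur(m + 1, NEG);
  std::vector<int> Fcol(m + 1, NEG); // F for current row, per column
  std::vector<uint8_t> tb((size_t)(n + 1) * (m + 1), 0);
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    Hcur[0] = 0; Ecur[0] = NEG;
    for (int j = 1; j <= m; ++j) {
      uint8_t code = 0;
      // E: gap consuming target (D) arriving from the left
      int e_open = Hcur[j - 1] - gap_open;
      int e_ext  = Ecur[j - 1] - gap_ext;
      int e = e_open >= e_ext ? e_open : e_ext;
      if (e_open >= e_ext) code |= 4;
      Ecur[j] = e;
      // F: gap consuming query (I) arriving from above
      int f_open = Hprev[j] - gap_open;
      int f_ext  = Fcol[j] - gap_ext;
      int f = f_open >= f_ext ? f_open : f_ext;
      if (f_open >= f_ext) code |= 8;
      Fcol[j] = f;
      int diag = Hprev[j - 1] +
        (base_match(query[i - 1], target[j - 1]) ? match : -mismatch);
      int h = 0; uint8_t src = 0;
      if (diag > h) { h = diag; src = 1; }
      if (e > h)    { h = e;    src = 2; }
      if (f > h)    { h = f;    src = 3; }
      Hcur[j] = h;
      tb[(size_t)i * (m + 1) + j] = code | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
  }
  // traceback
  int i = bi, j = bj;
  int n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0;
  std::string ops; // reversed op-per-column string
  int state = 0;   // 0 = H, 1 = E, 2 = F
  while (i > 0 || j > 0) {
    uint8_t code = tb[(size_t)i * (m + 1) + j];
    if (state == 0) {
      uint8_t src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        if (base_match(query[i - 1], target[j - 1])) ++n_match; else ++n_mismatch;
        ops.push_back('M'); --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D'); ++n_del;
      bool open = (code & 4) != 0;
      --j;
      if (open) state = 0;
    } else {
      ops.push_back('I'); ++n_ins;
      bool open = (code & 8) != 0;
      --i;
      if (open) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  // run-length encode the cigar
  std::string cigar;
  for (size_t k = 0; k < ops.size();) {
    size_t k2 = k;
    while (k2 < ops.size() && ops[k2] == ops[k]) ++k2;
    cigar += std::to_string(k2 - k); cigar.push_back(ops[k]);
    k = k2;
  }
  return List::create(
    _["score"] = best,
    _["query_start"] = i, _["query_end"] = bi,     // 0-based half-open
    _["target_start"] = j, _["target_end"] = bj,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_ins"] = n_ins, _["n_del"] = n_del,
    _["cigar"] = cigar);
}

static inline int enc_base(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': return 3;
  default: return -1;
  }
}

// Shared k-mer counts between each query and each target (k <= 15).
// Counts, for every query k-mer occurrence, whether the k-mer occurs in the
// target; a cheap minimizer-free seeding proxy used to shortlist alignment
// candidates.
// [[Rcpp::export(name = ".kmer_share_cpp")]]
IntegerMatrix kmer_share_cpp(CharacterVector queries, CharacterVector targets,
                             int k = 13) {
  if (k < 3 || k > 15) stop("k must be in [3, 15]");
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  const int nq = queries.size(), nt = targets.size();
  std::unordered_map<uint64_t, std::vector<int> > index;
  for (int t = 0; t < nt; ++t) {
    std::string s = as<std::string>(targets[t]);
    uint64_t kmer = 0; int run = 0;
    std::unordered_map<uint64_t, bool> seen;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = enc_base(s[p]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        if (!seen.count(kmer)) { seen[kmer] = true; index[kmer].push_back(t); }
      }
    }
  }
  IntegerMatrix out(nq, nt);
  for (int q = 0; q < nq; ++q) {
    std::string s = as<std::string>(queries[q]);
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < s.size(); ++p) {
      int b = enc_base(s[p]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = index.find(kmer);
        if (it != index.end())
          for (int t : it->second) out(q, t) += 1;
      }
    }
  }
  return out;
}

// Pileup of aligned reads on a linear reference.
// Rows: A, C, G, T, other-base, deletion. Columns: reference positions.
// target_start / query_start are 0-based offsets of the alignment.
// [[Rcpp::export(name = ".cigar_pileup_cpp")]]
IntegerMatrix cigar_pileup_cpp(CharacterVector reads, CharacterVector cigars,
                               IntegerVector target_start,
                               IntegerVector query_start, int ref_len) {
  IntegerMatrix out(6, ref_len);
  const int n = reads.size();
  for (int r = 0; r < n; ++r) {
    std::string seq = as<std::string>(reads[r]);
    std::string cg = as<std::string>(cigars[r]);
    int tp = target_start[r], qp = query_start[r];
    size_t p = 0;
    while (p < cg.size()) {
      int len = 0;
      while (p < cg.size() && isdigit(cg[p])) { len = len * 10 + (cg[p] - '0'); ++p; }
      if (p >= cg.size()) break;
      char op = cg[p++];
      if (op == 'M' || op == '=' || op == 'X') {
        for (int x = 0; x < len; ++x) {
          if (tp >= 0 && tp < ref_len && qp >= 0 && qp < (int)seq.size()) {
            int b = enc_base(seq[qp]);
            out(b < 0 ? 4 : b, tp) += 1;
          }
          ++tp; ++qp;
        }
      } else if (op == 'I' || op == 'S') {
        qp += len;
      } else if (op == 'D' || op == 'N') {
        for (int x = 0; x < len; ++x) {
          if (tp >= 0 && tp < ref_len) out(5, tp) += 1;
          ++tp;
        }
      } else if (op == 'H' || op == 'P') {
        // consumes neither
      } else stop("unsupported cigar op '%c'", op);
    }
  }
  return out;
}

// Per-read base call at given reference positions (0-based); returns a
// character matrix reads x positions with "A/C/G/T", "-" for deletion and
// "" when the read does not cover the position. Used for read-backed phasing.
// [[Rcpp::export(name = ".read_bases_at_cpp")]]
CharacterMatrix read_bases_at_cpp(CharacterVector reads, CharacterVector cigars,
                                  IntegerVector target_start,
                                  IntegerVector query_start,
                                  IntegerVector positions) {
  const int n = reads.size(), np = positions.size();
  CharacterMatrix out(n, np);
  std::fill(out.begin(), out.end(), NA_STRING);
  for (int r = 0; r < n; ++r) {
    std::string seq = as<std::string>(reads[r]);
    std::string cg = as<std::string>(cigars[r]);
    int tp = target_start[r], qp = query_start[r];
    size_t p = 0;
    while (p < cg.size()) {
      int len = 0;
      while (p < cg.size() && isdigit(cg[p])) { len = len * 10 + (cg[p] - '0'); ++p; }
      if (p >= cg.size()) break;
      char op = cg[p++];
      if (op == 'M' || op == '=' || op == 'X') {
        for (int x = 0; x < len; ++x, ++tp, ++qp)
          for (int pi = 0; pi < np; ++pi)
            if (positions[pi] == tp && qp < (int)seq.size())
              out(r, pi) = std::string(1, (char)toupper(seq[qp]));
      } else if (op == 'I' || op == 'S') {
        qp += len;
      } else if (op == 'D' || op == 'N') {
        for (int x = 0; x < len; ++x, ++tp)
          for (int pi = 0; pi < np; ++pi)
            if (positions[pi] == tp) out(r, pi) = "-";
      }
    }
  }
  return out;
}

// [[Rcpp::export(name = ".revcomp_cpp")]]
CharacterVector revcomp_cpp(CharacterVector x) {
  CharacterVector out(x.size());
  for (int i = 0; i < x.size(); ++i) {
    std::string s = as<std::string>(x[i]);
    std::string r(s.rbegin(), s.rend());
    for (char &c : r) {
      switch (c) {
      case 'A': c = 'T'; break; case 'a': c = 't'; break;
      case 'C': c = 'G'; break; case 'c': c = 'g'; break;
      case 'G': c = 'C'; break; case 'g': c = 'c'; break;
      case 'T': c = 'A'; break; case 't': c = 'a'; break;
      default: break;
      }
    }
    out[i] = r;
  }
  return out;
}

// Most-supported alignment diagonal (target_pos - query_pos) from shared
// k-mers, plus the number of supporting k-mer hits. Diagonals are binned
// (width 16) to tolerate indel drift.
// [[Rcpp::export(name = ".kmer_diag_cpp")]]
IntegerVector kmer_diag_cpp(std::string query, std::string target, int k = 13) {
  const uint64_t mask = (1ULL << (2 * k)) - 1;
  std::unordered_map<uint64_t, std::vector<int> > tpos;
  {
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < target.size(); ++p) {
      int b = enc_base(target[p]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto &v = tpos[kmer];
        if (v.size() < 8) v.push_back((int)p - k + 1);
      }
    }
  }
  std::unordered_map<int, int> votes;
  int total = 0;
  {
    uint64_t kmer = 0; int run = 0;
    for (size_t p = 0; p < query.size(); ++p) {
      int b = enc_base(query[p]);
      if (b < 0) { run = 0; kmer = 0; continue; }
      kmer = ((kmer << 2) | (uint64_t)b) & mask;
      if (++run >= k) {
        auto it = tpos.find(kmer);
        if (it == tpos.end()) continue;
        ++total;
        int qp = (int)p - k + 1;
        for (int tp : it->second) votes[((tp - qp) + (1 << 20)) / 16] += 1;
      }
    }
  }
  int best_bin = 0, best_votes = 0;
  for (auto &kv : votes)
    if (kv.second > best_votes) { best_votes = kv.second; best_bin = kv.first; }
  int diag = best_bin * 16 - (1 << 20) + 8;
  return IntegerVector::create(total, diag, best_votes);
}

// Banded affine-gap Smith-Waterman around a given diagonal
// (target_pos - query_pos in [diag - half_width, diag + half_width]).
// Same conventions and return shape as sw_align_cpp.
// [[Rcpp::export(name = ".sw_align_banded_cpp")]]
List sw_align_banded_cpp(std::string query, std::string target,
                         int diag, int half_width = 120,
                         int match = 2, int mismatch = 4,
                         int gap_open = 4, int gap_ext = 2) {
  const int n = (int)query.size(), m = (int)target.size();
  if (n == 0 || m == 0) stop("empty sequence");
  const int lo = diag - half_width, hi = diag + half_width;
  const int B = hi - lo + 1;
  const int NEG = -1000000000;
  std::vector<int> Hprev(B + 2, 0), Hcur(B + 2, 0);
  std::vector<int> Eprev(B + 2, NEG), Ecur(B + 2, NEG);
  std::vector<int> Fprev(B + 2, NEG), Fcur(B + 2, NEG);
  std::vector<uint8_t> tb((size_t)(n + 1) * B, 0);
  // band index b in [0, B): j = i + lo + b (using 1-based i, j)
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    std::fill(Hcur.begin(), Hcur.end(), 0);
    std::fill(Ecur.begin(), Ecur.end(), NEG);
    std::fill(Fcur.begin(), Fcur.end(), NEG);
    for (int b = 0; b < B; ++b) {
      int j = i + lo + b;
      if (j < 1 || j > m) continue;
      uint8_t code = 0;
      // E (left): (i, j-1) -> band b-1, same row
      int e = NEG;
      if (b > 0) {
        int e_open = Hcur[b - 1 + 1] - gap_open;
        int e_ext  = Ecur[b - 1 + 1] - gap_ext;
        e = e_open >= e_ext ? e_open : e_ext;
        if (e_open >= e_ext) code |= 4;
      }
      Ecur[b + 1] = e;
      // F (up): (i-1, j) -> band b+1, previous row
      int f = NEG;
      if (b < B - 1) {
        int f_open = Hprev[b + 1 + 1] - gap_open;
        int f_ext  = Fprev[b + 1 + 1] - gap_ext;
        f = f_open >= f_ext ? f_open : f_ext;
        if (f_open >= f_ext) code |= 8;
      }
      Fcur[b + 1] = f;
      // diag: (i-1, j-1) -> band b, previous row
      int dg = NEG;
      if (i > 1 || j == 1) {
        int hp = (j > 1) ? Hprev[b + 1] : 0;
        dg = hp + (base_match(query[i - 1], target[j - 1]) ? match : -mismatch);
      } else if (i == 1) {
        dg = (base_match(query[i - 1], target[j - 1]) ? match : -mismatch);
      }
      int h = 0; uint8_t src = 0;
      if (dg > h) { h = dg; src = 1; }
      if (e > h)  { h = e;  src = 2; }
      if (f > h)  { h = f;  src = 3; }
      Hcur[b + 1] = h;
      tb[(size_t)i * B + b] = code | src;
      if (h > best) { best = h; bi = i; bj = j; }
    }
    std::swap(Hprev, Hcur);
    std::swap(Eprev, Ecur);
    std::swap(Fprev, Fcur);
  }
  int i = bi, j = bj;
  int n_match = 0, n_mismatch = 0, n_ins = 0, n_del = 0;
  std::string ops;
  int state = 0;
  while (i > 0 && j > 0) {
    int b = j - i - lo;
    if (b < 0 || b >= B) break;
    uint8_t code = tb[(size_t)i * B + b];
    if (state == 0) {
      uint8_t src = code & 3;
      if (src == 0) break;
      if (src == 1) {
        if (base_match(query[i - 1], target[j - 1])) ++n_match; else ++n_mismatch;
        ops.push_back('M'); --i; --j;
      } else if (src == 2) state = 1;
      else state = 2;
    } else if (state == 1) {
      ops.push_back('D'); ++n_del;
      bool open = (code & 4) != 0;
      --j;
      if (open) state = 0;
    } else {
      ops.push_back('I'); ++n_ins;
      bool open = (code & 8) != 0;
      --i;
      if (open) state = 0;
    }
  }
  std::reverse(ops.begin(), ops.end());
  std::string cigar;
  for (size_t kk = 0; kk < ops.size();) {
    size_t k2 = kk;
    while (k2 < ops.size() && ops[k2] == ops[kk]) ++k2;
    cigar += std::to_string(k2 - kk); cigar.push_back(ops[kk]);
    kk = k2;
  }
  return List::create(
    _["score"] = best,
    _["query_start"] = i, _["query_end"] = bi,
    _["target_start"] = j, _["target_end"] = bj,
    _["n_match"] = n_match, _["n_mismatch"] = n_mismatch,
    _["n_ins"] = n_ins, _["n_del"] = n_del,
    _["cigar"] = cigar);
}
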