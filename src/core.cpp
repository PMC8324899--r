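// Compiled kernels: banded affine local alignment (seeded and scan modes),
// longest-common-subsequence identity, greedy identity clustering, ungapped
// read assignment, and exact-repeat mini-CRISPR array detection.
#include <Rcpp.h>
#include <unordered_map>
#include <algorithm>
#include <cstdint>
#include <string>
#include <vector>

using namespace Rcpp;

static const int NEG_INF = -100000000;

static inline int base_code(char c) {
  switch (c) {
    case 'A': return 0;
    case 'C': return 1;
    case 'G': return 2;
    case 'T': return 3;
    default:  return -1;
  }
}

static std::string revcomp_str(const std::string& s) {
  std::string r(s.rbegin(), s.rend());
  for (auto& c : r) {
    switch (c) {
      case 'A': c = 'T'; break;
      case 'C': c = 'G'; break;
      case 'G': c = 'C'; break;
      case 'T': c = 'A'; break;
      default:  c = 'N'; break;
    }
  }
  return r;
}

// [[Rcpp::export]]
int lcs_length_cpp(std::string a, std::string b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return prev[m];
}

static inline double lcs_identity(const std::string& a, const std::string& b) {
  const int n = a.size(), m = b.size();
  std::vector<int> prev(m + 1, 0), cur(m + 1, 0);
  for (int i = 1; i <= n; ++i) {
    for (int j = 1; j <= m; ++j) {
      if (a[i - 1] == b[j - 1]) cur[j] = prev[j - 1] + 1;
      else cur[j] = std::max(prev[j], cur[j - 1]);
    }
    std::swap(prev, cur);
  }
  return (double)prev[m] / (double)std::min(n, m);
}

// seqs must arrive pre-sorted (length descending, ties lexicographic).
// Returns 1-based cluster index per sequence; the founder of each cluster is
// its representative.
// [[Rcpp::export]]
IntegerVector greedy_cluster_cpp(CharacterVector seqs, double threshold) {
  const int n = seqs.size();
  std::vector<std::string> s(n);
  for (int i = 0; i < n; ++i) s[i] = as<std::string>(seqs[i]);
  IntegerVector assign(n);
  std::vector<int> reps;  // index of founding sequence per cluster
  for (int i = 0; i < n; ++i) {
    int found = -1;
    for (size_t c = 0; c < reps.size(); ++c) {
      if (lcs_identity(s[i], s[reps[c]]) + 1e-12 >= threshold) { found = (int)c; break; }
    }
    if (found < 0) { reps.push_back(i); found = (int)reps.size() - 1; }
    assign[i] = found + 1;
  }
  return assign;
}

// [[Rcpp::export]]
NumericMatrix identity_matrix_cpp(CharacterVector a, CharacterVector b) {
  const int n = a.size(), m = b.size();
  std::vector<std::string> sa(n), sb(m);
  for (int i = 0; i < n; ++i) sa[i] = as<std::string>(a[i]);
  for (int j = 0; j < m; ++j) sb[j] = as<std::string>(b[j]);
  NumericMatrix out(n, m);
  for (int i = 0; i < n; ++i)
    for (int j = 0; j < m; ++j)
      out(i, j) = lcs_identity(sa[i], sb[j]);
  return out;
}

struct Aln {
  int qstart, qend, sstart, send;  // 0-based half-open
  int score, identities;
  bool valid;
};

// Banded local alignment of q against s restricted to diagonals
// j - i in [diag_lo, diag_hi] (i query index, j subject index, 0-based).
// Affine gaps: a gap of length k costs gap_open + k * gap_ext.
// Traceback prefers diagonal moves; zero-score diagonal tails at both ends
// are kept so that reported identities are maximal among co-optimal paths.
static Aln banded_sw(const std::string& q, const std::string& s,
                     int diag_lo, int diag_hi,
                     int match, int mismatch, int gap_open, int gap_ext) {
  Aln res; res.valid = false; res.score = 0; res.identities = 0;
  const int n = q.size(), m = s.size();
  if (n == 0 || m == 0) return res;
  if (diag_lo < -n) diag_lo = -n;
  if (diag_hi > m) diag_hi = m;
  if (diag_hi < diag_lo) return res;
  const int W = diag_hi - diag_lo + 1;
  const int go = gap_open, ge = gap_ext;

  std::vector<int> H((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> E((size_t)(n + 1) * W, NEG_INF);
  std::vector<int> F((size_t)(n + 1) * W, NEG_INF);
  auto idx = [&](int i, int k) { return (size_t)i * W + k; };

  int best = 0, bi = -1, bk = -1;
  for (int i = 0; i <= n; ++i) {
    for (int k = 0; k < W; ++k) {
      const int j = i + diag_lo + k;
      if (j < 0 || j > m) continue;
      if (i == 0 || j == 0) { H[idx(i, k)] = 0; continue; }
      const int sub = (q[i - 1] == s[j - 1]) ? match : mismatch;
      const int hdiag = H[idx(i - 1, k)];
      int e = NEG_INF;
      if (k - 1 >= 0) {
        const int hl = H[idx(i, k - 1)], el = E[idx(i, k - 1)];
        if (hl > NEG_INF / 2) e = hl - go - ge;
        if (el > NEG_INF / 2) e = std::max(e, el - ge);
      }
      int f = NEG_INF;
      if (k + 1 < W) {
        const int hu = H[idx(i - 1, k + 1)], fu = F[idx(i - 1, k + 1)];
        if (hu > NEG_INF / 2) f = hu - go - ge;
        if (fu > NEG_INF / 2) f = std::max(f, fu - ge);
      }
      int h = 0;
      if (hdiag > NEG_INF / 2) h = std::max(h, hdiag + sub);
      h = std::max(h, std::max(e, f));
      E[idx(i, k)] = e; F[idx(i, k)] = f; H[idx(i, k)] = h;
      if (h > best || (h == best && h > 0)) {  // ties -> latest cell (longest tail)
        best = h; bi = i; bk = k;
      }
    }
  }
  if (best <= 0) return res;

  // traceback
  int i = bi, k = bk, identities = 0;
  char state = 'H';
  while (true) {
    const int j = i + diag_lo + k;
    if (state == 'H') {
      const int h = H[idx(i, k)];
      if (h == 0) break;
      const int sub = (i >= 1 && j >= 1 && q[i - 1] == s[j - 1]) ? match : mismatch;
      if (i >= 1 && j >= 1 && H[idx(i - 1, k)] > NEG_INF / 2 &&
          h == H[idx(i - 1, k)] + sub) {
        if (q[i - 1] == s[j - 1]) ++identities;
        --i;  // k unchanged: (i-1, j-1)
      } else if (h == E[idx(i, k)]) {
        state = 'E';
      } else if (h == F[idx(i, k)]) {
        state = 'F';
      } else break;
    } else if (state == 'E') {
      const int e = E[idx(i, k)];
      if (k - 1 >= 0 && H[idx(i, k - 1)] > NEG_INF / 2 &&
          e == H[idx(i, k - 1)] - go - ge) { --k; state = 'H'; }
      else { --k; }  // E extension
    } else {  // F
      const int f = F[idx(i, k)];
      if (k + 1 < W && H[idx(i - 1, k + 1)] > NEG_INF / 2 &&
          f == H[idx(i - 1, k + 1)] - go - ge) { --i; ++k; state = 'H'; }
      else { --i; ++k; }
    }
  }
  int qs = i, ss = i + diag_lo + k;
  int qe = bi, se = bi + diag_lo + bk;

  // zero-score diagonal tail extension (keeps identities maximal among
  // co-optimal alignments; capped walk)
  {
    int cum = 0, cur_id = 0, ext = 0, ext_id = 0;
    for (int p = 0; p < 200 && qe + p < n && se + p < m; ++p) {
      const bool mt = q[qe + p] == s[se + p];
      cum += mt ? match : mismatch;
      if (mt) ++cur_id;
      if (cum > 0) break;
      if (cum == 0) { ext = p + 1; ext_id = cur_id; }
    }
    qe += ext; se += ext; identities += ext_id;
  }
  {
    int cum = 0, cur_id = 0, ext = 0, ext_id = 0;
    for (int p = 1; p <= 200 && qs - p >= 0 && ss - p >= 0; ++p) {
      const bool mt = q[qs - p] == s[ss - p];
      cum += mt ? match : mismatch;
      if (mt) ++cur_id;
      if (cum > 0) break;
      if (cum == 0) { ext = p; ext_id = cur_id; }
    }
    qs -= ext; ss -= ext; identities += ext_id;
  }

  res.qstart = qs; res.qend = qe; res.sstart = ss; res.send = se;
  res.score = best; res.identities = identities; res.valid = true;
  return res;
}

struct DiagCluster { int lo, hi, support; };

static void merge_diag_clusters(std::vector<int>& diags, int pad,
                                std::vector<DiagCluster>& clusters) {
  if (diags.empty()) return;
  std::sort(diags.begin(), diags.end());
  int lo = diags[0], hi = diags[0], sup = 1;
  for (size_t i = 1; i < diags.size(); ++i) {
    if (diags[i] - hi <= pad) { hi = diags[i]; ++sup; }
    else { clusters.push_back({lo, hi, sup}); lo = hi = diags[i]; sup = 1; }
  }
  clusters.push_back({lo, hi, sup});
}

static DataFrame alns_to_df(const std::vector<Aln>& alns) {
  const int n = alns.size();
  IntegerVector qs(n), qe(n), ss(n), se(n), sc(n), id(n);
  for (int i = 0; i < n; ++i) {
    qs[i] = alns[i].qstart; qe[i] = alns[i].qend;
    ss[i] = alns[i].sstart; se[i] = alns[i].send;
    sc[i] = alns[i].score;  id[i] = alns[i].identities;
  }
  return DataFrame::create(_["query_start"] = qs, _["query_end"] = qe,
                           _["subject_start"] = ss, _["subject_end"] = se,
                           _["score"] = sc, _["identities"] = id);
}

// Word-seeded local alignment, single strand.
// [[Rcpp::export]]
DataFrame seed_extend_cpp(std::string query, std::string subject, int word_size,
                          int match, int mismatch, int gap_open, int gap_ext,
                          int pad, int min_score, int min_seeds) {
  const int n = query.size(), m = subject.size();
  std::vector<Aln> out;
  if (n < word_size || m < word_size) return alns_to_df(out);

  const uint64_t mask = (word_size >= 32) ? ~0ULL : ((1ULL << (2 * word_size)) - 1);
  std::unordered_map<uint64_t, std::vector<int>> qwords;
  {
    uint64_t w = 0; int run = 0;
    for (int i = 0; i < n; ++i) {
      const int c = base_code(query[i]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask; ++run;
      if (run >= word_size) qwords[w].push_back(i - word_size + 1);
    }
  }
  std::vector<int> diags;
  {
    uint64_t w = 0; int run = 0;
    for (int j = 0; j < m; ++j) {
      const int c = base_code(subject[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask; ++run;
      if (run >= word_size) {
        auto it = qwords.find(w);
        if (it != qwords.end()) {
          const int spos = j - word_size + 1;
          for (int qpos : it->second) diags.push_back(spos - qpos);
        }
      }
    }
  }
  std::vector<DiagCluster> clusters;
  merge_diag_clusters(diags, pad, clusters);
  for (auto& cl : clusters) {
    if (cl.support < min_seeds) continue;
    Aln a = banded_sw(query, subject, cl.lo - pad, cl.hi + pad,
                      match, mismatch, gap_open, gap_ext);
    if (a.valid && a.score >= min_score) out.push_back(a);
  }
  return alns_to_df(out);
}

// Exhaustive per-diagonal match counting followed by banded extension of
// diagonals reaching min_matches; guarantees that any substitution-only
// alignment with at least min_matches identities is examined.
// [[Rcpp::export]]
DataFrame scan_extend_cpp(std::string query, std::string subject,
                          int min_matches, int match, int mismatch,
                          int gap_open, int gap_ext, int pad, int min_score) {
  const int n = query.size(), m = subject.size();
  std::vector<Aln> out;
  if (n == 0 || m == 0) return alns_to_df(out);
  std::vector<int> cnt(n + m - 1, 0);
  std::vector<int> qoff[4];
  for (int i = 0; i < n; ++i) {
    const int c = base_code(query[i]);
    if (c >= 0) qoff[c].push_back(n - 1 - i);
  }
  for (int j = 0; j < m; ++j) {
    const int c = base_code(subject[j]);
    if (c < 0) continue;
    for (int off : qoff[c]) ++cnt[off + j];
  }
  std::vector<int> diags;
  for (int d = 0; d < n + m - 1; ++d)
    if (cnt[d] >= min_matches) diags.push_back(d - (n - 1));
  std::vector<DiagCluster> clusters;
  merge_diag_clusters(diags, pad, clusters);
  for (auto& cl : clusters) {
    Aln a = banded_sw(query, subject, cl.lo - pad, cl.hi + pad,
                      match, mismatch, gap_open, gap_ext);
    if (a.valid && a.score >= min_score) out.push_back(a);
  }
  return alns_to_df(out);
}

// Ungapped best-hit read assignment with word seeding on both strands.
// Ties at equal mismatch count go to the earliest reference in input order.
// multi_mode: 0 = first, 1 = discard multi-reference ties, 2 = fractional.
// [[Rcpp::export]]
List assign_reads_cpp(CharacterVector reads, CharacterVector refs,
                      int word_size, double max_mm_frac, int multi_mode) {
  const int nref = refs.size(), nread = reads.size();
  std::vector<std::string> R(nref);
  for (int r = 0; r < nref; ++r) R[r] = as<std::string>(refs[r]);

  const uint64_t mask = ((1ULL << (2 * word_size)) - 1);
  std::unordered_map<uint64_t, std::vector<std::pair<int,int>>> index;
  for (int r = 0; r < nref; ++r) {
    uint64_t w = 0; int run = 0;
    const std::string& s = R[r];
    for (size_t j = 0; j < s.size(); ++j) {
      const int c = base_code(s[j]);
      if (c < 0) { run = 0; w = 0; continue; }
      w = ((w << 2) | (uint64_t)c) & mask; ++run;
      if (run >= word_size) index[w].push_back({r, (int)j - word_size + 1});
    }
  }

  NumericVector mapped(nref);
  IntegerVector a_ref(nread, NA_INTEGER), a_pos(nread, NA_INTEGER),
                a_mm(nread, NA_INTEGER);
  CharacterVector a_strand(nread, NA_STRING);
  int n_assigned = 0;

  std::vector<std::pair<int,int>> cands;  // (ref, diag)
  for (int q = 0; q < nread; ++q) {
    const std::string fwd = as<std::string>(reads[q]);
    const int L = fwd.size();
    if (L < word_size) continue;
    const int allowed = (int)(max_mm_frac * L + 1e-9);
    int best_mm = allowed + 1, best_r = -1, best_pos = -1, best_strand = -1;
    std::vector<int> tied;  // distinct refs at best_mm
    for (int strand = 0; strand < 2; ++strand) {
      const std::string seq = (strand == 0) ? fwd : revcomp_str(fwd);
      cands.clear();
      uint64_t w = 0; int run = 0;
      for (int i = 0; i < L; ++i) {
        const int c = base_code(seq[i]);
        if (c < 0) { run = 0; w = 0; continue; }
        w = ((w << 2) | (uint64_t)c) & mask; ++run;
        if (run >= word_size) {
          auto it = index.find(w);
          if (it != index.end()) {
            const int qpos = i - word_size + 1;
            for (auto& rp : it->second) {
              const int diag = rp.second - qpos;
              if (diag >= 0 && diag + L <= (int)R[rp.first].size())
                cands.push_back({rp.first, diag});
            }
          }
        }
      }
      std::sort(cands.begin(), cands.end());
      cands.erase(std::unique(cands.begin(), cands.end()), cands.end());
      for (auto& cd : cands) {
        const std::string& ref = R[cd.first];
        int mm = 0;
        for (int i = 0; i < L; ++i) {
          if (seq[i] != ref[cd.second + i]) { if (++mm > allowed) break; }
        }
        if (mm > allowed) continue;
        if (mm < best_mm) {
          best_mm = mm; best_r = cd.first; best_pos = cd.second;
          best_strand = strand; tied.assign(1, cd.first);
        } else if (mm == best_mm) {
          if (std::find(tied.begin(), tied.end(), cd.first) == tied.end())
            tied.push_back(cd.first);
          if (cd.first < best_r) {
            best_r = cd.first; best_pos = cd.second; best_strand = strand;
          }
        }
      }
    }
    if (best_mm <= allowed && best_r >= 0) {
      const int ntied = (int)tied.size();
      if (multi_mode == 1 && ntied > 1) continue;  // discard
      if (multi_mode == 2) {
        for (int r : tied) mapped[r] += (double)L / ntied;
      } else {
        mapped[best_r] += L;
      }
      a_ref[q] = best_r + 1; a_pos[q] = best_pos; a_mm[q] = best_mm;
      a_strand[q] = (best_strand == 0) ? "+" : "-";
      ++n_assigned;
    }
  }
  return List::create(_["mapped_bp"] = mapped, _["n_assigned"] = n_assigned,
                      _["ref_index"] = a_ref, _["pos"] = a_pos,
                      _["strand"] = a_strand, _["mismatches"] = a_mm);
}

static inline bool eq_run(const char* a, const char* b, int r) {
  for (int i = 0; i < r; ++i) if (a[i] != b[i]) return false;
  return true;
}

// Maximal runs of >= min_units exact copies of a candidate repeat separated
// by spacers within [smin, smax]. For each eligible start the chain with the
// most units wins (ties -> longer repeat); covered regions are not rescanned.
// [[Rcpp::export]]
DataFrame mini_crispr_cpp(std::string seq, int rmin, int rmax,
                          int smin, int smax, int min_units) {
  const int N = seq.size();
  const char* s = seq.c_str();
  std::vector<char> covered(N, 0);
  std::vector<int> out_start, out_end, out_nspacer;
  std::vector<std::string> out_rep;

  for (int i = 0; i + 2 * rmin + smin <= N; ++i) {
    if (covered[i]) continue;
    int best_units = 0, best_r = 0, best_end = 0;
    for (int r = rmin; r <= rmax && i + r <= N; ++r) {
      int units = 1, p = i, end = i + r;
      while (true) {
        int next = -1;
        for (int g = smin; g <= smax; ++g) {
          const int q0 = p + r + g;
          if (q0 + r > N) break;
          if (eq_run(s + i, s + q0, r)) { next = q0; break; }
        }
        if (next < 0) break;
        p = next; ++units; end = p + r;
      }
      if (units >= min_units &&
          (units > best_units || (units == best_units && r > best_r))) {
        best_units = units; best_r = r; best_end = end;
      }
    }
    if (best_units >= min_units) {
      out_start.push_back(i);
      out_end.push_back(best_end);
      out_nspacer.push_back(best_units - 1);
      out_rep.push_back(seq.substr(i, best_r));
      for (int p = i; p < best_end; ++p) covered[p] = 1;
    }
  }
  return DataFrame::create(_["start"] = wrap(out_start), _["end"] = wrap(out_end),
                           _["repeat"] = wrap(out_rep),
                           _["spacer_count"] = wrap(out_nspacer),
                           _["stringsAsFactors"] = false);
}
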