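// Mismatch-tolerant short-oligo search: pigeonhole seeding with exact
// segment lookup plus full Hamming verification.
//
// Splitting a length-k query into seg_count segments guarantees that any
// occurrence with <= seg_count - 1 mismatches matches at least one segment
// exactly, so with 3 segments the search is complete up to 2 mismatches.
// 'N' never matches anything (N vs N counts as a mismatch), which keeps
// off-target counts conservative for ambiguous bases.

#include <Rcpp.h>
#include <unordered_map>
#include <vector>
#include <string>
#include <set>
using namespace Rcpp;

static inline int hamming_n(const char* a, const char* b, int k, int cap) {
  int mm = 0;
  for (int i = 0; i < k; ++i) {
    if (a[i] != b[i] || a[i] == 'N' || b[i] == 'N') {
      if (++mm > cap) return mm;
    }
  }
  return mm;
}

// [[Rcpp::export]]
DataFrame cpp_pigeonhole_search(CharacterVector queries, CharacterVector texts,
                                int max_mm, int seg_count) {
  int nq = queries.size(), nt = texts.size();
  if (nq == 0)
    return DataFrame::create(_["query_idx"] = IntegerVector(0),
                             _["text_idx"] = IntegerVector(0),
                             _["offset"] = IntegerVector(0),
                             _["mismatches"] = IntegerVector(0));
  std::vector<std::string> qs(nq), ts(nt);
  for (int i = 0; i < nq; ++i) qs[i] = as<std::string>(queries[i]);
  for (int i = 0; i < nt; ++i) ts[i] = as<std::string>(texts[i]);
  int k = (int) qs[0].size();
  for (int i = 1; i < nq; ++i)
    if ((int) qs[i].size() != k) stop("all queries in one batch must share one length");
  if (k < 3 * seg_count) stop("query too short for %d pigeonhole segments", seg_count);

  // segment layout: seg_count segments of floor(k/seg_count), remainder on the last
  std::vector<int> seg_off(seg_count), seg_len(seg_count);
  int base = k / seg_count;
  for (int s = 0; s < seg_count; ++s) {
    seg_off[s] = s * base;
    seg_len[s] = (s == seg_count - 1) ? k - s * base : base;
  }

  // one exact-lookup table per segment slot: segment string -> (text, offset)
  std::vector<std::unordered_map<std::string, std::vector<std::pair<int,int> > > > tab(seg_count);
  for (int s = 0; s < seg_count; ++s) {
    int len = seg_len[s];
    for (int t = 0; t < nt; ++t) {
      int tl = (int) ts[t].size();
      for (int p = 0; p + len <= tl; ++p)
        tab[s][ts[t].substr(p, len)].push_back(std::make_pair(t, p));
    }
  }

  std::vector<int> r_q, r_t, r_o, r_m;
  for (int q = 0; q < nq; ++q) {
    std::set<std::pair<int,int> > seen;
    for (int s = 0; s < seg_count; ++s) {
      std::string seg = qs[q].substr(seg_off[s], seg_len[s]);
      if (seg.find('N') != std::string::npos) continue; // N never seed-matches
      std::unordered_map<std::string, std::vector<std::pair<int,int> > >::iterator it =
        tab[s].find(seg);
      if (it == tab[s].end()) continue;
      for (size_t h = 0; h < it->second.size(); ++h) {
        int t = it->second[h].first;
        int start = it->second[h].second - seg_off[s];
        if (start < 0 || start + k > (int) ts[t].size()) continue;
        std::pair<int,int> key(t, start);
        if (seen.count(key)) continue;
        seen.insert(key);
        int mm = hamming_n(qs[q].c_str() + 0, ts[t].c_str() + start, k, max_mm);
        if (mm <= max_mm) {
          r_q.push_back(q + 1); r_t.push_back(t + 1);
          r_o.push_back(start); r_m.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["query_idx"] = wrap(r_q), _["text_idx"] = wrap(r_t),
                           _["offset"] = wrap(r_o), _["mismatches"] = wrap(r_m));
}

// Exhaustive Hamming scan over every window: O(nq * total_len * k).
// Kept as a slow reference path for small problems and cross-checks.
// [[Rcpp::export]]
DataFrame cpp_brute_search(CharacterVector queries, CharacterVector texts, int max_mm) {
  int nq = queries.size(), nt = texts.size();
  std::vector<int> r_q, r_t, r_o, r_m;
  for (int q = 0; q < nq; ++q) {
    std::string qs = as<std::string>(queries[q]);
    int k = (int) qs.size();
    for (int t = 0; t < nt; ++t) {
      std::string ts = as<std::string>(texts[t]);
      for (int p = 0; p + k <= (int) ts.size(); ++p) {
        int mm = hamming_n(qs.c_str(), ts.c_str() + p, k, max_mm);
        if (mm <= max_mm) {
          r_q.push_back(q + 1); r_t.push_back(t + 1);
          r_o.push_back(p); r_m.push_back(mm);
        }
      }
    }
  }
  return DataFrame::create(_["query_idx"] = wrap(r_q), _["text_idx"] = wrap(r_t),
                           _["offset"] = wrap(r_o), _["mismatches"] = wrap(r_m));
}
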