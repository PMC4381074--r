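#include <Rcpp.h>
#include <set>
#include <vector>
using namespace Rcpp;

// Bitmask encoding of the DNA alphabet: A=1, C=2, G=4, T=8.  Any other
// character (N and other ambiguity codes in the *sequence*) encodes to 0 and
// therefore never satisfies a motif position.
static inline int base_mask(char c) {
  switch (c) {
    case 'A': case 'a': return 1;
    case 'C': case 'c': return 2;
    case 'G': case 'g': return 4;
    case 'T': case 't': return 8;
    default: return 0;
  }
}

// All 0-based start positions where the masked motif matches.
// [[Rcpp::export(name = ".cpp_site_positions")]]
IntegerVector cpp_site_positions(std::string seq, IntegerVector masks) {
  int w = masks.size();
  int n = seq.size();
  std::vector<int> hits;
  for (int i = 0; i + w <= n; ++i) {
    bool ok = true;
    for (int j = 0; j < w; ++j) {
      if ((base_mask(seq[i + j]) & masks[j]) == 0) { ok = false; break; }
    }
    if (ok) hits.push_back(i);
  }
  return wrap(hits);
}

// Per-sequence indicator: does the motif match at least once?
// [[Rcpp::export(name = ".cpp_has_motif")]]
LogicalVector cpp_has_motif(CharacterVector seqs, IntegerVector masks) {
  int ns = seqs.size();
  int w = masks.size();
  LogicalVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    bool found = false;
    for (int i = 0; i + w <= n && !found; ++i) {
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        if ((base_mask(seq[i + j]) & masks[j]) == 0) { ok = false; break; }
      }
      found = ok;
    }
    out[s] = found;
  }
  return out;
}

static inline int code_of(char c) {
  switch (c) {
    case 'A': case 'a': return 0;
    case 'C': case 'c': return 1;
    case 'G': case 'g': return 2;
    case 'T': case 't': return 3;
    default: return 4;  // N etc.: matches nothing
  }
}

// upper-tail hypergeometric P(X >= k) with K white, NK black, n draws
static double hyper_tail(int k, int K, int NK, int n) {
  int hi = std::min(K, n);
  if (k <= std::max(0, n - NK)) return 1.0;
  if (k > hi) return 0.0;
  double denom = R::lchoose(K + NK, n);
  double s = 0.0;
  for (int i = k; i <= hi; ++i) {
    s += std::exp(R::lchoose(K, i) + R::lchoose(NK, n - i) - denom);
  }
  return std::min(1.0, s);
}

// encode sequences as code vectors (0..3 bases, 4 = other)
static std::vector<std::vector<int> > encode_set(CharacterVector seqs) {
  std::vector<std::vector<int> > out(seqs.size());
  for (int s = 0; s < seqs.size(); ++s) {
    const char *q = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    out[s].resize(n);
    for (int i = 0; i < n; ++i) out[s][i] = code_of(q[i]);
  }
  return out;
}

static int presence(const std::vector<std::vector<int> > &set,
                    const std::vector<int> &masks) {
  int w = masks.size(), cnt = 0;
  for (size_t s = 0; s < set.size(); ++s) {
    const std::vector<int> &q = set[s];
    int n = q.size();
    bool found = false;
    for (int i = 0; i + w <= n && !found; ++i) {
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        int c = q[i + j];
        if (c == 4 || ((masks[j] >> c) & 1) == 0) { ok = false; break; }
      }
      found = ok;
    }
    if (found) ++cnt;
  }
  return cnt;
}

// Hill-climb one exact seed word: per pass, evaluate every single-position
// replacement by a 2-/3-letter class (class_masks, 4-bit base masks with
// bit order A,C,G,T) and accept the best candidate whose p beats the
// current p by more than the number of moves evaluated in the pass
// (p_cand * penalty < p_cur); repeat until no admissible move. Because a
// generalization can only enlarge the match sets, candidates whose
// positive-set presence does not increase are skipped exactly (their p
// cannot decrease). Returns the refined masks, counts, p, and the number
// of distinct candidates tried.
// [[Rcpp::export(name = ".cpp_refine_word")]]
List cpp_refine_word(CharacterVector pos, CharacterVector ref,
                     IntegerVector seed_masks, IntegerVector class_masks,
                     int max_general) {
  std::vector<std::vector<int> > P = encode_set(pos), R_ = encode_set(ref);
  int np = pos.size(), nr = ref.size();
  int w = seed_masks.size();
  std::vector<int> cur(seed_masks.begin(), seed_masks.end());
  int cur_pw = presence(P, cur), cur_rw = presence(R_, cur);
  double cur_p = hyper_tail(cur_pw, cur_pw + cur_rw,
                            (np - cur_pw) + (nr - cur_rw), np);
  std::set<std::vector<int> > seen;
  seen.insert(cur);
  int n_eval = 0;
  bool improved = true;
  while (improved) {
    improved = false;
    // count moves in this pass for the selection penalty
    int n_moves = 0;
    int n_general = 0;  // positions already widened to a class
    for (int j = 0; j < w; ++j) {
      int b = 0;
      for (int t = 0; t < 4; ++t) b += (cur[j] >> t) & 1;
      if (b > 1) ++n_general;
    }
    std::vector<std::pair<int, int> > moves;  // (position, class index)
    for (int j = 0; j < w; ++j) {
      int b = 0;
      for (int t = 0; t < 4; ++t) b += (cur[j] >> t) & 1;
      bool widens_new = (b == 1);
      if (widens_new && n_general >= max_general) continue;
      for (int c = 0; c < class_masks.size(); ++c) {
        if (cur[j] == class_masks[c]) continue;
        std::vector<int> cand = cur;
        cand[j] = class_masks[c];
        if (seen.count(cand)) continue;
        moves.push_back(std::make_pair(j, c));
        ++n_moves;
      }
    }
    double best_p = cur_p;
    std::vector<int> best;
    int best_pw = 0, best_rw = 0;
    for (size_t m = 0; m < moves.size(); ++m) {
      std::vector<int> cand = cur;
      cand[moves[m].first] = class_masks[moves[m].second];
      seen.insert(cand);
      ++n_eval;
      int pw = presence(P, cand);
      if (pw <= cur_pw) continue;  // p cannot improve
      int rw = presence(R_, cand);
      double p = hyper_tail(pw, pw + rw, (np - pw) + (nr - rw), np);
      if (p * n_moves < cur_p && p < best_p) {
        best_p = p; best = cand; best_pw = pw; best_rw = rw;
      }
    }
    if (!best.empty()) {
      cur = best; cur_p = best_p; cur_pw = best_pw; cur_rw = best_rw;
      improved = true;
    }
  }
  return List::create(_["masks"] = wrap(cur), _["p"] = cur_p,
                      _["pos_with"] = cur_pw, _["ref_with"] = cur_rw,
                      _["n_eval"] = n_eval);
}

// Per-sequence number of (possibly overlapping) match sites.
// [[Rcpp::export(name = ".cpp_site_counts")]]
IntegerVector cpp_site_counts(CharacterVector seqs, IntegerVector masks) {
  int ns = seqs.size();
  int w = masks.size();
  IntegerVector out(ns);
  for (int s = 0; s < ns; ++s) {
    const char *seq = CHAR(STRING_ELT(seqs, s));
    int n = LENGTH(STRING_ELT(seqs, s));
    int cnt = 0;
    for (int i = 0; i + w <= n; ++i) {
      bool ok = true;
      for (int j = 0; j < w; ++j) {
        if ((base_mask(seq[i + j]) & masks[j]) == 0) { ok = false; break; }
      }
      if (ok) ++cnt;
    }
    out[s] = cnt;
  }
  return out;
}
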