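#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Weighted base-pair maximization (Nussinov-style) with a minimum hairpin
// loop. Pair weights: G-C = 3, A-U = 2, G-U = 1. DNA input is treated as RNA
// (T == U). Non-ACGU characters never pair.

static inline int enc(char c) {
  switch (c) {
  case 'A': case 'a': return 0;
  case 'C': case 'c': return 1;
  case 'G': case 'g': return 2;
  case 'T': case 't': case 'U': case 'u': return 3;
  default: return -1;
  }
}

static inline int pair_weight(int a, int b) {
  if (a < 0 || b < 0) return 0;
  if ((a == 2 && b == 1) || (a == 1 && b == 2)) return 3; // G-C
  if ((a == 0 && b == 3) || (a == 3 && b == 0)) return 2; // A-U
  if ((a == 2 && b == 3) || (a == 3 && b == 2)) return 1; // G-U
  return 0;
}

// Fill the DP matrix for one encoded sequence. N(i,j) stored row-major in a
// flat vector of size n*n; N(i,j) = best score on s[i..j]. Only positions k
// that can actually pair with s[j] are visited (partner position lists).
static void fill_dp(const std::vector<int>& s, int min_loop,
                    std::vector<int>& N) {
  int n = (int)s.size();
  std::fill(N.begin(), N.end(), 0);
  // partners[v]: sorted positions k whose base pairs with base value v
  std::vector<std::vector<int> > partners(4);
  for (int k = 0; k < n; ++k) {
    switch (s[k]) {
    case 0: partners[3].push_back(k); break;                      // A-U
    case 1: partners[2].push_back(k); break;                      // C-G
    case 2: partners[1].push_back(k); partners[3].push_back(k); break;
    case 3: partners[0].push_back(k); partners[2].push_back(k); break;
    }
  }
  for (int len = 2; len <= n; ++len) {
    for (int i = 0; i + len - 1 < n; ++i) {
      int j = i + len - 1;
      int* Ni = &N[(size_t)i * n];
      int best = Ni[j - 1]; // j unpaired
      int bj = s[j];
      if (bj >= 0) {
        const std::vector<int>& ks = partners[bj];
        int hi = j - min_loop - 1;
        std::vector<int>::const_iterator it =
          std::lower_bound(ks.begin(), ks.end(), i);
        for (; it != ks.end() && *it <= hi; ++it) {
          int k = *it;
          int sc = pair_weight(s[k], bj);
          if (k > i) sc += Ni[k - 1];
          if (k + 1 <= j - 1) sc += N[(size_t)(k + 1) * n + (j - 1)];
          if (sc > best) best = sc;
        }
      }
      Ni[j] = best;
    }
  }
}

// Deterministic traceback: prefer j unpaired, else the smallest qualifying k.
static void traceback(const std::vector<int>& s, int min_loop,
                      const std::vector<int>& N, std::string& db) {
  int n = (int)s.size();
  std::vector<std::pair<int, int> > stack;
  stack.push_back(std::make_pair(0, n - 1));
  while (!stack.empty()) {
    std::pair<int, int> iv = stack.back();
    stack.pop_back();
    int i = iv.first, j = iv.second;
    if (i >= j) continue;
    if (N[i * n + j] == N[i * n + (j - 1)]) {
      stack.push_back(std::make_pair(i, j - 1));
      continue;
    }
    for (int k = i; k <= j - min_loop - 1; ++k) {
      int w = pair_weight(s[k], s[j]);
      if (w == 0) continue;
      int sc = w;
      if (k > i) sc += N[i * n + (k - 1)];
      if (k + 1 <= j - 1) sc += N[(k + 1) * n + (j - 1)];
      if (sc == N[i * n + j]) {
        db[k] = '(';
        db[j] = ')';
        if (k > i) stack.push_back(std::make_pair(i, k - 1));
        if (k + 1 <= j - 1) stack.push_back(std::make_pair(k + 1, j - 1));
        break;
      }
    }
  }
}

// [[Rcpp::export(name = ".fold_one_cpp")]]
List fold_one_cpp(std::string seq, int min_loop) {
  int n = (int)seq.size();
  std::vector<int> s(n);
  for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
  if (n == 0) return List::create(_["structure"] = "", _["score"] = 0);
  std::vector<int> N((size_t)n * n, 0);
  fill_dp(s, min_loop, N);
  std::string db(n, '.');
  traceback(s, min_loop, N, db);
  return List::create(_["structure"] = db, _["score"] = N[0 * n + (n - 1)]);
}

// [[Rcpp::export(name = ".fold_scores_cpp")]]
IntegerVector fold_scores_cpp(CharacterVector seqs, int min_loop) {
  int m = seqs.size();
  IntegerVector out(m);
  std::vector<int> N;
  for (int q = 0; q < m; ++q) {
    std::string seq = as<std::string>(seqs[q]);
    int n = (int)seq.size();
    if (n == 0) { out[q] = 0; continue; }
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
    N.assign((size_t)n * n, 0);
    fill_dp(s, min_loop, N);
    out[q] = N[0 * n + (n - 1)];
  }
  return out;
}

// [[Rcpp::export(name = ".fold_structures_cpp")]]
CharacterVector fold_structures_cpp(CharacterVector seqs, int min_loop) {
  int m = seqs.size();
  CharacterVector out(m);
  std::vector<int> N;
  for (int q = 0; q < m; ++q) {
    std::string seq = as<std::string>(seqs[q]);
    int n = (int)seq.size();
    if (n == 0) { out[q] = ""; continue; }
    std::vector<int> s(n);
    for (int i = 0; i < n; ++i) s[i] = enc(seq[i]);
    N.assign((size_t)n * n, 0);
    fill_dp(s, min_loop, N);
    std::string db(n, '.');
    traceback(s, min_loop, N, db);
    out[q] = db;
  }
  return out;
}
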