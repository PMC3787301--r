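#include <Rcpp.h>
#include <vector>
#include <string>
#include <climits>
#include <algorithm>
using namespace Rcpp;

// Residue -> row index lookup built from the substitution matrix dimnames.
static void build_lookup(const IntegerMatrix &sub, int lookup[256]) {
  CharacterVector rn = rownames(sub);
  for (int i = 0; i < 256; ++i) lookup[i] = -1;
  for (int i = 0; i < rn.size(); ++i) {
    const char *s = CHAR(STRING_ELT(rn, 0 + i));
    lookup[(unsigned char)s[0]] = i;
  }
}

static std::vector<int> encode(const std::string &s, const int lookup[256]) {
  std::vector<int> v(s.size());
  for (size_t i = 0; i < s.size(); ++i) {
    int code = lookup[(unsigned char)s[i]];
    if (code < 0)
      stop("residue '%s' not covered by the scoring matrix",
           std::string(1, s[i]).c_str());
    v[i] = code;
  }
  return v;
}

// Score-only affine-gap Smith-Waterman (gap of length L costs go + L*ge).
static int sw_score_one(const std::vector<int> &a, const std::vector<int> &b,
                        const int *S, int ncol, int go, int ge) {
  const int n = (int)a.size(), m = (int)b.size();
  const int open = go + ge, NEG = INT_MIN / 2;
  std::vector<int> H(m + 1, 0), E(m + 1, NEG);
  int best = 0;
  for (int i = 1; i <= n; ++i) {
    int hdiag = 0;   // H[i-1][j-1]
    int hprev = 0;   // H[i][j-1]
    int f = NEG;     // F[i][j]: gap consuming subject within this row
    const int *Srow = S + (size_t)a[i - 1] * ncol;
    for (int j = 1; j <= m; ++j) {
      int e = E[j] - ge, eo = H[j] - open;   // H[j] still holds row i-1
      if (eo > e) e = eo;
      E[j] = e;
      int fo = hprev - open, fe = f - ge;
      f = fo > fe ? fo : fe;
      int h = hdiag + Srow[b[j - 1]];
      if (e > h) h = e;
      if (f > h) h = f;
      if (h < 0) h = 0;
      hdiag = H[j];
      H[j] = h;
      hprev = h;
      if (h > best) best = h;
    }
  }
  return best;
}

// [[Rcpp::export(name = ".sw_score_block")]]
IntegerMatrix sw_score_block(CharacterVector queries, CharacterVector subjects,
                             IntegerMatrix sub, int gap_open, int gap_extend) {
  int lookup[256];
  build_lookup(sub, lookup);
  const int ncol = sub.ncol();
  std::vector<int> S(sub.begin(), sub.end());
  // column-major in R; transpose into row-major for cache-friendly access
  std::vector<int> Srm((size_t)sub.nrow() * ncol);
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < ncol; ++j)
      Srm[(size_t)i * ncol + j] = S[(size_t)j * sub.nrow() + i];

  std::vector<std::vector<int>> qs(queries.size()), ss(subjects.size());
  for (int i = 0; i < queries.size(); ++i)
    qs[i] = encode(as<std::string>(queries[i]), lookup);
  for (int j = 0; j < subjects.size(); ++j)
    ss[j] = encode(as<std::string>(subjects[j]), lookup);

  IntegerMatrix out(queries.size(), subjects.size());
  for (int i = 0; i < queries.size(); ++i) {
    for (int j = 0; j < subjects.size(); ++j)
      out(i, j) = sw_score_one(qs[i], ss[j], Srm.data(), ncol,
                               gap_open, gap_extend);
    Rcpp::checkUserInterrupt();
  }
  return out;
}

// Full Smith-Waterman with deterministic traceback.
// Tie order when choosing the source of H: diagonal > up (gap in subject,
// consumes query) > left (gap in query, consumes subject).
// [[Rcpp::export(name = ".sw_traceback")]]
List sw_traceback(std::string a, std::string b, IntegerMatrix sub,
                  int gap_open, int gap_extend) {
  int lookup[256];
  build_lookup(sub, lookup);
  const int ncol = sub.ncol();
  std::vector<int> Srm((size_t)sub.nrow() * ncol);
  for (int i = 0; i < sub.nrow(); ++i)
    for (int j = 0; j < ncol; ++j)
      Srm[(size_t)i * ncol + j] = sub(i, j);
  std::vector<int> av = encode(a, lookup), bv = encode(b, lookup);
  const int n = (int)av.size(), m = (int)bv.size();
  const int open = gap_open + gap_extend, ge = gap_extend;
  const int NEG = INT_MIN / 2;

  std::vector<int> H((n + 1) * (m + 1), 0), E((n + 1) * (m + 1), NEG),
      F((n + 1) * (m + 1), NEG);
  // trace codes for H: 0 stop, 1 diag, 2 up(F), 3 left(E)
  std::vector<unsigned char> TH((n + 1) * (m + 1), 0),
      TE((n + 1) * (m + 1), 0), TF((n + 1) * (m + 1), 0); // 1 = opened from H
  int best = 0, bi = 0, bj = 0;
  for (int i = 1; i <= n; ++i) {
    const int *Srow = Srm.data() + (size_t)av[i - 1] * ncol;
    for (int j = 1; j <= m; ++j) {
      size_t k = (size_t)i * (m + 1) + j;
      size_t ku = k - (m + 1), kl = k - 1, kd = ku - 1;
      int e_ext = E[kl] - ge, e_open = H[kl] - open;
      E[k] = e_open >= e_ext ? e_open : e_ext;   // prefer fresh open on ties
      TE[k] = e_open >= e_ext ? 1 : 0;
      int f_ext = F[ku] - ge, f_open = H[ku] - open;
      F[k] = f_open >= f_ext ? f_open : f_ext;
      TF[k] = f_open >= f_ext ? 1 : 0;
      int diag = H[kd] + Srow[bv[j - 1]];
      int h = diag, t = 1;
      if (F[k] > h) { h = F[k]; t = 2; }
      if (E[k] > h) { h = E[k]; t = 3; }
      if (h <= 0) { h = 0; t = 0; }
      H[k] = h; TH[k] = (unsigned char)t;
      if (h > best) { best = h; bi = i; bj = j; }
    }
  }

  std::string qa, sa;
  int identical = 0, mismatch = 0, gaps = 0, gapopen = 0;
  int i = bi, j = bj, state = 0; // 0 = in H
  int qend = bi, send = bj;
  while (best > 0 && !(state == 0 && TH[(size_t)i * (m + 1) + j] == 0)) {
    size_t k = (size_t)i * (m + 1) + j;
    if (state == 0) {
      int t = TH[k];
      if (t == 1) {
        qa.push_back(a[i - 1]); sa.push_back(b[j - 1]);
        if (av[i - 1] == bv[j - 1]) ++identical; else ++mismatch;
        --i; --j;
      } else if (t == 2) state = 2;
      else state = 3;
    } else if (state == 2) { // F: gap in subject, consume query
      qa.push_back(a[i - 1]); sa.push_back('-');
      ++gaps;
      if (TF[k]) { state = 0; ++gapopen; }
      --i;
    } else {                 // E: gap in query, consume subject
      qa.push_back('-'); sa.push_back(b[j - 1]);
      ++gaps;
      if (TE[k]) { state = 0; ++gapopen; }
      --j;
    }
  }
  std::reverse(qa.begin(), qa.end());
  std::reverse(sa.begin(), sa.end());
  int qstart = best > 0 ? i + 1 : 0, sstart = best > 0 ? j + 1 : 0;
  if (best == 0) { qend = 0; send = 0; }
  return List::create(
      _["score"] = best, _["qstart"] = qstart, _["qend"] = qend,
      _["sstart"] = sstart, _["send"] = send,
      _["length"] = (int)qa.size(), _["identical"] = identical,
      _["mismatch"] = mismatch, _["gapopen"] = gapopen, _["gaps"] = gaps,
      _["query_aligned"] = qa, _["subject_aligned"] = sa);
}
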