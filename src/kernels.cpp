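#include <Rcpp.h>
#include <cstring>
using namespace Rcpp;

// IUPAC nucleotide codes as 4-bit masks: A=1, C=2, G=4, T=8.
static int iupac_mask(char c) {
  switch (c) {
  case 'A': case 'a': return 1;
  case 'C': case 'c': return 2;
  case 'G': case 'g': return 4;
  case 'T': case 't': case 'U': case 'u': return 8;
  case 'R': case 'r': return 1 | 4;
  case 'Y': case 'y': return 2 | 8;
  case 'S': case 's': return 2 | 4;
  case 'W': case 'w': return 1 | 8;
  case 'K': case 'k': return 4 | 8;
  case 'M': case 'm': return 1 | 2;
  case 'B': case 'b': return 2 | 4 | 8;
  case 'D': case 'd': return 1 | 4 | 8;
  case 'H': case 'h': return 1 | 2 | 8;
  case 'V': case 'v': return 1 | 2 | 4;
  case 'N': case 'n': return 1 | 2 | 4 | 8;
  default: return 0;
  }
}

// A primer symbol is compatible with a template symbol iff the template's
// base set is contained in the primer's (conservative: template N matches
// only primer N; any non-IUPAC template symbol never matches).
static inline bool iupac_ok(int pmask, char t) {
  const int tmask = iupac_mask(t);
  return tmask != 0 && (pmask & tmask) == tmask;
}

// Mismatches of a degenerate primer against each same-length window.
// [[Rcpp::export]]
IntegerVector cpp_iupac_mismatch(std::string primer, CharacterVector windows) {
  const int plen = primer.size();
  std::vector<int> pmask(plen);
  for (int i = 0; i < plen; ++i) pmask[i] = iupac_mask(primer[i]);
  const int n = windows.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char *w = CHAR(STRING_ELT(windows, k));
    if ((int)std::strlen(w) != plen) {
      out[k] = NA_INTEGER;
      continue;
    }
    int mm = 0;
    for (int i = 0; i < plen; ++i)
      if (!iupac_ok(pmask[i], w[i])) ++mm;
    out[k] = mm;
  }
  return out;
}

// Mismatch count of a primer at every offset of a template (sliding window).
// [[Rcpp::export]]
IntegerVector cpp_scan_template(std::string primer, std::string templ) {
  const int plen = primer.size(), tlen = templ.size();
  if (tlen < plen) return IntegerVector(0);
  std::vector<int> pmask(plen);
  for (int i = 0; i < plen; ++i) pmask[i] = iupac_mask(primer[i]);
  IntegerVector out(tlen - plen + 1);
  for (int s = 0; s <= tlen - plen; ++s) {
    int mm = 0;
    for (int i = 0; i < plen; ++i)
      if (!iupac_ok(pmask[i], templ[s + i])) ++mm;
    out[s] = mm;
  }
  return out;
}

// Best ungapped overlap merge of forward reads with reverse-complemented
// mates. Scored by quality-weighted matches: sum over the overlap of
// min(qf, qr) for agreements minus min(qf, qr) for conflicts. Consensus at
// agreements keeps the base with quality max(qf, qr); at conflicts the
// higher-quality base wins with quality |qf - qr|.
// fwd/rcrev are sequence strings; fq/rq the matching Phred+33 strings
// (rcrev and rq already reversed/complemented by the caller).
// [[Rcpp::export]]
List cpp_merge_pairs(CharacterVector fwd, CharacterVector rcrev,
                     CharacterVector fq, CharacterVector rq,
                     int min_overlap, double min_score,
                     double min_match_frac) {
  const int n = fwd.size();
  CharacterVector seq(n), qual(n);
  IntegerVector ovl(n);
  LogicalVector aligned(n);
  std::string sbuf, qbuf;
  for (int k = 0; k < n; ++k) {
    const char *a = CHAR(STRING_ELT(fwd, k));
    const char *b = CHAR(STRING_ELT(rcrev, k));
    const char *qa = CHAR(STRING_ELT(fq, k));
    const char *qb = CHAR(STRING_ELT(rq, k));
    const int la = std::strlen(a), lb = std::strlen(b);
    const int omax = la < lb ? la : lb;
    double best_score = -1e18;
    int best_o = -1, best_match = 0;
    for (int o = min_overlap; o <= omax; ++o) {
      // overlap: a[la - o + j] vs b[j]
      double score = 0;
      int nmatch = 0;
      for (int j = 0; j < o; ++j) {
        const int i = la - o + j;
        int qmin = (qa[i] < qb[j] ? qa[i] : qb[j]) - 33;
        if (a[i] == b[j] && a[i] != 'N') { score += qmin; ++nmatch; }
        else score -= qmin;
      }
      if (score > best_score) {
        best_score = score; best_o = o; best_match = nmatch;
      }
    }
    if (best_o < min_overlap || best_score < min_score ||
        best_match < min_match_frac * best_o) {
      seq[k] = NA_STRING; qual[k] = NA_STRING;
      ovl[k] = best_o > 0 ? best_o : 0; aligned[k] = false;
      continue;
    }
    const int o = best_o;
    sbuf.assign(a, la - o);
    qbuf.assign(qa, la - o);
    for (int j = 0; j < o; ++j) {
      const int i = la - o + j;
      int qfa = qa[i] - 33, qfb = qb[j] - 33;
      char base; int q;
      if (a[i] == b[j]) { base = a[i]; q = qfa > qfb ? qfa : qfb; }
      else if (qfa >= qfb) { base = a[i]; q = qfa - qfb; }
      else { base = b[j]; q = qfb - qfa; }
      if (q > 60) q = 60;
      sbuf.push_back(base);
      qbuf.push_back((char)(q + 33));
    }
    sbuf.append(b + o, lb - o);
    qbuf.append(qb + o, lb - o);
    seq[k] = sbuf; qual[k] = qbuf;
    ovl[k] = o; aligned[k] = true;
  }
  return List::create(_["sequence"] = seq, _["quality"] = qual,
                      _["overlap_length"] = ovl, _["aligned"] = aligned);
}

// Global (Needleman-Wunsch) alignment of one query against each reference:
// match +1, mismatch -1, gap -1, end-to-end. Traceback prefers diagonal,
// then vertical, then horizontal (deterministic). Returns per reference the
// optimal score, the number of matched columns and the alignment length.
// [[Rcpp::export]]
NumericMatrix cpp_nw_identity(std::string query, CharacterVector refs) {
  const int la = query.size();
  const int n = refs.size();
  NumericMatrix out(n, 4); // score, matches, columns, identity
  colnames(out) = CharacterVector::create("score", "matches", "columns",
                                          "identity");
  for (int k = 0; k < n; ++k) {
    const char *b = CHAR(STRING_ELT(refs, k));
    const int lb = std::strlen(b);
    // DP over (la+1) x (lb+1)
    std::vector<int> S((la + 1) * (lb + 1));
    const int W = lb + 1;
    for (int j = 0; j <= lb; ++j) S[j] = -j;
    for (int i = 1; i <= la; ++i) {
      S[i * W] = -i;
      const char ai = query[i - 1];
      for (int j = 1; j <= lb; ++j) {
        int diag = S[(i - 1) * W + (j - 1)] + (ai == b[j - 1] ? 1 : -1);
        int up = S[(i - 1) * W + j] - 1;
        int left = S[i * W + (j - 1)] - 1;
        int v = diag >= up ? diag : up;
        if (left > v) v = left;
        S[i * W + j] = v;
      }
    }
    // traceback
    int i = la, j = lb, matches = 0, cols = 0;
    while (i > 0 || j > 0) {
      if (i > 0 && j > 0) {
        int diag = S[(i - 1) * W + (j - 1)] +
          (query[i - 1] == b[j - 1] ? 1 : -1);
        if (S[i * W + j] == diag) {
          if (query[i - 1] == b[j - 1]) ++matches;
          --i; --j; ++cols; continue;
        }
      }
      if (i > 0 && S[i * W + j] == S[(i - 1) * W + j] - 1) {
        --i; ++cols; continue;
      }
      --j; ++cols;
    }
    out(k, 0) = S[la * W + lb];
    out(k, 1) = matches;
    out(k, 2) = cols;
    out(k, 3) = cols > 0 ? (double)matches / cols : 1.0;
  }
  return out;
}
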