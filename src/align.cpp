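#include <Rcpp.h>
#include <vector>
#include <string>
using namespace Rcpp;

// Reference position labels (see convert_reference()):
//   1 = A, 2 = G, 3 = T (genomic T), 4 = T from CpH cytosine,
//   5 = T from CpG cytosine (methylation-informative column).
// Substitution contract: read T matches any T-label; read C additionally
// matches labels 4 (conversion failure, forgiven in scoring) and 5
// (methylated CpG). Everything else is a standard match/mismatch on the
// underlying base.

namespace {

const double NEG_INF = -1e18;

inline bool base_matches(char r, int lab) {
  switch (lab) {
  case 1: return r == 'A';
  case 2: return r == 'G';
  case 3: return r == 'T';
  case 4: return r == 'T' || r == 'C';
  case 5: return r == 'T' || r == 'C';
  }
  return false;
}

struct Aln {
  double score;
  std::string read_g;       // gapped read, '-' for gap
  std::vector<int> lab_g;   // gapped reference labels, 0 for gap
  std::vector<int> ord_g;   // CpG ordinal per column, 0 if none
};

// reusable DP workspace, grown on demand
struct Workspace {
  std::vector<double> M, X, Y;
  std::vector<signed char> PM, PX, PY;
  void ensure(size_t cells) {
    if (M.size() < cells) {
      M.resize(cells); X.resize(cells); Y.resize(cells);
      PM.resize(cells); PX.resize(cells); PY.resize(cells);
    }
  }
};

// Global alignment anchored at the 5' end of both sequences, affine gaps
// (a gap of length L costs gap_open + L * gap_ext), with free trailing
// gaps: the path may stop at any cell in the last row (read consumed) or
// last column (reference consumed). Layers: 0 = M (diagonal), 1 = X
// (read base against gap in reference, "up"), 2 = Y (gap in read against
// reference base, "left"). Ties break deterministically preferring M,
// then X, then Y (diagonal, up, left).
Aln align_one(const std::string& read, const std::vector<int>& labels,
              const std::vector<int>& ords, double match, double mismatch,
              double gap_open, double gap_ext, Workspace& ws) {
  const int m = (int)read.size(), n = (int)labels.size();
  const int W = n + 1;
  ws.ensure((size_t)(m + 1) * W);
  double *M = ws.M.data(), *X = ws.X.data(), *Y = ws.Y.data();
  signed char *PM = ws.PM.data(), *PX = ws.PX.data(), *PY = ws.PY.data();
  const double go_ge = gap_open + gap_ext;

  M[0] = 0.0; X[0] = NEG_INF; Y[0] = NEG_INF;
  PM[0] = PX[0] = PY[0] = -1;
  for (int j = 1; j <= n; ++j) {
    M[j] = NEG_INF; X[j] = NEG_INF;
    Y[j] = gap_open + j * gap_ext;
    PY[j] = (j == 1) ? 0 : 2;
  }
  for (int i = 1; i <= m; ++i) {
    const int r0 = i * W;
    M[r0] = NEG_INF; Y[r0] = NEG_INF;
    X[r0] = gap_open + i * gap_ext;
    PX[r0] = (i == 1) ? 0 : 1;
  }

  for (int i = 1; i <= m; ++i) {
    const char rc = read[i - 1];
    const int row = i * W, prow = (i - 1) * W;
    for (int j = 1; j <= n; ++j) {
      const int ij = row + j, dg = prow + j - 1, up = prow + j,
                lf = row + j - 1;
      // M: diagonal step
      double best = M[dg]; signed char who = 0;
      if (X[dg] > best) { best = X[dg]; who = 1; }
      if (Y[dg] > best) { best = Y[dg]; who = 2; }
      M[ij] = best + (base_matches(rc, labels[j - 1]) ? match : mismatch);
      PM[ij] = who;
      // X: read base vs gap in reference
      double c0 = M[up] + go_ge, c1 = X[up] + gap_ext, c2 = Y[up] + go_ge;
      best = c0; who = 0;
      if (c1 > best) { best = c1; who = 1; }
      if (c2 > best) { best = c2; who = 2; }
      X[ij] = best; PX[ij] = who;
      // Y: gap in read vs reference base
      c0 = M[lf] + go_ge; c1 = X[lf] + go_ge; c2 = Y[lf] + gap_ext;
      best = c0; who = 0;
      if (c1 > best) { best = c1; who = 1; }
      if (c2 > best) { best = c2; who = 2; }
      Y[ij] = best; PY[ij] = who;
    }
  }

  // Endpoint: best over last row and last column, all layers. Scan order
  // fixes tie-breaking: (m,n) first, then row m right-to-left, then
  // column n bottom-up; layers M, X, Y.
  double best = NEG_INF;
  int ei = m, ej = n, el = 0;
  for (int j = n; j >= 0; --j) {
    const int ij = m * W + j;
    if (M[ij] > best) { best = M[ij]; ei = m; ej = j; el = 0; }
    if (X[ij] > best) { best = X[ij]; ei = m; ej = j; el = 1; }
    if (Y[ij] > best) { best = Y[ij]; ei = m; ej = j; el = 2; }
  }
  for (int i = m - 1; i >= 0; --i) {
    const int ij = i * W + n;
    if (M[ij] > best) { best = M[ij]; ei = i; ej = n; el = 0; }
    if (X[ij] > best) { best = X[ij]; ei = i; ej = n; el = 1; }
    if (Y[ij] > best) { best = Y[ij]; ei = i; ej = n; el = 2; }
  }

  Aln out;
  out.score = best;
  std::string rg; std::vector<int> lg, og;
  int i = ei, j = ej, l = el;
  while (i > 0 || j > 0) {
    const int ij = i * W + j;
    if (l == 0) {
      rg.push_back(read[i - 1]); lg.push_back(labels[j - 1]);
      og.push_back(ords[j - 1]);
      l = PM[ij]; --i; --j;
    } else if (l == 1) {
      rg.push_back(read[i - 1]); lg.push_back(0); og.push_back(0);
      l = PX[ij]; --i;
    } else {
      rg.push_back('-'); lg.push_back(labels[j - 1]); og.push_back(ords[j - 1]);
      l = PY[ij]; --j;
    }
  }
  out.read_g.assign(rg.rbegin(), rg.rend());
  out.lab_g.assign(lg.rbegin(), lg.rend());
  out.ord_g.assign(og.rbegin(), og.rend());
  return out;
}

struct Metrics {
  double identity, conversion;
  std::string calls;  // per CpG ordinal: 'M', 'U' or '.'
};

Metrics column_metrics(const Aln& a, int n_cpg, bool identity_strict) {
  Metrics mt;
  mt.calls.assign(n_cpg, '.');
  int eligible = 0, matched = 0, conv = 0, unconv = 0;
  for (size_t c = 0; c < a.lab_g.size(); ++c) {
    const int lab = a.lab_g[c];
    const char rc = a.read_g[c];
    const bool is_cpg = (lab == 5);
    if (lab == 4) {
      if (rc == 'T') ++conv; else if (rc == 'C') ++unconv;
    }
    if (is_cpg) {
      const int ord = a.ord_g[c];
      if (ord >= 1 && ord <= n_cpg)
        mt.calls[ord - 1] = (rc == 'C') ? 'M' : (rc == 'T') ? 'U' : '.';
    }
    if (identity_strict) {
      // every column counts; unconverted CpH is a mismatch
      ++eligible;
      bool ok = (rc != '-' && lab != 0 && base_matches(rc, lab));
      if (lab == 4 && rc == 'C') ok = false;
      if (ok) ++matched;
    } else {
      // CpG columns excluded; read C at CpH forgiven (dedicated filters
      // handle methylation state and conversion failure)
      if (!is_cpg) {
        ++eligible;
        if (rc != '-' && lab != 0 && base_matches(rc, lab)) ++matched;
      }
    }
  }
  mt.identity = eligible > 0 ? 100.0 * matched / eligible : NA_REAL;
  mt.conversion = (conv + unconv) > 0 ? 100.0 * conv / (conv + unconv) : 100.0;
  return mt;
}

}  // namespace

// [[Rcpp::export]]
List bs_align_batch_cpp(CharacterVector reads, IntegerVector labels,
                        IntegerVector ords, int n_cpg, double match,
                        double mismatch, double gap_open, double gap_ext,
                        bool identity_strict) {
  const int nr = reads.size();
  const std::vector<int> lab(labels.begin(), labels.end());
  const std::vector<int> ord(ords.begin(), ords.end());
  Workspace ws;
  NumericVector score(nr), identity(nr), conversion(nr);
  CharacterVector calls(nr), read_gapped(nr);
  List labels_gapped(nr), ords_gapped(nr);
  for (int k = 0; k < nr; ++k) {
    std::string rd = as<std::string>(reads[k]);
    Aln a = align_one(rd, lab, ord, match, mismatch, gap_open, gap_ext, ws);
    Metrics mt = column_metrics(a, n_cpg, identity_strict);
    score[k] = a.score;
    identity[k] = mt.identity;
    conversion[k] = mt.conversion;
    calls[k] = mt.calls;
    read_gapped[k] = a.read_g;
    labels_gapped[k] = IntegerVector(a.lab_g.begin(), a.lab_g.end());
    ords_gapped[k] = IntegerVector(a.ord_g.begin(), a.ord_g.end());
  }
  return List::create(_["score"] = score, _["identity_pct"] = identity,
                      _["conversion_pct"] = conversion, _["calls"] = calls,
                      _["read_gapped"] = read_gapped,
                      _["labels_gapped"] = labels_gapped,
                      _["ords_gapped"] = ords_gapped);
}

// Hamming distance from each string to a fixed pattern; strings must have
// the same length as the pattern (NA on a length clash).
// [[Rcpp::export]]
IntegerVector hamming_to_pattern_cpp(CharacterVector strs, std::string pattern) {
  const int n = strs.size();
  const size_t L = pattern.size();
  IntegerVector out(n);
  for (int k = 0; k < n; ++k) {
    const char* s = CHAR(STRING_ELT(strs, k));
    if (strlen(s) != L) { out[k] = NA_INTEGER; continue; }
    int d = 0;
    for (size_t i = 0; i < L; ++i) if (s[i] != pattern[i]) ++d;
    out[k] = d;
  }
  return out;
}
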