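#include <Rcpp.h>
#include <cstdint>
#include <vector>

using namespace Rcpp;

// Carrier columns are packed into 64-bit words, cases first then controls,
// so joint-carrier counts reduce to AND + popcount with no masking.

static inline int popcount64(uint64_t x) {
#if defined(__GNUC__) || defined(__clang__)
  return __builtin_popcountll(x);
#else
  int c = 0;
  while (x) { x &= x - 1; ++c; }
  return c;
#endif
}

struct PackedBlock {
  int n;                       // samples in block
  int nw;                      // words per column
  std::vector<uint64_t> bits;  // column-major: nw words per variant
};

static PackedBlock pack_block(const LogicalMatrix& m, const IntegerVector& rows) {
  PackedBlock b;
  b.n = rows.size();
  b.nw = (b.n + 63) / 64;
  int nv = m.ncol();
  b.bits.assign((size_t)b.nw * nv, 0ULL);
  for (int v = 0; v < nv; ++v) {
    uint64_t* col = &b.bits[(size_t)b.nw * v];
    for (int i = 0; i < b.n; ++i) {
      int r = rows[i] - 1;  // 1-based from R
      if (m(r, v) == TRUE) col[i >> 6] |= (1ULL << (i & 63));
    }
  }
  return b;
}

static inline int joint_count(const PackedBlock& b, int v1, int v2) {
  const uint64_t* c1 = &b.bits[(size_t)b.nw * v1];
  const uint64_t* c2 = &b.bits[(size_t)b.nw * v2];
  int s = 0;
  for (int w = 0; w < b.nw; ++w) s += popcount64(c1[w] & c2[w]);
  return s;
}

// Pearson chi-square without continuity correction; zero margin -> (0, 1).
static inline void chi2_cell(double a, double b, double c, double d,
                             double* chi2, double* p) {
  double n = a + b + c + d;
  double r1 = a + b, r2 = c + d, c1 = a + c, c2 = b + d;
  if (r1 <= 0 || r2 <= 0 || c1 <= 0 || c2 <= 0) { *chi2 = 0.0; *p = 1.0; return; }
  double diff = a * d - b * c;
  *chi2 = n * diff * diff / (r1 * r2 * c1 * c2);
  *p = R::pchisq(*chi2, 1.0, 0, 0);
}

// Per-column carrier counts within a row subset, via packed popcount.
// [[Rcpp::export(name = ".packedColumnCounts")]]
IntegerVector packed_column_counts(LogicalMatrix m, IntegerVector rows) {
  PackedBlock b = pack_block(m, rows);
  int nv = m.ncol();
  IntegerVector out(nv);
  for (int v = 0; v < nv; ++v) out[v] = joint_count(b, v, v);
  return out;
}

// Exhaustive scan over all unordered pairs of the given variant columns
// (1-based indices into m). Emits pairs with p < p_final.
// [[Rcpp::export(name = ".scanPairsPacked")]]
DataFrame scan_pairs_packed(LogicalMatrix m, IntegerVector variants,
                            IntegerVector caseRows, IntegerVector ctrlRows,
                            double pFinal) {
  int nv = variants.size();
  LogicalMatrix sub(m.nrow(), nv);
  for (int v = 0; v < nv; ++v) {
    int col = variants[v] - 1;
    for (int r = 0; r < m.nrow(); ++r) sub(r, v) = m(r, col);
  }
  PackedBlock ca = pack_block(sub, caseRows);
  PackedBlock co = pack_block(sub, ctrlRows);
  int nCase = ca.n, nCtrl = co.n;

  std::vector<int> vi, vj, va, vb, vc, vd;
  std::vector<double> vchi, vp;
  for (int i = 0; i < nv; ++i) {
    for (int j = i + 1; j < nv; ++j) {
      int a = joint_count(ca, i, j);
      int c = joint_count(co, i, j);
      int b = nCase - a, d = nCtrl - c;
      double chi2, p;
      chi2_cell(a, b, c, d, &chi2, &p);
      if (p < pFinal) {
        vi.push_back(variants[i]); vj.push_back(variants[j]);
        va.push_back(a); vb.push_back(b); vc.push_back(c); vd.push_back(d);
        vchi.push_back(chi2); vp.push_back(p);
      }
    }
    if (i % 256 == 0) Rcpp::checkUserInterrupt();
  }
  return DataFrame::create(_["i"] = vi, _["j"] = vj,
                           _["a"] = va, _["b"] = vb, _["c"] = vc, _["d"] = vd,
                           _["chi2"] = vchi, _["p"] = vp);
}
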