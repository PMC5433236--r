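#include <Rcpp.h>
#include <vector>
#include <algorithm>
using namespace Rcpp;

static const double NEG = -1e18;

// ---------------------------------------------------------------------------
// Local profile Viterbi (match/insert/delete) over a position-specific
// scoring model. Emissions are log2-odds bits per match column; insert
// states emit at background (0 bits). Alignment is local in both the
// sequence and the model; the score is the best match-state cell.
//
// seq: residue codes 0..19, -1 for X/unknown (emission 0).
// Returns score (bits), 1-based model span, and per-residue model column
// (0 = residue not aligned to a match column).
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_profile_align(NumericMatrix emis, IntegerVector seq,
                       double io, double ie, double dopen, double dext,
                       bool traceback) {
  const int M = emis.nrow();
  const int L = seq.size();
  if (L == 0 || M == 0)
    return List::create(_["score"] = R_NegInf, _["jstart"] = 0, _["jend"] = 0,
                        _["col_of_res"] = IntegerVector(L));
  // column-major copy of emissions for contiguous row access: e[a*M + j]
  std::vector<double> E(20 * M);
  for (int a = 0; a < 20; ++a)
    for (int j = 0; j < M; ++j) E[a * M + j] = emis(j, a);

  const size_t W = (size_t)M + 1;
  std::vector<double> Vm((L + 1) * W, NEG), Vi((L + 1) * W, NEG),
      Vd((L + 1) * W, NEG);
  std::vector<signed char> Pm, Pi, Pd;
  if (traceback) {
    Pm.assign((L + 1) * W, 0); Pi.assign((L + 1) * W, 0);
    Pd.assign((L + 1) * W, 0);
  }
  double best = R_NegInf; int bi = 0, bj = 0;
  for (int i = 1; i <= L; ++i) {
    const int a = seq[i - 1];
    const double *erow = (a >= 0 && a < 20) ? &E[(size_t)a * M] : nullptr;
    double *vm = &Vm[i * W], *vi = &Vi[i * W], *vd = &Vd[i * W];
    const double *pm = &Vm[(i - 1) * W], *pi = &Vi[(i - 1) * W],
                 *pd = &Vd[(i - 1) * W];
    for (int j = 1; j <= M; ++j) {
      const double e = erow ? erow[j - 1] : 0.0;
      double pre = pm[j - 1]; int ptr = 1;
      if (pi[j - 1] > pre) { pre = pi[j - 1]; ptr = 2; }
      if (pd[j - 1] > pre) { pre = pd[j - 1]; ptr = 3; }
      if (0.0 > pre) { pre = 0.0; ptr = 0; }
      vm[j] = pre + e;
      double iopen = pm[j] - io, iext = pi[j] - ie;
      double dopen2 = vm[j - 1] - dopen, dext2 = vd[j - 1] - dext;
      int pdir;
      if (iopen >= iext) { vi[j] = iopen; pdir = 1; } else { vi[j] = iext; pdir = 2; }
      if (traceback) { Pm[i * W + j] = (signed char)ptr; Pi[i * W + j] = (signed char)pdir; }
      if (dopen2 >= dext2) { vd[j] = dopen2; if (traceback) Pd[i * W + j] = 1; }
      else                 { vd[j] = dext2;  if (traceback) Pd[i * W + j] = 3; }
      if (vm[j] > best) { best = vm[j]; bi = i; bj = j; }
    }
  }

  IntegerVector col_of_res(L);
  int jstart = bj, jend = bj;
  if (traceback && bi > 0) {
    int i = bi, j = bj, st = 1;
    while (i > 0 && j > 0) {
      if (st == 1) {
        col_of_res[i - 1] = j;
        jstart = j;
        int p = Pm[i * W + j];
        --i; --j;
        if (p == 0) break;
        st = p;
      } else if (st == 2) {
        int p = Pi[i * W + j]; --i; st = p;
      } else {
        int p = Pd[i * W + j]; jstart = j; --j; st = p;
      }
    }
  }
  return List::create(_["score"] = (bi > 0 ? best : R_NegInf),
                      _["jstart"] = jstart, _["jend"] = jend,
                      _["col_of_res"] = col_of_res);
}

// Batch scorer without traceback (screening loop).
// [[Rcpp::export]]
NumericVector cpp_profile_scores(NumericMatrix emis, List seqs,
                                 double io, double ie, double dopen, double dext) {
  const int n = seqs.size();
  const int M = emis.nrow();
  NumericVector out(n);
  std::vector<double> E(20 * M);
  for (int a = 0; a < 20; ++a)
    for (int j = 0; j < M; ++j) E[a * M + j] = emis(j, a);
  std::vector<double> vm(M + 1), vi(M + 1), vd(M + 1), nm(M + 1), ni(M + 1),
      nd(M + 1);
  for (int s = 0; s < n; ++s) {
    IntegerVector seq = seqs[s];
    const int L = seq.size();
    if (L == 0 || M == 0) { out[s] = R_NegInf; continue; }
    std::fill(vm.begin(), vm.end(), NEG);
    std::fill(vi.begin(), vi.end(), NEG);
    std::fill(vd.begin(), vd.end(), NEG);
    double best = R_NegInf;
    for (int i = 1; i <= L; ++i) {
      const int a = seq[i - 1];
      const double *erow = (a >= 0 && a < 20) ? &E[(size_t)a * M] : nullptr;
      nm[0] = NEG; ni[0] = NEG; nd[0] = NEG;
      for (int j = 1; j <= M; ++j) {
        const double e = erow ? erow[j - 1] : 0.0;
        double pre = vm[j - 1];
        if (vi[j - 1] > pre) pre = vi[j - 1];
        if (vd[j - 1] > pre) pre = vd[j - 1];
        if (0.0 > pre) pre = 0.0;
        nm[j] = pre + e;
        double iopen = vm[j] - io, iext = vi[j] - ie;
        ni[j] = iopen >= iext ? iopen : iext;
        double dopen2 = nm[j - 1] - dopen, dext2 = nd[j - 1] - dext;
        nd[j] = dopen2 >= dext2 ? dopen2 : dext2;
        if (nm[j] > best) best = nm[j];
      }
      vm.swap(nm); vi.swap(ni); vd.swap(nd);
    }
    out[s] = best;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Frameshift-aware local alignment of a nucleotide read against a protein
// reference. Codon states consume 3 nt and score by the substitution
// matrix; frameshift transitions consume 2 or 4 nt for one reference
// residue at a fixed penalty; protein-level gaps are affine. Tie-breaking
// is fixed (codon > fs2 > fs4; M > I > D > restart) so an independent
// oracle can be compared cell-exactly.
//
// nt: 0=A,1=C,2=G,3=T, >=4 unknown. ref: aa codes into `submat` rows.
// code64: codon index (16*n1+4*n2+n3) -> aa code; X code used for unknowns.
// Returns score plus op list: 1=codon(3nt) 2=fs2 3=fs4 4=insert(3nt) 5=delete.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
List cpp_framebot(IntegerVector nt, IntegerVector ref, NumericMatrix submat,
                  IntegerVector code64, int xcode,
                  double gopen, double gext, double fs) {
  const int L = nt.size(), P = ref.size();
  const size_t W = (size_t)P + 1;
  std::vector<double> Vm((L + 1) * W, NEG), Vi((L + 1) * W, NEG),
      Vd((L + 1) * W, NEG);
  std::vector<signed char> Pm((L + 1) * W, 0), Pi((L + 1) * W, 0),
      Pd((L + 1) * W, 0);
  const int ns = submat.nrow();
  std::vector<double> S(ns * ns);
  for (int a = 0; a < ns; ++a)
    for (int b = 0; b < ns; ++b) S[a * ns + b] = submat(a, b);
  std::vector<int> C64(code64.begin(), code64.end());
  // aa code of the codon ending at nt position i (1-based), precomputed
  std::vector<int> aa_end(L + 1, xcode);
  for (int i = 3; i <= L; ++i) {
    int n1 = nt[i - 3], n2 = nt[i - 2], n3 = nt[i - 1];
    aa_end[i] = (n1 > 3 || n2 > 3 || n3 > 3) ? xcode
                                             : C64[16 * n1 + 4 * n2 + n3];
  }
  auto pre_of = [&](size_t idx, int &ptr) {
    double pre = Vm[idx]; ptr = 1;
    if (Vi[idx] > pre) { pre = Vi[idx]; ptr = 2; }
    if (Vd[idx] > pre) { pre = Vd[idx]; ptr = 3; }
    if (0.0 > pre) { pre = 0.0; ptr = 0; }
    return pre;
  };

  double best = R_NegInf; int bi = 0, bj = 0;
  for (int i = 0; i <= L; ++i) {
    const size_t row = (size_t)i * W;
    for (int j = 1; j <= P; ++j) {
      const int rj = ref[j - 1];
      double vbest = NEG; int code = 0;
      if (i >= 3) {
        int ptr; double pre = pre_of(row - 3 * W + j - 1, ptr);
        double v = pre + S[(size_t)aa_end[i] * ns + rj];
        if (v > vbest) { vbest = v; code = 10 + ptr; }
      }
      if (i >= 2) {
        int ptr; double pre = pre_of(row - 2 * W + j - 1, ptr);
        double v = pre + fs;
        if (v > vbest) { vbest = v; code = 20 + ptr; }
      }
      if (i >= 4) {
        int ptr; double pre = pre_of(row - 4 * W + j - 1, ptr);
        double v = pre + fs;
        if (v > vbest) { vbest = v; code = 30 + ptr; }
      }
      Vm[row + j] = vbest; Pm[row + j] = (signed char)code;
      double dopen = Vm[row + j - 1] - gopen, dext = Vd[row + j - 1] - gext;
      if (dopen >= dext) { Vd[row + j] = dopen; Pd[row + j] = 1; }
      else               { Vd[row + j] = dext;  Pd[row + j] = 3; }
      if (Vm[row + j] > best) { best = Vm[row + j]; bi = i; bj = j; }
    }
    if (i >= 3) {
      const size_t prow = row - 3 * W;
      for (int j = 0; j <= P; ++j) {
        double iopen = Vm[prow + j] - gopen, iext = Vi[prow + j] - gext;
        if (iopen >= iext) { Vi[row + j] = iopen; Pi[row + j] = 1; }
        else               { Vi[row + j] = iext;  Pi[row + j] = 2; }
      }
    }
  }

  std::vector<int> ops, opi, opj;
  int istart = bi, jstart = bj;
  if (bj > 0 && best > NEG / 2) {
    int i = bi, j = bj, st = 1;
    bool done = false;
    while (!done && j >= 0) {
      if (st == 1) {
        if (j == 0) break;
        int code = Pm[(size_t)i * W + j], way = code / 10, ptr = code % 10;
        int consumed = (way == 1) ? 3 : (way == 2 ? 2 : 4);
        ops.push_back(way); opi.push_back(i); opj.push_back(j);
        istart = i - consumed; jstart = j;
        i -= consumed; --j;
        if (ptr == 0) done = true; else st = ptr;
      } else if (st == 2) {
        int ptr = Pi[(size_t)i * W + j];
        ops.push_back(4); opi.push_back(i); opj.push_back(j);
        istart = i - 3;
        i -= 3; st = ptr;
      } else {
        int ptr = Pd[(size_t)i * W + j];
        ops.push_back(5); opi.push_back(i); opj.push_back(j);
        jstart = j;
        --j; st = ptr;
      }
    }
    std::reverse(ops.begin(), ops.end());
    std::reverse(opi.begin(), opi.end());
    std::reverse(opj.begin(), opj.end());
  }
  return List::create(_["score"] = (bj > 0 && best > NEG / 2 ? best : R_NegInf),
                      _["istart"] = istart, _["iend"] = bi,
                      _["jstart"] = jstart, _["jend"] = bj,
                      _["op"] = wrap(ops), _["op_i"] = wrap(opi),
                      _["op_j"] = wrap(opj));
}

// ---------------------------------------------------------------------------
// Pairwise identity over rows of an aligned integer matrix.
// identity = matches / shared columns. A column is shared unless either
// row carries the `misscode` (outside that sequence's aligned span) or
// both rows are gaps; a residue against an internal gap counts as a
// difference.
// ---------------------------------------------------------------------------
// [[Rcpp::export]]
NumericMatrix cpp_pairwise_identity(IntegerMatrix seqs, int gapcode,
                                    int misscode) {
  const int n = seqs.nrow(), L = seqs.ncol();
  // row-major copy for cache-friendly pair scans
  std::vector<int> X((size_t)n * L);
  for (int a = 0; a < n; ++a)
    for (int k = 0; k < L; ++k) X[(size_t)a * L + k] = seqs(a, k);
  NumericMatrix out(n, n);
  for (int a = 0; a < n; ++a) {
    out(a, a) = 1.0;
    const int *xa = &X[(size_t)a * L];
    for (int b = a + 1; b < n; ++b) {
      const int *xb = &X[(size_t)b * L];
      int match = 0, cols = 0;
      for (int k = 0; k < L; ++k) {
        const int x = xa[k], y = xb[k];
        if (x == misscode || y == misscode) continue;
        if (x == gapcode && y == gapcode) continue;
        ++cols;
        if (x == y) ++match;
      }
      double id = cols > 0 ? (double)match / cols : 0.0;
      out(a, b) = id; out(b, a) = id;
    }
  }
  return out;
}

// Mismatch counts of a degenerate primer (bitmask per position) along a
// bitmask-encoded template; returns counts for every start offset.
// [[Rcpp::export]]
IntegerVector cpp_primer_scan(IntegerVector tmpl, IntegerVector primer) {
  const int L = tmpl.size(), K = primer.size();
  if (L < K) return IntegerVector(0);
  IntegerVector out(L - K + 1);
  for (int s = 0; s <= L - K; ++s) {
    int mm = 0;
    for (int k = 0; k < K; ++k)
      if ((tmpl[s + k] & primer[k]) == 0) ++mm;
    out[s] = mm;
  }
  return out;
}
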