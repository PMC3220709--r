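#include <Rcpp.h>
using namespace Rcpp;

// Glocal (global in model, local in sequence) profile-HMM dynamic programming.
//
// The model must be traversed from column 1 to column M (through match or
// delete states); any contiguous subsequence of the target may be consumed.
// Flanking residues and insert-state emissions are scored against the same
// background as the null model, so their emission terms cancel and only the
// core log-odds matrix `mlo` (M x L, natural log of match emission over
// background) plus transition log-probabilities enter the recursion.
//
// Transition vectors are length M, entry k (0-based k-1) holding the
// out-transitions of column k: MM_k = M_k -> M_{k+1} (k = M: M_M -> E),
// MI_k = M_k -> I_k, MD_k = M_k -> D_{k+1}, IM_k / II_k for insert state k,
// DM_k = D_k -> M_{k+1} (k = M: D_M -> E), DD_k = D_k -> D_{k+1}.
// lbm / lbd are log P(B -> M_1) and log P(B -> D_1).
//
// Paths that consume zero residues (pure delete chains B->D_1..D_M->E) are
// excluded: entry into the model is folded into a closed-form "delayed
// entry" term that always lands on an emitting match state, so every path is
// anchored exactly once and has a well-defined envelope.

static inline double lse2(double a, double b) {
  if (a == R_NegInf) return b;
  if (b == R_NegInf) return a;
  double m = a > b ? a : b;
  return m + std::log(std::exp(a - m) + std::exp(b - m));
}

// entry_M[k]: log prob of B -> (D_1 .. D_{k-1}) -> M_k
static std::vector<double> entry_terms(int M, double lbm, double lbd,
                                       const NumericVector& ltDM,
                                       const NumericVector& ltDD) {
  std::vector<double> ent(M);
  ent[0] = lbm;
  double chain = lbd; // log P(B -> D_1)
  for (int k = 1; k < M; ++k) {
    ent[k] = chain + ltDM[k - 1];
    chain += ltDD[k - 1];
  }
  return ent;
}

// [[Rcpp::export(name = ".cpp_glocal_viterbi")]]
List cpp_glocal_viterbi(NumericMatrix mlo,
                        NumericVector ltMM, NumericVector ltMI, NumericVector ltMD,
                        NumericVector ltIM, NumericVector ltII,
                        NumericVector ltDM, NumericVector ltDD,
                        double lbm, double lbd) {
  const int M = mlo.nrow(), L = mlo.ncol();
  std::vector<double> ent = entry_terms(M, lbm, lbd, ltDM, ltDD);

  NumericMatrix VM(M, L), VI(M, L), VD(M, L);
  IntegerMatrix SM(M, L), SI(M, L), SD(M, L);
  std::fill(VM.begin(), VM.end(), R_NegInf);
  std::fill(VI.begin(), VI.end(), R_NegInf);
  std::fill(VD.begin(), VD.end(), R_NegInf);

  for (int j = 0; j < L; ++j) {
    for (int k = 0; k < M; ++k) {
      // match state M_{k+1} emitting residue j+1
      double best = ent[k];
      int src = j + 1; // envelope starts here (1-based)
      if (k > 0 && j > 0) {
        double a = VM(k - 1, j - 1) + ltMM[k - 1];
        if (a > best) { best = a; src = -SM(k - 1, j - 1); }
        double b = VI(k - 1, j - 1) + ltIM[k - 1];
        if (b > best) { best = b; src = -SI(k - 1, j - 1); }
        double c = VD(k - 1, j - 1) + ltDM[k - 1];
        if (c > best) { best = c; src = -SD(k - 1, j - 1); }
      }
      VM(k, j) = mlo(k, j) + best;
      SM(k, j) = src < 0 ? -src : src;
      // delete state D_{k+1} (no emission), entered after >=1 emission
      if (k > 0) {
        double a = VM(k - 1, j) + ltMD[k - 1];
        double b = VD(k - 1, j) + ltDD[k - 1];
        if (a >= b) { VD(k, j) = a; SD(k, j) = SM(k - 1, j); }
        else        { VD(k, j) = b; SD(k, j) = SD(k - 1, j); }
      }
      // insert state I_{k+1} (background emission, log-odds 0), k+1 < M
      if (k < M - 1 && j > 0) {
        double a = VM(k, j - 1) + ltMI[k];
        double b = VI(k, j - 1) + ltII[k];
        if (a >= b) { VI(k, j) = a; SI(k, j) = SM(k, j - 1); }
        else        { VI(k, j) = b; SI(k, j) = SI(k, j - 1); }
      }
    }
  }

  double best = R_NegInf;
  int bstart = NA_INTEGER, bend = NA_INTEGER;
  for (int j = 0; j < L; ++j) {
    double em = VM(M - 1, j) + ltMM[M - 1]; // M_M -> E
    if (em > best) { best = em; bstart = SM(M - 1, j); bend = j + 1; }
    double ed = VD(M - 1, j) + ltDM[M - 1]; // D_M -> E
    if (ed > best) { best = ed; bstart = SD(M - 1, j); bend = j + 1; }
  }
  return List::create(_["score_nats"] = best,
                      _["start"] = bstart, _["end"] = bend);
}

// [[Rcpp::export(name = ".cpp_glocal_forward")]]
double cpp_glocal_forward(NumericMatrix mlo,
                          NumericVector ltMM, NumericVector ltMI, NumericVector ltMD,
                          NumericVector ltIM, NumericVector ltII,
                          NumericVector ltDM, NumericVector ltDD,
                          double lbm, double lbd) {
  const int M = mlo.nrow(), L = mlo.ncol();
  std::vector<double> ent = entry_terms(M, lbm, lbd, ltDM, ltDD);

  NumericMatrix VM(M, L), VI(M, L), VD(M, L);
  std::fill(VM.begin(), VM.end(), R_NegInf);
  std::fill(VI.begin(), VI.end(), R_NegInf);
  std::fill(VD.begin(), VD.end(), R_NegInf);

  for (int j = 0; j < L; ++j) {
    for (int k = 0; k < M; ++k) {
      double acc = ent[k];
      if (k > 0 && j > 0) {
        acc = lse2(acc, VM(k - 1, j - 1) + ltMM[k - 1]);
        acc = lse2(acc, VI(k - 1, j - 1) + ltIM[k - 1]);
        acc = lse2(acc, VD(k - 1, j - 1) + ltDM[k - 1]);
      }
      VM(k, j) = mlo(k, j) + acc;
      if (k > 0)
        VD(k, j) = lse2(VM(k - 1, j) + ltMD[k - 1], VD(k - 1, j) + ltDD[k - 1]);
      if (k < M - 1 && j > 0)
        VI(k, j) = lse2(VM(k, j - 1) + ltMI[k], VI(k, j - 1) + ltII[k]);
    }
  }

  double tot = R_NegInf;
  for (int j = 0; j < L; ++j) {
    tot = lse2(tot, VM(M - 1, j) + ltMM[M - 1]);
    tot = lse2(tot, VD(M - 1, j) + ltDM[M - 1]);
  }
  return tot;
}
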