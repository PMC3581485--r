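// Core dynamic programming for a local multihit profile HMM, scored in bits
// against a length-matched null model.
//
// Model layout (0-based node index k = 0..M-1):
//   match M_k, insert I_k (k <= M-2), delete D_k (k >= 1).
//   Specials: N (leading flank), B (begin), E (end), J (between passes),
//   C (trailing flank), all emitting background residues, so their emission
//   log-odds are zero and only transition costs enter the recursion.
//   Entry is uniform B -> M_k (prob 1/M); exit is M_k -> E (per-node prob,
//   free at the last node) plus D_{M-1} -> E.  N/C/J self-loop probability is
//   configured from the target length L as L/(L+2); the null model emits L
//   background residues with a geometric length term L/(L+1).
//
// Emissions are passed as log-odds (log e/bg); column 20 is the wildcard X,
// which scores zero everywhere.  All arithmetic is in natural log space;
// scores are converted to bits at the end.

#include <Rcpp.h>
#include <cmath>
#include <vector>
#include <limits>
using namespace Rcpp;

static const double NEG_INF = -std::numeric_limits<double>::infinity();

static inline double lse2(double a, double b) {
  if (a == NEG_INF) return b;
  if (b == NEG_INF) return a;
  if (a > b) return a + std::log1p(std::exp(b - a));
  return b + std::log1p(std::exp(a - b));
}

struct Model {
  int M;
  NumericMatrix lm;                    // M x 21 match emission log-odds
  NumericVector ltmm, ltmi, ltmd, ltme, ltim, ltii, ltdm, ltdd;
  double lpej, lpec;                   // E -> J, E -> C
};

static Model unpack(const List& model) {
  Model m;
  m.M    = as<int>(model["m"]);
  m.lm   = as<NumericMatrix>(model["lm"]);
  m.ltmm = as<NumericVector>(model["ltmm"]);
  m.ltmi = as<NumericVector>(model["ltmi"]);
  m.ltmd = as<NumericVector>(model["ltmd"]);
  m.ltme = as<NumericVector>(model["ltme"]);
  m.ltim = as<NumericVector>(model["ltim"]);
  m.ltii = as<NumericVector>(model["ltii"]);
  m.ltdm = as<NumericVector>(model["ltdm"]);
  m.ltdd = as<NumericVector>(model["ltdd"]);
  m.lpej = as<double>(model["lpej"]);
  m.lpec = as<double>(model["lpec"]);
  return m;
}

// null model length correction: L residues, geometric L/(L+1)
static inline double null_length_nats(int L) {
  double p = (double)L / (L + 1.0);
  return L * std::log(p) + std::log(1.0 - p);
}

static double forward_nats_impl(const Model& mo, const IntegerVector& seq) {
  const int M = mo.M, L = seq.size();
  const double pLoop = (double)L / (L + 2.0);
  const double lLoop = std::log(pLoop), lMove = std::log(1.0 - pLoop);
  const double lBM = -std::log((double)M);

  std::vector<double> matp(M, NEG_INF), matc(M, NEG_INF),
      insp(M, NEG_INF), insc(M, NEG_INF),
      delp(M, NEG_INF), delc(M, NEG_INF);
  double Np = 0.0, Bp = lMove, Jp = NEG_INF, Cp = NEG_INF;

  for (int i = 0; i < L; ++i) {
    const int x = seq[i];
    for (int k = 0; k < M; ++k) {
      double v = Bp + lBM;
      if (k > 0) {
        v = lse2(v, matp[k - 1] + mo.ltmm[k - 1]);
        v = lse2(v, insp[k - 1] + mo.ltim[k - 1]);
        if (mo.ltdm[k - 1] != NEG_INF)
          v = lse2(v, delp[k - 1] + mo.ltdm[k - 1]);
      }
      matc[k] = mo.lm(k, x) + v;
    }
    delc[0] = NEG_INF;
    for (int k = 1; k < M; ++k) {
      double v = matc[k - 1] + mo.ltmd[k - 1];
      if (k > 1 && mo.ltdd[k - 1] != NEG_INF)
        v = lse2(v, delc[k - 1] + mo.ltdd[k - 1]);
      delc[k] = v;
    }
    for (int k = 0; k < M - 1; ++k)
      insc[k] = lse2(matp[k] + mo.ltmi[k], insp[k] + mo.ltii[k]);

    double E = NEG_INF;
    for (int k = 0; k < M; ++k) E = lse2(E, matc[k] + mo.ltme[k]);
    if (M > 1) E = lse2(E, delc[M - 1]);   // D_M -> E, prob 1

    const double Jc = lse2(Jp + lLoop, E + mo.lpej);
    const double Cc = lse2(Cp + lLoop, E + mo.lpec);
    const double Nc = Np + lLoop;
    const double Bc = lse2(Nc + lMove, Jc + lMove);

    matp.swap(matc); insp.swap(insc); delp.swap(delc);
    std::fill(insc.begin(), insc.end(), NEG_INF);
    Np = Nc; Bp = Bc; Jp = Jc; Cp = Cc;
  }
  return Cp + lMove - null_length_nats(L);
}

// [[Rcpp::export]]
NumericVector forward_bits_cpp(List model, List seqs) {
  Model mo = unpack(model);
  const int n = seqs.size();
  NumericVector out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    if (sq.size() < 1) stop("empty sequence at index %d", s + 1);
    out[s] = forward_nats_impl(mo, sq) / M_LN2;
  }
  return out;
}

// ---------------------------------------------------------------------------
// Viterbi with traceback.
//
// Tie-breaking: candidate predecessors are evaluated in the order
// match > delete > insert > begin-entry and replaced only on strict
// improvement, which makes envelopes deterministic.

// backpointer codes
enum { BP_M = 0, BP_D = 1, BP_I = 2, BP_B = 3, BP_LOOP = 0, BP_E = 1 };

static List viterbi_one(const Model& mo, const IntegerVector& seq,
                        const std::string& alpha) {
  const int M = mo.M, L = seq.size();
  const double pLoop = (double)L / (L + 2.0);
  const double lLoop = std::log(pLoop), lMove = std::log(1.0 - pLoop);
  const double lBM = -std::log((double)M);

  // full matrices, (L+1) x M, row 0 = before any emission
  const int R = L + 1;
  std::vector<double> vm((size_t)R * M, NEG_INF), vi((size_t)R * M, NEG_INF),
      vd((size_t)R * M, NEG_INF);
  std::vector<signed char> bm((size_t)R * M, -1), bi((size_t)R * M, -1),
      bd((size_t)R * M, -1);
  std::vector<double> vN(R, NEG_INF), vB(R, NEG_INF), vJ(R, NEG_INF),
      vC(R, NEG_INF), vE(R, NEG_INF);
  std::vector<int> bE(R, -1);
  std::vector<signed char> bB(R, -1), bJ(R, -1), bC(R, -1);

  vN[0] = 0.0; vB[0] = lMove; bB[0] = 0;
  auto ix = [M](int i, int k) { return (size_t)i * M + k; };

  for (int i = 1; i <= L; ++i) {
    const int x = seq[i - 1];
    for (int k = 0; k < M; ++k) {
      // order: M, D, I, B with strict improvement
      double best = NEG_INF; int bp = -1;
      if (k > 0) {
        double c = vm[ix(i - 1, k - 1)] + mo.ltmm[k - 1];
        if (c > best) { best = c; bp = BP_M; }
        if (mo.ltdm[k - 1] != NEG_INF) {
          c = vd[ix(i - 1, k - 1)] + mo.ltdm[k - 1];
          if (c > best) { best = c; bp = BP_D; }
        }
        c = vi[ix(i - 1, k - 1)] + mo.ltim[k - 1];
        if (c > best) { best = c; bp = BP_I; }
      }
      double c = vB[i - 1] + lBM;
      if (c > best) { best = c; bp = BP_B; }
      vm[ix(i, k)] = mo.lm(k, x) + best;
      bm[ix(i, k)] = bp;
    }
    for (int k = 1; k < M; ++k) {
      double best = vm[ix(i, k - 1)] + mo.ltmd[k - 1]; int bp = BP_M;
      if (k > 1 && mo.ltdd[k - 1] != NEG_INF) {
        double c = vd[ix(i, k - 1)] + mo.ltdd[k - 1];
        if (c > best) { best = c; bp = BP_D; }
      }
      vd[ix(i, k)] = best; bd[ix(i, k)] = (signed char)bp;
    }
    for (int k = 0; k < M - 1; ++k) {
      double best = vm[ix(i - 1, k)] + mo.ltmi[k]; int bp = BP_M;
      double c = vi[ix(i - 1, k)] + mo.ltii[k];
      if (c > best) { best = c; bp = BP_I; }
      vi[ix(i, k)] = best; bi[ix(i, k)] = (signed char)bp;
    }
    double E = NEG_INF; int bpk = -1;
    for (int k = 0; k < M; ++k) {
      double c = vm[ix(i, k)] + mo.ltme[k];
      if (c > E) { E = c; bpk = k; }
    }
    if (M > 1 && vd[ix(i, M - 1)] > E) { E = vd[ix(i, M - 1)]; bpk = M; }
    vE[i] = E; bE[i] = bpk;

    double Jv = vJ[i - 1] + lLoop; signed char Jb = BP_LOOP;
    if (E + mo.lpej > Jv) { Jv = E + mo.lpej; Jb = BP_E; }
    vJ[i] = Jv; bJ[i] = Jb;
    double Cv = vC[i - 1] + lLoop; signed char Cb = BP_LOOP;
    if (E + mo.lpec > Cv) { Cv = E + mo.lpec; Cb = BP_E; }
    vC[i] = Cv; bC[i] = Cb;
    vN[i] = vN[i - 1] + lLoop;
    double Bv = vN[i] + lMove; signed char Bb = 0;
    if (vJ[i] + lMove > Bv) { Bv = vJ[i] + lMove; Bb = 1; }
    vB[i] = Bv; bB[i] = Bb;
  }

  const double score_nats = vC[L] + lMove - null_length_nats(L);

  // traceback
  std::vector<int> d_start, d_end, d_kstart, d_kend;
  std::vector<double> d_score;
  std::vector<std::string> d_aln;

  int i = L;
  // walk trailing C loops back to the E that ends the last pass; every
  // complete path contains at least one B -> ... -> E pass
  while (i > 1 && bC[i] == BP_LOOP) --i;
  bool have_pass = (bC[i] == BP_E);
  while (have_pass) {
    // a pass ends at row i
    const int env_end = i;
    const double exit_val = vE[i];
    std::string aln((size_t)M, '-');
    const int kq = bE[i];
    int k, cur; // cur: 0=M, 1=D, 2=I
    if (kq == M) { // exited via D_M: descend delete chain at row i
      k = M - 1; cur = 1;
    } else { k = kq; cur = 0; }
    const int kend = (kq == M) ? M - 1 : kq;
    int env_start = -1, kstart = -1;
    double entry_B = NEG_INF;
    bool done = false;
    while (!done) {
      if (cur == 0) { // match at (i,k): emitted residue i
        aln[k] = alpha[seq[i - 1] <= 20 ? seq[i - 1] : 20];
        const int bp = bm[ix(i, k)];
        if (bp == BP_B) {
          env_start = i; kstart = k; entry_B = vB[i - 1];
          i = i - 1; done = true;
        } else if (bp == BP_M) { --i; --k; }
        else if (bp == BP_D) { --i; --k; cur = 1; }
        else { --i; --k; cur = 2; }
      } else if (cur == 1) { // delete at (i,k): no emission
        aln[k] = '-';
        const int bp = bd[ix(i, k)];
        if (bp == BP_M) { --k; cur = 0; }
        else { --k; }
      } else { // insert at (i,k): emitted residue i, not a model column
        const int bp = bi[ix(i, k)];
        if (bp == BP_M) { --i; cur = 0; }
        else { --i; }
      }
    }
    d_start.push_back(env_start); d_end.push_back(env_end);
    d_kstart.push_back(kstart + 1); d_kend.push_back(kend + 1);
    d_score.push_back((exit_val - entry_B) / M_LN2);
    d_aln.push_back(aln);
    // now at B[i]; the pass was entered from N (done) or from J
    if (bB[i] != 1) break;
    while (i > 1 && bJ[i] == BP_LOOP) --i;
    have_pass = (bJ[i] == BP_E);
  }

  // domains were collected right-to-left
  const int nd = d_start.size();
  IntegerVector env_start(nd), env_end(nd), k_start(nd), k_end(nd);
  NumericVector dscore(nd);
  CharacterVector daln(nd);
  for (int q = 0; q < nd; ++q) {
    int r = nd - 1 - q;
    env_start[q] = d_start[r]; env_end[q] = d_end[r];
    k_start[q] = d_kstart[r]; k_end[q] = d_kend[r];
    dscore[q] = d_score[r]; daln[q] = d_aln[r];
  }
  return List::create(_["score"] = score_nats / M_LN2,
                      _["env_start"] = env_start, _["env_end"] = env_end,
                      _["k_start"] = k_start, _["k_end"] = k_end,
                      _["domain_score"] = dscore, _["aligned"] = daln);
}

// [[Rcpp::export]]
List viterbi_cpp(List model, List seqs, std::string alphabet) {
  Model mo = unpack(model);
  const int n = seqs.size();
  List out(n);
  for (int s = 0; s < n; ++s) {
    IntegerVector sq = seqs[s];
    if (sq.size() < 1) stop("empty sequence at index %d", s + 1);
    out[s] = viterbi_one(mo, sq, alphabet);
  }
  return out;
}
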