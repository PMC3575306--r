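#include <Rcpp.h>
#include <vector>
#include <limits>
using namespace Rcpp;

// Protein-anchored spliced alignment of a genomic fragment against a
// homologous reference protein.
//
// Model: the fragment is a chain of ungapped coding exons separated by
// introns with canonical donor/acceptor dinucleotides (GT..AG; optionally
// GC donors). Exons are collinear with the reference: coding base number c
// of the fragment corresponds to reference coding coordinate c (reference
// protein residue c/3). The DP maximises the summed substitution score of
// translated codons against the reference minus a fixed per-intron penalty.
//
// State: S[i][c] = best score of a parse of genomic[0..i) that has emitted
// reference coding coordinates [c0..c) for some free start offset c0
// (semi-global in the reference, global in the genomic fragment).
// Transitions:
//  * coding: consume genomic base i as coding coordinate c; when c+1
//    completes a codon, add the substitution score of the translated codon
//    (bases are contiguous in the genomic because intron jumps themselves
//    complete any split codon and land on a codon boundary).
//  * intron: from a donor at i with within-codon phase r = c mod 3, jump to
//    any acceptor end a (a - i >= min_intron). For r > 0 the split codon is
//    scored at the jump from the r bases before the donor plus the 3-r
//    bases after the acceptor, landing at the next codon boundary.
// Ties are broken towards the leftmost donor (first writer wins on equal
// score, and donors are processed left to right).
//
// g: 0=A,1=C,2=G,3=T,4=other. ref: 0-based rows of submat. codon_aa maps
// codon index b0*16+b1*4+b2 -> submat row (64 entries); codons containing a
// non-ACGT base use aa_x.

static const double NEG = -1e30;

// [[Rcpp::export]]
List spliced_align_cpp(IntegerVector g, IntegerVector ref,
                       NumericMatrix submat, IntegerVector codon_aa,
                       int aa_x, int min_intron, double intron_penalty,
                       bool allow_gc_donor = false) {
  const int n = g.size();
  const int m = ref.size();
  const int C = 3 * m;
  const int W = C + 1;

  std::vector<double> S((size_t)(n + 1) * W, NEG);
  // backpointers: type 0 none, 1 coding, 2 jump phase 0, 3 jump phase r>0
  std::vector<signed char> ptype((size_t)(n + 1) * W, -1);
  std::vector<int> pdon((size_t)(n + 1) * W, -1);
  std::vector<signed char> pr((size_t)(n + 1) * W, 0);

  for (int c = 0; c <= C; ++c) {
    S[c] = 0.0;
    ptype[c] = 0;
  }

  // acceptor ends: positions a with g[a-2]=='A' and g[a-1]=='G'
  std::vector<int> acc;
  for (int a = 2; a <= n; ++a) {
    if (g[a - 2] == 0 && g[a - 1] == 2) acc.push_back(a);
  }

  auto aa_of = [&](int b0, int b1, int b2) -> int {
    if (b0 > 3 || b1 > 3 || b2 > 3) return aa_x;
    return codon_aa[b0 * 16 + b1 * 4 + b2];
  };

  for (int i = 0; i <= n; ++i) {
    const size_t row = (size_t)i * W;
    const bool is_donor =
        (i + 1 < n) && g[i] == 2 && (g[i + 1] == 3 || (allow_gc_donor && g[i + 1] == 1));
    for (int c = 0; c <= C; ++c) {
      const double s0 = S[row + c];
      if (s0 <= NEG / 2) continue;
      // coding transition
      if (i < n && c < C) {
        double v = s0;
        if ((c + 1) % 3 == 0 && i >= 2) {
          v += submat(aa_of(g[i - 2], g[i - 1], g[i]), ref[(c + 1) / 3 - 1]);
        }
        const size_t t = (size_t)(i + 1) * W + (c + 1);
        if (v > S[t]) {
          S[t] = v;
          ptype[t] = 1;
        }
      }
      // intron jumps from a donor at i
      if (is_donor) {
        const int r = c % 3;
        if (r > 0 && i - r < 0) continue;
        for (size_t k = 0; k < acc.size(); ++k) {
          const int a = acc[k];
          if (a - i < min_intron) continue;
          if (r == 0) {
            const size_t t = (size_t)a * W + c;
            const double v = s0 - intron_penalty;
            if (v > S[t]) {
              S[t] = v;
              ptype[t] = 2;
              pdon[t] = i;
              pr[t] = 0;
            }
          } else {
            if (a + 3 - r > n || c - r + 3 > C) continue;
            int b[3];
            for (int q = 0; q < r; ++q) b[q] = g[i - r + q];
            for (int q = r; q < 3; ++q) b[q] = g[a + q - r];
            double v = s0 - intron_penalty +
                       submat(aa_of(b[0], b[1], b[2]), ref[(c - r) / 3]);
            const size_t t = (size_t)(a + 3 - r) * W + (c + 3 - r);
            if (v > S[t]) {
              S[t] = v;
              ptype[t] = 3;
              pdon[t] = i;
              pr[t] = (signed char)r;
            }
          }
        }
      }
    }
  }

  // best end state: genomic fully consumed, free reference end
  int cbest = -1;
  double best = NEG;
  const size_t rown = (size_t)n * W;
  for (int c = 0; c <= C; ++c) {
    if (S[rown + c] > best) {
      best = S[rown + c];
      cbest = c;
    }
  }
  if (cbest < 0) {
    return List::create(_["score"] = NA_REAL);
  }

  // traceback
  std::vector<int> istart, iend, cdon;
  int i = n, c = cbest;
  while (true) {
    const size_t t = (size_t)i * W + c;
    const int tp = ptype[t];
    if (tp == 0) break;
    if (tp == 1) {
      --i;
      --c;
    } else if (tp == 2) {
      istart.push_back(pdon[t]);
      iend.push_back(i);
      cdon.push_back(c);
      i = pdon[t];
    } else {  // tp == 3: landed at a + 3 - r
      const int r = pr[t];
      const int a = i - (3 - r);
      istart.push_back(pdon[t]);
      iend.push_back(a);
      cdon.push_back(c - (3 - r));
      i = pdon[t];
      c -= (3 - r);
    }
  }
  const int c0 = c;
  std::reverse(istart.begin(), istart.end());
  std::reverse(iend.begin(), iend.end());
  std::reverse(cdon.begin(), cdon.end());

  return List::create(_["score"] = best, _["c0"] = c0, _["cend"] = cbest,
                      _["intron_start"] = wrap(istart),
                      _["intron_end"] = wrap(iend),
                      _["c_at_donor"] = wrap(cdon));
}
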