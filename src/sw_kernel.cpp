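#include <Rcpp.h>
using namespace Rcpp;

// Sentinel for the undefined E/F gap states on the matrix border.  Chosen so
// that repeated subtraction of gap penalties cannot underflow 32-bit range.
static const int NEG_SENTINEL = -(1 << 28);

// Substitution score for integer-encoded residues.  Code 0 is the wildcard
// ('N' under the DNA alphabet): it scores as a mismatch against everything,
// including itself.
static inline int sub_score(int a, int b, int match, int mismatch) {
  return (a == b && a > 0) ? match : mismatch;
}

//' @useDynLib wavealign, .registration = TRUE
//' @importFrom Rcpp evalCpp
// [[Rcpp::export(name = ".sw_block_kernel")]]
List sw_block_kernel(IntegerVector pcode, IntegerVector qcode,
                     IntegerVector top_H, IntegerVector top_F,
                     IntegerVector left_H, IntegerVector left_E,
                     int corner_H,
                     int match, int mismatch, int goe, int ge,
                     bool keep_tile) {
  const int mb = pcode.size();
  const int nb = qcode.size();
  if (mb < 1 || nb < 1)
    stop("block slices must be non-empty");
  if (top_H.size() != nb || top_F.size() != nb)
    stop("top halo length %d does not match block width %d",
         (int)top_H.size(), nb);
  if (left_H.size() != mb || left_E.size() != mb)
    stop("left halo length %d does not match block height %d",
         (int)left_H.size(), mb);

  std::vector<int> Hprev(top_H.begin(), top_H.end());
  std::vector<int> Fprev(top_F.begin(), top_F.end());
  std::vector<int> Hcur(nb), Fcur(nb);

  IntegerVector right_H(mb), right_E(mb);
  IntegerMatrix Ht, Et, Ft;
  if (keep_tile) {
    Ht = IntegerMatrix(mb, nb);
    Et = IntegerMatrix(mb, nb);
    Ft = IntegerMatrix(mb, nb);
  }

  // Local maximum: strict '>' with row-major scan keeps the smallest (i, j)
  // among ties, matching the global tie rule after offsetting.
  int best = -1, best_i = 1, best_j = 1;

  for (int i = 0; i < mb; ++i) {
    const int pi = pcode[i];
    // H(i-1, j-1) for j = 0 comes from the left halo (or the corner).
    int Hdiag = (i == 0) ? corner_H : left_H[i - 1];
    int Hleft = left_H[i];
    int Eleft = left_E[i];
    for (int j = 0; j < nb; ++j) {
      const int s  = sub_score(pi, qcode[j], match, mismatch);
      const int E  = std::max(Hleft - goe, Eleft - ge);
      const int F  = std::max(Hprev[j] - goe, Fprev[j] - ge);
      int H = Hdiag + s;
      if (E > H) H = E;
      if (F > H) H = F;
      if (H < 0) H = 0;
      if (H > best) { best = H; best_i = i + 1; best_j = j + 1; }
      Hdiag = Hprev[j];
      Hcur[j] = H; Fcur[j] = F;
      Hleft = H; Eleft = E;
      if (keep_tile) { Ht(i, j) = H; Et(i, j) = E; Ft(i, j) = F; }
    }
    right_H[i] = Hcur[nb - 1];
    right_E[i] = Eleft;
    std::swap(Hprev, Hcur);
    std::swap(Fprev, Fcur);
  }

  List out = List::create(
    _["bottom_H"] = IntegerVector(Hprev.begin(), Hprev.end()),
    _["bottom_F"] = IntegerVector(Fprev.begin(), Fprev.end()),
    _["right_H"] = right_H,
    _["right_E"] = right_E,
    _["out_corner_H"] = Hprev[nb - 1],
    _["local_max"] = IntegerVector::create(best, best_i, best_j));
  if (keep_tile) {
    out["H"] = Ht;
    out["E"] = Et;
    out["F"] = Ft;
  }
  return out;
}

// [[Rcpp::export(name = ".neg_sentinel")]]
int neg_sentinel() { return NEG_SENTINEL; }
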