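#include <Rcpp.h>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

// Greedy alignment-based cosine for one spectrum pair. Candidate fragment
// pairs with |dm/z| <= tolerance (inclusive) are sorted by intensity product
// descending (ties: smaller |dm/z|, then lower first-spectrum index, then
// lower second-spectrum index) and accepted greedily, each fragment at most
// once. Inputs must be sorted by m/z and unit-normalized upstream.
struct Cand {
  double prod;
  double dmz;
  int i, j;
};

static void pair_score(const double* mza, const double* inta, int na,
                       const double* mzb, const double* intb, int nb,
                       double tol, double& score, int& matches) {
  score = 0.0;
  matches = 0;
  if (na == 0 || nb == 0) return;
  std::vector<Cand> cands;
  int lo = 0;
  for (int i = 0; i < na; ++i) {
    while (lo < nb && mzb[lo] < mza[i] - tol) ++lo;
    for (int j = lo; j < nb && mzb[j] <= mza[i] + tol; ++j) {
      Cand c;
      c.prod = inta[i] * intb[j];
      c.dmz = std::fabs(mza[i] - mzb[j]);
      c.i = i;
      c.j = j;
      cands.push_back(c);
    }
  }
  if (cands.empty()) return;
  std::sort(cands.begin(), cands.end(), [](const Cand& a, const Cand& b) {
    if (a.prod != b.prod) return a.prod > b.prod;
    if (a.dmz != b.dmz) return a.dmz < b.dmz;
    if (a.i != b.i) return a.i < b.i;
    return a.j < b.j;
  });
  std::vector<char> ua(na, 0), ub(nb, 0);
  for (const Cand& c : cands) {
    if (!ua[c.i] && !ub[c.j]) {
      ua[c.i] = 1;
      ub[c.j] = 1;
      score += c.prod;
      ++matches;
    }
  }
}

// [[Rcpp::export]]
List greedy_cosine_all_cpp(List mzq, List intq, List mzr, List intr,
                           double tolerance) {
  const int nq = mzq.size(), nr = mzr.size();
  std::vector<NumericVector> MQ, IQ, MR, IR;
  MQ.reserve(nq); IQ.reserve(nq); MR.reserve(nr); IR.reserve(nr);
  for (int i = 0; i < nq; ++i) {
    MQ.push_back(as<NumericVector>(mzq[i]));
    IQ.push_back(as<NumericVector>(intq[i]));
  }
  for (int j = 0; j < nr; ++j) {
    MR.push_back(as<NumericVector>(mzr[j]));
    IR.push_back(as<NumericVector>(intr[j]));
  }
  NumericMatrix scores(nq, nr);
  IntegerMatrix matches(nq, nr);
  for (int i = 0; i < nq; ++i) {
    const double* ma = MQ[i].begin();
    const double* ia = IQ[i].begin();
    const int na = MQ[i].size();
    for (int j = 0; j < nr; ++j) {
      double s;
      int m;
      pair_score(ma, ia, na, MR[j].begin(), IR[j].begin(), MR[j].size(),
                 tolerance, s, m);
      scores(i, j) = s;
      matches(i, j) = m;
    }
  }
  return List::create(_["scores"] = scores, _["matches"] = matches);
}
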