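#include <Rcpp.h>
#include "suffix_index.h"

using namespace Rcpp;

// [[Rcpp::export]]
SEXP sidx_build(std::string seq) {
  XPtr<SuffixIndex> xp(new SuffixIndex(), true);
  xp->seq.swap(seq);
  xp->build();
  return xp;
}

// Rebuild an index object from a block sequence and a previously computed
// suffix array (as persisted on disk); the chunked minima are recomputed.
// [[Rcpp::export]]
SEXP sidx_from_sa(std::string seq, IntegerVector sa) {
  if ((R_xlen_t)seq.size() != sa.size())
    stop("suffix array length (%d) does not match sequence length (%d)",
         (int)sa.size(), (int)seq.size());
  XPtr<SuffixIndex> xp(new SuffixIndex(), true);
  xp->seq.swap(seq);
  xp->sa.assign(sa.begin(), sa.end());
  xp->finish();
  return xp;
}

// [[Rcpp::export]]
IntegerVector sidx_sa(SEXP xp_) {
  XPtr<SuffixIndex> xp(xp_);
  return IntegerVector(xp->sa.begin(), xp->sa.end());
}

// [[Rcpp::export]]
int sidx_length(SEXP xp_) {
  XPtr<SuffixIndex> xp(xp_);
  return (int)xp->seq.size();
}

// [[Rcpp::export]]
std::string sidx_sequence(SEXP xp_) {
  XPtr<SuffixIndex> xp(xp_);
  return xp->seq;
}

// [[Rcpp::export]]
IntegerVector sidx_query(SEXP xp_, std::string query, int max_len = 0) {
  XPtr<SuffixIndex> xp(xp_);
  SuffixIndex::Match m = xp->query(query.data(), (long)query.size(), max_len);
  return IntegerVector::create(_["position"] = m.pos, _["length"] = m.len);
}
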