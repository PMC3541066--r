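#include <Rcpp.h>
#include "suffix_index.h"

using namespace Rcpp;

// ---- entry stream buffer -------------------------------------------------
// Columnar representation of the compressed entry stream:
//   type 0 = block change BC(id), 1 = relative match RM(pos, len), 2 = raw R(s)
//   a: BC -> block id; RM -> 0-based position in block; R -> 1-based index
//      into texts
//   b: RM -> match length; R -> text length; BC -> 0
struct EntryBuf {
  std::vector<int> type;
  std::vector<double> a, b;
  std::vector<std::string> texts;
  bool merge_raws;

  explicit EntryBuf(bool merge) : merge_raws(merge) {}

  void add_bc(int id) {
    type.push_back(0); a.push_back(id); b.push_back(0);
  }
  void add_rm(long pos, long len) {
    type.push_back(1); a.push_back((double)pos); b.push_back((double)len);
  }
  void add_raw(const char *s, long len) {
    if (len <= 0) return;
    if (merge_raws && !type.empty() && type.back() == 2) {
      texts.back().append(s, len);
      b.back() += (double)len;
      return;
    }
    texts.push_back(std::string(s, len));
    type.push_back(2);
    a.push_back((double)texts.size());
    b.push_back((double)len);
  }

  List as_list() const {
    List out = List::create(
      _["type"] = IntegerVector(type.begin(), type.end()),
      _["a"] = NumericVector(a.begin(), a.end()),
      _["b"] = NumericVector(b.begin(), b.end()),
      _["texts"] = CharacterVector(texts.begin(), texts.end()));
    out.attr("class") = "rgc_entries";
    return out;
  }
};

struct Params {
  int min_long_match;     // global matches must be strictly longer than this
  int raw_fallback_len;   // raw characters emitted when no block qualifies
  int local_match_len;    // window comparison length
  int li_lo, li_hi;       // input-offset window (ascending, outer loop)
  int lj_lo, lj_hi;       // reference-offset window (ascending, inner loop)
  bool greedy;            // stop the global search at the first acceptable block
  long max_query_len;     // cap on match queries (0 = uncapped)

  static Params from_list(List p) {
    Params q;
    q.min_long_match  = as<int>(p["min_long_match"]);
    q.raw_fallback_len = as<int>(p["raw_fallback_len"]);
    q.local_match_len = as<int>(p["local_match_len"]);
    IntegerVector li = p["local_input_window"], lj = p["local_ref_window"];
    q.li_lo = li[0]; q.li_hi = li[1];
    q.lj_lo = lj[0]; q.lj_hi = lj[1];
    q.greedy = as<std::string>(p["search_mode"]) == "greedy_first_acceptable";
    q.max_query_len = p.containsElementNamed("max_query_len")
      ? (long)as<double>(p["max_query_len"]) : 0L;
    return q;
  }
};

struct Counters {
  long long ref_cmp = 0;      // character comparisons in match extension
  long long local_cmp = 0;    // window comparisons in the local search
  long long global_queries = 0;
  long long raw_chars = 0;
};

struct CompState {
  const std::string *input;
  long p_in = 0;
  long p_raw = 0;
  int current_block = -1;
  RObject cur_holder;              // keeps the active index SEXP alive
  const SuffixIndex *cur = NULL;   // active reference block (and its index)
  Counters ops;

  void set_block(SEXP xp_, int id) {
    cur_holder = xp_;
    XPtr<SuffixIndex> xp(xp_);
    cur = xp.get();
    current_block = id;
  }
};

static inline bool is_normal(char c) {
  return c == 'A' || c == 'C' || c == 'G' || c == 'T';
}

// Maximal run of equal characters starting at (p_in, p_raw); emits one RM.
// Precondition: input(p_in) == block(p_raw).
static void encode_ref(CompState &st, EntryBuf &out) {
  const std::string &in = *st.input;
  const std::string &B = st.cur->seq;
  const long n = (long)in.size(), bn = (long)B.size();
  const long start = st.p_raw;
  while (st.p_in < n && st.p_raw < bn && in[st.p_in] == B[st.p_raw]) {
    ++st.p_in; ++st.p_raw;
  }
  st.ops.ref_cmp += (st.p_raw - start) + 1;
  out.add_rm(start, st.p_raw - start);
}

// Maximal run of non-{A,C,G,T} characters; emits one R.
// Precondition: input(p_in) not in {A,C,G,T}.
static void encode_raw(CompState &st, EntryBuf &out) {
  const std::string &in = *st.input;
  const long n = (long)in.size();
  const long start = st.p_in;
  while (st.p_in < n && !is_normal(in[st.p_in])) ++st.p_in;
  st.ops.raw_chars += st.p_in - start;
  out.add_raw(in.data() + start, st.p_in - start);
}

// Bounded window scan around (p_in, p_raw) resolving SNP/indel-sized
// mismatches. On the first (i, j) whose local_match_len-character windows
// agree: emit the skipped input (if any) raw, shift p_raw by j and extend
// referentially. Window comparisons that would read past either end are
// skipped. Returns false when no active block or no (i, j) qualifies.
static bool has_local_alternative(CompState &st, EntryBuf &out, const Params &P) {
  if (st.current_block < 0) return false;
  const std::string &in = *st.input;
  const std::string &B = st.cur->seq;
  const long n = (long)in.size(), bn = (long)B.size();
  const int L = P.local_match_len;
  for (int i = P.li_lo; i <= P.li_hi; ++i) {
    if (st.p_in + i + L > n) break;  // larger i reads further past the end
    for (int j = P.lj_lo; j <= P.lj_hi; ++j) {
      const long rp = st.p_raw + j;
      if (rp < 0 || rp + L > bn) continue;
      ++st.ops.local_cmp;
      if (std::memcmp(in.data() + st.p_in + i, B.data() + rp, L) == 0) {
        if (i >= 1) {
          out.add_raw(in.data() + st.p_in, i);
          st.ops.raw_chars += i;
          st.p_in += i;
        }
        st.p_raw = rp;
        encode_ref(st, out);
        return true;
      }
    }
  }
  return false;
}

// Global re-anchoring: local alternative first; otherwise query candidate
// blocks (traversal order supplied by the store) for the longest
// prefix-suffix match of the remaining input. A block qualifies only with a
// match strictly longer than min_long_match; on success emit BC (unless the
// block is unchanged) and reposition p_raw so the main loop's next
// extension starts at the match. Otherwise emit raw_fallback_len raw
// characters (clipped to the input end).
static void find_match(CompState &st, EntryBuf &out, const Params &P,
                       Function &fetch_index, Function &traversal) {
  if (has_local_alternative(st, out, P)) return;

  const std::string &in = *st.input;
  const long remaining = (long)in.size() - st.p_in;

  int best_len = 0, best_id = -1;
  long best_pos = 0;
  RObject best_holder;

  if (remaining > P.min_long_match) {
    SEXP curarg = st.current_block < 0 ? R_NilValue
                                       : (SEXP)wrap(st.current_block);
    IntegerVector ord = traversal(curarg);
    for (R_xlen_t k = 0; k < ord.size(); ++k) {
      const int id = ord[k];
      RObject holder = fetch_index(id);
      XPtr<SuffixIndex> xp((SEXP)holder);
      ++st.ops.global_queries;
      SuffixIndex::Match m =
        xp->query(in.data() + st.p_in, remaining, P.max_query_len);
      if (m.len > best_len) {
        best_len = m.len; best_pos = m.pos; best_id = id;
        best_holder = holder;
      }
      if (P.greedy && best_len > P.min_long_match) break;
    }
  }

  if (best_len > P.min_long_match) {
    if (best_id != st.current_block) out.add_bc(best_id);
    st.set_block(best_holder, best_id);
    st.p_raw = best_pos;
  } else {
    const long len = std::min((long)P.raw_fallback_len, remaining);
    out.add_raw(in.data() + st.p_in, len);
    st.ops.raw_chars += len;
    st.p_in += len;
  }
}

// Main greedy compression loop. fetch_index(id) must return an index
// external pointer for a global block id; traversal(current_or_NULL) the
// candidate block order.
// [[Rcpp::export]]
List rc_compress(std::string input, Function fetch_index, Function traversal,
                 List params, bool merge_raws = true) {
  const Params P = Params::from_list(params);
  EntryBuf out(merge_raws);
  CompState st;
  st.input = &input;
  const long n = (long)input.size();

  if (n > 0) {
    find_match(st, out, P, fetch_index, traversal);
    while (st.p_in != n) {
      if (st.cur && st.p_raw < (long)st.cur->seq.size() &&
          input[st.p_in] == st.cur->seq[st.p_raw]) {
        encode_ref(st, out);
      } else if (!is_normal(input[st.p_in])) {
        encode_raw(st, out);
      } else {
        find_match(st, out, P, fetch_index, traversal);
      }
    }
  }

  List entries = out.as_list();
  entries.attr("ops") = List::create(
    _["ref_cmp"] = (double)st.ops.ref_cmp,
    _["local_cmp"] = (double)st.ops.local_cmp,
    _["global_queries"] = (double)st.ops.global_queries,
    _["raw_chars"] = (double)st.ops.raw_chars);
  return entries;
}

// ---- standalone entry points for the individual subroutines --------------
// These wrap the same statics the main loop uses, so unit tests exercise
// the production code paths. Positions are 0-based.

// [[Rcpp::export]]
List rc_encode_ref(std::string input, double p_in, std::string block,
                   double p_raw) {
  SuffixIndex si;
  si.seq.swap(block);
  CompState st;
  st.input = &input;
  st.p_in = (long)p_in;
  st.p_raw = (long)p_raw;
  st.cur = &si;
  st.current_block = 0;
  if (st.p_in >= (long)input.size() || st.p_raw >= (long)si.seq.size() ||
      input[st.p_in] != si.seq[st.p_raw])
    stop("encode_ref requires input(p_in) == block(p_raw)");
  EntryBuf out(false);
  encode_ref(st, out);
  return List::create(_["entries"] = out.as_list(),
                      _["p_in"] = (double)st.p_in,
                      _["p_raw"] = (double)st.p_raw);
}

// [[Rcpp::export]]
List rc_encode_raw(std::string input, double p_in) {
  CompState st;
  st.input = &input;
  st.p_in = (long)p_in;
  if (st.p_in >= (long)input.size() || is_normal(input[st.p_in]))
    stop("encode_raw requires a non-{A,C,G,T} character at p_in");
  EntryBuf out(false);
  encode_raw(st, out);
  return List::create(_["entries"] = out.as_list(),
                      _["p_in"] = (double)st.p_in);
}

// [[Rcpp::export]]
List rc_has_local_alternative(std::string input, double p_in,
                              std::string block, double p_raw, List params) {
  const Params P = Params::from_list(params);
  SuffixIndex si;
  si.seq.swap(block);
  CompState st;
  st.input = &input;
  st.p_in = (long)p_in;
  st.p_raw = (long)p_raw;
  st.cur = &si;
  st.current_block = 0;
  EntryBuf out(false);
  const bool fired = has_local_alternative(st, out, P);
  return List::create(_["fired"] = fired,
                      _["entries"] = out.as_list(),
                      _["p_in"] = (double)st.p_in,
                      _["p_raw"] = (double)st.p_raw);
}

// [[Rcpp::export]]
List rc_find_match(std::string input, double p_in, int current_block,
                   double p_raw, Function fetch_index, Function traversal,
                   List params) {
  const Params P = Params::from_list(params);
  CompState st;
  st.input = &input;
  st.p_in = (long)p_in;
  st.p_raw = (long)p_raw;
  if (current_block >= 0) st.set_block(fetch_index(current_block), current_block);
  EntryBuf out(true);
  find_match(st, out, P, fetch_index, traversal);
  return List::create(_["entries"] = out.as_list(),
                      _["p_in"] = (double)st.p_in,
                      _["p_raw"] = (double)st.p_raw,
                      _["current_block"] = st.current_block);
}
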