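#include <Rcpp.h>
#include <map>

using namespace Rcpp;

// Entry payload encoding: one tag byte per entry (0 = BC, 1 = RM, 2 = R)
// followed by unsigned LEB128-style varints (base-128 groups, least
// significant first): BC -> block id; RM -> position, length; R -> byte
// length, then the raw bytes verbatim.

static void push_varint(std::vector<unsigned char> &out, unsigned long long v) {
  while (v >= 0x80) {
    out.push_back((unsigned char)((v & 0x7F) | 0x80));
    v >>= 7;
  }
  out.push_back((unsigned char)v);
}

static unsigned long long read_varint(const unsigned char *buf, R_xlen_t n,
                                      R_xlen_t &off) {
  unsigned long long v = 0;
  int shift = 0;
  for (;;) {
    if (off >= n)
      stop("truncated varint at byte offset %.0f", (double)off);
    const unsigned char byte = buf[off++];
    v |= (unsigned long long)(byte & 0x7F) << shift;
    if (!(byte & 0x80)) return v;
    shift += 7;
    if (shift > 63)
      stop("varint overflow at byte offset %.0f", (double)(off - 1));
  }
}

// [[Rcpp::export]]
RawVector rc_serialize_entries(List entries) {
  IntegerVector type = entries["type"];
  NumericVector a = entries["a"], b = entries["b"];
  CharacterVector texts = entries["texts"];
  std::vector<unsigned char> out;
  out.reserve(type.size() * 4);
  for (R_xlen_t i = 0; i < type.size(); ++i) {
    out.push_back((unsigned char)type[i]);
    switch (type[i]) {
    case 0:
      push_varint(out, (unsigned long long)a[i]);
      break;
    case 1:
      push_varint(out, (unsigned long long)a[i]);
      push_varint(out, (unsigned long long)b[i]);
      break;
    case 2: {
      const char *s = CHAR(STRING_ELT(texts, (R_xlen_t)a[i] - 1));
      const R_xlen_t len = (R_xlen_t)b[i];
      push_varint(out, (unsigned long long)len);
      out.insert(out.end(), s, s + len);
      break;
    }
    default:
      stop("unknown entry type %d", type[i]);
    }
  }
  RawVector rv(out.size());
  if (!out.empty()) std::copy(out.begin(), out.end(), rv.begin());
  return rv;
}

// [[Rcpp::export]]
List rc_deserialize_entries(RawVector payload) {
  const unsigned char *buf = payload.begin();
  const R_xlen_t n = payload.size();
  R_xlen_t off = 0;
  std::vector<int> type;
  std::vector<double> a, b;
  std::vector<std::string> texts;
  while (off < n) {
    const unsigned char tag = buf[off++];
    switch (tag) {
    case 0:
      type.push_back(0);
      a.push_back((double)read_varint(buf, n, off));
      b.push_back(0);
      break;
    case 1: {
      const double pos = (double)read_varint(buf, n, off);
      const double len = (double)read_varint(buf, n, off);
      type.push_back(1); a.push_back(pos); b.push_back(len);
      break;
    }
    case 2: {
      const unsigned long long len = read_varint(buf, n, off);
      if (off + (R_xlen_t)len > n)
        stop("truncated raw entry at byte offset %.0f", (double)off);
      texts.push_back(std::string((const char *)buf + off, (size_t)len));
      off += (R_xlen_t)len;
      type.push_back(2);
      a.push_back((double)texts.size());
      b.push_back((double)len);
      break;
    }
    default:
      stop("unknown entry tag %d at byte offset %.0f", (int)tag,
           (double)(off - 1));
    }
  }
  List out = List::create(
    _["type"] = IntegerVector(type.begin(), type.end()),
    _["a"] = NumericVector(a.begin(), a.end()),
    _["b"] = NumericVector(b.begin(), b.end()),
    _["texts"] = CharacterVector(texts.begin(), texts.end()));
  out.attr("class") = "rgc_entries";
  return out;
}

// 64-bit FNV-1a over a raw vector, reported as a 16-character hex string
// (payload integrity checksum inside the container).
// [[Rcpp::export]]
std::string rc_fnv1a64(RawVector bytes) {
  unsigned long long h = 1469598103934665603ULL;
  for (R_xlen_t i = 0; i < bytes.size(); ++i) {
    h ^= (unsigned long long)bytes[i];
    h *= 1099511628211ULL;
  }
  char out[17];
  snprintf(out, sizeof(out), "%016llx", h);
  return std::string(out);
}

// Replay an entry stream against raw reference blocks. fetch_block(id)
// returns the block sequence as a character scalar; no match index is
// needed for decompression.
// [[Rcpp::export]]
std::string rc_decompress_entries(List entries, Function fetch_block) {
  IntegerVector type = entries["type"];
  NumericVector a = entries["a"], b = entries["b"];
  CharacterVector texts = entries["texts"];
  std::map<int, std::string> cache;
  const std::string *cur = NULL;
  std::string out;
  double total = 0;
  for (R_xlen_t i = 0; i < type.size(); ++i)
    if (type[i] != 0) total += b[i];
  out.reserve((size_t)total);
  for (R_xlen_t i = 0; i < type.size(); ++i) {
    switch (type[i]) {
    case 0: {
      const int id = (int)a[i];
      std::map<int, std::string>::iterator it = cache.find(id);
      if (it == cache.end()) {
        std::string s = as<std::string>(fetch_block(id));
        it = cache.insert(std::make_pair(id, s)).first;
      }
      cur = &it->second;
      break;
    }
    case 1: {
      if (!cur)
        stop("relative match entry %d before any block change", (int)i + 1);
      const long pos = (long)a[i], len = (long)b[i];
      if (pos < 0 || len < 0 || pos + len > (long)cur->size())
        stop("relative match entry %d exceeds block bounds (%.0f + %.0f > %d)",
             (int)i + 1, a[i], b[i], (int)cur->size());
      out.append(*cur, pos, len);
      break;
    }
    case 2:
      out.append(CHAR(STRING_ELT(texts, (R_xlen_t)a[i] - 1)), (size_t)b[i]);
      break;
    default:
      stop("unknown entry type %d", type[i]);
    }
  }
  return out;
}
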