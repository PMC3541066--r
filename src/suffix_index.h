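#ifndef REFCOMP_SUFFIX_INDEX_H
#define REFCOMP_SUFFIX_INDEX_H

#include <string>
#include <vector>
#include <cstring>
#include <algorithm>

// Longest prefix-suffix match index over one reference block: a plain
// suffix array plus a chunked minimum over suffix start positions so that
// equal-length maximal matches can be tied to the smallest block position
// without an O(range) scan in degenerate (highly repetitive) blocks.
struct SuffixIndex {
  std::string seq;
  std::vector<int> sa;
  std::vector<int> cmin;          // cmin[c] = min(sa[c*CHUNK .. c*CHUNK+CHUNK-1])
  static const int CHUNK = 2048;

  struct Match {
    int pos;
    int len;
  };

  void build();                   // suffix array from seq
  void finish();                  // cmin from sa (after build or deserialize)
  Match query(const char *q, long qlen, long max_len) const;

private:
  int lower_bound_prefix(const char *q, int qlen) const;
  int upper_bound_prefix(const char *q, int qlen) const;
  int range_min(int lo, int hi) const;  // min over sa[lo..hi)
};

#endif
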