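#include "suffix_index.h"

// O(n log n) suffix array construction by rank doubling with counting sort.
// Blocks are at most a few hundred MB of single-byte symbols, so 32-bit
// positions suffice.
void SuffixIndex::build() {
  const int n = (int)seq.size();
  sa.assign(n, 0);
  if (n == 0) { finish(); return; }

  const int ALPHA = 256;
  std::vector<int> rnk(n), tmp(n);
  std::vector<int> cnt(std::max(ALPHA, n) + 1, 0);

  for (int i = 0; i < n; ++i) rnk[i] = (unsigned char)seq[i];
  for (int i = 0; i < n; ++i) cnt[rnk[i] + 1]++;
  for (int i = 0; i < ALPHA; ++i) cnt[i + 1] += cnt[i];
  for (int i = 0; i < n; ++i) sa[cnt[rnk[i]]++] = i;

  int classes = ALPHA;
  for (int k = 1; k < n; k <<= 1) {
    // order by second key: suffixes whose second half is empty sort first
    int p = 0;
    for (int i = n - k; i < n; ++i) tmp[p++] = i;
    for (int i = 0; i < n; ++i)
      if (sa[i] >= k) tmp[p++] = sa[i] - k;

    // stable counting sort by first key (current rank)
    std::fill(cnt.begin(), cnt.begin() + classes + 1, 0);
    for (int i = 0; i < n; ++i) cnt[rnk[i] + 1]++;
    for (int i = 0; i < classes; ++i) cnt[i + 1] += cnt[i];
    for (int i = 0; i < n; ++i) sa[cnt[rnk[tmp[i]]]++] = tmp[i];

    // recompute ranks for length 2k
    tmp[sa[0]] = 0;
    int r = 0;
    for (int i = 1; i < n; ++i) {
      const int a = sa[i - 1], b = sa[i];
      const int a2 = a + k < n ? rnk[a + k] : -1;
      const int b2 = b + k < n ? rnk[b + k] : -1;
      if (rnk[a] != rnk[b] || a2 != b2) ++r;
      tmp[b] = r;
    }
    rnk.swap(tmp);
    classes = r + 1;
    if (classes == n) break;
  }
  finish();
}

void SuffixIndex::finish() {
  const int n = (int)sa.size();
  const int nc = (n + CHUNK - 1) / CHUNK;
  cmin.assign(nc, 0);
  for (int c = 0; c < nc; ++c) {
    int m = sa[(long)c * CHUNK];
    const int hi = std::min(n, (c + 1) * CHUNK);
    for (int i = c * CHUNK + 1; i < hi; ++i)
      if (sa[i] < m) m = sa[i];
    cmin[c] = m;
  }
}

// first index in sa whose suffix compares >= q (q truncated to qlen)
int SuffixIndex::lower_bound_prefix(const char *q, int qlen) const {
  const int n = (int)seq.size();
  int lo = 0, hi = n;
  while (lo < hi) {
    const int mid = lo + (hi - lo) / 2;
    const int pos = sa[mid];
    // suffix < query ?
    bool less = false, decided = false;
    int i = 0;
    while (pos + i < n && i < qlen) {
      const unsigned char a = (unsigned char)seq[pos + i];
      const unsigned char b = (unsigned char)q[i];
      if (a != b) { less = a < b; decided = true; break; }
      ++i;
    }
    if (!decided) less = (pos + i == n && i < qlen);  // suffix is a proper prefix of q
    if (less) lo = mid + 1; else hi = mid;
  }
  return lo;
}

// first index in sa whose suffix compares > q[0..qlen) (a suffix that merely
// starts with the full prefix is not greater)
int SuffixIndex::upper_bound_prefix(const char *q, int qlen) const {
  const int n = (int)seq.size();
  int lo = 0, hi = n;
  while (lo < hi) {
    const int mid = lo + (hi - lo) / 2;
    const int pos = sa[mid];
    // query < suffix ?
    bool greater = false, decided = false;
    int i = 0;
    while (pos + i < n && i < qlen) {
      const unsigned char a = (unsigned char)seq[pos + i];
      const unsigned char b = (unsigned char)q[i];
      if (a != b) { greater = b < a; decided = true; break; }
      ++i;
    }
    if (!decided) greater = false;  // suffix starts with (or equals) the prefix
    if (greater) hi = mid; else lo = mid + 1;
  }
  return lo;
}

int SuffixIndex::range_min(int lo, int hi) const {
  int m = sa[lo];
  const int cl = lo / CHUNK + 1, ch = hi / CHUNK;
  if (cl > ch) {
    for (int i = lo + 1; i < hi; ++i)
      if (sa[i] < m) m = sa[i];
    return m;
  }
  for (int i = lo + 1; i < cl * CHUNK; ++i)
    if (sa[i] < m) m = sa[i];
  for (int c = cl; c < ch; ++c)
    if (cmin[c] < m) m = cmin[c];
  for (int i = ch * CHUNK; i < hi; ++i)
    if (sa[i] < m) m = sa[i];
  return m;
}

// Longest prefix of q occurring anywhere in seq; ties on length resolve to
// the smallest start position. max_len <= 0 means uncapped.
SuffixIndex::Match SuffixIndex::query(const char *q, long qlen, long max_len) const {
  Match res = {0, 0};
  const int n = (int)seq.size();
  if (n == 0 || qlen <= 0) return res;
  if (max_len > 0 && max_len < qlen) qlen = max_len;
  const int ql = qlen > n ? n : (int)qlen;  // a match cannot exceed |seq|

  // the maximal lcp with q is attained at a lexicographic neighbour of q's
  // insertion point in suffix order
  const int ip = lower_bound_prefix(q, ql);
  int best = 0;
  for (int cand = ip - 1; cand <= ip; ++cand) {
    if (cand < 0 || cand >= n) continue;
    const int pos = sa[cand];
    const int lim = std::min(ql, n - pos);
    int l = 0;
    while (l < lim && seq[pos + l] == q[l]) ++l;
    if (l > best) best = l;
  }
  if (best == 0) return res;

  const int lo = lower_bound_prefix(q, best);
  const int hi = upper_bound_prefix(q, best);
  res.pos = range_min(lo, hi);
  res.len = best;
  return res;
}
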