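# Naive all-positions scan for the longest prefix-suffix match: for every
# start position of the block, the common prefix length with the query; the
# maximum wins, first (smallest) position on ties. O(n*m), independent of
# the suffix-array path.
naive_lps_match <- function(block, query, max_len = NULL) {
  n <- nchar(block)
  m <- nchar(query)
  if (!is.null(max_len)) m <- min(m, max_len)
  if (n == 0 || m == 0) return(list(position = 0L, length = 0L))
  b <- charToRaw(block)
  q <- charToRaw(query)[seq_len(m)]
  mlen <- integer(n)
  alive <- seq_len(n)
  d <- 0L
  while (length(alive) > 0 && d < m) {
    alive <- alive[alive + d <= n]
    alive <- alive[b[alive + d] == q[d + 1L]]
    mlen[alive] <- d + 1L
    d <- d + 1L
  }
  best <- max(mlen)
  list(position = if (best == 0L) 0L else which(mlen == best)[1L] - 1L,
       length = best)
}

rand_seq <- function(n, alphabet = c("A", "C", "G", "T")) {
  paste(sample(alphabet, n, replace = TRUE), collapse = "")
}

# store over in-memory records in a session temp dir
tmp_store <- function(records, BS, cache_blocks = 8L, ...) {
  dir <- tempfile("store")
  write_reference_store(records, dir, BS = BS, ...)
  load_reference_store(dir, cache_blocks = cache_blocks)
}

# thresholds relaxed for micro examples; local search left at its default
# 20-char window so it cannot fire on short strings
relaxed_params <- function(min_long_match = 2L, raw_fallback_len = 1L,
                           BS = 8, ...) {
  suppressWarnings(compression_params(BS = BS,
                                      min_long_match = min_long_match,
                                      raw_fallback_len = raw_fallback_len,
                                      ...))
}

# validity: every RM slice must equal the input slice it encodes, and
# coverage must equal the input length
check_entries_against <- function(entries, input, store) {
  p_in <- 0L
  cur <- NULL
  for (i in seq_along(entries$type)) {
    t <- entries$type[i]
    if (t == 0L) {
      cur <- store_block(store, entries$a[i])
    } else if (t == 1L) {
      len <- entries$b[i]
      slice <- substr(cur, entries$a[i] + 1, entries$a[i] + len)
      expect_identical(slice, substr(input, p_in + 1, p_in + len))
      p_in <- p_in + len
    } else {
      txt <- entries$texts[entries$a[i]]
      expect_identical(txt, substr(input, p_in + 1, p_in + nchar(txt)))
      p_in <- p_in + nchar(txt)
    }
  }
  expect_equal(p_in, nchar(input))
}
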