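test_that("split_into_blocks enforces the block size constraints", {
  b <- split_into_blocks(strrep("A", 10), "c1", BS = 4)
  expect_equal(vapply(b, function(x) nchar(x$sequence), integer(1)),
               c(4L, 4L, 2L))
  expect_equal(vapply(b, `[[`, integer(1), "global_id"), 0:2)
  expect_equal(vapply(b, function(x) x$offset, numeric(1)), c(0, 4, 8))

  one <- split_into_blocks(strrep("C", 7), "c1", BS = 7)
  expect_length(one, 1L)

  expect_warning(empty <- split_into_blocks("", "c1", BS = 4), "empty")
  expect_length(empty, 0L)

  # global ids continue across chromosomes
  b2 <- split_into_blocks(strrep("G", 9), "c2", BS = 4,
                          first_global_id = length(b))
  expect_equal(vapply(b2, `[[`, integer(1), "global_id"), 3:5)
})

test_that("a 1,000,003-char chromosome splits into 11 blocks and reassembles", {
  set.seed(11)
  chrom <- rand_seq(1000003)
  b <- split_into_blocks(chrom, "c1", BS = 100000)
  expect_length(b, 11L)
  expect_equal(nchar(b[[11]]$sequence), 3L)
  expect_identical(paste(vapply(b, `[[`, character(1), "sequence"),
                         collapse = ""), chrom)
})

test_that("splitting reassembles for random lengths and BS, including BS > |chrom|", {
  set.seed(7)
  for (k in 1:15) {
    n <- sample(1:500, 1)
    BS <- sample(1:600, 1)
    chrom <- rand_seq(n)
    b <- split_into_blocks(chrom, "cx", BS = BS)
    lens <- vapply(b, function(x) nchar(x$sequence), integer(1))
    if (length(lens) > 1) expect_true(all(lens[-length(lens)] == BS))
    expect_true(lens[length(lens)] <= BS)
    expect_identical(paste(vapply(b, `[[`, character(1), "sequence"),
                           collapse = ""), chrom)
  }
})

test_that("the index answers the worked single-block example", {
  idx <- build_block_index("ACGACGTA")
  r <- longest_prefix_suffix_match(idx, "ACGTAAT")
  expect_equal(r$position, 3L)
  expect_equal(r$length, 5L)
})

test_that("degenerate queries: empty query, 1-char block, absent characters", {
  idx <- build_block_index("ACGACGTA")
  expect_equal(longest_prefix_suffix_match(idx, "")$length, 0L)
  expect_equal(longest_prefix_suffix_match(idx, "TTT")$length, 1L)
  expect_equal(longest_prefix_suffix_match(idx, "XYZ"),
               list(position = 0L, length = 0L))

  tiny <- build_block_index("G")
  expect_equal(longest_prefix_suffix_match(tiny, "GA"),
               list(position = 0L, length = 1L))
  expect_equal(longest_prefix_suffix_match(tiny, "A")$length, 0L)

  expect_error(build_block_index(""), "empty")
})

test_that("max_len caps the reported match", {
  idx <- build_block_index("ACGACGTA")
  r <- longest_prefix_suffix_match(idx, "ACGTAAT", max_len = 3)
  expect_equal(r$length, 3L)
  # capped matches still tie-break to the smallest position: "ACG" at 0
  expect_equal(r$position, 0L)
})

test_that("index answers equal the naive scan, with smallest-position ties", {
  set.seed(42)
  for (k in 1:60) {
    n <- sample(5:300, 1)
    block <- rand_seq(n, alphabet = c("A", "C", "G", "T", "N"))
    idx <- build_block_index(block)
    for (j in 1:4) {
      q <- if (j %% 2 == 0) {
        rand_seq(sample(1:60, 1))
      } else {
        # substring of the block with a mutated tail: guaranteed partial match
        st <- sample(seq_len(n), 1)
        len <- sample(1:min(40, n - st + 1), 1)
        paste0(substr(block, st, st + len - 1), rand_seq(5))
      }
      got <- longest_prefix_suffix_match(idx, q)
      want <- naive_lps_match(block, q)
      expect_identical(got, want)
    }
  }
})

test_that("a store persists blocks and answers identically after reload", {
  set.seed(1)
  chrom <- rand_seq(2000)
  dir <- tempfile("store")
  write_reference_store(c(chr1 = chrom), dir, BS = 500)
  st <- load_reference_store(dir)
  expect_equal(nrow(store_blocks_meta(st)), 4L)

  # byte-identical reassembly through the store
  got <- paste(vapply(0:3, function(i) store_block(st, i), character(1)),
               collapse = "")
  expect_identical(got, chrom)

  # loaded (deserialized) index answers equal freshly built ones
  q <- paste0(substr(chrom, 700, 760), "TTTT")
  idx_loaded <- store_index(st, 1)
  idx_fresh <- build_block_index(substr(chrom, 501, 1000))
  expect_identical(longest_prefix_suffix_match(idx_loaded, q),
                   longest_prefix_suffix_match(idx_fresh, q))
})

test_that("the block cache is LRU-bounded and counts loads", {
  set.seed(2)
  st <- tmp_store(c(chr1 = rand_seq(300)), BS = 100, cache_blocks = 1L)
  for (i in 0:2) store_block(st, i)
  expect_equal(st$loads, 3L)                  # budget 1: every access loads
  store_block(st, 2)
  expect_equal(st$loads, 3L)                  # cache hit
  store_block(st, 0)
  expect_equal(st$loads, 4L)                  # re-load after eviction

  st2 <- tmp_store(c(chr1 = rand_seq(300)), BS = 100, cache_blocks = 3L)
  for (k in 1:5) for (i in 0:2) store_block(st2, i)
  expect_equal(st2$loads, 3L)                 # all resident
})

test_that("corrupt or missing block files fail loudly", {
  set.seed(3)
  dir <- tempfile("store")
  write_reference_store(c(chr1 = rand_seq(200)), dir, BS = 100)
  st <- load_reference_store(dir)
  f <- file.path(dir, "blocks", "b000001.seq")
  bytes <- readBin(f, "raw", file.size(f))
  bytes[5] <- as.raw(bitwXor(as.integer(bytes[5]), 1L))
  writeBin(bytes, f)
  expect_error(store_block(st, 1), "checksum mismatch")
  unlink(f)
  st2 <- load_reference_store(dir)
  expect_error(store_block(st2, 1), "missing")
})
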