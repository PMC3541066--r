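test_that("encode_ref extends the maximal equal run and emits one RM", {
  r <- encode_ref("ACGTA", 0, "ACGACGTA", 3)
  expect_equal(format_entries(r$entries), "RM(3,5)")
  expect_equal(r$p_in, 5)
  expect_equal(r$p_raw, 8)

  # single matching char then mismatch
  r <- encode_ref("AT", 0, "AC", 0)
  expect_equal(format_entries(r$entries), "RM(0,1)")

  # run stops at the block end even though input continues
  r <- encode_ref("ACGTACGT", 0, "ACGT", 0)
  expect_equal(format_entries(r$entries), "RM(0,4)")
  expect_equal(r$p_in, 4)

  expect_error(encode_ref("A", 0, "C", 0), "requires")
})

test_that("encode_raw consumes the maximal non-ACGT run", {
  r <- encode_raw("NNNA", 0)
  expect_equal(format_entries(r$entries), 'R("NNN")')
  expect_equal(r$p_in, 3)

  r <- encode_raw("ACGN", 3)                  # single trailing N at input end
  expect_equal(format_entries(r$entries), 'R("N")')
  expect_equal(r$p_in, 4)

  r <- encode_raw(paste0("ACG", "NRYN", "ACG"), 3)  # mixed symbols, one R
  expect_equal(format_entries(r$entries), 'R("NRYN")')

  expect_error(encode_raw("ACGT", 0), "non-")
})

test_that("the local search resolves substitutions at (i=1, j=1)", {
  set.seed(5)
  block <- random_genome(60, seed = 9)
  input <- block
  substr(input, 31, 31) <- if (substr(block, 31, 31) == "A") "C" else "A"
  r <- has_local_alternative(input, 30, block, 30)
  expect_true(r$fired)
  fe <- format_entries(r$entries)
  expect_equal(fe[1], sprintf('R("%s")', substr(input, 31, 31)))
  expect_match(fe[2], "^RM\\(31,")
  expect_equal(r$p_in, nchar(input))          # resumes and runs to the end
})

test_that("the local search resolves a deletion at (i=0, j=1) with no raw", {
  block <- random_genome(60, seed = 10)
  k <- 25
  input <- paste0(substr(block, 1, k), substr(block, k + 2, 60))
  r <- has_local_alternative(input, k, block, k)
  expect_true(r$fired)
  expect_equal(format_entries(r$entries), sprintf("RM(%d,%d)", k + 1, 60 - k - 1))
})

test_that("the local search skips out-of-bounds windows and can return false", {
  block <- random_genome(60, seed = 11)
  # fewer than local_match_len characters remain in the input
  r <- has_local_alternative("ACGTACGTACGT", 2, block, 30)
  expect_false(r$fired)
  expect_equal(entry_count(r$entries), 0L)
  # mismatch with nothing similar nearby
  r2 <- has_local_alternative(strrep("A", 40), 0, strrep("C", 60), 30)
  expect_false(r2$fired)
})

test_that("find_match reproduces the worked-example start", {
  st <- tmp_store(c(chr1 = "ACGACGTA"), BS = 8)
  p <- relaxed_params()
  # at position 0 no prefix longer than the threshold exists -> raw fallback
  r0 <- find_match("TACGTAAT", 0, NULL, 0, st, p)
  expect_equal(format_entries(r0$entries), 'R("T")')
  expect_equal(r0$p_in, 1)
  expect_equal(r0$current_block, -1L)
  # from position 1 the global search anchors block 0 at position 3
  r1 <- find_match("TACGTAAT", 1, NULL, 0, st, p)
  expect_equal(format_entries(r1$entries), "BC(0)")
  expect_equal(r1$p_raw, 3)
  expect_equal(r1$current_block, 0L)
})

test_that("find_match falls back to fixed-size raw entries when nothing matches", {
  set.seed(12)
  st <- tmp_store(c(chr1 = strrep("AC", 200)), BS = 400)
  p <- suppressWarnings(compression_params(min_long_match = 25,
                                           raw_fallback_len = 25))
  input <- strrep("G", 30)                    # shares no >1 char run
  r1 <- find_match(input, 0, NULL, 0, st, p)
  df1 <- as.data.frame(r1$entries)
  expect_equal(df1$entry, "R")
  expect_equal(df1$text, strrep("G", 25))
  expect_equal(r1$p_in, 25)
  r2 <- find_match(input, r1$p_in, NULL, 0, st, p)
  expect_equal(format_entries(r2$entries), 'R("GGGGG")')  # clipped remainder
  expect_equal(r2$p_in, 30)
})

test_that("a match of exactly min_long_match characters is rejected", {
  set.seed(13)
  ref <- random_genome(200, seed = 14)
  st <- tmp_store(c(chr1 = ref), BS = 200)
  frag <- substr(ref, 50, 74)                 # exactly 25 chars from the block
  input <- paste0(frag, strrep("N", 10))
  p25 <- compression_params(min_long_match = 25, raw_fallback_len = 25)
  r <- find_match(input, 0, NULL, 0, st, p25)
  expect_equal(r$current_block, -1L)          # 25 is not > 25: raw fallback
  expect_equal(as.data.frame(r$entries)$text, frag)
  # one character lower and the same match is accepted
  p24 <- compression_params(min_long_match = 24, raw_fallback_len = 24)
  r2 <- find_match(input, 0, NULL, 0, st, p24)
  expect_equal(format_entries(r2$entries), "BC(0)")
  expect_equal(r2$p_raw, 49)
})

test_that("block traversal favours the current block, neighbours, chromosome, rest", {
  set.seed(14)
  st <- tmp_store(c(chr1 = rand_seq(500)), BS = 100)   # 5 blocks
  expect_equal(block_traversal_order(2, st), c(2L, 1L, 3L, 0L, 4L))
  expect_equal(block_traversal_order(0, st), c(0L, 1L, 2L, 3L, 4L))
  expect_equal(block_traversal_order(NULL, st), 0:4)

  st2 <- tmp_store(c(chr1 = rand_seq(300), chr2 = rand_seq(300)), BS = 100)
  ord <- block_traversal_order(1, st2)
  expect_equal(ord[1], 1L)
  expect_true(all(which(ord %in% 0:2) < which(ord %in% 3:5)))
})

test_that("an input identical to the reference compresses to BC + one RM per block", {
  set.seed(15)
  ref <- rand_seq(1000)
  st <- tmp_store(c(chr1 = ref), BS = 250)    # 4 blocks
  e <- compress_sequence(ref, st)
  expect_lte(entry_count(e), 2L * 4L)
  expect_equal(format_entries(e)[1:2], c("BC(0)", "RM(0,250)"))
  expect_identical(decompress_entries(e, st), ref)
})

test_that("the worked micro-example compresses to R(T), BC(0), RM(3,5) ...", {
  st <- tmp_store(c(chr1 = "ACGACGTA"), BS = 8)
  e <- compress_sequence("TACGTAAT", st, relaxed_params())
  expect_equal(format_entries(e)[1:3], c('R("T")', "BC(0)", "RM(3,5)"))
  expect_identical(decompress_entries(e, st), "TACGTAAT")
})

test_that("a synthetic mutant round-trips losslessly through the entry stream", {
  ref <- random_genome(10000, seed = 21)
  m <- mutate(ref, mutation_model(snp_rate = 1e-3, indel_rate = 5e-4,
                                  n_run_rate = 2e-4, n_run_mean = 10,
                                  seed = 22))
  st <- tmp_store(c(chr1 = ref), BS = 2500)
  e <- compress_sequence(m$mutant, st)
  expect_identical(decompress_entries(e, st), m$mutant)
  check_entries_against(e, m$mutant, st)
})

test_that("coverage and match validity hold across random parameter settings", {
  set.seed(30)
  grid <- expand.grid(BS = c(97, 512), snp = c(0, 0.002, 0.02),
                      mode = c("greedy_first_acceptable", "exhaustive_best"),
                      stringsAsFactors = FALSE)
  for (g in seq_len(nrow(grid))) {
    ref <- rand_seq(3000)
    st <- tmp_store(c(chr1 = ref), BS = grid$BS[g])
    m <- mutate(ref, mutation_model(snp_rate = grid$snp[g],
                                    indel_rate = 2e-4, n_run_rate = 1e-4,
                                    n_run_mean = 8, seed = 100 + g))
    p <- compression_params(BS = grid$BS[g], search_mode = grid$mode[g])
    e <- compress_sequence(m$mutant, st, p)
    expect_equal(entry_coverage(e), nchar(m$mutant))
    expect_identical(decompress_entries(e, st), m$mutant)
    check_entries_against(e, m$mutant, st)
  }
})

test_that("empty input compresses to an empty entry stream", {
  st <- tmp_store(c(chr1 = "ACGTACGT"), BS = 8)
  e <- compress_sequence("", st)
  expect_equal(entry_count(e), 0L)
  expect_identical(decompress_entries(e, st), "")
})

test_that("operation counters are reported and grow with the input", {
  ref <- random_genome(20000, seed = 31)
  st <- tmp_store(c(chr1 = ref), BS = 5000)
  m <- mutate(ref, mutation_model(seed = 32))
  e <- compress_sequence(m$mutant, st)
  ops <- attr(e, "ops")
  expect_true(all(c("ref_cmp", "local_cmp", "global_queries", "raw_chars")
                  %in% names(ops)))
  expect_gt(ops$ref_cmp, 0)
})
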