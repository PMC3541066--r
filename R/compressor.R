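#' Candidate block order for the global match search
#'
#' When the compressor loses its anchor it searches reference blocks for a
#' new long match. Blocks are visited in an order that favours locality
#' (block loads are the expensive step): the current block itself (already
#' resident), its left and right neighbours on the same chromosome, the
#' remaining blocks of that chromosome, and finally all other blocks, each
#' group in genome order. With no current block the order is plain genome
#' order.
#'
#' @param current_block global id of the active block, or `NULL`.
#' @param store a `refcomp_store` (only its block metadata is consulted).
#' @return an integer vector of global block ids.
#' @export
block_traversal_order <- function(current_block, store) {
  blocks <- store_blocks_meta(store)
  ids <- blocks$global_id                 # already in genome order
  if (is.null(current_block) || is.na(current_block)) return(ids)
  current_block <- as.integer(current_block)
  row <- blocks[ids == current_block, , drop = FALSE]
  if (nrow(row) != 1) stop("unknown block id ", current_block)
  same <- blocks$chromosome_id == row$chromosome_id
  neigh <- blocks$global_id[same & abs(blocks$ordinal - row$ordinal) == 1]
  rest_chr <- setdiff(ids[same], c(current_block, neigh))
  other <- ids[!same]
  c(current_block, neigh, rest_chr, other)
}

params_cpp <- function(params) {
  params[c("min_long_match", "raw_fallback_len", "local_match_len",
           "local_input_window", "local_ref_window", "search_mode",
           "max_query_len")]
}

#' Compress a sequence against a reference store
#'
#' The greedy referential compression loop: while input remains, extend a
#' relative match while the input agrees with the active block, spool runs
#' of non-\{A,C,G,T\} characters into raw entries, and on any other mismatch
#' re-anchor — first by a bounded local neighbourhood search (SNP- and
#' indel-sized differences), then by a global longest prefix-suffix match
#' search over the reference blocks, falling back to raw characters when no
#' block offers a match longer than `min_long_match`.
#'
#' @param input a single character string (uppercase; arbitrary single-byte
#'   symbols are allowed, but only A/C/G/T participate in match extension
#'   dispatch).
#' @param store a `refcomp_store`.
#' @param params a [compression_params()] object.
#' @return an `rgc_entries` object: the ordered entry stream, carrying an
#'   `ops` attribute with operation counters (`ref_cmp`, `local_cmp`,
#'   `global_queries`, `raw_chars`).
#' @examples
#' dir <- tempfile()
#' write_reference_store(c(chr1 = "ACGACGTA"), dir, BS = 8)
#' st <- load_reference_store(dir)
#' p <- compression_params(BS = 8, min_long_match = 1, raw_fallback_len = 1)
#' compress_sequence("TACGTAAT", st, p)
#' @export
compress_sequence <- function(input, store, params = compression_params()) {
  stopifnot(is.character(input), length(input) == 1,
            inherits(store, "refcomp_store"))
  params <- as_params(params)
  fetch <- function(id) store_index(store, id)$ptr
  trav <- function(cur) block_traversal_order(cur, store)
  rc_compress(input, fetch, trav, params_cpp(params),
              merge_raws = params$merge_raws)
}

# ---- individual compressor subroutines -----------------------------------
# Thin wrappers over the same C++ statics the main loop runs; used by unit
# tests and for tracing. All positions are 0-based.

#' Extend a relative match (ENCODE-REF step)
#'
#' From `input(p_in) == block(p_raw)`, consumes the maximal run of equal
#' characters (stopping at input or block end) and emits one relative-match
#' entry.
#'
#' @param input,block character scalars.
#' @param p_in,p_raw 0-based current positions.
#' @return list with `entries` (one RM), `p_in`, `p_raw`.
#' @export
encode_ref <- function(input, p_in, block, p_raw) {
  rc_encode_ref(input, p_in, block, p_raw)
}

#' Spool a run of non-ACGT characters (ENCODE-RAW step)
#'
#' From a non-\{A,C,G,T\} character at `p_in`, consumes the maximal run of
#' such characters and emits one raw entry.
#'
#' @param input character scalar.
#' @param p_in 0-based current position.
#' @return list with `entries` (one R), `p_in`.
#' @export
encode_raw <- function(input, p_in) {
  rc_encode_raw(input, p_in)
}

#' Local neighbourhood mismatch resolution (HAS-LOCAL-ALTERNATIVE step)
#'
#' Scans input offsets `i` (outer, ascending) and reference offsets `j`
#' (inner, ascending); at the first `(i, j)` whose `local_match_len`-character
#' windows agree, emits the `i` skipped input characters raw (if
#' any), shifts the reference position by `j` and extends referentially.
#' Comparisons that would read past either end are skipped.
#'
#' @inheritParams encode_ref
#' @param params a [compression_params()] object.
#' @return list with `fired` (logical), `entries`, `p_in`, `p_raw`.
#' @export
has_local_alternative <- function(input, p_in, block, p_raw,
                                  params = compression_params()) {
  params <- as_params(params)
  rc_has_local_alternative(input, p_in, block, p_raw, params_cpp(params))
}

#' Re-anchor the compressor (FIND-MATCH step)
#'
#' Tries the local alternative first; otherwise searches candidate blocks
#' (in [block_traversal_order()]) for the longest prefix-suffix match of
#' the remaining input. A match strictly longer than `min_long_match`
#' yields a block change (omitted when the block is unchanged) and
#' repositions `p_raw` at the match start — the following main-loop
#' iteration emits the relative match. Otherwise `raw_fallback_len` input
#' characters are emitted raw.
#'
#' @param input character scalar.
#' @param p_in 0-based input position.
#' @param current_block active global block id, or `NULL` at compression
#'   start.
#' @param p_raw 0-based position in the active block.
#' @param store a `refcomp_store`.
#' @param params a [compression_params()] object.
#' @return list with `entries`, `p_in`, `p_raw`, `current_block` (-1 when
#'   still unanchored).
#' @export
find_match <- function(input, p_in, current_block, p_raw, store,
                       params = compression_params()) {
  params <- as_params(params)
  fetch <- function(id) store_index(store, id)$ptr
  trav <- function(cur) block_traversal_order(cur, store)
  rc_find_match(input, p_in,
                if (is.null(current_block)) -1L else as.integer(current_block),
                p_raw, fetch, trav, params_cpp(params))
}

# ---- entry stream helpers ------------------------------------------------

#' Number of entries in a stream
#' @param entries an `rgc_entries` object.
#' @return integer count.
#' @export
entry_count <- function(entries) length(entries$type)

#' Decompressed length implied by an entry stream
#' @param entries an `rgc_entries` object.
#' @return total characters covered by relative-match and raw entries.
#' @export
entry_coverage <- function(entries) sum(entries$b[entries$type != 0L])

#' Format entries in BC/RM/R notation
#' @param entries an `rgc_entries` object.
#' @param n maximum number of entries to format.
#' @return character vector like `c('R("T")', "BC(0)", "RM(3,5)")`.
#' @export
format_entries <- function(entries, n = length(entries$type)) {
  n <- min(n, length(entries$type))
  if (n == 0) return(character(0))
  vapply(seq_len(n), function(i) {
    switch(entries$type[i] + 1L,
           sprintf("BC(%d)", as.integer(entries$a[i])),
           sprintf("RM(%d,%d)", as.integer(entries$a[i]),
                   as.integer(entries$b[i])),
           {
             txt <- entries$texts[as.integer(entries$a[i])]
             if (nchar(txt) > 12)
               txt <- paste0(substr(txt, 1, 9), "...")
             sprintf('R("%s")', txt)
           })
  }, character(1))
}

#' Entry stream as a data frame
#' @param x an `rgc_entries` object.
#' @param ... unused.
#' @return data.frame with columns `entry` (BC/RM/R), `a`, `b`, `text`.
#' @export
as.data.frame.rgc_entries <- function(x, ...) {
  data.frame(
    entry = c("BC", "RM", "R")[x$type + 1L],
    a = ifelse(x$type == 2L, NA_real_, x$a),
    b = ifelse(x$type == 1L, x$b, NA_real_),
    text = ifelse(x$type == 2L, x$texts[pmax(1L, as.integer(x$a))], NA),
    stringsAsFactors = FALSE)
}

#' @export
print.rgc_entries <- function(x, n = 8L, ...) {
  m <- length(x$type)
  cat(sprintf("rgc entry stream: %d entries (%d BC, %d RM, %d R), %s chars covered\n",
              m, sum(x$type == 0L), sum(x$type == 1L), sum(x$type == 2L),
              format(entry_coverage(x), big.mark = ",")))
  if (m > 0) {
    shown <- format_entries(x, n)
    cat(" ", paste(shown, collapse = " "),
        if (m > n) sprintf(" ... (+%d more)", m - n) else "", "\n", sep = "")
  }
  invisible(x)
}
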