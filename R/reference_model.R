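#' Split a chromosome into reference blocks
#'
#' Cuts a chromosome sequence into consecutive blocks of exactly `BS`
#' characters; only the last block of a chromosome may be shorter.
#' Concatenating the blocks in ordinal order reproduces the chromosome.
#'
#' @param chromosome a single character string (the chromosome sequence).
#' @param chromosome_id label of the chromosome.
#' @param BS maximum block size in characters (>= 1).
#' @param first_global_id global id assigned to the first block produced;
#'   global ids number blocks consecutively across chromosomes in genome
#'   order.
#' @return a list of `refcomp_block` objects with fields `chromosome_id`,
#'   `ordinal` (0-based index within the chromosome), `global_id`,
#'   `offset` (0-based start within the chromosome) and `sequence`.
#'   An empty chromosome yields an empty list with a warning.
#' @examples
#' blocks <- split_into_blocks(strrep("ACGT", 5), "chr1", BS = 8)
#' vapply(blocks, function(b) nchar(b$sequence), integer(1))  # 8 8 4
#' @export
split_into_blocks <- function(chromosome, chromosome_id = "chr1", BS = 4e6,
                              first_global_id = 0L) {
  stopifnot(is.character(chromosome), length(chromosome) == 1, BS >= 1)
  n <- nchar(chromosome)
  if (n == 0) {
    warning(sprintf("chromosome '%s' is empty: no blocks produced",
                    chromosome_id))
    return(list())
  }
  BS <- as.numeric(BS)
  starts <- seq(1, n, by = BS)
  ends <- pmin(starts + BS - 1, n)
  lapply(seq_along(starts), function(k) {
    structure(
      list(chromosome_id = chromosome_id,
           ordinal = k - 1L,
           global_id = as.integer(first_global_id + k - 1L),
           offset = starts[k] - 1,
           sequence = substr(chromosome, starts[k], ends[k])),
      class = "refcomp_block")
  })
}

#' @export
print.refcomp_block <- function(x, ...) {
  cat(sprintf("reference block %d (%s #%d, offset %s, %s chars)\n",
              x$global_id, x$chromosome_id, x$ordinal,
              format(x$offset, big.mark = ","),
              format(nchar(x$sequence), big.mark = ",")))
  invisible(x)
}

#' Build a longest prefix-suffix match index over one block
#'
#' Constructs a suffix-array based index answering, for any query string,
#' the length and (smallest) start position of the longest prefix of the
#' query that occurs anywhere in the block.
#'
#' @param block a `refcomp_block`, or a single character string.
#' @return an object of class `refcomp_block_index`.
#' @examples
#' idx <- build_block_index("ACGACGTA")
#' longest_prefix_suffix_match(idx, "ACGTAAT")  # position 3, length 5
#' @export
build_block_index <- function(block) {
  seq <- if (inherits(block, "refcomp_block")) block$sequence else block
  stopifnot(is.character(seq), length(seq) == 1)
  if (nchar(seq) == 0) stop("cannot index an empty block")
  structure(
    list(ptr = sidx_build(seq),
         block_id = if (inherits(block, "refcomp_block"))
           block$global_id else NA_integer_,
         length = nchar(seq)),
    class = "refcomp_block_index")
}

block_index_from_sa <- function(seq, sa, block_id = NA_integer_) {
  structure(
    list(ptr = sidx_from_sa(seq, sa), block_id = block_id,
         length = nchar(seq)),
    class = "refcomp_block_index")
}

#' @export
print.refcomp_block_index <- function(x, ...) {
  cat(sprintf("block index over %s chars (block id %s)\n",
              format(x$length, big.mark = ","), x$block_id))
  invisible(x)
}

#' Longest prefix-suffix match query
#'
#' Finds the longest prefix of `query` occurring as a substring of the
#' indexed block. Among equal-length maximal matches the smallest block
#' position is returned. An empty query, or a query whose first character
#' does not occur in the block, yields length 0 (position 0 by convention).
#'
#' @param index a `refcomp_block_index` from [build_block_index()].
#' @param query a single character string.
#' @param max_len optional cap on the reported match length.
#' @return a list with `position` (0-based start within the block) and
#'   `length`.
#' @export
longest_prefix_suffix_match <- function(index, query, max_len = NULL) {
  stopifnot(inherits(index, "refcomp_block_index"),
            is.character(query), length(query) == 1)
  if (!is.null(max_len)) stopifnot(max_len >= 1)
  r <- sidx_query(index$ptr, query,
                  if (is.null(max_len)) 0L else as.integer(max_len))
  list(position = unname(r[["position"]]), length = unname(r[["length"]]))
}

# ---- reference store on disk ---------------------------------------------

store_paths <- function(dir, id) {
  list(seq = file.path(dir, "blocks", sprintf("b%06d.seq", id)),
       sai = file.path(dir, "blocks", sprintf("b%06d.sai", id)))
}

#' Build a reference store directory
#'
#' Splits every chromosome of a reference genome into blocks of at most
#' `BS` characters, computes the match index of each block, and writes raw
#' block + index + metadata to `out_dir`. Blocks are processed one at a
#' time, so peak memory is governed by the block (and one chromosome
#' sequence), not the genome.
#'
#' @param records named character vector of chromosome sequences (names are
#'   chromosome ids), e.g. from [read_fasta()].
#' @param out_dir target directory (created if missing).
#' @param BS block size in characters.
#' @param name reference name recorded in the metadata and in every
#'   container compressed against this store.
#' @param force overwrite a non-empty existing directory.
#' @param write_index write the per-block suffix arrays (decompression-only
#'   stores can omit them; compression rebuilds missing indexes on the fly).
#' @return the store directory path, invisibly.
#' @export
write_reference_store <- function(records, out_dir, BS = 4e6,
                                  name = "reference", force = FALSE,
                                  write_index = TRUE) {
  stopifnot(is.character(records), length(records) >= 1,
            !is.null(names(records)))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !force)
    stop("output directory ", out_dir, " is not empty (use force = TRUE)")
  dir.create(file.path(out_dir, "blocks"), recursive = TRUE,
             showWarnings = FALSE)

  block_rows <- list()
  chrom_rows <- list()
  gid <- 0L
  for (ci in seq_along(records)) {
    cid <- names(records)[ci]
    chrom <- records[[ci]]
    blocks <- split_into_blocks(chrom, cid, BS, first_global_id = gid)
    chrom_rows[[ci]] <- list(id = cid, length = nchar(chrom),
                             n_blocks = length(blocks))
    for (b in blocks) {
      p <- store_paths(out_dir, b$global_id)
      writeBin(charToRaw(b$sequence), p$seq)
      if (write_index) {
        idx <- build_block_index(b)
        con <- file(p$sai, "wb")
        writeBin(as.integer(nchar(b$sequence)), con, size = 4L,
                 endian = "little")
        writeBin(sidx_sa(idx$ptr), con, size = 4L, endian = "little")
        close(con)
      }
      block_rows[[length(block_rows) + 1L]] <-
        list(global_id = b$global_id, chromosome_id = b$chromosome_id,
             ordinal = b$ordinal, offset = b$offset,
             length = nchar(b$sequence),
             md5 = unname(tools::md5sum(p$seq)))
    }
    gid <- gid + length(blocks)
  }

  meta <- list(format = "refcomp-store", version = 1L, name = name, BS = BS,
               n_blocks = gid,
               chromosomes = chrom_rows, blocks = block_rows)
  jsonlite::write_json(meta, file.path(out_dir, "metadata.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' Open a reference store
#'
#' Loads store metadata and returns a handle with lazy, size-bounded access
#' to blocks and their indexes: blocks are read from disk on first use
#' (verified against their recorded MD5 checksum) and cached with
#' least-recently-used eviction beyond `cache_blocks` resident blocks.
#'
#' @param index_dir a directory written by [write_reference_store()] /
#'   [cmd_index()].
#' @param cache_blocks maximum number of blocks held in memory.
#' @param preload load every block (and index) up front; the cache budget is
#'   raised to the block count.
#' @param verify_checksums verify each block file's MD5 on load.
#' @return an environment of class `refcomp_store`; see [store_block()],
#'   [store_index()], [store_blocks_meta()].
#' @export
load_reference_store <- function(index_dir, cache_blocks = 4L,
                                 preload = FALSE, verify_checksums = TRUE) {
  mf <- file.path(index_dir, "metadata.json")
  if (!file.exists(mf)) stop("no metadata.json in ", index_dir)
  meta <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(meta$format, "refcomp-store"))
    stop(index_dir, " is not a refcomp reference store")
  st <- new.env(parent = emptyenv())
  st$dir <- index_dir
  st$meta <- meta
  st$blocks <- meta$blocks            # data.frame: global_id, chromosome_id,
                                      # ordinal, offset, length, md5
  st$budget <- if (preload) nrow(st$blocks) else as.integer(cache_blocks)
  st$verify <- isTRUE(verify_checksums)
  st$cache <- list()                  # id -> list(seq=, idx=)
  st$loads <- 0L
  class(st) <- "refcomp_store"
  if (preload) for (id in st$blocks$global_id) store_index(st, id)
  st
}

#' @export
print.refcomp_store <- function(x, ...) {
  cat(sprintf("refcomp reference store '%s': %d blocks (BS = %s) over %d chromosome(s)\n",
              x$meta$name, nrow(x$blocks),
              format(x$meta$BS, big.mark = ",", scientific = FALSE),
              nrow(x$meta$chromosomes)))
  cat(sprintf("  cache: %d/%d blocks resident, %d loads so far\n",
              length(x$cache), x$budget, x$loads))
  invisible(x)
}

#' Block-level metadata of a store
#' @param store a `refcomp_store`.
#' @return a data.frame with one row per block (`global_id`,
#'   `chromosome_id`, `ordinal`, `offset`, `length`, `md5`).
#' @export
store_blocks_meta <- function(store) store$blocks

store_touch <- function(store, key) {
  # move key to the back of the cache list (most recently used)
  v <- store$cache[[key]]
  store$cache[[key]] <- NULL
  store$cache[[key]] <- v
}

store_insert <- function(store, key, value) {
  store$cache[[key]] <- value
  while (length(store$cache) > store$budget)
    store$cache[[1L]] <- NULL
}

store_load_block <- function(store, id) {
  row <- store$blocks[store$blocks$global_id == id, , drop = FALSE]
  if (nrow(row) != 1) stop("no block with global id ", id, " in store")
  p <- store_paths(store$dir, id)
  if (!file.exists(p$seq)) stop("missing block file ", p$seq)
  if (store$verify) {
    md5 <- unname(tools::md5sum(p$seq))
    if (!identical(md5, row$md5))
      stop("checksum mismatch for block ", id, " (file ", p$seq, ")")
  }
  seq <- rawToChar(readBin(p$seq, "raw", n = row$length))
  if (nchar(seq) != row$length)
    stop("block ", id, " file is truncated")
  store$loads <- store$loads + 1L
  seq
}

#' Retrieve a raw block sequence from a store
#' @param store a `refcomp_store`.
#' @param id global block id.
#' @return the block sequence (character scalar).
#' @export
store_block <- function(store, id) {
  key <- as.character(id)
  if (!is.null(store$cache[[key]])) {
    store_touch(store, key)
    return(store$cache[[key]]$seq)
  }
  seq <- store_load_block(store, id)
  store_insert(store, key, list(seq = seq, idx = NULL))
  seq
}

#' Retrieve (building or loading if needed) a block's match index
#' @inheritParams store_block
#' @return a `refcomp_block_index`.
#' @export
store_index <- function(store, id) {
  key <- as.character(id)
  hit <- store$cache[[key]]
  if (!is.null(hit) && !is.null(hit$idx)) {
    store_touch(store, key)
    return(hit$idx)
  }
  seq <- store_block(store, id)
  p <- store_paths(store$dir, id)
  idx <- if (file.exists(p$sai)) {
    con <- file(p$sai, "rb")
    on.exit(close(con))
    n <- readBin(con, "integer", n = 1L, size = 4L, endian = "little")
    sa <- readBin(con, "integer", n = n, size = 4L, endian = "little")
    if (length(sa) != n || n != nchar(seq))
      stop("corrupt index file ", p$sai)
    block_index_from_sa(seq, sa, id)
  } else {
    build_block_index(seq)
  }
  store$cache[[as.character(id)]]$idx <- idx
  idx
}
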