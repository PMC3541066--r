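RGC_MAGIC <- charToRaw("RGC1")
RGC_VERSION <- 1L

#' Construct an entry stream from a data frame
#'
#' Inverse of the [as.data.frame.rgc_entries()] view: builds an
#' `rgc_entries` object from rows with `entry` in BC/RM/R, `a` (block id or
#' match position), `b` (match length) and `text` (raw characters).
#'
#' @param df a data.frame with columns `entry`, and as applicable `a`, `b`,
#'   `text`.
#' @return an `rgc_entries` object.
#' @examples
#' as_entries(data.frame(entry = c("R", "BC", "RM"), a = c(NA, 0, 3),
#'                       b = c(NA, NA, 5), text = c("T", NA, NA)))
#' @export
as_entries <- function(df) {
  type <- match(df$entry, c("BC", "RM", "R")) - 1L
  if (anyNA(type)) stop("entry must be one of BC, RM, R")
  texts <- character(0)
  a <- numeric(length(type))
  b <- numeric(length(type))
  for (i in seq_along(type)) {
    if (type[i] == 2L) {
      texts <- c(texts, df$text[i])
      a[i] <- length(texts)
      b[i] <- nchar(df$text[i])
    } else {
      a[i] <- df$a[i]
      b[i] <- if (type[i] == 1L) df$b[i] else 0
    }
  }
  structure(list(type = type, a = a, b = b, texts = texts),
            class = "rgc_entries")
}

#' Serialize an entry stream to bytes
#'
#' Each entry becomes one tag byte (0 = block change, 1 = relative match,
#' 2 = raw) followed by base-128 varints (least-significant group first):
#' block change carries the block id; relative match carries position then
#' length; raw carries the byte length then the characters verbatim.
#' Serialization is bit-exact deterministic.
#'
#' @param entries an `rgc_entries` object.
#' @return a raw vector.
#' @export
serialize_entries <- function(entries) {
  rc_serialize_entries(entries)
}

#' Deserialize an entry payload
#'
#' Exact inverse of [serialize_entries()]. Truncated or corrupt payloads
#' raise an error naming the offending byte offset.
#'
#' @param payload a raw vector produced by [serialize_entries()].
#' @return an `rgc_entries` object.
#' @export
deserialize_entries <- function(payload) {
  stopifnot(is.raw(payload))
  rc_deserialize_entries(payload)
}

# Container layout (.rgc): magic "RGC1" | int32 LE version |
# int32 LE header-JSON length | header JSON (params snapshot, reference
# identity with per-block MD5s, chunk table with per-chunk FNV-1a64) |
# concatenated chunk payloads. All fixed-width integers little-endian.

#' Write a compressed container
#'
#' @param path output file.
#' @param chunks list of chunks, each `list(record_id =, part =, payload =
#'   raw vector, out_len =)`; parts of a record are concatenated in order at
#'   decompression time.
#' @param store the `refcomp_store` the payloads were compressed against
#'   (its name, block count and per-block checksums are bound into the
#'   header).
#' @param params the [compression_params()] used.
#' @param compress_payload deflate each chunk's entry payload with zlib
#'   before storing (recorded per chunk; decompression is transparent).
#' @return `path`, invisibly.
#' @export
write_rgc <- function(path, chunks, store, params, compress_payload = TRUE) {
  params <- as_params(params)
  stored <- lapply(chunks, function(ch) {
    if (compress_payload && length(ch$payload) > 0)
      memCompress(ch$payload, "gzip")
    else ch$payload
  })
  enc <- if (compress_payload) "zlib" else "raw"
  sizes <- vapply(stored, length, numeric(1))
  offsets <- cumsum(c(0, head(sizes, -1)))
  table <- lapply(seq_along(chunks), function(k) {
    ch <- chunks[[k]]
    list(record_id = ch$record_id, part = ch$part,
         offset = offsets[k], size = sizes[k], enc = enc,
         out_len = ch$out_len,
         fnv64 = rc_fnv1a64(stored[[k]]))
  })
  header <- list(
    params = list(BS = params$BS,
                  min_long_match = params$min_long_match,
                  raw_fallback_len = params$raw_fallback_len,
                  local_match_len = params$local_match_len,
                  local_input_window = params$local_input_window,
                  local_ref_window = params$local_ref_window,
                  search_mode = params$search_mode),
    reference = list(name = store$meta$name,
                     n_blocks = nrow(store_blocks_meta(store)),
                     block_md5 = store_blocks_meta(store)$md5),
    chunks = table)
  hjson <- charToRaw(jsonlite::toJSON(header, auto_unbox = TRUE, digits = NA))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(RGC_MAGIC, con)
  writeBin(RGC_VERSION, con, size = 4L, endian = "little")
  writeBin(length(hjson), con, size = 4L, endian = "little")
  writeBin(hjson, con)
  for (p in stored) writeBin(p, con)
  invisible(path)
}

#' Read a compressed container
#'
#' Parses and validates the header; chunk payloads are verified against
#' their recorded FNV-1a64 checksums on access.
#'
#' @param path a `.rgc` file.
#' @return a list of class `rgc_file` with `header` (params, reference
#'   identity, chunk table) and `chunk_payload(k)`, a function returning the
#'   verified raw payload of chunk `k`.
#' @export
read_rgc <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  bytes <- readBin(path, "raw", n = file.size(path))
  if (length(bytes) < 12 || !identical(bytes[1:4], RGC_MAGIC))
    stop(path, ": bad magic, not an RGC container")
  version <- readBin(bytes[5:8], "integer", size = 4L, endian = "little")
  if (version != RGC_VERSION)
    stop(path, ": unsupported container version ", version)
  hlen <- readBin(bytes[9:12], "integer", size = 4L, endian = "little")
  if (12 + hlen > length(bytes)) stop(path, ": truncated header")
  header <- jsonlite::fromJSON(rawToChar(bytes[seq(13, 12 + hlen)]),
                               simplifyVector = TRUE)
  payload0 <- 12 + hlen
  tab <- header$chunks
  nchunks <- if (is.data.frame(tab)) nrow(tab) else 0L
  if (nchunks > 0) {
    want <- tab$offset[nchunks] + tab$size[nchunks]
    if (payload0 + want > length(bytes)) stop(path, ": truncated payload")
  }
  structure(
    list(path = path, header = header,
         chunk_payload = function(k) {
           row <- header$chunks[k, ]
           if (row$size == 0) return(raw(0))
           p <- bytes[seq(payload0 + row$offset + 1,
                          payload0 + row$offset + row$size)]
           if (!identical(rc_fnv1a64(p), row$fnv64))
             stop(path, ": checksum mismatch in chunk ", k,
                  " (record ", row$record_id, ")")
           if (identical(row$enc, "zlib")) memDecompress(p, "gzip") else p
         },
         file_size = length(bytes)),
    class = "rgc_file")
}

#' @export
print.rgc_file <- function(x, ...) {
  h <- x$header
  cat(sprintf("RGC container %s: %d chunk(s), %s bytes, reference '%s' (%d blocks)\n",
              x$path, NROW(h$chunks), format(x$file_size, big.mark = ","),
              h$reference$name, h$reference$n_blocks))
  invisible(x)
}

check_reference_match <- function(rgc, store) {
  ref <- rgc$header$reference
  meta <- store_blocks_meta(store)
  if (ref$n_blocks != nrow(meta) ||
      !identical(as.character(ref$block_md5), as.character(meta$md5)))
    stop("reference store does not match the container: ",
         "block count or checksums differ (compressed against '",
         ref$name, "', store is '", store$meta$name, "')")
  invisible(TRUE)
}

#' Decompress a container against a reference store
#'
#' Replays every chunk's entry stream: a block-change entry switches the
#' active reference block, a relative match appends a slice of it, a raw
#' entry appends its characters. Only raw blocks are touched — match
#' indexes are not loaded. The store is checked against the reference
#' identity in the header before any output is produced.
#'
#' @param rgc a path to a `.rgc` file or an object from [read_rgc()].
#' @param store a `refcomp_store` for the same reference.
#' @return named character vector of decompressed records, in container
#'   order.
#' @export
decompress <- function(rgc, store) {
  if (is.character(rgc)) rgc <- read_rgc(rgc)
  stopifnot(inherits(rgc, "rgc_file"), inherits(store, "refcomp_store"))
  check_reference_match(rgc, store)
  tab <- rgc$header$chunks
  if (!is.data.frame(tab) || nrow(tab) == 0)
    return(setNames(character(0), character(0)))
  fetch <- function(id) store_block(store, id)
  parts <- vapply(seq_len(nrow(tab)), function(k) {
    entries <- deserialize_entries(rgc$chunk_payload(k))
    out <- rc_decompress_entries(entries, fetch)
    if (nchar(out) != tab$out_len[k])
      stop("chunk ", k, " decompressed to ", nchar(out),
           " chars, expected ", tab$out_len[k])
    out
  }, character(1))
  rec_ids <- unique(tab$record_id)
  setNames(
    vapply(rec_ids, function(rid) {
      sel <- tab$record_id == rid
      paste(parts[sel][order(tab$part[sel])], collapse = "")
    }, character(1)),
    rec_ids)
}

#' Decompress a single entry stream
#'
#' Convenience form of [decompress()] for an in-memory entry list (no
#' container); used to round-trip [compress_sequence()] output directly.
#'
#' @param entries an `rgc_entries` object.
#' @param store a `refcomp_store`.
#' @return the decompressed sequence (character scalar).
#' @export
decompress_entries <- function(entries, store) {
  rc_decompress_entries(entries, function(id) store_block(store, id))
}
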