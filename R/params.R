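#' Compression parameters
#'
#' Bundles every threshold and window of the greedy referential compressor.
#' Defaults follow the published heuristic: global matches must be longer
#' than 25 characters (shorter ones are mostly random hits in mammalian-size
#' references), the raw fallback emits 25 characters at a time, and the
#' local mismatch search compares 20-character windows over input offsets
#' 0..7 and reference offsets -7..+7.
#'
#' @param BS block size in bytes used when building a reference store
#'   (default 4,000,000; allowed 1 kb to 300 Mb, the largest human
#'   chromosome).
#' @param min_long_match a global block match is accepted only when strictly
#'   longer than this many characters.
#' @param raw_fallback_len number of input characters emitted as a raw entry
#'   when no block holds an acceptable match (clipped at input end).
#' @param local_match_len window length (characters) compared during the
#'   local neighbourhood search.
#' @param local_input_window inclusive range of input offsets `i` scanned by
#'   the local search (outer loop, ascending).
#' @param local_ref_window inclusive range of reference offsets `j` (inner
#'   loop, ascending).
#' @param search_mode `"greedy_first_acceptable"` stops the global search at
#'   the first block whose match exceeds `min_long_match`;
#'   `"exhaustive_best"` scans every candidate and keeps the longest match
#'   (ties: earliest in traversal order).
#' @param threads worker count for the parallel compression driver.
#' @param merge_raws merge consecutive raw entries into one (smaller output,
#'   identical semantics).
#' @param max_query_len optional cap on the length of global match queries
#'   (0 = uncapped).
#'
#' @return an object of class `refcomp_params`.
#' @examples
#' p <- compression_params(BS = 1e6, min_long_match = 25)
#' p$local_input_window
#' @export
compression_params <- function(BS = 4e6,
                               min_long_match = 25L,
                               raw_fallback_len = 25L,
                               local_match_len = 20L,
                               local_input_window = c(0L, 7L),
                               local_ref_window = c(-7L, 7L),
                               search_mode = c("greedy_first_acceptable",
                                               "exhaustive_best"),
                               threads = 1L,
                               merge_raws = TRUE,
                               max_query_len = 0) {
  search_mode <- match.arg(search_mode)
  BS <- as.numeric(BS)
  stopifnot(length(BS) == 1, BS >= 1)
  if (BS > 3e8) stop("BS must not exceed 300 MB")
  min_long_match <- as.integer(min_long_match)
  raw_fallback_len <- as.integer(raw_fallback_len)
  local_match_len <- as.integer(local_match_len)
  stopifnot(min_long_match >= 1, raw_fallback_len >= 1, local_match_len >= 1)
  local_input_window <- as.integer(local_input_window)
  local_ref_window <- as.integer(local_ref_window)
  stopifnot(length(local_input_window) == 2,
            local_input_window[1] <= local_input_window[2],
            local_input_window[1] >= 0,
            length(local_ref_window) == 2,
            local_ref_window[1] <= local_ref_window[2])
  if (min_long_match < local_match_len)
    warning("min_long_match < local_match_len: global matches may be ",
            "shorter than the local windows they are meant to beat")
  threads <- as.integer(threads)
  stopifnot(threads >= 1)
  structure(
    list(BS = BS,
         min_long_match = min_long_match,
         raw_fallback_len = raw_fallback_len,
         local_match_len = local_match_len,
         local_input_window = local_input_window,
         local_ref_window = local_ref_window,
         search_mode = search_mode,
         threads = threads,
         merge_raws = isTRUE(merge_raws),
         max_query_len = as.numeric(max_query_len)),
    class = "refcomp_params")
}

#' @export
print.refcomp_params <- function(x, ...) {
  cat("refcomp compression parameters\n")
  cat(sprintf("  block size (BS): %s bytes\n",
              format(x$BS, big.mark = ",", scientific = FALSE)))
  cat(sprintf("  min long match: > %d chars | raw fallback: %d chars\n",
              x$min_long_match, x$raw_fallback_len))
  cat(sprintf("  local search: %d-char windows, i in %d..%d, j in %d..%d\n",
              x$local_match_len,
              x$local_input_window[1], x$local_input_window[2],
              x$local_ref_window[1], x$local_ref_window[2]))
  cat(sprintf("  search mode: %s | threads: %d\n", x$search_mode, x$threads))
  invisible(x)
}

as_params <- function(params) {
  if (inherits(params, "refcomp_params")) return(params)
  if (is.null(params)) return(compression_params())
  do.call(compression_params, params)
}
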