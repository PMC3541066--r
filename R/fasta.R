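#' Read a FASTA file
#'
#' Reads plain or gzip-compressed FASTA. Sequence lines of each record are
#' concatenated and uppercased (soft-masked lowercase bases are not
#' distinguished); full header lines are preserved as record ids, in file
#' order.
#'
#' @param path FASTA file, optionally `.gz`.
#' @return named character vector of sequences (names = headers).
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- gzfile(path, "rt")
  first <- tryCatch(readLines(con, n = 1L), finally = close(con))
  if (length(first) == 0) stop(path, ": empty FASTA file")
  if (!startsWith(trimws(first), ">"))
    stop(path, ": malformed FASTA (sequence data before first header)")
  x <- Biostrings::readBStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' Write a FASTA file
#'
#' @param records named character vector of sequences.
#' @param path output file; a `.gz` suffix selects gzip compression.
#' @param width line width for sequence lines.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(is.character(records), !is.null(names(records)))
  con <- if (grepl("\\.gz$", path)) gzfile(path, "wb") else file(path, "wb")
  on.exit(close(con))
  for (i in seq_along(records)) {
    writeLines(paste0(">", names(records)[i]), con)
    s <- records[[i]]
    n <- nchar(s)
    if (n > 0) {
      starts <- seq(1, n, by = width)
      writeLines(substring(s, starts, pmin(starts + width - 1, n)), con)
    }
  }
  invisible(path)
}
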