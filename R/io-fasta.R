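# Multi-FASTA I/O.  Reading uppercases sequences and keeps IDs verbatim up
# to the first whitespace; writing wraps at 70 columns.

#' Read a multi-FASTA file
#'
#' @param path FASTA file; an empty file yields an empty list.
#' @return named list of uppercase sequence strings (names = record IDs up
#'   to the first whitespace).
#' @export
read_fasta <- function(path) {
  if (file.size(path) == 0) return(setNames(list(), character(0)))
  ss <- Biostrings::readBStringSet(path)   # BString: validate alphabet ourselves
  seqs <- toupper(as.character(ss))
  ids <- sub("[[:space:]].*$", "", names(ss))
  for (i in seq_along(seqs)) {
    bad <- regexpr("[^ACGTUNRYSWKMBDHV-]", seqs[i])
    if (bad > 0L)
      stop("read_fasta: non-IUPAC character in record '", ids[i],
           "' at position ", bad)
  }
  setNames(as.list(unname(seqs)), ids)
}

#' Write sequences as multi-FASTA
#'
#' @param records named list or character vector of sequences.
#' @param path output path.
#' @param width line wrap width (default 70).
#' @export
write_fasta <- function(records, path, width = 70L) {
  records <- as.list(records)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(records)) {
    s <- as.character(records[[i]])
    writeLines(paste0(">", names(records)[i]), con)
    if (nzchar(s)) {
      starts <- seq(1L, nchar(s), width)
      writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
    }
  }
  invisible(path)
}
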