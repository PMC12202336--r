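# Small shared helpers. Internal coordinates are 0-based half-open on the
# forward strand of the linearized circle; all user-facing reports are
# 1-based inclusive.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Split a DNA string into a character vector of single bases
#' @param s character scalar
#' @return character vector
#' @keywords internal
s2c <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

#' @keywords internal
c2s <- function(x) paste0(x, collapse = "")

.COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A", N = "N",
                 a = "t", c = "g", g = "c", t = "a", n = "n")

#' Reverse complement of a DNA string
#'
#' @param s DNA string over \{A,C,G,T,N\} (case-insensitive).
#' @return reverse-complemented uppercase string.
#' @export
revcomp <- function(s) {
  if (!nzchar(s)) return(s)
  v <- .COMPLEMENT[rev(s2c(toupper(s)))]
  if (anyNA(v)) stop("revcomp: non-IUPAC character in sequence")
  c2s(v)
}

#' Complement (no reversal) of a DNA string
#' @inheritParams revcomp
#' @export
complement_seq <- function(s) {
  if (!nzchar(s)) return(s)
  v <- .COMPLEMENT[s2c(toupper(s))]
  if (anyNA(v)) stop("complement_seq: non-IUPAC character in sequence")
  c2s(v)
}

#' Round half away from zero
#'
#' Base R's round() is round-half-even; published percentage tables are
#' conventionally round-half-up (e.g. 45.164... -> 45.16, 76.195 -> 76.20).
#' @param x numeric
#' @param digits decimal places
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Format a proportion as a percentage string with 2 decimals
#' @param num,den numerator and denominator
#' @export
pct2 <- function(num, den) {
  sprintf("%.2f", round_half_up(100 * num / den, 2))
}

#' @keywords internal
fmt_num <- function(x, digits) {
  ifelse(is.na(x), "NA", sprintf(paste0("%.", digits, "f"), round_half_up(x, digits)))
}

#' Write a data.frame as a TSV report
#'
#' Header row, tab-separated, no quoting, no row names; the format shared by
#' every tabular report in the pipeline.
#' @param df data.frame
#' @param path output path
#' @export
write_tsv_report <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE, na = "NA")
  invisible(path)
}

#' @keywords internal
read_tsv_report <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                    check.names = FALSE)
}

# deterministic geometric-ish draw used by the simulator
#' @keywords internal
rgeom1 <- function(n, mean) 1L + stats::rgeom(n, prob = 1 / mean)
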