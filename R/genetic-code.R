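# Mold mitochondrial genetic code (translation table 4): identical to the
# standard code except TGA encodes tryptophan.  Stops are TAA and TAG.

.BASES <- c("A", "C", "G", "T")

.standard_code <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G"
)

#' Mold mitochondrial genetic code (table 4)
#'
#' Named character vector mapping the 64 DNA codons to one-letter amino
#' acids; stop codons (TAA, TAG) map to "*".  TGA encodes tryptophan.
#' @export
GENETIC_CODE_4 <- {
  gc <- .standard_code
  gc[["TGA"]] <- "W"
  gc
}

#' Stop codons under translation table 4
#' @export
STOP_CODONS_4 <- c("TAA", "TAG")

#' Split a CDS into codons
#' @param cds DNA string with length a multiple of 3
#' @return character vector of codons
#' @export
codons_of <- function(cds) {
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("codons_of: CDS length ", n, " is not a multiple of 3")
  if (n == 0L) return(character(0))
  substring(cds, seq(1L, n, 3L), seq(3L, n, 3L))
}

#' Translate a CDS under the mold mitochondrial code
#'
#' @param cds DNA string, length a multiple of 3.
#' @param strip_stop drop a single terminal stop codon if present.
#' @return amino-acid string; internal stops appear as "*".
#' @export
translate4 <- function(cds, strip_stop = FALSE) {
  cod <- codons_of(toupper(cds))
  aa <- GENETIC_CODE_4[cod]
  aa[is.na(aa)] <- "X"   # codons containing N
  if (strip_stop && length(aa) && aa[length(aa)] == "*") aa <- aa[-length(aa)]
  c2s(aa)
}

#' Does a CDS contain an internal stop under code 4?
#' @inheritParams translate4
#' @export
has_internal_stop4 <- function(cds) {
  cod <- codons_of(toupper(cds))
  if (length(cod) <= 1L) return(FALSE)
  any(cod[-length(cod)] %in% STOP_CODONS_4)
}

#' All 64 codons in a fixed lexicographic order
#' @keywords internal
all_codons <- function() {
  as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0))[
    order(as.vector(outer(outer(.BASES, .BASES, paste0), .BASES, paste0)))]
}

#' Synonymous codon families under code 4
#'
#' List of codon vectors, one per amino acid (stops excluded), used for RSCU.
#' @keywords internal
codon_families4 <- function() {
  ok <- GENETIC_CODE_4[GENETIC_CODE_4 != "*"]
  split(names(ok), unname(ok))
}
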