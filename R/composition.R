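# Genome- and gene-level composition statistics: base counts, AT/GC skew,
# region partition by annotation class, codon usage under genetic code 4,
# six-frame ORF census, and the intron-count vs genome-size correlation.
# Unknown bases (N) are excluded from every composition denominator.

#' Base composition and strand skews of a sequence
#'
#' AT-skew = (A - T)/(A + T), GC-skew = (G - C)/(G + C), computed on base
#' counts of the given strand.
#' @param sequence non-empty DNA string.
#' @return list with length, counts (A,C,G,T,N), gc_fraction, at_skew,
#'   gc_skew.
#' @export
skew_stats <- function(sequence) {
  if (!nzchar(sequence)) stop("skew_stats: empty sequence")
  v <- s2c(toupper(sequence))
  cnt <- c(A = sum(v == "A"), C = sum(v == "C"),
           G = sum(v == "G"), T = sum(v == "T"), N = sum(v == "N"))
  acgt <- sum(cnt[c("A", "C", "G", "T")])
  if (acgt == 0L) stop("skew_stats: no unambiguous bases")
  at <- cnt[["A"]] + cnt[["T"]]
  gc <- cnt[["G"]] + cnt[["C"]]
  at_skew <- if (at == 0L) {
    warning("skew_stats: A+T = 0, AT-skew undefined"); NA_real_
  } else (cnt[["A"]] - cnt[["T"]]) / at
  gc_skew <- if (gc == 0L) {
    warning("skew_stats: G+C = 0, GC-skew undefined"); NA_real_
  } else (cnt[["G"]] - cnt[["C"]]) / gc
  list(length = length(v), counts = cnt,
       gc_fraction = gc / acgt,
       at_skew = at_skew, gc_skew = gc_skew)
}

REGION_CLASSES <- c("PCG_exon", "rRNA", "tRNA", "intron", "free_orf",
                    "intergenic")

#' Partition every genome position into one annotation class
#'
#' Precedence when classes overlap: PCG exon > rRNA > tRNA > intron >
#' free-standing ORF > intergenic.  Two PCGs overlapping on their exons
#' trigger a warning and the earlier feature keeps the shared positions.
#' @param g a \code{mitogenome}
#' @return named integer vector of per-class nucleotide totals summing
#'   exactly to the genome length, with the per-position class vector
#'   attached as attribute \code{"class_vector"}.
#' @export
region_partition <- function(g) {
  L <- genome_length(g)
  # integer codes, higher = higher precedence
  code <- c(intergenic = 1L, free_orf = 2L, intron = 3L, tRNA = 4L,
            rRNA = 5L, PCG_exon = 6L)
  cls <- rep(code[["intergenic"]], L)
  assign_kind <- function(kinds, code_val) {
    for (f in g$features) {
      if (!f$kind %in% kinds) next
      for (i in seq_len(nrow(f$parts))) {
        idx <- (f$parts[i, "start"] + 1L):f$parts[i, "end"]
        cls[idx] <<- pmax(cls[idx], code_val)
      }
    }
  }
  assign_kind("orf", code[["free_orf"]])
  assign_kind("intron", code[["intron"]])
  assign_kind("tRNA", code[["tRNA"]])
  assign_kind("rRNA", code[["rRNA"]])
  # PCG exons: earlier feature wins on PCG/PCG overlap
  pcg_taken <- rep(FALSE, L)
  for (f in g$features) {
    if (f$kind != "PCG") next
    for (i in seq_len(nrow(f$parts))) {
      idx <- (f$parts[i, "start"] + 1L):f$parts[i, "end"]
      clash <- pcg_taken[idx]
      if (any(clash))
        warning("region_partition: PCG exon overlap at gene ", f$name,
                " (", sum(clash), " nt); earlier feature takes precedence")
      keep <- idx[!clash]
      cls[keep] <- code[["PCG_exon"]]
      pcg_taken[idx] <- TRUE
    }
  }
  lev <- names(sort(code))
  tab <- tabulate(cls, nbins = max(code))
  out <- setNames(tab[code[REGION_CLASSES]], REGION_CLASSES)
  stopifnot(sum(out) == L)
  attr(out, "class_vector") <- names(code)[match(cls, code)]
  out
}

#' Codon usage of protein-coding genes under genetic code 4
#'
#' Codons are counted on the coding strand 5'->3', including stop codons,
#' and reported in the RNA alphabet.  RSCU is computed within synonymous
#' families of the mold mitochondrial code (stops excluded).  Genes whose
#' exon-concatenated length is not a multiple of 3 are skipped with a
#' warning.
#' @param genomes a \code{mitogenome} or list of them.
#' @param genes gene symbols to include (default the 15 core PCGs).
#' @return list with \code{table} (data.frame: codon, amino_acid, count,
#'   per_thousand, rscu) and \code{start_stop} (per species x gene first and
#'   last codons).
#' @export
codon_usage <- function(genomes, genes = CORE_PCGS) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  counts <- setNames(integer(64), all_codons())
  census <- list()
  for (g in genomes) {
    for (gene in genes) {
      cds <- gene_cds(g, gene)
      if (is.null(cds)) next
      if (nchar(cds) %% 3L != 0L) {
        warning("codon_usage: ", g$species_id, "/", gene,
                " length not a multiple of 3; gene skipped")
        next
      }
      cod <- codons_of(cds)
      cod <- cod[!grepl("N", cod)]
      tb <- table(cod)
      counts[names(tb)] <- counts[names(tb)] + as.integer(tb)
      census[[length(census) + 1L]] <- data.frame(
        species = g$species_id, gene = gene,
        start_codon = cod[1], stop_codon = cod[length(cod)],
        stringsAsFactors = FALSE)
    }
  }
  total <- sum(counts)
  rscu <- setNames(rep(NA_real_, 64), names(counts))
  for (fam in codon_families4()) {
    cc <- counts[fam]
    m <- mean(cc)
    rscu[fam] <- if (m > 0) cc / m else NA_real_
  }
  tab <- data.frame(
    codon = gsub("T", "U", names(counts)),
    amino_acid = unname(GENETIC_CODE_4[names(counts)]),
    count = as.integer(counts),
    per_thousand = if (total > 0) 1000 * as.numeric(counts) / total else 0,
    rscu = as.numeric(rscu),
    stringsAsFactors = FALSE)
  list(table = tab,
       start_stop = if (length(census)) do.call(rbind, census) else
         data.frame(species = character(0), gene = character(0),
                    start_codon = character(0), stop_codon = character(0)))
}

#' @keywords internal
scan_orfs_strand <- function(seqstr, min_nt) {
  # single-strand, three-frame ORF scan: ATG .. {TAA,TAG}, code 4
  n <- nchar(seqstr)
  out <- list()
  for (fr in 0:2) {
    len <- ((n - fr) %/% 3L) * 3L
    if (len < min_nt) next
    cod <- codons_of(substring(seqstr, fr + 1L, fr + len))
    is_stop <- cod %in% STOP_CODONS_4
    is_atg <- cod == "ATG"
    start_cod <- NA_integer_
    for (k in seq_along(cod)) {
      if (is.na(start_cod) && is_atg[k]) start_cod <- k
      if (is_stop[k]) {
        if (!is.na(start_cod)) {
          orf_nt <- (k - start_cod + 1L) * 3L   # includes the stop codon
          if (orf_nt >= min_nt)
            out[[length(out) + 1L]] <- c(start = fr + (start_cod - 1L) * 3L,
                                         end = fr + k * 3L)
        }
        start_cod <- NA_integer_
      }
    }
  }
  out
}

#' Six-frame ORF census
#'
#' Scans both strands in all three frames under genetic code 4 (start ATG,
#' stops TAA/TAG) and reports ORFs of at least \code{min_nt} nucleotides
#' (stop codon included) that do not overlap core-PCG exons.  For a
#' circular genome the scan runs on the doubled sequence with starts
#' constrained to the first copy, so origin-spanning ORFs are found.
#' @param g a \code{mitogenome}
#' @param min_nt minimum ORF length in nucleotides (default 300).
#' @return data.frame: start, end (1-based inclusive, end may exceed the
#'   genome length for origin-spanning ORFs), strand, length_nt,
#'   in_intron flag.
#' @export
orf_census <- function(g, min_nt = 300L) {
  L <- genome_length(g)
  s <- g$sequence
  scan_len <- L
  if (g$circular) { s <- paste0(s, g$sequence); scan_len <- 2L * L }
  hits <- list()
  for (h in scan_orfs_strand(s, min_nt)) {
    st <- h[["start"]]
    if (st < L && (h[["end"]] - st) <= L)
      hits[[length(hits) + 1L]] <- c(st, h[["end"]], 1L)
  }
  rs <- revcomp(s)
  for (h in scan_orfs_strand(rs, min_nt)) {
    # map back: position p in rs corresponds to scan_len - p on forward
    st <- scan_len - h[["end"]]; en <- scan_len - h[["start"]]
    stm <- st %% L
    if ((en - st) <= L)
      hits[[length(hits) + 1L]] <- c(stm, stm + (en - st), -1L)
  }
  if (length(hits) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), length_nt = integer(0),
                      in_intron = logical(0)))
  m <- do.call(rbind, hits)
  m <- unique(m)
  # exclusion / containment masks from annotation
  pcg_mask <- rep(FALSE, L); intron_mask <- rep(FALSE, L)
  for (f in g$features) {
    if (!f$kind %in% c("PCG", "intron")) next
    for (i in seq_len(nrow(f$parts))) {
      idx <- (f$parts[i, "start"] + 1L):f$parts[i, "end"]
      if (f$kind == "PCG") pcg_mask[idx] <- TRUE else intron_mask[idx] <- TRUE
    }
  }
  span_idx <- function(st, en) ((st:(en - 1L)) %% L) + 1L
  keep <- logical(nrow(m)); in_intron <- logical(nrow(m))
  for (i in seq_len(nrow(m))) {
    idx <- span_idx(m[i, 1], m[i, 2])
    keep[i] <- !any(pcg_mask[idx])
    in_intron[i] <- all(intron_mask[idx])
  }
  m <- m[keep, , drop = FALSE]; in_intron <- in_intron[keep]
  ord <- order(m[, 1], m[, 2], m[, 3])
  m <- m[ord, , drop = FALSE]; in_intron <- in_intron[ord]
  data.frame(start = m[, 1] + 1L, end = m[, 2],
             strand = ifelse(m[, 3] > 0, "+", "-"),
             length_nt = m[, 2] - m[, 1], in_intron = in_intron)
}

#' Correlation between intron count and genome size
#'
#' Pearson correlation with the two-sided t-test p-value (df = n - 2), and
#' Spearman rank correlation on mid-ranks with the same t approximation.
#' An exact permutation p-value for the Pearson coefficient is available
#' for small n.
#' @param intron_count,genome_length numeric vectors (>= 3 points).
#' @param permutation_p also compute an exact permutation p-value
#'   (enumerates all n! orderings; only sensible for n <= 8).
#' @return list: pearson_r, pearson_p, spearman_rho, spearman_p
#'   (and pearson_p_perm when requested).
#' @export
intron_size_correlation <- function(intron_count, genome_length,
                                    permutation_p = FALSE) {
  x <- as.numeric(intron_count); y <- as.numeric(genome_length)
  n <- length(x)
  if (n < 3L || length(y) != n)
    stop("intron_size_correlation: need >= 3 paired points")
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("intron_size_correlation: zero variance in a coordinate")
  tp <- function(r) {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  r <- stats::cor(x, y)
  rho <- stats::cor(rank(x), rank(y))   # mid-ranks via rank() default
  out <- list(pearson_r = r, pearson_p = tp(r),
              spearman_rho = rho, spearman_p = tp(rho))
  if (permutation_p) {
    if (n > 8L) stop("permutation p only supported for n <= 8")
    perms <- permutations_of(n)
    robs <- abs(r)
    cnt <- sum(vapply(perms, function(p) abs(stats::cor(x[p], y)) >= robs - 1e-12,
                      TRUE))
    out$pearson_p_perm <- cnt / length(perms)
  }
  out
}

#' @keywords internal
permutations_of <- function(n) {
  if (n == 1L) return(list(1L))
  sub <- permutations_of(n - 1L)
  # insert n into every slot of each (n-1)-permutation
  out <- vector("list", 0)
  for (p in sub) for (pos in 0:(n - 1L))
    out[[length(out) + 1L]] <- append(p, n, after = pos)
  out
}
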