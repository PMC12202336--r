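# Shared genomic data model: an annotated (usually circular) mitogenome with
# typed features.  Coordinates are 0-based half-open internally; features
# crossing the origin of a circular molecule are stored as two-part joins.

FEATURE_KINDS <- c("PCG", "rRNA", "tRNA", "orf", "intron")
INTRON_GROUPS <- c("IA", "IB", "IC1", "IC2", "ID", "II", "unknown")

#' The 15 core protein-coding genes of a fungal mitogenome
#' @export
CORE_PCGS <- c("atp6", "atp8", "atp9", "cob", "cox1", "cox2", "cox3",
               "nad1", "nad2", "nad3", "nad4", "nad4L", "nad5", "nad6",
               "rps3")

#' The 14-gene set used for phylogeny (core PCGs minus rps3)
#' @export
PHYLO_PCGS <- setdiff(CORE_PCGS, "rps3")

#' Create a genomic feature
#'
#' @param kind one of PCG, rRNA, tRNA, orf, intron.
#' @param name gene symbol (e.g. "cox1", "rnl", "trnA", "orf319").
#' @param strand "+" or "-".
#' @param parts integer matrix with columns start, end: 0-based half-open
#'   intervals listed 5'->3' along the feature (exon parts for PCG/rRNA,
#'   a single interval otherwise).
#' @param intron_group intron subclass label (intron kind only).
#' @param parent_gene host gene symbol (intron kind only).
#' @param note free-text annotation.
#' @return an object of class \code{mito_feature}.
#' @export
feature <- function(kind, name, strand = "+", parts,
                    intron_group = NULL, parent_gene = NULL, note = NULL) {
  if (!kind %in% FEATURE_KINDS) stop("unknown feature kind: ", kind)
  if (!strand %in% c("+", "-")) stop("strand must be '+' or '-'")
  parts <- matrix(as.integer(parts), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(parts) == 0L) stop("feature '", name, "': parts must be non-empty")
  if (any(parts[, "end"] <= parts[, "start"]))
    stop("feature '", name, "': empty or inverted part interval")
  if (!is.null(intron_group) && !intron_group %in% INTRON_GROUPS)
    stop("feature '", name, "': unknown intron group ", intron_group)
  structure(list(kind = kind, name = name, strand = strand, parts = parts,
                 intron_group = intron_group, parent_gene = parent_gene,
                 note = note),
            class = "mito_feature")
}

#' @keywords internal
feature_start <- function(f) min(f$parts[, "start"])

#' Total length of a feature (sum of its parts)
#' @param f a \code{mito_feature}
#' @export
feature_length <- function(f) sum(f$parts[, "end"] - f$parts[, "start"])

#' Create an annotated mitogenome
#'
#' @param species_id short unique label.
#' @param sequence uppercase DNA string over \{A,C,G,T,N\}.
#' @param circular logical.
#' @param features list of \code{mito_feature}; sorted by start coordinate
#'   (stable on ties) on construction.
#' @return an object of class \code{mitogenome}.
#' @export
mitogenome <- function(species_id, sequence, circular = TRUE,
                       features = list()) {
  sequence <- toupper(sequence)
  if (nchar(sequence) < 1L) stop("mitogenome: sequence must be non-empty")
  bad <- regexpr("[^ACGTN]", sequence)
  if (bad > 0L)
    stop("mitogenome '", species_id, "': non-IUPAC character at position ", bad)
  g <- structure(list(species_id = species_id, sequence = sequence,
                      circular = circular, features = features),
                 class = "mitogenome")
  g$features <- features[order(vapply(features, feature_start, 0L))]
  validate_mitogenome(g)
  g
}

#' Validate a mitogenome against the data-model invariants
#'
#' Checks feature intervals against the sequence length, part ordering, and
#' (optionally) that PCG exon concatenations are in-frame and stop-free
#' under code 4.
#' @param g a \code{mitogenome}
#' @param check_cds also check PCG frame/stop invariants, with warnings
#'   (default TRUE).
#' @return \code{g}, invisibly; errors on interval violations, warns on
#'   annotation-quality problems.
#' @export
validate_mitogenome <- function(g, check_cds = TRUE) {
  L <- genome_length(g)
  for (f in g$features) {
    if (any(f$parts[, "start"] < 0L) || any(f$parts[, "end"] > L))
      stop("feature '", f$name, "' extends outside [0, ", L, ")")
    if (nrow(f$parts) > 1L) {
      o <- order(f$parts[, "start"])
      p <- f$parts[o, , drop = FALSE]
      if (any(p[-nrow(p), "end"] > p[-1L, "start"]))
        stop("feature '", f$name, "': overlapping parts")
    }
    if (check_cds && f$kind == "PCG") {
      # annotation-quality checks: warn (do not refuse to load a record)
      cds <- feature_seq(g, f)
      if (nchar(cds) %% 3L != 0L)
        warning("PCG '", f$name, "': exon length ", nchar(cds),
                " not a multiple of 3")
      else if (!grepl("N", cds, fixed = TRUE) && has_internal_stop4(cds))
        warning("PCG '", f$name, "': internal stop codon under code 4")
    }
  }
  invisible(g)
}

#' Genome length in nucleotides
#' @param g a \code{mitogenome}
#' @export
genome_length <- function(g) nchar(g$sequence)

#' Extract the 5'->3' sequence of a feature
#'
#' Parts are stored 5'->3' along the feature.  On the plus strand the part
#' substrings are concatenated as stored; on the minus strand each part is
#' reverse-complemented and the stored (5'->3') order is kept, which equals
#' the reverse complement of the ascending-coordinate concatenation.
#' @param g a \code{mitogenome}
#' @param f a \code{mito_feature} (or its index in \code{g$features})
#' @export
feature_seq <- function(g, f) {
  if (is.numeric(f)) f <- g$features[[f]]
  subs <- substring(g$sequence, f$parts[, "start"] + 1L, f$parts[, "end"])
  if (f$strand == "+") c2s(subs) else c2s(vapply(subs, revcomp, ""))
}

#' @keywords internal
features_of_kind <- function(g, kind) {
  Filter(function(f) f$kind == kind, g$features)
}

#' @keywords internal
find_gene <- function(g, name, kind = NULL) {
  for (f in g$features)
    if (f$name == name && (is.null(kind) || f$kind == kind)) return(f)
  NULL
}

#' Exon-concatenated CDS of a protein-coding gene
#'
#' @param g a \code{mitogenome}
#' @param gene gene symbol
#' @return DNA string (introns removed), 5'->3' on the coding strand, or
#'   NULL when the gene is absent.
#' @export
gene_cds <- function(g, gene) {
  f <- find_gene(g, gene, "PCG")
  if (is.null(f)) return(NULL)
  feature_seq(g, f)
}

#' Introns annotated on a given host gene
#' @param g a \code{mitogenome}
#' @param gene host gene symbol
#' @return list of intron \code{mito_feature}s in 5'->3' host-gene order.
#' @export
gene_introns <- function(g, gene) {
  ins <- Filter(function(f) f$kind == "intron" &&
                  identical(f$parent_gene, gene), g$features)
  if (length(ins) == 0L) return(ins)
  host <- find_gene(g, gene)
  ord <- order(vapply(ins, feature_start, 0L))
  if (!is.null(host) && host$strand == "-") ord <- rev(ord)
  ins[ord]
}

#' Rotate the origin of a circular genome
#'
#' Shifts the linearization origin by \code{offset} nucleotides; feature
#' coordinates are remapped and features that now cross the origin become
#' two-part joins.
#' @param g a circular \code{mitogenome}
#' @param offset new origin, 0-based position in the current coordinates.
#' @export
rotate_genome <- function(g, offset) {
  L <- genome_length(g)
  offset <- ((offset %% L) + L) %% L
  if (offset == 0L) return(g)
  if (!g$circular) stop("rotate_genome: genome is not circular")
  seq2 <- paste0(substring(g$sequence, offset + 1L, L),
                 substring(g$sequence, 1L, offset))
  shift_part <- function(st, en) {
    # remap one 0-based half-open interval, splitting at the new origin
    st2 <- (st - offset) %% L
    en2 <- st2 + (en - st)
    if (en2 <= L) matrix(c(st2, en2), ncol = 2)
    else matrix(c(st2, L, 0L, en2 - L), ncol = 2, byrow = TRUE)
  }
  feats <- lapply(g$features, function(f) {
    np <- do.call(rbind, lapply(seq_len(nrow(f$parts)), function(i)
      shift_part(f$parts[i, 1], f$parts[i, 2])))
    f$parts <- matrix(as.integer(np), ncol = 2,
                      dimnames = list(NULL, c("start", "end")))
    f
  })
  mitogenome(g$species_id, seq2, circular = TRUE, features = feats)
}

#' @exportS3Method print mitogenome
#' @export
print.mitogenome <- function(x, ...) {
  kinds <- table(factor(vapply(x$features, function(f) f$kind, ""),
                        levels = FEATURE_KINDS))
  cat("<mitogenome> ", x$species_id, ": ", genome_length(x), " bp, ",
      if (x$circular) "circular" else "linear", "\n  features: ",
      paste(names(kinds), as.integer(kinds), sep = "=", collapse = ", "),
      "\n", sep = "")
  invisible(x)
}

#' Structural equality of two mitogenomes
#'
#' Compares species id, sequence, circularity and every feature field;
#' used by the round-trip tests.
#' @param a,b \code{mitogenome}s
#' @export
genomes_equal <- function(a, b) {
  if (a$species_id != b$species_id || a$sequence != b$sequence ||
      a$circular != b$circular || length(a$features) != length(b$features))
    return(FALSE)
  for (i in seq_along(a$features)) {
    fa <- a$features[[i]]; fb <- b$features[[i]]
    if (fa$kind != fb$kind || fa$name != fb$name || fa$strand != fb$strand ||
        !identical(unname(fa$parts), unname(fb$parts)) ||
        !identical(fa$intron_group, fb$intron_group) ||
        !identical(fa$parent_gene, fb$parent_gene))
      return(FALSE)
  }
  TRUE
}
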