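# Per-gene pairwise evolutionary rates: Kimura two-parameter distances on
# codon-filtered nucleotide alignments, and Nei-Gojobori (1986) Ka/Ks with
# Jukes-Cantor correction under genetic code 4.  Protein-guided codon
# threading uses Biostrings global alignment; exhaustive DP and pathway
# oracles for both live in the test suite.

.rates_cache <- new.env(parent = emptyenv())

.PURINES <- c("A", "G")

#' @keywords internal
is_transition <- function(a, b) {
  (a %in% .PURINES) == (b %in% .PURINES)
}

#' Kimura two-parameter distance between two gapless sequences
#'
#' P is the proportion of transition differences, Q of transversions, over
#' sites where both sequences have an unambiguous base;
#' d = -1/2 log(1 - 2P - Q) - 1/4 log(1 - 2Q).
#' @param seq_a,seq_b equal-length gapless DNA strings.
#' @return list: sites, P, Q, k2p (NA when saturated), saturated flag.
#' @export
k2p <- function(seq_a, seq_b) {
  a <- s2c(toupper(seq_a)); b <- s2c(toupper(seq_b))
  if (length(a) != length(b)) stop("k2p: sequences differ in length")
  ok <- a %in% .BASES & b %in% .BASES
  a <- a[ok]; b <- b[ok]
  n <- length(a)
  if (n < 1L) stop("k2p: no comparable sites")
  diff <- a != b
  ts <- diff & ((a %in% .PURINES) == (b %in% .PURINES))
  P <- sum(ts) / n
  Q <- sum(diff & !ts) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0)
    return(list(sites = n, P = P, Q = Q, k2p = NA_real_, saturated = TRUE))
  list(sites = n, P = P, Q = Q,
       k2p = -0.5 * log(w1) - 0.25 * log(w2), saturated = FALSE)
}

#' @keywords internal
ng86_tables <- function() {
  # Per-codon synonymous site counts and per-codon-pair averaged minimal
  # pathway difference counts, cached after first computation.
  if (!is.null(.rates_cache$ng86)) return(.rates_cache$ng86)
  cods <- all_codons()
  aa <- GENETIC_CODE_4[cods]
  nonstop <- cods[aa != "*"]
  syn_sites <- setNames(rep(NA_real_, 64), cods)
  for (c0 in nonstop) {
    v <- s2c(c0); s <- 0
    for (pos in 1:3) for (nb in setdiff(.BASES, v[pos])) {
      w <- v; w[pos] <- nb; c1 <- c2s(w)
      # mutations creating a stop codon count as nonsynonymous
      if (GENETIC_CODE_4[[c1]] == GENETIC_CODE_4[[c0]]) s <- s + 1
    }
    syn_sites[c0] <- s / 3
  }
  SD <- matrix(NA_real_, 64, 64, dimnames = list(cods, cods))
  ND <- SD
  path_counts <- function(c1, c2) {
    v1 <- s2c(c1); v2 <- s2c(c2)
    dpos <- which(v1 != v2)
    if (length(dpos) == 0L) return(c(0, 0))
    perms <- permutations_of(length(dpos))
    acc <- matrix(NA_real_, length(perms), 2)
    for (pi in seq_along(perms)) {
      cur <- v1; sd <- 0; nd <- 0; valid <- TRUE
      for (pos in dpos[perms[[pi]]]) {
        prev <- c2s(cur); cur[pos] <- v2[pos]; nxt <- c2s(cur)
        if (GENETIC_CODE_4[[nxt]] == "*" && nxt != c2) { valid <- FALSE; break }
        if (GENETIC_CODE_4[[prev]] == GENETIC_CODE_4[[nxt]]) sd <- sd + 1
        else nd <- nd + 1
      }
      if (valid) acc[pi, ] <- c(sd, nd)
    }
    keep <- !is.na(acc[, 1])
    if (!any(keep)) {
      # all pathways pass through a stop: fall back to counting through them
      for (pi in seq_along(perms)) {
        cur <- v1; sd <- 0; nd <- 0
        for (pos in dpos[perms[[pi]]]) {
          prev <- c2s(cur); cur[pos] <- v2[pos]; nxt <- c2s(cur)
          if (GENETIC_CODE_4[[prev]] == GENETIC_CODE_4[[nxt]]) sd <- sd + 1
          else nd <- nd + 1
        }
        acc[pi, ] <- c(sd, nd)
      }
      keep <- rep(TRUE, length(perms))
    }
    colMeans(acc[keep, , drop = FALSE])
  }
  for (c1 in nonstop) for (c2 in nonstop) {
    if (!is.na(SD[c2, c1])) { SD[c1, c2] <- SD[c2, c1]; ND[c1, c2] <- ND[c2, c1]; next }
    pc <- path_counts(c1, c2)
    SD[c1, c2] <- pc[1]; ND[c1, c2] <- pc[2]
  }
  .rates_cache$ng86 <- list(syn_sites = syn_sites, SD = SD, ND = ND)
  .rates_cache$ng86
}

#' Nei-Gojobori (1986) Ka/Ks for a gapless codon alignment
#'
#' Synonymous/nonsynonymous site counts are averaged over both sequences;
#' multi-hit codons average over all minimal substitution pathways that do
#' not pass through a stop codon (if every pathway does, all are counted).
#' Proportions are corrected with the Jukes-Cantor formula
#' -(3/4) log(1 - (4/3) p).  A terminal stop codon pair, and any codon
#' containing N or a stop, is excluded from counting.
#' @param seq_a,seq_b equal-length DNA strings, lengths a multiple of 3.
#' @return list: codons, S, N, Sd, Nd, ps, pn, Ka, Ks, ka_ks (NA when Ks is
#'   0 or a correction is undefined).
#' @export
ng86 <- function(seq_a, seq_b) {
  ca <- codons_of(toupper(seq_a)); cb <- codons_of(toupper(seq_b))
  if (length(ca) != length(cb)) stop("ng86: alignments differ in length")
  if (length(ca) > 0L) {
    la <- ca[length(ca)]; lb <- cb[length(cb)]
    if (la %in% STOP_CODONS_4 && lb %in% STOP_CODONS_4) {
      ca <- ca[-length(ca)]; cb <- cb[-length(cb)]
    }
  }
  keep <- !grepl("N", ca) & !grepl("N", cb) &
    !(ca %in% STOP_CODONS_4) & !(cb %in% STOP_CODONS_4)
  ca <- ca[keep]; cb <- cb[keep]
  if (length(ca) == 0L) stop("ng86: no comparable codons")
  tb <- ng86_tables()
  S <- sum((tb$syn_sites[ca] + tb$syn_sites[cb]) / 2)
  N <- 3 * length(ca) - S
  Sd <- sum(tb$SD[cbind(ca, cb)])
  Nd <- sum(tb$ND[cbind(ca, cb)])
  jc <- function(p) {
    if (p >= 0.75) return(NA_real_)
    -0.75 * log(1 - 4 * p / 3)
  }
  ps <- Sd / S; pn <- Nd / N
  Ks <- jc(ps); Ka <- jc(pn)
  list(codons = length(ca), S = S, N = N, Sd = Sd, Nd = Nd,
       ps = ps, pn = pn, Ka = Ka, Ks = Ks,
       ka_ks = if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_)
}

#' @keywords internal
aln_map <- function(pat_aln, sub_aln) {
  # map: for each ungapped position of the pattern, the ungapped position
  # of the subject aligned to it (NA at gaps)
  pv <- s2c(pat_aln); sv <- s2c(sub_aln)
  ppos <- cumsum(pv != "-"); spos <- cumsum(sv != "-")
  idx <- pv != "-"
  m <- ifelse(sv[idx] != "-", spos[idx], NA_integer_)
  as.integer(m)
}

#' @keywords internal
align_proteins <- function(p_ref, p_other) {
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(p_ref), Biostrings::AAString(p_other),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 4,
    type = "global")
  aln_map(as.character(Biostrings::alignedPattern(aln)),
          as.character(Biostrings::alignedSubject(aln)))
}

#' Protein-guided gapless codon alignment of one gene across species
#'
#' Each CDS is translated under code 4 (after dropping a terminal stop) and
#' globally aligned to the protein of the first species in the input;
#' reference codon positions aligned in every species are kept and threaded
#' back to nucleotides, yielding a gapless codon matrix.  A CDS with an
#' internal stop aborts the gene with an error of class
#' \code{mitocomp_gene_error}.
#' @param gene_cds_by_species named list of CDS strings (>= 2 species).
#' @return named character vector of equal-length gapless codon sequences;
#'   attribute \code{"dropped_nt"} records how many reference nucleotides
#'   were discarded.
#' @export
codon_align <- function(gene_cds_by_species) {
  sp <- names(gene_cds_by_species)
  if (length(sp) < 2L) stop("codon_align: need >= 2 species")
  cods <- list()
  for (s in sp) {
    cds <- toupper(gene_cds_by_species[[s]])
    if (nchar(cds) %% 3L != 0L)
      stop(structure(class = c("mitocomp_gene_error", "error", "condition"),
                     list(message = paste0("codon_align: CDS of ", s,
                                           " not a multiple of 3"),
                          call = sys.call())))
    cc <- codons_of(cds)
    if (length(cc) && cc[length(cc)] %in% STOP_CODONS_4) cc <- cc[-length(cc)]
    if (any(cc %in% STOP_CODONS_4))
      stop(structure(class = c("mitocomp_gene_error", "error", "condition"),
                     list(message = paste0("codon_align: internal stop in ", s),
                          call = sys.call())))
    cods[[s]] <- cc
  }
  ref <- sp[1]
  p_ref <- c2s(GENETIC_CODE_4[cods[[ref]]])
  nref <- length(cods[[ref]])
  maps <- list()
  maps[[ref]] <- seq_len(nref)
  for (s in sp[-1])
    maps[[s]] <- align_proteins(p_ref, c2s(GENETIC_CODE_4[cods[[s]]]))
  keep <- Reduce(`&`, lapply(maps, function(m) !is.na(m)))
  out <- vapply(sp, function(s) c2s(cods[[s]][maps[[s]][keep]]), "")
  structure(setNames(out, sp), dropped_nt = 3L * sum(!keep))
}

#' Pairwise per-gene rate computation across a genome set
#'
#' For each gene present in at least two genomes, builds the gapless codon
#' alignment and computes K2P and NG86 statistics for every species pair.
#' Genes failing alignment (internal stops, frame problems) are skipped
#' with a warning.
#' @param genomes list of \code{mitogenome}s.
#' @param genes gene symbols (default the 15 core PCGs).
#' @return data.frame with one row per (gene, pair): gene, species_a,
#'   species_b, sites, P, Q, k2p, S, N, Sd, Nd, Ka, Ks, ka_ks, saturated.
#' @export
pairwise_rates <- function(genomes, genes = CORE_PCGS) {
  rows <- list()
  sp_order <- sort(vapply(genomes, function(g) g$species_id, ""))
  genomes <- genomes[order(vapply(genomes, function(g) g$species_id, ""))]
  for (gene in genes) {
    cds <- list()
    for (g in genomes) {
      x <- gene_cds(g, gene)
      if (!is.null(x)) cds[[g$species_id]] <- x
    }
    if (length(cds) < 2L) next
    aln <- tryCatch(codon_align(cds), mitocomp_gene_error = function(e) {
      warning("pairwise_rates: gene ", gene, " skipped: ",
              conditionMessage(e)); NULL
    })
    if (is.null(aln)) next
    sp <- names(aln)
    for (i in seq_len(length(sp) - 1L)) for (j in (i + 1L):length(sp)) {
      kk <- k2p(aln[[i]], aln[[j]])
      ng <- ng86(aln[[i]], aln[[j]])
      rows[[length(rows) + 1L]] <- data.frame(
        gene = gene, species_a = sp[i], species_b = sp[j],
        sites = kk$sites, P = kk$P, Q = kk$Q, k2p = kk$k2p,
        S = ng$S, N = ng$N, Sd = ng$Sd, Nd = ng$Nd,
        Ka = ng$Ka, Ks = ng$Ks, ka_ks = ng$ka_ks,
        saturated = kk$saturated, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(gene = character(0)))
  do.call(rbind, rows)
}

#' Per-gene rate aggregation
#'
#' Arithmetic means of K2P, Ka, Ks and Ka/Ks over all defined species
#' pairs, one row per gene in the canonical 15-gene order; pairs with a
#' saturated distance or undefined ratio are excluded from the respective
#' mean and counted.
#' @param pairs data.frame from \code{\link{pairwise_rates}}.
#' @param genes row order (default the 15 core PCGs).
#' @return data.frame: gene, n_pairs, n_dropped_k2p, mean_k2p, mean_ka,
#'   mean_ks, mean_ka_ks.
#' @export
aggregate_rates <- function(pairs, genes = CORE_PCGS) {
  mean_def <- function(x) if (any(!is.na(x))) mean(x, na.rm = TRUE) else NA_real_
  out <- lapply(genes, function(gene) {
    p <- pairs[pairs$gene == gene, , drop = FALSE]
    if (nrow(p) == 0L)
      return(data.frame(gene = gene, n_pairs = 0L, n_dropped_k2p = 0L,
                        mean_k2p = NA_real_, mean_ka = NA_real_,
                        mean_ks = NA_real_, mean_ka_ks = NA_real_))
    data.frame(gene = gene, n_pairs = nrow(p),
               n_dropped_k2p = sum(is.na(p$k2p)),
               mean_k2p = mean_def(p$k2p), mean_ka = mean_def(p$Ka),
               mean_ks = mean_def(p$Ks), mean_ka_ks = mean_def(p$ka_ks))
  })
  do.call(rbind, out)
}
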