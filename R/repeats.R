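# Repeat landscapes: microsatellites (MISA-style maximal runs), dispersed
# forward/palindromic repeats (REPuter-style, Hamming distance <= 3, length
# 30-5000), and a transparent k-mer-seeded tandem-repeat detector.
# Circular genomes are scanned on the doubled sequence with calls
# constrained to start in the first copy, so origin-spanning repeats are
# found; coordinates are reported 1-based and an end may exceed the genome
# length when a call wraps the origin.

#' MISA-style SSR copy-number thresholds by motif length
#' @export
SSR_THRESHOLDS <- c(10L, 5L, 4L, 3L, 3L, 3L)

#' @keywords internal
canonical_rotation <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(motif)
  rots <- vapply(seq_len(p), function(i)
    paste0(substring(motif, i, p), substring(motif, 1, i - 1L)), "")
  sort(rots)[1]
}

#' @keywords internal
is_primitive <- function(motif) {
  p <- nchar(motif)
  if (p == 1L) return(TRUE)
  for (d in seq_len(p - 1L)) {
    if (p %% d != 0L) next
    if (motif == strrep(substring(motif, 1, d), p / d)) return(FALSE)
  }
  TRUE
}

#' Find simple sequence repeats (microsatellites)
#'
#' Maximal tandem runs of a 1-6 nt primitive motif meeting the per-class
#' copy thresholds (mono 10, di 5, tri 4, tetra/penta/hexa 3).  Overlapping
#' SSRs of different motif lengths are all reported; runs are trimmed to
#' whole copies (leftmost) so interval length = motif length x copies.
#' Motifs are reported as the lexicographically smallest rotation.
#' @param g a \code{mitogenome} (or plain DNA string, treated as linear).
#' @param thresholds integer vector of length 6 of minimum copy numbers.
#' @return data.frame: motif, motif_class, copies, start, end (1-based
#'   inclusive), length.
#' @export
find_ssrs <- function(g, thresholds = SSR_THRESHOLDS) {
  if (is.character(g)) g <- mitogenome("seq", g, circular = FALSE)
  L <- genome_length(g)
  s <- if (g$circular) paste0(g$sequence, g$sequence) else g$sequence
  v <- s2c(s)
  n <- length(v)
  classes <- c("mono", "di", "tri", "tetra", "penta", "hexa")
  rows <- list()
  for (p in 1:6) {
    if (n <= p) next
    m <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (k in which(r$values & r$lengths + p >= p * thresholds[p])) {
      pos0 <- starts[k] - 1L               # 0-based run start
      total <- r$lengths[k] + p            # covered nucleotides
      copies <- total %/% p
      if (copies < thresholds[p]) next
      if (g$circular) {
        if (pos0 >= L) next
        # boundary-truncated image of an origin-spanning run
        if (pos0 == 0L && v[L] == v[L + p]) next
        copies <- min(copies, L %/% p)
      }
      motif <- c2s(v[(pos0 + 1L):(pos0 + p)])
      if (grepl("N", motif, fixed = TRUE)) next
      if (!is_primitive(motif)) next
      rows[[length(rows) + 1L]] <- data.frame(
        motif = canonical_rotation(motif), motif_class = classes[p],
        copies = copies, start = pos0 + 1L, end = pos0 + p * copies,
        length = p * copies, stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L)
    return(data.frame(motif = character(0), motif_class = character(0),
                      copies = integer(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  out <- do.call(rbind, rows)
  out[order(out$start, nchar(out$motif)), , drop = FALSE]
}

#' @keywords internal
canonical_pair_df <- function(df) {
  a_first <- df$start_a < df$start_b |
    (df$start_a == df$start_b & df$end_a <= df$end_b)
  res <- df
  res$start_a <- ifelse(a_first, df$start_a, df$start_b)
  res$end_a   <- ifelse(a_first, df$end_a, df$end_b)
  res$start_b <- ifelse(a_first, df$start_b, df$start_a)
  res$end_b   <- ifelse(a_first, df$end_b, df$end_a)
  res[!duplicated(res[, c("orientation", "start_a", "end_a",
                          "start_b", "end_b")]), , drop = FALSE]
}

#' Find dispersed (forward and palindromic) repeats
#'
#' Maximal repeated pairs with at most \code{max_mm} mismatches (Hamming
#' distance) and length within [\code{min_len}, \code{max_len}]: forward
#' pairs between two genome intervals, palindromic pairs between an
#' interval and the reverse complement of another.  Maximality means the
#' window cannot be extended in either direction without exceeding the
#' mismatch budget; symmetric duplicates are removed by interval ordering.
#' @param g a \code{mitogenome} (or plain DNA string, treated as linear).
#' @param min_len,max_len repeat size bounds (defaults 30 and 5000).
#' @param max_mm mismatch budget (default 3).
#' @return data.frame: orientation ("forward"/"palindromic"), start_a,
#'   end_a, start_b, end_b (1-based inclusive), length, mismatches.
#' @export
find_dispersed <- function(g, min_len = 30L, max_len = 5000L, max_mm = 3L) {
  if (is.character(g)) g <- mitogenome("seq", g, circular = FALSE)
  L <- genome_length(g)
  if (L < 2L * min_len)
    return(data.frame(orientation = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), length = integer(0),
                      mismatches = integer(0)))
  doubled <- g$circular
  s <- if (doubled) paste0(g$sequence, g$sequence) else g$sequence
  n <- nchar(s)
  eff_max <- min(max_len, L)

  fw <- .dispersed_scan_cpp(s, s, TRUE, as.integer(min_len),
                            as.integer(eff_max), as.integer(max_mm))
  fw <- as.data.frame(fw)
  if (nrow(fw)) {
    if (doubled) {
      edge <- fw$start_a == 0L | fw$start_b + fw$length == n
      fw <- fw[fw$start_a < L & (fw$start_b - fw$start_a) %% L != 0L & !edge, ,
               drop = FALSE]
      fw$start_a <- fw$start_a %% L
      fw$start_b <- fw$start_b %% L
    }
    fw <- data.frame(orientation = "forward",
                     start_a = fw$start_a + 1L,
                     end_a = fw$start_a + fw$length,
                     start_b = fw$start_b + 1L,
                     end_b = fw$start_b + fw$length,
                     length = fw$length, mismatches = fw$mismatches,
                     stringsAsFactors = FALSE)
  } else fw <- NULL

  # palindromic scan: the second sequence is the reverse complement of a
  # single genome copy.  For a circular genome the first side is doubled,
  # so any pair with at least one origin-contiguous interval is seen in
  # one of its two symmetric forms; boundary-truncated windows are dropped
  # because their full image appears in the other form.
  rc <- revcomp(g$sequence)
  pl <- .dispersed_scan_cpp(s, rc, FALSE, as.integer(min_len),
                            as.integer(eff_max), as.integer(max_mm))
  pl <- as.data.frame(pl)
  if (nrow(pl)) {
    # interval of the reverse-complement hit on the forward strand
    pl$fwd_b <- L - (pl$start_b + pl$length)
    if (doubled) {
      edge <- pl$start_a == 0L | pl$start_a + pl$length == n |
        pl$start_b == 0L | pl$start_b + pl$length == L
      pl <- pl[!edge, , drop = FALSE]
      pl$start_a <- pl$start_a %% L
    }
    pl <- pl[pl$start_a != pl$fwd_b, , drop = FALSE]
    if (nrow(pl)) {
      pl <- data.frame(orientation = "palindromic",
                       start_a = pl$start_a + 1L,
                       end_a = pl$start_a + pl$length,
                       start_b = pl$fwd_b + 1L,
                       end_b = pl$fwd_b + pl$length,
                       length = pl$length, mismatches = pl$mismatches,
                       stringsAsFactors = FALSE)
    } else pl <- NULL
  } else pl <- NULL

  out <- rbind(fw, pl)
  if (is.null(out) || nrow(out) == 0L)
    return(data.frame(orientation = character(0), start_a = integer(0),
                      end_a = integer(0), start_b = integer(0),
                      end_b = integer(0), length = integer(0),
                      mismatches = integer(0)))
  out <- canonical_pair_df(out)
  rownames(out) <- NULL
  out[order(out$orientation, out$start_a, out$start_b), , drop = FALSE]
}

#' Find tandem repeat arrays
#'
#' A transparent seeded detector: for each candidate period an exact
#' recurrence run seeds an array, which is extended greedily while the
#' running identity (matched positions at lag = period over compared
#' positions) stays at or above \code{min_identity}.  Overlapping calls are
#' resolved by largest array length, then smaller period, then leftmost
#' start.  Homopolymer arrays are left to the SSR scanner.
#' @param g a \code{mitogenome} (or plain DNA string, treated as linear).
#' @param min_period,max_period period bounds (defaults 2 and 100).
#' @param min_identity minimum running identity (default 0.85).
#' @param min_copies minimum copy number (default 1.9).
#' @param min_length minimum array length in nt (default 24).
#' @return data.frame: period, copies, start, end (1-based inclusive),
#'   length, consensus, identity.
#' @export
find_tandem <- function(g, min_period = 2L, max_period = 100L,
                        min_identity = 0.85, min_copies = 1.9,
                        min_length = 24L) {
  if (is.character(g)) g <- mitogenome("seq", g, circular = FALSE)
  L <- genome_length(g)
  s <- if (g$circular) paste0(g$sequence, g$sequence) else g$sequence
  v <- s2c(s)
  n <- length(v)
  cands <- list()
  for (p in min_period:min(max_period, n - 1L)) {
    m <- v[seq_len(n - p)] == v[(p + 1L):n]
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    seed_min <- max(4L, p)
    for (k in which(r$values & r$lengths >= seed_min)) {
      a <- starts[k] - 1L                 # 0-based array start
      len <- r$lengths[k] + p             # array nt length
      matches <- r$lengths[k]
      # greedy extension; compared positions are indices a .. a+len-p-1 of m
      repeat {
        ext <- FALSE
        if (a > 0L && (matches + m[a]) / (len + 1L - p) >= min_identity) {
          a <- a - 1L; len <- len + 1L; matches <- matches + m[a + 1L]
          ext <- TRUE
        }
        ri <- a + len - p + 1L            # 1-based index into m of right ext
        if (ri <= length(m) &&
            (matches + m[ri]) / (len + 1L - p) >= min_identity) {
          matches <- matches + m[ri]; len <- len + 1L
          ext <- TRUE
        }
        if (!ext) break
      }
      copies <- len / p
      if (copies < min_copies || len < min_length) next
      if (g$circular && a >= L) next
      len <- min(len, L)
      # consensus by per-column majority over the stacked copies
      idx <- (a + 1L):(a + len)
      cols <- ((seq_along(idx) - 1L) %% p) + 1L
      cons <- vapply(seq_len(p), function(ci) {
        tb <- sort(table(v[idx[cols == ci]]), decreasing = TRUE)
        top <- tb[tb == tb[1]]
        sort(names(top))[1]
      }, "")
      consensus <- c2s(cons)
      if (length(unique(cons)) == 1L) next   # homopolymer -> SSR territory
      ident <- matches / (len - p)
      cands[[length(cands) + 1L]] <- data.frame(
        period = p, copies = copies, start = a + 1L, end = a + len,
        length = len, consensus = consensus, identity = ident,
        stringsAsFactors = FALSE)
    }
  }
  if (length(cands) == 0L)
    return(data.frame(period = integer(0), copies = numeric(0),
                      start = integer(0), end = integer(0),
                      length = integer(0), consensus = character(0),
                      identity = numeric(0)))
  df <- unique(do.call(rbind, cands))
  df <- df[order(-df$length, df$period, df$start), , drop = FALSE]
  taken <- rep(FALSE, if (g$circular) 2L * L else L)
  keep <- logical(nrow(df))
  for (i in seq_len(nrow(df))) {
    idx <- df$start[i]:df$end[i]
    if (!any(taken[idx])) { keep[i] <- TRUE; taken[idx] <- TRUE }
  }
  df <- df[keep, , drop = FALSE]
  rownames(df) <- NULL
  df[order(df$start), , drop = FALSE]
}

#' Assign repeats to genome region classes
#'
#' Each repeat interval gets the region class covering the majority of its
#' nucleotides; ties go to the earlier class in the partition precedence
#' (PCG exon > rRNA > tRNA > intron > free ORF > intergenic).  For
#' dispersed repeats both intervals are classified.
#' @param g a \code{mitogenome}
#' @param repeats data.frame with 1-based columns start, end (and
#'   optionally start_b, end_b).
#' @return the input data.frame with region (and region_b) columns added.
#' @export
localize_repeats <- function(g, repeats) {
  part <- region_partition(g)
  cls <- attr(part, "class_vector")
  L <- genome_length(g)
  classify <- function(st, en) {
    idx <- (((st:en) - 1L) %% L) + 1L
    tb <- table(factor(cls[idx], levels = REGION_CLASSES))
    names(tb)[which.max(tb)]   # which.max takes the first max -> precedence
  }
  has_a <- "start_a" %in% names(repeats)
  sa <- if (has_a) repeats$start_a else repeats$start
  ea <- if (has_a) repeats$end_a else repeats$end
  repeats$region <- vapply(seq_len(nrow(repeats)),
                           function(i) classify(sa[i], ea[i]), "")
  if ("start_b" %in% names(repeats))
    repeats$region_b <- vapply(seq_len(nrow(repeats)), function(i)
      classify(repeats$start_b[i], repeats$end_b[i]), "")
  repeats
}
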