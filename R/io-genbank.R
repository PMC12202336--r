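# GenBank flat-file I/O for annotated mitogenomes.  Single record per file;
# CDS locations use join() for multi-exon genes and complement() for the
# minus strand; /transl_table=4 on coding features.  GenBank coordinates are
# 1-based inclusive and are converted to the internal 0-based half-open
# convention on read.

.GB_DATE <- "01-JAN-2026"   # fixed so identical genomes serialize identically

#' @keywords internal
location_string <- function(f, L) {
  iv <- function(st, en) {
    if (en - st == 1L) sprintf("%d", st + 1L) else sprintf("%d..%d", st + 1L, en)
  }
  if (f$strand == "+") {
    parts <- f$parts                      # stored 5'->3' (= reading order)
  } else {
    parts <- f$parts[order(f$parts[, "start"]), , drop = FALSE]
  }
  segs <- vapply(seq_len(nrow(parts)),
                 function(i) iv(parts[i, 1], parts[i, 2]), "")
  loc <- if (length(segs) > 1L) paste0("join(", paste(segs, collapse = ","), ")")
         else segs
  if (f$strand == "-") loc <- paste0("complement(", loc, ")")
  loc
}

#' @keywords internal
parse_location <- function(loc, feature_label) {
  loc <- gsub("[<>[:space:]]", "", loc)
  strand <- "+"
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) loc <- sub("^join\\((.*)\\)$", "\\1", loc)
  segs <- strsplit(loc, ",", fixed = TRUE)[[1]]
  if (length(segs) == 0L)
    stop("malformed location for feature ", feature_label, ": empty")
  parts <- matrix(0L, nrow = length(segs), ncol = 2,
                  dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(segs)) {
    s <- segs[i]
    if (grepl("^[0-9]+\\.\\.[0-9]+$", s)) {
      ab <- as.integer(strsplit(s, "..", fixed = TRUE)[[1]])
    } else if (grepl("^[0-9]+$", s)) {
      ab <- rep(as.integer(s), 2L)
    } else {
      stop("malformed location for feature ", feature_label, ": '", s, "'")
    }
    if (ab[2] < ab[1])
      stop("malformed location for feature ", feature_label,
           ": end before start in '", s, "'")
    parts[i, ] <- c(ab[1] - 1L, ab[2])    # 1-based inclusive -> 0-based half-open
  }
  if (strand == "-") parts <- parts[rev(seq_len(nrow(parts))), , drop = FALSE]
  list(strand = strand, parts = parts)
}

#' Write a mitogenome as a GenBank flat file
#'
#' Emits a single record with join() CDS locations, explicit intron
#' features carrying their subclass in /note, and the sequence in ORIGIN
#' blocks.  Byte output is deterministic for identical input.
#' @param g a \code{mitogenome}
#' @param path output file path
#' @export
write_genbank <- function(g, path) {
  L <- genome_length(g)
  topo <- if (g$circular) "circular" else "linear  "
  lines <- c(
    sprintf("LOCUS       %-16s %11d bp    DNA     %s MIT %s",
            g$species_id, L, topo, .GB_DATE),
    sprintf("DEFINITION  %s mitochondrion, complete genome.", g$species_id),
    sprintf("ACCESSION   %s", g$species_id),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-15s %s", "source", sprintf("1..%d", L)),
    sprintf("                     /organism=\"%s\"", g$species_id)
  )
  qual <- function(k, v) sprintf("                     /%s=%s", k, v)
  for (f in g$features) {
    key <- switch(f$kind, PCG = "CDS", orf = "CDS", rRNA = "rRNA",
                  tRNA = "tRNA", intron = "intron")
    lines <- c(lines, sprintf("     %-15s %s", key, location_string(f, L)),
               qual("gene", sprintf("\"%s\"", f$name)))
    if (f$kind %in% c("PCG", "orf"))
      lines <- c(lines, qual("transl_table", "4"))
    if (f$kind == "intron") {
      if (!is.null(f$parent_gene))
        lines <- c(lines, qual("parent_gene", sprintf("\"%s\"", f$parent_gene)))
      lines <- c(lines, qual("note",
                             sprintf("\"group=%s\"", f$intron_group %||% "unknown")))
    }
    if (!is.null(f$note) && f$kind != "intron")
      lines <- c(lines, qual("note", sprintf("\"%s\"", f$note)))
  }
  lines <- c(lines, "ORIGIN")
  pos <- seq(1L, L, 60L)
  for (p in pos) {
    starts <- seq(p, p + 50L, 10L)
    starts <- starts[starts <= L]
    blk <- substring(g$sequence, starts, pmin(starts + 9L, L))
    lines <- c(lines, sprintf("%9d %s", p, tolower(paste(blk, collapse = " "))))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

#' Read a GenBank flat file into a mitogenome
#'
#' Parses LOCUS, FEATURES and ORIGIN of a single-record flat file.  CDS
#' join() gaps between consecutive exon parts of the same gene are
#' reconciled with explicit intron features when both are present: an
#' explicit intron matching a join gap exactly supplies the subclass label;
#' a gap with no explicit intron becomes an intron feature with group
#' "unknown"; an explicit intron overlapping a gap with different
#' coordinates triggers a warning and the explicit feature wins.
#' @param path GenBank flat file
#' @return a \code{mitogenome}
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  if (length(lines) == 0L || !grepl("^LOCUS", lines[1]))
    stop("not a GenBank flat file (no LOCUS line): ", path)
  toks <- strsplit(trimws(lines[1]), "[[:space:]]+")[[1]]
  stated_len <- as.integer(toks[3])
  circular <- any(toks == "circular")
  species_id <- toks[2]
  fi <- grep("^FEATURES", lines)[1]
  oi <- grep("^ORIGIN", lines)[1]
  if (is.na(oi)) stop("no ORIGIN section in ", path)

  # --- sequence ---
  seq_lines <- lines[(oi + 1L):length(lines)]
  seq_lines <- seq_lines[!grepl("^//", seq_lines)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (!is.na(stated_len) && nchar(sequence) != stated_len)
    stop("integrity error in ", path, ": LOCUS says ", stated_len,
         " bp but ORIGIN has ", nchar(sequence))

  # --- features ---
  raw <- list()
  if (!is.na(fi)) {
    i <- fi + 1L
    while (i < oi) {
      ln <- lines[i]
      if (grepl("^     [A-Za-z]", ln)) {
        key <- trimws(substr(ln, 1, 20))
        loc <- trimws(substr(ln, 21, nchar(ln)))
        i <- i + 1L
        # location continuation lines (indented, not qualifiers)
        while (i < oi && grepl("^                     [^/]", lines[i])) {
          loc <- paste0(loc, trimws(lines[i])); i <- i + 1L
        }
        quals <- character(0)
        while (i < oi && grepl("^                     /", lines[i])) {
          quals <- c(quals, trimws(lines[i])); i <- i + 1L
        }
        raw[[length(raw) + 1L]] <- list(key = key, loc = loc, quals = quals)
      } else i <- i + 1L
    }
  }
  qval <- function(quals, name) {
    hit <- grep(paste0("^/", name, "="), quals, value = TRUE)
    if (length(hit) == 0L) return(NULL)
    gsub("^\"|\"$", "", sub(paste0("^/", name, "="), "", hit[1]))
  }

  feats <- list()
  explicit_introns <- list()
  for (r in raw) {
    if (r$key == "source") next
    label <- paste0(r$key, " ", qval(r$quals, "gene") %||% r$loc)
    pl <- parse_location(r$loc, label)
    gene <- qval(r$quals, "gene")
    note <- qval(r$quals, "note")
    if (r$key == "CDS") {
      nm <- gene %||% "unknown_cds"
      kind <- if (grepl("^orf", nm)) "orf" else "PCG"
      feats[[length(feats) + 1L]] <-
        feature(kind, nm, pl$strand, pl$parts,
                note = if (!is.null(note)) note else NULL)
    } else if (r$key %in% c("rRNA", "tRNA")) {
      feats[[length(feats) + 1L]] <-
        feature(r$key, gene %||% paste0("unknown_", r$key), pl$strand, pl$parts)
    } else if (r$key == "intron") {
      grp <- "unknown"
      if (!is.null(note) && grepl("group=", note))
        grp <- sub(".*group=([A-Za-z0-9]+).*", "\\1", note)
      if (!grp %in% INTRON_GROUPS) grp <- "unknown"
      explicit_introns[[length(explicit_introns) + 1L]] <-
        feature("intron", gene %||% "intron", pl$strand, pl$parts,
                intron_group = grp,
                parent_gene = qval(r$quals, "parent_gene") %||% gene)
    }
    # other keys (misc_feature etc.) ignored
  }

  # --- derive introns from CDS/rRNA join gaps and reconcile ---
  L <- nchar(sequence)
  gap_intervals <- function(f) {
    if (nrow(f$parts) < 2L) return(list())
    p <- f$parts
    ord <- if (f$strand == "+") seq_len(nrow(p)) else rev(seq_len(nrow(p)))
    pa <- p[ord, , drop = FALSE]           # ascending along genome in reading order
    gaps <- list()
    for (i in seq_len(nrow(pa) - 1L)) {
      a <- pa[i, "end"]; b <- pa[i + 1L, "start"]
      if (b > a) {
        gaps[[length(gaps) + 1L]] <- matrix(c(a, b), ncol = 2)
      } else if (b < a && circular) {
        # origin-crossing gap; parts contiguous across the origin leave
        # no gap and empty sub-intervals are dropped
        gp <- matrix(c(a, L, 0L, b), ncol = 2, byrow = TRUE)
        gp <- gp[gp[, 2] > gp[, 1], , drop = FALSE]
        if (nrow(gp)) gaps[[length(gaps) + 1L]] <- gp
      }
    }
    gaps
  }
  matched <- rep(FALSE, length(explicit_introns))
  for (f in feats) {
    if (!f$kind %in% c("PCG", "rRNA")) next
    for (gap in gap_intervals(f)) {
      hit <- NA_integer_
      for (j in seq_along(explicit_introns)) {
        if (matched[j]) next
        ej <- explicit_introns[[j]]
        pj <- ej$parts[order(ej$parts[, "start"]), , drop = FALSE]
        gj <- gap[order(gap[, 1]), , drop = FALSE]
        if (identical(unname(pj), unname(matrix(as.integer(gj), ncol = 2)))) {
          hit <- j; break
        }
      }
      if (!is.na(hit)) {
        matched[hit] <- TRUE
        ei <- explicit_introns[[hit]]
        ei$parent_gene <- ei$parent_gene %||% f$name
        feats[[length(feats) + 1L]] <- ei
      } else {
        overlap <- any(vapply(seq_along(explicit_introns), function(j) {
          if (matched[j]) return(FALSE)
          pj <- explicit_introns[[j]]$parts
          any(pj[, "start"] < max(gap[, 2]) & pj[, "end"] > min(gap[, 1]))
        }, TRUE))
        if (overlap)
          warning("intron annotation conflict in gene ", f$name,
                  ": join gap and explicit intron disagree; keeping explicit")
        gp <- if (f$strand == "-") gap[rev(seq_len(nrow(gap))), , drop = FALSE]
              else gap
        feats[[length(feats) + 1L]] <-
          feature("intron", paste0(f$name, "-intron"), f$strand, gp,
                  intron_group = "unknown", parent_gene = f$name)
      }
    }
  }
  # explicit introns not matching any gap are kept as annotated
  for (j in seq_along(explicit_introns))
    if (!matched[j]) feats[[length(feats) + 1L]] <- explicit_introns[[j]]

  mitogenome(species_id, sequence, circular = circular, features = feats)
}
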