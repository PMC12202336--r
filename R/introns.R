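# Group-I intron positional-class (Pcl) homology mapping: each intron is
# labeled by the coordinate of the last reference-CDS nucleotide 5' of its
# insertion point (label "P<pos>", 1-based), transferred through a global
# alignment of the host gene to an intronless reference CDS.  Co-positional
# introns are clustered into ortholog groups by sequence identity; the
# species x Pcl presence/absence matrix feeds Dollo or Fitch gain/loss
# reconstruction on a species tree.

#' Globally align a species CDS to an intronless reference CDS
#'
#' Affine-gap global DNA alignment (defaults: match +2, mismatch -3, gap
#' open 5, gap extend 2) returning the coordinate map from species CDS
#' positions to reference CDS positions (NA where the species base sits in
#' a reference gap).  An alignment with identity below \code{min_identity}
#' over its aligned columns raises an error of class
#' \code{mitocomp_unalignable}.
#' @param species_cds exon-concatenated CDS of the species gene.
#' @param reference_cds intronless reference CDS.
#' @param match,mismatch,gap_open,gap_extend scoring parameters.
#' @param min_identity unalignability threshold (default 0.3).
#' @return list: map (integer vector, length nchar(species_cds)), identity,
#'   score.
#' @export
align_cds_to_reference <- function(species_cds, reference_cds,
                                   match = 2, mismatch = -3,
                                   gap_open = 5, gap_extend = 2,
                                   min_identity = 0.3) {
  if (!nzchar(species_cds) || !nzchar(reference_cds))
    stop("align_cds_to_reference: empty sequence")
  sm <- Biostrings::nucleotideSubstitutionMatrix(match = match,
                                                 mismatch = mismatch,
                                                 baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(species_cds), Biostrings::DNAString(reference_cds),
    substitutionMatrix = sm, gapOpening = gap_open, gapExtension = gap_extend,
    type = "global")
  pa <- as.character(Biostrings::alignedPattern(aln))
  sa <- as.character(Biostrings::alignedSubject(aln))
  pv <- s2c(pa); sv <- s2c(sa)
  both <- pv != "-" & sv != "-"
  ident <- if (any(both)) mean(pv[both] == sv[both]) else 0
  if (ident < min_identity)
    stop(structure(list(message = paste0("align_cds_to_reference: identity ",
                                         sprintf("%.3f", ident),
                                         " below ", min_identity),
                        call = sys.call()),
                   class = c("mitocomp_unalignable", "error", "condition")))
  list(map = aln_map(pa, sa), identity = ident, score = Biostrings::score(aln))
}

#' @keywords internal
host_feature <- function(g, gene) {
  find_gene(g, gene, "PCG") %||% find_gene(g, gene, "rRNA")
}

#' @keywords internal
intron_insertion_offsets <- function(g, gene) {
  # species-CDS 1-based position of the last exon nucleotide 5' of each
  # intron of the host gene, in 5'->3' intron order
  host <- host_feature(g, gene)
  ins <- gene_introns(g, gene)
  if (is.null(host) || length(ins) == 0L) return(integer(0))
  p <- host$parts
  exon_cum <- cumsum(p[, "end"] - p[, "start"])
  offs <- vapply(ins, function(f) {
    st <- feature_start(f)
    # the intron sits in the gap after exon part k (5'->3')
    for (k in seq_len(nrow(p) - 1L)) {
      if (host$strand == "+") {
        gap_lo <- p[k, "end"]; gap_hi <- p[k + 1L, "start"]
        inside <- if (gap_hi >= gap_lo) st >= gap_lo && st < gap_hi
                  else st >= gap_lo || st < gap_hi   # origin-crossing gap
      } else {
        gap_lo <- p[k + 1L, "end"]; gap_hi <- p[k, "start"]
        inside <- if (gap_hi >= gap_lo) st >= gap_lo && st < gap_hi
                  else st >= gap_lo || st < gap_hi
      }
      if (inside) return(exon_cum[k])
    }
    NA_integer_
  }, 0L)
  offs
}

#' Assign positional classes to the introns of one gene
#'
#' Transfers each intron's insertion coordinate through the species-to-
#' reference CDS alignment.  The Pcl position is the reference coordinate
#' of the last aligned exon nucleotide 5' of the insertion; when that
#' column is a reference gap the nearest aligned column 5' of it is used
#' and the assignment is marked unconfident.  An unalignable gene yields
#' undetermined ("*") assignments for all its introns.
#' @param g a \code{mitogenome}
#' @param gene host gene symbol (PCG or rRNA)
#' @param reference_cds intronless reference CDS for the gene.
#' @param min_flank aligned columns required on each side of the insertion
#'   for a confident assignment (default 10, inspected within a 30-nt
#'   window).
#' @param flank_window window (nt) for the flank checks and the reported
#'   flanking identity (default 30).
#' @return data.frame: species, gene, intron_name, intron_group, position,
#'   label, confident, identity, intron_length, seq.
#' @export
assign_pcl <- function(g, gene, reference_cds, min_flank = 10L,
                       flank_window = 30L) {
  ins <- gene_introns(g, gene)
  empty <- data.frame(species = character(0), gene = character(0),
                      intron_name = character(0), intron_group = character(0),
                      position = integer(0), label = character(0),
                      confident = logical(0), identity = numeric(0),
                      intron_length = integer(0), seq = character(0),
                      stringsAsFactors = FALSE)
  if (length(ins) == 0L) return(empty)
  host <- host_feature(g, gene)
  if (is.null(host)) return(empty)
  species_cds <- feature_seq(g, host)
  al <- tryCatch(align_cds_to_reference(species_cds, reference_cds),
                 mitocomp_unalignable = function(e) NULL)
  offs <- intron_insertion_offsets(g, gene)
  n <- nchar(species_cds)
  rows <- lapply(seq_along(ins), function(k) {
    f <- ins[[k]]
    iseq <- feature_seq(g, f)
    base <- data.frame(species = g$species_id, gene = gene,
                       intron_name = f$name,
                       intron_group = f$intron_group %||% "unknown",
                       position = NA_integer_, label = "*",
                       confident = FALSE, identity = NA_real_,
                       intron_length = nchar(iseq), seq = iseq,
                       stringsAsFactors = FALSE)
    i <- offs[k]
    if (is.null(al) || is.na(i) || i < 1L) return(base)
    map <- al$map
    j <- i
    while (j >= 1L && is.na(map[j])) j <- j - 1L
    if (j < 1L) return(base)
    pos <- map[j]
    direct <- (j == i)
    lo <- max(1L, i - flank_window + 1L)
    hi <- min(n, i + flank_window)
    left_aln <- sum(!is.na(map[lo:i]))
    right_aln <- if (i < n) sum(!is.na(map[(i + 1L):hi])) else 0L
    conf <- direct && left_aln >= min_flank && right_aln >= min_flank
    sp <- s2c(species_cds); rf <- s2c(reference_cds)
    win <- lo:hi
    mapped <- win[!is.na(map[win])]
    ident <- if (length(mapped)) mean(sp[mapped] == rf[map[mapped]]) else NA_real_
    base$position <- pos
    base$label <- paste0("P", pos)
    base$confident <- conf
    base$identity <- ident
    base
  })
  do.call(rbind, rows)
}

#' Pcl assignments for every intron in a genome set
#'
#' @param genomes list of \code{mitogenome}s.
#' @param reference named list of intronless reference CDS strings (names =
#'   gene symbols); genes without a reference are skipped.
#' @inheritParams assign_pcl
#' @return row-bound assignment data.frame (see \code{\link{assign_pcl}}).
#' @export
pcl_assignments <- function(genomes, reference, min_flank = 10L,
                            flank_window = 30L) {
  out <- list()
  for (g in genomes) {
    hosts <- unique(vapply(features_of_kind(g, "intron"),
                           function(f) f$parent_gene %||% NA_character_, ""))
    for (gene in sort(stats::na.omit(hosts))) {
      if (is.null(reference[[gene]])) next
      out[[length(out) + 1L]] <-
        assign_pcl(g, gene, reference[[gene]], min_flank, flank_window)
    }
  }
  if (length(out) == 0L)
    return(assign_pcl(mitogenome("empty", "A", FALSE), "none", "ATG"))
  do.call(rbind, out)
}

#' @keywords internal
pair_identity_dna <- function(a, b) {
  if (!nzchar(a) || !nzchar(b)) return(0)
  aln <- Biostrings::pairwiseAlignment(Biostrings::DNAString(a),
                                       Biostrings::DNAString(b),
                                       type = "global")
  Biostrings::pid(aln, type = "PID3") / 100   # identity over shorter seq
}

#' Cluster co-positional introns into ortholog groups
#'
#' Introns sharing a (gene, position) are compared pairwise by global
#' sequence identity (over the shorter intron); single-linkage components
#' at \code{identity_threshold} become ortholog groups.  When a position
#' splits, labels get suffixes (P100a, P100b) in order of their first
#' species.  Matrix cells: "1" = confident presence, "*" = undetermined
#' (unconfident or unalignable assignments, never counted as presence),
#' "0" = absence.
#' @param assignments data.frame from \code{\link{pcl_assignments}}.
#' @param identity_threshold minimum within-group identity (default 0.7).
#' @param species row set (default: species seen in assignments, sorted).
#' @return character matrix species x Pcl with values in \{"0","1","*"\};
#'   columns named "<gene>:P<pos>[suffix]", positionless introns collected
#'   per gene under "<gene>:P*".
#' @export
cluster_orthologs <- function(assignments, identity_threshold = 0.7,
                              species = NULL) {
  if (is.null(species)) species <- sort(unique(assignments$species))
  a <- assignments
  cols <- list()
  det <- a[!is.na(a$position), , drop = FALSE]
  if (nrow(det)) {
    det$key <- paste0(det$gene, ":", det$position)
    for (key in unique(det$key[order(det$gene, det$position)])) {
      grp <- det[det$key == key, , drop = FALSE]
      m <- nrow(grp)
      comp <- seq_len(m)
      if (m > 1L) {
        for (i in seq_len(m - 1L)) for (j in (i + 1L):m) {
          if (pair_identity_dna(grp$seq[i], grp$seq[j]) >= identity_threshold) {
            ci <- comp[i]; cj <- comp[j]
            comp[comp == cj] <- ci
          }
        }
      }
      comp_ids <- unique(comp[order(match(grp$species, sort(grp$species)),
                                    seq_len(m))])
      for (ci in seq_along(comp_ids)) {
        members <- grp[comp == comp_ids[ci], , drop = FALSE]
        suffix <- if (length(comp_ids) > 1L) letters[ci] else ""
        label <- paste0(members$gene[1], ":P", members$position[1], suffix)
        cell <- setNames(rep("0", length(species)), species)
        for (r in seq_len(nrow(members))) {
          sp <- members$species[r]
          val <- if (members$confident[r]) "1" else "*"
          if (cell[sp] != "1") cell[sp] <- val
        }
        cols[[label]] <- cell
      }
    }
  }
  und <- a[is.na(a$position), , drop = FALSE]
  if (nrow(und)) {
    for (gene in sort(unique(und$gene))) {
      label <- paste0(gene, ":P*")
      cell <- setNames(rep("0", length(species)), species)
      cell[unique(und$species[und$gene == gene])] <- "*"
      cols[[label]] <- cell
    }
  }
  if (length(cols) == 0L)
    return(matrix(character(0), nrow = length(species), ncol = 0,
                  dimnames = list(species, NULL)))
  do.call(cbind, cols)
}

#' @keywords internal
node_label <- function(tree, node) {
  n_tip <- length(tree$tip.label)
  if (node <= n_tip) tree$tip.label[node] else paste0("node", node)
}

#' Gain/loss reconstruction of Pcl presence/absence on a species tree
#'
#' Dollo mode: a single gain on the branch to the most recent common
#' ancestor of all present tips, with the minimal set of losses below it
#' (maximal presence-free subtrees containing at least one confirmed
#' absence).  Fitch mode: two-pass parsimony with ties at the root resolved
#' toward absence.  Undetermined ("*") cells are treated as missing data
#' and never force an event; columns without a single presence are
#' rejected.
#' @param matrix character matrix from \code{\link{cluster_orthologs}}
#'   (values "0"/"1"/"*"), or a logical matrix.
#' @param tree rooted ape \code{phylo}; tips must cover the matrix rows.
#' @param mode "dollo" or "fitch".
#' @return data.frame: pcl, branch (label of the child node of the edge),
#'   node (child node id), event ("gain"/"loss").
#' @export
gain_loss <- function(matrix, tree, mode = c("dollo", "fitch")) {
  mode <- match.arg(mode)
  if (is.logical(matrix)) {
    m <- ifelse(matrix, "1", "0")
    dimnames(m) <- dimnames(matrix)
    matrix <- m
  }
  sp <- rownames(matrix)
  if (!all(sp %in% tree$tip.label))
    stop("gain_loss: matrix species not in tree: ",
         paste(setdiff(sp, tree$tip.label), collapse = ", "))
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  events <- list()
  add_ev <- function(pcl, node, event) {
    events[[length(events) + 1L]] <<- data.frame(
      pcl = pcl, branch = node_label(tree, node), node = node,
      event = event, stringsAsFactors = FALSE)
  }
  for (col in colnames(matrix) %||% seq_len(ncol(matrix))) {
    states <- setNames(rep("*", n_tip), tree$tip.label)
    states[sp] <- matrix[, col]
    if (!any(states == "1"))
      stop("gain_loss: column '", col, "' has no presence")
    if (mode == "dollo") {
      present_tips <- which(tree$tip.label %in% names(states)[states == "1"])
      mrca <- if (length(present_tips) == 1L) present_tips
              else ape::getMRCA(tree, present_tips)
      add_ev(col, mrca, "gain")
      # minimal losses: maximal subtrees below the mrca with no presence
      # and at least one confirmed absence
      summarize <- function(node) {
        # returns c(has_present, has_absent) for the subtree at node
        if (node <= n_tip) {
          st <- states[tree$tip.label[node]]
          return(c(st == "1", st == "0"))
        }
        agg <- c(FALSE, FALSE)
        for (k in kids[[as.character(node)]]) agg <- agg | summarize(k)
        agg
      }
      walk <- function(node) {
        for (k in kids[[as.character(node)]] %||% integer(0)) {
          s <- summarize(k)
          if (!s[1]) {
            if (s[2]) add_ev(col, k, "loss")
          } else if (k > n_tip) walk(k)
        }
      }
      if (mrca > n_tip) walk(mrca)
    } else {
      # Fitch two-pass with "*" as {0,1}
      up <- vector("list", max(tree$edge))
      for (i in seq_len(n_tip))
        up[[i]] <- switch(states[tree$tip.label[i]],
                          "1" = "1", "0" = "0", c("0", "1"))
      internal <- sort(unique(tree$edge[, 1]), decreasing = TRUE)
      for (node in internal) {
        sets <- lapply(kids[[as.character(node)]], function(k) up[[k]])
        inter <- Reduce(intersect, sets)
        up[[node]] <- if (length(inter)) inter else
          sort(unique(unlist(sets)))
      }
      final <- character(max(tree$edge))
      final[root] <- if ("0" %in% up[[root]]) "0" else "1"
      preorder <- unique(tree$edge[, 1])
      for (node in preorder) {
        for (k in kids[[as.character(node)]]) {
          final[k] <- if (final[node] %in% up[[k]]) final[node]
                      else if ("0" %in% up[[k]] && "1" %in% up[[k]]) final[node]
                      else up[[k]][1]
          if (final[k] != final[node])
            add_ev(col, k, if (final[k] == "1") "gain" else "loss")
        }
      }
      if (final[root] == "1") add_ev(col, root, "gain")
    }
  }
  if (length(events) == 0L)
    return(data.frame(pcl = character(0), branch = character(0),
                      node = integer(0), event = character(0)))
  do.call(rbind, events)
}

#' Replay gain/loss events along a tree
#'
#' Starting from absence at the root, applies the events of each Pcl on
#' the path from root to every tip; used to verify that a reconstruction
#' reproduces the tip matrix.
#' @param events data.frame from \code{\link{gain_loss}}.
#' @param tree the rooted \code{phylo} used for reconstruction.
#' @param pcls column set (default: Pcls seen in events).
#' @return logical matrix tips x pcls.
#' @export
replay_gain_loss <- function(events, tree, pcls = NULL) {
  if (is.null(pcls)) pcls <- unique(events$pcl)
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  out <- matrix(FALSE, n_tip, length(pcls),
                dimnames = list(tree$tip.label, pcls))
  for (pcl in pcls) {
    ev <- events[events$pcl == pcl, , drop = FALSE]
    state_at <- function(node, state) {
      here <- ev[ev$node == node, , drop = FALSE]
      if (nrow(here)) state <- here$event[nrow(here)] == "gain"
      if (node <= n_tip) {
        out[node, pcl] <<- state
      } else {
        for (k in kids[[as.character(node)]]) state_at(k, state)
      }
    }
    root_ev <- ev[ev$node == root, , drop = FALSE]
    state_at_root <- if (nrow(root_ev)) root_ev$event[nrow(root_ev)] == "gain"
                     else FALSE
    for (k in kids[[as.character(root)]]) state_at(k, state_at_root)
  }
  out
}

#' Per-species and per-gene intron census
#'
#' Counts and length totals of annotated introns per species, split by
#' host-feature kind (core PCG vs rRNA) and intron subclass, with shares
#' as percentages rounded half-up to 2 decimals.
#' @param genomes list of \code{mitogenome}s.
#' @return list: per_species (data.frame), per_gene (host gene counts),
#'   groups (subclass tallies), totals (n, in_pcg, in_rrna, unassigned,
#'   pcg_pct, rrna_pct).
#' @export
intron_census <- function(genomes) {
  if (inherits(genomes, "mitogenome")) genomes <- list(genomes)
  rows <- list(); per_gene <- list(); groups <- character(0)
  for (g in genomes) {
    ins <- features_of_kind(g, "intron")
    n_pcg <- 0L; n_rrna <- 0L; n_un <- 0L; nt <- 0L
    for (f in ins) {
      nt <- nt + feature_length(f)
      host <- if (!is.null(f$parent_gene)) host_feature(g, f$parent_gene)
              else NULL
      if (is.null(host)) {
        n_un <- n_un + 1L
        warning("intron_census: intron '", f$name, "' in ", g$species_id,
                " lacks a resolvable parent gene; counted as unassigned")
      } else if (host$kind == "PCG") n_pcg <- n_pcg + 1L
      else n_rrna <- n_rrna + 1L
      if (!is.null(f$parent_gene))
        per_gene[[f$parent_gene]] <- (per_gene[[f$parent_gene]] %||% 0L) + 1L
      groups <- c(groups, f$intron_group %||% "unknown")
    }
    rows[[length(rows) + 1L]] <- data.frame(
      species = g$species_id, n_introns = length(ins), intron_nt = nt,
      in_pcg = n_pcg, in_rrna = n_rrna, unassigned = n_un,
      stringsAsFactors = FALSE)
  }
  per_species <- do.call(rbind, rows)
  total <- sum(per_species$n_introns)
  tot <- list(n = total,
              in_pcg = sum(per_species$in_pcg),
              in_rrna = sum(per_species$in_rrna),
              unassigned = sum(per_species$unassigned))
  tot$pcg_pct <- if (total > 0) pct2(tot$in_pcg, total) else "0.00"
  tot$rrna_pct <- if (total > 0) pct2(tot$in_rrna, total) else "0.00"
  grp <- table(factor(groups, levels = INTRON_GROUPS))
  per_gene_df <- if (length(per_gene))
    data.frame(gene = names(per_gene), n_introns = unname(unlist(per_gene)),
               stringsAsFactors = FALSE)
  else data.frame(gene = character(0), n_introns = integer(0))
  list(per_species = per_species,
       per_gene = per_gene_df,
       groups = as.data.frame(grp, responseName = "n_introns",
                              stringsAsFactors = FALSE) |>
         setNames(c("group", "n_introns")),
       totals = tot)
}

#' Rare positional classes
#'
#' Pcl columns present in exactly one species — the candidates the field
#' screens for horizontal intron transfer against distant taxa.
#' @param matrix character matrix from \code{\link{cluster_orthologs}}.
#' @return data.frame: pcl, species.
#' @export
rare_pcls <- function(matrix) {
  out <- list()
  for (col in colnames(matrix)) {
    present <- rownames(matrix)[matrix[, col] == "1"]
    if (length(present) == 1L)
      out[[length(out) + 1L]] <- data.frame(pcl = col, species = present,
                                            stringsAsFactors = FALSE)
  }
  if (!length(out)) return(data.frame(pcl = character(0),
                                      species = character(0)))
  do.call(rbind, out)
}
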