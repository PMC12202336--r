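# Synthetic annotated mitogenomes with known ground truth.  An ancestral
# genome (stop-free PCGs under genetic code 4 at a target AT fraction,
# rRNAs, tRNAs, intergenic spacers, a catalog of group-I introns with fixed
# insertion positions) is evolved down a species tree; introns follow a
# planted presence/absence history, point substitutions accumulate per
# branch (internal stops repaired), intergenic spacers take indels, and
# repeats are planted at assembly time with recorded coordinates.

.DEFAULT_GENE_LENGTHS <- c(
  atp6 = 774L, atp8 = 147L, atp9 = 222L, cob = 1158L, cox1 = 1608L,
  cox2 = 750L, cox3 = 810L, nad1 = 1104L, nad2 = 1680L, nad3 = 417L,
  nad4 = 1470L, nad4L = 267L, nad5 = 1980L, nad6 = 630L, rps3 = 1341L)

.DEFAULT_RRNA_LENGTHS <- c(rns = 1500L, rnl = 3200L)

.TRNA_NAMES <- c("trnA", "trnC", "trnD", "trnE", "trnF", "trnG", "trnH",
                 "trnI", "trnK", "trnL1", "trnL2", "trnM", "trnN", "trnP",
                 "trnQ", "trnR", "trnS1", "trnS2", "trnT", "trnV", "trnW",
                 "trnY", "trnM2", "trnR2", "trnG2")

#' Default positional-class catalog of plantable group-I introns
#'
#' One row per intron lineage: host gene, insertion position in the
#' reference CDS/rRNA (1-based, nucleotide 5' of the insertion point),
#' intron length, and subclass.
#' @export
default_pcl_catalog <- function() {
  data.frame(
    gene = c(rep("cox1", 5), "cob", "cob", "nad1", "nad5", "nad5",
             "cox2", "cox3", "atp6", "atp9", "nad4",
             "rnl", "rnl", "rnl", "rns"),
    position = c(212L, 709L, 720L, 731L, 1057L, 392L, 823L, 400L, 717L,
                 416L, 151L, 219L, 572L, 100L, 505L,
                 1120L, 2050L, 2450L, 560L),
    length = c(1100L, 900L, 1300L, 1000L, 1200L, 1150L, 800L, 950L, 1050L,
               850L, 900L, 750L, 800L, 700L, 880L,
               1400L, 1000L, 1100L, 900L),
    group = c("IB", "IA", "IB", "IB", "IC1", "IB", "ID", "IB", "IC2", "IA",
              "IB", "ID", "IA", "IB", "IB",
              "IB", "IA", "IB", "IC1"),
    stringsAsFactors = FALSE)
}

#' Default planted presence/absence history (7 species, 84 introns)
#'
#' A hand-laid species x Pcl matrix with 64 intron presences in PCGs and
#' 20 in rRNA genes (84 total), per-species counts ranging from 5 to 15 —
#' the shape reported for intron-rich cordycipitoid mitogenome sets.
#' @export
default_presence <- function() {
  cat <- default_pcl_catalog()
  labels <- paste0(cat$gene, ":P", cat$position)
  sp <- sprintf("S%02d", 1:7)
  m <- matrix(FALSE, 7, nrow(cat), dimnames = list(sp, labels))
  pres <- list(
    "cox1:P212"  = c(1, 2, 3, 5, 6, 7),
    "cox1:P709"  = c(1, 2, 3, 4, 5, 6),
    "cox1:P720"  = c(1, 3, 5),
    "cox1:P731"  = c(1, 2, 3, 4, 6, 7),
    "cox1:P1057" = c(1, 2, 3, 5, 7),
    "cob:P392"   = c(1, 2, 3, 5, 6, 7),
    "cob:P823"   = c(1, 3, 5, 6),
    "nad1:P400"  = c(1, 2, 3, 6, 7),
    "nad5:P717"  = c(2, 4, 7),
    "nad5:P416"  = c(1, 2, 6, 7),
    "cox2:P151"  = c(1, 2, 3, 4, 5, 6),
    "cox3:P219"  = c(3, 5),
    "atp6:P572"  = c(1, 5, 7),
    "atp9:P100"  = c(2, 3, 6),
    "nad4:P505"  = c(1, 6),
    "rnl:P1120"  = 1:7,
    "rnl:P2050"  = c(1, 2, 3, 5, 6, 7),
    "rnl:P2450"  = c(1, 2, 6, 7),
    "rns:P560"   = c(2, 3, 5))
  for (lab in names(pres)) m[pres[[lab]], lab] <- TRUE
  m
}

#' Default planted repeats
#' @export
default_planted_repeats <- function() {
  list(list(type = "SSR", motif = "A", copies = 12L),
       list(type = "SSR", motif = "AT", copies = 7L),
       list(type = "SSR", motif = "AAT", copies = 5L),
       list(type = "tandem", motif = "ACGTAG", copies = 4L),
       list(type = "dispersed_forward", length = 60L),
       list(type = "dispersed_palindromic", length = 45L))
}

#' Simulation configuration
#'
#' @param seed integer; fixes all downstream randomness.
#' @param n_species number of tips (ignored when \code{tree} is given).
#' @param tree NULL for the default 7-species topology (when applicable),
#'   "random" for a Yule tree with unit-exponential branch lengths, a
#'   Newick string, or an ape \code{phylo}.
#' @param at_fraction target genomic AT fraction (default 0.74).
#' @param gene_lengths named vector of PCG CDS lengths (nt, multiples of 3).
#' @param rrna_lengths named vector of rRNA lengths.
#' @param trna_names tRNA gene symbols (lengths drawn from 71-85 nt).
#' @param pcl_catalog data.frame(gene, position, length, group).
#' @param presence logical species x Pcl-label matrix, or NULL to draw a
#'   Dollo-consistent random history.
#' @param loss_rate per-edge loss probability for random histories.
#' @param per_branch_sub_rate substitutions per site per branch (default
#'   0.02); multiplied by branch length when
#'   \code{scale_by_branch_length}.
#' @param scale_by_branch_length logical (default FALSE).
#' @param synonymous_only restrict PCG substitutions to synonymous
#'   third-position changes (default FALSE).
#' @param indel_rate indels per intergenic site per branch (default 0.002).
#' @param intergenic_mean mean spacer length, geometric (default 200).
#' @param intron_orf_prob probability an intron carries a homing
#'   endonuclease-like ORF (default 0.5).
#' @param free_orfs list of free-standing ORFs (name, length).
#' @param planted_repeats list of repeat specs (see
#'   \code{\link{default_planted_repeats}}); use list() for none.
#' @param minus_strand_trnas how many tRNAs go on the minus strand.
#' @param species_ids tip labels (default S01..).
#' @return a \code{sim_config} list.
#' @export
sim_config <- function(seed = 1L, n_species = 7L, tree = NULL,
                       at_fraction = 0.74,
                       gene_lengths = .DEFAULT_GENE_LENGTHS,
                       rrna_lengths = .DEFAULT_RRNA_LENGTHS,
                       trna_names = .TRNA_NAMES,
                       pcl_catalog = default_pcl_catalog(),
                       presence = NULL,
                       loss_rate = 0.15,
                       per_branch_sub_rate = 0.02,
                       scale_by_branch_length = FALSE,
                       synonymous_only = FALSE,
                       indel_rate = 0.002,
                       intergenic_mean = 200,
                       intron_orf_prob = 0.5,
                       free_orfs = list(list(name = "orf319", length = 960L)),
                       planted_repeats = default_planted_repeats(),
                       minus_strand_trnas = 2L,
                       species_ids = NULL) {
  if (any(gene_lengths %% 3L != 0L))
    stop("sim_config: PCG lengths must be multiples of 3")
  if (per_branch_sub_rate < 0 || per_branch_sub_rate > 0.5 ||
      indel_rate < 0 || indel_rate > 0.5)
    stop("sim_config: rates must lie in [0, 0.5]")
  # keep only catalog entries whose host is simulated
  hosts <- c(names(gene_lengths), names(rrna_lengths))
  pcl_catalog <- pcl_catalog[pcl_catalog$gene %in% hosts, , drop = FALSE]
  host_len <- c(gene_lengths, rrna_lengths)
  bad <- pcl_catalog$position < 1L |
    pcl_catalog$position >= host_len[pcl_catalog$gene]
  if (any(bad))
    stop("sim_config: catalog position outside host gene for ",
         paste(pcl_catalog$gene[bad], collapse = ", "))
  if (is.null(species_ids)) species_ids <- sprintf("S%02d", seq_len(n_species))
  if (!is.null(presence)) {
    if (!all(rownames(presence) %in% species_ids) ||
        nrow(presence) != length(species_ids))
      stop("sim_config: presence rows must match species ids")
    labels <- paste0(pcl_catalog$gene, ":P", pcl_catalog$position)
    if (!setequal(colnames(presence), labels))
      stop("sim_config: presence columns must match the catalog labels")
  }
  structure(list(seed = as.integer(seed), n_species = length(species_ids),
                 tree = tree, at_fraction = at_fraction,
                 gene_lengths = gene_lengths, rrna_lengths = rrna_lengths,
                 trna_names = trna_names, pcl_catalog = pcl_catalog,
                 presence = presence, loss_rate = loss_rate,
                 per_branch_sub_rate = per_branch_sub_rate,
                 scale_by_branch_length = scale_by_branch_length,
                 synonymous_only = synonymous_only,
                 indel_rate = indel_rate,
                 intergenic_mean = intergenic_mean,
                 intron_orf_prob = intron_orf_prob,
                 free_orfs = free_orfs,
                 planted_repeats = planted_repeats,
                 minus_strand_trnas = minus_strand_trnas,
                 species_ids = species_ids),
            class = "sim_config")
}

#' @keywords internal
random_bases <- function(n, at_fraction) {
  if (n <= 0L) return(character(0))
  p_at <- at_fraction / 2; p_gc <- (1 - at_fraction) / 2
  sample(.BASES, n, replace = TRUE, prob = c(p_at, p_gc, p_gc, p_at))
}

#' @keywords internal
random_cds <- function(len, at_fraction) {
  # ATG start, TAA stop, internal codons stop-free under code 4
  nc <- len %/% 3L
  v <- random_bases(len, at_fraction)
  v[1:3] <- c("A", "T", "G")
  v[(len - 2L):len] <- c("T", "A", "A")
  repeat {
    cods <- vapply(seq_len(nc), function(i) c2s(v[(3 * i - 2):(3 * i)]), "")
    bad <- which(cods[-c(1L, nc)] %in% STOP_CODONS_4) + 1L
    if (!length(bad)) break
    for (ci in bad)
      v[(3 * ci - 2):(3 * ci)] <- random_bases(3L, at_fraction)
  }
  v
}

#' @keywords internal
yule_tree <- function(species_ids) {
  n <- length(species_ids)
  if (n == 2L)
    return(ape::read.tree(text = sprintf("(%s:1,%s:1);",
                                         species_ids[1], species_ids[2])))
  # grow by splitting a uniformly chosen current tip (Yule process)
  as_nwk <- function(x) if (is.character(x)) x else
    paste0("(", as_nwk(x[[1]]), ",", as_nwk(x[[2]]), ")")
  split_tip <- function(node, target, newlab) {
    if (is.character(node))
      return(if (node == target) list(node, newlab) else node)
    list(split_tip(node[[1]], target, newlab),
         split_tip(node[[2]], target, newlab))
  }
  tips <- species_ids[1:2]
  tree <- list(species_ids[1], species_ids[2])
  for (k in 3:n) {
    pick <- sample(tips, 1)
    tree <- split_tip(tree, pick, species_ids[k])
    tips <- c(tips, species_ids[k])
  }
  tr <- ape::read.tree(text = paste0(as_nwk(tree), ";"))
  tr$edge.length <- stats::rexp(nrow(tr$edge))
  tr
}

#' @keywords internal
resolve_tree <- function(cfg) {
  sp <- cfg$species_ids
  if (length(sp) == 1L) return(NULL)
  if (is.null(cfg$tree)) {
    if (length(sp) == 7L)
      return(ape::read.tree(text = sprintf(
        "((%s:1,(%s:1,%s:1):1):1,((%s:1,%s:1):1,(%s:1,%s:1):1):1);",
        sp[1], sp[2], sp[3], sp[4], sp[5], sp[6], sp[7])))
    return(yule_tree(sp))
  }
  if (inherits(cfg$tree, "phylo")) tr <- cfg$tree
  else if (identical(cfg$tree, "random")) tr <- yule_tree(sp)
  else tr <- ape::read.tree(text = cfg$tree)
  if (!setequal(tr$tip.label, sp))
    stop("simulate: tree tips do not match species ids")
  if (is.null(tr$edge.length)) tr$edge.length <- rep(1, nrow(tr$edge))
  tr
}

# ---- ancestral genome -------------------------------------------------

#' @keywords internal
.sim_ancestor <- function(cfg) {
  set.seed(cfg$seed)
  blocks <- list(); meta <- list()
  for (g in names(cfg$gene_lengths)) {
    blocks[[paste0("cds:", g)]] <- random_cds(cfg$gene_lengths[[g]],
                                              cfg$at_fraction)
    meta[[paste0("cds:", g)]] <- list(type = "cds", gene = g)
  }
  for (g in names(cfg$rrna_lengths)) {
    blocks[[paste0("rrna:", g)]] <- random_bases(cfg$rrna_lengths[[g]],
                                                 cfg$at_fraction)
    meta[[paste0("rrna:", g)]] <- list(type = "rna", gene = g)
  }
  trna_len <- sample(71:85, length(cfg$trna_names), replace = TRUE)
  for (i in seq_along(cfg$trna_names)) {
    key <- paste0("trna:", cfg$trna_names[i])
    blocks[[key]] <- random_bases(trna_len[i], cfg$at_fraction)
    meta[[key]] <- list(type = "rna", gene = cfg$trna_names[i])
  }
  for (o in cfg$free_orfs) {
    key <- paste0("orf:", o$name)
    blocks[[key]] <- random_cds(o$length, cfg$at_fraction)
    meta[[key]] <- list(type = "cds", gene = o$name)
  }
  cat <- cfg$pcl_catalog
  if (nrow(cat)) for (i in seq_len(nrow(cat))) {
    key <- paste0("intron:", cat$gene[i], ":P", cat$position[i])
    v <- random_bases(cat$length[i], cfg$at_fraction)
    orf_off <- NA_integer_; orf_len <- NA_integer_; orf_fam <- NA_character_
    if (stats::runif(1) < cfg$intron_orf_prob && cat$length[i] >= 420L) {
      orf_len <- 3L * sample(100L:min(150L, (cat$length[i] - 60L) %/% 3L), 1)
      orf_off <- sample(30L:(cat$length[i] - orf_len - 30L), 1)
      v[(orf_off + 1L):(orf_off + orf_len)] <- random_cds(orf_len,
                                                          cfg$at_fraction)
      orf_fam <- sample(c("LAGLIDADG-like", "GIY-YIG-like"), 1)
    }
    blocks[[key]] <- v
    meta[[key]] <- list(type = "intron", gene = cat$gene[i],
                        position = cat$position[i], group = cat$group[i],
                        label = paste0(cat$gene[i], ":P", cat$position[i]),
                        orf_off = orf_off, orf_len = orf_len,
                        orf_family = orf_fam)
  }
  # feature order: majors with tRNAs distributed round-robin between them
  majors <- list()
  majors[[length(majors) + 1L]] <- list(kind = "rRNA", name = "rns",
                                        block = "rrna:rns", strand = "+")
  majors[[length(majors) + 1L]] <- list(kind = "rRNA", name = "rnl",
                                        block = "rrna:rnl", strand = "+")
  for (g in names(cfg$gene_lengths))
    majors[[length(majors) + 1L]] <- list(kind = "PCG", name = g,
                                          block = paste0("cds:", g),
                                          strand = "+")
  for (o in cfg$free_orfs)
    majors[[length(majors) + 1L]] <- list(kind = "orf", name = o$name,
                                          block = paste0("orf:", o$name),
                                          strand = "+")
  minus <- if (cfg$minus_strand_trnas > 0L)
    utils::tail(cfg$trna_names, cfg$minus_strand_trnas) else character(0)
  order_spec <- list()
  nt <- length(cfg$trna_names)
  nm <- length(majors)
  ti <- 1L
  for (k in seq_len(nm)) {
    order_spec[[length(order_spec) + 1L]] <- majors[[k]]
    # distribute tRNAs evenly after each major feature
    n_here <- (nt * k) %/% nm - (nt * (k - 1L)) %/% nm
    for (z in seq_len(n_here)) {
      nmx <- cfg$trna_names[ti]; ti <- ti + 1L
      order_spec[[length(order_spec) + 1L]] <-
        list(kind = "tRNA", name = nmx, block = paste0("trna:", nmx),
             strand = if (nmx %in% minus) "-" else "+")
    }
  }
  n_slots <- length(order_spec) + 1L
  igs_len <- rgeom1(n_slots, cfg$intergenic_mean)
  for (i in seq_len(n_slots)) {
    key <- paste0("igs:", i)
    blocks[[key]] <- random_bases(igs_len[i], cfg$at_fraction)
    meta[[key]] <- list(type = "igs", index = i)
  }
  # assign planted repeats to distinct intergenic slots
  planted_slots <- integer(0)
  if (length(cfg$planted_repeats)) {
    eligible <- seq(2L, n_slots - 1L)
    planted_slots <- sort(sample(eligible,
                                 min(length(cfg$planted_repeats) * 2L,
                                     length(eligible))))
  }
  list(blocks = blocks, meta = meta, order_spec = order_spec,
       n_slots = n_slots, planted_slots = planted_slots)
}

#' Reference intronless CDS set of a simulation
#'
#' The ancestral exon sequences (PCGs and rRNAs) that define the Pcl
#' coordinate frame for the run; equal to every species' genes when the
#' divergence dial is zero.
#' @param cfg a \code{sim_config}
#' @return named list of DNA strings.
#' @export
make_reference_cds <- function(cfg) {
  anc <- .sim_ancestor(cfg)
  keys <- names(anc$blocks)
  out <- list()
  for (k in keys[startsWith(keys, "cds:")])
    out[[sub("^cds:", "", k)]] <- c2s(anc$blocks[[k]])
  for (k in keys[startsWith(keys, "rrna:")])
    out[[sub("^rrna:", "", k)]] <- c2s(anc$blocks[[k]])
  out
}

# ---- per-branch mutation ----------------------------------------------

.TS_MAP <- c(A = "G", G = "A", C = "T", T = "C")
.TV_MAP <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))

#' @keywords internal
mutate_plain <- function(v, rate) {
  n <- length(v)
  if (rate <= 0 || n == 0L) return(v)
  idx <- which(stats::runif(n) < rate)
  for (i in idx) {
    b <- v[i]
    if (!b %in% .BASES) next
    v[i] <- if (stats::runif(1) < 0.5) .TS_MAP[[b]] else sample(.TV_MAP[[b]], 1)
  }
  v
}

#' @keywords internal
repair_stops <- function(v, from = 1L, to = length(v)) {
  # resample codons that became stops (keeps frame; first/last codon of the
  # window are the start and terminal stop and are left alone)
  nc <- (to - from + 1L) %/% 3L
  if (nc <= 2L) return(v)
  repeat {
    starts <- from + 3L * (seq_len(nc) - 1L)
    cods <- paste0(v[starts], v[starts + 1L], v[starts + 2L])
    bad <- which(cods %in% STOP_CODONS_4)
    bad <- bad[bad != 1L & bad != nc]
    if (!length(bad)) break
    for (ci in bad) {
      p <- starts[ci] + sample(0:2, 1)
      v[p] <- sample(.BASES, 1)
    }
  }
  v
}

#' @keywords internal
.SYN3_CACHE <- new.env(parent = emptyenv())

#' @keywords internal
synonymous_third <- function(cod) {
  if (is.null(.SYN3_CACHE$map)) {
    map <- list()
    for (c0 in all_codons()) {
      if (GENETIC_CODE_4[[c0]] == "*") { map[[c0]] <- character(0); next }
      alts <- character(0)
      for (b in setdiff(.BASES, substring(c0, 3, 3))) {
        c1 <- paste0(substring(c0, 1, 2), b)
        if (GENETIC_CODE_4[[c1]] == GENETIC_CODE_4[[c0]]) alts <- c(alts, b)
      }
      map[[c0]] <- alts
    }
    .SYN3_CACHE$map <- map
  }
  .SYN3_CACHE$map[[cod]]
}

#' @keywords internal
mutate_cds_block <- function(v, rate, synonymous_only) {
  n <- length(v); nc <- n %/% 3L
  if (rate <= 0) return(v)
  if (synonymous_only) {
    hit <- which(stats::runif(nc) < rate)
    hit <- hit[hit > 1L & hit < nc]
    for (ci in hit) {
      cod <- paste0(v[3 * ci - 2], v[3 * ci - 1], v[3 * ci])
      alts <- synonymous_third(cod)
      if (length(alts)) v[3 * ci] <- sample(alts, 1)
    }
    return(v)
  }
  w <- mutate_plain(v, rate)
  w[1:3] <- v[1:3]                       # keep start codon
  w[(n - 2L):n] <- v[(n - 2L):n]         # keep terminal stop
  repair_stops(w)
}

#' @keywords internal
mutate_blocks <- function(blocks, meta, rate, cfg) {
  for (key in names(blocks)) {
    m <- meta[[key]]
    v <- blocks[[key]]
    if (m$type == "cds") {
      blocks[[key]] <- mutate_cds_block(v, rate, cfg$synonymous_only)
    } else if (m$type == "intron") {
      w <- mutate_plain(v, rate)
      if (!is.na(m$orf_off %||% NA)) {
        a <- m$orf_off + 1L; b <- m$orf_off + m$orf_len
        w[a:(a + 2L)] <- v[a:(a + 2L)]
        w[(b - 2L):b] <- v[(b - 2L):b]
        w <- repair_stops(w, a, b)
      }
      blocks[[key]] <- w
    } else if (m$type == "igs") {
      w <- mutate_plain(v, rate)
      if (cfg$indel_rate > 0 && length(w) > 0L) {
        n_ev <- stats::rbinom(1, length(w), cfg$indel_rate)
        for (z in seq_len(n_ev)) {
          len <- sample(1:8, 1)
          if (stats::runif(1) < 0.5 && length(w) > len + 2L) {
            at <- sample(length(w) - len, 1)
            w <- w[-(at:(at + len - 1L))]
          } else {
            at <- sample(length(w), 1)
            w <- append(w, random_bases(len, cfg$at_fraction), after = at)
          }
        }
      }
      blocks[[key]] <- w
    } else {
      blocks[[key]] <- mutate_plain(v, rate)
    }
  }
  blocks
}

# ---- planted history ---------------------------------------------------

#' @keywords internal
random_history <- function(cfg, tree) {
  cat <- cfg$pcl_catalog
  labels <- paste0(cat$gene, ":P", cat$position)
  sp <- cfg$species_ids
  m <- matrix(FALSE, length(sp), length(labels), dimnames = list(sp, labels))
  if (length(sp) == 1L) {
    m[1, ] <- stats::runif(length(labels)) < 0.7
    return(m)
  }
  n_tip <- length(tree$tip.label)
  nodes <- c(seq_len(n_tip), (n_tip + 1L):(n_tip + tree$Nnode))
  desc_tips <- function(node) {
    if (node <= n_tip) return(tree$tip.label[node])
    ape::extract.clade(tree, node)$tip.label
  }
  for (j in seq_along(labels)) {
    for (try in 1:20) {
      gain_node <- if (stats::runif(1) < 0.5) n_tip + 1L
                   else sample(nodes, 1)
      below <- desc_tips(gain_node)
      lost <- below[stats::runif(length(below)) < cfg$loss_rate]
      present <- setdiff(below, lost)
      if (length(present)) break
    }
    if (!length(present)) present <- tree$tip.label
    m[present, j] <- TRUE
  }
  m
}

# ---- assembly ----------------------------------------------------------

#' @keywords internal
guard_base <- function(avoid) setdiff(.BASES, avoid)[1]

#' @keywords internal
plant_repeat_seqs <- function(spec, cfg) {
  # returns list of segments to insert (each: chars, truth row fields)
  if (spec$type %in% c("SSR", "tandem")) {
    motif <- spec$motif
    p <- nchar(motif)
    core <- s2c(strrep(motif, spec$copies))
    lg <- guard_base(substring(motif, p, p))
    rg <- guard_base(substring(motif, 1, 1))
    list(list(seq = c(lg, core, rg), core_off = 1L,
              core_len = length(core),
              info = list(type = spec$type, motif = motif,
                          copies = spec$copies)))
  } else {
    core <- random_bases(spec$length, cfg$at_fraction)
    second <- if (spec$type == "dispersed_forward") core else rev(.COMPLEMENT[core])
    list(list(seq = core, core_off = 0L, core_len = length(core),
              info = list(type = spec$type, motif = NA_character_,
                          copies = NA_integer_)),
         list(seq = unname(second), core_off = 0L, core_len = length(second),
              info = list(type = spec$type, motif = NA_character_,
                          copies = NA_integer_)))
  }
}

#' @keywords internal
assemble_tip <- function(sp, blocks, anc, presence_row, cfg) {
  cat <- cfg$pcl_catalog
  seq_parts <- character(0)
  feats <- list()
  pos <- 0L
  truth_introns <- list(); truth_orfs <- list(); truth_repeats <- list()
  totals <- setNames(numeric(length(REGION_CLASSES)), REGION_CLASSES)
  # pre-draw planted repeat segments and their slots
  plant_by_slot <- list()
  if (length(cfg$planted_repeats)) {
    slot_i <- 1L
    for (spec in cfg$planted_repeats) {
      segs <- plant_repeat_seqs(spec, cfg)
      for (sg in segs) {
        slot <- anc$planted_slots[((slot_i - 1L) %% length(anc$planted_slots)) + 1L]
        plant_by_slot[[as.character(slot)]] <-
          c(plant_by_slot[[as.character(slot)]] %||% list(), list(sg))
        slot_i <- slot_i + 1L
      }
    }
  }
  emit_igs <- function(i) {
    v <- blocks[[paste0("igs:", i)]]
    planted <- plant_by_slot[[as.character(i)]]
    if (!is.null(planted)) {
      for (sg in planted) {
        at <- max(1L, length(v) %/% 2L)
        v <- append(v, sg$seq, after = at)
        truth_repeats[[length(truth_repeats) + 1L]] <<- data.frame(
          species = sp, type = sg$info$type,
          motif = sg$info$motif, copies = sg$info$copies,
          start = pos + at + sg$core_off + 1L,
          end = pos + at + sg$core_off + sg$core_len,
          region = "intergenic", stringsAsFactors = FALSE)
      }
    }
    seq_parts[[length(seq_parts) + 1L]] <<- c2s(v)
    totals[["intergenic"]] <<- totals[["intergenic"]] + length(v)
    pos <<- pos + length(v)
  }
  for (k in seq_along(anc$order_spec)) {
    emit_igs(k)
    fd <- anc$order_spec[[k]]
    if (fd$kind %in% c("PCG", "rRNA")) {
      gene <- fd$name
      v <- blocks[[fd$block]]
      rows <- which(cat$gene == gene &
                      presence_row[paste0(cat$gene, ":P", cat$position)])
      rows <- rows[order(cat$position[rows])]
      cuts <- cat$position[rows]             # insert after this many exon nt
      exon_bounds <- c(0L, cuts, length(v))  # exon segment boundaries
      gstart <- pos
      exon_parts <- NULL
      cur <- pos
      for (e in seq_len(length(exon_bounds) - 1L)) {
        ex <- v[(exon_bounds[e] + 1L):exon_bounds[e + 1L]]
        seq_parts[[length(seq_parts) + 1L]] <- c2s(ex)
        exon_parts <- rbind(exon_parts, c(cur, cur + length(ex)))
        cur <- cur + length(ex)
        cls <- if (fd$kind == "PCG") "PCG_exon" else "rRNA"
        totals[[cls]] <- totals[[cls]] + length(ex)
        if (e <= length(rows)) {
          ri <- rows[e]
          ikey <- paste0("intron:", gene, ":P", cat$position[ri])
          iv <- blocks[[ikey]]
          seq_parts[[length(seq_parts) + 1L]] <- c2s(iv)
          im <- anc$meta[[ikey]]
          feats[[length(feats) + 1L]] <-
            feature("intron", paste0(gene, "-i", cat$position[ri]),
                    "+", matrix(c(cur, cur + length(iv)), ncol = 2),
                    intron_group = cat$group[ri], parent_gene = gene)
          truth_introns[[length(truth_introns) + 1L]] <- data.frame(
            species = sp, gene = gene,
            label = paste0(gene, ":P", cat$position[ri]),
            position = cat$position[ri], group = cat$group[ri],
            start = cur + 1L, end = cur + length(iv),
            stringsAsFactors = FALSE)
          if (!is.na(im$orf_off %||% NA))
            truth_orfs[[length(truth_orfs) + 1L]] <- data.frame(
              species = sp, intron = paste0(gene, ":P", cat$position[ri]),
              family = im$orf_family,
              start = cur + im$orf_off + 1L,
              end = cur + im$orf_off + im$orf_len,
              stringsAsFactors = FALSE)
          totals[["intron"]] <- totals[["intron"]] + length(iv)
          cur <- cur + length(iv)
        }
      }
      feats[[length(feats) + 1L]] <-
        feature(fd$kind, gene, "+", exon_parts)
      pos <- cur
    } else {
      v <- blocks[[fd$block]]
      emit <- if (fd$strand == "-") rev(unname(.COMPLEMENT[v])) else v
      seq_parts[[length(seq_parts) + 1L]] <- c2s(emit)
      cls <- switch(fd$kind, tRNA = "tRNA", orf = "free_orf", "tRNA")
      totals[[cls]] <- totals[[cls]] + length(v)
      feats[[length(feats) + 1L]] <-
        feature(fd$kind, fd$name, fd$strand,
                matrix(c(pos, pos + length(v)), ncol = 2))
      pos <- pos + length(v)
    }
  }
  emit_igs(anc$n_slots)
  g <- mitogenome(sp, c2s(unlist(seq_parts)), circular = TRUE,
                  features = feats)
  list(genome = g, totals = totals,
       introns = truth_introns, orfs = truth_orfs, repeats = truth_repeats)
}

#' Simulate annotated mitogenomes with ground truth
#'
#' @param cfg a \code{\link{sim_config}}.
#' @return list with \code{genomes} (named list of \code{mitogenome}),
#'   \code{truth} (tree, presence matrix, gain/loss events, per-species
#'   region totals, intron/intronic-ORF/planted-repeat tables, reference
#'   CDS list) and \code{config}.
#' @export
simulate_mitogenomes <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  anc <- .sim_ancestor(cfg)        # seeds the RNG with cfg$seed
  tree <- resolve_tree(cfg)
  presence <- if (!is.null(cfg$presence)) {
    m <- cfg$presence[cfg$species_ids, , drop = FALSE]
    labels <- paste0(cfg$pcl_catalog$gene, ":P", cfg$pcl_catalog$position)
    m[, labels, drop = FALSE]
  } else random_history(cfg, tree)
  # evolve blocks down the tree
  tip_blocks <- vector("list", cfg$n_species)
  names(tip_blocks) <- cfg$species_ids
  if (is.null(tree)) {
    rate <- cfg$per_branch_sub_rate
    tip_blocks[[1]] <- mutate_blocks(anc$blocks, anc$meta, rate, cfg)
  } else {
    n_tip <- length(tree$tip.label)
    recurse <- function(node, blocks) {
      child_rows <- which(tree$edge[, 1] == node)
      for (r in child_rows) {
        k <- tree$edge[r, 2]
        rate <- cfg$per_branch_sub_rate *
          (if (cfg$scale_by_branch_length) tree$edge.length[r] else 1)
        nb <- mutate_blocks(blocks, anc$meta, rate, cfg)
        if (k <= n_tip) tip_blocks[[tree$tip.label[k]]] <<- nb
        else recurse(k, nb)
      }
    }
    recurse(n_tip + 1L, anc$blocks)
  }
  genomes <- list(); totals <- list()
  introns <- list(); orfs <- list(); repeats <- list()
  for (sp in cfg$species_ids) {
    at <- assemble_tip(sp, tip_blocks[[sp]], anc, presence[sp, ], cfg)
    genomes[[sp]] <- at$genome
    totals[[sp]] <- at$totals
    introns <- c(introns, at$introns)
    orfs <- c(orfs, at$orfs)
    repeats <- c(repeats, at$repeats)
  }
  events <- if (!is.null(tree)) {
    pm <- matrix(ifelse(presence, "1", "0"), nrow = nrow(presence),
                 dimnames = dimnames(presence))
    keep <- colSums(presence) > 0
    if (any(keep)) gain_loss(pm[, keep, drop = FALSE], tree, mode = "dollo")
    else NULL
  } else NULL
  bindrows <- function(x) if (length(x)) do.call(rbind, x) else NULL
  ref <- list()
  for (k in names(anc$blocks)) {
    if (startsWith(k, "cds:")) ref[[sub("^cds:", "", k)]] <- c2s(anc$blocks[[k]])
    if (startsWith(k, "rrna:")) ref[[sub("^rrna:", "", k)]] <- c2s(anc$blocks[[k]])
  }
  list(genomes = genomes,
       truth = list(tree = tree, presence = presence, events = events,
                    region_totals = totals,
                    introns = bindrows(introns), intronic_orfs = bindrows(orfs),
                    planted_repeats = bindrows(repeats), reference = ref),
       config = cfg)
}

#' Write a simulation bundle to disk
#'
#' Per-species GenBank files, the reference FASTA, the species tree and a
#' JSON ground-truth file.
#' @param sim result of \code{\link{simulate_mitogenomes}}.
#' @param dir output directory (created if needed).
#' @export
sim_write_bundle <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sp in names(sim$genomes))
    write_genbank(sim$genomes[[sp]], file.path(dir, paste0(sp, ".gbk")))
  write_fasta(sim$truth$reference, file.path(dir, "reference.fasta"))
  if (!is.null(sim$truth$tree))
    write_newick(sim$truth$tree, file.path(dir, "tree.nwk"))
  gt <- list(presence = apply(sim$truth$presence, 1, function(r)
               names(r)[r], simplify = FALSE),
             region_totals = sim$truth$region_totals,
             introns = sim$truth$introns,
             planted_repeats = sim$truth$planted_repeats)
  jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
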