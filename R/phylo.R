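# Distance-based phylogeny stage: concatenation of gapless per-gene codon
# alignments, K2P distance matrix, neighbor joining (ape) with negative
# branch lengths clamped, nonparametric bootstrap over supermatrix columns,
# and Robinson-Foulds topology comparison via bipartition sets.

#' Concatenate per-gene alignments into a supermatrix
#'
#' @param per_gene_alignments named list of gapless alignments (each a
#'   named character vector of equal-length sequences, as produced by
#'   \code{\link{codon_align}}); all must share the same species set.
#' @return named character vector of concatenated sequences with attribute
#'   \code{"boundaries"} (cumulative end column of each gene, named).
#' @export
concatenate_alignments <- function(per_gene_alignments) {
  if (length(per_gene_alignments) == 0L)
    stop("concatenate_alignments: no alignments")
  sp <- sort(names(per_gene_alignments[[1]]))
  bad <- character(0)
  for (gene in names(per_gene_alignments)) {
    if (!setequal(names(per_gene_alignments[[gene]]), sp))
      bad <- c(bad, paste0(gene, " (",
                           paste(c(setdiff(sp, names(per_gene_alignments[[gene]])),
                                   setdiff(names(per_gene_alignments[[gene]]), sp)),
                                 collapse = ","), ")"))
  }
  if (length(bad))
    stop("concatenate_alignments: species set mismatch in ",
         paste(bad, collapse = "; "))
  segs <- lapply(per_gene_alignments, function(a) unname(a[sp]))
  out <- do.call(paste0, segs)
  names(out) <- sp
  bounds <- cumsum(vapply(per_gene_alignments,
                          function(a) nchar(a[[1]]), 0L))
  structure(out, boundaries = bounds)
}

#' K2P distance matrix from a set of equal-length sequences
#'
#' @param seqs named character vector of equal-length gapless sequences.
#' @return symmetric numeric matrix with zero diagonal; a saturated pair is
#'   NA.
#' @export
k2p_matrix <- function(seqs) {
  sp <- names(seqs)
  n <- length(sp)
  d <- matrix(0, n, n, dimnames = list(sp, sp))
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    d[i, j] <- d[j, i] <- k2p(seqs[[i]], seqs[[j]])$k2p
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Classic Q-criterion neighbor joining.  Taxa are sorted lexicographically
#' before agglomeration so tie-breaks are deterministic; negative branch
#' lengths are clamped to zero with the subtracted amount moved to the
#' sibling edge.
#' @param d symmetric distance matrix (>= 3 taxa, no missing entries).
#' @param outgroup optional taxon name; when given the returned tree is
#'   rooted on the edge leading to it.
#' @return ape \code{phylo} (unrooted unless \code{outgroup} is given).
#' @export
nj_tree <- function(d, outgroup = NULL) {
  if (any(is.na(d))) stop("nj_tree: missing distances (saturated pairs?)")
  if (nrow(d) < 3L) stop("nj_tree: need >= 3 taxa")
  ord <- order(rownames(d))
  d <- d[ord, ord]
  tr <- ape::nj(stats::as.dist(d))
  # clamp negative branch lengths, preserving path lengths where possible
  neg <- which(tr$edge.length < 0)
  for (e in neg) {
    amt <- tr$edge.length[e]
    parent <- tr$edge[e, 1]
    sibs <- which(tr$edge[, 1] == parent & seq_along(tr$edge.length) != e)
    tr$edge.length[e] <- 0
    if (length(sibs)) {
      s <- sibs[1]
      tr$edge.length[s] <- max(0, tr$edge.length[s] + amt)
    }
  }
  if (!is.null(outgroup)) {
    if (!outgroup %in% tr$tip.label)
      stop("nj_tree: outgroup '", outgroup, "' not among taxa")
    tr <- ape::root(tr, outgroup = outgroup, resolve.root = TRUE)
  }
  tr
}

#' Non-trivial bipartitions of an unrooted tree topology
#'
#' Each internal edge splits the leaf set in two; the split is canonicalized
#' as the side not containing the alphabetically first taxon, serialized as
#' a sorted comma-joined string.
#' @param tree ape \code{phylo}.
#' @return character vector of canonical bipartition keys.
#' @export
bipartitions <- function(tree) {
  tree <- ape::unroot(tree)
  n_tip <- length(tree$tip.label)
  anchor <- sort(tree$tip.label)[1]
  pp <- ape::prop.part(tree)
  keys <- character(0)
  for (p in pp) {
    side <- tree$tip.label[p]
    if (length(side) <= 1L || length(side) >= n_tip - 1L) next
    if (anchor %in% side) side <- setdiff(tree$tip.label, side)
    keys <- c(keys, paste(sort(side), collapse = ","))
  }
  unique(keys)
}

#' Robinson-Foulds distance between two trees
#'
#' Symmetric-difference count of non-trivial bipartitions, computed from
#' the canonical bipartition sets of the unrooted topologies.
#' @param tree_a,tree_b ape \code{phylo} objects on the same leaf set.
#' @return non-negative integer.
#' @export
rf_distance <- function(tree_a, tree_b) {
  if (!setequal(tree_a$tip.label, tree_b$tip.label))
    stop("rf_distance: leaf sets differ")
  ba <- bipartitions(tree_a)
  bb <- bipartitions(tree_b)
  length(setdiff(ba, bb)) + length(setdiff(bb, ba))
}

#' Neighbor-joining tree with nonparametric bootstrap support
#'
#' Resamples supermatrix columns with replacement, rebuilds the K2P + NJ
#' tree per replicate, and reports for each internal edge of the full-data
#' tree the percentage of replicates containing the same bipartition.
#' Replicates yielding a saturated (undefined) distance are dropped and
#' counted.
#' @param supermatrix named character vector of equal-length sequences.
#' @param n_reps bootstrap replicates (default 1000).
#' @param seed integer seed for the resampling.
#' @param outgroup optional rooting taxon for the reported tree.
#' @return list: tree (\code{phylo} with node labels = integer support for
#'   internal edges), support (named vector by bipartition key),
#'   n_effective, n_dropped.
#' @export
bootstrap_nj <- function(supermatrix, n_reps = 1000L, seed = 1L,
                         outgroup = NULL) {
  if (n_reps < 1L) stop("bootstrap_nj: n_reps must be >= 1")
  sp <- sort(names(supermatrix))
  chars <- do.call(rbind, lapply(supermatrix[sp], s2c))
  ncol_aln <- ncol(chars)
  main <- nj_tree(k2p_matrix(supermatrix))
  main_bips <- bipartitions(main)
  hit <- setNames(numeric(length(main_bips)), main_bips)
  dropped <- 0L
  # precompute pairwise per-column difference classes
  n <- length(sp)
  pair_idx <- utils::combn(n, 2)
  purine <- chars %in% c("A", "G")
  dim(purine) <- dim(chars)
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  set.seed(seed)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  TS <- matrix(FALSE, ncol(pair_idx), ncol_aln)
  DF <- matrix(FALSE, ncol(pair_idx), ncol_aln)
  for (k in seq_len(ncol(pair_idx))) {
    i <- pair_idx[1, k]; j <- pair_idx[2, k]
    df <- chars[i, ] != chars[j, ]
    DF[k, ] <- df
    TS[k, ] <- df & (purine[i, ] == purine[j, ])
  }
  for (rep in seq_len(n_reps)) {
    idx <- sample.int(ncol_aln, ncol_aln, replace = TRUE)
    P <- rowMeans(TS[, idx, drop = FALSE])
    D <- rowMeans(DF[, idx, drop = FALSE])
    Q <- D - P
    w1 <- 1 - 2 * P - Q; w2 <- 1 - 2 * Q
    if (any(w1 <= 0 | w2 <= 0)) { dropped <- dropped + 1L; next }
    dv <- -0.5 * log(w1) - 0.25 * log(w2)
    dm <- matrix(0, n, n, dimnames = list(sp, sp))
    dm[t(pair_idx)] <- dv
    dm[t(pair_idx[2:1, , drop = FALSE])] <- dv
    bt <- nj_tree(dm)
    bb <- bipartitions(bt)
    inb <- main_bips %in% bb
    hit[inb] <- hit[inb] + 1
  }
  eff <- n_reps - dropped
  support <- if (eff > 0) 100 * hit / eff else hit * NA_real_
  out_tree <- if (!is.null(outgroup)) {
    tr <- ape::root(main, outgroup = outgroup, resolve.root = TRUE)
    tr
  } else main
  # attach integer supports as internal node labels of the reported tree
  n_tip <- length(out_tree$tip.label)
  n_node <- out_tree$Nnode
  labs <- rep("", n_node)
  anchor <- sort(out_tree$tip.label)[1]
  for (nd in seq_len(n_node) + n_tip) {
    tips <- ape::extract.clade(out_tree, nd)$tip.label
    if (length(tips) <= 1L || length(tips) >= n_tip - 1L) next
    side <- if (anchor %in% tips) setdiff(out_tree$tip.label, tips) else tips
    key <- paste(sort(side), collapse = ",")
    if (key %in% names(support))
      labs[nd - n_tip] <- as.character(round(support[[key]]))
  }
  out_tree$node.label <- labs
  list(tree = out_tree, support = support,
       n_effective = eff, n_dropped = dropped)
}
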