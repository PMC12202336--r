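# Concatenation, neighbor joining, bootstrap and Robinson-Foulds.

test_that("concatenation records boundaries and rejects species mismatches", {
  a1 <- c(A = strrep("ACG", 100), B = strrep("ACT", 100))
  a2 <- c(A = strrep("GATTACA", 21), B = strrep("GATTACC", 21))
  sm <- concatenate_alignments(list(g1 = a1, g2 = a2))
  expect_equal(nchar(sm[["A"]]), 300L + 147L)
  expect_equal(unname(attr(sm, "boundaries")), c(300L, 447L))
  a3 <- c(A = "ACGT")
  expect_error(concatenate_alignments(list(g1 = a1, g3 = a3)),
               "species set mismatch.*g3")
  # boundary bookkeeping equals the sum of gene lengths on random inputs
  set.seed(606)
  genes <- lapply(1:5, function(i) {
    L <- sample(30:90, 1) * 3
    c(A = rand_dna(L), B = rand_dna(L), C = rand_dna(L))
  })
  names(genes) <- paste0("g", 1:5)
  smx <- concatenate_alignments(genes)
  expect_equal(unname(attr(smx, "boundaries")),
               unname(cumsum(vapply(genes, function(a) nchar(a[[1]]), 0L))))
})

test_that("NJ solves the 3-taxon system in closed form and recovers additive trees", {
  d <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  d["A", "B"] <- d["B", "A"] <- 0.3
  d["A", "C"] <- d["C", "A"] <- 0.5
  d["B", "C"] <- d["C", "B"] <- 0.6
  tr <- nj_tree(d)
  # closed form: a = (dAB + dAC - dBC)/2 etc.
  lens <- setNames(tr$edge.length[match(1:3, tr$edge[, 2])],
                   tr$tip.label)
  expect_equal(unname(lens["A"]), (0.3 + 0.5 - 0.6) / 2)
  expect_equal(unname(lens["B"]), (0.3 + 0.6 - 0.5) / 2)
  expect_equal(unname(lens["C"]), (0.5 + 0.6 - 0.3) / 2)
  # additive matrices from random trees are recovered exactly (RF = 0)
  set.seed(707)
  for (i in 1:20) {
    n <- sample(5:10, 1)
    tr0 <- ape::rtree(n)
    tr0$edge.length <- runif(nrow(tr0$edge), 0.05, 0.4)
    dm <- ape::cophenetic.phylo(tr0)
    rec <- nj_tree(dm)
    expect_equal(rf_distance(rec, tr0), 0L)
  }
  dna <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  dna["A", "B"] <- dna["B", "A"] <- NA
  expect_error(nj_tree(dna), "missing")
})

test_that("RF distance equals the bipartition-set definition and an external implementation", {
  t1 <- ape::read.tree(text = "((A,B),(C,D));")
  t2 <- ape::read.tree(text = "((A,C),(B,D));")
  expect_equal(rf_distance(t1, t1), 0L)
  expect_equal(rf_distance(t1, t2), 2L)
  expect_error(rf_distance(t1, ape::read.tree(text = "((A,B),(C,E));")),
               "leaf sets differ")
  set.seed(808)
  for (i in 1:15) {
    n <- sample(5:9, 1)
    ta <- ape::rtree(n); tb <- ape::rtree(n)
    tb$tip.label <- sample(ta$tip.label)
    expect_equal(rf_distance(ta, tb),
                 as.integer(phangorn::RF.dist(ape::unroot(ta),
                                              ape::unroot(tb))))
  }
})

test_that("bootstrap supports are deterministic, quantized at one replicate, and order-invariant", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 61L, n_species = 5L,
                                               sub_rate = 0.04))
  genes <- c("cox1", "cob", "atp6", "nad3")
  alns <- lapply(genes, function(gn)
    codon_align(lapply(sim$genomes, function(g) gene_cds(g, gn))))
  names(alns) <- genes
  sm <- concatenate_alignments(alns)
  b1 <- bootstrap_nj(sm, n_reps = 50L, seed = 7L)
  b2 <- bootstrap_nj(sm, n_reps = 50L, seed = 7L)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))
  # single replicate: supports only 0 or 100
  b3 <- bootstrap_nj(sm, n_reps = 1L, seed = 3L)
  expect_true(all(b3$support %in% c(0, 100)))
  # species input order does not change the supports
  perm <- rev(names(sm))
  smp <- structure(sm[perm], boundaries = attr(sm, "boundaries"))
  b4 <- bootstrap_nj(smp, n_reps = 50L, seed = 7L)
  expect_identical(b1$support[sort(names(b1$support))],
                   b4$support[sort(names(b4$support))])
})

test_that("a strongly structured simulation recovers its subclades with high support", {
  # 9 taxa: two outgroups plus two planted ingroup subclades (4 + 3)
  nwk <- paste0("((Out1:1,Out2:1):1,((I1:1,(I2:1,I3:1):1):1,",
                "((I4:1,I5:1):1,(I6:1,I7:1):1):1):1);")
  cfg2 <- sim_config(seed = 71L, tree = nwk,
                     gene_lengths = c(cox1 = 1608L, cob = 1158L,
                                      atp6 = 774L, nad3 = 417L),
                     trna_names = c("trnA", "trnC"),
                     pcl_catalog = default_pcl_catalog()[0, ],
                     planted_repeats = list(),
                     per_branch_sub_rate = 0.05,
                     species_ids = c("Out1", "Out2", paste0("I", 1:7)))
  sim <- simulate_mitogenomes(cfg2)
  genes <- c("cox1", "cob", "atp6", "nad3")
  alns <- lapply(genes, function(gn)
    codon_align(lapply(sim$genomes, function(g) gene_cds(g, gn))))
  names(alns) <- genes
  sm <- concatenate_alignments(alns)
  bt <- bootstrap_nj(sm, n_reps = 100L, seed = 5L, outgroup = "Out1")
  # both planted ingroup subclades appear as bipartitions at >= 95%
  all_sp <- names(sm)
  anchor <- sort(all_sp)[1]
  canon <- function(set) {
    if (anchor %in% set) set <- setdiff(all_sp, set)
    paste(sort(set), collapse = ",")
  }
  key1 <- canon(c("I1", "I2", "I3"))
  key2 <- canon(c("I4", "I5", "I6", "I7"))
  expect_true(key1 %in% names(bt$support))
  expect_true(key2 %in% names(bt$support))
  expect_gte(bt$support[[key1]], 95)
  expect_gte(bt$support[[key2]], 95)
})
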