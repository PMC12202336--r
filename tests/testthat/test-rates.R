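# K2P distances, NG86 Ka/Ks, protein-guided codon alignment, aggregation.

test_that("K2P matches the closed form and an established implementation", {
  a <- rand_dna(300, seed = 1)
  expect_equal(k2p(a, a)$k2p, 0)
  # P = 0.1, Q = 0.05 over 100 sites: plant exactly those differences
  base <- strsplit(strrep("ACGT", 25), "")[[1]]
  other <- base
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- c(A = "C", G = "T", C = "A", T = "G")
  other[1:10] <- ts_map[base[1:10]]
  other[11:15] <- tv_map[base[11:15]]
  r <- k2p(paste(base, collapse = ""), paste(other, collapse = ""))
  expect_equal(r$P, 0.1)
  expect_equal(r$Q, 0.05)
  expect_equal(r$k2p, -0.5 * log(1 - 2 * 0.1 - 0.05) - 0.25 * log(1 - 2 * 0.05))
  # saturation boundary raises a flagged missing value
  sat <- base
  sat[1:50] <- ts_map[base[1:50]]
  sat[51:75] <- tv_map[base[51:75]]
  rs <- k2p(paste(base, collapse = ""), paste(sat, collapse = ""))
  expect_true(rs$saturated)
  expect_true(is.na(rs$k2p))
  # Jensen: k2p >= P + Q on random defined pairs; cross-check vs ape
  set.seed(9)
  for (i in 1:10) {
    s1 <- rand_dna(500)
    v <- strsplit(s1, "")[[1]]
    idx <- sample(500, 40)
    for (j in idx) v[j] <- sample(setdiff(c("A", "C", "G", "T"), v[j]), 1)
    s2 <- paste(v, collapse = "")
    rr <- k2p(s1, s2)
    expect_gte(rr$k2p, rr$P + rr$Q)
    m <- matrix(c(strsplit(tolower(s1), "")[[1]],
                  strsplit(tolower(s2), "")[[1]]), nrow = 2, byrow = TRUE,
                dimnames = list(c("a", "b"), NULL))
    dd <- ape::dist.dna(ape::as.DNAbin(m), model = "K80")
    expect_equal(rr$k2p, as.numeric(dd), tolerance = 1e-10)
  }
})

test_that("NG86 handles the canonical single-difference cases and is symmetric", {
  bg <- strrep("ATGTTAGCTACTGCAGGTCTACATTTAGCTGCT", 9)  # 99 codons, stop-free
  bg <- substr(bg, 1, 297)
  a <- paste0(bg, "TTA")
  b <- paste0(bg, "TTG")   # Leu -> Leu synonymous under code 4
  r <- ng86(a, b)
  expect_equal(r$Nd, 0)
  expect_equal(r$Sd, 1)
  expect_equal(r$Ka, 0)
  expect_gt(r$Ks, 0)
  rid <- ng86(a, a)
  expect_equal(rid$Ka, 0)
  expect_equal(rid$Ks, 0)
  expect_true(is.na(rid$ka_ks))
  # S + N = 3 x codons
  expect_equal(r$S + r$N, 3 * r$codons)
  # symmetry
  r2 <- ng86(b, a)
  expect_equal(r[c("S", "N", "Sd", "Nd", "Ka", "Ks")],
               r2[c("S", "N", "Sd", "Nd", "Ka", "Ks")])
})

test_that("NG86 equals the pathway-enumeration oracle on random codon pairs", {
  set.seed(33)
  gc4 <- GENETIC_CODE_4
  nonstop <- names(gc4)[gc4 != "*"]
  for (i in 1:40) {
    ca <- sample(nonstop, 30, replace = TRUE)
    cb <- ca
    # mutate a few codons, possibly at multiple positions
    for (j in sample(30, 6)) {
      repeat {
        v <- strsplit(cb[j], "")[[1]]
        np <- sample(1:3, 1)
        for (pos in sample(3, np))
          v[pos] <- sample(c("A", "C", "G", "T"), 1)
        cand <- paste(v, collapse = "")
        if (!cand %in% c("TAA", "TAG")) { cb[j] <- cand; break }
      }
    }
    a <- paste(ca, collapse = ""); b <- paste(cb, collapse = "")
    got <- ng86(a, b)
    orc <- oracle_ng86(a, b)
    expect_equal(got$S, orc$S, tolerance = 1e-12)
    expect_equal(got$Sd, orc$Sd, tolerance = 1e-12)
    expect_equal(got$Nd, orc$Nd, tolerance = 1e-12)
    expect_equal(got$Ka, orc$Ka, tolerance = 1e-12)
    expect_equal(got$Ks, orc$Ks, tolerance = 1e-12)
  }
})

test_that("codon alignment is identity on equal input and drops exactly one codon per deletion", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 14L, n_species = 3L,
                                               sub_rate = 0))
  cds <- lapply(sim$genomes, function(g) gene_cds(g, "cox1"))
  aln <- codon_align(cds)
  # identical inputs align to themselves minus the terminal stop codon
  no_stop <- substr(cds[[1]], 1, nchar(cds[[1]]) - 3L)
  expect_true(all(aln == no_stop))
  expect_equal(attr(aln, "dropped_nt"), 0L)
  # single in-frame codon deletion -> exactly 3 nt of columns dropped
  cds2 <- cds
  cds2[[2]] <- paste0(substr(cds2[[2]], 1, 150),
                      substr(cds2[[2]], 154, nchar(cds2[[2]])))
  aln2 <- codon_align(cds2)
  expect_equal(attr(aln2, "dropped_nt"), 3L)
  expect_equal(nchar(aln2[[1]]), nchar(no_stop) - 3L)
  # internal stop aborts the gene with a classed condition
  cds3 <- cds
  substr(cds3[[3]], 31, 33) <- "TAA"
  expect_error(codon_align(cds3), class = "mitocomp_gene_error")
})

test_that("alignment scores equal the exhaustive affine DP oracle on toy pairs", {
  set.seed(55)
  for (i in 1:25) {
    n1 <- sample(8:30, 1); n2 <- sample(8:30, 1)
    a <- rand_dna(n1); b <- rand_dna(n2)
    got <- align_cds_to_reference(a, b, min_identity = 0)
    expect_equal(got$score, oracle_nw_affine(a, b), tolerance = 1e-9)
  }
})

test_that("rate aggregation reproduces per-pair values and purifying selection keeps Ka/Ks < 1", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 16L, n_species = 4L,
                                               synonymous_only = TRUE,
                                               sub_rate = 0.08))
  genes <- c("cox1", "cob", "atp6", "nad3")
  pr <- pairwise_rates(sim$genomes, genes = genes)
  agg <- aggregate_rates(pr, genes = genes)
  for (gene in genes) {
    sub <- pr[pr$gene == gene, ]
    expect_equal(agg$mean_k2p[agg$gene == gene], mean(sub$k2p))
    # synonymous-only evolution: nonsynonymous rate is exactly zero
    expect_equal(agg$mean_ka[agg$gene == gene], 0)
    expect_gt(agg$mean_ks[agg$gene == gene], 0)
  }
  # all-identical species: all means zero, ratios undefined
  sim0 <- simulate_mitogenomes(small_sim_config(seed = 17L, n_species = 3L,
                                                sub_rate = 0))
  pr0 <- pairwise_rates(sim0$genomes, genes = genes)
  agg0 <- aggregate_rates(pr0, genes = genes)
  expect_true(all(agg0$mean_k2p == 0))
  expect_true(all(is.na(agg0$mean_ka_ks)))
})

test_that("P/Q estimates recover the generating transition bias at long sequence length", {
  # kappa = 2 mutation process (transition twice each transversion class)
  set.seed(123)
  n <- 10000L
  s1 <- rand_dna(n)
  v <- strsplit(s1, "")[[1]]
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tv_map <- list(A = c("C", "T"), G = c("C", "T"),
                 C = c("A", "G"), T = c("A", "G"))
  mut <- runif(n) < 0.12
  for (i in which(mut)) {
    v[i] <- if (runif(1) < 0.5) ts_map[[v[i]]] else sample(tv_map[[v[i]]], 1)
  }
  r <- k2p(s1, paste(v, collapse = ""))
  expect_lt(abs(r$P / (r$P + r$Q) - 0.5), 0.05)
  expect_lt(abs(r$P + r$Q - 0.12), 0.012)
})
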