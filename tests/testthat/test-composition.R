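# Composition statistics, region partition, codon usage, ORF census,
# intron-count vs genome-size correlation.

test_that("skew formulas match their definition and a counting oracle", {
  expect_equal(suppressWarnings(skew_stats("AATT"))$at_skew, 0)
  expect_equal(suppressWarnings(skew_stats("AAAT"))$at_skew, (3 - 1) / (3 + 1))
  s <- rand_dna(1000, at = 0.7, seed = 21)
  st <- skew_stats(s)
  cnt <- oracle_base_counts(s)
  expect_equal(st$at_skew, (cnt[["A"]] - cnt[["T"]]) / (cnt[["A"]] + cnt[["T"]]))
  expect_equal(st$gc_skew, (cnt[["G"]] - cnt[["C"]]) / (cnt[["G"]] + cnt[["C"]]))
  expect_equal(st$gc_fraction, (cnt[["G"]] + cnt[["C"]]) / sum(cnt))
  # antisymmetry under complement
  expect_equal(skew_stats(complement_seq(s))$at_skew, -st$at_skew)
  expect_equal(skew_stats(complement_seq(s))$gc_skew, -st$gc_skew)
  # undefined denominators are loud, not silent NaN
  expect_warning(st2 <- skew_stats("AAAT"), "GC-skew undefined")
  expect_true(is.na(st2$gc_skew))
})

test_that("region partition is an exact conservation law with documented precedence", {
  g0 <- mitogenome("bare", rand_dna(500, seed = 2), circular = FALSE)
  p0 <- region_partition(g0)
  expect_equal(unname(p0[["intergenic"]]), 500L)
  expect_equal(sum(p0), 500L)
  for (seed in c(1L, 6L)) {
    sim <- simulate_mitogenomes(small_sim_config(seed = seed, n_species = 2L))
    for (sp in names(sim$genomes)) {
      part <- region_partition(sim$genomes[[sp]])
      expect_equal(sum(part), genome_length(sim$genomes[[sp]]))
      tt <- sim$truth$region_totals[[sp]]
      expect_equal(unname(part[names(tt)]), unname(tt))
    }
  }
})

test_that("codon usage counts match a brute-force triplet oracle and RSCU is 1 for balanced families", {
  g <- mitogenome("one", "ATGTTAAAATAA", circular = FALSE,
                  features = list(feature("PCG", "atp8", "+",
                                          matrix(c(0L, 12L), ncol = 2))))
  cu <- codon_usage(list(g), genes = "atp8")
  tab <- cu$table
  expect_equal(tab$count[tab$codon == "AUG"], 1L)
  expect_equal(tab$count[tab$codon == "UUA"], 1L)
  expect_equal(tab$count[tab$codon == "AAA"], 1L)
  expect_equal(tab$count[tab$codon == "UAA"], 1L)
  expect_equal(sum(tab$count), 4L)
  expect_equal(cu$start_stop$start_codon, "ATG")
  expect_equal(cu$start_stop$stop_codon, "TAA")
  # balanced synonymous family -> RSCU exactly 1
  cds <- paste0("ATG", "GGT", "GGC", "GGA", "GGG", "TAA")
  g2 <- mitogenome("two", cds, circular = FALSE,
                   features = list(feature("PCG", "atp9", "+",
                                           matrix(c(0L, nchar(cds)), ncol = 2))))
  tab2 <- codon_usage(list(g2), genes = "atp9")$table
  expect_equal(tab2$rscu[tab2$codon %in% c("GGU", "GGC", "GGA", "GGG")],
               rep(1, 4))
  # random simulated CDS set equals the exhaustive oracle
  sim <- simulate_mitogenomes(small_sim_config(seed = 8L, n_species = 2L))
  genes <- c("cox1", "cob", "atp6", "nad3")
  cu3 <- codon_usage(sim$genomes, genes = genes)$table
  cds_all <- unlist(lapply(sim$genomes, function(g)
    lapply(genes, function(gn) gene_cds(g, gn))))
  orc <- oracle_codon_counts(cds_all)
  for (cod in names(orc))
    expect_equal(cu3$count[cu3$codon == gsub("T", "U", cod)],
                 unname(orc[cod]))
  expect_equal(sum(cu3$count), sum(nchar(unlist(cds_all))) / 3)
})

test_that("ORF census finds planted intronic ORFs and honors the length threshold", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 12L, n_species = 2L,
                                               intron_orf_prob = 1))
  g <- sim$genomes[[1]]
  found <- orf_census(g, min_nt = 300L)
  truth <- sim$truth$intronic_orfs
  truth <- truth[truth$species == g$species_id, , drop = FALSE]
  expect_gt(nrow(truth), 0L)
  for (i in seq_len(nrow(truth))) {
    hit <- found[found$strand == "+" & found$start <= truth$start[i] &
                   found$end >= truth$end[i], , drop = FALSE]
    expect_gt(nrow(hit), 0L)
    expect_true(any(hit$in_intron))
  }
  # threshold above every ORF -> nothing reported
  longest <- max(found$length_nt)
  expect_equal(nrow(orf_census(g, min_nt = longest + 3L)), 0L)
  # census agrees with an independent six-frame scan on a small linear genome
  s <- rand_dna(900, at = 0.7, seed = 31)
  gl <- mitogenome("lin", s, circular = FALSE)
  got <- orf_census(gl, min_nt = 60L)
  naive <- list()
  code <- GENETIC_CODE_4
  for (strand in c("+", "-")) {
    sc <- if (strand == "+") s else revcomp(s)
    for (fr in 0:2) {
      cods <- substring(sc, seq(fr + 1, nchar(sc) - 2, 3),
                        seq(fr + 3, nchar(sc), 3))
      start <- NA
      for (k in seq_along(cods)) {
        if (is.na(start) && cods[k] == "ATG") start <- k
        if (cods[k] %in% c("TAA", "TAG")) {
          if (!is.na(start) && (k - start + 1) * 3 >= 60) {
            a <- fr + (start - 1) * 3 + 1; b <- fr + k * 3
            if (strand == "-") { t <- a; a <- nchar(s) - b + 1; b <- nchar(s) - t + 1 }
            naive[[length(naive) + 1]] <- c(a, b, strand)
          }
          start <- NA
        }
      }
    }
  }
  naive_keys <- sort(sapply(naive, paste, collapse = ":"))
  got_keys <- sort(paste(got$start, got$end, got$strand, sep = ":"))
  expect_identical(got_keys, naive_keys)
})

test_that("intron-count vs genome-size correlation matches rank/moment oracles", {
  x <- c(1, 2, 3, 4, 5, 6, 7); y <- 2 * x + 3
  r <- intron_size_correlation(x, y)
  expect_equal(r$pearson_r, 1)
  # monotone convex: spearman 1, pearson < 1
  y2 <- x^3
  r2 <- intron_size_correlation(x, y2)
  expect_equal(r2$spearman_rho, 1)
  expect_lt(r2$pearson_r, 1)
  # random n = 7 datasets match cor()/t-formula to 1e-12
  set.seed(77)
  for (i in 1:20) {
    xi <- sample.int(25, 7); yi <- stats::rnorm(7, 40000, 5000)
    ri <- intron_size_correlation(xi, yi)
    expect_equal(ri$pearson_r, stats::cor(xi, yi), tolerance = 1e-12)
    expect_equal(ri$spearman_rho, stats::cor(xi, yi, method = "spearman"),
                 tolerance = 1e-12)
    tt <- ri$pearson_r * sqrt(5 / (1 - ri$pearson_r^2))
    expect_equal(ri$pearson_p, 2 * stats::pt(-abs(tt), 5), tolerance = 1e-12)
  }
  expect_error(intron_size_correlation(c(1, 1, 1), c(1, 2, 3)),
               "zero variance")
  # exact permutation p available for small n
  rp <- intron_size_correlation(x, y2, permutation_p = TRUE)
  expect_lte(rp$pearson_p_perm, 1)
  expect_gte(rp$pearson_p_perm, 1 / factorial(7))
})
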