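# SSR, dispersed and tandem repeat detection against planted repeats and
# brute-force oracles.

test_that("SSR thresholds behave as boundaries and motifs are canonical", {
  pad1 <- rand_dna(200, seed = 61); pad2 <- rand_dna(200, seed = 62)
  g10 <- paste0(pad1, "C", strrep("A", 10), "C", pad2)
  hits <- find_ssrs(g10)
  mono <- hits[hits$motif_class == "mono" & hits$motif == "A", ]
  expect_equal(nrow(mono), 1L)
  expect_equal(mono$copies, 10L)
  expect_equal(mono$end - mono$start + 1L, 10L)
  g9 <- paste0(pad1, "C", strrep("A", 9), "C", pad2)
  hits9 <- find_ssrs(g9)
  expect_equal(nrow(hits9[hits9$motif_class == "mono" & hits9$motif == "A", ]),
               0L)
  # canonical motif is the smallest rotation; non-primitive motifs excluded
  gta <- paste0(pad1, "C", strrep("TA", 7), "C", pad2)
  ht <- find_ssrs(gta)
  expect_true("AT" %in% ht$motif[ht$motif_class == "di"])
  expect_false(any(nchar(ht$motif) == 4 & ht$motif %in% c("ATAT", "TATA")))
})

test_that("SSR scanner equals the exhaustive maximal-run oracle on random sequences", {
  set.seed(71)
  for (i in 1:8) {
    s <- rand_dna(4000, at = 0.74)
    got <- find_ssrs(s)
    orc <- oracle_ssrs(s)
    key <- function(df) sort(paste(df$motif, df$copies, df$start, df$end))
    expect_identical(key(got), key(orc))
  }
})

test_that("SSR calls are rotation-invariant on circular genomes", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 23L, n_species = 1L))
  g <- sim$genomes[[1]]
  h0 <- find_ssrs(g)
  L <- genome_length(g)
  for (off in c(137L, L %/% 3L)) {
    gr <- rotate_genome(g, off)
    hr <- find_ssrs(gr)
    expect_equal(nrow(hr), nrow(h0))
    # same motifs/copies up to a coordinate shift
    expect_identical(sort(paste(h0$motif, h0$copies)),
                     sort(paste(hr$motif, hr$copies)))
    shifted <- sort((h0$start - 1L - off) %% L)
    expect_identical(sort((hr$start - 1L) %% L), shifted)
  }
})

test_that("planted dispersed repeats are found with correct orientation and bounds respected", {
  set.seed(81)
  pads <- replicate(5, rand_dna(400, at = 0.74))
  core40 <- rand_dna(40)
  core29 <- rand_dna(29)
  g <- paste0(pads[1], core40, pads[2], core40, pads[3],
              revcomp(core40), pads[4], core29, pads[5], core29)
  hits <- find_dispersed(g)
  fw <- hits[hits$orientation == "forward", ]
  pl <- hits[hits$orientation == "palindromic", ]
  # the 40-nt duplication: found as forward pair(s) with length >= 40
  a1 <- nchar(pads[1]) + 1L
  expect_true(any(fw$start_a <= a1 & fw$end_a >= a1 + 39L & fw$mismatches <= 3))
  # its reverse complement elsewhere: palindromic
  expect_true(any(pl$length >= 40))
  # the 29-nt exact duplication must not be reported alone: any call
  # covering it must reach length >= 30 by extension
  expect_true(all(hits$length >= 30))
  # every reported repeat verifies its own contract on recheck
  v <- strsplit(g, "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in seq_len(nrow(hits))) {
    aa <- v[hits$start_a[i]:hits$end_a[i]]
    bb <- v[hits$start_b[i]:hits$end_b[i]]
    if (hits$orientation[i] == "palindromic") bb <- rev(unname(comp[bb]))
    expect_equal(sum(aa != bb), hits$mismatches[i])
    expect_lte(hits$mismatches[i], 3L)
  }
})

test_that("dispersed finder equals the quadratic Hamming-window oracle on random sequences", {
  set.seed(91)
  for (i in 1:6) {
    s <- rand_dna(1200, at = 0.74)
    # plant one near-identical pair so the comparison is not vacuous
    core <- rand_dna(45)
    v <- strsplit(core, "")[[1]]
    v[20] <- setdiff(c("A", "C", "G", "T"), v[20])[1]
    s <- paste0(substr(s, 1, 300), core, substr(s, 301, 900),
                paste(v, collapse = ""), substr(s, 901, 1200))
    got <- find_dispersed(s)
    orc <- oracle_dispersed(s)
    expect_identical(canon_dispersed(got), canon_dispersed(orc))
    expect_gt(nrow(got), 0L)
  }
})

test_that("tandem detector finds planted arrays, reports period/copies, and stays silent on shuffles", {
  pad1 <- rand_dna(500, seed = 101); pad2 <- rand_dna(500, seed = 102)
  arr <- strrep("ACGTAC", 4)
  g <- paste0(pad1, "T", arr, "T", pad2)
  hits <- find_tandem(g)
  expect_gte(nrow(hits), 1L)
  best <- hits[which.max(hits$length), ]
  expect_equal(best$period, 6L)
  expect_gte(best$copies, 4 - 0.2)
  # perfect dimer reported by both detectors
  g2 <- paste0(pad1, "C", strrep("AT", 20), "C", pad2)
  td <- find_tandem(g2)
  expect_true(any(td$period == 2L & td$copies >= 19))
  ssr <- find_ssrs(g2)
  expect_true(any(ssr$motif == "AT" & ssr$motif_class == "di"))
  # negative control: destroying the period silences the detector
  set.seed(111)
  base <- strsplit(g, "")[[1]]
  for (k in 1:20) {
    shuf <- paste(sample(base), collapse = "")
    expect_equal(nrow(find_tandem(shuf)), 0L)
  }
})

test_that("repeats are localized to region classes by majority with precedence ties", {
  g <- toy_genome()
  part <- region_partition(g)
  cls <- attr(part, "class_vector")
  intron_f <- Filter(function(f) f$kind == "intron", g$features)[[1]]
  i0 <- intron_f$parts[1, "start"] + 1L
  rep_df <- data.frame(start = i0 + 5L, end = i0 + 25L)
  expect_equal(localize_repeats(g, rep_df)$region, "intron")
  # 60/40 span across exon/intron boundary goes to the majority side
  pcg <- Filter(function(f) f$kind == "PCG", g$features)[[1]]
  b <- pcg$parts[1, "end"]   # exon ends at b (0-based), intron starts after
  span <- data.frame(start = b - 11L, end = b + 8L)  # 12 exon nt, 8 intron nt
  expect_equal(localize_repeats(g, span)$region, "PCG_exon")
  # planted repeats in simulator fixtures localize to their planted class
  sim <- simulate_mitogenomes(small_sim_config(seed = 26L, n_species = 2L))
  tr <- sim$truth$planted_repeats
  for (sp in names(sim$genomes)) {
    sub <- tr[tr$species == sp, , drop = FALSE]
    loc <- localize_repeats(sim$genomes[[sp]],
                            data.frame(start = sub$start, end = sub$end))
    expect_true(all(loc$region == sub$region))
  }
})
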