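# Positional-class assignment, ortholog clustering, gain/loss parsimony.

test_that("alignment coordinate transfer is exact for identity and offset cases", {
  ref <- rand_dna(600, seed = 201)
  al <- align_cds_to_reference(ref, ref)
  expect_identical(al$map, seq_len(600L))
  expect_equal(al$identity, 1)
  # species with a 3-nt deletion at position 50: downstream maps shift by +3
  spx <- paste0(substr(ref, 1, 49), substr(ref, 53, 600))
  al2 <- align_cds_to_reference(spx, ref)
  expect_equal(al2$map[300], 303L)
  expect_equal(al2$map[10], 10L)
  # unalignable input raises the classed error
  expect_error(align_cds_to_reference(strrep("A", 300), strrep("C", 300)),
               class = "mitocomp_unalignable")
})

test_that("Pcl labels transfer through identity and through upstream deletions", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 31L, n_species = 2L,
                                               sub_rate = 0))
  ref <- make_reference_cds(sim$config)
  g <- sim$genomes[[1]]
  asn <- assign_pcl(g, "cox1", ref[["cox1"]])
  truth <- sim$truth$introns
  truth <- truth[truth$species == g$species_id & truth$gene == "cox1", ]
  expect_setequal(paste0("cox1:", asn$label),
                  truth$label)
  expect_true(all(asn$confident))
  expect_true(all(asn$identity == 1))
})

test_that("Pcl assignment survives silent divergence and flags gap-adjacent insertions", {
  # synonymous-only divergence must not move any label
  sim <- simulate_mitogenomes(small_sim_config(seed = 32L, n_species = 4L,
                                               synonymous_only = TRUE,
                                               sub_rate = 0.06))
  ref <- make_reference_cds(sim$config)
  asn <- pcl_assignments(sim$genomes, ref)
  truth <- sim$truth$introns
  for (i in seq_len(nrow(asn))) {
    tr <- truth[truth$species == asn$species[i] &
                  truth$gene == asn$gene[i] &
                  paste0(asn$gene[i], ":", asn$label[i]) == truth$label, ]
    expect_equal(nrow(tr), 1L)
  }
  # constructed case: 3-nt deletion upstream of the insertion point keeps
  # the reference label (alignment-transfer, not raw offset)
  ref1 <- ref[["cox1"]]
  sim0 <- simulate_mitogenomes(small_sim_config(seed = 31L, n_species = 2L,
                                                sub_rate = 0))
  g <- sim0$genomes[[1]]
  pcg <- Filter(function(f) f$kind == "PCG" && f$name == "cox1",
                g$features)[[1]]
  # delete codon 10 (nt 28-30) from the first exon in the genome sequence
  del_at <- pcg$parts[1, "start"] + 27L
  seq2 <- paste0(substr(g$sequence, 1, del_at),
                 substring(g$sequence, del_at + 4L))
  shift <- function(x) ifelse(x > del_at, x - 3L, x)
  feats <- lapply(g$features, function(f) {
    f$parts <- matrix(as.integer(shift(f$parts)), ncol = 2,
                      dimnames = dimnames(f$parts))
    f
  })
  g2 <- suppressWarnings(mitogenome("mutant", seq2, TRUE, feats))
  asn2 <- assign_pcl(g2, "cox1", ref1)
  asn1 <- assign_pcl(g, "cox1", ref1)
  expect_identical(sort(asn2$label), sort(asn1$label))
})

test_that("ortholog clustering merges similar and splits dissimilar co-positional introns", {
  base <- data.frame(
    species = c("A", "B"), gene = "cox1", intron_name = "i",
    intron_group = "IB", position = 100L, label = "P100",
    confident = TRUE, identity = 1, intron_length = 60L,
    seq = NA_character_, stringsAsFactors = FALSE)
  shared <- rand_dna(400, seed = 301)
  near <- strsplit(shared, "")[[1]]
  idx <- seq(1, 400, by = 20)
  for (j in idx) near[j] <- setdiff(c("A", "C", "G", "T"), near[j])[1]
  base$seq <- c(shared, paste(near, collapse = ""))   # ~95% identity
  m1 <- cluster_orthologs(base)
  expect_equal(colnames(m1), "cox1:P100")
  expect_true(all(m1[, 1] == "1"))
  base2 <- base
  base2$seq <- c(shared, rand_dna(400, at = 0.2, seed = 999))
  m2 <- cluster_orthologs(base2, identity_threshold = 0.7)
  expect_setequal(colnames(m2), c("cox1:P100a", "cox1:P100b"))
  expect_equal(sum(m2 == "1"), 2L)
  # unconfident assignments become "*" and never count as presence
  base3 <- base
  base3$confident[2] <- FALSE
  m3 <- cluster_orthologs(base3)
  expect_equal(unname(m3["B", 1]), "*")
})

test_that("Dollo reconstruction places the single gain at the MRCA with minimal losses", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix("0", 4, 3, dimnames = list(c("A", "B", "C", "D"),
                                         c("p_all", "p_one", "p_abc")))
  m[, "p_all"] <- "1"
  m["C", "p_one"] <- "1"
  m[c("A", "B", "C"), "p_abc"] <- "1"
  ev <- gain_loss(m, tr, mode = "dollo")
  # present everywhere: one gain at the root, no losses
  e1 <- ev[ev$pcl == "p_all", ]
  expect_equal(nrow(e1), 1L)
  expect_equal(e1$event, "gain")
  expect_equal(e1$node, 5L)   # root of a 4-tip tree
  # single-taxon presence: gain on that terminal branch
  e2 <- ev[ev$pcl == "p_one", ]
  expect_equal(nrow(e2), 1L)
  expect_identical(e2$branch, "C")
  # {A,B,C}: gain at root, exactly one loss on D
  e3 <- ev[ev$pcl == "p_abc", ]
  expect_equal(sum(e3$event == "gain"), 1L)
  expect_equal(e3$node[e3$event == "gain"], 5L)
  expect_identical(e3$branch[e3$event == "loss"], "D")
  # exhaustive check: no single-gain scenario with fewer events exists
  # (gain at root + 1 loss = 2 events; any other gain node misses a tip)
  expect_equal(nrow(e3), 2L)
})

test_that("Dollo replay reproduces random tip matrices exactly", {
  set.seed(404)
  for (trial in 1:60) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    k <- sample(1:6, 1)
    m <- matrix(sample(c("0", "1"), n * k, replace = TRUE, prob = c(.5, .5)),
                n, k, dimnames = list(tr$tip.label, paste0("c", 1:k)))
    keep <- colSums(m == "1") > 0
    if (!any(keep)) next
    m <- m[, keep, drop = FALSE]
    ev <- gain_loss(m, tr, mode = "dollo")
    # Dollo invariant: exactly one gain per column
    expect_true(all(table(ev$pcl[ev$event == "gain"]) == 1))
    replay <- replay_gain_loss(ev, tr, pcls = colnames(m))
    expect_identical(ifelse(replay[rownames(m), colnames(m), drop = FALSE],
                            "1", "0"), m)
  }
})

test_that("Fitch parsimony needs no more events than Dollo and replays exactly", {
  set.seed(505)
  for (trial in 1:40) {
    n <- sample(4:8, 1)
    tr <- ape::rtree(n)
    m <- matrix(sample(c("0", "1"), n, replace = TRUE), n, 1,
                dimnames = list(tr$tip.label, "c1"))
    if (!any(m == "1")) m[1, 1] <- "1"
    evd <- gain_loss(m, tr, mode = "dollo")
    evf <- gain_loss(m, tr, mode = "fitch")
    expect_lte(nrow(evf), nrow(evd))
    replay <- replay_gain_loss(evf, tr, pcls = "c1")
    expect_identical(ifelse(replay[rownames(m), 1] , "1", "0"), m[, 1])
  }
})

test_that("undetermined cells are excluded from events rather than treated as absence", {
  tr <- ape::read.tree(text = "((A,B),(C,D));")
  m <- matrix(c("1", "0", "*", "1"), 4, 1,
              dimnames = list(c("A", "B", "C", "D"), "p"))
  ev <- gain_loss(m, tr, mode = "dollo")
  # gain at the root (MRCA of A and D); B's confirmed absence is a loss,
  # C's unknown state is not
  expect_equal(ev$node[ev$event == "gain"], 5L)
  expect_false("C" %in% ev$branch[ev$event == "loss"])
  expect_true("B" %in% ev$branch[ev$event == "loss"])
})

test_that("intron census totals, shares and subclass tallies are exact on planted fixtures", {
  sim <- simulate_mitogenomes(small_sim_config(seed = 44L, n_species = 3L))
  cen <- intron_census(sim$genomes)
  truth <- sim$truth$introns
  expect_equal(cen$totals$n, nrow(truth))
  for (sp in names(sim$genomes)) {
    expect_equal(cen$per_species$n_introns[cen$per_species$species == sp],
                 sum(truth$species == sp))
    expect_equal(cen$per_species$intron_nt[cen$per_species$species == sp],
                 sum(truth$end[truth$species == sp] -
                       truth$start[truth$species == sp] + 1L))
  }
  hosts_rrna <- truth$gene %in% c("rns", "rnl")
  expect_equal(cen$totals$in_pcg, sum(!hosts_rrna))
  expect_equal(cen$totals$in_rrna, sum(hosts_rrna))
  grp <- table(truth$group)
  for (g in names(grp))
    expect_equal(cen$groups$n_introns[cen$groups$group == g],
                 unname(as.integer(grp[g])))
  # zero-intron genome: all-zero census row
  cfg0 <- small_sim_config(seed = 45L, n_species = 1L)
  cfg0$pcl_catalog <- cfg0$pcl_catalog[0, ]
  sim0 <- simulate_mitogenomes(cfg0)
  cen0 <- intron_census(sim0$genomes)
  expect_equal(cen0$totals$n, 0L)
  expect_equal(cen0$per_species$intron_nt, 0)
})

test_that("planted Pcl histories are recovered as presence/absence matrices", {
  for (seed in c(51L, 52L, 53L)) {
    sim <- simulate_mitogenomes(small_sim_config(seed = seed, n_species = 4L,
                                                 sub_rate = 0.05))
    ref <- make_reference_cds(sim$config)
    asn <- pcl_assignments(sim$genomes, ref)
    mat <- cluster_orthologs(asn, species = names(sim$genomes))
    tp <- sim$truth$presence
    tp <- tp[, colSums(tp) > 0, drop = FALSE]
    common <- intersect(colnames(mat), colnames(tp))
    # every truth column is recovered under its own label
    expect_setequal(colnames(tp), common)
    acc <- mean((mat[rownames(tp), common] == "1") == tp[, common])
    expect_gte(acc, 0.99)
  }
})
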