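# Shared fixtures: all inputs are generated in code at test time.

rand_dna <- function(n, at = 0.5, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = p),
        collapse = "")
}

# a compact simulation: 4 PCGs + both rRNAs, 10 intron lineages, 5 tRNAs
small_sim_config <- function(seed = 1L, n_species = 4L, tree = "random",
                             sub_rate = 0.02, ...) {
  cat <- default_pcl_catalog()
  cat <- cat[cat$gene %in% c("cox1", "cob", "rnl"), ]
  sim_config(seed = seed, n_species = n_species, tree = tree,
             gene_lengths = c(cox1 = 1608L, cob = 1158L, atp6 = 774L,
                              nad3 = 417L),
             trna_names = c("trnA", "trnC", "trnD", "trnE", "trnF"),
             pcl_catalog = cat,
             per_branch_sub_rate = sub_rate,
             species_ids = sprintf("sp%02d", seq_len(n_species)),
             ...)
}

# minimal hand-built genome: one 2-exon PCG with an intron, one tRNA
toy_genome <- function() {
  exon1 <- "ATGTTAGCTACTGCAGGTCTACATTGATTAGCT"  # 33 nt
  intron <- paste(rep("GATTACA", 20), collapse = "")
  exon2 <- "GGTCTACATTGATTAGCTAAATTAGCTTAA"     # 30 nt
  trna <- rand_dna(72, seed = 42)
  igs1 <- rand_dna(100, at = 0.7, seed = 7)
  igs2 <- rand_dna(80, at = 0.7, seed = 8)
  seqs <- paste0(igs1, exon1, intron, exon2, igs2, trna)
  o1 <- nchar(igs1)
  cds_start <- o1
  i_start <- o1 + nchar(exon1)
  e2_start <- i_start + nchar(intron)
  e2_end <- e2_start + nchar(exon2)
  t_start <- e2_end + nchar(igs2)
  mitogenome("toy", seqs, circular = TRUE, features = list(
    feature("PCG", "cox1", "+",
            matrix(c(cds_start, i_start, e2_start, e2_end),
                   ncol = 2, byrow = TRUE)),
    feature("intron", "cox1-i33", "+",
            matrix(c(i_start, e2_start), ncol = 2),
            intron_group = "IB", parent_gene = "cox1"),
    feature("tRNA", "trnA", "+",
            matrix(c(t_start, t_start + nchar(trna)), ncol = 2))))
}
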