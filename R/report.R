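# End-to-end orchestration and paper-shaped report tables.  Every number in
# a report is produced by the underlying operation (no report-only
# arithmetic); percentages are rounded half-up to 2 decimals, skews to 4.

#' Per-genome overview table
#'
#' One row per species: length, GC%, AT/GC skew, feature counts, intron
#' nucleotide totals and the intron share of the genome.
#' @param genomes list of \code{mitogenome}s.
#' @param orf_min_nt minimum length for the ORF census column (default 300).
#' @return data.frame with formatted report columns.
#' @export
overview_table <- function(genomes, orf_min_nt = 300L) {
  rows <- lapply(genomes, function(g) {
    sk <- skew_stats(g$sequence)
    part <- region_partition(g)
    cen <- intron_census(list(g))
    kinds <- vapply(g$features, function(f) f$kind, "")
    n_orfs <- nrow(orf_census(g, orf_min_nt))
    data.frame(
      species = g$species_id,
      length_bp = genome_length(g),
      gc_pct = fmt_num(100 * sk$gc_fraction, 2),
      at_skew = fmt_num(sk$at_skew, 4),
      gc_skew = fmt_num(sk$gc_skew, 4),
      n_pcg = sum(kinds == "PCG"),
      n_trna = sum(kinds == "tRNA"),
      n_rrna = sum(kinds == "rRNA"),
      n_orf = n_orfs,
      n_introns = cen$per_species$n_introns[1],
      intron_nt = cen$per_species$intron_nt[1],
      intron_pct = pct2(part[["intron"]], genome_length(g)),
      intergenic_nt = part[["intergenic"]],
      stringsAsFactors = FALSE)
  })
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Arithmetic checkpoints from the published summary fixture
#'
#' Recomputes, by the same report arithmetic used on any genome set, the
#' headline quantities of the published seven-species comparison from the
#' reported per-species values shipped in \code{inst/extdata}: the intron
#' fraction of the largest and smallest genomes, the genome-size difference
#' of the reported pair, the PCG and rRNA shares of the 84 introns, and the
#' subclass tally sum.
#' @param extdata directory holding the fixture TSVs (default: the
#'   installed package's extdata).
#' @return named list of computed values.
#' @export
reported_checkpoints <- function(extdata = system.file("extdata",
                                                       package = "mitocomp")) {
  summ <- read_tsv_report(file.path(extdata, "cordyceps_reported_summary.tsv"))
  grp <- read_tsv_report(file.path(extdata, "cordyceps_intron_groups.tsv"))
  hosts <- read_tsv_report(file.path(extdata, "cordyceps_intron_hosts.tsv"))
  with_introns <- summ[!is.na(summ$intron_bp), , drop = FALSE]
  largest <- with_introns[which.max(with_introns$genome_bp), ]
  smallest <- with_introns[which.min(with_introns$genome_bp), ]
  pair <- summ[summ$species %in% c("C_cocoonihabita", "C_blackwelliae"), ]
  total <- sum(grp$n_introns)
  n_pcg <- hosts$n_introns[hosts$host == "PCG"]
  n_rrna <- hosts$n_introns[hosts$host == "rRNA"]
  list(
    intron_pct_largest = as.numeric(pct2(largest$intron_bp, largest$genome_bp)),
    intron_pct_smallest = as.numeric(pct2(smallest$intron_bp,
                                          smallest$genome_bp)),
    size_difference_bp = abs(diff(pair$genome_bp)),
    pcg_intron_share_pct = as.numeric(pct2(n_pcg, n_pcg + n_rrna)),
    rrna_intron_share_pct = as.numeric(pct2(n_rrna, n_pcg + n_rrna)),
    subclass_sum = total)
}

#' Run the full comparative pipeline
#'
#' Executes composition -> codon usage -> rates -> repeats -> introns ->
#' phylogeny on a genome set and writes every table as TSV plus the
#' bootstrap tree as Newick.  A failing stage marks the bundle partial and
#' skips stages depending on it; reruns with the same inputs and seed are
#' byte-identical.
#' @param genomes named list of \code{mitogenome}s.
#' @param out_dir output directory.
#' @param reference named list of reference CDS strings (NULL skips the
#'   intron Pcl stage).
#' @param tree species tree (\code{phylo}) for gain/loss (NULL infers
#'   events on the NJ tree when available).
#' @param seed integer seed (bootstrap resampling).
#' @param do_phylo run the NJ + bootstrap stage (default TRUE).
#' @param boot_reps bootstrap replicates (default 200).
#' @param outgroup optional outgroup species for rooting.
#' @param orf_min_nt ORF census threshold (default 300).
#' @return invisible list: paths of written files, stage status, and the
#'   in-memory results.
#' @export
run_all <- function(genomes, out_dir, reference = NULL, tree = NULL,
                    seed = 1L, do_phylo = TRUE, boot_reps = 200L,
                    outgroup = NULL, orf_min_nt = 300L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  status <- list(); paths <- character(0); res <- list()
  t0 <- proc.time()[["elapsed"]]
  timings <- list()
  stage <- function(name, expr) {
    ts <- proc.time()[["elapsed"]]
    out <- tryCatch(expr, error = function(e) {
      message("stage ", name, " failed: ", conditionMessage(e))
      structure(list(error = conditionMessage(e)), class = "stage_error")
    })
    timings[[name]] <<- round(proc.time()[["elapsed"]] - ts, 3)
    status[[name]] <<- !inherits(out, "stage_error")
    out
  }
  emit <- function(df, file) {
    p <- file.path(out_dir, file)
    write_tsv_report(df, p)
    paths <<- c(paths, p)
  }

  ov <- stage("overview", overview_table(genomes, orf_min_nt))
  if (status$overview) { emit(ov, "overview.tsv"); res$overview <- ov }

  cu <- stage("codon_usage", codon_usage(genomes))
  if (status$codon_usage) {
    tab <- cu$table
    tab$per_thousand <- fmt_num(tab$per_thousand, 2)
    tab$rscu <- fmt_num(tab$rscu, 4)
    emit(tab, "codon_usage.tsv")
    emit(cu$start_stop, "start_stop_codons.tsv")
    res$codon_usage <- cu
  }

  corr <- stage("correlation", {
    cen <- intron_census(genomes)$per_species
    if (nrow(cen) >= 3L) {
      lens <- vapply(genomes, genome_length, 0L)
      ic <- intron_size_correlation(cen$n_introns,
                                    lens[match(cen$species, names(lens))])
      data.frame(statistic = c("pearson_r", "pearson_p", "spearman_rho",
                               "spearman_p"),
                 value = fmt_num(c(ic$pearson_r, ic$pearson_p,
                                   ic$spearman_rho, ic$spearman_p), 4))
    } else data.frame(statistic = character(0), value = character(0))
  })
  if (status$correlation && nrow(corr)) {
    emit(corr, "intron_size_correlation.tsv"); res$correlation <- corr
  }

  rt <- stage("rates", {
    pr <- pairwise_rates(genomes)
    list(pairs = pr, table = aggregate_rates(pr))
  })
  if (status$rates) {
    pr <- rt$pairs
    for (col in c("P", "Q", "k2p", "Ka", "Ks", "ka_ks"))
      if (col %in% names(pr)) pr[[col]] <- fmt_num(pr[[col]], 4)
    emit(pr, "rate_pairs.tsv")
    tb <- rt$table
    for (col in c("mean_k2p", "mean_ka", "mean_ks", "mean_ka_ks"))
      tb[[col]] <- fmt_num(tb[[col]], 4)
    emit(tb, "rate_table.tsv")
    res$rates <- rt
  }

  reps <- stage("repeats", {
    out <- list()
    for (sp in names(genomes)) {
      g <- genomes[[sp]]
      ss <- find_ssrs(g)
      td <- find_tandem(g)
      dp <- find_dispersed(g)
      if (nrow(ss)) ss <- cbind(species = sp, localize_repeats(g, ss))
      if (nrow(td)) td <- cbind(species = sp, localize_repeats(g, td))
      if (nrow(dp)) dp <- cbind(species = sp, localize_repeats(g, dp))
      out$ssr[[sp]] <- ss; out$tandem[[sp]] <- td; out$dispersed[[sp]] <- dp
    }
    lapply(out, function(x) {
      x <- x[vapply(x, nrow, 0L) > 0]
      if (length(x)) do.call(rbind, c(x, list(make.row.names = FALSE)))
      else NULL
    })
  })
  if (status$repeats) {
    for (cls in c("ssr", "tandem", "dispersed")) {
      df <- reps[[cls]]
      if (is.null(df)) df <- data.frame(species = character(0))
      if (cls == "tandem" && nrow(df))
        df$copies <- fmt_num(df$copies, 2)
      if (cls == "tandem" && nrow(df))
        df$identity <- fmt_num(df$identity, 4)
      emit(df, paste0("repeats_", cls, ".tsv"))
    }
    res$repeats <- reps
  }

  cenl <- stage("intron_census", intron_census(genomes))
  if (status$intron_census) {
    emit(cenl$per_species, "intron_census.tsv")
    emit(cenl$groups, "intron_groups.tsv")
    res$census <- cenl
  }

  if (!is.null(reference)) {
    pcl <- stage("introns", {
      asn <- pcl_assignments(genomes, reference)
      mat <- cluster_orthologs(asn, species = names(genomes))
      list(assignments = asn, matrix = mat)
    })
    if (status$introns) {
      asn <- pcl$assignments
      asn$identity <- fmt_num(asn$identity, 4)
      emit(asn[, setdiff(names(asn), "seq")], "pcl_assignments.tsv")
      mat_df <- data.frame(species = rownames(pcl$matrix),
                           as.data.frame(pcl$matrix, check.names = FALSE),
                           check.names = FALSE)
      emit(mat_df, "pcl_matrix.tsv")
      res$pcl <- pcl
      gl_tree <- tree
      if (!is.null(gl_tree)) {
        ev <- stage("gain_loss", {
          m <- pcl$matrix
          keep <- apply(m, 2, function(col) any(col == "1"))
          gain_loss(m[, keep, drop = FALSE], gl_tree, mode = "dollo")
        })
        if (status$gain_loss) { emit(ev, "pcl_events.tsv"); res$events <- ev }
      }
    }
  }

  if (do_phylo) {
    ph <- stage("phylo", {
      alns <- list()
      for (gene in PHYLO_PCGS) {
        cds <- list()
        for (g in genomes) {
          x <- gene_cds(g, gene)
          if (!is.null(x)) cds[[g$species_id]] <- x
        }
        if (length(cds) == length(genomes))
          alns[[gene]] <- tryCatch(codon_align(cds),
                                   mitocomp_gene_error = function(e) NULL)
      }
      alns <- Filter(Negate(is.null), alns)
      if (length(alns) == 0L) stop("no alignable phylogeny genes")
      sm <- concatenate_alignments(alns)
      bootstrap_nj(sm, n_reps = boot_reps, seed = seed, outgroup = outgroup)
    })
    if (status$phylo) {
      p <- file.path(out_dir, "tree.nwk")
      write_newick(ph$tree, p)
      paths <- c(paths, p)
      res$phylo <- ph
    }
  }

  manifest <- list(package = "mitocomp",
                   version = as.character(utils::packageVersion("mitocomp")),
                   seed = seed, boot_reps = boot_reps,
                   species = names(genomes),
                   stages = status, timings = timings,
                   total_seconds = round(proc.time()[["elapsed"]] - t0, 3))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  partial <- !all(unlist(status))
  invisible(list(paths = paths, status = status, partial = partial,
                 results = res))
}
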