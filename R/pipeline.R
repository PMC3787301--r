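#' Mirror a hit table to the opposite search direction
#'
#' Swaps query and subject roles. Bitscores and raw scores are symmetric;
#' e-values are recomputed for the new direction (new query length times the
#' new database size), with the raw score recovered from the bitscore.
#'
#' @param hits hit table from [search_proteins()].
#' @param query_lengths named integer vector of sequence lengths for the new
#'   queries (the old subjects).
#' @param db_len total residues of the new subject set (the old query set).
#' @param scheme the [scoring_scheme()] used for the original search.
#' @return The mirrored hit table.
#' @keywords internal
mirror_hits <- function(hits, query_lengths, db_len,
                        scheme = scoring_scheme()) {
  raw <- (hits$bitscore * log(2) + log(scheme$k_const)) / scheme$lambda
  out <- data.frame(
    query_id = hits$subject_id, subject_id = hits$query_id,
    pident = hits$pident, length = hits$length, mismatch = hits$mismatch,
    gapopen = hits$gapopen, qstart = hits$sstart, qend = hits$send,
    sstart = hits$qstart, send = hits$qend,
    evalue = scheme$k_const * query_lengths[hits$subject_id] * db_len *
      exp(-scheme$lambda * raw),
    bitscore = hits$bitscore)
  rownames(out) <- NULL
  out
}

#' Run the full comparative pipeline on a simulated study
#'
#' Simulates the study inputs, performs all pairwise proteome searches,
#' builds the reciprocal-best-hit graph and forms ortholog clusters, assigns
#' cluster phyla by majority voting and KEGG categories via the decision
#' tree, grades each genome against the single-copy marker inventory with
#' assembly statistics, scans scaffolds for the RnpB motif, and tallies the
#' 16S survey with the two-group foregut/hindgut comparison.
#'
#' @param config a [simulation_config()].
#' @param out_dir optional directory: simulation inputs and all result
#'   tables are written there (byte-identical across runs with the same
#'   seed).
#' @param scheme a [scoring_scheme()].
#' @param max_evalue hit-reporting e-value cutoff (default 1e-5).
#' @param cfg a [voting_config()].
#' @return A list of class `"melacog_run"`: `sim`, `clusters`, `taxa`,
#'   `phylum_fractions`, `functions`, `functional_summary`, `genome_reports`
#'   (per genome: inventory, status, assembly stats, RnpB loci), `survey`
#'   (tally, plotting table, two-group test).
#' @export
run_pipeline <- function(config = simulation_config(), out_dir = NULL,
                         scheme = scoring_scheme(), max_evalue = 1e-5,
                         cfg = voting_config()) {
  sim <- simulate_all(config, out_dir)
  genomes <- names(sim$proteomes)

  # all-vs-all across every unordered genome pair, mirrored to both
  # directions (raw local scores are symmetric)
  pair_hits <- list()
  for (i in seq_along(genomes)) for (j in seq_along(genomes)) {
    if (i >= j) next
    A <- sim$proteomes[[i]]; B <- sim$proteomes[[j]]
    h_ab <- search_proteins(A, B, scheme, max_evalue)
    h_ba <- mirror_hits(h_ab, setNames(nchar(B$sequence), B$id),
                        sum(nchar(A$sequence)), scheme)
    h_ba <- h_ba[h_ba$evalue <= max_evalue, , drop = FALSE]
    pair_hits[[paste(genomes[i], genomes[j], sep = "~")]] <- h_ab
    pair_hits[[paste(genomes[j], genomes[i], sep = "~")]] <- h_ba
  }
  genome_map <- unlist(lapply(genomes, function(g)
    setNames(rep(g, nrow(sim$proteomes[[g]])), sim$proteomes[[g]]$id)))
  graph <- build_rbh_graph(pair_hits, genome_map, genomes)
  clusters <- form_clusters(graph)

  # reference search for taxon voting + KO assignment
  members <- unlist(clusters[, genomes, drop = FALSE], use.names = FALSE)
  member_df <- do.call(rbind, sim$proteomes)
  member_df <- member_df[member_df$id %in% members, , drop = FALSE]
  ref_hits <- if (nrow(sim$reference$reference) > 0)
    search_proteins(member_df, sim$reference$reference, scheme, max_evalue)
  else empty_hit_table()
  taxa <- assign_cog_taxa(clusters, ref_hits, sim$reference$taxonomy, cfg)
  phylum_fractions <- summarize_phylum_fractions(taxa$label)
  komap <- structure(list(gene2ko = sim$reference$gene2ko,
                          ko2pathway = sim$reference$ko2pathway,
                          pathway2category = sim$reference$pathway2category),
                     class = "ko_map")
  funcs <- assign_cog_functions(clusters, ref_hits, komap, max_evalue)
  fsummary <- functional_summary(funcs, taxa)

  # genome assessment + motif scan
  marker_set <- synthetic_marker_set()
  genome_reports <- lapply(genomes, function(g) {
    inv <- marker_inventory(sim$proteomes[[g]], marker_set, scheme,
                            max_evalue)
    sca <- sim$scaffolds[[g]]
    status <- classify_status(inv, sca$scaffolds$id, sca$linkage)
    stats <- assembly_stats(sca$scaffolds, sca$coding_counts)
    rnpb <- find_rnpb_loci(sca$scaffolds)
    list(genome = g, inventory = inv, status = status, stats = stats,
         rnpb = rnpb)
  })
  names(genome_reports) <- genomes

  # survey
  assigned <- filter_survey_hits(sim$survey$hits)
  tallies <- tally_survey(assigned, sim$survey$totals, sim$survey$types)
  plot_table <- group_filter(tallies)
  fg <- plot_table$log10_pct[plot_table$sample_type == "foregut_feces"]
  hg <- plot_table$log10_pct[plot_table$sample_type == "hindgut_feces"]
  two_group <- if (length(fg) >= 2 && length(hg) >= 2)
    compare_two_groups(fg, hg) else NULL

  run <- structure(list(
    sim = sim, graph = graph, clusters = clusters, taxa = taxa,
    phylum_fractions = phylum_fractions, functions = funcs,
    functional_summary = fsummary, genome_reports = genome_reports,
    survey = list(tallies = tallies, plot_table = plot_table,
                  two_group = two_group)), class = "melacog_run")
  if (!is.null(out_dir)) write_run_results(run, out_dir)
  run
}

write_run_results <- function(run, out_dir) {
  res <- file.path(out_dir, "results")
  dir.create(res, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) utils::write.table(
    x, file.path(res, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wt(as.data.frame(run$clusters), "cogs.tsv")
  wt(run$taxa, "cog_taxa.tsv")
  wt(run$phylum_fractions, "phylum_fractions.tsv")
  wt(run$functions, "cog_functions.tsv")
  wt(run$functional_summary$summary, "functional_summary.tsv")
  status_df <- do.call(rbind, lapply(run$genome_reports, function(r)
    data.frame(genome = r$genome, status = r$status$status,
               linked_fraction = r$status$linked_fraction,
               size_bp = r$stats$size_bp,
               pct_gc = round(r$stats$pct_gc, 2),
               n_scaffolds = r$stats$n_scaffolds, n50 = r$stats$n50,
               coding_features = r$stats$coding_features)))
  wt(status_df, "genome_status.tsv")
  rnpb <- do.call(rbind, lapply(run$genome_reports, `[[`, "rnpb"))
  rnpb$flank <- NULL
  wt(rnpb, "rnpb_loci.tsv")
  wt(run$survey$tallies, "survey_tallies.tsv")
  wt(run$survey$plot_table, "survey_plot_table.tsv")
  invisible(out_dir)
}

#' @export
print.melacog_run <- function(x, ...) {
  cat(sprintf("Pipeline run: %d genomes, %d clusters\n",
              length(x$sim$proteomes), nrow(x$clusters)))
  print(x$phylum_fractions)
  invisible(x)
}

#' Score recovered clusters against planted families
#'
#' A planted family (including the single-copy marker families, which are
#' genuine one-per-genome ortholog groups) is eligible when all genomes
#' retain an ortholog copy. A
#' recovered cluster is correct when its member set is exactly the planted
#' ortholog set of one family. Precision is correct clusters over recovered
#' clusters; recall is correct clusters over eligible families.
#'
#' @param clusters a `cog_clusters` data frame.
#' @param truth the `truth` element of a simulation.
#' @return A list with `precision`, `recall`, `n_clusters`,
#'   `n_eligible_families`, `n_correct`.
#' @export
cluster_accuracy <- function(clusters, truth) {
  mem <- truth$membership
  ort <- mem[mem$role %in% c("ortholog", "marker"), , drop = FALSE]
  fam_sets <- split(ort$protein_id, ort$family)
  n_genomes <- length(unique(mem$genome))
  eligible <- names(fam_sets)[lengths(fam_sets) == n_genomes]
  genomes <- setdiff(names(clusters), "cluster_id")
  keys <- apply(clusters[, genomes, drop = FALSE], 1, function(r)
    paste(sort(r), collapse = "|"))
  truth_keys <- vapply(fam_sets[eligible], function(s)
    paste(sort(s), collapse = "|"), "")
  n_correct <- sum(keys %in% truth_keys)
  list(precision = if (length(keys)) n_correct / length(keys) else NA_real_,
       recall = if (length(eligible)) n_correct / length(eligible)
                else NA_real_,
       n_clusters = length(keys), n_eligible_families = length(eligible),
       n_correct = n_correct)
}

#' Score per-gene phylum assignments against the planted nearest phyla
#'
#' The expected label of a gene is its family's planted nearest phylum, or
#' "No hit" for families with no reference counterpart. Accuracy is taken
#' over all cluster member genes whose family is known.
#'
#' @param taxa per-cluster label table from [assign_cog_taxa()].
#' @param clusters the matching `cog_clusters` data frame.
#' @param truth the `truth` element of a simulation.
#' @return A list with `accuracy`, `n_genes`, `n_correct`.
#' @export
gene_phylum_accuracy <- function(taxa, clusters, truth) {
  genomes <- setdiff(names(clusters), "cluster_id")
  fam_of <- setNames(truth$membership$family, truth$membership$protein_id)
  expected_of_fam <- setNames(truth$families$nearest_phylum,
                              truth$families$family)
  n <- 0L; ok <- 0L
  for (g in genomes) {
    gene <- clusters[[g]]
    lab <- taxa[[paste0(g, "_label")]]
    fam <- fam_of[gene]
    known <- !is.na(fam)
    expect <- expected_of_fam[fam[known]]
    expect[is.na(expect)] <- "No hit"
    n <- n + sum(known)
    ok <- ok + sum(lab[known] == expect)
  }
  list(accuracy = if (n) ok / n else NA_real_, n_genes = n, n_correct = ok)
}
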