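test_that("zero divergence yields identical family copies", {
  cfg <- simulation_config(seed = 3, n_families = 10, divergence = 0)
  pro <- simulate_proteomes(cfg)
  fams <- pro$truth$families
  for (i in 1:10) {
    copies <- vapply(pro$proteomes, function(p)
      p$sequence[p$id == sprintf("%s|%s", p$genome_id[1], fams$family[i])],
      "")
    expect_true(all(copies == copies[1]))
  }
})

test_that("mean pairwise identity tracks the divergence parameter", {
  cfg <- simulation_config(seed = 4, n_families = 200, divergence = 0.05,
                           marker_insertion = FALSE)
  pro <- simulate_proteomes(cfg)
  A <- pro$proteomes[[1]]; B <- pro$proteomes[[2]]
  idents <- vapply(seq_len(nrow(A)), function(i) {
    a <- strsplit(A$sequence[i], "")[[1]]
    b <- strsplit(B$sequence[i], "")[[1]]
    mean(a == b)
  }, 0)
  expect_equal(100 * mean(idents), 100 * (1 - 0.05), tolerance = 2)
})

test_that("loss and duplication parameters act as limits", {
  cfg <- simulation_config(seed = 5, n_families = 15, p_loss = 1)
  pro <- simulate_proteomes(cfg)
  for (p in pro$proteomes)
    expect_true(all(grepl("rp[LS]", p$id)))  # only markers remain
  cfg2 <- simulation_config(seed = 6, n_families = 15, p_dup = 1,
                            marker_insertion = FALSE)
  pro2 <- simulate_proteomes(cfg2)
  for (p in pro2$proteomes) expect_equal(nrow(p), 30L)
})

test_that("the reference database plants the nearest phylum by construction", {
  cfg <- simulation_config(seed = 7, n_families = 40)
  pro <- simulate_proteomes(cfg)
  ref <- simulate_reference_db(cfg, pro$truth)
  fams <- pro$truth$families
  with_phylum <- fams[!is.na(fams$nearest_phylum), ]
  expect_equal(nrow(ref$reference),
               nrow(with_phylum) * length(cfg$phyla))
  # per family, the closest reference by simple identity carries the label
  for (i in head(seq_len(nrow(with_phylum)), 10)) {
    fam <- with_phylum$family[i]
    anc <- strsplit(with_phylum$ancestor[i], "")[[1]]
    refs <- ref$reference[grepl(paste0("\\|", fam, "$"), ref$reference$id), ]
    ident <- vapply(refs$sequence, function(s)
      mean(strsplit(s, "")[[1]] == anc), 0)
    best <- refs$id[which.max(ident)]
    expect_equal(unname(ref$taxonomy[best]), with_phylum$nearest_phylum[i])
  }
  # families without a planted phylum have no reference counterpart
  absent <- fams$family[is.na(fams$nearest_phylum)]
  expect_false(any(vapply(absent, function(f)
    any(grepl(paste0("\\|", f, "$"), ref$reference$id)), TRUE)))
  # every reference gene carries a KO, and maps are structurally sound
  expect_true(all(ref$reference$id %in% names(ref$gene2ko)))
  expect_true(all(unlist(ref$ko2pathway) %in% names(ref$pathway2category)))
})

test_that("scaffold simulation respects linkage and plants motifs cleanly", {
  cfg <- simulation_config(seed = 8, n_families = 15,
                           scaffolds_per_genome = 5, n_motifs = 4)
  pro <- simulate_proteomes(cfg)
  sca <- simulate_scaffolds(cfg, pro$proteomes)
  for (g in names(sca)) {
    found <- find_rnpb_loci(sca[[g]]$scaffolds)
    truth <- sca[[g]]$motifs
    expect_equal(nrow(found), nrow(truth))
    expect_equal(found[order(found$scaffold_id, found$start),
                       c("scaffold_id", "start", "end", "strand")],
                 truth[order(truth$scaffold_id, truth$start), ],
                 ignore_attr = TRUE)
    expect_equal(linked_fraction(sca[[g]]$scaffolds$id, sca[[g]]$linkage), 1)
    expect_equal(sum(sca[[g]]$coding_counts), nrow(pro$proteomes[[g]]))
  }
  # single-scaffold limit: n50 equals genome size
  cfg1 <- simulation_config(seed = 9, n_families = 10,
                            scaffolds_per_genome = 1)
  sca1 <- simulate_scaffolds(cfg1, simulate_proteomes(cfg1)$proteomes)
  st <- assembly_stats(sca1[[1]]$scaffolds)
  expect_equal(st$n50, st$size_bp)
})

test_that("survey simulation matches planted counts when decoys are off", {
  cfg <- simulation_config(seed = 10, decoy_read_fraction = 0)
  sur <- simulate_16s_survey(cfg)
  asg <- filter_survey_hits(sur$hits)
  tl <- tally_survey(asg, sur$totals, sur$types)
  expect_equal(tl$target_reads,
               sur$truth$target_reads[match(tl$sample_id,
                                            sur$truth$sample_id)])
  # with decoys, sub-97 hits exist but are filtered out
  cfg2 <- simulation_config(seed = 10, decoy_read_fraction = 0.3)
  sur2 <- simulate_16s_survey(cfg2)
  expect_true(any(sur2$hits$pident < 97))
  tl2 <- tally_survey(filter_survey_hits(sur2$hits), sur2$totals, sur2$types)
  expect_equal(tl2$target_reads,
               sur2$truth$target_reads[match(tl2$sample_id,
                                             sur2$truth$sample_id)])
})

test_that("recovered per-type abundance medians are close to planted ones", {
  types <- data.frame(type = c("ta", "tb"), n_samples = c(50L, 50L),
                      meanlog = log(c(0.5, 0.1)), sdlog = c(0.6, 0.6))
  cfg <- simulation_config(seed = 11, survey_types = types,
                           decoy_read_fraction = 0)
  sur <- simulate_16s_survey(cfg)
  tl <- tally_survey(filter_survey_hits(sur$hits), sur$totals, sur$types)
  for (tt in types$type) {
    got <- median(tl$rel_abundance_pct[tl$sample_type == tt])
    planted <- median(sur$truth$true_pct[sur$truth$sample_type == tt])
    expect_lt(abs(got - planted) / planted, 0.25)
  }
})

test_that("identical seeds reproduce byte-identical outputs, new seeds differ", {
  cfg <- simulation_config(seed = 12, n_families = 8,
                           scaffolds_per_genome = 3)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_all(cfg, d1)
  simulate_all(cfg, d2)
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  d3 <- withr::local_tempdir()
  simulate_all(simulation_config(seed = 13, n_families = 8,
                                 scaffolds_per_genome = 3), d3)
  g1 <- readLines(file.path(d1, "genomes", "ACD20.faa"))
  g3 <- readLines(file.path(d3, "genomes", "ACD20.faa"))
  expect_false(identical(g1, g3))
})

test_that("emitted files pass the package parsers cleanly", {
  cfg <- simulation_config(seed = 14, n_families = 6,
                           scaffolds_per_genome = 2)
  d <- withr::local_tempdir()
  simulate_all(cfg, d)
  expect_no_warning({
    for (f in list.files(file.path(d, "genomes"), full.names = TRUE))
      read_fasta(f, type = "protein")
    for (f in list.files(file.path(d, "scaffolds"), full.names = TRUE))
      read_fasta(f, type = "nucleotide")
    read_fasta(file.path(d, "reference.faa"), type = "protein")
    load_taxonomy_map(file.path(d, "taxonomy.tsv"))
    read_hit_table(file.path(d, "survey", "hits.tsv"))
    load_ko_map(file.path(d, "ko"))
  })
})
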