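# Background residue frequencies (Robinson-Robinson), the standard protein
# composition underlying BLOSUM62 search statistics.
aa_background <- c(
  A = 0.07805, R = 0.05129, N = 0.04487, D = 0.05364, C = 0.01925,
  Q = 0.04264, E = 0.06295, G = 0.07377, H = 0.02199, I = 0.05142,
  L = 0.09019, K = 0.05744, M = 0.02243, F = 0.03856, P = 0.05203,
  S = 0.07120, T = 0.05841, W = 0.01330, Y = 0.03216, V = 0.06441)

sample_residues <- function(n) {
  sample(names(aa_background), n, replace = TRUE, prob = aa_background)
}

# Run code under a given seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Derive a per-module substream seed from the master seed (kept below 2^31).
derive_seed <- function(seed, offset) {
  ((as.numeric(seed) %% 65521) * 31627 + offset * 104729) %% 2147483647
}

# Per-copy mutation rate giving an expected *pairwise* divergence d between
# two independently mutated copies, under replacement draws from the
# background (a draw may reproduce the original residue).
copy_mutation_rate <- function(d) {
  pm <- 1 - sum(aa_background^2)
  if (d <= 0) return(0)
  if (d / pm >= 1) return(1)
  1 - sqrt(1 - d / pm)
}

mutate_protein <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- runif(length(chars)) < rate
  if (any(hit)) chars[hit] <- sample_residues(sum(hit))
  paste(chars, collapse = "")
}

#' Simulation configuration
#'
#' Parameters of the synthetic study: genome count, planted ortholog family
#' count, sequence divergence, duplication/loss rates, the reference-database
#' layout, scaffold fragmentation and the 16S survey design. The defaults
#' are the conditions every downstream check is run under.
#'
#' @param seed master integer seed; every module draws from a substream
#'   derived from it.
#' @param n_genomes genomes to simulate (default 4).
#' @param n_families planted ortholog families (default 200).
#' @param divergence expected pairwise amino-acid divergence between two
#'   genome copies of a family (default 0.05).
#' @param p_loss per-genome probability a family copy is lost (default 0).
#' @param p_dup per-genome probability of an extra paralogous copy
#'   (default 0).
#' @param paralog_extra_divergence additional pairwise divergence of
#'   paralogs (default 0.2).
#' @param protein_length_mean,protein_length_sd ancestral protein length
#'   distribution (defaults 250 and 50; lengths floored at 50).
#' @param phyla named numeric vector of per-phylum family fractions; the
#'   named phylum is planted as the family's nearest reference phylum. The
#'   remainder to 1 are "No hit" families with no reference counterpart.
#' @param close_offset mutation rate of the nearest-phylum reference
#'   homolog relative to the family ancestor (default 0.10).
#' @param decoy_offset mutation rate of decoy homologs from the other phyla
#'   (default 0.35; must exceed `close_offset`).
#' @param n_ko size of the planted KO catalog (default 40).
#' @param n_pathways planted pathways (default 30) spread over six KEGG-like
#'   categories.
#' @param marker_insertion insert one mutated copy of each of the 16
#'   single-copy marker representatives per genome (default `TRUE`).
#' @param scaffolds_per_genome scaffolds each genome is fragmented into
#'   (default 10).
#' @param spacer_length mean intergenic spacer length in nt (default 150).
#' @param linkage_completeness fraction of scaffolds connected by the
#'   emitted linkage table (default 1).
#' @param n_motifs RnpB motif copies planted per genome (default 3, mixed
#'   strands).
#' @param survey_types data frame `type`, `n_samples`, `meanlog`, `sdlog`
#'   describing per-type log-normal relative abundances (in percent);
#'   `NULL` for the built-in six-type design (feces from foregut and hindgut
#'   fermenters, human feces, soil, water, and a near-absent air type).
#' @param decoy_read_fraction fraction of extra sub-threshold (below 97
#'   percent identity) read hits emitted per sample (default 0.1).
#' @return A list of class `"sim_config"`.
#' @export
simulation_config <- function(
    seed = 1L, n_genomes = 4L, n_families = 200L, divergence = 0.05,
    p_loss = 0, p_dup = 0, paralog_extra_divergence = 0.2,
    protein_length_mean = 250, protein_length_sd = 50,
    phyla = c(Firmicutes = 0.30, Cyanobacteria = 0.15,
              Proteobacteria = 0.20, Bacteroidetes = 0.20),
    close_offset = 0.10, decoy_offset = 0.35,
    n_ko = 40L, n_pathways = 30L,
    marker_insertion = TRUE, scaffolds_per_genome = 10L,
    spacer_length = 150L, linkage_completeness = 1,
    n_motifs = 3L, survey_types = NULL, decoy_read_fraction = 0.1) {
  stopifnot(n_genomes >= 2L, n_families >= 1L,
            divergence >= 0, divergence <= 1,
            p_loss >= 0, p_loss <= 1, p_dup >= 0, p_dup <= 1,
            sum(phyla) <= 1 + 1e-9, all(phyla >= 0),
            close_offset < decoy_offset,
            linkage_completeness >= 0, linkage_completeness <= 1)
  if (is.null(survey_types))
    survey_types <- data.frame(
      type = c("foregut_feces", "hindgut_feces", "human_feces",
               "soil", "water", "air"),
      n_samples = c(15L, 15L, 20L, 20L, 10L, 5L),
      meanlog = log(c(0.5, 0.12, 0.05, 0.02, 0.8, 0.002)),
      sdlog = c(0.8, 0.8, 1.0, 1.0, 0.8, 0.5))
  structure(list(
    seed = as.integer(seed), n_genomes = as.integer(n_genomes),
    n_families = as.integer(n_families), divergence = divergence,
    p_loss = p_loss, p_dup = p_dup,
    paralog_extra_divergence = paralog_extra_divergence,
    protein_length_mean = protein_length_mean,
    protein_length_sd = protein_length_sd,
    phyla = phyla, close_offset = close_offset,
    decoy_offset = decoy_offset, n_ko = as.integer(n_ko),
    n_pathways = as.integer(n_pathways),
    marker_insertion = isTRUE(marker_insertion),
    scaffolds_per_genome = as.integer(scaffolds_per_genome),
    spacer_length = as.integer(spacer_length),
    linkage_completeness = linkage_completeness,
    n_motifs = as.integer(n_motifs), survey_types = survey_types,
    decoy_read_fraction = decoy_read_fraction), class = "sim_config")
}

genome_names <- function(n) {
  base <- c("ACD20", "MEL.A1", "MEL.B1", "MEL.B2")
  if (n <= 4L) base[seq_len(n)] else c(base, sprintf("MEL.X%d", seq_len(n - 4L)))
}

#' Simulate related proteomes with planted ortholog families
#'
#' Ancestral proteins are drawn residue-wise from the background amino-acid
#' frequencies; each genome receives an independently mutated copy
#' (replacement draws from the background at a rate calibrated so the
#' expected pairwise divergence between two copies equals `divergence`).
#' Families are dropped per genome with probability `p_loss`; paralogs are
#' added with probability `p_dup` at elevated divergence. When
#' `marker_insertion` is set, one mutated copy of each of the 16 synthetic
#' marker representatives is appended per genome.
#'
#' @param config a [simulation_config()].
#' @return A list with `proteomes` (named list of [read_fasta()]-style data
#'   frames) and `truth` (family table, per-protein family membership,
#'   marker identities).
#' @export
simulate_proteomes <- function(config) {
  with_seed(derive_seed(config$seed, 1), {
    G <- genome_names(config$n_genomes)
    nf <- config$n_families
    lens <- pmax(50L, round(rnorm(nf, config$protein_length_mean,
                                  config$protein_length_sd)))
    ancestors <- vapply(lens, function(L)
      paste(sample_residues(L), collapse = ""), "")
    # planted nearest phylum per family (fixed counts, shuffled order)
    counts <- floor(config$phyla * nf)
    phylum_of <- rep(NA_character_, nf)
    pool <- sample.int(nf)
    k <- 0L
    for (p in names(counts)) {
      if (counts[p] == 0) next
      phylum_of[pool[(k + 1L):(k + counts[p])]] <- p
      k <- k + counts[p]
    }
    ko_catalog <- sprintf("K%05d", seq_len(config$n_ko))
    ko_of <- ifelse(is.na(phylum_of), NA_character_,
                    sample(ko_catalog, nf, replace = TRUE))
    fam_ids <- sprintf("F%03d", seq_len(nf))
    rate <- copy_mutation_rate(config$divergence)
    para_rate <- copy_mutation_rate(
      min(1, config$divergence + config$paralog_extra_divergence))
    proteomes <- list()
    membership <- list()
    for (g in G) {
      ids <- character(); seqs <- character(); fams <- character()
      roles <- character()
      for (i in seq_len(nf)) {
        if (config$p_loss > 0 && runif(1) < config$p_loss) next
        id <- sprintf("%s|%s", g, fam_ids[i])
        ids <- c(ids, id)
        seqs <- c(seqs, mutate_protein(ancestors[i], rate))
        fams <- c(fams, fam_ids[i]); roles <- c(roles, "ortholog")
        if (config$p_dup > 0 && runif(1) < config$p_dup) {
          ids <- c(ids, paste0(id, ".p"))
          seqs <- c(seqs, mutate_protein(ancestors[i], para_rate))
          fams <- c(fams, fam_ids[i]); roles <- c(roles, "paralog")
        }
      }
      if (config$marker_insertion) {
        mk <- synthetic_marker_set()
        ids <- c(ids, sprintf("%s|%s", g, mk$id))
        seqs <- c(seqs, vapply(mk$sequence, mutate_protein, "", rate = rate,
                               USE.NAMES = FALSE))
        fams <- c(fams, paste0("MARKER|", mk$id))
        roles <- c(roles, rep("marker", nrow(mk)))
      }
      proteomes[[g]] <- fasta_frame(ids, "", seqs, g)
      membership[[g]] <- data.frame(protein_id = ids, genome = g,
                                    family = fams, role = roles)
    }
    truth <- list(
      families = data.frame(family = fam_ids, length = lens,
                            ancestor = ancestors,
                            nearest_phylum = phylum_of, ko = ko_of),
      membership = do.call(rbind, membership),
      marker_names = if (config$marker_insertion) default_marker_names()
                     else character())
    list(proteomes = proteomes, truth = truth)
  })
}

#' Simulate the taxon- and KO-labeled reference database
#'
#' For each family with a planted nearest phylum, one close homolog of the
#' family ancestor is emitted under that phylum's label, plus one decoy
#' homolog per other phylum at a larger divergence, so the planted phylum is
#' the best match by construction. Every reference gene carries a KO from
#' the planted catalog; the KO-to-pathway and pathway-to-category tables are
#' generated so that pathway-less KOs ("Undecided") and cross-category KOs
#' ("Multiple") both occur.
#'
#' @param config a [simulation_config()].
#' @param truth the `truth` element from [simulate_proteomes()].
#' @return A list with `reference` (protein data frame), `taxonomy` (named
#'   vector), `gene2ko` (named vector), `ko2pathway` (list),
#'   `pathway2category` (named vector).
#' @export
simulate_reference_db <- function(config, truth) {
  with_seed(derive_seed(config$seed, 2), {
    fams <- truth$families
    phyla <- names(config$phyla)
    ids <- character(); seqs <- character(); tax <- character()
    kos <- character()
    for (i in seq_len(nrow(fams))) {
      np <- fams$nearest_phylum[i]
      if (is.na(np)) next
      for (p in phyla) {
        rate <- if (p == np) config$close_offset else config$decoy_offset
        ids <- c(ids, sprintf("REF|%s|%s", p, fams$family[i]))
        seqs <- c(seqs, mutate_protein(fams$ancestor[i], rate))
        tax <- c(tax, p)
        kos <- c(kos, fams$ko[i])
      }
    }
    categories <- c("Carbohydrate metabolism", "Energy metabolism",
                    "Amino acid metabolism", "Nucleotide metabolism",
                    "Translation", "Membrane transport")
    pathways <- sprintf("map%05d", seq_len(config$n_pathways))
    pathway2category <- setNames(
      sample(categories, config$n_pathways, replace = TRUE), pathways)
    ko_ids <- sprintf("K%05d", seq_len(config$n_ko))
    ko2pathway <- lapply(ko_ids, function(k) {
      n <- sample(0:3, 1, prob = c(0.15, 0.45, 0.25, 0.15))
      if (n == 0) character() else sample(pathways, n)
    })
    names(ko2pathway) <- ko_ids
    ko2pathway <- ko2pathway[lengths(ko2pathway) > 0]
    list(reference = fasta_frame(ids, "", seqs, NULL),
         taxonomy = setNames(tax, ids),
         gene2ko = setNames(kos, ids),
         ko2pathway = ko2pathway,
         pathway2category = pathway2category)
  })
}

# Uniform back-translation table built from the standard genetic code.
codon_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      gc <- Biostrings::GENETIC_CODE
      cache <<- split(names(gc), unname(gc))
    }
    cache
  }
})

back_translate <- function(protein) {
  tab <- codon_table()
  chars <- strsplit(protein, "")[[1]]
  paste(vapply(chars, function(a) {
    cods <- tab[[a]]
    cods[sample.int(length(cods), 1)]
  }, "", USE.NAMES = FALSE), collapse = "")
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

rnpb_motif <- function() "GAGGAAAGTCC"

#' Simulate scaffolds with planted RnpB motifs and a linkage table
#'
#' Genes are back-translated with uniform codon choice and concatenated with
#' random intergenic spacers into scaffolds (about `scaffolds_per_genome`
#' per genome, built gene by gene so no gene is split). Chance occurrences
#' of the RnpB motif are disrupted, then `n_motifs` copies are planted per
#' genome at recorded positions on recorded strands. The linkage table
#' chains the first `ceiling(linkage_completeness * n)` scaffolds.
#'
#' @param config a [simulation_config()].
#' @param proteomes named list of proteome data frames from
#'   [simulate_proteomes()].
#' @return A list per genome: `scaffolds` (nucleotide data frame), `linkage`
#'   (pair data frame), `coding_counts` (named vector), `motifs` (truth data
#'   frame `scaffold_id`, `start`, `end`, `strand`).
#' @export
simulate_scaffolds <- function(config, proteomes) {
  with_seed(derive_seed(config$seed, 3), {
    motif <- rnpb_motif()
    motif_rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(motif)))
    out <- list()
    for (g in names(proteomes)) {
      prot <- proteomes[[g]]
      n_scaf <- max(1L, config$scaffolds_per_genome)
      per_scaf <- ceiling(nrow(prot) / n_scaf)
      scaf_seq <- character(); scaf_coding <- integer()
      i <- 1L
      while (i <= nrow(prot)) {
        take <- seq(i, min(i + per_scaf - 1L, nrow(prot)))
        pieces <- character(0)
        for (k in take) {
          pieces <- c(pieces, random_dna(max(
            10L, round(rnorm(1, config$spacer_length,
                             config$spacer_length / 4)))),
            back_translate(prot$sequence[k]))
        }
        pieces <- c(pieces, random_dna(config$spacer_length))
        scaf_seq <- c(scaf_seq, paste(pieces, collapse = ""))
        scaf_coding <- c(scaf_coding, length(take))
        i <- i + per_scaf
      }
      ids <- sprintf("%s|scaffold_%02d", g, seq_along(scaf_seq))
      # disrupt chance motif occurrences on either strand
      for (s in seq_along(scaf_seq)) {
        repeat {
          hit <- c(gregexpr(motif, scaf_seq[s], fixed = TRUE)[[1]],
                   gregexpr(motif_rc, scaf_seq[s], fixed = TRUE)[[1]])
          hit <- hit[hit > 0]
          if (length(hit) == 0L) break
          p <- hit[1] + 5L
          cur <- substr(scaf_seq[s], p, p)
          substr(scaf_seq[s], p, p) <- setdiff(c("A", "C", "G", "T"), cur)[1]
        }
      }
      # plant motifs at recorded positions
      motifs <- data.frame(scaffold_id = character(), start = integer(),
                           end = integer(), strand = character())
      if (config$n_motifs > 0L) {
        pick <- sample(rep(seq_along(scaf_seq),
                           length.out = config$n_motifs))
        w <- nchar(motif)
        for (s in pick) {
          L <- nchar(scaf_seq[s])
          repeat {
            pos <- sample.int(L - w + 1L, 1)
            prior <- motifs[motifs$scaffold_id == ids[s], , drop = FALSE]
            # keep planted copies separated so none is overwritten
            if (all(abs(prior$start - pos) >= w)) break
          }
          strand <- sample(c("+", "-"), 1)
          substr(scaf_seq[s], pos, pos + w - 1L) <-
            if (strand == "+") motif else motif_rc
          motifs <- rbind(motifs, data.frame(
            scaffold_id = ids[s], start = pos, end = pos + w - 1L,
            strand = strand))
        }
      }
      n_linked <- ceiling(config$linkage_completeness * length(ids))
      linkage <- if (n_linked >= 2L)
        data.frame(a = ids[seq_len(n_linked - 1L)],
                   b = ids[seq(2L, n_linked)])
      else data.frame(a = character(), b = character())
      out[[g]] <- list(
        scaffolds = fasta_frame(ids, "", scaf_seq, NULL),
        linkage = linkage,
        coding_counts = setNames(scaf_coding, ids),
        motifs = motifs[order(motifs$scaffold_id, motifs$start), ,
                        drop = FALSE])
    }
    out
  })
}

#' Simulate a 16S rRNA survey
#'
#' Per sample, the true relative abundance is drawn from its type's
#' log-normal distribution (in percent) and the target read count is
#' binomial given the sample's total reads. Target reads are emitted as hits
#' at 97-100 percent identity; an extra `decoy_read_fraction` of reads is
#' emitted below the 97 percent threshold and must be removed by the filter.
#'
#' @param config a [simulation_config()].
#' @return A list with `hits` (hit table), `totals`, `types` (data frames),
#'   and `truth` (per-sample planted abundance and target count).
#' @export
simulate_16s_survey <- function(config) {
  with_seed(derive_seed(config$seed, 4), {
    st <- config$survey_types
    rows <- list(); hit_rows <- list()
    sample_no <- 0L
    for (t in seq_len(nrow(st))) {
      for (k in seq_len(st$n_samples[t])) {
        sample_no <- sample_no + 1L
        sid <- sprintf("S%03d", sample_no)
        total <- sample(5000:20000, 1)
        true_pct <- min(100, rlnorm(1, st$meanlog[t], st$sdlog[t]))
        target <- rbinom(1, total, true_pct / 100)
        rows[[sample_no]] <- data.frame(
          sample_id = sid, sample_type = st$type[t], total_reads = total,
          true_pct = true_pct, target_reads = target)
        n_decoy <- rbinom(1, target, config$decoy_read_fraction)
        n_reads <- target + n_decoy
        if (n_reads > 0) {
          pid <- c(round(runif(target, 97, 100), 1),
                   round(runif(n_decoy, 90, 96.9), 1))
          hit_rows[[length(hit_rows) + 1L]] <- data.frame(
            query_id = sprintf("%s_%d", sid, seq_len(n_reads)),
            subject_id = "MEL16S", pident = pid, length = 250L,
            mismatch = as.integer(round(250 * (100 - pid) / 100)),
            gapopen = 0L, qstart = 1L, qend = 250L, sstart = 1L,
            send = 250L, evalue = 1e-100, bitscore = round(pid * 4, 1))
        }
      }
    }
    truth <- do.call(rbind, rows)
    hits <- if (length(hit_rows)) do.call(rbind, hit_rows) else
      empty_hit_table()
    list(hits = hits,
         totals = truth[, c("sample_id", "total_reads")],
         types = truth[, c("sample_id", "sample_type")],
         truth = truth)
  })
}

#' Generate the full synthetic input bundle
#'
#' Runs every simulator and, when `out_dir` is given, writes all standard
#' input files (genome FASTAs, reference FASTA, taxonomy and KO TSVs,
#' scaffold FASTAs, linkage TSVs, survey tables) plus ground-truth TSVs.
#' Identical seeds reproduce byte-identical files.
#'
#' @param config a [simulation_config()].
#' @param out_dir output directory, or `NULL` to keep everything in memory.
#' @return A list of class `"mel_simulation"` with elements `proteomes`,
#'   `truth`, `reference`, `scaffolds`, `survey`, `config`.
#' @export
simulate_all <- function(config = simulation_config(), out_dir = NULL) {
  pro <- simulate_proteomes(config)
  ref <- simulate_reference_db(config, pro$truth)
  sca <- simulate_scaffolds(config, pro$proteomes)
  sur <- simulate_16s_survey(config)
  sim <- structure(list(proteomes = pro$proteomes, truth = pro$truth,
                        reference = ref, scaffolds = sca, survey = sur,
                        config = config), class = "mel_simulation")
  if (!is.null(out_dir)) write_simulation(sim, out_dir)
  sim
}

write_simulation <- function(sim, out_dir) {
  dirs <- file.path(out_dir, c("genomes", "scaffolds", "linkage", "ko",
                               "survey", "truth"))
  for (d in dirs) dir.create(d, recursive = TRUE, showWarnings = FALSE)
  for (g in names(sim$proteomes)) {
    write_fasta(sim$proteomes[[g]],
                file.path(out_dir, "genomes", paste0(g, ".faa")))
    write_fasta(sim$scaffolds[[g]]$scaffolds,
                file.path(out_dir, "scaffolds", paste0(g, ".fna")))
    utils::write.table(sim$scaffolds[[g]]$linkage,
                       file.path(out_dir, "linkage", paste0(g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE,
                       col.names = FALSE)
  }
  write_fasta(sim$reference$reference, file.path(out_dir, "reference.faa"))
  write_taxonomy_map(sim$reference$taxonomy,
                     file.path(out_dir, "taxonomy.tsv"))
  writeLines(paste(names(sim$reference$gene2ko), sim$reference$gene2ko,
                   sep = "\t"), file.path(out_dir, "ko", "gene2ko.tsv"))
  k2p <- sim$reference$ko2pathway
  writeLines(unlist(lapply(names(k2p), function(k)
    paste(k, k2p[[k]], sep = "\t"))),
    file.path(out_dir, "ko", "ko2pathway.tsv"))
  writeLines(paste(names(sim$reference$pathway2category),
                   sim$reference$pathway2category, sep = "\t"),
             file.path(out_dir, "ko", "pathway2category.tsv"))
  write_hit_table(sim$survey$hits, file.path(out_dir, "survey", "hits.tsv"))
  utils::write.table(sim$survey$totals,
                     file.path(out_dir, "survey", "totals.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$survey$types,
                     file.path(out_dir, "survey", "types.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$families[, c("family", "nearest_phylum", "ko")],
                     file.path(out_dir, "truth", "families.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$membership,
                     file.path(out_dir, "truth", "membership.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  for (g in names(sim$scaffolds))
    utils::write.table(sim$scaffolds[[g]]$motifs,
                       file.path(out_dir, "truth",
                                 paste0("motifs_", g, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$survey$truth,
                     file.path(out_dir, "truth", "survey.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(out_dir)
}
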