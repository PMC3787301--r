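#' Default single-copy marker names
#'
#' The 16 ribosomal proteins used as the bundled completeness yardstick:
#' rpL2, 3, 4, 5, 6, 14, 15, 16, 18, 22, 24 and rpS3, 8, 10, 17, 19.
#' @return Character vector of marker names.
#' @export
default_marker_names <- function() {
  c(paste0("rpL", c(2, 3, 4, 5, 6, 14, 15, 16, 18, 22, 24)),
    paste0("rpS", c(3, 8, 10, 17, 19)))
}

#' Synthetic representative sequences for the default marker set
#'
#' Real curated representatives are not bundled; instead a deterministic
#' synthetic stand-in is generated (fixed internal seed) with one sequence
#' per marker, at ribosomal-protein-like lengths (100-280 residues). The
#' simulator plants these same sequences, so inventories computed against
#' this set are internally consistent. Supply your own curated FASTA for
#' real genomes.
#'
#' @param seed integer seed for the deterministic generator.
#' @return A data frame (as from [read_fasta()]) with one representative per
#'   marker, ids equal to marker names.
#' @export
synthetic_marker_set <- function(seed = 8471L) {
  names <- default_marker_names()
  lens <- 100L + (seq_along(names) * 11L) %% 181L
  seqs <- with_seed(seed, vapply(lens, function(L)
    paste(sample_residues(L), collapse = ""), ""))
  fasta_frame(names, rep("synthetic representative", length(names)),
              seqs, NULL)
}

#' Single-copy marker inventory of a proteome
#'
#' Each proteome protein is aligned against every marker representative;
#' proteins whose best marker hit (top bitscore, e-value at or below the
#' cutoff) is a given marker count toward that marker's copy number. Each
#' protein is counted at most once.
#'
#' @param proteome protein data frame from [read_fasta()].
#' @param marker_set marker representative data frame (default the bundled
#'   synthetic set).
#' @param scheme a [scoring_scheme()].
#' @param max_evalue e-value cutoff (default 1e-5).
#' @return Named integer vector of copy numbers, one per marker.
#' @export
marker_inventory <- function(proteome, marker_set = synthetic_marker_set(),
                             scheme = scoring_scheme(), max_evalue = 1e-5) {
  stopifnot(nrow(proteome) > 0)
  scores <- .sw_score_block(proteome$sequence, marker_set$sequence,
                            scheme$matrix, scheme$gap_open, scheme$gap_extend)
  db_len <- sum(nchar(marker_set$sequence))
  ev <- scheme$k_const * nchar(proteome$sequence) * db_len *
    exp(-scheme$lambda * scores)
  copies <- setNames(integer(nrow(marker_set)), marker_set$id)
  for (i in seq_len(nrow(proteome))) {
    ok <- which(ev[i, ] <= max_evalue & scores[i, ] > 0)
    if (length(ok) == 0L) next
    best <- ok[order(-scores[i, ok], marker_set$id[ok])][1]
    copies[best] <- copies[best] + 1L
  }
  copies
}

#' Load a scaffold linkage table
#'
#' Two-column TSV of scaffold id pairs with established linkage.
#' @param path path to the TSV.
#' @return A data frame with columns `a`, `b`.
#' @export
read_linkage <- function(path) {
  lines <- readLines(path); lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(data.frame(a = character(), b = character()))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("row ", which(lengths(parts) != 2L)[1], " of ", path,
         " does not have 2 fields")
  data.frame(a = vapply(parts, `[`, "", 1), b = vapply(parts, `[`, "", 2))
}

#' Fraction of scaffolds in the largest linkage component
#'
#' @param scaffold_ids character vector of scaffold ids.
#' @param linkage data frame with columns `a`, `b` of linked scaffold pairs.
#' @return Fraction in (0, 1]; a single scaffold gives 1.
#' @export
linked_fraction <- function(scaffold_ids, linkage) {
  if (length(scaffold_ids) == 0L) stop("empty scaffold set")
  bad <- setdiff(c(linkage$a, linkage$b), scaffold_ids)
  if (length(bad))
    stop("linkage references unknown scaffold(s): ",
         paste(unique(bad), collapse = ", "))
  if (length(scaffold_ids) == 1L) return(1)
  g <- igraph::graph_from_data_frame(linkage, directed = FALSE,
                                     vertices = scaffold_ids)
  max(igraph::components(g)$csize) / length(scaffold_ids)
}

#' Grade a genome bin as Complete, Near Complete or Partial
#'
#' Complete: every marker present (copy number at least 1) and linkage
#' established between all scaffolds (linked fraction 1). Near Complete:
#' every marker present and linkage between almost all scaffolds (linked
#' fraction at or above the threshold). Partial: the marker set is
#' incomplete and/or scaffold linkage is lacking.
#'
#' @param inventory named integer vector from [marker_inventory()], over the
#'   full marker set.
#' @param scaffold_ids scaffold ids of the bin (non-empty).
#' @param linkage linked scaffold pair data frame (see [read_linkage()]).
#' @param near_complete_linkage linked-fraction threshold quantifying
#'   "almost all" (default 0.9).
#' @return An object of class `"genome_status"`: list with `status`,
#'   `inventory`, `linked_fraction`, `missing_markers`.
#' @export
classify_status <- function(inventory, scaffold_ids,
                            linkage = data.frame(a = character(),
                                                 b = character()),
                            near_complete_linkage = 0.9) {
  if (length(scaffold_ids) == 0L) stop("empty scaffold set")
  lf <- linked_fraction(scaffold_ids, linkage)
  missing <- names(inventory)[inventory < 1L]
  status <- if (length(missing) == 0L && lf == 1) "Complete"
    else if (length(missing) == 0L && lf >= near_complete_linkage)
      "Near Complete"
    else "Partial"
  structure(list(status = status, inventory = inventory,
                 linked_fraction = lf, missing_markers = missing),
            class = "genome_status")
}

#' @export
print.genome_status <- function(x, ...) {
  cat(sprintf("Genome status: %s (%d/%d markers present, linked fraction %.2f)\n",
              x$status, sum(x$inventory >= 1L), length(x$inventory),
              x$linked_fraction))
  if (length(x$missing_markers))
    cat(" missing:", paste(x$missing_markers, collapse = ", "), "\n")
  invisible(x)
}

#' Assembly statistics for a set of scaffolds
#'
#' Size is the summed scaffold length; percent GC is computed over
#' unambiguous bases only (`100 * (G + C) / (A + C + G + T)`); N50 is the
#' largest length L such that scaffolds of length at least L together cover
#' at least half of the assembly.
#'
#' @param scaffolds nucleotide data frame from [read_fasta()].
#' @param coding_counts optional named integer vector of coding features per
#'   scaffold.
#' @return A list of class `"assembly_stats"`: `size_bp`, `pct_gc`,
#'   `n_scaffolds`, `n50`, `coding_features` (`NA` when counts not given).
#' @export
assembly_stats <- function(scaffolds, coding_counts = NULL) {
  stopifnot(nrow(scaffolds) >= 1L)
  lens <- nchar(scaffolds$sequence)
  dna <- Biostrings::DNAStringSet(gsub("U", "T", scaffolds$sequence,
                                       fixed = TRUE))
  base_tab <- colSums(Biostrings::letterFrequency(
    dna, letters = c("A", "C", "G", "T")))
  coding <- if (is.null(coding_counts)) NA_integer_ else
    sum(coding_counts[scaffolds$id], na.rm = TRUE)
  structure(list(
    size_bp = sum(lens),
    pct_gc = unname(100 * (base_tab["G"] + base_tab["C"]) / sum(base_tab)),
    n_scaffolds = nrow(scaffolds),
    n50 = n50(lens),
    coding_features = coding), class = "assembly_stats")
}

#' N50 of a set of lengths
#'
#' @param lengths positive integer scaffold lengths.
#' @return The largest L such that lengths at least L sum to at least half
#'   the total.
#' @export
n50 <- function(lengths) {
  stopifnot(length(lengths) >= 1L, all(lengths > 0))
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(s) >= sum(s) / 2)[1]]
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "Assembly: %s bp, %.1f%% GC, %d scaffold(s), N50 %s, coding features %s\n",
    format(x$size_bp, big.mark = ","), x$pct_gc, x$n_scaffolds,
    format(x$n50, big.mark = ","),
    ifelse(is.na(x$coding_features), "NA",
           format(x$coding_features, big.mark = ","))))
  invisible(x)
}
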