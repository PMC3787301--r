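#' Locate the conserved RnpB motif on scaffolds
#'
#' Finds every exact occurrence of the RNase P RNA motif GAGGAAAGUCC
#' (U treated as T) on both strands, with the surrounding sequence window
#' (truncated at scaffold ends) returned for inspection of the intergenic
#' region. Coordinates are 1-based inclusive on the forward strand for both
#' strands.
#'
#' @param scaffolds nucleotide data frame from [read_fasta()].
#' @param flank_size residues of context kept on each side of the match
#'   (default 500).
#' @param max_mismatch allowed mismatches (default 0, exact search).
#' @return A data frame `scaffold_id`, `start`, `end`, `strand`, `flank`.
#' @export
find_rnpb_loci <- function(scaffolds, flank_size = 500L, max_mismatch = 0L) {
  motif <- "GAGGAAAGTCC"
  if (nrow(scaffolds) == 0L)
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      flank = character()))
  seqs <- gsub("U", "T", toupper(scaffolds$sequence), fixed = TRUE)
  dna <- Biostrings::DNAStringSet(seqs)
  names(dna) <- scaffolds$id
  scan_strand <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, dna,
                                   max.mismatch = as.integer(max_mismatch))
    out <- list()
    for (i in seq_along(m)) {
      r <- m[[i]]
      if (length(r) == 0L) next
      st <- Biostrings::start(r); en <- Biostrings::end(r)
      fs <- pmax(1L, st - flank_size)
      fe <- pmin(nchar(seqs[i]), en + flank_size)
      out[[length(out) + 1L]] <- data.frame(
        scaffold_id = scaffolds$id[i], start = st, end = en,
        strand = strand, flank = substring(seqs[i], fs, fe))
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  fwd <- scan_strand(motif, "+")
  rev <- scan_strand(as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(motif))), "-")
  res <- rbind(fwd, rev)
  if (is.null(res))
    return(data.frame(scaffold_id = character(), start = integer(),
                      end = integer(), strand = character(),
                      flank = character()))
  res <- res[order(res$scaffold_id, res$start, res$strand), ]
  rownames(res) <- NULL
  res
}

#' Extract the TLR5 recognition region of a flagellin
#'
#' Globally aligns a flagellin protein to a reference flagellin (BLOSUM62,
#' affine gaps 11/1) and returns the query columns aligned to reference
#' residues 88-103 (reference coordinates), the span governing Toll-like
#' receptor 5 recognition. No recognized/unrecognized call is made; the
#' region is emitted for visual inspection.
#'
#' @param query flagellin protein sequence (string) or one-row data frame
#'   from [read_fasta()].
#' @param reference reference flagellin sequence (string or one-row data
#'   frame); must be at least `ref_end` residues long.
#' @param ref_start,ref_end reference coordinates of the region (defaults
#'   88 and 103).
#' @param scheme a [scoring_scheme()] (its matrix and gap penalties are
#'   used).
#' @return A list of class `"tlr5_region"` with `id`, `region` (query
#'   characters, `-` where the query has a gap), `gapped` (`TRUE` if any
#'   reference position in the span aligns to a query gap).
#' @export
extract_tlr5_region <- function(query, reference, ref_start = 88L,
                                ref_end = 103L, scheme = scoring_scheme()) {
  qid <- "query"
  if (is.data.frame(query)) { qid <- query$id[1]; query <- query$sequence[1] }
  if (is.data.frame(reference)) reference <- reference$sequence[1]
  check_protein_seq(query, "query"); check_protein_seq(reference, "reference")
  if (nchar(reference) < ref_end)
    stop("reference shorter than ", ref_end, " residues")
  mat <- scheme$matrix
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(reference),
    substitutionMatrix = mat, gapOpening = scheme$gap_open,
    gapExtension = scheme$gap_extend, type = "global")
  qa <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  ra <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  ref_pos <- cumsum(ra != "-")
  cols <- which(ref_pos >= ref_start & ref_pos <= ref_end & ra != "-")
  # include query insertions strictly inside the span
  span <- seq(min(cols), max(cols))
  region <- paste(qa[span], collapse = "")
  gapped <- any(qa[cols] == "-")
  structure(list(id = qid, region = region, gapped = gapped,
                 ref_start = ref_start, ref_end = ref_end),
            class = "tlr5_region")
}

#' @export
print.tlr5_region <- function(x, ...) {
  cat(sprintf("%s  %s%s\n", x$id, x$region,
              if (x$gapped) "  [gapped]" else ""))
  invisible(x)
}

#' Order TLR5 regions by similarity
#'
#' Deterministic ordering of extracted regions by average-linkage
#' hierarchical clustering on pairwise region identity (Hamming distance on
#' the padded region strings), ties broken by id. The ordering does not
#' depend on input order.
#'
#' @param regions a list of `tlr5_region` objects, or a named character
#'   vector of region strings.
#' @return Character vector of ids in display order.
#' @export
order_by_region_similarity <- function(regions) {
  if (is.list(regions) && length(regions) &&
      inherits(regions[[1]], "tlr5_region")) {
    ids <- vapply(regions, `[[`, "", "id")
    seqs <- vapply(regions, `[[`, "", "region")
  } else {
    ids <- names(regions); seqs <- unname(regions)
  }
  stopifnot(length(ids) >= 1L, !anyDuplicated(ids))
  ord0 <- order(ids)
  ids <- ids[ord0]; seqs <- seqs[ord0]
  if (length(ids) == 1L) return(ids)
  w <- max(nchar(seqs))
  padded <- formatC(seqs, width = -w, flag = "-")
  chars <- strsplit(padded, "")
  n <- length(ids)
  d <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    d[i, j] <- d[j, i] <- mean(chars[[i]] != chars[[j]])
  }
  hc <- hclust(as.dist(d), method = "average")
  ids[order.dendrogram(as.dendrogram(hc))]
}
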