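#' Read a FASTA file of protein or nucleotide records
#'
#' The token before the first whitespace in each header is the record id; the
#' remainder is kept as the description. Sequences are uppercased and
#' validated against the chosen alphabet: the 20 canonical amino acids plus X
#' for proteins, `A/C/G/T/N` plus IUPAC ambiguity codes for nucleotides.
#' Records with characters outside the alphabet, empty sequences or duplicate
#' ids raise an error naming the offending record; nothing is silently
#' dropped.
#'
#' @param path path to a FASTA file.
#' @param type `"protein"` or `"nucleotide"`; `"auto"` guesses from residue
#'   composition.
#' @param genome_id optional genome label stored in a `genome_id` column.
#' @return A data frame with columns `id`, `description`, `sequence` (and
#'   `genome_id` when given), one row per record in file order. An empty file
#'   yields an empty data frame with a warning.
#' @export
read_fasta <- function(path, type = c("auto", "protein", "nucleotide"),
                       genome_id = NULL) {
  type <- match.arg(type)
  if (!file.exists(path)) stop("no such file: ", path)
  if (file.size(path) == 0L || !any(grepl("^>", readLines(path, n = 1000L)))) {
    if (length(readLines(path)) > 0L)
      stop("malformed FASTA (no '>' header found): ", path)
    warning("empty FASTA file: ", path)
    return(fasta_frame(character(), character(), character(), genome_id))
  }
  set <- Biostrings::readBStringSet(path)
  headers <- names(set)
  seqs <- toupper(as.character(set))
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers),
                 sub("^\\S+\\s+", "", headers), "")
  if (any(nchar(ids) == 0L))
    stop("record ", which(nchar(ids) == 0L)[1], " in ", path,
         " has an empty header")
  if (any(nchar(seqs) == 0L))
    stop("empty sequence for record '", ids[nchar(seqs) == 0L][1], "' in ",
         path)
  if (anyDuplicated(ids))
    stop("duplicate record id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (type == "auto") {
    acgt <- vapply(seqs, function(s)
      mean(strsplit(s, "")[[1]] %in% c("A", "C", "G", "T", "N", "U")), 0)
    type <- if (mean(acgt) > 0.9) "nucleotide" else "protein"
  }
  alphabet <- if (type == "protein") protein_alphabet() else
    c("A", "C", "G", "T", "U", "N", "R", "Y", "S", "W", "K", "M",
      "B", "D", "H", "V")
  for (i in seq_along(seqs)) {
    bad <- setdiff(strsplit(seqs[i], "")[[1]], alphabet)
    if (length(bad))
      stop("record '", ids[i], "' in ", path, " contains characters outside ",
           "the ", type, " alphabet: ", paste(unique(bad), collapse = ", "))
  }
  fasta_frame(ids, desc, seqs, genome_id)
}

fasta_frame <- function(ids, desc, seqs, genome_id) {
  df <- data.frame(id = ids, description = desc, sequence = unname(seqs),
                   stringsAsFactors = FALSE)
  if (!is.null(genome_id)) df$genome_id <- genome_id
  df
}

#' Write records to a FASTA file
#'
#' @param records a data frame with `id`, `sequence` and optionally
#'   `description` columns (as returned by [read_fasta()]).
#' @param path output path.
#' @param width residues per sequence line.
#' @return The path, invisibly.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- records$id[i]
    if (!is.null(records$description) && nzchar(records$description[i]))
      hdr <- paste(hdr, records$description[i])
    writeLines(paste0(">", hdr), con)
    s <- records$sequence[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

hit_table_columns <- c("query_id", "subject_id", "pident", "length",
                       "mismatch", "gapopen", "qstart", "qend", "sstart",
                       "send", "evalue", "bitscore")

#' Read a 12-column tabular hit file
#'
#' Tab-separated, one hit per row, fields in the standard order: query id,
#' subject id, percent identity, alignment length (gapped columns),
#' mismatches, gap openings, query start/end, subject start/end, e-value,
#' bitscore. Rows with the wrong field count or non-numeric numeric fields
#' raise an error with the row index.
#'
#' @param path path to the hit file.
#' @return A data frame with the columns named above, in row order. An empty
#'   file yields an empty table.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) return(empty_hit_table())
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 12L))
    stop("row ", which(nf != 12L)[1], " of ", path, " has ",
         nf[nf != 12L][1], " fields (12 expected)")
  m <- matrix(unlist(parts), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad_row <- which(apply(is.na(num), 1, any))[1]
    stop("row ", bad_row, " of ", path, " has a non-numeric numeric field")
  }
  hits <- data.frame(query_id = m[, 1], subject_id = m[, 2],
                     pident = num[, 1], length = as.integer(num[, 2]),
                     mismatch = as.integer(num[, 3]),
                     gapopen = as.integer(num[, 4]),
                     qstart = as.integer(num[, 5]), qend = as.integer(num[, 6]),
                     sstart = as.integer(num[, 7]), send = as.integer(num[, 8]),
                     evalue = num[, 9], bitscore = num[, 10])
  validate_hits(hits)
  hits
}

validate_hits <- function(hits) {
  with(hits, {
    if (any(pident < 0 | pident > 100)) stop("pident outside [0, 100]")
    if (any(length < 1)) stop("alignment length < 1")
    if (any(evalue < 0)) stop("negative e-value")
    if (any(qend < qstart) || any(send < sstart))
      stop("alignment end before start")
  })
  invisible(hits)
}

#' Write hits to the 12-column tabular format
#'
#' Percent identity and bitscore are written with one decimal, the e-value in
#' scientific notation; a write/read round trip reproduces all fields at that
#' printed precision.
#'
#' @param hits a hit table data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_hit_table <- function(hits, path) {
  lines <- sprintf("%s\t%s\t%.1f\t%d\t%d\t%d\t%d\t%d\t%d\t%d\t%.2e\t%.1f",
                   hits$query_id, hits$subject_id, hits$pident, hits$length,
                   hits$mismatch, hits$gapopen, hits$qstart, hits$qend,
                   hits$sstart, hits$send, hits$evalue, hits$bitscore)
  writeLines(lines, path)
  invisible(path)
}

#' Load a subject-to-phylum taxonomy map
#'
#' Two-column tab-separated file: subject id, phylum name. The map must be
#' total over the reference set it describes; duplicate subject ids are
#' rejected.
#'
#' @param path path to the TSV file.
#' @return A named character vector mapping subject id to phylum.
#' @export
load_taxonomy_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) {
    warning("empty taxonomy file: ", path)
    return(setNames(character(), character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) != 2L))
    stop("row ", which(lengths(parts) != 2L)[1], " of ", path,
         " does not have 2 fields")
  ids <- vapply(parts, `[`, "", 1)
  phy <- vapply(parts, `[`, "", 2)
  if (anyDuplicated(ids))
    stop("duplicate subject id(s) in taxonomy: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (any(!nzchar(phy))) stop("empty phylum name for: ", ids[!nzchar(phy)][1])
  setNames(phy, ids)
}

#' Write a taxonomy map to TSV
#' @param taxonomy named character vector (subject id to phylum).
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_taxonomy_map <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy), taxonomy, sep = "\t"), path)
  invisible(path)
}
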