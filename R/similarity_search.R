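#' Protein scoring scheme
#'
#' Bundles the substitution matrix, affine gap penalties and Karlin-Altschul
#' statistical parameters used by the aligner. Defaults mirror the standard
#' protein search configuration: BLOSUM62, gap open 11, gap extend 1, and the
#' gapped parameters lambda = 0.267, K = 0.041 for that penalty combination.
#' A gap of length L costs `gap_open + L * gap_extend`.
#'
#' @param matrix substitution matrix name (currently only `"BLOSUM62"`) or a
#'   symmetric integer matrix with single-letter dimnames.
#' @param gap_open positive integer gap opening penalty.
#' @param gap_extend positive integer gap extension penalty; must not exceed
#'   `gap_open`.
#' @param lambda positive Karlin-Altschul scale parameter.
#' @param k_const positive Karlin-Altschul K constant.
#' @return An object of class `"scoring_scheme"`.
#' @examples
#' sc <- scoring_scheme()
#' sc$matrix["A", "A"]
#' @export
scoring_scheme <- function(matrix = "BLOSUM62", gap_open = 11L,
                           gap_extend = 1L, lambda = 0.267, k_const = 0.041) {
  if (is.character(matrix)) {
    if (!identical(matrix, "BLOSUM62"))
      stop("unknown matrix name: ", matrix)
    name <- matrix
    matrix <- blosum62_matrix()
  } else {
    name <- "custom"
    matrix <- as.matrix(matrix)
  }
  if (!isTRUE(all.equal(matrix, t(matrix))))
    stop("substitution matrix must be symmetric")
  gap_open <- as.integer(gap_open); gap_extend <- as.integer(gap_extend)
  stopifnot(gap_open > 0L, gap_extend > 0L, gap_extend <= gap_open,
            lambda > 0, k_const > 0)
  structure(list(matrix_name = name, matrix = matrix, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, k_const = k_const),
            class = "scoring_scheme")
}

#' @export
print.scoring_scheme <- function(x, ...) {
  cat(sprintf("Scoring scheme: %s, gap open/extend %d/%d, lambda %.3f, K %.3f\n",
              x$matrix_name, x$gap_open, x$gap_extend, x$lambda, x$k_const))
  invisible(x)
}

# BLOSUM62 restricted to the accepted protein alphabet (20 residues + X).
blosum62_matrix <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62[protein_alphabet(), protein_alphabet()]
    }
    cache
  }
})

protein_alphabet <- function() {
  c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M", "F",
    "P", "S", "T", "W", "Y", "V", "X")
}

#' Optimal local protein alignment
#'
#' Smith-Waterman local alignment with affine gap penalties and a
#' deterministic traceback (ties resolved diagonal, then up, then left).
#' Alignment length counts gapped columns, so percent identity is computed
#' over the gapped length, matching the tabular hit convention.
#'
#' @param a,b protein sequences (single strings over the 20 canonical amino
#'   acids plus X).
#' @param scheme a [scoring_scheme()].
#' @return An object of class `"sw_alignment"`: a list with `score`,
#'   `bitscore`, `qstart`, `qend`, `sstart`, `send`, `length`, `identical`,
#'   `mismatch`, `gapopen`, `pident` and the two aligned strings. A pair with
#'   no positive-scoring local alignment yields score 0 and length 0.
#' @examples
#' aln <- smith_waterman("MKVLA", "MKVLA")
#' aln$pident
#' @export
smith_waterman <- function(a, b, scheme = scoring_scheme()) {
  check_protein_seq(a, "a"); check_protein_seq(b, "b")
  res <- .sw_traceback(a, b, scheme$matrix, scheme$gap_open,
                       scheme$gap_extend)
  res$bitscore <- bit_score(res$score, scheme)
  res$pident <- if (res$length > 0) 100 * res$identical / res$length else NA_real_
  structure(res, class = "sw_alignment")
}

check_protein_seq <- function(x, what) {
  if (!is.character(x) || length(x) != 1L || is.na(x) || nchar(x) == 0L)
    stop("sequence '", what, "' must be a single non-empty string")
  bad <- setdiff(strsplit(x, "")[[1]], protein_alphabet())
  if (length(bad))
    stop("sequence '", what, "' contains characters outside the protein ",
         "alphabet: ", paste(unique(bad), collapse = ", "))
  invisible(TRUE)
}

#' @export
print.sw_alignment <- function(x, ...) {
  cat(sprintf("Local alignment: score %d (%.1f bits), length %d, %.1f%% identity\n",
              x$score, x$bitscore, x$length,
              ifelse(is.na(x$pident), 0, x$pident)))
  if (x$length > 0) {
    cat(" query  ", x$query_aligned, "\n", sep = "")
    cat(" sbjct  ", x$subject_aligned, "\n", sep = "")
  }
  invisible(x)
}

#' Bit score from a raw alignment score
#'
#' `bitscore = (lambda * raw - ln K) / ln 2`, monotone increasing in the raw
#' score.
#'
#' @param raw_score raw alignment score(s).
#' @inheritParams smith_waterman
#' @return Numeric bit score(s).
#' @export
bit_score <- function(raw_score, scheme = scoring_scheme()) {
  (scheme$lambda * raw_score - log(scheme$k_const)) / log(2)
}

#' Expectation value for a raw alignment score
#'
#' Karlin-Altschul expectation `E = K * m * n * exp(-lambda * raw)` for query
#' length `m` against a database of `n` total residues.
#'
#' @inheritParams bit_score
#' @param query_len query length in residues (m).
#' @param db_len total residues in the searched subject set (n).
#' @return Numeric e-value(s), decreasing in the raw score and linear in
#'   `m * n`.
#' @export
evalue_score <- function(raw_score, query_len, db_len,
                         scheme = scoring_scheme()) {
  stopifnot(all(query_len > 0), all(db_len > 0))
  scheme$k_const * query_len * db_len * exp(-scheme$lambda * raw_score)
}

#' All-vs-all protein similarity search
#'
#' Aligns every query against every subject with [smith_waterman()] and
#' returns hits passing the e-value cutoff as a standard 12-column hit table.
#' The database length used for e-values is the total residue count of the
#' subject set. Within each query, hits are sorted by bitscore (descending),
#' then e-value (ascending), then subject id.
#'
#' @param queries,subjects protein sets as returned by [read_fasta()] (data
#'   frames with `id` and `sequence` columns).
#' @inheritParams smith_waterman
#' @param max_evalue report only hits with e-value at or below this cutoff.
#' @return A hit table data frame (see [read_hit_table()] for the columns).
#' @export
search_proteins <- function(queries, subjects, scheme = scoring_scheme(),
                            max_evalue = 1e-5) {
  stopifnot(nrow(queries) > 0, nrow(subjects) > 0)
  db_len <- sum(nchar(subjects$sequence))
  scores <- .sw_score_block(queries$sequence, subjects$sequence,
                            scheme$matrix, scheme$gap_open, scheme$gap_extend)
  qlen <- nchar(queries$sequence)
  ev <- scheme$k_const * outer(qlen, rep(db_len, nrow(subjects))) *
    exp(-scheme$lambda * scores)
  keep <- which(ev <= max_evalue & scores > 0, arr.ind = TRUE)
  if (nrow(keep) == 0L) return(empty_hit_table())
  rows <- lapply(seq_len(nrow(keep)), function(r) {
    i <- keep[r, 1]; j <- keep[r, 2]
    tb <- .sw_traceback(queries$sequence[i], subjects$sequence[j],
                        scheme$matrix, scheme$gap_open, scheme$gap_extend)
    data.frame(query_id = queries$id[i], subject_id = subjects$id[j],
               pident = 100 * tb$identical / tb$length, length = tb$length,
               mismatch = tb$mismatch, gapopen = tb$gapopen,
               qstart = tb$qstart, qend = tb$qend, sstart = tb$sstart,
               send = tb$send, evalue = ev[i, j],
               bitscore = bit_score(tb$score, scheme))
  })
  hits <- do.call(rbind, rows)
  # stable sort: query file order, then bitscore desc, evalue asc, subject id
  qord <- match(hits$query_id, queries$id)
  hits <- hits[order(qord, -hits$bitscore, hits$evalue, hits$subject_id), ]
  rownames(hits) <- NULL
  hits
}

empty_hit_table <- function() {
  data.frame(query_id = character(), subject_id = character(),
             pident = numeric(), length = integer(), mismatch = integer(),
             gapopen = integer(), qstart = integer(), qend = integer(),
             sstart = integer(), send = integer(), evalue = numeric(),
             bitscore = numeric())
}
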