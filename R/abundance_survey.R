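#' Filter 16S read hits by percent identity
#'
#' Retains hits at or above the identity threshold (inclusive, default 97)
#' and reduces to one assignment per read: the retained hit with the highest
#' bitscore (ties by e-value then subject id).
#'
#' @param hits read-vs-reference hit table (query ids are read ids).
#' @param min_pident identity threshold in percent (default 97).
#' @return A hit table with one row per assigned read.
#' @export
filter_survey_hits <- function(hits, min_pident = 97) {
  hits <- hits[hits$pident >= min_pident, , drop = FALSE]
  if (nrow(hits) == 0L) return(hits)
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[ord, ]
  h <- h[!duplicated(h$query_id), ]
  rownames(h) <- NULL
  h
}

#' Tally target reads per sample
#'
#' Counts assigned reads per sample and computes the relative abundance in
#' percent and its log10. Read ids follow the QIIME-style convention
#' `sampleID_serial`: the sample id is the part before the last underscore.
#'
#' @param assignments filtered hit table from [filter_survey_hits()] (one
#'   row per read).
#' @param totals data frame `sample_id`, `total_reads` covering every sample
#'   that appears in the assignments.
#' @param types data frame `sample_id`, `sample_type`.
#' @return A data frame of class `"sample_tally"`: `sample_id`,
#'   `sample_type`, `total_reads`, `target_reads`, `rel_abundance_pct`,
#'   `log10_pct` (`NA` when no target reads). One row per sample in
#'   `totals`, including zero-count samples.
#' @export
tally_survey <- function(assignments, totals, types) {
  read_sample <- sub("_[^_]*$", "", assignments$query_id)
  missing <- setdiff(unique(read_sample), totals$sample_id)
  if (length(missing))
    stop("no total read count for sample(s): ",
         paste(missing, collapse = ", "))
  counts <- table(factor(read_sample, levels = totals$sample_id))
  out <- data.frame(
    sample_id = totals$sample_id,
    sample_type = types$sample_type[match(totals$sample_id, types$sample_id)],
    total_reads = totals$total_reads,
    target_reads = as.integer(counts))
  if (anyNA(out$sample_type))
    stop("no sample type for: ",
         paste(out$sample_id[is.na(out$sample_type)], collapse = ", "))
  stopifnot(all(out$target_reads <= out$total_reads))
  out$rel_abundance_pct <- 100 * out$target_reads / out$total_reads
  out$log10_pct <- ifelse(out$target_reads > 0,
                          log10(out$rel_abundance_pct), NA_real_)
  class(out) <- c("sample_tally", "data.frame")
  out
}

#' Apply the survey plotting filters
#'
#' Drops samples with zero target reads, then drops sample types whose
#' summed target reads fall below the minimum (default 5), and returns the
#' plotting table of log10-transformed relative abundances
#' (log10 of percent, so 0.1 percent maps to -1).
#'
#' @param tallies a [tally_survey()] result.
#' @param min_type_reads minimum summed target reads per sample type
#'   (default 5).
#' @return A data frame `sample_type`, `sample_id`, `log10_pct` — a subset
#'   of the input rows.
#' @export
group_filter <- function(tallies, min_type_reads = 5L) {
  keep <- tallies[tallies$target_reads > 0, , drop = FALSE]
  type_sums <- tapply(keep$target_reads, keep$sample_type, sum)
  good_types <- names(type_sums)[type_sums >= min_type_reads]
  keep <- keep[keep$sample_type %in% good_types, , drop = FALSE]
  out <- data.frame(sample_type = keep$sample_type,
                    sample_id = keep$sample_id,
                    log10_pct = keep$log10_pct)
  rownames(out) <- NULL
  out
}

#' Merge similar sample types
#'
#' Editorial regrouping (e.g. forest soil, grassland soil, shrubland all to
#' "soil") driven by a user-supplied map; types absent from the map are kept
#' unchanged.
#'
#' @param tallies a [tally_survey()] result.
#' @param type_map data frame with columns `from`, `to` (or a named
#'   character vector, names = original types).
#' @return The tallies with `sample_type` rewritten.
#' @export
merge_sample_types <- function(tallies, type_map) {
  if (is.data.frame(type_map))
    type_map <- setNames(type_map$to, type_map$from)
  hit <- tallies$sample_type %in% names(type_map)
  tallies$sample_type[hit] <- unname(type_map[tallies$sample_type[hit]])
  tallies
}

#' Two-group comparison of abundance values
#'
#' Two-tailed Student t test with pooled variance by default; set
#' `welch = TRUE` for unequal variances.
#'
#' @param values_a,values_b numeric vectors (each of length at least 2).
#' @param welch use the Welch correction (default `FALSE`).
#' @return A list with `t_statistic`, `p_two_tailed`, `df`.
#' @export
compare_two_groups <- function(values_a, values_b, welch = FALSE) {
  if (length(values_a) < 2L || length(values_b) < 2L)
    stop("each group needs at least 2 values")
  if (stats::sd(c(values_a, values_b)) == 0)
    stop("degenerate input: all values identical")
  tt <- t.test(values_a, values_b, var.equal = !welch,
               alternative = "two.sided")
  list(t_statistic = unname(tt$statistic), p_two_tailed = tt$p.value,
       df = unname(tt$parameter))
}
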