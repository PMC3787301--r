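#' Voting configuration for phylum assignment
#'
#' @param evalue_cut retain reference hits with e-value at or below this
#'   (default 1e-5).
#' @param margin the top hit wins outright when its identical-positions count
#'   is at least `(1 + margin)` times the runner-up's (default 0.05, the
#'   "at least 5 percent more" rule); the boundary is inclusive.
#' @param multiple_threshold a cluster is called "Multiple" when at least
#'   this many member genes are themselves "Multiple" (default 2).
#' @param collapse_same_phylum if `TRUE`, two top hits that cannot be
#'   separated by the margin but share a phylum yield that phylum rather
#'   than "Multiple" (default `FALSE`, the literal rule).
#' @return An object of class `"voting_config"`.
#' @export
voting_config <- function(evalue_cut = 1e-5, margin = 0.05,
                          multiple_threshold = 2L,
                          collapse_same_phylum = FALSE) {
  stopifnot(evalue_cut > 0, margin >= 0, multiple_threshold >= 1L)
  structure(list(evalue_cut = evalue_cut, margin = margin,
                 multiple_threshold = as.integer(multiple_threshold),
                 collapse_same_phylum = isTRUE(collapse_same_phylum)),
            class = "voting_config")
}

#' Identical positions of an alignment
#'
#' The per-alignment evidence score used to compare a gene's top two
#' reference hits: alignment length times percent identity (divided by 100),
#' i.e. the number of identical aligned columns.
#'
#' @param hits a hit table (or any data frame with `length` and `pident`).
#' @return Numeric vector of identical-position counts.
#' @examples
#' identical_positions(data.frame(length = 100, pident = 97)) # 97
#' @export
identical_positions <- function(hits) {
  hits$length * hits$pident / 100
}

#' Assign a phylum to one gene from its reference hits
#'
#' Hits are filtered to the e-value cutoff and ranked by bitscore
#' (descending; ties by e-value then subject id). With no retained hit the
#' gene is "No hit"; with exactly one, that hit's phylum. Otherwise the top
#' two are compared by identical positions: the top hit wins iff
#' `IP1 >= IP2 * (1 + margin)` (inclusive); otherwise the gene is "Multiple"
#' (unless `collapse_same_phylum` and both top hits share a phylum).
#'
#' @param gene_id the gene's id (stored in the result).
#' @param hits this gene's reference hit table.
#' @param taxonomy named character vector, subject id to phylum, covering
#'   every retained subject.
#' @param cfg a [voting_config()].
#' @return A list of class `"gene_taxon_assignment"` with `gene_id`, `label`,
#'   `top_hits` (up to two rows) and `identical_positions`.
#' @export
assign_gene_phylum <- function(gene_id, hits, taxonomy,
                               cfg = voting_config()) {
  hits <- hits[hits$evalue <= cfg$evalue_cut, , drop = FALSE]
  if (nrow(hits) == 0L)
    return(structure(list(gene_id = gene_id, label = "No hit",
                          top_hits = hits, identical_positions = numeric()),
                     class = "gene_taxon_assignment"))
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  top <- hits[ord, , drop = FALSE][seq_len(min(2L, nrow(hits))), ,
                                   drop = FALSE]
  miss <- setdiff(top$subject_id, names(taxonomy))
  if (length(miss))
    stop("subject(s) missing from taxonomy: ", paste(miss, collapse = ", "))
  ip <- identical_positions(top)
  if (nrow(top) == 1L) {
    label <- unname(taxonomy[top$subject_id])
  } else if (ip[1] >= ip[2] * (1 + cfg$margin)) {
    label <- unname(taxonomy[top$subject_id[1]])
  } else if (cfg$collapse_same_phylum &&
             taxonomy[top$subject_id[1]] == taxonomy[top$subject_id[2]]) {
    label <- unname(taxonomy[top$subject_id[1]])
  } else {
    label <- "Multiple"
  }
  structure(list(gene_id = gene_id, label = label, top_hits = top,
                 identical_positions = ip),
            class = "gene_taxon_assignment")
}

#' Majority-vote phylum for a cluster from its member gene labels
#'
#' All members "No hit" gives "No hit". At least `multiple_threshold`
#' members "Multiple" gives "Multiple". Otherwise phylum labels are counted
#' (ignoring "No hit" and "Multiple"): a unique plurality wins; a tied
#' plurality gives "Multiple".
#'
#' @param labels character vector of member gene labels (phylum names,
#'   "Multiple" or "No hit"); one per cluster member.
#' @param cfg a [voting_config()].
#' @return A single label string.
#' @export
assign_cog_phylum <- function(labels, cfg = voting_config()) {
  if (length(labels) == 0L) stop("empty label list")
  if (all(labels == "No hit")) return("No hit")
  if (sum(labels == "Multiple") >= cfg$multiple_threshold) return("Multiple")
  phyla <- labels[!labels %in% c("No hit", "Multiple")]
  if (length(phyla) == 0L) return("Multiple")
  tab <- table(phyla)
  winners <- names(tab)[tab == max(tab)]
  if (length(winners) == 1L) winners else "Multiple"
}

#' Assign phyla to every cluster
#'
#' Convenience wrapper: per-gene assignment for each cluster member followed
#' by the majority vote.
#'
#' @param clusters a `cog_clusters` data frame from [form_clusters()].
#' @param hits reference hit table for all member genes (query ids are gene
#'   ids).
#' @param taxonomy named character vector, subject id to phylum.
#' @param cfg a [voting_config()].
#' @return A data frame with `cluster_id`, one label column per genome
#'   (suffix `_label`), and the final `label`.
#' @export
assign_cog_taxa <- function(clusters, hits, taxonomy, cfg = voting_config()) {
  genomes <- setdiff(names(clusters), "cluster_id")
  by_gene <- split(hits, hits$query_id)
  gene_label <- function(g) {
    h <- by_gene[[g]]
    if (is.null(h)) h <- empty_hit_table()
    assign_gene_phylum(g, h, taxonomy, cfg)$label
  }
  lab <- lapply(genomes, function(gn)
    vapply(clusters[[gn]], gene_label, "", USE.NAMES = FALSE))
  names(lab) <- paste0(genomes, "_label")
  final <- vapply(seq_len(nrow(clusters)), function(i)
    assign_cog_phylum(vapply(lab, `[`, "", i), cfg), "")
  cbind(data.frame(cluster_id = clusters$cluster_id), as.data.frame(lab),
        data.frame(label = final))
}

#' Tabulate cluster label counts and fractions
#'
#' @param labels character vector of cluster labels.
#' @return A data frame `label`, `count`, `fraction` (fractions sum to 1),
#'   sorted by count descending then label.
#' @export
summarize_phylum_fractions <- function(labels) {
  stopifnot(length(labels) >= 1L)
  tab <- table(labels)
  out <- data.frame(label = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / length(labels))
  out[order(-out$count, out$label), , drop = FALSE] -> out
  rownames(out) <- NULL
  out
}
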