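#' Load a KEGG Orthology mapping bundle
#'
#' Three tab-separated files: `gene2ko.tsv` (reference gene id, KO id),
#' `ko2pathway.tsv` (KO id, pathway id; a KO may appear on several rows or on
#' none), and `pathway2category.tsv` (pathway id, category name). Every
#' pathway referenced by `ko2pathway` must have a category.
#'
#' @param dir directory containing the three files, or `NULL` to pass paths
#'   explicitly.
#' @param gene2ko,ko2pathway,pathway2category explicit file paths (override
#'   `dir`).
#' @return A list of class `"ko_map"` with `gene2ko` (named character),
#'   `ko2pathway` (list of character vectors keyed by KO) and
#'   `pathway2category` (named character).
#' @export
load_ko_map <- function(dir = NULL, gene2ko = NULL, ko2pathway = NULL,
                        pathway2category = NULL) {
  if (!is.null(dir)) {
    gene2ko <- gene2ko %||% file.path(dir, "gene2ko.tsv")
    ko2pathway <- ko2pathway %||% file.path(dir, "ko2pathway.tsv")
    pathway2category <- pathway2category %||%
      file.path(dir, "pathway2category.tsv")
  }
  read2 <- function(p) {
    lines <- readLines(p); lines <- lines[nzchar(lines)]
    if (length(lines) == 0L) return(data.frame(k = character(),
                                               v = character()))
    parts <- strsplit(lines, "\t", fixed = TRUE)
    if (any(lengths(parts) != 2L))
      stop("row ", which(lengths(parts) != 2L)[1], " of ", p,
           " does not have 2 fields")
    data.frame(k = vapply(parts, `[`, "", 1), v = vapply(parts, `[`, "", 2))
  }
  g2k <- read2(gene2ko)
  if (anyDuplicated(g2k$k))
    stop("duplicate gene id in gene2ko: ",
         g2k$k[duplicated(g2k$k)][1])
  k2p <- read2(ko2pathway)
  p2c <- read2(pathway2category)
  if (anyDuplicated(p2c$k))
    stop("duplicate pathway in pathway2category: ",
         p2c$k[duplicated(p2c$k)][1])
  km <- list(gene2ko = setNames(g2k$v, g2k$k),
             ko2pathway = split(k2p$v, k2p$k),
             pathway2category = setNames(p2c$v, p2c$k))
  missing_cat <- setdiff(unlist(km$ko2pathway), names(km$pathway2category))
  if (length(missing_cat))
    stop("pathway(s) without a category: ",
         paste(unique(missing_cat), collapse = ", "))
  structure(km, class = "ko_map")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign a KO identifier from a representative gene's hits
#'
#' The KO of the top-ranked hit (bitscore descending, ties by e-value then
#' subject id) with e-value at or below the cutoff; `NA` when no hit
#' survives, which downstream becomes the "unknown" category.
#'
#' @param hits the representative gene's hits against the KO-labeled
#'   reference.
#' @param gene2ko named character vector, reference gene id to KO.
#' @param max_evalue e-value cutoff (default 1e-5).
#' @return A KO id string, or `NA_character_` when there are no hits.
#' @export
assign_ko <- function(hits, gene2ko, max_evalue = 1e-5) {
  hits <- hits[hits$evalue <= max_evalue, , drop = FALSE]
  if (nrow(hits) == 0L) return(NA_character_)
  ord <- order(-hits$bitscore, hits$evalue, hits$subject_id)
  subj <- hits$subject_id[ord][1]
  if (!subj %in% names(gene2ko))
    stop("hit subject lacks a KO label: ", subj)
  unname(gene2ko[subj])
}

#' KEGG category for a KO identifier
#'
#' Decision tree: (a) "Undecided" if the KO belongs to no pathway;
#' (b) "Multiple" if its pathways span more than one category; (c) the
#' single shared category otherwise.
#'
#' @param ko KO id (non-missing).
#' @param komap a [load_ko_map()] result.
#' @return A category label string.
#' @export
categorize_ko <- function(ko, komap) {
  stopifnot(!is.na(ko))
  paths <- komap$ko2pathway[[ko]]
  if (is.null(paths) || length(paths) == 0L) return("Undecided")
  missing_cat <- setdiff(paths, names(komap$pathway2category))
  if (length(missing_cat))
    stop("pathway without a category: ", missing_cat[1])
  cats <- unique(unname(komap$pathway2category[paths]))
  if (length(cats) > 1L) "Multiple" else cats
}

#' Assign KOs and categories to every cluster
#'
#' The cluster representative is its member from the first genome in the
#' cluster table's column order (the configured reference genome). Clusters
#' whose representative has no surviving hit get category "unknown".
#'
#' @param clusters a `cog_clusters` data frame.
#' @param ko_hits hit table of representative genes against the KO-labeled
#'   reference.
#' @param komap a [load_ko_map()] result.
#' @param max_evalue e-value cutoff (default 1e-5).
#' @param representative genome column to use (default the first).
#' @return A data frame `cluster_id`, `ko`, `category`.
#' @export
assign_cog_functions <- function(clusters, ko_hits, komap,
                                 max_evalue = 1e-5,
                                 representative = NULL) {
  genomes <- setdiff(names(clusters), "cluster_id")
  representative <- representative %||% genomes[1]
  reps <- clusters[[representative]]
  by_gene <- split(ko_hits, ko_hits$query_id)
  ko <- vapply(reps, function(g) {
    h <- by_gene[[g]]
    if (is.null(h)) h <- empty_hit_table()
    assign_ko(h, komap$gene2ko, max_evalue)
  }, "", USE.NAMES = FALSE)
  category <- ifelse(is.na(ko), "unknown",
                     vapply(ko, function(k)
                       if (is.na(k)) "unknown" else categorize_ko(k, komap),
                       "", USE.NAMES = FALSE))
  data.frame(cluster_id = clusters$cluster_id, ko = ko, category = category)
}

#' Cross-tabulate functional categories by phylum subset
#'
#' For the whole cluster universe ("All") and each requested phylum subset,
#' counts clusters per named category, plus two summary counts: clusters
#' with no functional assignment ("unknown" and "Undecided" together, also
#' reported separately) and clusters with multiple assignments ("Multiple").
#'
#' @param functions a data frame from [assign_cog_functions()].
#' @param taxa a data frame with `cluster_id` and `label` (from
#'   [assign_cog_taxa()]); must cover the same cluster universe.
#' @param subsets phylum labels to tabulate besides "All" (default: every
#'   phylum present).
#' @return A list of class `"functional_summary"`: `categories` (data frame
#'   category x subset counts) and `summary` (data frame subset, n, no
#'   assignment split into unknown/undecided, multiple).
#' @export
functional_summary <- function(functions, taxa, subsets = NULL) {
  if (!setequal(functions$cluster_id, taxa$cluster_id))
    stop("cluster universes differ between functions and taxa")
  lab <- taxa$label[match(functions$cluster_id, taxa$cluster_id)]
  if (is.null(subsets))
    subsets <- sort(setdiff(unique(lab), c("Multiple", "No hit")))
  sel <- c(list(All = rep(TRUE, nrow(functions))),
           setNames(lapply(subsets, function(s) lab == s), subsets))
  cats <- sort(setdiff(unique(functions$category),
                       c("unknown", "Undecided", "Multiple")))
  cat_tab <- sapply(sel, function(s)
    vapply(cats, function(cc) sum(functions$category[s] == cc), 0L))
  cat_tab <- matrix(cat_tab, nrow = length(cats),
                    dimnames = list(cats, names(sel)))
  summ <- data.frame(
    subset = names(sel),
    n = vapply(sel, sum, 0L),
    unknown = vapply(sel, function(s) sum(functions$category[s] == "unknown"), 0L),
    undecided = vapply(sel, function(s) sum(functions$category[s] == "Undecided"), 0L),
    multiple = vapply(sel, function(s) sum(functions$category[s] == "Multiple"), 0L),
    row.names = NULL)
  summ$no_assignment <- summ$unknown + summ$undecided
  structure(list(categories = as.data.frame(cat_tab), summary = summ),
            class = "functional_summary")
}

#' @export
print.functional_summary <- function(x, ...) {
  cat("Functional category counts by subset:\n")
  print(x$categories)
  cat("\nNo/multiple functional assignments:\n")
  print(x$summary[, c("subset", "n", "no_assignment", "multiple")])
  invisible(x)
}
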