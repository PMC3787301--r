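#' Best hit per query for one ordered genome pair
#'
#' Reduces a hit table (queries from one genome, subjects from another) to
#' the single top hit per query: highest bitscore, ties broken by lower
#' e-value, then lexicographic subject id. Queries with no hits are absent.
#'
#' @param hits hit table for one ordered genome pair.
#' @return A named character vector, query id to best subject id; an
#'   attribute `"bitscore"` carries the supporting bitscores.
#' @export
best_hit_map <- function(hits) {
  if (nrow(hits) == 0L)
    return(structure(setNames(character(), character()),
                     bitscore = numeric()))
  ord <- order(hits$query_id, -hits$bitscore, hits$evalue, hits$subject_id)
  h <- hits[ord, ]
  top <- h[!duplicated(h$query_id), ]
  structure(setNames(top$subject_id, top$query_id), bitscore = top$bitscore)
}

#' Reciprocal best hits between two genomes
#'
#' An edge (a, b) exists iff b is a's best hit and a is b's best hit.
#'
#' @param map_ab,map_ba best-hit maps for the two directions of one genome
#'   pair, from [best_hit_map()].
#' @return A data frame with columns `a`, `b`, `weight` (mean of the two
#'   supporting bitscores), one row per reciprocal pair.
#' @export
reciprocal_best_hits <- function(map_ab, map_ba) {
  a <- names(map_ab)
  b <- unname(map_ab)
  mutual <- !is.na(map_ba[b]) & map_ba[b] == a
  mutual[is.na(mutual)] <- FALSE
  w_ab <- attr(map_ab, "bitscore")
  w_ba <- attr(map_ba, "bitscore")
  if (is.null(w_ab)) w_ab <- rep(NA_real_, length(map_ab))
  if (is.null(w_ba)) w_ba <- rep(NA_real_, length(map_ba))
  wa <- w_ab[mutual]
  wb <- w_ba[match(b[mutual], names(map_ba))]
  data.frame(a = a[mutual], b = b[mutual],
             weight = (wa + wb) / 2, row.names = NULL)
}

#' Build the reciprocal-best-hit graph across genomes
#'
#' Takes hit tables for every ordered genome pair and the genome of origin of
#' every protein, computes per-direction best-hit maps, and keeps reciprocal
#' pairs. Nodes are proteins tagged by genome; each node has at most one edge
#' per other genome and no intra-genome edges.
#'
#' @param hits either one combined hit table or a list of per-pair tables;
#'   self-comparisons (query and subject from the same genome) are rejected.
#' @param genome_map named character vector, protein id to genome id, total
#'   over all proteins that may appear in `hits`.
#' @param genomes character vector of genome ids in the run; every ordered
#'   pair must be represented in `hits` (a pair with an empty table is
#'   permitted only if neither direction has hits).
#' @return An object of class `"rbh_graph"`: list with `nodes` (data frame
#'   `id`, `genome`) and `edges` (data frame `a`, `b`, `weight`).
#' @export
build_rbh_graph <- function(hits, genome_map, genomes = NULL) {
  if (is.list(hits) && !is.data.frame(hits)) hits <- do.call(rbind, hits)
  miss <- setdiff(unique(c(hits$query_id, hits$subject_id)), names(genome_map))
  if (length(miss))
    stop("proteins missing from genome_map: ", paste(head(miss, 3),
         collapse = ", "))
  qg <- genome_map[hits$query_id]
  sg <- genome_map[hits$subject_id]
  if (any(qg == sg)) stop("intra-genome (self-comparison) hits are not allowed")
  if (is.null(genomes)) genomes <- sort(unique(genome_map))
  pair_key <- paste(qg, sg, sep = "\r")
  present <- unique(pair_key)
  want <- as.vector(outer(genomes, genomes, paste, sep = "\r"))
  want <- want[rep(genomes, times = length(genomes)) !=
               rep(genomes, each = length(genomes))]
  missing_pairs <- setdiff(want, present)
  if (length(missing_pairs)) {
    pp <- strsplit(missing_pairs, "\r", fixed = TRUE)[[1]]
    stop("no hits for genome pair ", pp[1], " vs ", pp[2],
         "; supply a table for every ordered pair")
  }
  by_pair <- split(hits, pair_key)
  edges <- list()
  for (i in seq_along(genomes)) {
    for (j in seq_along(genomes)) {
      if (i >= j) next
      ab <- paste(genomes[i], genomes[j], sep = "\r")
      ba <- paste(genomes[j], genomes[i], sep = "\r")
      map_ab <- best_hit_map(by_pair[[ab]])
      map_ba <- best_hit_map(by_pair[[ba]])
      edges[[length(edges) + 1L]] <- reciprocal_best_hits(map_ab, map_ba)
    }
  }
  edges <- do.call(rbind, edges)
  nodes <- data.frame(id = names(genome_map), genome = unname(genome_map),
                      row.names = NULL)
  nodes <- nodes[nodes$genome %in% genomes, ]
  structure(list(nodes = nodes, edges = edges, genomes = genomes),
            class = "rbh_graph")
}

#' @export
print.rbh_graph <- function(x, ...) {
  cat(sprintf("RBH graph: %d proteins over %d genomes, %d reciprocal edges\n",
              nrow(x$nodes), length(x$genomes), nrow(x$edges)))
  invisible(x)
}

#' Validate the cluster connectivity rule on one candidate member set
#'
#' A candidate cluster (one protein per genome; four for the canonical
#' four-genome run) is valid iff, in the subgraph induced by its members, at
#' least two members are connected to all other members and every member is
#' connected to at least all-but-one of the others. For G genomes: at least
#' two nodes of degree G-1 and minimum degree G-2.
#'
#' @param members character vector of protein ids, one per genome.
#' @param graph an [build_rbh_graph()] result.
#' @return `TRUE` or `FALSE`.
#' @export
quad_valid <- function(members, graph) {
  g <- graph$nodes$genome[match(members, graph$nodes$id)]
  if (anyNA(g)) stop("member(s) not in graph: ",
                     paste(members[is.na(g)], collapse = ", "))
  G <- length(graph$genomes)
  if (length(members) != G)
    stop("expected one member per genome (", G, " members)")
  if (anyDuplicated(g)) stop("duplicated genome among members")
  e <- graph$edges
  sel <- e$a %in% members & e$b %in% members
  deg <- table(factor(c(e$a[sel], e$b[sel]), levels = members))
  sum(deg == G - 1L) >= 2L && min(deg) >= G - 2L
}

#' Form disjoint ortholog clusters from the RBH graph
#'
#' Within each connected component of the reciprocal-best-hit graph, all
#' one-protein-per-genome subsets of size G (the genome count) are
#' enumerated; those passing [quad_valid()] become candidates. Candidates are
#' accepted greedily by induced edge count (descending), then summed edge
#' bitscore (descending), then lexicographic member ids, subject to members
#' not being reused. Components yielding no valid candidate produce no
#' cluster.
#'
#' @param graph an [build_rbh_graph()] result.
#' @return An object of class `"cog_clusters"`: a data frame with
#'   `cluster_id` plus one member column per genome (in `graph$genomes`
#'   order).
#' @export
form_clusters <- function(graph) {
  genomes <- graph$genomes
  G <- length(genomes)
  empty <- as.data.frame(setNames(
    c(list(character()), rep(list(character()), G)),
    c("cluster_id", genomes)))
  if (nrow(graph$edges) == 0L)
    return(structure(empty, class = c("cog_clusters", "data.frame")))
  ig <- igraph::graph_from_data_frame(
    graph$edges[, c("a", "b")], directed = FALSE,
    vertices = graph$nodes$id)
  comp <- igraph::components(ig)$membership
  ew <- setNames(graph$edges$weight,
                 paste(pmin(graph$edges$a, graph$edges$b),
                       pmax(graph$edges$a, graph$edges$b), sep = "\r"))
  node_genome <- setNames(graph$nodes$genome, graph$nodes$id)
  candidates <- list()
  for (cid in seq_len(max(comp))) {
    ids <- names(comp)[comp == cid]
    if (length(ids) < G) next
    by_gen <- split(ids, factor(node_genome[ids], levels = genomes))
    if (any(lengths(by_gen) == 0L)) next
    grid <- do.call(expand.grid,
                    c(by_gen, list(stringsAsFactors = FALSE)))
    for (r in seq_len(nrow(grid))) {
      members <- as.character(grid[r, ])
      key <- paste(pmin(rep(members, each = G), rep(members, times = G)),
                   pmax(rep(members, each = G), rep(members, times = G)),
                   sep = "\r")
      key <- unique(key[rep(members, each = G) != rep(members, times = G)])
      w <- ew[key]
      n_edges <- sum(!is.na(w))
      present <- key[!is.na(w)]
      ends <- unlist(strsplit(present, "\r", fixed = TRUE))
      degt <- table(factor(ends, levels = members))
      if (!(sum(degt == G - 1L) >= 2L && min(degt) >= G - 2L)) next
      candidates[[length(candidates) + 1L]] <- list(
        members = setNames(members, genomes),
        n_edges = n_edges,
        weight = sum(w, na.rm = TRUE),
        key = paste(sort(members), collapse = "|"))
    }
  }
  if (length(candidates) == 0L)
    return(structure(empty, class = c("cog_clusters", "data.frame")))
  ord <- order(-vapply(candidates, `[[`, 0L, "n_edges"),
               -vapply(candidates, `[[`, 0, "weight"),
               vapply(candidates, `[[`, "", "key"))
  used <- character()
  accepted <- list()
  for (k in ord) {
    mem <- candidates[[k]]$members
    if (any(mem %in% used)) next
    used <- c(used, mem)
    accepted[[length(accepted) + 1L]] <- mem
  }
  out <- as.data.frame(do.call(rbind, accepted), stringsAsFactors = FALSE)
  names(out) <- genomes
  out <- cbind(cluster_id = sprintf("COG%04d", seq_len(nrow(out))), out)
  structure(out, class = c("cog_clusters", "data.frame"))
}

#' @export
print.cog_clusters <- function(x, ...) {
  cat(sprintf("%d ortholog clusters over genomes: %s\n", nrow(x),
              paste(setdiff(names(x), "cluster_id"), collapse = ", ")))
  if (nrow(x) > 0) print.data.frame(head(x, 5))
  if (nrow(x) > 5) cat("...\n")
  invisible(x)
}

#' Write clusters to TSV
#' @param clusters a `cog_clusters` data frame.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_clusters <- function(clusters, path) {
  utils::write.table(clusters, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
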