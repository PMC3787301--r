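# Independent oracles used to validate the package implementations.
# Each is written from the rule definitions directly, in a different style
# from the package code, and stays test-only.

# Plain-R affine-gap local alignment DP (score only), three explicit
# matrices, no rolling arrays. Gap of length L costs go + L * ge.
bf_local_score <- function(a, b, mat, go = 11, ge = 1) {
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  n <- length(A); m <- length(B); NEG <- -1e9
  M <- matrix(0, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap consuming A
  Y <- matrix(NEG, n + 1, m + 1)  # gap consuming B
  best <- 0
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      X[i, j] <- max(M[i - 1, j] - go - ge, X[i - 1, j] - ge)
      Y[i, j] <- max(M[i, j - 1] - go - ge, Y[i, j - 1] - ge)
      M[i, j] <- max(0, M[i - 1, j - 1] + mat[A[i - 1], B[j - 1]],
                     X[i, j], Y[i, j])
      best <- max(best, M[i, j])
    }
  }
  best
}

aa20 <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]

random_protein <- function(n) {
  paste(sample(aa20, n, replace = TRUE), collapse = "")
}

test_blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env(); utils::data("BLOSUM62", package = "Biostrings",
                                  envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

# Degree-condition oracle for the 4-member cluster rule, straight from the
# wording: >= 2 members linked to all three others, every member linked to
# >= 2 others. `edges` is a logical vector over the 6 unordered pairs of
# nodes 1..4 in order (12, 13, 14, 23, 24, 34).
quad_rule_oracle <- function(edges) {
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  deg <- integer(4)
  for (k in which(edges)) {
    deg[pairs[k, 1]] <- deg[pairs[k, 1]] + 1L
    deg[pairs[k, 2]] <- deg[pairs[k, 2]] + 1L
  }
  sum(deg == 3L) >= 2L && all(deg >= 2L)
}

# Build a minimal rbh_graph over 4 one-protein genomes from the same
# 6-pair edge mask, for exercising quad_valid.
quad_graph <- function(edges) {
  ids <- c("a", "b", "c", "d")
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  e <- pairs[edges, , drop = FALSE]
  structure(list(
    nodes = data.frame(id = ids, genome = c("G1", "G2", "G3", "G4")),
    edges = data.frame(a = ids[e[, 1]], b = ids[e[, 2]],
                       weight = rep(100, nrow(e))),
    genomes = c("G1", "G2", "G3", "G4")), class = "rbh_graph")
}

# Truth-table oracle for the cluster-level vote, coded from the quoted
# rules rather than the package's control flow.
cog_vote_oracle <- function(labels, multiple_threshold = 2L) {
  is_phylum <- !labels %in% c("Multiple", "No hit")
  if (!any(labels != "No hit")) return("No hit")
  if (sum(labels == "Multiple") >= multiple_threshold) return("Multiple")
  if (!any(is_phylum)) return("Multiple")
  counts <- table(labels[is_phylum])
  top <- counts[counts == max(counts)]
  if (length(top) > 1L) "Multiple" else names(top)
}

# Rule oracle for the per-gene assignment.
gene_vote_oracle <- function(hits, taxonomy, evalue_cut = 1e-5,
                             margin = 0.05) {
  keep <- hits[hits$evalue <= evalue_cut, , drop = FALSE]
  if (nrow(keep) == 0) return("No hit")
  keep <- keep[order(-keep$bitscore, keep$evalue, keep$subject_id), ,
               drop = FALSE]
  ip <- keep$length * keep$pident / 100
  if (nrow(keep) == 1) return(unname(taxonomy[keep$subject_id[1]]))
  if (ip[1] >= (1 + margin) * ip[2])
    unname(taxonomy[keep$subject_id[1]])
  else "Multiple"
}

# N50 by direct application of the definition: the largest length L among
# the scaffolds such that scaffolds of length >= L cover half the total.
bf_n50 <- function(lengths) {
  total <- sum(lengths)
  cand <- sort(unique(lengths), decreasing = TRUE)
  for (L in cand) if (sum(lengths[lengths >= L]) >= total / 2) return(L)
  min(lengths)
}

# Naive substring scan for motif occurrences on the forward strand.
bf_motif_positions <- function(seq, motif) {
  w <- nchar(motif)
  hits <- integer()
  for (p in seq_len(max(0, nchar(seq) - w + 1)))
    if (substr(seq, p, p + w - 1) == motif) hits <- c(hits, p)
  hits
}

rc_dna <- function(s) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(s, "")[[1]]), collapse = ""))
}

# Random DNA guaranteed free of the RnpB motif on either strand.
rand_dna <- function(n, avoid = "GAGGAAAGTCC") {
  repeat {
    s <- paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
               collapse = "")
    if (!grepl(avoid, s) && !grepl(rc_dna(avoid), s)) return(s)
  }
}
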