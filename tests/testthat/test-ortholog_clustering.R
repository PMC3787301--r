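mk_hits <- function(q, s, bit, ev = 1e-20) {
  n <- max(length(q), length(s), length(bit))
  if (length(q) == 0L) n <- 0L
  data.frame(query_id = rep_len(q, n), subject_id = rep_len(s, n),
             pident = rep_len(90, n), length = rep_len(100, n),
             mismatch = rep_len(10, n), gapopen = rep_len(0, n),
             qstart = rep_len(1, n), qend = rep_len(100, n),
             sstart = rep_len(1, n), send = rep_len(100, n),
             evalue = rep_len(ev, n), bitscore = rep_len(bit, n))
}

test_that("best hit maps pick top bitscore with e-value then id tie-breaks", {
  h <- mk_hits(c("a1", "a1", "a2"), c("b1", "b2", "b1"), c(200, 150, 90))
  m <- best_hit_map(h)
  expect_equal(unname(m[c("a1", "a2")]), c("b1", "b1"))

  tie <- mk_hits(c("a1", "a1"), c("b1", "b2"), c(100, 100),
                 ev = c(1e-10, 1e-20))
  expect_equal(unname(best_hit_map(tie)["a1"]), "b2")
  expect_length(best_hit_map(mk_hits(character(), character(), numeric())), 0L)
})

test_that("reciprocal best hits require mutual agreement", {
  ab <- best_hit_map(mk_hits(c("a1", "a2"), c("b1", "b2"), c(100, 90)))
  ba <- best_hit_map(mk_hits(c("b1", "b2"), c("a1", "a9"), c(100, 90)))
  e <- reciprocal_best_hits(ab, ba)
  expect_equal(nrow(e), 1L)
  expect_equal(e$a, "a1"); expect_equal(e$b, "b1")
  expect_equal(e$weight, 100)
})

test_that("reciprocal best hits equal brute-force pair enumeration", {
  set.seed(11)
  for (k in 1:50) {
    na <- sample(2:6, 1); nb <- sample(2:6, 1)
    as <- sprintf("a%d", 1:na); bs <- sprintf("b%d", 1:nb)
    map_ab <- setNames(sample(bs, na, replace = TRUE), as)
    map_ba <- setNames(sample(as, nb, replace = TRUE), bs)
    attr(map_ab, "bitscore") <- rep(50, na)
    attr(map_ba, "bitscore") <- rep(50, nb)
    got <- reciprocal_best_hits(map_ab, map_ba)
    want <- expand.grid(a = as, b = bs, stringsAsFactors = FALSE)
    want <- want[apply(want, 1, function(r)
      map_ab[[r[1]]] == r[2] && map_ba[[r[2]]] == r[1]), ]
    expect_setequal(paste(got$a, got$b), paste(want$a, want$b))
  }
})

test_that("quad rule matches the degree-condition oracle on all 64 graphs", {
  for (mask in 0:63) {
    edges <- as.logical(bitwAnd(mask, 2^(0:5)))
    g <- quad_graph(edges)
    expect_identical(quad_valid(c("a", "b", "c", "d"), g),
                     quad_rule_oracle(edges),
                     label = sprintf("edge mask %d", mask))
  }
})

test_that("quad rule handles the canonical cases and rejects bad input", {
  expect_true(quad_valid(c("a", "b", "c", "d"), quad_graph(rep(TRUE, 6))))
  # 5 edges, degrees (3,3,2,2)
  expect_true(quad_valid(c("a", "b", "c", "d"),
                         quad_graph(c(TRUE, TRUE, TRUE, TRUE, TRUE, FALSE))))
  # 4-cycle: all degree 2, nobody fully connected
  expect_false(quad_valid(c("a", "b", "c", "d"),
                          quad_graph(c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))))
  g <- quad_graph(rep(TRUE, 6))
  expect_error(quad_valid(c("a", "b", "c"), g), "one member per genome")
  g$nodes$genome[2] <- "G1"
  expect_error(quad_valid(c("a", "b", "c", "d"), g), "duplicated genome")
})

test_that("perfect 1:1 orthologs give disjoint K4 clusters", {
  genomes <- c("G1", "G2", "G3", "G4")
  prots <- expand.grid(g = genomes, f = sprintf("F%d", 1:5),
                       stringsAsFactors = FALSE)
  prots$id <- paste(prots$g, prots$f, sep = "|")
  genome_map <- setNames(prots$g, prots$id)
  hits <- do.call(rbind, lapply(1:4, function(i) do.call(rbind, lapply(1:4,
    function(j) {
      if (i == j) return(NULL)
      q <- prots$id[prots$g == genomes[i]]
      s <- sub(genomes[i], genomes[j], q, fixed = TRUE)
      mk_hits(q, s, 150)
    }))))
  graph <- build_rbh_graph(hits, genome_map, genomes)
  expect_equal(nrow(graph$edges), 6 * 5)
  cl <- form_clusters(graph)
  expect_equal(nrow(cl), 5L)
  for (f in sprintf("F%d", 1:5)) {
    row <- cl[grep(f, cl$G1, fixed = TRUE), ]
    expect_equal(sort(unlist(row[genomes], use.names = FALSE)),
                 sort(paste(genomes, f, sep = "|")))
  }
})

test_that("missing pair tables are reported and degree stays bounded", {
  genome_map <- c(a1 = "G1", b1 = "G2", c1 = "G3")
  hits <- rbind(mk_hits("a1", "b1", 100), mk_hits("b1", "a1", 100))
  expect_error(build_rbh_graph(hits, genome_map, c("G1", "G2", "G3")),
               "pair")
  set.seed(5)
  genomes <- c("G1", "G2", "G3", "G4")
  for (rep in 1:20) {
    prots <- expand.grid(g = genomes, n = 1:3, stringsAsFactors = FALSE)
    prots$id <- sprintf("%s|p%d", prots$g, prots$n)
    gm <- setNames(prots$g, prots$id)
    hits <- do.call(rbind, lapply(seq_len(40), function(k) {
      qi <- sample(prots$id, 1)
      sj <- sample(prots$id[prots$g != gm[qi]], 1)
      mk_hits(qi, sj, runif(1, 50, 200))
    }))
    # ensure every ordered pair is present
    for (i in 1:4) for (j in 1:4) {
      if (i == j) next
      hits <- rbind(hits, mk_hits(paste0(genomes[i], "|p1"),
                                  paste0(genomes[j], "|p1"), 40))
    }
    graph <- build_rbh_graph(hits, gm, genomes)
    deg <- table(c(graph$edges$a, graph$edges$b))
    expect_true(all(deg <= 3))
    cl <- form_clusters(graph)
    if (nrow(cl) > 0) {
      members <- unlist(cl[genomes], use.names = FALSE)
      expect_false(anyDuplicated(members) > 0)
      for (r in seq_len(nrow(cl)))
        expect_true(quad_valid(unlist(cl[r, genomes], use.names = FALSE),
                               graph))
    }
  }
})

test_that("overlapping candidate quads resolve greedily and disjointly", {
  # component of 5 nodes: candidates {a,b,c,d1} (5 edges) and {a,b,c,d2}
  # (K4, 6 edges) share three members; the better-connected one must win
  genomes <- c("G1", "G2", "G3", "G4")
  graph <- structure(list(
    nodes = data.frame(id = c("a", "b", "c", "d1", "d2"),
                       genome = c("G1", "G2", "G3", "G4", "G4")),
    edges = data.frame(
      a = c("a", "a", "b", "a", "b", "a", "b", "c"),
      b = c("b", "c", "c", "d1", "d1", "d2", "d2", "d2"),
      weight = rep(100, 8)),
    genomes = genomes), class = "rbh_graph")
  cl <- form_clusters(graph)
  expect_equal(nrow(cl), 1L)
  expect_equal(unname(unlist(cl[1, genomes])), c("a", "b", "c", "d2"))
})
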