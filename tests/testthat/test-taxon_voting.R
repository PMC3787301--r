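ref_hits <- function(subjects, bits, evs = NULL, lens = 100, pidents = 90) {
  n <- length(subjects)
  data.frame(query_id = rep_len("g", n), subject_id = subjects,
             pident = rep_len(pidents, n), length = rep_len(lens, n),
             mismatch = rep_len(0, n), gapopen = rep_len(0, n),
             qstart = rep_len(1, n),
             qend = rep_len(lens, n), sstart = rep_len(1, n),
             send = rep_len(lens, n),
             evalue = if (is.null(evs)) rep(1e-30, n) else evs,
             bitscore = bits)
}

tax4 <- c(s1 = "Firmicutes", s2 = "Cyanobacteria", s3 = "Firmicutes",
          s4 = "Bacteroidetes")

test_that("identical positions is gapped length times identity", {
  expect_equal(identical_positions(data.frame(length = 100, pident = 97)), 97)
  expect_equal(identical_positions(data.frame(length = 150, pident = 80)), 120)
  expect_equal(identical_positions(data.frame(length = 80, pident = 0)), 0)
})

test_that("the 5 percent margin is inclusive at the boundary", {
  # IP1 = 105, IP2 = 100 -> exactly 5% more -> top phylum wins
  h <- ref_hits(c("s1", "s2"), bits = c(200, 190),
                lens = c(105, 100), pidents = c(100, 100))
  expect_equal(assign_gene_phylum("g", h, tax4)$label, "Firmicutes")
  # IP1 = 104 -> below the margin -> Multiple
  h2 <- ref_hits(c("s1", "s2"), bits = c(200, 190),
                 lens = c(104, 100), pidents = c(100, 100))
  expect_equal(assign_gene_phylum("g", h2, tax4)$label, "Multiple")
  # a hair under the boundary -> Multiple
  h3 <- ref_hits(c("s1", "s2"), bits = c(200, 190),
                 lens = c(105, 100), pidents = c(100 - 1e-3, 100))
  expect_equal(assign_gene_phylum("g", h3, tax4)$label, "Multiple")
})

test_that("e-value filtering, single hits and missing taxonomy behave", {
  h <- ref_hits("s1", 200, evs = 1e-3)
  expect_equal(assign_gene_phylum("g", h, tax4)$label, "No hit")
  one <- ref_hits("s2", 200)
  expect_equal(assign_gene_phylum("g", one, tax4)$label, "Cyanobacteria")
  bad <- ref_hits("sX", 200)
  expect_error(assign_gene_phylum("g", bad, tax4), "sX")
})

test_that("same-phylum collapse is off by default and works when enabled", {
  h <- ref_hits(c("s1", "s3"), bits = c(200, 199),
                lens = c(100, 100), pidents = c(90, 90))
  expect_equal(assign_gene_phylum("g", h, tax4)$label, "Multiple")
  cfg <- voting_config(collapse_same_phylum = TRUE)
  expect_equal(assign_gene_phylum("g", h, tax4, cfg)$label, "Firmicutes")
})

test_that("per-gene assignment matches the rule oracle on random hit sets", {
  set.seed(99)
  subjects <- sprintf("s%d", 1:6)
  taxonomy <- setNames(sample(c("P1", "P2", "P3"), 6, replace = TRUE),
                       subjects)
  for (k in 1:10000) {
    n <- sample(0:5, 1)
    if (n == 0) {
      h <- ref_hits(character(0), numeric(0))
    } else {
      h <- ref_hits(sample(subjects, n), bits = round(runif(n, 30, 60), 1),
                    evs = 10^-sample(c(3, 6, 9, 12), n, replace = TRUE),
                    lens = sample(50:150, n, replace = TRUE),
                    pidents = round(runif(n, 40, 100), 1))
    }
    expect_identical(assign_gene_phylum("g", h, taxonomy)$label,
                     gene_vote_oracle(h, taxonomy),
                     label = sprintf("case %d", k))
  }
})

test_that("cluster vote handles the canonical 4-tuples", {
  expect_equal(assign_cog_phylum(c("F", "F", "C", "No hit")), "F")
  expect_equal(assign_cog_phylum(c("F", "F", "C", "C")), "Multiple")
  expect_equal(assign_cog_phylum(rep("No hit", 4)), "No hit")
  expect_equal(assign_cog_phylum(c("Multiple", "Multiple", "F", "F")),
               "Multiple")
  expect_error(assign_cog_phylum(character(0)), "empty")
})

test_that("cluster vote agrees with the truth-table oracle on all 625 tuples", {
  vocab <- c("P1", "P2", "P3", "Multiple", "No hit")
  grid <- expand.grid(a = vocab, b = vocab, c = vocab, d = vocab,
                      stringsAsFactors = FALSE)
  for (r in seq_len(nrow(grid))) {
    labs <- unlist(grid[r, ], use.names = FALSE)
    expect_identical(assign_cog_phylum(labs), cog_vote_oracle(labs),
                     label = paste(labs, collapse = ","))
  }
})

test_that("cluster vote is permutation invariant and margin is monotone", {
  set.seed(17)
  vocab <- c("P1", "P2", "P3", "Multiple", "No hit")
  for (k in 1:200) {
    labs <- sample(vocab, 4, replace = TRUE)
    expect_identical(assign_cog_phylum(labs),
                     assign_cog_phylum(sample(labs)))
  }
  # raising the margin can only move a gene from a phylum toward Multiple
  subjects <- sprintf("s%d", 1:4)
  taxonomy <- setNames(c("P1", "P2", "P3", "P1"), subjects)
  for (k in 1:200) {
    n <- sample(2:4, 1)
    h <- ref_hits(sample(subjects, n), bits = round(runif(n, 30, 60), 1),
                  lens = sample(50:150, n, replace = TRUE),
                  pidents = round(runif(n, 40, 100), 1))
    lo <- assign_gene_phylum("g", h, taxonomy, voting_config(margin = 0.02))
    hi <- assign_gene_phylum("g", h, taxonomy, voting_config(margin = 0.20))
    if (lo$label == "Multiple") expect_equal(hi$label, "Multiple")
    if (hi$label != "Multiple") expect_equal(lo$label, hi$label)
  }
})

test_that("phylum fractions normalize and count correctly", {
  labs <- c(rep("F", 3), rep("C", 2), rep("No hit", 5))
  tab <- summarize_phylum_fractions(labs)
  expect_equal(sum(tab$fraction), 1, tolerance = 1e-9)
  expect_equal(sum(tab$count), 10L)
  expect_equal(tab$fraction[tab$label == "F"], 0.3)
  single <- summarize_phylum_fractions("F")
  expect_equal(single$fraction, 1)
})
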