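test_that("identity and single-residue alignments score as expected", {
  aln <- smith_waterman("MKVLA", "MKVLA")
  expect_equal(aln$identical, 5L)
  expect_equal(aln$length, 5L)
  expect_equal(aln$pident, 100)
  expect_equal(smith_waterman("A", "A")$score,
               unname(test_blosum62()["A", "A"]))
  expect_error(smith_waterman("", "A"), "non-empty")
  expect_error(smith_waterman("MKB", "MK"), "alphabet")
})

test_that("aligner matches the brute-force DP on random short pairs", {
  set.seed(101)
  mat <- test_blosum62()
  for (k in 1:500) {
    a <- random_protein(sample(1:6, 1))
    b <- random_protein(sample(1:6, 1))
    expect_identical(smith_waterman(a, b)$score,
                     as.integer(bf_local_score(a, b, mat)),
                     label = paste(a, b))
  }
})

test_that("aligner agrees with an independent implementation on longer pairs", {
  set.seed(202)
  mat <- test_blosum62()
  for (k in 1:25) {
    a <- random_protein(sample(30:80, 1))
    b <- random_protein(sample(30:80, 1))
    ours <- smith_waterman(a, b)$score
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(a), Biostrings::AAString(b),
      substitutionMatrix = mat, gapOpening = 11, gapExtension = 1,
      type = "local", scoreOnly = TRUE)
    if (ours > 0) expect_equal(ours, ref)
  }
})

test_that("score is symmetric and monotone under sequence extension", {
  set.seed(303)
  for (k in 1:1000) {
    a <- random_protein(sample(1:12, 1))
    b <- random_protein(sample(1:12, 1))
    expect_identical(smith_waterman(a, b)$score, smith_waterman(b, a)$score)
  }
  set.seed(304)
  for (k in 1:50) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    ext <- paste0(b, random_protein(5))
    expect_gte(smith_waterman(a, ext)$score, smith_waterman(a, b)$score)
  }
})

test_that("bit scores and e-values follow the Karlin-Altschul forms", {
  expect_equal(bit_score(0), -log(0.041) / log(2), tolerance = 1e-12)
  expect_equal(bit_score(0), 4.61, tolerance = 0.01)
  sc2 <- scoring_scheme(lambda = 2 * 0.267)
  expect_equal(bit_score(100, sc2) - bit_score(0, sc2),
               2 * (bit_score(100) - bit_score(0)), tolerance = 1e-9)
  expect_gt(bit_score(101), bit_score(100))

  expect_equal(evalue_score(100, 100, 100),
               0.041 * 1e4 * exp(-0.267 * 100), tolerance = 1e-12)
  expect_equal(evalue_score(50, 100, 400), 2 * evalue_score(50, 100, 200),
               tolerance = 1e-12)
  expect_lt(evalue_score(500, 100, 100), 1e-50)
})

test_that("search ranks an identical subject first and honors the cutoff", {
  set.seed(42)
  q <- data.frame(id = "q1", sequence = random_protein(60))
  subs <- data.frame(id = c("far", "self", "mid"),
                     sequence = c(random_protein(60), q$sequence,
                                  paste0(substr(q$sequence, 1, 40),
                                         random_protein(20))))
  hits <- search_proteins(q, subs, max_evalue = 1e-3)
  expect_equal(hits$subject_id[1], "self")
  expect_true(all(diff(hits$bitscore) <= 0))
  expect_true(all(hits$evalue <= 1e-3))
  none <- search_proteins(q, subs, max_evalue = 0)
  expect_equal(nrow(none), 0L)
})

test_that("search ranking equals an exhaustive alignment of all pairs", {
  set.seed(77)
  qs <- data.frame(id = sprintf("q%d", 1:3),
                   sequence = vapply(1:3, function(i) random_protein(40), ""))
  base <- random_protein(40)
  ss <- data.frame(id = sprintf("s%d", 1:4),
                   sequence = c(qs$sequence[1], base,
                                paste0(substr(qs$sequence[2], 1, 30),
                                       random_protein(10)),
                                random_protein(40)))
  db_len <- sum(nchar(ss$sequence))
  hits <- search_proteins(qs, ss, max_evalue = 10)
  for (i in seq_len(nrow(qs))) {
    exp_scores <- vapply(ss$sequence, function(s)
      smith_waterman(qs$sequence[i], s)$score, 0L)
    exp_ev <- evalue_score(exp_scores, nchar(qs$sequence[i]), db_len)
    want <- ss$id[exp_ev <= 10 & exp_scores > 0]
    got <- hits$subject_id[hits$query_id == qs$id[i]]
    expect_setequal(got, want)
    want_sorted <- want[order(-exp_scores[match(want, ss$id)],
                              exp_ev[match(want, ss$id)], want)]
    expect_equal(got, want_sorted)
  }
})
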