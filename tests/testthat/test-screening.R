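test_that("smith_waterman matches worked examples and dominance", {
  params <- alignment_params()
  a <- smith_waterman("ACD", "ACD", params)
  expect_equal(a$score, 19)  # BLOSUM62 diagonal 4 + 9 + 6
  expect_equal(c(a$q_start, a$q_end, a$t_start, a$t_end), c(1, 3, 1, 3))
  expect_equal(a$length, 3)

  set.seed(61)
  q <- random_protein(15)
  self <- smith_waterman(q, q, params)$score
  for (rep in 1:5)
    expect_gte(self, smith_waterman(q, random_protein(15), params)$score)

  # symmetric substitution matrix -> symmetric score
  for (rep in 1:5) {
    x <- random_protein(12); y <- random_protein(18)
    expect_equal(smith_waterman(x, y, params)$score,
                 smith_waterman(y, x, params)$score)
  }
  expect_error(smith_waterman("", "ACD", params), "empty")
})

test_that("smith_waterman equals the brute-force oracles", {
  params <- alignment_params()
  sub <- params$sub
  set.seed(62)
  for (rep in 1:50) {
    a <- random_protein(sample(5:20, 1))
    b <- random_protein(sample(5:20, 1))
    expect_equal(smith_waterman(a, b, params)$score,
                 oracle_sw(a, b, sub, params$gap_open, params$gap_extend),
                 info = paste(a, b))
  }
  # exhaustive enumeration on tiny instances
  for (rep in 1:8) {
    a <- random_protein(4); b <- random_protein(4)
    expect_equal(smith_waterman(a, b, params)$score,
                 oracle_sw_exhaustive(a, b, sub, params$gap_open,
                                      params$gap_extend),
                 info = paste(a, b))
  }
})

test_that("bit_score applies the Karlin-Altschul transform", {
  params <- alignment_params(lambda = 0.267, K = 0.041)
  expect_equal(bit_score(19, params), 11.93, tolerance = 0.01)
  expect_equal(bit_score(0, params), -log(0.041) / log(2))
  s <- sort(runif(10, 0, 500))
  expect_true(all(diff(bit_score(s, params)) > 0))  # monotone
})

test_that("screen_contigs finds planted genes on either strand", {
  set.seed(63)
  refs <- data.frame(id = c("celA", "celB"),
                     seq = c(random_protein(120), random_protein(150)))
  gene <- reverse_translate(refs$seq[1], seed = 64)
  contig_fwd <- paste0(paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                             collapse = ""),
                       gene,
                       paste(sample(c("A", "C", "G", "T"), 400, TRUE),
                             collapse = ""))
  hits <- screen_contigs(data.frame(id = "fwd", seq = contig_fwd), refs)
  expect_equal(nrow(hits), 1L)
  expect_equal(hits$reference_id, "celA")
  expect_gt(hits$bit_score, 200)
  expect_gt(hits$frame, 0)

  # reverse strand: same reference via a negative frame, same bit score
  hits_rc <- screen_contigs(data.frame(id = "rc", seq = revcomp(contig_fwd)),
                            refs)
  expect_equal(hits_rc$reference_id, "celA")
  expect_lt(hits_rc$frame, 0)
  expect_equal(hits_rc$bit_score, hits$bit_score)

  # raising the cutoff never adds hits
  n_low <- nrow(screen_contigs(data.frame(id = "fwd", seq = contig_fwd),
                               refs, cutoff_bits = 50))
  n_high <- nrow(screen_contigs(data.frame(id = "fwd", seq = contig_fwd),
                                refs, cutoff_bits = 1e4))
  expect_lte(n_high, n_low)

  # contigs below the minimum length are skipped; empty references error
  expect_equal(nrow(screen_contigs(data.frame(id = "tiny", seq = "ATGGCC"),
                                   refs)), 0L)
  expect_error(screen_contigs(data.frame(id = "x", seq = contig_fwd),
                              refs[0, ]), "empty reference")
})

test_that("random DNA yields no hits at the homology cutoff", {
  set.seed(65)
  refs <- do.call(rbind, lapply(1:20, function(i)
    data.frame(id = paste0("r", i), seq = random_protein(150))))
  dna <- paste(sample(c("A", "C", "G", "T"), 8000, TRUE), collapse = "")
  hits <- screen_contigs(data.frame(id = "bg", seq = dna), refs,
                         cutoff_bits = 50)
  expect_equal(nrow(hits), 0L)
})

test_that("shortlist_candidates applies the two filters", {
  hits <- data.frame(contig_id = paste0("c", 1:4), frame = 1,
                     peptide_start = 1, peptide_end = 100,
                     reference_id = "r", raw_score = 2000,
                     bit_score = c(500, 500, 500, 500),
                     align_length = 100, peptide = "M")
  coverage <- data.frame(contig_id = paste0("c", 1:4),
                         mapped_reads = c(10, 20, 30, 40))
  out <- shortlist_candidates(hits, coverage)
  expect_equal(attr(out, "coverage_threshold"), 40)
  expect_equal(out$contig_id[out$shortlisted], "c4")

  # bit score 299 with top coverage: excluded
  hits$bit_score <- c(500, 500, 500, 299)
  out <- shortlist_candidates(hits, coverage)
  expect_false(any(out$shortlisted))

  expect_equal(nrow(shortlist_candidates(hits[0, ], coverage)), 0L)
  expect_error(shortlist_candidates(hits, coverage[1:2, ]), "c3")
})
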