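test_that("read_fasta parses, folds case, preserves order, validates", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a desc", "mkv", ">b", "GG", "AA"), f)
  rec <- read_fasta(f, "protein")
  expect_equal(rec$id, c("a", "b"))
  expect_equal(rec$seq, c("MKV", "GGAA"))

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "", ">b", "GG"), empty)
  expect_error(read_fasta(empty), "a")
  expect_error(read_fasta(file.path(tempdir(), "nope.fasta")), "not found")

  nt <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c", "acgtn"), nt)
  expect_equal(read_fasta(nt, "nucleotide")$seq, "ACGTN")
  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">c", "ACGU"), bad)
  expect_error(read_fasta(bad, "nucleotide"), "non-ACGTN")
})

test_that("write_fasta round-trips records", {
  rec <- data.frame(id = c("x", "y"), seq = c("MKVLI", strrep("ACDEF", 30)))
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(rec, f)
  expect_equal(read_fasta(f, "protein"), rec)
})

test_that("clean_sequence removes non-standard symbols and is idempotent", {
  expect_equal(clean_sequence("MK*XV"), "MKV")
  expect_equal(clean_sequence("ACDEFGHIKLMNPQRSTVWY"),
               "ACDEFGHIKLMNPQRSTVWY")
  expect_equal(clean_sequence("mk-v bz8u"), "MKV")
  expect_error(clean_sequence(c(ok = "MKV", bad = "XXBZ")), "bad")
  set.seed(1)
  raw <- replicate(20, paste(sample(c(AAS, "X", "*", "-", "b", "u", "2"),
                                    50, replace = TRUE), collapse = ""))
  once <- clean_sequence(raw)
  expect_identical(clean_sequence(once), once)
})

test_that("six_frame_translate follows the codon table and splits at stops", {
  tf <- six_frame_translate(list(id = "c", seq = "ATGGCC"))
  expect_equal(tf[[1]]$frame, 1)
  expect_equal(tf[[1]]$peptides, "MA")
  expect_equal(tf[[1]]$offsets, 0L)

  tf <- six_frame_translate(list(id = "c", seq = "ATGTAAATG"))
  expect_equal(tf[[1]]$peptides, c("M", "M"))
  expect_equal(tf[[1]]$offsets, c(0L, 6L))

  # codons containing N break the peptide and never appear in it
  tf <- six_frame_translate(list(id = "c", seq = "ATGANTATG"))
  expect_equal(tf[[1]]$peptides, c("M", "M"))

  # shorter than one codon: empty lists, not an error
  tf <- six_frame_translate(list(id = "c", seq = "AT"))
  expect_true(all(vapply(tf, function(f) length(f$peptides) == 0L, TRUE)))
})

test_that("six-frame translation respects strand symmetry and length bound", {
  set.seed(42)
  for (rep in 1:5) {
    dna <- paste(sample(c("A", "C", "G", "T"), sample(30:90, 1),
                        replace = TRUE), collapse = "")
    fwd <- six_frame_translate(list(id = "x", seq = dna))
    rev <- six_frame_translate(list(id = "x", seq = revcomp(dna)))
    frame_of <- function(tr, f) tr[[which(vapply(tr, `[[`, 0, "frame") == f)]]
    expect_equal(frame_of(fwd, 1)$peptides, frame_of(rev, -1)$peptides)
    expect_equal(frame_of(rev, 1)$peptides, frame_of(fwd, -1)$peptides)
    for (fr in fwd)
      expect_lte(sum(nchar(fr$peptides)), floor(nchar(dna) / 3))
  }
})

test_that("greedy_cluster collapses near-duplicates like the brute force", {
  rec <- data.frame(id = c("a", "b"), seq = c("MKVLIMKVLI", "MKVLIMKVLI"))
  expect_equal(nrow(greedy_cluster(rec, 0.9)), 1L)

  rec <- data.frame(id = c("a", "b"), seq = c("MKVLI", "AAAAA"))
  expect_equal(nrow(greedy_cluster(rec, 0.9)), 2L)

  # 10 sequences, 3 of which are single-substitution variants of a 50-mer
  set.seed(7)
  base <- random_protein(50)
  variant <- function(s) {
    i <- sample(nchar(s), 1)
    substr(s, i, i) <- sample(setdiff(AAS, substr(s, i, i)), 1)
    s
  }
  seqs <- c(base, variant(base), variant(base),
            replicate(7, random_protein(50)))
  rec <- data.frame(id = paste0("s", 1:10), seq = seqs)
  reps <- greedy_cluster(rec, 0.9)

  idm <- oracle_identity_matrix(seqs)
  # brute-force greedy clustering over the same identity definition
  expected_reps <- Reduce(function(acc, i) {
    if (any(idm[i, acc] >= 0.9)) acc else c(acc, i)
  }, 2:10, accumulate = FALSE, init = 1L)
  expect_setequal(reps$id, rec$id[expected_reps])
  expect_equal(nrow(reps), 8L)

  # every input maps to exactly one cluster
  cl <- attr(reps, "clusters")
  expect_setequal(cl$member_id, rec$id)
  expect_false(anyDuplicated(cl$member_id) > 0)
})

test_that("lowering the identity threshold never grows the cluster count", {
  set.seed(11)
  base <- random_protein(60)
  mutate_n <- function(s, n) {
    for (k in seq_len(n)) {
      i <- sample(nchar(s), 1)
      substr(s, i, i) <- sample(setdiff(AAS, substr(s, i, i)), 1)
    }
    s
  }
  rec <- data.frame(id = paste0("m", 1:8),
                    seq = vapply(c(0, 2, 5, 9, 14, 20, 30, 45),
                                 function(n) mutate_n(base, n), ""))
  sizes <- vapply(c(1, 0.95, 0.9, 0.8, 0.6, 0.4),
                  function(th) nrow(greedy_cluster(rec, th)), 0L)
  expect_true(all(diff(sizes) <= 0))
  expect_equal(nrow(greedy_cluster(rec[0, ], 0.9)), 0L)
})
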