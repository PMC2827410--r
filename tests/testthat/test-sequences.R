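test_that("FASTA parsing extracts ids, tags, and rejects malformed input", {
  f <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">LLA_001 some description", "MKV", ">LLB_002", "PQR"), f)
  ps <- read_fasta(f)
  expect_equal(ps$id, c("LLA_001", "LLB_002"))
  expect_equal(ps$residues, c("MKV", "PQR"))
  expect_equal(ps$genome_tag, c("LLA", "LLB"))

  dup <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MKV", ">a", "PQR"), dup)
  expect_error(read_fasta(dup), "duplicate sequence id.*'a'")

  bad <- withr::local_tempfile(fileext = ".fasta")
  writeLines(c(">a", "MK9V"), bad)
  expect_error(read_fasta(bad), "position 3")

  empty <- withr::local_tempfile(fileext = ".fasta")
  writeLines(character(0), empty)
  expect_error(read_fasta(empty), "empty")
})

test_that("FASTA write -> read round-trips 50 simulated records exactly", {
  set.seed(7)
  ids <- sprintf("SEQ%02d_%d", 1:50, sample(1e4, 50))
  res <- vapply(sample(30:200, 50, replace = TRUE), random_protein,
                character(1))
  ps <- protein_set(ids, res)
  f <- withr::local_tempfile(fileext = ".fasta")
  write_fasta(ps, f)
  back <- read_fasta(f, genome_pattern = NULL)
  expect_identical(back$id, ids)
  expect_identical(back$residues, res)
})

test_that("self-alignment scores the matrix diagonal and identity 1", {
  S <- blosum62()
  a <- align_pair("MKVL", "MKVL")
  expect_equal(a$score, S["M", "M"] + S["K", "K"] + S["V", "V"] + S["L", "L"])
  expect_equal(a$identity_fraction, 1.0)
  expect_equal(a$aligned_query, "MKVL")
})

test_that("local mode finds an exact substring without gaps", {
  a <- align_pair("AAAWWWAAA", "WWW", mode = "local")
  expect_equal(a$aligned_query, "WWW")
  expect_equal(a$aligned_subject, "WWW")
  expect_equal(a$identity_fraction, 1.0)
  expect_equal(unname(a$query_range), c(4L, 6L))
})

test_that("alignment errors on empty sequences and bad penalties", {
  expect_error(align_pair("", "MKV"), "empty")
  expect_error(align_pair("MKV", "MK", gap_open = 0), "penalt")
})

test_that("global scores match the exhaustive enumeration oracle on all
           pairs of short sequences", {
  set.seed(11)
  pool <- c("M", "MK", "KVM", "WWP", "MKVL", "AC", "PQRST", "GG")
  S <- blosum62()
  for (i in seq_along(pool)) {
    for (j in seq_along(pool)) {
      got <- align_pair(pool[i], pool[j])$score
      want <- brute_force_global_score(pool[i], pool[j], S, 11, 1)
      expect_equal(got, want,
                   info = sprintf("%s vs %s", pool[i], pool[j]))
    }
  }
})

test_that("global score is symmetric for a symmetric matrix", {
  set.seed(3)
  for (k in 1:10) {
    a <- random_protein(sample(5:40, 1))
    b <- random_protein(sample(5:40, 1))
    expect_equal(align_pair(a, b)$score, align_pair(b, a)$score)
  }
})

test_that("ungapping the global alignment reproduces the inputs", {
  set.seed(5)
  for (k in 1:10) {
    a <- random_protein(sample(10:60, 1))
    b <- random_protein(sample(10:60, 1))
    al <- align_pair(a, b)
    expect_equal(gsub("-", "", al$aligned_query), a)
    expect_equal(gsub("-", "", al$aligned_subject), b)
    expect_equal(nchar(al$aligned_query), nchar(al$aligned_subject))
  }
})

test_that("percent identity counts only mutually non-gap columns", {
  expect_equal(percent_identity(list(aligned_query = "MK-V",
                                     aligned_subject = "MKAV")), 1.0)
  expect_equal(percent_identity(list(aligned_query = "--",
                                     aligned_subject = "AB")), 0)
  set.seed(9)
  for (k in 1:8) {
    a <- random_protein(60)
    b <- mutate_exact(a, k * 3)
    al <- align_pair(a, b)
    qa <- strsplit(al$aligned_query, "")[[1]]
    qb <- strsplit(al$aligned_subject, "")[[1]]
    both <- qa != "-" & qb != "-"
    expect_equal(al$identity_fraction,
                 sum(qa[both] == qb[both]) / sum(both))
  }
})

test_that("homolog collection recruits by best local hit with provenance", {
  set.seed(21)
  qseq <- random_protein(80)
  prot <- protein_set(c("p1", "p2", "p3"),
                      c(qseq, mutate_exact(qseq, 20), random_protein(80)),
                      genome_tag = c("g1", "g2", "g3"))
  q <- protein_set("q", qseq)
  hs <- collect_homologs(q, prot, min_score = 60, min_identity = 0.5)
  expect_true("p1" %in% hs$members$id)
  expect_equal(hs$provenance$identity[hs$provenance$id == "p1"], 1.0)
  expect_false("p3" %in% hs$members$id) # unrelated decoy
  # thresholds above the self-score give an empty set
  self_score <- align_pair(qseq, qseq, mode = "local")$score
  none <- collect_homologs(q, prot, min_score = self_score + 1,
                           min_identity = 0)
  expect_equal(nrow(none$members), 0L)
  expect_error(collect_homologs(q, prot[0, ]), "empty")
})

test_that("homolog collection is monotone in both thresholds and finds a
           simulated family without decoys", {
  fam <- simulate_family(n_duplications = 1, seq_length = 120, seed = 31)
  decoys <- protein_set(sprintf("decoy%d", 1:4),
                        vapply(rep(120, 4), random_protein, character(1)),
                        genome_tag = "DX")
  prot <- rbind(fam$sequences, decoys)
  class(prot) <- c("protein_set", "data.frame")
  q <- fam$sequences[1, ]
  class(q) <- class(fam$sequences)
  hs <- collect_homologs(q, prot, min_score = 60, min_identity = 0.25)
  recall <- mean(fam$sequences$id %in% hs$members$id)
  expect_gte(recall, 0.95)
  expect_false(any(decoys$id %in% hs$members$id))
  stricter <- collect_homologs(q, prot, min_score = 120, min_identity = 0.5)
  expect_true(all(stricter$members$id %in% hs$members$id))
})

test_that("redundancy removal uses a strict 90% boundary and greedy order", {
  set.seed(13)
  base <- random_protein(100)
  # exactly 90%: 10 mutations in 100 columns -> both kept
  at90 <- protein_set(c("s1", "s2"), c(base, mutate_exact(base, 10)))
  expect_equal(nrow(remove_redundant(at90, 0.90)), 2L)
  # identical -> only the first kept
  same <- protein_set(c("s1", "s2"), c(base, base))
  expect_equal(remove_redundant(same, 0.90)$id, "s1")
  # boundary sweep 85..95% identity in 1% steps: removal iff identity > 90%
  for (k in 5:15) {
    pair <- protein_set(c("a", "b"), c(base, mutate_exact(base, k)))
    kept <- nrow(remove_redundant(pair, 0.90))
    expect_equal(kept, if ((100 - k) / 100 > 0.90) 1L else 2L,
                 info = paste("mutations:", k))
  }
  expect_error(remove_redundant(at90, 0), "identity_threshold")
})

test_that("redundancy removal is idempotent and keeps the first sequence", {
  set.seed(17)
  base <- random_protein(80)
  ps <- protein_set(sprintf("s%d", 1:6),
                    c(base, mutate_exact(base, 2), mutate_exact(base, 4),
                      mutate_exact(base, 30), mutate_exact(base, 32),
                      random_protein(80)))
  once <- remove_redundant(ps)
  twice <- remove_redundant(once)
  expect_identical(once$id, twice$id)
  expect_equal(once$id[1], "s1")
})

test_that("protein_set enforces id uniqueness and genome->species mapping", {
  expect_error(protein_set(c("a", "a"), c("MK", "MV")), "duplicate")
  expect_error(protein_set(c("a", "b"), c("MK", "MV"),
                           genome_tag = c("g1", "g1"),
                           species_tag = c("s1", "s2")),
               "more than one species")
})
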