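segs4 <- data.frame(start = c(0L, 20L, 45L, 70L), end = c(12L, 32L, 58L, 82L))

make_template <- function(seed = 1, n = 90) {
  set.seed(seed)
  random_protein(n)
}

test_that("projecting a template onto itself reproduces the segments", {
  tpl <- make_template(41)
  pr <- project_segments(c(tpl = tpl), segs4, c(tgt = tpl))
  expect_false(any(pr$missing))
  expect_equal(pr$start, segs4$start)
  expect_equal(pr$end, segs4$end)
  expect_equal(pr$substring,
               substring(tpl, segs4$start + 1, segs4$end))
})

test_that("a cap insertion between segments shifts later projections by its
           length", {
  tpl <- make_template(43)
  set.seed(43)
  ins <- random_protein(10)
  # insert between segments 2 and 3 (position 40, inside the 32..45 gap)
  tgt <- paste0(substr(tpl, 1, 40), ins, substr(tpl, 41, nchar(tpl)))
  pr <- project_segments(c(tpl = tpl), segs4, c(tgt = tgt))
  expect_false(any(pr$missing))
  expect_equal(pr$start, segs4$start + c(0L, 0L, 10L, 10L))
  expect_equal(pr$substring,
               substring(tpl, segs4$start + 1, segs4$end))
})

test_that("a segment absent from the target is flagged missing", {
  tpl <- make_template(47)
  tgt <- substr(tpl, 1, 65)  # segment 4 (70..82) entirely gone
  pr <- project_segments(c(tpl = tpl), segs4, c(tgt = tgt))
  expect_true(pr$missing[4])
  expect_false(any(pr$missing[1:3]))
})

test_that("progressive alignment of substitution-only variants is gap-free
           with hand-countable column identities", {
  set.seed(51)
  base <- random_protein(40)
  seqs <- c(a = base, b = mutate_exact(base, 5), c = mutate_exact(base, 8))
  block <- align_segment(seqs)
  expect_true(all(nchar(block) == 40))
  expect_false(any(grepl("-", block)))
  m <- aln_matrix(block)
  ident_ab <- mean(m["a", ] == m["b", ])
  expect_equal(ident_ab, 35 / 40)
})

test_that("a known deletion is aligned as gaps of the right length", {
  set.seed(53)
  base <- random_protein(40)
  del <- paste0(substr(base, 1, 19), substr(base, 22, 40))
  block <- align_segment(c(full1 = base, full2 = mutate_exact(base, 3),
                           short = del))
  expect_equal(unique(nchar(block)), 40L)
  expect_equal(sum(strsplit(block[["short"]], "")[[1]] == "-"), 2L)
  expect_equal(gsub("-", "", block[["short"]]), del)
})

test_that("column curation drops sparse columns, preserves order, and is
           idempotent", {
  block <- c(s1 = "MKV-A", s2 = "MKV-A", s3 = "MKVWA", s4 = "MKV-A",
             s5 = "MKV-A", s6 = "MKV-A", s7 = "MKV-A", s8 = "MKV-A",
             s9 = "MKV-A", s10 = "MKV-A")
  cur <- curate_columns(block)
  expect_equal(unname(nchar(cur[1])), 4L)   # 0.1-occupancy column removed
  expect_equal(names(cur), names(block))
  expect_equal(as.character(curate_columns(cur)), as.character(cur))
  # gap-free block unchanged
  gf <- c(a = "MKV", b = "MLV")
  expect_equal(as.character(curate_columns(gf)), as.character(gf))
  expect_error(curate_columns(c(a = "---", b = "---", c = "A--")),
               "every column")
  # occupancy sweep equals direct counting
  set.seed(55)
  m <- matrix(sample(c("A", "-"), 200, TRUE, prob = c(0.6, 0.4)), 10)
  rownames(m) <- paste0("r", 1:10)
  occ <- colMeans(m != "-")
  for (thr in c(0.3, 0.5, 0.8)) {
    if (!any(occ >= thr)) next
    cur2 <- curate_columns(m, thr)
    expect_equal(unname(nchar(cur2[1])), sum(occ >= thr))
  }
})

test_that("concatenation records boundaries, gap-fills missing rows, and
           rejects mismatched ids", {
  b1 <- c(a = "MKVLMKVLMK", b = "MKVLMKVLMK")
  b2 <- c(a = "WWPQRSTANDQRSTA", b = "WWPQRSTANDQRSTA")
  cc <- concatenate_blocks(list(b1, b2))
  expect_equal(unname(nchar(cc[1])), 25L)
  expect_equal(attr(cc, "boundaries"), c(0L, 10L))
  # row missing from block 2 gets an all-gap span
  cc2 <- concatenate_blocks(list(b1, b2["a"]), ids = c("a", "b"))
  expect_equal(substr(cc2[["b"]], 11, 25), strrep("-", 15))
  expect_error(concatenate_blocks(list(b1, c(zz = "WWW"))),
               "id mismatch.*zz")
})

test_that("ungapping concatenated rows reproduces each sequence's projected
           substrings across a simulated structure family", {
  sim <- simulate_structures(n_members = 4,
                             segment_lengths = c(15, 12, 14, 10),
                             cap_lengths = c(5, 15), noise_sigma = 0.2,
                             seed = 57)
  core <- iterative_core_superpose(sim$structures)$core
  seqs <- sim$sequences
  tpl <- seqs[1, ]
  class(tpl) <- class(seqs)
  # with curation off the round-trip is exact
  msa <- core_alignment(tpl, core, seqs, min_occupancy = 0)
  projections <- attr(msa, "projections")
  for (id in seqs$id) {
    pr <- projections[[id]]
    expect_identical(gsub("-", "", msa[[id]]),
                     paste(pr$substring[!pr$missing], collapse = ""))
  }
  # pipeline determinism: identical inputs give identical alignments
  msa_a <- core_alignment(tpl, core, seqs)
  msa_b <- core_alignment(tpl, core, seqs)
  expect_identical(unname(msa_a), unname(msa_b))
})
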