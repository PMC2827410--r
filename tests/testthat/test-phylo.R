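test_that("alignment distances count mismatches over comparable columns", {
  aln <- c(a = "MKVL", b = "MKVL")
  expect_equal(msa_distances(aln)["a", "b"], 0)
  set.seed(61)
  base <- random_protein(100)
  var <- mutate_exact(base, 25)
  D <- msa_distances(c(a = base, b = var))
  expect_equal(D["a", "b"], 0.25)
  Dp <- msa_distances(c(a = base, b = var), correction = "poisson")
  expect_equal(Dp["a", "b"], -log(0.75))
  expect_error(msa_distances(c(a = "MKV")), "at least 2")
  expect_warning(D0 <- msa_distances(c(a = "MK--", b = "--VL", c = "MKVL")),
                 "no comparable column")
  expect_equal(D0["a", "b"], 1.1 * max(D0["a", "c"], D0["b", "c"]))
})

test_that("three-taxon NJ matches the closed form", {
  D <- matrix(c(0, 3, 4, 3, 0, 5, 4, 5, 0), 3,
              dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  tr <- neighbor_joining(D)
  expect_equal(length(tr$tip.label), 3L)
  la <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "A")]
  lb <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "B")]
  lc <- tr$edge.length[tr$edge[, 2] == which(tr$tip.label == "C")]
  expect_equal(la, (3 + 4 - 5) / 2)
  expect_equal(lb, (3 + 5 - 4) / 2)
  expect_equal(lc, (4 + 5 - 3) / 2)
  expect_error(neighbor_joining(D[1:2, 1:2]), "at least 3")
})

test_that("NJ is exact on additive matrices: topology and branch lengths", {
  for (s in 1:20) {
    gen <- random_additive_matrix(6, seed = 600 + s)
    tr <- neighbor_joining(gen$D)
    expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(gen$tree)), 0)
    Dhat <- ape::cophenetic.phylo(tr)[rownames(gen$D), colnames(gen$D)]
    expect_lt(max(abs(Dhat - gen$D)), 1e-9)
  }
})

test_that("NJ agrees with the reference implementation and is invariant to
           taxon order", {
  gen <- random_additive_matrix(8, seed = 71)
  tr <- neighbor_joining(gen$D)
  ref <- ape::nj(as.dist(gen$D))
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(ref)), 0)
  perm <- sample(rownames(gen$D))
  tr2 <- neighbor_joining(gen$D[perm, perm])
  expect_equal(phangorn::RF.dist(ape::unroot(tr), ape::unroot(tr2)), 0)
  expect_identical(write_newick(tr), write_newick(tr2))
})

test_that("negative branch lengths are clamped with the deficit recorded", {
  D <- matrix(c(0, 2, 2, 10,
                2, 0, 0.1, 10,
                2, 0.1, 0, 10,
                10, 10, 10, 0), 4,
              dimnames = list(letters[1:4], letters[1:4]))
  tr <- neighbor_joining(D)
  expect_true(all(tr$edge.length >= 0))
  expect_true(attr(tr, "clamped_deficit") >= 0)
})

test_that("bootstrap gives 100% support for perfectly separated clades and
           is seed-reproducible", {
  # every column separates {A,B} from {C,D}
  aln <- c(A = strrep("A", 30), B = strrep("A", 30),
           C = strrep("W", 30), D = strrep("W", 30))
  tr <- bootstrap_support(aln, n_replicates = 50, seed = 5)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup == 100))
  tr2 <- bootstrap_support(aln, n_replicates = 50, seed = 5)
  expect_identical(tr$node.label, tr2$node.label)
})

test_that("bootstrap supports lie in [0,100] on divergent simulated data", {
  fam <- simulate_family(n_duplications = 1, seq_length = 60, seed = 73)
  aln <- setNames(fam$sequences$residues, fam$sequences$id)
  tr <- bootstrap_support(aln, n_replicates = 40, seed = 9)
  sup <- tr$node.label[!is.na(tr$node.label)]
  expect_true(all(sup >= 0 & sup <= 100))
  expect_equal(length(tr$node.label), tr$Nnode)
})

test_that("Newick writing is canonical and round-trips annotations", {
  t1 <- read_newick("(A:1,B:2,(C:1,D:1):0.5);")
  s1 <- write_newick(t1)
  expect_identical(s1, "(A:1,B:2,(C:1,D:1):0.5);")
  expect_identical(write_newick(read_newick(s1)), s1)
  # canonical child ordering: permuted input serializes identically
  t1b <- read_newick("((D:1,C:1):0.5,B:2,A:1);")
  expect_identical(write_newick(t1b), s1)
  # supports + events + groups survive a round trip
  ann <- "(A:1,B:2,(C:1,D:1)87:0.5[&&NHX:Ev=D:OG=1.2]);"
  t2 <- read_newick(ann)
  expect_identical(write_newick(t2), ann)
  expect_true("D" %in% t2$event)
  expect_true("1.2" %in% t2$group)
})

test_that("malformed Newick reports the character offset", {
  expect_error(read_newick("(A:1,B:2;"), "offset 9")
  expect_error(read_newick("(A,B)); "), "offset")
})

test_that("midpoint rooting preserves supports and yields a rooted tree", {
  gen <- random_additive_matrix(6, seed = 81)
  aln_len <- 40
  tr <- neighbor_joining(gen$D)
  tr$node.label <- seq_len(tr$Nnode) * 10
  rt <- midpoint_root(tr)
  expect_true(ape::is.rooted(rt))
  expect_setequal(stats::na.omit(rt$node.label),
                  stats::na.omit(tr$node.label))
})
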