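test_that("PDB CA parsing keeps file order, altLoc-first, exact coordinates", {
  f <- withr::local_tempfile(fileext = ".pdb")
  writeLines(tiny_pdb_text(), f)
  m <- read_structure(f, chain = "A", id = "tiny")
  expect_equal(nrow(m$residues), 3L)
  expect_equal(m$residues$residue_name, c("ALA", "GLY", "SER"))
  expect_equal(m$residues$x, c(0, 3.8, 3.8))
  expect_equal(model_sequence(m), "AGS")

  fa <- withr::local_tempfile(fileext = ".pdb")
  writeLines(altloc_pdb_text(), fa)
  ma <- read_structure(fa, chain = "A")
  expect_equal(nrow(ma$residues), 3L)       # altLoc B dropped
  expect_equal(ma$residues$x[2], 3.8)       # first altLoc kept
  expect_error(read_structure(f, chain = "Z"), "no CA atoms")
})

test_that("structure write -> read round-trips coordinates at PDB precision", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 2)
  s <- sim$structures[[1]]
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  back <- read_structure(f, chain = "A")
  expect_equal(unname(model_xyz(back)), unname(model_xyz(s)),
               tolerance = 1e-3)
  expect_equal(back$residues$residue_name, s$residues$residue_name)
})

test_that("Kabsch superposition of a structure onto itself is the identity", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 4)
  X <- model_xyz(sim$structures[[1]])
  sup <- kabsch_superpose(X, X, cbind(seq_len(nrow(X)), seq_len(nrow(X))))
  expect_equal(sup$rmsd, 0, tolerance = 1e-10)
  expect_equal(sup$rotation, diag(3), tolerance = 1e-8)
})

test_that("Kabsch recovers random rigid transforms to numerical precision", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 6)
  X <- model_xyz(sim$structures[[1]])
  idx <- cbind(seq_len(nrow(X)), seq_len(nrow(X)))
  set.seed(100)
  for (k in 1:25) {
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    tv <- runif(3, -50, 50)
    Y <- sweep(X %*% t(R), 2, tv, `+`)
    sup <- kabsch_superpose(Y, X, idx)
    expect_lt(sup$rmsd, 1e-6)
    expect_equal(det(sup$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(sup$rotation), diag(3), tolerance = 1e-8)
    # recovered transform inverts the applied one
    expect_equal(sup$rotation, t(R), tolerance = 1e-6)
  }
})

test_that("Kabsch rmsd under isotropic noise stays within the scaling bound
           and is invariant to rigid pre-transformations", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 8)
  X <- model_xyz(sim$structures[[1]])
  idx <- cbind(seq_len(nrow(X)), seq_len(nrow(X)))
  sigma <- 0.5
  set.seed(200)
  for (k in 1:20) {
    Y <- X + matrix(rnorm(length(X), 0, sigma), nrow(X))
    sup <- kabsch_superpose(Y, X, idx)
    expect_gt(sup$rmsd, 0)
    expect_lt(sup$rmsd, 2 * sigma * sqrt(3))
    R <- qr.Q(qr(matrix(rnorm(9), 3)))
    if (det(R) < 0) R[, 1] <- -R[, 1]
    Y2 <- sweep(Y %*% t(R), 2, rnorm(3, 0, 10), `+`)
    expect_equal(kabsch_superpose(Y2, X, idx)$rmsd, sup$rmsd,
                 tolerance = 1e-9)
  }
})

test_that("Kabsch rejects degenerate correspondences", {
  X <- cbind(0:9 * 3.8, 0, 0)  # collinear
  expect_error(kabsch_superpose(X, X, cbind(1:10, 1:10)), "collinear")
  Y <- matrix(rnorm(30), 10)
  expect_error(kabsch_superpose(Y, Y, cbind(1:2, 1:2)), "at least 3")
})

test_that("sequence-based correspondence pairs all positions of identical
           structures and tracks an insertion", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 10)
  a <- sim$structures[[1]]
  pr <- initial_correspondence(a, a)
  expect_equal(pr[, "a"], seq_len(nrow(a$residues)))
  expect_equal(pr[, "b"], seq_len(nrow(a$residues)))
  # insert 5 random residues in the middle of a copy
  set.seed(3)
  res <- a$residues
  ins <- data.frame(residue_name = bio3d::aa123(sample(c("W", "Y", "F", "H",
                                                         "C"), 5, TRUE)),
                    residue_number = as.character(900:904),
                    x = rnorm(5, 50), y = rnorm(5, 50), z = rnorm(5, 50))
  cut <- 20L
  b <- structure_model("b", c(res$residue_name[1:cut], ins$residue_name,
                              res$residue_name[(cut + 1):nrow(res)]),
                       c(res$residue_number[1:cut], ins$residue_number,
                         res$residue_number[(cut + 1):nrow(res)]),
                       rbind(as.matrix(res[1:cut, c("x", "y", "z")]),
                             as.matrix(ins[, c("x", "y", "z")]),
                             as.matrix(res[(cut + 1):nrow(res),
                                           c("x", "y", "z")])))
  pr2 <- initial_correspondence(a, b)
  mapped <- pr2[, "b"] - ifelse(pr2[, "b"] > cut, 5L, 0L)
  expect_true(all(mapped == pr2[, "a"]))
  expect_equal(nrow(pr2), nrow(a$residues))
})

test_that("two identical structures yield one all-spanning zero-deviation
           segment", {
  sim <- simulate_structures(n_members = 2, cap_lengths = c(0, 0),
                             noise_sigma = 0, seed = 12)
  s <- sim$structures[[1]]
  res <- iterative_core_superpose(list(s, s))
  expect_equal(nrow(res$core$segments), 1L)
  expect_equal(res$core$segments$start, 0L)
  expect_equal(res$core$segments$end, nrow(s$residues))
  expect_true(all(res$core$deviation < 1e-9))
})

test_that("planted 4-segment cores are recovered with high overlap and the
           result ignores the order of non-reference members", {
  sim <- simulate_structures(n_members = 4,
                             segment_lengths = c(15, 12, 14, 10),
                             cap_lengths = c(10, 40), noise_sigma = 0.3,
                             seed = 14)
  res <- iterative_core_superpose(sim$structures)
  truth <- sim$truth$core_positions[[1]]
  found <- res$core$positions
  jac <- length(intersect(found, truth)) / length(union(found, truth))
  expect_gte(jac, 0.9)
  expect_equal(nrow(res$core$segments), 4L)
  # reorder the non-reference structures: identical segments
  res2 <- iterative_core_superpose(sim$structures[c(1, 4, 2, 3)])
  expect_equal(res2$core$segments, res$core$segments)
  # all rotations proper to tight tolerance
  for (sp in res$superpositions) {
    expect_equal(det(sp$rotation), 1, tolerance = 1e-8)
    expect_equal(crossprod(sp$rotation), diag(3), tolerance = 1e-8)
  }
})

test_that("triad classification reads S/H/D, S/H/E and flags gaps", {
  msa <- c(t1 = "SAHADA", t2 = "SAHAEA", t3 = "SAHA-A", t4 = "TAHADA")
  rep <- triad_check(msa, c(1, 3, 5))
  expect_equal(rep$triad_class, c("SHD", "SHE", "other", "other"))
  expect_equal(rep$has_gap, c(FALSE, FALSE, TRUE, FALSE))
  expect_error(triad_check(msa, c(1, 3, 99)), "out of range")
  expect_error(triad_check(msa, c(1, 3)), "length 3")
})

test_that("residue positions map through gapped rows to alignment columns", {
  msa <- c(tpl = "MK--VLW", oth = "MKAAVL-")
  expect_equal(map_to_columns(msa, "tpl", c(1, 3, 5)), c(1L, 5L, 7L))
  expect_error(map_to_columns(msa, "nope", 1), "not in alignment")
})
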