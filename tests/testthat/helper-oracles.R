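# Independent oracles and small fixture builders shared across tests.

# Exhaustive global affine-gap alignment score by enumeration of all gapped
# alignments (no dynamic programming): recursion over (i, j, state) where
# state records whether the previous column was a gap in a or b, so each gap
# run is charged gap_open + length * gap_extend.
brute_force_global_score <- function(a, b, S, gap_open, gap_ext) {
  ac <- strsplit(a, "")[[1]]
  bc <- strsplit(b, "")[[1]]
  rec <- function(i, j, state) {
    if (i > length(ac) && j > length(bc)) return(0)
    best <- -Inf
    if (i <= length(ac) && j <= length(bc))
      best <- max(best, S[ac[i], bc[j]] + rec(i + 1, j + 1, "m"))
    if (i <= length(ac)) {
      cost <- if (state == "x") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i + 1, j, "x"))
    }
    if (j <= length(bc)) {
      cost <- if (state == "y") gap_ext else gap_open + gap_ext
      best <- max(best, -cost + rec(i, j + 1, "y"))
    }
    best
  }
  rec(1, 1, "m")
}

# random additive distance matrix from a random tree; the generating tree is
# returned for topology comparison
random_additive_matrix <- function(n_taxa, seed) {
  set.seed(seed)
  tr <- ape::rtree(n_taxa, br = function(n) stats::runif(n, 0.05, 1))
  D <- ape::cophenetic.phylo(tr)
  D <- D[sort(rownames(D)), sort(colnames(D))]
  list(D = D, tree = tr)
}

random_protein <- function(n, alphabet = setdiff(c("A","R","N","D","C","Q",
  "E","G","H","I","L","K","M","F","P","S","T","W","Y","V"), NULL))
  paste(sample(alphabet, n, replace = TRUE), collapse = "")

# mutate exactly k positions of a sequence (guaranteed changes)
mutate_exact <- function(seq, k) {
  ch <- strsplit(seq, "")[[1]]
  pos <- sample(length(ch), k)
  aas <- c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S",
           "T","W","Y","V")
  for (p in pos) ch[p] <- sample(setdiff(aas, ch[p]), 1)
  paste(ch, collapse = "")
}

# minimal hand-written CA-only PDB text
tiny_pdb_text <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA  GLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA  SER A   3       3.800   3.800   0.000  1.00  0.00           C",
  "END")

altloc_pdb_text <- function() c(
  "ATOM      1  CA  ALA A   1       0.000   0.000   0.000  1.00  0.00           C",
  "ATOM      2  CA AGLY A   2       3.800   0.000   0.000  1.00  0.00           C",
  "ATOM      3  CA BGLY A   2       9.900   9.900   9.900  1.00  0.00           C",
  "ATOM      4  CA  SER A   3       3.800   3.800   0.000  1.00  0.00           C",
  "END")
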