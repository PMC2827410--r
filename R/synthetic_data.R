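# Simulators with known ground truth for every input the pipeline consumes:
# sequence families evolved along a species tree with planted duplications,
# structure sets sharing a rigid core with member-specific caps, and CGH
# score matrices with class-conditional score distributions.

.AA20 <- setdiff(.AA_LETTERS, "X")

#' Reference species tree for simulation studies
#'
#' Six ingroup species plus a distant outgroup `O`, with branch lengths in
#' expected substitutions per site chosen so that ingroup pairwise sequence
#' divergence averages about 30% under [simulate_family()] defaults — enough
#' signal for neighbor-joining without approaching saturation. The outgroup
#' anchors midpoint rooting the way reference sequences from other phyla do
#' in real superfamily trees; without it, a duplication near the ingroup
#' root produces copy clades as deep as the true root and rooting (hence
#' orthology) becomes unstable.
#'
#' @return A Newick string.
#' @export
example_species_tree <- function()
  paste0("(O:0.45,((A:0.10,B:0.10):0.12,",
         "((C:0.09,D:0.09):0.10,(E:0.11,F:0.11):0.08):0.07):0.10);")

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", .GlobalEnv))
    get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
          else rm(".Random.seed", envir = .GlobalEnv))
  force(expr)
}

.mutate_seq <- function(chars, n_sub) {
  if (n_sub < 1L) return(chars)
  pos <- sample.int(length(chars), n_sub, replace = TRUE)
  for (p in pos) {
    chars[p] <- sample(setdiff(.AA20, chars[p]), 1L)
  }
  chars
}

#' Simulate a protein family along a species tree with planted duplications
#'
#' A uniform-random root sequence evolves along the species tree; each branch
#' applies Poisson(`subst_rate` x branch length x sequence length)
#' substitutions, replacements drawn uniformly over the other 19 residues.
#' At each of `n_duplications` randomly chosen non-root internal nodes the
#' gene lineage duplicates halfway along the branch entering that node, both
#' copies then descending independently (the half-branch stem keeps the copy
#' split identifiable from sequence data). Leaves are lost with probability
#' `loss_prob`. The true orthologous groups are the sets of leaves sharing a
#' duplication-copy path.
#'
#' @param species_tree Newick string (or `phylo`) with branch lengths in
#'   expected substitutions per site.
#' @param n_duplications Number of duplication events to plant.
#' @param loss_prob Per-gene-copy leaf loss probability.
#' @param subst_rate Substitution rate multiplier.
#' @param seq_length Root sequence length.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#' @return List with `sequences` (a [protein_set]; ids are
#'   `<species>_<copy-path>`), and `truth`: list with `partition` (named
#'   vector id -> true group label), `duplication_nodes`, `species`
#'   (named vector id -> species) and `params`.
#' @export
simulate_family <- function(species_tree = example_species_tree(),
                            n_duplications = 1L,
                            loss_prob = 0, subst_rate = 1, seq_length = 300L,
                            seed = 1L) {
  if (subst_rate < 0 || loss_prob < 0 || loss_prob >= 1)
    stop("rates must be >= 0 and loss_prob in [0, 1)")
  tree <- if (inherits(species_tree, "phylo")) species_tree
          else read_newick(species_tree)
  if (is.null(tree$edge.length)) stop("species tree needs branch lengths")
  n_tip <- length(tree$tip.label)
  root <- n_tip + 1L
  internals <- setdiff((n_tip + 1L):(n_tip + tree$Nnode), root)
  if (n_duplications > length(internals))
    stop("more duplications than non-root internal nodes")
  .with_seed(seed, {
    dup_nodes <- if (n_duplications > 0L)
      sort(sample(internals, n_duplications)) else integer(0)
    root_seq <- sample(.AA20, seq_length, replace = TRUE)
    ids <- character(0)
    seqs <- character(0)
    species <- character(0)
    partition <- character(0)
    mutate_branch <- function(chars, len)
      .mutate_seq(chars, stats::rpois(1L, subst_rate * len * seq_length))
    record <- function(node, chars, tag) {
      if (loss_prob > 0 && stats::runif(1L) < loss_prob) return(invisible())
      sp <- tree$tip.label[node]
      id <- paste0(sp, "_", if (nzchar(tag)) tag else "0")
      ids <<- c(ids, id)
      seqs <<- c(seqs, paste(chars, collapse = ""))
      species <<- c(species, sp)
      partition <<- c(partition, if (nzchar(tag)) tag else "0")
      invisible()
    }
    evolve_down <- function(node, chars, tag) {
      kids <- tree$edge[tree$edge[, 1L] == node, 2L]
      lens <- tree$edge.length[tree$edge[, 1L] == node]
      for (z in seq_along(kids)) {
        k <- kids[z]
        if (k %in% dup_nodes) {
          # duplication halfway along the branch into k
          mid <- mutate_branch(chars, lens[z] / 2)
          for (copy in c("a", "b")) {
            cc <- mutate_branch(mid, lens[z] / 2)
            # tag carries the duplication node so independent duplications
            # in disjoint clades yield distinct true groups
            evolve_down(k, cc, paste0(tag, "n", k, copy))
          }
        } else {
          cc <- mutate_branch(chars, lens[z])
          if (k <= n_tip) record(k, cc, tag) else evolve_down(k, cc, tag)
        }
      }
    }
    evolve_down(root, root_seq, "")
    if (length(ids) < 3L)
      stop("fewer than 3 surviving gene copies; lower loss_prob")
    sequences <- protein_set(ids, seqs, genome_tag = species,
                             species_tag = species)
    truth <- list(partition = stats::setNames(partition, ids),
                  duplication_nodes = dup_nodes,
                  species = stats::setNames(species, ids),
                  params = list(n_duplications = n_duplications,
                                loss_prob = loss_prob,
                                subst_rate = subst_rate,
                                seq_length = seq_length, seed = seed))
    list(sequences = sequences, truth = truth)
  })
}

.random_rotation <- function() {
  # QR of a random Gaussian matrix, sign-fixed to a proper rotation
  qr_ <- qr(matrix(stats::rnorm(9L), 3L))
  R <- qr.Q(qr_)
  R <- R %*% diag(sign(diag(qr.R(qr_))))
  if (det(R) < 0) R[, 1L] <- -R[, 1L]
  R
}

.random_walk <- function(n, start = c(0, 0, 0), step = 3.8,
                         avoid = NULL, min_dist = 3.2) {
  pts <- matrix(NA_real_, n, 3L)
  prev <- start
  for (k in seq_len(n)) {
    for (try in 1:200) {
      v <- stats::rnorm(3L)
      cand <- prev + step * v / sqrt(sum(v^2))
      ok <- TRUE
      if (!is.null(avoid) || k > 2L) {
        existing <- rbind(avoid, pts[seq_len(max(k - 2L, 0L)), , drop = FALSE])
        if (nrow(existing) &&
            min(sqrt(rowSums(sweep(existing, 2L, cand)^2))) < min_dist)
          ok <- FALSE
      }
      if (ok) break
    }
    pts[k, ] <- cand
    prev <- cand
  }
  pts
}

#' Simulate structures sharing a rigid core with variable caps
#'
#' A shared core backbone is drawn as a self-avoiding random walk with
#' 3.8-Angstrom steps (the Calpha-Calpha virtual bond length). Each member is
#' a rigidly transformed copy of the core with isotropic Gaussian coordinate
#' noise, interrupted at the declared inter-segment junctions by
#' member-specific random-walk cap insertions. Core residues share one
#' random amino-acid sequence across members; caps are random per member,
#' so sequence alignment pairs core positions and leaves caps unpaired.
#'
#' @param n_members Number of structures (>= 2); the first is the reference.
#' @param segment_lengths Integer vector of core segment lengths.
#' @param cap_lengths Length-2 range of cap insertion lengths (residues),
#'   drawn uniformly per junction per member; `c(0, 0)` disables caps.
#' @param noise_sigma Coordinate noise standard deviation in Angstrom.
#' @param seed Integer seed.
#' @return List with `structures` (list of `structure_model`s), `sequences`
#'   (a [protein_set]) and `truth`: per-member true core position indices,
#'   segment layout, transforms and parameters.
#' @export
simulate_structures <- function(n_members = 4L,
                                segment_lengths = c(15L, 12L, 14L, 10L),
                                cap_lengths = c(10L, 40L),
                                noise_sigma = 0.3, seed = 1L) {
  if (n_members < 2L) stop("need at least 2 members")
  n_seg <- length(segment_lengths)
  total <- sum(segment_lengths)
  .with_seed(seed, {
    core_xyz <- .random_walk(total)
    core_seq <- sample(.AA20, total, replace = TRUE)
    seg_id <- rep(seq_len(n_seg), segment_lengths)
    structures <- vector("list", n_members)
    seq_strings <- character(n_members)
    core_positions <- vector("list", n_members)
    transforms <- vector("list", n_members)
    for (mbr in seq_len(n_members)) {
      noisy <- core_xyz + matrix(stats::rnorm(3L * total, 0, noise_sigma),
                                 total, 3L)
      xyz <- NULL
      letters_m <- character(0)
      pos_m <- integer(0)
      for (s in seq_len(n_seg)) {
        block <- noisy[seg_id == s, , drop = FALSE]
        pos_m <- c(pos_m, nrow(if (is.null(xyz)) matrix(0, 0, 3) else xyz) +
                     seq_len(nrow(block)))
        xyz <- rbind(xyz, block)
        letters_m <- c(letters_m, core_seq[seg_id == s])
        if (s < n_seg && cap_lengths[2L] > 0L) {
          cl <- if (cap_lengths[1L] == cap_lengths[2L]) cap_lengths[1L]
                else sample(cap_lengths[1L]:cap_lengths[2L], 1L)
          if (cl > 0L) {
            cap <- .random_walk(cl, start = xyz[nrow(xyz), ])
            xyz <- rbind(xyz, cap)
            letters_m <- c(letters_m, sample(.AA20, cl, replace = TRUE))
          }
        }
      }
      R <- .random_rotation()
      tvec <- stats::runif(3L, -20, 20)
      xyz <- sweep(xyz %*% t(R), 2L, tvec, `+`)
      id <- sprintf("SIM%02d", mbr)
      structures[[mbr]] <- structure_model(
        id, bio3d::aa123(letters_m), seq_len(nrow(xyz)), xyz)
      seq_strings[mbr] <- paste(letters_m, collapse = "")
      core_positions[[mbr]] <- pos_m
      transforms[[mbr]] <- list(rotation = R, translation = tvec)
    }
    names(core_positions) <- vapply(structures, `[[`, character(1L), "id")
    truth <- list(core_positions = core_positions,
                  segment_lengths = segment_lengths,
                  transforms = transforms,
                  params = list(n_members = n_members,
                                cap_lengths = cap_lengths,
                                noise_sigma = noise_sigma, seed = seed))
    list(structures = structures,
         sequences = protein_set(names(core_positions), seq_strings),
         truth = truth)
  })
}

#' Simulate a CGH hybridization score matrix with known truth
#'
#' Gene presence is Bernoulli(`presence_prob`) per gene x strain; probe
#' scores are drawn from class-conditional normal distributions
#' (present: N(`mu_present`, `sd_present`), absent: N(`mu_absent`,
#' `sd_absent`), defaults placing the conventional 5.5 cutoff between the
#' classes). Optionally the first `plasmid_block` genes share one truth
#' vector, emulating co-inherited plasmid-borne genes.
#'
#' @param n_genes,n_strains Matrix dimensions.
#' @param presence_prob Prior probability a gene is present in a strain.
#' @param mu_present,sd_present,mu_absent,sd_absent Score distributions.
#' @param probes_per_gene Probe replicates per gene (rows share the gene id).
#' @param plasmid_block Number of leading genes sharing one presence vector
#'   (0 = off).
#' @param seed Integer seed.
#' @return List with `scores` (probe-level matrix, repeated gene rownames)
#'   and `truth`: `presence` (logical gene x strain matrix), `plasmid_genes`,
#'   `params`.
#' @export
simulate_cgh <- function(n_genes = 500L, n_strains = 20L,
                         presence_prob = 0.7, mu_present = 12,
                         sd_present = 2, mu_absent = 2, sd_absent = 1.5,
                         probes_per_gene = 3L, plasmid_block = 0L,
                         seed = 1L) {
  if (probes_per_gene < 1L) stop("probes_per_gene must be >= 1")
  .with_seed(seed, {
    genes <- sprintf("gene%04d", seq_len(n_genes))
    strains <- sprintf("strain%02d", seq_len(n_strains))
    truth <- matrix(stats::runif(n_genes * n_strains) < presence_prob,
                    n_genes, n_strains, dimnames = list(genes, strains))
    plasmid_genes <- character(0)
    if (plasmid_block > 0L) {
      vec <- stats::runif(n_strains) < 0.5
      for (g in seq_len(min(plasmid_block, n_genes))) truth[g, ] <- vec
      plasmid_genes <- genes[seq_len(min(plasmid_block, n_genes))]
    }
    scores <- matrix(NA_real_, n_genes * probes_per_gene, n_strains,
                     dimnames = list(rep(genes, each = probes_per_gene),
                                     strains))
    for (g in seq_len(n_genes)) {
      rows <- (g - 1L) * probes_per_gene + seq_len(probes_per_gene)
      pres <- truth[g, ]
      for (s in seq_len(n_strains)) {
        scores[rows, s] <- if (pres[s])
          stats::rnorm(probes_per_gene, mu_present, sd_present)
        else stats::rnorm(probes_per_gene, mu_absent, sd_absent)
      }
    }
    list(scores = scores,
         truth = list(presence = truth, plasmid_genes = plasmid_genes,
                      params = list(presence_prob = presence_prob,
                                    mu_present = mu_present,
                                    sd_present = sd_present,
                                    mu_absent = mu_absent,
                                    sd_absent = sd_absent,
                                    probes_per_gene = probes_per_gene,
                                    plasmid_block = plasmid_block,
                                    seed = seed)))
  })
}
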