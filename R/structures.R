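# Calpha structure models, rigid-body (Kabsch) superposition, iterative
# detection of the structurally conserved core, and catalytic-triad
# diagnostics.

#' Read the Calpha trace of a PDB file
#'
#' Keeps one entry per residue with a CA atom on the selected chain; when a
#' residue has alternate locations the first is kept. Insertion codes are
#' preserved inside the residue number string.
#'
#' @param path PDB coordinate file.
#' @param chain Chain identifier, or `NULL` for the first chain with CA atoms.
#' @param id Identifier for the model; defaults to file name + chain.
#' @return An object of class `structure_model`: list with `id` and
#'   `residues`, a data frame of `residue_name` (3-letter code),
#'   `residue_number` (author numbering as character, insertion code
#'   appended) and `x`, `y`, `z` coordinates in Angstrom.
#' @export
read_structure <- function(path, chain = NULL, id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  pdb <- bio3d::read.pdb(path, verbose = FALSE)
  at <- pdb$atom
  ca <- at[at$type == "ATOM" & at$elety == "CA", , drop = FALSE]
  if (!is.null(chain)) ca <- ca[ca$chain %in% chain, , drop = FALSE]
  if (!nrow(ca)) stop("no CA atoms", if (!is.null(chain))
    paste0(" on chain '", chain, "'"), " in ", path)
  if (is.null(chain)) {
    chain <- ca$chain[1L]
    ca <- ca[ca$chain == chain, , drop = FALSE]
  }
  ins <- ifelse(is.na(ca$insert) | ca$insert == "", "", ca$insert)
  resnum <- paste0(ca$resno, ins)
  keep <- !duplicated(resnum) # altLoc duplicates: first kept
  ca <- ca[keep, , drop = FALSE]
  resnum <- resnum[keep]
  if (any(!is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z))) {
    bad <- which(!is.finite(ca$x) | !is.finite(ca$y) | !is.finite(ca$z))[1L]
    stop("unparseable coordinates for residue ", resnum[bad], " in ", path)
  }
  structure_model(
    id = if (is.null(id)) paste0(tools::file_path_sans_ext(basename(path)),
                                 "_", chain) else id,
    residue_name = ca$resid, residue_number = resnum,
    xyz = cbind(ca$x, ca$y, ca$z))
}

#' Construct a structure model from residue names and coordinates
#'
#' @param id Model identifier.
#' @param residue_name 3-letter residue codes, in file order.
#' @param residue_number Author residue numbers (character or integer).
#' @param xyz Numeric n x 3 matrix of Calpha coordinates in Angstrom.
#' @return A `structure_model`.
#' @export
structure_model <- function(id, residue_name, residue_number, xyz) {
  xyz <- as.matrix(xyz)
  if (ncol(xyz) != 3L) stop("xyz must have 3 columns")
  n <- nrow(xyz)
  if (n < 3L) stop("a structure model needs at least 3 residues")
  if (length(residue_name) != n || length(residue_number) != n)
    stop("residue_name/residue_number length must match coordinates")
  if (any(!is.finite(xyz))) stop("coordinates must be finite")
  out <- list(id = id,
              residues = data.frame(
                residue_name = as.character(residue_name),
                residue_number = as.character(residue_number),
                x = xyz[, 1L], y = xyz[, 2L], z = xyz[, 3L],
                stringsAsFactors = FALSE))
  class(out) <- "structure_model"
  out
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf("<structure_model %s: %d residues>\n", x$id, nrow(x$residues)))
  invisible(x)
}

#' Calpha coordinates of a structure model
#' @param model A `structure_model`.
#' @return Numeric n x 3 matrix.
#' @export
model_xyz <- function(model)
  as.matrix(model$residues[, c("x", "y", "z")])

#' One-letter sequence of a structure model
#'
#' Residue names are translated with the standard 3-to-1 letter code;
#' non-standard residues become `X`.
#'
#' @param model A `structure_model`.
#' @return Single amino-acid string.
#' @export
model_sequence <- function(model) {
  aa <- bio3d::aa321(model$residues$residue_name)
  aa[is.na(aa) | !aa %in% .AA_LETTERS] <- "X"
  paste(aa, collapse = "")
}

#' Write a structure model as a CA-only PDB file
#' @param model A `structure_model`.
#' @param path Output path.
#' @param chain Chain id to write.
#' @export
write_structure <- function(model, path, chain = "A") {
  n <- nrow(model$residues)
  resno <- suppressWarnings(as.integer(sub("[A-Za-z]$", "",
                                           model$residues$residue_number)))
  if (anyNA(resno)) resno <- seq_len(n)
  bio3d::write.pdb(file = path, xyz = as.numeric(t(model_xyz(model))),
                   type = rep("ATOM", n), resno = resno,
                   resid = model$residues$residue_name,
                   eleno = seq_len(n), elety = rep("CA", n),
                   chain = rep(chain, n))
  invisible(path)
}

#' Optimal rigid-body superposition (Kabsch algorithm)
#'
#' Least-squares rotation + translation (no reflection) mapping the movable
#' structure onto the reference over a residue correspondence, solved by SVD
#' of the cross-covariance matrix.
#'
#' @param movable,reference `structure_model`s (or plain n x 3 coordinate
#'   matrices).
#' @param correspondence Integer matrix with two columns (movable index,
#'   reference index, 1-based); at least 3 non-collinear pairs.
#' @return Object of class `superposition`: list with `rotation` (3 x 3,
#'   orthonormal, det +1), `translation` (length-3, Angstrom), `rmsd`
#'   (Angstrom over the correspondence) and `correspondence`. The transformed
#'   movable coordinate is `rotation %*% x + translation`.
#' @export
kabsch_superpose <- function(movable, reference, correspondence) {
  P <- if (inherits(movable, "structure_model")) model_xyz(movable)
       else as.matrix(movable)
  Q <- if (inherits(reference, "structure_model")) model_xyz(reference)
       else as.matrix(reference)
  correspondence <- as.matrix(correspondence)
  if (nrow(correspondence) < 3L)
    stop("need at least 3 correspondence pairs")
  p <- P[correspondence[, 1L], , drop = FALSE]
  q <- Q[correspondence[, 2L], , drop = FALSE]
  cp <- colMeans(p)
  cq <- colMeans(q)
  pc <- sweep(p, 2L, cp)
  qc <- sweep(q, 2L, cq)
  H <- t(pc) %*% qc
  sv <- svd(H)
  if (sv$d[2L] <= 1e-10 * max(sv$d[1L], 1e-30))
    stop("degenerate (collinear) correspondence; superposition is not unique")
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  tvec <- cq - as.numeric(R %*% cp)
  moved <- sweep(pc %*% t(R), 2L, cq, `+`)
  rmsd <- sqrt(mean(rowSums((moved - q)^2)))
  out <- list(rotation = R, translation = tvec, rmsd = rmsd,
              correspondence = correspondence)
  class(out) <- "superposition"
  out
}

#' Apply a superposition to a structure model
#' @param model A `structure_model` or n x 3 matrix.
#' @param sup A `superposition`.
#' @return Same type as `model`, transformed.
#' @export
apply_superposition <- function(model, sup) {
  is_model <- inherits(model, "structure_model")
  X <- if (is_model) model_xyz(model) else as.matrix(model)
  Y <- sweep(X %*% t(sup$rotation), 2L, sup$translation, `+`)
  if (!is_model) return(Y)
  model$residues$x <- Y[, 1L]
  model$residues$y <- Y[, 2L]
  model$residues$z <- Y[, 3L]
  model
}

#' Sequence-based residue correspondence between two structures
#'
#' Globally aligns the structure-derived one-letter sequences and returns the
#' match columns (both residues present) as index pairs.
#'
#' @param a,b `structure_model`s.
#' @param ... Passed to [align_pair()].
#' @return Integer matrix with columns `a` and `b` (1-based residue indices).
#' @export
initial_correspondence <- function(a, b, ...) {
  aln <- align_pair(stats::setNames(model_sequence(a), a$id),
                    stats::setNames(model_sequence(b), b$id),
                    mode = "global", ...)
  qa <- strsplit(aln$aligned_query, "")[[1L]]
  qb <- strsplit(aln$aligned_subject, "")[[1L]]
  ia <- cumsum(qa != "-")
  ib <- cumsum(qb != "-")
  both <- qa != "-" & qb != "-"
  pairs <- cbind(a = ia[both], b = ib[both])
  if (nrow(pairs) < 3L)
    stop("fewer than 3 aligned residue pairs between ", a$id, " and ", b$id)
  pairs
}

#' Iteratively detect the structurally conserved core of a structure set
#'
#' All structures are superposed onto the first (the reference) over the
#' current core position set — initially every reference position aligned in
#' all structures via [initial_correspondence()] — and the per-position
#' maximum pairwise Calpha deviation of every candidate position is
#' re-scored under the current fit; the new core is the set of candidates
#' below `deviation_cutoff`, so a position trimmed while the fit was still
#' contaminated can be recovered once it improves. While the fit is unstable
#' (the thresholded set would shed more than a quarter of the current core)
#' only the worst quartile is trimmed instead. The loop stops when the set
#' is stable or after `max_iter` rounds.
#' The surviving positions are split into maximal runs of consecutive
#' reference residues; runs of at least `min_segment_length` become the core
#' segments (the discontinuous superimposable regions of the catalytic
#' domain), shorter runs are reported as diagnostics.
#'
#' @param structures List of >= 2 `structure_model`s; the first is the
#'   reference.
#' @param deviation_cutoff Maximum allowed pairwise Calpha deviation in
#'   Angstrom (default 3.0).
#' @param min_segment_length Minimum run length of a reported segment
#'   (default 4).
#' @param max_iter Iteration cap (default 20).
#' @return List with `superpositions` (per structure, reference included as
#'   identity), `core`: an object of class `core_segments` with `segments`
#'   (data frame `start`/`end`, 0-based half-open over reference residue
#'   order), `positions` (1-based reference indices in the core), `deviation`
#'   (named per-position max pairwise deviation), `discarded` (runs shorter
#'   than `min_segment_length`), `reference_id` and `parameters`.
#' @export
iterative_core_superpose <- function(structures, deviation_cutoff = 3.0,
                                     min_segment_length = 4L,
                                     max_iter = 20L) {
  if (length(structures) < 2L) stop("need at least 2 structures")
  ref <- structures[[1L]]
  others <- structures[-1L]
  maps <- lapply(others, function(s) {
    pr <- initial_correspondence(ref, s)
    stats::setNames(pr[, "b"], pr[, "a"])
  })
  cand <- Reduce(intersect, lapply(maps, function(m) as.integer(names(m))))
  cand <- sort(cand)
  if (length(cand) < 3L)
    stop("fewer than 3 positions aligned across all structures")
  core <- cand
  refxyz <- model_xyz(ref)
  sups <- NULL
  dev <- NULL
  for (iter in seq_len(max_iter)) {
    # superpose everything onto the reference over the current core ...
    corr_ref <- cbind(core, core)
    sups <- vector("list", length(structures))
    sups[[1L]] <- structure(list(rotation = diag(3), translation = c(0, 0, 0),
                                 rmsd = 0, correspondence = corr_ref),
                            class = "superposition")
    coords <- vector("list", length(structures))
    coords[[1L]] <- refxyz[cand, , drop = FALSE]
    for (k in seq_along(others)) {
      midx_core <- unname(maps[[k]][as.character(core)])
      sup <- kabsch_superpose(others[[k]], ref, cbind(midx_core, core))
      sups[[k + 1L]] <- sup
      midx_all <- unname(maps[[k]][as.character(cand)])
      coords[[k + 1L]] <- apply_superposition(
        model_xyz(others[[k]])[midx_all, , drop = FALSE], sup)
    }
    # ... then re-score every candidate position under the current fit
    ns <- length(coords)
    dev <- rep(0, length(cand))
    for (i in seq_len(ns - 1L)) {
      for (j in (i + 1L):ns) {
        d <- sqrt(rowSums((coords[[i]] - coords[[j]])^2))
        dev <- pmax(dev, d)
      }
    }
    names(dev) <- as.character(cand)
    new_core <- cand[dev < deviation_cutoff]
    if (length(new_core) < 0.75 * length(core)) {
      # fit still contaminated by far-flung spurious matches: trim only the
      # worst quartile of the current core rather than trusting it
      dc <- dev[as.character(core)]
      drop <- order(dc, decreasing = TRUE)[seq_len(max(1L,
                                                       floor(length(core) / 4)))]
      new_core <- sort(core[-drop])
    }
    if (length(new_core) < 3L)
      stop("core collapsed below 3 positions; try a larger deviation_cutoff")
    if (identical(new_core, core)) break
    core <- new_core
  }
  # enforce the invariant even when max_iter stopped the trimming early
  strict <- core[dev[as.character(core)] < deviation_cutoff]
  if (length(strict) < 3L)
    stop("core collapsed below 3 positions; try a larger deviation_cutoff")
  core <- strict
  runs <- split(core, cumsum(c(1L, diff(core) != 1L)))
  lens <- lengths(runs)
  seg_runs <- runs[lens >= min_segment_length]
  segments <- data.frame(
    start = vapply(seg_runs, min, integer(1L)) - 1L,
    end = vapply(seg_runs, max, integer(1L)), # half-open: max index itself
    row.names = NULL)
  discarded <- data.frame(
    start = vapply(runs[lens < min_segment_length], min, integer(1L)) - 1L,
    end = vapply(runs[lens < min_segment_length], max, integer(1L)),
    row.names = NULL)
  core_obj <- list(segments = segments, positions = core,
                   deviation = dev[as.character(core)],
                   discarded = discarded, reference_id = ref$id,
                   parameters = list(deviation_cutoff = deviation_cutoff,
                                     min_segment_length = min_segment_length,
                                     max_iter = max_iter))
  class(core_obj) <- "core_segments"
  names(sups) <- vapply(structures, `[[`, character(1L), "id")
  list(superpositions = sups, core = core_obj)
}

#' @export
print.core_segments <- function(x, ...) {
  cat(sprintf("<core_segments on %s: %d segment(s), %d positions>\n",
              x$reference_id, nrow(x$segments), length(x$positions)))
  print(x$segments)
  invisible(x)
}

#' Export per-position deviations and segments as TSV
#' @param core A `core_segments` object.
#' @param deviation_file,segment_file Output paths (either may be `NULL`).
#' @export
write_core_tsv <- function(core, deviation_file = NULL, segment_file = NULL) {
  if (!is.null(deviation_file))
    utils::write.table(
      data.frame(position = as.integer(names(core$deviation)) - 1L,
                 max_pairwise_deviation = unname(core$deviation)),
      deviation_file, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(segment_file))
    utils::write.table(core$segments, segment_file, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  invisible(NULL)
}

#' Catalytic-triad residues across an alignment
#'
#' Reads the residues of every sequence at three alignment columns
#' (nucleophile, base, acid). The classic alpha/beta-hydrolase triad
#' Ser-His-Asp is class `"SHD"`; the Asp-to-Glu substituted form (diagnostic
#' of the PepR subfamily) is `"SHE"`; anything else, including gaps, is
#' `"other"`, with gaps flagged.
#'
#' @param msa Gapped alignment as in [aln_matrix()].
#' @param triad_columns Integer vector of three 1-based alignment columns in
#'   nucleophile, base, acid order.
#' @return Data frame with `id`, `nucleophile`, `base`, `acid`,
#'   `triad_class`, `has_gap`.
#' @export
triad_check <- function(msa, triad_columns) {
  m <- aln_matrix(msa)
  if (length(triad_columns) != 3L) stop("triad_columns must have length 3")
  if (any(triad_columns < 1L | triad_columns > ncol(m)))
    stop("triad column index out of range (alignment width ", ncol(m), ")")
  nuc <- m[, triad_columns[1L]]
  bas <- m[, triad_columns[2L]]
  aci <- m[, triad_columns[3L]]
  cls <- ifelse(nuc == "S" & bas == "H" & aci == "D", "SHD",
                ifelse(nuc == "S" & bas == "H" & aci == "E", "SHE", "other"))
  data.frame(id = rownames(m), nucleophile = nuc, base = bas, acid = aci,
             triad_class = cls,
             has_gap = nuc == "-" | bas == "-" | aci == "-",
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Map ungapped residue positions of one row to alignment columns
#'
#' Used to designate catalytic-triad columns from a template structure's
#' residue indices.
#'
#' @param msa Gapped alignment as in [aln_matrix()].
#' @param id Row id of the template sequence.
#' @param positions 1-based residue indices in the ungapped template.
#' @return Integer vector of alignment columns.
#' @export
map_to_columns <- function(msa, id, positions) {
  m <- aln_matrix(msa)
  if (!id %in% rownames(m)) stop("id '", id, "' not in alignment")
  row <- m[id, ]
  resi <- cumsum(row != "-")
  cols <- vapply(positions, function(p) {
    w <- which(resi == p & row != "-")
    if (!length(w)) stop("residue ", p, " of '", id,
                         "' is not present in the alignment")
    w[1L]
  }, integer(1L))
  cols
}
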