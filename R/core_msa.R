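# Projection of structure-defined core segments onto homologs, progressive
# alignment of each segment, column curation and concatenation into the
# alignment the superfamily trees are built from.

#' Project core segments of a template onto a target sequence
#'
#' The template (the reference structure's sequence) is globally aligned to
#' the target; each core segment then maps to the target positions aligned
#' with its template positions. A segment whose template positions align to
#' more than 50% gaps in the target is flagged missing.
#'
#' @param template Template sequence (single-row [protein_set] or string);
#'   must be the sequence the core segments are defined on.
#' @param core A `core_segments` object (or a data frame with `start`/`end`,
#'   0-based half-open over template positions).
#' @param target Target sequence (single-row [protein_set] or string).
#' @param max_gap_fraction Missingness threshold (default 0.5).
#' @param ... Passed to [align_pair()].
#' @return Object of class `segment_projection`: data frame with one row per
#'   segment: `segment`, `start`, `end` (0-based half-open in the target),
#'   `substring`, `missing`. The target id is kept in attribute `"id"`.
#' @export
project_segments <- function(template, core, target, max_gap_fraction = 0.5,
                             ...) {
  segs <- if (inherits(core, "core_segments")) core$segments else core
  tpl <- .as_entry(template, "template")
  tgt <- .as_entry(target, "target")
  aln <- align_pair(tpl$residues, tgt$residues, mode = "global", ...)
  qa <- strsplit(aln$aligned_query, "")[[1L]]
  qb <- strsplit(aln$aligned_subject, "")[[1L]]
  ti <- cumsum(qa != "-")  # template residue index per column
  si <- cumsum(qb != "-")  # target residue index per column
  out <- data.frame(segment = seq_len(nrow(segs)), start = NA_integer_,
                    end = NA_integer_, substring = NA_character_,
                    missing = FALSE)
  for (k in seq_len(nrow(segs))) {
    lo <- segs$start[k] + 1L
    hi <- segs$end[k]
    cols <- which(qa != "-" & ti >= lo & ti <= hi)
    gap_frac <- mean(qb[cols] == "-")
    hit <- cols[qb[cols] != "-"]
    if (gap_frac > max_gap_fraction || !length(hit)) {
      out$missing[k] <- TRUE
      next
    }
    lo_t <- si[hit[1L]]
    hi_t <- si[hit[length(hit)]]
    out$start[k] <- lo_t - 1L
    out$end[k] <- hi_t
    out$substring[k] <- substr(tgt$residues, lo_t, hi_t)
  }
  attr(out, "id") <- tgt$id
  class(out) <- c("segment_projection", "data.frame")
  out
}

.profile_from_block <- function(block_mat, alphabet) {
  P <- matrix(0, length(alphabet), ncol(block_mat))
  for (k in seq_along(alphabet))
    P[k, ] <- colSums(block_mat == alphabet[k])
  P / nrow(block_mat)
}

.merge_blocks <- function(A, B, S, gap_open, gap_ext) {
  alphabet <- rownames(S)
  r <- .align_profiles_cpp(.profile_from_block(A, alphabet),
                           .profile_from_block(B, alphabet),
                           S, gap_open, gap_ext)
  ops <- r$ops
  ncolo <- length(ops)
  out <- matrix("-", nrow(A) + nrow(B), ncolo,
                dimnames = list(c(rownames(A), rownames(B)), NULL))
  ia <- cumsum(ops != 3L)
  ib <- cumsum(ops != 2L)
  out[seq_len(nrow(A)), ops != 3L] <- A[, ia[ops != 3L], drop = FALSE]
  out[nrow(A) + seq_len(nrow(B)), ops != 2L] <- B[, ib[ops != 2L],
                                                  drop = FALSE]
  out
}

#' Progressive multiple alignment of sequence substrings
#'
#' Simple deterministic progressive aligner: pairwise distances are
#' 1 - identity from global pairwise alignments, the guide tree is UPGMA
#' (average-linkage clustering), and profiles are merged bottom-up with
#' profile-profile dynamic programming under the same substitution matrix
#' and affine gap penalties as [align_pair()]. Used both for the per-segment
#' blocks of the core alignment and for full-length alignments in
#' sequence-only runs.
#'
#' @param seqs Named character vector of >= 2 ungapped sequences (entries
#'   that are `NA` are dropped; at least 2 must remain).
#' @param matrix,gap_open,gap_extend Scoring, as in [align_pair()].
#' @return Named character vector of equal-length gapped rows, in the input
#'   order of `seqs`.
#' @export
align_segment <- function(seqs, matrix = blosum62(), gap_open = 11,
                          gap_extend = 1) {
  seqs <- seqs[!is.na(seqs)]
  if (length(seqs) < 2L)
    stop("progressive alignment needs at least 2 non-missing sequences")
  if (is.null(names(seqs)) || anyDuplicated(names(seqs)))
    stop("sequences must have unique names")
  storage.mode(matrix) <- "double"
  n <- length(seqs)
  D <- base::matrix(0, n, n, dimnames = list(names(seqs), names(seqs)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      a <- align_pair(seqs[i], seqs[j], matrix = matrix,
                      gap_open = gap_open, gap_extend = gap_extend)
      D[i, j] <- D[j, i] <- 1 - a$identity_fraction
    }
  }
  blocks <- lapply(seq_len(n), function(k)
    base::matrix(strsplit(seqs[[k]], "")[[1L]], nrow = 1L,
                 dimnames = list(names(seqs)[k], NULL)))
  if (n == 2L) {
    merged <- .merge_blocks(blocks[[1L]], blocks[[2L]], matrix,
                            gap_open, gap_extend)
  } else {
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    live <- blocks
    merged_list <- vector("list", n - 1L)
    for (step in seq_len(n - 1L)) {
      pick <- function(x) if (x < 0) live[[-x]] else merged_list[[x]]
      merged_list[[step]] <- .merge_blocks(pick(hc$merge[step, 1L]),
                                           pick(hc$merge[step, 2L]),
                                           matrix, gap_open, gap_extend)
    }
    merged <- merged_list[[n - 1L]]
  }
  merged <- merged[names(seqs), , drop = FALSE]
  stats::setNames(apply(merged, 1L, paste, collapse = ""), names(seqs))
}

#' Remove sparsely occupied alignment columns
#'
#' Columns whose non-gap fraction is below `min_occupancy` are removed — the
#' automated stand-in for manual curation of ambiguously aligned regions.
#' Row order is preserved and the operation is idempotent.
#'
#' @param block Gapped alignment as in [aln_matrix()].
#' @param min_occupancy Minimum non-gap fraction of a kept column
#'   (default 0.5).
#' @return Named character vector of curated rows.
#' @export
curate_columns <- function(block, min_occupancy = 0.5) {
  m <- aln_matrix(block)
  occ <- colMeans(m != "-")
  keep <- occ >= min_occupancy
  if (!any(keep)) stop("curation removed every column")
  m <- m[, keep, drop = FALSE]
  structure(stats::setNames(apply(m, 1L, paste, collapse = ""), rownames(m)),
            kept = which(keep))
}

#' Concatenate aligned segment blocks
#'
#' Blocks are joined left to right; a sequence absent from a block (missing
#' segment) receives an all-gap span of that block's width. When `ids` is
#' not given, all blocks must carry the same id set.
#'
#' @param blocks List of gapped blocks (named character vectors).
#' @param ids Optional character vector fixing the row set and order.
#' @return Named character vector of equal-length rows with attributes
#'   `boundaries` (0-based start column of each block) and `block_widths`.
#' @export
concatenate_blocks <- function(blocks, ids = NULL) {
  if (!length(blocks)) stop("no blocks to concatenate")
  idsets <- lapply(blocks, names)
  if (is.null(ids)) {
    ids <- idsets[[1L]]
    for (k in seq_along(idsets)) {
      extra <- c(setdiff(idsets[[k]], ids), setdiff(ids, idsets[[k]]))
      if (length(extra))
        stop("id mismatch across blocks: ", paste(extra, collapse = ", "))
    }
  } else {
    for (k in seq_along(idsets)) {
      extra <- setdiff(idsets[[k]], ids)
      if (length(extra))
        stop("id mismatch across blocks: ", paste(extra, collapse = ", "))
    }
  }
  widths <- vapply(blocks, function(b) unique(nchar(b))[1L], integer(1L))
  rows <- stats::setNames(rep("", length(ids)), ids)
  for (k in seq_along(blocks)) {
    b <- blocks[[k]]
    gap <- strrep("-", widths[k])
    add <- ifelse(ids %in% names(b), b[ids], gap)
    rows <- paste0(rows, add)
  }
  names(rows) <- ids
  structure(rows,
            boundaries = cumsum(c(0L, widths[-length(widths)])),
            block_widths = unname(widths))
}

#' Per-column occupancy of an alignment
#' @param aln Gapped alignment as in [aln_matrix()].
#' @return Numeric vector of non-gap fractions per column.
#' @export
column_occupancy <- function(aln) colMeans(aln_matrix(aln) != "-")

#' Build the concatenated core alignment for a set of homologs
#'
#' Projects the core segments of the reference structure onto every homolog,
#' aligns each segment block progressively, curates columns and
#' concatenates. Sequences missing a segment get all-gap spans.
#'
#' @param template Reference sequence the core is defined on.
#' @param core A `core_segments` object.
#' @param seqs [protein_set] of homologs (redundancy-filtered).
#' @param min_occupancy Column curation threshold (default 0.5).
#' @param ... Scoring arguments passed to the aligners.
#' @return A concatenated alignment (see [concatenate_blocks()]), plus
#'   attribute `projections` with the per-sequence segment projections.
#' @export
core_alignment <- function(template, core, seqs, min_occupancy = 0.5, ...) {
  projections <- lapply(seq_len(nrow(seqs)), function(k)
    project_segments(template, core, seqs[k, ], ...))
  names(projections) <- seqs$id
  segs <- if (inherits(core, "core_segments")) core$segments else core
  n_seg <- nrow(segs)
  tpl <- .as_entry(template, "template")
  blocks <- vector("list", n_seg)
  tpl_map <- integer(0) # template full-sequence position -> final column
  offset <- 0L
  for (s in seq_len(n_seg)) {
    subs <- vapply(projections, function(p) p$substring[s], character(1L))
    subs <- subs[!vapply(projections, function(p) p$missing[s], logical(1L))]
    if (length(subs) < 2L)
      stop("segment ", s, " is missing in all but ", length(subs),
           " sequence(s)")
    raw <- align_segment(subs, ...)
    cur <- curate_columns(raw, min_occupancy = min_occupancy)
    blocks[[s]] <- cur
    if (tpl$id %in% names(raw)) {
      rowch <- strsplit(raw[[tpl$id]], "")[[1L]]
      residx <- cumsum(rowch != "-") # index within the segment substring
      kept <- attr(cur, "kept")
      keep_res <- kept[rowch[kept] != "-"]
      # target coordinates of the template's own projection give the
      # full-sequence position of each substring residue
      p0 <- projections[[tpl$id]]$start[s]
      m <- stats::setNames(offset + match(keep_res, kept),
                           p0 + residx[keep_res])
      tpl_map <- c(tpl_map, m)
    }
    offset <- offset + nchar(cur[[1L]])
  }
  out <- concatenate_blocks(blocks, ids = seqs$id)
  attr(out, "projections") <- projections
  if (length(tpl_map)) attr(out, "template_map") <- tpl_map
  out
}

#' Write a gapped alignment to TSV (id, row per line)
#' @param aln Gapped alignment (named character vector).
#' @param file Output path.
#' @param boundary_file Optional sidecar TSV with block boundaries.
#' @export
write_alignment_tsv <- function(aln, file, boundary_file = NULL) {
  utils::write.table(data.frame(id = names(aln), row = unname(aln)),
                     file, sep = "\t", quote = FALSE, row.names = FALSE)
  b <- attr(aln, "boundaries")
  if (!is.null(boundary_file) && !is.null(b))
    utils::write.table(data.frame(block = seq_along(b), start = b,
                                  width = attr(aln, "block_widths")),
                       boundary_file, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  invisible(file)
}
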