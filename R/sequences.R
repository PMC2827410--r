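#' @useDynLib subfam, .registration = TRUE
#' @importFrom Rcpp evalCpp
NULL

.AA_LETTERS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                 "M", "F", "P", "S", "T", "W", "Y", "V", "X")

#' Construct a set of protein sequences
#'
#' A `protein_set` is a data frame with one row per sequence and columns
#' `id`, `residues`, `genome_tag` and `species_tag`. The `genome_tag` is a
#' short genome abbreviation (for example `"LLX"`); the `species_tag` is the
#' species identifier used for orthology calls. Every genome tag must map to
#' exactly one species tag.
#'
#' @param id Character vector of unique, non-empty sequence identifiers.
#' @param residues Character vector of uppercase amino-acid strings over the
#'   20 standard one-letter codes plus `X`.
#' @param genome_tag Optional character vector of genome abbreviations.
#' @param species_tag Optional character vector of species identifiers;
#'   defaults to `genome_tag`.
#' @return A data frame of class `protein_set`.
#' @export
protein_set <- function(id, residues, genome_tag = NA_character_,
                        species_tag = NULL) {
  id <- as.character(id)
  residues <- toupper(as.character(residues))
  if (length(id) != length(residues))
    stop("'id' and 'residues' must have the same length")
  if (any(!nzchar(id)) || anyNA(id)) stop("sequence ids must be non-empty")
  if (anyDuplicated(id)) {
    dup <- id[duplicated(id)][1L]
    stop("duplicate sequence id: '", dup, "'")
  }
  if (any(!nzchar(residues))) stop("residues must have length >= 1")
  for (k in seq_along(residues)) .check_residues(residues[k], id[k])
  genome_tag <- rep_len(as.character(genome_tag), length(id))
  if (is.null(species_tag)) species_tag <- genome_tag
  species_tag <- rep_len(as.character(species_tag), length(id))
  tab <- unique(data.frame(g = genome_tag, s = species_tag))
  tab <- tab[!is.na(tab$g), , drop = FALSE]
  if (anyDuplicated(tab$g))
    stop("genome_tag '", tab$g[duplicated(tab$g)][1L],
         "' maps to more than one species_tag")
  out <- data.frame(id = id, residues = residues, genome_tag = genome_tag,
                    species_tag = species_tag, stringsAsFactors = FALSE)
  class(out) <- c("protein_set", "data.frame")
  out
}

.check_residues <- function(res, id) {
  chars <- strsplit(res, "", fixed = TRUE)[[1L]]
  bad <- which(!chars %in% .AA_LETTERS)
  if (length(bad))
    stop("invalid residue character '", chars[bad[1L]], "' at position ",
         bad[1L], " in sequence '", id, "'")
  invisible(TRUE)
}

#' Read protein sequences from a FASTA file
#'
#' The identifier of each record is the header token before the first
#' whitespace. A genome tag can be extracted from the identifier with a
#' regular expression containing one capture group; identifiers that do not
#' match get `NA`.
#'
#' @param path Path to a FASTA file.
#' @param genome_pattern Regular expression with one capture group applied to
#'   each id to extract the genome tag, or `NULL` to skip tagging.
#' @param genome_map Optional named character vector mapping genome tags to
#'   species tags; unmapped tags use the genome tag itself.
#' @return A [protein_set].
#' @export
read_fasta <- function(path, genome_pattern = "^([^_]+)_", genome_map = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("empty FASTA file: ", path)
  hdr <- grepl("^>", lines)
  if (!hdr[1L]) stop("not a FASTA file (first line is not a header): ", path)
  rec <- cumsum(hdr)
  ids <- sub("^>\\s*", "", lines[hdr])
  ids <- vapply(strsplit(ids, "\\s+"), `[`, character(1L), 1L)
  res <- vapply(split(lines[!hdr], rec[!hdr]), paste, character(1L),
                collapse = "")
  if (length(res) != length(ids) || any(!nzchar(res)))
    stop("FASTA record without sequence lines in: ", path)
  if (anyDuplicated(ids))
    stop("duplicate sequence id in ", path, ": '",
         ids[duplicated(ids)][1L], "'")
  gtag <- rep(NA_character_, length(ids))
  if (!is.null(genome_pattern)) {
    m <- regmatches(ids, regexec(genome_pattern, ids))
    hit <- lengths(m) >= 2L
    gtag[hit] <- vapply(m[hit], `[`, character(1L), 2L)
  }
  stag <- gtag
  if (!is.null(genome_map)) {
    mapped <- !is.na(gtag) & gtag %in% names(genome_map)
    stag[mapped] <- unname(genome_map[gtag[mapped]])
  }
  protein_set(ids, toupper(res), gtag, stag)
}

#' Write protein sequences to a FASTA file
#'
#' @param x A [protein_set] or a named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.data.frame(x)) {
    ids <- x$id
    res <- x$residues
  } else {
    ids <- names(x)
    res <- unname(x)
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (k in seq_along(ids)) {
    writeLines(paste0(">", ids[k]), con)
    s <- res[k]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

.encode_seq <- function(res) {
  idx <- match(strsplit(res, "", fixed = TRUE)[[1L]], .BLOSUM62_ALPHABET)
  if (anyNA(idx)) stop("symbol not covered by the substitution matrix in '",
                       res, "'")
  idx - 1L
}

.as_entry <- function(x, default_id) {
  if (is.data.frame(x)) {
    if (nrow(x) != 1L) stop("expected a single sequence, got ", nrow(x))
    list(id = x$id, residues = x$residues)
  } else if (is.character(x) && length(x) == 1L) {
    list(id = if (!is.null(names(x))) names(x) else default_id,
         residues = unname(toupper(x)))
  } else stop("cannot interpret input as a protein sequence")
}

#' Optimal pairwise alignment with affine gap penalties
#'
#' Needleman-Wunsch (global) or Smith-Waterman (local) dynamic programming
#' under an affine gap model in which a gap run of length L costs
#' `gap_open + L * gap_extend`. Traceback ties are broken deterministically:
#' diagonal, then up (gap in the subject), then left (gap in the query).
#'
#' @param a,b Query and subject: single-row [protein_set]s or plain strings
#'   (optionally named with the sequence id).
#' @param matrix Substitution matrix with symbol names on both dimensions;
#'   defaults to [blosum62()].
#' @param gap_open,gap_extend Positive gap penalties.
#' @param mode `"global"` or `"local"`.
#' @return An object of class `pairwise_alignment`: a list with
#'   `query_id`, `subject_id`, `aligned_query`, `aligned_subject` (equal-length
#'   gapped strings), `score`, `identity_fraction`, `mode`, and for local mode
#'   the 1-based `query_range`/`subject_range` of the aligned region.
#' @export
align_pair <- function(a, b, matrix = blosum62(), gap_open = 11,
                       gap_extend = 1, mode = c("global", "local")) {
  mode <- match.arg(mode)
  if (gap_open <= 0 || gap_extend <= 0) stop("gap penalties must be > 0")
  a <- .as_entry(a, "query")
  b <- .as_entry(b, "subject")
  if (!nzchar(a$residues) || !nzchar(b$residues))
    stop("cannot align an empty sequence")
  if (!identical(rownames(matrix), .BLOSUM62_ALPHABET)) {
    ai <- match(strsplit(a$residues, "")[[1L]], rownames(matrix)) - 1L
    bi <- match(strsplit(b$residues, "")[[1L]], rownames(matrix)) - 1L
    if (anyNA(ai) || anyNA(bi))
      stop("substitution matrix does not cover all sequence symbols")
  } else {
    ai <- .encode_seq(a$residues)
    bi <- .encode_seq(b$residues)
  }
  storage.mode(matrix) <- "double"
  r <- .align_pair_cpp(ai, bi, matrix, gap_open, gap_extend,
                       mode == "local")
  ach <- strsplit(a$residues, "", fixed = TRUE)[[1L]]
  bch <- strsplit(b$residues, "", fixed = TRUE)[[1L]]
  ops <- r$ops
  ia <- r$a_start + cumsum(ops != 3L)
  jb <- r$b_start + cumsum(ops != 2L)
  qa <- rep("-", length(ops))
  qa[ops != 3L] <- ach[ia[ops != 3L]]
  qb <- rep("-", length(ops))
  qb[ops != 2L] <- bch[jb[ops != 2L]]
  out <- list(query_id = a$id, subject_id = b$id,
              aligned_query = paste(qa, collapse = ""),
              aligned_subject = paste(qb, collapse = ""),
              score = r$score, mode = mode,
              query_range = c(r$a_start + 1L,
                              if (length(ia)) ia[length(ia)] else r$a_start),
              subject_range = c(r$b_start + 1L,
                                if (length(jb)) jb[length(jb)] else r$b_start))
  out$identity_fraction <- percent_identity(out)
  class(out) <- "pairwise_alignment"
  out
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment %s vs %s: %s, score %.1f, identity %.1f%%>\n",
              x$query_id, x$subject_id, x$mode, x$score,
              100 * x$identity_fraction))
  cat(x$aligned_query, "\n", x$aligned_subject, "\n", sep = "")
  invisible(x)
}

#' Percent identity of a pairwise alignment
#'
#' Identity is counted over columns where both symbols are non-gap: the
#' number of identical such columns divided by their count. Returns 0 when no
#' mutually non-gap column exists.
#'
#' @param aln A `pairwise_alignment`, or a list with `aligned_query` and
#'   `aligned_subject` gapped strings of equal length.
#' @return A fraction in \[0, 1\].
#' @export
percent_identity <- function(aln) {
  qa <- strsplit(aln$aligned_query, "", fixed = TRUE)[[1L]]
  qb <- strsplit(aln$aligned_subject, "", fixed = TRUE)[[1L]]
  if (length(qa) != length(qb)) stop("aligned strings differ in length")
  both <- qa != "-" & qb != "-"
  if (!any(both)) return(0)
  sum(qa[both] == qb[both]) / sum(both)
}

#' Collect homologs of query sequences from a set of proteomes
#'
#' Every proteome sequence whose best local alignment against any query meets
#' both the score and the identity threshold is recruited exactly once; a
#' sequence hit by several queries is recorded under its best-scoring query.
#' This is the in-package equivalent of an exhaustive protein-vs-proteome
#' similarity search.
#'
#' @param queries,proteomes [protein_set]s; `queries` needs at least one row,
#'   `proteomes` must be non-empty.
#' @param min_score Minimum local alignment score (substitution-matrix units).
#' @param min_identity Minimum identity fraction of the local alignment.
#' @param family_name Label stored on the result.
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return An object of class `homolog_set`: list with `family_name`,
#'   `members` (a [protein_set]) and `provenance` (data frame with one row per
#'   member: recruiting query, score, identity).
#' @export
collect_homologs <- function(queries, proteomes, min_score = 60,
                             min_identity = 0.25, family_name = "family",
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  if (!is.data.frame(queries) || nrow(queries) < 1L)
    stop("need at least one query sequence")
  if (!is.data.frame(proteomes) || nrow(proteomes) < 1L)
    stop("proteome list is empty")
  if (!is.finite(min_score) || !is.finite(min_identity))
    stop("thresholds must be finite")
  best_score <- rep(-Inf, nrow(proteomes))
  best_ident <- rep(NA_real_, nrow(proteomes))
  best_query <- rep(NA_character_, nrow(proteomes))
  for (q in seq_len(nrow(queries))) {
    for (s in seq_len(nrow(proteomes))) {
      aln <- align_pair(queries[q, ], proteomes[s, ], matrix = matrix,
                        gap_open = gap_open, gap_extend = gap_extend,
                        mode = "local")
      if (aln$score > best_score[s]) {
        best_score[s] <- aln$score
        best_ident[s] <- aln$identity_fraction
        best_query[s] <- queries$id[q]
      }
    }
  }
  keep <- best_score >= min_score & best_ident >= min_identity
  members <- proteomes[keep, , drop = FALSE]
  class(members) <- c("protein_set", "data.frame")
  out <- list(family_name = family_name, members = members,
              provenance = data.frame(
                id = proteomes$id[keep], query_id = best_query[keep],
                score = best_score[keep], identity = best_ident[keep],
                stringsAsFactors = FALSE))
  class(out) <- "homolog_set"
  out
}

#' @export
print.homolog_set <- function(x, ...) {
  cat(sprintf("<homolog_set '%s': %d members>\n", x$family_name,
              nrow(x$members)))
  invisible(x)
}

#' Remove near-identical sequences
#'
#' Greedy scan in input order: a sequence is dropped when its global percent
#' identity to any already-kept sequence is strictly greater than the
#' threshold. The first sequence is always kept and the kept set retains the
#' input order, so the operation is idempotent.
#'
#' @param seqs A [protein_set].
#' @param identity_threshold Identity fraction in (0, 1]; sequences strictly
#'   above it are removed. Default 0.90.
#' @param matrix,gap_open,gap_extend Passed to [align_pair()].
#' @return The kept subset of `seqs`.
#' @export
remove_redundant <- function(seqs, identity_threshold = 0.90,
                             matrix = blosum62(), gap_open = 11,
                             gap_extend = 1) {
  if (!is.data.frame(seqs) || nrow(seqs) < 1L)
    stop("need at least one sequence")
  if (!is.numeric(identity_threshold) || identity_threshold <= 0 ||
      identity_threshold > 1)
    stop("identity_threshold must lie in (0, 1]")
  kept <- 1L
  if (nrow(seqs) > 1L) {
    for (k in 2L:nrow(seqs)) {
      redundant <- FALSE
      for (j in kept) {
        aln <- align_pair(seqs[j, ], seqs[k, ], matrix = matrix,
                          gap_open = gap_open, gap_extend = gap_extend,
                          mode = "global")
        if (aln$identity_fraction > identity_threshold) {
          redundant <- TRUE
          break
        }
      }
      if (!redundant) kept <- c(kept, k)
    }
  }
  out <- seqs[kept, , drop = FALSE]
  class(out) <- c("protein_set", "data.frame")
  out
}
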