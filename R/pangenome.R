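# CGH presence/absence analysis: thresholding hybridization scores, variable
# gene filtering, co-occurrence (plasmid-linkage) clustering and family
# census tables.

#' Read a CGH score matrix from TSV
#'
#' Expects a header row of strain ids and one row per probe, first column the
#' gene id. Several probe rows may share a gene id; they are kept and
#' collapsed later by [call_presence()].
#'
#' @param path TSV file, genes x strains.
#' @return Numeric matrix with (possibly repeated) gene ids as rownames.
#' @export
read_cgh_scores <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("score table needs a gene column plus strains")
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- as.character(df[[1L]])
  if (anyDuplicated(colnames(m))) stop("duplicate strain ids in ", path)
  if (any(!is.finite(m))) stop("non-finite scores in ", path)
  m
}

#' Call gene presence/absence from CGH hybridization scores
#'
#' Probe rows sharing a gene id are collapsed (by maximum, the convention for
#' hybridization statistics, or by mean). A gene is called present in a
#' strain when its collapsed score is strictly greater than
#' `cutoff + ambiguity_halfwidth`, absent when it is at most
#' `cutoff - ambiguity_halfwidth`, and ambiguous in between. The default
#' cutoff 5.5 with the strict ">" reproduces the standard pangenome-array
#' calling rule; a score of exactly 5.5 is absent.
#'
#' @param scores Numeric matrix genes x strains (repeated gene rownames are
#'   probe replicates), e.g. from [read_cgh_scores()].
#' @param cutoff Presence cutoff (default 5.5).
#' @param ambiguity_halfwidth Half-width of the optional ambiguity band
#'   around the cutoff (default 0, band off).
#' @param collapse `"max"` or `"mean"` over probes of one gene.
#' @return A character matrix (class `presence_matrix`) of
#'   `"present"`/`"absent"`/`"ambiguous"` calls with attributes `cutoff`,
#'   `ambiguity_halfwidth` and `scores` (the collapsed score matrix).
#' @export
call_presence <- function(scores, cutoff = 5.5, ambiguity_halfwidth = 0,
                          collapse = c("max", "mean")) {
  collapse <- match.arg(collapse)
  if (!length(scores)) stop("empty score matrix")
  if (!is.finite(cutoff) || ambiguity_halfwidth < 0)
    stop("cutoff must be finite and ambiguity_halfwidth >= 0")
  genes <- unique(rownames(scores))
  if (is.null(genes)) stop("score matrix needs gene rownames")
  s <- matrix(NA_real_, length(genes), ncol(scores),
              dimnames = list(genes, colnames(scores)))
  f <- if (collapse == "max") max else mean
  for (g in genes) {
    block <- scores[rownames(scores) == g, , drop = FALSE]
    s[g, ] <- apply(block, 2L, f)
  }
  calls <- matrix("ambiguous", nrow(s), ncol(s), dimnames = dimnames(s))
  calls[s > cutoff + ambiguity_halfwidth] <- "present"
  calls[s <= cutoff - ambiguity_halfwidth] <- "absent"
  structure(calls, cutoff = cutoff,
            ambiguity_halfwidth = ambiguity_halfwidth, scores = s,
            class = c("presence_matrix", class(calls)))
}

#' Keep only genes with variable presence across strains
#'
#' Genes whose calls are constant across all strains (ambiguous counted as
#' absent) are dropped, mirroring the convention that presence/absence tables
#' list only variable genes. Idempotent.
#'
#' @param presence A `presence_matrix` from [call_presence()].
#' @return The filtered `presence_matrix` (possibly with zero rows).
#' @export
filter_variable <- function(presence) {
  if (!ncol(presence)) stop("presence matrix has no strains")
  bin <- presence == "present"
  keep <- apply(bin, 1L, function(r) any(r) && !all(r))
  out <- presence[keep, , drop = FALSE]
  for (a in c("cutoff", "ambiguity_halfwidth"))
    attr(out, a) <- attr(presence, a)
  sc <- attr(presence, "scores")
  if (!is.null(sc)) attr(out, "scores") <- sc[keep, , drop = FALSE]
  class(out) <- class(presence)
  out
}

#' Cluster co-occurring genes (putative plasmid linkage)
#'
#' Single-linkage clustering of genes on the Jaccard similarity of their
#' present-strain sets; genes joined at similarity >= `min_jaccard` fall in
#' one cluster. Blocks of genes gained and lost together — e.g. plasmid-borne
#' genes — surface as clusters of size >= 2.
#'
#' @param presence A `presence_matrix` with at least 2 genes.
#' @param min_jaccard Similarity threshold in (0, 1] (default 0.9).
#' @return List with `clusters` (list of gene-id vectors, size >= 2 first,
#'   singletons included at the end) and `membership` (named integer vector).
#' @export
cooccurrence_clusters <- function(presence, min_jaccard = 0.9) {
  if (nrow(presence) < 2L) stop("need at least 2 variable genes")
  bin <- presence == "present"
  n <- nrow(bin)
  J <- matrix(1, n, n, dimnames = list(rownames(bin), rownames(bin)))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      u <- sum(bin[i, ] | bin[j, ])
      J[i, j] <- J[j, i] <- if (u == 0) 0 else sum(bin[i, ] & bin[j, ]) / u
    }
  }
  hc <- stats::hclust(stats::as.dist(1 - J), method = "single")
  memb <- stats::cutree(hc, h = 1 - min_jaccard)
  cl <- split(names(memb), memb)
  cl <- cl[order(-lengths(cl), vapply(cl, `[`, character(1L), 1L))]
  names(cl) <- NULL
  list(clusters = cl, membership = memb)
}

#' Genome-by-family gene count census
#'
#' @param assignments Data frame with columns `gene`, `genome`, `family`
#'   (one row per gene), e.g. derived from orthologous groups.
#' @return List with `counts` (genome x family integer matrix) and
#'   `category` (0 absent / 1 single / 2 for two or more).
#' @export
family_census <- function(assignments) {
  need <- c("gene", "genome", "family")
  if (!all(need %in% names(assignments)))
    stop("assignments needs columns gene, genome, family")
  tab <- table(assignments$genome, assignments$family)
  counts <- matrix(as.integer(tab), nrow(tab), ncol(tab),
                   dimnames = dimnames(tab))
  list(counts = counts, category = pmin(counts, 2L))
}

#' Write a presence matrix as a strain-by-gene TSV
#'
#' Strains are rows and genes columns; present is `1`, absent `0`, ambiguous
#' `0?`, the notation used in published variable-gene tables.
#'
#' @param presence A `presence_matrix`.
#' @param file Output path.
#' @export
write_presence_tsv <- function(presence, file) {
  sym <- matrix("0?", nrow(presence), ncol(presence),
                dimnames = dimnames(presence))
  sym[presence == "present"] <- "1"
  sym[presence == "absent"] <- "0"
  out <- t(sym)
  df <- data.frame(strain = rownames(out), out, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
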