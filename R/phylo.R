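# Distance computation, neighbor-joining, bootstrap supports and Newick I/O.
# Trees are standard ape "phylo" objects; bootstrap supports live in
# node.label, duplication/speciation labels in tree$event (named by node
# number), orthologous-group ids in tree$group.

.aln_ids <- function(aln) {
  if (is.matrix(aln)) rownames(aln) else names(aln)
}

#' Convert a gapped alignment to a character matrix
#'
#' @param aln Named character vector of equal-length gapped strings, or an
#'   already-split character matrix (returned unchanged).
#' @return Character matrix, one row per sequence, one column per position.
#' @export
aln_matrix <- function(aln) {
  if (is.matrix(aln)) return(aln)
  w <- unique(nchar(aln))
  if (length(w) != 1L) stop("alignment rows differ in length")
  m <- do.call(rbind, strsplit(unname(aln), "", fixed = TRUE))
  rownames(m) <- names(aln)
  m
}

#' Pairwise distances from a multiple alignment
#'
#' The p-distance of two rows is 1 minus the identity over mutually non-gap
#' columns. With `correction = "poisson"` the Poisson multiple-hit correction
#' d = -ln(1 - p) is applied. A pair with no mutually non-gap column gets 1.1
#' times the maximum observed distance, with a warning.
#'
#' @param aln Alignment as in [aln_matrix()]; at least 2 rows.
#' @param correction `"none"` (p-distance) or `"poisson"`.
#' @return Symmetric numeric matrix with zero diagonal, ids as dimnames.
#' @export
msa_distances <- function(aln, correction = c("none", "poisson")) {
  correction <- match.arg(correction)
  m <- aln_matrix(aln)
  if (nrow(m) < 2L) stop("alignment must have at least 2 rows")
  n <- nrow(m)
  gap <- m == "-"
  D <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  empty <- NULL
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      comp <- !gap[i, ] & !gap[j, ]
      if (!any(comp)) {
        empty <- rbind(empty, c(i, j))
        next
      }
      p <- mean(m[i, comp] != m[j, comp])
      d <- if (correction == "poisson") {
        if (p >= 1) stop("p-distance 1 cannot be Poisson-corrected")
        -log(1 - p)
      } else p
      D[i, j] <- D[j, i] <- d
    }
  }
  if (!is.null(empty)) {
    warning(nrow(empty),
            " pair(s) share no comparable column; assigned 1.1 * max distance")
    fill <- 1.1 * max(D)
    for (k in seq_len(nrow(empty)))
      D[empty[k, 1L], empty[k, 2L]] <- D[empty[k, 2L], empty[k, 1L]] <- fill
  }
  D
}

# internal nested tree node: either list(leaf = TRUE, label = chr) or
# list(leaf = FALSE, kids = list(list(node=, len=), ...), support =, event =,
# group =). minleaf caches the smallest descendant leaf label.
.leaf_node <- function(label) list(leaf = TRUE, label = label, minleaf = label)

.join_nodes <- function(kids, lens, support = NA_real_, event = NA_character_,
                        group = NA_character_) {
  list(leaf = FALSE,
       kids = Map(function(n, l) list(node = n, len = l), kids, lens),
       support = support, event = event, group = group,
       minleaf = min(vapply(kids, `[[`, character(1L), "minleaf")))
}

# nested node -> phylo (with node.label from support, $event, $group)
.tree_to_phylo <- function(root) {
  tips <- character(0)
  edges <- NULL
  lens <- numeric(0)
  supports <- numeric(0)
  events <- character(0)
  groups <- character(0)
  n_tip <- local({
    cnt <- function(nd) if (nd$leaf) 1L else
      sum(vapply(nd$kids, function(k) cnt(k$node), integer(1L)))
    cnt(root)
  })
  tip_i <- 0L
  node_i <- n_tip
  rec <- function(nd) {
    if (nd$leaf) {
      tip_i <<- tip_i + 1L
      tips[tip_i] <<- nd$label
      return(tip_i)
    }
    node_i <<- node_i + 1L
    me <- node_i
    supports[me - n_tip] <<- if (is.null(nd$support)) NA_real_ else nd$support
    events[me - n_tip] <<- if (is.null(nd$event)) NA_character_ else nd$event
    groups[me - n_tip] <<- if (is.null(nd$group)) NA_character_ else nd$group
    for (k in nd$kids) {
      child <- rec(k$node)
      edges <<- rbind(edges, c(me, child))
      lens <<- c(lens, k$len)
    }
    me
  }
  rec(root)
  tr <- list(edge = edges, edge.length = lens, tip.label = tips,
             Nnode = node_i - n_tip)
  if (any(!is.na(supports))) tr$node.label <- supports
  class(tr) <- "phylo"
  if (any(!is.na(events))) {
    ev <- events
    names(ev) <- as.character((n_tip + 1L):node_i)
    tr$event <- ev
  }
  if (any(!is.na(groups))) {
    gr <- groups
    names(gr) <- as.character((n_tip + 1L):node_i)
    tr$group <- gr
  }
  tr
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining with the standard Q criterion. Ties in Q are
#' broken by the lexicographically smallest pair of cluster keys (the
#' smallest leaf id inside each cluster). Negative branch lengths are clamped
#' to zero; the total clamped deficit is attached as attribute
#' `"clamped_deficit"`. The final three-cluster join is closed-form, so the
#' returned tree is unrooted with a trifurcating root node.
#'
#' @param D Symmetric distance matrix with unique ids as dimnames; >= 3 taxa.
#' @return An unrooted `phylo` tree.
#' @export
neighbor_joining <- function(D) {
  if (!is.matrix(D) || nrow(D) != ncol(D)) stop("D must be a square matrix")
  ids <- rownames(D)
  if (is.null(ids) || anyDuplicated(ids)) stop("D needs unique row names")
  if (nrow(D) < 3L) stop("neighbor joining needs at least 3 taxa")
  if (max(abs(D - t(D))) > 1e-12) stop("D is not symmetric")
  nodes <- lapply(ids, .leaf_node)
  deficit <- 0
  while (length(nodes) > 3L) {
    n <- length(nodes)
    r <- rowSums(D)
    Q <- (n - 2) * D - outer(r, r, `+`)
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q == qmin, arr.ind = TRUE)
    cand <- cand[cand[, 1L] < cand[, 2L], , drop = FALSE]
    keys <- vapply(nodes, `[[`, character(1L), "minleaf")
    k1 <- pmin(keys[cand[, 1L]], keys[cand[, 2L]])
    k2 <- pmax(keys[cand[, 1L]], keys[cand[, 2L]])
    pick <- order(k1, k2)[1L]
    i <- cand[pick, 1L]
    j <- cand[pick, 2L]
    dij <- D[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (n - 2))
    lj <- dij - li
    if (li < 0) { deficit <- deficit - li; lj <- lj + li; li <- 0 }
    if (lj < 0) { deficit <- deficit - lj; li <- li + lj; lj <- 0 }
    new_node <- .join_nodes(list(nodes[[i]], nodes[[j]]), c(li, lj))
    dnew <- (D[i, ] + D[j, ] - dij) / 2
    keep <- setdiff(seq_len(n), c(i, j))
    D <- rbind(cbind(D[keep, keep, drop = FALSE], dnew[keep]),
               c(dnew[keep], 0))
    nodes <- c(nodes[keep], list(new_node))
  }
  d12 <- D[1L, 2L]; d13 <- D[1L, 3L]; d23 <- D[2L, 3L]
  l1 <- (d12 + d13 - d23) / 2
  l2 <- (d12 + d23 - d13) / 2
  l3 <- (d13 + d23 - d12) / 2
  ls <- c(l1, l2, l3)
  deficit <- deficit - sum(ls[ls < 0])
  ls[ls < 0] <- 0
  root <- .join_nodes(nodes, ls)
  tr <- .tree_to_phylo(root)
  attr(tr, "clamped_deficit") <- deficit
  tr
}

# leaf-label sets below each internal node (named by node number)
.clades <- function(tree) {
  n_tip <- length(tree$tip.label)
  post <- ape::reorder.phylo(tree, "postorder")
  sets <- vector("list", n_tip + tree$Nnode)
  for (k in seq_len(n_tip)) sets[[k]] <- tree$tip.label[k]
  for (e in seq_len(nrow(post$edge))) {
    p <- post$edge[e, 1L]; ch <- post$edge[e, 2L]
    sets[[p]] <- c(sets[[p]], sets[[ch]])
  }
  lapply(sets, sort)
}

# canonical bipartition key for an internal node's clade: take the side not
# containing the overall-smallest taxon, so both orientations hash equally
.bipart_keys <- function(tree) {
  tips <- sort(tree$tip.label)
  ref <- tips[1L]
  n_tip <- length(tips)
  sets <- .clades(tree)
  nodes <- (n_tip + 1L):(n_tip + tree$Nnode)
  keys <- vapply(nodes, function(nd) {
    s <- sets[[nd]]
    if (ref %in% s) s <- setdiff(tips, s)
    paste(s, collapse = "\r")
  }, character(1L))
  names(keys) <- as.character(nodes)
  keys
}

#' Neighbor-joining tree with bootstrap supports
#'
#' Columns of the alignment are resampled with replacement `n_replicates`
#' times; the support of an internal edge is the percentage of replicate NJ
#' trees containing the same leaf bipartition. Supports are stored in
#' `node.label` (the root, which carries no edge, gets `NA`). Results are
#' reproducible for a fixed seed.
#'
#' @param aln Alignment as in [aln_matrix()].
#' @param n_replicates Number of bootstrap replicates (>= 1); the full-scale
#'   analyses in the field use 1000.
#' @param seed Integer seed for the column resampling.
#' @param correction Distance correction, see [msa_distances()].
#' @return A `phylo` tree (the tree built from the original alignment) with
#'   numeric `node.label` supports in \[0, 100\].
#' @export
bootstrap_support <- function(aln, n_replicates = 1000L, seed = 1L,
                              correction = "none") {
  if (n_replicates < 1L) stop("n_replicates must be >= 1")
  m <- aln_matrix(aln)
  base <- neighbor_joining(msa_distances(m, correction))
  base_keys <- .bipart_keys(base)
  counts <- setNames(numeric(length(base_keys)), base_keys)
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
  set.seed(seed)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
  for (b in seq_len(n_replicates)) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    Db <- msa_distances(m[, cols, drop = FALSE], correction)
    kb <- .bipart_keys(neighbor_joining(Db))
    hit <- base_keys %in% kb
    counts[hit] <- counts[hit] + 1
  }
  supports <- 100 * counts / n_replicates
  n_tip <- length(base$tip.label)
  lab <- unname(supports)
  # the root node's "clade" is the full leaf set, not an internal edge
  sets <- .clades(base)
  root <- n_tip + 1L
  lab[match(as.character(root), names(base_keys))] <- NA_real_
  base$node.label <- lab
  base
}

# ---------------------------------------------------------------------------
# Newick I/O with NHX-style annotations: name:length[&&NHX:Ev=D:OG=1.2]
# Supports are written as internal node labels.

.fmt_len <- function(x) {
  if (is.na(x)) "" else paste0(":", format(x, digits = 15, scientific = FALSE,
                                           trim = TRUE))
}

.newick_node <- function(tree, node, sets) {
  n_tip <- length(tree$tip.label)
  kids <- tree$edge[tree$edge[, 1L] == node, 2L]
  lens <- tree$edge.length[tree$edge[, 1L] == node]
  ord <- order(vapply(kids, function(k) sets[[k]][1L], character(1L)))
  parts <- character(length(kids))
  for (z in seq_along(ord)) {
    k <- kids[ord[z]]
    l <- lens[ord[z]]
    parts[z] <- paste0(.newick_node(tree, k, sets),
                       if (is.null(tree$edge.length)) "" else .fmt_len(l),
                       .nhx_comment(tree, k))
  }
  if (node <= n_tip) return(tree$tip.label[node])
  lab <- ""
  if (!is.null(tree$node.label)) {
    v <- tree$node.label[node - n_tip]
    if (!is.na(v) && nzchar(as.character(v)))
      lab <- format(as.numeric(v), digits = 15, trim = TRUE)
  }
  paste0("(", paste(parts, collapse = ","), ")", lab)
}

.nhx_comment <- function(tree, node) {
  tags <- character(0)
  ev <- tree$event[as.character(node)]
  if (!is.null(tree$event) && !is.na(ev) && length(ev))
    tags <- c(tags, paste0("Ev=", unname(ev)))
  gr <- tree$group[as.character(node)]
  if (!is.null(tree$group) && !is.na(gr) && length(gr))
    tags <- c(tags, paste0("OG=", unname(gr)))
  if (!length(tags)) "" else paste0("[&&NHX:", paste(tags, collapse = ":"), "]")
}

#' Write a tree as annotated Newick
#'
#' Children are ordered canonically by their smallest descendant leaf label,
#' so equal trees serialize identically. Bootstrap supports (`node.label`)
#' become internal node labels; event labels (`tree$event`, values `"S"` or
#' `"D"`) and orthologous-group ids (`tree$group`) are written as
#' `[&&NHX:Ev=..:OG=..]` comments after the branch length.
#'
#' @param tree A `phylo` tree.
#' @param file Optional path; when `NULL` the Newick string is returned.
#' @return The Newick string, invisibly when written to a file.
#' @export
write_newick <- function(tree, file = NULL) {
  n_tip <- length(tree$tip.label)
  sets <- .clades(tree)
  root <- n_tip + 1L
  s <- paste0(.newick_node(tree, root, sets), .nhx_comment(tree, root), ";")
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read an annotated Newick string
#'
#' Accepts standard Newick with branch lengths, internal node labels
#' (interpreted as bootstrap supports when numeric) and `[&&NHX:...]`
#' comments carrying `Ev` (event) and `OG` (orthologous group) tags, the
#' dialect written by [write_newick()]. Malformed input raises an error
#' reporting the 1-based character offset.
#'
#' @param text A Newick string (or a path to a file containing one).
#' @return A `phylo` tree, with `node.label`, `$event`, `$group` populated
#'   when present in the input.
#' @export
read_newick <- function(text) {
  if (length(text) == 1L && !grepl("[();]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE), collapse = "")
  text <- trimws(text)
  pos <- 1L
  n <- nchar(text)
  peek <- function() if (pos <= n) substr(text, pos, pos) else ""
  fail <- function(msg) stop("Newick parse error at offset ", pos, ": ", msg)
  read_label <- function() {
    start <- pos
    while (pos <= n && !substr(text, pos, pos) %in%
           c("(", ")", ",", ":", ";", "[")) pos <<- pos + 1L
    substr(text, start, pos - 1L)
  }
  read_annot <- function(nd) {
    len <- NA_real_
    if (peek() == ":") {
      pos <<- pos + 1L
      start <- pos
      while (pos <= n && grepl("[-0-9.eE+]", substr(text, pos, pos)))
        pos <<- pos + 1L
      len <- suppressWarnings(as.numeric(substr(text, start, pos - 1L)))
      if (is.na(len)) fail("invalid branch length")
    }
    if (peek() == "[") {
      close <- regexpr("]", substr(text, pos, n), fixed = TRUE)
      if (close < 0) fail("unterminated comment")
      cmt <- substr(text, pos, pos + close - 1L)
      pos <<- pos + close
      body <- sub("^\\[&&NHX:?", "", sub("\\]$", "", cmt))
      if (nzchar(body)) {
        for (tag in strsplit(body, ":", fixed = TRUE)[[1L]]) {
          kv <- strsplit(tag, "=", fixed = TRUE)[[1L]]
          if (length(kv) == 2L) {
            if (kv[1L] == "Ev") nd$event <- kv[2L]
            if (kv[1L] == "OG") nd$group <- kv[2L]
          }
        }
      }
    }
    list(node = nd, len = len)
  }
  parse_node <- function() {
    if (peek() == "(") {
      pos <<- pos + 1L
      kids <- list()
      repeat {
        kids[[length(kids) + 1L]] <- parse_node()
        if (peek() == ",") { pos <<- pos + 1L; next }
        if (peek() == ")") { pos <<- pos + 1L; break }
        fail("expected ',' or ')'")
      }
      lab <- read_label()
      nd <- list(leaf = FALSE, kids = kids,
                 support = if (nzchar(lab))
                   suppressWarnings(as.numeric(lab)) else NA_real_,
                 event = NA_character_, group = NA_character_)
      nd$minleaf <- min(vapply(kids, function(k) k$node$minleaf,
                               character(1L)))
      read_annot(nd)
    } else {
      lab <- read_label()
      if (!nzchar(lab)) fail("expected a leaf label")
      read_annot(.leaf_node(lab))
    }
  }
  root <- parse_node()
  if (peek() != ";") fail("expected ';'")
  pos <- pos + 1L
  if (pos <= n) fail("trailing characters")
  fix <- function(k) {
    nd <- k$node
    if (!nd$leaf) nd$kids <- lapply(nd$kids, fix)
    list(node = nd, len = if (is.na(k$len)) NA_real_ else k$len)
  }
  root <- fix(root)
  tr <- .tree_to_phylo(root$node)
  if (!is.null(tr$edge.length) && all(is.na(tr$edge.length)))
    tr$edge.length <- NULL
  tr
}

#' Midpoint-root a tree
#'
#' Roots the tree at the midpoint of the longest leaf-to-leaf path, the
#' rooting used for orthology analysis. Bootstrap supports in `node.label`
#' are carried across the rerooting; event/group annotations are dropped
#' (they are assigned after rooting).
#'
#' @param tree A `phylo` tree.
#' @return A rooted `phylo` tree.
#' @export
midpoint_root <- function(tree) {
  tree$event <- NULL
  tree$group <- NULL
  has_sup <- !is.null(tree$node.label)
  if (has_sup) tree$node.label <- as.character(tree$node.label)
  out <- phangorn::midpoint(tree, node.labels = "support")
  if (has_sup) out$node.label <- suppressWarnings(as.numeric(out$node.label))
  out
}

#' Export a distance matrix in PHYLIP format
#'
#' @param D Square distance matrix with ids as dimnames.
#' @param file Output path.
#' @export
write_phylip_dist <- function(D, file) {
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%5d", nrow(D)), con)
  for (i in seq_len(nrow(D)))
    writeLines(paste(c(sprintf("%-10s", rownames(D)[i]),
                       sprintf("%.6f", D[i, ])), collapse = " "), con)
  invisible(file)
}
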