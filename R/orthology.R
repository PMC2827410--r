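# Species-overlap event labelling and orthologous-group extraction.
# An internal node is a duplication when the species sets of its child
# subtrees overlap, otherwise a speciation; orthologous groups (subfamilies)
# are the maximal duplication-free regions of the rooted gene tree.

.node_children <- function(tree, node)
  tree$edge[tree$edge[, 1L] == node, 2L]

#' Label tree nodes as speciation or duplication by species overlap
#'
#' Post-order rule: an internal node is a duplication (`"D"`) when at least
#' two of its child subtrees share a species, otherwise a speciation (`"S"`).
#' No species tree is required.
#'
#' @param tree A rooted `phylo` tree whose tip labels are sequence ids.
#' @param species Named character vector mapping every tip label to a
#'   species tag.
#' @return The tree with `tree$event`, a character vector named by internal
#'   node number with values `"S"`/`"D"`.
#' @export
label_events <- function(tree, species) {
  n_tip <- length(tree$tip.label)
  missing <- setdiff(tree$tip.label, names(species))
  if (length(missing))
    stop("no species mapping for leaf '", missing[1L], "'")
  post <- ape::reorder.phylo(tree, "postorder")
  spsets <- vector("list", n_tip + tree$Nnode)
  for (k in seq_len(n_tip))
    spsets[[k]] <- unname(species[tree$tip.label[k]])
  event <- setNames(rep(NA_character_, tree$Nnode),
                    as.character((n_tip + 1L):(n_tip + tree$Nnode)))
  nodes <- unique(post$edge[, 1L])
  for (nd in nodes) {
    kids <- .node_children(tree, nd)
    ksets <- lapply(kids, function(k) unique(spsets[[k]]))
    total <- unlist(ksets)
    dup <- anyDuplicated(total) > 0L
    event[as.character(nd)] <- if (dup) "D" else "S"
    spsets[[nd]] <- unique(total)
  }
  tree$event <- event[order(as.integer(names(event)))]
  tree
}

#' Extract orthologous groups from an event-labelled tree
#'
#' Every edge below a duplication node is cut; the leaves of each maximal
#' duplication-free region form one orthologous group (subfamily).
#' Hierarchical ids start at `"1"` for the root region and gain one dot level
#' per duplication node passed: the children of each duplication inside a
#' region are numbered `<prefix>.1`, `<prefix>.2`, ... in pre-order, with a
#' duplication's children ordered by their smallest leaf id. A region whose
#' only content is duplication nodes contributes no group of its own.
#'
#' @param tree A rooted `phylo` tree with `tree$event` (see [label_events()]).
#' @return An object of class `ortho_groups`: list with `groups` (named list
#'   of leaf-id vectors partitioning the tips), `membership` (named vector
#'   tip -> group id) and `tree` (input tree with `$group` set at each
#'   region's entry node).
#' @export
extract_groups <- function(tree) {
  if (is.null(tree$event)) stop("tree has no event labels; run label_events()")
  n_tip <- length(tree$tip.label)
  sets <- .clades(tree)
  groups <- list()
  node_group <- setNames(rep(NA_character_, tree$Nnode),
                         as.character((n_tip + 1L):(n_tip + tree$Nnode)))
  rec_region <- function(entry, prefix) {
    members <- character(0)
    dups <- integer(0)
    walk <- function(nd) {
      if (nd <= n_tip) {
        members <<- c(members, tree$tip.label[nd])
      } else if (identical(unname(tree$event[as.character(nd)]), "D")) {
        dups <<- c(dups, nd)
      } else {
        kids <- .node_children(tree, nd)
        for (k in kids[order(vapply(kids, function(x) sets[[x]][1L],
                                    character(1L)))]) walk(k)
      }
    }
    walk(entry)
    if (length(members)) groups[[prefix]] <<- members
    if (entry > n_tip) node_group[as.character(entry)] <<- prefix
    counter <- 0L
    for (d in dups) {
      kids <- .node_children(tree, d)
      kids <- kids[order(vapply(kids, function(x) sets[[x]][1L],
                                character(1L)))]
      for (k in kids) {
        counter <- counter + 1L
        rec_region(k, paste0(prefix, ".", counter))
      }
    }
  }
  rec_region(n_tip + 1L, "1")
  membership <- setNames(rep(NA_character_, n_tip), tree$tip.label)
  for (g in names(groups)) membership[groups[[g]]] <- g
  if (anyNA(membership)) stop("internal error: groups do not partition leaves")
  tree$group <- node_group
  out <- list(groups = groups, membership = membership, tree = tree)
  class(out) <- "ortho_groups"
  out
}

#' @export
print.ortho_groups <- function(x, ...) {
  cat(sprintf("<ortho_groups: %d groups over %d sequences>\n",
              length(x$groups), length(x$membership)))
  for (g in names(x$groups))
    cat(sprintf("  %-8s %s\n", g, paste(x$groups[[g]], collapse = ", ")))
  invisible(x)
}

#' Per-species copy-number census of orthologous groups
#'
#' Counts group members per species and adds the categorical layer used in
#' family-distribution figures: 0 (absent), 1 (single gene), 2 for two or
#' more genes.
#'
#' @param og An `ortho_groups` object (or a named list of leaf-id vectors).
#' @param species Named character vector mapping sequence ids to species.
#' @return List with `counts` (group x species integer matrix) and
#'   `category` (same shape, values 0, 1, 2 where 2 means ">= 2").
#' @export
group_census <- function(og, species) {
  groups <- if (inherits(og, "ortho_groups")) og$groups else og
  sp_levels <- sort(unique(unname(species)))
  counts <- matrix(0L, length(groups), length(sp_levels),
                   dimnames = list(names(groups), sp_levels))
  for (g in names(groups)) {
    ids <- groups[[g]]
    missing <- setdiff(ids, names(species))
    if (length(missing))
      stop("no species mapping for sequence '", missing[1L], "'")
    tab <- table(unname(species[ids]))
    counts[g, names(tab)] <- as.integer(tab)
  }
  category <- pmin(counts, 2L)
  list(counts = counts, category = category)
}

#' Split groups into major subfamilies and intermediate genes
#'
#' Groups with at least `min_size` members count as major subfamilies;
#' smaller groups are reported separately as intermediate genes.
#'
#' @param og An `ortho_groups` object.
#' @param min_size Minimum member count of a major subfamily (default 3).
#' @return List with `major` (named list of groups) and `intermediate`
#'   (character vector of sequence ids).
#' @export
major_groups <- function(og, min_size = 3L) {
  sizes <- lengths(og$groups)
  list(major = og$groups[sizes >= min_size],
       intermediate = unlist(og$groups[sizes < min_size], use.names = FALSE))
}
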