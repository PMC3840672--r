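# Gene-tree handling: Newick parsing with support values, filtering by
# mean bootstrap support, and decomposition of each gene tree into
# maximally inclusive subtrees with at most one sequence per taxon.
# Each extracted subtree is a set of putative orthologs; paralogous
# copies end up in different sets.

#' Parse a Newick gene tree
#'
#' Leaves are labeled \code{"<taxon_id>@<seq_id>"}; numeric internal
#' node labels are interpreted as bootstrap support values in [0, 100].
#' A light structural pre-check reports the character offset of
#' unbalanced parentheses before handing off to the tree reader.
#'
#' @param text a Newick string, or \code{file} a path.
#' @param file optional path to a Newick file (one tree).
#' @return An \code{ape} \code{phylo} object.
#' @export
parse_newick <- function(text = NULL, file = NULL) {
  if (is.null(text)) text <- paste(readLines(file), collapse = "")
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") depth <- depth - 1L
    if (depth < 0L)
      stop("unbalanced ')' at character ", i, " of Newick string")
  }
  if (depth != 0L)
    stop("unbalanced '(' in Newick string (", depth, " unclosed)")
  if (grepl(",\\s*[,)]", text))
    stop("dangling comma at character ",
         regexpr(",\\s*[,)]", text)[1L], " of Newick string")
  tree <- tryCatch(ape::read.tree(text = text),
                   error = function(e) NULL)
  if (is.null(tree)) stop("malformed Newick string")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf label: ",
         tree$tip.label[duplicated(tree$tip.label)][1L])
  tree
}

#' Write a gene tree to Newick
#'
#' @param tree a \code{phylo} object.
#' @param file optional output path; omitted returns the string.
#' @return The Newick string (invisibly when writing to a file).
#' @export
write_newick <- function(tree, file = NULL) {
  s <- ape::write.tree(tree)
  if (!is.null(file)) { writeLines(s, file); return(invisible(s)) }
  s
}

# Numeric support values from internal node labels; NA where absent.
node_supports <- function(tree) {
  if (is.null(tree$node.label)) return(numeric())
  sup <- suppressWarnings(as.numeric(tree$node.label))
  sup[!is.na(sup)]
}

#' Mean bootstrap support of a gene tree
#'
#' Arithmetic mean over the internal nodes that carry a numeric support
#' value; nodes without a value (e.g. the root of an unrooted reading)
#' are excluded from the average.
#'
#' @param tree a \code{phylo} object.
#' @return The mean support.
#' @export
mean_support <- function(tree) {
  sup <- node_supports(tree)
  if (length(sup) == 0L) stop("unsupported tree: no support values")
  mean(sup)
}

#' Filter gene trees by mean bootstrap support
#'
#' Eliminates gene trees with little phylogenetic signal before ortholog
#' decomposition, which also restricts ortholog selection to
#' well-supported trees. Trees carrying no support values at all are
#' excluded with a warning (never silently kept).
#'
#' @param trees list of \code{phylo} objects.
#' @param min_mean_support threshold; trees with mean support >= it are
#'   kept.
#' @return The surviving trees (names preserved), with attribute
#'   \code{n_dropped}.
#' @export
filter_trees_by_support <- function(trees, min_mean_support) {
  ms <- vapply(trees, function(t) {
    sup <- node_supports(t)
    if (length(sup) == 0L) NA_real_ else mean(sup)
  }, numeric(1))
  if (anyNA(ms))
    warning(sum(is.na(ms)), " tree(s) carry no support values; excluded")
  keep <- !is.na(ms) & ms >= min_mean_support
  structure(trees[keep], n_dropped = sum(!keep))
}

## ---- ortholog decomposition ---------------------------------------------

# All candidate leaf sets of the unrooted tree: the two sides of the
# bipartition induced by deleting each branch, plus the whole leaf set.
branch_leaf_sets <- function(tree) {
  tips <- tree$tip.label
  n <- length(tips)
  sets <- list(tips)
  if (n >= 2L && !is.null(tree$edge)) {
    # descendant tip set of every node of the (arbitrarily rooted)
    # representation; each edge's child-side clade is one bipartition
    # side, its complement the other.
    desc <- descendant_tips(tree)
    for (child in tree$edge[, 2L]) {
      side <- desc[[child]]
      sets[[length(sets) + 1L]] <- side
      sets[[length(sets) + 1L]] <- setdiff(tips, side)
    }
  }
  sets <- lapply(sets, sort)
  sets[lengths(sets) > 0L]
}

# Tip labels under every node, by a single postorder pass.
descendant_tips <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  desc <- vector("list", n_node)
  for (i in seq_len(n_tip)) desc[[i]] <- tree$tip.label[i]
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1L]; c <- tree$edge[e, 2L]
    desc[[p]] <- c(desc[[p]], desc[[c]])
  }
  desc
}

taxon_unique <- function(labels) !anyDuplicated(taxon_of(labels))

# Pick the best taxon-unique candidate: most leaves, then most distinct
# taxa, then lexicographically smallest sorted label list.
best_candidate <- function(sets) {
  sets <- unique(sets[vapply(sets, taxon_unique, logical(1))])
  if (length(sets) == 0L) return(NULL)
  sizes <- lengths(sets)
  ntaxa <- vapply(sets, function(s) length(unique(taxon_of(s))), integer(1))
  keys <- vapply(sets, paste, "", collapse = "\r")
  sets[[order(-sizes, -ntaxa, keys)[1L]]]
}

#' Decompose a gene tree into ortholog sets
#'
#' Iterative greedy extraction on the unrooted tree. Candidates are the
#' leaf sets induced by deleting each branch (both sides), plus the
#' whole leaf set. Among candidates with at most one sequence per
#' taxon, the one with the most leaves is extracted (ties: most
#' distinct taxa, then lexicographically smallest sorted label list),
#' its leaves are deleted (suppressing degree-2 nodes), and the process
#' repeats until no leaves remain. Singleton sets are emitted too;
#' downstream cluster filters decide their fate.
#'
#' @param tree a \code{phylo} gene tree with \code{"taxon@seq"} leaf
#'   labels (a single label string is accepted for a one-leaf tree).
#' @param rooted if \code{TRUE}, only clades of the rooted tree (not
#'   bipartition complements) are candidates; for comparison only.
#' @return List of ortholog sets: each a list with \code{labels}
#'   (sorted character) and \code{rank} (extraction order).
#' @export
prune_orthologs <- function(tree, rooted = FALSE) {
  out <- list()
  current <- tree
  repeat {
    labels <- if (is.character(current)) current else current$tip.label
    if (length(labels) == 0L) break
    if (length(labels) <= 2L) {
      sets <- c(list(sort(labels)), as.list(sort(labels)))
    } else if (rooted) {
      sets <- lapply(descendant_tips(current), sort)
      sets <- sets[lengths(sets) > 0L]
    } else {
      sets <- branch_leaf_sets(current)
    }
    pick <- best_candidate(sets)
    if (is.null(pick)) pick <- sort(labels)[1L]   # unreachable in practice
    out[[length(out) + 1L]] <- list(labels = pick,
                                    rank = length(out) + 1L)
    rest <- setdiff(labels, pick)
    if (length(rest) == 0L) break
    current <- if (length(rest) <= 2L || is.character(current)) rest
    else ape::keep.tip(current, rest)
  }
  out
}

#' Convert ortholog sets to clusters
#'
#' Pruned subtrees re-enter the workflow as clusters (source
#' \code{treeprune}) for re-alignment and supermatrix assembly.
#'
#' @param ortholog_sets list as returned by [prune_orthologs], possibly
#'   concatenated over trees.
#' @param prefix cluster-id prefix.
#' @return Named list of character vectors.
#' @export
orthologs_to_clusters <- function(ortholog_sets, prefix = "o") {
  setNames(lapply(ortholog_sets, `[[`, "labels"),
           paste0(prefix, seq_along(ortholog_sets)))
}
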