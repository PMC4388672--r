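## Split extraction, majority-rule consensus with percent supports, and
## Newick import/export (via ape).

#' Nontrivial bipartitions of an unrooted tree
#'
#' Each internal edge of an unrooted tree induces a bipartition (split) of
#' the leaf set. Splits are returned in canonical form: the side NOT
#' containing the alphabetically first leaf, as a sorted character vector.
#' Trivial splits (single leaves) are omitted.
#'
#' @param tree A `phylo` object.
#' @return List of sorted character vectors, one per nontrivial split.
#' @export
tree_splits <- function(tree) {
  n <- length(tree$tip.label)
  ref <- sort(tree$tip.label)[1]
  ## tips under each internal node (rooted view); works for any root
  kids <- split(tree$edge[, 2], tree$edge[, 1])
  tips_under <- function(node) {
    out <- integer(0)
    stack <- node
    while (length(stack)) {
      v <- stack[[1]]; stack <- stack[-1]
      if (v <= n) out <- c(out, v) else stack <- c(stack, kids[[as.character(v)]])
    }
    out
  }
  root <- setdiff(tree$edge[, 1], tree$edge[, 2])[1]
  internal <- setdiff(unique(tree$edge[, 2]), seq_len(n))
  splits <- list()
  for (v in internal) {
    side <- tree$tip.label[tips_under(v)]
    if (length(side) <= 1 || length(side) >= n - 1) next
    if (ref %in% side) side <- setdiff(tree$tip.label, side)
    splits[[length(splits) + 1]] <- sort(side)
  }
  unique(splits)
}

split_compatible <- function(a, b, leaves) {
  ## two splits are compatible iff one of the four intersections is empty
  ac <- setdiff(leaves, a); bc <- setdiff(leaves, b)
  !length(intersect(a, b)) || !length(intersect(a, bc)) ||
    !length(intersect(ac, b)) || !length(intersect(ac, bc))
}

#' Majority-rule consensus with percent support
#'
#' Scores every nontrivial split by the percentage of input trees that
#' contain it (0-100, rounded to integer) and retains those with support
#' at or above `collapse_cutoff`; everything else is collapsed. For
#' cutoffs >= 50 the retained set is automatically pairwise compatible
#' (majority-rule property); for lower cutoffs splits are admitted
#' greedily by decreasing support, skipping any split incompatible with
#' those already kept.
#'
#' @param trees List of `phylo` trees over an identical leaf set (a
#'   `multiPhylo` is accepted).
#' @param collapse_cutoff Integer percent in [1, 100]; splits below it are
#'   collapsed.
#' @return An object of class `consensus_tree`: leaves, retained splits,
#'   integer supports, cutoff and replicate count.
#' @export
majority_consensus <- function(trees, collapse_cutoff = 50) {
  trees <- unclass(trees)
  if (!length(trees)) abort("invalid_tree", "no trees supplied")
  if (collapse_cutoff < 1 || collapse_cutoff > 100) {
    abort("bad_parameter", "collapse_cutoff must be in [1, 100]")
  }
  leaves <- sort(trees[[1]]$tip.label)
  for (t in trees) {
    if (!identical(sort(t$tip.label), leaves)) {
      abort("leafset_mismatch", "all trees must share one leaf set")
    }
  }
  keys <- unlist(lapply(trees, function(t) {
    ## a ~zero-length internal edge is an unresolved polytomy, not a split:
    ## collapse it so exactly-tied distances cannot manufacture support
    if (!is.null(t$edge.length)) t <- ape::di2multi(t, tol = 1e-10)
    vapply(tree_splits(t), paste, character(1), collapse = "\r")
  }))
  if (!length(keys)) {
    return(structure(list(leaves = leaves, splits = list(), support = integer(0),
                          collapse_cutoff = as.integer(collapse_cutoff),
                          n_trees = length(trees)),
                     class = "consensus_tree"))
  }
  tab <- sort(table(keys), decreasing = TRUE)
  support <- as.integer(round(100 * as.numeric(tab) / length(trees)))
  splits <- strsplit(names(tab), "\r", fixed = TRUE)
  keep <- support >= collapse_cutoff
  splits <- splits[keep]; support <- support[keep]
  ord <- order(-support, vapply(splits, paste, character(1), collapse = "\r"))
  splits <- splits[ord]; support <- support[ord]
  retained <- list(); ret_support <- integer(0)
  for (k in seq_along(splits)) {
    ok <- all(vapply(retained, split_compatible, logical(1),
                     b = splits[[k]], leaves = leaves))
    if (ok) {
      retained[[length(retained) + 1]] <- splits[[k]]
      ret_support <- c(ret_support, support[k])
    }
  }
  structure(list(leaves = leaves, splits = retained, support = ret_support,
                 collapse_cutoff = as.integer(collapse_cutoff),
                 n_trees = length(trees)),
            class = "consensus_tree")
}

#' @export
print.consensus_tree <- function(x, ...) {
  cat(sprintf("<consensus_tree> %d leaves, %d retained split(s) at cutoff %d (from %d trees)\n",
              length(x$leaves), length(x$splits), x$collapse_cutoff, x$n_trees))
  for (k in seq_along(x$splits)) {
    cat(sprintf("  [%3d%%] %s\n", x$support[k], paste(x$splits[[k]], collapse = ", ")))
  }
  invisible(x)
}

#' Support of a given clade in a consensus tree
#'
#' Looks up the percent support of the split separating `clade` from the
#' remaining leaves; 0 if the split was collapsed.
#'
#' @param consensus A `consensus_tree`.
#' @param clade Character vector of leaf labels (either side of the split).
#' @return Integer support in [0, 100].
#' @export
clade_support <- function(consensus, clade) {
  ref <- consensus$leaves[1]
  side <- sort(clade)
  if (ref %in% side) side <- setdiff(consensus$leaves, side)
  key <- paste(sort(side), collapse = "\r")
  hits <- vapply(consensus$splits, paste, character(1), collapse = "\r") == key
  if (any(hits)) consensus$support[which(hits)[1]] else 0L
}

#' Convert a consensus to a phylo tree
#'
#' Builds the (possibly multifurcating) tree whose internal edges are the
#' retained splits, with percent supports stored as internal node labels.
#'
#' @param consensus A `consensus_tree`.
#' @return A `phylo` object with node labels carrying supports.
#' @export
consensus_to_phylo <- function(consensus) {
  leaves <- consensus$leaves
  clusters <- consensus$splits           # canonical sides exclude leaves[1]
  support <- consensus$support
  ord <- order(-lengths(clusters))
  clusters <- clusters[ord]; support <- support[ord]
  build <- function(set, cluster_idx) {
    idx <- cluster_idx[vapply(cluster_idx, function(k) {
      all(clusters[[k]] %in% set) && length(clusters[[k]]) < length(set)
    }, logical(1))]
    ## maximal sub-clusters of this set
    maximal <- idx[vapply(idx, function(k) {
      !any(vapply(idx, function(j) {
        j != k && all(clusters[[k]] %in% clusters[[j]])
      }, logical(1)))
    }, logical(1))]
    used <- unlist(clusters[maximal])
    free <- setdiff(set, used)
    parts <- c(
      lapply(maximal, function(k) {
        paste0(build(clusters[[k]], idx), support[k])
      }),
      as.list(free)
    )
    paste0("(", paste(unlist(parts), collapse = ","), ")")
  }
  newick <- paste0(build(leaves, seq_along(clusters)), ";")
  ape::read.tree(text = newick)
}

#' Write a tree or consensus to Newick text
#'
#' Thin wrapper over [ape::write.tree()]; a `consensus_tree` is first
#' converted with [consensus_to_phylo()] so percent supports appear as
#' internal node labels.
#'
#' @param tree A `phylo` or `consensus_tree`.
#' @param path Optional file path; when `NULL` the Newick string is
#'   returned.
#' @return Newick string (invisibly when written to file).
#' @export
write_newick <- function(tree, path = NULL) {
  if (inherits(tree, "consensus_tree")) tree <- consensus_to_phylo(tree)
  txt <- ape::write.tree(tree)
  if (is.null(path)) return(txt)
  writeLines(txt, path, useBytes = TRUE)
  invisible(txt)
}

#' Read a Newick tree
#'
#' @param text Newick string (or `NULL` to read from `path`).
#' @param path File path.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, path = NULL) {
  tr <- if (is.null(text)) {
    tryCatch(ape::read.tree(path), error = function(e) NULL, warning = function(w) NULL)
  } else {
    tryCatch(ape::read.tree(text = text), error = function(e) NULL, warning = function(w) NULL)
  }
  if (is.null(tr)) abort("parse_error", "malformed Newick input")
  tr
}
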