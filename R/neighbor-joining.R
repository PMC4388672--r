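## Neighbor-joining tree construction. Implemented in-package so that the
## join tie-break and the negative-branch convention are pinned down and
## deterministic; trees are returned as ape "phylo" objects.

#' Neighbor-joining tree from a distance matrix
#'
#' Classic agglomerative neighbor joining: at each step the pair
#' minimising the Q criterion Q_ij = (n - 2) d_ij - r_i - r_j (r_i the row
#' sum) is joined, limb lengths follow the standard formulas, and the
#' matrix is reduced with d_uk = (d_ik + d_jk - d_ij) / 2. Additive
#' (tree-like) matrices are recovered exactly. Two conventions make runs
#' deterministic and lengths interpretable:
#' ties on Q are broken by joining the pair whose (sorted) pair of
#' smallest-member labels is lexicographically smallest, and a negative
#' limb length is clamped to zero with the deficit transferred to its
#' sister limb (their sum is preserved).
#'
#' @param D Symmetric numeric matrix with unique row/column labels, zero
#'   diagonal, finite entries, at least 3 taxa.
#' @return An unrooted `phylo` tree (trifurcating root node).
#' @export
neighbor_joining <- function(D) {
  D <- as.matrix(D)
  labels <- rownames(D)
  n <- nrow(D)
  if (is.null(labels) || anyDuplicated(labels)) {
    abort("invalid_matrix", "distance matrix must carry unique labels")
  }
  if (n < 3) abort("invalid_matrix", "need at least 3 taxa")
  if (any(!is.finite(D))) abort("invalid_matrix", "distance matrix contains non-finite entries")
  if (max(abs(D - t(D))) > 1e-9) abort("invalid_matrix", "distance matrix must be symmetric")

  ## active nodes: ids 1..n are tips; internal ids allocated from n+1
  active <- seq_len(n)
  rep_label <- labels            # representative (smallest member) label per active node
  edges <- matrix(integer(0), 0, 2)
  lens <- numeric(0)
  next_id <- n + 1L
  Dm <- D

  add_edge <- function(parent, child, len) {
    edges <<- rbind(edges, c(parent, child))
    lens <<- c(lens, len)
  }

  while (length(active) > 3) {
    m <- length(active)
    r <- rowSums(Dm)
    Q <- (m - 2) * Dm - outer(r, r, "+")
    diag(Q) <- Inf
    qmin <- min(Q)
    cand <- which(Q - qmin <= 1e-12 * max(1, abs(qmin)), arr.ind = TRUE)
    cand <- cand[cand[, 1] < cand[, 2], , drop = FALSE]
    key <- vapply(seq_len(nrow(cand)), function(k) {
      pair <- sort(c(rep_label[cand[k, 1]], rep_label[cand[k, 2]]))
      paste(pair, collapse = "\r")
    }, character(1))
    pick <- cand[order(key)[1], ]
    i <- pick[1]; j <- pick[2]

    dij <- Dm[i, j]
    li <- dij / 2 + (r[i] - r[j]) / (2 * (m - 2))
    lj <- dij - li
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    li <- max(li, 0); lj <- max(lj, 0)

    new_id <- next_id; next_id <- next_id + 1L
    add_edge(new_id, active[i], li)
    add_edge(new_id, active[j], lj)

    dk <- (Dm[i, ] + Dm[j, ] - dij) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    Dm2 <- rbind(cbind(Dm[keep, keep, drop = FALSE], dk[keep]), c(dk[keep], 0))
    Dm <- Dm2
    new_label <- min(rep_label[c(i, j)])
    active <- c(active[keep], new_id)
    rep_label <- c(rep_label[keep], new_label)
    dimnames(Dm) <- NULL
  }

  ## resolve the final three nodes around a trifurcating root
  root <- next_id
  la <- (Dm[1, 2] + Dm[1, 3] - Dm[2, 3]) / 2
  lb <- (Dm[1, 2] + Dm[2, 3] - Dm[1, 3]) / 2
  lc <- (Dm[1, 3] + Dm[2, 3] - Dm[1, 2]) / 2
  add_edge(root, active[1], max(la, 0))
  add_edge(root, active[2], max(lb, 0))
  add_edge(root, active[3], max(lc, 0))

  ## renumber internal nodes so the root is n+1, as phylo requires
  internal <- c(root, setdiff(sort(unique(edges[, 1])), root))
  remap <- stats::setNames(seq_along(internal) + n, internal)
  renum <- function(v) ifelse(v > n, remap[as.character(v)], v)
  phy <- structure(list(
    edge = cbind(as.integer(renum(edges[, 1])), as.integer(renum(edges[, 2]))),
    edge.length = lens,
    tip.label = labels,
    Nnode = length(internal)
  ), class = "phylo")
  ape::reorder.phylo(phy, "cladewise")
}
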