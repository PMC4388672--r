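five_leaf <- function(txt) ape::unroot(ape::read.tree(text = txt))

test_that("tree_splits agrees with ape::prop.part on random trees", {
  set.seed(15)
  for (k in 1:10) {
    tr <- ape::unroot(ape::rtree(8))
    ref <- sort(tr$tip.label)[1]
    pp <- ape::prop.part(tr)
    ape_sides <- lapply(pp, function(idx) sort(attr(pp, "labels")[idx]))
    ape_sides <- lapply(ape_sides, function(s) {
      if (ref %in% s) sort(setdiff(tr$tip.label, s)) else s
    })
    ape_sides <- unique(Filter(function(s) length(s) > 1 && length(s) < 7, ape_sides))
    expect_setequal(lapply(tree_splits(tr), paste, collapse = "|"),
                    lapply(ape_sides, paste, collapse = "|"))
  }
})

test_that("consensus of identical trees is that topology with support 100", {
  tr <- five_leaf("((a,b),(c,d),e);")
  cs <- majority_consensus(rep(list(tr), 100), 50)
  expect_identical(cs$support, rep(100L, length(cs$splits)))
  expect_setequal(lapply(cs$splits, paste, collapse = "|"),
                  lapply(tree_splits(tr), paste, collapse = "|"))
})

test_that("supports equal direct split counts and respect the cutoff", {
  t1 <- five_leaf("(((a,b),c),d,e);")     # contains {a,b} and {a,b,c}
  t2 <- five_leaf("((a,b),(c,d),e);")     # contains {a,b} and {c,d}
  t3 <- five_leaf("((a,c),(b,d),e);")     # contains {a,c} and {b,d}
  cs50 <- majority_consensus(list(t1, t2, t3), 50)
  expect_identical(clade_support(cs50, c("a", "b")), 67L)  # 2/3 rounded
  expect_identical(clade_support(cs50, c("c", "d")), 0L)   # 1/3 -> 33, collapsed
  cs90 <- majority_consensus(list(t1, t2, t3), 90)
  expect_identical(clade_support(cs90, c("a", "b")), 0L)   # collapsed at 90
  # clade given as the complementary side resolves to the same split
  expect_identical(clade_support(cs50, c("c", "d", "e")), 67L)
})

test_that("pairwise topology-disjoint trees collapse to a star", {
  t1 <- five_leaf("((a,b),(c,d),e);")
  t2 <- five_leaf("((a,c),(b,e),d);")
  t3 <- five_leaf("((a,d),(b,c),e);")
  cs <- majority_consensus(list(t1, t2, t3), 50)
  expect_length(cs$splits, 0)
})

test_that("supports are invariant under permutation of the tree sequence", {
  set.seed(16)
  trees <- replicate(9, ape::unroot(ape::rtree(7, tip.label = letters[1:7])),
                     simplify = FALSE)
  c1 <- majority_consensus(trees, 30)
  c2 <- majority_consensus(rev(trees), 30)
  k1 <- setNames(c1$support, vapply(c1$splits, paste, character(1), collapse = "|"))
  k2 <- setNames(c2$support, vapply(c2$splits, paste, character(1), collapse = "|"))
  expect_mapequal(as.list(k1), as.list(k2))
})

test_that("retained splits are pairwise compatible at majority cutoffs", {
  set.seed(17)
  for (k in 1:8) {
    base <- ape::unroot(ape::rtree(8, tip.label = letters[1:8]))
    noise <- replicate(5, ape::unroot(ape::rtree(8, tip.label = letters[1:8])),
                       simplify = FALSE)
    trees <- c(rep(list(base), 6), noise)   # base splits clear the cutoff
    cs <- majority_consensus(trees, 50)
    expect_gte(length(cs$splits), 2)
    leaves <- cs$leaves
    for (i in seq_along(cs$splits)) {
      for (j in seq_len(i - 1L)) {
        a <- cs$splits[[i]]; b <- cs$splits[[j]]
        ac <- setdiff(leaves, a); bc <- setdiff(leaves, b)
        compat <- !length(intersect(a, b)) || !length(intersect(a, bc)) ||
          !length(intersect(ac, b)) || !length(intersect(ac, bc))
        expect_true(compat)
      }
    }
  }
})

test_that("zero-length internal edges are treated as polytomies, not splits", {
  tr <- ape::read.tree(text = "((a:1,b:1):0,(c:1,d:1):1,e:1);")
  cs <- majority_consensus(rep(list(tr), 10), 50)
  keys <- vapply(cs$splits, paste, character(1), collapse = "|")
  expect_false("a|b" %in% keys)
  expect_true("c|d" %in% keys)
})

test_that("mismatched leaf sets are refused", {
  t1 <- five_leaf("((a,b),(c,d),e);")
  t2 <- five_leaf("((a,b),(c,d),f);")
  expect_error(majority_consensus(list(t1, t2)), class = "isonymia_leafset_mismatch")
})

test_that("Newick text round-trips trees and carries consensus supports", {
  tr <- read_newick("(a:1,b:2,(c:1,d:1):0.5);")
  expect_identical(sort(tr$tip.label), c("a", "b", "c", "d"))
  expect_identical(read_newick(write_newick(tr))$edge, tr$edge)
  expect_error(read_newick("((a,b;"), class = "isonymia_parse_error")

  t1 <- five_leaf("(((a,b),c),d,e);")
  t2 <- five_leaf("((a,b),(c,d),e);")
  t3 <- five_leaf("((a,c),(b,d),e);")
  txt <- write_newick(majority_consensus(list(t1, t2, t3), 50))
  expect_match(txt, "67")
  round_trip <- read_newick(txt)
  expect_true("67" %in% round_trip$node.label)
})

test_that("randomized trees round-trip write/read preserving their split sets", {
  set.seed(18)
  for (k in 1:10) {
    tr <- ape::unroot(ape::rtree(sample(5:10, 1)))
    back <- read_newick(write_newick(tr))
    expect_setequal(lapply(tree_splits(back), paste, collapse = "|"),
                    lapply(tree_splits(tr), paste, collapse = "|"))
  }
})
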