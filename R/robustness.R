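## Robustness machinery: surname-type bootstrap of token tables, noise
## injection for externally supplied distance matrices, and the composite
## replicate -> NJ -> consensus pipelines.

#' Surname-type bootstrap replicates of a token table
#'
#' Resamples the S surname types with replacement: in each replicate a
#' surname drawn k times has its count column multiplied by k and a
#' surname drawn zero times is absent. This reweights surnames between
#' replicates (rather than resampling individual tokens), so each
#' replicate probes how much the classification leans on particular
#' surnames.
#'
#' @param table Region-level `token_table` with at least 2 surnames.
#' @param replicates Number of bootstrap replicates.
#' @param seed Integer seed for reproducibility.
#' @return List of `token_table` replicates.
#' @export
bootstrap_tables <- function(table, replicates = 100, seed = NULL) {
  S <- ncol(table$counts)
  if (S < 2) abort("degenerate_corpus", "need at least 2 surname types to bootstrap")
  with_seed(seed, lapply(seq_len(replicates), function(r) {
    draw <- sample.int(S, S, replace = TRUE)
    mult <- tabulate(draw, nbins = S)
    keep <- mult > 0
    counts <- sweep(table$counts[, keep, drop = FALSE], 2, mult[keep], "*")
    token_table(counts, level = table$level,
                region_population = table$region_population)
  }))
}

#' Noise-injected replicates of a distance matrix
#'
#' Adds independent zero-mean perturbations to the off-diagonal entries:
#' d'_ij = max(0, d_ij + eps_ij) with eps_ij uniform on
#' [-noise_level * m, +noise_level * m], m the mean off-diagonal distance.
#' Symmetry and the zero diagonal are preserved. This is the replicate
#' generator for noisy clustering of matrices whose underlying raw data
#' (e.g. dialectometric feature tables) are unavailable for bootstrap.
#'
#' @param D Finite symmetric labeled distance matrix.
#' @param noise_level Noise amplitude as a fraction of the mean
#'   off-diagonal distance.
#' @param replicates Number of replicates.
#' @param seed Integer seed.
#' @return List of perturbed matrices.
#' @export
noisy_matrices <- function(D, noise_level = 0.5, replicates = 100, seed = NULL) {
  if (noise_level < 0) abort("bad_parameter", "noise_level must be non-negative")
  if (any(!is.finite(D))) abort("invalid_matrix", "matrix must be finite")
  n <- nrow(D)
  m <- mean(D[upper.tri(D)])
  amp <- noise_level * m
  with_seed(seed, lapply(seq_len(replicates), function(r) {
    eps <- matrix(0, n, n)
    eps[upper.tri(eps)] <- stats::runif(n * (n - 1) / 2, -amp, amp)
    eps <- eps + t(eps)
    out <- pmax(D + eps, 0)
    diag(out) <- 0
    dimnames(out) <- dimnames(D)
    out
  }))
}

#' Bootstrap NJ consensus of a surname corpus
#'
#' The full robustness pipeline for surname data: surname-type bootstrap
#' replicates, a Nei or Hedrick distance matrix and an NJ tree per
#' replicate, then the majority-rule consensus with percent supports.
#' Replicates whose distance matrix contains infinite entries (regions
#' left with disjoint surname sets) are rejected and redrawn; their count
#' is reported in the result.
#'
#' @param table Region-level `token_table`.
#' @param kind Distance kind, `"nei"` or `"hedrick"`.
#' @param replicates Number of accepted replicates (default 100).
#' @param collapse_cutoff Consensus support cutoff (percent).
#' @param seed Integer seed.
#' @return A `consensus_tree` with extra fields `rejected` (replicates
#'   redrawn) and `trees` (the accepted NJ trees).
#' @export
bootstrap_consensus_pipeline <- function(table, kind = c("nei", "hedrick"),
                                         replicates = 100, collapse_cutoff = 50,
                                         seed = NULL) {
  kind <- match.arg(kind)
  if (nrow(table$counts) == 2) {
    ## two regions: only the trivial split exists, no tree to build
    return(structure(list(leaves = sort(rownames(table$counts)), splits = list(),
                          support = integer(0),
                          collapse_cutoff = as.integer(collapse_cutoff),
                          n_trees = replicates, rejected = 0L, trees = list()),
                     class = "consensus_tree"))
  }
  seeds <- stage_seeds(seed, 2)
  rejected <- 0L
  trees <- list()
  with_seed(seeds[1], {
    attempts <- 0L
    max_attempts <- 2L * replicates
    while (length(trees) < replicates && attempts < max_attempts) {
      attempts <- attempts + 1L
      rep_tab <- bootstrap_tables(table, 1)[[1]]
      D <- tryCatch(distance_matrix(rep_tab, kind = kind),
                    isonymia_empty_region = function(e) NULL)
      if (is.null(D) || attr(D, "has_infinite")) {
        rejected <- rejected + 1L
        next
      }
      trees[[length(trees) + 1]] <- neighbor_joining(D)
    }
  })
  if (length(trees) < replicates) {
    abort("unstable_corpus",
          "more than half of bootstrap replicates rejected (%d rejections)", rejected)
  }
  out <- majority_consensus(trees, collapse_cutoff = collapse_cutoff)
  out$rejected <- rejected
  out$trees <- trees
  out
}

#' Noisy-clustering consensus of a distance matrix
#'
#' Robustness pipeline for externally supplied distance matrices: noise
#' injection replicates, an NJ tree per replicate, majority-rule
#' consensus. The conventional cutoff is higher (90) than for bootstrap
#' because structures probed this way are typically more stable.
#'
#' @param D Finite symmetric labeled distance matrix.
#' @param noise_level Fraction of the mean off-diagonal distance.
#' @param replicates Number of replicates.
#' @param collapse_cutoff Consensus support cutoff (percent).
#' @param seed Integer seed.
#' @return A `consensus_tree` (with the replicate NJ trees attached).
#' @export
noisy_consensus_pipeline <- function(D, noise_level = 0.5, replicates = 100,
                                     collapse_cutoff = 90, seed = NULL) {
  reps <- noisy_matrices(D, noise_level = noise_level, replicates = replicates,
                         seed = seed)
  trees <- lapply(reps, neighbor_joining)
  out <- majority_consensus(trees, collapse_cutoff = collapse_cutoff)
  out$trees <- trees
  out
}
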