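## Isonymy module: isonymy, Hedrick and Nei similarity coefficients,
## their log-distance transforms, surname entropy and pairwise distance
## matrices between regions.

align_freqs <- function(freq_i, freq_j) {
  if (!is.null(names(freq_i)) || !is.null(names(freq_j))) {
    if (is.null(names(freq_i)) || is.null(names(freq_j))) {
      abort("bad_frequency", "either both or neither frequency vector may be named")
    }
    support <- union(names(freq_i), names(freq_j))
    fi <- fj <- stats::setNames(numeric(length(support)), support)
    fi[names(freq_i)] <- freq_i
    fj[names(freq_j)] <- freq_j
    list(fi = fi, fj = fj)
  } else {
    if (length(freq_i) != length(freq_j)) {
      abort("bad_frequency", "unnamed frequency vectors must have equal length")
    }
    list(fi = freq_i, fj = freq_j)
  }
}

check_freq <- function(f, tol = 1e-8) {
  if (any(!is.finite(f)) || any(f < 0)) abort("bad_frequency", "frequencies must be finite and non-negative")
  s <- sum(f)
  if (s == 0) abort("bad_frequency", "all-zero frequency vector")
  if (abs(s - 1) > tol) abort("bad_frequency", "frequencies must sum to 1 (got %.6f)", s)
  invisible(f)
}

#' Between-location isonymy
#'
#' The probability that a surname token drawn at random in location i and
#' one drawn in location j are identical: I_ij = sum_s n_si n_sj, where
#' n_si is the relative frequency of surname s in location i. Equals 0
#' when the two locations share no surname and 1 when both consist of a
#' single identical surname.
#'
#' @param freq_i,freq_j Relative frequency vectors (non-negative, summing
#'   to 1). Named vectors are aligned on the union of their surnames;
#'   unnamed vectors must share the same support index.
#' @return Isonymy in [0, 1].
#' @export
isonymy_between <- function(freq_i, freq_j) {
  a <- align_freqs(freq_i, freq_j)
  check_freq(a$fi); check_freq(a$fj)
  sum(a$fi * a$fj)
}

#' Within-location (random) isonymy
#'
#' Random isonymy of a single location, sum of squared frequencies: the
#' probability that two tokens drawn with replacement share a surname.
#' High values indicate low surname diversity. The plug-in estimator is
#' the default; `unbiased = TRUE` uses the sampling-without-replacement
#' form sum n_s (n_s - 1) / (N (N - 1)), which requires raw counts.
#'
#' @param freq Relative frequency vector (or raw counts when
#'   `unbiased = TRUE`).
#' @param unbiased Use the unbiased small-sample estimator on counts?
#' @return Random isonymy in (0, 1].
#' @export
random_isonymy <- function(freq, unbiased = FALSE) {
  if (unbiased) {
    n <- freq
    if (any(n < 0) || any(n != round(n))) {
      abort("bad_frequency", "unbiased estimator requires integer counts")
    }
    N <- sum(n)
    if (N < 2) abort("bad_frequency", "need at least two tokens")
    return(sum(n * (n - 1)) / (N * (N - 1)))
  }
  check_freq(freq)
  sum(freq^2)
}

#' Hedrick similarity coefficient
#'
#' Shared-surname probability normalised by the arithmetic mean of the two
#' within-location isonymies:
#' H = sum_s n_si n_sj / (0.5 (sum n_si^2 + sum n_sj^2)). H = 1 when the
#' two frequency vectors are identical; 0 for disjoint surname sets. Not
#' scale invariant: it must be fed relative frequencies, not counts.
#'
#' @inheritParams isonymy_between
#' @return Similarity in [0, 1].
#' @export
hedrick_similarity <- function(freq_i, freq_j) {
  a <- align_freqs(freq_i, freq_j)
  check_freq(a$fi); check_freq(a$fj)
  sum(a$fi * a$fj) / (0.5 * (sum(a$fi^2) + sum(a$fj^2)))
}

#' Nei similarity coefficient
#'
#' Shared-surname probability normalised by the geometric mean of the two
#' within-location isonymies: N = sum_s n_si n_sj /
#' sqrt(sum n_si^2 sum n_sj^2) — the cosine of the two frequency vectors,
#' hence scale invariant and 1 iff the vectors are proportional.
#'
#' @inheritParams isonymy_between
#' @param normalized Require inputs to sum to 1? The cosine is scale-free,
#'   so raw counts are accepted when `FALSE`.
#' @return Similarity in [0, 1].
#' @export
nei_similarity <- function(freq_i, freq_j, normalized = TRUE) {
  a <- align_freqs(freq_i, freq_j)
  if (normalized) { check_freq(a$fi); check_freq(a$fj) }
  if (sum(a$fi) == 0 || sum(a$fj) == 0) abort("bad_frequency", "all-zero vector")
  sum(a$fi * a$fj) / sqrt(sum(a$fi^2) * sum(a$fj^2))
}

#' Log-transform a similarity into a distance
#'
#' d = -log(similarity): 0 for identical populations, growing without
#' bound as the overlap vanishes. A zero similarity (disjoint surname
#' sets) yields `Inf`, which downstream tree construction refuses rather
#' than silently capping. The logarithm base only rescales all distances
#' globally (leaving tree topologies and Mantel correlations unchanged);
#' natural log is the default.
#'
#' @param sim Similarity value(s) in [0, 1].
#' @param base Logarithm base.
#' @return Non-negative distance(s); `Inf` where `sim == 0`.
#' @export
similarity_to_distance <- function(sim, base = exp(1)) {
  if (any(sim < -1e-12 | sim > 1 + 1e-12)) abort("bad_similarity", "similarity outside [0, 1]")
  d <- -log(pmin(pmax(sim, 0), 1)) / log(base)
  d[sim >= 1] <- 0
  d
}

#' Shannon entropy of a surname frequency vector
#'
#' -sum_s n_s log(n_s) (natural log by default): 0 for a single surname,
#' log(S) for a uniform distribution over S surnames. Together with random
#' isonymy it summarises a region's surname diversity; across regions the
#' two are strongly anti-correlated.
#'
#' @param freq Relative frequency vector.
#' @param base Logarithm base.
#' @return Non-negative entropy.
#' @export
surname_entropy <- function(freq, base = exp(1)) {
  check_freq(freq)
  p <- freq[freq > 0]
  -sum(p * log(p)) / log(base)
}

#' Per-region diversity statistics
#'
#' Random isonymy and surname entropy for each region of a token table —
#' the two diversity columns of the province summary.
#'
#' @param table Region-level `token_table`.
#' @return `data.frame` with columns region, isonymy, entropy.
#' @export
region_diversity <- function(table) {
  f <- token_frequencies(table)
  data.frame(region = rownames(f),
             isonymy = apply(f, 1, function(p) sum(p^2)),
             entropy = apply(f, 1, function(p) surname_entropy(p)),
             row.names = NULL)
}

#' Pairwise surname distance matrix between regions
#'
#' Computes the chosen similarity coefficient for every pair of regions on
#' their relative surname frequencies and applies the log-distance
#' transform. Region pairs with disjoint surname sets get `Inf` and the
#' matrix is flagged via `attr(, "has_infinite")`.
#'
#' @param table Region-level `token_table` with at least 3 regions.
#' @param kind `"nei"` or `"hedrick"`.
#' @param base Logarithm base for the distance transform.
#' @return Symmetric matrix with zero diagonal, region dimnames, and
#'   attributes `kind` and `has_infinite`.
#' @export
distance_matrix <- function(table, kind = c("nei", "hedrick"), base = exp(1)) {
  kind <- match.arg(kind)
  if (table$level != "region") abort("wrong_level", "distances require a region-level table")
  if (nrow(table$counts) < 3) abort("invalid_table", "need at least 3 regions")
  f <- token_frequencies(table)
  cross <- f %*% t(f)               # cross[i, j] = sum_s n_si n_sj
  self <- diag(cross)
  sim <- switch(kind,
    nei = cross / sqrt(outer(self, self)),
    hedrick = cross / (0.5 * outer(self, self, "+"))
  )
  sim <- pmin(sim, 1)
  d <- similarity_to_distance(sim, base = base)
  diag(d) <- 0
  d <- (d + t(d)) / 2
  dimnames(d) <- list(rownames(f), rownames(f))
  attr(d, "kind") <- kind
  attr(d, "has_infinite") <- any(!is.finite(d))
  d
}

#' Read / write a square labeled distance matrix
#'
#' PHYLIP square format: a first line with the number of taxa, then one
#' row per taxon (label followed by the full row of distances,
#' whitespace-separated).
#'
#' @param D Symmetric labeled matrix.
#' @param path File path.
#' @return `read_phylip_matrix()` returns a labeled symmetric matrix.
#' @export
write_phylip_matrix <- function(D, path) {
  labels <- rownames(D)
  lines <- c(format(nrow(D)),
             vapply(seq_len(nrow(D)), function(i) {
               paste(c(labels[i], sprintf("%.10g", D[i, ])), collapse = "\t")
             }, character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_phylip_matrix
#' @export
read_phylip_matrix <- function(path) {
  lines <- readLines(path, encoding = "UTF-8")
  n <- suppressWarnings(as.integer(trimws(lines[1])))
  if (is.na(n) || length(lines) < n + 1) abort("parse_error", "malformed PHYLIP matrix")
  parts <- strsplit(trimws(lines[2:(n + 1)]), "[ \t]+")
  labels <- vapply(parts, `[[`, character(1), 1)
  D <- t(vapply(parts, function(p) as.numeric(p[-1]), numeric(n)))
  dimnames(D) <- list(labels, labels)
  D
}
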