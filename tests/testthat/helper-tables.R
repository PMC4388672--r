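# Shared fixtures built in code.

toy_table <- function(counts, level = "region", population = NULL) {
  token_table(as.matrix(counts), level = level, region_population = population)
}

rand_freq <- function(n, names = NULL) {
  x <- stats::runif(n)
  x <- x / sum(x)
  if (!is.null(names)) names(x) <- names
  x
}

# standard filtered pipeline used across tests
standard_pipeline <- function(roster, municipal = 5, global = 20) {
  filter_global(aggregate_regions(filter_municipal(tokenize(roster), municipal)), global)
}

# random symmetric zero-diagonal "distance" matrix (not metric; fine for Mantel)
rand_dist <- function(n, labels = sprintf("L%02d", seq_len(n))) {
  M <- matrix(stats::runif(n * n), n, n)
  M <- (M + t(M)) / 2
  diag(M) <- 0
  dimnames(M) <- list(labels, labels)
  M
}
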