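## Matrix-level statistics: Mantel permutation test, representativeness
## regression, percent-agreement (RIW-style) linguistic similarity and
## its distance transform.

#' Mantel permutation test between two distance matrices
#'
#' Pearson correlation over the strictly lower-triangular entries of two
#' distance matrices on the same labels, with significance from joint
#' row/column permutations of the second matrix. The p-value is two-sided
#' with the add-one convention:
#' p = (1 + #(|r*| >= |r|)) / (1 + permutations).
#'
#' @param A,B Symmetric labeled matrices with identical labels in
#'   identical order.
#' @param permutations Number of permutations.
#' @param seed Integer seed.
#' @return A list of class `mantel_result`: `r`, `p_value`,
#'   `permutations`.
#' @export
mantel_test <- function(A, B, permutations = 9999, seed = NULL) {
  if (!identical(rownames(A), rownames(B)) || is.null(rownames(A))) {
    abort("label_mismatch", "matrices must carry identical labels in identical order")
  }
  lt <- lower.tri(A)
  r <- stats::cor(A[lt], B[lt])
  n <- nrow(A)
  r_perm <- with_seed(seed, vapply(seq_len(permutations), function(k) {
    p <- sample.int(n)
    stats::cor(A[lt], B[p, p][lt])
  }, numeric(1)))
  p_value <- (1 + sum(abs(r_perm) >= abs(r))) / (1 + permutations)
  structure(list(r = r, p_value = p_value, permutations = permutations),
            class = "mantel_result")
}

#' @export
print.mantel_result <- function(x, ...) {
  cat(sprintf("Mantel r = %.4f, p = %.4g (%d permutations)\n",
              x$r, x$p_value, x$permutations))
  invisible(x)
}

#' Ordinary least-squares regression with optional label exclusion
#'
#' OLS of y on x with intercept, dropping labeled observations listed in
#' `exclude` first (e.g. outlying provinces excluded from the
#' representativeness regression). Returns both the coefficient of
#' determination and its adjusted form, plus the two-sided slope p-value.
#'
#' @param x,y Numeric vectors of equal length.
#' @param labels Optional labels for the observations.
#' @param exclude Labels to drop before fitting.
#' @return A list of class `regression_result`: `slope`, `intercept`,
#'   `r_squared`, `adj_r_squared`, `p_value`, `n`.
#' @export
linear_regression <- function(x, y, labels = NULL, exclude = character()) {
  stopifnot(length(x) == length(y))
  if (length(exclude)) {
    if (is.null(labels)) abort("label_mismatch", "exclusion requires labels")
    keep <- !(labels %in% exclude)
    x <- x[keep]; y <- y[keep]
  }
  if (length(x) < 3) abort("degenerate_predictor", "need at least 3 observations")
  if (stats::var(x) == 0) abort("degenerate_predictor", "predictor has zero variance")
  if (stats::var(y) == 0) {
    ## constant response: the regression explains nothing
    return(structure(list(slope = 0, intercept = y[1], r_squared = 0,
                          adj_r_squared = 0, p_value = NA_real_, n = length(x)),
                     class = "regression_result"))
  }
  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = sm$r.squared,
                 adj_r_squared = sm$adj.r.squared,
                 p_value = sm$coefficients[2, 4],
                 n = length(x)),
            class = "regression_result")
}

#' @export
print.regression_result <- function(x, ...) {
  cat(sprintf("OLS slope = %.4g, R2 = %.3f (adj %.3f), p = %.4g, n = %d\n",
              x$slope, x$r_squared, x$adj_r_squared, x$p_value, x$n))
  invisible(x)
}

#' Percent-agreement similarity between two feature vectors
#'
#' The relative identity value used in dialectometry: the percentage of
#' jointly observed items on which two categorical feature vectors (e.g.
#' basilectal variants over survey items) agree. Items missing (`NA`) in
#' either vector are excluded pairwise.
#'
#' @param features_a,features_b Equal-length categorical vectors.
#' @return Similarity in [0, 100].
#' @export
riw_similarity <- function(features_a, features_b) {
  if (length(features_a) != length(features_b)) {
    abort("label_mismatch", "feature vectors must have equal length")
  }
  joint <- !is.na(features_a) & !is.na(features_b)
  if (!any(joint)) abort("empty_overlap", "no jointly observed items")
  100 * mean(features_a[joint] == features_b[joint])
}

#' Pairwise percent-agreement similarity matrix
#'
#' @param features Matrix of categorical features (rows = varieties,
#'   columns = items; `NA` = not surveyed).
#' @return Symmetric similarity matrix in [0, 100] with diagonal 100.
#' @export
riw_matrix <- function(features) {
  n <- nrow(features)
  S <- matrix(100, n, n, dimnames = list(rownames(features), rownames(features)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      S[i, j] <- S[j, i] <- riw_similarity(features[i, ], features[j, ])
    }
  }
  S
}

#' Linguistic distance from a percent-agreement similarity matrix
#'
#' d = 1 - RIW/100: the percentage similarity is rescaled to [0, 1]
#' before the complement so distances stay in [0, 1] with zero diagonal.
#'
#' @param riw Symmetric similarity matrix with values in [0, 100] and
#'   diagonal 100.
#' @return Labeled symmetric distance matrix in [0, 1].
#' @export
riw_to_distance <- function(riw) {
  if (any(riw < 0 | riw > 100)) abort("bad_similarity", "RIW values must lie in [0, 100]")
  if (any(diag(as.matrix(riw)) != 100)) abort("bad_similarity", "RIW diagonal must be 100")
  d <- 1 - as.matrix(riw) / 100
  diag(d) <- 0
  attr(d, "kind") <- "linguistic"
  d
}
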