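test_that("isonymy matches its closed-form limits on small vectors", {
  expect_equal(isonymy_between(c(A = 1), c(A = 1)), 1)
  expect_equal(isonymy_between(c(A = .5, B = .5), c(C = .5, D = .5)), 0)
  expect_equal(isonymy_between(c(A = .5, B = .5), c(A = .5, C = .5)), 0.25)
  expect_equal(random_isonymy(rep(.25, 4)), 0.25)
  expect_equal(random_isonymy(1), 1)
  expect_equal(random_isonymy(c(.9, .1)), 0.82)
  expect_error(isonymy_between(c(A = .5, B = .6), c(A = 1)),
               class = "isonymia_bad_frequency")
})

test_that("unbiased random isonymy equals the without-replacement collision probability", {
  n <- c(A = 3L, B = 2L, C = 1L)
  # enumerate all ordered pairs of distinct tokens
  tokens <- rep(names(n), n)
  pairs <- expand.grid(i = seq_along(tokens), j = seq_along(tokens))
  pairs <- pairs[pairs$i != pairs$j, ]
  expected <- mean(tokens[pairs$i] == tokens[pairs$j])
  expect_equal(random_isonymy(n, unbiased = TRUE), expected)
})

test_that("Hedrick and Nei coefficients match hand-computed values", {
  expect_equal(hedrick_similarity(c(A = .5, B = .5), c(A = .5, B = .5)), 1)
  expect_equal(hedrick_similarity(c(A = .5, B = .5), c(A = .5, C = .5)), 0.5)
  expect_equal(hedrick_similarity(c(A = 1), c(B = 1)), 0)
  expect_equal(nei_similarity(c(A = .5, B = .5), c(A = .5, B = .5)), 1)
  expect_equal(nei_similarity(c(A = .5, B = .5), c(A = .5, C = .5)), 0.5)
  expect_equal(nei_similarity(c(A = 1), c(B = 1)), 0)
})

test_that("coefficients are bounded, symmetric; Nei is scale-free, Hedrick is not", {
  set.seed(101)
  for (k in 1:40) {
    nm <- sample(LETTERS, 8)
    fi <- rand_freq(8, nm[1:8])
    fj <- rand_freq(6, sample(c(nm[1:3], sample(letters, 3))))
    vals <- c(isonymy_between(fi, fj), hedrick_similarity(fi, fj),
              nei_similarity(fi, fj))
    expect_true(all(vals >= 0 & vals <= 1))
    expect_equal(isonymy_between(fj, fi), vals[1])
    expect_equal(hedrick_similarity(fj, fi), vals[2])
    expect_equal(nei_similarity(fj, fi), vals[3])
  }
  ci <- c(A = 30, B = 20, C = 10); cj <- c(A = 5, B = 10, D = 40)
  fi <- ci / sum(ci); fj <- cj / sum(cj)
  expect_equal(nei_similarity(ci, cj, normalized = FALSE), nei_similarity(fi, fj))
  # the Hedrick ratio computed on raw counts differs from its value on frequencies
  hed_counts <- sum(ci * cj) / (0.5 * (sum(ci^2) + sum(cj^2)))
  expect_false(isTRUE(all.equal(hed_counts, hedrick_similarity(fi, fj))))
})

test_that("random isonymy equals the Monte-Carlo token collision probability", {
  set.seed(202)
  f <- rand_freq(12, sprintf("S%02d", 1:12))
  draws <- 1e5
  a <- sample(names(f), draws, TRUE, prob = f)
  b <- sample(names(f), draws, TRUE, prob = f)
  p_hat <- mean(a == b)
  p <- random_isonymy(f)
  se <- sqrt(p * (1 - p) / draws)
  expect_lt(abs(p_hat - p), 3 * se)
})

test_that("log-distance transform maps similarity 1 to 0 and 0 to Inf", {
  expect_equal(similarity_to_distance(1), 0)
  expect_equal(similarity_to_distance(0.5), log(2))
  expect_identical(similarity_to_distance(0), Inf)
  # base only rescales
  expect_equal(similarity_to_distance(0.5, base = 10), log10(2))
})

test_that("surname entropy has its closed-form extremes", {
  expect_equal(surname_entropy(1), 0)
  expect_equal(surname_entropy(rep(.25, 4)), log(4))
  S <- 37
  expect_equal(surname_entropy(rep(1 / S, S)), log(S), tolerance = 1e-12)
})

test_that("distance_matrix agrees with an element-wise scalar recomputation", {
  set.seed(303)
  counts <- matrix(rpois(4 * 15, 8) + 1L, 4, 15,
                   dimnames = list(paste0("R", 1:4), sprintf("S%02d", 1:15)))
  tt <- toy_table(counts)
  for (kind in c("nei", "hedrick")) {
    D <- distance_matrix(tt, kind)
    f <- sweep(counts, 1, rowSums(counts), "/")
    for (i in 1:4) for (j in 1:4) {
      if (i == j) { expect_identical(D[i, j], 0); next }
      sim <- if (kind == "nei") nei_similarity(f[i, ], f[j, ])
             else hedrick_similarity(f[i, ], f[j, ])
      expect_equal(D[i, j], similarity_to_distance(sim), tolerance = 1e-12)
    }
    expect_identical(D, t(D))
  }
})

test_that("identical regions give zero distances; disjoint regions are flagged infinite", {
  same <- toy_table(matrix(rep(c(5L, 3L, 2L), each = 3), 3, 3,
                           dimnames = list(paste0("R", 1:3), LETTERS[1:3])))
  Dz <- distance_matrix(same, "nei")
  expect_true(all(Dz == 0))
  expect_false(attr(Dz, "has_infinite"))

  dm <- diag(3) * 10L
  dimnames(dm) <- list(paste0("R", 1:3), LETTERS[1:3])
  disj <- toy_table(dm)
  Dd <- distance_matrix(disj, "nei")
  expect_true(attr(Dd, "has_infinite"))
  expect_true(all(is.infinite(Dd[upper.tri(Dd)])))
})

test_that("region diversity recovers isonymy and entropy per region", {
  tt <- toy_table(rbind(R1 = c(A = 1L, B = 0L), R2 = c(A = 1L, B = 1L),
                        R3 = c(A = 3L, B = 1L)))
  d <- region_diversity(tt)
  expect_equal(d$isonymy, c(1, 0.5, 0.625))
  expect_equal(d$entropy, c(0, log(2), -(0.75 * log(0.75) + 0.25 * log(0.25))))
})

test_that("PHYLIP square matrices round-trip", {
  set.seed(9)
  D <- rand_dist(6)
  p <- withr::local_tempfile(fileext = ".phy")
  write_phylip_matrix(D, p)
  D2 <- read_phylip_matrix(p)
  expect_equal(D2, D, tolerance = 1e-9, ignore_attr = TRUE)
  expect_identical(rownames(D2), rownames(D))
  expect_error(read_phylip_matrix(withr::local_tempfile(lines = "not a matrix")),
               class = "isonymia_parse_error")
})
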