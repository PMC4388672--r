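test_that("normalize_name canonicalizes case and whitespace, preserving accents", {
  expect_identical(normalize_name("  rodríguez "), "RODRÍGUEZ")
  expect_identical(normalize_name("DIAZ"), "DIAZ")
  expect_identical(normalize_name("de  la   fuente"), "DE LA FUENTE")
  expect_identical(normalize_name("rodríguez", strip_accents = TRUE), "RODRIGUEZ")
  expect_error(normalize_name("   "), class = "isonymia_invalid_name")
})

test_that("tokenize splits double surnames into one token per surname", {
  r <- surname_roster("i1", "R1", "M1", "Rodriguez", "Diaz")
  tt <- tokenize(r)
  expect_identical(tt$counts["M1", c("RODRIGUEZ", "DIAZ")],
                   c(RODRIGUEZ = 1L, DIAZ = 1L))
  expect_identical(sum(tt$counts), 2L)

  single <- surname_roster("i1", "R1", "M1", "Smith", NA)
  expect_identical(sum(tokenize(single)$counts), 1L)

  both_same <- surname_roster(c("i1", "i2"), "R1", "M1", c("A", "A"), c("A", "A"))
  expect_identical(tokenize(both_same)$counts["M1", "A"], 4L)
})

test_that("token count is conserved: 2 per double- plus 1 per single-surname record", {
  set.seed(42)
  n <- 500
  has_mat <- runif(n) < 0.7
  r <- surname_roster(
    sprintf("i%03d", 1:n),
    region = sample(c("R1", "R2"), n, TRUE),
    municipality = NA,
    surname_paternal = sample(LETTERS[1:6], n, TRUE),
    surname_maternal = ifelse(has_mat, sample(LETTERS[1:6], n, TRUE), NA)
  )
  r$municipality <- paste0(r$region, "_", sample(1:3, n, TRUE))
  expect_identical(sum(tokenize(r)$counts), as.integer(2 * sum(has_mat) + sum(!has_mat)))
})

test_that("municipal cutoff zeroes sub-threshold cells per municipality", {
  counts <- rbind(town1 = c(X = 4L, Y = 5L), town2 = c(X = 7L, Y = 0L))
  tt <- toy_table(counts, level = "municipality")
  f <- filter_municipal(tt, 5)
  expect_identical(f$counts["town1", ], c(X = 0L, Y = 5L))
  expect_identical(f$counts["town2", "X"], 7L)  # per-municipality scope
  expect_identical(filter_municipal(tt, 1)$counts, tt$counts)
  expect_error(filter_municipal(toy_table(counts, "region"), 5),
               class = "isonymia_wrong_level")
})

test_that("aggregation sums municipality counts within regions", {
  counts <- rbind(t1 = c(X = 5L), t2 = c(X = 7L))
  tt <- token_table(counts, "municipality",
                    municipality_region = c(t1 = "R", t2 = "R"))
  expect_identical(aggregate_regions(tt)$counts["R", "X"], 12L)

  # singleton mapping renames, keeps counts
  tt1 <- token_table(rbind(t1 = c(X = 3L, Y = 1L)), "municipality",
                     municipality_region = c(t1 = "Solo"))
  agg1 <- aggregate_regions(tt1)
  expect_identical(unname(agg1$counts["Solo", ]), c(3L, 1L))

  expect_error(aggregate_regions(token_table(counts, "municipality")),
               class = "isonymia_mapping_gap")
})

test_that("aggregation equals a brute-force per-cell sum and preserves totals", {
  set.seed(7)
  counts <- matrix(rpois(7 * 5, 4), 7, 5,
                   dimnames = list(sprintf("m%d", 1:7), LETTERS[1:5]))
  mapping <- setNames(sample(c("R1", "R2", "R3"), 7, TRUE), rownames(counts))
  agg <- aggregate_regions(token_table(counts, "municipality"), mapping)
  for (reg in rownames(agg$counts)) {
    for (s in colnames(agg$counts)) {
      expect_identical(agg$counts[reg, s],
                       sum(counts[names(mapping)[mapping == reg], s]))
    }
  }
  expect_identical(colSums(agg$counts), colSums(counts))
})

test_that("global cutoff keeps surnames with nationwide total at or above threshold", {
  counts <- rbind(R1 = c(A = 10L, B = 12L, C = 150L),
                  R2 = c(A = 9L, B = 8L, C = 150L))
  tt <- toy_table(counts)
  expect_identical(colnames(filter_global(tt, 20)$counts), c("B", "C"))  # B at boundary kept
  expect_identical(filter_global(tt, 0)$counts, tt$counts)
  expect_error(filter_global(tt, 1000), class = "isonymia_empty_corpus")
  expect_error(filter_global(toy_table(counts, "municipality"), 20),
               class = "isonymia_wrong_level")
})

test_that("global cutoff on a Zipf-sampled corpus matches an independent recount", {
  set.seed(11)
  S <- 60
  w <- (1:S)^-1.2; w <- w / sum(w)
  counts <- rbind(R1 = as.integer(rmultinom(1, 800, w)),
                  R2 = as.integer(rmultinom(1, 600, w)),
                  R3 = as.integer(rmultinom(1, 400, w)))
  colnames(counts) <- sprintf("S%02d", 1:S)
  keep_brute <- colnames(counts)[colSums(counts) >= 20]
  tt <- filter_global(toy_table(counts), 20)
  expect_setequal(colnames(tt$counts), keep_brute)
})

test_that("frequency filters are monotone in their threshold", {
  set.seed(3)
  counts <- matrix(rpois(6 * 8, 6), 6, 8,
                   dimnames = list(sprintf("m%d", 1:6), LETTERS[1:8]))
  tt <- toy_table(counts, "municipality")
  f3 <- filter_municipal(tt, 3)$counts
  f6 <- filter_municipal(tt, 6)$counts
  shared <- intersect(colnames(f3), colnames(f6))
  expect_true(all(f6[, shared] == 0 | f6[, shared] == f3[, shared]))
  expect_true(all(f6[, shared] <= f3[, shared]))
})

test_that("full pipeline order equals an independent brute-force recount", {
  sc <- generate_scenario(scenario_config(individuals_per_region = 800, seed = 9))
  tt <- standard_pipeline(sc$roster)

  # brute force: long token list -> per-municipality filter -> aggregate -> global filter
  r <- sc$roster
  long <- data.frame(
    region = c(r$region, r$region[!is.na(r$surname_maternal)]),
    muni = c(r$municipality, r$municipality[!is.na(r$surname_maternal)]),
    name = toupper(c(r$surname_paternal, r$surname_maternal[!is.na(r$surname_maternal)]))
  )
  cell <- aggregate(list(n = rep(1L, nrow(long))), long[c("region", "muni", "name")], sum)
  cell <- cell[cell$n >= 5, ]
  reg <- aggregate(list(n = cell$n), cell[c("region", "name")], sum)
  tot <- tapply(reg$n, reg$name, sum)
  reg <- reg[reg$name %in% names(tot)[tot >= 20], ]

  expect_identical(sum(tt$counts), sum(reg$n))
  for (k in sample(nrow(reg), 25)) {
    expect_identical(unname(tt$counts[reg$region[k], reg$name[k]]),
                     as.integer(reg$n[k]))
  }
})

test_that("corpus_summary reports N, S, S/N and tokens per capita", {
  tt <- toy_table(rbind(R1 = c(A = 10L, B = 0L)), population = c(R1 = 100))
  s <- corpus_summary(tt)
  expect_equal(s$n_tokens, 10)
  expect_equal(s$s_surnames, 1)
  expect_equal(s$s_over_n, 0.1)
  expect_equal(s$tokens_per_capita, 0.1)

  tt2 <- toy_table(rbind(R1 = c(A = 2L, B = 3L, C = 5L)))
  s2 <- corpus_summary(tt2)
  expect_equal(s2$s_over_n, 0.3)
  expect_error(corpus_summary(tt2, require_population = TRUE),
               class = "isonymia_missing_metadata")
})

test_that("roster and token-table round-trip through their TSV formats", {
  r <- surname_roster(c("i1", "i2"), c("R1", "R1"), c("M1", "M2"),
                      c("García", "Pérez"), c("López", NA))
  p <- withr::local_tempfile(fileext = ".tsv")
  write_roster(r, p)
  r2 <- read_roster(p)
  expect_identical(as.data.frame(r2), as.data.frame(r))

  tt <- toy_table(rbind(R1 = c(A = 5L, B = 2L), R2 = c(A = 0L, B = 7L)),
                  population = c(R1 = 50, R2 = 60))
  p2 <- withr::local_tempfile(fileext = ".tsv")
  write_token_table(tt, p2, cutoffs = list(municipal = 5, global = 20))
  tt2 <- read_token_table(p2)
  got <- tt2$counts[rownames(tt$counts), colnames(tt$counts)]
  expect_equal(got, tt$counts, ignore_attr = TRUE)
  expect_identical(dimnames(got)[[1]], rownames(tt$counts))
  expect_equal(tt2$region_population[names(tt$region_population)],
               tt$region_population)
})
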