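## Corpus module: roster parsing, tokenization of double surnames, the
## two-stage frequency cutoffs and municipality-to-region aggregation.

#' Construct a surname roster
#'
#' An individual-level census roster in the style of the Spanish *Padrón
#' municipal*: one row per resident with a region label, a municipality
#' label, a paternal surname and (for bearers of the usual double surname)
#' a maternal surname. Single-surname bearers (e.g. immigrants from
#' single-surname countries) leave the maternal field `NA` or empty.
#'
#' @param id Character vector of unique individual identifiers.
#' @param region Character vector of region labels.
#' @param municipality Character vector of municipality labels.
#' @param surname_paternal Character vector of paternal surnames.
#' @param surname_maternal Character vector of maternal surnames; `NA` or
#'   `""` marks a single-surname bearer.
#' @return A `data.frame` of class `surname_roster`.
#' @export
surname_roster <- function(id, region, municipality, surname_paternal,
                           surname_maternal = NA_character_) {
  if (length(surname_maternal) == 1 && length(id) != 1) {
    surname_maternal <- rep(as.character(surname_maternal), length(id))
  }
  df <- data.frame(
    id = as.character(id),
    region = as.character(region),
    municipality = as.character(municipality),
    surname_paternal = as.character(surname_paternal),
    surname_maternal = as.character(surname_maternal),
    stringsAsFactors = FALSE
  )
  if (anyDuplicated(df$id)) abort("invalid_roster", "individual ids must be unique")
  if (any(!nzchar(df$region)) || any(!nzchar(df$municipality))) {
    abort("invalid_roster", "region and municipality labels must be non-empty")
  }
  class(df) <- c("surname_roster", "data.frame")
  df
}

#' Read / write a roster as tab-separated text
#'
#' The on-disk format is UTF-8 TSV with header
#' `id  region  municipality  surname1  surname2`; an empty `surname2`
#' field marks a single-surname bearer.
#'
#' @param path File path.
#' @return `read_roster()` returns a `surname_roster`.
#' @export
read_roster <- function(path) {
  df <- utils::read.delim(path, colClasses = "character", na.strings = "",
                          fileEncoding = "UTF-8")
  expected <- c("id", "region", "municipality", "surname1", "surname2")
  if (!identical(names(df), expected)) {
    abort("invalid_roster", "roster header must be: %s", paste(expected, collapse = "\t"))
  }
  surname_roster(df$id, df$region, df$municipality, df$surname1, df$surname2)
}

#' @rdname read_roster
#' @param roster A `surname_roster`.
#' @export
write_roster <- function(roster, path) {
  out <- data.frame(id = roster$id, region = roster$region,
                    municipality = roster$municipality,
                    surname1 = roster$surname_paternal,
                    surname2 = ifelse(is.na(roster$surname_maternal), "",
                                      roster$surname_maternal))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Canonicalize a surname string
#'
#' Uppercases, strips leading/trailing whitespace and collapses internal
#' runs of whitespace to a single space. Diacritics are preserved by
#' default; `strip_accents = TRUE` maps the usual Iberian accented letters
#' to their plain ASCII counterparts (for dirty inputs digitised without a
#' consistent encoding).
#'
#' @param raw Character vector of raw surname strings.
#' @param strip_accents Replace accented letters by unaccented ones?
#' @return Character vector of canonical surnames.
#' @export
normalize_name <- function(raw, strip_accents = FALSE) {
  x <- toupper(trimws(as.character(raw)))
  ## toupper() can leave accented minuscules untouched in a C locale
  x <- chartr("áéíóúüñàèìòùç",
              "ÁÉÍÓÚÜÑÀÈÌÒÙÇ", x)
  x <- gsub("[[:space:]]+", " ", x)
  if (strip_accents) {
    x <- chartr("ÁÉÍÓÚÜÑÀÈÌÒÙÇ",
                "AEIOUUNAEIOUC", x)
  }
  if (any(!nzchar(x) & !is.na(x))) {
    abort("invalid_name", "surname empty after normalization")
  }
  x
}

#' Construct a token count table
#'
#' The central container of the pipeline: a location x surname matrix of
#' token counts, at either the municipality or the region level. Relative
#' frequencies n_si used by the isonymy coefficients are row-normalised
#' counts.
#'
#' @param counts Non-negative integer matrix with location row names and
#'   surname column names.
#' @param level `"municipality"` or `"region"`.
#' @param region_population Optional named vector: full census population
#'   per region (the N(INE) column of the province table).
#' @param municipality_region Optional named character vector mapping
#'   municipality to region (carried by municipality-level tables).
#' @return An object of class `token_table`.
#' @export
token_table <- function(counts, level = c("region", "municipality"),
                        region_population = NULL, municipality_region = NULL) {
  level <- match.arg(level)
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    abort("invalid_table", "counts must carry location and surname dimnames")
  }
  if (anyDuplicated(colnames(counts))) abort("invalid_table", "surname labels must be unique")
  if (any(counts < 0)) abort("invalid_table", "counts must be non-negative")
  structure(list(counts = counts, level = level,
                 region_population = region_population,
                 municipality_region = municipality_region),
            class = "token_table")
}

#' @export
print.token_table <- function(x, ...) {
  cat(sprintf("<token_table> %d %s x %d surnames, %s tokens\n",
              nrow(x$counts), x$level, ncol(x$counts),
              format(sum(x$counts), big.mark = ",")))
  invisible(x)
}

#' Relative surname frequencies of a token table
#'
#' @param table A `token_table`.
#' @return Matrix of row-normalised frequencies (each row sums to 1).
#' @export
token_frequencies <- function(table) {
  n <- rowSums(table$counts)
  if (any(n == 0)) abort("empty_region", "location(s) with zero tokens: %s",
                         paste(rownames(table$counts)[n == 0], collapse = ", "))
  sweep(table$counts, 1, n, "/")
}

#' Split double surnames into single-surname tokens
#'
#' Each record contributes one token per surname present: two for the
#' usual double-surname bearer, one for single-surname bearers. Counts are
#' accumulated per (municipality, surname); the municipality-to-region
#' mapping observed in the roster is carried along for later aggregation.
#'
#' @param roster A `surname_roster`.
#' @param strip_accents Passed to [normalize_name()].
#' @return A municipality-level `token_table`.
#' @export
tokenize <- function(roster, strip_accents = FALSE) {
  if (nrow(roster) == 0) abort("empty_corpus", "roster has no records")
  pat <- normalize_name(roster$surname_paternal, strip_accents)
  mat <- roster$surname_maternal
  has_mat <- !is.na(mat) & nzchar(trimws(mat))
  mat_norm <- rep(NA_character_, length(mat))
  mat_norm[has_mat] <- normalize_name(mat[has_mat], strip_accents)

  muni <- c(roster$municipality, roster$municipality[has_mat])
  name <- c(pat, mat_norm[has_mat])
  counts <- table(municipality = muni, surname = name)
  counts <- matrix(as.integer(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))

  m2r <- tapply(roster$region, roster$municipality, unique)
  if (any(lengths(m2r) > 1)) {
    abort("invalid_roster", "municipality mapped to several regions: %s",
          paste(names(m2r)[lengths(m2r) > 1], collapse = ", "))
  }
  m2r <- vapply(m2r, `[[`, character(1), 1)[rownames(counts)]
  token_table(counts, level = "municipality", municipality_region = m2r)
}

#' Municipal anonymity cutoff
#'
#' Within each municipality, surname counts below `min_bearers` are set to
#' zero (structural zeros), emulating the census provider's rule of
#' releasing only surnames borne at least five times within a
#' municipality. Surviving counts are kept unchanged.
#'
#' @param table Municipality-level `token_table`.
#' @param min_bearers Minimum within-municipality count to retain.
#' @return Filtered municipality-level `token_table`.
#' @export
filter_municipal <- function(table, min_bearers = 5) {
  if (table$level != "municipality") {
    abort("wrong_level", "municipal filter requires a municipality-level table")
  }
  counts <- table$counts
  counts[counts < min_bearers] <- 0L
  keep <- colSums(counts) > 0
  token_table(counts[, keep, drop = FALSE], level = "municipality",
              region_population = table$region_population,
              municipality_region = table$municipality_region)
}

#' Aggregate municipality counts to regions
#'
#' @param table Municipality-level `token_table`.
#' @param mapping Named character vector municipality -> region; defaults
#'   to the mapping recorded by [tokenize()].
#' @param region_population Optional named vector of full-population sizes.
#' @return Region-level `token_table`.
#' @export
aggregate_regions <- function(table, mapping = table$municipality_region,
                              region_population = table$region_population) {
  if (table$level != "municipality") {
    abort("wrong_level", "aggregation requires a municipality-level table")
  }
  munis <- rownames(table$counts)
  if (is.null(mapping) || !all(munis %in% names(mapping))) {
    missing <- if (is.null(mapping)) munis else setdiff(munis, names(mapping))
    abort("mapping_gap", "unmapped municipalities: %s", paste(missing, collapse = ", "))
  }
  agg <- rowsum(table$counts, group = mapping[munis])
  agg <- matrix(as.integer(agg), nrow = nrow(agg), dimnames = dimnames(agg))
  token_table(agg, level = "region", region_population = region_population)
}

#' Global frequency cutoff
#'
#' Drops surnames whose total count over all regions falls below
#' `min_occurrences` (default 20, keeping surnames with total >= 20).
#' Regions left without tokens are dropped with a warning, since isonymy
#' is undefined for them.
#'
#' @param table Region-level `token_table`.
#' @param min_occurrences Minimum nationwide count to keep a surname.
#' @return Filtered region-level `token_table`.
#' @export
filter_global <- function(table, min_occurrences = 20) {
  if (table$level != "region") {
    abort("wrong_level", "global filter requires a region-level table")
  }
  keep <- colSums(table$counts) >= min_occurrences
  if (!any(keep)) abort("empty_corpus", "no surname reaches the global cutoff")
  counts <- table$counts[, keep, drop = FALSE]
  empty <- rowSums(counts) == 0
  if (any(empty)) {
    warning(sprintf("dropping region(s) with zero tokens after filtering: %s",
                    paste(rownames(counts)[empty], collapse = ", ")))
    counts <- counts[!empty, , drop = FALSE]
  }
  token_table(counts, level = "region",
              region_population = table$region_population)
}

#' Per-region corpus summary
#'
#' The descriptive columns of the province table: token count N, surname
#' type count S, types-per-token ratio S/N and, when the full census
#' population is known, the representativeness ratio N_tokens / N(full
#' population) (close to 2 for a fully double-surnamed, fully retained
#' population).
#'
#' @param table Region-level `token_table`.
#' @param require_population Fail if `region_population` is absent?
#' @return A `data.frame` with one row per region.
#' @export
corpus_summary <- function(table, require_population = FALSE) {
  if (table$level != "region") abort("wrong_level", "summary requires a region-level table")
  n <- rowSums(table$counts)
  s <- rowSums(table$counts > 0)
  out <- data.frame(region = rownames(table$counts), n_tokens = as.numeric(n),
                    s_surnames = as.numeric(s), s_over_n = as.numeric(s / n),
                    row.names = NULL)
  pop <- table$region_population
  if (is.null(pop)) {
    if (require_population) abort("missing_metadata", "region_population not set")
    out$tokens_per_capita <- NA_real_
  } else {
    if (!all(out$region %in% names(pop))) {
      abort("missing_metadata", "population missing for some regions")
    }
    out$tokens_per_capita <- out$n_tokens / as.numeric(pop[out$region])
  }
  out
}

#' Read / write a token table as long-format TSV
#'
#' Long format `region  surname  count` plus a sidecar `<path>.meta.tsv`
#' holding the level, applied cutoffs and region populations.
#'
#' @param table A `token_table`.
#' @param path Output TSV path.
#' @param cutoffs Optional named list of applied cutoffs, recorded in the
#'   sidecar for auditability.
#' @return `read_token_table()` returns a `token_table`.
#' @export
write_token_table <- function(table, path, cutoffs = NULL) {
  idx <- which(table$counts > 0, arr.ind = TRUE)
  long <- data.frame(location = rownames(table$counts)[idx[, 1]],
                     surname = colnames(table$counts)[idx[, 2]],
                     count = table$counts[idx])
  long <- long[order(long$location, long$surname), ]
  utils::write.table(long, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  meta <- data.frame(key = "level", value = table$level)
  if (!is.null(cutoffs)) {
    meta <- rbind(meta, data.frame(key = names(cutoffs),
                                   value = as.character(unlist(cutoffs))))
  }
  if (!is.null(table$region_population)) {
    meta <- rbind(meta, data.frame(
      key = paste0("population:", names(table$region_population)),
      value = as.character(table$region_population)))
  }
  utils::write.table(meta, paste0(path, ".meta.tsv"), sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_token_table
#' @export
read_token_table <- function(path) {
  long <- utils::read.delim(path, colClasses = c("character", "character", "integer"),
                            fileEncoding = "UTF-8")
  counts <- table(long$location, long$surname)
  counts <- matrix(as.integer(counts), nrow = nrow(counts), dimnames = dimnames(counts))
  idx <- cbind(match(long$location, rownames(counts)),
               match(long$surname, colnames(counts)))
  counts[] <- 0L
  counts[idx] <- long$count
  level <- "region"
  pop <- NULL
  meta_path <- paste0(path, ".meta.tsv")
  if (file.exists(meta_path)) {
    meta <- utils::read.delim(meta_path, colClasses = "character", fileEncoding = "UTF-8")
    if ("level" %in% meta$key) level <- meta$value[meta$key == "level"]
    pop_rows <- grepl("^population:", meta$key)
    if (any(pop_rows)) {
      pop <- as.numeric(meta$value[pop_rows])
      names(pop) <- sub("^population:", "", meta$key[pop_rows])
    }
  }
  token_table(counts, level = level, region_population = pop)
}
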