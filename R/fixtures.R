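## Packaged fixtures: the published per-province summary of the 2008
## Spanish municipal register and the foreign-population composition,
## plus consistency checks recomputing their derived columns.

fixture_path <- function(file) {
  p <- system.file("extdata", file, package = "isonymia")
  if (!nzchar(p)) abort("fixture_mismatch", "fixture %s not found", file)
  p
}

#' Per-province surname summary of mainland Spain (2008)
#'
#' The packaged 47-province table: municipalities, census population
#' N(INE), density, token count, tokens-per-capita ratio, surname type
#' count S, S/N, random isonymy and surname entropy per province.
#'
#' @return `data.frame` with 47 rows.
#' @export
province_table <- function() {
  t3 <- utils::read.delim(fixture_path("table3_provinces.tsv"),
                          fileEncoding = "UTF-8", check.names = FALSE)
  if (nrow(t3) != 47) abort("fixture_mismatch", "province table must have 47 rows")
  t3
}

#' Foreign-population composition fixtures (2008)
#'
#' Country-of-origin percentages of the foreign population, the printed
#' continental totals, and the national population counts.
#'
#' @return List with `origins`, `continent_totals`, `population` (named
#'   vector).
#' @export
foreign_population <- function() {
  origins <- utils::read.delim(fixture_path("table1_foreign_origin.tsv"),
                               fileEncoding = "UTF-8")
  totals <- utils::read.delim(fixture_path("table1_continent_totals.tsv"),
                              fileEncoding = "UTF-8")
  pop <- utils::read.delim(fixture_path("population_2008.tsv"),
                           fileEncoding = "UTF-8")
  list(origins = origins, continent_totals = totals,
       population = stats::setNames(pop$value, pop$quantity))
}

#' Recompute the derived fixture quantities
#'
#' Arithmetic audit of the packaged tables: tokens-per-capita per
#' province recomputed from the token and population columns (and
#' compared to the printed 2-decimal column), continental totals re-added
#' from country percentages, the foreign-population percentage
#' recomputed from the printed counts, the doubled full population, and
#' the representativeness regression of tokens-per-capita on municipality
#' count (fitted excluding the three large-agglomeration provinces whose
#' ratio collapses: Barcelona, Madrid, Valencia).
#'
#' @return List of class `fixture_report` with the recomputed values.
#' @export
fixture_checks <- function() {
  t3 <- province_table()
  fp <- foreign_population()

  ratio <- t3$n_tokens / t3$population
  if (max(abs(ratio - t3$tokens_per_capita)) > 0.005 + 1e-9) {
    abort("fixture_mismatch", "tokens-per-capita column inconsistent with counts")
  }

  totals <- tapply(fp$origins$percent, fp$origins$continent, sum)
  printed <- stats::setNames(fp$continent_totals$percent, fp$continent_totals$continent)
  if (!all(totals[names(printed)] == printed)) {
    abort("fixture_mismatch", "continental totals do not re-add")
  }

  pop <- fp$population
  foreign_percent <- 100 * pop[["foreign_population"]] / pop[["total_population"]]
  doubled_population <- 2 * pop[["total_population"]]

  excl <- c("Barcelona", "Madrid", "Valencia/València")
  reg <- linear_regression(t3$municipalities, ratio,
                           labels = t3$province, exclude = excl)

  structure(list(
    tokens_per_capita = stats::setNames(ratio, t3$province),
    continent_totals = totals,
    foreign_percent = unname(foreign_percent),
    doubled_population = unname(doubled_population),
    representativeness_regression = reg,
    excluded_provinces = excl
  ), class = "fixture_report")
}

#' @export
print.fixture_report <- function(x, ...) {
  cat(sprintf("foreign population: %.1f%% of %s (doubled: %s)\n",
              x$foreign_percent,
              format(x$doubled_population / 2, big.mark = ","),
              format(x$doubled_population, big.mark = ",")))
  cat("continental totals:", paste(sprintf("%s %d%%", names(x$continent_totals),
                                           x$continent_totals), collapse = ", "), "\n")
  cat(sprintf("representativeness regression (n = %d, excluding %s):\n  ",
              x$representativeness_regression$n,
              paste(x$excluded_provinces, collapse = ", ")))
  print(x$representativeness_regression)
  invisible(x)
}
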