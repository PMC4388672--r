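## End-to-end pipeline: roster -> tokens -> cutoffs -> aggregation ->
## distances -> bootstrap NJ consensus -> optional Mantel test, with an
## audit report of every parameter actually used.

#' Pipeline configuration
#'
#' Bundles every tunable of the end-to-end analysis. All randomness flows
#' from the single `seed`, split deterministically per stage.
#'
#' @param municipal_cutoff Minimum within-municipality surname count.
#' @param global_cutoff Minimum nationwide surname count.
#' @param kind Distance kind, `"nei"` or `"hedrick"`.
#' @param replicates Bootstrap replicates.
#' @param collapse_cutoff Consensus support cutoff (percent).
#' @param permutations Mantel permutations.
#' @param seed Top-level seed.
#' @param strip_accents Passed to [normalize_name()].
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(municipal_cutoff = 5, global_cutoff = 20,
                            kind = c("nei", "hedrick"), replicates = 100,
                            collapse_cutoff = 50, permutations = 9999,
                            seed = 1L, strip_accents = FALSE) {
  kind <- match.arg(kind)
  if (collapse_cutoff < 1 || collapse_cutoff > 100) abort("bad_parameter", "collapse_cutoff in [1, 100]")
  if (replicates < 1 || permutations < 1) abort("bad_parameter", "counts must be positive")
  structure(list(municipal_cutoff = municipal_cutoff, global_cutoff = global_cutoff,
                 kind = kind, replicates = replicates,
                 collapse_cutoff = collapse_cutoff, permutations = permutations,
                 seed = as.integer(seed), strip_accents = strip_accents),
            class = "pipeline_config")
}

#' Run the full surname-structure pipeline
#'
#' tokenize -> municipal cutoff -> aggregation to regions -> global
#' cutoff -> distance matrix -> bootstrap NJ consensus, plus a Mantel
#' test against a geographic distance matrix when coordinates are given.
#' Deterministic under the config seed; the returned report records the
#' parameters used, the tokens dropped by each cutoff and the bootstrap
#' replicates rejected.
#'
#' @param roster A `surname_roster` or a path to a roster TSV.
#' @param config A `pipeline_config`.
#' @param region_population Optional named vector of full-population
#'   sizes per region.
#' @param coords Optional `data.frame` (region, lat, lon) enabling the
#'   Mantel stage.
#' @return List of class `pipeline_result` with `token_table`,
#'   `distance`, `consensus`, `diversity`, `summary`, `mantel` (or
#'   `NULL`) and `report`.
#' @export
run_pipeline <- function(roster, config = pipeline_config(),
                         region_population = NULL, coords = NULL) {
  if (is.character(roster)) roster <- read_roster(roster)
  seeds <- stage_seeds(config$seed, 2)

  tt_muni <- tokenize(roster, strip_accents = config$strip_accents)
  total_raw <- sum(tt_muni$counts)
  tt_muni_f <- filter_municipal(tt_muni, config$municipal_cutoff)
  dropped_municipal <- total_raw - sum(tt_muni_f$counts)
  tt_region <- aggregate_regions(tt_muni_f, region_population = region_population)
  tt <- filter_global(tt_region, config$global_cutoff)
  dropped_global <- sum(tt_region$counts) - sum(tt$counts)

  D <- distance_matrix(tt, kind = config$kind)
  consensus <- bootstrap_consensus_pipeline(
    tt, kind = config$kind, replicates = config$replicates,
    collapse_cutoff = config$collapse_cutoff, seed = seeds[1]
  )

  mantel <- NULL
  if (!is.null(coords)) {
    coords <- coords[match(rownames(D), coords$region), ]
    G <- geographic_distance_matrix(coords)
    mantel <- mantel_test(D, G, permutations = config$permutations, seed = seeds[2])
  }

  report <- list(
    parameters = unclass(config),
    n_records = nrow(roster),
    n_tokens_raw = total_raw,
    dropped_municipal = dropped_municipal,
    dropped_global = dropped_global,
    n_regions = nrow(tt$counts),
    n_surnames = ncol(tt$counts),
    rejected_replicates = consensus$rejected
  )
  structure(list(token_table = tt, distance = D, consensus = consensus,
                 diversity = region_diversity(tt), summary = corpus_summary(tt),
                 mantel = mantel, report = report),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  r <- x$report
  cat(sprintf("<pipeline_result> %d records -> %d tokens -> %d regions x %d surnames (%s distance)\n",
              r$n_records, r$n_tokens_raw, r$n_regions, r$n_surnames,
              r$parameters$kind))
  cat(sprintf("  cutoffs: municipal >=%d (dropped %d tokens), global >=%d (dropped %d)\n",
              r$parameters$municipal_cutoff, r$dropped_municipal,
              r$parameters$global_cutoff, r$dropped_global))
  print(x$consensus)
  if (!is.null(x$mantel)) { cat("  geography: "); print(x$mantel) }
  invisible(x)
}
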