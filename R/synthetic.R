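## Synthetic roster generator with planted regional structure: kingdom
## surname pools with Zipf-ranked frequencies, migration between
## kingdoms, castilianization (pool merging that depresses diversity),
## single-surname immigrants, plus a synthetic geography and synthetic
## dialect features for the linguistic side of the analysis.

#' Scenario configuration for the synthetic roster generator
#'
#' Defaults describe the reference scenario used throughout the package's
#' tests and analyses: three historical "kingdoms" of four regions each,
#' 10,000 individuals per region, Zipf-distributed surnames (exponent
#' 1.5), 5% migration, mild (0.2) castilianization, an 11.3% immigrant
#' fraction of whom 66% carry a single surname and 34% carry native-style
#' surnames (the undetectable Latin-American-like component).
#'
#' @param n_kingdoms Number of planted clusters.
#' @param regions_per_kingdom Regions per kingdom.
#' @param municipalities_per_region Municipalities per region.
#' @param individuals_per_region Individuals per region.
#' @param surnames_per_kingdom_pool Size of each kingdom-specific pool.
#' @param shared_pool_size Size of the pan-national (shared) pool.
#' @param foreign_pool_size Size of the disjoint foreign pool.
#' @param zipf_exponent Zipf rank-frequency exponent within each pool.
#' @param migration_rate Probability that a native's surname draw comes
#'   from another kingdom's pool.
#' @param castilianization Fraction of each kingdom's draw mass diverted
#'   to the shared pool (raises isonymy, lowers entropy).
#' @param immigrant_fraction Fraction of individuals who are immigrants.
#' @param immigrant_single_surname_fraction Fraction of immigrants with a
#'   single surname.
#' @param latin_overlap Fraction of immigrants who carry native-style
#'   (shared-pool) surnames and thus escape detection.
#' @param seed Integer seed.
#' @return A list of class `scenario_config`.
#' @export
scenario_config <- function(n_kingdoms = 3,
                            regions_per_kingdom = 4,
                            municipalities_per_region = 5,
                            individuals_per_region = 10000,
                            surnames_per_kingdom_pool = 200,
                            shared_pool_size = 100,
                            foreign_pool_size = 100,
                            zipf_exponent = 1.5,
                            migration_rate = 0.05,
                            castilianization = 0.2,
                            immigrant_fraction = 0.113,
                            immigrant_single_surname_fraction = 0.66,
                            latin_overlap = 0.34,
                            seed = 1L) {
  cfg <- list(n_kingdoms = n_kingdoms, regions_per_kingdom = regions_per_kingdom,
              municipalities_per_region = municipalities_per_region,
              individuals_per_region = individuals_per_region,
              surnames_per_kingdom_pool = surnames_per_kingdom_pool,
              shared_pool_size = shared_pool_size,
              foreign_pool_size = foreign_pool_size,
              zipf_exponent = zipf_exponent, migration_rate = migration_rate,
              castilianization = castilianization,
              immigrant_fraction = immigrant_fraction,
              immigrant_single_surname_fraction = immigrant_single_surname_fraction,
              latin_overlap = latin_overlap, seed = as.integer(seed))
  fracs <- c("migration_rate", "castilianization", "immigrant_fraction",
             "immigrant_single_surname_fraction", "latin_overlap")
  for (f in fracs) {
    if (cfg[[f]] < 0 || cfg[[f]] > 1) abort("bad_config", "%s must lie in [0, 1]", f)
  }
  if (cfg$n_kingdoms < 1 || cfg$regions_per_kingdom < 1 ||
      cfg$municipalities_per_region < 1 || cfg$individuals_per_region < 1) {
    abort("bad_config", "counts must be positive")
  }
  if (cfg$surnames_per_kingdom_pool < 1 || cfg$shared_pool_size < 1 ||
      cfg$foreign_pool_size < 1) {
    abort("bad_config", "surname pools must be non-empty")
  }
  if (cfg$zipf_exponent <= 0) abort("bad_config", "zipf_exponent must be positive")
  class(cfg) <- "scenario_config"
  cfg
}

zipf_weights <- function(n, s) {
  w <- (seq_len(n))^(-s)
  w / sum(w)
}

#' Generate a synthetic roster with planted structure
#'
#' Builds surname pools (one Zipf-weighted pool per kingdom, one shared
#' pan-national pool, one disjoint foreign pool) and draws paternal and
#' maternal surnames independently for every individual. A native in
#' kingdom k draws each surname from the mixture
#' `(1 - migration) * kingdom-k distribution + migration * (uniformly
#' chosen other kingdom)`, where each kingdom's distribution already
#' diverts a `castilianization` fraction of its mass to the shared pool.
#' An `immigrant_fraction` of individuals draw from the foreign pool
#' (except a `latin_overlap` fraction who draw native-style shared-pool
#' surnames); a configured fraction of immigrants carry only a paternal
#' surname.
#'
#' @param config A `scenario_config`.
#' @return List with `roster` (a `surname_roster`) and `truth` (class
#'   `synthetic_truth`: `kingdom_of_region`, `expected_clades`,
#'   `pool_assignments`).
#' @export
generate_scenario <- function(config = scenario_config()) {
  stopifnot(inherits(config, "scenario_config"))
  K <- config$n_kingdoms
  R <- config$regions_per_kingdom
  P <- config$surnames_per_kingdom_pool
  shared <- sprintf("SH_S%03d", seq_len(config$shared_pool_size))
  foreign <- sprintf("FR_S%03d", seq_len(config$foreign_pool_size))
  wk <- zipf_weights(P, config$zipf_exponent)
  ws <- zipf_weights(config$shared_pool_size, config$zipf_exponent)
  wf <- zipf_weights(config$foreign_pool_size, config$zipf_exponent)
  cast <- config$castilianization
  mig <- config$migration_rate

  ## Castilianization merges pools from the common end: the minimal top
  ## prefix of rank slots covering a fraction `cast` of the pool's mass
  ## is replaced, in every kingdom alike, by prototype shared surnames
  ## (several rank slots map onto one shared name), while rare local
  ## surnames survive in the tail. Merging distinct names onto the same
  ## prototypes shrinks surname diversity: isonymy rises, entropy falls,
  ## and kingdoms become indistinguishable as `cast` approaches 1.
  n_replaced <- if (cast <= 0) 0L else which(cumsum(wk) >= cast - 1e-12)[1]
  pools <- lapply(seq_len(K), function(k) {
    nm <- sprintf("K%d_S%03d", k, seq_len(P))
    if (n_replaced > 0) {
      idx <- seq_len(n_replaced)
      nm[idx] <- shared[pmin(ceiling(idx * config$shared_pool_size / P),
                             config$shared_pool_size)]
    }
    nm
  })

  ## draw n surnames from kingdom k's (possibly merged) pool
  kingdom_names <- function(k, n) {
    sample(pools[[k]], n, replace = TRUE, prob = wk)
  }
  native_names <- function(k, n) {
    migrate <- stats::rbinom(n, 1, mig) == 1
    out <- character(n)
    if (any(migrate) && K > 1) {
      src <- sample(setdiff(seq_len(K), k), sum(migrate), replace = TRUE)
      for (k2 in unique(src)) {
        idx <- which(migrate)[src == k2]
        out[idx] <- kingdom_names(k2, length(idx))
      }
    } else {
      migrate[] <- FALSE
    }
    out[!migrate] <- kingdom_names(k, sum(!migrate))
    out
  }

  regions <- as.vector(t(outer(seq_len(K), seq_len(R),
                               function(k, r) sprintf("K%dR%d", k, r))))
  kingdom_of_region <- stats::setNames(rep(seq_len(K), each = R), regions)

  recs <- with_seed(config$seed, {
    lapply(regions, function(reg) {
      k <- kingdom_of_region[[reg]]
      n <- config$individuals_per_region
      munis <- sprintf("%sM%d", reg, seq_len(config$municipalities_per_region))
      muni <- sample(munis, n, replace = TRUE)
      is_imm <- stats::rbinom(n, 1, config$immigrant_fraction) == 1
      n_imm <- sum(is_imm)
      draw_pair <- function() {
        nm <- character(n)
        nm[!is_imm] <- native_names(k, n - n_imm)
        if (n_imm) {
          latin <- stats::rbinom(n_imm, 1, config$latin_overlap) == 1
          imm <- character(n_imm)
          if (any(latin)) imm[latin] <- sample(shared, sum(latin), replace = TRUE, prob = ws)
          if (any(!latin)) imm[!latin] <- sample(foreign, sum(!latin), replace = TRUE, prob = wf)
          nm[is_imm] <- imm
        }
        nm
      }
      pat <- draw_pair()
      mat <- draw_pair()
      if (n_imm) {
        single <- stats::rbinom(n_imm, 1, config$immigrant_single_surname_fraction) == 1
        mat[which(is_imm)[single]] <- NA_character_
      }
      data.frame(region = reg, municipality = muni, pat = pat, mat = mat,
                 stringsAsFactors = FALSE)
    })
  })
  recs <- do.call(rbind, recs)
  roster <- surname_roster(
    id = sprintf("I%07d", seq_len(nrow(recs))),
    region = recs$region, municipality = recs$municipality,
    surname_paternal = recs$pat, surname_maternal = recs$mat
  )
  distinctive <- lapply(seq_len(K), function(k) {
    grep(sprintf("^K%d_", k), pools[[k]], value = TRUE)
  })
  pool_assignments <- c(
    stats::setNames(rep(sprintf("kingdom%d", seq_len(K)), lengths(distinctive)),
                    unlist(distinctive)),
    stats::setNames(rep("shared", length(shared)), shared),
    stats::setNames(rep("foreign", length(foreign)), foreign)
  )
  truth <- structure(list(
    kingdom_of_region = kingdom_of_region,
    expected_clades = lapply(seq_len(K), function(k) names(kingdom_of_region)[kingdom_of_region == k]),
    pool_assignments = pool_assignments
  ), class = "synthetic_truth")
  list(roster = roster, truth = truth)
}

#' Synthetic geography for a planted scenario
#'
#' Places kingdom centres well apart (8 degrees of longitude between
#' neighbouring centres) and jitters each region around its kingdom
#' centre (within ~1 degree), so between-kingdom great-circle distances
#' always exceed within-kingdom ones.
#'
#' @param truth A `synthetic_truth`.
#' @param seed Integer seed.
#' @return `data.frame` with columns region, lat, lon.
#' @export
generate_geography <- function(truth, seed = NULL) {
  k_of <- truth$kingdom_of_region
  K <- max(k_of)
  centers <- data.frame(lat = 40, lon = 8 * (seq_len(K) - 1))
  with_seed(seed, {
    data.frame(
      region = names(k_of),
      lat = centers$lat[k_of] + stats::runif(length(k_of), -1, 1),
      lon = centers$lon[k_of] + stats::runif(length(k_of), -1, 1),
      row.names = NULL
    )
  })
}

#' Great-circle distance matrix from region coordinates
#'
#' @param coords `data.frame` with columns region, lat, lon.
#' @return Symmetric matrix of distances in kilometres.
#' @export
geographic_distance_matrix <- function(coords) {
  D <- geosphere::distm(coords[, c("lon", "lat")]) / 1000
  dimnames(D) <- list(coords$region, coords$region)
  attr(D, "kind") <- "geographic"
  D
}

#' Synthetic dialect features for a planted scenario
#'
#' Emulates an atlas of categorical survey items: each item has one
#' variant per kingdom; a region reports its kingdom's variant except for
#' a `within_noise` fraction of idiosyncratic region-level deviations.
#' Feeding the result to [riw_matrix()] and [riw_to_distance()] yields a
#' linguistic distance matrix whose structure matches the planted
#' kingdoms.
#'
#' @param truth A `synthetic_truth`.
#' @param n_items Number of survey items.
#' @param within_noise Per-item probability of a region-specific deviant
#'   variant.
#' @param seed Integer seed.
#' @return Character matrix (regions x items).
#' @export
generate_dialect_features <- function(truth, n_items = 200, within_noise = 0.05,
                                      seed = NULL) {
  k_of <- truth$kingdom_of_region
  regions <- names(k_of)
  with_seed(seed, {
    feat <- matrix(NA_character_, length(regions), n_items,
                   dimnames = list(regions, sprintf("item%03d", seq_len(n_items))))
    for (it in seq_len(n_items)) {
      variants <- sprintf("v%d_%d", it, seq_len(max(k_of)))
      feat[, it] <- variants[k_of]
      deviant <- stats::runif(length(regions)) < within_noise
      if (any(deviant)) {
        feat[deviant, it] <- sprintf("v%d_dev_%s", it, regions[deviant])
      }
    }
    feat
  })
}
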