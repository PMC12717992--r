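# Per-population diversity, per-individual inbreeding, great-circle
# distances to entry points, and diversity-distance gradient tests.

#' Per-site and mean expected heterozygosity within a population
#'
#' For each site, `H = 1 - p^2 - q^2 = 2pq` with `p` the sample allele
#' frequency among non-missing calls in the population. Sites with fewer
#' than two non-missing genotypes are undefined (`NA`) and ignored by the
#' mean, which by default averages over all remaining sites, monomorphic
#' ones included (their H is 0).
#'
#' @param panel A `genotype_panel`.
#' @param population Population label present in the panel.
#' @param segregating_only If `TRUE`, the mean is taken over sites
#'   segregating within the population only.
#' @return List with `per_site` (numeric vector, `NA` where undefined),
#'   `mean`, and `n_sites_used`.
#' @export
expected_heterozygosity <- function(panel, population,
                                    segregating_only = FALSE) {
  ids <- pop_samples(panel, population)
  d <- panel$dosage[ids, , drop = FALSE]
  n_obs <- colSums(!is.na(d))
  p <- colSums(d, na.rm = TRUE) / (2 * n_obs)
  h <- 2 * p * (1 - p)
  h[n_obs < 2L] <- NA_real_
  use <- !is.na(h)
  if (segregating_only) use <- use & h > 0
  list(per_site = h, mean = mean(h[use]), n_sites_used = sum(use))
}

#' Method-of-moments inbreeding coefficient per individual
#'
#' `F = (O_hom - E_hom) / (N - E_hom)` where `O_hom` is the individual's
#' observed homozygous count over its non-missing sites, and
#' `E_hom = sum(1 - 2 p q n/(n-1))` over the same sites uses cohort allele
#' frequencies with the small-sample correction `n/(n-1)` (`n` = non-missing
#' allele count in the cohort at the site).
#'
#' @param panel A `genotype_panel`.
#' @param sample Sample id, or `NULL` for all samples.
#' @param cohort `"panel"` (frequencies from all samples, the convention of
#'   whole-file estimators) or `"population"` (the sample's own population).
#' @return `data.frame` with columns `sample`, `F`, `n_sites_used`;
#'   `F` is `NA` with a warning when the denominator is 0.
#' @export
inbreeding_f <- function(panel, sample = NULL, cohort = c("panel", "population")) {
  stopifnot(inherits(panel, "genotype_panel"))
  cohort <- match.arg(cohort)
  samples <- sample %||% panel$sample_ids
  res <- lapply(samples, function(id) {
    coh_ids <- if (cohort == "panel") panel$sample_ids
               else pop_samples(panel, panel$pop_of_sample[[id]])
    dc <- panel$dosage[coh_ids, , drop = FALSE]
    n_allele <- 2 * colSums(!is.na(dc))
    p <- colSums(dc, na.rm = TRUE) / n_allele
    e_het <- 2 * p * (1 - p) * n_allele / (n_allele - 1)
    e_het[n_allele < 2L] <- NA_real_
    di <- panel$dosage[id, ]
    ok <- !is.na(di) & !is.na(e_het)
    N <- sum(ok)
    e_hom <- sum(1 - e_het[ok])
    o_hom <- sum(di[ok] != 1L)
    denom <- N - e_hom
    f <- if (N == 0L || abs(denom) < .Machine$double.eps^0.5) {
      warning("inbreeding F undefined for sample ", id,
              " (no expected heterozygosity in cohort)")
      NA_real_
    } else (o_hom - e_hom) / denom
    data.frame(sample = id, F = f, n_sites_used = N, stringsAsFactors = FALSE)
  })
  do.call(rbind, res)
}

#' Haversine great-circle distance in kilometres
#'
#' Spherical Earth with mean radius 6371.0088 km. Symmetric; zero iff the
#' two points coincide.
#'
#' @param lat1,lon1,lat2,lon2 Coordinates in decimal degrees (vectorized).
#' @return Distance(s) in km.
#' @export
haversine_km <- function(lat1, lon1, lat2, lon2) {
  if (any(abs(c(lat1, lat2)) > 90) || any(abs(c(lon1, lon2)) > 180)) {
    stop("coordinates outside valid decimal-degree ranges")
  }
  r <- 6371.0088
  to_rad <- pi / 180
  dlat <- (lat2 - lat1) * to_rad
  dlon <- (lon2 - lon1) * to_rad
  a <- sin(dlat / 2)^2 +
    cos(lat1 * to_rad) * cos(lat2 * to_rad) * sin(dlon / 2)^2
  2 * r * asin(pmin(1, sqrt(a)))
}

#' Spearman gradient test of a per-population statistic against distance
#'
#' Correlates a per-population value with the haversine distance from an
#' entry population (serial-founder expansions predict monotone gradients
#' along the route). Optionally restricted to one cluster.
#'
#' @param values_by_pop Named numeric vector (names = population labels).
#' @param entry_population Label of the route's entry population.
#' @param popmap `data.frame` from [read_coords()] (needs `population`,
#'   `latitude`, `longitude`, and `cluster` if `cluster` is given).
#' @param cluster Optional cluster label to subset populations.
#' @return List with `rho`, `p`, `n`, and the distance vector used
#'   (`distance_km`, named). Degenerate input yields `NA` statistics.
#' @export
gradient_correlation <- function(values_by_pop, entry_population, popmap,
                                 cluster = NULL) {
  stopifnot(entry_population %in% popmap$population)
  if (!is.null(cluster)) {
    popmap <- popmap[popmap$cluster %in% cluster |
                       popmap$population == entry_population, , drop = FALSE]
  }
  pops <- intersect(names(values_by_pop), popmap$population)
  if (length(pops) < 4L) stop("need >= 4 populations with values and coordinates")
  co <- popmap[match(pops, popmap$population), ]
  e <- popmap[popmap$population == entry_population, ]
  dist_km <- haversine_km(co$latitude, co$longitude, e$latitude, e$longitude)
  names(dist_km) <- pops
  sp <- spearman_or_na(values_by_pop[pops], dist_km)
  list(rho = sp$rho, p = sp$p, n = sp$n, distance_km = dist_km)
}

#' Diversity table across populations
#'
#' Convenience wrapper: mean expected heterozygosity per population plus
#' distances to the two entry populations.
#'
#' @param panel A `genotype_panel`.
#' @param popmap Coordinates table ([read_coords()]).
#' @param entry_south,entry_north Labels of the two entry populations.
#' @return `data.frame`: population, mean_hexp, n_sites_used,
#'   distance_south_km, distance_north_km.
#' @export
diversity_table <- function(panel, popmap, entry_south, entry_north) {
  pops <- intersect(unique(panel$pop_of_sample), popmap$population)
  co <- popmap[match(pops, popmap$population), ]
  es <- popmap[popmap$population == entry_south, ]
  en <- popmap[popmap$population == entry_north, ]
  if (!nrow(es) || !nrow(en)) stop("entry population(s) missing from coordinates")
  hx <- vapply(pops, function(p) {
    hh <- expected_heterozygosity(panel, p)
    c(hh$mean, hh$n_sites_used)
  }, numeric(2))
  data.frame(
    population = pops,
    mean_hexp = hx[1L, ],
    n_sites_used = as.integer(hx[2L, ]),
    distance_south_km = haversine_km(co$latitude, co$longitude, es$latitude, es$longitude),
    distance_north_km = haversine_km(co$latitude, co$longitude, en$latitude, en$longitude),
    stringsAsFactors = FALSE
  )
}
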