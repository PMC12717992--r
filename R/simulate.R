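# Serial-founder range-expansion simulator. Frequency-level simulation: a
# pool of ancestral derived-allele frequencies expands along two route trees
# rooted at two entry points; every edge applies a founder bottleneck
# followed by Wright-Fisher drift, geographic neighbours exchange migrants
# each generation, and genotypes are drawn per population under
# inbreeding-adjusted Hardy-Weinberg. Emits exactly the file formats the
# pipeline reads plus a truth table for recovery experiments.

#' Simulation configuration
#'
#' Defaults emulate a two-route introduction of a crop into a continental
#' landscape: 35 landrace populations in two clusters founded from a
#' south-western and a central-northern entry point, array-scale SNP counts,
#' population-specific drift, isolation by distance through neighbour
#' migration, derived deleterious alleles carrying conservation scores, and
#' bioclimatic variables with gradients along the routes.
#'
#' @param seed Root seed; all stage randomness derives from it via named
#'   substreams.
#' @param n_pops Number of landrace populations (split across two routes).
#' @param n_per_pop Diploid individuals sampled per landrace population.
#' @param entry_points List of two `c(lat, lon)` pairs (south, north).
#' @param n_sites Number of biallelic SNPs.
#' @param n_chrom Number of chromosomes the sites are spread over.
#' @param founder_size Haploid founder count per founding event.
#' @param deme_size Haploid deme size for Wright-Fisher drift.
#' @param generations_per_edge Generations of drift per route edge.
#' @param migration_rate Per-generation fraction exchanged between
#'   neighbouring populations (route-tree edges).
#' @param inter_route_migration Multiplier on `migration_rate` for the
#'   single contact edge between the two route subtrees.
#' @param ancestral_freq_law `c(a, b)` of the Beta law for ancestral derived
#'   frequencies (array-ascertained SNPs are mostly common).
#' @param frac_deleterious Fraction of sites assigned positive GERP scores.
#' @param gerp_law List `shape`, `scale` of the Gamma law for positive GERP
#'   scores plus `p_high` / `high_range` for a point mass above 5.
#' @param gerp_freq_coupling In [0,1]; >0 makes high-GERP derived alleles
#'   start rarer (negative-selection proxy). 0 = independent (default).
#' @param mutation_rate_per_edge Probability per deleterious site per
#'   founding edge of a new derived mutation entering the founded deme
#'   (expansion-load accumulation proxy).
#' @param sweep_specs List of sweeps, each a list with `population`,
#'   `chrom`, `pos` (site position, matched to the nearest simulated site),
#'   `freq` (final derived frequency) and `core_bp` (core window width).
#' @param env_gradient 19 x 4 matrix (`intercept`, `lat`, `lon`, `sd`) of
#'   linear bioclim models, or `NULL` for built-in defaults.
#' @param inbreeding_f Inbreeding coefficient used for genotype sampling in
#'   landrace populations.
#' @param missing_rate Per-call missing probability.
#' @param junk_quality_frac Fraction of sites given a non-whitelist array
#'   quality class (exercises filtering end-to-end).
#' @param n_elite_pops 0, 1 or 2 elite breeding pools derived from the route
#'   entries with strong drift and near-complete inbreeding.
#' @param n_per_elite Individuals per elite pool.
#' @param elite_inbreeding_f Inbreeding coefficient of elite pools.
#' @param elite_extra_generations Additional drift generations for elites.
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       n_pops = 35,
                       n_per_pop = 24,
                       entry_points = list(south = c(42.04, -8.64),
                                           north = c(49.57, 3.328)),
                       n_sites = 5000,
                       n_chrom = 2,
                       founder_size = 20,
                       deme_size = 200,
                       generations_per_edge = 30,
                       migration_rate = 0.02,
                       inter_route_migration = 0.1,
                       ancestral_freq_law = c(0.5, 0.5),
                       frac_deleterious = 0.25,
                       gerp_law = list(shape = 0.5, scale = 1.5,
                                       p_high = 0.03, high_range = c(5, 8)),
                       gerp_freq_coupling = 0,
                       mutation_rate_per_edge = 0.003,
                       sweep_specs = NULL,
                       env_gradient = NULL,
                       inbreeding_f = 0.05,
                       missing_rate = 0.005,
                       junk_quality_frac = 0.02,
                       n_elite_pops = 2,
                       n_per_elite = 30,
                       elite_inbreeding_f = 0.95,
                       elite_extra_generations = 150) {
  cfg <- as.list(environment())
  stopifnot(cfg$n_pops >= 2, cfg$n_sites >= 10,
            cfg$migration_rate >= 0, cfg$migration_rate <= 0.5,
            cfg$frac_deleterious >= 0, cfg$frac_deleterious <= 1)
  if (is.null(cfg$env_gradient)) cfg$env_gradient <- default_env_gradient()
  class(cfg) <- "sim_config"
  cfg
}

# Built-in linear climate models: temperature-like variables (bio1-bio11)
# decline with latitude at WorldClim-scale magnitudes; precipitation-like
# variables (bio12-bio19) trend with longitude; noise s.d. is a modest
# fraction of the across-range span so planted gradients remain detectable
# but not deterministic.
default_env_gradient <- function() {
  g <- matrix(0, nrow = 19, ncol = 4,
              dimnames = list(paste0("bio", 1:19),
                              c("intercept", "lat", "lon", "sd")))
  temp_idx <- 1:11
  prec_idx <- 12:19
  g[temp_idx, "intercept"] <- c(40, 12, 45, 700, 55, 20, 35, 40, 30, 45, 25)
  g[temp_idx, "lat"] <- c(-0.6, -0.05, -0.2, 6, -0.5, -0.7, -0.4, -0.55,
                          -0.6, -0.5, -0.65)
  g[temp_idx, "lon"] <- c(-0.05, 0.02, -0.1, 4, -0.05, -0.15, 0.02, -0.08,
                          -0.02, -0.05, -0.12)
  g[temp_idx, "sd"] <- c(0.8, 0.5, 2, 40, 1.2, 1.5, 1, 1, 1, 1, 1.3)
  g[prec_idx, "intercept"] <- c(900, 110, 40, 260, 180, 120, 200, 250)
  g[prec_idx, "lat"] <- c(5, 0.5, 0.2, 1.5, 1, 0.5, 1.2, 1.5)
  g[prec_idx, "lon"] <- c(-12, -1.5, 0.6, -4, -3.5, 2, -3, -4)
  g[prec_idx, "sd"] <- c(60, 6, 3, 15, 12, 8, 12, 15)
  g
}

# Route topology: populations are split across two subtrees; each new deme
# attaches to the most recent deme of its route with probability 0.7, else
# to a uniformly chosen earlier deme (occasional branching). Coordinates
# step away from the entry point with route-specific drift.
build_route_tree <- function(cfg) {
  n_south <- ceiling(cfg$n_pops / 2)
  n_north <- cfg$n_pops - n_south
  mk_route <- function(n, prefix, entry, dlat_mean, dlon_mean) {
    pop <- sprintf("%s%02d", prefix, seq_len(n))
    parent <- character(n); depth <- integer(n)
    lat <- numeric(n); lon <- numeric(n)
    lat[1] <- entry[1]; lon[1] <- entry[2]
    parent[1] <- NA_character_; depth[1] <- 0L
    for (i in seq_len(n)[-1]) {
      pi_ <- if (i == 2L || stats::runif(1) < 0.7) i - 1L
             else sample.int(i - 1L, 1L)
      parent[i] <- pop[pi_]
      depth[i] <- depth[pi_] + 1L
      lat[i] <- lat[pi_] + stats::rnorm(1, dlat_mean, 0.45)
      lon[i] <- lon[pi_] + stats::rnorm(1, dlon_mean, 0.5)
    }
    data.frame(population = pop, parent = parent, depth = depth,
               latitude = pmin(70, pmax(35, lat)),
               longitude = pmin(40, pmax(-10, lon)),
               stringsAsFactors = FALSE)
  }
  south <- mk_route(n_south, "S", cfg$entry_points$south, 0.18, 0.85)
  north <- mk_route(n_north, "N", cfg$entry_points$north, 0.10, 1.0)
  south$cluster <- "Western"; north$cluster <- "Eastern"
  south$route <- "south"; north$route <- "north"
  rbind(south, north)
}

# Site table: positions ~1 kb apart, random bases, a share of sites with the
# ancestral allele equal to ALT (exercising polarization flips) and a small
# share with a non-whitelist quality class.
build_sites <- function(cfg) {
  per_chr <- diff(round(seq(0, cfg$n_sites, length.out = cfg$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(cfg$n_chrom)), per_chr)
  pos <- unlist(lapply(per_chr, function(m) cumsum(sample(400:1600, m, TRUE))))
  bases <- c("A", "C", "G", "T")
  ref <- sample(bases, cfg$n_sites, TRUE)
  alt <- vapply(ref, function(r) sample(setdiff(bases, r), 1L), character(1))
  flip <- stats::runif(cfg$n_sites) < 0.3   # ancestral == alt at these sites
  qual <- ifelse(stats::runif(cfg$n_sites) < cfg$junk_quality_frac,
                 "CallRateBelowThreshold",
                 sample(c("PolyHighResolution", "NoMinorHom"),
                        cfg$n_sites, TRUE, prob = c(0.9, 0.1)))
  data.frame(chrom = chrom, pos = as.integer(pos), ref = ref, alt = alt,
             ancestral = ifelse(flip, alt, ref), quality_class = qual,
             multiallelic = FALSE, derived_is_alt = !flip,
             stringsAsFactors = FALSE)
}

# GERP scores: a frac_deleterious share of sites gets Gamma-distributed
# positive scores with a small point mass above 5 (highly deleterious);
# the rest score 0 (unconstrained).
build_gerp <- function(cfg, n_sites) {
  score <- numeric(n_sites)
  del <- stats::runif(n_sites) < cfg$frac_deleterious
  nd <- sum(del)
  sc <- stats::rgamma(nd, shape = cfg$gerp_law$shape, scale = cfg$gerp_law$scale)
  sc <- pmin(sc, 4.99)  # bulk stays below the highly-deleterious cutoff
  high <- stats::runif(nd) < cfg$gerp_law$p_high
  sc[high] <- stats::runif(sum(high), cfg$gerp_law$high_range[1],
                           cfg$gerp_law$high_range[2])
  score[del] <- sc
  score
}

#' Simulate a two-route serial-founder range expansion
#'
#' Ancestral derived-allele frequencies are drawn once; founding an edge
#' applies a binomial bottleneck of `founder_size` haploids, after which the
#' deme drifts by binomial Wright-Fisher updates at `deme_size`; existing
#' neighbour demes (route-tree edges, plus one reduced-rate contact edge
#' between the two routes) mix frequencies symmetrically each generation.
#' Genotypes are drawn per population under inbreeding-adjusted
#' Hardy-Weinberg: `P(het) = 2pq(1 - F)`.
#'
#' @param cfg A [sim_config()].
#' @return List of class `sim_result`: `panel` (`genotype_panel`,
#'   ALT-coded, with AA annotation), `popmap` (coordinates + cluster),
#'   `truth` (realized per-population derived frequencies, GERP vector,
#'   sweep list, route depths, expected bioclim), `gerp`, `bioclim`,
#'   `groups` (sample group map), and `config`.
#' @export
simulate_expansion <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(substream_seed(cfg$seed, "expansion"))
  tree <- build_route_tree(cfg)
  sites <- build_sites(cfg)
  gerp <- build_gerp(cfg, nrow(sites))

  p_anc <- stats::rbeta(cfg$n_sites, cfg$ancestral_freq_law[1],
                        cfg$ancestral_freq_law[2])
  if (cfg$gerp_freq_coupling > 0) {
    w <- pmin(1, gerp / 5) * cfg$gerp_freq_coupling
    p_anc <- p_anc * (1 - w)   # high-GERP derived alleles start rarer
  }

  k <- nrow(tree)
  found_gen <- tree$depth * cfg$generations_per_edge
  total_gen <- max(found_gen)
  freqs <- matrix(NA_real_, k, cfg$n_sites, dimnames = list(tree$population, NULL))
  parent_idx <- match(tree$parent, tree$population)
  deleterious <- gerp > 0

  # neighbour graph: tree edges + one inter-route contact (entry <-> entry)
  edges <- cbind(parent_idx, seq_len(k))
  edges <- edges[!is.na(edges[, 1L]), , drop = FALSE]
  contact <- c(which(tree$population == "S01"), which(tree$population == "N01"))
  m_edge <- rep(cfg$migration_rate, nrow(edges))
  edges <- rbind(edges, contact)
  m_edge <- c(m_edge, cfg$migration_rate * cfg$inter_route_migration)

  found_deme <- function(parent_p) {
    p <- stats::rbinom(cfg$n_sites, cfg$founder_size, parent_p) / cfg$founder_size
    if (cfg$mutation_rate_per_edge > 0) {
      mu <- deleterious & p == 0 &
        stats::runif(cfg$n_sites) < cfg$mutation_rate_per_edge
      p[mu] <- stats::runif(sum(mu), 0.05, 0.3)
    }
    p
  }

  for (t in 0:total_gen) {
    newly <- which(found_gen == t)
    for (i in newly) {
      freqs[i, ] <- found_deme(if (is.na(parent_idx[i])) p_anc
                               else freqs[parent_idx[i], ])
    }
    if (t == total_gen) break
    alive <- which(found_gen <= t)
    if (cfg$migration_rate > 0 && length(alive) > 1L) {
      mixed <- freqs
      for (e in seq_len(nrow(edges))) {
        a <- edges[e, 1L]; b <- edges[e, 2L]
        if (!(a %in% alive) || !(b %in% alive)) next
        m <- m_edge[e]
        mixed[a, ] <- mixed[a, ] + m * (freqs[b, ] - freqs[a, ])
        mixed[b, ] <- mixed[b, ] + m * (freqs[a, ] - freqs[b, ])
      }
      freqs[alive, ] <- mixed[alive, , drop = FALSE]
    }
    for (i in alive) {
      freqs[i, ] <- stats::rbinom(cfg$n_sites, cfg$deme_size, freqs[i, ]) /
        cfg$deme_size
    }
  }

  # planted sweeps: lift the focal derived frequency in the target deme
  sweeps <- lapply(cfg$sweep_specs %||% list(), function(sw) {
    cand <- which(sites$chrom == sw$chrom)
    if (!length(cand)) stop("sweep chromosome not simulated: ", sw$chrom)
    site <- cand[which.min(abs(sites$pos[cand] - sw$pos))]
    if (abs(sites$pos[site] - sw$pos) > 1e6) {
      stop("sweep position ", sw$pos, " too far from any simulated site")
    }
    if (!sw$population %in% tree$population) {
      stop("sweep population not simulated: ", sw$population)
    }
    freqs[sw$population, site] <<- sw$freq
    list(population = sw$population, chrom = sw$chrom,
         pos = sites$pos[site], site = site, freq = sw$freq,
         core_bp = sw$core_bp)
  })

  # elite pools: derived from the two entries with strong additional drift
  elite <- list()
  if (cfg$n_elite_pops > 0) {
    roots <- c("S01", "N01")[seq_len(min(2L, cfg$n_elite_pops))]
    for (j in seq_along(roots)) {
      p <- found_deme(freqs[roots[j], ])
      for (g in seq_len(cfg$elite_extra_generations)) {
        p <- stats::rbinom(cfg$n_sites, 50, p) / 50
      }
      elite[[paste0("Elite", LETTERS[j])]] <- p
    }
  }

  all_freqs <- rbind(freqs, do.call(rbind, elite))
  pop_names <- rownames(all_freqs)
  n_ind <- ifelse(pop_names %in% names(elite), cfg$n_per_elite, cfg$n_per_pop)
  f_ind <- ifelse(pop_names %in% names(elite), cfg$elite_inbreeding_f,
                  cfg$inbreeding_f)

  set.seed(substream_seed(cfg$seed, "genotypes"))
  dosage_list <- vector("list", length(pop_names))
  sample_ids <- character(0); sample_pop <- character(0)
  for (i in seq_along(pop_names)) {
    p <- all_freqs[i, ]; fin <- f_ind[i]; n <- n_ind[i]
    q <- 1 - p
    pr_het <- 2 * p * q * (1 - fin)
    pr_hom_d <- p^2 + fin * p * q
    u <- matrix(stats::runif(n * cfg$n_sites), n, cfg$n_sites)
    d <- matrix(0L, n, cfg$n_sites)
    d[u < rep(pr_hom_d, each = n)] <- 2L
    het <- u >= rep(pr_hom_d, each = n) & u < rep(pr_hom_d + pr_het, each = n)
    d[het] <- 1L
    if (cfg$missing_rate > 0) {
      d[matrix(stats::runif(n * cfg$n_sites) < cfg$missing_rate,
               n, cfg$n_sites)] <- NA_integer_
    }
    dosage_list[[i]] <- d
    ids <- sprintf("%s_%03d", pop_names[i], seq_len(n))
    sample_ids <- c(sample_ids, ids)
    sample_pop <- c(sample_pop, rep(pop_names[i], n))
  }
  derived_dosage <- do.call(rbind, dosage_list)

  # emit ALT-coded dosages as a VCF reader would produce them
  alt_dosage <- derived_dosage
  flip <- !sites$derived_is_alt
  alt_dosage[, flip] <- 2L - alt_dosage[, flip, drop = FALSE]

  popmap <- data.frame(
    population = pop_names,
    latitude = c(tree$latitude, rep(tree$latitude[contact], length.out = length(elite))),
    longitude = c(tree$longitude, rep(tree$longitude[contact], length.out = length(elite))),
    cluster = c(tree$cluster, rep("elite", length(elite))),
    stringsAsFactors = FALSE
  )
  set.seed(substream_seed(cfg$seed, "bioclim"))
  bioclim <- attach_bioclim(popmap, cfg$env_gradient,
                            seed = substream_seed(cfg$seed, "bioclim-vals"))

  groups <- data.frame(
    sample = sample_ids,
    group = ifelse(sample_pop %in% names(elite),
                   paste0("elite-", sub("Elite", "", sample_pop)),
                   paste0("landrace-",
                          popmap$cluster[match(sample_pop, popmap$population)])),
    stringsAsFactors = FALSE
  )

  panel <- genotype_panel(alt_dosage,
                          sites[, c("chrom", "pos", "ref", "alt", "ancestral",
                                    "quality_class", "multiallelic")],
                          sample_ids,
                          stats::setNames(sample_pop, sample_ids),
                          polarized = FALSE)
  truth <- list(
    pop_freqs = all_freqs,
    ancestral_freqs = p_anc,
    gerp = gerp,
    sweeps = sweeps,
    route = data.frame(population = tree$population, parent = tree$parent,
                       depth = tree$depth, route = tree$route,
                       stringsAsFactors = FALSE),
    bioclim_expected = attr(bioclim, "expected"),
    env_gradient = cfg$env_gradient
  )
  structure(list(panel = panel, popmap = popmap, truth = truth,
                 gerp = data.frame(chrom = sites$chrom, pos = sites$pos,
                                   score = gerp, stringsAsFactors = FALSE),
                 bioclim = bioclim, groups = groups, config = cfg),
            class = "sim_result")
}

#' @export
print.sim_result <- function(x, ...) {
  cat(sprintf("sim_result: %d populations (%d elite), %d samples x %d sites, %d sweep(s)\n",
              nrow(x$popmap), sum(x$popmap$cluster == "elite"),
              length(x$panel$sample_ids), nrow(x$panel$sites),
              length(x$truth$sweeps)))
  invisible(x)
}

#' Draw a doubled-haploid haplotype panel from population frequencies
#'
#' Haplotypes are drawn site-wise independently from the supplied derived
#' frequencies. Within each sweep core window, carriers of the focal derived
#' allele are then given one shared core haplotype with probability equal to
#' the sweep's completeness (its final derived frequency), producing the
#' elevated extended haplotype homozygosity a recent hard sweep leaves in a
#' recombination-poor panel.
#'
#' @param pop_freqs Numeric vector of derived frequencies, one per site.
#' @param sites Site table (`chrom`, `pos`).
#' @param n_lines Number of DH lines (>= 2).
#' @param sweep_spec Optional list with `site` (index), `freq`, `core_bp`.
#' @param seed Seed for this draw.
#' @return A `haplotype_panel`.
#' @export
make_dh_panel <- function(pop_freqs, sites, n_lines, sweep_spec = NULL,
                          seed = 1) {
  stopifnot(n_lines >= 2, length(pop_freqs) == nrow(sites))
  set.seed(seed)
  H <- matrix(stats::rbinom(n_lines * length(pop_freqs), 1L,
                            rep(pop_freqs, each = n_lines)),
              n_lines, length(pop_freqs))
  if (!is.null(sweep_spec)) {
    s <- sweep_spec$site
    if (is.null(s) || s < 1L || s > ncol(H)) stop("sweep site outside the simulated sites")
    core <- which(sites$chrom == sites$chrom[s] &
                    abs(sites$pos - sites$pos[s]) <= sweep_spec$core_bp / 2)
    H[, s] <- stats::rbinom(n_lines, 1L, sweep_spec$freq)
    carriers <- which(H[, s] == 1L)
    if (length(carriers) >= 2L) {
      template <- H[carriers[1L], core]
      template[match(s, core)] <- 1L
      copy <- carriers[stats::runif(length(carriers)) < sweep_spec$freq]
      copy <- union(copy, carriers[1L])
      H[copy, core] <- rep(template, each = length(copy))
      H[carriers, s] <- 1L
    }
  }
  haplotype_panel(H, sites[, c("chrom", "pos")],
                  sprintf("DH_%04d", seq_len(n_lines)))
}

#' Attach bioclimatic variables with planted spatial gradients
#'
#' Each of the 19 variables is `intercept + a*lat + b*lon + N(0, sd)`;
#' the noiseless expectations are recorded in the `"expected"` attribute.
#'
#' @param popmap `data.frame` with `population`, `latitude`, `longitude`.
#' @param env_gradient 19 x 4 matrix (`intercept`, `lat`, `lon`, `sd`).
#' @param seed Seed for the noise draw.
#' @return `data.frame` with `population`, `bio1`..`bio19`, `latitude`,
#'   `longitude`; attribute `"expected"` holds the noiseless values.
#' @export
attach_bioclim <- function(popmap, env_gradient = default_env_gradient(),
                           seed = 1) {
  stopifnot(all(c("latitude", "longitude") %in% names(popmap)),
            !anyNA(popmap$latitude), !anyNA(popmap$longitude))
  set.seed(seed)
  k <- nrow(popmap)
  mu <- sapply(seq_len(19), function(v) {
    env_gradient[v, "intercept"] +
      env_gradient[v, "lat"] * popmap$latitude +
      env_gradient[v, "lon"] * popmap$longitude
  })
  vals <- mu + sapply(seq_len(19), function(v) stats::rnorm(k, 0, env_gradient[v, "sd"]))
  colnames(mu) <- colnames(vals) <- paste0("bio", 1:19)
  out <- cbind(data.frame(population = popmap$population,
                          stringsAsFactors = FALSE),
               as.data.frame(vals),
               data.frame(latitude = popmap$latitude,
                          longitude = popmap$longitude))
  attr(out, "expected") <- cbind(population = popmap$population,
                                 as.data.frame(mu))
  out
}

#' Write a simulation bundle to disk in the pipeline's input formats
#'
#' Emits `genotypes.vcf`, `popmap.tsv`, `coords.tsv`, `gerp.tsv`,
#' `bioclim.tsv`, `groups.tsv`, `genes.bed`, `fourfold.tsv` and
#' `truth.json`.
#'
#' @param sim A `sim_result` from [simulate_expansion()].
#' @param dir Output directory (created if needed).
#' @param n_genes Number of synthetic gene intervals to place per
#'   chromosome.
#' @return Named character vector of file paths, invisibly.
#' @export
write_sim_bundle <- function(sim, dir, n_genes = 30) {
  stopifnot(inherits(sim, "sim_result"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(x) file.path(dir, x)
  write_vcf(sim$panel, f("genotypes.vcf"))
  write_tsv(data.frame(sample = sim$panel$sample_ids,
                       population = unname(sim$panel$pop_of_sample)),
            f("popmap.tsv"))
  write_tsv(sim$popmap, f("coords.tsv"))
  write_tsv(sim$gerp, f("gerp.tsv"))
  bc <- sim$bioclim; attr(bc, "expected") <- NULL
  write_tsv(bc, f("bioclim.tsv"))
  write_tsv(sim$groups, f("groups.tsv"))

  set.seed(substream_seed(sim$config$seed, "genes"))
  genes <- do.call(rbind, lapply(unique(sim$panel$sites$chrom), function(ch) {
    span <- range(sim$panel$sites$pos[sim$panel$sites$chrom == ch])
    start1 <- sort(sample(seq(span[1], span[2]), n_genes))
    len <- sample(500:5000, n_genes, TRUE)
    data.frame(chrom = ch, start0 = start1 - 1L, end = start1 + len,
               gene = paste0(ch, "g", seq_len(n_genes)))
  }))
  utils::write.table(genes, f("genes.bed"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)

  neutral <- which(sim$truth$gerp == 0)
  ff <- neutral[seq_along(neutral) %% 2 == 1]  # deterministic subsample
  write_tsv(data.frame(chrom = sim$panel$sites$chrom[ff],
                       pos = sim$panel$sites$pos[ff]),
            f("fourfold.tsv"))

  truth <- sim$truth
  truth$pop_freqs <- NULL  # large matrix kept in memory only
  jsonlite::write_json(truth, f("truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(c(vcf = f("genotypes.vcf"), popmap = f("popmap.tsv"),
              coords = f("coords.tsv"), gerp = f("gerp.tsv"),
              bioclim = f("bioclim.tsv"), groups = f("groups.tsv"),
              genes = f("genes.bed"), fourfold = f("fourfold.tsv"),
              truth = f("truth.json")))
}
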