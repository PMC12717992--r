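test_that("without drift every population keeps the ancestral frequencies", {
  cfg <- quick_sim_config(201, n_pops = 6, n_sites = 300,
                          founder_size = 1e6, deme_size = 1e6,
                          generations_per_edge = 0, migration_rate = 0)
  sim <- simulate_expansion(cfg)
  dev <- abs(sweep(sim$truth$pop_freqs, 2, sim$truth$ancestral_freqs))
  expect_lt(max(dev), 0.01)
})

test_that("long isolated drift at tiny deme size drives sites to fixation", {
  cfg <- quick_sim_config(202, n_pops = 4, n_sites = 200, deme_size = 20,
                          founder_size = 20, generations_per_edge = 1500,
                          migration_rate = 0, mutation_rate_per_edge = 0)
  sim <- simulate_expansion(cfg)
  fixed <- sim$truth$pop_freqs %in% c(0, 1)
  expect_gt(mean(fixed), 0.99)
})

test_that("final frequencies are a martingale without migration", {
  # mean deviation from the ancestral frequency over 200 replicates is
  # within 3 standard errors of zero for the deepest population
  devs <- vapply(1:200, function(r) {
    cfg <- quick_sim_config(5000 + r, n_pops = 4, n_sites = 60,
                            generations_per_edge = 5, migration_rate = 0,
                            mutation_rate_per_edge = 0)
    sim <- simulate_expansion(cfg)
    deepest <- sim$truth$route$population[which.max(sim$truth$route$depth)]
    mean(sim$truth$pop_freqs[deepest, ] - sim$truth$ancestral_freqs)
  }, numeric(1))
  se <- stats::sd(devs) / sqrt(length(devs))
  expect_lt(abs(mean(devs)), 3 * se + 1e-3)
})

test_that("expected heterozygosity declines with route depth (serial founder effect)", {
  # Monte-Carlo over seeds: within-route Spearman of 2pq vs depth is negative
  rhos <- vapply(1:20, function(r) {
    cfg <- quick_sim_config(300 + r, n_pops = 12, n_sites = 300,
                            generations_per_edge = 25, migration_rate = 0)
    sim <- simulate_expansion(cfg)
    f <- sim$truth$pop_freqs
    hexp <- rowMeans(2 * f * (1 - f))
    depth <- sim$truth$route$depth[match(rownames(f),
                                         sim$truth$route$population)]
    suppressWarnings(stats::cor(hexp, depth, method = "spearman"))
  }, numeric(1))
  expect_lt(median(rhos), 0)
  expect_gte(sum(rhos < 0), 18)
})

test_that("identical configurations reproduce byte-identical bundles", {
  cfg <- quick_sim_config(203, n_pops = 6, n_sites = 120,
                          missing_rate = 0.01, junk_quality_frac = 0.05)
  d1 <- tempfile(); d2 <- tempfile()
  f1 <- write_sim_bundle(simulate_expansion(cfg), d1)
  f2 <- write_sim_bundle(simulate_expansion(quick_sim_config(203, n_pops = 6,
                                                             n_sites = 120,
                                                             missing_rate = 0.01,
                                                             junk_quality_frac = 0.05)),
                         d2)
  for (k in names(f1)) {
    expect_identical(unname(tools::md5sum(f1[k])), unname(tools::md5sum(f2[k])),
                     label = paste("md5 of", k))
  }
  # different seed changes the genotypes
  f3 <- write_sim_bundle(simulate_expansion(quick_sim_config(204, n_pops = 6,
                                                             n_sites = 120,
                                                             missing_rate = 0.01,
                                                             junk_quality_frac = 0.05)),
                         tempfile())
  expect_false(unname(tools::md5sum(f1["vcf"])) == unname(tools::md5sum(f3["vcf"])))
})

test_that("DH panels reproduce site frequencies and haplotype independence", {
  # no sweep, 2 sites at freq 0.5: the four haplotypes are ~equifrequent
  sites <- data.frame(chrom = "chr1", pos = c(1000, 2000))
  hp <- make_dh_panel(c(0.5, 0.5), sites, n_lines = 10000, seed = 11)
  counts <- table(factor(paste0(hp$H[, 1], hp$H[, 2]),
                         levels = c("00", "01", "10", "11")))
  chi <- stats::chisq.test(counts, p = rep(0.25, 4))
  expect_gt(chi$p.value, 0.001)

  expect_error(make_dh_panel(c(0.5, 0.5), sites, n_lines = 10,
                             sweep_spec = list(site = 99, freq = 1,
                                               core_bp = 100), seed = 1),
               "outside the simulated sites")
})

test_that("bioclim attachment plants exact and noisy gradients", {
  popmap <- data.frame(population = paste0("P", 1:12),
                       latitude = runif(12, 38, 55),
                       longitude = runif(12, -9, 25),
                       stringsAsFactors = FALSE)
  grad <- landracepopgen:::default_env_gradient()
  grad[, "sd"] <- 0
  grad["bio1", c("intercept", "lat", "lon")] <- c(0, -1, 0)
  bc <- attach_bioclim(popmap, grad, seed = 2)
  expect_equal(suppressWarnings(stats::cor(bc$bio1, -popmap$latitude,
                                           method = "spearman")), 1)
  expect_equal(bc$bio1, -popmap$latitude)
  # expectations recorded for every variable
  expect_equal(dim(attr(bc, "expected")), c(12L, 20L))

  # zero gradient: no spurious distance correlation in >= 90% of seeds
  flat <- grad; flat[, c("lat", "lon")] <- 0; flat[, "sd"] <- 1
  entry <- popmap$population[1]
  null_ok <- vapply(1:100, function(r) {
    b <- attach_bioclim(popmap, flat, seed = r)
    g <- gradient_correlation(stats::setNames(b$bio2, b$population),
                              entry, popmap)
    g$p >= 0.05
  }, logical(1))
  expect_gte(mean(null_ok), 0.9)
})

test_that("a planted route gradient is recovered with the correct sign", {
  # bio12 declines with longitude (built-in gradient) and the southern route
  # heads east, so its value should fall with distance from the entry;
  # sign recovery is checked across seeds at the default route span
  rhos <- vapply(1:10, function(r) {
    cfg <- quick_sim_config(400 + r, n_pops = 24, n_sites = 20)
    sim <- simulate_expansion(cfg)
    route_correlation(sim$bioclim, "bio12", "S01", sim$popmap,
                      cluster = "Western")$rho
  }, numeric(1))
  expect_lt(median(rhos), 0)
  expect_gte(sum(rhos < 0), 8)
})

test_that("simulated panels carry the advertised structure", {
  cfg <- quick_sim_config(206, n_elite_pops = 2, missing_rate = 0.01,
                          junk_quality_frac = 0.03)
  sim <- simulate_expansion(cfg)
  expect_s3_class(sim$panel, "genotype_panel")
  expect_equal(nrow(sim$popmap), 12L)  # 10 landraces + 2 elite pools
  expect_setequal(unique(sim$groups$group),
                  c("landrace-Western", "landrace-Eastern",
                    "elite-A", "elite-B"))
  expect_true(any(is.na(sim$panel$dosage)))
  expect_true(any(sim$panel$sites$quality_class == "CallRateBelowThreshold"))
  # elite pools are near-fully inbred: almost no heterozygous calls
  el <- sim$panel$dosage[sim$panel$pop_of_sample %in% c("EliteA", "EliteB"), ]
  expect_lt(mean(el == 1L, na.rm = TRUE), 0.05)
  # route tree spans all landraces, acyclic by construction (depth strictly
  # greater than the parent's)
  rt <- sim$truth$route
  pd <- rt$depth[match(rt$parent, rt$population)]
  expect_true(all(rt$depth[!is.na(rt$parent)] == pd[!is.na(rt$parent)] + 1L))
})
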