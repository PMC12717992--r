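test_that("EHH hits closed-form values and the brute-force pair-counting oracle", {
  # all carriers identical over the window -> EHH = 1 everywhere
  H <- matrix(rep(c(1, 0, 1, 1, 0), 4), 4, 5, byrow = TRUE)
  hp <- haplotype_panel(H, data.frame(chrom = "chr1", pos = (1:5) * 1000))
  e <- ehh(hp, 1, 1, "right", ehh_cutoff = 0)
  expect_equal(e$ehh, rep(1, 5))

  # carriers split into two equal internally identical groups: EHH = 1/3
  H2 <- rbind(c(1, 0, 0), c(1, 0, 1), c(1, 1, 0), c(1, 1, 1),
              c(0, 0, 0), c(0, 0, 0))
  hp2 <- haplotype_panel(H2, data.frame(chrom = "chr1", pos = c(100, 200, 300)))
  e2 <- ehh(hp2, 1, 1, "right", ehh_cutoff = 0)
  expect_equal(e2$ehh[2], 2 * choose(2, 2) / choose(4, 2))  # = 1/3

  expect_error(ehh(hp2, 2, 1, "right"), NA)   # 2 carriers is enough
  H3 <- H2; H3[, 1] <- c(1, 0, 0, 0, 0, 0)
  hp3 <- haplotype_panel(H3, data.frame(chrom = "chr1", pos = c(100, 200, 300)))
  expect_error(ehh(hp3, 1, 1, "right"), "fewer than 2 carriers")

  # random panels against the exhaustive prefix-identity oracle, both directions
  for (seed in c(1, 2, 3)) {
    hp4 <- random_hpanel(seed, n_lines = 6, ns = 15)
    core <- 8L
    for (al in 0:1) for (dr in c("left", "right")) {
      if (sum(hp4$H[, core] == al) < 2) next
      got <- ehh(hp4, core, al, dr, ehh_cutoff = 0)
      want <- ehh_oracle(hp4$H, hp4$sites, core, al, dr)
      expect_equal(got$pos, want$pos)
      expect_equal(got$ehh, want$ehh)
      # monotone non-increasing, EHH(core) = 1
      expect_equal(got$ehh[1], 1)
      expect_true(all(diff(got$ehh) <= 1e-12))
    }
  }
})

test_that("iHH integrates EHH curves as rectangle, triangle and against integrate()", {
  # EHH == 1 over 10,000 bp -> area 10,000
  rect <- data.frame(pos = c(0, 10000), ehh = c(1, 1))
  expect_equal(ihh(rect), 10000)
  # linear decay 1 -> 0 over 10,000 bp -> area 5,000
  tri <- data.frame(pos = seq(0, 10000, by = 1000),
                    ehh = seq(1, 0, length.out = 11))
  expect_equal(ihh(tri), 5000)
  # random piecewise-linear curve vs adaptive quadrature oracle
  set.seed(8)
  pos <- sort(sample(1:50000, 20))
  vals <- sort(runif(20), decreasing = TRUE)
  curve <- data.frame(pos = pos, ehh = vals)
  # fine-grained midpoint Riemann sum (exact within linear segments)
  h <- (max(pos) - min(pos)) / 2^21
  mids <- seq(min(pos) + h / 2, max(pos) - h / 2, by = h)
  orc <- sum(stats::approx(pos, vals, xout = mids)$y * h)
  expect_equal(ihh(curve), orc, tolerance = 1e-6)
  # gap capping bounds any single trapezoid's width
  gap <- data.frame(pos = c(0, 1e6), ehh = c(1, 1))
  expect_equal(ihh(gap, max_gap = 200000), 200000)
  expect_equal(ihh(gap[1, , drop = FALSE]), 0)
})

test_that("iHS is 0 under derived/ancestral symmetry and negative for long derived haplotypes", {
  # symmetric panel: derived and ancestral carriers have mirror-image haplotypes
  ns <- 9
  H <- rbind(matrix(1, 3, ns), matrix(0, 3, ns))
  hp <- haplotype_panel(H, data.frame(chrom = "chr1", pos = (1:ns) * 1000))
  core <- 5L
  ihh_d <- ihh(ehh(hp, core, 1, "left")) + ihh(ehh(hp, core, 1, "right"))
  ihh_a <- ihh(ehh(hp, core, 0, "left")) + ihh(ehh(hp, core, 0, "right"))
  expect_equal(log(ihh_a / ihh_d), 0)

  # longer derived haplotypes => ihs_raw < 0 (ln(iHH_A / iHH_D) convention)
  set.seed(19)
  n <- 60; ns <- 41
  H2 <- matrix(rbinom(n * ns, 1, 0.5), n, ns)
  core <- 21L
  H2[, core] <- rep(c(1, 0), each = n / 2)
  H2[1:(n / 2), (core - 6):(core + 6)] <- 1   # shared long derived haplotype
  hp2 <- haplotype_panel(H2, data.frame(chrom = "chr1", pos = (1:ns) * 1000))
  suppressWarnings(res <- ihs_scan(hp2, n_bins = 10))
  expect_lt(res$ihs_raw[res$site == core], 0)

  # antisymmetry under swapping the derived/ancestral labels at every site
  hp_swap <- haplotype_panel(1L - H2, hp2$sites)
  suppressWarnings(res_swap <- ihs_scan(hp_swap, n_bins = 10))
  expect_equal(res_swap$ihs_raw[res_swap$site == core],
               -res$ihs_raw[res$site == core])
})

test_that("standardized iHS has mean 0 and sd 1 within frequency bins", {
  set.seed(23)
  hp <- random_hpanel(23, n_lines = 40, ns = 120)
  suppressWarnings(res <- ihs_scan(hp, n_bins = 5))
  ok <- !is.na(res$ihs_std)
  bins <- cut(res$daf, seq(0, 1, length.out = 6), include.lowest = TRUE)
  for (b in unique(bins[ok])) {
    z <- res$ihs_std[ok & bins == b]
    if (length(z) < 2) next
    expect_equal(mean(z), 0, tolerance = 1e-10)
    expect_equal(sd(z), 1, tolerance = 1e-10)
  }
})

test_that("empirical classification implements the rank-based dual-threshold rule", {
  mk <- function(z) {
    r <- data.frame(site = seq_along(z), chrom = "chr1",
                    pos = seq_along(z) * 1000, daf = 0.5,
                    ihh_d = 1, ihh_a = 1, ihs_raw = z, edge_censored = FALSE,
                    ihs_std = z)
    class(r) <- c("ihs_result", "data.frame")
    r
  }
  # N = 100, largest |iHS| gets emp_p = 0.01
  z <- seq(0.01, 1, length.out = 100); z[100] <- 5
  cl <- empirical_classify(mk(z))
  expect_equal(cl$emp_p[100], 0.01)
  # emp_p values form the uniform grid {1/N, ..., 1} for distinct scores
  expect_equal(sort(cl$emp_p), seq_len(100) / 100)

  # dual threshold: |z| = 2.5 at emp_p = 0.04 significant; 1.5 there is not
  z1 <- c(rep(0.1, 96), 2.5, 3, 3.5, 4)       # 2.5 has rank 4/100 -> 0.04
  cl1 <- empirical_classify(mk(z1))
  expect_equal(cl1$emp_p[97], 0.04)
  expect_true(cl1$significant[97])
  z2 <- c(rep(0.1, 96), 1.5, 3, 3.5, 4)       # same rank, |z| below 2
  cl2 <- empirical_classify(mk(z2))
  expect_equal(cl2$emp_p[97], 0.04)
  expect_false(cl2$significant[97])
})

test_that("planted hard sweeps give EHH = 1 cores and are flagged by the scan", {
  cfg <- quick_sim_config(301, sweep_specs = list(
    list(population = "S03", chrom = "chr1", pos = 120000, freq = 1.0,
         core_bp = 30000)))
  sim <- simulate_expansion(cfg)
  sw <- sim$truth$sweeps[[1]]
  hp <- make_dh_panel(sim$truth$pop_freqs["S03", ], sim$panel$sites, 100,
                      sw, seed = 5)
  # completeness 1: all haplotypes identical across the core -> EHH 1 across it
  core_sites <- which(hp$sites$chrom == sw$chrom &
                        abs(hp$sites$pos - sw$pos) <= sw$core_bp / 2)
  e <- ehh(hp, sw$site, 1, "right", ehh_cutoff = 0.01)
  in_core <- e$pos <= max(hp$sites$pos[core_sites])
  expect_true(all(e$ehh[in_core] == 1))

  # partial sweep (0.7) is flagged by the dual-threshold classification
  cfg2 <- quick_sim_config(302, sweep_specs = list(
    list(population = "S03", chrom = "chr1", pos = 120000, freq = 0.7,
         core_bp = 30000)))
  sim2 <- simulate_expansion(cfg2)
  sw2 <- sim2$truth$sweeps[[1]]
  hp2 <- make_dh_panel(sim2$truth$pop_freqs["S03", ], sim2$panel$sites, 200,
                       sw2, seed = 6)
  suppressWarnings(res <- empirical_classify(ihs_scan(hp2, n_bins = 20)))
  core <- res$chrom == sw2$chrom & abs(res$pos - sw2$pos) <= sw2$core_bp / 2
  expect_true(any(res$significant[core], na.rm = TRUE))
})

test_that("nearest_gene matches a brute-force all-genes scan with upstream tie-break", {
  genes <- data.frame(chrom = "chr1", start = c(1000, 5000, 9000),
                      end = c(2000, 6000, 9500),
                      gene = c("g1", "g2", "g3"), stringsAsFactors = FALSE)
  sites <- data.frame(chrom = c("chr1", "chr1", "chr1", "chr2"),
                      pos = c(1500, 3500, 7500, 100))
  ng <- nearest_gene(sites, genes)
  # 3500 is equidistant to g1 (end 2000) and g2 (start 5000): upstream g1 wins;
  # 7500 is equidistant to g2 (end 6000) and g3 (start 9000): upstream g2 wins
  expect_equal(ng$gene, c("g1", "g1", "g2", NA))
  expect_equal(ng$distance, c(0L, 1500L, 1500L, NA))
  expect_equal(ng$side, c("inside", "upstream", "upstream", "unplaced"))

  # 100 random sites vs 20 random genes: exhaustive scan oracle
  set.seed(71)
  g2 <- data.frame(chrom = sample(c("chr1", "chr2"), 20, TRUE),
                   start = sample(1:90000, 20), stringsAsFactors = FALSE)
  g2$end <- g2$start + sample(200:3000, 20, TRUE)
  g2$gene <- paste0("g", 1:20)
  s2 <- data.frame(chrom = sample(c("chr1", "chr2"), 100, TRUE),
                   pos = sample(1:100000, 100))
  got <- nearest_gene(s2, g2)
  for (i in seq_len(100)) {
    cand <- which(g2$chrom == s2$chrom[i])
    dists <- vapply(cand, function(g) {
      if (s2$pos[i] >= g2$start[g] && s2$pos[i] <= g2$end[g]) 0L
      else min(abs(s2$pos[i] - g2$start[g]), abs(s2$pos[i] - g2$end[g]))
    }, integer(1))
    best <- cand[dists == min(dists)]
    best <- best[order(g2$start[best])][1]
    expect_equal(got$gene[i], g2$gene[best])
    expect_equal(abs(got$distance[i]), min(dists))
  }
})
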