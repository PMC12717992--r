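test_that("neutral PCs separate groups and match an eigen-decomposition oracle", {
  set.seed(90)
  d <- rbind(matrix(rbinom(10 * 40, 2, 0.15), 10, 40),
             matrix(rbinom(10 * 40, 2, 0.85), 10, 40))
  panel <- toy_panel(d, pops = rep(c("A", "B"), each = 10))
  ff <- panel$sites[, c("chrom", "pos")]
  pcs <- neutral_pcs(panel, ff, n_pcs = 2)
  expect_true(all(pcs[1:10, 1] * pcs[11:20, 1] < 0))  # PC1 separates the groups

  # eigen oracle up to sign
  x <- scale(d, center = TRUE, scale = FALSE)
  ev <- eigen(stats::cov(x))
  score1 <- x %*% ev$vectors[, 1]
  expect_equal(abs(as.numeric(stats::cor(pcs[, 1], score1))), 1,
               tolerance = 1e-8)

  expect_error(neutral_pcs(panel, data.frame(chrom = "chrX", pos = 1)),
               "no overlap")
  expect_error(neutral_pcs(toy_panel(matrix(1L, 5, 10)),
                           data.frame(chrom = "chr1",
                                      pos = seq(1000, 10000, by = 1000))),
               "no variance")
})

test_that("partial_rda matches explicit hat-matrix algebra and OLS limits", {
  set.seed(91)
  n <- 10
  y <- matrix(rnorm(n * 3), n, 3)
  x <- matrix(rnorm(n * 2), n, 2)
  z <- matrix(rnorm(n), n, 1)
  got <- partial_rda(y, x, z, n_perm = 0)

  # brute-force oracle with explicit projection matrices
  cz <- scale(z, scale = FALSE)
  hz <- cz %*% solve(crossprod(cz)) %*% t(cz)
  yr <- scale(y, scale = FALSE) - hz %*% scale(y, scale = FALSE)
  xr <- scale(x, scale = FALSE) - hz %*% scale(x, scale = FALSE)
  hx <- xr %*% solve(crossprod(xr)) %*% t(xr)
  r2_oracle <- sum((hx %*% yr)^2) / sum(yr^2)
  expect_equal(got$r2, r2_oracle, tolerance = 1e-10)
  expect_equal(got$adj_r2, 1 - (1 - r2_oracle) * (n - 1) / (n - 2 - 1),
               tolerance = 1e-10)

  # orthogonal response: R2 ~ 0 at large n
  set.seed(92)
  yy <- matrix(rnorm(500), 250, 2); xx <- matrix(rnorm(250), 250, 1)
  expect_lt(partial_rda(yy, xx, n_perm = 0)$r2, 0.05)

  # exact linear map: unadjusted R2 = 1
  b <- matrix(rnorm(2 * 3), 2, 3)
  expect_equal(partial_rda(x %*% b, x, n_perm = 0)$r2, 1, tolerance = 1e-12)

  # empty conditions, single response column: exactly OLS R^2
  y1 <- y[, 1]
  fit <- lm(y1 ~ x)
  expect_equal(partial_rda(y1, x, n_perm = 0)$r2,
               summary(fit)$r.squared, tolerance = 1e-12)
})

test_that("partial_rda agrees with vegan's constrained ordination", {
  skip_if_not_installed("vegan")
  set.seed(93)
  n <- 24
  y <- matrix(rnorm(n * 6), n, 6)
  x <- data.frame(a = rnorm(n), b = rnorm(n))
  got <- partial_rda(y, x, n_perm = 0)
  v <- vegan::rda(y ~ a + b, data = x)
  expect_equal(got$r2, unname(vegan::RsquareAdj(v)$r.squared), tolerance = 1e-8)
  expect_equal(got$adj_r2, unname(vegan::RsquareAdj(v)$adj.r.squared),
               tolerance = 1e-8)
  # with conditions: constrained sum of squares matches vegan's inertia
  z <- data.frame(c1 = rnorm(n))
  gotc <- partial_rda(y, x, z, n_perm = 0)
  vc <- vegan::rda(y ~ a + b + Condition(c1), data = cbind(x, z))
  ss_constrained <- gotc$r2 * sum(landracepopgen:::residualize(y, z)^2)
  expect_equal(ss_constrained / (n - 1), unname(vc$CCA$tot.chi),
               tolerance = 1e-8)
})

test_that("forward selection finds an exact driver and resists pure noise", {
  set.seed(94)
  n <- 40
  cand <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(cand) <- paste0("bio", 1:6)
  resp <- cbind(2 * cand$bio3, -cand$bio3)   # exact function of bio3 only
  sel <- forward_select(resp, cand, n_perm = 199, seed = 4)
  expect_equal(sel$variable, "bio3")

  # two planted drivers recovered before any noise variable
  set.seed(94)
  resp2 <- cbind(cand$bio1 + 0.8 * cand$bio5 + rnorm(n, 0, 0.3),
                 cand$bio1 - 0.5 * cand$bio5 + rnorm(n, 0, 0.3))
  sel2 <- forward_select(resp2, cand, n_perm = 199, seed = 5)
  expect_true(all(c("bio1", "bio5") %in% sel2$variable[1:2]))

  # near-collinear candidate is skipped with a warning
  cand3 <- cand
  cand3$bio6 <- cand3$bio3 + rnorm(n, 0, 1e-4)
  expect_warning(sel3 <- forward_select(cbind(cand3$bio3 + rnorm(n, 0, 0.1)),
                                        cand3, stop_r2 = Inf, n_perm = 199,
                                        seed = 6),
                 "collinear")
  expect_false(all(c("bio3", "bio6") %in% sel3$variable))
})

test_that("forward selection under a pure-noise null rarely selects anything", {
  empty <- 0
  n_rep <- 40
  for (r in seq_len(n_rep)) {
    set.seed(1000 + r)
    n <- 30
    cand <- as.data.frame(matrix(rnorm(n * 6), n, 6))
    resp <- matrix(rnorm(n * 4), n, 4)
    sel <- forward_select(resp, cand, n_perm = 99, seed = r)
    if (nrow(sel) == 0) empty <- empty + 1
  }
  expect_gte(empty / n_rep, 0.85)
})

test_that("variance partitioning attributes planted climate effects and obeys nesting", {
  set.seed(95)
  n <- 50
  climate <- matrix(rnorm(n * 3), n, 3)
  structure_ <- matrix(rnorm(n * 2), n, 2)
  geo <- matrix(rnorm(n * 2), n, 2)
  resp <- climate %*% matrix(rnorm(3 * 8), 3, 8) + matrix(rnorm(n * 8, 0, 0.5), n, 8)
  vp <- variance_partition(resp, climate, structure_, geo, n_perm = 99, seed = 2)
  tab <- vp$model_table
  expect_gt(tab$adj_r2[tab$model == "climate-pure"],
            tab$adj_r2[tab$model == "structure-pure"])
  expect_gt(tab$adj_r2[tab$model == "climate-pure"],
            tab$adj_r2[tab$model == "geography-pure"])
  expect_lt(tab$p[tab$model == "climate-pure"], 0.05)

  # nested models: full unadjusted R2 >= any single block without conditions
  for (blk in list(climate, structure_, geo)) {
    expect_gte(tab$r2[tab$model == "full"] + 1e-12,
               partial_rda(resp, blk, n_perm = 0)$r2)
  }

  # affine rescaling of a block leaves the partition unchanged
  vp2 <- variance_partition(resp, climate * 100 + 3, structure_, geo,
                            n_perm = 99, seed = 2)
  expect_equal(vp2$model_table$r2, tab$r2, tolerance = 1e-8)
  expect_equal(vp2$model_table$p, tab$p)

  # independent response: all adjusted R2 near 0
  resp0 <- matrix(rnorm(n * 8), n, 8)
  vp0 <- variance_partition(resp0, climate, structure_, geo, n_perm = 0, seed = 3)
  expect_true(all(abs(vp0$model_table$adj_r2) < 0.15))
  expect_error(variance_partition(resp, climate * 0, structure_, geo),
               "constant column in block: climate")
})

test_that("route_correlation recovers monotone climate gradients", {
  popmap <- data.frame(population = paste0("P", 1:8),
                       latitude = rep(45, 8), longitude = seq(0, 21, by = 3),
                       stringsAsFactors = FALSE)
  bc <- attach_bioclim(popmap, seed = 1)
  # fabricate a variable strictly increasing with distance from P1
  bc$bio1 <- seq_len(8)
  rc <- route_correlation(bc, "bio1", "P1", popmap)
  expect_equal(rc$rho, 1)
})

test_that("Wilcoxon cluster contrasts behave at null, extreme and shifted alternatives", {
  pops <- paste0("P", 1:20)
  cl <- stats::setNames(rep(c("W", "E"), each = 10), pops)
  mk_bc <- function(vals) {
    bc <- data.frame(population = pops, stringsAsFactors = FALSE)
    for (v in paste0("bio", 1:19)) bc[[v]] <- 0
    bc$bio1 <- vals
    bc
  }
  # disjoint supports at n = 10 per group: minimal attainable two-sided p
  bc <- mk_bc(c(1:10, 101:110))
  ct <- suppressWarnings(cluster_bioclim_tests(bc, cl, vars = "bio1"))
  expect_equal(ct$table$p, 2 / choose(20, 10), tolerance = 1e-12)

  # all-tied variable: p = 1 with warning
  expect_warning(ct2 <- cluster_bioclim_tests(mk_bc(rep(1, 20)), cl,
                                              vars = "bio1"),
                 "all-tied")
  expect_equal(ct2$table$p, 1)

  # power > 0.9 for a 2-sd shift with n = 15 per cluster, over 200 draws
  pops2 <- paste0("Q", 1:30)
  cl2 <- stats::setNames(rep(c("W", "E"), each = 15), pops2)
  hits <- 0
  set.seed(96)
  for (r in 1:200) {
    a <- rnorm(15, 0, 1); b <- rnorm(15, 2, 1)
    if (suppressWarnings(stats::wilcox.test(a, b))$p.value < 0.05) hits <- hits + 1
  }
  expect_gt(hits / 200, 0.9)

  # null: p-values roughly uniform (mean near 0.5 over 200 draws)
  set.seed(97)
  ps <- replicate(200, suppressWarnings(
    stats::wilcox.test(rnorm(15), rnorm(15))$p.value))
  expect_gt(mean(ps), 0.4); expect_lt(mean(ps), 0.6)
})
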