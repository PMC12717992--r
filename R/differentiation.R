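# Pairwise Hudson F_ST with block structure, Slatkin linearization,
# geographic/environmental distance matrices, isolation-by-distance and
# cluster-contrast tests.

#' Per-site components of the Hudson F_ST estimator
#'
#' Bhatia-style unbiased per-site numerator and denominator:
#' `num = (p1-p2)^2 - p1(1-p1)/(n1-1) - p2(1-p2)/(n2-1)` and
#' `den = p1(1-p2) + p2(1-p1)`, with `n1`, `n2` the non-missing allele
#' counts. Sites with fewer than 2 alleles observed in either population are
#' skipped (`NA` components).
#'
#' @param p1,p2 Allele frequencies per site in the two populations.
#' @param n1,n2 Non-missing allele counts per site.
#' @return List with vectors `num` and `den` (`NA` where skipped).
#' @export
hudson_components <- function(p1, n1, p2, n2) {
  ok <- n1 >= 2 & n2 >= 2
  num <- (p1 - p2)^2 - p1 * (1 - p1) / (n1 - 1) - p2 * (1 - p2) / (n2 - 1)
  den <- p1 * (1 - p2) + p2 * (1 - p1)
  num[!ok] <- NA_real_
  den[!ok] <- NA_real_
  list(num = num, den = den)
}

#' Blockwise Hudson F_ST: ratio of sums with block-jackknife SE
#'
#' Overall `F_ST = sum(num) / sum(den)` (ratio of sums, not mean of
#' per-site ratios). The standard error comes from a delete-one-block
#' jackknife over contiguous blocks of `block_size` variants; with a single
#' block the SE is undefined.
#'
#' @param nums,dens Per-site components from [hudson_components()].
#' @param block_size Number of variants per jackknife block.
#' @return List with `fst`, `se`, `n_sites`, `n_blocks`.
#' @export
blockwise_fst <- function(nums, dens, block_size = 100000) {
  ok <- !is.na(nums) & !is.na(dens)
  nums <- nums[ok]; dens <- dens[ok]
  if (!length(nums)) stop("no usable site for F_ST")
  tot_den <- sum(dens)
  if (tot_den == 0) {
    warning("sum of denominators is 0; F_ST undefined")
    return(list(fst = NA_real_, se = NA_real_, n_sites = length(nums),
                n_blocks = 0L))
  }
  fst <- sum(nums) / tot_den
  blocks <- ceiling(seq_along(nums) / block_size)
  nb <- max(blocks)
  se <- NA_real_
  if (nb >= 2L) {
    bn <- tapply(nums, blocks, sum)
    bd <- tapply(dens, blocks, sum)
    loo <- (sum(bn) - bn) / (sum(bd) - bd)
    # standard delete-one jackknife variance
    se <- sqrt((nb - 1) / nb * sum((loo - mean(loo))^2))
  }
  list(fst = fst, se = se, n_sites = length(nums), n_blocks = as.integer(nb))
}

#' Slatkin's linearized F_ST
#'
#' `F / (1 - F)`, approximately linear in divergence time under drift.
#' `F = 1` maps to `NA` with a warning (infinite linearization).
#'
#' @param fst Numeric vector of F_ST values.
#' @return Numeric vector.
#' @export
slatkin_linearized <- function(fst) {
  out <- fst / (1 - fst)
  if (any(fst == 1, na.rm = TRUE)) {
    warning("F_ST = 1 linearizes to infinity; reported as NA")
    out[fst == 1] <- NA_real_
  }
  out
}

# Frequencies and allele counts per site for one population's samples.
pop_freq_counts <- function(panel, ids) {
  d <- panel$dosage[ids, , drop = FALSE]
  n <- 2 * colSums(!is.na(d))
  p <- ifelse(n > 0, colSums(d, na.rm = TRUE) / n, NA_real_)
  list(p = p, n = n)
}

#' All pairwise Hudson F_ST between populations
#'
#' Sites used per pair are, by default, those segregating within the union
#' of the pair (`seg_scope = "pair"`); `"global"` uses sites segregating
#' anywhere in the panel.
#'
#' @param panel A `genotype_panel`.
#' @param block_size Variants per jackknife block.
#' @param seg_scope `"pair"` or `"global"` segregating-site scope.
#' @return Object of class `fst_matrix`: list with `populations`, matrices
#'   `fst`, `se`, `linearized`, `n_sites`, and a long-format `pairs`
#'   `data.frame`. Raw (possibly slightly negative) estimates are kept; a
#'   zero-floored copy is in `fst_floored`.
#' @export
pairwise_fst <- function(panel, block_size = 100000,
                         seg_scope = c("pair", "global")) {
  seg_scope <- match.arg(seg_scope)
  pops <- sort(unique(panel$pop_of_sample))
  k <- length(pops)
  if (k < 2L) stop("need at least two populations")
  fc <- lapply(pops, function(pp) pop_freq_counts(panel, pop_samples(panel, pp)))
  names(fc) <- pops
  glob_seg <- {
    d <- panel$dosage
    p <- colMeans(d, na.rm = TRUE) / 2
    is.finite(p) & p > 0 & p < 1
  }
  m <- matrix(0, k, k, dimnames = list(pops, pops))
  se <- m; ns <- m
  rows <- list()
  for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) {
    a <- fc[[i]]; b <- fc[[j]]
    use <- if (seg_scope == "pair") {
      nu <- a$n + b$n
      pu <- ifelse(nu > 0, (a$p * a$n + b$p * b$n) / nu, NA_real_)
      is.finite(pu) & pu > 0 & pu < 1
    } else glob_seg
    hc <- hudson_components(a$p[use], a$n[use], b$p[use], b$n[use])
    bf <- blockwise_fst(hc$num, hc$den, block_size)
    m[i, j] <- m[j, i] <- bf$fst
    se[i, j] <- se[j, i] <- bf$se
    ns[i, j] <- ns[j, i] <- bf$n_sites
    rows[[length(rows) + 1L]] <- data.frame(
      popA = pops[i], popB = pops[j], fst = bf$fst,
      linearized = slatkin_linearized(min(bf$fst, 1 - 1e-12)),
      se = bf$se, n_sites = bf$n_sites, stringsAsFactors = FALSE)
  }
  structure(list(
    populations = pops, fst = m, se = se, n_sites = ns,
    linearized = {
      lm_ <- suppressWarnings(slatkin_linearized(m)); diag(lm_) <- 0; lm_
    },
    fst_floored = pmax(m, 0),
    pairs = do.call(rbind, rows)
  ), class = "fst_matrix")
}

#' @export
print.fst_matrix <- function(x, ...) {
  v <- x$fst[upper.tri(x$fst)]
  cat(sprintf("fst_matrix: %d populations, %d pairs; F_ST mean %.3f, median %.3f, range [%.3f, %.3f]\n",
              length(x$populations), length(v), mean(v), stats::median(v),
              min(v), max(v)))
  invisible(x)
}

#' Geographic distance matrix between populations
#' @param popmap Coordinates table ([read_coords()]).
#' @return Symmetric km matrix with population dimnames.
#' @export
geo_distance_matrix <- function(popmap) {
  k <- nrow(popmap)
  m <- matrix(0, k, k, dimnames = list(popmap$population, popmap$population))
  for (i in seq_len(k)) {
    m[i, ] <- haversine_km(popmap$latitude[i], popmap$longitude[i],
                           popmap$latitude, popmap$longitude)
  }
  (m + t(m)) / 2
}

#' Environmental distance matrix from bioclimatic variables
#'
#' Each variable is centred and scaled to unit standard deviation across
#' populations, then pairwise Euclidean distances are computed.
#' Zero-variance variables are dropped with a warning; missing cells are
#' mean-imputed (logged).
#'
#' @param bioclim Table from [read_bioclim()].
#' @param vars Variable columns to use (default `bio1`..`bio19`).
#' @return Symmetric distance matrix with population dimnames.
#' @export
environmental_distance <- function(bioclim, vars = paste0("bio", 1:19)) {
  x <- as.matrix(bioclim[, vars, drop = FALSE])
  rownames(x) <- bioclim$population
  if (anyNA(x)) {
    message("environmental_distance: mean-imputing ", sum(is.na(x)), " missing cell(s)")
    for (j in seq_len(ncol(x))) x[is.na(x[, j]), j] <- mean(x[, j], na.rm = TRUE)
  }
  sds <- apply(x, 2L, stats::sd)
  if (any(sds == 0)) {
    warning("dropping zero-variance variable(s): ",
            paste(colnames(x)[sds == 0], collapse = ", "))
    x <- x[, sds > 0, drop = FALSE]
  }
  as.matrix(stats::dist(scale(x)))
}

# Upper-triangle pair classification against cluster labels.
pair_subset_mask <- function(pops, cluster_of, subset) {
  k <- length(pops)
  same <- outer(cluster_of[pops], cluster_of[pops], "==")
  ut <- upper.tri(same)
  switch(subset,
         all = ut,
         `within-cluster` = ut & same,
         `between-cluster` = ut & !same,
         stop("unknown subset: ", subset))
}

#' Isolation-by-distance test
#'
#' Spearman rank correlation between the upper-triangle entries of a
#' differentiation matrix and a companion distance matrix, over all pairs or
#' a within-/between-cluster subset. Plain rank correlation mirrors common
#' reporting practice; an optional Mantel permutation test (via `vegan`)
#' accounts for pair non-independence.
#'
#' @param fst_mat Symmetric matrix (F_ST or linearized) with population dimnames.
#' @param dist_mat Symmetric distance matrix, same populations.
#' @param subset `"all"`, `"within-cluster"` or `"between-cluster"`.
#' @param cluster_of Named vector population -> cluster (needed unless
#'   `subset = "all"`).
#' @param mantel If `TRUE`, also run `vegan::mantel` (Spearman, 999
#'   permutations) and report its p-value as `mantel_p`.
#' @return List with `rho`, `p`, `n_pairs` (and `mantel_p` if requested).
#' @export
ibd_test <- function(fst_mat, dist_mat, subset = "all", cluster_of = NULL,
                     mantel = FALSE) {
  stopifnot(identical(dim(fst_mat), dim(dist_mat)))
  pops <- rownames(fst_mat)
  mask <- if (subset == "all") upper.tri(fst_mat)
          else pair_subset_mask(pops, cluster_of, subset)
  x <- fst_mat[mask]; y <- dist_mat[mask]
  if (sum(is.finite(x) & is.finite(y)) < 3L) stop("fewer than 3 usable pairs")
  sp <- spearman_or_na(x, y)
  out <- list(rho = sp$rho, p = sp$p, n_pairs = sp$n)
  if (mantel && subset == "all") {
    if (!requireNamespace("vegan", quietly = TRUE)) {
      warning("vegan not available; skipping Mantel test")
    } else {
      mt <- vegan::mantel(stats::as.dist(fst_mat), stats::as.dist(dist_mat),
                          method = "spearman", permutations = 999)
      out$mantel_p <- mt$signif
      message("ibd_test: Mantel permutation p = ", mt$signif)
    }
  }
  out
}

#' Within- vs between-cluster differentiation contrast
#'
#' Two-sample Kolmogorov-Smirnov comparison of within-cluster versus
#' between-cluster pairwise F_ST values.
#'
#' @param fst_mat Symmetric F_ST matrix with population dimnames.
#' @param cluster_of Named vector population -> cluster label.
#' @return List with `ks_statistic`, `p`, and per-set means/medians.
#' @export
cluster_contrast <- function(fst_mat, cluster_of) {
  pops <- rownames(fst_mat)
  sizes <- table(cluster_of[pops])
  if (any(sizes < 2L)) {
    stop("cluster(s) with < 2 populations have an empty within set; ",
         "both pair sets must be non-empty: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  }
  within <- fst_mat[pair_subset_mask(pops, cluster_of, "within-cluster")]
  between <- fst_mat[pair_subset_mask(pops, cluster_of, "between-cluster")]
  if (!length(within) || !length(between)) {
    stop("need non-empty within- and between-cluster pair sets (each cluster >= 2 populations)")
  }
  ks <- suppressWarnings(stats::ks.test(within, between))
  list(ks_statistic = unname(ks$statistic), p = ks$p.value,
       mean_within = mean(within), median_within = stats::median(within),
       mean_between = mean(between), median_between = stats::median(between),
       n_within = length(within), n_between = length(between))
}
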