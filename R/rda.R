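# Climate characterization and redundancy-analysis (RDA) variance
# partitioning of genotypes against climate, geography and neutral
# population structure.

#' Principal-component scores on near-neutral (fourfold-degenerate) sites
#'
#' Restricts the panel to the listed sites, mean-imputes missing dosages,
#' centres columns and takes the leading left singular vectors; the scores
#' summarise neutral population structure for use as RDA conditions.
#'
#' @param panel A `genotype_panel`.
#' @param fourfold_sites `data.frame` with `chrom`, `pos` (e.g. from
#'   [read_fourfold()]).
#' @param n_pcs Number of components.
#' @return Numeric matrix (individuals x `n_pcs`), rownames = sample ids.
#' @export
neutral_pcs <- function(panel, fourfold_sites, n_pcs = 2) {
  key <- paste(panel$sites$chrom, panel$sites$pos)
  want <- paste(fourfold_sites$chrom, fourfold_sites$pos)
  idx <- which(key %in% want)
  if (!length(idx)) stop("no overlap between the fourfold site list and the panel")
  if (length(panel$sample_ids) < n_pcs + 1L) stop("too few individuals for ", n_pcs, " PCs")
  x <- panel$dosage[, idx, drop = FALSE]
  storage.mode(x) <- "double"
  for (j in seq_len(ncol(x))) {
    m <- mean(x[, j], na.rm = TRUE)
    x[is.na(x[, j]), j] <- m
  }
  x <- scale(x, center = TRUE, scale = FALSE)
  if (all(abs(x) < 1e-12)) stop("neutral sites carry no variance among individuals")
  sv <- svd(x, nu = n_pcs, nv = 0)
  scores <- sv$u %*% diag(sv$d[seq_len(n_pcs)], n_pcs)
  dimnames(scores) <- list(panel$sample_ids, paste0("PC", seq_len(n_pcs)))
  scores
}

# Column-centre a numeric matrix/data.frame.
as_centered_matrix <- function(x) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  scale(x, center = TRUE, scale = FALSE)
}

# Residualize y on covariates (with intercept); covariates NULL -> centring only.
residualize <- function(y, covariates = NULL) {
  y <- as_centered_matrix(y)
  if (is.null(covariates) || ncol(as.matrix(covariates)) == 0L) return(y)
  z <- as_centered_matrix(covariates)
  qr_z <- qr(z)
  y - qr.fitted(qr_z, y)
}

#' Partial redundancy analysis by explicit projection
#'
#' Conditions are removed from both response and predictors by
#' ordinary-least-squares residualization; the constrained variance is the
#' squared norm of the projection of the response residuals onto the column
#' space of the predictor residuals. `R^2` is taken relative to the total
#' variance of the condition-residualized response; the adjusted value uses
#' the Ezekiel correction `1 - (1 - R^2)(n - 1)/(n - p - 1)` with `p` the
#' (post-residualization) predictor rank. The p-value comes from free row
#' permutation of the predictor residuals.
#'
#' @param response Numeric matrix (rows = individuals); centred internally.
#' @param predictors Numeric matrix/data.frame, same rows.
#' @param conditions Optional matrix/data.frame of conditioning covariates.
#' @param n_perm Number of permutations (0 skips the test).
#' @param seed Seed for the permutation draw.
#' @return List with `r2`, `adj_r2`, `p`, `rank`, `n`.
#' @export
partial_rda <- function(response, predictors, conditions = NULL,
                        n_perm = 999, seed = 1) {
  y <- residualize(response, conditions)
  x <- residualize(predictors, conditions)
  n <- nrow(y)
  stopifnot(nrow(x) == n)
  qr_x <- qr(x)
  p_rank <- qr_x$rank
  if (p_rank < ncol(x)) {
    message("partial_rda: predictors rank-deficient after residualization (rank ",
            p_rank, " of ", ncol(x), ")")
  }
  ss_tot <- sum(y^2)
  if (ss_tot == 0) stop("response has no variance after conditioning")
  stat <- function(xm) {
    f <- qr.fitted(qr(xm), y)
    sum(f^2) / ss_tot
  }
  r2 <- sum(qr.fitted(qr_x, y)^2) / ss_tot
  adj <- if (n - p_rank - 1L > 0L) 1 - (1 - r2) * (n - 1) / (n - p_rank - 1)
         else NA_real_
  p_val <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    exceed <- 0L
    for (b in seq_len(n_perm)) {
      if (stat(x[sample.int(n), , drop = FALSE]) >= r2) exceed <- exceed + 1L
    }
    p_val <- (1 + exceed) / (n_perm + 1)
  }
  list(r2 = r2, adj_r2 = adj, p = p_val, rank = p_rank, n = n)
}

#' Forward selection of constraining variables for RDA
#'
#' Greedy addition of the candidate giving the largest adjusted-`R^2`
#' increase, with the double stopping rule: stop when the best candidate's
#' permutation p-value (conditioned on the already-selected set) reaches
#' `alpha`, or when the cumulative adjusted `R^2` would exceed `stop_r2`
#' (by default the adjusted `R^2` of the model with all candidates).
#' Selection only starts if the global model with all candidates is itself
#' significant (`global_test`), the standard guard against the inflated
#' type-I error of picking the best of many candidates. Candidates nearly
#' collinear with the selected set (`R^2 >= 0.99` of the candidate on the
#' selected variables) are skipped with a warning.
#'
#' @param response Numeric response matrix (individuals x sites).
#' @param candidates `data.frame`/matrix of candidate variables (columns).
#' @param stop_r2 Adjusted-`R^2` ceiling; `NULL` = full-model value.
#' @param alpha Permutation-p entry threshold.
#' @param n_perm Permutations per entry test.
#' @param seed Seed.
#' @param global_test Require the all-candidate model to pass the
#'   permutation test at `alpha` before any selection.
#' @return `data.frame` with one row per selected variable: `variable`,
#'   `adj_r2_cum`, `p`; zero rows when nothing qualifies.
#' @export
forward_select <- function(response, candidates, stop_r2 = NULL, alpha = 0.05,
                           n_perm = 999, seed = 1, global_test = TRUE) {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) < 2L) stop("need at least 2 candidate variables")
  empty <- data.frame(variable = character(0), adj_r2_cum = numeric(0),
                      p = numeric(0), stringsAsFactors = FALSE)
  if (global_test) {
    g <- partial_rda(response, candidates,
                     n_perm = n_perm, seed = substream_seed(seed, "fwd-global"))
    if (is.na(g$p) || g$p >= alpha) return(empty)
    if (is.null(stop_r2)) stop_r2 <- g$adj_r2
  }
  if (is.null(stop_r2)) {
    stop_r2 <- partial_rda(response, candidates, n_perm = 0)$adj_r2
  }
  selected <- character(0)
  steps <- list()
  repeat {
    remaining <- setdiff(names(candidates), selected)
    if (!length(remaining)) break
    cond <- if (length(selected)) candidates[selected] else NULL
    fits <- vapply(remaining, function(v) {
      if (length(selected)) {
        r2v <- partial_rda(candidates[[v]], candidates[selected],
                           n_perm = 0)$r2
        if (is.finite(r2v) && r2v >= 0.99) {
          warning("skipping near-collinear candidate: ", v)
          return(NA_real_)
        }
      }
      partial_rda(response, candidates[c(selected, v)], n_perm = 0)$adj_r2
    }, numeric(1))
    if (all(is.na(fits))) break
    best <- remaining[which.max(fits)]
    pv <- tryCatch(
      partial_rda(response, candidates[[best]], cond,
                  n_perm = n_perm,
                  seed = substream_seed(seed, paste0("fwd-", best)))$p,
      error = function(e) 1)  # nothing left to explain after conditioning
    if (pv >= alpha) break
    # the adjusted-R^2 ceiling applies from the second step on: noise
    # candidates can drag the full model's adjusted R^2 below that of the
    # single best predictor, and the global gate plus the entry test already
    # certify the first variable
    if (length(selected) && is.finite(stop_r2) && fits[best] > stop_r2) break
    selected <- c(selected, best)
    steps[[best]] <- data.frame(variable = best, adj_r2_cum = fits[best],
                                p = pv, stringsAsFactors = FALSE)
    if (partial_rda(response, candidates[selected], n_perm = 0)$r2 >
        1 - 1e-10) break  # response fully explained
  }
  if (!length(steps)) return(empty)
  do.call(rbind, steps)
}

#' Four-model RDA variance partitioning
#'
#' Fits the full model (climate + neutral structure + geography as
#' predictors) and the three pure models in which one block is the
#' predictor and the other two are conditions, reporting adjusted `R^2` and
#' permutation p per model and flagging the best model by adjusted `R^2`.
#'
#' @param genotypes Individual-level response matrix (centred internally).
#' @param climate_vars Selected bioclim columns per individual.
#' @param neutral_pcs Neutral-structure PC scores per individual.
#' @param lat_lon Two-column matrix of latitude/longitude per individual.
#' @param n_perm Permutations per model.
#' @param seed Seed.
#' @return List of class `rda_report`: `model_table` (`data.frame`) and
#'   `best_model`.
#' @export
variance_partition <- function(genotypes, climate_vars, neutral_pcs, lat_lon,
                               n_perm = 999, seed = 1) {
  blocks <- list(climate = as.matrix(climate_vars),
                 structure = as.matrix(neutral_pcs),
                 geography = as.matrix(lat_lon))
  for (nm in names(blocks)) {
    if (any(apply(blocks[[nm]], 2L, stats::sd) == 0)) {
      stop("constant column in block: ", nm)
    }
  }
  fit <- function(pred, cond, tag) {
    partial_rda(genotypes, pred, cond, n_perm = n_perm,
                seed = substream_seed(seed, paste0("vp-", tag)))
  }
  full <- fit(do.call(cbind, blocks), NULL, "full")
  pure <- lapply(names(blocks), function(nm) {
    fit(blocks[[nm]], do.call(cbind, blocks[setdiff(names(blocks), nm)]), nm)
  })
  names(pure) <- names(blocks)
  tab <- data.frame(
    model = c("full", paste0(names(blocks), "-pure")),
    r2 = c(full$r2, vapply(pure, `[[`, numeric(1), "r2")),
    adj_r2 = c(full$adj_r2, vapply(pure, `[[`, numeric(1), "adj_r2")),
    p = c(full$p, vapply(pure, `[[`, numeric(1), "p")),
    stringsAsFactors = FALSE
  )
  structure(list(model_table = tab,
                 best_model = tab$model[which.max(tab$adj_r2)]),
            class = "rda_report")
}

#' @export
print.rda_report <- function(x, ...) {
  cat("RDA variance partitioning (adjusted R^2, permutation p):\n")
  print(x$model_table, row.names = FALSE)
  cat("best model:", x$best_model, "\n")
  invisible(x)
}

#' Climate gradient along an expansion route
#'
#' Spearman correlation of one bioclimatic variable against haversine
#' distance from an entry population; thin wrapper over
#' [gradient_correlation()].
#'
#' @param bioclim Bioclim table ([read_bioclim()]).
#' @param variable Column name, e.g. `"bio9"`.
#' @param entry_population Entry population label.
#' @param popmap Coordinates table.
#' @param cluster Optional cluster subset.
#' @return List with `rho`, `p`, `n`.
#' @export
route_correlation <- function(bioclim, variable, entry_population, popmap,
                              cluster = NULL) {
  vals <- stats::setNames(bioclim[[variable]], bioclim$population)
  gradient_correlation(vals, entry_population, popmap, cluster = cluster)
}

#' Wilcoxon rank-sum contrasts of bioclim variables between clusters
#'
#' Two-sided Wilcoxon rank-sum test per variable between two population
#' clusters, with the count of variables significant at `threshold`.
#'
#' @param bioclim Bioclim table.
#' @param cluster_of Named vector population -> cluster label (exactly two
#'   cluster levels used).
#' @param vars Variables to test.
#' @param threshold Significance threshold for the summary count.
#' @return List with `table` (`variable`, `statistic`, `p`,
#'   `median_diff`) and `n_significant`.
#' @export
cluster_bioclim_tests <- function(bioclim, cluster_of,
                                  vars = paste0("bio", 1:19),
                                  threshold = 0.05) {
  cl <- cluster_of[bioclim$population]
  lev <- unique(stats::na.omit(cl))
  if (length(lev) != 2L) stop("need exactly two clusters, got: ",
                              paste(lev, collapse = ", "))
  rows <- lapply(vars, function(v) {
    a <- bioclim[[v]][cl == lev[1L]]
    b <- bioclim[[v]][cl == lev[2L]]
    if (length(unique(c(a, b))) == 1L) {
      warning("all-tied variable: ", v)
      return(data.frame(variable = v, statistic = NA_real_, p = 1,
                        median_diff = 0, stringsAsFactors = FALSE))
    }
    wt <- suppressWarnings(stats::wilcox.test(a, b))
    data.frame(variable = v, statistic = unname(wt$statistic), p = wt$p.value,
               median_diff = stats::median(a) - stats::median(b),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  list(table = tab, n_significant = sum(tab$p < threshold),
       clusters = lev)
}
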