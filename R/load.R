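# GERP-based genetic load: per-individual totals, highly deleterious
# counts, fixed/segregating partition per group, missingness exclusion and
# load correlates.

# Join a GERP track onto panel sites; returns score vector (NA where the
# track has no entry for the site).
join_gerp <- function(panel, gerp) {
  key <- paste(panel$sites$chrom, panel$sites$pos)
  sc <- gerp$score[match(key, paste(gerp$chrom, gerp$pos))]
  if (all(is.na(sc))) stop("no site overlap between the panel and the GERP track")
  n_unscored <- sum(is.na(sc))
  if (n_unscored) message("load: ", n_unscored, " site(s) without a GERP score skipped")
  sc
}

#' Exclude samples with high missingness
#'
#' Removes samples whose per-sample missing fraction is strictly above the
#' empirical `quantile` of the per-sample missingness distribution (type-7
#' quantile); the threshold value is logged.
#'
#' @param panel A `genotype_panel`.
#' @param quantile Quantile of the missingness distribution (default 0.95).
#' @return List with `panel` (filtered), `excluded` (sample ids) and
#'   `threshold`.
#' @export
exclude_high_missing <- function(panel, quantile = 0.95) {
  mf <- row_missing_frac(panel$dosage)
  thr <- stats::quantile(mf, quantile, names = FALSE)
  drop <- mf > thr
  message(sprintf("exclude_high_missing: threshold %.4f%% missing; %d sample(s) excluded",
                  100 * thr, sum(drop)))
  out <- if (any(drop)) subset_panel(panel, samples = which(!drop)) else panel
  list(panel = out, excluded = panel$sample_ids[drop], threshold = thr)
}

#' Total genetic load per individual
#'
#' `total_load(sample) = sum_s gerp_s * dosage(sample, s)` over scored
#' sites, skipping missing calls (which contribute 0; no rescaling by
#' callable sites). The panel must be polarized so dosages count derived
#' alleles. A presence/absence mode counts each site's GERP once when any
#' derived allele is present.
#'
#' @param panel Polarized `genotype_panel`.
#' @param gerp GERP track ([read_gerp()]).
#' @param mode `"dosage"` (default) or `"presence"`.
#' @return Named numeric vector of loads per sample.
#' @export
individual_load <- function(panel, gerp, mode = c("dosage", "presence")) {
  stopifnot(inherits(panel, "genotype_panel"))
  mode <- match.arg(mode)
  if (!panel$polarized) stop("panel must be polarized (derived-coded) for load accounting")
  sc <- join_gerp(panel, gerp)
  use <- !is.na(sc)
  d <- panel$dosage[, use, drop = FALSE]
  if (mode == "presence") d <- (d > 0) * 1L
  storage.mode(d) <- "double"
  d[is.na(d)] <- 0
  as.vector(d %*% sc[use]) |> stats::setNames(panel$sample_ids)
}

#' Count of highly deleterious derived alleles per individual
#'
#' Dosage-summed derived alleles at sites with GERP score strictly greater
#' than `threshold`.
#'
#' @param panel Polarized `genotype_panel`.
#' @param gerp GERP track.
#' @param threshold GERP cutoff (strict `>`), default 5.
#' @return Named integer vector per sample.
#' @export
high_deleterious_count <- function(panel, gerp, threshold = 5) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!panel$polarized) stop("panel must be polarized (derived-coded)")
  sc <- join_gerp(panel, gerp)
  use <- !is.na(sc) & sc > threshold
  d <- panel$dosage[, use, drop = FALSE]
  cnt <- rowSums(d, na.rm = TRUE)
  stats::setNames(as.integer(cnt), panel$sample_ids)
}

#' Fixed/segregating load partition per group
#'
#' Within each group, sites are classified on non-missing calls as
#' derived-fixed (frequency 1), ancestral-fixed (frequency 0) or
#' segregating; classification is group-relative. The group's fixed load is
#' `sum(2 * gerp)` over its derived-fixed sites; each sample's segregating
#' load is `sum(gerp * dosage)` over the group's segregating sites. With
#' complete data, `fixed_load(group) + seg_load(sample) = total_load`.
#'
#' @param panel Polarized `genotype_panel`.
#' @param gerp GERP track.
#' @param group_of Named vector sample -> group label (each group needs
#'   >= 2 samples).
#' @return List with `groups` (`data.frame`: group, fixed_load,
#'   n_fixed_derived, n_fixed_ancestral, n_seg, n_unclassified) and
#'   `samples` (`data.frame`: sample, group, seg_load).
#' @export
partition_load <- function(panel, gerp, group_of) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!panel$polarized) stop("panel must be polarized (derived-coded)")
  sc <- join_gerp(panel, gerp)
  use <- which(!is.na(sc))
  groups <- unique(unname(group_of[panel$sample_ids]))
  small <- names(which(table(group_of[panel$sample_ids]) < 2L))
  if (length(small)) stop("group(s) with < 2 samples: ", paste(small, collapse = ", "))
  grows <- list(); srows <- list()
  for (g in groups) {
    ids <- panel$sample_ids[group_of[panel$sample_ids] == g]
    d <- panel$dosage[ids, use, drop = FALSE]
    n_obs <- colSums(!is.na(d))
    freq <- colSums(d, na.rm = TRUE) / (2 * n_obs)
    unclassified <- n_obs == 0L
    if (any(unclassified)) {
      message("partition_load: group ", g, ": ", sum(unclassified),
              " site(s) with all calls missing left unclassified")
    }
    fixed_d <- !unclassified & freq == 1
    fixed_a <- !unclassified & freq == 0
    seg <- !unclassified & !fixed_d & !fixed_a
    fixed_load <- sum(2 * sc[use][fixed_d])
    dseg <- d[, seg, drop = FALSE]
    storage.mode(dseg) <- "double"
    dseg[is.na(dseg)] <- 0
    seg_load <- as.vector(dseg %*% sc[use][seg])
    grows[[g]] <- data.frame(group = g, fixed_load = fixed_load,
                             n_fixed_derived = sum(fixed_d),
                             n_fixed_ancestral = sum(fixed_a),
                             n_seg = sum(seg),
                             n_unclassified = sum(unclassified),
                             stringsAsFactors = FALSE)
    srows[[g]] <- data.frame(sample = ids, group = g, seg_load = seg_load,
                             stringsAsFactors = FALSE)
  }
  list(groups = do.call(rbind, grows), samples = do.call(rbind, srows))
}

#' Per-sample load table
#'
#' Combines total load, highly deleterious counts, segregating load and
#' missingness into one table.
#'
#' @param panel Polarized `genotype_panel` (after
#'   [exclude_high_missing()] if desired).
#' @param gerp GERP track.
#' @param group_of Named vector sample -> group.
#' @param high_threshold GERP cutoff for the highly deleterious count.
#' @return `data.frame`: sample, population, group, total_load,
#'   high_del_count, seg_load, missing_frac.
#' @export
load_table <- function(panel, gerp, group_of, high_threshold = 5) {
  tot <- individual_load(panel, gerp)
  hd <- high_deleterious_count(panel, gerp, high_threshold)
  part <- partition_load(panel, gerp, group_of)
  seg <- stats::setNames(part$samples$seg_load, part$samples$sample)
  data.frame(
    sample = panel$sample_ids,
    population = unname(panel$pop_of_sample[panel$sample_ids]),
    group = unname(group_of[panel$sample_ids]),
    total_load = unname(tot),
    high_del_count = unname(hd),
    seg_load = unname(seg[panel$sample_ids]),
    missing_frac = unname(row_missing_frac(panel$dosage)),
    stringsAsFactors = FALSE
  )
}

#' Correlates of genetic load: route distance, climate, group contrasts
#'
#' Spearman correlations of per-individual total load against haversine
#' distance from each entry point and against selected bioclim variables
#' (population values broadcast to individuals), plus pairwise
#' Kolmogorov-Smirnov contrasts of the load distributions between groups.
#'
#' @param load_tab `data.frame` from [load_table()].
#' @param popmap Coordinates table.
#' @param entry_points Named character vector of entry population labels,
#'   e.g. `c(south = "S01", north = "N01")`.
#' @param bioclim Optional bioclim table; correlations are computed for
#'   `bioclim_vars`.
#' @param bioclim_vars Bioclim columns to correlate with load.
#' @return List with `correlations` (`data.frame`: pairing, rho, p, n) and
#'   `group_contrasts` (`data.frame`: groupA, groupB, ks_statistic, p).
#' @export
load_correlates <- function(load_tab, popmap, entry_points, bioclim = NULL,
                            bioclim_vars = character(0)) {
  co <- popmap[match(load_tab$population, popmap$population), ]
  rows <- list()
  for (nm in names(entry_points)) {
    e <- popmap[popmap$population == entry_points[[nm]], ]
    if (!nrow(e)) stop("entry population missing from coordinates: ", entry_points[[nm]])
    dist_km <- haversine_km(co$latitude, co$longitude, e$latitude, e$longitude)
    sp <- spearman_or_na(load_tab$total_load, dist_km)
    rows[[length(rows) + 1L]] <- data.frame(
      pairing = paste0("total_load~distance_", nm), rho = sp$rho, p = sp$p,
      n = sp$n, stringsAsFactors = FALSE)
  }
  for (v in bioclim_vars) {
    vals <- bioclim[[v]][match(load_tab$population, bioclim$population)]
    sp <- spearman_or_na(load_tab$total_load, vals)
    rows[[length(rows) + 1L]] <- data.frame(
      pairing = paste0("total_load~", v), rho = sp$rho, p = sp$p, n = sp$n,
      stringsAsFactors = FALSE)
  }
  gl <- split(load_tab$total_load, load_tab$group)
  gn <- names(gl)
  kc <- list()
  if (length(gn) >= 2L) {
    for (i in seq_len(length(gn) - 1L)) for (j in seq((i + 1L), length(gn))) {
      ks <- suppressWarnings(stats::ks.test(gl[[i]], gl[[j]]))
      kc[[length(kc) + 1L]] <- data.frame(
        groupA = gn[i], groupB = gn[j],
        ks_statistic = unname(ks$statistic), p = ks$p.value,
        stringsAsFactors = FALSE)
    }
  }
  list(correlations = do.call(rbind, rows),
       group_contrasts = if (length(kc)) do.call(rbind, kc) else NULL)
}
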