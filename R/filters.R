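# Site filtering, LD pruning and ancestral-allele polarization.

#' Filter sites by type, array quality class and missingness
#'
#' Applies, in order: indel removal, biallelic-only, quality-class whitelist
#' (array classifications such as `PolyHighResolution`, `MonoHighResolution`,
#' `NoMinorHom`), per-site missing-fraction cap, and optional removal of
#' monomorphic sites. Per-rule attrition counts are attached as the
#' `"attrition"` attribute and logged.
#'
#' @param panel A `genotype_panel`.
#' @param quality_whitelist Character vector of accepted quality classes, or
#'   `NULL` to skip quality filtering.
#' @param drop_indels Drop sites whose REF or ALT is not a single base.
#' @param biallelic_only Drop records flagged multi-allelic.
#' @param max_site_missing Maximum tolerated per-site missing fraction.
#' @param drop_monomorphic Also remove sites with no variation among
#'   non-missing calls.
#' @return Filtered `genotype_panel` with an `"attrition"` attribute.
#' @export
filter_sites <- function(panel, quality_whitelist = NULL, drop_indels = TRUE,
                         biallelic_only = TRUE, max_site_missing = 1,
                         drop_monomorphic = FALSE) {
  stopifnot(inherits(panel, "genotype_panel"))
  if (!is.null(quality_whitelist) && !length(quality_whitelist)) {
    stop("quality_whitelist must be non-empty when quality filtering is enabled")
  }
  s <- panel$sites
  keep <- rep(TRUE, nrow(s))
  attrition <- c(indel = 0L, multiallelic = 0L, quality = 0L,
                 missingness = 0L, monomorphic = 0L)

  if (drop_indels) {
    is_indel <- nchar(s$ref) != 1L |
      (nchar(s$alt) != 1L & !grepl(",", s$alt, fixed = TRUE)) |
      vapply(strsplit(s$alt, ",", fixed = TRUE),
             function(a) any(nchar(a) != 1L), logical(1))
    attrition["indel"] <- sum(keep & is_indel)
    keep <- keep & !is_indel
  }
  if (biallelic_only) {
    multi <- if ("multiallelic" %in% names(s)) s$multiallelic
             else grepl(",", s$alt, fixed = TRUE)
    attrition["multiallelic"] <- sum(keep & multi)
    keep <- keep & !multi
  }
  if (!is.null(quality_whitelist)) {
    qok <- !is.na(s$quality_class) & s$quality_class %in% quality_whitelist
    attrition["quality"] <- sum(keep & !qok)
    keep <- keep & qok
  }
  miss <- colMeans(is.na(panel$dosage))
  mok <- miss <= max_site_missing
  attrition["missingness"] <- sum(keep & !mok)
  keep <- keep & mok
  if (drop_monomorphic) {
    mono <- apply(panel$dosage, 2L, function(d) {
      d <- d[!is.na(d)]
      length(d) == 0L || all(d == 0L) || all(d == 2L)
    })
    attrition["monomorphic"] <- sum(keep & mono)
    keep <- keep & !mono
  }
  if (!any(keep)) {
    stop("all sites removed by filters; attrition: ",
         paste(names(attrition), attrition, sep = "=", collapse = ", "))
  }
  out <- subset_panel(panel, sites = which(keep))
  attr(out, "attrition") <- attrition
  message(sprintf("filter_sites: %d -> %d sites (%s)", nrow(s), sum(keep),
                  paste(names(attrition), attrition, sep = "=", collapse = ", ")))
  out
}

#' LD-prune a genotype panel with sliding windows
#'
#' Within each sliding window, site pairs with squared genotype correlation
#' above `r2_max` lose the later site; the scan repeats `n_iter` times or
#' until no further site is removed. Windows are counted in variants by
#' default (the convention of array-data pruning routines); a base-pair mode
#' is available.
#'
#' @param panel A `genotype_panel`.
#' @param window Window size (variants, or bp when `unit = "bp"`).
#' @param step Step size between window starts, same unit.
#' @param n_iter Maximum number of passes.
#' @param r2_max Squared-correlation threshold in [0, 1].
#' @param unit `"variants"` (default) or `"bp"`.
#' @return Pruned `genotype_panel`.
#' @export
ld_prune <- function(panel, window = 500, step = 200, n_iter = 5,
                     r2_max = 0.1, unit = c("variants", "bp")) {
  stopifnot(inherits(panel, "genotype_panel"))
  unit <- match.arg(unit)
  if (r2_max < 0 || r2_max > 1) stop("r2_max must be in [0, 1]")
  if (!(window >= step && step >= 1)) stop("need window >= step >= 1")
  if (n_iter < 1) stop("n_iter must be >= 1")

  keep <- rep(TRUE, nrow(panel$sites))
  chroms <- panel$sites$chrom
  for (iter in seq_len(n_iter)) {
    removed_this_pass <- FALSE
    for (ch in unique(chroms)) {
      idx_all <- which(chroms == ch)
      idx <- idx_all[keep[idx_all]]
      if (length(idx) < 2L) next
      wins <- if (unit == "variants") {
        starts <- seq(1L, length(idx), by = step)
        lapply(starts, function(s0) idx[s0:min(s0 + window - 1L, length(idx))])
      } else {
        pos <- panel$sites$pos[idx]
        starts <- seq(min(pos), max(pos), by = step)
        lapply(starts, function(s0) idx[pos >= s0 & pos < s0 + window])
      }
      for (w in wins) {
        w <- w[keep[w]]
        if (length(w) < 2L) next
        d <- panel$dosage[, w, drop = FALSE]
        r2 <- suppressWarnings(stats::cor(d, use = "pairwise.complete.obs"))^2
        for (i in seq_len(length(w) - 1L)) {
          if (!keep[w[i]]) next
          for (j in seq((i + 1L), length(w))) {
            if (!keep[w[j]]) next
            if (is.finite(r2[i, j]) && r2[i, j] > r2_max) {
              keep[w[j]] <- FALSE
              removed_this_pass <- TRUE
            }
          }
        }
      }
    }
    if (!removed_this_pass) break
  }
  subset_panel(panel, sites = which(keep))
}

#' Polarize dosages to the ancestral allele
#'
#' Sites with an unknown ancestral allele are dropped (count logged). Where
#' the ancestral allele equals ALT, dosages are flipped `d -> 2 - d`
#' (missing preserved) and the REF/ALT labels are swapped so dosages always
#' count derived alleles afterwards. Sites whose annotated ancestral allele
#' matches neither REF nor ALT are dropped with a warning count.
#'
#' @param panel A `genotype_panel`.
#' @return Polarized `genotype_panel` (`polarized = TRUE`); attribute
#'   `"polarization"` holds counts of kept/flipped/dropped sites.
#' @export
polarize_to_ancestral <- function(panel) {
  stopifnot(inherits(panel, "genotype_panel"))
  s <- panel$sites
  unknown <- is.na(s$ancestral)
  mismatch <- !unknown & s$ancestral != s$ref & s$ancestral != s$alt
  keep <- !unknown & !mismatch
  if (!any(keep)) stop("no site with a usable ancestral allele")
  if (any(mismatch)) {
    warning(sum(mismatch), " site(s) dropped: ancestral allele matches neither REF nor ALT")
  }
  message(sprintf("polarize: %d kept, %d unknown-ancestral dropped, %d mismatched dropped",
                  sum(keep), sum(unknown), sum(mismatch)))
  out <- subset_panel(panel, sites = which(keep))
  flip <- out$sites$ancestral == out$sites$alt
  if (any(flip)) {
    out$dosage[, flip] <- 2L - out$dosage[, flip, drop = FALSE]
    ref <- out$sites$ref[flip]
    out$sites$ref[flip] <- out$sites$alt[flip]
    out$sites$alt[flip] <- ref
  }
  out$polarized <- TRUE
  attr(out, "polarization") <- c(kept = sum(keep), flipped = sum(flip),
                                 unknown = sum(unknown), mismatched = sum(mismatch))
  out
}
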